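test_that("residualization reproduces least squares exactly", {
  st <- sharedStudy()
  traits <- st@traits
  res <- residualizeTrait(traits, "Q1", c("age", "smoke"))
  expect_lt(abs(mean(res@residuals)), 1e-8)
  ref <- resid(lm(Q1 ~ age + smoke, data = traits))
  expect_equal(unname(res@residuals), unname(ref), tolerance = 1e-10)

  # covariate-free call: deviations from the grand mean
  r0 <- residualizeTrait(traits, "Q1")
  expect_equal(unname(r0@residuals), traits$Q1 - mean(traits$Q1),
               tolerance = 1e-10)

  # trait equal to its covariate fit: all residuals zero
  tt <- traits; tt$Q1 <- 1.5 + 0.2 * tt$age
  rz <- residualizeTrait(tt, "Q1", "age")
  expect_true(all(abs(rz@residuals) < 1e-10))
})

test_that("simulated age slope on the trait is recovered", {
  # the generator writes a 0.018/year age effect into every trait
  st <- sharedStudy()
  fit <- lm(Q1 ~ age + smoke, data = st@traits)
  se <- summary(fit)$coefficients["age", "Std. Error"]
  expect_lt(abs(coef(fit)[["age"]] - 0.018), 3 * se)
})

test_that("score scan matches the closed form for a two-sibling family", {
  sib <- sibPed(2)
  kin <- kinshipMatrix(sib)
  ibd <- geneDrop(sib, nLoci = 200, seed = 3)
  # standardized residuals (1, 1) for the sibs, parents unobserved
  traits <- data.frame(uid = pedTable(sib)$uid, fid = 1,
                       y = c(NA, NA, 1, -1))
  res <- residualizeTrait(traits, "y")
  # residuals of (1, -1) standardize to (0.707.., -0.707..): use raw scan
  sc <- qtScoreScan(res, ibd, sib, kin = kin, nDrops = 4000, seed = 5)
  pm <- as.numeric(ibdProportion(ibd, data.frame(uid1 = "s1", uid2 = "s2")))
  # N = r1*r2*(pi - 1/2) with r = (1,-1)/sd = (.707,-.707): s12 = -1/2
  expect_equal(sc$N, -0.5 * (pm - 0.5), tolerance = 1e-10)
  # Var(N) = s12^2 * Var(pi) = 1/32; Z = N/sqrt(1/32)
  expect_equal(sc$Z, sc$N / sqrt(1 / 32), tolerance = 0.1)
})

test_that("label-trick numerator equals the explicit pair sum", {
  st <- sharedStudy(); ped <- sharedPed(); kin <- sharedKin()
  res <- residualizeTrait(st@traits, "Q1", c("age", "smoke"))
  loci <- colnames(st@genotypes)[c(1, 57, 400)]
  sc <- qtScoreScan(res, st@ibd, ped, kin = kin, loci = loci,
                    nDrops = 500, seed = 5)
  # oracle: explicit sum over all within-family related pairs
  pairs <- relativePairs(ped, kin)
  pm <- ibdProportion(st@ibd, pairs)[, loci]
  r <- res@residuals[pedTable(ped)$uid]
  r[is.na(r)] <- 0
  w <- r / sd(res@residuals)
  s <- w[pairs$uid1] * w[pairs$uid2]
  direct <- as.numeric(t(pm - 2 * pairs$phi) %*% s)
  expect_equal(sc$N, direct, tolerance = 1e-8)
})

test_that("Z is invariant to affine transformation of the trait", {
  st <- sharedStudy(); ped <- sharedPed(); kin <- sharedKin()
  tr2 <- st@traits; tr2$Q1 <- 100 - 7 * tr2$Q1
  r1 <- residualizeTrait(st@traits, "Q1", c("age", "smoke"))
  r2 <- residualizeTrait(tr2, "Q1", c("age", "smoke"))
  loci <- colnames(st@genotypes)[1:20]
  s1 <- qtScoreScan(r1, st@ibd, ped, kin = kin, loci = loci,
                    nDrops = 1000, seed = 5)
  s2 <- qtScoreScan(r2, st@ibd, ped, kin = kin, loci = loci,
                    nDrops = 1000, seed = 5)
  expect_equal(s1$Z, s2$Z, tolerance = 1e-8)
})

test_that("family numerators sum to the pooled numerator", {
  st <- sharedStudy(); ped <- sharedPed(); kin <- sharedKin()
  res <- residualizeTrait(st@traits, "Q1", c("age", "smoke"))
  loci <- colnames(st@genotypes)[1:10]
  sc <- qtScoreScan(res, st@ibd, ped, kin = kin, loci = loci,
                    nDrops = 500, seed = 5)
  famZ <- attr(sc, "familyZ"); famVar <- attr(sc, "familyVar")
  famNum <- sweep(famZ, 2, sqrt(famVar), "*")
  expect_equal(rowSums(famNum), sc$N, tolerance = 1e-8)
})

test_that("degenerate residuals produce a flat null scan", {
  st <- sharedStudy(); ped <- sharedPed()
  tt <- st@traits; tt$flat <- 2 + 0.5 * tt$age
  res <- residualizeTrait(tt, "flat", "age")
  sc <- qtScoreScan(res, st@ibd, ped, kin = sharedKin(), nDrops = 10,
                    seed = 5, loci = colnames(st@genotypes)[1:5])
  expect_true(all(sc$N == 0) && all(sc$LOD == 0))
})

test_that("conditional scan on the causal variants collapses their LOD", {
  st <- sharedStudy(); ped <- sharedPed(); kin <- sharedKin()
  snps <- st@truth$snp[st@truth$trait == "Q1"]
  cs <- conditionalScan(st@traits, "Q1", c("age", "smoke"), st@genotypes,
                        snps, st@ibd, ped, kin = kin, loci = snps,
                        nDrops = 1500, seed = 5)
  # adjustment absorbs the variant effects: scores move toward the null
  expect_true(all(cs$LODafter <= pmax(cs$LODbefore, 0.5)))
  # adjusting for a monomorphic SNP leaves the scan identical
  g2 <- cbind(st@genotypes, MONO = 0L)
  expect_warning(
    cs2 <- conditionalScan(st@traits, "Q1", c("age", "smoke"), g2,
                           "MONO", st@ibd, ped, kin = kin, loci = snps[1],
                           nDrops = 500, seed = 5),
    "MONO")
  expect_equal(cs2$Zafter, cs2$Zbefore, tolerance = 1e-10)
  # unknown SNP id errors
  expect_error(residualizeTrait(st@traits, "Q1", "age", st@genotypes, "nope"),
               "unknown SNP")
})
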