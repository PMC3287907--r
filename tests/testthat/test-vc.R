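test_that("polygenic likelihood at h2 = 0 equals independent regression", {
  st <- sharedStudy(); kin <- sharedKin()
  tt <- st@traits
  withr::with_seed(8, tt$noise <- rnorm(nrow(tt)))
  fit <- fitPolygenic(tt, "noise", c("age"), kin)
  # reference: ML log-likelihood of the plain linear model (sigma_g = 0
  # makes the polygenic likelihood the independent-normal regression one)
  lmfit <- lm(noise ~ age, data = tt)
  ll0 <- pedscan:::.profileGaussian(0, matrix(tt$noise, ncol = 1),
                                    cbind(1, tt$age), rep(1, nrow(tt)))$nll
  expect_equal(-ll0, as.numeric(logLik(lmfit)), tolerance = 1e-6)
  # pure noise: estimated heritability collapses to the boundary
  expect_lt(fit@h2, 0.08)
})

test_that("heritability is recovered and scale-invariant", {
  # traits generated with h2 = 0.6; a handful of replicates for the mean
  cfg <- simConfig(nSNPs = 2, plantDichotomous = list(),
                   plantQuantitative = list())
  ped <- sharedPed(); kin <- sharedKin()
  h2 <- sapply(1:6, function(r) {
    st <- simulateStudy(cfg, seed = 5000 + r, ped = ped, kin = kin)
    fitPolygenic(st@traits, "Q1", c("age", "smoke"), kin)@h2
  })
  expect_lt(abs(mean(h2) - 0.6), 0.08)

  st <- sharedNullStudy()
  f1 <- fitPolygenic(st@traits, "Q1", c("age", "smoke"), kin)
  tt <- st@traits; tt$Q1 <- 3 + 12 * tt$Q1
  f2 <- fitPolygenic(tt, "Q1", c("age", "smoke"), kin)
  expect_equal(f1@h2, f2@h2, tolerance = 1e-4)
  expect_equal(f2@sigmaG / f1@sigmaG, 144, tolerance = 1e-3)
})

test_that("REML and ML agree closely at this sample size", {
  st <- sharedNullStudy(); kin <- sharedKin()
  ml <- fitPolygenic(st@traits, "Q1", c("age", "smoke"), kin, method = "ML")
  rm <- fitPolygenic(st@traits, "Q1", c("age", "smoke"), kin, method = "REML")
  expect_lt(abs(ml@h2 - rm@h2), 0.03)
})

test_that("founders-only samples flag unidentifiable genetic variance", {
  ped <- sharedPed(); kin <- sharedKin()
  st <- sharedNullStudy()
  tt <- st@traits[st@traits$uid %in% founders(ped), ]
  expect_warning(fit <- fitPolygenic(tt, "Q1", c("age"), kin),
                 "unidentifiable")
  expect_equal(fit@h2, 0)
  expect_false(fit@identifiable)
})

test_that("variance-explained accounting reproduces the printed arithmetic", {
  expect_equal(varianceExplained(0.615, 0.491), 12.4, tolerance = 1e-9)
  expect_equal(varianceExplained(0.814, 0.547), 26.7, tolerance = 1e-9)
  expect_equal(varianceExplained(0.5, 0.5), 0)
  # fit-based accounting: identical fits explain nothing
  st <- sharedNullStudy(); kin <- sharedKin()
  f <- fitPolygenic(st@traits, "Q1", c("age"), kin)
  expect_equal(varianceExplained(f, f), 0)
  # mismatched samples error
  f2 <- fitPolygenic(st@traits[-1, ], "Q1", c("age"), kin)
  expect_error(varianceExplained(f, f2), "same individuals")
})

test_that("adding causal variants as fixed effects lowers estimated h2", {
  st <- sharedStudy(); kin <- sharedKin()
  snps <- st@truth$snp[st@truth$trait == "Q1"]
  f0 <- fitPolygenic(st@traits, "Q1", c("age", "smoke"), kin)
  f1 <- fitPolygenic(st@traits, "Q1", c("age", "smoke"), kin,
                     genotypes = st@genotypes, adjustSNPs = snps)
  expect_gt(varianceExplained(f0, f1), 0)
  expect_gt(f1@snpVariance, 0)
})

test_that("bivariate fit respects bounds and reduces to univariate fits", {
  st <- sharedNullStudy(); kin <- sharedKin()
  # identical traits: genetic correlation pegs at the upper boundary
  tt <- st@traits; tt$Q1b <- tt$Q1
  same <- fitBivariate(tt, "Q1", "Q1b", c("age"), kin)
  expect_gt(same@rG, 0.98)
  # with cross-covariances fixed at zero, the log-likelihood equals the sum
  # of the two univariate model log-likelihoods
  biv0 <- fitBivariate(st@traits, "Q1", "Q4", c("age"), kin,
                       fixRG = 0, fixRE = 0)
  u1 <- fitPolygenic(st@traits, "Q1", c("age"), kin)
  u4 <- fitPolygenic(st@traits, "Q4", c("age"), kin)
  expect_equal(biv0@logLik, u1@logLik + u4@logLik, tolerance = 1e-3)
})

test_that("generator genetic correlation is recovered in sign and size", {
  cfg <- simConfig(nSNPs = 2, plantDichotomous = list(),
                   plantQuantitative = list())
  ped <- sharedPed(); kin <- sharedKin()
  rg <- sapply(1:5, function(r) {
    st <- simulateStudy(cfg, seed = 7000 + r, ped = ped, kin = kin)
    fitBivariate(st@traits, "Q1", "Q2", c("age", "smoke"), kin)@rG
  })
  expect_lt(abs(mean(rg) - 0.25), 0.12)
  # Q4 shares no genes with Q1: correlation near zero
  st <- sharedNullStudy()
  b14 <- fitBivariate(st@traits, "Q1", "Q4", c("age", "smoke"), kin)
  expect_lt(abs(b14@rG), 0.25)
})

test_that("variance-component association is calibrated and orthogonalized", {
  st <- sharedNullStudy(); ped <- sharedPed(); kin <- sharedKin()
  fit <- fitPolygenic(st@traits, "Q1", c("age", "smoke"), kin)
  # permuted genotypes: p-values uniform (KS at alpha = .01)
  withr::with_seed(31, {
    G <- st@genotypes[sample(nrow(st@genotypes)), ]
    rownames(G) <- rownames(st@genotypes)
  })
  vc <- vcAssocScan(st@traits, "Q1", G, c("age", "smoke"), kin, fit = fit)
  ks <- ks.test(vc$p[vc$tested], "punif")
  expect_gt(ks$p.value, 0.01)
  # a SNP identical to an adjusted covariate scores ~0
  G2 <- cbind(G[, 1:3], AGE = st@traits$age[match(rownames(G),
                                                  st@traits$uid)])
  vc2 <- vcAssocScan(st@traits, "Q1", G2, c("age", "smoke"), kin, fit = fit)
  expect_lt(abs(vc2$score[vc2$snp == "AGE"]) /
            max(abs(vc2$score[vc2$snp != "AGE"])), 1e-6)
  # monomorphic SNPs flagged untested
  G3 <- cbind(G[, 1:2], MONO = 0L)
  vc3 <- vcAssocScan(st@traits, "Q1", G3, c("age"), kin, fit = fit)
  expect_false(vc3$tested[vc3$snp == "MONO"])
  expect_true(is.na(vc3$p[vc3$snp == "MONO"]))
})

test_that("a planted quantitative variant reaches genome-wide significance", {
  st <- sharedStudy(); kin <- sharedKin()
  fit <- fitPolygenic(st@traits, "Q1", c("age", "smoke"), kin)
  vc <- vcAssocScan(st@traits, "Q1", st@genotypes, c("age", "smoke"), kin,
                    fit = fit)
  causal <- st@truth$snp[st@truth$trait == "Q1"]
  expect_lt(min(vc$p[vc$snp %in% causal]), 1e-6)
})
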