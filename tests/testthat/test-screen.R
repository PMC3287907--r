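# Founders-only genotype fixture: n founders in one family.
.founderPool <- function(n, dosages) {
  ped <- Pedigree(fid = rep(1, n), id = paste0("i", seq_len(n)),
                  father = rep("0", n), mother = rep("0", n),
                  sex = rep(1:2, length.out = n))
  G <- matrix(dosages, nrow = n,
              dimnames = list(paste0("i", seq_len(n)),
                              paste0("V", seq_len(length(dosages) / n))))
  list(ped = ped, G = G)
}

test_that("founder MAF uses founders only, at the printed precision", {
  # 2 minor copies among 202 diploid founders: 2/404 = 0.00495 -> 0.005
  fp <- .founderPool(202, c(c(1, 1), rep(0, 200)))
  maf <- founderMAF(fp$G, fp$ped)
  expect_equal(unname(round(maf, 3)), 0.005)
  expect_equal(unname(maf), 2 / 404, tolerance = 1e-12)
  # one copy rounds to 0.002
  fp1 <- .founderPool(202, c(1, rep(0, 201)))
  expect_equal(unname(round(founderMAF(fp1$G, fp1$ped), 3)), 0.002)
  # monomorphic 0; all heterozygous 0.5
  fp0 <- .founderPool(10, rep(0, 10))
  expect_equal(unname(founderMAF(fp0$G, fp0$ped)), 0)
  fph <- .founderPool(10, rep(1, 10))
  expect_equal(unname(founderMAF(fph$G, fph$ped)), 0.5)
})

test_that("founder MAF is invariant to nonfounder genotypes", {
  st <- sharedStudy(); ped <- sharedPed()
  m1 <- founderMAF(st@genotypes, ped)
  G2 <- st@genotypes
  nonf <- setdiff(rownames(G2), founders(ped))
  G2[nonf, ] <- 2L  # corrupt every nonfounder genotype
  cohortStable <- founderMAF(G2, ped)
  # the founder allele count is untouched; only the cohort-wide minor-allele
  # orientation can flip, so frequencies agree up to complementation
  expect_true(all(abs(cohortStable - m1) < 1e-12 |
                  abs((1 - cohortStable) - m1) < 1e-12))
})

test_that("carrier odds screen reproduces the printed operating point", {
  # 15 carriers (9 affected, 6 unaffected) among 400 founders
  n <- 400
  dos <- rep(0, n); dos[1:15] <- 1
  fp <- .founderPool(n, dos)
  aff <- setNames(c(rep(1, 9), rep(0, 6), rep(c(1, 0), length.out = n - 15)),
                  paste0("i", 1:n))
  mafs <- founderMAF(fp$G, fp$ped)
  hits <- carrierOddsScreen(fp$G, aff, mafs, fp$ped)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$odds, 9 / 6)           # = 1.5, flagged at oddsMin = 1
  expect_equal(hits$carriersAffected, 9L)
  expect_equal(hits$carriersUnaffected, 6L)
  # zero unaffected carriers: odds +Inf with counts still shown
  dos2 <- rep(0, n); dos2[1:4] <- 1
  fp2 <- .founderPool(n, dos2)
  aff2 <- setNames(rep(c(1, 0), length.out = n), paste0("i", 1:n))
  aff2[1:4] <- 1
  h2 <- carrierOddsScreen(fp2$G, aff2, founderMAF(fp2$G, fp2$ped), fp2$ped)
  expect_true(is.infinite(h2$odds))
  expect_equal(h2$carriersUnaffected, 0L)
})

test_that("screen thresholds exclude by MAF, carrier count and odds", {
  n <- 400
  G <- cbind(highMaf = rep(c(1, 0), c(60, n - 60)),    # MAF 0.075
             few = rep(c(1, 0), c(2, n - 2)),          # 2 carriers
             protective = rep(c(1, 0), c(12, n - 12)))
  rownames(G) <- paste0("i", 1:n)
  ped <- .founderPool(n, rep(0, n))$ped
  aff <- setNames(rep(c(1, 0), length.out = n), paste0("i", 1:n))
  aff[1:12] <- c(rep(1, 2), rep(0, 10))  # protective-looking pattern
  mafs <- founderMAF(G, ped)
  hits <- carrierOddsScreen(G, aff, mafs, ped)
  expect_false("highMaf" %in% hits$snp)   # excluded by mafMax
  expect_false("few" %in% hits$snp)       # below min carriers
  expect_false("protective" %in% hits$snp)  # odds < 1, protective off
  hp <- carrierOddsScreen(G, aff, mafs, ped, protective = TRUE)
  expect_true("protective" %in% hp$snp)
})

test_that("planted risk variants are family-private and screened out", {
  st <- sharedStudy(); ped <- sharedPed()
  mafs <- founderMAF(st@genotypes, ped)
  hits <- carrierOddsScreen(st@genotypes, st@traits, mafs, ped)
  rv <- st@truth$snp[st@truth$trait == "affected"]
  expect_true(rv %in% hits$snp)
  expect_true(hits$familyPrivate[hits$snp == rv])
  # screen order-invariance up to the deterministic position ordering
  perm <- sample(ncol(st@genotypes))
  h2 <- carrierOddsScreen(st@genotypes[, perm], st@traits, mafs, ped)
  expect_equal(h2$snp[order(h2$snp)], hits$snp[order(hits$snp)])
})

test_that("quantitative carrier screen flags shifted carriers only", {
  st <- sharedStudy(); ped <- sharedPed()
  res <- residualizeTrait(st@traits, "Q1", c("age", "smoke"))
  mafs <- founderMAF(st@genotypes, ped)
  hits <- carrierQtScreen(st@genotypes, res, mafs, ped)
  rv <- st@truth$snp[st@truth$trait == "Q1"]
  expect_true(all(rv %in% hits$snp))      # large planted shifts recovered
  expect_true(all(abs(hits$shiftSD) >= 1))
  expect_true(all(hits$maf < 0.05))
  # single extreme carrier excluded by the carrier-count rule
  G <- cbind(st@genotypes, SOLO = 0L)
  G[which.max(res@residuals), "SOLO"] <- 1L
  mafs2 <- c(mafs, SOLO = 1 / (2 * length(founders(ped))))
  h2 <- carrierQtScreen(G, res, mafs2, ped)
  expect_false("SOLO" %in% h2$snp)
})

test_that("EM haplotype frequencies recover truth from phased construction", {
  # oracle: build founder genotypes from known haplotype pairs
  withr::with_seed(11, {
    hapFreq <- c(h11 = 0.08, h10 = 0.02, h01 = 0.12, h00 = 0.78)
    haps <- matrix(c(1, 1, 1, 0, 0, 1, 0, 0), ncol = 2, byrow = TRUE)
    idx <- sample(1:4, 2 * 500, replace = TRUE, prob = hapFreq)
    g1 <- haps[idx[1:500], 1] + haps[idx[501:1000], 1]
    g2 <- haps[idx[1:500], 2] + haps[idx[501:1000], 2]
  })
  # truth from the phased draw itself
  pA <- mean(haps[idx, 1]); pB <- mean(haps[idx, 2])
  D <- mean(haps[idx, 1] * haps[idx, 2]) - pA * pB
  r2True <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  em <- emLD(g1, g2)
  expect_lt(abs(em$r2 - r2True), 0.02)
  # a SNP duplicated exactly is in complete LD with itself
  dup <- emLD(g1, g1)
  expect_equal(dup$r2, 1, tolerance = 1e-6)
  expect_equal(dup$dprime, 1, tolerance = 1e-6)
})

test_that("LD pruning groups complete-LD hits and annotates subsets", {
  st <- sharedStudy(); ped <- sharedPed()
  rv <- st@truth$snp[st@truth$trait == "affected"]
  G <- st@genotypes
  G <- cbind(G, DUP = G[, rv])            # complete-LD duplicate
  sub <- G[, rv]
  aff <- st@traits$affected[match(rownames(G), st@traits$uid)]
  drop1 <- which(sub >= 1 & aff == 0)[1]  # drop an unaffected carrier so
  sub[drop1] <- 0L                        # the subset's odds stay >= 1
  G <- cbind(G, SUB = sub)                # strict carrier subset of rv
  mafs <- founderMAF(G, ped)
  hits <- carrierOddsScreen(G, st@traits, mafs, ped,
                            map = rbind(st@map,
                                        data.frame(snp = c("DUP", "SUB"),
                                                   chr = "4",
                                                   pos = c(9e6, 9.1e6))))
  expect_true(all(c(rv, "DUP", "SUB") %in% hits$snp))
  pruned <- pruneHits(hits, G, ped)
  ld <- attr(pruned, "ld")
  expect_equal(ld$r2[ld$snp1 %in% c(rv, "DUP") & ld$snp2 %in% c(rv, "DUP")],
               1, tolerance = 1e-6)
  # founder genotypes of all three are identical (the dropped carrier is a
  # nonfounder), so they form one complete-LD group with one survivor:
  # the most extreme odds, which is the carrier-subset column
  expect_equal(sum(c(rv, "DUP", "SUB") %in% pruned$snp), 1L)
  subRow <- pruned[pruned$snp == "SUB", ]
  expect_equal(nrow(subRow), 1L)
  # its cohort-level carrier-subset relation to the parent SNPs is annotated
  expect_match(subRow$subsetOf, paste0(rv, "|DUP"))
})
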