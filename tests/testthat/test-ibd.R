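test_that("gene dropping respects Mendelian transmission structure", {
  trio <- trioPed()
  ibd <- geneDrop(trio, nLoci = 200, seed = 7)
  # child shares exactly half its alleles with each parent at every locus
  pm <- ibdProportion(ibd, data.frame(uid1 = c("p1", "p2"),
                                      uid2 = c("c1", "c1")))
  expect_true(all(pm == 0.5))
  # two founders never share
  expect_true(all(ibdProportion(ibd,
    data.frame(uid1 = "p1", uid2 = "p2")) == 0))
  # reproducible under seed, and the caller RNG state is untouched
  set.seed(1); before <- runif(1)
  ibd2 <- geneDrop(trio, nLoci = 200, seed = 7)
  expect_identical(ibd@pat, ibd2@pat)
  set.seed(1); expect_identical(runif(1), before)
  expect_error(geneDrop(trio, nLoci = 0, seed = 1), "positive")
})

test_that("sibling IBD distribution matches exact Mendelian enumeration", {
  sib <- sibPed()
  # oracle: exact enumeration of the 16 equally likely transmission patterns
  pc <- pairCovariance(sib, data.frame(uid1 = "s1", uid2 = "s2"),
                       method = "enumerate")
  expect_equal(pc@expectedPi, 0.5)
  expect_equal(pc@sigma[1, 1], 1 / 8)
  # empirical distribution over 1e5 drops: (1/4, 1/2, 1/4) on {0, 1/2, 1}
  ibd <- geneDrop(sib, nLoci = 1e5, seed = 11)
  pm <- ibdProportion(ibd, data.frame(uid1 = "s1", uid2 = "s2"))
  freq <- table(factor(pm, levels = c(0, 0.5, 1))) / length(pm)
  expect_true(all(abs(as.numeric(freq) - c(1, 2, 1) / 4) < 0.01))
})

test_that("mean sharing converges to twice the kinship for all pair types", {
  ped <- threeGenPed()
  kin <- kinshipMatrix(ped)
  pairs <- relativePairs(ped, kin)
  ibd <- geneDrop(ped, nLoci = 1e5, seed = 13)
  pm <- ibdProportion(ibd, pairs)
  mu <- rowMeans(pm)
  mcse <- apply(pm, 1, sd) / sqrt(ncol(pm))
  expect_true(all(abs(mu - 2 * pairs$phi) <= 3 * pmax(mcse, 1e-6)))
})

test_that("enumerated pair covariance agrees with Monte Carlo", {
  ped <- threeGenPed()
  kin <- kinshipMatrix(ped)
  pairs <- relativePairs(ped, kin)
  pairs <- pairs[pairs$label != "parent-offspring", ][1:8, ]
  en <- pairCovariance(ped, pairs, method = "enumerate")
  mc <- pairCovariance(ped, pairs, method = "montecarlo", nDrops = 2e5,
                       seed = 17)
  tol <- pmax(3 * mc@mcse, 1e-4)
  expect_true(all(abs(en@sigma - mc@sigma) <= tol))
  # overlapping sibling pairs within a sibship of three: the enumeration
  # gives the classical result Cov(pi_12, pi_13) = 0 (conditional on the
  # shared sib's transmissions, the other sharings are independent with
  # constant mean), and Monte Carlo agrees within sampling error
  sib3 <- sibPed(3)
  trip <- data.frame(uid1 = c("s1", "s1"), uid2 = c("s2", "s3"))
  en3 <- pairCovariance(sib3, trip, method = "enumerate")
  mc3 <- pairCovariance(sib3, trip, method = "montecarlo", nDrops = 1e6,
                        seed = 19)
  expect_equal(en3@sigma[1, 2], 0)
  expect_lt(abs(en3@sigma[1, 2] - mc3@sigma[1, 2]),
            3 * max(mc3@mcse[1, 2], 1e-4))
})

test_that("pairs in different families have exactly zero covariance", {
  two <- Pedigree(fid = rep(c(1, 2), each = 4),
                  id = c("f", "m", "s1", "s2", "F", "M", "S1", "S2"),
                  father = c(0, 0, "f", "f", 0, 0, "F", "F"),
                  mother = c(0, 0, "m", "m", 0, 0, "M", "M"),
                  sex = rep(c(1, 2, 1, 2), 2))
  pc <- pairCovariance(two, data.frame(uid1 = c("s1", "S1"),
                                       uid2 = c("s2", "S2")),
                       method = "enumerate")
  expect_equal(pc@sigma[1, 2], 0)
  mc <- pairCovariance(two, data.frame(uid1 = c("s1", "S1"),
                                       uid2 = c("s2", "S2")),
                       method = "montecarlo", nDrops = 5000, seed = 3)
  expect_equal(mc@sigma[1, 2], 0)  # structural zero
})

test_that("Monte-Carlo covariance error follows 1/n scaling", {
  # variance of the Cov estimate should halve when drops double:
  # check the log-log slope of the error variance against exact enumeration
  sib <- sibPed()
  pr <- data.frame(uid1 = "s1", uid2 = "s2")
  exact <- 1 / 8
  drops <- c(250, 1000, 4000)
  errVar <- sapply(drops, function(nd) {
    ests <- sapply(1:60, function(r)
      pairCovariance(sib, pr, method = "montecarlo", nDrops = nd,
                     seed = 1000 + r)@sigma[1, 1])
    mean((ests - exact)^2)
  })
  slope <- coef(lm(log(errVar) ~ log(drops)))[2]
  expect_lt(abs(slope + 1), 0.2)
})

test_that("enumeration refuses oversized closures and unknown pairs error", {
  ped <- sharedPed()
  pairs <- relativePairs(ped, sharedKin())
  big <- pairs[which(pairs$degree >= 5)[1:2], ]
  expect_error(pairCovariance(ped, big, method = "enumerate"), "meioses")
  expect_error(pairCovariance(trioPed(),
                              data.frame(uid1 = "p1", uid2 = "zz")),
               "unknown uid")
})
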