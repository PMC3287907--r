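# Build a set of independent trios with chosen parent/child genotypes.
.trioSet <- function(gF, gM, gC, affected = NULL) {
  n <- length(gF)
  fid <- rep(seq_len(n), each = 3)
  id <- paste0(rep(c("f", "m", "c"), n), fid)
  ped <- Pedigree(fid = fid, id = id,
                  father = as.vector(rbind("0", "0", paste0("f", seq_len(n)))),
                  mother = as.vector(rbind("0", "0", paste0("m", seq_len(n)))),
                  sex = rep(c(1, 2, 1), n))
  G <- matrix(as.vector(rbind(gF, gM, gC)), ncol = 1,
              dimnames = list(id, "S1"))
  if (is.null(affected)) affected <- rep(c(0, 0, 1), n)
  list(ped = ped, G = G, aff = setNames(affected, id))
}

test_that("TDT counts transmissions correctly in all trio configurations", {
  # 10 trios: het father x hom-ref mother, child het => 10 transmissions
  ts <- .trioSet(gF = rep(1, 10), gM = rep(0, 10), gC = rep(1, 10))
  out <- tdt(ts$G, ts$ped, ts$aff)
  expect_equal(out$b, 10); expect_equal(out$c, 0)
  expect_equal(out$chisq, 10)  # (10-0)^2/10

  # balanced transmissions: chi-square 0
  ts2 <- .trioSet(gF = rep(1, 10), gM = rep(0, 10),
                  gC = rep(c(1, 0), 5))
  out2 <- tdt(ts2$G, ts2$ped, ts2$aff)
  expect_equal(out2$b, out2$c)
  expect_equal(out2$chisq, 0)

  # double-het trio resolved through the child: child 2 => 2 transmissions
  ts3 <- .trioSet(gF = 1, gM = 1, gC = 2)
  out3 <- tdt(ts3$G, ts3$ped, ts3$aff)
  expect_equal(out3$b, 2); expect_equal(out3$c, 0)
  ts4 <- .trioSet(gF = 1, gM = 1, gC = 1)
  out4 <- tdt(ts4$G, ts4$ped, ts4$aff)
  expect_equal(out4$b, 1); expect_equal(out4$c, 1)

  # unaffected offspring and homozygous parents are uninformative
  ts5 <- .trioSet(gF = 0, gM = 0, gC = 0)
  expect_false(tdt(ts5$G, ts5$ped, ts5$aff)$tested)
})

test_that("TDT type-I error is nominal under familial clustering", {
  # null: unlinked, unassociated SNP in structured families
  ped <- sharedPed(); st <- sharedNullStudy()
  G <- st@genotypes[, grep("^S", colnames(st@genotypes))[1:300]]
  common <- founderMAF(G, ped) > 0.1
  out <- tdt(G[, common], ped, st@traits)
  rate <- mean(out$p[out$tested] < 0.05)
  n <- sum(out$tested)
  expect_lt(abs(rate - 0.05), 2.5 * sqrt(0.05 * 0.95 / n) + 0.01)
})

test_that("GDT scores discordant pairs with family-robust variance", {
  # one family, one genotyped discordant pair, g_aff = 1, g_unaff = 0:
  # U = 1, Z = 1
  ped <- sibPed(2)
  G <- matrix(c(1, 0), ncol = 1, dimnames = list(c("s1", "s2"), "S1"))
  aff <- setNames(c(1, 0), c("s1", "s2"))
  out <- gdt(G, ped, aff)
  expect_equal(out$T, 1); expect_equal(out$Z, 1)

  # swapping affected and unaffected everywhere negates Z
  out2 <- gdt(G, ped, 1 - aff)
  expect_equal(out2$Z, -out$Z)

  # allele-label swap flips the dosage: Z negates
  out3 <- gdt(2 - G, ped, aff)
  expect_equal(out3$Z, -out$Z)

  # all families concordant: untested
  expect_error(gdt(G, ped, setNames(rep(1, 2), c("s1", "s2"))),
               "affected and unaffected")
})

test_that("GDT is family-exchangeable and calibrated under the null", {
  ped <- sharedPed(); st <- sharedNullStudy()
  G <- st@genotypes[, grep("^S", colnames(st@genotypes))[1:300]]
  out <- gdt(G, ped, st@traits)
  # permuting family blocks leaves T and the variance unchanged
  tab <- pedTable(ped)
  ord <- order(match(tab$fid, rev(families(ped))))
  out2 <- gdt(G[tab$uid[ord], ], ped, st@traits)
  expect_equal(out2$T, out$T); expect_equal(out2$varT, out$varT)
  # null calibration at |Z| > 1.96
  rate <- mean(abs(out$Z[out$tested]) > 1.96)
  n <- sum(out$tested)
  expect_lt(abs(rate - 0.05), 2.5 * sqrt(0.05 * 0.95 / n) + 0.01)
})

test_that("sandwich logistic regression matches its reference identities", {
  st <- sharedStudy()
  tr <- st@traits
  snp <- st@truth$snp[st@truth$trait == "affected"][1]
  design <- data.frame(Age = tr$age, Smoke = tr$smoke,
                       RV = st@genotypes[match(tr$uid,
                                               rownames(st@genotypes)), snp])
  out <- logisticSandwich(setNames(tr$affected, tr$uid), design, tr$fid)
  expect_equal(out$OR, exp(out$estimate), tolerance = 1e-12)
  expect_equal(attr(out, "nClusters"), 8L)
  # the planted risk variant carries a positive log-odds
  expect_gt(out$estimate[out$term == "RV"], 0)

  # one individual per cluster: sandwich SE == HC0 heteroskedasticity SE
  out2 <- logisticSandwich(setNames(tr$affected, tr$uid), design,
                           seq_len(nrow(tr)))
  fit <- glm(tr$affected ~ Age + Smoke + RV, data = design,
             family = binomial())
  hc0 <- sqrt(diag(sandwich::vcovHC(fit, type = "HC0")))
  expect_equal(out2$robustSE, unname(hc0), tolerance = 1e-10)

  # separation detected and named
  sep <- data.frame(bad = as.numeric(tr$affected))
  expect_error(
    suppressWarnings(logisticSandwich(setNames(tr$affected, tr$uid), sep,
                                      tr$fid)),
    "separation.*bad")
})

test_that("gene collapsing is a carrier union and idempotent", {
  G <- matrix(c(0, 1, 0, 2,
                0, 0, 1, 0,
                0, 0, 0, 1), ncol = 3,
              dimnames = list(paste0("i", 1:4), c("v1", "v2", "v3")))
  gm <- data.frame(snp = c("v1", "v2", "v3"), gene = c("A", "A", "B"))
  cg <- collapseGene(G, gm)
  # carrier-of-any indicator; rare-allele homozygote is coded carrier (1)
  expect_equal(unname(cg[, "A"]), c(0L, 1L, 1L, 1L))
  expect_equal(unname(cg[, "B"]), c(0L, 0L, 0L, 1L))
  # idempotent under re-collapsing
  cg2 <- collapseGene(cg, data.frame(snp = c("A", "B"), gene = c("A", "B")))
  expect_equal(unname(cg2), unname(cg))
  # single-variant collapse equals that variant's carrier indicator
  one <- collapseGene(G, gm, variantIds = "v3")
  expect_equal(unname(one[, "B"]), as.integer(G[, "v3"] >= 1))
  # empty gene: zeros with warning
  expect_warning(z <- collapseGene(G, data.frame(snp = "zz", gene = "C")),
                 "no variants")
  expect_true(all(z == 0))
})
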