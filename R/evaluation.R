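# Replication studies of the package's operating characteristics:
# null calibration of the linkage statistics, recovery of planted effects,
# and parameter recovery for the variance-component models. These drive the
# calibration/recovery sections of the methods vignette and the acceptance
# report.

#' Null calibration of the linkage statistics
#'
#' Simulates a null study (no planted causal variants; traits depend on
#' covariates and polygenes only, independent of IBD at every locus) and
#' evaluates the NPL and QT-score statistics at \code{nLoci} unlinked loci.
#' Because loci are dropped independently, each locus is an independent
#' replicate of the null statistic for the given family set. Reports
#' empirical one-sided and two-sided exceedance rates at 1.96 together with
#' the mean and variance of Z.
#'
#' @param seed integer seed (pedigree, phenotypes, IBD, Monte Carlo).
#' @param nLoci number of null replicates (loci).
#' @param config base [simConfig()]; planted variants are removed and
#'   \code{nSNPs} is set to \code{nLoci}.
#' @param nplDrops,qtDrops gene drops behind the null variances.
#' @return list with elements npl and qt, each holding tailUpper,
#'   tailTwoSided, mean, var, n.
#' @export
calibrateNull <- function(seed, nLoci = 500L, config = simConfig(),
                          nplDrops = 100000L, qtDrops = 8000L) {
  cfg <- config
  cfg$plantDichotomous <- list()
  cfg$plantQuantitative <- list()
  cfg$nSNPs <- as.integer(nLoci)
  ped <- simulatePedigrees(cfg, seed = seed)
  kin <- kinshipMatrix(ped)
  st <- simulateStudy(cfg, seed = seed, ped = ped, kin = kin)
  pairs <- pairWeights(selectAffectedPairs(ped, st@traits, kin = kin))
  npl <- nplScan(st@ibd, pairs, ped = ped, nDrops = nplDrops,
                 seed = seed + 101L)
  res <- residualizeTrait(st@traits, "Q1", c("age", "smoke"))
  qt <- qtScoreScan(res, st@ibd, ped, kin = kin, nDrops = qtDrops,
                    seed = seed + 103L)
  summarize <- function(z) list(
    tailUpper = mean(z > 1.96), tailTwoSided = mean(abs(z) > 1.96),
    mean = mean(z), var = stats::var(z), n = length(z))
  list(npl = summarize(npl$Z), qt = summarize(qt$Z))
}

#' Recovery of planted causal effects over study replicates
#'
#' Holds the pedigrees fixed (the design of a family study) and replicates
#' genotypes and phenotypes \code{nReplicates} times under the default
#' causal architecture: one family-private dichotomous risk variant and two
#' quantitative-trait variants jointly sized to a fixed share of the
#' phenotypic variance. Per replicate it records whether the risk variant
#' is recovered by the carrier-odds screen, the variance explained by the
#' quantitative variants from the heritability-drop accounting, and the
#' conditional-linkage LOD at the causal loci before and after adjusting
#' for the variants.
#'
#' @param seed integer seed.
#' @param nReplicates number of study replicates.
#' @param config a [simConfig()] with planted variants.
#' @param qtDrops gene drops for the QT-scan null variance.
#' @return list: screenRecoveryRate, veMean, veSD, lodOver3 (count of
#'   replicates with unadjusted causal LOD > 3), conditionalDropRate
#'   (fraction of those with adjusted LOD < 1), detail (per-replicate
#'   data.frame).
#' @export
assessRecovery <- function(seed, nReplicates = 50L, config = simConfig(),
                           qtDrops = 1500L) {
  ped <- simulatePedigrees(config, seed = seed)
  kin <- kinshipMatrix(ped)
  qtSnps <- vapply(config$plantQuantitative, `[[`, "", "name")
  dSnps <- vapply(config$plantDichotomous, `[[`, "", "name")
  out <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    st <- simulateStudy(config, seed = seed + 1000L * r, ped = ped,
                        kin = kin)
    mafs <- founderMAF(st@genotypes, ped)
    hits <- carrierOddsScreen(st@genotypes, st@traits, mafs, ped)
    screened <- all(dSnps %in% hits$snp)
    f0 <- fitPolygenic(st@traits, "Q1", c("age", "smoke"), kin)
    f1 <- fitPolygenic(st@traits, "Q1", c("age", "smoke"), kin,
                       genotypes = st@genotypes, adjustSNPs = qtSnps)
    ve <- varianceExplained(f0, f1)
    cs <- conditionalScan(st@traits, "Q1", c("age", "smoke"), st@genotypes,
                          qtSnps, st@ibd, ped, kin = kin, loci = qtSnps,
                          nDrops = qtDrops, seed = seed + 7L + r)
    best <- which.max(cs$LODbefore)
    out[[r]] <- data.frame(replicate = r, screened = screened, ve = ve,
                           lodBefore = cs$LODbefore[best],
                           lodAfter = cs$LODafter[best])
  }
  detail <- do.call(rbind, out)
  qual <- detail$lodBefore > 3
  list(screenRecoveryRate = mean(detail$screened),
       veMean = mean(detail$ve), veSD = stats::sd(detail$ve),
       lodOver3 = sum(qual),
       conditionalDropRate = if (any(qual)) mean(detail$lodAfter[qual] < 1)
                             else NA_real_,
       detail = detail)
}

#' Parameter recovery for the variance-component models
#'
#' Replicated phenotype draws on a fixed pedigree: univariate heritability
#' recovery (generator h2 for Q1) and bivariate genetic-correlation
#' recovery (generator rG between Q1 and Q2). The fits adjust Age, Smoking
#' and the structure covariate, as in the analysis model; the generator's
#' true ancestry fraction stands in for the estimated PC1 here (PC1
#' estimation is assessed separately by the structure module), since the
#' shared family-structured ancestry effect would otherwise inflate both
#' h2 and rG.
#'
#' @param seed integer seed.
#' @param nH2 replicates for the univariate fit.
#' @param nRG replicates for the bivariate fit.
#' @param config base [simConfig()]; planted variants are removed and the
#'   SNP panel shrunk (genotypes do not enter these fits).
#' @return list: h2Mean, h2SD, rGMean, rGSD, targets.
#' @export
assessVCRecovery <- function(seed, nH2 = 100L, nRG = 50L,
                             config = simConfig()) {
  cfg <- config
  cfg$plantDichotomous <- list()
  cfg$plantQuantitative <- list()
  cfg$nSNPs <- 2L
  ped <- simulatePedigrees(cfg, seed = seed)
  kin <- kinshipMatrix(ped)
  h2 <- numeric(nH2); rg <- numeric(nRG)
  for (r in seq_len(max(nH2, nRG))) {
    st <- simulateStudy(cfg, seed = seed + 1000L * r, ped = ped, kin = kin)
    if (r <= nH2)
      h2[r] <- fitPolygenic(st@traits, "Q1", c("age", "smoke", "ancestry"),
                            kin)@h2
    if (r <= nRG)
      rg[r] <- fitBivariate(st@traits, "Q1", "Q2",
                            c("age", "smoke", "ancestry"), kin)@rG
  }
  list(h2Mean = mean(h2), h2SD = stats::sd(h2),
       rGMean = mean(rg), rGSD = stats::sd(rg),
       targets = c(h2 = cfg$h2[["Q1"]], rG = cfg$rG12))
}
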