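# End-to-end orchestration: simulate or ingest, structure, linkage scans,
# association, screening, variance-component models, conditional analyses,
# reports.

#' One-LOD-drop support interval around a linkage peak
#'
#' The outermost contiguous positions around the maximum where the LOD stays
#' within \code{drop} of the peak.
#'
#' @param pos positions (bp), need not be sorted.
#' @param lod LOD values parallel to \code{pos}.
#' @param drop LOD drop defining the interval (default 1).
#' @return c(startBp, endBp), or NULL for a curve with no positive maximum.
#' @export
supportInterval <- function(pos, lod, drop = 1) {
  o <- order(pos)
  pos <- pos[o]; lod <- lod[o]
  if (!length(lod) || max(lod) <= 0) return(NULL)
  pk <- which.max(lod)
  thr <- lod[pk] - drop
  lo <- pk; while (lo > 1 && lod[lo - 1] >= thr) lo <- lo - 1
  hi <- pk; while (hi < length(lod) && lod[hi + 1] >= thr) hi <- hi + 1
  c(start = pos[lo], end = pos[hi])
}

# TSV writer with provenance header lines ("#key<TAB>value").
.writeStage <- function(df, file, provenance) {
  con <- file(file, "w")
  on.exit(close(con))
  for (k in names(provenance))
    writeLines(paste0("#", k, "\t", provenance[[k]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# Peak region (chr, start, end) of a per-locus scan joined to a map.
.peakRegion <- function(scan, map, drop = 1) {
  m <- map[match(scan$locus, map$snp), ]
  best <- which.max(scan$LOD)
  chr <- m$chr[best]
  on <- m$chr == chr
  si <- supportInterval(m$pos[on], scan$LOD[on], drop = drop)
  if (is.null(si)) return(NULL)
  list(chr = chr, start = si[["start"]], end = si[["end"]],
       peakPos = m$pos[best], peakLOD = scan$LOD[best],
       peakSnp = scan$locus[best])
}

#' Run the full analysis pipeline on a simulated or ingested study
#'
#' Stages, in order: simulate (or take the supplied study), kinship, founder
#' MDS with nonfounder projection (PC1 covariate), NPL scan for the
#' dichotomous trait with age filtering, per-trait QT score scans with
#' Age/Smoking/PC1 adjustment, one-LOD support intervals and per-family
#' decomposition at the peaks, carrier-odds and carrier-phenotype screens in
#' the linkage regions with LD pruning, TDT/GDT in the dichotomous linkage
#' region, a sandwich logistic model of the screened variants with Age and
#' Smoking, polygenic and bivariate fits, a variance-component association
#' scan in the Q1 linkage region, conditional linkage adjusting for the top
#' associated SNPs, and variance-explained accounting. Every stage writes a
#' TSV whose header records the thresholds and seed; the summary only
#' re-states stage-TSV numbers.
#'
#' @param config [simConfig()] used when \code{study} is NULL.
#' @param seed integer seed for simulation and Monte-Carlo variances.
#' @param study optional [SimulatedStudy-class] to analyse instead of
#'   simulating.
#' @param outDir output directory for stage TSVs (NULL: nothing written).
#' @param maxAgeDiff NPL age-difference filter in years.
#' @param weightScheme NPL pair weight scheme.
#' @param mafMax rare/less-frequent MAF cutoff for the screens.
#' @param oddsMin carrier-odds threshold.
#' @param minCarriers minimum carriers for a screen hit.
#' @param followUpP association p-value flag threshold (default 0.001).
#' @param lodDrop support-interval LOD drop (default 1).
#' @param nplDrops,qtDrops Monte-Carlo drops for the null variances.
#' @return A list of class \code{"pedscanPipeline"} with elements study,
#'   pc, npl, nplRegion, qt (per trait), qtRegion, screenHits, prunedHits,
#'   qtHits, tdt, gdt, logistic, polygenic, bivariate, vcAssoc, conditional,
#'   varianceExplained, summary.
#' @export
runPipeline <- function(config = simConfig(), seed, study = NULL,
                        outDir = NULL, maxAgeDiff = 16,
                        weightScheme = "inverse_sd", mafMax = 0.05,
                        oddsMin = 1.0, minCarriers = 3L, followUpP = 0.001,
                        lodDrop = 1, nplDrops = 20000L, qtDrops = 2000L) {
  prov <- list(seed = seed, maxAgeDiff = maxAgeDiff,
               weightScheme = weightScheme, mafMax = mafMax,
               oddsMin = oddsMin, minCarriers = minCarriers,
               followUpP = followUpP, lodDrop = lodDrop,
               packageVersion = as.character(utils::packageVersion("pedscan")))
  emit <- function(df, name) {
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      .writeStage(df, file.path(outDir, paste0(name, ".tsv")), prov)
    }
    df
  }

  if (is.null(study)) study <- simulateStudy(config, seed = seed)
  ped <- study@ped
  kin <- kinshipMatrix(ped)
  map <- study@map
  traits <- study@traits

  # structure: PC1 covariate
  mdsF <- founderMDS(study@genotypes, ped, k = 1)
  pc <- projectNonfounders(mdsF, ped)
  traits$pc1 <- pc$PC1[match(traits$uid, pc$uid)]
  emit(pc, "structure")

  # NPL scan for the dichotomous trait
  pairs <- selectAffectedPairs(ped, traits, maxAgeDiff = maxAgeDiff,
                               kin = kin)
  pairs <- pairWeights(pairs, scheme = weightScheme)
  npl <- nplScan(study@ibd, pairs, ped = ped, nDrops = nplDrops,
                 seed = seed + 11L)
  nplOut <- cbind(npl, map[match(npl$locus, map$snp), c("chr", "pos")],
                  attr(npl, "familyLOD"))
  emit(nplOut, "npl_scan")
  nplRegion <- .peakRegion(npl, map, drop = lodDrop)

  # QT score scans
  qtTraits <- c("Q1", "Q2", "Q4")
  qt <- list(); qtRegion <- list()
  for (tr in qtTraits) {
    res <- residualizeTrait(traits, tr, c("age", "smoke", "pc1"))
    sc <- qtScoreScan(res, study@ibd, ped, kin = kin, nDrops = qtDrops,
                      seed = seed + 13L)
    qt[[tr]] <- sc
    emit(cbind(sc, map[match(sc$locus, map$snp), c("chr", "pos")]),
         paste0("qt_scan_", tr))
    qtRegion[[tr]] <- .peakRegion(sc, map, drop = lodDrop)
  }

  # screens in the linkage regions
  mafs <- founderMAF(study@genotypes, ped)
  region <- if (!is.null(nplRegion))
    list(nplRegion$chr, nplRegion$start, nplRegion$end) else NULL
  hits <- carrierOddsScreen(study@genotypes, traits, mafs, ped, map = map,
                            region = region, mafMax = mafMax,
                            oddsMin = oddsMin, minCarriers = minCarriers)
  emit(hits, "screen_hits")
  pruned <- if (nrow(hits) >= 2L) pruneHits(hits, study@genotypes, ped)
            else hits
  emit(pruned, "screen_hits_pruned")
  resQ1 <- residualizeTrait(traits, "Q1", c("age", "smoke", "pc1"))
  regionQ1 <- if (!is.null(qtRegion$Q1))
    list(qtRegion$Q1$chr, qtRegion$Q1$start, qtRegion$Q1$end) else NULL
  qtHits <- carrierQtScreen(study@genotypes, resQ1, mafs, ped, map = map,
                            region = regionQ1, mafMax = mafMax,
                            minCarriers = minCarriers)
  emit(qtHits, "qt_screen_hits")

  # family-based association in the dichotomous linkage region
  regionSnps <- if (!is.null(region)) .regionSnps(map, region) else map$snp
  regionSnps <- intersect(regionSnps, colnames(study@genotypes))
  tdtRes <- tdt(study@genotypes[, regionSnps, drop = FALSE], ped, traits)
  tdtRes$flagged <- !is.na(tdtRes$p) & tdtRes$p < followUpP
  emit(tdtRes, "tdt")
  gdtRes <- gdt(study@genotypes[, regionSnps, drop = FALSE], ped, traits)
  gdtRes$flagged <- !is.na(gdtRes$p) & gdtRes$p < followUpP
  emit(gdtRes, "gdt")

  # sandwich logistic model: Age + Smoke + screened variants
  topSnps <- utils::head(pruned$snp[order(-pruned$odds, pruned$pos)], 3L)
  design <- data.frame(Age = traits$age, Smoke = traits$smoke)
  for (s in topSnps)
    design[[s]] <- study@genotypes[match(traits$uid,
                                         rownames(study@genotypes)), s]
  logistic <- logisticSandwich(
    stats::setNames(traits$affected, traits$uid), design, traits$fid)
  emit(logistic, "logistic_model")

  # variance-component models
  poly <- lapply(stats::setNames(qtTraits, qtTraits), function(tr)
    fitPolygenic(traits, tr, c("age", "smoke", "pc1"), kin))
  polyTab <- data.frame(trait = qtTraits,
                        h2 = vapply(poly, slot, numeric(1), "h2"),
                        sigmaG = vapply(poly, slot, numeric(1), "sigmaG"),
                        sigmaE = vapply(poly, slot, numeric(1), "sigmaE"),
                        logLik = vapply(poly, slot, numeric(1), "logLik"))
  emit(polyTab, "polygenic")
  biv <- fitBivariate(traits, "Q1", "Q2", c("age", "smoke", "pc1"), kin)

  vcSnps <- if (!is.null(regionQ1)) .regionSnps(map, regionQ1) else map$snp
  vcSnps <- intersect(vcSnps, colnames(study@genotypes))
  vc <- vcAssocScan(traits, "Q1", study@genotypes[, vcSnps, drop = FALSE],
                    c("age", "smoke", "pc1"), kin, fit = poly$Q1)
  vc <- cbind(vc, map[match(vc$snp, map$snp), c("chr", "pos")],
              maf = mafs[vc$snp])
  vc$flagged <- !is.na(vc$p) & vc$p < followUpP
  emit(vc, "vc_assoc")

  adjSnps <- vc$snp[vc$flagged & !is.na(vc$p)]
  adjSnps <- utils::head(adjSnps[order(vc$p[match(adjSnps, vc$snp)])], 2L)
  conditional <- NULL; ve <- NA_real_
  if (length(adjSnps)) {
    conditional <- conditionalScan(traits, "Q1", c("age", "smoke", "pc1"),
                                   study@genotypes, adjSnps, study@ibd, ped,
                                   kin = kin, nDrops = qtDrops,
                                   seed = seed + 17L)
    emit(conditional, "conditional_scan")
    fitWith <- fitPolygenic(traits, "Q1", c("age", "smoke", "pc1"), kin,
                            genotypes = study@genotypes,
                            adjustSNPs = adjSnps)
    ve <- varianceExplained(poly$Q1, fitWith)
  }

  fmtMb <- function(x) sprintf("%.2f", x / 1e6)
  summary <- list(
    nIndividuals = nrow(traits), prevalence = mean(traits$affected),
    nplPeak = nplRegion,
    nplSupportMb = if (!is.null(nplRegion))
      paste0(fmtMb(nplRegion$start), "-", fmtMb(nplRegion$end), " Mb"),
    qtPeaks = qtRegion,
    nScreenHits = nrow(hits), nPrunedHits = nrow(pruned),
    adjustedSnps = adjSnps, varianceExplainedPct = ve,
    h2 = polyTab$h2, rG = biv@rG)
  out <- list(study = study, pc = pc, npl = npl, nplRegion = nplRegion,
              qt = qt, qtRegion = qtRegion, screenHits = hits,
              prunedHits = pruned, qtHits = qtHits, tdt = tdtRes,
              gdt = gdtRes, logistic = logistic, polygenic = poly,
              bivariate = biv, vcAssoc = vc, conditional = conditional,
              varianceExplained = ve, summary = summary,
              thresholds = prov)
  class(out) <- "pedscanPipeline"
  out
}

#' @export
print.pedscanPipeline <- function(x, ...) {
  cat("pedscan pipeline result\n")
  cat("  individuals:", x$summary$nIndividuals,
      " prevalence:", round(x$summary$prevalence, 3), "\n")
  if (!is.null(x$nplRegion))
    cat("  NPL peak: chr", x$nplRegion$chr, " LOD ",
        round(x$nplRegion$peakLOD, 2), " support ", x$summary$nplSupportMb,
        "\n", sep = "")
  cat("  h2 (Q1,Q2,Q4):", paste(round(x$summary$h2, 3), collapse = ", "),
      " rG:", round(x$summary$rG, 3), "\n")
  if (!is.na(x$varianceExplained))
    cat("  variance explained by adjusted SNPs:",
        round(x$varianceExplained, 1), "%\n")
  invisible(x)
}
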