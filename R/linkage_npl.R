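# Weighted affected-relative-pair nonparametric linkage scan.

.LOD_FACTOR <- 2 * log(10)

.lodFromZ <- function(z) ifelse(z > 0, z^2 / .LOD_FACTOR, 0)

#' Select affected relative pairs for the NPL scan
#'
#' All within-family affected relative pairs of degree >= 1, excluding
#' parent-offspring pairs (no variation in IBD sharing) and pairs whose age
#' difference exceeds \code{maxAgeDiff} years. Age is a strong risk factor
#' for late-onset dichotomous traits, so pairs of very different ages are
#' less informative; the default threshold is 16 years. Affected individuals
#' with missing age are dropped (their pairs are excluded) with a warning.
#'
#' @param ped a [Pedigree-class].
#' @param traits data.frame with columns \code{uid}, \code{affected}
#'   (0/1 or logical) and \code{age} (years).
#' @param maxAgeDiff maximum allowed age difference in years (default 16).
#' @param kin optional precomputed [kinshipMatrix()].
#' @return data.frame: uid1, uid2, fid, degree, label, phi, ageDiff, in
#'   deterministic pedigree order. Attribute \code{"maxAgeDiff"} records the
#'   threshold.
#' @export
selectAffectedPairs <- function(ped, traits, maxAgeDiff = 16, kin = NULL) {
  tab <- ped@tab
  aff <- traits$uid[as.logical(traits$affected) %in% TRUE]
  age <- traits$age[match(aff, traits$uid)]
  if (anyNA(age)) {
    warning(sum(is.na(age)), " affected individual(s) with missing age dropped")
    aff <- aff[!is.na(age)]; age <- age[!is.na(age)]
  }
  if (is.null(kin)) kin <- kinshipMatrix(ped)
  pairs <- relativePairs(ped, kin)
  keep <- pairs$uid1 %in% aff & pairs$uid2 %in% aff &
    pairs$label != "parent-offspring"
  pairs <- pairs[keep, , drop = FALSE]
  a1 <- age[match(pairs$uid1, aff)]
  a2 <- age[match(pairs$uid2, aff)]
  pairs$ageDiff <- abs(a1 - a2)
  pairs <- pairs[pairs$ageDiff <= maxAgeDiff, , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "maxAgeDiff") <- maxAgeDiff
  pairs
}

#' Attach weights to an affected-pair set
#'
#' Distant relative pairs share little IBD in expectation, but a shared rare
#' allele in such a pair is strong evidence; up-weighting them raises power
#' for rare variants. Schemes: \code{"uniform"} (w = 1),
#' \code{"inverse_expected_sharing"} (w = 1/(2 phi)) and the default
#' \code{"inverse_sd"} (w = 1/sqrt(Var pi)), which standardizes each pair's
#' contribution.
#'
#' @param pairs data.frame from [selectAffectedPairs()] (columns phi, label).
#' @param scheme weighting scheme.
#' @return Input with columns \code{varPi} and \code{weight} added;
#'   attribute \code{"scheme"} records the choice.
#' @export
pairWeights <- function(pairs,
                        scheme = c("inverse_sd", "uniform",
                                   "inverse_expected_sharing")) {
  scheme <- match.arg(scheme)
  pairs$varPi <- .varPi(pairs$phi, pairs$label)
  pairs$weight <- switch(scheme,
    uniform = rep(1, nrow(pairs)),
    inverse_expected_sharing = 1 / (2 * pairs$phi),
    inverse_sd = 1 / sqrt(pairs$varPi))
  attr(pairs, "scheme") <- scheme
  pairs
}

# Monte-Carlo variance of the per-family weighted sums sum w (pi - 2 phi)
# under the null, via fresh gene drops. Returns named numeric per family.
.mcPairSumVar <- function(ped, pairs, nDrops, seed, chunkSize = 5000L) {
  tab <- ped@tab
  i1 <- match(pairs$uid1, tab$uid); i2 <- match(pairs$uid2, tab$uid)
  idx <- .dropIndex(tab)
  fams <- unique(pairs$fid)
  withr::local_seed(as.integer(seed))
  sums <- matrix(0, nDrops, length(fams), dimnames = list(NULL, fams))
  done <- 0L
  while (done < nDrops) {
    b <- min(as.integer(chunkSize), nDrops - done)
    dr <- .geneDropRaw(tab, idx, b)
    for (f in fams) {
      rows <- which(pairs$fid == f)
      acc <- numeric(b)
      for (k in rows)
        acc <- acc + pairs$weight[k] *
          .piRows(dr$pat[i1[k], ], dr$mat[i1[k], ],
                  dr$pat[i2[k], ], dr$mat[i2[k], ])
      sums[(done + 1):(done + b), f] <- acc
    }
    done <- done + b
  }
  apply(sums, 2, stats::var)
}

#' Nonparametric linkage scan over affected relative pairs
#'
#' Per locus,
#' \deqn{Z = \sum w_{ij} (\pi_{ij} - 2\phi_{ij}) \Big/
#'       \sqrt{\sum\sum w_{ij} w_{kl} Cov(\pi_{ij}, \pi_{kl})},}
#' standard normal under the null of no linkage. One-sided LOD
#' \eqn{= Z^2 / (2 \ln 10)} for Z > 0, else 0 (affected pairs share more
#' under linkage; deficits are reported as negative Z only). The overall
#' numerator is the sum of per-family numerators and the overall variance
#' the sum of per-family variances (families are independent), so a
#' per-family Z/LOD decomposition is emitted alongside.
#'
#' The null variance comes either from a supplied [PairCovariance-class]
#' (exact for small pedigrees) or from seeded gene-dropping Monte Carlo.
#'
#' @param ibd [IBDSharing-class] with the true IBD labels at the scanned loci.
#' @param pairs weighted pair set from [pairWeights()].
#' @param ped the [Pedigree-class] (needed for Monte-Carlo variance).
#' @param cov optional [PairCovariance-class] computed for exactly this pair
#'   set (same order).
#' @param nDrops,seed Monte-Carlo settings when \code{cov} is NULL.
#' @return data.frame per locus: locus, Z, LOD. Attributes:
#'   \code{familyZ}, \code{familyLOD} (loci x family matrices),
#'   \code{familyVar}, \code{weightScheme}.
#' @export
nplScan <- function(ibd, pairs, ped = NULL, cov = NULL,
                    nDrops = 50000L, seed = 1L) {
  if (nrow(pairs) == 0L)
    stop("empty affected pair set: relax the age threshold or check the ",
         "affection coding")
  if (is.null(pairs$weight)) pairs <- pairWeights(pairs)
  w <- pairs$weight
  fams <- unique(pairs$fid)
  if (!is.null(cov)) {
    if (nrow(cov@pairs) != nrow(pairs) ||
        any(cov@pairs$uid1 != pairs$uid1) || any(cov@pairs$uid2 != pairs$uid2))
      stop("cov was not computed for this pair set")
    famVar <- vapply(fams, function(f) {
      r <- which(pairs$fid == f)
      as.numeric(t(w[r]) %*% cov@sigma[r, r, drop = FALSE] %*% w[r])
    }, numeric(1))
  } else {
    if (is.null(ped)) stop("ped is required when cov is NULL")
    famVar <- .mcPairSumVar(ped, pairs, nDrops = nDrops, seed = seed)
  }
  if (any(famVar < -1e-10)) stop("non-PSD covariance: negative pair-sum variance")
  famVar <- pmax(famVar, 0)
  totVar <- sum(famVar)
  if (totVar <= 0) stop("degenerate pair set: null variance is zero")

  pm <- ibdProportion(ibd, pairs)           # pairs x loci
  dev <- w * (pm - 2 * pairs$phi)           # weighted centered sharing
  famNum <- t(rowsum(dev, group = pairs$fid, reorder = FALSE))  # loci x fam
  famNum <- famNum[, fams, drop = FALSE]
  famZ <- sweep(famNum, 2, sqrt(pmax(famVar, .Machine$double.eps)), "/")
  famZ[, famVar == 0] <- 0
  z <- rowSums(famNum) / sqrt(totVar)
  out <- data.frame(locus = ibd@loci, Z = z, LOD = .lodFromZ(z))
  attr(out, "familyZ") <- famZ
  attr(out, "familyLOD") <- .lodFromZ(famZ)
  attr(out, "familyVar") <- famVar
  attr(out, "weightScheme") <- attr(pairs, "scheme")
  attr(out, "maxAgeDiff") <- attr(pairs, "maxAgeDiff")
  out
}

#' Sensitivity of the NPL scan to the age-difference threshold
#'
#' Re-runs pair selection and the scan across a grid of age-difference
#' thresholds and reports the maximum LOD per threshold.
#'
#' @param ped,traits,ibd as in [selectAffectedPairs()] / [nplScan()].
#' @param thresholds numeric vector of age thresholds (years).
#' @param scheme weight scheme passed to [pairWeights()].
#' @param nDrops,seed Monte-Carlo variance settings.
#' @return data.frame: maxAgeDiff, nPairs, maxLOD, locusAtMax.
#' @export
nplAgeSweep <- function(ped, traits, ibd, thresholds = c(8, 12, 16, 20, 24),
                        scheme = "inverse_sd", nDrops = 20000L, seed = 1L) {
  kin <- kinshipMatrix(ped)
  res <- lapply(thresholds, function(th) {
    pairs <- selectAffectedPairs(ped, traits, maxAgeDiff = th, kin = kin)
    if (nrow(pairs) == 0L)
      return(data.frame(maxAgeDiff = th, nPairs = 0L, maxLOD = NA_real_,
                        locusAtMax = NA_character_))
    pairs <- pairWeights(pairs, scheme = scheme)
    scan <- nplScan(ibd, pairs, ped = ped, nDrops = nDrops, seed = seed)
    data.frame(maxAgeDiff = th, nPairs = nrow(pairs),
               maxLOD = max(scan$LOD),
               locusAtMax = scan$locus[which.max(scan$LOD)])
  })
  do.call(rbind, res)
}
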