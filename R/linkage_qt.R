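# Score-based robust linkage scan for quantitative traits.

# Build a fixed-effect design matrix from trait-table covariates and optional
# SNP dosage columns; drops monomorphic and collinear columns with a warning.
.buildDesign <- function(traits, covariates, genotypes = NULL,
                         adjustSNPs = NULL) {
  X <- matrix(1, nrow(traits), 1L, dimnames = list(traits$uid, "(Intercept)"))
  for (cv in covariates) {
    if (!cv %in% names(traits)) stop("covariate not found: ", cv)
    X <- cbind(X, stats::setNames(traits[[cv]], NULL))
    colnames(X)[ncol(X)] <- cv
  }
  dropped <- character(0)
  for (s in adjustSNPs) {
    if (is.null(genotypes) || !s %in% colnames(genotypes))
      stop("unknown SNP id: ", s)
    g <- genotypes[match(traits$uid, rownames(genotypes)), s]
    if (stats::var(g, na.rm = TRUE) < .Machine$double.eps) {
      dropped <- c(dropped, s)   # monomorphic: coefficient undefined
      next
    }
    X <- cbind(X, g)
    colnames(X)[ncol(X)] <- s
  }
  list(X = X, dropped = dropped)
}

#' Residualize a quantitative trait on covariates (and SNP dosages)
#'
#' Ordinary least-squares residuals of the trait on the given covariates;
#' SNP dosages named in \code{adjustSNPs} are appended as additive covariates
#' (the device used for conditional linkage analysis). Monomorphic or
#' collinear columns are dropped with a warning and recorded.
#'
#' @param traits data.frame with \code{uid} and the trait/covariate columns.
#' @param trait name of the trait column.
#' @param covariates character vector of covariate column names (may be
#'   empty: residuals are then deviations from the grand mean).
#' @param genotypes optional dosage matrix (individuals x SNPs, rownames uid).
#' @param adjustSNPs optional SNP ids to adjust for.
#' @return A [ResidualTrait-class].
#' @export
residualizeTrait <- function(traits, trait, covariates = character(0),
                             genotypes = NULL, adjustSNPs = NULL) {
  y <- traits[[trait]]
  keep <- !is.na(y)
  for (cv in covariates) keep <- keep & !is.na(traits[[cv]])
  tt <- traits[keep, , drop = FALSE]
  d <- .buildDesign(tt, covariates, genotypes, adjustSNPs)
  if (length(d$dropped))
    warning("dropping monomorphic SNP column(s): ",
            paste(d$dropped, collapse = ", "))
  fit <- stats::lm.fit(d$X, tt[[trait]])
  aliased <- is.na(fit$coefficients)
  if (any(aliased)) {
    warning("dropping collinear column(s): ",
            paste(names(fit$coefficients)[aliased], collapse = ", "))
    d$dropped <- c(d$dropped, names(fit$coefficients)[aliased])
    fit <- stats::lm.fit(d$X[, !aliased, drop = FALSE], tt[[trait]])
  }
  res <- stats::setNames(fit$residuals, tt$uid)
  new("ResidualTrait", residuals = res,
      coefficients = fit$coefficients, dropped = d$dropped,
      trait = trait, covariates = as.character(covariates),
      snps = setdiff(as.character(adjustSNPs), d$dropped))
}

setMethod("show", "ResidualTrait", function(object) {
  cat("ResidualTrait '", object@trait, "': n = ", length(object@residuals),
      "; covariates: ", paste(object@covariates, collapse = ", "),
      if (length(object@snps))
        paste0("; adjusted SNPs: ", paste(object@snps, collapse = ", ")),
      "\n", sep = "")
})

# Per-locus sum over within-family pairs i<j of w_i w_j pi_ij, computed from
# founder-allele labels without enumerating pairs: group allele slots by
# label L with weight sums t_L; then (non-inbred labels)
#   sum_{i<j} w_i w_j pi_ij = (sum_L t_L^2 - 2 sum_i w_i^2) / 4.
# labsPat/labsMat: n x L integer label matrices; w: per-individual weights.
.pairProductSums <- function(labsPat, labsMat, w, maxLab) {
  L <- ncol(labsPat)
  T <- matrix(0, maxLab, L)
  colIdx <- maxLab * (seq_len(L) - 1L)
  for (i in seq_len(nrow(labsPat))) {
    if (w[i] == 0) next
    idx <- labsPat[i, ] + colIdx
    T[idx] <- T[idx] + w[i]
    idx <- labsMat[i, ] + colIdx
    T[idx] <- T[idx] + w[i]
  }
  (colSums(T^2) - 2 * sum(w^2)) / 4
}

# Family-wise version: returns loci x family matrix. Labels are disjoint by
# family, so restricting the weight vector per family suffices.
.pairProductSumsByFamily <- function(ibd, w, fams) {
  maxLab <- max(ibd@pat[, 1L], ibd@mat[, 1L])
  out <- matrix(0, length(ibd@loci), length(fams),
                dimnames = list(NULL, fams))
  for (f in fams) {
    wf <- ifelse(ibd@fid == f, w, 0)
    if (all(wf == 0)) next
    out[, f] <- .pairProductSums(ibd@pat, ibd@mat, wf, maxLab)
  }
  out
}

# Per-family constant sum_{i<j in f} w_i w_j * 2 phi_ij, from the kinship
# matrix: (w' K w - sum_i w_i^2 K_ii) / 2 restricted to the family block,
# with K = 2 * kinship.
.pairProductExpectation <- function(kin, w, fid, fams) {
  K <- 2 * kin
  vapply(fams, function(f) {
    r <- which(fid == f & w != 0)
    if (length(r) < 2L) return(0)
    Kf <- K[r, r, drop = FALSE]
    (as.numeric(t(w[r]) %*% Kf %*% w[r]) - sum(w[r]^2 * diag(Kf))) / 2
  }, numeric(1))
}

# Null variance per family of the pair-product score via fresh gene drops.
.mcProductVar <- function(ped, w, nDrops, seed, chunkSize = 2000L) {
  tab <- ped@tab
  idx <- .dropIndex(tab)
  fams <- unique(tab$fid[w != 0])
  maxLab <- 2L * sum(tab$founder)
  withr::local_seed(as.integer(seed))
  sums <- matrix(0, nDrops, length(fams), dimnames = list(NULL, fams))
  done <- 0L
  while (done < nDrops) {
    b <- min(as.integer(chunkSize), nDrops - done)
    dr <- .geneDropRaw(tab, idx, b)
    for (f in fams) {
      wf <- ifelse(tab$fid == f, w, 0)
      sums[(done + 1):(done + b), f] <-
        .pairProductSums(dr$pat, dr$mat, wf, maxLab)
    }
    done <- done + b
  }
  apply(sums, 2, stats::var)
}

#' Score-based robust linkage scan for a quantitative trait
#'
#' Per locus, the score numerator is
#' \deqn{N = \sum_{i<j} \tilde r_i \tilde r_j (\pi_{ij} - 2\phi_{ij})}
#' over all within-family pairs, where \eqn{\tilde r} are the
#' covariate-adjusted residuals standardized to unit sample variance. The
#' null variance \eqn{Var(N) = \sum\sum s_{ij} s_{kl} Cov(\pi_{ij},
#' \pi_{kl})} is a function of pedigree structure only and is estimated by
#' seeded gene-dropping Monte Carlo (constant across loci). Z = N/sqrt(Var)
#' and LOD = Z^2/(2 ln 10) for Z > 0, else 0. Parent-offspring pairs are
#' retained (trait linkage uses all pairs). Individuals without a residual
#' (missing trait or covariates) are excluded throughout.
#'
#' @param res a [ResidualTrait-class].
#' @param ibd [IBDSharing-class] at the scanned loci.
#' @param ped the [Pedigree-class].
#' @param kin optional precomputed [kinshipMatrix()].
#' @param loci optional subset of locus names to scan.
#' @param nDrops gene drops for the null variance (default 2000).
#' @param seed mandatory seed for the variance estimation.
#' @return data.frame per locus: locus, N, Z, LOD. Attributes
#'   \code{familyZ}, \code{familyLOD}, \code{familyVar},
#'   \code{standardization} (the residual SD used).
#' @export
qtScoreScan <- function(res, ibd, ped, kin = NULL, loci = NULL,
                        nDrops = 2000L, seed = 1L) {
  tab <- ped@tab
  sdr <- stats::sd(res@residuals)
  if (!is.finite(sdr)) stop("zero residual variance")
  r <- res@residuals[match(tab$uid, names(res@residuals))]
  r[is.na(r)] <- 0
  if (sdr < 1e-8) {
    # trait fully explained by the covariate fit: flat null scan
    lociOut <- if (is.null(loci)) ibd@loci else loci
    out <- data.frame(locus = lociOut, N = 0, Z = 0, LOD = 0)
    attr(out, "standardization") <- 0
    return(out)
  }
  w <- r / sdr
  if (is.null(kin)) kin <- kinshipMatrix(ped)

  sub <- ibd
  if (!is.null(loci)) {
    li <- match(loci, ibd@loci)
    if (anyNA(li)) stop("unknown locus: ", paste(loci[is.na(li)], collapse = ", "))
    sub <- new("IBDSharing", pat = ibd@pat[, li, drop = FALSE],
               mat = ibd@mat[, li, drop = FALSE], uid = ibd@uid,
               fid = ibd@fid, loci = ibd@loci[li])
  }
  if (any(sub@uid != tab$uid)) stop("ibd and ped must index the same individuals")

  fams <- unique(tab$fid[w != 0])
  raw <- .pairProductSumsByFamily(sub, w, fams)        # loci x fam
  expf <- .pairProductExpectation(kin, w, tab$fid, fams)
  famNum <- sweep(raw, 2, expf)
  famVar <- .mcProductVar(ped, w, nDrops = nDrops, seed = seed)
  famVar <- pmax(famVar, 0)
  totVar <- sum(famVar)
  if (totVar <= 0) stop("degenerate: null score variance is zero")
  num <- rowSums(famNum)
  z <- num / sqrt(totVar)
  out <- data.frame(locus = sub@loci, N = num, Z = z, LOD = .lodFromZ(z))
  famZ <- sweep(famNum, 2, sqrt(pmax(famVar, .Machine$double.eps)), "/")
  famZ[, famVar == 0] <- 0
  attr(out, "familyZ") <- famZ
  attr(out, "familyLOD") <- .lodFromZ(famZ)
  attr(out, "familyVar") <- famVar
  attr(out, "standardization") <- sdr
  out
}

#' Conditional linkage scan adjusting for candidate SNPs
#'
#' Residualizes the trait with the candidate SNP dosages included as
#' additive covariates, re-runs the score scan, and reports LOD before and
#' after adjustment per locus. A LOD that collapses after adjustment
#' indicates the SNPs account for the linkage signal.
#'
#' @param traits,trait,covariates as in [residualizeTrait()].
#' @param genotypes dosage matrix (individuals x SNPs).
#' @param snps SNP ids to adjust for.
#' @param ibd,ped,kin,loci,nDrops,seed as in [qtScoreScan()].
#' @return data.frame per locus: locus, LODbefore, LODafter, Zbefore, Zafter.
#' @export
conditionalScan <- function(traits, trait, covariates, genotypes, snps,
                            ibd, ped, kin = NULL, loci = NULL,
                            nDrops = 2000L, seed = 1L) {
  if (is.null(kin)) kin <- kinshipMatrix(ped)
  r0 <- residualizeTrait(traits, trait, covariates)
  r1 <- residualizeTrait(traits, trait, covariates, genotypes, snps)
  s0 <- qtScoreScan(r0, ibd, ped, kin, loci, nDrops, seed)
  s1 <- qtScoreScan(r1, ibd, ped, kin, loci, nDrops, seed)
  data.frame(locus = s0$locus, Zbefore = s0$Z, Zafter = s1$Z,
             LODbefore = s0$LOD, LODafter = s1$LOD)
}
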