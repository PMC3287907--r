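# Multidimensional-scaling structure analysis on founders, with projection
# of nonfounders from their relationships to founders.

#' Classical MDS of founders from genotype distances
#'
#' Founders are the independent draws from the source population(s);
#' nonfounders merely recombine founder alleles, so structure is estimated
#' on founders only. Dosages are standardized by founder allele frequencies
#' ((g - 2p)/sqrt(2p(1-p)); monomorphic SNPs skipped) and classical
#' (metric) MDS of the Euclidean distances gives the top-k principal
#' coordinates. Founder coordinates are centered at zero and components
#' ordered by decreasing eigenvalue.
#'
#' @param genotypes dosage matrix (individuals x SNPs, rownames uid).
#' @param ped a [Pedigree-class].
#' @param k number of components (default 1); must be < number of founders.
#' @param mafMin minimum founder MAF for a SNP to enter the distance
#'   (default 0.05): rare variants carry almost no ancestry information but
#'   their standardized dosages are extreme outliers that would dominate
#'   the distances.
#' @return data.frame: uid, fid, PC1..PCk, projected (FALSE for founders).
#'   Attribute \code{"eigenvalues"}.
#' @export
founderMDS <- function(genotypes, ped, k = 1L, mafMin = 0.05) {
  fnd <- intersect(founders(ped), rownames(genotypes))
  if (k >= length(fnd)) stop("k must be smaller than the number of founders")
  G <- genotypes[fnd, , drop = FALSE]
  p <- colMeans(G, na.rm = TRUE) / 2
  poly <- p >= mafMin & p <= 1 - mafMin
  G <- G[, poly, drop = FALSE]; p <- p[poly]
  if (!ncol(G)) {
    coords <- matrix(0, length(fnd), k)
    eig <- rep(0, k)
  } else {
    Z <- sweep(sweep(G, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
    Z[is.na(Z)] <- 0
    mds <- suppressWarnings(stats::cmdscale(stats::dist(Z), k = k,
                                            eig = TRUE))
    coords <- mds$points
    if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
    if (ncol(coords) < k)   # degenerate geometry: pad with zeros
      coords <- cbind(coords, matrix(0, nrow(coords), k - ncol(coords)))
    eig <- mds$eig[seq_len(k)]
  }
  out <- data.frame(uid = fnd, fid = ped@tab$fid[match(fnd, ped@tab$uid)],
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) out[[paste0("PC", j)]] <- coords[, j]
  out$projected <- FALSE
  attr(out, "eigenvalues") <- eig
  attr(out, "k") <- k
  out
}

#' Project nonfounders onto founder MDS components
#'
#' Nonfounder coordinates are approximated from their relationship to
#' founders. Default \code{"midparent"}: each nonfounder's coordinate is
#' the mean of its parents' coordinates (the expected standardized genotype
#' of an offspring is the parental mean), resolved in generation order.
#' Alternative \code{"kinship"}: kinship-weighted regression on founder
#' coordinates, \eqn{c_i = \phi_{iF} \Phi_{FF}^{-1} c_F}. Projection is
#' linear in the founder coordinates.
#'
#' @param structure result of [founderMDS()].
#' @param ped a [Pedigree-class].
#' @param method "midparent" (default) or "kinship".
#' @return data.frame as [founderMDS()] covering every individual,
#'   in pedigree order, with \code{projected = TRUE} for nonfounders.
#' @export
projectNonfounders <- function(structure, ped, method = c("midparent",
                                                          "kinship")) {
  method <- match.arg(method)
  tab <- ped@tab
  k <- attr(structure, "k")
  if (is.null(k)) k <- sum(grepl("^PC[0-9]+$", names(structure)))
  pcs <- paste0("PC", seq_len(k))
  coords <- matrix(NA_real_, nrow(tab), k,
                   dimnames = list(tab$uid, pcs))
  fi <- match(structure$uid, tab$uid)
  coords[fi, ] <- as.matrix(structure[, pcs, drop = FALSE])
  if (method == "midparent") {
    ord <- .topoOrder(tab)
    fIdx <- match(tab$father, tab$uid); mIdx <- match(tab$mother, tab$uid)
    for (i in ord) {
      if (!is.na(coords[i, 1])) next
      if (tab$founder[i])
        stop("founder without coordinates: ", tab$uid[i])
      coords[i, ] <- (coords[fIdx[i], ] + coords[mIdx[i], ]) / 2
    }
  } else {
    kin <- kinshipMatrix(ped)
    fnd <- structure$uid
    Kff <- kin[fnd, fnd, drop = FALSE]
    nonf <- tab$uid[!(tab$uid %in% fnd)]
    Knf <- kin[nonf, fnd, drop = FALSE]
    coords[nonf, ] <- Knf %*% solve(Kff,
                                    as.matrix(structure[, pcs, drop = FALSE]))
  }
  out <- data.frame(uid = tab$uid, fid = tab$fid, stringsAsFactors = FALSE)
  for (j in seq_len(k)) out[[pcs[j]]] <- coords[, j]
  out$projected <- !(tab$uid %in% structure$uid)
  attr(out, "eigenvalues") <- attr(structure, "eigenvalues")
  attr(out, "k") <- k
  attr(out, "method") <- method
  out
}
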