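# Carrier-based screening of rare/less-frequent variants, founder allele
# frequencies, and LD / carrier-subset pruning of screened hits.

#' Founder-based minor allele frequencies
#'
#' Allele frequencies estimated from founders only, who represent the
#' general population (nonfounders over-count the alleles segregating in
#' large sibships). The minor allele is defined cohort-wide (over all
#' genotyped individuals); the reported frequency is that allele's count
#' among genotyped founders divided by twice the number of genotyped
#' founders. Missing genotypes are excluded from the denominator.
#'
#' @param genotypes dosage matrix (individuals x SNPs, rownames uid).
#' @param ped a [Pedigree-class].
#' @return Named numeric vector of founder MAFs (NA when no founder is
#'   genotyped at a SNP).
#' @examples
#' # 2 copies among 202 founders: 2/404 = 0.005 (3 decimals)
#' @export
founderMAF <- function(genotypes, ped) {
  fnd <- intersect(founders(ped), rownames(genotypes))
  if (!length(fnd)) stop("no genotyped founders")
  G <- genotypes[fnd, , drop = FALSE]
  nAll <- 2 * colSums(!is.na(genotypes[intersect(ped@tab$uid,
                                                 rownames(genotypes)), ,
                                       drop = FALSE]))
  cohortFreq <- colSums(genotypes[intersect(ped@tab$uid, rownames(genotypes)),
                                  , drop = FALSE], na.rm = TRUE) / nAll
  minorIsCoded <- cohortFreq <= 0.5
  nF <- 2 * colSums(!is.na(G))
  cntCoded <- colSums(G, na.rm = TRUE)
  maf <- ifelse(minorIsCoded, cntCoded, nF - cntCoded) / nF
  maf[nF == 0] <- NA
  stats::setNames(maf, colnames(genotypes))
}

.regionSnps <- function(map, region) {
  if (is.null(region)) return(map$snp)
  map$snp[map$chr == as.character(region[[1]]) &
          map$pos >= as.numeric(region[[2]]) &
          map$pos <= as.numeric(region[[3]])]
}

.familyPrivate <- function(carrierUid, ped) {
  f <- ped@tab$fid[match(carrierUid, ped@tab$uid)]
  length(unique(f)) == 1L
}

#' Screen rare variants by carrier affection odds
#'
#' At each SNP with founder MAF below \code{mafMax}, computes the odds of
#' being affected among carriers of the minor allele
#' (affected carriers / unaffected carriers). SNPs whose carrier odds reach
#' \code{oddsMin} (or fall below 1/\code{oddsMin} when \code{protective}) and
#' that have at least \code{minCarriers} carriers are emitted as hits,
#' ordered by position then id. When all carriers belong to one family the
#' hit is flagged family-private. Zero unaffected carriers give odds +Inf
#' with both counts still reported. The optional likelihood score is the
#' binomial log-likelihood ratio of the carrier affection counts against the
#' overall prevalence (gives less weight to tiny carrier groups).
#'
#' @param genotypes dosage matrix (individuals x SNPs, rownames uid).
#' @param affection named 0/1 vector or data.frame (uid, affected).
#' @param mafs founder MAFs from [founderMAF()].
#' @param ped a [Pedigree-class] (for the family-privacy flag).
#' @param map optional data.frame (snp, chr, pos) to restrict by region and
#'   annotate positions.
#' @param region optional list/vector (chr, startBp, endBp).
#' @param mafMax MAF cutoff defining "rare or less frequent" (default 0.05).
#' @param oddsMin carrier-odds threshold (default 1.0).
#' @param minCarriers minimum carrier count (default 3).
#' @param protective also screen for odds <= 1/oddsMin (off by default).
#' @param likelihoodScore add the binomial log-likelihood-ratio score.
#' @return data.frame of hits: snp, chr, pos, maf, carriersAffected,
#'   carriersUnaffected, odds, familyPrivate (plus llr when requested).
#' @export
carrierOddsScreen <- function(genotypes, affection, mafs, ped, map = NULL,
                              region = NULL, mafMax = 0.05, oddsMin = 1.0,
                              minCarriers = 3L, protective = FALSE,
                              likelihoodScore = FALSE) {
  aff <- .affVector(affection)
  ids <- intersect(rownames(genotypes), names(aff))
  G <- genotypes[ids, , drop = FALSE]
  aff <- aff[ids]
  snps <- colnames(G)
  if (!is.null(region)) {
    if (is.null(map)) stop("region filtering needs a map")
    snps <- intersect(snps, .regionSnps(map, region))
  }
  snps <- snps[!is.na(mafs[snps]) & mafs[snps] < mafMax & mafs[snps] > 0]
  if (!length(snps)) return(.emptyHits(likelihoodScore))
  prev <- mean(aff)
  rows <- lapply(snps, function(s) {
    carrier <- !is.na(G[, s]) & G[, s] >= 1
    nA <- sum(aff[carrier] == 1); nU <- sum(aff[carrier] == 0)
    nC <- nA + nU
    if (nC < minCarriers) return(NULL)
    odds <- if (nU > 0) nA / nU else Inf
    hit <- odds >= oddsMin || (protective && odds <= 1 / oddsMin)
    if (!hit) return(NULL)
    out <- data.frame(snp = s,
                      chr = if (!is.null(map)) map$chr[match(s, map$snp)] else NA,
                      pos = if (!is.null(map)) map$pos[match(s, map$snp)] else NA,
                      maf = unname(mafs[s]), carriersAffected = nA,
                      carriersUnaffected = nU, odds = odds,
                      familyPrivate = .familyPrivate(ids[carrier], ped))
    if (likelihoodScore) {
      ph <- nA / nC
      ll1 <- ifelse(nA > 0, nA * log(ph), 0) + ifelse(nU > 0, nU * log(1 - ph), 0)
      ll0 <- nA * log(prev) + nU * log(1 - prev)
      out$llr <- ll1 - ll0
    }
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.emptyHits(likelihoodScore))
  out <- do.call(rbind, rows)
  out <- out[order(out$pos, out$snp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyHits <- function(likelihoodScore = FALSE, qt = FALSE) {
  out <- data.frame(snp = character(0), chr = character(0), pos = numeric(0),
                    maf = numeric(0), carriersAffected = integer(0),
                    carriersUnaffected = integer(0), odds = numeric(0),
                    familyPrivate = logical(0))
  if (qt) {
    out$carriersAffected <- NULL; out$carriersUnaffected <- NULL
    out$odds <- NULL
    out$nCarriers <- integer(0); out$shiftSD <- numeric(0)
  }
  if (likelihoodScore) out$llr <- numeric(0)
  out
}

#' Screen rare variants by the carrier phenotype distribution
#'
#' For a quantitative trait, flags SNPs (founder MAF < \code{mafMax}, at
#' least \code{minCarriers} carriers) whose carriers' mean covariate-adjusted
#' residual is shifted by at least \code{shiftMinSd} residual standard
#' deviations from zero, in either direction.
#'
#' @param genotypes dosage matrix.
#' @param res a [ResidualTrait-class] (covariate-adjusted residuals).
#' @param mafs founder MAFs.
#' @param ped a [Pedigree-class].
#' @param map,region optional region restriction as in
#'   [carrierOddsScreen()].
#' @param mafMax MAF cutoff (default 0.05).
#' @param shiftMinSd minimum |carrier mean shift| in residual SD units.
#' @param minCarriers minimum carrier count (default 3).
#' @return data.frame of hits: snp, chr, pos, maf, nCarriers, shiftSD,
#'   familyPrivate.
#' @export
carrierQtScreen <- function(genotypes, res, mafs, ped, map = NULL,
                            region = NULL, mafMax = 0.05, shiftMinSd = 1.0,
                            minCarriers = 3L) {
  r <- res@residuals
  ids <- intersect(rownames(genotypes), names(r))
  G <- genotypes[ids, , drop = FALSE]
  r <- r[ids]
  sdr <- stats::sd(r)
  snps <- colnames(G)
  if (!is.null(region)) {
    if (is.null(map)) stop("region filtering needs a map")
    snps <- intersect(snps, .regionSnps(map, region))
  }
  snps <- snps[!is.na(mafs[snps]) & mafs[snps] < mafMax & mafs[snps] > 0]
  rows <- lapply(snps, function(s) {
    carrier <- !is.na(G[, s]) & G[, s] >= 1
    nC <- sum(carrier)
    if (nC < minCarriers) return(NULL)
    shift <- mean(r[carrier]) / sdr
    if (abs(shift) < shiftMinSd) return(NULL)
    data.frame(snp = s,
               chr = if (!is.null(map)) map$chr[match(s, map$snp)] else NA,
               pos = if (!is.null(map)) map$pos[match(s, map$snp)] else NA,
               maf = unname(mafs[s]), nCarriers = nC, shiftSD = shift,
               familyPrivate = .familyPrivate(ids[carrier], ped))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.emptyHits(qt = TRUE))
  out <- do.call(rbind, rows)
  out <- out[order(out$pos, out$snp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' EM haplotype frequencies and LD for a SNP pair
#'
#' Two-locus haplotype frequencies from unphased founder genotypes by EM
#' (double heterozygotes are the only ambiguous class), and the derived
#' \eqn{r^2} and \eqn{D'}.
#'
#' @param g1,g2 dosage vectors at the two SNPs (same individuals).
#' @param maxIter,tol EM controls.
#' @return list(hap = 2x2 haplotype frequency matrix, r2, dprime, D).
#' @export
emLD <- function(g1, g2, maxIter = 100L, tol = 1e-10) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  # haplotypes: 11 (minor-minor), 10, 01, 00 at the coded (minor) alleles
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  dh <- g1 == 1 & g2 == 1
  nDH <- sum(dh)
  gg1 <- g1[!dh]; gg2 <- g2[!dh]
  # phase is determined for every genotype class except double heterozygotes
  tal <- function(a, b) {
    # returns counts of haplotypes 11,10,01,00 for one non-double-het indiv
    if (a == 1 && b == 1) stop("double het")
    h11 <- min(a, b); rem <- abs(a - b)
    if (a > b) c(h11, rem, 0, 2 - h11 - rem)
    else c(h11, 0, rem, 2 - h11 - rem)
  }
  cnt <- c(0, 0, 0, 0)
  for (i in seq_along(gg1)) cnt <- cnt + tal(gg1[i], gg2[i])
  for (it in seq_len(maxIter)) {
    # E step: split double hets between cis (11/00) and trans (10/01)
    pc <- h[1] * h[4]; pt <- h[2] * h[3]
    wc <- if (pc + pt > 0) pc / (pc + pt) else 0.5
    e <- cnt + nDH * c(wc, 1 - wc, 1 - wc, wc)
    hNew <- e / sum(e)
    if (max(abs(hNew - h)) < tol) { h <- hNew; break }
    h <- hNew
  }
  pA <- h[1] + h[2]; pB <- h[1] + h[3]
  D <- h[1] - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- if (denom > 0) D^2 / denom else NA_real_
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (!is.na(r2) && dmax > 0) D / dmax else NA_real_
  list(hap = matrix(h, 2, 2, byrow = TRUE,
                    dimnames = list(snp1 = c("minor", "major"),
                                    snp2 = c("minor", "major"))),
       r2 = r2, dprime = dprime, D = D)
}

#' Prune screened hits by LD and carrier-subset structure
#'
#' Computes pairwise \eqn{r^2} and \eqn{D'} between hit SNPs from founder
#' genotypes (EM haplotype frequencies, phase unknown) and the
#' carrier-subset relations between hits. Hits in complete LD
#' (\eqn{r^2 = 1} within tolerance) are grouped and one representative per
#' group retained: the one with the more extreme screen statistic, ties
#' broken by lower position. Carrier-subset relations ("B subset-of A") are
#' annotated on the retained hits.
#'
#' @param hits data.frame from [carrierOddsScreen()] or
#'   [carrierQtScreen()].
#' @param genotypes dosage matrix (individuals x SNPs).
#' @param ped a [Pedigree-class] (founders used for LD).
#' @param r2Complete threshold treated as complete LD (default 0.999).
#' @return The pruned hits with columns \code{ldGroup} and \code{subsetOf}
#'   added; attribute \code{"ld"} holds the pairwise LD table.
#' @export
pruneHits <- function(hits, genotypes, ped, r2Complete = 0.999) {
  if (nrow(hits) < 2L) {
    if (nrow(hits) == 1L) { hits$ldGroup <- 1L; hits$subsetOf <- NA_character_ }
    return(hits)
  }
  fnd <- intersect(founders(ped), rownames(genotypes))
  Gf <- genotypes[fnd, hits$snp, drop = FALSE]
  G <- genotypes[, hits$snp, drop = FALSE]
  n <- nrow(hits)
  ld <- NULL
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    e <- emLD(Gf[, i], Gf[, j])
    ld <- rbind(ld, data.frame(snp1 = hits$snp[i], snp2 = hits$snp[j],
                               r2 = e$r2, dprime = e$dprime))
    if (!is.na(e$r2) && e$r2 >= r2Complete)
      parent[findRoot(j)] <- findRoot(i)
  }
  group <- vapply(seq_len(n), findRoot, integer(1))
  hits$ldGroup <- match(group, unique(group))
  # carrier subset relations over the full cohort
  carriers <- lapply(seq_len(n), function(k)
    rownames(G)[!is.na(G[, k]) & G[, k] >= 1])
  subsetOf <- rep(NA_character_, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (length(carriers[[i]]) && all(carriers[[i]] %in% carriers[[j]]) &&
        length(carriers[[i]]) < length(carriers[[j]]))
      subsetOf[i] <- if (is.na(subsetOf[i])) hits$snp[j]
                     else paste(subsetOf[i], hits$snp[j], sep = ",")
  }
  hits$subsetOf <- subsetOf
  stat <- if ("odds" %in% names(hits)) {
    s <- hits$odds; s[is.infinite(s)] <- .Machine$double.xmax; s
  } else abs(hits$shiftSD)
  keep <- logical(n)
  for (g in unique(hits$ldGroup)) {
    idx <- which(hits$ldGroup == g)
    best <- idx[order(-stat[idx], hits$pos[idx], hits$snp[idx])][1L]
    keep[best] <- TRUE
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ld") <- ld
  out
}
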