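# Family-based association: TDT, generalized disequilibrium test,
# cluster-robust logistic regression, gene-level collapsing.

#' Odds ratio from a log-odds estimate
#'
#' The transform used throughout the association reports:
#' \code{OR = exp(estimate)}.
#'
#' @param logOdds log-odds (logistic regression coefficient).
#' @return The odds ratio.
#' @examples
#' oddsRatio(0.57)  # 1.77
#' @export
oddsRatio <- function(logOdds) exp(logOdds)

#' Transmission disequilibrium test
#'
#' For every SNP, counts transmissions (b) and non-transmissions (c) of the
#' minor allele from heterozygous parents to affected offspring over all
#' genotyped parent-offspring trios, and tests \eqn{\chi^2 = (b - c)^2 /
#' (b + c)} on 1 df. Only affected offspring with both parents genotyped are
#' used; missing parental genotypes are not reconstructed. Both-parents-
#' heterozygous transmissions are resolved through the offspring genotype
#' (dosage 0: two non-transmissions; 2: two transmissions; 1: one of each).
#'
#' @param genotypes dosage matrix (individuals x SNPs, rownames uid).
#' @param ped a [Pedigree-class].
#' @param affection named (uid) 0/1 vector or data.frame with uid, affected.
#' @return data.frame per SNP: snp, b, c, chisq, p, tested.
#' @export
tdt <- function(genotypes, ped, affection) {
  aff <- .affVector(affection)
  tab <- ped@tab
  off <- which(!tab$founder & tab$uid %in% names(aff)[aff == 1])
  off <- off[tab$father[off] %in% rownames(genotypes) &
             tab$mother[off] %in% rownames(genotypes) &
             tab$uid[off] %in% rownames(genotypes)]
  nsnp <- ncol(genotypes)
  b <- numeric(nsnp); cc <- numeric(nsnp)
  for (o in off) {
    gF <- genotypes[tab$father[o], ]
    gM <- genotypes[tab$mother[o], ]
    gC <- genotypes[tab$uid[o], ]
    for (gP in list(list(p = gF, q = gM), list(p = gM, q = gF))) {
      het <- !is.na(gP$p) & gP$p == 1 & !is.na(gP$q) & !is.na(gC)
      oneHet <- het & gP$q != 1
      b[oneHet] <- b[oneHet] + (gC[oneHet] - gP$q[oneHet] %/% 2 > 0)
      cc[oneHet] <- cc[oneHet] + (gC[oneHet] - gP$q[oneHet] %/% 2 <= 0)
    }
    # both parents heterozygous: resolved jointly from the child dosage
    bothHet <- !is.na(gF) & !is.na(gM) & gF == 1 & gM == 1 & !is.na(gC)
    b[bothHet] <- b[bothHet] + gC[bothHet]
    cc[bothHet] <- cc[bothHet] + (2 - gC[bothHet])
  }
  tot <- b + cc
  chisq <- ifelse(tot > 0, (b - cc)^2 / tot, NA)
  data.frame(snp = colnames(genotypes), b = b, c = cc, chisq = chisq,
             p = ifelse(tot > 0,
                        stats::pchisq(chisq, 1, lower.tail = FALSE), NA),
             tested = tot > 0, row.names = NULL)
}

.affVector <- function(affection) {
  if (is.data.frame(affection))
    stats::setNames(as.integer(as.logical(affection$affected)), affection$uid)
  else stats::setNames(as.integer(as.logical(affection)), names(affection))
}

#' Generalized disequilibrium test
#'
#' Within-family allele-frequency contrast over all discordant relative
#' pairs: for family f the score is \eqn{U_f = \sum_{i \in aff, j \in unaff}
#' (g_i - g_j)} over genotyped affected-unaffected pairs; the test statistic
#' is \eqn{Z = \sum_f U_f / \sqrt{\sum_f U_f^2}} with the empirical
#' (family-robust) variance. Families with no discordant genotyped pair
#' contribute nothing; SNPs with zero variance are flagged untested.
#' Implemented in the unweighted form; covariates do not enter (the test is
#' within-family).
#'
#' @inheritParams tdt
#' @return data.frame per SNP: snp, T, varT, Z, p, tested.
#' @export
gdt <- function(genotypes, ped, affection) {
  aff <- .affVector(affection)
  tab <- ped@tab
  nsnp <- ncol(genotypes)
  Tsum <- numeric(nsnp); Vsum <- numeric(nsnp)
  informative <- FALSE
  for (f in unique(tab$fid)) {
    uids <- tab$uid[tab$fid == f]
    uids <- uids[uids %in% rownames(genotypes) & uids %in% names(aff)]
    a <- uids[aff[uids] == 1]; u <- uids[aff[uids] == 0]
    if (!length(a) || !length(u)) next
    informative <- TRUE
    Ga <- genotypes[a, , drop = FALSE]; Gu <- genotypes[u, , drop = FALSE]
    Uf <- length(u) * colSums(Ga) - length(a) * colSums(Gu)
    Tsum <- Tsum + Uf
    Vsum <- Vsum + Uf^2
  }
  if (!informative) stop("no family with both affected and unaffected ",
                         "genotyped members")
  tested <- Vsum > 0
  z <- ifelse(tested, Tsum / sqrt(Vsum), NA)
  data.frame(snp = colnames(genotypes), T = Tsum, varT = Vsum, Z = z,
             p = ifelse(tested, 2 * stats::pnorm(-abs(z)), NA),
             tested = tested, row.names = NULL)
}

#' Cluster-robust (sandwich) logistic regression
#'
#' Maximum-likelihood logistic regression of affection status on covariates
#' and SNP dosages, with a cluster-robust sandwich covariance taking
#' families as the independent clusters. With one individual per cluster the
#' sandwich covariance reduces exactly to the heteroskedasticity-robust
#' (HC0) form. Odds ratios are exp(coefficient).
#'
#' @param affection named 0/1 vector or data.frame (uid, affected).
#' @param design data.frame or matrix of covariates/dosages, rows matching
#'   the affection entries (rownames or uid column used for alignment).
#' @param cluster family id per individual (character/factor).
#' @return data.frame per term: term, estimate, robustSE, OR, Z, p.
#'   Attribute \code{"nClusters"}.
#' @export
logisticSandwich <- function(affection, design, cluster) {
  aff <- .affVector(affection)
  X <- as.data.frame(design)
  if (nrow(X) != length(aff)) stop("design rows must match affection length")
  dat <- cbind(data.frame(.y = aff), X)
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
  if (!fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
    bad <- names(which.max(abs(stats::coef(fit))))
    stop("separation detected (diverging coefficient): ", bad)
  }
  vc <- sandwich::vcovCL(fit, cluster = as.factor(cluster),
                         type = "HC0", cadjust = FALSE)
  est <- stats::coef(fit)
  se <- sqrt(diag(vc))
  z <- est / se
  out <- data.frame(term = names(est), estimate = as.numeric(est),
                    robustSE = as.numeric(se), OR = oddsRatio(est),
                    Z = as.numeric(z), p = 2 * stats::pnorm(-abs(z)),
                    row.names = NULL)
  attr(out, "nClusters") <- length(unique(cluster))
  out
}

#' Collapse rare variants within genes to carrier indicators
#'
#' Per individual and gene, 1 when the individual carries any of the listed
#' rare variants, else 0 (rare-allele homozygotes are carriers too;
#' two-copy carriers are rare enough that the collapsed genotype is treated
#' as heterozygous). Idempotent: collapsing a collapsed column returns it
#' unchanged, and collapsing a single variant gives that variant's carrier
#' indicator.
#'
#' @param genotypes dosage matrix (individuals x SNPs).
#' @param geneMap data.frame with columns \code{snp}, \code{gene}.
#' @param variantIds optional subset of SNPs to collapse (default: all SNPs
#'   in \code{geneMap}).
#' @return Integer matrix individuals x genes of 0/1 carrier indicators.
#' @export
collapseGene <- function(genotypes, geneMap, variantIds = NULL) {
  if (!is.null(variantIds))
    geneMap <- geneMap[geneMap$snp %in% variantIds, , drop = FALSE]
  genes <- unique(geneMap$gene)
  out <- matrix(0L, nrow(genotypes), length(genes),
                dimnames = list(rownames(genotypes), genes))
  for (g in genes) {
    snps <- intersect(geneMap$snp[geneMap$gene == g], colnames(genotypes))
    if (!length(snps)) {
      warning("no variants available for gene ", g, "; all zeros")
      next
    }
    out[, g] <- as.integer(rowSums(genotypes[, snps, drop = FALSE] >= 1,
                                   na.rm = TRUE) > 0)
  }
  out
}
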