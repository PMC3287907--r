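# Gene-dropping IBD engine and the null covariance of IBD sharing.

# Family-wise structural index reused by the droppers.
.dropIndex <- function(tab) {
  list(ord = .topoOrder(tab),
       fi = match(tab$father, tab$uid),
       mi = match(tab$mother, tab$uid),
       founder = tab$founder)
}

# Core gene dropper: returns list(pat, mat) integer label matrices
# (n individuals x nLoci). Founder alleles get labels 2k-1, 2k in pedigree
# row order of founders, unique across the study. Assumes the RNG state is
# already set by the caller.
.geneDropRaw <- function(tab, idx, nLoci) {
  n <- nrow(tab)
  pat <- matrix(0L, n, nLoci)
  mat <- matrix(0L, n, nLoci)
  fRank <- cumsum(idx$founder)
  for (i in idx$ord) {
    if (idx$founder[i]) {
      pat[i, ] <- 2L * fRank[i] - 1L
      mat[i, ] <- 2L * fRank[i]
    } else {
      f <- idx$fi[i]; m <- idx$mi[i]
      pick <- stats::runif(nLoci) < 0.5
      pat[i, ] <- ifelse(pick, pat[f, ], mat[f, ])
      pick <- stats::runif(nLoci) < 0.5
      mat[i, ] <- ifelse(pick, pat[m, ], mat[m, ])
    }
  }
  list(pat = pat, mat = mat)
}

#' Gene-dropping simulation of founder-allele transmission
#'
#' Drops founder alleles down the pedigree independently at each locus:
#' every founder carries two uniquely labelled alleles and each nonfounder
#' inherits one allele from each parent with probability 1/2 per meiosis.
#' Loci are unlinked. Reproducible under \code{seed}; the caller's RNG state
#' is left untouched.
#'
#' @param ped a [Pedigree-class].
#' @param nLoci number of independent loci to drop (> 0).
#' @param seed mandatory integer seed.
#' @return An [IBDSharing-class].
#' @examples
#' trio <- Pedigree(fid = c(1,1,1), id = c("p1","p2","c1"),
#'                  father = c(0,0,"p1"), mother = c(0,0,"p2"), sex = c(1,2,1))
#' ibd <- geneDrop(trio, nLoci = 4, seed = 7)
#' ibdProportion(ibd, data.frame(uid1 = "p1", uid2 = "c1"))  # always 1/2
#' @export
geneDrop <- function(ped, nLoci, seed) {
  if (!is.numeric(nLoci) || length(nLoci) != 1L || nLoci <= 0)
    stop("nLoci must be a positive count")
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  nLoci <- as.integer(nLoci)
  tab <- ped@tab
  idx <- .dropIndex(tab)
  withr::local_seed(as.integer(seed))
  dr <- .geneDropRaw(tab, idx, nLoci)
  new("IBDSharing", pat = dr$pat, mat = dr$mat, uid = tab$uid,
      fid = tab$fid, loci = paste0("L", seq_len(nLoci)))
}

setMethod("show", "IBDSharing", function(object) {
  cat("IBDSharing: ", length(object@uid), " individuals x ",
      length(object@loci), " loci\n", sep = "")
})

#' Number of loci in an IBDSharing object
#' @param ibd an [IBDSharing-class].
#' @export
nLoci <- function(ibd) length(ibd@loci)

# pi between two label rows: proportion of alleles IBD in {0, 1/2, 1} for
# non-inbred pairs (each individual's two labels are then distinct).
.piRows <- function(p1, m1, p2, m2) {
  ((p1 == p2) + (p1 == m2) + (m1 == p2) + (m1 == m2)) / 2
}

#' Pairwise IBD proportions from founder-allele labels
#'
#' For each requested pair and each locus, the proportion \eqn{\pi} of
#' alleles shared identical by descent (0, 1/2 or 1 for non-inbred pairs).
#' Cross-family pairs share nothing; \eqn{E[\pi] = 2\phi}.
#'
#' @param ibd an [IBDSharing-class].
#' @param pairs data.frame with columns \code{uid1}, \code{uid2}.
#' @return Matrix (pairs x loci) of IBD proportions.
#' @export
ibdProportion <- function(ibd, pairs) {
  i <- match(as.character(pairs$uid1), ibd@uid)
  j <- match(as.character(pairs$uid2), ibd@uid)
  if (anyNA(i) || anyNA(j)) stop("unknown uid in pairs")
  out <- matrix(0, nrow(pairs), length(ibd@loci))
  for (k in seq_len(nrow(pairs)))
    out[k, ] <- .piRows(ibd@pat[i[k], ], ibd@mat[i[k], ],
                        ibd@pat[j[k], ], ibd@mat[j[k], ])
  rownames(out) <- paste(pairs$uid1, pairs$uid2, sep = "~")
  colnames(out) <- ibd@loci
  out
}

#' Export IBD proportions as long-format TSV
#'
#' Columns: family, id1, id2, locus, pi.
#'
#' @param ibd an [IBDSharing-class].
#' @param pairs data.frame with columns \code{fid}, \code{uid1}, \code{uid2}.
#' @param file output path.
#' @export
writeIBD <- function(ibd, pairs, file) {
  pm <- ibdProportion(ibd, pairs)
  long <- data.frame(
    family = rep(pairs$fid, times = ncol(pm)),
    id1 = rep(pairs$uid1, times = ncol(pm)),
    id2 = rep(pairs$uid2, times = ncol(pm)),
    locus = rep(colnames(pm), each = nrow(pm)),
    pi = as.vector(pm))
  utils::write.table(long, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# Ancestor closure (row indices) of a set of individuals.
.ancestorClosure <- function(tab, idx) {
  fi <- match(tab$father, tab$uid); mi <- match(tab$mother, tab$uid)
  seen <- logical(nrow(tab))
  stack <- idx
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (seen[v]) next
    seen[v] <- TRUE
    if (!is.na(fi[v])) stack <- c(stack, fi[v], mi[v])
  }
  which(seen)
}

# Exact pi matrix (pairs x configurations) by enumerating all transmission
# vectors of the nonfounders in the ancestor closure. Each nonfounder has 4
# equally likely (paternal pick, maternal pick) combinations.
.enumeratePi <- function(tab, pairIdx) {
  cl <- .ancestorClosure(tab, unique(c(pairIdx[, 1L], pairIdx[, 2L])))
  sub <- tab[cl, , drop = FALSE]
  # re-resolve parents inside the closure (ancestors are closed under parentage)
  loc <- match(sub$uid, sub$uid)  # identity, for clarity
  fi <- match(sub$father, sub$uid); mi <- match(sub$mother, sub$uid)
  nf <- which(!sub$founder)
  if (2L * length(nf) > 12L)
    stop("enumeration limited to <= 12 meioses in the ancestor closure; ",
         "use method = \"montecarlo\"")
  nC <- 4L^length(nf)
  cfg <- 0:(nC - 1L)
  n <- nrow(sub)
  pat <- matrix(0L, n, nC); mat <- matrix(0L, n, nC)
  fRank <- cumsum(sub$founder)
  ordSub <- .topoOrder(sub)
  nfPos <- match(ordSub[ordSub %in% nf], nf)  # enumeration digit per nonfounder
  for (i in ordSub) {
    if (sub$founder[i]) {
      pat[i, ] <- 2L * fRank[i] - 1L
      mat[i, ] <- 2L * fRank[i]
    } else {
      k <- match(i, nf)
      code <- (cfg %/% 4L^(k - 1L)) %% 4L
      bp <- code %% 2L; bm <- code %/% 2L
      pat[i, ] <- ifelse(bp == 0L, pat[fi[i], ], mat[fi[i], ])
      mat[i, ] <- ifelse(bm == 0L, pat[mi[i], ], mat[mi[i], ])
    }
  }
  i1 <- match(tab$uid[pairIdx[, 1L]], sub$uid)
  i2 <- match(tab$uid[pairIdx[, 2L]], sub$uid)
  pm <- matrix(0, nrow(pairIdx), nC)
  for (k in seq_len(nrow(pairIdx)))
    pm[k, ] <- .piRows(pat[i1[k], ], mat[i1[k], ], pat[i2[k], ], mat[i2[k], ])
  pm
}

#' Null covariance of IBD sharing across relative pairs
#'
#' Computes \eqn{Cov(\pi_{ij}, \pi_{kl})} over an ordered list of
#' within-family pairs under the null of no linkage, as a function of
#' pedigree structure only. \code{method = "enumerate"} is exact, by
#' exhausting all transmission vectors of the nonfounders in the ancestor
#' closure of the pair members (permitted up to 12 meioses);
#' \code{"montecarlo"} estimates the covariance from seeded gene drops and
#' reports elementwise Monte-Carlo standard errors. Pairs in different
#' families have covariance exactly 0 (enforced structurally).
#'
#' @param ped a [Pedigree-class].
#' @param pairs data.frame with columns \code{uid1}, \code{uid2} (and
#'   optionally \code{fid}).
#' @param method "auto" (enumerate when feasible), "enumerate" or
#'   "montecarlo".
#' @param nDrops gene drops for the Monte-Carlo method.
#' @param seed mandatory seed for the Monte-Carlo method.
#' @param chunkSize loci simulated per chunk (memory control).
#' @return A [PairCovariance-class].
#' @examples
#' ped <- Pedigree(fid = rep(1, 4), id = c("f", "m", "s1", "s2"),
#'                 father = c(0, 0, "f", "f"), mother = c(0, 0, "m", "m"),
#'                 sex = c(1, 2, 1, 2))
#' pc <- pairCovariance(ped, data.frame(uid1 = "s1", uid2 = "s2"),
#'                      method = "enumerate")
#' pc@sigma  # Var(pi) = 1/8 for full siblings
#' @export
pairCovariance <- function(ped, pairs,
                           method = c("auto", "enumerate", "montecarlo"),
                           nDrops = 10000L, seed = 1L, chunkSize = 5000L) {
  method <- match.arg(method)
  tab <- ped@tab
  i1 <- match(as.character(pairs$uid1), tab$uid)
  i2 <- match(as.character(pairs$uid2), tab$uid)
  if (anyNA(i1) || anyNA(i2)) stop("unknown uid in pairs")
  if (any(tab$fid[i1] != tab$fid[i2]))
    stop("all pairs must be within a family")
  pr <- data.frame(fid = tab$fid[i1], uid1 = tab$uid[i1], uid2 = tab$uid[i2],
                   stringsAsFactors = FALSE)
  nm <- paste(pr$uid1, pr$uid2, sep = "~")
  np <- nrow(pr)
  fids <- pr$fid
  sigma <- matrix(0, np, np, dimnames = list(nm, nm))
  expPi <- numeric(np)

  if (method == "auto") {
    feasible <- all(vapply(unique(fids), function(f) {
      idx <- which(fids == f)
      cl <- .ancestorClosure(tab, unique(c(i1[idx], i2[idx])))
      2L * sum(!tab$founder[cl]) <= 12L
    }, logical(1)))
    method <- if (feasible) "enumerate" else "montecarlo"
  }

  if (method == "enumerate") {
    for (f in unique(fids)) {
      idx <- which(fids == f)
      pm <- .enumeratePi(tab, cbind(i1[idx], i2[idx]))
      mu <- rowMeans(pm)
      cc <- tcrossprod(pm) / ncol(pm) - tcrossprod(mu)
      sigma[idx, idx] <- cc
      expPi[idx] <- mu
    }
    return(new("PairCovariance", sigma = sigma, expectedPi = expPi,
               pairs = pr, method = "enumerate", nDrops = 0L,
               mcse = matrix(0, 0, 0)))
  }

  # Monte Carlo: chunked accumulation of first/second moments.
  idx <- .dropIndex(tab)
  withr::local_seed(as.integer(seed))
  nDrops <- as.integer(nDrops)
  s1 <- numeric(np); s2 <- matrix(0, np, np); s2sq <- matrix(0, np, np)
  done <- 0L
  while (done < nDrops) {
    b <- min(as.integer(chunkSize), nDrops - done)
    dr <- .geneDropRaw(tab, idx, b)
    pm <- matrix(0, np, b)
    for (k in seq_len(np))
      pm[k, ] <- .piRows(dr$pat[i1[k], ], dr$mat[i1[k], ],
                         dr$pat[i2[k], ], dr$mat[i2[k], ])
    s1 <- s1 + rowSums(pm)
    s2 <- s2 + tcrossprod(pm)
    s2sq <- s2sq + tcrossprod(pm^2)
    done <- done + b
  }
  mu <- s1 / nDrops
  cc <- s2 / nDrops - tcrossprod(mu)
  # SE of each covariance entry from the variance of cross products
  vprod <- s2sq / nDrops - (s2 / nDrops)^2
  mcse <- sqrt(pmax(vprod, 0) / nDrops)
  cc[outer(fids, fids, "!=")] <- 0  # structural zeros across families
  dimnames(cc) <- list(nm, nm)
  new("PairCovariance", sigma = cc, expectedPi = mu, pairs = pr,
      method = "montecarlo", nDrops = nDrops, mcse = mcse)
}

setMethod("show", "PairCovariance", function(object) {
  cat("PairCovariance (", object@method, "): ", nrow(object@pairs),
      " pairs", if (object@method == "montecarlo")
        paste0(", ", object@nDrops, " drops"), "\n", sep = "")
})
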