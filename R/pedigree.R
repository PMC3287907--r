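# Pedigree construction, validation, kinship and relationship classification.

.SEX_CODES <- c(0L, 1L, 2L)

# Build the canonical pedigree table from raw vectors. Missing parents are
# "0" or NA on input and stored as NA. uid is the id itself when ids are
# globally unique, else "fid:id".
.pedBuild <- function(fid, id, father, mother, sex) {
  fid <- as.character(fid); id <- as.character(id)
  father <- as.character(father); mother <- as.character(mother)
  father[father %in% c("0", "", NA)] <- NA_character_
  mother[mother %in% c("0", "", NA)] <- NA_character_
  sex <- suppressWarnings(as.integer(sex))
  sex[is.na(sex)] <- 0L
  uid <- if (anyDuplicated(id) > 0L) paste(fid, id, sep = ":") else id
  fuid <- ifelse(is.na(father), NA_character_,
                 if (identical(uid, id)) father else paste(fid, father, sep = ":"))
  muid <- ifelse(is.na(mother), NA_character_,
                 if (identical(uid, id)) mother else paste(fid, mother, sep = ":"))
  data.frame(fid = fid, id = id, father = fuid, mother = muid,
             sex = sex, founder = is.na(fuid) & is.na(muid), uid = uid,
             stringsAsFactors = FALSE)
}

# Kahn's algorithm over parent->child edges; returns ordering indices or
# stops naming the individuals on a cycle.
.topoOrder <- function(tab) {
  n <- nrow(tab)
  fi <- match(tab$father, tab$uid)
  mi <- match(tab$mother, tab$uid)
  indeg <- (!is.na(fi)) + (!is.na(mi))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(fi[i])) children[[fi[i]]] <- c(children[[fi[i]]], i)
    if (!is.na(mi[i])) children[[mi[i]]] <- c(children[[mi[i]]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    loop <- setdiff(seq_len(n), ord)
    stop("cycle detected in pedigree involving: ",
         paste(tab$uid[loop], collapse = ", "))
  }
  ord
}

.pedValidate <- function(tab) {
  msg <- character(0)
  if (any(duplicated(paste(tab$fid, tab$id))))
    msg <- c(msg, paste("duplicate individual id within a family:",
                        paste(unique(tab$id[duplicated(paste(tab$fid, tab$id))]),
                              collapse = ", ")))
  single <- xor(is.na(tab$father), is.na(tab$mother))
  if (any(single))
    msg <- c(msg, paste("single-parent records (both parents must be present",
                        "or both missing):", paste(tab$uid[single], collapse = ", ")))
  for (col in c("father", "mother")) {
    p <- tab[[col]]
    known <- !is.na(p)
    hit <- match(p[known], tab$uid)
    if (anyNA(hit))
      msg <- c(msg, paste0("unresolved ", col, " reference: ",
                           paste(p[known][is.na(hit)], collapse = ", ")))
    else {
      if (any(tab$fid[hit] != tab$fid[known]))
        msg <- c(msg, paste0(col, " reference crosses families for: ",
                             paste(tab$uid[known][tab$fid[hit] != tab$fid[known]],
                                   collapse = ", ")))
      badsex <- if (col == "father") tab$sex[hit] == 2L else tab$sex[hit] == 1L
      if (any(badsex))
        msg <- c(msg, paste0(col, " with inconsistent sex: ",
                             paste(unique(p[known][badsex]), collapse = ", ")))
    }
  }
  if (!all(tab$sex %in% .SEX_CODES))
    msg <- c(msg, "sex must be coded 0 (unknown), 1 (male) or 2 (female)")
  if (!length(msg)) {
    ok <- tryCatch({ .topoOrder(tab); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) msg <- c(msg, ok)
  }
  msg
}

setValidity("Pedigree", function(object) {
  tab <- object@tab
  need <- c("fid", "id", "father", "mother", "sex", "founder", "uid")
  if (!all(need %in% names(tab)))
    return(paste("missing pedigree columns:",
                 paste(setdiff(need, names(tab)), collapse = ", ")))
  msg <- .pedValidate(tab)
  if (length(msg)) msg else TRUE
})

#' Construct a Pedigree
#'
#' Builds and validates a [Pedigree-class] from parallel vectors or a
#' data.frame with columns \code{fid}, \code{id}, \code{father},
#' \code{mother}, \code{sex}. \code{"0"}, \code{""} and \code{NA} denote a
#' missing parent (PLINK convention); sex is 1 = male, 2 = female,
#' 0 = unknown.
#'
#' @param fid family ids, or a data.frame holding all five columns.
#' @param id,father,mother,sex see description.
#' @return A validated [Pedigree-class]; individuals keep input order.
#' @examples
#' trio <- Pedigree(fid = c(1, 1, 1), id = c("p1", "p2", "c1"),
#'                  father = c(0, 0, "p1"), mother = c(0, 0, "p2"),
#'                  sex = c(1, 2, 1))
#' nIndividuals(trio)
#' @export
Pedigree <- function(fid, id = NULL, father = NULL, mother = NULL, sex = NULL) {
  if (is.data.frame(fid)) {
    df <- fid
    tab <- .pedBuild(df$fid, df$id, df$father, df$mother, df$sex)
    extra <- setdiff(names(df), names(tab))
    for (col in extra) tab[[col]] <- df[[col]]
  } else {
    tab <- .pedBuild(fid, id, father, mother, sex)
  }
  msg <- .pedValidate(tab)
  if (length(msg)) stop("invalid pedigree: ", paste(msg, collapse = "; "))
  new("Pedigree", tab = tab)
}

#' Read a pedigree from a PED/FAM text file
#'
#' Whitespace-delimited rows: family, individual, father, mother, sex and
#' optionally further (phenotype) columns, which are kept as extra columns.
#' \code{"0"} denotes a missing parent.
#'
#' @param file path to the PED/FAM file.
#' @return A [Pedigree-class].
#' @export
readPedigree <- function(file) {
  df <- utils::read.table(file, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 5L) stop("PED/FAM file needs at least 5 columns")
  names(df)[1:5] <- c("fid", "id", "father", "mother", "sex")
  if (ncol(df) >= 6L) names(df)[6] <- "phenotype"
  Pedigree(df)
}

#' Read a MAP file (chromosome, SNP id, position in bp)
#'
#' Accepts 3-column (chr, snp, bp) or 4-column PLINK MAP (chr, snp, cM, bp).
#'
#' @param file path to the MAP file.
#' @return data.frame with columns \code{snp}, \code{chr}, \code{pos}.
#' @export
readMap <- function(file) {
  df <- utils::read.table(file, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) == 3L)
    data.frame(snp = as.character(df[[2]]), chr = as.character(df[[1]]),
               pos = as.numeric(df[[3]]))
  else
    data.frame(snp = as.character(df[[2]]), chr = as.character(df[[1]]),
               pos = as.numeric(df[[4]]))
}

#' @describeIn Pedigree The underlying pedigree table.
#' @param ped a [Pedigree-class].
#' @export
pedTable <- function(ped) ped@tab

#' @describeIn Pedigree Number of individuals.
#' @export
nIndividuals <- function(ped) nrow(ped@tab)

#' @describeIn Pedigree uids of founders (both parents missing).
#' @export
founders <- function(ped) ped@tab$uid[ped@tab$founder]

#' @describeIn Pedigree Family ids in order of first appearance.
#' @export
families <- function(ped) unique(ped@tab$fid)

setMethod("show", "Pedigree", function(object) {
  tab <- object@tab
  cat("Pedigree: ", nrow(tab), " individuals in ", length(unique(tab$fid)),
      " families (", sum(tab$founder), " founders)\n", sep = "")
  sz <- table(tab$fid)
  cat("  family sizes: ", paste(sz, collapse = ", "), "\n", sep = "")
})

#' Generation depth of each individual
#'
#' Depth of the longest ancestor chain: founders are 1, a child is
#' 1 + max(parental depths).
#'
#' @param ped a [Pedigree-class].
#' @return Named integer vector of depths (names = uid).
#' @export
pedigreeDepth <- function(ped) {
  tab <- ped@tab
  ord <- .topoOrder(tab)
  fi <- match(tab$father, tab$uid); mi <- match(tab$mother, tab$uid)
  depth <- integer(nrow(tab))
  for (i in ord)
    depth[i] <- if (is.na(fi[i])) 1L else 1L + max(depth[fi[i]], depth[mi[i]])
  names(depth) <- tab$uid
  depth
}

#' Kinship coefficient matrix
#'
#' Recursive kinship over the whole pedigree: for a nonfounder j with parents
#' f, m and any earlier (non-descendant) i,
#' \eqn{\phi_{ij} = (\phi_{if} + \phi_{im})/2};
#' \eqn{\phi_{jj} = 1/2 + \phi_{fm}/2}. Founders are unrelated and
#' non-inbred. Cross-family kinship is exactly 0. For an outbred d-th-degree
#' relative pair \eqn{\phi = 1/2^{d+1}}.
#'
#' @param ped a [Pedigree-class].
#' @return Symmetric matrix of kinship coefficients with uid dimnames, in
#'   pedigree row order.
#' @export
kinshipMatrix <- function(ped) {
  tab <- ped@tab
  n <- nrow(tab)
  ord <- .topoOrder(tab)
  fi <- match(tab$father, tab$uid); mi <- match(tab$mother, tab$uid)
  phi <- matrix(0, n, n, dimnames = list(tab$uid, tab$uid))
  done <- integer(0)
  for (j in ord) {
    if (is.na(fi[j])) {
      phi[j, j] <- 0.5
    } else {
      phi[j, j] <- 0.5 + 0.5 * phi[fi[j], mi[j]]
      if (length(done)) {
        v <- 0.5 * (phi[done, fi[j]] + phi[done, mi[j]])
        phi[done, j] <- v
        phi[j, done] <- v
      }
    }
    done <- c(done, j)
  }
  phi
}

# Variance of the IBD proportion pi for a standard outbred pair, from the
# pair's kinship and label. Full siblings are bilineal (var 1/8); all other
# standard outbred pairs are unilineal with var = phi * (1 - 4 phi).
.varPi <- function(phi, label) {
  ifelse(label == "full-sibling", 1 / 8,
         ifelse(label == "parent-offspring", 0, phi * (1 - 4 * phi)))
}

.degreeLabel <- function(degree) {
  lab <- c("first-degree", "second-degree", "third-degree", "fourth-degree",
           "fifth-degree")
  ifelse(degree <= 5, lab[pmax(degree, 1L)], paste0(degree, "th-degree"))
}

# Classify a set of pairs given the pedigree table and kinship matrix.
# Returns degree, label and kinship phi per pair.
.classifyPairs <- function(tab, phi, i, j) {
  sameFam <- tab$fid[i] == tab$fid[j]
  ph <- phi[cbind(i, j)]
  po <- (!is.na(tab$father[j]) & tab$father[j] == tab$uid[i]) |
        (!is.na(tab$mother[j]) & tab$mother[j] == tab$uid[i]) |
        (!is.na(tab$father[i]) & tab$father[i] == tab$uid[j]) |
        (!is.na(tab$mother[i]) & tab$mother[i] == tab$uid[j])
  fs <- !is.na(tab$father[i]) & !is.na(tab$father[j]) &
        tab$father[i] == tab$father[j] & tab$mother[i] == tab$mother[j]
  d <- ifelse(ph > 0, round(-log2(2 * ph)), NA_real_)
  complex <- ph > 0 & abs(2 * ph - 2^(-round(-log2(2 * ph)))) > 1e-9
  degree <- ifelse(!sameFam | ph == 0, NA_integer_, as.integer(d))
  label <- rep("unrelated", length(i))
  rel <- sameFam & ph > 0
  label[rel] <- .degreeLabel(degree[rel])
  label[rel & fs] <- "full-sibling"
  label[rel & po] <- "parent-offspring"
  label[rel & complex] <- "complex"
  degree[rel & po] <- 1L
  degree[rel & fs] <- 1L
  degree[rel & complex] <- NA_integer_
  data.frame(uid1 = tab$uid[i], uid2 = tab$uid[j], fid = tab$fid[i],
             degree = degree, label = label, phi = ph,
             stringsAsFactors = FALSE)
}

#' Classify the relationship of a pair
#'
#' Degree and label for a pair of individuals. For outbred pairs the degree d
#' satisfies \eqn{2\phi = 1/2^d}; parent-offspring and full siblings (both
#' degree 1) are distinguished through parent links. Pairs whose doubled
#' kinship is not a power of 1/2 (within 1e-9), e.g. double cousins, are
#' labelled \code{"complex"}. Cross-family pairs are \code{"unrelated"}.
#'
#' @param ped a [Pedigree-class].
#' @param i,j uids of the two individuals (i != j).
#' @param kin optional precomputed [kinshipMatrix()].
#' @return One-row data.frame: uid1, uid2, fid, degree, label, phi.
#' @export
classifyRelationship <- function(ped, i, j, kin = NULL) {
  tab <- ped@tab
  ii <- match(as.character(i), tab$uid); jj <- match(as.character(j), tab$uid)
  if (is.na(ii) || is.na(jj)) stop("unknown individual uid")
  if (ii == jj) stop("i and j must differ")
  if (is.null(kin)) kin <- kinshipMatrix(ped)
  .classifyPairs(tab, kin, ii, jj)
}

#' All related within-family pairs
#'
#' Enumerates every within-family pair with kinship > 0, classified as in
#' [classifyRelationship()]. Ordering is deterministic (row order of the
#' pedigree table).
#'
#' @param ped a [Pedigree-class].
#' @param kin optional precomputed [kinshipMatrix()].
#' @return data.frame: uid1, uid2, fid, degree, label, phi.
#' @export
relativePairs <- function(ped, kin = NULL) {
  tab <- ped@tab
  if (is.null(kin)) kin <- kinshipMatrix(ped)
  out <- vector("list", length(unique(tab$fid)))
  k <- 0L
  for (f in unique(tab$fid)) {
    idx <- which(tab$fid == f)
    if (length(idx) < 2L) next
    cmb <- utils::combn(idx, 2L)
    keep <- kin[cbind(cmb[1, ], cmb[2, ])] > 0
    if (!any(keep)) next
    k <- k + 1L
    out[[k]] <- .classifyPairs(tab, kin, cmb[1, keep], cmb[2, keep])
  }
  if (k == 0L)
    return(data.frame(uid1 = character(0), uid2 = character(0),
                      fid = character(0), degree = integer(0),
                      label = character(0), phi = numeric(0)))
  do.call(rbind, out[seq_len(k)])
}
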