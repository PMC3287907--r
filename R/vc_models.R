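# Polygenic and bivariate variance-component models; measured-genotype
# variance-component association; variance-explained accounting.

# Per-family eigendecomposition of 2*Phi restricted to the given uids.
# Returns list(d = eigenvalues, Ut = transposed eigenvectors, rows = uid
# indices) per family, plus the stacked transform applied to a matrix.
.kinTransforms <- function(kin, uid, fid) {
  out <- list()
  for (f in unique(fid)) {
    r <- which(fid == f)
    K <- 2 * kin[uid[r], uid[r], drop = FALSE]
    e <- eigen(K, symmetric = TRUE)
    out[[f]] <- list(rows = r, d = pmax(e$values, 0), Ut = t(e$vectors))
  }
  out
}

.applyTransform <- function(tr, M) {
  M <- as.matrix(M)
  out <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  for (f in names(tr))
    out[tr[[f]]$rows, ] <- tr[[f]]$Ut %*% M[tr[[f]]$rows, , drop = FALSE]
  out
}

.stackedEigenvalues <- function(tr, n) {
  d <- numeric(n)
  for (f in names(tr)) d[tr[[f]]$rows] <- tr[[f]]$d
  d
}

# Profiled negative log-likelihood of the polygenic model at heritability h.
# Returns list(nll, beta, sigma2, XtVX) using transformed data (yt, Xt, d).
.profileGaussian <- function(h, yt, Xt, d, reml = FALSE) {
  v <- h * d + (1 - h)
  if (any(v <= 0)) return(list(nll = Inf))
  wX <- Xt / sqrt(v); wy <- yt / sqrt(v)
  qr <- qr(wX)
  beta <- qr.coef(qr, wy)
  e <- wy - wX %*% beta
  rss <- sum(e^2)
  n <- length(yt); p <- ncol(Xt)
  if (reml) {
    s2 <- rss / (n - p)
    XtVX <- crossprod(wX)
    nll <- 0.5 * ((n - p) * log(2 * pi * s2) + sum(log(v)) +
                    determinant(XtVX, logarithm = TRUE)$modulus + (n - p))
  } else {
    s2 <- rss / n
    nll <- 0.5 * (n * log(2 * pi * s2) + sum(log(v)) + n)
  }
  list(nll = as.numeric(nll), beta = beta, sigma2 = s2, qr = qr, v = v)
}

#' Fit the additive polygenic model by maximum likelihood
#'
#' Per family, the trait is modelled as multivariate normal with mean
#' \eqn{X\beta} and covariance \eqn{2\Phi\sigma^2_g + I\sigma^2_e}.
#' The likelihood is profiled over \eqn{\beta} and the total variance and
#' maximized over \eqn{h^2 \in [0, 1)} (variance components are thereby
#' nonnegative by construction). Families are independent, so each
#' 128-member family contributes through its own eigendecomposition of
#' \eqn{2\Phi}; no whole-cohort dense solve is performed.
#'
#' When no individual has a relative in the sample (all eigenvalues equal),
#' \eqn{\sigma^2_g} is unidentifiable: the fit returns \eqn{h^2 = 0} with a
#' warning and \code{identifiable = FALSE}.
#'
#' @param traits data.frame with uid, fid, the trait and covariates.
#' @param trait trait column name.
#' @param covariates covariate column names (fixed effects).
#' @param kin [kinshipMatrix()] covering all individuals.
#' @param genotypes,adjustSNPs optional dosage matrix and SNP ids to include
#'   as additive fixed effects (measured-genotype model).
#' @param method "ML" (default) or "REML".
#' @param tol convergence tolerance on the heritability scale.
#' @return A [PolygenicFit-class].
#' @export
fitPolygenic <- function(traits, trait, covariates = character(0), kin,
                         genotypes = NULL, adjustSNPs = NULL,
                         method = c("ML", "REML"), tol = 1e-8) {
  method <- match.arg(method)
  keep <- !is.na(traits[[trait]])
  for (cv in covariates) keep <- keep & !is.na(traits[[cv]])
  tt <- traits[keep, , drop = FALSE]
  d0 <- .buildDesign(tt, covariates, genotypes, adjustSNPs)
  X <- d0$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("dropping collinear column(s): ", paste(bad, collapse = ", "))
    X <- X[, setdiff(colnames(X), bad), drop = FALSE]
  }
  tr <- .kinTransforms(kin, tt$uid, tt$fid)
  d <- .stackedEigenvalues(tr, nrow(tt))
  yt <- .applyTransform(tr, matrix(tt[[trait]], ncol = 1))
  Xt <- .applyTransform(tr, X)
  reml <- method == "REML"

  identifiable <- diff(range(d)) > 1e-8
  if (!identifiable) {
    warning("no relative pairs in the sample: sigma_g unidentifiable; ",
            "reporting h2 = 0")
    h <- 0
  } else {
    opt <- stats::optimize(function(h)
      .profileGaussian(h, yt, Xt, d, reml)$nll, c(0, 1 - 1e-7), tol = tol)
    h <- opt$minimum
    # also test the boundary h = 0 explicitly
    if (.profileGaussian(0, yt, Xt, d, reml)$nll <= opt$objective) h <- 0
  }
  fit <- .profileGaussian(h, yt, Xt, d, reml)
  XtVXinv <- solve(crossprod(Xt / sqrt(fit$v)))
  se <- sqrt(diag(XtVXinv) * fit$sigma2)
  beta <- stats::setNames(as.numeric(fit$beta), colnames(X))
  snpCols <- intersect(as.character(adjustSNPs), colnames(X))
  snpVar <- if (length(snpCols))
    as.numeric(stats::var(X[, snpCols, drop = FALSE] %*% beta[snpCols]))
  else 0
  new("PolygenicFit", beta = beta, betaSE = stats::setNames(se, colnames(X)),
      sigmaG = h * fit$sigma2, sigmaE = (1 - h) * fit$sigma2,
      h2 = h, logLik = -fit$nll, method = method, n = nrow(tt),
      trait = trait, uid = tt$uid, identifiable = identifiable,
      snpVariance = snpVar)
}

setMethod("show", "PolygenicFit", function(object) {
  cat("PolygenicFit (", object@method, ") for '", object@trait, "', n = ",
      object@n, "\n  h2 = ", signif(object@h2, 4), "  sigma2_g = ",
      signif(object@sigmaG, 4), "  sigma2_e = ", signif(object@sigmaE, 4),
      "  logLik = ", signif(object@logLik, 6), "\n", sep = "")
  print(signif(cbind(estimate = object@beta, SE = object@betaSE), 4))
})

#' Variance explained by measured variants
#'
#' Fitting the polygenic model with candidate variant dosages as fixed
#' effects removes their contribution from the additive genetic component;
#' the heritability drop \eqn{h^2_{without} - h^2_{with}} is then the share
#' of total phenotypic variance the variants explain. For the accounting to
#' be coherent both heritabilities must be measured against the same total
#' phenotypic variance, so for a fit that adjusts variant dosages the
#' heritability entering this difference is
#' \eqn{\sigma^2_g / (\sigma^2_g + \sigma^2_e + V_{SNP})}, with
#' \eqn{V_{SNP}} the sample variance of the fitted variant effects. Returned
#' in percent. The numeric method takes two bare heritability values and
#' returns their difference in percent.
#'
#' @param fitWithout,fitWith two [PolygenicFit-class] objects on the same
#'   individuals (\code{fitWith} including the variant dosages), or two bare
#'   heritability values.
#' @return Percent of total phenotypic variance explained.
#' @examples
#' varianceExplained(0.615, 0.491)  # 12.4
#' @export
setGeneric("varianceExplained",
           function(fitWithout, fitWith) standardGeneric("varianceExplained"))

#' @rdname varianceExplained
setMethod("varianceExplained", signature("PolygenicFit", "PolygenicFit"),
  function(fitWithout, fitWith) {
    if (fitWithout@n != fitWith@n ||
        !identical(fitWithout@uid, fitWith@uid))
      stop("fits are not on the same individuals")
    if (fitWithout@trait != fitWith@trait) stop("fits are for different traits")
    hWo <- fitWithout@sigmaG /
      (fitWithout@sigmaG + fitWithout@sigmaE + fitWithout@snpVariance)
    hW <- fitWith@sigmaG /
      (fitWith@sigmaG + fitWith@sigmaE + fitWith@snpVariance)
    (hWo - hW) * 100
  })

#' @rdname varianceExplained
setMethod("varianceExplained", signature("numeric", "numeric"),
  function(fitWithout, fitWith) (fitWithout - fitWith) * 100)

# --- bivariate polygenic model -------------------------------------------

.bivNegLL <- function(par, y1t, y2t, Xt, d, fixRG = NULL, fixRE = NULL) {
  sg1 <- exp(par[1]); sg2 <- exp(par[2])
  rG <- if (is.null(fixRG)) tanh(pmin(pmax(par[3], -3), 3)) else fixRG
  se1 <- exp(par[4]); se2 <- exp(par[5])
  rE <- if (is.null(fixRE)) tanh(pmin(pmax(par[6], -3), 3)) else fixRE
  g12 <- rG * sqrt(sg1 * sg2); e12 <- rE * sqrt(se1 * se2)
  # component-wise 2x2 covariance S_k = d_k G + E
  s11 <- d * sg1 + se1; s22 <- d * sg2 + se2; s12 <- d * g12 + e12
  det <- s11 * s22 - s12^2
  if (any(det <= 1e-12)) return(Inf)
  w11 <- s22 / det; w22 <- s11 / det; w12 <- -s12 / det
  # GLS for (beta1, beta2)
  A11 <- crossprod(Xt, Xt * w11); A22 <- crossprod(Xt, Xt * w22)
  A12 <- crossprod(Xt, Xt * w12)
  b1 <- crossprod(Xt, w11 * y1t + w12 * y2t)
  b2 <- crossprod(Xt, w12 * y1t + w22 * y2t)
  A <- rbind(cbind(A11, A12), cbind(A12, A22))
  beta <- tryCatch(solve(A, rbind(b1, b2)), error = function(e) NULL)
  if (is.null(beta)) return(Inf)
  p <- ncol(Xt)
  e1 <- y1t - Xt %*% beta[seq_len(p), , drop = FALSE]
  e2 <- y2t - Xt %*% beta[p + seq_len(p), , drop = FALSE]
  q <- sum(w11 * e1^2 + 2 * w12 * e1 * e2 + w22 * e2^2)
  0.5 * (sum(log(det)) + q) + length(d) * log(2 * pi)
}

#' Fit the bivariate polygenic model
#'
#' Two-trait polygenic model with genetic covariance \eqn{2\Phi \otimes G}
#' and environmental covariance \eqn{I \otimes E} (G, E 2x2), fit by maximum
#' likelihood on individuals observed for both traits. Reports per-trait
#' heritabilities and the genetic (rG) and environmental (rE) correlations.
#' With \code{fixRG = 0, fixRE = 0} the model decouples into the two
#' univariate fits.
#'
#' @param traits data.frame with uid, fid, both traits and covariates.
#' @param traitA,traitB trait column names.
#' @param covariates covariate column names (shared design for both traits).
#' @param kin [kinshipMatrix()].
#' @param fixRG,fixRE optionally fix the correlations (e.g. at 0).
#' @return A [BivariateFit-class].
#' @export
fitBivariate <- function(traits, traitA, traitB, covariates = character(0),
                         kin, fixRG = NULL, fixRE = NULL) {
  keep <- !is.na(traits[[traitA]]) & !is.na(traits[[traitB]])
  for (cv in covariates) keep <- keep & !is.na(traits[[cv]])
  tt <- traits[keep, , drop = FALSE]
  X <- .buildDesign(tt, covariates)$X
  tr <- .kinTransforms(kin, tt$uid, tt$fid)
  d <- .stackedEigenvalues(tr, nrow(tt))
  y1t <- .applyTransform(tr, matrix(tt[[traitA]], ncol = 1))
  y2t <- .applyTransform(tr, matrix(tt[[traitB]], ncol = 1))
  Xt <- .applyTransform(tr, X)

  # initialize from univariate fits
  f1 <- fitPolygenic(tt, traitA, covariates, kin)
  f2 <- fitPolygenic(tt, traitB, covariates, kin)
  par0 <- c(log(max(f1@sigmaG, 1e-4)), log(max(f2@sigmaG, 1e-4)), 0,
            log(max(f1@sigmaE, 1e-4)), log(max(f2@sigmaE, 1e-4)), 0)
  fn <- function(p) .bivNegLL(p, y1t, y2t, Xt, d, fixRG, fixRE)
  opt <- stats::optim(par0, fn, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  if (opt$convergence != 0)
    warning("bivariate optimizer did not fully converge (code ",
            opt$convergence, ")")
  p <- opt$par
  sg <- exp(p[c(1, 2)]); se <- exp(p[c(4, 5)])
  rG <- if (is.null(fixRG)) tanh(pmin(pmax(p[3], -3), 3)) else fixRG
  rE <- if (is.null(fixRE)) tanh(pmin(pmax(p[6], -3), 3)) else fixRE
  G <- matrix(c(sg[1], rG * sqrt(prod(sg)), rG * sqrt(prod(sg)), sg[2]), 2)
  E <- matrix(c(se[1], rE * sqrt(prod(se)), rE * sqrt(prod(se)), se[2]), 2)
  dimnames(G) <- dimnames(E) <- list(c(traitA, traitB), c(traitA, traitB))
  new("BivariateFit", h2 = stats::setNames(sg / (sg + se), c(traitA, traitB)),
      rG = rG, rE = rE, G = G, E = E, logLik = -opt$value,
      traits = c(traitA, traitB), n = nrow(tt))
}

setMethod("show", "BivariateFit", function(object) {
  cat("BivariateFit (", paste(object@traits, collapse = ", "), "), n = ",
      object@n, "\n  h2 = ", paste(signif(object@h2, 3), collapse = ", "),
      "; rG = ", signif(object@rG, 3), "; rE = ", signif(object@rE, 3),
      "; logLik = ", signif(object@logLik, 6), "\n", sep = "")
})

#' Measured-genotype variance-component association scan
#'
#' Score test of each SNP's additive dosage effect on a quantitative trait
#' under the null polygenic covariance (fit once, reused for every SNP).
#' For SNP dosage g, the score is \eqn{U = g'V^{-1}(y - X\hat\beta)} with
#' information \eqn{I = g'V^{-1}g - g'V^{-1}X (X'V^{-1}X)^{-1} X'V^{-1}g};
#' the test is \eqn{U^2 / I \sim \chi^2_1} and the one-step effect estimate
#' is \eqn{U / I}. Monomorphic SNPs are flagged untested.
#'
#' @param traits,trait,covariates,kin as in [fitPolygenic()].
#' @param genotypes dosage matrix (individuals x SNPs, rownames uid).
#' @param fit optional precomputed null [PolygenicFit-class].
#' @return data.frame per SNP: snp, beta (one-step estimate in trait units
#'   per allele), score, info, chisq, p, tested.
#' @export
vcAssocScan <- function(traits, trait, genotypes, covariates = character(0),
                        kin, fit = NULL) {
  if (is.null(fit)) fit <- fitPolygenic(traits, trait, covariates, kin)
  tt <- traits[match(fit@uid, traits$uid), , drop = FALSE]
  X <- .buildDesign(tt, covariates)$X
  X <- X[, intersect(colnames(X), names(fit@beta)), drop = FALSE]
  tr <- .kinTransforms(kin, tt$uid, tt$fid)
  d <- .stackedEigenvalues(tr, nrow(tt))
  v <- (fit@sigmaG * d + fit@sigmaE)
  yt <- .applyTransform(tr, matrix(tt[[trait]], ncol = 1))
  Xt <- .applyTransform(tr, X)
  e <- yt - Xt %*% fit@beta[colnames(X)]
  G <- genotypes[match(tt$uid, rownames(genotypes)), , drop = FALSE]
  mono <- apply(G, 2, function(g) stats::var(g, na.rm = TRUE)) <
    .Machine$double.eps
  G[is.na(G)] <- 0
  Gt <- .applyTransform(tr, G)
  XtVXinv <- solve(crossprod(Xt / sqrt(v)))
  U <- as.numeric(crossprod(Gt, e / v))
  GVX <- crossprod(Gt / v, Xt)               # snp x p
  info <- colSums(Gt^2 / v) - rowSums((GVX %*% XtVXinv) * GVX)
  info[info < 1e-12] <- NA
  chisq <- U^2 / info
  beta <- U / info
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  tested <- !mono & !is.na(chisq)
  chisq[!tested] <- NA; p[!tested] <- NA; beta[!tested] <- NA
  data.frame(snp = colnames(G), beta = beta, score = U, info = info,
             chisq = chisq, p = p, tested = tested, row.names = NULL)
}
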