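# Simulator of extended-family studies: pedigrees, genotypes with a
# rare-variant-heavy site frequency spectrum tied to true IBD, and
# dichotomous plus quantitative traits with major-gene, polygenic,
# covariate and substructure components.

#' Simulation configuration
#'
#' Defaults emulate a large extended-family study: 8 four-generation
#' pedigrees of 73-128 members (about 700 individuals, about 200 founders),
#' a site frequency spectrum with 85% of SNPs below MAF 0.05, a dichotomous
#' trait at 30% prevalence driven by Age (log-OR 0.077/year, i.e. a 10-year
#' increase doubles the risk) and Smoking (log-OR 0.947), and heritable
#' quantitative traits (h2 = 0.60, 0.45, 0.70 for Q1, Q2, Q4) with Age slope
#' 0.018/year, Smoking effect 0.44 and a genetic correlation of 0.25 between
#' Q1 and Q2. Founders come from two subpopulations (allele-frequency
#' divergence \code{fst}); the family-level mixture proportions differ so
#' ancestry varies between and within families. By default one
#' family-private rare variant (per-allele OR 6.8) is planted for the
#' dichotomous trait and two rare variants jointly explaining 12% of the
#' phenotypic variance are planted for Q1, each traced to recorded
#' founder(s).
#'
#' @param nFamilies,sizeRange,generations pedigree design.
#' @param nSNPs number of unlinked SNPs (desk-scale default 2000).
#' @param spectrum fractions of SNPs with MAF < 0.01, in [0.01, 0.05), and
#'   >= 0.05; must sum to 1.
#' @param fst founder subpopulation divergence for common SNPs.
#' @param meanOffspring,marryProb family-growth parameters.
#' @param founderAge,generationGap,ageSD,minAge age model: generation g mean
#'   age is founderAge - (g-1) * generationGap, SD ageSD, truncated at
#'   minAge.
#' @param smokingPrevalence Bernoulli smoking probability.
#' @param prevalence target affection prevalence.
#' @param ageLogOR,smokeLogOR dichotomous-trait effects (per year / binary).
#' @param ageSlopeQT,smokeEffectQT,ancestryEffectQT quantitative-trait fixed
#'   effects (trait units per year / binary / ancestry fraction).
#' @param h2 named per-trait heritabilities (polygenic, after fixed effects).
#' @param rG12 genetic correlation between Q1 and Q2 polygenic components.
#' @param plantDichotomous,plantQuantitative lists describing planted causal
#'   variants; see Details. Pass \code{list()} for a null study.
#' @details Each planted-variant entry is a list with fields \code{name},
#'   \code{chr}, \code{pos}, \code{copies} (founder allele copies),
#'   \code{family} ("largest" or a family id or NULL for random founders),
#'   and either \code{logOR} (dichotomous) or, for quantitative variants,
#'   \code{trait} plus \code{beta} (trait SD units per allele) or
#'   \code{varShare} (the variant group's joint share of total phenotypic
#'   variance is \code{sum(varShare)}; effects are sized from realized
#'   dosage variances).
#' @return A list of class \code{"simConfig"}.
#' @export
simConfig <- function(nFamilies = 8L, sizeRange = c(73L, 128L),
                      generations = 4L, nSNPs = 2000L,
                      spectrum = c(rare = 0.50, low = 0.35, common = 0.15),
                      fst = 0.05, meanOffspring = 3.5, marryProb = 0.9,
                      founderAge = 75, generationGap = 25, ageSD = 8,
                      minAge = 18, smokingPrevalence = 0.25,
                      prevalence = 0.30, ageLogOR = 0.077,
                      smokeLogOR = 0.947, ageSlopeQT = 0.018,
                      smokeEffectQT = 0.44, ancestryEffectQT = 0.5,
                      h2 = c(Q1 = 0.60, Q2 = 0.45, Q4 = 0.70), rG12 = 0.25,
                      plantDichotomous = list(
                        list(name = "RVD1", chr = "4", pos = 177845572,
                             copies = 1L, family = "largest",
                             logOR = log(6.8))),
                      plantQuantitative = list(
                        list(name = "RVQ1A", trait = "Q1", chr = "4",
                             pos = 177845572, copies = 1L,
                             family = "largest", varShare = 0.06),
                        list(name = "RVQ1B", trait = "Q1", chr = "6",
                             pos = 43854181, copies = 3L, family = NULL,
                             varShare = 0.06))) {
  stopifnot(abs(sum(spectrum) - 1) < 1e-8, all(spectrum >= 0),
            prevalence > 0, prevalence < 1, all(h2 >= 0), all(h2 < 1),
            abs(rG12) <= 1, sizeRange[1] <= sizeRange[2])
  structure(as.list(environment()), class = "simConfig")
}

# One family attempt; returns a data.frame or NULL when the size misses the
# target range.
.growFamily <- function(fid, cfg) {
  rows <- data.frame(fid = fid, id = c("I1", "I2"), father = "0",
                     mother = "0", sex = c(1L, 2L), generation = 1L,
                     stringsAsFactors = FALSE)
  couples <- data.frame(f = "I1", m = "I2", gen = 1L)
  counter <- 2L
  for (g in 2:cfg$generations) {
    newCouples <- NULL
    prev <- couples[couples$gen == g - 1L, , drop = FALSE]
    for (ci in seq_len(nrow(prev))) {
      nKids <- min(max(stats::rpois(1, cfg$meanOffspring), 1L), 8L)
      for (k in seq_len(nKids)) {
        counter <- counter + 1L
        kid <- paste0("I", counter)
        sexK <- sample(1:2, 1L)
        rows <- rbind(rows, data.frame(fid = fid, id = kid,
                                       father = prev$f[ci],
                                       mother = prev$m[ci], sex = sexK,
                                       generation = g))
        if (g < cfg$generations && stats::runif(1) < cfg$marryProb) {
          counter <- counter + 1L
          sp <- paste0("I", counter)
          rows <- rbind(rows, data.frame(fid = fid, id = sp, father = "0",
                                         mother = "0", sex = 3L - sexK,
                                         generation = g))
          newCouples <- rbind(newCouples, data.frame(
            f = if (sexK == 1L) kid else sp,
            m = if (sexK == 1L) sp else kid, gen = g))
        }
      }
    }
    if (is.null(newCouples) && g < cfg$generations) return(NULL)
    couples <- rbind(couples, newCouples)
  }
  if (nrow(rows) < cfg$sizeRange[1] || nrow(rows) > cfg$sizeRange[2])
    return(NULL)
  rows
}

#' Simulate extended pedigrees
#'
#' Grows each family from a founding couple over the configured number of
#' generations: couples have Poisson offspring counts, children marry in a
#' new founder with probability \code{marryProb} (last generation excepted),
#' and the draw is repeated until the family size lands in
#' \code{sizeRange}. Deterministic under \code{seed}. The generation index
#' (marry-in founders take their spouse's generation) is kept as an extra
#' pedigree column for the age model.
#'
#' @param config a [simConfig()].
#' @param seed mandatory integer seed.
#' @return A [Pedigree-class] with extra column \code{generation}.
#' @export
simulatePedigrees <- function(config, seed) {
  withr::local_seed(as.integer(seed))
  fams <- vector("list", config$nFamilies)
  for (i in seq_len(config$nFamilies)) {
    fid <- paste0("F", i)
    rows <- NULL
    for (attempt in seq_len(2000L)) {
      rows <- .growFamily(fid, config)
      if (!is.null(rows)) break
    }
    if (is.null(rows))
      stop("infeasible size range for the configured generations/offspring")
    fams[[i]] <- rows
  }
  df <- do.call(rbind, fams)
  df$id <- paste0(df$fid, "-", df$id)
  df$father <- ifelse(df$father == "0", "0", paste0(df$fid, "-", df$father))
  df$mother <- ifelse(df$mother == "0", "0", paste0(df$fid, "-", df$mother))
  Pedigree(df)
}

# Resolve a planted variant's founder carrier slots: returns allele-slot
# indices (into 1..2*nFounders, founder pedigree order).
.plantSlots <- function(tab, plant, famSizes) {
  fam <- plant$family
  if (identical(fam, "largest")) fam <- names(which.max(famSizes))
  if (is.null(fam)) {
    pool <- which(tab$founder)
  } else {
    pool <- which(tab$founder & tab$fid == fam)
    # prefer earliest-generation founders: ancestors of most of the family
    if (!is.null(tab$generation)) {
      g1 <- pool[tab$generation[pool] == min(tab$generation[pool])]
      if (length(g1)) pool <- g1
    }
  }
  founderRank <- cumsum(tab$founder)
  slots <- as.vector(rbind(2L * founderRank[pool] - 1L,
                           2L * founderRank[pool]))
  nCopies <- min(max(plant$copies, 1L), length(slots))
  slots[sample.int(length(slots), nCopies)]
}

#' Simulate genotypes tied to true IBD
#'
#' Draws founder alleles per subpopulation under the configured site
#' frequency spectrum (common SNPs diverge between the two founder
#' subpopulations with the configured Fst, Balding-Nichols model) and
#' transmits them by gene dropping, so the returned dosages are exactly
#' consistent with the returned true IBD labels and contain no Mendelian
#' errors by construction. Planted variants are realized as single founder
#' allele copies (family-private when a family is specified), so every
#' carrier traces to the recorded founder(s).
#'
#' @param ped a [Pedigree-class] from [simulatePedigrees()].
#' @param config a [simConfig()].
#' @param seed mandatory integer seed.
#' @return list: \code{genotypes} (dosage matrix), \code{ibd}
#'   ([IBDSharing-class]), \code{map}, \code{truth} (planted-variant
#'   ledger), \code{subpop} (founder subpopulation indicator),
#'   \code{ancestry} (per-individual ancestry fraction).
#' @export
simulateGenotypes <- function(ped, config, seed) {
  withr::local_seed(as.integer(seed))
  tab <- ped@tab
  n <- nrow(tab)
  nFnd <- sum(tab$founder)
  famSizes <- table(tab$fid)

  plants <- c(config$plantDichotomous, config$plantQuantitative)
  nBg <- config$nSNPs
  M <- nBg + length(plants)
  snpNames <- c(sprintf("S%05d", seq_len(nBg)),
                vapply(plants, `[[`, "", "name"))

  # site frequency spectrum for background SNPs
  cls <- sample(c("rare", "low", "common"), nBg, replace = TRUE,
                prob = config$spectrum)
  p <- numeric(nBg)
  p[cls == "rare"] <- stats::runif(sum(cls == "rare"), 0.001, 0.01)
  p[cls == "low"] <- stats::runif(sum(cls == "low"), 0.01, 0.05)
  p[cls == "common"] <- stats::runif(sum(cls == "common"), 0.05, 0.5)

  # founder subpopulations: family-specific mixture proportions
  famProb <- stats::setNames(stats::runif(length(famSizes), 0.2, 0.8),
                             names(famSizes))
  subpop <- rep(NA_integer_, n)
  fIdx <- which(tab$founder)
  subpop[fIdx] <- stats::rbinom(nFnd, 1, famProb[tab$fid[fIdx]])

  # per-subpop frequencies: Balding-Nichols divergence for common SNPs
  p1 <- p; p2 <- p
  if (config$fst > 0) {
    com <- which(cls == "common")
    a <- p[com] * (1 - config$fst) / config$fst
    b <- (1 - p[com]) * (1 - config$fst) / config$fst
    p1[com] <- stats::rbeta(length(com), a, b)
    p2[com] <- stats::rbeta(length(com), a, b)
  }

  # founder allele values: slot s belongs to founder ceiling(s/2). The
  # configured frequencies are realized exactly in each subpopulation's
  # founder haplotype pool (allele counts fixed, placement random), so the
  # realized founder-MAF spectrum matches the configured spectrum up to
  # rounding; rare variants get at least one copy.
  val <- matrix(0L, 2L * nFnd, M)
  fndSub <- subpop[fIdx]
  for (s in c(1L, 0L)) {
    slotRows <- as.vector(rbind(2L * which(fndSub == s) - 1L,
                                2L * which(fndSub == s)))
    ps <- if (s == 1L) p1 else p2
    nSlot <- length(slotRows)
    k <- pmax(1L, round(nSlot * ps))
    for (j in seq_len(nBg))
      val[slotRows[sample.int(nSlot, k[j])], j] <- 1L
  }

  # planted variants: exact founder copies
  truth <- NULL
  for (k in seq_along(plants)) {
    pl <- plants[[k]]
    slots <- .plantSlots(tab, pl, famSizes)
    val[slots, nBg + k] <- 1L
    fnd <- tab$uid[tab$founder][ceiling(slots / 2)]
    truth <- rbind(truth, data.frame(
      snp = pl$name,
      trait = if (!is.null(pl$trait)) pl$trait else "affected",
      effectType = if (!is.null(pl$logOR)) "logOR" else
        if (!is.null(pl$beta)) "beta" else "varShare",
      effect = if (!is.null(pl$logOR)) pl$logOR else
        if (!is.null(pl$beta)) pl$beta else NA_real_,
      varShare = if (!is.null(pl$varShare)) pl$varShare else NA_real_,
      family = paste(unique(tab$fid[match(fnd, tab$uid)]), collapse = ","),
      founderUid = paste(fnd, collapse = ","),
      carriers = NA_integer_, stringsAsFactors = FALSE))
  }

  # transmit by gene dropping; dosage = sum of the two founder-allele values
  # (linear index val[label[i, m] + 2F * (m - 1)])
  idx <- .dropIndex(tab)
  dr <- .geneDropRaw(tab, idx, M)
  colOff <- rep(2L * nFnd * (seq_len(M) - 1L), each = n)
  geno <- matrix(val[as.vector(dr$pat) + colOff] +
                   val[as.vector(dr$mat) + colOff],
                 n, M, dimnames = list(tab$uid, snpNames))
  storage.mode(geno) <- "integer"

  if (!is.null(truth))
    truth$carriers <- vapply(truth$snp, function(s) sum(geno[, s] >= 1),
                             integer(1))

  # map: background SNPs spread over 22 autosomes; planted at their spots
  chrBg <- sort(rep_len(1:22, nBg))
  posBg <- unlist(lapply(split(seq_len(nBg), chrBg), function(i)
    sort(sample.int(2.4e8, length(i)))), use.names = FALSE)
  map <- data.frame(
    snp = snpNames,
    chr = c(as.character(chrBg),
            vapply(plants, function(z) as.character(z$chr), "")),
    pos = c(posBg, vapply(plants, function(z) as.numeric(z$pos), numeric(1))))

  ibd <- new("IBDSharing", pat = dr$pat, mat = dr$mat, uid = tab$uid,
             fid = tab$fid, loci = snpNames)
  # ancestry fraction: founders = subpop indicator; nonfounders midparent
  anc <- subpop
  fI <- match(tab$father, tab$uid); mI <- match(tab$mother, tab$uid)
  for (i in .topoOrder(tab))
    if (!tab$founder[i]) anc[i] <- (anc[fI[i]] + anc[mI[i]]) / 2
  list(genotypes = geno, ibd = ibd, map = map,
       truth = if (is.null(truth)) data.frame() else truth,
       subpop = subpop, ancestry = stats::setNames(anc, tab$uid))
}

# Age/smoking covariates from the generation structure.
.simCovariates <- function(ped, config) {
  tab <- ped@tab
  g <- tab$generation
  age <- stats::rnorm(nrow(tab),
                      config$founderAge - (g - 1) * config$generationGap,
                      config$ageSD)
  age <- pmax(age, config$minAge)
  smoke <- stats::rbinom(nrow(tab), 1, config$smokingPrevalence)
  data.frame(uid = tab$uid, fid = tab$fid, generation = g,
             age = round(age, 1), smoke = smoke, stringsAsFactors = FALSE)
}

#' Simulate the dichotomous trait
#'
#' Logistic liability: \eqn{logit P(affected) = \alpha + 0.077 Age +
#' 0.947 Smoke + \sum log(OR_v) dosage_v} with the baseline \eqn{\alpha}
#' calibrated by bisection so the realized cohort prevalence matches the
#' target (within 1/n). Ages are drawn per generation (older generations
#' older); smoking is independent Bernoulli.
#'
#' @param ped a [Pedigree-class] with a \code{generation} column.
#' @param genotypes dosage matrix.
#' @param config a [simConfig()].
#' @param seed mandatory integer seed.
#' @param covars optional precomputed covariate table (uid, age, smoke).
#' @return data.frame: uid, fid, generation, age, smoke, affected.
#' @export
simulateDichotomous <- function(ped, genotypes, config, seed,
                                covars = NULL) {
  withr::local_seed(as.integer(seed))
  if (is.null(covars)) covars <- .simCovariates(ped, config)
  eta <- config$ageLogOR * covars$age + config$smokeLogOR * covars$smoke
  for (pl in config$plantDichotomous)
    eta <- eta + pl$logOR * genotypes[match(covars$uid, rownames(genotypes)),
                                      pl$name]
  u <- stats::runif(nrow(covars))
  f <- function(a) mean(stats::plogis(a + eta) > u)
  lo <- -60; hi <- 30
  if (f(hi) < config$prevalence || f(lo) > config$prevalence)
    stop("unattainable target prevalence")
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < config$prevalence) lo <- mid else hi <- mid
  }
  alpha <- hi
  covars$affected <- as.integer(stats::plogis(alpha + eta) > u)
  attr(covars, "alpha") <- alpha
  covars
}

#' Simulate quantitative traits
#'
#' Trait = ageSlope * Age + smokeEffect * Smoke + ancestryEffect *
#' (ancestry - mean) + planted variant effects + polygenic component +
#' residual noise. The polygenic component is multivariate normal per
#' family with covariance \eqn{2\Phi\sigma^2_g}; \eqn{\sigma^2_g =
#' h^2}, \eqn{\sigma^2_e = 1 - h^2} (unit base phenotypic variance), and
#' the Q1/Q2 polygenic components share correlation rG. Variant effects
#' given as \code{varShare} are sized from realized dosage variances so the
#' group jointly explains its target share of total phenotypic variance.
#'
#' @param ped a [Pedigree-class].
#' @param genotypes dosage matrix.
#' @param kin [kinshipMatrix()].
#' @param config a [simConfig()].
#' @param seed mandatory integer seed.
#' @param covars covariate table with uid, age, smoke (from
#'   [simulateDichotomous()] or internal draw).
#' @param ancestry named per-individual ancestry fractions.
#' @return data.frame: uid plus Q1, Q2, Q4 columns; attribute
#'   \code{"effects"} records the realized per-variant betas.
#' @export
simulateQuantitative <- function(ped, genotypes, kin, config, seed, covars,
                                 ancestry) {
  withr::local_seed(as.integer(seed))
  tab <- ped@tab
  n <- nrow(tab)
  ord <- match(tab$uid, covars$uid)
  fixedBase <- config$ageSlopeQT * covars$age[ord] +
    config$smokeEffectQT * covars$smoke[ord] +
    config$ancestryEffectQT * (ancestry[tab$uid] - mean(ancestry))

  # family-block choleskys of 2*Phi
  chol2K <- lapply(unique(tab$fid), function(f) {
    r <- which(tab$fid == f)
    list(rows = r, L = t(chol(2 * kin[r, r] + diag(1e-10, length(r)))))
  })
  drawPoly <- function(z) {
    g <- numeric(n)
    for (b in chol2K) g[b$rows] <- b$L %*% z[b$rows]
    g
  }
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n); z4 <- stats::rnorm(n)
  a1 <- drawPoly(z1)
  a2 <- drawPoly(config$rG12 * z1 + sqrt(1 - config$rG12^2) * z2)
  a4 <- drawPoly(z4)
  h2 <- config$h2
  poly <- cbind(Q1 = sqrt(h2[["Q1"]]) * a1, Q2 = sqrt(h2[["Q2"]]) * a2,
                Q4 = sqrt(h2[["Q4"]]) * a4)
  env <- cbind(Q1 = stats::rnorm(n, 0, sqrt(1 - h2[["Q1"]])),
               Q2 = stats::rnorm(n, 0, sqrt(1 - h2[["Q2"]])),
               Q4 = stats::rnorm(n, 0, sqrt(1 - h2[["Q4"]])))

  # variant effects; varShare entries sized against base variance 1
  effects <- NULL
  variant <- matrix(0, n, 3, dimnames = list(NULL, c("Q1", "Q2", "Q4")))
  byTrait <- split(config$plantQuantitative,
                   vapply(config$plantQuantitative, `[[`, "", "trait"))
  for (tr in names(byTrait)) {
    pls <- byTrait[[tr]]
    shares <- vapply(pls, function(z)
      if (!is.null(z$varShare)) z$varShare else NA_real_, numeric(1))
    fTot <- sum(shares, na.rm = TRUE)
    vTot <- if (fTot > 0 && fTot < 1) fTot / (1 - fTot) else 0
    for (k in seq_along(pls)) {
      pl <- pls[[k]]
      g <- genotypes[tab$uid, pl$name]
      vg <- stats::var(g)
      beta <- if (!is.null(pl$beta)) pl$beta
      else if (vg > 0 && !is.na(shares[k]))
        sqrt(vTot * shares[k] / fTot / vg) else 0
      variant[, tr] <- variant[, tr] + beta * g
      effects <- rbind(effects, data.frame(snp = pl$name, trait = tr,
                                           beta = beta,
                                           dosageVar = vg))
    }
  }
  out <- data.frame(uid = tab$uid,
                    Q1 = fixedBase + variant[, "Q1"] + poly[, "Q1"] + env[, "Q1"],
                    Q2 = fixedBase + variant[, "Q2"] + poly[, "Q2"] + env[, "Q2"],
                    Q4 = fixedBase + variant[, "Q4"] + poly[, "Q4"] + env[, "Q4"],
                    stringsAsFactors = FALSE)
  attr(out, "effects") <- effects
  out
}

#' Simulate a complete family study
#'
#' Orchestrates [simulatePedigrees()], [simulateGenotypes()],
#' [simulateDichotomous()] and [simulateQuantitative()] under seeds derived
#' from \code{seed}. A pedigree (with its kinship matrix) can be supplied to
#' hold the family structure fixed across phenotype/genotype replicates, the
#' usual design for replicated family studies.
#'
#' @param config a [simConfig()].
#' @param seed mandatory integer seed; sub-seeds are derived from it.
#' @param ped optional fixed [Pedigree-class].
#' @param kin optional precomputed [kinshipMatrix()] for \code{ped}.
#' @return A [SimulatedStudy-class].
#' @export
simulateStudy <- function(config = simConfig(), seed, ped = NULL,
                          kin = NULL) {
  seed <- as.integer(seed)
  if (is.null(ped)) ped <- simulatePedigrees(config, seed = seed)
  if (is.null(kin)) kin <- kinshipMatrix(ped)
  gen <- simulateGenotypes(ped, config, seed = seed + 1L)
  dich <- simulateDichotomous(ped, gen$genotypes, config, seed = seed + 2L)
  qt <- simulateQuantitative(ped, gen$genotypes, kin, config,
                             seed = seed + 3L, covars = dich,
                             ancestry = gen$ancestry)
  traits <- cbind(dich, ancestry = as.numeric(gen$ancestry[dich$uid]),
                  qt[match(dich$uid, qt$uid), c("Q1", "Q2", "Q4")])
  truth <- gen$truth
  if (nrow(truth)) {
    eff <- attr(qt, "effects")
    if (!is.null(eff)) {
      m <- match(truth$snp, eff$snp)
      truth$effect <- ifelse(truth$effectType == "varShare" & !is.na(m),
                             eff$beta[m], truth$effect)
    }
  }
  new("SimulatedStudy", ped = ped, genotypes = gen$genotypes, map = gen$map,
      ibd = gen$ibd, traits = traits, truth = truth,
      config = unclass(config), seed = seed)
}

setMethod("show", "SimulatedStudy", function(object) {
  cat("SimulatedStudy: ", nrow(object@traits), " individuals, ",
      ncol(object@genotypes), " SNPs, seed ", object@seed, "\n", sep = "")
  cat("  prevalence ", round(mean(object@traits$affected), 3),
      "; planted variants: ",
      if (nrow(object@truth)) paste(object@truth$snp, collapse = ", ")
      else "none", "\n", sep = "")
})

#' Check genotypes for Mendelian consistency
#'
#' Exhaustive scan: every nonfounder's dosage must be attainable from its
#' parents' dosages.
#'
#' @param genotypes dosage matrix (individuals x SNPs).
#' @param ped a [Pedigree-class].
#' @return Number of (individual, SNP) Mendelian violations (0 when clean).
#' @export
checkMendelian <- function(genotypes, ped) {
  tab <- ped@tab
  bad <- 0L
  for (i in which(!tab$founder)) {
    gC <- genotypes[tab$uid[i], ]
    gF <- genotypes[tab$father[i], ]
    gM <- genotypes[tab$mother[i], ]
    lo <- (gF == 2) + (gM == 2)
    hi <- (gF > 0) + (gM > 0)
    bad <- bad + sum(gC < lo | gC > hi, na.rm = TRUE)
  }
  bad
}

#' Write a simulated study to PED/MAP, phenotype and truth files
#'
#' PED alleles are coded A (major) / B (minor) with arbitrary phase; the MAP
#' is 4-column (chr, snp, 0, bp). The phenotype TSV carries the full trait
#' table and the truth TSV the planted-variant ledger.
#'
#' @param study a [SimulatedStudy-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- study@ped@tab
  g <- study@genotypes[tab$uid, , drop = FALSE]
  a1 <- ifelse(g >= 1, "B", "A")
  a2 <- ifelse(g == 2, "B", "A")
  alle <- matrix("", nrow(g), 2 * ncol(g))
  alle[, seq(1, 2 * ncol(g), 2)] <- a1
  alle[, seq(2, 2 * ncol(g), 2)] <- a2
  pedOut <- cbind(tab$fid, tab$uid,
                  ifelse(is.na(tab$father), "0", tab$father),
                  ifelse(is.na(tab$mother), "0", tab$mother),
                  tab$sex,
                  study@traits$affected[match(tab$uid, study@traits$uid)] + 1L,
                  alle)
  pedFile <- file.path(dir, "study.ped")
  utils::write.table(pedOut, pedFile, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  mapFile <- file.path(dir, "study.map")
  utils::write.table(data.frame(study@map$chr, study@map$snp, 0,
                                study@map$pos),
                     mapFile, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  pheFile <- file.path(dir, "phenotypes.tsv")
  utils::write.table(study@traits, pheFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truthFile <- file.path(dir, "truth.tsv")
  utils::write.table(study@truth, truthFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pedFile, mapFile, pheFile, truthFile))
}
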