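#' @import methods
NULL

#' Pedigree of one or more extended families
#'
#' Stores a validated pedigree table. Rows keep the input order. The table
#' carries at least the columns \code{fid}, \code{id}, \code{father},
#' \code{mother} (both \code{NA} for founders), \code{sex} (1 = male,
#' 2 = female, 0 = unknown), \code{founder} and a globally unique key
#' \code{uid}. Extra columns (e.g. a simulator's generation index) are
#' preserved but ignored by the validity check.
#'
#' Invariants enforced: parent references resolve within the same family,
#' either both parents are present or both missing, individual ids are unique
#' within a family, fathers are male and mothers female when sex is known,
#' and the parent graph is acyclic.
#'
#' @slot tab data.frame as described above.
#' @seealso [Pedigree()], [readPedigree()], [kinshipMatrix()]
#' @export
setClass("Pedigree", representation(tab = "data.frame"))

#' Per-locus founder-allele labels from gene dropping
#'
#' Each individual carries two founder-allele labels per locus (paternally and
#' maternally inherited lineage). Labels are integers that are unique per
#' founder allele across the whole study, so identity of labels is identity
#' by descent. Derive pairwise IBD proportions with [ibdProportion()].
#'
#' @slot pat,mat integer matrices (individuals x loci) of founder-allele
#'   labels on the paternally / maternally transmitted chromosome.
#' @slot uid,fid individual keys and family ids, parallel to the rows.
#' @slot loci character vector of locus names.
#' @export
setClass("IBDSharing", representation(
  pat = "matrix", mat = "matrix", uid = "character",
  fid = "character", loci = "character"))

#' Null covariance of IBD sharing over relative pairs
#'
#' Square covariance matrix of per-locus IBD proportions
#' \eqn{Cov(\pi_{ij}, \pi_{kl})} over an ordered list of within-family pairs,
#' under the null of no linkage. A function of pedigree structure only.
#'
#' @slot sigma covariance matrix (pairs x pairs).
#' @slot expectedPi expected sharing (2 x kinship) per pair.
#' @slot pairs data.frame with columns \code{fid}, \code{uid1}, \code{uid2}.
#' @slot method "enumerate" (exact) or "montecarlo".
#' @slot nDrops number of gene drops used (0 for enumerate).
#' @slot mcse matrix of Monte-Carlo standard errors (0 x 0 for enumerate).
#' @export
setClass("PairCovariance", representation(
  sigma = "matrix", expectedPi = "numeric", pairs = "data.frame",
  method = "character", nDrops = "integer", mcse = "matrix"))

#' Covariate-adjusted trait residuals
#'
#' Least-squares residuals of a quantitative trait on covariates (and,
#' optionally, SNP dosages for conditional analyses), as consumed by
#' [qtScoreScan()] and the carrier screens.
#'
#' @slot residuals named numeric vector (names are individual uids).
#' @slot coefficients fitted fixed-effect coefficients.
#' @slot dropped columns dropped for collinearity or monomorphism.
#' @slot trait,covariates,snps names of the modelled columns.
#' @export
setClass("ResidualTrait", representation(
  residuals = "numeric", coefficients = "numeric", dropped = "character",
  trait = "character", covariates = "character", snps = "character"))

#' Maximum-likelihood polygenic model fit
#'
#' Fit of the additive polygenic model: per family, the trait is multivariate
#' normal with mean \eqn{X\beta} and covariance
#' \eqn{\Omega = 2\Phi\sigma^2_g + I\sigma^2_e}, where \eqn{\Phi} is the
#' kinship matrix. Heritability is
#' \eqn{h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)}.
#'
#' @slot beta fixed-effect estimates (named).
#' @slot betaSE standard errors of \code{beta}.
#' @slot sigmaG,sigmaE additive genetic and residual variance components.
#' @slot h2 heritability estimate in [0, 1].
#' @slot logLik maximized log-likelihood.
#' @slot method "ML" or "REML".
#' @slot n number of individuals used.
#' @slot trait trait name.
#' @slot uid individuals used (for sample-identity checks downstream).
#' @slot identifiable FALSE when no relative pairs inform sigmaG.
#' @slot snpVariance sample variance of the fitted adjusted-SNP fixed
#'   effects (0 when no SNPs are adjusted); used by [varianceExplained()] so
#'   heritabilities with and without measured variants share the same total
#'   phenotypic variance denominator.
#' @export
setClass("PolygenicFit", representation(
  beta = "numeric", betaSE = "numeric", sigmaG = "numeric",
  sigmaE = "numeric", h2 = "numeric", logLik = "numeric",
  method = "character", n = "integer", trait = "character",
  uid = "character", identifiable = "logical", snpVariance = "numeric"))

#' Bivariate polygenic model fit
#'
#' Two-trait polygenic model with genetic covariance \eqn{2\Phi \otimes G}
#' and environmental covariance \eqn{I \otimes E}; reports per-trait
#' heritabilities, the genetic correlation rG and environmental
#' correlation rE.
#'
#' @slot h2 length-2 heritabilities.
#' @slot rG,rE genetic and environmental correlations in [-1, 1].
#' @slot G,E 2x2 genetic and environmental covariance matrices.
#' @slot logLik maximized log-likelihood.
#' @slot traits the two trait names.
#' @slot n number of individuals with both traits.
#' @export
setClass("BivariateFit", representation(
  h2 = "numeric", rG = "numeric", rE = "numeric", G = "matrix",
  E = "matrix", logLik = "numeric", traits = "character", n = "integer"))

#' A simulated extended-family study
#'
#' Bundle produced by [simulateStudy()]: pedigree, genotype dosages, marker
#' map, true per-locus IBD labels, trait/covariate table and the truth ledger
#' describing every planted causal effect.
#'
#' @slot ped [Pedigree-class].
#' @slot genotypes integer matrix of 0/1/2 minor-allele dosages
#'   (individuals x SNPs, rownames = uid).
#' @slot map data.frame with columns \code{snp}, \code{chr}, \code{pos}.
#' @slot ibd [IBDSharing-class] with one locus per SNP.
#' @slot traits data.frame: uid, fid, generation, age, smoke, ancestry,
#'   affected, Q1, Q2, Q4.
#' @slot truth data.frame describing planted causal variants (snp, trait,
#'   effect, family, founder uid, carrier count, target variance share).
#' @slot config the [simConfig()] list used.
#' @slot seed integer seed the study was generated from.
#' @export
setClass("SimulatedStudy", representation(
  ped = "Pedigree", genotypes = "matrix", map = "data.frame",
  ibd = "IBDSharing", traits = "data.frame", truth = "data.frame",
  config = "list", seed = "integer"))
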