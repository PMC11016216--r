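#' @import methods
NULL

## Column order used for every summary-statistics table in the package.
.SUMSTAT_COLS <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se",
                   "pval", "n")

#' Validate a GWAS summary-statistics table
#'
#' Checks that a data.frame carries the canonical per-variant columns
#' (\code{snp, chr, pos, ea, oa, eaf, beta, se, pval, n}) with finite effects,
#' positive standard errors, p-values in (0, 1] and allele frequencies in
#' (0, 1).
#'
#' @param x data.frame of per-variant associations.
#' @return \code{x} invisibly; stops with an informative error otherwise.
#' @export
validateSumstats <- function(x) {
  stopifnot(is.data.frame(x))
  miss <- setdiff(.SUMSTAT_COLS, names(x))
  if (length(miss))
    stop("summary-statistics table lacks columns: ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(x$snp))
    stop("duplicate snp ids in summary-statistics table")
  if (nrow(x)) {
    if (!all(is.finite(x$beta)) || !all(is.finite(x$se)))
      stop("non-finite beta/se in summary-statistics table")
    if (any(x$se <= 0)) stop("se must be > 0")
    if (any(x$pval <= 0 | x$pval > 1)) stop("pval must lie in (0, 1]")
    if (any(x$eaf <= 0 | x$eaf >= 1)) stop("eaf must lie in (0, 1)")
    if (any(!nzchar(x$ea)) || any(!nzchar(x$oa)) || any(x$ea == x$oa))
      stop("alleles must be non-empty and distinct")
  }
  invisible(x)
}

#' LD reference panel for one chromosome
#'
#' Holds pairwise squared correlations (r-squared) between variants of one
#' synthetic or real chromosome, with 1-based base-pair positions. The square
#' root of \code{r2} is used wherever a signed genotype correlation is needed;
#' the exponential-decay generator produces non-negative correlations only.
#'
#' @slot variantIds character, ordered variant identifiers.
#' @slot r2 numeric matrix of squared correlations, symmetric with unit
#'   diagonal, entries in [0, 1].
#' @slot positions integer-valued base-pair coordinates (1-based).
#' @slot chromosome single chromosome label.
#' @export
setClass("LDReference",
  representation(variantIds = "character", r2 = "matrix",
                 positions = "numeric", chromosome = "character"),
  validity = function(object) {
    n <- length(object@variantIds)
    msg <- character()
    if (!identical(dim(object@r2), c(n, n)))
      msg <- c(msg, "r2 dimensions do not match variantIds")
    if (length(object@positions) != n)
      msg <- c(msg, "positions length does not match variantIds")
    if (n) {
      if (max(abs(object@r2 - t(object@r2))) > 1e-12)
        msg <- c(msg, "r2 must be symmetric")
      if (any(abs(diag(object@r2) - 1) > 0))
        msg <- c(msg, "r2 diagonal must be exactly 1")
      if (any(object@r2 < 0 | object@r2 > 1))
        msg <- c(msg, "r2 entries must lie in [0, 1]")
      if (anyDuplicated(object@variantIds))
        msg <- c(msg, "duplicate variant ids")
    }
    if (length(msg)) msg else TRUE
  })

#' Simulated GWAS with attached generating truth
#'
#' A summary-statistics table for one trait together with the generating
#' parameters needed downstream (true per-variant marginal effects, sample
#' size, trait identity). The table uses the canonical column layout of
#' \code{\link{validateSumstats}}.
#'
#' @slot traitId trait label.
#' @slot table data.frame of per-variant associations.
#' @slot truth list carrying at least \code{trueBeta} (true marginal effects,
#'   in table order) and the generating \code{TruthConfig} fields used.
#' @export
setClass("SimulatedStudy",
  representation(traitId = "character", table = "data.frame", truth = "list"),
  validity = function(object) {
    out <- tryCatch({ validateSumstats(object@table); TRUE },
                    error = function(e) conditionMessage(e))
    if (!isTRUE(out)) return(out)
    tb <- object@truth$trueBeta
    if (!is.null(tb) && length(tb) != nrow(object@table))
      return("truth$trueBeta length does not match table")
    TRUE
  })

#' Selected, strength-validated instruments for one exposure
#'
#' @slot exposureId exposure (protein) label.
#' @slot instruments data.frame of retained variant associations.
#' @slot r2Explained per-instrument variance explained in the exposure.
#' @slot fStat per-instrument F-statistic.
#' @slot provenance data.frame recording, for every candidate variant, which
#'   selection rule removed it (or "kept"), and any proxy substitutions.
#' @export
setClass("InstrumentSet",
  representation(exposureId = "character", instruments = "data.frame",
                 r2Explained = "numeric", fStat = "numeric",
                 provenance = "data.frame"),
  validity = function(object) {
    k <- nrow(object@instruments)
    if (length(object@r2Explained) != k || length(object@fStat) != k)
      return("r2Explained/fStat length must match instrument count")
    if (k && any(object@fStat < 0)) return("F-statistics must be >= 0")
    if (k && any(object@r2Explained < 0 | object@r2Explained >= 1))
      return("r2Explained must lie in [0, 1)")
    TRUE
  })

#' Harmonized exposure-outcome dataset
#'
#' Per-variant aligned effect pairs ready for MR estimation: the outcome
#' effect is expressed on the exposure's effect allele and palindromic or
#' irreconcilable variants have been removed.
#'
#' @slot exposureId,outcomeId trait labels.
#' @slot snp variant identifiers.
#' @slot bx,bxse exposure effect and standard error.
#' @slot by,byse outcome effect and standard error.
#' @slot log data.frame recording per-candidate harmonization actions.
#' @export
setClass("HarmonizedData",
  representation(exposureId = "character", outcomeId = "character",
                 snp = "character", bx = "numeric", bxse = "numeric",
                 by = "numeric", byse = "numeric", log = "data.frame"),
  validity = function(object) {
    k <- length(object@snp)
    lens <- c(length(object@bx), length(object@bxse), length(object@by),
              length(object@byse))
    if (any(lens != k)) return("effect vectors must have equal length")
    if (k && (any(object@bxse <= 0) || any(object@byse <= 0)))
      return("standard errors must be > 0")
    if (anyDuplicated(object@snp)) return("duplicate snp ids")
    TRUE
  })

#' A single method-tagged MR estimate
#'
#' @slot method one of \code{"wald"}, \code{"ivw"}, \code{"egger"},
#'   \code{"weighted_median"}, \code{"weighted_mode"}.
#' @slot beta,se causal effect (SD outcome per SD exposure) and its standard
#'   error.
#' @slot ciLow,ciHigh normal-theory 95\% bounds (beta +/- 1.96 se).
#' @slot pval two-sided normal p-value.
#' @slot nsnp instrument count.
#' @slot extra list; for MR-Egger holds \code{intercept}, \code{interceptSE},
#'   \code{interceptP}; estimators may add bootstrap metadata.
#' @export
setClass("MRResult",
  representation(method = "character", beta = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pval = "numeric",
                 nsnp = "integer", extra = "list"),
  validity = function(object) {
    ok <- c("wald", "ivw", "egger", "weighted_median", "weighted_mode")
    if (!object@method %in% ok) return("unknown method")
    if (object@se <= 0) return("se must be > 0")
    if (object@pval <= 0 || object@pval > 1) return("pval must be in (0, 1]")
    if (abs(object@ciLow - (object@beta - 1.96 * object@se)) > 1e-8 ||
        abs(object@ciHigh - (object@beta + 1.96 * object@se)) > 1e-8)
      return("confidence bounds must equal beta +/- 1.96 se")
    TRUE
  })

#' Cochran's Q heterogeneity test
#'
#' @slot q statistic (>= 0).
#' @slot df degrees of freedom (nsnp - 1).
#' @slot pval upper-tail chi-square probability.
#' @export
setClass("QTest",
  representation(q = "numeric", df = "integer", pval = "numeric"),
  validity = function(object) {
    if (object@q < 0) return("q must be >= 0")
    if (object@pval <= 0 || object@pval > 1) return("pval must be in (0, 1]")
    TRUE
  })

#' Full MR analysis of one exposure-outcome pair
#'
#' Returned by \code{\link{mrAuto}}: the primary estimate (Wald ratio for a
#' single instrument, IVW otherwise), any applicable sensitivity estimates,
#' and Cochran's Q when at least two instruments are present.
#'
#' @slot exposureId,outcomeId trait labels.
#' @slot estimates named list of \code{MRResult} objects.
#' @slot qtest list: empty, or holding one \code{QTest} under \code{$q}.
#' @export
setClass("MRAnalysis",
  representation(exposureId = "character", outcomeId = "character",
                 estimates = "list", qtest = "list"))

#' Regional association summary for colocalization
#'
#' @slot traitId trait label.
#' @slot variants ordered variant ids (shared across the pair).
#' @slot beta,se per-variant association and standard error.
#' @slot maf per-variant minor-allele frequency in (0, 0.5].
#' @slot n GWAS sample size.
#' @slot sdTrait trait standard deviation (1 for standardized traits).
#' @export
setClass("RegionalSummary",
  representation(traitId = "character", variants = "character",
                 beta = "numeric", se = "numeric", maf = "numeric",
                 n = "numeric", sdTrait = "numeric"),
  validity = function(object) {
    k <- length(object@variants)
    if (length(object@beta) != k || length(object@se) != k ||
        length(object@maf) != k)
      return("beta/se/maf must match variants in length")
    if (k && any(object@se <= 0)) return("se must be > 0")
    if (k && any(object@maf <= 0 | object@maf > 0.5))
      return("maf must lie in (0, 0.5]")
    TRUE
  })

#' Colocalization posteriors
#'
#' Posterior probabilities of the five single-causal-variant hypotheses:
#' H0 no association, H1/H2 one trait only, H3 two distinct causal variants,
#' H4 one shared causal variant.
#'
#' @slot pp numeric(5), named pph0..pph4, summing to 1.
#' @slot nVariants variant count of the analyzed region.
#' @slot call one of \code{"colocalized"}, \code{"suggestive"},
#'   \code{"not_colocalized"}.
#' @slot notes character annotations (e.g. single-variant region).
#' @export
setClass("ColocResult",
  representation(pp = "numeric", nVariants = "integer", call = "character",
                 notes = "character"),
  validity = function(object) {
    if (length(object@pp) != 5) return("pp must have length 5")
    if (any(object@pp < -1e-12 | object@pp > 1 + 1e-12))
      return("posteriors must lie in [0, 1]")
    if (abs(sum(object@pp) - 1) > 1e-9) return("posteriors must sum to 1")
    TRUE
  })

#' Screen report: the pipeline's result container
#'
#' @slot primary data.frame of primary protein-outcome MR results.
#' @slot step1 data.frame of risk-factor to outcome MR results (Step-1).
#' @slot step2 data.frame of protein to risk-factor MR results (Step-2).
#' @slot mediation data.frame of mediation decompositions.
#' @slot coloc data.frame of per-pair colocalization posteriors and calls.
#' @slot config the \code{ScreenConfig}-style list used for the run,
#'   including resolved Bonferroni thresholds and the seed.
#' @export
setClass("ScreenReport",
  representation(primary = "data.frame", step1 = "data.frame",
                 step2 = "data.frame", mediation = "data.frame",
                 coloc = "data.frame", config = "list"))
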