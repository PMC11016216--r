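#' @include AllClasses.R
NULL

#' Accessors for protMR result objects
#'
#' Small accessor family: \code{mrBeta}, \code{mrSE}, \code{pvalue},
#' \code{nsnp}, \code{confint95}, \code{posteriors}, \code{colocCall},
#' \code{variantIds}, \code{instruments}.
#'
#' @param x a protMR object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))
#' @rdname accessors
#' @export
setGeneric("mrSE", function(x) standardGeneric("mrSE"))
#' @rdname accessors
#' @export
setGeneric("pvalue", function(x) standardGeneric("pvalue"))
#' @rdname accessors
#' @export
setGeneric("nsnp", function(x) standardGeneric("nsnp"))
#' @rdname accessors
#' @export
setGeneric("confint95", function(x) standardGeneric("confint95"))
#' @rdname accessors
#' @export
setGeneric("posteriors", function(x) standardGeneric("posteriors"))
#' @rdname accessors
#' @export
setGeneric("colocCall", function(x) standardGeneric("colocCall"))
#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
#' @rdname accessors
#' @export
setGeneric("instruments", function(x) standardGeneric("instruments"))

#' @rdname accessors
setMethod("mrBeta", "MRResult", function(x) x@beta)
#' @rdname accessors
setMethod("mrSE", "MRResult", function(x) x@se)
#' @rdname accessors
setMethod("pvalue", "MRResult", function(x) x@pval)
#' @rdname accessors
setMethod("pvalue", "QTest", function(x) x@pval)
#' @rdname accessors
setMethod("nsnp", "MRResult", function(x) x@nsnp)
#' @rdname accessors
setMethod("nsnp", "HarmonizedData", function(x) length(x@snp))
#' @rdname accessors
setMethod("confint95", "MRResult", function(x) c(x@ciLow, x@ciHigh))
#' @rdname accessors
setMethod("posteriors", "ColocResult", function(x) x@pp)
#' @rdname accessors
setMethod("colocCall", "ColocResult", function(x) x@call)
#' @rdname accessors
setMethod("variantIds", "LDReference", function(x) x@variantIds)
#' @rdname accessors
setMethod("variantIds", "RegionalSummary", function(x) x@variants)
#' @rdname accessors
setMethod("instruments", "InstrumentSet", function(x) x@instruments)

setMethod("show", "LDReference", function(object) {
  cat("LDReference:", length(object@variantIds), "variants on chromosome",
      object@chromosome, "\n")
})

setMethod("show", "SimulatedStudy", function(object) {
  cat("SimulatedStudy '", object@traitId, "': ", nrow(object@table),
      " variants\n", sep = "")
})

setMethod("show", "InstrumentSet", function(object) {
  cat("InstrumentSet for '", object@exposureId, "': ",
      nrow(object@instruments), " instruments (",
      nrow(object@provenance), " candidates considered)\n", sep = "")
  if (nrow(object@instruments))
    cat("  F-statistics: ", paste(signif(object@fStat, 4), collapse = ", "),
        "\n", sep = "")
})

setMethod("show", "HarmonizedData", function(object) {
  cat("HarmonizedData ", object@exposureId, " -> ", object@outcomeId, ": ",
      length(object@snp), " aligned variants\n", sep = "")
})

setMethod("show", "MRResult", function(object) {
  cat(sprintf("MRResult [%s] beta = %.4g (95%% CI %.4g, %.4g), p = %.3g, nsnp = %d\n",
              object@method, object@beta, object@ciLow, object@ciHigh,
              object@pval, object@nsnp))
  if (object@method == "egger")
    cat(sprintf("  Egger intercept = %.4g (p = %.3g)\n",
                object@extra$intercept, object@extra$interceptP))
})

setMethod("show", "QTest", function(object) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g\n",
              object@q, object@df, object@pval))
})

setMethod("show", "MRAnalysis", function(object) {
  cat("MRAnalysis ", object@exposureId, " -> ", object@outcomeId, "\n",
      sep = "")
  for (est in object@estimates) show(est)
  if (length(object@qtest)) show(object@qtest$q)
})

setMethod("show", "ColocResult", function(object) {
  cat("ColocResult (", object@nVariants, " variants): call = ",
      object@call, "\n  ", sep = "")
  cat(paste(sprintf("%s=%.3f", names(object@pp), object@pp),
            collapse = " "), "\n")
})

setMethod("show", "ScreenReport", function(object) {
  cat("ScreenReport:",
      nrow(object@primary), "primary,",
      nrow(object@step1), "step-1,",
      nrow(object@step2), "step-2 MR rows;",
      nrow(object@coloc), "coloc rows;",
      nrow(object@mediation), "mediation rows\n")
})
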