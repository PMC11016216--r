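#' Assemble mediation-analysis inputs
#'
#' The two-step decomposition uses three MR estimates: \code{beta1}
#' (exposure to mediator, Step-2 MR), \code{beta2} (mediator to outcome,
#' Step-1 MR) and \code{beta3} (total exposure-to-outcome effect, primary
#' MR), each with its standard error.
#'
#' @param exposureId,mediatorId,outcomeId labels.
#' @param beta1,se1 exposure-to-mediator effect and se.
#' @param beta2,se2 mediator-to-outcome effect and se.
#' @param beta3,se3 total exposure-to-outcome effect and se.
#' @return validated list of class \code{"MediationInput"}.
#' @export
mediationInput <- function(exposureId, mediatorId, outcomeId,
                           beta1, se1, beta2, se2, beta3, se3) {
  stopifnot(se1 > 0, se2 > 0, se3 > 0,
            is.finite(beta1), is.finite(beta2), is.finite(beta3))
  structure(list(exposureId = exposureId, mediatorId = mediatorId,
                 outcomeId = outcomeId, beta1 = beta1, se1 = se1,
                 beta2 = beta2, se2 = se2, beta3 = beta3, se3 = se3),
            class = "MediationInput")
}

#' Indirect (mediated) effect by the product method
#'
#' \code{indirect = beta1 * beta2}, with first-order delta-method standard
#' error \code{sqrt(beta1^2 se2^2 + beta2^2 se1^2)} — no covariance term, as
#' the two coefficients come from non-overlapping samples — and a normal
#' 95\% CI.
#'
#' @param inp a \code{\link{mediationInput}}.
#' @return list with \code{indirect}, \code{se}, \code{ci} (length-2).
#' @examples
#' inp <- mediationInput("CTSA", "SHBG", "liver_volume",
#'                       beta1 = 0.51, se1 = 0.017,
#'                       beta2 = -0.139, se2 = 0.042,
#'                       beta3 = -0.29, se3 = 0.05)
#' indirectEffect(inp)
#' @export
indirectEffect <- function(inp) {
  stopifnot(inherits(inp, "MediationInput"))
  ind <- inp$beta1 * inp$beta2
  se <- sqrt(inp$beta1^2 * inp$se2^2 + inp$beta2^2 * inp$se1^2)
  list(indirect = ind, se = se, ci = ind + c(-1.96, 1.96) * se)
}

#' Proportion of the total effect that is mediated
#'
#' \code{proportion = indirect / beta3}, reported as a percentage, with a
#' first-order delta-method CI for the ratio (independence of numerator and
#' denominator assumed). When the indirect and total effects disagree in
#' sign, or the proportion exceeds 1 in magnitude, an inconsistent-mediation
#' warning note is attached (the value is still reported, untruncated).
#'
#' @param inp a \code{\link{mediationInput}}.
#' @param indirect optional result of \code{\link{indirectEffect}}
#'   (recomputed when missing).
#' @return list with \code{proportion} (fraction), \code{proportionPct},
#'   \code{ci} (fraction scale), \code{note}.
#' @export
proportionMediated <- function(inp, indirect = indirectEffect(inp)) {
  stopifnot(inherits(inp, "MediationInput"))
  if (inp$beta3 == 0) stop("undefined-proportion: total effect beta3 = 0")
  prop <- indirect$indirect / inp$beta3
  se <- sqrt(indirect$se^2 / inp$beta3^2 +
             indirect$indirect^2 * inp$se3^2 / inp$beta3^4)
  note <- ""
  if (indirect$indirect != 0 &&
      sign(indirect$indirect) != sign(inp$beta3))
    note <- "inconsistent mediation: indirect and total effects differ in sign"
  else if (abs(prop) > 1)
    note <- "inconsistent mediation: |proportion| > 1"
  list(proportion = prop, proportionPct = 100 * prop,
       ci = prop + c(-1.96, 1.96) * se, note = note)
}

#' Reverse-MR bidirectionality check
#'
#' The mediation model assumes the exposure acts on the mediator and not the
#' reverse; a significant reverse (mediator-to-exposure) MR estimate flags
#' the model as potentially invalid. The flag annotates results, it does not
#' remove them. A reverse p-value exactly at the threshold is not flagged
#' (strict inequality).
#'
#' @param reverseEstimate \code{\linkS4class{MRResult}} of the mediator on
#'   the exposure.
#' @param alpha significance threshold (default the protein-family
#'   Bonferroni threshold 0.05/1002).
#' @return logical: \code{TRUE} when the mediation model is considered
#'   valid.
#' @export
checkBidirectionality <- function(reverseEstimate, alpha = 0.05 / 1002) {
  stopifnot(is(reverseEstimate, "MRResult"))
  !(pvalue(reverseEstimate) < alpha)
}

#' Full mediation decomposition for one exposure-mediator-outcome triple
#'
#' Combines \code{\link{indirectEffect}} and
#' \code{\link{proportionMediated}}; the direct effect is the total minus
#' the indirect effect, so \code{direct + indirect = beta3} exactly.
#'
#' @param inp a \code{\link{mediationInput}}.
#' @param reverseEstimate optional reverse-MR \code{MRResult} for the
#'   validity flag.
#' @param alpha threshold for \code{\link{checkBidirectionality}}.
#' @return list with \code{indirect}, \code{indirectSE},
#'   \code{indirectCI}, \code{direct}, \code{proportion},
#'   \code{proportionPct}, \code{proportionCI}, \code{valid}, \code{notes}.
#' @export
mediate <- function(inp, reverseEstimate = NULL, alpha = 0.05 / 1002) {
  ind <- indirectEffect(inp)
  prop <- proportionMediated(inp, ind)
  valid <- if (is.null(reverseEstimate)) NA
           else checkBidirectionality(reverseEstimate, alpha)
  list(exposureId = inp$exposureId, mediatorId = inp$mediatorId,
       outcomeId = inp$outcomeId,
       indirect = ind$indirect, indirectSE = ind$se, indirectCI = ind$ci,
       direct = inp$beta3 - ind$indirect,
       proportion = prop$proportion, proportionPct = prop$proportionPct,
       proportionCI = prop$ci, valid = valid, notes = prop$note)
}
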