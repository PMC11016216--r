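#' Simulate a full screening study with known causal structure
#'
#' Builds a synthetic proteome-wide screen: each protein occupies its own
#' LD region (one synthetic chromosome, exponential-decay kernel) with
#' \code{nInstruments} causal pQTLs spread far enough apart to survive
#' clumping. Proteins are of three kinds: \emph{null} (no outcome effect),
#' \emph{causal} (true effect \code{theta}, so the pQTL region colocalizes
#' with the outcome signal), and \emph{confounded} (no causal effect, but a
#' distinct outcome-causal variant planted two positions away from each
#' pQTL, in moderate LD with it — an MR signal that colocalization should
#' expose as two different variants).
#'
#' @param nNull,nCausal,nConfounded protein counts per kind.
#' @param theta true causal effect of the causal proteins (SD/SD).
#' @param nInstruments causal pQTLs per protein. The default of one
#'   sentinel pQTL per region keeps the single-causal-variant assumption of
#'   the colocalization model true by construction; multi-instrument
#'   behaviour is exercised by \code{\link{simulateMediationChain}}.
#' @param regionSize variants per protein region.
#' @param spacing,decay LD kernel geometry (bp, per-bp rate).
#' @param nExposure,nOutcome GWAS sample sizes.
#' @param instrumentR2 per-pQTL variance explained in its protein.
#' @param confoundedZ target outcome z-score at the confounded proteins'
#'   pQTLs (the planted variant is scaled so LD leakage reaches this).
#' @param seed integer seed.
#' @return list with \code{proteinStudies}, \code{outcomeStudies} (one
#'   outcome), \code{ld} (list of per-protein references), and
#'   \code{truth} (\code{causal}, \code{confounded}, \code{null} protein
#'   ids and the \code{TruthConfig}).
#' @export
simulateScreenScenario <- function(nNull = 20, nCausal = 3,
                                   nConfounded = 2, theta = 0.4,
                                   nInstruments = 1, regionSize = 41,
                                   spacing = 1e4, decay = 5e-5,
                                   nExposure = 10000, nOutcome = 30000,
                                   instrumentR2 = 0.02,
                                   confoundedZ = 10, seed = 1) {
  kinds <- c(rep("causal", nCausal), rep("confounded", nConfounded),
             rep("null", nNull))
  nP <- length(kinds)
  ids <- paste0(kinds, ave(seq_len(nP), kinds, FUN = seq_along))
  thetaM <- matrix(ifelse(kinds == "causal", theta, 0), ncol = 1,
                   dimnames = list(ids, "outcome"))
  ld <- lapply(seq_len(nP), function(i)
    simulateLDReference(regionSize, decay = decay,
                        chromosome = as.character(i), spacing = spacing,
                        prefix = paste0("rs", i, "_")))
  ## plant outcome-causal variants near (not at) the confounded pQTLs
  causalIdx <- unique(round(seq(1, regionSize,
                                length.out = nInstruments)))
  rNear <- exp(-decay * 2 * spacing)
  gammaVal <- confoundedZ / (rNear * sqrt(nOutcome))
  gamma <- numeric(0)
  for (i in which(kinds == "confounded")) {
    nb <- ifelse(causalIdx + 2 <= regionSize, causalIdx + 2, causalIdx - 2)
    g <- stats::setNames(rep(gammaVal, length(nb)),
                         ld[[i]]@variantIds[nb])
    gamma <- c(gamma, g)
  }
  truth <- truthConfig(nProteins = nP,
                       nVariantsPerProtein = nInstruments,
                       nExposure = nExposure, nOutcome = nOutcome,
                       theta = thetaM, gamma = gamma,
                       instrumentR2 = instrumentR2,
                       palindromicRate = 0, seed = seed)
  prot <- simulateProteinGwas(truth, ld)
  outcome <- simulateOutcomeGwas(truth, prot, "outcome")
  list(proteinStudies = prot,
       outcomeStudies = list(outcome = outcome),
       ld = ld,
       truth = list(causal = ids[kinds == "causal"],
                    confounded = ids[kinds == "confounded"],
                    null = ids[kinds == "null"], config = truth))
}

#' Simulate a protein - mediator - outcome causal chain
#'
#' Two-step mediation ground truth: the protein affects the mediator
#' (\code{theta1}), the mediator affects the outcome (\code{theta2}), and
#' the protein additionally has a direct outcome path (\code{direct}), so
#' the total effect is \code{theta1 * theta2 + direct} and the true
#' proportion mediated is \code{theta1 * theta2 / (theta1 * theta2 +
#' direct)}. The protein and the mediator have disjoint instrument sets on
#' separate synthetic chromosomes; every trait's table covers both regions
#' so that all six MR directions (including reverse MR) are estimable.
#'
#' @param theta1,theta2,direct chain coefficients.
#' @param nInstruments instruments per exposure.
#' @param nExposure,nMediator,nOutcome GWAS sample sizes.
#' @param instrumentR2 per-instrument variance explained.
#' @param seed integer seed.
#' @return list with \code{proteinStudies}, \code{riskFactorStudies},
#'   \code{outcomeStudies}, \code{ld}, \code{truth}.
#' @export
simulateMediationChain <- function(theta1 = 0.4, theta2 = 0.3,
                                   direct = 0.1, nInstruments = 10,
                                   nExposure = 20000, nMediator = 20000,
                                   nOutcome = 30000, instrumentR2 = 0.02,
                                   seed = 1) {
  refA <- simulateLDReference(nInstruments, decay = 5e-5,
                              chromosome = "1", spacing = 1e5,
                              prefix = "rsA_")
  refB <- simulateLDReference(nInstruments, decay = 5e-5,
                              chromosome = "2", spacing = 1e5,
                              prefix = "rsB_")
  total <- theta1 * theta2 + direct
  thCfg <- function(who, th, trait, nExp, nOut, sd)
    truthConfig(nProteins = 1, nVariantsPerProtein = nInstruments,
                nExposure = nExp, nOutcome = nOut,
                theta = matrix(th, 1, 1, dimnames = list(who, trait)),
                instrumentR2 = instrumentR2, palindromicRate = 0,
                seed = sd)
  ## protein region (A): protein is the exposure; the mediator and the
  ## outcome are measured downstream with their own GWAS sample sizes
  tMedA <- thCfg("protein", theta1, "mediator", nExposure, nMediator, seed)
  tOutA <- thCfg("protein", total, "outcome", nExposure, nOutcome, seed)
  tProtB <- thCfg("mediator", 0, "protein", nMediator, nExposure,
                  seed + 1003L)
  tOutB <- thCfg("mediator", theta2, "outcome", nMediator, nOutcome,
                 seed + 1003L)
  protA <- simulateProteinGwas(tMedA, list(refA))$protein
  medB <- simulateProteinGwas(tOutB, list(refB))$mediator
  medA <- simulateDownstreamGwas(tMedA, protA, "mediator")
  outA <- simulateDownstreamGwas(tOutA, protA, "outcome")
  outB <- simulateDownstreamGwas(tOutB, medB, "outcome")
  protB <- simulateDownstreamGwas(tProtB, medB, "protein")
  bind <- function(a, b) rbind(a@table, b@table, make.row.names = FALSE)
  list(proteinStudies = list(protein = bind(protA, protB)),
       riskFactorStudies = list(mediator = bind(medA, medB)),
       outcomeStudies = list(outcome = bind(outA, outB)),
       ld = list(refA, refB),
       truth = list(theta1 = theta1, theta2 = theta2, direct = direct,
                    total = total,
                    proportion = theta1 * theta2 / total))
}
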