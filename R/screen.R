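#' Configuration of the screening pipeline
#'
#' @param alpha family-wise error level.
#' @param nProteinTests Bonferroni denominator for the protein family
#'   (number of distinct proteins tested; 1002 in the reference analysis).
#'   \code{NULL} uses the number of instrumentable proteins in the run.
#' @param nRiskFactorTests Bonferroni denominator for the risk-factor
#'   family (18 in the reference analysis). \code{NULL} uses the number of
#'   risk-factor studies supplied.
#' @param selection \code{\link{selectionParams}}.
#' @param priors \code{\link{colocPriors}}.
#' @param colocWindow,colocMafMin region extraction settings.
#' @param colocStrong,colocSuggestive PPH4 call thresholds.
#' @param ivwMode IVW variance model.
#' @param nBoot bootstrap replicates for median/mode.
#' @param seed integer seed.
#' @return validated list of class \code{"ScreenConfig"}.
#' @export
screenConfig <- function(alpha = 0.05, nProteinTests = 1002,
                         nRiskFactorTests = 18,
                         selection = selectionParams(),
                         priors = colocPriors(),
                         colocWindow = 1e6, colocMafMin = 0.01,
                         colocStrong = 0.8, colocSuggestive = 0.6,
                         ivwMode = "multiplicative_random",
                         nBoot = 1000, seed = 1) {
  stopifnot(alpha > 0, alpha < 1,
            is.null(nProteinTests) || nProteinTests >= 1,
            is.null(nRiskFactorTests) || nRiskFactorTests >= 1)
  structure(list(alpha = alpha, nProteinTests = nProteinTests,
                 nRiskFactorTests = nRiskFactorTests,
                 selection = selection, priors = priors,
                 colocWindow = colocWindow, colocMafMin = colocMafMin,
                 colocStrong = colocStrong,
                 colocSuggestive = colocSuggestive, ivwMode = ivwMode,
                 nBoot = nBoot, seed = as.integer(seed)),
            class = "ScreenConfig")
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error level.
#' @param m number of tests (>= 1).
#' @return \code{alpha / m}.
#' @examples
#' bonferroniThreshold(0.05, 1002)
#' bonferroniThreshold(0.05, 18)
#' @export
bonferroniThreshold <- function(alpha, m) {
  if (m < 1) stop("invalid-argument: m must be >= 1")
  stopifnot(alpha > 0, alpha < 1)
  alpha / m
}

.studyTableOf <- function(x) if (is(x, "SimulatedStudy")) x@table else x

## One MR screen of every exposure study against every outcome study.
## Returns a flat result table; zero-instrument exposures appear as
## untestable rows rather than errors.
.mrScreen <- function(exposureStudies, outcomeStudies, ld, config,
                      threshold) {
  counts <- countProteinAssociations(exposureStudies,
                                     config$selection$pThreshold)
  rows <- list()
  sets <- list()
  for (ex in names(exposureStudies)) {
    tab <- .studyTableOf(exposureStudies[[ex]])
    sets[[ex]] <- selectInstruments(tab, counts, ld, config$selection,
                                    exposureId = ex)
  }
  for (ex in names(exposureStudies)) {
    iset <- sets[[ex]]
    for (oc in names(outcomeStudies)) {
      otab <- .studyTableOf(outcomeStudies[[oc]])
      row <- data.frame(exposure = ex, outcome = oc, method = NA_character_,
                        nsnp = 0L, beta = NA_real_, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        pval = NA_real_, q = NA_real_, q_df = NA_integer_,
                        q_pval = NA_real_, egger_intercept = NA_real_,
                        egger_intercept_p = NA_real_, pqtl = NA_character_,
                        untestable = TRUE, significant = FALSE,
                        stringsAsFactors = FALSE)
      if (nrow(iset@instruments)) {
        h <- harmonize(iset, otab, outcomeId = oc, ld = ld,
                       params = config$selection)
        if (nsnp(h) >= 1) {
          an <- mrAuto(h, ivwMode = config$ivwMode, nBoot = config$nBoot,
                       seed = config$seed)
          pe <- primaryEstimate(an)
          top <- h@snp[which.max(abs(h@bx / h@bxse))]
          row$method <- pe@method
          row$nsnp <- pe@nsnp
          row$beta <- pe@beta; row$se <- pe@se
          row$ci_low <- pe@ciLow; row$ci_high <- pe@ciHigh
          row$pval <- pe@pval
          if (length(an@qtest)) {
            row$q <- an@qtest$q@q
            row$q_df <- an@qtest$q@df
            row$q_pval <- an@qtest$q@pval
          }
          if (!is.null(an@estimates$egger)) {
            row$egger_intercept <- an@estimates$egger@extra$intercept
            row$egger_intercept_p <- an@estimates$egger@extra$interceptP
          }
          row$pqtl <- top
          row$untestable <- FALSE
          row$significant <- pe@pval < threshold
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(exposure = character(0), outcome = character(0),
                         method = character(0), nsnp = integer(0),
                         beta = numeric(0), se = numeric(0),
                         ci_low = numeric(0), ci_high = numeric(0),
                         pval = numeric(0), q = numeric(0),
                         q_df = integer(0), q_pval = numeric(0),
                         egger_intercept = numeric(0),
                         egger_intercept_p = numeric(0),
                         pqtl = character(0), untestable = logical(0),
                         significant = logical(0), stringsAsFactors = FALSE)
  attr(out, "instrumentSets") <- sets
  out
}

#' Primary proteome-wide MR screen
#'
#' For every protein x outcome pair: instrument selection, harmonization,
#' \code{\link{mrAuto}}, and a significance flag at the protein-family
#' Bonferroni threshold. Proteins with no surviving instruments are
#' reported as untestable rows.
#'
#' @param proteinStudies named list of protein studies (data.frames or
#'   \code{SimulatedStudy}).
#' @param outcomeStudies named list of outcome studies.
#' @param ld LD reference(s) covering the candidate variants.
#' @param config \code{\link{screenConfig}}.
#' @return data.frame of per-pair results with attributes
#'   \code{"threshold"} and \code{"instrumentSets"}.
#' @export
runPrimaryScreen <- function(proteinStudies, outcomeStudies, ld,
                             config = screenConfig()) {
  m <- config$nProteinTests
  if (is.null(m)) m <- max(1L, length(proteinStudies))
  thr <- bonferroniThreshold(config$alpha, m)
  out <- .mrScreen(proteinStudies, outcomeStudies, ld, config, thr)
  attr(out, "threshold") <- thr
  out
}

#' Two-step MR screen (risk factors and proteins)
#'
#' Step-1 screens risk factors against outcomes at the risk-factor-family
#' Bonferroni threshold; Step-2 screens proteins against the risk factors
#' that passed Step-1, at the protein-family threshold. When no risk factor
#' passes Step-1, the Step-2 table is empty.
#'
#' @param proteinStudies,riskFactorStudies,outcomeStudies named study
#'   lists.
#' @param ld LD reference(s).
#' @param config \code{\link{screenConfig}}.
#' @return list with \code{step1}, \code{step2} data.frames and the two
#'   thresholds.
#' @export
runTwoStepScreen <- function(proteinStudies, riskFactorStudies,
                             outcomeStudies, ld,
                             config = screenConfig()) {
  mRF <- config$nRiskFactorTests
  if (is.null(mRF)) mRF <- max(1L, length(riskFactorStudies))
  thr1 <- bonferroniThreshold(config$alpha, mRF)
  step1 <- .mrScreen(riskFactorStudies, outcomeStudies, ld, config, thr1)
  attr(step1, "threshold") <- thr1
  mP <- config$nProteinTests
  if (is.null(mP)) mP <- max(1L, length(proteinStudies))
  thr2 <- bonferroniThreshold(config$alpha, mP)
  flagged <- unique(step1$exposure[step1$significant])
  step2 <- if (length(flagged))
    .mrScreen(proteinStudies, riskFactorStudies[flagged], ld, config, thr2)
  else {
    e <- step1[0, , drop = FALSE]
    attr(e, "instrumentSets") <- list()
    e
  }
  attr(step2, "threshold") <- thr2
  list(step1 = step1, step2 = step2, step1Threshold = thr1,
       step2Threshold = thr2)
}

#' Select mediation candidates from the three screens
#'
#' Emits one \code{\link{mediationInput}} for every (protein, mediator,
#' outcome) triple where the protein passes the primary screen for the
#' outcome, the mediator passes Step-1 for the same outcome, and the
#' protein passes Step-2 for the mediator. A direction-consistency note is
#' attached comparing sign(beta1 * beta2) with sign(beta3).
#'
#' @param primary primary screen data.frame.
#' @param step1,step2 two-step screen data.frames.
#' @return list of \code{MediationInput} objects, each with a
#'   \code{"directionNote"} attribute.
#' @export
selectMediationCandidates <- function(primary, step1, step2) {
  out <- list()
  sigP <- primary[primary$significant & !primary$untestable, , drop = FALSE]
  sig1 <- step1[step1$significant & !step1$untestable, , drop = FALSE]
  sig2 <- step2[step2$significant & !step2$untestable, , drop = FALSE]
  for (i in seq_len(nrow(sigP))) {
    prot <- sigP$exposure[i]
    oc <- sigP$outcome[i]
    meds <- sig1[sig1$outcome == oc, , drop = FALSE]
    for (j in seq_len(nrow(meds))) {
      med <- meds$exposure[j]
      s2 <- sig2[sig2$exposure == prot & sig2$outcome == med, ,
                 drop = FALSE]
      if (!nrow(s2)) next
      inp <- mediationInput(prot, med, oc,
                            beta1 = s2$beta[1], se1 = s2$se[1],
                            beta2 = meds$beta[j], se2 = meds$se[j],
                            beta3 = sigP$beta[i], se3 = sigP$se[i])
      attr(inp, "directionNote") <-
        if (sign(inp$beta1 * inp$beta2) == sign(inp$beta3))
          "direction-consistent" else "direction-inconsistent"
      out[[length(out) + 1L]] <- inp
    }
  }
  out
}

#' Colocalization verification of flagged associations
#'
#' For every significant primary-screen pair, extracts the +/- 1 Mb region
#' around the pair's sentinel pQTL from the protein and outcome tables,
#' computes colocalization posteriors, and labels the pair
#' \code{prioritized} when the call is \code{"colocalized"}
#' (PPH4 above the strong threshold). Region-extraction failures are
#' annotated, not fatal.
#'
#' @param flagged primary screen data.frame (only rows with
#'   \code{significant == TRUE} are analyzed).
#' @param proteinStudies,outcomeStudies named study lists.
#' @param config \code{\link{screenConfig}}.
#' @return data.frame: exposure, outcome, pqtl, n_variants, pph0..pph4,
#'   call, prioritized, note.
#' @export
runColocVerification <- function(flagged, proteinStudies, outcomeStudies,
                                 config = screenConfig()) {
  rows <- list()
  sel <- flagged[flagged$significant & !flagged$untestable, , drop = FALSE]
  for (i in seq_len(nrow(sel))) {
    row <- data.frame(exposure = sel$exposure[i], outcome = sel$outcome[i],
                      pqtl = sel$pqtl[i], n_variants = 0L,
                      pph0 = NA_real_, pph1 = NA_real_, pph2 = NA_real_,
                      pph3 = NA_real_, pph4 = NA_real_,
                      call = NA_character_, prioritized = FALSE,
                      note = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      reg <- extractRegion(sel$pqtl[i],
                           .studyTableOf(proteinStudies[[sel$exposure[i]]]),
                           .studyTableOf(outcomeStudies[[sel$outcome[i]]]),
                           window = config$colocWindow,
                           mafMin = config$colocMafMin,
                           trait1 = sel$exposure[i],
                           trait2 = sel$outcome[i])
      colocPosteriors(reg$region1, reg$region2, priors = config$priors,
                      strong = config$colocStrong,
                      suggestive = config$colocSuggestive)
    }, error = function(e) conditionMessage(e))
    if (is(res, "ColocResult")) {
      row$n_variants <- res@nVariants
      row[paste0("pph", 0:4)] <- as.list(unname(res@pp))
      row$call <- res@call
      row$prioritized <- res@call == "colocalized"
      if (length(res@notes)) row$note <- res@notes[1]
    } else row$note <- res
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(exposure = character(0), outcome = character(0),
                  pqtl = character(0), n_variants = integer(0),
                  pph0 = numeric(0), pph1 = numeric(0), pph2 = numeric(0),
                  pph3 = numeric(0), pph4 = numeric(0), call = character(0),
                  prioritized = logical(0), note = character(0),
                  stringsAsFactors = FALSE)
}

#' Run the full four-step screen
#'
#' Orchestrates the study design: (1) proteome-wide primary MR screen;
#' (2) colocalization verification of the flagged pairs; (3) Step-1 /
#' Step-2 risk-factor screens; (4) mediation decomposition for the gated
#' candidate triples, with a reverse-MR validity flag where the mediator's
#' instruments overlap the protein study.
#'
#' @param proteinStudies,outcomeStudies,riskFactorStudies named study
#'   lists (risk factors optional).
#' @param ld LD reference(s).
#' @param config \code{\link{screenConfig}}.
#' @return a \code{\linkS4class{ScreenReport}}.
#' @export
runScreen <- function(proteinStudies, outcomeStudies,
                      riskFactorStudies = list(), ld,
                      config = screenConfig()) {
  primary <- runPrimaryScreen(proteinStudies, outcomeStudies, ld, config)
  coloc <- runColocVerification(primary, proteinStudies, outcomeStudies,
                                config)
  if (length(riskFactorStudies)) {
    two <- runTwoStepScreen(proteinStudies, riskFactorStudies,
                            outcomeStudies, ld, config)
    cands <- selectMediationCandidates(primary, two$step1, two$step2)
  } else {
    two <- list(step1 = primary[0, , drop = FALSE],
                step2 = primary[0, , drop = FALSE],
                step1Threshold = NA_real_, step2Threshold = NA_real_)
    cands <- list()
  }
  medRows <- lapply(cands, function(inp) {
    rev <- .reverseMR(inp, riskFactorStudies, proteinStudies, ld, config)
    m <- mediate(inp, reverseEstimate = rev,
                 alpha = attr(primary, "threshold"))
    data.frame(exposure = m$exposureId, mediator = m$mediatorId,
               outcome = m$outcomeId,
               beta1 = inp$beta1, beta2 = inp$beta2, beta3 = inp$beta3,
               indirect = m$indirect, indirect_se = m$indirectSE,
               indirect_ci_low = m$indirectCI[1],
               indirect_ci_high = m$indirectCI[2],
               direct = m$direct, proportion_pct = m$proportionPct,
               proportion_ci_low = 100 * m$proportionCI[1],
               proportion_ci_high = 100 * m$proportionCI[2],
               valid = m$valid,
               notes = paste(c(attr(inp, "directionNote"),
                               if (nzchar(m$notes)) m$notes),
                             collapse = "; "),
               stringsAsFactors = FALSE)
  })
  mediation <- if (length(medRows)) do.call(rbind, medRows)
               else data.frame(exposure = character(0))
  cfg <- unclass(config)
  cfg$proteinThreshold <- attr(primary, "threshold")
  cfg$riskFactorThreshold <- two$step1Threshold
  cfg$nProteins <- length(proteinStudies)
  cfg$nInstrumentable <-
    sum(vapply(attr(primary, "instrumentSets"),
               function(s) nrow(s@instruments) > 0, logical(1)))
  attr(primary, "instrumentSets") <- NULL
  attr(two$step1, "instrumentSets") <- NULL
  attr(two$step2, "instrumentSets") <- NULL
  new("ScreenReport", primary = primary, step1 = two$step1,
      step2 = two$step2, mediation = mediation, coloc = coloc,
      config = cfg)
}

## Reverse MR (mediator -> protein) for the bidirectionality flag; NULL when
## the mediator has no usable instruments in the protein study.
.reverseMR <- function(inp, riskFactorStudies, proteinStudies, ld, config) {
  med <- riskFactorStudies[[inp$mediatorId]]
  prot <- proteinStudies[[inp$exposureId]]
  if (is.null(med) || is.null(prot)) return(NULL)
  counts <- countProteinAssociations(riskFactorStudies,
                                     config$selection$pThreshold)
  iset <- tryCatch(selectInstruments(.studyTableOf(med), counts, ld,
                                     config$selection,
                                     exposureId = inp$mediatorId),
                   error = function(e) NULL)
  if (is.null(iset) || !nrow(iset@instruments)) return(NULL)
  h <- harmonize(iset, .studyTableOf(prot), outcomeId = inp$exposureId,
                 ld = ld, params = config$selection)
  if (nsnp(h) < 1) return(NULL)
  primaryEstimate(mrAuto(h, ivwMode = config$ivwMode,
                         nBoot = config$nBoot, seed = config$seed))
}

#' Write the screen report as tab-delimited tables plus a manifest
#'
#' Writes \code{primary.tsv}, \code{step1.tsv}, \code{step2.tsv},
#' \code{mediation.tsv}, \code{coloc.tsv} and \code{manifest.json}
#' (configuration, seed, resolved Bonferroni thresholds, package version)
#' into \code{outDir}. Re-running with identical inputs reproduces
#' byte-identical files.
#'
#' @param report a \code{\linkS4class{ScreenReport}}.
#' @param outDir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
writeReport <- function(report, outDir) {
  stopifnot(is(report, "ScreenReport"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  tabs <- list(primary = report@primary, step1 = report@step1,
               step2 = report@step2, mediation = report@mediation,
               coloc = report@coloc)
  paths <- character(0)
  for (nm in names(tabs)) {
    p <- file.path(outDir, paste0(nm, ".tsv"))
    df <- tabs[[nm]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) signif(v, 10))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- report@config
  manifest$package <- "protMR"
  manifest$version <-
    as.character(utils::packageVersion("protMR"))
  mp <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mp))
}
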