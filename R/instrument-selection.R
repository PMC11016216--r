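#' Instrument strength: variance explained and F-statistic
#'
#' Uses the standardized-trait approximation
#' \code{R2 = 2 maf (1 - maf) beta^2} with \code{maf = min(eaf, 1 - eaf)},
#' and \code{F = R2 (n - 2) / (1 - R2)}. An alternative z-score form
#' \code{R2 = z^2 / (z^2 + n)} is available via \code{method = "zscore"}.
#'
#' @param beta,se per-allele effect and standard error.
#' @param eaf effect-allele frequency in (0, 1).
#' @param n sample size (>= 3).
#' @param method \code{"standardized"} (default) or \code{"zscore"}.
#' @return list with \code{r2} and \code{f}.
#' @examples
#' computeInstrumentStrength(beta = 0.2, se = 0.02, eaf = 0.5, n = 3000)
#' @export
computeInstrumentStrength <- function(beta, se, eaf, n,
                                      method = c("standardized", "zscore")) {
  method <- match.arg(method)
  if (any(n < 3)) stop("invalid-argument: n must be >= 3")
  if (any(eaf <= 0 | eaf >= 1)) stop("invalid-argument: eaf must be in (0,1)")
  maf <- pmin(eaf, 1 - eaf)
  r2 <- if (method == "standardized") 2 * maf * (1 - maf) * beta^2
        else { z <- beta / se; z^2 / (z^2 + n) }
  r2 <- pmin(r2, 1 - 1e-12)
  list(r2 = r2, f = r2 * (n - 2) / (1 - r2))
}

#' Default instrument-selection parameters
#'
#' The four-rule pQTL selection procedure: genome-wide significance
#' (p <= 5e-8), MHC exclusion (chr6:26-34 Mb, GRCh37, 1-based inclusive),
#' greedy LD clumping at r2 < 0.001, exclusion of variants associated with
#' 5 or more proteins, plus the weak-instrument filter (F < 10) and the
#' proxy-lookup LD floor (r2 > 0.8).
#'
#' @param pThreshold significance cutoff.
#' @param mhcChrom,mhcStart,mhcEnd MHC exclusion window.
#' @param clumpR2 LD clumping cutoff (kept iff pairwise r2 < clumpR2).
#' @param maxProteinsPerSnp variants associated with more than this many
#'   proteins are excluded (default 4, i.e. excluded at >= 5).
#' @param minF weak-instrument cutoff.
#' @param proxyR2 minimum proxy LD (strict inequality).
#' @param r2Method how variance explained is computed; see
#'   \code{\link{computeInstrumentStrength}}.
#' @return a validated list of selection parameters.
#' @export
selectionParams <- function(pThreshold = 5e-8, mhcChrom = "6",
                            mhcStart = 26e6, mhcEnd = 34e6,
                            clumpR2 = 0.001, maxProteinsPerSnp = 4,
                            minF = 10, proxyR2 = 0.8,
                            r2Method = "standardized") {
  stopifnot(pThreshold > 0, pThreshold < 1, mhcStart < mhcEnd,
            clumpR2 >= 0, clumpR2 < 1, proxyR2 > 0, proxyR2 <= 1,
            maxProteinsPerSnp >= 1, minF >= 0)
  list(pThreshold = pThreshold, mhcChrom = as.character(mhcChrom),
       mhcStart = mhcStart, mhcEnd = mhcEnd, clumpR2 = clumpR2,
       maxProteinsPerSnp = maxProteinsPerSnp, minF = minF,
       proxyR2 = proxyR2, r2Method = r2Method)
}

#' Select MR instruments for one protein
#'
#' Applies, in order: (1) keep genome-wide significant variants
#' (p <= pThreshold); (2) drop variants inside the MHC window; (3) greedy LD
#' clumping — candidates sorted by ascending p-value, a variant is kept iff
#' its r2 with every already-kept variant is below \code{clumpR2}; (4) drop
#' variants associated with \code{maxProteinsPerSnp + 1} or more proteins;
#' finally drop weak instruments (F < \code{minF}). Every candidate's fate is
#' recorded in the provenance table.
#'
#' @param assocs data.frame of per-variant associations for one exposure
#'   (canonical summary-statistics columns).
#' @param crossProteinCounts named integer: for each variant id, the number
#'   of proteins it is associated with at the significance threshold.
#'   Variants absent from the map count as 1 (the exposure itself).
#' @param ld \code{\linkS4class{LDReference}} or list of them covering all
#'   candidates on their chromosomes; variants in different references are
#'   treated as unlinked.
#' @param params \code{\link{selectionParams}}.
#' @param exposureId exposure label for the returned set.
#' @return an \code{\linkS4class{InstrumentSet}}.
#' @export
selectInstruments <- function(assocs, crossProteinCounts = integer(0),
                              ld, params = selectionParams(),
                              exposureId = "exposure") {
  validateSumstats(assocs)
  prov <- data.frame(snp = assocs$snp, status = "kept", proxy_for = NA_character_,
                     stringsAsFactors = FALSE)
  mark <- function(sel, why) prov$status[sel & prov$status == "kept"] <<- why
  ## rule 1: significance
  mark(assocs$pval > params$pThreshold, "p_above_threshold")
  ## rule 2: MHC window (1-based inclusive)
  inMHC <- assocs$chr == params$mhcChrom &
    assocs$pos >= params$mhcStart & assocs$pos <= params$mhcEnd
  mark(inMHC, "mhc_region")
  ## rule 3: greedy clumping by ascending p among survivors
  alive <- which(prov$status == "kept")
  ord <- alive[order(assocs$pval[alive], assocs$snp[alive])]
  kept <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (j in kept) {
      r2 <- .ldR2(ld, assocs$snp[i], assocs$snp[j])
      if (r2 >= params$clumpR2) { conflict <- TRUE; break }
    }
    if (conflict) prov$status[i] <- "clumped" else kept <- c(kept, i)
  }
  ## rule 4: cross-protein pleiotropy
  if (length(crossProteinCounts)) {
    cnt <- crossProteinCounts[assocs$snp]
    cnt[is.na(cnt)] <- 1L
    mark(cnt > params$maxProteinsPerSnp, "pleiotropic_snp")
  }
  ## weak-instrument filter
  keep <- prov$status == "kept"
  st <- computeInstrumentStrength(assocs$beta, assocs$se, assocs$eaf,
                                  assocs$n, method = params$r2Method)
  mark(keep & st$f < params$minF, "weak_instrument")
  keep <- prov$status == "kept"
  idx <- which(keep)[order(assocs$pos[keep])]
  new("InstrumentSet", exposureId = exposureId,
      instruments = assocs[idx, , drop = FALSE],
      r2Explained = st$r2[idx], fStat = st$f[idx], provenance = prov)
}

#' Count cross-protein associations per variant
#'
#' Pools all supplied protein summary-statistics tables and counts, for each
#' variant, the number of distinct proteins it is associated with at the
#' selection significance threshold.
#'
#' @param proteinTables named list of summary-statistics data.frames (or
#'   \code{SimulatedStudy} objects), one per protein.
#' @param pThreshold significance cutoff.
#' @return named integer vector keyed by variant id.
#' @export
countProteinAssociations <- function(proteinTables, pThreshold = 5e-8) {
  hits <- lapply(proteinTables, function(x) {
    if (is(x, "SimulatedStudy")) x <- x@table
    unique(x$snp[x$pval <= pThreshold])
  })
  tab <- table(unlist(hits, use.names = FALSE))
  stats::setNames(as.integer(tab), names(tab))
}

#' Find an LD proxy for a missing variant
#'
#' Returns the available variant with maximal r2 to the target, subject to
#' r2 strictly above \code{params$proxyR2}; ties are broken by smaller
#' base-pair distance to the target, then by lexicographic id. The target
#' itself, if available, is its own proxy (r2 = 1).
#'
#' @param target variant id present in \code{ld}.
#' @param ld \code{\linkS4class{LDReference}} or list of them.
#' @param available character vector of variant ids present in the outcome
#'   study.
#' @param params \code{\link{selectionParams}}.
#' @return the proxy variant id, or \code{NA_character_} if none qualifies.
#' @export
findProxy <- function(target, ld, available, params = selectionParams()) {
  panel <- .ldPanel(ld)
  if (is.na(.ldFind(panel, target)))
    stop("invalid-argument: target '", target, "' absent from LD reference")
  if (!length(available)) return(NA_character_)
  available <- unique(as.character(available))
  r2 <- vapply(available, function(s) {
    v <- .ldR2(ld, target, s, error = FALSE)
    if (is.na(v)) 0 else v
  }, numeric(1))
  ok <- r2 > params$proxyR2
  if (!any(ok)) return(NA_character_)
  cand <- available[ok]
  r2 <- r2[ok]
  tpos <- .ldPosition(ld, target)
  dist <- abs(vapply(cand, function(s) .ldPosition(ld, s), numeric(1)) - tpos)
  ord <- order(-r2, dist, cand)
  cand[ord[1]]
}

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.complementAllele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

.isPalindromic <- function(ea, oa) {
  nchar(ea) == 1 & nchar(oa) == 1 & .complementAllele(ea) == oa
}

#' Harmonize instrument and outcome associations
#'
#' Aligns each instrument's outcome association to the exposure's effect
#' allele: direct matches are kept as-is; swapped alleles flip the outcome
#' effect sign (and complement the frequency); strand-complement matches are
#' complemented then aligned. Palindromic variants (A/T or C/G) are dropped
#' unconditionally, as are variants whose allele sets cannot be reconciled.
#' Instruments absent from the outcome table are resolved through
#' \code{\link{findProxy}} when an LD reference is supplied (the proxy's own
#' outcome association is used, unscaled), and dropped otherwise.
#'
#' @param instrumentSet an \code{\linkS4class{InstrumentSet}}.
#' @param outcomeTable data.frame of outcome associations (canonical
#'   columns).
#' @param outcomeId outcome label.
#' @param ld optional LD reference enabling proxy lookup.
#' @param params \code{\link{selectionParams}} (proxy threshold).
#' @return a \code{\linkS4class{HarmonizedData}}.
#' @export
harmonize <- function(instrumentSet, outcomeTable, outcomeId = "outcome",
                      ld = NULL, params = selectionParams()) {
  stopifnot(is(instrumentSet, "InstrumentSet"))
  validateSumstats(outcomeTable)
  ins <- instrumentSet@instruments
  if (anyDuplicated(ins$snp)) stop("malformed-input: duplicate snp ids")
  recs <- list()
  log <- data.frame(snp = character(0), action = character(0),
                    stringsAsFactors = FALSE)
  note <- function(snp, action)
    log <<- rbind(log, data.frame(snp = snp, action = action,
                                  stringsAsFactors = FALSE))
  for (i in seq_len(nrow(ins))) {
    x <- ins[i, ]
    if (.isPalindromic(x$ea, x$oa)) { note(x$snp, "dropped_palindromic"); next }
    j <- match(x$snp, outcomeTable$snp)
    used <- x$snp
    if (is.na(j) && !is.null(ld)) {
      proxy <- findProxy(x$snp, ld, outcomeTable$snp, params)
      if (!is.na(proxy)) { j <- match(proxy, outcomeTable$snp); used <- proxy }
    }
    if (is.na(j)) { note(x$snp, "dropped_missing_outcome"); next }
    y <- outcomeTable[j, ]
    if (.isPalindromic(y$ea, y$oa)) { note(x$snp, "dropped_palindromic"); next }
    xe <- toupper(x$ea); xo <- toupper(x$oa)
    ye <- toupper(y$ea); yo <- toupper(y$oa)
    if (used != x$snp) { xe <- ye; xo <- yo }   # proxy: take proxy orientation
    flip <- NA
    if (ye == xe && yo == xo) flip <- FALSE
    else if (ye == xo && yo == xe) flip <- TRUE
    else {
      yec <- .complementAllele(ye); yoc <- .complementAllele(yo)
      if (yec == xe && yoc == xo) flip <- FALSE
      else if (yec == xo && yoc == xe) flip <- TRUE
    }
    if (is.na(flip)) { note(x$snp, "dropped_ambiguous"); next }
    by <- if (flip) -y$beta else y$beta
    action <- if (used != x$snp) paste0("proxy:", used)
              else if (flip) "aligned_flipped" else "aligned"
    note(x$snp, action)
    recs[[length(recs) + 1L]] <-
      data.frame(snp = x$snp, bx = x$beta, bxse = x$se, by = by,
                 byse = y$se, stringsAsFactors = FALSE)
  }
  d <- if (length(recs)) do.call(rbind, recs)
       else data.frame(snp = character(0), bx = numeric(0),
                       bxse = numeric(0), by = numeric(0), byse = numeric(0))
  new("HarmonizedData", exposureId = instrumentSet@exposureId,
      outcomeId = outcomeId, snp = d$snp, bx = d$bx, bxse = d$bxse,
      by = d$by, byse = d$byse, log = log)
}

#' Construct a HarmonizedData object directly from aligned effect vectors
#'
#' Convenience constructor for already-aligned exposure/outcome pairs (used
#' heavily in simulation studies and tests).
#'
#' @param bx,bxse,by,byse aligned effect vectors.
#' @param snp optional variant ids.
#' @param exposureId,outcomeId labels.
#' @return a \code{\linkS4class{HarmonizedData}}.
#' @export
harmonizedData <- function(bx, bxse, by, byse,
                           snp = sprintf("v%d", seq_along(bx)),
                           exposureId = "exposure", outcomeId = "outcome") {
  new("HarmonizedData", exposureId = exposureId, outcomeId = outcomeId,
      snp = as.character(snp), bx = as.numeric(bx), bxse = as.numeric(bxse),
      by = as.numeric(by), byse = as.numeric(byse),
      log = data.frame(snp = character(0), action = character(0)))
}
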