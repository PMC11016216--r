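#' Ground-truth configuration for the synthetic GWAS generator
#'
#' Bundles and validates the generating parameters of the synthetic
#' summary-statistics studies: per-protein instrument architecture, sample
#' sizes, true causal effects on each outcome, and horizontal pleiotropy.
#' All traits are simulated in standardized (SD) units so that instrument
#' strength arithmetic is closed-form: a variant with per-allele effect b and
#' minor-allele frequency m explains R2 = 2 m (1 - m) b^2 of the exposure.
#'
#' @param nProteins number of protein exposures.
#' @param nVariantsPerProtein causal pQTLs per protein.
#' @param nExposure,nOutcome GWAS sample sizes (>= 10).
#' @param theta true causal effects, SD outcome per SD exposure: a single
#'   number (applied to every protein on outcome \code{"outcome"}), a named
#'   numeric vector over proteins, or a proteins x outcomes matrix with
#'   dimnames.
#' @param alpha per-variant horizontal-pleiotropy effect on the outcome (SD
#'   units), recycled over instruments; default 0.
#' @param mafRange range of minor-allele frequencies, within (0, 0.5].
#' @param instrumentR2 per-variant variance explained in the exposure: a
#'   single value in (0, 1) or a range to draw from uniformly.
#' @param gamma named numeric of direct variant-to-outcome effects (per
#'   allele), keyed by variant id; used to plant LD-confounded signals.
#' @param palindromicRate fraction of variants given strand-ambiguous (A/T or
#'   C/G) allele pairs, to exercise harmonization filters.
#' @param overlap fraction of shared noise between exposure and outcome
#'   samples; 0 (the default) is the two-sample design.
#' @param seed integer RNG seed.
#' @return a validated list of class \code{"TruthConfig"}.
#' @export
truthConfig <- function(nProteins = 1, nVariantsPerProtein = 10,
                        nExposure = 10000, nOutcome = 30000,
                        theta = 0, alpha = 0,
                        mafRange = c(0.05, 0.5),
                        instrumentR2 = c(0.005, 0.05),
                        gamma = numeric(0),
                        palindromicRate = 0.1, overlap = 0, seed = 1) {
  stopifnot(nProteins >= 1, nVariantsPerProtein >= 1,
            nExposure >= 10, nOutcome >= 10,
            length(mafRange) == 2, all(mafRange > 0), all(mafRange <= 0.5),
            mafRange[1] <= mafRange[2],
            all(instrumentR2 >= 0), all(instrumentR2 < 1),
            palindromicRate >= 0, palindromicRate <= 1,
            overlap >= 0, overlap <= 1)
  proteins <- paste0("prot", seq_len(nProteins))
  if (is.matrix(theta)) {
    if (is.null(rownames(theta)) || is.null(colnames(theta)))
      stop("theta matrix needs protein rownames and outcome colnames")
  } else {
    if (is.null(names(theta)) && length(theta) == 1)
      theta <- stats::setNames(rep(theta, nProteins), proteins)
    if (length(theta) != nProteins || is.null(names(theta)))
      stop("theta must be a scalar, a named vector over proteins, or a matrix")
    theta <- matrix(theta, ncol = 1,
                    dimnames = list(names(theta), "outcome"))
  }
  if (!all(is.finite(theta))) stop("theta entries must be finite")
  structure(list(nProteins = nProteins,
                 nVariantsPerProtein = nVariantsPerProtein,
                 nExposure = nExposure, nOutcome = nOutcome,
                 theta = theta, alpha = alpha, mafRange = mafRange,
                 instrumentR2 = instrumentR2, gamma = gamma,
                 palindromicRate = palindromicRate, overlap = overlap,
                 seed = as.integer(seed), proteins = rownames(theta)),
            class = "TruthConfig")
}

#' Simulate an LD reference with exponential distance decay
#'
#' Pairwise genotype correlation between variants at base-pair distance d is
#' \code{exp(-decay * d)}, so the stored squared correlation is
#' \code{exp(-decay * d)^2}. A single decay parameter gives dense, realistic
#' local LD for clumping, proxy lookup and colocalization while distant
#' variants become effectively independent.
#'
#' @param nVariants number of variants (>= 1).
#' @param decay per-bp correlation decay rate (>= 0); 0 gives perfect LD.
#' @param chromosome chromosome label.
#' @param start position of the first variant (1-based bp).
#' @param spacing distance between adjacent variants (bp).
#' @param seed integer seed (kept for interface symmetry; the kernel is
#'   deterministic).
#' @param prefix variant-id prefix.
#' @return an \code{\linkS4class{LDReference}}.
#' @examples
#' ld <- simulateLDReference(5, decay = 1e-5, spacing = 1e4)
#' ld@r2[1, 2]  # exp(-0.1)^2
#' @export
simulateLDReference <- function(nVariants, decay = 1e-5, chromosome = "1",
                                start = 1e6, spacing = 1e4, seed = 1,
                                prefix = paste0("rs", chromosome, "_")) {
  if (nVariants < 1) stop("invalid-argument: nVariants must be >= 1")
  if (decay < 0) stop("invalid-argument: decay must be >= 0")
  pos <- start + (seq_len(nVariants) - 1) * spacing
  d <- abs(outer(pos, pos, "-"))
  r2 <- exp(-decay * d)^2
  diag(r2) <- 1
  new("LDReference",
      variantIds = paste0(prefix, seq_len(nVariants)),
      r2 = r2, positions = pos, chromosome = chromosome)
}

## Deterministic sub-seed derivation (kept below 2^31).
.subSeed <- function(seed, tag) {
  (as.integer(seed) %% 100000L) * 20011L + sum(utf8ToInt(tag)) %% 20011L
}

## Allele pairs: non-palindromic transitions/transversions vs palindromic.
.ALLELE_OK  <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"),
                    c("A", "C"), c("C", "A"), c("G", "T"), c("T", "G"))
.ALLELE_PAL <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

.drawAlleles <- function(k, palindromicRate) {
  pal <- stats::runif(k) < palindromicRate
  pick <- ifelse(pal, sample.int(4L, k, replace = TRUE),
                 sample.int(8L, k, replace = TRUE))
  ea <- character(k); oa <- character(k)
  for (i in seq_len(k)) {
    pr <- if (pal[i]) .ALLELE_PAL[[pick[i]]] else .ALLELE_OK[[pick[i]]]
    ea[i] <- pr[1]; oa[i] <- pr[2]
  }
  list(ea = ea, oa = oa)
}

## Layout: which LDReference and which causal indices belong to protein i.
.proteinLayout <- function(truth, ld) {
  panel <- .ldPanel(ld)
  nP <- truth$nProteins
  k <- truth$nVariantsPerProtein
  if (length(panel) == nP) {
    lapply(seq_len(nP), function(i) {
      ref <- panel[[i]]
      nv <- length(ref@variantIds)
      if (nv < k) stop("LD reference ", i, " has fewer than ", k, " variants")
      ## causal pQTLs spread evenly across the region
      list(ref = ref, causal = unique(round(seq(1, nv, length.out = k))))
    })
  } else if (length(panel) == 1L) {
    ref <- panel[[1]]
    if (length(ref@variantIds) < nP * k)
      stop("shared LD reference too small for ", nP, " x ", k, " variants")
    lapply(seq_len(nP), function(i)
      list(ref = ref, causal = (i - 1L) * k + seq_len(k)))
  } else stop("ld must be one LDReference or one per protein")
}

## One study table over a reference's variants given true marginal betas.
.studyTable <- function(ref, trueBeta, maf, n, ea, oa, noiseZ) {
  se <- 1 / sqrt(2 * maf * (1 - maf) * n)
  beta <- trueBeta + noiseZ * se
  data.frame(snp = ref@variantIds, chr = ref@chromosome,
             pos = ref@positions, ea = ea, oa = oa, eaf = maf,
             beta = beta, se = se,
             pval = .pTwoSidedNormal(beta, se), n = n,
             stringsAsFactors = FALSE)
}

#' Simulate protein (exposure) GWAS summary statistics
#'
#' For each protein, draws causal per-allele effects so the configured
#' variance explained holds exactly (\code{b = sqrt(R2 / (2 maf (1 - maf)))},
#' oriented positive: the effect allele is the protein-raising allele),
#' propagates them to marginal effects through the LD correlation matrix, and
#' adds sampling noise with \code{se = 1 / sqrt(2 maf (1 - maf) nExposure)}.
#'
#' @param truth a \code{\link{truthConfig}}.
#' @param ld an \code{\linkS4class{LDReference}} shared by all proteins
#'   (causal variants assigned in disjoint blocks) or a list with one
#'   reference per protein.
#' @return named list of \code{\linkS4class{SimulatedStudy}}, one per
#'   protein. Each study's \code{truth} records the true marginal betas,
#'   causal indices, minor-allele frequencies and exposure noise (for
#'   optional sample-overlap coupling).
#' @export
simulateProteinGwas <- function(truth, ld) {
  stopifnot(inherits(truth, "TruthConfig"))
  layout <- .proteinLayout(truth, ld)
  set.seed(.subSeed(truth$seed, "exposure"))
  out <- vector("list", truth$nProteins)
  names(out) <- truth$proteins
  for (i in seq_len(truth$nProteins)) {
    ref <- layout[[i]]$ref
    causal <- layout[[i]]$causal
    nv <- length(ref@variantIds)
    maf <- stats::runif(nv, truth$mafRange[1], truth$mafRange[2])
    r2v <- if (length(truth$instrumentR2) == 2)
      stats::runif(length(causal), truth$instrumentR2[1],
                   truth$instrumentR2[2])
    else rep(truth$instrumentR2, length(causal))
    bCausal <- numeric(nv)
    bCausal[causal] <- sqrt(r2v / (2 * maf[causal] * (1 - maf[causal])))
    ## per-allele effects propagate through LD on the standardized-genotype
    ## scale: beta_j = sum_k r_jk sqrt(2 p_k q_k / 2 p_j q_j) beta_k
    R <- sqrt(ref@r2)                      # non-negative correlations
    d <- sqrt(2 * maf * (1 - maf))
    trueBeta <- as.numeric(R %*% (d * bCausal)) / d
    al <- .drawAlleles(nv, truth$palindromicRate)
    noiseZ <- stats::rnorm(nv)
    tab <- .studyTable(ref, trueBeta, maf, truth$nExposure,
                       al$ea, al$oa, noiseZ)
    out[[i]] <- new("SimulatedStudy", traitId = truth$proteins[i],
                    table = tab,
                    truth = list(trueBeta = trueBeta, causal = causal,
                                 maf = maf, noiseZ = noiseZ,
                                 instrumentR2 = r2v, ld = ref,
                                 config = truth))
  }
  out
}

#' Simulate an outcome GWAS downstream of one exposure
#'
#' Two-sample data model: the outcome's true marginal effect at variant j is
#' \code{theta * bx_true_j + alpha_j} (alpha is horizontal pleiotropy acting
#' directly on the outcome), observed with noise independent of the
#' exposure study and standard error
#' \code{1 / sqrt(2 maf (1 - maf) nOutcome)} (standardized outcome,
#' per-allele scale, matching the exposure convention). The outcome table
#' covers the same variants as the exposure study.
#'
#' @param truth a \code{\link{truthConfig}}; \code{truth$theta} must contain
#'   a \code{(protein, traitId)} entry.
#' @param exposureStudy a \code{\linkS4class{SimulatedStudy}} from
#'   \code{\link{simulateProteinGwas}}.
#' @param traitId outcome label (column of \code{truth$theta}).
#' @return a \code{\linkS4class{SimulatedStudy}} for the outcome.
#' @export
simulateDownstreamGwas <- function(truth, exposureStudy, traitId = "outcome") {
  stopifnot(inherits(truth, "TruthConfig"),
            is(exposureStudy, "SimulatedStudy"))
  if (!traitId %in% colnames(truth$theta))
    stop("invalid-argument: unknown trait '", traitId, "' in theta map")
  prot <- exposureStudy@traitId
  if (!prot %in% rownames(truth$theta))
    stop("invalid-argument: unknown protein '", prot, "' in theta map")
  set.seed(.subSeed(truth$seed, paste0("outcome:", prot, ":", traitId)))
  th <- truth$theta[prot, traitId]
  st <- exposureStudy@truth
  tab <- exposureStudy@table
  nv <- nrow(tab)
  alpha <- rep_len(truth$alpha, nv)
  byTrue <- th * st$trueBeta + alpha
  ## planted direct variant effects (LD-confounding), propagated through
  ## the exposure study's LD structure: marginal contribution = R gamma
  d <- sqrt(2 * st$maf * (1 - st$maf))
  if (length(truth$gamma) && !is.null(st$ld)) {
    hit <- intersect(names(truth$gamma), tab$snp)
    if (length(hit)) {
      g <- numeric(nv)
      g[match(hit, tab$snp)] <- truth$gamma[hit]
      byTrue <- byTrue + as.numeric(sqrt(st$ld@r2) %*% (d * g)) / d
    }
  }
  seOut <- 1 / sqrt(2 * st$maf * (1 - st$maf) * truth$nOutcome)
  z <- stats::rnorm(nv)
  if (truth$overlap > 0)
    z <- sqrt(1 - truth$overlap) * z + sqrt(truth$overlap) * st$noiseZ
  beta <- byTrue + z * seOut
  out <- tab
  out$beta <- beta
  out$se <- seOut
  out$pval <- .pTwoSidedNormal(beta, seOut)
  out$n <- truth$nOutcome
  new("SimulatedStudy", traitId = traitId, table = out,
      truth = list(trueBeta = byTrue, theta = th, exposure = prot,
                   maf = st$maf, config = truth))
}

#' Simulate an outcome GWAS aggregating several protein exposures
#'
#' Generalizes \code{\link{simulateDownstreamGwas}} to many proteins: each
#' protein region (disjoint variant sets, e.g. one synthetic chromosome per
#' protein) contributes \code{theta_p * bx_true} on its own variants, and the
#' pieces are concatenated into one genome-wide outcome table.
#'
#' @param truth a \code{\link{truthConfig}}.
#' @param exposureStudies list of studies from
#'   \code{\link{simulateProteinGwas}}.
#' @param traitId outcome label.
#' @return a \code{\linkS4class{SimulatedStudy}}.
#' @export
simulateOutcomeGwas <- function(truth, exposureStudies, traitId = "outcome") {
  pieces <- lapply(exposureStudies, function(st)
    simulateDownstreamGwas(truth, st, traitId))
  tab <- do.call(rbind, c(lapply(pieces, slot, "table"),
                          list(make.row.names = FALSE)))
  trueBeta <- unlist(lapply(pieces, function(p) p@truth$trueBeta),
                     use.names = FALSE)
  maf <- unlist(lapply(pieces, function(p) p@truth$maf), use.names = FALSE)
  if (anyDuplicated(tab$snp))
    stop("exposure studies must cover disjoint variants")
  new("SimulatedStudy", traitId = traitId, table = tab,
      truth = list(trueBeta = trueBeta, maf = maf, config = truth))
}

#' Simulate a colocalization test region under a known hypothesis
#'
#' Builds a pair of regional association tables over one LD reference under
#' one of the five single-causal-variant hypotheses: H0 no signal, H1/H2 a
#' causal variant for one trait only, H3 two distinct causal variants
#' (maximally separated, hence near-zero LD under the decay kernel), H4 one
#' shared causal variant. Marginal per-allele effects propagate through the
#' signed LD correlations on the standardized-genotype scale
#' (\code{beta_j = sum_k r_jk sqrt(2 p_k q_k / 2 p_j q_j) beta_k});
#' observed effects add independent noise with
#' \code{se = 1 / sqrt(2 maf (1 - maf) n)}.
#'
#' @param scenario one of \code{"H0","H1","H2","H3","H4"}.
#' @param ld an \code{\linkS4class{LDReference}} (>= 2 variants for H3).
#' @param n1,n2 sample sizes of the two studies.
#' @param effectSd per-allele effect size of each causal variant.
#' @param seed integer seed.
#' @param mafRange minor-allele frequency range.
#' @return list with \code{region1}, \code{region2}
#'   (\code{\linkS4class{RegionalSummary}}) and \code{truth} (scenario label
#'   and causal variant ids).
#' @export
simulateColocRegion <- function(scenario, ld, n1 = 20000, n2 = 20000,
                                effectSd = 0.1, seed = 1,
                                mafRange = c(0.05, 0.5)) {
  scenario <- match.arg(scenario, c("H0", "H1", "H2", "H3", "H4"))
  stopifnot(is(ld, "LDReference"))
  nv <- length(ld@variantIds)
  if (scenario == "H3" && nv < 2)
    stop("invalid-argument: H3 requires at least 2 variants")
  set.seed(.subSeed(seed, paste0("coloc:", scenario)))
  maf <- stats::runif(nv, mafRange[1], mafRange[2])
  R <- sqrt(ld@r2)
  mid <- (nv + 1L) %/% 2L
  c1 <- switch(scenario, H0 = integer(0), H1 = mid, H2 = integer(0),
               H3 = 1L, H4 = mid)
  c2 <- switch(scenario, H0 = integer(0), H1 = integer(0), H2 = mid,
               H3 = nv, H4 = mid)
  d <- sqrt(2 * maf * (1 - maf))
  mkRegion <- function(causal, n, tag) {
    b <- numeric(nv); b[causal] <- effectSd
    true <- as.numeric(R %*% (d * b)) / d
    se <- 1 / sqrt(2 * maf * (1 - maf) * n)
    beta <- true + stats::rnorm(nv) * se
    new("RegionalSummary", traitId = tag, variants = ld@variantIds,
        beta = beta, se = se, maf = maf, n = n, sdTrait = 1)
  }
  list(region1 = mkRegion(c1, n1, "trait1"),
       region2 = mkRegion(c2, n2, "trait2"),
       truth = list(scenario = scenario,
                    causal1 = ld@variantIds[c1],
                    causal2 = ld@variantIds[c2]))
}
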