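## Internal numerical helpers shared across modules.

## Two-sided normal tail of z = beta / se, floored away from exact 0 so the
## (0, 1] p-value invariant holds even for astronomically large |z|.
.pTwoSidedNormal <- function(beta, se) {
  p <- 2 * stats::pnorm(-abs(beta / se))
  pmax(p, .Machine$double.xmin)
}

.logSumExp <- function(x) {
  x <- x[is.finite(x) | x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Normal-theory MRResult constructor used by every estimator.
.mrResult <- function(method, beta, se, nsnp, extra = list()) {
  new("MRResult", method = method, beta = beta, se = se,
      ciLow = beta - 1.96 * se, ciHigh = beta + 1.96 * se,
      pval = .pTwoSidedNormal(beta, se), nsnp = as.integer(nsnp),
      extra = extra)
}

## Squared LD between two variants, searched over one LDReference or a list
## of them (an LD "panel"). Variants on different chromosomes (i.e. found in
## different references) have r2 = 0; a variant found in no reference is a
## missing-ld error when error = TRUE, else NA.
.ldPanel <- function(ld) if (is(ld, "LDReference")) list(ld) else ld

.ldFind <- function(panel, snp) {
  for (i in seq_along(panel))
    if (snp %in% panel[[i]]@variantIds) return(i)
  NA_integer_
}

.ldR2 <- function(ld, snp1, snp2, error = TRUE) {
  panel <- .ldPanel(ld)
  i1 <- .ldFind(panel, snp1)
  i2 <- .ldFind(panel, snp2)
  if (is.na(i1) || is.na(i2)) {
    if (error) stop("missing-ld: variant absent from LD reference: ",
                    if (is.na(i1)) snp1 else snp2)
    return(NA_real_)
  }
  if (i1 != i2) return(0)
  ref <- panel[[i1]]
  ref@r2[match(snp1, ref@variantIds), match(snp2, ref@variantIds)]
}

## Pairwise r2 matrix among a set of variants (0 across chromosomes).
.ldR2Matrix <- function(ld, snps) {
  panel <- .ldPanel(ld)
  k <- length(snps)
  out <- matrix(0, k, k, dimnames = list(snps, snps))
  diag(out) <- 1
  idx <- vapply(snps, function(s) .ldFind(panel, s), integer(1))
  if (anyNA(idx))
    stop("missing-ld: variant absent from LD reference: ",
         paste(snps[is.na(idx)], collapse = ", "))
  for (ref_i in unique(idx)) {
    sel <- which(idx == ref_i)
    if (length(sel) < 2) next
    ref <- panel[[ref_i]]
    m <- match(snps[sel], ref@variantIds)
    out[sel, sel] <- ref@r2[m, m]
  }
  out
}

## Base-pair position of a variant within an LD panel (NA if absent).
.ldPosition <- function(ld, snp) {
  panel <- .ldPanel(ld)
  i <- .ldFind(panel, snp)
  if (is.na(i)) return(NA_real_)
  ref <- panel[[i]]
  ref@positions[match(snp, ref@variantIds)]
}
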