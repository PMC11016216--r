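#' Read and write GWAS summary-statistics tables
#'
#' Tab-delimited text with the canonical header
#' \code{snp chr pos ea oa eaf beta se pval n}.
#'
#' @param x data.frame (or \code{SimulatedStudy}) to write.
#' @param path file path.
#' @return \code{readSumstats} returns a validated data.frame;
#'   \code{writeSumstats} returns \code{path} invisibly.
#' @export
writeSumstats <- function(x, path) {
  if (is(x, "SimulatedStudy")) x <- x@table
  validateSumstats(x)
  utils::write.table(x[, .SUMSTAT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeSumstats
#' @export
readSumstats <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(snp = "character",
                                        chr = "character", ea = "character",
                                        oa = "character"))
  validateSumstats(x)
  x
}

#' Read and write an LD reference
#'
#' The r-squared matrix is written as a square tab-delimited table and the
#' variant index (id, chromosome, position) as a companion
#' \code{<path>.index} file.
#'
#' @param ld an \code{\linkS4class{LDReference}}.
#' @param path file path for the matrix.
#' @return \code{readLDReference} returns an \code{LDReference};
#'   \code{writeLDReference} returns \code{path} invisibly.
#' @export
writeLDReference <- function(ld, path) {
  stopifnot(is(ld, "LDReference"))
  m <- ld@r2
  dimnames(m) <- list(ld@variantIds, ld@variantIds)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  idx <- data.frame(snp = ld@variantIds, chr = ld@chromosome,
                    pos = ld@positions)
  utils::write.table(idx, paste0(path, ".index"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLDReference
#' @export
readLDReference <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  ## symmetrize away text round-trip noise
  m <- (m + t(m)) / 2
  diag(m) <- 1
  idx <- utils::read.table(paste0(path, ".index"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE,
                           colClasses = c(snp = "character",
                                          chr = "character"))
  new("LDReference", variantIds = idx$snp, r2 = unname(m),
      positions = idx$pos, chromosome = unique(idx$chr))
}
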