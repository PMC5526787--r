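#' @importFrom methods new validObject is slot
#' @importFrom stats lm coef median quantile rnorm runif setNames
#' @importFrom utils read.delim write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importMethodsFrom SummarizedExperiment assay assayNames colData rowData
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES4 <- c("A", "C", "G", "T")

#' Reverse complement of a plain character DNA string
#' @param x character vector of DNA strings (ACGTN).
#' @return character vector of reverse complements.
#' @keywords internal
revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC fraction of a DNA string
#' @param x character vector of DNA strings.
#' @return numeric in \[0, 1\].
#' @keywords internal
gcFraction <- function(x) {
  vapply(strsplit(toupper(x), ""), function(ch) {
    n <- sum(ch %in% DNA_BASES4)
    if (n == 0L) return(NA_real_)
    sum(ch %in% c("G", "C")) / n
  }, numeric(1))
}

#' Midpoint percentile ranks with average ties
#'
#' Percentile of value i among n values is `100 * (rank_i - 0.5) / n` with
#' ties receiving their average rank, so five distinct values map to
#' 10, 30, 50, 70, 90 and an all-tied vector maps to 50 everywhere.
#'
#' @param x numeric vector.
#' @return numeric vector of percentiles in \[0, 100\].
#' @export
percentileRank <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  100 * (rank(x, ties.method = "average") - 0.5) / n
}

#' Read a tab-separated table
#' @param path file path.
#' @return data.frame, no factor conversion.
#' @keywords internal
readTsv <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a tab-separated table
#' @param x data.frame.
#' @param path file path.
#' @keywords internal
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

## deterministic sub-seed derivation: keeps derived seeds inside 32-bit range
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset) %% 2147483647)
}
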