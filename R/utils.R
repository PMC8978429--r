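# Internal helpers shared across modules.

#' @importFrom data.table data.table as.data.table setDT setkey := .N .SD
#' @importFrom stats sd prcomp pnorm rnbinom rpois runif chisq.test p.adjust
#' @importFrom utils write.table read.table packageVersion
#' @importFrom methods is
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "chrom", "start", "end", "strand", "sequence", "copy_count",
  "n_hits", "length_nt", "read_id", "island", "cluster_id", "five_prime"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement DNA strings
#'
#' Thin wrapper over Biostrings for character vectors.
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

geometric_mean <- function(x) exp(mean(log(x)))

# Deterministic small-integer stream seed for (master seed, label),
# kept below 2^31 so it is a valid R integer.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
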