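#' Round half-up to a fixed number of decimals
#'
#' Report tables round percentages half-up (so 20.95 -> 21.0), matching the
#' usual presentation of genome summary tables, rather than using R's
#' round-half-to-even.
#'
#' @param x numeric vector
#' @param digits decimal places to keep
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a total
#'
#' @param numerator,denominator counts
#' @param digits decimal places (half-up)
#' @return `100 * numerator / denominator`, rounded half-up
#' @export
fraction_pct <- function(numerator, denominator, digits = 1) {
  round_half_up(100 * numerator / denominator, digits)
}

#' Genes per megabase
#'
#' @param n_genes gene count
#' @param genome_size_mb genome size in Mb (non-mitochondrial bases / 1e6)
#' @return genes per Mb (unrounded)
#' @export
genes_per_mb <- function(n_genes, genome_size_mb) {
  n_genes / genome_size_mb
}

#' Reverse complement of DNA strings
#'
#' Vectorised; `N` is preserved.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N)
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# integer encoding A=1 C=2 G=3 T=4, anything else (N) -> NA
.encode_dna <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
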