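#' Promoter-level motif co-occurrence enrichment
#'
#' Presence/absence co-occurrence of two motifs over a promoter set: given
#' the sets of promoters carrying at least one hit of each motif, computes
#' the expected number carrying both under independence
#' (`n_a * n_b / n`), the observed/expected ratio, and the exact
#' hypergeometric upper-tail probability of seeing at least the observed
#' overlap (drawing `n_b` promoters from `n` of which `n_a` are marked).
#' A seeded permutation mode is available as a cross-check of the
#' marginal-product null.
#'
#' @param promoters_a,promoters_b promoter-id vectors (promoters with >= 1
#'   hit of each motif); duplicates are collapsed
#' @param n total number of promoters tested
#' @param motif_a,motif_b motif names for the report
#' @param method `"hypergeometric"` (exact, default) or `"permutation"`
#' @param n_perm permutation count for `method = "permutation"`
#' @return one-row data.frame `motif_a`, `motif_b`, `n`, `n_a`, `n_b`,
#'   `n_both`, `expected_both`, `ratio`, `p_value`
#' @export
cooccurrence <- function(promoters_a, promoters_b, n,
                         motif_a = "motif_a", motif_b = "motif_b",
                         method = c("hypergeometric", "permutation"),
                         n_perm = 1000L) {
  method <- match.arg(method)
  if (n == 0) .stopf("n = 0 promoters tested")
  a <- unique(promoters_a)
  b <- unique(promoters_b)
  n_a <- length(a)
  n_b <- length(b)
  if (n < max(n_a, n_b)) .stopf("n smaller than a hit set")
  n_both <- length(intersect(a, b))
  expected <- n_a * n_b / n
  ratio <- if (expected == 0) {
    if (n_both > 0) Inf else NA_real_
  } else {
    n_both / expected
  }
  p <- if (method == "hypergeometric") {
    stats::phyper(n_both - 1, n_a, n - n_a, n_b, lower.tail = FALSE)
  } else {
    marked <- c(rep(TRUE, n_a), rep(FALSE, n - n_a))
    exceed <- vapply(seq_len(n_perm), function(i)
      sum(marked[sample.int(n, n_b)]) >= n_both, logical(1))
    (1 + sum(exceed)) / (n_perm + 1)
  }
  data.frame(
    motif_a = motif_a, motif_b = motif_b,
    n = n, n_a = n_a, n_b = n_b, n_both = n_both,
    expected_both = expected, ratio = ratio, p_value = p,
    stringsAsFactors = FALSE
  )
}

#' All pairwise co-occurrence results for a motif hit list
#'
#' @param hit_sets named list of promoter-id vectors, one per motif
#' @param n total number of promoters tested
#' @param ... passed to [cooccurrence()]
#' @return data.frame of all unordered motif pairs
#' @export
cooccurrence_table <- function(hit_sets, n, ...) {
  nm <- names(hit_sets)
  stopifnot(length(nm) >= 2)
  combos <- utils::combn(nm, 2)
  do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
    cooccurrence(hit_sets[[combos[1, k]]], hit_sets[[combos[2, k]]], n,
                 motif_a = combos[1, k], motif_b = combos[2, k], ...)
  }))
}
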