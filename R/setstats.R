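#' Hypergeometric upper-tail overlap test
#'
#' Probability of observing at least `n_overlap` common elements between two
#' sets of sizes `n_a` and `n_b` drawn without replacement from a universe
#' of `n_universe` genes: `P[X >= n_overlap]` with
#' `X ~ Hypergeometric(n_universe, n_a, n_b)`.  Computed through
#' [stats::phyper()], which works in log space and is numerically stable
#' across the support.
#'
#' @param n_universe universe size.
#' @param n_a,n_b set sizes.
#' @param n_overlap observed intersection size.
#' @return upper-tail p-value in (0, 1].
#' @export
hypergeom_upper_tail <- function(n_universe, n_a, n_b, n_overlap) {
  for (v in list(n_universe, n_a, n_b, n_overlap)) {
    if (!.is_count(v)) .stopf("all arguments must be non-negative integers")
  }
  if (n_a > n_universe || n_b > n_universe) {
    .stopf("set sizes cannot exceed the universe size")
  }
  if (n_overlap > min(n_a, n_b)) {
    .stopf("n_overlap (%d) exceeds min(n_a, n_b) = %d",
           n_overlap, min(n_a, n_b))
  }
  if (n_overlap < n_a + n_b - n_universe) {
    .stopf("n_overlap (%d) below the minimum possible overlap %d",
           n_overlap, n_a + n_b - n_universe)
  }
  if (n_overlap == 0) return(1)
  stats::phyper(n_overlap - 1, n_a, n_universe - n_a, n_b, lower.tail = FALSE)
}

.overlap_record <- function(n_universe, n_a, n_b, n_overlap) {
  data.frame(n_universe = n_universe, n_a = n_a, n_b = n_b,
             n_overlap = n_overlap,
             pct_of_a = if (n_a > 0) 100 * n_overlap / n_a else NA_real_,
             pct_of_b = if (n_b > 0) 100 * n_overlap / n_b else NA_real_,
             pct_of_a_int = if (n_a > 0) floor(100 * n_overlap / n_a) else NA_real_,
             pct_of_b_int = if (n_b > 0) floor(100 * n_overlap / n_b) else NA_real_,
             p_value = hypergeom_upper_tail(n_universe, n_a, n_b, n_overlap))
}

#' Overlap summary between two gene sets
#'
#' Counts, percentage of each set covered by the intersection (unrounded,
#' and as the integer form used in "about NN%" reporting, which truncates:
#' 81.6% is reported as 81%), and the
#' hypergeometric upper-tail p-value.  The universe defaults to the gene
#' complement of the supplied annotation; its size may be overridden when
#' the true background is known to differ.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param universe character vector of gene ids, or an [annotation_set()].
#' @param n_universe optional universe size overriding `length(universe)`.
#' @return one-row data.frame with columns `n_universe`, `n_a`, `n_b`,
#'   `n_overlap`, `pct_of_a`, `pct_of_b`, `pct_of_a_int`, `pct_of_b_int`,
#'   `p_value`.
#' @export
overlap_summary <- function(set_a, set_b, universe, n_universe = NULL) {
  if (inherits(universe, "annotation_set")) universe <- universe$genes$gene_id
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  universe <- unique(as.character(universe))
  outside <- setdiff(union(set_a, set_b), universe)
  if (length(outside)) {
    .stopf("gene id(s) outside the universe: %s",
           paste(utils::head(outside, 10L), collapse = ", "))
  }
  .overlap_record(n_universe %||% length(universe),
                  length(set_a), length(set_b),
                  length(intersect(set_a, set_b)))
}

#' Overlap summary from printed counts
#'
#' Same record as [overlap_summary()] but starting from the four counts
#' directly, for re-deriving percentages and p-values reported for set
#' sizes whose membership is not available.
#'
#' @inheritParams hypergeom_upper_tail
#' @return one-row data.frame, see [overlap_summary()].
#' @export
overlap_from_counts <- function(n_universe, n_a, n_b, n_overlap) {
  rec <- .overlap_record(n_universe, n_a, n_b, n_overlap)
  rec
}
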