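#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a superposition result
#'
#' One row per result: the final Tanimoto and overlap, the start family and
#' index that won, and optimiser diagnostics.
#'
#' @param x A `superposition_result` from [optimize_overlap()] or
#'   [pair_tanimoto()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy superposition_result
#' @export
tidy.superposition_result <- function(x, ...) {
  tibble::tibble(
    tanimoto = x$tanimoto,
    overlap = x$overlap,
    start_family = x$start_family,
    start_index = x$start_index,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' @rdname tidy.superposition_result
#' @method glance superposition_result
#' @export
glance.superposition_result <- function(x, ...) {
  tibble::tibble(tanimoto = x$tanimoto, converged = x$converged,
                 iterations = x$iterations)
}

#' Summarise a shape-match table
#'
#' @param x A `shape_match_table` from [all_vs_all_match()].
#' @param ... Unused.
#' @return One-row tibble with the pair count and Tanimoto summary.
#' @method glance shape_match_table
#' @export
glance.shape_match_table <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    max_tanimoto = if (nrow(x)) max(x$tanimoto) else NA_real_,
    median_tanimoto = if (nrow(x)) stats::median(x$tanimoto) else NA_real_
  )
}
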