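#' All-vs-all shape matching over a ligand set
#'
#' Evaluates every unordered pair of ligands once with the symmetrised
#' ensemble protocol ([ligand_pair_tanimoto()]) and retains pairs whose
#' final Tanimoto is strictly greater than the reporting threshold.
#' Self-pairs are excluded; output rows are sorted by descending Tanimoto,
#' then lexicographically by ids, so repeated runs with the same seed are
#' byte-identical. Pairs are independent work units: any evaluation order
#' gives the same table.
#'
#' @param ligands List of [new_ligand()] objects with distinct `ligand_id`s.
#' @param threshold Reporting threshold (strict `>`), default 0.85.
#' @param settings A [shape_settings()].
#' @return Tibble of class `shape_match_table` with columns `query_id`,
#'   `db_id`, `tanimoto`, `best_conformer_index`, `best_start_family`,
#'   `direction`.
#' @examples
#' \donttest{
#' ligs <- list(make_toy_ligand("ring", 6, id = "R6"),
#'              make_toy_ligand("linear", 4, id = "L4"))
#' all_vs_all_match(ligs, threshold = 0.5)
#' }
#' @export
all_vs_all_match <- function(ligands, threshold = 0.85,
                             settings = shape_settings()) {
  stopifnot(is.list(ligands), length(ligands) >= 2)
  ids <- vapply(ligands, function(l) l$ligand_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate ligand_ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  pairs <- utils::combn(length(ligands), 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(ij) {
    ligand_pair_tanimoto(ligands[[ij[1]]], ligands[[ij[2]]], settings)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::filter(out, .data$tanimoto > threshold)
  out <- dplyr::arrange(out, dplyr::desc(.data$tanimoto), .data$query_id,
                        .data$db_id)
  class(out) <- c("shape_match_table", class(out))
  out
}
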