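#' Final Tanimoto for a pair of rigid conformers
#'
#' The full multi-start protocol for one query pose against one database
#' conformer. Local overlap maximisation is run from three start families:
#'
#' 1. the center-of-mass alignment (one start),
#' 2. random placements of the query center of mass over the database
#'    molecule's atoms (default 8, seeded), and
#' 3. the four principal-axes alignments.
#'
#' The maximum Tanimoto over all starts is the final coefficient for the
#' pair, labelled by the start family and index that produced it. Conformers
#' stay rigid throughout; only the six rigid-body degrees of freedom are
#' optimised.
#'
#' @param query_pose Conformer (atom data frame) supplying the fixed query
#'   pose.
#' @param db_conformer Conformer of the database ligand.
#' @param settings A [shape_settings()].
#' @return A `superposition_result` (see [optimize_overlap()]) with
#'   `start_family` and `start_index` filled in.
#' @export
pair_tanimoto <- function(query_pose, db_conformer,
                          settings = shape_settings()) {
  qs <- build_shape(query_pose, radii = settings$radii,
                    include_hydrogens = settings$include_hydrogens)
  ds <- build_shape(db_conformer, radii = settings$radii,
                    include_hydrogens = settings$include_hydrogens)
  starts <- c(
    list(list(family = "com", index = 1L,
              transform = com_align(qs, ds))),
    purrr::imap(generate_starts(qs, ds, "random",
                                n = settings$n_random_starts,
                                seed = settings$seed),
                function(tr, i) list(family = "random", index = i,
                                     transform = tr)),
    purrr::imap(generate_starts(qs, ds, "inertial"),
                function(tr, i) list(family = "inertial", index = i,
                                     transform = tr))
  )
  best <- NULL
  for (st in starts) {
    res <- optimize_overlap(qs, ds, start = st$transform, settings = settings)
    res$start_family <- st$family
    res$start_index <- as.integer(st$index)
    if (is.null(best) || res$tanimoto > best$tanimoto) best <- res
  }
  best
}

#' Best Tanimoto of a query pose against a conformer ensemble
#'
#' Runs [pair_tanimoto()] for the query pose against every conformer of the
#' database ligand (up to the configured cap, truncating in input order) and
#' reports the maximum, recording which conformer achieved it. With a
#' single-conformer ensemble this reduces exactly to [pair_tanimoto()].
#'
#' @param query_pose Conformer supplying the fixed query pose.
#' @param db_ligand A [new_ligand()] object whose conformer ensemble is
#'   searched.
#' @param settings A [shape_settings()].
#' @param query_id Identifier recorded for the query side.
#' @return One-row tibble (class `shape_match`) with columns `query_id`,
#'   `db_id`, `tanimoto`, `best_conformer_index`, `best_start_family`,
#'   `direction`.
#' @export
ensemble_tanimoto <- function(query_pose, db_ligand,
                              settings = shape_settings(),
                              query_id = "query") {
  stopifnot(inherits(db_ligand, "ligand"))
  confs <- db_ligand$conformers
  if (length(confs) == 0) stop("empty conformer ensemble")
  if (length(confs) > settings$max_conformers) {
    confs <- confs[seq_len(settings$max_conformers)]
  }
  best <- NULL
  best_i <- NA_integer_
  for (i in seq_along(confs)) {
    res <- pair_tanimoto(query_pose, confs[[i]], settings)
    if (is.null(best) || res$tanimoto > best$tanimoto) {
      best <- res
      best_i <- i
    }
  }
  out <- tibble::tibble(
    query_id = query_id,
    db_id = db_ligand$ligand_id,
    tanimoto = best$tanimoto,
    best_conformer_index = best_i,
    best_start_family = best$start_family,
    direction = paste0(query_id, "->", db_ligand$ligand_id)
  )
  class(out) <- c("shape_match", class(out))
  out
}

#' Symmetrised ensemble Tanimoto for a ligand pair
#'
#' Evaluates both directions -- the pose of `a` (its first conformer)
#' against the ensemble of `b`, and the pose of `b` against the ensemble of
#' `a` -- and returns the better match. A single symmetric number per
#' unordered pair is what a database reports.
#'
#' @param a,b [new_ligand()] objects.
#' @param settings A [shape_settings()].
#' @return One-row `shape_match` tibble.
#' @export
ligand_pair_tanimoto <- function(a, b, settings = shape_settings()) {
  fwd <- ensemble_tanimoto(a$conformers[[1]], b, settings, query_id = a$ligand_id)
  rev <- ensemble_tanimoto(b$conformers[[1]], a, settings, query_id = b$ligand_id)
  if (fwd$tanimoto >= rev$tanimoto) fwd else rev
}
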