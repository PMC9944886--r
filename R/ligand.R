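#' Ligand and conformer containers
#'
#' A conformer is a tibble of atoms (columns `element`, `x`, `y`, `z`,
#' `is_heavy`) carrying a `source_label` attribute, e.g. `"pdb_pose"` or
#' `"generated_3"`. A ligand bundles one or more conformers of the same
#' molecule under a `ligand_id`; all conformers must share the element
#' composition and atom order (conformers are alternative rigid geometries
#' of one molecule, not different molecules).
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` (an
#'   `is_heavy` column is derived if absent).
#' @param source_label Text label recording where the geometry came from.
#' @return `conformer()`: a tibble of class `conformer`;
#'   `new_ligand()`: an object of class `ligand`.
#' @export
conformer <- function(atoms, source_label = "pose") {
  stopifnot(is.data.frame(atoms),
            all(c("element", "x", "y", "z") %in% names(atoms)))
  atoms <- tibble::as_tibble(atoms)
  if (nrow(atoms) == 0) stop("conformer must contain at least one atom")
  atoms$element <- as.character(atoms$element)
  if (any(!nzchar(atoms$element))) stop("empty element symbol in conformer")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite coordinates in conformer")
  }
  if (!"is_heavy" %in% names(atoms)) atoms$is_heavy <- atoms$element != "H"
  attr(atoms, "source_label") <- source_label
  class(atoms) <- c("conformer", class(atoms))
  atoms
}

#' @rdname conformer
#' @param ligand_id Identifier text (e.g. a HET code).
#' @param conformers List of conformers (tibbles of atoms).
#' @export
new_ligand <- function(ligand_id, conformers) {
  stopifnot(is.character(ligand_id), length(ligand_id) == 1, nzchar(ligand_id))
  if (!is.list(conformers) || length(conformers) == 0) {
    stop("ligand '", ligand_id, "' needs at least one conformer")
  }
  conformers <- lapply(conformers, function(cf) {
    if (inherits(cf, "conformer")) cf else conformer(cf)
  })
  comp <- sort(conformers[[1]]$element)
  for (i in seq_along(conformers)) {
    if (!identical(sort(conformers[[i]]$element), comp)) {
      stop("ligand '", ligand_id, "': conformer ", i,
           " has a different element composition")
    }
  }
  structure(list(ligand_id = ligand_id, conformers = conformers),
            class = "ligand")
}

#' @export
print.ligand <- function(x, ...) {
  cat("<ligand>", x$ligand_id, "-", length(x$conformers), "conformer(s),",
      nrow(x$conformers[[1]]), "atoms",
      paste0("(", sum(x$conformers[[1]]$is_heavy), " heavy)"), "\n")
  invisible(x)
}

#' Number of conformers in a ligand
#' @param ligand A `ligand`.
#' @return Integer count.
#' @export
n_conformers <- function(ligand) length(ligand$conformers)
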