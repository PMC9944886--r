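#' Read ligand structures from SDF, MOL2 or PDB files
#'
#' SDF (V2000) files are parsed with ChemmineR; consecutive records sharing
#' a title line are collapsed into one ligand with multiple conformers, so
#' multi-conformer ensembles written one record per conformer round-trip as
#' a single [new_ligand()]. MOL2 files are parsed with bio3d and treated as
#' single-conformer, one ligand per file. PDB files delegate to
#' [extract_het_ligands()]. Hydrogens are retained in the atom tables but
#' flagged via `is_heavy`; atom order is preserved as read.
#'
#' @param path Path to the structure file.
#' @param format `"SDF"`, `"MOL2"` or `"PDB"`; default guesses from the file
#'   extension.
#' @return List of [new_ligand()] objects. SDF records with zero heavy atoms
#'   are skipped with a warning.
#' @export
read_ligands <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- toupper(tools::file_ext(path))
    if (format == "ENT") format <- "PDB"
  }
  format <- match.arg(toupper(format), c("SDF", "MOL2", "PDB"))
  switch(format,
         SDF = read_ligands_sdf(path),
         MOL2 = read_ligands_mol2(path),
         PDB = extract_het_ligands(path))
}

read_ligands_sdf <- function(path) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                  error = function(e) stop("failed to parse SDF '", path,
                                           "': ", conditionMessage(e)))
  # logic="|": accept bond-free records (shape analysis needs centers only);
  # truncated records still fail via the NA check on the atom block
  ok <- ChemmineR::validSDF(sdf, logic = "|")
  if (any(!ok)) {
    stop("malformed SDF record(s) at index ",
         paste(which(!ok), collapse = ", "), " in '", path, "'")
  }
  n <- length(sdf)
  titles <- vapply(seq_len(n), function(i) {
    h <- ChemmineR::header(sdf[[i]])
    title <- unname(h["Molecule_Name"])
    if (is.na(title) || !nzchar(trimws(title))) paste0("record_", i)
    else trimws(title)
  }, character(1))
  confs <- vector("list", n)
  for (i in seq_len(n)) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    el <- sub("_[0-9]+$", "", rownames(ab))
    confs[[i]] <- conformer(
      tibble::tibble(element = el, x = unname(ab[, 1]), y = unname(ab[, 2]),
                     z = unname(ab[, 3])),
      source_label = paste0("sdf_record_", i)
    )
  }
  out <- list()
  for (title in unique(titles)) {
    idx <- which(titles == title)
    heavy_ok <- vapply(idx, function(i) any(confs[[i]]$is_heavy), logical(1))
    if (!any(heavy_ok)) {
      warning("skipping SDF ligand '", title, "': no heavy atoms")
      next
    }
    if (any(!heavy_ok)) {
      warning("skipping ", sum(!heavy_ok), " conformer(s) of '", title,
              "' with no heavy atoms")
    }
    out[[title]] <- new_ligand(title, confs[idx[heavy_ok]])
  }
  unname(out)
}

read_ligands_mol2 <- function(path) {
  m <- tryCatch(bio3d::read.mol2(path),
                error = function(e) stop("failed to parse MOL2 '", path,
                                         "': ", conditionMessage(e)))
  if (!is.list(m) || is.null(m$atom)) m <- m[[1]]
  el <- sub("\\..*$", "", m$atom$elety)
  atoms <- tibble::tibble(element = el, x = m$atom$x, y = m$atom$y,
                          z = m$atom$z)
  id <- if (!is.null(m$name) && nzchar(m$name)) m$name
        else tools::file_path_sans_ext(basename(path))
  list(new_ligand(id, list(conformer(atoms, source_label = "mol2"))))
}

#' Extract HET ligands from a PDB file
#'
#' One ligand per distinct `(HET code, chain, residue number, insertion
#' code)` among the HETATM records. Waters (HOH/WAT/DOD) are always
#' skipped. Alternate locations are resolved per atom by keeping the
#' highest-occupancy copy, ties going to altloc `A`, so each ligand instance
#' is a single coherent conformer. Coordinates are taken verbatim
#' (Angstroms, PDB frame, no re-centering).
#'
#' @param pdb_path Path to a PDB-format file.
#' @return List of single-conformer [new_ligand()] objects (empty list when
#'   the file has no HETATM records). Ligand ids are
#'   `"<code>_<chain>_<resno>"`.
#' @export
extract_het_ligands <- function(pdb_path) {
  if (!file.exists(pdb_path)) stop("file not found: ", pdb_path)
  pdb <- tryCatch(bio3d::read.pdb(pdb_path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", pdb_path,
                                           "': ", conditionMessage(e)))
  at <- tibble::as_tibble(pdb$atom)
  het <- dplyr::filter(at, .data$type == "HETATM",
                       !.data$resid %in% c("HOH", "WAT", "DOD"))
  if (nrow(het) == 0) return(list())
  het$insert[is.na(het$insert)] <- ""
  het$alt[is.na(het$alt)] <- ""
  het$o[is.na(het$o)] <- 1
  # altloc rule: per atom name within a residue instance keep the
  # highest-occupancy copy; ties go to altloc 'A' ('' sorts first, which is
  # correct -- an un-lettered atom is the sole copy)
  het <- het |>
    dplyr::group_by(.data$resid, .data$chain, .data$resno, .data$insert,
                    .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$eleno)
  het$element <- pdb_element(het$elesy, het$elety)
  groups <- dplyr::group_split(het, .data$resid, .data$chain, .data$resno,
                               .data$insert)
  purrr::map(groups, function(g) {
    id <- paste(g$resid[1], g$chain[1], g$resno[1], sep = "_")
    if (nzchar(g$insert[1])) id <- paste0(id, g$insert[1])
    atoms <- tibble::tibble(element = g$element, x = g$x, y = g$y, z = g$z)
    new_ligand(id, list(conformer(atoms, source_label = "pdb_pose")))
  })
}

pdb_element <- function(elesy, elety) {
  el <- ifelse(is.na(elesy) | !nzchar(trimws(elesy)), NA_character_,
               trimws(elesy))
  miss <- is.na(el)
  if (any(miss)) {
    # fall back to the atom name: strip digits and primes, first letters
    guess <- sub("^([A-Za-z]+).*$", "\\1", gsub("[0-9']", "", elety[miss]))
    el[miss] <- substr(guess, 1, 1)
  }
  paste0(toupper(substr(el, 1, 1)),
         tolower(substr(el, 2, nchar(el))))
}

#' Write and read shape-match tables
#'
#' Tab-separated, one row per ligand pair, columns `query_id`, `db_id`,
#' `tanimoto` (6 decimals), `best_conformer_index`, `best_start_family`.
#' Rows are written in deterministic order (descending Tanimoto, then
#' lexicographic ids) and the pair round-trips losslessly at the printed
#' precision.
#'
#' @param matches A tibble of shape matches ([all_vs_all_match()] output).
#' @param path Output/input path.
#' @return `write_match_table()` invisibly returns `path`;
#'   `read_match_table()` returns the match tibble.
#' @export
write_match_table <- function(matches, path) {
  need <- c("query_id", "db_id", "tanimoto", "best_conformer_index",
            "best_start_family")
  stopifnot(is.data.frame(matches), all(need %in% names(matches)))
  out <- matches |>
    dplyr::arrange(dplyr::desc(.data$tanimoto), .data$query_id, .data$db_id) |>
    dplyr::transmute(
      query_id = .data$query_id,
      db_id = .data$db_id,
      tanimoto = sprintf("%.6f", .data$tanimoto),
      best_conformer_index = as.integer(.data$best_conformer_index),
      best_start_family = .data$best_start_family
    )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_match_table
#' @export
read_match_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    query_id = readr::col_character(),
    db_id = readr::col_character(),
    tanimoto = readr::col_double(),
    best_conformer_index = readr::col_integer(),
    best_start_family = readr::col_character()
  ))
}

#' Write ligands to an SDF (V2000) file
#'
#' One record per conformer, titled with the `ligand_id`, so multi-conformer
#' ligands round-trip through [read_ligands()] (which collapses records
#' sharing a title). Bond blocks are empty: downstream shape analysis uses
#' atomic centers only.
#'
#' @param ligands A [new_ligand()] or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sdf <- function(ligands, path) {
  if (inherits(ligands, "ligand")) ligands <- list(ligands)
  lines <- character(0)
  for (lig in ligands) {
    for (cf in lig$conformers) {
      lines <- c(lines,
        lig$ligand_id,
        "  ligshape",
        "",
        sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(cf), 0L),
        sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                cf$x, cf$y, cf$z, cf$element),
        "M  END",
        "$$$$")
    }
  }
  writeLines(lines, path)
  invisible(path)
}
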