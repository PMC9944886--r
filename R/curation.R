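#' Default ligand validity lists
#'
#' Validity is list-driven: crystallographic additives, salts, buffers,
#' metals and solvents are invalid; heme groups and modified amino acids are
#' part of the protein rather than bound ligands. The shipped lists cover
#' the common crystallisation additives and are fully user-editable -- no
#' chemistry perception is attempted.
#'
#' @return List with character vectors `invalid` and `part_of_protein`.
#' @export
default_validity_lists <- function() {
  list(
    invalid = c(
      # salts, buffers, cryoprotectants, solvents
      "SO4", "PO4", "GOL", "EDO", "PEG", "PG4", "ACT", "DMS", "MPD", "EPE",
      "MES", "TRS", "BME", "FMT", "CIT", "TLA", "NO3", "ACY", "IMD", "BCT",
      # single-atom metals and halide ions
      "NA", "K", "MG", "CA", "ZN", "MN", "FE", "NI", "CU", "CO", "CD", "HG",
      "LI", "CS", "SR", "BA", "CL", "BR", "IOD", "F"
    ),
    part_of_protein = c(
      # heme variants
      "HEM", "HEC", "HEA", "HEB", "HDD",
      # modified amino acids
      "MSE", "SEP", "TPO", "PTR", "CSO", "CSD", "CME", "PCA", "KCX", "LLP",
      "HYP", "MLY"
    )
  )
}

#' Classify a ligand's biological relevance
#'
#' Precedence: part-of-protein lists beat the invalid lists, which beat the
#' default `valid`; a covalently bound ligand is excluded like a
#' part-of-protein group regardless of its code, with reason
#' `"covalently bound"`.
#'
#' @param ligand_id HET code text.
#' @param covalent Is the ligand covalently bound to the protein chain?
#' @param lists Validity lists, see [default_validity_lists()].
#' @return One-row tibble with columns `ligand_id`, `label` (one of
#'   `valid`, `invalid`, `part_of_protein`) and `reason`.
#' @export
classify_ligand <- function(ligand_id, covalent = FALSE,
                            lists = default_validity_lists()) {
  id <- toupper(trimws(ligand_id))
  if (id %in% lists$part_of_protein) {
    label <- "part_of_protein"; reason <- "part-of-protein list (heme/modified residue)"
  } else if (isTRUE(covalent)) {
    label <- "part_of_protein"; reason <- "covalently bound"
  } else if (id %in% lists$invalid) {
    label <- "invalid"; reason <- "additive/salt/buffer/metal/solvent list"
  } else {
    label <- "valid"; reason <- "not on any exclusion list"
  }
  tibble::tibble(ligand_id = ligand_id, label = label, reason = reason)
}

#' @rdname classify_ligand
#' @param ligands Tibble with columns `ligand_id` and optionally `covalent`.
#' @export
classify_ligands <- function(ligands, lists = default_validity_lists()) {
  cov <- if ("covalent" %in% names(ligands)) ligands$covalent else FALSE
  extra <- dplyr::select(ligands, -dplyr::any_of(c("label", "reason")))
  dplyr::bind_cols(
    dplyr::select(extra, -dplyr::any_of("ligand_id")),
    purrr::map2_dfr(ligands$ligand_id, rep_len(cov, nrow(ligands)),
                    classify_ligand, lists = lists)
  ) |>
    dplyr::relocate(dplyr::any_of("pdb_id"), "ligand_id")
}

#' Default single-bond covalent radii (Angstroms)
#' @return Named numeric vector keyed by element symbol.
#' @export
covalent_radius_table <- function() {
  c(H = 0.37, C = 0.77, N = 0.75, O = 0.73, F = 0.71, P = 1.10, S = 1.02,
    Cl = 0.99, Br = 1.14, I = 1.33, Se = 1.17, B = 0.82)
}

#' Detect a covalent ligand-protein contact
#'
#' A ligand is flagged covalent when any of its heavy atoms lies within the
#' sum of covalent radii plus `tolerance` of any protein heavy atom. Both
#' atom sets must share a coordinate frame (Angstroms).
#'
#' @param ligand A [new_ligand()] (first conformer is used) or an atom data
#'   frame with `element`, `x`, `y`, `z`.
#' @param protein_atoms Atom data frame for the protein; an empty frame
#'   yields `FALSE`.
#' @param tolerance Slack added to the covalent-radius sum (default 0.4 A).
#' @param radii Covalent radius table.
#' @return Logical flag.
#' @export
detect_covalent <- function(ligand, protein_atoms, tolerance = 0.4,
                            radii = covalent_radius_table()) {
  la <- if (inherits(ligand, "ligand")) ligand$conformers[[1]] else ligand
  la <- la[la$element != "H", , drop = FALSE]
  pa <- protein_atoms[protein_atoms$element != "H", , drop = FALSE]
  if (nrow(pa) == 0 || nrow(la) == 0) return(FALSE)
  rl <- radii[la$element]
  rp <- radii[pa$element]
  if (anyNA(rl) || anyNA(rp)) {
    miss <- unique(c(la$element[is.na(rl)], pa$element[is.na(rp)]))
    stop("no covalent radius for element(s): ", paste(miss, collapse = ", "))
  }
  lm <- as.matrix(la[, c("x", "y", "z")])
  pm <- as.matrix(pa[, c("x", "y", "z")])
  d2 <- outer(rowSums(lm^2), rowSums(pm^2), `+`) - 2 * lm %*% t(pm)
  d2[d2 < 0] <- 0
  cutoff <- outer(rl, rp, `+`) + tolerance
  any(sqrt(d2) <= cutoff)
}

#' Filter complexes by structure-quality rules
#'
#' The standard inclusion rules keep complexes with resolution of at least
#' 2.5 A (i.e. a numeric value `<= 2.5`), at least one protein chain, and at
#' least one valid, non-covalent ligand. The high-quality (`hiq`) mode adds
#' `r_free - r_work <= 0.05`, real-space R `<= 0.2` and real-space
#' correlation `>= 0.9`, all boundaries inclusive. Every discarded complex
#' carries the first rule it failed; a record missing a field required by
#' the chosen mode is discarded with a `missing field` reason.
#'
#' @param complexes Tibble with columns `pdb_id`, `resolution` and, for
#'   `hiq`, `r_work`, `r_free`, `rsr`, `rscc`.
#' @param ligand_labels Tibble of per-complex ligand labels (`pdb_id`,
#'   `ligand_id`, `label`), e.g. from [classify_ligands()].
#' @param chains Tibble of protein chains (`pdb_id`, `chain`, `sequence`).
#' @param mode `"standard"` or `"hiq"`.
#' @return List with tibbles `kept` (the surviving complex rows) and
#'   `discarded` (`pdb_id`, `reason`); the two partition the input.
#' @export
filter_complexes <- function(complexes, ligand_labels, chains,
                             mode = c("standard", "hiq")) {
  mode <- match.arg(mode)
  stopifnot(all(c("pdb_id", "resolution") %in% names(complexes)))
  need <- if (mode == "hiq") c("r_work", "r_free", "rsr", "rscc") else character(0)
  n_valid <- ligand_labels |>
    dplyr::filter(.data$label == "valid") |>
    dplyr::count(.data$pdb_id, name = "n_valid")
  n_chain <- chains |>
    dplyr::filter(nzchar(.data$sequence)) |>
    dplyr::count(.data$pdb_id, name = "n_chain")
  df <- complexes |>
    dplyr::left_join(n_valid, by = "pdb_id") |>
    dplyr::left_join(n_chain, by = "pdb_id") |>
    dplyr::mutate(n_valid = dplyr::coalesce(.data$n_valid, 0L),
                  n_chain = dplyr::coalesce(.data$n_chain, 0L))
  reason <- vapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    for (f in c("resolution", need)) {
      if (!f %in% names(row) || is.na(row[[f]])) {
        return(paste("missing field:", f))
      }
    }
    # boundaries are inclusive; eps absorbs binary representation error so
    # e.g. 0.23 - 0.18 still counts as exactly 0.05
    eps <- 1e-9
    if (row$resolution > 2.5 + eps) return("resolution worse than 2.5 A")
    if (row$n_chain < 1) return("no protein chain")
    if (row$n_valid < 1) return("no valid ligand")
    if (mode == "hiq") {
      if (row$r_free - row$r_work > 0.05 + eps) {
        return("r_free - r_work above 0.05")
      }
      if (row$rsr > 0.2 + eps) return("real-space R above 0.2")
      if (row$rscc < 0.9 - eps) return("RSCC below 0.9")
    }
    NA_character_
  }, character(1))
  keep <- is.na(reason)
  list(
    kept = complexes[keep, , drop = FALSE],
    discarded = tibble::tibble(pdb_id = complexes$pdb_id[!keep],
                               reason = reason[!keep])
  )
}
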