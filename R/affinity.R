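#' Unit factors for affinity normalisation
#'
#' Concentration units are converted to molar; the inverse-molar unit is
#' reserved for association constants (Ka), which are stored as their
#' reciprocal (a dissociation constant in M). ASCII aliases (`uM`, `M^-1`,
#' `1/M`) are accepted alongside the typographic forms.
#'
#' @return Named numeric vector of multiplicative factors to molar.
#' @export
affinity_unit_table <- function() {
  c(fM = 1e-15, pM = 1e-12, nM = 1e-9, uM = 1e-6, mM = 1e-3, M = 1)
}

normalize_unit <- function(unit) {
  u <- trimws(unit)
  u[u %in% c("μM", "µM")] <- "uM"                    # micro signs
  u[u %in% c("M⁻¹", "M^-1", "M-1", "1/M")] <- "M^-1" # inverse molar
  u
}

#' Parse one affinity measurement
#'
#' Turns a raw field like `"3.0 nM"` together with its measurement type and
#' relation into a normalised record. Concentration values are converted to
#' molar via the unit table; an association constant (type `Ka`, unit
#' inverse molar) is stored as its reciprocal, i.e. the equivalent
#' dissociation constant in M, so `Ka` records compete directly with `Kd`
#' records downstream.
#'
#' @param text Raw value-unit field, e.g. `"0.003 uM"` (the micro sign is
#'   accepted too).
#' @param type One of `"Kd"`, `"Ka"`, `"Ki"`, `"IC50"`.
#' @param relation One of `=`, `~`, `<`, `>`, `<=`, `>=` (typographic
#'   `≤`/`≥` accepted).
#' @param pdb_id,ligand_id Optional identifiers carried along.
#' @return One-row tibble with columns `pdb_id`, `ligand_id`,
#'   `measurement_type`, `relation`, `value`, `unit`, `molar_value`.
#' @examples
#' parse_affinity("3.0 nM", "Kd")     # molar_value 3e-9
#' parse_affinity("0.00108 M^-1", "Ka")  # stored as 1/0.00108 M
#' @export
parse_affinity <- function(text, type, relation = "=",
                           pdb_id = NA_character_, ligand_id = NA_character_) {
  type <- match.arg(type, c("Kd", "Ka", "Ki", "IC50"))
  relation <- normalize_relation(relation)
  parts <- strsplit(trimws(text), "\\s+")[[1]]
  if (length(parts) != 2) {
    stop("cannot parse affinity field '", text, "': expected 'value unit'")
  }
  value <- suppressWarnings(as.numeric(parts[1]))
  if (is.na(value) || value <= 0) {
    stop("affinity value must be a positive number, got '", parts[1], "'")
  }
  unit <- normalize_unit(parts[2])
  molar <- affinity_to_molar(value, unit, type)
  tibble::tibble(pdb_id = pdb_id, ligand_id = ligand_id,
                 measurement_type = type, relation = relation,
                 value = value, unit = unit, molar_value = molar)
}

normalize_relation <- function(relation) {
  r <- trimws(relation)
  r[r == "≤"] <- "<="
  r[r == "≥"] <- ">="
  bad <- !r %in% c("=", "~", "<", ">", "<=", ">=")
  if (any(bad)) stop("unknown relation symbol: ", paste(unique(r[bad]), collapse = ", "))
  r
}

affinity_to_molar <- function(value, unit, type) {
  units <- affinity_unit_table()
  inv <- unit == "M^-1"
  if (any(inv & type != "Ka")) {
    stop("inverse-molar unit is only meaningful for Ka records")
  }
  if (any(!inv & type == "Ka")) {
    stop("Ka records must carry an inverse-molar unit (M^-1)")
  }
  known <- inv | unit %in% names(units)
  if (any(!known)) {
    stop("unknown affinity unit: ", paste(unique(unit[!known]), collapse = ", "))
  }
  out <- numeric(length(value))
  out[inv] <- 1 / value[inv]               # Ka -> equivalent Kd in M
  out[!inv] <- value[!inv] * units[unit[!inv]]
  out
}

#' Normalise a table of affinity records
#'
#' Vectorised companion of [parse_affinity()] for delimited input with
#' columns `pdb_id`, `ligand_id`, `type`, `relation`, `value`, `unit`.
#'
#' @param records Data frame with the columns above.
#' @return Tibble with `measurement_type` and `molar_value` columns added.
#' @export
normalize_affinities <- function(records) {
  stopifnot(all(c("pdb_id", "ligand_id", "type", "relation", "value",
                  "unit") %in% names(records)))
  if (any(!is.finite(records$value) | records$value <= 0)) {
    stop("affinity values must be positive")
  }
  type <- as.character(records$type)
  bad <- !type %in% c("Kd", "Ka", "Ki", "IC50")
  if (any(bad)) stop("unknown measurement type: ",
                     paste(unique(type[bad]), collapse = ", "))
  unit <- normalize_unit(as.character(records$unit))
  tibble::tibble(
    pdb_id = as.character(records$pdb_id),
    ligand_id = as.character(records$ligand_id),
    measurement_type = type,
    relation = normalize_relation(as.character(records$relation)),
    value = as.numeric(records$value),
    unit = unit,
    molar_value = affinity_to_molar(as.numeric(records$value), unit, type)
  )
}

#' Read an affinity table from delimited text
#'
#' @param path TSV/CSV file with columns `pdb_id`, `ligand_id`, `type`,
#'   `relation`, `value`, `unit`.
#' @param delim Field delimiter (default tab).
#' @return Normalised tibble (see [normalize_affinities()]).
#' @export
read_affinity_table <- function(path, delim = "\t") {
  normalize_affinities(readr::read_delim(path, delim = delim,
                                         col_types = readr::cols()))
}

#' Format an affinity record back to a value-unit field
#'
#' Inverse of [parse_affinity()]: re-parsing the result reproduces the
#' molar value.
#'
#' @param record One-row affinity tibble.
#' @return Character like `"3 nM"`.
#' @export
format_affinity <- function(record) {
  paste(format(record$value, digits = 15, scientific = TRUE, trim = TRUE),
        record$unit)
}

#' Select the preferred affinity measurement
#'
#' Preference order over measurement types: dissociation constants
#' (`Kd`, including converted `Ka`) over inhibition constants (`Ki`) over
#' half-maximal inhibitory concentrations (`IC50`). Within the winning
#' type, exact (`=`) relations are preferred over qualified ones, and then
#' the tightest (smallest molar) value wins.
#'
#' @param records Normalised affinity tibble (possibly empty).
#' @return One-row tibble, or `NULL` when `records` is empty.
#' @export
select_preferred <- function(records) {
  if (is.null(records) || nrow(records) == 0) return(NULL)
  rank <- c(Kd = 1L, Ka = 1L, Ki = 2L, IC50 = 3L)
  records |>
    dplyr::mutate(.pref = rank[.data$measurement_type]) |>
    dplyr::arrange(.data$.pref, .data$relation != "=", .data$molar_value) |>
    dplyr::slice(1) |>
    dplyr::select(-".pref")
}

#' Affinity bin labels
#' @return Character vector of the four bin labels, tightest first.
#' @export
affinity_bins <- function() c("<1 nM", "1 nM-1 uM", "1 uM-1 mM", ">1 mM")

assign_bin <- function(molar) {
  # [0, 1 nM) / [1 nM, 1 uM) / [1 uM, 1 mM] / (1 mM, Inf)
  bins <- affinity_bins()
  dplyr::case_when(
    molar < 1e-9 ~ bins[1],
    molar < 1e-6 ~ bins[2],
    molar <= 1e-3 ~ bins[3],
    TRUE ~ bins[4]
  )
}

#' Bin an affinity distribution
#'
#' Counts records of one measurement type into the four conventional bins:
#' sub-nanomolar, nanomolar-to-micromolar, micromolar-to-millimolar, and
#' weaker than millimolar. Boundary membership is left-closed at 1 nM and
#' 1 uM; exactly 1 mM falls in the third bin. Every record lands in exactly
#' one bin, so the counts always sum to the input size.
#'
#' @param records Normalised affinity tibble.
#' @param type Requested type; `"Kd"` also admits converted `Ka` records.
#' @return Tibble with columns `bin` (ordered factor) and `n`.
#' @export
bin_distribution <- function(records, type = c("Kd", "Ki", "IC50")) {
  type <- match.arg(type)
  allowed <- if (type == "Kd") c("Kd", "Ka") else type
  if (!all(records$measurement_type %in% allowed)) {
    stop("bin_distribution expects records of type ",
         paste(allowed, collapse = "/"), " only; filter first")
  }
  bins <- affinity_bins()
  counts <- table(factor(assign_bin(records$molar_value), levels = bins))
  tibble::tibble(bin = factor(bins, levels = bins), n = as.integer(counts))
}

#' Discrepancy categories for cross-database affinity comparison
#' @return Character vector of the five categories.
#' @export
discrepancy_categories <- function() {
  c("unit_equivalent_agreement", "measurement_type_error",
    "inequality_error", "wrong_pair_error", "value_error")
}

#' Classify a cross-database affinity discrepancy
#'
#' Compares one record pair for the same PDB entry and assigns exactly one
#' category:
#'
#' 1. `unit_equivalent_agreement` -- same measurement type, relation and
#'    ligand, and molar values within 0.5% relative (absorbs pure
#'    unit-rewriting such as 0.003 uM vs 3.0 nM);
#' 2. `measurement_type_error` -- measurement types differ;
#' 3. `inequality_error` -- relation symbols differ;
#' 4. `wrong_pair_error` -- ligand ids differ;
#' 5. `value_error` -- everything matches but the values disagree.
#'
#' The precedence (type over relation over pair over value) makes the
#' categories mutually exclusive.
#'
#' @param a,b One-row normalised affinity tibbles referencing the same
#'   `pdb_id`.
#' @param tol Relative agreement tolerance (default 0.005).
#' @return One-row tibble with columns `category` and `details`.
#' @export
classify_discrepancy <- function(a, b, tol = 0.005) {
  if (!is.na(a$pdb_id) && !is.na(b$pdb_id) && a$pdb_id != b$pdb_id) {
    stop("records reference different pdb_ids: ", a$pdb_id, " vs ", b$pdb_id)
  }
  values_agree <- abs(a$molar_value - b$molar_value) <=
    tol * pmax(a$molar_value, b$molar_value)
  same_ligand <- is.na(a$ligand_id) || is.na(b$ligand_id) ||
    a$ligand_id == b$ligand_id
  if (a$measurement_type == b$measurement_type &&
      a$relation == b$relation && same_ligand && values_agree) {
    cat_ <- "unit_equivalent_agreement"
    det <- sprintf("%g %s == %g %s", a$value, a$unit, b$value, b$unit)
  } else if (a$measurement_type != b$measurement_type) {
    cat_ <- "measurement_type_error"
    det <- paste(a$measurement_type, "vs", b$measurement_type)
  } else if (a$relation != b$relation) {
    cat_ <- "inequality_error"
    det <- paste0("'", a$relation, "' vs '", b$relation, "'")
  } else if (!same_ligand) {
    cat_ <- "wrong_pair_error"
    det <- paste(a$ligand_id, "vs", b$ligand_id)
  } else {
    cat_ <- "value_error"
    det <- sprintf("%g M vs %g M", a$molar_value, b$molar_value)
  }
  tibble::tibble(category = cat_, details = det)
}

#' Classify every discrepancy between two affinity tables
#'
#' Rows are matched by position (the tables are two databases' views of the
#' same complex list, as produced by [make_synthetic_affinity_set()]).
#'
#' @param left,right Normalised affinity tibbles of equal length.
#' @param tol Relative agreement tolerance.
#' @return Tibble with `pdb_id`, `category`, `details` per pair.
#' @export
classify_discrepancies <- function(left, right, tol = 0.005) {
  stopifnot(nrow(left) == nrow(right))
  purrr::map_dfr(seq_len(nrow(left)), function(i) {
    dplyr::bind_cols(
      tibble::tibble(pdb_id = left$pdb_id[i]),
      classify_discrepancy(left[i, ], right[i, ], tol = tol)
    )
  })
}
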