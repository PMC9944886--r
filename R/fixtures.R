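#' Deterministic toy ligand geometries
#'
#' Synthetic single-element geometries with closed-form sanity checks:
#' `linear` chains at 1.5 A spacing on the x axis, `ring` regular planar
#' polygons with 1.5 A edges, and `tetrahedral` a central atom with four
#' neighbours at 1.5 A. An optional seeded Gaussian jitter (default 0)
#' breaks the exact symmetries when a generic asymmetric shape is wanted.
#'
#' @param shape `"linear"`, `"ring"` or `"tetrahedral"`.
#' @param n_atoms Atom count (`ring` needs >= 3; `tetrahedral` is always 5
#'   atoms and `n_atoms` is ignored).
#' @param element Element symbol for every atom.
#' @param seed Seed for the jitter draw.
#' @param jitter Standard deviation (A) of per-coordinate jitter.
#' @param id Ligand id.
#' @return A single-conformer [new_ligand()].
#' @examples
#' make_toy_ligand("ring", 6)
#' @export
make_toy_ligand <- function(shape = c("linear", "ring", "tetrahedral"),
                            n_atoms = 5, element = "C", seed = 0,
                            jitter = 0, id = NULL) {
  shape <- match.arg(shape)
  if (n_atoms < 1) stop("n_atoms must be >= 1")
  if (shape == "ring" && n_atoms < 3) stop("a ring needs at least 3 atoms")
  coords <- switch(shape,
    linear = cbind(1.5 * (seq_len(n_atoms) - 1), 0, 0),
    ring = {
      # regular n-gon with edge 1.5 A: circumradius = edge / (2 sin(pi/n))
      rad <- 1.5 / (2 * sin(pi / n_atoms))
      th <- 2 * pi * (seq_len(n_atoms) - 1) / n_atoms
      cbind(rad * cos(th), rad * sin(th), 0)
    },
    tetrahedral = {
      n_atoms <- 5L
      d <- 1.5 / sqrt(3)
      rbind(c(0, 0, 0), d * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                                  c(-1, -1, 1)))
    })
  if (jitter > 0) {
    coords <- coords + withr::with_seed(as.integer(seed), {
      matrix(stats::rnorm(length(coords), sd = jitter), ncol = 3)
    })
  }
  if (is.null(id)) id <- paste0(toupper(substr(shape, 1, 3)), nrow(coords))
  atoms <- tibble::tibble(element = element, x = coords[, 1], y = coords[, 2],
                          z = coords[, 3])
  new_ligand(id, list(conformer(atoms, source_label = shape)))
}

#' Apply a seeded random rigid transform to a ligand
#'
#' Creates known-answer superposition cases: the returned ligand is a rigid
#' copy, so its optimal shape Tanimoto against the original is exactly 1.
#'
#' @param ligand A [new_ligand()]; every conformer is transformed by the
#'   same draw.
#' @param seed Seed for the transform draw.
#' @param max_rotation Upper bound on the rotation angle (degrees).
#' @param max_translation Upper bound on the translation norm (A).
#' @param id Id for the new ligand (default `<id>_perturbed`).
#' @return A transformed [new_ligand()].
#' @export
perturb_ligand <- function(ligand, seed = 1, max_rotation = 60,
                           max_translation = 3, id = NULL) {
  stopifnot(inherits(ligand, "ligand"))
  tr <- withr::with_seed(as.integer(seed), {
    axis <- stats::rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
    angle <- stats::runif(1, 0, max_rotation) * pi / 180
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    shift <- stats::runif(1, 0, max_translation) * dir
    rigid_transform(quat_from_rotvec(axis * angle), shift)
  })
  confs <- lapply(ligand$conformers, function(cf) {
    xyz <- apply_transform(tr, as.matrix(cf[, c("x", "y", "z")]))
    out <- cf
    out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
    out
  })
  new_ligand(id %||% paste0(ligand$ligand_id, "_perturbed"), confs)
}

#' Synthetic paired affinity tables with planted discrepancies
#'
#' Generates two views ("left" and "right") of the same complex list that
#' realise exactly the planted per-category counts, plus optional single
#' records realising planted per-bin counts:
#'
#' * `unit_equivalent_agreement` pairs re-express the same value in a
#'   different unit (e.g. 0.003 uM vs 3.0 nM);
#' * `measurement_type_error` pairs differ only in measurement type;
#' * `inequality_error` pairs differ only in the relation symbol;
#' * `wrong_pair_error` pairs differ only in the ligand id;
#' * `value_error` pairs differ only in the value (by well over the
#'   agreement tolerance).
#'
#' @param categories Named integer vector over
#'   [discrepancy_categories()] (missing names count 0).
#' @param bins Named integer vector over [affinity_bins()] for the single
#'   records (missing names count 0).
#' @param bin_type Measurement type of the binned records.
#' @param seed Seed for value draws.
#' @return List with tibbles `left`, `right`, `truth` (pair ground truth)
#'   and `records` (binned singles with a `true_bin` column).
#' @export
make_synthetic_affinity_set <- function(categories = integer(0),
                                        bins = integer(0),
                                        bin_type = "Kd", seed = 0) {
  cats <- stats::setNames(integer(length(discrepancy_categories())),
                          discrepancy_categories())
  cats[names(categories)] <- as.integer(categories)
  if (any(cats < 0)) stop("category counts must be >= 0")
  binplan <- stats::setNames(integer(4), affinity_bins())
  binplan[names(bins)] <- as.integer(bins)
  if (any(binplan < 0)) stop("bin counts must be >= 0")

  units <- c("pM", "nM", "uM", "mM")
  withr::with_seed(as.integer(seed), {
    n <- sum(cats)
    left <- right <- vector("list", n)
    truth <- character(n)
    k <- 0
    for (cat_ in discrepancy_categories()) {
      for (r in seq_len(cats[[cat_]])) {
        k <- k + 1
        pdb <- sprintf("%04x", k)
        lig <- sprintf("L%02d", k %% 37)
        unit <- sample(units, 1)
        value <- signif(stats::runif(1, 1, 999), 3)
        base <- list(pdb_id = pdb, ligand_id = lig, type = "Kd",
                     relation = "=", value = value, unit = unit)
        other <- base
        if (cat_ == "unit_equivalent_agreement") {
          # same molar value expressed one unit step away
          i <- match(unit, units)
          j <- if (i == length(units)) i - 1L else i + 1L
          other$unit <- units[j]
          other$value <- value * affinity_unit_table()[[unit]] /
            affinity_unit_table()[[units[j]]]
        } else if (cat_ == "measurement_type_error") {
          other$type <- sample(c("Ki", "IC50"), 1)
        } else if (cat_ == "inequality_error") {
          other$relation <- sample(c("~", "<", ">"), 1)
        } else if (cat_ == "wrong_pair_error") {
          other$ligand_id <- paste0(lig, "X")
        } else {
          other$value <- value * stats::runif(1, 1.5, 4)
        }
        left[[k]] <- tibble::as_tibble(base)
        right[[k]] <- tibble::as_tibble(other)
        truth[k] <- cat_
      }
    }
    left <- if (n > 0) dplyr::bind_rows(left) else empty_affinity_input()
    right <- if (n > 0) dplyr::bind_rows(right) else empty_affinity_input()

    # single records realising the planted bin counts; values are drawn
    # strictly inside each bin so boundary conventions cannot move them
    ranges <- list(c(1e-12, 0.9e-9), c(1.1e-9, 0.9e-6), c(1.1e-6, 0.9e-3),
                   c(1.1e-3, 10))
    recs <- purrr::map_dfr(seq_along(binplan), function(i) {
      nb <- binplan[[i]]
      if (nb == 0) return(NULL)
      molar <- exp(stats::runif(nb, log(ranges[[i]][1]), log(ranges[[i]][2])))
      tibble::tibble(pdb_id = sprintf("b%03d_%d", seq_len(nb), i),
                     ligand_id = "LIG", type = bin_type, relation = "=",
                     value = molar * 1e9, unit = "nM",
                     true_bin = affinity_bins()[i])
    })
  })
  list(
    left = normalize_affinities(left),
    right = normalize_affinities(right),
    truth = tibble::tibble(pdb_id = left$pdb_id, category = truth),
    records = if (nrow(recs) == 0) recs else
      dplyr::bind_cols(normalize_affinities(recs),
                       tibble::tibble(true_bin = recs$true_bin))
  )
}

empty_affinity_input <- function() {
  tibble::tibble(pdb_id = character(0), ligand_id = character(0),
                 type = character(0), relation = character(0),
                 value = numeric(0), unit = character(0))
}

#' Synthetic complex with a matching minimal PDB file
#'
#' Emits a short poly-alanine chain plus HETATM ligands placed either within
#' covalent-bonding distance of the chain or well away from it, together
#' with the metadata row the curation filters consume. The PDB text is
#' standard-conformant (CRYST1/ATOM/HETATM/TER/END) so the real parser is
#' exercised rather than bypassed.
#'
#' @param pdb_id 4-character id for the complex.
#' @param resolution,r_work,r_free,rsr,rscc Metadata values.
#' @param ligand_codes Character vector of HET codes to place.
#' @param covalent Place the first ligand within covalent distance of the
#'   chain?
#' @param n_residues Length of the poly-ALA chain.
#' @param dir Directory for the PDB file (default `tempdir()`).
#' @return List with `record` (one-row metadata tibble), `ligands`
#'   (tibble `pdb_id`, `ligand_id`), `chains` (tibble with the ALA
#'   sequence) and `pdb_file` (path to the written file).
#' @export
make_toy_complex <- function(pdb_id = "1abc", resolution = 2.0,
                             r_work = 0.18, r_free = 0.22, rsr = 0.1,
                             rscc = 0.95, ligand_codes = "LIG",
                             covalent = FALSE, n_residues = 6,
                             dir = tempdir()) {
  lines <- c(sprintf("%-6s%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d", "CRYST1",
                     50, 50, 50, 90, 90, 90, "P 1", 1))
  serial <- 0
  # poly-ALA backbone spaced along x; N/CA/C/O per residue
  names4 <- c("N", "CA", "C", "O")
  els <- c("N", "C", "C", "O")
  offs <- rbind(c(0, 0, 0), c(1.46, 0, 0), c(2.0, 1.3, 0), c(2.0, 2.5, 0))
  for (r in seq_len(n_residues)) {
    for (k in 1:4) {
      serial <- serial + 1
      lines <- c(lines, pdb_atom_line("ATOM", serial, names4[k], "ALA", "A",
                                      r, offs[k, 1] + 3.8 * (r - 1),
                                      offs[k, 2], offs[k, 3], els[k]))
    }
  }
  lines <- c(lines, "TER")
  chains <- tibble::tibble(pdb_id = pdb_id, chain = "A",
                           sequence = strrep("A", n_residues))
  ligrows <- list()
  for (i in seq_along(ligand_codes)) {
    code <- ligand_codes[i]
    # first ligand sits 1.4 A from a backbone CA when covalent, else 8 A away
    base_y <- if (covalent && i == 1) 1.4 else 8 + 3 * (i - 1)
    for (k in 1:3) {
      serial <- serial + 1
      lines <- c(lines, pdb_atom_line("HETATM", serial, paste0("C", k), code,
                                      "A", 100 + i, 1.46 + 1.5 * (k - 1),
                                      base_y, 0, "C"))
    }
    ligrows[[i]] <- tibble::tibble(pdb_id = pdb_id, ligand_id = code)
  }
  lines <- c(lines, "END")
  pdb_file <- file.path(dir, paste0(pdb_id, ".pdb"))
  writeLines(lines, pdb_file)
  list(
    record = tibble::tibble(pdb_id = pdb_id, resolution = resolution,
                            r_work = r_work, r_free = r_free, rsr = rsr,
                            rscc = rscc),
    ligands = dplyr::bind_rows(ligrows),
    chains = chains,
    pdb_file = pdb_file
  )
}

pdb_atom_line <- function(type, serial, name, resid, chain, resno, x, y, z,
                          element) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, nm, resid, chain, resno, x, y, z, 1, 20, element)
}
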