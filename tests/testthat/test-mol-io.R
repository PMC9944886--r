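sdf_record <- function(title, coords, elements) {
  c(title, "  fixture", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(coords), 0L),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[, 1], coords[, 2], coords[, 3], elements),
    "M  END", "$$$$")
}

test_that("SDF records sharing a title collapse into one multi-conformer ligand", {
  path <- withr::local_tempfile(fileext = ".sdf")
  xyz <- cbind(c(0, 1.5), 0, 0)
  writeLines(c(sdf_record("LIG1", xyz, c("C", "O")),
               sdf_record("LIG1", xyz + 0.2, c("C", "O"))), path)
  ligs <- read_ligands(path)
  expect_length(ligs, 1)
  expect_equal(n_conformers(ligs[[1]]), 2)
  expect_equal(ligs[[1]]$ligand_id, "LIG1")
})

test_that("distinct SDF titles give distinct single-conformer ligands", {
  path <- withr::local_tempfile(fileext = ".sdf")
  xyz <- cbind(c(0, 1.5), 0, 0)
  writeLines(c(sdf_record("A", xyz, c("C", "C")),
               sdf_record("B", xyz, c("N", "C"))), path)
  ligs <- read_ligands(path)
  expect_length(ligs, 2)
  expect_equal(vapply(ligs, function(l) l$ligand_id, ""), c("A", "B"))
  expect_true(all(vapply(ligs, n_conformers, 1L) == 1))
  # hydrogens retained but flagged
  path2 <- withr::local_tempfile(fileext = ".sdf")
  writeLines(sdf_record("HH", rbind(xyz, c(3, 0, 0)), c("C", "C", "H")), path2)
  cf <- read_ligands(path2)[[1]]$conformers[[1]]
  expect_equal(nrow(cf), 3)
  expect_equal(cf$is_heavy, c(TRUE, TRUE, FALSE))
})

test_that("truncated SDF records raise a parse error naming the record", {
  path <- withr::local_tempfile(fileext = ".sdf")
  good <- sdf_record("OK", cbind(c(0, 1.5), 0, 0), c("C", "C"))
  bad <- c("BROKEN", "  fixture", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", 5L, 0L),
           "    0.0000    0.0000    0.0000 C   0  0",
           "M  END", "$$$$")
  writeLines(c(good, bad), path)
  expect_error(read_ligands(path), "2")
  expect_error(read_ligands(tempfile(fileext = ".sdf")), "not found")
})

test_that("HETATM extraction skips waters and splits chains and instances", {
  cx <- make_toy_complex("1wat", ligand_codes = "LIG",
                         dir = withr::local_tempdir())
  # append waters and a second-chain copy of the ligand
  lines <- readLines(cx$pdb_file)
  end <- which(lines == "END")
  waters <- vapply(1:30, function(i) {
    sprintf("%-6s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            "HETATM", 900 + i, " O  ", "HOH", "A", 200 + i, 30 + i, 0, 0, 1,
            20, "O")
  }, "")
  other <- sprintf("%-6s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   "HETATM", 990, " C1 ", "LIG", "B", 101, 0, 20, 0, 1, 20, "C")
  writeLines(c(lines[1:(end - 1)], waters, other, "END"), cx$pdb_file)
  ligs <- extract_het_ligands(cx$pdb_file)
  expect_length(ligs, 2)
  ids <- vapply(ligs, function(l) l$ligand_id, "")
  expect_setequal(ids, c("LIG_A_101", "LIG_B_101"))
  expect_false(any(grepl("HOH", ids)))
})

test_that("an ATOM-only PDB file yields an empty ligand list", {
  cx <- make_toy_complex("1apo", ligand_codes = character(0),
                         dir = withr::local_tempdir())
  expect_length(extract_het_ligands(cx$pdb_file), 0)
})

test_that("altloc resolution keeps the highest-occupancy copy, ties to A", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "alt.pdb")
  writeLines(c(
    "HETATM    1  C1 ALIG A 101       1.000   0.000   0.000  0.30 20.00           C",
    "HETATM    2  C1 BLIG A 101       2.000   0.000   0.000  0.70 20.00           C",
    "HETATM    3  C2 ALIG A 101       3.000   0.000   0.000  0.50 20.00           C",
    "HETATM    4  C2 BLIG A 101       4.000   0.000   0.000  0.50 20.00           C",
    "END"), path)
  lig <- extract_het_ligands(path)[[1]]
  cf <- lig$conformers[[1]]
  expect_equal(nrow(cf), 2)
  expect_equal(sort(cf$x), c(2, 3))  # occupancy winner, then altloc-A tie
})

test_that("match tables round-trip losslessly at the printed precision", {
  m <- tibble::tibble(
    query_id = c("A", "B", "C"),
    db_id = c("B", "C", "A"),
    tanimoto = c(0.912345678, 0.85, 0.4999999),
    best_conformer_index = c(2L, 1L, 7L),
    best_start_family = c("inertial", "com", "random")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_match_table(m, path)
  back <- read_match_table(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$tanimoto, sort(round(m$tanimoto, 6), decreasing = TRUE))
  expect_identical(readLines(path)[1],
                   "query_id\tdb_id\ttanimoto\tbest_conformer_index\tbest_start_family")
  # writing what was read back reproduces the file byte-for-byte
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_match_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
  # empty table -> header-only file
  write_match_table(m[0, ], path)
  expect_length(readLines(path), 1)
})

test_that("SDF writer round-trips ligands through the reader", {
  lig <- make_toy_ligand("ring", 5, seed = 2, jitter = 0.1, id = "RT")
  two <- new_ligand("RT", list(lig$conformers[[1]],
                               perturb_ligand(lig, seed = 3)$conformers[[1]]))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(two, path)
  back <- read_ligands(path)
  expect_length(back, 1)
  expect_equal(n_conformers(back[[1]]), 2)
  expect_equal(back[[1]]$conformers[[1]]$x, two$conformers[[1]]$x,
               tolerance = 1e-4)
})

test_that("MOL2 files read as single-conformer ligands", {
  path <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "ML1", " 2 1 0 0 0", "SMALL",
               "NO_CHARGES", "", "@<TRIPOS>ATOM",
               "  1 C1  0.000 0.000 0.000 C.3 1 LIG 0.0",
               "  2 O1  1.500 0.000 0.000 O.3 1 LIG 0.0",
               "@<TRIPOS>BOND", "  1 1 2 1"), path)
  ligs <- read_ligands(path)
  expect_length(ligs, 1)
  expect_equal(ligs[[1]]$ligand_id, "ML1")
  expect_equal(ligs[[1]]$conformers[[1]]$element, c("C", "O"))
})
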