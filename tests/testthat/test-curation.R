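toy_meta <- function(pdb_id = "1abc", resolution = 2.0, r_work = 0.18,
                     r_free = 0.22, rsr = 0.1, rscc = 0.95) {
  tibble::tibble(pdb_id = pdb_id, resolution = resolution, r_work = r_work,
                 r_free = r_free, rsr = rsr, rscc = rscc)
}
toy_ligs <- function(pdb_id = "1abc", ligand_id = "XYZ", label = "valid") {
  tibble::tibble(pdb_id = pdb_id, ligand_id = ligand_id, label = label)
}
toy_chains <- function(pdb_id = "1abc") {
  tibble::tibble(pdb_id = pdb_id, chain = "A", sequence = "MKTAYIAK")
}

test_that("resolution cut keeps 2.5 A and discards 2.6 A", {
  meta <- toy_meta(c("good", "bad9"), resolution = c(2.5, 2.6))
  out <- filter_complexes(meta, toy_ligs(c("good", "bad9")),
                          toy_chains(c("good", "bad9")), mode = "standard")
  expect_equal(out$kept$pdb_id, "good")
  expect_match(out$discarded$reason, "resolution")
  # kept and discarded partition the input
  expect_setequal(c(out$kept$pdb_id, out$discarded$pdb_id), meta$pdb_id)
})

test_that("standard mode requires a protein chain and a valid ligand", {
  meta <- toy_meta(c("c1", "c2", "c3"))
  ligs <- dplyr::bind_rows(toy_ligs("c1"),
                           toy_ligs("c2", "SO4", label = "invalid"),
                           toy_ligs("c3"))
  chains <- toy_chains(c("c1", "c2"))
  out <- filter_complexes(meta, ligs, chains, mode = "standard")
  expect_equal(out$kept$pdb_id, "c1")
  expect_equal(out$discarded$reason[out$discarded$pdb_id == "c2"],
               "no valid ligand")
  expect_equal(out$discarded$reason[out$discarded$pdb_id == "c3"],
               "no protein chain")
})

test_that("hiq boundaries are inclusive exactly as stated", {
  meta <- dplyr::bind_rows(
    toy_meta("edge", r_work = 0.18, r_free = 0.23, rsr = 0.2, rscc = 0.90),
    toy_meta("gap6", r_work = 0.18, r_free = 0.24),   # r_free - r_work = 0.06
    toy_meta("rsrX", rsr = 0.21),
    toy_meta("rscX", rscc = 0.89)
  )
  ids <- meta$pdb_id
  out <- filter_complexes(meta, toy_ligs(ids), toy_chains(ids), mode = "hiq")
  expect_equal(out$kept$pdb_id, "edge")
  expect_match(out$discarded$reason[out$discarded$pdb_id == "gap6"], "r_free")
  expect_match(out$discarded$reason[out$discarded$pdb_id == "rsrX"],
               "real-space R")
  expect_match(out$discarded$reason[out$discarded$pdb_id == "rscX"], "RSCC")
  # a missing hiq field is a record-level discard, not an error
  na_meta <- toy_meta("miss")
  na_meta$rscc <- NA_real_
  out2 <- filter_complexes(na_meta, toy_ligs("miss"), toy_chains("miss"),
                           mode = "hiq")
  expect_match(out2$discarded$reason, "missing field")
})

test_that("ligand validity follows the lists with covalency override", {
  expect_equal(classify_ligand("SO4")$label, "invalid")
  expect_equal(classify_ligand("HEM")$label, "part_of_protein")
  expect_equal(classify_ligand("STI")$label, "valid")
  cov <- classify_ligand("STI", covalent = TRUE)
  expect_equal(cov$label, "part_of_protein")
  expect_match(cov$reason, "covalently bound")
  # part-of-protein listing outranks the invalid list
  lists <- default_validity_lists()
  lists$invalid <- c(lists$invalid, "HEM")
  expect_equal(classify_ligand("HEM", lists = lists)$label,
               "part_of_protein")
  tab <- classify_ligands(tibble::tibble(pdb_id = "1abc",
                                         ligand_id = c("SO4", "STI"),
                                         covalent = c(FALSE, FALSE)))
  expect_equal(tab$label, c("invalid", "valid"))
})

test_that("covalency detection uses covalent radii plus tolerance", {
  lig <- tibble::tibble(element = "C", x = 0, y = 0, z = 0)
  prot_near <- tibble::tibble(element = "C", x = 1.4, y = 0, z = 0)
  prot_far <- tibble::tibble(element = "C", x = 4.0, y = 0, z = 0)
  expect_true(detect_covalent(lig, prot_near))    # 1.4 < 0.77+0.77+0.4
  expect_false(detect_covalent(lig, prot_far))
  expect_false(detect_covalent(lig, prot_near[0, ]))
  # boundary: contact exactly at the cutoff counts as covalent
  at_cut <- tibble::tibble(element = "C", x = 1.94, y = 0, z = 0)
  expect_true(detect_covalent(lig, at_cut))
  expect_false(detect_covalent(lig, tibble::tibble(element = "C", x = 1.95,
                                                   y = 0, z = 0)))
})

test_that("sequence identity handles the trivial and oracle cases", {
  expect_equal(pairwise_identity("MKTAYIAK", "MKTAYIAK"), 1.0)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  expect_equal(pairwise_identity("MKTAYIAK", "KTAYIAK"), 1.0)  # free end gap
  # X never counts as a match
  expect_equal(pairwise_identity("AXAA", "AXAA"), 0.75)
  expect_error(pairwise_identity("", "AAA"), "non-empty")
  expect_error(pairwise_identity("AB1", "AAA"), "non-amino-acid")
  # unambiguous internal-deletion case, worked by hand: the diagonal
  # alignment (5 matches, no gap) beats the gapped one (9 - 5 = 4)
  expect_equal(pairwise_identity("MKTAYIAKQR", "MKTAYAKQR"), 5 / 9)
  # insertion inside a perfect repeat: mismatching one column beats a gap
  expect_equal(pairwise_identity("WWWWWWWWWW", "WWWWWCWWWWW"), 9 / 10)
})

test_that("alignment scores equal an independent recursive oracle", {
  withr::with_seed(123, {
    for (k in 1:12) {
      a <- random_aa_seq(sample(4:12, 1))
      b <- random_aa_seq(sample(4:12, 1))
      got <- ligshape:::align_overlap(ligshape:::seq_to_int(a, "a"),
                                      ligshape:::seq_to_int(b, "b"))
      expect_equal(got$score, oracle_align_score(a, b),
                   info = paste(a, b))
      # symmetry of the identity itself
      expect_equal(pairwise_identity(a, b), pairwise_identity(b, a),
                   info = paste(a, b))
    }
  })
})

test_that("families are single-linkage components with leaders at 90%", {
  # sequences engineered so identity(A,B) and identity(B,C) >= 0.9 but
  # identity(A,C) < 0.9: single linkage still joins all three
  base <- "MKTAYIAKQRQISFVKSHFSRQLEE"
  sA <- base
  sB <- paste0(substr(base, 1, 23), "DD")          # 2 substitutions vs A
  sC <- paste0(substr(base, 1, 21), "DDDD")        # 4 vs A, 2 vs B
  expect_gte(pairwise_identity(sA, sB), 0.9)
  expect_gte(pairwise_identity(sB, sC), 0.9)
  expect_lt(pairwise_identity(sA, sC), 0.9)
  chains <- tibble::tibble(pdb_id = c("pdbA", "pdbB", "pdbC"), chain = "A",
                           sequence = c(sA, sB, sC))
  fam <- build_families(chains, threshold = 0.90)
  expect_equal(length(unique(fam$family_id)), 1)
  expect_equal(sum(fam$is_leader), 1)
  # unrelated sequence stays a singleton
  chains2 <- dplyr::bind_rows(chains,
                              tibble::tibble(pdb_id = "pdbZ", chain = "A",
                                             sequence = "GGGGGGGGGGPPPPPPPPPP"))
  fam2 <- build_families(chains2, threshold = 0.90)
  expect_equal(length(unique(fam2$family_id)), 2)
  expect_equal(sum(fam2$member == "pdbZ" & fam2$is_leader), 1)
})

test_that("lowering the identity threshold never splits a family", {
  withr::with_seed(7, {
    base <- random_aa_seq(30)
    mut <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      idx <- sample(seq_along(ch), k)
      ch[idx] <- sample(c("A", "G", "P", "W"), k, replace = TRUE)
      paste(ch, collapse = "")
    }
    chains <- tibble::tibble(
      pdb_id = sprintf("p%02d", 1:6), chain = "A",
      sequence = c(base, mut(base, 2), mut(base, 8), mut(base, 12),
                   random_aa_seq(30), random_aa_seq(25)))
  })
  f90 <- build_families(chains, 0.90)
  f50 <- build_families(chains, 0.50)
  # members sharing a family at 0.90 still share one at 0.50
  for (f in unique(f90$family_id)) {
    members <- f90$member[f90$family_id == f]
    expect_equal(length(unique(f50$family_id[f50$member %in% members])), 1)
  }
  # no leaders below 0.90
  expect_equal(sum(f50$is_leader), 0)
  # families partition the complex set at every threshold
  expect_setequal(f50$member, chains$pdb_id)
  expect_setequal(f90$member, chains$pdb_id)
})

test_that("leaders prefer tightest affinity, then resolution, then id", {
  affinities <- normalize_affinities(tibble::tibble(
    pdb_id = c("p1", "p2"), ligand_id = "L", type = "Kd", relation = "=",
    value = c(10, 1), unit = "nM"))
  complexes <- tibble::tibble(pdb_id = c("p1", "p2", "p3"),
                              resolution = c(1.2, 2.0, 1.5))
  expect_equal(select_leader(c("p1", "p2"), complexes, affinities), "p2")
  # members without affinity rank after all with affinity
  expect_equal(select_leader(c("p1", "p3"), complexes, affinities), "p1")
  # no affinity anywhere: best resolution wins
  expect_equal(select_leader(c("p1", "p3"), complexes, NULL), "p1")
  # full tie: lexicographically smallest id
  expect_equal(select_leader(c("pB", "pA"), NULL, NULL), "pA")
})
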