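#' Pairwise sequence identity by end-gap-free global alignment
#'
#' An in-package global aligner over the amino-acid alphabet scores match
#' +1, mismatch 0, gap open -5, gap extension -1 (an L-long gap costs
#' 5 + (L - 1)), with leading and trailing gaps free. Identity is the number
#' of identical aligned columns divided by the alignment length (the aligned
#' region between the first and last paired residues; free end overhangs do
#' not count). The unknown residue `X` is allowed but never counts as a
#' match. Traceback ties are broken deterministically: diagonal first, then
#' the gap consuming a residue of `seq_a` ("up"), then `seq_b`.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings.
#' @return Identity fraction in \[0, 1\].
#' @examples
#' pairwise_identity("MKTAYIAK", "MKTAYIAK")  # 1
#' pairwise_identity("AAAA", "CCCC")          # 0
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  # canonical argument order: with a zero mismatch score, distinct optimal
  # alignments can tie, and the traceback preference would otherwise let
  # identity(a, b) differ from identity(b, a)
  if (seq_b < seq_a) {
    tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp
  }
  a <- seq_to_int(seq_a, "seq_a")
  b <- seq_to_int(seq_b, "seq_b")
  aln <- align_overlap(a, b)
  if (aln$length == 0) return(0)
  aln$matches / aln$length
}

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X")

seq_to_int <- function(seq, what) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq)) {
    stop(what, " must be a non-empty sequence string")
  }
  ch <- strsplit(toupper(seq), "")[[1]]
  idx <- match(ch, AA_ALPHABET)
  if (anyNA(idx)) {
    stop(what, " contains non-amino-acid letters: ",
         paste(unique(ch[is.na(idx)]), collapse = ", "))
  }
  idx
}

# Gotoh affine-gap DP with free end gaps. States: M (a_i aligned to b_j),
# Ix (gap in b, consuming a_i), Iy (gap in a, consuming b_j). Returns the
# match count and column count of the aligned (non-overhang) region.
align_overlap <- function(a, b, match = 1, mismatch = 0, gap_open = 5,
                          gap_extend = 1) {
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0  # free leading gaps: an alignment may start at any boundary cell
  M[, 1] <- 0
  xi <- AA_ALPHABET[a] != "X"  # X never scores as a match
  for (i in seq_len(n)) {
    sub <- ifelse(b == a[i] & xi[i], match, mismatch)
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- sub[j] + max(M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open, Ix[i, j + 1] - gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open, Iy[i + 1, j] - gap_extend)
    }
  }
  # free trailing gaps: terminate at the best cell on the last row or column
  best <- c(NEG, 0L, 0L, 0L)  # score, i, j, state (1=M, 2=Ix, 3=Iy)
  consider <- function(i, j) {
    for (s in 1:3) {
      sc <- switch(s, M[i + 1, j + 1], Ix[i + 1, j + 1], Iy[i + 1, j + 1])
      if (sc > best[1]) best <<- c(sc, i, j, s)
    }
  }
  for (i in 0:n) consider(i, m)
  for (j in 0:(m - 1)) consider(n, j)
  i <- best[2]; j <- best[3]; s <- best[4]
  matches <- 0L; len <- 0L
  while (i > 0 && j > 0) {
    if (s == 1) {
      sc <- M[i + 1, j + 1]
      if (i == 0 || j == 0) break
      if (a[i] == b[j] && AA_ALPHABET[a[i]] != "X") matches <- matches + 1L
      len <- len + 1L
      prev <- sc - ifelse(b[j] == a[i] & AA_ALPHABET[a[i]] != "X", 1, 0)
      # tie order: diagonal (M), then up (Ix), then left (Iy)
      if (i == 1 || j == 1) {  # reached a free boundary: alignment starts here
        i <- i - 1L; j <- j - 1L
        break
      } else if (near(prev, M[i, j])) { s <- 1 } else if (near(prev, Ix[i, j])) { s <- 2 } else { s <- 3 }
      i <- i - 1L; j <- j - 1L
    } else if (s == 2) {
      len <- len + 1L
      sc <- Ix[i + 1, j + 1]
      if (near(sc, M[i, j + 1] - 5)) s <- 1 else s <- 2
      i <- i - 1L
    } else {
      len <- len + 1L
      sc <- Iy[i + 1, j + 1]
      if (near(sc, M[i + 1, j] - 5)) s <- 1 else s <- 3
      j <- j - 1L
    }
  }
  list(matches = matches, length = len, score = best[1])
}

near <- function(x, y) abs(x - y) < 1e-9

#' Group complexes into sequence-identity families
#'
#' Pairwise identities are computed on each complex's longest protein chain
#' and complexes are joined into families by single-linkage: a family is a
#' connected component of the graph whose edges are pairs with identity at
#' or above the threshold. Lowering the threshold can only merge families,
#' never split them. Leaders are assigned at the 0.90 threshold only (see
#' [select_leader()]); the looser 0.70/0.50 groupings are offered for
#' homologous-set analysis without leaders.
#'
#' @param chains Tibble with columns `pdb_id`, `chain`, `sequence`.
#' @param threshold One of 0.90, 0.70, 0.50.
#' @param complexes Optional complex metadata (`pdb_id`, `resolution`) used
#'   for leader selection.
#' @param affinities Optional normalised affinity tibble used for leader
#'   selection.
#' @return Tibble with columns `family_id`, `threshold`, `member`
#'   (pdb_id), `is_leader`.
#' @export
build_families <- function(chains, threshold = 0.90, complexes = NULL,
                           affinities = NULL) {
  if (!threshold %in% c(0.90, 0.70, 0.50)) {
    stop("threshold must be one of 0.90, 0.70, 0.50")
  }
  longest <- chains |>
    dplyr::mutate(len = nchar(.data$sequence)) |>
    dplyr::group_by(.data$pdb_id) |>
    dplyr::arrange(dplyr::desc(.data$len), .data$chain, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  ids <- sort(longest$pdb_id)
  seqs <- stats::setNames(longest$sequence, longest$pdb_id)[ids]
  edges <- NULL
  if (length(ids) >= 2) {
    comb <- utils::combn(ids, 2)
    hit <- vapply(seq_len(ncol(comb)), function(k) {
      pairwise_identity(seqs[[comb[1, k]]], seqs[[comb[2, k]]]) >= threshold
    }, logical(1))
    edges <- comb[, hit, drop = FALSE]
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(ids)
  if (!is.null(edges) && ncol(edges) > 0) {
    g <- igraph::add_edges(g, as.vector(edges))
  }
  comp <- igraph::components(g)
  fam <- tibble::tibble(member = ids,
                        family_id = as.integer(comp$membership[ids]),
                        threshold = threshold)
  fam <- dplyr::arrange(fam, .data$family_id, .data$member)
  fam$is_leader <- FALSE
  if (threshold == 0.90) {
    for (f in unique(fam$family_id)) {
      members <- fam$member[fam$family_id == f]
      leader <- select_leader(members, complexes = complexes,
                              affinities = affinities)
      fam$is_leader[fam$family_id == f & fam$member == leader] <- TRUE
    }
  }
  dplyr::relocate(fam, "family_id", "threshold", "member", "is_leader")
}

#' Select the leader of a sequence family
#'
#' The leader is the member with the tightest preferred binding affinity
#' (smallest molar value after the Kd > Ki > IC50 preference); members
#' without any affinity rank after all members that have one. Ties fall
#' back to the best (smallest) resolution, and finally to the
#' lexicographically smallest PDB id.
#'
#' @param members Character vector of pdb_ids.
#' @param complexes Optional tibble with `pdb_id`, `resolution`.
#' @param affinities Optional normalised affinity tibble.
#' @return The leader's pdb_id.
#' @export
select_leader <- function(members, complexes = NULL, affinities = NULL) {
  stopifnot(length(members) >= 1)
  key <- purrr::map_dfr(members, function(m) {
    molar <- Inf
    if (!is.null(affinities)) {
      pref <- select_preferred(dplyr::filter(affinities, .data$pdb_id == m))
      if (!is.null(pref)) molar <- pref$molar_value
    }
    res <- Inf
    if (!is.null(complexes)) {
      hit <- complexes$resolution[complexes$pdb_id == m]
      if (length(hit) > 0 && is.finite(hit[1])) res <- hit[1]
    }
    tibble::tibble(pdb_id = m, molar = molar, resolution = res)
  })
  key <- dplyr::arrange(key, .data$molar, .data$resolution, .data$pdb_id)
  key$pdb_id[1]
}

#' Read protein chains from a FASTA file
#'
#' Headers are expected as `>pdbid_chain` (anything after the first
#' underscore is the chain id; a header without an underscore gets chain
#' `"A"`).
#'
#' @param path FASTA file path.
#' @return Tibble with columns `pdb_id`, `chain`, `sequence`.
#' @export
read_chain_fasta <- function(path) {
  fa <- bio3d::read.fasta(path)
  ids <- names(fa$id) %||% fa$id
  seqs <- apply(fa$ali, 1, function(r) paste(r[r != "-"], collapse = ""))
  tibble::tibble(
    pdb_id = sub("_.*$", "", ids),
    chain = ifelse(grepl("_", ids), sub("^[^_]*_", "", ids), "A"),
    sequence = toupper(unname(seqs))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
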