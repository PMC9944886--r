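# Independent oracles used across tests.

# Recursive, memoised affine-gap aligner with free end gaps: an
# implementation of the same scoring contract as pairwise_identity written
# along a different route (top-down recursion over explicit states rather
# than the package's bottom-up table fill). Returns the optimal score,
# which is invariant under traceback tie-breaking.
oracle_align_score <- function(seq_a, seq_b, match = 1, mismatch = 0,
                               gap_open = 5, gap_extend = 1) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  n <- length(a); m <- length(b)
  memo <- new.env(parent = emptyenv())
  # best score of an alignment path ending at (i, j) in state st
  sc <- function(i, j, st) {
    if (i == 0 || j == 0) {
      return(if (st == "M") 0 else -Inf)  # free leading overhang
    }
    key <- paste(i, j, st)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (st == "M") {
      s <- if (a[i] == b[j] && a[i] != "X") match else mismatch
      s + max(sc(i - 1, j - 1, "M"), sc(i - 1, j - 1, "Ix"),
              sc(i - 1, j - 1, "Iy"))
    } else if (st == "Ix") {
      max(sc(i - 1, j, "M") - gap_open, sc(i - 1, j, "Ix") - gap_extend)
    } else {
      max(sc(i, j - 1, "M") - gap_open, sc(i, j - 1, "Iy") - gap_extend)
    }
    memo[[key]] <- val
    val
  }
  best <- 0  # empty alignment is always available
  for (i in 0:n) for (st in c("M", "Ix", "Iy")) {
    best <- max(best, sc(i, m, st))
  }
  for (j in 0:(m - 1)) for (st in c("M", "Ix", "Iy")) {
    best <- max(best, sc(n, j, st))
  }
  best
}

# in-package equivalent of the oracle score: matches * 1 + mismatches * 0 -
# gap costs, recovered from the aligned-region statistics is not exposed, so
# tests that need score equality recompute identity cases instead.

random_aa_seq <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I"), n,
               replace = TRUE), collapse = "")
}

# a generic (jittered, asymmetric) toy shape for property tests
generic_shape <- function(n = 5, seed = 1, element = "C") {
  lig <- make_toy_ligand("linear", n, element = element, seed = seed,
                         jitter = 0.3)
  build_shape(lig$conformers[[1]])
}

random_rigid <- function(seed) {
  withr::with_seed(seed, {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    rigid_transform(c(cos(0.4), sin(0.4) * ax), stats::rnorm(3))
  })
}
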