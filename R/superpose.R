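#' Convergence and protocol settings for shape superposition
#'
#' @param tol Relative overlap-change tolerance for convergence.
#' @param max_iter Iteration cap for the local optimizer.
#' @param n_random_starts Number of random-placement starting poses.
#' @param seed Integer seed governing all stochastic behaviour (random
#'   starts). Every randomised step in the package flows from one explicit
#'   seed so full runs are bit-reproducible.
#' @param radii Element radius table used when conformers are turned into
#'   shapes.
#' @param include_hydrogens Include hydrogens when building shapes?
#' @param max_conformers Conformer-ensemble cap; ensembles longer than this
#'   are truncated in input order.
#' @return A list of class `shape_settings`.
#' @export
shape_settings <- function(tol = 1e-6, max_iter = 200, n_random_starts = 8,
                           seed = 0, radii = default_radius_table(),
                           include_hydrogens = FALSE, max_conformers = 64) {
  stopifnot(tol > 0, max_iter >= 1, n_random_starts >= 1, max_conformers >= 1)
  structure(list(tol = tol, max_iter = max_iter,
                 n_random_starts = n_random_starts, seed = as.integer(seed),
                 radii = radii, include_hydrogens = include_hydrogens,
                 max_conformers = max_conformers),
            class = "shape_settings")
}

#' Center-of-mass alignment start
#'
#' Identity rotation with the translation that maps the query's center of
#' mass onto the reference's. Centers of mass are unweighted means over the
#' Gaussian centers.
#'
#' @param query,reference `gaussian_shape` objects; the transform applies to
#'   the query.
#' @return A `rigid_transform`.
#' @export
com_align <- function(query, reference) {
  rigid_transform(translation = shape_com(reference) - shape_com(query))
}

#' Generate starting poses for superposition
#'
#' Two families of deterministic-by-seed start transforms for the query:
#'
#' * `random`: `n` poses, each placing the query center of mass on a
#'   uniformly chosen reference atom center with a uniformly random
#'   rotation. This concentrates starts where overlap is attainable and
#'   accounts for ligands of very different sizes.
#' * `inertial`: exactly 4 poses aligning the principal axes of the two
#'   shapes' second-moment tensors, one per right-handed sign-flip
#'   combination, with centers of mass superimposed. A deterministic start
#'   family that frequently lands in the global basin.
#'
#' @param query,reference `gaussian_shape` objects.
#' @param mode `"random"` or `"inertial"`.
#' @param n Number of random starts (ignored for `inertial`, which always
#'   yields 4).
#' @param seed Integer seed (random mode).
#' @return List of `rigid_transform`s (applied to the query).
#' @export
generate_starts <- function(query, reference, mode = c("random", "inertial"),
                            n = 8, seed = 0) {
  mode <- match.arg(mode)
  qcom <- shape_com(query)
  rcom <- shape_com(reference)
  if (mode == "random") {
    if (n < 1) stop("n must be >= 1 for random starts")
    withr::with_seed(as.integer(seed), {
      lapply(seq_len(n), function(i) {
        target <- reference$centers[sample.int(nrow(reference$centers), 1), ]
        q <- random_unit_quaternion()
        R <- rotation_matrix(rigid_transform(q))
        rigid_transform(q, target - as.numeric(R %*% qcom))
      })
    })
  } else {
    Eq <- principal_axes(query$centers)
    Er <- principal_axes(reference$centers)
    flips <- list(diag(3), diag(c(1, -1, -1)), diag(c(-1, 1, -1)),
                  diag(c(-1, -1, 1)))
    lapply(flips, function(S) {
      R <- Er %*% S %*% t(Eq)
      rigid_transform(quat_from_matrix(R), rcom - as.numeric(R %*% qcom))
    })
  }
}

# right-handed principal axes of the (unweighted) second-moment tensor,
# columns ordered by decreasing moment; sign convention: largest-magnitude
# component of each axis positive, third axis forced to e1 x e2
principal_axes <- function(centers) {
  cc <- sweep(centers, 2, colMeans(centers))
  M <- crossprod(cc) / nrow(cc)
  E <- eigen(M, symmetric = TRUE)$vectors
  for (j in 1:2) {
    k <- which.max(abs(E[, j]))
    if (E[k, j] < 0) E[, j] <- -E[, j]
  }
  E[, 3] <- c(E[2, 1] * E[3, 2] - E[3, 1] * E[2, 2],
              E[3, 1] * E[1, 2] - E[1, 1] * E[3, 2],
              E[1, 1] * E[2, 2] - E[2, 1] * E[1, 2])
  E
}

#' Locally maximise overlap volume over rigid transforms
#'
#' Solid-body optimisation: derivative-free local ascent (Nelder-Mead over
#' the 6-DOF manifold, rotation parameterised by a rotation vector applied
#' about the query's current center of mass) on [overlap_volume()] starting
#' from `start`. The returned overlap is never below the starting overlap.
#'
#' @param query,reference `gaussian_shape` objects; the optimised transform
#'   applies to the query.
#' @param start Starting `rigid_transform`.
#' @param settings A [shape_settings()] object (only `tol` and `max_iter`
#'   are used here).
#' @return An object of class `superposition_result` with fields
#'   `transform`, `overlap` (A^3), `tanimoto`, `start_family`,
#'   `start_index`, `iterations`, `converged`.
#' @export
optimize_overlap <- function(query, reference, start = com_align(query, reference),
                             settings = shape_settings()) {
  pivot <- colMeans(apply_transform(start, query$centers))
  objective <- function(par) {
    tr <- delta_transform(par, pivot, start)
    O <- overlap_volume(reference, query, tr)
    if (!is.finite(O)) {
      stop("non-finite overlap during ascent (par = ",
           paste(format(par, digits = 4), collapse = ", "), ")")
    }
    -O
  }
  opt <- stats::optim(rep(0, 6), objective, method = "Nelder-Mead",
                      control = list(maxit = settings$max_iter,
                                     reltol = settings$tol))
  best <- delta_transform(opt$par, pivot, start)
  O <- overlap_volume(reference, query, best)
  O0 <- overlap_volume(reference, query, start)
  if (O < O0) {  # never report worse than the start pose
    best <- start
    O <- O0
  }
  tan <- O / (query$self_overlap + reference$self_overlap - O)
  structure(list(transform = best, overlap = O, tanimoto = tan,
                 start_family = NA_character_, start_index = NA_integer_,
                 iterations = unname(opt$counts["function"]),
                 converged = opt$convergence == 0),
            class = "superposition_result")
}

# perturbation (rotation vector w, translation t) composed on top of `start`,
# rotating about `pivot` so rotation and translation stay decoupled
delta_transform <- function(par, pivot, start) {
  q <- quat_from_rotvec(par[1:3])
  R <- rotation_matrix(rigid_transform(q))
  delta <- rigid_transform(q, pivot + par[4:6] - as.numeric(R %*% pivot))
  compose_transforms(delta, start)
}

#' @export
print.superposition_result <- function(x, ...) {
  cat("<superposition_result>\n")
  cat("  tanimoto:", format(x$tanimoto, digits = 6),
      " overlap:", format(x$overlap, digits = 6), "A^3\n")
  cat("  start:", x$start_family,
      if (!is.na(x$start_index)) paste0("#", x$start_index) else "",
      " iterations:", x$iterations,
      " converged:", x$converged, "\n")
  invisible(x)
}
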