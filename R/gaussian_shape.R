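#' Default van der Waals radius table
#'
#' Hard-sphere radii (Angstroms) used to calibrate the atomic Gaussian
#' exponents. The table is a named numeric vector keyed by element symbol and
#' can be replaced or extended by the user; elements missing from the table
#' are a hard error when building a shape, never silently defaulted, because
#' the overlap volumes (and hence every Tanimoto) depend directly on the
#' radius.
#'
#' @return Named numeric vector of radii in Angstroms.
#' @export
default_radius_table <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Se = 1.90)
}

#' Read a radius table from a two-column text file
#'
#' Lines are `element radius` (whitespace separated); `#` starts a comment.
#'
#' @param path Path to the table.
#' @return Named numeric vector of radii in Angstroms.
#' @export
read_radius_table <- function(path) {
  df <- utils::read.table(path, col.names = c("element", "radius"),
                          comment.char = "#", stringsAsFactors = FALSE)
  if (any(df$radius <= 0)) stop("radius table contains non-positive radii")
  stats::setNames(df$radius, df$element)
}

#' Build a Gaussian shape from a conformer
#'
#' The molecular volume is modelled as a sum of atom-centred isotropic
#' Gaussians, `f(r) = sum_i p * exp(-alpha_i |r - c_i|^2)`. Each exponent is
#' calibrated so that the isolated-atom density integrates to the hard-sphere
#' volume `(4/3) pi r^3`, which gives the closed form
#' `alpha = pi * (3 p / (4 pi r^3))^(2/3)`. With this density, self- and
#' cross-overlap volumes (`I` and `O` terms) are exact double sums of
#' Gaussian product integrals -- no grid and no truncated
#' inclusion-exclusion.
#'
#' Hydrogens are excluded by default; heavy-atom shape comparison is the
#' usual convention for shape screening.
#'
#' @param atoms A data frame of atoms with columns `element`, `x`, `y`, `z`
#'   (a conformer as returned by [read_ligands()] or [make_toy_ligand()]).
#' @param radii Named radius table (Angstroms), see [default_radius_table()].
#' @param include_hydrogens Include H atoms in the density? Default `FALSE`.
#' @param prefactor Gaussian amplitude `p`, shared by all atoms. The default
#'   `2 * sqrt(2)` (approx. 2.828) is the conventional value for
#'   hard-sphere-calibrated Gaussian atoms.
#' @return An object of class `gaussian_shape` with fields `centers`
#'   (n x 3 matrix), `alphas`, `prefactor` and the cached analytic
#'   `self_overlap` (Angstroms^3).
#' @examples
#' lig <- make_toy_ligand("linear", 4)
#' build_shape(lig$conformers[[1]])
#' @export
build_shape <- function(atoms, radii = default_radius_table(),
                        include_hydrogens = FALSE,
                        prefactor = 2 * sqrt(2)) {
  stopifnot(is.data.frame(atoms),
            all(c("element", "x", "y", "z") %in% names(atoms)))
  el <- as.character(atoms$element)
  keep <- if (include_hydrogens) rep(TRUE, length(el)) else el != "H"
  el <- el[keep]
  if (length(el) == 0) {
    stop("degenerate input: no atoms available for shape construction ",
         "(conformer has no ", if (include_hydrogens) "atoms" else "heavy atoms", ")")
  }
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown) > 0) {
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "),
         " -- extend the radius table rather than relying on a default")
  }
  centers <- as.matrix(atoms[keep, c("x", "y", "z")])
  if (!all(is.finite(centers))) stop("non-finite atomic coordinates")
  dimnames(centers) <- NULL
  r <- radii[el]
  alphas <- pi * (3 * prefactor / (4 * pi * r^3))^(2 / 3)
  shape <- structure(
    list(centers = centers, alphas = unname(alphas), prefactor = prefactor,
         self_overlap = NA_real_),
    class = "gaussian_shape"
  )
  shape$self_overlap <- gaussian_cross_sum(shape, shape)
  shape
}

#' @export
print.gaussian_shape <- function(x, ...) {
  cat("<gaussian_shape>", nrow(x$centers), "Gaussian centers\n")
  cat("  prefactor p =", format(x$prefactor, digits = 6),
      " self-overlap I_f =", format(x$self_overlap, digits = 8), "A^3\n")
  invisible(x)
}

# exact double sum of pairwise Gaussian product integrals between the atoms
# of A and of B (B already in its final frame):
#   int pA e^{-a|r-cA|^2} pB e^{-b|r-cB|^2} dV
#     = pA pB (pi/(a+b))^{3/2} exp(-a b/(a+b) |cA-cB|^2)
gaussian_cross_sum <- function(A, B, B_centers = B$centers) {
  a <- A$alphas
  b <- B$alphas
  d2 <- outer(rowSums(A$centers^2), rowSums(B_centers^2), `+`) -
    2 * A$centers %*% t(B_centers)
  d2[d2 < 0] <- 0
  asum <- outer(a, b, `+`)
  aprod <- outer(a, b, `*`)
  sum(A$prefactor * B$prefactor * (pi / asum)^1.5 * exp(-(aprod / asum) * d2))
}

#' Overlap volume of two Gaussian shapes
#'
#' The overlap term `O_{f,g} = int f g dV`, evaluated as the exact analytic
#' double sum of pairwise Gaussian product integrals after applying
#' `transform` to `B`. Symmetric under swapping the two shapes (with the
#' inverse transform) and always non-negative.
#'
#' @param A,B `gaussian_shape` objects.
#' @param transform `rigid_transform` applied to `B` before integration.
#' @return Overlap volume in Angstroms^3.
#' @export
overlap_volume <- function(A, B, transform = rigid_identity()) {
  stopifnot(inherits(A, "gaussian_shape"), inherits(B, "gaussian_shape"),
            inherits(transform, "rigid_transform"))
  gaussian_cross_sum(A, B, B_centers = apply_transform(transform, B$centers))
}

#' Shape Tanimoto coefficient
#'
#' `O / (I_A + I_B - O)` where `O` is the cross-overlap volume and the `I`
#' terms are the cached self-overlaps: the volumetric intersection over
#' union. Equals 1 exactly when the two densities coincide.
#'
#' @inheritParams overlap_volume
#' @return Dimensionless value in (0, 1].
#' @export
shape_tanimoto <- function(A, B, transform = rigid_identity()) {
  O <- overlap_volume(A, B, transform)
  O / (A$self_overlap + B$self_overlap - O)
}

#' Shape dissimilarity (mismatch volume)
#'
#' The integrated squared density mismatch `int (f - g)^2 dV` expanded to the
#' closed form `I_A + I_B - 2 O`. For hard (0/1) characteristic functions
#' this equals the integrated absolute mismatch volume; for Gaussian
#' densities it is its natural analytic analogue, and it relates to the
#' Tanimoto `T` by `(I_A + I_B) (1 - T) / (1 + T)`. Zero iff the densities
#' coincide.
#'
#' @inheritParams overlap_volume
#' @return Mismatch volume in Angstroms^3 (non-negative).
#' @export
shape_dissimilarity <- function(A, B, transform = rigid_identity()) {
  A$self_overlap + B$self_overlap - 2 * overlap_volume(A, B, transform)
}

#' Brute-force grid estimate of the overlap volume
#'
#' Riemann-sum evaluation of `int f g dV` on a regular grid; an independent
#' numerical oracle for the analytic [overlap_volume()]. The grid covers the
#' union bounding box of both center sets padded by at least four standard
#' deviations of the widest Gaussian, so truncation error is negligible
#' relative to the discretisation error.
#'
#' @inheritParams overlap_volume
#' @param spacing Grid spacing in Angstroms.
#' @return Estimated overlap volume in Angstroms^3.
#' @export
grid_overlap_oracle <- function(A, B, transform = rigid_identity(),
                                spacing = 0.1) {
  stopifnot(spacing > 0)
  Bc <- apply_transform(transform, B$centers)
  pad <- 4 / sqrt(2 * min(c(A$alphas, B$alphas)))
  allc <- rbind(A$centers, Bc)
  lo <- apply(allc, 2, min) - pad
  hi <- apply(allc, 2, max) + pad
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  density_on_grid <- function(centers, alphas, p) {
    val <- 0
    for (i in seq_along(alphas)) {
      ex <- exp(-alphas[i] * (gx - centers[i, 1])^2)
      ey <- exp(-alphas[i] * (gy - centers[i, 2])^2)
      ez <- exp(-alphas[i] * (gz - centers[i, 3])^2)
      val <- val + p * (ex %o% ey) %o% ez
    }
    val
  }
  f <- density_on_grid(A$centers, A$alphas, A$prefactor)
  g <- density_on_grid(Bc, B$alphas, B$prefactor)
  sum(f * g) * spacing^3
}

#' Center of mass of a Gaussian shape
#'
#' Unweighted mean of the Gaussian centers.
#'
#' @param shape A `gaussian_shape`.
#' @return Numeric length-3 coordinates (Angstroms).
#' @export
shape_com <- function(shape) colMeans(shape$centers)
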