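# Van der Waals radii (Angstrom), united-atom style table. Overridable via
# the `radii` argument of compute_sasa(); unknown elements are an error so a
# bad radius can never silently shrink a surface.
.default_vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                        SE = 1.90)

#' Deterministic Fibonacci sphere lattice
#'
#' `n` near-uniform points on the unit sphere from the golden-angle spiral.
#' Deterministic (no RNG), so surface areas computed from it are bitwise
#' reproducible.
#'
#' @param n Number of points (>= 1).
#' @return An `n` x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)  # golden angle
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

.atom_radii <- function(atoms, radii = NULL) {
  tab <- .default_vdw_radii
  if (!is.null(radii)) tab[names(radii)] <- radii
  r <- unname(tab[atoms$element])
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    stop("no van der Waals radius for element '", atoms$element[bad],
         "' (atom ", atoms$atom[bad], " in residue ", atoms$resid[bad], " ",
         atoms$chain[bad], atoms$resno[bad],
         "); supply it via the radii argument", call. = FALSE)
  }
  r
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA over heavy atoms with a probe-inflated sphere sampled on a
#' deterministic Fibonacci lattice: a lattice point survives if it lies
#' outside every neighbouring atom's inflated sphere, and the accessible
#' fraction scales the closed-form sphere area 4*pi*(r + probe)^2.
#'
#' @param atoms An atom data frame (the `atoms` element of a `complex_model`,
#'   or any data frame with `element`, `x`, `y`, `z` and, for error messages,
#'   `atom`, `resid`, `chain`, `resno`). Hydrogens are dropped if an
#'   `is_heavy` column is present.
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points Lattice points per atom (default 960).
#' @param radii Named numeric vector of per-element radius overrides in
#'   Angstrom, merged over the built-in table
#'   (C 1.70, N 1.55, O 1.52, S 1.80).
#' @return A `sasa_result`: list with `area` (per-atom SASA, Angstrom^2),
#'   `probe`, `n_points`, `radii_label`.
#' @examples
#' a <- data.frame(element = "C", x = 0, y = 0, z = 0,
#'                 atom = "CA", resid = "ALA", chain = "A", resno = 1)
#' compute_sasa(a, probe = 1.4)$area  # 4*pi*(1.7 + 1.4)^2
#' @export
compute_sasa <- function(atoms, probe = 1.4, n_points = 960, radii = NULL) {
  stopifnot(probe > 0, n_points >= 100)
  if ("is_heavy" %in% names(atoms)) atoms <- atoms[atoms$is_heavy, , drop = FALSE]
  n <- nrow(atoms)
  if (n == 0L) stop("no heavy atoms to compute SASA over", call. = FALSE)
  r <- .atom_radii(atoms, radii) + probe
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  lattice <- fibonacci_sphere(n_points)

  # neighbour lists: spheres i, j can occlude each other iff centres closer
  # than r_i + r_j; distances computed per atom to keep memory linear in n
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2i <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2i < (r[i] + r)^2)
    nb <- nb[nb != i]
    pts <- sweep(lattice * r[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & dj > r[j]^2
      if (!any(acc)) break
    }
    area[i] <- mean(acc) * 4 * pi * r[i]^2
  }
  structure(list(area = area, probe = probe, n_points = n_points,
                 radii_label = if (is.null(radii)) "builtin" else "custom"),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: %d atoms, total %.2f A^2 (probe %.2f, %d points, %s radii)\n",
              length(x$area), sum(x$area), x$probe, x$n_points, x$radii_label))
  invisible(x)
}
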