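# In-code fixtures shared across test files. Everything is generated
# programmatically; the canonical seed for stochastic fixtures is 1.

pdb_line <- function(serial, name, resid, chain, resno, x, y, z,
                     occ = 1, alt = " ", element = substr(name, 1, 1),
                     record = "ATOM  ") {
  sprintf("%s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, sprintf(" %-3s", name), alt, resid, chain, resno,
          x, y, z, occ, 0, element)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Monte-Carlo surface-integration SASA oracle, independent of the lattice
# implementation: uniform random points on each probe-inflated sphere.
mc_sasa <- function(atoms, probe = 1.4, n_samples = 1e6, seed = 1,
                    radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)) {
  set.seed(seed)
  r <- unname(radii[atoms$element]) + probe
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  vapply(seq_len(nrow(atoms)), function(i) {
    g <- matrix(stats::rnorm(3 * n_samples), ncol = 3)
    g <- g / sqrt(rowSums(g^2))
    pts <- sweep(g * r[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_samples)
    for (j in setdiff(seq_len(nrow(atoms)), i)) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > r[j]^2
    }
    mean(acc) * 4 * pi * r[i]^2
  }, numeric(1))
}

# Exhaustive global-alignment oracle: enumerates every alignment of a and b
# under linear gap scoring and returns the best score and the identity
# fraction of a best-scoring alignment (ties: first found).
brute_force_nw <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  best <- list(score = -Inf, matches = 0, len = 0)
  recurse <- function(i, j, score, matches, len) {
    if (i > length(a) && j > length(b)) {
      if (score > best$score) {
        best <<- list(score = score, matches = matches, len = len)
      }
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      recurse(i + 1, j + 1, score + s, matches + (a[i] == b[j]), len + 1)
    }
    if (i <= length(a)) recurse(i + 1, j, score + gap, matches, len + 1)
    if (j <= length(b)) recurse(i, j + 1, score + gap, matches, len + 1)
  }
  recurse(1, 1, 0, 0, 0)
  best
}

# Random rigid transform (proper rotation + translation), seeded.
random_rigid_transform <- function(seed = 1) {
  set.seed(seed)
  A <- matrix(stats::rnorm(9), 3, 3)
  qr_dec <- qr(A)
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, 0, 20))
}

apply_rigid <- function(model, R, t) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1] + t[1]
  model$atoms$y <- xyz[, 2] + t[2]
  model$atoms$z <- xyz[, 3] + t[3]
  model
}

# Docked toy: TCR low enough over the cleft that the interface buries area.
docked_toy <- function(...) {
  make_toy_complex(mode = "end_to_end", tcr_height = 8, ...)
}
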