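test_that("self-superposition gives zero rmsd and the identity rotation", {
  toy <- make_toy_complex()
  sup <- superpose_rmsd(toy$model, toy$model)
  expect_equal(sup$rmsd, 0, tolerance = 1e-9)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
})

test_that("a known rigid transform is recovered to 1e-6", {
  toy <- make_toy_complex(plant_salt_bridge = 3.2)
  tr <- random_rigid_transform(seed = 1)
  moved <- apply_rigid(toy$model, tr$R, tr$t)
  sup <- superpose_rmsd(toy$model, moved)
  expect_lt(sup$rmsd, 1e-6)
  # recovered transform must invert the applied one
  expect_equal(sup$rotation %*% tr$R, diag(3), tolerance = 1e-6)
})

test_that("rmsd is symmetric under exchange of reference and mobile", {
  toy <- make_toy_complex()
  jit <- toy$model
  set.seed(1)
  jit$atoms$x <- jit$atoms$x + rnorm(nrow(jit$atoms), 0, 0.3)
  jit$atoms$y <- jit$atoms$y + rnorm(nrow(jit$atoms), 0, 0.3)
  r1 <- superpose_rmsd(toy$model, jit)$rmsd
  r2 <- superpose_rmsd(jit, toy$model)$rmsd
  expect_equal(r1, r2, tolerance = 1e-9)
  expect_gt(r1, 0)
})

test_that("selection mini-language restricts the paired atom set", {
  toy <- make_toy_complex()
  all_sel <- superpose_rmsd(toy$model, toy$model)
  pep_only <- superpose_rmsd(toy$model, toy$model, "PEPTIDE")
  expect_equal(pep_only$n_atoms_used, 9L)
  expect_lt(pep_only$n_atoms_used, all_sel$n_atoms_used)
  ranged <- superpose_rmsd(toy$model, toy$model, "MHC_ALPHA:1-10")
  expect_equal(ranged$n_atoms_used, 10L)
  expect_error(superpose_rmsd(toy$model, toy$model, "PEPTIDE:1-2"), ">= 3")
})

test_that("toy constructions classify as built: polarity x mode grid", {
  for (pol in c("canonical", "reversed")) {
    for (md in c("end_to_end", "end_to_side")) {
      toy <- make_toy_complex(polarity = pol, mode = md)
      d <- docking_descriptors(toy$model)
      expect_equal(d$polarity, toupper(pol))
      expect_equal(d$mode, toupper(md))
    }
  }
})

test_that("swapping Valpha/Vbeta centroids flips the polarity call", {
  toy <- make_toy_complex(polarity = "canonical")
  d0 <- docking_descriptors(toy$model)
  swapped <- make_toy_complex(valpha_centre = d0$vbeta_centroid,
                              vbeta_centre = d0$valpha_centroid)
  d1 <- docking_descriptors(swapped$model)
  expect_equal(d0$polarity, "CANONICAL")
  expect_equal(d1$polarity, "REVERSED")
  # mirror-swap: crossing angle reflects about 90 degrees
  expect_equal(d1$crossing_angle, 180 - d0$crossing_angle, tolerance = 1e-6)
})

test_that("descriptors are invariant under global rigid motion", {
  toy <- make_toy_complex(polarity = "reversed", mode = "end_to_side")
  d0 <- docking_descriptors(toy$model)
  for (s in 1:3) {
    tr <- random_rigid_transform(seed = s)
    d1 <- docking_descriptors(apply_rigid(toy$model, tr$R, tr$t))
    expect_equal(d1$crossing_angle, d0$crossing_angle, tolerance = 1e-6)
    expect_equal(d1$tilt_angle, d0$tilt_angle, tolerance = 1e-6)
    expect_equal(d1$min_cdr_peptide_distance, d0$min_cdr_peptide_distance,
                 tolerance = 1e-6)
    expect_identical(d1$polarity, d0$polarity)
    expect_identical(d1$mode, d0$mode)
  }
})

test_that("min CDR-peptide distance matches a brute-force all-pairs check", {
  toy <- make_toy_complex(polarity = "reversed", mode = "end_to_side")
  d <- docking_descriptors(toy$model)
  reg <- assign_imgt_regions(toy$model)
  cdr <- reg[grepl("^CDR", reg$region), ]
  at <- toy$model$atoms
  cdr_at <- at[paste(at$role, at$resno) %in% paste(cdr$role, cdr$resno) &
                 at$role %in% c("TCR_ALPHA", "TCR_BETA"), ]
  pep_at <- at[at$role == "PEPTIDE", ]
  brute <- min(sqrt(outer(cdr_at$x, pep_at$x, "-")^2 +
                      outer(cdr_at$y, pep_at$y, "-")^2 +
                      outer(cdr_at$z, pep_at$z, "-")^2))
  expect_equal(d$min_cdr_peptide_distance, brute, tolerance = 1e-12)
})

test_that("centroids are Calpha centres of mass of the variable domains", {
  toy <- make_toy_complex()
  d <- docking_descriptors(toy$model)
  expect_equal(d$valpha_centroid, toy$truth$valpha_centroid, tolerance = 1e-9)
  expect_equal(d$vbeta_centroid, toy$truth$vbeta_centroid, tolerance = 1e-9)
})

test_that("rmsd agrees with an independent structural-biology implementation", {
  toy <- make_toy_complex()
  jit <- toy$model
  set.seed(4)
  for (cc in c("x", "y", "z"))
    jit$atoms[[cc]] <- jit$atoms[[cc]] + rnorm(nrow(jit$atoms), 0, 0.5)
  mine <- superpose_rmsd(toy$model, jit)
  ca <- toy$model$atoms$atom == "CA"
  ref_xyz <- as.vector(t(as.matrix(toy$model$atoms[ca, c("x", "y", "z")])))
  mob_xyz <- as.vector(t(as.matrix(jit$atoms[ca, c("x", "y", "z")])))
  # bio3d::rmsd reports at 3-decimal precision
  expect_equal(bio3d::rmsd(ref_xyz, mob_xyz, fit = TRUE), round(mine$rmsd, 3))
})
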