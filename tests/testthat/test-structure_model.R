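test_that("minimal PDB parses into chains with assigned roles", {
  path <- write_pdb_fixture(c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "ALA", "B", 1, 5, 0, 0)))
  m <- load_complex(path, c(A = "other", B = "other"))
  expect_s3_class(m, "complex_model")
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(sort(unique(m$atoms$chain)), c("A", "B"))
  expect_true(all(m$atoms$role == "OTHER"))
})

test_that("alternate locations collapse to the highest-occupancy conformer", {
  path <- write_pdb_fixture(c(
    pdb_line(1, "CA", "SER", "A", 1, 0, 0, 0, occ = 0.6, alt = "A"),
    pdb_line(2, "CA", "SER", "A", 1, 9, 9, 9, occ = 0.4, alt = "B"),
    pdb_line(3, "CB", "SER", "A", 1, 1, 1, 1)))
  m <- load_complex(path, c(A = "other"))
  ca <- m$atoms[m$atoms$atom == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 0)        # the 0.6 conformer
  expect_equal(ca$occ, 0.6)
})

test_that("alt-loc occupancy ties resolve to the first label", {
  path <- write_pdb_fixture(c(
    pdb_line(1, "CA", "SER", "A", 1, 7, 0, 0, occ = 0.5, alt = "B"),
    pdb_line(2, "CA", "SER", "A", 1, 3, 0, 0, occ = 0.5, alt = "A")))
  m <- load_complex(path, c(A = "other"))
  expect_equal(m$atoms$x, 3)   # label A wins the tie
})

test_that("waters always drop; hetero drops unless whitelisted", {
  lines <- c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "O", "HOH", "A", 90, 1, 1, 1, record = "HETATM"),
    pdb_line(3, "ZN", "ZN", "A", 91, 2, 2, 2, element = "ZN",
             record = "HETATM"))
  m <- load_complex(write_pdb_fixture(lines), c(A = "other"))
  expect_equal(nrow(m$atoms), 1L)
  m2 <- load_complex(write_pdb_fixture(lines), c(A = "other"),
                     het_whitelist = "ZN")
  expect_equal(sort(m2$atoms$resid), c("GLY", "ZN"))
})

test_that("unknown config chain errors and lists available chains", {
  path <- write_pdb_fixture(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0))
  expect_error(load_complex(path, c(Z = "peptide")), "available chains: A")
})

test_that("unreadable file raises a parse error naming the file", {
  bad <- tempfile(fileext = ".pdb")
  writeLines("not a coordinate file", bad)
  expect_error(load_complex(bad, c(A = "other")), "parse|no atoms")
})

test_that("a loaded model round-trips through PDB within coordinate precision", {
  toy <- make_toy_complex(plant_salt_bridge = 3.2)
  path <- tempfile(fileext = ".pdb")
  write_complex_pdb(toy$model, path)
  back <- load_complex(path, toy$role_config)
  expect_equal(nrow(back$atoms), nrow(toy$model$atoms))
  a0 <- toy$model$atoms[order(toy$model$atoms$chain, toy$model$atoms$resno,
                              toy$model$atoms$atom), ]
  a1 <- back$atoms[order(back$atoms$chain, back$atoms$resno, back$atoms$atom), ]
  expect_equal(a1$resno, a0$resno)
  expect_equal(a1$atom, a0$atom)
  expect_lt(max(abs(a1$x - a0$x), abs(a1$y - a0$y), abs(a1$z - a0$z)), 1e-3)
})

test_that("parsing is deterministic across repeated loads", {
  toy <- make_toy_complex()
  path <- tempfile(fileext = ".pdb")
  write_complex_pdb(toy$model, path)
  m1 <- load_complex(path, toy$role_config)
  m2 <- load_complex(path, toy$role_config)
  expect_identical(m1$atoms, m2$atoms)
})

test_that("peptide role outside 8-25 residues is rejected", {
  lines <- vapply(1:3, function(i)
    pdb_line(i, "CA", "ALA", "C", i, i * 3.5, 0, 0), character(1))
  expect_error(load_complex(write_pdb_fixture(lines), c(C = "peptide")),
               "8-25")
})

test_that("IMGT region labels follow the unique-numbering boundaries", {
  toy <- make_toy_complex()
  reg <- assign_imgt_regions(toy$model)
  lab <- function(role, n) reg$region[reg$role == role & reg$resno == n]
  # boundary residues of the scheme, from both chains
  expect_equal(lab("TCR_ALPHA", 30), "CDR1")
  expect_equal(lab("TCR_ALPHA", 80), "FR3")   # reported under FW alpha
  expect_equal(lab("TCR_BETA", 70), "FR3")    # reported under FW beta
  expect_equal(lab("TCR_BETA", 60), "CDR2")
  expect_equal(lab("TCR_ALPHA", 105), "CDR3")
  expect_equal(lab("TCR_ALPHA", 125), "FR4")
  expect_true(all(reg$group[grepl("^FR", reg$region)] == "FW"))
})

test_that("region labels partition each TCR chain exactly once", {
  toy <- make_toy_complex(plant_salt_bridge = 3.4)  # adds resno 201 (beta)
  reg <- assign_imgt_regions(toy$model)
  tcr_res <- unique(toy$model$atoms[
    toy$model$atoms$role %in% c("TCR_ALPHA", "TCR_BETA"),
    c("role", "resno", "ins")])
  expect_equal(nrow(reg), nrow(tcr_res))          # every residue labelled once
  expect_false(any(is.na(reg$region)))
  expect_equal(reg$region[reg$resno == 201], "CONSTANT")
})

test_that("explicit region ranges override the IMGT defaults", {
  toy <- make_toy_complex()
  ov <- list(tcr_alpha = list(CDR1 = c(1, 128)))
  reg <- assign_imgt_regions(toy$model, override = ov)
  expect_true(all(reg$region[reg$role == "TCR_ALPHA"] == "CDR1"))
  expect_equal(sort(unique(reg$region[reg$role == "TCR_BETA"])),
               c("CDR1", "CDR2", "CDR3", "FR1", "FR2", "FR3", "FR4"))
})

test_that("TCR chain without IMGT-range residues suggests explicit ranges", {
  toy <- make_toy_complex()
  at <- toy$model$atoms
  at$resno[at$role == "TCR_ALPHA"] <- at$resno[at$role == "TCR_ALPHA"] + 500L
  m <- structure(list(atoms = at, source_id = "x", region_override = NULL),
                 class = "complex_model")
  expect_error(assign_imgt_regions(m), "explicit region ranges")
})
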