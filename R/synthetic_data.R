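# Deterministic blob of atoms: centred Fibonacci-sphere offsets, so the
# centroid equals `center` exactly and no RNG is involved.
.blob_offsets <- function(n, radius) {
  pts <- fibonacci_sphere(n) * radius
  sweep(pts, 2, colMeans(pts))
}

.toy_chain <- function(chain, role, resno, resid, atom, element, xyz) {
  data.frame(chain = chain, role = role, resno = as.integer(resno), ins = "",
             resid = resid, atom = atom, element = element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
             is_heavy = element != "H", stringsAsFactors = FALSE)
}

#' Build a toy TCR-pMHC complex with known geometry
#'
#' Constructs a minimal five-chain complex whose ground truth is fixed by
#' construction: a 9-residue peptide along the x axis, two MHC helix strands
#' flanking it in the cleft plane (z = 0), and two TCR variable-domain blobs
#' whose centroids are placed to realize a requested docking polarity and
#' mode. Geometry is deterministic (no RNG) unless `jitter_sd > 0`.
#'
#' Chains are A (MHC alpha), B (MHC beta), C (peptide), D (TCR alpha),
#' E (TCR beta); TCR residues are numbered on the IMGT scheme (5, 10, ...,
#' 125), so region annotation covers every CDR and framework region.
#'
#' Contact plants add isolated atom pairs across the interface at exact
#' distances, away from all other atoms, so contact detection on the toy has
#' a known answer: `salt` plants Lys NZ against Glu OE1, `hbond` Ser OG
#' against Thr OG1, `vdw` Ala CB against Ala CB.
#'
#' @param polarity `"canonical"` or `"reversed"` - which side of the peptide
#'   axis carries the Valpha centroid.
#' @param mode `"end_to_end"` (TCR centred over the cleft) or
#'   `"end_to_side"` (TCR displaced laterally past the beta-chain helix).
#' @param n_atoms_per_domain Calpha count per TCR variable domain.
#' @param domain_radius Blob radius in Angstrom.
#' @param tcr_height Height of the TCR centroids above the cleft plane for
#'   `end_to_end` (Angstrom).
#' @param plant_contacts List of `list(type = "salt"|"hbond"|"vdw",
#'   distance = <Angstrom>)` contact plants.
#' @param plant_salt_bridge Convenience: a single salt-bridge distance
#'   (Angstrom), equivalent to one `type = "salt"` plant.
#' @param valpha_centre,vbeta_centre Optional explicit centroid overrides
#'   (length-3, Angstrom), taking precedence over `polarity`/`mode`
#'   placement.
#' @param jitter_sd Gaussian coordinate noise (Angstrom; default 0).
#' @param seed RNG seed, used only when `jitter_sd > 0`.
#' @return List with `model` (a `complex_model`), `role_config`, and `truth`
#'   (list: `valpha_centroid`, `vbeta_centroid`, `polarity`, `mode`,
#'   `planted` data frame of planted pairs and distances).
#' @examples
#' toy <- make_toy_complex(polarity = "reversed", mode = "end_to_side")
#' toy$truth$polarity
#' @export
make_toy_complex <- function(polarity = c("canonical", "reversed"),
                             mode = c("end_to_end", "end_to_side"),
                             n_atoms_per_domain = 25, domain_radius = 4,
                             tcr_height = 20, plant_contacts = list(),
                             plant_salt_bridge = NULL,
                             valpha_centre = NULL, vbeta_centre = NULL,
                             jitter_sd = 0, seed = 1) {
  polarity <- match.arg(polarity)
  mode <- match.arg(mode)
  if (!is.null(plant_salt_bridge))
    plant_contacts <- c(plant_contacts,
                        list(list(type = "salt", distance = plant_salt_bridge)))

  # peptide: 9 Calpha along x, 3.5 A spacing, centred at the origin
  pep_x <- (seq_len(9) - 5) * 3.5
  pep <- .toy_chain("C", "PEPTIDE", seq_len(9), "ALA", "CA", "C",
                    cbind(pep_x, 0, 0))

  helix_x <- (seq_len(30) - 15.5) * 2
  mhc_a <- .toy_chain("A", "MHC_ALPHA", seq_len(30), "ALA", "CA", "C",
                      cbind(helix_x, 9, 0))
  mhc_b <- .toy_chain("B", "MHC_BETA", seq_len(30), "ALA", "CA", "C",
                      cbind(helix_x, -9, 0))

  # canonical class II: Valpha over the beta-chain helix (y < 0) and toward
  # the peptide C-terminus, so the Vbeta->Valpha vector crosses the N->C
  # peptide axis at < 90 degrees
  base <- switch(mode,
                 end_to_end = list(va = c(7, -5, tcr_height),
                                   vb = c(-7, 5, tcr_height)),
                 end_to_side = list(va = c(7, -29, 6), vb = c(-7, -19, 6)))
  if (polarity == "reversed") base <- list(va = base$vb, vb = base$va)
  va <- valpha_centre %||% base$va
  vb <- vbeta_centre %||% base$vb

  tcr_res <- seq(5, 125, by = 5)[seq_len(min(n_atoms_per_domain, 25))]
  if (n_atoms_per_domain > 25)
    tcr_res <- c(tcr_res, seq(126, 125 + n_atoms_per_domain - 25))
  off <- .blob_offsets(length(tcr_res), domain_radius)
  tcr_a <- .toy_chain("D", "TCR_ALPHA", tcr_res, "ALA", "CA", "C",
                      sweep(off, 2, va, `+`))
  tcr_b <- .toy_chain("E", "TCR_BETA", tcr_res, "ALA", "CA", "C",
                      sweep(off, 2, vb, `+`))

  planted <- NULL
  plant_x <- 40
  plant_kinds <- list(
    salt = list(res_t = "LYS", atom_t = "NZ", el_t = "N",
                res_m = "GLU", atom_m = "OE1", el_m = "O"),
    hbond = list(res_t = "SER", atom_t = "OG", el_t = "O",
                 res_m = "THR", atom_m = "OG1", el_m = "O"),
    vdw = list(res_t = "ALA", atom_t = "CB", el_t = "C",
               res_m = "ALA", atom_m = "CB", el_m = "C"))
  extra <- list()
  for (k in seq_along(plant_contacts)) {
    pc <- plant_contacts[[k]]
    if (is.null(pc$distance) || pc$distance <= 1)
      stop("planted contact distance must exceed 1 Angstrom", call. = FALSE)
    kind <- plant_kinds[[match.arg(pc$type, names(plant_kinds))]]
    # isolated pair on the x axis extension, 8 A further out per plant
    x0 <- plant_x + 8 * (k - 1)
    resno <- 200L + k
    extra[[length(extra) + 1]] <- .toy_chain(
      "B", "MHC_BETA", resno, kind$res_m, kind$atom_m, kind$el_m,
      cbind(x0, -9, 0))
    extra[[length(extra) + 1]] <- .toy_chain(
      "E", "TCR_BETA", resno, kind$res_t, kind$atom_t, kind$el_t,
      cbind(x0 + pc$distance, -9, 0))
    planted <- rbind(planted, data.frame(
      type = toupper(pc$type), distance = pc$distance, resno = resno,
      stringsAsFactors = FALSE))
  }

  atoms <- do.call(rbind, c(list(mhc_a, mhc_b, pep, tcr_a, tcr_b), extra))
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  if (jitter_sd > 0) {
    set.seed(seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, jitter_sd)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, jitter_sd)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, jitter_sd)
  }
  rownames(atoms) <- NULL
  model <- structure(list(atoms = atoms, source_id = "toy_complex",
                          region_override = NULL),
                     class = "complex_model")
  .validate_complex_model(model)
  list(model = model,
       role_config = c(A = "mhc_alpha", B = "mhc_beta", C = "peptide",
                       D = "tcr_alpha", E = "tcr_beta"),
       truth = list(valpha_centroid = unname(va), vbeta_centroid = unname(vb),
                    polarity = toupper(polarity),
                    mode = toupper(mode),
                    planted = planted))
}

#' Deterministic or seeded atom cluster
#'
#' A free-standing cluster of carbon atoms for surface-area tests: either a
#' deterministic centred Fibonacci shell (`seed = NULL`) or a seeded uniform
#' cloud inside a sphere.
#'
#' @param n Atom count.
#' @param center Length-3 centre (Angstrom).
#' @param radius Cluster radius (Angstrom).
#' @param chain,role Chain ID and role attached to the atoms.
#' @param seed `NULL` for the deterministic shell, else an integer seed.
#' @return Atom data frame in `complex_model` layout.
#' @export
make_atom_cluster <- function(n, center = c(0, 0, 0), radius = 3,
                              chain = "A", role = "OTHER", seed = NULL) {
  if (is.null(seed)) {
    pts <- .blob_offsets(n, radius)
  } else {
    set.seed(seed)
    pts <- matrix(stats::runif(3 * n, -radius, radius), ncol = 3)
  }
  .toy_chain(chain, role, seq_len(n), "ALA", "CA", "C",
             sweep(pts, 2, center, `+`))
}

#' Simulate a steady-state SPR titration
#'
#' Equilibrium responses from the 1:1 Langmuir isotherm
#' `Req = rmax * C / (kd + C)` with additive Gaussian noise of standard
#' deviation `noise_sd_fraction * rmax`, seeded for reproducibility.
#'
#' @param kd Dissociation constant (uM, > 0).
#' @param rmax Maximal response (RU, > 0).
#' @param concentrations Analyte concentrations (uM); default eight two-fold
#'   dilutions from 80 uM, the usual TCR titration design.
#' @param noise_sd_fraction Noise SD as a fraction of `rmax` (>= 0).
#' @param seed Integer seed.
#' @param replicate Replicate label attached to the series.
#' @return Data frame `concentration_uM`, `response_RU`, `replicate`.
#' @examples
#' simulate_spr(12.4, 100, noise_sd_fraction = 0)
#' @export
simulate_spr <- function(kd, rmax, concentrations = 80 / 2^(0:7),
                         noise_sd_fraction = 0.05, seed = 1,
                         replicate = "r1") {
  stopifnot(kd > 0, rmax > 0)
  if (noise_sd_fraction < 0)
    stop("noise_sd_fraction must be >= 0", call. = FALSE)
  req <- rmax * concentrations / (kd + concentrations)
  if (noise_sd_fraction > 0) {
    set.seed(seed)
    req <- req + stats::rnorm(length(req), 0, noise_sd_fraction * rmax)
  }
  data.frame(concentration_uM = concentrations, response_RU = req,
             replicate = replicate, stringsAsFactors = FALSE)
}

#' Default 180-bead single-antigen HLA panel layout
#'
#' Allele names for a synthetic LABScreen-style panel: class I (HLA-A/B/C)
#' and class II (DR/DQ/DP) beads, with four DQB1*02 (DQ2-group) beads.
#'
#' @param n Total bead count (default 180).
#' @return Character vector of `n` allele names.
#' @export
default_hla_panel <- function(n = 180) {
  dq2 <- c("DQB1*02:01", "DQB1*02:02", "DQB1*02:03", "DQB1*02:04")
  dq_other <- sprintf("DQB1*%02d:%02d", rep(3:6, each = 4), 1:4)
  dr <- sprintf("DRB1*%02d:01", 1:30)
  dp <- sprintf("DPB1*%02d:01", 1:20)
  a <- sprintf("A*%02d:01", 1:40)
  b <- sprintf("B*%02d:01", 1:40)
  cc <- sprintf("C*%02d:01", 1:40)
  all <- c(dq2, dq_other, dr, dp, a, b, cc)
  if (n > length(all))
    stop("panel template holds at most ", length(all), " beads", call. = FALSE)
  all[seq_len(n)]
}

#' Simulate a single-antigen bead panel pair (sample + isotype)
#'
#' Positive-group beads receive signal plus background in the sample panel;
#' all other beads, the nude negative-control bead, and the whole
#' isotype-control panel receive background only. All four normalization
#' terms (`s_n`, `snc`, `bg_n`, `bgnc`) are populated, with seeded Gaussian
#' noise on each.
#'
#' @param alleles Character vector of bead allele names (default
#'   [default_hla_panel()]).
#' @param positive_group Alleles that carry signal; default every DQ2-group
#'   bead (see [allele_group()]).
#' @param signal_mfi Specific signal MFI added to positive beads.
#' @param background_mfi Background MFI common to all beads.
#' @param noise_sd Gaussian noise SD on every fluorescence term.
#' @param n_replicates Replicate panels (the assay is typically run twice).
#' @param seed Integer seed.
#' @return List with `sample` and `isotype` bead panels (see
#'   [normalize_panel()]) and `truth` (the positive allele set).
#' @examples
#' pans <- simulate_bead_panel(seed = 7)
#' head(pans$sample)
#' @export
simulate_bead_panel <- function(alleles = default_hla_panel(),
                                positive_group = NULL,
                                signal_mfi = 8000, background_mfi = 400,
                                noise_sd = 40, n_replicates = 2, seed = 1) {
  if (length(alleles) == 0) stop("allele list is empty", call. = FALSE)
  if (is.null(positive_group)) {
    grp <- allele_group(alleles)
    positive_group <- alleles[!is.na(grp) & grp == "DQ2"]
  }
  if (!all(positive_group %in% alleles))
    stop("positive_group contains alleles absent from the panel",
         call. = FALSE)
  set.seed(seed)
  one_panel <- function(signal, replicate) {
    n <- length(alleles)
    noise <- function() stats::rnorm(n, 0, noise_sd)
    s_n <- pmax(0, background_mfi + signal * (alleles %in% positive_group) +
                  noise())
    # the negative-control (nude) bead is a single bead; its value is shared
    # across all rows of the panel
    snc <- max(0, background_mfi + stats::rnorm(1, 0, noise_sd))
    bgnc <- max(0, background_mfi / 2 + stats::rnorm(1, 0, noise_sd))
    data.frame(bead_id = seq_len(n), allele = alleles,
               s_n = s_n,
               snc = snc,
               bg_n = pmax(0, background_mfi / 2 + noise()),
               bgnc = bgnc,
               replicate = replicate, stringsAsFactors = FALSE)
  }
  sample <- do.call(rbind, lapply(seq_len(n_replicates), function(r)
    one_panel(signal_mfi, paste0("r", r))))
  isotype <- do.call(rbind, lapply(seq_len(n_replicates), function(r)
    one_panel(0, paste0("r", r))))
  list(sample = sample, isotype = isotype,
       truth = list(positives = positive_group))
}
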