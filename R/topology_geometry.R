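# Calpha coordinate matrix keyed by (role, resno, ins) for pairing.
.ca_table <- function(model, roles = NULL, res_range = NULL) {
  at <- model_atoms(model, roles)
  at <- at[at$atom == "CA", , drop = FALSE]
  if (!is.null(res_range))
    at <- at[at$resno >= res_range[1] & at$resno <= res_range[2], , drop = FALSE]
  at
}

.parse_selection <- function(selection) {
  # mini-language: "ROLE" or "ROLE:from-to", case-insensitive
  if (is.null(selection))
    selection <- c(.tcr_roles, .pmhc_roles)
  lapply(selection, function(s) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    role <- .normalize_role(parts[1])
    rng <- NULL
    if (length(parts) > 1) {
      ft <- as.integer(strsplit(parts[2], "-", fixed = TRUE)[[1]])
      if (length(ft) != 2 || anyNA(ft))
        stop("bad selection range: ", s, call. = FALSE)
      rng <- ft
    }
    list(role = role, range = rng)
  })
}

#' Rigid-body superposition and r.m.s.d. (Kabsch)
#'
#' Least-squares rigid superposition of `mobile` onto `reference` over paired
#' Calpha atoms, pairing by (role, residue number, insertion code). The
#' rotation is a proper rotation: if the least-squares optimum would require
#' a reflection (degenerate, e.g. planar input), the nearest proper rotation
#' is used and a warning is issued.
#'
#' @param reference,mobile `complex_model` objects.
#' @param selection Character vector of selections `"ROLE"` or
#'   `"ROLE:from-to"` (e.g. `c("MHC_ALPHA:1-90", "PEPTIDE")`); `NULL` selects
#'   all five roles.
#' @return A `superposition_result`: list with `rotation` (3x3, det +1),
#'   `translation` (length-3, Angstrom), `rmsd` (Angstrom), `n_atoms_used`.
#'   The transform maps mobile coordinates as `x %*% t(rotation) +
#'   translation`.
#' @examples
#' toy <- make_toy_complex()
#' superpose_rmsd(toy$model, toy$model)$rmsd  # 0
#' @export
superpose_rmsd <- function(reference, mobile, selection = NULL) {
  sel <- .parse_selection(selection)
  pair_one <- function(model) {
    do.call(rbind, lapply(sel, function(s)
      .ca_table(model, s$role, s$range)))
  }
  ca_ref <- pair_one(reference)
  ca_mob <- pair_one(mobile)
  key_ref <- paste(ca_ref$role, ca_ref$resno, ca_ref$ins)
  key_mob <- paste(ca_mob$role, ca_mob$resno, ca_mob$ins)
  common <- intersect(key_ref, key_mob)
  if (length(common) < 3)
    stop("selection pairs only ", length(common),
         " Calpha atoms; need >= 3", call. = FALSE)
  P <- as.matrix(ca_mob[match(common, key_mob), c("x", "y", "z")])
  Q <- as.matrix(ca_ref[match(common, key_ref), c("x", "y", "z")])

  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d < 0)
    warning("optimal superposition required a reflection; ",
            "nearest proper rotation used")
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  translation <- as.numeric(cq - R %*% cp)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  structure(list(rotation = R, translation = translation, rmsd = rmsd,
                 n_atoms_used = length(common)),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition_result: rmsd %.4f A over %d Calpha\n",
              x$rmsd, x$n_atoms_used))
  invisible(x)
}

.unit <- function(v) v / sqrt(sum(v^2))

.angle_deg <- function(u, v) {
  cosang <- sum(.unit(u) * .unit(v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Even-odd ray casting; polygon as closed-ordered 2-column matrix.
.point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2])) {
      xint <- poly[j, 1] + (pt[2] - poly[j, 2]) *
        (poly[i, 1] - poly[j, 1]) / (poly[i, 2] - poly[j, 2])
      if (pt[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Docking-topology descriptors for a TCR-pMHC complex
#'
#' Computes the geometric descriptors behind docking-mode classification:
#' \enumerate{
#'   \item Valpha/Vbeta centroids: Calpha centres of mass over IMGT variable
#'     domain residues 1-128;
#'   \item peptide axis: least-squares line through peptide Calpha, oriented
#'     N to C;
#'   \item cleft plane: least-squares plane through the membrane-distal
#'     (alpha1 + beta1) domain Calpha of the two MHC chains (residues up to
#'     `cleft_resmax`), normal oriented toward the TCR;
#'   \item crossing angle: in-plane angle between the peptide axis and the
#'     Vbeta-to-Valpha centroid vector, in [0, 180] degrees;
#'   \item polarity: CANONICAL if crossing angle < 90 degrees (for class II,
#'     canonical places Valpha over the beta-chain helix), REVERSED
#'     otherwise;
#'   \item tilt angle: between the cleft-plane normal and the vector from
#'     the cleft centroid to the Valpha/Vbeta midpoint, in [0, 90];
#'   \item mode: END_TO_END if the TCR midpoint projects inside the cleft
#'     footprint (convex hull of the cleft Calpha projected onto the plane)
#'     and tilt < 45 degrees, else END_TO_SIDE;
#'   \item minimum CDR-peptide distance: minimum heavy-atom distance between
#'     any CDR-labelled residue and the peptide.
#' }
#' These conventions are this package's reference definitions; the raw angles
#' depend on them, the categorical classes are the robust output.
#'
#' @param model A `complex_model` with all five roles assigned.
#' @param regions Optional `region_annotation`; computed if `NULL`.
#' @param cleft_resmax Last residue number of the alpha1/beta1 cleft domains
#'   (default 90).
#' @param polarity_threshold,tilt_threshold Classification thresholds in
#'   degrees (defaults 90 and 45).
#' @return A `topology_summary`: list with `valpha_centroid`,
#'   `vbeta_centroid`, `crossing_angle`, `tilt_angle`, `polarity`, `mode`,
#'   `min_cdr_peptide_distance`.
#' @examples
#' toy <- make_toy_complex(polarity = "reversed", mode = "end_to_side")
#' docking_descriptors(toy$model)[c("polarity", "mode")]
#' @export
docking_descriptors <- function(model, regions = NULL, cleft_resmax = 90,
                                polarity_threshold = 90, tilt_threshold = 45) {
  if (is.null(regions)) regions <- assign_imgt_regions(model)
  need <- c(.tcr_roles, .pmhc_roles)
  have <- unique(model$atoms$role)
  if (!all(need %in% have))
    stop("missing role(s): ", paste(setdiff(need, have), collapse = ", "),
         call. = FALSE)

  ca_va <- .ca_table(model, "TCR_ALPHA", c(1, 128))
  ca_vb <- .ca_table(model, "TCR_BETA", c(1, 128))
  if (nrow(ca_va) == 0L || nrow(ca_vb) == 0L)
    stop("TCR variable domain (IMGT 1-128) has no Calpha atoms", call. = FALSE)
  va <- colMeans(as.matrix(ca_va[, c("x", "y", "z")]))
  vb <- colMeans(as.matrix(ca_vb[, c("x", "y", "z")]))
  tcr_mid <- (va + vb) / 2

  pep <- .ca_table(model, "PEPTIDE")
  pep <- pep[order(pep$resno, pep$ins), , drop = FALSE]
  if (nrow(pep) < 8) stop("peptide has < 8 Calpha atoms", call. = FALSE)
  pep_xyz <- as.matrix(pep[, c("x", "y", "z")])
  pc <- stats::prcomp(pep_xyz, center = TRUE)
  axis <- pc$rotation[, 1]
  if (sum(axis * (pep_xyz[nrow(pep_xyz), ] - pep_xyz[1, ])) < 0) axis <- -axis

  cleft <- rbind(.ca_table(model, "MHC_ALPHA", c(-Inf, cleft_resmax)),
                 .ca_table(model, "MHC_BETA", c(-Inf, cleft_resmax)))
  cleft_xyz <- as.matrix(cleft[, c("x", "y", "z")])
  c0 <- colMeans(cleft_xyz)
  pcc <- stats::prcomp(cleft_xyz, center = TRUE)
  normal <- pcc$rotation[, 3]
  if (sum(normal * (tcr_mid - c0)) < 0) normal <- -normal
  in_plane <- function(v) v - sum(v * normal) * normal

  crossing <- .angle_deg(in_plane(axis), in_plane(va - vb))
  polarity <- if (crossing < polarity_threshold) "CANONICAL" else "REVERSED"

  tilt <- .angle_deg(normal, tcr_mid - c0)

  # footprint test in the plane's own 2D basis
  e1 <- pcc$rotation[, 1]; e2 <- pcc$rotation[, 2]
  proj2d <- function(p) c(sum((p - c0) * e1), sum((p - c0) * e2))
  cleft2d <- t(apply(cleft_xyz, 1, proj2d))
  hull <- cleft2d[grDevices::chull(cleft2d), , drop = FALSE]
  inside <- .point_in_polygon(proj2d(tcr_mid), hull)
  mode <- if (inside && tilt < tilt_threshold) "END_TO_END" else "END_TO_SIDE"

  cdr_keys <- regions[grepl("^CDR", regions$region), ]
  tcr_at <- model_atoms(model, .tcr_roles)
  in_cdr <- paste(tcr_at$role, tcr_at$resno, tcr_at$ins) %in%
    paste(cdr_keys$role, cdr_keys$resno, cdr_keys$ins)
  cdr_xyz <- as.matrix(tcr_at[in_cdr, c("x", "y", "z")])
  pep_heavy <- as.matrix(model_atoms(model, "PEPTIDE")[, c("x", "y", "z")])
  if (nrow(cdr_xyz) == 0L) stop("no CDR atoms found", call. = FALSE)
  dmin <- min(apply(cdr_xyz, 1, function(p)
    min(sqrt(rowSums(sweep(pep_heavy, 2, p)^2)))))

  structure(list(valpha_centroid = unname(va), vbeta_centroid = unname(vb),
                 crossing_angle = crossing, tilt_angle = tilt,
                 polarity = polarity, mode = mode,
                 min_cdr_peptide_distance = dmin),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(paste0("topology_summary: %s polarity, %s docking\n",
                     "  crossing angle %.1f deg, tilt %.1f deg, ",
                     "min CDR-peptide distance %.1f A\n"),
              x$polarity, x$mode, x$crossing_angle, x$tilt_angle,
              x$min_cdr_peptide_distance))
  invisible(x)
}
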