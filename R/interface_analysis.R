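# Role groupings defining the two sides of the interface.
.tcr_roles <- c("TCR_ALPHA", "TCR_BETA")
.pmhc_roles <- c("MHC_ALPHA", "MHC_BETA", "PEPTIDE")

#' Buried surface area decomposed by IMGT region
#'
#' Buried area per atom is SASA of the side in isolation minus SASA of the
#' same atoms within the full complex, summed to residues and aggregated to
#' IMGT regions (CDR1/2/3 and the pooled framework FW, per TCR chain).
#' Percentages are taken over the selected side's total, matching the
#' convention of reporting each CDR loop's relative contribution to the
#' TCR-side interface.
#'
#' @param model A `complex_model` with TCR and pMHC roles assigned.
#' @param regions A `region_annotation` from [assign_imgt_regions()];
#'   computed on the fly if `NULL`.
#' @param side `"TCR"` (default; the side the headline totals refer to),
#'   `"PMHC"`, or `"COMBINED"`.
#' @param probe,n_points,radii Passed to [compute_sasa()].
#' @return A `bsa_table`: list with `per_residue` (chain, role, resno, ins,
#'   resid, region, group, area), `per_region` (region label, area, percent),
#'   `total` (Angstrom^2), and `side`.
#' @examples
#' toy <- make_toy_complex()
#' compute_bsa_decomposition(toy$model, n_points = 240)$total
#' @export
compute_bsa_decomposition <- function(model, regions = NULL,
                                      side = c("TCR", "PMHC", "COMBINED"),
                                      probe = 1.4, n_points = 960,
                                      radii = NULL) {
  side <- match.arg(side)
  side_roles <- switch(side,
                       TCR = .tcr_roles,
                       PMHC = .pmhc_roles,
                       COMBINED = c(.tcr_roles, .pmhc_roles))
  at_all <- model_atoms(model, c(.tcr_roles, .pmhc_roles))
  at_side <- model_atoms(model, side_roles)
  if (nrow(at_side) == 0L) stop("no atoms on side ", side, call. = FALSE)

  sasa_alone <- compute_sasa(at_side, probe, n_points, radii)$area
  sasa_complex_all <- compute_sasa(at_all, probe, n_points, radii)$area
  side_idx <- at_all$role %in% side_roles
  buried <- sasa_alone - sasa_complex_all[side_idx]
  buried <- pmax(buried, 0)  # guard tiny negative lattice noise

  per_res <- stats::aggregate(
    buried,
    by = at_side[, c("chain", "role", "resno", "ins", "resid")],
    FUN = sum)
  names(per_res)[6] <- "area"

  # region labels: TCR chains by IMGT region group, pMHC chains by role
  if (any(per_res$role %in% .tcr_roles)) {
    if (is.null(regions)) regions <- assign_imgt_regions(model)
    key_r <- paste(regions$role, regions$resno, regions$ins)
    key_p <- paste(per_res$role, per_res$resno, per_res$ins)
    grp <- regions$group[match(key_p, key_r)]
  } else grp <- rep(NA_character_, nrow(per_res))
  suffix <- c(TCR_ALPHA = "a", TCR_BETA = "b")
  per_res$region <- ifelse(
    per_res$role %in% .tcr_roles,
    paste0(grp, suffix[per_res$role]),
    c(MHC_ALPHA = "MHCa", MHC_BETA = "MHCb", PEPTIDE = "peptide")[per_res$role])

  total <- sum(per_res$area)
  per_region <- stats::aggregate(area ~ region, data = per_res, FUN = sum)
  per_region$percent <- if (total > 0) 100 * per_region$area / total else 0
  per_region <- per_region[order(-per_region$area), , drop = FALSE]
  rownames(per_region) <- NULL

  structure(list(per_residue = per_res, per_region = per_region,
                 total = total, side = side),
            class = "bsa_table")
}

#' @export
print.bsa_table <- function(x, ...) {
  cat(sprintf("bsa_table (%s side): total %.1f A^2\n", x$side, x$total))
  print(transform(x$per_region, area = round(area, 1),
                  percent = round(percent, 1)))
  invisible(x)
}

# Side-chain atoms carrying formal charge, for salt-bridge typing.
.basic_atoms <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                     HIS = c("ND1", "NE2"))
.acidic_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.is_charged <- function(atoms, table) {
  mapply(function(res, nm) nm %in% (table[[res]] %||% character()),
         atoms$resid, atoms$atom, USE.NAMES = FALSE) |
    # C-terminal carboxylate
    (identical(table, .acidic_atoms) & atoms$atom == "OXT")
}

# Polar atoms for distance-only H-bond typing (structures lack hydrogens, so
# donor/acceptor chemistry is approximated by element + residue type).
.is_polar <- function(atoms) {
  atoms$element %in% c("N", "O") |
    (atoms$element == "S" & atoms$resid %in% c("CYS", "MET"))
}

#' Typed atomic contacts across the TCR-pMHC interface
#'
#' Every cross-interface heavy-atom pair within the van der Waals cutoff
#' yields one contact record, typed by precedence
#' SALT_BRIDGE > HBOND > VDW:
#' \itemize{
#'   \item SALT_BRIDGE: Arg NE/NH1/NH2, Lys NZ, His ND1/NE2 versus
#'     Asp OD1/OD2, Glu OE1/OE2 or a C-terminal carboxylate, within
#'     `cutoffs$salt` (default 4.0 Angstrom);
#'   \item HBOND: both atoms polar (N, O, or S of Cys/Met) within
#'     `cutoffs$hbond` (default 3.5 Angstrom); distance-only, since deposited
#'     crystal structures carry no reliable hydrogens;
#'   \item VDW: any remaining pair within `cutoffs$vdw` (default 4.0
#'     Angstrom).
#' }
#'
#' @param model A `complex_model` with both interface sides assigned.
#' @param cutoffs Named list overriding `vdw`, `hbond`, `salt` (Angstrom).
#' @return A `contact_table` data frame: `chain_a`, `resno_a`, `ins_a`,
#'   `resid_a`, `atom_a`, `role_a` (TCR side), the `_b` equivalents (pMHC
#'   side), `distance`, `type`. Use [contact_summary()] for the residue-pair
#'   view.
#' @examples
#' toy <- make_toy_complex(plant_salt_bridge = 3.2)
#' subset(detect_contacts(toy$model), type == "SALT_BRIDGE")
#' @export
detect_contacts <- function(model, cutoffs = list()) {
  cut <- utils::modifyList(list(vdw = 4.0, hbond = 3.5, salt = 4.0), cutoffs)
  a <- model_atoms(model, .tcr_roles)
  b <- model_atoms(model, .pmhc_roles)
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("model must carry both TCR and pMHC sides", call. = FALSE)

  maxcut <- max(cut$vdw, cut$hbond, cut$salt)
  xyz_a <- cbind(a$x, a$y, a$z)
  xyz_b <- cbind(b$x, b$y, b$z)
  pairs <- NULL
  for (i in seq_len(nrow(a))) {
    d2 <- (xyz_b[, 1] - xyz_a[i, 1])^2 + (xyz_b[, 2] - xyz_a[i, 2])^2 +
      (xyz_b[, 3] - xyz_a[i, 3])^2
    hit <- which(d2 <= maxcut^2)
    if (length(hit))
      pairs <- rbind(pairs, cbind(i = i, j = hit, d = sqrt(d2[hit])))
  }
  empty <- data.frame(chain_a = character(), resno_a = integer(),
                      ins_a = character(), resid_a = character(),
                      atom_a = character(), role_a = character(),
                      chain_b = character(), resno_b = integer(),
                      ins_b = character(), resid_b = character(),
                      atom_b = character(), role_b = character(),
                      distance = numeric(), type = character(),
                      stringsAsFactors = FALSE)
  if (is.null(pairs)) return(structure(empty, class = c("contact_table", "data.frame")))

  ai <- a[pairs[, "i"], , drop = FALSE]
  bj <- b[pairs[, "j"], , drop = FALSE]
  d <- pairs[, "d"]

  salt <- d <= cut$salt &
    ((.is_charged(ai, .basic_atoms) & .is_charged(bj, .acidic_atoms)) |
       (.is_charged(ai, .acidic_atoms) & .is_charged(bj, .basic_atoms)))
  hbond <- !salt & d <= cut$hbond & .is_polar(ai) & .is_polar(bj)
  vdw <- !salt & !hbond & d <= cut$vdw
  type <- ifelse(salt, "SALT_BRIDGE", ifelse(hbond, "HBOND",
                                             ifelse(vdw, "VDW", NA)))
  keep <- !is.na(type)

  out <- data.frame(
    chain_a = ai$chain[keep], resno_a = ai$resno[keep], ins_a = ai$ins[keep],
    resid_a = ai$resid[keep], atom_a = ai$atom[keep], role_a = ai$role[keep],
    chain_b = bj$chain[keep], resno_b = bj$resno[keep], ins_b = bj$ins[keep],
    resid_b = bj$resid[keep], atom_b = bj$atom[keep], role_b = bj$role[keep],
    distance = d[keep], type = type[keep], stringsAsFactors = FALSE)
  out <- out[order(out$chain_a, out$resno_a, out$atom_a,
                   out$chain_b, out$resno_b, out$atom_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("contact_table", "data.frame"))
}

#' Residue-pair contact summary
#'
#' Aggregates an atomic [detect_contacts()] table to residue pairs, reporting
#' the strongest contact type (SALT_BRIDGE > HBOND > VDW), per-type counts,
#' and the minimum atomic distance.
#'
#' @param contacts A `contact_table`.
#' @return Data frame with one row per interacting residue pair.
#' @export
contact_summary <- function(contacts) {
  if (nrow(contacts) == 0L)
    return(data.frame(chain_a = character(), resno_a = integer(),
                      resid_a = character(), chain_b = character(),
                      resno_b = integer(), resid_b = character(),
                      strongest = character(), n_salt = integer(),
                      n_hbond = integer(), n_vdw = integer(),
                      min_distance = numeric(), stringsAsFactors = FALSE))
  key <- paste(contacts$chain_a, contacts$resno_a, contacts$ins_a,
               contacts$chain_b, contacts$resno_b, contacts$ins_b, sep = "\r")
  rank <- c(SALT_BRIDGE = 3L, HBOND = 2L, VDW = 1L)
  split_idx <- split(seq_len(nrow(contacts)), key)
  rows <- lapply(split_idx, function(ii) {
    cc <- contacts[ii, , drop = FALSE]
    data.frame(chain_a = cc$chain_a[1], resno_a = cc$resno_a[1],
               resid_a = cc$resid_a[1], chain_b = cc$chain_b[1],
               resno_b = cc$resno_b[1], resid_b = cc$resid_b[1],
               strongest = names(rank)[match(max(rank[cc$type]), rank)],
               n_salt = sum(cc$type == "SALT_BRIDGE"),
               n_hbond = sum(cc$type == "HBOND"),
               n_vdw = sum(cc$type == "VDW"),
               min_distance = min(cc$distance),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chain_a, out$resno_a, out$chain_b, out$resno_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write BSA and contact tables to TSV
#'
#' @param bsa A `bsa_table`.
#' @param contacts A `contact_table`.
#' @param bsa_path,contacts_path Output paths.
#' @return Invisibly, the paths written.
#' @export
write_interface_tables <- function(bsa, contacts, bsa_path = "bsa.tsv",
                                   contacts_path = "contacts.tsv") {
  pr <- bsa$per_residue
  pr$percent <- if (bsa$total > 0) 100 * pr$area / bsa$total else 0
  utils::write.table(format_df_fixed(pr), bsa_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(format_df_fixed(as.data.frame(contacts)), contacts_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bsa_path, contacts_path))
}

# 6 significant digits for byte-stable text reports
format_df_fixed <- function(df) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(signif(x, 6), format = "fg"))
  df
}
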