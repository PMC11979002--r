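#' @importFrom stats setNames
NULL

# Biological roles a chain can take in a TCR-pMHC complex.
.chain_roles <- c("TCR_ALPHA", "TCR_BETA", "MHC_ALPHA", "MHC_BETA",
                  "PEPTIDE", "OTHER")

# Residue names treated as water and always dropped.
.water_names <- c("HOH", "WAT", "DOD", "H2O")

.normalize_role <- function(x) {
  up <- toupper(gsub("[ -]", "_", x))
  if (!all(up %in% .chain_roles)) {
    bad <- setdiff(unique(up), .chain_roles)
    stop("unknown chain role(s): ", paste(bad, collapse = ", "),
         "; valid roles: ", paste(tolower(.chain_roles), collapse = ", "),
         call. = FALSE)
  }
  up
}

#' Load a TCR-pMHC complex from a coordinate file
#'
#' Parses a PDB or mmCIF file into a validated `complex_model`: a flat atom
#' table with biological chain roles attached. Waters are removed, hydrogens
#' are retained but flagged, alternate locations are collapsed to the
#' highest-occupancy conformer (ties broken by alternate-location label), and
#' hetero compounds are excluded unless whitelisted.
#'
#' Author chain identifiers and author residue numbering are authoritative
#' throughout the package, because published residue names (e.g. Asp43 of the
#' MHC beta chain) use author numbering.
#'
#' @param path Path to a `.pdb`, `.ent`, `.cif` or `.mmcif` file.
#' @param role_config Either a named character vector / list mapping chain IDs
#'   to roles (`c(D = "tcr_alpha", E = "tcr_beta", A = "mhc_alpha",
#'   B = "mhc_beta", C = "peptide")`), or a list with elements `chains` (that
#'   mapping) and optionally `regions` (see [assign_imgt_regions()]) and
#'   `het_whitelist`, or a path to a YAML/JSON file holding that list.
#'   Valid roles: `tcr_alpha`, `tcr_beta`, `mhc_alpha`, `mhc_beta`,
#'   `peptide`, `other`.
#' @param het_whitelist Character vector of hetero residue names to retain
#'   (ions, glycans); everything else HETATM is dropped. Waters are always
#'   dropped.
#' @return An object of class `complex_model`: a list with `atoms` (data frame
#'   with columns `chain`, `role`, `resno`, `ins`, `resid`, `atom`, `element`,
#'   `x`, `y`, `z`, `occ`, `is_heavy`), `source_id`, and `region_override`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' toy <- make_toy_complex()
#' write_complex_pdb(toy$model, pdb)
#' m <- load_complex(pdb, toy$role_config)
#' nrow(m$atoms)
#' @export
load_complex <- function(path, role_config, het_whitelist = character()) {
  if (!file.exists(path)) stop("coordinate file not found: ", path, call. = FALSE)
  cfg <- .resolve_role_config(role_config)
  if (length(cfg$het_whitelist)) het_whitelist <- union(het_whitelist, cfg$het_whitelist)

  ext <- tolower(tools::file_ext(path))
  parsed <- tryCatch({
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE)
  }, error = function(e) {
    stop("failed to parse coordinate file '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })

  at <- parsed$atom
  at$chain[is.na(at$chain)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # waters out unconditionally; hetero out unless whitelisted
  at <- at[!(toupper(at$resid) %in% .water_names), , drop = FALSE]
  keep_het <- at$type != "HETATM" | toupper(at$resid) %in% toupper(het_whitelist)
  at <- at[keep_het, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms remain after filtering in ", path, call. = FALSE)

  avail <- sort(unique(at$chain))
  missing <- setdiff(names(cfg$chains), avail)
  if (length(missing)) {
    stop("role config names chain(s) absent from file: ",
         paste(missing, collapse = ", "),
         "; available chains: ", paste(avail, collapse = ", "), call. = FALSE)
  }

  # highest-occupancy alternate conformer per (chain, resno, ins, atom name);
  # ties resolved by alphabetical alt_loc label
  ord <- order(at$chain, at$resno, at$insert, at$elety, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  at <- at[!duplicated(key), , drop = FALSE]
  at <- at[order(at$chain, at$resno, at$insert, at$elety), , drop = FALSE]

  element <- .atom_element(at$elesy, at$elety)
  atoms <- data.frame(
    chain = at$chain,
    role = unname(ifelse(at$chain %in% names(cfg$chains),
                         cfg$chains[at$chain], "OTHER")),
    resno = as.integer(at$resno),
    ins = at$insert,
    resid = toupper(at$resid),
    atom = at$elety,
    element = element,
    x = at$x, y = at$y, z = at$z,
    occ = at$o,
    is_heavy = !(element %in% c("H", "D")),
    stringsAsFactors = FALSE
  )
  model <- structure(
    list(atoms = atoms,
         source_id = basename(path),
         region_override = cfg$regions),
    class = "complex_model")
  .validate_complex_model(model)
  model
}

.resolve_role_config <- function(role_config) {
  if (is.character(role_config) && length(role_config) == 1L &&
      is.null(names(role_config)) && file.exists(role_config)) {
    ext <- tolower(tools::file_ext(role_config))
    role_config <- if (ext %in% c("yml", "yaml")) {
      yaml::read_yaml(role_config)
    } else {
      jsonlite::read_json(role_config, simplifyVector = TRUE)
    }
  }
  if (!is.null(names(role_config)) && !("chains" %in% names(role_config))) {
    role_config <- list(chains = role_config)
  }
  chains <- unlist(role_config$chains)
  if (is.null(chains) || is.null(names(chains)) || any(names(chains) == "")) {
    stop("role config must map chain IDs to roles, e.g. ",
         "c(A = \"mhc_alpha\", ...)", call. = FALSE)
  }
  chains <- setNames(.normalize_role(chains), names(chains))
  list(chains = chains,
       regions = role_config$regions,
       het_whitelist = unlist(role_config$het_whitelist))
}

.atom_element <- function(elesy, elety) {
  el <- toupper(trimws(as.character(elesy)))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # derive from the atom name: strip digits, take the leading letters;
    # two-letter elements in proteins are rare (FE, ZN, MG ...)
    guess <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", elety[miss])))
    two <- c("FE", "ZN", "MG", "MN", "CA", "NA", "CL", "CU", "NI", "SE", "BR")
    first2 <- substr(guess, 1, 2)
    el[miss] <- ifelse(first2 %in% two & nchar(guess) > 1, first2,
                       substr(guess, 1, 1))
  }
  el
}

.validate_complex_model <- function(model) {
  atoms <- model$atoms
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in model", call. = FALSE)
  if (any(atoms$occ < 0 | atoms$occ > 1))
    stop("occupancy outside [0, 1]", call. = FALSE)
  # one chain per non-OTHER role
  cr <- unique(atoms[, c("chain", "role")])
  dup <- cr$role[duplicated(cr$role) & cr$role != "OTHER"]
  if (length(dup))
    stop("multiple chains share role(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  pep <- atoms[atoms$role == "PEPTIDE", , drop = FALSE]
  if (nrow(pep)) {
    nres <- nrow(unique(pep[, c("resno", "ins")]))
    if (nres < 8 || nres > 25)
      stop("peptide chain has ", nres,
           " residues; expected 8-25 for a class II groove peptide",
           call. = FALSE)
  }
  invisible(model)
}

#' @export
print.complex_model <- function(x, ...) {
  cat("complex_model:", x$source_id, "\n")
  tab <- table(x$atoms$role[!duplicated(paste(x$atoms$chain, x$atoms$resno,
                                              x$atoms$ins))])
  for (r in names(tab)) cat(sprintf("  %-10s %4d residues\n", r, tab[[r]]))
  cat("  atoms:", nrow(x$atoms), "(", sum(x$atoms$is_heavy), "heavy )\n")
  invisible(x)
}

# Atom subset helper used across the analysis modules.
model_atoms <- function(model, roles = NULL, heavy_only = TRUE) {
  at <- model$atoms
  if (!is.null(roles)) at <- at[at$role %in% roles, , drop = FALSE]
  if (heavy_only) at <- at[at$is_heavy, , drop = FALSE]
  at
}

#' Write a complex model to a PDB file
#'
#' Serializes the atom table back to fixed-width PDB `ATOM` records (one
#' model, author numbering preserved). Round-trips through [load_complex()]
#' to 1e-3 Angstrom, the precision of the PDB coordinate field.
#'
#' @param model A `complex_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(model, path) {
  at <- model$atoms
  name4 <- ifelse(nchar(at$atom) >= 4, substr(at$atom, 1, 4),
                  sprintf(" %-3s", at$atom))
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)) %% 100000L, name4, at$resid, substr(at$chain, 1, 1),
    at$resno, ifelse(at$ins == "", " ", at$ins),
    at$x, at$y, at$z, at$occ, 0, at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# IMGT unique-numbering region boundaries for TCR variable domains.
.imgt_regions <- data.frame(
  region = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"),
  from = c(1L, 27L, 39L, 56L, 66L, 105L, 118L),
  to   = c(26L, 38L, 55L, 65L, 104L, 117L, 128L),
  stringsAsFactors = FALSE
)

#' Annotate TCR variable-domain regions from IMGT numbering
#'
#' Labels every residue of the TCR alpha and beta chains with its IMGT
#' unique-numbering region: FR1 1-26, CDR1 27-38, FR2 39-55, CDR2 56-65,
#' FR3 66-104, CDR3 105-117, FR4 118-128, and CONSTANT beyond 128. The four
#' framework regions aggregate to "FW" for reporting (the FWalpha / FWbeta
#' groupings used when decomposing interface area).
#'
#' @param model A `complex_model` whose TCR chains carry IMGT numbering
#'   (true for deposited TCR complexes numbered on the IMGT scheme). If not,
#'   supply explicit ranges via `override` or the `regions` entry of the role
#'   config: a list per role, e.g.
#'   `list(tcr_alpha = list(CDR1 = c(25, 32), ...))`.
#' @param override Optional explicit region ranges (same shape as above),
#'   taking precedence over both IMGT defaults and the config.
#' @return A `region_annotation` data frame with columns `chain`, `role`,
#'   `resno`, `ins`, `region`, `group` (region with FR1-FR4 collapsed to FW).
#' @examples
#' toy <- make_toy_complex()
#' head(assign_imgt_regions(toy$model))
#' @export
assign_imgt_regions <- function(model, override = NULL) {
  override <- override %||% model$region_override
  tcr <- model$atoms[model$atoms$role %in% c("TCR_ALPHA", "TCR_BETA"),
                     c("chain", "role", "resno", "ins")]
  if (nrow(tcr) == 0L) stop("model has no TCR chains", call. = FALSE)
  res <- unique(tcr)
  res <- res[order(res$role, res$resno, res$ins), , drop = FALSE]

  label_one <- function(role_res, role) {
    ranges <- .imgt_regions
    ov <- override[[tolower(role)]] %||% override[[role]]
    if (!is.null(ov)) {
      ranges <- do.call(rbind, lapply(names(ov), function(nm) {
        data.frame(region = nm, from = ov[[nm]][1], to = ov[[nm]][2],
                   stringsAsFactors = FALSE)
      }))
    } else if (!any(role_res$resno >= 1 & role_res$resno <= 128)) {
      stop("TCR chain with role ", role, " has no residues numbered 1-128; ",
           "not on the IMGT scheme - supply explicit region ranges",
           call. = FALSE)
    }
    idx <- findInterval(role_res$resno, ranges$from)
    region <- ifelse(idx >= 1 & role_res$resno <= ranges$to[pmax(idx, 1)],
                     ranges$region[pmax(idx, 1)], NA_character_)
    region[is.na(region) & role_res$resno > max(ranges$to)] <- "CONSTANT"
    region[is.na(region)] <- "CONSTANT"  # numbering gaps outside any range
    region
  }

  out <- do.call(rbind, lapply(split(res, res$role), function(rr) {
    rr$region <- label_one(rr, rr$role[1])
    rr
  }))
  rownames(out) <- NULL
  out$group <- ifelse(grepl("^FR", out$region), "FW", out$region)
  class(out) <- c("region_annotation", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
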