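#' Run the full interface analysis and assemble a report bundle
#'
#' Executes load -> region annotation -> buried-surface decomposition ->
#' contact detection -> docking topology for each configured structure and
#' writes, per structure, `bsa.tsv`, `contacts.tsv` and `topology.json`,
#' plus a bundle-level human-readable `summary.txt` and machine-readable
#' `metrics.json` holding every headline quantity (TCR-side total buried
#' area, per-region percentages, topology classes, minimum CDR-peptide
#' distance, salt-bridge count). Floats are serialized at 6 significant
#' digits with sorted keys, so identical inputs give byte-identical reports.
#'
#' @param config A list with:
#'   \describe{
#'     \item{structures}{list of entries `list(id =, path =, chains =,
#'       regions = NULL, het_whitelist = NULL)`; alternatively `model =` a
#'       ready-made `complex_model` instead of `path`/`chains`.}
#'     \item{out_dir}{output directory (created if missing).}
#'     \item{cutoffs}{optional contact cutoff overrides, see
#'       [detect_contacts()].}
#'     \item{sasa}{optional list of `probe`, `n_points`, `radii` overrides.}
#'   }
#'   or a path to a YAML/JSON file holding that list.
#' @return Invisibly, the metrics list (also written to `metrics.json`).
#' @examples
#' toy <- make_toy_complex()
#' cfg <- list(structures = list(list(id = "toy", model = toy$model)),
#'             out_dir = tempfile(), sasa = list(n_points = 240))
#' m <- run_analyze(cfg)
#' m$toy$topology$polarity
#' @export
run_analyze <- function(config) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$structures) || !length(config$structures))
    stop("config must list at least one structure", call. = FALSE)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sasa_cfg <- utils::modifyList(list(probe = 1.4, n_points = 960,
                                     radii = NULL),
                                config$sasa %||% list())
  cutoffs <- config$cutoffs %||% list()

  metrics <- list()
  summary_lines <- character()
  for (entry in config$structures) {
    id <- entry$id %||% basename(entry$path %||% "model")
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed for structure '", id, "': ",
             conditionMessage(e), call. = FALSE))
    }
    model <- stage("load", {
      if (!is.null(entry$model)) entry$model
      else load_complex(entry$path,
                        list(chains = entry$chains, regions = entry$regions),
                        het_whitelist = entry$het_whitelist %||% character())
    })
    regions <- stage("regions", assign_imgt_regions(model))
    bsa <- stage("bsa", compute_bsa_decomposition(
      model, regions, side = "TCR", probe = sasa_cfg$probe,
      n_points = sasa_cfg$n_points, radii = sasa_cfg$radii))
    contacts <- stage("contacts", detect_contacts(model, cutoffs))
    topo <- stage("topology", docking_descriptors(model, regions))

    sdir <- file.path(out_dir, id)
    dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
    write_interface_tables(bsa, contacts,
                           file.path(sdir, "bsa.tsv"),
                           file.path(sdir, "contacts.tsv"))
    topo_out <- lapply(unclass(topo), function(v)
      if (is.numeric(v)) signif(v, 6) else v)
    jsonlite::write_json(topo_out, file.path(sdir, "topology.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    pct <- stats::setNames(as.list(signif(bsa$per_region$percent, 6)),
                           bsa$per_region$region)
    metrics[[id]] <- list(
      tcr_bsa_total = signif(bsa$total, 6),
      region_percent = pct[order(names(pct))],
      topology = list(polarity = topo$polarity, mode = topo$mode,
                      crossing_angle = signif(topo$crossing_angle, 6),
                      tilt_angle = signif(topo$tilt_angle, 6)),
      min_cdr_peptide_distance = signif(topo$min_cdr_peptide_distance, 6),
      n_contacts = nrow(contacts),
      n_salt_bridges = sum(contacts$type == "SALT_BRIDGE"),
      n_hbonds = sum(contacts$type == "HBOND"))
    summary_lines <- c(summary_lines, sprintf(
      "%s: BSA(TCR) %.1f A^2; %s %s; min CDR-peptide %.1f A; %d contacts (%d salt bridges)",
      id, bsa$total, topo$polarity, topo$mode,
      topo$min_cdr_peptide_distance, nrow(contacts),
      sum(contacts$type == "SALT_BRIDGE")))
  }
  metrics <- metrics[order(names(metrics))]
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(metrics)
}
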