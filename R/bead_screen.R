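.bead_terms <- c("s_n", "snc", "bg_n", "bgnc")

#' Normalize a single-antigen bead panel
#'
#' Applies the standard single-antigen bead normalization
#' `(S#N - SNC) - (BG#N - BGNC)` per bead, where `S#N` is the
#' sample-specific trimmed-mean fluorescence for bead N, `SNC` the sample
#' value on the negative-control (nude) bead, `BG#N` the background value for
#' bead N, and `BGNC` the background value on the negative-control bead.
#' Negative normalized values are retained (clipping would bias downstream
#' threshold estimation).
#'
#' @param panel Data frame with columns `bead_id`, `allele`, `s_n`, `snc`,
#'   `bg_n`, `bgnc`, and optionally `replicate`, `panel`.
#' @return The panel with a `normalized` column appended.
#' @examples
#' normalize_panel(data.frame(bead_id = 1, allele = "DQB1*02:01",
#'                            s_n = 1000, snc = 100, bg_n = 150, bgnc = 50))
#' @export
normalize_panel <- function(panel) {
  miss_col <- setdiff(.bead_terms, names(panel))
  if (length(miss_col))
    stop("bead panel lacks column(s): ", paste(miss_col, collapse = ", "),
         call. = FALSE)
  for (term in .bead_terms) {
    bad <- which(!is.finite(panel[[term]]))
    if (length(bad))
      stop("bead ", panel$bead_id[bad[1]], " has missing term '", term, "'",
           call. = FALSE)
    if (any(panel[[term]] < 0))
      stop("fluorescence term '", term, "' has negative raw values",
           call. = FALSE)
  }
  panel$normalized <- (panel$s_n - panel$snc) - (panel$bg_n - panel$bgnc)
  panel
}

#' Bundled HLA allele-group lookup
#'
#' Maps allele names (e.g. `DQB1*02:01`) to serological groups (e.g. `DQ2`)
#' using the editable table shipped in `inst/extdata/allele_groups.csv`.
#' Alleles with no entry map to `NA`.
#'
#' @param alleles Character vector of allele names.
#' @param table_path Optional path to an alternative lookup CSV with columns
#'   `pattern` (regular expression) and `group`.
#' @return Character vector of group labels.
#' @export
allele_group <- function(alleles, table_path = NULL) {
  path <- table_path %||%
    system.file("extdata", "allele_groups.csv", package = "tcrdock")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- rep(NA_character_, length(alleles))
  for (k in seq_len(nrow(tab))) {
    hit <- is.na(out) & grepl(tab$pattern[k], alleles)
    out[hit] <- tab$group[k]
  }
  out
}

#' Call per-allele reactivity after isotype subtraction
#'
#' Net MFI per bead is the normalized sample signal minus the normalized
#' isotype-control signal (a PE-conjugated IgG run on the same bead set).
#' Replicate panels are aggregated by mean before calling. A bead is POSITIVE
#' when its net MFI strictly exceeds the threshold; by default the threshold
#' is `mean + 3 * SD` of the net values of beads outside the candidate allele
#' group (a robust null estimated from the beads not expected to react), with
#' a fixed numeric alternative.
#'
#' @param sample_panel,isotype_panel Bead panels (see [normalize_panel()];
#'   normalized on the fly if the `normalized` column is absent). Bead sets
#'   must match.
#' @param threshold Either `NULL` (default `mean + 3 * SD` rule), or a fixed
#'   numeric MFI threshold.
#' @param candidate_group Group label (see [allele_group()]) whose beads are
#'   excluded from the threshold estimate, e.g. `"DQ2"`. Ignored for a fixed
#'   threshold.
#' @param group_table_path Optional alternative allele-group lookup.
#' @return A `reactivity_calls` data frame: `bead_id`, `allele`, `group`,
#'   `net_mfi`, `normalized_sample`, `call`, `threshold`.
#' @examples
#' pans <- simulate_bead_panel(seed = 1)
#' calls <- call_reactivity(pans$sample, pans$isotype, candidate_group = "DQ2")
#' subset(calls, call == "POSITIVE")$allele
#' @export
call_reactivity <- function(sample_panel, isotype_panel, threshold = NULL,
                            candidate_group = NULL, group_table_path = NULL) {
  if (!"normalized" %in% names(sample_panel))
    sample_panel <- normalize_panel(sample_panel)
  if (!"normalized" %in% names(isotype_panel))
    isotype_panel <- normalize_panel(isotype_panel)

  agg <- function(p) {
    out <- stats::aggregate(normalized ~ bead_id + allele, data = p, FUN = mean)
    out[order(out$bead_id), , drop = FALSE]
  }
  s <- agg(sample_panel)
  i <- agg(isotype_panel)
  only_s <- setdiff(s$bead_id, i$bead_id)
  only_i <- setdiff(i$bead_id, s$bead_id)
  if (length(only_s) || length(only_i))
    stop("bead sets differ; only in sample: ",
         paste(only_s, collapse = ", "), "; only in isotype: ",
         paste(only_i, collapse = ", "), call. = FALSE)

  net <- s$normalized - i$normalized[match(s$bead_id, i$bead_id)]
  grp <- allele_group(s$allele, group_table_path)
  if (is.null(threshold)) {
    null_net <- if (is.null(candidate_group)) net else net[is.na(grp) | grp != candidate_group]
    if (length(null_net) < 2)
      stop("too few beads outside the candidate group to estimate a threshold",
           call. = FALSE)
    threshold <- mean(null_net) + 3 * stats::sd(null_net)
  }
  out <- data.frame(bead_id = s$bead_id, allele = s$allele, group = grp,
                    net_mfi = net, normalized_sample = s$normalized,
                    call = ifelse(net > threshold, "POSITIVE", "NEGATIVE"),
                    threshold = threshold, stringsAsFactors = FALSE)
  class(out) <- c("reactivity_calls", "data.frame")
  out
}

#' Write reactivity calls and a bar-chart-ready summary
#'
#' @param calls A `reactivity_calls` data frame.
#' @param reactivity_path,summary_path Output TSV paths.
#' @return Invisibly, the paths written.
#' @export
write_reactivity_tables <- function(calls, reactivity_path = "reactivity.tsv",
                                    summary_path = "reactivity_summary.tsv") {
  utils::write.table(format_df_fixed(as.data.frame(calls)), reactivity_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- stats::aggregate(net_mfi ~ allele, data = calls, FUN = mean)
  summ$call <- calls$call[match(summ$allele, calls$allele)]
  utils::write.table(format_df_fixed(summ), summary_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(reactivity_path, summary_path))
}
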