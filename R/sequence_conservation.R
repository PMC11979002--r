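# Clustal residue substitution groups used for column conservation classes.
.clustal_strong <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF",
                     "HY", "FYW")
.clustal_weak <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND", "SNDEQK",
                   "NDEQHK", "NEQHRK", "FVLIM", "HFY")

#' Pairwise sequence identity
#'
#' Fraction of identical residues between two amino-acid sequences, either
#' over a supplied alignment (`ALIGNED`: equal-length strings, gaps as `-`)
#' or after global Needleman-Wunsch alignment (`GLOBAL_NW`: default scoring
#' match = 1, mismatch = 0, linear gap = -1). The denominator is
#' configurable, since published identity percentages depend on it.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings.
#' @param mode `"ALIGNED"` or `"GLOBAL_NW"`.
#' @param denominator `"alignment"` (aligned length, default), `"shorter"`,
#'   or `"longer"` (the unaligned sequence lengths).
#' @param match,mismatch,gap NW scoring parameters.
#' @return List with `identity` (fraction in [0, 1]), `matches`,
#'   `alignment_length`, and for `GLOBAL_NW` also `score` and the two
#'   aligned strings.
#' @examples
#' pairwise_identity("ACGTA", "ACTA", mode = "GLOBAL_NW")$identity
#' @export
pairwise_identity <- function(seq_a, seq_b, mode = c("ALIGNED", "GLOBAL_NW"),
                              denominator = c("alignment", "shorter", "longer"),
                              match = 1, mismatch = 0, gap = -1) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("sequences must be non-empty", call. = FALSE)
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]

  if (mode == "ALIGNED") {
    if (length(a) != length(b))
      stop("ALIGNED mode requires equal-length sequences", call. = FALSE)
    ali_a <- a; ali_b <- b; score <- NA_real_
  } else {
    nw <- needleman_wunsch(a, b, match, mismatch, gap)
    ali_a <- nw$aligned_a; ali_b <- nw$aligned_b; score <- nw$score
  }
  matches <- sum(ali_a == ali_b & ali_a != "-")
  denom <- switch(denominator,
                  alignment = length(ali_a),
                  shorter = min(length(a), length(b)),
                  longer = max(length(a), length(b)))
  out <- list(identity = matches / denom, matches = matches,
              alignment_length = length(ali_a), score = score)
  if (mode == "GLOBAL_NW") {
    out$aligned_a <- paste(ali_a, collapse = "")
    out$aligned_b <- paste(ali_b, collapse = "")
  }
  out
}

# Global alignment with linear gap penalty; ties resolved deterministically
# (diagonal > up > left) so repeated runs give the same traceback.
needleman_wunsch <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(S[i, j] + sub[j],
                             S[i, j + 1] + gap,
                             S[i + 1, j] + gap)
    }
  }
  i <- n; j <- m
  ra <- character(0); rb <- character(0)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + ifelse(a[i] == b[j], match, mismatch)) {
      ra <- c(a[i], ra); rb <- c(b[j], rb); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ra <- c(a[i], ra); rb <- c("-", rb); i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(b[j], rb); j <- j - 1
    }
  }
  list(score = S[n + 1, m + 1], aligned_a = ra, aligned_b = rb)
}

#' Columnwise conservation profile of an alignment
#'
#' Classifies every column of a pre-aligned set of sequences in Clustal
#' style: `IDENTICAL` (one residue type, no gaps), `HIGH` (all residues in
#' one strong substitution group), `SEMI` (one weak group), else `VARIABLE`.
#' Columns containing a gap are `VARIABLE` unless all rows are identical
#' non-gap residues (a gap breaks physicochemical grouping). Interface
#' positions of interest can be flagged, and the count of interface
#' positions classed `IDENTICAL` is returned - the "conserved interacting
#' residues" statistic.
#'
#' @param alignment Character vector of equal-length aligned sequences
#'   (gap `-`), optionally named.
#' @param interface_positions Integer vector of 1-based alignment columns.
#' @return A `conservation_profile`: list with `columns` (data frame:
#'   `position`, `class`, `is_interface`), `n_interface`,
#'   `n_interface_identical`.
#' @examples
#' prof <- conservation_profile(c("LLKV", "LIKV", "LVKV"), c(1, 3))
#' prof$columns$class
#' @export
conservation_profile <- function(alignment, interface_positions = integer()) {
  if (length(alignment) < 2)
    stop("alignment needs >= 2 sequences", call. = FALSE)
  rows <- strsplit(toupper(alignment), "")
  len <- unique(lengths(rows))
  if (length(len) != 1)
    stop("aligned sequences must have equal length", call. = FALSE)
  if (length(interface_positions) &&
      (min(interface_positions) < 1 || max(interface_positions) > len))
    stop("interface position(s) outside alignment columns 1-", len,
         call. = FALSE)
  mat <- do.call(rbind, rows)

  classify_col <- function(col) {
    u <- unique(col)
    if (length(u) == 1 && u != "-") return("IDENTICAL")
    if ("-" %in% u) return("VARIABLE")
    in_group <- function(groups) any(vapply(
      strsplit(groups, ""), function(g) all(u %in% g), logical(1)))
    if (in_group(.clustal_strong)) return("HIGH")
    if (in_group(.clustal_weak)) return("SEMI")
    "VARIABLE"
  }
  cls <- apply(mat, 2, classify_col)
  cols <- data.frame(position = seq_len(len), class = cls,
                     is_interface = seq_len(len) %in% interface_positions,
                     stringsAsFactors = FALSE)
  structure(list(columns = cols,
                 n_interface = length(interface_positions),
                 n_interface_identical =
                   sum(cols$class == "IDENTICAL" & cols$is_interface)),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("conservation_profile: %d columns (%s)\n",
              nrow(x$columns),
              paste(names(table(x$columns$class)),
                    table(x$columns$class), sep = "=", collapse = ", ")))
  if (x$n_interface)
    cat(sprintf("  interface positions identical: %d / %d\n",
                x$n_interface_identical, x$n_interface))
  invisible(x)
}

#' Read aligned or unaligned FASTA sequences
#'
#' Thin wrapper returning plain named character strings.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  fa <- bio3d::read.fasta(path)
  stats::setNames(apply(fa$ali, 1, paste, collapse = ""), rownames(fa$ali))
}

#' Write a conservation profile to TSV
#'
#' @param profile A `conservation_profile`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_conservation_tsv <- function(profile, path = "conservation.tsv") {
  utils::write.table(profile$columns, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
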