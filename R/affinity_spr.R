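#' Fit a steady-state 1:1 binding isotherm
#'
#' Nonlinear least-squares fit of the Langmuir isotherm
#' `Req(C) = Rmax * C / (KD + C)` to equilibrium surface plasmon resonance
#' responses, the standard model for steady-state TCR-pMHC affinity
#' measurement. Starting values are `Rmax0 = max(Req)` and `KD0` at the
#' concentration nearest half-maximal response; parameters are bounded to
#' `KD in (0, 100 * Cmax]` and `Rmax in (0, 10 * max(Req)]`, with a small
#' grid of bounded restarts on failure. A fit whose estimated KD exceeds
#' `10 * Cmax` is beyond the quantifiable range of the titration and is
#' flagged `censored`, carrying that bound in `kd_lower_bound` ("no binding"
#' in mutant-effect terms).
#'
#' @param series A data frame with columns `concentration_uM` and
#'   `response_RU` (optionally `replicate`), or a numeric vector of
#'   concentrations with `response` supplied separately.
#' @param response Equilibrium responses (RU) if `series` is a numeric
#'   vector.
#' @param normalise If `TRUE`, responses are divided by the fitted maximum
#'   and the isotherm refit on the normalised scale (the optional
#'   preprocessing used when overlaying curves); default `FALSE`, fitting raw
#'   responses.
#' @return A `binding_fit`: list with `kd` (uM), `rmax` (RU), `kd_se`,
#'   `rmax_se`, `rss`, `converged`, `censored`, `kd_lower_bound`,
#'   `n_concentrations`.
#' @examples
#' s <- simulate_spr(kd = 10, rmax = 100,
#'                   concentrations = 80 / 2^(0:7), noise_sd_fraction = 0)
#' fit_steady_state(s)$kd
#' @export
fit_steady_state <- function(series, response = NULL, normalise = FALSE) {
  if (is.numeric(series)) {
    series <- data.frame(concentration_uM = series, response_RU = response)
  }
  conc <- series$concentration_uM
  resp <- series$response_RU
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("concentrations must be positive and finite", call. = FALSE)
  if (length(unique(conc)) < 4)
    stop("need >= 4 distinct analyte concentrations", call. = FALSE)

  cmax <- max(conc)
  rmax0 <- max(resp)
  half <- rmax0 / 2
  kd0 <- conc[which.min(abs(resp - half))]
  kd0 <- min(max(kd0, 1e-6), 100 * cmax)
  lower <- c(kd = 1e-9, rmax = 1e-9)
  upper <- c(kd = 100 * cmax, rmax = 10 * rmax0)

  starts <- rbind(c(kd0, rmax0),
                  c(cmax, rmax0), c(cmax / 10, rmax0), c(10 * cmax, 2 * rmax0))
  fit <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        resp ~ rmax * conc / (kd + conc),
        start = list(kd = starts[k, 1], rmax = starts[k, 2]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(structure(list(kd = NA_real_, rmax = NA_real_, kd_se = NA_real_,
                          rmax_se = NA_real_, rss = NA_real_,
                          converged = FALSE, censored = FALSE,
                          kd_lower_bound = NA_real_,
                          n_concentrations = length(unique(conc))),
                     class = "binding_fit"))
  }
  if (normalise) {
    rmax_hat <- stats::coef(fit)[["rmax"]]
    resp <- resp / rmax_hat
    fit <- minpack.lm::nlsLM(
      resp ~ rmax * conc / (kd + conc),
      start = list(kd = stats::coef(fit)[["kd"]], rmax = 1),
      lower = lower, upper = c(kd = 100 * cmax, rmax = 10))
  }
  co <- summary(fit)$coefficients
  kd <- co["kd", "Estimate"]
  # a KD estimate at/above 10 Cmax, or a fit pinned to its Rmax bound, means
  # the titration never approaches saturation: KD and Rmax are only jointly
  # identified (the kd/rmax ridge), so the affinity is unquantifiable
  censored <- kd >= 10 * cmax * (1 - 1e-9) ||
    co["rmax", "Estimate"] >= 10 * rmax0 * (1 - 1e-9)
  structure(list(
    kd = if (censored) NA_real_ else kd,
    rmax = co["rmax", "Estimate"],
    kd_se = co["kd", "Std. Error"],
    rmax_se = co["rmax", "Std. Error"],
    rss = sum(stats::resid(fit)^2),
    converged = TRUE,
    censored = censored,
    kd_lower_bound = if (censored) 10 * cmax else NA_real_,
    n_concentrations = length(unique(conc))),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("binding_fit: censored (KD > %.3g uM; binding too weak to quantify)\n",
                x$kd_lower_bound))
  } else if (!x$converged) {
    cat("binding_fit: did not converge\n")
  } else {
    cat(sprintf("binding_fit: KD = %.4g +/- %.2g uM, Rmax = %.4g +/- %.2g RU\n",
                x$kd, x$kd_se, x$rmax, x$rmax_se))
  }
  invisible(x)
}

# Mutant-effect category boundaries. Published captions leave gaps (2..3 in
# the TCR scheme, 1..1.5 in the HLA scheme); intervals are made total here:
# TCR scheme (0,2], (2,5], (5,10], (10,Inf) - every upper bound closed;
# HLA scheme (0,1.5), [1.5,3], (3,10], (10,Inf) - 1.5 opens the mild class.
# `upper_closed` says whether a fold exactly at `upper` takes this label.
.effect_schemes <- list(
  TCR_MUTANT = data.frame(
    label = c("negligible", "moderate", "substantial", "critical"),
    upper = c(2, 5, 10, Inf),
    upper_closed = c(TRUE, TRUE, TRUE, TRUE), stringsAsFactors = FALSE),
  HLA_MUTANT = data.frame(
    label = c("negligible", "mild", "moderate", "critical"),
    upper = c(1.5, 3, 10, Inf),
    upper_closed = c(FALSE, TRUE, TRUE, TRUE), stringsAsFactors = FALSE)
)

#' Classify a mutant's effect from its affinity fold change
#'
#' Maps `fold = kd_mutant / kd_wildtype` onto a categorical effect label.
#' Two published schemes are supported:
#' \itemize{
#'   \item `TCR_MUTANT` (alanine scan on the TCR): negligible (fold <= 2),
#'     moderate (2-5], substantial (5-10], critical (> 10 or no binding);
#'   \item `HLA_MUTANT` (alanine scan on the HLA): negligible (< 1.5),
#'     mild [1.5-3], moderate (3-10], critical (> 10 or no binding).
#' }
#' A censored mutant fit (binding too weak to quantify) is always critical.
#'
#' @param kd_mut Mutant KD in uM, or a censored `binding_fit`.
#' @param kd_wt Wild-type KD in uM (> 0).
#' @param scheme `"TCR_MUTANT"` or `"HLA_MUTANT"` (prefix-matched,
#'   case-insensitive).
#' @param boundaries Optional data frame with `label` and `upper` columns
#'   overriding the scheme's upper interval bounds.
#' @return An `effect_class`: list with `scheme`, `label`, `fold`,
#'   `censored`.
#' @examples
#' classify_fold_change(4 * 12.4, 12.4, "TCR_MUTANT")$label  # "moderate"
#' @export
classify_fold_change <- function(kd_mut, kd_wt,
                                 scheme = c("TCR_MUTANT", "HLA_MUTANT"),
                                 boundaries = NULL) {
  scheme <- match.arg(toupper(scheme[1]), names(.effect_schemes))
  if (!is.finite(kd_wt) || kd_wt <= 0)
    stop("kd_wt must be positive", call. = FALSE)
  censored <- inherits(kd_mut, "binding_fit") && kd_mut$censored
  if (inherits(kd_mut, "binding_fit")) kd_mut <- kd_mut$kd
  bounds <- boundaries %||% .effect_schemes[[scheme]]
  if (censored) {
    return(structure(list(scheme = scheme, label = "critical", fold = Inf,
                          censored = TRUE), class = "effect_class"))
  }
  fold <- kd_mut / kd_wt
  if (!is.finite(fold) || fold <= 0)
    stop("fold change must be positive and finite; got ", fold, call. = FALSE)
  if (!"upper_closed" %in% names(bounds)) bounds$upper_closed <- TRUE
  hit <- which(ifelse(bounds$upper_closed, fold <= bounds$upper,
                      fold < bounds$upper))[1]
  label <- bounds$label[hit]
  structure(list(scheme = scheme, label = label, fold = fold,
                 censored = FALSE), class = "effect_class")
}

#' @export
print.effect_class <- function(x, ...) {
  cat(sprintf("effect_class (%s): %s (%.3g-fold)\n",
              x$scheme, x$label, x$fold))
  invisible(x)
}

#' Fit and classify a batch of mutant binding series
#'
#' @param series_list Named list of binding series (see
#'   [fit_steady_state()]); must include the entry named by `wildtype`.
#' @param wildtype Name of the wild-type series.
#' @param scheme Classification scheme, see [classify_fold_change()].
#' @return Data frame (one row per series): `mutant`, `kd`, `censored`,
#'   `fold`, `class`.
#' @export
fit_mutant_batch <- function(series_list, wildtype = "WT",
                             scheme = "TCR_MUTANT") {
  stopifnot(wildtype %in% names(series_list))
  fits <- lapply(series_list, fit_steady_state)
  kd_wt <- fits[[wildtype]]$kd
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    cl <- if (nm == wildtype) NULL else classify_fold_change(f, kd_wt, scheme)
    data.frame(mutant = nm, kd = f$kd, censored = f$censored,
               fold = if (is.null(cl)) 1 else cl$fold,
               class = if (is.null(cl)) "wildtype" else cl$label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a concentration-response CSV
#'
#' Expects columns `concentration_uM`, `response_RU` and optionally
#' `replicate`.
#'
#' @param path CSV file path.
#' @return Data frame suitable for [fit_steady_state()].
#' @export
read_binding_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration_uM", "response_RU")
  if (!all(need %in% names(df)))
    stop("binding CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}
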