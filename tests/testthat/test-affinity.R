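test_that("noiseless isotherm data recover KD and Rmax to 1e-6 relative", {
  s <- simulate_spr(kd = 10, rmax = 100, concentrations = 80 / 2^(0:7),
                    noise_sd_fraction = 0)
  fit <- fit_steady_state(s)
  expect_true(fit$converged)
  expect_equal(fit$kd, 10, tolerance = 1e-6)
  expect_equal(fit$rmax, 100, tolerance = 1e-6)
})

test_that("response at C = KD equals half of Rmax", {
  s <- simulate_spr(kd = 12.4, rmax = 80, concentrations = c(12.4, 5, 50, 100),
                    noise_sd_fraction = 0)
  expect_equal(s$response_RU[1], 40, tolerance = 1e-12)
})

test_that("fit is scale-equivariant in concentration and response", {
  s <- simulate_spr(kd = 12.4, rmax = 100, noise_sd_fraction = 0.05, seed = 1)
  f0 <- fit_steady_state(s)
  s_c <- transform(s, concentration_uM = concentration_uM * 7)
  f_c <- fit_steady_state(s_c)
  expect_equal(f_c$kd, 7 * f0$kd, tolerance = 1e-4)
  expect_equal(f_c$rmax, f0$rmax, tolerance = 1e-4)
  s_r <- transform(s, response_RU = response_RU * 3)
  f_r <- fit_steady_state(s_r)
  expect_equal(f_r$rmax, 3 * f0$rmax, tolerance = 1e-4)
  expect_equal(f_r$kd, f0$kd, tolerance = 1e-4)
})

test_that("KD recovery across 200 noisy titrations meets bias and spread bounds", {
  kd_true <- 12.4
  conc <- 8 * kd_true / 2^(0:7)       # spans KD/8 .. 8 KD
  kds <- vapply(1:200, function(i) {
    s <- simulate_spr(kd_true, 100, conc, noise_sd_fraction = 0.05, seed = i)
    fit_steady_state(s)$kd
  }, numeric(1))
  expect_lt(abs(median(kds) - kd_true) / kd_true, 0.10)
  expect_lt(abs(mean(kds) - kd_true) / kd_true, 0.02)
  # every single replicate stays within a factor of 3 of truth
  expect_true(all(kds > kd_true / 3 & kds < kd_true * 3))
})

test_that("undetectable binding is censored with a lower bound", {
  s <- simulate_spr(kd = 1e5, rmax = 500, concentrations = 80 / 2^(0:7),
                    noise_sd_fraction = 0)
  fit <- fit_steady_state(s)
  expect_true(fit$censored)
  expect_true(is.na(fit$kd))
  expect_equal(fit$kd_lower_bound, 800)
  cl <- classify_fold_change(fit, 12.4, "TCR_MUTANT")
  expect_equal(cl$label, "critical")
  expect_true(cl$censored)
})

test_that("fewer than four distinct concentrations is an error", {
  expect_error(fit_steady_state(data.frame(
    concentration_uM = c(1, 2, 4), response_RU = c(10, 20, 30))), ">= 4")
  expect_error(fit_steady_state(data.frame(
    concentration_uM = c(-1, 2, 4, 8), response_RU = 1:4)), "positive")
})

test_that("TCR-scan scheme maps boundary folds exactly", {
  lab <- function(f) classify_fold_change(f * 12.4, 12.4, "TCR_MUTANT")$label
  expect_equal(lab(0.5), "negligible")
  expect_equal(lab(1.5), "negligible")
  expect_equal(lab(2), "negligible")     # <= 2-fold
  expect_equal(lab(2.0001), "moderate")  # gap 2..3 closed upward
  expect_equal(lab(4), "moderate")
  expect_equal(lab(5), "moderate")
  expect_equal(lab(5.0001), "substantial")
  expect_equal(lab(10), "substantial")
  expect_equal(lab(12), "critical")
})

test_that("HLA-scan scheme maps boundary folds exactly", {
  lab <- function(f) classify_fold_change(f, 1, "HLA_MUTANT")$label
  expect_equal(lab(1), "negligible")
  expect_equal(lab(1.49), "negligible")
  expect_equal(lab(1.5), "mild")         # 1.5 opens the mild class
  expect_equal(lab(2), "mild")
  expect_equal(lab(3), "mild")
  expect_equal(lab(3.0001), "moderate")
  expect_equal(lab(10), "moderate")
  expect_equal(lab(10.0001), "critical")
})

test_that("invalid fold changes are rejected", {
  expect_error(classify_fold_change(5, 0, "TCR_MUTANT"), "positive")
  expect_error(classify_fold_change(-5, 1, "TCR_MUTANT"), "positive")
})

test_that("mutant batch table classifies against the wild type", {
  conc <- 80 / 2^(0:7)
  series <- list(
    WT = simulate_spr(12.4, 100, conc, 0, seed = 1),
    M_neutral = simulate_spr(12.4 * 1.2, 100, conc, 0, seed = 2),
    M_moderate = simulate_spr(12.4 * 4, 100, conc, 0, seed = 3),
    M_critical = simulate_spr(12.4 * 20, 100, conc, 0, seed = 4))
  tab <- fit_mutant_batch(series, wildtype = "WT", scheme = "TCR_MUTANT")
  expect_equal(tab$class[tab$mutant == "WT"], "wildtype")
  expect_equal(tab$class[tab$mutant == "M_neutral"], "negligible")
  expect_equal(tab$class[tab$mutant == "M_moderate"], "moderate")
  expect_equal(tab$class[tab$mutant == "M_critical"], "critical")
})

test_that("binding CSV round-trips through the reader", {
  s <- simulate_spr(10, 100, noise_sd_fraction = 0)
  p <- tempfile(fileext = ".csv")
  write.csv(s, p, row.names = FALSE)
  expect_equal(fit_steady_state(read_binding_csv(p))$kd, 10, tolerance = 1e-6)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_binding_csv(bad), "concentration_uM")
})
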