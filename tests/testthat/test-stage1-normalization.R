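# With variance components pinned to zero, the stage-1 model for a single
# spectrum reduces to independent Poisson channels with a free baseline and
# flat ratio priors, whose channel-vs-reference log-ratio posterior is known
# in closed form: mean psi(y_c + 1) - psi(y_ref + 1), variance
# psi'(y_c + 1) + psi'(y_ref + 1) (log ratio of independent Gamma counts).

fit_pinned_single_spectrum <- function(counts, iterations = 2000) {
  recs <- make_records(list(counts))
  fit_stage1_protein(recs, single_run_design(), "protA",
                     control = fast_ctl(iterations = iterations, ess = 100),
                     digest_sd = 0, overdispersion = FALSE, seed = 3)
}

test_that("equal counts give symmetric, centred log-ratio posteriors", {
  f <- fit_pinned_single_spectrum(rep(500, 8))
  nonref <- f$ratios[f$ratios$channel != "113", ]
  ess <- f$convergence$parameters
  for (i in seq_len(nrow(nonref))) {
    e <- ess$ess[ess$parameter == sprintf("rho[%d]", i)]
    expect_lt(abs(nonref$mean[i]), 3 * nonref$sd[i] / sqrt(e))
  }
  expect_true(all(f$ratios$mean[f$ratios$channel == "113"] == 0))
  expect_true(all(f$ratios$sd[f$ratios$channel == "113"] == 0))
})

test_that("a doubled channel recovers log 2 against the conjugate oracle", {
  counts <- c(100, 200, rep(100, 6))  # ch114 doubled
  f <- fit_pinned_single_spectrum(counts)
  ratios <- f$ratios
  conv <- f$convergence$parameters

  oracle_mean <- function(yc, yref) digamma(yc + 1) - digamma(yref + 1)
  oracle_sd <- function(yc, yref) sqrt(trigamma(yc + 1) + trigamma(yref + 1))

  r114 <- ratios[ratios$channel == "114", ]
  e114 <- conv$ess[conv$parameter == "rho[1]"]
  expect_lt(abs(r114$mean - oracle_mean(200, 100)),
            3 * oracle_sd(200, 100) / sqrt(e114))
  expect_lt(abs(r114$mean - log(2)), 0.05)  # printed-value sanity
  expect_lt(abs(r114$sd - oracle_sd(200, 100)), 0.2 * oracle_sd(200, 100))

  for (ch in c("115", "116", "117", "118", "119", "121")) {
    k <- which(setdiff(itraq_channels(), "113") == ch)
    rch <- ratios[ratios$channel == ch, ]
    ech <- conv$ess[conv$parameter == sprintf("rho[%d]", k)]
    expect_lt(abs(rch$mean - 0), 3 * oracle_sd(100, 100) / sqrt(ech))
  }
})

test_that("scaling a whole spectrum leaves the ratio posteriors in place", {
  set.seed(10)
  base <- lapply(1:4, function(i) rpois(8, 400))
  scaled <- base
  scaled[[2]] <- scaled[[2]] * 10L
  f1 <- fit_stage1_protein(make_records(base), single_run_design(), "protA",
                          control = fast_ctl(), seed = 3)
  f2 <- fit_stage1_protein(make_records(scaled), single_run_design(), "protA",
                          control = fast_ctl(), seed = 3)
  # shifts stay within Monte-Carlo noise of each fit
  diff <- abs(f1$ratios$mean - f2$ratios$mean)
  tol <- 3 * sqrt(pmax(f1$ratios$sd, f2$ratios$sd)^2 / 50 + 1e-8) +
    3 * 0.02  # MC error of two independent short runs
  expect_true(all(diff < pmax(tol, 0.1)))
})

test_that("injected digest variation inflates the digest-SD posterior", {
  mk <- function(dsd, seed) {
    sim <- simulate_study(sim_config(n_proteins = 1, peptide_range = c(3, 3),
                                     spectra_range = c(4, 4), n_plexes = 2,
                                     baseline_log_sd = 0.3,
                                     fraction_differential = 0,
                                     subject_sd_case = 0, subject_sd_control = 0,
                                     digest_sd = dsd,
                                     channel_overdispersion_sd = 0.02,
                                     loading_bias_sd = 0, seed = seed))
    fit_stage1_protein(sim$records, sim$design, "prot001",
                       control = fast_ctl(), seed = 3)
  }
  hi <- mk(0.5, 19)
  lo <- mk(0, 19)
  expect_gt(unname(hi$sigma_digest["mean"]), 2 * unname(lo$sigma_digest["mean"]))
})

test_that("the draw-wise median of degenerate posteriors is exact", {
  fits <- list(fake_stage1_fit("P1", 0.1), fake_stage1_fit("P2", 0.2),
               fake_stage1_fit("P3", 0.3))
  norm <- infer_normalization(fits)
  nonref <- norm[norm$channel != "113", ]
  expect_true(all(abs(nonref$mean - 0.2) < 1e-12))
  expect_true(all(nonref$sd == 0))
  expect_true(all(nonref$n_proteins_used == 3))
  # reference channel is (0, 0) regardless of input
  ref <- norm[norm$channel == "113", ]
  expect_true(all(ref$mean == 0) && all(ref$sd == 0))

  zero <- infer_normalization(list(fake_stage1_fit("P1", 0),
                                   fake_stage1_fit("P2", 0),
                                   fake_stage1_fit("P3", 0)))
  expect_true(all(zero$mean == 0) && all(zero$sd == 0))
})

test_that("fewer than three proteins is refused; non-converged fits are dropped", {
  expect_error(infer_normalization(list(fake_stage1_fit("P1", 0.1),
                                        fake_stage1_fit("P2", 0.2))),
               class = "itraq_domain_error")
  fits <- list(fake_stage1_fit("P1", 0.1), fake_stage1_fit("P2", 0.2),
               fake_stage1_fit("P3", 0.3),
               fake_stage1_fit("P4", 9, converged = FALSE))
  expect_warning(norm <- infer_normalization(fits), "non-converged")
  expect_true(all(norm$n_proteins_used[norm$channel != "113"] == 3))
  expect_true(all(abs(norm$mean[norm$channel != "113"] - 0.2) < 1e-12))
})

test_that("the median factor resists large biases in a minority of proteins", {
  fits <- c(lapply(1:5, function(i) fake_stage1_fit(sprintf("P%d", i), 0.1)),
            lapply(6:7, function(i) fake_stage1_fit(sprintf("P%d", i), 5)))
  norm <- infer_normalization(fits)
  nonref <- norm[norm$channel != "113", ]
  expect_true(all(abs(nonref$mean - 0.1) < 1e-12))
})

test_that("the point-estimate median variant is available behind a flag", {
  fits <- list(fake_stage1_fit("P1", 0.1), fake_stage1_fit("P2", 0.2),
               fake_stage1_fit("P3", 0.4))
  norm <- infer_normalization(fits, method = "point")
  nonref <- norm[norm$channel != "113", ]
  expect_true(all(abs(nonref$mean - 0.2) < 1e-12))
})

test_that("normalisation factors survive a JSON round trip", {
  fits <- list(fake_stage1_fit("P1", 0.1), fake_stage1_fit("P2", 0.2),
               fake_stage1_fit("P3", 0.3))
  norm <- infer_normalization(fits)
  f <- withr::local_tempfile(fileext = ".json")
  write_normalization(norm, f)
  back <- read_normalization(f)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(norm),
               ignore_attr = TRUE)
})

test_that("the posterior is insensitive to the prior scale", {
  set.seed(11)
  recs <- make_records(lapply(1:3, function(i) rpois(8, 500)))
  sens <- prior_sensitivity(recs, single_run_design(), "protA",
                            scales = c(0.1, 10),
                            control = fast_ctl(iterations = 400), seed = 8)
  expect_equal(nrow(sens), 2)
  # a hundred-fold prior-scale change moves the summary by less than the
  # posterior spread
  expect_lt(abs(diff(sens$estimate)), mean(sens$sd))
})

test_that("missing proteins raise lookup errors", {
  recs <- make_records(list(rep(10, 8)))
  expect_error(fit_stage1_protein(recs, single_run_design(), "nope",
                                  control = fast_ctl()),
               class = "itraq_lookup_error")
})
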