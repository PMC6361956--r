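# Shared fixtures and independent oracles for the test suite.
# MCMC-heavy tests run a scaled-down regime: 2 chains x 500 post-burn-in
# iterations with a proportionately scaled ESS gate (100), as documented in
# the methods vignette. The desk preset (4 x 2000, ESS 400) is exercised in
# the acceptance suite.

fast_ctl <- function(iterations = 500, burn_in = 250, ess = 100,
                     adapt = 150) {
  mcmc_control(chains = 2, iterations = iterations, burn_in = burn_in,
               adapt = adapt, ess_threshold = ess)
}

# A single-run design with the canonical layout: reference digests at 113
# and 119, cases at 114-116, controls at 117, 118, 121.
single_run_design <- function(run = "plex1") {
  as_itraq_design(tibble::tibble(
    run = run,
    channel = c("113", "119", "114", "115", "116", "117", "118", "121"),
    sample = c("refA", "refB", "case01", "case02", "case03",
               "ctrl01", "ctrl02", "ctrl03"),
    subject = c("pool", "pool", "case01", "case02", "case03",
                "ctrl01", "ctrl02", "ctrl03"),
    group = c("reference", "reference", "case", "case", "case",
              "control", "control", "control"),
    digest = c("dA", "dB", "case01_d", "case02_d", "case03_d",
               "ctrl01_d", "ctrl02_d", "ctrl03_d")
  ))
}

# Wide spectrum table from a named list of count vectors (one per spectrum),
# each ordered as ch113..ch121.
make_records <- function(counts, protein = "protA", peptide = "pep1",
                         run = "plex1") {
  rows <- purrr::imap(counts, function(y, i) {
    tibble::tibble(protein = protein, peptide = peptide, run = run,
                   spectrum = sprintf("s%03d", as.integer(i)),
                   ch113 = y[1], ch114 = y[2], ch115 = y[3], ch116 = y[4],
                   ch117 = y[5], ch118 = y[6], ch119 = y[7], ch121 = y[8])
  })
  as_itraq_spectra(dplyr::bind_rows(rows))
}

# Degenerate stage-1 fit whose ratio posteriors are fixed draw vectors;
# used to test the normalisation median arithmetic in isolation.
fake_stage1_fit <- function(protein, value, runs = "plex1",
                            channels = setdiff(itraq_channels(), "113"),
                            n_draws = 100, converged = TRUE) {
  rd <- tidyr::expand_grid(run = runs, channel = channels)
  rd$draws <- lapply(seq_len(nrow(rd)), function(i) rep(value, n_draws))
  ratios <- tibble::tibble(run = rd$run, channel = rd$channel,
                           mean = value, sd = 0)
  structure(list(protein = protein, ratio_draws = rd, ratios = ratios,
                 sigma_digest = NULL, convergence = NULL,
                 converged = converged),
            class = "itraq_stage1")
}

# Independent oracle: exhaustive maximisation over all prefixes of the
# lfdr-sorted list.
oracle_global_fdr <- function(lfdr, alpha) {
  ord <- order(lfdr)
  best <- 0L
  for (k in seq_along(lfdr)) {
    if (mean(lfdr[ord][seq_len(k)]) <= alpha) best <- k
  }
  sel <- logical(length(lfdr))
  if (best > 0) sel[ord[seq_len(best)]] <- TRUE
  sel
}

# Independent oracle: brute-force membership-pattern enumeration for the
# overlap partition.
oracle_overlap <- function(quantified, significant) {
  labels <- names(quantified)
  universe <- Reduce(intersect, quantified)
  n <- length(labels)
  out <- list()
  for (k in seq_len(n)) {
    for (s in utils::combn(n, k, simplify = FALSE)) {
      cnt <- sum(vapply(universe, function(p) {
        inset <- vapply(labels, function(l) p %in% significant[[l]], logical(1))
        all(inset[s]) && !any(inset[-s]) || (length(s) == n && all(inset))
      }, logical(1)))
      out[[paste(labels[s], collapse = "+")]] <- cnt
    }
  }
  out
}

# Fabricated stage-2 fit for testing tidiers/plots without MCMC cost.
fake_stage2_fit <- function(protein = "protA", draws = NULL) {
  draws <- draws %||% stats::rnorm(1000, 0.2, 0.1)
  h <- coda::HPDinterval(coda::mcmc(draws), prob = 0.95)
  sq <- tibble::tibble(sample = c("case01", "ctrl01"), run = "plex1",
                       channel = c("114", "117"),
                       subject = c("case01", "ctrl01"),
                       group = c("case", "control"))
  sq$draws <- list(draws, draws * 0)
  sq$mean <- vapply(sq$draws, mean, numeric(1))
  sq$sd <- vapply(sq$draws, stats::sd, numeric(1))
  conv <- structure(list(parameters = tibble::tibble(parameter = "theta",
                                                     rhat = 1.0, ess = 900),
                         run_length = NA_integer_, converged = TRUE,
                         thresholds = c(r_hat = 1.05, ess = 400)),
                    class = "itraq_convergence")
  structure(list(protein = protein, theta_draws = draws,
                 mean_log_ratio = mean(draws),
                 hpd = c(lower = h[1, "lower"], upper = h[1, "upper"]),
                 sample_quant = sq, variance_components = list(),
                 convergence = conv, converged = TRUE),
            class = "itraq_fit")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
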