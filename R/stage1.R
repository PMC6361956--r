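# Stage 1: per-protein run x channel model and sample normalisation factors.
#
# Within each run the protein-level log ratio of every channel against the
# reference channel 113 is a fixed effect; each spectrum gets a baseline
# fixed effect (selection/ionisation/fragmentation efficiency), each peptide
# a random digest effect, and each channel an independent lognormal residual
# variance for over-dispersion. Across proteins, the draw-wise median of the
# channel log ratios yields the posterior of the sample normalisation
# factors.

# Model code for one protein. The Poisson likelihood with a free baseline
# fixed effect per spectrum is fitted through its exact conditional form:
# given a spectrum's total ion count, the eight channel counts are
# multinomial with log-odds equal to the remaining linear predictor. The
# latent channel log-abundances (eta) are hierarchically centred on the
# linear predictor, and a flat per-spectrum level term (b) carries the
# baseline, which keeps the fixed and random effects conditionally
# conjugate — JAGS's glm module then block-updates them.
stage1_model_code <- function(has_digest, fixed_digest_sd, has_od, fixed_od_sd,
                              prior_scale) {
  m <- "      m[s,c] <- b[s] + rho[rc[s,c]]"
  if (has_digest) m <- paste0(m, " + d[pd[s,c]]")
  blocks <- c(
    "model {",
    "  for (s in 1:S) {",
    "    y[s,1:C] ~ dmulti(p[s,1:C], nTot[s])",
    "    for (c in 1:C) {",
    if (has_od) c(
      "      eta[s,c] ~ dnorm(m[s,c], tau_eps[c])",
      "      e[s,c] <- exp(eta[s,c])"
    ) else "      e[s,c] <- exp(m[s,c])",
    m,
    "      p[s,c] <- e[s,c] / sum(e[s,1:C])",
    "    }",
    "    b[s] ~ dnorm(0, 1.0E-4)",
    "  }",
    "  for (k in 1:K) { rho[k] ~ dnorm(0, 1.0E-4) }",
    "  rho[KP1] <- 0"
  )
  if (has_digest) {
    if (is.null(fixed_digest_sd)) {
      # parameter expansion: d = xi * w induces a half-Cauchy(prior_scale)
      # prior on sigma_d and removes the variance-component funnel
      blocks <- c(blocks,
        "  for (j in 1:JD) {",
        "    d[j] <- xi_d * w_d[j]",
        "    w_d[j] ~ dnorm(0, tau_wd)",
        "  }",
        sprintf("  xi_d ~ dnorm(0, %.8g)", 1 / prior_scale^2),
        "  tau_wd ~ dgamma(0.5, 0.5)",
        "  sigma_d <- abs(xi_d) / sqrt(tau_wd)")
    } else {
      blocks <- c(blocks,
        "  for (j in 1:JD) { d[j] ~ dnorm(0, tau_d) }",
        sprintf("  tau_d <- %.8g", 1 / fixed_digest_sd^2))
    }
  }
  if (has_od) {
    if (is.null(fixed_od_sd)) {
      blocks <- c(blocks,
        sprintf("  for (c in 1:C) { tau_eps[c] ~ dgamma(0.001, %.8g) }",
                0.001 * prior_scale^2))
    } else {
      blocks <- c(blocks,
        sprintf("  for (c in 1:C) { tau_eps[c] <- %.8g }", 1 / fixed_od_sd^2))
    }
  }
  paste(c(blocks, "}"), collapse = "\n")
}

# Shared index construction for one protein: spectrum-by-channel matrices
# aligned with the reporter-channel order, plus the design slices per run.
protein_model_frame <- function(records, design, protein) {
  sub <- records[records$protein == protein, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort_itraq(paste0("Protein not present in records: ", protein),
                "itraq_lookup_error")
  }
  sub <- dplyr::arrange(tibble::as_tibble(sub), .data$run, .data$spectrum)
  runs <- sort(unique(sub$run))
  design <- tibble::as_tibble(design)
  dmat <- lapply(setNames(runs, runs), function(r) {
    d <- design[design$run == r, , drop = FALSE]
    d <- d[match(itraq_channels(), d$channel), , drop = FALSE]
    if (anyNA(d$sample)) {
      abort_itraq(paste0("Design does not assign all 8 channels of run ", r),
                  "itraq_config_error")
    }
    d
  })
  y <- as.matrix(sub[, channel_cols()])
  run_idx <- match(sub$run, runs)
  # (run, channel != reference) fixed-effect index; reference -> K + 1
  rc_pairs <- tidyr::expand_grid(run = runs,
                                 channel = setdiff(itraq_channels(),
                                                   itraq_reference_channel()))
  rc_map <- t(vapply(runs, function(r) {
    ifelse(itraq_channels() == itraq_reference_channel(),
           nrow(rc_pairs) + 1L,
           match(paste(r, itraq_channels()),
                 paste(rc_pairs$run, rc_pairs$channel)))
  }, integer(8)))
  rc <- rc_map[run_idx, , drop = FALSE]
  # peptide x digest random-effect index
  dig_map <- t(vapply(runs, function(r) dmat[[r]]$digest, character(8)))
  pd_pairs <- dplyr::distinct(tibble::tibble(
    peptide = rep(sub$peptide, each = 8),
    digest = as.vector(t(dig_map[run_idx, , drop = FALSE]))
  ))
  pd <- matrix(match(paste(rep(sub$peptide, times = 8),
                           dig_map[run_idx, , drop = FALSE]),
                     paste(pd_pairs$peptide, pd_pairs$digest)),
               nrow = nrow(sub))
  list(sub = sub, y = y, S = nrow(sub), runs = runs, run_idx = run_idx,
       dmat = dmat, rc_pairs = rc_pairs, rc = rc, pd_pairs = pd_pairs, pd = pd)
}

# Remove a constant (structurally pinned) parameter from a draws object so
# convergence assessment only sees sampled quantities.
drop_constant_param <- function(draws, name) {
  draws$draws[[name]] <- NULL
  draws
}

# Convergence gate restricted to the parameters a fit reports downstream
# (log ratios, condition effect, subject effects). Variance hyper-parameters
# are diagnosed and reported but mix slowest and do not gate the flag.
gate_converged <- function(conv, pattern, control) {
  p <- conv$parameters[grepl(pattern, conv$parameters$parameter), , drop = FALSE]
  if (nrow(p) == 0) return(conv$converged)
  all(!is.na(p$rhat)) && max(p$rhat) <= control$rhat_threshold &&
    min(p$ess) >= control$ess_threshold
}

variance_spec <- function(x, what) {
  # NULL -> estimate; 0 -> omit the term; positive number -> fixed SD
  if (is.null(x) || (is.logical(x) && x)) return(list(has = TRUE, fixed = NULL))
  if (is.logical(x) && !x) return(list(has = FALSE, fixed = NULL))
  if (!is.numeric(x) || length(x) != 1 || x < 0) {
    abort_itraq(paste0("`", what, "` must be NULL, logical, or a single SD >= 0."),
                "itraq_config_error")
  }
  if (x == 0) list(has = FALSE, fixed = NULL) else list(has = TRUE, fixed = x)
}

#' Fit the stage-1 model for one protein
#'
#' Infers, within each run, the protein-level natural-log ratio between the
#' reference channel 113 and channels 114-121 as run x channel fixed effects,
#' with per-spectrum baseline fixed effects, per-peptide random digest
#' effects (half-Cauchy prior on their SD), and channel-specific lognormal
#' over-dispersion (inverse-Gamma priors on the residual variances).
#'
#' @param records Spectrum table (typically after [filter_min_spectra()]).
#' @param design Study-design tibble covering every run in `records`.
#' @param protein Protein accession to fit.
#' @param control An [mcmc_control()].
#' @param seed Integer seed (per-protein sub-seeds are derived from it, so
#'   fits are order-independent).
#' @param prior_scale Multiplier on the half-Cauchy scale and the
#'   inverse-Gamma rate; used by [prior_sensitivity()] to check the priors
#'   are uninformative.
#' @param digest_sd `NULL` to estimate the digest SD (default), `0` to drop
#'   the term, or a positive value to pin it.
#' @param overdispersion `TRUE` to estimate channel residual variances
#'   (default), `FALSE`/`0` to drop the term, or a positive SD to pin them.
#' @return An object of class `itraq_stage1`: the per-(run, channel) log
#'   ratio posterior (`$ratios` summary tibble; `$ratio_draws` with pooled
#'   draws), digest-SD posterior summary, convergence report and flag. The
#'   `converged` flag gates on the log-ratio parameters that downstream
#'   steps consume; variance hyper-parameters appear in the report but mix
#'   more slowly and do not gate the flag.
#' @export
fit_stage1_protein <- function(records, design, protein,
                               control = mcmc_control(), seed = 1,
                               prior_scale = 1, digest_sd = NULL,
                               overdispersion = TRUE) {
  dg <- variance_spec(digest_sd, "digest_sd")
  od <- variance_spec(overdispersion, "overdispersion")
  mf <- protein_model_frame(records, design, protein)
  K <- nrow(mf$rc_pairs)

  data <- list(y = mf$y, nTot = rowSums(mf$y), S = mf$S, C = 8L,
               K = K, KP1 = K + 1L, rc = mf$rc)
  if (dg$has) { data$JD <- nrow(mf$pd_pairs); data$pd <- mf$pd }

  eta0 <- log(mf$y + 0.5)
  b0 <- rowMeans(eta0)
  inits <- function(chain_seed) {
    withr::with_seed(chain_seed, {
      ini <- list(b = b0 + rnorm(length(b0), 0, 0.2),
                  rho = c(rnorm(K, 0, 0.1), NA))
      if (od$has) ini$eta <- eta0
      ini
    })
  }
  monitor <- c("rho", if (dg$has && is.null(dg$fixed)) "sigma_d",
               if (od$has && is.null(od$fixed)) "tau_eps")
  spec <- jags_spec(stage1_model_code(dg$has, dg$fixed, od$has, od$fixed,
                                      prior_scale),
                    monitor = monitor, inits = inits)
  draws <- sample_posterior(spec, data, n_chains = control$chains,
                            n_iterations = control$iterations,
                            burn_in = control$burn_in,
                            seed = derive_seed(seed, protein),
                            adapt = control$adapt)
  draws <- drop_constant_param(draws, sprintf("rho[%d]", K + 1L))
  conv <- assess_convergence(draws,
                             r_hat_threshold = control$rhat_threshold,
                             ess_threshold = control$ess_threshold)

  ratio_draws <- mf$rc_pairs
  ratio_draws$draws <- lapply(seq_len(K), function(k) {
    pooled_draws(draws, sprintf("rho[%d]", k))
  })
  ref_rows <- tibble::tibble(run = mf$runs,
                             channel = itraq_reference_channel())
  ratios <- dplyr::bind_rows(
    tibble::tibble(run = ratio_draws$run, channel = ratio_draws$channel,
                   mean = vapply(ratio_draws$draws, mean, numeric(1)),
                   sd = vapply(ratio_draws$draws, sd, numeric(1))),
    tibble::tibble(run = ref_rows$run, channel = ref_rows$channel,
                   mean = 0, sd = 0)
  )
  ratios <- dplyr::arrange(ratios, .data$run, match(.data$channel, itraq_channels()))

  sigma_digest <- NULL
  if (dg$has && is.null(dg$fixed)) {
    sd_draws <- pooled_draws(draws, "sigma_d")
    sigma_digest <- c(mean = mean(sd_draws), sd = sd(sd_draws))
  }
  structure(list(protein = protein, ratio_draws = ratio_draws, ratios = ratios,
                 sigma_digest = sigma_digest, convergence = conv,
                 converged = gate_converged(conv, "^rho\\[", control),
                 draws = draws),
            class = "itraq_stage1")
}

#' @export
print.itraq_stage1 <- function(x, ...) {
  cat("Stage-1 fit:", x$protein,
      sprintf("(%d run x channel ratios, %s)\n", nrow(x$ratio_draws),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Fit the stage-1 model for every protein in a table
#'
#' @inheritParams fit_stage1_protein
#' @param proteins Optional subset of proteins; default all in `records`.
#' @param ... Passed to [fit_stage1_protein()].
#' @return A named list of `itraq_stage1` fits (class `itraq_stage1_set`).
#' @export
fit_stage1 <- function(records, design, control = mcmc_control(), seed = 1,
                       proteins = NULL, ...) {
  proteins <- proteins %||% sort(unique(records$protein))
  fits <- purrr::map(setNames(proteins, proteins), function(p) {
    fit_stage1_protein(records, design, p, control = control, seed = seed, ...)
  })
  structure(fits, class = "itraq_stage1_set")
}

#' Combine stage-1 posteriors into sample normalisation factors
#'
#' For each `(run, channel)` the per-protein log-ratio posteriors are
#' combined into the posterior of their across-protein median: draws are
#' paired by iteration index (valid because proteins are fitted
#' independently), the median across proteins is taken draw-wise, and its
#' posterior mean and SD become the normalisation factor. The reference
#' channel is `(0, 0)` by construction.
#'
#' @param fits A list of `itraq_stage1` fits (or an `itraq_stage1_set`).
#' @param design Optional design tibble; when supplied, factors are reported
#'   for every assigned `(run, channel)` and their coverage is checked.
#' @param method `"drawwise"` (default: median taken per draw) or `"point"`
#'   (median of posterior point estimates, with an asymptotic SE of the
#'   median as the SD).
#' @param exclude_nonconverged Drop fits whose convergence gate failed
#'   (warned about, default `TRUE`).
#' @return A tibble of class `itraq_norm` with columns `run`, `channel`,
#'   `mean`, `sd`, `n_proteins_used`.
#' @export
infer_normalization <- function(fits, design = NULL,
                                method = c("drawwise", "point"),
                                exclude_nonconverged = TRUE) {
  method <- match.arg(method)
  if (inherits(fits, "itraq_stage1")) fits <- list(fits)
  fits <- unclass(fits)
  if (exclude_nonconverged) {
    bad <- vapply(fits, function(f) !isTRUE(f$converged), logical(1))
    if (any(bad)) {
      rlang::warn(paste0("Excluding ", sum(bad),
                         " non-converged protein fit(s) from normalisation: ",
                         paste(head(names(fits)[bad], 5), collapse = ", ")))
      fits <- fits[!bad]
    }
  }
  if (length(fits) < 3) {
    abort_itraq("Normalisation needs >= 3 proteins with posterior draws (median is not robust below that).",
                "itraq_domain_error")
  }
  rd <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(protein = f$protein, run = f$ratio_draws$run,
                   channel = f$ratio_draws$channel, draws = f$ratio_draws$draws)
  }))
  pairs <- dplyr::distinct(rd[, c("run", "channel")])
  pairs <- dplyr::arrange(pairs, .data$run, match(.data$channel, itraq_channels()))
  out <- purrr::pmap_dfr(pairs, function(run, channel) {
    dl <- rd$draws[rd$run == run & rd$channel == channel]
    if (length(dl) < 3) {
      abort_itraq(sprintf("Fewer than 3 proteins carry draws for (%s, %s).",
                          run, channel), "itraq_domain_error")
    }
    if (method == "drawwise") {
      L <- min(lengths(dl))
      mat <- vapply(dl, function(v) v[ceiling(seq_len(L) * length(v) / L)],
                    numeric(L))
      med <- apply(mat, 1, median)
      tibble::tibble(run = run, channel = channel, mean = mean(med),
                     sd = sd(med), n_proteins_used = length(dl))
    } else {
      means <- vapply(dl, mean, numeric(1))
      tibble::tibble(run = run, channel = channel, mean = median(means),
                     sd = 1.2533 * sd(means) / sqrt(length(means)),
                     n_proteins_used = length(dl))
    }
  })
  ref <- tibble::tibble(run = unique(pairs$run),
                        channel = itraq_reference_channel(),
                        mean = 0, sd = 0,
                        n_proteins_used = max(out$n_proteins_used))
  out <- dplyr::bind_rows(ref, out)
  if (!is.null(design)) {
    assigned <- dplyr::distinct(tibble::as_tibble(design)[, c("run", "channel")])
    missing <- dplyr::anti_join(assigned, out, by = c("run", "channel"))
    if (nrow(missing) > 0) {
      rlang::warn(paste0("No normalisation factor for ",
                         nrow(missing), " assigned (run, channel) pair(s)."))
    }
  }
  out <- dplyr::arrange(out, .data$run, match(.data$channel, itraq_channels()))
  class(out) <- unique(c("itraq_norm", class(out)))
  out
}

#' Read/write normalisation factors as JSON
#'
#' @param norm An `itraq_norm` tibble.
#' @param path File path.
#' @return `read_normalization()` returns the `itraq_norm` tibble;
#'   `write_normalization()` returns `path` invisibly.
#' @export
write_normalization <- function(norm, path) {
  jsonlite::write_json(
    list(factors = tibble::as_tibble(norm)[, c("run", "channel", "mean", "sd",
                                               "n_proteins_used")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalization
#' @export
read_normalization <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- tibble::as_tibble(x$factors)
  out$channel <- as.character(out$channel)
  class(out) <- unique(c("itraq_norm", class(out)))
  out
}

#' Per-sample protein quantification table from stage-1 fits
#'
#' Collects every protein's per-(run, channel) log-ratio posterior mean and
#' SD — the "sample observations" that, after normalisation, feed the
#' ordination matrix of [prepare_pca_matrix()].
#'
#' @param fits A list of `itraq_stage1` fits.
#' @return A tibble with columns `protein`, `run`, `channel`, `mean`, `sd`.
#' @export
stage1_quant_table <- function(fits) {
  if (inherits(fits, "itraq_stage1")) fits <- list(fits)
  dplyr::bind_rows(lapply(unclass(fits), function(f) {
    dplyr::mutate(f$ratios, protein = f$protein, .before = 1)
  }))
}

#' Prior-scale sensitivity harness
#'
#' Refits one protein with the half-Cauchy scale and inverse-Gamma rate
#' multiplied by each element of `scales`, to establish that the priors do
#' not drive the posterior.
#'
#' @inheritParams fit_stage1_protein
#' @param scales Multipliers to try (default `c(0.1, 1, 10)`).
#' @param stage `1` or `2` (stage 2 requires `norm`).
#' @param norm Normalisation factors (stage 2 only).
#' @return A tibble with one row per scale: condition-effect (stage 2) or
#'   mean absolute channel-ratio (stage 1) posterior mean and SD.
#' @export
prior_sensitivity <- function(records, design, protein, scales = c(0.1, 1, 10),
                              control = mcmc_control(), seed = 1, stage = 1,
                              norm = NULL) {
  purrr::map_dfr(scales, function(sc) {
    if (stage == 1) {
      f <- fit_stage1_protein(records, design, protein, control = control,
                              seed = seed, prior_scale = sc)
      nonref <- f$ratios[f$ratios$channel != itraq_reference_channel(), ]
      tibble::tibble(prior_scale = sc, summary = "mean |log ratio|",
                     estimate = mean(abs(nonref$mean)),
                     sd = mean(nonref$sd))
    } else {
      f <- fit_stage2_protein(records, design, norm, protein, control = control,
                              seed = seed, prior_scale = sc)
      tibble::tibble(prior_scale = sc, summary = "condition effect",
                     estimate = f$mean_log_ratio,
                     sd = sd(f$theta_draws))
    }
  })
}
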