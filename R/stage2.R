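# Stage 2: full-design model per protein, fold-change-threshold test,
# local FDR, and global-FDR selection.
#
# Rather than subtracting point-estimate normalisation factors, per-(run,
# channel) sample fixed effects are fitted with Normal priors set to the
# stage-1 posterior mean and SD of the median log ratio. The case/control
# fold change is a condition fixed effect with control as baseline; subject
# enters as two random effects with separate variances for cases and
# controls (biological variance differs between the groups). Reference-pool
# samples carry condition covariate 0 and share a single pool effect, so
# they anchor normalisation without inflating control biological variance.

# Same conditional-multinomial construction as stage 1 (see
# stage1_model_code): spectrum totals are conditioned on, the latent channel
# log-abundances are centred on the linear predictor, and a flat
# per-spectrum level term carries the baseline.
stage2_model_code <- function(has_digest, fixed_digest_sd, has_od, fixed_od_sd,
                              has_subject, fixed_subject_sd, has_nu,
                              prior_scale) {
  m <- "      m[s,c] <- b[s] + off[s,c] + x[s,c] * theta"
  if (has_nu) m <- paste0(m, " + nu[rc[s,c]]")
  if (has_subject) m <- paste0(m, " + u[subj[s,c]]")
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
    if (has_nu) c(
      "  for (k in 1:K) { nu[k] ~ dnorm(nu_m[k], nu_prec[k]) }",
      "  nu[KP1] <- 0"
    ),
    "  theta ~ dnorm(0, 1.0E-2)"
  )
  if (has_subject) {
    if (is.null(fixed_subject_sd)) {
      # parameter expansion (u = xi * w): half-Cauchy(prior_scale) priors on
      # the group-specific subject SDs; the pool's single shared effect
      # keeps a fixed N(0, 1) prior (one subject cannot inform a variance)
      blocks <- c(blocks,
        "  for (j in 1:J) {",
        "    u[j] <- xi_u[grp[j]] * w_u[j]",
        "    w_u[j] ~ dnorm(0, tau_wu[grp[j]])",
        "  }",
        sprintf("  xi_u[1] ~ dnorm(0, %.8g)", 1 / prior_scale^2),
        sprintf("  xi_u[2] ~ dnorm(0, %.8g)", 1 / prior_scale^2),
        "  xi_u[3] <- 1",
        "  tau_wu[1] ~ dgamma(0.5, 0.5)",
        "  tau_wu[2] ~ dgamma(0.5, 0.5)",
        "  tau_wu[3] <- 1",
        "  sigma_case <- abs(xi_u[1]) / sqrt(tau_wu[1])",
        "  sigma_ctrl <- abs(xi_u[2]) / sqrt(tau_wu[2])")
    } else {
      blocks <- c(blocks,
        "  for (j in 1:J) { u[j] ~ dnorm(0, tau_subj[grp[j]]) }",
        sprintf("  tau_subj[1] <- %.8g", 1 / fixed_subject_sd^2),
        sprintf("  tau_subj[2] <- %.8g", 1 / fixed_subject_sd^2),
        "  tau_subj[3] <- 1")
    }
  }
  if (has_digest) {
    if (is.null(fixed_digest_sd)) {
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

#' Fit the stage-2 differential model for one protein
#'
#' Fits the full experimental design under the Poisson-lognormal model:
#' per-spectrum baseline fixed effects, per-(run, channel) sample fixed
#' effects with `Normal(mean, sd^2)` priors taken from the stage-1
#' normalisation factors, a condition fixed effect `theta` (natural-log
#' case/control fold change, control as baseline), group-specific subject
#' random effects, peptide x digest random effects, and channel-specific
#' over-dispersion. Normalisation entries with zero SD (the reference
#' channel) enter as fixed offsets.
#'
#' @inheritParams fit_stage1_protein
#' @param norm Normalisation factors from [infer_normalization()] covering
#'   every `(run, channel)` of the protein's records.
#' @param subject_sd `NULL` to estimate group-specific subject SDs
#'   (default), `0` to drop subject effects, or a positive value to pin both.
#' @return An object of class `itraq_fit`: condition-effect draws
#'   (`$theta_draws`), posterior mean log ratio, 95% highest-posterior-density
#'   interval, per-sample quantification posteriors (`$sample_quant`),
#'   variance-component summaries, convergence report and flag.
#' @export
fit_stage2_protein <- function(records, design, norm, protein,
                               control = mcmc_control(), seed = 1,
                               prior_scale = 1, digest_sd = NULL,
                               overdispersion = TRUE, subject_sd = NULL) {
  dg <- variance_spec(digest_sd, "digest_sd")
  od <- variance_spec(overdispersion, "overdispersion")
  sb <- variance_spec(subject_sd, "subject_sd")
  mf <- protein_model_frame(records, design, protein)

  # per-run design slices stacked in channel order
  dd <- dplyr::bind_rows(mf$dmat)
  nm <- tibble::as_tibble(norm)
  dd <- dplyr::left_join(dd, nm[, c("run", "channel", "mean", "sd")],
                         by = c("run", "channel"))
  if (anyNA(dd$mean)) {
    miss <- dd[is.na(dd$mean), c("run", "channel")]
    abort_itraq(paste0("Missing normalisation factor for: ",
                       paste(paste0("(", miss$run, ", ", miss$channel, ")"),
                             collapse = ", ")),
                "itraq_config_error")
  }

  # (run, channel) pairs with informative (sd > 0) priors become sampled
  # sample fixed effects; zero-SD entries (the reference channel) are fixed
  # offsets.
  sampled <- dd[dd$sd > 1e-8, , drop = FALSE]
  K <- nrow(sampled)
  dd$off <- ifelse(dd$sd > 1e-8, 0, dd$mean)
  dd$rc_idx <- ifelse(dd$sd > 1e-8,
                      match(paste(dd$run, dd$channel),
                            paste(sampled$run, sampled$channel)),
                      K + 1L)
  subj_tbl <- dplyr::distinct(dd[, c("subject", "group")])
  subj_tbl$grp <- match(subj_tbl$group, c("case", "control", "reference"))
  dd$subj_idx <- match(dd$subject, subj_tbl$subject)
  dd$x <- as.numeric(dd$group == "case")

  # expand run-level vectors to spectrum x channel matrices
  to_mat <- function(v) {
    m <- matrix(v, nrow = length(mf$runs), ncol = 8, byrow = TRUE)
    m[mf$run_idx, , drop = FALSE]
  }
  data <- list(y = mf$y, nTot = rowSums(mf$y), S = mf$S, C = 8L,
               off = to_mat(dd$off), x = to_mat(dd$x))
  if (K > 0) {
    data$K <- K; data$KP1 <- K + 1L; data$rc <- to_mat(dd$rc_idx)
    data$nu_m <- sampled$mean; data$nu_prec <- 1 / sampled$sd^2
  }
  if (sb$has) { data$J <- nrow(subj_tbl); data$subj <- to_mat(dd$subj_idx)
                data$grp <- subj_tbl$grp }
  if (dg$has) { data$JD <- nrow(mf$pd_pairs); data$pd <- mf$pd }

  eta0 <- log(mf$y + 0.5)
  b0 <- rowMeans(eta0)
  inits <- function(chain_seed) {
    withr::with_seed(chain_seed, {
      ini <- list(b = b0 + rnorm(length(b0), 0, 0.2),
                  theta = rnorm(1, 0, 0.2))
      if (od$has) ini$eta <- eta0
      if (K > 0) ini$nu <- c(rnorm(K, sampled$mean, 0.05), NA)
      ini
    })
  }
  monitor <- c("theta",
               if (sb$has) "u",
               if (sb$has && is.null(sb$fixed)) c("sigma_case", "sigma_ctrl"),
               if (dg$has && is.null(dg$fixed)) "sigma_d",
               if (od$has && is.null(od$fixed)) "tau_eps")
  spec <- jags_spec(stage2_model_code(dg$has, dg$fixed, od$has, od$fixed,
                                      sb$has, sb$fixed, K > 0, prior_scale),
                    monitor = monitor, inits = inits)
  draws <- sample_posterior(spec, data, n_chains = control$chains,
                            n_iterations = control$iterations,
                            burn_in = control$burn_in,
                            seed = derive_seed(seed, protein),
                            adapt = control$adapt)
  conv <- assess_convergence(draws,
                             r_hat_threshold = control$rhat_threshold,
                             ess_threshold = control$ess_threshold)

  theta <- pooled_draws(draws, "theta")
  hpd <- coda::HPDinterval(coda::mcmc(theta), prob = 0.95)

  sample_tbl <- dd[, c("sample", "run", "channel", "subject", "group", "x")]
  squant <- sample_tbl
  squant$draws <- lapply(seq_len(nrow(sample_tbl)), function(i) {
    q <- sample_tbl$x[i] * theta
    if (sb$has) {
      j <- match(sample_tbl$subject[i], subj_tbl$subject)
      q <- q + pooled_draws(draws, sprintf("u[%d]", j))
    }
    q
  })
  squant$mean <- vapply(squant$draws, mean, numeric(1))
  squant$sd <- vapply(squant$draws, sd, numeric(1))
  squant$x <- NULL

  vc <- list()
  for (p in c("sigma_case", "sigma_ctrl", "sigma_d")) {
    if (p %in% draw_parameters(draws)) {
      v <- pooled_draws(draws, p)
      vc[[p]] <- c(mean = mean(v), sd = sd(v))
    }
  }

  structure(list(protein = protein, theta_draws = theta,
                 mean_log_ratio = mean(theta),
                 hpd = c(lower = hpd[1, "lower"], upper = hpd[1, "upper"]),
                 sample_quant = squant, variance_components = vc,
                 convergence = conv,
                 converged = gate_converged(conv, "^theta$|^u\\[|^u$", control),
                 draws = draws),
            class = "itraq_fit")
}

#' @export
print.itraq_fit <- function(x, ...) {
  cat(sprintf("Stage-2 fit: %s\n  log fold change %.3f [%.3f, %.3f] (95%% HPD), fold change %.3f, %s\n",
              x$protein, x$mean_log_ratio, x$hpd["lower"], x$hpd["upper"],
              exp(x$mean_log_ratio),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Fit the stage-2 model for every protein in a table
#'
#' @inheritParams fit_stage2_protein
#' @param proteins Optional subset of proteins; default all in `records`.
#' @param ... Passed to [fit_stage2_protein()].
#' @return A named list of `itraq_fit` objects (class `itraq_fit_set`).
#' @export
fit_stage2 <- function(records, design, norm, control = mcmc_control(),
                       seed = 1, proteins = NULL, ...) {
  proteins <- proteins %||% sort(unique(records$protein))
  fits <- purrr::map(setNames(proteins, proteins), function(p) {
    fit_stage2_protein(records, design, norm, p, control = control,
                       seed = seed, ...)
  })
  structure(fits, class = "itraq_fit_set")
}

#' Posterior fold-change-threshold test
#'
#' One-sided significance test on the posterior probability that the mean
#' fold change lies above `threshold` or below `1/threshold`:
#' `p_up = P(theta > log(threshold))`, `p_down = P(theta < -log(threshold))`,
#' `p_fc = max(p_up, p_down)` with the winning direction reported (ties break
#' upward). The local FDR is the complement `1 - p_fc`: the posterior
#' probability that calling this protein differential is a false discovery.
#'
#' @param fit An `itraq_fit`, or a numeric vector of condition-effect draws.
#' @param threshold Fold-change threshold (> 1); default 1.05, i.e. at least
#'   a 5% change from control.
#' @param protein Protein label (used when `fit` is a bare draw vector).
#' @return A one-row tibble: `protein`, `mean_log_ratio`, `hpd_low`,
#'   `hpd_high`, `p_fc`, `lfdr`, `direction`, `significant` (`NA` until
#'   [select_global_fdr()]), `converged`.
#' @export
test_fold_change <- function(fit, threshold = 1.05, protein = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 1) {
    abort_itraq("`threshold` must be a single number > 1.", "itraq_domain_error")
  }
  if (inherits(fit, "itraq_fit")) {
    draws <- fit$theta_draws
    protein <- fit$protein
    hpd <- fit$hpd
    converged <- fit$converged
  } else {
    draws <- as.numeric(fit)
    protein <- protein %||% "protein"
    h <- coda::HPDinterval(coda::mcmc(draws), prob = 0.95)
    hpd <- c(lower = h[1, "lower"], upper = h[1, "upper"])
    converged <- NA
  }
  if (length(draws) < 1000) {
    rlang::warn(sprintf("Only %d posterior draws for %s; P(%.2f fc) will be noisy.",
                        length(draws), protein, threshold))
  }
  lt <- log(threshold)
  p_up <- mean(draws > lt)
  p_down <- mean(draws < -lt)
  p_fc <- max(p_up, p_down)
  tibble::tibble(protein = protein, mean_log_ratio = mean(draws),
                 hpd_low = unname(hpd["lower"]), hpd_high = unname(hpd["upper"]),
                 p_fc = p_fc, lfdr = 1 - p_fc,
                 direction = if (p_up >= p_down) "up" else "down",
                 significant = NA, converged = converged)
}

#' Differential calls for a set of protein fits
#'
#' Applies [test_fold_change()] to every fit and stacks the results.
#'
#' @param fits A list of `itraq_fit` objects.
#' @param threshold Fold-change threshold (> 1).
#' @return A tibble of class `itraq_calls`, one row per protein.
#' @export
call_differential <- function(fits, threshold = 1.05) {
  if (inherits(fits, "itraq_fit")) fits <- list(fits)
  out <- suppressWarnings(
    dplyr::bind_rows(lapply(unclass(fits), test_fold_change,
                            threshold = threshold))
  )
  class(out) <- unique(c("itraq_calls", class(out)))
  out
}

#' Global-FDR selection: largest set with average local FDR below a level
#'
#' Sorts the calls by local FDR (ties broken by protein accession) and marks
#' as significant the largest prefix whose mean lFDR does not exceed `alpha`.
#' This controls the expected proportion of false discoveries in the reported
#' set at `alpha`.
#'
#' @param calls An `itraq_calls` tibble (see [call_differential()]).
#' @param alpha Global FDR level in `(0, 1)`; default 0.05.
#' @return The calls tibble with `significant` set (original row order
#'   preserved).
#' @export
select_global_fdr <- function(calls, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort_itraq("`alpha` must lie in (0, 1).", "itraq_domain_error")
  }
  if (nrow(calls) == 0) {
    calls$significant <- logical(0)
    return(calls)
  }
  ord <- order(calls$lfdr, calls$protein)
  cm <- cumsum(calls$lfdr[ord]) / seq_along(ord)
  n_sig <- if (any(cm <= alpha)) max(which(cm <= alpha)) else 0L
  sig <- logical(nrow(calls))
  if (n_sig > 0) sig[ord[seq_len(n_sig)]] <- TRUE
  calls$significant <- sig
  class(calls) <- unique(c("itraq_calls", class(calls)))
  calls
}

#' Write differential-quantification results to TSV
#'
#' Columns mirror the per-protein record a study database would expose:
#' posterior mean log ratio, 95% HPD bounds, `P(fc)` for the configured
#' threshold, local FDR, direction, global-FDR significance and convergence.
#'
#' @param calls An `itraq_calls` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(calls, path) {
  readr::write_tsv(tibble::as_tibble(calls), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- unique(c("itraq_calls", class(out)))
  out
}
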