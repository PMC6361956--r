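# Posterior-sampling and convergence contract shared by both model stages.
#
# Sampling is delegated to JAGS (rjags); the contract here is distributional
# and is verified against conjugate closed forms in the test suite. Draws are
# stored per parameter as an iterations x chains matrix with burn-in removed.

#' MCMC run-length settings
#'
#' Presets: `"desk"` (4 chains of 2,000 post-burn-in iterations after 500
#' burn-in — minutes for a full desk-scale study) and the full-scale
#' presets `"full_stage1"` / `"full_stage2"` (10 and 100 chains per protein
#' respectively, 10,000 iterations after 3,000 burn-in).
#'
#' @param chains Number of chains (>= 2 for convergence assessment).
#' @param iterations Post-burn-in iterations per chain.
#' @param burn_in Discarded initial iterations per chain.
#' @param adapt JAGS adaptation steps before burn-in.
#' @param rhat_threshold,ess_threshold Convergence gate applied to each fit
#'   (see [assess_convergence()]). Scaled-down run lengths should carry a
#'   proportionately scaled ESS gate, since ESS cannot exceed the draw count.
#' @param preset Optional preset name overriding the numeric arguments.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, iterations = 2000, burn_in = 500,
                         adapt = 500, rhat_threshold = 1.05,
                         ess_threshold = 400, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("desk", "full_stage1", "full_stage2"))
    return(switch(preset,
      desk = mcmc_control(4, 2000, 500, 500),
      full_stage1 = mcmc_control(10, 10000, 3000, 1000),
      full_stage2 = mcmc_control(100, 10000, 3000, 1000)
    ))
  }
  if (iterations <= 0 || burn_in < 0 || chains < 1) {
    abort_itraq("Invalid MCMC control: need iterations > 0, burn_in >= 0, chains >= 1.",
                "itraq_config_error")
  }
  structure(list(chains = as.integer(chains), iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), adapt = as.integer(adapt),
                 rhat_threshold = rhat_threshold, ess_threshold = ess_threshold),
            class = "mcmc_control")
}

#' Specify a model for the sampling engine
#'
#' A model specification names every parameter to monitor, carries the model
#' code (JAGS/BUGS language: priors plus likelihood contributions), and an
#' optional initial-values generator used to over-disperse chain starting
#' points.
#'
#' @param code Model code as a single string.
#' @param monitor Character vector of parameters to record.
#' @param inits Optional `function(chain_seed)` returning a named list of
#'   initial values for one chain.
#' @return A list of class `jags_spec`.
#' @export
jags_spec <- function(code, monitor, inits = NULL) {
  stopifnot(is.character(code), length(code) == 1, is.character(monitor))
  structure(list(code = code, monitor = monitor, inits = inits),
            class = "jags_spec")
}

#' Draw from the posterior of a specified model
#'
#' Runs `n_chains` MCMC chains, discards `burn_in` iterations, and returns
#' the remaining draws. Chains are initialised with over-dispersed starting
#' points derived deterministically from `seed` (via the spec's `inits`
#' generator when present) and per-chain RNG streams, so identical seeds give
#' identical draws.
#'
#' @param model A [jags_spec()].
#' @param data Named list of observations and constants.
#' @param n_chains,n_iterations,burn_in Run lengths (see [mcmc_control()]).
#' @param seed Integer seed.
#' @param adapt Adaptation steps (sampler tuning) before burn-in.
#' @return A `posterior_draws` object: per-parameter draw matrices
#'   (iterations x chains) plus run metadata.
#' @export
sample_posterior <- function(model, data, n_chains = 4, n_iterations = 2000,
                             burn_in = 500, seed = 1, adapt = 500) {
  stopifnot(inherits(model, "jags_spec"))
  if (n_iterations <= 0 || burn_in < 0) {
    abort_itraq("Need n_iterations > 0 and burn_in >= 0.", "itraq_config_error")
  }
  chain_seeds <- withr::with_seed(seed, sample.int(2147483562L, n_chains))
  inits <- lapply(seq_len(n_chains), function(i) {
    ini <- if (!is.null(model$inits)) model$inits(chain_seeds[i]) else list()
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- chain_seeds[i]
    ini
  })
  jm <- tryCatch(
    rjags::jags.model(textConnection(model$code), data = data, inits = inits,
                      n.chains = n_chains, n.adapt = adapt, quiet = TRUE),
    error = function(e) {
      abort_itraq(paste0("Sampler initialisation failed: ", conditionMessage(e)),
                  "itraq_init_error")
    }
  )
  if (burn_in > 0) update(jm, burn_in, progress.bar = "none")
  sm <- tryCatch(
    rjags::coda.samples(jm, model$monitor, n.iter = n_iterations,
                        progress.bar = "none"),
    error = function(e) {
      abort_itraq(paste0("Sampling failed: ", conditionMessage(e)),
                  "itraq_sampling_error")
    }
  )
  new_posterior_draws(sm, burn_in = burn_in, seed = seed)
}

new_posterior_draws <- function(mcmc_list, burn_in, seed) {
  pars <- colnames(mcmc_list[[1]])
  draws <- lapply(pars, function(p) {
    vapply(mcmc_list, function(ch) as.numeric(ch[, p]),
           numeric(nrow(mcmc_list[[1]])))
  })
  names(draws) <- pars
  draws <- lapply(draws, function(m) matrix(m, nrow = nrow(mcmc_list[[1]])))
  structure(list(draws = draws,
                 n_chains = length(mcmc_list),
                 n_iterations = nrow(mcmc_list[[1]]),
                 burn_in = burn_in, seed = seed),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws:", length(x$draws), "parameters,",
      x$n_chains, "chains x", x$n_iterations, "iterations",
      sprintf("(burn-in %d, seed %d)\n", x$burn_in, x$seed))
  invisible(x)
}

#' Access draws from a `posterior_draws` object
#'
#' `pooled_draws()` concatenates chains into one vector; `draws_matrix()`
#' returns the iterations x chains matrix for one parameter;
#' `draw_parameters()` lists monitored parameter names.
#'
#' @param x A `posterior_draws` object.
#' @param parameter Parameter name (as monitored; vector components appear as
#'   e.g. `"rho[2]"`).
#' @return A numeric vector, matrix, or character vector respectively.
#' @export
pooled_draws <- function(x, parameter) {
  m <- draws_matrix(x, parameter)
  as.numeric(m)
}

#' @rdname pooled_draws
#' @export
draws_matrix <- function(x, parameter) {
  if (!parameter %in% names(x$draws)) {
    abort_itraq(paste0("Unknown parameter: ", parameter), "itraq_lookup_error")
  }
  x$draws[[parameter]]
}

#' @rdname pooled_draws
#' @export
draw_parameters <- function(x) names(x$draws)

as_mcmc_list <- function(x) {
  coda::as.mcmc.list(lapply(seq_len(x$n_chains), function(ch) {
    coda::mcmc(vapply(x$draws, function(m) m[, ch], numeric(x$n_iterations)))
  }))
}

# Split-R-hat (each chain halved, between/within-half variance ratio).
split_rhat <- function(m) {
  n <- nrow(m)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(m)), function(j) {
    cbind(m[seq_len(half), j], m[(n - half + 1):n, j])
  }))
  w <- mean(apply(halves, 2, var))
  b <- half * var(colMeans(halves))
  if (w == 0) return(if (b == 0) 1 else Inf)
  max(1, sqrt(((half - 1) / half * w + b / half) / w))
}

#' Assess MCMC convergence
#'
#' Computes per-parameter split-R-hat and effective sample size, plus an
#' advisory Raftery-Lewis run-length recommendation (defaults `q = 0.025`,
#' `r = 0.005`, `s = 0.95`): the smallest chain length at which the 2.5%
#' posterior quantile is estimated to within 0.005 with 95% confidence. The
#' converged gate is `max R-hat <= r_hat_threshold` and
#' `min ESS >= ess_threshold`.
#'
#' @param draws A `posterior_draws` object with at least two chains.
#' @param r_hat_threshold Split-R-hat gate (default 1.05).
#' @param ess_threshold Effective-sample-size gate (default 400).
#' @param q,r,s Raftery-Lewis quantile, precision and confidence settings.
#' @return A list of class `itraq_convergence`: tibble `parameters`
#'   (`parameter`, `rhat`, `ess`), `run_length` (integer iterations per
#'   chain, `NA` if the pilot run is too short to estimate), and `converged`.
#' @export
assess_convergence <- function(draws, r_hat_threshold = 1.05,
                               ess_threshold = 400,
                               q = 0.025, r = 0.005, s = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (draws$n_chains < 2) {
    abort_itraq("Convergence assessment requires at least 2 chains.",
                "itraq_config_error")
  }
  total <- draws$n_chains * draws$n_iterations
  rhat <- vapply(draws$draws, split_rhat, numeric(1))
  ess <- vapply(names(draws$draws), function(p) {
    e <- tryCatch(as.numeric(coda::effectiveSize(coda::mcmc(pooled_draws(draws, p)))),
                  error = function(e) NA_real_)
    min(e, total)  # the estimator cannot certify more than the draw count
  }, numeric(1))
  run_length <- tryCatch({
    rl <- vapply(names(draws$draws), function(p) {
      d <- coda::raftery.diag(coda::mcmc(pooled_draws(draws, p)), q = q, r = r, s = s)
      if (is.null(d$resmatrix) || is.character(d$resmatrix)) return(NA_real_)
      as.numeric(d$resmatrix[1, "N"])
    }, numeric(1))
    if (all(is.na(rl))) NA_integer_ else as.integer(ceiling(max(rl, na.rm = TRUE)))
  }, error = function(e) NA_integer_)
  params <- tibble::tibble(parameter = names(draws$draws), rhat = unname(rhat),
                           ess = unname(ess))
  converged <- all(!is.na(params$rhat)) &&
    max(params$rhat) <= r_hat_threshold && min(params$ess) >= ess_threshold
  structure(list(parameters = params, run_length = run_length,
                 converged = converged,
                 thresholds = c(r_hat = r_hat_threshold, ess = ess_threshold)),
            class = "itraq_convergence")
}

#' @export
print.itraq_convergence <- function(x, ...) {
  cat("Convergence:", if (x$converged) "converged" else "NOT converged",
      sprintf("(max R-hat %.3f, min ESS %.0f, run-length %s)\n",
              max(x$parameters$rhat), min(x$parameters$ess),
              ifelse(is.na(x$run_length), "NA", x$run_length)))
  invisible(x)
}

#' @export
tidy.itraq_convergence <- function(x, ...) x$parameters
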