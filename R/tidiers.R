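# broom-style methods: tidy() rows are terms/parameters, glance() is a
# one-row model summary.

#' Tidy a stage-2 protein fit
#'
#' @param x An `itraq_fit`.
#' @param ... Unused.
#' @return A tibble with one row per reported quantity: the condition effect
#'   and each per-sample quantification, with posterior mean, SD and 95%
#'   HPD bounds.
#' @export
tidy.itraq_fit <- function(x, ...) {
  hpd_of <- function(v) {
    h <- coda::HPDinterval(coda::mcmc(v), prob = 0.95)
    c(h[1, "lower"], h[1, "upper"])
  }
  cond <- tibble::tibble(term = "condition", estimate = x$mean_log_ratio,
                         std.error = sd(x$theta_draws),
                         conf.low = unname(x$hpd["lower"]),
                         conf.high = unname(x$hpd["upper"]))
  samp <- purrr::pmap_dfr(
    list(x$sample_quant$sample, x$sample_quant$draws),
    function(sample, draws) {
      h <- hpd_of(draws)
      tibble::tibble(term = paste0("sample:", sample), estimate = mean(draws),
                     std.error = sd(draws), conf.low = h[1], conf.high = h[2])
    })
  dplyr::bind_rows(cond, samp)
}

#' @rdname tidy.itraq_fit
#' @export
glance.itraq_fit <- function(x, ...) {
  tibble::tibble(protein = x$protein,
                 mean_log_ratio = x$mean_log_ratio,
                 fold_change = exp(x$mean_log_ratio),
                 hpd_low = unname(x$hpd["lower"]),
                 hpd_high = unname(x$hpd["upper"]),
                 rhat_max = max(x$convergence$parameters$rhat),
                 ess_min = min(x$convergence$parameters$ess),
                 converged = x$converged)
}

#' Tidy a stage-1 protein fit
#'
#' @param x An `itraq_stage1`.
#' @param ... Unused.
#' @return A tibble of per-(run, channel) log-ratio posterior summaries.
#' @export
tidy.itraq_stage1 <- function(x, ...) {
  dplyr::mutate(x$ratios, protein = x$protein, .before = 1)
}

#' @rdname tidy.itraq_stage1
#' @export
glance.itraq_stage1 <- function(x, ...) {
  tibble::tibble(protein = x$protein,
                 n_ratios = nrow(x$ratio_draws),
                 sigma_digest = if (is.null(x$sigma_digest)) NA_real_
                                else unname(x$sigma_digest["mean"]),
                 rhat_max = max(x$convergence$parameters$rhat),
                 ess_min = min(x$convergence$parameters$ess),
                 converged = x$converged)
}

#' @export
tidy.itraq_norm <- function(x, ...) tibble::as_tibble(x)

#' @export
tidy.itraq_calls <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.itraq_calls <- function(x, ...) {
  tibble::tibble(n_proteins = nrow(x),
                 n_significant = sum(x$significant %in% TRUE),
                 proportion = if (nrow(x) == 0) 0
                              else sum(x$significant %in% TRUE) / nrow(x),
                 min_lfdr = if (nrow(x) == 0) NA_real_ else min(x$lfdr))
}
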