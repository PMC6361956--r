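# Synthetic iTRAQ study generator.
#
# The generator is the exact generative inverse of the model the package
# fits: reporter counts are Poisson with log-mean
#   beta_s + lambda_{r,c} + a_{i,sample} + d_{i,p,digest} + eps_{s,c}
# where beta_s is a per-spectrum baseline, lambda the per-(run, channel)
# loading bias (0 for the reference channel), a the sample's true protein
# log abundance relative to the control mean (condition effect + subject
# effect), d a peptide x digest effect and eps channel-specific lognormal
# over-dispersion. A truth table records everything that recovery, coverage
# and FDR-calibration tests need.

#' Configuration for a synthetic iTRAQ study
#'
#' Defaults describe a desk-scale study with the canonical layout: 3 plexes,
#' each carrying two reference-pool digests plus three case and three control
#' samples; 60 proteins with 1-4 unique peptides and 1-5 spectra per peptide
#' per run. Effects and variances are on the natural-log scale throughout.
#'
#' @param n_proteins Number of proteins to simulate.
#' @param peptide_range Integer bounds (discrete uniform) for peptides per
#'   protein.
#' @param spectra_range Integer bounds (discrete uniform) for spectra per
#'   peptide per run.
#' @param baseline_log_mean,baseline_log_sd Mean and SD of the per-spectrum
#'   baseline log count.
#' @param n_plexes Number of 8-plex runs.
#' @param fraction_differential Fraction of proteins with a true condition
#'   effect.
#' @param effect_size_log True condition effect magnitude (natural log) for
#'   differential proteins; sign is randomised per protein. Alternatively a
#'   function `f(n)` returning `n` signed effects.
#' @param subject_sd_case,subject_sd_control Biological between-subject SDs,
#'   allowed to differ between groups (disease tissue is typically more
#'   variable).
#' @param digest_sd SD of peptide x digest effects (trypsin digestion
#'   reproducibility).
#' @param channel_overdispersion_sd Per-channel SD of the lognormal
#'   over-dispersion residual; a single number is recycled to all eight
#'   channels, or supply a vector named by channel.
#' @param loading_bias Optional tibble `(run, channel, bias)` of true
#'   normalisation offsets. `NULL` (default) draws them from
#'   `N(0, loading_bias_sd^2)` with the reference channel fixed at 0.
#' @param loading_bias_sd SD used when `loading_bias` is drawn.
#' @param seed Integer seed; identical configurations give byte-identical
#'   studies.
#' @return A list of class `sim_config`.
#' @seealso [simulate_study()]
#' @export
sim_config <- function(n_proteins = 60,
                       peptide_range = c(1, 4),
                       spectra_range = c(1, 5),
                       baseline_log_mean = log(500),
                       baseline_log_sd = 1,
                       n_plexes = 3,
                       fraction_differential = 0.2,
                       effect_size_log = log(1.5),
                       subject_sd_case = 0.2,
                       subject_sd_control = 0.1,
                       digest_sd = 0.1,
                       channel_overdispersion_sd = 0.1,
                       loading_bias = NULL,
                       loading_bias_sd = 0.2,
                       seed = 1) {
  if (fraction_differential < 0 || fraction_differential > 1) {
    abort_itraq("`fraction_differential` must lie in [0, 1].", "itraq_config_error")
  }
  sds <- c(subject_sd_case, subject_sd_control, digest_sd, baseline_log_sd,
           loading_bias_sd)
  if (any(sds < 0)) {
    abort_itraq("Standard deviations must be >= 0.", "itraq_config_error")
  }
  od <- channel_overdispersion_sd
  if (length(od) == 1 && is.null(names(od))) {
    od <- setNames(rep(od, 8), itraq_channels())
  }
  if (!all(itraq_channels() %in% names(od)) || any(od < 0)) {
    abort_itraq("`channel_overdispersion_sd` must cover all 8 channels with values >= 0.",
                "itraq_config_error")
  }
  if (!is.null(loading_bias)) {
    ref <- loading_bias$bias[loading_bias$channel == itraq_reference_channel()]
    if (length(ref) > 0 && any(ref != 0)) {
      abort_itraq("Loading bias for the reference channel must be 0.",
                  "itraq_config_error")
    }
  }
  structure(list(n_proteins = n_proteins, peptide_range = peptide_range,
                 spectra_range = spectra_range,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd, n_plexes = n_plexes,
                 fraction_differential = fraction_differential,
                 effect_size_log = effect_size_log,
                 subject_sd_case = subject_sd_case,
                 subject_sd_control = subject_sd_control,
                 digest_sd = digest_sd,
                 channel_overdispersion_sd = od[itraq_channels()],
                 loading_bias = loading_bias,
                 loading_bias_sd = loading_bias_sd,
                 seed = seed),
            class = "sim_config")
}

# Canonical synthetic layout: reference digests at channels 113 and 119
# (the model is channel-symmetric given the design table; some fixed
# convention is needed), case/control placement randomised among the
# remaining six channels per plex so condition is not confounded with
# channel label.
simulate_design <- function(n_plexes, n_case_subjects = 3 * n_plexes,
                            n_ctrl_subjects = 3 * n_plexes) {
  runs <- sprintf("plex%d", seq_len(n_plexes))
  case_ids <- sprintf("case%02d", seq_len(n_case_subjects))
  ctrl_ids <- sprintf("ctrl%02d", seq_len(n_ctrl_subjects))
  rows <- list()
  for (p in seq_len(n_plexes)) {
    ref_ch <- c("113", "119")
    other <- setdiff(itraq_channels(), ref_ch)
    placement <- sample(other, 6)
    case_ch <- placement[1:3]
    ctrl_ch <- placement[4:6]
    cases <- case_ids[((p - 1) * 3 + 1):(p * 3)]
    ctrls <- ctrl_ids[((p - 1) * 3 + 1):(p * 3)]
    rows[[p]] <- tibble::tibble(
      run = runs[p],
      channel = c(ref_ch, case_ch, ctrl_ch),
      sample = c(sprintf("%s_ref%s", runs[p], c("A", "B")), cases, ctrls),
      subject = c("pool", "pool", cases, ctrls),
      group = c("reference", "reference", rep("case", 3), rep("control", 3)),
      digest = c(sprintf("%s_pooldigest%s", runs[p], c("A", "B")),
                 paste0(cases, "_d1"), paste0(ctrls, "_d1"))
    )
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$run, match(out$channel, itraq_channels())), ]
  as_itraq_design(out)
}

#' Simulate a complete synthetic iTRAQ study
#'
#' Generates spectrum-level reporter counts, the matching study design and a
#' truth table under exactly the statistical structure the two-stage model
#' assumes (see the package vignette for the generative law). The reference
#' pool is simulated at the case/control mixture abundance
#' `log((1 + exp(theta)) / 2)`, i.e. an equal-parts pool of case and control
#' material on the natural scale.
#'
#' Identical configurations (including the seed) give identical output;
#' spectra that come out all-zero (essentially impossible at the default
#' baseline) are discarded so every record satisfies the load invariants.
#'
#' @param config A [sim_config()].
#' @return A list with elements `records` (spectrum tibble), `design` (design
#'   tibble) and `truth` (list: `effects` tibble with per-protein true log
#'   effects and differential flags, `loading_bias` tibble, `sample_abundance`
#'   tibble of per-sample true protein log abundances, and the `config`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  design <- simulate_design(cfg$n_plexes)

  proteins <- sprintf("prot%03d", seq_len(cfg$n_proteins))
  n_diff <- round(cfg$fraction_differential * cfg$n_proteins)
  diff_idx <- if (n_diff > 0) sort(sample.int(cfg$n_proteins, n_diff)) else integer(0)
  effects <- numeric(cfg$n_proteins)
  if (n_diff > 0) {
    if (is.function(cfg$effect_size_log)) {
      effects[diff_idx] <- cfg$effect_size_log(n_diff)
    } else {
      effects[diff_idx] <- cfg$effect_size_log * sample(c(-1, 1), n_diff, replace = TRUE)
    }
  }

  # True loading biases per (run, channel); reference channel pinned at 0.
  if (is.null(cfg$loading_bias)) {
    lb <- tidyr::expand_grid(run = unique(design$run), channel = itraq_channels())
    lb$bias <- ifelse(lb$channel == itraq_reference_channel(), 0,
                      rnorm(nrow(lb), 0, cfg$loading_bias_sd))
  } else {
    lb <- tibble::as_tibble(cfg$loading_bias)
  }

  # Per-subject biological effects, drawn independently per protein.
  subjects <- unique(design[, c("subject", "group")])

  # discrete-uniform draw that is safe for degenerate ranges
  runif_int <- function(lo, hi, n) lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
  n_pep <- runif_int(cfg$peptide_range[1], cfg$peptide_range[2], cfg$n_proteins)

  design_key <- paste(design$run, design$channel)
  lb_key <- paste(lb$run, lb$channel)
  lambda <- lb$bias[match(design_key, lb_key)]
  chan_idx <- match(design$channel, itraq_channels())
  od_sd <- unname(cfg$channel_overdispersion_sd[design$channel])

  rec_list <- vector("list", cfg$n_proteins)
  abun_list <- vector("list", cfg$n_proteins)
  spec_counter <- 0L

  for (i in seq_len(cfg$n_proteins)) {
    th <- effects[i]
    u <- numeric(nrow(subjects))
    u[subjects$group == "case"] <- rnorm(sum(subjects$group == "case"), 0, cfg$subject_sd_case)
    u[subjects$group == "control"] <- rnorm(sum(subjects$group == "control"), 0, cfg$subject_sd_control)
    # reference pool: same physical material in every plex, no subject noise
    a_subj <- ifelse(subjects$group == "case", th + u,
                     ifelse(subjects$group == "control", u, log((1 + exp(th)) / 2)))
    a_sample <- a_subj[match(design$subject, subjects$subject)]

    peptides <- sprintf("%s_pep%d", proteins[i], seq_len(n_pep[i]))
    digests <- unique(design$digest)
    d_eff <- matrix(rnorm(n_pep[i] * length(digests), 0, cfg$digest_sd),
                    nrow = n_pep[i],
                    dimnames = list(peptides, digests))

    # design rows are ordered run-major with channels in reporter order, so
    # the count vector for one spectrum aligns with ch113..ch121 directly
    pep_v <- character(0); run_v <- character(0); ymat <- NULL
    yrows <- list(); k <- 0
    for (p in seq_len(n_pep[i])) {
      for (r in unique(design$run)) {
        n_spec <- runif_int(cfg$spectra_range[1], cfg$spectra_range[2], 1)
        idx <- which(design$run == r)
        for (s in seq_len(n_spec)) {
          beta <- rnorm(1, cfg$baseline_log_mean, cfg$baseline_log_sd)
          eps <- rnorm(length(idx), 0, od_sd[idx])
          logmu <- beta + lambda[idx] + a_sample[idx] +
            d_eff[p, design$digest[idx]] + eps
          k <- k + 1
          yrows[[k]] <- rpois(length(idx), exp(logmu))
          pep_v[k] <- peptides[p]
          run_v[k] <- r
        }
      }
    }
    ymat <- do.call(rbind, yrows)
    rec <- tibble::tibble(protein = proteins[i], peptide = pep_v, run = run_v,
                          spectrum = sprintf("spec%06d", spec_counter + seq_len(k)))
    spec_counter <- spec_counter + k
    for (j in seq_along(channel_cols())) rec[[channel_cols()[j]]] <- as.integer(ymat[, j])
    rec_list[[i]] <- rec
    abun_list[[i]] <- tibble::tibble(protein = proteins[i],
                                     sample = design$sample,
                                     run = design$run, channel = design$channel,
                                     log_abundance = a_sample)
  }

  records <- dplyr::bind_rows(rec_list)
  records <- records[, c("protein", "peptide", "run", "spectrum", channel_cols())]
  keep <- rowSums(as.matrix(records[, channel_cols()])) > 0
  records <- records[keep, , drop = FALSE]

  truth <- list(
    effects = tibble::tibble(protein = proteins,
                             true_effect_log = effects,
                             differential = seq_len(cfg$n_proteins) %in% diff_idx),
    loading_bias = lb,
    sample_abundance = dplyr::bind_rows(abun_list),
    config = cfg
  )
  list(records = new_itraq_spectra(records), design = design, truth = truth)
}

#' Inject heavy-tailed contamination into a fraction of spectra
#'
#' Multiplies every channel of a randomly chosen fraction of spectra by an
#' independent lognormal factor, emulating background contamination and
#' misidentified spectra — the disturbances the model's channel-specific
#' over-dispersion term is there to absorb.
#'
#' @param records Spectrum table.
#' @param fraction Fraction of spectra to perturb, in `[0, 1]`.
#' @param magnitude_sd SD (natural log) of the perturbation.
#' @param seed Integer seed; the perturbed subset is reproducible.
#' @return The perturbed spectrum table.
#' @export
corrupt_spectra <- function(records, fraction, magnitude_sd, seed = 1) {
  if (fraction < 0 || fraction > 1) {
    abort_itraq("`fraction` must lie in [0, 1].", "itraq_config_error")
  }
  withr::with_seed(seed, {
    n <- nrow(records)
    n_hit <- round(fraction * n)
    if (n_hit == 0 || magnitude_sd == 0) {
      if (n_hit > 0) sample.int(n, n_hit)  # keep RNG stream stable either way
      return(records)
    }
    hit <- sample.int(n, n_hit)
    m <- as.matrix(records[, channel_cols()])
    fac <- matrix(exp(rnorm(n_hit * ncol(m), 0, magnitude_sd)), nrow = n_hit)
    m[hit, ] <- round(m[hit, ] * fac)
    for (j in seq_along(channel_cols())) {
      records[[channel_cols()[j]]] <- as.integer(m[, j])
    }
    records
  })
}
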