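# Post-inference summarisation across brain regions (or any per-region
# analyses run in isolation): change proportions, cross-region overlap
# partitions, k-of-n region selections, and the normalised/scaled
# protein-by-sample matrix handed to ordination.

#' Bundle one region's quantified and significant protein sets
#'
#' @param region Region label (e.g. `"HP"`).
#' @param calls Optional `itraq_calls` tibble (after [select_global_fdr()]);
#'   the quantified set is every called protein and the significant set those
#'   flagged, with directions carried along.
#' @param quantified,significant Alternatively, give the sets directly:
#'   `quantified` a character vector, `significant` a character vector or a
#'   tibble with columns `protein` and `direction`.
#' @return A list of class `region_call_set` with elements `region`,
#'   `quantified` (character) and `significant` (tibble `protein`,
#'   `direction`).
#' @export
region_call_set <- function(region, calls = NULL, quantified = NULL,
                            significant = NULL) {
  if (!is.null(calls)) {
    quantified <- calls$protein
    significant <- tibble::tibble(
      protein = calls$protein[calls$significant %in% TRUE],
      direction = calls$direction[calls$significant %in% TRUE]
    )
  } else {
    quantified <- as.character(quantified %||% character(0))
    if (is.null(significant)) {
      significant <- tibble::tibble(protein = character(0), direction = character(0))
    } else if (is.character(significant)) {
      significant <- tibble::tibble(protein = significant,
                                    direction = NA_character_)
    } else {
      significant <- tibble::as_tibble(significant)
    }
  }
  if (!all(significant$protein %in% quantified)) {
    abort_itraq("Significant proteins must be a subset of quantified proteins.",
                "itraq_integrity_error")
  }
  structure(list(region = region, quantified = unique(quantified),
                 significant = significant),
            class = "region_call_set")
}

#' @export
print.region_call_set <- function(x, ...) {
  cat(sprintf("Region %s: %d quantified, %d significant\n", x$region,
              length(x$quantified), nrow(x$significant)))
  invisible(x)
}

# proteins x regions logical membership matrix (robust to single rows)
membership_matrix <- function(proteins, call_sets, extract) {
  m <- vapply(call_sets, function(x) proteins %in% extract(x),
              logical(length(proteins)))
  matrix(m, nrow = length(proteins))
}

check_call_sets <- function(call_sets, min_regions = 1) {
  if (inherits(call_sets, "region_call_set")) call_sets <- list(call_sets)
  stopifnot(all(vapply(call_sets, inherits, logical(1), "region_call_set")))
  labels <- vapply(call_sets, function(x) x$region, character(1))
  if (anyDuplicated(labels) > 0) {
    abort_itraq("Duplicate region labels.", "itraq_integrity_error")
  }
  if (length(call_sets) < min_regions) {
    abort_itraq(sprintf("Need at least %d region(s).", min_regions),
                "itraq_domain_error")
  }
  setNames(call_sets, labels)
}

#' Summarise differential calls across regions
#'
#' Per region: quantified and significant protein counts and the proportion
#' changed. Across regions: how many proteins are quantified in exactly `k`
#' and in at least `k` regions, for `k = 1 ... n`.
#'
#' @param call_sets A list of [region_call_set()] objects.
#' @return A list of class `itraq_region_summary` with tibbles `per_region`
#'   (`region`, `n_quantified`, `n_significant`, `proportion`) and
#'   `cross_region` (`k`, `n_exactly`, `n_at_least`).
#' @export
summarize_regions <- function(call_sets) {
  call_sets <- check_call_sets(call_sets, 1)
  per_region <- purrr::map_dfr(call_sets, function(x) {
    tibble::tibble(region = x$region,
                   n_quantified = length(x$quantified),
                   n_significant = nrow(x$significant),
                   proportion = if (length(x$quantified) == 0) 0
                                else nrow(x$significant) / length(x$quantified))
  })
  n <- length(call_sets)
  all_prot <- unique(unlist(lapply(call_sets, function(x) x$quantified)))
  tally <- rowSums(membership_matrix(all_prot, call_sets,
                                     function(x) x$quantified))
  cross <- tibble::tibble(
    k = seq_len(n),
    n_exactly = vapply(seq_len(n), function(k) sum(tally == k), integer(1)),
    n_at_least = vapply(seq_len(n), function(k) sum(tally >= k), integer(1))
  )
  structure(list(per_region = per_region, cross_region = cross),
            class = "itraq_region_summary")
}

#' @export
print.itraq_region_summary <- function(x, ...) {
  cat("Per-region differential calls:\n")
  print(x$per_region)
  cat("Proteins quantified in k regions:\n")
  print(x$cross_region)
  invisible(x)
}

#' @export
tidy.itraq_region_summary <- function(x, ...) x$per_region

#' Overlap partition of expression changes across regions
#'
#' Restricted to proteins quantified in every region (the comparison is only
#' meaningful where all regions had the chance to call a change), counts for
#' each non-empty subset `S` of regions the proteins significant in exactly
#' the regions of `S` — the cell counts of an Edwards-Venn diagram.
#' Region-exclusive changes are the singleton cells.
#'
#' @param call_sets A list of at least two [region_call_set()] objects.
#' @param restrict_universal Keep the restriction to proteins quantified in
#'   all regions (default `TRUE`); `FALSE` partitions every protein
#'   significant anywhere.
#' @return A tibble with columns `region_subset` (labels joined by `+`),
#'   `n_regions`, `count`, covering every non-empty subset.
#' @export
overlap_partition <- function(call_sets, restrict_universal = TRUE) {
  call_sets <- check_call_sets(call_sets, 2)
  labels <- names(call_sets)
  n <- length(labels)
  if (n > 12) {
    abort_itraq("Overlap partition over more than 12 regions is not sensible.",
                "itraq_domain_error")
  }
  if (restrict_universal) {
    universe <- Reduce(intersect, lapply(call_sets, function(x) x$quantified))
  } else {
    universe <- unique(unlist(lapply(call_sets, function(x) x$quantified)))
  }
  member <- vapply(call_sets,
                   function(x) universe %in% x$significant$protein,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe))
  pattern <- apply(member, 1, function(row) paste(which(row), collapse = ","))

  subsets <- unlist(lapply(seq_len(n), function(k) {
    utils::combn(n, k, simplify = FALSE)
  }), recursive = FALSE)
  out <- purrr::map_dfr(subsets, function(s) {
    key <- paste(s, collapse = ",")
    tibble::tibble(region_subset = paste(labels[s], collapse = "+"),
                   n_regions = length(s),
                   count = sum(pattern == key))
  })
  out
}

#' Proteins changed in at least k regions
#'
#' Selects proteins significant in `>= k` regions, restricted to proteins
#' quantified in `>= k` regions (a protein cannot be required to change where
#' it was never quantified).
#'
#' @param call_sets A list of [region_call_set()] objects.
#' @param k Minimum number of regions, `1 <= k <= length(call_sets)`.
#' @return Character vector of protein accessions.
#' @export
count_regions_changed <- function(call_sets, k) {
  call_sets <- check_call_sets(call_sets, 1)
  n <- length(call_sets)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n) {
    abort_itraq(sprintf("`k` must lie in [1, %d].", n), "itraq_domain_error")
  }
  all_prot <- unique(unlist(lapply(call_sets, function(x) x$quantified)))
  n_quant <- rowSums(membership_matrix(all_prot, call_sets,
                                       function(x) x$quantified))
  n_sig <- rowSums(membership_matrix(all_prot, call_sets,
                                     function(x) x$significant$protein))
  sort(all_prot[n_quant >= k & n_sig >= k])
}

#' Normalised, centred and scaled protein-by-sample matrix for ordination
#'
#' Implements the matrix preparation for sample-level ordination: each
#' protein's per-sample log-ratio posterior mean is normalised by
#' subtracting the sample's normalisation factor, centred across samples,
#' and divided by the mean standard deviation of its posterior distributions.
#' Proteins lacking a measurement in any sample of the design are excluded
#' (ordination needs a complete matrix), as are proteins whose mean posterior
#' SD is zero.
#'
#' @param quant A tibble of per-sample protein quantification posteriors with
#'   columns `protein`, `run`, `channel`, `mean`, `sd` (see
#'   [stage1_quant_table()]).
#' @param norm Normalisation factors ([infer_normalization()]).
#' @param design Study design; defines the sample set (rows of the matrix).
#' @return A tibble with one row per sample: `sample`, `run`, `channel`,
#'   `group` followed by one column per retained protein. Each protein
#'   column has zero mean across samples.
#' @export
prepare_pca_matrix <- function(quant, norm, design) {
  design <- tibble::as_tibble(design)
  nm <- tibble::as_tibble(norm)[, c("run", "channel", "mean")]
  names(nm)[3] <- "norm_mean"
  q <- dplyr::inner_join(tibble::as_tibble(quant), nm, by = c("run", "channel"))
  q <- dplyr::inner_join(q, design[, c("run", "channel", "sample", "group")],
                         by = c("run", "channel"))
  q$value <- q$mean - q$norm_mean

  n_samples <- nrow(design)
  keep <- q %>%
    dplyr::group_by(.data$protein) %>%
    dplyr::summarise(complete = dplyr::n() == n_samples,
                     mean_sd = mean(.data$sd), .groups = "drop")
  excluded_sd <- keep$protein[keep$complete & keep$mean_sd == 0]
  if (length(excluded_sd) > 0) {
    rlang::warn(paste0("Excluding protein(s) with zero mean posterior SD: ",
                       paste(head(excluded_sd, 5), collapse = ", ")))
  }
  keep_prot <- keep$protein[keep$complete & keep$mean_sd > 0]
  q <- q[q$protein %in% keep_prot, , drop = FALSE]
  if (nrow(q) == 0) {
    return(dplyr::mutate(design[, c("sample", "run", "channel", "group")]))
  }
  q <- q %>%
    dplyr::group_by(.data$protein) %>%
    dplyr::mutate(scaled = (.data$value - mean(.data$value)) / mean(.data$sd)) %>%
    dplyr::ungroup()
  wide <- tidyr::pivot_wider(q[, c("sample", "run", "channel", "group",
                                   "protein", "scaled")],
                             names_from = "protein", values_from = "scaled")
  dplyr::arrange(wide, .data$run, match(.data$channel, itraq_channels()))
}
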