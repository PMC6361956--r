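# Reading, validating and filtering spectrum-level quantification tables.
#
# The on-disk dialect is a tab-separated table with one row per identified
# MS/MS spectrum: provenance columns (protein, peptide, run, spectrum, and an
# optional `unique` flag) followed by the eight reporter-ion count columns
# ch113..ch121. Reporter intensities exported as areas are rounded
# half-to-even to counts and flagged in the load report; the Poisson
# likelihood needs integer observations.

default_schema <- function() {
  c(
    list(protein = "protein", peptide = "peptide", run = "run",
         spectrum = "spectrum", unique = "unique"),
    as.list(setNames(channel_cols(), channel_cols()))
  )
}

resolve_schema <- function(schema) {
  base <- default_schema()
  if (is.null(schema)) return(base)
  if (is.character(schema) && length(schema) == 1) {
    schema <- yaml::read_yaml(schema)
  }
  if (!is.list(schema)) {
    abort_itraq("`schema` must be NULL, a named list, or a YAML file path.",
                "itraq_format_error")
  }
  unknown <- setdiff(names(schema), names(base))
  if (length(unknown) > 0) {
    abort_itraq(paste0("Unknown schema entries: ", paste(unknown, collapse = ", ")),
                "itraq_format_error")
  }
  utils::modifyList(base, schema)
}

truthy <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes", "y")
}

#' Read a spectrum-level quantification table
#'
#' Loads a tab-separated table of identified spectra with eight reporter-ion
#' count columns and validates it against the spectrum-record invariants:
#' counts are non-negative integers, no spectrum is all-zero, and
#' `(run, spectrum)` identifies a row uniquely.
#'
#' Rows are handled in three tiers:
#' * fatal problems abort the load: a missing column (format error), a
#'   negative or unparseable count, or a duplicated `(run, spectrum)` pair
#'   (integrity errors);
#' * all-zero spectra are rejected row-by-row (they carry no likelihood
#'   contribution and leave the spectrum baseline undefined) and reported;
#' * non-integer reporter values (area exports) are rounded half-to-even and
#'   the affected rows flagged.
#'
#' If the table has a `unique` column, rows flagged as shared between
#' proteins are dropped at load, so that each protein is quantified from
#' peptide measurements unique to it.
#'
#' No row is lost silently: the number of input rows always equals the number
#' of returned records plus the rejected and shared-dropped rows enumerated in
#' [load_report()].
#'
#' @param path Path to a TSV file with a header.
#' @param schema Optional named list (or YAML file path) overriding column
#'   names; entries are `protein`, `peptide`, `run`, `spectrum`, `unique`, and
#'   `ch113` ... `ch121`.
#' @return A tibble of validated spectrum records (class `itraq_spectra`) with
#'   columns `protein`, `peptide`, `run`, `spectrum`, `ch113` ... `ch121`.
#'   The load report is attached as an attribute; retrieve it with
#'   [load_report()].
#' @seealso [write_spectrum_table()], [filter_min_spectra()]
#' @export
read_spectrum_table <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort_itraq(paste0("Spectrum table not found: ", path), "itraq_format_error")
  }
  sch <- resolve_schema(schema)
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- unlist(sch[c("protein", "peptide", "run", "spectrum", channel_cols())])
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort_itraq(paste0("Missing required column(s): ", paste(missing, collapse = ", ")),
                "itraq_format_error")
  }
  out <- tibble::tibble(
    .row = seq_len(nrow(tbl)),
    protein = tbl[[sch$protein]],
    peptide = tbl[[sch$peptide]],
    run = tbl[[sch$run]],
    spectrum = tbl[[sch$spectrum]]
  )
  for (cc in channel_cols()) out[[cc]] <- tbl[[sch[[cc]]]]

  n_input <- nrow(out)

  # Shared (non-unique) peptides are dropped before invariant checks.
  dropped_shared <- integer(0)
  if (sch$unique %in% names(tbl)) {
    shared <- !truthy(tbl[[sch$unique]])
    dropped_shared <- out$.row[shared]
    out <- out[!shared, , drop = FALSE]
  }

  counts <- suppressWarnings(
    vapply(channel_cols(), function(cc) as.numeric(out[[cc]]), numeric(nrow(out)))
  )
  counts <- matrix(counts, nrow = nrow(out))
  if (anyNA(counts)) {
    bad <- out$.row[apply(counts, 1, anyNA)]
    abort_itraq(paste0("Non-numeric reporter count(s) in row(s): ",
                       paste(head(bad, 10), collapse = ", ")),
                "itraq_format_error")
  }
  if (any(counts < 0)) {
    bad <- out$.row[apply(counts < 0, 1, any)]
    abort_itraq(paste0("Negative reporter count(s) in row(s): ",
                       paste(head(bad, 10), collapse = ", ")),
                "itraq_integrity_error")
  }
  rounded_rows <- out$.row[apply(counts != round(counts), 1, any)]
  counts <- round(counts)  # base round() is round-half-to-even
  for (j in seq_along(channel_cols())) out[[channel_cols()[j]]] <- as.integer(counts[, j])

  allzero <- rowSums(counts) == 0
  rejections <- tibble::tibble(row = out$.row[allzero],
                               reason = rep("all-zero spectrum", sum(allzero)))
  out <- out[!allzero, , drop = FALSE]

  dup <- duplicated(out[, c("run", "spectrum")])
  if (any(dup)) {
    abort_itraq(paste0("Duplicate (run, spectrum) pair(s), e.g. row(s): ",
                       paste(head(out$.row[dup], 10), collapse = ", ")),
                "itraq_integrity_error")
  }

  report <- list(n_input = n_input,
                 n_records = nrow(out),
                 rejections = rejections,
                 rounded_rows = rounded_rows,
                 dropped_shared_rows = dropped_shared)
  out$.row <- NULL
  new_itraq_spectra(out, report = report)
}

new_itraq_spectra <- function(tbl, report = NULL) {
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "load_report") <- report
  class(tbl) <- unique(c("itraq_spectra", class(tbl)))
  tbl
}

#' Coerce a data frame to a validated spectrum table
#'
#' Checks the spectrum-record invariants on an in-memory table (integer
#' non-negative counts, no all-zero spectra, unique `(run, spectrum)`).
#'
#' @param tbl A data frame with columns `protein`, `peptide`, `run`,
#'   `spectrum` and `ch113` ... `ch121`.
#' @return The validated tibble with class `itraq_spectra`.
#' @export
as_itraq_spectra <- function(tbl) {
  needed <- c("protein", "peptide", "run", "spectrum", channel_cols())
  missing <- setdiff(needed, names(tbl))
  if (length(missing) > 0) {
    abort_itraq(paste0("Missing required column(s): ", paste(missing, collapse = ", ")),
                "itraq_format_error")
  }
  counts <- as.matrix(tbl[, channel_cols()])
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort_itraq("Reporter counts must be non-negative integers.",
                "itraq_integrity_error")
  }
  if (any(rowSums(counts) == 0)) {
    abort_itraq("All-zero spectra are not valid records.", "itraq_integrity_error")
  }
  if (anyDuplicated(tbl[, c("run", "spectrum")]) > 0) {
    abort_itraq("(run, spectrum) pairs must be unique.", "itraq_integrity_error")
  }
  new_itraq_spectra(tbl[, needed])
}

#' Retrieve the load report attached by `read_spectrum_table()`
#'
#' @param x A table returned by [read_spectrum_table()].
#' @return A list with elements `n_input`, `n_records`, `rejections` (tibble
#'   of row numbers and reasons), `rounded_rows` and `dropped_shared_rows`.
#' @export
load_report <- function(x) attr(x, "load_report")

#' Write a spectrum table to TSV
#'
#' Inverse of [read_spectrum_table()] under the default schema; a write
#' followed by a read reproduces the records exactly.
#'
#' @param records Spectrum table (tibble).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(records, path) {
  cols <- c("protein", "peptide", "run", "spectrum", channel_cols())
  readr::write_tsv(tibble::as_tibble(records)[, cols], path, progress = FALSE)
  invisible(path)
}

#' Read a study-design table
#'
#' The design table maps each `(run, channel)` position of every 8-plex to a
#' sample, and each sample to its subject, group and digest. Groups must be
#' `case`, `control` or `reference` (the reference pool that links plexes).
#'
#' @param path Path to a TSV file with columns `run`, `channel`, `sample`,
#'   `subject`, `group`, `digest`.
#' @return A tibble with class `itraq_design`.
#' @export
read_design_table <- function(path) {
  if (!file.exists(path)) {
    abort_itraq(paste0("Design table not found: ", path), "itraq_format_error")
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  as_itraq_design(tbl)
}

#' @rdname read_design_table
#' @param tbl A data frame with the design columns.
#' @export
as_itraq_design <- function(tbl) {
  needed <- c("run", "channel", "sample", "subject", "group", "digest")
  missing <- setdiff(needed, names(tbl))
  if (length(missing) > 0) {
    abort_itraq(paste0("Design table missing column(s): ", paste(missing, collapse = ", ")),
                "itraq_format_error")
  }
  tbl <- tibble::as_tibble(tbl)[, needed]
  tbl$channel <- as.character(tbl$channel)
  bad <- setdiff(unique(tbl$group), c("case", "control", "reference"))
  if (length(bad) > 0) {
    abort_itraq(paste0("Unknown group label(s): ", paste(bad, collapse = ", ")),
                "itraq_format_error")
  }
  if (anyDuplicated(tbl[, c("run", "channel")]) > 0) {
    abort_itraq("Each (run, channel) may be assigned only once.",
                "itraq_integrity_error")
  }
  class(tbl) <- unique(c("itraq_design", class(tbl)))
  tbl
}

#' Write a design table to TSV
#'
#' @param design Design tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design_table <- function(design, path) {
  cols <- c("run", "channel", "sample", "subject", "group", "digest")
  readr::write_tsv(tibble::as_tibble(design)[, cols], path, progress = FALSE)
  invisible(path)
}

#' Cross-check a study design against spectrum records
#'
#' Produces a validation report rather than erroring: entries are `fatal`
#' (runs present in the data but absent from the design; channels left
#' unassigned within an assigned run) or `warning` (plexes deviating from the
#' canonical 2-reference-digests + 3-case + 3-control layout — real designs
#' may legitimately differ). Callers such as [run_pipeline()] treat fatal
#' entries as errors.
#'
#' @param design Design tibble (see [read_design_table()]).
#' @param records Spectrum table (see [read_spectrum_table()]).
#' @return A list with tibbles `fatal` and `warnings` (columns `check`,
#'   `detail`), class `itraq_validation`.
#' @export
validate_design <- function(design, records) {
  fatal <- list()
  warns <- list()
  add <- function(lst, check, detail) c(lst, list(tibble::tibble(check = check, detail = detail)))

  data_runs <- unique(records$run)
  missing_runs <- setdiff(data_runs, unique(design$run))
  if (length(missing_runs) > 0) {
    fatal <- add(fatal, "run-missing-from-design", missing_runs)
  }
  for (r in intersect(data_runs, unique(design$run))) {
    assigned <- design$channel[design$run == r]
    unassigned <- setdiff(itraq_channels(), assigned)
    if (length(unassigned) > 0) {
      fatal <- add(fatal, "channel-unassigned",
                   paste0(r, ": ", paste(unassigned, collapse = ", ")))
    }
  }

  for (r in unique(design$run)) {
    d <- design[design$run == r, ]
    n_ref <- sum(d$group == "reference")
    n_case <- sum(d$group == "case")
    n_ctrl <- sum(d$group == "control")
    if (n_ref != 2 || n_case != 3 || n_ctrl != 3) {
      warns <- add(warns, "plex-layout",
                   sprintf("%s: %d reference / %d case / %d control (expected 2/3/3)",
                           r, n_ref, n_case, n_ctrl))
    }
    ref <- d[d$group == "reference", ]
    if (n_ref == 2) {
      if (length(unique(ref$digest)) != 2) {
        warns <- add(warns, "reference-digests",
                     paste0(r, ": reference pool digests are not distinct"))
      }
      if (length(unique(ref$subject)) != 1) {
        warns <- add(warns, "reference-subject",
                     paste0(r, ": reference pool entries map to several subjects"))
      }
    }
    nonref <- d[d$group != "reference", ]
    multi <- tapply(nonref$digest, nonref$sample, function(z) length(unique(z)))
    if (length(multi) > 0 && any(multi > 1)) {
      warns <- add(warns, "sample-digests",
                   paste0(r, ": sample(s) with several digests: ",
                          paste(names(multi)[multi > 1], collapse = ", ")))
    }
  }

  bind_or_empty <- function(lst) {
    if (length(lst) == 0) {
      tibble::tibble(check = character(0), detail = character(0))
    } else {
      dplyr::bind_rows(lst)
    }
  }
  structure(list(fatal = bind_or_empty(fatal), warnings = bind_or_empty(warns)),
            class = "itraq_validation")
}

#' @export
print.itraq_validation <- function(x, ...) {
  cat("Study-design validation\n")
  cat("  fatal:   ", nrow(x$fatal), "\n")
  if (nrow(x$fatal) > 0) print(x$fatal)
  cat("  warnings:", nrow(x$warnings), "\n")
  if (nrow(x$warnings) > 0) print(x$warnings)
  invisible(x)
}

#' Drop proteins quantified from too few spectra
#'
#' Proteins whose total spectrum count across all runs of a region falls
#' below `min_spectra` are removed entirely. The default of three spectra
#' retains only proteins whose quantification is precise enough for
#' cross-region comparison; proteins seen in just one or two spectra are
#' omitted. The filter is idempotent and monotone in the threshold.
#'
#' @param records Spectrum table.
#' @param min_spectra Minimum total number of spectra per protein (default 3).
#' @return The filtered spectrum table; the filter report (kept/dropped
#'   protein sets and per-protein spectrum counts) is attached as an
#'   attribute, retrievable with [filter_report()].
#' @export
filter_min_spectra <- function(records, min_spectra = 3) {
  if (!is.numeric(min_spectra) || length(min_spectra) != 1 || min_spectra < 1) {
    abort_itraq("`min_spectra` must be a single number >= 1.", "itraq_domain_error")
  }
  counts <- dplyr::count(tibble::as_tibble(records), .data$protein, name = "n_spectra")
  kept <- counts$protein[counts$n_spectra >= min_spectra]
  dropped <- counts$protein[counts$n_spectra < min_spectra]
  out <- records[records$protein %in% kept, , drop = FALSE]
  report <- structure(
    list(kept_proteins = sort(kept),
         dropped_proteins = sort(dropped),
         spectra_per_protein = dplyr::arrange(counts, .data$protein),
         min_spectra = min_spectra),
    class = "itraq_filter_report"
  )
  attr(out, "filter_report") <- report
  out
}

#' @rdname filter_min_spectra
#' @param x A table returned by [filter_min_spectra()].
#' @export
filter_report <- function(x) attr(x, "filter_report")

#' @export
print.itraq_filter_report <- function(x, ...) {
  cat("Minimum-spectra filter (threshold ", x$min_spectra, ")\n", sep = "")
  cat("  kept:    ", length(x$kept_proteins), " proteins\n", sep = "")
  cat("  dropped: ", length(x$dropped_proteins), " proteins\n", sep = "")
  invisible(x)
}

filter_report_json <- function(report) {
  list(min_spectra = report$min_spectra,
       kept_proteins = as.list(report$kept_proteins),
       dropped_proteins = as.list(report$dropped_proteins),
       spectra_per_protein = setNames(as.list(report$spectra_per_protein$n_spectra),
                                      report$spectra_per_protein$protein))
}
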