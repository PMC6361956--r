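test_that("spectrum tables round-trip through TSV exactly", {
  sim <- simulate_study(sim_config(n_proteins = 4, peptide_range = c(1, 2),
                                   spectra_range = c(1, 2), seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum_table(sim$records, path)
  back <- read_spectrum_table(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(sim$records),
               ignore_attr = TRUE)
  rep <- load_report(back)
  expect_equal(rep$n_input, nrow(sim$records))
  expect_equal(nrow(rep$rejections), 0)

  dpath <- withr::local_tempfile(fileext = ".tsv")
  write_design_table(sim$design, dpath)
  expect_equal(tibble::as_tibble(read_design_table(dpath)),
               tibble::as_tibble(sim$design))
})

test_that("loading rejects bad rows and never drops rows silently", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  hdr <- c("protein", "peptide", "run", "spectrum", "unique", paste0("ch", itraq_channels()))
  rows <- list(
    c("P1", "p1", "r1", "s1", "TRUE", rep("10", 8)),
    c("P1", "p1", "r1", "s2", "TRUE", rep("0", 8)),          # all-zero
    c("P1", "p2", "r1", "s3", "FALSE", rep("10", 8)),        # shared peptide
    c("P2", "p3", "r1", "s4", "TRUE", c("12.4", "12.5", "13.5", rep("7", 5)))
  )
  writeLines(c(paste(hdr, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")), tsv)
  rec <- read_spectrum_table(tsv)
  rep <- load_report(rec)

  expect_equal(nrow(rec), 2)
  expect_equal(rep$rejections$reason, "all-zero spectrum")
  expect_equal(rep$rejections$row, 2)
  expect_equal(rep$dropped_shared_rows, 3)
  # conservation: every input row is a record, a rejection, or a shared drop
  expect_equal(rep$n_input, nrow(rec) + nrow(rep$rejections) +
                 length(rep$dropped_shared_rows))
  # round-half-to-even on area exports, flagged
  s4 <- rec[rec$spectrum == "s4", ]
  expect_equal(s4$ch113, 12L)
  expect_equal(s4$ch114, 12L)  # 12.5 -> 12
  expect_equal(s4$ch115, 14L)  # 13.5 -> 14
  expect_equal(rep$rounded_rows, 4)
})

test_that("structural problems abort with informative errors", {
  base <- tibble::tibble(protein = "P1", peptide = "p1", run = "r1",
                         spectrum = c("s1", "s2"))
  for (cc in paste0("ch", itraq_channels())) base[[cc]] <- c(5L, 6L)

  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::select(base, -"ch121"), f)
  expect_error(read_spectrum_table(f), "ch121", class = "itraq_format_error")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  bad <- base; bad$spectrum <- c("s1", "s1")
  readr::write_tsv(bad, f2)
  expect_error(read_spectrum_table(f2), "Duplicate",
               class = "itraq_integrity_error")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  neg <- base; neg$ch114 <- c(-1L, 3L)
  readr::write_tsv(neg, f3)
  expect_error(read_spectrum_table(f3), "Negative",
               class = "itraq_integrity_error")

  expect_error(read_spectrum_table(tempfile()), "not found",
               class = "itraq_format_error")
})

test_that("schema overrides rename columns, including via YAML", {
  sim <- simulate_study(sim_config(n_proteins = 2, peptide_range = c(1, 1),
                                   spectra_range = c(1, 1), seed = 5))
  tbl <- tibble::as_tibble(sim$records)
  names(tbl)[names(tbl) == "protein"] <- "Accession"
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, f)
  expect_error(read_spectrum_table(f), "protein", class = "itraq_format_error")
  rec <- read_spectrum_table(f, schema = list(protein = "Accession"))
  expect_equal(sort(unique(rec$protein)), sort(unique(sim$records$protein)))

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines("protein: Accession", yml)
  rec2 <- read_spectrum_table(f, schema = yml)
  expect_equal(rec2, rec)
})

test_that("minimum-spectra filter drops exactly the low-evidence proteins", {
  recs <- dplyr::bind_rows(lapply(1:5, function(i) {
    tibble::as_tibble(make_records(rep(list(rep(10, 8)), i),
                                   protein = sprintf("P%d", i),
                                   run = "plex1"))
  }))
  recs$spectrum <- sprintf("s%03d", seq_len(nrow(recs)))  # unique ids
  recs <- as_itraq_spectra(recs)

  kept <- filter_min_spectra(recs)  # default threshold 3
  rep <- filter_report(kept)
  expect_equal(rep$kept_proteins, c("P3", "P4", "P5"))
  expect_equal(rep$dropped_proteins, c("P1", "P2"))
  expect_equal(rep$min_spectra, 3)
  expect_setequal(unique(kept$protein), c("P3", "P4", "P5"))

  # min_spectra = 1 keeps everything
  all_kept <- filter_min_spectra(recs, 1)
  expect_equal(length(filter_report(all_kept)$dropped_proteins), 0)
  expect_equal(nrow(all_kept), nrow(recs))

  expect_error(filter_min_spectra(recs, 0), class = "itraq_domain_error")
})

test_that("the filter is idempotent and monotone in the threshold", {
  sim <- simulate_study(sim_config(n_proteins = 8, peptide_range = c(1, 2),
                                   spectra_range = c(1, 2), n_plexes = 1,
                                   seed = 9))
  prev_kept <- NULL
  for (thr in c(1, 3, 5, 8, 12)) {
    out <- filter_min_spectra(sim$records, thr)
    again <- filter_min_spectra(out, thr)
    expect_equal(tibble::as_tibble(again), tibble::as_tibble(out),
                 ignore_attr = TRUE)
    kept <- filter_report(out)$kept_proteins
    if (!is.null(prev_kept)) expect_true(all(kept %in% prev_kept))
    prev_kept <- kept
  }
})

test_that("design validation separates fatal problems from layout warnings", {
  sim <- simulate_study(sim_config(n_proteins = 3, peptide_range = c(1, 1),
                                   spectra_range = c(1, 1), seed = 2))
  ok <- validate_design(sim$design, sim$records)
  expect_equal(nrow(ok$fatal), 0)
  expect_equal(nrow(ok$warnings), 0)

  # run present in the data but absent from the design: fatal, named
  missing_run <- sim$design[sim$design$run != "plex3", ]
  v <- validate_design(missing_run, sim$records)
  expect_true(any(grepl("plex3", v$fatal$detail)))

  # unassigned channel within a run: fatal
  dropped_ch <- sim$design[!(sim$design$run == "plex1" &
                               sim$design$channel == "121"), ]
  v2 <- validate_design(dropped_ch, sim$records)
  expect_true(any(v2$fatal$check == "channel-unassigned"))

  # one reference digest only: layout warning, not fatal
  d3 <- tibble::as_tibble(sim$design)
  i <- which(d3$run == "plex1" & d3$group == "reference")[1]
  d3$group[i] <- "control"; d3$subject[i] <- "extra_ctrl"
  v3 <- validate_design(d3, sim$records)
  expect_equal(nrow(v3$fatal), 0)
  expect_true(any(v3$warnings$check == "plex-layout"))
})
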