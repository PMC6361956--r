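cs <- function(region, quantified, significant = character(0)) {
  region_call_set(region, quantified = quantified, significant = significant)
}

test_that("per-region summaries report counts and proportions", {
  one <- summarize_regions(list(cs("HP", sprintf("p%02d", 1:10),
                                   c("p01", "p02", "p03"))))
  expect_equal(one$per_region$n_quantified, 10)
  expect_equal(one$per_region$n_significant, 3)
  expect_equal(one$per_region$proportion, 0.3)

  empty <- summarize_regions(list(cs("HP", c("a", "b")), cs("CB", "a")))
  expect_true(all(empty$per_region$proportion == 0))
})

test_that("a single region with a single protein is summarised correctly", {
  s <- summarize_regions(list(cs("HP", "p01", "p01")))
  expect_equal(s$per_region$proportion, 1)
  expect_equal(s$cross_region$n_exactly, 1L)
  expect_equal(count_regions_changed(list(cs("HP", "p01", "p01")), 1), "p01")
})

test_that("cross-region tallies count exact and cumulative membership", {
  s <- summarize_regions(list(cs("R1", c("A", "B")), cs("R2", c("B", "C")),
                              cs("R3", "B")))
  # B in all three; A and C in one each
  expect_equal(s$cross_region$n_exactly, c(2L, 0L, 1L))
  expect_equal(s$cross_region$n_at_least, c(3L, 1L, 1L))
})

test_that("significance must be a subset of quantification", {
  expect_error(cs("HP", "a", c("a", "b")), class = "itraq_integrity_error")
  expect_error(summarize_regions(list(cs("HP", "a"), cs("HP", "b"))),
               class = "itraq_integrity_error")  # duplicate labels
})

test_that("overlap partition isolates region-exclusive changes", {
  regions <- sprintf("R%d", 1:6)
  sets <- lapply(regions, function(r) {
    cs(r, sprintf("p%02d", 1:10),
       if (r == "R6") "p01" else character(0))
  })
  out <- overlap_partition(sets)
  expect_equal(sum(out$count), 1)
  expect_equal(out$count[out$region_subset == "R6"], 1)

  same <- lapply(regions, function(r) cs(r, c("a", "b", "c"), c("a", "b")))
  out2 <- overlap_partition(same)
  expect_equal(out2$count[out2$region_subset == paste(regions, collapse = "+")], 2)
  expect_equal(sum(out2$count), 2)
})

test_that("overlap partition matches brute-force pattern enumeration", {
  set.seed(50)
  proteins <- sprintf("p%02d", 1:20)
  for (rep in 1:5) {
    regions <- sprintf("R%d", 1:6)
    quantified <- setNames(lapply(regions, function(r) {
      sample(proteins, sample(14:20, 1))
    }), regions)
    significant <- setNames(lapply(regions, function(r) {
      q <- quantified[[r]]
      sample(q, sample(0:length(q), 1))
    }), regions)
    sets <- lapply(regions, function(r) {
      cs(r, quantified[[r]], significant[[r]])
    })
    got <- overlap_partition(sets)
    want <- oracle_overlap(quantified, significant)
    for (i in seq_len(nrow(got))) {
      expect_equal(got$count[i], want[[got$region_subset[i]]])
    }
    # cell sums reconcile with the significant-somewhere universe
    universe <- Reduce(intersect, quantified)
    sig_any <- unique(unlist(significant))
    expect_equal(sum(got$count), length(intersect(universe, sig_any)))
  }
})

test_that("k-of-n selection reduces to union and intersection at the extremes", {
  sets <- list(cs("R1", c("a", "b", "c"), c("a", "b")),
               cs("R2", c("a", "b", "d"), c("b", "d")),
               cs("R3", c("a", "b", "c", "d"), c("b")))
  expect_setequal(count_regions_changed(sets, 1), c("a", "b", "d"))
  expect_equal(count_regions_changed(sets, 3), "b")
  expect_setequal(count_regions_changed(sets, 2), c("b"))
  expect_error(count_regions_changed(sets, 0), class = "itraq_domain_error")
  expect_error(count_regions_changed(sets, 4), class = "itraq_domain_error")

  # non-increasing in k
  set.seed(51)
  rsets <- lapply(1:5, function(i) {
    q <- sample(sprintf("p%02d", 1:15), 12)
    cs(sprintf("R%d", i), q, sample(q, 5))
  })
  sizes <- vapply(1:5, function(k) length(count_regions_changed(rsets, k)),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("the ordination matrix is normalised, centred and scaled", {
  quant <- tidyr::expand_grid(protein = c("P1", "P2"), run = "plex1",
                              channel = itraq_channels())
  quant$mean <- ifelse(quant$protein == "P1",
                       seq(0.1, 0.8, by = 0.1), seq(-0.4, 0.3, by = 0.1))
  quant$sd <- 1
  design <- single_run_design()
  norm0 <- tibble::tibble(run = "plex1", channel = itraq_channels(),
                          mean = 0, sd = 0.01)

  m <- prepare_pca_matrix(quant, norm0, design)
  expect_setequal(setdiff(names(m), c("sample", "run", "channel", "group")),
                  c("P1", "P2"))
  # with zero factors and unit SDs the columns are the row-centred means
  expect_equal(sort(m$P1), sort(seq(0.1, 0.8, 0.1) - mean(seq(0.1, 0.8, 0.1))))
  expect_lt(abs(mean(m$P1)), 1e-12)
  expect_lt(abs(mean(m$P2)), 1e-12)

  # a +0.3 normalisation factor on one sample shifts its value by -0.3
  norm1 <- norm0
  norm1$mean[norm1$channel == "115"] <- 0.3
  m1 <- prepare_pca_matrix(quant, norm1, design)
  delta <- m1$P1 - m$P1
  shifted <- m1$channel == "115"
  expect_equal(unique(round(delta[!shifted], 10)),
               round(0.3 / 8, 10))  # re-centring spreads the shift
  expect_equal(round(delta[shifted], 10), round(-0.3 + 0.3 / 8, 10))
})

test_that("incomplete or zero-SD proteins are excluded from the matrix", {
  quant <- tidyr::expand_grid(protein = c("P1", "P2", "P3"), run = "plex1",
                              channel = itraq_channels())
  quant$mean <- rep(seq(0, 0.7, 0.1), 3)
  quant$sd <- ifelse(quant$protein == "P3", 0, 1)
  quant <- quant[!(quant$protein == "P2" & quant$channel == "117"), ]
  design <- single_run_design()
  norm0 <- tibble::tibble(run = "plex1", channel = itraq_channels(),
                          mean = 0, sd = 0.01)
  expect_warning(m <- prepare_pca_matrix(quant, norm0, design), "zero mean")
  expect_true("P1" %in% names(m))
  expect_false("P2" %in% names(m))  # missing a sample
  expect_false("P3" %in% names(m))  # zero posterior SD
})
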