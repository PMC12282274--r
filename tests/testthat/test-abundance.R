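make_records <- function(n = 50, refs, seed = 1, unmapped_frac = 0.1) {
  set.seed(seed)
  mapped <- runif(n) >= unmapped_frac
  ref_id <- ifelse(mapped, sample(refs$ref_id, n, replace = TRUE), NA)
  read_length <- 100L
  aligned_length <- ifelse(mapped, sample(40:100, n, replace = TRUE), NA)
  tibble::tibble(
    read_id = sprintf("r%03d", seq_len(n)),
    mapped = mapped,
    ref_id = ref_id,
    ref_start = ifelse(mapped, sample(1:500, n, replace = TRUE), NA),
    aligned_length = as.integer(aligned_length),
    read_length = read_length,
    percent_identity = ifelse(mapped, runif(n, 60, 100), NA)
  )
}

test_refs <- function() {
  reference_set(c("gA1", "gA2", "gB1"), c(1000, 1000, 1000),
                c("catA", "catA", "catB"))
}

test_that("filter boundaries are inclusive and unmapped reads are tallied", {
  p <- filter_params(86, 95)
  rec <- tibble::tibble(
    read_id = c("below", "at_identity", "at_fraction", "unmapped"),
    mapped = c(TRUE, TRUE, TRUE, FALSE),
    ref_id = c("gA1", "gA1", "gA1", NA),
    ref_start = c(1L, 1L, 1L, NA),
    aligned_length = c(100L, 100L, 95L, NA),
    read_length = 100L,
    percent_identity = c(85.9, 86, 100, NA)
  )
  out <- filter_records(rec, p)
  expect_setequal(out$kept$read_id, c("at_identity", "at_fraction"))
  expect_equal(out$n_unmapped, 1)
  expect_equal(out$n_failed, 1)
})

test_that("filters match a brute-force predicate recount", {
  refs <- test_refs()
  rec <- make_records(200, refs, seed = 3)
  for (p in list(genome_mode_filters(), contig_mode_filters(),
                 filter_params(70, 70))) {
    out <- filter_records(rec, p)
    manual <- sum(
      rec$mapped &
        rec$percent_identity >= p$min_identity &
        100 * rec$aligned_length / rec$read_length >= p$min_aligned_pct,
      na.rm = TRUE
    )
    expect_equal(out$n_kept, manual)
    expect_equal(out$n_kept + out$n_failed + out$n_unmapped, nrow(rec))
  }
})

test_that("tightening any threshold never keeps more reads", {
  refs <- test_refs()
  rec <- make_records(300, refs, seed = 5)
  base <- filter_records(rec, filter_params(80, 50))$n_kept
  expect_lte(filter_records(rec, filter_params(86, 50))$n_kept, base)
  expect_lte(filter_records(rec, filter_params(80, 70))$n_kept, base)
})

test_that("records violating aligned_length <= read_length are rejected", {
  rec <- make_records(5, test_refs(), seed = 6, unmapped_frac = 0)
  rec$aligned_length[1] <- 200L
  expect_error(filter_records(rec, genome_mode_filters()), "aligned_length")
})

test_that("covered fraction uses interval union and matches per-base recount", {
  refs <- test_refs()
  one <- tibble::tibble(
    read_id = "r1", mapped = TRUE, ref_id = "gA1", ref_start = 1L,
    aligned_length = 500L, read_length = 500L, percent_identity = 100
  )
  expect_equal(covered_fraction(one, "gA1", refs), 50)
  # a duplicate read does not raise the union
  two <- dplyr::bind_rows(one, one |> dplyr::mutate(read_id = "r2"))
  expect_equal(covered_fraction(two, "gA1", refs), 50)
  expect_error(covered_fraction(one, "nope", refs), "Unknown")

  set.seed(7)
  for (case in 1:10) {
    rec <- make_records(80, refs, seed = case, unmapped_frac = 0)
    kept <- filter_records(rec, filter_params(0, 0))$kept
    for (r in refs$ref_id) {
      expect_equal(
        covered_fraction(kept, r, refs),
        covered_fraction_oracle(kept, r, refs$length_bp[refs$ref_id == r])
      )
    }
  }
})

test_that("relative abundance sums to 100 and handles edge corpora", {
  refs <- test_refs()
  # all reads on one category, none filtered
  rec <- tibble::tibble(
    read_id = sprintf("r%d", 1:10), mapped = TRUE, ref_id = "gB1",
    ref_start = 1L, aligned_length = 100L, read_length = 100L,
    percent_identity = 100
  )
  tab <- relative_abundance(rec, refs)
  expect_equal(tab$relative_abundance_pct[tab$category == "catB"], 100)
  expect_equal(tab$relative_abundance_pct[tab$category == "unmapped"], 0)

  # nothing maps
  none <- tibble::tibble(
    read_id = "r1", mapped = FALSE, ref_id = NA_character_,
    ref_start = NA_integer_, aligned_length = NA_integer_,
    read_length = 100L, percent_identity = NA_real_
  )
  tab0 <- relative_abundance(none, refs)
  expect_equal(tab0$relative_abundance_pct[tab0$category == "unmapped"], 100)
  expect_true(all(tab0$relative_abundance_pct[tab0$category != "unmapped"] == 0))

  set.seed(9)
  for (case in 1:10) {
    rec <- make_records(150, refs, seed = case + 20)
    tab <- relative_abundance(rec, refs)
    expect_equal(sum(tab$relative_abundance_pct), 100, tolerance = 1e-12)
    expect_true(all(tab$relative_abundance_pct >= 0))
  }
})

test_that("RPKM equals its closed form and respects the coverage gate", {
  refs <- reference_set("ref1", 1000, "catA")
  # 100 kept reads fully covering a 1 kb reference out of 100 total kept
  rec <- tibble::tibble(
    read_id = sprintf("r%d", 1:100), mapped = TRUE, ref_id = "ref1",
    ref_start = rep(c(1L, 501L), 50), aligned_length = 500L,
    read_length = 500L, percent_identity = 100
  )
  out <- rpkm(rec, refs, filter_params(86, 95, 55))
  expect_equal(out$rpkm, 100 / ((1000 / 1000) * (100 / 1e6)))
  expect_false(out$below_covered_threshold)

  # coverage below the 55% gate zeroes RPKM
  low <- rec |> dplyr::mutate(ref_start = 1L)
  out_low <- rpkm(low, refs, filter_params(86, 95, 55))
  expect_equal(out_low$covered_fraction_pct, 50)
  expect_true(out_low$below_covered_threshold)
  expect_equal(out_low$rpkm, 0)

  # no kept reads -> all zero with a warning
  none <- rec |> dplyr::mutate(percent_identity = 50)
  expect_warning(out0 <- rpkm(none, refs), "filters")
  expect_equal(out0$rpkm, 0)

  # random corpora match an independent closed-form recomputation
  refs2 <- test_refs()
  set.seed(10)
  for (case in 1:5) {
    rec <- make_records(200, refs2, seed = case + 40)
    p <- filter_params(70, 60, 0)
    out <- rpkm(rec, refs2, p)
    fl <- filter_records(rec, p)
    for (i in seq_len(nrow(out))) {
      k <- sum(fl$kept$ref_id == out$ref_id[i], na.rm = TRUE)
      len <- refs2$length_bp[refs2$ref_id == out$ref_id[i]]
      expect_equal(out$rpkm[i], k / ((len / 1000) * (fl$n_kept / 1e6)))
    }
  }
})

test_that("SAM round-trip reproduces simulated records", {
  refs <- test_refs() |> dplyr::mutate(length_bp = 2000)
  spec <- read_sim_spec(refs, c(catA = 0.6, catB = 0.4), n_reads = 200,
                        unmapped_fraction = 0.15, seed = 23)
  sim <- simulate_alignments(spec)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam_records(sim$records, refs, sam)
  back <- read_sam_records(sam)
  expect_equal(nrow(back), 200)
  orig <- sim$records |>
    dplyr::select(read_id, mapped, ref_id, ref_start, aligned_length,
                  read_length, percent_identity)
  back_sorted <- back[match(orig$read_id, back$read_id), ]
  expect_equal(back_sorted$mapped, orig$mapped)
  expect_equal(back_sorted$ref_id, orig$ref_id)
  expect_equal(back_sorted$ref_start, orig$ref_start)
  expect_equal(back_sorted$aligned_length[orig$mapped],
               orig$aligned_length[orig$mapped])
  expect_equal(back_sorted$percent_identity[orig$mapped],
               orig$percent_identity[orig$mapped], tolerance = 1e-9)
})

test_that("mapped SAM records without an edit-distance tag are rejected", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:ref1\tLN:1000",
    paste("r1", 0L, "ref1", 1L, 60L, "80M", "*", 0L, 0L,
          strrep("A", 80), "*", sep = "\t")
  ), sam)
  expect_error(read_sam_records(sam), "NM")
})
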