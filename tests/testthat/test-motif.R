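test_that("motif scans of the printed oligos find 2/3/4 GGAA sites", {
  wt_hits <- scan_ets(fx_wt)
  expect_equal(wt_hits$start, c(1295195, 1295200))
  mut_hits <- scan_ets(fx_g228a)
  expect_equal(nrow(mut_hits), 3)
  new_site <- setdiff(mut_hits$start, wt_hits$start)
  expect_true(mut_hits$ccggaa_context[mut_hits$start == new_site])
  expect_false(any(wt_hits$ccggaa_context))
  dup_hits <- scan_ets(fx_dup$sequence)
  expect_equal(nrow(dup_hits), 4)
})

test_that("N never matches and empty input yields an empty scan", {
  expect_equal(nrow(scan_ets("NNNN")), 0)
  expect_equal(nrow(scan_ets("GGANGGAA")), 1)
  expect_equal(nrow(scan_ets("")), 0)
})

test_that("scanning agrees with a naive all-positions oracle on random sequences", {
  for (seed in 1:10) {
    s <- rand_seq(300, seed + 100)
    expect_equal(scan_ets(s)$start, naive_scan(s))
  }
  # overlapping occurrences are all reported
  expect_equal(scan_ets("GGAAGGAAGGAA")$start, c(1, 5, 9))
})

test_that("both-strand scanning adds reverse-complement (TTCC) hits", {
  cfg <- phase_config(scan_strands = "both")
  hits <- scan_ets("TTCCAAGGAA", cfg)
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$strand, c("plus", "minus"))
  expect_equal(nrow(scan_ets("TTCCAA")), 0) # plus-only default
})

test_that("origin assignment separates native from de novo sites", {
  call <- duplication_from_region(fx_wt, fx_map, -100, -79)
  variant <- apply_insertion(fx_wt, as_insertion(call))
  sites <- assign_origin(fx_wt, variant, call)
  expect_equal(nrow(sites), 4)
  expect_equal(sum(sites$origin == "native"), 2)
  expect_equal(sum(sites$origin == "de_novo_copy"), 2)
  expect_setequal(sites$genomic[sites$origin == "native"], c(1295195, 1295200))
  # point substitution
  mut_sites <- assign_origin(fx_wt, fx_g228a$sequence, call = NULL)
  expect_equal(sum(mut_sites$origin == "native"), 2)
  expect_equal(sum(mut_sites$origin == "de_novo_point"), 1)
  # wild type: all native
  wt_sites <- assign_origin(fx_wt, fx_wt$sequence, call = NULL)
  expect_true(all(wt_sites$origin == "native"))
})

test_that("spacing arithmetic follows the 10.5-bp helical period", {
  s22 <- motif_spacing(0, 22)
  expect_equal(s22$d, 22)
  expect_equal(s22$nearest_turns, 2)
  expect_true(s22$in_phase)
  s21 <- motif_spacing(100, 121)
  expect_equal(s21$HT, 2)
  expect_equal(s21$phase_deviation, 0)
  s16 <- motif_spacing(0, 16)
  expect_equal(s16$HT, 16 / 10.5, tolerance = 1e-12)
  expect_false(s16$in_phase)
  expect_error(motif_spacing(5, 5), "degenerate")
  expect_error(motif_spacing(7, 3), "a.start < b.start")
})

test_that("phase deviation is invariant under full-turn shifts", {
  cfg <- phase_config()
  for (d in 1:40) {
    a <- motif_spacing(0, d, cfg)$phase_deviation
    b <- motif_spacing(0, d + cfg$P, cfg)$phase_deviation
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("every motif inside an exact duplication template gains a copy at insert-size distance", {
  t1 <- parse_cohort(tertdup_extdata("cohort_duplications.tsv"))
  exact <- unique(t1[t1$insert_size != 23 & t1$duplicated_region != "c.-125_-106",
    c("duplicated_region", "insert_size")])
  for (i in seq_len(nrow(exact))) {
    region <- parse_region_label(exact$duplicated_region[i])
    call <- duplication_from_region(fx_window, fx_map, region$c_up, region$c_down)
    variant <- apply_insertion(fx_window, as_insertion(call))
    sites <- assign_origin(fx_window, variant, call)
    pairs <- duplication_spacing(sites, call)
    expect_gt(nrow(pairs), 0)
    expect_true(all(pairs$d == exact$insert_size[i]))
  }
})
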