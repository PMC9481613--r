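test_that("the bundled cohort table parses to 21 records", {
  t1 <- parse_cohort(tertdup_extdata("cohort_duplications.tsv"))
  expect_equal(nrow(t1), 21)
  expect_equal(nrow(attr(t1, "errors")), 0)
})

test_that("an empty table and planted corruptions are handled row-wise", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  header <- paste(
    "duplicated_region", "duplicated_seq", "insert_size",
    "insert_pos_start", "insert_pos_end", "cancer_type",
    sep = "\t"
  )
  writeLines(header, tmp)
  expect_equal(nrow(parse_cohort(tmp)), 0)
  writeLines(c(
    header,
    "c.-100_-79\tGGGCGGGGCCGCGGAAAGGAAG\t22\t1295182\t1295183\tGlioblastoma",
    "c.-100_-79\tGGGC\t22\t1295182\t1295183\tGlioblastoma",
    "not_a_region\tGGGC\t4\t1295182\t1295183\tGlioblastoma"
  ), tmp)
  parsed <- parse_cohort(tmp)
  expect_equal(nrow(parsed), 1)
  errors <- attr(parsed, "errors")
  expect_equal(errors$row, c(2, 3))
  expect_match(errors$problem[1], "insert_size")
  expect_match(errors$problem[2], "malformed")
})

test_that("validation recomputes every printed insert position from the region alone", {
  t1 <- parse_cohort(tertdup_extdata("cohort_duplications.tsv"))
  val <- validate_cohort(t1, fx_window, fx_map)
  expect_true(all(val$covered))
  expect_true(all(val$agree_pos))
  expect_equal(val$breakpoint_start, t1$insert_pos_start)
  expect_equal(val$breakpoint_end, t1$insert_pos_end)
})

test_that("recomputed templates match the printed sequences for exact-copy records", {
  t1 <- parse_cohort(tertdup_extdata("cohort_duplications.tsv"))
  val <- validate_cohort(t1, fx_window, fx_map)
  exact <- t1$insert_size == nchar(t1$duplicated_seq) &
    t1$insert_size != 23 & t1$duplicated_region != "c.-125_-106"
  expect_true(all(val$agree_seq[exact]))
  expect_equal(val$template_len[t1$duplicated_region == "c.-120_-96"], c(25, 25))
})

test_that("ETS content: 20 of 21 templates carry ETS 200; the outlier copies the hotspot", {
  t1 <- parse_cohort(tertdup_extdata("cohort_duplications.tsv"))
  val <- validate_cohort(t1, fx_window, fx_map)
  expect_equal(sum(val$contains_ets200), 20)
  outlier <- val[!val$contains_ets200, ]
  expect_equal(outlier$duplicated_region, "c.-125_-106")
  expect_equal(outlier$source_template, "carries_hotspot")
  expect_equal(outlier$hotspot, "G228A")
  expect_true(all(val$source_template[val$duplicated_region != "c.-125_-106"] == "wildtype"))
})

test_that("cohort summary reports 7 normalized cancer types over 21-25 bp inserts", {
  t1 <- parse_cohort(tertdup_extdata("cohort_duplications.tsv"))
  sm <- summarize_cohort(t1)
  expect_equal(sm$n_samples, 21)
  expect_equal(sm$n_cancer_types, 7)
  expect_equal(sm$insert_size_range, c(21, 25))
  expect_equal(length(sm$unmapped), 0)
  one <- summarize_cohort(t1[1, , drop = FALSE])
  expect_equal(one$n_cancer_types, 1)
  expect_equal(one$insert_size_range, c(22, 22))
  # unmapped labels become their own type and are listed
  odd <- t1[1, , drop = FALSE]
  odd$cancer_type <- "Completely Novel Carcinoma"
  sm2 <- summarize_cohort(rbind(t1, odd))
  expect_equal(sm2$n_cancer_types, 8)
  expect_equal(sm2$unmapped, "Completely Novel Carcinoma")
})

test_that("the GGAA screen recovers planted counts and is order-invariant", {
  cfg <- sim_config(seed = 5)
  scr <- gen_insertion_screen(cfg)
  tab <- ggaa_screen(scr$insertions)
  sm <- attr(tab, "summary")
  expect_equal(sm$n_ggaa, 14)
  expect_equal(sm$n_ggaa_core, 13)
  expect_equal(sm$n_non_ggaa, 19)
  expect_equal(sm$n_ggaa + sm$n_non_ggaa, sm$n_total)
  shuffled <- scr$insertions[rev(seq_len(nrow(scr$insertions))), ]
  expect_equal(attr(ggaa_screen(shuffled), "summary"), sm)
})

test_that("screen boundaries are inclusive and out-of-window insertions are excluded", {
  ins <- data.frame(
    breakpoint_left = c(1295160, 1299000, 1299001, 1295159),
    inserted_seq = c("GGAAGG", "CCTCCT", "GGAAGG", "GGAAGG"),
    stringsAsFactors = FALSE
  )
  expect_message(tab <- ggaa_screen(ins), "excluded")
  expect_equal(nrow(tab), 2)
  expect_equal(nrow(attr(tab, "excluded")), 2)
  expect_equal(attr(tab, "summary")$n_excluded, 2)
})

test_that("strand option changes the class of a TTCC-only insertion", {
  ins <- data.frame(breakpoint_left = 1295190, inserted_seq = "TTCCTTCC")
  expect_false(ggaa_screen(ins)$ggaa_containing)
  expect_true(ggaa_screen(ins, scan_strands = "both")$ggaa_containing)
})
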