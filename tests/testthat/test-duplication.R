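test_that("applying the c.-100_-79 duplication reproduces the printed 82-nt oligo", {
  call <- duplication_from_region(fx_wt, fx_map, -100, -79)
  variant <- apply_insertion(fx_wt, as_insertion(call))
  expect_identical(variant, fx_dup$sequence)
  expect_equal(nchar(variant), 82)
})

test_that("insertions reject empty inserts and out-of-window breakpoints", {
  expect_error(insertion_variant(1295182, ""), "length >= 1")
  expect_error(
    apply_insertion(fx_wt, insertion_variant(1295300, "GGAA")),
    "outside reference window"
  )
})

test_that("equivalent windows yield byte-identical variant sequences", {
  a <- apply_insertion(fx_wt, as_insertion(duplication_from_region(fx_wt, fx_map, -105, -84)))
  b <- apply_insertion(fx_wt, as_insertion(duplication_from_region(fx_wt, fx_map, -106, -85)))
  expect_identical(a, b)
})

test_that("tandem duplications are detected from their insertion representation", {
  # exact 22-bp copy
  d <- detect_tandem_duplication(
    fx_wt, fx_map, insertion_variant(1295182, "GGGCGGGGCCGCGGAAAGGAAG")
  )
  expect_equal(c(d$template_c_up, d$template_c_down), c(-100, -79))
  expect_equal(d$insert_size, 22)
  expect_equal(nrow(d$nontemplated), 0)
  # copy plus one nontemplated junction base
  d23 <- detect_tandem_duplication(
    fx_wt, fx_map, insertion_variant(1295192, "GCGGAAAGGAAGGGGAGGGGCTA")
  )
  expect_equal(c(d23$template_c_up, d23$template_c_down), c(-110, -89))
  expect_equal(d23$insert_size, 23)
  expect_equal(d23$nontemplated$base, "A")
  # non-matching insert
  expect_null(detect_tandem_duplication(
    fx_wt, fx_map, insertion_variant(1295192, "ACGTACGTACGT")
  ))
})

test_that("a mutant-template duplication is recognized against the hotspot reference", {
  mut <- apply_hotspot(fx_window, fx_registry, "G228A")
  expect_equal(ref_subseq(mut, 1295228, 1295228), "A")
  d <- detect_tandem_duplication(
    fx_window, fx_map,
    insertion_variant(1295228, "GGGGCTGGGCTGGGAGGGCCCGGAA"),
    max_nontemplated = 6, mutant_refs = list(G228A = mut)
  )
  expect_equal(d$source_template, "carries_hotspot")
  expect_equal(d$hotspot, "G228A")
  # the detected template lies inside the annotated c.-125_-106 region and
  # its copy carries the hotspot-created motif
  expect_gte(d$template_genomic[1], 1295210)
  expect_lte(d$template_genomic[2], 1295229)
  expect_true(grepl("GGAA", d$inserted_seq, fixed = TRUE))
})

test_that("normalization left-aligns to the published canonical members and is idempotent", {
  call <- duplication_from_region(fx_window, fx_map, -90, -69)
  norm <- normalize_duplication(fx_window, call)
  expect_equal(c(norm$template_c_up, norm$template_c_down), c(-88, -67))
  expect_equal(
    normalize_duplication(fx_window, norm)[c("template_c_up", "template_c_down")],
    norm[c("template_c_up", "template_c_down")]
  )
  # already canonical stays put
  c100 <- duplication_from_region(fx_window, fx_map, -100, -79)
  expect_equal(normalize_duplication(fx_window, c100)$template_c_up, -100)
})

test_that("normalization is class-invariant and agrees with the string oracle", {
  for (w in list(c(-105, -84), c(-106, -85), c(-107, -86), c(-108, -87), c(-109, -88))) {
    norm <- normalize_duplication(
      fx_window, duplication_from_region(fx_window, fx_map, w[1], w[2])
    )
    expect_equal(c(norm$template_c_up, norm$template_c_down), c(-104, -83))
    expect_identical(
      oracle_variant(fx_window, fx_map, w[1], w[2]),
      oracle_variant(fx_window, fx_map, norm$template_c_up, norm$template_c_down)
    )
  }
})

test_that("equivalence classing matches the string-identity oracle on random references", {
  for (seed in 1:5) {
    ref <- promoter_reference(rand_seq(400, seed), 1295105, name = "rand")
    windows <- enumerate_windows(22, 220, 180)
    classes <- equivalence_classes(ref, fx_map, windows)
    # oracle: group by brute-force variant strings
    strings <- vapply(
      seq_len(nrow(windows)),
      function(i) oracle_variant(ref, fx_map, windows$c_up[i], windows$c_down[i]),
      character(1)
    )
    expect_equal(length(classes), length(unique(strings)))
    for (cl in classes) {
      member_strings <- vapply(
        seq_len(nrow(cl$members)),
        function(i) oracle_variant(ref, fx_map, cl$members$c_up[i], cl$members$c_down[i]),
        character(1)
      )
      expect_equal(length(unique(member_strings)), 1L)
      expect_identical(member_strings[1], cl$variant_seq)
      expect_equal(abs(cl$canonical[1]), min(abs(cl$members$c_up)))
    }
    # partition: disjoint and covering
    all_members <- do.call(rbind, lapply(classes, `[[`, "members"))
    expect_equal(nrow(all_members), nrow(windows))
    expect_equal(anyDuplicated(all_members), 0L)
  }
})

test_that("windows over a non-repetitive sequence form only singleton classes", {
  # period-4 alphabet rotation: no base ever equals its neighbor 22 apart
  base <- paste(rep(c("A", "C", "G", "T"), length.out = 120), collapse = "")
  ref <- promoter_reference(base, 1295105, name = "rot")
  windows <- enumerate_windows(22, 110, 90)
  classes <- equivalence_classes(ref, fx_map, windows)
  expect_equal(length(classes), nrow(windows))
})

test_that("detection recovers planted synthetic duplications exactly", {
  cfg <- sim_config(seed = 11, ref_length = 2000)
  ref <- gen_reference(cfg, start_genomic = 1295105)
  set.seed(42)
  for (i in 1:25) {
    len <- sample(10:40, 1)
    lo <- sample(seq(ref$start_genomic + len + 2L, ref_end(ref) - len - 2L), 1)
    hi <- lo + len - 1L
    template <- ref_subseq(ref, lo, hi)
    var <- insertion_variant(lo - 1L, template)
    d <- detect_tandem_duplication(ref, fx_map, var)
    expect_false(is.null(d))
    # the detected (left-aligned) call must reproduce the same variant string
    expect_identical(
      apply_insertion(ref, as_insertion(d)),
      apply_insertion(ref, var)
    )
    expect_equal(d$insert_size, len)
  }
})

test_that("detection round-trips every wild-type cohort record", {
  t1 <- parse_cohort(tertdup_extdata("cohort_duplications.tsv"))
  wt_rows <- t1[t1$duplicated_region != "c.-125_-106", ]
  for (i in seq_len(nrow(wt_rows))) {
    var <- insertion_variant(wt_rows$insert_pos_start[i], wt_rows$duplicated_seq[i])
    d <- detect_tandem_duplication(fx_window, fx_map, var)
    expect_false(is.null(d))
    region <- parse_region_label(wt_rows$duplicated_region[i])
    # equivalent left-alignments allowed; the variant string must agree
    expect_identical(
      apply_insertion(fx_window, as_insertion(d)),
      apply_insertion(fx_window, var)
    )
    expect_equal(d$insert_size, wt_rows$insert_size[i])
  }
})

test_that("variant digests separate distinct sequences and match on equal ones", {
  expect_identical(variant_digest("ACGT"), variant_digest("ACGT"))
  expect_false(variant_digest("ACGT") == variant_digest("ACGA"))
})
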