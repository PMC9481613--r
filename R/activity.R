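#' Classify a promoter variant's activation potential
#'
#' Ordinal classifier encoding the empirical activation rules for TERT core
#' promoter variants:
#'
#' * without GABPA (`gabpa_present = FALSE`) every construct is `baseline` --
#'   knockdown of the GABP DNA-binding subunit collapses all ETS-driven
#'   activation to wild-type levels;
#' * registered hotspot point variants are `active`;
#' * a duplication whose template fully contains the native ETS 200 motif and
#'   whose copy spacing is in helical phase is `active` at ~2 turns and
#'   `partial` at >= 3 turns (in-phase 3-turn constructs recover activity
#'   only partially);
#' * duplications copying only ETS 195, copying no motif, or placing the copy
#'   off phase are `baseline`.
#'
#' @param variant a [duplication_call()], or a registry hotspot name.
#' @param sites origin-annotated motif sites of the variant sequence from
#'   [assign_origin()] (required for duplication calls).
#' @param cfg a [phase_config()].
#' @param gabpa_present is the GABP complex available (default `TRUE`).
#' @param registry a [motif_registry()].
#' @param id construct identifier (defaults to the region label / hotspot name).
#' @return a list of class `activity_call`: `id`, `klass` (`baseline`,
#'   `partial`, `active`), `reasons`, `gabpa_present`.
#' @export
classify_activity <- function(variant, sites = NULL, cfg = phase_config(),
                              gabpa_present = TRUE, registry = motif_registry(),
                              id = NULL) {
  if (is.character(variant)) {
    if (!variant %in% registry$hotspot_variants$name) {
      stop("unknown hotspot variant: ", variant)
    }
    id <- id %||% variant
    if (!gabpa_present) {
      return(activity_call(id, "baseline", "gabpa_absent", gabpa_present))
    }
    return(activity_call(id, "active", "hotspot_site", gabpa_present))
  }
  stopifnot(inherits(variant, "duplication_call"))
  id <- id %||% region_label(variant$template_c_up, variant$template_c_down)
  if (!gabpa_present) {
    return(activity_call(id, "baseline", "gabpa_absent", gabpa_present))
  }
  if (is.null(sites)) stop("classify_activity needs the variant's motif report (sites)")
  contains <- template_contains_sites(variant, registry)
  if (!any(contains)) {
    return(activity_call(id, "baseline", "no_de_novo_ets", gabpa_present))
  }
  if (!contains["ETS 200"]) {
    return(activity_call(id, "baseline", "contains_ETS195_only", gabpa_present))
  }
  # spacing between the ETS 200 copy and its native counterpart
  pairs <- duplication_spacing(sites, variant, cfg)
  ets200 <- registry$native_sites$start[registry$native_sites$name == "ETS 200"]
  pair <- pairs[!is.na(pairs$native_genomic) & pairs$native_genomic == ets200, , drop = FALSE]
  if (nrow(pair) != 1L) {
    # fall back to the tandem-duplication identity d = insert size
    sp <- motif_spacing(0L, variant$insert_size, cfg)
  } else {
    sp <- motif_spacing(pair$copy_start, pair$native_start, cfg)
  }
  if (!sp$in_phase) {
    return(activity_call(id, "baseline", c("contains_ETS200_copy", "off_phase"), gabpa_present))
  }
  if (sp$nearest_turns == 2L) {
    activity_call(id, "active", c("contains_ETS200_copy", "in_phase_2HT"), gabpa_present)
  } else {
    activity_call(id, "partial", c("contains_ETS200_copy", "in_phase_3HT"), gabpa_present)
  }
}

activity_call <- function(id, klass, reasons, gabpa_present) {
  structure(
    list(id = id, klass = klass, reasons = reasons, gabpa_present = gabpa_present),
    class = "activity_call"
  )
}

#' @export
print.activity_call <- function(x, ...) {
  cat(
    "<activity_call> ", x$id, ": ", x$klass,
    " (", paste(x$reasons, collapse = ", "), ")",
    if (!x$gabpa_present) " [GABPA absent]", "\n",
    sep = ""
  )
  invisible(x)
}

# which registry native sites are fully contained in the duplicated template
template_contains_sites <- function(call, registry) {
  sites <- registry$native_sites
  contained <- sites$start >= call$template_genomic[1] &
    sites$end <= call$template_genomic[2]
  stats::setNames(contained, sites$name)
}

#' Spacing scan: perturb the distance between the duplicated and native motif
#'
#' Starting from a duplication construct, inserts (positive `delta`) neutral
#' C bases or deletes (negative `delta`) bases immediately 3' of the
#' duplicated ETS 200 copy, so that the copy-to-native start distance becomes
#' `insert_size + delta`, then rescans the edited sequence and classifies its
#' activity. This reproduces the engineered spacer series: full activity at
#' ~2 turns, loss off phase, partial recovery at ~3 turns.
#'
#' @param ref a [promoter_reference()].
#' @param call a [duplication_call()] whose template contains ETS 200.
#' @param deltas integer vector of spacing offsets in bp.
#' @param cfg a [phase_config()].
#' @param registry a [motif_registry()].
#' @return data.frame with columns `delta`, `d`, `HT`, `nearest_turns`,
#'   `phase_deviation`, `in_phase`, `klass`.
#' @export
spacing_scan <- function(ref, call, deltas, cfg = phase_config(),
                         registry = motif_registry()) {
  stopifnot(inherits(call, "duplication_call"))
  base_variant <- apply_insertion(ref, as_insertion(call))
  sites <- assign_origin(ref, base_variant, call, cfg)
  pairs <- duplication_spacing(sites, call, cfg)
  ets200 <- registry$native_sites$start[registry$native_sites$name == "ETS 200"]
  pair <- pairs[!is.na(pairs$native_genomic) & pairs$native_genomic == ets200, , drop = FALSE]
  if (nrow(pair) != 1L) stop("spacing_scan needs a duplication copying ETS 200")
  copy_end <- pair$copy_start + nchar(cfg$pattern) - 1L
  spacer_len <- pair$native_start - copy_end - 1L
  rows <- lapply(as.integer(deltas), function(delta) {
    d_new <- pair$d + delta
    if (d_new <= 0L) {
      stop("degenerate construct: delta ", delta, " gives non-positive spacing")
    }
    if (delta < 0L && -delta > spacer_len) {
      stop(
        "delta ", delta, " would remove motif bases (only ", spacer_len,
        " spacer bases between the copies)"
      )
    }
    edited <- if (delta >= 0L) {
      paste0(
        substr(base_variant, 1L, copy_end),
        strrep("C", delta),
        substring(base_variant, copy_end + 1L)
      )
    } else {
      paste0(
        substr(base_variant, 1L, copy_end),
        substring(base_variant, copy_end + 1L - delta)
      )
    }
    hits <- scan_ets(edited, cfg)
    copy_hit <- hits$start[hits$start == pair$copy_start]
    native_hit <- hits$start[hits$start == pair$native_start + delta]
    if (length(copy_hit) != 1L || length(native_hit) != 1L) {
      stop("spacing edit disturbed the motif pair at delta ", delta)
    }
    sp <- motif_spacing(copy_hit, native_hit, cfg)
    klass <- if (!sp$in_phase) {
      "baseline"
    } else if (sp$nearest_turns == 2L) "active" else "partial"
    data.frame(
      delta = delta, d = sp$d, HT = sp$HT, nearest_turns = sp$nearest_turns,
      phase_deviation = sp$phase_deviation, in_phase = sp$in_phase, klass = klass,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Simulate a dual-luciferase reporter readout
#'
#' Draws per-replicate firefly/renilla ratios around ordinal class means
#' (arbitrary units) with multiplicative lognormal noise, mirroring the shape
#' of a normalized dual-reporter assay. The lognormal draw is mean-corrected
#' so the expected ratio equals the class mean; with `sd = 0` the ratio is
#' exactly the class mean.
#'
#' @param calls list of `activity_call`s (or a character vector of classes).
#' @param n_replicates replicates per construct (>= 1).
#' @param seed RNG seed.
#' @param means named class means in arbitrary units.
#' @param sd lognormal noise standard deviation (log scale), default 0.2.
#' @return data.frame with columns `construct`, `klass`, `replicate`,
#'   `firefly`, `renilla`, `ratio`.
#' @export
simulate_reporter <- function(calls, n_replicates = 3L, seed = 1L,
                              means = c(baseline = 1, partial = 3, active = 10),
                              sd = 0.2) {
  stopifnot(n_replicates >= 1L)
  if (is.character(calls)) {
    klass <- unname(calls)
    ids <- unname(names(calls) %||% paste0("construct_", seq_along(calls)))
  } else {
    klass <- vapply(calls, function(x) x$klass, character(1))
    ids <- vapply(calls, function(x) x$id, character(1))
  }
  stopifnot(all(klass %in% names(means)))
  set.seed(as.integer(seed))
  rows <- lapply(seq_along(klass), function(i) {
    mu <- means[[klass[i]]]
    noise <- exp(stats::rnorm(n_replicates, mean = -sd^2 / 2, sd = sd))
    renilla <- exp(stats::rnorm(n_replicates, mean = -sd^2 / 2, sd = sd))
    ratio <- mu * noise
    data.frame(
      construct = ids[i], klass = klass[i], replicate = seq_len(n_replicates),
      firefly = ratio * renilla, renilla = renilla, ratio = ratio,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
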