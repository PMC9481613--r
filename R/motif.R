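#' Helical-phase configuration for ETS motif analysis
#'
#' @param P helical periodicity in bp per turn (default 10.5).
#' @param tol phase tolerance in turns (default 0.15): two motifs are "in
#'   phase" when their start-to-start distance is within `tol` turns of an
#'   integer number of turns. The default classifies the recurrent 22-bp
#'   spacing (deviation 0.095 turns) and a ~30-bp / 3-turn spacing (deviation
#'   0.143) as in phase while mid-phase spacings such as 26 bp (deviation
#'   0.476) are not.
#' @param scan_strands `"plus"` (default) scans the stored strand only;
#'   `"both"` also reports reverse-complement (TTCC) matches.
#' @param pattern motif core, default `"GGAA"`.
#' @return An object of class `phase_config`.
#' @export
phase_config <- function(P = 10.5, tol = 0.15,
                         scan_strands = c("plus", "both"), pattern = "GGAA") {
  scan_strands <- match.arg(scan_strands)
  stopifnot(P > 0, tol > 0, tol < 0.5)
  structure(
    list(P = P, tol = tol, scan_strands = scan_strands, pattern = toupper(pattern)),
    class = "phase_config"
  )
}

#' Scan a sequence for ETS core motifs
#'
#' Reports every occurrence of the motif core (default GGAA) left to right,
#' overlapping occurrences included; `N` never matches. Each plus-strand hit
#' is annotated with whether it sits in the extended CCGGAA consensus context
#' created by the hotspot mutations (i.e. is directly preceded by CC).
#'
#' @param seq DNA string, or a [promoter_reference()] (whose genomic anchor is
#'   then used for the `start` column).
#' @param cfg a [phase_config()].
#' @return data.frame with columns `start` (1-based within `seq`, or genomic
#'   when `seq` is a reference window), `strand`, `pattern`, `ccggaa_context`.
#' @export
scan_ets <- function(seq, cfg = phase_config()) {
  offset <- 0L
  if (inherits(seq, "promoter_reference")) {
    offset <- seq$start_genomic - 1L
    seq <- seq$sequence
  }
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) {
    return(empty_sites_df())
  }
  subject <- Biostrings::DNAString(seq)
  hit_df <- function(pattern, strand) {
    hits <- Biostrings::matchPattern(pattern, subject, fixed = TRUE)
    starts <- Biostrings::start(hits)
    if (!length(starts)) {
      return(empty_sites_df())
    }
    ctx <- vapply(starts, function(s) {
      s >= 3L && substr(seq, s - 2L, s + nchar(pattern) - 1L) ==
        paste0("CC", pattern)
    }, logical(1))
    data.frame(
      start = starts + offset,
      strand = strand,
      pattern = pattern,
      ccggaa_context = if (strand == "plus") ctx else FALSE,
      stringsAsFactors = FALSE
    )
  }
  out <- hit_df(cfg$pattern, "plus")
  if (cfg$scan_strands == "both") {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cfg$pattern)))
    out <- rbind(out, hit_df(rc, "minus"))
  }
  out[order(out$start), , drop = FALSE]
}

empty_sites_df <- function() {
  data.frame(
    start = integer(), strand = character(), pattern = character(),
    ccggaa_context = logical(), stringsAsFactors = FALSE
  )
}

#' Assign native / de novo origin to motif sites on a variant sequence
#'
#' Projects each motif occurrence on the variant sequence back onto the
#' reference frame. Sites that project onto a motif present in the reference
#' are `native`; sites falling inside a duplication insert are
#' `de_novo_copy`; remaining sites (created by point substitution) are
#' `de_novo_point`.
#'
#' @param ref the [promoter_reference()] the variant was built from.
#' @param variant_seq variant sequence (from [apply_insertion()] for
#'   duplications, or the mutated window from [apply_hotspot()]).
#' @param call the [duplication_call()] that produced the variant, or `NULL`
#'   for same-length substitution variants.
#' @param cfg a [phase_config()].
#' @return data.frame of sites with columns `start` (variant frame),
#'   `genomic` (projected reference coordinate, `NA` inside an insert),
#'   `strand`, `pattern`, `ccggaa_context`, `origin`.
#' @export
assign_origin <- function(ref, variant_seq, call = NULL, cfg = phase_config()) {
  ref_sites <- scan_ets(ref$sequence, cfg)
  var_sites <- scan_ets(variant_seq, cfg)
  expected_len <- nchar(ref$sequence) + if (is.null(call)) 0L else call$insert_size
  if (nchar(variant_seq) != expected_len) {
    stop(
      "variant sequence length ", nchar(variant_seq),
      " inconsistent with reference (", nchar(ref$sequence), " bp) and call"
    )
  }
  if (is.null(call)) {
    ins_after <- Inf
    ins_len <- 0L
  } else {
    ins_after <- call$breakpoint[1] - ref$start_genomic + 1L # last ref position before insert
    ins_len <- call$insert_size
  }
  project <- function(v) {
    if (v <= ins_after) {
      return(v)
    }
    if (v > ins_after + ins_len) {
      return(v - ins_len)
    }
    NA_integer_ # inside the insert
  }
  proj <- vapply(var_sites$start, project, numeric(1))
  origin <- ifelse(
    is.na(proj), "de_novo_copy",
    ifelse(proj %in% ref_sites$start, "native", "de_novo_point")
  )
  var_sites$genomic <- ifelse(is.na(proj), NA_integer_, ref$start_genomic + proj - 1L)
  var_sites$origin <- origin
  n_de_novo <- sum(origin != "native")
  if (nrow(var_sites) != nrow(ref_sites) + n_de_novo) {
    stop(
      "origin projection inconsistent: ", nrow(var_sites), " variant sites != ",
      nrow(ref_sites), " reference sites + ", n_de_novo, " de novo"
    )
  }
  var_sites[, c("start", "genomic", "strand", "pattern", "ccggaa_context", "origin")]
}

#' Spacing between two motif sites in bp and helical turns
#'
#' @param a,b motif start coordinates in the same frame (`a < b`), or
#'   single-row site data.frames from [scan_ets()].
#' @param cfg a [phase_config()].
#' @return a list of class `spacing_result`: `d` (start-to-start bp), `HT`
#'   (`d / P` helical turns), `nearest_turns`, `phase_deviation` (turns,
#'   in `[0, 0.5]`), `in_phase`.
#' @examples
#' motif_spacing(1295200, 1295222) # the recurrent 22-bp duplication spacing
#' @export
motif_spacing <- function(a, b, cfg = phase_config()) {
  if (is.data.frame(a)) a <- a$start
  if (is.data.frame(b)) b <- b$start
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (a == b) stop("degenerate motif pair: equal start coordinates")
  if (a > b) stop("motif_spacing expects a.start < b.start")
  d <- b - a
  ht <- d / cfg$P
  nearest <- round(ht)
  dev <- abs(ht - nearest)
  structure(
    list(
      d = as.integer(d), HT = ht, P = cfg$P, nearest_turns = as.integer(nearest),
      phase_deviation = dev, in_phase = dev <= cfg$tol
    ),
    class = "spacing_result"
  )
}

#' @export
print.spacing_result <- function(x, ...) {
  cat(sprintf(
    "<spacing> d = %d bp, HT = %.3f (P = %g), nearest %d turns, deviation %.3f -> %s\n",
    x$d, x$HT, x$P, x$nearest_turns, x$phase_deviation,
    if (x$in_phase) "in phase" else "off phase"
  ))
  invisible(x)
}

#' Spacing between each duplicated motif copy and its native counterpart
#'
#' For an exact tandem duplication every motif inside the template gains a
#' copy at start-to-start distance equal to the insert size; this pairs each
#' `de_novo_copy` site with the corresponding `native` site and reports the
#' spacing for each pair.
#'
#' @param sites origin-annotated sites from [assign_origin()].
#' @param call the [duplication_call()].
#' @param cfg a [phase_config()].
#' @return data.frame with one row per copied motif: `copy_start`,
#'   `native_start`, `native_genomic`, `d`, `HT`, `nearest_turns`,
#'   `phase_deviation`, `in_phase`.
#' @export
duplication_spacing <- function(sites, call, cfg = phase_config()) {
  copies <- sites[sites$origin == "de_novo_copy", , drop = FALSE]
  natives <- sites[sites$origin == "native", , drop = FALSE]
  rows <- lapply(copies$start, function(v) {
    partner <- natives[natives$start == v + call$insert_size, , drop = FALSE]
    if (nrow(partner) != 1L) {
      return(NULL)
    }
    sp <- motif_spacing(v, partner$start, cfg)
    data.frame(
      copy_start = v, native_start = partner$start,
      native_genomic = partner$genomic,
      d = sp$d, HT = sp$HT, nearest_turns = sp$nearest_turns,
      phase_deviation = sp$phase_deviation, in_phase = sp$in_phase
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      copy_start = integer(), native_start = integer(), native_genomic = integer(),
      d = integer(), HT = numeric(), nearest_turns = integer(),
      phase_deviation = numeric(), in_phase = logical()
    )
  }
  out
}
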