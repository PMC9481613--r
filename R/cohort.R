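#' Parse a cohort duplication table
#'
#' Reads a TSV in the cohort schema (`duplicated_region`, `duplicated_seq`,
#' `insert_size`, `insert_pos_start`, `insert_pos_end`, `other_ets_variants`,
#' `age`, `race`, `sex`, `cancer_type`, `tumor_type`, `dataset`). Rows whose
#' insert size disagrees with the printed sequence length, or whose region
#' label is malformed, are collected into an error report attached as
#' `attr(, "errors")` rather than silently dropped.
#'
#' @param path TSV file.
#' @return data.frame of valid records; malformed rows in `attr(, "errors")`.
#' @export
parse_cohort <- function(path) {
  required <- c(
    "duplicated_region", "duplicated_seq", "insert_size",
    "insert_pos_start", "insert_pos_end", "cancer_type"
  )
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cohort table missing column(s): ", paste(missing, collapse = ", "))
  }
  problems <- character(nrow(df))
  seq_len_ok <- nchar(df$duplicated_seq) == df$insert_size
  problems[!seq_len_ok] <- "insert_size != nchar(duplicated_seq)"
  region_ok <- grepl("^c\\.-[0-9]+_-[0-9]+$", df$duplicated_region)
  problems[!region_ok] <- paste0(
    problems[!region_ok],
    ifelse(nzchar(problems[!region_ok]), "; ", ""), "malformed duplicated_region"
  )
  pos_ok <- !is.na(df$insert_pos_start) & !is.na(df$insert_pos_end) &
    df$insert_pos_end == df$insert_pos_start + 1L
  problems[!pos_ok] <- paste0(
    problems[!pos_ok],
    ifelse(nzchar(problems[!pos_ok]), "; ", ""),
    "insert_pos_end != insert_pos_start + 1"
  )
  ok <- !nzchar(problems)
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "errors") <- data.frame(
    row = which(!ok),
    duplicated_region = df$duplicated_region[!ok],
    problem = problems[!ok],
    stringsAsFactors = FALSE
  )
  out
}

#' Recompute and cross-check cohort duplication records against the reference
#'
#' For every record the duplicated region c.-X_-Y is re-anchored on the
#' reference: the template sequence is re-extracted, the insertion breakpoint
#' recomputed, and the ETS content (full ETS 200 / ETS 195 containment,
#' hotspot copy) determined, then compared against the printed columns.
#'
#' Templates are first read from the wild-type reference; when the printed
#' sequence fits a hotspot-substituted template better (by edit distance) and
#' the region overlaps that hotspot, the record is flagged
#' `source_template = "carries_hotspot"`. For wild-type templates the
#' breakpoint is the left-aligned pair flanking the template's ATG-proximal
#' end; hotspot-copy records are anchored at the template's upstream end,
#' where their source call places the insertion against the hotspot base.
#'
#' @param records data.frame from [parse_cohort()].
#' @param ref a [promoter_reference()] covering the templates.
#' @param map a [coordinate_map()].
#' @param registry a [motif_registry()].
#' @return data.frame with one row per record: recomputed template,
#'   breakpoints, ETS flags and agreement columns.
#' @export
validate_cohort <- function(records, ref, map, registry = motif_registry()) {
  regions <- parse_region_label(records$duplicated_region)
  mutant_refs <- lapply(
    stats::setNames(nm = registry$hotspot_variants$name),
    function(h) try(apply_hotspot(ref, registry, h), silent = TRUE)
  )
  mutant_refs <- Filter(function(x) !inherits(x, "try-error"), mutant_refs)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    c_up <- regions$c_up[i]
    c_down <- regions$c_down[i]
    lo <- c_to_genomic(map, c_down)
    hi <- c_to_genomic(map, c_up)
    if (lo < ref$start_genomic || hi > ref_end(ref)) {
      return(data.frame(
        duplicated_region = records$duplicated_region[i],
        covered = FALSE, template = NA_character_, template_len = NA_integer_,
        source_template = NA_character_, hotspot = NA_character_,
        breakpoint_start = NA_integer_, breakpoint_end = NA_integer_,
        contains_ets200 = NA, contains_ets195 = NA,
        agree_seq = NA, agree_size = NA, agree_pos = NA,
        stringsAsFactors = FALSE
      ))
    }
    wt_template <- ref_subseq(ref, lo, hi)
    printed <- records$duplicated_seq[i]
    source_template <- "wildtype"
    hotspot <- NA_character_
    template <- wt_template
    if (printed != wt_template) {
      # does a hotspot-substituted template explain the printed copy better?
      overlapping <- registry$hotspot_variants$name[
        registry$hotspot_variants$start >= lo & registry$hotspot_variants$start <= hi
      ]
      for (h in intersect(overlapping, names(mutant_refs))) {
        mut_template <- ref_subseq(mutant_refs[[h]], lo, hi)
        if (utils::adist(printed, mut_template) < utils::adist(printed, wt_template)) {
          source_template <- "carries_hotspot"
          hotspot <- h
          template <- mut_template
          break
        }
      }
    }
    bp <- if (source_template == "carries_hotspot") c(hi - 1L, hi) else c(lo - 1L, lo)
    s200 <- registry$native_sites[registry$native_sites$name == "ETS 200", ]
    s195 <- registry$native_sites[registry$native_sites$name == "ETS 195", ]
    contains <- c(
      ets200 = s200$start >= lo & s200$end <= hi,
      ets195 = s195$start >= lo & s195$end <= hi
    )
    data.frame(
      duplicated_region = records$duplicated_region[i],
      covered = TRUE, template = template, template_len = nchar(template),
      source_template = source_template, hotspot = hotspot,
      breakpoint_start = bp[1], breakpoint_end = bp[2],
      contains_ets200 = unname(contains["ets200"]),
      contains_ets195 = unname(contains["ets195"]),
      agree_seq = printed == template,
      agree_size = records$insert_size[i] == nchar(printed),
      agree_pos = records$insert_pos_start[i] == bp[1] &
        records$insert_pos_end[i] == bp[2],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Default cancer-type normalization map
#'
#' Collapses the raw cohort labels into the normalized tumor-type groups used
#' for cohort summaries (squamous carcinomas of oral cavity/oropharynx
#' together; papillary with poorly differentiated thyroid cancer together).
#' Override by passing any named character vector `raw -> normalized` to
#' [summarize_cohort()].
#'
#' @return named character vector.
#' @export
default_cancer_type_map <- function() {
  c(
    "Glioblastoma Multiforme" = "Glioblastoma",
    "Squamous Cell Carcinoma" = "Squamous Cell Carcinoma",
    "Oral Cavity Squamous Cell Carcinoma" = "Squamous Cell Carcinoma",
    "Duodenal Adenocarcinoma" = "Duodenal Adenocarcinoma",
    "Bladder Urothelial Carcinoma" = "Bladder Urothelial Carcinoma",
    "Hepatocellular Carcinoma" = "Hepatocellular Carcinoma",
    "Papillary Thyroid Cancer" = "Thyroid Cancer",
    "Poorly Differentiated Thyroid Cancer" = "Thyroid Cancer",
    "Malignant Phyllodes Tumor of the Breast" = "Malignant Phyllodes Tumor of the Breast"
  )
}

#' Summarize a cohort duplication table
#'
#' @param records data.frame from [parse_cohort()].
#' @param grouping_map named character vector mapping raw cancer-type labels
#'   to normalized types; unmapped labels are kept as their own type and
#'   listed under `unmapped`.
#' @return list: `n_samples`, `n_cancer_types`, `type_counts`,
#'   `insert_size_range`, `sex_counts`, `dataset_counts`, `unmapped`.
#' @export
summarize_cohort <- function(records, grouping_map = default_cancer_type_map()) {
  raw <- records$cancer_type
  normalized <- ifelse(raw %in% names(grouping_map), grouping_map[raw], raw)
  unmapped <- sort(unique(raw[!raw %in% names(grouping_map)]))
  list(
    n_samples = nrow(records),
    n_cancer_types = length(unique(normalized)),
    type_counts = sort(table(normalized), decreasing = TRUE),
    insert_size_range = range(records$insert_size),
    sex_counts = table(records$sex, useNA = "ifany"),
    dataset_counts = if ("dataset" %in% names(records)) table(records$dataset) else NULL,
    unmapped = unmapped
  )
}

#' Screen-window configuration for the GGAA insertion screen
#'
#' @param screen_window genomic interval screened for insertions (default the
#'   4-kb region upstream of TERT, chr5:1295160-1299000).
#' @param core_adjacent_window genomic interval adjacent to the native ETS
#'   cassette (default chr5:1295180-1295199).
#' @param pattern motif core (default GGAA).
#' @param length_band inclusive bp band counted as "approximately 22 bp"
#'   (default 20-25).
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(screen_window = c(1295160L, 1299000L),
                          core_adjacent_window = c(1295180L, 1295199L),
                          pattern = "GGAA", length_band = c(20L, 25L)) {
  stopifnot(
    screen_window[1] <= screen_window[2],
    core_adjacent_window[1] <= core_adjacent_window[2],
    length_band[1] <= length_band[2]
  )
  structure(
    list(
      screen_window = as.integer(screen_window),
      core_adjacent_window = as.integer(core_adjacent_window),
      pattern = toupper(pattern), length_band = as.integer(length_band)
    ),
    class = "screen_config"
  )
}

#' Screen insertion variants for GGAA content and core-promoter localization
#'
#' Classifies each insertion by (i) whether its inserted sequence contains
#' the motif core, (ii) whether its breakpoint localizes to the core promoter
#' -- operationally, within the core-adjacent window extended by the insert
#' length on either side, since an insertion of a core-promoter template can
#' be anchored up to one template length away -- and (iii) whether its length
#' falls in the "approximately 22 bp" band. Insertions outside the screen
#' window are excluded (boundary-inclusive) and reported.
#'
#' @param insertions list of [insertion_variant()]s, or a data.frame with
#'   columns `breakpoint_left` and `inserted_seq`.
#' @param cfg a [screen_config()].
#' @param scan_strands `"plus"` (default) or `"both"` (also counts TTCC).
#' @return data.frame with one row per in-window insertion; excluded
#'   insertions in `attr(, "excluded")`; class counts in `attr(, "summary")`.
#' @export
ggaa_screen <- function(insertions, cfg = screen_config(),
                        scan_strands = c("plus", "both")) {
  scan_strands <- match.arg(scan_strands)
  if (is.data.frame(insertions)) {
    df <- insertions[, c("breakpoint_left", "inserted_seq")]
  } else {
    df <- data.frame(
      breakpoint_left = vapply(insertions, function(v) v$breakpoint_left, integer(1)),
      inserted_seq = vapply(insertions, function(v) v$inserted_seq, character(1)),
      stringsAsFactors = FALSE
    )
  }
  in_window <- df$breakpoint_left >= cfg$screen_window[1] &
    df$breakpoint_left <= cfg$screen_window[2]
  excluded <- df[!in_window, , drop = FALSE]
  if (nrow(excluded)) {
    message(
      nrow(excluded), " insertion(s) outside screen window ",
      cfg$screen_window[1], "-", cfg$screen_window[2], " excluded"
    )
  }
  df <- df[in_window, , drop = FALSE]
  len <- nchar(df$inserted_seq)
  has_motif <- grepl(cfg$pattern, df$inserted_seq, fixed = TRUE)
  if (scan_strands == "both") {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cfg$pattern)))
    has_motif <- has_motif | grepl(rc, df$inserted_seq, fixed = TRUE)
  }
  core_localized <- df$breakpoint_left >= cfg$core_adjacent_window[1] - len &
    df$breakpoint_left <= cfg$core_adjacent_window[2] + len
  out <- data.frame(
    breakpoint_left = df$breakpoint_left,
    insert_length = len,
    ggaa_containing = has_motif,
    core_localized = core_localized,
    in_length_band = len >= cfg$length_band[1] & len <= cfg$length_band[2],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "summary") <- list(
    n_total = nrow(out),
    n_ggaa = sum(has_motif),
    n_ggaa_core = sum(has_motif & core_localized),
    n_non_ggaa = sum(!has_motif),
    n_excluded = nrow(excluded)
  )
  out
}
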