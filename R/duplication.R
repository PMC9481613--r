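#' Insertion variant
#'
#' An insertion is anchored by the genomic coordinate of the base immediately
#' 5' (lower coordinate) of the inserted sequence, matching the two adjacent
#' "insert position" coordinates cohort tables print: the insertion sits
#' between `breakpoint_left` and `breakpoint_left + 1`.
#'
#' @param breakpoint_left genomic coordinate of the base 5' of the insertion.
#' @param inserted_seq inserted DNA string (length >= 1).
#' @param provenance free-text source annotation.
#' @return An object of class `insertion_variant`.
#' @export
insertion_variant <- function(breakpoint_left, inserted_seq, provenance = "") {
  inserted_seq <- toupper(as.character(inserted_seq))
  if (!nzchar(inserted_seq)) stop("inserted_seq must have length >= 1")
  if (grepl("[^ACGTN]", inserted_seq)) stop("inserted_seq contains non-DNA characters")
  structure(
    list(
      breakpoint_left = as.integer(breakpoint_left),
      inserted_seq = inserted_seq,
      provenance = provenance
    ),
    class = "insertion_variant"
  )
}

#' Apply an insertion to a reference window
#'
#' @param ref a [promoter_reference()].
#' @param var an [insertion_variant()].
#' @return the variant sequence (reference with the insertion placed between
#'   `breakpoint_left` and `breakpoint_left + 1`).
#' @export
apply_insertion <- function(ref, var) {
  stopifnot(inherits(ref, "promoter_reference"), inherits(var, "insertion_variant"))
  p <- var$breakpoint_left
  # need a reference base on both sides of the junction
  if (p < ref$start_genomic || p >= ref_end(ref)) {
    stop(
      "insertion breakpoint ", p, " outside reference window ",
      ref$contig, ":", ref$start_genomic, "-", ref_end(ref)
    )
  }
  i <- p - ref$start_genomic + 1L
  paste0(
    substr(ref$sequence, 1L, i),
    var$inserted_seq,
    substr(ref$sequence, i + 1L, nchar(ref$sequence))
  )
}

#' Apply a registered hotspot point substitution to a reference window
#'
#' @param ref a [promoter_reference()].
#' @param registry a [motif_registry()].
#' @param name hotspot name in the registry (e.g. `"G228A"`).
#' @return a [promoter_reference()] carrying the substitution.
#' @export
apply_hotspot <- function(ref, registry, name) {
  stopifnot(inherits(registry, "motif_registry"))
  row <- registry$hotspot_variants[registry$hotspot_variants$name == name, ]
  if (nrow(row) != 1L) stop("unknown hotspot variant: ", name)
  from <- row$start
  to <- row$start + nchar(row$ref) - 1L
  observed <- ref_subseq(ref, from, to)
  if (observed != row$ref) {
    stop(
      "reference mismatch applying ", name, ": expected ", row$ref,
      " at ", from, ", found ", observed
    )
  }
  seq <- ref$sequence
  i <- from - ref$start_genomic + 1L
  substr(seq, i, i + nchar(row$ref) - 1L) <- row$alt
  out <- ref
  out$sequence <- seq
  out$name <- paste0(ref$name, "_", name)
  out
}

#' Duplication call
#'
#' Describes an insertion variant explained as a tandem duplication: the
#' duplicated template region in promoter (c.-X_-Y) and genomic coordinates,
#' the insert size, any nontemplated junction bases, and whether the template
#' is plain wild-type sequence or carries a registered hotspot substitution.
#'
#' @param template_c_up,template_c_down promoter positions of the template.
#' @param template_genomic closed genomic interval `c(lo, hi)`.
#' @param insert_size insertion length in bp.
#' @param inserted_seq the inserted sequence.
#' @param breakpoint genomic pair `c(left, right)` flanking the insertion.
#' @param nontemplated data.frame(offset, base) of junction bases absent from
#'   the template (offsets are 1-based within the insert).
#' @param mismatches data.frame(offset, template_base, inserted_base).
#' @param source_template `"wildtype"` or `"carries_hotspot"`.
#' @param hotspot registry hotspot name when `source_template` is
#'   `"carries_hotspot"`, else `NA`.
#' @return An object of class `duplication_call`.
#' @export
duplication_call <- function(template_c_up, template_c_down, template_genomic,
                             insert_size, inserted_seq, breakpoint,
                             nontemplated = empty_offset_df(),
                             mismatches = empty_mismatch_df(),
                             source_template = c("wildtype", "carries_hotspot"),
                             hotspot = NA_character_) {
  source_template <- match.arg(source_template)
  template_len <- template_genomic[2] - template_genomic[1] + 1L
  if (insert_size != template_len + nrow(nontemplated)) {
    stop(
      "insert_size (", insert_size, ") != template length (", template_len,
      ") + nontemplated bases (", nrow(nontemplated), ")"
    )
  }
  structure(
    list(
      template_c_up = as.integer(template_c_up),
      template_c_down = as.integer(template_c_down),
      template_genomic = as.integer(template_genomic),
      insert_size = as.integer(insert_size),
      inserted_seq = inserted_seq,
      breakpoint = as.integer(breakpoint),
      nontemplated = nontemplated,
      mismatches = mismatches,
      source_template = source_template,
      hotspot = hotspot
    ),
    class = "duplication_call"
  )
}

empty_offset_df <- function() {
  data.frame(offset = integer(), base = character(), stringsAsFactors = FALSE)
}
empty_mismatch_df <- function() {
  data.frame(
    offset = integer(), template_base = character(),
    inserted_base = character(), stringsAsFactors = FALSE
  )
}

#' @export
print.duplication_call <- function(x, ...) {
  cat("<duplication_call> c.", x$template_c_up, "_", x$template_c_down,
    " (", x$template_genomic[1], "-", x$template_genomic[2], "), ",
    x$insert_size, " bp insert at ", x$breakpoint[1], "/", x$breakpoint[2],
    ", template ", x$source_template,
    if (nrow(x$nontemplated)) paste0(", +", nrow(x$nontemplated), " nontemplated") else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Build a duplication call directly from a c.-X_-Y region
#'
#' Convenience constructor for exact duplications of a known template region:
#' the insert is the template copy itself and the breakpoint is the
#' left-aligned one (immediately 5', in genomic coordinates, of the template).
#'
#' @param ref a [promoter_reference()] (pass a hotspot-mutated reference from
#'   [apply_hotspot()] for mutant-template duplications).
#' @param map a [coordinate_map()].
#' @param c_up,c_down promoter positions of the duplicated region.
#' @param source_template template provenance, see [duplication_call()].
#' @param hotspot hotspot name for mutant templates.
#' @return a [duplication_call()].
#' @export
duplication_from_region <- function(ref, map, c_up, c_down,
                                    source_template = "wildtype",
                                    hotspot = NA_character_) {
  template <- extract_template(ref, map, c_up, c_down)
  lo <- c_to_genomic(map, c_down)
  hi <- c_to_genomic(map, c_up)
  # the left-aligned breakpoint needs a covered base 5' of the template; when
  # the template abuts the window start, anchoring the copy 3' of the
  # template yields the byte-identical variant sequence
  bp <- if (lo - 1L >= ref$start_genomic) c(lo - 1L, lo) else c(hi, hi + 1L)
  duplication_call(
    template_c_up = c_up, template_c_down = c_down,
    template_genomic = c(lo, hi),
    insert_size = nchar(template),
    inserted_seq = template,
    breakpoint = bp,
    source_template = source_template,
    hotspot = hotspot
  )
}

#' Realize a duplication call as its insertion variant
#' @param call a [duplication_call()].
#' @return an [insertion_variant()].
#' @export
as_insertion <- function(call) {
  stopifnot(inherits(call, "duplication_call"))
  insertion_variant(call$breakpoint[1], call$inserted_seq)
}

#' Detect whether an insertion variant is a tandem duplication
#'
#' The inserted sequence is compared with the reference flank on each side of
#' the breakpoint, allowing up to `max_nontemplated` extra bases at the
#' insert's junction end (the only non-exact pattern seen in practice is a
#' short run of junction bases such as a terminal A). A downstream-flank match
#' means the insert copies the template that starts at `breakpoint + 1`; an
#' upstream-flank match means it copies the template ending at the breakpoint.
#' Either way the duplicated template interval and its promoter (c.) region
#' are reported along with the canonical left-aligned breakpoint.
#'
#' When both flanks match (perfect repeats) the left-aligned reading is kept
#' and the call is flagged `ambiguous_flank`.
#'
#' @param ref a [promoter_reference()].
#' @param map a [coordinate_map()].
#' @param var an [insertion_variant()].
#' @param max_nontemplated maximum junction bases not explained by the
#'   template (default 2).
#' @param mutant_refs optional named list of hotspot-substituted references
#'   (from [apply_hotspot()]) to try when the wild-type reference does not
#'   explain the insert; a match sets `source_template = "carries_hotspot"`.
#' @return a [duplication_call()], or `NULL` when the insert is not a tandem
#'   duplication of the adjacent sequence.
#' @export
detect_tandem_duplication <- function(ref, map, var, max_nontemplated = 2L,
                                      mutant_refs = NULL) {
  stopifnot(inherits(var, "insertion_variant"))
  hit <- match_tandem_flanks(ref, var, max_nontemplated)
  if (!is.null(hit)) {
    return(build_dup_call(ref, map, var, hit, "wildtype", NA_character_))
  }
  for (name in names(mutant_refs)) {
    hit <- match_tandem_flanks(mutant_refs[[name]], var, max_nontemplated)
    if (!is.null(hit)) {
      return(build_dup_call(mutant_refs[[name]], map, var, hit, "carries_hotspot", name))
    }
  }
  NULL
}

# Try to explain the insert as a copy of the downstream or upstream flank,
# with k in 0..max_nontemplated junction bases left unexplained at the
# insert's prefix or suffix. Returns NULL or a list describing the match.
match_tandem_flanks <- function(ref, var, max_nontemplated) {
  s <- var$inserted_seq
  L <- nchar(s)
  p <- var$breakpoint_left
  hits <- list()
  for (k in 0:max_nontemplated) {
    core_len <- L - k
    if (core_len < 1L) break
    # core as prefix (extras at insert suffix) or as suffix (extras at prefix)
    for (extras_at in c("suffix", "prefix")) {
      core <- if (extras_at == "suffix") substr(s, 1L, core_len) else substr(s, k + 1L, L)
      extra_bases <- if (extras_at == "suffix") substring(s, core_len + 1L) else substr(s, 1L, k)
      extra_offsets <- if (extras_at == "suffix") seq_len(k) + core_len else seq_len(k)
      # downstream flank: template starts at p + 1
      if (p + core_len <= ref_end(ref) && p + 1L >= ref$start_genomic &&
        ref_subseq(ref, p + 1L, p + core_len) == core) {
        hits[[length(hits) + 1L]] <- list(
          template = c(p + 1L, p + core_len), k = k,
          extra_offsets = extra_offsets, extra_bases = extra_bases
        )
      }
      # upstream flank: template ends at p
      if (p - core_len + 1L >= ref$start_genomic && p <= ref_end(ref) &&
        ref_subseq(ref, p - core_len + 1L, p) == core) {
        hits[[length(hits) + 1L]] <- list(
          template = c(p - core_len + 1L, p), k = k,
          extra_offsets = extra_offsets, extra_bases = extra_bases
        )
      }
      if (k == 0L) break # prefix/suffix identical when no extras
    }
    if (length(hits)) break # prefer the fewest nontemplated bases
  }
  if (!length(hits)) {
    return(NULL)
  }
  hit <- hits[[1L]] # left-alignment below canonicalizes; flag ambiguity
  hit$ambiguous <- length(unique(vapply(
    hits, function(h) paste(h$template, collapse = "-"), ""
  ))) > 1L
  hit
}

build_dup_call <- function(ref, map, var, hit, source_template, hotspot) {
  nontemplated <- data.frame(
    offset = as.integer(hit$extra_offsets),
    base = if (hit$k > 0L) strsplit(hit$extra_bases, "")[[1]] else character(),
    stringsAsFactors = FALSE
  )
  call <- duplication_call(
    template_c_up = genomic_to_c(map, hit$template[2]),
    template_c_down = genomic_to_c(map, hit$template[1]),
    template_genomic = hit$template,
    insert_size = nchar(var$inserted_seq),
    inserted_seq = var$inserted_seq,
    breakpoint = c(hit$template[1] - 1L, hit$template[1]),
    nontemplated = nontemplated,
    source_template = source_template,
    hotspot = hotspot
  )
  call <- normalize_duplication(ref, call)
  call$ambiguous_flank <- isTRUE(hit$ambiguous)
  call
}

#' Left-align a duplication call to its canonical representation
#'
#' Shifts the template window towards the ATG (lower genomic coordinates) for
#' as long as the shifted window yields the byte-identical variant sequence,
#' i.e. while the base 5' of the template equals the template's last base.
#' Shifting stops at the reference window edge, so the canonical member is
#' defined relative to reference coverage. Idempotent.
#'
#' @param ref a [promoter_reference()].
#' @param call a [duplication_call()].
#' @return the canonical [duplication_call()] (smallest `|template_c_up|`).
#' @export
normalize_duplication <- function(ref, call) {
  stopifnot(inherits(call, "duplication_call"))
  lo <- call$template_genomic[1]
  hi <- call$template_genomic[2]
  while (lo - 1L >= ref$start_genomic &&
    ref_subseq(ref, lo - 1L, lo - 1L) == ref_subseq(ref, hi, hi)) {
    lo <- lo - 1L
    hi <- hi - 1L
  }
  shift <- call$template_genomic[1] - lo
  if (shift == 0L) {
    return(call)
  }
  out <- call
  out$template_genomic <- c(lo, hi)
  out$template_c_up <- call$template_c_up + shift
  out$template_c_down <- call$template_c_down + shift
  out$breakpoint <- c(lo - 1L, lo)
  # the canonical insert is the left-aligned template copy plus junction extras
  template <- ref_subseq(ref, lo, hi)
  if (nrow(call$nontemplated)) {
    extra <- paste(call$nontemplated$base, collapse = "")
    if (min(call$nontemplated$offset) == 1L) {
      out$inserted_seq <- paste0(extra, template)
    } else {
      out$inserted_seq <- paste0(template, extra)
    }
  } else {
    out$inserted_seq <- template
  }
  out
}

#' Deterministic digest of a variant sequence
#'
#' 64-bit FNV-1a over the byte sequence, reported as hex. Used as the
#' identity key of duplication equivalence classes; computed over the full
#' variant window string so that position-shifted identical inserts collide
#' exactly when the variant sequences are byte-identical.
#'
#' @param x character string.
#' @return hex digest string.
#' @export
variant_digest <- function(x) {
  bytes <- utf8ToInt(x)
  # two polynomial rolling hashes over distinct Mersenne-adjacent moduli;
  # intermediate values stay well inside exact double-precision range
  h1 <- 17
  h2 <- 257
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 131 + b) %% 2147483629
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

#' Partition duplication windows into equivalence classes
#'
#' Two duplication windows are equivalent when inserting their template copies
#' into the same reference yields byte-identical variant sequences. Each class
#' reports its members, the canonical (left-aligned, smallest `|c_up|`)
#' member, and a digest of the shared variant sequence. Classes are sorted by
#' canonical member (most ATG-proximal first).
#'
#' @param ref a [promoter_reference()].
#' @param map a [coordinate_map()].
#' @param windows data.frame with columns `c_up`, `c_down` (one window per
#'   row), e.g. from [enumerate_windows()].
#' @return list of classes; each class is a list with `members` (data.frame),
#'   `canonical` (`c(c_up, c_down)`), `variant_seq` and `variant_seq_hash`.
#' @export
equivalence_classes <- function(ref, map, windows) {
  stopifnot(is.data.frame(windows), all(c("c_up", "c_down") %in% names(windows)))
  variants <- vapply(seq_len(nrow(windows)), function(i) {
    call <- duplication_from_region(ref, map, windows$c_up[i], windows$c_down[i])
    apply_insertion(ref, as_insertion(call))
  }, character(1))
  groups <- split(seq_len(nrow(windows)), variants)
  classes <- lapply(groups, function(idx) {
    members <- windows[idx, c("c_up", "c_down"), drop = FALSE]
    members <- members[order(abs(members$c_up)), , drop = FALSE]
    rownames(members) <- NULL
    list(
      members = members,
      canonical = c(members$c_up[1], members$c_down[1]),
      variant_seq = variants[idx[1]],
      variant_seq_hash = variant_digest(variants[idx[1]])
    )
  })
  classes <- classes[order(vapply(classes, function(cl) abs(cl$canonical[1]), numeric(1)))]
  names(classes) <- NULL
  classes
}

#' Format a window pair as the conventional region label
#' @param c_up,c_down promoter positions.
#' @return string such as `"c.-100_-79"`.
#' @export
region_label <- function(c_up, c_down) {
  paste0("c.", c_up, "_", c_down)
}

#' Parse a region label of the form `c.-X_-Y`
#' @param x region string(s).
#' @return data.frame with columns `c_up`, `c_down`.
#' @export
parse_region_label <- function(x) {
  m <- regmatches(x, regexec("^c\\.(-[0-9]+)_(-[0-9]+)$", x))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("malformed region label(s): ", paste(x[bad], collapse = ", "))
  data.frame(
    c_up = vapply(m, function(g) as.integer(g[2]), integer(1)),
    c_down = vapply(m, function(g) as.integer(g[3]), integer(1))
  )
}
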