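#' Coordinate map between promoter c.-positions and hg19 genomic coordinates
#'
#' The TERT promoter literature annotates variants both by genomic coordinate
#' (hg19 chr5) and by position relative to the TERT translation start (ATG),
#' e.g. c.-124 for the hotspot at chr5:1,295,228. TERT is transcribed towards
#' lower genomic coordinates, so promoter position c.-n sits n bases *above*
#' the ATG: `genomic(c.-n) = atg_genomic + n`.
#'
#' The constructor refuses to build a map whose anchor does not reproduce the
#' c.-124 == chr5:1,295,228 identity, so a mistyped ATG coordinate fails
#' immediately rather than silently shifting every downstream annotation.
#'
#' @param atg_genomic 1-based hg19 genomic coordinate (chr5) of the first base
#'   of the TERT ATG. Default 1295104.
#' @param contig contig label, default `"chr5"`.
#' @return An object of class `coordinate_map`.
#' @examples
#' map <- coordinate_map()
#' c_to_genomic(map, -124) # 1295228
#' @export
coordinate_map <- function(atg_genomic = 1295104L, contig = "chr5") {
  stopifnot(is.numeric(atg_genomic), length(atg_genomic) == 1L, atg_genomic >= 1)
  map <- structure(
    list(atg_genomic = as.integer(atg_genomic), contig = contig),
    class = "coordinate_map"
  )
  if (map$atg_genomic + 124L != 1295228L) {
    stop(
      "coordinate_map anchor self-check failed: c.-124 maps to ",
      map$atg_genomic + 124L, ", expected 1295228 (hg19 chr5 hotspot anchor)"
    )
  }
  map
}

#' @export
print.coordinate_map <- function(x, ...) {
  cat("<coordinate_map> ", x$contig, " ATG at ", x$atg_genomic,
    " (c.-n -> ", x$atg_genomic, " + n)\n",
    sep = ""
  )
  invisible(x)
}

#' Convert promoter c.-positions to genomic coordinates
#'
#' @param map a [coordinate_map()].
#' @param c promoter position(s), negative integers (c.-1 is the base
#'   immediately upstream of the ATG).
#' @return integer genomic coordinate(s).
#' @export
c_to_genomic <- function(map, c) {
  stopifnot(inherits(map, "coordinate_map"))
  c <- as.integer(c)
  if (any(is.na(c)) || any(c >= 0L)) {
    stop("promoter c.-positions must be negative integers (got ", paste(c, collapse = ", "), ")")
  }
  map$atg_genomic + abs(c)
}

#' Convert genomic coordinates back to promoter c.-positions
#'
#' Exact inverse of [c_to_genomic()] for coordinates above the ATG.
#'
#' @inheritParams c_to_genomic
#' @param genomic genomic coordinate(s), each `> atg_genomic`.
#' @return negative integer promoter position(s).
#' @export
genomic_to_c <- function(map, genomic) {
  stopifnot(inherits(map, "coordinate_map"))
  genomic <- as.integer(genomic)
  if (any(is.na(genomic)) || any(genomic <= map$atg_genomic)) {
    stop("genomic coordinate must lie upstream of the ATG (> ", map$atg_genomic, ")")
  }
  -(genomic - map$atg_genomic)
}

#' Promoter reference window
#'
#' A plus-strand DNA window written left-to-right in increasing genomic
#' coordinate. "Plus" here is the strand on which the GGAA (ETS core) motifs
#' read directly -- the strand every promoter duplication sequence in the
#' cohort tables is reported on. TERT itself is transcribed from the other
#' strand; TERT-sense display is a presentation concern, not a storage one.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param start_genomic 1-based genomic coordinate of the first base.
#' @param name window name.
#' @param contig contig label.
#' @return An object of class `promoter_reference`.
#' @export
promoter_reference <- function(sequence, start_genomic, name = "window", contig = "chr5") {
  sequence <- toupper(as.character(sequence))
  stopifnot(length(sequence) == 1L, nchar(sequence) >= 1L)
  if (grepl("[^ACGTN]", sequence)) {
    stop("reference sequence contains characters outside {A,C,G,T,N}")
  }
  structure(
    list(
      sequence = sequence,
      start_genomic = as.integer(start_genomic),
      name = name,
      contig = contig
    ),
    class = "promoter_reference"
  )
}

#' @export
print.promoter_reference <- function(x, ...) {
  cat("<promoter_reference> ", x$name, " ", x$contig, ":", x$start_genomic,
    "-", ref_end(x), " (", nchar(x$sequence), " bp)\n",
    sep = ""
  )
  invisible(x)
}

#' Last genomic coordinate covered by a reference window
#' @param ref a [promoter_reference()].
#' @return integer genomic coordinate.
#' @export
ref_end <- function(ref) {
  stopifnot(inherits(ref, "promoter_reference"))
  ref$start_genomic + nchar(ref$sequence) - 1L
}

#' Extract the plus-strand subsequence over a closed genomic interval
#' @param ref a [promoter_reference()].
#' @param from,to 1-based genomic coordinates, `from <= to`, both inside the
#'   window.
#' @return DNA string.
#' @export
ref_subseq <- function(ref, from, to) {
  stopifnot(inherits(ref, "promoter_reference"), from <= to)
  if (from < ref$start_genomic || to > ref_end(ref)) {
    stop(
      "interval ", ref$contig, ":", from, "-", to, " extends outside reference window ",
      ref$contig, ":", ref$start_genomic, "-", ref_end(ref)
    )
  }
  substr(ref$sequence, from - ref$start_genomic + 1L, to - ref$start_genomic + 1L)
}

#' Extract a duplication template sequence from its promoter region
#'
#' Cohort tables describe duplicated regions as c.-X_-Y (X > Y): the
#' template runs from promoter position c.-X (upstream, higher genomic
#' coordinate) to c.-Y. The returned string is the plus-strand sequence read
#' in increasing genomic coordinate, which is how the tables print it.
#'
#' @param ref a [promoter_reference()].
#' @param map a [coordinate_map()].
#' @param c_up,c_down promoter positions of the region ends, `c_up < c_down <= -1`.
#' @return DNA string of length `|c_up| - |c_down| + 1`.
#' @examples
#' ref <- read_promoter_fasta(tertdup_extdata("wt_oligo.fa"))
#' extract_template(ref, coordinate_map(), -110, -89)
#' @export
extract_template <- function(ref, map, c_up, c_down) {
  if (!(c_up < c_down && c_down <= -1L)) {
    stop("need c_up < c_down <= -1; got c_up=", c_up, ", c_down=", c_down)
  }
  ref_subseq(ref, c_to_genomic(map, c_down), c_to_genomic(map, c_up))
}

#' Single-base accessor by promoter position
#' @inheritParams extract_template
#' @param c promoter position (negative integer).
#' @return single-character base.
#' @export
extract_base <- function(ref, map, c) {
  g <- c_to_genomic(map, c)
  ref_subseq(ref, g, g)
}

#' Read a promoter reference window from FASTA
#'
#' The header carries the window name and its anchor as `contig:start`
#' (1-based), e.g. `>wt_oligo chr5:1295182`.
#'
#' @param path FASTA file.
#' @return a [promoter_reference()].
#' @export
read_promoter_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) stop("expected a single-record FASTA, got ", length(set), " records")
  header <- names(set)[1]
  tokens <- strsplit(header, "\\s+")[[1]]
  anchor <- grep("^[A-Za-z0-9_.]+:[0-9]+$", tokens, value = TRUE)
  if (length(anchor) < 1L) {
    stop("FASTA header must carry a 'contig:start' token, got: ", header)
  }
  parts <- strsplit(anchor[1], ":")[[1]]
  promoter_reference(
    sequence = as.character(set[[1]]),
    start_genomic = as.integer(parts[2]),
    name = tokens[1],
    contig = parts[1]
  )
}

#' Write a promoter reference window to FASTA
#' @param ref a [promoter_reference()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(ref, path) {
  seq <- Biostrings::DNAStringSet(ref$sequence)
  names(seq) <- paste0(ref$name, " ", ref$contig, ":", ref$start_genomic)
  Biostrings::writeXStringSet(seq, path)
  invisible(path)
}

#' Path to a bundled fixture file
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available fixtures.
#' @return file path (or a character vector of file names).
#' @export
tertdup_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "tertdup")))
  }
  path <- system.file("extdata", file, package = "tertdup")
  if (!nzchar(path)) stop("no bundled fixture named ", file)
  path
}

#' Registry of named ETS motifs, hotspot variants and screen windows
#'
#' Defaults describe the TERT core promoter on hg19 chr5: the two native GGAA
#' sites "ETS 195" and "ETS 200" (named by genomic motif start), the recurrent
#' hotspot point substitutions, the core-promoter interval adjacent to the
#' native ETS cassette, and the 4-kb upstream screen window.
#'
#' Hotspot names follow the genomic-offset convention (G228A is a G>A at
#' chr5:1,295,228 on the stored strand, i.e. c.-124C>T in TERT-sense HGVS).
#'
#' @param native_sites data.frame with columns `name`, `start`, `end`, `motif`.
#' @param hotspot_variants data.frame with columns `name`, `start`, `ref`, `alt`
#'   (multi-base `ref`/`alt` describe dinucleotide substitutions).
#' @param core_adjacent_window genomic interval `c(lo, hi)` adjacent to the
#'   native ETS cassette.
#' @param screen_window genomic interval of the upstream insertion screen.
#' @return An object of class `motif_registry`.
#' @export
motif_registry <- function(
    native_sites = data.frame(
      name = c("ETS 195", "ETS 200"),
      start = c(1295195L, 1295200L),
      end = c(1295198L, 1295203L),
      motif = c("GGAA", "GGAA"),
      stringsAsFactors = FALSE
    ),
    hotspot_variants = data.frame(
      name = c("G228A", "G250A", "T161G", "G228T", "GG228AA", "GG242AA"),
      start = c(1295228L, 1295250L, 1295161L, 1295228L, 1295228L, 1295242L),
      ref = c("G", "G", "T", "G", "GG", "GG"),
      alt = c("A", "A", "G", "T", "AA", "AA"),
      stringsAsFactors = FALSE
    ),
    core_adjacent_window = c(1295180L, 1295199L),
    screen_window = c(1295160L, 1299000L)) {
  stopifnot(
    all(c("name", "start", "end", "motif") %in% names(native_sites)),
    all(c("name", "start", "ref", "alt") %in% names(hotspot_variants)),
    length(core_adjacent_window) == 2L, length(screen_window) == 2L,
    core_adjacent_window[1] <= core_adjacent_window[2],
    screen_window[1] <= screen_window[2]
  )
  if (core_adjacent_window[1] < screen_window[1] ||
    core_adjacent_window[2] > screen_window[2]) {
    stop("core_adjacent_window must be contained in screen_window")
  }
  structure(
    list(
      native_sites = native_sites,
      hotspot_variants = hotspot_variants,
      core_adjacent_window = as.integer(core_adjacent_window),
      screen_window = as.integer(screen_window)
    ),
    class = "motif_registry"
  )
}

#' Check a registry against a reference window
#'
#' Verifies that every native-site motif text matches the reference at its
#' coordinates (sites outside the window are reported, not silently skipped).
#'
#' @param registry a [motif_registry()].
#' @param ref a [promoter_reference()].
#' @return data.frame with one row per native site and a logical `matches`.
#' @export
validate_registry <- function(registry, ref) {
  stopifnot(inherits(registry, "motif_registry"))
  sites <- registry$native_sites
  covered <- sites$start >= ref$start_genomic & sites$end <= ref_end(ref)
  observed <- rep(NA_character_, nrow(sites))
  observed[covered] <- mapply(
    function(s, e) ref_subseq(ref, s, e),
    sites$start[covered], sites$end[covered]
  )
  data.frame(
    name = sites$name,
    start = sites$start,
    covered = covered,
    observed = observed,
    matches = !is.na(observed) & observed == sites$motif,
    stringsAsFactors = FALSE
  )
}

#' Load a registry (and optional coordinate overrides) from a YAML config
#'
#' The YAML mirrors the [motif_registry()] arguments: top-level keys
#' `atg_genomic`, `native_sites`, `hotspot_variants`, `core_adjacent_window`,
#' `screen_window`; any key omitted keeps its default.
#'
#' @param path YAML file.
#' @return list with elements `map` ([coordinate_map()]) and `registry`
#'   ([motif_registry()]).
#' @export
read_registry_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  map <- coordinate_map(atg_genomic = cfg$atg_genomic %||% 1295104L)
  args <- list()
  if (!is.null(cfg$native_sites)) {
    args$native_sites <- do.call(rbind, lapply(cfg$native_sites, as.data.frame))
  }
  if (!is.null(cfg$hotspot_variants)) {
    args$hotspot_variants <- do.call(rbind, lapply(cfg$hotspot_variants, as.data.frame))
  }
  if (!is.null(cfg$core_adjacent_window)) args$core_adjacent_window <- cfg$core_adjacent_window
  if (!is.null(cfg$screen_window)) args$screen_window <- cfg$screen_window
  list(map = map, registry = do.call(motif_registry, args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
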