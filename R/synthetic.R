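#' Configuration for the synthetic-data generators
#'
#' Defaults encode the study conditions the generators emulate: an insertion
#' screen with 14 GGAA-containing insertions of which 13 localize to the core
#' promoter at ~22 bp, plus 19 non-GGAA insertions dispersed in length and
#' position over the 4-kb screen window; and multiregion tumors of 5 tumor
#' samples plus a germline normal with a 17-mutation truncal cluster and
#' region-private subclones.
#'
#' A single `seed` fans out to fixed per-generator streams (`seed + 101` for
#' references, `seed + 211` for screens, `seed + 307` for multiregion
#' matrices), so generators are reproducible independently of call order.
#'
#' @param seed global seed (integer).
#' @param ref_length,ref_gc reference length (bp) and GC fraction.
#' @param cassette native two-site ETS cassette planted in generated
#'   references.
#' @param cassette_at 1-based plant position (`NULL` = centered).
#' @param n_ggaa,n_ggaa_core,n_non_ggaa screen composition.
#' @param ggaa_len_band insert-length band for GGAA insertions (centered 22).
#' @param non_ggaa_len_range length dispersion of non-GGAA insertions.
#' @param n_samples multiregion samples including the normal.
#' @param truncal_size mutations in the truncal cluster.
#' @param private_range per-branch private/shared mutation count range.
#' @param flip_noise per-entry call-flip probability.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       ref_length = 10000L, ref_gc = 0.6,
                       cassette = "CGGAAAGGAAG", cassette_at = NULL,
                       n_ggaa = 14L, n_ggaa_core = 13L, n_non_ggaa = 19L,
                       ggaa_len_band = c(18L, 30L),
                       non_ggaa_len_range = c(3L, 60L),
                       n_samples = 6L, truncal_size = 17L,
                       private_range = c(5L, 15L), flip_noise = 0) {
  stopifnot(
    seed == as.integer(seed), n_ggaa_core <= n_ggaa,
    ref_gc >= 0, ref_gc <= 1, flip_noise >= 0, flip_noise <= 1,
    n_samples >= 3L, truncal_size >= 0L
  )
  structure(
    list(
      seed = as.integer(seed),
      ref_length = as.integer(ref_length), ref_gc = ref_gc,
      cassette = toupper(cassette), cassette_at = cassette_at,
      n_ggaa = as.integer(n_ggaa), n_ggaa_core = as.integer(n_ggaa_core),
      n_non_ggaa = as.integer(n_non_ggaa),
      ggaa_len_band = as.integer(ggaa_len_band),
      non_ggaa_len_range = as.integer(non_ggaa_len_range),
      n_samples = as.integer(n_samples), truncal_size = as.integer(truncal_size),
      private_range = as.integer(private_range), flip_noise = flip_noise
    ),
    class = "sim_config"
  )
}

random_dna <- function(n, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# resample any GGAA occurrence (scanning the stored strand) until none remain
scrub_motif <- function(seq, pattern = "GGAA", gc = 0.5) {
  repeat {
    hit <- regexpr(pattern, seq, fixed = TRUE)
    if (hit < 0) {
      return(seq)
    }
    # mutate one base inside the occurrence
    i <- as.integer(hit) + sample.int(nchar(pattern), 1) - 1L
    replacement <- sample(setdiff(c("A", "C", "G", "T"), substr(seq, i, i)), 1)
    substr(seq, i, i) <- replacement
  }
}

#' Generate a synthetic promoter-like reference window
#'
#' Random background sequence (configurable GC) with the two-site native ETS
#' cassette planted once; the background is scrubbed so the only GGAA
#' occurrences are the planted ones. Deterministic under the config seed.
#'
#' @param cfg a [sim_config()].
#' @param start_genomic genomic anchor of the generated window.
#' @return a [promoter_reference()]; the plant position (1-based, within the
#'   window) is attached as `attr(, "cassette_at")`.
#' @export
gen_reference <- function(cfg = sim_config(), start_genomic = 1L) {
  set.seed(cfg$seed + 101L)
  seq <- random_dna(cfg$ref_length, cfg$ref_gc)
  seq <- scrub_motif(seq, "GGAA", cfg$ref_gc)
  at <- cfg$cassette_at %||% as.integer((cfg$ref_length - nchar(cfg$cassette)) %/% 2)
  stopifnot(at >= 1L, at + nchar(cfg$cassette) - 1L <= cfg$ref_length)
  substr(seq, at, at + nchar(cfg$cassette) - 1L) <- cfg$cassette
  # planting may abut background G/A runs and create extra GGAA: scrub the
  # junctions (never the cassette) until the scan sees only planted sites
  cassette_sites <- at + as.integer(gregexpr("GGAA", cfg$cassette, fixed = TRUE)[[1]]) - 1L
  repeat {
    sites <- gregexpr("GGAA", seq, fixed = TRUE)[[1]]
    sites <- sites[sites > 0]
    stray <- setdiff(sites, cassette_sites)
    if (!length(stray)) break
    for (s in stray) {
      # mutate a base of the stray occurrence lying outside the cassette
      pos <- s:(s + 3L)
      pos <- pos[pos < at | pos > at + nchar(cfg$cassette) - 1L]
      i <- pos[1]
      substr(seq, i, i) <- sample(setdiff(c("C", "T"), substr(seq, i, i)), 1)
    }
  }
  ref <- promoter_reference(seq, start_genomic,
    name = "synthetic_reference", contig = "synth"
  )
  attr(ref, "cassette_at") <- at
  ref
}

#' Generate a synthetic GGAA insertion screen with ground truth
#'
#' Emulates the structure of the pan-cancer insertion screen: GGAA-bearing
#' insertions drawn at ~22 bp with breakpoints in (or, for the planted
#' non-core exception(s), well outside) the core-adjacent window, and
#' non-GGAA insertions with dispersed lengths and positions across the screen
#' window. Insert positions are uniform within their windows.
#'
#' @param cfg a [sim_config()].
#' @param screen a [screen_config()].
#' @return list with `insertions` (data.frame `breakpoint_left`,
#'   `inserted_seq`) and `truth` (data.frame adding the planted class labels
#'   `ggaa`, `core`).
#' @export
gen_insertion_screen <- function(cfg = sim_config(), screen = screen_config()) {
  set.seed(cfg$seed + 211L)
  core <- screen$core_adjacent_window
  win <- screen$screen_window
  rows <- list()
  make_ggaa_insert <- function(len) {
    # GGAA embedded in scrubbed random flanks
    at <- sample.int(len - 3L, 1)
    left <- if (at > 1L) scrub_motif(random_dna(at - 1L, 0.6)) else ""
    right <- if (at + 4L <= len) scrub_motif(random_dna(len - at - 3L, 0.6)) else ""
    paste0(left, "GGAA", right)
  }
  n_far <- cfg$n_ggaa - cfg$n_ggaa_core
  for (i in seq_len(cfg$n_ggaa)) {
    len <- sample(seq(cfg$ggaa_len_band[1], cfg$ggaa_len_band[2]), 1,
      prob = stats::dnorm(seq(cfg$ggaa_len_band[1], cfg$ggaa_len_band[2]), 22, 2)
    )
    core_planted <- i > n_far
    bp <- if (core_planted) {
      sample(seq(core[1], core[2]), 1)
    } else {
      # outside the core window even after the +/- insert-length margin
      sample(seq(core[2] + len + 10L, core[2] + len + 200L), 1)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      breakpoint_left = bp, inserted_seq = make_ggaa_insert(len),
      ggaa = TRUE, core = core_planted, stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(cfg$n_non_ggaa)) {
    len <- sample(seq(cfg$non_ggaa_len_range[1], cfg$non_ggaa_len_range[2]), 1)
    seq <- scrub_motif(random_dna(len, 0.55))
    bp <- sample(seq(win[1], win[2]), 1)
    rows[[length(rows) + 1L]] <- data.frame(
      breakpoint_left = bp, inserted_seq = seq,
      ggaa = FALSE, core = NA, stringsAsFactors = FALSE
    )
  }
  truth <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      breakpoint_left = integer(), inserted_seq = character(),
      ggaa = logical(), core = logical(), stringsAsFactors = FALSE
    )
  }
  list(
    insertions = truth[, c("breakpoint_left", "inserted_seq")],
    truth = truth
  )
}

#' Generate a synthetic multiregion tumor with known clonal structure
#'
#' Builds a random rooted binary tree over the tumor samples, assigns a
#' truncal mutation cluster to the trunk and private/shared clusters to every
#' other edge, and emits the binary presence matrix (variant present in
#' exactly the descendant samples of its edge). The germline normal is an
#' all-zero row. Optional call-flip noise perturbs entries independently.
#'
#' @param cfg a [sim_config()].
#' @return list: `matrix` (a [mutation_matrix()]), `tree` (true rooted
#'   `ape::phylo`, unit branch lengths), `clusters` (data.frame of planted
#'   clusters: pattern, edge samples, size).
#' @export
gen_multiregion <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 307L)
  n_tumor <- cfg$n_samples - 1L
  stopifnot(n_tumor >= 2L)
  tumors <- paste0("T", seq_len(n_tumor))
  normal <- "N"
  # random rooted binary tree over tumor samples by sequential attachment
  phy <- ape::rtree(n_tumor, tip.label = sample(tumors), br = NULL)
  desc <- descendant_tips(phy)
  edge_samples <- lapply(seq_len(nrow(phy$edge)), function(e) {
    sort(phy$tip.label[desc[[phy$edge[e, 2]]]])
  })
  sizes <- sample(seq(cfg$private_range[1], cfg$private_range[2]),
    length(edge_samples),
    replace = TRUE
  )
  clusters <- data.frame(
    samples = c(
      paste(sort(tumors), collapse = ","),
      vapply(edge_samples, paste, character(1), collapse = ",")
    ),
    size = c(cfg$truncal_size, sizes),
    truncal = c(TRUE, rep(FALSE, length(edge_samples))),
    stringsAsFactors = FALSE
  )
  # drop non-truncal clusters that would duplicate the full-tumor pattern
  # (cannot happen on a binary tree with n_tumor >= 2, but keep the guard)
  calls <- matrix(0L, cfg$n_samples, sum(clusters$size),
    dimnames = list(
      c(normal, sort(tumors)),
      paste0("v", seq_len(sum(clusters$size)))
    )
  )
  col <- 0L
  for (k in seq_len(nrow(clusters))) {
    members <- strsplit(clusters$samples[k], ",")[[1]]
    for (j in seq_len(clusters$size[k])) {
      col <- col + 1L
      calls[members, col] <- 1L
    }
  }
  if (cfg$flip_noise > 0) {
    flips <- matrix(
      stats::runif(length(calls)) < cfg$flip_noise,
      nrow(calls), ncol(calls),
      dimnames = dimnames(calls)
    )
    flips[normal, ] <- FALSE # germline calls stay clean
    calls[flips] <- 1L - calls[flips]
  }
  list(
    matrix = mutation_matrix(calls, normal = normal),
    tree = phy,
    clusters = clusters
  )
}
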