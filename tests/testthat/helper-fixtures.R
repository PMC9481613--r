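# Shared fixtures: the bundled EMSA oligos and promoter window, plus the
# default coordinate map and registry. Loaded once per test file.

fx_map <- coordinate_map()
fx_registry <- motif_registry()
fx_wt <- read_promoter_fasta(tertdup_extdata("wt_oligo.fa"))
fx_g228a <- read_promoter_fasta(tertdup_extdata("g228a_oligo.fa"))
fx_dup <- read_promoter_fasta(tertdup_extdata("dup_oligo.fa"))
fx_window <- read_promoter_fasta(tertdup_extdata("promoter_window_reconstructed.fa"))

# independent brute-force motif scan: all-positions substring comparison
naive_scan <- function(seq, pattern = "GGAA") {
  n <- nchar(seq)
  k <- nchar(pattern)
  starts <- integer(0)
  for (i in seq_len(max(n - k + 1L, 0L))) {
    if (substr(seq, i, i + k - 1L) == pattern) starts <- c(starts, i)
  }
  starts
}

# independent string-identity oracle for window equivalence: build both
# variant strings by plain string surgery and compare bytes
oracle_variant <- function(ref, map, c_up, c_down) {
  lo <- c_to_genomic(map, c_down)
  hi <- c_to_genomic(map, c_up)
  i <- lo - ref$start_genomic # bases before the template
  template <- substr(ref$sequence, i + 1L, hi - ref$start_genomic + 1L)
  paste0(
    substr(ref$sequence, 1L, i), template, template,
    substring(ref$sequence, hi - ref$start_genomic + 2L)
  )
}

# random DNA helper with its own RNG stream
rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
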