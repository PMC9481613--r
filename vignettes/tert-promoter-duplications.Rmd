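---
title: "Annotating ETS-creating duplications in the TERT core promoter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating ETS-creating duplications in the TERT core promoter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tertdup)
```

## The biological model

Telomerase reactivation through the *TERT* promoter is most often driven by
two recurrent noncoding point mutations, G228A and G250A (hg19
chr5:1,295,228 and 1,295,250; c.-124C>T and c.-146C>T relative to the TERT
ATG). Each creates a de novo ETS binding site (extended consensus CCGGAA)
positioned roughly an integer number of DNA helical turns from the native
ETS sites, so that the new and native GGAA motifs lie on the same helical
face. That geometry is what the GABP transcription-factor heterotetramer —
the only ETS-family member requiring two binding motifs — needs to engage
the promoter and activate *TERT*.

Small tandem duplications of wild-type core-promoter sequence can achieve
the same thing: a ~22-bp duplication that copies the native ETS 200 motif
places the copy 22 bp (≈2 helical turns at 10.5 bp/turn) from the original,
in phase, mimicking a hotspot mutation without altering a single base of
the duplicated sequence. This package implements the computational side of
that argument as reusable, tested components:

1. **Coordinates** — c.-position ↔ hg19 genomic mapping anchored at the
   TERT ATG (`coordinate_map()`), promoter reference windows
   (`promoter_reference()`), and a registry of named motifs and hotspots
   (`motif_registry()`).
2. **Duplications** — applying, detecting, left-aligning and
   equivalence-classing tandem duplications expressed as insertion variants.
3. **Motifs and phase** — GGAA scanning, native/de novo origin assignment,
   and bp ↔ helical-turn spacing.
4. **Activity** — an ordinal activation classifier and a simulated
   dual-luciferase readout.
5. **Enumeration** — the full panel of 22-bp duplication windows and its
   collapse to distinct variant sequences.
6. **Cohort** — validation of duplication tables and a GGAA-insertion
   screen.
7. **Clonality** — multiregion tumor trees from binary mutation calls.
8. **Synthetic data** — seeded generators with machine-readable truth.

## Strand and coordinate conventions

All sequences are stored and scanned on the genomic **plus-oriented GGAA
strand**, written left-to-right in increasing hg19 coordinate. This is the
strand on which every published duplication sequence and EMSA oligo reads
directly, and it makes the coordinate algebra trivial: with the ATG first
base at 1,295,104, promoter position c.-n maps to `1295104 + n`. TERT
itself is transcribed toward lower coordinates; TERT-sense display is a
presentation choice we do not store. Intervals are 1-based and fully
closed; there is no liftover support.

The constructor of `coordinate_map()` refuses to build a map that does not
reproduce the c.-124 ↔ 1,295,228 hotspot identity, so a wrong anchor fails
loudly.

```{r coords}
map <- coordinate_map()
c_to_genomic(map, c(-124, -146, -100, -79))
```

## The bundled reference windows

`inst/extdata` bundles the three EMSA oligos (wild type, G228A mutant, and
the c.-100_-79 duplication variant), the 21-record cohort duplication
table, and `promoter_window_reconstructed.fa`, a chr5:1,295,171–1,295,300
window on the GGAA strand reconstructed from the published core-promoter
sequence. The reconstruction is byte-identical to the printed wild-type
oligo over 1,295,182–1,295,241 and reproduces the expected reference bases
at every registered hotspot position; the flanking positions outside the
oligo (c.-67..-77 and c.-138..-196) come from the published promoter
sequence and are additionally constrained by the equivalence-group
structure of the 22-bp window panel (below). The window deliberately starts
at c.-67 — the most ATG-proximal base any analysis here needs — so that
left-alignment is defined relative to exactly the coverage the panel uses.

```{r window}
wt <- read_promoter_fasta(tertdup_extdata("wt_oligo.fa"))
win <- read_promoter_fasta(tertdup_extdata("promoter_window_reconstructed.fa"))
win
validate_registry(motif_registry(), win)
```

## Tandem duplications and equivalence classes

A tandem duplication inserted next to its template is coordinate-ambiguous:
sliding the template window by one base yields the byte-identical variant
sequence whenever the base 5' of the template equals the template's last
base. The package therefore treats **byte identity of the full variant
sequence** as the ground truth of equivalence (`equivalence_classes()`),
and canonicalizes every call by left-aligning toward the ATG
(`normalize_duplication()`), matching how the cohort tables anchor their
insert positions.

```{r dup}
call <- duplication_from_region(wt, map, -100, -79)
variant <- apply_insertion(wt, as_insertion(call))
nchar(variant) # the 82-nt duplication oligo
detect_tandem_duplication(wt, map, insertion_variant(1295182, "GGGCGGGGCCGCGGAAAGGAAG"))
```

Enumerating all 22-bp windows with upstream ends c.-121 through c.-88 gives
34 windows. Byte identity collapses them to **17** distinct variant
sequences:

```{r panel}
rep <- window_panel_report(win, map)
s <- window_panel_summary(rep)
s$windows
s$unique
Filter(function(x) length(x) > 1, s$classes)
```

Seven multi-member groups emerge. Six of them are the published
equivalence groups; byte identity additionally merges c.-100_-79 with the
c.-101_-80 group, c.-104_-83 with the c.-105_-84 group, and c.-110_-89 with
c.-111_-90, because in each case the flanking base equality that licenses
the shift holds in the wild-type sequence itself. Seventeen distinct
sequences is also exactly the number of unique constructs the published
reporter panel represents, so we report 17 and treat the string identity as
authoritative. Left-alignment stops at the reference edge, so canonical
representatives are defined relative to window coverage; over a longer
reference the c.-88_-67 class would left-shift further, outside this panel.

## Helical phase and the activity rule

Spacing between two motif sites is start-to-start on the stored strand;
under this convention an exact tandem duplication places every copied motif
exactly `insert_size` bp from its native counterpart. Helical turns are
`HT = d / P` with period `P = 10.5` bp, and a pair is *in phase* when `HT`
is within `tol = 0.15` turns of an integer. The tolerance is a package
choice made once: it classifies the recurrent 22-bp spacing (deviation
0.095 turns) and a 30-bp / ~3-turn spacing (deviation 0.143) as in phase
while a mid-phase 26-bp spacing (deviation 0.476) is not, which is the
qualitative pattern the engineered spacer series shows.

The activity classifier is deliberately **ordinal** (baseline / partial /
active) because the underlying reporter data support a rule, not a fitted
dose-response: a duplication is *active* when its template fully contains
the native ETS 200 motif and the copy sits in phase at ~2 turns; in-phase
~3-turn constructs are *partial* (their activity recovers but not fully);
ETS 195-only, motif-less or off-phase duplications are *baseline*; hotspot
point variants are *active*; and absence of GABPA forces *baseline*
everywhere, encoding the knockdown result. Whether duplications copying
neither full motif were individually assayed is figure-level information we
cannot re-derive, so the classifier's `baseline` for them is flagged as a
prediction, not a validated value.

```{r activity}
scan <- spacing_scan(win, duplication_from_region(win, map, -100, -79),
  deltas = c(-3, 0, 4, 8)
)
scan
```

`simulate_reporter()` exists to exercise downstream concordance tests: it
draws firefly/renilla ratios about ordinal class means (1, 3, 10 arbitrary
units; lognormal sd 0.2, mean-corrected) and is exact at zero noise. The
magnitudes are simulator conventions, not measured values.

## Cohort validation and the GGAA screen

`validate_cohort()` re-derives every record of the bundled 21-sample
duplication table from its c.-X_-Y region alone: template sequence,
breakpoint pair, and ETS content. Twenty of the 21 templates contain the
full ETS 200 motif; the single exception, c.-125_-106, sits further
upstream and copies the G228A hotspot site — it only matches a
G228A-substituted template (`source_template = "carries_hotspot"`), and its
printed insert position anchors at the hotspot base rather than the
template's ATG-proximal edge, which the breakpoint rule reproduces.
Cancer-type labels are normalized through an overridable grouping map
(`default_cancer_type_map()`), yielding 7 tumor types over 21–25-bp
inserts.

The insertion screen (`ggaa_screen()`) classifies arbitrary insertions in
the 4-kb upstream window by GGAA content, core-promoter localization and
length band. "Localized adjacent to the native ETS motif" is
operationalized as a breakpoint within the core window extended by the
insert length on either side, since a duplication of core sequence can be
anchored up to one template length away; the window bounds themselves are
configuration, not code. GGAA is scanned on the stored strand by default —
the strand every reported duplication reads on — with a `both` option that
also counts TTCC; the choice is exposed because the original screen's
strand convention is not stated.

## Multiregion clonality

`manhattan_distance()` on a binary sample×variant matrix equals Hamming
distance, and `ols_me_tree()` reconstructs a rooted sample tree by
**exhaustive** ordinary-least-squares minimum evolution: every unrooted
binary topology (105 at six samples) is OLS-fitted and the topology with
minimal total fitted length wins, rooted at the germline normal. The
exhaustive search is exact where the common `fastme.ols` implementation is
a heuristic; that implementation serves as an independent cross-check in
the test suite, and ties (resolved lexicographically on the split encoding)
are flagged. Negative OLS branch lengths are retained in the fit and
clamped to zero only for display and newick export. Above eight samples an
agglomerative (neighbor-joining) starting topology is OLS-fitted instead —
a documented approximation behind an explicit flag.

`assign_mutations()` groups variants by their tumor-presence pattern and
maps each pattern to the tree edge with exactly that descendant set; the
all-tumor pattern is the truncal cluster, and patterns matching no edge are
homoplasy-flagged onto their minimal covering edge. These presence-pattern
clusters stand in for MCMC cellular-prevalence clustering (which needs
allele frequencies, not binary calls) and are labelled as such.

```{r clonality}
sim <- gen_multiregion(sim_config(seed = 7))
fit <- ols_me_tree(manhattan_distance(sim$matrix), root_label = "N")
fit
assign_mutations(sim$matrix, fit)$clusters
```

## What the synthetic generators do and do not emulate

The generators exist so every pipeline stage has seeded inputs with exact
ground truth. `gen_reference()` plants the two-site native ETS cassette
(`CGGAAAGGAAG`) in scrubbed random background (no stray GGAA) at a
configurable GC bias. `gen_insertion_screen()` draws the screen composition
stated above, with breakpoints uniform within their windows — the original
data's positional distribution is not published, so uniform is the neutral
choice. `gen_multiregion()` plants a random tumor topology, a 17-mutation
truncal cluster and 5–15 mutations per remaining branch (enough to make
every internal edge strictly positive), then emits presence calls with
optional per-entry flip noise that never touches the germline row.

What they do **not** emulate: sequencing reads and their error models,
copy-number changes, allele frequencies, purity, or mutational signatures.
A passing recovery test therefore shows the algorithms are correct on
noise-free or simply-perturbed calls, not that variant calling on real
panels would produce such calls. The real multiregion exome and pan-cancer
screen data are access-restricted, which is precisely why recovery is
demonstrated on synthetic truth.

## Numerical and scale choices

All analyses here are small and exact: promoter windows are ≤ a few hundred
bp, the window panel has 34 members, cohort tables tens of rows, and trees
≤ 8 leaves exhaustively (10,395 topologies at n = 8, each a 28×13 least
squares — well under a minute). The seeded recovery study in the test suite
uses 100 six-sample tumors, a size at which the exhaustive search is
instantaneous; the generators accept larger settings. Phase arithmetic uses
plain doubles with a 1e-9 comparison tolerance where invariance is
asserted; equivalence classing compares bytes, never hashes (digests are
reported for bookkeeping only). Degenerate inputs error early and
specifically: zero-length inserts, non-negative c.-positions, out-of-window
intervals, equal motif starts, non-binary call matrices, spacer deletions
that would truncate a motif.

## Known limitations

* The reconstructed promoter window is validated byte-for-byte only where
  the printed oligos cover it; outside that range it rests on the published
  promoter sequence and on consistency with the panel's equivalence
  structure.
* Origin assignment labels any non-native, non-insert site
  `de_novo_point`; motifs created across an insertion junction (which do
  not occur in this promoter's panel) would need a dedicated label.
* The activity rule is qualitative by design and inherits the reporter
  panel's scope: 22-bp-scale duplications and the registered hotspots.
* Clonality assumes binary presence calls; no VAF modeling, copy-number
  awareness, or bootstrap support.
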