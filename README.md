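# tertdup

Annotation and analysis of tandem-duplication insertion variants in the
*TERT* core promoter — the noncoding duplications that mimic the recurrent
hotspot point mutations by creating a de novo ETS binding site in helical
phase with the native one.

## Scientific background

The hotspot mutations G228A and G250A (hg19 chr5:1,295,228 / 1,295,250,
i.e. c.-124C>T / c.-146C>T relative to the TERT ATG) each create a de novo
ETS site (CCGGAA) that recruits the GABP transcription-factor
heterotetramer — the one ETS-family factor that needs **two** GGAA motifs
on the same helical face. A ~22-bp tandem duplication that copies the
native **ETS 200** motif (GGAA at chr5:1,295,200) achieves the same
geometry: with helical period P = 10.5 bp, the copy sits at

> d = insert size, HT = d / P, in phase ⇔ |HT − round(HT)| ≤ 0.15 turns

so d = 22 bp ≈ 2 helical turns places the duplicated and native motifs in
phase, exactly like a hotspot mutation. The package implements, as tested
components: the c.-position ↔ genomic coordinate map anchored at the ATG;
tandem-duplication detection, left-aligned normalization and byte-identity
equivalence classes; GGAA motif scanning with native/de-novo origin
assignment and bp↔helical-turn spacing; an ordinal promoter-activity
classifier (baseline/partial/active, with GABPA dependence); cohort-table
validation and a GGAA-insertion screen; multiregion tumor clonality by
exhaustive OLS minimum-evolution trees on Manhattan distances of binary
calls; and seeded synthetic-data generators with ground truth.

## Worked example

```r
library(tertdup)

map <- coordinate_map()                       # anchored: c.-124 -> 1,295,228
wt  <- read_promoter_fasta(tertdup_extdata("wt_oligo.fa"))

# realize the recurrent c.-100_-79 duplication and inspect its motifs
call    <- duplication_from_region(wt, map, -100, -79)
variant <- apply_insertion(wt, as_insertion(call))
sites   <- assign_origin(wt, variant, call)
duplication_spacing(sites, call)
#>   copy_start native_start native_genomic  d       HT nearest_turns phase_deviation in_phase
#> 1         14           36        1295195 22 2.095238             2       0.0952381     TRUE
#> 2         19           41        1295200 22 2.095238             2       0.0952381     TRUE
```

Both native motifs gain a copy 22 bp away — 2.10 helical turns, deviation
0.095 turns, in phase — which the activity rule classifies as `active`
(and as `baseline` once `gabpa_present = FALSE`).

Enumerating the full 22-bp window panel over the bundled reconstructed
promoter window:

```r
win <- read_promoter_fasta(tertdup_extdata("promoter_window_reconstructed.fa"))
s   <- window_panel_summary(window_panel_report(win, map))
s$windows   #> 34
s$unique    #> 17  (distinct variant sequences by byte identity)
```

And the cohort table of 21 tumor duplications re-derives entirely from its
c.-X_-Y regions:

```r
t1 <- parse_cohort(tertdup_extdata("cohort_duplications.tsv"))
val <- validate_cohort(t1, win, map)
all(val$agree_pos)          #> TRUE   (all 21 printed insert positions)
sum(val$contains_ets200)    #> 20    (the outlier copies the G228A site)
summarize_cohort(t1)$n_cancer_types  #> 7
```

## Layout

* `R/` — coordinates/reference, duplications, motifs/phase, activity,
  enumeration, cohort/screen, clonality, synthetic data, IO.
* `inst/extdata/` — the three EMSA oligo FASTAs, the reconstructed
  chr5:1,295,171–1,295,300 promoter window, the 21-record cohort table.
* `vignettes/tert-promoter-duplications.Rmd` — the methods vignette:
  model, conventions, parameter choices, limitations.
* `tests/testthat/` — unit, property and acceptance tests.
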