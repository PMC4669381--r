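# uindel

Analysis of uridine insertion/deletion (U-indel) RNA editing from deep
sequencing reads.

In the mitochondria of kinetoplastid protists, most protein-coding
transcripts are not translatable as transcribed: uridine residues are
inserted into and deleted from the pre-mRNA at many sites, directed by
small guide RNAs (gRNAs), until an open reading frame emerges.  Editing
proceeds 3′→5′ within an editing domain, in blocks of roughly 45 nt (the
span covered by one gRNA), and a substantial fraction of steady-state
transcripts are partially or *alternatively* edited ("misedited").
Standard read mappers fail on such data: a read may differ from the
reference by dozens of closely spaced U-indels.

`uindel` provides, for researchers studying kinetoplastid (or diplonemid)
organellar gene expression:

* **an editing-aware local aligner** — Smith–Waterman with
  *nucleotide-specific* gap penalties, so "T, −" and "−, T" gaps can be
  free while A/C/G gaps stay prohibitive, plus seed-anchored read mapping
  against a pre-edited cryptogene;
* **the editing-state algebra** — every sequence is decomposed into its
  non-T *skeleton* and the T-run length at each inter-base site, the
  coordinate system in which editing states are applied, diffed and
  compared;
* **main-pathway reconstruction** — the mature edited mRNA is rebuilt
  site by site in the 3′→5′ direction of editing, with iterative
  re-seeding on partially edited templates (pan-edited transcripts have
  no mappable seed on the pre-edited sequence);
* **misediting analysis** — reads are classified as pre-edited
  (*reference*), *main-pathway* or *alternative*; alternative reads merge
  into non-redundant editing intermediates with fractional (1/k) support
  values, terminal/internal stretch annotation, per-domain summaries and
  a monospaced text rendering;
* **editing statistics** — U-insertion/deletion/edited-site counts per
  editing region, percent size increase, percent U in the ORF, and
  translation of edited ORFs under the mold/protozoan mitochondrial
  genetic code (TGA = Trp);
* **a gRNA gene search** — genomic stretches ≥ 25 nt complementary to the
  edited mRNA with up to 5 G-U wobble pairs and transcriptomic read
  support;
* **a simulator** of cryptogenes, gRNA-block editing cascades, partially
  and alternatively edited transcript populations, and reads — the
  package's fully reproducible ground-truth test bed.

## The core scoring model

For a read *r* and reference *x*, the aligner maximises the usual local
alignment score except that gap costs are indexed by the base being
skipped:

```
gap(b, L) = gap_open[b] + L * gap_extend[b],   b ∈ {A, C, G, T}
```

In strict mode (`scheme_strict()`), `gap_open[T] = gap_extend[T] = 0` and
A/C/G gaps are disallowed, so an alignment exists **iff** the read is a
U-indel variant of a reference stretch — equivalently, iff the read's
non-T skeleton is a contiguous substring of the reference skeleton (this
equivalence is property-tested).  A permissive preset
(`scheme_mapping()`: A/C/G gaps 10/10, T gaps 1/1, mismatch 18) mirrors a
short-read mapper patched with base-specific penalties.  Equal-scoring
traces are canonicalised with gaps leftmost inside each T run.

## Worked example

Everything below is simulated, so it runs anywhere in a few seconds:

```r
library(uindel)

cfg <- simulation_config(rng_seed = 7, n_bases = 60, n_domains = 1,
                         coverage = 100, read_len = c(60, 90),
                         misedit_rate = 0.1, internal_misedit_rate = 0.01,
                         strand_specific = TRUE)
loc   <- simulate_locus(cfg)        # cryptogene + planted mature state
reads <- simulate_reads(loc)        # 144 partially/misedited reads

main <- reconstruct_main(NULL, loc$crypt, reads = reads,
                         scheme = scheme_strict(), strand_specific = TRUE)
glance(main)
#>   cryptogene_id iterations_used frontier n_sites
#> 1 sim_locus                   3        4      61
identical(main$state$runs, loc$mature_state$runs)
#> [1] TRUE                        # planted mature state recovered exactly

tmpl <- recompose(loc$crypt$skeleton, main$state$runs)
aln  <- map_all(reads, loc$crypt, seed = tile_seeds(tmpl),
                template = tmpl, scheme = scheme_strict(),
                strand_specific = TRUE)
cls  <- classify_reads(aln, loc$crypt, main)
table(cls$class)
#> alternative        main   reference
#>          30          81          29

ints <- merge_intermediates(dplyr::filter(cls, class == "alternative"),
                            loc$crypt, main)
misediting_summary(cls, ints, loc$crypt)$by_domain
#>   domain site_lo site_hi n_reads n_reference n_main n_alternative n_edited
#> 1      1       4      45     140          29     81            30      111
```

27% of the edited reads in this simulation carry at least one
alternatively edited site — a site never edited in the main product, a
U-indel longer than in the main product, or an indel in the opposite
direction — and the intermediates table carries their merged patterns
with fractional read support summing exactly to the number of
alternative reads.

Editing statistics in the shape of a per-gene summary table:

```r
editing_stats(loc$crypt, tmpl)
#>   gene      pre_edited_size edited_size pct_size_increase u_insertions ...
#> 1 sim_locus              87         108                24           21 ...
```

A shell entry point wrapping the same functions lives at
`inst/cli/uindel.R` (subcommands `simulate`, `align`, `pathway`, `stats`,
`grna`, `coverage`).

## Limitations

No real *Perkinsela* sequence data are shipped; table-scale checks run
on synthetic sequences that plant the published per-region editing
counts (see `synthetic_transcripts_from_counts()`).  The
simulator emulates error-free reads from a single-transcript locus; it
does not model sequencing errors (off by default), library-preparation
bias, or inter-locus multi-mapping.  See the methods vignette
(`vignettes/u-indel-editing.Rmd`) for the model, parameter defaults and
design decisions.
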