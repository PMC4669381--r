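---
title: "U-indel editing analysis: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{U-indel editing analysis: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the editing model and its assumptions, the parameters that matter, what
the simulator does and does not emulate, and the decisions taken where
the design was genuinely open.  It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The editing model and its coordinate system

U-indel editing inserts and deletes uridines only; it never touches A, C
or G.  Every sequence is therefore fully described by its **skeleton**
— the ordered string of its non-T bases — plus the number of Ts at each
of the `N + 1` inter-base **sites** (site 0 holds leading Ts, site `N`
trailing Ts; all intervals in the package are 0-based and half-open).
Two consequences anchor the whole package:

* a pre-edited gene (cryptogene) and *any* of its edited forms share the
  same skeleton, so one site-index system serves the pre-edited
  reference, every partially edited template, and every read;
* an **editing state** — a run-length vector over a site range — is a
  complete, alignment-free description of an editing pattern, and
  `apply_editing()` / `diff_editing()` are exact inverses (a
  property-tested round trip).

Sites at read boundaries are **censored**: a T run truncated by a read
end cannot be measured, so boundary sites are flagged and excluded from
all state comparisons.  This is a deliberately conservative choice:
censored sites never generate alternative-editing calls, trading a
little sensitivity at read ends for zero boundary artefacts.

## Alignment scoring

The aligner is a Smith–Waterman dynamic programme whose gap costs are
indexed by the base being skipped, `gap(b, L) = open[b] + L * extend[b]`,
with `NA` banning gaps over a base.  Two presets:

| preset | match | mismatch | A/C/G gaps | T gaps | max mismatches |
|---|---|---|---|---|---|
| `scheme_strict()` | +1 | −18 | banned | 0/0 | 0 |
| `scheme_mapping()` | +1 | −18 | 10/10 | 1/1 | 2 |

Strict mode encodes the biology directly: an alignment exists iff the
read is a U-indel variant of a reference stretch, which is equivalent to
its skeleton being a contiguous substring of the reference skeleton.
The test suite asserts this equivalence against an independent
skeleton-matching oracle, and asserts score equality with an exhaustive
affine-gap DP oracle for both presets.  Among equal-scoring traces, gaps
are canonicalised leftmost within each T run, so emitted CIGARs are
deterministic; gap placement inside a T run never changes the extracted
editing state, which depends only on per-site T counts.

A banded mode (`band`, default off) restricts the DP to a diagonal band;
it exists for long templates, but the exact DP is the default because
the templates here are short (≤ 2 kb) and the full matrix is already
fast in compiled code.

## Read mapping

`map_read()` admits a read only when (i) it contains an anchoring seed
exactly, (ii) part of the read lies 5′ of the seed (editing-informative
reads must extend into the editable region), (iii) the alignment
contains no indels beyond what the scheme allows, and (iv) mismatches do
not exceed the scheme's tolerance (default 0 in strict mode — the
mismatch tolerance of editing-aware mapping is left adjustable because
no principled fixed value exists).  Unmapped is a normal outcome with a
reason code.  Reads are tried in both orientations unless the library is
strand-specific.  `tile_seeds()` generates seeds along a whole template
at fixed spacing; with several seeds a read is admitted when any seed
gates it, which is how all reads — not only 3′-anchored ones — are
mapped once a template is known.

## Main-pathway reconstruction

Editing progresses 3′→5′, so the mature product is rebuilt from the
3′-most edited site towards 5′.  At each site the voters are mapped
reads that

1. observe the site uncensored,
2. agree with the reconstruction at every more-3′ site they cover (the
   filter that removes reads whose own editing frontier lies 3′ of the
   site), and
3. are themselves edited at or 5′ of the site ("informed" voters):
   under 3′→5′ progression such reads have already been processed
   through the site, whereas unedited precursors carry no information
   about the mature value there and abstain.  Without rule 3,
   pre-edited reads — which are shorter and therefore over-sample any
   fixed anchor region — would outvote edited reads at the very first
   edited site and the reconstruction could never bootstrap.

The modal value among voters is adopted, with two guards on non-pre
values: at least `min_support` supporting reads (default 2), and at
least `min_fraction` (default 0.25) of the *edited* reads observing the
site.  The second guard encodes that the main pathway is the
predominant product: without it, two coinciding misedits among hundreds
of edited reads would extend the reconstruction 5′ of the true end of
editing.  Ties break towards the smaller `|run − pre_run|`, then towards
insertion.  These rules (modal vote, both guards, tie-breaks) are this
package's design; they are all configurable, and a user-supplied mature
mRNA bypasses reconstruction entirely.

Pan-edited transcripts have no seed match on the pre-edited sequence,
so reconstruction iterates: after each pass the partially edited
template is rebuilt, seeds are re-tiled along it, and unmapped reads get
another chance (`max_iterations`, default 3, each round extending the
mapped set).  Insufficient coverage yields a partial pathway with an
explicit 5′ frontier site; sites 5′ of the deepest supported site keep
their pre-edited values.

## Read classification and misediting

Per uncensored site, with pre-edited run `p`, main-pathway run `m` and
read run `r`:

* `r == p` — unedited;
* `m != p` and `r` between `p` and `m` (same direction, shorter or
  equal) — main-consistent;
* otherwise alternative, subtyped *never-edited-site* (`m == p`,
  `r != p`), *longer-indel* (same direction, `|r−p| > |m−p|`) or
  *direction-reversed*.

A read is *reference* if every observed site is pre-edited, *main* if no
site is alternative, else *alternative* — a strict trichotomy, asserted
over all simulated reads.

Alternative reads merge into **editing intermediates**: containment is
computed on editing states over uncensored site ranges (not on raw
strings), so identical editing observed through different read lengths
merges; chains of containment are resolved against maximal intermediates
only.  A read contained in `k` retained intermediates contributes `1/k`
support to each, making total support exactly equal to the number of
merged reads (asserted on random merge problems).  Each intermediate's
alternative stretches are annotated *terminal* (no canonically edited
site 5′ of the stretch within the read — abortive editing at the
frontier) or *internal* (framed by canonically edited sequence);
intermediates with both kinds are *mixed*.

`misediting_summary()` reports, per editing domain, the three-way read
split and the percentage of alternative reads among *edited* reads
(reads with at least one non-pre-edited uncensored site — the natural
denominator for a three-way pre-edited/main/alternative split), plus a
histogram of alternative-site counts per read and the intermediates
ranked by support.  `domain_order_analysis()` cross-tabulates, over
reads spanning two domains, which domains are edited — the package's
test simulations enforce completion of the 5′ domain before the 3′
domain starts, matching the domain order observed in multi-domain
transcripts, and the "3′ only" cell is asserted empty under that order.

## gRNA candidate search

A gRNA gene is a genomic stretch complementary to *edited* mRNA with G-U
wobble pairs allowed.  The search reverse-complements the edited
transcript, takes every 25-mer within the editing domains (step 1), and
matches both contig strands allowing up to 5 substitutions per 25-mer —
only `A→G` and `C→T`, genome relative to seed, the two directions that
create G-U pairs in the duplex; the reverse substitutions are rejected.
Overlapping hits merge only when on the same contig/strand/diagonal at
consecutive offsets, which (a) preserves the per-window wobble cap for
every constituent 25-mer of a merged anchor and (b) refuses to merge
hits that would imply an indel in the duplex.  Candidates need at least
one supporting read sharing a ≥ 25-nt exact substring with the anchor
(implemented as shared 25-mers, reverse complement included unless the
library is strand-specific).  Because the merging granularity of
published candidate counts is ambiguous, `glance()` reports both the
merged-anchor and raw seed-hit counts.  Upstream-flank A and A+C
fractions are reported descriptively, with no threshold.

## The simulator

`simulate_locus()` / `simulate_reads()` generate the ground truth the
test suite measures against:

* a random cryptogene (skeleton over A/C/G, geometric pre-edited T runs,
  mean 0.6), one or two editing domains, a never-edited 3′ tail carrying
  the anchoring seed region;
* a mature state drawn per site (insertion probability 0.35, geometric
  insertion sizes of mean 2, deletion probability 0.08) — site densities
  of the same order as the per-gene counts the package's
  `perkinsela_editing_counts()` table records (roughly one edited site
  per 2–3 sites, ~2 U per insertion event);
* a 3′→5′ cascade of gRNA-sized blocks (45 nt of edited sequence per
  block, the span covered by an average gRNA), the 5′ domain completing
  before the 3′ domain; each block is guaranteed one edited site so that
  editing frontiers are identifiable (switchable off);
* transcripts with an editing frontier — blocks 3′ of it edited, 5′ of
  it pre-edited — with half the mass on the fully edited product and the
  rest uniform over intermediate frontiers;
* misediting at the two granularities observed in real data: a
  *terminal* alternative stretch (1–3 sites) just past the frontier with
  per-read probability `misedit_rate` (default 0.1), and *internal*
  alternative values per edited-region site with probability
  `internal_misedit_rate` (default 0.01).  The defaults are free
  parameters chosen to land the alternative-read fraction in the tens of
  percent, the regime reported for real edited domains (19–52%);
* error-free reads of configurable length and strandedness (a
  substitution-error rate exists but defaults to 0, because the analysis
  treats mismatches as near-disqualifying).

For full-length reads, the probability that a read is alternatively
edited has a closed form over the frontier distribution
(`expected_alternative_fraction()`), which the acceptance suite compares
with the observed fraction within three binomial standard errors.

All sampling derives from `rng_seed` via R's integer RNG; outputs are
bit-reproducible and the caller's RNG stream is left untouched.

What the simulator does **not** emulate: sequencing errors and quality
scores, indel sequencing artefacts, library-preparation and coverage
biases, multiple cryptogenes competing for reads, and gRNA sequence
biology beyond block geometry.  Tests passing on simulated data
therefore demonstrate the *algorithms* (exact recovery of planted truth,
conservation laws, closed-form agreement), not robustness to every
artefact of real libraries.

## Table-scale synthetic constructions

No real *Perkinsela* transcript sequences are shipped with the package,
so table-scale checks use
`synthetic_transcripts_from_counts()`: deterministic, fully synthetic
pre-edited/edited pairs that plant the published per-region
U-insertion/U-deletion/edited-site counts exactly (deletion sites carry
single pre-edited Ts, insertion sites share the planted insertion mass).
Running `diff_editing()`/`editing_stats()` over all six genes of each
strain must then recover the published column totals by computation.
Where the published table is internally inconsistent (rows whose printed
edited size differs from `pre + insertions − deletions`, and one strain
total that differs from its own column sum), the package reports its own
consistent arithmetic; the conservation identity is the invariant the
code guarantees.

## Numerical and formatting choices

* Percentages are rounded half-up to integers to match per-gene table
  formatting; raw values are always returned alongside.
* Translation uses NCBI genetic code 4 (mold/protozoan mitochondrial,
  TGA = Trp), configurable; the longest sense-strand ORF is taken, and
  an ORF running into the transcript end counts.
* Pairwise identity uses a global alignment with unit mismatch/indel
  costs; gap columns count as differences, so the difference count
  equals the unit-cost edit distance (cross-checked against
  `utils::adist`), and identity is `100 · identical / alignment_length`.
  The alternative convention (ignoring end gaps) is isolated behind this
  one function.
* Degenerate inputs: empty read sets yield empty, well-formed outputs;
  all-T sequences decompose to an empty skeleton; empty alignments score
  0.

## Problem sizes

The test and acceptance suites run entirely on generated data, sized to
exercise every code path while staying lightweight: loci of 30–120
skeleton bases (10–60 editable sites per domain), coverages of 20–1000×,
read lengths of 30–500 nt, 20 simulator configurations for
mature-state recovery, 1000-case algebra round trips, 200 alignment
oracle instances, 100 merge-conservation problems, and planted gRNA
contigs of a few hundred bp with wobble counts spanning 0–6.

## Known limitations

* One cryptogene is processed at a time; reads from paralogous loci are
  not disambiguated.
* The reconstruction guards (`min_support`, `min_fraction`) assume the
  mature product is the predominant edited form; a genuinely bistable
  editing system would need the bypass mode with explicit candidate
  products.
* The gRNA search reports sequence-level candidates only: no duplex
  thermodynamics, no anchor/guiding partitioning, no assignment of
  candidates to editing blocks.
* SAM output carries editing states in custom tags (`ZS`, `ZR`, `ZC`);
  standard viewers display the alignments but are unaware of the tags.
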