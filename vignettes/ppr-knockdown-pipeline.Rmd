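---
title: "Designing and verifying a PPR-protein knockdown of an organelle transcript"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and verifying a PPR-protein knockdown of an organelle transcript}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprcleave)
```

## The problem

Plant mitochondria cannot be transformed, so loss-of-function genetics for
mitochondrial genes needs a detour through the nucleus. Pentatricopeptide
repeat (PPR) proteins provide one: they are nuclear-encoded, imported into
the organelle, and bind RNA sequence-specifically, one base per ~35-amino-acid
repeat. Members of the restorer-of-fertility-like clade induce cleavage of
the transcript they bind. Retargeting such a scaffold to a chosen mRNA
therefore yields a sequence-programmable knockdown, and the experiment has a
well-defined computational skeleton:

1. choose a target site in the mitochondrial genome that the scaffold can be
   retargeted to with few residue changes;
2. predict the residue substitutions and the expected cleavage products;
3. verify cleavage from circularized RT-PCR (cRT-PCR) clone sequences and
   from RNA-seq 5′-end profiles;
4. quantify downstream molecular consequences (splicing, editing) and
   physiological ones (adenylate status, amino-acid pools, flux control).

`pprcleave` implements each step behind a small, testable surface. This
vignette explains the models, the defaults and their rationale, and the
choices made where the design was genuinely open.

## The PPR code and scaffold redesign

A scaffold is an ordered list of motifs, each carrying two specifying
residues (in the common numbering, repeat positions 5 and 35). A *code
table* maps a residue pair to a graded preference over the four bases:
`perfect`, `partial`, `neutral` or `mismatch`. Binding prediction aligns
motif *i* with target base *i*, N-terminal motif opposite the 5′ base, and
classifies each pairing; a configurable weighted sum (defaults
perfect = 2, partial = 1, neutral = 0, mismatch = −2, not derived from any
measurement) summarizes the prediction.

Three conventions matter:

* **Unknown residue pairs classify as neutral.** Neutral is the
  non-committal class; an unobserved combination carries no evidence either
  way.
* **Which residues are "specifying" is an annotation, not an inference.**
  Scaffolds arrive as pre-annotated motif tables; the package does not parse
  protein sequence.
* **L-class motifs receive no special treatment**: if their residue pair is
  in the table it scores like any other.

`redesign()` substitutes, at every offending motif, the first residue pair
in the code table classified perfect for the opposing base — table order
makes the result deterministic. The default mode fixes only mismatches (the
minimal intervention that removes all predicted incompatibilities); strict
mode fixes everything not perfect. Both behaviours are exposed because
experimental designs have used either.

The shipped default code (`default_ppr_code()`) covers the canonical
P-class pairs and is assembled from the published PPR-code literature. It is
a convenience: the test suite exercises all logic with explicit small
tables, so no correctness claim rests on the default's biology. The shipped
16-motif scaffold is likewise a synthetic example (its residues and perfect
target are internally consistent but are not a published protein's).

## Coordinates, site scanning and fragment prediction

External coordinates are 1-based inclusive, GenBank-style, and intervals on
the reverse strand are written 5′→3′ (start > end) — the convention in which
organelle literature prints gene spans. A reverse-strand CDS whose 5′ base
sits at genome coordinate *s* maps CDS position *p* to *s* − *p* + 1; the
forward strand maps to *s* + *p* − 1. Round-trip identity is tested
exhaustively on toy models.

`fuzzy_scan()` reports *every* window within the mismatch budget on either
strand (degenerate IUPAC letters in the query match their base sets at zero
cost), sorted by (mismatches, coordinate), with no suppression of
overlapping hits: the search is exhaustive even though a designer will
typically take the single best site. Circular genomes are supported behind a
flag (plant mitogenomes are drawn circular); wrapped windows are reported
with end < start. Internally the scan runs on
`Biostrings::matchPattern`; the test suite holds it against a brute-force
all-window Hamming oracle on 200 random kilobase genomes.

`predict_fragments()` encodes the bookkeeping that links a cleavage position
to observable band sizes: 5′ fragment = 5′ UTR + cut position, 3′ fragment =
remaining CDS + 3′ UTR; the two always sum to the transcript length. For the
shipped *atp1* model (1,524 nt CDS, 520 nt of UTRs) any cut yields fragments
summing to 2,044 nt. Only the combined UTR length is directly annotated for
this gene; the shipped 363/157 split is derived from the observed mature
transcript and downstream-fragment sizes and is marked as derived in the
data file.

## Mapping transcript ends from cRT-PCR clones

Circularizing a transcript fragment and sequencing across the ligation
junction puts both of its ends in one read: the clone is
reference[… → 3′ end] followed by reference[5′ end → …], in transcript
orientation. `locate_junction()` finds the split position where both sides
map exactly and contiguously with at least `min_anchor` (default 15 nt,
roughly the uniqueness scale of a 10-kb genome) on each side. Exact
anchoring rather than alignment is deliberate: cRT-PCR products are
near-exact reference copies, and exactness keeps the operation invertible
and the tests constructive.

One subtlety is inherent to the assay: if the base just past the 3′ end
equals the base at the 5′ end, splits shifted by one (or more) positions
produce the *identical* clone sequence. No mapper can distinguish members of
such a shift family. The package collapses a family to its canonical member
(maximal 3′ extension) instead of discarding the clone; genuinely distinct
split solutions (for example caused by repeated sequence) still raise an
ambiguous-clone error, and `map_clone_ends()` excludes and counts such
clones rather than dropping them silently. The synthetic clone generator
records canonicalized end coordinates as its truth for the same reason — it
is the truth any exact mapper can recover.

`call_consensus()` tallies clone 5′ ends, reports the boundary as the
adjacent base pair flanking the cut ("cleavage between bases x and y"), the
support count, and the span of all observed ends. Ties between equally
supported 5′ ends are broken toward the binding site's 3′ edge when one is
supplied — the mechanistically expected cleavage region — and flagged
multi-modal otherwise.

## 5′-end profiles and genotype comparison

A cleavage event creates a new 5′ end: the downstream fragment's first base
gains a sharp, genotype-specific spike in per-position counts of read 5′
termini (reverse-strand reads contribute their rightmost aligned base).
`smooth_normalize()` makes profiles comparable across libraries and
positions: counts are scaled to the mean library size, averaged over a
centered window (`smooth_window`, default 5 nt; 1 disables smoothing), and
divided by the local background — a running median over `background_window`
(default 201 nt) plus a pseudocount (default 0.5). The defaults are not
taken from any publication; they were chosen so that a single-nucleotide
spike survives smoothing (5 nt ≪ peak spacing) while the background median
is estimated from a window long enough (201 nt) to be insensitive to the
peak itself. The median, unlike a mean, ignores the spike entirely. The
pseudocount regularizes empty regions; with it, a lone spike of height *h*
on a zero background normalizes to *h*/pseudocount, and a uniform profile
normalizes to values just below 1 (exactly 1 when the pseudocount is 0).

`compare_genotypes()` tests each candidate position (pooled normalized mean
at or above `floor`, default 2, i.e. at least twice background) with an
equal-variance two-sample t statistic on replicate normalized values,
reporting two-sided raw p-values and Benjamini–Hochberg adjusted p-values
across candidates. Raw p-values are emitted alongside adjusted ones because
the comparison is often made for one or two pre-specified positions, where
the raw value is the quantity of interest; the adjusted value is the one to
use when scanning the transcriptome.

With three replicates per genotype, the unmoderated t statistic has a known
pathology: a position whose replicate values are nearly identical by chance
gets an enormous statistic regardless of effect size. `call_cleavage_sites()`
therefore defines the package's detection rule for *gained* peaks: keep
positions elevated in the test genotype at raw p ≤ α, then rank by fold
enrichment of the normalized signal. A genuine cleavage site is both
statistically elevated and strongly enriched; ranking by enrichment among
significant candidates is robust to variance flukes without touching the
reported statistics.

At single-nucleotide calling resolution, profiles are normalized with
`smooth_window = 1`: a moving average spreads a point mass evenly over its
window, which blurs the argmax by up to the half-window, so smoothing is for
visualization and regional comparison, not for pinpointing a cut.

## Splicing, editing and physiology readouts

Splicing efficiency is defined from junction-spanning evidence:
spliced/(spliced + unspliced) per replicate. The definition is the minimal
one consistent with counting; transcript-level ratio alternatives exist, and
the junction-read definition is labelled as such. Trans-spliced introns —
whose halves are transcribed separately and joined in trans, so the
downstream half's 5′ end appears as a natural profile peak — are handled
identically once their half-junction evidence is reduced to
spliced/unspliced tallies. Genotype comparison uses an equal-variance t
test, one-tailed in the direction "knockdown less spliced than control";
when both efficiency vectors are constant and equal the statistic is 0 and
the one-tailed p is 0.5 by convention. Editing rates are the analogous
pileup ratio edited/(edited + unedited), with the relative rate the ratio of
genotype means.

The adenylate energy charge is (ATP + ½ADP)/(ATP + ADP + AMP), bounded in
[0, 1] and invariant to common rescaling of the pools. The flux control
coefficient from a single knockdown is estimated in log-ratio form,
ln(flux fraction remaining)/ln(enzyme fraction remaining) — the
finite-difference version of the scaled sensitivity d ln *J*/d ln *E*. It is
a one-point estimate, documented as this package's estimator choice: with
flux at 56% and enzyme at 20% of control levels it gives ≈ 0.36, i.e.
moderate control. Amino-acid family aggregation checks that the family map
partitions the measured amino acids, returns absolute totals and fractions
of the total pool, and emits the Gly/Ser ratio when both are measured.

## What the synthetic generator emulates — and what it does not

`simulate_genome()` builds a 10-kb genome with three genes: a forward gene
with a cis intron, a reverse-strand target gene (the planted 16-nt binding
site, at a configurable Hamming distance — default 5 — from the scaffold's
perfect target, sits in its CDS with the cleavage boundary 44 nt further
3′), and a forward gene with a trans-spliced intron. 10 kb with three genes
is small enough for exhaustive oracles yet long enough that the 201-nt
background window always sits inside a homogeneous region.

`simulate_end_counts()` draws per-position 5′-end counts: background
proportional to transcript abundance (default mean 20 per position for unit
abundance), natural peaks at transcript starts and at the trans-spliced
half-intron start (default 50× gene background; the half-intron peak scales
with the unspliced fraction), and — in the knockdown only — a point mass of
cleaved fraction × peak-scale × gene depth at the boundary's downstream 5′
side (default cleaved fraction 0.5 over 3 replicates per genotype,
mirroring a typical replicate structure). Replicate noise is negative
binomial with dispersion 0.1, a typical RNA-seq replicate overdispersion;
dispersion 0 is the exact deterministic limit, used by tests that assert the
expected point mass. Junction and editing evidence are binomial draws at the
planted fractions (defaults: splicing 0.9 control vs 0.7 knockdown; editing
rates uniform on 0.5–0.95 with a 0.9× knockdown shift across 10 sites).
Clones are reference concatenations with a jitter distribution over ends
whose mode (42%) is the exact boundary. Every generator accepts a seed, and
a fixed seed reproduces outputs byte-for-byte.

Deliberately *not* emulated: read-level error models and quality strings,
soft-clipping and indels, 5′ phosphorylation chemistry that distinguishes
transcription starts from processed ends, PCR duplicates, and any
genome-wide base composition structure. Passing tests therefore demonstrate
that the algorithms recover planted truth under realistic count noise — not
that they are robust to alignment artefacts or library-preparation biases in
real data.

## Numerical choices and degenerate inputs

* U and T are interchangeable on input; the internal canonical alphabet is
  DNA. Invalid symbols are input errors, not silent drops.
* Zero-coverage replicates in ratio estimators return `NA` with a warning;
  all-zero adenylate pools, empty clone sets and out-of-range coordinates
  are classed input errors.
* In the per-position t test, zero pooled variance with equal means gives
  t = 0 (p = 1); with unequal means, ±∞ (p = 0).
* The moving average uses shrinking windows at profile edges so every
  position keeps a value; the running median uses `stats::runmed` with
  median end rules.
* Null calibration of the per-position test holds where the test has data:
  on expressed positions the raw p < 0.05 rate is 5% within binomial error
  (verified in the acceptance suite on three simulated null datasets);
  zero-coverage positions are degenerate (p ≡ 1 by construction).

## Problem sizes used by the test suite

The suites run at sizes chosen to keep the full check under a few minutes on
one core while leaving no oracle approximate: 200 random 1-kb genomes for
the scan-vs-oracle equivalence; the complete 4⁶ target enumeration for
strict redesign; 100 seeded 3-vs-3 simulations (10-kb genome) for planted
cleavage-site recovery, of which at least 95 must land within ±1 nt; three
null datasets (~4,400 expressed positions) for calibration; 36-clone
jittered and 100-clone noise-free cRT-PCR simulations; depth-200 binomial
evidence for splicing/editing accuracy (mean absolute error ≤ 0.05).

## Known limitations

* The code table treats motifs independently; cooperative or
  position-dependent effects, and binding-affinity prediction generally, are
  out of scope.
* `redesign()` substitutes whole residue pairs from the table; it does not
  search for minimal *nucleotide-level* mutation paths in the protein's
  coding sequence, nor design cloning constructs.
* Junction mapping is exact-match; heavily mutated or chimeric clones
  surface as excluded, not rescued. A mismatch-tolerant mode would require
  alignment and a rethought ambiguity rule.
* The per-position test assumes replicate normalized values are
  approximately normal; at three replicates the raw p-values are calibrated
  in simulation but have little power, which is why detection ranks by
  enrichment among significant candidates.
* Fragment-size prediction ignores post-transcriptional tailing and
  secondary 5′→3′ trimming of cleavage products.
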