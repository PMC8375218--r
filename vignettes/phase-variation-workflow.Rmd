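---
title: "Quantifying invertible-promoter phase variation and phage persistence metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying invertible-promoter phase variation and phage persistence metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaseflip)
```

## The biological system

Gut *Bacteroides* species decorate themselves with capsular polysaccharides
(CPS) whose biosynthesis operons are frequently controlled by *invertible
promoters*: a short promoter cassette (~183–186 bp in the loci this package
was designed around) flanked by a perfect inverted repeat (canonically the
10 bp arm `GTTCGTTTAA`). Serine-family recombinases acting at the arms flip
the cassette between an ON orientation, which drives the downstream operon,
and an OFF orientation, which silences it. Because the flip is reversible
and heritable, a clonal culture is really a mixture of expression states —
*phase variation*. The mixture matters ecologically: CPS variants serve as
receptors or shields for bacteriophage, so the ON/OFF composition of a
population controls what fraction of cells a phage can infect, and thereby
whether phage and host can coexist long-term ("herd immunity" plus a
restricted, slowly replicating sensitive subpopulation).

`phaseflip` implements the computational side of studying such a system:

1. **Locus discovery** (`findInvertedRepeatLoci`, `matchIupacMotif`):
   find spacers flanked by perfect inverted repeats, seeded by a known arm
   or de novo.
2. **Orientation quantification** (`quantifyOrientations`): estimate, per
   locus, the fraction of cells in the ON orientation from paired-end
   reads.
3. **Long-read rearrangement detection** (`splitMap`,
   `chainReadBlocks`, `detectRearrangements`, `hotspotHistogram`): find
   within-read inverted or displaced alignment blocks and call
   recombination hotspots genome-wide.
4. **Phage–host population metrics** (`estimateVMR`, `perCapitaProgeny`,
   `detectBurstSteps`, `adsorptionConstant`, `efficiencyMetrics`).
5. **Synthetic data with truth** (`makeGenome`, `assignOrientations`,
   `simulatePairedReads`, `simulateLongReads`, `simulateMetagenome`), so
   that 1–4 are testable end-to-end without external data.

## Coordinate conventions

All objects use the Bioconductor convention: 1-based, closed intervals, on
the forward strand of the reference, carried in `GRanges`/`IRanges`
containers. External formats are converted at the boundary: PAF (0-based,
half-open) and BLAST tabular (1-based, subject interval reversed on the
minus strand) are normalised by `parseAlignmentTable` so that
`ref_start <= ref_end` always holds, with a `strand` column carrying the
orientation.

## Locus discovery

A locus is modelled as `arm + spacer + reverse complement of arm`. In
seeded mode every occurrence pair of a known arm motif and its reverse
complement with a spacer length inside `spacer_range` is reported. In de
novo mode the genome is compared against its own reverse complement via
exact k-mer seeds (k = `min_arm_len`); seeds on a common antidiagonal are
extended outward and inward while the positions remain perfect
complements, yielding *maximal* arms. Candidates are then filtered to
`spacer_range` and deduplicated greedily: longest arm first, then smallest
spacer (local pairing), then leftmost. The defaults — `min_arm_len = 10`,
`spacer_range = c(150, 250)` — bracket the 183–186 bp promoter cassettes
with margin on both sides; in random sequence a 10 bp complementary pair
within a ~100 nt spacer window occurs by chance every few tens of kb, so
candidate lists from de novo scans should be intersected with annotation
or a seed motif for biological interpretation. Whether a reported
"promoter length" includes the arms is a convention choice; here the
spacer is the interval strictly between the arms.

Degenerate motif matching (`matchIupacMotif`) delegates to
`Biostrings::matchPattern(fixed = FALSE)` on both strands; the test suite
checks it against an independent regex-expansion oracle.

`setOrientationConvention` resolves which physical orientation is called
ON. From coordinates alone the promoter's direction is unknowable — the
arms are sequence-invariant under inversion — so the caller supplies the
promoter's direction in the reference orientation (e.g. from
transcription-start mapping), and the function finds the nearest operon
the promoter could drive within a window (default 5 kb). Loci without an
eligible operon fall back to "reference is ON" and are flagged.

## Orientation quantification

The estimator is *competitive dual-reference alignment*. For each locus,
two haplotypes are built (`buildDualReferences`): the locus ±1 kb of flank
as in the reference (ON), and the same window with the
`[left arm start, right arm end]` segment reverse-complemented in place
(OFF). Since the arms are perfect inverted repeats, the two haplotypes
differ *only inside the spacer* — arms and flanks are byte-identical — so
a read pair carries orientation information exactly when one of its mates
overlaps the spacer. Each pair is aligned to both haplotypes
(`minimalMap`, below); it is called ON when it aligns concordantly to the
ON haplotype with at least `min_informative_overlap = 10` spacer bases and
fails, or scores lower (summed identity), on the OFF haplotype;
symmetrically for OFF; everything else is AMBIGUOUS. Concordance means:
both mates mapped to the same haplotype, opposite strands,
forward–reverse orientation, outer insert within `[100, 1000]` nt
(bracketing a ~350 bp library; aligners do not publish a universal
definition, so the contract is explicit here).

Counts are summarised per locus with the ON fraction and a Wilson 95%
interval — chosen over the Wald interval because locus fractions near 0
or 1 are common and the Wilson interval remains calibrated there. Loci
with zero informative pairs are reported with counts (0, 0) and an
`undefined` flag rather than a fabricated fraction. Pairs informative for
several loci (possible only when loci sit closer than a flank) go to the
locus with the larger spacer overlap; ties are dropped as ambiguous.

An alternative to competitive alignment would be single-reference
breakpoint-spanning logic (count pairs whose orientation pattern is
discordant at the locus); competitive alignment handles reads ending
inside the arms correctly and needs no special-casing, which is why it is
the implementation here.

## The internal mappers

Real studies use a production aligner and feed SAM/PAF/BLAST tables in;
`phaseflip` additionally ships two small mappers so synthetic data flows
end-to-end without external tools:

* `minimalMap` (C++): exact k-mer seeding (k = 21, three seeds per strand:
  read start, middle, end) plus ungapped full-read extension; only a
  unique best placement is reported, ties are unmapped, so ambiguous
  placements can never pollute orientation counts. A 21-mer is effectively
  unique in a few-Mb genome and at least one of three seeds survives
  low substitution error with high probability.
* `splitMap` (data.table joins): every read k-mer is matched against the
  reference on both strands; co-diagonal seeds are grouped into local
  blocks, and groups are split where consecutive seeds are more than
  `max_seed_gap = 100` nt apart on the read — that split is what turns a
  read across an inverted segment into the `+ / − / +` block signature
  downstream modules look for. Block identities are computed by direct
  sequence comparison. Block edges are fuzzy by up to k−1 nt (k-mers
  straddling a junction match nothing), which is irrelevant at 1 kb bin
  resolution.

Neither mapper handles indels; the synthetic error model is substitutions
only, and real data should come through a real aligner.

## Long-read rearrangement detection

Blocks (from `parseAlignmentTable` or `splitMap`) are filtered with the
canonical thresholds for this analysis: reads > 1000 nt, blocks > 200 nt
and > 90% identity, e-value ≤ 1e-20 where present — all strict
inequalities, applied bit-exactly. Within each read, blocks are ordered
along the read axis (reference order is free to disagree; the
disagreement *is* the signal). Adjacent blocks on opposite strands emit an
`inverted` event anchored at the boundary of the minority-strand block
facing the junction, so a fully spanned inversion contributes one event
at each edge of the inverted segment. Adjacent same-strand blocks whose
reference gap differs from their read gap by more than 200 nt emit a
`displaced` event carrying the shift. Only *adjacent* pairs are compared;
comparing every block against every other would also flag secondary
junctions of complex shuffled regions, at the cost of quadratic event
inflation — the adjacent-pair reading is the conservative choice.

Event start coordinates are binned into 1000 nt windows. "Hotspot" needs
an explicit threshold; the default is
`max(5, qpois(0.999, total events / bins))` — the 99.9th percentile of a
uniform Poisson background, floored at 5 — and the raw histogram is
always returned so users can re-threshold. Structural resolution of
shuffled regions (which segment went where) is out of scope; such regions
appear as hotspots only.

## Population metrics

* **VMR** — virus-to-microbe ratio from shotgun co-culture sequencing:
  `(phage bases / phage genome length) / (host bases / host length)`,
  with bases counted from alignment spans rather than read counts so the
  estimate is robust to read-length differences between libraries.
* **Per-capita growth** — a one-step growth curve divided by the number of
  infected cells at time zero.
* **Burst steps** — the multi-burst staircase reading of a growth curve is
  made reproducible: binary segmentation on log10 per-capita values
  minimising within-segment squared error, accepting a split only when
  the adjacent segment means jump by at least log10(1.5). Zero titers are
  floored at half the assay detection limit before the log transform
  (standard plaque-assay handling). The detector is idempotent: refitting
  its own piecewise-constant fit returns the same changepoints.
* **Adsorption constant** — first-order kinetics,
  `k = ln(p0/pt) / (N t)`; a rising titer yields a negative `k` with a
  warning rather than an error.
* **EOP / EOCI** — `100 × count_with / count_without`.

## The synthetic-data generator

The generator emulates the study design the analysis modules target:

* genome: random background (GC 0.42, Bacteroides-like) with non-
  overlapping planted cassettes `GTTCGTTTAA + spacer(183–186) + TTAAACGAAC`,
  placed by an exact spacing construction (uniform over valid
  configurations) with ≥2.5 kb separation so inserts and flanks never
  bridge loci; the reference state is ON by construction;
* population: independent Bernoulli ON/OFF per cell per locus; OFF is
  realised by reverse-complementing the whole `[left arm, right arm]`
  segment, so the arms are invariant and the recombination breakpoint
  within the arm is unobservable — as in real data;
* short reads: 2×150 nt, Normal(350, 35) inserts truncated at the read
  length, i.i.d. substitutions at 0.1%;
* long reads: log-normal lengths fitted in closed form to median 1882 nt
  and IQR 4697 nt (`fitLongReadLengths`), sampled by rejection inside
  `[50, genome length]` — a floor of 50 nt rather than a few hundred,
  because a higher floor clips enough of the left tail to shift the
  sample median by >10% away from the configured value; substitutions at
  5% by default (per-sample error rates are rarely published; 5% is a
  representative figure for the relevant nanopore chemistry and is
  configurable);
* metagenome mixtures: single-end reads with the phage-read probability
  `vmr·Lp / (vmr·Lp + Lh)`, so the expected length-normalised coverage
  ratio equals the requested VMR.

Truth tables record, per fragment or read: source cell, coordinates,
overlapped locus, its orientation in that cell, and the spacer overlap —
sufficient to compute every downstream module's expected output without
re-alignment.

What the generator does **not** emulate: indels and homopolymer errors,
quality-score structure, GC or fragmentation bias, chimeras, plasmids,
within-arm breakpoint heterogeneity. Passing tests therefore demonstrate
correctness of the algorithms under a clean error model, not robustness
to every artefact of real libraries; for real data the package expects
alignments from production tools.

## Problem sizes and numerical choices

The validation suite runs at deliberately compact scales chosen to keep
estimator noise far below the tolerances being checked: orientation
recovery uses 4 loci on a 16 kb genome with 5000 cells and exactly 20,000
informative pairs per locus (binomial standard error ≈ 0.004, checked
against ±0.02); interval calibration uses 100 replicate populations with
count-level pair draws reported through the same Wilson-interval code
path (full read-level replication would add nothing to the interval
check but two orders of magnitude of runtime); hotspot recovery uses a
50 kb genome, 3 loci, 500 zero-error long reads (~20–50 events per locus
bin against a Poisson background of ~1–3); repeat-finder equivalence uses
50 × 10 kb genomes against a brute-force all-pairs oracle; VMR recovery
uses 200,000 reads against a 50 kb host and 10 kb phage. Ties in binary
segmentation resolve to the first candidate; ties in best-placement
mapping resolve to unmapped; the hotspot threshold floor of 5 events
guards the Poisson rule when very few events exist.

## Limitations

* Perfect arms only: loci whose repeats have mutated are invisible to the
  finder by design (`min_arm_len` trades sensitivity against chance hits).
* The orientation estimator assumes the two orientations differ only
  within the locus; structural variation in the flanks will push pairs to
  AMBIGUOUS rather than mis-call them.
* The burst-step detector is an explicit operator standing in for what is
  usually a by-eye reading; its factor threshold (1.5) is a tuning
  parameter, not an inferred quantity.
* Internal mappers are substitution-only and ungapped; use a production
  aligner for real libraries and feed the tables in.
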