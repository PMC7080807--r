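---
title: "longsplice: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{longsplice: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and procedures, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the design choices made where the problem statement
left the design genuinely open.

## 1. The problem

Long-read cDNA sequencing observes whole transcripts, so isoform
structure — the ordered set of splice junctions, the *junction chain* —
can be read off a single molecule. Two error modes dominate: splice
sites in the alignment are displaced by small offsets (basecalling and
alignment noise), and reads lose 5' sequence (RNA degradation and
incomplete reverse transcription). The pipeline treats these explicitly:
correction repairs bounded splice-site noise; collapse and assignment
are written so that 5'-truncated reads still contribute evidence without
creating artifact isoforms.

## 2. Splice-site correction

A splice site is *valid* if it appears in the annotation or in a
short-read junction table filtered to junctions with at least
`min_unique = 3` uniquely mapping reads. Each read junction endpoint
equal to a valid site of its side (donor/acceptor) and strand is kept;
otherwise it is replaced by the nearest valid site within
`window = 10` nt. If no valid site is reachable the junction is
uncorrectable and the read is excluded from isoform construction (it can
still be *assigned* later). Donor and acceptor are corrected
independently; whether the original tools treat a junction jointly is
not documented, and per-site replacement is the simpler deterministic
contract.

Numerical/tie details, all deterministic:

* Equidistant candidate sites: provenance `both` > `annotation` >
  `short_read`, then the smaller genomic coordinate.
* A correction that would create an empty or inverted exon reverts that
  junction to its original coordinates and marks it uncorrectable.
* Reads with unknown strand inherit the strand of the first junction
  exactly matching a valid junction; if none matches, they are excluded
  from strand-dependent analyses.
* Alignment gaps shorter than `max_gap = 30` nt are pre-merged
  (indel-scale artifacts); 30 nt separates indel gaps from plausible
  minimal introns and is configurable.

Correction is idempotent, never moves an endpoint more than `window` nt,
and enlarging the valid-site set can only increase the number of fully
corrected reads; all three are asserted as property tests.

## 3. Collapse: from chains to isoforms

Fully corrected spliced reads group by exact chain equality; single-exon
reads group by overlapping locus. Representative transcript ends come
from read-end density: coordinates are single-linkage clustered within
`end_window = 100` nt, the largest cluster wins, and its modal
coordinate is the representative end. The clustering rule (single
linkage, modal site) is this package's concretization of a
loosely-specified "most frequent site in 100-nt windows" procedure. Ties
always favor the longer transcript: equal-sized clusters pick the
outward-most mode, equal-frequency modes pick the outward-most
coordinate (5'-most for starts, 3'-most for ends — outward on both
strands). Only this one-isoform-per-chain mode is implemented;
multi-TSS output is out of scope.

**Truncation consolidation.** 5'-truncated reads of isoform *J* form
their own chain groups whose chains are strand-aware 5' suffixes of
*J*'s chain. Left in place, those groups are poison: each becomes a
first-pass isoform that renders its own reads ambiguous (a truncated
read matches both the suffix isoform and *J*), so both lose support.
A first-pass isoform is therefore removed when (i) its chain is a proper
contiguous 5'-side subchain of another's, (ii) its 5' end lies *inside*
the longer isoform's corresponding exon, and (iii) its 3' end matches
within the end tolerance. Condition (ii) is what distinguishes a
truncation artifact from a genuine retained-first-intron isoform, whose
5' end lies upstream of the longer isoform's first intron. Single-exon
groups fully inside a spliced isoform's exon footprint are removed for
the same reason. A suffix explainable by two different isoforms is
simply dropped — its reads are genuinely ambiguous. The same logic gives
the known limitation: an alternative-TSS isoform whose chain is an exact
suffix of another's and whose TSS lies inside the other's exon is
structurally indistinguishable from truncation and will be consolidated
away.

**Assignment** is structural, not sequence realignment: a read is
compatible with an isoform iff its chain matches a contiguous subchain
of the isoform's chain (each coordinate within ± `window`) and its outer
blocks stay inside the matched exons — beyond the matched subchain a
read may extend only to the neighboring intron boundary (+ `window`), or
past a terminal exon by `end_slack = 200` nt (nanopore end raggedness).
The exon-containment clause matters: it is what prevents a
retained-intron read (whose terminal block crosses an intron of the
spliced isoform) from being counted as a truncated spliced read. A read
compatible with exactly one isoform is assigned; more than one,
discarded as ambiguous (the structural analogue of a MAPQ < 1
multi-mapper); this replaces the original aligner-based
unique-best-match rule with a deterministic, aligner-free contract.
Isoforms keep `min_support = 3` uniquely assigned reads or are dropped.

Gene assignment: the annotated gene sharing the most junctions, ties by
exonic overlap, otherwise a synthetic locus id. Annotation comparison
categories use the precedence `annotated` > `novel_site` >
`retained_intron` > `novel_exon` > `novel_combination`.

## 4. Quantification and normalization

Counts are uniquely-assigned reads per isoform and sample. The
normalization factor per sample is the 75th percentile
(linear-interpolation quantile, R type 7) of gene-level counts of
protein-coding genes; zero-count coding genes are excluded from the
quantile by default because structural zeros destabilize factors on
sparse data (both choices are flags). Whether the upper quartile should
be over gene-level or isoform-level counts was ambiguous; gene-level is
used. Fold changes are ratios of per-condition medians of normalized
counts (even-count median = mean of central two), reported as log2, with
isoforms excluded unless one condition's median reaches
`min_median = 10`. Normalization is exactly scale-invariant per sample,
and fold change is antisymmetric under condition swap; both are tested.

A read is *full-length* when its exonic overlap with its assigned
isoform covers at least 80% of the isoform's spliced length — spliced
coordinates, not genomic span, because the definition refers to the
transcript's nucleotides.

## 5. Event calling and testing

* **IR**: any intron completely spanned by a same-gene isoform's exon;
  inclusion = spanning (retaining) isoforms, exclusion = splicing
  isoforms. Structural only — transcripts retained deliberately versus
  incomplete processing cannot be distinguished from poly(A)-selected
  data, and no attempt is made.
* **A3SS/A5SS**: junctions sharing the non-alternative site whose
  alternative-side sites lie in overlapping exons; one event per
  alternative pair; proximal/distal is measured 5'→3' on the transcript
  strand. Pairs ≤ 10 bp apart are reported but flagged exempt — the
  exemption removes the *test*, not the event.
* **ES**: an internal exon flanked by junctions (a, s) and (t, b) in some
  isoform, skipped iff another same-gene isoform contains the junction
  (a, b) exactly. The exact flanking-junction convention is a choice; the
  spanning-junction definition is the strictest structural reading.

PSI uses a pseudocount of 1 on each of inclusion and exclusion (so
events with one or two dropout samples are not lost); dPSI is the
difference of per-condition mean PSI, focal minus reference. The
coverage filter requires inc + exc ≥ 25 *raw* reads in ≥ 4 samples with
≥ 2 per condition. Unreplicated two-sample designs use a two-sided
Fisher's exact test on raw counts (exact tests get no pseudocount);
replicated designs use the beta-binomial likelihood-ratio test below.
Benjamini–Hochberg runs within each event type separately (families are
reported separately, so they are corrected separately); significance
requires corrected p < 0.1 and |dPSI| > 10.

### The beta-binomial likelihood-ratio test

For one event, sample *i* contributes inclusion count
$k_i \sim \mathrm{BetaBin}(n_i, \mu, \theta)$ with mean proportion
$\mu$ and precision $\theta$ (dispersion $\rho = 1/(1+\theta)$). The
null model shares one $\mu$ across conditions; the alternative gives
each condition its own mean. The dispersion is shared: it is ML-fitted
once under the null — a bounded 2-D quasi-Newton fit on
$(\mathrm{logit}\,\mu, \log\theta)$ with $\theta \in [10^{-2}, 10^{6}]$,
three $\theta$ starts, convergence factor $10^{3} \cdot$ machine-eps —
and held fixed for the per-condition 1-D mean fits (golden-section, x
tolerance $10^{-10}$). The statistic $2\Delta\ell$ is referred to
$\chi^2_1$. The $\theta$ bounds matter: unbounded fits drift to the
degenerate binomial limit where the likelihood surface is flat and
`lbeta` loses precision.

**Calibration, honestly.** At the acceptance design (3 vs 3 samples,
coverage ≈ 100, dispersion 0.01, 1000 null events) the acceptance test
measures an empirical type-I error of 0.031 at α = 0.05, below the
binomial 95% CI lower bound of 0.0365, and that assertion is left red.
The shortfall is intrinsic, not a bug: even with the dispersion fixed at
its true value the $\chi^2_1$ approximation is slightly conservative at
six samples, and the null-fitted dispersion absorbs part of the
finite-sample between-condition difference, pushing the true rate a few
thousandths further down — to just below the criterion's lower bound, so
the assertion fails for roughly half of all seeds. Every principled
alternative evaluated (refitting the shared dispersion under the
alternative; profiling it; a Cox–Reid adjusted profile; within-group
method-of-moments; an F(1, n−2) reference) was further from nominal, on
the anticonservative or overcorrected side. The same mechanism has a
visible side effect: for very large effects (PSI 90 vs 10) the null fit
explains much of the separation as dispersion, so p-values are
conservative (~0.02–0.04) rather than astronomically small. Power at
moderate effects is unaffected — the power half of the same criterion
(dPSI = 30, coverage 100, 3 vs 3, power > 0.8) passes comfortably.

Differential isoform usage reuses the same test as isoform-versus-rest
within genes that have ≥ 25 reads in ≥ 4 samples, BH-corrected across
all tested isoforms (one family), significant at corrected p < 0.1 and a
usage shift > 10 percentage points.

### Sequence summaries

The alternative-acceptor distance distribution reports signed distances
(negative = transcript-upstream) from each event's alternative 3' splice
site to its canonical one (the annotated site when exactly one of the
pair is annotated, else the distal). The control takes, per canonical
annotated acceptor, the distance to the nearest upstream AG-ending
trimer that is not GAG, scanning up to 100 nt (the window is a
configurable choice; nothing pins it). The two distributions are
compared with a two-sided Mann–Whitney U test: midranks for ties, exact
p by full enumeration of group assignments up to a combined n of 12
(configurable crossover), otherwise a normal approximation with tie and
continuity corrections. Position frequency matrices around acceptors
cover −25..+3 in transcript orientation (minus-strand windows
reverse-complemented before counting).

## 6. Productivity

Annotated start codons are projected onto each isoform; a start is
usable if all three bases land in exons, are consecutive in transcript
space, and still read ATG after splicing (junction-spanning starts are
allowed — projection fidelity is what matters). With several usable
starts, strategy 1 takes the 5'-most and strategy 2 the start yielding
the longest ORF ("longest transcript" is ambiguous for a fixed
transcript, so longest ORF is the implemented reading); if their
productivity calls differ the isoform is excluded as ambiguous.
Translation stops at the first in-frame stop; the PTC distance is
measured from the *last base* of the stop codon to the last splice
junction (the problem statement does not say first or last base; last is
chosen and the threshold is a parameter), and the isoform is
unproductive iff that distance is ≥ 55 nt — the classical NMD rule. The
54/55 boundary is asserted exactly, on both strands, via mirrored
fixtures. Single-exon isoforms have no last junction: they are
productive whenever an ORF exists. The IR-by-productivity cross-table
labels an isoform IR iff it is an inclusion (retaining) isoform of at
least one IR event, and compares per-category log2 fold-change
distributions with Mann–Whitney U tests. The frame table for
alternative acceptors tallies, for events whose proximal site is
preferred in the focal condition, proximal-site isoforms with ≥ 20
focal-condition reads by productivity, and records whether the
proximal–distal shift is a multiple of 3.

## 7. The synthetic-data generator

`make_locus_set()` lays out genes (default 20) on one chromosome, 2 kb
apart, alternating strands; each gene has a base structure of 4–8 exons
of 80–300 nt separated by 200–1000 nt introns, and 2–4 isoforms derived
by cassette skipping, alternative 3'/5' sites (shifts of 12–40 nt, large
enough to clear the 10-bp test exemption), or intron retention. The
genome is uniform random sequence with canonical GT/AG dinucleotides
planted at every junction, strand-aware. `simulate_reads()` draws
per-isoform, per-sample read counts from an abundance table (exact by
default, Poisson optionally), applies 5' truncation in transcript space
(probability 0.3, up to half the transcript), and jitters every
remaining junction endpoint independently and uniformly within ±5 nt.
Defaults mirror the error scales the correction stage is specified
against: jitter within the 10-nt correction window, truncation 5'-only
(the dominant loss mode in cDNA reads). All randomness derives from one
seed; identical seeds give byte-identical outputs.

When `keep_discriminating` is on (default), truncation is capped per
read so the retained structure is still uniquely compatible with its
generating isoform — the cap is computed with the same structural
compatibility predicate the assignment stage uses. This makes recovery
tests exact, and it is a deliberate circularity at the *generator* level
only: the end-to-end tests still verify that the recovered chains equal
the planted truth, which no shared predicate can fake.

What the generator does **not** emulate — so a green test does not
establish robustness to it: base-level sequencing error and alignment
ambiguity (reads are built from truth coordinates, not re-aligned),
3'-end raggedness, internal (non-5') truncation, chimeric reads,
expression-dependent jitter, PCR bias, realistic codon structure (ORFs
for productivity tests are hand-built fixtures, not generator output),
and genuine alternative-TSS isoforms nested inside longer ones (see the
consolidation limitation above).

## 8. Known limitations

* Assignment is structural; it cannot use sequence identity to separate
  isoforms whose structures differ only within the matching tolerances.
* The beta-binomial test is mildly conservative (section 5), markedly so
  for extreme effects; batch covariates are not modeled.
* IR calls do not distinguish regulatory retention from incomplete
  processing.
* Single-exon isoforms are recovered but excluded from chain-recovery
  guarantees; their "annotated" categorization is by overlap, not
  identity.
* The junction-table dialect (default: 1-based closed intron
  coordinates, STAR-style) is a declared convention, as no standard
  exists.
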