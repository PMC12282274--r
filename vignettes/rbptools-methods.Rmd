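---
title: "Methods: head-domain classification, abundance and binding scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: head-domain classification, abundance and binding scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbptools)
```

## The biological model

*Skunavirus* phages adsorb to *Lactococcus* hosts through the
receptor-binding protein (RBP) at the tip of the tail. The N-terminal
shoulder and neck regions (~135 aa) are strongly conserved across the genus,
while the C-terminal **head domain** (~110 aa) is variable and contacts the
host's cell-wall polysaccharide (CWPS). Head-domain sequence therefore
predicts host range, and a sequence-identity classification of head domains
doubles as a host-specificity typing scheme.

`rbptools` operationalizes that idea as a two-tier rule over pairwise
identities:

* **Group**: two head domains belong together when they share at least
  **50% amino-acid identity across at least 90% of the head domain**.
  Groups are labelled I, II, III, … and typically show within-group
  identities far above the floor (roughly 82–95%).
* **Subgroup**: within a group, clusters in which **every** member pair
  shares at least **65% identity** are lettered A, B, …. Subgroups capture
  divergence that correlates with host-range differences (for example
  preferences among CWPS C-subtypes) while staying within one group.
* A sequence joining no group is reported as `ungrouped` rather than
  dropped — genuinely novel head domains exist and should stay visible.

## Head window

The head window is fixed at exactly **110 C-terminal residues** by default
(`head_length`), a concrete rendering of the "~110 aa" head region;
sequences shorter than the window are used whole, with a warning and a
`truncated` flag. The window length is configurable for RBPs with atypical
architectures.

## Pairwise alignment and the identity/coverage statistics

Comparisons use affine-gap **global** (Needleman–Wunsch) alignment with
BLOSUM62, gap open −11 and gap extend −1 — the standard protein
parametrization. A gap run of length L costs `gap_open + (L−1)·gap_extend`.
Global alignment, rather than local alignment with an E-value cut-off, is
appropriate here because head domains are short and of near-equal length,
and because E-value calibration depends on database size while the
classification needs only thresholded pairwise identity.

Definitions, chosen to be symmetric and conservative:

* `identity_pct` = 100 · matches / aligned columns, where a column counts
  only when **both** sequences hold a residue; `X` is alignment-neutral
  (scores 0 against everything) and never counts as a match;
* `coverage_pct` of each sequence = 100 · aligned columns / its ungapped
  length; the **pair-level coverage is the minimum of the two**, so
  "across 90% of the head domain" must hold for both partners.

Two numerical details matter for reproducibility. The traceback tie-break
prefers match/mismatch over a gap in the first sequence over a gap in the
second, making the reported alignment deterministic. And because co-optimal
alignments can differ in match count, every pair is aligned in a canonical
orientation (lexicographic order of the residue strings), which makes
`identity_and_coverage()` exactly invariant under sequence swap. The
dynamic program is compiled (Rcpp); its optimum is checked in the test
suite against exhaustive enumeration of all gapped alignments on short
sequences.

## Group formation: single linkage

The published phrasing — sharing the thresholds "with other group members" —
is ambiguous between single- and complete-linkage. `rbptools` uses
**single linkage** (connected components of the thresholded graph) by
default: observed groups combine a tight identity core (82–95%) with
members down near the 50% floor, a pattern complete linkage would split.
Complete linkage is available behind `assign_groups(..., linkage =
"complete")` for sensitivity analyses. Components of size one are flagged
ungrouped.

Subgroups use **complete linkage** (agglomerative, distance
100 − identity, cut at 100 − 65), because the subgroup rule explicitly
binds *all* subgroup members. An exact minimum clique cover would be
NP-hard and is unnecessary at this scale; the complete-linkage cut already
guarantees the defining property (checked post-hoc on every run), and on
block-structured inputs it returns the unique minimal valid partition.
Letters are only reported when a group actually divides, matching the
convention that undivided groups carry no letters.

Labels are deterministic: groups ordered by descending size, ties by
smallest member id; subgroups likewise. Permuting the input changes
nothing.

A related screen (identity > 50% across ≥ 50% of the sequence) is sometimes
applied when collecting candidate RBPs before classification. Whether that
screen and the 50/90 group rule were meant to apply sequentially is not
stated in the source analyses; `rbptools` exposes both thresholds but
applies **only the group rule** by default, since the screen is subsumed by
it for near-full-length head domains.

## Phylogeny

The tree is canonical **neighbor-joining** on the distance
`100 − identity_pct`. No evolutionary-model correction is applied: the
quantity the classification thresholds act on is raw identity, and the
tree's role is visual grouping, not divergence-time estimation. Bootstrap
support would require a multiple-alignment column resampling stage and is
deliberately out of scope. Negative branch-length estimates (possible on
non-additive inputs) are clamped to zero with a warning. The two-taxon case
uses the closed form (each pendant d/2). Newick output writes branch
lengths in 6-decimal fixed format and quotes labels containing reserved
characters. On additive matrices NJ recovers the generating tree exactly
(topology identical, path lengths within 1e−9), which the tests verify on
trees with branch lengths in [1, 10].

## Read-filtering abundance

Alignment records carry: reference, 1-based start, aligned length (read
bases in alignment operations; soft/hard clips excluded), read length, and
percent identity derived from the standard SAM edit-distance tag as
100 · (aligned − NM) / aligned. Mapped records lacking the tag are rejected
rather than guessed at. One primary alignment per read is assumed;
secondary/supplementary records are dropped on input.

Two published filter presets ship as defaults (all comparisons
**inclusive**):

| mode   | min identity | min aligned % of read | min covered fraction |
|--------|--------------|-----------------------|----------------------|
| genome | 80           | 50                    | —                    |
| contig | 86           | 95                    | 55                   |

**Relative abundance** weights each category (phage genus, or RBP group) by
the sum over its references of kept reads divided by reference length,
scales category percentages by the kept fraction of all reads, and reports
the remainder as `unmapped`, so the table sums to 100 exactly. This is a
documented length-normalized read-count estimator, not a bit-reproduction
of any external tool's internal coverage trimming, which is unspecified;
the filter semantics, however, are reproduced exactly. **RPKM** is the
closed form reads / ((length/1000) · (total kept/10⁶)); references whose
covered fraction (interval union of kept reads) falls below the contig-mode
gate report RPKM 0 with a flag.

## Binding-assay scoring

Plate wells are normalized to fluorescence units as

FU = (sample fluorescence − mean control-well fluorescence of the same RBP) / OD₆₀₀,

with negative values clamped to 0 (a fluorescence deficit below the no-cell
control is noise) and flagged. Controls are averaged **per RBP**; whether
the original assays used one or several control wells per plate is not
stated, so the per-RBP mean is the declared convention.

The **relative binding-affinity score** of a strain is
100 · (mean FU at that strain) / (mean FU at the optimal host), the optimal
host being the strain with the highest mean FU (ties broken by smallest
strain id). The optimal host scores exactly 100; an RBP whose means are all
zero yields a flagged no-binding row rather than an error. Strain-vs-strain
significance uses **Welch's two-sample t-test** — the source analyses report
P-value bounds without naming a test, and Welch's test is the standard
robust choice for small plate replicates with unequal variance; no
multiple-testing correction is applied, matching per-comparison reporting
(both choices are configurable). When both replicate vectors are constant
the statistic is undefined; p is reported as 1 for equal means and 0
otherwise, with a `zero_variance` flag.

## What the synthetic generators emulate — and what they do not

**Families** (`simulate_rbp_families()`): one random ancestor per group,
members by point substitutions, with every candidate rejection-sampled
against identities *measured by the same aligner the classifier uses* until
all band constraints hold (cap 1,000 attempts, then a configuration error
rather than a silent band violation). Defaults: within-(sub)group identity
85–95%, between-group ≤ 35%, cross-subgroup 52–64%. The cross-subgroup band
must sit strictly between the 50% group floor and the 65% subgroup
threshold — that is what makes the planted labels recoverable — so subgroup
ancestors mutate *disjoint* position blocks of the group ancestor, pinning
their pairwise identity near the band's centre before member-level
substitutions spread it. No indels are introduced by default (the
classification statistic is identity; indel realism would only complicate
coverage calibration), so same-group pair coverage is always 100. The
generator is a pure function of its spec and seed.

What this does *not* emulate: substitution-rate heterogeneity, codon
structure, indel architecture, or the historical sampling biases of real
RBP collections. Perfect label recovery on these families therefore
demonstrates the correctness of the thresholding machinery under the stated
identity structure, not classifier performance on arbitrary real data.

**Plates** (`simulate_plate()`): sample wells read
background + OD · gain · affinity plus additive Gaussian noise at 5% of the
expected signal; OD is drawn from 0.3–0.7 (mid-log cultures); 3 replicates
and 3 control wells per RBP. Truth scores are the affinity ratios. The
optics model is deliberately minimal — additive Gaussian noise only.

**Reads** (`simulate_alignments()`): category drawn from the configured
weights, reference within category proportional to length, position
uniform; identity and aligned fraction drawn from pass/fail ranges that
keep a safety margin around the filter thresholds so integer edit-distance
quantization cannot flip a read across a boundary. The truth table reports
the *analytic expectation of the length-normalized abundance estimator
under this sampling scheme* (with equal-length references per category it
reduces to the category weights scaled by the mapped-and-kept fraction);
recovery tests compare against that expectation, which keeps the check
honest about what the estimator actually estimates.

## Configuration, determinism and the file drivers

`pipeline_config()` carries every threshold, defaulting to the published
values (110; 50/90/65; 80/50; 86/95/55; α = 0.01); it round-trips through a
flat `key = value` text file, and every run writes a JSON manifest with the
package version, the full configuration, the seed, input/output MD5
checksums and surfaced warnings. All file drivers are deterministic given
(inputs, config, seed); the test suite asserts byte-identical reruns of
every command.

## Problem sizes used in the tests

The suite verifies: the aligner against exhaustive enumeration on 200+
random short pairs (length ≤ 7, 3-letter alphabet); grouping against
brute-force component search on 100+ random matrices up to n = 12; label
recovery on 20 family seeds (5 groups × 8 members, one group split 4 + 4);
NJ exactness on 50 additive 5-leaf matrices; filtering/abundance/RPKM on
corpora of 10,000 reads across 20 seeds (recovery within ±2 percentage
points); and binding-score recovery on 100 plate seeds (within ±5 points in
≥95% of cells, exact in the noiseless limit). These sizes give tight Monte
Carlo error at interactive runtimes and are re-run from scratch by
`scripts/acceptance.R`.

## Known limitations

* The published group labels I–XI for the full 332-sequence RBP collection
  depend on external sequence archives and on an assignment history that is
  not fully specified; `rbptools` reproduces the *rule*, with deterministic
  size-based labels, not the historical numbering.
* Multi-mapping reads across near-identical phage genomes are resolved by
  the single-primary-alignment convention; the original analysis's handling
  is unstated.
* The relative-abundance estimator is a documented length-normalized
  read-count estimator, not a clone of any particular mapping tool's
  trimmed-coverage estimator.
* Dereplication of RBP sequences within a sample is not reimplemented; the
  classifier expects its input already dereplicated.
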