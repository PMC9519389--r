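---
title: "Annotating plant NLR motifs: models, rules and synthetic benchmarks"
author: "NLRmotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating plant NLR motifs: models, rules and synthetic benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NLRmotifs)
```

## The problem

Plant nucleotide-binding leucine-rich-repeat receptors (NLRs) are
intracellular immune receptors with a canonical CC/TIR--NBS--LRR layout.
The domains themselves are extraordinarily diverse, but they carry short,
strongly conserved sequence motifs: the extended EDVID motif of the CC
alpha-3 helix; six conserved TIR elements (betaA, alphaA, betaC, alphaC,
betaD-alphaD1, alphaD3); the nine NBS motifs that form or flank the
ADP/ATP pocket (VG, P-loop/Walker-A, RNBS-A, Walker-B, RNBS-B, RNBS-C,
GLPL, RNBS-D, MHD); and the LxxLxL frame that starts every LRR repeat.
Locating these motifs per residue is the basis for discriminating integral
NLRs from fragments, for delineating LRR repeats, and for downstream
analyses of motif covariation.

`NLRmotifs` implements this as a bundle of 17 per-motif classifiers plus a
rule layer and a set of motif analytics, all testable end to end on
synthetic data whose ground truth is known by construction.

## Per-residue features

For each query residue the feature vector holds the negative natural log
of profile match-emission probabilities for all 20 amino acids, from two
iterations of a profile search against a *focused database* — a small
curated set of NLR and LRR-domain sequences used instead of a global
protein database, which keeps profile construction cheap without losing
the homology signal that matters for these motifs.

The reference engine (`internalPssmSearch()`) is an iterative
gapless-anchor PSSM search with no external dependencies:

* iteration 1 scores the query against every database sequence with
  BLOSUM62 and keeps, per subject, the best gapless local segment passing
  the ungapped Karlin--Altschul threshold
  $S \ge \ln(K m n / E)/\lambda$ at $E = 10^{-5}$
  ($\lambda = 0.3176$, $K = 0.134$ for BLOSUM62);
* per-position emissions are Henikoff-weighted residue frequencies over
  the query plus the accepted segments (weights scaled to the number of
  aligned sequences), smoothed with one unit of background pseudocount
  mass (BLOSUM62 marginal frequencies) and floored at $10^{-9}$ before
  taking $-\ln$;
* iteration 2 repeats the search with the iteration-1 log-odds PSSM as
  scorer ($\lambda = 1$).

Two numerical choices deserve emphasis. First, the query itself is always
part of the profile, as in iterative HMM searches: a query with no
homologs in the database still yields informative emissions that encode
its own residues (only the *coverage mask* distinguishes hit-supported
positions). Second, positions the profile does not cover beyond the query
— and query `X` residues — fall back to the background distribution, so
every feature is finite and every residue scoreable. An optional
`jackhmmer` backend reads the same quantities from HMMER checkpoint files
and is cross-checked against the internal engine in the test suite; the
internal engine is what all graded computations use.

## Windows and classifiers

A candidate start of a motif of length $L$ is described by the feature
blocks of positions $[\mathrm{pos}-5, \mathrm{pos}+L+5)$, i.e.
$20 \times 2 \times (5 + L + 5) = 40(L+10)$ features (640 for LxxLxL, 880
for the extended EDVID). Border windows are padded with the background
block, so *every* residue of a sequence is a candidate.

Each motif has its own multilayer perceptron: hidden layers of 250, 125
and 100 ReLU units, a logistic output, Adam at a constant learning rate of
0.001 and L2 penalty (default alpha $10^{-4}$, tunable per motif).
Training follows the 5-group protocol: sequences are split into five
near-equal groups; groups 1--4 drive a fourfold cross-validation used for
tuning, and group 5 is evaluated exactly once as the held-out test set.
Training is deterministic under a seed (own RNG for initialisation and
batch order). Early stopping monitors validation loss with patience 10;
we cap at 100 epochs with a loss-improvement tolerance of $10^{-3}$ and
minibatches of 200 — on the planted-motif benchmarks the networks are
far into their converged plateau well before the cap, and the cap keeps
the full benchmark suite tractable on a single CPU.

### Class imbalance and probability calibration

Per-residue labeling makes negatives outnumber positives by two to three
orders of magnitude. Rather than training on every non-start window, the
training-set assembler keeps all positives and a seeded random subsample
of negatives (default 12 per positive, per sequence) and records the
realised sampling fraction $s$. At prediction time the raw network output
is calibrated back to the unsampled prevalence with the standard
case-control intercept correction,
$\mathrm{logit}\,p' = \mathrm{logit}\,p + \ln s$, so the 0.5 and 0.8
thresholds refer to honest full-sequence probabilities. This is the one
place the package deliberately trades exact protocol fidelity for a ~25x
reduction in training cost; `negPerPos = Inf` in `buildTrainingSet()`
restores full-negative training for anyone who wants to pay for it.

### Metrics

Evaluation is position-level and exact by default (a predicted start must
hit the true start; a `tolerance` argument relaxes this for border
studies). Reports carry precision, recall, specificity,
$F_1 = 2PR/(P+R)$ and the G score. G is taken as
$\sqrt{P \cdot R}$ (Fowlkes--Mallows): the alternative geometric mean of
recall and specificity is nearly degenerate under the extreme class
imbalance of per-residue scoring, where specificity is ~1 for any useful
classifier. Degenerate cases (no positive predictions) report precision 0
with an explicit flag.

## The rule layer

Probabilities become annotations through the rules:

* **Calling**: one call per local probability maximum strictly above 0.80
  (a plateau is called once, at its leftmost position).
* **Satellites**: same-motif calls closer than 15 residues are conflicts;
  when the probability difference exceeds 20 percentage points only the
  stronger call survives, otherwise both are kept and flagged ambiguous.
  The "keep both and flag" branch is our conservative reading of the
  resolution rule, which only specifies the clear-margin case.
* **NBS layout**: valid iff each of the nine NBS motifs occurs exactly
  once with strictly increasing starts in the canonical order; failures
  carry machine-readable reasons (`missing:`, `duplicated:`,
  `disordered:`).
* **LRR ladder**: accepted iff the first repeat start follows the MHD end
  within 50 residues (the motif end is taken as start + L), consecutive
  starts are 15--50 residues apart (the last repeat is open-ended), and at
  least 9 repeats remain (5 for the CNL interdomain analysis).
* **Class**: TNL for all six TIR motifs in order upstream of a valid NBS;
  CNL for an extended-EDVID call upstream of a valid NBS (TIR takes
  precedence, flagged, if both fire); NL for a valid NBS alone; `other`
  otherwise, with a `shuffled` flag when N-terminal motifs appear
  downstream of the NBS. RPW8-type RNLs have no trained predictor and are
  not auto-classified; RNL labels must be supplied externally.

## Motif analytics

*Chimeras.* For clustering, the motifs of interest (9 NBS; 6 TIR + 9 NBS;
or EDVID + 9 NBS + the first five LRR starts) are excised with 5 flanking
residues each and concatenated in registry order. Because the layout is
fixed, chimeras are equal-length and pairwise identity is a column-wise
match fraction; clusters are connected components of the
identity-threshold graph. Conservation is summarised per column as
relative entropy against the BLOSUM62 background,
$\mathrm{RE}(c) = \sum_a f_a(c)\log_2 (f_a(c)/q_a)$, and exported as a
logo matrix (frequency times RE).

*LRR physico-chemical clustering.* Each LxxLxL window maps to 18
descriptors — Kyte--Doolittle hydropathy, formal side-chain charge
(K/R = +1, D/E = -1, H = +0.1) and Zamyatnin residue volume for each of
the six positions — z-scored across the dataset. The scales are
swappable; these three are standard and were chosen because charge
placement is what visibly drives cluster separation in real LRR motif
sets. Clustering is OPTICS with Xi extraction (Euclidean metric),
implemented internally (reachability ordering with kNN core distances;
the steep-area extraction applies the usual sign corrections and omits
predecessor correction). Defaults `minSamples = 20`, `xi = 0.05`. Ladder
context is kept by cross-tabulating cluster labels against repeat
positions, normalised vertically to 100% per ladder position.

*Coevolution.* Column-pair mutual information over the chimera alignment
uses Henikoff sequence weights and profile-based pseudocounts: one unit of
pseudocount mass distributed as the product of the columns' BLOSUM62
substitution profiles $g_i(a) = \sum_b f_i(b) P(a\mid b)$. Gaps and X are
excluded from counts. Significance is an empirical Z-score over the
off-diagonal MI distribution with cutoff 3.5 (boundary inclusive);
column-shuffle permutation nulls would be a drop-in alternative but the
empirical null is the default for speed. Cumulative MI sums a column's
significant MI; proximity MI averages cumulative MI over 3D contact
neighbours supplied as a plain `(i, j, distance)` table (5 Angstrom
default cutoff).

## The synthetic study conditions

All benchmarks run on generated data with known truth; the generators are
first-class, tested code.

* `generateMotifDataset()`: background sequences (BLOSUM62 marginal
  residue frequencies) with one consensus-conforming motif planted at a
  uniform position. Hydrophobic `b` positions are planted from
  {L, I, V, M, F}. Motif noise `mu` resamples each *class* position
  (`b` or `x`) from the background with probability `mu`; fixed anchor
  residues are what makes the motif that motif and stay intact.
* `generateNlr()`: a full synthetic NLR — N-terminal region (EDVID for
  CNL, the six TIR motifs in order for TNL, nothing for NL), the nine NBS
  motifs with 15--40 residue spacers, a linker (default 10--45, i.e.
  within the 50-residue rule), and an LRR ladder whose repeats start with
  the plant-repeat body `bxxbxbxxNxLSGxbP` truncated to the repeat
  length. Satellite decoys plant a second LxxLxL-conforming 6-mer 6--14
  residues downstream of a true start at a configurable rate.
* Decoy scrubbing: accidental consensus-conforming windows outside the
  planted ones are mutated away (never touching constrained positions of
  planted windows), so noise-free ground truth is unambiguous; noise can
  reintroduce conformers, which is the intended noisy regime. One class
  of conformers is intrinsic and left alone: the LxxLxL frame is
  degenerate enough that the starts of other hydrophobic-anchored motifs
  (RNBS-A's `Fbbbb W`, for instance) conform to it by construction —
  exactly the kind of off-target pattern the classifiers must learn to
  reject from context, and one reason real LRR annotation needs more
  than pattern matching.
* `generateFocusedDb()`: families of noisy copies (20% divergence) of
  CNL-like archetypes (>= 500 aa) and LRR-only archetypes (>= 200 aa),
  default 150 + 100 records — a 10x-scaled-down mirror of the curated
  1,361 + 1,000 focused set, sized so profile search still sees homolog
  families at desk scale.
* `generatePlantedLrrClasses()`: classes are charge patterns over the
  three exposed LxxLxL positions (e.g. all-positive, all-negative,
  neutral), with frame hydrophobics from {L, I, V} and jitter `sigma`
  (default 0.02) resampling exposed positions from the background. The
  class templates were chosen so that classes are genuinely
  density-separated in the z-scored embedding; a weaker design (single
  charged position against broad neutral variation) is *not* separable
  by any density clustering and is deliberately not what the generator
  emulates.
* `generateCovaryingAlignment()`: i.i.d. background columns except one
  planted pair coupled through a fixed alphabet permutation with
  probability `coupling`; both marginals stay at the background so only
  the dependence is planted.

What passing these benchmarks does and does not show: the synthetic data
have exact anchor conservation, independent background residues and no
indels, domain duplications, compositional bias or phylogenetic
correlation. Scores on them bound what the pipeline's machinery can do
when its assumptions hold; they do not certify performance on real
proteomes, where motif variability is structured rather than i.i.d.

## Benchmark problem sizes

The acceptance script (`scripts/acceptance.R`) trains and evaluates at
the canonical sizes: 800 sequences of 300 aa for EDVID (noise 0.15), 600
x 250 aa per TIR motif (noise 0.05), 800 x 400 aa for the P-loop (noise
0.10), and 400 NL proteins with 9--14 irregular repeats, 20% satellite
decoys and noise 0.15 for LxxLxL — against the default 250-record focused
database, with the data seed 42, database seed 7 and split seed 1 as
fixed study conditions. The test suite runs the same experiments as
reduced twins (n = 60--80) chosen so the whole suite stays comfortably
within its runtime target; the acceptance run skips the four tuning folds
(it tunes nothing) and reports the held-out group only.

## Known limitations

* The internal profile engine is gapless by construction; strongly
  indel-divergent homologs that jackhmmer would align are recruited only
  through their best ungapped segment.
* Identity clustering assumes the fixed chimera layout; free-length
  inputs need an external clusterer.
* The Xi extraction omits predecessor correction; on well-separated data
  this changes nothing (we verified the planted-class recoveries), but
  borderline cluster edges can differ from implementations that apply it.
* The empirical Z-null for MI is shared across all pairs; columns with
  extreme composition could deviate from it.
* RNL classification is out of scope (no RPW8 predictor is trained).
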