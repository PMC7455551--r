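---
title: "Methods: comparative genomics of early green plant evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of early green plant evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viridicore)
```

# Scope and the scientific setting

The green plants (Viridiplantae) have classically been split into two
phyla, Chlorophyta and Streptophyta.  The discovery of a third lineage —
the Prasinodermophyta, deep-water picoplanktonic algae diverging *before*
the Chlorophyta/Streptophyta split — turns several routine comparative
analyses into instruments for reconstructing the ancestral green plant:
any gene family shared between the new lineage and either classical phylum
was, barring convergence, present in the common ancestor of all green
plants.

`viridicore` implements that analytical toolbox as a reusable, tested
pipeline: k-mer genome-size estimation, orthogroup set algebra and
minimal-core-genome reconstruction, Dollo parsimony gain/loss mapping,
reciprocal-best-hit protein inventories with a flagellate-capability
classifier, supermatrix construction with gap-column masking, and
clade-diagnostic synapomorphy scanning.  Each stage can be fed either real
files (FASTA/FASTQ, GFF3, Newick, OrthoFinder-style gene-count TSVs) or
synthetic data with planted ground truth, so every claim the package makes
is checkable offline.

Out of scope by design: genome assembly and polishing, orthogroup
inference itself (MCL/OrthoFinder clustering), HMM database searches, and
tree inference engines.  The package prepares inputs for and consumes
outputs of those tools; it does not re-implement them.

# K-mer genome-size estimation

For reads of length $L$ and k-mers of length $K$, a read contributes
$L-K+1$ k-mers, so the k-mer coverage at the spectrum peak $M$ relates to
the base sequencing depth $N$ as

$$M = N \times \frac{L-K+1}{L},$$

and the genome size follows as $G = (\text{k-mer instances above the error
valley}) / M$.  Choices made here:

* **Canonical k-mers.** Reads are unstranded, so each k-mer is collapsed
  with its reverse complement (lexicographically smaller 2-bit encoding
  kept).  $K$ odd is recommended so a k-mer can never equal its own
  reverse complement; the default is $K=17$.
* **Error valley.** Sequencing errors create a mass of low-multiplicity
  k-mers.  The valley is the first local minimum of the histogram scanned
  upward from $m=2$ when the histogram descends from $m=1$; for a
  rising-then-falling (unimodal) spectrum the valley is 0.  This is the
  standard spectrum heuristic; the threshold is not tuned per dataset.
* **Continuous peak and the mode-to-mean correction.** K-mer
  multiplicities at single-copy positions are approximately Poisson with
  mean $\lambda = N(L-K+1)/L$.  The *continuous* peak of a Poisson mass
  function sits at $\lambda - \tfrac12$, and the discrete argmax is biased
  by up to half a unit more — together a 2–5% genome-size error at
  25–30×.  `estimate_genome_size()` therefore interpolates the peak
  position quadratically through the mode and its two neighbours and adds
  $\tfrac12$; on error-free 1 Mb simulations at 30× this brings the
  genome-size error from ~3% to ~0.3%.  `find_peak()` still reports the
  discrete argmax as `M` (that is its contract) alongside `M_refined`.
* **Haploid model only.** The target organisms here are homozygous or
  haploid; no heterozygous-peak mixture is fitted (that is GenomeScope's
  job, a stated non-goal).

A real genome's published size is not reproducible without the deposited
reads, so the tests validate the estimator on simulated reads where the
truth is known exactly: recovery is within 5% across 0.1–5 Mb genomes at
30×, and invariant (within 2%) to doubling the depth.

# Orthogroup set algebra and the minimal core genome

An `orthogroup_table` is an orthogroup × species gene-count matrix plus a
partition of the species into named groups; *membership* means a positive
count.  Three operations are built on it:

* **Venn partition** — each orthogroup is assigned to the subset of groups
  in which it has at least one member species.  Only membership matters,
  so the partition is invariant to gene-count magnitude and species order.
  "Shared among two groups" means at least one species per group, which is
  the reading consistent with the published Venn arithmetic.
* **Core at a node (span rule)** — an orthogroup is placed in the ancestor
  at a tree node when it is present on at least two distinct child
  subtrees of that node: such a family spans the node's basal split and
  must have been present in the ancestor unless it was gained twice
  independently.  At the Viridiplantae root (children: Prasinodermophyta
  and Chlorophyta+Streptophyta) the rule reduces to
  $(P \wedge C) \vee (P \wedge S)$, and on a table realising the published
  partition (3,292 shared by all three lineages, 621 uniquely
  P+Chlorophyta, 179 uniquely P+Streptophyta) it returns exactly
  $3{,}292+621+179 = 4{,}092$ orthogroups — the minimal core genome of the
  green plants.  "Minimal" is meant literally: families lost in two of the
  three lineages are invisible to the rule.
* **Lineage trichotomy** — gene families over early-diverging Chlorophyta
  and early-diverging Streptophyta exemplars are classified
  groupA-biased / groupB-biased / shared by comparing group means
  (strictly more than twice the other group's mean), after removing
  (1) outlier families in which any one species exceeds ten times the mean
  of all other species and (2) families present in a single species.
  Two readings had to be fixed where the published wording is ambiguous:
  the tenfold test compares each species against the mean of the *other*
  species, zeros included; and the test requires that mean to be positive,
  because "tenfold larger than zero" is vacuous and would otherwise
  swallow the single-species category entirely.  Group means include
  member species with zero copies.  The filter order
  (outliers → singletons → classify) follows the published sentence order.

# Dollo parsimony trait mapping

Binary trait matrices (transcription-factor types, pathway enzymes,
flagellar genes) are mapped on a rooted, clade-labelled species tree under
Dollo parsimony: each trait arises exactly once — on the stem of the MRCA
of all carriers — and absences inside that clade are explained by the
minimal set of loss branches, i.e. the stems of the maximal all-absent
subtrees.  Dollo rather than Fitch because complex gene families are far
easier to lose than to re-invent, which is exactly the gains-then-losses
logic used to place a family gained on the Viridiplantae stem when it is
present across green plants but absent from both Glaucoplantae and
Rhodoplantae.  A Fitch mode exists for sensitivity analysis.

The canonical worked example ships as `tf_fixture()`: a group-level
presence/absence matrix of 73 transcription-factor/regulator types over
Rhodoplantae, Glaucoplantae, *P. coloniale*, Chlorophyta and Streptophyta.
Mapping it on the five-clade group tree yields 5 gains on the
Viridiplantae stem, 6 losses on the *P. coloniale* branch, 5 gains on the
Chlorophyta+Streptophyta stem and 7 gains on the Streptophyta stem:

```{r tf}
em <- dollo_map(tf_fixture(), group_tree())
em
```

One definitional subtlety deserves a note.  `ancestral_toolbox()` at a
node returns every trait whose gain lies on or above the node's stem with
no loss on the path from the root — at the Archaeplastida root of the
fixture that is 56 types, because the 6 types later lost on the
*P. coloniale* branch were also ancestral.  The familiar figure of a
50-type ancestral toolbox is the *intersection* of that set with the types
present in *P. coloniale* (55 present − 5 Viridiplantae-stem gains = 50).
Both numbers are correct answers to different questions; the package
computes the toolbox per its definition and leaves the intersection to the
caller.

The trait-history generator simulates the same process forward (single
gain per trait, losses only below the gain, no regain).  Its default rates
are gain 0.2 and loss 0.02 per branch.  The loss rate is deliberately low:
when a loss erases an *entire child subtree* of the gain node, no mapper
can recover the planted gain — the observable trait span no longer reaches
the gain branch — so higher loss rates measure unidentifiability, not
mapping error.  At the defaults, 95–97% of planted event branches are
recovered on a 10-leaf tree; at loss 0.05 that drops to ~91% for the
information-theoretic reason above, not because of an algorithmic defect.
The Dollo mapper itself is verified exactly against exhaustive enumeration
of all single-gain histories on trees of up to 8 leaves.

# Reciprocal-best-hit inventories and the flagellate classifier

At desk scale, BLAST is replaced by an in-repo affine-gap Smith–Waterman
(BLOSUM62, gap open 11, extend 1 — a gap of length $g$ costs
$11 + g$), verified cell-for-cell against an independent reference
implementation on short pairs.  A pair $(a, b)$ is an ortholog call when
each is the other's best hit and both pass the score threshold; equal-score
ties break by higher query coverage, then lexicographic id, and applied
tie-breaks are recorded.  Significance, when wanted, is a
Karlin–Altschul-style Gumbel estimate calibrated on composition-preserving
shuffled decoys (method of moments); the published screening threshold
"<10 × 10⁻⁵" is read as $E < 10^{-5}$, taking the printed form as a typo
for $1\times10^{-5}$ — both the value and its interpretation are function
arguments, not constants.

`panel_inventory()` counts reciprocal-best-hit partners of a curated query
panel (e.g. 397 flagellar genes) in a proteome, overall and within a
designated core subset; which panel members count as "core" is
configuration, since that designation comes from the literature rather
than from an algorithm.  `flagellate_call()` then applies the empirical
thresholds: ≥40 core and ≥192 total flagellar-protein homologues is
flagellate-capable, ≤26 core and ≤140 total non-flagellate, anything
between indeterminate.  The published worked point (50 core, 217 total)
classifies flagellate-capable; the boundary point (26, 140) classifies
non-flagellate.

# Supermatrix construction

Per-locus alignments are masked and concatenated into a partitioned
supermatrix:

* A column is removed when **50% or more** of its sequences carry a gap
  (boundary removes — "50% or more" is inclusive).  Missing-data symbols
  (`?`, and `N`/`X` per alphabet) count as gaps by default; both the
  threshold and that behaviour are arguments.
* Blocks are linked in input order; the taxon set is the union and absent
  taxa are filled with `-` across the block's span.  Partition coordinates
  are 1-based inclusive, contiguous, and sum to the total length — on the
  four published rRNA operon sections (1,621 + 3,025 + 1,535 + 2,637 nt)
  the supermatrix is exactly 8,818 columns in four partitions.
* Writers emit relaxed PHYLIP or FASTA plus RAxML- or NEXUS-dialect
  partition files; reading back is byte-faithful.  Masking commutes with
  concatenation (columns are independent), and every kept-column map is
  strictly increasing, so masked coordinates are always recoverable in the
  original frame.

The expert curation of "unambiguously aligned" positions in the published
operon alignment is human judgement and is not reproduced; only the
bookkeeping is in scope.

# Synapomorphy scanning

A column is a candidate synapomorphy for a clade when every clade member
shares one unambiguous state and no outside taxon has — or, through an
IUPAC ambiguity code, *could have* — that state.  Ambiguity is treated
asymmetrically on purpose: ambiguous states inside the clade disqualify
the column (they cannot prove uniformity), while ambiguous states outside
potentially match (they cannot disprove homoplasy); both conventions are
conservative against false synapomorphies and both are switchable.  By
default the clade must be completely covered (`strictness = 1`); lowering
strictness admits columns where up to that fraction of clade rows are
gapped.

Candidates are then audited against taxon-richer *control alignments*
sharing the coordinate frame: the clade state appearing in any non-member
makes the column a parallelism; a clade member carrying a different
unambiguous state makes it a reversal; a column no control covers is
ambiguous, never silently dropped; survivors are genuine non-homoplasious
synapomorphies (NHS).  The published procedure's third control — BLAST
searches against public databases — is replaced by additional control
alignments, since desk-scale verification cannot depend on an external
service.  Positions are reported 1-based in the original alignment frame.

The paired generator plants diagnostic, parallel and reversal columns:
all three classes are clade-diagnostic in the *main* alignment, and the
homoplasy is expressed through extra taxa in the generated *control*
(an extra outsider carrying the clade state; an extra clade member
reverted to the outside state).  This mirrors how homoplasy is actually
discovered — by widening the taxon sample — and makes the planted classes
exactly recoverable: on noise-free fixtures the scanner's sensitivity is
1.0 with zero false positives.

# Structural genome statistics

GC content excludes ambiguous bases from the denominator.  Coverage
fractions (repeats, CDS) merge intervals before summing, so they are
idempotent and invariant to interval splitting; repeat intervals are an
*input* (from any masker), never computed here.  Introns are derived as
gaps between consecutive exons of a transcript rather than trusted from
intron features, because GFF3 files routinely omit them; overlapping exons
within a transcript are a hard error naming the transcript.  GFF3 is
1-based inclusive and BED 0-based half-open; the conversion lives in one
place.  Whether "coding fraction" means CDS only or all exonic sequence is
ambiguous in the field's usage, so both are reported (`coding_fraction`,
`exonic_fraction`); the gene-model generator emits CDS equal to exons
(ab initio style, no UTRs), making its truth check exact.

# What the synthetic data does and does not establish

Every generator is a pure function of its arguments and a seed
(byte-identical reruns) and emits ground truth sufficient to score the
consuming module without re-deriving it.  The simulations are deliberately
idealised: reads have uniform coverage, no indels and i.i.d. substitution
errors; proteome decoys are composition-preserving shuffles, not real
paralogs; planted alignment columns are noise-free unless a background
rate is requested; simulated genomes are base-i.i.d., with essentially no
repeat structure.  A green test therefore establishes algorithmic
correctness — the set algebra, the parsimony optimum, the DP recurrence,
the masking arithmetic — on data satisfying each method's own assumptions.
It does not establish robustness to coverage bias, paralogy,
alignment error or repeat-rich genomes, which is precisely why the
published empirical values that depend on the deposited sequencing data
(genome size 26.04 Mb, GC 69.8%, 7,139 genes, BUSCO 93.1%) are not
acceptance targets here: they are not reproducible from first principles
without those reads.

# Numerical and interface choices

* Thresholds that the source procedures state (50% gap masking, the
  26/140 and 40/192 flagellar boundaries, twice-the-mean and tenfold-rule
  cutoffs, $E<10^{-5}$) are defaults, stated in the documentation, and
  never silently changed; boundary semantics (≥ vs >) follow the stated
  wording in each case.
* Trees are `ape::phylo` objects; clades are addressed by internal node
  labels, and unlabelled nodes are auto-labelled `N1, N2, …` on entry.
  The default rooting places Rhodoplantae sister to
  (Glaucoplantae, Viridiplantae); Viridiplantae-internal inferences are
  invariant to that choice (asserted by test).
* Group/threshold configurations are JSON rather than YAML: the target
  environment ships no R YAML parser, and JSON round-trips through
  `jsonlite` without an added dependency.
* All randomness flows through a single seeded generator per call; the
  global RNG state of the session is left untouched.

# Limitations

Beyond the synthetic-data caveats above: the k-mer module fits no
heterozygosity or repeat mixture model; Dollo mapping assumes the trait
matrix is error-free (a single false absence creates a spurious loss);
the Smith–Waterman inventory is quadratic per pair and meant for panels of
hundreds, not proteome-scale all-vs-all searches; and the synapomorphy
scanner requires controls in the same coordinate frame or an explicit
column map — it will mark candidates ambiguous rather than guess a
mapping.
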