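---
title: "Methods: the lignoscan monolignol gene-family pipeline"
author: "lignoscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the lignoscan monolignol gene-family pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`lignoscan` implements the standard genome-wide survey of the eleven
monolignol biosynthesis gene families (PAL, C4H, 4CL, HCT, C3H, CSE, COMT,
F5H, CCoAOMT, CCR, CAD) for a plant genome, with explicit support for a
tetraploid willow genome whose 38 chromosomes split into At and Bt
sub-genomes. The pipeline is a chain of decision rules rather than a single
statistical model; each rule is stated below together with its parameters
and the reasoning behind the defaults.

# Family assignment

A candidate protein is assigned to the family holding its best-scoring
local alignment (Smith–Waterman, BLOSUM62 for proteins, +1/−1 with a linear
gap penalty of 2 for DNA), provided the score reaches `minScore` and, when
the domain gate is on, the candidate contains at least one of the family's
required patterns as an exact substring. Ties on score break by higher
identity, then lexicographic family label, so assignment is deterministic
and invariant to the order of the reference list.

* `minScore` (default 100, raw score units): separates genuine family
  membership from spurious short alignments. On the synthetic data the
  within-family scores are an order of magnitude above this and
  cross-family scores an order of magnitude below, so the default is not
  delicate; for real data it should be calibrated against known catalogues.
  We deliberately do not reproduce BLAST E-value statistics — the
  Karlin–Altschul calibration adds nothing to a presence/absence decision
  at this scale.
* The domain gate replaces profile-HMM domain scans with exact required
  substrings. This keeps the gate's role (presence/absence of an essential
  domain) while removing the dependency on external profile databases. Real
  analyses should supply per-family patterns appropriate to their
  reference set.

# Duplication, tandem duplicates and hotspots

A gene pair is a duplicate when the locally aligned region covers **more
than** 80 % of the longer gene's CDS and the identity of the aligned region
(matches / aligned columns, gaps included) is **greater than** 80 %. Both
inequalities are strict: a pair engineered at exactly 0.80 is rejected, and
the tests pin this boundary. Comparison is at the CDS (DNA) level by
default — identity of an "aligned region" reads most naturally as sequence
identity — with a protein option. By default only genes sharing a family
label are compared (duplicates arise within families); `withinFamily =
FALSE` evaluates all pairs, which the oracle-equivalence tests use.

Tandem status is not part of the duplication rule: a duplicate pair is
flagged tandem when both genes sit on the same chromosome at most 100 kb
apart. The 100 kb default is a package choice — the field has no single
definition of "tandem" — and is exposed as `maxSeparationBp`.

A hotspot is a chromosomal region holding at least 5 family-assigned genes
whose genomic span (first gene start to the largest gene end among them) is
strictly under 5 Mb. Per chromosome we report every *maximal* qualifying
run of position-sorted genes: extending a reported run in either direction
breaks the span bound. Maximal runs may overlap each other but are never
nested. We do not merge overlapping runs into one region: a merged region
could exceed the 5 Mb bound and would no longer be a hotspot under the
rule's own definition. The implementation is tested for equality against a
brute-force enumeration over all subintervals of the sorted gene list.

# Phylogeny and family classes

Per-family trees are built by neighbor joining (Saitou–Nei) on
Poisson-corrected distances, `d = −ln(1 − p)`, where `p` is the fraction of
differing sites among the columns where neither sequence of the pair has a
gap (pairwise deletion). The Poisson correction assumes equal rates across
sites and corrects the observed proportion for multiple hits; it is exact
as `p → 0` and diverges as `p → 1`, so a pair with `p ≥ 1` is an error
naming the pair, as is a pair with no comparable columns. NJ on an additive
matrix provably recovers the generating unrooted topology, and the suite
checks this on random trees up to 10 leaves.

We use distance-based NJ rather than maximum likelihood throughout: the
Poisson correction *is* a distance model, so NJ is the self-consistent
choice, and distance methods keep bootstrap replication cheap. Bootstrap
support resamples alignment columns with replacement, rebuilds the NJ tree,
and scores each internal bipartition of the reference tree by the
percentage of replicates containing it; the seed is mandatory, making
supports reproducible.

Family classes are a function of the unrooted topology and a three-way
grouping of the leaves (herbaceous monocots, herbaceous dicots, woody
plants):

* **Ib** — all three groups are simultaneously monophyletic (the tree
  resolves into three pure lineages; in a binary tree the three clades
  necessarily meet at one internal vertex);
* **Ia** — the monocots are monophyletic but the herbaceous dicots group
  with the woody sequences instead of forming their own lineage;
* **II** — otherwise (groups interleave; the expanded-family pattern).

Checking Ib before Ia makes the three cases mutually exclusive; the
classification is invariant to leaf order and re-rooting, which the suite
verifies against a rooting-based monophyly oracle.

Multiple sequence alignments are *consumed*, not computed: the package
never aligns family sequences itself. The synthetic generator produces
substitution-only families, which are already aligned by construction, so
no aligner ships with the package; real analyses should align with a
dedicated tool and hand the alignment in.

# Expression and differential expression

FPKM is `counts × 10⁹ / (gene length × library size)`; it is invariant to
uniform rescaling of a sample's counts. Genes pass the expression filter
when FPKM is strictly greater than `minFpkm = 1.0` in at least one
replicate; the filter is idempotent.

The DEG rule is the conventional two-criterion call: |log₂ fold change|
≥ 1 (a two-fold difference, inclusive at the boundary) and
Benjamini–Hochberg adjusted p < 0.05. The fold change is computed on
shifted group means, `log2((mean_tall + 1)/(mean_short + 1))`, which keeps
zero-expression genes finite without a pseudocount tuned to the data. The
per-gene test is a two-sided Welch t-test on `log2(FPKM + 1)`; genes with
essentially constant values in both groups get p = 1. We chose this test —
rather than a negative-binomial GLM — because the decision rule above, not
the count model, is what defines the call, and the t-test on the
variance-stabilised scale is deterministic, dependency-free, and holds the
empirical false-call rate at the nominal FDR in the null simulations the
suite runs (200 genes × 50 replicates). A `testFun` hook swaps in any other
per-gene test. Whether the two-fold criterion should apply to genotype-mean
FPKM or to a model-estimated fold change is genuinely open; we use group
means, which is what the shifted-mean formula computes.

# Phenotypes

Lignin content follows the assay kit's calibration,
`lignin (mg/g) = 2.184 × ΔA / W`, with ΔA the OD280 absorbance difference
and W the dry weight in grams. The height–lignin association is a sample
Pearson correlation with the exact t reference distribution
(`t = r·sqrt((n−2)/(1−r²))`, n−2 df). The default mode correlates
*genotype means*: the bundled four-genotype reference table reproduces the
survey-level value r = −0.62 on means, and a replicate-level mode is
provided. At n = 4 the t-test on |r| = 0.62 is far from significant
(p ≈ 0.38); we report the p-value our formula computes and leave the
interpretation to the analyst — a permutation test is pointless at n = 4
(only 24 orderings exist).

# Promoter motifs

Promoters are the 2000 bp immediately upstream of the annotated gene start
(a proxy for the start codon, since the catalogue model carries gene spans
only — a documented simplification): bases `[start−2000, start−1]` for
plus-strand genes and the reverse complement of `[end+1, end+2000]` for
minus-strand genes, truncated at chromosome edges. Scanning is exact IUPAC
matching — no position-weight matrices — on both strands: a minus-strand
hit is a match of the motif's reverse complement, reported at its position
on the plus-strand sequence. All overlapping occurrences are reported
(collapsing them is a summarisation choice that belongs downstream), and an
`N` in the promoter matches nothing. The scanner is tested for equality
against a naive position-by-position oracle. The bundled 23-motif
vocabulary (MYB, AP2/ERF, bZIP, MADS-box, NAC, ARF and other tags) is a
labelled synthetic stand-in for fixture work; real scans should supply
their own motif list.

# The synthetic-study generator

The generator emulates the *structure* of a tetraploid willow study with
every planted entity recorded as ground truth:

* **Genome** — 38 chromosomes (A01–A19, B01–B19) of 10–20 Mb; 11 families
  × 18 members (~200 genes, the scale of a real willow catalogue) plus a
  few unplaced scaffold genes. Founder proteins of 200–320 residues carry a
  fixed 8-residue domain pattern; members derive from the founder by 15 %
  protein-level substitutions and independent reverse translation, which
  keeps protein-level family signal strong while pushing between-member CDS
  identity (~0.7) well below the 0.8 duplication threshold.
* **Duplicates** — created by copying a parent CDS and applying evenly
  spread nucleotide substitutions, so the full-length local alignment has
  identity exactly `(L − m)/L` (±1 % after rounding); coverage is
  controlled by truncating the copy. Substitutions only, no indels: this
  makes the 80/80 rule testable at exact boundaries.
* **Placement** — background genes are spaced ≥ 1.7 Mb apart on a
  chromosome, at most one tandem pair (20 kb gap) per chromosome, and no
  background genes on hotspot chromosomes, so the only regions satisfying
  5-in-<5 Mb are the planted ones and recovery can be asserted as set
  equality.
* **Counts** — negative binomial with dispersion 0.05 at base mean 500,
  4 genotypes × 3 replicates; planted DEGs apply |log₂FC| = 2 to the tall
  group, most of them down-regulated in tall genotypes (19/23 of DEG calls
  in the motivating surveys point that way).
* **Phenotypes** — heights uniform over a sapling range; lignin contents
  constructed from standardised heights plus noise and rejection-sampled
  until the Pearson r lands within ±0.1 of the −0.62 target; ΔA and W are
  back-computed so the assay formula holds exactly.
* **Promoters** — 2000 bp of uniform background with 1–3 non-overlapping
  concrete motif instances planted per selected gene at recorded offsets
  and strands.

Everything is deterministic given the seed, down to file bytes, and the
suite checks this end to end. What the generator does **not** emulate:
codon usage, intron/exon structure, indels and alignment uncertainty,
genuine evolutionary site-rate variation, expression heteroskedasticity
across genes, or background motif composition bias. Passing tests
therefore demonstrate that the decision rules are implemented exactly and
recover planted structure under clean conditions — not that the pipeline
is robust to every artefact of real genomes and real RNA-seq.

# Numerical and design notes

* "More than"/"greater than" thresholds are strict everywhere (0.80
  duplication rule, 5 Mb hotspot span, FPKM > 1); boundaries are pinned by
  tests.
* Coverage uses the full length of the longer gene's sequence as the
  denominator and the aligned width within that sequence as the numerator.
* The exhaustive BH check is literal for vectors of length ≤ 3 on a
  0.05-step grid and uses large fixed-seed grid samples for lengths 4–8
  (a literal length-8 enumeration is ~10¹⁰ vectors).
* Problem sizes in the suite — 100 random additive matrices (≤ 10 taxa),
  100 random gene layouts, 200 genes × 50 null replicates, ≤ 50-gene
  duplication oracles, ≤ 200-bp scan oracles — were chosen as the smallest
  sizes at which the corresponding property is convincingly exercised.
* Degenerate inputs fail loudly: empty sequences, p ≥ 1 Poisson pairs,
  zero-variance correlations, zero library sizes, groups with fewer than
  two samples, motifs longer than the promoter.

# Limitations

* Family assignment quality is bounded by the reference set; the raw-score
  threshold is not an E-value and does not adapt to database size.
* The classification rule formalises "clearly distinguished" as exact
  monophyly; a single stray leaf demotes a family from Ia/Ib to II. Real
  trees with weakly supported edges may warrant a support-aware variant.
* The Welch-on-log2 test is a deliberate simplification of count-model
  inference; with very low counts or few replicates a negative-binomial
  test will be more powerful (use the `testFun` hook).
* Promoter extraction uses the annotated gene start, not the start codon;
  for annotations with UTRs the two differ.
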