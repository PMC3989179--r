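---
title: "Barcode-gap species delimitation and integrative refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode-gap species delimitation and integrative refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The problem

Faunal checklists are built over decades from morphology. DNA barcoding
offers an independent check: if a fauna of, say, 36 recognised species is
surveyed broadly and its mitochondrial sequences are partitioned into
genetically distinct clusters, do the clusters recover the checklist — or
reveal overlooked species and cryptic invasions? `barcodegap` implements
that workflow end to end for aligned mitochondrial barcode data (a ~650 bp
COI or ~440 bp 16S fragment is typical), with land molluscs as the
motivating study system. Species boundaries are proposed from genetic
distances alone (a *primary species hypothesis*, PSH), then refined by
congruence with morphology and tree-based monophyly (a *secondary species
hypothesis*, SSH), compared to the known fauna, and screened for
mitochondrial/morphological conflicts that indicate introgressive
hybridisation.

## The distance model

All distances are Kimura two-parameter (K2P) corrected:

$$ d = -\tfrac{1}{2}\,\ln\!\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right], $$

where $P$ and $Q$ are the proportions of transition (A↔G, C↔T) and
transversion differences across the sites comparable in both sequences.
Sites with a gap or IUPAC ambiguity in either sequence are excluded for
that pair only (*pairwise deletion*); an `N` is missing data, never a
match. When the logarithm's argument is non-positive the correction is
undefined (saturation); such pairs are reported as flagged errors and
every downstream stage refuses a flagged matrix, because silently clamping
a distance would distort the very gap structure the method relies on.

Identical sequences are collapsed to haplotypes first (exact string
identity after upper-casing), both because shared haplotypes carry no
extra distance information and because unequal sampling across species
would otherwise swamp the pairwise distance distribution.

## Barcode-gap partitioning

A *barcode gap* is a discontinuity in the ranked pairwise distances that
separates intraspecific from interspecific comparisons. For a given prior
maximum intraspecific divergence $P$, the scan sorts the distinct
distances $d_{(1)} < \dots < d_{(N)}$ and examines each gap
$g_i = d_{(i+1)} - d_{(i)}$:

* a gap is a **candidate** when it reaches the prior
  ($d_{(i+1)} \ge P$) — distances lying wholly below the prior are assumed
  intraspecific and are never separated;
* a candidate is **significant** when $g_i > X\,\bar w_i$, where
  $\bar w_i$ is the mean of up to $W$ (default 10) preceding gaps and
  $X$ (default 1.5) is the relative gap width. The sequence of gaps begins
  with the baseline gap from zero divergence to $d_{(1)}$, which supplies
  the intraspecific scale for the earliest candidates but can never itself
  be significant;
* the first significant gap wins, and haplotypes are partitioned by
  single linkage at its lower edge (the last pre-gap distance): groups are
  the connected components of the graph joining pairs at or below it.

The gap scan is then re-applied *within* every group of three or more
members with at least two distinct internal distances, until nothing
splits (groups of two or fewer are never re-split: a gap needs two
distinct distances). This recursion can pick up finer, locally significant
gaps whose global context hid them. The recursive partition always refines
the initial one.

The whole procedure is swept over a geometric series of priors
$P_k = P_{\min}(P_{\max}/P_{\min})^{k/(s-1)}$. Defaults: $P_{\min} =
0.001$, $P_{\max} = 0.2$, $s = 20$ steps — a range wide enough to cover
the fastest-evolving lineages (some mollusc groups show intraspecific 16S
divergences above 10%), at a resolution that gives the stability rule
below enough successive priors to bite. A `bins` parameter (default 20)
controls only the diagnostic distance histogram.

Very small priors inevitably delimit unrealistically many groups and very
large priors too few; the interesting behaviour is the plateau in between.
A dataset whose largest pairwise distance falls below 0.005
substitutions/site (or with fewer than two distinct distances) is flagged
*degenerate* rather than scanned: no plausible barcode gap can exist below
half a percent divergence, and such datasets are carried through as single
species — matching how families with essentially invariant sequences must
be handled in practice.

### Choosing one partition: the stability rule

At each prior the initial and recursive partitions may disagree; the
smaller group count (and its partition) is retained — the conservative
choice. `select_psh()` then finds maximal runs of successive priors with a
constant count and chooses the **smallest count stable over three or more
successive priors**. Two qualifications, both reported in the output:

* the trivial all-in-one count of 1 is excluded as a candidate whenever
  any other count qualifies, since every dataset collapses to one group at
  large enough priors and that plateau is uninformative;
* ties between equal counts go to the run starting at the lower prior,
  and the reported partition is taken at the chosen run's smallest prior.

The largest prior of the chosen run is reported as the stability limit; on
clean data it falls between the intra- and interspecific scales, typically
close to the interspecific one, because the dominant gap remains the first
significant candidate until the prior passes its upper edge.

## Trees, monophyly and bootstrap

Secondary refinement requires monophyly evidence. Trees are built by
neighbour joining on the K2P matrix (`ape::nj()`), with negative branch
lengths zeroed and the deficit shifted onto adjacent descendant branches
(a common adjustment; path lengths through the node are preserved), and
midpoint-rooted for display. Monophyly of a putative species is the
unrooted *clan* test: the group must be exactly one side of some
bipartition, which makes the test rooting-invariant and means support
attaches to groups rather than nodes. Support comes from a
column-resampling bootstrap (default 1000 pseudoreplicates): each
replicate resamples alignment columns with replacement, recomputes
distances with pairwise deletion of the resampled columns, rebuilds the NJ
tree and re-tests each group; replicates with an undefined distance are
dropped and counted. The run is reproducible given a seed.

## Integration by congruence

`refine()` turns a table of per-PSH evidence into an SSH. A PSH counts as
monophyletic when its NJ bootstrap support reaches 75% in any available
analysis (whole-dataset or subset) — the same threshold commonly used to
display support on published trees; Bayesian posteriors, where available,
are carried as corroborating columns but are not required, and a PSH
represented by a single haplotype is trivially monophyletic. The rules:

* **R1 accept** — a monophyletic PSH becomes an SSH unchanged.
* **R2 split** — a non-monophyletic PSH whose declared child groups are
  each monophyletic and morphologically distinguishable becomes one SSH
  per child group.
* **R3 merge** — a set of PSHs declared morphologically indistinguishable
  from one another is combined into one SSH when their union is
  monophyletic.
* **R4 keep** — members of such a set stay separate when their union is
  not monophyletic: genetic distinctness without morphological backing is
  retained rather than collapsed, since merging non-sister lineages would
  create a non-monophyletic "species".

Morphological uniqueness means external *or* internal (genital) anatomy
distinguishes the PSH; an "uncertain" never vetoes acceptance of a
strongly monophyletic PSH but does not count as uniqueness either. Every
decision is logged with its rule id, and each PSH ends up in exactly one
SSH.

`compare_fauna()` matches SSHs to a checklist by their applied names:
besides one-to-one matches it recognises *lumped* outcomes (one SSH
covering two checklist names), *split* outcomes (two SSHs sharing one
name) and *additional* species (no checklist name), and reports the
percentage increase over the checklist, rounded to the nearest integer.

### The packaged case study

`inst/extdata/` carries a transcribed evidence table for the British and
Irish slug fauna: 45 putative species with their NJ/BI supports and
morphology flags, one declared split (a large-arionid PSH whose children
are supported while the whole is not), three merge candidate sets, two
species from families too invariant to delimit, and the 36-name checklist
of the previously recognised fauna. Blank morphology cells in the source
table are encoded `"no"` and "?" as `"uncertain"`; joint monophyly values
for merge sets are external evidence transcribed from the published trees.
Running `slug_case_study()` reproduces the published refinement: 42
delimited SSH species (44 with the two invariant families), 36 PSHs
accepted unchanged, and 8 additional species — a 22% increase on the
checklist. The `ssh_expected` column in the fixture records the published
outcome for the test suite and is never read by the engine.

## Detecting introgression

`conflict_table()` cross-tabulates each specimen's morphospecies label
against its mtDNA species assignment. Because mtDNA is maternally
inherited, a specimen with species A's anatomy carrying species B's mtDNA
is expected from hybridisation with a B mother followed by backcrossing.
Conflicts confined to a single direction (`one_way`) are the signature of
asymmetric introgression; the reported direction names the morphospecies
receiving foreign mtDNA. `nuclear_congruence()` adds the nuclear view:
when several mitochondrially distinct SSHs are each unsupported as clades
at a nuclear locus while their union is a clade (to the exclusion of a
congruent outgroup species), they are flagged as sharing a nuclear gene
pool — the pattern expected when hybridisation has homogenised nuclear
genomes across lineages that remain distinct in mtDNA.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` generates ground-truth datasets under the
two-parameter (transition-biased) Markov substitution process — the same
model family the K2P distance inverts, so calibration is closed-form: the
expected K2P estimate between two tips equals their path length in
expected substitutions per site. Species ancestors radiate from a root on
a star tree with branch $(\text{inter} - \text{intra})/2$ and individuals
evolve from their ancestor with branch $\text{intra}/2$, so within-species
pairs target `intra` and between-species pairs target `inter` exactly.
Defaults (`intra = 0.01`, `inter = 0.15`, $\kappa = 4$, L = 650, six
individuals per species) mirror the scales of published barcode tables,
where intraspecific means sit at a few percent or less and interspecific
minima run from 0.05 to over 0.2. Haplotype sharing arises naturally at
small `intra`; introgression directives transplant the mtDNA of an exact
(rounded) fraction of a recipient species' individuals onto the donor
lineage while leaving morphology labels untouched.

`simulate_paper_like_suite()` fixes a battery used throughout the tests:
clean sets with 2, 5 and 9 species, a degenerate near-invariant set, an
unbalanced set (1 vs 50 sequences), a one-way introgression set, and a
paired two-locus set in which five species share one nuclear pool while a
sixth is distinct at both loci.

The simulator deliberately omits rate heterogeneity among sites and
lineages, non-star species trees by default (coalescent gene-tree
variance, incomplete lineage sorting), base-composition bias in the
substitution process, and alignment error. Passing tests therefore show
the pipeline recovers planted structure under the distance model's own
assumptions — they do not show robustness to the violations real barcode
data exhibit, where stability plateaus are shorter and support values
lower.

## Numerical and design choices

* Gap candidacy uses the gap's **upper** edge ($d_{(i+1)} \ge P$). The
  alternative (lower edge at or above the prior) makes the sweep collapse
  to one group as soon as the prior passes the largest intraspecific
  distance, destroying the stability plateau the selection rule needs.
* The single-linkage cut is implemented with `stats::hclust(method =
  "single")`/`cutree`; the test suite checks it against an independent
  graph-components oracle on a thousand random matrices.
* Ties in the gap scan go to the lowest rank; group ids are assigned by
  smallest contained haplotype index, making partitions deterministic
  under input permutation.
* NJ agglomeration and its tie behaviour follow `ape::nj`; determinism
  holds for tie-free matrices (additive test matrices are tie-free by
  construction).
* The bootstrap drops (and reports) replicates with undefined distances
  rather than imputing them.
* Problem sizes in the test suite (alignments of a few hundred to 650
  sites, up to ~54 sequences, 100 sweep replicates, 50 introgression
  replicates, 50-replicate bootstraps) were chosen as the smallest scales
  at which the statistical acceptance properties are comfortably
  non-marginal.

## Known limitations

* The gap-detection rule is an operational reconstruction of
  distance-based gap discovery (sliding-window relative-gap test); exact
  numeric agreement with any particular web implementation is not a goal —
  the contract is the sweep semantics and the recovery properties the test
  suite enforces.
* K2P saturation is reported, not worked around; heavily saturated
  datasets need a different distance (or model-based delimitation) and are
  out of scope.
* Bayesian posterior columns in evidence tables are always external
  inputs; the package never runs an MCMC.
* `compare_fauna()` matches names by exact string equality; synonymy and
  orthography must be resolved upstream in the evidence table.
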