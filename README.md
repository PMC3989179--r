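# barcodegap

Species delimitation from DNA-barcode alignments, and its refinement
against morphology and nuclear evidence.

Surveys that barcode a whole fauna face a recurring question: do the
genetic clusters in the data match the species on the books? `barcodegap`
is aimed at taxonomists and molecular ecologists running that comparison.
It takes aligned mitochondrial sequences (COI- or 16S-type fragments) with
specimen metadata and produces, in three stages:

1. a **primary species hypothesis (PSH)** from genetic distances alone —
   haplotype collapsing, Kimura two-parameter (K2P) distances with
   pairwise deletion, barcode-gap partitioning swept over prior maximum
   intraspecific divergences, and a conservative stability rule;
2. a **secondary species hypothesis (SSH)** by *integration by
   congruence* — putative species are accepted, split or merged according
   to neighbour-joining bootstrap monophyly and morphological
   distinctness;
3. a comparison of the SSH to a known faunal checklist, plus screens for
   mitochondrial/morphological conflict (one-way introgression) and for
   species sharing a nuclear gene pool.

A calibrated sequence simulator with planted ground truth (species
structure, haplotype sharing, unbalanced sampling, introgression) backs
the test suite and lets users validate every stage without real data.

## The core statistic

For each pair of sequences, with $P$ and $Q$ the transition and
transversion proportions over sites comparable in both sequences:

$$ d = -\tfrac{1}{2}\ln\left[(1-2P-Q)\sqrt{1-2Q}\right]. $$

For each prior $P_k$ in a geometric sweep (defaults: 0.001 to 0.2 in 20
steps), the ranked distinct distances are scanned for the first gap
$g_i = d_{(i+1)} - d_{(i)}$ that reaches the prior and exceeds $X = 1.5$
times the mean of the preceding (up to 10) gaps; haplotypes are split by
single linkage at the last pre-gap distance, recursively within groups.
The selected PSH is the smallest group count stable over three or more
successive priors. Details, defaults and design choices are in the
vignette (`vignettes/species-delimitation.Rmd`).

## Worked example

Simulate a five-species dataset and delimit it:

```r
library(barcodegap)

sim   <- simulate_dataset(sim_config(K = 5, n = 6), seed = 42)
haps  <- collapse_haplotypes(sim$alignment)
dm    <- k2p_matrix(haps)
sweep <- prior_sweep(dm)
psh   <- select_psh(sweep)
print(sweep)
print(psh)
```

```
Barcode-gap sweep over 20 priors [ 0.001 , 0.2 ]
  group counts (initial): 19 19 19 19 19 19 19 19 11 9 5 5 5 5 5 5 5 5 2 1
  group counts (recursive): 19 19 19 19 19 19 19 19 11 9 5 5 5 5 5 5 5 5 2 1
PSH: 5 putative species, stable over priors [ 0.0163 , 0.115 ]
```

Tiny priors over-split (19 groups), huge priors under-split (1 group);
the stability rule picks the 5-group plateau — the true species count —
stable from prior 0.016 up to 0.115, between the intraspecific (0.01) and
interspecific (0.15) scales. Per-group distances confirm a clean barcode
gap (minimum mean interspecific distance 10–18× the intraspecific mean):

```r
round(group_distance_summary(dm, psh$chosen_partition), 4)
```

```
  group n mean_intra min_inter   ratio
1     1 6     0.0088    0.1378 15.6811
2     2 6     0.0139    0.1434 10.3307
3     3 6     0.0083    0.1494 18.0944
4     4 6     0.0114    0.1378 12.1060
5     5 6     0.0104    0.1626 15.7030
```

The packaged case study — a transcribed evidence table for the 45
putative species of the British and Irish slug fauna, with merge/split
evidence and the 36-name checklist — runs the refinement engine end to
end:

```r
cs <- slug_case_study()
print(cs$ssh)
print(cs$fauna)
```

```
Secondary species hypothesis: 44 species
   accept: 36, degenerate: 2, keep_separate: 2, merge: 2, split_child: 2
Fauna comparison: 44 SSH species vs a checklist of 36
  corresponding to known species: 36 ( 1 covering two known names; 1 known name(s) split across SSHs )
  additional species: 8 (+22% on the known fauna)
```

36 putative species are accepted unchanged; one is split in two, two
pairs/sets are merged, one morphologically indistinguishable pair is kept
separate (its union is not monophyletic), and two invariant families ride
through as single species. Eight SSH species match no checklist name — a
22% increase on the recognised fauna.

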