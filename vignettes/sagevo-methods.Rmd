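---
title: "Methods: strain divergence and recombination from single-amplified genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain divergence and recombination from single-amplified genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

sagevo analyses closely related bacterial strains recovered as
single-amplified genomes (SAGs): partial, unevenly covered assemblies of
individual cells sorted from a community, such as the *Snodgrassella* and
*Gilliamella* symbionts of the honey-bee gut. The scientific question it
serves is how strains that look identical at the 16S rRNA locus can hide deep
divergence and distinct gene repertoires at protein-coding loci, and how much
of that divergence was shaped by homologous recombination. This vignette
documents the models, the numeric choices, and the simulator that makes every
stage testable without external data.

## The pipeline at a glance

1. **Read cleanup** (`clean_read_set()`): multiplexed sequencing misassigns a
   small fraction of reads (~0.3%) to the wrong library. Misassigned reads
   are concentrated wherever the *source* library has ultra-high coverage
   (MDA amplification hotspots, thousands of x), yet they arrive in the
   recipient library at low depth. We therefore map each library's reads
   against the other libraries' contigs exceeding 5000x coverage; reads whose
   pile-up depth within their own set is at most 20x are removed, and reads
   above that depth are kept only if they also align (full-length, ungapped,
   at >= 90% identity) to their own assembly — the rescue that protects reads
   from genuinely conserved loci such as rRNA.
2. **Contig QC** (`filter_contigs()`, `remove_redundant_contigs()`,
   `estimate_completeness()`): contigs are excluded when shorter than 250 bp;
   when shorter than 500 bp with coverage below 5x or no translated-search
   hit against the reference proteome (E <= 1e-5); or when lacking any hit
   against a bacterial protein panel. Exact duplicates (either strand,
   including substrings of longer contigs) are removed. Completeness is the
   fraction of a minimal essential gene set recovered.
3. **Orthologs** (`all_vs_all_search()`, `build_graph_and_cluster()`):
   all-vs-all local protein alignment, hits gated at >= 50% identity and
   > 50% coverage of both sequences, Markov clustering (expansion 2,
   inflation 1.5) of the score-weighted graph, paralog resolution by mean
   identity, and remnant/genome-specific classification of the leftovers.
4. **Divergence** (`ng86_divergence()`, `ml_pairwise_divergence()`,
   `ternary_analysis()`): per-gene and concatenated dS/dN, plus the ternary
   representation of relative dS across strain triplets.
5. **Recombination** (`minimum_recombination_events()`,
   `detect_gi_fragments()`, `r_over_m()`): the Hudson-Kaplan lower bound,
   a gene-conversion fragment scan, and r/m ratios.
6. **Phylogeny** (`build_tree()`, `bootstrap_support()`,
   `topology_concordance()`): JC + neighbor-joining trees, bootstrap
   support, and counting single-gene trees congruent with each split of the
   concatenated tree.

## Divergence estimators

**NG86 counting.** Synonymous sites per codon are the fraction of the nine
single-base changes that preserve the amino acid (changes to stop codons
count as nonsynonymous opportunity), averaged between the two sequences, so
S + N = 3L always. Differences in codons differing at 2-3 positions are
averaged over the mutational paths that avoid stop codons. Proportions are
corrected with Jukes-Cantor, d = -3/4 log(1 - 4p/3); pS >= 3/4 is flagged
saturated and dS reported capped at `ds_cap` (default 3, the same convention
used to call dS >= 3 "at or near saturation" throughout).

**Pairwise ML.** A Goldman-Yang-style codon model with F3x4 frequencies
(position-specific base composition of the pair, floored at 1e-8 so no sense
codon has zero frequency) and free parameters t, kappa, omega. The rate
matrix is normalised to one expected substitution per codon; the two-sequence
likelihood over codon-pair counts is maximised by L-BFGS-B on log-parameters
from three fixed starting divergences (t = 0.1, 1, 3), which makes the fit
deterministic. The fitted model's expected synonymous substitution count
(t rhoS per codon, with rhoS the synonymous share of substitution flow) is
converted to a per-site rate using the same physical NG86-style site counts
as the counting estimator, in which mutations to stop codons count as
nonsynonymous opportunity. One site convention across both estimators keeps
their dS directly comparable; the codeml convention (stop mutations excluded
from the opportunity) would deflate dS by the stop-neighbour flow, about
4-5% under the standard code. Identical sequences return exactly 0. Codon columns containing gaps, ambiguity or stops in either
sequence are dropped pairwise (complete deletion), matching the
counting-method convention.

**Ternary analysis.** For each gene shared by three strains the three
pairwise dS values are capped at 3, normalised to sum to 1, and placed in the
2-simplex; colours follow the maximum raw dS (< 0.1 yellow, >= 0.1 orange,
>= 1 red). Two spread definitions are in circulation — the mean and the
median Euclidean distance from the points to their mean point — so both are
computed and reported; `spread` defaults to the mean. Distances are Euclidean
on the normalised triplets, which equals the in-plane distance because the
simplex is an affine subset of R^3.

## Recombination statistics

**Hudson-Kaplan Rm.** Biallelic segregating sites only; a site pair showing
all four gametes is an incompatible interval, and Rm is the largest set of
pairwise non-overlapping intervals (intervals sharing an endpoint do not
overlap). The greedy earliest-right-endpoint scan is provably optimal for
this interval-scheduling problem; the test suite nevertheless checks it
against an exhaustive branch-and-bound search on 200 random alignments.

**Gene-conversion fragments.** In the spirit of Sawyer's runs test: restrict
to polymorphic columns, score each sequence pair +1 per shared match with a
mismatch penalty set by `gscale` (0: a mismatch ends the tract; 1 and 2:
Kadane maximum-segment scoring with penalties 6 and 3, so larger gscale
tolerates older, partially overwritten tracts). Significance comes from
>= 10,000 permutations of the polymorphic-site columns — the null depends
only on the site and mismatch counts, so it is cached per configuration and
drawn from an internally seeded RNG stream (making repeated pipelines
byte-identical) — with Bonferroni correction across sequence pairs. Only
"global inner" fragments (donor present in the alignment) are in scope. This
is a re-implementation in spirit, not bit-compatibly: the permutation null
replaces the original's Karlin-Altschul tail fit, trading speed for an exact
finite-sample null.

**r/m.** Given per-site probabilities that a substitution arose by
recombination, `all_positions` divides the summed probabilities by the
summed complements; `confident_only` counts sites with p >= 0.95 as
recombinant and p <= 0.05 as mutational and ignores the rest. The package
does not infer these probabilities (no ClonalFrame-style MCMC); they come
from the simulator's ground truth or any external per-site posterior.

## The simulator and what it does (not) emulate

`generate_ancestor()` packs non-overlapping CDS (bodies of sense codons,
random strand) plus one rRNA-like locus into a random replicon.
`evolve_strains()` evolves each strain independently from the ancestor (star
phylogeny) with a Gillespie engine: candidate substitutions arrive at rate d
per site, proposals are uniform over the three alternative bases, proposals
creating stops are rejected and nonsynonymous proposals accepted with
probability omega. Because a codon position with f synonymous alternatives
accrues accepted synonymous changes at rate d·f/3 while contributing f/3
synonymous sites, accepted synonymous substitutions per synonymous site have
expectation exactly d — the quantity dS estimators target. One consequence
worth knowing: two-fold degenerate sites behave as two-state chains rather
than four-state JC, so at high divergence (summed d around 0.6) the mean
synonymous p-distance sits a few percent above the naive 3/4(1 - e^(-4d/3));
the test suite checks the exact expectation by matrix exponential of the
61-state thinned chain, and the plain JC formula at d in {0.05, 0.2} where
the approximation is good.

Recombination overwrites recipient tracts (geometric lengths, uniform donor)
with donor sequence, recording each tract and marking affected substituted
sites with origin 1 in the truth ledger. With `rrna_homogenize`, every
strain's rRNA locus is replaced by a donor copy each generation plus ~0.4%
residual noise, reproducing the signature of interest: 16S identity above
99% while concatenated dS saturates.

`simulate_partial_recovery()` removes uniformly placed intervals totalling
`dropout_fraction` of the genome (MDA dropout), assigns lognormal per-contig
coverage, and boosts a configurable number of contigs to hotspot depth.
Hotspots are drawn from the smallest contigs that can hold a read pair and
never from the rRNA-carrying contig — real MDA hotspots are short
hyper-amplified loci, and excluding the conserved rRNA keeps the simulator's
misassignment truth labels unambiguous with respect to the rescue step.
`simulate_reads()` emits error-free 2x76 nt pairs at ~400 nt inserts; a
pair's probability of being relabeled to another library is proportional to
its source contig's depth, normalised so the expected hopped fraction equals
`misassignment_rate` (default 0.003) — hopping concentrated on
ultra-high-coverage template.

Not emulated: sequencing error (optional uniform rate exists but defaults to
0 — the cleanup logic, not error correction, is under test), indels within
CDS, chimeric MDA artefacts, plasmids, and compositional heterogeneity.
Passing tests therefore demonstrate the *logic* of each stage under the
stated statistical structure, not robustness to every artefact of real SAG
data.

## Numeric and design choices

- **Coordinates** are 1-based inclusive everywhere, in memory and in
  reports — the universal R/Bioconductor convention; mixing coordinate
  systems inside one codebase invites off-by-one errors.
- **Minus-strand CDS** are stored reverse-complemented so codon analyses
  always operate in reading frame; the original strand is retained.
- **Translated search** (contig QC) is six-frame translation plus local
  protein alignment against the panel, gated at E <= 1e-5 under a fixed
  Karlin-Altschul calibration (lambda = 0.267, K = 0.041, the standard
  gapped BLOSUM62/11-1 parameterisation).
- **Mapper**: exact 31-mer seeding with ungapped extension and a 2-mismatch
  cap, trying up to three seed positions and both strands. Error-free reads
  from their true source always carry an exact seed; sensitivity for reads
  with mismatches in all seed windows is deliberately sacrificed.
- **Rescue direction**: a high-pile-up read is rescued by self-consistency —
  alignment to its *own* assembly at >= 90% identity over >= 90% of its
  length (implemented as full-length ungapped alignment with the equivalent
  mismatch allowance). The alternative direction (absence from the foreign
  data) is intentionally not the default.
- **MCL inflation** defaults to 1.5, the common OrthoMCL choice; it is
  exposed in `pipeline_config()`. Self-loops are set to each node's maximum
  incident weight before normalisation, the usual stabilisation.
- **Unclustered genes** with a similarity hit are classified `remnant`
  (partial homology), those with none `genome_specific`; genes dropped by
  paralog resolution stay `paralog_dropped`, so the four classes always
  partition the gene set.
- **Trees**: JC distances with pairwise deletion; saturated pairs
  (p >= 3/4) are a hard error naming the pair. Negative NJ branch lengths
  are clamped to zero with the deficit moved to the sibling edge. Splits are
  compared as canonical bipartitions after pruning to the shared taxon set.
- **Degenerate inputs**: identical sequences give dS = dN = 0 exactly;
  fewer than 10 comparable codons is an error; an empty gene set for
  concatenation is an error; genes whose capped ternary triplet sums to 0
  are dropped and reported.

## Problem sizes used by the test and acceptance runs

These are the package's desk-scale study conditions: 200 random alignments
(4-8 sequences, <= 12 segregating sites) for the Rm oracle; 100 codon-pair
alignments of 1000 codons at true dS 0.2 for estimator recovery; a
two-genome cleanup simulation (60 kb ancestor, 30 genes, 35% dropout, 20x
base coverage, two 6000x hotspot contigs, 0.3% hop rate, ~80,000 read pairs
in total); 50 tract-bearing and 100 tract-free three-sequence alignments
(1500 nt, 10% focal-pair divergence, 25% background branch, 300 nt tracts,
10,000 permutations) for the conversion scan; and a two-strain simulation at
0.8 substitutions per synonymous site per branch for the rRNA-homogenization
signature. `scripts/acceptance.R` re-runs exactly these computations from a
command-line seed.

## Known limitations

- The ML codon model is pairwise-only (no site-rate variation, no shared
  tree likelihood); concatenated estimates treat the concatenation as one
  gene.
- The gene-conversion scan reports fragment boundaries at the outermost
  matching polymorphic sites; boundary precision is limited by polymorphic
  site density.
- r/m requires externally supplied (or simulated) per-site origin
  probabilities.
- The ortholog stage assumes globally unique gene identifiers.
- `run_pipeline()` aligns orthologs positionally when their CDS lengths
  match (the simulator produces no indels) and falls back to protein-guided
  pairwise alignment otherwise; genes that cannot be aligned are skipped and
  logged.
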