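---
title: "Methods: TI-PKS classification, orthogroups and topology tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TI-PKS classification, orthogroups and topology tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lichenpks)
```

`lichenpks` re-implements, as a tested and reusable pipeline, the
comparative analysis of iterative Type I polyketide synthase (TI-PKS)
genes in lichen-forming fungi: classification of PKS domain architectures
into reducing classes and named groups, an ortholog screen with Markov
clustering into orthogroups, per-genome censuses of biosynthetic gene
clusters (BGCs) with an atranorin-cluster screen, and RELL-based tree
topology tests over per-site log-likelihoods. This vignette explains the
models and procedures, the tunable parameters and the numerical choices;
it is the package's own account of its methods.

## Domain grammars and reducing classes

A TI-PKS protein is modelled as an ordered token sequence over a closed
domain alphabet (`domain_tokens()`). Named groups are described by linear
grammars in a packaged registry (`pks_group_registry()`): each element is
mandatory or optional (`[X]`) and may offer alternatives (`X|Y`). An
architecture belongs to a group exactly when it is an expansion of the
grammar — optional elements taken 0 or 1 times, order preserved, no extra
tokens. Because every grammar has a finite expansion set (at most the
product of its alternative counts times two per optional element), the
matcher can be checked exhaustively against full enumeration
(`expand_pattern()`), which the test suite does for every packaged group.

The reducing class is decided by the reductive domains only: `R` when an
enoyl reductase (ER) is present, `PR` when a ketoreductase (KR) is present
without ER, `NR` otherwise, and `not_T1PKS` when the obligatory KS or AT
is missing. The non-reducing grammars do contain a DH-position element;
in NR-PKS proteins this region is a product-template-like domain rather
than a functional dehydratase, so DH deliberately plays no role in the
class call — keying on KR/ER alone reproduces the published class counts.

Two design points were genuinely open:

* **Cross-class grammar overlap.** The reduced expansions of the R-X
  grammar (`KS-AT-[DH]-[ER]-KR-[ACP]`) coincide partly with the PR
  grammar (`KS-AT-[DH]-KR-ACP`): `KS-AT-KR-ACP` is an expansion of both.
  Group R-X is ultimately a clade, not a domain formula, so grammar-only
  evidence cannot decide such cases. `assign_group()` therefore keeps all
  matching candidates, orders class-consistent ones first, flags the
  result as ambiguous, and only promotes a group when orthogroup evidence
  (`orthogroup_group_map()`) supports it.
* **Finer NR groups.** The NR-I…NR-VIII distinctions are narrative rather
  than grammatical; the registry encodes the two subclade-level NR
  grammars plus the NR-IX specialisation (which always carries ADH and
  never NAD after CMeT). Finer NR assignment is left to orthogroup
  evidence. A second ACP is modelled as a single optional repeat (`[ACP]`,
  i.e. at most two copies), since no architecture with more is described.

## Ortholog screen, similarity graph and MCL

`align_pair()` computes an optimal local alignment with affine gaps
(BLOSUM62, gap open 11, extend 1 — common BLASTP-style settings,
configurable via `scoring_scheme()`). Identity is matches over alignment
columns; coverage is aligned query residues over query length. The screen
(`screen_orthologs()`) keeps hits with identity ≥ 30% and query coverage
≥ 50% (defaults of `screen_params()`), ranked by raw score with
deterministic tie-breaks. E-values are not computed: Karlin–Altschul
calibration adds a database-size dependence without changing any decision
made here, because the thresholds are identity and coverage. Note that
the percent *similarity* figures reported in comparative studies are
sometimes positive-scoring fractions rather than identities; this package
reports identity throughout.

The similarity graph averages the two directed scores of each pair and
normalises edge weights to [0, 1] by the maximum observed score; isolated
proteins remain as nodes. `mcl_cluster()` is a from-scratch Markov
Cluster implementation: self-loops at each node's maximum incident weight
(1 for isolated nodes), column normalisation, then alternating expansion
(matrix power 2) and inflation (entrywise power 1.5, the conventional
default, then renormalisation) until the matrix changes by less than
1e-6 or 200 iterations (non-convergence warns and clusters the final
matrix). Values below 1e-12 are pruned for numerical hygiene. Clusters
are read as connected components of the converged flow matrix, which for
a converged run coincide with its attractor systems; the result is always
a partition.

## Censuses and the atranorin screen

`census_genome()` counts clusters by type label and classifies T1PKS core
genes into NR/R/PR via the grammar layer; `aggregate_census()` sums the
TI-PKS totals, expresses the class breakdown as percentages (half-up
rounding at two decimals, which reproduces printed percentages from
integer counts), and reports the mean cluster count (rounded to the
nearest integer) plus extreme genomes with lexicographic, flagged
tie-breaks. The packaged 23-genome census (`census_fixture()`) is typed
in from the published table and is used by the acceptance checks.

`screen_atranorin()` requires a core hit to a PKS23 reference passing the
ortholog-screen thresholds, plus three accessory genes identified by
Pfam accession among the cluster's non-core genes: cytochrome P450
(PF00067), O-methyltransferase (PF08241) and a transporter. Published
descriptions of the cluster disagree on the transporter's accession —
the major facilitator superfamily domain (PF07690) or the WD-40 repeat
(PF00400) — so the accepted set is a configurable, logged policy
(`transporter_pfams()`, default: either). Accessories may sit anywhere in
the cluster record; no gene-distance constraint is imposed, since none is
established. The verdict is a conjunction, hence monotone: deleting genes
can only flip it to negative. `compare_clusters()` matches two clusters'
genes by reciprocal best score (ties broken by smallest positional
offset, keeping arrow plots deterministic) for `plot_gene_arrows()`.

## Alignment trimming and site statistics

`trim_alignment()` fixes an operational two-stage contract approximating
the overlap trimming of common tools (whose exact internal definitions
are not restated in their method descriptions): first drop sequences — a
residue is *good* when at least 70% of the other sequences have a residue
in its column (`res_overlap`), and a sequence survives when at least 60%
of the alignment length consists of its good residues (`seq_overlap`);
then drop columns with fewer than 70% residues among the kept sequences
(`gap_threshold`). The output is always a sub-matrix of the input.
`site_stats()` classifies each column over its non-gap residues as
constant (≤ 1 state), parsimony-informative (≥ 2 states each in ≥ 2
sequences) or singleton, and counts distinct whole-column patterns with
gap as a state; the three categories always partition the sites.

## Likelihoods and topology tests

`subst_model()` builds a reversible rate matrix from packaged
exchangeabilities — Poisson (equal rates/frequencies, used for
closed-form checks) or the standard LG matrix with its published
frequencies, optionally with empirical (+F) frequencies — scaled to one
expected substitution per site per unit branch length. Rate
heterogeneity uses the discrete-gamma approximation with k
equal-probability categories at their conditional means (k and the shape
α are user knobs; nothing is inferred silently). `site_loglik()` is
Felsenstein pruning over distinct site patterns with per-pattern
rescaling against underflow; gaps are missing data. The implementation is
tested against closed two-taxon forms, an exhaustive summation over
internal-node states on small trees (tolerance 1e-10 in log space) and an
independent likelihood implementation.

`optimize_branch_lengths()` maximises the total log-likelihood
coordinate-wise: golden-section search per branch on [1e-8, 20], sweeps
until a full sweep gains less than 1e-6, accepting only non-decreasing
moves (so the trajectory is monotone). Full joint estimation of model
parameters is out of scope; α can be supplied or grid-chosen by the
caller.

The topology tests all operate on a trees × sites matrix of per-site
log-likelihoods via RELL resampling (`rell_resample()`): replicates
redraw site indices with replacement — the same indices for every tree —
and re-sum stored values, never re-optimising. On top sit:

* `kh_test()` — one-sided Kishino–Hasegawa with RELL centring (the
  common implementation choice; sidedness is not dictated by the sources,
  and one-sided matches the published p-values' convention), p = fraction
  of centred null differences at least the observed deficit;
* `sh_test()` — Shimodaira–Hasegawa with per-tree centring and the
  per-replicate maximum;
* `elw()` — expected likelihood weights (mean softmax weight, summing
  to 1);
* `au_test()` — the approximately unbiased test by multiscale bootstrap:
  scales 0.5–1.4 in steps of 0.1, B/10 replicates per scale (total work
  ≈ B), weighted least squares of `qnorm(1 − BP)` on `d√r + c/√r` over
  scales with non-degenerate bootstrap proportions, p = 1 − Φ(d − c);
  trees degenerate at almost all scales are flagged and given p 0 or 1.

`toptest_report()` assembles total log-likelihood, `deltal` (the raw
deficit from the best tree — the convention consistent with published
tables), the four test columns and +/− marks at α = 0.05. A two-row,
one-column matrix of total log-likelihoods is accepted, so printed totals
can be re-analysed for their deficit directly.

## Synthetic data: what it emulates, and what not

`gen_genomes()` plants a configurable number of TI-PKS families shared
across genomes. Each family carries a group label drawn from
`group_frequencies`, whose defaults allocate the census class shares
(44.35% NR / 53.35% R / 2.3% PR, split across named groups within each
class as a fixed package choice), a concrete architecture sampled
uniformly from its group's grammar expansions, and an ancestral protein
from which per-genome members descend by per-site substitution. The
substitution rate is tuned by bisection so the *expected* pairwise
identity sits five points above the requested `within_family_identity`
floor, and the floor is then enforced exactly by bounded regeneration —
the parameter acts as a guaranteed minimum under the package's aligner.
Families descend from independent random ancestors, so between-family
identity is chance level (about 5% per site), far below any sensible
`between_family_identity_ceiling`; separability assertions use
screen-eligible (coverage-passing) hits, because unrelated proteins can
show high identity over very short spurious local alignments that the
coverage threshold removes. Cluster counts per genome are truncated
Poisson (≥ 1, so every genome is censusable), coordinates are 1-based
closed GFF3-style laid along one contig, strands uniform, and accessory
genes carry explicit Pfam accessions because the atranorin screen keys on
them. Selected genomes receive one atranorin-like cluster whose core
derives from the packaged *synthetic* PKS23 stand-in (a random sequence,
deliberately not a real PKS23 — real analyses should supply a real
reference).

Scaled-down problem sizes are package choices: core proteins default to
200 residues and accessories to 120 (real PKSs run to ~2000 residues),
and a handful of genomes with a few clusters each stand in for real
fungal genomes with dozens. Simulated alignments (`gen_alignment()`) draw
root states from the stationary distribution and evolve them along the
tree; there are no indels, no rate variation beyond the discrete-gamma
model, no domain-level homology structure and no annotation noise.
Passing tests therefore demonstrate algorithmic correctness on data whose
generative assumptions match the models exactly — not robustness to
misannotation, alignment error or model misspecification in real
genomes.

Everything is seeded: one master seed per run, with each stochastic stage
deriving a labelled substream (`derive_seed()`), so identical parameters
reproduce bundles byte for byte and pipeline stages are independently
reproducible.

## Test problem sizes

The suite checks the alignment scorer against a brute-force DP oracle on
random pairs of up to 12 residues; MCL against an independent
matrix-iteration oracle on small random graphs; orthogroup recovery
(adjusted Rand index 1.0 and exact screen recovery) on seeded bundles at
60% within-family identity; pruning against exhaustive enumeration on
trees of up to 5 leaves; branch-length recovery within 10% on a
20,000-site simulation; and the size and power of KH/AU over 200 seeded
1,000-site quartet simulations with B = 1,000 (rejection of the
generating topology ≤ 8%, allowing binomial error around the nominal 5%;
rejection of a strongly separated alternative ≥ 90%). These sizes were
chosen once as the smallest that make the checks statistically
meaningful.

## Known limitations

* Group grammars cover the subclade-level NR structure and the named R
  groups with distinctive grammars; narrative distinctions between other
  groups are out of grammar reach by design.
* The screen reports identity, not BLAST "similarity"; comparisons with
  published similarity percentages are approximate.
* The AU implementation follows the canonical multiscale-bootstrap
  recipe; exotic likelihood surfaces with bootstrap proportions
  degenerate at interior scales fall back to flagged degenerate
  p-values rather than attempting extrapolation.
* Tree *search* is out of scope throughout: topologies are inputs, and
  only branch lengths are optimised.
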