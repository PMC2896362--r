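---
title: "Methods: from gel spots to pathways, networks and a Bayesian ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gel spots to pathways, networks and a Bayesian ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

protpipe implements the inference chain of a classic two-condition
comparative proteomics experiment: two cell lines are separated on 2-D
gels, differential spots are identified by peptide mass fingerprinting
(PMF), the identified proteins are interpreted through pathway
over-representation and interaction-network construction, and selected
fold changes are validated by Bayesian analysis of western-blot
densitometry. This vignette describes the models and procedures, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the design decisions taken where the workflow's
published description left the choice open.

## Spot quantification

A spot's normalized volume is its optical density divided by the total
density of all spots in the same gel, so normalized volumes sum to one
per condition. Fold change is reported symmetrically as
`max(normA, normB) / min(normA, normB)` (always at least 1) with a
separate direction flag; this avoids ratios below one and makes a
single threshold serve both directions. Two thresholds are used in the
standard workflow: a permissive 1.1-fold cut to *pick* spots for mass
spectrometry, and a strict 1.5-fold cut to define the *focus set* for
pathway and network analysis. "At least x-fold" is read inclusively
(`>=`): a 1.5-fold spot survives a 1.5-fold filter. Spots absent from
one gel are excluded with a warning rather than imputed — the analysis
concerns the spots matched in common. All logarithms in the package are
decadic, matching the blot model below.

Because both gels' normalized volumes sum to one, it is arithmetically
impossible for every null spot to sit at a ratio of exactly 1 while
changed spots sit above 1: the changed spots' excess mass must be
compensated somewhere. In real gels the compensation is diluted over
hundreds of spots and ignored. The synthetic generator instead plants
de spots in direction-balanced pairs (up in A, then up in B) that share
a base volume, so at a common planted fold the two gels' totals balance
exactly and the zero-noise limit reproduces planted folds and unit null
ratios to machine precision. With an odd number of de spots, or
per-spot folds that differ within a pair, a residual compensation of
order (fold − 1) · de-fraction remains, exactly as in real data.

## Peptide mass fingerprinting

**Digestion.** Trypsin cleaves C-terminal to Lys or Arg except before
Pro (the Keil rule). Peptides with up to one missed internal cleavage
site are generated by default, matching common search practice for
single-protein spots.

**Masses.** Peptide m/z is the sum of monoisotopic residue masses plus
water (18.010565 Da) and one proton (1.007276 Da), as singly charged
ions. Cysteines carry a fixed +57.02146 Da carbamidomethyl group: the
alkylation chemistry in these workflows is iodoacetamide, whose product
is carbamidomethyl-Cys, even though PMF search settings are sometimes
(mis)labelled carboxymethyl; the carboxymethyl mass (+58.00548) remains
selectable in `pmf_config()`. Methionine oxidation (+15.9949) is a
variable modification expanded to one candidate mass per oxidation
count. The implementation reproduces the ACTH(18-39) internal calibrant
(m/z 2465.1989) to within 0.001.

**Background elimination.** PMF batches from one gel share contaminant
peaks (keratin, trypsin autolysis, matrix). Peaks are pooled across the
batch and clustered into bins by single-linkage agglomeration with a
100 ppm gap threshold — twice the 50 ppm search tolerance, so that
jittered observations of one contaminant land in one bin while distinct
peptides generally do not. A bin observed in strictly more than 10% of
the lists is removed from every list. The rule needs a denominator to
be meaningful, so batches smaller than 10 lists are refused instead of
silently filtered. Occurrence is counted per input batch. Chance m/z
collisions between genuine peptides of unrelated proteins can put a
real mass bin just above the cut in small synthetic batches; the
planted contaminants are distinguished by their much higher occurrence.

**Matching and scoring.** An observed peak matches a theoretical mass
when their relative deviation is at most 50 ppm (inclusive); each peak
matches only its nearest candidate in ppm. Three scoring algorithms
stand in for the usual trio of proprietary search engines, preserving
the published two-of-three consensus rule while making the scores
reproducible:

1. *shared peaks* — the number of matched observed peaks;
2. *coverage* — the percentage of the candidate's residues inside at
   least one matched peptide;
3. *rarity-weighted* — the sum over matched peptides of −log10 of the
   fraction of all database peptide masses in the peptide's 100 Da
   bin, so matches in sparsely populated mass regions count more (a
   deliberately simple cousin of frequency-based PMF scores).

Ranks are assigned within each scorer among candidates with positive
score, ties broken by accession order; zero-score candidates are
unranked, so an empty spectrum can never reach consensus. "Ranked
high" is not quantified in the published description; here it means
rank at most `r_top = 5`, exposed in `pmf_config()`. A candidate is a
consensus identification when it ranks high in at least two scorers.

**Mr/pI plausibility.** The apparent molecular mass and isoelectric
point of the gel spot support an identification when they agree with
the candidate's theoretical values within 20% relative Mr and 1.0 pH
unit — deliberately loose bands reflecting the qualitative use of this
check. The theoretical pI solves the Henderson–Hasselbalch net-charge
equation (termini plus D, E, C, Y, H, K, R; Bjellqvist pKa set,
embedded as `PKA_BJELLQVIST`) by bisection; the charge curve is
strictly decreasing in pH, so the root is unique.

## Pathway over-representation

For each pathway the 2×2 contingency quadruple is `(k, n, K, N)`: `k`
focus proteins among the pathway's `n` members, `K` focus proteins in
the annotation universe of `N` molecules. The p-value is the
right-tailed Fisher's exact (hypergeometric) tail, computed as the
explicit tail sum of `dhyper` terms, with Benjamini–Hochberg correction
across pathways (via `stats::p.adjust`). Significance uses strict
`p_bh < 0.05`. The coverage ratio is `k/n`, reported alongside the
p-value as a second ranking axis.

The universe `N` defaults to the union of all pathway annotation
members — the natural reading of "all pathway annotations" — but is
configurable to an explicit background list, because knowledgebase
tools differ on whether unannotated molecules count. Focus proteins
outside the universe are dropped with a warning (they reduce `K`).

## Focus networks

Knowledgebase network algorithms are unpublished; their stated
objective — include as many focus proteins as possible, plus the
non-focus connectors needed for connectivity — is implemented as a
deterministic greedy growth with documented tie-breaks. The seed is
the focus protein with the most focus neighbors (ties by accession
order). Each step adds the neighboring candidate that (1) prospectively
connects the most not-yet-included focus proteins (itself counted if
focus), then (2) has the most edges into the current set, then (3) is
first in accession order. When no candidate offers focus gain but
reachable focus proteins remain, the step tunnels along shortest paths
toward the nearest one. Growth stops at 35 nodes (a typical
knowledgebase network size, configurable) or when every reachable focus
protein is included. After a network is emitted, its focus proteins are
removed and growth repeats until the focus set is exhausted;
Benjamini–Hochberg correction is applied across the emitted networks.

With a non-binding size cap this greedy includes every reachable focus
protein, so it attains the maximum focus count of any connected
subgraph of equal size; the test suite verifies this against exhaustive
subgraph enumeration on small random graphs. When the cap binds, the
greedy is a heuristic and can be beaten by exhaustive search — a known
limitation of any polynomial surrogate for what is essentially a
Steiner-tree objective.

A network's p-value is the right-tailed hypergeometric probability of
drawing at least its observed focus count in a uniform sample of its
size from the graph; the score is −log10(p), and a score of at least 6
(p < 10⁻⁶) flags significance. This sampling model is an explicit
design choice: the published description specifies only "a score
derived from a p-value". Nodes of degree at most one within the
network are classified as *hanging* — swept in by a single association
rather than forming a loop.

## Bayesian ratio estimation

Densitometry replicates are normalized to the loading control (e.g.
GAPDH); the model is `log10(X_A) = R + log10(X_B)` with replicate
log-ratios `y_i ~ Normal(R, sigma²)`. The published description states
the mean model but neither likelihood nor prior; the package adopts the
minimal Gaussian likelihood on log-ratios with flat priors on R and on
log sigma, and samples sigma rather than fixing it. The phrase "an
initial unbiased gaussian prior distribution was used to propose new
steps" conflates prior and proposal; it is read here as a zero-mean
Gaussian random-walk *proposal* whose scale is tuned, with the
alternative reading (a Gaussian prior on R) available as
`prior = "normal"`.

Sampling is random-walk Metropolis on `(R, log sigma)`. During burn-in
the proposal scale is multiplied or divided by 1.1 after each
100-iteration block according to whether the block's acceptance exceeds
or falls short of the 0.4 target; the scale is frozen afterwards so the
retained samples form a genuine Markov chain. Three chains start
overdispersed at the sample mean and ±2 sample standard deviations.
Convergence is assessed by the Gelman–Rubin potential scale reduction
factor, `sqrt(((n-1)/n W + B/n) / W)`; summaries refuse to pool chains
whose PSRF for R is 1.1 or above. The pooled post-burn-in tails give
the posterior mean and median of R, an equal-tail 95% credible
interval, the fold-change point estimate `10^R`, and the tail
probability `P(R <= 0)` used as the significance measure for up-in-A
claims (reported as `< 1/n` when no sample crosses zero). "Tails of
the chains following convergence" is read as the post-burn-in final
segments, not the distributional tails. A sigma floor of 1e−6 guards
the degenerate case of identical replicates. Defaults are 15000
iterations with 5000 burn-in per chain, which on the six-replicate
problems used here yields effective sample sizes far beyond what the
±0.05 recovery checks require, at well under a second per run.

## The synthetic-data generator

All inputs are generated with planted ground truth under one global
seed, split into per-generator child seeds by a fixed affine-mod
scheme (`child_seed`), so each input can be regenerated independently.
The default study is desk-scale rather than full-scale: 60 proteins of
150–400 residues, 60 spots with 10 planted at 2-fold under 10%
multiplicative log-normal noise, one peak list per spot (70% peptide
detection, 10 ppm Gaussian mass jitter, 6 shared contaminants at 15%
occurrence), 12 pathways of 4–10 members with one planted at 80%
purity from the de proteins, a 240-edge interaction graph wiring 60% of
the pairs inside one 20-node community around the de proteins, and 6
densitometry replicates at `true_R = log10(1.4) ≈ 0.146` with 0.05
log10 replicate sd — the order of fold change and replication typical
of validation blots. Noise is multiplicative log-normal throughout
because gel and film densities are positive and right-skewed.

The generator emulates the *statistical* structure the pipeline
consumes, not the physics: no gel images, streaks or saturation, no
isotope envelopes or fragmentation, no chromatography, and protein
sequences are random rather than homologous. Passing tests therefore
demonstrate that the inference chain recovers planted signal under
realistic noise of the assumed form — not that it is robust to
correlated spot artifacts, shared peptides between homologs, or
knowledgebase annotation bias, all of which real studies face.

## Numerical choices

- Fisher tails are explicit `dhyper` sums, clamped to 1 against
  floating-point overshoot when the full support is summed; tests
  verify equality with binomial-coefficient enumeration for N ≤ 30.
- pI bisection runs on pH ∈ [0, 14] to 1e−4; monotonicity of the
  charge curve guarantees uniqueness.
- ppm matching is inclusive at the tolerance; nearest-in-ppm wins, and
  because ppm normalizes by the theoretical mass, the winner between
  two absolutely equidistant candidates is the higher mass.
- All orderings (scorer ranks, pathway and network ties, greedy
  candidate selection) break ties by accession/pathway identifier, so
  every result is invariant to input order.
- Degenerate inputs fail loudly: all-zero gel conditions, sub-minimum
  PMF batches, single-replicate densitometry, unconverged chains.

## Limitations

- The three PMF scorers are reproducible surrogates, not
  reimplementations of proprietary engines; absolute scores are not
  comparable to Mascot/Aldente/MS-Fit, only the consensus logic is.
- The greedy network growth is optimal only when the size cap does not
  bind (see above).
- The enrichment universe is a modelling choice; with a handful of
  pathways the Benjamini–Hochberg correction is coarse.
- The expression-ratio model assumes exchangeable Gaussian log-ratio
  replicates; systematic loading-control error is not modelled.
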