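---
title: "Phylogenetic core groups: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic core groups: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgpipe)
```

## The problem

A Phylogenetic Core Group (PCG) is a cluster of marker-gene sequences, fixed
at the highest identity threshold at which the cluster occurs in *every*
sample of a sample set, after sequences already captured at higher thresholds
have been removed. The idea is that when a niche requires a phylogenetically
conserved set of traits, its occupants form a discrete portion of the
phylogeny — and that portion should surface as a ubiquitous sequence cluster.
Whether a PCG reflects such a *phylo-niche*, a niche defined by traits
without phylogenetic signal, or mere sampling structure cannot be decided
from the clusters alone; it requires knowing how many niches were sampled and
whether assembly within them was neutral.

`pcgpipe` implements a complete workflow for this question in two halves:

1. a **simulator** that builds phylogenies, traits (divergent, convergent,
   horizontally transferred), marker sequences, and sample-by-taxon count
   tables under controlled assembly processes, so that every claim about the
   detection side can be checked against data with known truth;
2. a **detection pipeline**: community classes from beta-diversity, a
   per-class neutrality test with per-taxon departure calls, nearest-taxon
   dispersion, PCG determination, and a final niche-type classification.

## The assembly model

### Neutral sampling law

A local community of `depth` reads is drawn from a metacommunity with
relative abundances $p$ by dispersal-limited sampling. We use the
Dirichlet-multinomial form: latent relative abundances
$x \sim \mathrm{Dirichlet}(N m \, p)$ followed by a multinomial draw of $N$
reads, with $N$ the depth and $m \in (0,1]$ the migration parameter. Small
$Nm$ means strong drift: single taxa dominate samples and whole clades drop
out of individual samples — the regime in which coarse (genus- or
family-level) PCGs exist at all.

Implementation is by normalized gammas,
$g_i \sim \Gamma(\text{shape} = Nmp_i w_i v_i,\ \text{rate} = v_i)$,
$x = g / \sum g$, which reduces to the Dirichlet when all weights are 1 and
gives selection two distinct channels:

* **share weights** $w$ multiply the expected share ($\mathbb{E}[x_i]
  \propto p_i w_i$) — a classical fitness multiplier on effective
  immigration. A crucial identifiability fact drove this design: a pure
  share reweighting is *exactly* absorbed into a rescaled metacommunity and
  migration parameter, and is therefore undetectable by any
  occupancy–abundance neutrality test. A simulator that modelled selective
  advantage only this way would make its own detection stage vacuous.
* **stability weights** $v$ multiply the concentration of the local
  population at fixed mean: a taxon with $v_i > 1$ fluctuates less, and so
  occupies more samples than a neutral taxon of equal mean abundance. This
  is the channel the neutrality test genuinely detects. A "selective
  advantage" in [make_niche()] sets both channels, reading the advantage as
  better establishment *and* persistence.

### Traits and niches

Traits live on branches and are inherited by the subtended clade
(`branch_conserved`), appear independently on several branches while
encoding one function (`convergent`), or jump lineages (`hgt`, with donor
branch recorded). A niche is labelled by its required trait or function set;
species covering the requirements are eligible, all others have zero counts
in every sample of that niche.

### Sequences

Marker sequences evolve by Jukes–Cantor along the tree; expected pairwise
identity at patristic distance $d$ is $1/4 + 3/4\,e^{-4d/3}$. The worked
four-species example instead *plants* substitutions in disjoint site blocks
so the identity hierarchy is calibrated exactly: ESV variants of one species
cluster at 0.99, species of one genus at 0.97, the two genera at 0.92, with
gaps below 0.99 and 0.95 so no cluster forms at intermediate rungs.

## The detection pipeline

### Community classes

Classes are discovered by average-linkage hierarchical clustering of sample
distances (Jaccard on ESV presence/absence by default; Bray–Curtis
available). Two non-obvious choices, both forced by observed failure modes
of the naive recipe:

* **Presence/absence as default metric.** Under strong drift each sample is
  dominated by a different taxon, so abundance-based distances genuinely
  cluster samples by dominant ESV even in a single homogeneous niche, and
  conversely dilute two-niche structure whose real signal is *which* taxa
  occur. The class concept targets environmental filtering of membership,
  which Jaccard reads directly.
* **Selection-aware significance.** A label-permutation test applied to a
  partition *chosen from the same data* is badly anti-conservative (the
  partition was optimized to look significant). `find_classes()` therefore
  judges the best silhouette against a null that repeats the entire
  selection: each taxon's counts are independently shuffled across samples
  (per-taxon abundance and occupancy preserved, sample structure destroyed),
  the clustering and silhouette search is re-run, and a gap-statistic
  p-value is computed from the null curves. The plain label-permutation
  test, `class_significance()`, is kept for testing a *given* partition,
  where it is exact.

Candidate class numbers whose smallest class would have fewer than
`min_class_size` (default 10) samples are not admissible: a class must carry
enough samples to reconstruct its metacommunity downstream. With fewer than
4 samples class discovery is refused as undecidable rather than failing.

### Neutrality test

`sloan_fit()` fits the occupancy–abundance form of the neutral model: the
detection probability of a taxon with metacommunity abundance $p$ is the
Beta-binomial survival $1 - \mathbb{E}[(1-x)^{N_s}]$ with
$x \sim \mathrm{Beta}(Nmp, Nm(1-p))$, averaged over the per-sample depths
$N_s$ (binned to at most 8 values). The composite $Nm$ is estimated by least
squares on the observed occupancy cloud, with a log-spaced grid bracketing
the optimum (the SSE profile need not be unimodal). `predicted_occupancy()`
exposes the continuous-limit form (Beta survival at a detection limit),
which is the large-depth limit of the fitted quantity.

Per-taxon calls come from a **neutral envelope**. The fitted model is
resimulated as whole pseudo-datasets; each is refitted, and the pooled
pseudo residuals give local quantile bands as a function of *observed* mean
abundance. Two details matter:

* the envelope pushes draws through the full observation process (latent
  Dirichlet, multinomial reads, trimming of unobserved taxa), because a
  taxon detected once has its abundance underestimated by an order of
  magnitude, and a band conditioned on that misestimated abundance must
  marginalize over the error;
* the plug-in parameters are jittered by their own estimated sampling
  uncertainty (per-taxon lognormal jitter of $\hat p$ by its standard error;
  lognormal jitter of $\widehat{Nm}$ by the spread of pilot refits), the
  standard smoothing that repairs parametric-bootstrap undercoverage.

A taxon above/below its band is called `above`/`below`. The verdict compares
the *number* of departing taxa to the null distribution of that number in
the envelope itself: `neutral` within its 97.5% quantile, otherwise
`subset_departure` when fewer than half the taxa depart and
`global_departure` when at least half do. Fixed-fraction verdict cutoffs
(e.g. "neutral iff < 5% depart") are not calibrated: with well-sized 95%
bands the expected departing fraction *equals* 5% under neutrality, so such
a rule rejects half of all truly neutral datasets.

For subset departures, `run_pipeline()` automatically refits without the
departing taxa. If the refit is itself non-neutral, the departure was not
attributable to a subset and the verdict escalates to `global_departure` —
the operational version of the distinction between departure "from subsets
of species" and "from the community as a whole".

### Phylogenetic dispersion

`mntd()` is the mean nearest-taxon patristic distance; `nti()` compares it
to draws of equally many tips from a pool (all tree tips by default — the
simulator deliberately embeds sampled clades in a larger regional phylogeny
so this null is informative). The z keeps the sign of the distances: $z \le
-2$ is clustered, $z \ge 2$ overdispersed. On pools small enough the null is
enumerated exactly. `beta_nti()` is the between-community variant
(symmetrized nearest-taxon distance between two memberships): significantly
positive z separates memberships drawn from distant clades (heterogeneous
selection), significantly negative z memberships from one narrow clade
(homogeneous selection). Degenerate nulls (zero variance, e.g. community =
pool) yield an explicit `undefined` call.

### PCG determination

Sequences are clustered by complete linkage on $1 -$ identity — chosen so a
threshold is a guaranteed identity floor within every cluster — and the
ladder (default $1.00, 0.99, 0.97, 0.95, 0.92, 0.90$; 0.97 is the
conventional OTU rung) is descended from the top: clusters of still-unassigned
sequences whose summed counts reach `min_count` (default one read) in every
sample become PCGs and are removed. Ties and input order are neutralized by
lexicographic processing. Sequences never captured are reported as the
non-core residual. `pcg_per_class()` repeats the search inside each
community class, which is the robust variant: one class's core is not
diluted by samples of another class.

### Classification

`classify_niche()` is a pure decision table over (classes found, verdict,
dispersion, refit outcome): neutral + clustered is a neutral phylo-niche;
neutral + overdispersed a neutral nonphylo-niche; a subset departure whose
exclusion restores neutrality is a mixed neutral/selective niche; a global
departure is a selective phylo-niche when clustered and `other_interactions`
otherwise. All other combinations are `undecidable` — the table is total by
construction. Communities shaped by reciprocal dependence of distant clades
(the niche-construction scenario) map to `other_interactions` but are *not*
claimed detectable by neutrality testing alone: their abundance
distributions can be compatible with a neutral model.

## Study conditions of the bundled scenarios

The scenario generator's defaults are the package's study conditions; they
were fixed once, by design-time calibration, to make two requirements hold
simultaneously with high per-seed probability:

* **ladder structure** — in scenario 1 every genus (and species, and ESV)
  cluster must be absent from at least one sample while the family is
  ubiquitous, which requires strong dispersal limitation (clade-level
  Dirichlet concentration well below 1);
* **test calibration** — the neutrality verdict must remain calibrated and
  the class search quiet on those same deeply drift-dominated tables.

The frozen values: 11 ESVs per species (scenario 4: 4 ESVs, where class
detectability needs higher per-ESV occupancy), species masses split over
ESVs by a Dirichlet(4) draw, depth 2000 reads; scenarios 1/2/3/5: 60
samples, $m = 2\times10^{-4}$; scenario 4: 60 samples per niche,
$m = 1.25\times10^{-4}$; scenario 6: 80 samples, advantage 5 on species SA;
selective: a 16-tip clade of a 64-tip pool, 80 samples, $m = 10^{-3}$, with
the clade's adaptive trait in an efficient ($v = e^{2}$) and an inefficient
($v = e^{-2}$) variant. Scenario 5 generates data distributionally identical
to scenario 1 within the family — its truth label (neutral nonphylo-niche,
the niche being defined by convergent star traits) is deliberately *not*
recoverable from this sampling, which is the known ambiguity of the design;
it is excluded from recovery benchmarks. Scenario 4's pooled-versus-split
neutrality contrast is demonstrated at a milder migration
($m = 5\times10^{-3}$): at the PCG-calibrated defaults the pooled two-niche
signal drowns in abundance uncertainty.

These synthetic communities emulate dispersal-limited sampling, clade-level
trait filtering, selection acting on establishment/persistence, and a
calibrated sequence-identity hierarchy. They do **not** emulate sequencing
error or chimeras, compositional biases of library preparation, time series
or priority effects, within-genome 16S copy variation, or continuous
environmental gradients (which the class framework explicitly does not
address). Passing tests therefore validate the method's logic under its own
model, not robustness to those artefacts.

## Numerical choices and degenerate inputs

* Envelope size: 150 resimulations plus 30 pilot refits; band level 0.95;
  local bands from the 200 nearest envelope points on a 40-point log-grid.
* The gamma sampler can underflow to an all-zero sample at extreme
  dispersal limitation; the most abundant taxon then receives the sample
  (one guard draw), keeping column sums exact.
* Samples emptied by taxon exclusion are dropped before refitting; refits
  leaving fewer than 5 taxa return verdict `undecidable` instead of failing.
* `cutree` thresholds add $10^{-9}$ so that identity exactly at a ladder
  rung joins the cluster.
* All randomness flows from one integer seed through stage-specific derived
  seeds; RNG state of the calling session is restored after every call.

## Limitations

The neutrality machinery is calibrated by simulation from the fitted model,
which costs roughly 180 refits per call — noticeable on tables with
thousands of taxa. The class search tests only the best partition per k
and, like any co-occurrence method, cannot distinguish niche structure from
unmodelled compositional coupling; its shuffle null preserves per-taxon
margins only. Trait identification from marker sequences is out of scope:
the pipeline says *where* in the phylogeny a core lives and which assembly
regime is consistent with it, not which genes are responsible.
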