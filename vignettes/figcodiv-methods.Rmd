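---
title: "Methods: barcode delimitation and codivergence testing for fig wasp communities"
author: "figcodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode delimitation and codivergence testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(figcodiv)
```

# The scientific problem

A fig species hosts a closed community of chalcid wasps organised into
five ecological guilds: the obligate pollinator, non-pollinating small
gallers, the small parasitoids/kleptoparasites that attack them, large
gallers of fig wall tissue, and large parasitoids.  When the host
occurs on two continents, the central comparative questions are
(i) which wasp species and genera are shared, (ii) whether the two
communities keep the same guild structure, and (iii) whether the
intercontinental splits of the resident lineages happened together — a
single inherited "ancestral community" — or guild by guild, as when
herbivores expand their range ahead of their parasitoids.

`figcodiv` implements that full chain for two-marker barcode data
(mitochondrial COI standardised to a 394 bp fragment, nuclear ITS2 of
variable length): distance-based species delimitation, community
composition tables, hierarchical approximate Bayesian computation
(hABC) over divergence histories, and strict-clock split dating —
together with a coalescent community simulator that provides data with
known truth for every stage.

# Distances and species delimitation

## Kimura two-parameter distances

All delimitation thresholds operate on the Kimura two-parameter (K2P)
distance.  For a pair of aligned sequences let $P$ and $Q$ be the
proportions of sites differing by a transition and a transversion among
*pairwise-complete* columns (both residues in `A,C,G,T`), then

$$d = -\tfrac12 \ln\!\big[(1-2P-Q)\sqrt{1-2Q}\,\big].$$

Numerical choices:

* **Pairwise deletion.** Columns with `-` or `N` in either sequence are
  dropped per pair, and the per-pair count of used columns is kept in
  the distance object.  ITS2 carries indels and COI has failed
  stretches; complete deletion would discard most of the alignment.
* **Saturation flags.** When $1-2P-Q \le 0$ or $1-2Q \le 0$ the
  logarithm is undefined; the entry is flagged and excluded from
  summaries, never imputed.  This happens routinely between genera and
  is not an error.
* **Ambiguity codes.** Inputs are upper-cased and `U` is mapped to `T`;
  IUPAC codes other than `N` are rejected because the distance is
  defined over unambiguous bases.
* Distances are held internally in substitutions/site and rendered as
  percentages (×100) only in reports.

## Delimitation criteria

Species hypotheses are built genus by genus:

1. **Primary partition.** Single-linkage clustering of COI K2P
   distances at the fixed 3% cutoff, split by region: a delimited
   species never spans continents.  Single linkage at a threshold is
   exactly the connected components of the graph with an edge wherever
   $d \le$ cutoff; it is computed through the single-linkage dendrogram
   (`hclust`), whose merge heights equal minimum inter-cluster
   distances.
2. **Empirical threshold.** The "95% interval of intraspecific
   distances" rule is implemented distributionally: the 97.5th
   percentile of all intraspecific distances pooled across the primary
   partition.  Both flags (`within_3pct`, `within_CI`) are always
   reported; where they disagree the 3% rule decides the partition,
   since it is the criterion applied throughout the original analyses.
3. **Monophyly.** Each hypothesis is checked for monophyly on
   within-genus neighbor-joining trees per marker.  On an unrooted tree
   monophyly is defined as bipartition membership (no outgroup exists
   inside a genus alignment).  NJ replaces Bayesian tree inference
   deliberately: the delimitation criteria, not the tree engine, are
   the scientific content, and NJ on the same K2P matrix is
   deterministic at desk scale.  Negative NJ branch estimates are
   clamped to zero with the deficit moved to the sibling edge.
4. **Marker congruence.** An individual is flagged as a conflict when
   its nearest ITS2 neighbour belongs to a different COI species while
   members of its own species have ITS2 data and sit farther away.
   Conflicted individuals stay assigned by COI (COI primacy) — the flag
   mirrors how incongruent individuals are narrated rather than
   re-assigned in practice.
5. **Missing markers.** ITS2-only individuals are attached to the
   nearest delimited species within the ITS2 threshold; coherent
   ITS2-only clusters distant from every species become
   `possible_additional` species, reported separately and counted as a
   range in composition tables, never silently merged.  A genus with a
   single sequenced individual yields a low-confidence singleton.

## MOTU sweep and the barcoding gap

`motu_sweep()` clusters COI sequences by single linkage across a cutoff
grid (default 0–10% in 0.25% steps).  MOTU counts are non-increasing
and the partitions nest as the cutoff grows.  The barcoding gap is read
as the longest run of consecutive cutoffs with a constant MOTU count,
excluding the terminal all-one-cluster plateau; ties break toward the
lower cutoff, and a profile that never repeats a count returns a
distinguished no-gap value.

## Intercontinental sisters

Within a genus, two species form a sister pair when each is the
other's nearest heterospecific (minimum defined K2P between members)
and they come from different regions.  Genera present in one region
only contribute nothing.  Because delimited species never span regions,
"shared species" are counted through the genus-level COI cluster
recorded before the region split: a 3% cluster containing both
continents is the signal that one species occurs in both.

# The hABC codivergence test

## Model

Each intercontinental sister pair $i$ follows a two-population
isolation coalescent: lineages coalesce within each descendant
population at rate $k(k-1)/\theta$, merge into the ancestral population
at the split, and coalesce there under $\theta_{anc}$.  Time is
measured in expected *pairwise* substitutions per site, so a pair with
divergence time $\tau_i$ split $\tau_i/2$ lineage-units ago and the
expected raw between-population diversity is roughly
$\tau_i + \theta_{anc}$.  Mutations follow a Poisson process along
branches with Jukes–Cantor substitution — a documented simplification
of the HKY default used by the reference tool; at the divergences
involved here (up to ~35% pairwise) the model-choice surface is
insensitive to the transition/transversion ratio.  The simulator is
implemented in C++ and is exact (sequences are evolved site by site, so
multiple hits saturate naturally).

## Hierarchical prior

A draw from the prior consists of:

* a partition of the pairs into divergence events from a Chinese
  restaurant process whose concentration $\alpha$ carries a diffuse
  Gamma(shape 2) hyperprior;
* one event time $\tau \sim \mathrm{Uniform}(0, \tau_{max})$ per event,
  with $\tau_{max} = 0.35$ by default (≈18 Ma at the 1.9%/Myr clock,
  spanning the plausible 4–16.5 Ma window with headroom);
* independent $\theta \sim \mathrm{Uniform}(0, \theta_{max})$ for each
  descendant and ancestral population, $\theta_{max} = 0.02$ by
  default.

The divergence-scenario labels (two, four, six events) are read as the
prior mean of the number of events $\Psi$; the Gamma scale is solved by
quadrature so $E[\Psi]$ matches the label.  One boundary property of
the Dirichlet process matters here: for $n$ pairs, $E[\Psi] < n$ for
every finite concentration, so the six-event scenario with six pairs is
calibrated to $E[\Psi] = 5.85$, the closest attainable mean.

## Rejection step and statistics

Each prior draw is pushed through the simulator and summarised per pair
by six statistics: $\pi_b$ (mean between-population diversity),
$\pi_w$ per side, Watterson's $\hat\theta_W = S/(a_n L)$ per side, and
the net divergence $\pi_{net} = \pi_b - \bar\pi_w$.  These are the
standard statistics of multi-pair codivergence ABC and each is testable
in closed form.  Statistics are standardised by the simulated pool's
mean and standard deviation (the observation is a single vector and
cannot set the scale); zero-variance statistics are dropped with a
warning.  The `keep_fraction` closest draws in Euclidean distance form
the posterior sample.  With `keep_fraction = 1` the posterior provably
equals the prior, which the tests exercise as the no-data limit.

## Guild models and Bayes factors

Nine constraint models are built from the guild labels: synchrony
models SYNC(set) hold when every pair in the set shares one event;
precedence models BEFORE(set1, set2) hold when the *youngest* member of
set1 is strictly older than the *oldest* member of set2.  Strict
dominance is deliberate — a mean-ordering reading cannot produce the
near-zero posterior probabilities that staggered models show on
synchronous data.  In the models that oppose gallers to parasitoids the
pollinator counts as a galler (it galls fig flowers); in the small-wasp
models "small gallers" excludes the pollinator because
pollinator-specific models are evaluated separately.

Support is the Bayes factor
$BF = \frac{p/(1-p)}{q/(1-q)}$ of posterior against prior constraint
probability, reported on the $2\ln BF$ scale with the conventional
reading: 2–5 positive, 5–10 strong, above 10 very strong; a zero prior
with positive posterior is reported as infinite support, a zero
posterior as $-\infty$.

A practical property of rejection-sampling constraint tests governs the
choice of scenario in the validation harness: a constraint's posterior
probability can only be estimated if the scenario prior gives the
constraint non-negligible mass relative to the retained-sample
resolution.  The two-event prior essentially never proposes fully
staggered histories, and the six-event prior essentially never proposes
$\Psi = 1$, so the package's recovery harness runs under the
four-event scenario, the only one of the three whose prior visits both
the synchronous and the staggered regions.  This is a limitation of
desk-scale rejection ABC, not of the models.

## Divergence-time summary

`mean_divergence_time()` averages $\tau$ over pairs within each
retained draw and converts the posterior of that community mean to Ma
through the strict clock, $t = \tau / r$ with $r$ the *pairwise*
proportion divergence per Myr (0.019 by default) — pairwise, so no
division by two.

# Strict-clock dating

`bootstrap_split_time()` dates one sister pair from its COI alignments:
the point estimate is the mean between-group K2P converted by the
clock, in two modes — `raw_between`, and the default `net_between`
which subtracts the mean within-species K2P to remove the ancestral
polymorphism that otherwise inflates the split by about
$\theta_{anc}/r$.  Both modes are always reported.  Uncertainty comes
from a percentile bootstrap over alignment columns (95% interval,
replicates with fully saturated distances dropped and counted).

**Known limitation.** The site bootstrap resamples mutational noise
*conditional on the realized genealogy*.  The coalescent variance of
the realized divergence — when the ancestral lineages happened to
coalesce, and the within-species genealogies entering the net
correction — is not resampled, so the interval's coverage of the
*generating* split time falls short of its nominal level; the shortfall
grows with $\theta$.  The acceptance battery measures this directly and
the coverage check can fall just below its 90% bar at the generator's
default $\theta = 0.01$.  Integrating over genealogies is exactly what
full Bayesian dating buys; a desk-scale distance method cannot, and the
package reports the interval for what it is.

# The synthetic community generator

`simulate_community()` is first-class, tested code, not a fixture.  It
emulates the assumed structure of the real system:

* nine genera over the five guilds with the published species counts
  (14 species per region; six shared genera each contributing one
  intercontinental sister pair; two China-only and one Australia-only
  genus);
* COI of 394 columns; ITS2 simulated indel-free at 0.3× the COI rate —
  ITS2 serves only congruence and monophyly, so indel realism buys
  nothing for the validation surface;
* sister pairs generated by the same isolation coalescent as the hABC
  at $\tau = \tau_{Ma} \times 0.019$; non-sister congeners hang from a
  shared genus ancestor at half the configured congener divergence
  (default 0.24 pairwise, ≈12.6 Ma), so congeners are distinct but
  unsaturated while sisters remain mutually nearest;
* different genera draw independent ancestral sequences, so between-
  genus distances saturate — as they do in real data;
* a configured fraction of samples (default 10%, matching the scale of
  amplification failure in the real material) loses one randomly chosen
  marker;
* the truth record carries every sample's species, every pair's
  $\tau$ and $\theta$, and the seed; identical configs reproduce output
  files byte for byte.

Defaults are study conditions, chosen once: $\theta = 0.01$ gives
within-species K2P of the low percents with occasional excursions past
3% — the same behaviour the real tables show, where a few individuals
lack any conspecific within the threshold.  The delimitation-recovery
battery instead generates at $\theta = 0.002$ because its claim is
conditional on a ≥3× inter/intra separation, which that construction
guarantees (and the test verifies on the realized distances before
relying on it).

What the generator does **not** emulate: sequencing error,
recombination, selection, ITS2 indels, rate variation among sites, and
migration after the split.  Passing recovery tests therefore shows the
inference chain is correct and well-calibrated under the isolation
model — not that real communities obey that model.

# Guild vocabulary

The genus-to-guild map ships with the package (`fig_wasp_guilds`).  The
pollinator is carried as its own guild — it galls fig flowers like the
other small gallers, but the five-guild structure and the
pollinator-specific divergence models require it to be distinguishable
— which is also the only reading under which both communities display
all five guilds.

# Problem sizes

The shipped tests and the acceptance battery run at the sizes the
methods are designed for: six sister pairs of 4 + 4 sequences of
394 bp; hABC with 2×10⁴ simulations keeping 1%; 20 seeded replicates
per recovery claim; bootstrap intervals from 500 column resamples;
whole synthetic communities of ~112 samples.  A full
`run_pipeline("all")` on a synthetic community completes in well under
a minute except for the hABC stage, which is a few seconds per
scenario.

# Known limitations

* Monophyly is judged on NJ topologies without clade support values;
  individuals misplaced by homoplasy are flagged through the distance
  criteria instead.
* The conflict rule is a nearest-neighbour heuristic; it finds
  individuals moved between species, not deeper introgression.
* Constraint Bayes factors inherit the resolution of the retained
  sample (1/`n_kept`); probabilities below that resolution are
  reported as 0 and surface as the infinite/zero categories.
* The bootstrap dating interval under-covers the generating time, as
  analysed above.
* Prior probabilities of the published analysis depend on the exact
  internals of its tooling and are reproduced in ordering only, not in
  value; the Bayes-factor arithmetic itself is reproduced exactly.
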