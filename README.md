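# figcodiv

Community-level molecular analysis of the chalcid fig wasps that share
one host fig across two biogeographic regions (China and Australia).
The package answers three questions about such paired communities from
two-marker barcode data (mitochondrial COI standardised to a 394 bp
fragment, nuclear ITS2):

1. **Who is there?** Species delimitation by Kimura two-parameter (K2P)
   distance thresholds (the fixed 3% COI cutoff and the empirical 97.5th
   percentile of intraspecific distances), congruent monophyly across
   both markers, and a MOTU cutoff sweep whose count plateau locates the
   barcoding gap.
2. **Is the guild structure conserved?** Genus × region × guild
   composition tables, shared and region-exclusive genera, and
   intercontinental sister-pair identification (mutual nearest
   heterospecifics from different regions).
3. **Did the community diverge together?** A hierarchical approximate
   Bayesian computation (hABC) test over divergence histories: each
   sister pair follows a two-population isolation coalescent with
   divergence time τ (expected pairwise substitutions/site) and
   population mutation parameters θ; a Dirichlet-process prior groups
   pairs into shared divergence events Ψ; nine guild-constraint models
   (e.g. *all synchronised*, *gallers before parasitoids*) are scored by
   Bayes factors, BF = [p/(1−p)]/[q/(1−q)] of posterior against prior
   constraint probability, read on Raftery's 2·ln BF scale.  Splits are
   also dated under a strict clock of 1.9% pairwise divergence per Myr
   (t = d/r), with site-bootstrap intervals.

A coalescent community simulator with a full truth record
(`simulate_community()`) generates study-shaped synthetic communities —
nine genera, five guilds, 14 species per region, six intercontinental
sister pairs — so the whole chain is testable end to end without any
sequence download.  It is intended for researchers working on
host-associated insect communities and for anyone who wants a
transparent, scriptable re-implementation of the barcode-delimitation +
msBayes-style codivergence workflow at desk scale.

## Worked example

Simulate a study-shaped community whose six sister pairs all split
5.2 Ma ago, delimit it, find the intercontinental sisters, and test the
guild models:

```r
library(figcodiv)

sim <- simulate_community(community_config(seed = 7))
#> <synthetic_community> 28 species, 112 samples, 6 sister pairs (seed 7)

hyp <- delimit_species(sim$dataset)
sis <- cross_continent_sisters(sim$dataset, hyp)
sis[, c("genus", "species_cn", "species_aus", "inter_min", "inter_max")]
#>           genus        species_cn        species_aus inter_min inter_max
#> 1    Eupristina    Eupristina_CN1    Eupristina_AUS1    0.0775    0.1004
#> 2 Philotrypesis Philotrypesis_CN1 Philotrypesis_AUS1    0.1181    0.1423
#> 3 Philotrypesis Philotrypesis_CN4 Philotrypesis_AUS3    0.2264    0.2403
#> 4       Sycobia       Sycobia_CN1       Sycobia_AUS1    0.0946    0.1033
#> 5     Sycophila     Sycophila_CN1     Sycophila_AUS1    0.1211    0.1361
#> 6   Sycoscapter   Sycoscapter_CN1   Sycoscapter_AUS1    0.0917    0.0946
#> 7    Walkerella    Walkerella_CN1    Walkerella_AUS1    0.1032    0.1180
```

At the generator's realistic diversity (θ = 0.01) the delimitation
behaves like real data: a few coalescent-deep species split past the 3%
rule (31 delimited vs 28 true here), and one extra "sister pair" is a
mutually-nearest pair of distant congeners (the second *Philotrypesis*
row, at ~23% divergence).  The hABC is run on the observed COI of the
pairs and compared against the nine guild models:

```r
pairs <- data.frame(pair_id = sis$genus,
                    guild = unname(fig_wasp_guilds[sis$genus]),
                    n_a = sis$n_cn, n_b = sis$n_aus)
coi <- sim$dataset$alignments$COI
members <- function(sp)
  intersect(strsplit(hyp$members[hyp$species_id == sp], ",")[[1]],
            rownames(coi))
obs <- lapply(seq_len(nrow(sis)), function(i)
  list(a = coi[members(sis$species_cn[i]), , drop = FALSE],
       b = coi[members(sis$species_aus[i]), , drop = FALSE]))

post <- habc_reject(obs, pairs, scenario = 4, n_sims = 20000,
                    keep_fraction = 0.01, seed = 7)
head(evaluate_guild_models(post, seed = 7), 2)
#>                        model posterior_p prior_p    BF two_ln_BF category
#> 1           all_synchronised       0.165  0.0566 3.297     2.386 positive
#> 2 gallers_before_parasitoids       0.015  0.0255 0.582    -1.083     none

mean_divergence_time(post)$estimate_Ma
#> [1] 6.49   # generating truth: 5.2 Ma

bootstrap_split_time(obs[[1]]$a, obs[[1]]$b, clock_config(), 1000, seed = 7)
#> <split_estimate> 4.09 Ma (95% CI 2.73-5.61; net_between, 1000 bootstraps)
```

Synchrony wins (positive evidence, 2·ln BF ≈ 2.4) even with the noisy
seventh pair aboard, and the community divergence estimate brackets the
truth.  `bayes_factor()` is the same arithmetic applied anywhere:

```r
bayes_factor(0.814, 0.582)
#> BF = 3.143 (2lnBF = 2.29; positive)  posterior 0.814 vs prior 0.582
```

The whole chain also runs as a pipeline with a manifest and
hash-based stage skipping:

```r
run_pipeline("all", outdir = "run1", seed = 7)
```

or from a shell via the thin wrapper `inst/scripts/figcodiv.R`.
The published composition table ships as a plain-text fixture:
`benjamina_community_table()` and `compare_communities()` reproduce the
6 shared genera, 14 + 14 species, the region-exclusive genera and the
five-guild structure of both communities.

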