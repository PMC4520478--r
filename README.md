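# nicheclone

Are morphologically cryptic species "ecological clones"? `nicheclone` is an
R package for answering that question from distributional, trait and
molecular data, built around a four-species case study of spring-dwelling
*Niphargus* amphipods (two pairs of cryptic sister species, NKA/NKB and
NSA/NSB) on a small karst peninsula. It provides, as tested reusable
components:

* **distance-based species delimitation** — uncorrected p, Kimura
  two-parameter and patristic distances with pairwise deletion, clade
  means, and a monophyly + threshold rule
  (`delimit()`, default 0.16 substitutions/site);
* **niche reconstruction along three axes** —
  feeding-morphology indices from binary traits (`feeding_index()`,
  `feeding_similarity()`); epi-hypogean habitat preference with a
  stratified Cochran–Mantel–Haenszel permutation test controlled for
  geology (`build_3way()`, `cmh_permutation_p()`); and a bioclimatic
  envelope from a penalized maximum-entropy presence–background model
  (`fit_maxent_lite()`, `predict_map()`, `auc()`, `lpt_binary()`) compared
  between species with Schoener's *D* and a niche equivalency
  randomization test (`schoener_d()`, `equivalency_test()`);
* **a joint three-dimensional niche similarity**
  `joint_similarity(f, e, d)` $= \lVert(s_{feed}, s_{epi}, s_D)\rVert_2/\sqrt3$;
* **competition inference from co-occurrences** — sympatry zones from
  thresholded range maps, an independence null
  $(p_A(1-p_B),\,(1-p_A)p_B,\,p_Ap_B,\,(1-p_A)(1-p_B))$ for the four site
  occupancy categories, and a probability-ordering exact multinomial test
  (`run_competition_suite()`, `exact_multinomial_test()`), plus
  Clark–Evans nearest-neighbour pattern analysis (`clark_evans()`);
* **a synthetic-data generator** (`make_landscape()`,
  `simulate_occurrences()`, `apply_competitive_thinning()`,
  `assign_habitat_types()`, `simulate_divergence()`, `synth_community()`)
  that emulates the statistical structure of such field data, so the whole
  pipeline is testable without downloads;
* **an end-to-end pipeline** (`run_pipeline()`) that reads occurrences
  (CSV), environmental layers (ESRI ASCII grids), traits, trees (newick)
  and alignments (FASTA), and writes the full set of report tables with
  seeds and configuration echoed for reproducibility.

See the methods vignette
(`vignettes/niche-reconstruction-methods.Rmd`) for the models, their
assumptions, and the design choices.

## Worked example

The bundled case-study tables drive the trait axis end to end:

```r
library(nicheclone)

tr <- niphargus_traits()
sapply(rownames(tr), function(s) feeding_index(tr, s))
#> NKA NKB NSA NSB
#>   1   0   3   3

feeding_similarity(tr, "NKA", "NKB")   # 1 - |1 - 0|/3
#> [1] 0.6666667

axes <- niphargus_axes()
round(joint_similarity(axes$s_feed, axes$s_epi, axes$D_0.7), 2)
#> [1] 0.55 0.68 0.59 0.45 0.43 0.77
```

The indices range from 0 (predator) to 3 (filter-feeder): NKB is the
predator of the community, NSA/NSB are identical filter-feeders, and the
joint values combine each pair's feeding, habitat and climate similarities
into one number per pair (1 = ecological clones).

A complete synthetic study system exercises the distributional stages:

```r
world <- synth_community(seed = 1, gamma = 0.5)  # gamma injects exclusion
world$occ
#> <occurrence_table> 235 records, 4 species, 233 localities

pres <- grid_deduplicate(world$occ, world$grid)
pres
#> <presence_cells> NKA: 22, NKB: 38, NSA: 4, NSB: 65

fit <- fit_maxent_lite(pres[["NSB"]], world$stack, c("env1", "env2"))
round(auc(fit, world$stack, pres[["NSB"]]), 3)
#> [1] 0.621

res <- cmh_permutation_p(build_3way(world$occ), n_perm = 999, seed = 1)
c(M2 = round(res$statistic, 1), df = res$df, p = res$p_value)
#>    M2    df     p
#> 30.4     6 0.001

nsb <- world$occ[world$occ$species == "NSB", ]
clark_evans(cbind(nsb$x, nsb$y), area = 3600)
#> <nn_result> n = 126, ratio = 0.417 (obs 1.115 / exp 2.673), z = -12.516, p = 6.131e-36
```

Here the permutation CMH finds the species x habitat association (one
synthetic species is subterranean-leaning), and the nearest-neighbour ratio
far below 1 classifies the clustered occurrences as clumped. The full
pipeline on generated inputs:

```r
cfg <- demo_config(seed = 1)        # writes a synthetic world to tempdir
reports <- run_pipeline(cfg)        # 8 CSV report tables + log + config echo
names(reports)
#> [1] "presence_counts" "pruned_variables" "sdm_auc" "niche_overlap"
#> [5] "habitat_cmh" "niche_axes" "clark_evans" "competition"
```

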