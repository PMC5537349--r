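# pollcoex

Coextinction cascades in plant-pollinator networks, with a hybrid model:
**stochastic** plant extinctions driven by measured dependence on
pollination, **topological** pollinator extinctions driven by resource
loss.

Purely topological coextinction models assume a species dies only when all
of its partners are gone — which ignores that plants differ enormously in
how much they actually need pollinators, and that interactions differ in
strength. `pollcoex` is for community ecologists who want to simulate
pollinator loss in quantitative visitation networks while accounting for
both: after the removal of pollinator *j*, each extant plant partner *i*
survives with probability

> P<sub>ij</sub> = 1 − IPD<sub>i</sub> · d<sub>ij</sub>

where IPD<sub>i</sub> ∈ [0, 1] is plant *i*'s intrinsic dependence on
insect pollination (estimated from open-pollination vs pollinator-exclusion
seed set as IPD = 1 − SS<sub>pe</sub>/SS<sub>op</sub>) and d<sub>ij</sub>
is the share of *i*'s visitation delivered by *j* among surviving partners
(recomputed after every event; d<sub>ij</sub> = 1 for a last partner).
Pollinators go extinct only when their last plant partner is lost, and
interactions are never rewired. Removal sequences run until no pollinators
remain, under random, generalist-first or specialist-first scenarios, with
variants that force full dependence (D), homogeneous weights (H), or both
(DH), plus a pure topological baseline (TCM) for comparison.

The package provides:

* network I/O and validation (edge-list and adjacency CSV), structural
  metrics (degree, interaction evenness, eigenvector centrality, species
  strength);
* IPD estimation from seed-set experiments;
* the cascade simulator (`run_simulation()`, 10,000-replicate protocol),
  the topological baseline (`run_tcm()`), per-plant survival surfaces and
  robustness (area under the survival curve, `plant_robustness()`);
* keystone-pollinator identification by selective single removals
  (`keystone_scan()`), functional-group summaries and Spearman
  trait-survival correlations;
* exact enumeration oracles for small networks
  (`exhaustive_expected_survival()`) and the closed-form event-1 identity
  P<sub>i</sub> = 1 − IPD<sub>i</sub>/N<sub>P</sub>;
* a synthetic community generator with presets at the two studied
  community scales (`synth_preset("SB")`, `synth_preset("PM")`);
* an end-to-end pipeline (`run_full_study()`) driven by a config list or
  YAML file, writing tidy CSVs and a checksummed JSON manifest.

## Worked example

```r
library(pollcoex)

comm <- synth_preset("SB", seed = 1)   # 27 plants, 60 pollinators, IPD ~ 0.59 ± 0.38
scm <- run_simulation(comm$network, comm$dep, scenario = "random",
                      variant = "F", replicates = 2000, seed = 1)
scm
#> Survival surface: SCM (variant F), random scenario, 2000 replicates
#>   27 plants x 60 extinction events
#>   surviving plant fraction after all events: 0.293

tcm <- run_tcm(comm$network, scenario = "random", replicates = 2000, seed = 1)
mean(surface_robustness(scm)$R)   # 0.685
mean(surface_robustness(tcm)$R)   # 0.930
```

29.3% of plants persist even after every pollinator is gone — these are the
low-IPD species reproducing by selfing or wind, which a topological model
cannot represent; accordingly the stochastic mean robustness (0.685) sits
well below the topological baseline (0.930). Keystone pollinators are the
species whose selective loss coextinguishes the most plants:

```r
ks <- keystone_scan(comm$network, comm$dep, replicates = 2000, seed = 1)
head(ks[order(-ks$mean_coextinctions),
        c("pollinator", "guild", "mean_coextinctions", "strength")], 3)
#>    pollinator       guild mean_coextinctions strength
#> 21     pol_21        ants              1.013    1.416
#> 9      pol_09 butterflies              0.881    0.945
#> 34     pol_34    honeybee              0.779    1.441
```

High species strength — summed plant dependence — marks the keystones, not
raw visit totals.

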