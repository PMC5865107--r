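# pollinet

Pollen-transport networks and pollen-load comparison from DNA
metabarcoding data.

When individual flower-visiting insects (the motivating case is a
community of hoverflies at species-rich grassland sites) are washed for
pollen and the rbcL plant barcode in each wash is sequenced, every insect
yields a list of sequencing reads and, after alignment against a plant
reference library, a table of hits. pollinet turns those inputs into
ecology:

* **Consensus taxonomic assignment.** Reads over 450 bp are classified
  from their top-20 distinct bit-score hits: a unanimous species wins;
  otherwise a genus holding ≥ 60% of the retained hits wins; otherwise the
  read is `various`, resolvable to family or tribe by an auditable
  curation tier, else `unknown`.
* **Per-site bipartite networks.** Cell *a<sub>ij</sub>* counts the
  individuals of pollinator species *i* carrying plant taxon *j*. From the
  two-dimensional Shannon entropy H₂ = −Σ p<sub>ij</sub> ln p<sub>ij</sub>
  the network specialisation index is standardised between its
  marginal-constrained extremes, H₂′ = (H₂max − H₂)/(H₂max − H₂min), and
  the species-level index d′ standardises the Kullback–Leibler divergence
  of a species' partner use from partner availability between an
  integer-feasible minimum and ln(m/A<sub>i</sub>). Both run 0
  (generalised) to 1 (specialised); minima are found by exhaustive
  enumeration on small matrices and a stated concentration heuristic
  otherwise.
* **Pollen-load comparison.** Binary Jaccard distances
  (1 − |∩|/|∪|) between insect presence/absence profiles, a permutational
  MANOVA (pseudo-F, R², add-one permutation p) whose permutations respect
  site strata, one-vs-rest genus contrasts plus within-genus species
  contrasts under the Dunn–Šidák cutoff 1 − (1 − α)^(1/k), and a
  tie-corrected Kruskal–Wallis test over d′ values.
* **A synthetic study generator.** Dirichlet–multinomial pollen loads over
  simulated site communities and a hierarchically structured barcode
  library, with ground truth retained, so every stage above is testable
  and calibratable without any sequence archive.

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe; fitted objects carry `tidy()`/`glance()`
methods and the main result types have `autoplot()`s.

## Worked example

Simulate a small two-site study, classify its reads, and compute the
networks and the comparison battery:

```r
library(pollinet)

cfg <- sim_config(seed = 11, n_sites = 2, n_families = 3,
                  genera_per_family = 3, species_per_genus = 2,
                  n_pollinator_species = 6, n_pollinator_genera = 3,
                  individuals_per_species_site = 3,
                  reads_per_individual = 60, ref_length = 400)
sim <- simulate_pollen_study(cfg)

kept <- length_filter(sim$reads, min_length = 350)
asg  <- consensus_assign(select_top_hits(sim$hits, assignment_rule()),
                         sim$refdb$taxonomy, assignment_rule(),
                         query_ids = kept$read_id)
counts <- tally_pollen(asg, sim$insects)

net <- build_network(to_presence_absence(counts), sim$insects, "S01")
network_h2prime(net)
#> <network_specialization> site S01: H2 = 4.3053  [min 2.8192, max 4.5690]  H2' = 0.1507

head(species_dprime(net), 3)
#> # A tibble: 3 × 7
#>   site  species             d   dmin  dmax dprime dmin_method
#> 1 S01   HovergenusA sp1 0.280 0.0432  1.76  0.138 largest_remainder
#> 2 S01   HovergenusA sp2 0.225 0.0205  1.65  0.125 largest_remainder
#> 3 S01   HovergenusB sp1 0.449 0.0667  2.07  0.190 largest_remainder

d <- jaccard_distances(jaccard_input_filter(counts))
run_contrast_battery(d, sim$insects, n_perm = 999, seed = 1)
#> # A tibble: 6 × 8
#>   contrast                n df_between df_resid     F    R2     p significant
#> 1 HovergenusA_vs_rest    36          1       34  4.27 0.112 0.001 TRUE
#> 2 HovergenusB_vs_rest    36          1       34  4.22 0.110 0.001 TRUE
#> 3 HovergenusC_vs_rest    36          1       34  3.95 0.104 0.001 TRUE
#> 4 HovergenusA_species    12          1       10  1.27 0.113 0.309 FALSE
#> 5 HovergenusB_species    12          1       10  1.58 0.136 0.057 FALSE
#> 6 HovergenusC_species    12          1       10  1.52 0.132 0.099 FALSE
```

Read it as: the site-S01 network is generalised (H₂′ = 0.15, closer to 0
than 1), individual species show little exclusivity (d′ ≈ 0.12–0.19), yet
the three simulated pollinator genera carry compositionally distinct
pollen loads (each one-vs-rest contrast significant under the Šidák
cutoff for the 6-contrast family, here 0.0085), while congeneric species
do not separate — the generator's genus-level preference structure,
recovered by the statistics.

A YAML-configured end-to-end run (simulate → assign → profiles →
networks → stats, with a reproducibility manifest) is available as
`run_pipeline("run.yaml")`, or from a shell via the thin wrapper
`inst/scripts/pollinet.R`.

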