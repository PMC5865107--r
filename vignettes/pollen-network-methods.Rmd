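---
title: "Methods: pollen metabarcoding networks and pollen-load comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollen metabarcoding networks and pollen-load comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollinet)
```

pollinet analyses the pollen carried by individual flower-visiting insects,
characterised by high-throughput sequencing of the rbcL plant barcode. Its
motivating use case is a community of hoverflies (Syrphidae) sampled at a
few species-rich grassland sites: each insect is washed, the pollen DNA is
amplified and sequenced, each merged read is matched against a reference
barcode library, and the resulting per-insect pollen profiles feed two
complementary analyses — bipartite pollen-transport networks with the
specialisation indices H2' and d', and a presence/absence comparison of
pollen-load composition between pollinator genera and species.

This vignette is the package's own account of the models and the numerical
choices behind each stage. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## Consensus taxonomic assignment

The classifier consumes a 12-column tabular alignment file (the classic
`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
evalue bitscore` layout) rather than running an aligner itself. Reads of
450 bp or less are discarded first; the filter is strictly
greater-than, so a 451 bp read survives and a 450 bp read does not.

For each read, `select_top_hits()` keeps every hit whose bit score is among
the `top_k = 20` highest *distinct* score values, with ties retained at
every level. We read the top-k rule over distinct values rather than file
rows because file-row truncation makes the result depend on the otherwise
meaningless row order of the hit table; the distinct-value reading is
deterministic and order-free, which the suite verifies by shuffling.

`consensus_assign()` then applies, in order:

1. **Species unanimity** — all retained hits map to one species.
2. **Genus majority** — one genus accounts for at least
   `genus_fraction = 0.60` of the retained hits (hit-count weighted; a
   bit-score-weighted variant sits behind `score_weighted = TRUE`, off by
   default because count weighting is the plainer reading). The boundary is
   inclusive: 12 of 20 hits suffice. At thresholds above 0.5 at most one
   genus can qualify; for configured thresholds at or below 0.5, ties fall
   through.
3. **`various`** otherwise; reads with no hits at all are `unknown`.

A curation tier (`apply_curation()`) emulates the expert-verification pass
of metabarcoding pipelines: ordered rules map `various` reads — matched by
an explicit read id or by the read's *family signature*, the sorted set of
families among its retained hits — to family or tribe level. `various`
reads no rule claims become `unknown`. Only `various` entries are ever
touched, and every remap lands in an audit log. No minimum identity or
e-value cutoff is applied before the top-k rule; none is part of the
default protocol the classifier mirrors, and one can always be imposed by
prefiltering the hit table.

## Profiles and filters

`tally_pollen()` turns assignments into per-insect read counts (row sums
equal the number of length-passing reads, with `unknown` in a dedicated
column, so nothing is silently lost). Downstream, two views exist:

* `to_percent()` — row-normalised percentages over identified reads,
  controlling for amplification-depth differences between insects;
* `to_presence_absence()` — qualitative profiles used for all networks and
  distance-based tests, avoiding abundance biases from pollen retrieval,
  extraction and PCR. The detection threshold `presence_min_reads`
  defaults to 1 (no threshold beyond detection) but is configurable
  because metabarcoding practice often imposes proportion cutoffs.

`jaccard_input_filter()` prepares the comparison input: it removes
`unknown`, then removes taxa resolved *above* genus (family, tribe,
uncurated `various`) whose study-wide share of identified reads is
strictly below 1%. The denominator is the grand total across all insects
in the analysis set — the natural reading of a study-wide filter — and
species- or genus-rank columns are never dropped however rare, since the
filter exists only to stop poorly resolved rare categories from dominating
a presence/absence distance.

`entomophilous_coverage()` compares a site's insect-pollinated flora
(site species list minus Poaceae, Cyperaceae, Juncaceae) with the pollen
taxa detected there. A species-rank pollen taxon detects its species; a
taxon above species rank is conservatively assumed to represent a single
plant species, so it contributes at most one detected species however many
candidates the site list offers — and zero when the site has no candidate,
because pollen cannot "detect" an absent plant. Coverage is computed per
site from that site's detected taxa.

## Bipartite specialisation: H2' and d'

Networks are built per site from individual presence/absence profiles:
cell \(a_{ij}\) counts the *individuals* of pollinator species \(i\)
carrying plant taxon \(j\). The aggregation deserves emphasis because
published matrices rarely state it: summing individual presences keeps the
matrix integer-valued (which the entropy bounds require) and weights a
species' interactions by how consistently its individuals carry a taxon.

With \(m = \sum a_{ij}\), \(p_{ij} = a_{ij}/m\), row totals \(A_i\) and
column totals \(B_j\):

* the network-level two-dimensional entropy is
  \(H_2 = -\sum_{a_{ij}>0} p_{ij}\ln p_{ij}\), standardised as
  \(H_2' = (H_{2,max} - H_2) / (H_{2,max} - H_{2,min})\), 0 for perfect
  generalisation, 1 for perfect specialisation;
* the species-level index is the Kullback–Leibler divergence
  \(d_i = \sum_j (a_{ij}/A_i)\,\ln\!\big[(a_{ij}/A_i)\,/\,q_j\big]\) of the
  row's partner use from availability \(q_j = B_j/m\), standardised between
  an integer-feasible minimum and \(d_{max} = \ln(m/A_i)\). Availability
  includes the focal row (no self-exclusion), the standard formulation.
  Natural logarithms throughout.

The bounds are where implementations genuinely differ:

* \(H_{2,max}\) uses the (generally non-integer) independence table
  \(A_iB_j/m\).
* \(H_{2,min}\) is found by exhaustive enumeration of all integer tables
  with the observed marginals whenever \(m \le 12\) and both dimensions are
  at most 4; beyond that, a greedy concentration heuristic (repeatedly
  allocate \(\min\) of the largest remaining row and column totals, ties by
  label order) supplies an upper bound. The greedy table is always
  feasible, so the heuristic can only overestimate the minimum — never
  undercut it — and enumeration shows it is *not* exactly optimal on a few
  percent of small margin configurations, which is exactly why the exact
  branch exists where it is affordable.
* \(d_{min}\) similarly: exact enumeration of the compositions of \(A_i\)
  when \(A_i \le 10\) over at most 5 columns, largest-remainder allocation
  proportional to \(q\) otherwise (again a feasible upper bound, again not
  always optimal).

Because the maximum is continuous while the minimum is integer, the
standardised ratio can overshoot \([0,1]\) by a sliver; it is clipped with
a warning. Degenerate shapes are flagged rather than scored: a single row
or column makes \(H_2'\) undefined, and a single column forces
\(d_{max} = d_{min}\), reported as \(d' = 0\) with a warning.

```{r anchors}
glance(network_h2prime(matrix(c(5L, 0L, 0L, 5L), 2, 2)))
species_dprime(matrix(c(5L, 0L, 0L, 5L), 2, 2,
                      dimnames = list(c("s1", "s2"), c("t1", "t2"))))
```

## The comparison suite

`jaccard_distances()` computes the classic binary Jaccard distance
\(1 - |x \cap y|/|x \cup y|\), a metric. We implement the set formula
directly rather than routing through a binary Bray–Curtis transform;
the two agree here, but the pseudo-F statistic is not invariant to
monotone rescalings of a dissimilarity, so the distance definition is
stated exactly and cross-checked against an independent implementation in
the tests.

`permanova()` is a one-factor permutational MANOVA on the squared
distances via the Gower identity: \(SS_{total} = \sum_{i<j} d_{ij}^2/n\),
\(SS_{within} = \sum_g \sum_{i<j \in g} d_{ij}^2/n_g\),
\(F = (SS_{between}/(k-1))/(SS_{within}/(n-k))\). Group labels are
permuted only *within* strata (collection sites), the exchangeability
restriction appropriate for spatially clustered insects — functionally
similar to a random site effect. p-values use the add-one estimator
\((1 + \#\{F^* \ge F\})/(1 + n_{perm})\) with `n_perm = 9999` by default,
so they are never exactly zero and have resolution \(1/(n_{perm}+1)\). A
degenerate fit with \(SS_{within} = 0\) reports \(F = \infty\); permuted
relabellings that also attain \(SS_{within} = 0\) count as ties, which
keeps the p-value honest instead of pinning it to the resolution floor.
Degrees of freedom are reported as \(k-1\) and \(n-k\).

`run_contrast_battery()` runs the study design built by
`study_contrasts()`: one one-vs-rest contrast per pollinator genus plus a
within-genus species contrast for each multi-species genus, every contrast
judged against the Dunn–Šidák cutoff \(1-(1-\alpha)^{1/k}\) for the family
of \(k\) contrasts (five genera of which two are multi-species give
\(k = 7\) and cutoff 0.0073008 at \(\alpha = 0.05\)). Whether omnibus
tests belong in the corrected family is a design decision; they are
excluded by default and the family size follows the supplied contrast
list. `kruskal_wallis()` supplies the tie-corrected rank test used to
compare d' values across species, matching `stats::kruskal.test` exactly
(the latter serves as a cross-check oracle in the tests, never as the
implementation).

## The synthetic study generator

No public, desk-scale dataset exists that exercises every stage —
reference library, hit tables, metadata, site lists and ground-truth
loads — so the package ships a generator whose defaults mirror the
sampling design it targets: 3 sites, 11 pollinator species in 5 genera,
4 individuals per species per site (132 insects, the scale of the ~143
in the motivating design), and 5 plant families × 4 genera × 3 species =
60 barcode taxa with roughly 80% of the species pool shared across sites.

* **References.** Family roots are independent random sequences; genus
  ancestors mutate at half the between-genus rate (default 8%), species at
  half the within-genus rate (default 2%), so pairwise Hamming fractions
  approximate the configured divergences. One of the five families is
  flagged wind-pollinated and named Poaceae so the entomophilous filter
  engages on synthetic data.
* **Preferences and loads.** Each pollinator genus draws a log-weight
  vector over plant species scaled by `genus_effect_size`; each species
  adds a perturbation scaled by `species_effect_sd` (0.3). Exponentiated
  weights restricted to the site community give the centroid;
  wind-pollinated taxa receive a constant 1% background share, mimicking
  incidental transport of wind-borne pollen. Individual loads are
  Dirichlet draws with total concentration `preference_concentration`
  around the centroid — there is no quantitative foraging model to borrow
  for hoverflies, so the Dirichlet–multinomial is this module's own,
  clearly stated modelling assumption. Lower concentration means
  individuals commit to fewer taxa, the dial the parameter-recovery checks
  turn. Reads are multinomial over the load with independent per-base
  substitution errors (default 0.5%).
* **Hit tables.** Reads are scored against every reference by ungapped
  identity; the pseudo-bit-score is `max(0, 2 * (matches - mismatches))` —
  a stated linear ranking score, deliberately not a Karlin–Altschul
  bit score, because the classifier consumes only the ranking and a linear
  score is exactly checkable. The emitted list holds the `top_n`
  best-scoring references with ties. `top_n` defaults to 1 (the
  maximal-scoring set): the synthetic library holds a single accession per
  species, and on such a library a deep hit list dilutes the consensus
  below the genus threshold purely as an artefact of library composition —
  real barcode libraries owe the informativeness of their deep hit lists
  to many (often rbcL-identical) accessions per species, which the
  generator deliberately does not model. The classifier keeps its own
  depth-20 rule and is simply idempotent on shallow tables.
* **Randomness.** One top-level seed fans out through labelled
  sub-streams (a stable string hash), so adding one stage never shifts
  another stage's draws, and per-insect streams make loads invariant to
  roster changes.

What the generator does *not* emulate — chimeras, primer artefacts, length
polymorphism, PCR abundance bias, multi-accession reference libraries —
bounds what passing tests show about real data: they validate the
statistical machinery and its calibration, not robustness to artefact-laden
libraries or sequencing chemistry.

## Problem sizes and numerical checks

The simulation-based checks run a reduced frame (2 sites × 6 pollinator
species × 2 individuals × 30 reads over 12 plant taxa, 250 bp references)
so that 20 replicates per condition remain comfortable on a laptop; the
full default frame is exercised once end-to-end in the pipeline tests.
Under that frame the suite verifies, among others:

* exact agreement of the entropy/divergence minima with brute-force
  enumeration over every 3×3 margin configuration with \(m \le 12\) and
  every row total up to 8 over up to 4 columns;
* mean network H2' strictly increasing as the Dirichlet concentration
  drops through 100, 1, 0.1 (20 replicates each);
* uniform PERMANOVA p-values under a simulated null (500 replicates × 199
  permutations, KS test) and rejection rates increasing with the genus
  effect size;
* at least 99% species-level recovery on error-free reads against the
  generator's ground truth, with exact behaviour at the 450/451 bp and
  60%/55% decision boundaries.

Floating-point tolerances are 1e-9 for the combinatorial bounds (pure
arithmetic on small integers) and 1e-12 for algebraic identities;
permutation-based comparisons use tolerances derived from their binomial
resolution.

## Known limitations

* H2'/d' values published for any particular field study are not
  reproducible without that study's raw reads and reference library; the
  package's guarantees about the indices are therefore structural
  (anchors, bounds, invariances, parameter recovery) rather than
  value-for-value.
* The exact minimum-entropy branch is exponential and capped at small
  sizes; larger networks use the heuristic bound, which can make H2'
  slightly conservative.
* The curation tier models expert knowledge as deterministic rules; it
  cannot capture judgment that depends on context outside the hit table.
* Jaccard presence/absence discards abundance entirely; the percentage
  view exists for description, not testing.
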