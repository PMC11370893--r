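---
title: "Compiling and characterizing disease-associated gut signature species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling and characterizing disease-associated gut signature species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutsig)
library(dplyr)
```

## The problem

Meta-analyses of case–control gut metagenome cohorts repeatedly identify
*signature species*: taxa whose relative abundance is consistently higher
(enriched) or lower (depleted) in a disease than in healthy controls.
Individually these lists are noisy; compiled across many meta-studies and
diseases, they support questions the single studies cannot answer. Are
disease-enriched species disproportionately residents of body sites other
than the gut — the oral cavity in particular, suggesting translocation along
the oral–gut axis? Are they more often reported from bloodstream infections
(bacteremia)? Are they more often aerotolerant, as expected if disease
disrupts gut redox homeostasis? And how reproducible are the signatures
between meta-studies of the same disease?

`gutsig` implements that analysis as a tested pipeline with five stages:

1. **Compilation** (`consolidate()`): per-study records of
   (study, disease, species, direction) collapse to one consensus row per
   species with a direction class — *enriched*, *depleted*, or
   *inconsistent* (enriched in at least one disease and depleted in at least
   one other) — and a disease count.
2. **Body-site classification** (`compute_site_profiles()`,
   `assign_body_site()`, `resolve_with_secondary_evidence()`): each species
   is assigned its typical body site from detection frequency and mean
   relative abundance across gut, oral cavity, vagina, and skin samples.
3. **Annotation** (`merge_annotations()`): consensus, site assignment, and
   curated bacteremia/aerotolerance tables join into one master table;
   `table1_summary()` tabulates property proportions by direction and
   disease count.
4. **Inference** (`fisher_exact_2x2()`, `run_comparison_battery()`): a
   pre-registered battery of stratified 2×2 comparisons, each reported with
   the exact two-sided Fisher p-value and the conditional-MLE odds ratio.
5. **Simulation** (`simulate_abundance_matrix()`,
   `simulate_annotated_species()`, `simulate_signature_studies()`):
   generators with planted ground truth make every stage testable without
   external downloads.

## Direction classes and disease counting

A disease counts once per species and direction, however many studies
report it. The three direction classes partition the species set exactly —
this invariant is enforced in the test suite on every fixture.

One meta-study pools **multiple diseases** under a single label (`"MD"`).
It is treated as one disease on input, but a species it reports is by
construction associated with at least two diseases. We therefore assign
`n_diseases = max(k, 2)`, where `k` is the species' count of named
diseases. This is a deliberate lower bound: the pooled study's internal
disease list is unknown and may overlap the named diseases, so any larger
value would be a guess. Ulcerative colitis and Crohn's disease count as
distinct diseases throughout.

*Shared* signatures (`shared_signatures()`) are species enriched (or
depleted) in at least `ceiling(threshold_fraction * n_total_diseases)`
diseases. The denominator is genuinely ambiguous — the six named diseases,
or seven including the pooled label — so it is a parameter; the default is
6 (CRC, UC, CD, IBS, PC, COVID-19) with `threshold_fraction = 0.5`, i.e. at
least 3 diseases. Inconsistent species never qualify.

Percentages everywhere are rounded **half away from zero** at one decimal;
banker's rounding (R's default) disagrees with conventional reporting on
exact halves.

## The body-site rule

For each species and site, `compute_site_profiles()` computes the detection
frequency `f` (share of the site's samples with abundance above the
detection threshold, default 0 — any nonzero abundance is a detection) and
the average relative abundance `a` (mean over **all** the site's samples,
zeros included). The site that maximizes both `f` and `a` is the species'
typical site. A species falls back to *indeterminate* under any of four
conditions, checked in a fixed precedence order so that every call is
reproducible and the triggering condition is always logged:

1. `not-detected`: zero frequency everywhere;
2. `low-frequency`: maximal frequency across the four sites below 5%
   (`min_frequency = 0.05`), read as "max over sites", the stricter of the
   two possible readings;
3. `discordant`: frequency and abundance argmaxes disagree (ties included);
4. `ambiguous-gut-oral`: the winner is gut or oral but the gut/oral ratio
   lies in \[0.1, 10\] (inclusive), so neither habitat clearly dominates.

The gut/oral ratio is computed on **mean relative abundance**, not
frequency: abundance quantifies residency strength, while frequency
saturates for common taxa; with the default detection threshold of zero a
frequency ratio would also be far more sensitive to rare spillover reads.
The ratio only gates gut or oral winners — a vaginal or skin winner is
unaffected by it. A ratio of 0 or infinity (one habitat undetected, the
other dominant) never triggers the fallback.

Indeterminate species can be resolved by
`resolve_with_secondary_evidence()`, which consumes a *curated* evidence
table (database membership, reference-cohort profiles, isolation sources)
and takes a weighted vote: unique top site wins, ties yield `multi`
(associated with multiple body sites). The underlying database and
literature searches are manual curation and outside the package's scope, as
is any live querying of those resources. Multi-site species are excluded
from site-stratified statistics (see below). Habitat classes derive from
the assigned site: gut is *intestinal*; oral, vaginal, skin, food-origin,
and other sites are *extra-intestinal*.

## Exact 2×2 inference

The statistical engine is the Fisher exact test with the conditional
maximum-likelihood odds ratio. Conditional on both margins, the first cell
of a 2×2 table follows a noncentral hypergeometric distribution with
noncentrality equal to the odds ratio $\psi$; the CMLE solves
$E_\psi[A] = a$. We find the root on the $\log\psi$ scale with `uniroot()`
at tolerance `1e-10` (the conditional mean is strictly increasing in
$\log\psi$), computing the noncentral weights in log space for stability.
The two-sided p-value follows the probability-mass rule: it sums the
central hypergeometric probabilities of all tables with the observed
margins that are no more probable than the observed one, with a relative
tolerance of `1e-7` when comparing probabilities, which protects ties
against floating-point noise. Boundary tables (the observed cell at an end
of its conditional support) report an odds ratio of 0 or $\infty$ with a
`boundary` flag rather than a continuity-corrected estimate; a table whose
margins pin it completely has no identifiable odds ratio and reports `NA`
with p = 1.

The CMLE rather than the sample cross-product ratio $ad/bc$ is the
reported estimate: it is finite-sample conditional-likelihood-consistent,
defined under the same conditioning as the exact p-value, and matches the
convention of the standard exact-test implementations. The test suite
checks the p-value against an independent brute-force enumeration oracle
(`fisher_p_enumeration()`, explicit log-factorial arithmetic) exhaustively
over all 2×2 tables with every margin ≤ 40, and the CMLE against two
independent reference implementations.

`run_comparison_battery()` applies a pre-registered list of comparisons
(`default_comparison_battery()`, 33 specs). Exclusion rules are attached to
the **factors**, not the battery: species with unknown aerotolerance drop
only from aerotolerance comparisons, multi-site or indeterminate-site
species only from habitat/oral comparisons, inconsistent species only from
direction comparisons. Every exclusion is logged per comparison with the
species and reason. Whether inconsistent species should also vanish from
non-direction comparisons is ambiguous in this style of analysis; since
every default spec involves the direction factor either as a margin or as a
stratum filter, both readings coincide here. A comparison whose filtered
table loses a row or column margin is flagged `degenerate` and reports no
estimate — a p-value of 1 would be an artifact of the empty stratum, not a
finding. No multiplicity correction is applied: the battery reports raw
exact p-values, matching the descriptive, pre-registered character of the
comparisons.

## The synthetic-data generators

Three generators provide ground-truth inputs.

**Abundance matrices** (`simulate_abundance_matrix()`): each species is
present in a sample with its site-specific prevalence, and when present its
pre-normalization abundance is log-normal; compositions are then closed to
sum to 1. The model is deliberately minimal — the classifier consumes only
detection frequency and mean relative abundance, so any heavy-tailed
presence/absence model with controllable prevalence exercises it fully. A
background filler taxon (`"unclassified"`) absorbs the unit mass of samples
in which no focal species occurs, so closure never divides by zero; when
every sample is occupied, no filler appears and a single always-present
species yields the exact composition (1.0). `niche_sim_params()` plants a
strongly separated niche structure — prevalence 0.9 in the home site versus
0.01 elsewhere and a three-orders-of-magnitude abundance gap — representing
the clearly resolved end of real niche separation; with 200 samples per
site, the classifier must recover at least 99% of planted homes via the
primary rule. What the generator does **not** emulate: taxon–taxon
correlation, sequencing depth and compositional bias, within-subject
longitudinal dynamics, or the long tail of rare taxa in real metagenomes —
so a passing classifier test demonstrates correctness of the rule, not
robustness to every real-data pathology.

**Annotation tables** (`simulate_annotated_species()`): direction is
Bernoulli(`p_enriched`); the property probability is `baseline_p` in the
depleted class and, in the enriched class, the probability whose odds are
`target_or` times the baseline odds (closed-form inversion). Defaults
(`p_enriched = 0.62`, `baseline_p = 0.163`, `target_or = 9.2`) mirror the
magnitudes of published cross-disease compilations. Against this generator
the test suite verifies CMLE parameter recovery (planted odds ratio 4
recovered within exact confidence bounds in ≥ 95% of 100 replicates at
n = 500, and within \[3.6, 4.4\] at n = 50,000) and type-I calibration at
the null (rejection rate in \[0.025, 0.075\] over 1,000 replicates at
n = 300 — the exact test is conservative, so rates sit below the nominal
5%).

**Signature studies** (`simulate_signature_studies()`): a planted overlap
design (how many species appear in exactly k of K studies) is reproduced
exactly; which particular study subset reports a species is randomized
under the seed. The bundled CRC-style design (36, 12, 3, 4 species in 1–4
studies) reproduces the published reproducibility histogram
(65.5 / 21.8 / 5.5 / 7.3%).

All generators are pure functions of their parameters and an explicit
`seed`; the caller's RNG state is untouched.

## The bundled example data

`example_signature_data()` returns a deterministic synthetic dataset of 273
species whose marginal counts match a published cross-disease compilation:
163 enriched (111 / 52 by disease count), 98 depleted (64 / 34), 12
inconsistent, with bacteremia, aerotolerance, oral, and extra-intestinal
counts planted per stratum, 8 + 9 shared signatures, and 5 species of
unknown aerotolerance. Only those marginals are meaningful; the joint
structure within strata is arbitrary. Multi-disease species are planted
through all three mechanisms (three-disease records, the pooled label,
two-disease records) so the compiler's counting rules are all exercised.

```{r example}
dat <- example_signature_data()
consensus <- consolidate(dat$records)
annotations <- merge_annotations(consensus, dat$assignments,
                                 dat$bacteremia, dat$aerotolerance)
table1_summary(annotations) |>
  filter(disease_group == "total", category != "total") |>
  select(direction_class, category, label)
```

```{r battery}
run_comparison_battery(annotations) |>
  filter(comparison_id == "direction_x_bacteremia") |>
  select(a, b, c, d, odds_ratio, p_value)
```

## Numerical and design choices

* **Rounding**: half away from zero at one decimal for all percentages.
* **Detection threshold**: 0 by default — presence in a shotgun profile is
  already a detection call; a stricter threshold is a parameter, not a
  hidden constant.
* **Unit auto-detection**: abundance files may be proportions or
  percentages; a file whose sample sums exceed 1.5 is treated as
  percentages, and the decision is reported. Validation rejects negative
  values, non-numeric cells, and sample sums above 1 + 1e-9 with
  positional diagnostics.
* **Missing curation defaults**: bacteremia `"no"` (the flag means
  *literature-reported* bloodstream detection, so absence of a report is
  the negative state, with the caveat that reported isolation does not
  imply causative infection); aerotolerance `"unknown"` (including the
  "unclassified anaerobe" curation category); site `"indeterminate"`.
* **Problem sizes**: the test suite runs the exhaustive oracle sweep at
  margins ≤ 40 (617,910 tables), 1,000 null replicates at n = 300, 100
  recovery replicates at n = 500, and 100 classifier replicates at 12
  species × 800 samples — sizes chosen so the full suite completes in
  about two minutes while keeping Monte-Carlo error well inside the
  asserted bands.

## Limitations

The package compiles and characterizes published signature lists; it does
not re-run the underlying meta-analyses (differential abundance, random
effects models), does not search literature databases, and does not query
HMP, eHOMD, ExperimentHub, or American Gut at run time — real multi-site
profiles and curated annotations enter as tables. The iTOL export writes an
annotation dataset for an existing phylogeny; tree construction and
rendering are out of scope. Conclusions drawn from the battery are
associations between species properties and direction classes, not causal
claims about translocation or infection.
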