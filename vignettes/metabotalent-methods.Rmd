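---
title: "Methods: occurrence analytics, molecular networking and strain prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occurrence analytics, molecular networking and strain prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabotalent)
```

## Scope and data model

metabotalent starts where peak picking ends. Its inputs are (i) an
MZmine-style quantification table — one row per *feature*, a unique
(m/z, retention time) pair with one peak-area column per extract — (ii) an
MGF file with one MS/MS spectrum per feature, keyed by `FEATURE_ID` (or
`SCANS`), and (iii) a sample metadata table mapping extract IDs to strain,
phylum, genus and 16S percent identity. m/z is in Da and retention time in
minutes throughout. Missing or empty area cells are read as 0: gap-filled
MZmine exports encode absence that way, and all presence/absence semantics
downstream rely on it. Blank/QC injections are flagged in the metadata and
excluded from every occurrence analytic — with multiple cultivation media a
clean blank subtraction is not possible, so exclusion is the conservative
default.

The package ships the metadata of a 60-isolate cohort of difficult-to-grow
marine and soil bacteria spanning Proteobacteria, Bacteroidetes,
Actinobacteria and Firmicutes (`load_study_metadata()`), used both as a
realistic fixture and as the template for the synthetic cohort design.

## Occurrence analytics

A feature is *present* in a sample when its area exceeds a threshold,
strictly; the default threshold is 0 (`presence_matrix()`). A
detection cutoff above 0 is exposed but not defaulted, because exported
area values are already the result of the peak picker's own filters.
Raising the threshold can only remove presences (monotonicity), which the
test suite checks.

Three set-algebra summaries follow:

* `venn_partition()` assigns each detected feature to exactly one region —
  the set of groups (phyla) in which it is present in *at least one*
  member strain. Regions are disjoint and sum to the number of detected
  features; the implementation enumerates all non-empty group subsets via
  bitmasks and is checked against brute-force enumeration.
* `strain_specific_counts()` counts features whose presence set is exactly
  one extract. These are the package's central "uniqueness" statistic.
* `uniqueness_isolate_correlation()` is the plain Pearson correlation
  between per-group specific-feature counts and group sizes, reported to
  2 decimals in summaries. It asks whether unique chemistry scales with
  sampling depth; with four phyla it is a descriptive, not inferential,
  quantity.

`mass_filter_count()` applies a strict `<` cutoff to the tabulated feature
m/z. For the singly charged ions that dominate positive-mode data the
tabulated m/z stands in for the neutral mass; no charge correction is
attempted.

## Modified cosine and molecular networking

The spectral similarity is the modified cosine used in feature-based
molecular networking. Peaks are weighted by the square root of their
intensity and L2-normalized, the convention of the major networking
platforms; the exponent is exposed as `intensity_power`. Two peaks are
candidate partners when their m/z agree within the fragment tolerance
(0.02 Da) either directly or after shifting by the signed precursor mass
difference, which links spectra of compounds differing by one
modification. A one-to-one assignment is then chosen *greedily* by
descending weight product, with ties broken on smaller m/z in the first,
then the second spectrum, so results are reproducible bit for bit. Greedy
assignment matches the exhaustive maximum-weight matching on the vast
majority of small random spectra (the suite requires equality on at least
95% of 1,000 draws and never a higher-than-optimal score) and runs in
O(k log k). Scores are bounded by 1 thanks to the unit norms.

Before networking, all fragments within ±17 Da of the precursor are
removed (`filter_precursor_window()`); residual precursor signal otherwise
dominates the cosine between unrelated spectra. Spectra emptied by the
filter are excluded from the network.

`build_network()` computes all pairwise similarities and applies, in
order:

1. edge thresholds — cosine ≥ 0.5 and ≥ 4 matched peaks. Published
   parameter descriptions mix "0.5 or more / at least four" with "above
   0.5 / more than four"; the package defaults to the inclusive reading
   (standard parameter semantics of the networking platforms) and exposes
   `inclusive = FALSE` for the strict one. A 1e-9 numerical guard keeps
   accumulated floating error from flipping a boundary score;
2. mutual top-k: an edge survives only if each endpoint ranks in the
   other's top 10 partners (by score, ties on partner id);
3. family capping: while any connected component exceeds 100 nodes, the
   globally lowest-scoring edge inside an oversized component is removed
   (ties on canonical edge id) and components are recomputed. Removal only
   splits components, so capping is idempotent. The exact removal order
   used by the original online workflow is not published; this
   deterministic rule may split very large components differently.

Connected components with ≥ 2 nodes are *molecular families*; degree-zero
nodes are singletons. `family_exclusivity()` reports, per family, the
extract with the most strain-specific member nodes and the fraction of the
family exclusive to it; fraction 1 marks a strain-exclusive family — a
whole cluster of related, typically unannotated candidate compounds seen
in a single strain, the strongest single signal for follow-up isolation.

Graph components, GraphML serialization and layout are delegated to
igraph; the similarity, pruning and capping rules are implemented in the
package.

## Dereplication cascade

Annotation proceeds consecutively through three confidence levels, and a
feature annotated at one level is never re-annotated lower:

1. **Level 1 — in-house standards**: precursor m/z within 0.02 Da,
   retention time within 0.2 min *and* spectral match (score ≥ 0.6, ≥ 3
   matched peaks). The RT tolerance is not prescribed anywhere; 0.2 min is
   typical UPLC reproducibility and is configurable.
2. **Level 2 — external spectral libraries**: the same spectral-match
   thresholds without the RT gate.
3. **Level 3 — in-silico candidates**: per feature the best candidate
   (highest formula confidence, then lowest structure score) is accepted
   only when the structure score is < −150 and the formula (Zodiac-style)
   confidence is > 0.6, both strict. Score sign conventions differ between
   tool versions, so both cutoffs are parameters. Manual curation steps
   that typically follow automated filtering are deliberately not
   modelled; the thresholds are the contract.

Everything else is `unknown`. The four levels always partition the feature
set, the cascade is order-invariant, and tightening any threshold can only
shrink a level.

`propagate_classes()` assigns each family the majority chemical class among
its annotated members — the deterministic reading of semi-automated
class-propagation tools. Ties and fully unannotated families resolve to
`unclassified` rather than an arbitrary pick.

## Strain prioritization

`build_strain_reports()` produces one row per extract: total features,
strain-specific features, percent unknown, strain-exclusive families, and
16S similarity. Flags use a specific-feature threshold of 80 (a working
cutoff separating the clearly talented tail in cohorts of this size), an
80% unknown-share threshold, and the 98.7% / 95% 16S identity cutoffs
conventionally recommended for new species / new genera. Ranking
(`rank_strains()`) is lexicographic — specific features, then percent
unknown, then exclusive families, ties on extract ID — because no
published combined score exists; an optional weighted sum over the
min-max-scaled criteria is provided for users who want one. Specificity
and unknown share are reported side by side rather than folded into a
single number by default.

## Synthetic cohorts and what they do (not) show

`synthesize_cohort()` generates a full testbed without instrument data.
The default design mirrors the packaged 60-strain cohort: four phyla with
35/17/8/1 strains, and planted annotation shares of 0.6% / 6.6% / 9.2%
(level 1/2/3, rest unknown) matching the dereplication depth reported for
such collections. Feature-stratum sizes are the package's own desk-scale
choice — 60 core features, 25/15/8/3 phylum-specific, 5 strain-specific
per strain (416 features in total) — large enough for every analytic to
have non-trivial structure while a full end-to-end run stays in seconds.

Presence follows the strata: core features are present everywhere with
i.i.d. dropout but never lose a whole phylum; phylum-specific features
occupy ≥ 2 strains of their phylum (dropout cannot demote them to
strain-specific, which keeps the specificity ground truth crisp); strain-
specific features never drop out. For a single-strain phylum,
phylum-specific and strain-specific coincide — as it does in any real
cohort with a singleton phylum.

Spectral families share a fragment template in which each peak is either
*conserved* (same m/z in every member) or *loss-linked* (offset by the
member's precursor shift). Every member pair therefore matches on all
template peaks — half directly, half via the precursor-difference shift —
exactly the structure the modified cosine is designed to detect. Fragment
templates keep ≥ 3× the fragment tolerance between peaks and all
precursors are ≥ 0.05 Da apart, so matchings and library gates are
unambiguous at default tolerances. Jitter (sd 0.005 Da), intensity noise
(CV 0.1) and dropout (0.1) default to values well inside the tolerance
budget.

`make_synthetic_libraries()` derives annotation inputs from the planted
levels, including deliberately failing in-silico decoys for half the
unknowns, so a correct cascade reproduces the planted distribution exactly
on a noiseless cohort.

What passing these tests shows: the set algebra, matching, pruning,
capping and cascade logic are correct, deterministic and tolerant to noise
within the stated budget. What they do not show: robustness to adducts,
isotopes, in-source fragments, chimeric MS/MS, media components or
retention-time drift — none of which the generator emulates. Results on
real cohorts inherit all the caveats of the upstream peak picking.

## Numerical and degenerate-input choices

* All RNG flows from one seed per generator run (`withr::with_seed`);
  identical configs give byte-identical artifacts, which the suite checks
  end to end.
* Tie-breaks are deterministic everywhere: greedy pairs (smaller m/z
  first), top-k ranks (partner id), capping (canonical edge id), ranking
  (extract ID), class propagation (ties → unclassified).
* Empty quantities are valid: zero-edge networks, empty hit tables and
  extracts without features all flow through; empty spectra are an error
  for the cosine but are filtered out before networking.
* Scores are clamped only by construction (unit norms), never post hoc; a
  1e-9 guard is applied at the edge-score cutoff comparison only.

## Problem sizes

The shipped suite runs cohorts of 63–416 features and networks of up to a
few hundred nodes, chosen so the full test suite and the acceptance script
complete in well under a minute while still exercising multi-phylum
designs, capped families and all three annotation levels. All-pairs
networking is quadratic in the number of spectra; cohorts beyond a few
thousand spectra are outside the intended desk scale of this
implementation.
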