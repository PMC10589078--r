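---
title: "Methods: dual-locus pollen metabarcoding profiles and nutritional niche summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-locus pollen metabarcoding profiles and nutritional niche summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenniche)
```

This vignette documents the models, conventions and numerical choices
behind the package, in the order the pipeline runs: reference cleaning,
read classification, dual-locus profiling, and nutrition arithmetic, plus
the synthetic-data module that makes all of it testable.

## The problem

A female solitary bee provisions each offspring with a pollen mass
gathered over many foraging trips. Two complementary measurements describe
that provision: its botanical composition (which plant genera contributed,
recovered by amplicon metabarcoding of the nuclear ribosomal spacers ITS1
and ITS2) and its macronutrient content (protein and lipid concentrations,
summarised as the protein:lipid mass ratio — the axis along which
nutritional-geometry studies locate a species' dietary niche). The package
implements the computational path from merged amplicon reads and a
reference barcode database to genus proportions, and from nutrition assays
and rearing trials to niche and survival summaries.

## Reference-barcode cleaning

Genus-level classification is only as good as the reference database, and
public ITS records are contaminated: fungal amplicons deposited under the
name of the plant the fungus grew on are the classic failure. The cleaning
cascade flags each reference barcode against two contrast databases — one
of non-plant ITS-region sequences, one of plant sequences — using exact
matching at 100% identity and 100% query coverage, implemented as
substring containment (the contrast record may be longer than the
barcode). The rules, in order:

1. an exact non-plant hit flags the barcode mislabeled;
2. exact plant hits are compared by genus: any same-genus hit flags it
   correctly labeled (same-genus concordance deliberately wins over a
   coexisting cross-genus hit — conservative retention, logged with a
   warning), cross-genus hits only flag it mislabeled;
3. with no exact plant hit, the top relaxed alignment hit over the plant
   database decides by genus equality;
4. finally, any exact match whose lineage class is known and is not
   Magnoliopsida overrides the rule (2)–(3) outcome to mislabeled. Rule 4
   considers exact matches only.

Two conventions deserve a note. First, `N` never matches any base, so a
barcode containing `N` cannot attain a 100%-identity hit. Second, the
"top hit" of rule 3 is ranked by identity with ties broken by longer
aligned span, then smallest record id; when the tie still spans several
genera, genus equality is tested against their lowest common ancestor, so
the outcome is order-independent. If the relaxed search returns nothing at
or above `relaxed_min_identity` (default 0), the barcode is flagged
mislabeled with empty evidence — the conservative reading of an
underdetermined case.

The relaxed search aligns the barcode *end to end* (query-global, the
blastn/usearch_global convention), not with free end gaps on both
sequences. The reason is numerical: under free end gaps on both sequences,
the optimal alignment against an unrelated reference is typically a short
perfect overlap with identity 1.0, so ranking references by the identity
of their score-optimal alignment would be dominated by such artifacts.
Forcing the query to span the alignment makes identity comparable across
references.

## Read classification

Merged reads are compared to the reference set by semi-global dynamic
programming: gaps at either terminus of either sequence cost zero,
internal gaps and mismatches are penalised (defaults +2 / −4 / −4).
Acceptance is decided by two thresholds, pairwise identity ≥ 0.95 and
query coverage ≥ 0.80; the score itself only orders ties, so any sensible
scoring scheme yields the same accepted sets. Identity is matching columns
over alignment columns with terminal-gap columns excluded and internal gap
columns counted as mismatches; coverage is the fraction of query bases
inside the aligned region.

Equal-score alignments can differ in identity and coverage, so the
alignment reported is the lexicographic optimum: score, then matched
columns (maximised), then alignment columns (minimised), then
query-consuming columns (maximised). All four quantities are additive
along a dynamic-programming path, so this optimum is computed exactly, and
two independent implementations of the convention must agree to the digit
— which is how the test suite checks the Rcpp core against a plain-R
oracle.

The search is exhaustive over the reference set (deterministic, and at
desk scale strictly more complete than the accept-count heuristics of
field tools); `max_accepts` (default 100) truncates only the returned hit
list. Both strands are tried by default, keeping the orientation with the
better score, because merged amplicon orientation is not guaranteed.
Assignment takes all hits tied with the top hit on (identity, score): if
their lineages share a genus the read is assigned, otherwise their lowest
common ancestor decides, and an LCA above genus leaves the read matched
but unassigned. Reads are classified as-is — no trimming, denoising or
merging, which belong to upstream tools.

## Dual-locus profiling

The two markers disagree: amplification bias makes a genus over- or
under-represented locus-specifically. The aggregation rule takes, per
genus, the larger of its two locus counts, and normalises by the sum of
those maxima. Genera at or above 1% of a sample form the retained set;
proportions are *not* renormalized after that filter by default (the
un-renormalized shares remain interpretable as fractions of all classified
pollen), with `renormalize = TRUE` available. Sample QC requires at least
5% (inclusive) of reads across both markers combined to have matched the
reference, where "matched" counts genus-assigned plus
matched-but-unassigned reads. Implausible genera — by default *Clusia*,
*Hirtella* and *Parinari*, tropical taxa taken as database mismatches in a
temperate study region — are excluded *before* proportions are computed,
so shares are shares of plausible pollen. Genus richness is the size of
the retained set; the host-plant proportion sums retained shares of
genera whose family is Rosaceae or Fabaceae (configurable), computed on
un-renormalized shares by default; both orderings are exposed because the
choice is not determined by the procedure itself.

## Nutrition arithmetic

`pl_ratio()` is protein/lipid on identical units (µg per mg dry mass
throughout); `niche_summary()` computes per-sample ratios first and
summarises them (never the ratio of means), reporting n, mean, SE (sample
SD over √n, undefined at n = 1) and range per group.

`formulate_diet()` uses the dilution-ignored convention: resulting
concentrations are expressed per mg of *base pollen*, so adding only lipid
leaves the printed protein concentration unchanged — the convention
experimental diet tables use. A single additive suffices (protein if the
target ratio exceeds the base ratio, lipid if below); with additive purity
c in (0, 1], the lipid mass to reach target ratio ρ from base (P₀, L₀) is
(P₀/ρ − L₀)/(1000·c) mg per mg pollen, and symmetrically for protein.
Additive purities default to 1 (pure casein / pure oil) and are
overridable. A `dilution_aware` mode divides both resulting concentrations
by total mixture mass; additive masses and the achieved ratio are
identical because dilution scales both nutrients equally. The round-trip
identity — formulate, then take the ratio of the resulting composition —
holds to 1e−9 and is tested on random targets.

`survival_summary()` computes larval survival (% cocoons completed) over
all individuals, but pupation and adult percentages over cocoon completers
only, matching the convention that later-stage models include only
survivors of the larval stage; the control diets' nominal 3:1 ratio is a
label, not a measurement. Inferential statistics (GLMs, rank tests,
ANOVA) are deliberately out of scope: the summaries are tidy inputs for
base R's `glm()`, `kruskal.test()` and friends.

## The synthetic-data module

Every generator is a pure function of a `sim_config()` and its seed; the
global seed expands into independent substreams (reference db, reads,
nutrition, rearing) so adding one call never perturbs another stream. The
defaults define the study conditions the tests run under:

* **Reference db**: 5 genera × 3 species per genus per locus, barcode
  length 150 (desk-scale stand-ins for few-hundred-bp ITS barcodes),
  founders evolved from a shared ancestor at 20% per-base divergence,
  species at 2%; 10% of barcodes planted as mislabels (alternating exact
  cross-genus and non-plant copies); 20 fungal-labeled contaminants.
  Genus/family names are synthetic stand-ins drawn from a small pool of
  temperate genera so host-family arithmetic is exercised; no real barcode
  data is embedded anywhere.
* **Reads**: 2000 per locus per sample, multinomial from the true mixture
  (default 0.40/0.25/0.20/0.10/0.05) reweighted by a 2-fold
  locus-alternating amplification bias — chosen so the dual-locus maximum
  rule is consequential — with 1% per-base substitution error. The
  expected systematic distortion of the max-rule profile under this bias
  is ≈0.03 in L∞, which is why the end-to-end recovery test's 0.05 bound
  is meaningful but not fragile.
* **Nutrition**: zero-truncated normals with moments on the published
  field scale (protein 151.42, lipid 53.94 µg/mg; SDs 47.78 and 20.66,
  derived as SE·√n from printed standard errors assuming n = 59, i.e.
  roughly ten provisions per week over a six-week season — the sample size
  itself was not printed, and this choice was made once, up front).
  Moments are interpreted pre-truncation; the truncation shift
  (σ·φ(µ/σ)/Φ(µ/σ)) is ≈0.3 µg/mg for lipid and smaller for protein, and
  the tests account for it analytically.
* **Rearing**: per-diet stage probabilities conditional on reaching the
  prior stage, so the cocoon ⊇ pupated ⊇ adult nesting holds by
  construction; timings uniform on plausible day ranges.

What the simulator does *not* emulate — ITS length variation and secondary
structure, indel sequencing error, chimeras, PCR duplicates, copy-number
variation among taxa — bounds what passing tests show: they validate the
*procedure* (thresholds, aggregation, bookkeeping, determinism), not
field-data accuracy. Reported field quantities that depend on the deposited
sequencing data or on external database versions (field mean P:L ratios,
genus-richness and host-proportion means, database removal fractions,
survival percentages) are correspondingly not reproduced here; the package
checks parameter recovery against synthetic truth instead.

## Problem sizes and determinism

The test suite runs the full preset (4000 reads against 30 references,
both strands) once for end-to-end recovery, ~500 random alignment pairs of
length ≤ 40 against the R oracle, and 100-barcode cleaning fixtures —
sizes chosen so any stage remains inspectable by hand. Identical reads are
classified once and their counts aggregated, which changes nothing
(classification is a function of the sequence alone). All tabular outputs
are tab-separated UTF-8 with a single header row; every threshold used by
`run_pipeline()` is echoed in its JSON run summary, so no filter is
silent.

## Known limitations

* Exact matching treats the contrast databases as ground truth; a
  contaminated *plant* contrast database would propagate its errors.
* The 1% / 5% / 95% / 80% thresholds are conventions of the profiled
  protocol, exposed as arguments but not auto-tuned.
* Genus-level assignment inherits the limits of ITS resolution; congeneric
  references closer than the error rate will push reads to
  `matched_unassigned` rather than force a call.
* The package profiles composition per sample and deliberately offers no
  between-group inference.
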