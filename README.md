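# pollenniche

Tools for asking two linked questions about solitary bees such as the
spring-flying mason bee *Osmia cornifrons*: **what pollen do they collect**
(genus-level diet profiles from dual-locus ITS1/ITS2 amplicon
metabarcoding), and **what nutrition does that pollen deliver**
(protein-to-lipid nutritional-niche summaries and experimental diet
formulation).

## What the package computes

**Reference-barcode decontamination.** Public barcode databases contain
mislabeled records (e.g. fungal ITS sequences deposited under plant names).
`clean_database()` flags each reference barcode by a four-rule cascade of
exact-match searches (100% identity, 100% query coverage, i.e. substring
containment) against a *non-plant* and a *plant* contrast database:

1. any exact non-plant hit ⇒ mislabeled;
2. exact plant hits are compared by genus — same genus ⇒ correctly
   labeled, different genus only ⇒ mislabeled;
3. with no exact plant hit, the top relaxed (alignment) hit's genus
   decides;
4. any exact match outside the class Magnoliopsida overrides to mislabeled.

**Read classification.** `classify_sample()` assigns merged amplicon reads
to plant genera by exhaustive semi-global alignment (free end gaps;
`semiglobal_align()` is a small Rcpp core) against a per-locus reference
set, accepting hits at ≥95% pairwise identity and ≥80% query coverage, and
resolving tied top hits through the lowest common ancestor of their
lineages.

**Dual-locus genus profiles.** `dual_locus_profile()` reconciles the two
markers with the maximum rule: for genus *g* with per-locus read counts
*c*₁(*g*), *c*₂(*g*),

    m(g) = max(c₁(g), c₂(g)),   p(g) = m(g) / Σ_g m(g),

keeping genera with *p*(*g*) ≥ 1% and requiring ≥5% of a sample's reads
(both markers combined) to match the reference. `genus_richness()` and
`host_plant_proportion()` (share of Rosaceae + Fabaceae, the bee's host
families) summarise each profile.

**Nutritional niche.** `pl_ratio()` and `niche_summary()` compute per-sample
protein:lipid ratios (the nutritional-geometry niche axis) and grouped
mean/SE/range summaries; `formulate_diet()` inverts the arithmetic to tell
you how much protein (casein) or lipid (oil) additive brings a base pollen
to a target P:L ratio; `survival_summary()` tabulates in vitro rearing
outcomes per diet with stage-conditional denominators.

**Synthetic data.** `sim_config()` plus `generate_reference_db()`,
`generate_sample_reads()`, `generate_provision_nutrition()` and
`generate_rearing_outcomes()` simulate every input with known truth
(planted mislabels, known genus mixtures with per-locus amplification bias
and substitution error, configured nutrition moments and survival
probabilities), so the whole pipeline is testable end to end without any
sequencing data.

## Worked example

```r
library(pollenniche)

cfg <- sim_config(seed = 1)              # 5 genera, 2000 reads per locus
db  <- generate_reference_db(cfg)
sim <- generate_sample_reads(cfg, db, "S1")
refs <- split(setNames(db$reference$sequence, db$reference$id),
              db$reference$locus)
lc   <- classify_sample(sim$reads, refs, db$reference_lineages)
prof <- dual_locus_profile(lc, exclude = character(0))
round(prof$proportions[names(cfg$composition)], 3)
#> Malus  Cercis    Acer Lonicera Quercus
#> 0.357   0.297   0.197    0.099   0.050
cfg$composition
#> Malus  Cercis    Acer Lonicera Quercus
#>  0.40    0.25    0.20     0.10    0.05
genus_richness(prof)
#> [1] 5
```

The recovered proportions track the simulated mixture within 0.05 despite
1% sequencing error and a 2-fold locus-specific amplification bias; all
five genera above the 1% threshold are retained. On the nutrition side:

```r
pl_ratio(191.40, 443.18)      # high-lipid experimental diet
#> [1] 0.4318787
formulate_diet(191.40, 34.40, target_ratio = 6.6)$protein_additive_mg
#> [1] 0.03564                 # mg casein per mg base pollen
```

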