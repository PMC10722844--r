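# dslst

Community-ecology toolkit for layer-stratified marine 16S rRNA amplicon
surveys centred on the mesopelagic **deep scattering layer (DSL)** — the
depth stratum (~450–600 m) where vertically migrating fish concentrate by
day and fertilize the resident microbes with labile organic matter.

**For whom:** microbial oceanographers with an ASV × sample count table,
taxonomy, and per-sample station/season/layer/depth metadata, who want to
quantify how the DSL community relates to the epipelagic (SURF, DCM) and the
surrounding mesopelagic (MS, MD) layers.

## What it computes

* **IO / normalization** — validated TSV (or sparse triples) reading, taxon
  exclusion rules (non-prokaryotes, chloroplasts/mitochondria), dataset-wide
  singleton removal, seeded rarefaction without replacement, rank
  aggregation, relative abundances.
* **Diversity** — Shannon *H* = −Σ pᵢ ln pᵢ (nats), richness *n*, Pielou
  *J* = *H*/ln *n*; Bray–Curtis *d*(x,y) = Σ|xᵢ−yᵢ|/Σ(xᵢ+yᵢ); PCoA (Gower
  double-centering, negative eigenvalues excluded); one-way PERMANOVA
  (Anderson pseudo-F, seeded permutations) with pairwise adjusted p-values;
  axis–environment Pearson correlations; the BIX fluorescence index
  (emission 380/430 nm at 310 nm excitation).
* **Zone enrichment** — per-clade 2×2 tables (clade/other ×
  mesopelagic/epipelagic pooled reads), natural-log odds ratio with
  Haldane–Anscombe correction of the estimate, Fisher's exact two-sided p.
* **Indicator species** — Dufrêne–Legendre IndVal (specificity × fidelity)
  with permutation p-values and the strict rule *p* < 0.05 & indval > 0.5.
* **Source partitioning** (the core) — per profile, each DSL ASV goes to
  exactly one of `EPI_shared`, `unique_DSL`, `MS_only_shared`,
  `MD_only_shared`, `all_meso_shared` (epipelagic precedence); DSL-enriched
  taxa flagged by ANOVA + Tukey across mesopelagic layers; per-profile
  percentages averaged; pooled DSL-unique contribution; 3-way seasonal
  overlap.
* **Synthetic data** — a seeded Dirichlet-multinomial generator planting all
  of the above as ground truth (3 seasons, MS/MD sampled only in spring,
  7+5+7 profiles = 67 samples by default).

## Worked example

```r
library(dslst)

spec <- community_spec(seed = 7, depth = 20000)   # planted ground truth
sim <- generate_community(spec)

pt <- partition_dsl(sim$counts, sim$metadata, season = "spring")
summarize_partition(pt)
#> $n_profiles            [1] 5
#> $mean_percent
#>  EPI_shared  unique_DSL  MS_only_shared  MD_only_shared  all_meso_shared
#>      15.890      16.103           0.423           0.106           67.477
#> $mean_n_dsl            [1] 188.8
#> $se_n_dsl              [1] 0.374
#> $mean_percent_enriched [1] 10.42
#> $mean_percent_meso_origin [1] 68.0
#> $percent_attributable  [1] 26.5
```

Reading: across the 5 spring profiles the DSL held on average 188.8 ASVs;
16.1 % occurred nowhere else in the profile (`unique_DSL`), 15.9 % were
shared with the epipelagic, 68 % with the neighbouring mesopelagic layers,
and 10.4 % of DSL ASVs were mesopelagic-shared but significantly *enriched*
at the DSL (ANOVA + Tukey, α = 0.05) — so 26.5 % of the diversity is
attributable to the DSL itself. This matches the planted design: of the 190
taxa that can reach the DSL, 30 are DSL-unique (15.8 %), 30 cosmopolitan
(15.8 %) and 20 enriched at 10-fold (10.5 %).

Alpha diversity shows the canonical depth pattern (mean per layer):

```r
a <- alpha_diversity(sim$counts)
round(tapply(a$shannon, sim$metadata[rownames(a), "layer"], mean), 2)
#>  DCM  DSL   MD   MS SURF
#> 3.79 4.76 4.64 4.64 3.87
round(tapply(a$richness, sim$metadata[rownames(a), "layer"], mean), 0)
#>  DCM  DSL   MD   MS SURF
#>   70  189  159  159   70
```

— richness peaks at the DSL and roughly doubles the epipelagic, as the
planted occupancy design dictates.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "dslst.R", package = "dslst"))')
Rscript $CLI simulate --seed 5 --depth 5000 --dir sim/
Rscript $CLI partition --counts sim/counts.tsv --taxonomy sim/taxonomy.tsv \
        --metadata sim/metadata.tsv --season spring --pooled
Rscript $CLI indval --counts sim/counts.tsv --taxonomy sim/taxonomy.tsv \
        --metadata sim/metadata.tsv --subset layer=DSL --perms 999 --seed 1
```

Other commands: `validate`, `filter`, `rarefy`, `alpha`, `beta`, `pcoa`,
`permanova [--pairwise]`, `zone-odds`, `seasonal-venn`.

## Documentation

`vignettes/dsl-source-partitioning.Rmd` describes the model, its
assumptions, the tunable parameters, what the synthetic generator does and
does not emulate, and the numerical choices.
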