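# cocoamap

Panel design, F1 segregation analytics and QTL scanning for a cacao SNP
genotyping array.

Cacao (*Theobroma cacao* L.) breeding programs lean on mid-density Infinium
SNP arrays: a panel of ~13,500 biallelic markers is distilled from two
variant-discovery datasets, trees from F1 full-sib ("CP") mapping
populations are genotyped, mislabeled or contaminated individuals are
screened out by Mendelian-error rates, a missing parent's genotype is
reconstructed from progeny segregation, and yield/disease phenotypes are
scanned for QTL. `cocoamap` implements that pipeline end to end for R
users — geneticists and breeders working with outbred full-sib families —
together with a seeded synthetic-cross generator so every stage is testable
without field data.

## What it computes

- **Panel design**: candidate-SNP filters (Phred ≥ 20, allele frequency
  ≥ 20%, ≥ 2 reads, SNV-only), a 60-bp probe-window proximity exclusion,
  dataset intersection, genes-in-QTL-region prioritisation with
  hypergeometric term enrichment, one-SNP-per-gene selection (unique flank
  ≻ missense ≻ single bead-type ≻ ADT score, ADT > 0.9), largest-remainder
  anchor apportionment, largest-gap filling, and Infinium II bead-type
  accounting (A/T and C/G cost 2; A/C, A/G, T/C, T/G cost 1).
- **Genotype QC**: per-locus GenTrain (< 0.4 drops the locus) and per-call
  GenCall (< 0.2 blanks the call) filters, missing-data accounting,
  duplicate-sample detection, heterozygosity.
- **CP segregation**: `lmxll`/`nnxnp`/`hkxhk` typing, exact Mendelian
  progeny distributions, chi-square goodness-of-fit inference of an unknown
  parent (smallest statistic wins; impossible classes tolerated up to 2% of
  the family), Mendelian-error off-type screening at the inclusive 3% rule,
  segregation-distortion χ² (> 15 removed), mapping-input hygiene and
  JoinMap CP `.loc` export.
- **Concordance**: 3×3 array-vs-sequencing contingency tables, pooling,
  and a discordance profile (het/hom classes).
- **Traits**: monthly observation aggregation and the derived responses —
  cherelle wilt ratio `c/(c + pods)`, percent sick / percent frosty pod,
  probability of monilia, fresh weight per pod — with undefined ratios kept
  missing.
- **QTL scan**: centered additive/dominance codings per segregation type,
  per-marker joint Wald tests, percent variance explained as incremental
  R², Li–Ji effective-test correction (`Meff = Σ I(λᵢ ≥ 1) + (λᵢ − ⌊λᵢ⌋)`
  per linkage group), threshold `α/Meff`, composite rescanning with greedy
  peak cofactors and a 10-cM exclusion window, and Table-style QTL
  summaries with favorable parental alleles.
- **Map statistics**: per-LG length, gaps, genome coverage, SNPs/cM, bp/cM,
  bp/SNP, Spearman collinearity, Kendall inversion counts, scaffold
  placement by majority linkage group.

## Worked example

Simulate a 249-progeny cross with an unknown father (mother 50%
heterozygous, father 58.8%), 400 markers on 10 linkage groups, 0.5%
genotyping error, 2% injected off-types, and one planted QTL (additive
effect 1 SD on LG 4 at 30 cM):

```r
library(cocoamap)
library(tibble)

cfg <- sim_config(n_lg = 10, markers_per_lg = 40, lg_lengths_cM = 100,
                  mother_het = 0.50, father_het = 0.588, n_progeny = 249,
                  genotyping_error = 0.005, off_type_fraction = 0.02,
                  qtl_spec = tibble(lg = 4, cm = 30, add = 1, dom = 0,
                                    trait = "weight"),
                  seed = 2026)
parents <- simulate_parents(cfg)
sim <- simulate_f1(parents, cfg)

ot <- detect_off_types(parents$mother$geno, parents$father$geno, sim$progeny)
ot$off_types
#> # A tibble: 5 x 4
#>   sample_id errors typed  rate
#> 1 F1_0182       84   400 0.21
#> 2 F1_0178       81   400 0.202
#> ...
```

All five injected off-types are flagged (their Mendelian-error rates, about
20%, dwarf the 3% rule) with no false positives. Drop them, reconstruct the
father from progeny segregation, prepare the mapping input and scan:

```r
clean <- gm_subset(sim$progeny,
                   samples = !sample_ids(sim$progeny) %in% ot$off_types$sample_id)
inf <- infer_parent_genome(parents$mother$geno, clean)
mean(inf$father == parents$father$geno, na.rm = TRUE)
#> [1] 0.995

prep <- prepare_mapping_dataset(clean, parents$mother$geno, inf$father)
prep$dataset
#> <mapping_dataset> 244 progeny x 322 loci (lmxll 82, nnxnp 112, hkxhk 128, ...)

rule <- significance_rule(li_ji_meff(prep$dataset,
  lg = cfg$map$lg[match(prep$dataset$loci$locus_id, cfg$map$marker)]))
rule
#> alpha 0.05, meff 130, threshold_p 3.85e-4, threshold -log10(p) 3.41
```

The 322 retained markers behave like ~130 independent tests, so the
genome-wide threshold is −log10(p) = 3.41. Scanning a trait built from the
planted genetic values plus unit Gaussian noise:

```r
res <- qtl_scan(trait, prep$dataset, cfg$map)
summarize_qtl(res, rule, prep$dataset)
#> # A tibble: 2 x 14
#>     lg peak_marker peak_cm peak_pos lower_limit upper_limit ...
#> 1    4 LG04_M0013     30.8 10769232           1    13461539
#> 2    4 LG04_M0021     51.3 17948719    17948719    17948719
```

The peak lands on LG 4 at 30.8 cM — 0.8 cM from the planted QTL — with the
physical bounds of the significant region alongside; `autoplot(res, rule)`
draws the profile.

A YAML-driven `run_pipeline()` chains the whole thing
(simulate → QC → off-types → father inference → traits → CIM scan) and
writes TSV outputs plus a JSON run manifest with seeds and file digests.

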