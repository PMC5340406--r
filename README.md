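# rohfunnel

Autozygosity mapping and recessive variant filtering for Mendelian
disease-gene discovery in inbred populations.

## The problem

In closed breeding populations (dog breeds are the motivating case), a
lethal recessive disorder typically traces back to a single recent
founder allele. Affected animals are then homozygous not just at the
causal site but across a long surrounding chromosomal segment inherited
identically by descent. This suggests a two-stage discovery design that
needs only a handful of cases:

1. **Homozygosity mapping.** Genotype a few affected animals on a SNP
   array, find each one's runs of homozygosity (ROH), and intersect
   them: the causal gene must lie in a region where all cases are
   homozygous *for the same haplotype*.
2. **Variant filtering.** Sequence one case, and filter its variants
   down with a funnel: keep variants homozygous in the case(s) and
   absent from a panel of unrelated control genomes, then restrict to
   exonic variants, to variants inside the shared ROH regions, and to
   protein-changing consequence classes (missense, nonsense,
   frameshift). Surviving candidates are checked for co-segregation in
   the pedigree (cases homozygous, obligate carriers heterozygous,
   unaffected relatives never homozygous) and for allelic association
   in a case/control cohort.

`rohfunnel` implements every stage of that design as composable R
functions, together with a synthetic-cohort simulator that plants a
known causal nonsense variant inside a known autozygous interval, so
the whole pipeline can be exercised and tested end-to-end without any
external data.

## Methods at a glance

* **ROH detection** is the classic sliding-window scan (PLINK v1.07
  defaults): a window of 50 SNPs is *homozygous* if it has ≤ 1 het and
  ≤ 5 missing calls; a marker is ROH-eligible if ≥ 5% of windows
  covering it are homozygous; maximal eligible runs become segments if
  they have ≥ 100 SNPs, span ≥ 1 Mb, exceed 1 SNP / 50 kb density and
  contain no gap > 1 Mb. All thresholds are arguments.
* **Shared regions** are interval intersections of case ROH that
  additionally require identical homozygous genotypes at every
  non-missing marker (allele sharing); discordant markers split a
  region.
* **Consequence annotation** projects variants onto spliced CDS
  coordinates (strand-aware), classifies SNVs by mutating the affected
  codon (alt codon = stop ⇒ nonsense), indels by frame (length change
  not divisible by 3 ⇒ frameshift), and emits simplified single-letter
  HGVS (`c.31C>T`, `p.R11*`, `c.233delC`, `p.A78fs`). For a nonsense
  consequence, `truncation_stats()` reports retained residues
  (codon index − 1) against the full-length product.
* **Association** uses the Pearson allelic chi-square on the 2×2
  allele-count table (df = 1, no continuity correction), with the tail
  computed on the survival-function side so that p-values such as
  10⁻⁵⁸ — and, via `log10_p`, far smaller — are reported accurately.
  Carrier frequency is the heterozygote percentage, rounded half-up to
  one decimal.

## Worked example

```r
library(rohfunnel)

# simulate a study: 7 cases, obligate-carrier parent and grandparent,
# 3 unaffected sibs, 176 screened population dogs (3 carriers),
# 136-genome control panel; 2 Mb autozygous interval planted on chr1
# with a causal C>T nonsense variant inside it
b <- simulate_cohort(sim_config(seed = 7))

# ROH mapping on the QC-filtered array genotypes of the cases
gm <- qc_filter(b$array)
cases <- paste0("case", 1:7)
segs <- lapply(setNames(cases, cases), function(s) detect_roh(gm, s))
regions <- shared_regions(segs, gm)

# the filtering funnel
fun <- run_funnel(b$cohort, b$reference$transcripts, regions)
print(fun)
#> Variant filtering funnel
#>   Total number of variants                                                              320
#>   Variants that segregate under recessive mode of inheritance                           10
#>   Variants in the exonic regions                                                        7
#>   Variants in the identified regions of homozygosity                                    4
#>   Non-synonymous, frameshift and nonsense variants in the regions of homozygosity       1

# the unique survivor is the planted causal variant; validate it
id <- fun$surviving_ids[[5]]
g <- setNames(b$cohort$calls[id, ], b$cohort$samples$id)
check_recessive_segregation(g, b$sample_sheet)
#> segregation_report: 188 consistent, 0 inconsistent; fully segregating

pop <- b$sample_sheet$sample[b$sample_sheet$relation == "population"]
carrier_frequency(g, pop)
#> carrier_estimate: 3/176 heterozygotes (1.7%), 0 genetically affected

tab <- build_allelic_table(g[cases], g[setdiff(b$sample_sheet$sample, cases)])
allelic_chisq(tab)
#> assoc_result: chi-square = 258.8376 (df = 1), p = 3.075e-58 (log10 p = -57.51)
```

The funnel narrows 320 simulated variants to exactly the planted
nonsense variant; it fully segregates in the pedigree, 3 of 176
population dogs carry it (1.7%), and the allelic test on the combined
cohort (14 alt alleles in cases vs 6 among 362 control alleles) gives
p ≈ 3.1 × 10⁻⁵⁸. Annotating it against the affected transcript yields
`c.31C>T` / `p.R11*` — a stop in codon 11 that truncates the
1121-residue product after 10 residues (`truncation_stats()`).

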