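---
title: "Autozygosity mapping and recessive variant filtering with rohfunnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autozygosity mapping and recessive variant filtering with rohfunnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohfunnel)
```

## The model

`rohfunnel` targets the standard study design for recessive Mendelian
disease-gene discovery in closed populations. The genetic model is a
single fully penetrant autosomal recessive allele descending from a
recent founder. Two consequences of that model drive the method:

* every affected individual is homozygous for the causal allele **and**
  for a long flanking haplotype inherited identically by descent, so
  the intersection of case runs of homozygosity (ROH) localizes the
  gene;
* the causal allele is absent (or present only as rare heterozygotes)
  outside the affected lineage, so filtering case variants against a
  panel of unrelated genomes removes nearly everything else.

The pipeline composes five parts: array QC and ROH mapping, shared
region intersection, a variant-filtering funnel, consequence
annotation, and pedigree/population validation statistics. Each part is
an exported function operating on plain containers
(`genotype_matrix`, `cohort_genotypes`, `transcript_model`), so stages
can be run, inspected and replaced independently.

## ROH detection and its parameters

`detect_roh()` is the sliding-window scan popularized by PLINK. The
defaults in `roh_params()` are that tool's documented v1.07 defaults:

| parameter | default | meaning |
|---|---|---|
| `window_snps` | 50 | markers per sliding window |
| `max_het_per_window` | 1 | het calls tolerated in a "homozygous" window |
| `max_missing_per_window` | 5 | missing calls tolerated per window |
| `window_hit_threshold` | 0.05 | fraction of covering windows that must be homozygous for a marker to be ROH-eligible |
| `min_segment_snps` | 100 | minimum markers per reported segment |
| `min_segment_kb` | 1000 | minimum span (kb) |
| `min_density_kb_per_snp` | 50 | maximum kb per SNP inside a segment |
| `max_gap_kb` | 1000 | maximum inter-marker gap (kb) |

The per-window het tolerance is what makes the scan robust to
genotyping error: a 0.1% per-call error rate leaves windows
overwhelmingly below the one-het budget. Segment bounds are reported at
the outermost eligible *marker positions* rather than window edges —
coordinates are then reproducible and anchored to observed data.

QC (`qc_filter()`) applies the conventional array regime — sample call
rate, then marker call rate and minor allele frequency computed on the
retained samples — with strict inequalities at the default 0.95 / 0.95 /
0.05 thresholds. The order (samples first, then markers) matters and is
recorded in the attached `qc_log`. Note that with small cohorts the
sample-wise call-rate threshold is aggressive at the marker level: with
12 samples, a single missing call drops a marker's call rate to 0.917,
so a 2% missing rate removes roughly a fifth of markers. This is the
intended behaviour of the threshold, not a defect; detection tolerates
the thinner map comfortably.

`shared_regions()` intersects case ROH as intervals and then enforces
allele sharing: at every non-missing marker inside a candidate region,
all cases must be homozygous for the same allele. A discordant marker
splits the region (the mismatch allowance is configurable, default 0).
With a single case the segments are returned verbatim.

## The filtering funnel

`run_funnel()` applies four filters in order and records the surviving
count and ids at each stage:

1. recessive, case-specific: every case homozygous for the alternate
   allele, panel violations within policy bounds;
2. exonic: overlapping any annotated exon (CDS **or** UTR — this stage
   deliberately uses the broader definition, while consequence classes
   below use the CDS);
3. inside the shared homozygosity regions;
4. protein-changing consequence class (missense, nonsense, frameshift).

The stages after the first commute — the funnel order matches the
narrative order of a discovery study, but the final set is
order-independent, and the tests assert this.

Two policy decisions deserve comment. **Panel heterozygotes**: the
strict default (`max_panel_het = 0`) demands the allele be fully absent
from the panel. A cross-breed panel is expected to be free of a
breed-private founder allele, so strictness is cheap and powerful. The
relaxed mode (`max_panel_het > 0`) tolerates carriers, which is the
right choice when the panel may contain related animals; the simulator
plants panel-carried decoys precisely so that both modes are
exercised — under the relaxed policy those decoys reach the final stage
and are then eliminated by the segregation check, reproducing the
discriminating step of the study design. **Missing case genotypes**:
the conservative default excludes the variant; `treat_missing_as =
"hom_alt"` is available for degraded (e.g. FFPE-derived) inputs where
dropouts are expected.

## Consequence annotation

`annotate_consequence()` projects a variant onto the spliced CDS
(strand-aware; minus-strand alleles are reverse-complemented), checks
the reference allele against the transcript sequence (a mismatch is an
error, never silently reinterpreted), and classifies:

* SNV: mutate the affected codon and translate; alt codon a stop ⇒
  `nonsense`; same residue ⇒ `synonymous`; otherwise `missense`;
* indel: length change not divisible by 3 ⇒ `frameshift`, else
  `inframe_indel`;
* positions outside the CDS ⇒ `non_coding` (UTR), `intronic`, or
  `intergenic`.

Notation follows the compact single-letter dialect used in study
summary tables (`c.31C>T`, `p.R11*`, `c.233delC`, `p.A78fs`) rather
than full HGVS (`p.(Arg11Ter)`), and `codon_index` is always
`ceiling(cds_pos / 3)`. Variants spanning an exon boundary or splice
junction are classified `non_coding` and excluded from the
protein-changing set — a documented simplification, as is the mapping
of stop-loss substitutions onto `missense` (the class enumeration has
no dedicated stop-loss member). Multi-allelic records must be
decomposed (`decompose_biallelic()`); alleles are left-normalized
internally so the notation is deterministic.

`truncation_stats()` applies to nonsense consequences only:
retained residues = codon index − 1, against a full length of
CDS/3 − 1 residues. A stop in codon 11 of a 1121-residue product
retains 10 residues — a 99.1% truncation.

## Segregation, carrier frequency, association

`check_recessive_segregation()` encodes the expectation table — cases
hom-alt, obligate carriers het, other unaffected relatives het or
hom-ref — and lists every deviation; samples missing from the genotype
vector are reported, never dropped. `carrier_frequency()` reports the
het percentage rounded half-up to one decimal, with hom-alt animals
flagged separately as genetically affected rather than counted as
carriers.

`allelic_chisq()` is the Pearson chi-square on the 2×2 allele table
(df = 1, no Yates correction). Extreme tails are computed on the
survival side (`pchisq(..., lower.tail = FALSE)`), never as
`1 − CDF`, and `log10_p` is additionally derived from the
log-scale tail so that results remain interpretable beyond double
underflow (chi-square above ~1500). Margins are cast to doubles before
the cross-product — allele counts from a few thousand diploids already
overflow 32-bit integer arithmetic. Fisher's exact test is available
behind `allelic_assoc(method = "fisher")` as a cross-check, not the
default: the chi-square is the statistic whose extreme tail remains
computable and comparable at arbitrary significance.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates, under one master seed (per-component
streams are derived by fixed offsets, so each stage is independently
reproducible):

* a 3 × 10 Mb genome with 9 spliced protein-coding genes (UTRs,
  introns, both strands), one of which — the designated gene, placed
  inside the planted interval — carries a 1121-residue CDS whose
  codon 11 is CGA, split so that CDS position 31 opens exon 2;
* 3,000 array markers per contig with B-allele frequencies from
  U(0.05, 0.5) and Hardy–Weinberg genotypes, matching the MAF > 0.05
  QC regime; a 2 Mb interval on chr1 over which the 7 cases *and* the
  obligate-carrier parent and grandparent are homozygous for one
  shared haplotype (the carriers are haplotype-homozygous but
  heterozygous at the causal site — exactly the configuration that
  makes the causal variant, not the haplotype, the discriminating
  observation);
* genotyping error (0.1% per call, replacing the call with a different
  code) and missingness (2%) at typical array rates;
* a cohort VCF holding the causal variant (hom-alt cases, het obligate
  carriers, one het of three siblings, 3 het carriers among 176
  population dogs, absent from the 136-genome panel), about 300
  Hardy–Weinberg background variants, and three decoys per class:
  case-specific non-exonic, case-specific exonic outside the interval,
  case-specific synonymous inside it (segregation-violating), and
  protein-changing inside it but panel-carried and
  segregation-violating.

Cohort counts (7 / 2+3 / 176 with 3 carriers / 136) are kept at
realistic study scale because the validation statistics — the 1.7%
carrier estimate and the ~10⁻⁵⁸ allelic p-value — depend on them;
genome size is shrunk because coordinate arithmetic does not care.

The simulator deliberately does **not** model linkage disequilibrium
or recombination (the planted interval is an idealized IBD block with
hard edges), population structure within the panel, read-level error
(no FASTQ/BAM), or realistic mutation-rate spectra. Consequently,
passing tests demonstrate the correctness of the algorithms under the
stated genetic model — not the false-positive behaviour of ROH scans
under real LD, which is known to require pruning or density tuning on
dense arrays.

## Numerical and degenerate-input choices

* QC thresholds are strict inequalities (call rate "> 0.95"), so a
  marker at exactly the threshold is removed; an all-markers-removed
  outcome is an explicit error, not an empty object.
* `detect_roh()` on fewer markers than one window returns no segments;
  an unknown sample id is an error.
* `shared_regions()` with an empty segment list returns an empty frame
  (not an error); region splitting re-anchors boundaries at the
  outermost concordant markers.
* Genotype codes are alt-allele counts (0/1/2/NA) throughout; PLINK
  round-trips re-infer allele coding lexicographically, so a marker at
  which only one allele is observed reads back as hom-reference — the
  het/missing pattern, which is all ROH detection consumes, is
  invariant.
* The perturbation, recovery and oracle-agreement properties in the
  test suite run at problem sizes (20 seeded cohorts, 1,000+ random
  transcript/variant pairs, ≤ 500-marker exhaustive-oracle matrices)
  chosen to keep the full suite within a few minutes on one CPU while
  leaving the statistical assertions comfortably powered.

## Known limitations

* One consequence per (variant, transcript); cross-transcript
  reporting picks the most severe class with no tie-break
  sophistication.
* HGVS coverage is the simplified dialect: no `dup`, `delins`,
  extension or intronic (`c.*+n`) notation.
* No F_ROH inbreeding coefficients, no LD pruning, no kinship-corrected
  association — outside the intended discovery workflow.
* The segregation expectation table assumes full penetrance and the
  affected ⇔ case study design; incomplete penetrance would need a
  different expectation model.
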