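test_that("cds_position maps spliced coordinates, both strands", {
  set.seed(101)
  toy <- toy_two_exon(n_res = 20)
  tx <- toy$tx
  # anchor: first CDS base
  expect_equal(cds_position(111L, tx), 1L)
  # 31st spliced CDS base opens exon 2 at genomic 161 (hand-spliced)
  expect_equal(cds_position(161L, tx), 31L)
  # exon1/intron boundary: genomic 140 is CDS 30, 141 is intronic
  expect_equal(cds_position(140L, tx), 30L)
  expect_true(is.na(cds_position(141L, tx)))
  # UTR and intergenic positions are NA
  expect_true(is.na(cds_position(105L, tx)))
  expect_true(is.na(cds_position(50L, tx)))
  # strand symmetry: the mirrored minus-strand locus gives the same offset
  mir <- mirror_locus(toy)
  expect_equal(cds_position(mir$flip(161L), mir$tx), 31L)
  # round trip through cds_to_genomic
  for (cp in c(1L, 15L, 31L, 59L)) {
    expect_equal(cds_position(cds_to_genomic(cp, tx), tx), cp)
    expect_equal(cds_position(cds_to_genomic(cp, mir$tx), mir$tx), cp)
  }
})

test_that("C>T in a CGA codon 11 is a nonsense p.R11* with c.31C>T", {
  set.seed(102)
  toy <- toy_two_exon(n_res = 20, codon11 = "CGA")
  v <- list(chrom = "chrT", pos = 161L, ref = "C", alt = "T", id = "v1")
  cq <- annotate_consequence(v, toy$tx)
  expect_equal(cq$effect_class, "nonsense")
  expect_equal(cq$cdna_notation, "c.31C>T")
  expect_equal(cq$protein_notation, "p.R11*")
  expect_equal(cq$codon_index, 11L)
  # identical call on the mirrored minus-strand locus
  mir <- mirror_locus(toy)
  vm <- list(chrom = "chrT", pos = mir$flip(161L), ref = "G", alt = "A",
             id = "v1m")
  cqm <- annotate_consequence(vm, mir$tx)
  expect_equal(cqm[c("effect_class", "cdna_notation", "protein_notation",
                     "codon_index")],
               cq[c("effect_class", "cdna_notation", "protein_notation",
                    "codon_index")])
})

test_that("a 1-bp deletion in an alanine codon 78 is a frameshift p.A78fs", {
  set.seed(103)
  cds <- toy_cds(100)
  substr(cds, 232, 234) <- "GCC"          # codon 78 = Ala; CDS 233 is C
  utr5 <- rohfunnel:::random_dna(10)
  contig <- paste0(rohfunnel:::random_dna(100), utr5, cds,
                   rohfunnel:::random_dna(100))
  tx <- transcript_model("TOYD", "chrT", "+",
                         data.frame(start = 101L, end = 110L + nchar(cds)),
                         cds_start = 111L, cds_end = 110L + nchar(cds),
                         cds_sequence = cds)
  # VCF-anchored deletion removing CDS base 233 (genomic 111+232)
  gpos <- 111L + 231L                      # CDS base 232
  ref2 <- substr(cds, 232, 233)
  v <- list(chrom = "chrT", pos = gpos, ref = ref2, alt = substr(cds, 232, 232),
            id = "d1")
  cq <- annotate_consequence(v, tx)
  expect_equal(cq$effect_class, "frameshift")
  expect_equal(cq$cdna_notation, "c.233delC")
  expect_equal(cq$protein_notation, "p.A78fs")
  # a 3-bp deletion at the same spot is in-frame
  v3 <- list(chrom = "chrT", pos = gpos, ref = substr(cds, 232, 235),
             alt = substr(cds, 232, 232), id = "d3")
  expect_equal(annotate_consequence(v3, tx)$effect_class, "inframe_indel")
})

test_that("third-position change in a four-fold degenerate codon is synonymous", {
  set.seed(104)
  cds <- toy_cds(30)
  substr(cds, 31, 33) <- "GGA"            # Gly, four-fold degenerate
  toy <- toy_two_exon(n_res = 30)
  tx <- toy$tx
  tx$cds_sequence <- cds                  # keep layout, swap sequence
  # CDS base 33 = third base of codon 11, genomic 163 (exon 2)
  v <- list(chrom = "chrT", pos = 163L, ref = "A", alt = "G", id = "s1")
  cq <- annotate_consequence(v, tx)
  expect_equal(cq$effect_class, "synonymous")
  expect_equal(cq$codon_index, 11L)
  expect_equal(cq$protein_notation, "p.G11G")
})

test_that("reference mismatch raises an error naming both alleles", {
  set.seed(105)
  toy <- toy_two_exon(n_res = 20, codon11 = "CGA")
  v <- list(chrom = "chrT", pos = 161L, ref = "A", alt = "T", id = "x")
  expect_error(annotate_consequence(v, toy$tx), "reference mismatch")
})

test_that("non-coding positions classify as intronic/non_coding/intergenic", {
  set.seed(106)
  toy <- toy_two_exon(n_res = 20)
  ann <- function(pos) annotate_consequence(
    list(chrom = "chrT", pos = pos, ref = "A", alt = "C", id = "n"), toy$tx)
  expect_equal(ann(150L)$effect_class, "intronic")   # inside the intron
  expect_equal(ann(105L)$effect_class, "non_coding") # 5' UTR
  expect_equal(ann(10L)$effect_class, "intergenic")
  expect_true(is.na(ann(150L)$protein_notation))
})

test_that("multi-allelic decomposition and left-normalization are deterministic", {
  v <- data.frame(chrom = "chr1", pos = 100L, id = "m", ref = "C",
                  alt = "T,G")
  d <- decompose_biallelic(v)
  expect_equal(nrow(d), 2)
  expect_equal(d$alt, c("T", "G"))
  expect_equal(d$id, c("m_1", "m_2"))
  n <- normalize_allele(100L, "CAG", "CTG")  # shared prefix and suffix
  expect_equal(n, list(pos = 101L, ref = "A", alt = "T"))
  n2 <- normalize_allele(100L, "ATT", "AT")  # anchored deletion
  expect_equal(n2, list(pos = 100L, ref = "AT", alt = "A"))
})

test_that("SNV classification agrees with the full-translation oracle (1000+ random pairs)", {
  set.seed(2025)
  n_checked <- 0
  while (n_checked < 1000) {
    toy <- toy_two_exon(n_res = sample(15:80, 1))
    use <- if (runif(1) < 0.5) list(tx = toy$tx, genome = toy$genome, flip = identity)
           else { m <- mirror_locus(toy); list(tx = m$tx, genome = m$genome, flip = m$flip) }
    tx <- use$tx
    L <- nchar(tx$cds_sequence)
    for (k in 1:25) {
      cp <- sample.int(L, 1)
      ref_c <- substr(tx$cds_sequence, cp, cp)
      alt_c <- sample(setdiff(c("A", "C", "G", "T"), ref_c), 1)
      gpos <- cds_to_genomic(cp, tx)
      ref_g <- ref_c; alt_g <- alt_c
      if (tx$strand == "-") {
        ref_g <- rohfunnel:::revcomp_chr(ref_g)
        alt_g <- rohfunnel:::revcomp_chr(alt_g)
      }
      cq <- annotate_consequence(list(chrom = tx$chrom, pos = gpos,
                                      ref = ref_g, alt = alt_g, id = "p"), tx)
      expected <- oracle_classify_snv(tx$cds_sequence, cp, alt_c)
      # the codon-level classifier and the whole-CDS translation oracle
      # agree except for stop-loss, which the oracle can only see as a
      # changed residue; both call it missense here by construction
      expect_equal(cq$effect_class, expected,
                   info = sprintf("cds_pos %d %s>%s", cp, ref_c, alt_c))
      expect_equal(cq$codon_index, as.integer(ceiling(cp / 3)))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 1000)
})

test_that("truncation statistics count retained residues before the stop", {
  set.seed(107)
  toy <- toy_two_exon(n_res = 1121, codon11 = "CGA")
  v <- list(chrom = "chrT", pos = 161L, ref = "C", alt = "T", id = "t")
  cq <- annotate_consequence(v, toy$tx)
  st <- truncation_stats(cq, toy$tx)
  expect_equal(st$retained_residues, 10L)
  expect_equal(st$full_length_residues, 1121L)
  expect_equal(st$retained_fraction, 10 / 1121)
  # immediate stop: codon 1 retains nothing
  cq1 <- structure(list(transcript = toy$tx$id, effect_class = "nonsense",
                        cdna_notation = "c.3G>A", protein_notation = "p.M1*",
                        codon_index = 1L), class = "consequence")
  expect_equal(truncation_stats(cq1, toy$tx)$retained_residues, 0L)
  # non-nonsense input violates the contract
  cq$effect_class <- "missense"
  expect_error(truncation_stats(cq, toy$tx), "nonsense")
})

test_that("random nonsense hits retain exactly the oracle's translated length", {
  set.seed(108)
  found <- 0
  while (found < 20) {
    toy <- toy_two_exon(n_res = sample(30:120, 1))
    tx <- toy$tx
    L <- nchar(tx$cds_sequence)
    cp <- sample.int(L - 3, 1)             # avoid the terminator codon
    ref_c <- substr(tx$cds_sequence, cp, cp)
    for (alt_c in setdiff(c("A", "C", "G", "T"), ref_c)) {
      if (oracle_classify_snv(tx$cds_sequence, cp, alt_c) != "nonsense") next
      gpos <- cds_to_genomic(cp, tx)
      cq <- annotate_consequence(list(chrom = tx$chrom, pos = gpos,
                                      ref = ref_c, alt = alt_c, id = "n"), tx)
      st <- truncation_stats(cq, tx)
      expect_equal(st$retained_residues,
                   oracle_translated_length(tx$cds_sequence, cp, alt_c))
      found <- found + 1
      break
    }
  }
})

test_that("annotate_variants picks the most severe consequence per variant", {
  b <- cached_bundle(7)
  v <- b$cohort$variants
  truth <- b$truth
  ann <- annotate_variants(v[v$id %in% c(truth$causal_variant_id,
                                         truth$decoys$synonymous_in_roh,
                                         truth$decoys$nonexonic), ],
                           b$reference$transcripts)
  expect_equal(ann$effect_class[ann$id == truth$causal_variant_id], "nonsense")
  expect_true(all(ann$effect_class[ann$id %in% truth$decoys$synonymous_in_roh] ==
                    "synonymous"))
  expect_true(all(ann$effect_class[ann$id %in% truth$decoys$nonexonic] %in%
                    c("intergenic")))
  expect_equal(ann$cdna_notation[ann$id == truth$causal_variant_id], "c.31C>T")
  expect_equal(ann$protein_notation[ann$id == truth$causal_variant_id], "p.R11*")
})
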