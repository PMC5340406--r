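# Independent oracles and toy fixture builders. Oracles deliberately use
# different code paths (seqinr translation, explicit loops, quadrature)
# from the implementation they check.

# brute-force translation via seqinr; returns the residue string
# including "*" for stops
oracle_translate <- function(seq) {
  paste(seqinr::translate(seqinr::s2c(seq)), collapse = "")
}

# classify an SNV by translating the full reference and mutated CDS and
# comparing residue strings
oracle_classify_snv <- function(cds, cds_pos, alt_base) {
  mut <- cds
  substr(mut, cds_pos, cds_pos) <- alt_base
  aa_ref <- oracle_translate(cds)
  aa_alt <- oracle_translate(mut)
  if (aa_ref == aa_alt) return("synonymous")
  diff <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])[1]
  alt_res <- substr(aa_alt, diff, diff)
  ref_res <- substr(aa_ref, diff, diff)
  if (alt_res == "*" && ref_res != "*") "nonsense" else "missense"
}

# residues translated before the first stop of a mutated CDS
oracle_translated_length <- function(cds, cds_pos, alt_base) {
  mut <- cds
  substr(mut, cds_pos, cds_pos) <- alt_base
  aa <- seqinr::translate(seqinr::s2c(mut))
  stop_at <- which(aa == "*")[1]
  if (is.na(stop_at)) length(aa) else stop_at - 1L
}

# exhaustive sliding-window ROH caller: explicit loops over windows,
# markers and runs
oracle_detect_roh <- function(g, pos, params) {
  n <- length(g)
  w <- params$window_snps
  elig <- logical(n)
  if (n >= w) {
    nw <- n - w + 1
    hom_win <- logical(nw)
    for (s in seq_len(nw)) {
      win <- g[s:(s + w - 1)]
      hom_win[s] <- sum(win == 1, na.rm = TRUE) <= params$max_het_per_window &&
        sum(is.na(win)) <= params$max_missing_per_window
    }
    for (i in seq_len(n)) {
      starts <- max(1, i - w + 1):min(i, nw)
      elig[i] <- mean(hom_win[starts]) >= params$window_hit_threshold
    }
  }
  segs <- list()
  run <- integer()
  flush_run <- function(run, segs) {
    if (length(run) == 0) return(segs)
    span_kb <- (pos[run[length(run)]] - pos[run[1]]) / 1000
    if (length(run) >= params$min_segment_snps &&
        span_kb >= params$min_segment_kb &&
        span_kb / length(run) <= params$min_density_kb_per_snp)
      segs[[length(segs) + 1]] <- c(start = pos[run[1]],
                                    end = pos[run[length(run)]],
                                    n = length(run))
    segs
  }
  for (i in seq_len(n)) {
    if (!elig[i]) { segs <- flush_run(run, segs); run <- integer(); next }
    if (length(run) > 0 &&
        (pos[i] - pos[run[length(run)]]) > params$max_gap_kb * 1000) {
      segs <- flush_run(run, segs)
      run <- integer()
    }
    run <- c(run, i)
  }
  segs <- flush_run(run, segs)
  if (length(segs) == 0)
    return(data.frame(start = integer(), end = integer(), n = integer()))
  as.data.frame(do.call(rbind, segs))
}

# chi-square df=1 upper-tail probability by quadrature
oracle_chisq_tail <- function(chi) {
  stats::integrate(function(x) stats::dchisq(x, df = 1), chi, Inf,
                   rel.tol = 1e-13)$value
}

# random CDS of n_res residues (incl. start, excl. terminator)
toy_cds <- function(n_res, codon11 = NULL) {
  stops <- c("TAA", "TAG", "TGA")
  sense <- setdiff(names(Biostrings::GENETIC_CODE), stops)
  cds <- paste0("ATG", paste(sample(sense, n_res - 1, replace = TRUE),
                             collapse = ""),
                sample(stops, 1))
  if (!is.null(codon11)) substr(cds, 31, 33) <- codon11
  cds
}

# two-exon plus-strand toy locus with hand-computable coordinates:
# contig = 100 bp flank | exon1 (10 bp UTR5 + CDS 1..30) | 20 bp intron |
# exon2 (CDS 31..end + 10 bp UTR3) | 100 bp flank.
# CDS base 31 sits at genomic position 161.
toy_two_exon <- function(n_res = 20, codon11 = NULL) {
  cds <- toy_cds(n_res, codon11)
  L <- nchar(cds)
  utr5 <- rohfunnel:::random_dna(10)
  utr3 <- rohfunnel:::random_dna(10)
  intron <- rohfunnel:::random_dna(20)
  contig <- paste0(rohfunnel:::random_dna(100), utr5, substr(cds, 1, 30),
                   intron, substr(cds, 31, L), utr3,
                   rohfunnel:::random_dna(100))
  exons <- data.frame(start = c(101L, 161L),
                      end = c(140L, 160L + (L - 30L) + 10L))
  tx <- transcript_model("TOY1", "chrT", "+", exons,
                         cds_start = 111L, cds_end = 160L + (L - 30L),
                         cds_sequence = cds)
  genome <- Biostrings::DNAStringSet(c(chrT = contig))
  list(tx = tx, genome = genome, contig = contig)
}

# mirror a toy locus: reverse-complement the contig and re-express the
# transcript on the minus strand of the mirrored coordinates
mirror_locus <- function(toy) {
  n <- nchar(toy$contig)
  contig_rc <- rohfunnel:::revcomp_chr(toy$contig)
  flip <- function(x) n - x + 1L
  exons <- data.frame(start = flip(toy$tx$exons$end),
                      end = flip(toy$tx$exons$start))
  exons <- exons[order(exons$start), ]
  tx <- transcript_model(toy$tx$id, "chrT", "-", exons,
                         cds_start = flip(toy$tx$cds_end),
                         cds_end = flip(toy$tx$cds_start),
                         cds_sequence = toy$tx$cds_sequence)
  list(tx = tx, genome = Biostrings::DNAStringSet(c(chrT = contig_rc)),
       contig = contig_rc, flip = flip)
}

# small genotype-matrix builder: calls is markers x samples
toy_gm <- function(calls, pos = NULL, chrom = "chr1",
                   samples = paste0("s", seq_len(ncol(calls)))) {
  nm <- nrow(calls)
  if (is.null(pos)) pos <- seq_len(nm) * 1000L
  genotype_matrix(
    data.frame(chrom = chrom, pos = pos, id = paste0(chrom, "_", pos),
               allele_a = "A", allele_b = "G"),
    samples, calls)
}

# cache the default simulated bundle across test files (deterministic in
# the seed, so sharing is safe)
.bundle_cache <- new.env(parent = emptyenv())
cached_bundle <- function(seed = 7) {
  key <- paste0("s", seed)
  if (is.null(.bundle_cache[[key]]))
    .bundle_cache[[key]] <- simulate_cohort(sim_config(seed = seed))
  .bundle_cache[[key]]
}

# run the whole discovery pipeline on a bundle; returns funnel + regions
run_pipeline <- function(bundle, policy = filter_policy()) {
  gm <- qc_filter(bundle$array)
  cases <- paste0("case", seq_len(bundle$config$n_cases))
  segs <- lapply(setNames(cases, cases), function(s) detect_roh(gm, s))
  regions <- shared_regions(segs, gm)
  funnel <- run_funnel(bundle$cohort, bundle$reference$transcripts,
                       regions, policy)
  list(gm = gm, segments = segs, regions = regions, funnel = funnel)
}
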