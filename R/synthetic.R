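#' Simulation configuration for the synthetic cohort
#'
#' Defaults encode the study conditions the pipeline is exercised
#' under: a desk-scale genome (3 contigs x 10 Mb, 3,000 array markers
#' per contig) carrying realistic study-scale cohort counts — 7 affected cases, an
#' obligate-carrier parent and grandparent, 3 unaffected siblings, 176
#' screened population dogs of whom 3 carry the risk allele, and a
#' 136-animal cross-breed control panel that lacks it. A 2 Mb
#' homozygous-by-descent interval is planted on chr1 and the causal
#' nonsense variant (CDS position 31, C>T in a CGA arginine codon 11 of
#' a 1121-residue product) is placed inside it.
#'
#' @param n_contigs,contig_length_bp genome shape.
#' @param n_array_snps_per_contig array markers simulated per contig.
#' @param n_genes protein-coding genes across the genome.
#' @param planted_roh list `(contig, start_bp, end_bp)` of the planted
#'   autozygous interval.
#' @param causal_spec list `(gene_index, cds_pos, ref, alt)` of the
#'   planted causal substitution (coding-strand alleles).
#' @param n_cases affected, hom-alt cases.
#' @param relative_roles named character vector mapping relative sample
#'   ids to `"obligate_carrier"` or `"unaffected_sib"`.
#' @param n_population_controls screened population dogs.
#' @param n_population_carriers het carriers among them.
#' @param n_panel_controls filtering-panel animals (never carry the
#'   causal allele).
#' @param background_variant_rate per-bp rate of background variants.
#' @param n_decoys_per_class planted decoy variants per decoy class (see
#'   [simulate_variant_cohort()]).
#' @param genotyping_error_rate,missing_rate array noise probabilities
#'   per call.
#' @param seed master seed; per-component streams are derived from it by
#'   fixed offsets.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_contigs = 3,
                       contig_length_bp = 10e6,
                       n_array_snps_per_contig = 3000,
                       n_genes = 9,
                       planted_roh = list(contig = "chr1", start_bp = 4e6,
                                          end_bp = 6e6),
                       causal_spec = list(gene_index = 2, cds_pos = 31,
                                          ref = "C", alt = "T"),
                       n_cases = 7,
                       relative_roles = c(parent = "obligate_carrier",
                                          grandparent = "obligate_carrier",
                                          sib1 = "unaffected_sib",
                                          sib2 = "unaffected_sib",
                                          sib3 = "unaffected_sib"),
                       n_population_controls = 176,
                       n_population_carriers = 3,
                       n_panel_controls = 136,
                       background_variant_rate = 1e-5,
                       n_decoys_per_class = 3,
                       genotyping_error_rate = 0.001,
                       missing_rate = 0.02,
                       seed = 1) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  stopifnot(cfg$n_contigs >= 1, cfg$contig_length_bp >= 1000,
            cfg$n_array_snps_per_contig >= 1,
            cfg$n_genes >= 0, cfg$n_cases >= 1,
            cfg$n_population_controls >= 1, cfg$n_panel_controls >= 0,
            cfg$n_population_carriers >= 0,
            cfg$n_population_carriers <= cfg$n_population_controls,
            cfg$background_variant_rate >= 0,
            cfg$genotyping_error_rate >= 0, cfg$genotyping_error_rate <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate <= 1)
  contig_i <- match(cfg$planted_roh$contig, paste0("chr", seq_len(cfg$n_contigs)))
  if (is.na(contig_i))
    stop("planted_roh contig not in genome")
  if (cfg$planted_roh$start_bp < 1 ||
      cfg$planted_roh$end_bp > cfg$contig_length_bp ||
      cfg$planted_roh$start_bp >= cfg$planted_roh$end_bp)
    stop("planted_roh must lie within its contig")
  if (cfg$n_genes > 0 &&
      (cfg$causal_spec$gene_index < 1 || cfg$causal_spec$gene_index > cfg$n_genes))
    stop("causal gene index outside gene list")
  if (!all(cfg$relative_roles %in% c("obligate_carrier", "unaffected_sib")))
    stop("relative roles must be obligate_carrier or unaffected_sib")
  cfg
}

.stop_codons <- c("TAA", "TAG", "TGA")
.sense_codons <- setdiff(names(Biostrings::GENETIC_CODE), .stop_codons)

# random CDS of n_res residues (excluding the terminator): ATG + sense
# codons + stop
random_cds <- function(n_res) {
  paste0("ATG",
         paste(sample(setdiff(.sense_codons, "ATG"), n_res - 1, replace = TRUE),
               collapse = ""),
         sample(.stop_codons, 1))
}

#' Build the synthetic reference: contigs plus transcript models
#'
#' Generates uniform-random contig sequences and plants protein-coding
#' genes at fixed relative positions, round-robin over contigs. The
#' designated causal-gene transcript gets a 1121-residue CDS with codon
#' 11 = CGA split over two exons so that CDS position 31 opens exon 2;
#' every third gene slot is placed on the minus strand. Gene sequences
#' (exons, introns, UTRs) are written into the contigs so that splicing
#' the CDS back out of the genome reproduces each model's
#' `cds_sequence`.
#'
#' @param config a [sim_config()].
#' @return object of class `reference_bundle`: list with `genome`
#'   (named `DNAStringSet`), `transcripts` (list of
#'   [transcript_model()]), `config`.
#' @export
build_reference <- function(config = sim_config()) {
  set.seed(.component_seed(config$seed, "reference"))
  contigs <- lapply(seq_len(config$n_contigs), function(i)
    random_dna(config$contig_length_bp))
  names(contigs) <- paste0("chr", seq_len(config$n_contigs))
  transcripts <- list()
  if (config$n_genes > 0) {
    per_contig <- ceiling(config$n_genes / config$n_contigs)
    slot_frac <- if (per_contig == 1) 0.5
                 else seq(0.15, 0.85, length.out = per_contig)
    last_end <- numeric(config$n_contigs)
    for (gi in seq_len(config$n_genes)) {
      ci <- (gi - 1) %/% per_contig + 1
      slot <- (gi - 1) %% per_contig + 1
      chrom <- paste0("chr", ci)
      g0 <- as.integer(round(slot_frac[slot] * config$contig_length_bp))
      designated <- gi == config$causal_spec$gene_index
      strand <- if (!designated && slot %% 3 == 0) "-" else "+"
      built <- .build_gene(gi, chrom, g0, strand, designated, config)
      if (g0 + built$length - 1 > config$contig_length_bp ||
          g0 <= last_end[ci])
        stop("sizing error: contig ", chrom, " too short for requested genes")
      last_end[ci] <- g0 + built$length - 1
      substr(contigs[[chrom]], g0, g0 + built$length - 1) <- built$placed_seq
      transcripts[[length(transcripts) + 1]] <- built$tx
    }
  }
  genome <- Biostrings::DNAStringSet(unlist(contigs))
  for (tx in transcripts) {
    if (splice_cds(tx, genome) != tx$cds_sequence)
      stop("internal error: spliced CDS disagrees with model for ", tx$id)
    validate_transcript(tx)
  }
  structure(list(genome = genome, transcripts = transcripts, config = config),
            class = "reference_bundle")
}

# Construct one gene: transcript-forward layout (exon/intron/UTR), then
# map to genomic coordinates at anchor g0 with the requested strand.
.build_gene <- function(gi, chrom, g0, strand, designated, config) {
  if (designated) {
    n_res <- 1121
    cds <- random_cds(n_res)
    stopifnot(nchar(cds) == 3 * n_res + 3)
    substr(cds, 31, 33) <- "CGA"             # codon 11, CDS position 31 = C
    chunks <- c(30L, nchar(cds) - 30L)       # position 31 opens exon 2
  } else {
    n_res <- sample(100:400, 1)
    cds <- random_cds(n_res)
    n_ex <- sample(1:3, 1)
    if (n_ex == 1) chunks <- nchar(cds)
    else {
      cuts <- sort(sample(seq(3, nchar(cds) - 3, by = 3), n_ex - 1))
      chunks <- diff(c(0L, cuts, nchar(cds)))
    }
  }
  utr5 <- sample(60:150, 1)
  utr3 <- sample(100:250, 1)
  n_ex <- length(chunks)
  introns <- if (n_ex > 1) sample(200:1500, n_ex - 1, replace = TRUE) else integer()
  # exon widths in transcript-forward order
  ex_w <- chunks
  ex_w[1] <- ex_w[1] + utr5
  ex_w[n_ex] <- ex_w[n_ex] + utr3
  # forward (unspliced) coordinates
  starts <- integer(n_ex); ends <- integer(n_ex)
  cursor <- 1L
  for (k in seq_len(n_ex)) {
    starts[k] <- cursor
    ends[k] <- cursor + ex_w[k] - 1L
    cursor <- ends[k] + 1L + if (k < n_ex) introns[k] else 0L
  }
  L <- ends[n_ex]
  # forward unspliced gene sequence
  spl_chunks <- character(0)
  cds_cursor <- 1L
  for (k in seq_len(n_ex)) {
    body <- substr(cds, cds_cursor, cds_cursor + chunks[k] - 1L)
    cds_cursor <- cds_cursor + chunks[k]
    piece <- body
    if (k == 1) piece <- paste0(random_dna(utr5), piece)
    if (k == n_ex) piece <- paste0(piece, random_dna(utr3))
    spl_chunks <- c(spl_chunks, piece)
    if (k < n_ex) spl_chunks <- c(spl_chunks, random_dna(introns[k]))
  }
  fwd <- paste(spl_chunks, collapse = "")
  stopifnot(nchar(fwd) == L)
  cds_f_start <- utr5 + 1L
  cds_f_end <- L - utr3
  if (strand == "+") {
    placed <- fwd
    exons <- data.frame(start = g0 + starts - 1L, end = g0 + ends - 1L)
    cds_start <- g0 + cds_f_start - 1L
    cds_end <- g0 + cds_f_end - 1L
  } else {
    placed <- revcomp_chr(fwd)
    exons <- data.frame(start = g0 + L - ends, end = g0 + L - starts)
    exons <- exons[order(exons$start), ]
    cds_start <- g0 + L - cds_f_end
    cds_end <- g0 + L - cds_f_start
  }
  tx <- transcript_model(id = sprintf("TX%04d", gi),
                         gene = if (designated) "ANLN_like" else sprintf("GENE%04d", gi),
                         chrom = chrom, strand = strand, exons = exons,
                         cds_start = cds_start, cds_end = cds_end,
                         cds_sequence = cds, validate = FALSE)
  list(tx = tx, placed_seq = placed, length = L)
}

new_sim_truth <- function() {
  structure(list(causal_variant_id = NA_character_,
                 planted_roh_intervals_per_case = list(),
                 sample_roles = character(),
                 decoys = list(),
                 warnings = character(),
                 notes = character()),
            class = "sim_truth")
}

#' Simulate SNP-array genotypes with a planted autozygous interval
#'
#' Markers get uniform-random positions, lexicographically ordered
#' allele pairs and B-allele frequencies drawn from U(0.05, 0.5);
#' genotypes follow Hardy-Weinberg. Inside the planted interval, cases
#' and obligate carriers are set homozygous for one shared haplotype.
#' Genotyping errors (call replaced by a different random code) and
#' missingness are then applied at the configured rates.
#'
#' @param reference a [build_reference()] bundle, or `NULL`: marker
#'   simulation only depends on the genome geometry carried by `config`.
#' @param config the [sim_config()] (defaults to the bundle's own).
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (a `sim_truth`).
#' @export
simulate_array_genotypes <- function(reference = NULL, config = reference$config) {
  set.seed(.component_seed(config$seed, "array"))
  samples <- c(paste0("case", seq_len(config$n_cases)),
               names(config$relative_roles))
  roles <- c(rep("case", config$n_cases), unname(config$relative_roles))
  names(roles) <- samples
  pair_pool <- list(c("A", "C"), c("A", "G"), c("A", "T"),
                    c("C", "G"), c("C", "T"), c("G", "T"))
  mk <- list()
  for (ci in seq_len(config$n_contigs)) {
    pos <- sort(sample.int(config$contig_length_bp,
                           config$n_array_snps_per_contig))
    mk[[ci]] <- data.frame(chrom = paste0("chr", ci), pos = pos,
                           id = paste0("chr", ci, "_", pos))
  }
  markers <- do.call(rbind, mk)
  nm <- nrow(markers)
  ns <- length(samples)
  pairs <- pair_pool[sample.int(6, nm, replace = TRUE)]
  markers$allele_a <- vapply(pairs, `[`, character(1), 1)
  markers$allele_b <- vapply(pairs, `[`, character(1), 2)
  p_b <- runif(nm, 0.05, 0.5)
  calls <- matrix(rbinom(nm * ns, 2L, rep(p_b, times = ns)), nrow = nm)
  # planted shared haplotype: cases and obligate carriers homozygous
  roh <- config$planted_roh
  in_roh <- which(markers$chrom == roh$contig & markers$pos >= roh$start_bp &
                  markers$pos <= roh$end_bp)
  hom_samples <- which(roles %in% c("case", "obligate_carrier"))
  hap <- rbinom(length(in_roh), 1L, p_b[in_roh])
  calls[in_roh, hom_samples] <- rep(2L * hap, times = length(hom_samples))
  # noise
  if (config$genotyping_error_rate > 0) {
    err <- which(matrix(runif(nm * ns) < config$genotyping_error_rate, nm, ns))
    if (length(err)) {
      cur <- calls[err]
      shift <- sample.int(2L, length(err), replace = TRUE)
      calls[err] <- (cur + shift) %% 3L
    }
  }
  if (config$missing_rate > 0)
    calls[matrix(runif(nm * ns) < config$missing_rate, nm, ns)] <- NA_integer_
  gm <- genotype_matrix(markers, samples, calls)
  truth <- new_sim_truth()
  truth$sample_roles <- roles
  truth$planted_roh_intervals_per_case <- setNames(
    rep(list(roh), config$n_cases), paste0("case", seq_len(config$n_cases)))
  if (length(in_roh) < 100)
    truth$warnings <- c(truth$warnings, sprintf(
      "planted interval holds %d markers, below the default detector minimum of 100",
      length(in_roh)))
  list(genotypes = gm, truth = truth)
}

# search the transcript CDS for an SNV of the wanted class, avoiding
# given cds positions; returns genomic-strand record or NULL
.find_snv_of_class <- function(tx, wanted, avoid_cds = integer()) {
  n_cod <- nchar(tx$cds_sequence) / 3 - 1       # skip terminator codon
  for (ci in sample(2:n_cod)) {                 # skip the start codon too
    codon <- substr(tx$cds_sequence, (ci - 1) * 3 + 1, ci * 3)
    for (off in sample(1:3)) {
      cp <- (ci - 1L) * 3L + off
      if (cp %in% avoid_cds) next
      ref_c <- substr(codon, off, off)
      for (alt_c in sample(setdiff(c("A", "C", "G", "T"), ref_c))) {
        alt_codon <- codon
        substr(alt_codon, off, off) <- alt_c
        ref_aa <- aa1(codon); alt_aa <- aa1(alt_codon)
        klass <- if (alt_aa == "*" && ref_aa != "*") "nonsense"
                 else if (alt_aa == ref_aa) "synonymous" else "missense"
        if (klass != wanted) next
        gpos <- cds_to_genomic(cp, tx)
        ref_g <- ref_c; alt_g <- alt_c
        if (tx$strand == "-") { ref_g <- revcomp_chr(ref_g); alt_g <- revcomp_chr(alt_g) }
        return(list(chrom = tx$chrom, pos = gpos, ref = ref_g, alt = alt_g,
                    cds_pos = cp))
      }
    }
  }
  NULL
}

#' Simulate the cohort and control-panel variant calls
#'
#' Plants the causal nonsense variant (hom-alt in every case, het in the
#' obligate carriers, het in `n_population_carriers` population dogs,
#' absent from the panel) plus decoy variants of four classes —
#' `nonexonic` (case-specific, intergenic), `exonic_outside_roh`
#' (case-specific missense outside the planted interval),
#' `synonymous_in_roh` (case-specific, in the causal gene, silent, with
#' a segregation-violating obligate carrier) and `panel_carried_in_roh`
#' (protein-changing in the causal gene, segregation-violating, and
#' carried het by panel animals so that only the relaxed panel policy
#' admits it) — and Hardy-Weinberg background variants across all
#' samples.
#'
#' @param reference a [build_reference()] bundle.
#' @param config the [sim_config()] (defaults to the bundle's own).
#' @return list with `cohort` (a [cohort_genotypes()]), `sample_sheet`
#'   (data.frame) and `truth` (a `sim_truth`).
#' @export
simulate_variant_cohort <- function(reference, config = reference$config) {
  set.seed(.component_seed(config$seed, "variants"))
  if (config$n_genes == 0) stop("variant simulation requires gene models")
  txs <- reference$transcripts
  causal_tx <- txs[[config$causal_spec$gene_index]]
  cases <- paste0("case", seq_len(config$n_cases))
  relatives <- names(config$relative_roles)
  pop <- sprintf("pop%03d", seq_len(config$n_population_controls))
  panel <- sprintf("panel%03d", seq_len(config$n_panel_controls))
  samples <- data.frame(
    id = c(cases, relatives, pop, panel),
    role = c(rep("case", length(cases)), rep("control", length(relatives)),
             rep("control", length(pop)), rep("panel", length(panel))))
  ns <- nrow(samples)
  obligate <- relatives[config$relative_roles == "obligate_carrier"]
  sibs <- relatives[config$relative_roles == "unaffected_sib"]

  used <- new.env()
  used$pos <- character()
  claim <- function(chrom, pos) {
    key <- paste0(chrom, ":", pos)
    if (key %in% used$pos) return(FALSE)
    used$pos <- c(used$pos, key)
    TRUE
  }
  gt_row <- function(spec) {
    g <- integer(ns); names(g) <- samples$id
    for (nm in names(spec)) g[nm] <- spec[[nm]]
    g
  }
  rows <- list(); calls <- list(); classes <- list()
  add_variant <- function(chrom, pos, ref, alt, g, class) {
    rows[[length(rows) + 1]] <<- data.frame(chrom = chrom, pos = as.integer(pos),
                                            id = paste0("v_", chrom, "_", pos),
                                            ref = ref, alt = alt)
    calls[[length(calls) + 1]] <<- g
    classes[[length(classes) + 1]] <<- class
  }

  # --- causal variant
  cs <- config$causal_spec
  cpos <- cds_to_genomic(cs$cds_pos, causal_tx)
  ref_g <- cs$ref; alt_g <- cs$alt
  if (causal_tx$strand == "-") { ref_g <- revcomp_chr(ref_g); alt_g <- revcomp_chr(alt_g) }
  stopifnot(claim(causal_tx$chrom, cpos))
  carriers <- sample(pop, config$n_population_carriers)
  g <- gt_row(c(setNames(rep(2L, length(cases)), cases),
                setNames(rep(1L, length(obligate)), obligate)))
  if (length(sibs)) {
    g[sibs] <- 0L
    g[sibs[1]] <- 1L                    # one het sibling, two wild-type
  }
  g[carriers] <- 1L
  add_variant(causal_tx$chrom, cpos, ref_g, alt_g, g, "causal")

  # --- decoys
  avoid <- cs$cds_pos + c(-2:2)         # keep clear of the causal codon
  case_specific_gt <- function(violating = c("none", "parent_hom", "sib_hom")) {
    violating <- match.arg(violating)
    g <- gt_row(c(setNames(rep(2L, length(cases)), cases),
                  setNames(rep(1L, length(obligate)), obligate)))
    if (violating == "parent_hom" && length(obligate)) g[obligate[1]] <- 2L
    if (violating == "sib_hom" && length(sibs)) g[sibs[1]] <- 2L
    g
  }
  outside_txs <- Filter(function(tx) {
    !(tx$chrom == config$planted_roh$contig &&
      min(tx$exons$start) <= config$planted_roh$end_bp &&
      max(tx$exons$end) >= config$planted_roh$start_bp)
  }, txs)
  for (k in seq_len(config$n_decoys_per_class)) {
    # (a) case-specific, non-exonic
    repeat {
      ci <- sample.int(config$n_contigs, 1)
      pos <- sample.int(config$contig_length_bp, 1)
      chrom <- paste0("chr", ci)
      in_gene <- any(vapply(txs, function(tx)
        tx$chrom == chrom && pos >= min(tx$exons$start) && pos <= max(tx$exons$end),
        logical(1)))
      if (!in_gene && claim(chrom, pos)) break
    }
    ref <- as.character(Biostrings::subseq(reference$genome[[chrom]], pos, pos))
    add_variant(chrom, pos, ref, sample(setdiff(c("A", "C", "G", "T"), ref), 1),
                case_specific_gt("none"), "nonexonic")
    # (b) case-specific missense outside the planted interval
    if (length(outside_txs)) {
      repeat {
        tx <- outside_txs[[sample.int(length(outside_txs), 1)]]
        snv <- .find_snv_of_class(tx, "missense")
        if (!is.null(snv) && claim(snv$chrom, snv$pos)) break
      }
      add_variant(snv$chrom, snv$pos, snv$ref, snv$alt,
                  case_specific_gt("none"), "exonic_outside_roh")
    }
    # (c) case-specific synonymous inside the causal gene, parent violates
    repeat {
      snv <- .find_snv_of_class(causal_tx, "synonymous", avoid_cds = avoid)
      if (claim(snv$chrom, snv$pos)) break
    }
    avoid <- c(avoid, snv$cds_pos)
    add_variant(snv$chrom, snv$pos, snv$ref, snv$alt,
                case_specific_gt("parent_hom"), "synonymous_in_roh")
    # (d) protein-changing in the causal gene, panel-carried, sib violates
    repeat {
      snv <- .find_snv_of_class(causal_tx, "missense", avoid_cds = avoid)
      if (claim(snv$chrom, snv$pos)) break
    }
    avoid <- c(avoid, snv$cds_pos)
    g <- case_specific_gt("sib_hom")
    if (length(panel) >= 2) g[sample(panel, 2)] <- 1L
    add_variant(snv$chrom, snv$pos, snv$ref, snv$alt, g, "panel_carried_in_roh")
  }

  # --- Hardy-Weinberg background variants across all samples
  n_bg <- stats::rpois(1, config$background_variant_rate *
                          config$n_contigs * config$contig_length_bp)
  n_redraws <- 0L
  for (k in seq_len(n_bg)) {
    repeat {
      ci <- sample.int(config$n_contigs, 1)
      pos <- sample.int(config$contig_length_bp, 1)
      chrom <- paste0("chr", ci)
      if (claim(chrom, pos)) break
      n_redraws <- n_redraws + 1L
    }
    ref <- as.character(Biostrings::subseq(reference$genome[[chrom]], pos, pos))
    q <- runif(1, 0.01, 0.3)
    add_variant(chrom, pos, ref, sample(setdiff(c("A", "C", "G", "T"), ref), 1),
                setNames(rbinom(ns, 2L, q), samples$id), "background")
  }

  variants <- do.call(rbind, rows)
  call_mat <- do.call(rbind, calls)
  class_v <- unlist(classes)
  ord <- order(match(variants$chrom, paste0("chr", seq_len(config$n_contigs))),
               variants$pos)
  variants <- variants[ord, , drop = FALSE]
  call_mat <- call_mat[ord, , drop = FALSE]
  class_v <- class_v[ord]
  rownames(variants) <- NULL
  cohort <- cohort_genotypes(variants, samples, call_mat)

  truth <- new_sim_truth()
  if (n_redraws > 0)
    truth$notes <- sprintf("%d background position(s) collided with planted variants and were re-drawn",
                           n_redraws)
  truth$causal_variant_id <- variants$id[class_v == "causal"]
  truth$decoys <- split(variants$id[!class_v %in% c("causal", "background")],
                        class_v[!class_v %in% c("causal", "background")])
  truth$sample_roles <- setNames(
    c(rep("case", length(cases)), unname(config$relative_roles),
      rep("population", length(pop)), rep("panel", length(panel))),
    c(cases, relatives, pop, panel))
  sheet <- data.frame(
    sample = c(cases, relatives, pop),
    phenotype = c(rep("affected", length(cases)),
                  rep("unaffected", length(relatives) + length(pop))),
    relation = c(rep("case", length(cases)),
                 ifelse(relatives %in% obligate,
                        ifelse(relatives == "grandparent", "grandparent", "parent"),
                        "sibling"),
                 rep("population", length(pop))),
    obligate_carrier = c(rep(FALSE, length(cases)),
                         relatives %in% obligate,
                         rep(FALSE, length(pop))))
  list(cohort = cohort, sample_sheet = sheet, truth = truth)
}

#' Simulate a complete study bundle
#'
#' Runs [build_reference()], [simulate_array_genotypes()] and
#' [simulate_variant_cohort()] under one configuration and merges their
#' ground truth.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_bundle`: list with `reference`,
#'   `array`, `cohort`, `sample_sheet`, `truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  ref <- build_reference(config)
  arr <- simulate_array_genotypes(ref, config)
  coh <- simulate_variant_cohort(ref, config)
  truth <- coh$truth
  truth$planted_roh_intervals_per_case <- arr$truth$planted_roh_intervals_per_case
  truth$warnings <- c(arr$truth$warnings, coh$truth$warnings)
  structure(list(reference = ref, array = arr$genotypes, cohort = coh$cohort,
                 sample_sheet = coh$sample_sheet, truth = truth,
                 config = config),
            class = "sim_bundle")
}
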