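#' @importClassesFrom vcfR vcfR
NULL

#' Write cohort genotypes as VCF
#'
#' Emits a VCF v4.2 with GT-only FORMAT through vcfR (gzip-compressed;
#' use a `.vcf.gz` path).
#'
#' @param cohort a [cohort_genotypes()].
#' @param path output path (`.vcf.gz`).
#' @param sample_ids optional subset of samples to write.
#' @return invisibly, `path`.
#' @export
write_cohort_vcf <- function(cohort, path, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- cohort$samples$id
  j <- match(sample_ids, cohort$samples$id)
  if (anyNA(j)) stop("unknown sample id(s) requested")
  v <- cohort$variants
  meta <- c("##fileformat=VCFv4.2",
            paste0("##contig=<ID=", unique(v$chrom), ">"),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  fix <- cbind(CHROM = v$chrom, POS = as.character(v$pos), ID = v$id,
               REF = v$ref, ALT = v$alt, QUAL = ".", FILTER = "PASS",
               INFO = ".")
  gt_str <- matrix(c("0/0", "0/1", "1/1")[cohort$calls[, j, drop = FALSE] + 1L],
                   nrow = nrow(v))
  gt_str[is.na(gt_str)] <- "./."
  gt <- cbind(FORMAT = "GT", gt_str)
  colnames(gt) <- c("FORMAT", sample_ids)
  vcf <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Read a VCF into cohort genotypes
#'
#' @param path VCF (optionally gzipped) with GT genotypes.
#' @param roles optional named character vector mapping sample id to
#'   role (`case`/`control`/`panel`); unnamed samples default to
#'   `control`.
#' @return a [cohort_genotypes()].
#' @export
read_cohort_vcf <- function(path, roles = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         id = fix[, "ID"], ref = fix[, "REF"],
                         alt = fix[, "ALT"])
  gt <- vcfR::extract.gt(vcf, element = "GT")
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  norm <- gsub("|", "/", gt, fixed = TRUE)
  code[norm %in% c("0/0")] <- 0L
  code[norm %in% c("0/1", "1/0")] <- 1L
  code[norm %in% c("1/1")] <- 2L
  ids <- colnames(gt)
  role <- rep("control", length(ids))
  if (!is.null(roles)) {
    hit <- ids %in% names(roles)
    role[hit] <- unname(roles[ids[hit]])
  }
  cohort_genotypes(variants, data.frame(id = ids, role = role), code)
}

#' Write an annotated variant table as VCF and TSV
#'
#' The VCF carries INFO keys `EFFECT`, `CDNA` and `PROT`; the TSV
#' mirrors the summary-table layout (chromosome, position, alleles,
#' gene, transcript notation, protein notation, effect).
#'
#' @param variants variant table (`chrom`, `pos`, `id`, `ref`, `alt`).
#' @param consequences [annotate_variants()] output for those variants.
#' @param vcf_path,tsv_path output paths (`NULL` to skip either).
#' @return invisibly, the written paths.
#' @export
write_annotated_variants <- function(variants, consequences,
                                     vcf_path = NULL, tsv_path = NULL) {
  m <- match(variants$id, consequences$id)
  if (anyNA(m)) stop("missing consequences for some variants")
  cq <- consequences[m, , drop = FALSE]
  written <- character()
  if (!is.null(vcf_path)) {
    meta <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", unique(variants$chrom), ">"),
              "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Effect class\">",
              "##INFO=<ID=CDNA,Number=1,Type=String,Description=\"cDNA notation\">",
              "##INFO=<ID=PROT,Number=1,Type=String,Description=\"Protein notation\">")
    info <- sprintf("EFFECT=%s;CDNA=%s;PROT=%s", cq$effect_class,
                    ifelse(is.na(cq$cdna_notation), ".", cq$cdna_notation),
                    ifelse(is.na(cq$protein_notation), ".", cq$protein_notation))
    fix <- cbind(CHROM = variants$chrom, POS = as.character(variants$pos),
                 ID = variants$id, REF = variants$ref, ALT = variants$alt,
                 QUAL = ".", FILTER = "PASS", INFO = info)
    vcf <- methods::new("vcfR", meta = meta, fix = fix,
                        gt = matrix(character(), nrow = 0, ncol = 0))
    vcfR::write.vcf(vcf, file = vcf_path)
    written <- c(written, vcf_path)
  }
  if (!is.null(tsv_path)) {
    tab <- data.frame(chrom = variants$chrom, pos = variants$pos,
                      ref = variants$ref, alt = variants$alt,
                      transcript = cq$transcript,
                      variant_transcript = cq$cdna_notation,
                      variant_protein = cq$protein_notation,
                      effect = cq$effect_class)
    write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, tsv_path)
  }
  invisible(written)
}

#' Write per-sample ROH segments as TSV
#'
#' @param segments [detect_roh()] output (rows from several samples may
#'   be row-bound).
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_roh_tsv <- function(segments, path) {
  write.table(segments[, c("sample", "chrom", "start_bp", "end_bp",
                           "n_snps", "kb")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write shared regions as BED and TSV
#'
#' The BED is 0-based half-open; the TSV keeps 1-based inclusive
#' coordinates.
#'
#' @param regions [shared_regions()] output.
#' @param bed_path,tsv_path output paths (`NULL` to skip either).
#' @return invisibly, the written paths.
#' @export
write_regions <- function(regions, bed_path = NULL, tsv_path = NULL) {
  written <- character()
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = regions$chrom, start = regions$start_bp - 1L,
                      end = regions$end_bp)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    written <- c(written, bed_path)
  }
  if (!is.null(tsv_path)) {
    write.table(regions, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, tsv_path)
  }
  invisible(written)
}

#' Write a funnel report as TSV and JSON
#'
#' @param funnel a [run_funnel()] result.
#' @param tsv_path,json_path output paths (`NULL` to skip either).
#' @return invisibly, the written paths.
#' @export
write_funnel_report <- function(funnel, tsv_path = NULL, json_path = NULL) {
  written <- character()
  if (!is.null(tsv_path)) {
    write.table(funnel$stages, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, tsv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(stages = funnel$stages,
                              surviving_ids = funnel$surviving_ids),
                         json_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, json_path)
  }
  invisible(written)
}

#' Write a simulated bundle to disk as standard file formats
#'
#' Emits the reference FASTA, transcript GFF3, cohort and panel VCFs,
#' PLINK PED/MAP array genotypes, the sample sheet TSV, planted-truth
#' BED (0-based half-open) and JSON, plus a JSON manifest listing every
#' file with its record count.
#'
#' @param bundle a [simulate_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @return data.frame manifest (`file`, `records`).
#' @export
write_fixture <- function(bundle, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok) stop("cannot create output directory: ", out_dir)
  p <- function(f) file.path(out_dir, f)
  manifest <- list()
  note <- function(f, n) manifest[[length(manifest) + 1]] <<-
    data.frame(file = f, records = n)

  Biostrings::writeXStringSet(bundle$reference$genome, p("reference.fa"))
  note("reference.fa", length(bundle$reference$genome))
  write_transcripts_gff3(bundle$reference$transcripts, p("genes.gff3"))
  note("genes.gff3", length(bundle$reference$transcripts))
  nonpanel <- bundle$cohort$samples$id[bundle$cohort$samples$role != "panel"]
  panel <- bundle$cohort$samples$id[bundle$cohort$samples$role == "panel"]
  write_cohort_vcf(bundle$cohort, p("cohort.vcf.gz"), sample_ids = nonpanel)
  note("cohort.vcf.gz", nrow(bundle$cohort$variants))
  if (length(panel)) {
    write_cohort_vcf(bundle$cohort, p("panel.vcf.gz"), sample_ids = panel)
    note("panel.vcf.gz", nrow(bundle$cohort$variants))
  }
  write_plink(bundle$array, p("array"))
  note("array.ped", length(bundle$array$samples))
  note("array.map", nrow(bundle$array$markers))
  write.table(bundle$sample_sheet, p("samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("samples.tsv", nrow(bundle$sample_sheet))
  roh <- bundle$truth$planted_roh_intervals_per_case
  bed <- do.call(rbind, lapply(names(roh), function(cs)
    data.frame(chrom = roh[[cs]]$contig, start = roh[[cs]]$start_bp - 1L,
               end = roh[[cs]]$end_bp, name = cs)))
  write.table(bed, p("roh_truth.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  note("roh_truth.bed", nrow(bed))
  jsonlite::write_json(unclass(bundle$truth), p("truth.json"),
                       auto_unbox = TRUE, digits = NA)
  note("truth.json", 1L)
  manifest <- do.call(rbind, manifest)
  jsonlite::write_json(manifest, p("manifest.json"), digits = NA)
  manifest
}
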