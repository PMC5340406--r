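#' Cohort variant genotypes
#'
#' Variant-by-sample genotype calls for the filtering funnel. Calls are
#' alt-allele counts (`0` hom-ref, `1` het, `2` hom-alt, `NA` missing).
#' Sample roles are `case`, `control` (relatives and population dogs) or
#' `panel` (the cross-breed control panel the funnel filters against).
#'
#' @param variants data.frame with `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param samples data.frame with `id`, `role`.
#' @param calls integer matrix, variants x samples.
#' @return object of class `cohort_genotypes`.
#' @export
cohort_genotypes <- function(variants, samples, calls) {
  stopifnot(all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)),
            all(c("id", "role") %in% names(samples)))
  if (!all(samples$role %in% c("case", "control", "panel")))
    stop("sample roles must be case, control or panel")
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(variants) || ncol(calls) != nrow(samples))
    stop("calls matrix dimensions do not match variants x samples")
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  if (anyDuplicated(samples$id)) stop("sample ids must be unique")
  rownames(calls) <- variants$id
  colnames(calls) <- samples$id
  structure(list(variants = variants, samples = samples, calls = calls),
            class = "cohort_genotypes")
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat("cohort_genotypes:", nrow(x$variants), "variants x",
      nrow(x$samples), "samples (",
      paste(names(table(x$samples$role)), table(x$samples$role),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Recessive-model filtering policy
#'
#' @param require_case_hom_alt require every case to be homozygous for
#'   the alternate allele.
#' @param max_panel_hom_alt maximum panel samples allowed hom-alt.
#' @param max_panel_het maximum panel samples allowed het. The strict
#'   default (0) demands the alternate allele be fully absent from the
#'   panel; raising it gives the relaxed mode that tolerates carriers in
#'   the panel.
#' @param treat_missing_as how a missing case genotype is handled:
#'   `"exclude"` drops the variant (conservative default), `"ref"`
#'   counts it as hom-ref (also dropping it under the recessive
#'   requirement), `"hom_alt"` counts it as hom-alt (for degraded
#'   FFPE-style inputs).
#' @return list of class `filter_policy`.
#' @export
filter_policy <- function(require_case_hom_alt = TRUE,
                          max_panel_hom_alt = 0, max_panel_het = 0,
                          treat_missing_as = c("exclude", "ref", "hom_alt")) {
  treat_missing_as <- match.arg(treat_missing_as)
  stopifnot(max_panel_hom_alt >= 0, max_panel_het >= 0)
  structure(list(require_case_hom_alt = require_case_hom_alt,
                 max_panel_hom_alt = as.integer(max_panel_hom_alt),
                 max_panel_het = as.integer(max_panel_het),
                 treat_missing_as = treat_missing_as),
            class = "filter_policy")
}

#' Variants segregating under a recessive model, case-specific vs panel
#'
#' Keeps variants where every case is hom-alt (missing genotypes handled
#' per policy) and the panel carries the alternate allele within the
#' policy bounds. Missing panel genotypes are never counted as
#' violations.
#'
#' @param cohort a [cohort_genotypes()].
#' @param policy a [filter_policy()].
#' @return character vector of surviving variant ids.
#' @export
recessive_case_specific <- function(cohort, policy = filter_policy()) {
  case_j <- which(cohort$samples$role == "case")
  if (length(case_j) == 0) stop("cohort contains no case samples")
  panel_j <- which(cohort$samples$role == "panel")
  cc <- cohort$calls[, case_j, drop = FALSE]
  if (policy$treat_missing_as == "hom_alt") cc[is.na(cc)] <- 2L
  if (policy$treat_missing_as == "ref") cc[is.na(cc)] <- 0L
  case_ok <- if (policy$require_case_hom_alt)
    rowSums(cc == 2L, na.rm = TRUE) == length(case_j) & !apply(is.na(cc), 1, any)
  else rowSums(cc >= 1L, na.rm = TRUE) == length(case_j) & !apply(is.na(cc), 1, any)
  pc <- cohort$calls[, panel_j, drop = FALSE]
  panel_ok <- rowSums(pc == 2L, na.rm = TRUE) <= policy$max_panel_hom_alt &
              rowSums(pc == 1L, na.rm = TRUE) <= policy$max_panel_het
  cohort$variants$id[case_ok & panel_ok]
}

#' Restrict variant ids to those overlapping annotated exons
#'
#' A variant overlaps an exon when its reference footprint
#' (`pos .. pos + nchar(ref) - 1`) intersects any exon (CDS or UTR) of
#' any transcript; 1-based inclusive on both sides.
#'
#' @param ids variant ids to filter.
#' @param variants variant table (`chrom`, `pos`, `id`, `ref`, `alt`).
#' @param transcripts list of [transcript_model()] objects.
#' @return surviving ids, in input order.
#' @export
restrict_exonic <- function(ids, variants, transcripts) {
  if (length(ids) == 0 || length(transcripts) == 0) return(character())
  v <- variants[match(ids, variants$id), , drop = FALSE]
  vgr <- GenomicRanges::GRanges(v$chrom,
                                IRanges::IRanges(v$pos, v$pos + nchar(v$ref) - 1L))
  ex <- do.call(rbind, lapply(transcripts, function(tx)
    data.frame(chrom = tx$chrom, start = tx$exons$start, end = tx$exons$end)))
  egr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
  hits <- GenomicRanges::countOverlaps(vgr, egr) > 0
  ids[hits]
}

#' Restrict variant ids to shared homozygosity regions
#'
#' Keeps variants whose position satisfies
#' `start_bp <= pos <= end_bp` in some region on the same chromosome.
#'
#' @param ids variant ids to filter.
#' @param variants variant table.
#' @param regions data.frame with `chrom`, `start_bp`, `end_bp`
#'   (1-based inclusive), as from [shared_regions()].
#' @return surviving ids, in input order.
#' @export
restrict_to_regions <- function(ids, variants, regions) {
  if (length(ids) == 0 || nrow(regions) == 0) return(character())
  v <- variants[match(ids, variants$id), , drop = FALSE]
  keep <- vapply(seq_len(nrow(v)), function(i)
    any(regions$chrom == v$chrom[i] & regions$start_bp <= v$pos[i] &
        regions$end_bp >= v$pos[i]), logical(1))
  ids[keep]
}

#' Restrict variant ids to protein-changing consequence classes
#'
#' @param ids variant ids to filter; every id must appear in
#'   `consequences`.
#' @param consequences data.frame as from [annotate_variants()] (best
#'   consequence per variant).
#' @param keep effect classes to retain.
#' @return surviving ids, in input order.
#' @export
effect_class_filter <- function(ids, consequences,
                                keep = c("missense", "nonsense", "frameshift")) {
  if (length(ids) == 0) return(character())
  m <- match(ids, consequences$id)
  if (anyNA(m))
    stop("no consequence available for variant(s): ",
         paste(ids[is.na(m)], collapse = ", "))
  ids[consequences$effect_class[m] %in% keep]
}

#' Run the full recessive variant-filtering funnel
#'
#' Applies, in order: the recessive case-specific filter against the
#' control panel, the exonic restriction, the homozygosity-region
#' restriction, and the protein-changing effect-class restriction,
#' recording the surviving count and ids at every stage.
#'
#' @param cohort a [cohort_genotypes()].
#' @param transcripts list of [transcript_model()] objects.
#' @param regions shared homozygosity regions ([shared_regions()] output
#'   or any data.frame with `chrom`, `start_bp`, `end_bp`).
#' @param policy a [filter_policy()].
#' @param consequences optional precomputed [annotate_variants()] table;
#'   computed on the fly for the surviving ids when `NULL`.
#' @return object of class `filter_funnel`: list with `stages`
#'   (data.frame of `label`, `count`) and `surviving_ids` (list of id
#'   vectors per stage).
#' @export
run_funnel <- function(cohort, transcripts, regions,
                       policy = filter_policy(), consequences = NULL) {
  ids0 <- cohort$variants$id
  ids1 <- recessive_case_specific(cohort, policy)
  ids2 <- restrict_exonic(ids1, cohort$variants, transcripts)
  ids3 <- restrict_to_regions(ids2, cohort$variants, regions)
  if (is.null(consequences) && length(ids3) > 0) {
    v3 <- cohort$variants[match(ids3, cohort$variants$id), , drop = FALSE]
    consequences <- annotate_variants(v3, transcripts)
  }
  ids4 <- if (length(ids3) == 0) character()
          else effect_class_filter(ids3, consequences)
  labels <- c("Total number of variants",
              "Variants that segregate under recessive mode of inheritance",
              "Variants in the exonic regions",
              "Variants in the identified regions of homozygosity",
              "Non-synonymous, frameshift and nonsense variants in the regions of homozygosity")
  surv <- list(ids0, ids1, ids2, ids3, ids4)
  structure(list(stages = data.frame(label = labels,
                                     count = vapply(surv, length, integer(1))),
                 surviving_ids = setNames(surv, labels)),
            class = "filter_funnel")
}

#' @export
print.filter_funnel <- function(x, ...) {
  cat("Variant filtering funnel\n")
  for (i in seq_len(nrow(x$stages)))
    cat(sprintf("  %-85s %d\n", x$stages$label[i], x$stages$count[i]))
  invisible(x)
}

#' @export
as.data.frame.filter_funnel <- function(x, ...) x$stages
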