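#' @importFrom Biostrings GENETIC_CODE
NULL

.severity_order <- c("nonsense", "frameshift", "missense", "inframe_indel",
                     "synonymous", "non_coding", "intronic", "intergenic")

aa1 <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("invalid codon: ", codon)
  aa
}

#' Split multi-allelic variant records into biallelic ones
#'
#' ALT alleles separated by commas become one record each; ids get a
#' `_1`, `_2`, ... suffix when split.
#'
#' @param variants data.frame with `chrom`, `pos`, `id`, `ref`, `alt`.
#' @return data.frame of biallelic records.
#' @export
decompose_biallelic <- function(variants) {
  out <- lapply(seq_len(nrow(variants)), function(i) {
    alts <- strsplit(variants$alt[i], ",", fixed = TRUE)[[1]]
    v <- variants[rep(i, length(alts)), , drop = FALSE]
    v$alt <- alts
    if (length(alts) > 1) v$id <- paste0(v$id, "_", seq_along(alts))
    v
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Reduce a variant to its minimal left-aligned representation
#'
#' Trims the common suffix, then the common prefix, of ref/alt, adjusting
#' `pos`, so that notation is deterministic.
#'
#' @param pos,ref,alt the VCF-style record.
#' @return list with normalized `pos`, `ref`, `alt`.
#' @export
normalize_allele <- function(pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  # trim shared suffix
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  # trim shared prefix, keeping at least one base each
  while (nchar(ref) > 1 && nchar(alt) > 1 && substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref)); alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

new_consequence <- function(transcript, effect_class, cdna = NA_character_,
                            prot = NA_character_, codon_index = NA_integer_) {
  structure(list(transcript = transcript, effect_class = effect_class,
                 cdna_notation = cdna, protein_notation = prot,
                 codon_index = codon_index),
            class = "consequence")
}

#' @export
print.consequence <- function(x, ...) {
  cat(sprintf("consequence [%s] %s %s %s (codon %s)\n", x$transcript,
              x$effect_class, x$cdna_notation %||% "", x$protein_notation %||% "",
              x$codon_index))
  invisible(x)
}

.classify_noncoding <- function(variant, tx) {
  if (variant$chrom != tx$chrom) return("intergenic")
  span <- range(c(tx$exons$start, tx$exons$end))
  p0 <- variant$pos
  p1 <- variant$pos + nchar(variant$ref) - 1L
  if (p1 < span[1] || p0 > span[2]) return("intergenic")
  in_exon <- any(p1 >= tx$exons$start & p0 <= tx$exons$end)
  if (in_exon) "non_coding" else "intronic"
}

#' Annotate the coding consequence of a variant on one transcript
#'
#' SNVs are classified by mutating the affected codon and comparing the
#' translated residues (stop written `*`): alt codon stop gives
#' `nonsense`, identical residue `synonymous`, otherwise `missense`.
#' Indels are `frameshift` when the length change is not a codon
#' multiple, `inframe_indel` otherwise. Notation follows the simplified
#' single-letter HGVS dialect (`c.31C>T`, `p.R11*`, `c.233delC`,
#' `p.A78fs`). Variants spanning an exon boundary or a splice junction
#' are classified `non_coding` and carry no protein notation.
#'
#' @param variant list or one-row data.frame with `chrom`, `pos`, `ref`,
#'   `alt` (and optionally `id`). Multi-allelic records must be
#'   decomposed first ([decompose_biallelic()]); alleles are
#'   left-normalized internally.
#' @param tx a [transcript_model()].
#' @return a `consequence` object with fields `transcript`,
#'   `effect_class`, `cdna_notation`, `protein_notation`, `codon_index`.
#' @examples
#' # a CGA (Arg) codon 11 hit by C>T becomes TGA: p.R11*
#' @export
annotate_consequence <- function(variant, tx) {
  variant <- as.list(variant)
  norm <- normalize_allele(variant$pos, variant$ref, variant$alt)
  variant$pos <- norm$pos; variant$ref <- norm$ref; variant$alt <- norm$alt
  if (variant$ref == variant$alt) stop("ref and alt alleles are identical")
  nr <- nchar(variant$ref); na <- nchar(variant$alt)

  if (nr == 1 && na == 1) {
    cp <- cds_position(variant$pos, tx, chrom = variant$chrom)
    if (is.na(cp))
      return(new_consequence(tx$id, .classify_noncoding(variant, tx)))
    ref_c <- variant$ref; alt_c <- variant$alt
    if (tx$strand == "-") { ref_c <- revcomp_chr(ref_c); alt_c <- revcomp_chr(alt_c) }
    have <- substr(tx$cds_sequence, cp, cp)
    if (have != ref_c)
      stop(sprintf("reference mismatch at CDS position %d of %s: transcript has %s, variant ref is %s",
                   cp, tx$id, have, ref_c))
    ci <- as.integer(ceiling(cp / 3))
    codon <- substr(tx$cds_sequence, (ci - 1L) * 3L + 1L, ci * 3L)
    off <- cp - (ci - 1L) * 3L
    alt_codon <- codon
    substr(alt_codon, off, off) <- alt_c
    ref_aa <- aa1(codon); alt_aa <- aa1(alt_codon)
    klass <- if (alt_aa == "*" && ref_aa != "*") "nonsense"
             else if (alt_aa == ref_aa) "synonymous"
             else "missense"
    return(new_consequence(tx$id, klass,
                           cdna = sprintf("c.%d%s>%s", cp, ref_c, alt_c),
                           prot = sprintf("p.%s%d%s", ref_aa, ci, alt_aa),
                           codon_index = ci))
  }

  # indel (VCF anchored style: first base shared)
  if (nr > na) {                         # deletion
    del_start <- variant$pos + na        # first deleted genomic base
    del_end <- variant$pos + nr - 1L
    cps <- vapply(del_start:del_end, cds_position, integer(1), tx = tx,
                  chrom = variant$chrom)
    if (all(is.na(cps)))
      return(new_consequence(tx$id, .classify_noncoding(variant, tx)))
    if (anyNA(cps))                      # spans a splice/exon boundary
      return(new_consequence(tx$id, "non_coding"))
    cp <- min(cps)
    k <- nr - na
    del_seq <- substr(tx$cds_sequence, cp, cp + k - 1L)
    cdna <- if (k == 1) sprintf("c.%ddel%s", cp, del_seq)
            else sprintf("c.%d_%ddel", cp, cp + k - 1L)
  } else {                               # insertion
    cp_anchor <- cds_position(variant$pos, tx, chrom = variant$chrom)
    if (is.na(cp_anchor))
      return(new_consequence(tx$id, .classify_noncoding(variant, tx)))
    cp <- cp_anchor
    k <- na - nr
    ins <- substr(variant$alt, nr + 1L, na)
    if (tx$strand == "-") ins <- revcomp_chr(ins)
    cdna <- sprintf("c.%d_%dins%s", cp, cp + 1L, ins)
  }
  ci <- as.integer(ceiling(cp / 3))
  codon <- substr(tx$cds_sequence, (ci - 1L) * 3L + 1L, ci * 3L)
  ref_aa <- aa1(codon)
  if (k %% 3 != 0)
    new_consequence(tx$id, "frameshift", cdna = cdna,
                    prot = sprintf("p.%s%dfs", ref_aa, ci), codon_index = ci)
  else
    new_consequence(tx$id, "inframe_indel", cdna = cdna,
                    prot = sprintf("p.%s%d%s", ref_aa, ci,
                                   if (nr > na) "del" else "ins"),
                    codon_index = ci)
}

#' Annotate a variant table against a set of transcripts
#'
#' Each variant is annotated against every transcript on its chromosome;
#' the single most severe consequence (nonsense > frameshift > missense >
#' inframe_indel > synonymous > non_coding > intronic > intergenic) is
#' reported per variant.
#'
#' @param variants data.frame with `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param transcripts list of [transcript_model()] objects.
#' @return data.frame with one row per variant: `id`, `transcript`,
#'   `effect_class`, `cdna_notation`, `protein_notation`, `codon_index`.
#' @export
annotate_variants <- function(variants, transcripts) {
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    cons <- lapply(transcripts, function(tx) {
      if (tx$chrom != v$chrom) return(new_consequence(tx$id, "intergenic"))
      annotate_consequence(v, tx)
    })
    sev <- vapply(cons, function(cq) match(cq$effect_class, .severity_order),
                  integer(1))
    best <- cons[[which.min(sev)]]
    data.frame(id = v$id, transcript = best$transcript,
               effect_class = best$effect_class,
               cdna_notation = best$cdna_notation,
               protein_notation = best$protein_notation,
               codon_index = best$codon_index,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Truncation statistics for a nonsense consequence
#'
#' @param consequence a `consequence` with `effect_class == "nonsense"`.
#' @param tx the [transcript_model()] it was annotated on.
#' @return list with `retained_residues` (residues translated before the
#'   premature stop), `full_length_residues` (the unmutated product
#'   length, excluding the terminator) and `retained_fraction`.
#' @export
truncation_stats <- function(consequence, tx) {
  if (!identical(consequence$effect_class, "nonsense"))
    stop("truncation_stats requires a nonsense consequence, got ",
         consequence$effect_class)
  full <- nchar(tx$cds_sequence) / 3 - 1
  retained <- consequence$codon_index - 1L
  list(retained_residues = as.integer(retained),
       full_length_residues = as.integer(full),
       retained_fraction = retained / full)
}
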