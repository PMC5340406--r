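#' Transcript model with exon/CDS structure and coding sequence
#'
#' @param id transcript identifier.
#' @param gene gene symbol (defaults to `id`).
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end` (1-based inclusive genomic
#'   coordinates), sorted and non-overlapping.
#' @param cds_start,cds_end genomic bounds of the coding region
#'   (`cds_start <= cds_end` regardless of strand).
#' @param cds_sequence spliced coding-strand CDS as a character string;
#'   must start with ATG, have length divisible by 3 and end with a stop
#'   codon, with no internal stop.
#' @param validate check CDS invariants (set `FALSE` only when building
#'   deliberately malformed models in tests).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(id, chrom, strand, exons, cds_start, cds_end,
                             cds_sequence, gene = id, validate = TRUE) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(exons),
            all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), c("start", "end")]
  if (any(exons$end < exons$start)) stop("malformed transcript: exon end < start")
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("malformed transcript: overlapping exons")
  tx <- structure(list(id = id, gene = gene, chrom = as.character(chrom),
                       strand = strand, exons = exons,
                       cds_start = as.integer(cds_start),
                       cds_end = as.integer(cds_end),
                       cds_sequence = toupper(cds_sequence)),
                  class = "transcript_model")
  if (validate) validate_transcript(tx)
  tx
}

#' Validate a transcript model's CDS invariants
#'
#' Checks that the CDS length is a codon multiple, starts with ATG, ends
#' with a stop codon, contains no internal stop, and that its length
#' equals the genomic CDS footprint within the exons.
#'
#' @param tx a [transcript_model()].
#' @return `tx`, invisibly; stops with a validation error otherwise.
#' @export
validate_transcript <- function(tx) {
  s <- tx$cds_sequence
  n <- nchar(s)
  if (n %% 3 != 0) stop("malformed transcript: CDS length not divisible by 3")
  if (substr(s, 1, 3) != "ATG") stop("malformed transcript: CDS does not start with ATG")
  aa <- translate_cds(s)
  if (substr(aa, nchar(aa), nchar(aa)) != "*")
    stop("malformed transcript: CDS does not end with a stop codon")
  if (grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    stop("malformed transcript: internal stop codon in CDS")
  parts <- cds_genomic_ranges(tx)
  if (sum(parts$end - parts$start + 1) != n)
    stop("malformed transcript: CDS sequence length disagrees with exon/CDS coordinates")
  invisible(tx)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s) %s:%d-%d [%s], %d exon(s), CDS %d nt (%d aa)\n",
              x$id, x$gene, x$chrom, min(x$exons$start), max(x$exons$end),
              x$strand, nrow(x$exons), nchar(x$cds_sequence),
              nchar(x$cds_sequence) / 3 - 1))
  invisible(x)
}

# Genomic intervals of the coding part of each exon, in genomic order.
cds_genomic_ranges <- function(tx) {
  p <- tx$exons
  p$start <- pmax(p$start, tx$cds_start)
  p$end <- pmin(p$end, tx$cds_end)
  p[p$start <= p$end, , drop = FALSE]
}

translate_cds <- function(seq) {
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     if.fuzzy.codon = "X"))
}

#' Map a genomic position to a 1-based spliced CDS offset
#'
#' Strand aware: on the minus strand offset 1 is the genomically highest
#' CDS base. Positions in introns, UTRs or outside the transcript give
#' `NA`.
#'
#' @param pos genomic position (1-based), on the same chromosome as `tx`
#'   (checked when `chrom` is given).
#' @param tx a [transcript_model()].
#' @param chrom optional chromosome of the query; mismatch returns `NA`.
#' @return integer CDS offset or `NA`.
#' @export
cds_position <- function(pos, tx, chrom = NULL) {
  if (!is.null(chrom) && chrom != tx$chrom) return(NA_integer_)
  parts <- cds_genomic_ranges(tx)
  if (nrow(parts) == 0) stop("malformed transcript: no CDS within exons")
  w <- parts$end - parts$start + 1
  hit <- which(pos >= parts$start & pos <= parts$end)
  if (length(hit) == 0) return(NA_integer_)
  before <- if (hit > 1) sum(w[seq_len(hit - 1)]) else 0L
  plus_off <- before + (pos - parts$start[hit]) + 1L
  if (tx$strand == "+") as.integer(plus_off)
  else as.integer(sum(w) - plus_off + 1L)
}

#' Map a 1-based spliced CDS offset back to its genomic position
#'
#' Inverse of [cds_position()].
#'
#' @param cds_pos 1-based offset into the spliced CDS.
#' @param tx a [transcript_model()].
#' @return integer genomic position.
#' @export
cds_to_genomic <- function(cds_pos, tx) {
  parts <- cds_genomic_ranges(tx)
  w <- parts$end - parts$start + 1
  total <- sum(w)
  if (cds_pos < 1 || cds_pos > total) stop("cds_pos outside CDS")
  plus_off <- if (tx$strand == "+") cds_pos else total - cds_pos + 1L
  cum <- cumsum(w)
  hit <- which(plus_off <= cum)[1]
  before <- if (hit > 1) cum[hit - 1] else 0L
  as.integer(parts$start[hit] + (plus_off - before) - 1L)
}

# Spliced coding-strand CDS extracted from a genome (DNAStringSet).
splice_cds <- function(tx, genome) {
  parts <- cds_genomic_ranges(tx)
  contig <- genome[[tx$chrom]]
  seqs <- vapply(seq_len(nrow(parts)), function(i)
    as.character(Biostrings::subseq(contig, parts$start[i], parts$end[i])),
    character(1))
  s <- paste(seqs, collapse = "")
  if (tx$strand == "-") revcomp_chr(s) else s
}

#' Export transcript models as GFF3
#'
#' Writes gene/mRNA/exon/CDS features with ID/Parent attributes,
#' 1-based inclusive coordinates.
#'
#' @param transcripts list of [transcript_model()] objects.
#' @param path output GFF3 path.
#' @return invisibly, `path`.
#' @export
write_transcripts_gff3 <- function(transcripts, path) {
  feats <- lapply(transcripts, function(tx) {
    parts <- cds_genomic_ranges(tx)
    n_ex <- nrow(tx$exons)
    n_cds <- nrow(parts)
    # GFF3 phase: bases to skip to reach a codon boundary, in
    # transcription order
    w <- parts$end - parts$start + 1
    before <- if (tx$strand == "+") c(0, cumsum(w))[seq_len(n_cds)]
              else rev(c(0, cumsum(rev(w)))[seq_len(n_cds)])
    data.frame(
      chrom = tx$chrom,
      start = c(min(tx$exons$start), min(tx$exons$start), tx$exons$start,
                parts$start),
      end = c(max(tx$exons$end), max(tx$exons$end), tx$exons$end, parts$end),
      strand = tx$strand,
      type = c("gene", "mRNA", rep("exon", n_ex), rep("CDS", n_cds)),
      ID = c(paste0("gene:", tx$gene), paste0("transcript:", tx$id),
             paste0(tx$id, ":exon", seq_len(n_ex)),
             paste0(tx$id, ":cds", seq_len(n_cds))),
      Parent = c(NA, paste0("gene:", tx$gene),
                 rep(paste0("transcript:", tx$id), n_ex + n_cds)),
      Name = c(tx$gene, tx$id, rep(NA, n_ex + n_cds)),
      phase = c(rep(NA_integer_, 2 + n_ex), as.integer((3 - before %% 3) %% 3)))
  })
  feats <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(feats$chrom,
                               IRanges::IRanges(feats$start, feats$end),
                               strand = feats$strand)
  gr$type <- feats$type
  gr$ID <- feats$ID
  gr$Parent <- feats$Parent
  gr$Name <- feats$Name
  gr$phase <- feats$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read transcript models from GFF3 plus a reference genome
#'
#' Rebuilds [transcript_model()] objects from mRNA/exon/CDS features,
#' splicing each CDS sequence out of `genome`.
#'
#' @param path GFF3 file as written by [write_transcripts_gff3()] (or any
#'   GFF3 with mRNA/exon/CDS Parent links).
#' @param genome named `DNAStringSet` of contig sequences.
#' @return list of [transcript_model()] objects.
#' @export
read_transcripts_gff3 <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  mrna <- gr[gr$type == "mRNA"]
  lapply(seq_along(mrna), function(i) {
    tid <- mrna$ID[i]
    txid <- sub("^transcript:", "", tid)
    kids <- gr[vapply(gr$Parent, function(p) tid %in% p, logical(1))]
    ex <- kids[kids$type == "exon"]
    cds <- kids[kids$type == "CDS"]
    exons <- data.frame(start = GenomicRanges::start(ex), end = GenomicRanges::end(ex))
    exons <- exons[order(exons$start), ]
    gene <- sub("^gene:", "", unlist(mrna$Parent[i]))
    tx <- transcript_model(
      id = txid, gene = gene,
      chrom = as.character(GenomicRanges::seqnames(mrna)[i]),
      strand = as.character(GenomicRanges::strand(mrna)[i]),
      exons = exons,
      cds_start = min(GenomicRanges::start(cds)),
      cds_end = max(GenomicRanges::end(cds)),
      cds_sequence = "ATGTAA", validate = FALSE)
    tx$cds_sequence <- splice_cds(tx, genome)
    validate_transcript(tx)
    tx
  })
}
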