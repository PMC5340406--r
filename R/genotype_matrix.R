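#' Biallelic array genotype matrix
#'
#' Container for SNP-array genotypes over ordered markers and samples.
#' Calls are coded as the count of the B allele: `0` hom-A, `1` het,
#' `2` hom-B, `NA` missing.
#'
#' @param markers data.frame with columns `chrom`, `pos`, `id`,
#'   `allele_a`, `allele_b`; must be strictly sorted by (`chrom`, `pos`)
#'   with unique marker ids.
#' @param samples character vector of unique sample ids.
#' @param calls integer matrix, `nrow(markers)` x `length(samples)`, values
#'   in `{0, 1, 2, NA}`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `markers`, `samples`, `calls`.
#' @examples
#' m <- data.frame(chrom = "chr1", pos = c(100, 200), id = c("m1", "m2"),
#'                 allele_a = "A", allele_b = "G")
#' gm <- genotype_matrix(m, c("s1", "s2"),
#'                       matrix(c(0L, 1L, 2L, NA), nrow = 2))
#' @export
genotype_matrix <- function(markers, samples, calls) {
  stopifnot(is.data.frame(markers),
            all(c("chrom", "pos", "id", "allele_a", "allele_b") %in% names(markers)))
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(markers) || ncol(calls) != length(samples))
    stop("calls matrix dimensions do not match markers x samples")
  if (anyDuplicated(markers$id)) stop("marker ids must be unique")
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  bad <- !(calls %in% c(0L, 1L, 2L)) & !is.na(calls)
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  # strictly increasing positions within each chromosome, chromosomes in
  # block order
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0)) stop("marker positions must be strictly increasing per chromosome")
  }
  if (any(rle(markers$chrom)$values != unique(markers$chrom)))
    stop("markers must be grouped by chromosome")
  rownames(calls) <- markers$id
  colnames(calls) <- samples
  structure(list(markers = markers, samples = samples, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$markers), "markers x", length(x$samples),
      "samples over", length(unique(x$markers$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing call fraction: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Write array genotypes as PLINK text PED/MAP
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @return invisibly, the two file paths.
#' @export
write_plink <- function(gm, prefix) {
  map <- data.frame(chrom = gm$markers$chrom, id = gm$markers$id,
                    cm = 0, pos = gm$markers$pos)
  write.table(map, paste0(prefix, ".map"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  a <- gm$markers$allele_a
  b <- gm$markers$allele_b
  lines <- vapply(seq_along(gm$samples), function(j) {
    g <- gm$calls[, j]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, b, a))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, b, a))
    paste(c(gm$samples[j], gm$samples[j], "0", "0", "0", "-9",
            as.vector(rbind(a1, a2))), collapse = " ")
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}

#' Read PLINK text PED/MAP into a genotype matrix
#'
#' Allele coding is inferred per marker: `allele_a` is the
#' lexicographically smaller observed allele (so a marker where only one
#' allele is observed is coded hom-A regardless of its original
#' orientation).
#'
#' @param prefix path prefix of the `.ped`/`.map` pair.
#' @return a [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    col.names = c("chrom", "id", "cm", "pos"),
                    colClasses = c("character", "character", "numeric", "integer"))
  ped <- strsplit(readLines(paste0(prefix, ".ped")), "[ \t]+")
  nm <- nrow(map)
  samples <- vapply(ped, `[`, character(1), 2L)
  a1 <- t(vapply(ped, function(f) f[6L + 2L * seq_len(nm) - 1L], character(nm)))
  a2 <- t(vapply(ped, function(f) f[6L + 2L * seq_len(nm)], character(nm)))
  if (nm == 1L) { a1 <- t(a1); a2 <- t(a2) }
  calls <- matrix(NA_integer_, nrow = nm, ncol = length(samples))
  allele_a <- allele_b <- character(nm)
  for (i in seq_len(nm)) {
    x1 <- a1[, i]; x2 <- a2[, i]
    obs <- sort(setdiff(unique(c(x1, x2)), "0"))
    allele_a[i] <- if (length(obs)) obs[1] else "0"
    allele_b[i] <- if (length(obs) > 1) obs[2] else allele_a[i]
    ok <- x1 != "0" & x2 != "0"
    calls[i, ok] <- if (length(obs) < 2) 0L else
      (x1[ok] == allele_b[i]) + (x2[ok] == allele_b[i])
  }
  markers <- data.frame(chrom = map$chrom, pos = map$pos, id = map$id,
                        allele_a = allele_a, allele_b = allele_b)
  genotype_matrix(markers, samples, calls)
}
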