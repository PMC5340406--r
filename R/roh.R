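#' Array QC thresholds
#'
#' @param min_snp_call_rate retain markers with call rate strictly above
#'   this fraction.
#' @param min_sample_call_rate retain samples with call rate strictly
#'   above this fraction.
#' @param min_maf retain markers with minor allele frequency strictly
#'   above this fraction.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_snp_call_rate = 0.95,
                          min_sample_call_rate = 0.95,
                          min_maf = 0.05) {
  stopifnot(min_snp_call_rate >= 0, min_snp_call_rate <= 1,
            min_sample_call_rate >= 0, min_sample_call_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  structure(list(min_snp_call_rate = min_snp_call_rate,
                 min_sample_call_rate = min_sample_call_rate,
                 min_maf = min_maf), class = "qc_thresholds")
}

#' QC-filter an array genotype matrix
#'
#' Samples are filtered first on call rate; marker call rate and MAF are
#' then computed on the retained samples and markers failing either are
#' removed. Marker order is preserved. The removal counts per criterion
#' are attached as attribute `qc_log`.
#'
#' @param gm a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return the filtered [genotype_matrix()] with a `qc_log` attribute.
#' @export
qc_filter <- function(gm, thresholds = qc_thresholds()) {
  if (nrow(gm$markers) == 0) stop("empty genotype matrix")
  sample_cr <- colMeans(!is.na(gm$calls))
  keep_s <- sample_cr > thresholds$min_sample_call_rate
  calls <- gm$calls[, keep_s, drop = FALSE]
  ns <- sum(keep_s)
  if (ns == 0) stop("QC removed all samples")
  marker_cr <- rowMeans(!is.na(calls))
  alt <- rowSums(calls, na.rm = TRUE)
  called <- rowSums(!is.na(calls))
  p <- ifelse(called > 0, alt / (2 * called), 0)
  maf <- pmin(p, 1 - p)
  keep_cr <- marker_cr > thresholds$min_snp_call_rate
  keep_maf <- maf > thresholds$min_maf
  keep_m <- keep_cr & keep_maf
  if (!any(keep_m))
    stop("QC removed all markers (", sum(!keep_cr), " by call rate, ",
         sum(!keep_maf), " by MAF)")
  out <- genotype_matrix(gm$markers[keep_m, , drop = FALSE],
                         gm$samples[keep_s],
                         calls[keep_m, , drop = FALSE])
  attr(out, "qc_log") <- list(
    n_samples_removed = sum(!keep_s),
    n_markers_low_call_rate = sum(!keep_cr),
    n_markers_low_maf = sum(!keep_maf),
    n_markers_removed = sum(!keep_m),
    n_markers_retained = sum(keep_m))
  out
}

#' Sliding-window ROH detection parameters
#'
#' Defaults are the PLINK v1.07 documented defaults for
#' `--homozyg`-style segment search.
#'
#' @param window_snps markers per sliding window.
#' @param max_het_per_window maximum heterozygous calls for a window to
#'   count as homozygous.
#' @param max_missing_per_window maximum missing calls per homozygous
#'   window.
#' @param window_hit_threshold minimum fraction of homozygous windows
#'   covering a marker for the marker to be ROH-eligible.
#' @param min_segment_snps minimum markers per reported segment.
#' @param min_segment_kb minimum segment span in kb.
#' @param min_density_kb_per_snp maximum kb per SNP (segment density).
#' @param max_gap_kb maximum gap between consecutive markers inside a
#'   segment, in kb.
#' @return list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50, max_het_per_window = 1,
                       max_missing_per_window = 5,
                       window_hit_threshold = 0.05,
                       min_segment_snps = 100, min_segment_kb = 1000,
                       min_density_kb_per_snp = 50, max_gap_kb = 1000) {
  stopifnot(window_snps >= 1, max_het_per_window >= 0,
            max_missing_per_window >= 0,
            window_hit_threshold > 0, window_hit_threshold <= 1,
            min_segment_snps >= 1, min_segment_kb >= 0,
            min_density_kb_per_snp > 0, max_gap_kb > 0)
  structure(list(window_snps = as.integer(window_snps),
                 max_het_per_window = as.integer(max_het_per_window),
                 max_missing_per_window = as.integer(max_missing_per_window),
                 window_hit_threshold = window_hit_threshold,
                 min_segment_snps = as.integer(min_segment_snps),
                 min_segment_kb = min_segment_kb,
                 min_density_kb_per_snp = min_density_kb_per_snp,
                 max_gap_kb = max_gap_kb), class = "roh_params")
}

# rolling sum of x over windows of width w: result length n-w+1
.rollsum <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1):length(cs)] - cs[seq_len(length(cs) - w)]
}

#' Detect runs of homozygosity for one sample
#'
#' Every contiguous window of `window_snps` markers is scored homozygous
#' when it holds at most `max_het_per_window` het and
#' `max_missing_per_window` missing calls; a marker is ROH-eligible when
#' at least `window_hit_threshold` of the windows covering it are
#' homozygous. Maximal runs of eligible markers are then reported as
#' segments if they satisfy the marker-count, span, density and
#' inter-marker gap constraints. Segments never span chromosomes and
#' their bounds are the outermost eligible marker positions.
#'
#' @param gm a [genotype_matrix()].
#' @param sample sample id present in `gm`.
#' @param params a [roh_params()].
#' @return data.frame with columns `sample`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `n_het`, `n_missing`, `kb`.
#' @export
detect_roh <- function(gm, sample, params = roh_params()) {
  j <- match(sample, gm$samples)
  if (is.na(j)) stop("unknown sample id: ", sample)
  out <- list()
  for (ch in unique(gm$markers$chrom)) {
    idx <- which(gm$markers$chrom == ch)
    g <- gm$calls[idx, j]
    pos <- gm$markers$pos[idx]
    elig <- .eligible_markers(g, params)
    if (!any(elig)) next
    runs <- .eligible_runs(elig, pos, params$max_gap_kb)
    for (r in runs) {
      n_snps <- length(r)
      span_kb <- (pos[r[n_snps]] - pos[r[1]]) / 1000
      if (n_snps < params$min_segment_snps) next
      if (span_kb < params$min_segment_kb) next
      if (span_kb / n_snps > params$min_density_kb_per_snp) next
      out[[length(out) + 1]] <- data.frame(
        sample = sample, chrom = ch,
        start_bp = pos[r[1]], end_bp = pos[r[n_snps]],
        n_snps = n_snps,
        n_het = sum(g[r] == 1L, na.rm = TRUE),
        n_missing = sum(is.na(g[r])),
        kb = span_kb, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(sample = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer(), kb = numeric()))
  do.call(rbind, out)
}

# marker eligibility by window vote
.eligible_markers <- function(g, params) {
  n <- length(g)
  w <- params$window_snps
  if (n < w) return(rep(FALSE, n))
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  win_hom <- as.integer(.rollsum(het, w) <= params$max_het_per_window &
                        .rollsum(mis, w) <= params$max_missing_per_window)
  nw <- n - w + 1L
  i <- seq_len(n)
  lo <- pmax(1L, i - w + 1L)          # first window start covering marker i
  hi <- pmin(i, nw)                   # last window start covering marker i
  cs <- c(0, cumsum(win_hom))
  n_hom <- cs[hi + 1L] - cs[lo]
  n_cov <- hi - lo + 1L
  n_cov > 0 & (n_hom / n_cov) >= params$window_hit_threshold
}

# maximal runs of eligible indices, split where the bp gap exceeds max_gap_kb
.eligible_runs <- function(elig, pos, max_gap_kb) {
  idx <- which(elig)
  if (length(idx) == 0) return(list())
  brk <- which(diff(idx) > 1 |
               (pos[idx[-1]] - pos[idx[-length(idx)]]) > max_gap_kb * 1000)
  starts <- c(1, brk + 1)
  ends <- c(brk, length(idx))
  lapply(seq_along(starts), function(k) idx[starts[k]:ends[k]])
}

#' Intersect case ROH into shared allele-matched regions
#'
#' A shared region is a maximal interval covered by at least one ROH
#' segment in every case, over which the cases carry identical
#' homozygous genotypes at every non-missing marker. A marker at which
#' any case is heterozygous, or at which two cases are homozygous for
#' opposite alleles, splits the region; sub-regions are re-anchored at
#' their outermost concordant markers.
#'
#' @param segments_by_case named list (one element per case) of
#'   [detect_roh()]-style data.frames.
#' @param gm the [genotype_matrix()] the segments were called from.
#' @param max_mismatch_markers markers with discordant genotypes
#'   tolerated before a region is split (default 0).
#' @return data.frame with columns `chrom`, `start_bp`, `end_bp`,
#'   `n_cases_supporting`, `n_markers`; sorted and non-overlapping.
#' @export
shared_regions <- function(segments_by_case, gm, max_mismatch_markers = 0) {
  n_cases <- length(segments_by_case)
  if (n_cases == 0 ||
      all(vapply(segments_by_case, nrow, integer(1)) == 0))
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_cases_supporting = integer(),
                      n_markers = integer()))
  if (n_cases == 1) {
    s <- segments_by_case[[1]]
    return(data.frame(chrom = s$chrom, start_bp = s$start_bp,
                      end_bp = s$end_bp, n_cases_supporting = 1L,
                      n_markers = s$n_snps)[order(s$chrom, s$start_bp), ,
                                            drop = FALSE])
  }
  grs <- lapply(segments_by_case, function(s)
    GenomicRanges::reduce(GenomicRanges::GRanges(
      s$chrom, IRanges::IRanges(s$start_bp, s$end_bp))))
  inter <- Reduce(GenomicRanges::intersect, grs)
  if (length(inter) == 0)
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_cases_supporting = integer(),
                      n_markers = integer()))
  cases <- names(segments_by_case)
  jj <- match(cases, gm$samples)
  out <- list()
  for (k in seq_along(inter)) {
    ch <- as.character(GenomicRanges::seqnames(inter)[k])
    s0 <- GenomicRanges::start(inter)[k]
    e0 <- GenomicRanges::end(inter)[k]
    midx <- which(gm$markers$chrom == ch & gm$markers$pos >= s0 &
                  gm$markers$pos <= e0)
    if (length(midx) == 0) next
    calls <- gm$calls[midx, jj, drop = FALSE]
    # concordant marker: all non-missing calls homozygous and equal
    conc <- apply(calls, 1, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) return(TRUE)
      all(x %in% c(0L, 2L)) && length(unique(x)) == 1
    })
    if (all(conc)) {
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start_bp = s0, end_bp = e0,
        n_cases_supporting = n_cases, n_markers = length(midx))
      next
    }
    # split at discordant markers (beyond the allowance)
    bad <- which(!conc)
    if (length(bad) <= max_mismatch_markers) {
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start_bp = s0, end_bp = e0,
        n_cases_supporting = n_cases, n_markers = length(midx))
      next
    }
    pos <- gm$markers$pos[midx]
    bounds <- c(0, bad, length(midx) + 1)
    for (b in seq_len(length(bounds) - 1)) {
      lo <- bounds[b] + 1
      hi <- bounds[b + 1] - 1
      if (hi < lo) next
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start_bp = pos[lo], end_bp = pos[hi],
        n_cases_supporting = n_cases, n_markers = hi - lo + 1)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_cases_supporting = integer(),
                      n_markers = integer()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start_bp), , drop = FALSE]
}
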