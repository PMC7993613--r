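#' Per-SNP allele-frequency differentiation between pools
#'
#' dAF at a site is the absolute difference between the alternate-allele
#' read frequencies of the two pools, `|mut_alt/(mut_ref+mut_alt) -
#' wt_alt/(wt_ref+wt_alt)|`. Sites with zero depth in either pool cannot be
#' scored: they get `NA` and their row indices are recorded in the
#' `excluded` attribute rather than being silently dropped.
#'
#' @param sites Pool-site `data.frame` with columns `mut_ref`, `mut_alt`,
#'   `wt_ref`, `wt_alt`.
#' @return Numeric vector of dAF values in `[0,1]` (NA where excluded),
#'   with attribute `excluded` holding the indices of zero-depth sites.
#' @examples
#' s <- data.frame(mut_ref = 0, mut_alt = 37, wt_ref = 28, wt_alt = 9)
#' site_delta_af(s)  # 0.7568
#' @export
site_delta_af <- function(sites) {
  dm <- sites$mut_ref + sites$mut_alt
  dw <- sites$wt_ref + sites$wt_alt
  bad <- which(dm == 0 | dw == 0)
  daf <- abs(sites$mut_alt / dm - sites$wt_alt / dw)
  daf[bad] <- NA_real_
  attr(daf, "excluded") <- bad
  daf
}

#' Enumerate sliding windows over a SNP table by SNP rank
#'
#' Windows are defined by SNP rank within each chromosome (not bp): spans
#' of `window_snps` SNPs starting at ranks 1, 1+step, 1+2*step, ... A span
#' truncated by the chromosome end is kept if it still holds at least
#' `min_snps` SNPs; shorter spans are dropped, as are whole chromosomes
#' with fewer than `min_snps` SNPs. Windows never cross chromosome
#' boundaries.
#'
#' @param sites Pool-site table sorted by (chrom, pos).
#' @param window_snps Window size in SNPs.
#' @param step_snps Step between window starts in SNPs.
#' @param min_snps Minimum SNPs for a window to be emitted.
#' @return `data.frame` with `chrom`, `first_snp_index`, `last_snp_index`
#'   (global row indices into `sites`), `n_snps`.
#' @export
make_windows <- function(sites, window_snps = 5000L, step_snps = 1000L,
                         min_snps = 4000L) {
  window_snps <- as.integer(window_snps)
  step_snps <- as.integer(step_snps)
  min_snps <- as.integer(min_snps)
  stopifnot(window_snps >= 1L, step_snps >= 1L, min_snps >= 1L)
  chrom <- as.character(sites$chrom)
  runs <- rle(chrom)
  offsets <- cumsum(c(0L, runs$lengths))
  if (anyDuplicated(runs$values)) stop("sites not sorted: chromosome blocks interleaved")
  out <- vector("list", length(runs$values))
  for (i in seq_along(runs$values)) {
    n <- runs$lengths[i]
    off <- offsets[i]
    if (is.unsorted(sites$pos[(off + 1L):(off + n)])) {
      stop("sites not sorted by position within chromosome ", runs$values[i])
    }
    starts <- seq.int(1L, n, by = step_snps)
    ends <- pmin(starts + window_snps - 1L, n)
    keep <- (ends - starts + 1L) >= min_snps
    out[[i]] <- data.frame(
      chrom = rep(runs$values[i], sum(keep)),
      first_snp_index = off + starts[keep],
      last_snp_index = off + ends[keep],
      n_snps = (ends - starts + 1L)[keep],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(0), first_snp_index = integer(0),
                      last_snp_index = integer(0), n_snps = integer(0),
                      stringsAsFactors = FALSE)
  }
  res
}

#' Mean dAF within a window
#'
#' Arithmetic mean of per-SNP dAF over the window's sites, excluding
#' zero-depth sites (exclusions are counted, not imputed).
#'
#' @param sites Pool-site table.
#' @param first,last Row range of the window.
#' @return Mean dAF (NA if no scorable site).
#' @export
window_delta_af <- function(sites, first = 1L, last = nrow(sites)) {
  daf <- site_delta_af(sites[first:last, , drop = FALSE])
  if (all(is.na(daf))) NA_real_ else mean(daf, na.rm = TRUE)
}

#' Pooled heterozygosity of a window within one pool
#'
#' Per SNP, the pool's major and minor allele read counts are
#' `nMAJ = max(ref, alt)` and `nMIN = min(ref, alt)`; the window statistic
#' is `Hp = 2 * sum(nMAJ) * sum(nMIN) / (sum(nMAJ) + sum(nMIN))^2`, which
#' lies in `[0, 0.5]` and collapses toward 0 where the pool is fixed.
#'
#' @param sites Pool-site table.
#' @param pool `"mut"` or `"wt"`.
#' @param first,last Row range of the window.
#' @return Hp in `[0, 0.5]`, or NA if all counts are zero.
#' @export
window_hp <- function(sites, pool = c("mut", "wt"), first = 1L,
                      last = nrow(sites)) {
  pool <- match.arg(pool)
  ref <- sites[[paste0(pool, "_ref")]][first:last]
  alt <- sites[[paste0(pool, "_alt")]][first:last]
  smaj <- sum(pmax(ref, alt))
  smin <- sum(pmin(ref, alt))
  if (smaj + smin == 0) return(NA_real_)
  2 * smaj * smin / (smaj + smin)^2
}

#' Heterozygosity ratio between pools for a window
#'
#' `(hp_wt + epsilon) / (hp_mut + epsilon)` by default: elevated values
#' flag windows where the mutant pool has collapsed to homozygosity, the
#' signature of identity by descent around a recessive causal locus in
#' phenotype-selected pools. The additive epsilon keeps ratios finite and
#' rankable when a pool is fully fixed. Orientation is configurable.
#'
#' @param hp_mut,hp_wt Window Hp per pool.
#' @param epsilon Additive stabilizer.
#' @param orientation `"wt_over_mut"` (default) or `"mut_over_wt"`.
#' @return Ratio (NA if either Hp is missing).
#' @export
hp_ratio <- function(hp_mut, hp_wt, epsilon = 1e-4,
                     orientation = c("wt_over_mut", "mut_over_wt")) {
  orientation <- match.arg(orientation)
  r <- if (orientation == "wt_over_mut") {
    (hp_wt + epsilon) / (hp_mut + epsilon)
  } else {
    (hp_mut + epsilon) / (hp_wt + epsilon)
  }
  r[is.na(hp_mut) | is.na(hp_wt)] <- NA_real_
  r
}

#' Windowed genome scan of dAF and pooled heterozygosity
#'
#' Runs the full sliding-window scan: window enumeration by SNP rank,
#' per-window mean dAF (zero-depth sites excluded and counted), Hp per
#' pool, and the Hp ratio. Window sums are computed with cumulative sums,
#' so the scan is linear in the number of SNPs.
#'
#' @inheritParams make_windows
#' @param epsilon Stabilizer passed to [hp_ratio()].
#' @param orientation Ratio orientation passed to [hp_ratio()].
#' @return `data.frame` of window statistics: `chrom`, `first_snp_index`,
#'   `last_snp_index`, `start_pos`, `end_pos`, `n_snps`, `n_excluded`,
#'   `mean_daf`, `hp_mut`, `hp_wt`, `hp_ratio`.
#' @export
pool_scan <- function(sites, window_snps = 5000L, step_snps = 1000L,
                      min_snps = 4000L, epsilon = 1e-4,
                      orientation = c("wt_over_mut", "mut_over_wt")) {
  orientation <- match.arg(orientation)
  win <- make_windows(sites, window_snps, step_snps, min_snps)
  if (nrow(win) == 0L) {
    return(cbind(win[0, , drop = FALSE],
                 data.frame(start_pos = integer(0), end_pos = integer(0),
                            n_excluded = integer(0), mean_daf = numeric(0),
                            hp_mut = numeric(0), hp_wt = numeric(0),
                            hp_ratio = numeric(0))))
  }
  daf <- site_delta_af(sites)
  ok <- !is.na(daf)
  cs <- function(x) cumsum(c(0, x))
  daf_sum <- cs(ifelse(ok, daf, 0))
  daf_n <- cs(as.numeric(ok))
  maj_mut <- cs(pmax(sites$mut_ref, sites$mut_alt))
  min_mut <- cs(pmin(sites$mut_ref, sites$mut_alt))
  maj_wt <- cs(pmax(sites$wt_ref, sites$wt_alt))
  min_wt <- cs(pmin(sites$wt_ref, sites$wt_alt))
  a <- win$first_snp_index
  b <- win$last_snp_index + 1L
  nok <- daf_n[b] - daf_n[a]
  hp_of <- function(maj, min_) {
    smaj <- maj[b] - maj[a]
    smin <- min_[b] - min_[a]
    ifelse(smaj + smin == 0, NA_real_, 2 * smaj * smin / (smaj + smin)^2)
  }
  win$start_pos <- sites$pos[win$first_snp_index]
  win$end_pos <- sites$pos[win$last_snp_index]
  win$n_excluded <- win$n_snps - as.integer(nok)
  win$mean_daf <- ifelse(nok > 0, (daf_sum[b] - daf_sum[a]) / nok, NA_real_)
  win$hp_mut <- hp_of(maj_mut, min_mut)
  win$hp_wt <- hp_of(maj_wt, min_wt)
  win$hp_ratio <- hp_ratio(win$hp_mut, win$hp_wt, epsilon, orientation)
  win[, c("chrom", "first_snp_index", "last_snp_index", "start_pos",
          "end_pos", "n_snps", "n_excluded", "mean_daf", "hp_mut",
          "hp_wt", "hp_ratio")]
}

#' Empirical top-fraction threshold and flags
#'
#' The threshold is the smallest value among the `ceiling(fraction * N)`
#' largest finite values; every value `>= threshold` is flagged, so ties at
#' the threshold are all included.
#'
#' @param values Numeric vector (NAs ignored for the threshold, never
#'   flagged).
#' @param fraction Top fraction, e.g. 0.01.
#' @return List with `threshold` and logical `flags` aligned with `values`.
#' @export
empirical_top_fraction <- function(values, fraction = 0.01) {
  finite <- values[is.finite(values)]
  if (length(finite) == 0L) stop("no finite values to threshold")
  k <- max(1L, ceiling(fraction * length(finite)))
  threshold <- sort(finite, decreasing = TRUE)[k]
  flags <- !is.na(values) & values >= threshold
  list(threshold = threshold, flags = flags)
}

#' Merge flagged windows into candidate genomic intervals
#'
#' Takes the bp spans of flagged windows and returns their per-chromosome
#' union: overlapping or book-ended spans are merged and the result is
#' sorted. Returns a `GRanges` so standard range operations and BED export
#' apply directly.
#'
#' @param windows Window table from [pool_scan()].
#' @param flags Logical vector aligned with `windows` rows (e.g. from
#'   [empirical_top_fraction()]).
#' @return A sorted `GRanges` of merged candidate intervals (empty if no
#'   window is flagged).
#' @export
call_candidate_interval <- function(windows, flags) {
  stopifnot(length(flags) == nrow(windows))
  w <- windows[flags, , drop = FALSE]
  if (nrow(w) == 0L) {
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(
    seqnames = w$chrom,
    ranges = IRanges::IRanges(start = w$start_pos, end = w$end_pos)
  )
  GenomicRanges::reduce(sort(gr), min.gapwidth = 1L)
}

#' Export candidate intervals as a BED file
#'
#' Standard 0-based half-open BED via `rtracklayer`.
#'
#' @param intervals `GRanges` from [call_candidate_interval()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_intervals_bed <- function(intervals, path) {
  rtracklayer::export.bed(intervals, path)
  invisible(path)
}
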