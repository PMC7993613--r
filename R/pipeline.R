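#' Run the full mapping pipeline on a simulated cross
#'
#' Convenience end-to-end driver: simulate founders, the F2 cross, pooled
#' sequencing, a reference panel and consequence annotations; run the
#' windowed dAF / Hp scan; call candidate intervals; and run the
#' prioritization cascade.
#'
#' Interval calling follows the two-stage logic of a genome-wide scan. The
#' empirical top-fraction threshold is a genome-wide quantile, so the
#' focal chromosome's windows are combined with a simulated unlinked
#' background standing in for the rest of the genome: `n_bg_windows`
#' non-overlapping windows of unlinked sites are simulated and each
#' counts for `bg_multiplier` genome windows, giving roughly the 9,400
#' windows of a full mammalian genome at this window geometry. Windows at
#' or above the threshold are merged into the coarse top-fraction
#' interval. Because identity by descent around a recessive locus
#' produces a broad plateau of elevated values, the cascade then searches
#' the refined region where the Hp ratio exceeds `min_fold`
#' (default 100-fold), falling back to the coarse interval when no window
#' reaches that fold change.
#'
#' @param design A [cross_design()].
#' @param window_snps,step_snps,min_snps Scan geometry (SNP ranks); scale
#'   these down together with `design$n_snps`.
#' @param top_fraction Empirical top fraction for coarse interval calling.
#' @param stat Window statistic driving interval calling: `"hp_ratio"`
#'   (default) or `"mean_daf"`.
#' @param min_fold Hp-ratio cutoff defining the refined candidate region
#'   (ignored for `stat = "mean_daf"`).
#' @param n_panel Reference-panel size.
#' @param n_bg_windows Distinct unlinked background windows to simulate
#'   (0 disables the genome-wide background).
#' @param bg_multiplier Genome windows each simulated background window
#'   stands for.
#' @return List of class `bsa_result`: `sites`, `windows`,
#'   `bg_windows`, `threshold`, `interval` (coarse `GRanges`),
#'   `refined_interval`, `report` (cascade over the refined region),
#'   `causal_pos`, `causal_window_ratio` (largest hp_ratio among windows
#'   whose bp span contains the causal SNP).
#' @export
run_bsa_pipeline <- function(design, window_snps = 5000L, step_snps = 1000L,
                             min_snps = 4000L, top_fraction = 0.01,
                             stat = c("hp_ratio", "mean_daf"),
                             min_fold = 100, n_panel = 20L,
                             n_bg_windows = 94L, bg_multiplier = 99L) {
  stat <- match.arg(stat)
  founders <- simulate_founders(design)
  cohort <- simulate_f2_cross(founders)
  sites <- pool_and_sequence(cohort)
  panel <- simulate_reference_panel(founders, n_samples = n_panel)
  ann <- simulate_annotations(sites, seed = derive_seed(design$seed, 8L))
  windows <- pool_scan(sites, window_snps, step_snps, min_snps)
  bg_windows <- NULL
  values <- windows[[stat]]
  if (n_bg_windows > 0L) {
    bg_sites <- simulate_unlinked_sites(design, n_bg_windows * window_snps)
    bg_windows <- pool_scan(bg_sites, window_snps, step_snps = window_snps,
                            min_snps = min_snps)
    values <- c(values, rep(bg_windows[[stat]], times = bg_multiplier))
  }
  top <- empirical_top_fraction(values, top_fraction)
  focal_flags <- !is.na(windows[[stat]]) & windows[[stat]] >= top$threshold
  interval <- call_candidate_interval(windows, focal_flags)
  refined <- interval
  if (stat == "hp_ratio") {
    fold_flags <- !is.na(windows$hp_ratio) & windows$hp_ratio >= min_fold
    if (any(fold_flags)) {
      # resolution-aware smoothing: a window-granularity scan localizes a
      # boundary only to about one window span, so sub-window gaps between
      # extreme windows are bridged and the region is padded by half a span
      span <- stats::median(windows$end_pos - windows$start_pos + 1)
      refined <- call_candidate_interval(windows, fold_flags)
      refined <- GenomicRanges::reduce(refined, min.gapwidth = span)
      refined <- GenomicRanges::restrict(suppressWarnings(
        GenomicRanges::resize(refined,
                              GenomicRanges::width(refined) + span,
                              fix = "center")), start = 1L)
      refined <- GenomicRanges::reduce(refined, min.gapwidth = 1L)
    }
  }
  variants <- annotate_sites(sites, ann, panel)
  report <- prioritize(variants, refined)
  causal_pos <- sites$pos[attr(sites, "causal_index")]
  in_win <- windows$start_pos <= causal_pos & windows$end_pos >= causal_pos
  causal_ratio <- if (any(in_win)) max(windows$hp_ratio[in_win], na.rm = TRUE) else NA_real_
  structure(list(
    sites = sites, windows = windows, bg_windows = bg_windows,
    threshold = top$threshold, interval = interval,
    refined_interval = refined, report = report, causal_pos = causal_pos,
    causal_window_ratio = causal_ratio
  ), class = "bsa_result")
}

#' @export
print.bsa_result <- function(x, ...) {
  cat(sprintf("BSA scan: %d sites, %d windows (top threshold %.4g)\n",
              nrow(x$sites), nrow(x$windows), x$threshold))
  cat(sprintf("causal SNP at %d bp; causal-window Hp ratio %.1f\n",
              x$causal_pos, x$causal_window_ratio))
  cat(sprintf("top-fraction interval : %s\n",
              paste(as.character(x$interval), collapse = ", ")))
  cat(sprintf("refined interval      : %s\n",
              paste(as.character(x$refined_interval), collapse = ", ")))
  print(x$report)
  invisible(x)
}
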