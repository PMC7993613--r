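#' Default mapping of consequence terms to impact classes
#'
#' Conventional SnpEff-style scheme mapping annotation consequence terms to
#' the four impact classes. Effect prediction itself is consumed as input;
#' this table only standardizes the labels and is editable (pass your own
#' table of the same shape to [annotate_sites()]).
#'
#' @return `data.frame` with columns `consequence`, `impact_class`.
#' @export
impact_class_table <- function() {
  data.frame(
    consequence = c(
      "frameshift_variant", "stop_gained", "stop_lost", "start_lost",
      "splice_donor_variant", "splice_acceptor_variant",
      "missense_variant", "inframe_insertion", "inframe_deletion",
      "synonymous_variant", "splice_region_variant",
      "intron_variant", "intergenic_variant",
      "upstream_gene_variant", "downstream_gene_variant",
      "5_prime_UTR_variant", "3_prime_UTR_variant"
    ),
    impact_class = c(
      rep("HIGH", 6),
      rep("MODERATE", 3),
      rep("LOW", 2),
      rep("MODIFIER", 6)
    ),
    stringsAsFactors = FALSE
  )
}

#' Assemble an annotated-variant table for the filtering cascade
#'
#' Joins pool sites with consequence annotations (by position), computes
#' per-site dAF, and counts panel samples carrying the alternate allele.
#' Variant positions absent from the panel are counted as unobserved
#' (`panel_alt_observed = 0`) and reported via a message, matching the
#' convention that "not present in the panel" means zero observations.
#'
#' @param sites Pool-site `data.frame`.
#' @param annotations `data.frame` with `pos`, `consequence` and optionally
#'   `impact_class` (filled from `impact_table` when missing).
#' @param panel A `reference_panel` (or `NULL` to skip panel counts).
#' @param impact_table Consequence-to-class map, default
#'   [impact_class_table()].
#' @return `data.frame`: the site columns plus `consequence`,
#'   `impact_class`, `daf`, `panel_alt_observed`.
#' @export
annotate_sites <- function(sites, annotations, panel = NULL,
                           impact_table = impact_class_table()) {
  v <- sites
  m <- match(v$pos, annotations$pos)
  v$consequence <- annotations$consequence[m]
  if (!is.null(annotations$impact_class)) {
    v$impact_class <- annotations$impact_class[m]
  } else {
    v$impact_class <- impact_table$impact_class[
      match(v$consequence, impact_table$consequence)]
  }
  v$daf <- as.numeric(site_delta_af(v))
  if (is.null(panel)) {
    v$panel_alt_observed <- NA_integer_
  } else {
    pm <- match(v$pos, panel$positions)
    missing_n <- sum(is.na(pm))
    if (missing_n > 0) {
      message(missing_n, " variant position(s) absent from panel; treated as unobserved")
    }
    v$panel_alt_observed <- ifelse(is.na(pm), 0L, panel$alt_carriers[pm])
  }
  v
}

#' Discard sites with excessive read depth in either pool
#'
#' Collapsed repeats and copy-number variable regions accumulate reads far
#' above the genome mean and produce spurious allele-frequency signals, so
#' a site is discarded when its depth in either pool is strictly greater
#' than `multiplier` times that pool's genome-wide mean depth.
#'
#' @param sites Pool-site or annotated-variant table.
#' @param mean_depth Named vector `c(mut = , wt = )` of genome-wide mean
#'   depths; computed from `sites` when `NULL`.
#' @param multiplier Cap as a multiple of the mean (default 2).
#' @return The retained rows of `sites`.
#' @export
depth_cap_filter <- function(sites, mean_depth = NULL, multiplier = 2.0) {
  dm <- sites$mut_ref + sites$mut_alt
  dw <- sites$wt_ref + sites$wt_alt
  if (is.null(mean_depth)) {
    mean_depth <- c(mut = mean(dm), wt = mean(dw))
  }
  if (anyNA(mean_depth[c("mut", "wt")]) || any(mean_depth[c("mut", "wt")] <= 0)) {
    stop("mean depth must be positive for both pools")
  }
  keep <- dm <= multiplier * mean_depth[["mut"]] &
    dw <= multiplier * mean_depth[["wt"]]
  sites[keep, , drop = FALSE]
}

#' Retain biallelic sites at or above a quality threshold
#'
#' Keeps sites with `qual >= min_qual` and exactly one alternate allele
#' (an `alt` field containing a comma marks a multiallelic record).
#'
#' @param sites Site table with `qual` and `alt`.
#' @param min_qual Minimum variant quality (default 200).
#' @return The retained rows.
#' @export
quality_biallelic_filter <- function(sites, min_qual = 200) {
  keep <- !is.na(sites$qual) & sites$qual >= min_qual &
    !grepl(",", sites$alt, fixed = TRUE)
  sites[keep, , drop = FALSE]
}

#' Retain variants with a moderate or high predicted impact
#'
#' @param variants Annotated-variant table with `impact_class`.
#' @return The retained rows; variants with an unknown class are excluded
#'   with a warning.
#' @export
impact_filter <- function(variants) {
  known <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  unknown <- !(variants$impact_class %in% known)
  if (any(unknown)) {
    warning(sum(unknown), " variant(s) with unknown impact class excluded")
  }
  variants[!unknown & variants$impact_class %in% c("MODERATE", "HIGH"), ,
           drop = FALSE]
}

#' Retain variants with dAF strictly above a threshold
#'
#' Under a recessive model with phenotype-selected pools the causal variant
#' is expected to show strong pool differentiation, so weakly
#' differentiated variants (dAF at or below the threshold) are unlikely to
#' explain the phenotype and are removed.
#'
#' @param variants Annotated-variant table with `daf`.
#' @param threshold Exclusion boundary (default 0.5; retention requires
#'   `daf > threshold`).
#' @return The retained rows.
#' @export
daf_criterion <- function(variants, threshold = 0.5) {
  variants[!is.na(variants$daf) & variants$daf > threshold, , drop = FALSE]
}

#' Retain variants whose alternate allele is absent from a reference panel
#'
#' A fully penetrant recessive allele private to the mutant strain should
#' not be carried by any unrelated sample; `panel_alt_observed = 0`
#' (including positions missing from the panel, which count as unobserved)
#' retains the variant.
#'
#' @param variants Annotated-variant table with `panel_alt_observed`.
#' @return The retained rows.
#' @export
panel_absence_filter <- function(variants) {
  obs <- variants$panel_alt_observed
  obs[is.na(obs)] <- 0L
  variants[obs == 0L, , drop = FALSE]
}

#' Run the candidate-variant prioritization cascade
#'
#' Applies, in order: restriction to the candidate interval, quality /
#' biallelic filter, depth cap, impact-class filter, dAF criterion, and
#' panel absence. The filters are pure intersections, so the final set is
#' order-independent; the stage-count report reflects the stated order.
#' Survivors are ranked by dAF descending, position ascending on ties.
#'
#' @param variants Annotated-variant table from [annotate_sites()].
#' @param interval `GRanges` of candidate intervals (e.g. from
#'   [call_candidate_interval()]); `NULL` skips the region restriction.
#' @param mean_depth,depth_multiplier Passed to [depth_cap_filter()]. The
#'   default `mean_depth = NULL` computes genome-wide means from the full
#'   `variants` table before any restriction.
#' @param min_qual Passed to [quality_biallelic_filter()].
#' @param daf_threshold Passed to [daf_criterion()].
#' @return List of class `cascade_report`: `stages` (`data.frame` of stage
#'   names and surviving counts) and `candidates` (ranked survivors).
#' @export
prioritize <- function(variants, interval = NULL, mean_depth = NULL,
                       depth_multiplier = 2.0, min_qual = 200,
                       daf_threshold = 0.5) {
  if (is.null(mean_depth)) {
    mean_depth <- c(mut = mean(variants$mut_ref + variants$mut_alt),
                    wt = mean(variants$wt_ref + variants$wt_alt))
  }
  stages <- list(input = variants)
  v <- variants
  if (!is.null(interval)) {
    gr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
    v <- v[IRanges::overlapsAny(gr, interval), , drop = FALSE]
  }
  stages$interval <- v
  v <- quality_biallelic_filter(v, min_qual)
  stages$quality_biallelic <- v
  v <- depth_cap_filter(v, mean_depth, depth_multiplier)
  stages$depth_cap <- v
  v <- impact_filter(v)
  stages$impact <- v
  v <- daf_criterion(v, daf_threshold)
  stages$daf <- v
  v <- panel_absence_filter(v)
  stages$panel_absence <- v
  ord <- order(-v$daf, v$pos)
  structure(list(
    stages = data.frame(stage = names(stages),
                        n_variants = vapply(stages, nrow, integer(1)),
                        row.names = NULL, stringsAsFactors = FALSE),
    candidates = v[ord, , drop = FALSE]
  ), class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Candidate-variant prioritization cascade\n")
  print(x$stages, row.names = FALSE)
  n <- nrow(x$candidates)
  cat(sprintf("final candidates: %d\n", n))
  if (n > 0) {
    show <- utils::head(x$candidates[, intersect(
      c("chrom", "pos", "ref", "alt", "consequence", "impact_class", "daf",
        "panel_alt_observed"), names(x$candidates))], 10L)
    print(show, row.names = FALSE)
  }
  invisible(x)
}
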