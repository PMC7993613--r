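#' Specify a simulated F2 intercross with phenotype-based pooling
#'
#' A `cross_design` captures every parameter of the simulated experiment:
#' the cross itself (one homozygous-mutant sire x one wild-type dam, F1
#' intercrossed to give `n_f2` F2 animals), the recessive phenotype with an
#' optional misclassification rate, the phenotype-based DNA pools, and the
#' pooled short-read sequencing (mean depth and per-read base error).
#'
#' Defaults reproduce the mapping design the package targets: 52 F2
#' animals, pools of 12 mutant-phenotype and 40 wild-type-phenotype
#' individuals sequenced to mean effective depths of 37.6X and 36.5X, and a
#' misclassification probability of 2/14 (two of the fourteen homozygous
#' mutants in such a cross were phenotyped as wild type at ~4 weeks).
#' The SNP grid emulates the density of a pool-seq callset (5 informative
#' SNPs/kb, so a 5,000-SNP window spans ~1 Mb as in a genome-wide scan at
#' ~10M markers) on a single 25-Mb chromosome with a uniform 1 cM/Mb map.
#'
#' @param n_f2 Number of F2 individuals.
#' @param pool_sizes Named numeric vector `c(mut = , wt = )`: maximum number
#'   of mutant-phenotype and wild-type-phenotype animals entering each pool.
#'   Animals are pooled by phenotype label; if fewer are available than the
#'   stated size, all available animals are pooled.
#' @param chrom_length_bp Physical chromosome length in bp.
#' @param recomb_rate Recombination rate in Morgans per bp (uniform map).
#' @param n_snps Number of founder-difference SNPs on the chromosome.
#' @param causal_pos bp coordinate of the recessive causal variant; it is
#'   snapped to the nearest simulated SNP.
#' @param misphenotype_prob Probability that a homozygous-mutant F2 is
#'   labeled wild type (incomplete penetrance / misphenotyping).
#' @param coverage Named numeric vector `c(mut = , wt = )` of mean
#'   sequencing depths per pool.
#' @param base_error Per-read, per-site probability that the observed
#'   allele is flipped (symmetric biallelic error).
#' @param seed Integer seed; identical seeds give bit-identical output
#'   across all `simulate_*` functions driven by the design.
#'
#' @return An object of class `cross_design` (a validated list).
#' @examples
#' d <- cross_design(n_snps = 1000, chrom_length_bp = 1e6, seed = 7)
#' d
#' @export
cross_design <- function(n_f2 = 52L,
                         pool_sizes = c(mut = 12L, wt = 40L),
                         chrom_length_bp = 25e6,
                         recomb_rate = 1e-8,
                         n_snps = 125000L,
                         causal_pos = 12.5e6,
                         misphenotype_prob = 2 / 14,
                         coverage = c(mut = 37.6, wt = 36.5),
                         base_error = 0.001,
                         seed = 1L) {
  d <- list(
    n_f2 = as.integer(n_f2),
    pool_sizes = stats::setNames(as.integer(pool_sizes[c("mut", "wt")]), c("mut", "wt")),
    chrom_length_bp = as.numeric(chrom_length_bp),
    recomb_rate = as.numeric(recomb_rate),
    n_snps = as.integer(n_snps),
    causal_pos = as.numeric(causal_pos),
    misphenotype_prob = as.numeric(misphenotype_prob),
    coverage = stats::setNames(as.numeric(coverage[c("mut", "wt")]), c("mut", "wt")),
    base_error = as.numeric(base_error),
    seed = as.integer(seed)
  )
  validate_cross_design(d)
  structure(d, class = "cross_design")
}

validate_cross_design <- function(d) {
  stop_invalid <- function(msg) stop("invalid cross design: ", msg, call. = FALSE)
  if (is.na(d$n_f2) || d$n_f2 < 1L) stop_invalid("n_f2 must be >= 1")
  if (anyNA(d$pool_sizes) || any(d$pool_sizes < 1L)) {
    stop_invalid("pool sizes must be named c(mut=, wt=) and >= 1")
  }
  if (sum(d$pool_sizes) > d$n_f2) stop_invalid("pool sizes sum exceeds n_f2")
  if (!is.finite(d$chrom_length_bp) || d$chrom_length_bp <= 0) {
    stop_invalid("chromosome length must be positive")
  }
  if (!is.finite(d$recomb_rate) || d$recomb_rate < 0) {
    stop_invalid("recombination rate must be non-negative")
  }
  if (is.na(d$n_snps) || d$n_snps < 1L) stop_invalid("n_snps must be >= 1")
  if (d$causal_pos < 1 || d$causal_pos > d$chrom_length_bp) {
    stop_invalid("causal_pos outside chromosome")
  }
  if (d$misphenotype_prob < 0 || d$misphenotype_prob > 1) {
    stop_invalid("misphenotype_prob must be in [0,1]")
  }
  if (anyNA(d$coverage) || any(d$coverage <= 0)) {
    stop_invalid("coverage must be positive for both pools")
  }
  if (d$base_error < 0 || d$base_error > 1) {
    stop_invalid("base_error must be in [0,1]")
  }
  invisible(d)
}

#' @export
print.cross_design <- function(x, ...) {
  cat("F2 intercross pool-seq design\n")
  cat(sprintf("  F2 individuals : %d (pools mut=%d, wt=%d; misphenotype %.3f)\n",
              x$n_f2, x$pool_sizes["mut"], x$pool_sizes["wt"],
              x$misphenotype_prob))
  cat(sprintf("  chromosome     : %.3g bp, %.3g Morgans, %d SNPs\n",
              x$chrom_length_bp, x$chrom_length_bp * x$recomb_rate, x$n_snps))
  cat(sprintf("  causal variant : %.0f bp\n", x$causal_pos))
  cat(sprintf("  sequencing     : %.1fX / %.1fX mean depth, base error %.2g, seed %d\n",
              x$coverage["mut"], x$coverage["wt"], x$base_error, x$seed))
  invisible(x)
}

#' Read a cross design from a JSON configuration file
#'
#' Fields mirror the arguments of [cross_design()]; absent fields fall back
#' to the defaults.
#'
#' @param path Path to a JSON file.
#' @return A `cross_design`.
#' @export
read_design_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_pair <- function(x) {
    x <- unlist(x)
    if (is.null(names(x)) && length(x) == 2L) names(x) <- c("mut", "wt")
    x
  }
  if (!is.null(cfg$pool_sizes)) cfg$pool_sizes <- fix_pair(cfg$pool_sizes)
  if (!is.null(cfg$coverage)) cfg$coverage <- fix_pair(cfg$coverage)
  do.call(cross_design, cfg)
}

# Run expr with a temporary RNG seed, restoring global RNG state after.
local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a sub-seed for a pipeline stage, kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
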