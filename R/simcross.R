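#' Simulate founder haplotypes carrying fixed differences
#'
#' Constructs the two founder diplotypes of the cross: a mutant-strain
#' founder homozygous for the alternate allele at every SNP (including the
#' causal variant) and a wild-type founder homozygous for the reference
#' allele. Every SNP is therefore a fixed difference and fully informative
#' about founder origin, the idealization under which pool-seq bulked
#' segregant analysis is usually modeled.
#'
#' SNP positions are drawn uniformly along the chromosome and sorted; the
#' causal variant is snapped to the nearest SNP.
#'
#' @param design A [cross_design()].
#' @return A list of class `founder_set` with elements `positions` (sorted
#'   bp), `causal_index` (SNP rank of the causal variant), `ref`/`alt`
#'   (allele bases per SNP), and the design.
#' @export
simulate_founders <- function(design) {
  validate_cross_design(design)
  local_seed(derive_seed(design$seed, 1L), {
    pos <- sort(sample.int(design$chrom_length_bp, design$n_snps))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, design$n_snps, replace = TRUE)
    alt <- bases[(match(ref, bases) - 1L +
                    sample.int(3L, design$n_snps, replace = TRUE)) %% 4L + 1L]
    structure(list(
      positions = pos,
      causal_index = which.min(abs(pos - design$causal_pos)),
      ref = ref,
      alt = alt,
      design = design
    ), class = "founder_set")
  })
}

# F1 gametes under Haldane's model: crossover count ~ Poisson(L Morgans),
# crossover positions uniform, no interference. Returns an n_gametes x
# n_snps 0/1 matrix of mutant-founder origin.
simulate_gametes <- function(founders, n_gametes, seed) {
  design <- founders$design
  L <- design$chrom_length_bp * design$recomb_rate
  local_seed(seed, {
    out <- matrix(0L, nrow = n_gametes, ncol = length(founders$positions))
    for (g in seq_len(n_gametes)) {
      k <- stats::rpois(1L, L)
      breaks <- if (k > 0) sort(stats::runif(k, 0, design$chrom_length_bp)) else numeric(0)
      phase <- sample.int(2L, 1L) - 1L
      seg <- findInterval(founders$positions, breaks)
      out[g, ] <- (seg + phase) %% 2L
    }
    out
  })
}

#' Simulate an F2 intercross from founder haplotypes
#'
#' F1 animals are heterozygous at every SNP; each F2 receives two
#' independent F1 gametes formed under Haldane's model (Poisson crossover
#' count, uniform positions, no interference). The phenotype follows the
#' recessive rule at the causal SNP: homozygous mutants are labeled
#' `mutant` except with probability `misphenotype_prob`, in which case they
#' are labeled `wildtype` (all other genotypes are always `wildtype`).
#'
#' @param founders A `founder_set` from [simulate_founders()].
#' @param design Optional design override; defaults to the design stored in
#'   `founders`.
#' @return A list of class `f2_cohort`: `genotypes` (n_f2 x n_snps mutant
#'   allele dose 0/1/2), `phenotype` (factor `mutant`/`wildtype`),
#'   `causal_genotype` (dose at the causal SNP), `positions`,
#'   `causal_index`, and the design.
#' @export
simulate_f2_cross <- function(founders, design = founders$design) {
  validate_cross_design(design)
  if (design$chrom_length_bp <= 0) stop("invalid cross design: zero-length chromosome")
  gam1 <- simulate_gametes(founders, design$n_f2, derive_seed(design$seed, 2L))
  gam2 <- simulate_gametes(founders, design$n_f2, derive_seed(design$seed, 3L))
  geno <- gam1 + gam2
  causal <- geno[, founders$causal_index]
  pheno <- local_seed(derive_seed(design$seed, 4L), {
    lab <- ifelse(causal == 2L, "mutant", "wildtype")
    flip <- stats::runif(design$n_f2) < design$misphenotype_prob
    lab[causal == 2L & flip] <- "wildtype"
    factor(lab, levels = c("mutant", "wildtype"))
  })
  structure(list(
    genotypes = geno,
    phenotype = pheno,
    causal_genotype = causal,
    positions = founders$positions,
    causal_index = founders$causal_index,
    ref = founders$ref,
    alt = founders$alt,
    design = design
  ), class = "f2_cohort")
}

# Sequencing layer shared by linked and unlinked simulators: depth per pool
# ~ Poisson(mean coverage), alt reads ~ Binomial(depth, pool allele
# frequency), then reads flipped with probability base_error.
sample_pool_reads <- function(freq, mean_depth, base_error) {
  n <- length(freq)
  depth <- stats::rpois(n, mean_depth)
  alt_true <- stats::rbinom(n, depth, freq)
  alt_obs <- stats::rbinom(n, alt_true, 1 - base_error) +
    stats::rbinom(n, depth - alt_true, base_error)
  list(ref = depth - alt_obs, alt = alt_obs)
}

#' Pool F2 animals by phenotype and simulate pooled sequencing
#'
#' All mutant-labeled animals (up to `pool_sizes["mut"]`) enter the mutant
#' pool and wild-type-labeled animals (up to `pool_sizes["wt"]`) the
#' wild-type pool. Per SNP and pool, read depth is Poisson around the
#' pool's mean coverage, alternate-read counts are binomial in the pool
#' allele frequency, and each read is flipped with probability
#' `base_error`.
#'
#' @param cohort An `f2_cohort` from [simulate_f2_cross()].
#' @param design Optional design override.
#' @param chrom Chromosome name used in the output table.
#' @return A `data.frame` of pool sites with columns `chrom`, `pos`, `ref`,
#'   `alt`, `qual`, `mut_ref`, `mut_alt`, `wt_ref`, `wt_alt` plus truth
#'   columns `truth_mut_af`, `truth_wt_af` (true pool allele frequencies)
#'   and attribute `pools` (row indices of the pooled animals).
#' @export
pool_and_sequence <- function(cohort, design = cohort$design, chrom = "chr1") {
  validate_cross_design(design)
  mut_ids <- which(cohort$phenotype == "mutant")
  wt_ids <- which(cohort$phenotype == "wildtype")
  if (length(mut_ids) == 0L || length(wt_ids) == 0L) {
    stop("invalid cross design: a pool has zero individuals")
  }
  mut_ids <- utils::head(mut_ids, design$pool_sizes["mut"])
  wt_ids <- utils::head(wt_ids, design$pool_sizes["wt"])
  fmut <- colSums(cohort$genotypes[mut_ids, , drop = FALSE]) / (2 * length(mut_ids))
  fwt <- colSums(cohort$genotypes[wt_ids, , drop = FALSE]) / (2 * length(wt_ids))
  local_seed(derive_seed(design$seed, 5L), {
    mut <- sample_pool_reads(fmut, design$coverage["mut"], design$base_error)
    wt <- sample_pool_reads(fwt, design$coverage["wt"], design$base_error)
    qual <- round(stats::runif(length(fmut), 500, 3000), 1)
    sites <- data.frame(
      chrom = chrom,
      pos = cohort$positions,
      ref = cohort$ref,
      alt = cohort$alt,
      qual = qual,
      mut_ref = mut$ref, mut_alt = mut$alt,
      wt_ref = wt$ref, wt_alt = wt$alt,
      truth_mut_af = fmut, truth_wt_af = fwt,
      stringsAsFactors = FALSE
    )
    attr(sites, "pools") <- list(mut = mut_ids, wt = wt_ids)
    attr(sites, "causal_index") <- cohort$causal_index
    sites
  })
}

#' Simulate pooled read counts at SNPs unlinked to the causal locus
#'
#' Serves as the genome-wide null background: at a founder-difference SNP
#' unlinked to the selected locus, every F2 chromosome carries the mutant
#' founder allele independently with probability 1/2 regardless of
#' phenotype, so the pool allele frequency is Binomial(2n, 1/2)/2n.
#' Sequencing noise is layered on exactly as in [pool_and_sequence()].
#'
#' @param design A [cross_design()]; only pool sizes, coverage, base error
#'   and seed are used.
#' @param n_sites Number of unlinked SNPs.
#' @param seed Optional seed override (default derived from the design).
#' @param chrom Chromosome label for the output.
#' @return A pool-site `data.frame` as in [pool_and_sequence()].
#' @export
simulate_unlinked_sites <- function(design, n_sites, seed = NULL, chrom = "chrU") {
  validate_cross_design(design)
  n_sites <- as.integer(n_sites)
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (is.null(seed)) seed <- derive_seed(design$seed, 6L)
  local_seed(seed, {
    fmut <- stats::rbinom(n_sites, 2L * design$pool_sizes["mut"], 0.5) /
      (2 * design$pool_sizes["mut"])
    fwt <- stats::rbinom(n_sites, 2L * design$pool_sizes["wt"], 0.5) /
      (2 * design$pool_sizes["wt"])
    mut <- sample_pool_reads(fmut, design$coverage["mut"], design$base_error)
    wt <- sample_pool_reads(fwt, design$coverage["wt"], design$base_error)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- bases[(match(ref, bases) - 1L +
                    sample.int(3L, n_sites, replace = TRUE)) %% 4L + 1L]
    data.frame(
      chrom = chrom,
      pos = seq_len(n_sites) * 1000L,
      ref = ref, alt = alt,
      qual = round(stats::runif(n_sites, 500, 3000), 1),
      mut_ref = mut$ref, mut_alt = mut$alt,
      wt_ref = wt$ref, wt_alt = wt$alt,
      truth_mut_af = fmut, truth_wt_af = fwt,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a reference panel of unrelated samples lacking the causal allele
#'
#' Emulates a panel of unrelated animals (wild populations plus other
#' domestic breeds) used to test whether a candidate allele segregates
#' outside the mapping cross. Founder-difference SNPs between two domestic
#' lineages are overwhelmingly common variants in the wider species, so
#' non-causal sites are polymorphic with allele frequencies drawn uniformly
#' from `maf_range`; the causal site carries the wild-type allele in every
#' panel sample by construction.
#'
#' @param founders A `founder_set`.
#' @param n_samples Panel size (default 20, mirroring a 14 + 6 sample
#'   panel of wild populations and domestic breeds).
#' @param maf_range Range of population alternate-allele frequencies for
#'   non-causal sites.
#' @param seed Integer seed (default derived from the design).
#' @return A list of class `reference_panel`: `genotypes` (n_samples x
#'   n_snps alt dose), `positions`, `alt_carriers` (per-SNP count of
#'   samples carrying the alt allele), `causal_index`.
#' @export
simulate_reference_panel <- function(founders, n_samples = 20L,
                                     maf_range = c(0.1, 0.5), seed = NULL) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (is.null(seed)) seed <- derive_seed(founders$design$seed, 7L)
  n_snps <- length(founders$positions)
  local_seed(seed, {
    af <- stats::runif(n_snps, maf_range[1], maf_range[2])
    geno <- matrix(stats::rbinom(n_samples * n_snps, 2L, rep(af, each = n_samples)),
                   nrow = n_samples)
    geno[, founders$causal_index] <- 0L
    structure(list(
      genotypes = geno,
      positions = founders$positions,
      alt_carriers = as.integer(colSums(geno > 0L)),
      causal_index = founders$causal_index
    ), class = "reference_panel")
  })
}

#' Simulate variant-consequence annotations for a pool-site table
#'
#' Assigns SnpEff-style consequence labels to simulated SNPs at rates that
#' emulate an annotated mammalian callset (~0.3% of SNPs with a
#' protein-impact consequence, i.e. roughly a dozen impact variants per Mb
#' at ~4 SNPs/kb). The causal site is always labeled `splice_donor_variant`
#' (HIGH impact). Annotation is consumed, not computed, by the filtering
#' cascade, mirroring the use of an external effect predictor.
#'
#' @param sites Pool-site `data.frame` (needs a `pos` column).
#' @param causal_index Row index of the causal variant (defaults to the
#'   `causal_index` attribute set by [pool_and_sequence()]).
#' @param seed Integer seed.
#' @return `data.frame` with `pos`, `consequence`, `impact_class`.
#' @export
simulate_annotations <- function(sites, causal_index = attr(sites, "causal_index"),
                                 seed = 1L) {
  stopifnot(is.data.frame(sites), !is.null(causal_index))
  terms <- c(
    intergenic_variant = 0.55, intron_variant = 0.30,
    upstream_gene_variant = 0.06, downstream_gene_variant = 0.06,
    synonymous_variant = 0.027,
    missense_variant = 0.0024, frameshift_variant = 3e-4,
    stop_gained = 2e-4, stop_lost = 5e-5,
    splice_donor_variant = 5e-5, splice_acceptor_variant = 5e-5
  )
  local_seed(seed, {
    cons <- sample(names(terms), nrow(sites), replace = TRUE, prob = terms)
    cons[causal_index] <- "splice_donor_variant"
    tbl <- impact_class_table()
    data.frame(
      pos = sites$pos,
      consequence = cons,
      impact_class = tbl$impact_class[match(cons, tbl$consequence)],
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate barcoded noisy amplicon reads from an isoform mixture
#'
#' Each read is `barcode + adapter + template`, where the template is the
#' transcript sequence of one isoform drawn from `mixture` and sequencing
#' noise is a symmetric substitution applied to the template at
#' `error_rate` per base (barcode and adapter are written error-free, so
#' demultiplexing losses are exercised separately by mutating prefixes in
#' tests). Truth labels are retained for validation.
#'
#' @param isoforms A list of isoform models from [build_isoforms()] (or any
#'   list with `isoform_id` and `transcript` elements).
#' @param mixture Numeric vector of isoform proportions, summing to 1
#'   (tolerance 1e-9), one per isoform.
#' @param barcode 7-character sample barcode.
#' @param adapter Adapter overhang appended after the barcode (default a
#'   fixed 10-mer).
#' @param n_reads Number of reads to simulate.
#' @param error_rate Per-base substitution probability on the template.
#' @param seed Integer seed.
#' @return A `data.frame` with `read_id`, `sequence`, and truth column
#'   `true_isoform`.
#' @export
simulate_amplicon_reads <- function(isoforms, mixture, barcode,
                                    adapter = "ACGTACGTAC", n_reads = 1000L,
                                    error_rate = 0.1, seed = 1L) {
  if (abs(sum(mixture) - 1) > 1e-9 || any(mixture < 0)) {
    stop("invalid mixture: proportions must be non-negative and sum to 1")
  }
  if (length(mixture) != length(isoforms)) {
    stop("invalid mixture: one proportion per isoform required")
  }
  if (nchar(barcode) != 7L) stop("barcode must be exactly 7 characters")
  templates <- vapply(isoforms, function(x) x$transcript, character(1))
  ids <- vapply(isoforms, function(x) x$isoform_id, character(1))
  bases <- c("A", "C", "G", "T")
  local_seed(seed, {
    pick <- sample.int(length(ids), n_reads, replace = TRUE, prob = mixture)
    seqs <- vapply(pick, function(i) {
      tpl <- strsplit(templates[i], "")[[1]]
      err <- stats::runif(length(tpl)) < error_rate
      if (any(err)) {
        tpl[err] <- vapply(tpl[err], function(b) {
          sample(setdiff(bases, b), 1L)
        }, character(1))
      }
      paste0(barcode, adapter, paste(tpl, collapse = ""))
    }, character(1))
    data.frame(
      read_id = sprintf("read_%s_%06d", barcode, seq_len(n_reads)),
      sequence = seqs,
      true_isoform = ids[pick],
      stringsAsFactors = FALSE
    )
  })
}
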