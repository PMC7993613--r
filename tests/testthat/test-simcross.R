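test_that("founder construction gives fixed differences and snaps the causal SNP", {
  d <- tiny_design(n_snps = 10L)
  f <- simulate_founders(d)
  expect_length(f$positions, 10L)
  expect_false(is.unsorted(f$positions))
  expect_true(all(f$ref != f$alt))
  expect_equal(f$causal_index, which.min(abs(f$positions - d$causal_pos)))
  # determinism contract
  f2 <- simulate_founders(tiny_design(n_snps = 10L))
  expect_identical(f, f2)
  expect_error(cross_design(n_snps = 0), "invalid cross design")
})

test_that("F2 genotypes segregate 1:2:1 at the causal locus", {
  d <- tiny_design(n_f2 = 10000L, n_snps = 10L, pool_sizes = c(mut = 12, wt = 40))
  co <- simulate_f2_cross(simulate_founders(d))
  counts <- tabulate(co$causal_genotype + 1L, 3L)
  p <- chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
  expect_gt(p, 0.01)
  # recessive rule is exact with misphenotype_prob = 0
  expect_identical(co$phenotype == "mutant", co$causal_genotype == 2L)
})

test_that("gamete recombinant fraction follows the Haldane map function", {
  # two SNPs 0.01 Morgans apart: expected r = (1 - exp(-0.02)) / 2
  d <- cross_design(n_f2 = 2L, pool_sizes = c(mut = 1, wt = 1),
                    chrom_length_bp = 1e6, recomb_rate = 1e-8, n_snps = 2L,
                    causal_pos = 1L, seed = 11L)
  founders <- structure(list(positions = c(1, 1e6), design = d),
                        class = "founder_set")
  gam <- bsamap:::simulate_gametes(founders, 40000L, seed = 12L)
  r_obs <- mean(gam[, 1] != gam[, 2])
  r_exp <- (1 - exp(-0.02)) / 2
  expect_lt(abs(r_obs - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / 40000))
})

test_that("misphenotyping sends homozygous mutants to the wild-type label only", {
  d <- tiny_design(n_f2 = 4000L, n_snps = 20L, misphenotype_prob = 0.3)
  co <- simulate_f2_cross(simulate_founders(d))
  # non-mutant genotypes are never labeled mutant
  expect_true(all(co$causal_genotype[co$phenotype == "mutant"] == 2L))
  flipped <- co$causal_genotype == 2L & co$phenotype == "wildtype"
  rate <- sum(flipped) / sum(co$causal_genotype == 2L)
  expect_lt(abs(rate - 0.3), 0.05)
})

test_that("pooled sequencing has Poisson depth and unbiased allele frequencies", {
  d <- tiny_design(n_snps = 10000L, base_error = 0)
  s <- pool_and_sequence(simulate_f2_cross(simulate_founders(d)))
  depth_mut <- s$mut_ref + s$mut_alt
  expect_lt(abs(mean(depth_mut) / d$coverage["mut"] - 1), 0.01)
  expect_lt(abs(mean(s$wt_ref + s$wt_alt) / d$coverage["wt"] - 1), 0.01)
  # binomial read sampling is unbiased for the true pool frequency
  obs <- s$mut_alt / depth_mut
  expect_lt(abs(mean(obs - s$truth_mut_af, na.rm = TRUE)), 0.005)
  # degenerate case: monomorphic pool, no error, no alt reads
  mono <- s[s$truth_mut_af == 0, ]
  expect_true(all(mono$mut_alt == 0))
})

test_that("pooling respects phenotype labels and stated pool sizes", {
  d <- tiny_design(n_f2 = 52L, pool_sizes = c(mut = 12, wt = 40))
  co <- simulate_f2_cross(simulate_founders(d))
  s <- pool_and_sequence(co)
  pools <- attr(s, "pools")
  expect_true(all(co$phenotype[pools$mut] == "mutant"))
  expect_true(all(co$phenotype[pools$wt] == "wildtype"))
  expect_lte(length(pools$mut), 12L)
  expect_lte(length(pools$wt), 40L)
})

test_that("unlinked background sites match pool-frequency expectations", {
  d <- cross_design(seed = 5L)
  s <- simulate_unlinked_sites(d, 20000L)
  # mean truth frequency 1/2 in both pools, no phenotype selection
  expect_lt(abs(mean(s$truth_mut_af) - 0.5), 0.005)
  expect_lt(abs(mean(s$truth_wt_af) - 0.5), 0.005)
  expect_identical(s, simulate_unlinked_sites(d, 20000L))
})

test_that("reference panel lacks the causal allele and is otherwise polymorphic", {
  d <- tiny_design(n_snps = 500L)
  f <- simulate_founders(d)
  p <- simulate_reference_panel(f, n_samples = 20L)
  expect_identical(nrow(p$genotypes), 20L)
  expect_identical(p$alt_carriers[f$causal_index], 0L)
  expect_gt(mean(p$alt_carriers > 0), 0.95)
  expect_identical(p$genotypes,
                   simulate_reference_panel(f, n_samples = 20L)$genotypes)
})

test_that("amplicon reads follow the mixture and carry exact prefixes", {
  g <- synthetic_gene_model(seed = 3L)
  iso <- build_isoforms(g, attr(g, "target_intron"), c(8L, 15L, 221L))
  mix <- c(0.4, 0.5, 0.1, 0)
  reads <- simulate_amplicon_reads(iso, mix, barcode = "AACCGGT",
                                   n_reads = 1000L, error_rate = 0.05, seed = 8L)
  expect_true(all(substr(reads$sequence, 1, 7) == "AACCGGT"))
  counts <- table(factor(reads$true_isoform,
                         levels = vapply(iso, `[[`, "", "isoform_id")))
  sds <- sqrt(1000 * mix * (1 - mix))
  expect_true(all(abs(counts - 1000 * mix) <= 3 * sds + 1e-9))
  # degenerate error rate: reads equal template with prefix
  clean <- simulate_amplicon_reads(iso[1], 1, barcode = "AACCGGT",
                                   n_reads = 5L, error_rate = 0, seed = 8L)
  expect_true(all(clean$sequence ==
                    paste0("AACCGGT", "ACGTACGTAC", iso[[1]]$transcript)))
  expect_error(simulate_amplicon_reads(iso, c(0.5, 0.5, 0.2, 0), "AACCGGT"),
               "invalid mixture")
  expect_error(simulate_amplicon_reads(iso[1], 1, barcode = "ACGT"),
               "7 characters")
})
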