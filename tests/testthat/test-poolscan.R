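test_that("per-site dAF arithmetic and zero-depth signaling", {
  s <- data.frame(
    mut_ref = c(0, 10, 20, 0), mut_alt = c(37, 10, 20, 0),
    wt_ref = c(28, 20, 40, 5), wt_alt = c(9, 20, 0, 5)
  )
  daf <- site_delta_af(s)
  expect_equal(daf[1], abs(1 - 9 / 37), tolerance = 1e-12)
  expect_equal(daf[2], 0)
  expect_equal(daf[3], 0.5)
  expect_true(is.na(daf[4]))
  expect_identical(attr(daf, "excluded"), 4L)
})

test_that("window enumeration matches brute-force enumeration", {
  # stated examples: 9,000 SNPs -> 6 windows; 3,999 -> 0; 5,000 -> 1
  n9 <- make_sites(9000)
  w <- make_windows(n9, 5000, 1000, 4000)
  expect_identical(nrow(w), 6L)
  expect_identical(w$first_snp_index, as.integer(seq(1, 5001, 1000)))
  expect_identical(w$n_snps[6], 4000L)
  expect_identical(nrow(make_windows(make_sites(3999), 5000, 1000, 4000)), 0L)
  # a 5,000-SNP chromosome: the full window at rank 1 plus the truncated
  # 4,000-SNP span starting at rank 1001, which meets the minimum exactly
  expect_identical(nrow(make_windows(make_sites(5000), 5000, 1000, 4000)), 2L)
  expect_identical(nrow(make_windows(make_sites(4999), 5000, 1000, 4000)), 1L)
  # randomized multi-chromosome tables against the oracle
  withr::with_seed(21, {
    for (rep in 1:8) {
      sizes <- sample(50:2000, sample(1:4, 1))
      sites <- do.call(rbind, lapply(seq_along(sizes), function(i) {
        make_sites(sizes[i], chrom = paste0("chr", i), seed = rep * 10 + i)
      }))
      window <- sample(20:800, 1); step <- sample(5:400, 1)
      minsn <- sample(seq_len(window), 1)
      got <- make_windows(sites, window, step, minsn)
      want <- oracle_windows(sizes, window, step, minsn)
      if (is.null(want)) {
        expect_identical(nrow(got), 0L)
      } else {
        expect_identical(got$first_snp_index, as.integer(want[, 2]))
        expect_identical(got$last_snp_index, as.integer(want[, 3]))
      }
    }
  })
  bad <- make_sites(100)
  bad$pos <- rev(bad$pos)
  expect_error(make_windows(bad), "sorted")
})

test_that("window Hp equals the direct formula and hits its bounds", {
  # (30,10) and (20,20): 2*50*30/80^2
  s <- data.frame(mut_ref = c(30, 20), mut_alt = c(10, 20),
                  wt_ref = c(40, 40), wt_alt = c(0, 0))
  expect_equal(window_hp(s, "mut"), 0.46875)
  expect_equal(window_hp(s, "wt"), 0)          # fixed pool
  s2 <- data.frame(mut_ref = c(20, 30), mut_alt = c(20, 30),
                   wt_ref = 1, wt_alt = 1)
  expect_equal(window_hp(s2, "mut"), 0.5)      # balanced counts: maximum
  s3 <- data.frame(mut_ref = 0, mut_alt = 0, wt_ref = 0, wt_alt = 0)
  expect_true(is.na(window_hp(s3, "mut")))
})

test_that("vectorized scan agrees with per-window recomputation", {
  sites <- make_sites(3000, seed = 33)
  w <- pool_scan(sites, window_snps = 400, step_snps = 150, min_snps = 200)
  expect_gt(nrow(w), 5)
  for (i in sample(nrow(w), 5)) {
    a <- w$first_snp_index[i]; b <- w$last_snp_index[i]
    expect_equal(w$mean_daf[i], window_delta_af(sites, a, b))
    expect_equal(w$hp_mut[i], window_hp(sites, "mut", a, b))
    expect_equal(w$hp_wt[i], window_hp(sites, "wt", a, b))
    expect_equal(w$hp_ratio[i], hp_ratio(w$hp_mut[i], w$hp_wt[i]))
  }
  expect_true(all(w$mean_daf >= 0 & w$mean_daf <= 1))
  expect_true(all(w$hp_mut >= 0 & w$hp_mut <= 0.5))
})

test_that("Hp and mean dAF are invariant to ref/alt label swaps", {
  sites <- make_sites(500, seed = 44)
  swap <- withr::with_seed(45, runif(500) < 0.5)
  flipped <- sites
  flipped[swap, c("mut_ref", "mut_alt")] <- sites[swap, c("mut_alt", "mut_ref")]
  flipped[swap, c("wt_ref", "wt_alt")] <- sites[swap, c("wt_alt", "wt_ref")]
  w1 <- pool_scan(sites, 100, 50, 50)
  w2 <- pool_scan(flipped, 100, 50, 50)
  expect_equal(w1$hp_mut, w2$hp_mut)
  expect_equal(w1$hp_wt, w2$hp_wt)
  expect_equal(w1$mean_daf, w2$mean_daf)
})

test_that("hp_ratio stabilization and orientation", {
  expect_equal(hp_ratio(0.3, 0.3), 1, tolerance = 1e-3)
  expect_equal(hp_ratio(0, 0.4), 0.4001 / 1e-4)
  expect_gte(hp_ratio(0, 0.4), 100)
  expect_equal(hp_ratio(0, 0.4, orientation = "mut_over_wt"), 1e-4 / 0.4001)
  expect_true(is.na(hp_ratio(NA_real_, 0.4)))
})

test_that("empirical top fraction uses ceiling and includes ties", {
  r <- empirical_top_fraction(1:100, 0.01)
  expect_equal(r$threshold, 100)
  expect_identical(sum(r$flags), 1L)
  expect_identical(sum(empirical_top_fraction(1:200, 0.01)$flags), 2L)
  tied <- c(1:98, 99, 99)
  rt <- empirical_top_fraction(tied, 0.01)
  expect_equal(rt$threshold, 99)
  expect_identical(sum(rt$flags), 2L)  # both tied values flagged
  expect_error(empirical_top_fraction(c(NA, NaN)), "finite")
})

test_that("candidate interval calling merges flagged spans like the oracle", {
  w <- data.frame(chrom = "chr1",
                  start_pos = c(100, 150, 400, 600),
                  end_pos = c(200, 250, 500, 700))
  got <- call_candidate_interval(w, rep(TRUE, 4))
  want <- oracle_merge(w$start_pos, w$end_pos)
  expect_equal(GenomicRanges::start(got), want[, 1])
  expect_equal(GenomicRanges::end(got), want[, 2])
  # book-ended spans merge; disjoint spans stay separate
  w2 <- data.frame(chrom = "chr1", start_pos = c(100, 201), end_pos = c(200, 300))
  expect_identical(length(call_candidate_interval(w2, c(TRUE, TRUE))), 1L)
  expect_identical(length(call_candidate_interval(w, c(TRUE, FALSE, TRUE, FALSE))), 2L)
  expect_identical(length(call_candidate_interval(w, rep(FALSE, 4))), 0L)
  # randomized against the oracle
  withr::with_seed(71, {
    for (rep in 1:10) {
      n <- sample(2:30, 1)
      st <- sample.int(1000, n)
      en <- st + sample.int(100, n)
      wr <- data.frame(chrom = "chr1", start_pos = st, end_pos = en)
      got <- call_candidate_interval(wr, rep(TRUE, n))
      want <- oracle_merge(st, en)
      expect_equal(cbind(GenomicRanges::start(got), GenomicRanges::end(got)),
                   unname(want))
    }
  })
})
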