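# deterministic cascade fixture mirroring the shape of a real candidate
# region: 69 impact variants, 61 weakly differentiated, 8 strong, of which
# exactly one (the causal splice-donor variant) is absent from the panel
cascade_fixture <- function() {
  n <- 69L
  withr::with_seed(13, {
    v <- data.frame(
      chrom = "chr1",
      pos = sort(sample.int(5.4e6, n)) + 6e7,
      ref = "G", alt = "A",
      qual = runif(n, 250, 3000),
      stringsAsFactors = FALSE
    )
    daf <- c(runif(61, 0.05, 0.5), 0.76, runif(7, 0.55, 0.75))[sample.int(n)]
    causal <- which(daf == 0.76)
    depth <- function() rpois(n, 37)
    v$mut_ref <- pmax(0L, as.integer(round(depth() * (1 - pmin(1, 0.3 + daf)))))
    v$mut_alt <- as.integer(round(37 * pmin(1, 0.3 + daf)))
    v$wt_ref <- as.integer(round(36 * 0.7))
    v$wt_alt <- as.integer(round(36 * 0.3))
    v$consequence <- sample(c("missense_variant", "frameshift_variant",
                              "stop_gained"), n, replace = TRUE)
    v$consequence[causal] <- "splice_donor_variant"
    tbl <- impact_class_table()
    v$impact_class <- tbl$impact_class[match(v$consequence, tbl$consequence)]
    v$daf <- daf
    v$panel_alt_observed <- sample(1:15, n, replace = TRUE)
    v$panel_alt_observed[causal] <- 0L
    attr(v, "causal_pos") <- v$pos[causal]
    v
  })
}

test_that("depth cap discards only sites strictly above the cap", {
  s <- data.frame(chrom = "chr1", pos = 1:3, ref = "A", alt = "G", qual = 900,
                  mut_ref = c(40, 40, 20), mut_alt = c(41, 40, 20),
                  wt_ref = c(20, 20, 20), wt_alt = c(16, 16, 16))
  kept <- depth_cap_filter(s, mean_depth = c(mut = 40, wt = 36), multiplier = 2)
  expect_identical(kept$pos, 2:3)   # depth 81 dropped, 80 retained
  expect_identical(nrow(depth_cap_filter(s, c(mut = 40.5, wt = 36))), 3L)
  expect_error(depth_cap_filter(s, c(mut = 0, wt = 36)), "positive")
})

test_that("quality and biallelic filtering at the stated boundary", {
  s <- data.frame(chrom = "chr1", pos = 1:4, ref = "A",
                  alt = c("G", "G", "G,T", "G"),
                  qual = c(199, 200, 900, NA),
                  mut_ref = 1, mut_alt = 1, wt_ref = 1, wt_alt = 1)
  expect_identical(quality_biallelic_filter(s)$pos, 2L)
  expect_identical(nrow(quality_biallelic_filter(s[0, ])), 0L)
})

test_that("impact classes gate exactly MODERATE and HIGH", {
  v <- data.frame(pos = 1:5,
                  impact_class = c("LOW", "HIGH", "MODERATE", "MODIFIER", "weird"))
  expect_warning(kept <- impact_filter(v), "unknown impact class")
  expect_identical(kept$pos, 2:3)
})

test_that("dAF criterion is strict at 0.5", {
  v <- data.frame(pos = 1:4, daf = c(0.5, 0.51, 0.76, NA))
  expect_identical(daf_criterion(v)$pos, 2:3)
  expect_identical(nrow(daf_criterion(data.frame(pos = 1, daf = 0.2))), 0L)
})

test_that("panel absence retains zero-observation and missing positions", {
  v <- data.frame(pos = 1:3, panel_alt_observed = c(1L, 0L, NA))
  expect_identical(panel_absence_filter(v)$pos, 2:3)
})

test_that("cascade reproduces the 69 -> 8 -> 1 funnel on the fixture", {
  v <- cascade_fixture()
  rep <- prioritize(v, interval = NULL, mean_depth = c(mut = 37, wt = 36),
                    min_qual = 200, daf_threshold = 0.5)
  st <- rep$stages
  expect_identical(st$n_variants[st$stage == "input"], 69L)
  expect_identical(st$n_variants[st$stage == "daf"], 8L)
  expect_identical(st$n_variants[st$stage == "panel_absence"], 1L)
  expect_identical(rep$candidates$pos[1], attr(v, "causal_pos"))
  expect_equal(rep$candidates$daf[1], 0.76)
  # stage counts never increase
  expect_true(all(diff(st$n_variants) <= 0))
})

test_that("filters are idempotent and order-independent in their final set", {
  v <- cascade_fixture()
  v$qual[5] <- 100
  filters <- list(
    function(x) quality_biallelic_filter(x, 200),
    function(x) depth_cap_filter(x, c(mut = 37, wt = 36), 2),
    impact_filter,
    daf_criterion,
    panel_absence_filter
  )
  apply_all <- function(x, ord) {
    for (f in filters[ord]) x <- f(x)
    x$pos
  }
  base <- apply_all(v, 1:5)
  withr::with_seed(3, {
    for (i in 1:6) expect_identical(apply_all(v, sample(5)), base)
  })
  # idempotence
  for (f in filters) {
    once <- f(v)
    expect_identical(f(once), once)
  }
})

test_that("interval restriction and empty interval behave", {
  v <- cascade_fixture()
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(attr(v, "causal_pos") - 10,
                                                attr(v, "causal_pos") + 10))
  rep <- prioritize(v, gr, mean_depth = c(mut = 37, wt = 36))
  expect_identical(rep$stages$n_variants[2], 1L)
  empty <- prioritize(v, GenomicRanges::GRanges(), mean_depth = c(mut = 37, wt = 36))
  expect_identical(nrow(empty$candidates), 0L)
})

test_that("annotate_sites joins annotation, daf and panel counts", {
  d <- tiny_design(n_snps = 300L)
  f <- simulate_founders(d)
  s <- pool_and_sequence(simulate_f2_cross(f))
  ann <- simulate_annotations(s, seed = 2L)
  panel <- simulate_reference_panel(f, 10L)
  v <- annotate_sites(s, ann, panel)
  expect_identical(v$consequence[attr(s, "causal_index")], "splice_donor_variant")
  expect_equal(v$daf, as.numeric(site_delta_af(s)))
  expect_identical(v$panel_alt_observed[attr(s, "causal_index")], 0L)
  # positions missing from the panel are unobserved, with a message
  short_panel <- panel
  short_panel$positions <- panel$positions[-1]
  short_panel$alt_carriers <- panel$alt_carriers[-1]
  expect_message(v2 <- annotate_sites(s, ann, short_panel), "absent from panel")
  expect_identical(v2$panel_alt_observed[1], 0L)
})
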