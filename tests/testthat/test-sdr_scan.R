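fixed_site <- function(alt1 = 0, d1 = 30, alt2 = 28, d2 = 28, n = 40) {
  pool_sites("chr1", 100, "A", "T", d1 - alt1, alt1, d2 - alt2, alt2, n, n)
}

test_that("per-site Hudson F_ST matches hand-computed values", {
  # fixed difference: exactly 1
  f <- site_fst(fixed_site(alt1 = 0, d1 = 30, alt2 = 30, d2 = 30))
  expect_equal(f$fst, 1)
  expect_equal(f$num, 1); expect_equal(f$den, 1)
  # p1 = p2 = 0.5, n = 40: num = -2 * 0.25/39, den = 0.5
  h <- site_fst(fixed_site(alt1 = 15, d1 = 30, alt2 = 15, d2 = 30))
  expect_equal(h$num, -2 * 0.25 / 39)
  expect_equal(h$fst, (-2 * 0.25 / 39) / 0.5, tolerance = 1e-12)
  expect_equal(round(h$fst, 5), -0.02564)
  # monomorphic: denominator 0, fst undefined
  m <- site_fst(fixed_site(alt1 = 0, alt2 = 0, d2 = 30))
  expect_equal(m$den, 0)
  expect_true(is.na(m$fst))
  # swapping pool labels leaves fst unchanged
  s <- pool_sites("c", 1, "A", "T", 22, 8, 3, 27, 40, 40)
  sw <- pool_sites("c", 1, "A", "T", 3, 27, 22, 8, 40, 40)
  expect_equal(site_fst(s)$fst, site_fst(sw)$fst)
})

test_that("window scan equals brute-force recomputation and conserves totals", {
  lay <- genome_layout(c("c1", "c2"), c(5e4, 3e4))
  set.seed(42)
  n <- 1000
  sites <- pool_sites(sample(c("c1", "c2"), n, TRUE, prob = c(.6, .4)),
                      sample.int(4.9e4, n, replace = TRUE),
                      "A", "T",
                      rbinom(n, 30, .5), rbinom(n, 30, .5),
                      rbinom(n, 30, .5), rbinom(n, 30, .5), 40, 40)
  sites <- site_fst(sites, min_depth = 1)
  for (mode in c("ratio_of_sums", "count")) {
    got <- window_scan(sites, lay, 1e4, 5e3, mode = mode)
    want <- brute_window_scan(sites, lay, 1e4, 5e3, mode)
    expect_equal(got$value, want$value, tolerance = 1e-12)
    expect_equal(got$n_sites, as.integer(want$n_sites))
  }
  # one whole-chromosome window reproduces the ratio of summed num/den
  c1 <- sites[sites$chrom == "c1", ]
  whole <- window_scan(c1, genome_layout("c1", 5e4), 5e4, 5e4)
  expect_equal(whole$value[1],
               sum(c1$num, na.rm = TRUE) / sum(c1$den, na.rm = TRUE))
  # empty window: NA for ratio, 0 for count
  far <- window_scan(c1, lay, 1e4, 1e4, mode = "ratio_of_sums")
  expect_true(all(is.na(far$value[far$chrom == "c2"])))
  farc <- window_scan(c1, lay, 1e4, 1e4, mode = "count")
  expect_true(all(farc$value[farc$chrom == "c2"] == 0))
})

test_that("two sites with num/den (1,1) and (0,1) give a 0.5 window", {
  lay <- genome_layout("c1", 1e4)
  sites <- data.frame(chrom = "c1", pos = c(10, 20),
                      num = c(1, 0), den = c(1, 1))
  w <- window_scan(sites, lay, 1e4, 1e4)
  expect_equal(w$value[1], 0.5)
})

test_that("male-specific filter applies thresholds and tolerances", {
  expect_equal(nrow(male_specific_filter(fixed_site(alt1 = 0))), 1)
  one_err <- fixed_site(alt1 = 1, d1 = 30)
  expect_equal(nrow(male_specific_filter(one_err, eps1 = 0)), 0)
  expect_equal(nrow(male_specific_filter(one_err, eps1 = 0.05)), 1)
  shallow <- fixed_site(d2 = 28, alt2 = 28)
  expect_equal(nrow(male_specific_filter(shallow, min_depth = 29)), 0)
})

test_that("error-free simulation is recovered exactly by the filter", {
  lay <- genome_layout(c("c1", "c2"), c(2e6, 2e6))
  sim <- gen_pool_counts(lay, n_background_sites = 3000,
                         sdr = list("c2", 5e5, 8e5), n_sdr_sites = 300,
                         error_rate = 0, n_batches = 1, seed = 5)
  kept <- male_specific_filter(sim$batches[[1]])
  expect_setequal(kept$pos[kept$chrom == "c2"], sim$truth$sdr_positions)
  expect_true(all(kept$chrom == "c2"))
})

test_that("replicate intersection behaves on identical/disjoint batches and cuts noise", {
  b <- fixed_site()
  expect_equal(nrow(intersect_replicates(list(b, b))), 1)
  b2 <- pool_sites("chr9", 5, "G", "C", 10, 0, 0, 10, 40, 40)
  expect_equal(nrow(intersect_replicates(list(b, b2))), 0)
  expect_error(intersect_replicates(list(b)), "2 batches")
  # at shallow depth with loose tolerances, mid-frequency background sites
  # can pass one batch by sampling noise; intersection prunes them
  lay <- genome_layout(c("c1", "c2"), c(2e6, 2e6))
  worse <- better <- numeric(10)
  for (s in 1:10) {
    sim <- gen_pool_counts(lay, n_background_sites = 4000,
                           sdr = list("c2", 5e5, 8e5), n_sdr_sites = 100,
                           depth = 10, error_rate = 0.01, n_batches = 2,
                           seed = s)
    fp <- function(v) sum(!(v$chrom == "c2" &
                              v$pos %in% sim$truth$sdr_positions))
    flt <- function(b) male_specific_filter(b, eps1 = 0.3, eps2 = 0.3,
                                            min_depth = 5)
    f1 <- flt(sim$batches[[1]]); f2 <- flt(sim$batches[[2]])
    worse[s] <- fp(f1)
    better[s] <- fp(intersect_replicates(list(f1, f2)))
  }
  expect_lt(mean(better), mean(worse))
})

test_that("call_sdr equals brute-force minimal-interval enumeration", {
  set.seed(33)
  for (rep in 1:5) {
    pos <- sort(sample.int(1e5, 60))
    v <- pool_sites("cZ", pos, "A", "T", 30, 0, 0, 30, 40, 40)
    got <- call_sdr(v, q = 0.5)
    want <- brute_min_interval(pos, 0.5)
    expect_equal(got$start, want$start)
    expect_equal(got$end - got$start, want$len)
  }
  # all variants at one position
  v1 <- pool_sites("cZ", rep(777, 5), "A", "T", 30, 0, 0, 30, 40, 40)
  one <- call_sdr(v1, q = 0.9)
  expect_equal(c(one$start, one$end), c(776, 777))
  expect_equal(one$n_inside, 5)
  expect_error(call_sdr(v1[0, ]), "no variants")
})

test_that("SDR interval length is monotone in the coverage fraction", {
  set.seed(12)
  pos <- sort(sample.int(3e5, 200))
  v <- pool_sites("cZ", pos, "A", "T", 30, 0, 0, 30, 40, 40)
  lens <- vapply(c(0.5, 0.7, 0.85, 0.95, 1),
                 function(q) { cl <- call_sdr(v, q = q); cl$end - cl$start },
                 0)
  expect_true(all(diff(lens) >= 0))
})

test_that("with all fixed differences in the SDR, the top F_ST window overlaps a q=1 call", {
  lay <- genome_layout(c("c1", "c2"), c(2e6, 2e6))
  sim <- gen_pool_counts(lay, n_background_sites = 2000,
                         sdr = list("c2", 9e5, 1.2e6), n_sdr_sites = 400,
                         error_rate = 0, n_batches = 1, seed = 19)
  out <- sdr_pipeline(sim$batches[1:1], lay, eps1 = 0, eps2 = 0, q = 1)
  # single batch: pipeline needs >= 2 batches only for intersection
  expect_equal(out$call$chrom, "c2")
  tw <- out$top_fst_window
  expect_equal(tw$chrom, "c2")
  expect_gt(tw$end, out$call$start)
  expect_lt(tw$start, out$call$end)
})
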