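test_that("every generator is deterministic given its seed", {
  lay <- genome_layout(c("c1", "c2"), c(2e6, 2e6))
  a <- gen_pool_counts(lay, 500, list("c1", 5e5, 8e5), 50, seed = 9)
  b <- gen_pool_counts(lay, 500, list("c1", 5e5, 8e5), 50, seed = 9)
  expect_identical(a, b)
  hl <- genome_layout("cX", 50 * 1e5, bin_size = 1e5)
  expect_identical(gen_contact_map(hl, seed = 4)$cm$mat,
                   gen_contact_map(hl, seed = 4)$cm$mat)
  expect_identical(gen_codon_alignments(3, 50, seed = 2),
                   gen_codon_alignments(3, 50, seed = 2))
  expect_identical(gen_anchors(c(q = 40), seed = 5),
                   gen_anchors(c(q = 40), seed = 5))
  expect_identical(gen_expression(100, seed = 6)$counts,
                   gen_expression(100, seed = 6)$counts)
  expect_identical(gen_repeat_table(lay, seed = 7)$repeats,
                   gen_repeat_table(lay, seed = 7)$repeats)
})

test_that("error-free SDR sites are exactly fixed in opposite pools", {
  lay <- genome_layout("c1", 1e6)
  sim <- gen_pool_counts(lay, n_background_sites = 100,
                         sdr = list("c1", 4e5, 6e5), n_sdr_sites = 1,
                         error_rate = 0, n_batches = 1, seed = 11)
  s <- sim$batches[[1]]
  sdr_row <- s[s$pos %in% sim$truth$sdr_positions, ]
  expect_equal(sdr_row$alt1, 0)
  expect_equal(sdr_row$ref2, 0)
})

test_that("fraction of SDR sites passing the exact filter matches the closed form", {
  # (P(no error read in a pool))^2 per batch = ((1-e)^depth)^2
  lay <- genome_layout("c1", 5e6)
  sim <- gen_pool_counts(lay, n_background_sites = 0,
                         sdr = list("c1", 1e6, 4e6), n_sdr_sites = 2000,
                         depth = 30, error_rate = 0.01, n_batches = 1,
                         seed = 21)
  kept <- male_specific_filter(sim$batches[[1]], eps1 = 0, eps2 = 0,
                               min_depth = 10)
  p_expect <- (0.99^30)^2              # ~0.547
  ci <- qbinom(c(0.0005, 0.9995), 2000, p_expect) / 2000
  expect_gt(nrow(kept) / 2000, ci[1])
  expect_lt(nrow(kept) / 2000, ci[2])
})

test_that("contact decay follows the requested power law", {
  lay <- genome_layout("cX", 300 * 5e4, bin_size = 5e4)
  g <- gen_contact_map(lay, gamma = 1, tau = 1, delta = 0, coverage = 100,
                       seed = 13)
  dec <- oe_transform(ice_balance(g$cm), "cX")$decay
  sel <- dec$distance_bins >= 2 & dec$distance_bins <= 50 &
    !is.na(dec$expected) & dec$expected > 0
  fit <- lm(log(expected) ~ log(distance_bins), data = dec[sel, ])
  expect_lt(abs(coef(fit)[2] - (-1)), 0.1)
})

test_that("a structureless map yields no confident compartment signal", {
  lay <- genome_layout("cX", 200 * 5e4, bin_size = 5e4)
  g <- gen_contact_map(lay, gamma = 1, tau = 1, delta = 0, coverage = 50,
                       seed = 17)
  comp <- call_compartments(ice_balance(g$cm), "cX")
  expect_lt(attr(comp, "var_explained"), 0.10)
  expect_false(attr(comp, "reliable"))
})

test_that("codon alignment generator plants exact substitution counts", {
  z <- gen_codon_alignments(1, 30, syn_changes_per_gene = 0,
                            nonsyn_changes_per_gene = 0, seed = 1)
  expect_identical(z$pairs[[1]]$a, z$pairs[[1]]$b)
  one <- gen_codon_alignments(5, 40, syn_changes_per_gene = 1,
                              nonsyn_changes_per_gene = 0, seed = 3)
  for (p in one$pairs) {
    r <- nei_gojobori(p$a, p$b)
    expect_equal(r$ka, 0)
    expect_equal(r$Sd, 1)
  }
  expect_error(gen_codon_alignments(1, 2, 3, 3, seed = 1), "changes")
})

test_that("anchor generator plants fusion and inversion breakpoints", {
  plain <- gen_anchors(c(q1 = 50, q2 = 40), seed = 2)
  bl <- chain_anchors(plain$anchors)
  expect_equal(nrow(bl), 2)
  expect_equal(nrow(count_rearrangements(bl)$breakpoints), 0)

  fus <- gen_anchors(c(q1 = 400),
                     fusion = list(qchrom = "q1", targetA = "A",
                                   targetB = "B", fusion_index = 200),
                     seed = 2)
  tc <- fus$anchors$tchrom
  expect_equal(sum(tc[-1] != tc[-length(tc)]), 1)   # one transition

  expect_error(gen_anchors(c(q1 = 100),
    inversions = list(list(qchrom = "q1", from = 10, to = 30),
                      list(qchrom = "q1", from = 25, to = 40))),
    "overlapping")
})

test_that("five planted inversions are recovered as five flip breakpoint pairs", {
  inv <- lapply(c(40, 90, 140, 190, 240), function(f)
    list(qchrom = "q1", from = f, to = f + 20))
  sim <- gen_anchors(c(q1 = 300), inversions = inv, seed = 8)
  rr <- count_rearrangements(chain_anchors(sim$anchors))
  expect_equal(sum(rr$breakpoints$kind == "inversion"), 10)  # 2 flanks each
  expect_equal(rr$per_chrom$inversion, 10)
})

test_that("expression generator: null false positives and planted recall", {
  # effect absent: classifier stays below 5% false positives
  fp <- vapply(1:10, function(s) {
    ex <- gen_expression(400, biased_fraction = 0, seed = s)
    cpm <- normalize_counts(ex$counts)$cpm
    cl <- classify_sex_bias(cpm, ex$groups)
    mean(cl$label != "unbiased")
  }, 0)
  expect_lte(mean(fp), 0.05)
  # strong planted effect: recalled
  rec <- vapply(1:10, function(s) {
    ex <- gen_expression(400, biased_fraction = 0.1, effect_log2fc = 2,
                         seed = s)
    cpm <- normalize_counts(ex$counts)$cpm
    cl <- classify_sex_bias(cpm, ex$groups)
    called <- cl$gene_id[cl$label == "male-biased"]
    length(intersect(called, ex$truth$biased_genes)) /
      length(ex$truth$biased_genes)
  }, 0)
  expect_gte(mean(rec), 0.8)
})

test_that("repeat generator: null Z-scores small, planted enrichment is row max", {
  lay <- genome_layout(paste0("c", 1:6), rep(5e6, 6))
  nullz <- gen_repeat_table(lay, seed = 31)
  z0 <- repeat_zscores(nullz$repeats, lay)$Z
  expect_lt(max(abs(z0)), 3)
  enr <- gen_repeat_table(lay,
                          enrichment = data.frame(chrom = "c4",
                                                  subfamily = "sf2",
                                                  fold = 5), seed = 32)
  z <- repeat_zscores(enr$repeats, lay)$Z
  expect_equal(unname(which.max(z["sf2", ])), 4)
})
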