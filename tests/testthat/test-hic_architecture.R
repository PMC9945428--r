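# one mid-sized planted map reused across several blocks
pm <- planted_map(n = 400, n_bnd = 8, tau = 2, delta = 0.3, coverage = 50,
                  seed = 101)
cm_pm <- ice_balance(pm$cm)

test_that("ICE balancing equalizes row sums, is idempotent and scale-robust", {
  B <- balanced_matrix(cm_pm)
  live <- !cm_pm$mask
  rs <- Matrix::rowSums(B)[live]
  expect_lt(sd(rs) / mean(rs), 1e-3)
  # idempotent: rebalancing changes biases negligibly
  again <- ice_balance(cm_pm)
  expect_lt(max(abs(again$bias[live] / cm_pm$bias[live] - 1)), 1e-3)
  # scaling one row by 10x leaves the balanced matrix equal up to a constant
  g <- as(as(pm$cm$mat, "generalMatrix"), "TsparseMatrix")
  x2 <- g@x * ifelse(g@i == 10 | g@j == 10, 10, 1)
  cm2 <- contact_matrix(pm$layout, g@i, g@j, x2)
  cm2$mask <- pm$cm$mask
  b2 <- balanced_matrix(ice_balance(cm2))
  r <- as.matrix(b2[live, live]) / as.matrix(balanced_matrix(cm_pm)[live, live])
  r <- r[is.finite(r) & r > 0]
  expect_lt(stats::sd(r) / mean(r), 0.02)
  # an all-masked (empty) matrix passes through untouched
  lay0 <- genome_layout("z", 30 * 5e4, bin_size = 5e4)
  cm0 <- contact_matrix(lay0, integer(0), integer(0), numeric(0))
  out0 <- ice_balance(cm0)
  expect_true(all(is.na(out0$bias)))
  expect_true(attr(out0, "converged"))
})

test_that("O/E transform: row means near 1, constant matrix gives O/E of 1", {
  # on a structureless map, every unmasked O/E row averages ~1
  lay0 <- genome_layout("c", 200 * 5e4, bin_size = 5e4)
  g0 <- gen_contact_map(lay0, gamma = 1, coverage = 50, seed = 61)
  cm0 <- ice_balance(g0$cm)
  oe0 <- oe_transform(cm0, "c")$oe
  rm0 <- rowMeans(oe0, na.rm = TRUE)
  # rows touching the longest distances are noisy (few pairs, low counts),
  # so the row means are checked in aggregate
  expect_lt(mean(abs(rm0[!cm0$mask] - 1)), 0.1)
  expect_equal(mean(rm0[!cm0$mask]), 1, tolerance = 0.02)
  # with planted structure only the overall mean is pinned to 1
  oe <- oe_transform(cm_pm, "chrT")
  rm_ <- rowMeans(oe$oe, na.rm = TRUE)
  expect_equal(mean(rm_[!cm_pm$mask], na.rm = TRUE), 1, tolerance = 0.02)
  # constant matrix
  lay <- genome_layout("c", 40 * 1e5, bin_size = 1e5)
  ij <- which(upper.tri(diag(40), diag = TRUE), arr.ind = TRUE)
  cmc <- contact_matrix(lay, ij[, 1] - 1, ij[, 2] - 1, rep(7, nrow(ij)))
  oec <- oe_transform(cmc, "c")$oe
  expect_true(all(abs(oec[!is.na(oec)] - 1) < 1e-12))
})

test_that("compartment calling recovers the planted checkerboard and respects the covariate sign", {
  comp <- call_compartments(cm_pm, "chrT", covariate = pm$truth$v)
  got <- ifelse(comp$pc1 > 0, 1, -1)
  agree <- mean(got == pm$truth$v, na.rm = TRUE)
  expect_gte(agree, 0.95)
  flipped <- call_compartments(cm_pm, "chrT", covariate = -pm$truth$v)
  expect_equal(ifelse(flipped$pc1 > 0, "A", "B")[!is.na(flipped$pc1)],
               ifelse(comp$pc1 > 0, "B", "A")[!is.na(comp$pc1)])
  expect_error(call_compartments(cm_pm, "chrT",
                                 covariate = pm$truth$v[1:5]))
})

test_that("insulation TAD calling recovers planted boundaries and sizes", {
  res <- insulation_tads(cm_pm, "chrT")
  truthb <- pm$truth$tad_boundaries
  hit <- vapply(truthb, function(b) any(abs(res$boundaries$bin - b) <= 1),
                TRUE)
  recall <- mean(hit)
  prec <- mean(vapply(res$boundaries$bin,
                      function(b) any(abs(truthb - b) <= 1), TRUE))
  expect_gte(recall, 0.9)
  expect_gte(prec, 0.9)
  # two planted TADs of 30 and 60 bins inside one chromosome
  lay2 <- genome_layout("c", 90 * 5e4, bin_size = 5e4)
  g2 <- gen_contact_map(lay2, gamma = 1, tad_boundaries = 30, tau = 2,
                        coverage = 60, seed = 7)
  r2 <- insulation_tads(ice_balance(g2$cm), "c")
  sizes <- sort(r2$tads$n_bins)
  expect_equal(length(sizes), 2)
  expect_lte(abs(sizes[1] - 30), 1)
  expect_lte(abs(sizes[2] - 60), 1)
})

test_that("decay-only maps rarely produce boundary calls", {
  null_counts <- vapply(1:10, function(s) {
    lay <- genome_layout("c", 200 * 5e4, bin_size = 5e4)
    g <- gen_contact_map(lay, gamma = 1, tau = 1, delta = 0, coverage = 50,
                         seed = 200 + s)
    nrow(insulation_tads(ice_balance(g$cm), "c")$boundaries)
  }, 0)
  expect_gte(mean(null_counts == 0), 0.9)
})

test_that("boundary sharing: identity, disjoint and 1-bin shifts", {
  a <- c(10L, 40L, 80L)
  expect_equal(tad_boundary_sharing(a, a)$fraction, 1)
  expect_equal(tad_boundary_sharing(a, c(20L, 60L))$fraction, 0)
  expect_equal(tad_boundary_sharing(a, a + 1L, tol = 1)$fraction, 1)
  expect_equal(tad_boundary_sharing(a, a + 1L, tol = 0)$fraction, 0)
  expect_error(tad_boundary_sharing(a, a, bin_size_a = 5e4,
                                    bin_size_b = 1e5), "bin sizes differ")
})

test_that("cis-range fractions classify by distance and respond to decay", {
  lay <- genome_layout("c", 300 * 5e4, bin_size = 5e4)
  # single contact at 200 kb -> mid range (edges 160 kb / 10 Mb)
  cm1 <- contact_matrix(lay, 0, 4, 10)
  cm1$mask[] <- FALSE
  fr1 <- cis_range_fractions(cm1)
  expect_equal(unname(fr1["mid"]), 1)
  expect_equal(sum(fr1), 1)
  # steeper decay shifts weight into the short range
  fshort <- vapply(c(0.5, 1, 1.5), function(gam) {
    g <- gen_contact_map(lay, gamma = gam, coverage = 50, seed = 5)
    cis_range_fractions(ice_balance(g$cm))[["short"]]
  }, 0)
  expect_true(all(diff(fshort) > 0))
})

test_that("interaction caller controls the null and finds planted loops", {
  lay <- genome_layout(c("cA", "cB"), c(200, 120) * 5e4, bin_size = 5e4)
  # null calibration (cis + trans)
  frac_sig <- vapply(1:10, function(s) {
    g <- gen_contact_map(lay, gamma = 1, coverage = 40, seed = 300 + s)
    cmn <- ice_balance(g$cm)
    ci <- call_significant_interactions(cmn, "cis")
    tr <- call_significant_interactions(cmn, "trans")
    (nrow(ci) + nrow(tr)) /
      (attr(ci, "n_tested") + attr(tr, "n_tested"))
  }, 0)
  expect_lte(mean(frac_sig), 0.05)
  # planted loops at 5x enrichment: >= 80% recovered
  set.seed(9)
  li <- sample(30:170, 12)
  lj <- li + sample(10:25, 12, replace = TRUE)
  loops <- cbind(li, pmin(lj, 199))
  g <- gen_contact_map(lay, gamma = 1, loops = loops, loop_strength = 4,
                       coverage = 40, seed = 12)
  calls <- call_significant_interactions(ice_balance(g$cm), "cis")
  found <- vapply(seq_len(nrow(loops)), function(k)
    any(calls$bin1 == loops[k, 1] & calls$bin2 == loops[k, 2]), TRUE)
  expect_gte(mean(found), 0.8)
  # a zero-count pair is never called
  expect_true(all(calls$observed > 0))
})

test_that("anchor annotation follows promoter > exon > intron > intergenic", {
  lay <- genome_layout("chrA", 10 * 1e3, bin_size = 1e3)
  gm <- structure(list(
    genes = data.frame(gene_id = "g1", chrom = "chrA", strand = "+",
                       start = 2100, end = 6900, tss = 2100),
    exons = data.frame(gene_id = "g1", start = c(2100, 6000),
                       end = c(2500, 6900))), class = "gene_models")
  calls <- data.frame(bin1 = c(2, 4, 6, 9), bin2 = c(2, 4, 6, 9))
  ann <- annotate_anchors(calls, gm, lay, promoter_up = 200,
                          promoter_down = 100)
  cats <- ann$anchors$category[match(c(2, 4, 6, 9), ann$anchors$bin)]
  # bin 2 covers the TSS -> promoter wins over exon
  expect_equal(cats, c("promoter", "intron", "exon", "intergenic"))
  expect_equal(sum(ann$fractions), 1)
  expect_equal(unname(ann$fractions["promoter"]), 0.25)
  expect_equal(ann$genes_by_category$exon, "g1")
})

test_that("contact scores are symmetric, size-normalized and linear in trans counts", {
  lay <- genome_layout(c("a", "b", "c"), c(40, 30, 20) * 5e4,
                       bin_size = 5e4)
  g <- gen_contact_map(lay, gamma = 1, coverage = 30, trans_scale = 0.2,
                       seed = 3)
  cs <- contact_scores(g$cm)
  expect_equal(nrow(cs), 3)
  expect_true(all(cs$score >= 0))
  # doubling a-b trans counts doubles exactly that score
  t2 <- as(as(g$cm$mat, "generalMatrix"), "TsparseMatrix")
  chrom_of <- g$cm$layout$bins$chrom
  ab <- (chrom_of[t2@i + 1] == "a" & chrom_of[t2@j + 1] == "b") |
    (chrom_of[t2@i + 1] == "b" & chrom_of[t2@j + 1] == "a")
  cm2 <- contact_matrix(lay, t2@i, t2@j, t2@x * ifelse(ab, 2, 1))
  cm2$mask <- g$cm$mask
  cs2 <- contact_scores(cm2)
  key <- paste(cs$chromA, cs$chromB)
  expect_equal(cs2$score[key == "a b"], 2 * cs$score[key == "a b"],
               tolerance = 1e-12)
  expect_equal(cs2$score[key == "a c"], cs$score[key == "a c"],
               tolerance = 1e-12)
  # block-diagonal (no trans) map scores 0 everywhere
  ij <- which(upper.tri(diag(40), diag = TRUE), arr.ind = TRUE)
  cmd <- contact_matrix(lay, ij[, 1] - 1, ij[, 2] - 1, rep(5, nrow(ij)))
  expect_true(all(contact_scores(cmd)$score[
    paste(contact_scores(cmd)$chromA, contact_scores(cmd)$chromB) !=
      "a a"] == 0))
  # windowed trans profile sums to the pair total
  tp <- trans_profile(g$cm, "a", "b", window = 5e5, step = 5e5)
  B <- balanced_matrix(g$cm)
  tot <- sum(as.matrix(B)[chrom_bins(lay, "a") + 1, chrom_bins(lay, "b") + 1])
  expect_equal(sum(tp$value), tot, tolerance = 1e-9)
})

test_that("matrix correlation: self-correlation 1, weakened by perturbing a TAD", {
  small <- planted_map(n = 150, n_bnd = 4, seed = 55)
  cm <- ice_balance(small$cm)
  self <- matrix_correlation(cm, cm)
  expect_equal(self$r_log, 1)
  expect_equal(self$r_oe, 1)
  # strengthening one TAD progressively lowers the correlation
  g <- as(as(small$cm$mat, "generalMatrix"), "TsparseMatrix")
  inside <- g@i >= 30 & g@i <= 60 & g@j >= 30 & g@j <= 60
  rs <- vapply(c(2, 4, 8), function(f) {
    cm2 <- contact_matrix(small$layout, g@i, g@j,
                          g@x * ifelse(inside, f, 1))
    matrix_correlation(cm, ice_balance(cm2))$r_log
  }, 0)
  expect_true(all(diff(rs) < 0))
  expect_true(all(rs < 1))
})
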