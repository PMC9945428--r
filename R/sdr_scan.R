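#' Per-site Hudson F_ST from pool allele counts
#'
#' For each site, allele frequencies `p_k = alt_k / depth_k` feed the
#' two-population Hudson estimator with finite-sample correction using the
#' haploid pool sizes `n1`, `n2`:
#' `num = (p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1)` and
#' `den = p1 (1 - p2) + p2 (1 - p1)`; `fst = num / den` where `den > 0`.
#' Per-site values are not clamped (they may be negative); windowed values
#' should be formed as a ratio of sums ([window_scan()]), not by averaging
#' per-site ratios.
#'
#' @param sites a [pool_sites] table.
#' @param min_depth minimum read depth in both pools; shallower sites get
#'   `NA` numerator/denominator and are excluded from window sums.
#' @return `sites` with added columns `p1`, `p2`, `num`, `den`, `fst`
#'   (`fst` `NA` where the denominator is 0 or depth is insufficient).
#' @export
site_fst <- function(sites, min_depth = 10) {
  d1 <- sites$ref1 + sites$alt1
  d2 <- sites$ref2 + sites$alt2
  if (any(sites$n1 < 2 | sites$n2 < 2)) stop("haploid pool sizes must be >= 2")
  ok <- d1 >= pmax(min_depth, 1) & d2 >= pmax(min_depth, 1)
  n_zero <- sum(d1 == 0 | d2 == 0)
  if (n_zero) message(n_zero, " site(s) with zero depth skipped")
  p1 <- ifelse(ok, sites$alt1 / d1, NA_real_)
  p2 <- ifelse(ok, sites$alt2 / d2, NA_real_)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (sites$n1 - 1) -
    p2 * (1 - p2) / (sites$n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  out <- sites
  out$p1 <- p1; out$p2 <- p2; out$num <- num; out$den <- den
  out$fst <- ifelse(!is.na(den) & den > 0, num / den, NA_real_)
  out
}

#' Sliding-window scan over per-site values
#'
#' Windows tile each chromosome from 0 by `step` (last window truncated).
#' In `ratio_of_sums` mode the window value is `sum(num) / sum(den)` over
#' sites falling in the window (`NA` when the denominator sum is 0 or no
#' site falls in it); in `count` mode it is the number of sites.
#'
#' @param sites data.frame with `chrom`, `pos` (1-based) and, for
#'   `ratio_of_sums`, `num` and `den` columns (e.g. from [site_fst()]).
#'   Sites with `NA` num/den are ignored.
#' @param layout a [genome_layout].
#' @param window,step window and step in bp (`window >= step`).
#' @param mode `"ratio_of_sums"` or `"count"`.
#' @return window track data.frame: `chrom`, `start`, `end` (0-based
#'   half-open), `value`, `n_sites`.
#' @export
window_scan <- function(sites, layout, window = 1e4, step = 5e3,
                        mode = c("ratio_of_sums", "count")) {
  mode <- match.arg(mode)
  stopifnot(window >= step)
  for (ch in unique(sites$chrom))
    if (is.unsorted(sites$pos[sites$chrom == ch]))
      stop("sites must be sorted by (chrom, pos)")
  wins <- tile_windows(layout, window, step)
  wins$value <- NA_real_
  wins$n_sites <- 0L
  for (ch in unique(wins$chrom)) {
    wi <- which(wins$chrom == ch)
    s <- sites[sites$chrom == ch, , drop = FALSE]
    if (mode == "ratio_of_sums") s <- s[!is.na(s$num) & !is.na(s$den), , drop = FALSE]
    if (!nrow(s)) { if (mode == "count") wins$value[wi] <- 0; next }
    x <- s$pos - 1                       # 0-based
    o <- order(x); x <- x[o]
    lo <- findInterval(wins$start[wi] - 0.5, x) + 1
    hi <- findInterval(wins$end[wi] - 0.5, x)
    cnt <- pmax(0, hi - lo + 1)
    wins$n_sites[wi] <- cnt
    if (mode == "count") {
      wins$value[wi] <- cnt
    } else {
      cn <- cumsum(s$num[o]); cd <- cumsum(s$den[o])
      sn <- ifelse(cnt > 0, cn[pmax(hi, 1)] - c(0, cn)[lo], 0)
      sd_ <- ifelse(cnt > 0, cd[pmax(hi, 1)] - c(0, cd)[lo], 0)
      wins$value[wi] <- ifelse(cnt > 0 & sd_ > 0, sn / sd_, NA_real_)
    }
  }
  wins
}

#' Filter for male-specific (sex-linked) variants
#'
#' Keeps sites fixed (or nearly fixed, under the tolerances) for the
#' reference allele in the XX pool and for the alternate allele in the YY
#' pool: `alt1/depth1 <= eps1` and `alt2/depth2 >= 1 - eps2`, with both
#' depths at least `min_depth`. The defaults (`eps = 0`) demand exact
#' fixation, the criterion used to call a variant male-specific.
#'
#' @param sites a [pool_sites] table.
#' @param eps1 maximum alternate-allele frequency in pool 1 (XX).
#' @param eps2 tolerance below 1 for the alternate frequency in pool 2 (YY).
#' @param min_depth minimum depth per pool.
#' @return the retained subset, with `attr(, "counts")` recording sites in,
#'   depth-failing, and kept (SNPs and indels separately).
#' @export
male_specific_filter <- function(sites, eps1 = 0, eps2 = 0, min_depth = 10) {
  d1 <- sites$ref1 + sites$alt1
  d2 <- sites$ref2 + sites$alt2
  deep <- d1 >= min_depth & d2 >= min_depth
  keep <- deep & sites$alt1 <= eps1 * d1 & sites$alt2 >= (1 - eps2) * d2
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(n_in = nrow(sites), n_shallow = sum(!deep),
                           n_kept = sum(keep),
                           n_snp = sum(keep & !sites$is_indel),
                           n_indel = sum(keep & sites$is_indel))
  out
}

#' Intersect variants across replicate batches
#'
#' Retains variants present in every batch, matched by
#' (chrom, pos, ref, alt). Counts (and all other columns) are taken from the
#' first batch.
#'
#' @param batches list (length >= 2) of [pool_sites] tables.
#' @return subset of `batches[[1]]`.
#' @export
intersect_replicates <- function(batches) {
  if (length(batches) < 2) stop("need at least 2 batches to intersect")
  key <- function(b) paste(b$chrom, b$pos, b$ref, b$alt)
  common <- Reduce(intersect, lapply(batches, key))
  out <- batches[[1]][key(batches[[1]]) %in% common, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call the sex-determining region as a minimal variant-covering interval
#'
#' On the chromosome carrying the most variants, returns the shortest
#' interval containing at least a fraction `q` of that chromosome's
#' variants (two-pointer scan over sorted positions; ties broken by smaller
#' start). The default `q = 0.85` reflects that the large majority — but
#' not all — of genuine sex-linked variants cluster in the SDR, with a tail
#' of scattered survivors.
#'
#' @param variants a [pool_sites] table (e.g. intersected male-specific
#'   variants).
#' @param layout a [genome_layout] (used for validation only).
#' @param q coverage fraction in (0, 1].
#' @return list of class `sdr_call`: `chrom`, `start`, `end` (0-based
#'   half-open bp), `n_inside`, `n_chrom`, `fraction`, `q`.
#' @export
call_sdr <- function(variants, layout = NULL, q = 0.85) {
  if (!nrow(variants)) stop("no variants to call an SDR from")
  stopifnot(q > 0, q <= 1)
  tab <- table(variants$chrom)
  ch <- names(tab)[which.max(tab)]
  pos <- sort(variants$pos[variants$chrom == ch]) - 1   # 0-based
  n <- length(pos)
  m <- ceiling(q * n)
  len <- pos[m:n] - pos[1:(n - m + 1)] + 1
  i <- which.min(len)                                    # ties -> smallest start
  start <- pos[i]; end <- pos[i + m - 1] + 1
  inside <- sum(pos >= start & pos < end)
  structure(list(chrom = ch, start = start, end = end, n_inside = inside,
                 n_chrom = n, fraction = inside / n, q = q),
            class = "sdr_call")
}

#' @export
print.sdr_call <- function(x, ...) {
  cat(sprintf(
    "SDR call: %s:%d-%d (%.1f kb), %d/%d variants (%.1f%%) at q = %.2f\n",
    x$chrom, x$start, x$end, (x$end - x$start) / 1e3, x$n_inside,
    x$n_chrom, 100 * x$fraction, x$q))
  invisible(x)
}

#' Full SDR-localization pipeline on replicate pool-seq batches
#'
#' Runs, per batch, the male-specific variant filter, intersects the batches,
#' calls the SDR, and computes genome-wide windowed F_ST (10-kb/5-kb
#' defaults) and male-specific-variant density (20-kb/5-kb) tracks from the
#' first batch.
#'
#' The pipeline default `eps = 0.05` tolerates about one stray read at 30x
#' depth in each pool: raw pooled read counts carry sequencing error that no
#' genotype caller has absorbed, and demanding exact fixation discards a
#' large fraction of genuine sex-linked sites while a 5% tolerance admits
#' essentially no background site (which would have to be simultaneously
#' below 5% and above 95% frequency). Pass `eps1 = eps2 = 0` for the strict
#' criterion.
#'
#' @param batches list of [pool_sites] tables (one per replicate batch).
#' @param layout a [genome_layout].
#' @param eps1,eps2,min_depth see [male_specific_filter()].
#' @param q see [call_sdr()].
#' @param fst_window,fst_step,snp_window,snp_step track windowing (bp).
#' @return list: `call` ([call_sdr()] result), `variants` (intersected),
#'   `fst_track`, `snp_track`, `top_fst_window` (row of `fst_track`),
#'   `filter_log` (per-batch filter counts).
#' @export
sdr_pipeline <- function(batches, layout, eps1 = 0.05, eps2 = 0.05,
                         min_depth = 10, q = 0.85,
                         fst_window = 1e4, fst_step = 5e3,
                         snp_window = 2e4, snp_step = 5e3) {
  if (!is.list(batches) || inherits(batches, "data.frame"))
    stop("batches must be a list of pool_sites tables")
  filtered <- lapply(batches, male_specific_filter, eps1 = eps1,
                     eps2 = eps2, min_depth = min_depth)
  log <- do.call(rbind, lapply(filtered, attr, "counts"))
  variants <- if (length(batches) >= 2) intersect_replicates(filtered)
    else filtered[[1]]
  call <- call_sdr(variants, layout, q = q)
  fst <- site_fst(batches[[1]], min_depth = min_depth)
  fst_track <- window_scan(fst, layout, fst_window, fst_step,
                           mode = "ratio_of_sums")
  snp_track <- window_scan(variants, layout, snp_window, snp_step,
                           mode = "count")
  defined <- which(!is.na(fst_track$value))
  top <- defined[order(-fst_track$value[defined],
                       -fst_track$n_sites[defined])][1]
  list(call = call, variants = variants, fst_track = fst_track,
       snp_track = snp_track, top_fst_window = fst_track[top, ],
       filter_log = log)
}
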