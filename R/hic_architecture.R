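#' ICE balancing of a contact matrix
#'
#' Iterative correction: per-bin biases are updated by the (normalized)
#' row sums of the bias-corrected matrix until the largest relative change
#' falls below `tol`, after which every unmasked row of the balanced matrix
#' `raw_ij / (bias_i bias_j)` has (nearly) equal sum. Masked bins keep
#' `NA` bias and are excluded throughout.
#'
#' @param cm a [contact_matrix].
#' @param tol convergence tolerance on the row-sum update.
#' @param max_iter maximum iterations; non-convergence gives a warning and
#'   the last iterate, flagged in `attr(, "converged")`.
#' @return the `contact_matrix` with its `bias` filled in.
#' @export
ice_balance <- function(cm, tol = 1e-5, max_iter = 200) {
  n <- n_bins(cm$layout)
  G <- as(as(cm$mat, "generalMatrix"), "TsparseMatrix")
  ii <- G@i + 1L; jj <- G@j + 1L; xx <- G@x
  live <- !cm$mask
  keep <- live[ii] & live[jj]
  ii <- ii[keep]; jj <- jj[keep]; xx <- xx[keep]
  b <- rep(1, n); b[!live] <- NA
  converged <- FALSE
  if (length(xx)) {
    for (it in seq_len(max_iter)) {
      xb <- xx / (b[ii] * b[jj])
      rs <- numeric(n)
      agg <- rowsum(xb, ii, reorder = FALSE)
      rs[as.integer(rownames(agg))] <- agg[, 1]
      s <- rs[live] / mean(rs[live][rs[live] > 0])
      s[s == 0] <- 1
      b[live] <- b[live] * s
      if (max(abs(s - 1)) < tol) { converged <- TRUE; break }
    }
  } else converged <- TRUE
  if (!converged) warning("ICE balancing did not converge in ", max_iter,
                          " iterations")
  # normalize biases to unit geometric mean for comparability
  gm <- exp(mean(log(b[live][b[live] > 0])))
  b[live] <- b[live] / gm
  cm$bias <- b
  attr(cm, "converged") <- converged
  cm
}

#' Observed/expected transform and distance-decay curve
#'
#' For one chromosome of a balanced matrix, the expected count at bin
#' distance `d` is the mean balanced count over unmasked pairs at that
#' distance (zeros included); the O/E matrix divides observed by expected.
#'
#' @param cm a balanced [contact_matrix].
#' @param chrom chromosome name.
#' @return list: `oe` (dense matrix, `NA` at masked bins or undefined
#'   distances), `decay` (data.frame `distance_bins`, `distance_bp`,
#'   `expected`, `n_pairs`).
#' @export
oe_transform <- function(cm, chrom) {
  D <- chrom_dense(cm, chrom)
  m <- cm$mask[chrom_bins(cm$layout, chrom) + 1L]
  n <- nrow(D)
  D[m, ] <- NA; D[, m] <- NA
  dist_ <- abs(row(D) - col(D))
  exp_d <- rep(NA_real_, n)  # index d+1
  npair <- integer(n)
  for (d in 0:(n - 1)) {
    v <- D[cbind(1:(n - d), (1 + d):n)]   # one diagonal, O(n)
    v <- v[!is.na(v)]
    npair[d + 1] <- length(v)
    if (length(v)) exp_d[d + 1] <- mean(v)
  }
  oe <- D / matrix(exp_d[dist_ + 1], n, n)
  oe[matrix(exp_d[dist_ + 1] == 0, n, n)] <- NA
  decay <- data.frame(distance_bins = 0:(n - 1),
                      distance_bp = (0:(n - 1)) * cm$layout$bin_size,
                      expected = exp_d, n_pairs = npair)
  list(oe = oe, decay = decay)
}

#' A/B compartment calling from the O/E correlation matrix
#'
#' PC1 is the leading eigenvector of the Pearson correlation matrix of the
#' per-chromosome O/E matrix. Its sign is oriented so that it correlates
#' positively with `covariate` (per-bin gene density, GC, or any activity
#' proxy; by default the bin's total raw coverage). Bins with `PC1 > 0` are
#' labelled A, `PC1 < 0` B. When PC1 explains less than 10% of the
#' correlation-matrix variance the labels are flagged unreliable.
#'
#' @param cm a balanced [contact_matrix].
#' @param chrom chromosome name.
#' @param covariate optional per-bin (full chromosome length) orientation
#'   vector.
#' @return data.frame of class `compartment_track`: `bin` (global id),
#'   `chrom`, `start`, `end`, `pc1`, `label` (A/B/NA); attributes
#'   `var_explained`, `reliable`, `segments` (contiguous A/B runs).
#' @export
call_compartments <- function(cm, chrom, covariate = NULL) {
  gb <- chrom_bins(cm$layout, chrom)
  m <- cm$mask[gb + 1L]
  if (sum(!m) < 20) stop("need >= 20 unmasked bins on ", chrom)
  oe <- oe_transform(cm, chrom)$oe
  keep <- which(!m)
  sub <- oe[keep, keep, drop = FALSE]
  sub[!is.finite(sub)] <- NA
  C <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
  if (any(!is.finite(C))) {
    bad <- !is.finite(C)
    C[bad] <- 0
  }
  if (all(C == 0) || any(is.na(diag(C))))
    stop("degenerate O/E correlation matrix on ", chrom)
  eg <- eigen(C, symmetric = TRUE)
  pc1 <- eg$vectors[, 1]
  var_explained <- eg$values[1] / sum(pmax(eg$values, 0))
  if (is.null(covariate)) {
    cov_full <- Matrix::rowSums(cm$mat)[gb + 1L]
  } else {
    stopifnot(length(covariate) == length(gb))
    cov_full <- covariate
  }
  cc <- suppressWarnings(stats::cor(pc1, cov_full[keep]))
  if (!is.na(cc) && cc < 0) pc1 <- -pc1
  full <- rep(NA_real_, length(gb))
  full[keep] <- pc1
  bins <- cm$layout$bins[cm$layout$bins$chrom == chrom, ]
  out <- data.frame(bin = gb, chrom = chrom, start = bins$start,
                    end = bins$end, pc1 = full,
                    label = ifelse(is.na(full), NA,
                                   ifelse(full > 0, "A", "B")),
                    stringsAsFactors = FALSE)
  lab <- out$label
  r <- rle(ifelse(is.na(lab), "NA", lab))
  cs <- cumsum(r$lengths)
  segs <- data.frame(label = r$values,
                     start = out$start[c(1, utils::head(cs, -1) + 1)],
                     end = out$end[cs])
  attr(out, "var_explained") <- var_explained
  attr(out, "reliable") <- var_explained >= 0.10
  attr(out, "segments") <- segs[segs$label != "NA", ]
  class(out) <- c("compartment_track", "data.frame")
  out
}

#' Insulation-score TAD calling
#'
#' The insulation score of bin `i` is `log2(mean contact in the w x w
#' square upstream-vs-downstream of the bin / chromosome mean of those
#' square means)`; it is defined only where the full square fits inside the
#' chromosome and the bin is unmasked. Boundaries are local minima (of the
#' 3-bin-smoothed score) whose prominence (mean of the flanking local maxima
#' minus the minimum) is at least `boundary_strength_min`; TADs are the
#' intervals between
#' consecutive boundaries (chromosome/defined-region ends included) of at
#' least `min_tad` bins.
#'
#' @param cm a balanced [contact_matrix].
#' @param chrom chromosome name.
#' @param w square size in bins.
#' @param boundary_strength_min minimum boundary prominence (log2 units).
#'   The default 0.25 sits about twice above the largest prominence Poisson
#'   counting noise produces on structureless maps at moderate coverage,
#'   and about twice below the weakest prominence of a genuine 2-fold
#'   contact-enriched domain boundary.
#' @param min_tad minimum TAD size in bins.
#' @return list: `insulation` (data.frame `bin` local 0-based, `chrom`,
#'   `start`, `end`, `score`), `boundaries` (data.frame `bin`, `strength`),
#'   `tads` (data.frame `chrom`, `start`, `end`, `start_bin`, `end_bin`,
#'   `n_bins`).
#' @export
insulation_tads <- function(cm, chrom, w = 10, boundary_strength_min = 0.25,
                            min_tad = 3) {
  D <- chrom_dense(cm, chrom)
  gb <- chrom_bins(cm$layout, chrom)
  m <- cm$mask[gb + 1L]
  n <- nrow(D)
  if (n < 2 * w + 1) stop(chrom, " shorter than 2w+1 bins")
  Dm <- D; Dm[m, ] <- NA; Dm[, m] <- NA
  raw <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {
    if (m[i]) next
    sq <- Dm[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
    if (all(is.na(sq))) next
    raw[i] <- mean(sq, na.rm = TRUE)
  }
  mu <- mean(raw[raw > 0], na.rm = TRUE)
  score <- ifelse(!is.na(raw) & raw > 0, log2(raw / mu), NA_real_)
  # extrema are found on a 3-bin running mean: single-bin Poisson noise in
  # the square means would otherwise clear the prominence threshold, while
  # genuine boundaries span several bins
  smooth3 <- function(z) {
    out <- z
    for (k in seq_along(z)) {
      w <- z[max(1, k - 1):min(length(z), k + 1)]
      out[k] <- if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
    }
    out
  }
  score_s <- smooth3(score)
  # local extrema over runs of defined bins
  boundaries <- list()
  def <- which(!is.na(score_s))
  if (length(def)) {
    runs <- split(def, cumsum(c(1, diff(def) > 1)))
    for (r in runs) {
      s <- score_s[r]
      if (length(s) < 3) next
      dd <- diff(s)
      sgn <- sign(dd); sgn[sgn == 0] <- 1
      turn <- diff(sgn)
      mins <- which(turn > 0) + 1
      maxs <- which(turn < 0) + 1
      for (mi in mins) {
        lmax <- maxs[maxs < mi]
        rmax <- maxs[maxs > mi]
        lv <- if (length(lmax)) s[max(lmax)] else s[1]
        rv <- if (length(rmax)) s[min(rmax)] else s[length(s)]
        strength <- mean(c(lv, rv)) - s[mi]
        if (strength >= boundary_strength_min)
          boundaries[[length(boundaries) + 1]] <-
            data.frame(bin = r[mi] - 1L, strength = strength)
      }
    }
  }
  bdf <- if (length(boundaries)) do.call(rbind, boundaries) else
    data.frame(bin = integer(0), strength = numeric(0))
  bins <- cm$layout$bins[cm$layout$bins$chrom == chrom, ]
  ins <- data.frame(bin = seq_len(n) - 1L, chrom = chrom,
                    start = bins$start, end = bins$end, score = score)
  edges <- sort(unique(c(0L, bdf$bin, n)))
  tads <- data.frame(start_bin = utils::head(edges, -1),
                     end_bin = edges[-1])
  tads$n_bins <- tads$end_bin - tads$start_bin
  tads <- tads[tads$n_bins >= min_tad, , drop = FALSE]
  tads <- data.frame(chrom = chrom,
                     start = tads$start_bin * cm$layout$bin_size,
                     end = pmin(tads$end_bin * cm$layout$bin_size,
                                cm$layout$lengths[[chrom]]),
                     tads, stringsAsFactors = FALSE)
  rownames(tads) <- NULL
  list(insulation = ins, boundaries = bdf, tads = tads)
}

#' Shared TAD boundaries between two TAD sets
#'
#' Greedy one-to-one matching: each boundary of `a` is matched to the
#' nearest unmatched boundary of `b` within `tol` bins.
#'
#' @param a,b results of [insulation_tads()] (their `boundaries` are used),
#'   or plain integer vectors of boundary bins.
#' @param tol matching tolerance in bins.
#' @param bin_size_a,bin_size_b bin sizes, checked for equality when given.
#' @return list: `n_shared`, `fraction` (of `a`'s boundaries matched),
#'   `matches` (data.frame `a_bin`, `b_bin`).
#' @export
tad_boundary_sharing <- function(a, b, tol = 1, bin_size_a = NULL,
                                 bin_size_b = NULL) {
  if (!is.null(bin_size_a) && !is.null(bin_size_b) &&
      bin_size_a != bin_size_b)
    stop("bin sizes differ")
  ab <- if (is.list(a) && !is.null(a$boundaries)) a$boundaries$bin else a
  bb <- if (is.list(b) && !is.null(b$boundaries)) b$boundaries$bin else b
  ab <- sort(ab); bb <- sort(bb)
  used <- logical(length(bb))
  matches <- list()
  for (x in ab) {
    d <- abs(bb - x)
    d[used] <- Inf
    k <- which.min(d)
    if (length(k) && is.finite(d[k]) && d[k] <= tol) {
      used[k] <- TRUE
      matches[[length(matches) + 1]] <- data.frame(a_bin = x, b_bin = bb[k])
    }
  }
  md <- if (length(matches)) do.call(rbind, matches) else
    data.frame(a_bin = integer(0), b_bin = integer(0))
  list(n_shared = nrow(md),
       fraction = if (length(ab)) nrow(md) / length(ab) else NA_real_,
       matches = md)
}

#' Contact-weighted cis distance-range fractions
#'
#' Every unmasked cis bin pair at distance `d > 0` contributes its balanced
#' count to one of three ranges: short (`d <= short_max`), mid
#' (`short_max < d <= mid_max`) or long (`d > mid_max`); the three
#' fractions sum to 1.
#'
#' @param cm a balanced [contact_matrix].
#' @param short_max,mid_max class edges in bp.
#' @param chroms chromosomes to include (default all).
#' @return named numeric `c(short =, mid =, long =)`.
#' @export
cis_range_fractions <- function(cm, short_max = 160e3, mid_max = 10e6,
                                chroms = cm$layout$chroms) {
  bs <- cm$layout$bin_size
  if (bs > short_max) stop("bin size exceeds the short-range edge")
  tot <- c(short = 0, mid = 0, long = 0)
  B <- balanced_matrix(cm)
  Bt <- as(B, "TsparseMatrix")
  ii <- Bt@i + 1L; jj <- Bt@j + 1L; xx <- Bt@x
  chrom_of <- cm$layout$bins$chrom
  cis <- chrom_of[ii] == chrom_of[jj] & ii < jj &
    chrom_of[ii] %in% chroms
  d <- (jj[cis] - ii[cis]) * bs
  x <- xx[cis]
  tot["short"] <- sum(x[d <= short_max])
  tot["mid"] <- sum(x[d > short_max & d <= mid_max])
  tot["long"] <- sum(x[d > mid_max])
  tot / sum(tot)
}

#' Significant cis/trans interaction calling
#'
#' Distance-stratified Poisson test. For cis pairs the expected balanced
#' count comes from the pair's geometric distance stratum (strata double in
#' width; strata with fewer than 10 pairs are merged into their neighbor);
#' for trans pairs from the mean balanced count over the chromosome pair's
#' unmasked bin pairs (zeros included). Balanced values are mapped back to
#' effective counts with a global raw/balanced scale, and
#' `p = P(Poisson(expected_eff) >= observed_eff)`; Benjamini-Hochberg
#' within the mode, calls retained at `q < fdr`.
#'
#' @param cm a balanced [contact_matrix].
#' @param mode `"cis"` or `"trans"`.
#' @param fdr BH threshold.
#' @return data.frame of calls (`bin1`, `bin2`, `chrom1`, `chrom2`,
#'   `distance_bp` (`NA` for trans), `observed`, `expected`, `p`, `q`,
#'   `mode`), with `attr(, "n_tested")`.
#' @export
call_significant_interactions <- function(cm, mode = c("cis", "trans"),
                                          fdr = 0.05) {
  mode <- match.arg(mode)
  B <- as(balanced_matrix(cm), "TsparseMatrix")
  ii <- B@i + 1L; jj <- B@j + 1L; xx <- B@x
  up <- ii < jj
  ii <- ii[up]; jj <- jj[up]; xx <- xx[up]
  chrom_of <- cm$layout$bins$chrom
  is_cis <- chrom_of[ii] == chrom_of[jj]
  live <- !cm$mask
  scale <- sum(cm$mat@x) / sum(B@x)            # balanced -> effective counts
  if (mode == "cis") {
    sel <- is_cis & (jj - ii) > 0
    i <- ii[sel]; j <- jj[sel]; x <- xx[sel]
    d <- j - i
    # per-chromosome unmasked pair counts per stratum, pooled genome-wide
    edges <- sort(unique(c(2^(0:ceiling(log2(max(d) + 1))), max(d) + 1)))
    stratum_of <- findInterval(d, edges)
    # total unmasked pairs at each distance (for zero-inclusive means)
    npairs_d <- numeric(max(d))
    for (ch in cm$layout$chroms) {
      lv <- live[chrom_bins(cm$layout, ch) + 1L]
      nc <- length(lv)
      if (nc < 2) next
      for (dd in 1:(nc - 1)) {
        if (dd > length(npairs_d)) break
        npairs_d[dd] <- npairs_d[dd] + sum(lv[1:(nc - dd)] & lv[(dd + 1):nc])
      }
    }
    st <- sort(unique(stratum_of))
    sums <- vapply(st, function(s) sum(x[stratum_of == s]), 0)
    cnts <- vapply(st, function(s) {
      dd <- which(findInterval(seq_along(npairs_d), edges) == s)
      sum(npairs_d[dd])
    }, 0)
    # merge sparse strata (< 10 pairs) into the previous one
    k <- 1
    while (k <= length(st)) {
      if (cnts[k] < 10 && length(st) > 1) {
        tgt <- if (k > 1) k - 1 else 2
        sums[tgt] <- sums[tgt] + sums[k]
        cnts[tgt] <- cnts[tgt] + cnts[k]
        stratum_of[stratum_of == st[k]] <- st[tgt]
        sums <- sums[-k]; cnts <- cnts[-k]; st <- st[-k]
      } else k <- k + 1
    }
    expmean <- (sums / cnts)[match(stratum_of, st)]
    expected <- expmean
    out <- data.frame(bin1 = i - 1L, bin2 = j - 1L,
                      chrom1 = chrom_of[i], chrom2 = chrom_of[j],
                      distance_bp = d * cm$layout$bin_size,
                      observed = x, expected = expected,
                      stringsAsFactors = FALSE)
  } else {
    sel <- !is_cis
    i <- ii[sel]; j <- jj[sel]; x <- xx[sel]
    cp <- paste(chrom_of[i], chrom_of[j])
    un_per_chrom <- vapply(cm$layout$chroms, function(ch)
      sum(live[chrom_bins(cm$layout, ch) + 1L]), 0)
    names(un_per_chrom) <- cm$layout$chroms
    psum <- tapply(x, cp, sum)
    npair <- un_per_chrom[sub(" .*", "", names(psum))] *
      un_per_chrom[sub(".* ", "", names(psum))]
    expected <- (psum / npair)[cp]
    out <- data.frame(bin1 = i - 1L, bin2 = j - 1L,
                      chrom1 = chrom_of[i], chrom2 = chrom_of[j],
                      distance_bp = NA_real_, observed = x,
                      expected = as.numeric(expected),
                      stringsAsFactors = FALSE)
  }
  obs_eff <- out$observed * scale
  exp_eff <- out$expected * scale
  out$p <- stats::ppois(ceiling(obs_eff) - 1, exp_eff, lower.tail = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$mode <- mode
  n_tested <- nrow(out)
  out <- out[out$q < fdr, , drop = FALSE]
  out <- out[order(out$q), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  out
}

#' Annotate interaction anchors against gene models
#'
#' Each anchor bin of each call is intersected with genomic features with
#' precedence promoter > exon > intron > intergenic. The promoter is
#' `[TSS - promoter_up, TSS + promoter_down)` oriented by strand.
#'
#' @param calls data.frame from [call_significant_interactions()].
#' @param genes a `gene_models` object ([read_gff3()]).
#' @param layout the binned [genome_layout] of the calls.
#' @param promoter_up,promoter_down promoter extent around the TSS (bp).
#' @return list: `anchors` (one row per anchor bin with `category`),
#'   `fractions` (named numeric over the four categories), `genes_by_category`.
#' @export
annotate_anchors <- function(calls, genes, layout, promoter_up = 2000,
                             promoter_down = 500) {
  g <- genes$genes
  e <- genes$exons
  prom_start <- ifelse(g$strand == "-", g$tss - promoter_down + 1,
                       g$tss - promoter_up)
  prom_end <- ifelse(g$strand == "-", g$tss + promoter_up + 1,
                     g$tss + promoter_down)
  bins <- layout$bins
  anchor_bins <- unique(c(calls$bin1, calls$bin2))
  cat_of <- character(length(anchor_bins))
  hit_genes <- vector("list", length(anchor_bins))
  for (k in seq_along(anchor_bins)) {
    b <- bins[bins$bin_id == anchor_bins[k], ]
    ov <- function(s, e2, chr) chr == b$chrom & s < b$end & e2 > b$start
    ph <- ov(prom_start, prom_end, g$chrom)
    if (any(ph)) {
      cat_of[k] <- "promoter"; hit_genes[[k]] <- g$gene_id[ph]; next
    }
    ge <- merge(e, g[, c("gene_id", "chrom")], by = "gene_id")
    eh <- ov(ge$start, ge$end, ge$chrom)
    if (any(eh)) {
      cat_of[k] <- "exon"; hit_genes[[k]] <- unique(ge$gene_id[eh]); next
    }
    gh <- ov(g$start, g$end, g$chrom)
    if (any(gh)) {
      cat_of[k] <- "intron"; hit_genes[[k]] <- g$gene_id[gh]; next
    }
    cat_of[k] <- "intergenic"
  }
  anchors <- data.frame(bin = anchor_bins, category = cat_of,
                        stringsAsFactors = FALSE)
  cats <- c("promoter", "exon", "intron", "intergenic")
  fr <- vapply(cats, function(cc) mean(cat_of == cc), 0)
  gl <- lapply(cats, function(cc)
    sort(unique(unlist(hit_genes[cat_of == cc]))))
  names(gl) <- cats
  list(anchors = anchors, fractions = fr, genes_by_category = gl)
}

#' Inter-chromosome contact scores and windowed trans profiles
#'
#' The contact score of a chromosome pair is `1e6 x` the sum of balanced
#' trans counts between them divided by the product of their unmasked bin
#' counts — a size-normalized spatial-proximity proxy.
#'
#' @param cm a balanced [contact_matrix].
#' @return data.frame `chromA`, `chromB`, `score` (all unordered pairs).
#' @export
contact_scores <- function(cm) {
  chroms <- cm$layout$chroms
  if (length(chroms) < 2) stop("need >= 2 chromosomes")
  live <- !cm$mask
  B <- as(balanced_matrix(cm), "TsparseMatrix")
  ii <- B@i + 1L; jj <- B@j + 1L; xx <- B@x
  up <- ii <= jj
  ii <- ii[up]; jj <- jj[up]; xx <- xx[up]
  chrom_of <- cm$layout$bins$chrom
  un <- vapply(chroms, function(ch) sum(live[chrom_bins(cm$layout, ch) + 1L]), 0)
  names(un) <- chroms
  out <- list()
  for (a in seq_along(chroms)) for (b in seq_along(chroms)) {
    if (b <= a) next
    A <- chroms[a]; Bc <- chroms[b]
    sel <- (chrom_of[ii] == A & chrom_of[jj] == Bc) |
      (chrom_of[ii] == Bc & chrom_of[jj] == A)
    denom <- un[A] * un[Bc]
    out[[length(out) + 1]] <- data.frame(
      chromA = A, chromB = Bc,
      score = if (denom > 0) 1e6 * sum(xx[sel]) / denom else 0,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname contact_scores
#' @param chromA,chromB chromosome pair for the windowed profile.
#' @param window,step sliding window on `chromA` (bp).
#' @return for `trans_profile`: data.frame `chrom`, `start`, `end`,
#'   `value` (balanced trans counts between the window and all of
#'   `chromB`).
#' @export
trans_profile <- function(cm, chromA, chromB, window = 5e5, step = 1e5) {
  B <- as(balanced_matrix(cm), "TsparseMatrix")
  ii <- B@i + 1L; jj <- B@j + 1L; xx <- B@x
  chrom_of <- cm$layout$bins$chrom
  # the symmetric matrix stores both orientations; keep one
  sel <- chrom_of[ii] == chromA & chrom_of[jj] == chromB
  ai <- ii[sel]
  x <- xx[sel]
  binsA <- cm$layout$bins[cm$layout$bins$chrom == chromA, ]
  mid <- (binsA$start + binsA$end) / 2
  lay1 <- genome_layout(chromA, cm$layout$lengths[[chromA]])
  wins <- tile_windows(lay1, window, step)
  wins$value <- vapply(seq_len(nrow(wins)), function(w) {
    inb <- binsA$bin_id[mid >= wins$start[w] & mid < wins$end[w]]
    sum(x[(ai - 1L) %in% inb])
  }, 0)
  wins
}

#' Correlation between two contact matrices
#'
#' Pearson correlation of `log(1 + balanced count)` over the union of
#' unmasked cis bin pairs of the two matrices. Because the shared distance
#' decay dominates raw counts, the correlation of the O/E-transformed
#' matrices (decay removed) is reported alongside; the raw-log value is the
#' headline number, the O/E value the structure-sensitive one.
#'
#' @param a,b balanced [contact_matrix] objects on the same layout.
#' @return list: `r_log` (log1p balanced), `r_oe` (O/E), `n_pairs`.
#' @export
matrix_correlation <- function(a, b) {
  if (!identical(a$layout$chroms, b$layout$chroms) ||
      !identical(unname(a$layout$lengths), unname(b$layout$lengths)) ||
      a$layout$bin_size != b$layout$bin_size)
    stop("layout mismatch")
  va <- vb <- oa <- ob <- list()
  for (ch in a$layout$chroms) {
    Da <- chrom_dense(a, ch); Db <- chrom_dense(b, ch)
    keep <- !(a$mask[chrom_bins(a$layout, ch) + 1L] |
                b$mask[chrom_bins(b$layout, ch) + 1L])
    ut <- upper.tri(Da)
    sel <- ut & outer(keep, keep, "&")
    va[[ch]] <- log1p(Da[sel]); vb[[ch]] <- log1p(Db[sel])
    Oa <- oe_transform(a, ch)$oe; Ob <- oe_transform(b, ch)$oe
    oa[[ch]] <- Oa[sel]; ob[[ch]] <- Ob[sel]
  }
  x <- unlist(va); y <- unlist(vb)
  xo <- unlist(oa); yo <- unlist(ob)
  ok <- is.finite(xo) & is.finite(yo)
  list(r_log = stats::cor(x, y),
       r_oe = stats::cor(xo[ok], yo[ok]),
       n_pairs = length(x))
}
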