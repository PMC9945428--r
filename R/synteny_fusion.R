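#' Chain homologous-gene anchors into collinear synteny blocks
#'
#' Greedy left-to-right chaining along each query chromosome: the current
#' block is extended while the next anchor hits the same target chromosome,
#' jumps at most `max_gap` target gene ranks, and moves in the block's
#' orientation (set by the first rank difference). Blocks with fewer than
#' `min_anchors` anchors are discarded.
#'
#' @param anchors anchor table ([read_anchors()] columns), sorted by
#'   (qchrom, qidx); duplicate `qidx` within a query chromosome is an error.
#' @param min_anchors minimum anchors per retained block.
#' @param max_gap maximum target gene-rank jump inside a block.
#' @return data.frame of class `synteny_blocks`: one row per block with
#'   `block`, `qchrom`, `tchrom`, `orientation` (+1/-1; 0 before the second
#'   anchor fixes it), `n_anchors`, `qstart`, `qend`, `tstart`, `tend`
#'   (bp, half-open), `qidx_start`, `qidx_end`, `tidx_min`, `tidx_max`.
#' @export
chain_anchors <- function(anchors, min_anchors = 5, max_gap = 25) {
  anchors <- validate_anchors(anchors)
  blocks <- list()
  for (qc in unique(anchors$qchrom)) {
    a <- anchors[anchors$qchrom == qc, , drop = FALSE]
    start <- 1; orient <- 0L
    flush <- function(from, to, orient) {
      if (to - from + 1 < min_anchors) return()
      seg <- a[from:to, ]
      blocks[[length(blocks) + 1]] <<- data.frame(
        qchrom = qc, tchrom = seg$tchrom[1],
        orientation = if (orient == 0) 1L else orient,
        n_anchors = nrow(seg),
        qstart = min(seg$qpos), qend = max(seg$qpos) + 1,
        tstart = min(seg$tpos), tend = max(seg$tpos) + 1,
        qidx_start = seg$qidx[1], qidx_end = seg$qidx[nrow(seg)],
        tidx_min = min(seg$tidx), tidx_max = max(seg$tidx),
        stringsAsFactors = FALSE)
    }
    if (nrow(a) == 1) { flush(1, 1, 0L); next }
    for (k in 2:nrow(a)) {
      dt <- a$tidx[k] - a$tidx[k - 1]
      same <- a$tchrom[k] == a$tchrom[k - 1] && abs(dt) <= max_gap &&
        dt != 0 && (orient == 0L || sign(dt) == orient)
      if (same) {
        if (orient == 0L) orient <- sign(dt)
      } else {
        flush(start, k - 1, orient)
        start <- k; orient <- 0L
      }
    }
    flush(start, nrow(a), orient)
  }
  out <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(qchrom = character(0), tchrom = character(0),
               orientation = integer(0), n_anchors = integer(0),
               qstart = numeric(0), qend = numeric(0), tstart = numeric(0),
               tend = numeric(0), qidx_start = integer(0),
               qidx_end = integer(0), tidx_min = numeric(0),
               tidx_max = numeric(0))
  out <- out[order(out$qchrom, out$qstart), , drop = FALSE]
  out$block <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("synteny_blocks", "data.frame")
  out
}

#' Count rearrangement breakpoints between adjacent synteny blocks
#'
#' Each adjacent block pair on a query chromosome contributes one
#' breakpoint, classified by what changes across the junction: target
#' chromosome (`interchromosomal`), orientation (`inversion`), or — with
#' target and orientation unchanged — a target-rank displacement
#' (`translocation`). The breakpoint position is the midpoint of the
#' inter-block gap.
#'
#' @param blocks output of [chain_anchors()].
#' @return list: `breakpoints` (data.frame `qchrom`, `qpos`, `kind`),
#'   `per_chrom` (data.frame `qchrom`, `inversion`, `translocation`,
#'   `interchromosomal`, `total`).
#' @export
count_rearrangements <- function(blocks) {
  bps <- list()
  for (qc in unique(blocks$qchrom)) {
    b <- blocks[blocks$qchrom == qc, , drop = FALSE]
    if (nrow(b) < 2) next
    for (k in 2:nrow(b)) {
      prev <- b[k - 1, ]; cur <- b[k, ]
      kind <- if (cur$tchrom != prev$tchrom) "interchromosomal"
        else if (cur$orientation != prev$orientation) "inversion"
        else "translocation"  # same target and orientation, but the chain
                              # broke: a rank jump/displacement lies between
      bps[[length(bps) + 1]] <- data.frame(
        qchrom = qc, qpos = (prev$qend - 1 + cur$qstart) / 2, kind = kind,
        stringsAsFactors = FALSE)
    }
  }
  bp <- if (length(bps)) do.call(rbind, bps) else
    data.frame(qchrom = character(0), qpos = numeric(0), kind = character(0))
  per <- data.frame(qchrom = unique(blocks$qchrom), stringsAsFactors = FALSE)
  for (k in c("inversion", "translocation", "interchromosomal"))
    per[[k]] <- vapply(per$qchrom,
                       function(qc) sum(bp$qchrom == qc & bp$kind == k), 0)
  per$total <- rowSums(per[, -1, drop = FALSE])
  list(breakpoints = bp, per_chrom = per)
}

#' Detect an autosome-autosome fusion from the block sequence
#'
#' A query chromosome is a fusion candidate when, after dropping at most
#' `max_noise_blocks` blocks, its block sequence is a prefix mapping
#' entirely to one target chromosome followed by a suffix mapping to a
#' second. The fusion position is the midpoint between the last prefix
#' block and the first suffix block.
#'
#' @param blocks output of [chain_anchors()].
#' @param max_noise_blocks how many stray blocks may be ignored.
#' @return data.frame (possibly 0-row): `qchrom`, `targetA`, `targetB`,
#'   `fusion_pos`, `support_A`, `support_B` (anchors on each side).
#' @export
detect_fusion <- function(blocks, max_noise_blocks = 1) {
  out <- list()
  for (qc in unique(blocks$qchrom)) {
    b <- blocks[blocks$qchrom == qc, , drop = FALSE]
    tc <- b$tchrom
    best <- NULL
    for (drop_n in 0:max_noise_blocks) {
      if (drop_n >= nrow(b)) break
      drops <- if (drop_n == 0) list(integer(0)) else
        utils::combn(nrow(b), drop_n, simplify = FALSE)
      for (dr in drops) {
        keep <- setdiff(seq_len(nrow(b)), dr)
        t2 <- tc[keep]
        r <- rle(t2)
        if (length(r$values) == 2 && r$values[1] != r$values[2]) {
          k <- r$lengths[1]
          prefix <- b[keep[seq_len(k)], ]
          suffix <- b[keep[(k + 1):length(keep)], ]
          best <- data.frame(
            qchrom = qc, targetA = r$values[1], targetB = r$values[2],
            fusion_pos = (max(prefix$qend) - 1 + min(suffix$qstart)) / 2,
            support_A = sum(prefix$n_anchors),
            support_B = sum(suffix$n_anchors), stringsAsFactors = FALSE)
          break
        }
      }
      if (!is.null(best)) break
    }
    if (!is.null(best)) out[[qc]] <- best
  }
  if (!length(out))
    return(data.frame(qchrom = character(0), targetA = character(0),
                      targetB = character(0), fusion_pos = numeric(0),
                      support_A = numeric(0), support_B = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Delimit highly rearranged regions (HRRs)
#'
#' Breakpoints are counted in sliding windows; windows with a count at
#' least `mean + k_sigma * sd` (computed genome-wide over all windows) are
#' flagged, and maximal runs of flagged (overlapping) windows are merged
#' into HRR intervals. Because any tight cluster of a few breakpoints flags
#' the full footprint of the windows containing it, merged intervals
#' shorter than `min_span` (by default twice the window size — wider than a
#' single window's footprint) are discarded; a genuine HRR extends over
#' many windows.
#'
#' @param breakpoints data.frame from [count_rearrangements()].
#' @param layout a [genome_layout].
#' @param window,step window size and step in bp.
#' @param k_sigma threshold in genome-wide SDs above the mean window count.
#' @param min_span minimum merged-interval extent in bp.
#' @return data.frame: `chrom`, `start`, `end`, `n_breakpoints`.
#' @export
detect_hrr <- function(breakpoints, layout, window = 1e6, step = 2e5,
                       k_sigma = 2, min_span = 2 * window) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_breakpoints = numeric(0))
  if (!nrow(breakpoints)) return(empty)
  bp <- data.frame(chrom = breakpoints$qchrom, pos = breakpoints$qpos + 1)
  bp <- bp[order(bp$chrom, bp$pos), ]
  track <- window_scan(bp, layout, window, step, mode = "count")
  thr <- mean(track$value) + k_sigma * stats::sd(track$value)
  hot <- track[track$value >= thr & track$value > 0, , drop = FALSE]
  if (!nrow(hot)) return(empty)
  out <- list()
  for (ch in unique(hot$chrom)) {
    h <- hot[hot$chrom == ch, , drop = FALSE]
    h <- h[order(h$start), ]
    grp <- cumsum(c(1, h$start[-1] > utils::head(h$end, -1)))
    for (g in unique(grp)) {
      seg <- h[grp == g, ]
      s <- min(seg$start); e <- max(seg$end)
      if (e - s < min_span) next
      n <- sum(bp$chrom == ch & bp$pos - 1 >= s & bp$pos - 1 < e)
      out[[length(out) + 1]] <- data.frame(chrom = ch, start = s, end = e,
                                           n_breakpoints = n)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
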