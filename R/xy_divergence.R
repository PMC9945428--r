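# Genetic-code helpers shared by the Ka/Ks machinery and the alignment
# generator. The code table comes from Biostrings (standard code, DNA).

genetic_code <- function() Biostrings::GENETIC_CODE

codon_aa <- function(codon) unname(genetic_code()[codon])

is_stop <- function(codon) codon_aa(codon) == "*"

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}
# constant used by gen_codon_alignments
delayedAssign("SENSE_CODONS", sense_codons())

NUC <- c("A", "C", "G", "T")

# all 9 single-nucleotide neighbours of a codon, classified
codon_single_mutations <- function(codon) {
  s <- strsplit(codon, "")[[1]]
  out <- list()
  for (p in 1:3) for (n in setdiff(NUC, s[p])) {
    m <- s; m[p] <- n
    mc <- paste(m, collapse = "")
    out[[length(out) + 1]] <- data.frame(
      codon = mc, pos = p,
      syn = identical(codon_aa(mc), codon_aa(codon)),
      stop = is_stop(mc), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# per-codon synonymous site count: at each position, the fraction of the
# three single-nucleotide changes that preserve the amino acid (changes to
# stop codons count as nonsynonymous, as in the original counting method)
codon_syn_sites <- function(codon) {
  muts <- codon_single_mutations(codon)
  sum(muts$syn) / 3
}

# memoized lookup tables (computed once per session)
codon_env <- new.env(parent = emptyenv())
syn_sites_table <- function() {
  if (is.null(codon_env$syn)) {
    cods <- names(genetic_code())
    codon_env$syn <- vapply(cods, codon_syn_sites, 0)
  }
  codon_env$syn
}

# pathway-averaged (Sd, Nd) contribution of one codon pair; pathways through
# stop codons are excluded unless no stop-free pathway exists
codon_pair_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  key <- paste(c1, c2)
  if (!is.null(codon_env$pair[[key]])) return(codon_env$pair[[key]])
  paths <- permutations_of(pos)
  acc <- matrix(NA_real_, nrow = nrow(paths), ncol = 2)
  blocked <- logical(nrow(paths))
  for (r in seq_len(nrow(paths))) {
    cur <- c1; sd <- 0; nd <- 0
    for (p in paths[r, ]) {
      nxt <- strsplit(cur, "")[[1]]
      nxt[p] <- strsplit(c2, "")[[1]][p]
      nxt <- paste(nxt, collapse = "")
      if (is_stop(nxt)) blocked[r] <- TRUE
      if (identical(codon_aa(cur), codon_aa(nxt))) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    acc[r, ] <- c(sd, nd)
  }
  use <- if (all(blocked)) seq_len(nrow(paths)) else which(!blocked)
  res <- c(sd = mean(acc[use, 1]), nd = mean(acc[use, 2]))
  if (is.null(codon_env$pair)) codon_env$pair <- list()
  codon_env$pair[[key]] <- res
  res
}

permutations_of <- function(x) {
  if (length(x) == 1) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], permutations_of(x[-i])))
  out
}

# Jukes-Cantor multiple-hit correction; NA when saturated (p >= 3/4)
jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - (4 / 3) * p), NA_real_)
}

#' Nei-Gojobori Ka/Ks for one codon-aligned sequence pair
#'
#' Counting method with equal pathway weighting: synonymous site counts per
#' codon come from the standard genetic code (mutations to stops counted as
#' nonsynonymous sites); codon pairs differing at `k > 1` positions average
#' observed synonymous/nonsynonymous differences over all `k!` mutational
#' pathways, excluding pathways that pass through a stop codon (unless every
#' pathway does). `pS = Sd/S` and `pN = Nd/N` get the Jukes-Cantor
#' correction `d = -(3/4) ln(1 - (4/3) p)`, reported `NA` with a `saturated`
#' flag when `p >= 3/4`.
#'
#' @param a,b codon-aligned DNA strings (equal length, multiple of 3).
#'   Codons containing gaps (`-`) or ambiguity codes are skipped in both
#'   sequences.
#' @param gene optional identifier carried into the result.
#' @return one-row data.frame of class `kaks_result`: `gene`, `codons`
#'   (used), `N`, `S`, `Nd`, `Sd`, `pN`, `pS`, `ka`, `ks`, `ka_ks`,
#'   `saturated`.
#' @export
#' @examples
#' # one synonymous third-position change among ten Phe codons
#' nei_gojobori(strrep("TTT", 10), paste0(strrep("TTT", 9), "TTC"))
nei_gojobori <- function(a, b, gene = NA_character_) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("aligned sequences differ in length")
  if (nchar(a) %% 3 != 0) stop("aligned length must be a multiple of 3")
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[clean]; cb <- cb[clean]
  if (!length(ca)) stop("no ungapped codons in alignment")
  if (any(is_stop(ca)) || any(is_stop(cb)))
    stop("internal stop codon in alignment")
  st <- syn_sites_table()
  S <- (sum(st[ca]) + sum(st[cb])) / 2
  N <- 3 * length(ca) - S
  diffs <- mapply(function(x, y) codon_pair_diffs(x, y), ca, cb)
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  pS <- Sd / S; pN <- Nd / N
  ks <- jc_correct(pS); ka <- jc_correct(pN)
  out <- data.frame(gene = gene, codons = length(ca), N = N, S = S,
                    Nd = Nd, Sd = Sd, pN = pN, pS = pS, ka = ka, ks = ks,
                    ka_ks = ifelse(!is.na(ks) & ks > 0, ka / ks, NA_real_),
                    saturated = (!is.na(pS) & pS >= 0.75) |
                      (!is.na(pN) & pN >= 0.75),
                    stringsAsFactors = FALSE)
  class(out) <- c("kaks_result", "data.frame")
  out
}

#' Ka/Ks over a list of aligned gene pairs
#' @param pairs list of `list(a =, b =)` codon-aligned pairs (e.g. from
#'   [gen_codon_alignments()]).
#' @param genes optional identifiers.
#' @return row-bound [nei_gojobori()] results.
#' @export
kaks_table <- function(pairs, genes = seq_along(pairs)) {
  do.call(rbind, Map(function(p, g) nei_gojobori(p$a, p$b, gene = g),
                     pairs, genes))
}

#' Windowed nucleotide identity of a pairwise alignment
#'
#' Alignment columns are assigned to reference (first-sequence) coordinates;
#' gap columns do not advance the reference and are excluded from the
#' identity denominator, so identity = matches / (matches + mismatches).
#'
#' @param a reference-aligned sequence (defines coordinates).
#' @param b the other aligned sequence (same length).
#' @param window,step window and step in reference bp.
#' @return data.frame (`chrom` = "ref", `start`, `end`, `value`, `n_sites`)
#'   with the global identity in `attr(, "global")`.
#' @export
identity_windows <- function(a, b, window = 1e5, step = window) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("aligned sequences differ in length")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  refpos <- cumsum(av != "-") - 1            # 0-based ref coordinate
  refpos[av == "-"] <- refpos[av == "-"]     # gap cols inherit prev base
  comp <- av != "-" & bv != "-"
  match <- comp & av == bv
  reflen <- sum(av != "-")
  lay <- genome_layout("ref", reflen)
  wins <- tile_windows(lay, window, step)
  idx <- findInterval(refpos, seq(0, reflen, by = step))
  val <- n <- numeric(nrow(wins))
  for (w in seq_len(nrow(wins))) {
    inw <- refpos >= wins$start[w] & refpos < wins$end[w] & comp
    n[w] <- sum(inw)
    val[w] <- if (n[w]) sum(match[inw]) / n[w] else NA_real_
  }
  out <- data.frame(chrom = "ref", start = wins$start, end = wins$end,
                    value = val, n_sites = n)
  attr(out, "global") <- sum(match) / sum(comp)
  out
}

#' Evolutionary-strata scan: changepoints in Ks along the chromosome
#'
#' Binary segmentation on per-gene Ks ordered by position: at each step the
#' candidate split maximizes the standardized between-segment mean
#' difference `|mean_L - mean_R| * sqrt(nL nR / n)`; its significance is
#' assessed by permuting Ks values within the segment (`n_perm`
#' permutations) and recursion stops when the permutation p-value exceeds
#' `alpha / 2^depth` (a per-depth Bonferroni guard against the doubling
#' number of tests).
#'
#' @param pos gene positions (bp on the X chromosome).
#' @param ks per-gene Ks (same order).
#' @param n_perm permutations per split test.
#' @param alpha base significance level.
#' @param min_seg smallest allowed segment (genes).
#' @param seed seed for the permutation draws.
#' @return list: `segments` (data.frame `start_gene`, `end_gene`, `start`,
#'   `end`, `mean_ks`), `changepoints` (data.frame `after_gene`, `pos`,
#'   `p`).
#' @export
strata_scan <- function(pos, ks, n_perm = 1000, alpha = 0.05, min_seg = 5,
                        seed = 1) {
  stopifnot(length(pos) == length(ks))
  if (length(ks) < 10) stop("need at least 10 genes")
  o <- order(pos)
  pos <- pos[o]; ks <- ks[o]
  set.seed(as.integer(seed))
  cps <- list()
  recurse <- function(lo, hi, depth) {
    n <- hi - lo + 1
    if (n < 2 * min_seg) return()
    x <- ks[lo:hi]
    stat <- function(z) {
      n <- length(z)
      cs <- cumsum(z); tot <- cs[n]
      k <- min_seg:(n - min_seg)
      ml <- cs[k] / k; mr <- (tot - cs[k]) / (n - k)
      s <- abs(ml - mr) * sqrt(k * (n - k) / n)
      c(max(s), k[which.max(s)])
    }
    obs <- stat(x)
    perm <- vapply(seq_len(n_perm), function(i) stat(sample(x))[1], 0)
    p <- (1 + sum(perm >= obs[1])) / (n_perm + 1)
    if (p < alpha / 2^depth) {
      k <- lo + obs[2] - 1
      cps[[length(cps) + 1]] <<- data.frame(
        after_gene = k, pos = (pos[k] + pos[k + 1]) / 2, p = p)
      recurse(lo, k, depth + 1)
      recurse(k + 1, hi, depth + 1)
    }
  }
  recurse(1, length(ks), 0)
  cp <- if (length(cps)) do.call(rbind, cps) else
    data.frame(after_gene = integer(0), pos = numeric(0), p = numeric(0))
  cp <- cp[order(cp$after_gene), , drop = FALSE]
  bnd <- c(0, cp$after_gene, length(ks))
  segs <- data.frame(
    start_gene = utils::head(bnd, -1) + 1, end_gene = bnd[-1])
  segs$start <- pos[segs$start_gene]; segs$end <- pos[segs$end_gene]
  segs$mean_ks <- mapply(function(a, b) mean(ks[a:b]),
                         segs$start_gene, segs$end_gene)
  list(segments = segs, changepoints = cp)
}

#' Repeat-subfamily abundance Z-score landscape
#'
#' Abundance is the fraction of each chromosome covered by each subfamily
#' (summed repeat bp / chromosome length); each subfamily row is then
#' standardized across chromosomes (`Z = (x - mean) / sd`), so enrichment of
#' a subfamily on one chromosome stands out against its genome-wide level.
#' Rows with zero variance get a zero Z row.
#'
#' @param records repeat table ([read_repeat_table()] columns).
#' @param layout a [genome_layout].
#' @return list with matrices `abundance` and `Z`
#'   (subfamilies x chromosomes) and `mean_divergence` (same shape).
#' @export
repeat_zscores <- function(records, layout) {
  bad <- setdiff(unique(records$chrom), layout$chroms)
  if (length(bad)) stop("unknown chromosome in repeat table: ", bad[1])
  sfs <- sort(unique(records$subfamily))
  ab <- dv <- matrix(0, length(sfs), length(layout$chroms),
                     dimnames = list(sfs, layout$chroms))
  bp <- tapply(records$end - records$start,
               list(records$subfamily, records$chrom), sum)
  dvt <- tapply(records$divergence,
                list(records$subfamily, records$chrom), mean)
  ab[rownames(bp), colnames(bp)] <- ifelse(is.na(bp), 0, bp)
  ab <- sweep(ab, 2, layout$lengths[colnames(ab)], "/")
  dv[rownames(dvt), colnames(dvt)] <- ifelse(is.na(dvt), NA, dvt)
  z <- t(apply(ab, 1, function(r) {
    s <- stats::sd(r)
    if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  dimnames(z) <- dimnames(ab)
  list(abundance = ab, Z = z, mean_divergence = dv)
}

#' Satellite-based centromere localization
#'
#' Selects the genome-wide most abundant satellite subfamily (total bp among
#' records of class "Satellite"), computes its windowed bp density per
#' chromosome, and reports per chromosome the contiguous run of windows —
#' containing that chromosome's densest window — whose density is at least
#' half the chromosome maximum.
#'
#' @param records repeat table.
#' @param layout a [genome_layout].
#' @param window window size in bp.
#' @return data.frame (`chrom`, `start`, `end`, `subfamily`,
#'   `peak_density`); zero rows (with a message) when no satellite records
#'   exist.
#' @export
centromere_scan <- function(records, layout, window = 1e5) {
  sat <- records[records$class == "Satellite", , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), subfamily = character(0),
                      peak_density = numeric(0))
  if (!nrow(sat)) {
    message("no Satellite-class repeats; centromere scan skipped")
    return(empty)
  }
  tot <- tapply(sat$end - sat$start, sat$subfamily, sum)
  top <- names(tot)[which.max(tot)]
  sat <- sat[sat$subfamily == top, , drop = FALSE]
  out <- list()
  for (ch in intersect(layout$chroms, unique(sat$chrom))) {
    s <- sat[sat$chrom == ch, ]
    len <- layout$lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = window)
    dens <- vapply(starts, function(w0) {
      w1 <- min(w0 + window, len)
      sum(pmax(0, pmin(s$end, w1) - pmax(s$start, w0))) / (w1 - w0)
    }, 0)
    if (max(dens) == 0) next
    peak <- which.max(dens)
    ok <- dens >= 0.5 * dens[peak]
    lo <- peak; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
    hi <- peak; while (hi < length(ok) && ok[hi + 1]) hi <- hi + 1
    out[[ch]] <- data.frame(chrom = ch, start = starts[lo],
                            end = min(starts[hi] + window, len),
                            subfamily = top, peak_density = dens[peak],
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
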