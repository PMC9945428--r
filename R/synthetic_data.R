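#' Synthetic pool-seq allele counts with a planted sex-determining region
#'
#' Emulates a two-pool resequencing design (an XX-female pool and a
#' YY-supermale pool, replicated in independent batches). Background sites
#' share an allele frequency `p ~ Uniform(0.05, 0.95)` between the pools;
#' planted SDR sites are fixed reference in pool 1 (`p = 0`) and fixed
#' alternate in pool 2 (`p = 1`). Read counts are Binomial(depth, p) per pool
#' and batch, and sequencing error flips each read independently with rate
#' `error_rate`, so the observed alternate-read probability is
#' `p (1 - e) + (1 - p) e`.
#'
#' @param layout a [genome_layout].
#' @param n_background_sites number of non-sex-linked variant sites.
#' @param sdr list/vector `(chrom, start, end)` of the planted SDR
#'   (0-based half-open bp).
#' @param n_sdr_sites number of planted male-specific sites inside `sdr`.
#' @param pool_sizes haploid sample sizes `c(n1, n2)` of the two pools
#'   (default 40 = 2 x 20 individuals each).
#' @param depth read depth per site and pool.
#' @param error_rate per-read error (flip) rate, `0 <= e < 0.5`.
#' @param n_batches number of replicate batches.
#' @param seed integer seed; the generator is deterministic given
#'   (parameters, seed).
#' @return list with `batches` (list of [pool_sites] tables, one per batch)
#'   and `truth` (list: `sdr`, `sdr_positions` of planted sites, 1-based).
#' @export
gen_pool_counts <- function(layout, n_background_sites = 20000,
                            sdr = list(chrom = layout$chroms[1],
                                       start = 1e6, end = 1.3e6),
                            n_sdr_sites = 600, pool_sizes = c(40, 40),
                            depth = 30, error_rate = 0.01, n_batches = 2,
                            seed = 1) {
  sdr <- as.list(sdr); names(sdr) <- c("chrom", "start", "end")
  sdr$start <- as.numeric(sdr$start); sdr$end <- as.numeric(sdr$end)
  if (!sdr$chrom %in% layout$chroms) stop("SDR chromosome not in layout")
  if (sdr$end > layout$lengths[[sdr$chrom]] || sdr$start < 0)
    stop("SDR outside its chromosome")
  if (n_sdr_sites > sdr$end - sdr$start)
    stop("n_sdr_sites exceeds 1-bp site density of the SDR")
  stopifnot(depth > 0, error_rate >= 0, error_rate < 0.5)
  seed_rng(seed)
  tot <- sum(layout$lengths)
  # background site positions genome-wide (0-based), distinct
  gpos <- sort(sample.int(tot, n_background_sites))
  off <- cumsum(c(0, layout$lengths))
  ci <- findInterval(gpos - 1, off, rightmost.closed = FALSE)
  bg_chrom <- layout$chroms[ci]
  bg_pos <- gpos - off[ci]              # 1-based within chromosome
  # planted male-specific sites, distinct positions inside the SDR
  sp <- sort(sample.int(sdr$end - sdr$start, n_sdr_sites)) + sdr$start
  p_bg <- stats::runif(n_background_sites, 0.05, 0.95)
  alleles <- c("A", "C", "G", "T")
  mk_alleles <- function(n) {
    r <- sample(alleles, n, replace = TRUE)
    a <- sample(alleles, n, replace = TRUE)
    clash <- a == r
    a[clash] <- alleles[(match(r[clash], alleles)) %% 4 + 1]
    list(ref = r, alt = a)
  }
  al_bg <- mk_alleles(n_background_sites)
  al_sdr <- mk_alleles(n_sdr_sites)
  chrom <- c(bg_chrom, rep(sdr$chrom, n_sdr_sites))
  pos <- c(bg_pos, sp)
  ref <- c(al_bg$ref, al_sdr$ref)
  alt <- c(al_bg$alt, al_sdr$alt)
  p1 <- c(p_bg, rep(0, n_sdr_sites))
  p2 <- c(p_bg, rep(1, n_sdr_sites))
  e <- error_rate
  batches <- lapply(seq_len(n_batches), function(b) {
    a1 <- stats::rbinom(length(p1), depth, p1 * (1 - e) + (1 - p1) * e)
    a2 <- stats::rbinom(length(p2), depth, p2 * (1 - e) + (1 - p2) * e)
    pool_sites(chrom, pos, ref, alt, depth - a1, a1, depth - a2, a2,
               pool_sizes[1], pool_sizes[2])
  })
  list(batches = batches,
       truth = list(sdr = sdr, sdr_positions = sp))
}

#' Synthetic Hi-C contact map with planted TADs, compartments and loops
#'
#' Cis expectation
#' `mu_ij = C * max(|i-j|, 1)^-gamma * (1 + delta * v_i * v_j) *
#'  tau^[same TAD] * (1 + loop_strength * [planted loop])`;
#' trans expectation `C_t * (1 + delta * v_i * v_j)`. Counts are Poisson and
#' symmetric; `C` is set so the mean cis count equals `coverage`.
#'
#' @param layout a binned [genome_layout].
#' @param gamma distance-decay exponent (`>= 0`).
#' @param tad_boundaries integer vector of global bin indices (0-based) at
#'   which TADs start/end; chromosome ends are implicit boundaries.
#' @param tau within-TAD contact enrichment (`>= 1`).
#' @param v per-bin compartment vector of +1/-1 (length = total bins); NULL
#'   for none.
#' @param delta compartment checkerboard strength, `0 <= delta < 1`.
#' @param loops 2-column matrix of global bin pairs, or NULL.
#' @param loop_strength extra enrichment at loop pixels.
#' @param coverage target mean cis count per bin pair.
#' @param trans_scale trans mean as a fraction of `coverage`.
#' @param seed integer seed.
#' @return list with `cm` (a [contact_matrix]) and `truth` (boundaries,
#'   `v`, loops).
#' @export
gen_contact_map <- function(layout, gamma = 1, tad_boundaries = integer(0),
                            tau = 1, v = NULL, delta = 0, loops = NULL,
                            loop_strength = 0, coverage = 50,
                            trans_scale = 0.05, seed = 1) {
  stopifnot(gamma >= 0, tau >= 1, delta >= 0, delta < 1)
  n <- n_bins(layout)
  if (is.null(v)) v <- rep(1, n)
  stopifnot(length(v) == n, all(v %in% c(-1, 1)))
  if (length(tad_boundaries) &&
      (min(tad_boundaries) < 0 || max(tad_boundaries) >= n))
    stop("TAD boundary out of range")
  seed_rng(seed)
  chrom_of <- rep(seq_along(layout$chroms),
                  vapply(layout$chroms, function(c) n_bins(layout, c), 0L))
  # TAD id per bin: segments between boundaries, restarting at chromosomes
  brk <- sort(unique(c(tad_boundaries,
                       cumsum(table(chrom_of)[as.character(seq_along(layout$chroms))]))))
  tad_id <- findInterval(seq_len(n) - 1, brk, left.open = TRUE)
  ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  cis <- chrom_of[i] == chrom_of[j]
  d <- pmax(abs(i - j), 1)
  mu <- numeric(length(i))
  base <- d[cis]^(-gamma) * (1 + delta * v[i[cis]] * v[j[cis]]) *
    tau^(tad_id[i[cis]] == tad_id[j[cis]] & i[cis] != j[cis])
  mu[cis] <- base
  Cc <- coverage / mean(base)
  mu[cis] <- mu[cis] * Cc
  if (any(!cis))
    mu[!cis] <- coverage * trans_scale * (1 + delta * v[i[!cis]] * v[j[!cis]])
  if (!is.null(loops) && nrow(loops)) {
    lk <- paste(pmin(loops[, 1], loops[, 2]), pmax(loops[, 1], loops[, 2]))
    hit <- paste(i - 1, j - 1) %in% lk | paste(j - 1, i - 1) %in% lk
    mu[hit] <- mu[hit] * (1 + loop_strength)
  }
  x <- stats::rpois(length(mu), mu)
  keep <- x > 0
  cm <- contact_matrix(layout, i[keep] - 1L, j[keep] - 1L, x[keep])
  list(cm = cm,
       truth = list(tad_boundaries = sort(tad_boundaries), v = v,
                    loops = loops, gamma = gamma, tau = tau, delta = delta))
}

#' Synthetic codon-aligned sequence pairs with known substitution counts
#'
#' Draws a random stop-free codon sequence and applies the requested numbers
#' of single-nucleotide synonymous and nonsynonymous substitutions, each in a
#' distinct codon, never creating a stop codon.
#'
#' @param n_genes number of gene pairs.
#' @param n_codons codons per gene.
#' @param syn_changes_per_gene,nonsyn_changes_per_gene substitutions per gene
#'   (recycled to `n_genes`; may be vectors for per-gene counts).
#' @param seed integer seed.
#' @return list with `pairs` (list of list(a =, b =) character strings) and
#'   `truth` (data.frame `gene`, `syn`, `nonsyn`).
#' @export
gen_codon_alignments <- function(n_genes = 10, n_codons = 300,
                                 syn_changes_per_gene = 2,
                                 nonsyn_changes_per_gene = 2, seed = 1) {
  seed_rng(seed)
  syn <- rep_len(syn_changes_per_gene, n_genes)
  nsy <- rep_len(nonsyn_changes_per_gene, n_genes)
  pairs <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    if (syn[g] + nsy[g] > n_codons)
      stop("requested more changes than codons in gene ", g)
    a <- sample(SENSE_CODONS, n_codons, replace = TRUE)
    b <- a
    # candidate single-nt mutations per codon, classified
    pickable <- sample(seq_len(n_codons))
    placed_s <- 0; placed_n <- 0
    for (ci in pickable) {
      if (placed_s >= syn[g] && placed_n >= nsy[g]) break
      muts <- codon_single_mutations(b[ci])
      syn_m <- muts[muts$syn & !muts$stop, , drop = FALSE]
      non_m <- muts[!muts$syn & !muts$stop, , drop = FALSE]
      if (placed_s < syn[g] && nrow(syn_m)) {
        b[ci] <- syn_m$codon[sample.int(nrow(syn_m), 1)]
        placed_s <- placed_s + 1
      } else if (placed_n < nsy[g] && nrow(non_m)) {
        b[ci] <- non_m$codon[sample.int(nrow(non_m), 1)]
        placed_n <- placed_n + 1
      }
    }
    if (placed_s < syn[g] || placed_n < nsy[g])
      stop("could not place requested changes in gene ", g)
    pairs[[g]] <- list(a = paste(a, collapse = ""),
                       b = paste(b, collapse = ""))
  }
  list(pairs = pairs,
       truth = data.frame(gene = seq_len(n_genes), syn = syn, nonsyn = nsy))
}

#' Synthetic homologous-gene anchors with planted fusion and rearrangements
#'
#' Query gene order is `1..n` per query chromosome; the target order is
#' collinear except for planted events. A fusion splits one query chromosome
#' into a prefix mapping to `targetA` and a suffix mapping to `targetB`.
#' Inversions reverse the target rank order and flip strand over a query
#' index range; translocations displace a range's target ranks to the end of
#' the target chromosome.
#'
#' @param genes_per_chrom named integer vector: query chromosomes and their
#'   gene counts.
#' @param gene_spacing bp between consecutive gene starts.
#' @param fusion NULL or list `(qchrom, targetA, targetB, fusion_index)`:
#'   query genes `1..fusion_index` map to `targetA`, the rest to `targetB`.
#' @param inversions list of `(qchrom, from, to)` query gene-rank ranges.
#' @param translocations list of `(qchrom, from, to)` ranges.
#' @param seed integer seed (reserved; the construction is deterministic).
#' @return list with `anchors` (see [read_anchors()]) and `truth`
#'   (fusion point in bp, event breakpoint positions in bp).
#' @export
gen_anchors <- function(genes_per_chrom = c(q1 = 400), gene_spacing = 5e4,
                        fusion = NULL, inversions = list(),
                        translocations = list(), seed = 1) {
  seed_rng(seed)
  evs <- c(lapply(inversions, function(e) c(e, kind = "inv")),
           lapply(translocations, function(e) c(e, kind = "tra")))
  # overlap check within chromosome
  by_chr <- split(evs, vapply(evs, function(e) e$qchrom, ""))
  for (g in by_chr) {
    rng <- do.call(rbind, lapply(g, function(e) c(e$from, e$to)))
    if (nrow(rng) > 1) {
      o <- order(rng[, 1]); rng <- rng[o, , drop = FALSE]
      if (any(rng[-1, 1] <= rng[-nrow(rng), 2]))
        stop("overlapping planted events")
    }
  }
  out <- list(); truth_bp <- list()
  for (qc in names(genes_per_chrom)) {
    n <- genes_per_chrom[[qc]]
    qidx <- seq_len(n)
    qpos <- (qidx - 1) * gene_spacing
    tchrom <- rep(paste0("t_", qc), n)
    tidx <- qidx
    strand <- rep(1, n)
    if (!is.null(fusion) && fusion$qchrom == qc) {
      k <- fusion$fusion_index
      stopifnot(k >= 1, k < n)
      tchrom[seq_len(k)] <- fusion$targetA
      tchrom[(k + 1):n] <- fusion$targetB
      tidx[(k + 1):n] <- seq_len(n - k)
      truth_bp$fusion <- list(qchrom = qc,
                              gap = c(qpos[k], qpos[k + 1]),
                              pos = (qpos[k] + qpos[k + 1]) / 2)
    }
    for (e in evs) {
      if (e$qchrom != qc) next
      r <- e$from:e$to
      if (e$kind == "inv") {
        tidx[r] <- rev(tidx[r])
        strand[r] <- -strand[r]
      } else {
        tidx[r] <- max(tidx) + seq_along(r)
      }
      truth_bp$events <- c(truth_bp$events, list(list(
        qchrom = qc, kind = e$kind,
        bp = c((qpos[e$from - 1] + qpos[e$from]) / 2,
               if (e$to < n) (qpos[e$to] + qpos[e$to + 1]) / 2))))
    }
    out[[qc]] <- data.frame(qchrom = qc, qidx = qidx, qpos = qpos,
                            tchrom = tchrom, tidx = tidx,
                            tpos = (tidx - 1) * gene_spacing,
                            strand = strand, stringsAsFactors = FALSE)
  }
  anchors <- validate_anchors(do.call(rbind, out))
  list(anchors = anchors, truth = truth_bp)
}

#' Synthetic expression counts with planted male-biased genes
#'
#' Counts are negative binomial with a common mean and dispersion; a planted
#' fraction of genes has the male-group mean multiplied by
#' `2^effect_log2fc`.
#'
#' @param n_genes number of genes.
#' @param group_sizes `c(F, M)` samples per group.
#' @param nb_mean,nb_dispersion NB mean and dispersion (`size` in
#'   [stats::rnbinom()] parametrization `size = 1/dispersion`).
#' @param biased_fraction fraction of genes planted male-biased.
#' @param effect_log2fc planted log2 fold change (`> 0` when
#'   `biased_fraction > 0`).
#' @param region_labels optional data.frame (`chrom`, `start`, `end`) per
#'   gene; default places genes consecutively on one chromosome.
#' @param seed integer seed.
#' @return list with `counts` (genes x samples matrix, columns `F1..M1..`),
#'   `groups` (factor), `gene_info`, and `truth$biased_genes`.
#' @export
gen_expression <- function(n_genes = 1000, group_sizes = c(4, 4),
                           nb_mean = 100, nb_dispersion = 0.1,
                           biased_fraction = 0, effect_log2fc = 1,
                           region_labels = NULL, seed = 1) {
  stopifnot(all(group_sizes >= 2))
  if (biased_fraction > 0) stopifnot(effect_log2fc > 0)
  seed_rng(seed)
  nF <- group_sizes[1]; nM <- group_sizes[2]
  biased <- sort(sample.int(n_genes, round(biased_fraction * n_genes)))
  muF <- rep(nb_mean, n_genes)
  muM <- muF
  muM[biased] <- muM[biased] * 2^effect_log2fc
  size <- 1 / nb_dispersion
  cf <- matrix(stats::rnbinom(n_genes * nF, mu = muF, size = size), n_genes)
  cmale <- matrix(stats::rnbinom(n_genes * nM, mu = muM, size = size), n_genes)
  counts <- cbind(cf, cmale)
  colnames(counts) <- c(paste0("F", seq_len(nF)), paste0("M", seq_len(nM)))
  rownames(counts) <- paste0("g", seq_len(n_genes))
  if (is.null(region_labels)) {
    region_labels <- data.frame(chrom = "chr1",
                                start = (seq_len(n_genes) - 1) * 1e4,
                                end = (seq_len(n_genes) - 1) * 1e4 + 5e3)
  }
  gene_info <- cbind(data.frame(gene_id = rownames(counts)), region_labels)
  list(counts = counts,
       groups = factor(rep(c("F", "M"), c(nF, nM)), levels = c("F", "M")),
       gene_info = gene_info,
       truth = list(biased_genes = rownames(counts)[biased],
                    effect_log2fc = effect_log2fc))
}

#' Synthetic repeat annotation with planted subfamily enrichment
#'
#' Repeats of each subfamily are placed as a Poisson process along every
#' chromosome at a base density; enriched (chrom, subfamily) pairs get
#' `fold` times that density.
#'
#' @param layout a [genome_layout].
#' @param subfamilies data.frame (`class`, `family`, `subfamily`) or
#'   character vector of subfamily names (class/family default to "DNA").
#' @param base_density repeats per bp per subfamily.
#' @param mean_len mean repeat length (bp, exponential).
#' @param enrichment NULL or data.frame (`chrom`, `subfamily`, `fold`).
#' @param seed integer seed.
#' @return list with `repeats` (see [read_repeat_table()]) and
#'   `truth$enrichment`.
#' @export
gen_repeat_table <- function(layout, subfamilies = paste0("sf", 1:8),
                             base_density = 2e-5, mean_len = 300,
                             enrichment = NULL, seed = 1) {
  if (!is.data.frame(subfamilies))
    subfamilies <- data.frame(class = "DNA", family = "DNA",
                              subfamily = subfamilies)
  if (!is.null(enrichment) && any(enrichment$fold <= 0))
    stop("enrichment fold must be > 0")
  seed_rng(seed)
  rows <- list()
  for (ch in layout$chroms) {
    len <- layout$lengths[[ch]]
    for (k in seq_len(nrow(subfamilies))) {
      sf <- subfamilies$subfamily[k]
      fold <- 1
      if (!is.null(enrichment)) {
        hit <- enrichment$chrom == ch & enrichment$subfamily == sf
        if (any(hit)) fold <- enrichment$fold[hit][1]
      }
      nrep <- stats::rpois(1, base_density * len * fold)
      if (nrep == 0) next
      start <- sort(stats::runif(nrep, 0, len - 1))
      w <- pmax(20, stats::rexp(nrep, 1 / mean_len))
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = floor(start),
        end = pmin(floor(start + w) + 1, len),
        class = subfamilies$class[k], family = subfamilies$family[k],
        subfamily = sf,
        divergence = round(stats::runif(nrep, 0, 30), 2),
        stringsAsFactors = FALSE)
    }
  }
  reps <- if (length(rows)) validate_repeats(do.call(rbind, rows)) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               class = character(0), family = character(0),
               subfamily = character(0), divergence = numeric(0))
  list(repeats = reps, truth = list(enrichment = enrichment))
}

# seed every source of randomness of a generator
seed_rng <- function(seed) set.seed(as.integer(seed))
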