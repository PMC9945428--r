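# Shared fixtures and independent oracles used across test files.

jaccard_iv <- function(a_start, a_end, b_start, b_end) {
  inter <- max(0, min(a_end, b_end) - max(a_start, b_start))
  union <- max(a_end, b_end) - min(a_start, b_start)
  inter / union
}

# brute-force window recomputation: literal per-window filtering
brute_window_scan <- function(sites, layout, window, step, mode) {
  wins <- tile_windows(layout, window, step)
  wins$value <- NA_real_; wins$n_sites <- 0L
  for (w in seq_len(nrow(wins))) {
    x <- sites$pos - 1
    inw <- sites$chrom == wins$chrom[w] & x >= wins$start[w] &
      x < wins$end[w]
    if (mode == "count") {
      wins$value[w] <- sum(inw); wins$n_sites[w] <- sum(inw)
    } else {
      inw <- inw & !is.na(sites$num) & !is.na(sites$den)
      wins$n_sites[w] <- sum(inw)
      sn <- sum(sites$num[inw]); sd_ <- sum(sites$den[inw])
      wins$value[w] <- if (sum(inw) && sd_ > 0) sn / sd_ else NA_real_
    }
  }
  wins
}

# brute-force minimal interval covering >= q of positions: all (i, j) pairs
brute_min_interval <- function(pos, q) {
  pos <- sort(pos) - 1
  n <- length(pos)
  m <- ceiling(q * n)
  best <- NULL
  for (i in seq_len(n)) for (j in i:n) {
    k <- j - i + 1
    if (k < m) next
    len <- pos[j] - pos[i] + 1
    if (is.null(best) || len < best$len ||
        (len == best$len && pos[i] < best$start))
      best <- list(start = pos[i], end = pos[j] + 1, len = len)
  }
  best
}

# independent Nei-Gojobori oracle: explicit, recursive pathway enumeration,
# written without reference to the package internals
ng_oracle <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  aa <- function(cod) unname(code[cod])
  codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- codons(toupper(a)); cb <- codons(toupper(b))
  keep <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[keep]; cb <- cb[keep]
  syn_sites <- function(cod) {
    s <- strsplit(cod, "")[[1]]
    cnt <- 0
    for (p in 1:3) for (nuc in setdiff(c("A", "C", "G", "T"), s[p])) {
      alt <- s; alt[p] <- nuc
      if (aa(paste(alt, collapse = "")) == aa(cod)) cnt <- cnt + 1
    }
    cnt / 3
  }
  # recursive enumeration of orderings; returns matrix of (sd, nd, blocked)
  walk <- function(cur, target) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(pos)) return(matrix(c(0, 0, 0), 1))
    out <- NULL
    for (p in pos) {
      nxt <- strsplit(cur, "")[[1]]
      nxt[p] <- strsplit(target, "")[[1]][p]
      nxt <- paste(nxt, collapse = "")
      step_syn <- as.numeric(aa(nxt) == aa(cur))
      hit_stop <- as.numeric(aa(nxt) == "*")
      rest <- walk(nxt, target)
      out <- rbind(out, cbind(rest[, 1] + step_syn,
                              rest[, 2] + (1 - step_syn),
                              pmax(rest[, 3], hit_stop)))
    }
    out
  }
  S <- (sum(vapply(ca, syn_sites, 0)) + sum(vapply(cb, syn_sites, 0))) / 2
  N <- 3 * length(ca) - S
  Sd <- Nd <- 0
  for (k in seq_along(ca)) {
    paths <- walk(ca[k], cb[k])
    ok <- paths[, 3] == 0
    if (!any(ok)) ok <- rep(TRUE, nrow(paths))
    Sd <- Sd + mean(paths[ok, 1])
    Nd <- Nd + mean(paths[ok, 2])
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(N = N, S = S, Nd = Nd, Sd = Sd, ka = jc(Nd / N), ks = jc(Sd / S))
}

# helix contact fixture: c_ij = 1 / ||x_i - x_j||
helix_contacts <- function(n = 100, turns = 3, rise = 1) {
  t <- seq(0, turns * 2 * pi, length.out = n)
  X <- cbind(cos(t), sin(t), rise * t / (2 * pi))
  D <- as.matrix(stats::dist(X))
  C <- 1 / D; diag(C) <- 0
  lay <- genome_layout("helix", n * 1e4, bin_size = 1e4)
  ij <- which(upper.tri(C), arr.ind = TRUE)
  list(cm = contact_matrix(lay, ij[, 1] - 1, ij[, 2] - 1, C[ij]),
       coords = X)
}

# standard small synthetic contact map with planted structure; compartment
# sign is constant within each planted TAD (switches co-located with
# boundaries, as in real maps)
planted_map <- function(n = 400, n_bnd = 8, tau = 2, delta = 0.3,
                        coverage = 50, seed = 1, bin = 5e4, ...) {
  lay <- genome_layout("chrT", n * bin, bin_size = bin)
  set.seed(seed + 1000)
  bnd <- sort(sample(seq(15, n - 15, by = 5), n_bnd))
  edges <- c(0, bnd, n)
  segs <- diff(edges)
  v <- rep(sample(c(1, -1), length(segs), replace = TRUE), segs)
  g <- gen_contact_map(lay, gamma = 1, tad_boundaries = bnd, tau = tau,
                       v = v, delta = delta, coverage = coverage,
                       seed = seed, ...)
  g$layout <- lay
  g
}
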