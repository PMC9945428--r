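#' 3D chromosome reconstruction from a contact matrix
#'
#' Distance-geometry reconstruction: balanced contacts are converted to
#' target distances `d_ij = c_ij^(-alpha)` (for `c_ij > 0`), the distance
#' matrix is completed by all-pairs shortest paths over the contact graph,
#' and classical multidimensional scaling (double-centering of `-D^2/2`,
#' top-3 eigenpairs) yields centered 3D coordinates.
#'
#' For matrices carrying counting noise (real or Poisson-sampled data), a
#' light Gaussian smoothing of the contact map before distance conversion
#' (`smooth_r = 2` recommended) suppresses the downward bias that noisy
#' edge weights impose on shortest-path distances; it is off by default so
#' that noiseless input is reconstructed exactly.
#'
#' @param cm a balanced [contact_matrix] (single chromosome, or pass
#'   `chrom`).
#' @param chrom chromosome to reconstruct (default: first).
#' @param alpha contact-to-distance exponent.
#' @param smooth_r half-width (bins) of the Gaussian pre-smoothing kernel
#'   (sd `smooth_r / 1.5`); 0 disables smoothing.
#' @return object of class `structure3d`: list with `coords` (n x 3 matrix,
#'   rows named by local bin index), `bins` (global bin ids used), `alpha`.
#' @export
reconstruct3d <- function(cm, chrom = cm$layout$chroms[1], alpha = 1,
                          smooth_r = 0) {
  gb <- chrom_bins(cm$layout, chrom)
  keep <- which(!cm$mask[gb + 1L])
  D <- chrom_dense(cm, chrom)[keep, keep, drop = FALSE]
  n <- nrow(D)
  if (n < 4) stop("need >= 4 unmasked bins")
  if (smooth_r > 0) {
    k <- stats::dnorm(-smooth_r:smooth_r, sd = smooth_r / 1.5)
    K <- outer(seq_len(n), seq_len(n), function(i, j)
      ifelse(abs(i - j) <= smooth_r, k[pmin(abs(i - j), smooth_r) + smooth_r + 1], 0))
    K <- K / rowSums(K)
    D <- K %*% D %*% t(K)
    D <- (D + t(D)) / 2          # exact symmetry after convolution
    diag(D) <- 0
  }
  W <- ifelse(D > 0, D^(-alpha), NA)
  g <- igraph::graph_from_adjacency_matrix(
    ifelse(is.na(W), 0, W), mode = "undirected", weighted = TRUE,
    diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1)
    stop("contact graph disconnected: ", comp$no, " components of sizes ",
         paste(comp$csize, collapse = ", "))
  SP <- igraph::distances(g, weights = igraph::E(g)$weight)
  B <- -0.5 * SP^2
  J <- diag(n) - 1 / n
  Bc <- J %*% B %*% J
  eg <- eigen((Bc + t(Bc)) / 2, symmetric = TRUE)
  ev <- pmax(eg$values[1:3], 0)
  X <- eg$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(ev), 3)
  X <- sweep(X, 2, colMeans(X))
  rownames(X) <- keep - 1
  structure(list(coords = X, bins = gb[keep], alpha = alpha,
                 chrom = chrom), class = "structure3d")
}

# scale coordinates to unit radius of gyration
normalize_rg <- function(X) {
  X <- sweep(X, 2, colMeans(X))
  rg <- sqrt(mean(rowSums(X^2)))
  if (rg == 0) stop("degenerate (single-point) structure")
  X / rg
}

#' Procrustes alignment and similarity of two 3D structures
#'
#' Both structures (restricted to their common bins) are normalized to unit
#' radius of gyration, then `b` is aligned onto `a` by the optimal
#' translation, uniform scale and rotation — reflections allowed — that
#' minimizes the summed squared coordinate distance. Reported are the RMSE
#' on the aligned normalized coordinates and the Spearman correlation of
#' the condensed pairwise-distance vectors (which needs no alignment).
#'
#' @param a,b `structure3d` objects (or bare n x 3 coordinate matrices on
#'   identical bin sets).
#' @return list: `rmse`, `rho`, `b_aligned` (aligned coordinates),
#'   `n_common` bins used.
#' @export
procrustes_align <- function(a, b) {
  Xa <- if (inherits(a, "structure3d")) a$coords else a
  Xb <- if (inherits(b, "structure3d")) b$coords else b
  if (inherits(a, "structure3d") && inherits(b, "structure3d")) {
    common <- intersect(a$bins, b$bins)
    Xa <- Xa[match(common, a$bins), , drop = FALSE]
    Xb <- Xb[match(common, b$bins), , drop = FALSE]
  }
  n <- nrow(Xa)
  if (n < 4 || nrow(Xb) != n) stop("need >= 4 common bins")
  Xa <- normalize_rg(Xa); Xb <- normalize_rg(Xb)
  M <- crossprod(Xa, Xb)            # 3x3
  sv <- svd(M)
  R <- sv$v %*% t(sv$u)             # rotation (reflection permitted)
  s <- sum(sv$d) / sum(Xb^2)
  Yb <- s * Xb %*% R
  rmse <- sqrt(mean(rowSums((Xa - Yb)^2)))
  # ranks on 10 significant digits: exactly-tied distances (symmetric
  # structures) must stay tied after a numerically perturbed rigid motion
  rho <- stats::cor(signif(stats::dist(Xa), 10), signif(stats::dist(Xb), 10),
                    method = "spearman")
  list(rmse = rmse, rho = rho, b_aligned = Yb, n_common = n)
}

#' Write 3D coordinates as TSV
#' @param s a `structure3d`.
#' @param path output path (columns `bin`, `x`, `y`, `z`).
#' @export
write_structure3d <- function(s, path) {
  df <- data.frame(bin = s$bins, x = s$coords[, 1], y = s$coords[, 2],
                   z = s$coords[, 3])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
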