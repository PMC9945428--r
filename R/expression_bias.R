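#' CPM and TPM normalization of a count matrix
#'
#' @param counts genes x samples matrix of nonnegative counts.
#' @param gene_lengths optional per-gene lengths (bp) for TPM.
#' @return list: `cpm` (`1e6 * count / column sum`) and, when lengths are
#'   given, `tpm` (`1e6 * rate / sum(rate)`, `rate = count / length`).
#' @export
normalize_counts <- function(counts, gene_lengths = NULL) {
  if (any(counts < 0)) stop("counts must be >= 0")
  libs <- colSums(counts)
  if (any(libs == 0)) stop("zero library size in column ",
                           which(libs == 0)[1])
  cpm <- sweep(counts, 2, libs, "/") * 1e6
  out <- list(cpm = cpm)
  if (!is.null(gene_lengths)) {
    stopifnot(length(gene_lengths) == nrow(counts), all(gene_lengths > 0))
    rate <- sweep(counts, 1, gene_lengths, "/")
    out$tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  }
  out
}

#' Threshold classification of sex-biased genes
#'
#' A gene is male-biased when `log2((mean_M + 1) / (mean_F + 1)) >= lfc_min`
#' and its male-group mean CPM is at least `expr_min`; female-biased
#' symmetrically; otherwise unbiased. Means are per-group means of CPM; the
#' pseudocount of 1 bounds fold changes for silent genes.
#'
#' @param cpm genes x samples CPM matrix ([normalize_counts()]).
#' @param groups factor/character of "F"/"M" per column.
#' @param lfc_min minimum |log2 fold change| (male/female).
#' @param expr_min minimum mean CPM in the favored group.
#' @param gene_info optional data.frame with `gene_id`, `chrom`, `start`,
#'   `end` merged into the result.
#' @return data.frame: `gene_id`, `mean_F`, `mean_M`, `log2fc`, `label`
#'   (male-biased / female-biased / unbiased), plus `gene_info` columns.
#' @export
classify_sex_bias <- function(cpm, groups, lfc_min = 1, expr_min = 1,
                              gene_info = NULL) {
  groups <- as.character(groups)
  stopifnot(all(groups %in% c("F", "M")),
            sum(groups == "F") >= 2, sum(groups == "M") >= 2)
  mF <- rowMeans(cpm[, groups == "F", drop = FALSE])
  mM <- rowMeans(cpm[, groups == "M", drop = FALSE])
  lfc <- log2((mM + 1) / (mF + 1))
  label <- ifelse(lfc >= lfc_min & mM >= expr_min, "male-biased",
                  ifelse(-lfc >= lfc_min & mF >= expr_min, "female-biased",
                         "unbiased"))
  out <- data.frame(gene_id = rownames(cpm) %||% seq_len(nrow(cpm)),
                    mean_F = mF, mean_M = mM, log2fc = lfc, label = label,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(gene_info))
    out <- merge(out, gene_info, by = "gene_id", sort = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks for ties; exact p-value by full enumeration of the
#' `choose(n + m, n)` group assignments when `n + m <= 12` and there are no
#' ties, otherwise the normal approximation with tie correction and
#' continuity correction. `U` counts pairs where an `x` exceeds a `y`
#' (+ 1/2 per tie).
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (x shifted up) or
#'   `"less"`.
#' @return list of class `rank_sum`: `U`, `n`, `m`, `p`, `method`
#'   ("exact" or "normal").
#' @export
rank_sum <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("empty sample")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (n + m <= 12 && !ties) {
    method <- "exact"
    combos <- utils::combn(n + m, n)
    us <- colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2
    p <- switch(alternative,
      greater = mean(us >= U),
      less = mean(us <= U),
      two.sided = min(1, 2 * min(mean(us >= U), mean(us <= U))))
  } else {
    method <- "normal"
    N <- n + m
    tie_tab <- table(r)
    mu <- n * m / 2
    sig2 <- n * m / 12 * (N + 1 - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    sig <- sqrt(sig2)
    z <- switch(alternative,
      greater = (U - mu - 0.5) / sig,
      less = (U - mu + 0.5) / sig,
      two.sided = (U - mu - sign(U - mu) * 0.5) / sig)
    p <- switch(alternative,
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z),
      two.sided = if (sig == 0) 1 else
        min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE)))
    if (sig == 0) p <- 1
  }
  structure(list(U = U, n = n, m = m, p = p, method = method,
                 alternative = alternative), class = "rank_sum")
}

#' @export
print.rank_sum <- function(x, ...) {
  cat(sprintf("rank-sum test (%s): U = %.1f (n = %d, m = %d), p = %.4g [%s]\n",
              x$alternative, x$U, x$n, x$m, x$p, x$method))
  invisible(x)
}

#' Regional enrichment of expression bias (rank-sum on log2FC)
#'
#' Compares the log2 fold changes of genes carrying the given bias label
#' inside a region against same-label genes elsewhere on the same
#' chromosome, one-sided by default (inside shifted up).
#'
#' @param biases output of [classify_sex_bias()] with `chrom`, `start`,
#'   `end` columns.
#' @param region list/vector `(chrom, start, end)` (0-based half-open).
#' @param label `"male-biased"` or `"female-biased"`.
#' @param alternative passed to [rank_sum()] (`"greater"`: inside > outside).
#' @return list: `test` ([rank_sum()] result), `n_inside`, `n_outside`,
#'   `median_inside`, `median_outside`.
#' @export
region_bias_test <- function(biases, region, label = "male-biased",
                             alternative = "greater") {
  region <- as.list(region); names(region) <- c("chrom", "start", "end")
  need <- c("chrom", "start", "end", "log2fc", "label")
  stopifnot(all(need %in% names(biases)))
  sel <- biases$label == label & biases$chrom == region$chrom
  g <- biases[sel, , drop = FALSE]
  inside <- g$start < as.numeric(region$end) &
    g$end > as.numeric(region$start)
  if (sum(inside) < 3 || sum(!inside) < 3)
    stop("insufficient ", label, " genes: ", sum(inside), " inside, ",
         sum(!inside), " outside")
  t <- rank_sum(g$log2fc[inside], g$log2fc[!inside],
                alternative = alternative)
  list(test = t, n_inside = sum(inside), n_outside = sum(!inside),
       median_inside = stats::median(g$log2fc[inside]),
       median_outside = stats::median(g$log2fc[!inside]))
}
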