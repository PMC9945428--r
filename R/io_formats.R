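#' Construct a pool-site table
#'
#' The per-variant data model for two-pool (pool-seq) designs: read counts of
#' the reference and alternate allele in pool 1 (XX females) and pool 2
#' (YY supermales), plus the haploid sample sizes of the pools.
#'
#' @param chrom,pos chromosome and 1-based position.
#' @param ref,alt allele strings.
#' @param ref1,alt1,ref2,alt2 read counts per allele and pool.
#' @param n1,n2 haploid pool sizes (2 x number of pooled individuals).
#' @return data.frame of class `pool_sites`, sorted by (chrom, pos), with an
#'   `is_indel` column derived from allele lengths.
#' @export
pool_sites <- function(chrom, pos, ref, alt, ref1, alt1, ref2, alt2,
                       n1 = 40, n2 = 40) {
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   ref1 = as.numeric(ref1), alt1 = as.numeric(alt1),
                   ref2 = as.numeric(ref2), alt2 = as.numeric(alt2),
                   n1 = as.numeric(n1), n2 = as.numeric(n2),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    cnt <- as.matrix(df[, c("ref1", "alt1", "ref2", "alt2")])
    if (any(cnt < 0) || anyNA(cnt)) stop("allele counts must be >= 0")
    if (any(df$pos < 1)) stop("positions are 1-based (>= 1)")
    df$is_indel <- nchar(df$ref) != nchar(df$alt)
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df$is_indel <- logical(0)
  }
  class(df) <- c("pool_sites", "data.frame")
  df
}

empty_pool_sites <- function() {
  pool_sites(character(0), numeric(0), character(0), character(0),
             numeric(0), numeric(0), numeric(0), numeric(0),
             numeric(0), numeric(0))
}

#' Read pooled-sequencing variants from VCF or TSV
#'
#' VCF input must carry per-sample `AD` (allele depth) for the two pool
#' samples named in `pool_labels`. Multiallelic records are split into
#' biallelic sites by default (`multiallelic = "split"`) or dropped
#' (`"skip"`). TSV input has columns
#' `chrom pos ref alt ref1 alt1 ref2 alt2 n1 n2`.
#'
#' @param path VCF (`.vcf`) or TSV file.
#' @param pool_labels for VCF: character(2), sample names of pool 1 (XX) and
#'   pool 2 (YY).
#' @param n1,n2 haploid pool sizes attached to each site (VCF input; TSV
#'   carries its own).
#' @param multiallelic `"split"` or `"skip"`.
#' @return a [pool_sites] table, positions 1-based as in the VCF.
#' @export
read_pool_variants <- function(path, pool_labels = NULL, n1 = 40, n2 = 40,
                               multiallelic = c("split", "skip")) {
  multiallelic <- match.arg(multiallelic)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_pool_vcf(path, pool_labels, n1, n2, multiallelic)
  } else {
    read_pool_tsv(path)
  }
}

read_pool_vcf <- function(path, pool_labels, n1, n2, multiallelic) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) return(empty_pool_sites())
  fmt <- vcf@gt
  if (is.null(fmt) || !"FORMAT" %in% colnames(fmt)[1])
    stop("VCF has no genotype columns")
  samples <- colnames(fmt)[-1]
  if (is.null(pool_labels)) {
    if (length(samples) != 2)
      stop("pool_labels required when the VCF has != 2 samples")
    pool_labels <- samples
  }
  if (!all(pool_labels %in% samples))
    stop("unknown pool label(s): ",
         paste(setdiff(pool_labels, samples), collapse = ", "))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || all(is.na(ad)))
    stop("VCF records lack the per-sample AD field")
  out <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1 && multiallelic == "skip") next
    ad1 <- as.numeric(strsplit(ad[i, pool_labels[1]], ",", fixed = TRUE)[[1]])
    ad2 <- as.numeric(strsplit(ad[i, pool_labels[2]], ",", fixed = TRUE)[[1]])
    if (anyNA(ad1) || anyNA(ad2)) stop("missing AD at record ", i)
    for (k in seq_along(alts)) {
      out[[length(out) + 1]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.numeric(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k],
        ref1 = ad1[1], alt1 = ad1[k + 1], ref2 = ad2[1], alt2 = ad2[k + 1],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_pool_sites())
  df <- do.call(rbind, out)
  pool_sites(df$chrom, df$pos, df$ref, df$alt, df$ref1, df$alt1,
             df$ref2, df$alt2, n1, n2)
}

read_pool_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "ref1", "alt1", "ref2", "alt2",
            "n1", "n2")
  if (!all(need %in% names(df)))
    stop("pool TSV must have columns: ", paste(need, collapse = " "))
  if (nrow(df) == 0) return(empty_pool_sites())
  pool_sites(df$chrom, df$pos, df$ref, df$alt, df$ref1, df$alt1,
             df$ref2, df$alt2, df$n1, df$n2)
}

#' Write pool sites to TSV or a minimal VCF
#'
#' The VCF writer emits one biallelic record per site with an `AD` FORMAT
#' field for the two pool samples, so the file round-trips through
#' [read_pool_variants()].
#'
#' @param sites a [pool_sites] table.
#' @param path output file; `.vcf` selects VCF, anything else TSV.
#' @param pool_labels sample names used in the VCF header.
#' @return `path`, invisibly.
#' @export
write_pool_variants <- function(sites, path, pool_labels = c("XX", "YY")) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
             paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                    pool_labels[1], "\t", pool_labels[2]))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD\t%d,%d\t%d,%d",
                    sites$chrom, as.integer(sites$pos), sites$ref, sites$alt,
                    as.integer(sites$ref1), as.integer(sites$alt1),
                    as.integer(sites$ref2), as.integer(sites$alt2))
    writeLines(c(hdr, body), path)
  } else {
    utils::write.table(
      sites[, c("chrom", "pos", "ref", "alt", "ref1", "alt1", "ref2", "alt2",
                "n1", "n2")],
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Contact matrices

#' Construct a binned Hi-C contact matrix
#'
#' Entries are symmetrized (where both `(i, j)` and `(j, i)` are supplied the
#' maximum is kept). Bins with no nonzero entries, or with a nonzero-entry
#' count below `mask_frac` times the median nonzero-entry count of their
#' chromosome, are masked and excluded from every downstream statistic.
#'
#' @param layout a [genome_layout] with `bin_size` set.
#' @param i,j 0-based global bin indices.
#' @param x counts (`>= 0`).
#' @param bias optional per-bin balancing weights (see [ice_balance()]).
#' @param mask_frac low-coverage mask threshold.
#' @return object of class `contact_matrix`: list with `layout`, `mat`
#'   (symmetric `Matrix::sparseMatrix` of raw counts), `bias`, `mask`
#'   (logical, `TRUE` = excluded).
#' @export
contact_matrix <- function(layout, i, j, x, bias = NULL, mask_frac = 0.1) {
  n <- n_bins(layout)
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) && (min(c(i, j)) < 0 || max(c(i, j)) >= n))
    stop("bin index out of range [0, ", n - 1, "]")
  if (any(x < 0)) stop("contact counts must be >= 0")
  # symmetrize to upper triangle, max where duplicated
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    x <- tapply(x, key, max)
    pq <- do.call(rbind, strsplit(names(x), " ", fixed = TRUE))
    lo <- as.integer(pq[, 1]); hi <- as.integer(pq[, 2])
    x <- as.numeric(x)
  }
  mat <- Matrix::sparseMatrix(i = lo + 1L, j = hi + 1L, x = x, dims = c(n, n),
                              symmetric = TRUE)
  cm <- structure(list(layout = layout, mat = mat, bias = bias,
                       mask = logical(n)), class = "contact_matrix")
  cm$mask <- compute_mask(cm, mask_frac)
  cm
}

compute_mask <- function(cm, mask_frac = 0.1) {
  n <- n_bins(cm$layout)
  nz <- Matrix::rowSums(cm$mat != 0)
  mask <- nz == 0
  for (ch in cm$layout$chroms) {
    b <- chrom_bins(cm$layout, ch) + 1L
    med <- stats::median(nz[b][nz[b] > 0])
    if (is.na(med)) { mask[b] <- TRUE; next }
    mask[b] <- mask[b] | nz[b] < mask_frac * med
  }
  mask
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", n_bins(x$layout), "bins,",
      length(x$mat@x), "stored entries,", sum(x$mask), "masked bins,",
      if (is.null(x$bias)) "raw\n" else "balanced\n")
  invisible(x)
}

#' Balanced (bias-corrected) dense or sparse matrix of a contact_matrix
#' @param cm a `contact_matrix`.
#' @return sparse symmetric matrix of `raw / (bias_i * bias_j)`; raw counts
#'   when no bias is attached. Masked bins are zeroed.
#' @export
balanced_matrix <- function(cm) {
  m <- as(cm$mat, "generalMatrix")
  if (!is.null(cm$bias)) {
    b <- cm$bias
    m@x <- m@x / (b[m@i + 1L] * b[rep(seq_along(m@p[-1]), diff(m@p))])
  }
  if (any(cm$mask)) {
    idx <- which(cm$mask)
    keep <- !((m@i + 1L) %in% idx |
                rep(seq_along(m@p[-1]), diff(m@p)) %in% idx)
    m <- Matrix::sparseMatrix(i = m@i[keep] + 1L,
                              j = rep(seq_along(m@p[-1]), diff(m@p))[keep],
                              x = m@x[keep], dims = dim(m))
  }
  m
}

# dense balanced submatrix for one chromosome (1-based local indexing)
chrom_dense <- function(cm, chrom) {
  b <- chrom_bins(cm$layout, chrom) + 1L
  as.matrix(balanced_matrix(cm)[b, b, drop = FALSE])
}

#' Read a contact matrix from Matrix Market / COO plus a bin table
#'
#' @param matrix_path Matrix Market coordinate file (`.mtx`) or 3-column COO
#'   TSV `i j count` with 0-based bin indices.
#' @param bins_path 4-column TSV/BED-like bin table
#'   `chrom start end bin_id` defining the layout (uniform bin size).
#' @param mask_frac see [contact_matrix()].
#' @return a `contact_matrix`.
#' @export
read_contact_matrix <- function(matrix_path, bins_path, mask_frac = 0.1) {
  bins <- utils::read.table(bins_path, header = FALSE, sep = "\t",
                            col.names = c("chrom", "start", "end", "bin_id"),
                            stringsAsFactors = FALSE)
  bins <- bins[order(bins$bin_id), ]
  bs <- max(bins$end - bins$start)
  lens <- tapply(bins$end, bins$chrom, max)
  layout <- genome_layout(unique(bins$chrom),
                          as.numeric(lens[unique(bins$chrom)]), bin_size = bs)
  if (nrow(layout$bins) != nrow(bins))
    stop("bin table does not tile its chromosomes at a uniform bin size")
  if (grepl("\\.mtx$", matrix_path)) {
    m <- Matrix::readMM(matrix_path)
    if (nrow(m) != ncol(m)) stop("contact matrix must be square")
    tm <- as(as(m, "generalMatrix"), "TsparseMatrix")
    ii <- tm@i; jj <- tm@j; xx <- tm@x
  } else {
    coo <- utils::read.table(matrix_path, header = FALSE, sep = "\t",
                             col.names = c("i", "j", "count"))
    ii <- coo$i; jj <- coo$j; xx <- coo$count
  }
  contact_matrix(layout, ii, jj, xx, mask_frac = mask_frac)
}

#' Write a contact matrix (Matrix Market + bin table)
#' @param cm a `contact_matrix` (raw counts are written).
#' @param matrix_path output `.mtx` path.
#' @param bins_path output bin-table TSV path.
#' @return `matrix_path`, invisibly.
#' @export
write_contact_matrix <- function(cm, matrix_path, bins_path) {
  Matrix::writeMM(as(cm$mat, "generalMatrix"), matrix_path)
  b <- cm$layout$bins
  utils::write.table(b[, c("chrom", "start", "end", "bin_id")], bins_path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(matrix_path)
}

# ---------------------------------------------------------------------------
# Gene models (GFF3)

#' Read gene models from GFF3
#'
#' Parses `gene`/`mRNA`/`exon` features; for genes with several mRNAs the
#' longest is kept. GFF3 1-based inclusive coordinates are converted to the
#' package-wide 0-based half-open convention; the TSS is the start for `+`
#' genes and `end - 1` for `-` genes. Exons without a resolvable parent are
#' skipped with a warning.
#'
#' @param path GFF3 file.
#' @return object of class `gene_models`: list with `genes` (data.frame:
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, `tss`) and `exons`
#'   (data.frame: `gene_id`, `start`, `end`, sorted within gene).
#' @export
read_gff3 <- function(path) {
  tab <- rtracklayer::readGFF(path, columns = c("seqid", "type", "start",
                                                "end", "strand"),
                              tags = c("ID", "Parent"))
  if (!nrow(tab))
    return(structure(list(genes = data.frame(), exons = data.frame()),
                     class = "gene_models"))
  typ <- as.character(tab$type)
  id <- as.character(tab$ID)
  parent <- vapply(tab$Parent, function(p)
    if (length(p)) p[1] else NA_character_, "")
  start1 <- as.numeric(tab$start); end1 <- as.numeric(tab$end)
  gi <- which(typ == "gene")
  mi <- which(typ == "mRNA")
  ei <- which(typ == "exon")
  # mRNA -> gene map; exon -> mRNA -> gene
  m2g <- stats::setNames(parent[mi], id[mi])
  g_of_exon <- m2g[parent[ei]]
  # exons may hang directly off a gene
  direct <- parent[ei] %in% id[gi]
  g_of_exon[direct] <- parent[ei][direct]
  orphan <- is.na(g_of_exon)
  if (any(orphan)) {
    warning(sum(orphan), " exon(s) without a resolvable parent skipped")
    ei <- ei[!orphan]; g_of_exon <- g_of_exon[!orphan]
  }
  # longest mRNA per gene; exons restricted to it when mRNA ids are present
  if (length(mi)) {
    mlen <- end1[mi] - start1[mi] + 1
    keep_m <- vapply(split(seq_along(mi), m2g), function(k) {
      id[mi][k[which.max(mlen[k])]]
    }, "")
    via_m <- parent[ei] %in% id[mi]
    drop <- via_m & !(parent[ei] %in% keep_m)
    ei <- ei[!drop]; g_of_exon <- g_of_exon[!drop]
  }
  genes <- data.frame(
    gene_id = id[gi], chrom = as.character(tab$seqid)[gi],
    strand = as.character(tab$strand)[gi],
    start = start1[gi] - 1, end = end1[gi],
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  exons <- data.frame(gene_id = unname(g_of_exon),
                      start = start1[ei] - 1, end = end1[ei],
                      stringsAsFactors = FALSE)
  exons <- exons[order(exons$gene_id, exons$start), ]
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

# ---------------------------------------------------------------------------
# Repeat tables, anchors, BED/bedGraph

#' Read a RepeatMasker-style repeat table
#'
#' TSV columns: `chrom start end class family subfamily divergence`
#' (0-based half-open, divergence in percent from consensus).
#'
#' @param path TSV file (header optional, detected).
#' @return validated data.frame sorted by (chrom, start).
#' @export
read_repeat_table <- function(path) {
  cols <- c("chrom", "start", "end", "class", "family", "subfamily",
            "divergence")
  first <- readLines(path, n = 1)
  has_header <- length(first) && grepl("^chrom\t", first)
  df <- if (has_header)
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else
    utils::read.table(path, header = FALSE, sep = "\t", col.names = cols,
                      stringsAsFactors = FALSE)
  names(df) <- cols
  if (nrow(df) == 0) return(df)
  validate_repeats(df)
}

validate_repeats <- function(df) {
  bad <- which(df$end <= df$start)
  if (length(bad)) stop("repeat row ", bad[1], ": end <= start")
  bad <- which(df$divergence < 0 | df$divergence > 100)
  if (length(bad)) stop("repeat row ", bad[1], ": divergence outside [0,100]")
  df <- df[order(df$chrom, df$start), ]
  rownames(df) <- NULL
  df
}

#' Write a repeat table
#' @param df repeat table as returned by [read_repeat_table()].
#' @param path output TSV.
#' @export
write_repeat_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a homologous-gene anchor table
#'
#' TSV columns `qchrom qidx qpos tchrom tidx tpos strand`: gene rank (`qidx`,
#' unique within its query chromosome) and bp position on query and target,
#' with strand +1/-1.
#'
#' @param path TSV file.
#' @return data.frame sorted by (qchrom, qidx).
#' @export
read_anchors <- function(path) {
  cols <- c("qchrom", "qidx", "qpos", "tchrom", "tidx", "tpos", "strand")
  first <- readLines(path, n = 1)
  has_header <- length(first) && grepl("^qchrom\t", first)
  df <- if (has_header)
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else
    utils::read.table(path, header = FALSE, sep = "\t", col.names = cols,
                      stringsAsFactors = FALSE)
  names(df) <- cols
  validate_anchors(df)
}

validate_anchors <- function(df) {
  if (nrow(df) == 0) return(df)
  if (!all(df$strand %in% c(-1, 1))) stop("anchor strand must be +1/-1")
  dup <- unlist(lapply(split(df$qidx, df$qchrom), duplicated))
  if (any(dup)) stop("duplicate qidx within a query chromosome")
  df <- df[order(df$qchrom, df$qidx), ]
  rownames(df) <- NULL
  df
}

#' @rdname read_anchors
#' @param df anchor table.
#' @export
write_anchors <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write BED (0-based half-open) and bedGraph tracks
#' @param df data.frame whose first three columns are chrom, start, end; for
#'   bedGraph a `value` column is required.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
write_bedgraph <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  keep <- !is.na(df$value)
  utils::write.table(df[keep, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
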