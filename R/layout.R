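#' Genome layout: chromosome names, lengths and an optional bin size
#'
#' A `genome_layout` holds the ordered chromosome table shared by every
#' analysis stage. All internal coordinates in this package are 0-based,
#' half-open; bin `i` of a chromosome covers `[i * bin_size, (i + 1) * bin_size)`.
#'
#' @param chroms character vector of chromosome names (order is kept).
#' @param lengths numeric vector of chromosome lengths in bp (`> 0`).
#' @param bin_size optional bin size in bp for binned data (e.g. Hi-C).
#'
#' @return An object of class `genome_layout`: a list with `chroms`,
#'   `lengths` (named), `bin_size`, and — when `bin_size` is set — a bin
#'   table `bins` (data.frame: `chrom`, `start`, `end`, `bin_id` with global
#'   0-based `bin_id`).
#' @export
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5), bin_size = 1e5)
genome_layout <- function(chroms, lengths, bin_size = NULL) {
  stopifnot(length(chroms) == length(lengths), !anyDuplicated(chroms))
  if (any(lengths <= 0)) stop("chromosome lengths must be > 0")
  lengths <- stats::setNames(as.numeric(lengths), chroms)
  obj <- structure(list(chroms = as.character(chroms), lengths = lengths,
                        bin_size = bin_size), class = "genome_layout")
  if (!is.null(bin_size)) {
    stopifnot(bin_size > 0)
    obj$bins <- layout_bin_table(obj)
  }
  obj
}

layout_bin_table <- function(layout) {
  bs <- layout$bin_size
  pieces <- lapply(layout$chroms, function(ch) {
    len <- layout$lengths[[ch]]
    n <- ceiling(len / bs)
    start <- (seq_len(n) - 1) * bs
    data.frame(chrom = ch, start = start, end = pmin(start + bs, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$bin_id <- seq_len(nrow(out)) - 1L
  out
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chroms), "chromosomes,",
      format(sum(x$lengths), big.mark = ","), "bp total")
  if (!is.null(x$bin_size))
    cat(";", nrow(x$bins), "bins of", x$bin_size, "bp")
  cat("\n")
  invisible(x)
}

#' Number of bins of a layout (total or per chromosome)
#' @param layout a `genome_layout` with `bin_size` set.
#' @param chrom optional chromosome name.
#' @return integer bin count.
#' @export
n_bins <- function(layout, chrom = NULL) {
  stopifnot(!is.null(layout$bins))
  if (is.null(chrom)) return(nrow(layout$bins))
  sum(layout$bins$chrom == chrom)
}

#' Global bin ids of a chromosome
#' @inheritParams n_bins
#' @return integer vector of 0-based global bin ids.
#' @export
chrom_bins <- function(layout, chrom) {
  stopifnot(!is.null(layout$bins))
  layout$bins$bin_id[layout$bins$chrom == chrom]
}

# map (chrom, 0-based bp) -> global 0-based bin id
pos_to_bin <- function(layout, chrom, pos) {
  stopifnot(!is.null(layout$bin_size))
  off <- cumsum(c(0, ceiling(layout$lengths / layout$bin_size)))
  i <- match(chrom, layout$chroms)
  if (anyNA(i)) stop("unknown chromosome: ", paste(unique(chrom[is.na(i)]), collapse = ", "))
  as.integer(off[i] + floor(pos / layout$bin_size))
}

#' Sliding windows tiling each chromosome
#'
#' Windows start at 0 and advance by `step`; the last window is truncated at
#' the chromosome end. Coordinates are 0-based half-open.
#'
#' @param layout a `genome_layout`.
#' @param window window size in bp.
#' @param step step in bp (`<= window`).
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
tile_windows <- function(layout, window, step = window) {
  stopifnot(window >= step, step > 0)
  pieces <- lapply(layout$chroms, function(ch) {
    len <- layout$lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    data.frame(chrom = ch, start = starts, end = pmin(starts + window, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}
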