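#' Define a reference genome frame
#'
#' A genome definition holds the ordered chromosome names and lengths that
#' every coordinate in the pipeline is validated against, plus an optional set
#' of excluded regions (typically centromeres and telomeres) that are removed
#' before footprint classification and hotspot scanning.
#'
#' @param chroms Character vector of unique chromosome names, in order.
#' @param lengths Integer vector of chromosome lengths in bp (all > 0),
#'   parallel to `chroms`.
#' @param excluded Optional data.frame with columns `chrom`, `start`, `end`
#'   (1-based, closed) of regions to exclude; each region must lie within its
#'   chromosome.
#' @return An object of class `genome_def`: a list with elements `chroms`,
#'   `lengths` (named), and `excluded`.
#' @examples
#' gd <- genome_def(c("chr1", "chr2"), c(3e6, 2e6))
#' @export
genome_def <- function(chroms, lengths, excluded = NULL) {
  chroms <- as.character(chroms)
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (length(lengths) != length(chroms)) {
    stop("'chroms' and 'lengths' must have equal length")
  }
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("chromosome lengths must be positive")
  }
  names(lengths) <- chroms
  if (!is.null(excluded)) {
    excluded <- as.data.frame(excluded)
    stopifnot(all(c("chrom", "start", "end") %in% names(excluded)))
    excluded$chrom <- as.character(excluded$chrom)
    bad <- !(excluded$chrom %in% chroms)
    if (any(bad)) stop("excluded region on unknown chromosome: ",
                       paste(unique(excluded$chrom[bad]), collapse = ", "))
    if (any(excluded$start < 1) ||
        any(excluded$end > lengths[excluded$chrom]) ||
        any(excluded$start > excluded$end)) {
      stop("excluded regions must lie within their chromosome")
    }
  } else {
    excluded <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(chroms = chroms, lengths = lengths, excluded = excluded),
            class = "genome_def")
}

#' @export
print.genome_def <- function(x, ...) {
  cat(sprintf("genome_def: %d chromosomes, %.1f Mb total, %d excluded regions\n",
              length(x$chroms), sum(x$lengths) / 1e6, nrow(x$excluded)))
  invisible(x)
}

#' Total genome length in bp
#' @param genome A [genome_def()].
#' @return Numeric scalar, sum of chromosome lengths.
#' @export
genome_length <- function(genome) {
  stopifnot(inherits(genome, "genome_def"))
  sum(genome$lengths)
}

#' Tile a genome into (possibly overlapping) bins
#'
#' Divides each chromosome into bins of `width` bp advancing by `step` bp
#' (the default 1 Mb / 500 kb gives 50%-overlapping bins). Full-width bins are
#' placed at every multiple of `step` with `start + width <= L`; when those do
#' not reach the chromosome end one truncated tail bin is added at the next
#' step multiple, so every base is covered at least once. Bins overlapping a
#' genome excluded region are flagged.
#'
#' @param genome A [genome_def()].
#' @param width Bin width in bp.
#' @param step Distance between successive bin starts in bp; must satisfy
#'   `0 < step <= width`.
#' @return data.frame with columns `bin` (globally unique index), `chrom`,
#'   `start`, `end` (0-based, half-open) and `excluded` (logical).
#' @examples
#' bins <- make_bins(genome_def("chr1", 3e6))
#' @export
make_bins <- function(genome, width = 1e6, step = 5e5) {
  stopifnot(inherits(genome, "genome_def"))
  if (!(step > 0 && width >= step)) stop("require width >= step > 0")
  out <- lapply(genome$chroms, function(ch) {
    L <- genome$lengths[[ch]]
    starts <- seq(0, L, by = step)
    starts <- starts[starts + width <= L]
    if (length(starts) == 0 || max(starts) + width < L) {
      tail_start <- if (length(starts) == 0) 0 else max(starts) + step
      if (tail_start < L) starts <- c(starts, tail_start)
    }
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + width, L), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- data.frame(bin = seq_len(nrow(out)), out, stringsAsFactors = FALSE)
  out$excluded <- rep(FALSE, nrow(out))
  if (nrow(genome$excluded) > 0) {
    bg <- GenomicRanges::GRanges(out$chrom,
                                 IRanges::IRanges(out$start + 1, out$end))
    eg <- GenomicRanges::GRanges(genome$excluded$chrom,
                                 IRanges::IRanges(genome$excluded$start,
                                                  genome$excluded$end))
    out$excluded <- IRanges::overlapsAny(bg, eg)
  }
  out
}

#' Drop calls with a breakend inside an excluded region
#'
#' Removes SV calls having either breakend within any of the genome's
#' excluded (centromere/telomere) regions; applied before footprint
#' classification.
#'
#' @param calls An SV call data.frame (see [sv_calls()]).
#' @param genome A [genome_def()] carrying excluded regions.
#' @return The filtered call data.frame.
#' @export
drop_excluded_calls <- function(calls, genome) {
  stopifnot(inherits(genome, "genome_def"))
  if (nrow(genome$excluded) == 0 || nrow(calls) == 0) return(calls)
  eg <- GenomicRanges::GRanges(genome$excluded$chrom,
                               IRanges::IRanges(genome$excluded$start,
                                                genome$excluded$end))
  g1 <- GenomicRanges::GRanges(calls$chrom1, IRanges::IRanges(calls$pos1, calls$pos1))
  g2 <- GenomicRanges::GRanges(calls$chrom2, IRanges::IRanges(calls$pos2, calls$pos2))
  keep <- !(IRanges::overlapsAny(g1, eg) | IRanges::overlapsAny(g2, eg))
  calls[keep, , drop = FALSE]
}
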