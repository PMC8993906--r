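#' Per-bin breakpoint statistics
#'
#' Counts breakpoints (every breakend of every non-blacklisted SV) per bin
#' and patient, and derives breakpoint *recurrence* (number of patients with
#' at least one breakpoint in the bin) and *density* (mean breakpoints per
#' patient). Overlapping bins each count a breakend that falls in them. Bins
#' overlapping supplied fragile-site regions are flagged.
#'
#' @param cohort An [sv_cohort()].
#' @param bins Bin table from [make_bins()].
#' @param covariates Optional covariate data.frame (`bin` + covariate
#'   columns) merged onto the result.
#' @param fragile_regions Optional data.frame `chrom`, `start`, `end`
#'   (1-based closed) of fragile sites.
#' @param use_blacklisted Include panel-blacklisted calls (default FALSE).
#' @return Object of class `bin_table`: the bin data.frame with `total`,
#'   `recurrence`, `density`, `fragile`, covariate columns, and the
#'   bin-by-patient count matrix in attribute `"counts"`.
#' @export
bin_breakpoint_stats <- function(cohort, bins, covariates = NULL,
                                 fragile_regions = NULL,
                                 use_blacklisted = FALSE) {
  calls <- cohort$calls
  if (!use_blacklisted) calls <- calls[!calls$blacklisted, , drop = FALSE]
  npat <- length(cohort$patients)
  counts <- matrix(0L, nrow = nrow(bins), ncol = npat,
                   dimnames = list(bins$bin, cohort$patients))
  if (nrow(calls) > 0) {
    bk_chrom <- c(calls$chrom1, calls$chrom2)
    bk_pos <- c(calls$pos1, calls$pos2)
    bk_pat <- rep(calls$patient, 2)
    bg <- GenomicRanges::GRanges(bins$chrom,
                                 IRanges::IRanges(bins$start + 1, bins$end))
    kg <- GenomicRanges::GRanges(bk_chrom, IRanges::IRanges(bk_pos, bk_pos))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(kg, bg))
    if (length(ov) > 0) {
      bin_i <- S4Vectors::subjectHits(ov)
      pat_i <- match(bk_pat[S4Vectors::queryHits(ov)], cohort$patients)
      counts[] <- tabulate(bin_i + (pat_i - 1L) * nrow(bins),
                           nbins = nrow(bins) * npat)
    }
  }
  out <- bins
  out$total <- as.integer(rowSums(counts))
  out$recurrence <- as.integer(rowSums(counts > 0))
  out$density <- out$total / npat
  out$fragile <- 0
  if (!is.null(fragile_regions) && nrow(fragile_regions) > 0) {
    bg <- GenomicRanges::GRanges(bins$chrom,
                                 IRanges::IRanges(bins$start + 1, bins$end))
    fg <- GenomicRanges::GRanges(fragile_regions$chrom,
                                 IRanges::IRanges(fragile_regions$start,
                                                  fragile_regions$end))
    out$fragile <- as.numeric(suppressWarnings(IRanges::overlapsAny(bg, fg)))
  }
  if (!is.null(covariates)) {
    out <- merge(out, covariates, by = "bin", sort = FALSE)
    out <- out[order(out$bin), , drop = FALSE]
    # the fragile-site covariate flag and the region flag are one signal
    if ("fragile.y" %in% names(out)) {
      combined <- as.numeric(out$fragile.x == 1 | out$fragile.y == 1)
      out$fragile.x <- NULL
      out$fragile.y <- NULL
      out$fragile <- combined
    }
  }
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  class(out) <- c("bin_table", "data.frame")
  out
}

std_pearson_resid <- function(fit) {
  r <- stats::residuals(fit, type = "pearson")
  s <- stats::sd(r)
  if (!is.finite(s) || s == 0) return(rep(0, length(r)))
  (r - mean(r)) / s
}

#' Negative-binomial genomic-context background model
#'
#' Models per-bin breakpoint recurrence (or total counts) as a
#' negative-binomial log-linear regression on the eight genomic covariates
#' (fragile site, copy-number aberration, GC, replication timing, H3K36me3,
#' H3K27ac, DNase, ALU density). Bins whose standardised Pearson residual is
#' at least `resid_threshold` SD above the residual mean are flagged as
#' recurrently altered beyond the modelled background. Falls back to a
#' Poisson GLM (recorded in `family`) if the NB fit fails to converge.
#'
#' @param bintable A `bin_table` from [bin_breakpoint_stats()] carrying
#'   covariate columns.
#' @param response `"recurrence"` (default) or `"count"`.
#' @param covariates Covariate column names (default [covariate_names()];
#'   only those present are used).
#' @param resid_threshold Flagging threshold in residual SD (default 2).
#' @return Object of class `nb_fit`: list with `coefficients`, `se`,
#'   `theta`, `fitted`, `residuals` (standardised), `significant` (logical
#'   per bin), `family`, `response`, and the fitted `model`.
#' @export
fit_context_model <- function(bintable, response = c("recurrence", "count"),
                              covariates = covariate_names(),
                              resid_threshold = 2) {
  response <- match.arg(response)
  if (nrow(bintable) < 50) stop("need at least 50 bins")
  covariates <- intersect(covariates, names(bintable))
  if (length(covariates) == 0) stop("no covariate columns in bintable")
  y <- if (response == "recurrence") bintable$recurrence else bintable$total
  dat <- data.frame(y = y, bintable[, covariates, drop = FALSE])
  fit <- NULL
  family <- "negative binomial"
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ ., data = dat)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    family <- "poisson"
    fit <- stats::glm(y ~ ., data = dat, family = stats::poisson())
  }
  r <- std_pearson_resid(fit)
  co <- summary(fit)$coefficients
  structure(list(coefficients = stats::coef(fit), se = co[, 2],
                 theta = if (family == "negative binomial") fit$theta else Inf,
                 fitted = stats::fitted(fit), residuals = r,
                 significant = r >= resid_threshold,
                 family = family, response = response, model = fit),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("nb_fit (%s, response = %s): theta = %.3g, %d/%d bins flagged\n",
              x$family, x$response, x$theta, sum(x$significant),
              length(x$significant)))
  invisible(x)
}

#' Rank-sum / k-means focal significance
#'
#' Ranks bins within each patient by breakpoint count (average ranks for
#' ties), sums the ranks per bin across patients, and splits the rank sums
#' into two clusters by exact 1-D 2-means (all split points of the sorted
#' sums are enumerated; the minimum within-cluster sum of squares wins, so
#' the result is deterministic and globally optimal). Bins in the
#' higher-mean cluster are flagged. Degenerate guards: identical rank sums
#' flag nothing, and a "high" cluster holding more than `max_flag_frac` of
#' the bins flags nothing (no focal structure).
#'
#' @param counts Bin-by-patient count matrix.
#' @param max_flag_frac Largest admissible flagged fraction (default 0.2).
#' @return Logical vector, one flag per bin.
#' @export
ranksum_kmeans <- function(counts, max_flag_frac = 0.2) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need at least 2 bins")
  ranks <- apply(counts, 2, rank)
  rs <- rowSums(as.matrix(ranks))
  if (max(rs) - min(rs) < 1e-12) return(rep(FALSE, nrow(counts)))
  ord <- order(rs)
  x <- rs[ord]
  n <- length(x)
  css <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  wss <- vapply(seq_len(n - 1), function(i)
    css(x[seq_len(i)]) + css(x[(i + 1):n]), numeric(1))
  split <- which.min(wss)
  flag <- logical(n)
  flag[(split + 1):n] <- TRUE
  out <- logical(n)
  out[ord] <- flag
  # degenerate-split guard: a "high" cluster that is a sizeable share of all
  # bins is not focal structure (at least one flag is always admissible)
  if (sum(out) > max(1, max_flag_frac * n)) return(rep(FALSE, n))
  out
}

#' Three-method focal hotspot consensus
#'
#' After removing fragile-site bins and (optionally) high-density bins --
#' both reflect breakage-prone regions rather than selection -- three
#' methods scan the retained bins: (1) an intercept-only negative-binomial
#' model of per-bin counts genome-wide with standardised-residual outliers
#' flagged at `resid_threshold` SD, (2) the same model fit per chromosome to
#' absorb chromosomal context (chromosomes with fewer than `min_chrom_bins`
#' retained bins are skipped and reported), and (3) the rank-sum/k-means
#' method [ranksum_kmeans()]. Bins flagged by at least two methods form the
#' focal consensus, merged into regions by [merge_bins_to_regions()].
#'
#' @param bintable A `bin_table` from [bin_breakpoint_stats()].
#' @param response `"count"` (default, per-bin SV breakpoint counts) or
#'   `"recurrence"`.
#' @param density_quantile Bins with density at or above this quantile are
#'   removed before scanning (default 0.975); `1` disables the high-density
#'   filter.
#' @param resid_threshold Residual flagging threshold in SD (default 2).
#' @param min_chrom_bins Minimum retained bins for the per-chromosome method.
#' @param max_flag_frac Degenerate-split guard of [ranksum_kmeans()].
#' @return Object of class `hotspot_calls`: data.frame of retained bins with
#'   logical columns `genomewide`, `perchrom`, `ranksum`, `consensus`, plus
#'   attributes `"regions"` (merged consensus regions), `"removed"` (bin ids
#'   filtered before the scan) and `"skipped_chroms"`.
#' @export
focal_hotspots <- function(bintable, response = c("count", "recurrence"),
                           density_quantile = 0.975, resid_threshold = 2,
                           min_chrom_bins = 5, max_flag_frac = 0.2) {
  response <- match.arg(response)
  counts <- attr(bintable, "counts")
  drop <- bintable$fragile > 0
  if (density_quantile < 1) {
    dens_cut <- stats::quantile(bintable$density, density_quantile)
    drop <- drop | (bintable$density >= dens_cut & bintable$density > 0)
  }
  keep <- which(!drop)
  bt <- as.data.frame(bintable)[keep, , drop = FALSE]
  cnt <- counts[keep, , drop = FALSE]
  y <- if (response == "count") bt$total else bt$recurrence
  nb_flags <- function(yy) {
    if (length(yy) == 0) return(logical(0))
    if (max(yy) == min(yy)) return(rep(FALSE, length(yy)))
    fit <- tryCatch(suppressWarnings(MASS::glm.nb(yy ~ 1)),
                    error = function(e) NULL)
    if (is.null(fit)) fit <- stats::glm(yy ~ 1, family = stats::poisson())
    std_pearson_resid(fit) >= resid_threshold
  }
  m1 <- nb_flags(y)
  m2 <- rep(FALSE, nrow(bt))
  skipped <- character()
  for (ch in unique(bt$chrom)) {
    idx <- which(bt$chrom == ch)
    if (length(idx) < min_chrom_bins) {
      skipped <- c(skipped, ch)
      next
    }
    m2[idx] <- nb_flags(y[idx])
  }
  m3 <- if (nrow(bt) >= 2) ranksum_kmeans(cnt, max_flag_frac) else
    rep(FALSE, nrow(bt))
  consensus <- (m1 + m2 + m3) >= 2
  out <- data.frame(bt[, c("bin", "chrom", "start", "end", "total",
                           "recurrence", "density")],
                    genomewide = m1, perchrom = m2, ranksum = m3,
                    consensus = consensus, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "regions") <- merge_bins_to_regions(out[out$consensus, ,
                                                    drop = FALSE])
  attr(out, "removed") <- bintable$bin[drop]
  attr(out, "skipped_chroms") <- skipped
  class(out) <- c("hotspot_calls", "data.frame")
  out
}

#' Merge flagged bins into regions
#'
#' Overlapping or bookended flagged bins on the same chromosome are merged
#' into single regions (interval union).
#'
#' @param flagged_bins data.frame with `chrom`, `start`, `end` (0-based
#'   half-open bins).
#' @return data.frame `region`, `chrom`, `start`, `end`, `n_bins`.
#' @export
merge_bins_to_regions <- function(flagged_bins) {
  if (nrow(flagged_bins) == 0) {
    return(data.frame(region = integer(), chrom = character(),
                      start = numeric(), end = numeric(), n_bins = integer(),
                      stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::GRanges(
    flagged_bins$chrom,
    IRanges::IRanges(flagged_bins$start + 1, flagged_bins$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  ov <- GenomicRanges::countOverlaps(red, gr)
  out <- data.frame(
    region = seq_along(red),
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1,
    end = GenomicRanges::end(red),
    n_bins = as.integer(ov), stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}
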