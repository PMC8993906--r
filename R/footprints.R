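#' Cluster one patient's SVs into footprints
#'
#' Agglomerative clustering of a patient's rearrangements: two SVs join the
#' same footprint when the nearest distance between any of their breakends is
#' smaller than expected under uniform breakpoint placement. With `N` total
#' breakends on a genome of length `G`, nearest-neighbour gaps are
#' approximately exponential with mean `G / (2 N)`; the merge threshold is
#' the lower-tail `alpha` quantile `d* = -log(1 - alpha) * G / (2 N)`, so
#' only gaps improbably small under the null (at significance `alpha`) cause
#' a merge. Merging is transitive; breakends on different chromosomes are at
#' infinite distance. The output partitions the input call set.
#'
#' @param patient_calls [sv_calls()] rows of a single patient (already panel-
#'   and excluded-region-filtered).
#' @param genome A [genome_def()] (supplies `G`).
#' @param alpha Significance level of the merge threshold (default 0.05);
#'   smaller `alpha` merges less.
#' @return `patient_calls` with the `cluster` column set (integer ids,
#'   contiguous from 1).
#' @export
cluster_footprints <- function(patient_calls, genome, alpha = 0.05) {
  if (nrow(patient_calls) == 0) return(patient_calls)
  if (length(unique(patient_calls$patient)) > 1) {
    stop("cluster_footprints expects calls of a single patient")
  }
  n_bp <- 2L * nrow(patient_calls)
  dstar <- -log(1 - alpha) * genome_length(genome) / (2 * n_bp)
  bk <- data.frame(
    call = rep(seq_len(nrow(patient_calls)), 2L),
    chrom = c(patient_calls$chrom1, patient_calls$chrom2),
    pos = c(patient_calls$pos1, patient_calls$pos2),
    stringsAsFactors = FALSE)
  # union-find over calls; linking consecutive sorted breakends with gap <
  # d* yields the same transitive closure as all-pairs linking
  parent <- seq_len(nrow(patient_calls))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (ch in unique(bk$chrom)) {
    sub <- bk[bk$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    if (nrow(sub) < 2) next
    gaps <- diff(sub$pos)
    link <- which(gaps < dstar)
    for (i in link) union_(sub$call[i], sub$call[i + 1])
  }
  roots <- vapply(seq_len(nrow(patient_calls)), find, integer(1))
  patient_calls$cluster <- match(roots, sort(unique(roots)))
  patient_calls
}

#' Cluster all patients of a cohort
#'
#' Applies [cluster_footprints()] per patient; cluster ids are made globally
#' unique across patients.
#'
#' @param cohort An [sv_cohort()].
#' @param genome A [genome_def()].
#' @param alpha Merge significance, see [cluster_footprints()].
#' @return The cohort with the `cluster` column of its calls set.
#' @export
cluster_cohort <- function(cohort, genome, alpha = 0.05) {
  calls <- cohort$calls
  if (nrow(calls) == 0) return(cohort)
  out <- lapply(split(seq_len(nrow(calls)), calls$patient), function(idx) {
    cluster_footprints(calls[idx, , drop = FALSE], genome, alpha)
  })
  offset <- 0L
  for (i in seq_along(out)) {
    if (nrow(out[[i]]) == 0) next
    out[[i]]$cluster <- out[[i]]$cluster + offset
    offset <- max(out[[i]]$cluster)
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  key <- function(d) paste(d$patient, d$call_id)
  cohort$calls <- calls[order(match(key(calls), key(cohort$calls))), ]
  rownames(cohort$calls) <- NULL
  cohort
}

#' Summarise and classify footprint clusters
#'
#' Singleton footprints are `simple` (a single rearrangement not belonging
#' to a cluster), multi-member footprints are `complex`; a footprint whose
#' members are all mobile-element-annotated BNDs (see [annotate_me()]) is
#' labelled `ME` and set aside from the simple/complex classes.
#'
#' @param calls Clustered [sv_calls()] (the `cluster` column set).
#' @param me_rule `"all"` (default) labels a cluster ME when every member is
#'   an ME-flagged BND; `"any"` when at least one member is.
#' @return data.frame with one row per cluster: `patient`, `cluster`,
#'   `n_members`, `class`, `members` (comma-separated call ids), `chroms`,
#'   `span_start`, `span_end` (breakend envelope of the first chromosome).
#'   The input calls are returned via attribute `"calls"` with
#'   `cluster_class` filled in.
#' @export
classify_clusters <- function(calls, me_rule = c("all", "any")) {
  me_rule <- match.arg(me_rule)
  if (nrow(calls) == 0) {
    out <- data.frame(patient = character(), cluster = integer(),
                      n_members = integer(), class = character(),
                      members = character(), stringsAsFactors = FALSE)
    attr(out, "calls") <- calls
    return(out)
  }
  if (any(is.na(calls$cluster))) stop("calls must be clustered first")
  parts <- split(seq_len(nrow(calls)), calls$cluster)
  rows <- lapply(parts, function(idx) {
    d <- calls[idx, , drop = FALSE]
    me_bnd <- d$svtype == "BND" & d$me
    cls <- if ((me_rule == "all" && all(me_bnd)) ||
               (me_rule == "any" && any(me_bnd))) "ME"
      else if (nrow(d) == 1) "simple" else "complex"
    ch <- unique(c(d$chrom1, d$chrom2))
    on1 <- c(d$pos1[d$chrom1 == ch[1]], d$pos2[d$chrom2 == ch[1]])
    data.frame(patient = d$patient[1], cluster = d$cluster[1],
               n_members = nrow(d), class = cls,
               members = paste(d$call_id, collapse = ","),
               chroms = paste(ch, collapse = ","),
               span_start = min(on1), span_end = max(on1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  calls$cluster_class <- out$class[match(calls$cluster, out$cluster)]
  attr(out, "calls") <- calls
  out
}

#' Drop mobile-element insertions lacking a poly-A tail
#'
#' Retrotransposition leaves a poly-A tract at the integration site; calls
#' without it are likely artefacts and are discarded before annotation.
#'
#' @param insertions ME insertion data.frame with a logical `polyA` column.
#' @return The filtered data.frame.
#' @export
filter_polya <- function(insertions) {
  insertions[insertions$polyA, , drop = FALSE]
}

#' Annotate BND calls as mobile-element insertions
#'
#' A BND call is flagged iff either breakend lies within an insertion
#' interval (+/- `window_bp`) or within a region known to be transduced by
#' LINE-1 source elements. Non-BND calls are never flagged. Insertions are
#' expected to be poly-A filtered already (see [filter_polya()]).
#'
#' @param calls An [sv_calls()] data.frame.
#' @param insertions data.frame with `chrom`, `pos` (or `start`/`end`) of
#'   insertion sites.
#' @param transduction_regions Optional data.frame `chrom`, `start`, `end`
#'   (1-based closed) of known transduced sequence.
#' @param window_bp Proximity window around insertion sites (default 0:
#'   direct overlap).
#' @return `calls` with the `me` flag set.
#' @export
annotate_me <- function(calls, insertions, transduction_regions = NULL,
                        window_bp = 0) {
  if (nrow(calls) == 0) return(calls)
  calls$me <- FALSE
  bnd <- which(calls$svtype == "BND")
  if (length(bnd) == 0) return(calls)
  targets <- list()
  if (!is.null(insertions) && nrow(insertions) > 0) {
    s <- if (!is.null(insertions$start)) insertions$start else insertions$pos
    e <- if (!is.null(insertions$end)) insertions$end else insertions$pos
    targets$ins <- GenomicRanges::GRanges(
      insertions$chrom,
      IRanges::IRanges(pmax(1, s - window_bp), e + window_bp))
  }
  if (!is.null(transduction_regions) && nrow(transduction_regions) > 0) {
    targets$tr <- GenomicRanges::GRanges(
      transduction_regions$chrom,
      IRanges::IRanges(transduction_regions$start, transduction_regions$end))
  }
  if (length(targets) == 0) return(calls)
  tg <- suppressWarnings(do.call(c, unname(targets)))
  g1 <- GenomicRanges::GRanges(calls$chrom1[bnd],
                               IRanges::IRanges(calls$pos1[bnd], calls$pos1[bnd]))
  g2 <- GenomicRanges::GRanges(calls$chrom2[bnd],
                               IRanges::IRanges(calls$pos2[bnd], calls$pos2[bnd]))
  calls$me[bnd] <- suppressWarnings(
    IRanges::overlapsAny(g1, tg) | IRanges::overlapsAny(g2, tg))
  calls
}

#' Overlap of footprint clusters with ME insertions and source regions
#'
#' For a set of clusters (typically restricted to one signature group by the
#' caller), counts clusters with at least one member breakend inside an
#' insertion interval, and clusters overlapping only known transduction
#' source regions. Each cluster counts once; insertion overlap takes
#' precedence.
#'
#' @param clusters Cluster table from [classify_clusters()] (its `"calls"`
#'   attribute, or pass `calls=`).
#' @param calls Clustered calls backing the clusters.
#' @param insertions Insertion data.frame (`chrom`, `pos`).
#' @param transduction_regions Optional source-region data.frame (`chrom`,
#'   `start`, `end`).
#' @param window_bp Proximity window (default 0).
#' @return List: `n_clusters`, `n_insertion`, `n_source_only`,
#'   `frac_insertion`, `frac_source_only` (fractions `NA` when there are no
#'   clusters).
#' @export
me_cluster_overlap <- function(clusters, calls, insertions,
                               transduction_regions = NULL, window_bp = 0) {
  n <- nrow(clusters)
  if (n == 0) {
    return(list(n_clusters = 0L, n_insertion = 0L, n_source_only = 0L,
                frac_insertion = NA_real_, frac_source_only = NA_real_))
  }
  hit_set <- function(targets) {
    if (is.null(targets) || nrow(targets) == 0) return(rep(FALSE, n))
    s <- if (!is.null(targets$start)) targets$start else targets$pos
    e <- if (!is.null(targets$end)) targets$end else targets$pos
    tg <- GenomicRanges::GRanges(targets$chrom,
                                 IRanges::IRanges(pmax(1, s - window_bp),
                                                  e + window_bp))
    bk <- GenomicRanges::GRanges(
      c(calls$chrom1, calls$chrom2),
      IRanges::IRanges(c(calls$pos1, calls$pos2), c(calls$pos1, calls$pos2)))
    hit_bk <- suppressWarnings(IRanges::overlapsAny(bk, tg))
    hit_call <- hit_bk[seq_len(nrow(calls))] |
      hit_bk[nrow(calls) + seq_len(nrow(calls))]
    vapply(clusters$cluster,
           function(cl) any(hit_call[calls$cluster == cl]), logical(1))
  }
  ins_hit <- hit_set(insertions)
  src_hit <- hit_set(transduction_regions)
  n_ins <- sum(ins_hit)
  n_src <- sum(src_hit & !ins_hit)
  list(n_clusters = n, n_insertion = n_ins, n_source_only = n_src,
       frac_insertion = n_ins / n, frac_source_only = n_src / n)
}

#' Summarise mobile-element insertions across a cohort
#'
#' Reports the per-tumour insert burden (median and IQR, 25th/75th
#' percentiles with linear interpolation) and the class/source composition
#' of the grand total, with printed percentages via [format_percent()].
#'
#' @param insertions ME insertion data.frame with `patient`, `class`,
#'   `source` columns.
#' @param patients Optional full patient id vector (patients without inserts
#'   count as zero).
#' @return List: `median`, `iqr` (length-2), `n_total`, `class_table` and
#'   `source_table` (data.frames with `n` and rendered `percent`).
#' @export
summarize_me <- function(insertions, patients = NULL) {
  per <- table(insertions$patient)
  if (!is.null(patients)) {
    per <- table(factor(insertions$patient, levels = patients))
  }
  counts <- as.numeric(per)
  qs <- stats::quantile(counts, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  n_tot <- nrow(insertions)
  tab <- function(x) {
    t <- sort(table(x), decreasing = TRUE)
    data.frame(category = names(t), n = as.integer(t),
               percent = vapply(as.integer(t), function(k)
                 format_percent(k, n_tot), character(1)),
               stringsAsFactors = FALSE)
  }
  list(median = qs[2], iqr = qs[c(1, 3)], n_total = n_tot,
       class_table = tab(insertions$class),
       source_table = tab(insertions$source))
}
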