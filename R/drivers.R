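#' Convert SV calls to genomic spans
#'
#' Intra-chromosomal calls span the interval between their two breakends;
#' inter-chromosomal calls contribute one window of `+/- bnd_window_bp`
#' around each breakend (point intervals by default).
#'
#' @param calls An [sv_calls()] data.frame.
#' @param bnd_window_bp Half-width of the window around BND breakends
#'   (default 0).
#' @param genome Optional [genome_def()] used to clip windows to chromosome
#'   bounds.
#' @return data.frame `call_id`, `patient`, `svtype`, `chrom`, `start`,
#'   `end` (1-based closed; one row per intra call, two per BND).
#' @export
sv_spans <- function(calls, bnd_window_bp = 0, genome = NULL) {
  intra <- calls[calls$chrom1 == calls$chrom2, , drop = FALSE]
  inter <- calls[calls$chrom1 != calls$chrom2, , drop = FALSE]
  spans <- data.frame(
    call_id = c(intra$call_id, inter$call_id, inter$call_id),
    patient = c(intra$patient, inter$patient, inter$patient),
    svtype = c(intra$svtype, inter$svtype, inter$svtype),
    chrom = c(intra$chrom1, inter$chrom1, inter$chrom2),
    start = c(pmin(intra$pos1, intra$pos2),
              inter$pos1 - bnd_window_bp, inter$pos2 - bnd_window_bp),
    end = c(pmax(intra$pos1, intra$pos2),
            inter$pos1 + bnd_window_bp, inter$pos2 + bnd_window_bp),
    stringsAsFactors = FALSE)
  spans$start <- pmax(1, spans$start)
  if (!is.null(genome)) {
    spans$end <- pmin(spans$end, genome$lengths[spans$chrom])
  }
  rownames(spans) <- NULL
  spans
}

#' Patient-by-gene exon hit table
#'
#' A patient hits a gene iff any of the patient's SV spans intersects at
#' least one exon of the gene's canonical transcript (closed-interval,
#' any-overlap).
#'
#' @param spans Span table from [sv_spans()].
#' @param gene_models Exon table from [read_gene_models()].
#' @return Logical matrix, patients (rows, from `spans`) x genes (columns).
#' @export
gene_hits <- function(spans, gene_models) {
  patients <- unique(spans$patient)
  genes <- unique(gene_models$gene)
  m <- matrix(FALSE, length(patients), length(genes),
              dimnames = list(patients, genes))
  if (nrow(spans) == 0 || nrow(gene_models) == 0) return(m)
  sg <- GenomicRanges::GRanges(spans$chrom,
                               IRanges::IRanges(spans$start, spans$end))
  eg <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(gene_models$exon_start, gene_models$exon_end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(sg, eg))
  if (length(ov) > 0) {
    pat <- spans$patient[S4Vectors::queryHits(ov)]
    gen <- gene_models$gene[S4Vectors::subjectHits(ov)]
    m[cbind(match(pat, patients), match(gen, genes))] <- TRUE
  }
  m
}

#' Two-proportion test of driver recurrence with vs without SVs
#'
#' For each gene, tests whether the recurrence including SV hits is
#' significantly higher than without them (one-sided two-proportion z-test
#' with continuity correction, `alternative = "greater"`), followed by
#' Benjamini-Hochberg correction across genes.
#'
#' @param tally data.frame with columns `gene`, `without` (patients altered
#'   by SNV/indel/CN only), `with` (patients altered once SVs are added) and
#'   optionally `n` (cohort size; or supply `cohort_size`).
#' @param cohort_size Cohort size applied to all genes when `tally$n` is
#'   absent.
#' @param correct Continuity correction (default TRUE).
#' @param strict Enforce the tally invariant `with >= without` (default
#'   TRUE; calibration simulations on independent proportions disable it).
#' @return `tally` with `z`, `p`, `q` columns appended.
#' @export
recurrence_test <- function(tally, cohort_size = NULL, correct = TRUE,
                            strict = TRUE) {
  if (is.null(tally$n)) {
    if (is.null(cohort_size)) stop("supply tally$n or cohort_size")
    tally$n <- cohort_size
  }
  if (any(tally$n <= 0)) stop("cohort size must be positive")
  if (strict && any(tally$with < tally$without)) {
    stop("with-SV recurrence below without-SV recurrence")
  }
  res <- lapply(seq_len(nrow(tally)), function(i) {
    pt <- suppressWarnings(stats::prop.test(
      x = c(tally$with[i], tally$without[i]),
      n = c(tally$n[i], tally$n[i]),
      alternative = "greater", correct = correct))
    z <- sqrt(unname(pt$statistic)) *
      sign(tally$with[i] / tally$n[i] - tally$without[i] / tally$n[i])
    c(z = z, p = pt$p.value)
  })
  res <- do.call(rbind, res)
  tally$z <- res[, "z"]
  tally$p <- res[, "p"]
  tally$q <- stats::p.adjust(tally$p, method = "BH")
  tally
}

#' Narrow hotspot regions to candidate driver genes
#'
#' Keeps cancer-census-flagged genes whose exons intersect a hotspot region,
#' excludes genes overlapping fragile-site regions, and requires at least
#' one patient with an exon-overlapping SV span (genes inside hotspots may
#' still not be directly hit).
#'
#' @param regions Region table from [merge_bins_to_regions()] (0-based
#'   half-open) or any data.frame `chrom`, `start`, `end` with
#'   `zero_based = FALSE` for 1-based closed input.
#' @param gene_models Exon table with a `cancer` flag column.
#' @param fragile_regions Optional data.frame `chrom`, `start`, `end`
#'   (1-based closed).
#' @param spans Span table from [sv_spans()] used for the direct-hit check.
#' @param zero_based Whether `regions` uses 0-based half-open coordinates
#'   (default TRUE, as produced by the binning code).
#' @return data.frame `gene`, `chrom`, `n_patients` (with exon-overlapping
#'   SVs), `region`.
#' @export
candidate_driver_filter <- function(regions, gene_models, fragile_regions,
                                    spans, zero_based = TRUE) {
  empty <- data.frame(gene = character(), chrom = character(),
                      n_patients = integer(), region = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(regions) == 0) return(empty)
  rg <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(regions$start + as.integer(zero_based), regions$end))
  cg <- gene_models[gene_models$cancer, , drop = FALSE]
  if (nrow(cg) == 0) return(empty)
  eg <- GenomicRanges::GRanges(cg$chrom,
                               IRanges::IRanges(cg$exon_start, cg$exon_end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(eg, rg))
  if (length(ov) == 0) return(empty)
  cand <- unique(data.frame(
    gene = cg$gene[S4Vectors::queryHits(ov)],
    region = S4Vectors::subjectHits(ov), stringsAsFactors = FALSE))
  # drop genes overlapping fragile sites
  if (!is.null(fragile_regions) && nrow(fragile_regions) > 0) {
    fg <- GenomicRanges::GRanges(
      fragile_regions$chrom,
      IRanges::IRanges(fragile_regions$start, fragile_regions$end))
    frag_genes <- unique(cg$gene[suppressWarnings(
      IRanges::overlapsAny(eg, fg))])
    cand <- cand[!(cand$gene %in% frag_genes), , drop = FALSE]
  }
  if (nrow(cand) == 0) return(empty)
  hits <- gene_hits(spans, gene_models[gene_models$gene %in% cand$gene, ,
                                       drop = FALSE])
  n_pat <- colSums(hits)
  cand$n_patients <- as.integer(n_pat[cand$gene])
  cand <- cand[cand$n_patients > 0, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  cand$chrom <- cg$chrom[match(cand$gene, cg$gene)]
  rownames(cand) <- NULL
  cand[, c("gene", "chrom", "n_patients", "region")]
}

#' Simple/complex SV profile of one gene
#'
#' Per patient, counts exon-overlapping SVs of the gene split by footprint
#' class (simple vs complex; ME clusters are counted under their own label)
#' and SV type.
#'
#' @param gene Gene symbol.
#' @param cohort Clustered and classified [sv_cohort()] (calls carry
#'   `cluster_class`).
#' @param gene_models Exon table.
#' @param bnd_window_bp Window used for BND spans (default 0).
#' @return data.frame `patient`, `class`, `svtype`, `n` (patients without
#'   overlap are absent).
#' @export
gene_sv_profile <- function(gene, cohort, gene_models, bnd_window_bp = 0) {
  calls <- cohort$calls
  empty <- data.frame(patient = character(), class = character(),
                      svtype = character(), n = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0) return(empty)
  if (any(is.na(calls$cluster_class))) {
    stop("calls must carry cluster_class (run classify_clusters first)")
  }
  gm <- gene_models[gene_models$gene == gene, , drop = FALSE]
  if (nrow(gm) == 0) stop("unknown gene: ", gene)
  spans <- sv_spans(calls, bnd_window_bp = bnd_window_bp)
  eg <- GenomicRanges::GRanges(gm$chrom,
                               IRanges::IRanges(gm$exon_start, gm$exon_end))
  sg <- GenomicRanges::GRanges(spans$chrom,
                               IRanges::IRanges(spans$start, spans$end))
  hit <- suppressWarnings(IRanges::overlapsAny(sg, eg))
  hit_keys <- unique(paste(spans$patient, spans$call_id)[hit])
  sub <- calls[paste(calls$patient, calls$call_id) %in% hit_keys, ,
               drop = FALSE]
  if (nrow(sub) == 0) return(empty)
  agg <- stats::aggregate(list(n = rep(1L, nrow(sub))),
                          by = list(patient = sub$patient,
                                    class = sub$cluster_class,
                                    svtype = sub$svtype), FUN = sum)
  agg[order(agg$patient, agg$class, agg$svtype), , drop = FALSE]
}

#' Bins with SV frequency differing between two patient groups
#'
#' Per non-fragile bin, computes the fraction of each group's patients with
#' at least one breakpoint and returns bins whose frequency difference
#' (group A minus group B) is at least `min_diff`.
#'
#' @param bintable A `bin_table` from [bin_breakpoint_stats()].
#' @param groupA_patients,groupB_patients Disjoint patient id vectors.
#' @param min_diff Minimum frequency difference (default 0.15).
#' @return data.frame of qualifying bins with `freqA`, `freqB`, `diff`.
#' @export
rs_group_bin_enrichment <- function(bintable, groupA_patients,
                                    groupB_patients, min_diff = 0.15) {
  if (length(groupA_patients) == 0 || length(groupB_patients) == 0) {
    stop("both groups need at least one patient")
  }
  if (length(intersect(groupA_patients, groupB_patients)) > 0) {
    stop("groups must be disjoint")
  }
  counts <- attr(bintable, "counts")
  stopifnot(all(c(groupA_patients, groupB_patients) %in% colnames(counts)))
  freqA <- rowMeans(counts[, groupA_patients, drop = FALSE] > 0)
  freqB <- rowMeans(counts[, groupB_patients, drop = FALSE] > 0)
  keep <- bintable$fragile == 0 & (freqA - freqB >= min_diff)
  out <- data.frame(as.data.frame(bintable)[keep, c("bin", "chrom", "start",
                                                    "end")],
                    freqA = freqA[keep], freqB = freqB[keep],
                    diff = (freqA - freqB)[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Patients whose deletion spans hit named locus features
#'
#' For each named feature interval (enhancer, exon set, promoter, ...),
#' counts the distinct patients with a deletion span intersecting it; a
#' patient may count toward several features.
#'
#' @param deletion_spans Span table (typically [sv_spans()] of DEL calls).
#' @param locus_features data.frame `name`, `chrom`, `start`, `end`
#'   (1-based closed).
#' @return data.frame `feature`, `n_patients`.
#' @export
locus_feature_overlap <- function(deletion_spans, locus_features) {
  fg <- GenomicRanges::GRanges(
    locus_features$chrom,
    IRanges::IRanges(locus_features$start, locus_features$end))
  if (nrow(deletion_spans) == 0) {
    return(data.frame(feature = locus_features$name, n_patients = 0L,
                      stringsAsFactors = FALSE))
  }
  sg <- GenomicRanges::GRanges(
    deletion_spans$chrom,
    IRanges::IRanges(deletion_spans$start, deletion_spans$end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(fg, sg))
  n <- vapply(seq_len(nrow(locus_features)), function(i) {
    length(unique(deletion_spans$patient[
      S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]]))
  }, integer(1))
  data.frame(feature = locus_features$name, n_patients = n,
             stringsAsFactors = FALSE)
}

#' Permutation test of query/target region overlap
#'
#' Observed statistic: the number of query regions overlapping at least one
#' target region. Null: each query region is placed uniformly at random
#' within its own chromosome, preserving its length, independently per
#' permutation. The empirical p-value is `(1 + #{perm >= obs}) / (n_perm +
#' 1)`.
#'
#' @param query_regions,target_regions data.frames `chrom`, `start`, `end`
#'   (1-based closed).
#' @param genome A [genome_def()].
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed.
#' @return List: `observed`, `expected` (mean over permutations), `p`.
#' @export
permutation_overlap_test <- function(query_regions, target_regions, genome,
                                     n_perm = 5000, seed = 1) {
  lens <- query_regions$end - query_regions$start + 1
  chrom_len <- genome$lengths[query_regions$chrom]
  if (any(lens > chrom_len)) stop("query region longer than its chromosome")
  count_overlap <- function(qs, qe) {
    if (nrow(target_regions) == 0) return(0L)
    qg <- GenomicRanges::GRanges(query_regions$chrom,
                                 IRanges::IRanges(qs, qe))
    tg <- GenomicRanges::GRanges(target_regions$chrom,
                                 IRanges::IRanges(target_regions$start,
                                                  target_regions$end))
    sum(suppressWarnings(IRanges::overlapsAny(qg, tg)))
  }
  observed <- count_overlap(query_regions$start, query_regions$end)
  set.seed(seed)
  nq <- nrow(query_regions)
  perm <- vapply(seq_len(n_perm), function(i) {
    s <- floor(stats::runif(nq, 0, chrom_len - lens + 1)) + 1
    count_overlap(s, s + lens - 1)
  }, numeric(1))
  list(observed = observed, expected = mean(perm),
       p = (1 + sum(perm >= observed)) / (n_perm + 1))
}
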