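# Independent brute-force oracles and tiny fixture builders shared by the
# tests. Oracles deliberately avoid the package's interval machinery.

toy_genome <- function(nchrom = 2, len = 1e6) {
  genome_def(paste0("chr", seq_len(nchrom)), rep(len, nchrom))
}

make_call <- function(id, patient, chrom1, pos1, strand1, chrom2, pos2,
                      strand2, svtype = NA_character_) {
  data.frame(call_id = id, patient = patient, chrom1 = chrom1, pos1 = pos1,
             strand1 = strand1, chrom2 = chrom2, pos2 = pos2,
             strand2 = strand2, svtype = svtype, stringsAsFactors = FALSE)
}

simple_del <- function(id, patient, chrom, start, end) {
  make_call(id, patient, chrom, start, "+", chrom, end, "-", "DEL")
}

# interval intersection, closed coordinates, no ranges machinery
intersects <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1

brute_gene_hits <- function(spans, gene_models) {
  patients <- unique(spans$patient)
  genes <- unique(gene_models$gene)
  m <- matrix(FALSE, length(patients), length(genes),
              dimnames = list(patients, genes))
  for (i in seq_len(nrow(spans))) {
    for (j in seq_len(nrow(gene_models))) {
      if (spans$chrom[i] == gene_models$chrom[j] &&
          intersects(spans$start[i], spans$end[i],
                     gene_models$exon_start[j], gene_models$exon_end[j])) {
        m[spans$patient[i], gene_models$gene[j]] <- TRUE
      }
    }
  }
  m
}

brute_locus_overlap <- function(spans, features) {
  n <- integer(nrow(features))
  for (j in seq_len(nrow(features))) {
    pats <- character()
    for (i in seq_len(nrow(spans))) {
      if (spans$chrom[i] == features$chrom[j] &&
          intersects(spans$start[i], spans$end[i],
                     features$start[j], features$end[j])) {
        pats <- union(pats, spans$patient[i])
      }
    }
    n[j] <- length(pats)
  }
  data.frame(feature = features$name, n_patients = n,
             stringsAsFactors = FALSE)
}

# number of merged regions of 1-based closed intervals, by per-base membership
brute_n_regions <- function(starts, ends, limit) {
  covered <- logical(limit)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  r <- rle(covered)
  sum(r$values == TRUE)
}

random_spans <- function(n, genome, patients, max_len = 5e4) {
  chrom <- sample(genome$chroms, n, replace = TRUE)
  start <- floor(runif(n, 1, genome$lengths[chrom] - max_len))
  data.frame(call_id = paste0("s", seq_len(n)),
             patient = sample(patients, n, replace = TRUE),
             svtype = "DEL", chrom = chrom, start = start,
             end = start + floor(runif(n, 0, max_len)),
             stringsAsFactors = FALSE)
}

random_gene_models <- function(n_genes, genome, max_exons = 4) {
  rows <- lapply(seq_len(n_genes), function(g) {
    chrom <- sample(genome$chroms, 1)
    n_ex <- sample.int(max_exons, 1)
    s <- sort(sample.int(genome$lengths[[chrom]] - 2000, n_ex))
    data.frame(gene = paste0("G", g), transcript = paste0("T", g),
               chrom = chrom, strand = sample(c("+", "-"), 1),
               exon_start = s, exon_end = s + sample.int(1500, n_ex),
               cancer = runif(1) < 0.5, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# flat-rate simulation parameters used by several calibration tests
flat_beta <- function(intercept) {
  b <- c(intercept, rep(0, 8))
  names(b) <- c("intercept", covariate_names())
  b
}
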