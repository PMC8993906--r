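test_that("sv_spans builds intra intervals and BND windows", {
  d <- sv_calls(simple_del("a", "P", "chr1", 1000, 5000))
  s <- sv_spans(d)
  expect_equal(c(s$start, s$end), c(1000, 5000))
  b <- sv_calls(make_call("b", "P", "chr1", 100, "+", "chr2", 200, "-"))
  sb <- sv_spans(b, bnd_window_bp = 0)
  expect_equal(nrow(sb), 2)
  expect_true(all(sb$end - sb$start == 0))   # two 1-bp intervals
  sw <- sv_spans(b, bnd_window_bp = 50)
  expect_equal(sw$end - sw$start, c(100, 100))
  # swapped input breakends normalise to the same interval
  inv1 <- sv_calls(make_call("i", "P", "chr1", 9000, "+", "chr1", 2000, "+"))
  inv2 <- sv_calls(make_call("i", "P", "chr1", 2000, "+", "chr1", 9000, "+"))
  expect_equal(sv_spans(inv1)[, c("start", "end")],
               sv_spans(inv2)[, c("start", "end")])
})

test_that("gene_hits requires exon overlap and matches the oracle", {
  gm <- data.frame(gene = "G", transcript = "T", chrom = "chr1",
                   strand = "+", exon_start = c(2000, 8000),
                   exon_end = c(2500, 8500), cancer = TRUE,
                   stringsAsFactors = FALSE)
  covering <- data.frame(call_id = "a", patient = "P1", svtype = "DEL",
                         chrom = "chr1", start = 1000, end = 9000)
  expect_true(gene_hits(covering, gm)["P1", "G"])
  intronic <- data.frame(call_id = "b", patient = "P2", svtype = "DEL",
                         chrom = "chr1", start = 3000, end = 7000)
  expect_false(gene_hits(intronic, gm)["P2", "G"])
  expect_equal(gene_hits(intronic, gm), brute_gene_hits(intronic, gm))
})

test_that("recurrence_test matches an independent oracle and BH properties", {
  t0 <- recurrence_test(data.frame(gene = "g", without = 50, with = 50),
                        cohort_size = 383)
  expect_gte(t0$p, 0.5)
  # continuity-corrected one-sided two-proportion z computed from scratch
  n <- 383; x1 <- 165; x2 <- 96
  p1 <- x1 / n; p2 <- x2 / n; pp <- (x1 + x2) / (2 * n)
  z <- (p1 - p2 - 1 / n) / sqrt(pp * (1 - pp) * 2 / n)
  p_oracle <- pnorm(z, lower.tail = FALSE)
  t1 <- recurrence_test(data.frame(gene = "RUNX1", without = x2, with = x1),
                        cohort_size = n)
  expect_equal(t1$p, p_oracle, tolerance = 1e-10)
  expect_error(recurrence_test(data.frame(gene = "g", without = 5, with = 2),
                               cohort_size = 10), "below")
  expect_error(recurrence_test(data.frame(gene = "g", without = 1, with = 2),
                               cohort_size = 0), "positive")
  # BH q-values dominate p and are monotone in rank
  set.seed(33)
  tt <- data.frame(gene = paste0("g", 1:48),
                   without = rbinom(48, 383, 0.2))
  tt$with <- tt$without + rbinom(48, 20, 0.3)
  out <- recurrence_test(tt, cohort_size = 383)
  expect_true(all(out$q >= out$p - 1e-12))
  ord <- order(out$p)
  expect_true(all(diff(cummin(rev(out$q[ord]))) <= 1e-12) ||
                !is.unsorted(out$q[ord], strictly = FALSE))
})

test_that("candidate_driver_filter applies census, fragile and direct-hit rules", {
  gm <- rbind(
    data.frame(gene = "CG1", transcript = "T1", chrom = "chr1", strand = "+",
               exon_start = 1e6, exon_end = 1.01e6, cancer = TRUE),
    data.frame(gene = "CG2", transcript = "T2", chrom = "chr1", strand = "+",
               exon_start = 1.2e6, exon_end = 1.21e6, cancer = TRUE),
    data.frame(gene = "FRG", transcript = "T3", chrom = "chr1", strand = "+",
               exon_start = 1.4e6, exon_end = 1.41e6, cancer = TRUE),
    data.frame(gene = "NC", transcript = "T4", chrom = "chr1", strand = "+",
               exon_start = 1.6e6, exon_end = 1.61e6, cancer = FALSE))
  regions <- data.frame(chrom = "chr1", start = 9e5, end = 1.7e6)
  fragile <- data.frame(chrom = "chr1", start = 1.39e6, end = 1.42e6)
  spans <- data.frame(call_id = c("a", "b"), patient = c("P1", "P1"),
                      svtype = "DEL", chrom = "chr1",
                      start = c(9.9e5, 1.39e6), end = c(1.02e6, 1.42e6))
  cand <- candidate_driver_filter(regions, gm, fragile, spans)
  expect_equal(cand$gene, "CG1")        # CG2: no hit; FRG: fragile; NC: not census
  expect_equal(cand$n_patients, 1L)
  expect_true(all(cand$gene %in% gm$gene[gm$cancer]))
})

test_that("gene_sv_profile tallies by footprint class and svtype", {
  gd <- genome_def("chr1", 1e8)
  gm <- data.frame(gene = "G", transcript = "T", chrom = "chr1",
                   strand = "+", exon_start = 5e6, exon_end = 5.01e6,
                   cancer = TRUE)
  one <- sv_calls(simple_del("a", "P1", "chr1", 4.99e6, 5.02e6))
  co <- sv_cohort(one)
  co <- cluster_cohort(co, gd)
  co$calls <- attr(classify_clusters(co$calls), "calls")
  pr <- gene_sv_profile("G", co, gm)
  expect_equal(pr$class, "simple")
  expect_equal(pr$svtype, "DEL")
  expect_equal(pr$n, 1L)
  # 3-member complex cluster, 2 members overlapping exons
  trio <- sv_calls(rbind(
    simple_del("c1", "P2", "chr1", 4.995e6, 5.005e6),
    simple_del("c2", "P2", "chr1", 5.006e6, 5.02e6),
    simple_del("c3", "P2", "chr1", 5.03e6, 5.04e6)))
  co2 <- cluster_cohort(sv_cohort(trio), gd)
  co2$calls <- attr(classify_clusters(co2$calls), "calls")
  expect_equal(unique(co2$calls$cluster_class), "complex")
  pr2 <- gene_sv_profile("G", co2, gm)
  expect_equal(sum(pr2$n[pr2$class == "complex"]), 2L)
  # no overlap at all
  none <- cluster_cohort(sv_cohort(sv_calls(
    simple_del("z", "P3", "chr1", 1e6, 1.1e6))), gd)
  none$calls <- attr(classify_clusters(none$calls), "calls")
  expect_equal(nrow(gene_sv_profile("G", none, gm)), 0)
  expect_error(gene_sv_profile("NOPE", co, gm), "unknown gene")
})

test_that("rs_group_bin_enrichment screens by frequency difference", {
  gd <- genome_def("chr1", 1e7)
  tiles <- make_bins(gd, width = 1e6, step = 1e6)
  pats <- sprintf("P%02d", 1:20)
  ga <- pats[1:10]; gb <- pats[11:20]
  # group A: 4 patients hit bin 3; group B: 1 patient
  calls <- sv_calls(do.call(rbind, lapply(c(ga[1:4], gb[1]), function(p)
    simple_del(paste0("c", p), p, "chr1", 2.2e6, 2.3e6))))
  bt <- bin_breakpoint_stats(sv_cohort(calls, patients = pats), tiles)
  enr <- rs_group_bin_enrichment(bt, ga, gb, min_diff = 0.15)
  expect_equal(enr$bin, 3L)
  expect_equal(enr$freqA, 0.4)
  expect_equal(enr$freqB, 0.1)
  # identical groups -> nothing
  enr0 <- rs_group_bin_enrichment(bt, ga[1:2], c(ga[3:4], gb[1])[1:2])
  expect_equal(nrow(enr0), 0)
  expect_error(rs_group_bin_enrichment(bt, character(), gb), "at least one")
  expect_error(rs_group_bin_enrichment(bt, ga, ga), "disjoint")
})

test_that("locus_feature_overlap counts distinct patients per feature", {
  features <- data.frame(name = c("enhancer", "exons", "promoter2"),
                         chrom = "chr1",
                         start = c(1e4, 3e4, 5e4), end = c(2e4, 4e4, 6e4))
  covering <- data.frame(call_id = "a", patient = "P1", svtype = "DEL",
                         chrom = "chr1", start = 5e3, end = 7e4)
  ov <- locus_feature_overlap(covering, features)
  expect_equal(ov$n_patients, c(1L, 1L, 1L))
  between <- data.frame(call_id = "b", patient = "P2", svtype = "DEL",
                        chrom = "chr1", start = 2.1e4, end = 2.9e4)
  expect_equal(locus_feature_overlap(between, features)$n_patients,
               c(0L, 0L, 0L))
})

test_that("permutation_overlap_test: degenerate cases and analytic placement", {
  gd <- genome_def("chr1", 4e6)
  q <- data.frame(chrom = "chr1", start = 1e6 + 1, end = 2e6)
  none <- permutation_overlap_test(q, q[0, ], gd, n_perm = 100, seed = 1)
  expect_equal(none$observed, 0)
  expect_equal(none$p, 1)
  full <- permutation_overlap_test(q, data.frame(chrom = "chr1", start = 1,
                                                 end = 4e6),
                                   gd, n_perm = 200, seed = 1)
  expect_equal(full$p, 1)
  expect_error(permutation_overlap_test(
    data.frame(chrom = "chr1", start = 1, end = 5e6), q, gd), "longer")
  # 4-Mb toy with one 1-Mb target and a point query: P(overlap) = 1/4
  pt <- data.frame(chrom = "chr1", start = 3e6, end = 3e6)
  tg <- data.frame(chrom = "chr1", start = 1, end = 1e6)
  r <- permutation_overlap_test(pt, tg, gd, n_perm = 4000, seed = 5)
  expect_equal(r$expected, 0.25, tolerance = 0.05)
  expect_gte(r$p, 1 / 4001)
  expect_lte(r$p, 1)
})
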