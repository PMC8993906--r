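test_that("bin_breakpoint_stats computes recurrence and density", {
  gd <- genome_def("chr1", 1.5e6)
  bins <- make_bins(gd)                   # [0,1M) and [0.5M,1.5M)
  calls <- sv_calls(rbind(
    make_call("a", "P1", "chr1", 1e5, "+", "chr1", 6e5, "-"),
    make_call("b", "P2", "chr1", 6e5, "+", "chr1", 6.05e5, "-")))
  # use only breakends at 100 kb / 600 kb (P1) and 600 kb (P2): drop P2's 2nd
  co <- sv_cohort(calls)
  bt <- bin_breakpoint_stats(co, bins)
  counts <- attr(bt, "counts")
  expect_equal(counts["1", ], c(P1 = 2L, P2 = 2L))
  expect_equal(bt$recurrence, c(2L, 2L))
  # hand-built example from single breakends
  bks <- sv_cohort(sv_calls(rbind(
    make_call("x", "P1", "chr1", 1e5, "+", "chr1", 6e5, "-"),
    make_call("y", "P2", "chr1", 6e5, "+", "chr1", 1.4e6, "-"))))
  bt2 <- bin_breakpoint_stats(bks, bins)
  expect_equal(bt2$total, c(3L, 3L))
  expect_equal(bt2$recurrence, c(2L, 2L))
  expect_equal(bt2$density, c(1.5, 1.5))
  # exact integer identities
  expect_true(all(bt2$recurrence <= bt2$total))
  expect_equal(bt2$density * length(bks$patients), bt2$total)
})

test_that("a breakend at a bin boundary counts once per containing bin", {
  gd <- genome_def("chr1", 2e6)
  tiles <- make_bins(gd, width = 1e6, step = 1e6)
  co <- sv_cohort(sv_calls(
    make_call("a", "P1", "chr1", 1e6 + 1, "+", "chr1", 1.5e6, "-")))
  bt <- bin_breakpoint_stats(co, tiles)
  expect_equal(bt$total, c(0L, 2L))       # position start+1 is in bin 2 only
})

test_that("fit_context_model recovers a planted covariate effect", {
  gd <- genome_def(c("chr1", "chr2"), c(2e8, 2e8))
  beta <- flat_beta(-2.6)
  beta["gc"] <- 0.7
  sim <- simulate_cohort(sim_params(n_patients = 60, genome = gd,
                                    beta = beta, seed = 17))
  bt <- bin_breakpoint_stats(sim$cohort, sim$tiles,
                             covariates = sim$covariates)
  fit <- fit_context_model(bt, response = "count")
  expect_equal(fit$family, "negative binomial")
  expect_lt(abs(fit$coefficients[["gc"]] - 0.7), 3 * fit$se[["gc"]])
  # flags are invariant under bin reordering
  perm <- sample(nrow(bt))
  btp <- bt[perm, , drop = FALSE]
  attr(btp, "counts") <- attr(bt, "counts")[perm, , drop = FALSE]
  class(btp) <- class(bt)
  fitp <- fit_context_model(btp, response = "count")
  expect_equal(fitp$significant, fit$significant[perm])
  expect_error(fit_context_model(bt[1:10, ]), "50 bins")
})

test_that("constant counts with constant covariates flag nothing", {
  gd <- genome_def("chr1", 6e7)
  tiles <- make_bins(gd, width = 1e6, step = 1e6)
  co <- sv_cohort(empty_calls <- sv_calls(
    make_call("a", "P1", "chr1", 10, "+", "chr1", 20, "-")))
  bt <- bin_breakpoint_stats(co, tiles)
  bt$total <- rep(5L, nrow(bt))
  bt$recurrence <- rep(1L, nrow(bt))
  cov <- data.frame(bin = tiles$bin)
  for (nm in covariate_names()) cov[[nm]] <- 0.5
  btc <- merge(as.data.frame(bt), cov, by = "bin")
  attr(btc, "counts") <- attr(bt, "counts")
  class(btc) <- c("bin_table", "data.frame")
  fit <- fit_context_model(btc, response = "count")
  expect_false(any(fit$significant))
})

test_that("ranksum_kmeans reproduces the worked toy exactly", {
  counts <- cbind(P1 = c(0, 0, 0, 10), P2 = c(1, 0, 0, 8))
  ranks <- apply(counts, 2, rank)
  expect_equal(unname(rowSums(ranks)), c(5, 3.5, 3.5, 8))
  flags <- ranksum_kmeans(counts)
  expect_equal(which(flags), 4L)
  # exhaustive 2-means oracle on the 4 rank sums
  rs <- c(5, 3.5, 3.5, 8)
  ord <- order(rs); x <- rs[ord]
  wss <- vapply(1:3, function(i)
    sum((x[1:i] - mean(x[1:i]))^2) +
      sum((x[(i + 1):4] - mean(x[(i + 1):4]))^2), numeric(1))
  expect_equal(which.min(wss), 3L)        # only the largest sum splits off
})

test_that("ranksum_kmeans degenerate and invariance properties", {
  expect_false(any(ranksum_kmeans(cbind(c(0, 0, 0), c(0, 0, 0)))))
  expect_equal(which(ranksum_kmeans(cbind(c(1, 5)))), 2L)
  expect_error(ranksum_kmeans(cbind(1)), "2 bins")
  # rank-based: any strictly monotone per-patient transform leaves flags alone
  set.seed(19)
  counts <- matrix(rpois(200, 2), 40, 5)
  hot <- c(7, 21, 33)
  counts[hot, ] <- counts[hot, ] + 30L
  f1 <- ranksum_kmeans(counts)
  f2 <- ranksum_kmeans(exp(counts / 3))
  f3 <- ranksum_kmeans(counts * 100L)
  expect_identical(f1, f2)
  expect_identical(f1, f3)
  expect_true(all(f1[hot]))
  expect_false(any(f1[-hot]))
})

test_that("focal_hotspots flags implanted bins and reports skipped work", {
  gd <- genome_def(c("chr1", "chr2", "chr3"), c(5e7, 5e7, 2e6))
  sim <- simulate_cohort(sim_params(
    n_patients = 30, genome = gd, seed = 23,
    hotspots = data.frame(bin = 40, multiplier = 10)))
  bt <- bin_breakpoint_stats(sim$cohort, sim$tiles,
                             covariates = sim$covariates)
  hs <- focal_hotspots(bt, density_quantile = 1)
  expect_true(hs$consensus[hs$bin == 40])
  expect_true(sum(hs$genomewide) + sum(hs$perchrom) + sum(hs$ranksum) >= 2)
  # chr3 has 2 retained bins < 5 -> per-chromosome method skips it
  expect_true("chr3" %in% attr(hs, "skipped_chroms"))
  # fragile and high-density bins are removed before scanning
  hs2 <- focal_hotspots(bt, density_quantile = 0.5)
  expect_true(all(setdiff(bt$bin, hs2$bin) %in% attr(hs2, "removed")))
  expect_false(40 %in% hs2$bin)          # the hottest bin is filtered
})

test_that("identical counts yield no focal flags from any method", {
  gd <- genome_def("chr1", 6e7)
  tiles <- make_bins(gd, width = 1e6, step = 1e6)
  co <- sv_cohort(sv_calls(make_call("a", "P1", "chr1", 10, "+",
                                     "chr1", 20, "-")))
  bt <- bin_breakpoint_stats(co, tiles)
  cnt <- attr(bt, "counts")
  cnt[] <- 4L
  attr(bt, "counts") <- cnt
  bt$total <- rowSums(cnt)
  bt$recurrence <- as.integer(rowSums(cnt > 0))
  bt$density <- bt$total / 1
  hs <- focal_hotspots(bt, density_quantile = 1)
  expect_false(any(hs$genomewide | hs$perchrom | hs$ranksum))
})

test_that("focal consensus is monotone when one bin's counts increase", {
  set.seed(29)
  gd <- genome_def(c("chr1", "chr2"), c(5e7, 5e7))
  sim <- simulate_cohort(sim_params(
    n_patients = 25, genome = gd, seed = 29,
    hotspots = data.frame(bin = 20, multiplier = 8)))
  bt <- bin_breakpoint_stats(sim$cohort, sim$tiles,
                             covariates = sim$covariates)
  hs1 <- focal_hotspots(bt, density_quantile = 1)
  # add more counts to the implanted bin for every patient
  cnt <- attr(bt, "counts")
  cnt[20, ] <- cnt[20, ] + 10L
  bt2 <- bt
  attr(bt2, "counts") <- cnt
  bt2$total <- as.integer(rowSums(cnt))
  bt2$recurrence <- as.integer(rowSums(cnt > 0))
  bt2$density <- bt2$total / ncol(cnt)
  hs2 <- focal_hotspots(bt2, density_quantile = 1)
  m1 <- hs1[hs1$bin == 20, c("genomewide", "perchrom")]
  m2 <- hs2[hs2$bin == 20, c("genomewide", "perchrom")]
  expect_true(all(unlist(m1) <= unlist(m2)) ||
                all(unlist(m2) == unlist(m1)))
  if (hs1$consensus[hs1$bin == 20]) {
    expect_true(hs2$consensus[hs2$bin == 20])
  }
})

test_that("merge_bins_to_regions unions overlapping and bookended bins", {
  b <- data.frame(chrom = "chr1", start = c(0, 5e5), end = c(1e6, 1.5e6))
  r <- merge_bins_to_regions(b)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(0, 1.5e6))
  b2 <- data.frame(chrom = c("chr1", "chr2"), start = c(0, 0),
                   end = c(1e6, 1e6))
  expect_equal(nrow(merge_bins_to_regions(b2)), 2)
  # bookended bins merge
  b3 <- data.frame(chrom = "chr1", start = c(0, 1e6), end = c(1e6, 2e6))
  expect_equal(nrow(merge_bins_to_regions(b3)), 1)
  # random toys against a per-base membership oracle
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    s <- sample.int(500, n)
    e <- s + sample.int(120, n)
    rr <- merge_bins_to_regions(data.frame(chrom = "c", start = s, end = e))
    expect_equal(nrow(rr), brute_n_regions(s + 1, e, 1000))
  }
})
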