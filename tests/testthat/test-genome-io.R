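test_that("genome_def validates chromosomes and excluded regions", {
  gd <- genome_def(c("chr1", "chr2"), c(3e6, 2e6))
  expect_equal(genome_length(gd), 5e6)
  expect_error(genome_def(c("chr1", "chr1"), c(1, 2)), "unique")
  expect_error(genome_def("chr1", 0), "positive")
  expect_error(genome_def("chr1", 1e6,
                          excluded = data.frame(chrom = "chr1",
                                                start = 5e5, end = 2e6)),
               "within")
  gd2 <- genome_def("chr1", 1e6,
                    excluded = data.frame(chrom = "chr1", start = 1,
                                          end = 1e4))
  expect_equal(nrow(gd2$excluded), 1)
})

test_that("make_bins follows the tiling rule and flags excluded bins", {
  b1 <- make_bins(genome_def("chr1", 1e6))
  expect_equal(nrow(b1), 1)
  expect_equal(c(b1$start, b1$end), c(0, 1e6))
  b2 <- make_bins(genome_def(c("c1", "c2"), c(3e6, 2e6)))
  expect_equal(nrow(b2), 8)          # 5 + 3
  expect_equal(b2$bin, 1:8)          # globally unique indices
  expect_equal(b2$start[b2$chrom == "c1"], seq(0, 2e6, by = 5e5))
  # truncated tail bin when full bins stop short of the chromosome end
  b3 <- make_bins(genome_def("c1", 2.3e6))
  expect_equal(b3$end[nrow(b3)], 2.3e6)
  expect_error(make_bins(genome_def("c1", 1e6), width = 1e5, step = 2e5),
               "width >= step")
  gd <- genome_def("chr1", 3e6,
                   excluded = data.frame(chrom = "chr1", start = 1.2e6,
                                         end = 1.3e6))
  be <- make_bins(gd)
  expect_true(all(be$excluded[be$start < 1.3e6 & be$end > 1.2e6]))
})

test_that("make_bins covers every base; interior bases covered exactly twice", {
  gd <- genome_def(c("a", "b"), c(3.7e6, 2.2e6))
  bins <- make_bins(gd, width = 1e6, step = 5e5)
  for (ch in gd$chroms) {
    L <- gd$lengths[[ch]]
    bb <- bins[bins$chrom == ch, ]
    probe <- c(1, seq(1, L, by = 9973), L)  # 1-based positions
    cov <- vapply(probe, function(p) sum(bb$start < p & p <= bb$end),
                  numeric(1))
    expect_true(all(cov >= 1))
    interior <- probe > 1e6 & probe <= max(bb$start)
    expect_true(all(cov[interior] == 2))
  }
})

test_that("classify_sv_type maps junction geometry and is swap-invariant", {
  expect_equal(classify_sv_type("chr1", "+", "chr2", "-"), "BND")
  expect_equal(classify_sv_type("chr1", "+", "chr1", "-"), "DEL")
  expect_equal(classify_sv_type("chr1", "-", "chr1", "+"), "DUP")
  expect_equal(classify_sv_type("chr1", "+", "chr1", "+"), "INV")
  expect_equal(classify_sv_type("chr1", "-", "chr1", "-"), "INV")
  # swapping breakend order before normalisation gives the same type
  set.seed(1)
  for (i in 1:25) {
    pos <- sort(sample.int(1e6, 2))
    st <- sample(c("+", "-"), 2, replace = TRUE)
    a <- sv_calls(make_call("x", "P", "chr1", pos[1], st[1],
                            "chr1", pos[2], st[2]))
    b <- sv_calls(make_call("x", "P", "chr1", pos[2], st[2],
                            "chr1", pos[1], st[1]))
    expect_equal(a$svtype, b$svtype)
    expect_equal(a$pos1, b$pos1)
  }
})

test_that("sv_calls normalises breakends and validates against the genome", {
  gd <- toy_genome()
  expect_error(sv_calls(make_call("a", "P", "chr9", 1, "+", "chr1", 2, "-"),
                        genome = gd), "unknown chromosome")
  expect_error(sv_calls(make_call("a", "P", "chr1", 0, "+", "chr1", 2, "-"),
                        genome = gd), "outside")
  expect_error(sv_calls(rbind(simple_del("a", "P", "chr1", 1, 10),
                              simple_del("a", "P", "chr1", 5, 20))),
               "unique")
  x <- sv_calls(make_call("a", "P", "chr2", 10, "-", "chr1", 5, "+"),
                genome = gd)
  expect_equal(x$chrom1, "chr1")    # ordered by genome chromosome order
  expect_equal(x$svtype, "BND")
  expect_true(is.na(x$span))
})

test_that("read_sv_bedpe parses the dialect and converts coordinates", {
  f <- withr::local_tempfile()
  writeLines(character(), f)
  expect_equal(nrow(read_sv_bedpe(f)), 0)

  writeLines("chr1\t99\t100\tchr1\t5099\t5100\tsv1\t.\t+\t-\tP1\tDEL", f)
  x <- read_sv_bedpe(f)
  expect_equal(nrow(x), 1)
  expect_equal(x$svtype, "DEL")
  expect_equal(x$span, 5000)
  expect_equal(c(x$pos1, x$pos2), c(100, 5100))

  writeLines(c("chr1\t99\t100\tchr1\t5099\t5100\tsv1\t.\t+\t-\tP1\tDEL",
               "chr2\t199\t200\tchr2\t999\t1000\tsv2\t.\t-\t+\tP1\tDUP",
               "chr1\t49\t50\tchr2\t69\t70\tsv3\t.\t+\t-\tP2\t."), f)
  x <- read_sv_bedpe(f)
  expect_equal(nrow(x), 3)
  expect_equal(sum(x$svtype == "BND"), 1)

  writeLines("chr1\t99\t100\tchr1", f)
  expect_error(read_sv_bedpe(f), "line 1")
  writeLines(c("chr1\t99\t100\tchr1\t5099\t5100\tsv1\t.\t+\t-\tP1\tDEL",
               "chrUn\t9\t10\tchrUn\t99\t100\tsv2\t.\t+\t-\tP1\tDEL"), f)
  expect_warning(x <- read_sv_bedpe(f, genome = toy_genome()), "rejected")
  expect_equal(nrow(x), 1)
  expect_equal(attr(x, "rejected"), 2L)
})

test_that("BEDPE round trip is the identity on well-formed records", {
  set.seed(7)
  gd <- toy_genome()
  n <- 40
  chrom1 <- sample(gd$chroms, n, replace = TRUE)
  chrom2 <- sample(gd$chroms, n, replace = TRUE)
  calls <- sv_calls(data.frame(
    call_id = paste0("c", 1:n), patient = sample(c("P1", "P2"), n, TRUE),
    chrom1 = chrom1, pos1 = sample.int(9e5, n), strand1 = sample(c("+", "-"), n, TRUE),
    chrom2 = chrom2, pos2 = sample.int(9e5, n), strand2 = sample(c("+", "-"), n, TRUE),
    stringsAsFactors = FALSE), genome = gd)
  f <- withr::local_tempfile()
  write_sv_bedpe(calls, f)
  back <- read_sv_bedpe(f, genome = gd)
  expect_equal(as.data.frame(back), as.data.frame(calls),
               ignore_attr = TRUE)
})

test_that("read_regions and read_gene_models use BED conventions", {
  f <- withr::local_tempfile()
  writeLines("chr1\t0\t100", f)
  r <- read_regions(f)
  expect_equal(c(r$start, r$end), c(1, 100))
  writeLines(character(), f)
  expect_equal(nrow(read_regions(f)), 0)

  # BED12 with 3 blocks -> 3 exons (block arithmetic checked by hand)
  writeLines("chr1\t999\t2100\tG1|T1\t0\t+\t999\t2100\t0\t3\t50,60,100\t0,500,1001",
             f)
  gm <- read_gene_models(f, cancer_genes = "G1")
  expect_equal(nrow(gm), 3)
  expect_equal(gm$exon_start, c(1000, 1500, 2001))
  expect_equal(gm$exon_end, c(1049, 1559, 2100))
  expect_true(all(gm$cancer))
  expect_equal(gm$transcript[1], "T1")
})

test_that("read_matrix round-trips write_matrix", {
  m <- matrix(c(1.5, 2, 0, 7), 2, 2,
              dimnames = list(c("r1", "r2"), c("s1", "s2")))
  f <- withr::local_tempfile()
  write_matrix(m, f)
  expect_equal(read_matrix(f), m)
})

test_that("read_sv_vcf pairs MATEID breakends and rejects unpaired records", {
  f <- withr::local_tempfile()
  writeLines(c("##fileformat=VCFv4.1",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\tbnd_1\tN\tN[chr2:5000[\t.\tPASS\tSVTYPE=BND;MATEID=bnd_2",
               "chr2\t5000\tbnd_2\tN\t]chr1:100]N\t.\tPASS\tSVTYPE=BND;MATEID=bnd_1",
               "chr1\t900\tbnd_x\tN\tN[chr1:2000[\t.\tPASS\tSVTYPE=BND"), f)
  expect_warning(v <- read_sv_vcf(f, patient = "P9"), "rejected")
  expect_equal(nrow(v), 1)
  expect_equal(v$svtype, "BND")
  expect_equal(c(v$pos1, v$pos2), c(100, 5000))
  expect_equal(c(v$strand1, v$strand2), c("+", "-"))
  expect_equal(attr(v, "rejected"), "bnd_x")
})

test_that("filter_panel flags by type, chromosome pair and both breakends", {
  call <- sv_calls(simple_del("c1", "P1", "chr1", 1000, 2000))
  expect_false(filter_panel(call, NULL)$blacklisted)
  panel <- simple_del("p1", "panel", "chr1", 1250, 2100)
  expect_true(filter_panel(call, panel, 300)$blacklisted)
  expect_false(filter_panel(call, panel, 100)$blacklisted)
  # type must match
  panel_dup <- make_call("p2", "panel", "chr1", 1250, "-", "chr1", 2100, "+")
  expect_false(filter_panel(call, panel_dup, 300)$blacklisted)
  expect_error(filter_panel(call, panel, -1), "non-negative")
})

test_that("filter_panel flags are monotone in the window", {
  set.seed(3)
  gd <- toy_genome()
  calls <- sv_calls(do.call(rbind, lapply(1:30, function(i)
    simple_del(paste0("c", i), "P", "chr1", i * 3e4, i * 3e4 + 5e3))))
  panel <- do.call(rbind, lapply(1:10, function(i)
    simple_del(paste0("p", i), "x", "chr1", i * 9e4 + sample.int(500, 1),
               i * 9e4 + 5e3 + sample.int(500, 1))))
  prev <- rep(FALSE, nrow(calls))
  for (w in c(0, 100, 300, 600, 1200)) {
    cur <- filter_panel(calls, panel, w)$blacklisted
    expect_true(all(prev[cur == FALSE] == FALSE))
    expect_true(all(cur[prev] == TRUE))   # superset of smaller window
    prev <- cur
  }
})

test_that("match_callsets metrics follow the greedy one-to-one contract", {
  b <- sv_calls(do.call(rbind, lapply(1:5, function(i)
    simple_del(paste0("b", i), "P", "chr1", i * 1e4, i * 1e4 + 4e3))))
  for (w in c(0, 10, 300)) {
    m <- match_callsets(b, b, w)
    expect_equal(c(m$precision, m$sensitivity, m$f1), c(1, 1, 1))
  }
  # A = 4 of B's 5 calls plus one spurious -> precision = sensitivity = 0.8
  a <- sv_calls(rbind(as.data.frame(b)[1:4, 1:9],
                      simple_del("spur", "P", "chr2", 5e5, 6e5)))
  m <- match_callsets(a, b)
  expect_equal(m$matched, 4)
  expect_equal(m$precision, 0.8)
  expect_equal(m$sensitivity, 0.8)
  # strict window: 1-bp jitter, window 0 -> nothing matches
  jit <- b
  jit$pos1 <- jit$pos1 + 1
  m0 <- match_callsets(sv_calls(as.data.frame(jit)[, 1:9]), b, 0)
  expect_equal(m0$matched, 0)
  # both empty -> all metrics 1 by convention
  e <- sv_calls(as.data.frame(b)[0, 1:9])
  me <- match_callsets(e, e)
  expect_equal(c(me$precision, me$sensitivity, me$f1), c(1, 1, 1))
})

test_that("drop_excluded_calls removes breakends in excluded regions", {
  gd <- genome_def("chr1", 1e6,
                   excluded = data.frame(chrom = "chr1", start = 4e5,
                                         end = 5e5))
  calls <- sv_calls(rbind(simple_del("a", "P", "chr1", 1e3, 2e3),
                          simple_del("b", "P", "chr1", 4.5e5, 6e5)))
  kept <- drop_excluded_calls(calls, gd)
  expect_equal(kept$call_id, "a")
})
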