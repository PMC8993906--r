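#!/usr/bin/env Rscript
# Stage 5 -- driver-gene recurrence from SV spans.
#
# Converts calls to genomic spans, narrows the focal hotspot regions to
# cancer-census genes with direct exon hits, profiles the implanted driver
# gene by footprint class and SV type, and tests whether adding SV hits
# raises each gene's recurrence over a background alteration table
# (two-proportion z-test, alternative = greater, BH-corrected).

suppressPackageStartupMessages(library(svscape))

out <- "results/drivers"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(20260919L)

genome <- genome_def(c("chr1", "chr2", "chr3"), c(8e7, 6e7, 6e7))
calls <- sv_calls(utils::read.delim("results/footprints/calls_clustered.tsv"))
cohort <- sv_cohort(calls)
gene_models <- utils::read.delim("results/cohort/gene_models.tsv")
regions <- utils::read.delim("results/hotspots/focal_regions.tsv")

spans <- sv_spans(cohort$calls, genome = genome)
hits <- gene_hits(spans, gene_models)

cand <- candidate_driver_filter(regions, gene_models,
                                fragile_regions = NULL, spans = spans)
message(sprintf("candidate drivers in hotspot regions: %s",
                if (nrow(cand)) paste(cand$gene, collapse = ", ") else "none"))

# recurrence with vs without SVs; the without-SV alteration table emulates
# SNV/indel/CN calls hitting a background fraction of patients
n <- length(cohort$patients)
tally <- data.frame(gene = unique(gene_models$gene))
tally$without <- rbinom(nrow(tally), n, 0.10)
with_sv <- colSums(hits)[tally$gene]
tally$with <- pmin(n, tally$without +
                     ifelse(is.na(with_sv), 0, with_sv))
test <- recurrence_test(tally, cohort_size = n)
for (i in seq_len(nrow(test))) {
  message(sprintf("%-6s %s -> %s with SVs (p = %.3g, q = %.3g)",
                  test$gene[i], format_percent(test$without[i], n),
                  format_percent(test$with[i], n), test$p[i], test$q[i]))
}

prof <- gene_sv_profile("TSG1", cohort, gene_models)
message(sprintf("TSG1 profile: %d simple / %d complex SVs",
                sum(prof$n[prof$class == "simple"]),
                sum(prof$n[prof$class == "complex"])))

groups <- utils::read.delim("results/signatures/patient_groups.tsv")
g1 <- groups$patient[groups$group == 1]
g2 <- groups$patient[groups$group == 2]
enr <- if (length(g1) && length(g2)) {
  tiles <- utils::read.delim("results/cohort/tiles.tsv")
  bt <- bin_breakpoint_stats(cohort, tiles)
  rs_group_bin_enrichment(bt, g1, g2, min_diff = 0.15)
} else data.frame()
message(sprintf("bins enriched in group 1 vs 2 (>=15%% difference): %d",
                nrow(enr)))

write_tsv(cand, file.path(out, "candidate_drivers.tsv"))
write_tsv(test, file.path(out, "recurrence_test.tsv"))
write_tsv(prof, file.path(out, "tsg1_profile.tsv"))
if (nrow(enr)) write_tsv(enr, file.path(out, "group_enriched_bins.tsv"))
message("wrote ", out)
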