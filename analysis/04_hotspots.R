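#!/usr/bin/env Rscript
# Stage 4 -- binned breakpoint statistics, context model, focal consensus.
#
# Tiles the genome into 1 Mb bins with 500 kb overlap, counts breakpoints
# per bin and patient, fits the negative-binomial genomic-context model of
# recurrence, runs the three-method focal scan on the non-overlapping tiles,
# and checks the implanted hotspot tiles against the consensus calls.

suppressPackageStartupMessages(library(svscape))

out <- "results/hotspots"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- genome_def(c("chr1", "chr2", "chr3"), c(8e7, 6e7, 6e7))
calls <- sv_calls(utils::read.delim("results/footprints/calls_clustered.tsv"))
cohort <- sv_cohort(calls)
tiles <- utils::read.delim("results/cohort/tiles.tsv")
covariates <- utils::read.delim("results/cohort/covariates.tsv")
truth <- utils::read.delim("results/cohort/truth_hotspots.tsv")

# overlapping 1 Mb / 500 kb bins for the recurrence/density landscape
bins <- make_bins(genome)
bt_overlap <- bin_breakpoint_stats(cohort, bins)
write_tsv(as.data.frame(bt_overlap), file.path(out, "bin_stats_overlap.tsv"))

# context model + focal scan on the simulation tiles (covariates live there)
bt <- bin_breakpoint_stats(cohort, tiles, covariates = covariates)
ctx <- fit_context_model(bt)
message(sprintf("context model (%s): %d/%d bins beyond 2 SD", ctx$family,
                sum(ctx$significant), nrow(bt)))

hs <- focal_hotspots(bt, density_quantile = 1)
regions <- attr(hs, "regions")
message(sprintf("focal consensus: %d bins in %d regions",
                sum(hs$consensus), nrow(regions)))
found <- intersect(truth$bin, hs$bin[hs$consensus])
message(sprintf("implanted hotspots recovered: %d/%d (%s)", length(found),
                nrow(truth), paste(found, collapse = ", ")))

ctx_out <- data.frame(bin = bt$bin, fitted = ctx$fitted,
                      std_residual = ctx$residuals,
                      significant = ctx$significant)
write_tsv(ctx_out, file.path(out, "context_model.tsv"))
write_tsv(data.frame(term = names(ctx$coefficients),
                     estimate = unname(ctx$coefficients),
                     se = unname(ctx$se)),
          file.path(out, "context_coefficients.tsv"))
write_tsv(as.data.frame(hs), file.path(out, "focal_bins.tsv"))
write_tsv(regions, file.path(out, "focal_regions.tsv"))
message("wrote ", out)
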