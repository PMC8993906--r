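#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic study cohort.
#
# Builds a desk-scale cohort of 100 tumours on a 200 Mb three-chromosome
# genome: breakpoint counts follow the log-linear negative-binomial covariate
# model, three hotspot tiles carry a 10x rate multiplier, a cancer-census
# tumour-suppressor gene ("TSG1") is deleted across one exon in 25% of
# patients, and LINE-1 mobile-element insertions are implanted with the
# solo/partnered/orphan class mix. All downstream stages read the files this
# stage writes under results/cohort/.

suppressPackageStartupMessages(library(svscape))

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260919L

genome <- genome_def(c("chr1", "chr2", "chr3"), c(8e7, 6e7, 6e7))
gene_models <- data.frame(
  gene = c("TSG1", "ONC1", "PASS1"),
  transcript = c("T1", "T2", "T3"),
  chrom = c("chr1", "chr2", "chr3"),
  strand = c("+", "-", "+"),
  exon_start = c(5.02e7, 3.01e7, 1.55e7),
  exon_end = c(5.021e7, 3.012e7, 1.551e7),
  cancer = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)

params <- sim_params(
  n_patients = 100, genome = genome, seed = seed,
  hotspots = data.frame(bin = c(51, 110, 170), multiplier = 10),
  drivers = data.frame(gene = "TSG1", svtype = "DEL", fraction = 0.25),
  gene_models = gene_models,
  me = me_params())

sim <- simulate_cohort(params)

message(sprintf("cohort: %d patients, %d SV calls, %d ME insertions",
                length(sim$cohort$patients), nrow(sim$cohort$calls),
                nrow(sim$truth$me_insertions)))

write_sv_bedpe(sim$cohort$calls, file.path(out, "calls.bedpe"))
write_tsv(sim$tiles, file.path(out, "tiles.tsv"))
write_tsv(sim$covariates, file.path(out, "covariates.tsv"))
write_tsv(sim$truth$me_insertions, file.path(out, "me_insertions.tsv"))
write_tsv(data.frame(gene = names(sim$truth$driver_patients),
                     patients = vapply(sim$truth$driver_patients,
                                       paste, character(1), collapse = ",")),
          file.path(out, "truth_drivers.tsv"))
write_tsv(data.frame(bin = sim$truth$hotspot_bins),
          file.path(out, "truth_hotspots.tsv"))
write_tsv(gene_models, file.path(out, "gene_models.tsv"))
write_tsv(data.frame(param = c("seed", "n_patients", "dispersion"),
                     value = c(seed, 100, params$dispersion)),
          file.path(out, "params.tsv"))
message("wrote ", out)
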