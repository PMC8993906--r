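#!/usr/bin/env Rscript
# Stage 2 -- footprint clustering and mobile-element annotation.
#
# Reads the simulated cohort from results/cohort/, annotates BNDs whose
# breakends coincide with poly-A-positive LINE-1 insertion sites, clusters
# each tumour's SVs into footprints, classifies them simple/complex/ME, and
# summarises the ME landscape (per-tumour burden, class shares, fraction of
# clusters with ME evidence).

suppressPackageStartupMessages(library(svscape))

cdir <- "results/cohort"
out <- "results/footprints"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- genome_def(c("chr1", "chr2", "chr3"), c(8e7, 6e7, 6e7))
calls <- read_sv_bedpe(file.path(cdir, "calls.bedpe"), genome = genome)
cohort <- sv_cohort(calls)
insertions <- utils::read.delim(file.path(cdir, "me_insertions.tsv"))

ins <- filter_polya(insertions)
message(sprintf("%d/%d insertions retain the poly-A tail", nrow(ins),
                nrow(insertions)))
cohort$calls <- annotate_me(cohort$calls, ins)
cohort <- cluster_cohort(cohort, genome, alpha = 0.05)
clusters <- classify_clusters(cohort$calls)
cohort$calls <- attr(clusters, "calls")

tab <- table(clusters$class)
message(sprintf("footprints: %s",
                paste(names(tab), as.integer(tab), collapse = ", ")))

me_sum <- summarize_me(ins, patients = cohort$patients)
message(sprintf("ME inserts per tumour: median %g (IQR %g-%g)",
                me_sum$median, me_sum$iqr[1], me_sum$iqr[2]))
print(me_sum$class_table)

ov <- me_cluster_overlap(clusters, cohort$calls, ins)
message(sprintf("%s (%d/%d) of footprint clusters overlap ME insertions",
                format_percent(ov$n_insertion, ov$n_clusters),
                ov$n_insertion, ov$n_clusters))

write_tsv(clusters, file.path(out, "clusters.tsv"))
write_sv_bedpe(cohort$calls, file.path(out, "calls_annotated.bedpe"))
write_tsv(data.frame(patient = cohort$patients,
                     cluster = cohort$calls$cluster[
                       match(cohort$patients, cohort$calls$patient)]),
          file.path(out, "first_cluster_by_patient.tsv"))
write_tsv(me_sum$class_table, file.path(out, "me_class_table.tsv"))
write_tsv(data.frame(metric = c("median_inserts", "iqr_lo", "iqr_hi",
                                "clusters_total", "clusters_me_overlap"),
                     value = c(me_sum$median, me_sum$iqr, ov$n_clusters,
                               ov$n_insertion)),
          file.path(out, "me_summary.tsv"))
# cluster classes are needed downstream; persist the per-call table
write_tsv(as.data.frame(cohort$calls), file.path(out, "calls_clustered.tsv"))
message("wrote ", out)
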