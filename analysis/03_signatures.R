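#!/usr/bin/env Rscript
# Stage 3 -- rearrangement catalogue, NMF signatures, patient grouping.
#
# Builds the 32-channel type x size x clustering catalogue from the
# clustered calls, extracts signatures by multiplicative-update NMF over a
# rank scan, matches them to a reference built from the simulation's channel
# composition, groups patients by consensus clustering of exposures, and
# tests one orthogonal feature (ME insert burden) for association with each
# signature's presence.

suppressPackageStartupMessages(library(svscape))

out <- "results/signatures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260919L

calls <- sv_calls(utils::read.delim("results/footprints/calls_clustered.tsv"))
cohort <- sv_cohort(calls)
catalogue <- build_catalogue(cohort)
message(sprintf("catalogue: %d SVs over %d patients", sum(catalogue),
                ncol(catalogue)))

sig <- extract_signatures(catalogue, kmin = 2, kmax = 6, iters = 500,
                          replicates = 10, seed = seed)
message(sprintf("chosen k = %d (cophenetic %.3f, silhouette %.3f)", sig$k,
                sig$scores$cophenetic[sig$scores$k == sig$k],
                sig$scores$silhouette[sig$scores$k == sig$k]))

groups <- consensus_group(sig, Kmax = 6, resamples = 300, seed = seed)
message(sprintf("patient groups: K = %d (mean consensus %.3f)", groups$K,
                max(groups$scores$mean_consensus)))

presence <- signature_presence(sig)
ins <- utils::read.delim("results/cohort/me_insertions.tsv")
me_burden <- as.integer(table(factor(ins$patient,
                                     levels = cohort$patients)))
features <- data.frame(me_inserts = me_burden)
assoc <- associate_features(presence, features)
print(assoc$univariate)
stab <- holdout_validate(presence, features, reps = 5, seed = seed)

write_matrix(catalogue, file.path(out, "catalogue.tsv"), label = "channel")
write_matrix(sig$W, file.path(out, "signatures.tsv"), label = "channel")
write_matrix(sig$H, file.path(out, "exposures.tsv"), label = "signature")
write_tsv(sig$scores, file.path(out, "rank_scores.tsv"))
write_tsv(data.frame(patient = names(groups$labels),
                     group = as.integer(groups$labels)),
          file.path(out, "patient_groups.tsv"))
write_tsv(groups$scores, file.path(out, "consensus_scores.tsv"))
write_tsv(assoc$univariate, file.path(out, "assoc_univariate.tsv"))
if (nrow(assoc$multivariate)) {
  write_tsv(assoc$multivariate, file.path(out, "assoc_multivariate.tsv"))
}
if (nrow(stab)) write_tsv(stab, file.path(out, "holdout_stability.tsv"))
message("wrote ", out)
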