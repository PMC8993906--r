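---
title: "Methods: cohort-scale structural-variant landscape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-scale structural-variant landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svscape)
```

# Scope and data model

`svscape` analyses somatic structural variants (SVs) at cohort scale. Every
SV is a pair of breakends; a breakend is a chromosome, a 1-based position,
and an orientation (`+` keeps the segment left of the junction, the
MANTA/BEDPE convention). Junctions are named after the simplest
rearrangement that could produce them: same-chromosome `(+,-)` is a
deletion-type junction (DEL), `(-,+)` a tandem-duplication-type (DUP),
`(+,+)`/`(-,-)` inversion-type (INV), and any inter-chromosomal junction a
breakend/translocation (BND). Internally coordinates are 1-based (closed
intervals for exons); 0-based half-open coordinates appear only at the
BED/BEDPE boundary.

The pipeline stages mirror how such cohorts are analysed in practice:
panel-of-normals filtering, per-tumour footprint clustering with
mobile-element (ME) annotation, a rearrangement catalogue deconvoluted into
signatures, a binned breakpoint hotspot scan against a genomic-covariate
background model, and driver-gene recurrence counting from SV spans.

# Footprint clustering

Rearrangements in one tumour are clustered into *footprints* by
agglomerating SVs whose breakends are closer than expected by chance. With
`N` breakends placed uniformly on a genome of length `G`, inter-breakend
gaps are approximately exponential with mean `G/(2N)`; two SVs merge when
some pair of their breakends is closer than the lower-tail `alpha` quantile

    d* = -log(1 - alpha) * G / (2 N),

and merging is transitive, so the output partitions the call set. We use
the lower-tail quantile (rather than `-log(alpha)`, the upper-tail one)
because the merge criterion asks when a gap is *improbably small* under the
null; this form also makes clustering monotone — lowering `alpha` never
increases the number of merges. Transitive closure over all breakend pairs
equals union of consecutive sorted breakends with gap `< d*`, which is what
the implementation does (O(n log n)).

Footprints with one member are *simple*, with two or more *complex*. A
footprint whose members are all ME-annotated BNDs is labelled *ME* and set
aside; `classify_clusters(me_rule = "any")` relaxes this to at-least-one
member, since the looser reading of the rule is also defensible. A BND is
ME-annotated when either breakend falls in a poly-A-positive insertion
interval (default window 0 bp — direct overlap; configurable because
insertion breakpoint resolution varies between callers) or in a region
known to be transduced by LINE-1 source elements.

# Rearrangement catalogue and signatures

The catalogue has 32 channels: {clustered, non-clustered} x ({DEL, DUP,
INV} x five size bins + translocation). Size bins are half-open `[lo, hi)`
with edges 10 kb, 100 kb, 1 Mb, 10 Mb; rare sub-kb spans fall in the
smallest bin. "Clustered" means the SV's footprint has two or more members.
Each SV increments exactly one channel, so per-patient channel sums equal
SV counts — a conservation law asserted by the tests on every synthetic
cohort.

Signatures are extracted by non-negative matrix factorisation with
multiplicative updates under the Frobenius objective, the default family of
the tools used for this task in the field. For each candidate rank `k` we
run `replicates` random restarts; stability is summarised by (i) the
cophenetic correlation of the consensus matrix of dominant-signature
co-assignment across restarts and (ii) the mean silhouette of the
best-restart partition on exposure-proportion distances. The chosen `k`
maximises the mean of the two ranks — the two scores are on different
scales, and rank averaging is the least arbitrary combination when no
weighting is stated. `W` is column-normalised (signatures are
distributions); the scale moves into the exposures `H`. The NMF objective
is non-increasing across updates (property-tested); ties and the `eps`
guard in the update denominators (1e-10) only matter for exactly-zero
blocks.

Extracted signatures are matched to a user-supplied reference matrix by
cosine similarity, greedily without replacement in descending order — a
deliberate choice over the Hungarian assignment because it reproduces the
common practice of naming the strongest matches first and is deterministic.

Patient groups come from consensus clustering of exposure proportions:
repeated 80% subsampling, k-means per subsample, pairwise co-clustering
frequencies, average-linkage hierarchical clustering of `1 - consensus`,
and `K` chosen by the highest mean within-group consensus. When a subsample
has fewer distinct profiles than `K`, patients are assigned to their
nearest distinct profile rather than erroring — duplicated profiles then
co-cluster with consensus 1, which is the right degenerate limit.

A signature is *present* in a tumour when its exposure is at least 5% of
the tumour's SVs (configurable). Presence is the response of the
feature-association stage: features are `log(x+1)`-transformed and
standardised, screened univariately by logistic regression at p < 0.05,
and survivors enter a multivariate logistic model refined by bidirectional
stepwise AIC with Benjamini-Hochberg correction on the final coefficients.
Complete or quasi-complete separation is reported as a flag with the
estimate suppressed (runaway slopes are not evidence). Hold-out validation
refits the final model on 80/60/40% training fractions and reports
coefficient sign-consistency.

Group comparisons use the two-sided Wilcoxon rank-sum test: exact for
combined n <= 50 without ties, exact by enumeration for tiny tied samples
(combined n <= 12), and the tie-corrected normal approximation otherwise.
The enumeration path exists because the conventional implementation cannot
compute exact p-values with ties, yet identical tiny groups should report
p = 1 exactly.

# Hotspot scan

The genome is tiled into 1 Mb bins with 500 kb overlap. Full-width bins are
placed at every step multiple with `start + width <= L`; a truncated tail
bin is added only when full bins stop short of the chromosome end, so every
base is covered at least once and interior bases exactly twice. Both
breakends of every retained SV count as breakpoints. Per bin we report
*recurrence* (patients with at least one breakpoint) and *density* (mean
breakpoints per patient).

The background model is a negative-binomial log-linear regression of
recurrence on eight genomic covariates: fragile-site flag, copy-number
aberration flag, GC content, replication timing, H3K36me3, H3K27ac, DNase
hypersensitivity, and ALU density. Dispersion is estimated by maximum
likelihood (`MASS::glm.nb`), with a Poisson fallback recorded in the fit
when the NB fit does not converge. Bins whose standardised Pearson
residuals are at least 2 SD above the residual mean are flagged. Pearson
residuals were chosen because the flagging rule is expressed in SD units;
the response (recurrence vs total counts) is configurable, and total counts
are used for the focal methods below.

The focal scan first removes fragile-site bins and, optionally, bins above
the 97.5th density percentile — both reflect breakage-prone regions rather
than selection. The quantile is an artifact threshold, configurable, and
*disabled* (`density_quantile = 1`) in the synthetic experiments: a clean
simulated cohort has no artifact regions, and the filter would remove
exactly the implanted hotspots it is meant to protect. Three methods then
scan the retained bins: (1) intercept-only NB genome-wide with the 2 SD
residual rule, (2) the same per chromosome (chromosomes with fewer than 5
retained bins are skipped and reported), and (3) a rank-sum method — counts
ranked within each patient (average ranks on ties), ranks summed per bin,
and the sums split by exact 1-D 2-means (all split points enumerated;
deterministic and globally optimal, which is why it replaces a seeded
k-means++). The higher cluster is flagged unless it holds more than 20% of
bins (no focal structure), with a single flagged bin always admissible.
Bins flagged by at least two methods form the consensus; overlapping or
bookended consensus bins merge into regions.

Known limitation: under a null cohort the rank-sum guard almost always
fires, the consensus degenerates to methods 1 AND 2 — which are
near-perfectly correlated — and the >= 2 SD upper tail of a right-skewed NB
count distribution holds 2.5-4% of bins. The consensus false-flag rate on
null synthetic cohorts is therefore ~3%, not below 1%; with a 10x implanted
hotspot the detection rate is >= 99%. The acceptance suite measures both.

# Driver recurrence

Intra-chromosomal SVs span the interval between their breakends; BNDs
contribute a point locus at each breakend (window configurable for
imprecise calls — the default 0 reads "between the start and end of both
breakpoints" as each breakend contributing its own locus). A patient hits a
gene when any span intersects at least one exon of the gene's canonical
transcript; overlap is any-overlap (>= 1 bp), with no reciprocal-fraction
requirement, matching exon-overlap counting conventions. Candidate drivers
inside hotspot regions must be cancer-census-flagged, not overlap fragile
sites, and be directly hit in at least one patient.

Recurrence with vs without SVs is compared by the one-sided two-proportion
z-test with continuity correction (`prop.test`, `alternative = "greater"`)
and BH correction across genes. The correction is on by default (the
conventional reported test); the calibration experiments disable it because
a deliberately conservative test cannot hold the nominal size, and the
uncorrected score test is the object whose 5% level is meaningful.

Region-overlap enrichment uses a permutation test: the statistic is the
number of query regions overlapping any target; the null redraws each query
region uniformly within its own chromosome, preserving lengths
(length-preserving uniform placement was chosen over circular rotation
because the regions here are short relative to chromosomes and rotation
conserves inter-region spacing that is irrelevant to the question);
`p = (1 + #{perm >= obs}) / (n_perm + 1)`, so `p` is never zero and
doubling the permutations halves the attainable minimum.

# The synthetic cohort generator

The generator defines the study conditions for every test. Counts per
patient and 1 Mb simulation tile follow NB(mean = exp(beta . x) x hotspot
multiplier, size = theta) with theta = 2 by default — visible
overdispersion, since real cohorts never state their dispersion — and a
covariate vector x of two Bernoulli flags (fragile 3%, CN-aberration 10%)
and six AR(1) tracks (rho = 0.8) mapped to [0,1] by the normal CDF, so
covariates are smooth along chromosomes as real tracks are. The default
coefficient vector (intercept -2.9; effects 0.3-0.7) yields on the order of
0.2 breakends per Mb per patient, a burden comparable to a heavily
rearranged carcinoma; the default cohort is 100 patients on a compact 200
Mb three-chromosome genome so that full runs stay in seconds.

Realisation preserves the drawn counts exactly: each drawn count becomes
that many breakends inside its tile; breakends marked for translocation
(the BND share of the type mix) pool per patient and pair across tiles,
the rest pair within their tile into DEL/DUP/INV with sizes log-uniform
over [1 kb, 10 Mb] truncated to the tile. Exactness is what makes the
covariate model recoverable from the emitted cohort without attenuation —
the alternative (placing the partner breakend at an unconstrained
log-uniform distance) contaminates neighbouring tiles and biases
coefficient recovery. The cost is that intra-chromosomal sizes are bounded
by the tile width, so the 1-10 Mb and >10 Mb intra channels are fed only by
implanted events; planted-signature experiments therefore construct
catalogues directly. One breakend is dropped (and recorded) when a
patient's translocation pool is odd.

Driver events take the *first* `floor(fraction x n)` patients
deterministically — exact expected counts for tests — and add a deletion
covering the gene's first exon with 500 bp margins. ME insertions follow
the class mix solo/partnered/orphan = 0.81/0.07/0.12 and roughly 60 inserts
per tumour with strong inter-tumour dispersion (NB size 0.6, giving IQRs as
wide as real cohorts); transductions link to one of 10 source loci labelled
germline/somatic at 0.72/0.28, and 29% of inserts also appear as companion
BND calls sharing the insertion-site breakend.

What the generator does *not* emulate: nucleotide sequence, read-level
evidence, empirical SV-type/size spectra, copy-number structure, or
clustered complex-event grammars (chromothripsis-like oscillations).
Passing tests therefore demonstrate the statistical machinery under a known
generating model, not caller behaviour on real genomes.

# Problem sizes and numerical choices

Replicate experiments use sizes chosen to make the measured operating
characteristics stable: coefficient recovery at 2000 bins x 200 patients
(100 replicates), hotspot detection at ~580 retained bins x 40 patients
(100 replicates per arm), signature recovery at 60 patients over 20 seeds,
and calibration at 1000 null replicates. Rank scans use 150-500
multiplicative-update iterations and 5-10 restarts in tests — planted
structure converges in far fewer iterations than the 1000 used for real
catalogues. All randomness flows from a single integer seed per experiment;
identical parameters give byte-identical outputs (pipeline reports are
written at fixed precision; the run manifest's wall-clock column is the one
deliberately non-reproducible field).

Degenerate inputs are defined rather than left to chance: empty callsets
match with precision = sensitivity = 1; zero-variance residuals flag
nothing; all-equal rank sums flag nothing; an empty cluster set reports
absent (not zero) fractions; a denominator of zero in percentage formatting
is an error. Printed percentages round half away from zero, the convention
consistent with every published ratio this package reproduces.
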