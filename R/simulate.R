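#' Default parameters for the synthetic SV cohort generator
#'
#' Returns the parameter list consumed by [simulate_cohort()]. The defaults
#' describe a desk-scale cancer cohort: a compact multi-chromosome genome,
#' per-patient per-bin breakpoint counts following a log-linear
#' negative-binomial model on eight genomic covariates, an SV-type mix with
#' the deletion/duplication/translocation predominance seen in heavily
#' rearranged adenocarcinomas, optional implanted hotspot bins (rate
#' multipliers), driver deletions hitting exons of named genes in a fixed
#' fraction of patients, and LINE-1 mobile-element insertions with a
#' solo/partnered/orphan class mix of 0.81/0.07/0.12 and roughly 60 inserts
#' per tumour.
#'
#' @param n_patients Number of patients.
#' @param genome A [genome_def()]; default three chromosomes (80/60/60 Mb).
#' @param bin_width Simulation tile width in bp (tiles are non-overlapping).
#' @param beta Named log-scale coefficient vector: `intercept` plus the eight
#'   covariates produced by [gen_covariates()].
#' @param dispersion Negative-binomial size parameter `theta`
#'   (Var = mu + mu^2/theta).
#' @param sv_type_mix Named probabilities for DEL/DUP/INV/BND.
#' @param size_range Intra-chromosomal SV size range in bp (log-uniform,
#'   truncated so both breakends stay within the simulation tile).
#' @param hotspots data.frame(`bin`, `multiplier`) of implanted hotspot tiles
#'   (multipliers > 1).
#' @param drivers data.frame(`gene`, `svtype`, `fraction`) of driver events;
#'   requires `gene_models`.
#' @param gene_models Exon table as from [read_gene_models()] (used by the
#'   driver spec).
#' @param me List of mobile-element parameters (`mean_per_patient`,
#'   `dispersion`, `class_mix`, `polyA_prob`, `source_mix`, `n_sources`,
#'   `companion_prob`); `NULL` disables ME simulation.
#' @param covariate_prevalence Prevalence of the two binary covariate flags.
#' @param seed Integer seed fixing the whole stream.
#' @return Parameter list of class `sim_params`.
#' @export
sim_params <- function(n_patients = 100,
                       genome = genome_def(c("chr1", "chr2", "chr3"),
                                           c(8e7, 6e7, 6e7)),
                       bin_width = 1e6,
                       beta = c(intercept = -2.9, fragile = 0.5, cna = 0.4,
                                gc = 0.7, reptime = 0.5, h3k36me3 = 0.3,
                                h3k27ac = 0.3, dnase = 0.3, alu = 0.4),
                       dispersion = 2,
                       sv_type_mix = c(DEL = 0.35, DUP = 0.25,
                                       INV = 0.10, BND = 0.30),
                       size_range = c(1e3, 1e7),
                       hotspots = NULL,
                       drivers = NULL,
                       gene_models = NULL,
                       me = NULL,
                       covariate_prevalence = c(fragile = 0.03, cna = 0.10),
                       seed = 1) {
  p <- list(n_patients = n_patients, genome = genome, bin_width = bin_width,
            beta = beta, dispersion = dispersion,
            sv_type_mix = sv_type_mix / sum(sv_type_mix),
            size_range = size_range, hotspots = hotspots, drivers = drivers,
            gene_models = gene_models, me = me,
            covariate_prevalence = covariate_prevalence, seed = seed)
  class(p) <- "sim_params"
  p
}

#' Default mobile-element simulation parameters
#' @param mean_per_patient Mean inserts per tumour (default 60).
#' @param dispersion NB size for the per-patient insert count (small values
#'   give the wide inter-tumour spread seen in real cohorts).
#' @param class_mix Named probabilities for solo/partnered/orphan.
#' @param polyA_prob Probability an insert carries the expected poly-A tail.
#' @param source_mix Probabilities that a transduction source element is
#'   germline vs somatic.
#' @param n_sources Number of distinct source-element loci in the cohort.
#' @param companion_prob Probability an insert also appears as a BND pair in
#'   the conventional SV calls.
#' @return List of ME parameters.
#' @export
me_params <- function(mean_per_patient = 60, dispersion = 0.6,
                      class_mix = c(solo = 0.81, partnered = 0.07,
                                    orphan = 0.12),
                      polyA_prob = 0.9,
                      source_mix = c(germline = 0.72, somatic = 0.28),
                      n_sources = 10, companion_prob = 0.29) {
  list(mean_per_patient = mean_per_patient, dispersion = dispersion,
       class_mix = class_mix / sum(class_mix), polyA_prob = polyA_prob,
       source_mix = source_mix / sum(source_mix), n_sources = n_sources,
       companion_prob = companion_prob)
}

#' Generate per-bin genomic covariates
#'
#' Produces the eight-covariate table used by the background model: two
#' binary flags (fragile site, copy-number aberration) drawn at configurable
#' prevalence, and six continuous tracks (GC content, replication timing,
#' H3K36me3, H3K27ac, DNase hypersensitivity, ALU density) from stationary
#' AR(1) processes along each chromosome mapped to [0, 1] by the normal CDF
#' (marginal mean 0.5).
#'
#' @param bins Bin table from [make_bins()].
#' @param prevalence Named vector, prevalence of `fragile` and `cna` flags.
#' @param ar_rho AR(1) autocorrelation of the continuous tracks.
#' @param seed Optional integer seed.
#' @return data.frame with `bin` plus columns `fragile`, `cna`, `gc`,
#'   `reptime`, `h3k36me3`, `h3k27ac`, `dnase`, `alu`.
#' @export
gen_covariates <- function(bins, prevalence = c(fragile = 0.03, cna = 0.10),
                           ar_rho = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(bins)
  ar_track <- function() {
    z <- numeric(n)
    for (ch in unique(bins$chrom)) {
      idx <- which(bins$chrom == ch)
      e <- stats::rnorm(length(idx))
      zc <- numeric(length(idx))
      zc[1] <- e[1]
      if (length(idx) > 1) {
        for (t in 2:length(idx)) {
          zc[t] <- ar_rho * zc[t - 1] + sqrt(1 - ar_rho^2) * e[t]
        }
      }
      z[idx] <- zc
    }
    stats::pnorm(z)
  }
  out <- data.frame(
    bin = bins$bin,
    fragile = stats::rbinom(n, 1, prevalence[["fragile"]]),
    cna = stats::rbinom(n, 1, prevalence[["cna"]]),
    gc = ar_track(), reptime = ar_track(), h3k36me3 = ar_track(),
    h3k27ac = ar_track(), dnase = ar_track(), alu = ar_track())
  out
}

#' Covariate column names used by the background model
#' @return Character vector of the eight covariate names.
#' @export
covariate_names <- function() {
  c("fragile", "cna", "gc", "reptime", "h3k36me3", "h3k27ac", "dnase", "alu")
}

#' Simulate an SV cohort with known ground truth
#'
#' Draws, for every patient and non-overlapping simulation tile, a breakpoint
#' count from NB(mean = exp(beta . x) x hotspot multiplier, size =
#' dispersion) and realises exactly that many breakends inside the tile:
#' breakends marked for translocation (probability = the BND share of the
#' type mix) are pooled per patient and paired across tiles into BND calls,
#' the rest are paired within their tile into DEL/DUP/INV calls with sizes
#' log-uniform over the configured range truncated to the tile. Per-tile
#' realised breakend counts therefore equal the NB draws exactly (up to one
#' breakend dropped per patient when the translocation pool is odd), so the
#' covariate model is exactly recoverable from the emitted cohort. Driver
#' events add exon-overlapping deletions of the named genes for the first
#' `floor(fraction x n)` patients; the ME spec adds insertion records and
#' companion BND calls via [gen_me_insertions()].
#'
#' @param params A [sim_params()] list.
#' @return List with `cohort` ([sv_cohort()]), `tiles` (simulation bins),
#'   `covariates`, and `truth` (list: `beta`, `expected_rate` per tile,
#'   `counts` drawn bin-by-patient matrix, `hotspot_bins`, `driver_patients`,
#'   `me_insertions`, `dropped_breakends`).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  genome <- params$genome
  tiles <- make_bins(genome, width = params$bin_width,
                     step = params$bin_width)
  covs <- gen_covariates(tiles, prevalence = params$covariate_prevalence,
                         seed = params$seed)
  set.seed(params$seed + 1L)
  X <- as.matrix(covs[, covariate_names()])
  beta <- params$beta
  stopifnot(identical(names(beta), c("intercept", covariate_names())))
  log_mu <- beta[["intercept"]] + drop(X %*% beta[-1])
  mult <- rep(1, nrow(tiles))
  if (!is.null(params$hotspots) && nrow(params$hotspots) > 0) {
    if (any(!(params$hotspots$bin %in% tiles$bin))) {
      stop("hotspot bin id outside the genome tiling")
    }
    if (any(params$hotspots$multiplier <= 1)) {
      stop("hotspot multipliers must exceed 1")
    }
    mult[match(params$hotspots$bin, tiles$bin)] <- params$hotspots$multiplier
  }
  mu <- exp(log_mu) * mult
  npat <- params$n_patients
  ntile <- nrow(tiles)
  counts <- matrix(stats::rnbinom(ntile * npat, mu = rep(mu, npat),
                                  size = params$dispersion),
                   nrow = ntile, ncol = npat)
  patients <- sprintf("P%03d", seq_len(npat))
  dimnames(counts) <- list(tiles$bin, patients)

  mix <- params$sv_type_mix
  intra_mix <- mix[c("DEL", "DUP", "INV")]
  intra_mix <- if (sum(intra_mix) > 0) intra_mix / sum(intra_mix) else
    c(DEL = 1, DUP = 0, INV = 0)
  calls_list <- vector("list", npat)
  dropped <- 0L
  for (p in seq_len(npat)) {
    cnt <- counts[, p]
    tot <- sum(cnt)
    if (tot == 0) { calls_list[[p]] <- NULL; next }
    tile_of <- rep.int(seq_len(ntile), cnt)
    pos <- floor(stats::runif(tot, tiles$start[tile_of], tiles$end[tile_of])) + 1
    is_bnd <- stats::runif(tot) < mix[["BND"]]
    # pair non-translocation breakends within their tile
    intra_rows <- list()
    pool <- which(is_bnd)
    for (tl in unique(tile_of[!is_bnd])) {
      idx <- which(tile_of == tl & !is_bnd)
      if (length(idx) %% 2 == 1) {
        pool <- c(pool, idx[length(idx)])
        idx <- idx[-length(idx)]
      }
      if (length(idx) == 0) next
      idx <- sample(idx)
      a <- idx[seq(1, length(idx), by = 2)]
      b <- idx[seq(2, length(idx), by = 2)]
      # re-place b at a log-uniform distance from a, inside the tile
      lo <- log(params$size_range[1])
      hi <- log(pmax(params$size_range[1] + 1,
                     pmin(params$size_range[2], tiles$end[tl] - pos[a])))
      size <- floor(exp(stats::runif(length(a), lo, pmax(lo + 1e-9, hi))))
      size <- pmax(1, pmin(size, tiles$end[tl] - pos[a]))
      typ <- sample(names(intra_mix), length(a), replace = TRUE,
                    prob = intra_mix)
      s1 <- ifelse(typ == "DEL", "+", ifelse(typ == "DUP", "-",
                   sample(c("+", "-"), length(a), replace = TRUE)))
      s2 <- ifelse(typ == "DEL", "-", ifelse(typ == "DUP", "+", s1))
      intra_rows[[as.character(tl)]] <- data.frame(
        chrom1 = tiles$chrom[tl], pos1 = pos[a], strand1 = s1,
        chrom2 = tiles$chrom[tl], pos2 = pos[a] + size, strand2 = s2,
        svtype = typ, stringsAsFactors = FALSE)
    }
    # pair pooled breakends across tiles (translocation-like)
    bnd_rows <- NULL
    if (length(pool) > 1) {
      pool <- sample(pool)
      if (length(pool) %% 2 == 1) {
        dropped <- dropped + 1L
        pool <- pool[-length(pool)]
      }
      a <- pool[seq(1, length(pool), by = 2)]
      b <- pool[seq(2, length(pool), by = 2)]
      same <- tiles$chrom[tile_of[a]] == tiles$chrom[tile_of[b]]
      s1 <- sample(c("+", "-"), length(a), replace = TRUE)
      s2 <- sample(c("+", "-"), length(a), replace = TRUE)
      bnd_rows <- data.frame(
        chrom1 = tiles$chrom[tile_of[a]], pos1 = pos[a], strand1 = s1,
        chrom2 = tiles$chrom[tile_of[b]],
        pos2 = pos[b] + ifelse(same & pos[a] == pos[b], 1, 0), strand2 = s2,
        svtype = NA_character_, stringsAsFactors = FALSE)
    } else if (length(pool) == 1) {
      dropped <- dropped + 1L
    }
    df <- do.call(rbind, c(intra_rows, list(bnd_rows)))
    if (is.null(df) || nrow(df) == 0) next
    df$pos2 <- pmin(df$pos2, genome$lengths[df$chrom2])
    eq <- df$chrom1 == df$chrom2 & df$pos1 == df$pos2
    df$pos2[eq] <- df$pos1[eq] + 1
    over <- df$pos2 > genome$lengths[df$chrom2]
    df$pos1[over] <- df$pos1[over] - 1
    df$pos2[over] <- df$pos2[over] - 1
    df$patient <- patients[p]
    calls_list[[p]] <- df
  }
  calls <- do.call(rbind, calls_list)
  if (is.null(calls)) {
    calls <- empty_calls()
  } else {
    calls$call_id <- sprintf("sv%06d", seq_len(nrow(calls)))
    calls$svtype[calls$chrom1 != calls$chrom2] <- "BND"
    calls <- sv_calls(calls, genome = genome)
  }

  driver_patients <- list()
  if (!is.null(params$drivers) && nrow(params$drivers) > 0) {
    if (is.null(params$gene_models)) {
      stop("driver spec requires gene_models")
    }
    extra <- list()
    for (i in seq_len(nrow(params$drivers))) {
      d <- params$drivers[i, ]
      ex <- params$gene_models[params$gene_models$gene == d$gene, ]
      if (nrow(ex) == 0) stop("driver gene not in gene_models: ", d$gene)
      n_aff <- floor(d$fraction * npat)
      aff <- patients[seq_len(n_aff)]
      driver_patients[[d$gene]] <- aff
      if (n_aff == 0) next
      extra[[i]] <- data.frame(
        call_id = sprintf("drv%s_%s", i, seq_len(n_aff)), patient = aff,
        chrom1 = ex$chrom[1], pos1 = pmax(1, ex$exon_start[1] - 500),
        strand1 = "+",
        chrom2 = ex$chrom[1],
        pos2 = pmin(genome$lengths[[ex$chrom[1]]], ex$exon_end[1] + 500),
        strand2 = "-", svtype = d$svtype, stringsAsFactors = FALSE)
    }
    if (length(extra)) {
      calls <- sv_calls(rbind(as.data.frame(calls)[, names(extra[[1]])],
                              do.call(rbind, extra)), genome = genome)
    }
  }

  me_out <- NULL
  if (!is.null(params$me)) {
    me_out <- gen_me_insertions(params, patients = patients,
                                seed = params$seed + 2L)
    if (nrow(me_out$calls) > 0) {
      base_cols <- c("call_id", "patient", "chrom1", "pos1", "strand1",
                     "chrom2", "pos2", "strand2", "svtype")
      calls <- sv_calls(rbind(as.data.frame(calls)[, base_cols],
                              as.data.frame(me_out$calls)[, base_cols]),
                        genome = genome)
    }
  }

  truth <- list(beta = beta, expected_rate = mu, counts = counts,
                hotspot_bins = if (is.null(params$hotspots)) integer() else
                  params$hotspots$bin,
                driver_patients = driver_patients,
                me_insertions = if (is.null(me_out)) NULL else me_out$insertions,
                dropped_breakends = dropped)
  list(cohort = sv_cohort(calls, patients = patients), tiles = tiles,
       covariates = covs, truth = truth)
}

#' Simulate LINE-1 mobile-element insertions and companion BND calls
#'
#' Each insertion gets a class (solo / partnered transduction / orphan
#' transduction), a poly-A flag, and -- for transductions -- a source-element
#' locus labelled germline or somatic. A configurable fraction of insertions
#' also appears in the conventional SV calls as a BND pair sharing a breakend
#' with the insertion site (transductions link to their source locus).
#'
#' @param params A [sim_params()] whose `me` element is a [me_params()] list.
#' @param patients Character vector of patient ids (defaults to
#'   `P001..P<n>`).
#' @param seed Optional integer seed.
#' @return List with `insertions` (data.frame: `patient`, `chrom`, `pos`,
#'   `class`, `source`, `source_chrom`, `source_pos`, `polyA`) and `calls`
#'   (companion BND [sv_calls()]).
#' @export
gen_me_insertions <- function(params, patients = NULL, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  me <- params$me
  if (is.null(me)) stop("params$me is NULL")
  if (!is.null(seed)) set.seed(seed)
  genome <- params$genome
  if (is.null(patients)) {
    patients <- sprintf("P%03d", seq_len(params$n_patients))
  }
  stopifnot(abs(sum(me$class_mix) - 1) < 1e-8)
  src <- data.frame(
    chrom = sample(genome$chroms, me$n_sources, replace = TRUE,
                   prob = genome$lengths / sum(genome$lengths)),
    stringsAsFactors = FALSE)
  src$pos <- floor(stats::runif(me$n_sources, 0, genome$lengths[src$chrom])) + 1
  src$source <- sample(names(me$source_mix), me$n_sources, replace = TRUE,
                       prob = me$source_mix)
  n_per <- stats::rnbinom(length(patients), mu = me$mean_per_patient,
                          size = me$dispersion)
  tot <- sum(n_per)
  if (tot == 0) {
    ins <- data.frame(patient = character(), chrom = character(),
                      pos = numeric(), class = character(),
                      source = character(), source_chrom = character(),
                      source_pos = numeric(), polyA = logical(),
                      stringsAsFactors = FALSE)
    return(list(insertions = ins, calls = empty_calls(), sources = src))
  }
  chrom <- sample(genome$chroms, tot, replace = TRUE,
                  prob = genome$lengths / sum(genome$lengths))
  ins <- data.frame(
    patient = rep(patients, n_per),
    chrom = chrom,
    pos = floor(stats::runif(tot, 0, genome$lengths[chrom])) + 1,
    class = sample(names(me$class_mix), tot, replace = TRUE,
                   prob = me$class_mix),
    polyA = stats::runif(tot) < me$polyA_prob,
    stringsAsFactors = FALSE)
  trans <- ins$class != "solo"
  si <- sample.int(nrow(src), tot, replace = TRUE)
  ins$source <- ifelse(trans, src$source[si], "unknown")
  ins$source_chrom <- ifelse(trans, src$chrom[si], NA_character_)
  ins$source_pos <- ifelse(trans, src$pos[si], NA_real_)
  comp <- which(stats::runif(tot) < me$companion_prob)
  calls <- empty_calls()
  if (length(comp) > 0) {
    partner_chrom <- ifelse(is.na(ins$source_chrom[comp]),
                            sample(genome$chroms, length(comp), replace = TRUE),
                            ins$source_chrom[comp])
    partner_pos <- ifelse(is.na(ins$source_pos[comp]),
                          floor(stats::runif(length(comp), 0,
                                             genome$lengths[partner_chrom])) + 1,
                          ins$source_pos[comp])
    same <- partner_chrom == ins$chrom[comp] & partner_pos == ins$pos[comp]
    partner_pos[same] <- partner_pos[same] + 1
    calls <- sv_calls(data.frame(
      call_id = sprintf("me%05d", seq_along(comp)),
      patient = ins$patient[comp],
      chrom1 = ins$chrom[comp], pos1 = ins$pos[comp],
      strand1 = sample(c("+", "-"), length(comp), replace = TRUE),
      chrom2 = partner_chrom, pos2 = partner_pos,
      strand2 = sample(c("+", "-"), length(comp), replace = TRUE),
      svtype = NA_character_, stringsAsFactors = FALSE), genome = genome)
  }
  list(insertions = ins, calls = calls, sources = src)
}
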