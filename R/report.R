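#' Render a count ratio as a printed percentage
#'
#' Formats `100 * numerator / denominator` rounded half-away-from-zero to
#' `decimals` digits, matching the printed-ratio convention of cohort
#' reports ("59%", "58.2%").
#'
#' @param numerator,denominator Counts (`denominator > 0`).
#' @param decimals Digits after the point (default 0: integer percent).
#' @return Character scalar like `"59%"`.
#' @examples
#' format_percent(1622, 2751) # "59%"
#' @export
format_percent <- function(numerator, denominator, decimals = 0) {
  if (denominator <= 0) stop("denominator must be positive")
  x <- 100 * numerator / denominator
  f <- 10^decimals
  r <- sign(x) * floor(abs(x) * f + 0.5) / f
  paste0(formatC(r, format = "f", digits = decimals), "%")
}

#' Load and validate a pipeline configuration file
#'
#' Reads a flat `key<TAB-or-=>value` text file naming the input files of a
#' run (`sv_bedpe`, and optionally `panel_bedpe`, `insertions_bed`,
#' `transduction_bed`, `gene_models_bed12`, `fragile_bed`, `covariates_tsv`,
#' `cancer_genes`, `reference_signatures_tsv`, `excluded_bed`,
#' `chrom_sizes`) plus numeric parameters (any other key). Every referenced
#' path is checked before anything is loaded, so a missing input fails
#' validation up front.
#'
#' @param path Configuration file.
#' @return A config list suitable for [run_pipeline()].
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  kv <- strsplit(lines, "[=\t]", perl = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  names(vals) <- keys
  path_keys <- intersect(keys, c("sv_bedpe", "panel_bedpe", "insertions_bed",
                                 "transduction_bed", "gene_models_bed12",
                                 "fragile_bed", "covariates_tsv",
                                 "cancer_genes", "reference_signatures_tsv",
                                 "excluded_bed", "chrom_sizes"))
  missing <- path_keys[!file.exists(vals[path_keys])]
  if (length(missing)) {
    stop("config validation: missing input file(s): ",
         paste(sprintf("%s (%s)", missing, vals[missing]), collapse = ", "))
  }
  if (!("chrom_sizes" %in% keys)) stop("config needs 'chrom_sizes'")
  cs <- utils::read.delim(vals[["chrom_sizes"]], header = FALSE)
  excl <- if ("excluded_bed" %in% keys) read_regions(vals[["excluded_bed"]])
  genome <- genome_def(cs[[1]], cs[[2]], excluded = excl)
  if (!("sv_bedpe" %in% keys)) stop("config needs 'sv_bedpe'")
  cfg <- list(genome = genome,
              cohort = sv_cohort(read_sv_bedpe(vals[["sv_bedpe"]], genome)))
  if ("panel_bedpe" %in% keys)
    cfg$panel <- read_sv_bedpe(vals[["panel_bedpe"]])
  if ("insertions_bed" %in% keys) {
    ins <- read_regions(vals[["insertions_bed"]])
    ins$pos <- ins$start
    ins$polyA <- TRUE
    cfg$insertions <- ins
  }
  if ("transduction_bed" %in% keys)
    cfg$transduction_regions <- read_regions(vals[["transduction_bed"]])
  if ("gene_models_bed12" %in% keys) {
    cg <- if ("cancer_genes" %in% keys)
      utils::read.delim(vals[["cancer_genes"]], header = FALSE)[[1]]
    cfg$gene_models <- read_gene_models(vals[["gene_models_bed12"]],
                                        cancer_genes = cg)
  }
  if ("fragile_bed" %in% keys)
    cfg$fragile_regions <- read_regions(vals[["fragile_bed"]])
  if ("covariates_tsv" %in% keys) {
    cfg$covariates <- utils::read.delim(vals[["covariates_tsv"]])
  }
  if ("reference_signatures_tsv" %in% keys) {
    cfg$reference_signatures <- read_matrix(vals[["reference_signatures_tsv"]])
  }
  for (k in setdiff(keys, c(path_keys, "chrom_sizes"))) {
    v <- suppressWarnings(as.numeric(vals[[k]]))
    if (!is.na(v)) cfg[[k]] <- v
  }
  cfg
}

#' Run the full SV analysis pipeline on a simulated or loaded cohort
#'
#' Orchestrates the stages in their methodological order: panel and
#' excluded-region filtering, footprint clustering and ME annotation,
#' catalogue and signature extraction with patient grouping, binned
#' breakpoint statistics with the genomic-context background model and the
#' focal hotspot consensus, and driver-gene recurrence. Each stage writes a
#' TSV report into `out_dir`; a run manifest (parameters, per-stage row
#' counts, timings) is written last. Stages whose outputs exist are skipped
#' when `resume = TRUE`.
#'
#' @param config List with elements: `cohort` ([sv_cohort()]), `genome`
#'   ([genome_def()]), optional `panel`, `insertions`,
#'   `transduction_regions`, `gene_models`, `fragile_regions`, `covariates`,
#'   `reference_signatures`, and parameters `bin_width` (default 1e6),
#'   `bin_step` (default `bin_width / 2`), `alpha` (footprint merge, 0.05),
#'   `kmin`/`kmax`/`nmf_iters`/`nmf_replicates` (signature extraction),
#'   `Kmax`/`resamples` (grouping), `density_quantile`, `seed`.
#' @param out_dir Output directory (created if needed).
#' @param resume Skip stages whose output files already exist.
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the in-memory stage results
#'   (`cohort`, `clusters`, `catalogue`, `signatures`, `groups`, `bintable`,
#'   `context_fit`, `hotspots`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE, quiet = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  stopifnot(is.list(config), !is.null(config$cohort), !is.null(config$genome))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list()
  stamp <- function(stage, n, t_start) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, rows = n,
      seconds = round(proc.time()[["elapsed"]] - t_start, 2))
  }
  seed <- if (is.null(config$seed)) 1L else config$seed
  p <- function(name, default) {
    if (is.null(config[[name]])) default else config[[name]]
  }

  # stage 1: filtering
  t1 <- proc.time()[["elapsed"]]
  cohort <- config$cohort
  calls <- cohort$calls
  if (!is.null(config$panel)) {
    calls <- filter_panel(calls, config$panel, window_bp = p("panel_window", 300))
  }
  calls <- calls[!calls$blacklisted, , drop = FALSE]
  calls <- drop_excluded_calls(calls, config$genome)
  cohort <- sv_cohort(calls, patients = cohort$patients)
  say("filter: %d calls retained", nrow(calls))
  stamp("filter", nrow(calls), t1)
  write_sv_bedpe(cohort$calls, file.path(out_dir, "calls_filtered.bedpe"))

  # stage 2: footprints + ME annotation
  t1 <- proc.time()[["elapsed"]]
  if (!is.null(config$insertions)) {
    ins <- filter_polya(config$insertions)
    cohort$calls <- annotate_me(cohort$calls, ins,
                                config$transduction_regions,
                                window_bp = p("me_window", 0))
  }
  cohort <- cluster_cohort(cohort, config$genome, alpha = p("alpha", 0.05))
  clusters <- classify_clusters(cohort$calls)
  cohort$calls <- attr(clusters, "calls")
  say("footprints: %d clusters (%d simple, %d complex, %d ME)",
      nrow(clusters), sum(clusters$class == "simple"),
      sum(clusters$class == "complex"), sum(clusters$class == "ME"))
  stamp("footprints", nrow(clusters), t1)
  write_tsv(clusters, file.path(out_dir, "footprints.tsv"))

  # stage 3: catalogue, signatures, grouping (resumable: the expensive stage)
  t1 <- proc.time()[["elapsed"]]
  catalogue <- build_catalogue(cohort)
  sig <- NULL; groups <- NULL
  sig_files <- file.path(out_dir, c("signatures.tsv", "exposures.tsv",
                                    "patient_groups.tsv"))
  if (resume && all(file.exists(sig_files))) {
    say("signatures: resumed from cached outputs")
    sig <- list(W = read_matrix(sig_files[1]), H = read_matrix(sig_files[2]))
    grp <- utils::read.delim(sig_files[3])
    groups <- list(K = max(grp$group),
                   labels = stats::setNames(grp$group, grp$patient))
  } else if (ncol(catalogue) >= p("kmax", 6) && sum(catalogue) > 0) {
    sig <- extract_signatures(catalogue, kmin = p("kmin", 2),
                              kmax = p("kmax", 6),
                              iters = p("nmf_iters", 200),
                              replicates = p("nmf_replicates", 10),
                              seed = seed)
    if (!is.null(config$reference_signatures)) {
      sig$assignment <- match_reference(sig, config$reference_signatures)
    }
    groups <- consensus_group(sig, Kmax = p("Kmax", 6),
                              resamples = p("resamples", 200), seed = seed)
    write_matrix(sig$W, file.path(out_dir, "signatures.tsv"),
                 label = "channel")
    write_matrix(sig$H, file.path(out_dir, "exposures.tsv"),
                 label = "signature")
    write_tsv(data.frame(patient = names(groups$labels),
                         group = as.integer(groups$labels)),
              file.path(out_dir, "patient_groups.tsv"))
    say("signatures: k = %d, groups K = %d", sig$k, groups$K)
  }
  write_matrix(catalogue, file.path(out_dir, "catalogue.tsv"),
               label = "channel")
  stamp("signatures", sum(catalogue), t1)

  # stage 4: bins, context model, focal hotspots
  t1 <- proc.time()[["elapsed"]]
  bins <- make_bins(config$genome, width = p("bin_width", 1e6),
                    step = p("bin_step", p("bin_width", 1e6) / 2))
  bintable <- bin_breakpoint_stats(cohort, bins,
                                   covariates = config$covariates,
                                   fragile_regions = config$fragile_regions)
  ctx <- NULL
  if (!is.null(config$covariates) && nrow(bintable) >= 50) {
    ctx <- fit_context_model(bintable)
  }
  hs <- focal_hotspots(bintable,
                       density_quantile = p("density_quantile", 0.975))
  say("hotspots: %d consensus bins, %d regions", sum(hs$consensus),
      nrow(attr(hs, "regions")))
  stamp("hotspots", sum(hs$consensus), t1)
  bt_out <- as.data.frame(bintable)
  if (!is.null(ctx)) {
    bt_out$context_flag <- ctx$significant
  }
  write_tsv(bt_out, file.path(out_dir, "bin_stats.tsv"))
  write_tsv(as.data.frame(hs), file.path(out_dir, "hotspot_bins.tsv"))
  write_tsv(attr(hs, "regions"), file.path(out_dir, "hotspot_regions.tsv"))

  # stage 5: drivers
  t1 <- proc.time()[["elapsed"]]
  cand <- NULL
  if (!is.null(config$gene_models)) {
    spans <- sv_spans(cohort$calls, bnd_window_bp = p("bnd_window", 0),
                      genome = config$genome)
    cand <- candidate_driver_filter(attr(hs, "regions"), config$gene_models,
                                    config$fragile_regions, spans)
    write_tsv(cand, file.path(out_dir, "candidate_drivers.tsv"))
    say("drivers: %d candidates", nrow(cand))
    stamp("drivers", nrow(cand), t1)
  }

  manifest <- do.call(rbind, manifest)
  manifest$seed <- seed
  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t0, 2)
  write_tsv(manifest, file.path(out_dir, "run_manifest.tsv"))
  invisible(list(cohort = cohort, clusters = clusters, catalogue = catalogue,
                 signatures = sig, groups = groups, bintable = bintable,
                 context_fit = ctx, hotspots = hs, candidates = cand,
                 manifest = manifest))
}
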