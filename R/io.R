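#' Read SV calls from a BEDPE file
#'
#' Expects the 10+-column BEDPE dialect
#' `chrom1 start1 end1 chrom2 start2 end2 name score strand1 strand2`
#' with optional extra columns `patient` and `svtype` (positions 11 and 12,
#' or named in a header line starting with `#`). BEDPE intervals are 0-based
#' half-open; the internal 1-based breakend position is taken as `start + 1`.
#'
#' @param path Path to a BEDPE file (plain text, tab- or space-separated).
#' @param genome Optional [genome_def()]. Records on chromosomes absent from
#'   the genome are rejected and reported via the `"rejected"` attribute and
#'   a warning, not silently dropped.
#' @param patient Fallback patient id used when the file has no patient
#'   column.
#' @return An [sv_calls()] data.frame; attribute `"rejected"` holds rejected
#'   input line numbers (integer, possibly empty).
#' @export
read_sv_bedpe <- function(path, genome = NULL, patient = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  header <- grepl("^#", lines)
  body <- which(!header & nzchar(trimws(lines)))
  if (length(body) == 0) {
    out <- empty_calls()
    attr(out, "rejected") <- integer()
    return(out)
  }
  fields <- strsplit(trimws(lines[body]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 10)) {
    stop("malformed BEDPE line ", body[which(nf < 10)[1]],
         ": fewer than 10 columns")
  }
  get <- function(i) vapply(fields, `[`, character(1), i)
  start1 <- suppressWarnings(as.numeric(get(2)))
  start2 <- suppressWarnings(as.numeric(get(5)))
  bad_num <- is.na(start1) | is.na(start2)
  if (any(bad_num)) {
    stop("malformed BEDPE line ", body[which(bad_num)[1]],
         ": non-numeric coordinate")
  }
  df <- data.frame(
    call_id = get(7), patient = if (any(nf >= 11)) get(11) else patient,
    chrom1 = get(1), pos1 = start1 + 1, strand1 = get(9),
    chrom2 = get(4), pos2 = start2 + 1, strand2 = get(10),
    svtype = if (any(nf >= 12)) get(12) else NA_character_,
    stringsAsFactors = FALSE)
  rejected <- integer()
  if (!is.null(genome)) {
    bad <- !(df$chrom1 %in% genome$chroms) | !(df$chrom2 %in% genome$chroms)
    if (any(bad)) {
      rejected <- body[bad]
      warning(sum(bad), " BEDPE record(s) on unknown chromosomes rejected ",
              "(lines ", paste(utils::head(rejected, 5), collapse = ", "),
              if (sum(bad) > 5) ", ..." else "", ")")
      df <- df[!bad, , drop = FALSE]
    }
  }
  out <- sv_calls(df, genome = genome)
  attr(out, "rejected") <- rejected
  out
}

#' Write SV calls as BEDPE
#'
#' Inverse of [read_sv_bedpe()]: breakend positions are emitted as 0-based
#' half-open single-base intervals (`pos - 1`, `pos`), with patient and
#' svtype in columns 11-12.
#'
#' @param calls An [sv_calls()] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_bedpe <- function(calls, path) {
  df <- data.frame(calls$chrom1, format_pos(calls$pos1 - 1), format_pos(calls$pos1),
                   calls$chrom2, format_pos(calls$pos2 - 1), format_pos(calls$pos2),
                   calls$call_id, ".", calls$strand1, calls$strand2,
                   calls$patient, calls$svtype, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_pos <- function(x) format(x, scientific = FALSE, trim = TRUE)

empty_calls <- function() {
  sv_calls(data.frame(call_id = character(), patient = character(),
                      chrom1 = character(), pos1 = numeric(),
                      strand1 = character(), chrom2 = character(),
                      pos2 = numeric(), strand2 = character(),
                      svtype = character(), stringsAsFactors = FALSE))
}

#' Read paired-breakend SV calls from a minimal Manta-style VCF
#'
#' Parses simple breakend (`SVTYPE=BND`) records whose `ALT` uses the four
#' bracket forms (`t[p[`, `t]p]`, `]p]t`, `[p[t`) and pairs mates through the
#' `MATEID` INFO key. Records without a resolvable single mate (missing,
#' duplicated, or multi-mate) are rejected and reported. The full nested
#' breakend grammar is out of scope.
#'
#' @param path Path to an uncompressed VCF.
#' @param genome Optional [genome_def()] for validation.
#' @param patient Patient id assigned to the calls.
#' @return An [sv_calls()] data.frame (one row per breakend pair); attribute
#'   `"rejected"` lists rejected record ids.
#' @export
read_sv_vcf <- function(path, genome = NULL, patient = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- empty_calls(); attr(out, "rejected") <- character(); return(out)
  }
  f <- strsplit(lines, "\t")
  rec <- data.frame(
    chrom = vapply(f, `[`, character(1), 1),
    pos = as.numeric(vapply(f, `[`, character(1), 2)),
    id = vapply(f, `[`, character(1), 3),
    alt = vapply(f, `[`, character(1), 5),
    info = vapply(f, `[`, character(1), 8),
    stringsAsFactors = FALSE)
  mate <- sub(".*MATEID=([^;]+).*", "\\1", rec$info)
  mate[!grepl("MATEID=", rec$info)] <- NA
  # orientation: leading base + '[' => (+ here, - mate); leading base + ']' =>
  # (+,+); trailing base with ']' => (-,+); trailing with '[' => (-,-)
  m <- regmatches(rec$alt, regexec("(\\[|\\])([^][]+):([0-9]+)(\\[|\\])",
                                   rec$alt))
  ok <- lengths(m) == 5 & !is.na(mate) & !grepl(",", rec$alt)
  strand_here <- ifelse(grepl("^[ACGTNacgtn]+[][]", rec$alt), "+", "-")
  rejected <- rec$id[!ok]
  rec <- rec[ok, , drop = FALSE]
  strand_here <- strand_here[ok]
  mate <- mate[ok]
  # pair each record with its mate; keep one row per pair
  idx <- match(mate, rec$id)
  unpaired <- is.na(idx) | rec$id[idx] == rec$id | mate[idx] != rec$id
  rejected <- c(rejected, rec$id[unpaired])
  keep <- !unpaired & rec$id < mate
  if (length(rejected)) {
    warning(length(rejected), " VCF breakend record(s) rejected: ",
            paste(utils::head(rejected, 5), collapse = ", "))
  }
  a <- which(keep)
  b <- idx[keep]
  df <- data.frame(
    call_id = sub("[:_][12]$", "", rec$id[a]),
    patient = patient,
    chrom1 = rec$chrom[a], pos1 = rec$pos[a], strand1 = strand_here[a],
    chrom2 = rec$chrom[b], pos2 = rec$pos[b], strand2 = strand_here[b],
    svtype = NA_character_, stringsAsFactors = FALSE)
  out <- sv_calls(df, genome = genome)
  attr(out, "rejected") <- unique(rejected)
  out
}

#' Read a BED3(+) file of regions
#'
#' BED coordinates (0-based, half-open) are converted to internal 1-based
#' closed intervals. Extra columns beyond the third are kept (`name`, ...).
#'
#' @param path Path to a BED file.
#' @param genome Optional [genome_def()]; out-of-bounds or unknown-chromosome
#'   records are rejected with a warning and reported via the `"rejected"`
#'   attribute.
#' @return data.frame with columns `chrom`, `start`, `end` (1-based closed)
#'   and any extra columns (`name`, ...).
#' @export
read_regions <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- which(!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines)))
  if (length(body) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(trimws(lines[body]), "[ \t]+")
  if (any(lengths(f) < 3)) {
    stop("malformed BED line ", body[which(lengths(f) < 3)[1]])
  }
  out <- data.frame(
    chrom = vapply(f, `[`, character(1), 1),
    start = as.numeric(vapply(f, `[`, character(1), 2)) + 1,
    end = as.numeric(vapply(f, `[`, character(1), 3)),
    stringsAsFactors = FALSE)
  if (max(lengths(f)) >= 4) {
    out$name <- vapply(f, function(x) if (length(x) >= 4) x[4] else NA_character_,
                       character(1))
  }
  rejected <- integer()
  if (!is.null(genome)) {
    bad <- !(out$chrom %in% genome$chroms)
    bad[!bad] <- out$end[!bad] > genome$lengths[out$chrom[!bad]] |
      out$start[!bad] < 1
    if (any(bad)) {
      rejected <- body[bad]
      warning(sum(bad), " BED record(s) outside the genome rejected")
      out <- out[!bad, , drop = FALSE]
    }
  }
  attr(out, "rejected") <- rejected
  out
}

#' Write regions as BED3(+1 name column)
#' @param regions data.frame with `chrom`, `start`, `end` (1-based closed)
#'   and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  df <- data.frame(regions$chrom, format_pos(regions$start - 1),
                   format_pos(regions$end), stringsAsFactors = FALSE)
  if (!is.null(regions$name)) df[[4]] <- regions$name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models with canonical-transcript exons from BED12
#'
#' The BED12 `name` field is interpreted as `symbol` or
#' `symbol|transcript_id`; blocks become exon intervals (1-based, closed).
#' Exons are normalised: sorted by start, overlapping blocks merged.
#'
#' @param path Path to a BED12 file.
#' @param cancer_genes Optional character vector of cancer-census gene
#'   symbols; matching genes get `cancer = TRUE`.
#' @param genome Optional [genome_def()] for bounds validation (violations
#'   rejected with a warning).
#' @return data.frame with one row per exon: `gene`, `transcript`, `chrom`,
#'   `strand`, `exon_start`, `exon_end`, `cancer`.
#' @export
read_gene_models <- function(path, cancer_genes = NULL, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- which(!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines)))
  empty <- data.frame(gene = character(), transcript = character(),
                      chrom = character(), strand = character(),
                      exon_start = numeric(), exon_end = numeric(),
                      cancer = logical(), stringsAsFactors = FALSE)
  if (length(body) == 0) return(empty)
  f <- strsplit(trimws(lines[body]), "\t")
  if (any(lengths(f) < 12)) {
    stop("malformed BED12 line ", body[which(lengths(f) < 12)[1]],
         ": need 12 columns")
  }
  rows <- lapply(seq_along(f), function(i) {
    x <- f[[i]]
    chrom_start <- as.numeric(x[2])
    nb <- as.integer(x[10])
    sizes <- as.numeric(strsplit(x[11], ",")[[1]])[seq_len(nb)]
    offs <- as.numeric(strsplit(x[12], ",")[[1]])[seq_len(nb)]
    nm <- strsplit(x[4], "|", fixed = TRUE)[[1]]
    data.frame(gene = nm[1],
               transcript = if (length(nm) > 1) nm[2] else nm[1],
               chrom = x[1], strand = x[6],
               exon_start = chrom_start + offs + 1,
               exon_end = chrom_start + offs + sizes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- normalize_exons(out)
  out$cancer <- if (is.null(cancer_genes)) FALSE else out$gene %in% cancer_genes
  if (!is.null(genome)) {
    bad <- !(out$chrom %in% genome$chroms)
    bad[!bad] <- out$exon_end[!bad] > genome$lengths[out$chrom[!bad]]
    if (any(bad)) {
      warning(sum(bad), " exon record(s) outside the genome rejected")
      out <- out[!bad, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

# merge overlapping exons within a transcript, sort by start
normalize_exons <- function(ex) {
  parts <- split(ex, list(ex$gene, ex$transcript), drop = TRUE)
  out <- lapply(parts, function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$exon_start, d$exon_end))
    data.frame(gene = d$gene[1], transcript = d$transcript[1],
               chrom = d$chrom[1], strand = d$strand[1],
               exon_start = IRanges::start(ir), exon_end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$gene, out$chrom, out$exon_start), , drop = FALSE]
}

#' Read a labelled numeric matrix from TSV
#'
#' First column = row labels, header row = column labels.
#' @param path Path to a TSV file.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a labelled numeric matrix as TSV
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param label Header name for the row-label column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, label = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write any data.frame as TSV with stable column order
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
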