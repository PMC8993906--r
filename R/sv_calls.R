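#' Construct and normalise a table of SV calls
#'
#' The internal SV representation is one row per call with paired breakends.
#' Positions are 1-based; orientation `+` means the segment to the left of
#' the junction is retained at that breakend (the MANTA/BEDPE convention).
#' Normalisation orders the two breakends (by position for intra-chromosomal
#' calls, by chromosome then position for inter-chromosomal ones), derives
#' missing SV types from the junction geometry via [classify_sv_type()], and
#' computes span lengths for intra-chromosomal calls.
#'
#' @param df data.frame with columns `call_id`, `patient`, `chrom1`, `pos1`,
#'   `strand1`, `chrom2`, `pos2`, `strand2` and optionally `svtype`. Extra
#'   columns are preserved.
#' @param genome Optional [genome_def()]; when supplied, positions are
#'   validated against chromosome bounds and breakends are ordered by the
#'   genome's chromosome order.
#' @return data.frame of class `sv_calls` with the canonical columns plus
#'   `span` (NA for inter-chromosomal calls), `blacklisted`, `me`, `cluster`
#'   and `cluster_class`.
#' @examples
#' sv_calls(data.frame(call_id = "sv1", patient = "P1",
#'                     chrom1 = "chr1", pos1 = 100, strand1 = "+",
#'                     chrom2 = "chr1", pos2 = 5100, strand2 = "-"))
#' @export
sv_calls <- function(df, genome = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("call_id", "patient", "chrom1", "pos1", "strand1",
           "chrom2", "pos2", "strand2")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  for (col in c("call_id", "patient", "chrom1", "chrom2", "strand1", "strand2"))
    df[[col]] <- as.character(df[[col]])
  df$pos1 <- as.numeric(df$pos1)
  df$pos2 <- as.numeric(df$pos2)
  if (nrow(df) > 0 && !all(c(df$strand1, df$strand2) %in% c("+", "-")))
    stop("strands must be '+' or '-'")
  if (!is.null(genome)) {
    stopifnot(inherits(genome, "genome_def"))
    for (side in 1:2) {
      ch <- df[[paste0("chrom", side)]]
      pos <- df[[paste0("pos", side)]]
      bad <- !(ch %in% genome$chroms)
      if (any(bad)) stop("unknown chromosome in calls: ",
                         paste(unique(ch[bad]), collapse = ", "))
      if (any(pos < 1 | pos > genome$lengths[ch]))
        stop("breakend position outside chromosome bounds")
    }
  }
  dup <- duplicated(df[, c("patient", "call_id")])
  if (any(dup)) stop("call ids must be unique within patient")

  chrom_rank <- function(ch) {
    if (is.null(genome)) ch else match(ch, genome$chroms)
  }
  swap <- (df$chrom1 == df$chrom2 & df$pos1 > df$pos2) |
    (df$chrom1 != df$chrom2 &
       order_pair(chrom_rank(df$chrom1), chrom_rank(df$chrom2)))
  if (any(swap)) {
    tmp <- df[swap, c("chrom1", "pos1", "strand1")]
    df[swap, c("chrom1", "pos1", "strand1")] <-
      df[swap, c("chrom2", "pos2", "strand2")]
    df[swap, c("chrom2", "pos2", "strand2")] <- tmp
  }
  derived <- classify_sv_type(df$chrom1, df$strand1, df$chrom2, df$strand2)
  if (is.null(df$svtype)) {
    df$svtype <- derived
  } else {
    df$svtype <- as.character(df$svtype)
    fill <- is.na(df$svtype) | df$svtype %in% c("", ".")
    df$svtype[fill] <- derived[fill]
    inter <- df$chrom1 != df$chrom2
    if (any(inter & df$svtype != "BND") || any(!inter & df$svtype == "BND"))
      stop("svtype BND iff breakends on different chromosomes")
  }
  df$span <- ifelse(df$chrom1 == df$chrom2, df$pos2 - df$pos1, NA_real_)
  n <- nrow(df)
  if (is.null(df$blacklisted)) df$blacklisted <- rep(FALSE, n)
  if (is.null(df$me)) df$me <- rep(FALSE, n)
  if (is.null(df$cluster)) df$cluster <- rep(NA_integer_, n)
  if (is.null(df$cluster_class)) df$cluster_class <- rep(NA_character_, n)
  class(df) <- c("sv_calls", "data.frame")
  df
}

# TRUE where the (chromA, chromB) pair should be swapped to canonical order
order_pair <- function(ra, rb) {
  if (is.null(ra) || all(is.na(ra))) return(rep(FALSE, length(ra)))
  ifelse(is.na(ra) | is.na(rb), FALSE, ra > rb)
}

#' Classify an SV junction by its geometry
#'
#' Names a junction after the simplest rearrangement that could generate it:
#' breakends on different chromosomes give `BND` (an inter-chromosome
#' junction/translocation); on the same chromosome, orientations `(+,-)`
#' give `DEL`, `(-,+)` give `DUP` (tandem-duplication-like), and `(+,+)` or
#' `(-,-)` give `INV`. Breakends are assumed normalised (first position
#' leftmost for intra-chromosomal junctions).
#'
#' @param chrom1,chrom2 Chromosomes of the two breakends (vectorised).
#' @param strand1,strand2 Orientations, `+`/`-`.
#' @return Character vector in `{DEL, DUP, INV, BND}`.
#' @examples
#' classify_sv_type("chr1", "+", "chr1", "-") # DEL
#' @export
classify_sv_type <- function(chrom1, strand1, chrom2, strand2) {
  out <- rep("INV", length(chrom1))
  out[strand1 == "+" & strand2 == "-"] <- "DEL"
  out[strand1 == "-" & strand2 == "+"] <- "DUP"
  out[chrom1 != chrom2] <- "BND"
  out
}

#' Assemble a cohort from per-patient SV calls
#'
#' @param calls An `sv_calls` data.frame covering one or more patients.
#' @param patients Optional character vector of patient ids (to include
#'   patients with zero calls); defaults to the ids present in `calls`.
#' @return List of class `sv_cohort` with elements `patients` and `calls`.
#' @export
sv_cohort <- function(calls, patients = NULL) {
  if (!inherits(calls, "sv_calls")) calls <- sv_calls(calls)
  if (is.null(patients)) patients <- unique(calls$patient)
  if (!all(calls$patient %in% patients))
    stop("calls reference patients absent from the id list")
  structure(list(patients = as.character(patients), calls = calls),
            class = "sv_cohort")
}

#' @export
print.sv_cohort <- function(x, ...) {
  cat(sprintf("sv_cohort: %d patients, %d SV calls (%s)\n",
              length(x$patients), nrow(x$calls),
              paste(sprintf("%s=%d", names(table(x$calls$svtype)),
                            as.integer(table(x$calls$svtype))),
                    collapse = ", ")))
  invisible(x)
}
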