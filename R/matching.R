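#' Flag calls present in a panel of normals
#'
#' A call is flagged as blacklisted iff some panel record has the same SV
#' type, the same (ordered) chromosome pair, and both breakends within
#' `window_bp` of the call's breakends. Flagged calls are excluded from
#' downstream counting by the pipeline. This reproduces panel-of-normals
#' filtering of artefact-prone junctions seen in unmatched normal genomes.
#'
#' @param calls An [sv_calls()] data.frame.
#' @param panel_calls data.frame of panel records with the same breakend
#'   columns (patient semantics ignored).
#' @param window_bp Maximum per-breakend coordinate difference (default 300).
#' @return `calls` with the `blacklisted` column set.
#' @export
filter_panel <- function(calls, panel_calls, window_bp = 300) {
  if (window_bp < 0) stop("window_bp must be non-negative")
  if (nrow(calls) == 0) return(calls)
  if (is.null(panel_calls) || nrow(panel_calls) == 0) {
    calls$blacklisted <- FALSE
    return(calls)
  }
  if (!inherits(panel_calls, "sv_calls")) {
    pc <- as.data.frame(panel_calls)
    if (is.null(pc$patient)) pc$patient <- "panel"
    if (is.null(pc$call_id)) pc$call_id <- paste0("panel", seq_len(nrow(pc)))
    panel_calls <- sv_calls(pc)
  }
  key <- function(d) paste(d$svtype, d$chrom1, d$chrom2)
  pk <- key(panel_calls)
  ck <- key(calls)
  flag <- logical(nrow(calls))
  for (k in unique(ck)) {
    ci <- which(ck == k)
    pi <- which(pk == k)
    if (length(pi) == 0) next
    for (i in ci) {
      hit <- abs(panel_calls$pos1[pi] - calls$pos1[i]) <= window_bp &
        abs(panel_calls$pos2[pi] - calls$pos2[i]) <= window_bp
      flag[i] <- any(hit)
    }
  }
  calls$blacklisted <- flag
  calls
}

#' Match two callsets and compute precision/sensitivity/F1
#'
#' Greedy one-to-one matching of calls in `callsA` against `callsB`:
#' candidate pairs require identical SV type, identical ordered chromosome
#' pair, and both breakend offsets within `window_bp`; pairs are accepted in
#' order of ascending summed breakend distance (ties broken by call id), each
#' call matched at most once. Precision = matched/|A|, sensitivity =
#' matched/|B|, F1 their harmonic mean. With both sets empty all three
#' metrics are 1 by convention; with exactly one set empty the corresponding
#' ratio with denominator 0 is reported as 1 (nothing to get wrong) and the
#' other as 0.
#'
#' @param callsA,callsB [sv_calls()] data.frames from the same genome.
#' @param window_bp Per-breakend matching window in bp (default 300).
#' @return List with `matched`, `precision`, `sensitivity`, `f1`, and the
#'   matched id pairs (`pairs`, data.frame).
#' @export
match_callsets <- function(callsA, callsB, window_bp = 300) {
  if (window_bp < 0) stop("window_bp must be non-negative")
  nA <- nrow(callsA); nB <- nrow(callsB)
  pairs <- data.frame(id_a = character(), id_b = character(),
                      dist = numeric(), stringsAsFactors = FALSE)
  if (nA > 0 && nB > 0) {
    cand <- list()
    keyA <- paste(callsA$svtype, callsA$chrom1, callsA$chrom2)
    keyB <- paste(callsB$svtype, callsB$chrom1, callsB$chrom2)
    for (k in intersect(unique(keyA), unique(keyB))) {
      ia <- which(keyA == k); ib <- which(keyB == k)
      grid <- expand.grid(a = ia, b = ib)
      d1 <- abs(callsA$pos1[grid$a] - callsB$pos1[grid$b])
      d2 <- abs(callsA$pos2[grid$a] - callsB$pos2[grid$b])
      ok <- d1 <= window_bp & d2 <= window_bp
      if (any(ok)) {
        cand[[k]] <- data.frame(a = grid$a[ok], b = grid$b[ok],
                                dist = (d1 + d2)[ok])
      }
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand$dist, callsA$call_id[cand$a],
                         callsB$call_id[cand$b]), , drop = FALSE]
      usedA <- logical(nA); usedB <- logical(nB)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        if (!usedA[cand$a[i]] && !usedB[cand$b[i]]) {
          keep[i] <- TRUE
          usedA[cand$a[i]] <- TRUE
          usedB[cand$b[i]] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      pairs <- data.frame(id_a = callsA$call_id[cand$a],
                          id_b = callsB$call_id[cand$b],
                          dist = cand$dist, stringsAsFactors = FALSE)
    }
  }
  m <- nrow(pairs)
  precision <- if (nA == 0) 1 else m / nA
  sensitivity <- if (nB == 0) 1 else m / nB
  f1 <- if (precision + sensitivity == 0) 0 else
    2 * precision * sensitivity / (precision + sensitivity)
  list(matched = m, precision = precision, sensitivity = sensitivity,
       f1 = f1, pairs = pairs)
}
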