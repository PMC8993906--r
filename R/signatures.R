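#' Channel labels of the rearrangement catalogue
#'
#' 32 channels: \{clustered, non-clustered\} x (\{DEL, DUP, INV\} x 5 size
#' bins + translocation). Size bins are half-open `[lo, hi)` with edges 10
#' kb, 100 kb, 1 Mb and 10 Mb; spans below 1 kb fall in the smallest bin.
#'
#' @return Character vector of length 32.
#' @export
catalogue_channels <- function() {
  sizes <- c("1-10kb", "10-100kb", "100kb-1Mb", "1-10Mb", ">10Mb")
  unlist(lapply(c("clustered", "non-clustered"), function(cl) {
    base <- c(as.vector(t(outer(c("DEL", "DUP", "INV"), sizes, paste,
                                sep = ":"))), "translocation")
    paste(cl, base, sep = ":")
  }))
}

size_bin_of <- function(span) {
  cut(span, breaks = c(-Inf, 1e4, 1e5, 1e6, 1e7, Inf), right = FALSE,
      labels = c("1-10kb", "10-100kb", "100kb-1Mb", "1-10Mb", ">10Mb"))
}

#' Build the per-patient rearrangement catalogue
#'
#' Bins every SV into one of the 32 type x size x clustering channels:
#' intra-chromosomal calls by SV type and span size bin, BNDs into the
#' translocation channel; an SV counts as `clustered` when its footprint
#' cluster has two or more members. Each SV increments exactly one channel,
#' so per-patient channel sums equal per-patient SV counts.
#'
#' @param cohort An [sv_cohort()] whose calls carry cluster ids (see
#'   [cluster_cohort()]).
#' @return Integer matrix, 32 channels (rows, see [catalogue_channels()]) by
#'   patients (columns).
#' @export
build_catalogue <- function(cohort) {
  calls <- cohort$calls
  if (nrow(calls) > 0 && any(is.na(calls$cluster))) {
    stop("calls must be clustered before cataloguing (pipeline order)")
  }
  channels <- catalogue_channels()
  m <- matrix(0L, nrow = length(channels), ncol = length(cohort$patients),
              dimnames = list(channels, cohort$patients))
  if (nrow(calls) == 0) return(m)
  csize <- stats::ave(rep(1L, nrow(calls)),
                      paste(calls$patient, calls$cluster), FUN = sum)
  clustered <- ifelse(csize >= 2, "clustered", "non-clustered")
  chan <- ifelse(calls$svtype == "BND",
                 paste(clustered, "translocation", sep = ":"),
                 paste(clustered, calls$svtype,
                       as.character(size_bin_of(calls$span)), sep = ":"))
  tab <- table(factor(chan, levels = channels),
               factor(calls$patient, levels = cohort$patients))
  m[] <- as.integer(tab)
  m
}

nmf_update <- function(V, W, H, eps = 1e-10) {
  H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
  W <- W * (V %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
  list(W = W, H = H)
}

nmf_fit <- function(V, k, iters, seed) {
  set.seed(seed)
  n <- ncol(V); m <- nrow(V)
  W <- matrix(stats::runif(m * k, 0.1, 1), m, k)
  H <- matrix(stats::runif(k * n, 0.1, 1), k, n)
  scale0 <- mean(V) / mean(W %*% H)
  H <- H * scale0
  for (i in seq_len(iters)) {
    up <- nmf_update(V, W, H)
    W <- up$W; H <- up$H
  }
  list(W = W, H = H, objective = sum((V - W %*% H)^2))
}

silhouette_mean <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (length(unique(labels)) < 2 || n < 3) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Extract rearrangement signatures by NMF
#'
#' For each candidate rank `k`, runs `replicates` random restarts of
#' non-negative matrix factorisation (multiplicative updates, Frobenius
#' objective) of the catalogue. Restart stability is summarised by the
#' consensus matrix of dominant-signature co-assignment of patients
#' (cophenetic correlation) and the mean silhouette of the dominant-signature
#' partition on exposure-proportion distances; the chosen `k` maximises the
#' mean of the two ranks. The returned factors come from the best-objective
#' restart at the chosen rank, with signature columns normalised to sum 1.
#'
#' @param catalogue Channel-by-patient count matrix from [build_catalogue()]
#'   (or any non-negative matrix with dimnames).
#' @param kmin,kmax Rank range to scan.
#' @param iters Multiplicative-update iterations per restart.
#' @param replicates Random restarts per rank.
#' @param seed Integer seed; the restart stream is a deterministic function
#'   of `(seed, k, replicate)`.
#' @return Object of class `signature_model`: list with `k`, `W` (channel x
#'   k, column-stochastic), `H` (k x patient), `scores` (per-k cophenetic,
#'   silhouette, mean rank), `objective`, and `assignment` (NULL until
#'   [match_reference()] is applied).
#' @export
extract_signatures <- function(catalogue, kmin = 2, kmax = 10, iters = 1000,
                               replicates = 30, seed = 1) {
  V <- as.matrix(catalogue)
  if (all(V == 0)) stop("catalogue is all zero")
  if (ncol(V) < kmax) stop("need at least kmax patients")
  ks <- kmin:kmax
  npat <- ncol(V)
  scores <- data.frame(k = ks, cophenetic = NA_real_, silhouette = NA_real_)
  best <- vector("list", length(ks))
  props <- sweep(V, 2, pmax(colSums(V), 1), "/")
  pdist <- stats::dist(t(props))
  for (ki in seq_along(ks)) {
    k <- ks[ki]
    co <- matrix(0, npat, npat)
    fits <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      fits[[r]] <- nmf_fit(V, k, iters, seed = seed + 7919L * k + r)
      lab <- apply(fits[[r]]$H, 2, which.max)
      co <- co + outer(lab, lab, "==")
    }
    co <- co / replicates
    best[[ki]] <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
    if (k >= 2 && npat >= 3) {
      dd <- stats::as.dist(1 - co)
      hc <- stats::hclust(dd, method = "average")
      scores$cophenetic[ki] <- suppressWarnings(
        stats::cor(stats::cophenetic(hc), dd))
      lab_best <- apply(best[[ki]]$H, 2, which.max)
      scores$silhouette[ki] <- silhouette_mean(pdist, lab_best)
    }
  }
  if (length(ks) == 1) {
    chosen <- 1
  } else {
    rk <- rank(-scores$cophenetic, ties.method = "average") +
      rank(-scores$silhouette, ties.method = "average")
    scores$mean_rank <- rk / 2
    chosen <- which.min(rk)
  }
  fit <- best[[chosen]]
  csum <- colSums(fit$W)
  W <- sweep(fit$W, 2, csum, "/")
  H <- sweep(fit$H, 1, csum, "*")
  dimnames(W) <- list(rownames(V), paste0("S", seq_len(ncol(W))))
  dimnames(H) <- list(colnames(W), colnames(V))
  structure(list(k = ks[chosen], W = W, H = H, scores = scores,
                 objective = fit$objective, assignment = NULL),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("signature_model: k = %d, %d channels, %d patients\n",
              x$k, nrow(x$W), ncol(x$H)))
  invisible(x)
}

cosine_sim <- function(a, b) {
  s <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  if (!is.finite(s)) 0 else s
}

#' Match extracted signatures to a reference catalogue
#'
#' Assigns each extracted signature the reference signature of maximal
#' cosine similarity, greedily without replacement in order of descending
#' cosine. Channel labels must agree (rows are reordered by label; a
#' mismatch is an error).
#'
#' @param W Extracted signature matrix (channel x k) or a `signature_model`.
#' @param reference Reference signature matrix (channel x r) with the same
#'   channel labels.
#' @return data.frame `signature`, `reference` (NA when references run out),
#'   `cosine`.
#' @export
match_reference <- function(W, reference) {
  if (inherits(W, "signature_model")) W <- W$W
  if (!setequal(rownames(W), rownames(reference))) {
    stop("channel labels of W and reference do not match")
  }
  reference <- reference[rownames(W), , drop = FALSE]
  cs <- matrix(0, ncol(W), ncol(reference),
               dimnames = list(colnames(W), colnames(reference)))
  for (i in seq_len(ncol(W)))
    for (j in seq_len(ncol(reference)))
      cs[i, j] <- cosine_sim(W[, i], reference[, j])
  out <- data.frame(signature = colnames(W), reference = NA_character_,
                    cosine = NA_real_, stringsAsFactors = FALSE)
  avail_s <- seq_len(nrow(cs)); avail_r <- seq_len(ncol(cs))
  while (length(avail_s) > 0 && length(avail_r) > 0) {
    sub <- cs[avail_s, avail_r, drop = FALSE]
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    si <- avail_s[ij[1]]; rj <- avail_r[ij[2]]
    out$reference[si] <- colnames(cs)[rj]
    out$cosine[si] <- cs[si, rj]
    avail_s <- setdiff(avail_s, si)
    avail_r <- setdiff(avail_r, rj)
  }
  # cosines for unassigned signatures: best remaining reference similarity
  miss <- is.na(out$reference)
  if (any(miss)) out$cosine[miss] <- apply(cs[miss, , drop = FALSE], 1, max)
  out
}

#' Group patients by consensus clustering of signature exposures
#'
#' For each candidate group number `K`, repeatedly subsamples patients,
#' k-means-clusters their exposure proportions, and accumulates a pairwise
#' consensus matrix (fraction of co-sampled runs in which two patients
#' co-cluster). Final labels come from average-linkage hierarchical
#' clustering of `1 - consensus`; the chosen `K` maximises the mean
#' within-group consensus.
#'
#' @param H Exposure matrix (k signatures x patients) or a
#'   `signature_model`.
#' @param Kmax Largest K scanned (from 2).
#' @param resamples Subsampling repetitions per K.
#' @param subsample Fraction of patients per subsample.
#' @param seed Integer seed.
#' @return Object of class `patient_groups`: list with `K`, `labels` (named
#'   integer vector, contiguous 1..K), `scores` (per-K mean consensus), and
#'   `consensus` (matrix at the chosen K).
#' @export
consensus_group <- function(H, Kmax = 6, resamples = 1000, subsample = 0.8,
                            seed = 1) {
  if (inherits(H, "signature_model")) H <- H$H
  npat <- ncol(H)
  if (npat < Kmax) stop("need at least Kmax patients")
  props <- t(sweep(H, 2, pmax(colSums(H), 1e-12), "/"))
  set.seed(seed)
  Ks <- 2:Kmax
  res <- lapply(Ks, function(K) {
    hit <- matrix(0, npat, npat)
    both <- matrix(0, npat, npat)
    m <- max(2, floor(subsample * npat))
    for (r in seq_len(resamples)) {
      idx <- sample.int(npat, m)
      sub <- props[idx, , drop = FALSE]
      distinct <- unique(sub)
      if (nrow(distinct) <= K) {
        lab <- vapply(seq_len(nrow(sub)), function(i)
          which.min(rowSums(sweep(distinct, 2, sub[i, ])^2)), integer(1L))
      } else {
        lab <- stats::kmeans(sub, centers = K, nstart = 1)$cluster
      }
      both[idx, idx] <- both[idx, idx] + 1
      co <- outer(lab, lab, "==")
      hit[idx, idx] <- hit[idx, idx] + co
    }
    cons <- ifelse(both > 0, hit / both, 0)
    diag(cons) <- 1
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
    lab <- stats::cutree(hc, k = K)
    within <- outer(lab, lab, "==") & upper.tri(cons)
    score <- if (any(within)) mean(cons[within]) else 1
    list(cons = cons, labels = lab, score = score)
  })
  scores <- data.frame(K = Ks,
                       mean_consensus = vapply(res, `[[`, numeric(1), "score"))
  chosen <- which.max(scores$mean_consensus)
  labels <- res[[chosen]]$labels
  labels <- as.integer(factor(labels, levels = unique(labels)))
  names(labels) <- colnames(H)
  structure(list(K = Ks[chosen], labels = labels, scores = scores,
                 consensus = res[[chosen]]$cons),
            class = "patient_groups")
}

#' @export
print.patient_groups <- function(x, ...) {
  cat(sprintf("patient_groups: K = %d (%s)\n", x$K,
              paste(sprintf("g%d=%d", seq_len(x$K), tabulate(x$labels, x$K)),
                    collapse = ", ")))
  invisible(x)
}

#' Signature presence calls from exposures
#'
#' A signature is called present in a patient when its exposure accounts for
#' at least `threshold` of the patient's SVs.
#'
#' @param H Exposure matrix (k x patients) or `signature_model`.
#' @param threshold Minimum exposure proportion (default 0.05).
#' @return Logical matrix, patients x signatures.
#' @export
signature_presence <- function(H, threshold = 0.05) {
  if (inherits(H, "signature_model")) H <- H$H
  props <- sweep(H, 2, pmax(colSums(H), 1e-12), "/")
  t(props >= threshold)
}

fit_logistic <- function(y, x_df) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = x_df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # quasi-separation also shows as runaway slope estimates
  if (!sep && length(stats::coef(fit)) > 1 &&
      any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)) {
    sep <- TRUE
  }
  list(fit = fit, separation = sep)
}

#' Associate orthogonal features with signature presence
#'
#' Features are transformed `log(x + 1)` then standardised. For each
#' response (signature presence), every feature is first fit univariately by
#' logistic regression; features with univariate p < `alpha_in` enter a
#' multivariate logistic model refined by bidirectional stepwise AIC, and
#' Benjamini-Hochberg q-values are computed on the final model's
#' coefficients. Complete separation is reported as a flag with the estimate
#' suppressed.
#'
#' @param presence Logical/binary matrix or data.frame, patients x
#'   responses (e.g. from [signature_presence()]).
#' @param features Numeric data.frame/matrix, patients x features (counts or
#'   expressions; transformed internally).
#' @param alpha_in Univariate inclusion threshold (default 0.05).
#' @return List with `univariate` and `multivariate` data.frames
#'   (`response`, `feature`, `log_odds`, `p`, and in the multivariate table
#'   `q`, plus a `separation` flag).
#' @export
associate_features <- function(presence, features, alpha_in = 0.05) {
  presence <- as.matrix(presence)
  if (is.null(colnames(presence)))
    colnames(presence) <- paste0("RS", seq_len(ncol(presence)))
  X <- as.matrix(features)
  X <- apply(X, 2, function(col) {
    z <- log1p(col)
    s <- stats::sd(z)
    if (is.na(s) || s == 0) rep(0, length(z)) else (z - mean(z)) / s
  })
  uni <- list(); multi <- list()
  for (rs in colnames(presence)) {
    y <- as.numeric(presence[, rs])
    rows <- lapply(colnames(X), function(f) {
      fl <- fit_logistic(y, data.frame(x = X[, f]))
      co <- summary(fl$fit)$coefficients
      has <- "x" %in% rownames(co)
      data.frame(response = rs, feature = f,
                 log_odds = if (fl$separation || !has) NA_real_ else co["x", 1],
                 p = if (has) co["x", 4] else NA_real_,
                 separation = fl$separation, stringsAsFactors = FALSE)
    })
    u <- do.call(rbind, rows)
    uni[[rs]] <- u
    surv <- u$feature[!is.na(u$p) & u$p < alpha_in & !u$separation]
    if (length(surv) == 0) next
    dat <- data.frame(X[, surv, drop = FALSE])
    names(dat) <- surv
    fl <- fit_logistic(y, dat)
    fit <- suppressWarnings(MASS::stepAIC(fl$fit, direction = "both",
                                          trace = 0))
    co <- summary(fit)$coefficients
    keep <- setdiff(rownames(co), "(Intercept)")
    if (length(keep) == 0) next
    sep_any <- fl$separation
    multi[[rs]] <- data.frame(
      response = rs, feature = gsub("`", "", keep),
      log_odds = if (sep_any) NA_real_ else co[keep, 1],
      p = co[keep, 4],
      q = stats::p.adjust(co[keep, 4], method = "BH"),
      separation = sep_any, stringsAsFactors = FALSE)
  }
  list(univariate = do.call(rbind, c(uni, list(NULL))),
       multivariate = if (length(multi)) do.call(rbind, multi) else
         data.frame(response = character(), feature = character(),
                    log_odds = numeric(), p = numeric(), q = numeric(),
                    separation = logical(), stringsAsFactors = FALSE))
}

#' Hold-out stability of feature-signature associations
#'
#' Refits each response's final multivariate model on random training
#' fractions and reports how often each coefficient keeps the sign it has in
#' the full-data fit.
#'
#' @param presence,features As in [associate_features()].
#' @param splits Training fractions (default 0.8, 0.6, 0.4 for 80/20, 60/40
#'   and 40/60 splits).
#' @param reps Replicates per split.
#' @param seed Integer seed.
#' @return data.frame `response`, `feature`, `split`, `sign_consistency`.
#' @export
holdout_validate <- function(presence, features, splits = c(0.8, 0.6, 0.4),
                             reps = 10, seed = 1) {
  empty <- data.frame(response = character(), feature = character(),
                      split = numeric(), sign_consistency = numeric(),
                      stringsAsFactors = FALSE)
  if (reps == 0) return(empty)
  full <- associate_features(presence, features)$multivariate
  if (nrow(full) == 0) return(empty)
  presence <- as.matrix(presence)
  if (is.null(colnames(presence)))
    colnames(presence) <- paste0("RS", seq_len(ncol(presence)))
  X <- as.matrix(features)
  X <- apply(X, 2, function(col) {
    z <- log1p(col); s <- stats::sd(z)
    if (is.na(s) || s == 0) rep(0, length(z)) else (z - mean(z)) / s
  })
  set.seed(seed)
  n <- nrow(X)
  out <- list()
  for (rs in unique(full$response)) {
    feats <- full$feature[full$response == rs]
    ref_sign <- sign(full$log_odds[full$response == rs])
    for (sp in splits) {
      agree <- matrix(NA, reps, length(feats))
      for (r in seq_len(reps)) {
        tr <- sample.int(n, max(2, floor(sp * n)))
        dat <- data.frame(X[tr, feats, drop = FALSE])
        names(dat) <- feats
        fl <- fit_logistic(as.numeric(presence[tr, rs]), dat)
        co <- stats::coef(fl$fit)[feats]
        agree[r, ] <- sign(co) == ref_sign
      }
      out[[length(out) + 1]] <- data.frame(
        response = rs, feature = feats, split = sp,
        sign_consistency = colMeans(agree, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Pairwise two-sided Wilcoxon rank-sum tests between groups
#'
#' Uses the exact null distribution for small samples (combined n <= 50
#' without ties; tiny tied samples are enumerated exactly) and the normal
#' approximation with tie correction otherwise.
#'
#' @param values Numeric vector.
#' @param group_labels Group label per value (>= 1 value per group).
#' @return data.frame `group1`, `group2`, `n1`, `n2`, `p`.
#' @export
compare_groups <- function(values, group_labels) {
  groups <- if (is.factor(group_labels)) levels(group_labels) else
    unique(as.character(group_labels))
  sizes <- table(factor(group_labels, levels = groups))
  if (any(sizes == 0)) stop("every group needs at least one value")
  if (length(groups) < 2) stop("need at least two groups")
  combs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- lapply(combs, function(gp) {
    x <- values[group_labels == gp[1]]
    y <- values[group_labels == gp[2]]
    ties <- anyDuplicated(c(x, y)) > 0
    n <- length(x) + length(y)
    if (!ties && n <= 50) {
      p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    } else if (ties && n <= 12) {
      p <- exact_ranksum_p(x, y)
    } else {
      p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    }
    data.frame(group1 = gp[1], group2 = gp[2],
               n1 = length(x), n2 = length(y), p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# exact two-sided rank-sum p by enumeration (handles ties; tiny n only)
exact_ranksum_p <- function(x, y) {
  r <- rank(c(x, y))
  nx <- length(x)
  obs <- sum(r[seq_len(nx)])
  all_idx <- utils::combn(length(r), nx)
  sums <- colSums(matrix(r[all_idx], nrow = nx))
  mu <- mean(sums)
  p <- mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
  min(1, p)
}
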