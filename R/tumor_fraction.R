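#' Segment binned log2 ratios by greedy merging
#'
#' One-pass, deterministic segmentation: within each arm, a bin joins the
#' current segment while its value differs from the segment's running mean
#' by less than `min_gap`; otherwise it starts a new segment.  Segment
#' means are arithmetic means of member bins.  A post-pass absorbs
#' segments shorter than `min_seg_bins` into the adjacent segment with
#' the closer mean, so isolated noise bins do not survive as spurious
#' one-bin segments (which downstream copy-state fitting would otherwise
#' chase).
#'
#' @param bins `bin_series` data frame (`arm`, `start`, `end`, `log2ratio`),
#'   sorted within arm.
#' @param min_gap Log2 gap that opens a new segment (default 0.1).
#' @param min_bins Minimum bins required per arm (default 1).
#' @param min_seg_bins Segments shorter than this are merged into a
#'   neighbor (default 3); arms with fewer bins in total keep their single
#'   segment.
#' @return Object of class `segment_set`: data frame with columns `arm`,
#'   `first_bin`, `last_bin`, `mean_log2ratio`, `n_bins`.
#' @export
segment_bins <- function(bins, min_gap = 0.1, min_bins = 1L,
                         min_seg_bins = 3L) {
  if (NROW(bins) == 0L) stop("empty bin series")
  if (!all(c("arm", "log2ratio") %in% names(bins)))
    stop("bins must have columns arm and log2ratio")
  if (any(!is.finite(bins$log2ratio))) stop("non-finite log2 ratios")
  segs <- list()
  for (a in unique(bins$arm)) {
    v <- bins$log2ratio[bins$arm == a]
    if (length(v) < min_bins)
      stop(sprintf("arm %s has %d bin(s), fewer than min_bins = %d",
                   a, length(v), min_bins))
    start <- 1L; s <- v[1L]
    for (i in seq_along(v)[-1L]) {
      m <- s / (i - start)          # running mean of the open segment
      if (abs(v[i] - m) < min_gap) {
        s <- s + v[i]
      } else {
        segs[[length(segs) + 1L]] <- data.frame(
          arm = a, first_bin = start, last_bin = i - 1L,
          mean_log2ratio = s / (i - start), n_bins = i - start,
          stringsAsFactors = FALSE)
        start <- i; s <- v[i]
      }
    }
    segs[[length(segs) + 1L]] <- data.frame(
      arm = a, first_bin = start, last_bin = length(v),
      mean_log2ratio = s / (length(v) - start + 1L),
      n_bins = length(v) - start + 1L, stringsAsFactors = FALSE)
    # absorb runts into the neighbor with the closer mean
    k <- length(segs)
    first_of_arm <- which(vapply(segs, function(s_) s_$arm, "") == a)[1L]
    arm_idx <- first_of_arm:k
    sub <- segs[arm_idx]
    repeat {
      nb <- vapply(sub, function(s_) s_$n_bins, 0L)
      if (length(sub) < 2L || all(nb >= min_seg_bins)) break
      i <- which.min(ifelse(nb < min_seg_bins, nb, NA))
      mu <- vapply(sub, function(s_) s_$mean_log2ratio, 0)
      nbrs <- c(if (i > 1L) i - 1L, if (i < length(sub)) i + 1L)
      j <- nbrs[which.min(abs(mu[nbrs] - mu[i]))]
      a_ <- sub[[min(i, j)]]; b_ <- sub[[max(i, j)]]
      merged <- data.frame(
        arm = a, first_bin = a_$first_bin, last_bin = b_$last_bin,
        mean_log2ratio = (a_$mean_log2ratio * a_$n_bins +
                            b_$mean_log2ratio * b_$n_bins) /
          (a_$n_bins + b_$n_bins),
        n_bins = a_$n_bins + b_$n_bins, stringsAsFactors = FALSE)
      sub <- append(sub[-c(i, j)], list(merged), after = min(i, j) - 1L)
    }
    segs <- c(segs[seq_len(first_of_arm - 1L)], sub)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  class(out) <- c("segment_set", "data.frame")
  out
}

#' Grid-search tumor-fraction estimator from segmented log2 ratios
#'
#' Simplified alternative to HMM-based tumor-fraction callers: for each
#' candidate tumor fraction tf on a grid, every segment is assigned the
#' integer copy state `cn` in 0..6 minimizing the squared deviation of its
#' mean from the mixture prediction `log2((2 + tf * (cn - 2)) / 2)`; the
#' objective adds a graded non-diploid penalty and the tf minimizing it is
#' returned (ties to the smallest tf, keeping the estimator conservative).
#'
#' The penalty `lambda * sum(n_bins * |cn - 2|)` prefers the parsimonious
#' explanation among the exactly-fitting (tf, cn) pairs that the mixture
#' formula leaves indistinguishable (e.g. tf = 0.4 with cn = 3 versus
#' tf = 0.1 with cn = 6), resolving the estimator toward states near
#' diploid.
#'
#' @param segs [segment_bins()] output (or a `bin_series`, which is
#'   segmented first with defaults).
#' @param grid_step Grid resolution on tf in `[0, 0.95]` (default 0.01).
#' @param lambda Per-bin penalty per copy-state step away from 2
#'   (default 3e-4).  The penalty must stay below the squared log2 shift
#'   of the faintest alteration to be detected (about `(tf/2.77)^2` for a
#'   single-copy gain), otherwise small tumor fractions are absorbed into
#'   the neutral state; the default resolves single-copy events down to
#'   tf of roughly 0.05.
#' @return Object of class `tf_fit`: list with `tf` (the estimate),
#'   `segments` (with fitted `copy_number`), `objective`,
#'   `altered_fraction` (bin-weighted share of non-diploid genome), and
#'   `grid` (per-candidate objective, for diagnostics).
#' @export
fit_tumor_fraction <- function(segs, grid_step = 0.01, lambda = 3e-4) {
  if (inherits(segs, "bin_series") ||
      (!inherits(segs, "segment_set") && "log2ratio" %in% names(segs)))
    segs <- segment_bins(segs)
  if (nrow(segs) == 0L) stop("need at least one segment")
  tf_grid <- seq(0, 0.95, by = grid_step)
  states <- 0:6
  nb <- segs$n_bins
  mean_lr <- segs$mean_log2ratio
  obj <- numeric(length(tf_grid))
  cn_best <- matrix(2L, nrow(segs), length(tf_grid))
  for (k in seq_along(tf_grid)) {
    tf <- tf_grid[k]
    pred <- log2((2 + tf * (states - 2)) / 2)      # length 7; -Inf only if tf=1
    # residual matrix: segments x states
    res2 <- outer(mean_lr, pred, "-")^2
    pen <- matrix(lambda * abs(states - 2), nrow(segs), 7, byrow = TRUE)
    tot <- res2 + pen
    pick <- max.col(-tot, ties.method = "first")
    cn_best[, k] <- states[pick]
    obj[k] <- sum(nb * tot[cbind(seq_len(nrow(segs)), pick)])
  }
  k_hat <- which.min(obj)                           # which.min ties -> first = smallest tf
  segs$copy_number <- cn_best[, k_hat]
  out <- list(tf = tf_grid[k_hat],
              segments = segs,
              objective = obj[k_hat],
              altered_fraction = sum(nb[segs$copy_number != 2L]) / sum(nb),
              grid = data.frame(tf = tf_grid, objective = obj))
  class(out) <- "tf_fit"
  out
}

#' @export
print.tf_fit <- function(x, ...) {
  cat(sprintf(
    "Tumor-fraction fit: tf = %.2f (objective %.4g, altered fraction %.2f)\n",
    x$tf, x$objective, x$altered_fraction))
  invisible(x)
}

#' @export
coef.tf_fit <- function(object, ...) c(tf = object$tf)

#' Concordance between aneuploidy z-scores and tumor-fraction estimates
#'
#' Spearman rank correlation (average-rank ties) and the R-squared of an
#' ordinary least-squares fit of tf on Z, cohort-wide or per group
#' (e.g. per patient).
#'
#' @param Z Genome-wide z-scores.
#' @param tf Paired tumor-fraction estimates.
#' @param group Optional grouping factor (one statistic pair per group).
#' @return Data frame with columns `group`, `n`, `spearman_r`, `r_squared`,
#'   `note` (reason when a statistic is undefined).
#' @export
concordance_analysis <- function(Z, tf, group = NULL) {
  stopifnot(length(Z) == length(tf))
  if (is.null(group)) group <- rep("all", length(Z))
  one <- function(z, t, g) {
    if (length(z) < 3L)
      return(data.frame(group = g, n = length(z), spearman_r = NA_real_,
                        r_squared = NA_real_, note = "fewer than 3 pairs",
                        stringsAsFactors = FALSE))
    if (stats::sd(z) == 0 || stats::sd(t) == 0)
      return(data.frame(group = g, n = length(z), spearman_r = NA_real_,
                        r_squared = NA_real_, note = "constant vector",
                        stringsAsFactors = FALSE))
    r <- stats::cor(z, t, method = "spearman")
    # a perfect fit is legitimate on noise-free input; silence lm's caution
    r2 <- suppressWarnings(summary(stats::lm(t ~ z))$r.squared)
    data.frame(group = g, n = length(z), spearman_r = r, r_squared = r2,
               note = "", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(seq_along(Z), group), function(idx)
    one(Z[idx], tf[idx], as.character(group[idx[1L]]))))
  rownames(out) <- NULL
  out
}
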