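#' Aggregate per-read arm assignments into arm counts
#'
#' Counts BED-like read records per chromosome arm of a catalog.  Records
#' on arms absent from the catalog are dropped with a warning reporting
#' how many were discarded.
#'
#' @param records Data frame whose first column (or an `arm` column) holds
#'   arm identifiers, one row per read.
#' @param catalog Arm catalog.
#' @return Named integer vector of counts in catalog arm order.
#' @export
count_reads_per_arm <- function(records, catalog) {
  arm_col <- if ("arm" %in% names(records)) records$arm else records[[1L]]
  counts <- stats::setNames(integer(nrow(catalog)), catalog$arm)
  if (length(arm_col) == 0L) {
    warning("no read records: returning an all-zero arm count row")
    return(counts)
  }
  known <- arm_col %in% catalog$arm
  if (any(!known))
    warning(sprintf("dropped %d record(s) on arms absent from the catalog (%s)",
                    sum(!known),
                    paste(unique(arm_col[!known]), collapse = ", ")))
  tab <- table(factor(arm_col[known], levels = catalog$arm))
  counts[] <- as.integer(tab)
  counts
}

#' Normalize arm counts to per-sample fractions
#'
#' @param m Count matrix (samples x arms) or a single named count vector.
#' @return Matrix (or vector) of arm fractions; each sample sums to 1.
#' @export
normalize_to_fractions <- function(m) {
  if (is.null(dim(m))) {
    tot <- sum(m)
    if (tot <= 0) stop("sample has zero total count")
    return(m / tot)
  }
  tot <- rowSums(m)
  zero <- tot <= 0
  if (any(zero))
    stop("zero-total sample(s): ",
         paste(rownames(m)[zero], collapse = ", "))
  sweep(m, 1L, tot, "/")
}

#' Build a healthy reference panel for arm z-scoring
#'
#' Computes per-arm mean and sd (n-1 denominator) of control arm fractions,
#' and the control distribution of the sum-of-squares statistic S used to
#' standardize the genome-wide z-score.  Each control's S is computed
#' leave-one-out — its per-arm z-scores are taken against the panel of the
#' remaining controls — to avoid self-inclusion bias.
#'
#' @param controls Integer count matrix (controls x arms), >= 3 rows.
#' @return Object of class `ref_panel` with fields `arms`, `mu`, `sigma`,
#'   `n_controls`, `loo_S` (per-control leave-one-out S), `mu_S`, `sigma_S`.
#' @export
build_reference_panel <- function(controls) {
  if (nrow(controls) < 3L) stop("need at least 3 controls")
  fr <- normalize_to_fractions(controls)
  sigma <- apply(fr, 2L, stats::sd)
  flat <- colnames(fr)[sigma == 0]
  if (length(flat))
    stop("arm(s) constant across controls (sd = 0): ",
         paste(flat, collapse = ", "))
  n <- nrow(fr)
  loo_S <- vapply(seq_len(n), function(i) {
    mu_i <- colMeans(fr[-i, , drop = FALSE])
    sd_i <- apply(fr[-i, , drop = FALSE], 2L, stats::sd)
    if (any(sd_i == 0))
      stop("arm variance vanishes in a leave-one-out panel; controls too few or identical")
    sum(((fr[i, ] - mu_i) / sd_i)^2)
  }, numeric(1))
  out <- list(arms = colnames(fr),
              mu = colMeans(fr),
              sigma = sigma,
              n_controls = n,
              loo_S = loo_S,
              mu_S = mean(loo_S),
              sigma_S = stats::sd(loo_S))
  if (!is.finite(out$sigma_S) || out$sigma_S <= 0)
    stop("degenerate control S distribution (sigma_S = 0)")
  class(out) <- "ref_panel"
  out
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf(
    "Reference panel: %d controls, %d arms\n  control S: mean %.3f, sd %.3f\n",
    x$n_controls, length(x$arms), x$mu_S, x$sigma_S))
  invisible(x)
}

#' Per-arm z-scores of a sample against a reference panel
#'
#' `z_a = (x_a - mu_a) / sigma_a` where `x_a` is the sample's arm fraction.
#'
#' @param fractions Named fraction vector (or matrix, samples x arms).
#' @param panel [build_reference_panel()] object.
#' @return Named z vector (or matrix).
#' @export
arm_zscores <- function(fractions, panel) {
  nm <- if (is.null(dim(fractions))) names(fractions) else colnames(fractions)
  if (!identical(nm, panel$arms))
    stop("sample arms do not match the reference panel's arms")
  if (is.null(dim(fractions)))
    return((fractions - panel$mu) / panel$sigma)
  sweep(sweep(fractions, 2L, panel$mu, "-"), 2L, panel$sigma, "/")
}

#' Genome-wide aneuploidy z-score
#'
#' Squares and sums the per-arm z-scores into S, then standardizes S
#' against the control panel's leave-one-out S distribution:
#' `Z = (S - mu_S) / sigma_S`.  Z may be negative (a sample less variable
#' than a typical control).
#'
#' @param z Named per-arm z vector.
#' @param panel Reference panel.
#' @param cutoff Positivity cutoff applied by [classify_sample()]
#'   (default 3).
#' @return Object of class `zscore_result`: list with `z` (per-arm), `S`,
#'   `Z`, `cutoff`, `elevated`.
#' @export
genomewide_zscore <- function(z, panel, cutoff = 3) {
  if (!is.finite(panel$sigma_S) || panel$sigma_S <= 0)
    stop("panel has degenerate sigma_S")
  S <- sum(z^2)
  Z <- (S - panel$mu_S) / panel$sigma_S
  out <- list(z = z, S = S, Z = Z, cutoff = cutoff,
              elevated = classify_sample(Z, cutoff))
  class(out) <- "zscore_result"
  out
}

#' @export
print.zscore_result <- function(x, ...) {
  cat(sprintf("Genome-wide z-score: Z = %.3f (S = %.3f)%s\n", x$Z, x$S,
              if (x$elevated) sprintf("  [elevated at cutoff %g]", x$cutoff)
              else ""))
  invisible(x)
}

#' ctDNA positivity call from a genome-wide z-score
#'
#' A sample is called elevated when `Z >= cutoff`; the boundary value
#' counts as positive.
#'
#' @param Z Genome-wide z-score (or a `zscore_result`).
#' @param cutoff Finite threshold, default 3.
#' @return Logical flag.
#' @export
classify_sample <- function(Z, cutoff = 3) {
  if (inherits(Z, "zscore_result")) Z <- Z$Z
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  Z >= cutoff
}

#' Score a count matrix against a reference panel
#'
#' Convenience wrapper running fractions -> per-arm z -> genome-wide Z for
#' every sample row.
#'
#' @param counts Count matrix (samples x arms).
#' @param panel Reference panel.
#' @param cutoff Positivity cutoff (default 3).
#' @return Data frame with one row per sample (`sample`, `S`, `Z`,
#'   `elevated`); the per-arm z matrix is attached as attribute
#'   `"arm_z"`.
#' @export
score_samples <- function(counts, panel, cutoff = 3) {
  fr <- normalize_to_fractions(counts)
  zmat <- arm_zscores(fr, panel)
  S <- rowSums(zmat^2)
  Z <- (S - panel$mu_S) / panel$sigma_S
  out <- data.frame(sample = rownames(counts) %||% seq_len(nrow(counts)),
                    S = S, Z = Z, elevated = Z >= cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "arm_z") <- zmat
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
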