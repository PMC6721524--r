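#' Kaplan-Meier estimate with the study's conventions
#'
#' Product-limit estimator (events processed before censorings at tied
#' times); the median is the smallest time with `S(t) <= 0.5` and is `NA`
#' ("not reached") when the curve never falls to 0.5.
#'
#' @param time Follow-up times in months (> 0).
#' @param event Event indicator (1 = event, 0 = censored).
#' @return Object of class `km_fit`: list with `time`, `surv` (step
#'   function values after each distinct time), `n_risk`, `n_event`,
#'   `median`, and `surv_at(t)`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("need at least one record")
  if (any(time <= 0)) stop("non-positive survival time")
  if (!all(event %in% c(0, 1))) stop("event flags must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  # median as the smallest time with S(t) <= 0.5 (no interval midpointing)
  below <- fit$surv <= 0.5 + 1e-12
  med <- if (any(below)) fit$time[which(below)[1L]] else NA_real_
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  out <- list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
              n_event = fit$n.event, median = med,
              surv_at = function(t) sf(t))
  class(out) <- "km_fit"
  out
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: %d distinct times, median %s\n",
              length(x$time),
              if (is.na(x$median)) "not reached"
              else sprintf("%.2f months", x$median)))
  invisible(x)
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Swaps event and censoring flags so censoring becomes the "event", then
#' reads off the KM median: the median potential follow-up time.
#'
#' @inheritParams km_estimate
#' @return Median follow-up in months (`NA` if not reached).
#' @export
reverse_km_median_followup <- function(time, event) {
  km_estimate(time, 1 - event)$median
}

#' Two-group log-rank test
#'
#' Standard log-rank with hypergeometric variance; p from the chi-square
#' distribution with 1 df.  A group with zero events is admissible but the
#' result is flagged.
#'
#' @param time,event Survival records.
#' @param group Two-level grouping vector.
#' @return List with `chisq`, `df`, `p`, `n_events` (per group),
#'   `zero_event_group` flag.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("logrank_test expects exactly two groups")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g)
  nev <- tapply(event, g, sum)
  list(chisq = unname(sd_$chisq), df = 1L,
       p = stats::pchisq(sd_$chisq, df = 1L, lower.tail = FALSE),
       n_events = nev,
       zero_event_group = any(nev == 0))
}

#' Scan genome-wide z-score cutoffs against survival
#'
#' Evaluates each candidate cutoff by the log-rank p-value for OS (and
#' PFS, reported alongside); the selected cutoff is the one minimizing the
#' OS p-value (ties to the smaller cutoff).  A cutoff leaving fewer than
#' two patients in either group is skipped with a reason.  Because the
#' cutoff is selected to minimize a p-value over candidates, the selected
#' p-value is optimistic; the scan table is reported in full so that this
#' selection is visible.
#'
#' @param Z Baseline genome-wide z-score per patient.
#' @param os_time,os_event,pfs_time,pfs_event Survival records per patient.
#' @param cutoffs Candidate cutoffs (default `c(2, 3, 4, 5)`).
#' @return List of class `cutoff_scan`: `table` (cutoff, admissible,
#'   n_low, n_high, p_os, p_pfs, reason), `selected` cutoff.
#' @export
scan_cutoffs <- function(Z, os_time, os_event, pfs_time, pfs_event,
                         cutoffs = c(2, 3, 4, 5)) {
  rows <- lapply(cutoffs, function(ct) {
    hi <- Z >= ct
    n_low <- sum(!hi); n_high <- sum(hi)
    if (n_low < 2L || n_high < 2L)
      return(data.frame(cutoff = ct, admissible = FALSE,
                        n_low = n_low, n_high = n_high,
                        p_os = NA_real_, p_pfs = NA_real_,
                        reason = "fewer than 2 patients in a group",
                        stringsAsFactors = FALSE))
    p_os <- logrank_test(os_time, os_event, hi)$p
    p_pfs <- logrank_test(pfs_time, pfs_event, hi)$p
    data.frame(cutoff = ct, admissible = TRUE, n_low = n_low,
               n_high = n_high, p_os = p_os, p_pfs = p_pfs, reason = "",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$admissible)
  if (!length(ok)) stop("no admissible cutoff: every split leaves a group with < 2 patients")
  sel <- tab$cutoff[ok[which.min(tab$p_os[ok])]]
  out <- list(table = tab, selected = sel)
  class(out) <- "cutoff_scan"
  out
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat("Cutoff scan (selection minimizes the OS log-rank p; optimistic by construction):\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("Selected cutoff: %g\n", x$selected))
  invisible(x)
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit via the survival package; Efron tie handling by
#' default (Breslow available).  Monotone likelihood (complete separation)
#' is detected and flagged, with the affected confidence interval reported
#' as unbounded.
#'
#' @param time,event Survival records.
#' @param covariates Data frame of covariates (e.g. z-score group and
#'   tumor subtype); none may be constant.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `coxph_fit`: `hr` (hazard ratios), `ci_lower`,
#'   `ci_upper`, `p` (Wald), `coef`, `se`, `separation` flag, and the
#'   underlying `fit`.
#' @export
cox_ph <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(event) < 1L) stop("need at least one event")
  const <- vapply(covariates, function(v) length(unique(v)) < 2L, logical(1))
  if (any(const))
    stop("constant covariate(s): ",
         paste(names(covariates)[const], collapse = ", "))
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(names(covariates), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)),
    warning = function(w) invokeRestart("muffleWarning"))
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  sep <- !is.finite(se) | se > 100 | abs(cf) > 15
  lo <- exp(cf - 1.96 * se); hi <- exp(cf + 1.96 * se)
  lo[sep] <- 0; hi[sep] <- Inf
  out <- list(hr = exp(cf), ci_lower = lo, ci_upper = hi,
              p = 2 * stats::pnorm(-abs(cf / se)),
              coef = cf, se = se, separation = sep, fit = fit)
  class(out) <- "coxph_fit"
  out
}

#' @export
print.coxph_fit <- function(x, ...) {
  tab <- data.frame(HR = round(x$hr, 3),
                    `95% CI` = sprintf("[%.3f, %.3f]", x$ci_lower, x$ci_upper),
                    p = round(x$p, 4), check.names = FALSE)
  if (any(x$separation))
    cat("note: monotone likelihood detected; affected CIs unbounded\n")
  print(tab)
  invisible(x)
}

#' Random-intercept linear mixed model for serial z-scores
#'
#' Fits `Z_ij = beta_cat(ij) + u_i + e_ij` with a patient-level random
#' intercept, `u_i ~ N(0, tau^2)`, `e_ij ~ N(0, sigma^2)` (independent
#' variance-covariance structure), by maximum likelihood.  Reports the
#' per-category mean estimates with 95% Wald confidence intervals, the
#' overall Wald test of equal category means, and pairwise Wald contrasts
#' (progression vs treatment; baseline vs treatment).
#'
#' @param data Data frame with columns named by `patient_col`,
#'   `category_col`, `value_col`.
#' @param patient_col,category_col,value_col Column names.
#' @param omit_post_progression Drop samples taken after a patient's first
#'   progression sample (requires a `week` column); mirrors restricting
#'   the monitoring analysis to the course of disease up to progression.
#' @param tau2_zero Fix the random-intercept variance at zero (degenerates
#'   to per-category means via ordinary least squares).
#' @return Object of class `lmm_fit`: `means` (estimate, se, ci per
#'   category), `tau2`, `sigma2`, `wald_overall` (chisq, df, p),
#'   `contrasts` (estimate, se, p per pairwise contrast),
#'   `boundary` flag (tau^2 estimated at ~0), `n_obs`, `n_patients`.
#' @export
lmm_random_intercept <- function(data, patient_col = "patient",
                                 category_col = "category",
                                 value_col = "z",
                                 omit_post_progression = FALSE,
                                 tau2_zero = FALSE) {
  d <- data.frame(patient = data[[patient_col]],
                  category = data[[category_col]],
                  y = data[[value_col]],
                  stringsAsFactors = FALSE)
  if (omit_post_progression) {
    if (!"week" %in% names(data))
      stop("omit_post_progression requires a 'week' column")
    d$week <- data$week
    keep <- unlist(lapply(split(seq_len(nrow(d)), d$patient), function(idx) {
      w <- d$week[idx]
      prog <- d$category[idx] == "progression"
      cut <- if (any(prog)) min(w[prog]) else Inf
      idx[w <= cut]
    }))
    d <- d[sort(keep), , drop = FALSE]
  }
  if (length(unique(d$patient)) < 2L) stop("need at least 2 patients")
  if (length(unique(d$category)) < 2L) stop("need at least 2 categories present")
  lev <- intersect(c("baseline", "treatment", "progression"),
                   unique(d$category))
  if (!length(lev)) lev <- sort(unique(d$category))
  d$category <- factor(d$category, levels = lev)

  if (tau2_zero) {
    fit <- stats::lm(y ~ 0 + category, data = d)
    beta <- stats::coef(fit); V <- stats::vcov(fit)
    tau2 <- 0; sigma2 <- summary(fit)$sigma^2; boundary <- TRUE
  } else {
    fit <- nlme::lme(y ~ 0 + category, random = ~ 1 | patient, data = d,
                     method = "ML")
    beta <- nlme::fixef(fit); V <- stats::vcov(fit)
    vc <- nlme::VarCorr(fit)
    tau2 <- as.numeric(vc["(Intercept)", "Variance"])
    sigma2 <- as.numeric(vc["Residual", "Variance"])
    boundary <- tau2 < 1e-6 * sigma2
  }
  names(beta) <- sub("^category", "", names(beta))
  se <- sqrt(diag(as.matrix(V)))
  means <- data.frame(category = names(beta), estimate = unname(beta),
                      se = unname(se),
                      ci_lower = unname(beta - 1.96 * se),
                      ci_upper = unname(beta + 1.96 * se),
                      stringsAsFactors = FALSE)

  k <- length(beta)
  C <- diff(diag(k))                       # equality of all means
  W <- drop(t(C %*% beta) %*% solve(C %*% as.matrix(V) %*% t(C)) %*% (C %*% beta))
  wald_overall <- list(chisq = W, df = k - 1L,
                       p = stats::pchisq(W, k - 1L, lower.tail = FALSE))

  ctr <- list()
  pair <- function(a, b) {
    if (!all(c(a, b) %in% names(beta))) return(NULL)
    est <- beta[a] - beta[b]
    v <- as.matrix(V); i <- match(a, names(beta)); j <- match(b, names(beta))
    s <- sqrt(v[i, i] + v[j, j] - 2 * v[i, j])
    data.frame(contrast = paste(a, "vs", b), estimate = unname(est),
               se = s, p = 2 * stats::pnorm(-abs(est / s)),
               stringsAsFactors = FALSE)
  }
  contrasts <- do.call(rbind, Filter(Negate(is.null),
                                     list(pair("progression", "treatment"),
                                          pair("baseline", "treatment"))))
  out <- list(means = means, tau2 = tau2, sigma2 = sigma2,
              wald_overall = wald_overall, contrasts = contrasts,
              boundary = boundary, n_obs = nrow(d),
              n_patients = length(unique(d$patient)), fit = fit)
  class(out) <- "lmm_fit"
  out
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept LMM (ML): %d obs, %d patients; tau^2 = %.3f, sigma^2 = %.3f%s\n",
    x$n_obs, x$n_patients, x$tau2, x$sigma2,
    if (x$boundary) " [boundary]" else ""))
  print(transform(x$means, estimate = round(estimate, 2),
                  se = round(se, 2), ci_lower = round(ci_lower, 2),
                  ci_upper = round(ci_upper, 2)), row.names = FALSE)
  cat(sprintf("Overall Wald test: chisq = %.2f (df %d), p = %.4f\n",
              x$wald_overall$chisq, x$wald_overall$df, x$wald_overall$p))
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...)
  stats::setNames(object$means$estimate, object$means$category)

# log-probability of an r x c table under fixed margins
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by direct hypergeometric enumeration: the sum of
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed table's (within a 1e-12 float-tie
#' tolerance).  This is the convention used by mainstream clinical
#' statistics software.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Object of class `contingency_result`: `observed`, `test`
#'   (`"fisher-2x2"`), `statistic` (NA), `p`, `flag`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0), all(tab == round(tab)))
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  flag <- ""
  if (any(rs == 0) || any(cs == 0)) {
    res <- list(observed = tab, test = "fisher-2x2", statistic = NA_real_,
                p = 1, flag = "zero margin; p = 1 by convention")
    class(res) <- "contingency_result"
    return(res)
  }
  k <- max(0, rs[1] - cs[2]):min(rs[1], cs[1])
  probs <- stats::dhyper(k, cs[1], cs[2], rs[1])
  p_obs <- stats::dhyper(tab[1, 1], cs[1], cs[2], rs[1])
  p <- min(1, sum(probs[probs <= p_obs + 1e-12]))
  res <- list(observed = tab, test = "fisher-2x2", statistic = NA_real_,
              p = p, flag = flag)
  class(res) <- "contingency_result"
  res
}

# enumerate all r x c tables with the given margins, calling f(table)
enumerate_tables <- function(rs, cs, f) {
  r <- length(rs); c <- length(cs)
  cells <- matrix(0L, r, c)
  rec <- function(i, j, row_left, col_left) {
    if (i == r && j == c) {
      v <- min(row_left[i], col_left[j])
      if (row_left[i] == col_left[j]) {
        cells[i, j] <<- v
        f(cells)
      }
      return(invisible())
    }
    last_in_row <- j == c
    last_row <- i == r
    lo <- if (last_row) col_left[j] else if (last_in_row) row_left[i] else
      max(0L, row_left[i] - sum(col_left[(j + 1):c]))
    hi <- min(row_left[i], col_left[j])
    if (last_row || last_in_row) {
      v <- lo
      if (v < 0 || v > hi) return(invisible())
      cells[i, j] <<- v
      rl <- row_left; cl <- col_left
      rl[i] <- rl[i] - v; cl[j] <- cl[j] - v
      if (last_in_row) rec(i + 1L, 1L, rl, cl) else rec(i, j + 1L, rl, cl)
    } else {
      for (v in lo:hi) {
        cells[i, j] <<- v
        rl <- row_left; cl <- col_left
        rl[i] <- rl[i] - v; cl[j] <- cl[j] - v
        rec(i, j + 1L, rl, cl)
      }
    }
    invisible()
  }
  rec(1L, 1L, as.integer(rs), as.integer(cs))
}

#' Fisher's exact test for an r x c table (Freeman-Halton)
#'
#' Generalizes the 2x2 exact test by full enumeration of all tables with
#' the observed margins; the two-sided p is the total probability of
#' tables no more probable than the observed one.  Limited to r*c <= 12
#' cells (enumeration bound); larger tables are rejected with advice to
#' use a Monte-Carlo approximation (out of scope here).
#'
#' @param tab r x c matrix of non-negative integer counts.
#' @return A `contingency_result` with `test = "fisher-rxc"` (or
#'   `"fisher-2x2"` for 2x2 input, to which this reduces exactly).
#' @export
fisher_exact_rxc <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), all(tab == round(tab)))
  if (all(dim(tab) == 2L)) return(fisher_exact_2x2(tab))
  if (prod(dim(tab)) > 12L)
    stop("table larger than the r*c <= 12 enumeration bound; ",
         "use a Monte-Carlo approximation")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    keep_r <- rs > 0; keep_c <- cs > 0
    sub <- tab[keep_r, keep_c, drop = FALSE]
    if (nrow(sub) < 2L || ncol(sub) < 2L) {
      res <- list(observed = tab, test = "fisher-rxc", statistic = NA_real_,
                  p = 1, flag = "degenerate margins; p = 1 by convention")
      class(res) <- "contingency_result"
      return(res)
    }
    res <- fisher_exact_rxc(sub)
    res$observed <- tab
    res$flag <- "zero margin row/column dropped"
    return(res)
  }
  lp_obs <- log_table_prob(tab)
  total <- 0
  enumerate_tables(rs, cs, function(tt) {
    lp <- log_table_prob(tt)
    if (lp <= lp_obs + 1e-12) total <<- total + exp(lp)
  })
  res <- list(observed = tab, test = "fisher-rxc", statistic = NA_real_,
              p = min(1, total), flag = "")
  class(res) <- "contingency_result"
  res
}

#' Choose and run the association test for a contingency table
#'
#' Applies the expected-count rule: Pearson chi-square (without continuity
#' correction) when every expected cell count is at least 5, otherwise the
#' exact test (2x2 or Freeman-Halton).
#'
#' @param tab Contingency table of non-negative integers.
#' @return A `contingency_result` with the additional field `rule`
#'   recording which branch fired.
#' @export
choose_association_test <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    res <- list(observed = tab, test = "chi-square",
                statistic = unname(ct$statistic), p = unname(ct$p.value),
                flag = "")
    class(res) <- "contingency_result"
    res$rule <- "all expected counts >= 5: chi-square"
  } else {
    res <- if (all(dim(tab) == 2L)) fisher_exact_2x2(tab)
           else fisher_exact_rxc(tab)
    res$rule <- "an expected count < 5: Fisher's exact test"
  }
  res
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("%s: p = %.3f%s\n", x$test, x$p,
              if (!is.na(x$statistic))
                sprintf(" (statistic %.3f)", x$statistic) else ""))
  if (nzchar(x$flag)) cat("note:", x$flag, "\n")
  invisible(x)
}

#' Pairwise Spearman correlation matrix
#'
#' Pairwise-complete Spearman correlations (average-rank ties) with the
#' per-pair sample size and a two-sided significance flag from the
#' t approximation.
#'
#' @param data Data frame of numeric columns (e.g. z-score, CTC count,
#'   CEA, CA15-3); NAs allowed.
#' @param alpha Significance level for the flag (default 0.05).
#' @return Object of class `spearman_matrix`: list of matrices `r`, `n`,
#'   `p`, `significant`, plus `note` entries for undefined pairs.
#' @export
spearman_matrix <- function(data, alpha = 0.05) {
  vars <- names(data)
  k <- length(vars)
  r <- n <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  notes <- character()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    x <- data[[i]]; y <- data[[j]]
    ok <- stats::complete.cases(x, y)
    n[i, j] <- sum(ok)
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    if (sum(ok) < 3L) {
      notes <- c(notes, sprintf("%s~%s: fewer than 3 complete pairs",
                                vars[i], vars[j]))
      next
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      notes <- c(notes, sprintf("%s~%s: constant column", vars[i], vars[j]))
      next
    }
    rho <- stats::cor(x[ok], y[ok], method = "spearman")
    r[i, j] <- rho
    m <- sum(ok)
    if (abs(rho) >= 1) { p[i, j] <- 0 } else {
      tstat <- rho * sqrt((m - 2) / (1 - rho^2))
      p[i, j] <- 2 * stats::pt(-abs(tstat), df = m - 2)
    }
  }
  out <- list(r = r, n = n, p = p, significant = p < alpha,
              note = unique(notes))
  class(out) <- "spearman_matrix"
  out
}

#' @export
print.spearman_matrix <- function(x, ...) {
  cat("Spearman correlation matrix (pairwise complete):\n")
  print(round(x$r, 2))
  if (length(x$note)) cat("notes:", paste(x$note, collapse = "; "), "\n")
  invisible(x)
}

#' Positivity overlap by inclusion-exclusion
#'
#' Given the counts of samples positive by marker A, by marker B, by
#' either, and the total, recovers the both-positive count
#' `nBoth = nA + nB - nEither` and reports all proportions to one decimal.
#'
#' @param nA,nB,nEither,total Non-negative integer counts.
#' @return List with `n_both` and percentages `pct_a`, `pct_b`,
#'   `pct_either`, `pct_both` (rounded to one decimal).
#' @export
positivity_overlap <- function(nA, nB, nEither, total) {
  if (nEither > nA + nB || any(c(nA, nB, nEither) > total) ||
      nEither < max(nA, nB) || any(c(nA, nB, nEither, total) < 0))
    stop("inconsistent positivity counts")
  n_both <- nA + nB - nEither
  pct <- function(x) round(100 * x / total, 1)
  list(n_both = n_both, pct_a = pct(nA), pct_b = pct(nB),
       pct_either = pct(nEither), pct_both = pct(n_both))
}
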