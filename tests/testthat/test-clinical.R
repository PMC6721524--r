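test_that("Kaplan-Meier matches the hand product-limit on toys", {
  # {1 censored, 2 event, 3 event}: S(2) = 1 * (1 - 1/2) = 0.5, S(3) = 0
  km <- km_estimate(c(1, 2, 3), c(0, 1, 1))
  expect_equal(km$surv_at(2), 0.5)
  expect_equal(km$surv_at(3), 0)
  expect_equal(km$median, 2)
  # all censored: flat at 1, median not reached
  km2 <- km_estimate(c(4, 5, 6), c(0, 0, 0))
  expect_equal(km2$surv_at(6), 1)
  expect_true(is.na(km2$median))
  # no censoring: empirical survival function
  t <- c(1, 2, 3, 4)
  km3 <- km_estimate(t, rep(1, 4))
  expect_equal(sapply(t, km3$surv_at), c(0.75, 0.5, 0.25, 0))
  expect_error(km_estimate(c(0, 1), c(1, 1)), "non-positive")
})

test_that("reverse KM median follow-up behaves as the flag-swapped KM", {
  # everyone followed exactly 27 months, no deaths
  expect_equal(reverse_km_median_followup(rep(27, 10), rep(0, 10)), 27)
  t <- c(3, 9, 14, 20, 27, 27)
  e <- c(1, 0, 1, 0, 0, 1)
  expect_equal(reverse_km_median_followup(t, e),
               km_estimate(t, 1 - e)$median)
  # administrative censoring at 27: median follow-up recovers the horizon
  set.seed(3)
  tt <- pmin(rexp(300, 1 / 50), 27)
  ev <- as.integer(tt < 27)
  expect_equal(reverse_km_median_followup(tt, ev), 27)
})

test_that("log-rank statistic matches a step-by-step risk-set expansion", {
  # 6 subjects, two groups, no ties
  t <- c(1, 3, 5, 2, 4, 6)
  e <- c(1, 1, 0, 1, 1, 1)
  g <- rep(c("A", "B"), each = 3)
  # independent oracle: hypergeometric expectation/variance at event times
  ord <- order(t)
  O <- E <- V <- 0
  for (i in ord) {
    if (e[i] == 0) next
    at_risk <- t >= t[i]
    n <- sum(at_risk); nA <- sum(at_risk & g == "A")
    O <- O + (g[i] == "A")
    E <- E + nA / n
    if (n > 1) V <- V + nA / n * (1 - nA / n) * 1 * (n - 1) / (n - 1)
  }
  oracle <- (O - E)^2 / V
  got <- logrank_test(t, e, g)
  expect_equal(got$chisq, oracle, tolerance = 1e-9)
  expect_equal(got$p, pchisq(oracle, 1, lower.tail = FALSE))
  # identical groups: statistic 0, p = 1
  same <- logrank_test(c(t, t), c(e, e), rep(c("A", "B"), each = 6))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  # invariance under common time rescaling
  expect_equal(logrank_test(t * 7, e, g)$chisq, got$chisq)
})

test_that("log-rank has power against a strong simulated hazard ratio", {
  set.seed(53)
  hits <- replicate(30, {
    g <- rep(0:1, each = 50)
    t <- rexp(100, rate = 0.05 * 3^g)
    cens <- runif(100, 0, 40)
    logrank_test(pmin(t, cens), as.integer(t <= cens), g)$p < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("cutoff scan selects the discriminating cutoff and reports all rows", {
  set.seed(59)
  n <- 80
  Z <- c(runif(n / 2, -1, 2.8), runif(n / 2, 3.2, 30))
  hi <- Z >= 3
  os <- rexp(n, 0.02 * ifelse(hi, 3, 1)); ose <- rep(1L, n)
  pfs <- os * 0.6; pfse <- ose
  sc <- scan_cutoffs(Z, os, ose, pfs, pfse)
  expect_equal(sc$selected, 3)
  expect_lte(nrow(sc$table), 4L)
  expect_true(all(c("p_os", "p_pfs") %in% names(sc$table)))
  # single-group data: every cutoff inadmissible
  expect_error(scan_cutoffs(rep(10, 6), os[1:6], ose[1:6], pfs[1:6],
                            pfse[1:6]),
               "no admissible cutoff")
  # a cutoff isolating < 2 patients is skipped with a reason
  Z2 <- c(1, 1, 1, 1, 4.5, 6)
  sc2 <- scan_cutoffs(Z2, os[1:6], ose[1:6], pfs[1:6], pfse[1:6])
  expect_false(sc2$table$admissible[sc2$table$cutoff == 5])
  expect_match(sc2$table$reason[sc2$table$cutoff == 5], "fewer than 2")
})

test_that("Cox fit matches a brute-force partial-likelihood grid on a toy", {
  # 4 subjects, binary covariate, no ties
  t <- c(2, 5, 7, 9); e <- c(1, 1, 1, 0); x <- c(1, 0, 1, 0)
  negpl <- function(b) {
    ll <- 0
    for (i in which(e == 1)) {
      risk <- t >= t[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    -ll
  }
  b_grid <- seq(-5, 5, by = 1e-4)
  b_oracle <- b_grid[which.min(sapply(b_grid, negpl))]
  fit <- cox_ph(t, e, data.frame(x = x))
  expect_equal(unname(fit$coef), b_oracle, tolerance = 1e-3)
  expect_error(cox_ph(t, e, data.frame(x = c(1, 1, 1, 1))), "constant")
})

test_that("Cox CI covers 1 for an independent covariate at roughly 95%", {
  set.seed(61)
  cover <- replicate(60, {
    n <- 60
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.05); cens <- runif(n, 0, 40)
    f <- cox_ph(pmin(t, cens), as.integer(t <= cens), data.frame(x = x))
    f$ci_lower <= 1 && 1 <= f$ci_upper
  })
  expect_gte(mean(cover), 0.85)
})

test_that("log-rank equals the Cox score test connection on small no-ties data", {
  t <- c(1, 3, 5, 2, 4, 6); e <- c(1, 1, 0, 1, 1, 1)
  g <- rep(0:1, each = 3)
  lr <- logrank_test(t, e, g)
  sc <- survival::coxph(survival::Surv(t, e) ~ g)
  expect_equal(lr$chisq, unname(summary(sc)$sctest["test"]),
               tolerance = 1e-6)
})

test_that("LMM collapses to per-category means with tau^2 fixed at zero", {
  set.seed(67)
  d <- data.frame(patient = rep(paste0("p", 1:10), each = 3),
                  category = rep(c("baseline", "treatment", "progression"), 10),
                  z = rnorm(30, 5, 2))
  fit <- lmm_random_intercept(d, tau2_zero = TRUE)
  means <- tapply(d$z, d$category, mean)
  expect_equal(unname(coef(fit)[names(means)]), as.numeric(means),
               tolerance = 1e-12)
  expect_equal(fit$tau2, 0)
})

test_that("LMM ML solution matches a brute-force likelihood optimum on a toy", {
  d <- data.frame(patient = rep(c("p1", "p2"), each = 4),
                  category = rep(c("baseline", "treatment"), 4),
                  z = c(5.1, 2.2, 4.8, 2.5, 8.9, 6.2, 9.3, 6.0))
  fit <- lmm_random_intercept(d)
  # independent oracle: direct ML over (b1, b2, log tau, log sigma)
  X <- model.matrix(~ 0 + category, d)
  negll <- function(par) {
    b <- par[1:2]; tau2 <- exp(par[3])^2; s2 <- exp(par[4])^2
    ll <- 0
    for (p in unique(d$patient)) {
      idx <- d$patient == p
      V <- diag(s2, sum(idx)) + tau2
      r <- d$z[idx] - X[idx, ] %*% b
      ll <- ll - 0.5 * (determinant(V)$modulus +
                          t(r) %*% solve(V, r) + sum(idx) * log(2 * pi))
    }
    -as.numeric(ll)
  }
  o <- optim(c(4, 3, 0, 0), negll, method = "BFGS")
  expect_equal(sort(unname(coef(fit))), sort(unname(o$par[1:2])),
               tolerance = 1e-3)
  expect_equal(fit$tau2, exp(o$par[3])^2, tolerance = 1e-2)
  expect_equal(fit$sigma2, exp(o$par[4])^2, tolerance = 1e-2)
})

test_that("LMM recovers simulated category means within Wald intervals", {
  set.seed(71)
  beta <- c(baseline = 8, treatment = 3, progression = 17)
  ok <- replicate(20, {
    npat <- 30
    d <- do.call(rbind, lapply(seq_len(npat), function(i) {
      cats <- c("baseline", sample(c("treatment", "progression"), 3,
                                   replace = TRUE))
      data.frame(patient = paste0("p", i), category = cats,
                 z = beta[cats] + rnorm(1, 0, 5) + rnorm(length(cats), 0, 4))
    }))
    fit <- lmm_random_intercept(d)
    est <- coef(fit)
    se <- fit$means$se[match(names(est), fit$means$category)]
    all(abs(est - beta[names(est)]) <= 2 * se)
  })
  expect_gte(mean(ok), 0.9)
})

test_that("LMM input contracts hold", {
  d <- data.frame(patient = "p1", category = c("baseline", "treatment"),
                  z = c(1, 2))
  expect_error(lmm_random_intercept(d), "2 patients")
  d2 <- data.frame(patient = c("p1", "p2"), category = "baseline",
                   z = c(1, 2))
  expect_error(lmm_random_intercept(d2), "2 categories")
})

test_that("post-progression samples can be filtered before modelling", {
  d <- data.frame(
    patient = rep(c("p1", "p2"), each = 4),
    category = c("baseline", "treatment", "progression", "treatment",
                 "baseline", "treatment", "treatment", "progression"),
    week = c(0, 4, 8, 12, 0, 3, 6, 9),
    z = c(4, 2, 9, 1, 5, 3, 2, 11))
  fit <- lmm_random_intercept(d, omit_post_progression = TRUE)
  # p1's week-12 sample follows its progression and is dropped
  expect_equal(fit$n_obs, 7L)
})

test_that("Fisher 2x2 enumeration: probabilities sum to 1 and match stats::fisher.test", {
  tabs <- list(matrix(c(18, 1, 3, 7), 2, byrow = TRUE),
               matrix(c(13, 3, 8, 5), 2, byrow = TRUE),
               matrix(c(2, 3, 17, 7), 2, byrow = TRUE),
               matrix(c(10, 5, 9, 5), 2, byrow = TRUE),
               matrix(c(0, 5, 9, 2), 2, byrow = TRUE))
  for (tb in tabs) {
    got <- fisher_exact_2x2(tb)
    expect_equal(got$p, fisher.test(tb)$p.value, tolerance = 1e-7)
    # enumeration sanity: hypergeometric probabilities over the support sum to 1
    rs <- rowSums(tb); cs <- colSums(tb)
    k <- max(0, rs[1] - cs[2]):min(rs[1], cs[1])
    expect_equal(sum(dhyper(k, cs[1], cs[2], rs[1])), 1, tolerance = 1e-12)
  }
  zm <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(zm$p, 1)
  expect_match(zm$flag, "zero margin")
})

test_that("Freeman-Halton r x c test reduces to 2x2 and matches fisher.test", {
  t32 <- matrix(c(13, 5, 0, 3, 6, 2), 3, 2, byrow = TRUE)
  got <- fisher_exact_rxc(t32)
  expect_equal(got$p, fisher.test(t32)$p.value, tolerance = 1e-7)
  t22 <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(fisher_exact_rxc(t22)$p, fisher_exact_2x2(t22)$p)
  # degenerate single-column table
  t31 <- matrix(c(2, 3, 4), 3, 1)
  expect_equal(fisher_exact_rxc(cbind(t31, 0))$p, 1)
  expect_error(fisher_exact_rxc(matrix(1, 4, 4)), "enumeration bound")
})

test_that("expected-count rule routes between chi-square and Fisher", {
  liver <- matrix(c(18, 1, 3, 7), 2, byrow = TRUE)
  r1 <- choose_association_test(liver)
  expect_equal(r1$test, "fisher-2x2")   # min expected = 10*8/29 = 2.76 < 5
  big <- matrix(c(20, 20, 20, 20), 2)
  r2 <- choose_association_test(big)
  expect_equal(r2$test, "chi-square")
  expect_equal(r2$p, chisq.test(big, correct = FALSE)$p.value)
  men <- matrix(c(10, 5, 9, 5), 2, byrow = TRUE)
  r3 <- choose_association_test(men)
  expect_equal(r3$test, "fisher-2x2")
  expect_equal(round(r3$p, 3), 1.000)
})

test_that("spearman matrix handles ties, NAs and self-correlation", {
  set.seed(73)
  d <- data.frame(z = c(1, 2, 2, 4, 5, 7, 3),
                  ctc = c(0, 0, 1, 3, 2, 8, NA),
                  cea = exp(c(1, 2, 2, 4, 5, 7, 3)))
  sm <- spearman_matrix(d)
  expect_equal(unname(diag(sm$r)), c(1, 1, 1))
  # monotone transform invariance (cea = exp(z))
  expect_equal(sm$r["z", "cea"], 1)
  # pairwise n accounts for the NA
  expect_equal(unname(sm$n["z", "ctc"]), 6)
  # ties handled by average ranks: compare to the definitional formula
  x <- d$z[1:6]; y <- d$ctc[1:6]
  expect_equal(unname(sm$r["z", "ctc"]),
               cor(rank(x), rank(y)))
  cm <- spearman_matrix(data.frame(a = c(1, 1, 1), b = c(1, 2, 3)))
  expect_true(is.na(cm$r["a", "b"]))
  expect_match(cm$note, "constant", all = FALSE)
})

test_that("positivity overlap applies inclusion-exclusion and validates input", {
  ov <- positivity_overlap(31, 49, 62, 97)
  expect_equal(ov$n_both, 18)
  expect_equal(ov$pct_both, 18.6)
  ov2 <- positivity_overlap(10, 17, 19, 29)
  expect_equal(ov2$n_both, 8)
  expect_equal(ov2$pct_either, 65.5)
  expect_equal(positivity_overlap(0, 0, 0, 10)$n_both, 0)
  expect_error(positivity_overlap(5, 5, 20, 30), "inconsistent")
})
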