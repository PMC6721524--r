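# shared fixtures built in code

# a tiny 3-arm catalog with equal weights
toy_catalog <- function() {
  make_arm_catalog(c(A = 1, B = 1, C = 1))
}

# 4-control toy count matrix with hand-enterable fractions (depth 100)
toy_controls <- function() {
  m <- rbind(c(50, 30, 20),
             c(48, 33, 19),
             c(52, 27, 21),
             c(50, 30, 20))
  dimnames(m) <- list(paste0("c", 1:4), c("A", "B", "C"))
  storage.mode(m) <- "integer"
  m
}

# independent step-by-step recomputation of a reference panel
oracle_panel <- function(controls) {
  fr <- controls / rowSums(controls)
  n <- nrow(fr)
  mu <- colMeans(fr)
  sigma <- apply(fr, 2, function(v) sqrt(sum((v - mean(v))^2) / (n - 1)))
  S <- sapply(seq_len(n), function(i) {
    rest <- fr[-i, , drop = FALSE]
    m <- colMeans(rest)
    s <- apply(rest, 2, function(v) sqrt(sum((v - mean(v))^2) / (nrow(rest) - 1)))
    sum(((fr[i, ] - m) / s)^2)
  })
  list(mu = mu, sigma = sigma, loo_S = S, mu_S = mean(S),
       sigma_S = sqrt(sum((S - mean(S))^2) / (n - 1)))
}

# hand-made panel with chosen summary statistics, for formula-level tests
fake_panel <- function(mu, sigma, mu_S, sigma_S) {
  p <- list(arms = names(mu), mu = mu, sigma = sigma,
            n_controls = 18L, loo_S = numeric(0),
            mu_S = mu_S, sigma_S = sigma_S)
  class(p) <- "ref_panel"
  p
}

# many-arm profile with odd-state anchors, identifiable at any tf
anchored_profile <- function(catalog, n_altered, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arms <- sample(catalog$arm, n_altered)
  states <- c(3L, 1L,
              sample(c(0L, 1L, 3L, 4L), n_altered - 2L, replace = TRUE))
  scna_profile(catalog, stats::setNames(states[seq_len(n_altered)], arms))
}
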