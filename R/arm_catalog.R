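#' Build a chromosome-arm catalog
#'
#' An arm catalog fixes the set of chromosome arms used throughout the
#' pipeline together with each arm's expected share of reads in a diploid
#' (copy-neutral) genome.  The default catalog contains the 39 autosomal
#' arms commonly used for arm-level cfDNA aneuploidy scoring: the
#' acrocentric short arms (13p, 14p, 15p, 21p, 22p) and the sex chromosomes
#' are excluded, and weights are proportional to approximate GRCh37 arm
#' lengths.
#'
#' @param weights A named numeric vector or a two-column data frame
#'   (arm, weight) of strictly positive arm weights.  `NULL` (default)
#'   loads the packaged GRCh37 arm-length table.
#' @return An object of class `arm_catalog`: a data frame with columns
#'   `arm` and `weight`, weights renormalized to sum to 1.
#' @examples
#' cat39 <- make_arm_catalog()
#' nrow(cat39)          # 39
#' sum(cat39$weight)    # 1
#' @export
make_arm_catalog <- function(weights = NULL) {
  if (is.null(weights)) {
    path <- system.file("extdata", "grch37_arm_weights.tsv",
                        package = "plasmaZ", mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    weights <- stats::setNames(tab$length_mb, tab$arm)
  }
  if (is.data.frame(weights)) {
    if (ncol(weights) < 2L)
      stop("weights data frame must have columns (arm, weight)")
    weights <- stats::setNames(as.numeric(weights[[2L]]),
                               as.character(weights[[1L]]))
  }
  arms <- names(weights)
  if (is.null(arms) || anyNA(arms) || any(arms == ""))
    stop("every arm weight must be named with its arm identifier")
  if (anyDuplicated(arms))
    stop("duplicate arm identifiers: ",
         paste(unique(arms[duplicated(arms)]), collapse = ", "))
  bad <- arms[!is.finite(weights) | weights <= 0]
  if (length(bad))
    stop("non-positive or missing weight for arm(s): ",
         paste(bad, collapse = ", "))
  out <- data.frame(arm = arms, weight = as.numeric(weights) / sum(weights),
                    stringsAsFactors = FALSE)
  class(out) <- c("arm_catalog", "data.frame")
  out
}

#' @export
print.arm_catalog <- function(x, ...) {
  cat(sprintf("Chromosome-arm catalog: %d arms (%s ... %s)\n",
              nrow(x), x$arm[1L], x$arm[nrow(x)]))
  invisible(x)
}

#' Define a somatic copy-number profile over a catalog
#'
#' A profile assigns one integer copy state per catalog arm (2 = neutral).
#' Profiles describe the tumor component of a diploid/tumor cfDNA mixture.
#'
#' @param catalog An [make_arm_catalog()] catalog.
#' @param alterations Named integer vector of non-neutral states, e.g.
#'   `c("8q" = 3, "17p" = 1)`.  Unlisted arms are neutral (2).
#' @param label Free-text label for the profile.
#' @return Object of class `scna_profile`: data frame with columns `arm`,
#'   `copy_number`, plus a `label` attribute.
#' @export
scna_profile <- function(catalog, alterations = integer(), label = "") {
  cn <- stats::setNames(rep(2L, nrow(catalog)), catalog$arm)
  if (length(alterations)) {
    unknown <- setdiff(names(alterations), catalog$arm)
    if (length(unknown))
      stop("alterations name arms absent from the catalog: ",
           paste(unknown, collapse = ", "))
    if (any(alterations < 0) || any(alterations != round(alterations)))
      stop("copy states must be non-negative integers")
    cn[names(alterations)] <- as.integer(alterations)
  }
  out <- data.frame(arm = catalog$arm, copy_number = unname(cn),
                    stringsAsFactors = FALSE)
  attr(out, "label") <- label
  class(out) <- c("scna_profile", "data.frame")
  out
}

#' Draw a random somatic copy-number profile
#'
#' Picks `n_altered` arms uniformly without replacement and assigns each a
#' state from `states` (gains and losses), leaving the rest neutral.
#'
#' @param catalog Arm catalog.
#' @param n_altered Number of altered arms (1 to `nrow(catalog)`).
#' @param states Candidate non-neutral states, default `c(0,1,3,4)`.
#' @param state_probs Sampling weights over `states`; the default favors
#'   single-copy losses and gains over homozygous deletions and
#'   double gains, as in typical arm-level tumor profiles.
#' @param label Profile label.
#' @return An `scna_profile`.
#' @export
random_scna_profile <- function(catalog, n_altered,
                                states = c(0L, 1L, 3L, 4L),
                                state_probs = c(0.1, 0.35, 0.35, 0.2),
                                label = "") {
  n_altered <- as.integer(n_altered)
  if (n_altered < 1L || n_altered > nrow(catalog))
    stop("n_altered must be between 1 and the number of catalog arms")
  arms <- sample(catalog$arm, n_altered)
  alt <- stats::setNames(
    sample(states, n_altered, replace = TRUE, prob = state_probs), arms)
  scna_profile(catalog, alt, label = label)
}

#' Expected arm read fractions of a diploid/tumor mixture
#'
#' At tumor fraction `tf`, the expected read share of arm a is proportional
#' to `w_a * ((1 - tf) * 2 + tf * cn_a) / 2`, renormalized over arms.  At
#' `tf = 0` (or an all-neutral profile) this collapses to the catalog
#' weights.
#'
#' @param catalog Arm catalog.
#' @param profile `scna_profile` over the same catalog.
#' @param tf Tumor fraction in `[0, 1)`.
#' @return Named numeric vector of expected fractions (sums to 1).
#' @export
expected_arm_fractions <- function(catalog, profile, tf) {
  stopifnot(identical(catalog$arm, profile$arm))
  if (!is.numeric(tf) || length(tf) != 1L || tf < 0 || tf >= 1)
    stop("tf must be a single value in [0, 1)")
  raw <- catalog$weight * ((1 - tf) * 2 + tf * profile$copy_number) / 2
  stats::setNames(raw / sum(raw), catalog$arm)
}
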