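#' Resample reference-cohort ICCs at a matched sample size
#'
#' Builds the reference distribution of test-retest ICCs that an n-subject
#' travelling-heads estimate should be compared against: from a large
#' two-visit reference cohort, repeatedly draw `subset_size` subjects
#' without replacement (draws independent of one another), compute the
#' consistency ICC on each subset-by-2 matrix, and collect the `n_resamples`
#' values. Subject draws are integer-indexed against the lexicographically
#' sorted subject list, so the distribution is reproducible from the seed
#' across platforms.
#'
#' @param reference An [idp_table()] with exactly two sessions (a
#'   test-retest cohort).
#' @param idp_name IDP to resample.
#' @param subset_size Subjects per draw; default 8, matching the
#'   travelling-heads design being benchmarked.
#' @param n_resamples Number of draws; default 1000.
#' @param seed Integer seed.
#' @param method Passed to [icc_consistency()].
#' @return An object of class `reference_distribution`: list with
#'   `idp_name`, `icc_samples`, `subset_size`, `n_resamples`, `seed`,
#'   `n_available`.
#' @export
#' @examples
#' ref <- generate_reference_cohort(200, idp_specs_from_icc(1, 0.66), seed = 3)
#' rd <- resample_reference_iccs(ref, "idp_0001", n_resamples = 100, seed = 4)
#' rd
resample_reference_iccs <- function(reference, idp_name, subset_size = 8,
                                    n_resamples = 1000, seed = 1L,
                                    method = c("anova", "reml")) {
  stopifnot(inherits(reference, "idp_table"))
  method <- match.arg(method)
  if (nrow(reference$sessions) != 2L) {
    stop_idprel("Reference cohort must have exactly 2 sessions.",
                "idprel_config_error")
  }
  m <- extract_matrix(reference, idp_name)
  n <- nrow(m)
  if (subset_size > n) {
    stop_idprel(sprintf("subset_size (%d) exceeds available subjects (%d).",
                        subset_size, n),
                "idprel_config_error")
  }
  if (subset_size < 3) {
    stop_idprel("subset_size must be >= 3.", "idprel_config_error")
  }
  samples <- with_seed(seed, vapply(seq_len(n_resamples), function(b) {
    idx <- sample.int(n, subset_size)
    icc_consistency(m[idx, , drop = FALSE], method = method)$icc
  }, numeric(1)))
  structure(list(idp_name = idp_name, icc_samples = samples,
                 subset_size = as.integer(subset_size),
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed), n_available = n),
            class = "reference_distribution")
}

#' @export
print.reference_distribution <- function(x, ...) {
  cat(sprintf(
    "<reference_distribution> %s: %d ICCs from %d-subject draws (of %d), seed %d\n",
    x$idp_name, x$n_resamples, x$subset_size, x$n_available, x$seed))
  print(summary(x$icc_samples), ...)
  invisible(x)
}

#' Empirical two-sided p-value against a resampled reference distribution
#'
#' Tests whether an observed multi-site ICC could have been drawn from the
#' reference test-retest distribution, using the add-one doubled-tail
#' convention:
#' `p = min(1, 2 min((1 + #{icc* <= obs})/(B+1), (1 + #{icc* >= obs})/(B+1)))`.
#' The add-one form never returns 0 from a finite number of draws.
#'
#' @param icc_observed Observed ICC(s); vectorised.
#' @param ref A [resample_reference_iccs()] result.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
empirical_two_sided_p <- function(icc_observed, ref) {
  stopifnot(inherits(ref, "reference_distribution"))
  s <- ref$icc_samples
  b <- length(s)
  if (!b) stop_idprel("Reference distribution is empty.", "idprel_input_error")
  vapply(icc_observed, function(x) {
    if (is.na(x)) return(NA_real_)
    lo <- (1 + sum(s <= x)) / (b + 1)
    hi <- (1 + sum(s >= x)) / (b + 1)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
}

#' Concordance of per-IDP ICCs across two cohorts
#'
#' Pearson and Spearman correlations of ICC estimates over the IDPs shared
#' by two cohorts (e.g. multi-site travelling-heads versus single-site
#' test-retest), quantifying whether the same phenotypes are reliable in
#' both.
#'
#' @param icc_a,icc_b Data frames with columns `idp_name` and `icc`, or
#'   named numeric vectors.
#' @return One-row tibble with `pearson_r`, `spearman_rho`, `n_idps`,
#'   `degenerate` (TRUE when either vector is constant, leaving r
#'   undefined).
#' @export
icc_concordance <- function(icc_a, icc_b) {
  as_pairs <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(all(c("idp_name", "icc") %in% names(x)))
      stats::setNames(x$icc, x$idp_name)
    } else if (!is.null(names(x))) {
      x
    } else {
      stop_idprel("Inputs must be data frames (idp_name, icc) or named vectors.",
                  "idprel_input_error")
    }
  }
  a <- as_pairs(icc_a)
  b <- as_pairs(icc_b)
  shared <- intersect(names(a), names(b))
  av <- a[shared]
  bv <- b[shared]
  ok <- is.finite(av) & is.finite(bv)
  av <- av[ok]
  bv <- bv[ok]
  if (length(av) < 3) {
    stop_idprel(sprintf("Need >= 3 shared estimable IDPs, got %d.", length(av)),
                "idprel_insufficient_data")
  }
  degenerate <- sd(av) == 0 || sd(bv) == 0
  tibble::tibble(
    pearson_r = if (degenerate) NA_real_ else cor(av, bv, method = "pearson"),
    spearman_rho = if (degenerate) NA_real_ else cor(av, bv, method = "spearman"),
    n_idps = length(av),
    degenerate = degenerate
  )
}

#' Quantile summary of a reference ICC distribution
#'
#' Plotting-ready quantiles (2.5, 25, 50, 75, 97.5%) of the resampled
#' reference ICCs, the numbers behind a violin/box display of the
#' benchmark band.
#'
#' @param ref A [resample_reference_iccs()] result.
#' @return Tibble with `quantile` (probability) and `icc`.
#' @export
reference_violin_summary <- function(ref) {
  stopifnot(inherits(ref, "reference_distribution"))
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  tibble::tibble(quantile = probs,
                 icc = unname(quantile(ref$icc_samples, probs, names = FALSE)))
}

#' @export
#' @importFrom generics tidy
#' @rdname reference_distribution_methods
#' @title Broom-style methods for reference distributions
#' @description `tidy()` returns the resampled ICCs one per row; `glance()`
#'   returns a one-row summary with quantiles and draw metadata.
#' @param x A `reference_distribution`.
#' @param ... Unused.
tidy.reference_distribution <- function(x, ...) {
  tibble::tibble(idp_name = x$idp_name,
                 draw = seq_along(x$icc_samples),
                 icc = x$icc_samples)
}

#' @export
#' @importFrom generics glance
#' @rdname reference_distribution_methods
glance.reference_distribution <- function(x, ...) {
  qs <- quantile(x$icc_samples, c(0.025, 0.5, 0.975), names = FALSE)
  tibble::tibble(idp_name = x$idp_name, n_resamples = x$n_resamples,
                 subset_size = x$subset_size, mean_icc = mean(x$icc_samples),
                 sd_icc = sd(x$icc_samples),
                 q025 = qs[1], median = qs[2], q975 = qs[3],
                 seed = x$seed)
}
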