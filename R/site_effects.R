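# Two-way within-subject sums-of-squares decomposition shared by the ANOVA
# and ICC routines: SS_total = SS_subjects + SS_sessions + SS_error.
ss_decompose <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  gm <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  ss_subjects <- k * sum((rowm - gm)^2)
  ss_sessions <- n * sum((colm - gm)^2)
  resid <- m - outer(rowm, colm, "+") + gm
  ss_error <- sum(resid^2)
  list(n = n, k = k, grand_mean = gm,
       ss_subjects = ss_subjects, ss_sessions = ss_sessions,
       ss_error = ss_error, residuals = resid,
       ms_subjects = ss_subjects / (n - 1),
       ms_sessions = ss_sessions / (k - 1),
       ms_error = ss_error / ((n - 1) * (k - 1)),
       session_means = colm)
}

# SS_error == 0 up to rounding marks a perfectly additive matrix.
is_degenerate_error <- function(d) {
  tol <- 1e-12 * max(1, d$ss_subjects + d$ss_sessions)
  d$ss_error <= tol
}

#' Repeated-measures ANOVA for a session (site) effect
#'
#' One-way within-subject ANOVA on a complete subject-by-session matrix,
#' testing the null hypothesis of zero between-session difference in mean.
#' Uses the two-way decomposition
#' `SS_total = SS_subjects + SS_sessions + SS_error` with
#' `F = MS_sessions / MS_error` on `(k-1, (n-1)(k-1))` degrees of freedom.
#'
#' Effect size is partial eta-squared
#' `SS_sessions / (SS_sessions + SS_error)` by default (the within-subject
#' convention); classical eta-squared `SS_sessions / SS_total` is also
#' returned. `p_reported` equals `p_uncorrected` until [apply_gg()]
#' substitutes a sphericity-corrected value.
#'
#' A perfectly additive matrix (zero residual) is flagged `degenerate` and
#' reported as `F = Inf`, `p = 0` rather than erroring, so scans over
#' thousands of IDPs never abort.
#'
#' @param m Complete numeric n x k matrix (subjects x sessions), `n >= 3`,
#'   `k >= 2`; see [extract_matrix()].
#' @param eta Which eta-squared to place in `eta_squared`:
#'   `"partial"` (default) or `"classical"`.
#' @return One-row tibble with `F`, `df_effect`, `df_error`,
#'   `p_uncorrected`, `p_reported`, `eta_squared`, `eta_squared_classical`,
#'   mean squares, `gg_applied` and `degenerate`.
#' @export
#' @examples
#' m <- matrix(rnorm(32), 8, 4)
#' rm_anova(m)
rm_anova <- function(m, eta = c("partial", "classical")) {
  eta <- match.arg(eta)
  assert_matrix_input(m)
  d <- ss_decompose(m)
  df1 <- d$k - 1
  df2 <- (d$n - 1) * (d$k - 1)
  degenerate <- is_degenerate_error(d)
  eta_p <- if (d$ss_sessions + d$ss_error > 0) {
    d$ss_sessions / (d$ss_sessions + d$ss_error)
  } else 0
  eta_c <- if (d$ss_subjects + d$ss_sessions + d$ss_error > 0) {
    d$ss_sessions / (d$ss_subjects + d$ss_sessions + d$ss_error)
  } else 0
  if (degenerate) {
    f <- if (d$ss_sessions > 0) Inf else 0
    p <- if (d$ss_sessions > 0) 0 else 1
  } else {
    f <- d$ms_sessions / d$ms_error
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  tibble::tibble(
    F = f, df_effect = df1, df_error = df2,
    p_uncorrected = p, p_reported = p,
    eta_squared = if (eta == "partial") eta_p else eta_c,
    eta_squared_partial = eta_p, eta_squared_classical = eta_c,
    ms_subjects = d$ms_subjects, ms_error = d$ms_error,
    ss_sessions = d$ss_sessions, ss_error = d$ss_error,
    n_subjects = d$n, k_sessions = d$k,
    gg_applied = FALSE, degenerate = degenerate
  )
}

# Orthonormal (k-1) x k contrast basis (normalised Helmert rows).
contrast_basis <- function(k) {
  h <- t(stats::contr.helmert(k))
  h / sqrt(rowSums(h^2))
}

#' Mauchly's test of sphericity and Greenhouse-Geisser epsilon
#'
#' Tests whether the covariance of the session columns is spherical (equal
#' variances of all pairwise session differences), the assumption under
#' which the repeated-measures F statistic has its nominal null
#' distribution. A sphericity violation indicates a between-session
#' difference in the scale of the measurements, independent of any mean
#' shift.
#'
#' With `C` an orthonormal contrast basis and `S` the sample covariance of
#' the session columns, `W = det(CSC') / (tr(CSC')/(k-1))^(k-1)` and the
#' chi-square approximation uses the standard Box correction factor. The
#' Greenhouse-Geisser epsilon is
#' `(tr CSC')^2 / ((k-1) tr((CSC')^2))`, bounded in `[1/(k-1), 1]`.
#'
#' For `k = 2` sphericity holds by construction (`W = 1`, `p = 1`,
#' `epsilon = 1`). When the contrast covariance is singular (e.g.
#' `n <= k - 1`) the test is not estimable: `estimable = FALSE` and epsilon
#' is set to its conservative lower bound `1/(k-1)`.
#'
#' @inheritParams rm_anova
#' @return One-row tibble with `W`, `chi_square`, `df`, `p`, `epsilon_gg`,
#'   `estimable`.
#' @export
mauchly_test <- function(m) {
  assert_matrix_input(m, min_n = 3L)
  n <- nrow(m)
  k <- ncol(m)
  if (k == 2L) {
    return(tibble::tibble(W = 1, chi_square = 0, df = 0L, p = 1,
                          epsilon_gg = 1, estimable = TRUE))
  }
  cmat <- contrast_basis(k)
  s <- stats::cov(m)
  v <- cmat %*% s %*% t(cmat)
  lambda <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-12 * max(abs(lambda), 1)
  if (n <= k - 1 || min(lambda) <= tol) {
    return(tibble::tibble(W = NA_real_, chi_square = NA_real_,
                          df = as.integer(k * (k - 1) / 2 - 1), p = NA_real_,
                          epsilon_gg = 1 / (k - 1), estimable = FALSE))
  }
  w <- prod(lambda) / (mean(lambda))^(k - 1)
  w <- min(w, 1)
  q <- k - 1
  d <- 1 - (2 * q^2 + q + 2) / (6 * q * (n - 1))
  chi <- -(n - 1) * d * log(w)
  df <- as.integer(k * (k - 1) / 2 - 1)
  p <- pchisq(chi, df, lower.tail = FALSE)
  eps <- sum(lambda)^2 / (q * sum(lambda^2))
  tibble::tibble(W = w, chi_square = chi, df = df, p = p,
                 epsilon_gg = min(max(eps, 1 / q), 1), estimable = TRUE)
}

#' Apply the Greenhouse-Geisser correction to an ANOVA result
#'
#' When Mauchly's test detects a sphericity violation at
#' `alpha_sphericity`, both ANOVA degrees of freedom are multiplied by the
#' Greenhouse-Geisser epsilon and the p-value is recomputed from the same F
#' statistic; otherwise the result is returned unchanged. The corrected (or
#' untouched) value lands in `p_reported`.
#'
#' @param anova One-row tibble from [rm_anova()].
#' @param sphericity One-row tibble from [mauchly_test()] on the same matrix.
#' @param alpha_sphericity Detection threshold for the Mauchly p-value,
#'   default 0.05. A non-estimable Mauchly test triggers the conservative
#'   correction (epsilon at its lower bound).
#' @return The ANOVA tibble with `df_effect`, `df_error`, `p_reported`,
#'   `gg_applied` and `epsilon_applied` updated.
#' @export
apply_gg <- function(anova, sphericity, alpha_sphericity = 0.05) {
  correct <- if (!sphericity$estimable) TRUE else {
    isTRUE(sphericity$p < alpha_sphericity)
  }
  anova$epsilon_applied <- 1
  if (correct && !anova$degenerate) {
    eps <- sphericity$epsilon_gg
    anova$df_effect <- anova$df_effect * eps
    anova$df_error <- anova$df_error * eps
    anova$p_reported <- pf(anova$F, anova$df_effect, anova$df_error,
                           lower.tail = FALSE)
    anova$gg_applied <- TRUE
    anova$epsilon_applied <- eps
  }
  anova
}

#' Friedman rank test for a session effect
#'
#' Nonparametric within-subject analogue of [rm_anova()]: values are ranked
#' within each subject (mid-ranks for ties) and the chi-square statistic
#' `Q = [12 sum_j R_j^2 - 3 n^2 k (k+1)^2] / (n k (k+1))`, divided by the
#' standard tie-correction factor, is referred to a chi-square distribution
#' with `k - 1` degrees of freedom. The statistic is invariant to any
#' monotone within-subject transformation of the data.
#'
#' @inheritParams rm_anova
#' @return One-row tibble with `Q`, `df`, `p`.
#' @export
friedman_test <- function(m) {
  assert_matrix_input(m)
  n <- nrow(m)
  k <- ncol(m)
  r <- t(apply(m, 1L, rank))
  rj <- colSums(r)
  q_raw <- (12 * sum(rj^2) - 3 * n^2 * k * (k + 1)^2) / (n * k * (k + 1))
  # tie correction: sum of (t^3 - t) over tie groups within each subject
  ties <- sum(vapply(seq_len(n), function(i) {
    t <- table(m[i, ])
    sum(t^3 - t)
  }, numeric(1)))
  cfac <- 1 - ties / (n * k * (k^2 - 1))
  if (cfac <= 0) {
    q <- 0
    p <- 1
  } else {
    q <- q_raw / cfac
    p <- pchisq(q, k - 1, lower.tail = FALSE)
  }
  tibble::tibble(Q = q, df = as.integer(k - 1), p = p)
}

#' Shapiro-Wilk normality test on ANOVA residuals
#'
#' Tests normality of the doubly-centred residuals
#' `r_ij = y_ij - rowmean_i - colmean_j + grandmean`, the quantities whose
#' normality the repeated-measures F test actually assumes. Residuals with
#' (numerically) zero variance are reported as not estimable.
#'
#' @inheritParams rm_anova
#' @return One-row tibble with `statistic`, `p`, `estimable`.
#' @export
shapiro_residuals <- function(m) {
  assert_matrix_input(m)
  r <- as.vector(ss_decompose(m)$residuals)
  if (length(r) < 3 || sd(r) <= 1e-10 * max(1, max(abs(r)))) {
    return(tibble::tibble(statistic = NA_real_, p = NA_real_, estimable = FALSE))
  }
  if (length(r) > 5000) r <- r[round(seq(1, length(r), length.out = 5000))]
  sw <- shapiro.test(r)
  tibble::tibble(statistic = unname(sw$statistic), p = sw$p.value,
                 estimable = TRUE)
}

#' Class-wise false-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up adjustment applied independently within each
#' IDP class, controlling the FDR at level `q` separately per class. The
#' within-class adjustment can reject a different set than a pooled
#' adjustment of the same p-values; classes with heterogeneous signal
#' density are exactly where the two differ.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed;
#'   propagated).
#' @param grouping Class label per p-value (recycled if length 1).
#' @param q FDR level, default 0.05.
#' @return Tibble with `p`, `class_label`, `p_adjusted`, `significant`.
#' @export
fdr_adjust <- function(p_values, grouping = "all", q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_idprel("p-values must lie in [0, 1].", "idprel_input_error")
  }
  out <- tibble::tibble(p = as.numeric(p_values),
                        class_label = rep_len(as.character(grouping),
                                              length(p_values)))
  out <- dplyr::mutate(dplyr::group_by(out, .data$class_label),
                       p_adjusted = p.adjust(.data$p, method = "BH"))
  out <- dplyr::ungroup(out)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted <= q
  out
}

#' Run the full per-IDP site-effect battery
#'
#' For every IDP in the table (restricted to the requested session subset):
#' repeated-measures ANOVA, Mauchly sphericity with Greenhouse-Geisser
#' correction gated at `alpha_sphericity`, Shapiro-Wilk on residuals,
#' Friedman cross-check, then class-wise Benjamini-Hochberg FDR on the
#' reported ANOVA p-values. IDPs with fewer than 3 complete subjects are
#' reported as skipped rows, never dropped silently.
#'
#' @param table An [idp_table()].
#' @param sessions Character vector of session labels (default: all).
#' @param q FDR level within each class, default 0.05.
#' @param alpha_sphericity Mauchly gate for the GG correction, default 0.05.
#' @param eta Passed to [rm_anova()].
#' @return Tibble, one row per IDP, with test statistics, FDR flags,
#'   `skipped` and `skip_reason`.
#' @export
site_effect_scan <- function(table, sessions = NULL, q = 0.05,
                             alpha_sphericity = 0.05,
                             eta = c("partial", "classical")) {
  stopifnot(inherits(table, "idp_table"))
  eta <- match.arg(eta)
  if (is.null(sessions)) sessions <- table$sessions$session_label
  idps <- table$classes$idp_name
  mats <- scan_matrices(table, sessions)

  rows <- purrr::map(idps, function(idp) {
    m <- mats[[idp]]
    if (is.null(m) || nrow(m) < 3L) {
      n_complete <- if (is.null(m)) 0L else nrow(m)
      return(tibble::tibble(
        idp_name = idp, skipped = TRUE,
        skip_reason = sprintf("only %d complete subjects (need >= 3)", n_complete),
        n_subjects = n_complete
      ))
    }
    an <- rm_anova(m, eta = eta)
    sph <- mauchly_test(m)
    an <- apply_gg(an, sph, alpha_sphericity)
    sw <- shapiro_residuals(m)
    fr <- friedman_test(m)
    tibble::tibble(
      idp_name = idp, skipped = FALSE, skip_reason = NA_character_,
      n_subjects = an$n_subjects, k_sessions = an$k_sessions,
      F = an$F, df_effect = an$df_effect, df_error = an$df_error,
      p_uncorrected = an$p_uncorrected, p_reported = an$p_reported,
      eta_squared = an$eta_squared, gg_applied = an$gg_applied,
      degenerate = an$degenerate,
      mauchly_w = sph$W, mauchly_p = sph$p, epsilon_gg = sph$epsilon_gg,
      sphericity_estimable = sph$estimable,
      shapiro_stat = sw$statistic, shapiro_p = sw$p,
      friedman_q = fr$Q, friedman_p = fr$p
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::left_join(out, table$classes, by = "idp_name")

  adj <- fdr_adjust(ifelse(out$skipped, NA_real_, out$p_reported),
                    out$class_label, q = q)
  out$p_fdr <- adj$p_adjusted
  out$significant <- adj$significant
  dplyr::relocate(out, "idp_name", "class_label")
}
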