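#' Consistency intra-class correlation ICC(3,1) from variance components
#'
#' Estimates the "consistency" ICC of a two-way model with session (site)
#' as a fixed effect and subject as a random effect — the ICC that ignores
#' additive session offsets and quantifies how well the ranking of subjects
#' is preserved across sessions.
#'
#' Two estimators are available on the balanced complete-case matrix:
#' \describe{
#'   \item{`"anova"`}{Closed form from the two-way mean squares,
#'     `(MS_subjects - MS_error) / (MS_subjects + (k-1) MS_error)`. Can be
#'     negative in small samples; negative values are reported raw with a
#'     `negative` flag and never silently truncated (truncation biases
#'     class means upward at n = 8).}
#'   \item{`"reml"`}{REML fit of `y_ij = mu + beta_j + a_i + e_ij` with
#'     fixed session effects and a random subject intercept. For a balanced
#'     design this has the closed-form solution
#'     `sigma2_error = MS_error`,
#'     `sigma2_subject = max(0, (MS_subjects - MS_error)/k)`, so the REML
#'     ICC equals the ANOVA ICC whenever the latter is non-negative.}
#' }
#'
#' ICC values between 0.5 and 0.8 are conventionally read as fair-to-good
#' reliability, above 0.8 (0.9) as good (very good).
#'
#' @inheritParams rm_anova
#' @param method `"anova"` (default) or `"reml"`.
#' @return One-row tibble with `icc`, `sigma2_subject`, `sigma2_error`,
#'   `n_subjects`, `k_sessions`, `method`, `degenerate`, `negative`.
#'   `MS_error = 0` yields `icc = 1` with the degenerate flag set.
#' @export
#' @examples
#' tbl <- generate_travelling_heads(specs = idp_specs_from_icc(1, 0.8), seed = 2)
#' icc_consistency(extract_matrix(tbl, "idp_0001"))
icc_consistency <- function(m, method = c("anova", "reml")) {
  method <- match.arg(method)
  assert_matrix_input(m)
  d <- ss_decompose(m)
  k <- d$k
  degenerate <- is_degenerate_error(d)
  if (degenerate) {
    return(tibble::tibble(icc = 1,
                          sigma2_subject = (d$ms_subjects - d$ms_error) / k,
                          sigma2_error = 0,
                          n_subjects = d$n, k_sessions = k, method = method,
                          degenerate = TRUE, negative = FALSE))
  }
  if (method == "anova") {
    icc <- (d$ms_subjects - d$ms_error) / (d$ms_subjects + (k - 1) * d$ms_error)
    s2s <- (d$ms_subjects - d$ms_error) / k  # raw, may be negative
    s2e <- d$ms_error
  } else {
    s2e <- d$ms_error
    s2s <- max(0, (d$ms_subjects - d$ms_error) / k)
    icc <- s2s / (s2s + s2e)
  }
  tibble::tibble(icc = icc, sigma2_subject = s2s, sigma2_error = s2e,
                 n_subjects = d$n, k_sessions = k, method = method,
                 degenerate = FALSE, negative = icc < 0)
}

#' Per-IDP ICC scan over a session subset
#'
#' Computes the consistency ICC for every IDP in the table over the
#' requested sessions, using complete cases per IDP. IDPs with fewer than 3
#' complete subjects are reported as skipped rows.
#'
#' @inheritParams site_effect_scan
#' @param method Passed to [icc_consistency()].
#' @return Tibble, one row per IDP, with class labels, `icc`, variance
#'   components and skip flags.
#' @export
icc_scan <- function(table, sessions = NULL, method = c("anova", "reml")) {
  stopifnot(inherits(table, "idp_table"))
  method <- match.arg(method)
  if (is.null(sessions)) sessions <- table$sessions$session_label
  mats <- scan_matrices(table, sessions)
  rows <- purrr::map(table$classes$idp_name, function(idp) {
    m <- mats[[idp]]
    if (is.null(m) || nrow(m) < 3L) {
      n_complete <- if (is.null(m)) 0L else nrow(m)
      return(tibble::tibble(idp_name = idp, skipped = TRUE,
                            skip_reason = sprintf(
                              "only %d complete subjects (need >= 3)", n_complete)))
    }
    res <- icc_consistency(m, method = method)
    dplyr::bind_cols(tibble::tibble(idp_name = idp, skipped = FALSE,
                                    skip_reason = NA_character_), res)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::left_join(out, table$classes, by = "idp_name")
  dplyr::relocate(out, "idp_name", "class_label")
}

#' Pairwise-site ICCs for one IDP
#'
#' Consistency ICC for every unordered pair of the requested sessions
#' (k = 2 per pair), with complete cases per pair. Pairs with fewer than 3
#' complete subjects are reported as skipped.
#'
#' @param table An [idp_table()].
#' @param idp_name IDP to analyse.
#' @param sessions Session labels; default all. Four sessions yield 6 pairs.
#' @param method Passed to [icc_consistency()].
#' @return Tibble with one row per pair: `session_a`, `session_b`, `icc`,
#'   `n_subjects`, `skipped`.
#' @export
pairwise_icc <- function(table, idp_name, sessions = NULL,
                         method = c("anova", "reml")) {
  stopifnot(inherits(table, "idp_table"))
  method <- match.arg(method)
  if (is.null(sessions)) sessions <- table$sessions$session_label
  sessions <- sort(unique(sessions))
  if (length(sessions) < 2) {
    stop_idprel("Need at least 2 sessions for pairwise ICCs.",
                "idprel_config_error")
  }
  pairs <- combn(sessions, 2L)
  rows <- purrr::map(seq_len(ncol(pairs)), function(j) {
    pr <- pairs[, j]
    base <- tibble::tibble(session_a = pr[1L], session_b = pr[2L])
    m <- tryCatch(extract_matrix(table, idp_name, pr),
                  idprel_insufficient_data = function(e) e)
    if (inherits(m, "condition")) {
      base$icc <- NA_real_
      base$n_subjects <- NA_integer_
      base$skipped <- TRUE
      return(base)
    }
    res <- icc_consistency(m, method = method)
    base$icc <- res$icc
    base$n_subjects <- res$n_subjects
    base$skipped <- FALSE
    base
  })
  dplyr::bind_rows(rows)
}

#' Between-site correlation matrix for one IDP
#'
#' k x k matrix of between-session correlations of subject values: Pearson
#' correlations in the upper triangle, Spearman (mid-rank ties) in the
#' lower triangle, 1 on the diagonal — the standard compact display for
#' pairwise site agreement. Columns with zero variance produce `NA` entries
#' and are listed in the `degenerate_sessions` attribute.
#'
#' @inheritParams rm_anova
#' @return A k x k numeric matrix with session dimnames, class
#'   `site_correlation`.
#' @export
site_correlation_matrix <- function(m) {
  assert_matrix_input(m)
  k <- ncol(m)
  out <- diag(1, k)
  dimnames(out) <- list(colnames(m), colnames(m))
  sds <- apply(m, 2L, sd)
  degen <- colnames(m)[sds == 0]
  for (j in seq_len(k - 1)) {
    for (l in (j + 1):k) {
      if (sds[j] == 0 || sds[l] == 0) {
        out[j, l] <- NA_real_
        out[l, j] <- NA_real_
      } else {
        out[j, l] <- cor(m[, j], m[, l], method = "pearson")
        out[l, j] <- cor(m[, j], m[, l], method = "spearman")
      }
    }
  }
  structure(out, class = c("site_correlation", "matrix", "array"),
            degenerate_sessions = degen)
}

#' @export
print.site_correlation <- function(x, digits = 3, ...) {
  cat("<site_correlation> upper: Pearson, lower: Spearman\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Class-level ICC summaries
#'
#' Arithmetic mean and sample SD of the estimated ICCs per IDP class, the
#' summary used to compare reliability across phenotype classes and session
#' subsets. Skipped IDPs are excluded from means but counted.
#'
#' @param icc_table Per-IDP tibble from [icc_scan()] (columns `class_label`,
#'   `icc`, `skipped`).
#' @return Tibble with `class_label`, `mean_icc`, `sd_icc`, `n_idps`,
#'   `n_skipped`.
#' @export
class_icc_summary <- function(icc_table) {
  stopifnot(all(c("class_label", "icc") %in% names(icc_table)))
  if (!"skipped" %in% names(icc_table)) icc_table$skipped <- is.na(icc_table$icc)
  dplyr::summarise(
    dplyr::group_by(icc_table, .data$class_label),
    mean_icc = mean(.data$icc[!.data$skipped]),
    sd_icc = sd(.data$icc[!.data$skipped]),
    n_idps = sum(!.data$skipped),
    n_skipped = sum(.data$skipped),
    .groups = "drop"
  )
}
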