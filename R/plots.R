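#' Plot a reliability report
#'
#' Two displays mirroring the standard multi-site reliability panels:
#' `"pvalues"` shows the per-class distribution of `-log10` site-effect
#' p-values by session subset (points above the FDR threshold line indicate
#' significant mean site effects); `"icc"` shows the per-class distribution
#' of consistency ICCs by subset with the conventional fair/good (0.5, 0.8)
#' reliability bands.
#'
#' @param object A [run_pipeline()] result.
#' @param type `"pvalues"` or `"icc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reliability_report <- function(object, type = c("pvalues", "icc"),
                                        ...) {
  type <- match.arg(type)
  dat <- object$per_idp[!object$per_idp$skipped, ]
  if (type == "pvalues") {
    dat$neglog_p <- -log10(pmax(dat$p_reported, 1e-300))
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$class_label,
                                      y = .data$neglog_p,
                                      colour = .data$subset)) +
      ggplot2::geom_jitter(width = 0.25, height = 0, alpha = 0.6) +
      ggplot2::labs(x = "IDP class", y = expression(-log[10] ~ p),
                    colour = "sessions",
                    title = "Site effects on mean IDP values") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$class_label, y = .data$icc,
                                      colour = .data$subset)) +
      ggplot2::geom_hline(yintercept = c(0.5, 0.8), linetype = "dashed",
                          colour = "grey60") +
      ggplot2::geom_jitter(width = 0.25, height = 0, alpha = 0.6) +
      ggplot2::labs(x = "IDP class", y = "ICC(3,1)", colour = "sessions",
                    title = "Between-site consistency ICCs") +
      ggplot2::theme_minimal()
  }
}

#' Plot a resampled reference ICC distribution
#'
#' Histogram of the subsample-resampled reference ICCs with the central 95%
#' band, optionally overlaying observed multi-site ICCs for comparison.
#'
#' @param object A [resample_reference_iccs()] result.
#' @param observed Optional numeric vector of observed ICCs to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reference_distribution <- function(object, observed = NULL, ...) {
  dat <- tidy.reference_distribution(object)
  qs <- quantile(object$icc_samples, c(0.025, 0.975), names = FALSE)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$icc)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = qs, linetype = "dashed") +
    ggplot2::labs(x = "ICC(3,1)", y = "draws",
                  title = sprintf("Reference ICC distribution: %s (m = %d, B = %d)",
                                  object$idp_name, object$subset_size,
                                  object$n_resamples)) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "firebrick")
  }
  p
}

#' Plot a power curve
#'
#' Line plot of a [power_curve()] table.
#'
#' @param curve Tibble from [power_curve()].
#' @param xlab Axis label for the varied parameter.
#' @return A ggplot object.
#' @export
plot_power_curve <- function(curve, xlab = "effect size") {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$value, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = xlab, y = "power",
                  title = "Repeated-measures site-effect test power") +
    ggplot2::theme_minimal()
}

#' Plot a between-site correlation matrix
#'
#' Tile display of a [site_correlation_matrix()]: Pearson above the
#' diagonal, Spearman below.
#'
#' @param x A `site_correlation` matrix.
#' @return A ggplot object.
#' @export
plot_site_correlations <- function(x) {
  stopifnot(inherits(x, "site_correlation"))
  m <- unclass(x)
  dat <- tibble::tibble(
    row = rep(rownames(m), times = ncol(m)),
    col = rep(colnames(m), each = nrow(m)),
    r = as.vector(m)
  )
  dat$row <- factor(dat$row, levels = rev(rownames(m)))
  dat$col <- factor(dat$col, levels = colnames(m))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$col, y = .data$row,
                                    fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = "Between-site correlations (upper Pearson, lower Spearman)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
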