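#' Run the full multi-site reliability battery
#'
#' Orchestrates the complete analysis over one or more session subsets:
#' per-IDP site-effect tests ([site_effect_scan()]), consistency ICCs
#' ([icc_scan()]) with class-level summaries, optional pairwise-site ICCs,
#' and — when a test-retest reference cohort is supplied — per-IDP
#' subsample-resampling benchmarks with empirical two-sided p-values.
#' Identical inputs and seed produce identical outputs; all randomness
#' derives from the single top-level seed via counter-based sub-seeds, so
#' the benchmark of one IDP does not depend on how many others are run.
#'
#' @param study An [idp_table()] (e.g. a travelling-heads cohort) or a path
#'   readable by [read_idp_table()].
#' @param reference Optional two-session [idp_table()] test-retest cohort
#'   (or path) used for benchmarking.
#' @param subsets Named list defining the session subsets to analyse. Each
#'   element is either a manufacturer keyword (`"NONE"`, `"SIEMENS"`,
#'   `"GE"`, resolved via [subset_sessions()]) or a character vector of
#'   session labels. Default: all sites and the Siemens-only subset.
#' @param q Class-wise FDR level, default 0.05.
#' @param alpha_sphericity Mauchly gate for the GG correction.
#' @param icc_method `"anova"` or `"reml"`.
#' @param pairwise If `TRUE`, compute pairwise-site ICCs per IDP and subset.
#' @param subset_size,n_resamples Benchmark resampling settings (defaults 8
#'   and 1000).
#' @param seed Top-level integer seed.
#' @param out_dir Optional directory; when given, per-IDP and per-class
#'   TSVs plus a JSON run manifest are written there.
#' @return An object of class `reliability_report`: list with tibbles
#'   `per_idp`, `per_class`, optionally `pairwise`, and a `manifest` list.
#' @export
#' @examples
#' tbl <- generate_travelling_heads(
#'   sessions = travelling_sessions(ge_offset = 1),
#'   specs = idp_specs_from_icc(4, 0.8, class_label = "volumes"), seed = 5
#' )
#' rep <- run_pipeline(tbl, n_resamples = 50, seed = 6)
#' rep$per_class
run_pipeline <- function(study, reference = NULL,
                         subsets = list(all = "NONE", siemens = "SIEMENS"),
                         q = 0.05, alpha_sphericity = 0.05,
                         icc_method = c("anova", "reml"), pairwise = FALSE,
                         subset_size = 8, n_resamples = 1000, seed = 1L,
                         out_dir = NULL) {
  icc_method <- match.arg(icc_method)
  if (is.character(study)) study <- read_idp_table(study)
  if (is.character(reference)) reference <- read_idp_table(reference)
  stopifnot(inherits(study, "idp_table"))
  if (is.null(names(subsets)) || any(!nzchar(names(subsets)))) {
    stop_idprel("`subsets` must be a fully named list.", "idprel_config_error")
  }

  resolved <- lapply(subsets, function(s) {
    if (length(s) == 1L && toupper(s) %in% c("NONE", "SIEMENS", "GE")) {
      subset_sessions(study, toupper(s))
    } else {
      sort(unique(as.character(s)))
    }
  })
  for (nm in names(resolved)) {
    if (length(resolved[[nm]]) < 2L) {
      stop_idprel(sprintf("Subset '%s' resolves to < 2 sessions.", nm),
                  "idprel_config_error")
    }
  }

  # reference distributions are per IDP, shared across subsets
  ref_dists <- NULL
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "idp_table"))
    shared <- intersect(study$classes$idp_name, reference$classes$idp_name)
    ref_dists <- stats::setNames(lapply(seq_along(shared), function(i) {
      tryCatch(
        resample_reference_iccs(reference, shared[i],
                                subset_size = subset_size,
                                n_resamples = n_resamples,
                                seed = derive_seed(seed, i),
                                method = icc_method),
        idprel_error = function(e) NULL
      )
    }), shared)
  }

  per_idp <- purrr::map(names(resolved), function(nm) {
    sess <- resolved[[nm]]
    scan <- site_effect_scan(study, sess, q = q,
                             alpha_sphericity = alpha_sphericity)
    iccs <- icc_scan(study, sess, method = icc_method)
    iccs <- iccs[c("idp_name", "icc", "sigma2_subject", "sigma2_error",
                   "negative")]
    out <- dplyr::left_join(scan, iccs, by = "idp_name")
    out$subset <- nm
    if (!is.null(ref_dists)) {
      out$ref_median_icc <- NA_real_
      out$ref_q025 <- NA_real_
      out$ref_q975 <- NA_real_
      out$p_vs_reference <- NA_real_
      for (i in seq_len(nrow(out))) {
        rd <- ref_dists[[out$idp_name[i]]]
        if (is.null(rd) || is.na(out$icc[i])) next
        qs <- quantile(rd$icc_samples, c(0.025, 0.5, 0.975), names = FALSE)
        out$ref_q025[i] <- qs[1]
        out$ref_median_icc[i] <- qs[2]
        out$ref_q975[i] <- qs[3]
        out$p_vs_reference[i] <- empirical_two_sided_p(out$icc[i], rd)
      }
    }
    dplyr::relocate(out, "subset")
  })
  per_idp <- dplyr::bind_rows(per_idp)

  pairwise_tbl <- NULL
  if (pairwise) {
    pairwise_tbl <- dplyr::bind_rows(purrr::map(names(resolved), function(nm) {
      dplyr::bind_rows(purrr::map(study$classes$idp_name, function(idp) {
        pw <- pairwise_icc(study, idp, resolved[[nm]], method = icc_method)
        pw$idp_name <- idp
        pw$subset <- nm
        dplyr::relocate(pw, "subset", "idp_name")
      }))
    }))
  }

  per_class <- dplyr::bind_rows(purrr::map(names(resolved), function(nm) {
    sub <- per_idp[per_idp$subset == nm, ]
    summ <- class_icc_summary(sub)
    props <- dplyr::summarise(
      dplyr::group_by(sub[!sub$skipped, ], .data$class_label),
      prop_mean_effect = mean(.data$significant),
      prop_sphericity_violation = mean(.data$mauchly_p < alpha_sphericity,
                                       na.rm = TRUE),
      prop_nonnormal = mean(.data$shapiro_p < 0.05, na.rm = TRUE),
      .groups = "drop"
    )
    out <- dplyr::left_join(summ, props, by = "class_label")
    out$subset <- nm
    dplyr::relocate(out, "subset")
  }))

  manifest <- list(
    package = "idprel",
    version = as.character(packageVersion("idprel")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = as.integer(seed), q = q, alpha_sphericity = alpha_sphericity,
    icc_method = icc_method,
    subsets = resolved,
    n_idps = nrow(study$classes),
    n_subjects = dplyr::n_distinct(study$records$subject_id),
    benchmark = if (!is.null(reference)) {
      list(subset_size = as.integer(subset_size),
           n_resamples = as.integer(n_resamples),
           n_reference_subjects = dplyr::n_distinct(reference$records$subject_id))
    }
  )

  report <- structure(
    list(per_idp = per_idp, per_class = per_class, pairwise = pairwise_tbl,
         manifest = manifest),
    class = "reliability_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(per_idp, file.path(out_dir, "per_idp.tsv"), progress = FALSE)
    readr::write_tsv(per_class, file.path(out_dir, "per_class.tsv"), progress = FALSE)
    if (!is.null(pairwise_tbl)) {
      readr::write_tsv(pairwise_tbl, file.path(out_dir, "pairwise_icc.tsv"),
                       progress = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> %d IDPs x %d subsets (seed %d)\n",
              x$manifest$n_idps, length(x$manifest$subsets), x$manifest$seed))
  print(x$per_class, ...)
  invisible(x)
}

#' Per-class proportions of flagged IDPs
#'
#' Proportions of estimable IDPs per class and subset with (i) an
#' FDR-significant mean site effect, (ii) a Mauchly sphericity violation,
#' (iii) a Shapiro-Wilk normality violation. Denominators are the estimable
#' IDPs only; skipped counts are reported alongside.
#'
#' @param report A [run_pipeline()] result.
#' @param alpha Per-test level for the sphericity and normality flags,
#'   default 0.05.
#' @return Tibble with one row per (subset, class).
#' @export
class_proportions <- function(report, alpha = 0.05) {
  stopifnot(inherits(report, "reliability_report"))
  sub <- report$per_idp[!report$per_idp$skipped, ]
  props <- dplyr::summarise(
    dplyr::group_by(sub, .data$subset, .data$class_label),
    n_idps = dplyr::n(),
    prop_mean_effect = mean(.data$significant),
    prop_sphericity_violation = mean(.data$mauchly_p < alpha, na.rm = TRUE),
    prop_nonnormal = mean(.data$shapiro_p < alpha, na.rm = TRUE),
    .groups = "drop"
  )
  skipped <- dplyr::summarise(
    dplyr::group_by(report$per_idp, .data$subset, .data$class_label),
    n_skipped = sum(.data$skipped), .groups = "drop"
  )
  dplyr::left_join(props, skipped, by = c("subset", "class_label"))
}

#' @export
#' @importFrom generics tidy
#' @rdname reliability_report_methods
#' @title Broom-style methods for reliability reports
#' @description `tidy()` returns the per-IDP result table; `glance()` one
#'   row per session subset with headline counts.
#' @param x A `reliability_report`.
#' @param ... Unused.
tidy.reliability_report <- function(x, ...) x$per_idp

#' @export
#' @importFrom generics glance
#' @rdname reliability_report_methods
glance.reliability_report <- function(x, ...) {
  sub <- x$per_idp[!x$per_idp$skipped, ]
  dplyr::summarise(
    dplyr::group_by(sub, .data$subset),
    n_idps = dplyr::n(),
    n_significant = sum(.data$significant),
    mean_icc = mean(.data$icc, na.rm = TRUE),
    sd_icc = sd(.data$icc, na.rm = TRUE),
    .groups = "drop"
  )
}
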