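#' Site-effect specification for a synthetic session
#'
#' One row per scanning session in a simulated travelling-heads design.
#' Site effects are limited to an additive value shift and a multiplicative
#' scale change of the measured phenotype; a null site has `offset = 0`,
#' `scale = 1`. The scale factor multiplies both the subject effect and the
#' measurement noise, the minimal model under which scale changes perturb
#' sphericity while preserving the within-site ranking of subjects.
#'
#' @param session_label Session identifier (typically the site acronym).
#' @param offset Additive shift, in IDP units.
#' @param scale Multiplicative factor, strictly positive.
#' @param manufacturer `"SIEMENS"`, `"GE"` or `"NONE"`.
#' @param site_name,scanner_model Free-text metadata.
#' @return One-row tibble; bind rows to describe a multi-site design.
#' @export
#' @examples
#' rbind(site_spec("CAM"), site_spec("KCL", offset = 1, scale = 1.5,
#'                                   manufacturer = "GE"))
site_spec <- function(session_label, offset = 0, scale = 1,
                      manufacturer = c("SIEMENS", "GE", "NONE"),
                      site_name = session_label, scanner_model = NA_character_) {
  manufacturer <- match.arg(manufacturer)
  if (!is.finite(scale) || scale <= 0) {
    stop_idprel("`scale` must be a positive real.", "idprel_config_error")
  }
  tibble::tibble(session_label = as.character(session_label),
                 offset = as.numeric(offset), scale = as.numeric(scale),
                 manufacturer = manufacturer,
                 site_name = as.character(site_name),
                 scanner_model = as.character(scanner_model))
}

#' Default four-site travelling-heads session layout
#'
#' Three Siemens Prisma sites (Cambridge, Oxford, Liverpool) and one GE
#' MR750 site (KCL), the canonical multi-manufacturer pilot layout. Sites
#' default to null effects; supply `ge_offset`/`ge_scale` to inject a
#' manufacturer effect at the GE session.
#'
#' @param ge_offset,ge_scale Site effect applied at the GE session.
#' @return Tibble of [site_spec()] rows.
#' @export
travelling_sessions <- function(ge_offset = 0, ge_scale = 1) {
  dplyr::bind_rows(
    site_spec("CAM", site_name = "Cambridge", scanner_model = "Siemens Prisma 3T"),
    site_spec("OXF", site_name = "Oxford", scanner_model = "Siemens Prisma 3T"),
    site_spec("LIV", site_name = "Liverpool", scanner_model = "Siemens Prisma 3T"),
    site_spec("KCL", offset = ge_offset, scale = ge_scale, manufacturer = "GE",
              site_name = "London KCL", scanner_model = "GE MR750 Discovery 3T")
  )
}

#' Build IDP variance-component specifications
#'
#' Convenience constructor for the per-IDP generative parameters: grand mean
#' `mu`, between-subject standard deviation `sigma_subject` and residual
#' standard deviation `sigma_error`. The implied consistency ICC is
#' `sigma_subject^2 / (sigma_subject^2 + sigma_error^2)`; see
#' [theoretical_icc()]. `idp_specs_from_icc()` parameterises directly by the
#' target ICC at unit total variance.
#'
#' @param idp_name,class_label Identifiers (recycled to a common length).
#' @param mu Grand mean, IDP units.
#' @param sigma_subject Between-subject SD, `>= 0`.
#' @param sigma_error Residual SD, `> 0`.
#' @return Tibble with one row per IDP.
#' @export
idp_specs <- function(idp_name, class_label = "unclassified", mu = 0,
                      sigma_subject = 1, sigma_error = 1) {
  out <- tibble::tibble(idp_name = as.character(idp_name),
                        class_label = as.character(class_label),
                        mu = as.numeric(mu),
                        sigma_subject = as.numeric(sigma_subject),
                        sigma_error = as.numeric(sigma_error))
  if (any(out$sigma_subject < 0) || any(out$sigma_error <= 0)) {
    stop_idprel("Need sigma_subject >= 0 and sigma_error > 0.",
                "idprel_config_error")
  }
  if (anyDuplicated(out$idp_name)) {
    stop_idprel("IDP names must be unique.", "idprel_config_error")
  }
  out
}

#' @rdname idp_specs
#' @param n_idps Number of IDPs to create.
#' @param icc_true Target consistency ICC in `[0, 1)`; recycled across IDPs.
#' @param prefix Stem for generated IDP names.
#' @export
idp_specs_from_icc <- function(n_idps, icc_true, class_label = "unclassified",
                               mu = 0, prefix = "idp") {
  if (any(icc_true < 0 | icc_true >= 1)) {
    stop_idprel("`icc_true` must lie in [0, 1).", "idprel_config_error")
  }
  icc <- rep_len(icc_true, n_idps)
  idp_specs(
    idp_name = sprintf("%s_%04d", prefix, seq_len(n_idps)),
    class_label = rep_len(class_label, n_idps),
    mu = rep_len(mu, n_idps),
    sigma_subject = sqrt(icc),
    sigma_error = sqrt(1 - icc)
  )
}

#' Theoretical consistency ICC of a variance-component specification
#'
#' Closed form `sigma_subject^2 / (sigma_subject^2 + sigma_error^2)`, the
#' population ICC(3,1) of the generative model when all session scales are
#' equal. By convention `sigma_error = 0` returns 1.
#'
#' @param sigma_subject,sigma_error Standard deviations (vectorised).
#' @return Numeric vector of ICCs in `[0, 1]`.
#' @export
theoretical_icc <- function(sigma_subject, sigma_error) {
  s2 <- sigma_subject^2
  e2 <- sigma_error^2
  ifelse(e2 == 0, 1, s2 / (s2 + e2))
}

# Core generative model shared by both cohort generators:
#   y_ij = mu + b_j + s_j * (a_i + e_ij)
# a_i ~ N(0, sigma_subject), e_ij ~ N(0, sigma_error), independent.
simulate_records <- function(subjects, sessions, specs, missing_rate) {
  n <- length(subjects)
  k <- nrow(sessions)
  recs <- vector("list", nrow(specs))
  for (r in seq_len(nrow(specs))) {
    a <- rnorm(n, 0, specs$sigma_subject[r])
    e <- matrix(rnorm(n * k, 0, specs$sigma_error[r]), n, k)
    y <- specs$mu[r] +
      matrix(sessions$offset, n, k, byrow = TRUE) +
      matrix(sessions$scale, n, k, byrow = TRUE) * (a + e)
    keep <- if (missing_rate > 0) runif(n * k) >= missing_rate else TRUE
    recs[[r]] <- tibble::tibble(
      subject_id = rep(subjects, times = k),
      session_label = rep(sessions$session_label, each = n),
      idp_name = specs$idp_name[r],
      value = as.vector(y)
    )[keep, ]
  }
  dplyr::bind_rows(recs)
}

#' Simulate a travelling-heads cohort
#'
#' Generates a synthetic multi-site cohort in which every subject is scanned
#' once per session, under the variance-component model
#' `y_ij = mu + b_j + s_j * (a_i + e_ij)` with per-subject effects
#' `a_i ~ N(0, sigma_subject)` and noise `e_ij ~ N(0, sigma_error)`.
#' Additive offsets `b_j` shift session means without touching subject
#' ranking; scale factors `s_j` additionally perturb the covariance of
#' session differences (a sphericity violation). Missing sessions are
#' dropped completely at random, emulating acquisition failures.
#'
#' @param n_subjects Number of subjects (the canonical pilot design uses 8).
#' @param sessions Tibble of [site_spec()] rows; default four-site layout of
#'   [travelling_sessions()].
#' @param specs Tibble of per-IDP parameters from [idp_specs()].
#' @param missing_rate Probability in `[0, 1)` that any (subject, session)
#'   measurement is lost; default 0.
#' @param seed Integer seed; identical inputs give byte-identical tables.
#' @return An [idp_table()].
#' @export
#' @examples
#' tbl <- generate_travelling_heads(
#'   specs = idp_specs_from_icc(3, 0.8, class_label = "volumes"), seed = 1
#' )
#' tbl
generate_travelling_heads <- function(n_subjects = 8,
                                      sessions = travelling_sessions(),
                                      specs = idp_specs("idp_0001"),
                                      missing_rate = 0, seed = 1L) {
  if (n_subjects < 2) stop_idprel("Need n_subjects >= 2.", "idprel_config_error")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_idprel("`missing_rate` must lie in [0, 1).", "idprel_config_error")
  }
  if (any(sessions$scale <= 0)) {
    stop_idprel("Session scales must be positive.", "idprel_config_error")
  }
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  records <- with_seed(seed, simulate_records(subjects, sessions, specs, missing_rate))
  idp_table(
    records,
    sessions = sessions[c("session_label", "site_name", "manufacturer", "scanner_model")],
    classes = specs[c("idp_name", "class_label")]
  )
}

#' Simulate a single-site test-retest reference cohort
#'
#' Generates a large two-visit cohort with no site effects, emulating a
#' population test-retest benchmark (same scanner, two visits per subject).
#' Uses the same variance-component model as
#' [generate_travelling_heads()] with both sessions at offset 0, scale 1.
#'
#' @param n_subjects Number of subjects (the benchmark design uses 2,817).
#' @param specs Tibble of per-IDP parameters from [idp_specs()].
#' @param seed Integer seed.
#' @return An [idp_table()] with sessions `visit1`, `visit2`
#'   (manufacturer `"NONE"`).
#' @export
generate_reference_cohort <- function(n_subjects = 2817,
                                      specs = idp_specs("idp_0001"),
                                      seed = 1L) {
  if (n_subjects < 2) stop_idprel("Need n_subjects >= 2.", "idprel_config_error")
  sessions <- dplyr::bind_rows(
    site_spec("visit1", manufacturer = "NONE", site_name = "reference"),
    site_spec("visit2", manufacturer = "NONE", site_name = "reference")
  )
  subjects <- sprintf("R%04d", seq_len(n_subjects))
  records <- with_seed(seed, simulate_records(subjects, sessions, specs, 0))
  idp_table(
    records,
    sessions = sessions[c("session_label", "site_name", "manufacturer", "scanner_model")],
    classes = specs[c("idp_name", "class_label")]
  )
}
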