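#' Assemble an IDP measurement table
#'
#' Bundles long-format imaging-derived-phenotype (IDP) measurements with
#' session metadata and an IDP-to-class map into a validated `idp_table`
#' object, the input to every analysis in the package.
#'
#' The long format is canonical: one record per
#' (subject, session, IDP) with a numeric value. Missing measurements may be
#' encoded either by an absent record or by an `NA` value; both are accepted
#' and treated identically. Wide per-IDP matrices are derived views obtained
#' with [extract_matrix()].
#'
#' @param records Data frame with columns `subject_id`, `session_label`,
#'   `idp_name` (character or coercible) and `value` (numeric; `NA` or
#'   non-finite values are treated as missing).
#' @param sessions Optional data frame of session metadata with columns
#'   `session_label`, `site_name`, `manufacturer` (one of `"SIEMENS"`,
#'   `"GE"`, `"NONE"`) and `scanner_model`. When omitted, sessions are
#'   derived from the records with manufacturer `"NONE"`.
#' @param classes Optional data frame mapping `idp_name` to `class_label`.
#'   IDPs absent from the map are assigned class `"unclassified"`.
#'
#' @return An object of class `idp_table`: a list with tibbles `records`,
#'   `sessions` and `classes`.
#' @seealso [read_idp_table()], [extract_matrix()], [subset_sessions()]
#' @export
#' @examples
#' rec <- expand.grid(subject_id = c("S1", "S2", "S3"),
#'                    session_label = c("CAM", "OXF"),
#'                    idp_name = "vol_hippo", stringsAsFactors = FALSE)
#' rec$value <- rnorm(nrow(rec))
#' tbl <- idp_table(rec)
#' tbl
idp_table <- function(records, sessions = NULL, classes = NULL) {
  required <- c("subject_id", "session_label", "idp_name", "value")
  if (!all(required %in% names(records))) {
    stop_idprel(
      paste0("`records` must have columns ",
             paste(required, collapse = ", "), "."),
      "idprel_format_error"
    )
  }
  records <- tibble::as_tibble(records)
  records <- dplyr::mutate(
    records,
    subject_id = as.character(.data$subject_id),
    session_label = as.character(.data$session_label),
    idp_name = as.character(.data$idp_name),
    value = suppressWarnings(as.numeric(.data$value))
  )
  # non-finite measurements are missing, not errors
  records$value[!is.finite(records$value)] <- NA_real_

  dup <- duplicated(records[c("subject_id", "session_label", "idp_name")])
  if (any(dup)) {
    first <- records[which(dup)[1L], ]
    stop_idprel(
      sprintf("Duplicate record for (%s, %s, %s).",
              first$subject_id, first$session_label, first$idp_name),
      "idprel_integrity_error"
    )
  }

  labels <- sort(unique(records$session_label))
  if (is.null(sessions)) {
    sessions <- tibble::tibble(
      session_label = labels, site_name = labels,
      manufacturer = "NONE", scanner_model = NA_character_
    )
  } else {
    sessions <- tibble::as_tibble(sessions)
    if (!all(c("session_label", "manufacturer") %in% names(sessions))) {
      stop_idprel("`sessions` needs columns session_label and manufacturer.",
                  "idprel_format_error")
    }
    sessions$session_label <- as.character(sessions$session_label)
    sessions$manufacturer <- toupper(as.character(sessions$manufacturer))
    if (!"site_name" %in% names(sessions)) sessions$site_name <- sessions$session_label
    if (!"scanner_model" %in% names(sessions)) sessions$scanner_model <- NA_character_
    bad <- setdiff(unique(sessions$manufacturer), c("SIEMENS", "GE", "NONE"))
    if (length(bad)) {
      stop_idprel(sprintf("Unknown manufacturer: %s.", paste(bad, collapse = ", ")),
                  "idprel_format_error")
    }
    if (anyDuplicated(sessions$session_label)) {
      stop_idprel("Duplicate session_label in session metadata.",
                  "idprel_integrity_error")
    }
    missing_meta <- setdiff(labels, sessions$session_label)
    if (length(missing_meta)) {
      stop_idprel(sprintf("Sessions without metadata: %s.",
                          paste(missing_meta, collapse = ", ")),
                  "idprel_integrity_error")
    }
    sessions <- sessions[c("session_label", "site_name", "manufacturer", "scanner_model")]
  }
  sessions <- dplyr::arrange(sessions, .data$session_label)

  idps <- sort(unique(records$idp_name))
  if (is.null(classes)) {
    classes <- tibble::tibble(idp_name = idps, class_label = "unclassified")
  } else {
    classes <- tibble::as_tibble(classes)
    if (!all(c("idp_name", "class_label") %in% names(classes))) {
      stop_idprel("`classes` needs columns idp_name and class_label.",
                  "idprel_format_error")
    }
    classes <- dplyr::mutate(classes,
                             idp_name = as.character(.data$idp_name),
                             class_label = as.character(.data$class_label))
    if (anyDuplicated(classes$idp_name)) {
      stop_idprel("Each IDP must map to exactly one class.",
                  "idprel_integrity_error")
    }
    unmapped <- setdiff(idps, classes$idp_name)
    if (length(unmapped)) {
      classes <- dplyr::bind_rows(
        classes,
        tibble::tibble(idp_name = unmapped, class_label = "unclassified")
      )
    }
    classes <- classes[classes$idp_name %in% idps, c("idp_name", "class_label")]
  }
  classes <- dplyr::arrange(classes, .data$idp_name)

  structure(list(records = records, sessions = sessions, classes = classes),
            class = "idp_table")
}

#' @export
print.idp_table <- function(x, ...) {
  cat(sprintf(
    "<idp_table> %d records | %d subjects x %d sessions | %d IDPs in %d classes\n",
    nrow(x$records), dplyr::n_distinct(x$records$subject_id),
    nrow(x$sessions), nrow(x$classes),
    dplyr::n_distinct(x$classes$class_label)
  ))
  n_miss <- sum(is.na(x$records$value))
  if (n_miss > 0) cat(sprintf("  %d missing values\n", n_miss))
  print(x$sessions, ...)
  invisible(x)
}

#' Read an IDP table from delimited files
#'
#' Reads a long-format measurement table (columns `subject_id`,
#' `session_label`, `idp_name`, `value`) plus optional session-metadata and
#' class-map sidecars, all TSV or CSV with `.` as the decimal separator.
#' Empty fields and the token `NA` in the value column are read as missing.
#'
#' @param path Path to the measurement table.
#' @param format `"auto"` (by extension; default TSV), `"tsv"` or `"csv"`.
#' @param sessions_path,classes_path Optional sidecar paths, same dialect.
#' @return An [idp_table()].
#' @export
read_idp_table <- function(path, format = c("auto", "tsv", "csv"),
                           sessions_path = NULL, classes_path = NULL) {
  format <- match.arg(format)
  reader <- function(p) {
    fmt <- if (format == "auto") {
      if (grepl("\\.csv$", p, ignore.case = TRUE)) "csv" else "tsv"
    } else format
    f <- if (fmt == "csv") readr::read_csv else readr::read_tsv
    f(p, col_types = readr::cols(.default = readr::col_character()),
      na = c("", "NA"), progress = FALSE)
  }
  records <- reader(path)
  required <- c("subject_id", "session_label", "idp_name", "value")
  if (!all(required %in% names(records))) {
    stop_idprel(
      sprintf("Malformed header in %s: need columns %s.", path,
              paste(required, collapse = ", ")),
      "idprel_format_error"
    )
  }
  sessions <- if (!is.null(sessions_path)) reader(sessions_path)
  classes <- if (!is.null(classes_path)) reader(classes_path)
  idp_table(records, sessions = sessions, classes = classes)
}

#' Write an IDP table to delimited files
#'
#' Inverse of [read_idp_table()]: values are serialised at full double
#' precision so that a write/read round trip reproduces the table exactly.
#' Missing values are written as empty fields.
#'
#' @param table An [idp_table()].
#' @param path Output path for the records.
#' @param format `"tsv"` or `"csv"`.
#' @param sessions_path,classes_path Optional sidecar output paths.
#' @return `table`, invisibly.
#' @export
write_idp_table <- function(table, path, format = c("tsv", "csv"),
                            sessions_path = NULL, classes_path = NULL) {
  stopifnot(inherits(table, "idp_table"))
  format <- match.arg(format)
  writer <- if (format == "csv") readr::write_csv else readr::write_tsv
  out <- table$records
  out$value <- ifelse(is.na(out$value), "", sprintf("%.17g", out$value))
  writer(out, path, na = "", progress = FALSE)
  if (!is.null(sessions_path)) writer(table$sessions, sessions_path, na = "", progress = FALSE)
  if (!is.null(classes_path)) writer(table$classes, classes_path, na = "", progress = FALSE)
  invisible(table)
}

#' Extract a complete-case subject-by-session matrix for one IDP
#'
#' Builds the n x k matrix that is the unit of all per-IDP statistics.
#' Subjects missing any value among the requested sessions are dropped
#' (complete-case analysis per analysed session subset). Rows and columns
#' are ordered lexicographically so results are reproducible regardless of
#' input record order.
#'
#' @param table An [idp_table()].
#' @param idp_name Name of the IDP to extract.
#' @param sessions Character vector of session labels; default all sessions.
#' @return A numeric matrix with subject row names and session column names.
#'   Errors with class `idprel_insufficient_data` if fewer than 3 complete
#'   subjects survive (below that the error degrees of freedom make every
#'   downstream test meaningless).
#' @export
extract_matrix <- function(table, idp_name, sessions = NULL) {
  stopifnot(inherits(table, "idp_table"))
  if (is.null(sessions)) sessions <- table$sessions$session_label
  sessions <- sort(unique(as.character(sessions)))
  if (!length(sessions)) {
    stop_idprel("`sessions` must be non-empty.", "idprel_config_error")
  }
  unknown <- setdiff(sessions, table$sessions$session_label)
  if (length(unknown)) {
    stop_idprel(sprintf("Unknown sessions: %s.", paste(unknown, collapse = ", ")),
                "idprel_config_error")
  }
  if (!idp_name %in% table$classes$idp_name) {
    stop_idprel(sprintf("IDP '%s' not present in table.", idp_name),
                "idprel_config_error")
  }

  rec <- table$records[table$records$idp_name == idp_name &
                         table$records$session_label %in% sessions, ]
  m <- build_matrix(rec, sessions)
  if (nrow(m) < 3L) {
    stop_idprel(
      sprintf("IDP '%s': only %d complete subjects across %d sessions (need >= 3).",
              idp_name, nrow(m), length(sessions)),
      "idprel_insufficient_data", n_complete = nrow(m)
    )
  }
  m
}

# Fast core shared with the per-IDP scans: index-assign records for one IDP
# into an n x k matrix and drop incomplete subjects. `sessions` must be
# sorted; `rec` must already be restricted to one IDP and those sessions.
build_matrix <- function(rec, sessions) {
  subjects <- sort(unique(rec$subject_id))
  m <- matrix(NA_real_, length(subjects), length(sessions),
              dimnames = list(subjects, sessions))
  m[cbind(match(rec$subject_id, subjects),
          match(rec$session_label, sessions))] <- rec$value
  m[rowSums(!is.finite(m)) == 0L, , drop = FALSE]
}

# One-pass extraction of all per-IDP matrices for a session subset; returns
# a named list (NULL entries for IDPs with no records at those sessions).
scan_matrices <- function(table, sessions) {
  sessions <- sort(unique(as.character(sessions)))
  unknown <- setdiff(sessions, table$sessions$session_label)
  if (length(unknown)) {
    stop_idprel(sprintf("Unknown sessions: %s.", paste(unknown, collapse = ", ")),
                "idprel_config_error")
  }
  rec <- table$records[table$records$session_label %in% sessions, ]
  idx <- split(seq_len(nrow(rec)), rec$idp_name)
  lapply(idx, function(i) build_matrix(rec[i, ], sessions))
}

#' Select sessions by scanner manufacturer
#'
#' Returns the session labels whose scanners come from the given
#' manufacturer, supporting the all-sites versus Siemens-only contrasts of
#' multi-manufacturer designs. `"NONE"` selects every session.
#'
#' @param table An [idp_table()].
#' @param manufacturer `"SIEMENS"`, `"GE"` or `"NONE"`.
#' @return Character vector of session labels, lexicographically sorted.
#' @export
subset_sessions <- function(table, manufacturer = c("NONE", "SIEMENS", "GE")) {
  stopifnot(inherits(table, "idp_table"))
  manufacturer <- match.arg(toupper(manufacturer[1L]), c("NONE", "SIEMENS", "GE"))
  out <- if (manufacturer == "NONE") {
    table$sessions$session_label
  } else {
    table$sessions$session_label[table$sessions$manufacturer == manufacturer]
  }
  if (!length(out)) {
    stop_idprel(sprintf("No sessions with manufacturer %s.", manufacturer),
                "idprel_config_error")
  }
  sort(out)
}
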