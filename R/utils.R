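#' @importFrom rlang abort %||% .data
#' @importFrom stats pf qf pchisq cor quantile sd shapiro.test p.adjust rnorm runif
#' @importFrom utils combn packageVersion
NULL

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based fan-out of a top-level seed into independent sub-stream seeds.
# Keeps every derived seed a valid 32-bit integer.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter)) %% 2147483647L)
}

stop_idprel <- function(message, class, ...) {
  abort(message, class = c(class, "idprel_error"), ...)
}

assert_matrix_input <- function(m, min_n = 3L, min_k = 2L) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_idprel("`m` must be a numeric subject-by-session matrix.",
                "idprel_input_error")
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop_idprel("Matrix contains missing or non-finite values; extract a complete-case matrix first.",
                "idprel_input_error")
  }
  if (nrow(m) < min_n) {
    stop_idprel(
      sprintf("Need at least %d complete subjects, got %d.", min_n, nrow(m)),
      "idprel_insufficient_data", n_complete = nrow(m)
    )
  }
  if (ncol(m) < min_k) {
    stop_idprel(sprintf("Need at least %d sessions, got %d.", min_k, ncol(m)),
                "idprel_insufficient_data")
  }
  invisible(m)
}
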