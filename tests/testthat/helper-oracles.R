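# Independent oracles, written from first principles and kept free of the
# package's own decomposition helpers.

# Brute-force within-subject ANOVA from the definitional sums of squares.
oracle_rm_anova <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  gm <- sum(m) / (n * k)
  ss_sub <- 0
  for (i in seq_len(n)) ss_sub <- ss_sub + k * (mean(m[i, ]) - gm)^2
  ss_sess <- 0
  for (j in seq_len(k)) ss_sess <- ss_sess + n * (mean(m[, j]) - gm)^2
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_sub - ss_sess
  ms_sess <- ss_sess / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  list(F = ms_sess / ms_err,
       p = pf(ms_sess / ms_err, k - 1, (n - 1) * (k - 1), lower.tail = FALSE),
       eta_partial = ss_sess / (ss_sess + ss_err),
       ms_subjects = ss_sub / (n - 1), ms_error = ms_err)
}

# Eigenvalue-based Mauchly W and GG epsilon using a difference contrast
# orthonormalised by QR (a different basis than the implementation uses;
# W and epsilon are basis-invariant).
oracle_mauchly <- function(m) {
  k <- ncol(m)
  d <- diag(k - 1)
  cmat <- cbind(d, -1)          # differences from the last session
  cmat <- qr.Q(qr(t(cmat)))     # orthonormal columns
  v <- t(cmat) %*% cov(m) %*% cmat
  lambda <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  list(W = prod(lambda) / (sum(lambda) / (k - 1))^(k - 1),
       epsilon = sum(lambda)^2 / ((k - 1) * sum(lambda^2)))
}

# ICC(3,1) from raw sums of squares, written independently.
oracle_icc31 <- function(m) {
  o <- oracle_rm_anova(m)
  k <- ncol(m)
  (o$ms_subjects - o$ms_error) / (o$ms_subjects + (k - 1) * o$ms_error)
}

# Literal Benjamini-Hochberg step-up enumeration.
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  cutoffs <- seq_len(m) * q / m
  below <- which(ps <= cutoffs)
  reject <- logical(m)
  if (length(below)) reject[ord[seq_len(max(below))]] <- TRUE
  reject
}

# Friedman statistic from within-subject ranks, no tie handling (use only
# on tie-free data).
oracle_friedman <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  r <- t(apply(m, 1, rank))
  rbar <- colMeans(r)
  12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
}

# Small deterministic travelling-heads fixture used across files.
fixture_table <- function(n = 8, icc = 0.8, n_idps = 3, seed = 101,
                          ge_offset = 0, ge_scale = 1, missing_rate = 0) {
  generate_travelling_heads(
    n_subjects = n,
    sessions = travelling_sessions(ge_offset = ge_offset, ge_scale = ge_scale),
    specs = idp_specs_from_icc(n_idps, icc, class_label = "volumes"),
    missing_rate = missing_rate, seed = seed
  )
}
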