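test_that("rm_anova matches the brute-force sums-of-squares oracle", {
  # small integer fixture, computed independently from the definition
  m <- matrix(c(3, 5, 4,
                6, 8, 7,
                2, 4, 5,
                7, 9, 9), nrow = 4, byrow = TRUE)
  o <- oracle_rm_anova(m)
  a <- rm_anova(m)
  expect_equal(a$F, o$F)
  expect_equal(a$p_uncorrected, o$p)
  expect_equal(a$eta_squared, o$eta_partial)
  # and a larger random case against base aov()
  set.seed(14)
  m2 <- matrix(rnorm(32), 8, 4) + rnorm(8)
  df <- data.frame(y = as.vector(m2), subj = factor(rep(1:8, 4)),
                   sess = factor(rep(1:4, each = 8)))
  tab <- summary(aov(y ~ sess + Error(subj), data = df))[["Error: Within"]][[1]]
  a2 <- rm_anova(m2)
  expect_equal(a2$F, tab["sess", "F value"], tolerance = 1e-10)
  expect_equal(a2$p_uncorrected, tab["sess", "Pr(>F)"], tolerance = 1e-10)
})

test_that("no session effect gives F = 0, p = 1; additive data are degenerate", {
  m <- matrix(rnorm(6), 6, 3)  # identical columns per subject
  m[, 2] <- m[, 1]
  m[, 3] <- m[, 1]
  a <- rm_anova(m)
  expect_equal(a$F, 0)
  expect_equal(a$p_uncorrected, 1)
  # subject vector plus column offsets, zero noise: SS_error = 0
  m2 <- outer(c(1, 3, 5, 7), c(0, 2, -1), "+")
  a2 <- rm_anova(m2)
  expect_true(a2$degenerate)
  expect_equal(a2$F, Inf)
  expect_equal(a2$p_uncorrected, 0)
})

test_that("rm_anova F is invariant to per-subject constants and affine maps", {
  set.seed(20)
  m <- matrix(rnorm(32), 8, 4)
  f0 <- rm_anova(m)$F
  expect_equal(rm_anova(m + rnorm(8))$F, f0, tolerance = 1e-9)
  expect_equal(rm_anova(3.7 * m + 11)$F, f0, tolerance = 1e-9)
})

test_that("mauchly matches the eigenvalue oracle and the base-R test", {
  set.seed(33)
  m <- matrix(rnorm(32), 8, 4, dimnames = list(NULL, letters[1:4]))
  m[, 4] <- m[, 4] * 2  # induce some nonsphericity
  got <- mauchly_test(m)
  o <- oracle_mauchly(m)
  expect_equal(got$W, o$W, tolerance = 1e-10)
  expect_equal(got$epsilon_gg, o$epsilon, tolerance = 1e-10)
  base <- stats::mauchly.test(lm(m ~ 1), X = ~1)
  expect_equal(got$W, unname(base$statistic), tolerance = 1e-10)
  # base uses a higher-order series for the null distribution; the
  # first-order chi-square approximation should still be close
  expect_lt(abs(got$p - base$p.value), 0.02)
})

test_that("mauchly edge cases: k = 2 forced, singular covariance flagged", {
  m <- matrix(rnorm(16), 8, 2)
  got <- mauchly_test(m)
  expect_equal(got[c("W", "epsilon_gg", "p")],
               tibble::tibble(W = 1, epsilon_gg = 1, p = 1))
  # n <= k - 1: contrast covariance singular
  m2 <- matrix(rnorm(3 * 5), 3, 5)
  got2 <- mauchly_test(m2)
  expect_false(got2$estimable)
  expect_equal(got2$epsilon_gg, 1 / 4)
})

test_that("mauchly type-I rate is near alpha under compound symmetry", {
  # compound-symmetric population: subject effect + iid noise, large n
  set.seed(424)
  rej <- mean(replicate(2000, {
    m <- matrix(rnorm(50 * 4), 50, 4) + rnorm(50)
    mauchly_test(m)$p < 0.05
  }))
  # binomial 99% band around 0.05 at 2000 reps: +/- 2.58*sqrt(.05*.95/2000)
  expect_lt(abs(rej - 0.05), 0.0126 + 0.01)
})

test_that("greenhouse-geisser correction rescales dfs and p only when gated", {
  set.seed(40)
  m <- matrix(rnorm(32), 8, 4)
  an <- rm_anova(m)
  no_viol <- apply_gg(an, tibble::tibble(W = 0.9, chi_square = 1, df = 5L,
                                         p = 0.5, epsilon_gg = 0.8,
                                         estimable = TRUE))
  expect_false(no_viol$gg_applied)
  expect_identical(no_viol$p_reported, an$p_uncorrected)
  viol <- apply_gg(an, tibble::tibble(W = 0.1, chi_square = 20, df = 5L,
                                      p = 0.01, epsilon_gg = 0.6,
                                      estimable = TRUE))
  expect_true(viol$gg_applied)
  expect_equal(viol$df_effect, 3 * 0.6)
  expect_equal(viol$df_error, 21 * 0.6)
  expect_equal(viol$p_reported, pf(an$F, 1.8, 12.6, lower.tail = FALSE))
  expect_equal(viol$F, an$F)  # F itself never changes
  # epsilon = 1 exactly: corrected p equals uncorrected p
  eps1 <- apply_gg(an, tibble::tibble(W = 0.1, chi_square = 20, df = 5L,
                                      p = 0.01, epsilon_gg = 1,
                                      estimable = TRUE))
  expect_equal(eps1$p_reported, an$p_uncorrected)
})

test_that("friedman: ties, degenerate and maximal-separation cases", {
  m <- matrix(rep(rnorm(5), 3), 5, 3)  # identical columns
  fr <- friedman_test(m)
  expect_equal(fr$Q, 0)
  expect_equal(fr$p, 1)
  # all values tied within every subject
  m2 <- matrix(1, 4, 3)
  fr2 <- friedman_test(m2)
  expect_equal(fr2$Q, 0)
  expect_equal(fr2$p, 1)
  # strictly increasing columns for all subjects: maximal Q from rank oracle
  m3 <- matrix(c(1, 2, 3, 2, 4, 6, 0, 5, 9), 3, 3, byrow = TRUE)
  fr3 <- friedman_test(m3)
  expect_equal(fr3$Q, oracle_friedman(m3))
  expect_equal(fr3$df, 2L)
  # tie-free data agree with stats::friedman.test exactly
  set.seed(60)
  m4 <- matrix(rnorm(28), 7, 4)
  base <- stats::friedman.test(m4)
  fr4 <- friedman_test(m4)
  expect_equal(fr4$Q, unname(base$statistic))
  expect_equal(fr4$p, base$p.value)
})

test_that("friedman is invariant to monotone within-subject transforms", {
  set.seed(61)
  m <- matrix(rexp(32), 8, 4)
  expect_equal(friedman_test(exp(m))$Q, friedman_test(m)$Q)
  expect_equal(friedman_test(m^3)$Q, friedman_test(m)$Q)
})

test_that("friedman null p-values are roughly uniform and track ANOVA", {
  set.seed(62)
  ps <- t(replicate(400, {
    m <- matrix(rnorm(32), 8, 4) + rnorm(8)
    c(friedman_test(m)$p, rm_anova(m)$p_uncorrected)
  }))
  expect_lt(abs(mean(ps[, 1] < 0.5) - 0.5), 0.08)
  # the two tests should order the same datasets similarly
  expect_gt(cor(ps[, 1], ps[, 2], method = "spearman"), 0.5)
})

test_that("shapiro on residuals: calibration, degenerate flag and power", {
  set.seed(70)
  rej <- mean(replicate(500, shapiro_residuals(matrix(rnorm(32), 8, 4))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.04)
  m2 <- outer(1:5, c(0, 1, 2), "+")  # perfectly additive: zero residuals
  expect_false(shapiro_residuals(m2)$estimable)
  rej_exp <- mean(replicate(300, {
    shapiro_residuals(matrix(rexp(32), 8, 4))$p < 0.05
  }))
  expect_gt(rej_exp, 0.2)  # heavy contamination must be detected above alpha
})

test_that("class-wise BH adjustment matches the step-up oracle", {
  expect_true(all(fdr_adjust(rep(0.001, 10), "a")$significant))
  p <- c(0.01, 0.02, 0.03, 0.04, 0.2)
  got <- fdr_adjust(p, "one", q = 0.05)
  expect_equal(got$significant, oracle_bh_reject(p, 0.05))
  set.seed(80)
  p2 <- runif(60)^2
  cls <- rep(c("a", "b", "c"), each = 20)
  got2 <- fdr_adjust(p2, cls, q = 0.05)
  for (g in unique(cls)) {
    expect_equal(got2$significant[cls == g], oracle_bh_reject(p2[cls == g], 0.05))
  }
  # within-class adjustment differs from pooled on a constructed case:
  # a dense-signal class would drag a sparse class's threshold up when pooled
  p3 <- c(rep(0.001, 15), 0.04, rep(0.5, 4))
  cls3 <- c(rep("dense", 15), rep("sparse", 5))
  pooled <- oracle_bh_reject(p3, 0.05)  # 0.04 has rank 16: 16 * 0.05/20 = 0.04
  split <- fdr_adjust(p3, cls3, q = 0.05)$significant
  expect_true(pooled[16])   # rejected when pooled with the dense class
  expect_false(split[16])   # but not within its own sparse class
})

test_that("rm_anova type-I error is nominal under the null generator", {
  set.seed(90)
  rej <- mean(replicate(2000, {
    m <- matrix(rnorm(32), 8, 4) + rnorm(8)
    rm_anova(m)$p_uncorrected < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.0126)  # binomial 99% band at 2000 reps
})

test_that("site_effect_scan reports skips, concentrates rejections, flags GE", {
  # offsets injected into one class only
  sess <- dplyr::bind_rows(site_spec("A"), site_spec("B", offset = 3),
                           site_spec("C"), site_spec("D"))
  specs <- idp_specs_from_icc(40, 0.5,
                              class_label = rep(c("shifted", "null"), each = 20))
  specs_null <- specs
  tbl_shift <- generate_travelling_heads(10, sess, specs[1:20, ], seed = 91)
  tbl_null <- generate_travelling_heads(
    10, dplyr::mutate(sess, offset = 0), specs[21:40, ], seed = 92)
  tbl <- idp_table(rbind(tbl_shift$records, tbl_null$records),
                   sessions = tbl_shift$sessions,
                   classes = specs[c("idp_name", "class_label")])
  scan <- site_effect_scan(tbl)
  by_class <- tapply(scan$significant, scan$class_label, mean)
  expect_gt(by_class["shifted"], 0.9)
  expect_lt(by_class["null"], 0.2)

  # IDPs below the minimum-n floor are reported as skipped rows
  rec <- tbl$records
  rec <- rec[!(rec$idp_name == "idp_0001" & rec$subject_id %in%
                 sprintf("S%02d", 1:8) & rec$session_label == "A"), ]
  tbl2 <- idp_table(rec, sessions = tbl$sessions, classes = tbl$classes)
  scan2 <- site_effect_scan(tbl2)
  expect_equal(nrow(scan2), 40)  # skipped rows retained
  expect_true(scan2$skipped[scan2$idp_name == "idp_0001"])
})

test_that("including a shifted GE site yields more mean-effect rejections", {
  tbl <- fixture_table(n = 8, icc = 0.8, n_idps = 60, seed = 93,
                       ge_offset = 0.8, ge_scale = 1.5)
  all4 <- site_effect_scan(tbl, subset_sessions(tbl, "NONE"))
  siem <- site_effect_scan(tbl, subset_sessions(tbl, "SIEMENS"))
  expect_gt(sum(all4$significant), sum(siem$significant))
})
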