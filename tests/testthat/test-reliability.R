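test_that("icc matches the mean-squares oracle and handles degeneracy", {
  set.seed(100)
  m <- matrix(rnorm(32), 8, 4) + 2 * rnorm(8)
  expect_equal(icc_consistency(m)$icc, oracle_icc31(m), tolerance = 1e-12)
  # identical columns: perfect repeatability
  m2 <- matrix(rnorm(5), 5, 3)[, c(1, 1, 1)]
  r2 <- icc_consistency(m2)
  expect_equal(r2$icc, 1)
  expect_true(r2$degenerate)
  # subject vector plus arbitrary column offsets: the defining property of
  # the consistency ICC — session main effects do not count against it
  m3 <- outer(c(2, 5, 1, 9, 4), c(0, 10, -3), "+")
  expect_equal(icc_consistency(m3)$icc, 1)
})

test_that("negative ICC estimates are reported raw with a flag", {
  set.seed(101)
  repeat {  # find a matrix whose subject variance estimate is negative
    m <- matrix(rnorm(32), 8, 4)
    if (icc_consistency(m)$icc < 0) break
  }
  ra <- icc_consistency(m, "anova")
  expect_lt(ra$icc, 0)
  expect_true(ra$negative)
  rr <- icc_consistency(m, "reml")
  expect_equal(rr$icc, 0)  # REML truncates the variance at the boundary
  expect_equal(rr$sigma2_subject, 0)
})

test_that("closed-form REML equals lme4 on balanced data", {
  set.seed(102)
  for (i in 1:5) {
    tbl <- fixture_table(n = 8, icc = 0.7, n_idps = 1, seed = 200 + i)
    m <- extract_matrix(tbl, "idp_0001")
    df <- data.frame(y = as.vector(m),
                     subj = factor(rep(rownames(m), ncol(m))),
                     sess = factor(rep(colnames(m), each = nrow(m))))
    fit <- lme4::lmer(y ~ sess + (1 | subj), data = df, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))$vcov
    got <- icc_consistency(m, "reml")
    expect_equal(got$sigma2_subject, vc[1], tolerance = 1e-6)
    expect_equal(got$sigma2_error, vc[2], tolerance = 1e-6)
    expect_equal(got$icc, vc[1] / sum(vc), tolerance = 1e-6)
  }
})

test_that("affine maps leave ICC unchanged; per-session scalings change it", {
  set.seed(103)
  tbl <- fixture_table(n = 8, icc = 0.6, n_idps = 1, seed = 300)
  m <- extract_matrix(tbl, "idp_0001")
  icc0 <- icc_consistency(m)$icc
  expect_equal(icc_consistency(2.5 * m - 7)$icc, icc0, tolerance = 1e-10)
  expect_equal(icc_consistency(-1.5 * m)$icc, icc0, tolerance = 1e-10)
  offsets <- matrix(c(0, 4, -2, 100), nrow(m), 4, byrow = TRUE)
  expect_lt(abs(icc_consistency(m + offsets)$icc - icc0), 1e-10)
  scales <- matrix(c(1, 1, 1, 3), nrow(m), 4, byrow = TRUE)
  expect_gt(abs(icc_consistency(m * scales)$icc - icc0), 1e-6)
})

test_that("pairwise ICCs enumerate the session pairs", {
  tbl <- fixture_table(n = 8, icc = 0.8, n_idps = 1, seed = 104)
  pw <- pairwise_icc(tbl, "idp_0001")
  expect_equal(nrow(pw), 6)
  pw3 <- pairwise_icc(tbl, "idp_0001", subset_sessions(tbl, "SIEMENS"))
  expect_equal(nrow(pw3), 3)
  # noise-free fixture with offsets: every pair has ICC 1
  m <- outer(c(1, 4, 2, 8, 6), c(0, 3), "+")
  rec <- data.frame(subject_id = rep(sprintf("P%d", 1:5), 2),
                    session_label = rep(c("A", "B"), each = 5),
                    idp_name = "x", value = as.vector(m))
  pw2 <- pairwise_icc(idp_table(rec), "x")
  expect_equal(pw2$icc, 1)
})

test_that("site correlation matrix has Pearson above, Spearman below", {
  set.seed(105)
  m <- matrix(rnorm(32), 8, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  m[, 2] <- m[, 1]  # identical pair
  m[, 3] <- exp(m[, 1])  # monotone nonlinear transform of column 1
  cm <- site_correlation_matrix(m)
  expect_equal(cm["A", "B"], 1)
  expect_equal(cm["B", "A"], 1)
  expect_equal(cm["C", "A"], 1)            # Spearman exact under monotone map
  expect_lt(cm["A", "C"], 1)               # Pearson attenuated
  # against the direct formula
  expect_equal(cm["A", "D"], cor(m[, "A"], m[, "D"]))
  expect_equal(cm["D", "A"], cor(m[, "A"], m[, "D"], method = "spearman"))
  expect_equal(diag(unclass(cm)), rep(1, 4), ignore_attr = TRUE)
  # zero-variance column flagged
  m[, 4] <- 2
  cm2 <- site_correlation_matrix(m)
  expect_true(is.na(cm2["A", "D"]))
  expect_equal(attr(cm2, "degenerate_sessions"), "D")
})

test_that("class summaries average estimable IDPs and preserve ordering", {
  tb <- tibble::tibble(class_label = c("a", "a", "b", "b", "b"),
                       icc = c(0.8, 0.8, 0.2, 0.3, NA),
                       skipped = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  s <- class_icc_summary(tb)
  expect_equal(s$mean_icc[s$class_label == "a"], 0.8)
  expect_equal(s$sd_icc[s$class_label == "a"], 0)
  expect_equal(s$n_skipped[s$class_label == "b"], 1)
  # recovery: simulated class with true ICC 0.9 averages close to truth,
  # and classes with distinct true ICCs keep their ordering
  specs <- idp_specs_from_icc(300, rep(c(0.9, 0.4), each = 150),
                              class_label = rep(c("hi", "lo"), each = 150))
  tbl <- generate_travelling_heads(specs = specs, seed = 106)
  s2 <- class_icc_summary(icc_scan(tbl))
  expect_lt(abs(s2$mean_icc[s2$class_label == "hi"] - 0.9), 0.06)
  expect_gt(s2$mean_icc[s2$class_label == "hi"],
            s2$mean_icc[s2$class_label == "lo"])
})
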