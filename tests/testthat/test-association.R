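test_that("covariate encoding matches the published conventions", {
  clin <- as_clinical(data.frame(
    patient_id = c("P1", "P2", "P3"),
    sex = c("female", "male", "female"),
    age = c(54, 60, NA),
    wos = c(5, 4, 6),
    survived = c(1, 0, 1), stringsAsFactors = FALSE))
  pb <- data.frame(patient_id = c("P1", "P2", "P3"),
                   label = c("A", "C", "A"), stringsAsFactors = FALSE)
  expect_message(design <- encode_covariates(clin, pb), "dropped 1")
  expect_equal(attr(design, "n_dropped"), 1L)
  p1 <- design[design$patient_id == "P1", ]
  expect_equal(unlist(p1[c("female", "age", "severe", "bias_A")]),
               c(female = 1, age = 54, severe = 1, bias_A = 1))
  p2 <- design[design$patient_id == "P2", ]
  expect_equal(unlist(p2[c("female", "severe")]), c(female = 0, severe = 0))
  expect_false("P3" %in% design$patient_id)
  # all records incomplete -> error
  clin$age <- NA
  expect_error(suppressMessages(encode_covariates(clin, pb)), "empty design")
})

test_that("one-covariate logistic coefficient equals the contingency log odds ratio", {
  design <- data.frame(
    patient_id = sprintf("P%02d", 1:80),
    outcome = c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30)),
    exposed = c(rep(1, 40), rep(0, 40)))
  fit <- fit_logistic(design)
  expect_equal(fit$estimate[fit$term == "exposed"], log(9), tolerance = 1e-6)
  expect_equal(fit$ci_low, fit$estimate - 1.96 * fit$se)
  expect_equal(fit$ci_high, fit$estimate + 1.96 * fit$se)
  expect_true(all(fit$p_value >= 0 & fit$p_value <= 1))
  expect_true(attr(fit, "converged"))
  expect_equal(attr(fit, "n"), 80L)
})

test_that("separation, collinearity and degenerate outcomes are rejected", {
  design <- data.frame(patient_id = sprintf("P%02d", 1:40),
                       outcome = rep(c(1, 0), each = 20),
                       x = rep(c(1, 0), each = 20))
  expect_error(fit_logistic(design), "separation.*x")
  design$x <- stats::rnorm(40)
  design$y <- 2 * design$x
  expect_error(fit_logistic(design), "collinear")
  design$y <- NULL
  design$outcome <- 1
  expect_error(fit_logistic(design), "constant")
})

test_that("Kaplan-Meier product-limit estimates match hand calculations", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 0, 0, 0))
  expect_equal(km$surv[km$time == 1], 0.75)  # 1 * (1 - 1/4)
  expect_true(all(kaplan_meier(c(5, 6, 7), c(0, 0, 0))$surv == 1))
  km2 <- kaplan_meier(c(1, 2), c(1, 1))
  expect_equal(km2$surv[km2$time == 2], 0)
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "negative")
  # survival is non-increasing, starts at/below 1, within [0, 1]
  set.seed(3)
  km3 <- kaplan_meier(stats::rexp(50), stats::rbinom(50, 1, 0.7))
  expect_true(all(diff(km3$surv) <= 1e-12))
  expect_true(all(km3$surv >= 0 & km3$surv <= 1))
})

test_that("Kaplan-Meier equals the empirical survival function without censoring", {
  set.seed(4)
  times <- stats::rexp(60)
  km <- kaplan_meier(times, rep(1, 60))
  emp <- vapply(km$time, function(t) mean(times > t), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("log-rank test is null on identical groups and powered on separated ones", {
  times <- c(1, 2, 3, 4, 1, 2, 3, 4)
  events <- rep(1, 8)
  grp <- rep(c("a", "b"), each = 4)
  res <- logrank_test(times, events, grp)
  expect_equal(res$value, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)

  set.seed(8)
  t2 <- c(stats::rexp(200, 1), stats::rexp(200, 2))
  res2 <- logrank_test(t2, rep(1, 400), rep(c("a", "b"), each = 200))
  expect_lt(res2$p_value, 0.05)
  expect_error(logrank_test(1:3, c(1, 1, 1), c("a", "a", "a")), "two non-empty")
  expect_error(logrank_test(1:4, rep(0, 4), rep(c("a", "b"), 2)), "one event")
})

test_that("hypergeometric tails match the frozen enumeration example", {
  res <- hypergeometric_overlap(4, 5, 4, 10)
  expect_equal(res$p_over, 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeometric_overlap(0, 5, 4, 10)$p_over, 1)
  degen <- hypergeometric_overlap(0, 0, 4, 10)
  expect_equal(degen$p_over, 1)
  expect_equal(degen$p_under, 1)
  expect_error(hypergeometric_overlap(5, 4, 4, 10), "inconsistent")
})

test_that("hypergeometric tails complement each other", {
  set.seed(9)
  for (i in 1:30) {
    N <- sample(2:40, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(seq(1, max(1, min(K, n))), 1)
    if (k > min(K, n)) next
    res <- hypergeometric_overlap(k, K, n, N)
    prev <- hypergeometric_overlap(k - 1, K, n, N)
    expect_equal(res$p_over + prev$p_under, 1, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney exact branch matches enumeration and symmetry", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$p_value, 2 / 6, tolerance = 1e-12)
  expect_identical(attr(res, "method"), "exact")
  same <- mann_whitney(c(1, 2, 2, 5), c(2, 1, 5, 2))
  expect_equal(same$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1), "empty")
})

test_that("Mann-Whitney agrees with wilcox.test on tie-free small samples", {
  set.seed(10)
  for (i in 1:20) {
    a <- stats::rnorm(sample(2:6, 1))
    b <- stats::rnorm(sample(2:6, 1))
    mine <- mann_whitney(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$value, unname(ref$statistic))
  }
})

test_that("the normal approximation tracks the exact branch closely", {
  set.seed(11)
  dev <- numeric(15)
  for (i in 1:15) {
    a <- stats::rnorm(10); b <- stats::rnorm(10)
    exact <- mann_whitney(a, b, exact_limit = 20L)$p_value
    approx <- mann_whitney(a, b, exact_limit = 12L)$p_value
    dev[i] <- abs(exact - approx)
  }
  # continuity-corrected normal: deviation from the exact enumeration is
  # bounded by the discreteness of the exact distribution at n = 10+10
  expect_lt(max(dev), 0.01)
})

test_that("correlation tests behave under monotone transforms and reversals", {
  x <- c(0.2, 1.4, 2.1, 3.3, 4.8)
  expect_equal(spearman_corr(x, exp(x))$value, 1)
  expect_equal(spearman_corr(x, -x)$value, -1)
  expect_equal(pearson_corr(x, -x)$value, -1, tolerance = 1e-12)
  set.seed(12)
  y <- stats::rnorm(5)
  expect_equal(spearman_corr(x, y)$value, spearman_corr(exp(x), y)$value)
  expect_error(pearson_corr(rep(1, 5), x), "constant")
  expect_error(spearman_corr(1:2, 1:2), "at least 3")
})

test_that("differential protein selection enforces both thresholds with direction", {
  tp <- function(p, lfc) data.frame(protein = "X", p = p, lfc = lfc)
  base <- data.frame(protein = c("A", "B"), p = c(0.5, 0.9), lfc = c(1, 1))
  sel <- select_de_proteins(list(tp(0.04, 0.5), base, base))
  expect_identical(sel$protein, "X")
  expect_false(sel$late_significant)
  expect_equal(nrow(select_de_proteins(list(tp(0.06, 2), base, base))), 0L)
  expect_equal(nrow(select_de_proteins(list(tp(0.001, -1), base, base))), 0L)
  late <- select_de_proteins(list(base, base, tp(0.01, 2)))
  expect_true(late$late_significant)
  expect_error(select_de_proteins(list(data.frame(x = 1))), "malformed")
})

test_that("confident gene filters use floor arithmetic and flag empty sets", {
  set.seed(13)
  m <- matrix(stats::runif(500), nrow = 5,
              dimnames = list(paste0("s", 1:5), sprintf("G%03d", 1:100)))
  em <- expression_matrix(m, "ln_cpm1")
  expect_length(confident_gene_filter(em, "top_decile")$genes, 10L)
  small <- expression_matrix(m[, 1:10], "ln_cpm1")
  expect_length(confident_gene_filter(small, "top_decile")$genes, 1L)
  zero <- expression_matrix(matrix(0, 2, 3, dimnames = list(c("a", "b"),
                                                            c("g1", "g2", "g3"))),
                            "counts")
  expect_message(gs <- confident_gene_filter(zero, "abs_threshold"), "empty")
  expect_true(gs$empty)
  keep <- confident_gene_filter(em, "abs_threshold", threshold = 0.5)$genes
  expect_setequal(keep, names(which(colMeans(m) > 0.5)))
})

test_that("antibody gene set keeps immunoglobulin prefixes minus the stop-list", {
  gs <- antibody_gene_set(c("IGHG1", "IGKC", "IGLV1-40", "CD8A", "IGHMBP2"))
  expect_setequal(gs$genes, c("IGHG1", "IGKC", "IGLV1-40"))
  expect_message(empty <- antibody_gene_set(c("CD8A", "MS4A1")),
                 "no immunoglobulin")
  expect_true(empty$empty)
})
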