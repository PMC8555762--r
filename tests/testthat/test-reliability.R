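# brute-force two-way mean squares by explicit double loops (oracle)
bf_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ssr <- 0
  for (i in 1:n) ssr <- ssr + k * (mean(m[i, ]) - grand)^2
  ssc <- 0
  for (j in 1:k) ssc <- ssc + n * (mean(m[, j]) - grand)^2
  sse <- 0
  for (i in 1:n) for (j in 1:k) {
    sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + grand)^2
  }
  c(MSR = ssr / (n - 1), MSC = ssc / (k - 1), MSE = sse / ((n - 1) * (k - 1)))
}

test_that("perfectly agreeing raters give ICC(2,1) = 1", {
  m <- cbind(c(1, 5, 9, 2), c(1, 5, 9, 2), c(1, 5, 9, 2))
  expect_equal(icc(m)$estimate, 1)
  expect_false(icc(m)$degenerate)
})

test_that("mean squares and both ICC forms match a brute-force ANOVA oracle", {
  set.seed(402)
  for (rep in 1:10) {
    m <- matrix(stats::rnorm(15, mean = 5), nrow = 5, ncol = 3) +
      stats::rnorm(5)  # row effects recycled down columns
    ms <- bf_mean_squares(m)
    r1 <- icc(m, "ICC2_1")
    rk <- icc(m, "ICC2_k")
    expect_equal(r1$mean_squares, ms, tolerance = 1e-9)
    n <- 5; k <- 3
    expect_equal(r1$estimate,
                 (ms["MSR"] - ms["MSE"]) /
                   (ms["MSR"] + (k - 1) * ms["MSE"] +
                      k * (ms["MSC"] - ms["MSE"]) / n),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(rk$estimate,
                 (ms["MSR"] - ms["MSE"]) / (ms["MSR"] + (ms["MSC"] - ms["MSE"]) / n),
                 tolerance = 1e-9, ignore_attr = TRUE)
    # and against the standard two-way anova decomposition
    df <- data.frame(y = as.vector(m),
                     subject = factor(rep(1:n, k)),
                     rater = factor(rep(1:k, each = n)))
    tab <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
    expect_equal(unname(r1$mean_squares),
                 tab[c("subject", "rater", "Residuals"), "Mean Sq"],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("ICC is invariant to shifting and positive scaling of all cells", {
  set.seed(7)
  m <- matrix(stats::rnorm(12), 4, 3) + stats::rnorm(4)
  base <- icc(m)$estimate
  expect_equal(icc(m + 100)$estimate, base, tolerance = 1e-9)
  expect_equal(icc(m * 3.7)$estimate, base, tolerance = 1e-9)
  expect_equal(icc(m * 3.7 + 100, "ICC2_k")$estimate,
               icc(m, "ICC2_k")$estimate, tolerance = 1e-9)
})

test_that("the averaged-rater form dominates the single-rater form", {
  set.seed(11)
  for (rep in 1:20) {
    m <- matrix(stats::rnorm(12), 4, 3) + 2 * stats::rnorm(4)
    e1 <- icc(m, "ICC2_1")$estimate
    ek <- icc(m, "ICC2_k")$estimate
    if (e1 >= 0 && e1 <= 1 && ek >= 0 && ek <= 1) expect_gte(ek, e1)
  }
})

test_that("ICC approaches the variance-ratio expectation on large panels", {
  set.seed(5150)
  n <- 400; k <- 3
  subject_effect <- stats::rnorm(n, sd = 1)
  m <- matrix(subject_effect, n, k) + matrix(stats::rnorm(n * k, sd = 1), n, k)
  expect_equal(icc(m)$estimate, 0.5, tolerance = 0.08)
})

test_that("degenerate and undersized matrices are handled as specified", {
  flat <- matrix(3.3, 4, 3)
  res <- icc(flat)
  expect_true(res$degenerate)
  expect_equal(res$estimate, 1)
  expect_error(icc(matrix(1:3, ncol = 1)), "at least 2")
  expect_error(icc(matrix(1:2, nrow = 1)), "at least 2")
  # negative estimates are reported, flagged, never truncated
  crossing <- cbind(c(1, 10), c(10, 1), c(1, 10))
  res2 <- icc(crossing)
  expect_lt(res2$estimate, 0)
  expect_true(res2$negative)
})

test_that("q-correlation spans identical, reversed and independent sorts", {
  a <- random_sort(seed = 1)
  expect_equal(q_correlation(a, a)$estimate, 1)
  # capacity-respecting reversal: the same item ordering refilled bottom-up
  fwd <- extremal_odf_sort(the_bank, maximize = TRUE)
  bwd <- extremal_odf_sort(the_bank, maximize = FALSE)
  expect_lt(q_correlation(fwd, bwd)$estimate, -0.5)
  # independent random sorts decorrelate on average
  cors <- vapply(1:40, function(i) {
    q_correlation(random_sort(2 * i), random_sort(2 * i + 1),
                  method = "linear")$estimate
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.05)
  # mismatched item sets are a domain error
  partial <- qsort(stats::setNames(rep(1L, 10), 1:10))
  expect_error(q_correlation(a, partial), "different item sets")
})

test_that("score matrices round-trip and noiseless panels are perfectly reliable", {
  res <- reliability_experiment(n_subjects = 5, n_raters = 3, noise_sd = 0,
                                seed = 17, scales = c("ODF", "C1", "L7", "D30"),
                                bank = the_bank)
  expect_equal(res$estimate, rep(1, 4))
  # matrix file round-trip
  profiles <- lapply(1:4, random_profile)
  panel <- rater_panel(profiles, list(rater_model(0.05, 3),
                                      rater_model(0.05, 4)), bank = the_bank)
  m <- score_matrix(panel, bank = the_bank, scale = "ODF")
  path <- tempfile(fileext = ".csv")
  write_score_matrix(m, path)
  expect_equal(read_score_matrix(path), m, tolerance = 1e-12)
  expect_error(score_matrix(panel, bank = the_bank, scale = "X9"),
               "unknown scale")
})

test_that("simulated reliability degrades from perfect toward zero with rater noise", {
  iccs <- vapply(c(0, 0.05, 2), function(nsd) {
    reliability_experiment(n_subjects = 6, n_raters = 2, noise_sd = nsd,
                           seed = 29, scales = "ODF",
                           bank = the_bank)$estimate
  }, numeric(1))
  expect_equal(iccs[1], 1)
  expect_lt(iccs[3], iccs[2])
  expect_lt(iccs[3], 0.5)
})
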