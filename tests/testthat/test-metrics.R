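test_that("metrics match hand-computed values", {
  perfect <- solubility_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$acc_half_log, 100)
  # constant predictions: Pearson r is NA here, by design
  m <- suppressWarnings(solubility_metrics(c(0, 0, 0), c(1, -1, 0.3)))
  expect_equal(m$rmse, sqrt(2.09 / 3), tolerance = 1e-12)
  expect_equal(m$mae, 2.3 / 3, tolerance = 1e-12)
  expect_equal(m$acc_half_log, 100 / 3, tolerance = 1e-12)
  expect_identical(m$n, 3L)
})

test_that("metrics agree with a brute-force implementation on random input", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(2:200, 1)
    p <- rnorm(n, sd = 2)
    o <- rnorm(n, sd = 2)
    m <- solubility_metrics(p, o)
    expect_lt(abs(m$rmse - sqrt(sum((p - o)^2) / n)), 1e-12)
    expect_lt(abs(m$mae - sum(abs(p - o)) / n), 1e-12)
    r_brute <- sum((p - mean(p)) * (o - mean(o))) /
      sqrt(sum((p - mean(p))^2) * sum((o - mean(o))^2))
    expect_lt(abs(m$pearson_r - r_brute), 1e-12)
    expect_lt(abs(m$acc_half_log - 100 * sum(abs(p - o) <= 0.5) / n), 1e-12)
  }
})

test_that("metrics are translation-invariant, order-invariant and bounded", {
  set.seed(3)
  p <- rnorm(30); o <- rnorm(30)
  m <- solubility_metrics(p, o)
  shifted <- solubility_metrics(p + 2.5, o + 2.5)
  expect_equal(m[c("rmse", "mae", "pearson_r", "acc_half_log")],
               shifted[c("rmse", "mae", "pearson_r", "acc_half_log")],
               tolerance = 1e-12)
  perm <- sample(30)
  reordered <- solubility_metrics(p[perm], o[perm])
  expect_equal(m$rmse, reordered$rmse, tolerance = 1e-14)
  expect_gte(m$rmse, m$mae)
  expect_true(m$acc_half_log >= 0 && m$acc_half_log <= 100)
  # the +-0.5 boundary is inclusive
  edge <- suppressWarnings(solubility_metrics(c(0.5, 0.51), c(0, 0)))
  expect_equal(edge$acc_half_log, 50)
})

test_that("degenerate inputs are flagged", {
  expect_error(solubility_metrics(1:3, 1:4), "equal length")
  expect_error(solubility_metrics(1, 1), "at least 2")
  expect_warning(m <- solubility_metrics(c(1, 1), c(0, 2)), "constant")
  expect_true(is.na(m$pearson_r))
})

test_that("uncertainty summaries match direct computation", {
  pred <- data.frame(sigma2_ale = c(1, 2, 3, 4), sigma2_epi = c(0, 0, 0, 0.4))
  s <- summarize_uncertainty(pred)
  expect_equal(s$summary$sigma2_ale[s$summary$statistic == "mean"], 2.5)
  expect_equal(s$summary$sigma2_ale[s$summary$statistic == "median"], 2.5)
  expect_equal(s$summary$sigma2_ale[s$summary$statistic == "max"], 4)
  expect_equal(s$summary$sigma2_epi[s$summary$statistic == "mean"], 0.1)
  expect_equal(s$summary$sigma2_epi[s$summary$statistic == "p95"],
               unname(quantile(c(0, 0, 0, 0.4), 0.95)))
  # identical members -> epistemic summaries all zero
  degen <- summarize_uncertainty(data.frame(sigma2_ale = c(1, 1),
                                            sigma2_epi = c(0, 0)))
  expect_true(all(degen$summary$sigma2_epi == 0))
})

test_that("parity export embeds the metrics and round-trips the data", {
  set.seed(12)
  p <- rnorm(3); o <- rnorm(3)
  path <- withr::local_tempfile(fileext = ".csv")
  met <- parity_export(p, o, path)
  df <- read.csv(path, comment.char = "#")
  expect_identical(nrow(df), 3L)
  expect_equal(df$predicted, p, tolerance = 1e-15)
  expect_equal(df$observed, o, tolerance = 1e-15)
  header <- grep("^#", readLines(path), value = TRUE)
  rmse_line <- as.numeric(sub("# rmse=", "", header[1]))
  direct <- solubility_metrics(p, o)
  expect_equal(rmse_line, direct$rmse, tolerance = 1e-15)
  expect_equal(met$mae, direct$mae, tolerance = 1e-15)
})
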