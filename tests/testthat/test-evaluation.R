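test_that("the KS statistic matches the pooled-ECDF oracle and ks.test", {
  expect_equal(ks_statistic(c(1, 2), c(3, 4)), 1) # disjoint supports
  expect_equal(ks_statistic(c(1, 2), c(1, 3)), 0.5)
  x <- withr::with_seed(1, rnorm(30))
  expect_equal(ks_statistic(x, x), 0)
  expect_error(ks_statistic(numeric(0), 1), "empty sample")

  for (s in 1:200) {
    pair <- withr::with_seed(s, list(
      x = round(rnorm(sample(2:12, 1)), 1), # rounding forces ties
      y = round(rnorm(sample(2:12, 1), sd = 2), 1)
    ))
    d <- ks_statistic(pair$x, pair$y)
    expect_equal(d, ks_oracle(pair$x, pair$y), tolerance = 1e-12)
    expect_equal(d, ks_statistic(pair$y, pair$x), tolerance = 1e-12) # symmetry
  }
  # independent implementation cross-check
  x <- withr::with_seed(3, rnorm(40)); y <- withr::with_seed(4, rnorm(60, 1))
  expect_equal(ks_statistic(x, y),
               unname(suppressWarnings(stats::ks.test(x, y)$statistic)))
})

test_that("Jaccard similarity follows set arithmetic", {
  expect_equal(jaccard_categories(c("a", "b", "a"), c("b", "a")), 1)
  expect_equal(jaccard_categories(c("a"), c("b")), 0)
  expect_equal(jaccard_categories(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard_categories(c("x", "y"), c("y", "z")),
               jaccard_categories(c("y", "z"), c("x", "y"))) # symmetry
  expect_error(jaccard_categories(character(0), "a"), "empty column")
})

test_that("correlation preservation counts pairs within tolerance", {
  a <- 1:20
  b <- rep(c(0, 1, 1, 0), 5) # exactly uncorrelated with a by construction
  real <- tibble::tibble(a = a, b = b, c = a + 0)
  synth <- tibble::tibble(a = a, b = b, c = -a + 0)
  # pairs: (a,b) preserved, (a,c) flips 1 -> -1 (broken), (b,c) 0 -> 0 (preserved)
  expect_equal(correlation_preservation_rate(real, synth, tau = 0.1),
               100 * 2 / 3, tolerance = 1e-10)
  expect_equal(correlation_preservation_rate(real, real, tau = 0.1), 100)
  expect_equal(correlation_preservation_rate(real, synth, tau = 2), 100) # bound

  # monotone non-decreasing in tau
  taus <- c(0.01, 0.1, 0.5, 1, 2)
  rates <- vapply(taus, function(t) correlation_preservation_rate(real, synth, t),
                  numeric(1))
  expect_true(all(diff(rates) >= 0))

  real$d <- 1
  synth$d <- 1
  expect_warning(correlation_preservation_rate(real, synth, 0.1), "constant column")
})

test_that("a full fidelity report is internally consistent", {
  sch <- tiny_schema()
  real <- tiny_table(n = 60, seed = 2)
  synth <- tiny_table(n = 80, seed = 3)

  rep <- evaluate_fidelity(real, synth, sch)
  expect_equal(rep$continuous$column, c("x", "y")) # schema order
  expect_equal(rep$categorical$column, c("g", "h"))
  expect_equal(rep$mean_ks, mean(rep$continuous$ks), tolerance = 1e-12)
  expect_true(all(rep$continuous$ks >= 0 & rep$continuous$ks <= 1))
  expect_true(all(rep$categorical$jaccard >= 0 & rep$categorical$jaccard <= 1))
  expect_equal(diag(rep$cor_real), rep(1, 2), ignore_attr = TRUE)
  expect_equal(rep$cor_synth, t(rep$cor_synth))

  self <- evaluate_fidelity(real, real, sch)
  expect_equal(self$continuous$ks, c(0, 0))
  expect_equal(self$categorical$jaccard, c(1, 1))
  expect_equal(self$preservation_rate, 100)

  td <- tidy(rep)
  expect_equal(nrow(td), 4L)
  gl <- glance(rep)
  expect_equal(gl$mean_ks, rep$mean_ks)
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("distribution exports are valid CDFs and complete counts", {
  sch <- tiny_schema()
  real <- tiny_table(n = 50, seed = 4)
  synth <- tiny_table(n = 70, seed = 5)
  dir <- withr::local_tempdir()

  files <- export_distribution_data(real, synth, sch, dir)
  expect_length(files, 4L)
  for (f in files[grepl("cdf_", files)]) {
    d <- readr::read_csv(f, show_col_types = FALSE)
    expect_true(all(diff(d$cdf_real) >= 0))
    expect_true(all(diff(d$cdf_synth) >= 0))
    expect_equal(d$cdf_real[nrow(d)], 1)
    expect_equal(d$cdf_synth[nrow(d)], 1)
  }
  for (f in files[grepl("freq_", files)]) {
    d <- readr::read_csv(f, show_col_types = FALSE)
    expect_equal(sum(d$n_real), 50L)
    expect_equal(sum(d$n_synth), 70L)
  }
  expect_error(export_distribution_data(real, synth[0, ], sch, dir), "empty table")
})
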