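test_that("sliding windows tile the chromosome and keep the partial tail", {
  w <- sliding_windows(30000, 10000)
  expect_equal(nrow(w), 3L)
  expect_false(any(w$partial))

  w <- sliding_windows(25000, 10000)
  expect_equal(nrow(w), 3L)
  expect_equal(c(w$start[3], w$end[3]), c(20001L, 25000L))
  expect_equal(w$partial, c(FALSE, FALSE, TRUE))

  w <- sliding_windows(5000, 10000)
  expect_equal(nrow(w), 1L)
  expect_true(w$partial)

  # overlapping windows when step < width
  w <- sliding_windows(20000, 10000, step = 5000)
  expect_equal(w$start, c(1L, 5001L, 10001L, 15001L))

  expect_error(sliding_windows(1000, 0), class = "dfbf_config_error")
  expect_error(sliding_windows(1000, 100, step = -1),
               class = "dfbf_config_error")
})

test_that("a scan of the maximal-introgression fixture gives full support", {
  sites <- make_pattern_fixture(10, 0, 1, 1)
  res <- scan_introgression(sites, width = 100, lambda_s = 100,
                            lambda_p = 10)
  expect_s3_class(res, "introgression_scan")
  expect_equal(nrow(res), 1L)
  expect_equal(res$n_snps, 10L)
  expect_equal(res$df, 1)
  expect_equal(res$df_theta, 1)
  expect_equal(res$df_bf, 59.0677731896, tolerance = 1e-8)
  expect_equal(res$supported_model, "ABBA (P2<->P3)")
  expect_equal(res$evidence, "very strong")
})

test_that("windows without sites are reported with missing statistics", {
  sites <- make_pattern_fixture(10, 0, 1, 1)
  res <- scan_introgression(sites, width = 100, lambda_s = 100,
                            lambda_p = 10,
                            chrom_lengths = c(fixture = 250))
  expect_equal(nrow(res), 3L)
  expect_equal(res$n_snps, c(10L, 0L, 0L))
  expect_true(all(is.na(res$df[2:3])))
  expect_true(all(is.na(res$df_bf[2:3])))
  expect_true(all(is.na(res$df_theta[2:3])))
})

test_that("symmetric windows scan to the null result", {
  sites <- make_pattern_fixture(8, 0.5, 0.5, 0.5)
  res <- scan_introgression(sites, width = 100, lambda_s = 46)
  expect_equal(res$df, 0)
  expect_equal(res$df_theta, 0)
  expect_equal(res$df_bf, 1)
  expect_equal(res$supported_model, "none")
})

test_that("window summaries are additive under concatenation", {
  a <- random_sites(30, seed = 21)
  b <- dplyr::mutate(random_sites(20, seed = 22), pos = pos + 30L)
  merged <- summarize_window(dplyr::bind_rows(a, b))
  parts <- dplyr::bind_rows(summarize_window(a), summarize_window(b))
  sums <- grep("^sum_", names(merged), value = TRUE)
  for (col in sums) {
    expect_equal(merged[[col]], sum(parts[[col]]), tolerance = 1e-12)
  }
  expect_equal(merged$n_sites, sum(parts$n_sites))
})

test_that("single-SNP extreme-df windows are reported, with low evidence", {
  # one fixed-difference SNP in its own window: df hits 1 but the Bayes
  # factor must expose the thin support rather than the window vanishing
  sites <- make_pattern_fixture(1, 0, 1, 1)
  res <- scan_introgression(sites, width = 100, lambda_s = 46,
                            lambda_p = 46)
  expect_equal(nrow(res), 1L)
  expect_equal(res$df, 1)
  expect_true(is.finite(res$df_bf))
  expect_lt(res$df_bf, 30)   # not "very strong" from one SNP
  n50 <- scan_introgression(make_pattern_fixture(50, 0, 1, 1), width = 100,
                            lambda_s = 46, lambda_p = 46)
  expect_gt(n50$df_bf, res$df_bf)
})

test_that("unsorted site tables are rejected", {
  sites <- make_pattern_fixture(5, 0, 1, 1)[5:1, ]
  expect_error(scan_introgression(sites, width = 100, lambda_s = 10),
               class = "dfbf_input_error")
})

test_that("scan results expose tidy and glance summaries", {
  sites <- make_pattern_fixture(10, 0, 1, 1)
  res <- scan_introgression(sites, width = 100, lambda_s = 100,
                            lambda_p = 10)
  td <- generics::tidy(res)
  expect_true(all(c("chrom", "df", "df_bf", "evidence") %in% names(td)))
  gl <- generics::glance(res)
  expect_equal(gl$n_windows, 1L)
  expect_equal(gl$lambda_p, 10)
  expect_equal(gl$max_df_bf, res$df_bf)
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
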