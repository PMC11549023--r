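# frozen oracle values computed from log-factorial sums (independent of
# lgamma()): logGamma(n) = sum(log(1:(n-1))) for integer n
LM_1000_0_10 <- -56.4196440330
LM_0_0_10 <- -13.7362292270
BF_10SNP_LS100_LP10 <- 59.0677731896

test_that("prior configuration is validated", {
  pc <- prior_config(46)
  expect_equal(pc$lambda_p, 46)       # defaults to lambda_s
  expect_error(prior_config(0), class = "dfbf_config_error")
  expect_error(prior_config(10, -1), class = "dfbf_config_error")
})

test_that("posterior shapes accumulate lambda_s-scaled pattern sums", {
  w <- accumulate_shapes(summarize_window(make_pattern_fixture(10, 0, 1, 1)),
                         lambda_s = 100)
  expect_equal(c(w$alpha_abba, w$alpha_baba, w$beta_bbaa), c(1000, 0, 0))

  w <- accumulate_shapes(summarize_window(make_pattern_fixture(1, 0.1, 0.6, 0.8)),
                         lambda_s = 1)
  expect_equal(c(w$alpha_abba, w$alpha_baba, w$beta_bbaa),
               c(0.444, 0.044, 0.012))

  w <- accumulate_shapes(summarize_window(make_pattern_fixture(0, 0, 0, 0)),
                         lambda_s = 46)
  expect_equal(c(w$alpha_abba, w$alpha_baba, w$beta_bbaa), c(0, 0, 0))

  # scaled = lambda_s x raw
  s <- random_sites(50, seed = 3)
  w <- accumulate_shapes(summarize_window(s), lambda_s = 46)
  expect_equal(w$alpha_abba, 46 * w$raw_abba, tolerance = 1e-9)
  expect_equal(w$alpha_baba, 46 * w$raw_baba, tolerance = 1e-9)
  expect_equal(w$beta_bbaa, 46 * w$raw_bbaa, tolerance = 1e-9)
})

test_that("log marginal evidence matches the log-gamma oracle and stays finite", {
  expect_equal(log_marginal(1000, 0, 10), LM_1000_0_10, tolerance = 1e-9)
  expect_equal(log_marginal(0, 0, 10), LM_0_0_10, tolerance = 1e-9)
  expect_equal(log_marginal(1, 0, 1), -log(2), tolerance = 1e-12)
  expect_true(is.finite(log_marginal(1e7, 12.5, 46)))
  expect_error(log_marginal(Inf, 0, 10), class = "dfbf_domain_error")
  expect_error(log_marginal(NA_real_, 0, 10), class = "dfbf_domain_error")
})

test_that("df_theta transforms the supported shape ratio to [0, 1]", {
  expect_equal(df_theta(5, 1, 2, df = 0), 0)
  expect_equal(df_theta(1000, 0, 0, df = 1), 1)
  expect_equal(df_theta(0.444, 0.044, 0.012, df = 0.8197), 0.9473684211,
               tolerance = 1e-9)
  # df < 0 branch uses the BABA shape; signed mode negates it
  expect_equal(df_theta(0.044, 0.444, 0.012, df = -0.8197), 0.9473684211,
               tolerance = 1e-9)
  expect_equal(df_theta(0.044, 0.444, 0.012, df = -0.8197, signed = TRUE),
               -0.9473684211, tolerance = 1e-9)
  expect_error(df_theta(0, 0, 0, df = 0.5), class = "dfbf_domain_error")
})

test_that("df_theta is invariant to the scaling factor lambda_s", {
  s <- random_sites(30, seed = 11)
  w0 <- summarize_window(s)
  ref <- df_bf_test(w0, lambda_s = 1)$df_theta
  for (ls in c(10, 46, 100, 1000)) {
    expect_equal(df_bf_test(w0, lambda_s = ls)$df_theta, ref,
                 tolerance = 1e-12)
  }
  # beta = 0 with positive alpha forces the maximum
  expect_equal(df_theta(3, 0, 0, df = 0.4), 1)
})

test_that("Jeffreys labels follow the evidence bins", {
  expect_equal(jeffreys_label(c(1, 2, 7.27, 15, 59.1, 150)),
               c("no evidence", "anecdotal", "moderate", "strong",
                 "very strong", "extreme"))
  expect_equal(jeffreys_label(0.4), "no evidence")   # sub-unit ratios
  expect_equal(jeffreys_label(Inf), "extreme")
  expect_true(is.na(jeffreys_label(NA_real_)))
})

test_that("df-BF matches the worked fixture and its zero branch", {
  w <- summarize_window(make_pattern_fixture(10, 0, 1, 1))
  res <- df_bf_test(w, lambda_s = 100, lambda_p = 10)
  expect_equal(res$df_bf, BF_10SNP_LS100_LP10, tolerance = 1e-8)
  expect_equal(res$log_marginal_abba, LM_1000_0_10, tolerance = 1e-8)
  expect_equal(res$log_marginal_baba, LM_0_0_10, tolerance = 1e-8)
  expect_equal(res$supported_model, "ABBA (P2<->P3)")
  expect_equal(res$evidence, "very strong")
  expect_equal(res$df_theta, 1)

  sym <- df_bf_test(summarize_window(make_pattern_fixture(3, 0.4, 0.4, 0.7)),
                    lambda_s = 46)
  expect_equal(sym$df, 0)
  expect_equal(sym$df_bf, 1)
  expect_equal(sym$df_theta, 0)
  expect_equal(sym$supported_model, "none")
  expect_equal(sym$evidence, "no evidence")

  empty <- df_bf_test(summarize_window(make_pattern_fixture(0, 0, 0, 0)),
                      lambda_s = 46)
  expect_true(is.na(empty$df_bf))
  expect_true(is.na(empty$df_theta))
})

test_that("df-BF grows with the number of identical introgressed SNPs", {
  w <- purrr::map_dfr(1:100, function(n) {
    summarize_window(make_pattern_fixture(n, 0, 1, 1))
  })
  bf <- df_bf_test(w, lambda_s = 100, lambda_p = 10)$df_bf
  expect_true(all(diff(bf) > 0))
})

test_that("df-BF is symmetric under exchanging P1 and P2", {
  s <- random_sites(40, seed = 13)
  res <- df_bf_test(summarize_window(s), lambda_s = 46)
  res_sw <- df_bf_test(summarize_window(swap_p1_p2(s)), lambda_s = 46)
  expect_equal(res_sw$df_bf, res$df_bf, tolerance = 1e-12)
  expect_equal(res_sw$df, -res$df, tolerance = 1e-12)
})
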