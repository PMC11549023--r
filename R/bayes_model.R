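# Conjugate-Beta model selection for introgression: posterior shape
# parameters, the df-theta estimator, log-marginal evidence and the df-BF
# Bayes factor with Jeffreys-scale labels.

# numeric tolerance below which df is treated as exactly zero
.df_zero_tol <- 1e-12

#' Prior configuration for the Beta model
#'
#' Two positive scalars govern the model. `lambda_p` is the symmetric
#' Beta(`lambda_p`, `lambda_p`) prior pseudo-count — the initial guess of
#' *no* introgression evidence; larger values make the test more
#' conservative. `lambda_s` scales the observed pattern-weight sums into
#' pseudo-observations and is conventionally set to the average number of
#' sampled haplotypes across P1, P2 and P3. By default `lambda_p = lambda_s`,
#' the conservative setting; smaller `lambda_p` (e.g. 5-15) declares strong
#' evidence from fewer supporting SNPs.
#'
#' @param lambda_s Positive scaling factor (average sample size of P1-P3).
#' @param lambda_p Positive prior pseudo-count; defaults to `lambda_s`.
#' @return A list of class `"prior_config"`.
#' @export
prior_config <- function(lambda_s, lambda_p = lambda_s) {
  if (!is.numeric(lambda_s) || length(lambda_s) != 1 || !is.finite(lambda_s) ||
      lambda_s <= 0) {
    abort("lambda_s must be a single positive number",
          class = "dfbf_config_error")
  }
  if (!is.numeric(lambda_p) || length(lambda_p) != 1 || !is.finite(lambda_p) ||
      lambda_p <= 0) {
    abort("lambda_p must be a single positive number",
          class = "dfbf_config_error")
  }
  structure(list(lambda_s = lambda_s, lambda_p = lambda_p),
            class = "prior_config")
}

#' Posterior shape parameters of the two introgression models
#'
#' Accumulates the Beta posterior shapes from a window summary: the model
#' M_ABBA (P2-P3 sharing) has shape `alpha_abba = lambda_s * sum(p2 d13)`,
#' M_BABA (P1-P3 sharing) has `alpha_baba = lambda_s * sum(p1 d23)`, and
#' both share the species-tree shape `beta_bbaa = lambda_s *
#' sum(p1 p2 (1-p3))`. Unscaled sums are retained as `raw_*` columns.
#'
#' @param w A window-summary tibble ([summarize_window()]).
#' @param lambda_s Positive scaling factor (see [prior_config()]).
#' @return `w` with columns `alpha_abba`, `alpha_baba`, `beta_bbaa`,
#'   `raw_abba`, `raw_baba`, `raw_bbaa` added.
#' @examples
#' accumulate_shapes(summarize_window(make_pattern_fixture(10, 0, 1, 1)),
#'                   lambda_s = 100)
#' @export
accumulate_shapes <- function(w, lambda_s) {
  stopifnot(is.numeric(lambda_s), all(lambda_s > 0))
  mutate(as_tibble(w),
    raw_abba = .data$sum_p2d13,
    raw_baba = .data$sum_p1d23,
    raw_bbaa = .data$sum_bbaa,
    alpha_abba = lambda_s * .data$raw_abba,
    alpha_baba = lambda_s * .data$raw_baba,
    beta_bbaa = lambda_s * .data$raw_bbaa
  )
}

#' Log marginal evidence of one Beta model
#'
#' Evaluates `log Gamma(lambda_p + alpha) + log Gamma(lambda_p + beta) -
#' log Gamma(alpha + beta + 2 lambda_p)` on the natural-log scale via
#' [lgamma()], so it stays finite for shape parameters well beyond 1e6.
#'
#' @param alpha,beta Non-negative shape accumulations.
#' @param lambda_p Positive prior pseudo-count.
#' @return Numeric vector of log marginal evidences (natural log).
#' @examples
#' log_marginal(1000, 0, 10)   # about -56.42
#' @export
log_marginal <- function(alpha, beta, lambda_p) {
  if (any(!is.finite(alpha)) || any(!is.finite(beta)) ||
      any(!is.finite(lambda_p))) {
    abort("log_marginal requires finite inputs", class = "dfbf_domain_error")
  }
  if (any(lambda_p + alpha <= 0) || any(lambda_p + beta <= 0)) {
    abort("lambda_p + shape must be positive", class = "dfbf_domain_error")
  }
  lgamma(lambda_p + alpha) + lgamma(lambda_p + beta) -
    lgamma(alpha + beta + 2 * lambda_p)
}

#' The df-theta estimate of the fraction of introgression
#'
#' Transforms the supported model's Beta shape ratio from the `[0.5, 1]`
#' range (the species-tree pattern BBAA contributes to both shapes) back to
#' the full `[0, 1]` range: `alpha / (alpha + beta) / 0.5 - 1` for the
#' model selected by the sign of `df`, and 0 when `df` is 0. The scaling
#' factor `lambda_s` cancels, so scaled and raw shapes give the same value.
#'
#' @param alpha_abba,alpha_baba,beta_bbaa Shape parameters (vectorised).
#' @param df The window's df statistic (selects the supported model).
#' @param signed If `TRUE`, windows with `df < 0` (P1-P3 sharing) report a
#'   negative df-theta; the default keeps the estimate in `[0, 1]`.
#' @return Numeric vector; `NA` where `df` is `NA`.
#' @examples
#' df_theta(0.444, 0.044, 0.012, df = 0.82)   # about 0.947
#' @export
df_theta <- function(alpha_abba, alpha_baba, beta_bbaa, df, signed = FALSE) {
  n <- length(df)
  out <- rep(NA_real_, n)
  zero <- !is.na(df) & abs(df) <= .df_zero_tol
  out[zero] <- 0
  pos <- !is.na(df) & df > .df_zero_tol
  neg <- !is.na(df) & df < -.df_zero_tol
  if (any(pos & (alpha_abba + beta_bbaa) <= 0) ||
      any(neg & (alpha_baba + beta_bbaa) <= 0)) {
    abort("df is non-zero but the supported model's shapes are all zero",
          class = "dfbf_domain_error")
  }
  out[pos] <- (alpha_abba / (alpha_abba + beta_bbaa) / 0.5 - 1)[pos]
  th_neg <- (alpha_baba / (alpha_baba + beta_bbaa) / 0.5 - 1)[neg]
  out[neg] <- if (signed) -th_neg else th_neg
  out
}

#' Jeffreys-scale evidence labels for Bayes factors
#'
#' Bins a df-BF value on Jeffreys' scale: 1 no evidence, (1,3] anecdotal,
#' (3,10] moderate, (10,30] strong, (30,100] very strong, >100 extreme.
#' Values below 1 carry no evidence for the supported model and are
#' labelled `"no evidence"` as well.
#'
#' @param bf Numeric vector of Bayes factors (`Inf` allowed).
#' @return A character vector of evidence labels (`NA` where `bf` is `NA`).
#' @examples
#' jeffreys_label(c(1, 7.27, 59.1, 150))
#' @export
jeffreys_label <- function(bf) {
  lab <- cut(bf,
             breaks = c(-Inf, 1, 3, 10, 30, 100, Inf),
             labels = c("no evidence", "anecdotal", "moderate", "strong",
                        "very strong", "extreme"),
             right = TRUE)
  as.character(lab)
}

#' Bayes-factor model selection for each window
#'
#' @description
#' The central evidence computation. For each window the log marginal
#' evidences of the two introgression models are
#' `L_A = log_marginal(alpha_abba, beta_bbaa, lambda_p)` and
#' `L_B = log_marginal(alpha_baba, beta_bbaa, lambda_p)`, and the Bayes
#' factor is the exponentiated ratio of the log marginals, anchored so that
#' equal evidence maps to 1:
#'
#' * `df = 0`  ->  `df_bf = 1`
#' * `df > 0`  ->  `df_bf = exp(L_A / L_B) - e + 1`
#' * `df < 0`  ->  `df_bf = exp(L_B / L_A) - e + 1`
#'
#' Unlike df itself, df-BF grows with the number of variant sites carrying
#' the signal, so a window whose extreme df rests on one or two SNPs is
#' assigned low evidence. If the ratio's denominator log marginal is within
#' 1e-12 of zero the Bayes factor is reported as `Inf` with a warning. A
#' window with undefined df (no informative sites) gets `NA` throughout.
#'
#' @param w A window-summary tibble ([summarize_window()] /
#'   [summarize_windows()]).
#' @param lambda_s,lambda_p Prior configuration (see [prior_config()]);
#'   `lambda_p` defaults to `lambda_s`.
#' @param signed_theta Sign convention for [df_theta()].
#' @return `w` with columns `df`, `alpha_abba`, `alpha_baba`, `beta_bbaa`,
#'   `log_marginal_abba`, `log_marginal_baba`, `df_theta`, `df_bf`,
#'   `supported_model` (`"ABBA (P2<->P3)"`, `"BABA (P1<->P3)"` or
#'   `"none"`) and `evidence` added.
#' @examples
#' w <- summarize_window(make_pattern_fixture(10, 0, 1, 1))
#' df_bf_test(w, lambda_s = 100, lambda_p = 10)   # df-BF about 59.1
#' @export
df_bf_test <- function(w, lambda_s, lambda_p = lambda_s,
                       signed_theta = FALSE) {
  prior <- prior_config(lambda_s, lambda_p)
  w <- accumulate_shapes(w, prior$lambda_s)
  df <- df_statistic(w)

  L_A <- log_marginal(w$alpha_abba, w$beta_bbaa, prior$lambda_p)
  L_B <- log_marginal(w$alpha_baba, w$beta_bbaa, prior$lambda_p)

  n <- length(df)
  bf <- rep(NA_real_, n)
  zero <- !is.na(df) & abs(df) <= .df_zero_tol
  pos <- !is.na(df) & df > .df_zero_tol
  neg <- !is.na(df) & df < -.df_zero_tol
  bf[zero] <- 1

  ratio_bf <- function(num, den, idx) {
    out <- rep(NA_real_, length(num))
    degenerate <- idx & abs(den) <= 1e-12
    if (any(degenerate)) {
      warn("denominator log marginal is numerically zero; reporting Inf")
      out[degenerate] <- Inf
    }
    ok <- idx & !degenerate
    out[ok] <- exp(num[ok] / den[ok]) - exp(1) + 1
    out
  }
  bf[pos] <- ratio_bf(L_A, L_B, pos)[pos]
  bf[neg] <- ratio_bf(L_B, L_A, neg)[neg]

  theta <- df_theta(w$alpha_abba, w$alpha_baba, w$beta_bbaa, df,
                    signed = signed_theta)
  model <- rep(NA_character_, n)
  model[zero] <- "none"
  model[pos] <- "ABBA (P2<->P3)"
  model[neg] <- "BABA (P1<->P3)"

  mutate(as_tibble(w),
    df = df,
    log_marginal_abba = L_A,
    log_marginal_baba = L_B,
    df_theta = theta,
    df_bf = bf,
    supported_model = model,
    evidence = jeffreys_label(bf)
  )
}
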