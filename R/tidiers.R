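# broom-style tidiers for scan results and BF curves.

#' Tidy an introgression scan
#'
#' @param x An [scan_introgression()] result.
#' @param ... Unused.
#' @return A plain tibble with one row per window and the statistic
#'   columns.
#' @exportS3Method generics::tidy
tidy.introgression_scan <- function(x, ...) {
  as_tibble(x)[, c("chrom", "start", "end", "n_snps", "df", "D", "fd",
                   "dp", "df_theta", "df_bf", "supported_model",
                   "evidence")]
}

#' Summarise an introgression scan in one row
#'
#' @param x An [scan_introgression()] result.
#' @param ... Unused.
#' @return A one-row tibble: number of windows and sites, the prior
#'   settings, the strongest window's Bayes factor and coordinates, and the
#'   number of windows with at least moderate evidence (df-BF > 3).
#' @exportS3Method generics::glance
glance.introgression_scan <- function(x, ...) {
  best <- which.max(replace(x$df_bf, is.na(x$df_bf), -Inf))
  tibble(
    n_windows = nrow(x),
    n_sites = sum(x$n_snps),
    lambda_s = attr(x, "lambda_s"),
    lambda_p = attr(x, "lambda_p"),
    width = attr(x, "width"),
    step = attr(x, "step"),
    max_df_bf = if (length(best) == 1 && nrow(x) > 0) x$df_bf[best] else NA_real_,
    max_df_bf_chrom = if (nrow(x) > 0) x$chrom[best] else NA_character_,
    max_df_bf_start = if (nrow(x) > 0) x$start[best] else NA_integer_,
    n_moderate_plus = sum(x$df_bf > 3, na.rm = TRUE)
  )
}

#' @export
print.introgression_scan <- function(x, ...) {
  cat("# Introgression scan: ", nrow(x), " windows, lambda_s = ",
      attr(x, "lambda_s"), ", lambda_p = ", attr(x, "lambda_p"), "\n",
      sep = "")
  NextMethod()
}
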