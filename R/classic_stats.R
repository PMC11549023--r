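# Window-level pattern-weight sums and the comparator statistics
# df, Patterson's D, fd and Dp.

#' Summarise polarized sites over a window
#'
#' Sums the per-site pattern weights needed by every window statistic. The
#' dynamic-donor sums used by fd substitute, per site, the donor frequency
#' `pD = max(p2, p3)` for both `p2` and `p3` (and, for the mirrored
#' P1-recipient configuration, `pDm = max(p1, p3)` for both `p1` and `p3`).
#'
#' @param sites A sites tibble (zero or more rows) with columns
#'   `p1, p2, p3`; `chrom`/`pos` are used for the window coordinates when
#'   present.
#' @param chrom,start,end Optional explicit window coordinates (1-based,
#'   inclusive); defaults are taken from the sites' own range.
#' @return A one-row tibble with columns `chrom, start, end, n_sites,
#'   sum_abba, sum_baba, sum_bbaa, sum_p2d13, sum_p1d23, sum_abba_dyn,
#'   sum_baba_dyn, sum_abba_dyn_m, sum_baba_dyn_m`. An empty input yields an
#'   all-zero summary.
#' @examples
#' summarize_window(make_pattern_fixture(10, 0, 1, 1))
#' @export
summarize_window <- function(sites, chrom = NULL, start = NULL, end = NULL) {
  n <- nrow(sites)
  if (is.null(chrom)) {
    chrom <- if (n > 0 && "chrom" %in% names(sites)) sites$chrom[1] else NA_character_
  }
  if (is.null(start)) {
    start <- if (n > 0 && "pos" %in% names(sites)) min(sites$pos) else NA_integer_
  }
  if (is.null(end)) {
    end <- if (n > 0 && "pos" %in% names(sites)) max(sites$pos) else NA_integer_
  }
  if (n == 0L) {
    return(tibble(chrom = chrom, start = start, end = end, n_sites = 0L,
                  sum_abba = 0, sum_baba = 0, sum_bbaa = 0,
                  sum_p2d13 = 0, sum_p1d23 = 0,
                  sum_abba_dyn = 0, sum_baba_dyn = 0,
                  sum_abba_dyn_m = 0, sum_baba_dyn_m = 0))
  }
  w <- pattern_weights(sites)
  pD <- pmax(w$p2, w$p3)
  pDm <- pmax(w$p1, w$p3)
  tibble(
    chrom = chrom, start = start, end = end, n_sites = n,
    sum_abba = sum(w$abba), sum_baba = sum(w$baba), sum_bbaa = sum(w$bbaa),
    sum_p2d13 = sum(w$p2 * w$d13), sum_p1d23 = sum(w$p1 * w$d23),
    sum_abba_dyn = sum((1 - w$p1) * pD * pD),
    sum_baba_dyn = sum(w$p1 * (1 - pD) * pD),
    sum_abba_dyn_m = sum((1 - w$p2) * pDm * pDm),
    sum_baba_dyn_m = sum(w$p2 * (1 - pDm) * pDm)
  )
}

.ratio_or_na <- function(num, den) {
  ifelse(abs(den) > 0, num / den, NA_real_)
}

#' Window statistics of introgression
#'
#' @description
#' Comparator statistics evaluated on a window summary (each vectorised over
#' the rows of `w`):
#'
#' * `df_statistic()`: the distance-based estimator of the proportion of
#'   introgression, `(sum_p2d13 - sum_p1d23) / (sum_p2d13 + sum_p1d23)`;
#'   algebraically identical to `(ABBA - BABA) / (ABBA + BABA + 2 BBAA)`.
#' * `patterson_d()`: `(ABBA - BABA) / (ABBA + BABA)`, the classic
#'   imbalance test (not a fraction estimator).
#' * `fd_statistic()`: the dynamic-donor estimator, `(ABBA - BABA)` over the
#'   same numerator recomputed with `pD = max(p2, p3)` in place of both `p2`
#'   and `p3`. Windows with a negative numerator are evaluated on the
#'   mirrored configuration (P1 as recipient, donor `max(p1, p3)`) and
#'   reported with a negative sign; see the `fd_mirrored` column of
#'   [window_statistics()].
#' * `dp_statistic()`: `(ABBA - BABA) / (ABBA + BABA + BBAA)`.
#'
#' A statistic whose denominator is zero is undefined and returned as `NA`,
#' never as 0: a window with no informative sites carries no signal, which
#' is distinct from a balanced one.
#'
#' @param w A window-summary tibble from [summarize_window()] or
#'   [summarize_windows()].
#' @return A numeric vector, one value per row of `w`.
#' @examples
#' w <- summarize_window(make_pattern_fixture(1, 0.2, 0.8, 1.0))
#' df_statistic(w)   # 0.60 / 0.68
#' patterson_d(w)
#' @export
df_statistic <- function(w) {
  .ratio_or_na(w$sum_p2d13 - w$sum_p1d23, w$sum_p2d13 + w$sum_p1d23)
}

#' @rdname df_statistic
#' @export
patterson_d <- function(w) {
  .ratio_or_na(w$sum_abba - w$sum_baba, w$sum_abba + w$sum_baba)
}

#' @rdname df_statistic
#' @export
fd_statistic <- function(w) {
  num <- w$sum_abba - w$sum_baba
  fwd <- .ratio_or_na(num, w$sum_abba_dyn - w$sum_baba_dyn)
  mir <- -.ratio_or_na(-num, w$sum_abba_dyn_m - w$sum_baba_dyn_m)
  ifelse(is.na(num) | num >= 0, fwd, mir)
}

#' @rdname df_statistic
#' @export
dp_statistic <- function(w) {
  .ratio_or_na(w$sum_abba - w$sum_baba,
               w$sum_abba + w$sum_baba + w$sum_bbaa)
}

#' All comparator statistics for each window
#'
#' @param w A window-summary tibble.
#' @return `w` with columns `df`, `D`, `fd`, `fd_mirrored` (logical: fd was
#'   evaluated on the mirrored P1-recipient configuration) and `dp` added.
#' @export
window_statistics <- function(w) {
  mutate(as_tibble(w),
    df = df_statistic(w),
    D = patterson_d(w),
    fd = fd_statistic(w),
    fd_mirrored = !is.na(.data$sum_abba - .data$sum_baba) &
      (.data$sum_abba - .data$sum_baba) < 0,
    dp = dp_statistic(w)
  )
}
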