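# Sliding-window scan: window layout, per-window summaries, and the
# assembled results table.

#' Sliding-window layout over a chromosome
#'
#' Consecutive (or overlapping, when `step < width`) windows covering
#' positions `1..chrom_length`. The final window is retained even when it is
#' shorter than `width`, and flagged `partial`.
#'
#' @param chrom_length Chromosome length in bases (>= 1).
#' @param width Window width in bases (default 10000, i.e. 10-kb windows).
#' @param step Step between window starts; defaults to `width`
#'   (consecutive, non-overlapping windows).
#' @return A tibble with columns `start`, `end` (1-based inclusive) and
#'   `partial`.
#' @examples
#' sliding_windows(25000, 10000)
#' @export
sliding_windows <- function(chrom_length, width = 10000L, step = width) {
  if (!is.numeric(width) || width < 1 || !is.numeric(step) || step < 1) {
    abort("window width and step must be positive integers",
          class = "dfbf_config_error")
  }
  if (!is.numeric(chrom_length) || chrom_length < 1) {
    abort("chrom_length must be a positive integer",
          class = "dfbf_config_error")
  }
  width <- as.integer(width); step <- as.integer(step)
  starts <- seq.int(1L, as.integer(chrom_length), by = step)
  ends <- pmin(starts + width - 1L, as.integer(chrom_length))
  keep <- starts <= chrom_length
  tibble(start = starts[keep], end = ends[keep],
         partial = (ends - starts + 1L)[keep] < width)
}

#' Summarise sites over a set of windows
#'
#' @param sites A sites tibble sorted by (`chrom`, `pos`).
#' @param windows A tibble of windows with columns `chrom`, `start`, `end`
#'   (1-based inclusive), e.g. built from [sliding_windows()].
#' @return A window-summary tibble with one row per window (in the order of
#'   `windows`), including `n_sites` and all pattern-weight sums.
#' @export
summarize_windows <- function(sites, windows) {
  stopifnot(all(c("chrom", "start", "end") %in% names(windows)))
  purrr::pmap_dfr(
    windows[c("chrom", "start", "end")],
    function(chrom, start, end) {
      sub <- sites[sites$chrom == chrom & sites$pos >= start &
                     sites$pos <= end, , drop = FALSE]
      summarize_window(sub, chrom = chrom, start = start, end = end)
    }
  )
}

#' Scan a genome for introgression in sliding windows
#'
#' Runs the full per-window analysis: pattern-weight sums, the comparator
#' statistics (df, Patterson's D, fd, Dp), and the Bayesian model selection
#' (df-theta, df-BF, supported model, Jeffreys evidence label). Windows with
#' no informative sites report `NA` statistics — they are never silently
#' suppressed, and a window whose extreme df rests on a single SNP is
#' reported with its (low) Bayes factor so that evidence can be judged
#' per window.
#'
#' @param sites A sites tibble sorted by (`chrom`, `pos`), e.g. from
#'   [read_vcf_sites()], [alignment_sites()] or [simulate_four_taxon()].
#' @param width,step Window width and step in bases (default 10-kb
#'   consecutive windows).
#' @param lambda_s Scaling factor; defaults to the average number of
#'   haplotypes sampled from P1, P2 and P3 (taken from the sites table's
#'   `n1, n2, n3` columns).
#' @param lambda_p Prior pseudo-count; defaults to `lambda_s`.
#' @param signed_theta If `TRUE`, df-theta is negative where `df < 0`.
#' @param chrom_lengths Optional named vector of chromosome lengths; by
#'   default each chromosome extends to its last observed site.
#' @return A tibble of class `"introgression_scan"`, one row per window,
#'   with columns `chrom, start, end, partial, n_snps, df, D, fd,
#'   fd_mirrored, dp, df_theta, df_bf, supported_model, evidence,
#'   log_marginal_abba, log_marginal_baba`. The prior settings are stored
#'   as attributes and shown by [glance()].
#' @examples
#' sites <- make_pattern_fixture(10, 0, 1, 1)
#' scan_introgression(sites, width = 100, lambda_s = 100, lambda_p = 10)
#' @export
scan_introgression <- function(sites, width = 10000L, step = width,
                               lambda_s = NULL, lambda_p = NULL,
                               signed_theta = FALSE, chrom_lengths = NULL) {
  stopifnot(is.data.frame(sites))
  if (nrow(sites) > 0) {
    ord <- order(sites$chrom, sites$pos)
    if (!identical(ord, seq_len(nrow(sites)))) {
      abort("sites must be sorted by (chrom, pos)",
            class = "dfbf_input_error")
    }
  }
  if (is.null(lambda_s)) {
    if (!all(c("n1", "n2", "n3") %in% names(sites)) ||
        nrow(sites) == 0 || anyNA(sites[c("n1", "n2", "n3")])) {
      abort(paste0("lambda_s not given and sites table carries no complete ",
                   "sample counts (n1, n2, n3)"),
            class = "dfbf_config_error")
    }
    lambda_s <- mean(c(max(sites$n1), max(sites$n2), max(sites$n3)))
  }
  if (is.null(lambda_p)) lambda_p <- lambda_s

  chroms <- unique(sites$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) {
      max(sites$pos[sites$chrom == ch])
    }, double(1))
    names(chrom_lengths) <- chroms
  }
  windows <- purrr::map_dfr(names(chrom_lengths), function(ch) {
    mutate(sliding_windows(chrom_lengths[[ch]], width, step),
           chrom = ch, .before = 1)
  })
  w <- summarize_windows(sites, windows)
  w$partial <- windows$partial
  res <- df_bf_test(window_statistics(w), lambda_s = lambda_s,
                    lambda_p = lambda_p, signed_theta = signed_theta)
  res <- arrange(res, .data$chrom, .data$start)
  out <- select(res, "chrom", "start", "end", "partial",
                n_snps = "n_sites", "df", "D", "fd", "fd_mirrored", "dp",
                "df_theta", "df_bf", "supported_model", "evidence",
                "log_marginal_abba", "log_marginal_baba")
  structure(out,
            class = c("introgression_scan", class(out)),
            lambda_s = lambda_s, lambda_p = lambda_p,
            width = as.integer(width), step = as.integer(step),
            signed_theta = signed_theta)
}

#' Single-window introgression test
#'
#' Convenience wrapper treating all supplied sites as one window.
#'
#' @inheritParams scan_introgression
#' @param lambda_s,lambda_p Prior configuration; `lambda_s` defaults to the
#'   mean sample size as in [scan_introgression()].
#' @return A one-row tibble as returned by [df_bf_test()] combined with the
#'   comparator statistics.
#' @export
introgression_test <- function(sites, lambda_s = NULL, lambda_p = NULL,
                               signed_theta = FALSE) {
  if (is.null(lambda_s)) {
    if (!all(c("n1", "n2", "n3") %in% names(sites)) ||
        nrow(sites) == 0 || anyNA(sites[c("n1", "n2", "n3")])) {
      abort("lambda_s not given and sites table carries no sample counts",
            class = "dfbf_config_error")
    }
    lambda_s <- mean(c(max(sites$n1), max(sites$n2), max(sites$n3)))
  }
  if (is.null(lambda_p)) lambda_p <- lambda_s
  w <- window_statistics(summarize_window(sites))
  df_bf_test(w, lambda_s = lambda_s, lambda_p = lambda_p,
             signed_theta = signed_theta)
}
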