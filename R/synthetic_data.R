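# Four-taxon coalescent simulator with a gene-flow pulse, deterministic
# frequency fixtures, and the sweep experiment driver.

#' Simulation configuration for the four-taxon model
#'
#' Defines the demography of the validation experiments: the species tree
#' (((P1,P2),P3),O) with splits at `t12`, `t123` and `t123O` (all times in
#' units of 4N generations, as in Hudson's ms), plus a single pulse of gene
#' flow at time `t_gf` moving a fraction `f` of the recipient's lineages
#' from the donor P3 (backwards in time, each P2 — or P1 — lineage jumps to
#' P3 with probability `f`).
#'
#' @param t12,t123,t123O Split times in 4N units (defaults 1, 2, 3).
#' @param t_gf Time of the gene-flow pulse in 4N units (default 0.1); must
#'   satisfy `0 < t_gf < t12 < t123 < t123O`.
#' @param f Fraction of introgression in `[0, 1]` (default 0.1).
#' @param direction `"P3->P2"` (default) or `"P3->P1"`.
#' @param seq_length Sequence length in bases (default 5000).
#' @param r Recombination parameter: expected number of independent-locus
#'   breakpoints per replicate (ms-style total rho over the region; default
#'   0.01, i.e. effectively non-recombining 5-kb loci).
#' @param s Mutation branch-scaling: expected substitutions per site per
#'   unit (4N generations) of branch length (default 0.01).
#' @param n_per_taxon Haplotypes sampled per taxon (default 8).
#' @param replicates Number of replicate loci (default 100).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(t12 = 1, t123 = 2, t123O = 3, t_gf = 0.1, f = 0.1,
                       direction = c("P3->P2", "P3->P1"),
                       seq_length = 5000L, r = 0.01, s = 0.01,
                       n_per_taxon = 8L, replicates = 100L) {
  direction <- match.arg(direction)
  if (!(0 < t_gf && t_gf < t12 && t12 < t123 && t123 < t123O)) {
    abort("times must satisfy 0 < t_gf < t12 < t123 < t123O",
          class = "dfbf_config_error")
  }
  if (f < 0 || f > 1) {
    abort("introgression fraction f must lie in [0, 1]",
          class = "dfbf_config_error")
  }
  stopifnot(seq_length >= 1, r >= 0, s > 0, n_per_taxon >= 1, replicates >= 1)
  structure(list(t12 = t12, t123 = t123, t123O = t123O, t_gf = t_gf, f = f,
                 direction = direction, seq_length = as.integer(seq_length),
                 r = r, s = s, n_per_taxon = as.integer(n_per_taxon),
                 replicates = as.integer(replicates)),
            class = "sim_config")
}

# One non-recombining genealogy: structured Kingman coalescent over the
# four populations with the configured mergers and pulse. Time in 4N units;
# pairwise coalescence rate 2 (ms scaling), i.e. total rate k(k-1) within a
# population of k lineages. Returns branch lengths and descendant sets.
.sim_genealogy <- function(cfg) {
  n <- cfg$n_per_taxon
  ntot <- 4L * n
  pop <- rep(1:4, each = n)           # 1=P1, 2=P2, 3=P3, 4=O
  desc <- diag(ntot) > 0
  birth <- rep(0, ntot)
  active <- rep(TRUE, ntot)
  blen <- numeric(2L * ntot - 2L)
  bdesc <- matrix(FALSE, 2L * ntot - 2L, ntot)
  nb <- 0L
  recipient <- if (cfg$direction == "P3->P2") 2L else 1L
  sched <- c(cfg$t_gf, cfg$t12, cfg$t123, cfg$t123O, Inf)
  si <- 1L
  t <- 0
  repeat {
    k <- tabulate(pop[active], 4L)
    rate <- sum(k * (k - 1))
    dt <- if (rate > 0) rexp(1L, rate) else Inf
    if (t + dt >= sched[si]) {
      t <- sched[si]
      if (si == 1L) {
        idx <- which(active & pop == recipient)
        mv <- idx[runif(length(idx)) < cfg$f]
        pop[mv] <- 3L
      } else if (si == 2L) {
        pop[active & pop == 2L] <- 1L
      } else if (si == 3L) {
        pop[active & pop == 3L] <- 1L
      } else {
        pop[active & pop == 4L] <- 1L
      }
      si <- si + 1L
      next
    }
    t <- t + dt
    p <- sample.int(4L, 1L, prob = k * (k - 1))
    pair <- which(active & pop == p)
    pair <- pair[sample.int(length(pair), 2L)]
    for (i in pair) {
      nb <- nb + 1L
      blen[nb] <- t - birth[i]
      bdesc[nb, ] <- desc[i, ]
    }
    desc[pair[1L], ] <- desc[pair[1L], ] | desc[pair[2L], ]
    birth[pair[1L]] <- t
    active[pair[2L]] <- FALSE
    if (sum(active) == 1L) break
  }
  list(len = blen[seq_len(nb)], desc = bdesc[seq_len(nb), , drop = FALSE])
}

# Drop infinite-sites mutations on one genealogy restricted to `bases`
# available positions; returns derived-allele carrier sets per site.
.sim_mutations <- function(gen, cfg, bases) {
  total_len <- sum(gen$len)
  nm <- rpois(1L, total_len * cfg$s * length(bases))
  nm <- min(nm, length(bases))
  if (nm == 0L) return(NULL)
  b <- sample.int(length(gen$len), nm, replace = TRUE, prob = gen$len)
  pos <- sort(sample(bases, nm))
  list(carriers = gen$desc[b, , drop = FALSE], pos = pos)
}

#' Simulate four-taxon data with a gene-flow pulse
#'
#' Coalescent simulation of the configured demography under infinite-sites
#' mutation. Each replicate is an independent locus of `seq_length` bases;
#' recombination is approximated by splitting the locus into
#' `1 + Poisson(r)` independently coalescing segments (at the default
#' `r = 0.01` virtually all replicates are single genealogies). Sites are
#' polarized against the outgroup exactly as alignment/VCF input would be:
#' mutations making the outgroup polymorphic are discarded.
#'
#' @param config A [sim_config()].
#' @param as `"sites"` (default) returns one sites tibble with a
#'   `replicate` column; `"alignment"` returns a list of
#'   `"dfbf_alignment"` objects (one per replicate) together with the
#'   matching population map in attribute `"pop_map"`.
#' @param seed Optional integer seed; the same seed reproduces the output
#'   exactly.
#' @return See `as`.
#' @examples
#' cfg <- sim_config(f = 0.5, replicates = 3)
#' sites <- simulate_four_taxon(cfg, seed = 1)
#' @export
simulate_four_taxon <- function(config, as = c("sites", "alignment"),
                                seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  as <- match.arg(as)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_per_taxon
  samples <- paste0(rep(c("P1", "P2", "P3", "O"), each = n), "_",
                    rep(seq_len(n), 4L))
  pm <- population_map(samples, rep(.dfbf_roles, each = n))

  one_replicate <- function(rep_id) {
    nbreak <- rpois(1L, config$r)
    cuts <- sort(sample.int(config$seq_length - 1L,
                            min(nbreak, config$seq_length - 1L)))
    bounds <- c(0L, cuts, config$seq_length)
    segs <- purrr::map(seq_len(length(bounds) - 1L), function(i) {
      bases <- (bounds[i] + 1L):bounds[i + 1L]
      gen <- .sim_genealogy(config)
      .sim_mutations(gen, config, bases)
    })
    segs <- segs[!vapply(segs, is.null, logical(1))]
    if (length(segs) == 0L) {
      return(list(carriers = matrix(FALSE, 0L, 4L * n), pos = integer()))
    }
    list(carriers = do.call(rbind, purrr::map(segs, "carriers")),
         pos = unlist(purrr::map(segs, "pos")))
  }

  o_cols <- (3L * n + 1L):(4L * n)
  role_cols <- list(P1 = 1:n, P2 = (n + 1L):(2L * n),
                    P3 = (2L * n + 1L):(3L * n), O = o_cols)

  carriers_to_sites <- function(cm, pos, rep_id) {
    nO <- rowSums(cm[, o_cols, drop = FALSE])
    keep <- nO == 0L | nO == n
    cm <- cm[keep, , drop = FALSE]
    if (nrow(cm) == 0L) {
      return(tibble(replicate = integer(), chrom = character(),
                    pos = integer(), p1 = double(), p2 = double(),
                    p3 = double(), pO = double(), n1 = integer(),
                    n2 = integer(), n3 = integer(), nO = integer()))
    }
    flip <- nO[keep] == n
    fr <- function(cols) rowSums(cm[, cols, drop = FALSE]) / length(cols)
    p1 <- fr(role_cols$P1); p2 <- fr(role_cols$P2); p3 <- fr(role_cols$P3)
    p1[flip] <- 1 - p1[flip]; p2[flip] <- 1 - p2[flip]
    p3[flip] <- 1 - p3[flip]
    ord <- order(pos[keep])
    tibble(replicate = rep_id, chrom = paste0("rep", rep_id),
           pos = pos[keep][ord],
           p1 = p1[ord], p2 = p2[ord], p3 = p3[ord], pO = 0,
           n1 = n, n2 = n, n3 = n, nO = n)
  }

  if (as == "sites") {
    out <- purrr::map_dfr(seq_len(config$replicates), function(i) {
      r <- one_replicate(i)
      carriers_to_sites(r$carriers, r$pos, i)
    })
    attr(out, "pop_map") <- pm
    attr(out, "config") <- config
    return(out)
  }

  # alignment mode: ancestral/derived bases drawn per site
  alns <- purrr::map(seq_len(config$replicates), function(i) {
    r <- one_replicate(i)
    mat <- matrix("A", nrow = 4L * n, ncol = config$seq_length,
                  dimnames = list(samples, NULL))
    if (length(r$pos) > 0L) {
      anc <- sample(.dfbf_alphabet, length(r$pos), replace = TRUE)
      der <- vapply(anc, function(a) sample(setdiff(.dfbf_alphabet, a), 1L),
                    "")
      for (j in seq_along(r$pos)) {
        mat[, r$pos[j]] <- anc[j]
        mat[r$carriers[j, ], r$pos[j]] <- der[j]
      }
    }
    structure(list(seq = mat, samples = samples,
                   chrom = paste0("rep", i), offset = 0L),
              class = "dfbf_alignment")
  })
  attr(alns, "pop_map") <- pm
  alns
}

#' Deterministic frequency fixtures
#'
#' Builds `n_snps` identical polarized sites with the given derived-allele
#' frequencies — e.g. the maximal-introgression single-SNP configuration
#' `p1 = 0, p2 = 1, p3 = 1` used in the Bayes-factor scaling experiments.
#'
#' @param n_snps Number of identical sites (0 gives an empty table).
#' @param p1,p2,p3 Derived-allele frequencies in `[0, 1]`.
#' @param chrom Chromosome label (default `"fixture"`).
#' @return A sites tibble with positions `1..n_snps`; sample counts are
#'   `NA` (fixtures specify frequencies, not samples), so `lambda_s` must
#'   be given explicitly downstream.
#' @examples
#' make_pattern_fixture(10, 0, 1, 1)
#' @export
make_pattern_fixture <- function(n_snps, p1, p2, p3, chrom = "fixture") {
  stopifnot(n_snps >= 0, p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1,
            p3 >= 0, p3 <= 1)
  n_snps <- as.integer(n_snps)
  tibble(chrom = rep(chrom, n_snps), pos = seq_len(n_snps),
         p1 = rep(as.numeric(p1), n_snps), p2 = rep(as.numeric(p2), n_snps),
         p3 = rep(as.numeric(p3), n_snps), pO = rep(0, n_snps),
         n1 = rep(NA_integer_, n_snps), n2 = rep(NA_integer_, n_snps),
         n3 = rep(NA_integer_, n_snps), nO = rep(NA_integer_, n_snps))
}

#' Replicate sweeps over introgression parameters
#'
#' Runs the replicate simulation over a grid of `f` or `t_gf` values and
#' evaluates the chosen statistics on each replicate locus (the whole locus
#' is one window), producing the long table behind estimator-recovery and
#' error-metric comparisons.
#'
#' @param param `"f"` or `"t_gf"`.
#' @param values Numeric grid of parameter values.
#' @param config Base [sim_config()]; the swept parameter is overridden.
#' @param statistics Character subset of
#'   `c("df", "df_theta", "D", "fd", "dp", "df_bf")`.
#' @param lambda_s,lambda_p Prior configuration; default `lambda_s` is the
#'   per-taxon haplotype count, `lambda_p = lambda_s`.
#' @param seed Optional integer seed.
#' @return A long tibble with columns `param`, `value`, `replicate`,
#'   `statistic`, `estimate`.
#' @export
sweep_experiment <- function(param = c("f", "t_gf"), values, config,
                             statistics = c("df", "df_theta", "D", "fd",
                                            "dp"),
                             lambda_s = NULL, lambda_p = NULL, seed = NULL) {
  param <- match.arg(param)
  stopifnot(inherits(config, "sim_config"))
  statistics <- match.arg(statistics,
                          c("df", "df_theta", "D", "fd", "dp", "df_bf"),
                          several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(lambda_s)) lambda_s <- config$n_per_taxon
  if (is.null(lambda_p)) lambda_p <- lambda_s

  purrr::map_dfr(values, function(v) {
    cfg <- config
    cfg[[if (param == "f") "f" else "t_gf"]] <- v
    cfg <- do.call(sim_config, unclass(cfg))
    sites <- simulate_four_taxon(cfg, as = "sites")
    per_rep <- purrr::map_dfr(seq_len(cfg$replicates), function(i) {
      sub <- sites[sites$replicate == i, , drop = FALSE]
      res <- df_bf_test(window_statistics(summarize_window(sub)),
                        lambda_s = lambda_s, lambda_p = lambda_p)
      tibble(replicate = i,
             statistic = statistics,
             estimate = purrr::map_dbl(statistics, function(st) res[[st]]))
    })
    mutate(per_rep, param = param, value = v, .before = 1)
  })
}

#' Error metrics of a sweep against the true fraction of introgression
#'
#' @param sweep A [sweep_experiment()] table from an `f` sweep (or any
#'   table with `value`, `statistic`, `estimate`); for `t_gf` sweeps pass
#'   the fixed true fraction via `truth`.
#' @param truth Either `"value"` (use the swept parameter as the truth,
#'   for `f` sweeps) or a single number (fixed true `f`).
#' @return A tibble with one row per statistic: `sse`, `rmse`, `mae`
#'   computed over all replicates and grid values, with `NA` estimates
#'   excluded.
#' @export
sweep_errors <- function(sweep, truth = "value") {
  tv <- if (identical(truth, "value")) sweep$value else as.numeric(truth)
  d <- mutate(sweep, .err = .data$estimate - tv)
  d <- filter(d, !is.na(.data$.err))
  summarise(group_by(d, .data$statistic),
            sse = sum(.data$.err^2),
            rmse = sqrt(mean(.data$.err^2)),
            mae = mean(abs(.data$.err)),
            .groups = "drop")
}

#' Bayes-factor scaling with the number of supporting SNPs
#'
#' The deterministic numeric experiment behind prior calibration: for each
#' combination of `lambda_s`, `lambda_p` and SNP count `n`, the df-BF of a
#' window holding `n` copies of the maximally introgressed site
#' `(p1, p2, p3) = (0, 1, 1)`.
#'
#' @param n_snps Integer vector of SNP counts (default `0:100`).
#' @param lambda_s,lambda_p Numeric grids (crossed).
#' @return A tibble of class `"dfbf_curve"` with columns `lambda_s`,
#'   `lambda_p`, `n_snps`, `df_bf`, `evidence`.
#' @examples
#' bf_curve(n_snps = c(0, 10, 50), lambda_s = 100, lambda_p = c(5, 10, 100))
#' @export
bf_curve <- function(n_snps = 0:100, lambda_s = c(10, 46, 100),
                     lambda_p = c(1, 5, 10, 15)) {
  grid <- tidyr::expand_grid(lambda_s = lambda_s, lambda_p = lambda_p,
                             n_snps = as.integer(n_snps))
  rows <- purrr::pmap_dfr(grid, function(lambda_s, lambda_p, n_snps) {
    if (n_snps == 0L) {
      # zero supporting SNPs: the models are indistinguishable
      return(tibble(lambda_s = lambda_s, lambda_p = lambda_p,
                    n_snps = n_snps, df_bf = 1,
                    evidence = "no evidence"))
    }
    w <- summarize_window(make_pattern_fixture(n_snps, 0, 1, 1))
    res <- df_bf_test(w, lambda_s = lambda_s, lambda_p = lambda_p)
    tibble(lambda_s = lambda_s, lambda_p = lambda_p, n_snps = n_snps,
           df_bf = res$df_bf, evidence = res$evidence)
  })
  structure(rows, class = c("dfbf_curve", class(rows)))
}
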