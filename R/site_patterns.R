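# Polarization of alignment/genotype columns into derived-allele frequency
# records, and the per-site four-taxon pattern weights.

#' Construct a population map
#'
#' Assigns each sample to one of the four taxon roles of the ABBA-BABA
#' configuration: the sister taxa `P1` and `P2`, the candidate donor `P3`,
#' and the outgroup `O`.
#'
#' @param sample Character vector of sample identifiers.
#' @param role Character vector of roles, each one of `"P1"`, `"P2"`,
#'   `"P3"`, `"O"`.
#' @return A tibble with columns `sample` and `role`, validated so that each
#'   role has at least one sample and no sample appears twice.
#' @examples
#' population_map(c("a", "b", "c", "d"), c("P1", "P2", "P3", "O"))
#' @export
population_map <- function(sample, role) {
  pm <- tibble(sample = as.character(sample), role = as.character(role))
  validate_population_map(pm)
}

validate_population_map <- function(pm) {
  stopifnot(is.data.frame(pm), all(c("sample", "role") %in% names(pm)))
  bad <- setdiff(unique(pm$role), .dfbf_roles)
  if (length(bad) > 0) {
    abort(paste0("unknown role(s) in population map: ",
                 paste(bad, collapse = ", "),
                 " (expected P1, P2, P3, O)"), class = "dfbf_config_error")
  }
  if (anyDuplicated(pm$sample)) {
    abort(paste0("sample(s) assigned to more than one role: ",
                 paste(unique(pm$sample[duplicated(pm$sample)]), collapse = ", ")),
          class = "dfbf_config_error")
  }
  missing_roles <- setdiff(.dfbf_roles, unique(pm$role))
  if (length(missing_roles) > 0) {
    abort(paste0("population map has no sample for role(s): ",
                 paste(missing_roles, collapse = ", ")),
          class = "dfbf_config_error")
  }
  as_tibble(pm[, c("sample", "role")])
}

# integer base codes: 0 = missing, 1..4 = A,C,G,T
.encode_calls <- function(x, pos = NULL) {
  x <- toupper(as.character(x))
  code <- match(x, .dfbf_alphabet)
  code[x %in% .dfbf_missing_chars] <- 0L
  if (anyNA(code)) {
    where <- which(is.na(code))[1]
    lab <- if (!is.null(pos)) paste0(" at position ", pos) else ""
    abort(paste0("malformed call '", x[where], "'", lab,
                 ": alphabet is A/C/G/T with N/?/-/. as missing"),
          class = "dfbf_input_error")
  }
  code
}

#' Polarize one genotype column against the outgroup
#'
#' Classifies a single alignment/genotype column. A site is retained only if
#' exactly two alleles are observed across all samples and the outgroup is
#' monomorphic; the outgroup allele is labelled ancestral ("A") and the other
#' allele derived ("B"). Frequencies are derived-allele fractions among
#' non-missing calls per role.
#'
#' @param calls Named character vector of single-base calls (names are sample
#'   identifiers present in `pop_map`). `N`, `?`, `-` and `.` are missing;
#'   case-insensitive.
#' @param pop_map A population map, see [population_map()].
#' @param chrom,pos Coordinates attached to the returned record.
#' @return A one-row sites tibble (columns `chrom, pos, p1, p2, p3, pO,
#'   n1, n2, n3, nO`) if the site is retained, otherwise a drop signal of
#'   class `"site_drop"` whose `reason` is one of `"insufficient-data"`,
#'   `"monomorphic"`, `"multiallelic"`, `"outgroup-polymorphic"`.
#' @seealso [call_sites()] for whole matrices, [is_site_drop()].
#' @examples
#' pm <- population_map(c("a", "b", "c", "d"), c("P1", "P2", "P3", "O"))
#' polarize_site(c(a = "A", b = "T", c = "T", d = "A"), pm)
#' @export
polarize_site <- function(calls, pop_map, chrom = "chr", pos = 1L) {
  pop_map <- validate_population_map(pop_map)
  if (is.null(names(calls)) || !all(pop_map$sample %in% names(calls))) {
    abort("calls must be named with every sample of the population map",
          class = "dfbf_input_error")
  }
  m <- matrix(.encode_calls(calls[pop_map$sample], pos), nrow = nrow(pop_map))
  res <- call_sites(m, pop_map, chrom = chrom, pos = pos)
  if (nrow(res) == 1L) return(res)
  drops <- site_drop_counts(res)
  site_drop(drops$reason[drops$n > 0][1], chrom = chrom, pos = pos)
}

site_drop <- function(reason, chrom = NA_character_, pos = NA_integer_) {
  structure(list(reason = reason, chrom = chrom, pos = pos),
            class = "site_drop")
}

#' @rdname polarize_site
#' @param x Object to test.
#' @export
is_site_drop <- function(x) inherits(x, "site_drop")

#' @export
print.site_drop <- function(x, ...) {
  cat("<site dropped: ", x$reason, "> ", x$chrom, ":", x$pos, "\n", sep = "")
  invisible(x)
}

#' Polarize and filter a matrix of calls into a sites table
#'
#' Vectorised form of [polarize_site()]: converts a samples-by-positions
#' matrix of base calls into the table of retained polarized biallelic
#' sites. Sites failing the filters are counted per reason, available via
#' [site_drop_counts()].
#'
#' @param calls Character or integer matrix, rows ordered as
#'   `pop_map$sample`, columns are positions. Character entries use the
#'   A/C/G/T alphabet with N/?/-/. as missing.
#' @param pop_map A population map.
#' @param chrom Chromosome label for all columns.
#' @param pos Integer vector of 1-based positions (default `1:ncol`).
#' @return A sites tibble with one row per retained site and columns
#'   `chrom, pos, p1, p2, p3, pO, n1, n2, n3, nO`, where `p*` are
#'   derived-allele frequencies (the outgroup frequency `pO` is 0 by
#'   construction) and `n*` are non-missing call counts per role. Drop
#'   counts are stored in the `"drops"` attribute.
#' @export
call_sites <- function(calls, pop_map, chrom = "chr", pos = NULL) {
  pop_map <- validate_population_map(pop_map)
  if (is.character(calls)) {
    dm <- dim(calls)
    calls <- .encode_calls(calls)
    dim(calls) <- dm
  }
  stopifnot(is.matrix(calls), nrow(calls) == nrow(pop_map))
  L <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(L)
  stopifnot(length(pos) == L)

  role_rows <- lapply(.dfbf_roles, function(r) which(pop_map$role == r))
  # per role: 4 x L matrix of base counts
  base_counts <- lapply(role_rows, function(rows) {
    sub <- calls[rows, , drop = FALSE]
    out <- matrix(0L, nrow = 4L, ncol = L)
    for (b in 1:4) out[b, ] <- colSums(sub == b)
    out
  })
  tot <- Reduce(`+`, base_counts)
  n_role <- lapply(base_counts, colSums)

  n_alleles <- colSums(tot > 0L)
  o_counts <- base_counts[[4]]
  o_alleles <- colSums(o_counts > 0L)

  has_data <- Reduce(`&`, lapply(n_role, function(n) n > 0L))
  reason <- rep(NA_character_, L)
  reason[!has_data] <- "insufficient-data"
  rest <- is.na(reason)
  reason[rest & n_alleles <= 1L] <- "monomorphic"
  rest <- is.na(reason)
  reason[rest & n_alleles > 2L] <- "multiallelic"
  rest <- is.na(reason)
  reason[rest & o_alleles != 1L] <- "outgroup-polymorphic"
  keep <- is.na(reason)

  drop_reasons <- c("insufficient-data", "monomorphic", "multiallelic",
                    "outgroup-polymorphic")
  drop_n <- vapply(drop_reasons,
                   function(r) sum(reason == r, na.rm = TRUE), integer(1))
  drops <- tibble(reason = drop_reasons, n = unname(drop_n))

  idx <- which(keep)
  if (length(idx) == 0L) {
    out <- tibble(chrom = character(), pos = integer(),
                  p1 = double(), p2 = double(), p3 = double(), pO = double(),
                  n1 = integer(), n2 = integer(), n3 = integer(),
                  nO = integer())
    attr(out, "drops") <- drops
    return(out)
  }

  # ancestral allele = the single outgroup allele; derived = the other one
  anc <- max.col(t(o_counts[, idx, drop = FALSE]), ties.method = "first")
  derived_count <- function(k) {
    bc <- base_counts[[k]][, idx, drop = FALSE]
    # derived count = non-missing minus ancestral-allele count
    n_role[[k]][idx] - bc[cbind(anc, seq_along(idx))]
  }
  freqs <- lapply(1:4, function(k) derived_count(k) / n_role[[k]][idx])

  out <- tibble(
    chrom = rep(chrom, length(idx)),
    pos = as.integer(pos[idx]),
    p1 = freqs[[1]], p2 = freqs[[2]], p3 = freqs[[3]], pO = freqs[[4]],
    n1 = as.integer(n_role[[1]][idx]), n2 = as.integer(n_role[[2]][idx]),
    n3 = as.integer(n_role[[3]][idx]), nO = as.integer(n_role[[4]][idx])
  )
  attr(out, "drops") <- drops
  out
}

#' Dropped-site counts of a sites table
#'
#' @param sites A sites tibble produced by [call_sites()],
#'   [alignment_sites()] or [read_vcf_sites()].
#' @return A tibble with columns `reason` and `n`.
#' @export
site_drop_counts <- function(sites) {
  d <- attr(sites, "drops")
  if (is.null(d)) {
    d <- tibble(reason = character(), n = integer())
  }
  d
}

#' Per-site four-taxon pattern weights
#'
#' Adds, for each polarized site, the frequency-weighted sharing patterns
#' `abba = (1-p1) p2 p3`, `baba = p1 (1-p2) p3`, the species-tree pattern
#' `bbaa = p1 p2 (1-p3)`, and the average pairwise-difference terms
#' `d13 = p1(1-p3) + p3(1-p1)` and `d23 = p2(1-p3) + p3(1-p2)`. The
#' identities `p2 * d13 = abba + bbaa` and `p1 * d23 = baba + bbaa` link the
#' pattern-count and distance formulations of the df estimator.
#'
#' @param sites A sites tibble with columns `p1`, `p2`, `p3`.
#' @return `sites` with columns `abba`, `baba`, `bbaa`, `d13`, `d23` added.
#' @examples
#' pattern_weights(make_pattern_fixture(1, 0.2, 0.8, 1.0))
#' @export
pattern_weights <- function(sites) {
  stopifnot(all(c("p1", "p2", "p3") %in% names(sites)))
  p <- sites[c("p1", "p2", "p3")]
  if (any(vapply(p, function(v) any(!is.finite(v)) || any(v < 0 | v > 1),
                 logical(1)))) {
    abort("allele frequencies must lie in [0, 1]", class = "dfbf_domain_error")
  }
  mutate(as_tibble(sites),
    d13 = .data$p1 * (1 - .data$p3) + .data$p3 * (1 - .data$p1),
    d23 = .data$p2 * (1 - .data$p3) + .data$p3 * (1 - .data$p2),
    abba = (1 - .data$p1) * .data$p2 * .data$p3,
    baba = .data$p1 * (1 - .data$p2) * .data$p3,
    bbaa = .data$p1 * .data$p2 * (1 - .data$p3)
  )
}
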