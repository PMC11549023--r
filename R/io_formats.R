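# Readers for alignments, variant calls and population maps; writers for
# the results table (TSV, BED).

#' Read a two-column population map file
#'
#' Whitespace- or tab-separated file with one line per sample:
#' `sample role`, role in {P1, P2, P3, O}. Lines starting with `#` are
#' ignored.
#'
#' @param path Path to the map file.
#' @return A validated population-map tibble (see [population_map()]).
#' @export
read_population_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    abort("population map file is empty", class = "dfbf_config_error")
  }
  parts <- strsplit(lines, "[ \t]+")
  if (any(lengths(parts) != 2L)) {
    abort("population map lines must be '<sample> <role>'",
          class = "dfbf_config_error")
  }
  population_map(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
}

#' Read a FASTA alignment
#'
#' One record per haplotype; all sequences must be the same length and
#' identifiers unique. Lowercase bases are accepted and upper-cased.
#'
#' @param path Path to a FASTA file.
#' @param chrom Chromosome/label attached to the alignment (default: file
#'   name without extension).
#' @param offset 0-based offset added to column indices to form positions
#'   (column i has position `offset + i`).
#' @return An alignment object of class `"dfbf_alignment"`: a list with
#'   `seq` (samples-by-positions character matrix), `samples`, `chrom` and
#'   `offset`.
#' @export
read_fasta_alignment <- function(path, chrom = NULL, offset = 0L) {
  seqs <- Biostrings::readDNAStringSet(path)
  nms <- names(seqs)
  nms <- sub("\\s.*$", "", nms)
  if (anyDuplicated(nms)) {
    abort("duplicate sequence identifiers in FASTA",
          class = "dfbf_format_error")
  }
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) > 1) {
    abort("FASTA sequences have unequal lengths (not an alignment)",
          class = "dfbf_format_error")
  }
  mat <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(mat) <- nms
  if (is.null(chrom)) chrom <- sub("\\.[^.]*$", "", basename(path))
  structure(list(seq = mat, samples = nms, chrom = chrom,
                 offset = as.integer(offset)),
            class = "dfbf_alignment")
}

#' @export
print.dfbf_alignment <- function(x, ...) {
  cat("<dfbf_alignment> ", length(x$samples), " sequences x ",
      ncol(x$seq), " bp (", x$chrom, ", offset ", x$offset, ")\n", sep = "")
  invisible(x)
}

#' Polarized sites from an alignment
#'
#' Applies [call_sites()] to every column of an alignment, keeping the
#' polarized biallelic sites.
#'
#' @param aln A `"dfbf_alignment"` (see [read_fasta_alignment()]) or a
#'   samples-by-positions character matrix with row names.
#' @param pop_map A population map covering the alignment's samples.
#' @return A sites tibble; drop counts in the `"drops"` attribute.
#' @export
alignment_sites <- function(aln, pop_map) {
  pop_map <- validate_population_map(pop_map)
  if (inherits(aln, "dfbf_alignment")) {
    mat <- aln$seq; chrom <- aln$chrom; offset <- aln$offset
  } else {
    mat <- aln; chrom <- "chr"; offset <- 0L
  }
  missing_samples <- setdiff(pop_map$sample, rownames(mat))
  if (length(missing_samples) > 0) {
    abort(paste0("samples in population map absent from alignment: ",
                 paste(missing_samples, collapse = ", ")),
          class = "dfbf_config_error")
  }
  call_sites(mat[pop_map$sample, , drop = FALSE], pop_map,
             chrom = chrom, pos = offset + seq_len(ncol(mat)))
}

#' Read polarized biallelic sites from a VCF
#'
#' Converts biallelic SNP records into the sites table by counting alleles
#' in GT fields (phased and unphased genotypes are treated identically;
#' haploid and diploid calls are both supported). Indel and multiallelic
#' records, records whose outgroup is polymorphic or missing, and records
#' monomorphic across the mapped samples are dropped with counted reasons
#' (see [site_drop_counts()]).
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param pop_map A population map; all mapped samples must be in the VCF
#'   header.
#' @return A position-sorted sites tibble.
#' @export
read_vcf_sites <- function(path, pop_map) {
  pop_map <- validate_population_map(pop_map)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  empty <- tibble(chrom = character(), pos = integer(),
                  p1 = double(), p2 = double(), p3 = double(), pO = double(),
                  n1 = integer(), n2 = integer(), n3 = integer(),
                  nO = integer())
  reasons <- c("indel", "multiallelic", "monomorphic",
               "outgroup-polymorphic", "insufficient-data")
  zero_drops <- tibble(reason = reasons, n = rep(0L, length(reasons)))
  if (nrow(fix) == 0) {
    attr(empty, "drops") <- zero_drops
    return(empty)
  }
  vcf_samples <- colnames(v@gt)[-1]
  missing_samples <- setdiff(pop_map$sample, vcf_samples)
  if (length(missing_samples) > 0) {
    abort(paste0("samples in population map absent from VCF header: ",
                 paste(missing_samples, collapse = ", ")),
          class = "dfbf_config_error")
  }

  ref <- fix$REF
  alt <- fix$ALT
  is_multi <- grepl(",", alt, fixed = TRUE)
  is_indel <- nchar(ref) != 1L | (nchar(alt) != 1L & !is_multi)
  snp <- !is_indel & !is_multi

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[, pop_map$sample, drop = FALSE]

  # ALT-allele count and call count per sample per record
  split_counts <- function(g) {
    alleles <- strsplit(gsub("\\|", "/", ifelse(is.na(g), ".", g)), "/")
    nonmiss <- vapply(alleles, function(a) sum(a %in% c("0", "1")), integer(1))
    altc <- vapply(alleles, function(a) sum(a == "1"), integer(1))
    cbind(nonmiss, altc)
  }

  role_of <- setNames(pop_map$role, pop_map$sample)
  n_rec <- nrow(fix)
  alt_count <- matrix(0L, n_rec, 4L, dimnames = list(NULL, .dfbf_roles))
  n_count <- matrix(0L, n_rec, 4L, dimnames = list(NULL, .dfbf_roles))
  for (s in pop_map$sample) {
    sc <- split_counts(gt[, s])
    r <- role_of[[s]]
    n_count[, r] <- n_count[, r] + sc[, 1]
    alt_count[, r] <- alt_count[, r] + sc[, 2]
  }

  tot_n <- rowSums(n_count)
  tot_alt <- rowSums(alt_count)
  has_data <- n_count[, "P1"] > 0 & n_count[, "P2"] > 0 &
    n_count[, "P3"] > 0 & n_count[, "O"] > 0
  mono <- tot_alt == 0L | tot_alt == tot_n
  o_poly <- alt_count[, "O"] > 0L & alt_count[, "O"] < n_count[, "O"]

  reason <- rep(NA_character_, n_rec)
  reason[is_indel] <- "indel"
  reason[is.na(reason) & is_multi] <- "multiallelic"
  reason[is.na(reason) & !has_data] <- "insufficient-data"
  reason[is.na(reason) & mono] <- "monomorphic"
  reason[is.na(reason) & o_poly] <- "outgroup-polymorphic"
  keep <- is.na(reason)

  drop_n <- vapply(reasons, function(r) sum(reason == r, na.rm = TRUE),
                   integer(1))
  drops <- tibble(reason = reasons, n = unname(drop_n))
  if (!any(keep)) {
    attr(empty, "drops") <- drops
    return(empty)
  }

  # polarize: outgroup fixed ALT means ALT is ancestral -> derived = REF
  flip <- alt_count[keep, "O"] == n_count[keep, "O"]
  freq <- alt_count[keep, , drop = FALSE] / n_count[keep, , drop = FALSE]
  freq[flip, ] <- 1 - freq[flip, , drop = FALSE]

  out <- tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    p1 = freq[, "P1"], p2 = freq[, "P2"], p3 = freq[, "P3"],
    pO = freq[, "O"],
    n1 = n_count[keep, "P1"], n2 = n_count[keep, "P2"],
    n3 = n_count[keep, "P3"], nO = n_count[keep, "O"]
  )
  out <- arrange(out, .data$chrom, .data$pos)
  attr(out, "drops") <- drops
  out
}

#' Write and re-read scan results
#'
#' `write_scan_tsv()` writes the results table as tab-separated text with
#' `NA` for missing statistics and at least six significant digits;
#' `read_scan_tsv()` reads it back. `write_scan_bed()` exports window
#' coordinates in BED convention (0-based half-open) with the df-theta,
#' df-BF and evidence columns.
#'
#' @param x An [scan_introgression()] result (any data frame with its
#'   columns).
#' @param path Output path.
#' @return `write_*` return `path` invisibly; `read_scan_tsv()` returns a
#'   tibble.
#' @export
write_scan_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, na = "NA")
  invisible(path)
}

#' @rdname write_scan_tsv
#' @export
read_scan_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, na = "NA",
                  progress = FALSE)
}

#' @rdname write_scan_tsv
#' @export
write_scan_bed <- function(x, path) {
  bed <- tibble(
    chrom = x$chrom,
    start = x$start - 1L,   # BED: 0-based half-open
    end = x$end,
    name = paste0("df_theta=", signif(x$df_theta, 6),
                  ";df_bf=", signif(x$df_bf, 6),
                  ";evidence=", gsub(" ", "_", x$evidence))
  )
  readr::write_tsv(bed, path, col_names = FALSE, na = "NA")
  invisible(path)
}

#' Write a haplotype alignment as FASTA
#'
#' @param aln A `"dfbf_alignment"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "dfbf_alignment"))
  seqs <- apply(aln$seq, 1, paste0, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", aln$samples[i]), seqs[[i]]), con)
  }
  invisible(path)
}
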