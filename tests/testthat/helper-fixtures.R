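# shared fixtures: random frequency tables and tiny on-disk inputs,
# all generated in code at test time.

random_sites <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    chrom = "chr", pos = seq_len(n),
    p1 = runif(n), p2 = runif(n), p3 = runif(n), pO = 0,
    n1 = 8L, n2 = 8L, n3 = 8L, nO = 8L
  )
}

swap_p1_p2 <- function(sites) {
  dplyr::mutate(sites, tmp = p1, p1 = p2, p2 = tmp, tmp = NULL)
}

toy_pop_map <- function() {
  population_map(c("p1_a", "p2_a", "p3_a", "out_a"),
                 c("P1", "P2", "P3", "O"))
}

# FASTA holding n copies of the fixed-difference column (p1=0, p2=1, p3=1)
write_fixture_fasta <- function(path, n = 10) {
  lines <- c(
    ">p1_a", strrep("A", n),
    ">p2_a", strrep("T", n),
    ">p3_a", strrep("T", n),
    ">out_a", strrep("A", n)
  )
  writeLines(lines, path)
  path
}

write_pop_map_file <- function(path, roles = c("P1", "P2", "P3", "O")) {
  writeLines(paste(c("p1_a", "p2_a", "p3_a", "out_a"), roles), path)
  path
}

vcf_header <- function(samples = c("p1_a", "p2_a", "p3_a", "out_a")) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_record <- function(pos, ref, alt, gts) {
  paste(c("chr1", pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

write_toy_vcf <- function(path, records) {
  writeLines(c(vcf_header(), records), path)
  path
}
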