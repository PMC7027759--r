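# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

write_weight_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a minimal two-SNP weight table
tiny_panel <- function() {
  data.frame(variant_id = c("v1", "v2"),
             chrom = c("1", "2"),
             pos = c(100L, 200L),
             risk_allele = c("A", "C"),
             other_allele = c("G", "T"),
             weight = c(0.5, 1.2),
             stringsAsFactors = FALSE)
}

# write a small VCF from explicit per-variant fields and GT strings
write_tiny_vcf <- function(variants, gt, samples,
                           path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", unique(variants$chrom)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chrom[i], variants$pos[i], variants$id[i],
            variants$ref[i], variants$alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# small, fast generator configuration for ROH tests: 200 Mb toy genome,
# 4 chromosomes, 50 kb marker spacing, with the consanguineous segment
# length model scaled down (mean 6 Mb) so segments stay well inside the
# short toy chromosomes while remaining far above the 3 Mb rule
small_roh_config <- function(seed, genome_size_bp = 2e8, n_chrom = 4L, ...) {
  sim_config(seed = seed, genome_size_bp = genome_size_bp, n_chrom = n_chrom,
             marker_spacing_bp = 5e4, consang_len_scale = 1.5e6, ...)
}

# homozygosity call track with heterozygous background and optional
# planted homozygous segments (list of c(start, end))
make_roh_calls <- function(n = 2000, spacing = 5000, seed = 1,
                           het_rate = 0.4, segments = list(), chrom = "chr1") {
  set.seed(seed)
  pos <- seq(spacing, by = spacing, length.out = n)
  is_het <- runif(n) < het_rate
  for (s in segments) is_het[pos >= s[1] & pos <= s[2]] <- FALSE
  data.frame(chrom = chrom, pos = pos, is_het = is_het,
             is_missing = FALSE, stringsAsFactors = FALSE)
}
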