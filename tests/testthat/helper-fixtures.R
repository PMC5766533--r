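# Small in-code fixtures shared across test files.

# a tiny hand-built LD panel from explicit pairs
tiny_panel <- function(snps, pairs = NULL) {
  if (is.null(pairs)) return(ld_panel(snps))
  ld_panel(snps, match(pairs$a, snps), match(pairs$b, snps), pairs$r2)
}

write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(data.table::as.data.table(df), path, sep = "\t",
                     quote = FALSE, na = "NA")
  path
}

# reference set matching a set of summary stats rows
ref_from <- function(snp, chr, bp, a1, a2) reference_snps(snp, chr, bp, a1, a2)
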