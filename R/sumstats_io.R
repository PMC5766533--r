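#' Read and validate a GWAS summary-statistics table
#'
#' Reads a delimited text file of per-SNP association statistics, maps its
#' columns onto the canonical layout (`SNP`, `CHR`, `BP`, `A1`, `A2`, `Z`,
#' `P`, `N`), validates rows, and reconstructs whichever of the z-score or
#' p-value is missing. `A1` is the reference allele and `A2` the effect
#' allele; `Z` is the signed effect of `A2`.
#'
#' Row-level validation drops (with a reported count): alleles outside
#' A/C/G/T, identical alleles, p-values outside (0, 1] (p below 1e-300 is
#' clamped, not dropped), chromosomes outside 1-22, rows with neither a
#' usable z nor p, and duplicated SNP ids (first occurrence kept). When both
#' z and p are present but disagree by more than 0.05 on the -log10 scale,
#' the z-score wins and p is recomputed from it (z carries the effect sign
#' needed downstream). If more than half of the rows are dropped the read
#' fails.
#'
#' @param path path to a tab- or whitespace-delimited file with a header.
#' @param column_map named list mapping canonical names (lower-case: `snp`,
#'   `chr`, `bp`, `a1`, `a2`, `z`, `p`, `n`, `sign`) to the file's column
#'   names. `sign` names a signed numeric column (e.g. a beta or log-OR)
#'   used to orient z when only p is present. Unmapped canonical names fall
#'   back to the upper-case defaults.
#' @return a `data.table` with canonical columns; attribute `n_dropped`
#'   records how many rows failed validation.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("cannot read summary statistics: ", path)
  raw <- fread(path, header = TRUE)
  map <- list(snp = "SNP", chr = "CHR", bp = "BP", a1 = "A1", a2 = "A2",
              z = "Z", p = "P", n = "N", sign = NULL)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  pick <- function(key) {
    nm <- map[[key]]
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else NULL
  }
  snp <- pick("snp")
  if (is.null(snp)) stop("no SNP id column resolvable in ", path)
  n_in <- length(snp)
  ss <- data.table(SNP = as.character(snp))
  chr <- pick("chr")
  ss[, CHR := if (is.null(chr)) NA_integer_ else
    suppressWarnings(as.integer(gsub("^chr", "", as.character(chr))))]
  bp <- pick("bp")
  ss[, BP := if (is.null(bp)) NA_integer_ else as.integer(bp)]
  a1 <- pick("a1"); a2 <- pick("a2")
  ss[, A1 := if (is.null(a1)) NA_character_ else toupper(as.character(a1))]
  ss[, A2 := if (is.null(a2)) NA_character_ else toupper(as.character(a2))]
  z <- pick("p"); # placeholder to keep data.table happy with NULLs
  zcol <- pick("z"); pcol <- pick("p"); scol <- pick("sign"); ncol_ <- pick("n")
  if (is.null(zcol) && is.null(pcol))
    stop("neither a z-score nor a p-value column is resolvable in ", path)
  if (is.null(zcol) && is.null(scol))
    stop("a sign column is required when only p-values are present: ", path)
  ss[, Z := if (is.null(zcol)) NA_real_ else as.numeric(zcol)]
  ss[, P := if (is.null(pcol)) NA_real_ else as.numeric(pcol)]
  if (!is.null(ncol_)) ss[, N := as.numeric(ncol_)]

  bad <- logical(n_in)
  # alleles: drop non-ACGT and identical pairs, but only where alleles exist
  has_al <- !is.na(ss$A1) & !is.na(ss$A2)
  ok_al <- ss$A1 %chin% c("A", "C", "G", "T") & ss$A2 %chin% c("A", "C", "G", "T")
  bad <- bad | (has_al & (!ok_al | ss$A1 == ss$A2))
  if (!is.null(chr)) bad <- bad | is.na(ss$CHR) | ss$CHR < 1L | ss$CHR > 22L
  # p range: clamp the deep tail, drop the invalid
  ss[!is.na(P) & P > 0 & P < .P_FLOOR, P := .P_FLOOR]
  bad <- bad | (!is.na(ss$P) & (ss$P <= 0 | ss$P > 1))
  bad <- bad | (is.na(ss$Z) & is.na(ss$P))
  bad <- bad | (!is.finite(ss$Z) & !is.na(ss$Z))

  # reconstruct z from p (+ sign) where z is missing
  need_z <- !bad & is.na(ss$Z)
  if (any(need_z)) {
    if (is.null(scol)) bad <- bad | need_z
    else {
      sgn <- sign(as.numeric(scol))
      sgn[sgn == 0] <- 1
      ss[need_z, Z := p_to_absz(P) * sgn[need_z]]
      bad <- bad | (need_z & !is.finite(ss$Z))
    }
  }
  # reconstruct or repair p from z
  need_p <- !bad & is.na(ss$P)
  ss[need_p, P := z_to_p(Z)]
  both <- !bad & !is.na(ss$Z) & !is.na(ss$P)
  if (any(both)) {
    incons <- both & abs(-log10(ss$P) - (-log10(z_to_p(ss$Z)))) > 0.05
    ss[incons, P := z_to_p(Z)]
  }
  # duplicated ids: keep the first occurrence
  bad <- bad | (duplicated(ss$SNP) & !bad)

  n_drop <- sum(bad)
  if (n_drop > 0.5 * n_in)
    stop(sprintf("%d of %d rows failed validation in %s", n_drop, n_in, path))
  if (n_drop > 0)
    message(sprintf("read_sumstats: dropped %d of %d rows failing validation",
                    n_drop, n_in))
  out <- ss[!bad]
  setattr(out, "n_dropped", n_drop)
  out[]
}

#' Write a summary-statistics table
#'
#' Tab-delimited with header, full numeric precision (round-trips through
#' [read_sumstats()] to 1e-12 or better).
#'
#' @param ss summary-statistics `data.table`.
#' @param path output path.
#' @export
write_sumstats <- function(ss, path) {
  fwrite(ss, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Align summary statistics to a reference SNP set
#'
#' Restricts the table to SNPs present in the reference and harmonizes allele
#' orientation: if the (A1, A2) pair is swapped relative to the reference the
#' z sign is flipped; if the alleles are strand complements of the reference
#' pair they are complemented then matched (with sign flip if also swapped).
#' Strand-ambiguous SNPs (A/T or C/G pairs) are dropped, as are SNPs whose
#' alleles cannot be reconciled with the reference. Chromosome and position
#' are taken from the reference; output rows follow reference order.
#'
#' @param ss summary-statistics `data.table` (canonical columns).
#' @param ref reference SNP set (see [reference_snps()]).
#' @return aligned table with attribute `coverage` (fraction of reference
#'   SNPs retained). Errors if no SNPs overlap or ids are duplicated after
#'   harmonization.
#' @export
align_to_reference <- function(ss, ref) {
  stopifnot(is.data.frame(ss), is.data.frame(ref))
  m <- merge(ss, ref[, .(SNP, REF_CHR = CHR, REF_BP = BP, REF_A1 = A1,
                         REF_A2 = A2)],
             by = "SNP", sort = FALSE)
  if (nrow(m) == 0L) stop("no SNPs overlap the reference panel")
  if (anyDuplicated(m$SNP)) stop("duplicated SNP ids after harmonization")
  amb <- m$A2 == .COMPLEMENT[m$A1]
  c1 <- .COMPLEMENT[m$A1]; c2 <- .COMPLEMENT[m$A2]
  exact <- m$A1 == m$REF_A1 & m$A2 == m$REF_A2
  swap  <- m$A1 == m$REF_A2 & m$A2 == m$REF_A1
  cexact <- c1 == m$REF_A1 & c2 == m$REF_A2
  cswap  <- c1 == m$REF_A2 & c2 == m$REF_A1
  keep <- !amb & (exact | swap | cexact | cswap)
  flip <- !amb & !exact & !cexact & (swap | cswap)
  n_amb <- sum(amb); n_mis <- sum(!keep & !amb)
  if (n_amb + n_mis > 0)
    message(sprintf(
      "align_to_reference: dropped %d strand-ambiguous and %d irreconcilable SNPs",
      n_amb, n_mis))
  out <- m[keep]
  out[flip[keep], Z := -Z]
  out[, `:=`(CHR = REF_CHR, BP = REF_BP, A1 = REF_A1, A2 = REF_A2,
             REF_CHR = NULL, REF_BP = NULL, REF_A1 = NULL, REF_A2 = NULL)]
  # reference order
  out <- out[order(match(SNP, ref$SNP))]
  coverage <- nrow(out) / nrow(ref)
  message(sprintf("align_to_reference: %d SNPs retained (coverage %.3f)",
                  nrow(out), coverage))
  setattr(out, "coverage", coverage)
  out[]
}

#' Construct a reference SNP set
#'
#' @param snp,chr,bp,a1,a2 per-SNP id, chromosome (1-22), 1-based position,
#'   and allele pair.
#' @return `data.table` sorted by (CHR, BP) with unique ids.
#' @export
reference_snps <- function(snp, chr, bp, a1, a2) {
  ref <- data.table(SNP = as.character(snp), CHR = as.integer(chr),
                    BP = as.integer(bp), A1 = toupper(a1), A2 = toupper(a2))
  if (anyDuplicated(ref$SNP)) stop("reference SNP ids must be unique")
  setorder(ref, CHR, BP)
  ref[]
}

#' Parse a 1-based inclusive genomic region
#'
#' Accepts `"chr6:29,528,318-33,373,649"` syntax (the `chr` prefix and commas
#' are optional) or a list with `chrom`, `start`, `end`.
#'
#' @param x region string or list.
#' @param label optional region label.
#' @return list with `chrom`, `start`, `end`, `label` (class
#'   `genomic_region`).
#' @export
parse_region <- function(x, label = NULL) {
  if (inherits(x, "genomic_region")) return(x)
  if (is.list(x)) {
    r <- list(chrom = as.integer(x$chrom), start = as.numeric(x$start),
              end = as.numeric(x$end),
              label = if (!is.null(x$label)) x$label else label)
  } else {
    s <- gsub(",", "", trimws(x))
    mtch <- regmatches(s, regexec("^(chr)?([0-9]+):([0-9]+)-([0-9]+)$", s))[[1]]
    if (length(mtch) == 0) stop("cannot parse region: ", x)
    r <- list(chrom = as.integer(mtch[3]), start = as.numeric(mtch[4]),
              end = as.numeric(mtch[5]), label = label)
  }
  if (is.na(r$chrom) || r$start > r$end) stop("invalid region: start > end")
  structure(r, class = "genomic_region")
}

#' Built-in exclusion regions (hg19)
#'
#' The extended major histocompatibility complex (MHC) on chromosome 6 and
#' the nicotinic acetylcholine receptor (CHRNA3/CHRNA5/CHRNB4) cluster on
#' 15q25.1; both are conventional exclusion regions for cross-trait FDR
#' fitting because of their extreme LD and association signal.
#'
#' @return a `genomic_region`.
#' @export
region_mhc <- function()
  parse_region("chr6:29,528,318-33,373,649", label = "MHC")

#' @rdname region_mhc
#' @export
region_chrna <- function()
  parse_region("chr15:78,686,690-79,231,478", label = "CHRNA")

#' Remove SNPs inside a genomic region
#'
#' Boundaries are 1-based inclusive on both ends.
#'
#' @param ss summary-statistics table with `CHR` and `BP`.
#' @param region a `genomic_region`, region string, or list of either.
#' @return filtered table; attribute `n_excluded` counts removed SNPs.
#' @export
exclude_region <- function(ss, region) {
  regions <- if (inherits(region, "genomic_region")) list(region)
    else if (is.character(region)) as.list(region)
    else if (is.list(region) && !is.null(region$chrom)) list(region)
    else region
  drop <- logical(nrow(ss))
  for (r in regions) {
    r <- parse_region(r)
    drop <- drop | (!is.na(ss$CHR) & ss$CHR == r$chrom &
                      ss$BP >= r$start & ss$BP <= r$end)
  }
  n_ex <- sum(drop)
  if (n_ex > 0)
    message(sprintf("exclude_region: removed %d SNPs", n_ex))
  out <- ss[!drop]
  setattr(out, "n_excluded", n_ex)
  out[]
}

#' Read genomic regions from a BED file
#'
#' BED coordinates are 0-based half-open; they are converted to the package's
#' 1-based inclusive convention (`start + 1`, `end`). `track`/`browser`
#' header lines and `#` comments are skipped.
#'
#' @param path BED file path.
#' @return list of `genomic_region` objects.
#' @export
read_bed_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0) return(list())
  bed <- fread(text = lines, header = FALSE)
  if (ncol(bed) < 3) stop("BED file needs at least 3 columns: ", path)
  lapply(seq_len(nrow(bed)), function(i)
    parse_region(list(chrom = gsub("^chr", "", as.character(bed[[1]][i])),
                      start = bed[[2]][i] + 1, end = bed[[3]][i],
                      label = if (ncol(bed) >= 4) as.character(bed[[4]][i])
                              else NA_character_)))
}
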