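#' Construct an LD panel from pairwise r-squared entries
#'
#' Stores the symmetric pairwise r-squared structure of a reference SNP set
#' as a sparse matrix (unit diagonal implied) together with per-SNP LD
#' scores, `l(i) = sum_j r2(i, j)` over all panel SNPs including self.
#' Pairs absent from the input are treated as r2 = 0 (the standard sparse
#' windowed-LD dialect).
#'
#' @param snps character vector of panel SNP ids (defines panel order).
#' @param i,j,r2 parallel vectors of pair indices (into `snps`) and their
#'   r-squared; each unordered pair given once.
#' @return list of class `ld_panel` with `snps`, `r2` (symmetric
#'   `dgCMatrix` with unit diagonal) and `scores`.
#' @export
ld_panel <- function(snps, i = integer(), j = integer(), r2 = numeric()) {
  n <- length(snps)
  stopifnot(length(i) == length(j), length(i) == length(r2))
  if (length(r2) && (min(r2) < 0 || max(r2) > 1))
    stop("r2 values must lie in [0, 1]")
  off <- i != j
  ii <- c(seq_len(n), i[off], j[off])
  jj <- c(seq_len(n), j[off], i[off])
  xx <- c(rep(1, n), r2[off], r2[off])
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  structure(list(snps = as.character(snps), r2 = m,
                 scores = Matrix::colSums(m)),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("ld_panel: %d SNPs, %d stored off-diagonal pairs, mean LD score %.2f\n",
              length(x$snps), (Matrix::nnzero(x$r2) - length(x$snps)) / 2,
              mean(x$scores)))
  invisible(x)
}

#' Load a PLINK-style `.ld` pair table
#'
#' Accepts whitespace-delimited tables with columns `SNP_A`, `SNP_B`, `R2`
#' (extra columns such as `CHR_A`/`BP_A` are ignored). Pairs involving SNPs
#' outside the panel are skipped with a message; duplicate pair rows with
#' conflicting r2 raise an error naming the pair.
#'
#' @param path `.ld` file path.
#' @param panel_snps reference SNP set (see [reference_snps()]) or a
#'   character vector of panel SNP ids.
#' @return an [ld_panel()].
#' @export
load_ld <- function(path, panel_snps) {
  snps <- if (is.data.frame(panel_snps)) panel_snps$SNP else
    as.character(panel_snps)
  tab <- fread(path, header = TRUE)
  need <- c("SNP_A", "SNP_B", "R2")
  if (!all(need %in% names(tab)))
    stop("LD file must have columns SNP_A, SNP_B, R2: ", path)
  if (nrow(tab)) {
    if (min(tab$R2) < 0 || max(tab$R2) > 1)
      stop("r2 values outside [0, 1] in ", path)
    ia <- match(tab$SNP_A, snps); ib <- match(tab$SNP_B, snps)
    unknown <- is.na(ia) | is.na(ib)
    if (any(unknown))
      message(sprintf("load_ld: skipped %d pairs with unknown SNP ids",
                      sum(unknown)))
    tab <- tab[!unknown]; ia <- ia[!unknown]; ib <- ib[!unknown]
    key <- paste(pmin(ia, ib), pmax(ia, ib))
    dup <- duplicated(key)
    if (any(dup)) {
      first <- match(key[dup], key)
      conflict <- tab$R2[dup] != tab$R2[first]
      if (any(conflict)) {
        w <- which(dup)[which(conflict)[1]]
        stop(sprintf("conflicting r2 for pair %s-%s in %s",
                     tab$SNP_A[w], tab$SNP_B[w], path))
      }
      tab <- tab[!dup]; ia <- ia[!dup]; ib <- ib[!dup]
    }
    ld_panel(snps, ia, ib, tab$R2)
  } else ld_panel(snps)
}

#' Per-SNP LD scores of a panel
#'
#' @param panel an [ld_panel()].
#' @return numeric vector, `>= 1` for every SNP.
#' @export
ld_scores <- function(panel) panel$scores

#' Restrict an LD panel to a subset of SNPs
#'
#' LD scores are recomputed on the subset.
#'
#' @param panel an [ld_panel()].
#' @param keep logical mask or character vector of SNP ids to retain.
#' @return an [ld_panel()] over the retained SNPs.
#' @export
subset_panel <- function(panel, keep) {
  idx <- if (is.logical(keep)) which(keep) else match(keep, panel$snps)
  m <- panel$r2[idx, idx, drop = FALSE]
  structure(list(snps = panel$snps[idx], r2 = m,
                 scores = Matrix::colSums(m)),
            class = "ld_panel")
}

# CSR adjacency of pairs with r2 strictly above `thr` (diagonal excluded):
# list(ptr = 0-based offsets, idx = 0-based neighbour indices)
.prune_adjacency <- function(panel, thr) {
  A <- methods::as(panel$r2, "CsparseMatrix")
  n <- ncol(A)
  jcol <- rep.int(seq_len(n), diff(A@p))
  sel <- A@x > thr & (A@i + 1L) != jcol
  idx <- A@i[sel]
  cnt <- tabulate(jcol[sel], nbins = n)
  list(ptr = c(0L, cumsum(cnt)), idx = idx)
}

#' Random LD pruning
#'
#' Visits panel SNPs in a seed-determined random order and keeps a SNP iff
#' its r-squared with every already-kept SNP is at or below the threshold —
#' i.e. one random representative per greedy-transitive LD block. The result
#' is maximal (every dropped SNP exceeds the threshold with some kept SNP)
#' and deterministic given the seed.
#'
#' @param panel an [ld_panel()].
#' @param r2_threshold r-squared threshold in (0, 1] (default 0.8).
#' @param seed integer seed controlling the visit order.
#' @param adjacency precomputed result of the internal adjacency builder
#'   (used by [build_prune_ensemble()] to avoid recomputation).
#' @return logical keep-mask over panel SNPs.
#' @export
random_prune <- function(panel, r2_threshold = 0.8, seed = 1L,
                         adjacency = NULL) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  if (is.null(adjacency)) adjacency <- .prune_adjacency(panel, r2_threshold)
  n <- length(panel$snps)
  ord <- with_seed(seed, sample.int(n))
  greedy_prune(ord, adjacency$ptr, adjacency$idx)
}

#' Build an ensemble of random pruning masks
#'
#' Per-iteration seeds are derived deterministically from `base_seed`, so
#' identical inputs give bit-identical ensembles.
#'
#' @param panel an [ld_panel()].
#' @param n_iter number of pruning iterations (default 100).
#' @param r2_threshold r-squared threshold (default 0.8).
#' @param base_seed integer seed.
#' @return list of class `prune_ensemble` with `masks` (logical matrix,
#'   SNPs x iterations), `seeds`, `r2_threshold`, `n_iter`.
#' @export
build_prune_ensemble <- function(panel, n_iter = 100L, r2_threshold = 0.8,
                                 base_seed = 1L) {
  stopifnot(n_iter >= 1)
  seeds <- with_seed(base_seed, sample.int(.Machine$integer.max, n_iter))
  adj <- .prune_adjacency(panel, r2_threshold)
  masks <- vapply(seeds, function(s)
    random_prune(panel, r2_threshold, s, adjacency = adj),
    logical(length(panel$snps)))
  structure(list(masks = masks, seeds = seeds, r2_threshold = r2_threshold,
                 n_iter = as.integer(n_iter)),
            class = "prune_ensemble")
}

#' Clump discovery SNPs into independent loci
#'
#' Greedy clumping: hits are ranked by ascending `CONJFDR` (ties broken by
#' ascending trait-1 p-value, then lexically by SNP id); the best unassigned
#' hit becomes a locus lead and absorbs every unassigned hit with r-squared
#' above the threshold to it. Lead SNPs of distinct loci therefore have
#' pairwise r-squared at or below the threshold.
#'
#' @param hits `data.table` of discovery SNPs; must contain `SNP` and
#'   `CONJFDR`, ranking uses `P_TRAIT1` when present; other columns are
#'   carried through to the lead rows.
#' @param panel an [ld_panel()] covering the hit SNPs.
#' @param r2_threshold clumping threshold (default 0.2).
#' @return `data.table` of class `loci`, one row per locus: the lead SNP's
#'   columns plus `N_SNPS` and `MEMBERS` (comma-separated member ids).
#' @export
clump_loci <- function(hits, panel, r2_threshold = 0.2) {
  stopifnot(nrow(hits) >= 1)
  h <- copy(as.data.table(hits))
  if (is.null(h$P_TRAIT1)) h[, P_TRAIT1 := NA_real_]
  setorder(h, CONJFDR, P_TRAIT1, SNP, na.last = TRUE)
  idx <- match(h$SNP, panel$snps)
  if (anyNA(idx)) stop("hit SNPs missing from the LD panel")
  assigned <- logical(nrow(h))
  rows <- list()
  while (any(!assigned)) {
    lead <- which(!assigned)[1]
    r2col <- panel$r2[, idx[lead]]
    members <- which(!assigned & (r2col[idx] > r2_threshold |
                                    seq_len(nrow(h)) == lead))
    assigned[members] <- TRUE
    row <- h[lead]
    row[, `:=`(N_SNPS = length(members),
               MEMBERS = paste(h$SNP[members], collapse = ","))]
    rows[[length(rows) + 1L]] <- row
  }
  out <- rbindlist(rows)
  setattr(out, "class", c("loci", class(out)))
  out[]
}
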