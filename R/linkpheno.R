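#' Link clonotype assignments to transcriptome cells
#'
#' Joins per-cell clonotype assignments (from [cell_clonotypes()]) to
#' per-cell transcriptome metadata on `(sample, barcode)`. Transcriptome
#' cells without TCR information are kept with `key = NA` so they remain
#' available for background statistics.
#'
#' @param clono `data.frame` with `barcode`, `sample`, `key` and optionally
#'   `known_name` (one row per TCR-bearing cell).
#' @param gex_meta `data.frame` of per-cell metadata with `barcode`,
#'   `sample` and any annotation columns (e.g. `cluster`).
#' @return `data.frame` of linked cells: all `gex_meta` columns plus `key`
#'   and `known_name`.
#' @export
link_cells <- function(clono, gex_meta) {
  for (col in c("barcode", "sample"))
    if (!col %in% names(clono) || !col %in% names(gex_meta))
      stop(sprintf("both inputs need a '%s' column", col), call. = FALSE)
  ka <- paste(clono$sample, clono$barcode)
  kb <- paste(gex_meta$sample, gex_meta$barcode)
  idx <- match(kb, ka)
  if (!any(!is.na(idx)))
    stop("modalities do not share barcodes", call. = FALSE)
  out <- gex_meta
  out$key <- ifelse(is.na(idx), NA_character_, clono$key[idx])
  out$known_name <- if ("known_name" %in% names(clono))
    ifelse(is.na(idx), NA_character_, clono$known_name[idx])
  else NA_character_
  out
}

#' Per-group cluster composition
#'
#' For each group (clonotype or named TCR, within a sample), the percentage
#' of its cells falling in each transcriptome cluster. Groups must surpass
#' the minimum cell threshold strictly (`n_cells > min_cells`) to be
#' reported; the rest are listed with their counts in the `excluded`
#' attribute.
#'
#' @param linked Linked cells from [link_cells()] with a `cluster` column.
#' @param group Character vector (length `nrow(linked)`) naming each cell's
#'   group; cells with `NA` group are ignored.
#' @param min_cells Strict lower threshold on group size (default 25:
#'   groups with more than 25 cells are kept).
#' @return Object of class `composition_table`: `data.frame` with `group`,
#'   `n_cells` and one percentage column per cluster (rows sum to 100);
#'   attribute `excluded` lists the too-small groups.
#' @export
cluster_composition <- function(linked, group, min_cells = 25L) {
  if (!"cluster" %in% names(linked))
    stop("linked cells need a 'cluster' column", call. = FALSE)
  keep <- !is.na(group)
  grp <- group[keep]
  cl <- linked$cluster[keep]
  sizes <- table(grp)
  ok <- names(sizes)[sizes > min_cells]
  excluded <- data.frame(group = names(sizes)[!(names(sizes) %in% ok)],
                         n_cells = as.integer(sizes[!(names(sizes) %in% ok)]),
                         stringsAsFactors = FALSE, row.names = NULL)
  clusters <- sort(unique(linked$cluster))
  rows <- lapply(ok, function(g) {
    cnt <- table(factor(cl[grp == g], levels = clusters))
    100 * as.numeric(cnt) / sum(cnt)
  })
  out <- data.frame(group = ok,
                    n_cells = as.integer(sizes[ok]),
                    stringsAsFactors = FALSE, row.names = NULL)
  pc <- do.call(rbind, rows)
  if (is.null(pc)) pc <- matrix(numeric(0), 0, length(clusters))
  colnames(pc) <- paste0("cluster_", clusters)
  out <- cbind(out, as.data.frame(pc))
  structure(out, class = c("composition_table", "data.frame"),
            excluded = excluded, min_cells = min_cells)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact null enumeration when the pooled sample size is at most
#' `exact_max` with no ties; otherwise the normal approximation with tie
#' and continuity correction. This is the test behind
#' [de_between_groups()].
#'
#' @param x,y Numeric observations of the two groups.
#' @param exact_max Largest pooled size for the exact p-value (default 12).
#' @return The two-sided p-value.
#' @export
rank_sum_p <- function(x, y, exact_max = 12L) {
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y)) <= exact_max && !ties
  suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value)
}

#' Differential expression between two cell groups
#'
#' Per gene: log2 fold change of group means on back-transformed normalized
#' expression (`expm1`, pseudocount 1), detection fractions, a two-sided
#' Wilcoxon rank-sum p-value (exact enumeration when the pooled size is at
#' most 12 without ties, else normal approximation with tie and continuity
#' correction), and Bonferroni adjustment over the genes actually tested.
#' Genes are pre-filtered to those detected in at least `min_pct` of either
#' group and with `|log2_fc| >= min_abs_log2fc`.
#'
#' @param normalized Genes x cells normalized matrix.
#' @param cells_a,cells_b Barcodes (or column indices) of the two groups;
#'   each must contain at least 3 cells.
#' @param min_pct Minimum detection fraction in either group (default 0.1).
#' @param min_abs_log2fc Minimum absolute log2 fold change (default 0.25).
#' @return `data.frame` of class `de_result`: `gene`, `log2_fc`, `pct_in`,
#'   `pct_out`, `p_value`, `p_adj`, ordered by `p_value`; attribute
#'   `n_tested`.
#' @export
de_between_groups <- function(normalized, cells_a, cells_b, min_pct = 0.1,
                              min_abs_log2fc = 0.25) {
  a <- as.matrix(normalized[, cells_a, drop = FALSE])
  b <- as.matrix(normalized[, cells_b, drop = FALSE])
  if (ncol(a) < 3L || ncol(b) < 3L)
    stop("each group needs at least 3 cells", call. = FALSE)

  mean_a <- rowMeans(expm1(a))
  mean_b <- rowMeans(expm1(b))
  lfc <- log2((mean_a + 1) / (mean_b + 1))
  pct_in <- rowMeans(a > 0)
  pct_out <- rowMeans(b > 0)
  test <- (pct_in >= min_pct | pct_out >= min_pct) &
    abs(lfc) >= min_abs_log2fc
  genes <- rownames(normalized)[test]
  m <- length(genes)
  p <- vapply(which(test), function(g) rank_sum_p(a[g, ], b[g, ]),
              numeric(1))
  out <- data.frame(gene = genes, log2_fc = lfc[test],
                    pct_in = pct_in[test], pct_out = pct_out[test],
                    p_value = p, p_adj = pmin(1, p * m),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("de_result", "data.frame"), n_tested = m)
}

#' Scaled per-group mean expression (heatmap table)
#'
#' Per gene: mean normalized expression within each group, z-scored across
#' groups (mean 0, SD 1 per gene). The table behind per-group signature
#' heatmaps.
#'
#' @param normalized Genes x cells normalized matrix.
#' @param group Per-cell group labels (length `ncol(normalized)`); cells
#'   with `NA` are ignored.
#' @param genes Optional subset of genes (default all).
#' @return Genes x groups matrix of z-scored group means.
#' @export
group_signature_table <- function(normalized, group, genes = NULL) {
  keep <- !is.na(group)
  levs <- unique(group[keep])
  if (length(levs) < 2L) stop("need at least two groups", call. = FALSE)
  if (is.null(genes)) genes <- rownames(normalized)
  genes <- intersect(genes, rownames(normalized))
  mm <- vapply(levs, function(g)
    Matrix::rowMeans(normalized[genes, keep & group == g, drop = FALSE]),
    numeric(length(genes)))
  mm <- matrix(mm, nrow = length(genes))
  mu <- rowMeans(mm)
  sdv <- apply(mm, 1, sd)
  sdv[sdv < 1e-12] <- 1
  z <- (mm - mu) / sdv
  dimnames(z) <- list(genes, levs)
  z
}
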