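#' Per-cell quality-control metrics
#'
#' For each cell: the number of detected genes (count > 0), total UMI count,
#' and fraction of counts in mitochondrial genes (matched case-sensitively
#' by name prefix). A zero-UMI cell gets `pct_mito = 0` and is flagged.
#'
#' @param counts Genes x cells matrix (sparse or dense) with dimnames.
#' @param mito_prefix Gene-name prefix marking mitochondrial genes
#'   (default `"MT-"`).
#' @return `data.frame` with `barcode`, `n_genes`, `n_umi`, `pct_mito`,
#'   `zero_umi`.
#' @export
compute_qc_metrics <- function(counts, mito_prefix = "MT-") {
  if (is.null(dim(counts)) || nrow(counts) == 0L || ncol(counts) == 0L)
    stop("counts matrix is empty", call. = FALSE)
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  n_umi <- Matrix::colSums(m)
  n_genes <- Matrix::colSums(m > 0)
  mito <- startsWith(rownames(m), mito_prefix)
  mito_umi <- if (any(mito)) Matrix::colSums(m[mito, , drop = FALSE]) else
    rep(0, ncol(m))
  pct <- ifelse(n_umi > 0, mito_umi / n_umi, 0)
  data.frame(barcode = colnames(m), n_genes = as.integer(n_genes),
             n_umi = n_umi, pct_mito = pct, zero_umi = n_umi == 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cell and gene quality-control filtering
#'
#' Genes detected in fewer than `min_cells_per_gene` cells are removed first,
#' on the raw matrix (as at object construction); then cells are kept when
#' `n_genes >= min_genes`, `n_genes < max_genes` and
#' `pct_mito <= max_mito`. The gene filter is not re-iterated after the cell
#' filter.
#'
#' @param counts Genes x cells count matrix with dimnames.
#' @param metrics QC metrics from [compute_qc_metrics()] on the same matrix.
#' @param min_genes Minimum detected genes per kept cell (default 200).
#' @param max_genes Exclusive upper bound on detected genes (default 6000).
#' @param max_mito Maximum mitochondrial count fraction (default 0.18).
#' @param min_cells_per_gene Minimum cells a kept gene is detected in
#'   (default 3).
#' @return The filtered count matrix.
#' @export
filter_cells_genes <- function(counts, metrics, min_genes = 200L,
                               max_genes = 6000L, max_mito = 0.18,
                               min_cells_per_gene = 3L) {
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  keep_gene <- Matrix::rowSums(m > 0) >= min_cells_per_gene
  idx <- match(colnames(m), metrics$barcode)
  keep_cell <- metrics$n_genes[idx] >= min_genes &
    metrics$n_genes[idx] < max_genes &
    metrics$pct_mito[idx] <= max_mito
  if (!any(keep_cell)) stop("no cells pass QC", call. = FALSE)
  m[keep_gene, keep_cell, drop = FALSE]
}

#' Log-normalize counts
#'
#' Per cell: counts are divided by the cell's total, multiplied by
#' `scale_factor`, then `ln(1 + x)` transformed. Invariant to rescaling all
#' counts of a cell.
#'
#' @param counts QC-filtered genes x cells count matrix.
#' @param scale_factor Scale applied after depth division (default `1e4`).
#' @return Sparse genes x cells matrix of normalized values; attribute
#'   `scale_factor`.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  depth <- Matrix::colSums(m)
  depth[depth == 0] <- 1
  norm <- m %*% Matrix::Diagonal(x = scale_factor / depth)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m)
  attr(norm, "scale_factor") <- scale_factor
  norm
}

# per-gene mean and variance of a sparse genes x cells matrix
sparse_row_stats <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowSums(m) / n
  ex2 <- Matrix::rowSums(m^2) / n
  v <- (ex2 - mu^2) * n / (n - 1)
  list(mean = mu, var = pmax(v, 0))
}

#' Variable-gene detection (variance-stabilizing scoring)
#'
#' Fits the expected standard deviation of each gene as a smooth function of
#' its mean (local regression of log10 variance on log10 mean over genes
#' with positive variance, as in the vst approach), standardizes raw counts
#' by `(x - mean)/expected_sd` with clipping, and scores each gene by the
#' variance of its clipped standardized counts. Genes are returned in
#' nonincreasing score order.
#'
#' @param counts Genes x cells raw count matrix (QC-filtered).
#' @param n_top Number of variable genes to report (default 2000; all genes
#'   scored).
#' @param loess_span Span of the mean-variance trend fit (default 0.3).
#' @param clip Clip value for standardized counts; default
#'   `sqrt(ncol(counts))`.
#' @return Object of class `variable_genes`: `data.frame` with `gene`,
#'   `mean`, `variance`, `variance_expected`, `score`, ordered by
#'   decreasing score, truncated to `n_top`; attribute `all_scores` keeps
#'   every gene's score.
#' @export
find_variable_genes <- function(counts, n_top = 2000L, loess_span = 0.3,
                                clip = NULL) {
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (nrow(m) < 10L || ncol(m) < 10L)
    stop("need at least 10 genes and 10 cells", call. = FALSE)
  n <- ncol(m)
  if (is.null(clip)) clip <- sqrt(n)
  st <- sparse_row_stats(m)
  mu <- st$mean
  v <- st$var

  fit <- rep(0, nrow(m))
  usable <- v > 0 & mu > 0
  lo <- loess(log10(v[usable]) ~ log10(mu[usable]), span = loess_span,
              degree = 2)
  fit[usable] <- 10^predict(lo)
  sd_exp <- sqrt(pmax(fit, 0))

  # variance of clipped standardized counts, computed from nonzeros: the
  # standardized value of a zero count is constant per gene.
  score <- numeric(nrow(m))
  mt <- Matrix::t(m)   # column-oriented access per gene
  p <- mt@p
  xs <- mt@x
  for (g in which(usable)) {
    nz <- if (p[g + 1L] > p[g]) xs[(p[g] + 1L):p[g + 1L]] else numeric(0)
    z_nz <- pmin(pmax((nz - mu[g]) / sd_exp[g], -clip), clip)
    z0 <- pmin(pmax((0 - mu[g]) / sd_exp[g], -clip), clip)
    n0 <- n - length(nz)
    s1 <- sum(z_nz) + n0 * z0
    s2 <- sum(z_nz^2) + n0 * z0^2
    score[g] <- (s2 - s1^2 / n) / (n - 1)
  }

  ord <- order(-score, rownames(m))
  take <- seq_len(min(n_top, nrow(m)))
  if (n_top > nrow(m))
    warning(sprintf("only %d genes available (< n_top = %d)", nrow(m), n_top),
            call. = FALSE)
  out <- data.frame(gene = rownames(m)[ord][take], mean = mu[ord][take],
                    variance = v[ord][take],
                    variance_expected = fit[ord][take],
                    score = score[ord][take],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("variable_genes", "data.frame"),
            all_scores = setNames(score, rownames(m)), clip = clip)
}

#' Scale expression with covariate regression
#'
#' Per gene: ordinary least squares of normalized expression on an intercept
#' plus the covariates (by default total UMIs and mitochondrial fraction);
#' residuals are standardized to mean 0, SD 1, and clipped. A constant gene
#' yields all-zero residuals (SD treated as 1). When `sample` is given,
#' regression and standardization run within each sample separately — the
#' package's substitute for anchor-based batch integration before joint PCA.
#'
#' @param normalized Genes x cells normalized matrix from [log_normalize()].
#' @param genes Character vector of genes to scale (e.g.
#'   `variable_genes$gene`), or a `variable_genes` object.
#' @param covariates `data.frame` of per-cell covariates, rows aligned to
#'   the matrix columns (e.g. `n_umi`, `pct_mito`); `NULL` for plain
#'   centering/scaling.
#' @param clip Absolute clip value for scaled residuals (default 10).
#' @param sample Optional per-cell sample labels for within-sample scaling.
#' @return Dense genes x cells matrix of scaled residuals.
#' @export
scale_with_regression <- function(normalized, genes, covariates = NULL,
                                  clip = 10, sample = NULL) {
  if (inherits(genes, "variable_genes")) genes <- genes$gene
  genes <- intersect(genes, rownames(normalized))
  y <- as.matrix(normalized[genes, , drop = FALSE])
  n <- ncol(y)
  if (!is.null(covariates) && nrow(covariates) != n)
    stop("covariates must have one row per cell", call. = FALSE)

  scale_block <- function(yb, cb) {
    nb <- ncol(yb)
    x <- cbind(`(Intercept)` = rep(1, nb),
               if (!is.null(cb)) as.matrix(cb))
    res <- t(lm.fit(x, t(yb))$residuals)
    mu <- rowMeans(res)
    res <- res - mu
    sdv <- sqrt(rowSums(res^2) / (nb - 1))
    flat <- sdv < 1e-12
    sdv[flat] <- 1
    res <- res / sdv
    res[flat, ] <- 0
    pmin(pmax(res, -clip), clip)
  }

  if (is.null(sample)) {
    out <- scale_block(y, covariates)
  } else {
    out <- y
    for (s in unique(sample)) {
      sel <- sample == s
      out[, sel] <- scale_block(y[, sel, drop = FALSE],
                                if (is.null(covariates)) NULL else
                                  covariates[sel, , drop = FALSE])
    }
  }
  dimnames(out) <- dimnames(y)
  out
}

# blocked exact kNN on a cells x dims score matrix; returns index matrix
knn_indices <- function(scores, k, block = 512L) {
  n <- nrow(scores)
  k <- min(k, n - 1L)
  sq <- rowSums(scores^2)
  idx <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    end <- min(start + block - 1L, n)
    d2 <- outer(sq[start:end], sq, "+") -
      2 * tcrossprod(scores[start:end, , drop = FALSE], scores)
    for (i in seq_len(end - start + 1L)) {
      row <- d2[i, ]
      row[start + i - 1L] <- Inf
      idx[start + i - 1L, ] <- order(row)[seq_len(k)]
    }
  }
  idx
}

#' PCA embedding and graph clustering
#'
#' Principal components of the scaled matrix (cells x `n_pcs` scores), an
#' exact Euclidean k-nearest-neighbor graph, and Louvain community detection
#' at the given resolution under a fixed seed. Cluster ids are relabeled by
#' decreasing size, `0..K-1`.
#'
#' @param scaled Variable-genes x cells scaled matrix from
#'   [scale_with_regression()].
#' @param n_pcs Number of principal components (default 30).
#' @param n_neighbors Neighbors per cell in the kNN graph (default 15).
#' @param resolution Community-detection resolution (default 0.8).
#' @param seed Integer seed fixing the community detection.
#' @return Object of class `cluster_assignment`: `data.frame` with
#'   `barcode` and `cluster`; attributes `params` and `pca` (the cell
#'   scores).
#' @export
embed_and_cluster <- function(scaled, n_pcs = 30L, n_neighbors = 15L,
                              resolution = 0.8, seed = 0L) {
  if (n_pcs > min(dim(scaled)))
    stop(sprintf("n_pcs = %d exceeds matrix rank bound %d", n_pcs,
                 min(dim(scaled))), call. = FALSE)
  pcs <- prcomp(t(scaled), center = TRUE, scale. = FALSE,
                rank. = n_pcs)$x
  n <- nrow(pcs)
  nn <- knn_indices(pcs, n_neighbors)
  edges <- cbind(rep(seq_len(n), ncol(nn)), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- with_seed(seed,
                    igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  cluster <- as.integer(relabel[as.character(memb)])
  structure(
    data.frame(barcode = colnames(scaled), cluster = cluster,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("cluster_assignment", "data.frame"),
    params = list(n_pcs = n_pcs, n_neighbors = n_neighbors,
                  resolution = resolution, seed = seed),
    pca = pcs)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("cluster_assignment: %d cells, %d clusters (n_pcs=%d, k=%d, resolution=%.2f, seed=%d)\n",
              nrow(x), length(unique(x$cluster)), p$n_pcs, p$n_neighbors,
              p$resolution, p$seed))
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Gene-signature module score with bin-matched controls
#'
#' All genes are binned by their average expression across cells
#' (`n_bins` equal-occupancy bins); each signature gene draws `n_ctrl`
#' control genes from the non-signature members of its own bin with
#' replacement under the given seed (the full bin is used only when a bin
#' holds no other gene). The per-cell score is the mean expression of the
#' signature genes minus the mean expression of the pooled control genes,
#' so the expectation is zero when signature genes behave like their bin
#' mates, while a shift confined to the signature cannot cancel through its
#' own control pool.
#'
#' @param normalized Genes x cells normalized matrix.
#' @param gene_set Character vector of signature genes; genes absent from
#'   the matrix are dropped with a warning.
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Control genes drawn per signature gene (default 100).
#' @param seed Integer seed for the control draw.
#' @return Object of class `module_score`: numeric per-cell scores (named by
#'   barcode) with parameter attributes.
#' @export
module_score <- function(normalized, gene_set, n_bins = 24L, n_ctrl = 100L,
                         seed = 0L) {
  present <- intersect(gene_set, rownames(normalized))
  if (length(present) < length(gene_set))
    warning(sprintf("%d signature gene(s) absent from the matrix",
                    length(gene_set) - length(present)), call. = FALSE)
  if (length(present) == 0L)
    stop("no signature genes present in the matrix", call. = FALSE)

  avg <- Matrix::rowMeans(normalized)
  n_bins <- min(n_bins, length(avg))
  r <- rank(avg, ties.method = "first")
  bin <- ceiling(r * n_bins / length(avg))

  sig_idx <- match(present, rownames(normalized))
  ctrl <- with_seed(seed, {
    unlist(lapply(sig_idx, function(gi) {
      mates <- which(bin == bin[gi])
      # controls are bin mates outside the signature itself, so a shift of
      # the signature cannot leak into its own control pool; fall back to
      # the full bin only if no other mate exists
      non_sig <- setdiff(mates, sig_idx)
      pool <- if (length(non_sig)) non_sig else mates
      sample(pool, n_ctrl, replace = TRUE)
    }))
  })
  sig_mean <- Matrix::colMeans(normalized[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(normalized[ctrl, , drop = FALSE])
  structure(as.numeric(sig_mean - ctrl_mean),
            names = colnames(normalized), class = "module_score",
            genes = present, n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
}

#' @export
print.module_score <- function(x, ...) {
  cat(sprintf("module_score over %d gene(s), %d cells: mean %.4f, range [%.4f, %.4f]\n",
              length(attr(x, "genes")), length(x), mean(x), min(x), max(x)))
  invisible(x)
}

#' Cell-cycle phase scoring
#'
#' S and G2/M module scores via [module_score()]; the phase call is the
#' argmax of the two scores when the maximum is positive, else G1.
#'
#' @param normalized Genes x cells normalized matrix.
#' @param s_genes,g2m_genes Phase signature gene sets.
#' @param seed Seed passed to the module scores.
#' @return `data.frame` with `barcode`, `s_score`, `g2m_score`, `phase`.
#' @export
cell_cycle_score <- function(normalized, s_genes, g2m_genes, seed = 0L) {
  s_in <- intersect(s_genes, rownames(normalized))
  g_in <- intersect(g2m_genes, rownames(normalized))
  if (length(s_in) == 0L && length(g_in) == 0L)
    stop("no cell-cycle genes present in the matrix", call. = FALSE)
  score_or_zero <- function(gs, sd) {
    if (length(gs) == 0L) {
      warning("one phase gene list is empty after intersection; scoring 0",
              call. = FALSE)
      return(rep(0, ncol(normalized)))
    }
    as.numeric(module_score(normalized, gs, seed = sd))
  }
  s <- score_or_zero(s_in, seed)
  g <- score_or_zero(g_in, derive_seed(seed, 1L))
  phase <- ifelse(pmax(s, g) <= 0, "G1", ifelse(s >= g, "S", "G2M"))
  data.frame(barcode = colnames(normalized), s_score = s, g2m_score = g,
             phase = phase, stringsAsFactors = FALSE, row.names = NULL)
}
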