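#' Median-of-ratios size factors
#'
#' For every gene with strictly positive counts in all samples, the
#' geometric mean across samples is formed; each sample's size factor is
#' the median, over those genes, of its count divided by the gene's
#' geometric mean.
#'
#' @param counts Genes x samples nonnegative integer matrix (>= 2 samples).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  m <- as.matrix(counts)
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  allpos <- rowSums(m <= 0) == 0L
  if (!any(allpos))
    stop("no gene has positive counts in every sample", call. = FALSE)
  sub <- m[allpos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  sf <- apply(sub / geo, 2, median)
  setNames(sf, colnames(m))
}

#' Divide counts by size factors
#'
#' @param counts Genes x samples count matrix.
#' @param size_factors Per-sample positive factors from
#'   [size_factors_median_of_ratios()].
#' @return Genes x samples matrix of normalized counts.
#' @export
normalize_by_size_factors <- function(counts, size_factors) {
  m <- as.matrix(counts)
  if (length(size_factors) != ncol(m))
    stop("one size factor per sample required", call. = FALSE)
  sweep(m, 2, size_factors, "/")
}

#' Control-condition ratio normalization
#'
#' Divides each sample's normalized expression, plus a pseudocount, by the
#' mean normalized expression of its mapped control sample(s) plus the same
#' pseudocount — removing unspecific culture/processing signatures shared
#' with the control TCR condition. A control sample mapped to itself
#' normalizes to exactly 1.
#'
#' @param normalized Genes x samples normalized matrix.
#' @param control_map Named list: for each sample name, the character
#'   vector of control sample names in its group.
#' @param pseudocount Additive pseudocount (default 1).
#' @return Genes x samples matrix of control ratios; attribute
#'   `pseudocount`.
#' @export
control_ratio <- function(normalized, control_map, pseudocount = 1) {
  m <- as.matrix(normalized)
  unmapped <- setdiff(colnames(m), names(control_map))
  if (length(unmapped))
    stop(sprintf("sample(s) without a control mapping: %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  out <- m
  for (s in colnames(m)) {
    ctrl <- control_map[[s]]
    if (!all(ctrl %in% colnames(m)))
      stop(sprintf("control sample(s) absent for '%s'", s), call. = FALSE)
    denom <- rowMeans(m[, ctrl, drop = FALSE])
    out[, s] <- (m[, s] + pseudocount) / (denom + pseudocount)
  }
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Log-transform and PCA scores for sample visualization
#'
#' `log2(normalized + 1)` transform of the matrix and centered PCA across
#' samples; the scores of the first two components are returned for
#' visualization.
#'
#' @param normalized Genes x samples normalized matrix (>= 3 samples).
#' @return List with `transformed` (genes x samples log2 matrix), `scores`
#'   (samples x 2 PC score matrix) and `variance_explained` (first two
#'   proportions).
#' @export
pca_input <- function(normalized) {
  m <- as.matrix(normalized)
  if (ncol(m) < 3L) stop("need at least 3 samples", call. = FALSE)
  lt <- log2(m + 1)
  pc <- prcomp(t(lt), center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2L || pc$sdev[2] < 1e-12)
    stop("matrix rank below 2; PCA scores undefined", call. = FALSE)
  list(transformed = lt,
       scores = pc$x[, 1:2, drop = FALSE],
       variance_explained = (pc$sdev^2 / sum(pc$sdev^2))[1:2])
}
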