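toy_counts <- function(mat, genes = NULL, cells = NULL) {
  m <- Matrix::Matrix(mat, sparse = TRUE)
  rownames(m) <- genes %||% sprintf("G%03d", seq_len(nrow(m)))
  colnames(m) <- cells %||% sprintf("C%03d-1", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("QC metrics compute genes, UMIs and mitochondrial fraction", {
  m <- toy_counts(matrix(c(30, 70, 0, 5), 2, 2),
                  genes = c("MT-CO1", "ACTB"))
  qc <- compute_qc_metrics(m)
  expect_equal(qc$n_umi, c(100, 5))
  expect_equal(qc$n_genes, c(2, 1))
  expect_equal(qc$pct_mito, c(0.30, 0))
  expect_true(all(qc$n_genes <= qc$n_umi))

  no_mito <- toy_counts(matrix(1:4, 2, 2))
  expect_true(all(compute_qc_metrics(no_mito)$pct_mito == 0))

  with_zero <- toy_counts(cbind(c(1, 1), 0), genes = c("MT-1", "G1"))
  qc0 <- compute_qc_metrics(with_zero)
  expect_equal(qc0$pct_mito[2], 0)
  expect_true(qc0$zero_umi[2])
})

test_that("QC filtering enforces the exact cell and gene boundaries", {
  n_gene <- 6001
  # cells engineered to detect exactly 199/200/5999/6000 genes
  det <- c(199, 200, 5999, 6000)
  m <- matrix(0L, n_gene, length(det))
  for (j in seq_along(det)) m[seq_len(det[j]), j] <- 1L
  m <- toy_counts(m)
  qc <- compute_qc_metrics(m)
  kept <- colnames(filter_cells_genes(m, qc, min_cells_per_gene = 1))
  expect_identical(kept, colnames(m)[c(2, 3)])

  # mitochondrial boundary: 0.18 kept, 0.181 removed
  mm <- matrix(0, 3, 2)
  mm[1, ] <- c(180, 181); mm[2, ] <- c(820, 819); mm[3, ] <- 0
  mm <- toy_counts(mm, genes = c("MT-1", "G1", "G2"))
  qcm <- compute_qc_metrics(mm)
  expect_equal(qcm$pct_mito, c(0.180, 0.181))
  keptm <- colnames(filter_cells_genes(mm, qcm, min_genes = 1,
                                       min_cells_per_gene = 1))
  expect_identical(keptm, colnames(mm)[1])

  # hand-enumerated toy: gene filter first on the raw matrix, then cells
  toy <- toy_counts(rbind(c(1, 1, 1, 1, 1, 1),
                          c(1, 1, 1, 1, 1, 0),
                          c(1, 0, 0, 0, 0, 0),   # detected in 1 cell: drop
                          c(1, 1, 1, 1, 0, 0),
                          c(1, 1, 1, 0, 0, 0)))
  qct <- compute_qc_metrics(toy)
  out <- filter_cells_genes(toy, qct, min_genes = 3, max_genes = 100,
                            max_mito = 1, min_cells_per_gene = 3)
  expect_equal(dim(out), c(4, 4))
  expect_identical(colnames(out), colnames(toy)[1:4])
  expect_false("G003" %in% rownames(out))

  expect_error(filter_cells_genes(toy, qct, min_genes = 100),
               "no cells pass QC")
  # idempotence
  qc2 <- compute_qc_metrics(out)
  out2 <- filter_cells_genes(out, qc2, min_genes = 3, max_genes = 100,
                             max_mito = 1, min_cells_per_gene = 3)
  expect_equal(as.matrix(out2), as.matrix(out))
})

test_that("log-normalization matches the closed form and is depth-invariant", {
  m <- toy_counts(rbind(c(1, 2), c(9999, 0)))
  norm <- log_normalize(m, scale_factor = 1e4)
  expect_equal(norm[1, 1], log(1 + 1), tolerance = 1e-12)
  expect_equal(norm[2, 2], 0)

  doubled <- m
  doubled[, 1] <- doubled[, 1] * 2
  norm2 <- log_normalize(doubled)
  expect_equal(as.matrix(norm2[, 1]), as.matrix(norm[, 1]), tolerance = 1e-12)
})

test_that("variable-gene scoring finds overdispersed genes and is deterministic", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n_cells <- 120
    mu <- rep(2, 200)
    counts <- matrix(rpois(200 * n_cells, mu), 200, n_cells)
    od <- 1:10    # overdispersed genes: gamma-mixed Poisson, 5x variance
    counts[od, ] <- matrix(rpois(10 * n_cells,
                                 rgamma(10 * n_cells, shape = 0.5,
                                        scale = 4)), 10, n_cells)
    vg <- find_variable_genes(toy_counts(counts), n_top = 20)
    sum(sprintf("G%03d", od) %in% vg$gene[1:20])
  }, numeric(1))
  expect_gte(mean(hits), 9)
  expect_true(all(hits >= 7))

  set.seed(1)
  counts <- matrix(rpois(200 * 60, 3), 200, 60)
  counts[5, ] <- counts[4, ]          # identical vectors, identical scores
  counts[6, ] <- 7                    # constant gene: zero variance
  vg <- find_variable_genes(toy_counts(counts), n_top = 200)
  sc <- attr(vg, "all_scores")
  expect_equal(sc[["G004"]], sc[["G005"]])
  expect_equal(sc[["G006"]], 0)
  expect_false("G006" %in% vg$gene[vg$score > 0])
  expect_true(all(diff(vg$score) <= 1e-12))
})

test_that("covariate regression scaling matches hand-computed OLS residuals", {
  # 3 genes x 5 cells against two covariates, solved by normal equations
  y <- rbind(c(1.0, 2.2, 1.4, 2.9, 2.7),
             c(0.2, 0.1, 0.4, 0.3, 0.5),
             c(5, 5, 5, 5, 5))
  rownames(y) <- c("A", "B", "C"); colnames(y) <- paste0("c", 1:5)
  cov <- data.frame(n_umi = c(100, 200, 150, 300, 250),
                    pct_mito = c(.01, .05, .02, .08, .03))
  out <- scale_with_regression(y, rownames(y), covariates = cov, clip = 10)

  X <- cbind(1, as.matrix(cov))
  for (g in c("A", "B")) {
    beta <- solve(t(X) %*% X, t(X) %*% y[g, ])
    r <- as.numeric(y[g, ] - X %*% beta)
    r <- (r - mean(r)) / sd(r)
    expect_equal(unname(out[g, ]), r, tolerance = 1e-10)
  }
  # constant gene: residuals all zero, no division blow-up
  expect_true(all(out["C", ] == 0))
  # per-gene mean 0 before clipping
  expect_lt(max(abs(rowMeans(out[c("A", "B"), ]))), 1e-8)

  # gene exactly linear in a covariate: residuals all zero
  y2 <- rbind(lin = 0.01 * cov$n_umi + 2)
  colnames(y2) <- paste0("c", 1:5)
  out2 <- scale_with_regression(y2, "lin", covariates = cov)
  expect_true(all(abs(out2) < 1e-10))

  # no covariates reduces to plain (x - mean)/sd
  out3 <- scale_with_regression(y, "A", covariates = NULL)
  expect_equal(unname(out3["A", ]),
               as.numeric(scale(y["A", ])), tolerance = 1e-12)
})

test_that("clustering separates well-separated blobs and is deterministic", {
  set.seed(7)
  blob <- function(center, n) {
    m <- matrix(rnorm(40 * n, 0, 0.1), 40, n) + center
    m
  }
  scaled <- cbind(blob(0, 200), blob(10, 200))
  rownames(scaled) <- sprintf("G%02d", 1:40)
  colnames(scaled) <- sprintf("C%03d", 1:400)
  truth <- rep(0:1, each = 200)
  cl <- embed_and_cluster(scaled, n_pcs = 10, n_neighbors = 15,
                          resolution = 0.8, seed = 1)
  expect_equal(length(unique(cl$cluster)), 2)
  agree <- max(mean(cl$cluster == truth), mean(cl$cluster == 1 - truth))
  expect_gte(agree, 0.99)
  # every cell assigned; ids 0..K-1 with nonincreasing sizes
  expect_equal(nrow(cl), 400)
  expect_setequal(unique(cl$cluster), 0:1)
  sizes <- as.integer(table(cl$cluster))
  expect_true(all(diff(sizes) <= 0))

  cl2 <- embed_and_cluster(scaled, n_pcs = 10, n_neighbors = 15,
                           resolution = 0.8, seed = 1)
  expect_identical(cl$cluster, cl2$cluster)

  expect_error(embed_and_cluster(scaled, n_pcs = 1000), "n_pcs")
})

test_that("module scores are zero on constant input and recover known shifts", {
  const <- toy_counts(matrix(2, 50, 30))
  ms <- module_score(log_normalize(const), rownames(const)[1:5], seed = 1)
  expect_true(all(abs(ms) < 1e-12))

  # signature genes shifted by +delta in half the cells
  delta <- 1.0
  rel_err <- vapply(1:20, function(s) {
    set.seed(s)
    norm <- matrix(rnorm(1000 * 80, 1, 0.3), 1000, 80)
    rownames(norm) <- sprintf("G%04d", 1:1000)
    colnames(norm) <- sprintf("C%03d", 1:80)
    sig <- sample(rownames(norm), 15)
    hot <- 1:40
    norm[sig, hot] <- norm[sig, hot] + delta
    sc <- module_score(norm, sig, seed = s)
    diff_obs <- mean(sc[hot]) - mean(sc[-hot])
    abs(diff_obs - delta) / delta
  }, numeric(1))
  expect_lt(median(rel_err), 0.10)

  set.seed(3)
  norm <- matrix(rnorm(100 * 40), 100, 40,
                 dimnames = list(sprintf("G%03d", 1:100),
                                 sprintf("C%02d", 1:40)))
  a <- module_score(norm, rownames(norm)[1:10], seed = 5)
  b <- module_score(norm, rownames(norm)[1:10], seed = 5)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_warning(module_score(norm, c(rownames(norm)[1:3], "NOPE"), seed = 1),
                 "absent")
  expect_error(suppressWarnings(module_score(norm, "NOPE", seed = 1)))
})

test_that("module score is centered under exchangeability", {
  set.seed(11)
  norm <- matrix(rnorm(300 * 60, 1, 0.5), 300, 60,
                 dimnames = list(sprintf("G%03d", 1:300),
                                 sprintf("C%02d", 1:60)))
  means <- vapply(1:50, function(s)
    mean(module_score(norm, sample(rownames(norm), 20), seed = s)),
    numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se + 1e-9)
})

test_that("cell-cycle calls follow the argmax rule and track the proliferative program", {
  norm <- matrix(0.5, 20, 3,
                 dimnames = list(sprintf("G%02d", 1:20), c("a", "b", "c")))
  # constant matrix: scores are 0 -> G1 for everyone
  cc <- cell_cycle_score(norm, rownames(norm)[1:3], rownames(norm)[4:6],
                         seed = 1)
  expect_true(all(cc$phase == "G1"))

  # synthetic proliferative program: its cells call S/G2M more often
  progs <- list(list(name = "naive", genes = 31:60, mean_shift = 1.5),
                list(name = "proliferative", genes = 61:90, mean_shift = 1.5))
  cfg <- sim_config(n_clonotypes = 20, n_cells_pre = 250, n_cells_post = 250,
                    n_genes = 200, programs = progs, seed = 23)
  sim <- generate_repertoire_pair(cfg)
  gex <- generate_gex(cfg, sim$truth)
  norm2 <- log_normalize(gex$counts)
  genes <- rownames(norm2)
  cc2 <- cell_cycle_score(norm2, s_genes = genes[61:75],
                          g2m_genes = genes[76:90], seed = 2)
  prolif <- gex$truth$cells_gex$program == "proliferative"
  frac_cycling <- function(sel) mean(cc2$phase[sel] != "G1")
  expect_gt(frac_cycling(prolif), frac_cycling(!prolif))

  expect_error(cell_cycle_score(norm, "NOPE1", "NOPE2"), "no cell-cycle genes")
})
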