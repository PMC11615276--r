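test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(n_clonotypes = 0), "n_clonotypes")
  expect_error(sim_config(clonal_alpha = -1), "clonal_alpha")
  expect_error(sim_config(chain_dropout_rate = 1.2), "chain_dropout_rate")
  expect_error(sim_config(spikes = list(list(id = 9999, factor = 2)),
                          n_clonotypes = 10), "spikes")
  expect_error(sim_config(spikes = list(list(id = 1, factor = -2))),
               "spikes")
  expect_error(sim_config(n_genes = 10,
                          programs = list(list(name = "x", genes = 11,
                                               mean_shift = 1))),
               "programs")
})

test_that("sampling probabilities are a renormalized power law with spikes", {
  cfg <- sim_config(n_clonotypes = 100, clonal_alpha = 2,
                    n_cells_pre = 50, n_cells_post = 50,
                    spikes = list(list(id = 10, factor = 25)), seed = 3)
  sim <- generate_repertoire_pair(cfg)
  tr <- sim$truth
  expect_equal(sum(tr$p_pre), 1, tolerance = 1e-12)
  expect_equal(sum(tr$p_post), 1, tolerance = 1e-12)
  raw <- (1:100)^(-2)
  expect_equal(tr$p_pre, raw / sum(raw), tolerance = 1e-12)
  spiked <- raw
  spiked[10] <- spiked[10] * 25
  expect_equal(tr$p_post, spiked / sum(spiked), tolerance = 1e-12)
})

test_that("fixed seed gives byte-identical repertoire and expression files", {
  cfg <- sim_config(n_clonotypes = 50, n_cells_pre = 200, n_cells_post = 200,
                    n_genes = 60, seed = 11)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  s1 <- generate_repertoire_pair(cfg); g1 <- generate_gex(cfg, s1$truth)
  s2 <- generate_repertoire_pair(cfg); g2 <- generate_gex(cfg, s2$truth)
  write_simulation(s1, d1, gex = g1)
  write_simulation(s2, d2, gex = g2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
})

test_that("contig row counts and barcodes obey conservation", {
  cfg <- sim_config(n_clonotypes = 80, n_cells_pre = 500, n_cells_post = 500,
                    seed = 5)
  sim <- generate_repertoire_pair(cfg)
  for (s in c("pre", "post")) {
    df <- sim[[s]]
    expect_false(anyDuplicated(unique(df$barcode)) > 0)
    per_cell <- table(df$barcode)
    expect_equal(nrow(df), sum(per_cell))
    expect_true(all(per_cell >= 1 & per_cell <= 3))
  }
  expect_equal(length(unique(sim$pre$barcode)), cfg$n_cells_pre)
  expect_equal(length(unique(sim$post$barcode)), cfg$n_cells_post)
})

test_that("null simulations give fold changes concentrated near 1", {
  meds <- vapply(1:20, function(s) {
    cfg <- sim_config(n_cells_pre = 5000, n_cells_post = 5000,
                      spikes = list(), seed = s)
    sim <- generate_repertoire_pair(cfg)
    rec <- compare_frequencies(sim_table(sim$pre, "unstimulated"),
                               sim_table(sim$post, "restimulated"))
    median(rec$fold_change)
  }, numeric(1))
  expect_gte(median(meds), 0.8)
  expect_lte(median(meds), 1.25)
  expect_true(all(meds > 0.6 & meds < 1.6))
})

test_that("a strong spike is recovered at fold-change rank 1", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_cells_pre = 5000, n_cells_post = 5000,
                      spikes = list(list(id = 54, factor = 50)), seed = s)
    sim <- generate_repertoire_pair(cfg)
    rk <- rank_candidates(compare_frequencies(
      sim_table(sim$pre, "unstimulated"),
      sim_table(sim$post, "restimulated")))
    rk$rank_fc[match(truth_key(sim$truth, 54), rk$key)]
  }, numeric(1))
  # pre-stimulation probability of clonotype 54 under alpha = 1.5 is ~0.1%
  p <- (1:500)^(-1.5); p <- p / sum(p)
  expect_equal(p[54], 0.001, tolerance = 0.15)
  expect_gte(sum(hits == 1, na.rm = TRUE), 19)
})

test_that("null fraction of FC > 2 matches the multinomial expectation", {
  cfg <- sim_config(n_clonotypes = 100, n_cells_pre = 2000,
                    n_cells_post = 2000, chain_dropout_rate = 0,
                    multi_chain_rate = 0, nonproductive_rate = 0, seed = 21)
  sim <- generate_repertoire_pair(cfg)
  rec <- compare_frequencies(sim_table(sim$pre, "pre"),
                             sim_table(sim$post, "post"))
  frac_pipeline <- mean(rec$fold_change > 2)

  # brute-force multinomial oracle under the same probabilities
  set.seed(99)
  fracs <- vapply(1:200, function(i) {
    c_pre <- as.vector(stats::rmultinom(1, cfg$n_cells_pre, sim$truth$p_pre))
    c_post <- as.vector(stats::rmultinom(1, cfg$n_cells_post,
                                         sim$truth$p_post))
    seen <- c_pre + c_post > 0
    fc <- ((c_post[seen] + 1) / (cfg$n_cells_post + 1)) /
      ((c_pre[seen] + 1) / (cfg$n_cells_pre + 1))
    mean(fc > 2)
  }, numeric(1))
  expect_lte(abs(frac_pipeline - mean(fracs)),
             3 * sd(fracs) + 1e-9)
})

test_that("expression counts reflect program shifts, mito fractions, and truth", {
  cfg <- sim_config(n_clonotypes = 30, n_cells_pre = 300, n_cells_post = 300,
                    n_genes = 200,
                    library_size_lognormal = c(log(20000), 0.1), seed = 13)
  sim <- generate_repertoire_pair(cfg)
  gex <- generate_gex(cfg, sim$truth)
  expect_s4_class(gex$counts, "dgCMatrix")
  expect_identical(colnames(gex$counts),
                   c(sim$truth$cells_pre$barcode, sim$truth$cells_post$barcode))

  qc <- compute_qc_metrics(gex$counts)
  expect_lt(max(abs(qc$pct_mito - gex$truth$cells_gex$mito_fraction)), 0.03)

  # program genes are elevated in their own program's cells
  prog <- cfg$programs[[2]]
  own <- gex$truth$cells_gex$program == prog$name
  pg <- Matrix::rowMeans(gex$counts[prog$genes, own, drop = FALSE])
  other <- Matrix::rowMeans(gex$counts[prog$genes, !own, drop = FALSE])
  expect_gt(mean(pg / pmax(other, 1e-9)), 2)

  expect_error(generate_gex(sim_config(seed = 99), sim$truth),
               "not produced from this config")
})

test_that("zero mean shift leaves per-gene expression exchangeable across programs", {
  progs <- lapply(c("a", "b"), function(nm)
    list(name = nm, genes = 21:60, mean_shift = 0))
  # fixed library size and near-constant mito fraction keep the per-gene
  # tests independent across genes, so the binomial band applies
  cfg <- sim_config(n_clonotypes = 20, n_cells_pre = 150, n_cells_post = 150,
                    n_genes = 200, programs = progs,
                    library_size_lognormal = c(log(5000), 0),
                    mito_count_beta = c(6000, 94000), seed = 31)
  sim <- generate_repertoire_pair(cfg)
  gex <- generate_gex(cfg, sim$truth)
  grp <- gex$truth$cells_gex$program
  counts <- as.matrix(gex$counts)
  pvals <- apply(counts[21:220 - 20, , drop = FALSE], 1, function(g)
    suppressWarnings(wilcox.test(g[grp == "a"], g[grp == "b"])$p.value))
  pvals <- pvals[!is.na(pvals)]
  rej <- mean(pvals < 0.05)
  ci <- qbinom(c(0.025, 0.975), length(pvals), 0.05) / length(pvals)
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
})

test_that("MTX round-trip preserves the count matrix", {
  cfg <- sim_config(n_clonotypes = 10, n_cells_pre = 40, n_cells_post = 40,
                    n_genes = 50, seed = 17)
  sim <- generate_repertoire_pair(cfg)
  gex <- generate_gex(cfg, sim$truth)
  d <- file.path(tempdir(), "mtxrt")
  write_gex_mtx(gex$counts, d)
  back <- read_gex_mtx(d)
  expect_equal(as.matrix(back), as.matrix(gex$counts))
})
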