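# Independent oracles and fixture builders used across the suite.

# Exhaustive two-sided Wilcoxon rank-sum p-value: enumerate every assignment
# of group labels to the pooled observations, take 2 * min(tail) capped at 1.
# Independent of stats::wilcox.test.
enumerate_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  nx <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force median-of-ratios size factors, gene-by-gene loops.
brute_size_factors <- function(m) {
  pos <- apply(m, 1, function(r) all(r > 0))
  geo <- apply(m[pos, , drop = FALSE], 1, function(r) prod(r)^(1 / length(r)))
  vapply(seq_len(ncol(m)), function(j)
    median(m[pos, j] / geo), numeric(1))
}

# Minimal contig table in the 10x dialect.
toy_contig_df <- function(barcode, chain, cdr3, v = "TRAV1", j = "TRAJ1",
                          productive = "True") {
  n <- length(barcode)
  if (n == 0L)
    return(toy_contig_df("X-1", "TRA", "CAF")[0, ])
  data.frame(
    barcode = barcode, is_cell = "True",
    contig_id = paste0(barcode, "_c", seq_len(n)),
    high_confidence = "True", length = 500L, chain = chain,
    v_gene = rep_len(v, n), d_gene = "None", j_gene = rep_len(j, n),
    c_gene = "TRAC", full_length = "True",
    productive = rep_len(productive, n),
    cdr3 = cdr3, cdr3_nt = strrep("GCT", nchar(cdr3)),
    reads = 100L, umis = 5L, raw_clonotype_id = "clonotype1",
    stringsAsFactors = FALSE
  )
}

# Clonotype table built directly from per-clonotype cell counts.
table_from_counts <- function(counts, label) {
  keys <- sprintf("TRAV%d:CAAA%dF|TRBV%d:CASS%dF",
                  seq_along(counts), seq_along(counts),
                  seq_along(counts), seq_along(counts))
  cells <- rep(seq_along(counts), counts)
  contigs <- rbind(
    toy_contig_df(sprintf("BC%04d-1", seq_along(cells)), "TRA",
                  sprintf("CAAA%dF", cells),
                  v = sprintf("TRAV%d", cells), j = "TRAJ1"),
    toy_contig_df(sprintf("BC%04d-1", seq_along(cells)), "TRB",
                  sprintf("CASS%dF", cells),
                  v = sprintf("TRBV%d", cells), j = "TRBJ1"))
  cellsobj <- filter_paired_strict(assemble_cells(as_contig_records(contigs)))
  tab <- build_clonotype_table(cellsobj, label)
  stopifnot(sum(tab$cell_count) == sum(counts))
  tab
}

# Canonical key of a truth clonotype row.
truth_key <- function(truth, id) {
  clonotype_key(truth$clonotypes[id, c("alpha_v", "alpha_cdr3",
                                       "beta_v", "beta_cdr3")])
}

# Run the vdj pipeline on a simulated contig data.frame.
sim_table <- function(df, label, filter = filter_paired_strict) {
  build_clonotype_table(filter(assemble_cells(as_contig_records(df))), label)
}
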