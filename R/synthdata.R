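#' Configuration for the paired-repertoire simulator
#'
#' Describes the study conditions emulated by the synthetic generator: a
#' heavy-tailed clonal frequency distribution before stimulation,
#' multiplicative enrichment of chosen antigen-specific clonotypes after
#' restimulation and activation-marker selection, per-cell chain
#' dropout/multi-chain/non-productive corruption of the V(D)J output, and
#' cluster-structured expression programs with library-size and
#' mitochondrial-fraction variation in the expression output.
#'
#' Pre-stimulation clonal sampling probabilities follow a discrete power law
#' `p_i` proportional to `i^(-clonal_alpha)`, renormalized. Post-stimulation
#' probabilities are the pre-stimulation ones with each spiked clonotype
#' multiplied by its enrichment factor, renormalized.
#'
#' @param n_clonotypes Number of distinct clonotypes in the repertoire.
#' @param clonal_alpha Power-law exponent of pre-stimulation clonal
#'   frequencies (larger = more dominated by the top clones).
#' @param n_cells_pre,n_cells_post Cells sequenced per sample.
#' @param spikes List of `list(id =, factor =)` entries: clonotype index
#'   (1-based) and multiplicative post-stimulation enrichment factor.
#' @param chain_dropout_rate Per-cell probability that one chain is missing
#'   from the contig table.
#' @param multi_chain_rate Per-cell probability of an extra alpha or beta
#'   contig copied from a random other clonotype (doublet-like artifact the
#'   QC filters must remove).
#' @param nonproductive_rate Per-contig probability of being flagged
#'   non-productive.
#' @param n_genes Number of genes in the expression matrix.
#' @param programs List of `list(name =, genes =, mean_shift =)` expression
#'   programs; `genes` are 1-based gene indices, `mean_shift` is an additive
#'   shift on the natural-log gene weight for cells of that program.
#'   `NULL` builds four default programs (naive, effector, inhibitory,
#'   proliferative) over disjoint non-mitochondrial gene blocks.
#' @param mito_gene_fraction Fraction of genes that are mitochondrial
#'   (named with prefix `"MT-"`).
#' @param mito_count_beta Length-2 Beta shape parameters for the per-cell
#'   mitochondrial count fraction.
#' @param library_size_lognormal Named vector `c(meanlog =, sdlog =)` for the
#'   per-cell library size.
#' @param seed Integer master seed; all output streams derive from it, so a
#'   fixed seed gives byte-identical output.
#'
#' @return An object of class `sim_config`.
#' @seealso [generate_repertoire_pair()], [generate_gex()]
#' @export
sim_config <- function(n_clonotypes = 500L,
                       clonal_alpha = 1.5,
                       n_cells_pre = 5000L,
                       n_cells_post = 5000L,
                       spikes = list(),
                       chain_dropout_rate = 0.05,
                       multi_chain_rate = 0.03,
                       nonproductive_rate = 0.02,
                       n_genes = 400L,
                       programs = NULL,
                       mito_gene_fraction = 0.05,
                       mito_count_beta = c(2.4, 37.6),
                       library_size_lognormal = c(meanlog = log(4000),
                                                  sdlog = 0.35),
                       seed = 1L) {
  n_clonotypes <- check_pos_int(n_clonotypes, "n_clonotypes")
  n_cells_pre  <- check_pos_int(n_cells_pre, "n_cells_pre")
  n_cells_post <- check_pos_int(n_cells_post, "n_cells_post")
  n_genes      <- check_pos_int(n_genes, "n_genes")
  if (!is.numeric(clonal_alpha) || length(clonal_alpha) != 1L ||
      is.na(clonal_alpha) || clonal_alpha <= 0)
    stop_field("clonal_alpha", "must be a positive real")
  check_prob(chain_dropout_rate, "chain_dropout_rate")
  check_prob(multi_chain_rate, "multi_chain_rate")
  check_prob(nonproductive_rate, "nonproductive_rate")
  check_prob(mito_gene_fraction, "mito_gene_fraction")
  if (!is.numeric(mito_count_beta) || length(mito_count_beta) != 2L ||
      any(mito_count_beta <= 0))
    stop_field("mito_count_beta", "must be two positive Beta shapes")
  if (!is.numeric(library_size_lognormal) ||
      length(library_size_lognormal) != 2L ||
      library_size_lognormal[2] < 0)
    stop_field("library_size_lognormal", "must be c(meanlog, sdlog), sdlog >= 0")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_field("seed", "must be a single integer")

  if (!is.list(spikes))
    stop_field("spikes", "must be a list of list(id =, factor =)")
  for (s in spikes) {
    if (!is.list(s) || is.null(s$id) || is.null(s$factor))
      stop_field("spikes", "each entry needs 'id' and 'factor'")
    if (s$id < 1 || s$id > n_clonotypes || s$id != round(s$id))
      stop_field("spikes", sprintf("id %s outside 1..%d", s$id, n_clonotypes))
    if (!is.numeric(s$factor) || s$factor <= 0)
      stop_field("spikes", "enrichment factor must be > 0")
  }

  n_mito <- max(1L, round(mito_gene_fraction * n_genes))
  if (is.null(programs)) {
    programs <- default_programs(n_genes, n_mito)
  }
  for (p in programs) {
    if (!is.list(p) || is.null(p$name) || is.null(p$genes) ||
        is.null(p$mean_shift))
      stop_field("programs", "each entry needs 'name', 'genes', 'mean_shift'")
    if (any(p$genes < 1 | p$genes > n_genes))
      stop_field("programs",
                 sprintf("gene indices of '%s' outside 1..%d", p$name, n_genes))
  }

  structure(list(
    n_clonotypes = n_clonotypes, clonal_alpha = clonal_alpha,
    n_cells_pre = n_cells_pre, n_cells_post = n_cells_post,
    spikes = spikes, chain_dropout_rate = chain_dropout_rate,
    multi_chain_rate = multi_chain_rate,
    nonproductive_rate = nonproductive_rate,
    n_genes = n_genes, n_mito = n_mito, programs = programs,
    mito_gene_fraction = mito_gene_fraction,
    mito_count_beta = as.numeric(mito_count_beta),
    library_size_lognormal = as.numeric(library_size_lognormal),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Four disjoint 30-gene programs laid out after the mitochondrial block.
default_programs <- function(n_genes, n_mito) {
  avail <- setdiff(seq_len(n_genes), seq_len(n_mito))
  block <- max(1L, min(30L, floor(length(avail) / 4)))
  nm <- c("naive", "effector", "inhibitory", "proliferative")
  lapply(seq_along(nm), function(i) {
    list(name = nm[i],
         genes = avail[seq.int((i - 1L) * block + 1L, i * block)],
         mean_shift = 1.5)
  })
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic repertoire/expression configuration\n")
  cat(sprintf("  %d clonotypes (power-law alpha = %.2f), %d + %d cells\n",
              x$n_clonotypes, x$clonal_alpha, x$n_cells_pre, x$n_cells_post))
  cat(sprintf("  %d spiked clonotype(s); dropout %.2f, multi-chain %.2f, non-productive %.2f\n",
              length(x$spikes), x$chain_dropout_rate, x$multi_chain_rate,
              x$nonproductive_rate))
  cat(sprintf("  %d genes (%d mitochondrial), %d programs; seed %d\n",
              x$n_genes, x$n_mito, length(x$programs), x$seed))
  invisible(x)
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# one fixed codon per residue so nucleotide CDR3s are deterministic
CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
           H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
           P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
           W = "TGG", Y = "TAT")

random_cdr3 <- function(n, prefix) {
  len <- sample(6:11, n, replace = TRUE)
  vapply(len, function(l)
    paste0(prefix, paste(sample(AA20, l, replace = TRUE), collapse = ""), "F"),
    character(1))
}

unique_cdr3 <- function(n, prefix) {
  out <- random_cdr3(n, prefix)
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- random_cdr3(length(dup), prefix)
  }
  out
}

random_barcodes <- function(n) {
  bc <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 16, replace = TRUE), collapse = ""),
    character(1))
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- vapply(seq_along(dup), function(i)
      paste(sample(c("A", "C", "G", "T"), 16, replace = TRUE), collapse = ""),
      character(1))
  }
  paste0(bc, "-1")
}

aa_to_nt <- function(aa) {
  vapply(strsplit(aa, ""), function(ch) paste(CODON[ch], collapse = ""),
         character(1))
}

#' Simulate a paired unstimulated/restimulated TCR repertoire
#'
#' Draws cells from the configured clonal distribution for both samples
#' (restimulated probabilities carry the spiked enrichment factors) and emits
#' 10x-style contig annotation tables: one productive alpha and one
#' productive beta contig per cell, corrupted at the configured chain
#' dropout, multi-chain and non-productive rates.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `pre` and `post` (contig `data.frame`s in the
#'   dialect read by [read_contigs()]) and `truth` (class `sim_truth`:
#'   sampling probabilities, per-cell true clonotype ids, clonotype
#'   sequences, and the spike list).
#' @export
generate_repertoire_pair <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("`config` must be a sim_config object", call. = FALSE)
  n <- config$n_clonotypes

  p_pre <- seq_len(n)^(-config$clonal_alpha)
  p_pre <- p_pre / sum(p_pre)
  p_post <- p_pre
  for (s in config$spikes) p_post[s$id] <- p_post[s$id] * s$factor
  p_post <- p_post / sum(p_post)

  clonotypes <- with_seed(derive_seed(config$seed, 1L), {
    data.frame(
      clonotype_id = seq_len(n),
      alpha_cdr3 = unique_cdr3(n, "CA"),
      alpha_v = sample(paste0("TRAV", 1:45), n, replace = TRUE),
      alpha_j = sample(paste0("TRAJ", 1:50), n, replace = TRUE),
      beta_cdr3 = unique_cdr3(n, "CASS"),
      beta_v = sample(paste0("TRBV", 1:30), n, replace = TRUE),
      beta_j = sample(paste0("TRBJ", 1:13), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })

  sim_one <- function(n_cells, p, stream) {
    with_seed(derive_seed(config$seed, stream), {
      cid <- sample.int(n, n_cells, replace = TRUE, prob = p)
      barcode <- random_barcodes(n_cells)
      emit_contigs(config, clonotypes, barcode, cid)
    })
  }
  pre <- sim_one(config$n_cells_pre, p_pre, 2L)
  post <- sim_one(config$n_cells_post, p_post, 3L)

  truth <- structure(list(
    p_pre = p_pre, p_post = p_post,
    clonotypes = clonotypes,
    cells_pre = pre$cells, cells_post = post$cells,
    spikes = config$spikes, config = config
  ), class = "sim_truth")

  list(pre = pre$contigs, post = post$contigs, truth = truth)
}

# Emit contig rows for a vector of cells: base TRA+TRB per cell, then
# per-cell dropout, multi-chain and non-productive corruption.
emit_contigs <- function(config, clonotypes, barcode, cid) {
  n_cells <- length(barcode)
  base <- data.frame(
    cell = rep(seq_len(n_cells), each = 2L),
    chain = rep(c("TRA", "TRB"), n_cells),
    src = rep(cid, each = 2L),
    stringsAsFactors = FALSE
  )

  drop_cell <- runif(n_cells) < config$chain_dropout_rate
  drop_chain <- sample(c("TRA", "TRB"), n_cells, replace = TRUE)
  keep <- !(drop_cell[base$cell] & base$chain == drop_chain[base$cell])
  rows <- base[keep, , drop = FALSE]

  extra_cell <- which(runif(n_cells) < config$multi_chain_rate)
  if (length(extra_cell)) {
    donor <- vapply(cid[extra_cell], function(ci)
      sample(setdiff(seq_len(config$n_clonotypes), ci), 1L), integer(1))
    rows <- rbind(rows, data.frame(
      cell = extra_cell,
      chain = sample(c("TRA", "TRB"), length(extra_cell), replace = TRUE),
      src = donor, stringsAsFactors = FALSE))
  }
  rows <- rows[order(rows$cell, rows$chain), , drop = FALSE]

  productive <- ifelse(runif(nrow(rows)) < config$nonproductive_rate,
                       "False", "True")

  is_a <- rows$chain == "TRA"
  cdr3 <- ifelse(is_a, clonotypes$alpha_cdr3[rows$src],
                 clonotypes$beta_cdr3[rows$src])
  vg <- ifelse(is_a, clonotypes$alpha_v[rows$src], clonotypes$beta_v[rows$src])
  jg <- ifelse(is_a, clonotypes$alpha_j[rows$src], clonotypes$beta_j[rows$src])
  cdr3_nt <- aa_to_nt(cdr3)
  umis <- 1L + rpois(nrow(rows), 4)
  reads <- umis * (30L + rpois(nrow(rows), 20))

  contigs <- data.frame(
    barcode = barcode[rows$cell],
    is_cell = "True",
    contig_id = paste0(barcode[rows$cell], "_contig_",
                       stats::ave(rows$cell, rows$cell, FUN = seq_along)),
    high_confidence = "True",
    length = 420L + nchar(cdr3_nt),
    chain = rows$chain,
    v_gene = vg,
    d_gene = ifelse(is_a, "None", "TRBD1"),
    j_gene = jg,
    c_gene = ifelse(is_a, "TRAC", "TRBC1"),
    full_length = "True",
    productive = productive,
    cdr3 = cdr3,
    cdr3_nt = cdr3_nt,
    reads = reads,
    umis = umis,
    raw_clonotype_id = paste0("clonotype", rows$src),
    stringsAsFactors = FALSE
  )
  list(contigs = contigs,
       cells = data.frame(barcode = barcode, clonotype_id = cid,
                          stringsAsFactors = FALSE))
}

#' Simulate gene-expression counts matched to a simulated repertoire
#'
#' Every cell of both repertoire samples receives an expression profile:
#' Poisson counts with per-cell rate = library size (lognormal) times a
#' gene-probability vector in which the cell's program genes are shifted up
#' and mitochondrial genes (prefix `"MT-"`) receive the cell's true
#' mitochondrial count fraction (Beta-distributed).
#'
#' @param config The [sim_config()] the repertoire was generated from.
#' @param truth The `sim_truth` returned by [generate_repertoire_pair()].
#' @return A list of class `gex_sim`: `counts` (genes x cells sparse
#'   dgCMatrix, dimnames set), `barcodes`, `features`, `sample` (per-cell
#'   label), and `truth` — the input truth extended with per-cell program,
#'   true mitochondrial fraction and library size (`$cells_gex`).
#' @export
generate_gex <- function(config, truth) {
  if (!inherits(config, "sim_config"))
    stop("`config` must be a sim_config object", call. = FALSE)
  if (!inherits(truth, "sim_truth") || !identical(truth$config, config))
    stop("truth was not produced from this config", call. = FALSE)

  barcodes <- c(truth$cells_pre$barcode, truth$cells_post$barcode)
  sample_lab <- rep(c("unstimulated", "restimulated"),
                    c(nrow(truth$cells_pre), nrow(truth$cells_post)))
  n_cells <- length(barcodes)
  n_mito <- config$n_mito
  gene_names <- c(paste0("MT-", seq_len(n_mito)),
                  sprintf("GENE%04d", seq_len(config$n_genes - n_mito)))

  res <- with_seed(derive_seed(config$seed, 4L), {
    w <- rnorm(config$n_genes, 0, 1)
    mito_idx <- seq_len(n_mito)
    non_idx <- setdiff(seq_len(config$n_genes), mito_idx)

    prog_names <- vapply(config$programs, `[[`, character(1), "name")
    n_prog <- max(1L, length(config$programs))
    # per-program probability vector over non-mito genes
    prog_prob <- vapply(seq_len(n_prog), function(pi) {
      wp <- w[non_idx]
      if (length(config$programs)) {
        p <- config$programs[[pi]]
        sel <- intersect(p$genes, non_idx)
        wp[match(sel, non_idx)] <- wp[match(sel, non_idx)] + p$mean_shift
      }
      e <- exp(wp - max(wp))
      e / sum(e)
    }, numeric(length(non_idx)))
    mito_prob <- {
      e <- exp(w[mito_idx] - max(w[mito_idx]))
      e / sum(e)
    }

    program <- if (length(config$programs))
      sample(prog_names, n_cells, replace = TRUE) else rep("none", n_cells)
    prog_i <- if (length(config$programs)) match(program, prog_names)
              else rep(1L, n_cells)
    f <- rbeta(n_cells, config$mito_count_beta[1], config$mito_count_beta[2])
    L <- rlnorm(n_cells, config$library_size_lognormal[1],
                config$library_size_lognormal[2])

    rate <- matrix(0, config$n_genes, n_cells)
    rate[non_idx, ] <- prog_prob[, prog_i, drop = FALSE] *
      rep((1 - f) * L, each = length(non_idx))
    rate[mito_idx, ] <- mito_prob %o% (f * L)
    counts <- matrix(rpois(length(rate), rate), config$n_genes, n_cells)
    list(counts = counts, program = program, f = f, L = L)
  })

  counts <- methods::as(Matrix::Matrix(res$counts, sparse = TRUE),
                        "CsparseMatrix")
  dimnames(counts) <- list(gene_names, barcodes)

  truth$cells_gex <- data.frame(
    barcode = barcodes, sample = sample_lab, program = res$program,
    mito_fraction = res$f, library_size = res$L, stringsAsFactors = FALSE)

  structure(list(
    counts = counts, barcodes = barcodes,
    features = data.frame(id = gene_names, name = gene_names,
                          type = "Gene Expression", stringsAsFactors = FALSE),
    sample = sample_lab, truth = truth
  ), class = "gex_sim")
}

#' Write simulated data to disk in standard formats
#'
#' Contig tables go to `filtered_contig_annotations`-style CSV, expression
#' matrices to MatrixMarket MTX with barcodes/features TSV, truth tables to
#' TSV. Output is byte-identical for a fixed config seed.
#'
#' @param sim Result of [generate_repertoire_pair()].
#' @param gex Optional result of [generate_gex()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir, gex = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (s in c("pre", "post")) {
    f <- file.path(dir, sprintf("%s_filtered_contig_annotations.csv", s))
    write.csv(sim[[s]], f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  tt <- file.path(dir, "truth_clonotypes.tsv")
  write.table(cbind(sim$truth$clonotypes,
                    p_pre = sim$truth$p_pre, p_post = sim$truth$p_post),
              tt, sep = "\t", row.names = FALSE, quote = FALSE)
  files <- c(files, tt)
  if (!is.null(gex)) {
    files <- c(files, write_gex_mtx(gex$counts, file.path(dir, "gex")))
    ct <- file.path(dir, "truth_cells.tsv")
    write.table(gex$truth$cells_gex, ct, sep = "\t", row.names = FALSE,
                quote = FALSE)
    files <- c(files, ct)
  }
  invisible(files)
}

#' Write a genes x cells count matrix as MTX + barcodes/features TSV
#'
#' @param counts Sparse or dense genes x cells matrix with dimnames.
#' @param dir Output directory.
#' @return Invisibly, the three file paths.
#' @export
write_gex_mtx <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  fm <- file.path(dir, "matrix.mtx")
  fb <- file.path(dir, "barcodes.tsv")
  ff <- file.path(dir, "features.tsv")
  Matrix::writeMM(m, fm)
  writeLines(colnames(m), fb)
  write.table(data.frame(id = rownames(m), name = rownames(m),
                         type = "Gene Expression"),
              ff, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(c(fm, fb, ff))
}

#' Read a genes x cells count matrix from MTX + barcodes/features TSV
#'
#' Accepts the layout written by [write_gex_mtx()] (and the plain-text 10x
#' convention): `matrix.mtx`, `barcodes.tsv`, `features.tsv` in one
#' directory.
#'
#' @param dir Directory holding the three files.
#' @return A genes x cells sparse `dgCMatrix` with dimnames.
#' @export
read_gex_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  bc <- readLines(file.path(dir, "barcodes.tsv"))
  ft <- read.delim(file.path(dir, "features.tsv"), header = FALSE,
                   stringsAsFactors = FALSE)
  if (length(bc) != ncol(m) || nrow(ft) != nrow(m))
    stop("barcodes/features do not match matrix dimensions", call. = FALSE)
  dimnames(m) <- list(ft[[1]], bc)
  m
}
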