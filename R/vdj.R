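#' Read a 10x-style contig annotation table
#'
#' Parses a `filtered_contig_annotations.csv`-dialect table into a
#' standardized contig `data.frame`. Chains other than TRA/TRB are mapped to
#' `"other"`; rows with `is_cell` or `high_confidence` false are dropped when
#' those columns exist (configurable). `productive` accepts
#' `"True"/"False"/"None"` strings or logicals; `"None"` is treated as not
#' productive.
#'
#' @param path CSV file with a header row.
#' @param drop_uncertain Drop rows with `is_cell` or `high_confidence` false
#'   (default `TRUE`; ignored when the columns are absent).
#' @return A `data.frame` with columns `barcode`, `chain`, `cdr3_aa`,
#'   `cdr3_nt`, `v_gene`, `j_gene`, `c_gene`, `productive` (logical),
#'   `umis`, `reads`, `is_cell`, `high_confidence`.
#' @export
read_contigs <- function(path, drop_uncertain = TRUE) {
  if (!file.exists(path))
    stop(sprintf("contig file not found: %s", path), call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_contig_records(raw, drop_uncertain = drop_uncertain)
}

#' Standardize an in-memory contig annotation table
#'
#' The `data.frame` equivalent of [read_contigs()]: applies the same column
#' mapping, chain normalization and uncertainty filtering to a raw contig
#' table already in memory (e.g. straight from
#' [generate_repertoire_pair()]).
#'
#' @param raw Contig `data.frame` in the 10x dialect.
#' @inheritParams read_contigs
#' @return Standardized contig `data.frame` (see [read_contigs()]).
#' @export
as_contig_records <- function(raw, drop_uncertain = TRUE) {
  need <- c("barcode", "chain", "cdr3", "productive")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop(sprintf("contig table is missing mandatory column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)

  as_flag <- function(x) {
    if (is.logical(x)) return(x)
    tolower(trimws(as.character(x))) %in% c("true", "t", "1")
  }
  opt_num <- function(col) {
    if (col %in% names(raw)) as.integer(raw[[col]]) else {
      warning(sprintf("optional column '%s' absent; defaulting to 0", col),
              call. = FALSE)
      rep(0L, nrow(raw))
    }
  }
  opt_chr <- function(col) {
    if (col %in% names(raw)) as.character(raw[[col]]) else rep("", nrow(raw))
  }

  rec <- data.frame(
    barcode = as.character(raw$barcode),
    chain = ifelse(raw$chain %in% c("TRA", "TRB"), raw$chain, "other"),
    cdr3_aa = ifelse(raw$cdr3 %in% c("None", NA), "", as.character(raw$cdr3)),
    cdr3_nt = opt_chr("cdr3_nt"),
    v_gene = opt_chr("v_gene"),
    j_gene = opt_chr("j_gene"),
    c_gene = opt_chr("c_gene"),
    productive = as_flag(raw$productive),
    umis = opt_num("umis"),
    reads = opt_num("reads"),
    is_cell = if ("is_cell" %in% names(raw)) as_flag(raw$is_cell) else TRUE,
    high_confidence = if ("high_confidence" %in% names(raw))
      as_flag(raw$high_confidence) else TRUE,
    stringsAsFactors = FALSE
  )
  if (any(rec$barcode == ""))
    stop("contig table contains empty barcodes", call. = FALSE)
  if (drop_uncertain) rec <- rec[rec$is_cell & rec$high_confidence, ,
                                 drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Group contig records into per-cell chain sets
#'
#' Groups contigs by barcode and collapses duplicate identical productive
#' contigs (same barcode, chain, CDR3 and V/J genes) to one, so sequencing
#' artifacts do not disqualify a cell in the paired-chain filters. TRA/TRB
#' input order is preserved within each cell; `"other"` chains are carried
#' but ignored by the filters.
#'
#' @param records Contig `data.frame` from [read_contigs()].
#' @return An object of class `cell_chains`: the (deduplicated) contig
#'   `data.frame` with a `cell` grouping column.
#' @export
assemble_cells <- function(records) {
  if (nrow(records) == 0L) {
    out <- cbind(records, cell = integer(0))
    class(out) <- c("cell_chains", "data.frame")
    return(out)
  }
  dup <- duplicated(records[, c("barcode", "chain", "cdr3_aa", "v_gene",
                                "j_gene", "productive")])
  rec <- records[!dup, , drop = FALSE]
  ord <- order(match(rec$barcode, unique(rec$barcode)))
  rec <- rec[ord, , drop = FALSE]
  rec$cell <- match(rec$barcode, unique(rec$barcode))
  rownames(rec) <- NULL
  class(rec) <- c("cell_chains", "data.frame")
  rec
}

#' @export
print.cell_chains <- function(x, ...) {
  cat(sprintf("cell_chains: %d contigs across %d cells\n",
              nrow(x), length(unique(x$barcode))))
  invisible(x)
}

n_productive <- function(cells, which_chain) {
  tab <- table(factor(cells$barcode[cells$chain == which_chain &
                                      cells$productive],
                      levels = unique(cells$barcode)))
  as.integer(tab)
}

subset_cells <- function(cells, keep_barcodes) {
  out <- cells[cells$barcode %in% keep_barcodes, , drop = FALSE]
  out$cell <- match(out$barcode, unique(out$barcode))
  rownames(out) <- NULL
  class(out) <- c("cell_chains", "data.frame")
  out
}

#' Strict paired-chain filter
#'
#' Retains cells with exactly one productive alpha and exactly one
#' productive beta chain; all other cells are removed. This is the refined
#' clonotype universe used for candidate-TCR selection.
#'
#' @param cells A `cell_chains` object.
#' @return A filtered `cell_chains` object.
#' @seealso [filter_any_defined()] for the looser universe.
#' @export
filter_paired_strict <- function(cells) {
  bcs <- unique(cells$barcode)
  na <- n_productive(cells, "TRA")
  nb <- n_productive(cells, "TRB")
  subset_cells(cells, bcs[na == 1L & nb == 1L])
}

#' Any-defined-chain filter
#'
#' Retains cells with at least one productive alpha or beta chain, provided
#' no chain type is represented by more than one productive contig. A
#' superset of [filter_paired_strict()].
#'
#' @param cells A `cell_chains` object.
#' @return A filtered `cell_chains` object.
#' @export
filter_any_defined <- function(cells) {
  bcs <- unique(cells$barcode)
  na <- n_productive(cells, "TRA")
  nb <- n_productive(cells, "TRB")
  subset_cells(cells, bcs[(na + nb) >= 1L & na <= 1L & nb <= 1L])
}

# sentinel for a chain absent under the any-defined filter
CHAIN_NA <- "."

cell_keys <- function(cells) {
  bcs <- unique(cells$barcode)
  pick <- function(chain_name, col) {
    sel <- cells$chain == chain_name & cells$productive
    v <- rep(CHAIN_NA, length(bcs))
    idx <- match(cells$barcode[sel], bcs)
    v[idx] <- cells[[col]][sel]
    v
  }
  data.frame(
    barcode = bcs,
    alpha_cdr3 = pick("TRA", "cdr3_aa"),
    alpha_v = pick("TRA", "v_gene"),
    alpha_j = pick("TRA", "j_gene"),
    beta_cdr3 = pick("TRB", "cdr3_aa"),
    beta_v = pick("TRB", "v_gene"),
    beta_j = pick("TRB", "j_gene"),
    stringsAsFactors = FALSE
  )
}

#' Canonical clonotype key string
#'
#' `"TRAV..:CDR3a|TRBV..:CDR3b"`; a missing chain (any-defined universe) is
#' rendered as `"."`.
#'
#' @param df Data frame with `alpha_v`, `alpha_cdr3`, `beta_v`, `beta_cdr3`.
#' @return Character vector of canonical key strings.
#' @export
clonotype_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  paste0(df$alpha_v, ":", df$alpha_cdr3, "|", df$beta_v, ":", df$beta_cdr3)
}

#' Per-cell clonotype assignments
#'
#' One row per filtered cell with its chain fields and canonical clonotype
#' key; the join table used to link TCR identity to transcriptome cells.
#'
#' @param cells A filtered `cell_chains` object.
#' @return `data.frame` with `barcode`, chain fields, and `key`.
#' @export
cell_clonotypes <- function(cells) {
  ck <- cell_keys(cells)
  ck$key <- clonotype_key(ck)
  ck
}

#' Build a per-sample clonotype frequency table
#'
#' Counts cells per clonotype key over the filtered cell population and
#' derives frequencies; the universe (denominator) is the population that
#' passed the same filter.
#'
#' @param cells A filtered `cell_chains` object.
#' @param sample_label Label stored on the table (e.g. `"unstimulated"`).
#' @return Object of class `clonotype_table`: a `data.frame` with chain
#'   fields, `key`, `cell_count`, `frequency`; attributes `sample_label` and
#'   `total_cells`.
#' @export
build_clonotype_table <- function(cells, sample_label) {
  ck <- cell_clonotypes(cells)
  if (nrow(ck) == 0L) stop("empty repertoire", call. = FALSE)
  first <- ck[!duplicated(ck$key), c("key", "alpha_cdr3", "alpha_v",
                                     "alpha_j", "beta_cdr3", "beta_v",
                                     "beta_j"), drop = FALSE]
  cnt <- table(ck$key)
  agg <- first
  agg$cell_count <- as.integer(cnt[agg$key])
  total <- nrow(ck)
  agg$frequency <- agg$cell_count / total
  agg <- agg[order(-agg$cell_count, agg$key), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("clonotype_table", "data.frame"),
            sample_label = sample_label, total_cells = total)
}

#' @export
print.clonotype_table <- function(x, n = 6L, ...) {
  cat(sprintf("clonotype_table '%s': %d clonotypes over %d cells\n",
              attr(x, "sample_label"), nrow(x), attr(x, "total_cells")))
  print(head(as.data.frame(x)[, c("key", "cell_count", "frequency")], n))
  invisible(x)
}

#' Write / read a clonotype table as TSV
#'
#' @param table A `clonotype_table`.
#' @param path Output TSV path.
#' @return `write_clonotype_table` invisibly returns `path`;
#'   `read_clonotype_table` returns the reconstructed `clonotype_table`.
#' @export
write_clonotype_table <- function(table, path) {
  df <- as.data.frame(table)
  df$sample_label <- attr(table, "sample_label")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clonotype_table
#' @export
read_clonotype_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  lab <- unique(df$sample_label)
  df$sample_label <- NULL
  total <- sum(df$cell_count)
  df$frequency <- df$cell_count / total
  structure(df, class = c("clonotype_table", "data.frame"),
            sample_label = lab, total_cells = total)
}

#' Match known TCRs against a clonotype table
#'
#' Known receptors are identified by their CDR3 regions: exact string match
#' on the alpha/beta CDR3 amino-acid pair (default), optionally also on V/J
#' gene names. One known name may match several keys (convergent V/J use);
#' all are returned.
#'
#' @param table A `clonotype_table`.
#' @param known `data.frame` with columns `name`, `alpha_cdr3`, `beta_cdr3`
#'   and, for the stricter mode, `alpha_v`, `alpha_j`, `beta_v`, `beta_j`.
#' @param mode `"cdr3_pair"` (default) or `"cdr3_pair_plus_vj"`.
#' @return Named list: for each known name, the character vector of matching
#'   canonical keys (possibly empty).
#' @export
match_known <- function(table, known, mode = c("cdr3_pair",
                                               "cdr3_pair_plus_vj")) {
  mode <- match.arg(mode)
  if (anyDuplicated(known$name))
    stop("duplicate names in known-TCR list", call. = FALSE)
  df <- as.data.frame(table)
  out <- lapply(seq_len(nrow(known)), function(i) {
    hit <- df$alpha_cdr3 == known$alpha_cdr3[i] &
      df$beta_cdr3 == known$beta_cdr3[i]
    if (mode == "cdr3_pair_plus_vj") {
      hit <- hit & df$alpha_v == known$alpha_v[i] &
        df$alpha_j == known$alpha_j[i] &
        df$beta_v == known$beta_v[i] & df$beta_j == known$beta_j[i]
    }
    df$key[hit]
  })
  names(out) <- known$name
  out
}
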