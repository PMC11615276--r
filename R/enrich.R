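#' Compare clonotype frequencies before and after restimulation
#'
#' For the union of clonotype keys in the two tables, computes raw pre/post
#' frequencies and a pseudocount-smoothed fold change:
#' \deqn{FC = \frac{(c_{post}+q)/(t_{post}+q)}{(c_{pre}+q)/(t_{pre}+q)}}
#' with pseudocount \eqn{q} (default 1 cell) added to counts and totals, so
#' clonotypes absent before stimulation remain rankable. Frequency columns
#' are raw (no pseudocount).
#'
#' @param pre,post `clonotype_table`s built with the same filter mode.
#' @param pseudocount Nonnegative real added to counts and totals (default 1).
#' @return `data.frame` of class `enrichment_records`: chain fields, `key`,
#'   `count_pre`, `count_post`, `freq_pre`, `freq_post`, `fold_change`.
#' @export
compare_frequencies <- function(pre, post, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  t_pre <- attr(pre, "total_cells")
  t_post <- attr(post, "total_cells")
  if (is.null(t_pre) || t_pre == 0 || is.null(t_post) || t_post == 0)
    stop("both tables must contain cells", call. = FALSE)

  a <- as.data.frame(pre)
  b <- as.data.frame(post)
  chain_cols <- c("alpha_cdr3", "alpha_v", "alpha_j",
                  "beta_cdr3", "beta_v", "beta_j")
  keys <- union(a$key, b$key)
  ia <- match(keys, a$key)
  ib <- match(keys, b$key)
  src <- ifelse(is.na(ia), "b", "a")
  chains <- a[ifelse(is.na(ia), 1L, ia), chain_cols, drop = FALSE]
  chains[src == "b", ] <- b[ib[src == "b"], chain_cols]

  count_pre <- ifelse(is.na(ia), 0L, a$cell_count[ia])
  count_post <- ifelse(is.na(ib), 0L, b$cell_count[ib])
  fc <- ((count_post + pseudocount) / (t_post + pseudocount)) /
    ((count_pre + pseudocount) / (t_pre + pseudocount))

  out <- cbind(data.frame(key = keys, stringsAsFactors = FALSE), chains,
               data.frame(count_pre = count_pre, count_post = count_post,
                          freq_pre = count_pre / t_pre,
                          freq_post = count_post / t_post,
                          fold_change = fc))
  rownames(out) <- NULL
  structure(out, class = c("enrichment_records", "data.frame"),
            total_pre = t_pre, total_post = t_post,
            pseudocount = pseudocount)
}

#' Rank candidate neoantigen-specific TCRs
#'
#' Flags previously identified (known) clonotypes and, among the remaining
#' records, ranks by the two selection metrics: descending fold change
#' (`rank_fc`) and descending absolute post-stimulation frequency
#' (`rank_abs`). Ties are broken by descending post count, then by the
#' canonical key string. The candidate selection is the union of the top
#' `top_k` clonotypes under each metric; known clonotypes never enter the
#' candidate set but stay in the record list with `is_known = TRUE`.
#'
#' @param records Result of [compare_frequencies()].
#' @param known Named list of matched keys from [match_known()] (may be
#'   empty).
#' @param top_k Candidates taken per metric (default 2).
#' @return Object of class `candidate_ranking`: the records with `is_known`,
#'   `known_name`, `rank_fc`, `rank_abs` (NA for known), ordered by
#'   `rank_fc`; attribute `selection` holds the selected candidate keys.
#' @export
rank_candidates <- function(records, known = list(), top_k = 2L) {
  if (!is.numeric(top_k) || top_k < 1)
    stop("top_k must be a positive integer", call. = FALSE)
  df <- as.data.frame(records)
  df$is_known <- FALSE
  df$known_name <- NA_character_
  for (nm in names(known)) {
    hit <- df$key %in% known[[nm]]
    df$is_known[hit] <- TRUE
    df$known_name[hit] <- nm
  }

  cand <- which(!df$is_known)
  tie_order <- function(metric) {
    cand[order(-metric[cand], -df$count_post[cand], df$key[cand])]
  }
  ord_fc <- tie_order(df$fold_change)
  ord_abs <- tie_order(df$freq_post)
  df$rank_fc <- df$rank_abs <- NA_integer_
  df$rank_fc[ord_fc] <- seq_along(ord_fc)
  df$rank_abs[ord_abs] <- seq_along(ord_abs)

  k <- min(as.integer(top_k), length(cand))
  selection <- union(df$key[ord_fc[seq_len(k)]], df$key[ord_abs[seq_len(k)]])

  df <- df[order(ifelse(is.na(df$rank_fc), Inf, df$rank_fc), df$key), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("candidate_ranking", "data.frame"),
            selection = selection, top_k = as.integer(top_k),
            total_pre = attr(records, "total_pre"),
            total_post = attr(records, "total_post"),
            pseudocount = attr(records, "pseudocount"))
}

#' @export
print.candidate_ranking <- function(x, n = 8L, ...) {
  cat(sprintf("candidate_ranking: %d clonotypes (%d known), top-%d selection: %d key(s)\n",
              nrow(x), sum(x$is_known), attr(x, "top_k"),
              length(attr(x, "selection"))))
  cols <- c("key", "count_pre", "count_post", "fold_change",
            "rank_fc", "rank_abs", "is_known")
  print(head(as.data.frame(x)[, cols], n))
  invisible(x)
}

#' Write / read an enrichment report as TSV
#'
#' Rows are ordered by `rank_fc` then key (known clonotypes last); all
#' record fields are written.
#'
#' @param ranking A `candidate_ranking`.
#' @param path Output TSV path.
#' @return `write_enrichment_report` invisibly returns `path`;
#'   `read_enrichment_report` returns the table as a `data.frame`.
#' @export
write_enrichment_report <- function(ranking, path) {
  df <- as.data.frame(ranking)
  ok <- tryCatch({
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop(sprintf("cannot write enrichment report to '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' @rdname write_enrichment_report
#' @export
read_enrichment_report <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
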