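#' Cosine similarity matrix between two embedding matrices
#'
#' For a query matrix (`n x L`) and a candidate matrix (`m x L`), both
#' row-normalized, entry `(i, j)` is the inner product of query slice `i`
#' and candidate slice `j`, i.e. their cosine similarity.
#'
#' @param m_q,m_w Row-normalized numeric matrices with the same number of
#'   columns.
#' @return An `n x m` numeric matrix.
#' @export
similarity_matrix <- function(m_q, m_w) {
  if (!is.matrix(m_q) || !is.matrix(m_w))
    stop("both arguments must be matrices", call. = FALSE)
  if (ncol(m_q) != ncol(m_w))
    stop("embedding dimensions differ: ", ncol(m_q), " vs ", ncol(m_w),
         call. = FALSE)
  tcrossprod(m_q, m_w)
}

#' Late-interaction rank score of a candidate volume
#'
#' The ColBERT-style score: for each query slice take the maximum cosine
#' similarity over all candidate slices (row-wise max pooling), then sum
#' over query slices.  The score is bounded above by the number of query
#' slices and attains that bound exactly on a duplicate of the query.
#'
#' @param sim A [similarity_matrix()] (`n x m`, non-empty).
#' @return Numeric scalar.
#' @export
cmir_rank_score <- function(sim) {
  if (!is.matrix(sim) || nrow(sim) < 1L || ncol(sim) < 1L)
    stop("similarity matrix must be non-empty", call. = FALSE)
  # row maxima via max.col (ties resolved to the first, value identical)
  j <- max.col(sim, ties.method = "first")
  sum(sim[cbind(seq_len(nrow(sim)), j)])
}

#' Re-rank candidate volumes by late interaction (C-MIR)
#'
#' Recomputes the relevance of each first-stage candidate using the full
#' embedding matrices of the query and the candidate (not just the slices
#' that produced hits) and reorders the top `m_top` candidates by descending
#' rank score.  Membership of the list is unchanged: re-ranking only
#' permutes.  Ties preserve the incoming first-stage order (stable sort).
#'
#' @param query A [volume_record()].
#' @param candidates A ranked list from [retrieve_top_volumes()].
#' @param x The [cohort()] holding the candidate volumes.
#' @param m_top Number of leading candidates re-ranked (default 20).
#' @return A ranked list tagged `method = "cmir"`, scores = rank scores.
#' @export
cmir_rerank <- function(query, candidates, x, m_top = 20L) {
  stopifnot(inherits(query, "volume_record"), inherits(x, "volume_cohort"))
  ids <- head(candidates$volume_id, as.integer(m_top))
  missing_ids <- setdiff(ids, names(x$records))
  if (length(missing_ids))
    stop("candidate volumes not in cohort: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  if (!length(ids))
    return(ranked_list(character(), numeric(), "cmir", query$volume_id))
  rs <- vapply(ids, function(id) {
    cmir_rank_score(similarity_matrix(query$matrix, x$records[[id]]$matrix))
  }, numeric(1))
  ord <- order(-rs, method = "radix")  # stable: ties keep incoming order
  ranked_list(ids[ord], unname(rs[ord]), "cmir", query$volume_id)
}

#' Reciprocal rank fusion scores from three ranked lists
#'
#' Fuses the Count-base, Max-Score and Sum-Sim top-k lists of one query:
#' each volume receives `sum over lists of 1 / (k_smooth + rank)` with
#' 1-based ranks; a list not containing the volume contributes zero.  The
#' result depends only on ranks, never on the underlying scores.
#'
#' @param lists A list of exactly 3 ranked lists for the same query.
#' @param k_smooth Smoothing constant added to the rank (default 60).
#' @return Named numeric vector of RRF scores over the union of members.
#' @export
rrf_scores <- function(lists, k_smooth = 60) {
  if (!is.list(lists) || length(lists) != 3L)
    stop("RRF fuses exactly 3 ranked lists (count, max_score, sum_sim); got ",
         length(lists), call. = FALSE)
  ids <- sort(unique(unlist(lapply(lists, function(l) l$volume_id))))
  if (!length(ids)) return(setNames(numeric(0), character(0)))
  out <- setNames(numeric(length(ids)), ids)
  for (l in lists) {
    rank_in <- match(ids, l$volume_id)  # NA when absent -> zero summand
    got <- !is.na(rank_in)
    out[got] <- out[got] + 1 / (k_smooth + rank_in[got])
  }
  out
}

#' Re-rank by reciprocal rank fusion
#'
#' Orders the union of the three lists' members by descending RRF score;
#' ties break by ascending volume id for determinism.
#'
#' @inheritParams rrf_scores
#' @return A ranked list tagged `method = "rrf"`.
#' @export
rrf_rerank <- function(lists, k_smooth = 60) {
  sc <- rrf_scores(lists, k_smooth)
  qid <- attr(lists[[1L]], "query_id") %||% NA_character_
  ord <- order(-sc, names(sc), method = "radix")
  ranked_list(names(sc)[ord], unname(sc[ord]), "rrf", qid)
}
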