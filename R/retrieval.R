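#' Build the hit table for a query volume
#'
#' Runs one nearest-neighbour search per query slice and stacks the results:
#' the hit table records, for every query slice, the top `n_neighbors`
#' database slices with their cosine scores.  Slices of the query volume
#' itself are never reported (query/database splits are disjoint by
#' construction; when the query volume *is* indexed, e.g. in planted-copy
#' tests, its own slices are filtered out and the next-best hits returned
#' instead).
#'
#' @param query A [volume_record()].
#' @param index A [build_slice_index()] object.
#' @param n_neighbors Hits kept per query slice (default 20).
#' @return An object of class `"hit_table"`: a data frame with columns
#'   `query_slice`, `volume_id`, `slice_index`, `score`, with attributes
#'   `query_id` and `n_query_slices`.
#' @export
build_hit_table <- function(query, index, n_neighbors = 20L) {
  stopifnot(inherits(query, "volume_record"), inherits(index, "slice_index"))
  n_neighbors <- as.integer(n_neighbors)
  own <- sum(index$ref$volume_id == query$volume_id)
  rows <- lapply(seq_len(query$n_slices), function(i) {
    hits <- search_slices(index, query$matrix[i, ], n_neighbors + own)
    hits <- hits[hits$volume_id != query$volume_id, , drop = FALSE]
    hits <- head(hits, n_neighbors)
    if (!nrow(hits)) return(NULL)
    cbind(data.frame(query_slice = i), hits)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  ht <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_slice = integer(), volume_id = character(),
               slice_index = integer(), score = numeric(),
               stringsAsFactors = FALSE)
  rownames(ht) <- NULL
  structure(ht, class = c("hit_table", "data.frame"),
            query_id = query$volume_id, n_query_slices = query$n_slices)
}

# internal constructor for ranked lists: data frame (volume_id, score),
# already ordered, tagged with the producing method and the query id
ranked_list <- function(volume_id, score, method, query_id) {
  structure(data.frame(volume_id = volume_id, score = score,
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"),
            method = method, query_id = query_id)
}

# shared aggregation core: per-volume count / max / sum over all hit-table
# entries, ordered by the chosen statistic with the deterministic tie rule
# (higher summed similarity, then ascending volume id)
aggregate_hit_table <- function(ht, method) {
  stopifnot(inherits(ht, "hit_table"))
  if (!nrow(ht)) {
    return(ranked_list(character(), numeric(), method, attr(ht, "query_id")))
  }
  f <- factor(ht$volume_id)
  cnt <- as.vector(tapply(ht$score, f, length))
  mx <- as.vector(tapply(ht$score, f, max))
  sm <- as.vector(tapply(ht$score, f, sum))
  score <- switch(method, count = cnt, max_score = mx, sum_sim = sm)
  ids <- levels(f)
  ord <- order(-score, -sm, ids, method = "radix")
  ranked_list(ids[ord], score[ord], method, attr(ht, "query_id"))
}

#' Count-base aggregation of a hit table
#'
#' Scores each database volume by its total number of slice hits across all
#' query slices (multiple hits of one volume within a single query-slice row
#' all count) and ranks volumes by descending count.
#'
#' @param ht A [build_hit_table()] result.
#' @return A ranked list: data frame (`volume_id`, `score`) ordered by
#'   descending score, tagged with `method = "count"`.
#' @export
aggregate_count <- function(ht) aggregate_hit_table(ht, "count")

#' Max-Score aggregation of a hit table
#'
#' Scores each database volume by the maximum cosine similarity over all of
#' its hits.
#'
#' @inheritParams aggregate_count
#' @return A ranked list tagged with `method = "max_score"`.
#' @export
aggregate_max_score <- function(ht) aggregate_hit_table(ht, "max_score")

#' Sum-Sim aggregation of a hit table
#'
#' Scores each database volume by the sum of the cosine similarities of all
#' of its hits; repeated hits accumulate.
#'
#' @inheritParams aggregate_count
#' @return A ranked list tagged with `method = "sum_sim"`.
#' @export
aggregate_sum_sim <- function(ht) aggregate_hit_table(ht, "sum_sim")

#' First-stage volume retrieval from a hit table
#'
#' Applies the chosen aggregation and truncates to the top `k` volumes.
#'
#' @inheritParams aggregate_count
#' @param method One of `"count"`, `"max_score"`, `"sum_sim"`.
#' @param k Number of volumes returned (default 20, the candidate list
#'   length handed to re-ranking).
#' @return A ranked list of at most `k` volumes.
#' @export
retrieve_top_volumes <- function(ht, method = c("count", "max_score",
                                                "sum_sim"), k = 20L) {
  method <- match.arg(method)
  if (k < 0L) stop("k must be >= 0", call. = FALSE)
  rl <- aggregate_hit_table(ht, method)
  if (k == 0L) warning("k = 0 requested; returning an empty ranked list")
  out <- head(rl, as.integer(k))
  structure(out, class = class(rl), method = attr(rl, "method"),
            query_id = attr(rl, "query_id"))
}
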