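#' Build a slice-level similarity index over a cohort
#'
#' Indexes every (unmasked) slice of every selected volume under the
#' inner-product metric, which equals cosine similarity because rows are
#' unit-norm.  Two backends share one contract:
#'
#' * `"exact"` — full scan by dense matrix algebra; returns the true top-n
#'   neighbours and serves as the oracle for the approximate backend.
#' * `"hnsw"` — a hierarchical navigable small world graph built in
#'   compiled code; approximate but near-exact at the default parameters
#'   (graph degree 32, construction breadth 200, search breadth 128).
#'
#' @param x A [cohort()].
#' @param backend `"exact"` or `"hnsw"`.
#' @param volume_ids Volumes to index (default: all).  Used to restrict the
#'   index to the database side of a split.
#' @param slice_masks Optional named list `volume_id -> integer vector` of
#'   1-based slice indices to index (the segmentation-derived searchable
#'   slices); volumes absent from the list contribute all slices, volumes
#'   with an empty mask contribute none.
#' @param params Named list overriding HNSW parameters `m`,
#'   `ef_construction`, `ef_search`, `seed`.
#' @return An object of class `"slice_index"`; `$entries` is the number of
#'   indexed slices and `$ref` maps internal row ids to
#'   (`volume_id`, `slice_index`) pairs.
#' @export
build_slice_index <- function(x, backend = c("exact", "hnsw"),
                              volume_ids = NULL, slice_masks = NULL,
                              params = list()) {
  stopifnot(inherits(x, "volume_cohort"))
  backend <- match.arg(backend)
  ids <- volume_ids %||% names(x$records)
  missing_ids <- setdiff(ids, names(x$records))
  if (length(missing_ids))
    stop("volume_ids not in cohort: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  rows <- vector("list", length(ids))
  refs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    r <- x$records[[ids[[i]]]]
    keep <- seq_len(r$n_slices)
    if (!is.null(slice_masks) && ids[[i]] %in% names(slice_masks))
      keep <- sort(unique(as.integer(slice_masks[[ids[[i]]]])))
    if (length(keep) && (min(keep) < 1L || max(keep) > r$n_slices))
      stop("slice mask for '", ids[[i]], "' outside 1..n_slices",
           call. = FALSE)
    if (!length(keep)) next
    rows[[i]] <- r$matrix[keep, , drop = FALSE]
    refs[[i]] <- data.frame(volume_id = ids[[i]], slice_index = keep,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  refs <- refs[!vapply(refs, is.null, logical(1))]
  if (!length(rows))
    stop("no slices to index (empty cohort selection)", call. = FALSE)
  emb <- do.call(rbind, rows)
  ref <- do.call(rbind, refs)
  rownames(ref) <- NULL
  if (!rows_unit_norm(emb))
    stop("indexed slices must be unit-norm", call. = FALSE)
  p <- list(m = 32L, ef_construction = 200L, ef_search = 128L, seed = 1L)
  p[names(params)] <- params
  ann <- NULL
  if (backend == "hnsw")
    ann <- hnsw_build(emb, as.integer(p$m), as.integer(p$ef_construction),
                      as.integer(p$seed))
  structure(list(backend = backend, embeddings = emb, ref = ref,
                 entries = nrow(emb), dim = ncol(emb),
                 params = p, ann = ann),
            class = "slice_index")
}

#' @export
print.slice_index <- function(x, ...) {
  cat(sprintf("<slice_index> backend=%s  %d slices from %d volumes, L=%d\n",
              x$backend, x$entries, length(unique(x$ref$volume_id)), x$dim))
  invisible(x)
}

#' Search the slice index for the nearest database slices
#'
#' Returns the `n_neighbors` most cosine-similar indexed slices for one
#' unit-norm query embedding, scores non-increasing.  Exact ties are broken
#' by ascending (`volume_id`, `slice_index`) so results are deterministic.
#' The exact backend returns the true top-n; the HNSW backend is best-effort
#' with recall near 1 at default parameters.
#'
#' @param index A [build_slice_index()] object.
#' @param q Unit-norm numeric vector of length `index$dim`.
#' @param n_neighbors Number of hits requested (default 20, the number of
#'   slice hits the retrieval stage keeps per query slice).
#' @return Data frame with columns `volume_id`, `slice_index`, `score`.
#' @export
search_slices <- function(index, q, n_neighbors = 20L) {
  stopifnot(inherits(index, "slice_index"))
  if (length(q) != index$dim)
    stop("query has length ", length(q), ", index dimension is ",
         index$dim, call. = FALSE)
  if (!is.numeric(n_neighbors) || n_neighbors < 1L)
    stop("n_neighbors must be >= 1", call. = FALSE)
  k <- min(as.integer(n_neighbors), index$entries)
  if (index$backend == "exact") {
    scores <- as.vector(index$embeddings %*% q)
    ord <- order(-scores, index$ref$volume_id, index$ref$slice_index,
                 method = "radix")
    take <- ord[seq_len(k)]
    data.frame(volume_id = index$ref$volume_id[take],
               slice_index = index$ref$slice_index[take],
               score = scores[take], stringsAsFactors = FALSE)
  } else {
    res <- hnsw_query(index$ann, as.numeric(q), k,
                      as.integer(index$params$ef_search))
    take <- res$idx
    # enforce the deterministic tie rule on the returned set
    ord <- order(-res$score, index$ref$volume_id[take],
                 index$ref$slice_index[take], method = "radix")
    take <- take[ord]
    data.frame(volume_id = index$ref$volume_id[take],
               slice_index = index$ref$slice_index[take],
               score = res$score[ord], stringsAsFactors = FALSE)
  }
}
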