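#' Normalize a slice embedding to unit length
#'
#' Divides a raw embedding vector by its Euclidean norm so that inner
#' products between stored embeddings equal cosine similarities.  Zero and
#' non-finite vectors are rejected: they carry no direction and a database
#' built on them would silently corrupt every downstream similarity.
#'
#' @param v Numeric vector (length >= 1), the raw embedding of one slice.
#' @return Numeric vector of the same length with unit L2 norm.
#' @examples
#' normalize_embedding(c(3, 4))   # (0.6, 0.8)
#' @export
normalize_embedding <- function(v) {
  if (!is.numeric(v) || length(v) < 1L)
    stop("embedding must be a non-empty numeric vector", call. = FALSE)
  if (!all(is.finite(v)))
    stop("embedding contains non-finite entries", call. = FALSE)
  nrm <- sqrt(sum(v * v))
  if (nrm == 0)
    stop("cannot normalize an all-zero embedding", call. = FALSE)
  v / nrm
}

#' Build a row-normalized embedding matrix from a list of slice embeddings
#'
#' Stacks the per-slice embeddings of one volume into an `n x L` matrix with
#' every row normalized to unit length, preserving slice order.  This matrix
#' is the volume's multi-vector representation used both for indexing and for
#' late-interaction re-ranking.
#'
#' @param slices List of numeric vectors, all of the same length `L`.
#' @return Numeric matrix, `length(slices)` rows, each of unit L2 norm.
#' @examples
#' build_embedding_matrix(list(c(3, 4), c(0, 2)))
#' @export
build_embedding_matrix <- function(slices) {
  if (!is.list(slices) || length(slices) < 1L)
    stop("need a non-empty list of slice embeddings", call. = FALSE)
  lens <- lengths(slices)
  if (length(unique(lens)) != 1L)
    stop("slice embeddings have mixed lengths: ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  m <- do.call(rbind, lapply(slices, normalize_embedding))
  dimnames(m) <- NULL
  m
}

# internal: TRUE if all rows of m have unit L2 norm within tol
rows_unit_norm <- function(m, tol = 1e-6) {
  all(abs(sqrt(rowSums(m * m)) - 1) <= tol)
}

#' Stage levels recognised for tumor-bearing volumes
#' @export
STAGES <- c("S1", "S2", "S3", "S4")

#' Construct a volume record
#'
#' A volume record bundles a volume's metadata with its row-normalized
#' embedding matrix.  `stage` must be one of `"S1".."S4"` when
#' `tumor_flag` is `TRUE` and `"NONE"` when it is `FALSE`; the negative
#' class is modelled as its own stage level so staging relevance covers
#' negative queries uniformly.
#'
#' @param volume_id Character scalar, unique within a cohort.
#' @param organ Character scalar, the organ/task label.
#' @param tumor_flag Logical scalar, whether the volume carries a tumor.
#' @param stage `"S1".."S4"` for positives, `"NONE"` for negatives.
#' @param matrix Numeric `n x L` matrix with unit-norm rows (see
#'   [build_embedding_matrix()]).
#' @param organ_presence Optional named list mapping organ labels to 1-based
#'   slice indices on which that organ appears (the stand-in for
#'   segmentation-derived slice selection).
#' @return An object of class `"volume_record"`.
#' @export
volume_record <- function(volume_id, organ, tumor_flag, stage, matrix,
                          organ_presence = NULL) {
  stopifnot(is.character(volume_id), length(volume_id) == 1L, nzchar(volume_id),
            is.character(organ), length(organ) == 1L,
            is.logical(tumor_flag), length(tumor_flag) == 1L)
  if (!is.matrix(matrix) || !is.numeric(matrix) || nrow(matrix) < 1L)
    stop("'matrix' must be a numeric matrix with >= 1 row", call. = FALSE)
  if (!all(is.finite(matrix)))
    stop("embedding matrix of '", volume_id, "' has non-finite entries",
         call. = FALSE)
  if (!rows_unit_norm(matrix))
    stop("embedding matrix of '", volume_id,
         "' has rows that are not unit-norm; normalize at ingest",
         call. = FALSE)
  if (tumor_flag) {
    if (!stage %in% STAGES)
      stop("tumor-positive volume '", volume_id,
           "' needs stage in S1..S4, got '", stage, "'", call. = FALSE)
  } else if (!identical(stage, "NONE")) {
    stop("tumor-negative volume '", volume_id, "' must have stage 'NONE'",
         call. = FALSE)
  }
  n <- nrow(matrix)
  if (!is.null(organ_presence)) {
    if (is.null(names(organ_presence)) || any(!nzchar(names(organ_presence))))
      stop("organ_presence must be a named list", call. = FALSE)
    organ_presence <- lapply(organ_presence, function(ix) {
      ix <- as.integer(ix)
      if (any(ix < 1L | ix > n))
        stop("organ_presence indices of '", volume_id,
             "' outside 1..n_slices", call. = FALSE)
      sort(unique(ix))
    })
  }
  structure(
    list(volume_id = volume_id, organ = organ,
         tumor_flag = tumor_flag, stage = stage,
         n_slices = n, matrix = matrix,
         organ_presence = organ_presence),
    class = "volume_record")
}

#' @export
print.volume_record <- function(x, ...) {
  cat(sprintf("<volume_record> %s  organ=%s  tumor=%s  stage=%s  %d x %d\n",
              x$volume_id, x$organ, x$tumor_flag, x$stage,
              x$n_slices, ncol(x$matrix)))
  invisible(x)
}

#' Construct a cohort of volume records
#'
#' A cohort is the unit stored, indexed and split: a list of volume records
#' sharing one embedding dimension, plus free-form provenance metadata
#' (generator configuration, source description, ...).
#'
#' @param records List of [volume_record()] objects with unique ids.
#' @param provenance Named list of metadata carried through persistence.
#' @return An object of class `"volume_cohort"` with elements `records`
#'   (named by volume id), `embedding_dim` and `provenance`.
#' @export
cohort <- function(records, provenance = list()) {
  if (!is.list(records) || length(records) < 1L)
    stop("a cohort needs at least one volume record", call. = FALSE)
  ok <- vapply(records, inherits, logical(1), "volume_record")
  if (!all(ok)) stop("all records must be volume_record objects", call. = FALSE)
  ids <- vapply(records, `[[`, character(1), "volume_id")
  if (anyDuplicated(ids))
    stop("duplicate volume_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  dims <- vapply(records, function(r) ncol(r$matrix), integer(1))
  if (length(unique(dims)) != 1L)
    stop("records disagree on embedding dimension: ",
         paste(unique(dims), collapse = ", "), call. = FALSE)
  names(records) <- ids
  structure(list(records = records,
                 embedding_dim = dims[[1L]],
                 provenance = provenance),
            class = "volume_cohort")
}

#' @export
print.volume_cohort <- function(x, ...) {
  ns <- vapply(x$records, `[[`, integer(1), "n_slices")
  cat(sprintf("<volume_cohort> %d volumes, %d slices, L=%d\n",
              length(x$records), sum(ns), x$embedding_dim))
  invisible(x)
}

#' Cohort metadata as a data frame
#'
#' One row per volume: id, organ, tumor flag, stage and slice count.
#' Convenience view used by the split and evaluation machinery.
#'
#' @param x A [cohort()].
#' @return A data frame with columns `volume_id`, `organ`, `tumor_flag`,
#'   `stage`, `n_slices`.
#' @export
cohort_metadata <- function(x) {
  stopifnot(inherits(x, "volume_cohort"))
  data.frame(
    volume_id = vapply(x$records, `[[`, character(1), "volume_id"),
    organ = vapply(x$records, `[[`, character(1), "organ"),
    tumor_flag = vapply(x$records, `[[`, logical(1), "tumor_flag"),
    stage = vapply(x$records, `[[`, character(1), "stage"),
    n_slices = vapply(x$records, `[[`, integer(1), "n_slices"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Save a cohort to a single JSON file
#'
#' The store is one self-describing JSON document: a `manifest` object
#' (embedding dimension, volume count, provenance) and a `volumes` array,
#' one object per volume holding the metadata fields and the embedding
#' matrix as a nested array of decimal strings in `%.17g` format — 17
#' significant digits uniquely determine an IEEE double, so
#' `load_cohort(save_cohort(x))` round-trips matrices bit-exactly.
#'
#' @param x A [cohort()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @seealso [load_cohort()]
#' @export
save_cohort <- function(x, path) {
  stopifnot(inherits(x, "volume_cohort"))
  vols <- lapply(unname(x$records), function(r) {
    v <- list(volume_id = jsonlite::unbox(r$volume_id),
              organ = jsonlite::unbox(r$organ),
              tumor_flag = jsonlite::unbox(r$tumor_flag),
              stage = jsonlite::unbox(r$stage),
              n_slices = jsonlite::unbox(r$n_slices),
              embeddings = matrix(sprintf("%.17g", r$matrix),
                                  nrow(r$matrix)))
    if (!is.null(r$organ_presence)) v$organ_presence <- r$organ_presence
    v
  })
  doc <- list(
    manifest = list(format = jsonlite::unbox("volcbir-cohort"),
                    version = jsonlite::unbox(1L),
                    embedding_dim = jsonlite::unbox(x$embedding_dim),
                    n_volumes = jsonlite::unbox(length(x$records)),
                    provenance = x$provenance),
    volumes = vols)
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = FALSE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a cohort from a JSON store
#'
#' Validates the manifest, the per-volume matrix shapes against the
#' cohort-level embedding dimension, and volume-id uniqueness; a malformed
#' file fails with an error naming the offending volume.
#'
#' @param path File written by [save_cohort()].
#' @return A [cohort()].
#' @export
load_cohort <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                                     simplifyMatrix = TRUE),
                  error = function(e)
                    stop("cannot parse cohort store '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  man <- doc$manifest
  if (is.null(man) || !identical(man$format, "volcbir-cohort"))
    stop("'", path, "' is not a volcbir cohort store", call. = FALSE)
  L <- as.integer(man$embedding_dim)
  recs <- lapply(doc$volumes, function(v) {
    id <- v$volume_id %||% "<missing id>"
    m <- v$embeddings
    if (is.list(m)) m <- do.call(rbind, m)
    if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
    if (is.character(m)) m <- matrix(as.numeric(m), nrow(m))
    storage.mode(m) <- "double"
    if (ncol(m) != L)
      stop("volume '", id, "': matrix has ", ncol(m),
           " columns, manifest says embedding_dim=", L, call. = FALSE)
    if (!is.null(v$n_slices) && nrow(m) != v$n_slices)
      stop("volume '", id, "': n_slices=", v$n_slices,
           " but matrix has ", nrow(m), " rows", call. = FALSE)
    op <- v$organ_presence
    if (!is.null(op)) op <- lapply(op, as.integer)
    volume_record(id, v$organ, v$tumor_flag, v$stage, m, op)
  })
  prov <- man$provenance %||% list()
  out <- cohort(recs, provenance = prov)
  if (length(out$records) != man$n_volumes)
    stop("manifest says ", man$n_volumes, " volumes, found ",
         length(out$records), call. = FALSE)
  out
}
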