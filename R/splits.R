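#' Specify a query/database split configuration
#'
#' Three configurations mirror the evaluation settings:
#' * `"organ_specific_seg"` — queries for one organ; the database search
#'   space is restricted to the slices on which that organ appears
#'   (segmentation-derived slice masks);
#' * `"organ_specific_noseg"` — same query set, all database slices
#'   searchable;
#' * `"organ_agnostic"` — queries pooled over all organs, one unified
#'   database with all slices searchable.
#'
#' @param config One of the three configuration names.
#' @param organ Target organ label for the organ-specific configurations;
#'   `"ALL"` for organ-agnostic.
#' @param p_query Fraction of tumor-positive volumes sampled per stage into
#'   the query set (default 0.25).
#' @param seed Integer seed controlling the draw.
#' @return An object of class `"split_spec"`.
#' @export
split_spec <- function(config = c("organ_specific_seg", "organ_specific_noseg",
                                  "organ_agnostic"),
                       organ = "ALL", p_query = 0.25, seed = 1L) {
  config <- match.arg(config)
  if (!(p_query > 0 && p_query < 1))
    stop("p_query must be in (0, 1)", call. = FALSE)
  if (config != "organ_agnostic" && identical(organ, "ALL"))
    stop("organ-specific configurations need a target organ", call. = FALSE)
  structure(list(config = config, organ = organ, p_query = p_query,
                 seed = as.integer(seed)),
            class = "split_spec")
}

round_half_up <- function(x) floor(x + 0.5)

# organs on which a volume is usable as a negative for `organ`: its own
# label, or any organ its presence map covers
negative_eligible <- function(x, meta, organ) {
  covers <- vapply(x$records[meta$volume_id], function(r) {
    identical(r$organ, organ) ||
      (!is.null(r$organ_presence) && organ %in% names(r$organ_presence))
  }, logical(1))
  !meta$tumor_flag & covers
}

# stage-stratified positive draw + matched negatives for one organ;
# returns character vectors of ids.  Assumes the RNG is already seeded.
draw_organ_queries <- function(x, meta, organ, p_query, exclude = character()) {
  pos_pool <- meta[meta$organ == organ & meta$tumor_flag &
                     !(meta$volume_id %in% exclude), , drop = FALSE]
  if (!nrow(pos_pool))
    stop("no tumor-positive volumes for organ '", organ, "'", call. = FALSE)
  pos <- character(0)
  for (s in STAGES) {
    ids <- pos_pool$volume_id[pos_pool$stage == s]
    if (!length(ids)) next
    n_take <- max(1L, round_half_up(p_query * length(ids)))
    n_take <- min(n_take, length(ids))
    pos <- c(pos, sample(ids, n_take))
  }
  neg_ok <- negative_eligible(x, meta, organ) &
    !(meta$volume_id %in% c(exclude, pos))
  neg_pool <- meta$volume_id[neg_ok]
  if (length(neg_pool) < length(pos))
    stop("insufficient negatives for organ '", organ, "': need ",
         length(pos), ", have ", length(neg_pool), call. = FALSE)
  neg <- sample(neg_pool, length(pos))
  list(positive = pos, negative = neg)
}

#' Sample a stage-stratified query set and its complementary database
#'
#' For an organ-specific specification: per tumor stage, `p_query` of that
#' organ's positive volumes are drawn (round half up, at least one when the
#' stratum is non-empty) and an equal number of tumor-free volumes covering
#' the same organ are drawn as matched negatives.  All remaining volumes
#' form the database.  Splits are at the volume level, so the query and
#' database id sets are disjoint; draws are independent across seeds (two
#' seeds may yield overlapping query sets) but without replacement within a
#' seed.
#'
#' For `"organ_agnostic"` this dispatches to [build_agnostic_split()].
#'
#' @param x A [cohort()].
#' @param spec A [split_spec()].
#' @return An object of class `"volume_split"`: `query_ids`,
#'   `database_ids`, `slice_masks` (filled by [apply_database_config()]),
#'   plus the spec fields.
#' @export
sample_query_set <- function(x, spec) {
  stopifnot(inherits(x, "volume_cohort"), inherits(spec, "split_spec"))
  if (spec$config == "organ_agnostic") return(build_agnostic_split(x, spec))
  meta <- cohort_metadata(x)
  qs <- with_seed(spec$seed, draw_organ_queries(x, meta, spec$organ,
                                                spec$p_query))
  query_ids <- c(qs$positive, qs$negative)
  split <- structure(
    list(config = spec$config, organ = spec$organ, seed = spec$seed,
         query_ids = query_ids,
         database_ids = setdiff(meta$volume_id, query_ids),
         slice_masks = NULL),
    class = "volume_split")
  apply_database_config(split, x, spec)
}

#' Apply the database search-space configuration to a split
#'
#' Sets the per-database-volume searchable slice masks: under
#' `"organ_specific_seg"` a database volume exposes only the slices on
#' which the target organ appears (volumes without any such slice expose
#' none); under the no-segmentation and organ-agnostic configurations every
#' slice is searchable.  Query volumes are untouched — the query set is
#' identical across database configurations for the same seed.
#'
#' @param split A `"volume_split"`.
#' @param x The [cohort()].
#' @param spec The [split_spec()].
#' @return The split with `slice_masks` filled (`NULL` means all slices).
#' @export
apply_database_config <- function(split, x, spec) {
  stopifnot(inherits(split, "volume_split"), inherits(x, "volume_cohort"))
  if (spec$config != "organ_specific_seg") {
    split$slice_masks <- NULL
    return(split)
  }
  masks <- lapply(x$records[split$database_ids], function(r) {
    if (is.null(r$organ_presence))
      stop("organ_specific_seg needs organ_presence on database volume '",
           r$volume_id, "'", call. = FALSE)
    as.integer(r$organ_presence[[spec$organ]] %||% integer(0))
  })
  names(masks) <- split$database_ids
  split$slice_masks <- masks
  split
}

#' Build an organ-agnostic split
#'
#' Repeats the stage-stratified positive/negative draw for every organ in
#' the cohort, pools all queries, and pools every remaining volume into a
#' single unified database with all slices searchable.
#'
#' @param x A [cohort()] with at least one organ.
#' @param spec A [split_spec()] with `config = "organ_agnostic"`.
#' @return A `"volume_split"`.
#' @export
build_agnostic_split <- function(x, spec) {
  stopifnot(inherits(x, "volume_cohort"), inherits(spec, "split_spec"))
  meta <- cohort_metadata(x)
  organs <- sort(unique(meta$organ[meta$tumor_flag]))
  query_ids <- with_seed(spec$seed, {
    taken <- character(0)
    for (org in organs) {
      qs <- draw_organ_queries(x, meta, org, spec$p_query, exclude = taken)
      taken <- c(taken, qs$positive, qs$negative)
    }
    taken
  })
  structure(
    list(config = "organ_agnostic", organ = "ALL", seed = spec$seed,
         query_ids = query_ids,
         database_ids = setdiff(meta$volume_id, query_ids),
         slice_masks = NULL),
    class = "volume_split")
}

#' @export
print.volume_split <- function(x, ...) {
  cat(sprintf("<volume_split> %s organ=%s seed=%d  %d queries / %d database\n",
              x$config, x$organ, x$seed,
              length(x$query_ids), length(x$database_ids)))
  invisible(x)
}
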