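#' Configuration for the synthetic embedding-cohort generator
#'
#' Describes a cohort with planted organ/stage structure: every
#' (organ, class) pair — classes are the four tumor stages plus the
#' negative class — gets a unit prototype direction, and a volume's slices
#' are noisy, serially correlated draws around its class prototype.
#' Prototypes are nested: stages of one organ sit closer to each other than
#' to other organs, mirroring the real task where stage confusion within an
#' organ is harder than organ confusion.
#'
#' @param embedding_dim Embedding length `L` (default 64).
#' @param organs Organ labels (default the four tumor sites).
#' @param stages_per_organ Number of tumor stages per organ (default 4).
#' @param volumes_per_class Volumes per (organ, stage) class (default 6).
#' @param negatives_per_organ Tumor-free volumes per organ (default
#'   `2 * volumes_per_class`): negatives must outnumber the per-stage
#'   positive draw so matched-negative sampling is feasible, as in the real
#'   setting where an organ's negatives come from the other tasks.
#' @param slice_count_range Inclusive range of per-volume slice counts
#'   (default 20–60).
#' @param separation Class-separation scale `delta >= 0`: 0 collapses all
#'   prototypes onto one shared direction (classes indistinguishable);
#'   larger values spread organs apart by `delta` and stages within an
#'   organ by `stage_nesting * delta`.
#' @param stage_nesting Within-organ separation as a fraction of the
#'   between-organ separation (default 0.5).
#' @param within_volume_drift AR(1) coefficient `rho` in `[0, 1)` of the
#'   slice-to-slice deviation process (default 0.5).
#' @param noise Stationary deviation magnitude `sigma > 0`, the expected
#'   L2 norm of a slice's deviation from its prototype (default 1, chosen
#'   together with `separation` and `stage_nesting` so retrieval at the
#'   defaults is good but imperfect rather than saturated).
#' @param organ_span_fraction Fraction of a volume's slices annotated as
#'   carrying its organ (contiguous span, default 0.6).
#' @param background_outside_span If `TRUE`, slices outside the organ span
#'   are drawn around a volume-specific background direction instead of the
#'   class prototype, so only the organ span carries class signal.  Default
#'   `FALSE`: every slice carries the prototype and `organ_presence` is
#'   annotation only.
#' @param seed Integer seed; the same configuration generates a
#'   bit-identical cohort.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(embedding_dim = 64L,
                             organs = c("colon", "liver", "lung", "pancreas"),
                             stages_per_organ = 4L,
                             volumes_per_class = 6L,
                             negatives_per_organ = 2L * volumes_per_class,
                             slice_count_range = c(20L, 60L),
                             separation = 2,
                             stage_nesting = 0.35,
                             within_volume_drift = 0.5,
                             noise = 1,
                             organ_span_fraction = 0.6,
                             background_outside_span = FALSE,
                             seed = 1L) {
  stopifnot(embedding_dim >= 2L, length(organs) >= 1L,
            stages_per_organ >= 1L, stages_per_organ <= 4L,
            volumes_per_class >= 1L, negatives_per_organ >= 0L,
            length(slice_count_range) == 2L,
            slice_count_range[1L] >= 1L,
            slice_count_range[2L] >= slice_count_range[1L],
            separation >= 0, noise > 0,
            within_volume_drift >= 0, within_volume_drift < 1,
            organ_span_fraction > 0, organ_span_fraction <= 1)
  structure(list(embedding_dim = as.integer(embedding_dim),
                 organs = organs,
                 stages_per_organ = as.integer(stages_per_organ),
                 volumes_per_class = as.integer(volumes_per_class),
                 negatives_per_organ = as.integer(negatives_per_organ),
                 slice_count_range = as.integer(slice_count_range),
                 separation = separation,
                 stage_nesting = stage_nesting,
                 within_volume_drift = within_volume_drift,
                 noise = noise,
                 organ_span_fraction = organ_span_fraction,
                 background_outside_span = isTRUE(background_outside_span),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# random unit direction in R^L
runit <- function(L) normalize_embedding(rnorm(L))

# sample() that never falls into the 1:x scalar trap
resample <- function(x, n) x[sample.int(length(x), n)]

# AR(1) deviation process with stationary per-coordinate variance
# (noise^2 / L), so the deviation vector's expected norm is ~ noise
drift_path <- function(n, L, rho, noise) {
  sd0 <- noise / sqrt(L)
  d <- matrix(0, n, L)
  d[1L, ] <- rnorm(L, sd = sd0)
  if (n > 1L) {
    innov_sd <- sd0 * sqrt(1 - rho^2)
    for (t in 2L:n)
      d[t, ] <- rho * d[t - 1L, ] + rnorm(L, sd = innov_sd)
  }
  d
}

#' Generate a synthetic embedding cohort with planted structure
#'
#' For each organ and class (negative, S1..Sk) a prototype direction is
#' drawn as `normalize(u0 + delta * (organ_axis + nesting * class_dir))`
#' where `u0` is a global base direction shared by every class; at
#' `separation = 0` all prototypes coincide and classes are
#' indistinguishable in expectation.  Each volume draws a slice count
#' uniformly from the configured range and its slice `t` embedding is
#' `normalize(prototype + d_t)` with `d_t` an AR(1) deviation of
#' coefficient `within_volume_drift` and stationary magnitude `noise`.
#' A contiguous span covering `organ_span_fraction` of the slices is
#' recorded in `organ_presence` under the volume's organ label.
#'
#' @param config A [generator_config()].
#' @return A [cohort()]; `provenance` echoes the configuration.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  with_seed(cfg$seed, {
    L <- cfg$embedding_dim
    u0 <- runit(L)
    classes <- c("NONE", STAGES[seq_len(cfg$stages_per_organ)])
    recs <- list()
    for (org in cfg$organs) {
      organ_axis <- runit(L)
      for (cl in classes) {
        class_dir <- runit(L)
        proto <- normalize_embedding(
          u0 + cfg$separation * (organ_axis + cfg$stage_nesting * class_dir))
        n_vol <- if (cl == "NONE") cfg$negatives_per_organ else
          cfg$volumes_per_class
        for (v in seq_len(n_vol)) {
          n <- resample(cfg$slice_count_range[1L]:cfg$slice_count_range[2L], 1L)
          dev <- drift_path(n, L, cfg$within_volume_drift, cfg$noise)
          span_len <- max(1L, round_half_up(cfg$organ_span_fraction * n))
          start <- resample(seq_len(n - span_len + 1L), 1L)
          span <- start:(start + span_len - 1L)
          base <- matrix(proto, n, L, byrow = TRUE)
          if (cfg$background_outside_span && span_len < n) {
            bg <- runit(L)
            outside <- setdiff(seq_len(n), span)
            base[outside, ] <- matrix(bg, length(outside), L, byrow = TRUE)
          }
          emb <- base + dev
          emb <- emb / sqrt(rowSums(emb * emb))
          id <- sprintf("%s_%s_%03d", org, tolower(cl), v)
          recs[[id]] <- volume_record(
            id, org, tumor_flag = cl != "NONE", stage = cl, matrix = emb,
            organ_presence = setNames(list(span), org))
        }
      }
    }
    cohort(recs, provenance = list(
      generator = "volcbir synthetic cohort",
      config = unclass(cfg)))
  })
}

#' Plant an exact duplicate of a volume into a cohort
#'
#' Adds a bit-identical copy of an existing volume under a new id.  Used as
#' a test construction: the copy must be retrieved first by every
#' aggregation and attain the maximal late-interaction rank score against
#' the original.
#'
#' @param x A [cohort()].
#' @param volume_id Id of the volume to duplicate.
#' @param copy_id Id for the duplicate (default `<volume_id>_copy`).
#' @return The cohort with one additional record.
#' @export
plant_copy <- function(x, volume_id, copy_id = paste0(volume_id, "_copy")) {
  stopifnot(inherits(x, "volume_cohort"))
  if (!volume_id %in% names(x$records))
    stop("unknown volume_id '", volume_id, "'", call. = FALSE)
  if (copy_id %in% names(x$records))
    stop("copy id '", copy_id, "' already present", call. = FALSE)
  r <- x$records[[volume_id]]
  dup <- volume_record(copy_id, r$organ, r$tumor_flag, r$stage, r$matrix,
                       r$organ_presence)
  cohort(c(x$records, setNames(list(dup), copy_id)),
         provenance = x$provenance)
}
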