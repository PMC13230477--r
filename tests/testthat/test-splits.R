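# small hand-built cohort: one target organ with known stage strata plus
# tumor-free volumes covering that organ
split_fixture <- function(stage_counts = c(S1 = 4, S2 = 4), n_neg = 6,
                          n_other = 3, L = 8) {
  recs <- list()
  for (s in names(stage_counts)) {
    for (i in seq_len(stage_counts[[s]])) {
      id <- sprintf("lung_%s_%d", tolower(s), i)
      recs[[id]] <- random_record(id, 4, L, organ = "lung",
                                  tumor_flag = TRUE, stage = s,
                                  organ_presence = list(lung = 2:3))
    }
  }
  for (i in seq_len(n_neg)) {
    id <- sprintf("neg_%d", i)
    recs[[id]] <- random_record(id, 4, L, organ = "liver",
                                organ_presence = list(liver = 1:4,
                                                      lung = c(1L, 2L)))
  }
  for (i in seq_len(n_other)) {  # volumes never eligible for lung queries
    id <- sprintf("other_%d", i)
    recs[[id]] <- random_record(id, 4, L, organ = "colon",
                                organ_presence = list(colon = 1:4))
  }
  cohort(recs)
}

test_that("stage-stratified sampling draws 25% per stage with matched negatives", {
  set.seed(1)
  co <- split_fixture(stage_counts = c(S1 = 4, S2 = 4))
  sp <- split_spec("organ_specific_noseg", organ = "lung", seed = 11)
  s <- sample_query_set(co, sp)
  meta <- cohort_metadata(co)
  qmeta <- meta[meta$volume_id %in% s$query_ids, ]
  expect_equal(length(s$query_ids), 4L)        # 1 + 1 positives, 2 negatives
  expect_equal(sum(qmeta$tumor_flag), 2L)
  expect_equal(sum(qmeta$stage == "S1"), 1L)
  expect_equal(sum(qmeta$stage == "S2"), 1L)
  expect_equal(sum(!qmeta$tumor_flag), 2L)     # 1:1 positive:negative
  # the remainder constitutes the database
  expect_setequal(c(s$query_ids, s$database_ids), meta$volume_id)
  expect_length(intersect(s$query_ids, s$database_ids), 0)
})

test_that("round-half-up with a minimum of one governs small strata", {
  set.seed(2)
  co <- split_fixture(stage_counts = c(S1 = 2, S3 = 1))
  s <- sample_query_set(co, split_spec("organ_specific_noseg", organ = "lung",
                                       seed = 3))
  meta <- cohort_metadata(co)
  qmeta <- meta[meta$volume_id %in% s$query_ids & meta$tumor_flag, ]
  # 0.25 * 2 = 0.5 rounds up to 1; the singleton stratum also contributes 1
  expect_equal(sum(qmeta$stage == "S1"), 1L)
  expect_equal(sum(qmeta$stage == "S3"), 1L)
})

test_that("insufficient negatives fail loudly", {
  set.seed(3)
  co <- split_fixture(stage_counts = c(S1 = 8, S2 = 8), n_neg = 1)
  expect_error(
    sample_query_set(co, split_spec("organ_specific_noseg", organ = "lung",
                                    seed = 1)),
    "insufficient negatives")
})

test_that("negatives are drawn from organ-covering tumor-free volumes only", {
  set.seed(4)
  co <- split_fixture()
  for (seed in 1:5) {
    s <- sample_query_set(co, split_spec("organ_specific_noseg",
                                         organ = "lung", seed = seed))
    meta <- cohort_metadata(co)
    negs <- meta[meta$volume_id %in% s$query_ids & !meta$tumor_flag, ]
    expect_true(all(grepl("^neg_", negs$volume_id)))
  }
})

test_that("query sets coincide across seg/noseg for a seed; masks differ", {
  set.seed(5)
  co <- split_fixture()
  seg <- sample_query_set(co, split_spec("organ_specific_seg", organ = "lung",
                                         seed = 9))
  noseg <- sample_query_set(co, split_spec("organ_specific_noseg",
                                           organ = "lung", seed = 9))
  expect_identical(seg$query_ids, noseg$query_ids)
  expect_identical(seg$database_ids, noseg$database_ids)
  expect_null(noseg$slice_masks)
  # seg masks equal the target-organ presence spans
  for (id in seg$database_ids) {
    r <- co$records[[id]]
    expect_identical(seg$slice_masks[[id]],
                     as.integer(r$organ_presence$lung %||% integer(0)))
  }
  # masked index is smaller by exactly the masked-out slices
  i_seg <- build_slice_index(co, "exact", volume_ids = seg$database_ids,
                             slice_masks = seg$slice_masks)
  i_no <- build_slice_index(co, "exact", volume_ids = noseg$database_ids)
  expect_equal(i_no$entries - i_seg$entries,
               sum(vapply(co$records[seg$database_ids], function(r)
                 r$n_slices - length(r$organ_presence$lung %||% integer(0)),
                 numeric(1))))
})

test_that("independent draws across seeds, without replacement within one", {
  set.seed(6)
  co <- split_fixture(stage_counts = c(S1 = 8, S2 = 8), n_neg = 12)
  sets <- lapply(1:6, function(seed)
    sample_query_set(co, split_spec("organ_specific_noseg", organ = "lung",
                                    seed = seed))$query_ids)
  for (s in sets) expect_false(anyDuplicated(s) > 0)
  expect_identical(
    sets[[1]],
    sample_query_set(co, split_spec("organ_specific_noseg", organ = "lung",
                                    seed = 1))$query_ids)
  expect_true(length(unique(vapply(sets, paste, "", collapse = ","))) > 1)
})

test_that("organ-agnostic splits pool per-organ draws into one database", {
  cfg <- generator_config(volumes_per_class = 4, negatives_per_organ = 8,
                          slice_count_range = c(6L, 10L), seed = 2)
  co <- generate_cohort(cfg)
  sp <- split_spec("organ_agnostic", seed = 13)
  s <- build_agnostic_split(co, sp)
  meta <- cohort_metadata(co)
  qmeta <- meta[meta$volume_id %in% s$query_ids, ]
  # per organ: 4 positive strata of 4 volumes -> 1 each, plus 4 negatives
  per_organ <- table(qmeta$organ)
  expect_true(all(per_organ == 8))
  expect_equal(sum(per_organ), length(s$query_ids))
  expect_equal(sum(qmeta$tumor_flag), sum(!qmeta$tumor_flag))
  expect_length(intersect(s$query_ids, s$database_ids), 0)
  expect_null(s$slice_masks)
  # seeded rebuild is identical; sample_query_set dispatches here
  expect_identical(s$query_ids, build_agnostic_split(co, sp)$query_ids)
  expect_identical(s$query_ids, sample_query_set(co, sp)$query_ids)
})

test_that("split_spec validates its arguments", {
  expect_error(split_spec("organ_specific_seg"), "target organ")
  expect_error(split_spec("organ_agnostic", p_query = 0), "p_query")
  expect_error(split_spec("bogus", organ = "lung"), "arg")
})
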