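test_that("similarity matrices match hand-computed cosines", {
  q <- f1_query()$matrix
  a <- f1_cohort()$records[["A"]]$matrix
  b <- f1_cohort()$records[["B"]]$matrix
  expect_equal(similarity_matrix(q, a), rbind(c(1, 0.6), c(0, 0.8)))
  expect_equal(similarity_matrix(q, b), rbind(c(0.6, 0), c(0.8, 1)))
  expect_equal(diag(similarity_matrix(q, q)), c(1, 1))
  expect_error(similarity_matrix(q, matrix(1, 2, 3)), "dimension")
})

test_that("late-interaction rank scores match the fixture and the bounds", {
  q <- f1_query()$matrix
  co <- f1_cohort()
  expect_equal(cmir_rank_score(similarity_matrix(q, co$records$A$matrix)), 1.8)
  expect_equal(cmir_rank_score(similarity_matrix(q, co$records$B$matrix)), 1.6)
  expect_equal(cmir_rank_score(matrix(1, 4, 7)), 4)
  expect_error(cmir_rank_score(matrix(numeric(0), 0, 3)), "non-empty")
})

test_that("rank score equals the nested-loop oracle on random matrices", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(1:12, 1); m <- sample(1:15, 1); L <- sample(2:20, 1)
    mq <- matrix(rnorm(n * L), n); mq <- mq / sqrt(rowSums(mq^2))
    mw <- matrix(rnorm(m * L), m); mw <- mw / sqrt(rowSums(mw^2))
    expect_equal(cmir_rank_score(similarity_matrix(mq, mw)),
                 oracle_cmir(mq, mw))
  }
})

test_that("rank score is monotone in any single similarity entry", {
  set.seed(71)
  for (i in 1:25) {
    s <- matrix(runif(20, -1, 1), 4, 5)
    base <- cmir_rank_score(s)
    s2 <- s
    idx <- c(sample(4, 1), sample(5, 1))
    s2[idx[1], idx[2]] <- s2[idx[1], idx[2]] + runif(1, 0, 0.5)
    expect_gte(cmir_rank_score(s2), base)
  }
})

test_that("self-similarity attains the maximal rank score n", {
  set.seed(81)
  q <- random_record("q", 9, 16)
  others <- lapply(1:10, function(i) random_record(sprintf("o%d", i), 7, 16))
  rs_self <- cmir_rank_score(similarity_matrix(q$matrix, q$matrix))
  expect_equal(rs_self, 9, tolerance = 1e-6)
  for (o in others) {
    rs <- cmir_rank_score(similarity_matrix(q$matrix, o$matrix))
    expect_lt(rs, rs_self)
  }
})

test_that("cmir_rerank orders the fixture candidates [A, B] from any start", {
  co <- f1_cohort()
  q <- f1_query()
  for (start in list(c("A", "B"), c("B", "A"))) {
    cand <- structure(data.frame(volume_id = start, score = c(2, 1)),
                      class = c("ranked_list", "data.frame"),
                      method = "count", query_id = "Q")
    out <- cmir_rerank(q, cand, co)
    expect_equal(out$volume_id, c("A", "B"))
    expect_equal(out$score, c(1.8, 1.6))
    expect_equal(attr(out, "method"), "cmir")
  }
  # single candidate passes through unchanged
  single <- structure(data.frame(volume_id = "B", score = 1),
                      class = c("ranked_list", "data.frame"),
                      method = "count", query_id = "Q")
  expect_equal(cmir_rerank(q, single, co)$volume_id, "B")
  # unknown candidate id is a data error
  bad <- structure(data.frame(volume_id = "nope", score = 1),
                   class = c("ranked_list", "data.frame"),
                   method = "count", query_id = "Q")
  expect_error(cmir_rerank(q, bad, co), "not in cohort")
})

test_that("re-ranking permutes but never changes list membership", {
  set.seed(91)
  co <- cohort(lapply(1:12, function(i) random_record(sprintf("v%02d", i),
                                                      sample(4:8, 1), 10)))
  idx <- build_slice_index(co, "exact", volume_ids = names(co$records)[-1])
  q <- co$records[[1]]
  cand <- retrieve_top_volumes(build_hit_table(q, idx, 10), "count")
  out <- cmir_rerank(q, cand, co)
  expect_setequal(out$volume_id, cand$volume_id)
  expect_true(all(diff(out$score) <= 0))
})

test_that("RRF closed forms and errors", {
  mk <- function(ids) structure(
    data.frame(volume_id = ids, score = rev(seq_along(ids))),
    class = c("ranked_list", "data.frame"), method = "count", query_id = "q")
  # first in all three lists: 3 / 61
  sc <- rrf_scores(list(mk(c("V", "x")), mk(c("V", "y")), mk(c("V", "z"))))
  expect_equal(unname(sc["V"]), 3 / 61)
  # ranks 2 and 3, absent from the third list
  sc2 <- rrf_scores(list(mk(c("a", "V")), mk(c("b", "c", "V")), mk(c("d"))))
  expect_equal(unname(sc2["V"]), 1 / 62 + 1 / 63)
  # absent everywhere -> not in the output
  expect_false("Q" %in% names(sc2))
  expect_error(rrf_scores(list(mk("a"), mk("b"))), "exactly 3")
})

test_that("RRF fusion depends on ranks only", {
  mk <- function(ids, scores) structure(
    data.frame(volume_id = ids, score = scores),
    class = c("ranked_list", "data.frame"), method = "count", query_id = "q")
  l1 <- mk(c("A", "B"), c(10, 5))
  l2 <- mk(c("B", "A"), c(0.2, 0.1))
  l3 <- mk(c("A", "B"), c(1000, 1))
  fused <- rrf_rerank(list(l1, l2, l3))
  expect_equal(fused$volume_id, c("A", "B"))
  expect_equal(fused$score[1], 2 / 61 + 1 / 62)
  # rescaling scores arbitrarily (ranks unchanged) leaves the fusion fixed
  scale <- function(l, f) { l$score <- l$score * f + 3; l }
  fused2 <- rrf_rerank(list(scale(l1, 7), scale(l2, 0.01), scale(l3, 100)))
  expect_equal(fused2, fused)
  # three identical lists preserve their common order
  same <- rrf_rerank(list(mk(c("x", "y", "z"), 3:1),
                          mk(c("x", "y", "z"), 3:1),
                          mk(c("x", "y", "z"), 3:1)))
  expect_equal(same$volume_id, c("x", "y", "z"))
  solo <- rrf_rerank(list(mk("only", 1), mk("only", 1), mk("only", 1)))
  expect_equal(solo$volume_id, "only")
})
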