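# Shared fixtures and independent oracles for the test suite.

# Two-volume toy database and a two-slice query in 2D, with all pairwise
# cosines computable by hand:
#   Q: q1 = (1, 0), q2 = (0, 1)
#   A: a1 = (1, 0), a2 = (0.6, 0.8)
#   B: b1 = (0.6, 0.8), b2 = (0, 1)
f1_record <- function(id, rows) {
  volume_record(id, organ = "organ1", tumor_flag = FALSE, stage = "NONE",
                matrix = rows)
}

f1_query <- function() f1_record("Q", rbind(c(1, 0), c(0, 1)))

f1_cohort <- function(include_query = FALSE) {
  recs <- list(
    f1_record("A", rbind(c(1, 0), c(0.6, 0.8))),
    f1_record("B", rbind(c(0.6, 0.8), c(0, 1))))
  if (include_query) recs <- c(recs, list(f1_query()))
  cohort(recs)
}

# a small random cohort of plain volumes for structural tests
random_record <- function(id, n, L, organ = "organ1", tumor_flag = FALSE,
                          stage = "NONE", organ_presence = NULL) {
  m <- matrix(rnorm(n * L), n, L)
  m <- m / sqrt(rowSums(m * m))
  volume_record(id, organ, tumor_flag, stage, m,
                organ_presence = organ_presence)
}

# hand-built hit table matching the worked aggregation example:
# row q1: (A, slice 1, 0.9), (B, slice 3, 0.8)
# row q2: (A, slice 2, 0.7), (A, slice 4, 0.6)
example_hit_table <- function() {
  ht <- data.frame(
    query_slice = c(1L, 1L, 2L, 2L),
    volume_id = c("A", "B", "A", "A"),
    slice_index = c(1L, 3L, 2L, 4L),
    score = c(0.9, 0.8, 0.7, 0.6),
    stringsAsFactors = FALSE)
  structure(ht, class = c("hit_table", "data.frame"),
            query_id = "Q", n_query_slices = 2L)
}

# independent full-scan search oracle: all cosines, sorted by score then
# ascending (volume_id, slice_index)
oracle_search <- function(cohort, q, k, volume_ids = NULL) {
  ids <- volume_ids %||% names(cohort$records)
  rows <- do.call(rbind, lapply(ids, function(id) {
    r <- cohort$records[[id]]
    data.frame(volume_id = id, slice_index = seq_len(r$n_slices),
               score = as.vector(r$matrix %*% q), stringsAsFactors = FALSE)
  }))
  rows <- rows[order(-rows$score, rows$volume_id, rows$slice_index,
                     method = "radix"), ]
  rownames(rows) <- NULL
  head(rows, k)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

# independent late-interaction oracle: explicit nested loops over slice pairs
oracle_cmir <- function(m_q, m_w) {
  total <- 0
  for (i in seq_len(nrow(m_q))) {
    best <- -Inf
    for (j in seq_len(nrow(m_w))) {
      s <- sum(m_q[i, ] * m_w[j, ])
      if (s > best) best <- s
    }
    total <- total + best
  }
  total
}

# independent Wilcoxon oracle: full enumeration of all 2^n sign assignments
# of the (mid)ranked absolute differences
oracle_wilcoxon <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p <- 2 * min(mean(vs <= v + 1e-9), mean(vs >= v - 1e-9))
  min(1, p)
}

# Eq-style average precision oracle: sum over positions of
# (R_n - R_{n-1}) * P_n with R_n normalized by the relevant count in top-10
oracle_ap <- function(rel, top = 10) {
  r <- head(c(as.logical(rel), rep(FALSE, top)), top)
  d <- sum(r)
  if (d == 0) return(0)
  p_n <- cumsum(r) / seq_len(top)
  r_n <- cumsum(r) / d
  sum((r_n - c(0, head(r_n, -1))) * p_n)
}
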