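#' Judge relevance of retrieved volumes against a query
#'
#' Two clinically motivated tasks:
#' * `"flagging"` — a retrieved volume is relevant iff its tumor flag
#'   matches the query's (tumor cases should retrieve tumor cases,
#'   negatives should retrieve negatives);
#' * `"staging"` — relevant iff both are negative, or both are positive
#'   with exactly the same stage (S1..S4; adjacent stages are not partially
#'   relevant).
#'
#' @param query A [volume_record()].
#' @param ranked A ranked list over cohort volumes.
#' @param x The [cohort()] the ranked volumes come from.
#' @param task `"flagging"` or `"staging"`.
#' @return Logical vector, one entry per ranked volume, in list order.
#' @export
judge_relevance <- function(query, ranked, x,
                            task = c("flagging", "staging")) {
  task <- match.arg(task)
  stopifnot(inherits(query, "volume_record"), inherits(x, "volume_cohort"))
  ids <- ranked$volume_id
  missing_ids <- setdiff(ids, names(x$records))
  if (length(missing_ids))
    stop("ranked volumes not in cohort: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  flags <- vapply(x$records[ids], `[[`, logical(1), "tumor_flag")
  stages <- vapply(x$records[ids], `[[`, character(1), "stage")
  if (task == "staging" && query$tumor_flag && !query$stage %in% STAGES)
    stop("query '", query$volume_id, "' has malformed stage '",
         query$stage, "'", call. = FALSE)
  if (task == "flagging") {
    unname(flags == query$tumor_flag)
  } else {
    unname((!flags & !query$tumor_flag) |
             (flags & query$tumor_flag & stages == query$stage))
  }
}

#' Precision among the top k retrieved volumes
#'
#' Fraction of relevant items among the first `k`; when fewer than `k`
#' volumes were retrieved, the missing slots count as non-relevant
#' (conservative and deterministic).
#'
#' @param relevant Logical vector of per-rank relevance (list order).
#' @param k Cut-off, conventionally 3, 5 or 10.
#' @return Numeric scalar in `[0, 1]`, a multiple of `1/k`.
#' @export
precision_at_k <- function(relevant, k) {
  stopifnot(k >= 1)
  r <- head(c(as.logical(relevant), rep(FALSE, k)), k)
  mean(r)
}

#' Average precision over the top-10 retrieved volumes
#'
#' The rank-weighted summary `AP = sum_n (R_n - R_{n-1}) P_n` over the first
#' 10 positions, where `P_n` is the precision at rank `n` and `R_n` the
#' recall at rank `n` with the number of relevant items *within the top-10
#' list* as denominator (0 relevant -> AP 0).  Algebraically this equals the
#' mean of the precisions at the relevant ranks.  Short lists are padded
#' with non-relevant slots.
#'
#' @param relevant Logical vector of per-rank relevance (list order).
#' @param top Evaluation depth (default 10).
#' @return Numeric scalar in `[0, 1]`.
#' @export
average_precision <- function(relevant, top = 10L) {
  r <- head(c(as.logical(relevant), rep(FALSE, top)), top)
  d <- sum(r)
  if (d == 0L) return(0)
  prec <- cumsum(r) / seq_len(top)
  sum(prec[r]) / d
}

#' Two-sided paired Wilcoxon signed-rank test
#'
#' Tests whether paired observations `a` and `b` differ in location.  Zero
#' differences are dropped (Wilcoxon's original treatment).  For up to 25
#' informative pairs the two-sided p-value is exact, computed from the full
#' null distribution of the signed-rank statistic over all `2^n` sign
#' assignments (a subset-sum recursion over the midranks, so ties in the
#' absolute differences are handled exactly); for larger n a normal
#' approximation with tie correction is used.  The two-sided p is
#' `min(1, 2 * min(P(V <= v), P(V >= v)))`.
#'
#' @param a,b Equal-length numeric vectors of paired observations
#'   (e.g. per-seed mean average precision of two methods).
#' @return The two-sided p-value.  All-zero differences give `p = 1` with a
#'   warning.
#' @export
wilcoxon_paired <- function(a, b) {
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  if (length(a) < 2L)
    stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25L) {
    # exact null distribution of V by convolution over doubled midranks
    # (doubling makes half-integer midranks integral)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)
    f[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(total + 1L - ri)])
      f <- f + shifted
    }
    f <- f / 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(f[seq_len(v2 + 1L)])
    p_ge <- sum(f[(v2 + 1L):(total + 1L)])
    min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu) / sqrt(sig2)
    min(1, 2 * pnorm(-abs(z)))
  }
}
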