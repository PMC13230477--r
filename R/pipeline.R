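#' Run the seeded retrieval experiment
#'
#' Executes the full evaluation protocol on one cohort: for every seed the
#' query/database split is redrawn, the slice index rebuilt over the
#' database side, and every query volume evaluated under every requested
#' method and task.  Methods are the three first-stage aggregations plus
#' the two re-rankers; `"rrf"` fuses the three first-stage top-k lists and
#' `"cmir"` re-ranks the top-`m_top` candidates of the `cmir_base`
#' aggregation by late interaction.
#'
#' With the exact backend the whole run is deterministic given the seeds.
#'
#' @param x A [cohort()].
#' @param spec A [split_spec()]; its `seed` field is replaced by each
#'   element of `seeds` in turn.
#' @param methods Subset of `c("count", "max_score", "sum_sim", "rrf",
#'   "cmir")`.
#' @param seeds Integer vector of experiment seeds (the protocol uses 10).
#' @param tasks Subset of `c("flagging", "staging")`.
#' @param backend Index backend, `"exact"` (default) or `"hnsw"`.
#' @param n_neighbors Slice hits kept per query slice (default 20).
#' @param k_top First-stage list length (default 20).
#' @param m_top Candidates re-ranked by C-MIR (default 20).
#' @param k_smooth RRF smoothing constant (default 60).
#' @param cmir_base Aggregation whose top list C-MIR re-ranks
#'   (default `"count"`).
#' @return List with `records` (one row per query x method x task x seed:
#'   `p3`, `p5`, `p10`, `ap`) and `seed_means` (per seed x method x task
#'   means of the four metrics).
#' @export
run_experiment <- function(x, spec,
                           methods = c("count", "max_score", "sum_sim",
                                       "rrf", "cmir"),
                           seeds = 1:10,
                           tasks = c("flagging", "staging"),
                           backend = "exact",
                           n_neighbors = 20L, k_top = 20L, m_top = 20L,
                           k_smooth = 60, cmir_base = "count") {
  stopifnot(inherits(x, "volume_cohort"), inherits(spec, "split_spec"))
  methods <- match.arg(methods, several.ok = TRUE)
  tasks <- match.arg(tasks, several.ok = TRUE)
  base_methods <- c("count", "max_score", "sum_sim")
  records <- list()
  for (seed in seeds) {
    sp <- spec
    sp$seed <- as.integer(seed)
    split <- sample_query_set(x, sp)
    index <- build_slice_index(
      x, backend = backend,
      volume_ids = split$database_ids,
      slice_masks = split$slice_masks,
      params = list(seed = derive_seed(seed, "index")))
    for (qid in split$query_ids) {
      q <- x$records[[qid]]
      ht <- build_hit_table(q, index, n_neighbors = n_neighbors)
      base_lists <- lapply(base_methods, function(m)
        retrieve_top_volumes(ht, m, k = k_top))
      names(base_lists) <- base_methods
      ranked <- base_lists[intersect(methods, base_methods)]
      if ("rrf" %in% methods)
        ranked$rrf <- rrf_rerank(base_lists, k_smooth = k_smooth)
      if ("cmir" %in% methods)
        ranked$cmir <- cmir_rerank(q, base_lists[[cmir_base]], x,
                                   m_top = m_top)
      for (m in names(ranked)) {
        for (task in tasks) {
          rel <- judge_relevance(q, ranked[[m]], x, task)
          records[[length(records) + 1L]] <- data.frame(
            seed = seed, method = m, task = task, query_id = qid,
            organ = q$organ, tumor_flag = q$tumor_flag, stage = q$stage,
            p3 = precision_at_k(rel, 3L),
            p5 = precision_at_k(rel, 5L),
            p10 = precision_at_k(rel, 10L),
            ap = average_precision(rel),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  records <- do.call(rbind, records)
  seed_means <- stats::aggregate(
    records[c("p3", "p5", "p10", "ap")],
    by = records[c("seed", "method", "task")], FUN = mean)
  names(seed_means)[names(seed_means) %in% c("p3", "p5", "p10", "ap")] <-
    c("mean_p3", "mean_p5", "mean_p10", "mean_ap")
  seed_means <- seed_means[order(seed_means$task, seed_means$method,
                                 seed_means$seed), ]
  rownames(seed_means) <- NULL
  list(records = records, seed_means = seed_means)
}

#' Paired Wilcoxon comparison of methods on per-seed mean AP
#'
#' For each task, pairs the per-seed mean average precision of a baseline
#' method with that of every other method and applies the two-sided
#' Wilcoxon signed-rank test — the statistical protocol used to compare the
#' late-interaction re-ranker against the best competing method.
#'
#' @param seed_means The `seed_means` table from [run_experiment()].
#' @param baseline Method compared against the others (default `"cmir"`).
#' @return Data frame: `task`, `method_a` (baseline), `method_b`,
#'   `mean_ap_a`, `mean_ap_b`, `p_value`.
#' @export
compare_methods <- function(seed_means, baseline = "cmir") {
  stopifnot(baseline %in% seed_means$method)
  out <- list()
  for (task in unique(seed_means$task)) {
    tab <- seed_means[seed_means$task == task, ]
    a <- tab[tab$method == baseline, ]
    a <- a[order(a$seed), ]
    for (m in setdiff(unique(tab$method), baseline)) {
      b <- tab[tab$method == m, ]
      b <- b[order(b$seed), ]
      stopifnot(identical(a$seed, b$seed))
      p <- suppressWarnings(wilcoxon_paired(a$mean_ap, b$mean_ap))
      out[[length(out) + 1L]] <- data.frame(
        task = task, method_a = baseline, method_b = m,
        mean_ap_a = mean(a$mean_ap), mean_ap_b = mean(b$mean_ap),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Run the full experiment grid and write result tables
#'
#' Orchestrates cohort generation (unless a cohort is supplied), the
#' configured database setups, all methods, seeds and tasks, and writes
#' `results.csv` (per-seed means, one row per config x organ x method x
#' task x seed) and `comparisons.csv` (pairwise Wilcoxon tests of the
#' baseline against every other method) to `out_dir`.
#'
#' @param x A [cohort()], or `NULL` to generate one from `gen_config`.
#' @param gen_config A [generator_config()] used when `x` is `NULL`.
#' @param configs Database configurations to run (default all three).
#' @param seeds Experiment seeds (default `1:10`).
#' @param tasks Tasks to evaluate (default both).
#' @param methods Methods to evaluate (default all five).
#' @param out_dir Output directory for the CSV tables, or `NULL` to skip
#'   writing.
#' @param baseline Baseline method for the comparisons table.
#' @inheritParams run_experiment
#' @return List with `results` and `comparisons` data frames (invisibly
#'   also written to `out_dir`).
#' @export
run_full_experiment <- function(x = NULL,
                                gen_config = generator_config(),
                                configs = c("organ_specific_seg",
                                            "organ_specific_noseg",
                                            "organ_agnostic"),
                                seeds = 1:10,
                                tasks = c("flagging", "staging"),
                                methods = c("count", "max_score", "sum_sim",
                                            "rrf", "cmir"),
                                out_dir = NULL,
                                baseline = "cmir",
                                backend = "exact",
                                n_neighbors = 20L, k_top = 20L, m_top = 20L,
                                k_smooth = 60) {
  if (is.null(x)) x <- generate_cohort(gen_config)
  meta <- cohort_metadata(x)
  organs <- sort(unique(meta$organ[meta$tumor_flag]))
  results <- list()
  comparisons <- list()
  for (config in configs) {
    specs <- if (config == "organ_agnostic") {
      list(split_spec(config, organ = "ALL"))
    } else {
      lapply(organs, function(o) split_spec(config, organ = o))
    }
    for (sp in specs) {
      res <- run_experiment(x, sp, methods = methods, seeds = seeds,
                            tasks = tasks, backend = backend,
                            n_neighbors = n_neighbors, k_top = k_top,
                            m_top = m_top, k_smooth = k_smooth)
      sm <- res$seed_means
      sm$config <- config
      sm$organ <- sp$organ
      results[[length(results) + 1L]] <- sm
      if (baseline %in% methods && length(methods) > 1L) {
        cmp <- compare_methods(res$seed_means, baseline = baseline)
        cmp$config <- config
        cmp$organ <- sp$organ
        comparisons[[length(comparisons) + 1L]] <- cmp
      }
    }
  }
  results <- do.call(rbind, results)
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    if (!is.null(comparisons))
      utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
  }
  list(results = results, comparisons = comparisons)
}
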