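#' Split each patient's cognitive tasks into folds
#'
#' Cross-validation protocol at the task level: for each patient, the tasks
#' are randomly partitioned into \code{n_folds} near-equal groups, and all
#' features of a task travel together into the same fold. By default each
#' patient receives an independent random partition; \code{shared = TRUE}
#' draws one partition and applies it to every patient.
#'
#' @param cohort a \code{cogrank_normalized} cohort (needs \code{task_map}).
#' @param n_folds number of folds (default 5).
#' @param seed integer seed; the plan is deterministic given the seed.
#' @param shared use a single task partition for all patients.
#' @return Object of class \code{cogrank_split}: list with \code{mode =
#'   "CV"}, \code{folds} (per-patient named integer vector task -> fold),
#'   \code{n_folds}, \code{seed}.
#' @export
cv_split <- function(cohort, n_folds = 5, seed = 1, shared = FALSE) {
  tasks <- sort(unique(unname(cohort$task_map)))
  if (n_folds < 2 || n_folds > length(tasks))
    stop("n_folds must be between 2 and the number of tasks")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  draw <- function() stats::setNames(
    sample(rep(seq_len(n_folds), length.out = length(tasks))), tasks)
  folds <- if (shared) {
    one <- draw()
    stats::setNames(rep(list(one), length(cohort$patient_ids)),
                    cohort$patient_ids)
  } else {
    stats::setNames(lapply(cohort$patient_ids, function(p) draw()),
                    cohort$patient_ids)
  }
  structure(list(mode = "CV", folds = folds, n_folds = n_folds, seed = seed,
                 shared = shared),
            class = "cogrank_split")
}

#' @export
print.cogrank_split <- function(x, ...) {
  if (x$mode == "CV") {
    cat("CV split plan:", length(x$folds), "patients,", x$n_folds,
        "folds over tasks,", if (x$shared) "shared" else "per-patient",
        "partition (seed", paste0(x$seed, ")\n"))
  } else {
    cat("LOV split plan:", length(x$holdout), "holdout /",
        length(x$training), "training patients (similarity >",
        x$sim_threshold, ", >", x$min_neighbors, "neighbors)\n")
  }
  invisible(x)
}

#' Select leave-out validation holdout patients by similarity
#'
#' Holds out the patients (optionally restricted by diagnosis, e.g. AD only)
#' that have more than \code{min_neighbors} other eligible patients with
#' imaging similarity above \code{sim_threshold}; the remaining patients form
#' the training set. Neighbours are counted among the other patients matching
#' the same diagnosis filter (a single row-wise pass over the similarity
#' matrix).
#'
#' @param sim patient similarity (\code{cogrank_similarity} or matrix with
#'   patient dimnames).
#' @param diagnosis per-patient diagnosis labels aligned with \code{sim}, or
#'   \code{NULL} to ignore the filter.
#' @param dx_filter labels eligible for holdout/neighbour counting (default
#'   \code{"AD"}).
#' @param sim_threshold similarity cutoff in (0, 1).
#' @param min_neighbors required number of similar training patients
#'   (strictly more; default 10).
#' @return Object of class \code{cogrank_split} with \code{mode = "LOV"},
#'   \code{holdout} and \code{training} patient ids. Empty holdout gives a
#'   warning and an empty plan.
#' @export
lov_select_holdout <- function(sim, diagnosis = NULL, dx_filter = "AD",
                               sim_threshold, min_neighbors = 10) {
  w <- sim_matrix(sim)
  if (!(sim_threshold > 0 && sim_threshold < 1))
    stop("sim_threshold must be in (0, 1)")
  ids <- rownames(w)
  if (is.null(ids)) ids <- paste0("p", seq_len(nrow(w)))
  eligible <- if (is.null(diagnosis)) rep(TRUE, nrow(w))
              else diagnosis %in% dx_filter
  above <- w > sim_threshold
  diag(above) <- FALSE

  counts <- rowSums(above[, eligible, drop = FALSE])
  holdout <- eligible & counts > min_neighbors
  if (!any(holdout))
    warning("no patient satisfies the holdout rule; empty plan", call. = FALSE)
  structure(list(mode = "LOV", holdout = ids[holdout],
                 training = ids[!holdout],
                 sim_threshold = sim_threshold,
                 min_neighbors = min_neighbors),
            class = "cogrank_split")
}

#' Run the task-wise cross-validation protocol
#'
#' For each fold: each patient's features belonging to their test-fold tasks
#' are masked out of training (relevance labels and loss pairs are built from
#' the remaining observed features only); the model is fitted; test-fold
#' features are then ranked by their fitted scores and evaluated against the
#' ground-truth ordering of their normalized values. Metrics are averaged
#' over patients within each fold; the report carries mean and sd over folds.
#'
#' @param cohort a \code{cogrank_normalized}.
#' @param sim patient similarity.
#' @param plan a CV \code{cogrank_split} from [cv_split()] (built at
#'   \code{n_folds = 5}, \code{seed} when omitted).
#' @param variant,d,alpha,beta,gamma,seed passed to [pltr()].
#' @param k feature-metric depth (capped per patient at the test-fold size).
#' @param g_values task-scoring depths for NH_g\@1.
#' @param seed seed for both the default plan and the fits.
#' @param scores_fun optional replacement for the model: a function
#'   \code{(train_values, sim)} returning a full patients x features score
#'   matrix (used to benchmark oracle or random scorers under the identical
#'   protocol).
#' @param ... further arguments to [pltr()].
#' @return Data frame with columns \code{setting}, \code{method}, \code{d},
#'   \code{alpha}, \code{beta}, \code{gamma}, \code{metric}, \code{mean},
#'   \code{sd} (over folds).
#' @export
run_cv <- function(cohort, sim, plan = NULL, variant = "pltr",
                   d = 10, alpha = 0.5, beta = 0.5, gamma = 1,
                   k = 5, g_values = c(1, 2, 3, 5, Inf), seed = 1,
                   scores_fun = NULL, ...) {
  if (is.null(plan)) plan <- cv_split(cohort, n_folds = 5, seed = seed)
  if (!identical(plan$mode, "CV")) stop("`plan` must be a CV split")
  values <- cohort$values
  tm <- cohort$task_map
  per_fold <- vector("list", plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    train_values <- values
    for (p in rownames(values)) {
      test_tasks <- names(plan$folds[[p]])[plan$folds[[p]] == f]
      test_feats <- names(tm)[tm %in% test_tasks]
      train_values[p, test_feats] <- NA_real_
    }
    scores <- if (is.null(scores_fun)) {
      fit <- pltr(train_values, sim, variant = variant, d = d, alpha = alpha,
                  beta = beta, gamma = gamma, seed = seed, ...)
      fitted(fit)
    } else {
      scores_fun(train_values, sim)
    }
    per_pat <- lapply(rownames(values), function(p) {
      test_tasks <- names(plan$folds[[p]])[plan$folds[[p]] == f]
      test_feats <- names(tm)[tm %in% test_tasks]
      tv <- values[p, test_feats]
      if (sum(!is.na(tv)) < 2L) return(NULL)
      evaluate_ranking(tv, scores[p, test_feats], task_map = tm[test_feats],
                       k = k, g_values = g_values, k_task = 1)
    })
    per_pat <- per_pat[!vapply(per_pat, is.null, TRUE)]
    per_fold[[f]] <- colMeans(do.call(rbind, per_pat))
  }
  fm <- do.call(rbind, per_fold)
  data.frame(setting = "CV", method = variant, d = d, alpha = alpha,
             beta = beta, gamma = gamma,
             metric = colnames(fm),
             mean = colMeans(fm), sd = apply(fm, 2, stats::sd),
             row.names = NULL)
}

#' Run the leave-out validation protocol
#'
#' Fits the model on training patients only (holdout patients' cognitive
#' values are never read; only their imaging-derived similarity rows are
#' used), infers each holdout patient's latent vector from their
#' \code{k_neighbors} most similar training patients via
#' [infer_holdout_latent()], ranks all features and tasks, and evaluates
#' against the holdout patients' ground-truth normalized values.
#'
#' @inheritParams run_cv
#' @param plan a LOV \code{cogrank_split} from [lov_select_holdout()].
#' @param k_neighbors cold-start neighbourhood size (default 10).
#' @param k_task task-metric depths (default \code{c(1, 5)}).
#' @return Data frame as in [run_cv()] with \code{setting = "LOV"}; means and
#'   sds are over holdout patients.
#' @export
run_lov <- function(cohort, sim, plan, variant = "pltr",
                    d = 10, alpha = 0.5, beta = 0.5, gamma = 1,
                    k = 5, g_values = c(1, 2, 3, 5, Inf),
                    k_task = c(1, 5), k_neighbors = 10, seed = 1, ...) {
  if (!identical(plan$mode, "LOV")) stop("`plan` must be a LOV split")
  if (!length(plan$holdout)) stop("empty holdout; nothing to evaluate")
  w <- sim_matrix(sim)
  if (is.null(rownames(w))) dimnames(w) <- list(rownames(cohort$values),
                                                rownames(cohort$values))
  tr <- plan$training; ho <- plan$holdout
  train_values <- cohort$values[tr, , drop = FALSE]
  fit <- pltr(structure(list(values = train_values,
                             task_map = cohort$task_map,
                             patient_ids = tr,
                             feature_ids = colnames(train_values)),
                        class = "cogrank_normalized"),
              w[tr, tr, drop = FALSE], variant = variant, d = d,
              alpha = alpha, beta = beta, gamma = gamma, seed = seed, ...)
  scores <- predict(fit, newdata = w[ho, tr, drop = FALSE],
                    k_neighbors = k_neighbors)
  per_pat <- lapply(ho, function(p)
    evaluate_ranking(cohort$values[p, ], scores[p, ],
                     task_map = cohort$task_map, k = k,
                     g_values = g_values, k_task = k_task))
  pm <- do.call(rbind, per_pat)
  data.frame(setting = "LOV", method = variant, d = d, alpha = alpha,
             beta = beta, gamma = gamma,
             metric = colnames(pm),
             mean = colMeans(pm), sd = apply(pm, 2, stats::sd),
             row.names = NULL)
}

#' Exhaustive grid search over hyperparameters
#'
#' Runs \code{runner} on every combination in \code{grid} and returns, for
#' each metric, the first-in-grid combination attaining the maximum mean.
#'
#' @param grid named list of hyperparameter vectors (e.g. \code{list(d =
#'   c(10, 30, 50), beta = c(0.5, 1.5))}); combinations are expanded in
#'   column-major order.
#' @param runner function taking a one-row data frame of hyperparameters and
#'   returning a metric report (data frame with \code{metric} and
#'   \code{mean}).
#' @return List with \code{table} (all reports bound together with their
#'   hyperparameters) and \code{best} (named list: per metric, the winning
#'   hyperparameter row with its mean).
#' @export
grid_search <- function(grid, runner) {
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  reports <- lapply(seq_len(nrow(combos)), function(i) {
    rep <- runner(combos[i, , drop = FALSE])
    rep$combo <- i
    rep
  })
  table <- do.call(rbind, reports)
  best <- lapply(split(table, table$metric), function(tb) {
    tb <- tb[order(tb$combo), , drop = FALSE]
    win <- tb[which.max(tb$mean), , drop = FALSE]   # first max wins ties
    cbind(combos[win$combo, , drop = FALSE], mean = win$mean,
          combo = win$combo, row.names = NULL)
  })
  list(table = table, best = best)
}
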