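#' Feature hits at k (QH@k)
#'
#' Number of items shared between the top \code{k} of the predicted list and
#' the top \code{k} of the ground-truth list,
#' \eqn{\sum_{i=1}^k I(\tilde\tau_i \in \tau(1:k))}. Higher is better;
#' maximum \code{k}.
#'
#' @param truth,pred character vectors: ground-truth and predicted rankings,
#'   most relevant first.
#' @param k depth; must not exceed the length of either list.
#' @return Integer hit count in 0..k.
#' @export
qh_at_k <- function(truth, pred, k) {
  if (k > length(truth) || k > length(pred))
    stop("k exceeds the length of a ranking list")
  if (k < 1) stop("k must be >= 1")
  length(intersect(pred[seq_len(k)], truth[seq_len(k)]))
}

#' Depth-weighted feature hits at k (WQH@k)
#'
#' Average of QH@j over j = 1..k: \eqn{(\sum_{j=1}^k QH@j)/k}. Rewards hits
#' placed near the top; equals \eqn{(k+1)/2} for a perfect ranking.
#'
#' @inheritParams qh_at_k
#' @return Real in [0, (k+1)/2].
#' @export
wqh_at_k <- function(truth, pred, k) {
  if (k > length(truth) || k > length(pred))
    stop("k exceeds the length of a ranking list")
  mean(vapply(seq_len(k), function(j) qh_at_k(truth, pred, j), numeric(1)))
}

#' Score and rank cognitive tasks from a feature list
#'
#' Each task is scored by the mean of the native scores of its top-\code{g}
#' features, where "top" follows the feature list's own orientation:
#' ascending values for ground truth (smaller normalized value = more
#' AD-relevant), descending for predictions. When a task has fewer than
#' \code{g} evaluable features, \code{g} is capped at availability. Tasks
#' with no evaluable feature are excluded. Tasks are then ranked
#' most-relevant-first in the list's native orientation, ties broken by task
#' id.
#'
#' @param scores named numeric vector of feature scores (names = feature
#'   ids); \code{NA} entries are dropped.
#' @param task_map named character vector, feature id -> task id.
#' @param g number of features used to score each task (\code{Inf} for all).
#' @param type \code{"truth"}: smaller score = more relevant;
#'   \code{"prediction"}: larger score = more relevant.
#' @return List with \code{scores} (named per-task score) and \code{ranking}
#'   (task ids, most relevant first).
#' @export
task_score <- function(scores, task_map, g = 1,
                       type = c("truth", "prediction")) {
  type <- match.arg(type)
  if (g < 1) stop("g must be >= 1")
  scores <- scores[!is.na(scores)]
  feats <- intersect(names(scores), names(task_map))
  tasks <- unique(unname(task_map[feats]))
  ts <- vapply(tasks, function(tk) {
    f <- feats[task_map[feats] == tk]
    v <- scores[f]
    ord <- if (type == "truth") order(v, f) else order(-v, f)
    mean(v[ord][seq_len(min(g, length(v)))])
  }, numeric(1))
  names(ts) <- tasks
  rk <- if (type == "truth") names(ts)[order(ts, names(ts))]
        else names(ts)[order(-ts, names(ts))]
  list(scores = ts, ranking = rk)
}

#' Task hits at k (NH_g@k)
#'
#' Top-\code{k} intersection count between predicted and ground-truth task
#' rankings, each built by top-\code{g} task scoring (see [task_score()]).
#'
#' @param truth_tasks,pred_tasks character vectors of task ids, most relevant
#'   first.
#' @inheritParams qh_at_k
#' @return Integer in 0..k.
#' @export
nh_g_at_k <- function(truth_tasks, pred_tasks, k) {
  qh_at_k(truth_tasks, pred_tasks, k)
}

#' Evaluate a predicted ranking against ground truth for one patient
#'
#' Builds the ground-truth feature list (ascending normalized value, ties by
#' feature id) and the predicted list (descending score, ties by feature id)
#' over the evaluable (observed) features, plus task rankings via top-g
#' scoring, and returns QH@k, WQH@k and NH_g@k.
#'
#' @param truth_values named numeric vector of normalized ground-truth values
#'   (smaller = more AD-relevant); \code{NA} = not evaluable.
#' @param pred_scores named numeric vector of predicted scores over (at
#'   least) the same features.
#' @param task_map feature id -> task id; \code{NULL} skips task metrics.
#' @param k feature-list depth (capped at the number of evaluable features).
#' @param g_values integer vector of g for NH_g (\code{Inf} = all features).
#' @param k_task task-list depth(s) (capped at the number of evaluable
#'   tasks).
#' @return Named numeric vector of metric values.
#' @export
evaluate_ranking <- function(truth_values, pred_scores, task_map = NULL,
                             k = 5, g_values = c(1, 2, 3, 5, Inf),
                             k_task = 1) {
  obs <- names(truth_values)[!is.na(truth_values)]
  tv <- truth_values[obs]
  ps <- pred_scores[obs]
  truth_list <- names(tv)[order(tv, names(tv))]
  pred_list <- rank_by_score(ps)
  keff <- min(k, length(obs))
  out <- c(qh = qh_at_k(truth_list, pred_list, keff),
           wqh = wqh_at_k(truth_list, pred_list, keff))
  if (!is.null(task_map)) {
    for (g in g_values) {
      tt <- task_score(tv, task_map, g = g, type = "truth")$ranking
      pt <- task_score(ps, task_map, g = g, type = "prediction")$ranking
      for (kt in k_task) {
        kt_eff <- min(kt, length(tt))
        gl <- if (is.infinite(g)) "all" else g
        out[paste0("nh", gl, "_at_", kt)] <- nh_g_at_k(tt, pt, kt_eff)
      }
    }
  }
  out
}
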