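#' Fit a joint push and learning-to-rank model
#'
#' Learns d-dimensional latent vectors for patients (\code{U}) and cognitive
#' features (\code{V}) whose inner products score each feature for each
#' patient, by minimizing
#' \deqn{(1-\alpha)\,P + \alpha\,O + (\beta/2) R_{uv} + (\gamma/2) R_{csim}}
#' where \eqn{P} pushes relevant features above irrelevant ones, \eqn{O}
#' enforces the ground-truth order among relevant features, \eqn{R_{uv}}
#' shrinks the factors and \eqn{R_{csim}} pulls imaging-similar patients
#' toward similar latent vectors. The \code{"pltr"} variant optimizes a
#' logistic surrogate of the indicator losses; \code{"pltr_h"} optimizes
#' hinge losses with margins \code{margin_push} (\eqn{t_p}) and
#' \code{margin_order} (\eqn{t_o}) directly via subgradients.
#'
#' Optimization is full-batch Adam with a monotonicity safeguard: a step that
#' would increase the objective is rejected and the step size halved, so the
#' recorded objective trace is non-increasing. Initialization is i.i.d.
#' uniform(-0.01, 0.01) from \code{seed}; fits with identical inputs and seed
#' are bit-identical.
#'
#' @param x a \code{cogrank_normalized} cohort (see [preprocess_cohort()]), or
#'   a patients x features matrix of normalized values in [0, 1] with
#'   dimnames.
#' @param sim patient similarity (\code{cogrank_similarity} or matrix) aligned
#'   with the patients of \code{x}.
#' @param labels optional \code{cogrank_labels}; computed from \code{x} with
#'   [label_relevance()] at \code{relevance_quantile} when omitted.
#' @param variant \code{"pltr"} (smoothed indicator objective) or
#'   \code{"pltr_h"} (hinge objective).
#' @param d latent dimension.
#' @param alpha,beta,gamma objective weights; \code{alpha} in [0, 1],
#'   \code{beta}, \code{gamma} non-negative.
#' @param margin_push,margin_order hinge margins (defaults 0.3 and 0.1).
#' @param rho logistic surrogate scale for \code{"pltr"}.
#' @param learning_rate Adam step size.
#' @param max_iter maximum iterations.
#' @param tol relative objective-change convergence tolerance.
#' @param relevance_quantile cutoff used when \code{labels} is omitted.
#' @param seed integer seed controlling initialization.
#' @param verbose print progress every 100 iterations.
#' @return Object of class \code{pltr} with elements \code{U}, \code{V}
#'   (latent factors with id dimnames), \code{variant}, \code{trace}
#'   (per-iteration data frame: optimized \code{objective} plus the
#'   reported-loss breakdown \code{push}, \code{order}, \code{reg_uv},
#'   \code{reg_csim}, \code{total}), \code{loss} (final breakdown),
#'   \code{labels}, \code{hyperparameters}, \code{converged},
#'   \code{iterations}, \code{seed}, \code{call}. For \code{"pltr"} the
#'   reported push/order in \code{trace}/\code{loss} are the indicator
#'   losses (the quantities the objective surrogates); for \code{"pltr_h"}
#'   they are the hinge losses.
#' @seealso [predict.pltr()], [infer_holdout_latent()], [total_loss()]
#' @export
pltr <- function(x, sim, labels = NULL, variant = c("pltr", "pltr_h"),
                 d = 10, alpha = 0.5, beta = 0.5, gamma = 1,
                 margin_push = 0.3, margin_order = 0.1, rho = 0.1,
                 learning_rate = 0.01, max_iter = 2000, tol = 1e-6,
                 relevance_quantile = 0.5, seed = 1, verbose = FALSE) {
  variant <- match.arg(variant)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (beta < 0 || gamma < 0) stop("beta and gamma must be non-negative")
  if (d < 1) stop("latent dimension d must be >= 1")
  if (margin_push < 0 || margin_order < 0) stop("margins must be non-negative")

  values <- if (inherits(x, "cogrank_normalized")) x$values else x
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`x` must carry patient and feature ids as dimnames")
  patient_ids <- rownames(values)
  feature_ids <- colnames(values)
  m <- length(patient_ids); n <- length(feature_ids)
  if (is.null(labels))
    labels <- label_relevance(values, quantile = relevance_quantile)
  w <- sim_matrix(sim)
  if (!all(dim(w) == m)) stop("similarity matrix does not match the cohort")

  pairs <- build_pairs(labels, patient_ids, feature_ids)
  if (!length(pairs$push$p))
    stop("no (relevant, irrelevant) pair available for any patient")
  lap <- graph_laplacian(w)
  smooth <- if (variant == "pltr") "surrogate" else "hinge"

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  U <- matrix(stats::runif(d * m, -0.01, 0.01), d, m,
              dimnames = list(NULL, patient_ids))
  V <- matrix(stats::runif(d * n, -0.01, 0.01), d, n,
              dimnames = list(NULL, feature_ids))

  eval_obj <- function(U, V)
    objective_grad(U, V, pairs, lap, alpha, beta, gamma, smooth,
                   margin_push, margin_order, rho)

  # Adam state
  mu_U <- mu_V <- nu_U <- nu_V <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- learning_rate
  lr_min <- learning_rate * 1e-6

  cur <- eval_obj(U, V)
  trace <- vector("list", max_iter + 1L)
  trace[[1L]] <- c(iter = 0, objective = cur$objective, cur$components,
                   total = NA_real_)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mu_U <- b1 * mu_U + (1 - b1) * cur$gU
    mu_V <- b1 * mu_V + (1 - b1) * cur$gV
    nu_U <- b2 * nu_U + (1 - b2) * cur$gU^2
    nu_V <- b2 * nu_V + (1 - b2) * cur$gV^2
    corr1 <- 1 - b1^it; corr2 <- 1 - b2^it
    step_U <- (mu_U / corr1) / (sqrt(nu_U / corr2) + eps)
    step_V <- (mu_V / corr1) / (sqrt(nu_V / corr2) + eps)

    accepted <- FALSE
    while (!accepted && lr >= lr_min) {
      U_new <- U - lr * step_U
      V_new <- V - lr * step_V
      nxt <- eval_obj(U_new, V_new)
      if (!is.finite(nxt$objective))
        stop("non-finite objective at iteration ", it,
             " (lr = ", lr, "); inspect the inputs or lower learning_rate")
      if (nxt$objective <= cur$objective * (1 + 1e-12) + 1e-15) {
        accepted <- TRUE
      } else {
        lr <- lr / 2
      }
    }
    if (!accepted) { it <- it - 1L; converged <- TRUE; break }
    rel_change <- abs(cur$objective - nxt$objective) /
      max(abs(cur$objective), .Machine$double.eps)
    U <- U_new; V <- V_new; cur <- nxt
    trace[[it + 1L]] <- c(iter = it, objective = cur$objective,
                          cur$components, total = NA_real_)
    if (verbose && it %% 100L == 0L)
      message(sprintf("iter %5d  objective %.8g", it, cur$objective))
    if (rel_change < tol) { converged <- TRUE; break }
  }

  trace <- as.data.frame(do.call(rbind, trace[!vapply(trace, is.null, TRUE)]))
  report_type <- if (variant == "pltr") "indicator" else "hinge"
  # Reported breakdown follows the model's defining losses (indicator for
  # PLTR, hinge for PLTR_h); the surrogate objective column is kept alongside.
  final <- total_loss(U, V, labels, w, alpha, beta, gamma,
                      variant = report_type,
                      margin_push = margin_push, margin_order = margin_order,
                      rho = rho)
  # push/order in the trace are the model's reported losses (indicator for
  # pltr, hinge for pltr_h); `objective` is the optimized smooth/hinge value
  trace$total <- (1 - alpha) * trace$push + alpha * trace$order +
    beta / 2 * trace$reg_uv + gamma / 2 * trace$reg_csim

  structure(list(U = U, V = V, variant = variant, trace = trace,
                 loss = final, labels = labels,
                 hyperparameters = list(d = d, alpha = alpha, beta = beta,
                                        gamma = gamma,
                                        margin_push = margin_push,
                                        margin_order = margin_order,
                                        rho = rho,
                                        learning_rate = learning_rate,
                                        max_iter = max_iter, tol = tol,
                                        relevance_quantile = relevance_quantile),
                 converged = converged, iterations = it, seed = seed,
                 patient_ids = patient_ids, feature_ids = feature_ids,
                 task_map = if (inherits(x, "cogrank_normalized")) x$task_map,
                 call = match.call()),
            class = "pltr")
}

#' @export
print.pltr <- function(x, ...) {
  hp <- x$hyperparameters
  cat(sprintf("%s model: %d patients x %d features, d = %d\n",
              toupper(x$variant), length(x$patient_ids),
              length(x$feature_ids), hp$d))
  cat(sprintf("  alpha %.2f  beta %.2f  gamma %.2f", hp$alpha, hp$beta, hp$gamma))
  if (x$variant == "pltr_h")
    cat(sprintf("  t_p %.2f  t_o %.2f", hp$margin_push, hp$margin_order))
  cat("\n")
  cat(sprintf("  %d iterations (%s), final objective %.6g\n", x$iterations,
              if (x$converged) "converged" else "max_iter reached",
              x$trace$objective[nrow(x$trace)]))
  print(x$loss)
  invisible(x)
}

#' @export
summary.pltr <- function(object, ...) {
  out <- list(variant = object$variant,
              dims = c(patients = length(object$patient_ids),
                       features = length(object$feature_ids),
                       d = object$hyperparameters$d),
              hyperparameters = object$hyperparameters,
              loss = object$loss,
              converged = object$converged,
              iterations = object$iterations,
              seed = object$seed)
  class(out) <- "summary.pltr"
  out
}

#' @export
print.summary.pltr <- function(x, ...) {
  cat(toupper(x$variant), "fit summary\n")
  cat("  patients:", x$dims["patients"], " features:", x$dims["features"],
      " latent d:", x$dims["d"], "\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(max_iter)", " seed:", x$seed, "\n")
  cat("  final loss: "); print(x$loss)
  invisible(x)
}

#' @export
coef.pltr <- function(object, ...) {
  list(U = object$U, V = object$V)
}

#' @export
fitted.pltr <- function(object, ...) {
  score_features(object$U, object$V)
}

#' Predict feature scores or rankings
#'
#' For fitted (training) patients, returns their bilinear scores or the
#' induced feature ranking. For new (cold-start) patients, supply
#' \code{newdata}: one row of imaging-derived similarities to the training
#' patients per new patient; their latent vectors are inferred with
#' [infer_holdout_latent()] and then scored.
#'
#' @param object a fitted \code{pltr} model.
#' @param newdata optional numeric matrix (new patients x training patients)
#'   or vector of similarities; columns must align with (or be named by) the
#'   training patients.
#' @param type \code{"scores"} for the score matrix, \code{"ranking"} for a
#'   per-patient list of feature ids ordered most-relevant first (descending
#'   score, ties broken by feature id).
#' @param k_neighbors neighbourhood size for cold-start inference.
#' @param ... unused.
#' @return Score matrix or named list of character vectors.
#' @export
predict.pltr <- function(object, newdata = NULL,
                         type = c("scores", "ranking"), k_neighbors = 10, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    s <- fitted(object)
  } else {
    if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
    if (!is.null(colnames(newdata)))
      newdata <- newdata[, object$patient_ids, drop = FALSE]
    if (ncol(newdata) != length(object$patient_ids))
      stop("`newdata` must have one similarity per training patient")
    Unew <- vapply(seq_len(nrow(newdata)), function(i)
      infer_holdout_latent(newdata[i, ], object$U, k_neighbors = k_neighbors),
      numeric(nrow(object$U)))
    Unew <- matrix(Unew, nrow = nrow(object$U))
    colnames(Unew) <- rownames(newdata)
    s <- score_features(Unew, object$V)
  }
  if (type == "scores") return(s)
  out <- lapply(seq_len(nrow(s)), function(i) rank_by_score(s[i, ]))
  names(out) <- rownames(s)
  out
}

# Descending score, ties by feature id (stable, deterministic).
rank_by_score <- function(scores) {
  names(scores)[order(-scores, names(scores), method = "radix")]
}

#' @export
plot.pltr <- function(x, ...) {
  graphics::plot(x$trace$iter, x$trace$objective, type = "l",
                 xlab = "iteration", ylab = "optimized objective",
                 main = paste(toupper(x$variant), "loss trace"), ...)
  invisible(x)
}

#' Infer a latent vector for a held-out patient
#'
#' Cold-start mechanism for leave-out validation: a new patient with imaging
#' data but no cognitive data receives the similarity-weighted average of the
#' latent vectors of their \code{k_neighbors} most similar training patients,
#' \eqn{u_{new} = \sum_{q \in topK} w_q u_q / \sum w_q}. An exact imaging
#' duplicate of a training patient (similarity 1 within 1e-12) receives that
#' patient's vector exactly.
#'
#' @param sim_row numeric vector of similarities to the training patients
#'   (aligned with the columns of \code{U_train}).
#' @param U_train d x m latent matrix of the fitted training patients.
#' @param k_neighbors how many top-similarity neighbours to average
#'   (default 10).
#' @return Latent vector of length d.
#' @export
infer_holdout_latent <- function(sim_row, U_train, k_neighbors = 10) {
  if (length(sim_row) != ncol(U_train))
    stop("similarity row does not match the training patients")
  if (all(sim_row <= 0)) stop("all similarities are zero; patient not inferable")
  exact <- which(sim_row >= 1 - 1e-12)
  if (length(exact))
    return(rowMeans(U_train[, exact, drop = FALSE]))
  k <- min(k_neighbors, sum(sim_row > 0))
  top <- order(-sim_row, seq_along(sim_row))[seq_len(k)]
  w <- sim_row[top]
  as.vector(U_train[, top, drop = FALSE] %*% w) / sum(w)
}

#' Save or load a model checkpoint
#'
#' A checkpoint is a single RDS archive holding the whole fitted object
#' (factors, hyperparameters, seed, loss trace); the round trip is lossless.
#'
#' @param object a \code{pltr} fit.
#' @param path file path.
#' @return \code{write_pltr} returns \code{path} invisibly; \code{read_pltr}
#'   the restored \code{pltr} object.
#' @export
write_pltr <- function(object, path) {
  stopifnot(inherits(object, "pltr"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_pltr
#' @export
read_pltr <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "pltr")) stop("not a pltr checkpoint: ", path)
  obj
}
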