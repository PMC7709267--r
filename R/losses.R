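#' Score all features for all patients
#'
#' Bilinear scoring: the score of feature \eqn{f_i} for patient \eqn{p} is the
#' inner product \eqn{s_p(f_i) = u_p^T v_i} of their latent vectors. Higher
#' score means predicted more AD-relevant.
#'
#' @param U d x m latent patient matrix (one column per patient).
#' @param V d x n latent feature matrix (one column per feature).
#' @return m x n score matrix carrying the column names of \code{U} (rows)
#'   and \code{V} (columns).
#' @export
score_features <- function(U, V) {
  if (nrow(U) != nrow(V)) stop("U and V must share the latent dimension")
  crossprod(U, V)
}

#' Logistic surrogate for the step indicator
#'
#' Smooth stand-in for \eqn{I(\mathrm{margin} \le 0)} used to optimize the
#' indicator-based objective: \eqn{1 / (1 + e^{\mathrm{margin}/\rho})}. As
#' \eqn{\rho \to 0^+} it converges pointwise to the indicator away from 0 and
#' equals 0.5 at margin 0.
#'
#' @param margin numeric vector of score margins.
#' @param rho positive scale; smaller = sharper.
#' @return Values in (0, 1).
#' @export
surrogate_sigmoid <- function(margin, rho = 0.1) {
  if (rho <= 0) stop("rho must be positive")
  stats::plogis(-margin / rho)
}

# Flatten relevance labels into integer pair-index arrays against a score
# matrix layout (m patients x n features, linear column-major indices).
# Push pairs: every (relevant, irrelevant) combination, weight 1/(n+ n-).
# Order pairs: every ordered relevant pair (i more relevant than j),
# weight 1/#pairs. Patients lacking either set (push) or with < 2 relevant
# features (order) contribute no pairs.
build_pairs <- function(labels, patient_ids, feature_ids) {
  m <- length(patient_ids)
  fidx <- stats::setNames(seq_along(feature_ids), feature_ids)
  pp <- pf1 <- pf2 <- pw <- list()   # push: f1 = relevant, f2 = irrelevant
  op <- of1 <- of2 <- ow <- list()   # order: f1 more relevant than f2
  for (k in seq_len(m)) {
    p <- patient_ids[k]
    rel <- labels$relevant[[p]]
    irr <- labels$irrelevant[[p]]
    nr <- length(rel); ni <- length(irr)
    if (nr >= 1L && ni >= 1L) {
      g <- expand.grid(r = fidx[rel], i = fidx[irr], KEEP.OUT.ATTRS = FALSE)
      pp[[p]]  <- rep.int(k, nr * ni)
      pf1[[p]] <- g$r; pf2[[p]] <- g$i
      pw[[p]]  <- rep.int(1 / (nr * ni), nr * ni)
    }
    if (nr >= 2L) {
      ri <- fidx[rel]                       # already ordered most-relevant first
      hi <- lo <- integer(0)
      for (a in seq_len(nr - 1L)) {
        hi <- c(hi, rep.int(ri[a], nr - a))
        lo <- c(lo, ri[(a + 1L):nr])
      }
      np <- length(hi)
      op[[p]]  <- rep.int(k, np)
      of1[[p]] <- hi; of2[[p]] <- lo
      ow[[p]]  <- rep.int(1 / np, np)
    }
  }
  cat0 <- function(l) if (length(l)) unlist(l, use.names = FALSE) else integer(0)
  push <- list(p = cat0(pp), f_pos = cat0(pf1), f_neg = cat0(pf2), w = cat0(pw))
  ord  <- list(p = cat0(op), f_hi = cat0(of1), f_lo = cat0(of2), w = cat0(ow))
  push$i_pos <- (push$f_pos - 1L) * m + push$p
  push$i_neg <- (push$f_neg - 1L) * m + push$p
  ord$i_hi <- (ord$f_hi - 1L) * m + ord$p
  ord$i_lo <- (ord$f_lo - 1L) * m + ord$p
  list(push = push, order = ord, m = m, n = length(feature_ids))
}

# Coerce a scores matrix + labels into pair structure, reusing dimnames.
pairs_from_scores <- function(scores, labels) {
  build_pairs(labels, rownames(scores), colnames(scores))
}

#' Push loss: relevant features ranked below irrelevant ones
#'
#' For each patient, averages over all (relevant, irrelevant) feature pairs a
#' penalty on the margin \eqn{s_p(f^+) - s_p(f^-)}, then sums over patients.
#' \code{"indicator"} counts violations with ties penalized
#' (\eqn{I(s^+ \le s^-)}); \code{"hinge"} uses
#' \eqn{\max(0, t_p - (s^+ - s^-))}; \code{"surrogate"} the logistic
#' surrogate. Patients flagged as one-sided (no relevant or no irrelevant
#' features) contribute nothing.
#'
#' @param scores m x n score matrix with patient row names and feature column
#'   names (e.g. from [score_features()]).
#' @param labels a \code{cogrank_labels}.
#' @param type penalty type.
#' @param margin hinge margin \eqn{t_p} (default 0.3; only used for hinge).
#' @param rho surrogate scale (only used for surrogate).
#' @return Scalar loss.
#' @export
push_loss <- function(scores, labels, type = c("indicator", "hinge", "surrogate"),
                      margin = 0.3, rho = 0.1) {
  type <- match.arg(type)
  pr <- pairs_from_scores(scores, labels)$push
  mg <- scores[pr$i_pos] - scores[pr$i_neg]
  sum(pr$w * pair_penalty(mg, type, margin, rho, ties_violate = TRUE))
}

#' Ordering loss among relevant features
#'
#' For each patient with at least two relevant features, averages over all
#' ordered relevant pairs (\eqn{f_i} ground-ranked above \eqn{f_j}) a penalty
#' on the margin \eqn{s_p(f_i) - s_p(f_j)}, then sums over patients.
#' \code{"indicator"} counts strict inversions only (\eqn{I(s_i < s_j)}; ties
#' are not violations); \code{"hinge"} uses \eqn{\max(0, t_o - (s_i - s_j))}.
#'
#' @inheritParams push_loss
#' @param margin hinge margin \eqn{t_o} (default 0.1).
#' @return Scalar loss.
#' @export
order_loss <- function(scores, labels, type = c("indicator", "hinge", "surrogate"),
                       margin = 0.1, rho = 0.1) {
  type <- match.arg(type)
  pr <- pairs_from_scores(scores, labels)$order
  mg <- scores[pr$i_hi] - scores[pr$i_lo]
  sum(pr$w * pair_penalty(mg, type, margin, rho, ties_violate = FALSE))
}

pair_penalty <- function(mg, type, margin, rho, ties_violate) {
  switch(type,
    indicator = if (ties_violate) as.numeric(mg <= 0) else as.numeric(mg < 0),
    hinge     = pmax(0, margin - mg),
    surrogate = surrogate_sigmoid(mg, rho))
}

#' Latent-factor norm regularizer
#'
#' \eqn{R_{uv} = \|U\|_F^2 / m + \|V\|_F^2 / n}, penalizing large latent
#' vectors, averaged per patient and per feature.
#'
#' @inheritParams score_features
#' @return Scalar.
#' @export
reg_uv <- function(U, V) {
  sum(U^2) / ncol(U) + sum(V^2) / ncol(V)
}

#' Similarity-graph regularizer on patient vectors
#'
#' \eqn{R_{csim} = m^{-2} \sum_{p,q} w_{pq} \|u_p - u_q\|^2}: patients with
#' similar imaging profiles are pulled toward similar latent vectors.
#'
#' @param U d x m latent patient matrix.
#' @param sim patient similarity (\code{cogrank_similarity} or m x m matrix).
#' @return Scalar.
#' @export
reg_csim <- function(U, sim) {
  w <- sim_matrix(sim)
  m <- ncol(U)
  if (!all(dim(w) == m)) stop("similarity matrix does not match U")
  g <- crossprod(U)                       # g_pq = u_p . u_q
  d <- diag(g)
  dsq <- outer(d, rep(1, m)) + outer(rep(1, m), d) - 2 * g
  sum(w * dsq) / m^2
}

#' Combined objective with component breakdown
#'
#' Weighted combination
#' \eqn{(1-\alpha)\,P + \alpha\,O + (\beta/2) R_{uv} + (\gamma/2) R_{csim}}
#' of the push, ordering and two regularization terms, with the push/order
#' penalty chosen by \code{variant}: \code{"indicator"} (the PLTR objective as
#' evaluated), \code{"hinge"} (the PLTR_h objective), or \code{"surrogate"}
#' (the smooth objective actually optimized for PLTR).
#'
#' @inheritParams score_features
#' @inheritParams reg_csim
#' @param labels a \code{cogrank_labels}.
#' @param alpha,beta,gamma component weights.
#' @param variant penalty type for the two ranking terms.
#' @param margin_push,margin_order hinge margins \eqn{t_p}, \eqn{t_o}.
#' @param rho surrogate scale.
#' @return List of class \code{cogrank_loss}: \code{push}, \code{order},
#'   \code{reg_uv}, \code{reg_csim}, \code{total}.
#' @export
total_loss <- function(U, V, labels, sim, alpha = 0.5, beta = 0.5, gamma = 1,
                       variant = c("indicator", "hinge", "surrogate"),
                       margin_push = 0.3, margin_order = 0.1, rho = 0.1) {
  variant <- match.arg(variant)
  s <- score_features(U, V)
  p <- push_loss(s, labels, type = variant, margin = margin_push, rho = rho)
  o <- order_loss(s, labels, type = variant, margin = margin_order, rho = rho)
  ru <- reg_uv(U, V)
  rc <- reg_csim(U, sim)
  structure(list(push = p, order = o, reg_uv = ru, reg_csim = rc,
                 total = (1 - alpha) * p + alpha * o +
                         beta / 2 * ru + gamma / 2 * rc),
            class = "cogrank_loss")
}

#' @export
print.cogrank_loss <- function(x, ...) {
  cat(sprintf("push %.6g  order %.6g  reg_uv %.6g  reg_csim %.6g  total %.6g\n",
              x$push, x$order, x$reg_uv, x$reg_csim, x$total))
  invisible(x)
}

# Objective and analytic gradient of the optimized objective (surrogate for
# PLTR, hinge subgradient for PLTR_h; 0 at the hinge kink). `pairs` from
# build_pairs(); `lap` = graph Laplacian of the similarity (D - W).
# Returns list(objective, components, gU, gV).
objective_grad <- function(U, V, pairs, lap, alpha, beta, gamma,
                           smooth = c("surrogate", "hinge"),
                           margin_push = 0.3, margin_order = 0.1, rho = 0.1) {
  smooth <- match.arg(smooth)
  m <- pairs$m; n <- pairs$n
  S <- crossprod(U, V)
  gS_num <- numeric(m * n)

  eval_term <- function(pr, i_hi, i_lo, margin, ties_violate) {
    mg <- S[pr[[i_hi]]] - S[pr[[i_lo]]]
    if (smooth == "surrogate") {
      l <- stats::plogis(-mg / rho)
      dl <- -l * (1 - l) / rho
      # report the indicator loss the surrogate stands in for
      rep_loss <- sum(pr$w * (if (ties_violate) mg <= 0 else mg < 0))
    } else {
      l <- pmax(0, margin - mg)
      dl <- -as.numeric(mg < margin)
      rep_loss <- sum(pr$w * l)
    }
    loss <- sum(pr$w * l)
    cw <- pr$w * dl
    # accumulate d loss / d S at the two pair endpoints
    idx <- c(pr[[i_hi]], pr[[i_lo]])
    val <- c(cw, -cw)
    agg <- rowsum(val, idx, reorder = FALSE)
    list(loss = loss, rep_loss = rep_loss,
         idx = as.integer(rownames(agg)), val = as.vector(agg))
  }

  pu <- eval_term(pairs$push, "i_pos", "i_neg", margin_push, TRUE)
  gS_num[pu$idx] <- gS_num[pu$idx] + (1 - alpha) * pu$val
  or <- eval_term(pairs$order, "i_hi", "i_lo", margin_order, FALSE)
  gS_num[or$idx] <- gS_num[or$idx] + alpha * or$val
  gS <- matrix(gS_num, m, n)

  ru <- sum(U^2) / m + sum(V^2) / n
  rc <- 2 * sum(U * (U %*% lap)) / m^2

  obj <- (1 - alpha) * pu$loss + alpha * or$loss +
         beta / 2 * ru + gamma / 2 * rc
  gU <- V %*% t(gS) + (beta / m) * U + (2 * gamma / m^2) * (U %*% lap)
  gV <- U %*% gS + (beta / n) * V
  list(objective = obj,
       components = c(push = pu$rep_loss, order = or$rep_loss,
                      reg_uv = ru, reg_csim = rc),
       gU = gU, gV = gV)
}

graph_laplacian <- function(w) {
  diag(rowSums(w)) - w
}
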