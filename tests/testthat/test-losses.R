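test_that("bilinear scores equal entrywise dot products", {
  set.seed(10)
  d <- 3; m <- 4; n <- 6
  U <- matrix(rnorm(d * m), d, m, dimnames = list(NULL, paste0("p", 1:m)))
  V <- matrix(rnorm(d * n), d, n, dimnames = list(NULL, paste0("f", 1:n)))
  s <- score_features(U, V)
  naive <- matrix(0, m, n)
  for (p in 1:m) for (f in 1:n) naive[p, f] <- sum(U[, p] * V[, f])
  expect_equal(unname(s), naive)
  expect_equal(unname(score_features(matrix(c(1, 2), 2), matrix(c(3, -1), 2))[1, 1]), 1)
  U[, 1] <- 0
  expect_equal(unname(score_features(U, V)[1, ]), rep(0, n))
})

test_that("push loss handles separation, inversion and partial overlap", {
  lab <- make_labels(list(p1 = c("r1", "r2")), list(p1 = "i1"))
  expect_equal(push_loss(score_row(r1 = 0.9, r2 = 0.8, i1 = 0.5), lab), 0)
  lab2 <- make_labels(list(p1 = "r1"), list(p1 = c("i1", "i2")))
  expect_equal(push_loss(score_row(r1 = 0.4, i1 = 0.6, i2 = 0.7), lab2), 1)
  lab3 <- make_labels(list(p1 = c("r1", "r2")), list(p1 = "i1"))
  expect_equal(push_loss(score_row(r1 = 0.7, r2 = 0.3, i1 = 0.5), lab3), 0.5)
  # ties count as violations in the push term
  expect_equal(push_loss(score_row(r1 = 0.5, r2 = 0.5, i1 = 0.5), lab3), 1)
})

test_that("order loss counts strict inversions over ordered relevant pairs", {
  lab <- make_labels(list(p1 = c("f1", "f2", "f3")),
                     list(p1 = "i1"))
  expect_equal(order_loss(score_row(f1 = 3, f2 = 2, f3 = 1, i1 = 0), lab), 0)
  expect_equal(order_loss(score_row(f1 = 1, f2 = 2, f3 = 3, i1 = 0), lab), 1)
  expect_equal(order_loss(score_row(f1 = 2, f2 = 3, f3 = 1, i1 = 0), lab), 1 / 3)
  # ties are not order violations
  expect_equal(order_loss(score_row(f1 = 1, f2 = 1, f3 = 1, i1 = 0), lab), 0)
})

test_that("hinge losses follow the margin closed forms", {
  lab <- make_labels(list(p1 = "r1"), list(p1 = "i1"))
  expect_equal(push_loss(score_row(r1 = 0.9, i1 = 0.5), lab, type = "hinge",
                         margin = 0.3), 0)
  expect_equal(push_loss(score_row(r1 = 0.6, i1 = 0.5), lab, type = "hinge",
                         margin = 0.3), 0.2)
  lab2 <- make_labels(list(p1 = c("f1", "f2")), list(p1 = "i1"))
  expect_equal(order_loss(score_row(f1 = 1.0, f2 = 0.5, i1 = 0), lab2,
                          type = "hinge", margin = 0.1), 0)
  expect_equal(order_loss(score_row(f1 = 0.55, f2 = 0.5, i1 = 0), lab2,
                          type = "hinge", margin = 0.1), 0.05)
  # equal scores: each pair is charged the full margin
  expect_equal(order_loss(score_row(f1 = 0.5, f2 = 0.5, i1 = 0), lab2,
                          type = "hinge", margin = 0.1), 0.1)
  # hinge loss is monotone in the margin
  set.seed(11)
  inst <- random_instance()
  expect_lte(push_loss(inst$scores, inst$labels, type = "hinge", margin = 0),
             push_loss(inst$scores, inst$labels, type = "hinge", margin = 0.3))
})

test_that("vectorized losses match brute-force pair enumeration", {
  set.seed(12)
  for (trial in 1:50) {
    inst <- random_instance(m = sample(1:5, 1))
    for (type in c("indicator", "hinge", "surrogate")) {
      expect_equal(push_loss(inst$scores, inst$labels, type = type),
                   oracle_push(inst$scores, inst$labels, type = type),
                   tolerance = 1e-12)
      expect_equal(order_loss(inst$scores, inst$labels, type = type),
                   oracle_order(inst$scores, inst$labels, type = type),
                   tolerance = 1e-12)
    }
  }
})

test_that("regularizers follow their closed forms and scaling laws", {
  expect_equal(reg_uv(matrix(0, 2, 3), matrix(0, 2, 4)), 0)
  expect_equal(reg_uv(matrix(2, 1, 1), matrix(3, 1, 1)), 13)
  set.seed(13)
  U <- matrix(rnorm(6), 2, 3); V <- matrix(rnorm(8), 2, 4)
  # doubling U quadruples the U term
  expect_equal(reg_uv(2 * U, V) - reg_uv(U, V), 3 * sum(U^2) / 3)

  # identical patient vectors: zero graph penalty for any similarity
  w <- matrix(runif(9), 3, 3); w <- (w + t(w)) / 2; diag(w) <- 1
  expect_equal(reg_csim(matrix(1, 2, 3), w), 0)
  # hand evaluation at m = 2
  U2 <- cbind(c(1, 0), c(0, 1))
  w2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(reg_csim(U2, w2), 0.5)
  # translation invariance
  expect_equal(reg_csim(U + 5, w), reg_csim(U, w))
})

test_that("total loss recombines its reported components", {
  set.seed(14)
  inst <- random_instance(m = 4)
  m <- nrow(inst$scores)
  d <- 3
  U <- matrix(rnorm(d * m), d, m, dimnames = list(NULL, rownames(inst$scores)))
  V <- matrix(rnorm(d * ncol(inst$scores)), d, ncol(inst$scores),
              dimnames = list(NULL, colnames(inst$scores)))
  w <- rbf_similarity(matrix(rnorm(m * 2), m), sigma = 1)$w
  for (variant in c("indicator", "hinge", "surrogate")) {
    tl <- total_loss(U, V, inst$labels, w, alpha = 0.3, beta = 0.7,
                     gamma = 0.2, variant = variant)
    expect_equal(tl$total,
                 0.7 * tl$push + 0.3 * tl$order +
                   0.35 * tl$reg_uv + 0.1 * tl$reg_csim)
  }
  # alpha = 1 keeps only the order term; alpha = 0 only the push term
  t1 <- total_loss(U, V, inst$labels, w, alpha = 1, beta = 0, gamma = 0)
  expect_equal(t1$total, t1$order)
  t0 <- total_loss(U, V, inst$labels, w, alpha = 0, beta = 0, gamma = 0)
  expect_equal(t0$total, t0$push)
})

test_that("losses are non-negative and bounded by the patient count", {
  set.seed(15)
  for (trial in 1:20) {
    m <- sample(1:5, 1)
    inst <- random_instance(m = m)
    p <- push_loss(inst$scores, inst$labels)
    o <- order_loss(inst$scores, inst$labels)
    expect_gte(p, 0); expect_lte(p, m)
    expect_gte(o, 0); expect_lte(o, m)
  }
})

test_that("logistic surrogate interpolates the indicator", {
  expect_equal(surrogate_sigmoid(0, 0.1), 0.5)
  expect_equal(surrogate_sigmoid(100, 0.1), 0)
  expect_equal(surrogate_sigmoid(-100, 0.1), 1)
  # rho -> 0 converges pointwise to the indicator away from 0
  expect_equal(surrogate_sigmoid(0.05, 1e-4), 0)
  expect_equal(surrogate_sigmoid(-0.05, 1e-4), 1)
  expect_error(surrogate_sigmoid(0, 0), "positive")
})

test_that("per-patient push loss equals one minus AUC with ties as violations", {
  set.seed(16)
  for (trial in 1:200) {
    npos <- sample(1:8, 1); nneg <- sample(1:8, 1)
    pos <- round(rnorm(npos), 1)   # rounding forces occasional ties
    neg <- round(rnorm(nneg), 1)
    sc <- c(pos, neg)
    names(sc) <- c(paste0("r", seq_len(npos)), paste0("i", seq_len(nneg)))
    lab <- make_labels(list(p1 = names(sc)[seq_len(npos)]),
                       list(p1 = names(sc)[npos + seq_len(nneg)]))
    expect_equal(push_loss(matrix(sc, 1, dimnames = list("p1", names(sc))), lab),
                 1 - oracle_auc(pos, neg))
  }
})

test_that("scores and losses are gauge-invariant under shared rotations", {
  set.seed(17)
  d <- 4
  inst <- random_instance(m = 3)
  U <- matrix(rnorm(d * 3), d, 3, dimnames = list(NULL, rownames(inst$scores)))
  V <- matrix(rnorm(d * ncol(inst$scores)), d, ncol(inst$scores),
              dimnames = list(NULL, colnames(inst$scores)))
  Q <- qr.Q(qr(matrix(rnorm(d * d), d)))
  expect_equal(score_features(Q %*% U, Q %*% V), score_features(U, V))
  w <- diag(3) * 0 + 0.5; diag(w) <- 1
  l1 <- total_loss(U, V, inst$labels, w)
  l2 <- total_loss(Q %*% U, Q %*% V, inst$labels, w)
  expect_equal(l1$total, l2$total)
})

test_that("push and order losses decompose across patient groups", {
  # with fixed factors the ranking terms are per-patient sums, so any
  # split of the patients partitions the loss exactly
  set.seed(18)
  inst <- random_instance(m = 6)
  lab <- inst$labels
  ids <- names(lab$relevant)
  g1 <- ids[1:3]; g2 <- ids[4:6]
  sub <- function(g) make_labels(lab$relevant[g], lab$irrelevant[g])
  expect_equal(push_loss(inst$scores, lab),
               push_loss(inst$scores[g1, , drop = FALSE], sub(g1)) +
                 push_loss(inst$scores[g2, , drop = FALSE], sub(g2)))
  expect_equal(order_loss(inst$scores, lab),
               order_loss(inst$scores[g1, , drop = FALSE], sub(g1)) +
                 order_loss(inst$scores[g2, , drop = FALSE], sub(g2)))
})
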