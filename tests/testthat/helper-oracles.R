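# Shared fixtures and independent brute-force oracles. Oracles are written
# as naive loops straight from the definitions and never share code with the
# package internals they check.

# Build a cogrank_labels object directly from explicit sets. `relevant` must
# be ordered most-relevant first.
make_labels <- function(relevant, irrelevant, quantile = 0.5) {
  structure(list(relevant = relevant, irrelevant = irrelevant,
                 quantile = quantile, flagged = character(0)),
            class = "cogrank_labels")
}

# One-row score matrix with feature names.
score_row <- function(..., patient = "p1") {
  v <- c(...)
  matrix(v, 1, dimnames = list(patient, names(v)))
}

# Random labelled instance: m patients, per-patient relevant/irrelevant
# sets of size 1..max_side over a shared feature pool, plus random scores.
random_instance <- function(m = 3, max_side = 8, n_features = 20) {
  feats <- sprintf("f%02d", seq_len(n_features))
  rel <- irr <- list()
  for (p in paste0("p", seq_len(m))) {
    nr <- sample.int(max_side, 1); ni <- sample.int(max_side, 1)
    pick <- sample(feats, nr + ni)
    rel[[p]] <- pick[seq_len(nr)]
    irr[[p]] <- pick[nr + seq_len(ni)]
  }
  scores <- matrix(rnorm(m * n_features), m, n_features,
                   dimnames = list(names(rel), feats))
  list(labels = make_labels(rel, irr), scores = scores)
}

# Triple-loop push loss straight from the definition.
oracle_push <- function(scores, labels, type = "indicator",
                        margin = 0.3, rho = 0.1) {
  total <- 0
  for (p in names(labels$relevant)) {
    rel <- labels$relevant[[p]]; irr <- labels$irrelevant[[p]]
    if (!length(rel) || !length(irr)) next
    acc <- 0
    for (fm in irr) for (fp in rel) {
      mg <- scores[p, fp] - scores[p, fm]
      acc <- acc + switch(type,
        indicator = as.numeric(mg <= 0),
        hinge = max(0, margin - mg),
        surrogate = 1 / (1 + exp(mg / rho)))
    }
    total <- total + acc / (length(rel) * length(irr))
  }
  total
}

# Loop over ordered relevant pairs straight from the definition.
oracle_order <- function(scores, labels, type = "indicator",
                         margin = 0.1, rho = 0.1) {
  total <- 0
  for (p in names(labels$relevant)) {
    rel <- labels$relevant[[p]]
    if (length(rel) < 2) next
    acc <- 0; npairs <- 0
    for (a in seq_len(length(rel) - 1)) for (b in (a + 1):length(rel)) {
      mg <- scores[p, rel[a]] - scores[p, rel[b]]
      npairs <- npairs + 1
      acc <- acc + switch(type,
        indicator = as.numeric(mg < 0),
        hinge = max(0, margin - mg),
        surrogate = 1 / (1 + exp(mg / rho)))
    }
    total <- total + acc / npairs
  }
  total
}

# AUC counting strictly-greater pairs only (ties are not credited).
oracle_auc <- function(pos, neg) {
  hits <- 0
  for (a in pos) for (b in neg) hits <- hits + (a > b)
  hits / (length(pos) * length(neg))
}

# Set-intersection metric oracles.
oracle_qh <- function(truth, pred, k) {
  hits <- 0L
  for (i in seq_len(k)) hits <- hits + (pred[i] %in% truth[seq_len(k)])
  hits
}
oracle_wqh <- function(truth, pred, k) {
  s <- 0
  for (j in seq_len(k)) s <- s + oracle_qh(truth, pred, j)
  s / k
}

# Central finite-difference gradient of a scalar function of (U, V).
numeric_grad <- function(f, U, V, h = 1e-6) {
  th <- c(U, V)
  g <- numeric(length(th))
  for (i in seq_along(th)) {
    tp <- th; tp[i] <- tp[i] + h
    tm <- th; tm[i] <- tm[i] - h
    g[i] <- (f(tp) - f(tm)) / (2 * h)
  }
  g
}

# Small deterministic raw cohort used across preprocessing tests: feature
# "good" separates groups, "flat" is constant, "reversed" has patients
# scoring higher than controls.
tiny_cohort <- function() {
  cog <- cbind(good = c(1, 2, 3, 4, 5, 6, 14, 15, 16, 17),
               reversed = c(9, 10, 11, 12, 13, 14, 2, 3, 4, 5),
               flat = rep(1, 10))
  rownames(cog) <- sprintf("s%02d", 1:10)
  img <- matrix(seq_len(20) + rep(c(0, 0, 0, 0, 0, 0, 9, 9, 9, 9), 2), 10, 2,
                dimnames = list(rownames(cog), c("i1", "i2")))
  cohort(cog, img, c(rep("MCI", 3), rep("AD", 3), rep("HC", 4)),
         c(good = "t1", reversed = "t1", flat = "t2"))
}
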