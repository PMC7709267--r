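test_that("group-difference screen matches the closed-form Welch test", {
  # independent oracle: Welch statistic and Welch-Satterthwaite df by hand
  welch_p <- function(x, y) {
    v1 <- var(x) / length(x); v2 <- var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
    2 * pt(-abs(t), df)
  }
  pats <- c(1, 2, 3); ctrl <- c(4, 5, 6)
  expect_equal(welch_p(pats, ctrl), 0.02131164, tolerance = 1e-6)

  cog <- cbind(f1 = c(pats, ctrl),                 # separated: p ~ 0.021
               f2 = c(1, 2, 3, 1, 2, 3),           # identical groups: p = 1
               f3 = c(rnorm(3), rnorm(3) + 100))   # huge shift
  rownames(cog) <- paste0("s", 1:6)
  raw <- cohort(cog, matrix(0, 6, 1, dimnames = list(rownames(cog), "i1")),
                c("MCI", "AD", "MCI", "HC", "HC", "HC"),
                c(f1 = "t1", f2 = "t1", f3 = "t1"))
  kept <- screen_features(raw, alpha_level = 0.05)
  expect_setequal(kept, c("f1", "f3"))
  expect_true("f1" %in% screen_features(raw, alpha_level = 0.05))
  expect_false("f2" %in% screen_features(raw, alpha_level = 0.5))
})

test_that("untestable features are excluded with a warning, not an error", {
  raw <- tiny_cohort()
  expect_warning(kept <- screen_features(raw), "constant")
  expect_setequal(kept, c("good", "reversed"))
})

test_that("min-max scaling and effect-size orientation follow the closed forms", {
  # feature values 2,4,6 across the cohort -> 0, 0.5, 1 before any flip
  cog <- cbind(low = c(2, 4, 6), high = c(6, 4, 2))
  rownames(cog) <- c("a", "b", "c")
  raw <- cohort(cog, matrix(0, 3, 1, dimnames = list(rownames(cog), "i1")),
                c("AD", "MCI", "HC"), c(low = "t1", high = "t1"))
  # patients (a, b) score lower than control (c) on `low`: d < 0, no flip
  norm <- normalize_and_orient(raw, c("low", "high"))
  expect_equal(unname(norm$values[, "low"]), c(0, 0.5))
  expect_false(unname(norm$flipped["low"]))
  # on `high` patients score higher: d > 0, flipped to 1 - x
  expect_equal(unname(norm$values[, "high"]), c(0, 0.5))
  expect_true(unname(norm$flipped["high"]))
  # oracle: pooled-SD Cohen's d sign decides the flip
  d_low <- (mean(c(2, 4)) - 6) / sqrt(((2 - 1) * var(c(2, 4))) / 1)
  expect_lt(d_low, 0)

  # idempotence: a feature already in [0, 1] with matching orientation is
  # returned unchanged
  cog2 <- cbind(u = c(0, 0.25, 1))
  rownames(cog2) <- c("a", "b", "c")
  raw2 <- cohort(cog2, matrix(0, 3, 1, dimnames = list(rownames(cog2), "i1")),
                 c("AD", "MCI", "HC"), c(u = "t1"))
  expect_equal(unname(normalize_and_orient(raw2, "u")$values[, "u"]),
               c(0, 0.25))
})

test_that("constant features are rejected by scaling", {
  raw <- tiny_cohort()
  expect_error(normalize_and_orient(raw, c("good", "flat")), "constant")
})

test_that("degeneracy filter drops features dominated by a special value", {
  m <- 100
  mk <- function(v) c(rep(v[1], v[2]), runif(m - v[2], 0.01, 0.49))
  vals <- cbind(drop0 = mk(c(0, 96)),        # 96% zeros: dropped
                keep0 = mk(c(0, 95)),        # exactly 95%: kept (not > 95%)
                half = c(rep(0, 50), rep(1, 50)),  # 50/50: kept
                drop5 = mk(c(0.5, 97)))
  rownames(vals) <- sprintf("p%03d", 1:m)
  kept <- filter_degenerate(vals, threshold = 0.95)
  expect_setequal(kept, c("keep0", "half"))
  # brute-force count oracle for the 50/50 column
  expect_true(max(sum(vals[, "half"] == 0), sum(vals[, "half"] == 1),
                  sum(vals[, "half"] == 0.5)) / m <= 0.95)
})

test_that("RBF similarity has unit diagonal, closed form and symmetry", {
  set.seed(1)
  x <- matrix(rnorm(40), 8, 5)
  x[2, ] <- x[1, ]                          # duplicated patient
  s <- rbf_similarity(x, sigma = 0.7)
  expect_equal(s$w[1, 2], 1)
  expect_equal(diag(s$w), rep(1, 8), ignore_attr = TRUE)
  expect_equal(s$w, t(s$w))
  # ||r_p - r_q||^2 = 2 sigma^2  ->  w = exp(-1)
  y <- rbind(c(0, 0), c(sqrt(2) * 0.7, 0))
  expect_equal(rbf_similarity(y, sigma = 0.7)$w[1, 2], exp(-1))
  # translation invariance: shift every patient by the same vector
  s2 <- rbf_similarity(sweep(x, 2, rnorm(5), "+"), sigma = 0.7)
  expect_equal(s2$w, s$w)
  expect_error(rbf_similarity(x, sigma = 0), "positive")
  expect_error(rbf_similarity(x, sigma = -1), "positive")
})

test_that("median-heuristic bandwidth equals the median pairwise distance", {
  set.seed(2)
  x <- matrix(rnorm(30), 10, 3)
  s <- rbf_similarity(x)
  d <- dist(x)
  expect_equal(s$sigma, median(d))
})

test_that("relevance labelling splits at the patient quantile with stable ties", {
  vals <- matrix(c(0.1, 0.2, 0.9, 0.8), 1,
                 dimnames = list("p1", c("a", "b", "c", "d")))
  lab <- label_relevance(vals, quantile = 0.5)
  expect_equal(lab$relevant$p1, c("a", "b"))      # a before b: more relevant
  expect_setequal(lab$irrelevant$p1, c("c", "d"))
  expect_length(lab$flagged, 0)

  # quantile near 0 with distinct values: only the single smallest relevant
  lab0 <- label_relevance(vals, quantile = 0.01)
  expect_equal(lab0$relevant$p1, "a")

  # all values equal: everything ties at the cutoff; partition is one-sided
  # and the patient is flagged, with order fixed by feature id
  same <- matrix(0.5, 1, 4, dimnames = list("p1", c("d", "c", "b", "a")))
  labs <- label_relevance(same, quantile = 0.5)
  expect_equal(labs$relevant$p1, c("a", "b", "c", "d"))
  expect_equal(labs$flagged, "p1")
})

test_that("relevance labels ignore patient ordering", {
  set.seed(3)
  vals <- matrix(runif(40), 8, 5,
                 dimnames = list(paste0("p", 1:8), paste0("f", 1:5)))
  lab1 <- label_relevance(vals)
  perm <- sample(8)
  lab2 <- label_relevance(vals[perm, ])
  for (p in rownames(vals)) {
    expect_identical(lab1$relevant[[p]], lab2$relevant[[p]])
    expect_identical(lab1$irrelevant[[p]], lab2$irrelevant[[p]])
  }
})

test_that("pipeline output re-passes its own filters and orientation check", {
  sim <- simulate_cohort(m = 40, n_controls = 20, n_features = 30,
                         n_tasks = 6, d_true = 4, noise = 0.3, seed = 5)
  pp <- preprocess_cohort(sim$cohort)
  vals <- pp$cohort$values
  expect_true(all(vals >= 0 & vals <= 1, na.rm = TRUE))
  # degeneracy filter is idempotent on the output
  expect_setequal(filter_degenerate(vals), colnames(vals))
  # orientation: recomputed patients-minus-controls effect is <= 0 everywhere
  raw <- sim$cohort
  pat <- raw$diagnosis %in% c("MCI", "AD")
  for (f in pp$cohort$feature_ids) {
    x <- raw$cognitive[, f]
    x <- (x - min(x)) / (max(x) - min(x))
    if (pp$cohort$flipped[f]) x <- 1 - x
    expect_lte(cohens_d(x[pat], x[!pat]), 0)
  }
  # every retained feature passed the screen
  expect_true(all(pp$cohort$feature_ids %in% screen_features(raw)))
})
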