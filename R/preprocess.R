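#' Screen features by patient-control group difference
#'
#' Runs a two-sided Welch (unequal-variance) t-test on every cognitive feature
#' between patients (MCI + AD) and controls (HC) and keeps features whose
#' p-value falls below \code{alpha_level}. No multiple-testing correction is
#' applied. Features that cannot be tested (constant in both groups, or fewer
#' than two non-missing values in either group) are excluded with a warning.
#'
#' @param cohort a \code{cogrank_cohort}.
#' @param alpha_level significance level for retention (default 0.05).
#' @param which \code{"cognitive"} (default) or \code{"imaging"}: which block
#'   of features to screen.
#' @return Character vector of retained feature ids.
#' @export
screen_features <- function(cohort, alpha_level = 0.05,
                            which = c("cognitive", "imaging")) {
  which <- match.arg(which)
  values <- cohort[[which]]
  pat <- is_patient(cohort)
  keep <- character(0)
  for (f in colnames(values)) {
    xp <- values[pat, f]; xp <- xp[!is.na(xp)]
    xc <- values[!pat, f]; xc <- xc[!is.na(xc)]
    if (length(xp) < 2L || length(xc) < 2L) {
      warning("feature ", f, " has fewer than 2 observed values in a group; excluded",
              call. = FALSE)
      next
    }
    p <- tryCatch(stats::t.test(xp, xc, var.equal = FALSE)$p.value,
                  error = function(e) NA_real_)
    if (is.na(p)) {
      warning("feature ", f, " is constant within both groups; excluded",
              call. = FALSE)
      next
    }
    if (p < alpha_level) keep <- c(keep, f)
  }
  keep
}

#' Cohen's d between patients and controls
#'
#' Pooled-standard-deviation standardized mean difference, patients minus
#' controls. Only the sign is consumed by the orientation step; if the pooled
#' SD is zero the effect size is defined as 0 (no flip).
#'
#' @param x_patients,x_controls numeric vectors (missing values dropped).
#' @return Scalar Cohen's d.
#' @export
cohens_d <- function(x_patients, x_controls) {
  xp <- x_patients[!is.na(x_patients)]
  xc <- x_controls[!is.na(x_controls)]
  n1 <- length(xp); n2 <- length(xc)
  if (n1 < 1L || n2 < 1L || n1 + n2 < 3L)
    stop("need at least 3 observed values across the two groups")
  # a single-observation group contributes zero weight to the pooled variance
  s1 <- if (n1 > 1L) stats::var(xp) else 0
  s2 <- if (n2 > 1L) stats::var(xc) else 0
  sp2 <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
  if (sp2 <= 0) return(0)
  (mean(xp) - mean(xc)) / sqrt(sp2)
}

#' Min-max normalize and orient features
#'
#' Rescales each selected feature to [0, 1] and flips features on which
#' patients score higher than controls (Cohen's d > 0) via \code{x <- 1 - x},
#' so that after this step smaller values always indicate higher AD
#' likelihood. Scaling statistics are computed over all subjects by default so
#' that controls anchor the healthy end of the scale; returned rows are
#' patients only.
#'
#' @param cohort a \code{cogrank_cohort}.
#' @param selected feature ids to keep (e.g. from [screen_features()]).
#' @param which \code{"cognitive"} or \code{"imaging"}.
#' @param scope \code{"all"} (default): min and max taken over patients and
#'   controls together; \code{"patients"}: over patients only.
#' @return A list of class \code{cogrank_normalized} with elements
#'   \code{patient_ids}, \code{feature_ids}, \code{values} (patients x
#'   features in [0, 1], \code{NA} = unobserved), \code{flipped} (logical per
#'   feature), \code{task_map} (cognitive block only), \code{diagnosis}
#'   (patients' labels).
#' @export
normalize_and_orient <- function(cohort, selected,
                                 which = c("cognitive", "imaging"),
                                 scope = c("all", "patients")) {
  which <- match.arg(which)
  scope <- match.arg(scope)
  values <- cohort[[which]][, selected, drop = FALSE]
  pat <- is_patient(cohort)
  basis <- if (scope == "all") values else values[pat, , drop = FALSE]
  lo <- apply(basis, 2L, min, na.rm = TRUE)
  hi <- apply(basis, 2L, max, na.rm = TRUE)
  if (any(hi - lo <= 0))
    stop("constant feature(s) cannot be min-max scaled: ",
         paste(selected[hi - lo <= 0], collapse = ", "))
  scaled <- sweep(sweep(values, 2L, lo, "-"), 2L, hi - lo, "/")
  d <- vapply(seq_along(selected), function(j)
    cohens_d(scaled[pat, j], scaled[!pat, j]), numeric(1))
  flip <- d > 0
  scaled[, flip] <- 1 - scaled[, flip, drop = FALSE]
  out <- list(patient_ids = rownames(values)[pat],
              feature_ids = selected,
              values      = scaled[pat, , drop = FALSE],
              flipped     = stats::setNames(flip, selected),
              task_map    = if (which == "cognitive")
                              cohort$task_map[selected] else NULL,
              diagnosis   = cohort$diagnosis[pat])
  class(out) <- "cogrank_normalized"
  out
}

#' @export
print.cogrank_normalized <- function(x, ...) {
  cat("Normalized cohort:", length(x$patient_ids), "patients x",
      length(x$feature_ids), "features in [0,1] (smaller = more AD-like)\n")
  if (!is.null(x$task_map))
    cat("  tasks:", length(unique(x$task_map)), "\n")
  cat("  flipped features:", sum(x$flipped), "\n")
  invisible(x)
}

#' Filter degenerate normalized features
#'
#' Drops any feature for which a single value among 0, 1 or 0.5 accounts for
#' more than \code{threshold} of the patients (strictly more). The three
#' special values are tested separately; the denominator is the number of
#' patients (missing cells never count as a special value). Equality with a
#' special value is tested to tolerance 1e-8.
#'
#' @param values patients x features matrix in [0, 1].
#' @param threshold fraction above which a feature is degenerate (default 0.95).
#' @return Character vector of retained feature ids.
#' @export
filter_degenerate <- function(values, threshold = 0.95) {
  m <- nrow(values)
  degen <- vapply(seq_len(ncol(values)), function(j) {
    v <- values[, j]
    any(vapply(c(0, 1, 0.5), function(s)
      sum(abs(v - s) < 1e-8, na.rm = TRUE) / m > threshold, logical(1)))
  }, logical(1))
  colnames(values)[!degen]
}

#' RBF patient similarity from imaging features
#'
#' Gaussian similarity \eqn{w_{pq} = \exp(-\|r_p - r_q\|^2 / 2\sigma^2)}
#' between patients' imaging-feature vectors. When \code{sigma} is omitted it
#' is set by the median heuristic: the median of all pairwise Euclidean
#' distances.
#'
#' @param imaging patients x imaging-features numeric matrix, no missing
#'   values.
#' @param sigma positive bandwidth, or \code{NULL} for the median heuristic.
#' @return Object of class \code{cogrank_similarity}: list with the symmetric
#'   similarity matrix \code{w} (unit diagonal) and the bandwidth
#'   \code{sigma}.
#' @export
rbf_similarity <- function(imaging, sigma = NULL) {
  if (anyNA(imaging)) stop("imaging matrix has missing values")
  d <- as.matrix(stats::dist(imaging))
  if (is.null(sigma)) {
    sigma <- stats::median(d[upper.tri(d)])
    if (!is.finite(sigma) || sigma <= 0)
      stop("median heuristic failed (zero or undefined pairwise distances); supply sigma")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive scalar")
  w <- exp(-d^2 / (2 * sigma^2))
  diag(w) <- 1
  structure(list(w = w, sigma = sigma), class = "cogrank_similarity")
}

#' @export
print.cogrank_similarity <- function(x, ...) {
  cat("RBF patient similarity:", nrow(x$w), "x", ncol(x$w),
      " sigma =", format(x$sigma, digits = 4), "\n")
  invisible(x)
}

# Accept either a cogrank_similarity or a bare symmetric matrix.
sim_matrix <- function(sim) {
  if (inherits(sim, "cogrank_similarity")) sim$w
  else if (is.matrix(sim)) sim
  else stop("`sim` must be a cogrank_similarity or a matrix")
}

#' Partition each patient's features into relevant and irrelevant sets
#'
#' Features whose normalized value falls at or below the patient-specific
#' \code{quantile} (type-7 sample quantile of that patient's observed values)
#' are labelled relevant (AD-indicative); the rest irrelevant. The ground-truth
#' order on the relevant set is ascending normalized value (smaller = more
#' AD-like = more relevant), with ties broken lexicographically by feature id,
#' giving a strict total order.
#'
#' @param cohort a \code{cogrank_normalized} (or plain values matrix).
#' @param quantile relevance cutoff in (0, 1); default 0.5.
#' @return Object of class \code{cogrank_labels}: per-patient lists
#'   \code{relevant} (ordered most-relevant first), \code{irrelevant}, plus
#'   \code{quantile} and \code{flagged} (ids of patients whose observed
#'   features are all relevant or all irrelevant; such patients are excluded
#'   from loss terms that need both sets).
#' @export
label_relevance <- function(cohort, quantile = 0.5) {
  if (!(quantile > 0 && quantile < 1)) stop("quantile must be in (0, 1)")
  values <- if (inherits(cohort, "cogrank_normalized")) cohort$values else cohort
  pts <- rownames(values)
  relevant <- irrelevant <- stats::setNames(vector("list", length(pts)), pts)
  flagged <- character(0)
  for (p in pts) {
    v <- values[p, ]
    v <- v[!is.na(v)]
    if (!length(v)) { flagged <- c(flagged, p); next }
    cut <- stats::quantile(v, probs = quantile, type = 7, names = FALSE)
    rel <- v <= cut
    ord <- order(v, names(v))                # ascending value, then id
    ids <- names(v)[ord]
    relevant[[p]]   <- ids[ids %in% names(v)[rel]]
    irrelevant[[p]] <- ids[!ids %in% names(v)[rel]]
    if (!length(relevant[[p]]) || !length(irrelevant[[p]]))
      flagged <- c(flagged, p)
  }
  structure(list(relevant = relevant, irrelevant = irrelevant,
                 quantile = quantile, flagged = flagged),
            class = "cogrank_labels")
}

#' @export
print.cogrank_labels <- function(x, ...) {
  np <- lengths(x$relevant)
  cat("Relevance labels for", length(x$relevant), "patients",
      "(quantile", x$quantile, ")\n")
  cat("  relevant per patient: median", stats::median(np), "\n")
  if (length(x$flagged))
    cat("  flagged (one-sided) patients:", length(x$flagged), "\n")
  invisible(x)
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: group-difference screening, min-max scaling with
#' effect-size orientation, and the degeneracy filter, to both the cognitive
#' and imaging blocks; then builds the RBF patient similarity from the
#' processed imaging features. Per-feature flips only negate distances
#' component-wise, so the similarity is unaffected by orientation.
#'
#' @inheritParams screen_features
#' @param degeneracy_threshold fraction for [filter_degenerate()].
#' @param sigma RBF bandwidth, \code{NULL} for the median heuristic.
#' @param scope scaling scope, see [normalize_and_orient()].
#' @return List with \code{cohort} (\code{cogrank_normalized}, cognitive
#'   block), \code{similarity} (\code{cogrank_similarity}), and
#'   \code{decisions}: per-feature record of kept/dropped and why.
#' @export
preprocess_cohort <- function(cohort, alpha_level = 0.05,
                              degeneracy_threshold = 0.95,
                              sigma = NULL, scope = c("all", "patients")) {
  scope <- match.arg(scope)
  decisions <- list()
  process <- function(which) {
    all_ids <- colnames(cohort[[which]])
    sel <- withCallingHandlers(
      screen_features(cohort, alpha_level, which = which),
      warning = function(w) invokeRestart("muffleWarning"))
    norm <- normalize_and_orient(cohort, sel, which = which, scope = scope)
    kept <- filter_degenerate(norm$values, degeneracy_threshold)
    status <- ifelse(all_ids %in% kept, "kept",
              ifelse(all_ids %in% sel, "dropped:degenerate", "dropped:screen"))
    decisions[[which]] <<- stats::setNames(as.list(status), all_ids)
    norm$feature_ids <- kept
    norm$values  <- norm$values[, kept, drop = FALSE]
    norm$flipped <- norm$flipped[kept]
    if (!is.null(norm$task_map)) norm$task_map <- norm$task_map[kept]
    norm
  }
  cog <- process("cognitive")
  img <- process("imaging")
  if (anyNA(img$values))
    stop("imaging block has missing values; impute or drop upstream")
  sim <- rbf_similarity(img$values, sigma = sigma)
  list(cohort = cog, similarity = sim, imaging = img, decisions = decisions)
}
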