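#' Simulate a cohort with planted low-rank ranking structure
#'
#' Generates data with exactly the structure the model assumes, so every
#' pipeline stage can be tested end to end: patients and cognitive features
#' receive planted latent vectors (i.i.d. standard Gaussian, \code{d_true}
#' dimensions); the planted relevance score of feature \eqn{i} for patient
#' \eqn{p} is \eqn{u_p^T v_i / \sqrt{d}}; the observed cognitive value is a
#' logistic squashing of minus that score plus Gaussian noise, so values lie
#' in (0, 1) and smaller values are more AD-like. Controls get their own
#' latent vectors plus a healthy mean shift on the logit scale, pushing their
#' values toward 1 and giving every feature a negative planted
#' patient-minus-control effect. A fraction of features is stored reversed
#' (\code{1 - value}) to exercise the orientation step. Imaging features are
#' a random linear map of each subject's latent vector plus noise, so RBF
#' imaging similarity tracks latent proximity. Features are assigned to tasks
#' round-robin.
#'
#' Defaults give a small cohort (120 patients + 50 controls, 60 features in
#' 15 tasks) that preserves the shape ratios of a typical AD case-control
#' study at minute-scale cost; \code{preset = "adni"} uses the full study
#' shape (590 patients + 229 controls, 112 features, 15 tasks, 86 imaging
#' features).
#'
#' @param m number of patients.
#' @param n_controls number of healthy controls.
#' @param n_features number of cognitive features.
#' @param n_tasks number of cognitive tasks (instruments).
#' @param d_true planted latent dimension.
#' @param n_imaging number of imaging (morphometric) features.
#' @param noise standard deviation of logit-scale cognitive noise (0 =
#'   noiseless planted rankings).
#' @param imaging_noise standard deviation of imaging noise.
#' @param control_shift healthy mean shift of controls on the logit scale.
#' @param control_latent_shift mean shift of controls' latent vectors (drives
#'   the patient-control difference visible in imaging features).
#' @param flip_fraction fraction of features stored in reversed orientation.
#' @param missing_rate probability that a patient cognitive value is missing.
#' @param mci_fraction fraction of patients labelled MCI (rest AD).
#' @param preset \code{"small"} (the defaults) or \code{"adni"} (full study
#'   shape); explicit size arguments override the preset.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return List with \code{cohort} (a \code{cogrank_cohort}) and
#'   \code{truth}: planted \code{U} (d x m, patients), \code{V} (d x n),
#'   \code{scores} (m x n planted score matrix), \code{feature_ranking}
#'   (per-patient list, most relevant first), \code{orientation} (+1/-1 per
#'   feature), and the generator parameters.
#' @export
simulate_cohort <- function(m = 120, n_controls = 50, n_features = 60,
                            n_tasks = 15, d_true = 8, n_imaging = 20,
                            noise = 0, imaging_noise = 0.1,
                            control_shift = 2, control_latent_shift = 1.5,
                            flip_fraction = 0.3,
                            missing_rate = 0, mci_fraction = 2 / 3,
                            preset = c("small", "adni"), seed = 1) {
  preset <- match.arg(preset)
  if (preset == "adni") {
    if (missing(m)) m <- 590
    if (missing(n_controls)) n_controls <- 229
    if (missing(n_features)) n_features <- 112
    if (missing(n_imaging)) n_imaging <- 86
  }
  if (m < 1 || n_controls < 1 || n_features < 1 || n_tasks < 1 || d_true < 1)
    stop("cohort sizes and d_true must be positive")
  if (noise < 0) stop("noise must be non-negative")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  pid <- sprintf("P%03d", seq_len(m))
  cid <- sprintf("C%03d", seq_len(n_controls))
  fid <- sprintf("cf%03d", seq_len(n_features))
  iid <- sprintf("img%03d", seq_len(n_imaging))
  tasks <- sprintf("task%02d", ((seq_len(n_features) - 1L) %% n_tasks) + 1L)
  task_map <- stats::setNames(tasks, fid)

  U <- matrix(stats::rnorm(d_true * m), d_true, m, dimnames = list(NULL, pid))
  Uc <- matrix(stats::rnorm(d_true * n_controls) + control_latent_shift,
               d_true, n_controls, dimnames = list(NULL, cid))
  V <- matrix(stats::rnorm(d_true * n_features), d_true, n_features,
              dimnames = list(NULL, fid))

  planted <- crossprod(U, V) / sqrt(d_true)          # m x n, higher = more relevant

  # patients: squashed planted score plus noise; controls: healthy ceiling,
  # independent of their latent vectors (unit spread around control_shift)
  logit_p <- -planted + noise * matrix(stats::rnorm(m * n_features), m)
  logit_c <- control_shift +
    matrix(stats::rnorm(n_controls * n_features), n_controls)
  cog <- rbind(stats::plogis(logit_p), stats::plogis(logit_c))
  rownames(cog) <- c(pid, cid); colnames(cog) <- fid

  orientation <- rep(1L, n_features)
  n_flip <- round(flip_fraction * n_features)
  if (n_flip > 0) {
    fl <- sample.int(n_features, n_flip)
    cog[, fl] <- 1 - cog[, fl]
    orientation[fl] <- -1L
  }
  names(orientation) <- fid

  if (missing_rate > 0) {
    mask <- matrix(stats::runif(m * n_features) < missing_rate, m)
    cog[seq_len(m), ][mask] <- NA_real_
  }

  A <- matrix(stats::rnorm(n_imaging * d_true), n_imaging) / sqrt(d_true)
  all_lat <- cbind(U, Uc)
  img <- t(A %*% all_lat) +
    imaging_noise * matrix(stats::rnorm((m + n_controls) * n_imaging),
                           m + n_controls)
  rownames(img) <- c(pid, cid); colnames(img) <- iid

  dx <- c(ifelse(seq_len(m) <= round(mci_fraction * m), "MCI", "AD"),
          rep("HC", n_controls))

  ranking <- lapply(seq_len(m), function(i) rank_by_score(planted[i, ]))
  names(ranking) <- pid

  list(cohort = cohort(cog, img, dx, task_map),
       truth = list(U = U, V = V, scores = planted,
                    feature_ranking = ranking,
                    orientation = orientation,
                    task_map = task_map,
                    params = list(m = m, n_controls = n_controls,
                                  n_features = n_features, n_tasks = n_tasks,
                                  d_true = d_true, n_imaging = n_imaging,
                                  noise = noise,
                                  imaging_noise = imaging_noise,
                                  control_shift = control_shift,
                                  flip_fraction = flip_fraction,
                                  missing_rate = missing_rate,
                                  seed = seed)))
}

#' Normalized view of a synthetic cohort with planted orientation restored
#'
#' Returns the generator's patient cognitive values as a
#' \code{cogrank_normalized} cohort, undoing the stored orientation flips
#' (\code{x <- 1 - x} on reversed features). Synthetic cognitive values are
#' already commensurable across features by construction (a single logistic
#' squashing of the planted scores), so no per-feature rescaling is applied:
#' at zero noise the per-patient ranking of these values is exactly the
#' planted ranking, which makes this the reference input for planted-truth
#' recovery experiments. Real data needs [preprocess_cohort()] instead.
#'
#' @param sim result of [simulate_cohort()].
#' @return A \code{cogrank_normalized}.
#' @export
synthetic_normalized <- function(sim) {
  values <- sim$cohort$cognitive[is_patient(sim$cohort), , drop = FALSE]
  flip <- sim$truth$orientation < 0
  values[, flip] <- 1 - values[, flip, drop = FALSE]
  structure(list(patient_ids = rownames(values),
                 feature_ids = colnames(values),
                 values = values,
                 flipped = stats::setNames(flip, colnames(values)),
                 task_map = sim$truth$task_map,
                 diagnosis = sim$cohort$diagnosis[is_patient(sim$cohort)]),
            class = "cogrank_normalized")
}

#' Summarize recovery of the planted ranking structure
#'
#' Compares fitted (or otherwise predicted) per-patient feature rankings
#' against the planted truth of a synthetic cohort: mean QH@k, WQH@k,
#' NH_g@k (tasks scored with top-\code{g} features) and mean Kendall tau
#' between predicted and planted scores.
#'
#' @param fit a \code{pltr} object, or an m x n matrix of predicted scores
#'   with patient/feature dimnames.
#' @param truth the \code{truth} element of [simulate_cohort()].
#' @param k feature-list depth (default 5).
#' @param g task-scoring depth (default 1).
#' @param k_task task-list depth (default 1).
#' @return Named numeric vector: \code{qh}, \code{wqh}, \code{nh},
#'   \code{tau} (means over patients).
#' @export
recovery_report <- function(fit, truth, k = 5, g = 1, k_task = 1) {
  scores <- if (inherits(fit, "pltr")) fitted(fit) else fit
  pid <- rownames(truth$scores)
  scores <- scores[pid, colnames(truth$scores), drop = FALSE]
  per <- vapply(pid, function(p) {
    tr <- truth$feature_ranking[[p]]
    pv <- scores[p, ]
    pl <- rank_by_score(pv)
    tt <- task_score(-truth$scores[p, ], truth$task_map, g = g,
                     type = "truth")$ranking
    pt <- task_score(pv, truth$task_map, g = g, type = "prediction")$ranking
    c(qh = qh_at_k(tr, pl, k),
      wqh = wqh_at_k(tr, pl, k),
      nh = nh_g_at_k(tt, pt, min(k_task, length(tt))),
      tau = stats::cor(truth$scores[p, ], pv, method = "kendall"))
  }, numeric(4))
  rowMeans(per)
}
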