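#' Assemble a raw cohort
#'
#' Bundles the three tables the pipeline consumes: a subjects x cognitive-score
#' matrix, a subjects x imaging-feature matrix, and a map from each cognitive
#' feature to the neuropsychological task (instrument) it belongs to. Subjects
#' carry a diagnosis label (\code{HC}, \code{MCI} or \code{AD}); MCI and AD
#' subjects are treated as patients downstream, HC subjects as controls.
#'
#' @param cognitive numeric matrix, subjects x cognitive features, with
#'   \code{NA} for missing scores. Must have row and column names.
#' @param imaging numeric matrix, subjects x imaging features, rows aligned
#'   with \code{cognitive}.
#' @param diagnosis character vector of \code{"HC"}, \code{"MCI"}, \code{"AD"},
#'   one per subject.
#' @param task_map named character vector mapping every cognitive feature id
#'   (names) to a task id (values).
#' @return An object of class \code{cogrank_cohort}: a list with elements
#'   \code{subject_ids}, \code{diagnosis}, \code{cognitive}, \code{imaging},
#'   \code{task_map}.
#' @export
cohort <- function(cognitive, imaging, diagnosis, task_map) {
  if (!is.matrix(cognitive) || !is.numeric(cognitive))
    stop("`cognitive` must be a numeric matrix")
  if (is.null(rownames(cognitive)) || is.null(colnames(cognitive)))
    stop("`cognitive` must have row (subject) and column (feature) names")
  if (!is.matrix(imaging) || !is.numeric(imaging))
    stop("`imaging` must be a numeric matrix")
  if (anyDuplicated(rownames(cognitive)))
    stop("duplicated subject id: ",
         rownames(cognitive)[duplicated(rownames(cognitive))][1L])
  if (nrow(imaging) != nrow(cognitive))
    stop("cognitive and imaging matrices must have the same subjects")
  if (!is.null(rownames(imaging)) &&
      !identical(rownames(imaging), rownames(cognitive)))
    stop("imaging rows are not aligned with cognitive rows")
  rownames(imaging) <- rownames(cognitive)
  diagnosis <- as.character(diagnosis)
  if (length(diagnosis) != nrow(cognitive))
    stop("`diagnosis` must have one label per subject")
  bad <- setdiff(unique(diagnosis), c("HC", "MCI", "AD"))
  if (length(bad))
    stop("unknown diagnosis label(s): ", paste(bad, collapse = ", "))
  unmapped <- setdiff(colnames(cognitive), names(task_map))
  if (length(unmapped))
    stop("cognitive feature(s) missing from task map: ",
         paste(unmapped, collapse = ", "))
  task_map <- task_map[colnames(cognitive)]
  structure(
    list(subject_ids = rownames(cognitive),
         diagnosis   = diagnosis,
         cognitive   = cognitive,
         imaging     = imaging,
         task_map    = task_map),
    class = "cogrank_cohort")
}

#' @export
print.cogrank_cohort <- function(x, ...) {
  tab <- table(factor(x$diagnosis, levels = c("HC", "MCI", "AD")))
  cat("Raw cohort:", length(x$subject_ids), "subjects (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  cat("  cognitive features:", ncol(x$cognitive),
      "in", length(unique(x$task_map)), "tasks\n")
  cat("  imaging features:  ", ncol(x$imaging), "\n")
  invisible(x)
}

is_patient <- function(cohort) cohort$diagnosis %in% c("MCI", "AD")

#' Read a cohort from delimited text files
#'
#' Reads the three CSV inputs (comma-separated, header row, \code{.} decimal,
#' empty cell = missing). The cognitive table must contain a subject-id column
#' named \code{SID} and a diagnosis column named \code{DX} with values
#' HC/MCI/AD; the imaging table must contain \code{SID}; the task map has two
#' columns \code{feature} and \code{task}.
#'
#' @param cognitive_file,imaging_file,task_map_file paths to the three tables.
#' @return A \code{cogrank_cohort}.
#' @export
read_cohort <- function(cognitive_file, imaging_file, task_map_file) {
  cog <- utils::read.csv(cognitive_file, check.names = FALSE,
                         na.strings = c("", "NA"))
  if (!"SID" %in% names(cog)) stop("cognitive table has no SID column")
  if (!"DX" %in% names(cog)) stop("cognitive table has no DX column")
  img <- utils::read.csv(imaging_file, check.names = FALSE,
                         na.strings = c("", "NA"))
  if (!"SID" %in% names(img)) stop("imaging table has no SID column")
  tm <- utils::read.csv(task_map_file, check.names = FALSE,
                        colClasses = "character")
  if (!all(c("feature", "task") %in% names(tm)))
    stop("task map must have columns `feature` and `task`")

  sid <- as.character(cog$SID)
  if (anyDuplicated(sid)) stop("duplicated subject id: ", sid[duplicated(sid)][1L])
  dx <- as.character(cog$DX)
  cm <- as.matrix(cog[, setdiff(names(cog), c("SID", "DX")), drop = FALSE])
  storage.mode(cm) <- "double"
  rownames(cm) <- sid

  img_sid <- as.character(img$SID)
  im <- as.matrix(img[, setdiff(names(img), "SID"), drop = FALSE])
  storage.mode(im) <- "double"
  rownames(im) <- img_sid
  if (!setequal(img_sid, sid))
    stop("imaging and cognitive tables cover different subjects")
  im <- im[sid, , drop = FALSE]

  task_map <- stats::setNames(tm$task, tm$feature)
  cohort(cm, im, dx, task_map)
}

#' Write a cohort to delimited text files
#'
#' Inverse of [read_cohort()]: writes \code{cognitive.csv}, \code{imaging.csv}
#' and \code{task_map.csv} into \code{dir}. Missing values become empty cells.
#'
#' @param cohort a \code{cogrank_cohort}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("cognitive.csv", "imaging.csv", "task_map.csv"))
  cog <- data.frame(SID = cohort$subject_ids, DX = cohort$diagnosis,
                    cohort$cognitive, check.names = FALSE)
  utils::write.csv(cog, paths[1L], row.names = FALSE, na = "")
  img <- data.frame(SID = cohort$subject_ids, cohort$imaging,
                    check.names = FALSE)
  utils::write.csv(img, paths[2L], row.names = FALSE, na = "")
  tm <- data.frame(feature = names(cohort$task_map),
                   task = unname(cohort$task_map))
  utils::write.csv(tm, paths[3L], row.names = FALSE)
  invisible(paths)
}
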