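#' Z-standardize a vector of task scores
#'
#' Centers to mean 0 and scales to sample SD 1 (n-1 denominator).
#'
#' @param x Numeric vector of per-subject scores (length >= 2, non-constant).
#' @param task Optional task name used in error messages.
#' @return Numeric vector of z scores.
#' @export
#' @examples
#' zscore(c(1, 2, 3))
zscore <- function(x, task = deparse(substitute(x))) {
  if (length(x) < 2L) stop("need at least 2 subjects to z-score ", task)
  if (anyNA(x)) stop("missing scores in task ", task)
  s <- stats::sd(x)
  if (s == 0) stop("zero variance in task ", task, "; cannot z-score")
  (x - mean(x)) / s
}

#' Factor loadings for the cognitive composites
#'
#' The fixed loadings relating the five cognitive tasks to the "Control" and
#' "Working Memory" factors. Control loads on flanker (0.922), pattern
#' comparison (0.525) and card sort (0.509); Working Memory loads on the
#' working-memory task (0.999) with small cross-loadings on vocabulary
#' (0.223), card sort (-0.119) and pattern (-0.128). The loadings are
#' consumed as constants: factor estimation itself is outside this
#' pipeline's scope.
#'
#' @param variant `"full"` uses every non-blank loading; `"salient"` zeroes
#'   cross-loadings below 0.3 in absolute value (leaving Working Memory
#'   defined by the working-memory task alone).
#' @return Tibble with columns `task`, `control`, `working_memory`.
#' @export
nih_loadings <- function(variant = c("full", "salient")) {
  variant <- match.arg(variant)
  out <- tibble::tibble(
    task = c("vocabulary", "flanker", "working_memory", "card_sort",
             "pattern"),
    control = c(0, 0.922, 0, 0.509, 0.525),
    working_memory = c(0.223, 0, 0.999, -0.119, -0.128)
  )
  if (variant == "salient") {
    out$control[abs(out$control) < 0.3] <- 0
    out$working_memory[abs(out$working_memory) < 0.3] <- 0
  }
  out
}

#' Composite scores from z-standardized task scores
#'
#' Each composite is the sum of the z-standardized task scores multiplied by
#' their factor loadings.
#'
#' @param z_scores Tibble with `subject_id` and one column per task named as
#'   in [nih_loadings()], already z-standardized (see [zscore_tasks()]).
#' @param loadings Loadings table, default [nih_loadings()].
#' @return Tibble: `subject_id`, `control`, `working_memory`.
#' @export
composite_scores <- function(z_scores, loadings = nih_loadings()) {
  missing_tasks <- setdiff(loadings$task, names(z_scores))
  if (length(missing_tasks))
    stop("missing task score column(s): ",
         paste(missing_tasks, collapse = ", "))
  z <- as.matrix(z_scores[loadings$task])
  if (anyNA(z)) {
    bad <- z_scores$subject_id[apply(z, 1, anyNA)]
    stop("missing task scores for subject(s): ", paste(bad, collapse = ", "))
  }
  tibble::tibble(
    subject_id = z_scores$subject_id,
    control = as.numeric(z %*% loadings$control),
    working_memory = as.numeric(z %*% loadings$working_memory)
  )
}

#' Z-standardize all task columns of a metadata table
#'
#' @param metadata Tibble with `subject_id` and the five task score columns.
#' @param tasks Task column names.
#' @return Tibble of z scores with the same columns.
#' @export
zscore_tasks <- function(metadata, tasks = nih_loadings()$task) {
  missing_tasks <- setdiff(tasks, names(metadata))
  if (length(missing_tasks))
    stop("missing task score column(s): ",
         paste(missing_tasks, collapse = ", "))
  out <- tibble::tibble(subject_id = metadata$subject_id)
  for (tk in tasks) out[[tk]] <- zscore(metadata[[tk]], task = tk)
  out
}

#' Attach composite scores to a metadata table
#'
#' Convenience wrapper: z-standardizes the task columns across subjects and
#' appends `control` and `working_memory` composites.
#'
#' @inheritParams zscore_tasks
#' @param loadings Loadings table.
#' @return `metadata` with `control` and `working_memory` columns
#'   (overwritten if already present).
#' @export
add_composites <- function(metadata, loadings = nih_loadings()) {
  comp <- composite_scores(zscore_tasks(metadata, loadings$task), loadings)
  metadata$control <- comp$control
  metadata$working_memory <- comp$working_memory
  metadata
}
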