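#' Apply participant exclusion rules to a choice dataset
#'
#' Two rules, applied per subject within the dataset (one domain at a time):
#' \enumerate{
#'   \item Attention: a catch trial offers a dominated lottery (a chance at
#'     the certain outcome itself); choosing the lottery there is a failure.
#'     Subjects failing 6 or more catch trials are excluded.
#'   \item Response variability: subjects choosing the lottery on fewer than
#'     2 non-catch trials are excluded, because a constant choice pattern
#'     carries no information for the choice models.
#' }
#' Catch trials of retained subjects are dropped from the returned data:
#' they carry no value information under any of the models and serve only
#' the attention rule. Attention takes precedence when both rules fire.
#'
#' @param data A ChoiceDataset (long data.frame with \code{subject_id},
#'   \code{is_catch}, \code{chose_lottery}).
#' @param catch_failure_threshold Exclusion threshold on failed catch
#'   trials (default 6).
#' @param min_lottery_choices Minimum number of non-catch lottery choices
#'   to retain a subject (default 2).
#' @return A list with \code{data} (retained subjects, catch trials
#'   removed) and \code{report} (per-subject data.frame: n_catch_failures,
#'   n_lottery_choices, excluded, reason in
#'   \{"attention", "no_variability", "retained"\}).
#' @examples
#' d <- simulate_choices(draw_agents(4, 0.3, seed = 2),
#'                       build_design("in_person", "monetary"))
#' apply_exclusions(d)$report
#' @export
apply_exclusions <- function(data, catch_failure_threshold = 6L,
                             min_lottery_choices = 2L) {
  req <- c("subject_id", "is_catch", "chose_lottery")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    stop("'data' must have columns ", paste(req, collapse = ", "))
  }
  if (!is.logical(data$is_catch) || anyNA(data$is_catch)) {
    stop("'is_catch' must be a complete logical column flagging catch trials")
  }
  subjects <- unique(data$subject_id)
  fails <- vapply(subjects, function(s) {
    as.integer(sum(data$chose_lottery[data$subject_id == s & data$is_catch]))
  }, integer(1))
  lotto <- vapply(subjects, function(s) {
    as.integer(sum(data$chose_lottery[data$subject_id == s & !data$is_catch]))
  }, integer(1))
  reason <- rep("retained", length(subjects))
  reason[lotto < min_lottery_choices] <- "no_variability"
  reason[fails >= catch_failure_threshold] <- "attention"
  report <- data.frame(
    subject_id = subjects,
    n_catch_failures = fails,
    n_lottery_choices = lotto,
    excluded = reason != "retained",
    reason = reason,
    row.names = NULL
  )
  keep <- data$subject_id %in% subjects[reason == "retained"] & !data$is_catch
  filtered <- data[keep, , drop = FALSE]
  rownames(filtered) <- NULL
  agents <- attr(data, "agents")
  if (!is.null(agents)) {
    attr(filtered, "agents") <-
      agents[agents$subject_id %in% unique(filtered$subject_id), , drop = FALSE]
  }
  list(data = filtered, report = report)
}
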