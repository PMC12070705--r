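#' Phase-wise summary of predicted blood pressure
#'
#' One row per phase and target with the prediction mean, standard
#' deviation, and mean absolute error of each phase's predictions against
#' the same subjects' baseline ("before") predictions — the baseline is
#' each subject's own reference, so the MAE reads as the average
#' per-subject departure from the pre-smoking state. Subjects lacking a
#' baseline prediction are excluded, with a log.
#'
#' @param predictions Data.frame with columns `subject_id`, `phase`,
#'   `target` (`"SBP"`/`"DBP"`), `value` (mmHg).
#' @return A data.frame (`phase`, `target`, `mean`, `std`,
#'   `mae_vs_baseline`, `n`), phases in protocol order, with excluded
#'   subjects in attribute `excluded`.
#' @export
summarize_phases <- function(predictions) {
  need <- c("subject_id", "phase", "target", "value")
  miss <- setdiff(need, names(predictions))
  if (length(miss) > 0) {
    stop_schema(paste("predictions need columns:", paste(miss, collapse = ", ")))
  }
  excluded <- character(0)
  out <- list()
  for (tg in unique(predictions$target)) {
    p <- predictions[predictions$target == tg, , drop = FALSE]
    base <- p[p$phase == "before", ]
    baseline <- stats::setNames(base$value, base$subject_id)
    has_base <- p$subject_id %in% names(baseline)
    excluded <- union(excluded, unique(p$subject_id[!has_base]))
    p <- p[has_base, , drop = FALSE]
    for (ph in intersect(PHASE_LEVELS, unique(p$phase))) {
      v <- p$value[p$phase == ph]
      ids <- p$subject_id[p$phase == ph]
      out[[length(out) + 1]] <- data.frame(
        phase = ph, target = tg,
        mean = mean(v), std = stats::sd(v),
        mae_vs_baseline = mean(abs(v - baseline[ids])),
        n = length(v)
      )
    }
  }
  if (length(excluded) > 0) {
    message("excluded subject(s) without a 'before' baseline: ",
            paste(excluded, collapse = ", "))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Per-subject prediction trajectories across the protocol intervals
#'
#' @param predictions As in [summarize_phases()] (one target at a time, or
#'   pass a `target` to filter).
#' @param subject_ids Subjects to extract; unknown ids are an error.
#' @param target Optional target filter (`"SBP"`/`"DBP"`).
#' @return A data.frame (`subject_id`, `phase`, `value`) ordered by subject
#'   then protocol phase; phases without a prediction appear with NA.
#' @export
subject_trajectories <- function(predictions, subject_ids, target = NULL) {
  if (!is.null(target)) {
    predictions <- predictions[predictions$target == target, , drop = FALSE]
  }
  unknown <- setdiff(subject_ids, unique(predictions$subject_id))
  if (length(unknown) > 0) {
    stop_invalid(paste("unknown subject id(s):", paste(unknown, collapse = ", ")))
  }
  out <- expand.grid(phase = PHASE_LEVELS, subject_id = subject_ids,
                     stringsAsFactors = FALSE)[, c("subject_id", "phase")]
  key <- paste(predictions$subject_id, predictions$phase)
  vals <- stats::setNames(predictions$value, key)
  out$value <- unname(vals[paste(out$subject_id, out$phase)])
  out[order(match(out$subject_id, subject_ids),
            match(out$phase, PHASE_LEVELS)), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Write a phase summary (or trajectory) table as CSV
#'
#' Byte-identical output for identical inputs: no timestamps, fixed column
#' order.
#'
#' @param x Data.frame from [summarize_phases()] or
#'   [subject_trajectories()].
#' @param path File path.
#' @export
write_report_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
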