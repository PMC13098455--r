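# Condition helpers: validation failures (bad input files / configs) are
# distinguishable from computation failures by condition class.
bws_validation_error <- function(msg, errors = character(0)) {
  stop(structure(
    class = c("bws_validation_error", "error", "condition"),
    list(message = paste(c(msg, paste0("  - ", errors)), collapse = "\n"),
         call = NULL, errors = errors)
  ))
}

demographic_columns <- function() {
  c("gender", "age_band", "experience_band", "education", "herd_band")
}

#' Write a survey dataset as a wide CSV
#'
#' One row per respondent: `respondent_id`, the five demographic columns,
#' then `task_<t>_best` / `task_<t>_worst` per choice task, holding
#' attribute codes. This mirrors typical survey-platform exports.
#'
#' @param dataset A `bws_survey`.
#' @param path Output file path.
#' @export
write_responses <- function(dataset, path) {
  roster <- dataset$roster
  resp <- dataset$responses
  tasks <- dataset$design$tasks$task
  wide <- roster
  for (t in tasks) {
    sel <- resp$task == t
    ord <- match(roster$respondent_id, resp$respondent_id[sel])
    wide[[sprintf("task_%s_best", t)]] <- resp$best[sel][ord]
    wide[[sprintf("task_%s_worst", t)]] <- resp$worst[sel][ord]
  }
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide survey CSV into a validated dataset
#'
#' Parses and validates the wide response format written by
#' [write_responses()]. Validation is itemised: every malformed row/cell is
#' reported with its line number, and nothing is loaded if any check fails
#' (no partial datasets). Checks: unique respondent ids, all and only the
#' design's tasks present, attribute codes legal and members of their
#' task, best differing from worst.
#'
#' @param path CSV path.
#' @param bound A `bws_design` resolving task ids to attribute sets.
#' @return A `bws_survey`.
#' @export
read_responses <- function(path, bound) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  errors <- character(0)
  if (!("respondent_id" %in% names(tab))) {
    bws_validation_error(path, "missing column respondent_id")
  }
  demo <- intersect(demographic_columns(), names(tab))
  tasks <- bound$tasks$task
  need <- c(sprintf("task_%s_best", tasks), sprintf("task_%s_worst", tasks))
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    errors <- c(errors, paste("missing task columns:",
                              paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(grep("^task_", names(tab), value = TRUE), need)
  if (length(extra)) {
    errors <- c(errors, paste("unexpected task columns:",
                              paste(extra, collapse = ", ")))
  }
  dup <- tab$respondent_id[duplicated(tab$respondent_id)]
  if (length(dup)) {
    errors <- c(errors, paste("duplicated respondent ids:",
                              paste(unique(dup), collapse = ", ")))
  }
  if (!length(errors)) {
    for (i in seq_len(nrow(tab))) {
      line <- i + 1L  # header is line 1
      for (t in tasks) {
        b <- tab[i, sprintf("task_%s_best", t)]
        w <- tab[i, sprintf("task_%s_worst", t)]
        codes <- task_codes(bound, t)
        if (is.na(b) || is.na(w) || b == "" || w == "") {
          errors <- c(errors, sprintf("line %d task %s: missing pick", line, t))
        } else if (!(b %in% codes) || !(w %in% codes)) {
          errors <- c(errors, sprintf(
            "line %d task %s: pick outside task attributes (%s/%s)",
            line, t, b, w))
        } else if (b == w) {
          errors <- c(errors, sprintf(
            "line %d task %s: best equals worst (%s)", line, t, b))
        }
      }
    }
  }
  if (length(errors)) {
    bws_validation_error(paste("invalid survey file:", path), errors)
  }
  roster <- tab[c("respondent_id", demo)]
  resp <- do.call(rbind, lapply(tasks, function(t) {
    data.frame(respondent_id = tab$respondent_id, task = t,
               best = tab[[sprintf("task_%s_best", t)]],
               worst = tab[[sprintf("task_%s_worst", t)]],
               stringsAsFactors = FALSE)
  }))
  new_bws_survey(roster, bound, resp)
}

#' Convert a survey dataset to long format
#'
#' One row per (respondent, task): `respondent_id`, demographics, `task`,
#' `best`, `worst`. Useful for interoperability with long-format choice
#' modelling tools.
#'
#' @param dataset A `bws_survey`.
#' @return A data frame.
#' @export
survey_long <- function(dataset) {
  merge(dataset$responses, dataset$roster, by = "respondent_id",
        sort = FALSE)
}
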