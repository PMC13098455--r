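# Deterministic per-respondent RNG sub-streams: each respondent's choices
# are drawn under a seed derived from the master seed and the respondent id,
# so adding or removing one respondent never reshuffles the others.
respondent_seed <- function(master, id) {
  h <- 0
  for (ch in utf8ToInt(as.character(id))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer((h + as.numeric(master) * 7919) %% 2147483647)
}

#' Simulate a demographic roster
#'
#' Generates `n` synthetic respondents with the study's five demographic
#' variables. In `"quota"` mode each variable independently receives exactly
#' `round(n * p)` respondents in its first-listed category (any rounding
#' remainder goes to the larger category), matching the marginal counts of a
#' quota-filled survey; category labels are then randomly permuted across
#' respondents so the variables are mutually independent. In
#' `"multinomial"` mode each respondent's category is drawn independently
#' with the stratum probabilities.
#'
#' @param n Cohort size (>= 0).
#' @param strata Named list of per-variable category proportion vectors,
#'   each summing to 1; default [study_strata()].
#' @param seed Integer seed; the roster is reproducible under a fixed seed.
#' @param mode `"quota"` (default) or `"multinomial"`.
#' @return Data frame with column `respondent_id` and one factor-free
#'   character column per demographic variable.
#' @examples
#' r <- simulate_respondents(51, seed = 1)
#' table(r$gender)  # 18 female, 33 male
#' @export
simulate_respondents <- function(n, strata = study_strata(), seed = 1L,
                                 mode = c("quota", "multinomial")) {
  mode <- match.arg(mode)
  if (n < 0) stop("`n` must be non-negative", call. = FALSE)
  for (nm in names(strata)) {
    p <- strata[[nm]]
    if (any(p < 0 | p > 1) || abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("proportions for '%s' must lie in [0,1] and sum to 1", nm),
           call. = FALSE)
    }
  }
  ids <- sprintf("R%03d", seq_len(n))
  roster <- data.frame(respondent_id = ids, stringsAsFactors = FALSE)
  if (n == 0L) {
    for (nm in names(strata)) roster[[nm]] <- character(0)
    return(roster)
  }
  set.seed(as.integer(seed %% 2147483647))
  for (nm in names(strata)) {
    p <- strata[[nm]]
    cats <- names(p)
    if (mode == "quota") {
      counts <- round(n * p)
      excess <- sum(counts) - n
      if (excess != 0) {
        larger <- which.max(p)
        counts[larger] <- counts[larger] - excess
      }
      labels <- rep(cats, times = counts)
      roster[[nm]] <- sample(labels)
    } else {
      roster[[nm]] <- sample(cats, n, replace = TRUE, prob = p)
    }
  }
  roster
}

#' Maxdiff probabilities over ordered (best, worst) pairs
#'
#' Under the maxdiff (paired) conditional logit model, a respondent shown a
#' task of k attributes picks the ordered pair (b, w), b != w, with
#' probability proportional to `exp(u_b - u_w)`; the denominator sums over
#' all k(k-1) ordered pairs in the task. With all utilities equal every
#' pair has probability `1 / (k(k-1))`.
#'
#' @param utilities Named numeric vector of latent utilities (the reference
#'   attribute carries 0).
#' @param task Character vector of k >= 2 attribute codes shown together.
#' @return Data frame with columns `best`, `worst`, `prob`; probabilities
#'   sum to 1.
#' @export
maxdiff_pair_probabilities <- function(utilities, task) {
  if (length(task) < 2L) stop("a task needs at least 2 attributes", call. = FALSE)
  missing <- setdiff(task, names(utilities))
  if (length(missing)) {
    stop("task attributes absent from utility vector: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  u <- utilities[task]
  grid <- expand.grid(best = seq_along(task), worst = seq_along(task))
  grid <- grid[grid$best != grid$worst, , drop = FALSE]
  eta <- u[grid$best] - u[grid$worst]
  eta <- eta - max(eta)                       # log-sum-exp stabilisation
  p <- exp(eta) / sum(exp(eta))
  data.frame(best = task[grid$best], worst = task[grid$worst],
             prob = as.numeric(p), stringsAsFactors = FALSE,
             row.names = NULL)
}

# Resolve the utility specification for one respondent.
# `utilities` is either a named numeric vector (shared by everyone) or a
# list(by = <roster column>, profiles = list(<category> = <named vector>)).
resolve_utilities <- function(utilities, respondent_row) {
  if (is.numeric(utilities)) return(utilities)
  if (is.list(utilities) && !is.null(utilities$by)) {
    categ <- as.character(respondent_row[[utilities$by]])
    prof <- utilities$profiles[[categ]]
    if (is.null(prof)) {
      stop(sprintf("no utility profile for %s = '%s'", utilities$by, categ),
           call. = FALSE)
    }
    return(prof)
  }
  stop("`utilities` must be a named numeric vector or list(by=, profiles=)",
       call. = FALSE)
}

#' Simulate best-worst choices for a roster
#'
#' Draws one (best, worst) pair per respondent and task from
#' [maxdiff_pair_probabilities()] under the given latent utilities. Each
#' respondent has their own RNG sub-stream derived from `seed` and their
#' id, so edits to the roster do not reshuffle other respondents' choices.
#'
#' @param roster Data frame from [simulate_respondents()] (or with the same
#'   columns).
#' @param bound A `bws_design` from [bind_attributes()].
#' @param utilities Either a named utility vector applied to everyone, or
#'   `list(by = "<demographic column>", profiles = list(category = vector))`
#'   for per-stratum profiles.
#' @param seed Master integer seed.
#' @return An object of class `bws_survey`: list with `roster`, `design`
#'   (the bound design) and `responses`, a data frame with one row per
#'   (respondent, task) holding `respondent_id`, `task`, `best`, `worst`.
#' @examples
#' bd <- bind_attributes(construct_bibd(7, 3, 1), nurse_sow_attributes())
#' ds <- simulate_choices(simulate_respondents(51, seed = 1), bd,
#'                        default_utilities(), seed = 1)
#' nrow(ds$responses)  # 357
#' @export
simulate_choices <- function(roster, bound, utilities = default_utilities(),
                             seed = 1L) {
  tasks <- bound$tasks$task
  out <- vector("list", nrow(roster))
  for (i in seq_len(max(nrow(roster), 0L))) {
    u <- resolve_utilities(utilities, roster[i, , drop = FALSE])
    set.seed(respondent_seed(seed, roster$respondent_id[i]))
    best <- character(length(tasks))
    worst <- character(length(tasks))
    for (t in seq_along(tasks)) {
      pp <- maxdiff_pair_probabilities(u, task_codes(bound, tasks[t]))
      pick <- sample.int(nrow(pp), 1L, prob = pp$prob)
      best[t] <- pp$best[pick]
      worst[t] <- pp$worst[pick]
    }
    out[[i]] <- data.frame(respondent_id = roster$respondent_id[i],
                           task = tasks, best = best, worst = worst,
                           stringsAsFactors = FALSE)
  }
  responses <- if (length(out)) do.call(rbind, out) else
    data.frame(respondent_id = character(0), task = integer(0),
               best = character(0), worst = character(0))
  new_bws_survey(roster, bound, responses)
}

# Constructor + invariant checks shared by the simulator and the CSV reader.
new_bws_survey <- function(roster, bound, responses) {
  ds <- structure(list(roster = roster, design = bound,
                       responses = responses),
                  class = "bws_survey")
  validate_survey(ds)
  ds
}

validate_survey <- function(ds) {
  resp <- ds$responses
  if (nrow(resp) == 0L) return(invisible(ds))
  if (any(resp$best == resp$worst)) {
    stop("responses with best == worst", call. = FALSE)
  }
  expected <- nrow(ds$roster) * nrow(ds$design$tasks)
  if (nrow(resp) != expected) {
    stop(sprintf("expected %d responses (respondents x tasks), found %d",
                 expected, nrow(resp)), call. = FALSE)
  }
  key <- paste(resp$respondent_id, resp$task)
  if (anyDuplicated(key)) {
    stop("duplicated (respondent, task) responses", call. = FALSE)
  }
  for (i in seq_len(nrow(ds$design$tasks))) {
    tid <- ds$design$tasks$task[i]
    codes <- task_codes(ds$design, tid)
    sel <- resp$task == tid
    bad <- !(resp$best[sel] %in% codes) | !(resp$worst[sel] %in% codes)
    if (any(bad)) {
      stop(sprintf("task %s has picks outside its attribute set", tid),
           call. = FALSE)
    }
  }
  invisible(ds)
}

#' @export
print.bws_survey <- function(x, ...) {
  cat(sprintf("BWS survey dataset: %d respondents x %d tasks = %d responses\n",
              nrow(x$roster), nrow(x$design$tasks), nrow(x$responses)))
  invisible(x)
}
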