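#' Tally best and worst picks
#'
#' Counts, over all responses, how often each attribute was picked best
#' (`B`) and worst (`W`), and builds the per-respondent score matrix
#' `s[i, j]` = (best picks minus worst picks of attribute j by respondent
#' i). Totals are conserved: `sum(B) = sum(W) = number of responses`, and
#' column sums of `s` equal `B - W`.
#'
#' @param dataset A `bws_survey`.
#' @return List of class `bws_tally` with `B`, `W` (named integer vectors
#'   over all attribute codes), `scores` (respondents x attributes integer
#'   matrix), `n_respondents`, `n_tasks` (tasks per respondent), `r`
#'   (appearances of each attribute across the design), and `T`
#'   (total responses).
#' @export
bws_tally <- function(dataset) {
  codes <- dataset$design$attributes$code
  resp <- dataset$responses
  unknown <- setdiff(unique(c(resp$best, resp$worst)), codes)
  if (length(unknown)) {
    stop("responses reference unknown attributes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  B <- table(factor(resp$best, levels = codes))
  W <- table(factor(resp$worst, levels = codes))
  ids <- dataset$roster$respondent_id
  scores <- matrix(0L, nrow = length(ids), ncol = length(codes),
                   dimnames = list(ids, codes))
  if (nrow(resp)) {
    bt <- table(factor(resp$respondent_id, levels = ids),
                factor(resp$best, levels = codes))
    wt <- table(factor(resp$respondent_id, levels = ids),
                factor(resp$worst, levels = codes))
    scores <- matrix(as.integer(bt - wt), nrow = length(ids),
                     dimnames = list(ids, codes))
  }
  occ <- table(factor(unlist(dataset$design$tasks[-1], use.names = FALSE),
                      levels = codes))
  r <- unique(as.integer(occ))
  structure(
    list(B = stats::setNames(as.integer(B), codes),
         W = stats::setNames(as.integer(W), codes),
         scores = scores,
         n_respondents = length(ids),
         n_tasks = nrow(dataset$design$tasks),
         r = if (length(r) == 1L) r else as.integer(occ),
         T = nrow(resp)),
    class = "bws_tally"
  )
}

# round half away from zero (reporting convention for rendered tables)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Counting-approach summary of a best-worst experiment
#'
#' Computes the aggregate score battery per attribute j:
#' \describe{
#'   \item{`bw_value`}{best-worst value `B_j - W_j`.}
#'   \item{`std_value`}{`(B_j - W_j) / (N * r)`, the best-worst value scaled
#'     by its attainable maximum (N respondents each seeing the attribute r
#'     times); lies in `[-1, 1]`.}
#'   \item{`sqrt_ratio`}{`sqrt(B_j / W_j)`, the multiplicative
#'     best-to-worst scale.}
#'   \item{`relative_pct`}{`100 * sqrt_ratio_j / max_j sqrt_ratio`, the
#'     relative-importance percentage (top attribute = 100).}
#'   \item{`std_minmax`, `relative_minmax`}{optional literal min-max
#'     rescalings of `bw_value`, `(bw - min)/(max - min)` and the same
#'     times 100, included when `minmax = TRUE`.}
#'   \item{`rank`}{dense rank by `relative_pct`, descending; ties share the
#'     smaller rank and are flagged in the `ties` attribute.}
#' }
#'
#' `sqrt_ratio` is undefined when any `W_j = 0`; by default this is an
#' error. With `continuity = TRUE` a +0.5 correction is added to every
#' `B_j` and `W_j` for the ratio columns only, and the correction is
#' recorded in the result's `continuity` attribute.
#'
#' @param B,W Named integer vectors of best/worst counts (same names).
#' @param N Number of respondents.
#' @param r Appearances of each attribute across the design.
#' @param continuity Apply the +0.5 continuity correction when some
#'   `W_j = 0` (default `FALSE`: hard error).
#' @param minmax Also include the literal min-max rescaled columns.
#' @return A data frame of class `bws_count` with one row per attribute and
#'   columns `attribute`, `best_count`, `worst_count`, `best_pct`,
#'   `worst_pct`, `bw_value`, `std_value`, `sqrt_ratio`, `relative_pct`,
#'   (`std_minmax`, `relative_minmax`,) `rank`. Attributes
#'   `continuity` (logical) and `ties` (logical).
#' @examples
#' s <- bws_summary(B = c(A = 105, B = 16), W = c(A = 16, B = 105),
#'                  N = 51, r = 3)  # toy two-attribute table
#' @export
bws_summary <- function(B, W, N, r, continuity = FALSE, minmax = FALSE) {
  stopifnot(length(B) == length(W))
  if (is.null(names(B))) names(B) <- names(W)
  if (is.null(names(B))) names(B) <- paste0("A", seq_along(B))
  Tt <- sum(B)
  Tw <- sum(W)
  if (Tw != Tt) {
    # counts reconstructed from rounded published percentages can be off
    # by a task or two; percentages are then computed on each total
    warning("best and worst totals differ (", Tt, " vs ", Tw,
            "); percentage columns use their own totals", call. = FALSE)
  }
  bw <- B - W
  Br <- B; Wr <- W
  if (any(W == 0)) {
    if (!continuity) {
      stop("W = 0 for some attribute: sqrt ratio undefined ",
           "(set continuity = TRUE for a +0.5 correction)", call. = FALSE)
    }
    Br <- B + 0.5
    Wr <- W + 0.5
  }
  sqrt_ratio <- sqrt(Br / Wr)
  relative <- 100 * sqrt_ratio / max(sqrt_ratio)
  std <- bw / (N * r)
  rk <- match(relative, sort(unique(relative), decreasing = TRUE))  # dense
  out <- data.frame(
    attribute = names(B),
    best_count = as.integer(B),
    worst_count = as.integer(W),
    best_pct = 100 * B / Tt,
    worst_pct = 100 * W / Tw,
    bw_value = as.integer(bw),
    std_value = as.numeric(std),
    sqrt_ratio = as.numeric(sqrt_ratio),
    relative_pct = as.numeric(relative),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (minmax) {
    rng <- range(bw)
    denom <- if (diff(rng) == 0) 1 else diff(rng)
    out$std_minmax <- (bw - rng[1]) / denom
    out$relative_minmax <- 100 * out$std_minmax
  }
  out$rank <- as.integer(rk)
  attr(out, "continuity") <- continuity && any(W == 0)
  attr(out, "ties") <- anyDuplicated(relative) > 0L
  class(out) <- c("bws_count", "data.frame")
  out
}

#' Full counting analysis of a survey dataset
#'
#' Convenience wrapper: [bws_tally()] then [bws_summary()].
#'
#' @inheritParams bws_tally
#' @inheritParams bws_summary
#' @return A `bws_count` data frame (see [bws_summary()]).
#' @export
bws_count <- function(dataset, continuity = FALSE, minmax = FALSE) {
  tl <- bws_tally(dataset)
  bws_summary(tl$B, tl$W, N = tl$n_respondents, r = tl$r[1],
              continuity = continuity, minmax = minmax)
}

#' @export
print.bws_count <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1)) & names(y) != "rank" &
    !vapply(y, is.integer, logical(1))
  y[num] <- lapply(y[num], round_half_away, digits = digits)
  print(y, row.names = FALSE)
  if (isTRUE(attr(x, "continuity"))) {
    cat("(+0.5 continuity correction applied to sqrt ratio columns)\n")
  }
  if (isTRUE(attr(x, "ties"))) cat("(ties present in relative_pct ranks)\n")
  invisible(x)
}

#' Reconstruct integer counts from published percentages
#'
#' Published best-worst tables often print only the percentage of tasks in
#' which each attribute was picked best/worst. Given the total number of
#' tasks `T`, integer counts are recovered as `round(pct * T / 100)` with
#' rounding half away from zero.
#'
#' @param best_pcts,worst_pcts Numeric vectors of percentages.
#' @param T Total number of tasks.
#' @return List with integer vectors `B` and `W` (names preserved).
#' @export
reconstruct_counts_from_percentages <- function(best_pcts, worst_pcts, T) {
  if (any(best_pcts < 0) || any(worst_pcts < 0)) {
    stop("percentages must be non-negative", call. = FALSE)
  }
  list(B = stats::setNames(as.integer(round_half_away(best_pcts * T / 100)),
                           names(best_pcts)),
       W = stats::setNames(as.integer(round_half_away(worst_pcts * T / 100)),
                           names(worst_pcts)))
}

#' Per-respondent score distribution
#'
#' Histograms the per-respondent scores `s[i, j]` over their support
#' `{-r, ..., +r}` (an attribute seen r times can be picked best at most r
#' and worst at most r times), and tabulates the task-level trichotomy:
#' how often each attribute was chosen best, chosen worst, or present but
#' unchosen. Per attribute the trichotomy counts sum to `N * r`
#' appearances.
#'
#' @param tally A `bws_tally` from [bws_tally()].
#' @return List of class `bws_scoredist` with `histogram` (attributes x
#'   score-levels matrix, column names `-r` .. `r`), `trichotomy` (data
#'   frame attribute / best / unchosen / worst), and `r`.
#' @export
score_distribution <- function(tally) {
  r <- tally$r[1]
  s <- tally$scores
  if (any(s < -r | s > r)) {
    stop("scores outside [-r, r]; inconsistent tally", call. = FALSE)
  }
  levels <- seq(-r, r)
  hist <- t(apply(s, 2, function(col) {
    tabulate(factor(col, levels = levels), nbins = length(levels))
  }))
  colnames(hist) <- as.character(levels)
  appearances <- tally$n_respondents * r
  tri <- data.frame(
    attribute = names(tally$B),
    best = as.integer(tally$B),
    unchosen = as.integer(appearances - tally$B - tally$W),
    worst = as.integer(tally$W),
    stringsAsFactors = FALSE
  )
  structure(list(histogram = hist, trichotomy = tri, r = r),
            class = "bws_scoredist")
}

#' Bar chart of best / unchosen / worst frequencies
#'
#' @param x A `bws_scoredist`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.bws_scoredist <- function(x, ...) {
  m <- t(as.matrix(x$trichotomy[c("best", "unchosen", "worst")]))
  colnames(m) <- x$trichotomy$attribute
  graphics::barplot(m, beside = TRUE,
                    legend.text = c("Best", "Unchosen", "Worst"),
                    ylab = "Frequency", xlab = "Attribute", ...)
  invisible(x)
}
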