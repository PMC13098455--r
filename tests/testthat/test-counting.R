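test_that("tally matches a naive double-loop recount", {
  ds <- demo_survey(20, seed = 4)
  tl <- bws_tally(ds)
  codes <- ds$design$attributes$code
  # independent oracle: plain loops over responses
  B <- W <- stats::setNames(integer(length(codes)), codes)
  s <- matrix(0L, nrow(ds$roster), length(codes),
              dimnames = list(ds$roster$respondent_id, codes))
  for (i in seq_len(nrow(ds$responses))) {
    row <- ds$responses[i, ]
    B[row$best] <- B[row$best] + 1L
    W[row$worst] <- W[row$worst] + 1L
    s[row$respondent_id, row$best] <- s[row$respondent_id, row$best] + 1L
    s[row$respondent_id, row$worst] <- s[row$respondent_id, row$worst] - 1L
  }
  expect_equal(tl$B, B)
  expect_equal(tl$W, W)
  expect_equal(tl$scores, s)
  expect_equal(tl$T, nrow(ds$responses))
})

test_that("unknown attribute codes in responses are an error", {
  ds <- demo_survey(5, seed = 4)
  ds$responses$best[1] <- "XYZ"
  expect_error(bws_tally(ds), "XYZ")
})

test_that("conservation and aggregate/individual consistency hold on simulated data", {
  for (seed in 1:5) {
    ds <- demo_survey(17, seed = seed)
    tl <- bws_tally(ds)
    sm <- bws_summary(tl$B, tl$W, N = tl$n_respondents, r = tl$r[1])
    expect_identical(sum(sm$bw_value), 0L)
    expect_equal(sum(sm$std_value), 0)
    # column sums of the individual score matrix equal the aggregate B - W
    expect_equal(unname(colSums(tl$scores)), sm$bw_value)
    # bounds
    expect_true(all(abs(sm$std_value) <= 1))
    expect_true(all(abs(sm$bw_value) <= tl$n_respondents * tl$r[1]))
  }
})

test_that("published percentages reconstruct the printed count and score rows", {
  cn <- reconstruct_counts_from_percentages(published_best_pct,
                                            published_worst_pct, 357)
  expect_equal(cn$B, c(SCLH = 105L, BCS = 85L, SCLS = 56L, STN = 43L,
                       LS = 25L, SB = 25L, P = 18L))
  expect_equal(cn$W, c(SCLH = 16L, BCS = 20L, SCLS = 54L, STN = 53L,
                       LS = 57L, SB = 64L, P = 95L))
  expect_equal(reconstruct_counts_from_percentages(rep(0, 3), rep(0, 3), 357),
               list(B = rep(0L, 3), W = rep(0L, 3)), ignore_attr = TRUE)
  # worst percentages sum to 100.61%, so totals differ by 2 tasks: warn
  expect_warning(sm <- bws_summary(cn$B, cn$W, N = 51, r = 3), "totals differ")
  rows <- match(consistent_attrs, sm$attribute)
  r2 <- function(x) round(x * 100) / 100  # 2 d.p. comparison
  expect_equal(sm$bw_value[rows], unname(published_bw[consistent_attrs]))
  expect_equal(r2(sm$std_value[rows]),
               unname(published_std[consistent_attrs]), tolerance = 1e-12)
  expect_equal(r2(sm$sqrt_ratio[rows]),
               unname(published_sqrt[consistent_attrs]), tolerance = 1e-12)
  expect_equal(r2(sm$relative_pct[rows]),
               unname(published_relative[consistent_attrs]), tolerance = 1e-12)
  expect_equal(sm$rank, 1:7)
  # the worked example: B=105, W=16 gives bw 89, std 0.58, sqrt 2.56
  expect_equal(sm$bw_value[1], 89L)
  expect_equal(r2(sm$std_value[1]), 0.58)
  expect_equal(r2(sm$sqrt_ratio[1]), 2.56)
})

test_that("all-tied counts collapse every score to its neutral value", {
  B <- c(A = 10L, B = 10L, C = 10L)
  sm <- bws_summary(B, B, N = 10, r = 3)
  expect_true(all(sm$bw_value == 0))
  expect_true(all(sm$std_value == 0))
  expect_true(all(sm$sqrt_ratio == 1))
  expect_true(all(sm$relative_pct == 100))
  expect_true(all(sm$rank == 1))
  expect_true(attr(sm, "ties"))
})

test_that("zero worst counts error unless the continuity correction is requested", {
  B <- c(A = 20L, B = 10L, C = 0L)
  W <- c(A = 0L, B = 10L, C = 20L)
  expect_error(bws_summary(B, W, N = 10, r = 3), "continuity")
  sm <- bws_summary(B, W, N = 10, r = 3, continuity = TRUE)
  expect_true(attr(sm, "continuity"))
  expect_equal(sm$sqrt_ratio[1], sqrt(20.5 / 0.5))
})

test_that("literal min-max rescalings are available as optional columns", {
  cn <- reconstruct_counts_from_percentages(published_best_pct,
                                            published_worst_pct, 357)
  sm <- suppressWarnings(bws_summary(cn$B, cn$W, N = 51, r = 3,
                                     minmax = TRUE))
  expect_equal(sm$std_minmax[1], 1)   # top attribute
  expect_equal(sm$std_minmax[7], 0)   # reference/bottom attribute
  expect_equal(sm$relative_minmax, 100 * sm$std_minmax)
})

test_that("score distribution respects bounds and trichotomy accounting", {
  ds <- demo_survey(25, seed = 6)
  tl <- bws_tally(ds)
  sd <- score_distribution(tl)
  r <- tl$r[1]
  expect_equal(colnames(sd$histogram), as.character(seq(-r, r)))
  # per-attribute histogram counts sum to N
  expect_true(all(rowSums(sd$histogram) == tl$n_respondents))
  # trichotomy counts sum to N * r appearances per attribute
  expect_true(all(rowSums(sd$trichotomy[c("best", "unchosen", "worst")])
                  == tl$n_respondents * r))
  expect_equal(sd$trichotomy$best, unname(tl$B))
  expect_equal(sd$trichotomy$worst, unname(tl$W))
})

test_that("a respondent who always best-picks an attribute attains score +r", {
  u <- equal_utilities()
  u["SCLH"] <- 50
  ds <- demo_survey(1, seed = 8, utilities = u)
  tl <- bws_tally(ds)
  expect_equal(unname(tl$scores[1, "SCLH"]), 3L)
})

test_that("the null score distribution is symmetric about zero", {
  ds <- demo_survey(400, seed = 15, utilities = equal_utilities())
  tl <- bws_tally(ds)
  sd <- score_distribution(tl)
  pooled <- colSums(sd$histogram)
  lv <- as.integer(names(pooled))
  # pooled mean score is 0 by conservation; compare the tails
  expect_equal(sum(pooled * lv), 0)
  for (s in 1:3) {
    lo <- pooled[as.character(-s)]; hi <- pooled[as.character(s)]
    expect_lt(abs(lo - hi) / sqrt(lo + hi + 1), 4)  # within sampling error
  }
})
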