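test_that("task expansion enumerates ordered pairs and round-trips the choice", {
  task <- c("A", "B", "C")
  alts <- expand_task(task)
  expect_equal(nrow(alts), 6)
  expect_true(all(alts$best != alts$worst))
  marked <- expand_task(task, best = "B", worst = "C")
  expect_equal(sum(marked$chosen), 1)
  # de-expansion recovers the original response
  expect_equal(marked$best[marked$chosen], "B")
  expect_equal(marked$worst[marked$chosen], "C")
  expect_error(expand_task(task, best = "B", worst = "B"), "inconsistent")
  expect_error(expand_task(task, best = "Z", worst = "A"), "inconsistent")
})

test_that("null log-likelihood equals -T log(k(k-1)) exactly", {
  ds <- demo_survey(51, seed = 1)
  ll0 <- as.numeric(bws_loglik(rep(0, 6), ds, reference = "P"))
  expect_equal(ll0, -357 * log(6), tolerance = 1e-10)
  # invariant under task/row order
  perm <- ds
  set.seed(1)
  perm$responses <- perm$responses[sample(nrow(perm$responses)), ]
  expect_equal(as.numeric(bws_loglik(rep(0, 6), perm, reference = "P")), ll0,
               tolerance = 1e-12)
})

test_that("log-likelihood equals the 6-term hand enumeration", {
  ds <- demo_survey(3, seed = 21)
  beta <- c(SCLH = 0.7, BCS = -0.2, SCLS = 1.1, STN = 0.05, LS = -0.6,
            SB = 0.3)
  ll <- as.numeric(bws_loglik(beta, ds, reference = "P"))
  expect_equal(ll, enumerate_loglik(ds, beta, "P"), tolerance = 1e-12)
  # single respondent (7 single tasks summed term by term)
  ds1 <- demo_survey(1, seed = 22)
  expect_equal(as.numeric(bws_loglik(beta, ds1, reference = "P")),
               enumerate_loglik(ds1, beta, "P"), tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences", {
  ds <- demo_survey(8, seed = 10)
  set.seed(99)
  h <- 1e-6
  for (trial in 1:20) {
    beta <- stats::rnorm(6, sd = 1)
    g <- attr(bws_loglik(beta, ds, reference = "P"), "gradient")
    fd <- vapply(1:6, function(j) {
      e <- rep(0, 6); e[j] <- h
      (as.numeric(bws_loglik(beta + e, ds, reference = "P")) -
         as.numeric(bws_loglik(beta - e, ds, reference = "P"))) / (2 * h)
    }, numeric(1))
    expect_equal(unname(g), fd, tolerance = 1e-6)
  }
})

test_that("the fitted model satisfies its definitional identities", {
  ds <- demo_survey(51, seed = 7)
  fit <- bws_clm(ds, reference = "P")
  expect_true(fit$converged)
  expect_lt(max(abs(fit$gradient)), 1e-6)
  expect_equal(fit$n_obs, 357)
  expect_equal(fit$K, 6)
  expect_equal(fit$aic, -2 * fit$ll_model + 12, tolerance = 1e-12)
  expect_equal(fit$bic, -2 * fit$ll_model + 6 * log(357), tolerance = 1e-12)
  expect_gte(fit$ll_model, fit$ll_null)
  expect_true(fit$pseudo_r2 >= 0 && fit$pseudo_r2 < 1)
  expect_equal(1 - fit$ll_model / fit$ll_null, fit$pseudo_r2,
               tolerance = 1e-12)
})

test_that("published fit statistics are reproduced from their inputs", {
  st <- fit_stats(published_ll_model, published_n_obs, 3, 6)
  expect_equal(round(st$pseudo_r2, 4), published_pseudo_r2)
  expect_equal(round(st$aic), published_aic)
  expect_equal(round(st$bic), published_bic)
  expect_equal(fit_stats(-639.66, 357, 3, 6)$ll_null, -357 * log(6))
  # pseudo-R2 vanishes when the model adds nothing
  llnull <- -357 * log(6)
  expect_equal(fit_stats(llnull, 357, 3, 6)$pseudo_r2, 0)
})

test_that("re-anchoring the reference shifts coefficients without changing fit", {
  ds <- demo_survey(40, seed = 14)
  f1 <- bws_clm(ds, reference = "P")
  f2 <- bws_clm(ds, reference = "SB")
  expect_equal(f1$ll_model, f2$ll_model, tolerance = 1e-8)
  # beta under the new reference = old beta minus old coefficient of SB
  shift <- f1$beta[["SB"]]
  common <- setdiff(names(f1$beta), "SB")
  expect_equal(f2$beta[common], f1$beta[common] - shift, tolerance = 1e-5)
  expect_equal(f2$beta[["P"]], -shift, tolerance = 1e-5)
})

test_that("all-equal utilities yield a null fit on large samples", {
  ds <- demo_survey(400, seed = 23, utilities = equal_utilities())
  fit <- bws_clm(ds, reference = "P")
  expect_true(all(abs(fit$beta) < 0.1))
  expect_lt(fit$pseudo_r2, 0.01)
})

test_that("robust and classical standard errors agree on well-specified iid data", {
  # homogeneous utilities: respondent clustering carries no extra
  # dependence, so the sandwich should track the information matrix
  ds <- demo_survey(300, seed = 17)
  fit <- bws_clm(ds, reference = "P")
  ratio <- fit$robust_se / fit$classical_se
  expect_true(all(ratio > 0.8 & ratio < 1.25))
  # task-level clustering is also available
  fit_t <- bws_clm(ds, reference = "P", cluster = "task")
  expect_true(all(fit_t$robust_se / fit$classical_se > 0.8))
})

test_that("separation is reported, not silent", {
  u <- equal_utilities()
  u["SCLH"] <- 50
  ds <- demo_survey(6, seed = 19, utilities = u)
  expect_warning(fit <- bws_clm(ds, reference = "P"), "separation")
  expect_true("SCLH" %in% fit$separation)
})

test_that("parameter recovery at moderate scale", {
  truth <- default_utilities()
  ds <- demo_survey(300, seed = 31, utilities = truth)
  fit <- bws_clm(ds, reference = "P")
  expect_lt(max(abs(fit$beta - truth[names(fit$beta)])), 0.2)
})

test_that("subgroup fits partition the data and nest the pooled likelihood", {
  ds <- demo_survey(51, seed = 12)
  sg <- subgroup_fit(ds, "gender", reference = "P")
  expect_equal(sg$fits$female$n_obs, 18 * 7)
  expect_equal(sg$fits$male$n_obs, 33 * 7)
  expect_equal(sort(unique(sg$table$category)), c("female", "male"))
  pooled <- bws_clm(ds, reference = "P")
  expect_gte(sg$fits$female$ll_model + sg$fits$male$ll_model,
             pooled$ll_model - 1e-6)
  expect_error(subgroup_fit(ds, "shoe_size"), "shoe_size")
})

test_that("identically generated categories give statistically equal coefficients", {
  ds <- demo_survey(200, seed = 25)  # one shared utility vector
  sg <- subgroup_fit(ds, "gender", reference = "P")
  d <- sg$fits$female$beta - sg$fits$male$beta
  pooled_se <- sqrt(sg$fits$female$robust_se^2 + sg$fits$male$robust_se^2)
  expect_true(all(abs(d) < 4 * pooled_se))
})
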