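#' Expand a best-worst response into ordered-pair alternatives
#'
#' The maxdiff conditional logit treats each choice task of k attributes as
#' a single choice among the k(k-1) ordered (best, worst) pairs; the pair
#' the respondent picked is the chosen alternative. The systematic utility
#' of pair (b, w) is `u_b - u_w`.
#'
#' @param task Character vector of the k attribute codes shown.
#' @param best,worst The observed picks (omit both to enumerate the
#'   alternatives without marking a choice).
#' @return Data frame with columns `best`, `worst` and (when a response is
#'   given) logical `chosen`, exactly one row `TRUE`.
#' @export
expand_task <- function(task, best = NULL, worst = NULL) {
  grid <- expand.grid(best = seq_along(task), worst = seq_along(task))
  grid <- grid[grid$best != grid$worst, , drop = FALSE]
  out <- data.frame(best = task[grid$best], worst = task[grid$worst],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(best) || !is.null(worst)) {
    if (is.null(best) || is.null(worst) || best == worst ||
        !(best %in% task) || !(worst %in% task)) {
      stop("response inconsistent with task: need best != worst, both shown",
           call. = FALSE)
    }
    out$chosen <- out$best == best & out$worst == worst
  }
  out
}

# Internal model frame for the pair-model likelihood.
#
# Returns: X      (n_alt x p) pair design matrix, p = v - 1 non-reference
#                 attributes; row = indicator(best) - indicator(worst)
#          group  task index per row (1..T), each group the same size m
#          m      alternatives per task, k(k-1)
#          chosen global row index of the chosen alternative per task
#          cluster respondent index per task
#          coef_names
clm_frame <- function(dataset, reference) {
  bound <- dataset$design
  codes <- bound$attributes$code
  if (!(reference %in% codes)) {
    stop(sprintf("reference attribute '%s' not in attribute set", reference),
         call. = FALSE)
  }
  free <- setdiff(codes, reference)
  p <- length(free)
  k <- ncol(bound$tasks) - 1L
  m <- k * (k - 1L)

  # per design task: m x p block and a lookup (best, worst) -> local row
  task_ids <- bound$tasks$task
  blocks <- vector("list", length(task_ids))
  lookups <- vector("list", length(task_ids))
  names(blocks) <- names(lookups) <- as.character(task_ids)
  for (ti in seq_along(task_ids)) {
    codes_t <- task_codes(bound, task_ids[ti])
    alts <- expand_task(codes_t)
    Xb <- matrix(0, nrow = m, ncol = p, dimnames = list(NULL, free))
    for (a in seq_len(m)) {
      bcode <- alts$best[a]; wcode <- alts$worst[a]
      if (bcode %in% free) Xb[a, bcode] <- Xb[a, bcode] + 1
      if (wcode %in% free) Xb[a, wcode] <- Xb[a, wcode] - 1
    }
    blocks[[ti]] <- Xb
    lookups[[ti]] <- stats::setNames(seq_len(m),
                                     paste(alts$best, alts$worst, sep = "|"))
  }

  resp <- dataset$responses
  Tn <- nrow(resp)
  ti_of <- match(as.character(resp$task), names(blocks))
  X <- do.call(rbind, blocks[ti_of])
  local <- vapply(seq_len(Tn), function(i) {
    lookups[[ti_of[i]]][[paste(resp$best[i], resp$worst[i], sep = "|")]]
  }, integer(1))
  chosen <- (seq_len(Tn) - 1L) * m + local
  cluster <- match(resp$respondent_id, unique(resp$respondent_id))
  list(X = X, m = m, T = Tn, chosen = chosen, cluster = cluster,
       coef_names = free, k = k)
}

# log-likelihood, gradient, and per-task quantities at beta.
# Group sizes are constant (m), so per-task reductions are matrix reshapes.
clm_eval <- function(beta, fr) {
  eta <- as.numeric(fr$X %*% beta)            # n_alt
  em <- matrix(eta, nrow = fr$m)              # m x T
  mx <- apply(em, 2, max)
  lse <- mx + log(colSums(exp(sweep(em, 2, mx))))
  ll <- sum(eta[fr$chosen]) - sum(lse)
  pm <- exp(sweep(em, 2, lse))                # m x T choice probabilities
  pvec <- as.numeric(pm)
  # M[t, ] = X_t' p_t (expected covariate per task)
  grp <- rep(seq_len(fr$T), each = fr$m)
  M <- rowsum(fr$X * pvec, grp)
  grad <- colSums(fr$X[fr$chosen, , drop = FALSE]) - colSums(M)
  # observed information A = sum_t [X_t' diag(p) X_t - M_t M_t']
  A <- crossprod(fr$X * sqrt(pvec)) - crossprod(M)
  # per-task scores for the sandwich
  S <- fr$X[fr$chosen, , drop = FALSE] - M
  list(ll = ll, grad = grad, info = A, scores = S, probs = pm)
}

#' Maxdiff pair-model log-likelihood
#'
#' Log-likelihood of the maxdiff conditional logit: for each task the
#' chosen (best, worst) pair has probability
#' `exp(u_best - u_worst) / sum over ordered pairs`, with the reference
#' attribute's utility fixed at 0. At `beta = 0` this is
#' `-T * log(k * (k - 1))` for T tasks of size k. Computation is
#' log-sum-exp stabilised; the gradient is analytic.
#'
#' @param beta Named (or ordered) coefficient vector over the non-reference
#'   attributes.
#' @param dataset A `bws_survey`.
#' @param reference Reference attribute code (default: picked by
#'   [choose_reference()]).
#' @return Scalar log-likelihood with attribute `"gradient"`.
#' @export
bws_loglik <- function(beta, dataset, reference = choose_reference(dataset)) {
  fr <- clm_frame(dataset, reference)
  if (length(beta) != length(fr$coef_names)) {
    stop(sprintf("beta must have length %d (one per non-reference attribute)",
                 length(fr$coef_names)), call. = FALSE)
  }
  if (!is.null(names(beta))) beta <- beta[fr$coef_names]
  ev <- clm_eval(as.numeric(beta), fr)
  structure(ev$ll, gradient = stats::setNames(ev$grad, fr$coef_names))
}

#' Default reference attribute
#'
#' The attribute with the lowest aggregate best-worst value (the least
#' important one) — the conventional zero-utility baseline that keeps the
#' remaining coefficients positive.
#'
#' @param dataset A `bws_survey`.
#' @return An attribute code.
#' @export
choose_reference <- function(dataset) {
  tl <- bws_tally(dataset)
  names(which.min(tl$B - tl$W))
}

#' Fit the maxdiff conditional logit model
#'
#' Maximum likelihood estimation of the attribute utilities under the
#' maxdiff pair model, with the reference attribute fixed at 0 for
#' identification. Optimisation is quasi-Newton (BFGS with analytic
#' gradient) from `beta = 0`, polished by Newton steps on the observed
#' information until the gradient norm falls below `gtol`.
#'
#' Classical standard errors come from the inverse observed information;
#' robust standard errors from the cluster sandwich estimator with scores
#' summed within respondent and a G/(G-1) small-sample factor (G clusters).
#' `cluster = "task"` instead treats every task as its own cluster
#' (heteroskedasticity-robust only).
#'
#' Fit statistics: null log-likelihood `-T log(k(k-1))`, McFadden
#' pseudo-R-squared, AIC `-2 ll + 2K` and BIC `-2 ll + K log(T)` with
#' `K = v - 1` estimated parameters and T tasks.
#'
#' @param dataset A `bws_survey`.
#' @param reference Reference attribute code; default the lowest-ranked
#'   attribute per [choose_reference()].
#' @param cluster `"respondent"` (default) or `"task"` for the sandwich.
#' @param gtol Gradient max-norm required at the solution.
#' @param maxit Iteration cap for the BFGS stage.
#' @return Object of class `bws_clm`; see Details. Key fields: `beta`,
#'   `robust_se`, `classical_se`, `vcov_robust`, `vcov_classical`,
#'   `ll_model`, `ll_null`, `pseudo_r2`, `aic`, `bic`, `n_obs`, `K`,
#'   `reference`, `converged`, `separation` (codes with diverging
#'   coefficients, if any), `p_value`, `stars`.
#' @examples
#' bd <- bind_attributes(construct_bibd(7, 3, 1), nurse_sow_attributes())
#' ds <- simulate_choices(simulate_respondents(51, seed = 7), bd, seed = 7)
#' fit <- bws_clm(ds, reference = "P")
#' fit$n_obs  # 357
#' @export
bws_clm <- function(dataset, reference = choose_reference(dataset),
                    cluster = c("respondent", "task"),
                    gtol = 1e-6, maxit = 500L) {
  cluster <- match.arg(cluster)
  fr <- clm_frame(dataset, reference)
  p <- length(fr$coef_names)

  negll <- function(b) -clm_eval(b, fr)$ll
  neggr <- function(b) -clm_eval(b, fr)$grad
  opt <- stats::optim(rep(0, p), negll, neggr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  beta <- opt$par
  # Newton polish to drive the gradient below gtol
  converged <- FALSE
  for (it in seq_len(50L)) {
    ev <- clm_eval(beta, fr)
    if (max(abs(ev$grad)) < gtol) { converged <- TRUE; break }
    step <- tryCatch(solve(ev$info, ev$grad), error = function(e) NULL)
    if (is.null(step)) break
    # backtracking on the log-likelihood
    lam <- 1
    repeat {
      cand <- beta + lam * step
      if (clm_eval(cand, fr)$ll >= ev$ll || lam < 1e-8) break
      lam <- lam / 2
    }
    beta <- beta + lam * step
  }
  ev <- clm_eval(beta, fr)
  separation <- fr$coef_names[abs(beta) > 15]
  if (length(separation)) {
    warning("possible separation: diverging coefficient(s) for ",
            paste(separation, collapse = ", "), call. = FALSE)
  }

  vcov_classical <- tryCatch(solve(ev$info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  S <- ev$scores
  G <- if (cluster == "respondent") {
    Sg <- rowsum(S, fr$cluster)
    nrow(Sg)
  } else {
    Sg <- S
    nrow(S)
  }
  meat <- crossprod(Sg)
  correction <- if (G > 1) G / (G - 1) else 1
  vcov_robust <- vcov_classical %*% (correction * meat) %*% vcov_classical

  dimnames(vcov_classical) <- dimnames(vcov_robust) <-
    list(fr$coef_names, fr$coef_names)
  classical_se <- sqrt(pmax(diag(vcov_classical), 0))
  robust_se <- sqrt(pmax(diag(vcov_robust), 0))

  st <- fit_stats(ev$ll, n_tasks = fr$T, k = fr$k, K = p)
  z <- beta / robust_se
  pval <- 2 * stats::pnorm(-abs(z))

  structure(list(
    reference = reference,
    beta = stats::setNames(beta, fr$coef_names),
    classical_se = stats::setNames(classical_se, fr$coef_names),
    robust_se = stats::setNames(robust_se, fr$coef_names),
    vcov_classical = vcov_classical,
    vcov_robust = vcov_robust,
    cluster = cluster,
    n_clusters = G,
    ll_model = ev$ll,
    ll_null = st$ll_null,
    pseudo_r2 = st$pseudo_r2,
    aic = st$aic,
    bic = st$bic,
    n_obs = fr$T,
    K = p,
    k = fr$k,
    converged = converged && opt$convergence == 0,
    separation = separation,
    gradient = stats::setNames(ev$grad, fr$coef_names),
    p_value = stats::setNames(pval, fr$coef_names),
    stars = stats::setNames(p_stars(pval), fr$coef_names)
  ), class = "bws_clm")
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "NS")))
}

#' Fit statistics for a maxdiff conditional logit
#'
#' For T tasks of k attributes (k(k-1) pair alternatives each) and K
#' estimated parameters: null log-likelihood `-T log(k(k-1))` (all
#' utilities equal), McFadden pseudo-R-squared `1 - ll_model / ll_null`,
#' `AIC = -2 ll_model + 2K`, `BIC = -2 ll_model + K log(T)`.
#'
#' @param ll_model Converged log-likelihood.
#' @param n_tasks Number of tasks T.
#' @param k Attributes per task.
#' @param K Number of estimated parameters.
#' @return List with `ll_null`, `pseudo_r2`, `aic`, `bic`.
#' @examples
#' fit_stats(-544.2, 357, 3, 6)$pseudo_r2  # 0.1492...
#' @export
fit_stats <- function(ll_model, n_tasks, k, K) {
  stopifnot(n_tasks > 0, k >= 2)
  ll_null <- -n_tasks * log(k * (k - 1))
  list(ll_null = ll_null,
       pseudo_r2 = 1 - ll_model / ll_null,
       aic = -2 * ll_model + 2 * K,
       bic = -2 * ll_model + K * log(n_tasks))
}

#' @export
print.bws_clm <- function(x, digits = 3, ...) {
  cat("Maxdiff conditional logit (reference:", x$reference, "= 0)\n\n")
  tab <- data.frame(
    coef = round(x$beta, digits),
    robust_se = round(x$robust_se, digits),
    classical_se = round(x$classical_se, digits),
    sig = x$stars
  )
  print(tab)
  cat(sprintf("\nObservations (tasks): %d   clusters (%s): %d\n",
              x$n_obs, x$cluster, x$n_clusters))
  cat(sprintf("LL(0) = %.1f   LL(model) = %.1f   pseudo-R2 = %.4f\n",
              x$ll_null, x$ll_model, x$pseudo_r2))
  cat(sprintf("AIC = %.1f   BIC = %.1f\n", x$aic, x$bic))
  if (!x$converged) cat("WARNING: optimiser did not converge\n")
  if (length(x$separation)) {
    cat("WARNING: possible separation:",
        paste(x$separation, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.bws_clm <- function(object, ...) object$beta

#' @export
vcov.bws_clm <- function(object, robust = TRUE, ...) {
  if (robust) object$vcov_robust else object$vcov_classical
}

#' @export
logLik.bws_clm <- function(object, ...) {
  structure(object$ll_model, df = object$K, nobs = object$n_obs,
            class = "logLik")
}

#' Confidence intervals for maxdiff CLM coefficients
#'
#' Wald intervals on the robust (default) or classical standard errors.
#'
#' @param object A `bws_clm`.
#' @param parm Coefficients to include (default all).
#' @param level Confidence level.
#' @param robust Use robust standard errors.
#' @param ... Unused.
#' @export
confint.bws_clm <- function(object, parm = names(object$beta), level = 0.95,
                            robust = TRUE, ...) {
  se <- if (robust) object$robust_se else object$classical_se
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(object$beta - zq * se, object$beta + zq * se)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out[parm, , drop = FALSE]
}

#' Subgroup conditional logit analysis
#'
#' Splits the respondents on one binary demographic variable and fits the
#' maxdiff conditional logit independently in each category, preserving the
#' pooled reference attribute. Categories too small for identification
#' yield a flagged (non-converged or separated) fit, not an error.
#'
#' @param dataset A `bws_survey`.
#' @param variable Name of a roster column with exactly two categories.
#' @param reference Reference attribute code (default from the pooled
#'   data).
#' @param ... Passed to [bws_clm()].
#' @return Object of class `bws_subgroups`: list with `variable`, `fits`
#'   (named list of `bws_clm` per category) and `table`, a tidy data frame
#'   (variable, category, n_respondents, attribute, estimate, robust_se,
#'   p_value, stars).
#' @export
subgroup_fit <- function(dataset, variable,
                         reference = choose_reference(dataset), ...) {
  roster <- dataset$roster
  if (!(variable %in% names(roster))) {
    stop(sprintf("no demographic variable '%s' in roster", variable),
         call. = FALSE)
  }
  cats <- sort(unique(as.character(roster[[variable]])))
  if (length(cats) < 2L) {
    stop(sprintf("variable '%s' does not split the roster", variable),
         call. = FALSE)
  }
  fits <- list()
  rows <- list()
  for (cat_i in cats) {
    ids <- roster$respondent_id[roster[[variable]] == cat_i]
    sub <- subset_survey(dataset, ids)
    fit <- withCallingHandlers(
      bws_clm(sub, reference = reference, ...),
      warning = function(w) invokeRestart("muffleWarning")
    )
    fits[[cat_i]] <- fit
    rows[[cat_i]] <- data.frame(
      variable = variable, category = cat_i, n_respondents = length(ids),
      attribute = names(fit$beta), estimate = as.numeric(fit$beta),
      robust_se = as.numeric(fit$robust_se),
      p_value = as.numeric(fit$p_value), stars = as.character(fit$stars),
      stringsAsFactors = FALSE
    )
  }
  structure(list(variable = variable, fits = fits,
                 table = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "bws_subgroups")
}

#' Restrict a survey dataset to a subset of respondents
#'
#' @param dataset A `bws_survey`.
#' @param ids Respondent ids to keep.
#' @return A `bws_survey` on the restricted roster.
#' @export
subset_survey <- function(dataset, ids) {
  keep_r <- dataset$roster$respondent_id %in% ids
  keep_resp <- dataset$responses$respondent_id %in% ids
  new_bws_survey(dataset$roster[keep_r, , drop = FALSE],
                 dataset$design,
                 dataset$responses[keep_resp, , drop = FALSE])
}

#' @export
print.bws_subgroups <- function(x, digits = 3, ...) {
  cat("Subgroup maxdiff CLM on", x$variable, "\n")
  tab <- x$table
  tab$estimate <- round(tab$estimate, digits)
  tab$robust_se <- round(tab$robust_se, digits)
  tab$p_value <- signif(tab$p_value, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
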