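# Discrete-time logistic survival model.
#
# The classical baseline: on person-period rows, the conditional hazard of
# interval k is logistic(alpha_k + beta . x). One free intercept per
# interval (no smoothing) gives an unrestricted baseline hazard; the single
# beta shared across intervals is the proportional-odds assumption the
# neural model relaxes. Fitting is penalized maximum likelihood via
# Newton-Raphson with an optional small ridge for separability; continuous
# covariates are standardized internally on training statistics and the
# coefficients reported back on the original scale.

#' Fit a discrete-time logistic hazard model
#'
#' Maximizes the Bernoulli log-likelihood of `event_in_interval` over
#' person-period rows, with one indicator intercept per interval of the
#' scheme plus a shared linear covariate term, and an optional ridge
#' penalty `ridge/2 * ||theta||^2` on all parameters (internal standardized
#' scale) for numerical stability under separation.
#'
#' `time_input` is excluded from the default covariate set: interval
#' midpoint age is an exact linear function of the interval index, so it is
#' collinear with the per-interval intercepts that already give this model
#' an unrestricted baseline hazard.
#'
#' @param table A `person_period_table` from [expand_person_periods()].
#' @param covariates Character vector of covariate columns to use.
#' @param ridge Non-negative ridge penalty (default `1e-6`). With
#'   `ridge = 0` a degenerate likelihood (complete separation, or no events
#'   at all) is reported as a non-convergence error.
#' @param max_iter,tol Newton iteration cap and gradient-norm tolerance.
#' @return An object of class `"hazard_glm"` with elements
#'   `interval_intercepts` (one per scheme interval; `NA` where no rows
#'   were at risk), `coefficients` (original scale), `standardization`,
#'   `scheme`, `loglik` (unpenalized, at the optimum) and `diagnostics`
#'   (`iterations`, `gradient_norm`, `converged`).
#' @export
fit_hazard_glm <- function(table,
                           covariates = setdiff(intersect(pp_covariate_names(),
                                                          names(table)),
                                                "time_input"),
                           ridge = 1e-6, max_iter = 200, tol = 1e-9) {
  if (nrow(table) == 0) stop("person-period table is empty", call. = FALSE)
  if (ridge < 0) stop("'ridge' must be non-negative", call. = FALSE)
  scheme <- attr(table, "scheme")
  nk <- scheme$n_intervals
  if (any(table$interval_index < 1 | table$interval_index > nk))
    stop("table contains interval indices outside its scheme", call. = FALSE)
  y <- table$event_in_interval
  X <- as.matrix(table[, covariates, drop = FALSE])

  cont <- intersect(covariates, pp_continuous_names())
  mu <- stats::setNames(rep(0, length(covariates)), covariates)
  sdv <- stats::setNames(rep(1, length(covariates)), covariates)
  for (nm in cont) {
    mu[nm] <- mean(X[, nm])
    s <- stats::sd(X[, nm])
    if (is.finite(s) && s > 0) sdv[nm] <- s
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  D <- matrix(0, nrow(table), nk)
  D[cbind(seq_len(nrow(table)), table$interval_index)] <- 1
  at_risk <- colSums(D) > 0
  Z <- cbind(D[, at_risk, drop = FALSE], Xs)
  p_all <- ncol(Z)

  theta <- numeric(p_all)
  grad_norm <- Inf
  it <- 0
  pen_ll <- function(th) {
    eta <- drop(Z %*% th)
    sum(y * eta - log1p(exp(eta))) - ridge / 2 * sum(th^2)
  }
  ll_old <- pen_ll(theta)
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1
    eta <- drop(Z %*% theta)
    pr <- stats::plogis(eta)
    g <- drop(crossprod(Z, y - pr)) - ridge * theta
    grad_norm <- max(abs(g))
    if (grad_norm < tol * max(1, nrow(table))) { converged <- TRUE; break }
    w <- pmax(pr * (1 - pr), 1e-10)
    H <- crossprod(Z * w, Z)
    diag(H) <- diag(H) + ridge + 1e-12
    step <- tryCatch(solve(H, g), error = function(e)
      stop("singular information matrix; refit with ridge > 0", call. = FALSE))
    # step-halving on the penalized log-likelihood
    sz <- 1
    repeat {
      cand <- theta + sz * step
      ll_new <- pen_ll(cand)
      if (ll_new >= ll_old - 1e-12 || sz < 1e-8) break
      sz <- sz / 2
    }
    theta <- cand
    ll_old <- ll_new
    if (max(abs(theta)) > 30) {
      if (ridge == 0)
        stop("likelihood is degenerate (separation or no events in some ",
             "stratum): estimates diverge; refit with ridge > 0", call. = FALSE)
    }
    if (max(abs(theta)) > 1e3)
      stop("estimates diverge despite the ridge penalty; data are degenerate",
           call. = FALSE)
  }
  if (ridge == 0 && max(abs(theta)) > 15)
    stop("likelihood is degenerate (separation or no events in some ",
         "stratum): estimates diverge; refit with ridge > 0", call. = FALSE)
  if (!converged && grad_norm > 1e-4 * max(1, nrow(table))) {
    if (ridge == 0)
      stop("discrete-hazard fit did not converge (gradient norm ",
           signif(grad_norm, 3), "); consider ridge > 0", call. = FALSE)
    warning("discrete-hazard fit stopped at iteration cap (gradient norm ",
            signif(grad_norm, 3), ")", call. = FALSE)
  }

  a_std <- stats::setNames(rep(NA_real_, nk), paste0("interval_", seq_len(nk)))
  a_std[at_risk] <- theta[seq_len(sum(at_risk))]
  b_std <- stats::setNames(theta[sum(at_risk) + seq_along(covariates)], covariates)
  b_orig <- b_std / sdv
  shift <- sum(b_std * mu / sdv)
  a_orig <- a_std - shift

  eta <- drop(Z %*% theta)
  structure(list(
    interval_intercepts = a_orig,
    coefficients = b_orig,
    covariates = covariates,
    standardization = list(mean = mu, sd = sdv),
    scheme = scheme, ridge = ridge,
    estimable_intervals = which(at_risk),
    loglik = sum(y * eta - log1p(exp(eta))),
    diagnostics = list(iterations = it, gradient_norm = grad_norm,
                       converged = converged || grad_norm <= 1e-4 * nrow(table))
  ), class = "hazard_glm")
}

#' @export
print.hazard_glm <- function(x, ...) {
  cat(sprintf("<hazard_glm> %d interval intercepts (+%d covariates), loglik %.3f\n",
              length(x$interval_intercepts), length(x$coefficients), x$loglik))
  invisible(x)
}

#' Predict conditional hazards from a discrete-time logistic model
#'
#' @param object A `"hazard_glm"` fit.
#' @param newdata Data frame of person-period rows: `interval_index` plus
#'   the model's covariate columns.
#' @param fill How to treat intervals whose intercept could not be
#'   estimated (no at-risk training rows): `"error"` (default) refuses to
#'   extrapolate; `"carry"` substitutes the nearest estimated intercept
#'   (used when composing whole-horizon survival curves, where late sparse
#'   intervals would otherwise make the curve undefined).
#' @param ... Unused.
#' @return Numeric vector of conditional event probabilities in (0, 1).
#' @export
predict.hazard_glm <- function(object, newdata, fill = c("error", "carry"), ...) {
  fill <- match.arg(fill)
  miss <- setdiff(object$covariates, names(newdata))
  if (length(miss))
    stop("newdata missing covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  k <- newdata$interval_index
  if (any(is.na(k)) || any(k < 1 | k > length(object$interval_intercepts)))
    stop("interval index outside the fitted scheme", call. = FALSE)
  ic <- object$interval_intercepts
  if (anyNA(ic) && fill == "carry") {
    ok <- which(!is.na(ic))
    if (!length(ok)) stop("model has no estimable intervals", call. = FALSE)
    ic <- ic[vapply(seq_along(ic), function(j) ok[which.min(abs(ok - j))],
                    integer(1))]
  }
  a <- ic[k]
  if (anyNA(a))
    stop("no intercept estimated for interval(s) ",
         paste(sort(unique(k[is.na(a)])), collapse = ", "),
         " (no at-risk rows in training data)", call. = FALSE)
  X <- as.matrix(newdata[, object$covariates, drop = FALSE])
  stats::plogis(unname(a) + drop(X %*% object$coefficients))
}

#' Serialize a discrete-hazard model to JSON
#'
#' @param model A `"hazard_glm"`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_hazard_glm <- function(model, path) {
  jsonlite::write_json(list(
    type = "hazard_glm",
    interval_intercepts = model$interval_intercepts,
    coefficients = as.list(model$coefficients),
    covariates = model$covariates,
    standardization = lapply(model$standardization, as.list),
    scheme = model$scheme[c("width", "min_age", "max_age")],
    ridge = model$ridge, loglik = model$loglik
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
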