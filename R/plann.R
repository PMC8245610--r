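# Partial logistic artificial neural network (PLANN).
#
# A feed-forward network with one hidden layer, sigmoid activations
# throughout, fit on the same person-period rows as the logistic model and
# by the same Bernoulli (cross-entropy) likelihood, plus weight decay. The
# sigmoid output is the conditional discrete hazard. Interval time enters
# as an ordinary input (`time_input`), so the network can represent
# non-proportional and non-linear covariate effects that the logistic
# baseline rules out.
#
# Training is full-batch gradient descent with an adaptive step size
# (backtracking: a step that increases the training objective is halved
# and retried, so the accepted-epoch training loss is non-increasing) and
# early stopping on a seeded held-out shuffle split.

#' PLANN hyperparameters
#'
#' @param hidden_units Hidden-layer width (>= 1). Default 8: enough
#'   capacity for low-order interactions at cohort scale without
#'   overwhelming a few hundred events.
#' @param weight_decay Non-negative L2 penalty on the connection weights
#'   (biases are not penalized), on the summed cross-entropy scale.
#'   Default 0.01.
#' @param max_epochs Maximum accepted training epochs.
#' @param patience Early stopping: training stops after this many accepted
#'   epochs without improvement of the held-out loss; weights revert to the
#'   best held-out epoch. `patience = 0` disables early stopping (the full
#'   table is then used for training).
#' @param val_fraction Fraction of rows held out for early stopping.
#' @param learning_rate Initial step size for the adaptive full-batch
#'   gradient descent.
#' @param init_scale Scale of the uniform weight initialization
#'   (`U(-s, s) / sqrt(fan_in)`).
#' @param seed Integer seed controlling initialization and the shuffle
#'   split; fits are fully reproducible given the seed.
#' @param standardize Standardize continuous inputs (including
#'   `time_input`) on training statistics; binary inputs stay 0/1.
#' @return A list of class `"plann_control"`.
#' @export
plann_control <- function(hidden_units = 8, weight_decay = 0.01,
                          max_epochs = 2000, patience = 100,
                          val_fraction = 0.1, learning_rate = 0.5,
                          init_scale = 0.7, seed = 1, standardize = TRUE) {
  if (hidden_units < 1) stop("'hidden_units' must be >= 1", call. = FALSE)
  if (weight_decay < 0) stop("'weight_decay' must be >= 0", call. = FALSE)
  if (max_epochs < 1 || patience < 0) stop("invalid epoch counts", call. = FALSE)
  if (val_fraction < 0 || val_fraction >= 1)
    stop("'val_fraction' must be in [0, 1)", call. = FALSE)
  structure(list(hidden_units = hidden_units, weight_decay = weight_decay,
                 max_epochs = max_epochs, patience = patience,
                 val_fraction = val_fraction, learning_rate = learning_rate,
                 init_scale = init_scale, seed = seed,
                 standardize = standardize),
            class = "plann_control")
}

# forward pass: list(hidden, out); X already standardized, with columns in
# training order
plann_forward <- function(W1, b1, W2, b2, X) {
  H <- stats::plogis(sweep(X %*% W1, 2, b1, "+"))
  list(H = H, p = stats::plogis(drop(H %*% W2) + b2))
}

# objective: summed cross-entropy + decay * sum of squared weights
# (biases are not decayed, so heavy regularization collapses predictions
# toward the marginal event rate, not toward 1/2)
plann_objective <- function(p, y, decay, W1, b1, W2, b2) {
  eps <- 1e-12
  -sum(y * log(p + eps) + (1 - y) * log(1 - p + eps)) +
    decay * (sum(W1^2) + sum(W2^2))
}

plann_gradient <- function(W1, b1, W2, b2, X, y, decay) {
  fw <- plann_forward(W1, b1, W2, b2, X)
  d_out <- fw$p - y                                   # dL/d eta_out
  gW2 <- drop(crossprod(fw$H, d_out)) + 2 * decay * W2
  gb2 <- sum(d_out)
  d_hid <- (d_out %o% W2) * fw$H * (1 - fw$H)         # n x h
  gW1 <- crossprod(X, d_hid) + 2 * decay * W1
  gb1 <- colSums(d_hid)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, p = fw$p)
}

#' Fit a PLANN hazard model
#'
#' @param table A `person_period_table` from [expand_person_periods()];
#'   must include `time_input` among `covariates` for the network to
#'   condition on time.
#' @param control A [plann_control()].
#' @param covariates Covariate columns used as network inputs (default: all
#'   person-period covariates, including `time_input`).
#' @return An object of class `"plann"`: weights (`W1`, `b1`, `W2`, `b2`),
#'   `standardization`, `covariates`, `scheme`, `control` and `history`
#'   (data.frame of per-epoch training/held-out loss).
#' @export
fit_plann <- function(table, control = plann_control(),
                      covariates = intersect(pp_covariate_names(), names(table))) {
  stopifnot(inherits(control, "plann_control"))
  if (nrow(table) == 0) stop("person-period table is empty", call. = FALSE)
  scheme <- attr(table, "scheme")
  y <- table$event_in_interval
  X <- as.matrix(table[, covariates, drop = FALSE])

  mu <- stats::setNames(rep(0, length(covariates)), covariates)
  sdv <- stats::setNames(rep(1, length(covariates)), covariates)
  if (control$standardize) {
    for (nm in intersect(covariates, pp_continuous_names())) {
      mu[nm] <- mean(X[, nm])
      s <- stats::sd(X[, nm])
      if (is.finite(s) && s > 0) sdv[nm] <- s
    }
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  n <- nrow(Xs)
  p <- ncol(Xs)
  h <- control$hidden_units
  with_seed(control$seed, {
    W1 <- matrix(stats::runif(p * h, -control$init_scale, control$init_scale) /
                   sqrt(p), p, h)
    b1 <- stats::runif(h, -control$init_scale, control$init_scale)
    W2 <- stats::runif(h, -control$init_scale, control$init_scale) / sqrt(h)
    b2 <- stats::qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))  # start at base rate
    use_val <- control$patience > 0 && control$val_fraction > 0 && n >= 10
    if (use_val) {
      idx <- sample.int(n)
      n_val <- max(1, floor(control$val_fraction * n))
      val <- idx[seq_len(n_val)]
      trn <- idx[-seq_len(n_val)]
    } else {
      trn <- seq_len(n)
      val <- integer(0)
    }
    Xt <- Xs[trn, , drop = FALSE]; yt <- y[trn]
    Xv <- Xs[val, , drop = FALSE]; yv <- y[val]
    decay <- control$weight_decay

    obj <- function(W1, b1, W2, b2)
      plann_objective(plann_forward(W1, b1, W2, b2, Xt)$p, yt, decay, W1, b1, W2, b2)
    val_loss <- function(W1, b1, W2, b2) {
      if (!length(val)) return(NA_real_)
      pv <- plann_forward(W1, b1, W2, b2, Xv)$p
      eps <- 1e-12
      -mean(yv * log(pv + eps) + (1 - yv) * log(1 - pv + eps))
    }

    lr <- control$learning_rate
    cur <- obj(W1, b1, W2, b2)
    if (!is.finite(cur)) stop("initial PLANN loss is not finite", call. = FALSE)
    best <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 val = val_loss(W1, b1, W2, b2), epoch = 0L)
    stall <- 0L
    hist_tr <- numeric(control$max_epochs)
    hist_val <- numeric(control$max_epochs)
    epoch <- 0L
    while (epoch < control$max_epochs) {
      g <- plann_gradient(W1, b1, W2, b2, Xt, yt, decay)
      gn2 <- sum(g$W1^2) + sum(g$b1^2) + sum(g$W2^2) + g$b2^2
      if (!is.finite(gn2)) stop("PLANN training diverged (non-finite gradient)",
                                call. = FALSE)
      if (sqrt(gn2) < 1e-8 * max(1, length(yt))) break
      accepted <- FALSE
      while (lr > 1e-12) {
        s <- lr / max(1, sqrt(gn2) / length(yt))   # scale-free step
        nW1 <- W1 - s * g$W1; nb1 <- b1 - s * g$b1
        nW2 <- W2 - s * g$W2; nb2 <- b2 - s * g$b2
        new <- obj(nW1, nb1, nW2, nb2)
        if (is.finite(new) && new <= cur + 1e-12) { accepted <- TRUE; break }
        lr <- lr / 2
      }
      if (!accepted) break                      # no descent step found
      W1 <- nW1; b1 <- nb1; W2 <- nW2; b2 <- nb2
      cur <- new
      lr <- min(lr * 1.1, 10)
      epoch <- epoch + 1L
      hist_tr[epoch] <- cur
      vl <- val_loss(W1, b1, W2, b2)
      hist_val[epoch] <- vl
      if (use_val) {
        if (is.na(best$val) || vl < best$val - 1e-9) {
          best <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, val = vl,
                       epoch = epoch)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= control$patience) break
        }
      }
    }
    if (use_val && !is.na(best$val)) {
      W1 <- best$W1; b1 <- best$b1; W2 <- best$W2; b2 <- best$b2
    }
    structure(list(
      W1 = W1, b1 = b1, W2 = W2, b2 = b2,
      covariates = covariates,
      standardization = list(mean = mu, sd = sdv),
      scheme = scheme, control = control,
      history = data.frame(epoch = seq_len(epoch),
                           train_loss = hist_tr[seq_len(epoch)],
                           val_loss = hist_val[seq_len(epoch)]),
      best_epoch = if (use_val) best$epoch else epoch
    ), class = "plann")
  })
}

#' @export
print.plann <- function(x, ...) {
  cat(sprintf("<plann> %d inputs -> %d hidden -> 1; %d epochs (best %d)\n",
              nrow(x$W1), ncol(x$W1), nrow(x$history), x$best_epoch))
  invisible(x)
}

#' Predict conditional hazards from a PLANN model
#'
#' @param object A `"plann"` fit.
#' @param newdata Data frame of person-period rows containing the model's
#'   input columns.
#' @param ... Unused.
#' @return Numeric vector of conditional event probabilities in (0, 1).
#' @export
predict.plann <- function(object, newdata, ...) {
  miss <- setdiff(object$covariates, names(newdata))
  if (length(miss))
    stop("newdata missing input column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(newdata[, object$covariates, drop = FALSE])
  Xs <- sweep(sweep(X, 2, object$standardization$mean), 2,
              object$standardization$sd, "/")
  plann_forward(object$W1, object$b1, object$W2, object$b2, Xs)$p
}

#' Serialize a PLANN model to JSON (weights, scaling, hyperparameters)
#'
#' @param model A `"plann"`.
#' @param path Output file; training history goes to `<path>.history.csv`.
#' @return Invisibly, `path`.
#' @export
write_plann <- function(model, path) {
  jsonlite::write_json(list(
    type = "plann",
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    covariates = model$covariates,
    standardization = lapply(model$standardization, as.list),
    scheme = model$scheme[c("width", "min_age", "max_age")],
    control = unclass(model$control)
  ), path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(model$history, paste0(path, ".history.csv"), row.names = FALSE)
  invisible(path)
}
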