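#' Fit a partial least squares regression by NIPALS
#'
#' Classic single-response NIPALS: X and y are mean-centered, latent
#' components extracted sequentially with deflation. No autoscaling is applied
#' here; similarity-field descriptor blocks arrive already block-scaled from
#' [assemble_descriptors()].
#'
#' Conventions (stated because the source tables give none):
#' \itemize{
#'   \item `R2 = 1 - SS_res / SS_tot`
#'   \item `SEE = sqrt(SS_res / (n - a - 1))` with `a` fitted components
#'   \item `F = (R2 / a) / ((1 - R2) / (n - a - 1))`
#' }
#' A constant response is fitted, by convention, with zero coefficients and
#' `R2 = 0`. If the matrix runs out of rank before `n_components`, extraction
#' stops early with a warning.
#'
#' @param X numeric matrix, observations x descriptors
#' @param y numeric response vector
#' @param n_components number of latent components requested
#' @return an object of class `pls_model` with elements `coefficients`,
#'   `intercept`, `n_components` (actually fitted), `fitted`, `residuals`,
#'   `r2`, `see`, `f_stat`, `y_mean`, plus the NIPALS loadings
#' @export
fit_pls <- function(X, y, n_components = 2L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2L, p >= 1L, all(is.finite(X)), all(is.finite(y)))
  n_components <- as.integer(n_components)
  if (n < n_components + 1L) {
    stop_duotox("need at least n_components + 1 observations",
                class = "duotox_config_error")
  }

  x_means <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_means)
  yc <- y - y_mean
  ss_tot <- sum(yc^2)

  W <- matrix(0, p, n_components)   # X weights
  P <- matrix(0, p, n_components)   # X loadings
  Q <- numeric(n_components)        # y loadings
  Tm <- matrix(0, n, n_components)  # scores
  tol <- 1e-12 * max(1, sum(Xc^2))

  a <- 0L
  if (ss_tot > 0) {
    Xd <- Xc; yd <- yc
    for (k in seq_len(n_components)) {
      w <- crossprod(Xd, yd)[, 1L]
      wn <- sqrt(sum(w^2))
      if (!is.finite(wn) || wn^2 < tol * 1e-6) break
      w <- w / wn
      t_ <- Xd %*% w
      tt <- sum(t_^2)
      if (tt < tol) break
      p_ <- crossprod(Xd, t_)[, 1L] / tt
      q_ <- sum(yd * t_) / tt
      Xd <- Xd - tcrossprod(t_, p_)
      yd <- yd - q_ * t_[, 1L]
      a <- a + 1L
      W[, a] <- w; P[, a] <- p_; Q[a] <- q_; Tm[, a] <- t_
    }
  }
  if (a < n_components && ss_tot > 0) {
    warning(sprintf("rank limited: fitted %d of %d requested components", a, n_components))
  }

  if (a == 0L) {
    beta <- numeric(p)
  } else {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    beta <- drop(Wa %*% solve(crossprod(Pa, Wa), Q[seq_len(a)]))
  }
  intercept <- y_mean - sum(x_means * beta)
  fitted <- drop(X %*% beta) + intercept
  ss_res <- sum((y - fitted)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  dof <- n - a - 1L
  see <- if (dof > 0) sqrt(ss_res / dof) else NA_real_
  f_stat <- if (a > 0 && dof > 0 && r2 < 1) (r2 / a) / ((1 - r2) / dof) else
    if (r2 >= 1 && a > 0) Inf else NA_real_

  structure(
    list(coefficients = beta, intercept = intercept,
         n_components = a, requested_components = n_components,
         x_means = x_means, y_mean = y_mean,
         fitted = fitted, residuals = y - fitted,
         r2 = r2, see = see, f_stat = f_stat,
         weights = W[, seq_len(max(a, 1L)), drop = FALSE],
         loadings = P[, seq_len(max(a, 1L)), drop = FALSE],
         scores = Tm[, seq_len(max(a, 1L)), drop = FALSE]),
    class = "pls_model"
  )
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$coefficients) + object$intercept
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), R2 = %.4f, SEE = %.4g, F = %.4g\n",
              x$n_components, x$r2, x$see, x$f_stat))
  invisible(x)
}

#' Leave-one-out cross-validated q2
#'
#' Refits the PLS model n times, each excluding one observation, and computes
#' `q2 = 1 - PRESS / SS_tot` with `SS_tot` about the full-set mean, plus the
#' cross-validated error `sqrt(PRESS / n)` (the cSDEP-style quantity).
#'
#' @param X descriptor matrix
#' @param y response
#' @param n_components components per fold fit
#' @return list with `q2`, `csdep`, `press`, `predictions`
#' @export
loo_q2 <- function(X, y, n_components = 2L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(n >= 3L)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- suppressWarnings(fit_pls(X[-i, , drop = FALSE], y[-i], n_components))
    pred[i] <- predict(fit, X[i, , drop = FALSE])
  }
  press <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  q2 <- if (ss_tot > 0) 1 - press / ss_tot else NA_real_
  list(q2 = q2, csdep = sqrt(press / n), press = press, predictions = pred)
}

#' Scan the number of components by LOO q2
#'
#' Evaluates q2 for 1..`max_components` components and returns the optimum:
#' either the q2-maximizing count (default; ties broken toward fewer
#' components) or the count minimizing the cross-validated error.
#'
#' @param X descriptor matrix
#' @param y response
#' @param max_components upper bound of the scan (capped at `nrow(X) - 2`)
#' @param criterion `"q2max"` or `"sep_min"`
#' @return list with `n_components`, `q2`, `csdep`, and the per-count `scan`
#' @export
scan_components <- function(X, y, max_components = 10L,
                            criterion = c("q2max", "sep_min")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  kmax <- min(as.integer(max_components), nrow(X) - 2L, ncol(X))
  stopifnot(kmax >= 1L)
  scan <- data.frame(n_components = seq_len(kmax), q2 = NA_real_, csdep = NA_real_)
  for (k in seq_len(kmax)) {
    cv <- loo_q2(X, y, k)
    scan$q2[k] <- cv$q2
    scan$csdep[k] <- cv$csdep
  }
  best <- if (criterion == "q2max") which.max(scan$q2) else which.min(scan$csdep)
  list(n_components = scan$n_components[best], q2 = scan$q2[best],
       csdep = scan$csdep[best], scan = scan)
}

#' External test-set validation
#'
#' `r2_pred = (SD - PRESS) / SD` where `SD` is the sum of squared deviations
#' of the test responses from the *training-set* mean and `PRESS` the sum of
#' squared prediction errors; `SEP = sqrt(PRESS / n_test)`.
#'
#' @param model fitted [fit_pls()] model
#' @param X_test,y_test external test set (>= 2 rows)
#' @param training_mean mean response of the training set; defaults to the
#'   model's stored `y_mean`
#' @return list with `r2_pred`, `sep`, `press`, `predictions`, `defined`
#' @export
external_validation <- function(model, X_test, y_test,
                                training_mean = model$y_mean) {
  stopifnot(inherits(model, "pls_model"))
  X_test <- as.matrix(X_test); y_test <- as.numeric(y_test)
  stopifnot(nrow(X_test) >= 2L, length(y_test) == nrow(X_test))
  pred <- predict(model, X_test)
  press <- sum((y_test - pred)^2)
  sd_ <- sum((y_test - training_mean)^2)
  defined <- sd_ > 0
  if (!defined) warning("test responses identical to training mean; r2_pred undefined")
  list(r2_pred = if (defined) (sd_ - press) / sd_ else NA_real_,
       sep = sqrt(press / length(y_test)),
       press = press, predictions = pred, defined = defined)
}

#' Per-field contribution percentages
#'
#' Field f contributes `sum_{j in f} |coef_j| * sd_j`, normalized to 100%
#' across fields, with `sd_j` the descriptor-column standard deviation in the
#' matrix the model was fitted to.
#'
#' @param model fitted [fit_pls()] model
#' @param descriptors a `field_descriptors` object from
#'   [assemble_descriptors()], or a factor/character vector assigning each
#'   descriptor column to a field (in which case `X` must be given)
#' @param X descriptor matrix (only when `descriptors` is a column-field map)
#' @return named numeric vector of percentages summing to 100
#' @export
field_contributions <- function(model, descriptors, X = NULL) {
  stopifnot(inherits(model, "pls_model"))
  if (inherits(descriptors, "field_descriptors")) {
    fields <- descriptors$columns$field
    X <- descriptors$X
  } else {
    fields <- as.character(descriptors)
    stopifnot(!is.null(X))
  }
  X <- as.matrix(X)
  stopifnot(length(fields) == ncol(X), length(model$coefficients) == ncol(X))
  sds <- apply(X, 2L, stats::sd)
  mass <- tapply(abs(model$coefficients) * sds, fields, sum)
  lv <- if (inherits(descriptors, "field_descriptors")) descriptors$field_names else
    sort(unique(fields))
  out <- stats::setNames(rep(0, length(lv)), lv)
  out[names(mass)] <- mass
  total <- sum(out)
  if (total <= 0) return(out)  # all-zero model: report zeros
  100 * out / total
}
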