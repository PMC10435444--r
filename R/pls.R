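#' Partial least squares regression (PLS1, NIPALS)
#'
#' Fits a single-response PLS model by the classical NIPALS recursion.
#' For each latent variable `a`: the weight `w_a = X'y / ||X'y||`, score
#' `t_a = X w_a`, y-loading `q_a = t_a'y / t_a't_a`, x-loading
#' `p_a = X't_a / t_a't_a`, then `X` and `y` are deflated by the rank-one
#' fits. The regression vector on centered data is
#' `b = W (P'W)^{-1} q`. `X` columns and `y` are mean-centered internally;
#' the centering vectors are stored for prediction.
#'
#' If the deflated residual becomes (numerically) orthogonal to `y` before
#' `ncomp` components are extracted, fitting stops early and the model is
#' returned with fewer latent variables and `early_stop = TRUE` (with a
#' warning).
#'
#' @param X n-by-p predictor matrix (preprocessed spectra).
#' @param y length-n response (stem water potential, MPa).
#' @param ncomp number of latent variables, at most `min(n - 1, p)`.
#' @param wavelengths optional channel labels carried into coefficients
#'   and VIP scores.
#' @return An object of class `"pls1"` with components `weights` (p x A),
#'   `loadings` (p x A), `yloadings` (A), `scores` (n x A), `b` (p),
#'   `x_mean`, `y_mean`, `ncomp`, `fitted.values`, `residuals`.
#' @seealso [vip_scores()], [cross_validate()], [psi_model()]
#' @export
pls_fit <- function(X, y, ncomp, wavelengths = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("PLS needs at least two samples")
  if (length(y) != n) stop("X and y sizes differ")
  if (ncomp < 1L || ncomp > min(n - 1L, p)) {
    stop(sprintf("ncomp must lie in [1, min(n-1, p)] = [1, %d]",
                 min(n - 1L, p)))
  }
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean); yc <- y - y_mean
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tt <- matrix(0, n, ncomp); q <- numeric(ncomp)
  tol <- 1e-12 * max(1, sqrt(sum(yc^2)) * sqrt(sum(Xc^2)))
  early <- FALSE
  A <- 0L
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw <= tol) { early <- TRUE; break }
    w <- w / nw
    t_a <- drop(Xc %*% w)
    tt <- sum(t_a^2)
    if (tt <= tol) { early <- TRUE; break }
    q_a <- sum(t_a * yc) / tt
    p_a <- drop(crossprod(Xc, t_a)) / tt
    Xc <- Xc - tcrossprod(t_a, p_a)
    yc <- yc - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tt[, a] <- t_a; q[a] <- q_a
    A <- a
  }
  if (A == 0L) {
    ## y orthogonal to X (e.g. constant response): null model
    warning("NIPALS deflation exhausted at the first component: returning the null model")
    b <- numeric(p)
    W <- W[, 0, drop = FALSE]; P <- P[, 0, drop = FALSE]
    Tt <- Tt[, 0, drop = FALSE]; q <- numeric(0)
  } else {
    if (early) {
      warning(sprintf("NIPALS deflation exhausted: model reduced to %d latent variable(s)", A))
    }
    W <- W[, seq_len(A), drop = FALSE]
    P <- P[, seq_len(A), drop = FALSE]
    Tt <- Tt[, seq_len(A), drop = FALSE]
    q <- q[seq_len(A)]
    b <- drop(W %*% solve(crossprod(P, W), q))
  }
  fitted <- drop(sweep(X, 2, x_mean) %*% b) + y_mean
  structure(list(weights = W, loadings = P, yloadings = q, scores = Tt,
                 b = b, x_mean = x_mean, y_mean = y_mean,
                 ncomp = A, requested_ncomp = ncomp, early_stop = early,
                 wavelengths = wavelengths,
                 fitted.values = fitted, residuals = y - fitted, y = y),
            class = "pls1")
}

#' @export
print.pls1 <- function(x, ...) {
  cat(sprintf("PLS1 (NIPALS): %d latent variable(s), %d predictors, n = %d\n",
              x$ncomp, length(x$b), length(x$y)))
  m <- regression_metrics(x$y, x$fitted.values)
  cat(sprintf("  calibration: R2c = %.4f, RMSEC = %.4f\n", m$r2, m$rmse))
  invisible(x)
}

#' @export
summary.pls1 <- function(object, ...) {
  m <- regression_metrics(object$y, object$fitted.values)
  ss_t <- colSums(object$scores^2)
  expl <- if (object$ncomp) object$yloadings^2 * ss_t /
    sum((object$y - object$y_mean)^2) else numeric(0)
  out <- list(ncomp = object$ncomp, metrics = m,
              y_variance_explained = expl, early_stop = object$early_stop)
  class(out) <- "summary.pls1"
  out
}

#' @export
print.summary.pls1 <- function(x, ...) {
  cat(sprintf("PLS1 model, %d latent variable(s)%s\n", x$ncomp,
              if (x$early_stop) " (early NIPALS stop)" else ""))
  cat(sprintf("  R2c = %.4f, RMSEC = %.4f MPa\n", x$metrics$r2,
              x$metrics$rmse))
  if (length(x$y_variance_explained)) {
    cat("  y-variance explained per LV:\n")
    cat("   ", paste(sprintf("%.3f", x$y_variance_explained),
                     collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
coef.pls1 <- function(object, ...) {
  b <- object$b
  if (!is.null(object$wavelengths)) names(b) <- object$wavelengths
  attr(b, "intercept") <- object$y_mean - sum(object$x_mean * object$b)
  b
}

#' @export
predict.pls1 <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$b)) {
    stop(sprintf("newdata has %d channels; model was trained on %d",
                 ncol(newdata), length(object$b)))
  }
  drop(sweep(newdata, 2, object$x_mean) %*% object$b) + object$y_mean
}

#' @export
fitted.pls1 <- function(object, ...) object$fitted.values

#' @export
residuals.pls1 <- function(object, ...) object$residuals

#' Venetian-blind fold assignment
#'
#' Interleaved k-fold split: sample `i` (in stored dataset order) goes to
#' fold `((i - 1) mod k) + 1`.
#'
#' @param n number of samples (`n >= k`).
#' @param k number of folds (default 10).
#' @return Integer fold id per sample, values in `1..k`.
#' @export
venetian_folds <- function(n, k = 10L) {
  if (k < 2L) stop("venetian blinds need at least 2 folds")
  if (n < k) stop(sprintf("cannot split %d samples into %d folds", n, k))
  as.integer(((seq_len(n) - 1L) %% k) + 1L)
}

## First-local-minimum rule for model complexity: the smallest A whose
## error is strictly below the next one; ties advance (treated as still
## decreasing); a monotonically non-increasing curve selects the last A.
first_local_min <- function(v) {
  for (a in seq_len(length(v) - 1L)) if (v[a] < v[a + 1L]) return(a)
  length(v)
}

#' Venetian-blind cross-validation of a PLS1 model
#'
#' For each fold, the model is refit on the remaining samples —
#' preprocessing and mean-centering are recomputed inside the training
#' fold only — and the held-out samples are predicted at every number of
#' latent variables up to `a_max`. The retained complexity is the first
#' local minimum of RMSECV (the smallest A with
#' `RMSECV(A) < RMSECV(A + 1)`; a monotonically decreasing curve selects
#' `a_max`): not necessarily the absolute minimum, which guards against
#' overfitting.
#'
#' @param X n-by-p raw (or already preprocessed) spectra matrix.
#' @param y length-n response, MPa.
#' @param k number of venetian-blind folds (default 10).
#' @param a_max maximum latent variables scanned (default 20; capped at
#'   what the smallest training fold supports).
#' @param preproc optional [preproc_config()] applied inside each fold
#'   (train and held-out separately).
#' @param wavelengths required when `preproc` is given.
#' @return A `"pls_cv"` object: `rmsecv_by_lv`, `chosen_lv`, `r2cv` (at
#'   the chosen complexity), `folds`, and the cross-validated predictions
#'   `cv_pred` (n x a_max).
#' @export
cross_validate <- function(X, y, k = 10L, a_max = 20L, preproc = NULL,
                           wavelengths = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  folds <- venetian_folds(n, k)
  a_max <- min(a_max, n - max(table(folds)) - 1L, ncol(X))
  if (a_max < 1L) stop("not enough samples per fold to fit any latent variable")
  cv_pred <- matrix(NA_real_, n, a_max)
  a_supported <- a_max
  for (f in seq_len(k)) {
    test <- folds == f
    Xtr <- X[!test, , drop = FALSE]; Xte <- X[test, , drop = FALSE]
    if (!is.null(preproc)) {
      Xtr <- apply_pipeline(Xtr, wavelengths, preproc)
      Xte <- apply_pipeline(Xte, wavelengths, preproc)
    }
    ## an early NIPALS stop inside a fold is expected when the data are
    ## low rank; the scan is truncated to what every fold supports
    fit <- suppressWarnings(pls_fit(Xtr, y[!test], a_max))
    a_supported <- min(a_supported, max(fit$ncomp, 1L))
    Xte_c <- sweep(Xte, 2, fit$x_mean)
    for (a in seq_len(fit$ncomp)) {
      Wa <- fit$weights[, seq_len(a), drop = FALSE]
      Pa <- fit$loadings[, seq_len(a), drop = FALSE]
      ba <- drop(Wa %*% solve(crossprod(Pa, Wa),
                              fit$yloadings[seq_len(a)]))
      cv_pred[test, a] <- drop(Xte_c %*% ba) + fit$y_mean
    }
    if (fit$ncomp < a_max) {  # early NIPALS stop: error flat beyond
      for (a in seq(fit$ncomp + 1L, a_max)) {
        cv_pred[test, a] <- cv_pred[test, fit$ncomp]
      }
    }
  }
  cv_pred <- cv_pred[, seq_len(a_supported), drop = FALSE]
  a_max <- a_supported
  rmsecv <- sqrt(colMeans((cv_pred - y)^2))
  chosen <- first_local_min(rmsecv)
  sst <- sum((y - mean(y))^2)
  r2cv <- 1 - sum((cv_pred[, chosen] - y)^2) / sst
  structure(list(rmsecv_by_lv = rmsecv, chosen_lv = chosen, r2cv = r2cv,
                 folds = folds, cv_pred = cv_pred, k = k, a_max = a_max),
            class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf("<%d-fold venetian-blind CV: chosen LV = %d, RMSECV = %.4f MPa, R2cv = %.4f>\n",
              x$k, x$chosen_lv, x$rmsecv_by_lv[x$chosen_lv], x$r2cv))
  invisible(x)
}

#' Variable importance in the projection
#'
#' For wavelength `j` over a model with A latent variables:
#' `VIP_j = sqrt( p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a )`
#' where `SSY_a = q_a^2 t_a't_a` is the y-sum-of-squares explained by
#' dimension `a`. The mean of squared scores is 1 by construction, so
#' wavelengths with VIP > 1 are the influential ones.
#'
#' @param model a fitted [pls_fit()] model.
#' @return A `"vip_scores"` object: `scores` (per wavelength),
#'   `influential` (indices with score > 1), `wavelengths`.
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "pls1") || model$ncomp < 1L) {
    stop("vip_scores needs a fitted PLS model with at least one latent variable")
  }
  W <- model$weights
  ssy <- model$yloadings^2 * colSums(model$scores^2)
  wnorm2 <- colSums(W^2)  # 1 by construction, kept for safety
  p <- nrow(W)
  scores <- sqrt(p * drop(W^2 %*% (ssy / wnorm2)) / sum(ssy))
  if (!is.null(model$wavelengths)) names(scores) <- model$wavelengths
  structure(list(scores = scores, influential = which(scores > 1),
                 wavelengths = model$wavelengths, ncomp = model$ncomp),
            class = "vip_scores")
}

#' @export
print.vip_scores <- function(x, ...) {
  cat(sprintf("<VIP scores: %d wavelengths, %d influential (>1), max %.2f%s>\n",
              length(x$scores), length(x$influential), max(x$scores),
              if (!is.null(x$wavelengths))
                sprintf(" at %.1f nm", x$wavelengths[which.max(x$scores)])
              else ""))
  invisible(x)
}

#' External validation split
#'
#' Holds out a fixed number of samples per measurement date for external
#' (prediction) validation. Samples attaining the date's maximum or
#' minimum potential are never eligible — extremes stay in calibration to
#' limit the influence of outliers on the validation metrics. With seven
#' samples per date over six 36-sample dates this reserves 42 of 216
#' samples, about 20% of the dataset.
#'
#' @param samples a [psi_samples()] object.
#' @param per_date validation samples drawn per date (default 7). `NULL`
#'   derives it from `frac`.
#' @param frac target validation fraction, used only when
#'   `per_date = NULL`.
#' @param rng_seed integer seed; the split is reproducible.
#' @return list with `train` and `validation` [psi_samples()] plus the
#'   index vectors `train_idx`, `val_idx`.
#' @export
external_split <- function(samples, per_date = 7L, frac = 0.20,
                           rng_seed = 1L) {
  info <- samples$info
  dates <- unique(info$date)
  if (is.null(per_date)) {
    per_date <- max(1L, round(frac * stats::median(table(info$date))))
  }
  val_idx <- integer(0)
  with_seed(rng_seed, {
    for (d in dates) {
      idx <- which(info$date == d)
      psi <- info$psi_mpa[idx]
      extreme <- psi == max(psi) | psi == min(psi)
      eligible <- idx[!extreme]
      if (length(eligible) < per_date) {
        stop(sprintf("date %s has only %d eligible samples (need %d after dropping extremes)",
                     d, length(eligible), per_date))
      }
      val_idx <- c(val_idx, sample(eligible, per_date))
    }
  })
  val_idx <- sort(val_idx)
  train_idx <- setdiff(seq_len(nrow(info)), val_idx)
  list(train = samples[train_idx], validation = samples[val_idx],
       train_idx = train_idx, val_idx = val_idx)
}

#' Regression quality metrics
#'
#' `R2 = 1 - SSE/SST` (coefficient of determination about the
#' evaluation-set mean — not squared Pearson correlation, which is also
#' returned since chemometrics software varies) and `RMSE = sqrt(SSE/n)`.
#'
#' @param obs observed values.
#' @param pred predicted values.
#' @return list with `r2`, `rmse`, `bias`, `r2_pearson`, `n`.
#' @export
regression_metrics <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("obs and pred lengths differ")
  if (length(obs) < 2L) stop("metrics need at least two samples")
  sse <- sum((obs - pred)^2)
  sst <- sum((obs - mean(obs))^2)
  list(r2 = 1 - sse / sst,
       rmse = sqrt(sse / length(obs)),
       bias = mean(pred - obs),
       r2_pearson = if (stats::sd(pred) > 0) stats::cor(obs, pred)^2 else 0,
       n = length(obs))
}
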