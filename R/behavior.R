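#' Spearman rank correlation with Bonferroni-corrected significance
#'
#' Rank correlation with average ranks for ties, two-sided p-value, and a
#' significance call at `alpha / n_tests` (the three depression scales make
#' the conventional family of three). The p-value uses the t approximation
#' for n >= 10 and the exact permutation distribution for n < 10.
#'
#' @param values numeric vector (e.g. per-subject connectivity metric).
#' @param scores numeric vector of the same length (behavior scores).
#' @param n_tests Bonferroni family size (default 3).
#' @param alpha nominal level (default 0.05).
#' @return List with `rho`, `p`, `significant`, `n`, and `flagged`
#'   (`TRUE` when either input is constant, with `rho`/`p` set to `NA`).
#' @export
spearman_bonferroni <- function(values, scores, n_tests = 3L, alpha = 0.05) {
  ok <- is.finite(values) & is.finite(scores)
  x <- values[ok]; y <- scores[ok]
  n <- length(x)
  if (n < 4L) stop_psd("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, significant = FALSE, n = n,
                flagged = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- if (n >= 10L) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  } else {
    spearman_perm_p(rx, ry, rho)
  }
  p <- min(p, 1)
  list(rho = rho, p = p, significant = p < alpha / n_tests, n = n,
       flagged = FALSE)
}

# Exact two-sided permutation p-value for Spearman rho at small n:
# enumerate all n! assignments of one rank vector.
spearman_perm_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  perms <- all_permutations(n)
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  stats_perm <- as.numeric(matrix(ryc[perms], nrow(perms)) %*% rxc) / denom
  mean(abs(stats_perm) >= abs(rho_obs) - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Ridge regression with leave-one-out cross-validation
#'
#' For every candidate penalty, each subject is held out in turn: features
#' are standardized with training-fold statistics only, a ridge model with
#' unpenalized intercept is fitted on the training fold
#' (`beta = (X'X + lambda I)^(-1) X' (y - ybar)`), and the held-out score is
#' predicted. The chosen penalty minimizes the LOOCV mean squared error
#' (ties to the smaller lambda); reported predictions are the LOOCV
#' predictions at that penalty and performance is their Spearman rank
#' correlation with the observed scores.
#'
#' @param features n-subjects x n-features numeric matrix (no missing
#'   entries).
#' @param targets numeric vector of observed scores.
#' @param lambda_grid positive penalties; default 17 values log-spaced over
#'   `[1e-3, 1e3]`.
#' @param n_tests,alpha passed to [spearman_bonferroni()] for the
#'   performance test.
#' @return Object of class `prediction_result`: `chosen_lambda`,
#'   `predictions`, `rho`, `p`, `significant`, `n_features`, `n_subjects`,
#'   `cv_mse` (named by lambda), `fold_coefficients` (the standardized-scale
#'   ridge coefficients of each training fold at the chosen penalty), and
#'   `flagged` for a constant target.
#' @export
ridge_loocv_predict <- function(features, targets,
                                lambda_grid = 10^seq(-3, 3, length.out = 17),
                                n_tests = 3L, alpha = 0.05) {
  X <- as.matrix(features)
  y <- as.numeric(targets)
  n <- nrow(X)
  if (n < 5L) stop_psd("need at least 5 subjects for LOOCV prediction")
  if (length(y) != n) stop_psd("targets must match feature rows")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop_psd("features/targets contain missing or non-finite entries")
  if (any(lambda_grid <= 0)) stop_psd("all lambda values must be positive")
  lambda_grid <- sort(lambda_grid)
  p <- ncol(X)
  preds <- matrix(NA_real_, n, length(lambda_grid))
  coefs <- array(NA_real_, c(n, p, length(lambda_grid)))
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    mu <- colMeans(Xtr)
    sd_tr <- apply(Xtr, 2L, stats::sd)
    sd_tr[sd_tr == 0] <- 1
    Z <- sweep(sweep(Xtr, 2L, mu, "-"), 2L, sd_tr, "/")
    z_new <- (X[i, ] - mu) / sd_tr
    ybar <- mean(ytr)
    G <- crossprod(Z)
    Zy <- crossprod(Z, ytr - ybar)
    for (j in seq_along(lambda_grid)) {
      beta <- solve(G + diag(lambda_grid[j], p), Zy)
      preds[i, j] <- ybar + sum(z_new * beta)
      coefs[i, , j] <- beta
    }
  }
  cv_mse <- colMeans((preds - y)^2)
  names(cv_mse) <- signif(lambda_grid, 6)
  best <- which.min(cv_mse)               # ties: smallest lambda (sorted grid)
  predictions <- preds[, best]
  if (stats::sd(y) == 0) {
    perf <- list(rho = NA_real_, p = NA_real_, significant = FALSE, flagged = TRUE)
  } else {
    perf <- spearman_bonferroni(y, predictions, n_tests = n_tests, alpha = alpha)
  }
  structure(list(chosen_lambda = lambda_grid[best], predictions = predictions,
                 rho = perf$rho, p = perf$p, significant = perf$significant,
                 n_features = p, n_subjects = n, cv_mse = cv_mse,
                 fold_coefficients = coefs[, , best, drop = TRUE],
                 flagged = isTRUE(perf$flagged)),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "<prediction_result> n=%d, %d feature(s), lambda=%g, rho=%.3f (p=%.4g%s)\n",
    x$n_subjects, x$n_features, x$chosen_lambda, x$rho, x$p,
    if (x$significant) ", significant" else ""))
  invisible(x)
}
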