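#' Fit a one-dimensional Gaussian mixture by expectation-maximization
#'
#' The workhorse behind simplified spatial patterns: a K-component univariate
#' Gaussian mixture fitted to pooled RMS amplitudes from all channels.  The
#' E-step computes responsibilities `r_ik` proportional to
#' `w_k * N(x_i; mu_k, sigma_k^2)`; the M-step re-estimates weights, means
#' and variances from the weighted samples.  Iteration stops when the
#' relative log-likelihood improvement falls below `tol` or after `max_iter`
#' iterations.  Components are relabeled by ascending mean after fitting, so
#' component 1 is always the quietest (its 0-based cluster index 0); this
#' makes cluster indices comparable across fits.
#'
#' Initialization is deterministic: means at the `(2i-1)/(2K)` quantiles of
#' the data, all variances equal to the pooled variance, uniform weights.
#' With `restarts > 0`, that fit competes against `restarts` seeded
#' random-start fits (means drawn from the data) and the best final
#' log-likelihood wins.  A variance floor of `var_floor_frac` times the
#' pooled variance prevents singular collapse; `floor_hit` records whether it
#' was ever active in the returned fit.
#'
#' @param x Numeric vector of observations (pooled RMS amplitudes, uV).
#' @param K Number of mixture components (>= 1).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Relative log-likelihood improvement below which EM stops
#'   (default 1e-8).
#' @param restarts Number of additional random-start fits (default 0).
#' @param seed Seed for the random restarts (ignored when `restarts = 0`).
#' @param var_floor_frac Variance floor as a fraction of the pooled variance.
#' @param init Optional list with `weights`, `means`, `variances` overriding
#'   the default initialization (used e.g. to compare against a reference EM
#'   from an identical starting point).
#'
#' @return An object of class `gmm1d` with elements `K`, `weights`, `means`,
#'   `variances`, `logLik`, `ll_trace` (per-iteration log-likelihood),
#'   `n`, `iterations`, `converged`, `floor_hit`, `degenerate`.
#' @seealso [fit_gmm()] for the feature-series interface, [discretize()],
#'   [predict.gmm1d()]
#' @export
gmm1d <- function(x, K, max_iter = 500, tol = 1e-8, restarts = 0,
                  seed = NULL, var_floor_frac = 1e-6, init = NULL) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("x contains non-finite values")
  n <- length(x)
  if (K < 1) stop("K must be a positive integer")
  K <- as.integer(K)
  u <- length(unique(x))
  degenerate <- FALSE
  if (u == 1L && K > 1L) {
    warning("all observations identical; collapsing to a single component")
    K <- 1L
    degenerate <- TRUE
  } else if (u < K) {
    stop("K = ", K, " exceeds the number of distinct values (", u, ")")
  }
  pooled_var <- if (n > 1) stats::var(x) * (n - 1) / n else 0
  floor_val <- max(var_floor_frac * pooled_var, .Machine$double.eps)

  if (K == 1L) {
    v <- max(pooled_var, floor_val)
    ll <- sum(stats::dnorm(x, mean(x), sqrt(v), log = TRUE))
    return(structure(
      list(K = 1L, weights = 1, means = mean(x), variances = v,
           logLik = ll, ll_trace = ll, n = n, iterations = 0L,
           converged = TRUE, floor_hit = pooled_var < floor_val,
           degenerate = degenerate, var_floor = floor_val,
           call = match.call()),
      class = "gmm1d"))
  }

  run_em <- function(w, mu, v) {
    ll_trace <- numeric(0)
    ll_prev <- -Inf
    floor_hit <- FALSE
    converged <- FALSE
    iter <- 0L
    lp <- matrix(0, n, K)
    repeat {
      # E-step in log space for numerical stability
      for (k in seq_len(K))
        lp[, k] <- log(w[k]) - 0.5 * log(2 * pi * v[k]) -
          (x - mu[k])^2 / (2 * v[k])
      m <- lp[cbind(seq_len(n), max.col(lp, ties.method = "first"))]
      lse <- m + log(rowSums(exp(lp - m)))
      ll <- sum(lse)
      ll_trace <- c(ll_trace, ll)
      if (iter > 0 &&
          (ll - ll_prev) <= tol * abs(ll_prev)) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
      ll_prev <- ll
      r <- exp(lp - lse)
      nk <- .colSums(r, n, K)
      w <- nk / n
      mu <- .colSums(r * x, n, K) / nk
      v <- .colSums(r * (x - rep(mu, each = n))^2, n, K) / nk
      if (any(v < floor_val)) {
        floor_hit <- TRUE
        v <- pmax(v, floor_val)
      }
      iter <- iter + 1L
    }
    list(w = w, mu = mu, v = v, ll = ll, ll_trace = ll_trace,
         iterations = iter, converged = converged, floor_hit = floor_hit)
  }

  inits <- list()
  if (is.null(init)) {
    q <- as.numeric(stats::quantile(x, (2 * seq_len(K) - 1) / (2 * K),
                                    names = FALSE))
    inits[[1]] <- list(w = rep(1 / K, K), mu = q,
                       v = rep(max(pooled_var, floor_val), K))
    if (restarts > 0) {
      if (!is.null(seed)) set.seed(seed)
      for (r in seq_len(restarts))
        inits[[r + 1]] <- list(w = rep(1 / K, K),
                               mu = sample(unique(x), K),
                               v = rep(max(pooled_var, floor_val), K))
    }
  } else {
    inits[[1]] <- list(w = init$weights, mu = init$means,
                       v = init$variances)
  }

  best <- NULL
  for (ini in inits) {
    fit <- run_em(ini$w, ini$mu, ini$v)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }

  ord <- order(best$mu)
  structure(
    list(K = K, weights = best$w[ord], means = best$mu[ord],
         variances = best$v[ord], logLik = best$ll,
         ll_trace = best$ll_trace, n = n, iterations = best$iterations,
         converged = best$converged, floor_hit = best$floor_hit,
         degenerate = degenerate, var_floor = floor_val,
         call = match.call()),
    class = "gmm1d")
}

#' Fit a pooled amplitude mixture from a feature series
#'
#' Pools the RMS amplitudes of all channels and windows of a feature series
#' into one sample and fits a [gmm1d] to it.  This is the model used to
#' discretize per-channel amplitudes into cluster indices.
#'
#' @param features A [semg_features].
#' @param K Number of mixture components (default 10, a good operating point
#'   for classification; 5 suits visual exploration).
#' @param stride Fit on every `stride`-th window (default 1 = all windows).
#'   At the default 5 ms step consecutive 200 ms windows overlap by 97.5%,
#'   so thinning the training pool leaves the fitted density essentially
#'   unchanged while cutting EM cost proportionally; discretization still
#'   covers every window.
#' @param ... Passed to [gmm1d()].
#' @return A `gmm1d` fit.
#' @export
fit_gmm <- function(features, K = 10, stride = 1, ...) {
  rows <- seq(1, nrow(features$values), by = stride)
  x <- as.vector(features$values[rows, , drop = FALSE])
  if (length(x) < 10 * K)
    stop("pooled sample count (", length(x),
         ") is below 10*K = ", 10 * K)
  gmm1d(x, K, ...)
}

#' @export
print.gmm1d <- function(x, digits = 4, ...) {
  cat(sprintf("gmm1d: %d-component univariate Gaussian mixture (n = %d)\n",
              x$K, x$n))
  print(round(coef(x), digits))
  cat(sprintf("logLik %.4f after %d iteration(s)%s%s\n", x$logLik,
              x$iterations,
              if (x$converged) ", converged" else " (not converged)",
              if (x$floor_hit) ", variance floor active" else ""))
  invisible(x)
}

#' @export
summary.gmm1d <- function(object, ...) {
  s <- list(coef = coef(object), logLik = object$logLik, n = object$n,
            K = object$K, iterations = object$iterations,
            converged = object$converged, floor_hit = object$floor_hit,
            degenerate = object$degenerate)
  class(s) <- "summary.gmm1d"
  s
}

#' @export
print.summary.gmm1d <- function(x, ...) {
  cat(sprintf("Univariate Gaussian mixture, K = %d, n = %d\n", x$K, x$n))
  print(x$coef)
  cat(sprintf("logLik: %.6g  iterations: %d  converged: %s\n",
              x$logLik, x$iterations, x$converged))
  if (x$floor_hit) cat("note: variance floor was active\n")
  if (x$degenerate) cat("note: degenerate data, K was collapsed\n")
  invisible(x)
}

#' @export
coef.gmm1d <- function(object, ...) {
  cbind(weight = object$weights, mean = object$means,
        variance = object$variances)
}

#' @export
logLik.gmm1d <- function(object, ...) {
  structure(object$logLik, df = 3 * object$K - 1, nobs = object$n,
            class = "logLik")
}

#' Posterior cluster assignment for new amplitudes
#'
#' Maps amplitudes to mixture components.  `type = "class"` returns the
#' 0-based index of the maximum-posterior component (0 = quietest cluster;
#' ties broken toward the lower index); `type = "posterior"` returns the
#' `n x K` matrix of posterior probabilities.
#'
#' @param object A [gmm1d] fit.
#' @param newdata Numeric vector (or matrix) of amplitudes.
#' @param type `"class"` or `"posterior"`.
#' @param ... Unused.
#' @return Integer vector (or matrix matching `newdata`) of cluster indices,
#'   or a posterior probability matrix.
#' @export
predict.gmm1d <- function(object, newdata,
                          type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  shape <- dim(newdata)
  x <- as.numeric(newdata)
  lp <- vapply(seq_len(object$K), function(k)
    log(object$weights[k]) +
      stats::dnorm(x, object$means[k], sqrt(object$variances[k]),
                   log = TRUE),
    numeric(length(x)))
  lp <- matrix(lp, ncol = object$K)
  if (type == "posterior") {
    m <- apply(lp, 1, max)
    p <- exp(lp - m)
    return(p / rowSums(p))
  }
  idx <- max.col(lp, ties.method = "first") - 1L
  if (!is.null(shape)) idx <- matrix(idx, shape[1], shape[2])
  idx
}

#' Mixture density
#'
#' @param object A [gmm1d] fit.
#' @param at Numeric vector of points.
#' @return Mixture density values at `at`.
#' @export
gmm_density <- function(object, at) {
  rowSums(vapply(seq_len(object$K), function(k)
    object$weights[k] *
      stats::dnorm(at, object$means[k], sqrt(object$variances[k])),
    numeric(length(at))))
}

#' @export
simulate.gmm1d <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  k <- sample.int(object$K, nsim, replace = TRUE, prob = object$weights)
  stats::rnorm(nsim, object$means[k], sqrt(object$variances[k]))
}

#' @export
plot.gmm1d <- function(x, data = NULL, breaks = 60, ...) {
  if (!is.null(data)) {
    graphics::hist(data, breaks = breaks, freq = FALSE,
                   main = "Pooled amplitude mixture",
                   xlab = "RMS amplitude (uV)", border = "grey70")
    xs <- seq(min(data), max(data), length.out = 512)
  } else {
    r <- range(x$means) + c(-4, 4) * sqrt(max(x$variances))
    xs <- seq(r[1], r[2], length.out = 512)
    graphics::plot(xs, gmm_density(x, xs), type = "n",
                   main = "Fitted amplitude mixture",
                   xlab = "RMS amplitude (uV)", ylab = "density")
  }
  graphics::lines(xs, gmm_density(x, xs), lwd = 2)
  for (k in seq_len(x$K))
    graphics::lines(xs, x$weights[k] *
                      stats::dnorm(xs, x$means[k], sqrt(x$variances[k])),
                    lty = 2, col = k + 1)
  invisible(x)
}

#' Discretize a feature series with a fitted mixture
#'
#' Replaces every RMS amplitude by the 0-based index of its maximum-
#' posterior mixture component.  Because components are amplitude-ordered,
#' index 0 always denotes the quietest cluster.  This is a pure function:
#' the same inputs always give identical indices.
#'
#' @param features A [semg_features].
#' @param model A [gmm1d] fit.
#' @return Integer matrix `n_windows x n_channels` of cluster indices in
#'   `[0, K-1]`, with the feature series' channels as column names and its
#'   window labels attached as attribute `"labels"` (plus `"times"`).
#' @export
discretize <- function(features, model) {
  idx <- predict(model, features$values, type = "class")
  colnames(idx) <- features$channels
  attr(idx, "labels") <- features$labels
  attr(idx, "times") <- features$times
  attr(idx, "K") <- model$K
  idx
}
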