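#' Fit a univariate Gaussian mixture by EM
#'
#' Maximum-likelihood fit of a k-component normal mixture with free
#' per-component means, variances and weights, the model used to decompose
#' centred gene-level aCGH signals into low-signal (deletions, exon-boundary
#' genes), single-copy and duplicated components. The first restart is
#' initialized at the 10th/50th/90th percentiles (for k = 3) with equal
#' weights and component SD equal to the overall SD; further restarts jitter
#' the means. The log-likelihood is non-decreasing across EM iterations and
#' the best restart is returned with components relabeled by ascending mean.
#'
#' @param x Numeric vector of observations (length >= `10 * k`, finite).
#' @param k Number of components.
#' @param seed Optional integer seed for the restart jitter.
#' @param tol Convergence tolerance on the relative log-likelihood change.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Number of EM restarts.
#' @param var_floor Lower bound on component variances; a restart whose
#'   variance collapses below it is discarded, and if all restarts collapse
#'   the fit aborts with a degenerate-mixture error.
#' @return An object of class `gmm3`: list with `weights`, `means`, `sds`
#'   (sorted by mean), `loglik`, `loglik_trace`, `converged`, `n_iter`, `n`,
#'   `k` and the data `x`.
#' @seealso [classify_copy_number()], and the usual methods `print`,
#'   `summary`, `coef`, `logLik`, `predict`, `simulate`, `plot`.
#' @export
fit_gaussian_mixture <- function(x, k = 3L, seed = NULL, tol = 1e-8,
                                 max_iter = 1000L, n_restarts = 5L,
                                 var_floor = 1e-6) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop("x must be finite")
  n <- length(x)
  if (n < 10L * k) stop("need at least 10 * k observations")
  if (!is.null(seed)) set.seed(seed)
  sd_all <- stats::sd(x)
  if (sd_all < sqrt(var_floor)) stop("degenerate mixture: data are constant")

  init_means <- stats::quantile(x, probs = seq(0.1, 0.9, length.out = k),
                                names = FALSE)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    mu <- if (r == 1L) init_means else
      init_means + stats::rnorm(k, 0, 0.5 * sd_all)
    fit <- em_gmm(x, k, mu, rep(sd_all, k), rep(1 / k, k), tol, max_iter,
                  var_floor)
    if (fit$collapsed) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("degenerate mixture: variance collapsed in every restart")
  ord <- order(best$means)
  structure(list(weights = best$weights[ord], means = best$means[ord],
                 sds = best$sds[ord], loglik = best$loglik,
                 loglik_trace = best$trace, converged = best$converged,
                 n_iter = best$n_iter, n = n, k = k, x = x),
            class = "gmm3")
}

# One EM run; returns collapsed = TRUE if a variance hits the floor.
em_gmm <- function(x, k, mu, sigma, w, tol, max_iter, var_floor) {
  n <- length(x)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sigma[j]),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    resp <- dens / tot
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- vapply(seq_len(k),
                function(j) sum(resp[, j] * (x - mu[j])^2) / nk[j],
                numeric(1L))
    if (any(v < var_floor) || any(!is.finite(v)))
      return(list(collapsed = TRUE))
    sigma <- sqrt(v)
  }
  list(collapsed = FALSE, weights = w, means = mu, sds = sigma, loglik = ll,
       trace = trace, converged = converged, n_iter = iter)
}

#' @export
print.gmm3 <- function(x, digits = 4L, ...) {
  cat(x$k, "-component Gaussian mixture (EM), n = ", x$n,
      if (!x$converged) " [not converged]", "\n", sep = "")
  print(round(coef(x), digits))
  cat("log-likelihood:", format(x$loglik, digits = digits + 3L),
      "in", x$n_iter, "iterations\n")
  invisible(x)
}

#' @export
coef.gmm3 <- function(object, ...) {
  out <- rbind(weight = object$weights, mean = object$means, sd = object$sds)
  colnames(out) <- paste0("comp", seq_len(object$k))
  out
}

#' @export
logLik.gmm3 <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- 3L * object$k - 1L
  attr(val, "nobs") <- object$n
  class(val) <- "logLik"
  val
}

#' @export
summary.gmm3 <- function(object, ...) {
  structure(list(coef = coef(object), loglik = object$loglik,
                 n = object$n, k = object$k, n_iter = object$n_iter,
                 converged = object$converged,
                 bic = -2 * object$loglik +
                   (3 * object$k - 1) * log(object$n)),
            class = "summary.gmm3")
}

#' @export
print.summary.gmm3 <- function(x, ...) {
  cat(x$k, "-component Gaussian mixture, n = ", x$n, "\n", sep = "")
  print(round(x$coef, 4L))
  cat("log-likelihood:", x$loglik, "  BIC:", x$bic, "\n")
  cat("EM iterations:", x$n_iter,
      if (!x$converged) "(not converged)", "\n")
  invisible(x)
}

#' Posterior responsibilities, classes or mixture density
#'
#' @param object A `gmm3` fit.
#' @param newdata Values to evaluate (defaults to the fitted data).
#' @param type `"posterior"` (n x k responsibilities, rows sum to 1),
#'   `"class"` (maximum-posterior component index) or `"density"` (mixture
#'   density).
#' @param ... Unused.
#' @return Matrix, integer vector or numeric vector according to `type`.
#' @export
predict.gmm3 <- function(object, newdata = NULL,
                         type = c("posterior", "class", "density"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$x else as.numeric(newdata)
  dens <- vapply(seq_len(object$k), function(j)
    object$weights[j] * stats::dnorm(x, object$means[j], object$sds[j]),
    numeric(length(x)))
  dens <- matrix(dens, nrow = length(x))
  tot <- rowSums(dens)
  if (type == "density") return(tot)
  tot[tot == 0] <- .Machine$double.xmin
  post <- dens / tot
  colnames(post) <- paste0("comp", seq_len(object$k))
  if (type == "posterior") post else max.col(post, ties.method = "first")
}

#' @export
simulate.gmm3 <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(object$k, nsim, replace = TRUE, prob = object$weights)
  stats::rnorm(nsim, object$means[comp], object$sds[comp])
}

#' @export
plot.gmm3 <- function(x, breaks = 60L, ...) {
  h <- graphics::hist(x$x, breaks = breaks, freq = FALSE,
                      main = "Gaussian mixture fit",
                      xlab = "centred log2 signal", ...)
  xs <- seq(min(x$x), max(x$x), length.out = 400L)
  for (j in seq_len(x$k))
    graphics::lines(xs, x$weights[j] * stats::dnorm(xs, x$means[j], x$sds[j]),
                    col = j + 1L, lwd = 2L)
  graphics::lines(xs, predict(x, xs, type = "density"), lty = 2L)
  invisible(h)
}

#' Draw samples from a parameterized three-normal mixture
#'
#' Convenience generator for mixture-recovery experiments: draws `n` values
#' from the mixture with the given weights, means and SDs.
#'
#' @param n Number of draws.
#' @param weights,means,sds Component parameters (equal lengths; weights are
#'   normalized to sum to 1).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
rgmm <- function(n, weights, means, sds, seed = NULL) {
  stopifnot(length(weights) == length(means), length(means) == length(sds))
  if (!is.null(seed)) set.seed(seed)
  w <- weights / sum(weights)
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  stats::rnorm(n, means[comp], sds[comp])
}
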