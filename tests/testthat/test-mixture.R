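table2 <- list(w = c(0.08, 0.82, 0.10), mu = c(-2.29, -0.01, 2.28),
               s = c(1.62, 0.88, 0.33))

test_that("EM log-likelihood is monotone and responsibilities sum to one", {
  x <- rgmm(2000, table2$w, table2$mu, table2$s, seed = 1)
  fit <- fit_gaussian_mixture(x, seed = 1, n_restarts = 2)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_true(all(diff(fit$means) > 0)) # relabeled ascending
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  post <- predict(fit, type = "posterior")
  expect_equal(rowSums(post), rep(1, length(x)), tolerance = 1e-9)
})

test_that("constant data raise a degenerate-mixture error", {
  expect_error(fit_gaussian_mixture(rep(2.5, 100)), "degenerate")
})

test_that("two tight well-separated clumps are captured and the EM
           log-likelihood beats a coarse grid oracle", {
  set.seed(4)
  x <- c(rnorm(25, 0, 0.05), rnorm(25, 10, 0.05))
  fit <- fit_gaussian_mixture(x, seed = 2, n_restarts = 5)
  # two components sit on the clumps
  expect_lt(min(abs(fit$means - 0)), 0.1)
  expect_lt(min(abs(fit$means - 10)), 0.1)
  # grid oracle: exhaustive scan over a small parameter grid
  grid_ll <- function(w, mu, s) {
    sum(log(rowSums(vapply(1:3, function(j)
      w[j] * dnorm(x, mu[j], s[j]), numeric(length(x))))))
  }
  best_grid <- -Inf
  for (m1 in c(-1, 0, 1)) for (m2 in c(4, 5, 6)) for (m3 in c(9, 10, 11))
    for (s0 in c(0.05, 0.1, 1))
      best_grid <- max(best_grid,
                       grid_ll(c(0.45, 0.10, 0.45), c(m1, m2, m3),
                               rep(s0, 3)))
  expect_gte(fit$loglik, best_grid - 1e-6)
})

test_that("the fitted model agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  x <- rgmm(10000, table2$w, table2$mu, table2$s, seed = 7)
  fit <- fit_gaussian_mixture(x, seed = 7, n_restarts = 3)
  mc <- Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  # our restarted EM must not be beaten by more than numerical slack
  expect_gte(fit$loglik, mc$loglik - 1e-3)
  expect_lt(abs(sort(fit$means)[3] - sort(mc$parameters$mean)[3]), 0.05)
  expect_lt(abs(sort(fit$means)[2] - sort(mc$parameters$mean)[2]), 0.05)
})

test_that("the duplicated component is recovered accurately over replicates", {
  res <- vapply(1:20, function(r) {
    x <- rgmm(25000, table2$w, table2$mu, table2$s, seed = 100 + r)
    f <- fit_gaussian_mixture(x, seed = r, n_restarts = 1, tol = 1e-6)
    c(f$means[3], f$sds[3])
  }, numeric(2))
  expect_lt(mean(abs(res[1, ] - 2.28)), 0.05)
  expect_lt(mean(abs(res[2, ] - 0.33)), 0.05)
})

test_that("simulate/predict/coef methods are consistent", {
  x <- rgmm(3000, table2$w, table2$mu, table2$s, seed = 3)
  fit <- fit_gaussian_mixture(x, seed = 3, n_restarts = 2)
  co <- coef(fit)
  expect_identical(dim(co), c(3L, 3L))
  expect_equal(unname(co["mean", ]), fit$means)
  sim <- simulate(fit, nsim = 20000, seed = 5)
  expect_lt(abs(mean(sim) - sum(fit$weights * fit$means)), 0.05)
  dens <- predict(fit, c(-2, 0, 2), type = "density")
  expect_true(all(dens > 0))
  cls <- predict(fit, fit$means, type = "class")
  expect_equal(cls, 1:3)
  expect_s3_class(summary(fit), "summary.gmm3")
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$loglik)
  expect_equal(attr(ll, "df"), 8L)
})

test_that("classification applies inclusive thresholds and the overall
           mean - 2 SD low rule", {
  x <- rgmm(5000, table2$w, table2$mu, table2$s, seed = 9)
  fit <- fit_gaussian_mixture(x, seed = 9, n_restarts = 2)
  # exact boundary value is called high ("greater than or equal to")
  boundary <- fit$means[3] - 2 * fit$sds[3]
  calls <- classify_copy_number(fit, c(a = boundary, b = boundary - 1e-9),
                                overall_mean = 0, overall_sd = 1)
  expect_true(calls$high[calls$gene_id == "a"])
  expect_false(calls$high[calls$gene_id == "b"])

  # the published low cutoff: mean 13.03, SD 1.34 -> below 10.35 is low
  calls2 <- classify_copy_number(fit, c(lo = 10.34, hi = 10.36),
                                 overall_mean = 13.03, overall_sd = 1.34)
  expect_equal(attr(calls2, "low_cutoff"), 10.35)
  expect_true(calls2$low[calls2$gene_id == "lo"])
  expect_false(calls2$low[calls2$gene_id == "hi"])

  # calls are non-exclusive: a wide normal band can reach the high cutoff
  vals <- stats::setNames(x, paste0("g", seq_along(x)))
  cc <- classify_copy_number(fit, vals)
  expect_s3_class(cc, "copy_calls")
  nb <- attr(cc, "normal_band")
  if (nb[2] >= attr(cc, "high_cutoff"))
    expect_gt(sum(cc$normal & cc$high), 0)
  # an unconverged fit is refused
  fit_bad <- fit; fit_bad$converged <- FALSE
  expect_error(classify_copy_number(fit_bad, vals), "converge")
})

test_that("classification accuracy exceeds 95% for well-separated classes", {
  # classes separated by >= 4 component SDs
  set.seed(12)
  truth <- sample(1:3, 6000, replace = TRUE, prob = c(0.1, 0.8, 0.1))
  mu <- c(-4, 0, 3); s <- c(0.5, 0.4, 0.3)
  x <- rnorm(6000, mu[truth], s[truth])
  fit <- fit_gaussian_mixture(x, seed = 12, n_restarts = 2)
  cls <- predict(fit, type = "class")
  expect_gt(mean(cls == truth), 0.95)
})

test_that("Venn partition of call sets matches the enumeration oracle", {
  sets <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"), C = "g3")
  cmp <- compare_group_calls(sets, reference = "A")
  get <- function(region)
    cmp$regions$count[cmp$regions$region == region]
  expect_equal(get("A"), 1L)       # g1
  expect_equal(get("B"), 1L)       # g4
  expect_equal(get("A&B"), 1L)     # g2
  expect_equal(get("A&B&C"), 1L)   # g3
  expect_equal(get("C"), 0L)
  expect_equal(get("A&C"), 0L)
  expect_equal(get("B&C"), 0L)
  expect_equal(sum(cmp$regions$count), 4L) # every gene in exactly one region

  # identical sets -> 100% overlap; disjoint -> 0%
  same <- compare_group_calls(list(X = c("a", "b"), Y = c("a", "b")))
  expect_equal(unname(same$overlap_pct), c(100, 100))
  expect_warning(
    disj <- compare_group_calls(list(X = c("a", "b"), Y = character(0))),
    "empty")
  expect_equal(unname(disj$overlap_pct["Y"]), 0)
})
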