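sim_kernel_steps <- function(n, shape, scale, mu, kappa, seed) {
  set.seed(seed)
  sl <- stats::rgamma(n, shape = shape, scale = scale)
  turn <- rvonmises(n, mu, kappa)
  heading <- cumsum(c(0, turn[-1]))
  data.frame(stratum = seq_len(n), bird_id = "b1", x1 = 0, y1 = 0,
             x2 = sl * cos(heading), y2 = sl * sin(heading),
             sl = sl, turn = c(NA, turn[-1]), heading = heading)
}

test_that("movement kernel recovers gamma and von Mises parameters", {
  st <- sim_kernel_steps(5000, shape = 2, scale = 500, mu = 0.3,
                         kappa = 1.5, seed = 1)
  k <- fit_kernel(st)
  expect_lt(abs(k$shape - 2) / 2, 0.05)
  expect_lt(abs(k$scale - 500) / 500, 0.05)
  expect_lt(abs(k$mu - 0.3), 0.1)
  expect_lt(abs(k$kappa - 1.5) / 1.5, 0.1)
  # uniform turns give kappa near 0
  st_u <- sim_kernel_steps(4000, 2, 500, 0, 0, seed = 2)
  expect_lt(fit_kernel(st_u)$kappa, 0.1)
  # degenerate lengths are refused
  st_d <- st; st_d$sl <- 100
  expect_error(fit_kernel(st_d), "degenerate")
})

test_that("control sets have K controls per stratum and are reproducible", {
  esc <- fixture_escape()
  kern <- list(shape = 2, scale = 800, mu = 0, kappa = 0.8)
  obs <- simulate_ssf_steps(esc, kern, beta = 1, n = 100, seed = 3)
  cs <- make_controls(obs, kern, K = 50, escape = esc, seed = 4)
  tab <- table(cs$stratum)
  expect_true(all(tab == 51))
  expect_true(all(tapply(cs$case, cs$stratum, sum) == 1))
  cs2 <- make_controls(obs, kern, K = 50, escape = esc, seed = 4)
  expect_identical(cs$log_hri, cs2$log_hri)
  expect_error(make_controls(obs, kern, K = 0, escape = esc), "K")
})

test_that("a degenerate kernel collapses controls onto the straight-ahead point", {
  esc <- flat_escape(n = 60)
  # tiny gamma variance around 1000 m, huge concentration at 0 turn
  kern <- list(shape = 1e6, scale = 1000 / 1e6, mu = 0, kappa = 1e5)
  obs <- data.frame(stratum = 1L, bird_id = "b1", x1 = 30000, y1 = 30000,
                    x2 = 31000, y2 = 30000, sl = 1000, turn = 0,
                    heading = 0)
  cs <- make_controls(obs, kern, K = 20, escape = esc, seed = 5)
  ctrl <- cs[cs$case == 0L, ]
  # straight ahead from (30000, 30000) with heading 0 at length 1000
  expect_lt(max(abs(ctrl$x - 31000)), 10)
  expect_lt(max(abs(ctrl$y - 30000)), 10)
})

test_that("conditional likelihood matches brute-force enumeration", {
  esc <- fixture_escape()
  kern <- list(shape = 2, scale = 800, mu = 0, kappa = 0.8)
  obs <- simulate_ssf_steps(esc, kern, beta = 0.5, n = 5, seed = 6)
  cs <- make_controls(obs, kern, K = 2, escape = esc, seed = 7)
  X <- as.matrix(cs[, c("sl", "log_sl", "cos_turn", "log_hri")])
  X[, "sl"] <- X[, "sl"] / 1000
  beta <- c(0.01, -0.2, 0.1, 0.7)
  sidx <- trophscape:::make_strata_index(cs$stratum)
  obj <- trophscape:::clogit_obj(X, cs$case, sidx, pen = rep(0, 4))
  expect_equal(-obj(beta),
               brute_clogit_loglik(beta, X, cs$case, cs$stratum),
               tolerance = 1e-8)
  # analytic gradient against central differences
  grd <- trophscape:::clogit_grad(X, cs$case, sidx, pen = rep(0, 4))
  num <- vapply(1:4, function(k) {
    h <- 1e-6; bp <- beta; bm <- beta
    bp[k] <- bp[k] + h; bm[k] <- bm[k] - h
    (obj(bp) - obj(bm)) / (2 * h)
  }, numeric(1))
  expect_equal(unname(grd(beta)), num, tolerance = 1e-5)
})

test_that("likelihood is invariant to stratum-constant covariate shifts", {
  esc <- fixture_escape()
  kern <- list(shape = 2, scale = 800, mu = 0, kappa = 0.8)
  obs <- simulate_ssf_steps(esc, kern, beta = 0.5, n = 20, seed = 8)
  cs <- make_controls(obs, kern, K = 5, escape = esc, seed = 9)
  X <- as.matrix(cs[, c("sl", "log_sl", "cos_turn", "log_hri")])
  beta <- c(0.0001, -0.1, 0.2, 0.9)
  ll1 <- brute_clogit_loglik(beta, X, cs$case, cs$stratum)
  shift <- as.numeric(factor(cs$stratum)) * 3.7
  X2 <- X
  X2[, "log_hri"] <- X2[, "log_hri"] + shift / beta[4]
  ll2 <- brute_clogit_loglik(beta, X2, cs$case, cs$stratum)
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("fitted coefficients agree with the Cox constant-time construction", {
  skip_if_not_installed("survival")
  library(survival)   # clogit constructs a coxph() call that needs it attached
  esc <- fixture_escape()
  kern <- list(shape = 2, scale = 800, mu = 0, kappa = 0.8)
  obs <- simulate_ssf_steps(esc, kern, beta = 1, n = 400, seed = 10)
  cs <- make_controls(obs, kern, K = 10, escape = esc, seed = 11)
  fit <- fit_issf(cs)
  cl <- survival::clogit(case ~ sl + log_sl + cos_turn + log_hri +
                           survival::strata(stratum), data = cs)
  expect_equal(unname(fit$coef), unname(coef(cl)), tolerance = 1e-4)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(cl)))),
               tolerance = 1e-3)
})

test_that("null covariates give an HRI estimate within 2 SE of zero", {
  esc <- fixture_escape()
  kern <- list(shape = 2, scale = 800, mu = 0, kappa = 0.8)
  obs <- simulate_ssf_steps(esc, kern, beta = 0, n = 500, seed = 12)
  cs <- make_controls(obs, kern, K = 20, escape = esc, seed = 13)
  fit <- fit_issf(cs)
  expect_lt(abs(fit$coef["log_hri"]), 2 * fit$se["log_hri"])
})

test_that("ridge deviations shrink to zero as the penalty grows", {
  esc <- fixture_escape()
  kern <- list(shape = 2, scale = 800, mu = 0, kappa = 0.8)
  obs <- simulate_ssf_steps(esc, kern, beta = 1, n = 300, seed = 14)
  obs$bird_id <- rep(c("b1", "b2", "b3"), length.out = nrow(obs))
  cs <- make_controls(obs, kern, K = 10, escape = esc, seed = 15)
  f_loose <- fit_issf(cs, individual_deviations = TRUE, lambda = 0.01)
  f_tight <- fit_issf(cs, individual_deviations = TRUE, lambda = 1e6)
  expect_lt(max(abs(f_tight$deviations)), 1e-3)
  expect_gt(max(abs(f_loose$deviations)), max(abs(f_tight$deviations)))
  # lambda selection runs and returns a grid member
  f_auto <- fit_issf(cs, individual_deviations = TRUE,
                     lambda_grid = c(0.1, 10))
  expect_true(f_auto$lambda %in% c(0.1, 10))
})

test_that("relative selection strength is exp-linear in the contrast", {
  esc <- fixture_escape()
  kern <- list(shape = 2, scale = 800, mu = 0, kappa = 0.8)
  obs <- simulate_ssf_steps(esc, kern, beta = 1, n = 300, seed = 16)
  cs <- make_controls(obs, kern, K = 10, escape = esc, seed = 17)
  fit <- fit_issf(cs)
  expect_equal(rss(fit, 0), 1)
  expect_equal(rss(fit, 2), rss(fit, 1)^2, tolerance = 1e-12)
  b <- unname(fit$coef["log_hri"])
  expect_equal(rss(fit, 1), exp(b))
})
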