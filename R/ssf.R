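# Integrated step-selection analysis: movement kernels fitted to the
# observed steps, kernel-sampled control steps, and selection for
# log(HRI) estimated by maximizing the stratified conditional
# (multinomial) log-likelihood -- the exact partial likelihood of the
# constant-event-time Cox construction used in the field.

#' Fit the movement kernel
#'
#' Maximum-likelihood gamma fit to positive step lengths (zero-length
#' steps excluded and counted) and closed-form von Mises fit to defined
#' turns.
#'
#' @param steps a [steps_and_turns()] data.frame.
#' @return `movement_kernel`: `shape`, `scale` (gamma, m), `mu`,
#'   `kappa` (von Mises, rad), `n_zero_dropped`.
#' @export
fit_kernel <- function(steps) {
  sl <- steps$sl
  pos <- is.finite(sl) & sl > 0
  n_zero <- sum(is.finite(sl) & sl <= 0)
  sl <- sl[pos]
  turns <- steps$turn[is.finite(steps$turn)]
  if (length(turns) < 10L) stop("need at least 10 steps with turns")
  if (stats::sd(sl) < 1e-12) stop("degenerate fit: all step lengths equal")
  m <- mean(sl); v <- stats::var(sl)
  fit <- fitdistrplus::fitdist(sl, "gamma", method = "mle",
                               start = list(shape = m^2 / v,
                                            rate = m / v),
                               lower = c(1e-8, 1e-12))
  vm <- fit_vonmises(turns)
  structure(list(shape = unname(fit$estimate["shape"]),
                 scale = 1 / unname(fit$estimate["rate"]),
                 mu = vm$mu, kappa = vm$kappa,
                 n_zero_dropped = n_zero),
            class = "movement_kernel")
}

#' Generate control steps
#'
#' For each observed step with a defined previous heading, draws `K`
#' alternative steps (gamma lengths, von Mises turns applied to the
#' previous heading), places their endpoints, and attaches log(HRI) at
#' every endpoint. Strata with any missing covariate (case or control
#' endpoint off the mapped landscape, or HRI = 0) are dropped entirely
#' and counted.
#'
#' @param steps a [steps_and_turns()] data.frame.
#' @param kernel a [fit_kernel()] result.
#' @param K controls per observed step; default 50.
#' @param escape an [compute_hri()] result supplying the covariate.
#' @param seed RNG seed.
#' @return data.frame (`control_set`): `stratum`, `case` (1 observed /
#'   0 control), `sl`, `log_sl`, `cos_turn`, `log_hri`, `x`, `y`,
#'   `bird_id`, `year`; attribute `n_dropped_strata`.
#' @export
make_controls <- function(steps, kernel, K = 50, escape, seed = 1L) {
  if (K < 1) stop("K must be >= 1")
  ok <- is.finite(steps$turn) & is.finite(steps$sl) & steps$sl > 0
  obs <- steps[ok, , drop = FALSE]
  n <- nrow(obs)
  if (n < 1L) stop("no usable observed steps")
  set.seed(seed)
  h_prev <- obs$heading - obs$turn
  len <- matrix(stats::rgamma(n * K, shape = kernel$shape,
                              scale = kernel$scale), n, K)
  trn <- matrix(rvonmises(n * K, kernel$mu, kernel$kappa), n, K)
  hd <- h_prev + trn
  cx <- obs$x1 + len * cos(hd)
  cy <- obs$y1 + len * sin(hd)
  year <- if ("timestamp" %in% names(obs))
    as.integer(format(obs$timestamp, "%Y")) else NA_integer_
  bird <- if ("bird_id" %in% names(obs)) obs$bird_id else "bird1"

  case_h <- as.numeric(sample_hri(escape, obs$x2, obs$y2))
  ctrl_h <- matrix(as.numeric(sample_hri(escape, as.vector(cx),
                                         as.vector(cy))), n, K)
  lh_case <- ifelse(is.finite(case_h) & case_h > 0, log(case_h), NA_real_)
  lh_ctrl <- ifelse(is.finite(ctrl_h) & ctrl_h > 0, log(ctrl_h), NA_real_)
  keep <- is.finite(lh_case) & apply(lh_ctrl, 1L, function(z)
    all(is.finite(z)))
  n_dropped <- sum(!keep)
  idx <- which(keep)
  if (!length(idx))
    stop("all strata dropped: no stratum has complete covariates; ",
         "does the E-scape cover the movement extent?")
  rows <- lapply(idx, function(i) {
    data.frame(stratum = obs$stratum[i],
               case = c(1L, rep(0L, K)),
               sl = c(obs$sl[i], len[i, ]),
               cos_turn = cos(c(obs$turn[i], trn[i, ])),
               log_hri = c(lh_case[i], lh_ctrl[i, ]),
               x = c(obs$x2[i], cx[i, ]),
               y = c(obs$y2[i], cy[i, ]),
               bird_id = bird[i],
               year = year[i])
  })
  out <- do.call(rbind, rows)
  out$log_sl <- log(out$sl)
  structure(out[, c("stratum", "case", "sl", "log_sl", "cos_turn",
                    "log_hri", "x", "y", "bird_id", "year")],
            n_dropped_strata = n_dropped, class = c("control_set",
                                                    "data.frame"))
}

# stratified conditional logit machinery ------------------------------

# precomputed stratum index structure
make_strata_index <- function(stratum) {
  f <- factor(stratum, levels = unique(stratum))
  list(f = f, i = as.integer(f), n = nlevels(f))
}

clogit_obj <- function(X, case, sidx, pen) {
  function(beta) {
    eta <- drop(X %*% beta)
    Ms <- vapply(split(eta, sidx$f), max, numeric(1))
    ex <- exp(eta - Ms[sidx$i])
    denom <- rowsum(ex, sidx$i, reorder = TRUE)[, 1L]
    ll <- sum(eta[case == 1L]) - sum(log(denom) + Ms)
    -(ll - sum(pen * beta^2) / 2)
  }
}

clogit_grad <- function(X, case, sidx, pen) {
  function(beta) {
    eta <- drop(X %*% beta)
    M <- vapply(split(eta, sidx$f), max, numeric(1))[sidx$i]
    ex <- exp(eta - M)
    denom <- rowsum(ex, sidx$i, reorder = TRUE)[, 1L]
    p <- ex / denom[sidx$i]
    g <- colSums(X[case == 1L, , drop = FALSE]) - colSums(X * p)
    -(g - pen * beta)
  }
}

#' Fit the integrated step-selection function
#'
#' Maximizes the stratified conditional multinomial log-likelihood:
#' each stratum (1 observed + K control steps) contributes
#' `log[exp(eta_case) / sum_choices exp(eta)]` with
#' `eta = b_sl*sl + b_lsl*log(sl) + b_cos*cos(turn) + b_HRI*log(HRI)`
#' plus optional ridge-penalized per-individual and per-year deviations
#' of the HRI slope. Fixed-effect standard errors come from the observed
#' information at the optimum.
#'
#' @param data a [make_controls()] data.frame.
#' @param individual_deviations,year_deviations add ridge-penalized
#'   deviations of the `log_hri` slope per bird / per year.
#' @param lambda ridge penalty for the deviations; `NULL` selects it by
#'   Laplace-approximate marginal likelihood over `lambda_grid`.
#' @param lambda_grid candidate penalties.
#' @return `ssf_fit`: `coef`, `se`, `z`, `p` (fixed effects), `loglik`,
#'   `n_strata`, `deviations` (named shrunken deviations), `lambda`,
#'   `converged`.
#' @export
fit_issf <- function(data, individual_deviations = FALSE,
                     year_deviations = FALSE, lambda = NULL,
                     lambda_grid = 10^seq(-1, 3, by = 1)) {
  sidx <- make_strata_index(data$stratum)
  if (sidx$n < 2L) stop("need at least 2 strata")
  fixed <- c("sl", "log_sl", "cos_turn", "log_hri")
  X <- as.matrix(data[, fixed])
  # scale step length to km for a well-conditioned optimization
  X[, "sl"] <- X[, "sl"] / 1000
  dev_names <- character(0)
  if (individual_deviations) {
    for (b in unique(data$bird_id)) {
      X <- cbind(X, data$log_hri * (data$bird_id == b))
      dev_names <- c(dev_names, paste0("dev_bird:", b))
    }
  }
  if (year_deviations) {
    for (yy in unique(data$year)) {
      X <- cbind(X, data$log_hri * (data$year == yy))
      dev_names <- c(dev_names, paste0("dev_year:", yy))
    }
  }
  colnames(X) <- c(fixed, dev_names)
  q <- length(dev_names)
  p_fixed <- length(fixed)

  fit_at <- function(lam) {
    pen <- c(rep(0, p_fixed), rep(lam, q))
    obj <- clogit_obj(X, data$case, sidx, pen)
    grd <- clogit_grad(X, data$case, sidx, pen)
    opt <- stats::optim(rep(0, ncol(X)), obj, grd, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    list(opt = opt, pen = pen, obj = obj)
  }

  lam_used <- 0
  if (q > 0) {
    if (is.null(lambda)) {
      # Laplace-approximate marginal likelihood of the ridge "prior"
      score <- vapply(lambda_grid, function(lam) {
        f <- fit_at(lam)
        H <- stats::optimHess(f$opt$par, f$obj)
        Hd <- H[p_fixed + seq_len(q), p_fixed + seq_len(q), drop = FALSE]
        -f$opt$value + q / 2 * log(lam) -
          0.5 * determinant(Hd, logarithm = TRUE)$modulus
      }, numeric(1))
      lam_used <- lambda_grid[which.max(score)]
    } else lam_used <- lambda
  }
  f <- fit_at(lam_used)
  H <- stats::optimHess(f$opt$par, f$obj)
  Vfull <- tryCatch(solve(H), error = function(e) {
    warning("information matrix is singular; using pseudo-inverse")
    svd_pinv(H)
  })
  est <- f$opt$par
  names(est) <- colnames(X)
  se <- sqrt(pmax(diag(Vfull), 0))
  names(se) <- colnames(X)
  coef_f <- est[fixed]
  se_f <- se[fixed]
  # undo the km scaling on step length
  coef_f["sl"] <- coef_f["sl"] / 1000
  se_f["sl"] <- se_f["sl"] / 1000
  z <- coef_f / se_f
  structure(list(coef = coef_f, se = se_f, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 loglik = -f$opt$value,
                 n_strata = sidx$n,
                 n_dropped_strata = attr(data, "n_dropped_strata"),
                 deviations = if (q > 0) est[dev_names] else NULL,
                 lambda = lam_used,
                 vcov = Vfull,
                 converged = f$opt$convergence == 0L),
            class = "ssf_fit")
}

svd_pinv <- function(H) {
  s <- svd(H)
  keep <- s$d > max(s$d) * 1e-10
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' @export
print.ssf_fit <- function(x, ...) {
  cat(sprintf("<ssf_fit> %d strata, loglik %.2f%s\n", x$n_strata,
              x$loglik, if (x$converged) "" else " (NOT converged)"))
  print(data.frame(coef = x$coef, se = x$se, z = x$z, p = x$p))
  invisible(x)
}

#' Relative selection strength
#'
#' Multiplicative change in the likelihood of taking a step per
#' `delta` difference in log(HRI): `exp(beta_HRI * delta)`. With fitted
#' deviations, per-group curves are returned as well.
#'
#' @param fit an [fit_issf()] result.
#' @param delta difference(s) in log(HRI).
#' @return numeric RSS (or list with `population` and `groups` when
#'   deviations were fitted).
#' @export
rss <- function(fit, delta) {
  if (!fit$converged) warning("fit did not converge")
  pop <- exp(fit$coef["log_hri"] * delta)
  if (is.null(fit$deviations)) return(unname(pop))
  groups <- sapply(fit$deviations, function(d)
    exp((fit$coef["log_hri"] + d) * delta))
  list(population = unname(pop), groups = groups)
}
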