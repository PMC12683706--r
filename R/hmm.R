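# Three-state hidden Markov movement model with log(HRI)-dependent
# transition probabilities: multinomial-logit link on the six
# off-diagonal transitions, gamma (mean/SD) step-length and von Mises
# turn emissions, multi-restart quasi-Newton fitting, Viterbi decoding
# and transition-curve summaries.

STATE_NAMES <- c("stationary", "foraging", "traveling")

#' HMM parameter set
#'
#' @param step_mean,step_sd per-state gamma step-length mean/SD (m, > 0).
#' @param turn_mu,turn_kappa per-state von Mises parameters.
#' @param alpha,beta 3x3 off-diagonal transition intercepts and slopes
#'   on log(HRI) (diagonal entries are the softmax reference and are
#'   forced to 0).
#' @return `hmm_params` list.
#' @export
hmm_params <- function(step_mean, step_sd, turn_mu, turn_kappa,
                       alpha, beta) {
  if (any(step_mean <= 0) || any(step_sd <= 0))
    stop("gamma means and SDs must be > 0")
  if (any(turn_kappa < 0)) stop("kappa must be >= 0")
  diag(alpha) <- 0; diag(beta) <- 0
  structure(list(step_mean = step_mean, step_sd = step_sd,
                 turn_mu = turn_mu, turn_kappa = turn_kappa,
                 alpha = alpha, beta = beta),
            class = "hmm_params")
}

#' Transition matrix at a covariate value
#'
#' Row `i` is the softmax over working values `eta_ij = alpha_ij +
#' beta_ij * logHRI` (off-diagonal) with the diagonal as reference 0;
#' rows sum to 1 (overflow-guarded).
#'
#' @param params an [hmm_params()] (or `hmm_fit$params`).
#' @param loghri a single finite log(HRI) value.
#' @return 3x3 row-stochastic matrix.
#' @export
transition_matrix <- function(params, loghri) {
  stopifnot(is.finite(loghri))
  eta <- params$alpha + params$beta * loghri
  diag(eta) <- 0
  p <- exp(eta - apply(eta, 1L, max))
  p <- p / rowSums(p)
  dimnames(p) <- list(STATE_NAMES, STATE_NAMES)
  p
}

# per-step, per-state emission log-densities (R-side; used by Viterbi
# and the pure-R oracle surface)
emission_logdens <- function(params, sl, turn) {
  T_ <- length(sl)
  ld <- matrix(0, T_, 3L)
  for (j in 1:3) {
    shape <- (params$step_mean[j] / params$step_sd[j])^2
    scale <- params$step_sd[j]^2 / params$step_mean[j]
    g <- ifelse(is.finite(sl) & sl > 0,
                stats::dgamma(sl, shape = shape, scale = scale,
                              log = TRUE), 0)
    v <- ifelse(is.finite(turn),
                dvonmises(ifelse(is.finite(turn), turn, 0),
                          params$turn_mu[j], params$turn_kappa[j],
                          log = TRUE), 0)
    ld[, j] <- g + v
  }
  ld
}

#' Forward log-likelihood
#'
#' Numerically stable scaled forward recursion over gamma x von Mises
#' emissions and per-step transition matrices evaluated at each step's
#' log(HRI). Each track is initialized from the stationary distribution
#' of the transition matrix at its first step's covariate. Missing
#' turns contribute the length-only emission; missing log(HRI) is
#' imputed as 0 (landscape-average HRI).
#'
#' @param params an [hmm_params()].
#' @param steps data.frame with `sl`, `turn` and a track identifier
#'   column (`track`, or `trip_id`/`bird_id`).
#' @param loghri per-step covariate; defaults to `steps$loghri`.
#' @return log-likelihood (scalar).
#' @export
forward_loglik <- function(params, steps, loghri = steps$loghri) {
  if (any(params$step_sd <= 0)) stop("emission SDs must be > 0")
  track <- hmm_track_ids(steps)
  lh <- ifelse(is.finite(loghri), loghri, 0)
  -hmm_forward_nll_cpp(as.numeric(steps$sl), as.numeric(steps$turn),
                       as.numeric(lh), track,
                       params$step_mean, params$step_sd,
                       params$turn_mu, params$turn_kappa,
                       params$alpha, params$beta)
}

hmm_track_ids <- function(steps) {
  id <- if ("track" %in% names(steps)) steps$track
  else if ("trip_id" %in% names(steps)) steps$trip_id
  else if ("bird_id" %in% names(steps)) steps$bird_id
  else rep(1L, nrow(steps))
  as.integer(factor(id, levels = unique(id)))
}

# parameter packing: working scale <-> natural scale
pack_params <- function(p) {
  od <- which(diag(3) == 0)
  c(log(p$step_mean), log(p$step_sd), p$turn_mu, log(pmax(p$turn_kappa,
                                                          1e-8)),
    p$alpha[od], p$beta[od])
}

unpack_params <- function(w) {
  od <- which(diag(3) == 0)
  alpha <- matrix(0, 3, 3); beta <- matrix(0, 3, 3)
  alpha[od] <- pmin(pmax(w[13:18], -50), 50)
  beta[od] <- pmin(pmax(w[19:24], -50), 50)
  # clamp to safe positive ranges: line searches can push exp() to 0/Inf.
  # SD is additionally capped at 3x the mean (gamma shape >= 1/9): this
  # excludes the degenerate spike-at-zero mode of the gamma likelihood
  # while leaving all plausible movement states (shape ~ 0.7-3 in this
  # system) far inside the bound.
  mean_ <- pmin(pmax(exp(w[1:3]), 1e-6), 1e9)
  sd_ <- pmin(pmax(exp(w[4:6]), 1e-6), 1e9, 3 * mean_)
  hmm_params(step_mean = mean_, step_sd = sd_,
             turn_mu = wrap_angle(w[7:9]),
             turn_kappa = pmin(pmax(exp(w[10:12]), 1e-8), 1e7),
             alpha = alpha, beta = beta)
}

#' Fit the covariate-transition HMM with random restarts
#'
#' Draws starting emission values from uniform ranges (defaults: 1-2000
#' m for mean/SD step length, 0-2 rad for mean/SD turning angle, the SD
#' mapped to a von Mises concentration), runs quasi-Newton maximization
#' of [forward_loglik()] from each, keeps the best optimum (polished
#' with a longer iteration budget), and relabels states in ascending
#' order of fitted mean step length (stationary < foraging < traveling
#' in the study system).
#'
#' @param steps step series (`sl`, `turn`, track id column).
#' @param loghri per-step covariate; defaults to `steps$loghri`.
#' @param n_restarts number of random starts; default 50.
#' @param step_range,turn_range uniform start ranges.
#' @param seed RNG seed (restart draws are deterministic given it).
#' @param restart_nm_maxit,restart_maxit,final_maxit iteration budgets:
#'   each restart runs a derivative-free Nelder-Mead phase (which
#'   escapes poorly conditioned regions far from any optimum) followed
#'   by BFGS; the best restart is polished with a longer BFGS run.
#' @param hessian compute the observed information at the optimum.
#' @return `hmm_fit`: `params` (natural scale, relabeled), `loglik`,
#'   `restarts` (start values, final loglik, convergence per restart),
#'   `vcov` (24 x 24, working scale), `se_beta` (slope SEs),
#'   `n_missing_cov`, `converged`.
#' @export
fit_hmm <- function(steps, loghri = steps$loghri, n_restarts = 50,
                    step_range = c(1, 2000), turn_range = c(0, 2),
                    seed = 1L, restart_nm_maxit = 1000,
                    restart_maxit = 75, final_maxit = 500,
                    hessian = TRUE) {
  if (any(step_range <= 0)) stop("step start range must be positive")
  track <- hmm_track_ids(steps)
  n_missing <- sum(!is.finite(loghri))
  lh <- as.numeric(ifelse(is.finite(loghri), loghri, 0))
  sl <- as.numeric(steps$sl); turn <- as.numeric(steps$turn)

  nll <- function(w) {
    p <- unpack_params(w)
    hmm_forward_nll_cpp(sl, turn, lh, track, p$step_mean, p$step_sd,
                        p$turn_mu, p$turn_kappa, p$alpha, p$beta)
  }

  set.seed(seed)
  restarts <- vector("list", n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    sm <- sort(stats::runif(3, step_range[1], step_range[2]))
    ss <- stats::runif(3, step_range[1], step_range[2])
    tm <- stats::runif(3, turn_range[1], turn_range[2])
    tsd <- stats::runif(3, turn_range[1], turn_range[2])
    start <- hmm_params(step_mean = sm, step_sd = ss,
                        turn_mu = tm,
                        turn_kappa = circular_sd_to_kappa(tsd),
                        alpha = matrix(-2, 3, 3),
                        beta = matrix(0, 3, 3))
    w0 <- pack_params(start)
    err <- NA_character_
    opt <- tryCatch({
      o0 <- stats::optim(w0, nll, method = "Nelder-Mead",
                         control = list(maxit = restart_nm_maxit))
      stats::optim(o0$par, nll, method = "BFGS",
                   control = list(maxit = restart_maxit,
                                  reltol = 1e-10))
    }, error = function(e) {
      err <<- conditionMessage(e)
      NULL
    })
    restarts[[r]] <- data.frame(restart = r,
                                start_mean1 = sm[1], start_mean2 = sm[2],
                                start_mean3 = sm[3],
                                loglik = if (is.null(opt)) NA_real_
                                else -opt$value,
                                convergence = if (is.null(opt)) NA_integer_
                                else opt$convergence,
                                error = err)
    if (!is.null(opt) && is.finite(opt$value) &&
        (is.null(best) || opt$value < best$value)) best <- opt
  }
  restart_tab <- do.call(rbind, restarts)
  if (is.null(best))
    stop("all restarts failed; restart table:\n",
         paste(utils::capture.output(print(restart_tab)), collapse = "\n"))
  polish <- stats::optim(best$par, nll, method = "BFGS",
                         control = list(maxit = final_maxit,
                                        reltol = 1e-12))
  w_hat <- polish$par
  # relabel states ascending by fitted mean step length
  p_hat <- unpack_params(w_hat)
  ord <- order(p_hat$step_mean)
  p_hat <- hmm_params(step_mean = p_hat$step_mean[ord],
                      step_sd = p_hat$step_sd[ord],
                      turn_mu = p_hat$turn_mu[ord],
                      turn_kappa = p_hat$turn_kappa[ord],
                      alpha = p_hat$alpha[ord, ord],
                      beta = p_hat$beta[ord, ord])
  w_hat <- pack_params(p_hat)
  V <- NULL; se_beta <- matrix(NA_real_, 3, 3)
  if (hessian) {
    H <- stats::optimHess(w_hat, nll)
    V <- tryCatch(solve(H), error = function(e) {
      warning("singular information matrix; using pseudo-inverse")
      svd_pinv(H)
    })
    od <- which(diag(3) == 0)
    se_beta[od] <- sqrt(pmax(diag(V)[19:24], 0))
  }
  structure(list(params = p_hat, loglik = -polish$value,
                 restarts = restart_tab, vcov = V, se_beta = se_beta,
                 n_missing_cov = n_missing,
                 converged = polish$convergence == 0L),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<hmm_fit> loglik %.2f%s\n", x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  print(data.frame(state = STATE_NAMES,
                   step_mean = p$step_mean, step_sd = p$step_sd,
                   turn_mu = p$turn_mu, turn_kappa = p$turn_kappa))
  invisible(x)
}

#' Viterbi decoding
#'
#' Most-probable state path under the fitted covariate-dependent chain;
#' ties break toward the lower state index. Initialization matches
#' [forward_loglik()] (stationary distribution per track).
#'
#' @param fit an [fit_hmm()] result (or bare [hmm_params()]).
#' @param steps step series as in [forward_loglik()].
#' @param loghri per-step covariate.
#' @return integer vector of decoded states (1 = stationary,
#'   2 = foraging, 3 = traveling) with levels in attribute `states`.
#' @export
viterbi <- function(fit, steps, loghri = steps$loghri) {
  params <- if (inherits(fit, "hmm_fit")) fit$params else fit
  track <- hmm_track_ids(steps)
  lh <- ifelse(is.finite(loghri), loghri, 0)
  ld <- emission_logdens(params, steps$sl, steps$turn)
  T_ <- nrow(ld)
  delta <- matrix(-Inf, T_, 3L)
  back <- matrix(0L, T_, 3L)
  for (t in seq_len(T_)) {
    G <- transition_matrix(params, lh[t])
    lG <- log(G)
    if (t == 1L || track[t] != track[t - 1L]) {
      pi0 <- stationary_dist(G)
      delta[t, ] <- log(pi0) + ld[t, ]
    } else {
      for (j in 1:3) {
        cand <- delta[t - 1L, ] + lG[, j]
        back[t, j] <- which.max(cand)   # which.max takes lowest on ties
        delta[t, j] <- cand[back[t, j]] + ld[t, j]
      }
    }
  }
  states <- integer(T_)
  for (t in rev(seq_len(T_))) {
    if (t == T_ || track[t + 1L] != track[t]) {
      states[t] <- which.max(delta[t, ])
    } else {
      states[t] <- back[t + 1L, states[t + 1L]]
    }
  }
  structure(states, states = STATE_NAMES)
}

#' Transition probabilities along a covariate grid
#'
#' All nine transition probabilities on a log(HRI) grid with delta-method
#' confidence bands from the working-scale covariance, plus the
#' per-transition slope estimates with Wald intervals.
#'
#' @param fit an [fit_hmm()] result with `vcov`.
#' @param loghri_grid covariate grid values.
#' @param level confidence level.
#' @return list: `curves` (data.frame loghri, from, to, prob, lower,
#'   upper) and `slopes` (data.frame from, to, beta, se, lower, upper).
#' @export
transition_curves <- function(fit, loghri_grid = seq(-2, 2,
                                                     length.out = 41),
                              level = 0.95) {
  stopifnot(inherits(fit, "hmm_fit"))
  if (is.null(fit$vcov)) stop("fit carries no covariance; refit with hessian = TRUE")
  zq <- stats::qnorm(1 - (1 - level) / 2)
  w_hat <- pack_params(fit$params)
  rows <- list()
  for (g in loghri_grid) {
    P <- transition_matrix(fit$params, g)
    for (i in 1:3) for (j in 1:3) {
      grad <- num_grad(function(w)
        transition_matrix(unpack_params(w), g)[i, j], w_hat)
      v <- drop(t(grad) %*% fit$vcov %*% grad)
      se <- sqrt(max(v, 0))
      rows[[length(rows) + 1L]] <-
        data.frame(loghri = g, from = STATE_NAMES[i], to = STATE_NAMES[j],
                   prob = P[i, j],
                   lower = max(0, P[i, j] - zq * se),
                   upper = min(1, P[i, j] + zq * se))
    }
  }
  od <- which(diag(3) == 0)
  idx <- cbind(row = row(diag(3))[od], col = col(diag(3))[od])
  slopes <- data.frame(from = STATE_NAMES[idx[, "row"]],
                       to = STATE_NAMES[idx[, "col"]],
                       beta = fit$params$beta[od],
                       se = fit$se_beta[od])
  slopes$lower <- slopes$beta - zq * slopes$se
  slopes$upper <- slopes$beta + zq * slopes$se
  list(curves = do.call(rbind, rows), slopes = slopes)
}

num_grad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(k) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + eps; xm[k] <- xm[k] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

#' Foraging-area segregation between colonies
#'
#' Jaccard overlap of the sets of landscape-unit cells containing
#' foraging-state points, per colony pair.
#'
#' @param points data.frame with `x`, `y`, `state` (decoded) and
#'   `colony`.
#' @param unit landscape-unit edge (m); default 1000.
#' @param foraging_state state index counted as foraging; default 2.
#' @return symmetric matrix of Jaccard overlaps (diagonal 1 where the
#'   colony has foraging points).
#' @export
foraging_segregation <- function(points, unit = 1000,
                                 foraging_state = 2L) {
  cols <- unique(points$colony)
  if (length(cols) < 2L) stop("need at least 2 colonies")
  sets <- lapply(cols, function(cc) {
    p <- points[points$colony == cc & points$state == foraging_state, ]
    unique(paste(floor(p$x / unit), floor(p$y / unit)))
  })
  names(sets) <- cols
  empty <- lengths(sets) == 0L
  if (any(empty))
    warning("colonies with zero foraging points: ",
            paste(cols[empty], collapse = ", "))
  J <- matrix(0, length(cols), length(cols),
              dimnames = list(cols, cols))
  for (a in seq_along(cols)) for (b in seq_along(cols)) {
    u <- length(union(sets[[a]], sets[[b]]))
    J[a, b] <- if (u == 0L) 0 else
      length(intersect(sets[[a]], sets[[b]])) / u
  }
  J
}
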