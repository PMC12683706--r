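# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (plain loops and closed forms), sharing
# no code with the implementation they check.

# count marsh-water 4-neighbour adjacencies by explicit double loop
brute_edge_total <- function(hab, width = 10) {
  v <- hab$values
  nr <- nrow(v); nc <- ncol(v)
  n_adj <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(v[i, j]) || v[i, j] != 1L) next       # 1 = marsh
    for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
          !is.na(v[ii, jj]) && v[ii, jj] == 2L)     # 2 = water
        n_adj <- n_adj + 1L
    }
  }
  n_adj * hab$cellsize * width
}

# transition matrix from first principles (softmax of the working scale)
oracle_trans <- function(alpha, beta, g) {
  eta <- alpha + beta * g
  diag(eta) <- 0
  p <- exp(eta)
  p / rowSums(p)
}

oracle_stationary <- function(P) {
  A <- rbind(t(diag(3) - P)[1:2, ], rep(1, 3))
  solve(A, c(0, 0, 1))
}

oracle_dens <- function(t, j, sl, turn, mean_, sd_, vmu, vkappa) {
  d <- 1
  if (is.finite(sl[t]) && sl[t] > 0) {
    shape <- (mean_[j] / sd_[j])^2
    d <- d * stats::dgamma(sl[t], shape = shape,
                           scale = sd_[j]^2 / mean_[j])
  }
  if (is.finite(turn[t]))
    d <- d * exp(vkappa[j] * cos(turn[t] - vmu[j])) /
      (2 * pi * besselI(vkappa[j], 0))
  d
}

# likelihood by explicit summation over all 3^T state paths (one track)
brute_forward_loglik <- function(params, sl, turn, lh) {
  T_ <- length(sl)
  G <- lapply(lh, function(g) oracle_trans(params$alpha, params$beta, g))
  pi0 <- oracle_stationary(G[[1]])
  paths <- as.matrix(expand.grid(rep(list(1:3), T_)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- pi0[s[1]] * oracle_dens(1, s[1], sl, turn, params$step_mean,
                                 params$step_sd, params$turn_mu,
                                 params$turn_kappa)
    if (T_ > 1) for (t in 2:T_) {
      p <- p * G[[t]][s[t - 1], s[t]] *
        oracle_dens(t, s[t], sl, turn, params$step_mean,
                    params$step_sd, params$turn_mu, params$turn_kappa)
    }
    tot <- tot + p
  }
  log(tot)
}

# most probable path by explicit argmax over all 3^T paths (one track)
brute_viterbi <- function(params, sl, turn, lh) {
  T_ <- length(sl)
  G <- lapply(lh, function(g) oracle_trans(params$alpha, params$beta, g))
  pi0 <- oracle_stationary(G[[1]])
  paths <- as.matrix(expand.grid(rep(list(1:3), T_)))
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- log(pi0[s[1]]) + log(oracle_dens(1, s[1], sl, turn,
                                          params$step_mean,
                                          params$step_sd,
                                          params$turn_mu,
                                          params$turn_kappa))
    if (T_ > 1) for (t in 2:T_) {
      p <- p + log(G[[t]][s[t - 1], s[t]]) +
        log(oracle_dens(t, s[t], sl, turn, params$step_mean,
                        params$step_sd, params$turn_mu,
                        params$turn_kappa))
    }
    if (p > best) { best <- p; best_path <- s }
  }
  list(path = best_path, logprob = best)
}

# conditional-logit log-likelihood by direct per-stratum arithmetic
brute_clogit_loglik <- function(beta, X, case, stratum) {
  ll <- 0
  for (s in unique(stratum)) {
    idx <- stratum == s
    eta <- as.vector(X[idx, , drop = FALSE] %*% beta)
    ll <- ll + eta[case[idx] == 1] - log(sum(exp(eta)))
  }
  ll
}
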