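# Brute-force quadrature oracles for posterior exceedance probabilities.
# Independent of the sampler: direct numerical integration of the
# unnormalised posterior. Only feasible for K <= 2 and small n.

# Independent model: 1-D adaptive quadrature over theta.
oracle_exceed_indep <- function(y, n, q0, prior_mean, prior_sd) {
  f <- function(th) exp(y * th - n * log1p(exp(th))) *
    stats::dnorm(th, prior_mean, prior_sd)
  Z <- stats::integrate(f, -40, 40, rel.tol = 1e-10)$value
  up <- stats::integrate(f, stats::qlogis(q0), 40, rel.tol = 1e-10)$value
  up / Z
}

# EXNEX model, K <= 2: sum over the 2^K delta configurations; EX terms
# integrated over (theta_k, mu, sigma) on fixed grids, NEX terms by 1-D
# adaptive quadrature. Returns P(p_k > q0 | y, n) for every basket.
oracle_exceed_exnex <- function(y, n, config,
                                theta_step = 0.02, mu_step = 0.05,
                                sigma_pts = 300, sigma_max = 4.5) {
  K <- length(y)
  stopifnot(K <= 2)
  pi_k <- recycle_k(config$pi, K, "pi")
  nex <- nex_prior_params(recycle_k(config$rho, K, "rho"))
  q0 <- config$q0
  lcut <- stats::qlogis(q0)

  th <- seq(-12, 8, by = theta_step)
  lik <- lapply(seq_len(K), function(k)
    exp(y[k] * th - n[k] * log1p(exp(th))))
  above <- th > lcut

  mu <- seq(-30, 25, by = mu_step)
  sg <- seq(sigma_max / sigma_pts, sigma_max, length.out = sigma_pts)
  w_mu <- stats::dnorm(mu, config$mu_prior_mean, config$mu_prior_sd) * mu_step
  w_sg <- 2 * stats::dnorm(sg, 0, config$sigma_prior_scale) *
    (sg[2] - sg[1])

  # I[[k]][mu, sigma]: integral of lik_k(theta) * N(theta | mu, sigma)
  # Iup restricted to theta > logit(q0)
  I <- Iup <- vector("list", K)
  for (k in seq_len(K)) {
    I[[k]] <- matrix(0, length(mu), length(sg))
    Iup[[k]] <- matrix(0, length(mu), length(sg))
    lw <- lik[[k]] * theta_step
    lw_up <- lw * above
    for (j in seq_along(sg)) {
      D <- stats::dnorm(outer(th, mu, "-"), 0, sg[j])  # theta x mu
      I[[k]][, j] <- crossprod(D, lw)
      Iup[[k]][, j] <- crossprod(D, lw_up)
    }
  }

  G <- Gup <- numeric(K)
  for (k in seq_len(K)) {
    G[k] <- oracle_norm_const(y[k], n[k], nex$m[k], sqrt(nex$v2[k]))
    Gup[k] <- G[k] *
      oracle_exceed_indep(y[k], n[k], q0, nex$m[k], sqrt(nex$v2[k]))
  }

  configs <- as.matrix(expand.grid(rep(list(0:1), K)))
  Z_total <- 0
  Z_up <- numeric(K)
  for (r in seq_len(nrow(configs))) {
    d <- configs[r, ]
    pr_d <- prod(ifelse(d == 1, pi_k, 1 - pi_k))
    if (pr_d == 0) next
    ex <- which(d == 1)
    nx <- which(d == 0)
    nex_part <- if (length(nx)) prod(G[nx]) else 1
    if (length(ex) == 0) {
      Zc <- nex_part
      Z_total <- Z_total + pr_d * Zc
      for (k in nx) Z_up[k] <- Z_up[k] + pr_d * Zc * Gup[k] / G[k]
    } else {
      M <- Reduce(`*`, I[ex])          # mu x sigma product over EX baskets
      Zc <- nex_part * as.numeric(w_mu %*% M %*% w_sg)
      Z_total <- Z_total + pr_d * Zc
      for (k in ex) {
        others <- setdiff(ex, k)
        Mk <- if (length(others)) Reduce(`*`, I[others]) * Iup[[k]]
              else Iup[[k]]
        Z_up[k] <- Z_up[k] +
          pr_d * nex_part * as.numeric(w_mu %*% Mk %*% w_sg)
      }
      for (k in nx) Z_up[k] <- Z_up[k] + pr_d * Zc * Gup[k] / G[k]
    }
  }
  Z_up / Z_total
}

oracle_norm_const <- function(y, n, prior_mean, prior_sd) {
  f <- function(th) exp(y * th - n * log1p(exp(th))) *
    stats::dnorm(th, prior_mean, prior_sd)
  stats::integrate(f, -40, 40, rel.tol = 1e-10)$value
}
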