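# Independent oracles used by the tests. These deliberately share no code
# with the package internals.

# first-order spherical Bessel derivative roots by bisection (independent of
# sphere_gpd_roots, which uses uniroot on a different formulation)
oracle_j1prime_roots <- function(count) {
  j1p <- function(x) {
    j1 <- sin(x) / x^2 - cos(x) / x
    (sin(x) / x - 2 * j1 / x) # d/dx j1 via recurrence j1' = j0 - 2 j1 / x
  }
  roots <- numeric(0)
  lo <- 1
  while (length(roots) < count) {
    hi <- lo + 0.05
    if (sign(j1p(lo)) != sign(j1p(hi))) {
      a <- lo; b <- hi
      for (i in 1:200) {
        m <- (a + b) / 2
        if (sign(j1p(a)) == sign(j1p(m))) a <- m else b <- m
      }
      roots <- c(roots, (a + b) / 2)
    }
    lo <- hi
  }
  roots
}

# second, independently coded Murday-Cotts implementation (plain R, own roots)
oracle_sphere_attn <- function(R, Di, G, delta_eff, Delta, n_roots = 40) {
  mu <- oracle_j1prime_roots(n_roots)
  gam <- 2.6752219e8
  Rsi <- R * 1e-6; Dsi <- Di * 1e-9; Gsi <- G * 1e-3
  d <- delta_eff * 1e-3; D <- Delta * 1e-3
  lam <- mu^2 * Dsi / Rsi^2
  C <- Rsi^2 / (mu^2 * (mu^2 - 2))
  br <- 2 * (lam * d - 1 + exp(-lam * d)) +
    2 * exp(-lam * D) - exp(-lam * (D - d)) - exp(-lam * (D + d))
  exp(-2 * gam^2 * Gsi^2 * sum(C * br / lam^2))
}

oracle_mm_signal <- function(R, Di, De, fi, protocol) {
  attn <- vapply(seq_len(nrow(protocol)), function(j) {
    if (protocol$G[j] == 0) 1
    else oracle_sphere_attn(R, Di, protocol$G[j],
                            protocol$delta[j] - protocol$rise[j],
                            protocol$Delta[j])
  }, numeric(1))
  fi * attn + (1 - fi) * exp(-protocol$b * 1e-3 * De)
}

# random-walk Monte Carlo oracle: spins diffusing in an impermeable sphere,
# rectangular gradient pulses of width delta, phase accumulated along z
oracle_mc_attn <- function(R, Di, G, delta, Delta, walkers = 30000,
                           nsteps = 1200, seed = 99) {
  set.seed(seed)
  gam <- 2.6752219e8
  Ttot <- Delta + delta
  dt <- Ttot / nsteps                  # ms
  r <- matrix(rnorm(3 * walkers), ncol = 3)
  u <- runif(walkers)^(1 / 3) * R
  r <- r * (u / sqrt(rowSums(r^2)))
  sig <- sqrt(2 * Di * dt)
  phi <- numeric(walkers)
  Gsi <- G * 1e-3
  for (s in seq_len(nsteps)) {
    t0 <- (s - 0.5) * dt
    gon <- if (t0 < delta) 1 else if (t0 >= Delta && t0 < Delta + delta) -1 else 0
    r <- r + matrix(rnorm(3 * walkers, sd = sig), ncol = 3)
    rad <- sqrt(rowSums(r^2))
    out <- rad > R
    if (any(out)) r[out, ] <- r[out, ] * ((2 * R - rad[out]) / rad[out])
    if (gon != 0) phi <- phi + gam * Gsi * gon * (r[, 3] * 1e-6) * (dt * 1e-3)
  }
  mean(cos(phi))
}
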