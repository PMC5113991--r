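# shared fixtures and independent oracles

# pure-NaCl bath pair (mM apical / basal)
nacl_baths <- function(apical, basal) {
  bath_pair(solution(sprintf("%g NaCl", apical), NaCl = apical),
            solution(sprintf("%g NaCl", basal), NaCl = basal))
}

# independent zero-current solver for the two-ion constant-field model:
# finds V (mV) where the GHK Na+ and Cl- current densities cancel, by
# root-finding on the current equation rather than the closed-form potential
ghk_zero_current_oracle <- function(beta, baths, ctx = physical_context()) {
  ions <- bath_ions(baths)
  vt <- thermal_voltage(ctx)
  current <- function(v_mv) {
    u <- (v_mv / 1000) / vt
    if (abs(u) < 1e-12) u <- 1e-12
    i_na <- beta * u * (ions[["na_a"]] - ions[["na_b"]] * exp(-u)) /
      (1 - exp(-u))
    i_cl <- u * (ions[["cl_a"]] - ions[["cl_b"]] * exp(u)) / (1 - exp(u))
    i_na + i_cl
  }
  lim <- nernst_limits(baths, ctx)
  lo <- min(lim) + 1e-6; hi <- max(lim) - 1e-6
  stats::uniroot(current, c(lo, hi), tol = 1e-12)$root
}

# analytic expected edge count for a uniformly placed square window: the
# probability that both endpoints of an edge fall inside the window,
# integrated over admissible window origins
expected_window_edges <- function(graph, window_area) {
  s <- sqrt(window_area)
  f <- graph$field
  vx <- stats::setNames(graph$vertices$x, graph$vertices$id)
  vy <- stats::setNames(graph$vertices$y, graph$vertices$id)
  span <- function(lo_f, hi_f, c1, c2) {
    lo <- max(lo_f, max(c1, c2) - s)
    hi <- min(hi_f - s, min(c1, c2))
    max(0, hi - lo) / (hi_f - s - lo_f)
  }
  p <- vapply(graph$edges, function(e) {
    span(f[1], f[2], vx[[e$v1]], vx[[e$v2]]) *
      span(f[3], f[4], vy[[e$v1]], vy[[e$v2]])
  }, numeric(1))
  list(mean = sum(p), var = sum(p * (1 - p)))
}

# rasterise a horizontal two-label interface y = f(x) (in pixel units)
rasterize_interface <- function(nrow, ncol, boundary_fun) {
  m <- matrix(2L, nrow, ncol)
  for (j in seq_len(ncol)) {
    yb <- boundary_fun(j - 0.5)
    m[seq_len(nrow) < yb, j] <- 1L
  }
  m
}
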