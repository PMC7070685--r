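# Independent oracles used to cross-check the analytic solvers.

# Bisection on the single-reaction mass-action balance
# g(z) = (b0+z)(pp0+z) - K (n0-z)(p0-z), root on the physical interval.
oracle_single_extent <- function(K, n0, p0, b0 = 0, pp0 = 0, tol = 1e-13) {
  g <- function(z) (b0 + z) * (pp0 + z) - K * (n0 - z) * (p0 - z)
  lo <- -min(b0, pp0)
  hi <- min(n0, p0)
  if (g(lo) > 0 || hi <= lo) return(lo)   # no forward reaction possible
  while (hi - lo > tol * max(1, abs(hi))) {
    mid <- (lo + hi) / 2
    if (g(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Brute-force grid + bisection oracle over (x, y) = (N2, P1P), independent
# of the solver's closed forms: for each trial x the product mass-action
# balance g(y) = (base0 - x) y - Kp x (phosphate0 - y) is solved for y by
# bisection (g is strictly increasing on [0, phosphate0] with a sign
# change), the donor residual f(x) is scanned on an exhaustive x grid for
# its sign change, and the bracketing interval refined by bisection.
oracle_coupled_equilibrium <- function(K_donor, K_product, donor0, base0,
                                       phosphate0, n_grid = 201L) {
  y_at <- function(x) {
    g <- function(y) (base0 - x) * y - K_product * x * (phosphate0 - y)
    lo <- 0; hi <- phosphate0
    for (k in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid) <= 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  f <- function(x) {
    y <- y_at(x)
    (x + y) * y - K_donor * (donor0 - x - y) * (phosphate0 - y)
  }
  xs <- seq(0, min(base0, donor0), length.out = n_grid)
  fv <- vapply(xs, f, numeric(1))
  i <- which(fv[-1] >= 0 & fv[-length(fv)] < 0)[1]
  if (is.na(i)) stop("oracle: no sign change found")
  lo <- xs[i]; hi <- xs[i + 1]
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  x <- (lo + hi) / 2
  c(x = x, y = y_at(x))
}

# Random but physically sensible coupled systems for property tests
random_system <- function(K_range = c(0.01, 1), conc_range = c(0.1, 50)) {
  transglycosylation_system(
    K_donor = stats::runif(1, K_range[1], K_range[2]),
    K_product = stats::runif(1, K_range[1], K_range[2]),
    donor0 = stats::runif(1, conc_range[1], conc_range[2]),
    base0 = stats::runif(1, conc_range[1], conc_range[2]),
    phosphate0 = stats::runif(1, conc_range[1], conc_range[2]))
}

conservation_deviations <- function(state, sys) {
  c(state[["N1"]] + state[["N2"]] + state[["P1P"]] - sys$donor0,
    state[["N1"]] + state[["B1"]] - sys$donor0,
    state[["N2"]] + state[["B2"]] - sys$base0,
    state[["Pi"]] + state[["P1P"]] - sys$phosphate0)
}

mass_action_residuals <- function(state, sys) {
  c(state[["B1"]] * state[["P1P"]] -
      sys$K_donor * state[["N1"]] * state[["Pi"]],
    state[["B2"]] * state[["P1P"]] -
      sys$K_product * state[["N2"]] * state[["Pi"]])
}
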