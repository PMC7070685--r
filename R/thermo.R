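#' Define a coupled transglycosylation reaction system
#'
#' A transglycosylation cascade transfers a pentose moiety from a sugar-donor
#' nucleoside (uridine or thymidine) to a free purine base through two coupled
#' phosphorolysis reactions that share inorganic phosphate and
#' pentose-1-phosphate.  Both reactions are reversible and under thermodynamic
#' control, so the attainable product yield is fixed by the two phosphorolysis
#' equilibrium constants and the initial composition.
#'
#' Equilibrium constants follow the phosphorolysis-forward convention
#' \deqn{K = \frac{[\mathrm{base}][\mathrm{P1P}]}{[\mathrm{nucleoside}][\mathrm{P_i}]}}
#' consistent with K = 0.18 for uridine and K = 0.125 for thymidine at 40 degC.
#' Activities are approximated by molar concentrations (dilute mM regime); no
#' ionic-strength correction is applied.  Temperature and pH are carried for
#' documentation only: the constants are valid at the temperature they were
#' measured at and are not extrapolated.
#'
#' @param K_donor Phosphorolysis equilibrium constant of the sugar-donor
#'   nucleoside (dimensionless, > 0).
#' @param K_product Phosphorolysis equilibrium constant of the product
#'   nucleoside (dimensionless, > 0).
#' @param donor0 Initial sugar-donor nucleoside concentration (mM).
#' @param base0 Initial free acceptor-base concentration (mM).
#' @param phosphate0 Initial inorganic phosphate concentration (mM).
#' @param donor_id,acceptor_base_id,product_id Optional species labels.
#' @param temperature_C,pH Informational reaction conditions.
#'
#' @return An object of class `transglycosylation_system`.
#' @seealso [solve_transglycosylation_equilibrium()], [donor_excess_for_yield()]
#' @examples
#' sys <- transglycosylation_system(K_donor = 0.18, K_product = 0.081,
#'                                  donor0 = 5, base0 = 5, phosphate0 = 2)
#' solve_transglycosylation_equilibrium(sys)
#' @export
transglycosylation_system <- function(K_donor, K_product,
                                      donor0, base0, phosphate0,
                                      donor_id = "donor",
                                      acceptor_base_id = "base",
                                      product_id = "product",
                                      temperature_C = 40, pH = 7.5) {
  stopifnot(is.numeric(K_donor), length(K_donor) == 1L,
            is.numeric(K_product), length(K_product) == 1L)
  if (!is.finite(K_donor) || K_donor <= 0)
    stop("'K_donor' must be a positive finite number", call. = FALSE)
  if (!is.finite(K_product) || K_product <= 0)
    stop("'K_product' must be a positive finite number", call. = FALSE)
  for (nm in c("donor0", "base0", "phosphate0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("'%s' must be a single non-negative number", nm),
           call. = FALSE)
  }
  structure(
    list(donor_id = donor_id, acceptor_base_id = acceptor_base_id,
         product_id = product_id,
         K_donor = K_donor, K_product = K_product,
         donor0 = donor0, base0 = base0, phosphate0 = phosphate0,
         temperature_C = temperature_C, pH = pH),
    class = "transglycosylation_system")
}

#' @export
print.transglycosylation_system <- function(x, ...) {
  cat("Transglycosylation system:", x$donor_id, "+", x$acceptor_base_id,
      "->", x$product_id, "\n")
  cat(sprintf("  K_donor = %.4g, K_product = %.4g\n", x$K_donor, x$K_product))
  cat(sprintf("  donor0 = %g mM, base0 = %g mM, phosphate0 = %g mM\n",
              x$donor0, x$base0, x$phosphate0))
  cat(sprintf("  %g degC, pH %g (informational)\n", x$temperature_C, x$pH))
  invisible(x)
}

#' Construct and validate a six-species equilibrium state
#'
#' The six tracked species are the donor nucleoside (N1), its liberated base
#' (B1, uracil or thymine), the product nucleoside (N2), the remaining free
#' acceptor base (B2), inorganic phosphate (Pi) and pentose-1-phosphate (P1P),
#' all in mM.  When the originating system is supplied the four linear
#' conservation laws (pentose, donor base, acceptor base, phosphate) are
#' checked to `tol`.
#'
#' @param N1,B1,N2,B2,Pi,P1P Species concentrations (mM, all >= 0).
#' @param system Optional `transglycosylation_system` used for conservation
#'   checks.
#' @param tol Absolute tolerance (mM) for the conservation checks.
#' @return A named numeric vector of class `species_state`.
#' @export
species_state <- function(N1, B1, N2, B2, Pi, P1P, system = NULL,
                          tol = 1e-9) {
  s <- c(N1 = N1, B1 = B1, N2 = N2, B2 = B2, Pi = Pi, P1P = P1P)
  if (any(!is.finite(s)))
    stop("species concentrations must be finite", call. = FALSE)
  if (any(s < -tol))
    stop("negative species concentration: infeasible state", call. = FALSE)
  s <- pmax(s, 0)
  if (!is.null(system)) {
    dev <- c(pentose   = s[["N1"]] + s[["N2"]] + s[["P1P"]] - system$donor0,
             donor_base = s[["N1"]] + s[["B1"]] - system$donor0,
             acceptor_base = s[["N2"]] + s[["B2"]] - system$base0,
             phosphate = s[["Pi"]] + s[["P1P"]] - system$phosphate0)
    if (any(abs(dev) > tol))
      stop("conservation law violated: ",
           paste(names(dev)[abs(dev) > tol], collapse = ", "),
           call. = FALSE)
  }
  structure(s, class = c("species_state", "numeric"))
}

#' @export
print.species_state <- function(x, ...) {
  cat("Species state (mM):\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Equilibrium extent of a single phosphorolysis reaction
#'
#' Solves the closed-form equilibrium of one reversible phosphorolysis,
#' nucleoside + Pi <-> base + pentose-1-phosphate, for the extent z with
#' \deqn{K = \frac{(b_0+z)(p1p_0+z)}{(n_0-z)(P_0-z)}}
#' The quadratic `(1-K) z^2 + (b0 + p1p0 + K (n0 + P0)) z + (b0 p1p0 - K n0 P0) = 0`
#' is solved and the physical root (all species non-negative) selected.
#'
#' @param K Phosphorolysis equilibrium constant (> 0).
#' @param nucleoside0 Initial nucleoside concentration (mM).
#' @param phosphate0 Initial phosphate concentration (mM).
#' @param base0 Initial free-base concentration (mM).
#' @param p1p0 Initial pentose-1-phosphate concentration (mM).
#' @return A list with the extent `z` (mM) and the equilibrium
#'   concentrations `nucleoside`, `phosphate`, `base`, `p1p`.
#' @examples
#' phosphorolysis_equilibrium(K = 0.18, nucleoside0 = 5, phosphate0 = 2)
#' @export
phosphorolysis_equilibrium <- function(K, nucleoside0, phosphate0,
                                       base0 = 0, p1p0 = 0) {
  stopifnot(is.numeric(K), K > 0, nucleoside0 >= 0, phosphate0 >= 0,
            base0 >= 0, p1p0 >= 0)
  # (b0+z)(p+z) = K (n0-z)(P0-z), rearranged to a z^2 + b z + c = 0
  a <- 1 - K
  b <- base0 + p1p0 + K * (nucleoside0 + phosphate0)
  cc <- base0 * p1p0 - K * nucleoside0 * phosphate0
  lo <- -min(base0, p1p0)         # reverse reaction limited by products
  hi <- min(nucleoside0, phosphate0)
  if (abs(a) < .Machine$double.eps) {   # K == 1: linear
    z <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0)
      stop("no physical equilibrium root: inconsistent inputs", call. = FALSE)
    roots <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
    ok <- roots >= lo - 1e-12 & roots <= hi + 1e-12
    if (!any(ok))
      stop("no physical equilibrium root: inconsistent inputs", call. = FALSE)
    z <- roots[ok][1]
  }
  z <- min(max(z, lo), hi)
  list(z = z,
       nucleoside = nucleoside0 - z, phosphate = phosphate0 - z,
       base = base0 + z, p1p = p1p0 + z)
}

## residual of the donor-reaction mass action at trial product concentration x,
## with P1P eliminated through the product-reaction mass action
.coupled_residual <- function(x, K_donor, K_product, donor0, base0,
                              phosphate0) {
  y <- K_product * x * phosphate0 / ((base0 - x) + K_product * x)
  (x + y) * y - K_donor * (donor0 - x - y) * (phosphate0 - y)
}

.p1p_from_product <- function(x, K_product, base0, phosphate0) {
  K_product * x * phosphate0 / ((base0 - x) + K_product * x)
}

#' Solve the coupled two-reaction transglycosylation equilibrium
#'
#' Finds the simultaneous equilibrium of donor phosphorolysis
#' (N1 + Pi <-> B1 + P1P) and product phosphorolysis (N2 + Pi <-> B2 + P1P)
#' under the four linear conservation laws.  The problem reduces to a 1-D
#' root find in x = \[N2\]: for a trial x the product mass-action relation
#' gives P1P in closed form,
#' \deqn{y = \frac{K_2\,x\,P_0}{(b_0-x) + K_2\,x},}
#' and the residual is the donor mass-action law
#' \deqn{f(x) = (x+y)\,y - K_1\,(d_0-x-y)(P_0-y).}
#' f is negative at x = 0 and positive as x approaches base0, so the root is
#' bracketed on (0, base0) and polished with Brent's method to a relative
#' residual below 1e-12.
#'
#' @param system A [transglycosylation_system()].
#' @param tol Relative residual tolerance for the root polish.
#' @return A `species_state` satisfying conservation and both mass-action
#'   laws.
#' @examples
#' sys <- transglycosylation_system(0.18, 0.081, 5, 5, 2)
#' st <- solve_transglycosylation_equilibrium(sys)
#' yield_from_state(st, base0 = 5)    # equilibrium conversion ~ 0.578
#' @export
solve_transglycosylation_equilibrium <- function(system, tol = 1e-12) {
  stopifnot(inherits(system, "transglycosylation_system"))
  d0 <- system$donor0; b0 <- system$base0; p0 <- system$phosphate0
  K1 <- system$K_donor; K2 <- system$K_product

  if (p0 == 0 || d0 == 0 || b0 == 0) {
    # no shared phosphate / nothing to transfer: trivial equilibrium of the
    # donor reaction alone (which is itself frozen when any pool is empty)
    if (p0 == 0 || d0 == 0)
      return(species_state(d0, 0, 0, b0, p0, 0, system = system))
    # b0 == 0: pure donor phosphorolysis
    eq <- phosphorolysis_equilibrium(K1, d0, p0)
    return(species_state(eq$nucleoside, eq$base, 0, 0, eq$phosphate, eq$p1p,
                         system = system))
  }

  scale <- max(K1, 1) * max(d0, b0, p0)^2
  f <- function(x) .coupled_residual(x, K1, K2, d0, b0, p0)
  lo <- 0; hi <- b0
  flo <- f(lo)
  if (flo > 0)
    stop("equilibrium solver: residual positive at x = 0 (no bracket); ",
         "check system inputs", call. = FALSE)
  # shrink the upper bound until f(hi) is finite and positive
  shrink <- 0
  fhi <- f(hi * (1 - 1e-12))
  while ((!is.finite(fhi) || fhi <= 0) && shrink < 60) {
    hi <- lo + (hi - lo) * 0.99
    fhi <- f(hi)
    shrink <- shrink + 1
  }
  if (!is.finite(fhi) || fhi <= 0)
    stop("equilibrium solver: failed to bracket the root on (0, base0); ",
         sprintf("f(0) = %.3g, f(%.6g) = %.3g", flo, hi, fhi), call. = FALSE)

  x <- stats::uniroot(f, c(lo, hi * (1 - 1e-15)),
                      tol = .Machine$double.eps^0.75,
                      maxiter = 2000L)$root
  # Newton polish on the residual
  for (i in 1:8) {
    fx <- f(x)
    if (abs(fx) <= tol * scale) break
    h <- max(abs(x), 1e-8) * 1e-7
    dfx <- (f(x + h) - f(x - h)) / (2 * h)
    if (!is.finite(dfx) || dfx == 0) break
    step <- fx / dfx
    xn <- x - step
    if (xn <= 0 || xn >= b0) break
    x <- xn
  }
  if (abs(f(x)) > tol * scale * 10)
    stop(sprintf(
      "equilibrium solver: residual %.3g exceeds tolerance %.3g",
      abs(f(x)), tol * scale), call. = FALSE)

  y <- .p1p_from_product(x, K2, b0, p0)
  species_state(N1 = d0 - x - y, B1 = x + y, N2 = x, B2 = b0 - x,
                Pi = p0 - y, P1P = y, system = system, tol = 1e-8)
}

#' Product yield on the acceptor base from an equilibrium state
#'
#' The yield is the fraction of the initially supplied acceptor base that has
#' been converted to product nucleoside, N2 / base0.  At equilibrium with the
#' base pool conserved this equals the conversion N2 / (N2 + B2) reported by
#' HPLC quantification.
#'
#' @param state A `species_state`.
#' @param base0 Initial acceptor-base concentration (mM, > 0).
#' @return Yield as a fraction in \[0, 1\].
#' @export
yield_from_state <- function(state, base0) {
  stopifnot(inherits(state, "species_state"))
  if (!is.numeric(base0) || length(base0) != 1L || base0 <= 0)
    stop("yield undefined: 'base0' must be positive", call. = FALSE)
  unname(state[["N2"]] / base0)
}

#' Read reaction scenarios from a structured text config
#'
#' Scenarios are stored as a YAML list; each entry carries species labels,
#' the two phosphorolysis constants and the initial composition in mM.
#'
#' @param path Path to a YAML file with a top-level `scenarios` list.
#' @return A list of `transglycosylation_system` objects.
#' @export
read_scenarios <- function(path) {
  cfg <- yaml::read_yaml(path)
  scen <- cfg$scenarios
  if (is.null(scen)) stop("config has no 'scenarios' entry", call. = FALSE)
  lapply(scen, function(s) {
    transglycosylation_system(
      K_donor = s$K_donor, K_product = s$K_product,
      donor0 = s$donor0, base0 = s$base0, phosphate0 = s$phosphate0,
      donor_id = s$donor_id %||% "donor",
      acceptor_base_id = s$acceptor_base_id %||% "base",
      product_id = s$product_id %||% "product",
      temperature_C = s$temperature_C %||% 40,
      pH = s$pH %||% 7.5)
  })
}

#' Solve a list of scenarios and write the equilibrium states as CSV
#'
#' @param systems A list of `transglycosylation_system` objects (e.g. from
#'   [read_scenarios()]).
#' @param path Output CSV path; one row per scenario with species columns
#'   and the equilibrium yield.
#' @return The result data frame, invisibly.
#' @export
write_equilibrium_csv <- function(systems, path) {
  rows <- lapply(systems, function(sys) {
    st <- solve_transglycosylation_equilibrium(sys)
    data.frame(donor_id = sys$donor_id, product_id = sys$product_id,
               K_donor = sys$K_donor, K_product = sys$K_product,
               donor0 = sys$donor0, base0 = sys$base0,
               phosphate0 = sys$phosphate0,
               N1 = st[["N1"]], B1 = st[["B1"]], N2 = st[["N2"]],
               B2 = st[["B2"]], Pi = st[["Pi"]], P1P = st[["P1P"]],
               yield = yield_from_state(st, sys$base0))
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
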