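#' Specify a target-yield reaction design
#'
#' @param K_donor,K_product Phosphorolysis equilibrium constants.
#' @param base0 Acceptor-base concentration (mM, > 0).
#' @param phosphate0 Phosphate concentration (mM, > 0).  Defaults to 0.5 mM
#'   with base0 = 5 mM (0.1 phosphate equivalents), the level used for the
#'   verification and preparative reactions; low phosphate favours high
#'   yields, so the design level matters and is always explicit.
#' @param target_yield Desired equilibrium product yield, fraction in (0, 1).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(K_donor, K_product, base0 = 5, phosphate0 = 0.5,
                        target_yield = 0.9) {
  stopifnot(K_donor > 0, K_product > 0, base0 > 0, phosphate0 > 0)
  if (!is.numeric(target_yield) || target_yield <= 0 || target_yield >= 1)
    stop("'target_yield' must lie strictly between 0 and 1 ",
         "(yield 1 needs infinite donor)", call. = FALSE)
  structure(list(K_donor = K_donor, K_product = K_product, base0 = base0,
                 phosphate0 = phosphate0, target_yield = target_yield),
            class = "design_spec")
}

#' Sugar-donor excess required for a target equilibrium yield
#'
#' Closed-form inverse of the coupled equilibrium: the target fixes the
#' product concentration x = target * base0, the product mass-action law
#' fixes pentose-1-phosphate
#' \deqn{y = \frac{K_2\,x\,P_0}{(b_0 - x) + K_2\,x},}
#' and the donor mass-action law then yields the required initial donor
#' \deqn{d_0 = x + y + \frac{(x+y)\,y}{K_1\,(P_0-y)}.}
#' The returned excess ratio is r = donor0 / base0 (e.g. 30.5 mM donor over
#' 5 mM base is r = 6.1).  Forward-solving the designed composition
#' reproduces the target yield exactly.
#'
#' @param spec A [design_spec()], or `K_donor` if the remaining arguments are
#'   given positionally.
#' @param K_product,base0,phosphate0,target_yield Used when `spec` is the
#'   numeric `K_donor` instead of a `design_spec`.
#' @return The excess ratio r, with the full designed composition in the
#'   `"composition"` attribute (`donor0`, `base0`, `phosphate0` in mM).
#' @examples
#' donor_excess_for_yield(design_spec(0.18, 0.081, 5, 0.5, 0.90))  # ~ 4.76
#' donor_excess_for_yield(design_spec(0.125, 0.071, 5, 0.5, 0.95)) # ~ 11.9
#' @export
donor_excess_for_yield <- function(spec, K_product = NULL, base0 = 5,
                                   phosphate0 = 0.5, target_yield = 0.9) {
  if (!inherits(spec, "design_spec")) {
    spec <- design_spec(spec, K_product, base0, phosphate0, target_yield)
  }
  x <- spec$target_yield * spec$base0
  y <- .p1p_from_product(x, spec$K_product, spec$base0, spec$phosphate0)
  stopifnot(y < spec$phosphate0)   # holds for any target_yield < 1
  donor0 <- x + y + (x + y) * y / (spec$K_donor * (spec$phosphate0 - y))
  r <- donor0 / spec$base0
  attr(r, "composition") <- c(donor0 = donor0, base0 = spec$base0,
                              phosphate0 = spec$phosphate0)
  r
}

#' Equilibrium yield as a function of sugar-donor excess
#'
#' Forward-solves the coupled equilibrium across a grid of donor/base ratios.
#' Yield increases strictly with excess, which is the design lever the
#' donor-excess calculation inverts.
#'
#' @param K_donor,K_product Equilibrium constants.
#' @param base0,phosphate0 Fixed composition (mM).
#' @param r_grid Positive, ascending donor/base ratios.
#' @return Data frame with columns `r`, `donor0_mM` and `yield`.
#' @export
yield_vs_excess_curve <- function(K_donor, K_product, base0 = 5,
                                  phosphate0 = 0.5,
                                  r_grid = seq(0.5, 15, by = 0.5)) {
  stopifnot(all(r_grid > 0), !is.unsorted(r_grid, strictly = TRUE))
  yields <- vapply(r_grid, function(r) {
    sys <- transglycosylation_system(K_donor, K_product,
                                     donor0 = r * base0, base0 = base0,
                                     phosphate0 = phosphate0)
    yield_from_state(solve_transglycosylation_equilibrium(sys), base0)
  }, numeric(1))
  data.frame(r = r_grid, donor0_mM = r_grid * base0, yield = yields)
}

#' Equilibrium yield as a function of phosphate loading
#'
#' Phosphate is a substrate of the forward donor phosphorolysis but also of
#' the back-reaction that cleaves the product, so equilibrium yield decreases
#' monotonically as phosphate rises; loadings above about 0.3 equivalents of
#' the base visibly depress the yield.
#'
#' @param K_donor,K_product Equilibrium constants.
#' @param donor0,base0 Fixed composition (mM).
#' @param phosphate_grid Positive phosphate concentrations (mM).
#' @return Data frame with columns `phosphate0_mM`, `phosphate_equivalents`
#'   (relative to base0) and `yield`.
#' @export
yield_vs_phosphate_curve <- function(K_donor, K_product, donor0 = 25,
                                     base0 = 5,
                                     phosphate_grid = seq(0.1, 5, by = 0.1)) {
  stopifnot(all(phosphate_grid > 0))
  yields <- vapply(phosphate_grid, function(p0) {
    sys <- transglycosylation_system(K_donor, K_product, donor0 = donor0,
                                     base0 = base0, phosphate0 = p0)
    yield_from_state(solve_transglycosylation_equilibrium(sys), base0)
  }, numeric(1))
  data.frame(phosphate0_mM = phosphate_grid,
             phosphate_equivalents = phosphate_grid / base0,
             yield = yields)
}
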