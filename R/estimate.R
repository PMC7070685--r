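#' Record an observed equilibrium conversion
#'
#' Bundles the known part of an analytical-scale transglycosylation reaction
#' (donor constant and initial composition) with the conversion measured once
#' the reaction has reached its equilibrium plateau.  Conversions may be given
#' as fractions in (0, 1) or as percentages in (1, 100); percentages are
#' normalised.
#'
#' @param K_donor Phosphorolysis equilibrium constant of the sugar donor.
#' @param donor0,base0,phosphate0 Initial concentrations (mM).
#' @param observed_conversion Equilibrium conversion, fraction or percent.
#' @param donor_id Optional label.
#' @return An object of class `equilibrium_observation`.
#' @export
equilibrium_observation <- function(K_donor, donor0, base0, phosphate0,
                                    observed_conversion,
                                    donor_id = "donor") {
  stopifnot(K_donor > 0, donor0 > 0, base0 > 0, phosphate0 > 0)
  conv <- observed_conversion
  if (!is.numeric(conv) || length(conv) != 1L || !is.finite(conv))
    stop("'observed_conversion' must be a single finite number", call. = FALSE)
  if (conv >= 100)
    stop("conversion must be below 100%", call. = FALSE)
  if (conv > 1) conv <- conv / 100            # percent supplied
  if (conv <= 0)
    stop("conversion must be positive (K undefined at zero conversion)",
         call. = FALSE)
  if (conv >= 1)
    stop("conversion must be below 1", call. = FALSE)
  if (conv * base0 >= donor0)
    stop("infeasible observation: more pentose transferred than supplied",
         call. = FALSE)
  structure(list(donor_id = donor_id, K_donor = K_donor, donor0 = donor0,
                 base0 = base0, phosphate0 = phosphate0,
                 observed_conversion = conv),
            class = "equilibrium_observation")
}

#' Estimate a product nucleoside's phosphorolysis equilibrium constant
#'
#' Inverts the coupled equilibrium model: given the donor constant K1 and an
#' observed equilibrium conversion, the product concentration is
#' x = conversion * base0, the pentose-1-phosphate concentration y is the
#' unique positive root of the donor mass-action quadratic
#' \deqn{(1-K_1)y^2 + [x + K_1(P_0 + d_0 - x)]y - K_1 (d_0 - x) P_0 = 0,}
#' and the product constant follows from its own mass-action quotient
#' \deqn{K_2 = \frac{(b_0-x)\,y}{x\,(P_0-y)}.}
#' Feeding the estimate back into [solve_transglycosylation_equilibrium()]
#' reproduces the observed conversion (the estimator is the exact inverse of
#' the forward solve).
#'
#' @param obs An [equilibrium_observation()].
#' @param boot_sd Optional standard deviation of the observed conversion; if
#'   supplied with `boot_n > 0`, a Gaussian bootstrap over the conversion is
#'   run and quantiles attached as the `"boot"` attribute.  Defaults off: the
#'   point estimate is returned as observed.
#' @param boot_n Number of bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return Estimated K_product (dimensionless).
#' @examples
#' obs <- equilibrium_observation(K_donor = 0.125, donor0 = 5, base0 = 5,
#'                                phosphate0 = 2, observed_conversion = 0.55)
#' estimate_product_K(obs)   # ~ 0.0732
#' @export
estimate_product_K <- function(obs, boot_sd = NULL, boot_n = 0L,
                               seed = NULL) {
  stopifnot(inherits(obs, "equilibrium_observation"))
  K <- .estimate_K_point(obs$K_donor, obs$donor0, obs$base0, obs$phosphate0,
                         obs$observed_conversion)
  if (!is.null(boot_sd) && boot_n > 0L) {
    if (!is.null(seed)) set.seed(seed)
    draws <- stats::rnorm(boot_n, obs$observed_conversion, boot_sd)
    draws <- draws[draws > 0 & draws < 1 & draws * obs$base0 < obs$donor0]
    ks <- vapply(draws, function(cv)
      .estimate_K_point(obs$K_donor, obs$donor0, obs$base0, obs$phosphate0,
                        cv), numeric(1))
    attr(K, "boot") <- stats::quantile(ks, c(0.025, 0.5, 0.975))
  }
  K
}

.estimate_K_point <- function(K_donor, donor0, base0, phosphate0,
                              conversion) {
  x <- conversion * base0
  d <- donor0 - x
  # (1-K1) y^2 + (x + K1 (P0 + d)) y - K1 d P0 = 0
  a <- 1 - K_donor
  b <- x + K_donor * (phosphate0 + d)
  cc <- -K_donor * d * phosphate0
  if (abs(a) < .Machine$double.eps) {
    y <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    roots <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
    pos <- roots[roots > 0]
    if (length(pos) == 0L)
      stop("no positive root for pentose-1-phosphate: infeasible observation",
           call. = FALSE)
    y <- min(pos)
  }
  if (y >= phosphate0)
    stop("infeasible observation: implied pentose-1-phosphate exceeds ",
         "available phosphate", call. = FALSE)
  if (y >= donor0 - x)
    stop("infeasible observation: implied pentose-1-phosphate exceeds ",
         "remaining donor pool", call. = FALSE)
  (base0 - x) * y / (x * (phosphate0 - y))
}

#' Estimate K_product for a table of observations read from CSV
#'
#' Input columns: `donor_id`, `K_donor`, `donor0`, `base0`, `phosphate0`,
#' `observed_conversion` (fraction or percent).  The output adds a
#' `K_product` column.
#'
#' @param path Input CSV path.
#' @param out Optional output CSV path.
#' @return Data frame with the estimated constants.
#' @export
estimate_product_K_csv <- function(path, out = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("K_donor", "donor0", "base0", "phosphate0", "observed_conversion")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df$K_product <- vapply(seq_len(nrow(df)), function(i) {
    obs <- equilibrium_observation(
      K_donor = df$K_donor[i], donor0 = df$donor0[i], base0 = df$base0[i],
      phosphate0 = df$phosphate0[i],
      observed_conversion = df$observed_conversion[i],
      donor_id = if ("donor_id" %in% names(df)) df$donor_id[i] else "donor")
    estimate_product_K(obs)
  }, numeric(1))
  if (!is.null(out)) utils::write.csv(df, out, row.names = FALSE)
  df
}
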