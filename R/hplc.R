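#' Fit a linear peak-area calibration curve
#'
#' Ordinary least squares of peak area on concentration, matching a six-step
#' serial-dilution calibration over 0 to 1 mM.  The fit includes an intercept;
#' for clean instruments the intercept is near zero and the inverse mapping
#' clips negative concentrations to zero.
#'
#' @param levels Data frame or matrix with columns `conc_mM` and `area`
#'   (a two-column unnamed object is accepted in that order).
#' @param analyte_id Label stored with the curve.
#' @return An object of class `calibration_curve` with fields `analyte_id`,
#'   `slope` (area per mM), `intercept` (area), `n_levels`, `r_squared`.
#' @examples
#' lv <- data.frame(conc_mM = seq(0, 1, by = 0.2),
#'                  area = 1000 * seq(0, 1, by = 0.2))
#' fit_calibration(lv, "1b")
#' @export
fit_calibration <- function(levels, analyte_id = "analyte") {
  levels <- as.data.frame(levels)
  if (!all(c("conc_mM", "area") %in% names(levels))) {
    if (ncol(levels) < 2L)
      stop("'levels' needs columns conc_mM and area", call. = FALSE)
    names(levels)[1:2] <- c("conc_mM", "area")
  }
  if (nrow(levels) < 2L || length(unique(levels$conc_mM)) < 2L)
    stop("calibration needs at least two distinct concentration levels",
         call. = FALSE)
  if (any(levels$conc_mM < 0 - 1e-12) || any(levels$conc_mM > 1 + 1e-12))
    warning("calibration levels outside the validated 0-1 mM range")
  fit <- stats::lm(area ~ conc_mM, data = levels)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("singular or non-positive calibration slope", call. = FALSE)
  ss_tot <- sum((levels$area - mean(levels$area))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(analyte_id = analyte_id, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 n_levels = nrow(levels),
                 r_squared = min(max(r2, 0), 1)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration [%s]: area = %.4g * conc_mM + %.4g (n = %d, r2 = %.4f)\n",
              x$analyte_id, x$slope, x$intercept, x$n_levels, x$r_squared))
  invisible(x)
}

#' Map concentrations to peak areas through a calibration curve
#' @param curve A `calibration_curve`.
#' @param conc_mM Concentrations (mM).
#' @return Peak areas (arbitrary units).
#' @export
area_from_conc <- function(curve, conc_mM) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$slope * conc_mM + curve$intercept
}

#' Map peak areas back to concentrations (inverse calibration)
#'
#' Negative back-calculated concentrations (possible with a positive
#' intercept and baseline noise) are clipped to zero.
#'
#' @param curve A `calibration_curve`.
#' @param area Peak areas.
#' @return Concentrations (mM), >= 0.
#' @export
conc_from_area <- function(curve, area) {
  stopifnot(inherits(curve, "calibration_curve"))
  pmax((area - curve$intercept) / curve$slope, 0)
}

#' Construct a peak table
#'
#' @param rt_min Retention times (min, > 0).
#' @param area Peak areas (>= 0).
#' @param time_h Optional sampling times.
#' @param analyte Optional pre-existing assignments (NA = unassigned).
#' @return Data frame of class `peak_table`.
#' @export
peak_table <- function(rt_min, area, time_h = NA_real_,
                       analyte = NA_character_) {
  stopifnot(all(rt_min > 0), all(area >= 0))
  structure(data.frame(time_h = time_h, rt_min = rt_min, area = area,
                       analyte = analyte, stringsAsFactors = FALSE),
            class = c("peak_table", "data.frame"))
}

#' Assign chromatogram peaks to analytes by retention time
#'
#' Each expected analyte is matched to its closest peak within `tol` minutes;
#' matching is greedy on distance so that when two analytes compete for one
#' peak the closer one wins and each peak serves at most one analyte.  The
#' expected set must be restricted to the species actually present in the
#' reaction: species from different reactions can share a retention time
#' (e.g. two product nucleosides both at 8.2 min), and supplying two expected
#' analytes closer than `2 * tol` raises an ambiguity error.
#'
#' @param table A [peak_table()] (or data frame with `rt_min`, `area`).
#' @param expected Named numeric vector: analyte id -> expected retention
#'   time (min).  See [retention_times()] for the shipped defaults.
#' @param tol Match tolerance in minutes (default 0.2).
#' @return The table with the `analyte` column filled where matched.
#' @export
assign_peaks <- function(table, expected, tol = 0.2) {
  stopifnot(is.numeric(expected), !is.null(names(expected)), tol > 0)
  table <- as.data.frame(table)
  if (!"analyte" %in% names(table)) table$analyte <- NA_character_
  # ambiguity: two expected species too close to separate at this tolerance
  if (length(expected) > 1L) {
    d <- abs(outer(expected, expected, "-"))
    diag(d) <- Inf
    if (any(d < 2 * tol)) {
      idx <- which(d < 2 * tol, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "ambiguous expected retention times: '%s' (%.2f min) and '%s' (%.2f min) are within 2*tol; restrict 'expected' to the species of one reaction",
        names(expected)[idx[1]], expected[idx[1]],
        names(expected)[idx[2]], expected[idx[2]]), call. = FALSE)
    }
  }
  table$analyte <- NA_character_
  dist <- abs(outer(expected, table$rt_min, "-"))   # analytes x peaks
  while (any(is.finite(dist)) && min(dist) <= tol) {
    hit <- which(dist == min(dist), arr.ind = TRUE)[1, ]
    table$analyte[hit[2]] <- names(expected)[hit[1]]
    dist[hit[1], ] <- Inf
    dist[, hit[2]] <- Inf
  }
  table
}

#' Shipped retention times for the compound panel
#'
#' Typical retention times (min) on the reversed-phase method used for
#' reaction monitoring.  Note the product ribosides of the two dihalogenated
#' bases co-elute at 8.2 min with each other's panel, which is why
#' [assign_peaks()] expects a per-reaction species subset.
#'
#' @param ids Optional subset of compound ids.
#' @return Named numeric vector of retention times (min).
#' @export
retention_times <- function(ids = NULL) {
  rt <- c(`1a` = 3.2, `4a` = 2.4, `1b` = 4.7, `4b` = 4.0,
          `2a` = 7.6, `2b` = 7.0,
          `3a` = 8.2, `3b` = 8.8, `3c` = 7.5, `3d` = 8.2)
  if (is.null(ids)) return(rt)
  miss <- setdiff(ids, names(rt))
  if (length(miss))
    stop("unknown compound ids: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rt[ids]
}

#' Conversion from product and substrate concentrations
#'
#' Percent conversion on a molar basis,
#' \deqn{\mathrm{Conversion\ \%} = 100 \times
#'   \frac{[\mathrm{product}]}{[\mathrm{product}] + [\mathrm{substrate}]}.}
#'
#' @param product_conc,substrate_conc Concentrations (mM, >= 0, not both 0).
#' @return Conversion in percent. Vectorised.
#' @export
conversion_percent <- function(product_conc, substrate_conc) {
  if (any(product_conc < 0) || any(substrate_conc < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  tot <- product_conc + substrate_conc
  if (any(tot == 0))
    stop("conversion undefined: product and substrate both zero",
         call. = FALSE)
  100 * product_conc / tot
}

#' Correct a measured concentration for quench and dilution
#'
#' Samples are quenched with an equal volume of methanol (factor 2) and the
#' supernatant diluted 1:10 (factor 10) before injection, so the default
#' reactor-to-vial factor is 20.
#'
#' @param measured Concentration measured in the vial (mM).
#' @param quench_factor Volume factor of the quench step (>= 1, default 2).
#' @param dilution_factor Subsequent dilution factor (>= 1, default 10).
#' @return Concentration in the reactor (mM).
#' @export
correct_dilution <- function(measured, quench_factor = 2,
                             dilution_factor = 10) {
  if (quench_factor < 1 || dilution_factor < 1)
    stop("dilution factors must be >= 1", call. = FALSE)
  if (any(measured < 0))
    stop("measured concentration must be non-negative", call. = FALSE)
  measured * quench_factor * dilution_factor
}

#' Detect the equilibrium plateau of a conversion time course
#'
#' The experimental criterion for "equilibrium reached" is operational: the
#' plateau starts at the earliest sample after which every successive
#' relative change in conversion stays within `rel_tol` (default 2%).  The
#' plateau conversion is the mean over the plateau samples.  Fast
#' (deoxyriboside) reactions plateau within about an hour; slow (riboside)
#' ones only after several hours.
#'
#' @param tc A [time_course()] containing product and substrate analytes, or
#'   a data frame with columns `time_h` and `conversion`.
#' @param product_id,substrate_id Analyte ids used to compute the conversion
#'   when `tc` is a time course of concentrations.
#' @param rel_tol Maximum relative change between consecutive plateau samples.
#' @return A list: `reached` (logical), `time_reached` (h; NA when not
#'   reached), `plateau_conversion` (percent; last value when not reached).
#' @export
detect_plateau <- function(tc, product_id = NULL, substrate_id = NULL,
                           rel_tol = 0.02) {
  if (all(c("time_h", "conversion") %in% names(tc))) {
    times <- tc$time_h
    conv <- tc$conversion
  } else {
    stopifnot(inherits(tc, "time_course") ||
                all(c("time_h", "analyte", "conc_mM") %in% names(tc)))
    if (is.null(product_id) || is.null(substrate_id))
      stop("supply 'product_id' and 'substrate_id' for a concentration ",
           "time course", call. = FALSE)
    p <- tc[tc$analyte == product_id, ]
    s <- tc[tc$analyte == substrate_id, ]
    times <- sort(intersect(p$time_h, s$time_h))   # both species observed
    conv <- vapply(times, function(t) {
      conversion_percent(p$conc_mM[p$time_h == t][1],
                         s$conc_mM[s$time_h == t][1])
    }, numeric(1))
  }
  if (length(times) < 3L)
    stop("plateau detection needs at least 3 time points", call. = FALSE)
  if (is.unsorted(times))
    stop("time points must be non-decreasing", call. = FALSE)
  relchg <- abs(diff(conv)) / pmax(abs(conv[-length(conv)]),
                                   .Machine$double.eps)
  # earliest index i such that all changes from i onwards are small
  ok_from <- rev(cumprod(rev(relchg <= rel_tol))) == 1
  if (!any(ok_from))
    return(list(reached = FALSE, time_reached = NA_real_,
                plateau_conversion = conv[length(conv)]))
  i <- which(ok_from)[1]
  list(reached = TRUE, time_reached = times[i],
       plateau_conversion = mean(conv[i:length(conv)]))
}

#' Construct a concentration time course
#'
#' @param time_h Sampling times (h, non-decreasing per analyte).
#' @param analyte Analyte ids.
#' @param conc_mM Concentrations (mM, >= 0).
#' @param reaction_id,dilution_factor Metadata attributes.
#' @return Data frame of class `time_course`.
#' @export
time_course <- function(time_h, analyte, conc_mM, reaction_id = NA_character_,
                        dilution_factor = 1) {
  stopifnot(all(conc_mM >= -1e-12))
  df <- data.frame(time_h = time_h, analyte = analyte,
                   conc_mM = pmax(conc_mM, 0), stringsAsFactors = FALSE)
  for (a in unique(df$analyte)) {
    if (is.unsorted(df$time_h[df$analyte == a]))
      stop("times must be non-decreasing within each analyte", call. = FALSE)
  }
  structure(df, class = c("time_course", "data.frame"),
            reaction_id = reaction_id, dilution_factor = dilution_factor)
}

#' Read and write the CSV dialects used for HPLC-style data
#'
#' Time courses use columns `time_h`, `analyte`, `conc_mM`; peak tables use
#' `time_h`, `rt_min`, `area` (plus `analyte` once assigned); calibrations
#' use `conc_mM`, `area`.
#'
#' @param path CSV path.
#' @param x Object to write.
#' @return The object read, or (for writers) `x` invisibly.
#' @name hplc_io
NULL

#' @rdname hplc_io
#' @export
read_time_course <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  time_course(df$time_h, df$analyte, df$conc_mM)
}

#' @rdname hplc_io
#' @export
write_time_course <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(x)
}

#' @rdname hplc_io
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  pt <- peak_table(df$rt_min, df$area,
                   time_h = if ("time_h" %in% names(df)) df$time_h else NA_real_)
  if ("analyte" %in% names(df)) pt$analyte <- df$analyte
  pt
}

#' @rdname hplc_io
#' @export
write_peak_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(x)
}
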