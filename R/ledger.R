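## IUPAC 2021 standard atomic weights (conventional values), g/mol
.atomic_weights <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     F = 18.998, P = 30.974, S = 32.06, Cl = 35.45,
                     Br = 79.904, I = 126.904)

#' Molar mass from a molecular formula
#'
#' Parses a Hill-style formula such as `"C10H14N2O5"` and sums conventional
#' atomic weights.  Only elements common in nucleoside chemistry are known.
#'
#' @param formula Molecular formula string.
#' @return Molar mass in g/mol.
#' @examples
#' molar_mass_from_formula("C10H14N2O5")  # thymidine, 242.23
#' @export
molar_mass_from_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula))
    stop("cannot parse formula: ", formula, call. = FALSE)
  total <- 0
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.atomic_weights))
      stop("unknown element '", el, "' in formula ", formula, call. = FALSE)
    total <- total + .atomic_weights[[el]] * n
  }
  total
}

#' Compound panel of the transglycosylation workflow
#'
#' The shipped table covers the sugar donors uridine (1a) and thymidine (1b),
#' the dihalogenated purine acceptor bases 2,6-dichloropurine (2a) and
#' 6-chloro-2-fluoropurine (2b), the four product nucleosides (3a riboside
#' and 3b 2'-deoxyriboside of 2a; 3c riboside and 3d 2'-deoxyriboside of 2b)
#' and the liberated pyrimidine bases uracil (4a) and thymine (4b).  Molar
#' masses are computed from the molecular formulas.
#'
#' @param extra Optional data frame with columns `id`, `formula`, `role` to
#'   append user compounds.
#' @return Data frame with columns `id`, `name`, `formula`, `role`,
#'   `molar_mass` (g/mol).
#' @export
compound_table <- function(extra = NULL) {
  tab <- data.frame(
    id = c("1a", "1b", "2a", "2b", "3a", "3b", "3c", "3d", "4a", "4b"),
    name = c("uridine", "thymidine",
             "2,6-dichloropurine", "6-chloro-2-fluoropurine",
             "2,6-dichloropurine riboside",
             "2,6-dichloropurine 2'-deoxyriboside",
             "6-chloro-2-fluoropurine riboside",
             "6-chloro-2-fluoropurine 2'-deoxyriboside",
             "uracil", "thymine"),
    formula = c("C9H12N2O6", "C10H14N2O5",
                "C5H2Cl2N4", "C5H2ClFN4",
                "C10H10Cl2N4O4", "C10H10Cl2N4O3",
                "C10H10ClFN4O4", "C10H10ClFN4O3",
                "C4H4N2O2", "C5H6N2O2"),
    role = c("donor", "donor", "base", "base",
             "product", "product", "product", "product",
             "byproduct", "byproduct"),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(all(c("id", "formula", "role") %in% names(extra)))
    extra$name <- if ("name" %in% names(extra)) extra$name else extra$id
    tab <- rbind(tab, extra[, c("id", "name", "formula", "role")])
  }
  tab$molar_mass <- vapply(tab$formula, molar_mass_from_formula, numeric(1))
  tab
}

.lookup_molar_mass <- function(compound, compounds = compound_table()) {
  if (is.numeric(compound)) return(compound)
  i <- match(compound, compounds$id)
  if (is.na(i)) stop("unknown compound id: ", compound, call. = FALSE)
  compounds$molar_mass[i]
}

#' Convert a weighed mass to a reactor concentration
#'
#' `mM = mass_mg / molar_mass / volume_mL * 1000`; e.g. 369 mg thymidine in
#' 50 mL gives 30.5 mM.
#'
#' @param mass_mg Mass (mg, >= 0).
#' @param compound Compound id from [compound_table()], or a molar mass in
#'   g/mol directly.
#' @param volume_mL Reaction volume (mL, > 0).
#' @return Concentration in mM.
#' @export
mass_to_millimolar <- function(mass_mg, compound, volume_mL) {
  if (any(mass_mg < 0)) stop("mass must be non-negative", call. = FALSE)
  if (any(volume_mL <= 0)) stop("volume must be positive", call. = FALSE)
  mm <- .lookup_molar_mass(compound)
  mass_mg / mm / volume_mL * 1000
}

#' @rdname mass_to_millimolar
#' @param conc_mM Concentration (mM).
#' @export
millimolar_to_mass <- function(conc_mM, compound, volume_mL) {
  if (any(conc_mM < 0)) stop("concentration must be non-negative",
                             call. = FALSE)
  if (any(volume_mL <= 0)) stop("volume must be positive", call. = FALSE)
  mm <- .lookup_molar_mass(compound)
  conc_mM * mm * volume_mL / 1000
}

#' Build a preparative process ledger
#'
#' An ordered record of mass in and mass out of each work-up step
#' (synthesis, protein removal + HPLC purification, freeze drying, ...) for
#' one tracked compound.
#'
#' @param compound Compound id.
#' @param step Step names, in process order.
#' @param amount_in_mg,amount_out_mg Masses entering and leaving each step
#'   (mg); out must not exceed in.
#' @param volume_mL Optional reaction volume.
#' @return Data frame of class `process_ledger`.
#' @export
process_ledger <- function(compound, step, amount_in_mg, amount_out_mg,
                           volume_mL = NA_real_) {
  stopifnot(length(step) == length(amount_in_mg),
            length(step) == length(amount_out_mg))
  if (any(amount_in_mg < 0) || any(amount_out_mg < 0))
    stop("amounts must be non-negative", call. = FALSE)
  if (any(amount_out_mg > amount_in_mg + 1e-9))
    stop("amount out exceeds amount in for step(s): ",
         paste(step[amount_out_mg > amount_in_mg + 1e-9], collapse = ", "),
         call. = FALSE)
  structure(data.frame(compound = compound, step = step,
                       amount_in_mg = amount_in_mg,
                       amount_out_mg = amount_out_mg,
                       stringsAsFactors = FALSE),
            class = c("process_ledger", "data.frame"),
            volume_mL = volume_mL)
}

#' Percent loss of a single process step
#'
#' @param amount_in_mg,amount_out_mg Masses before and after the step (mg).
#' @return Loss in percent of the input. Vectorised.
#' @export
step_loss_percent <- function(amount_in_mg, amount_out_mg) {
  if (any(amount_in_mg <= 0))
    stop("step loss undefined for zero input", call. = FALSE)
  100 * (amount_in_mg - amount_out_mg) / amount_in_mg
}

#' Overall recovery across a process ledger
#'
#' Recovery of the tracked compound as final output over the initial basis.
#' By default the basis is the first step's input; for donor recapture the
#' basis is the initially charged donor mass (the same thing when the ledger
#' starts at the synthesis charge).  195 mg recovered from a 369 mg charge
#' is 53% (nearest integer).
#'
#' @param ledger A [process_ledger()].
#' @param basis_mg Optional explicit basis mass (mg).
#' @return Recovery in percent (full precision; round for presentation).
#' @export
overall_recovery_percent <- function(ledger, basis_mg = NULL) {
  stopifnot(inherits(ledger, "process_ledger"))
  if (nrow(ledger) == 0L) stop("empty ledger", call. = FALSE)
  basis <- if (is.null(basis_mg)) ledger$amount_in_mg[1] else basis_mg
  if (basis <= 0) stop("recovery undefined for zero basis", call. = FALSE)
  100 * ledger$amount_out_mg[nrow(ledger)] / basis
}

#' Per-step loss report for a ledger
#'
#' @param ledger A [process_ledger()].
#' @return Data frame with per-step loss percentages and the overall
#'   recovery, mirroring an appendix-style loss summary.
#' @export
ledger_report <- function(ledger) {
  stopifnot(inherits(ledger, "process_ledger"))
  data.frame(compound = ledger$compound, step = ledger$step,
             amount_in_mg = ledger$amount_in_mg,
             amount_out_mg = ledger$amount_out_mg,
             loss_percent = step_loss_percent(ledger$amount_in_mg,
                                              ledger$amount_out_mg),
             cumulative_recovery_percent =
               100 * ledger$amount_out_mg / ledger$amount_in_mg[1],
             stringsAsFactors = FALSE)
}

#' @rdname hplc_io
#' @export
read_ledger <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  process_ledger(df$compound, df$step, df$amount_in_mg, df$amount_out_mg)
}

#' @rdname hplc_io
#' @export
write_ledger <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(x)
}
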