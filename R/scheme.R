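#' Build a capture/release kinetic scheme
#'
#' Constructs the continuous-time Markov scheme that describes gating of a
#' monobody-nanopore sensor between the analyte-released open substate
#' (`O_on`) and one or two analyte-captured substates (`O_off`). Association
#' rate constants (released to captured) scale with analyte concentration and
#' carry units of M^-1 s^-1; dissociation and interconversion rate constants
#' are first order (s^-1).
#'
#' Three presets are available:
#' \describe{
#'   \item{`bimolecular`}{two states `O_on`, `O_off`; rates `k_on`, `k_off`.}
#'   \item{`two_mode`}{three states `O_on`, `O_off1`, `O_off2` with
#'     independent capture substates; rates `k_on1`, `k_on2`, `k_off1`,
#'     `k_off2` (`k_12 = k_21 = 0`).}
#'   \item{`interconversion`}{as `two_mode` plus direct transitions between
#'     the captured substates, `k_12` and `k_21` (s^-1).}
#' }
#'
#' @param preset one of `"bimolecular"`, `"two_mode"`, `"interconversion"`.
#' @param rates named numeric vector of rate constants for the preset (see
#'   Details). All must be finite and non-negative.
#' @param levels named numeric vector of per-state current levels in pA under
#'   the applied potential, one per state (`O_on`, `O_off`/`O_off1`,
#'   `O_off2`). The released level must exceed every captured level
#'   (positive-current convention: blockades deflect toward 0).
#'
#' @return An object of class `kinetic_scheme`: a list with `states`
#'   (tibble: `name`, `class`, `level_pA`) and `rates` (tibble: `from`, `to`,
#'   `rate`, `concentration_scaled`).
#'
#' @examples
#' # hSUMO1-like sensor kinetics
#' sch <- kinetic_scheme("bimolecular",
#'                       rates  = c(k_on = 1.12e8, k_off = 74.5),
#'                       levels = c(O_on = 32.1, O_off = 2.9))
#' generator_matrix(sch, concentration = 260e-9)
#' @export
kinetic_scheme <- function(preset = c("bimolecular", "two_mode", "interconversion"),
                           rates, levels = NULL) {
  preset <- match.arg(preset)
  spec <- scheme_preset_spec(preset)
  missing_rates <- setdiff(spec$rate_names, names(rates))
  if (length(missing_rates) > 0) {
    stop("missing rate constant(s) for preset '", preset, "': ",
         paste(missing_rates, collapse = ", "), call. = FALSE)
  }
  rates <- rates[spec$rate_names]
  if (any(!is.finite(rates))) {
    stop("all rate constants must be finite", call. = FALSE)
  }
  if (any(rates < 0)) {
    stop("rate constants must be non-negative; got ",
         paste(spec$rate_names[rates < 0], collapse = ", "), " < 0",
         call. = FALSE)
  }
  if (is.null(levels)) levels <- spec$default_levels
  missing_lv <- setdiff(spec$state_names, names(levels))
  if (length(missing_lv) > 0) {
    stop("missing current level(s) for state(s): ",
         paste(missing_lv, collapse = ", "), call. = FALSE)
  }
  levels <- levels[spec$state_names]
  released_lv <- levels[spec$state_class == "released"]
  if (any(levels[spec$state_class == "captured"] >= released_lv)) {
    stop("captured-state current levels must lie below the released (open) level",
         call. = FALSE)
  }
  states <- tibble::tibble(
    name = spec$state_names,
    class = spec$state_class,
    level_pA = unname(levels)
  )
  rate_tbl <- tibble::tibble(
    from = spec$rate_from,
    to = spec$rate_to,
    rate = unname(rates),
    concentration_scaled = spec$rate_scaled
  )
  structure(list(preset = preset, states = states, rates = rate_tbl),
            class = "kinetic_scheme")
}

# preset wiring: state names/classes and the rate edges each preset requires
scheme_preset_spec <- function(preset) {
  switch(preset,
    bimolecular = list(
      state_names = c("O_on", "O_off"),
      state_class = c("released", "captured"),
      rate_names = c("k_on", "k_off"),
      rate_from = c("O_on", "O_off"),
      rate_to = c("O_off", "O_on"),
      rate_scaled = c(TRUE, FALSE),
      default_levels = c(O_on = 32.1, O_off = 2.9)
    ),
    two_mode = list(
      state_names = c("O_on", "O_off1", "O_off2"),
      state_class = c("released", "captured", "captured"),
      rate_names = c("k_on1", "k_on2", "k_off1", "k_off2"),
      rate_from = c("O_on", "O_on", "O_off1", "O_off2"),
      rate_to = c("O_off1", "O_off2", "O_on", "O_on"),
      rate_scaled = c(TRUE, TRUE, FALSE, FALSE),
      default_levels = c(O_on = 18.2, O_off1 = 6.4, O_off2 = 2.3)
    ),
    interconversion = list(
      state_names = c("O_on", "O_off1", "O_off2"),
      state_class = c("released", "captured", "captured"),
      rate_names = c("k_on1", "k_on2", "k_off1", "k_off2", "k_12", "k_21"),
      rate_from = c("O_on", "O_on", "O_off1", "O_off2", "O_off1", "O_off2"),
      rate_to = c("O_off1", "O_off2", "O_on", "O_on", "O_off2", "O_off1"),
      rate_scaled = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
      default_levels = c(O_on = 18.2, O_off1 = 6.4, O_off2 = 2.3)
    ),
    stop("unknown preset: ", preset, call. = FALSE)
  )
}

#' Generator (rate) matrix of a kinetic scheme at a given concentration
#'
#' Assembles the infinitesimal generator Q of the scheme's continuous-time
#' Markov chain. Concentration-scaled entries (association pathways) are
#' multiplied by the analyte concentration; rows sum to zero.
#'
#' @param scheme a [kinetic_scheme()].
#' @param concentration analyte concentration in mol/L (>= 0).
#' @return square numeric matrix (s^-1) with state names as dimnames.
#' @export
generator_matrix <- function(scheme, concentration) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!is.finite(concentration) || concentration < 0) {
    stop("concentration must be finite and >= 0", call. = FALSE)
  }
  nm <- scheme$states$name
  q <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  eff <- scheme$rates$rate *
    ifelse(scheme$rates$concentration_scaled, concentration, 1)
  q[cbind(match(scheme$rates$from, nm), match(scheme$rates$to, nm))] <- eff
  diag(q) <- -rowSums(q)
  q
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme> preset:", x$preset, "\n")
  cat("States:\n")
  print(as.data.frame(x$states), row.names = FALSE)
  cat("Rates (concentration-scaled rates in M^-1 s^-1, others s^-1):\n")
  print(as.data.frame(x$rates), row.names = FALSE)
  invisible(x)
}

# indices of released / captured states
scheme_class_index <- function(scheme, cls) {
  which(scheme$states$class == cls)
}
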