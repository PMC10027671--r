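# reference schemes at the sensors' published rate magnitudes, reused across
# tests as generator truth

hsumo_scheme <- function() {
  kinetic_scheme("bimolecular",
                 rates = c(k_on = 1.12e8, k_off = 74.5),
                 levels = c(O_on = 32.1, O_off = 2.9))
}

egfr_scheme <- function() {
  kinetic_scheme("two_mode",
                 rates = c(k_on1 = 6.62e7, k_on2 = 2.89e7,
                           k_off1 = 12.0, k_off2 = 1.01),
                 levels = c(O_on = 18.2, O_off1 = 6.4, O_off2 = 2.3))
}

egfr_ic_scheme <- function(k12 = 20, k21 = 20) {
  kinetic_scheme("interconversion",
                 rates = c(k_on1 = 6.62e7, k_on2 = 2.89e7,
                           k_off1 = 12.0, k_off2 = 1.01,
                           k_12 = k12, k_21 = k21),
                 levels = c(O_on = 18.2, O_off1 = 6.4, O_off2 = 2.3))
}

# hand-built rectangular state path (released/captured alternation)
manual_path <- function(durations, states = NULL) {
  n <- length(durations)
  if (is.null(states)) {
    states <- rep(c("O_on", "O_off"), length.out = n)
  }
  tibble::tibble(
    state = states,
    class = ifelse(states == "O_on", "released", "captured"),
    start_s = cumsum(c(0, durations[-n])),
    duration_s = durations,
    censored = c(rep(FALSE, n - 1), TRUE)
  )
}
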