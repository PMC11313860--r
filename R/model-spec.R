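#' Specify a generalized telegraph model
#'
#' A telegraph model describes a gene switching stochastically between a small
#' number of states; the last state is the sole active ("ON") state, from
#' which mRNA molecules are ejected at rate `k_eject` and then decay at rate
#' `k_decay`. The classic two-state model has one OFF and one ON state; the
#' three-state variant adds a second OFF state in a serial chain
#' OFF1 <-> OFF2 <-> ON; the one-state model is a plain birth-death (Poisson)
#' process with no OFF state.
#'
#' @param n_states Number of gene states, 1, 2 or 3.
#' @param n_alleles Number of independent alleles contributing to the
#'   per-cell count (default 2, the typical diploid assumption).
#' @param yield Capture probability `p` in (0, 1]: the fraction of cellular
#'   mRNA observed by the protocol. Random capture thins counts binomially
#'   and, for any telegraph model, only rescales the eject rate (`nu -> p*nu`),
#'   so fitting never thins explicitly; `yield` is used for reporting and
#'   simulation.
#' @param topology For `n_states = 3`, either `"reversible"` (serial chain
#'   OFF1 <-> OFF2 <-> ON with four switching rates, the default) or
#'   `"cyclic"` (OFF1 -> OFF2 -> ON -> OFF1 with three rates).
#'
#' @return An object of class `telegraph_model`.
#' @examples
#' telegraph_model(2)
#' telegraph_model(3, n_alleles = 1)
#' @export
telegraph_model <- function(n_states = 2L, n_alleles = 2L, yield = 1,
                            topology = c("reversible", "cyclic")) {
  topology <- match.arg(topology)
  n_states <- as.integer(n_states)
  n_alleles <- as.integer(n_alleles)
  if (!n_states %in% 1:3) stop("`n_states` must be 1, 2 or 3", call. = FALSE)
  if (is.na(n_alleles) || n_alleles < 1L)
    stop("`n_alleles` must be a positive integer", call. = FALSE)
  if (!is.numeric(yield) || length(yield) != 1L || yield <= 0 || yield > 1)
    stop("`yield` must be in (0, 1]", call. = FALSE)
  structure(
    list(n_states = n_states, n_alleles = n_alleles, yield = yield,
         topology = topology),
    class = "telegraph_model"
  )
}

#' @export
print.telegraph_model <- function(x, ...) {
  lab <- switch(x$n_states, "one-state (birth-death)",
                "two-state telegraph", "three-state telegraph")
  cat(lab,
      if (x$n_states == 3L) sprintf("[%s]", x$topology) else "",
      sprintf("| alleles: %d | yield: %g\n", x$n_alleles, x$yield))
  invisible(x)
}

# number of free switching rates (ejection excluded)
n_switch_rates <- function(spec) {
  switch(spec$n_states, 0L, 2L,
         if (spec$topology == "cyclic") 3L else 4L)
}

# number of free rates overall (decay excluded): switching + eject
n_free_rates <- function(spec) n_switch_rates(spec) + 1L

switch_rate_names <- function(spec) {
  switch(spec$n_states,
         character(0),
         c("k_on", "k_off"),
         if (spec$topology == "cyclic") c("r12", "r23", "r31")
         else c("r12", "r21", "r23", "r32"))
}

#' Kinetic rates of a telegraph model
#'
#' Bundles the state-switching rates, the ejection (mRNA creation) rate and
#' the decay rate of one gene, all in events per minute. For the two-state
#' model pass `k_on` (OFF to ON) and `k_off` (ON to OFF); for the three-state
#' reversible chain pass `state_rates = c(r12, r21, r23, r32)` for
#' OFF1 <-> OFF2 <-> ON. Derived quantities: mean OFF time `1/k_on` (minutes),
#' burst size `k_eject / k_off` (mean mRNA made per ON period), and the
#' decay-scaled parameters `alpha = k_on/k_decay`, `beta = k_off/k_decay`,
#' `nu = k_eject/k_decay` of the Beta-Poisson representation.
#'
#' @param k_on,k_off Two-state switching rates in 1/min (ignored when
#'   `state_rates` is given).
#' @param k_eject mRNA creation rate in the active state, 1/min.
#' @param k_decay mRNA decay rate, 1/min (typically `log(2) / (half-life in
#'   minutes)` from an independent measurement).
#' @param state_rates Optional explicit vector of switching rates, ordered as
#'   documented above; use `numeric(0)` for the one-state model.
#'
#' @return An object of class `telegraph_rates`.
#' @examples
#' telegraph_rates(k_on = 0.01, k_off = 0.1, k_eject = 0.5, k_decay = 0.005)
#' @export
telegraph_rates <- function(k_on = NULL, k_off = NULL, k_eject, k_decay,
                            state_rates = NULL) {
  if (is.null(state_rates)) {
    state_rates <- c(k_on = k_on, k_off = k_off)
    if (is.null(state_rates)) state_rates <- numeric(0)
  }
  state_rates <- as.numeric(state_rates)
  if (any(!is.finite(state_rates)) || any(state_rates <= 0))
    stop("all switching rates must be strictly positive and finite",
         call. = FALSE)
  if (!is.finite(k_eject) || k_eject < 0)
    stop("`k_eject` must be finite and >= 0", call. = FALSE)
  if (!is.finite(k_decay) || k_decay <= 0)
    stop("`k_decay` must be strictly positive and finite", call. = FALSE)
  structure(
    list(state_rates = state_rates, k_eject = k_eject, k_decay = k_decay),
    class = "telegraph_rates"
  )
}

#' @export
print.telegraph_rates <- function(x, ...) {
  if (length(x$state_rates))
    cat("switching rates (1/min):",
        paste(signif(x$state_rates, 4), collapse = ", "), "\n")
  cat(sprintf("k_eject: %g 1/min | k_decay: %g 1/min\n", x$k_eject, x$k_decay))
  if (length(x$state_rates) == 2L)
    cat(sprintf("OFF time: %g min | burst size: %g\n",
                off_time(x), burst_size(x)))
  invisible(x)
}

check_rates <- function(spec, rates) {
  n_sw <- n_switch_rates(spec)
  if (length(rates$state_rates) != n_sw)
    stop(sprintf("model with %d state(s) [%s] needs %d switching rate(s), got %d",
                 spec$n_states, spec$topology, n_sw,
                 length(rates$state_rates)), call. = FALSE)
  invisible(TRUE)
}

#' Derived bursting quantities
#'
#' `off_time()` is the mean OFF duration `1/k_on` in minutes (two-state model);
#' `burst_size()` is `k_eject` divided by the rate of leaving the active state
#' (`k_off` for the two-state model, `r32` for the reversible three-state
#' chain): the mean number of mRNA produced per ON period.
#'
#' @param rates A [telegraph_rates()] object.
#' @return A single number; `NA` where the quantity is undefined (one-state
#'   model).
#' @export
off_time <- function(rates) {
  if (length(rates$state_rates) < 2L) return(NA_real_)
  1 / rates$state_rates[[1L]]
}

#' @rdname off_time
#' @export
burst_size <- function(rates) {
  n <- length(rates$state_rates)
  if (n == 0L) return(NA_real_)
  k_off <- if (n == 2L) rates$state_rates[[2L]] else rates$state_rates[[n]]
  rates$k_eject / k_off
}

# decay-scaled (dimensionless) parameters of the two-state model
scaled_params <- function(rates) {
  stopifnot(length(rates$state_rates) == 2L)
  list(alpha = rates$state_rates[[1L]] / rates$k_decay,
       beta = rates$state_rates[[2L]] / rates$k_decay,
       nu = rates$k_eject / rates$k_decay)
}

# S x S switching-rate matrix (row = from, col = to, diagonal zero)
switching_matrix <- function(spec, rates) {
  check_rates(spec, rates)
  S <- spec$n_states
  sw <- matrix(0, S, S)
  r <- rates$state_rates
  if (S == 2L) {
    sw[1, 2] <- r[[1L]]; sw[2, 1] <- r[[2L]]
  } else if (S == 3L) {
    if (spec$topology == "cyclic") {
      sw[1, 2] <- r[[1L]]; sw[2, 3] <- r[[2L]]; sw[3, 1] <- r[[3L]]
    } else {
      sw[1, 2] <- r[[1L]]; sw[2, 1] <- r[[2L]]
      sw[2, 3] <- r[[3L]]; sw[3, 2] <- r[[4L]]
    }
  }
  sw
}

# 0-based (from, to) index pairs of the free switching rates, for the C++ core
switching_index <- function(spec) {
  S <- spec$n_states
  if (S == 1L) return(list(from = integer(0), to = integer(0)))
  if (S == 2L) return(list(from = c(0L, 1L), to = c(1L, 0L)))
  if (spec$topology == "cyclic")
    return(list(from = c(0L, 1L, 2L), to = c(1L, 2L, 0L)))
  list(from = c(0L, 1L, 1L, 2L), to = c(1L, 0L, 2L, 1L))
}

# stationary distribution of the switching chain alone
switching_stationary <- function(spec, rates) {
  if (spec$n_states == 1L) return(1)
  switching_stationary_cpp(switching_matrix(spec, rates))
}
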