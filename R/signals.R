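#' Nutrient signal
#'
#' The three external signals sensed by the model: intracellular glutamine
#' (the nitrogen signal, inhibiting EI-Ntr autophosphorylation),
#' phosphoenolpyruvate (the phosphoryl donor of the PTS-Ntr) and pyruvate
#' (the phosphoryl acceptor of the reverse reaction). All in uM.
#'
#' @param Gln,PEP,Pyr Non-negative concentrations (uM).
#' @return A named list of class `"cdgpp_signal"`.
#' @examples
#' nutrient_signal(Gln = 10000, PEP = 300, Pyr = 1500)  # nutrient rich
#' @export
nutrient_signal <- function(Gln, PEP, Pyr) {
  vals <- c(Gln = Gln, PEP = PEP, Pyr = Pyr)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("Gln, PEP and Pyr must be finite and non-negative")
  structure(list(Gln = Gln, PEP = PEP, Pyr = Pyr), class = "cdgpp_signal")
}

as_signal <- function(x) {
  if (inherits(x, "cdgpp_signal")) return(x)
  if (is.numeric(x) && length(x) == 3L && !is.null(names(x)) &&
      all(c("Gln", "PEP", "Pyr") %in% names(x)))
    return(nutrient_signal(x[["Gln"]], x[["PEP"]], x[["Pyr"]]))
  if (is.list(x) && all(c("Gln", "PEP", "Pyr") %in% names(x)))
    return(nutrient_signal(x$Gln, x$PEP, x$Pyr))
  stop("cannot interpret object as a nutrient signal")
}

#' Piecewise-constant signal schedule
#'
#' A schedule of nutrient signals, each taking effect at a start time. The
#' integrator restarts at every breakpoint so the discontinuity is honoured
#' exactly rather than smoothed over.
#'
#' @param times Numeric vector of segment start times (min); the first must
#'   be 0 and the rest strictly increasing.
#' @param signals A list of [nutrient_signal()] objects, one per start time.
#' @return An object of class `"cdgpp_schedule"`.
#' @examples
#' signal_schedule(
#'   times = c(0, 600),
#'   signals = list(nutrient_signal(10000, 300, 1500),
#'                  nutrient_signal(100, 300, 1500)))
#' @export
signal_schedule <- function(times, signals) {
  if (inherits(signals, "cdgpp_signal")) signals <- list(signals)
  signals <- lapply(signals, as_signal)
  if (length(times) != length(signals))
    stop("times and signals must have equal length")
  if (length(times) < 1L || times[1] != 0)
    stop("the first segment must start at t = 0")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("segment start times must be strictly increasing")
  structure(list(times = as.numeric(times), signals = signals),
            class = "cdgpp_schedule")
}

as_schedule <- function(x) {
  if (inherits(x, "cdgpp_schedule")) return(x)
  signal_schedule(0, list(as_signal(x)))
}

#' Look up the active signal of a schedule at time t
#'
#' @param schedule A [signal_schedule()].
#' @param t Time (min).
#' @return The [nutrient_signal()] in force at `t`.
#' @export
signal_at <- function(schedule, t) {
  schedule <- as_schedule(schedule)
  idx <- findInterval(t, schedule$times)
  if (idx < 1L) idx <- 1L
  schedule$signals[[idx]]
}
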