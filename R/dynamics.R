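#' Integrate the model under a nutrient schedule
#'
#' Solves the stiff seven-variable system with time-varying total DGC and
#' PDE abundances and piecewise-constant nutrient signals. The system is
#' stiff: the PTS phosphotransfer constants (~1e4 /(min uM)) outpace the
#' unimolecular nucleotide rates (~1e2 /min) by orders of magnitude, so a
#' stiff multistep solver ([deSolve::ode()] with `lsoda`) is used with
#' tight tolerances (`rtol = 1e-8`, `atol = 1e-10` uM by default), sized so
#' the conserved guanine total drifts by less than 1e-4 relative over any
#' run. Integration restarts at every schedule breakpoint so signal
#' discontinuities are not smoothed.
#'
#' @param init Initial state (named vector, see [model_state()]).
#' @param schedule A [signal_schedule()] or a single [nutrient_signal()].
#' @param t_end End time (min), > 0.
#' @param params Parameter set.
#' @param pled,pdea Sinusoid profiles for the variable PleD / PdeA
#'   components; use [constant_profile()] for non-oscillating runs.
#' @param rtol,atol Solver tolerances.
#' @param dt_out Output resolution (min).
#' @return A trajectory: data frame with `t_min`, the seven state columns
#'   and the active `Gln`, `PEP`, `Pyr`, of class `"cdgpp_trajectory"`.
#' @examples
#' \donttest{
#' tr <- integrate_model(default_state(),
#'                       nutrient_signal(10000, 300, 1500), t_end = 300)
#' max(tr$cdG)
#' }
#' @export
integrate_model <- function(init, schedule, t_end,
                            params = default_params(),
                            pled = pled_profile(), pdea = pdea_profile(),
                            rtol = 1e-8, atol = 1e-10, dt_out = 0.5) {
  if (t_end <= 0) stop("t_end must be positive")
  schedule <- as_schedule(schedule)
  init <- validate_state(init, params)
  total0 <- total_guanine(init)

  breaks <- schedule$times[schedule$times < t_end]
  seg_start <- breaks
  seg_end <- c(breaks[-1], t_end)

  deriv <- function(t, y, parms) {
    list(model_rhs(y, parms$signal,
                   dgc_total(t, parms$params, parms$pled),
                   pde_total(t, parms$params, parms$pdea),
                   parms$params))
  }

  out_list <- vector("list", length(seg_start))
  y <- init
  for (i in seq_along(seg_start)) {
    sig <- schedule$signals[[which(schedule$times == seg_start[i])]]
    times <- unique(c(seq(seg_start[i], seg_end[i], by = dt_out),
                      seg_end[i]))
    sol <- deSolve::ode(y = y, times = times, func = deriv,
                        parms = list(signal = sig, params = params,
                                     pled = pled, pdea = pdea),
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 1e5)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("solver failed on interval [%g, %g] min",
                   seg_start[i], seg_end[i]))
    sol_df <- as.data.frame(sol)
    names(sol_df)[1] <- "t_min"
    sol_df$Gln <- sig$Gln; sol_df$PEP <- sig$PEP; sol_df$Pyr <- sig$Pyr
    y <- validate_state(unlist(sol_df[nrow(sol_df), state_names()]), params)
    # a breakpoint row belongs to the incoming segment (the new signal takes
    # effect at its start time), so drop the outgoing segment's endpoint
    if (i < length(seg_start)) sol_df <- sol_df[-nrow(sol_df), , drop = FALSE]
    out_list[[i]] <- sol_df
  }
  traj <- do.call(rbind, out_list)
  rownames(traj) <- NULL

  drift <- abs(total_guanine(y) - total0) / total0
  if (drift > 1e-4)
    stop(sprintf("guanine conservation violated: relative drift %.2e", drift))
  structure(traj, class = c("cdgpp_trajectory", "data.frame"))
}

#' Numerically determined steady state at constant enzyme levels
#'
#' Integrates the model at a constant signal and constant DGC / PDE until
#' the scaled residual `max_i |dx_i/dt| / (|x_i| + 1 uM)` falls below
#' 1e-9 /min, then polishes the fixed point with damped Newton iteration on
#' the right-hand side (with the GMP equation replaced by the guanine
#' conservation constraint, which removes the Jacobian's null direction).
#'
#' This route is independent of the closed-form [equilibrium_state()]
#' oracle; the two agreeing to 1e-6 relative is a core correctness check.
#'
#' @param signal A [nutrient_signal()].
#' @param params Parameter set.
#' @param dgc_const,pde_const Constant total DGC / PDE (scaled uM);
#'   defaults are the cycle-mean levels.
#' @param init Starting state.
#' @param rtol,atol Solver tolerances for the settling phase.
#' @param max_t Simulated-time budget (min) before giving up.
#' @return The fixed-point state (named vector).
#' @export
steady_state <- function(signal, params = default_params(),
                         dgc_const = params$DgcB + pled_profile()$offset,
                         pde_const = params$basalPDE + pdea_profile()$offset,
                         init = default_state(),
                         rtol = 1e-8, atol = 1e-10, max_t = 1e5) {
  signal <- as_signal(signal)
  y <- validate_state(init, params)
  # conserved guanine total is set by the initial condition; the polish is
  # anchored to it so solver drift cannot bias the fixed point
  total0 <- total_guanine(y)
  rhs_here <- function(y) model_rhs(y, signal, dgc_const, pde_const, params)
  residual <- function(y) {
    d <- rhs_here(y)
    max(abs(d) / (abs(y) + 1))
  }

  deriv <- function(t, y, parms) list(rhs_here(y))
  t_done <- 0
  chunk <- 500
  while (residual(y) >= 1e-9) {
    if (t_done >= max_t)
      stop(sprintf(
        "no steady state within %g min; worst scaled residual %.3e /min",
        max_t, residual(y)))
    sol <- deSolve::ode(y = y, times = c(0, chunk), func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = 1e5)
    if (attr(sol, "istate")[1] < 0) stop("solver failure while settling")
    y <- validate_state(sol[nrow(sol), state_names()], params)
    t_done <- t_done + chunk
    chunk <- min(chunk * 2, 2e4)
  }

  # Newton polish on F(y) = rhs with the GMP row swapped for conservation
  Ffun <- function(y) {
    d <- rhs_here(y)
    d[["GMP"]] <- total_guanine(y) - total0
    d
  }
  for (iter in 1:30) {
    Fv <- Ffun(y)
    if (max(abs(Fv)) < 1e-12 * max(1, max(abs(y)))) break
    J <- matrix(0, 7, 7)
    for (j in 1:7) {
      h <- max(1e-7 * abs(y[j]), 1e-9)
      yp <- y; yp[j] <- yp[j] + h
      J[, j] <- (Ffun(yp) - Fv) / h
    }
    step <- tryCatch(solve(J, -Fv), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      y_new <- pmax(y + lam * step, 0)
      ok <- tryCatch(max(abs(Ffun(y_new))) <= max(abs(Fv)),
                     error = function(e) FALSE)
      if (ok || lam < 1e-4) break
      lam <- lam / 2
    }
    if (lam < 1e-4) break
    y <- setNames(y_new, state_names())
  }
  validate_state(y, params)
}

#' Min/max of a variable over one periodic cycle
#'
#' Integrates through a transient (default 600 min, four forcing periods)
#' plus one 150-min cycle with the oscillating DGC / PDE profiles and
#' reports the extrema of the named variable over the final cycle window.
#'
#' @param variable One of the seven state names (see [model_state()]).
#' @param signal A [nutrient_signal()].
#' @param params Parameter set.
#' @param pled,pdea Enzyme profiles.
#' @param transient Transient length (min), at least two periods.
#' @param init Initial state.
#' @param dt_out Output resolution (min).
#' @return A list with `variable`, `min`, `max`, `window` (c(t_lo, t_hi)).
#' @export
periodic_range <- function(variable, signal, params = default_params(),
                           pled = pled_profile(), pdea = pdea_profile(),
                           transient = 600, init = default_state(),
                           dt_out = 0.25) {
  stopifnot(variable %in% state_names())
  period <- 2 * pi / pled$angular_freq
  if (transient < 2 * period)
    stop("transient must cover at least two periods")
  tr <- integrate_model(init, as_signal(signal), transient + period,
                        params = params, pled = pled, pdea = pdea,
                        dt_out = dt_out)
  win <- tr[tr$t_min >= transient, ]
  list(variable = variable, min = min(win[[variable]]),
       max = max(win[[variable]]), window = c(transient, transient + period))
}

#' Glutamine-shift protocol
#'
#' Convenience wrapper for nutrient-shift experiments: builds a
#' piecewise-constant schedule that varies only glutamine over a fixed
#' PEP / Pyr background and integrates it. Segments chain naturally -- the
#' end state of each segment is the initial state of the next.
#'
#' @param gln_steps Data frame (or list coercible to one) with columns `t`
#'   (segment start, min; first must be 0) and `Gln` (uM).
#' @param base_signal [nutrient_signal()] providing PEP and Pyr (its Gln is
#'   ignored).
#' @param t_end End time (min).
#' @param params Parameter set.
#' @param pled,pdea Enzyme profiles.
#' @param ... Passed to [integrate_model()].
#' @return A trajectory (see [integrate_model()]).
#' @examples
#' \donttest{
#' tr <- shift_protocol(data.frame(t = c(0, 600), Gln = c(10000, 100)),
#'                      nutrient_signal(10000, 300, 1500), t_end = 900)
#' }
#' @export
shift_protocol <- function(gln_steps, base_signal, t_end,
                           params = default_params(),
                           pled = pled_profile(), pdea = pdea_profile(),
                           ...) {
  gln_steps <- as.data.frame(gln_steps)
  base_signal <- as_signal(base_signal)
  sched <- signal_schedule(
    gln_steps$t,
    lapply(gln_steps$Gln, function(g)
      nutrient_signal(g, base_signal$PEP, base_signal$Pyr)))
  integrate_model(default_state(), sched, t_end, params = params,
                  pled = pled, pdea = pdea, ...)
}

#' Read or write a trajectory as CSV
#'
#' Columns: `t_min`, the seven state variables, `Gln`, `PEP`, `Pyr`.
#'
#' @param traj A trajectory data frame.
#' @param path File path.
#' @param digits Significant digits written (fixed so identical runs give
#'   byte-identical files).
#' @return `read_trajectory()` returns the trajectory;
#'   `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path, digits = 6) {
  out <- as.data.frame(lapply(traj, function(col)
    if (is.numeric(col)) signif(col, digits) else col))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tr <- read.csv(path)
  structure(tr, class = c("cdgpp_trajectory", "data.frame"))
}
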