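#' Built-in nutrient presets
#'
#' Named nutrient conditions used throughout the model's simulations.
#' Glutamine tracks nitrogen availability (1 uM under nitrogen starvation,
#' 10000 uM with abundant ammonium); PEP and pyruvate track carbon: cells
#' on limited carbon hold (PEP, Pyr) = (2800, 900) uM, shifting to
#' (300, 1500) uM when carbon is plentiful. `carbon_limited` pins glutamine
#' at 1000 uM within its plausible 1000--2000 uM band.
#'
#' Besides the three headline conditions, the two six-level glutamine
#' series (`glnXXXX_highC`, `glnXXXX_lowC` for
#' Gln in 10000, 2000, 1000, 100, 10, 1) are included.
#'
#' @return A data frame with columns `name`, `Gln`, `PEP`, `Pyr`,
#'   `description`.
#' @examples
#' preset_signal("rich")
#' @export
builtin_presets <- function() {
  gln_levels <- c(10000, 2000, 1000, 100, 10, 1)
  base <- data.frame(
    name = c("rich", "nitrogen_starved", "carbon_limited"),
    Gln = c(10000, 1, 1000),
    PEP = c(300, 300, 2800),
    Pyr = c(1500, 1500, 900),
    description = c("ammonia with high carbon",
                    "nitrogen starvation",
                    "ammonia with limited carbon"))
  highC <- data.frame(
    name = paste0("gln", gln_levels, "_highC"),
    Gln = gln_levels, PEP = 300, Pyr = 1500,
    description = paste0("glutamine series, high carbon (Gln=",
                         gln_levels, " uM)"))
  lowC <- data.frame(
    name = paste0("gln", gln_levels, "_lowC"),
    Gln = gln_levels, PEP = 2800, Pyr = 900,
    description = paste0("glutamine series, limited carbon (Gln=",
                         gln_levels, " uM)"))
  rbind(base, highC, lowC)
}

#' @rdname builtin_presets
#' @param name Preset name.
#' @export
preset_signal <- function(name) {
  presets <- builtin_presets()
  row <- presets[presets$name == name, ]
  if (nrow(row) != 1L)
    stop("unknown preset '", name, "'; see builtin_presets()")
  nutrient_signal(row$Gln, row$PEP, row$Pyr)
}

#' Nutrient-condition grid of steady states and cdG oscillation ranges
#'
#' For each cell of the glutamine series (six levels) crossed with the two
#' carbon conditions, computes the closed-form steady-state nucleotide and
#' PTS pools (at cycle-mean constant DGC / PDE levels -- the non-cdG pools
#' vary well under 1% over the forcing cycle, so constant-enzyme steady
#' states represent them) and, when `cdg_ranges = TRUE`, the cdG
#' oscillation range under the periodic DGC / PDE profiles.
#'
#' @param params Parameter set.
#' @param cdg_ranges Integrate the oscillating model for the cdG range of
#'   every cell (12 stiff integrations) or skip those columns.
#' @param transient Transient before the range window (min).
#' @return A data frame, one row per condition, with columns `Gln`, `PEP`,
#'   `Pyr`, `cdG_min`, `cdG_max` (if requested), `ppGpp`, `GTP`,
#'   `ppGpp_GTP_ratio`, `GMP`, `EIP_tot`, `NPrP`, `EIIAP`.
#' @export
run_nutrient_grid <- function(params = default_params(), cdg_ranges = TRUE,
                              transient = 600) {
  gln_levels <- c(10000, 2000, 1000, 100, 10, 1)
  carbon <- data.frame(PEP = c(300, 2800), Pyr = c(1500, 900))
  rows <- list()
  for (ci in seq_len(nrow(carbon))) {
    for (g in gln_levels) {
      sig <- nutrient_signal(g, carbon$PEP[ci], carbon$Pyr[ci])
      eq <- equilibrium_state(sig, params)
      row <- data.frame(
        Gln = g, PEP = sig$PEP, Pyr = sig$Pyr,
        ppGpp = eq[["ppGpp"]], GTP = eq[["GTP"]],
        ppGpp_GTP_ratio = eq[["ppGpp"]] / eq[["GTP"]],
        GMP = eq[["GMP"]], EIP_tot = eq[["EIP_tot"]],
        NPrP = eq[["NPrP"]], EIIAP = eq[["EIIAP"]])
      if (cdg_ranges) {
        rng <- periodic_range("cdG", sig, params, transient = transient)
        row$cdG_min <- rng$min
        row$cdG_max <- rng$max
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  front <- c("Gln", "PEP", "Pyr",
             if (cdg_ranges) c("cdG_min", "cdG_max"))
  out[, c(front, setdiff(names(out), front))]
}

#' PTS calibration table: phosphorylation vs EI and NPr totals
#'
#' Evaluates [pts_phospho_sum()] over the enzyme-titration conditions of
#' the carbon-PTS phosphorylation experiments (PEP = 160 uM,
#' Pyr = 48.5 uM), returning the simulated `EI~P + NPr~P` next to the
#' published measurements for comparison.
#'
#' @param params Parameter set.
#' @param Gln Glutamine level of the calibration (see
#'   [pts_phospho_sum()]).
#' @return A data frame with columns `EI_T`, `NPr_T`, `experiment`
#'   (measured, uM; `NA` where the source value was below the figure's
#'   resolution), `simulated` (uM).
#' @export
run_pts_calibration <- function(params = default_params(), Gln = 10000) {
  grid <- data.frame(
    EI_T = c(0.157, 0.3125, 0.729, 1.57, 0.729, 0.729, 0.729),
    NPr_T = c(24.4, 24.4, 24.4, 24.4, 0, 12.2, 36.6),
    experiment = c(6, 6.5, 7, 7.5, NA, 3, 9.1))
  grid$simulated <- vapply(seq_len(nrow(grid)), function(i)
    pts_phospho_sum(grid$EI_T[i], grid$NPr_T[i], params, Gln = Gln),
    numeric(1))
  grid
}

#' Cell-cycle cdG oscillation under rich conditions
#'
#' Simulates one 150-min cell cycle of a swarmer cell under the rich preset
#' with the oscillating PleD and PdeA profiles (after a transient to reach
#' the periodic orbit). The cdG trace rises to ~0.28 uM at the
#' swarmer-to-stalked transition and falls below 0.1 uM late in the cycle.
#'
#' @param params Parameter set.
#' @param transient Transient length (min).
#' @return A list with `trajectory` (the final cycle, times shifted to
#'   start at 0) and `range` (the [periodic_range()] report for cdG).
#' @export
run_cell_cycle <- function(params = default_params(), transient = 600) {
  sig <- preset_signal("rich")
  period <- 150
  tr <- integrate_model(default_state(), sig, transient + period,
                        params = params, dt_out = 0.25)
  cycle <- tr[tr$t_min >= transient, ]
  cycle$t_min <- cycle$t_min - transient
  rownames(cycle) <- NULL
  list(trajectory = cycle,
       range = list(variable = "cdG", min = min(cycle$cdG),
                    max = max(cycle$cdG),
                    window = c(transient, transient + period)))
}

#' Nitrogen downshift and recovery protocol
#'
#' Three-segment glutamine schedule over the rich carbon background:
#' glutamine starts at 10000 uM, drops to `gln_shift` (default 100 uM) at
#' `t_shift`, and is restored at `t_restore`. The alarmone rises toward its
#' starved steady level within one cell cycle of the downshift, and the
#' nucleotide pools recover after restoration.
#'
#' @param params Parameter set.
#' @param gln_shift Glutamine level during the starvation segment (uM).
#' @param t_shift,t_restore Shift and restoration times (min).
#' @param t_end End of the simulation (min).
#' @return A trajectory (see [integrate_model()]).
#' @export
run_nitrogen_shift <- function(params = default_params(), gln_shift = 100,
                               t_shift = 600, t_restore = 1200,
                               t_end = 1800) {
  shift_protocol(
    data.frame(t = c(0, t_shift, t_restore),
               Gln = c(10000, gln_shift, 10000)),
    preset_signal("rich"), t_end = t_end, params = params)
}

#' Write a scenario table as CSV
#'
#' Numeric columns are rounded to 4 significant digits before writing so
#' repeated runs of the same configuration produce byte-identical files.
#'
#' @param table A data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(table, path) {
  out <- as.data.frame(lapply(table, function(col)
    if (is.numeric(col)) signif(col, 4) else col))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
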