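#' Sinusoid abundance profiles
#'
#' Enzyme abundances over the 150-min *C. crescentus* cell cycle are modelled
#' as `A * sin(omega * t + phi) + c` on the scaled (relative immunoblot)
#' concentration axis. `t = 0` is swarmer-cell birth.
#'
#' `pled_profile()` returns the PleD total-protein fit
#' `0.1834 * sin(pi*t/75 + 0.5587) + 0.7579` (the refit with the aberrant
#' second time point removed); `pled_profile(refit = FALSE)` returns the fit
#' to all points, `0.1442 * sin(pi*t/75 + 0.5037) + 0.7384`.
#' `pdea_profile()` returns the PdeA fit
#' `-0.3605 * sin(pi*t/75 + 0.1767) + 0.361`, whose trough approaches zero;
#' total PDE stays positive because of the basal term. All three share the
#' angular frequency `pi/75` rad/min, i.e. a 150-min period.
#'
#' @param amplitude,angular_freq,phase,offset Sinusoid coefficients
#'   (scaled uM, rad/min, rad, scaled uM); `angular_freq` must be positive.
#' @return An object of class `"cdgpp_profile"`.
#' @examples
#' eval_profile(pled_profile(), 30)
#' @export
sinusoid_profile <- function(amplitude, angular_freq, phase, offset) {
  if (!is.finite(angular_freq) || angular_freq <= 0)
    stop("angular_freq must be positive")
  structure(list(amplitude = amplitude, angular_freq = angular_freq,
                 phase = phase, offset = offset), class = "cdgpp_profile")
}

#' @rdname sinusoid_profile
#' @param refit If `TRUE` (default) use the fit with the outlying second
#'   point excluded.
#' @export
pled_profile <- function(refit = TRUE) {
  if (refit) sinusoid_profile(0.1834, pi / 75, 0.5587, 0.7579)
  else       sinusoid_profile(0.1442, pi / 75, 0.5037, 0.7384)
}

#' @rdname sinusoid_profile
#' @export
pdea_profile <- function() {
  sinusoid_profile(-0.3605, pi / 75, 0.1767, 0.361)
}

#' @rdname sinusoid_profile
#' @param level Constant level for a flat profile (scaled uM).
#' @export
constant_profile <- function(level) {
  sinusoid_profile(0, pi / 75, 0, level)
}

#' Evaluate a sinusoid profile
#'
#' @param profile A [sinusoid_profile()].
#' @param t Time or vector of times (min).
#' @return Profile value(s) (scaled uM).
#' @export
eval_profile <- function(profile, t) {
  profile$amplitude * sin(profile$angular_freq * t + profile$phase) +
    profile$offset
}

#' Total DGC and PDE abundances over the cell cycle
#'
#' Total diguanylate cyclase is the constant DgcB level plus the oscillating
#' PleD profile; total phosphodiesterase is the basal PDE level plus the
#' oscillating PdeA profile.
#'
#' @param t Time (min), vectorized.
#' @param params Parameter set (supplies `DgcB` / `basalPDE`).
#' @param pled,pdea Sinusoid profiles for the variable components.
#' @return Abundance (scaled uM).
#' @export
dgc_total <- function(t, params = default_params(), pled = pled_profile()) {
  params$DgcB + eval_profile(pled, t)
}

#' @rdname dgc_total
#' @export
pde_total <- function(t, params = default_params(), pdea = pdea_profile()) {
  params$basalPDE + eval_profile(pdea, t)
}

#' Fit a constrained sinusoid to abundance points
#'
#' Least-squares fit of `A * sin(omega*t + phi) + c` to time-course points.
#' By default the angular frequency is fixed at `pi/75` rad/min (the 150-min
#' cell-cycle period); with so few points per course a free frequency is
#' poorly identifiable. With `omega` fixed the problem is linear in
#' `(A sin phi, A cos phi, c)` and solved exactly by [lm()]; with
#' `fix_freq = NULL` the frequency is refined from the `pi/75` start by
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]).
#'
#' The fitted amplitude is canonicalized to `A >= 0`, `phi` in `[0, 2*pi)`
#' (using the symmetry `A sin(x) = -A sin(x + pi)`).
#'
#' Point exclusion is exposed through `mask` rather than automated: deciding
#' that a blot measurement is aberrant is a judgment call, so the caller
#' masks indices explicitly and refits.
#'
#' @param points A data frame with columns `t_min` and `level` (see
#'   [synth_profile_points()] / [read_profile_points()]), at least 4 rows
#'   (3 when the frequency is fixed).
#' @param fix_freq Angular frequency to hold fixed (rad/min), or `NULL` to
#'   fit it. Default `pi/75`.
#' @param mask Optional integer indices of points to exclude from the fit.
#' @return A list with `profile` (the fitted [sinusoid_profile()]),
#'   `r_squared` (coefficient of determination; `NA` with a warning when
#'   the points are constant so SS_tot = 0) and `n_used`.
#' @export
fit_sinusoid <- function(points, fix_freq = pi / 75, mask = NULL) {
  stopifnot(all(c("t_min", "level") %in% names(points)))
  if (!is.null(mask)) points <- points[-mask, , drop = FALSE]
  t <- points$t_min
  y <- points$level
  need <- if (is.null(fix_freq)) 4L else 3L
  if (length(t) < need)
    stop("need at least ", need, " points to fit")
  if (length(unique(t)) < 2L)
    stop("degenerate points: all at the same time")

  linfit <- function(w) {
    X <- cbind(s = sin(w * t), co = cos(w * t))
    fit <- lm(y ~ X)
    b <- coef(fit)
    list(a = b[["Xs"]], b = b[["Xco"]], c = b[["(Intercept)"]],
         resid = fit$residuals)
  }

  if (is.null(fix_freq)) {
    start <- linfit(pi / 75)
    nls_fit <- minpack.lm::nlsLM(
      y ~ a * sin(w * t) + b * cos(w * t) + c0,
      start = list(a = start$a, b = start$b, c0 = start$c, w = pi / 75),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    if (!nls_fit$convInfo$isConv)
      warning("frequency fit did not converge; returning best iterate")
    cf <- coef(nls_fit)
    a <- cf[["a"]]; b <- cf[["b"]]; c0 <- cf[["c0"]]; w <- abs(cf[["w"]])
    res <- y - (a * sin(w * t) + b * cos(w * t) + c0)
  } else {
    w <- fix_freq
    lf <- linfit(w)
    a <- lf$a; b <- lf$b; c0 <- lf$c; res <- lf$resid
  }

  A <- sqrt(a^2 + b^2)
  phi <- atan2(b, a) %% (2 * pi)

  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("constant points: R-squared is undefined")
    r2 <- NA_real_
  } else {
    r2 <- 1 - ss_res / ss_tot
  }
  list(profile = sinusoid_profile(A, w, phi, c0), r_squared = r2,
       n_used = length(t))
}

#' Generate synthetic abundance points from a profile
#'
#' Samples `n` points evenly spaced over one period of the profile and adds
#' i.i.d. Gaussian noise. Used to exercise [fit_sinusoid()]; real abundance
#' courses come from digitized immunoblots and are not bundled.
#'
#' The RNG state is restored afterwards when a seed is given, so fixture
#' generation does not perturb the caller's random stream.
#'
#' @param profile A [sinusoid_profile()].
#' @param n Number of points (>= 4).
#' @param noise_sd Gaussian noise standard deviation (scaled uM, >= 0).
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame with columns `t_min`, `level`.
#' @export
synth_profile_points <- function(profile, n, noise_sd = 0, seed = NULL) {
  if (n < 4) stop("n must be at least 4")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  period <- 2 * pi / profile$angular_freq
  t <- seq(0, period, length.out = n + 1L)[seq_len(n)]
  data.frame(t_min = t,
             level = eval_profile(profile, t) + rnorm(n, sd = noise_sd))
}

#' Read or write profile points as CSV
#'
#' Two-column CSV with header `t_min,level`.
#'
#' @param path File path.
#' @param points A data frame with columns `t_min`, `level`.
#' @return `read_profile_points()` returns the data frame;
#'   `write_profile_points()` returns `path` invisibly.
#' @export
read_profile_points <- function(path) {
  pts <- read.csv(path)
  stopifnot(all(c("t_min", "level") %in% names(pts)))
  if (is.unsorted(pts$t_min, strictly = TRUE))
    stop("times must be strictly increasing")
  pts
}

#' @rdname read_profile_points
#' @export
write_profile_points <- function(points, path) {
  write.csv(points[, c("t_min", "level")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
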