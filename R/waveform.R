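#' Left-ventricular volume waveform
#'
#' Prescribed cavity volume over one heartbeat: a single raised-cosine systolic
#' ejection followed by a two-phase diastole (E-wave and A-wave raised cosines
#' with a 2:1 E/A filling-volume ratio separated by diastasis). Time t = 0 is
#' end-diastole, so the cycle opens with systole.
#'
#' @param EDV end-diastolic volume (cm^3).
#' @param ESV end-systolic volume (cm^3), `0 < ESV < EDV`.
#' @param period heartbeat period T (s); default 1 s.
#' @param t_sys systolic duration as a fraction of T; default 0.35.
#' @param n_samples number of stored volume samples over one period.
#' @return An object of class `volume_waveform` with fields `EDV`, `ESV`,
#'   `SV`, `EF`, `period`, `t_end_systole`, sample vectors `t`, `V`, and
#'   vectorized functions `volume(t)`, `dvdt(t)` (periodic in t).
#' @export
volume_waveform <- function(EDV, ESV, period = 1, t_sys = 0.35,
                            n_samples = 401L) {
  stopifnot(EDV > ESV, ESV > 0, period > 0, t_sys > 0, t_sys < 0.6)
  SV <- EDV - ESV
  Ts <- t_sys * period
  ## diastolic windows (fractions of T): E-wave, diastasis, A-wave
  tE <- 0.42 * period; dE <- 0.28 * period
  tA <- 0.76 * period; dA <- 0.21 * period
  pulse <- function(t, t0, d) {
    tau <- (t - t0) / d
    ifelse(tau > 0 & tau < 1, (1 - cos(2 * pi * tau)) / d, 0)
  }
  cpulse <- function(t, t0, d) {  # running integral of pulse, in [0, 1]
    tau <- pmin(pmax((t - t0) / d, 0), 1)
    tau - sin(2 * pi * tau) / (2 * pi)
  }
  dvdt <- function(t) {
    t <- t %% period
    -SV * pulse(t, 0, Ts) + (2 / 3) * SV * pulse(t, tE, dE) +
      (1 / 3) * SV * pulse(t, tA, dA)
  }
  volume <- function(t) {
    t <- t %% period
    EDV - SV * cpulse(t, 0, Ts) + (2 / 3) * SV * cpulse(t, tE, dE) +
      (1 / 3) * SV * cpulse(t, tA, dA)
  }
  ts <- seq(0, period, length.out = n_samples)
  structure(list(EDV = EDV, ESV = ESV, SV = SV, EF = SV / EDV,
                 period = period, t_end_systole = Ts,
                 t = ts, V = volume(ts),
                 volume = volume, dvdt = dvdt),
            class = "volume_waveform")
}

#' Cardiac phase of a time instant
#'
#' Systole is the contiguous interval where dV/dt < 0; diastole is its
#' complement (including diastasis).
#' @param wf a `volume_waveform`.
#' @param t time (s), vectorized.
#' @return character vector `"systole"` / `"diastole"`.
#' @export
phase_of <- function(wf, t) {
  tm <- t %% wf$period
  ifelse(tm >= 0 & tm < wf$t_end_systole, "systole", "diastole")
}

#' @export
print.volume_waveform <- function(x, ...) {
  cat(sprintf(
    "volume_waveform: EDV %.2f ESV %.2f SV %.2f cm^3, EF %.0f%%, T %.2f s\n",
    x$EDV, x$ESV, x$SV, 100 * x$EF, x$period))
  invisible(x)
}
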