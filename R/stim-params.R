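## Stimulus-waveform safety arithmetic and the analytic response of the
## evoked-potential band-pass.

#' Charge per phase of a biphasic stimulation pulse
#'
#' For a current-controlled square pulse, charge per phase is current times
#' phase duration: 9 mA at 0.2 ms per phase gives 1.8 uC/phase.
#'
#' @param current_ma current intensity in mA.
#' @param phase_ms duration of one phase in ms.
#' @return Charge per phase in microcoulombs.
#' @export
stim_charge_per_phase <- function(current_ma = 9, phase_ms = 0.2) {
  stopifnot(current_ma > 0, phase_ms > 0)
  current_ma * phase_ms            # mA * ms = uC
}

#' Total duration of a charge-balanced biphasic pulse
#'
#' @param phase_ms duration of one phase in ms.
#' @param n_phases number of phases (2 for a biphasic pulse).
#' @param interphase_ms gap between phases in ms.
#' @return Total pulse duration in ms (0.4 ms for two 0.2 ms phases).
#' @export
stim_pulse_duration <- function(phase_ms = 0.2, n_phases = 2,
                                interphase_ms = 0) {
  stopifnot(phase_ms > 0, n_phases >= 1)
  n_phases * phase_ms + (n_phases - 1) * interphase_ms
}

#' Charge density at the electrode surface
#'
#' @param charge_uc charge per phase in uC.
#' @param area_cm2 geometric contact area in cm^2.
#' @return Charge density in uC/cm^2.
#' @export
stim_charge_density <- function(charge_uc, area_cm2) {
  stopifnot(area_cm2 > 0)
  charge_uc / area_cm2
}

#' Composed gain of the zero-phase evoked-potential band-pass
#'
#' Evaluates the magnitude response of the 2nd-order Butterworth band-pass
#' used by [bandpass_early()], composed forward-backward (so the gain is
#' |H(f)|^2 and the phase is zero). At the design band edges the single-pass
#' response is -3 dB, hence the composed response is -6 dB.
#'
#' @param freqs frequencies (Hz) at which to evaluate.
#' @param fs sampling rate in Hz.
#' @param band single-pass -3 dB band edges in Hz.
#' @return Composed gain in dB at each frequency.
#' @export
bandpass_gain_db <- function(freqs, fs = 8000, band = c(2, 200)) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  w <- 2 * pi * freqs / fs
  z <- exp(-1i * w)
  H <- vapply(z, function(zz)
    sum(bf$b * zz^(seq_along(bf$b) - 1)) /
      sum(bf$a * zz^(seq_along(bf$a) - 1)), complex(1))
  20 * log10(Mod(H)^2)             # forward-backward: |H|^2
}
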