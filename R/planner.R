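#' Concentration after merging substrate drops into a main drop
#'
#' Exact dilution arithmetic:
#' `c = n * v_drop * c_sub / (v_main + n * v_drop)`, reported in mM.
#'
#' @param n_drops number of substrate drops merged (>= 0).
#' @param v_drop_pL volume per substrate drop, pL.
#' @param c_sub_M substrate stock concentration, mol/L.
#' @param v_main_nL main-drop volume, nL.
#' @return merged concentration, mM.
#' @examples
#' merged_concentration(2, 120, 0.226, 3)   # 16.7 mM
#' merged_concentration(4, 120, 0.8, 3)     # 110.3 mM
#' merged_concentration(5, 60, 0.1, 4)      # 7.0 mM
#' @export
merged_concentration <- function(n_drops, v_drop_pL, c_sub_M, v_main_nL) {
  if (n_drops < 0 || n_drops != round(n_drops))
    stop("n_drops must be a non-negative integer", call. = FALSE)
  check_positive(v_drop_pL, "v_drop_pL")
  check_nonneg(c_sub_M, "c_sub_M")
  check_positive(v_main_nL, "v_main_nL")
  if (n_drops == 0) return(0)
  v_drop <- v_drop_pL * 1e-12
  v_main <- v_main_nL * 1e-9
  1e3 * n_drops * v_drop * c_sub_M / (v_main + n_drops * v_drop)
}

#' Reaction delay time from tape geometry
#'
#' The delay between drop merging and the X-ray (or optical) interaction
#' point is `path_length / tape_speed`.
#'
#' @param path_length_mm dispenser-to-interaction-point distance, mm.
#' @param tape_speed_mm_s tape speed, mm/s.
#' @return delay time, s.
#' @examples
#' delay_time(60, 600)   # 0.1 s
#' delay_time(60, 10)    # 6 s
#' @export
delay_time <- function(path_length_mm, tape_speed_mm_s) {
  check_nonneg(path_length_mm, "path_length_mm")
  check_positive(tape_speed_mm_s, "tape_speed_mm_s")
  path_length_mm / tape_speed_mm_s
}

#' Describe a substrate dispensing mode
#'
#' @param kind `"burst"` (a fixed number of drops per trigger) or
#'   `"continuous"` (free-running dispensing).
#' @param drops_per_trigger drops per burst (burst mode).
#' @param trigger_rate_hz burst trigger rate, Hz (burst mode).
#' @param continuous_rate_hz dispensing frequency, Hz (continuous mode).
#' @param drop_volume_pL drop volume, pL.
#' @param c_substrate_M substrate concentration, mol/L.
#' @return object of class `dispense_mode`.
#' @export
dispense_mode <- function(kind = c("burst", "continuous"),
                          drops_per_trigger = NULL, trigger_rate_hz = NULL,
                          continuous_rate_hz = NULL,
                          drop_volume_pL = 120, c_substrate_M = 0.226) {
  kind <- match.arg(kind)
  check_positive(drop_volume_pL, "drop_volume_pL")
  check_nonneg(c_substrate_M, "c_substrate_M")
  if (kind == "burst") {
    check_positive(drops_per_trigger, "drops_per_trigger")
    check_positive(trigger_rate_hz, "trigger_rate_hz")
    drops_s <- drops_per_trigger * trigger_rate_hz
  } else {
    check_positive(continuous_rate_hz, "continuous_rate_hz")
    drops_s <- continuous_rate_hz
  }
  structure(list(kind = kind, drops_per_trigger = drops_per_trigger,
                 trigger_rate_hz = trigger_rate_hz,
                 continuous_rate_hz = continuous_rate_hz,
                 drop_volume_pL = drop_volume_pL,
                 c_substrate_M = c_substrate_M,
                 drops_per_second = drops_s),
            class = "dispense_mode")
}

#' Substrate consumption of two dispensing modes
#'
#' Compares drop rates, dispensed volume and substance over a duration, and
#' reports the fold ratio of mode A over mode B (e.g. continuous delivery at
#' 6.1 kHz versus bursts of 10 drops at 30 Hz gives a ~20-fold reduction).
#'
#' @param mode_a,mode_b [dispense_mode()]s.
#' @param duration_s comparison duration, s.
#' @return object of class `plan_report` with per-mode `drops_per_second`,
#'   `volume_uL`, `substance_umol`, and `fold_ratio` (a over b).
#' @examples
#' cont <- dispense_mode("continuous", continuous_rate_hz = 6100)
#' burst <- dispense_mode("burst", drops_per_trigger = 10, trigger_rate_hz = 30)
#' consumption_report(cont, burst, 3600)$fold_ratio   # ~20.3
#' @export
consumption_report <- function(mode_a, mode_b, duration_s) {
  stopifnot(inherits(mode_a, "dispense_mode"),
            inherits(mode_b, "dispense_mode"))
  check_positive(duration_s, "duration_s")
  one <- function(m) {
    vol_L <- m$drops_per_second * duration_s * m$drop_volume_pL * 1e-12
    list(kind = m$kind, drops_per_second = m$drops_per_second,
         volume_uL = vol_L * 1e6,
         substance_umol = vol_L * m$c_substrate_M * 1e6)
  }
  a <- one(mode_a); b <- one(mode_b)
  structure(list(mode_a = a, mode_b = b, duration_s = duration_s,
                 fold_ratio = a$drops_per_second / b$drops_per_second),
            class = "plan_report")
}

#' @export
print.plan_report <- function(x, ...) {
  fmt <- function(m) sprintf(
    "  %-10s %8.4g drops/s  %8.4g uL  %8.4g umol",
    m$kind, m$drops_per_second, m$volume_uL, m$substance_umol)
  cat("Substrate consumption over", signif(x$duration_s, 3), "s:\n")
  cat(fmt(x$mode_a), "\n"); cat(fmt(x$mode_b), "\n")
  cat(sprintf("  fold ratio (a/b): %.3g\n", x$fold_ratio))
  invisible(x)
}

#' Amount of ligand in a dispensed volume
#'
#' @param volume_mL dispensed volume, mL.
#' @param c_M ligand concentration, mol/L.
#' @return amount in umol.
#' @examples
#' ligand_amount(0.18, 0.226)   # 40.7 umol (~41)
#' @export
ligand_amount <- function(volume_mL, c_M) {
  check_positive(volume_mL, "volume_mL")
  check_nonneg(c_M, "c_M")
  volume_mL * 1e-3 * c_M * 1e6
}

#' Characteristic diffusion time over a length scale
#'
#' Mean-square-displacement heuristic for how long a substrate needs to
#' diffuse through a crystal or drop of size `L`: `L^2 / (6 D)` in the 3-D
#' convention (default) or `L^2 / (2 D)` in 1-D. Free-solution values; no
#' crystal-lattice obstruction factor.
#'
#' @param length_um length scale, um.
#' @param D diffusion coefficient, m^2/s.
#' @param convention `"3d"` or `"1d"`.
#' @return time, s.
#' @examples
#' characteristic_diffusion_time(5, 7.9e-10)   # ~5.3e-3 s
#' @export
characteristic_diffusion_time <- function(length_um, D, convention = c("3d", "1d")) {
  convention <- match.arg(convention)
  check_positive(length_um, "length_um")
  check_positive(D, "D")
  L <- length_um * 1e-6
  L^2 / (if (convention == "3d") 6 else 2) / D
}
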