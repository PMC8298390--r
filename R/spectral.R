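#' Construct a fluorescence spectrum
#'
#' @param wavelength_nm strictly increasing wavelength grid, nm.
#' @param intensity fluorescence intensities (arbitrary units), same length.
#' @param tape_speed_mm_s tape speed at which the spectrum was recorded,
#'   mm/s (needed for residence-time correction).
#' @param replicates number of averaged replicates.
#' @return object of class `spectrum`.
#' @export
spectrum <- function(wavelength_nm, intensity, tape_speed_mm_s = NULL,
                     replicates = 1L) {
  if (length(wavelength_nm) != length(intensity))
    stop("wavelength and intensity must have equal length", call. = FALSE)
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 intensity = as.numeric(intensity),
                 tape_speed_mm_s = tape_speed_mm_s,
                 replicates = as.integer(replicates),
                 speed_corrected = FALSE),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("Spectrum: %d points, %.0f-%.0f nm", length(x$intensity),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  if (!is.null(x$tape_speed_mm_s))
    cat(sprintf(", tape speed %.4g mm/s%s", x$tape_speed_mm_s,
                if (x$speed_corrected) " (residence-corrected)" else ""))
  cat("\n")
  invisible(x)
}

#' Bundle normalised component spectra on a shared grid
#'
#' The four components of the calcium-indicator measurement: residual diode
#' scatter, Fluo-5N fluorescence (peak 515 nm), and the Ca-free (670 nm)
#' and Ca-bound (640 nm) forms of Fura Red. Each component is
#' max-normalised to 1.
#'
#' @param wavelength_nm shared, strictly increasing grid.
#' @param sc_diode,fl_fluo,fl_fura_minus,fl_fura_plus component intensities.
#' @param peaks optional named vector of peak wavelengths (metadata).
#' @return object of class `component_set`.
#' @export
component_set <- function(wavelength_nm, sc_diode, fl_fluo,
                          fl_fura_minus, fl_fura_plus, peaks = NULL) {
  comps <- list(sc_diode = sc_diode, fl_fluo = fl_fluo,
                fl_fura_minus = fl_fura_minus, fl_fura_plus = fl_fura_plus)
  for (nm in names(comps)) {
    if (length(comps[[nm]]) != length(wavelength_nm))
      stop(nm, " does not match the wavelength grid", call. = FALSE)
    if (abs(max(comps[[nm]]) - 1) > 1e-8)
      stop(nm, " must be max-normalised to 1", call. = FALSE)
  }
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  structure(c(list(wavelength_nm = as.numeric(wavelength_nm)), comps,
              list(peaks = peaks)),
            class = "component_set")
}

# internal: component matrix interpolated onto a target grid
component_matrix <- function(comps, grid) {
  if (min(grid) < min(comps$wavelength_nm) - 1e-9 ||
      max(grid) > max(comps$wavelength_nm) + 1e-9)
    stop("components do not cover the requested window", call. = FALSE)
  nm <- c("sc_diode", "fl_fluo", "fl_fura_minus", "fl_fura_plus")
  X <- vapply(nm, function(k)
    stats::approx(comps$wavelength_nm, comps[[k]], grid)$y, numeric(length(grid)))
  colnames(X) <- nm
  X
}

#' Linear spectral unmixing against the component set
#'
#' Decomposes a measured spectrum inside the fit window as
#' `f(lambda) = s_d * sc_diode + s_fluo * fl_fluo + s_fura_minus *
#' fl_fura_minus + s_fura_plus * fl_fura_plus + c` by ordinary (optionally
#' weighted) linear least squares. Coefficients are unconstrained in sign.
#'
#' @param spec a [spectrum()].
#' @param comps a [component_set()] covering the window.
#' @param window fit window in nm, default `c(510, 750)`.
#' @return object of class `spectral_fit` with `coefficients`
#'   (`s_d`, `s_fluo`, `s_fura_minus`, `s_fura_plus`, `c`),
#'   `residual_norm`, `window`, `fitted`, `wavelength_nm`.
#' @examples
#' cs <- make_component_spectra()
#' sp <- spectrum(cs$wavelength_nm, 2 * cs$fl_fluo)
#' coef(fit_components(sp, cs))["s_fluo"]   # 2
#' @export
fit_components <- function(spec, comps, window = c(510, 750)) {
  stopifnot(inherits(spec, "spectrum"), inherits(comps, "component_set"))
  if (window[1] >= window[2])
    stop("window must be an increasing interval", call. = FALSE)
  sel <- spec$wavelength_nm >= window[1] & spec$wavelength_nm <= window[2]
  if (sum(sel) < 6L)
    stop("fewer than 6 spectral points inside the fit window", call. = FALSE)
  grid <- spec$wavelength_nm[sel]
  X <- cbind(component_matrix(comps, grid), c = 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("singular design: component spectra are degenerate inside the window",
         call. = FALSE)
  beta <- qr.coef(qrX, spec$intensity[sel])
  names(beta) <- c("s_d", "s_fluo", "s_fura_minus", "s_fura_plus", "c")
  fitted <- as.numeric(X %*% beta)
  res <- spec$intensity[sel] - fitted
  structure(list(coefficients = beta,
                 residual_norm = sqrt(sum(res^2)),
                 window = window, wavelength_nm = grid,
                 fitted = fitted, residuals = res,
                 tape_speed_mm_s = spec$tape_speed_mm_s),
            class = "spectral_fit")
}

#' @export
coef.spectral_fit <- function(object, ...) object$coefficients

#' @export
residuals.spectral_fit <- function(object, ...) object$residuals

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("Spectral unmixing over %.0f-%.0f nm:\n",
              x$window[1], x$window[2]))
  print(signif(x$coefficients, 6))
  cat("  residual norm:", format(x$residual_norm, digits = 4), "\n")
  invisible(x)
}

#' @export
summary.spectral_fit <- function(object, ...) {
  cat("Coefficients (component scale factors + offset):\n")
  print(signif(object$coefficients, 6))
  cat(sprintf("Fit window %.0f-%.0f nm, %d points, residual norm %.4g\n",
              object$window[1], object$window[2],
              length(object$wavelength_nm), object$residual_norm))
  invisible(object)
}

#' Correct a spectrum for tape-speed-dependent residence time
#'
#' The optical signal integrates over the residence time of a drop in the
#' detection volume, which is inversely proportional to the tape speed;
#' intensities are therefore multiplied by `speed / reference_speed`.
#' Applying the correction twice with the same reference is a no-op.
#'
#' @param spec a [spectrum()] with `tape_speed_mm_s` metadata.
#' @param reference_speed reference tape speed, mm/s (default 100).
#' @return the corrected [spectrum()] with `speed_corrected = TRUE`.
#' @export
scale_by_tape_speed <- function(spec, reference_speed = 100) {
  stopifnot(inherits(spec, "spectrum"))
  check_positive(reference_speed, "reference_speed")
  if (is.null(spec$tape_speed_mm_s))
    stop("spectrum has no tape_speed_mm_s metadata", call. = FALSE)
  if (isTRUE(spec$speed_corrected)) return(spec)
  spec$intensity <- spec$intensity * spec$tape_speed_mm_s / reference_speed
  spec$speed_corrected <- TRUE
  spec
}

#' Fit an exponential rise to time-resolved scale factors
#'
#' Fits `s(t) = a * (1 - exp(-t / tau))` to (interaction time, scale factor)
#' points by damped nonlinear least squares ([minpack.lm::nlsLM()]), with
#' the initial rise time taken from the time of half-maximum and four
#' additional starts spread over a decade in tau. Optionally the `k`
#' earliest time points are first merged by averaging, mirroring the
#' treatment of weak fast-time-point signals.
#'
#' @param points data.frame with columns `t` (s, > 0), `s` (scale factor)
#'   and optionally `sd` (uncertainty used as weights `1/sd^2`).
#' @param average_fastest integer `k >= 0`: merge the `k` earliest points
#'   into their mean before fitting (0 or 1 leaves the data unchanged).
#' @return object of class `rise_fit`: `coefficients` (`a`, `tau` in s),
#'   `cov`, `stable` flag, `points`, and the underlying `nls` fit.
#' @examples
#' tp <- c(0.2, 0.3, 0.5, 1, 2)
#' fit <- fit_rise(data.frame(t = tp, s = 1 - exp(-tp / 0.15)))
#' coef(fit)   # a = 1, tau = 0.15
#' @export
fit_rise <- function(points, average_fastest = 0L) {
  stopifnot(is.data.frame(points), all(c("t", "s") %in% names(points)))
  if (any(points$t <= 0))
    stop("interaction times must be positive", call. = FALSE)
  if (average_fastest < 0 || average_fastest != round(average_fastest))
    stop("average_fastest must be a non-negative integer", call. = FALSE)
  points <- points[order(points$t), , drop = FALSE]
  k <- as.integer(average_fastest)
  if (k >= 2L) {
    head_pts <- points[seq_len(k), , drop = FALSE]
    merged <- data.frame(t = mean(head_pts$t), s = mean(head_pts$s))
    if ("sd" %in% names(points))
      merged$sd <- sqrt(mean(head_pts$sd^2)) / sqrt(k)
    points <- rbind(merged, points[-seq_len(k), , drop = FALSE])
  }
  if (nrow(points) < 3L)
    stop("at least 3 points are required after averaging", call. = FALSE)
  w <- if ("sd" %in% names(points)) 1 / points$sd^2 else rep(1, nrow(points))

  spread <- stats::sd(points$s) / max(abs(mean(points$s)), 1e-300)
  if (!is.finite(spread) || spread < 1e-8) {
    warning("scale factors carry no time dependence; rise time is not ",
            "identifiable", call. = FALSE)
    return(structure(list(coefficients = c(a = mean(points$s), tau = NA_real_),
                          cov = matrix(NA_real_, 2, 2), stable = FALSE,
                          points = points, fit = NULL),
                     class = "rise_fit"))
  }

  # initial tau from the time of half-maximum: s(t_half) = a/2 at t = tau ln 2
  a0 <- max(points$s)
  i_half <- which(points$s >= a0 / 2)[1]
  tau0 <- points$t[i_half] / log(2)
  starts <- tau0 * 10^seq(-0.5, 0.5, length.out = 5)

  best <- NULL
  for (tau_start in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(s ~ a * (1 - exp(-t / tau)), data = points,
                        start = list(a = a0, tau = tau_start),
                        weights = w,
                        lower = c(a = -Inf, tau = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(w * stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("exponential rise fit did not converge from any start", call. = FALSE)
  fit <- best$fit
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  structure(list(coefficients = c(a = unname(cf["a"]), tau = unname(cf["tau"])),
                 cov = vc, stable = is.finite(cf["tau"]) && cf["tau"] > 0,
                 points = points, fit = fit),
            class = "rise_fit")
}

#' @export
coef.rise_fit <- function(object, ...) object$coefficients

#' @export
print.rise_fit <- function(x, ...) {
  cat(sprintf("Exponential rise fit: a = %.4g, tau = %.4g s%s\n",
              x$coefficients["a"], x$coefficients["tau"],
              if (x$stable) "" else "  [unstable]"))
  invisible(x)
}

#' @export
summary.rise_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$fit)) {
    se <- sqrt(diag(object$cov))
    cat(sprintf("  std. errors: a %.3g, tau %.3g s (%d points)\n",
                se[1], se[2], nrow(object$points)))
  }
  invisible(object)
}

#' @export
predict.rise_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$points$t else newdata$t
  a <- object$coefficients["a"]; tau <- object$coefficients["tau"]
  unname(a * (1 - exp(-t / tau)))
}
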