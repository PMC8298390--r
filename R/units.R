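#' Convert a tagged concentration to molar
#'
#' All internal computation uses SI molar units. User-facing constructors
#' accept values tagged with the common laboratory units.
#'
#' @param x numeric value(s).
#' @param unit one of `"M"`, `"mM"`, `"uM"`, `"nM"` (the micro sign is also
#'   accepted, e.g. `"µM"`).
#' @return numeric concentration in mol/L.
#' @examples
#' as_molar(400, "nM")   # 4e-7
#' as_molar(90, "uM")    # 9e-5
#' @export
as_molar <- function(x, unit = "M") {
  f <- switch(gsub("µ", "u", unit),
    "M" = 1, "mM" = 1e-3, "uM" = 1e-6, "nM" = 1e-9,
    stop("unknown concentration unit: ", unit)
  )
  x * f
}

#' Convert a tagged volume to litres
#'
#' @param x numeric value(s).
#' @param unit one of `"L"`, `"mL"`, `"uL"`, `"nL"`, `"pL"`.
#' @return numeric volume in litres.
#' @export
as_litre <- function(x, unit = "L") {
  f <- switch(gsub("µ", "u", unit),
    "L" = 1, "mL" = 1e-3, "uL" = 1e-6, "nL" = 1e-9, "pL" = 1e-12,
    stop("unknown volume unit: ", unit)
  )
  x * f
}

# internal: positivity / non-negativity checks that name the offending argument
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(name, " must be a single positive finite number", call. = FALSE)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop(name, " must be non-negative and finite", call. = FALSE)
  invisible(x)
}
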