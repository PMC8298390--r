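#' Write a spectrum to CSV with metadata header lines
#'
#' Plain two-column CSV (`wavelength_nm`, `intensity`) preceded by
#' `# key=value` comment lines carrying the tape speed and replicate count.
#'
#' @param spec a [spectrum()].
#' @param file output path.
#' @export
write_spectrum_csv <- function(spec, file) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(spec$tape_speed_mm_s))
    writeLines(sprintf("# tape_speed_mm_s=%.10g", spec$tape_speed_mm_s), con)
  writeLines(sprintf("# replicates=%d", spec$replicates), con)
  writeLines(sprintf("# speed_corrected=%s", spec$speed_corrected), con)
  utils::write.csv(data.frame(wavelength_nm = spec$wavelength_nm,
                              intensity = spec$intensity),
                   con, row.names = FALSE)
  invisible(file)
}

#' Read a spectrum written by [write_spectrum_csv()]
#' @param file input path.
#' @return a [spectrum()].
#' @export
read_spectrum_csv <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  d <- utils::read.csv(text = lines[!grepl("^#", lines)])
  sp <- spectrum(d$wavelength_nm, d$intensity,
                 tape_speed_mm_s = if (!is.null(meta$tape_speed_mm_s))
                   as.numeric(meta$tape_speed_mm_s),
                 replicates = if (!is.null(meta$replicates))
                   as.integer(meta$replicates) else 1L)
  sp$speed_corrected <- identical(meta$speed_corrected, "TRUE")
  sp
}

#' Write a component set to CSV
#' @param comps a [component_set()].
#' @param file output path; one column per component.
#' @export
write_components_csv <- function(comps, file) {
  utils::write.csv(data.frame(wavelength_nm = comps$wavelength_nm,
                              sc_diode = comps$sc_diode,
                              fl_fluo = comps$fl_fluo,
                              fl_fura_minus = comps$fl_fura_minus,
                              fl_fura_plus = comps$fl_fura_plus),
                   file, row.names = FALSE)
  invisible(file)
}

#' Read a component set from CSV
#' @param file path to a CSV as written by [write_components_csv()].
#' @return a [component_set()].
#' @export
read_components_csv <- function(file) {
  d <- utils::read.csv(file)
  component_set(d$wavelength_nm, d$sc_diode, d$fl_fluo,
                d$fl_fura_minus, d$fl_fura_plus)
}
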