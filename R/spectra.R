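#' Construct a single spectrum
#'
#' A `spectrum` is one measured curve on a strictly monotone wavelength or
#' wavenumber grid: a fluorescence emission scan, a UV-vis absorbance trace,
#' an FT-IR amide-I segment or a CD trace, depending on context.
#'
#' @param axis Numeric grid of axis values (nm or cm^-1), strictly monotone,
#'   length >= 2, all finite.
#' @param intensity Numeric signal values, same length as `axis`, all finite.
#'   Units depend on context: arbitrary fluorescence units, absorbance (AU)
#'   or millidegrees.
#' @param axis_kind Either `"wavelength_nm"` or `"wavenumber_cm-1"`.
#' @param label Free-text label carried through unchanged.
#' @return An object of class `"spectrum"`.
#' @examples
#' sp <- spectrum(300:500, dnorm(300:500, 337, 25), "wavelength_nm", "HSA")
#' peak_intensity(sp, 337)
#' @export
spectrum <- function(axis, intensity,
                     axis_kind = c("wavelength_nm", "wavenumber_cm-1"),
                     label = "") {
  axis_kind <- match.arg(axis_kind)
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) < 2L || length(axis) != length(intensity)) {
    stop("`axis` and `intensity` must have equal length >= 2", call. = FALSE)
  }
  if (!all(is.finite(axis)) || !all(is.finite(intensity))) {
    stop("spectrum contains non-finite values", call. = FALSE)
  }
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0))) {
    stop("`axis` must be strictly monotone", call. = FALSE)
  }
  structure(
    list(axis = axis, intensity = intensity, axis_kind = axis_kind,
         label = as.character(label)[1L]),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  unit <- if (x$axis_kind == "wavelength_nm") "nm" else "cm-1"
  cat(sprintf("<spectrum> %s: %d points, %.6g-%.6g %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$axis), min(x$axis), max(x$axis), unit))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Construct a titration series
#'
#' A `titration_series` holds one spectrum per ligand concentration at a
#' fixed temperature, all on a common axis grid.  The first concentration
#' must be 0 (the ligand-free reference from which F0 is taken) and
#' concentrations must be strictly increasing.
#'
#' @param temperature_K Absolute temperature in kelvin (> 0).
#' @param concentrations_M Ligand (quencher) concentrations in mol/L,
#'   non-negative, strictly increasing, first entry 0.
#' @param spectra List of [spectrum()] objects, one per concentration,
#'   sharing one axis grid.
#' @param protein_concentration_M Protein concentration in mol/L
#'   (`NA` when unknown).
#' @return An object of class `"titration_series"`.
#' @export
titration_series <- function(temperature_K, concentrations_M, spectra,
                             protein_concentration_M = NA_real_) {
  temperature_K <- as.numeric(temperature_K)[1L]
  if (!is.finite(temperature_K) || temperature_K <= 0) {
    stop("`temperature_K` must be a positive number", call. = FALSE)
  }
  concentrations_M <- as.numeric(concentrations_M)
  if (length(concentrations_M) < 1L || any(!is.finite(concentrations_M)) ||
      any(concentrations_M < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  if (concentrations_M[1L] != 0) {
    stop("first concentration must be 0 (ligand-free reference)", call. = FALSE)
  }
  if (any(diff(concentrations_M) <= 0)) {
    stop("concentrations must be strictly increasing", call. = FALSE)
  }
  if (!is.list(spectra) || length(spectra) != length(concentrations_M) ||
      !all(vapply(spectra, is_spectrum, logical(1L)))) {
    stop("`spectra` must be a list of spectrum objects, one per concentration",
         call. = FALSE)
  }
  ax <- spectra[[1L]]$axis
  same <- vapply(spectra, function(s) {
    length(s$axis) == length(ax) && all(s$axis == ax) &&
      s$axis_kind == spectra[[1L]]$axis_kind
  }, logical(1L))
  if (!all(same)) stop("all spectra must share one axis grid", call. = FALSE)
  structure(
    list(temperature_K = temperature_K,
         ligand_concentrations_M = concentrations_M,
         spectra = spectra,
         protein_concentration_M = as.numeric(protein_concentration_M)[1L]),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration_series> %d concentrations (0-%.4g M) at %g K, %d-point grid\n",
    length(x$ligand_concentrations_M), max(x$ligand_concentrations_M),
    x$temperature_K, length(x$spectra[[1L]]$axis)))
  invisible(x)
}

axis_header_name <- function(axis_kind) {
  if (axis_kind == "wavelength_nm") "nm" else "cm-1"
}

axis_kind_from_header <- function(name) {
  name <- tolower(trimws(name))
  if (name %in% c("nm", "wavelength", "wavelength_nm")) return("wavelength_nm")
  if (name %in% c("cm-1", "cm.1", "wavenumber", "wavenumber_cm-1")) {
    return("wavenumber_cm-1")
  }
  stop(sprintf("unrecognised axis column header '%s' (expected 'nm' or 'cm-1')",
               name), call. = FALSE)
}

#' Read a titration series from a delimited text file
#'
#' Expects comma-separated UTF-8 text with a "." decimal mark and one header
#' row: the first column is the axis ("nm" or "cm-1"), each remaining column
#' one spectrum, with its header giving the ligand concentration in mol/L.
#' Columns are reordered so concentrations come out ascending.
#'
#' @param path Path to the CSV file.
#' @param temperature_K Temperature of the titration in kelvin.
#' @param meta Optional list; `meta$protein_concentration_M` and
#'   `meta$label` are honoured.
#' @return A [titration_series()].
#' @seealso [write_titration_table()] for the inverse operation.
#' @export
read_titration_table <- function(path, temperature_K, meta = list()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged row %d in %s: %d fields where %d expected",
                 bad, path, nf[bad], nf[1L]), call. = FALSE)
  }
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    stop(sprintf("%s: need an axis column plus at least one spectrum column",
                 path), call. = FALSE)
  }
  axis_kind <- axis_kind_from_header(header[1L])
  conc <- suppressWarnings(as.numeric(header[-1L]))
  if (any(is.na(conc))) {
    bad <- which(is.na(conc))[1L] + 1L
    stop(sprintf("%s: header of column %d ('%s') is not a concentration in M",
                 path, bad, header[bad]), call. = FALSE)
  }
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  mat <- as.matrix(tab)
  if (!is.numeric(mat) || anyNA(mat)) {
    stop(sprintf("%s: non-numeric or missing values in table body", path),
         call. = FALSE)
  }
  axis <- mat[, 1L]
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0))) {
    stop(sprintf("%s: axis column is not strictly monotone", path),
         call. = FALSE)
  }
  ord <- order(conc)
  label <- if (!is.null(meta$label)) meta$label else ""
  spectra <- lapply(ord, function(j) {
    spectrum(axis, mat[, j + 1L], axis_kind, label)
  })
  titration_series(
    temperature_K = temperature_K,
    concentrations_M = conc[ord],
    spectra = spectra,
    protein_concentration_M =
      if (!is.null(meta$protein_concentration_M))
        meta$protein_concentration_M else NA_real_
  )
}

#' Write a titration series to a delimited text file
#'
#' Inverse of [read_titration_table()]: values are written with 15
#' significant digits so a write/read round trip reproduces the series at
#' reader precision.
#'
#' @param series A [titration_series()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_titration_table <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  num <- function(x) formatC(x, format = "g", digits = 15)
  header <- c(axis_header_name(series$spectra[[1L]]$axis_kind),
              num(series$ligand_concentrations_M))
  body <- cbind(series$spectra[[1L]]$axis,
                do.call(cbind, lapply(series$spectra, `[[`, "intensity")))
  lines <- c(paste(header, collapse = ","),
             apply(body, 1L, function(r) paste(num(r), collapse = ",")))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write to %s", path), call. = FALSE)
  invisible(path)
}

#' Intensity at the grid point nearest an axis value
#'
#' Nearest-grid-point lookup, no interpolation: on grids of <= 1 nm (or
#' 1 cm^-1) spacing the quantisation is below analysis sensitivity, and the
#' lookup is exactly reproducible.
#'
#' @param spectrum A [spectrum()].
#' @param at_axis_value Axis value to query; must lie within the axis range.
#' @return The intensity at the nearest grid point.
#' @export
peak_intensity <- function(spectrum, at_axis_value) {
  stopifnot(is_spectrum(spectrum))
  at_axis_value <- as.numeric(at_axis_value)[1L]
  rng <- range(spectrum$axis)
  if (!is.finite(at_axis_value) || at_axis_value < rng[1L] ||
      at_axis_value > rng[2L]) {
    stop(sprintf("axis value %g outside spectrum range [%g, %g]",
                 at_axis_value, rng[1L], rng[2L]), call. = FALSE)
  }
  spectrum$intensity[which.min(abs(spectrum$axis - at_axis_value))]
}

#' Peak ratios F0/F of a titration at a fixed emission position
#'
#' Extracts the quenching trace used by the Stern-Volmer and double-log
#' fits: the emission maximum of the ligand-free spectrum fixes one grid
#' point, and every member of the titration is read at that same point.
#' Reading all members at a fixed position avoids conflating peak shifts
#' with quenching.
#'
#' @param series A [titration_series()].
#' @param at Optional axis position; default is the argmax of the
#'   ligand-free (first) spectrum.
#' @return A data frame with columns `concentration_M`, `F`, `F0F`.
#' @export
quench_ratios <- function(series, at = NULL) {
  stopifnot(inherits(series, "titration_series"))
  ref <- series$spectra[[1L]]
  if (is.null(at)) at <- ref$axis[which.max(ref$intensity)]
  f <- vapply(series$spectra, peak_intensity, numeric(1L),
              at_axis_value = at)
  data.frame(concentration_M = series$ligand_concentrations_M,
             F = f, F0F = f[1L] / f)
}
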