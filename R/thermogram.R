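#' Construct a DSC thermogram
#'
#' A thermogram is a tibble with columns `temperature` (kelvin) and `cp`
#' (molar excess heat capacity, kcal mol^-1 K^-1), one row per instrument
#' reading, stored in recorded scan order. Heating scans have a strictly
#' increasing grid, cooling scans a strictly decreasing one; the scan
#' direction is kept as an attribute and inferred from the grid ordering.
#'
#' @param x A data frame with at least two numeric columns; the first two are
#'   taken as temperature and heat capacity (or columns named `temperature`
#'   and `cp`).
#' @param units Temperature unit of the input, `"kelvin"` or `"celsius"`.
#'   Celsius values are converted by adding 273.15; internally the grid is
#'   always kelvin.
#' @param label Optional free-text label (protein, solvent, source).
#'
#' @return A tibble of class `dsc_thermogram` with columns `temperature`
#'   (kelvin) and `cp`, and attributes `scan_direction` and `label`.
#' @export
#' @examples
#' as_thermogram(data.frame(temperature = 25:30, cp = 0), units = "celsius")
as_thermogram <- function(x, units = c("kelvin", "celsius"), label = NULL) {
  units <- match.arg(units)
  x <- as.data.frame(x)
  if (all(c("temperature", "cp") %in% names(x))) {
    temperature <- x[["temperature"]]
    cp <- x[["cp"]]
  } else {
    if (ncol(x) < 2) abort("need two columns: temperature and cp")
    temperature <- x[[1]]
    cp <- x[[2]]
  }
  temperature <- as.numeric(temperature)
  cp <- as.numeric(cp)
  if (units == "celsius") temperature <- temperature + .C0
  new_thermogram(temperature, cp, label = label)
}

new_thermogram <- function(temperature, cp, label = NULL) {
  validate_thermogram(temperature, cp)
  direction <- if (temperature[2] > temperature[1]) "heating" else "cooling"
  out <- new_tibble(
    list(temperature = temperature, cp = cp),
    nrow = length(temperature),
    class = "dsc_thermogram"
  )
  attr(out, "scan_direction") <- direction
  attr(out, "label") <- label
  out
}

validate_thermogram <- function(temperature, cp) {
  if (length(temperature) != length(cp)) {
    abort("temperature and cp must have equal length")
  }
  if (length(temperature) < 3) {
    abort("a thermogram needs at least 3 grid points")
  }
  if (anyNA(temperature) || anyNA(cp)) {
    abort("temperature and cp must be numeric without missing values")
  }
  if (any(temperature <= 0)) {
    abort("all temperatures must be > 0 K (did you mean units = \"celsius\"?)")
  }
  d <- diff(temperature)
  if (!(all(d > 0) || all(d < 0))) {
    abort("temperature grid must be strictly monotone (one scan direction)")
  }
  invisible(TRUE)
}

#' Scan direction of a thermogram
#'
#' @param x A `dsc_thermogram`.
#' @return `"heating"` or `"cooling"`.
#' @export
scan_direction <- function(x) {
  attr(x, "scan_direction") %||% if (x$temperature[2] > x$temperature[1]) "heating" else "cooling"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a DSC thermogram from a delimited text file
#'
#' Reads a two-column numeric file (temperature, excess heat capacity).
#' The delimiter is auto-detected among comma, tab and semicolon; an optional
#' single header line is skipped. Decimal points only (no locale commas).
#' A header written by [write_thermogram()] (`temperature_K`) forces kelvin
#' regardless of `units`.
#'
#' @param path File to read.
#' @param units Temperature unit of the file, `"kelvin"` or `"celsius"`.
#' @inheritParams as_thermogram
#' @return A [as_thermogram()] tibble; scan direction is inferred from the
#'   grid ordering as recorded in the file.
#' @export
read_thermogram <- function(path, units = c("kelvin", "celsius"), label = NULL) {
  units <- match.arg(units)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("empty thermogram file: ", path))

  sep <- detect_delimiter(lines[[1]])
  first <- strsplit(trimws(lines[[1]]), sep, fixed = TRUE)[[1]]
  has_header <- suppressWarnings(anyNA(as.numeric(first[1:2])))
  if (has_header && grepl("temperature_K", lines[[1]], fixed = TRUE)) {
    units <- "kelvin"
  }
  body <- if (has_header) lines[-1] else lines
  if (length(body) < 3) abort("a thermogram needs at least 3 grid points")

  rows <- strsplit(trimws(body), sep, fixed = TRUE)
  offset <- if (has_header) 1L else 0L
  parsed <- vapply(seq_along(rows), function(i) {
    f <- rows[[i]]
    if (length(f) < 2) {
      abort(sprintf("line %d of %s: expected 2 delimited fields", i + offset, path))
    }
    v <- suppressWarnings(as.numeric(f[1:2]))
    if (anyNA(v)) {
      abort(sprintf("line %d of %s: non-numeric value '%s'",
                    i + offset, path, paste(f[1:2], collapse = sep)))
    }
    v
  }, numeric(2))

  as_thermogram(
    data.frame(temperature = parsed[1, ], cp = parsed[2, ]),
    units = units, label = label
  )
}

detect_delimiter <- function(line) {
  counts <- vapply(c(",", "\t", ";"), function(s) {
    lengths(regmatches(line, gregexpr(s, line, fixed = TRUE)))
  }, integer(1))
  if (all(counts == 0)) {
    # fall back to whitespace-separated columns
    return(" ")
  }
  names(counts)[which.max(counts)]
}

#' Write a thermogram to CSV
#'
#' Writes `temperature_K,cp_kcal_per_mol_K` at full double precision (17
#' significant digits) so that a write/read cycle round-trips bit-identically.
#' Rows keep the recorded scan order (descending temperature for cooling
#' scans).
#'
#' @param thermogram A `dsc_thermogram`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_thermogram <- function(thermogram, path) {
  stopifnot(is.data.frame(thermogram))
  validate_thermogram(thermogram$temperature, thermogram$cp)
  lines <- c(
    "temperature_K,cp_kcal_per_mol_K",
    paste(sprintf("%.17g", thermogram$temperature),
          sprintf("%.17g", thermogram$cp), sep = ",")
  )
  tryCatch(
    writeLines(lines, path),
    error = function(e) abort(paste0("cannot write thermogram to ", path, ": ",
                                     conditionMessage(e)))
  )
  invisible(path)
}

#' Define a transition window
#'
#' A transition window brackets one unfolding transition by its begin,
#' midpoint and end temperatures (kelvin). For cooling scans `t_ini` may
#' exceed `t_end`; the midpoint must lie strictly between the two ends.
#'
#' @param t_ini,t_m,t_end Temperatures in kelvin.
#' @return A one-row tibble of class `transition_window`.
#' @export
#' @examples
#' transition_window(318, 335, 346)
transition_window <- function(t_ini, t_m, t_end) {
  stopifnot(is.numeric(t_ini), is.numeric(t_m), is.numeric(t_end))
  if (!(min(t_ini, t_end) < t_m && t_m < max(t_ini, t_end))) {
    abort("t_m must lie strictly between t_ini and t_end")
  }
  new_tibble(
    list(t_ini = as.numeric(t_ini), t_m = as.numeric(t_m),
         t_end = as.numeric(t_end)),
    nrow = 1L, class = "transition_window"
  )
}

#' Crop a thermogram to a transition window
#'
#' Keeps the grid points with temperatures between `t_ini` and `t_end`
#' (inclusive), preserving the recorded scan order.
#'
#' @param thermogram A `dsc_thermogram`.
#' @param window A [transition_window()] (or anything with `t_ini`/`t_end`).
#' @return The cropped `dsc_thermogram`.
#' @export
crop <- function(thermogram, window) {
  lo <- min(window$t_ini, window$t_end)
  hi <- max(window$t_ini, window$t_end)
  keep <- thermogram$temperature >= lo & thermogram$temperature <= hi
  if (sum(keep) < 3) {
    abort("window does not overlap the thermogram grid (or leaves < 3 points)")
  }
  new_thermogram(thermogram$temperature[keep], thermogram$cp[keep],
                 label = attr(thermogram, "label"))
}

#' Read model parameters from a flat key=value config file
#'
#' Recognised keys follow the field names of the parameter records:
#' `dH0_kcal_mol`, `Tm_K`, `dCp0_kcal_molK` (chemical-equilibrium two-state);
#' `dE0_kcal_mol`, `Tm_K`, `Cv_kcal_molK` (statistical-mechanical two-state);
#' `h0_kcal_mol`, `cv_res_cal_molK` or `cv_res_kcal_molK`, `sigma`, `N`,
#' `Tm_K` (Zimm-Bragg). Per-residue heat capacities carry an explicit unit
#' suffix; `cal` values are converted to kcal internally.
#'
#' @param path Config file, one `key = value` pair per line; `#` comments and
#'   blank lines are ignored.
#' @return A parameter record ([equilibrium_params()], [stat_params()] or
#'   [zimm_bragg_params()]) depending on which keys are present.
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    abort(sprintf("config %s: line '%s' is not key=value", path,
                  lines[which(bad)[1]]))
  }
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2))))
  if (anyNA(vals)) {
    abort(sprintf("config %s: non-numeric value for key '%s'", path,
                  keys[which(is.na(vals))[1]]))
  }
  p <- as.list(setNames(vals, keys))

  if (!is.null(p$h0_kcal_mol)) {
    cv_res <- if (!is.null(p$cv_res_kcal_molK)) {
      p$cv_res_kcal_molK
    } else if (!is.null(p$cv_res_cal_molK)) {
      p$cv_res_cal_molK / 1000
    } else {
      abort("Zimm-Bragg config needs cv_res_cal_molK or cv_res_kcal_molK")
    }
    return(zimm_bragg_params(h0 = p$h0_kcal_mol, cv_res = cv_res,
                             sigma = p$sigma, n_res = p$N, t_m = p$Tm_K))
  }
  if (!is.null(p$dE0_kcal_mol)) {
    return(stat_params(dE0 = p$dE0_kcal_mol, t_m = p$Tm_K,
                       cv = p$Cv_kcal_molK))
  }
  if (!is.null(p$dH0_kcal_mol)) {
    return(equilibrium_params(dH0 = p$dH0_kcal_mol, t_m = p$Tm_K,
                              cp_step = p$dCp0_kcal_molK))
  }
  abort(sprintf("config %s: no recognised parameter keys", path))
}

#' @export
print.dsc_thermogram <- function(x, ...) {
  dir <- scan_direction(x)
  lab <- attr(x, "label")
  cat(sprintf("<DSC thermogram>  %d points, %.2f-%.2f K, %s scan%s\n",
              nrow(x), min(x$temperature), max(x$temperature), dir,
              if (is.null(lab)) "" else paste0(", ", lab)))
  NextMethod()
}
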