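#' Write a helical ensemble to CSV
#'
#' Full-precision CSV with a mandatory `# units:` header line plus
#' `# n_bp:` and `# temperature:` metadata, readable by [read_series()].
#' Values are written with 17 significant digits so that a write/read
#' round trip is bit-exact.
#'
#' @param ensemble A [helical_ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(ensemble, path) {
  if (!inherits(ensemble, "helical_ensemble"))
    stop("'ensemble' must be a helical_ensemble")
  lab <- ensemble$coordinate_label
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# units: twist=deg, %s=nm", lab),
               sprintf("# n_bp: %d", ensemble$n_bp),
               sprintf("# temperature: %g", ensemble$temperature),
               sprintf("snapshot,twist,%s", lab)), con)
  writeLines(sprintf("%d,%.17g,%.17g", seq_len(nrow(ensemble$records)),
                     ensemble$records$twist, ensemble$records$conj), con)
  invisible(path)
}

parse_header <- function(lines, key) {
  pat <- paste0("^#\\s*", key, ":\\s*")
  hit <- grep(pat, lines, value = TRUE)
  if (!length(hit)) return(NULL)
  trimws(sub(pat, "", hit[1]))
}

#' Read a helical-parameter series file
#'
#' Two dialects are supported.
#'
#' `format = "csv"`: comma-separated columns with a header row naming a
#' `twist` column and a conjugate-coordinate column (`groove_width` or
#' `diameter`), plus a mandatory `# units:` comment declaring `twist=deg`
#' and the conjugate unit `nm`.  Silent unit guessing is refused.
#' Optional `# n_bp:` and `# temperature:` comments carry metadata.
#'
#' `format = "curves_series"`: the whitespace-separated matrix layout of a
#' helical-parameter analysis program -- one row per snapshot, one column
#' per base-pair level.  One file holds one parameter, so `path` must be a
#' named character vector of two files, e.g.
#' `c(twist = "tw.ser", groove_width = "gw.ser")`; units are deg and nm by
#' convention of that layout.  `column_map` selects the level column for
#' each file, or `"average"` (default) to chain-average all levels.
#'
#' @param path File path (CSV) or named two-element vector (curves series).
#' @param format `"csv"` or `"curves_series"`.
#' @param column_map Optional mapping of roles to column names/indices:
#'   for CSV a named character vector like
#'   `c(twist = "Twist", groove_width = "W12")`; for curves series a list
#'   with per-role column index or `"average"`.
#' @param row_range Optional `(start, end)` snapshot rows to keep.
#' @param n_bp,temperature Metadata overrides (CSV headers win if present).
#' @return A [helical_ensemble()].
#' @export
read_series <- function(path, format = c("csv", "curves_series"),
                        column_map = NULL, row_range = NULL,
                        n_bp = 1, temperature = 295) {
  format <- match.arg(format)
  if (format == "csv")
    read_series_csv(path, column_map, row_range, n_bp, temperature)
  else
    read_series_curves(path, column_map, row_range, n_bp, temperature)
}

read_series_csv <- function(path, column_map, row_range, n_bp, temperature) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  units_raw <- parse_header(lines, "units")
  if (is.null(units_raw))
    stop("missing '# units:' header; units are never guessed")
  units <- strsplit(strsplit(units_raw, ",")[[1]], "=")
  units <- stats::setNames(trimws(vapply(units, `[`, "", 2)),
                           trimws(vapply(units, `[`, "", 1)))
  hdr_nbp <- parse_header(lines, "n_bp")
  if (!is.null(hdr_nbp)) n_bp <- as.integer(hdr_nbp)
  hdr_T <- parse_header(lines, "temperature")
  if (!is.null(hdr_T)) temperature <- as.numeric(hdr_T)
  d <- utils::read.csv(text = lines[!grepl("^#", lines)],
                       check.names = FALSE)
  tw_col <- if (!is.null(column_map) && "twist" %in% names(column_map))
    column_map[["twist"]] else "twist"
  conj_role <- intersect(c("groove_width", "diameter"),
                         c(names(column_map), names(d)))
  if (!length(conj_role))
    stop("no groove_width or diameter column identified")
  conj_role <- conj_role[1]
  cj_col <- if (!is.null(column_map) && conj_role %in% names(column_map))
    column_map[[conj_role]] else conj_role
  for (col in c(tw_col, cj_col))
    if (!col %in% names(d)) stop("missing column: ", col)
  if (is.na(units[tw_col]) || units[tw_col] != "deg")
    stop("twist column must be declared 'deg' in the units header")
  if (is.na(units[cj_col]) || units[cj_col] != "nm")
    stop("conjugate column must be declared 'nm' in the units header")
  tw <- d[[tw_col]]; cj <- d[[cj_col]]
  if (!is.numeric(tw) || !is.numeric(cj))
    stop("non-numeric cells in the series columns")
  if (!is.null(row_range)) {
    if (row_range[1] < 1 || row_range[2] > length(tw))
      stop("'row_range' outside the file")
    keep <- seq(row_range[1], row_range[2])
    tw <- tw[keep]; cj <- cj[keep]
  }
  helical_ensemble(tw, cj, n_bp = n_bp, temperature = temperature,
                   coordinate_label = conj_role,
                   conditions = list(source = path))
}

read_series_curves <- function(path, column_map, row_range, n_bp,
                               temperature) {
  if (length(path) != 2 || is.null(names(path)))
    stop("curves-series input needs a named two-element path vector, ",
         "e.g. c(twist = ..., groove_width = ...)")
  if (!"twist" %in% names(path))
    stop("one curves-series path must be named 'twist'")
  conj_role <- setdiff(names(path), "twist")
  if (!conj_role %in% c("groove_width", "diameter"))
    stop("second curves-series path must be named 'groove_width' or 'diameter'")
  pick <- function(role) {
    f <- path[[role]]
    if (!file.exists(f)) stop("file not found: ", f)
    m <- as.matrix(utils::read.table(f, comment.char = "#"))
    if (!is.numeric(m)) stop("non-numeric cells in ", f)
    sel <- if (!is.null(column_map) && !is.null(column_map[[role]]))
      column_map[[role]] else "average"
    if (identical(sel, "average")) rowMeans(m) else m[, sel]
  }
  tw <- pick("twist"); cj <- pick(conj_role)
  if (length(tw) != length(cj))
    stop("twist and conjugate series have different snapshot counts")
  if (!is.null(row_range)) {
    if (row_range[1] < 1 || row_range[2] > length(tw))
      stop("'row_range' outside the file")
    keep <- seq(row_range[1], row_range[2])
    tw <- tw[keep]; cj <- cj[keep]
  }
  helical_ensemble(tw, cj, n_bp = n_bp, temperature = temperature,
                   coordinate_label = conj_role,
                   conditions = list(source = unname(path["twist"])))
}

#' Write a whitespace-matrix series file
#'
#' One row per snapshot, one column per base-pair level, the layout read
#' back by `read_series(format = "curves_series")`.
#'
#' @param m Numeric matrix (snapshots x levels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves_series <- function(m, path) {
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = FALSE),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a harmonic fit as JSON with units recorded per field
#'
#' @param fit A [fit_harmonic2d()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonic_fit <- function(fit, path) {
  if (!inherits(fit, "harmonic_fit")) stop("'fit' must be a harmonic_fit")
  cc <- fit$constants
  out <- list(
    k_omega = list(value = cc$k_omega, units = "kBT/deg^2 per bp"),
    k_conj = list(value = cc$k_conj, units = "kBT/nm^2 per bp"),
    k_cross = list(value = cc$k_cross, units = "kBT/(deg nm) per bp"),
    omega0 = list(value = cc$omega0, units = "deg"),
    conj0 = list(value = cc$conj0, units = "nm"),
    coordinate_label = cc$coordinate_label,
    n_bp_used = fit$n_bp_used,
    residual_rms = list(value = fit$residual_rms, units = "kBT"),
    n_bins_used = fit$n_bins_used)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a response curve as CSV with a provenance header
#'
#' @param curve A `response_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_response_curve <- function(curve, path) {
  if (!inherits(curve, "response_curve"))
    stop("'curve' must be a response_curve")
  cc <- curve$constants
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# stimulus: %s", curve$stimulus_type),
    sprintf("# constants: k_omega=%g kBT/deg^2, k_conj=%g kBT/nm^2, k_cross=%g kBT/(deg nm) [%s]",
            cc$k_omega, cc$k_conj, cc$k_cross, cc$coordinate_label),
    sprintf("# driver: %s",
            paste(names(curve$driver_params),
                  unlist(curve$driver_params), sep = "=", collapse = ", "))),
    con)
  utils::write.csv(curve$data, con, row.names = FALSE)
  invisible(path)
}
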