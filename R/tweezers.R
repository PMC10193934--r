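#' Rotation-extension curve from a magnetic-tweezers measurement
#'
#' @param turns Magnet rotations, turns; strictly increasing.
#' @param extension Tether extensions, micrometre.
#' @param condition Free-form condition labels (named list).
#' @return An object of class `rotation_extension_curve`.
#' @export
rotation_extension_curve <- function(turns, extension, condition = list()) {
  turns <- as.numeric(turns); extension <- as.numeric(extension)
  if (length(turns) != length(extension))
    stop("'turns' and 'extension' must have equal length")
  if (any(diff(turns) <= 0)) stop("'turns' must be strictly increasing")
  structure(list(turns = turns, extension = extension,
                 condition = condition),
            class = "rotation_extension_curve")
}

#' @export
print.rotation_extension_curve <- function(x, ...) {
  cat("Rotation-extension curve:", length(x$turns), "points, turns in [",
      min(x$turns), ",", max(x$turns), "]\n")
  invisible(x)
}

#' @export
plot.rotation_extension_curve <- function(x, ...) {
  graphics::plot(x$turns, x$extension, xlab = "turns",
                 ylab = "extension (um)", ...)
  invisible(x)
}

#' Read a two-column rotation-extension file
#'
#' Whitespace- or comma-separated text with two columns (turns, extension
#' in micrometre); `#` starts a comment.
#'
#' @param path File path.
#' @param condition Free-form condition labels.
#' @return A [rotation_extension_curve()].
#' @export
read_rotation_extension <- function(path, condition = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, comment.char = "#", sep = "",
                         col.names = c("turns", "extension"))
  rotation_extension_curve(d$turns, d$extension, condition)
}

#' Locate the torsion-relaxed point of a rotation-extension curve
#'
#' Fits ordinary-least-squares lines to the negative- and
#' positive-plectoneme regions of a bell-shaped rotation-extension curve
#' and reports their crossing as the torsion-relaxed point.  When no
#' windows are supplied they are auto-selected as `[apex - 20, apex - 5]`
#' and `[apex + 5, apex + 20]` turns around the arg-max extension: the
#' region within `apex_exclusion` turns of the apex is flat and
#' uninformative and is excluded.
#'
#' @param curve A [rotation_extension_curve()].
#' @param windows Optional list of two length-2 turn intervals
#'   `list(left, right)`.
#' @param apex_exclusion Half-width of the excluded apex region, turns
#'   (default 5).
#' @param window_span Outer reach of the auto-windows from the apex,
#'   turns (default 20).
#' @return An object of class `torsion_fit`: `center_turn`, `left_line`
#'   and `right_line` as `(slope, intercept)`, and the windows used.
#' @export
#' @examples
#' cur <- synth_rotation_extension(7, noise_sd = 0, seed = 1)
#' fit_torsion_relaxed(cur)$center_turn
fit_torsion_relaxed <- function(curve, windows = NULL, apex_exclusion = 5,
                                window_span = 20) {
  if (!inherits(curve, "rotation_extension_curve"))
    stop("'curve' must be a rotation_extension_curve")
  if (is.null(windows)) {
    apex <- curve$turns[which.max(curve$extension)]
    windows <- list(c(apex - window_span, apex - apex_exclusion),
                    c(apex + apex_exclusion, apex + window_span))
  }
  fit_line <- function(win, side) {
    sel <- curve$turns >= win[1] & curve$turns <= win[2]
    if (sum(sel) < 4)
      stop("fewer than 4 points in the ", side, " window [",
           win[1], ", ", win[2], "]")
    co <- stats::coef(stats::lm(curve$extension[sel] ~ curve$turns[sel]))
    c(slope = unname(co[2]), intercept = unname(co[1]))
  }
  left <- fit_line(windows[[1]], "left")
  right <- fit_line(windows[[2]], "right")
  if (left["slope"] <= 0)
    stop("left (negative-plectoneme) slope is not positive")
  if (right["slope"] >= 0)
    stop("right (positive-plectoneme) slope is not negative")
  ds <- left["slope"] - right["slope"]
  if (abs(ds) < 1e-12) stop("plectoneme lines are parallel")
  center <- unname((right["intercept"] - left["intercept"]) / ds)
  structure(list(center_turn = center, left_line = left,
                 right_line = right, window_left = windows[[1]],
                 window_right = windows[[2]],
                 condition = curve$condition),
            class = "torsion_fit")
}

#' @export
print.torsion_fit <- function(x, ...) {
  cat(sprintf("Torsion-relaxed point: %.3f turns\n", x$center_turn))
  cat(sprintf("  left line:  slope %+.4f um/turn over [%g, %g]\n",
              x$left_line["slope"], x$window_left[1], x$window_left[2]))
  cat(sprintf("  right line: slope %+.4f um/turn over [%g, %g]\n",
              x$right_line["slope"], x$window_right[1], x$window_right[2]))
  invisible(x)
}

#' @export
coef.torsion_fit <- function(object, ...) {
  c(center_turn = object$center_turn,
    left_slope = unname(object$left_line["slope"]),
    right_slope = unname(object$right_line["slope"]))
}

#' Convert a turn count to a per-base-pair twist change
#'
#' `delta_omega = n_turn * 360 / n_bp` degrees per bp: a small twist change
#' accumulated over every base pair of a long tether appears as a
#' macroscopic rotation of its end.
#'
#' @param n_turn Number of turns (signed).
#' @param n_bp Number of base pairs in the tether (e.g. 1.36e4 for the
#'   duplex used in the rotation experiments).
#' @return Twist change, deg/bp.
#' @export
#' @examples
#' turns_to_twist(1, 13600)  # 0.0265 deg/bp
turns_to_twist <- function(n_turn, n_bp) {
  if (!is.numeric(n_bp) || n_bp <= 0) stop("'n_bp' must be positive")
  n_turn * 360 / n_bp
}

#' Twist change between two measured conditions
#'
#' Difference of torsion-relaxed points converted to deg/bp,
#' `turns_to_twist(center_b - center_a, n_bp)`.  Either argument may be a
#' list of replicate `torsion_fit`s for the same condition; the mean centre
#' is then used and the replicate standard deviation is propagated.
#'
#' @param fit_a,fit_b `torsion_fit` objects (or lists of replicates).
#' @param n_bp Number of base pairs in the tether.
#' @return A list with `delta_twist` (deg/bp) and `sd` (deg/bp; `NA`
#'   without replicates).
#' @export
shift_between_conditions <- function(fit_a, fit_b, n_bp) {
  centers <- function(f) {
    if (inherits(f, "torsion_fit")) return(f$center_turn)
    if (is.list(f) && all(vapply(f, inherits, logical(1), "torsion_fit")))
      return(vapply(f, function(z) z$center_turn, numeric(1)))
    stop("arguments must be torsion_fit objects or lists of them")
  }
  ca <- centers(fit_a); cb <- centers(fit_b)
  var_turn <- 0
  if (length(ca) > 1) var_turn <- var_turn + stats::var(ca) / length(ca)
  if (length(cb) > 1) var_turn <- var_turn + stats::var(cb) / length(cb)
  list(delta_twist = turns_to_twist(mean(cb) - mean(ca), n_bp),
       sd = if (length(ca) > 1 || length(cb) > 1)
         turns_to_twist(sqrt(var_turn), n_bp) else NA_real_)
}
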