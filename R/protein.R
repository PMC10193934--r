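#' Construct a deformation record directly
#'
#' @param delta_twist Twist deformation, deg.
#' @param delta_conj Conjugate-coordinate deformation, nm.
#' @param sd_twist,sd_conj Thermal-fluctuation standard deviations of the
#'   standalone duplex (> 0), deg and nm.
#' @param label Free-form identifier (e.g. a complex PDB ID).
#' @param coordinate_label `"groove_width"` or `"diameter"`.
#' @return An object of class `deformation_record`.
#' @export
deformation_record <- function(delta_twist, delta_conj, sd_twist, sd_conj,
                               label = "",
                               coordinate_label = c("groove_width",
                                                    "diameter")) {
  coordinate_label <- match.arg(coordinate_label)
  if (sd_twist <= 0 || sd_conj <= 0)
    stop("standard deviations must be positive")
  structure(list(delta_twist = delta_twist, delta_conj = delta_conj,
                 sd_twist = sd_twist, sd_conj = sd_conj, label = label,
                 coordinate_label = coordinate_label),
            class = "deformation_record")
}

#' Deformation of a duplex in complex relative to its standalone form
#'
#' Differences of mean twist and mean conjugate coordinate between a
#' complex ensemble and the corresponding standalone-duplex ensemble, with
#' the thermal-fluctuation standard deviations taken from the standalone
#' series (the natural scale of each coordinate's flexibility).
#'
#' @param complex_series,standalone_series [helical_ensemble()] objects
#'   with matching `coordinate_label`.
#' @param label Free-form identifier (e.g. a complex PDB ID).
#' @return An object of class `deformation_record` with fields
#'   `delta_twist` (deg), `delta_conj` (nm), `sd_twist`, `sd_conj`,
#'   `label`, `coordinate_label`.
#' @export
delta_vs_standalone <- function(complex_series, standalone_series,
                                label = "") {
  if (!inherits(complex_series, "helical_ensemble") ||
      !inherits(standalone_series, "helical_ensemble"))
    stop("both series must be helical_ensemble objects")
  if (complex_series$coordinate_label != standalone_series$coordinate_label)
    stop("coordinate_label mismatch: ", complex_series$coordinate_label,
         " vs ", standalone_series$coordinate_label)
  sd_t <- stats::sd(standalone_series$records$twist)
  sd_c <- stats::sd(standalone_series$records$conj)
  if (!is.finite(sd_t) || sd_t <= 0 || !is.finite(sd_c) || sd_c <= 0)
    stop("standalone series has degenerate fluctuations")
  structure(list(
    delta_twist = mean(complex_series$records$twist) -
      mean(standalone_series$records$twist),
    delta_conj = mean(complex_series$records$conj) -
      mean(standalone_series$records$conj),
    sd_twist = sd_t, sd_conj = sd_c, label = label,
    coordinate_label = complex_series$coordinate_label),
    class = "deformation_record")
}

#' @export
print.deformation_record <- function(x, ...) {
  cat(sprintf(
    "Deformation %s: d_twist = %+.4f deg (sd %.4f), d_%s = %+.5f nm (sd %.5f)\n",
    if (nzchar(x$label)) x$label else "record", x$delta_twist, x$sd_twist,
    x$coordinate_label, x$delta_conj, x$sd_conj))
  invisible(x)
}

#' Normalize a deformation by the thermal fluctuation scales
#'
#' Divides the twist and conjugate-coordinate deformations by the
#' standalone-duplex standard deviations, removing the sequence-dependent
#' flexibility scale from each coordinate.
#'
#' @param rec A [delta_vs_standalone()] record.
#' @return Named numeric `c(twist = delta_twist/sd_twist,
#'   conj = delta_conj/sd_conj)`, dimensionless.
#' @export
normalize_record <- function(rec) {
  if (!inherits(rec, "deformation_record"))
    stop("'rec' must be a deformation_record")
  if (rec$sd_twist <= 0 || rec$sd_conj <= 0)
    stop("standard deviations must be positive")
  c(twist = rec$delta_twist / rec$sd_twist,
    conj = rec$delta_conj / rec$sd_conj)
}

#' Alignment of deformations with the soft coupling direction
#'
#' In fluctuation-normalized coordinates `(d_twist/sd_twist,
#' d_conj/sd_conj)` the cheapest deformation direction is the eigenvector
#' of the normalized stiffness matrix `diag(sd) K diag(sd)` with the
#' smaller eigenvalue (the soft mode).  Each record's cosine against that
#' direction measures how closely its deformation follows the coupling
#' pathway; the summary is the mean absolute cosine.
#'
#' The soft mode is oriented with a non-negative twist component, so that
#' for positive cross-coupling a deformation with increased twist and
#' compressed conjugate coordinate scores a positive cosine.
#'
#' @param records A `deformation_record` or list of them.
#' @param constants A positive-definite [coupling_constants()].
#' @return A list with per-record `cosines`, `mean_abs_cosine`, and the
#'   per-record normalized `soft_modes` (2 x n matrix), plus the
#'   `direction` label recorded in the output.
#' @export
coupling_alignment <- function(records, constants) {
  if (inherits(records, "deformation_record")) records <- list(records)
  if (!length(records)) stop("'records' must be nonempty")
  if (!all(vapply(records, inherits, logical(1), "deformation_record")))
    stop("'records' must be deformation_record objects")
  if (!inherits(constants, "coupling_constants"))
    stop("'constants' must be a coupling_constants object")
  K <- stiffness_matrix(constants)
  cosines <- numeric(length(records))
  modes <- matrix(NA_real_, 2, length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    D <- diag(c(r$sd_twist, r$sd_conj))
    Kn <- D %*% K %*% D
    eg <- eigen(Kn, symmetric = TRUE)
    if (abs(eg$values[1] - eg$values[2]) <=
        1e-10 * max(abs(eg$values)))
      stop("normalized stiffness is isotropic; soft mode undefined")
    soft <- eg$vectors[, 2]  # smaller eigenvalue last for symmetric eigen
    if (soft[1] < 0 || (soft[1] == 0 && soft[2] < 0)) soft <- -soft
    u <- normalize_record(r)
    nu <- sqrt(sum(u^2))
    cosines[i] <- if (nu == 0) NA_real_ else sum(u * soft) / nu
    modes[, i] <- soft
  }
  list(cosines = cosines,
       mean_abs_cosine = mean(abs(cosines), na.rm = TRUE),
       soft_modes = modes, direction = "soft_mode_normalized_precision")
}

#' Collapse of deformation pathways in the (conjugate, twist) plane
#'
#' Interpolates each pathway's twist onto a common conjugate-coordinate
#' grid over the mutual overlap and returns the root-mean-square
#' across-pathway deviation, divided by the twist range of the pooled
#' (across-pathway mean) curve over the overlap so that the spread is
#' linear in a constant twist offset between pathways.  Pathways that
#' follow one underlying coupling line score near zero.
#'
#' @param curves List of pathways: `response_curve` objects or data frames
#'   with columns `conj` and `twist`.
#' @param n_grid Number of interpolation points (default 50).
#' @return Dimensionless spread (0 for identical pathways).
#' @export
collapse_metric <- function(curves, n_grid = 50) {
  if (!is.list(curves) || length(curves) < 2)
    stop("need at least 2 pathways")
  paths <- lapply(curves, function(cv) {
    if (inherits(cv, "response_curve"))
      cv <- data.frame(conj = cv$data$delta_conj, twist = cv$data$delta_twist)
    cv <- as.data.frame(cv)
    if (!all(c("conj", "twist") %in% names(cv)))
      stop("each pathway needs 'conj' and 'twist' columns")
    cv[order(cv$conj), ]
  })
  lo <- max(vapply(paths, function(p) min(p$conj), numeric(1)))
  hi <- min(vapply(paths, function(p) max(p$conj), numeric(1)))
  if (lo >= hi) stop("pathways have no overlapping conjugate range")
  grid <- seq(lo, hi, length.out = n_grid)
  tw <- vapply(paths, function(p)
    stats::approx(p$conj, p$twist, xout = grid, ties = mean)$y,
    numeric(n_grid))
  mid <- rowMeans(tw)
  dev <- tw - mid
  if (all(dev == 0)) return(0)
  rng <- diff(range(mid))
  if (rng == 0) stop("pooled pathway has zero twist range over the overlap")
  sqrt(mean(dev^2)) / rng
}
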