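#' One-dimensional potential of mean force
#'
#' @param grid Coordinate grid (bin midpoints), strictly increasing.
#' @param values Free energy in kBT, min-referenced over occupied bins;
#'   `NA` marks empty bins.
#' @param counts Optional bin counts (NULL for analytic profiles).
#' @param temperature Kelvin.
#' @param coordinate_label `"twist"` or `"conj"`.
#' @return An object of class `pmf1d`.
#' @export
pmf1d <- function(grid, values, counts = NULL, temperature = 295,
                  coordinate_label = "twist") {
  grid <- as.numeric(grid); values <- as.numeric(values)
  if (length(grid) != length(values)) stop("'grid' and 'values' lengths differ")
  if (any(diff(grid) <= 0)) stop("'grid' must be strictly increasing")
  structure(list(grid = grid, values = values, counts = counts,
                 temperature = temperature,
                 coordinate_label = coordinate_label),
            class = "pmf1d")
}

#' @export
print.pmf1d <- function(x, ...) {
  occ <- sum(!is.na(x$values))
  cat("1-D PMF over", x$coordinate_label, ":", length(x$grid), "bins (",
      occ, "occupied ),", x$temperature, "K\n")
  cat(sprintf("  minimum at %s = %.4f\n", x$coordinate_label,
              x$grid[which.min(x$values)]))
  invisible(x)
}

#' @export
plot.pmf1d <- function(x, ...) {
  graphics::plot(x$grid, x$values, xlab = x$coordinate_label,
                 ylab = "PMF (kBT)", ...)
  invisible(x)
}

#' Construct a 2-D PMF from precomputed values
#'
#' Wraps an externally computed (or analytic) free-energy surface in the
#' `pmf2d` container used by [fit_harmonic2d()].  Values are re-referenced
#' so the occupied-bin minimum is zero.
#'
#' @param twist_mid,conj_mid Bin midpoints, strictly increasing.
#' @param values Matrix of free energies in kBT
#'   (`length(twist_mid) x length(conj_mid)`); `NA` marks empty bins.
#' @param counts Optional count matrix (NULL for analytic surfaces).
#' @param n_bp Chain-averaging length the surface describes.
#' @param temperature Kelvin.
#' @param coordinate_label `"groove_width"` or `"diameter"`.
#' @return An object of class `pmf2d`.
#' @export
pmf2d <- function(twist_mid, conj_mid, values, counts = NULL, n_bp = 1,
                  temperature = 295,
                  coordinate_label = c("groove_width", "diameter")) {
  coordinate_label <- match.arg(coordinate_label)
  if (!is.matrix(values) || nrow(values) != length(twist_mid) ||
      ncol(values) != length(conj_mid))
    stop("'values' must be a length(twist_mid) x length(conj_mid) matrix")
  if (any(diff(twist_mid) <= 0) || any(diff(conj_mid) <= 0))
    stop("bin midpoints must be strictly increasing")
  if (all(is.na(values))) stop("surface has no occupied bins")
  values <- values - min(values, na.rm = TRUE)
  amin <- which(values == 0, arr.ind = TRUE)[1, ]
  structure(list(twist_mid = twist_mid, conj_mid = conj_mid,
                 values = values, counts = counts,
                 twist_bin = stats::median(diff(twist_mid)),
                 conj_bin = stats::median(diff(conj_mid)),
                 minimum = c(twist = twist_mid[amin[1]],
                             conj = conj_mid[amin[2]], value = 0),
                 n_bp = as.integer(n_bp), temperature = temperature,
                 coordinate_label = coordinate_label,
                 n_snapshots = if (is.null(counts)) NA_integer_
                               else sum(counts)),
            class = "pmf2d")
}

#' Build a two-dimensional potential of mean force
#'
#' Bins the ensemble's (twist, conjugate-coordinate) snapshots on a regular
#' grid and converts relative occupancies to free energies,
#' `-log(count/total)` in kBT, shifted so that the minimum over occupied
#' bins is zero.  Empty bins are flagged `NA`, never treated as zero
#' energy.
#'
#' @param ensemble A [helical_ensemble()].
#' @param twist_bin Twist bin width, degrees (default 0.1).
#' @param conj_bin Conjugate-coordinate bin width, nm (default 0.01).
#' @return An object of class `pmf2d` with bin midpoints `twist_mid`,
#'   `conj_mid`, a `values` matrix (kBT, `NA` = empty), a `counts` matrix,
#'   the raw arg-min bin `minimum`, and metadata.
#' @export
#' @examples
#' ens <- sample_pair_ensemble(ensemble_spec(coupling_preset("rna-eq3"),
#'                                           n_snapshots = 5000, seed = 1))
#' pmf <- build_pmf2d(ens)
#' pmf$minimum
build_pmf2d <- function(ensemble, twist_bin = 0.1, conj_bin = 0.01) {
  if (!inherits(ensemble, "helical_ensemble"))
    stop("'ensemble' must be a helical_ensemble")
  if (twist_bin <= 0 || conj_bin <= 0) stop("bin widths must be positive")
  tw <- ensemble$records$twist; cj <- ensemble$records$conj
  t0 <- floor(min(tw) / twist_bin) * twist_bin
  c0 <- floor(min(cj) / conj_bin) * conj_bin
  it <- pmin(floor((tw - t0) / twist_bin) + 1L,
             ceiling((max(tw) - t0) / twist_bin))
  ic <- pmin(floor((cj - c0) / conj_bin) + 1L,
             ceiling((max(cj) - c0) / conj_bin))
  nt <- max(it); nc <- max(ic)
  counts <- matrix(tabulate(it + (ic - 1L) * nt, nbins = nt * nc), nt, nc)
  if (sum(counts > 0) < 2)
    stop("degenerate ensemble: all snapshots fall in a single bin")
  values <- -log(counts / length(tw))
  values[counts == 0] <- NA_real_
  values <- values - min(values, na.rm = TRUE)
  twist_mid <- t0 + (seq_len(nt) - 0.5) * twist_bin
  conj_mid  <- c0 + (seq_len(nc) - 0.5) * conj_bin
  amin <- which(values == 0, arr.ind = TRUE)[1, ]
  structure(list(twist_mid = twist_mid, conj_mid = conj_mid,
                 values = values, counts = counts,
                 twist_bin = twist_bin, conj_bin = conj_bin,
                 minimum = c(twist = twist_mid[amin[1]],
                             conj = conj_mid[amin[2]], value = 0),
                 n_bp = ensemble$n_bp, temperature = ensemble$temperature,
                 coordinate_label = ensemble$coordinate_label,
                 n_snapshots = length(tw)),
            class = "pmf2d")
}

#' @export
print.pmf2d <- function(x, ...) {
  cat("2-D PMF over (twist,", x$coordinate_label, "):",
      length(x$twist_mid), "x", length(x$conj_mid), "bins,",
      sum(!is.na(x$values)), "occupied,", x$n_snapshots, "snapshots\n")
  cat(sprintf("  arg-min bin: twist = %.3f deg, %s = %.4f nm\n",
              x$minimum["twist"], x$coordinate_label, x$minimum["conj"]))
  invisible(x)
}

#' @export
plot.pmf2d <- function(x, cutoff = 6, ...) {
  v <- x$values; v[v > cutoff] <- NA
  graphics::image(x$twist_mid, x$conj_mid, v,
                  col = grDevices::hcl.colors(24, "viridis", rev = TRUE),
                  xlab = "twist (deg)",
                  ylab = paste0(x$coordinate_label, " (nm)"), ...)
  graphics::contour(x$twist_mid, x$conj_mid, v, add = TRUE,
                    levels = seq(0.5, cutoff, by = 0.5), drawlabels = FALSE)
  invisible(x)
}

#' Conditional 1-D twist PMF in a conjugate-coordinate window
#'
#' Restricts the ensemble to snapshots whose conjugate coordinate lies in
#' `conj_window` and returns the min-referenced 1-D PMF of twist.  As the
#' window moves to larger groove widths the profile's minimum shifts to
#' smaller twist when the cross-coupling is positive.
#'
#' @param ensemble A [helical_ensemble()].
#' @param conj_window Length-2 numeric `(lo, hi)` in nm.
#' @param twist_bin Twist bin width, degrees.
#' @return A [pmf1d()].
#' @export
conditional_profile <- function(ensemble, conj_window, twist_bin = 0.1) {
  if (!inherits(ensemble, "helical_ensemble"))
    stop("'ensemble' must be a helical_ensemble")
  if (length(conj_window) != 2 || diff(conj_window) <= 0)
    stop("'conj_window' must be (lo, hi) with lo < hi")
  sel <- ensemble$records$conj >= conj_window[1] &
         ensemble$records$conj <  conj_window[2]
  if (!any(sel)) stop("no snapshots in the conjugate-coordinate window")
  tw <- ensemble$records$twist[sel]
  t0 <- floor(min(tw) / twist_bin) * twist_bin
  it <- pmin(floor((tw - t0) / twist_bin) + 1L,
             ceiling((max(tw) - t0) / twist_bin))
  counts <- tabulate(it)
  if (sum(counts > 0) < 3) stop("fewer than 3 occupied twist bins in window")
  values <- -log(counts / length(tw))
  values[counts == 0] <- NA_real_
  values <- values - min(values, na.rm = TRUE)
  pmf1d(grid = t0 + (seq_along(counts) - 0.5) * twist_bin,
        values = values, counts = counts,
        temperature = ensemble$temperature, coordinate_label = "twist")
}

#' Least-squares parabola through a 1-D PMF
#'
#' Fits `value = curvature * (x - center)^2 + const` to the occupied bins
#' of a 1-D PMF (optionally only those below `cutoff`), by ordinary least
#' squares on the general quadratic.
#'
#' @param pmf A [pmf1d()].
#' @param cutoff Use only bins with value <= `cutoff` kBT (default `Inf`).
#' @return A list with `center` (same units as the grid), `curvature`
#'   (kBT per unit^2) and `n_bins_used`.
#' @export
fit_quadratic1d <- function(pmf, cutoff = Inf) {
  if (!inherits(pmf, "pmf1d")) stop("'pmf' must be a pmf1d")
  sel <- !is.na(pmf$values) & pmf$values <= cutoff
  if (sum(sel) < 3) stop("need at least 3 occupied bins for a quadratic fit")
  x <- pmf$grid[sel] - mean(pmf$grid[sel])
  y <- pmf$values[sel]
  co <- stats::coef(stats::lm(y ~ x + I(x^2)))
  a2 <- unname(co[3])
  if (!is.finite(a2) || a2 < 1e-10)
    stop("non-convex profile: fitted curvature is not positive")
  list(center = mean(pmf$grid[sel]) - unname(co[2]) / (2 * a2),
       curvature = a2, n_bins_used = sum(sel))
}

#' Slope of the conditional mean twist against the conjugate coordinate
#'
#' Bins the conjugate coordinate, computes the mean twist in each populated
#' bin, and regresses the bin means on the bin centres by ordinary least
#' squares.  For the harmonic coupled model the population value of this
#' slope is `-k_cross / k_omega` (deg/nm), independent of the
#' chain-averaging length.
#'
#' @param ensemble A [helical_ensemble()].
#' @param conj_bin Conjugate-coordinate bin width, nm (default 0.02).
#' @param min_count Minimum snapshots for a bin to enter the regression
#'   (default 1).
#' @return A list with `slope` (deg/nm), `stderr`, `intercept_at`
#'   (conjugate value where the line crosses the ensemble mean twist) and
#'   `n_bins`.
#' @export
conditional_mean_slope <- function(ensemble, conj_bin = 0.02, min_count = 1) {
  if (!inherits(ensemble, "helical_ensemble"))
    stop("'ensemble' must be a helical_ensemble")
  cj <- ensemble$records$conj; tw <- ensemble$records$twist
  c0 <- floor(min(cj) / conj_bin) * conj_bin
  ic <- pmin(floor((cj - c0) / conj_bin) + 1L,
             ceiling((max(cj) - c0) / conj_bin))
  counts <- tabulate(ic)
  keep <- which(counts >= max(1, min_count))
  if (length(keep) < 3) stop("fewer than 3 populated conjugate bins")
  centers <- c0 + (keep - 0.5) * conj_bin
  means <- vapply(keep, function(k) mean(tw[ic == k]), numeric(1))
  fit <- stats::lm(means ~ centers)
  sm <- summary(fit)$coefficients
  list(slope = unname(stats::coef(fit)[2]), stderr = unname(sm[2, 2]),
       intercept = unname(stats::coef(fit)[1]), n_bins = length(keep))
}
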