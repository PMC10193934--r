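#' Construct a helical-parameter ensemble
#'
#' A `helical_ensemble` holds per-snapshot chain-averaged helical
#' parameters: the twist (degrees per bp step) and one conjugate coordinate
#' (major groove width or diameter, nm), together with the averaging length
#' `n_bp`, the temperature and free-form condition labels.  Such series are
#' what a helical-parameter analysis of a molecular-dynamics trajectory
#' produces once averaged over the central base pairs of the duplex.
#'
#' @param twist Numeric vector of chain-averaged twists, deg/bp step.
#' @param conj Numeric vector of chain-averaged conjugate coordinates, nm.
#' @param n_bp Number of base-pair steps averaged per snapshot.
#' @param temperature Ensemble temperature, kelvin.
#' @param coordinate_label `"groove_width"` or `"diameter"`.
#' @param conditions Named list of free-form condition labels
#'   (e.g. `list(salt = 1)`).
#' @return An object of class `helical_ensemble` with element `records`,
#'   a data frame with columns `twist` and `conj`.
#' @export
helical_ensemble <- function(twist, conj, n_bp = 1, temperature = 295,
                             coordinate_label = c("groove_width", "diameter"),
                             conditions = list()) {
  coordinate_label <- match.arg(coordinate_label)
  twist <- as.numeric(twist); conj <- as.numeric(conj)
  if (length(twist) != length(conj))
    stop("'twist' and 'conj' must have equal length")
  if (length(twist) < 1) stop("ensemble must contain at least one snapshot")
  if (any(!is.finite(twist)) || any(!is.finite(conj)))
    stop("non-finite helical parameters")
  if (n_bp < 1) stop("'n_bp' must be >= 1")
  structure(list(records = data.frame(twist = twist, conj = conj),
                 n_bp = as.integer(n_bp), temperature = temperature,
                 coordinate_label = coordinate_label,
                 conditions = conditions),
            class = "helical_ensemble")
}

#' @export
print.helical_ensemble <- function(x, ...) {
  cat("Helical ensemble:", nrow(x$records), "snapshots,",
      x$n_bp, "bp chain average,", x$temperature, "K\n")
  cat("  coordinate:", x$coordinate_label, "\n")
  cat(sprintf("  mean twist = %.3f deg, mean %s = %.4f nm\n",
              mean(x$records$twist), x$coordinate_label, mean(x$records$conj)))
  if (length(x$conditions))
    cat("  conditions:", paste(names(x$conditions),
                               unlist(x$conditions), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.helical_ensemble <- function(object, ...) {
  r <- object$records
  out <- list(n_snapshots = nrow(r), n_bp = object$n_bp,
              temperature = object$temperature,
              coordinate_label = object$coordinate_label,
              mean = c(twist = mean(r$twist), conj = mean(r$conj)),
              sd = c(twist = stats::sd(r$twist), conj = stats::sd(r$conj)),
              cov = stats::cov(r))
  class(out) <- "summary.helical_ensemble"
  out
}

#' @export
print.summary.helical_ensemble <- function(x, ...) {
  cat("Helical ensemble:", x$n_snapshots, "snapshots,", x$n_bp,
      "bp chain average,", x$temperature, "K\n")
  cat(sprintf("  twist: %.3f +/- %.3f deg\n", x$mean["twist"], x$sd["twist"]))
  cat(sprintf("  %s: %.4f +/- %.4f nm\n", x$coordinate_label,
              x$mean["conj"], x$sd["conj"]))
  cat(sprintf("  sample correlation: %.3f\n",
              x$cov[1, 2] / sqrt(x$cov[1, 1] * x$cov[2, 2])))
  invisible(x)
}
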