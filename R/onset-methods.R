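#' @export
print.onset_fit <- function(x, ...) {
  e <- x$estimate
  cat("Cumulative-sum onset fit\n")
  if (x$plateau$detected)
    cat(sprintf("  plateau corrected: end index %d, level %.4g Bq.s/ml\n",
                x$plateau$plateau_end_index, x$plateau$plateau_level))
  cat(sprintf("  fits: %d attempted, %d accepted\n",
              e$n_fits_attempted, e$n_fits_accepted))
  if (is.finite(e$onset_time))
    cat(sprintf("  onset time: %.3f s\n", e$onset_time))
  else
    cat("  onset time: undefined (no accepted fit)\n")
  invisible(x)
}

#' @export
summary.onset_fit <- function(object, ...) {
  e <- object$estimate
  kept <- e$accepted
  tab <- if (length(kept))
    data.frame(a = vapply(kept, function(f) f$params[["a"]], numeric(1)),
               b = vapply(kept, function(f) f$params[["b"]], numeric(1)),
               c = vapply(kept, function(f) f$params[["c"]], numeric(1)),
               r_squared = vapply(kept, `[[`, numeric(1), "r_squared"),
               range_end_s = vapply(kept, `[[`, numeric(1),
                                    "range_end_time"),
               onset_s = vapply(kept, `[[`, numeric(1), "onset_time"))
  else data.frame()
  out <- list(onset_time = e$onset_time,
              median_params = e$median_params,
              n_fits_attempted = e$n_fits_attempted,
              n_fits_accepted = e$n_fits_accepted,
              plateau = object$plateau,
              kept_fits = tab)
  class(out) <- "summary.onset_fit"
  out
}

#' @export
print.summary.onset_fit <- function(x, ...) {
  cat("Cumulative-sum onset fit\n")
  cat(sprintf("  onset time: %s s\n",
              if (is.finite(x$onset_time)) sprintf("%.3f", x$onset_time)
              else "undefined"))
  cat(sprintf("  median parameters: a = %.4g, b = %.4g s, c = %.4g s\n",
              x$median_params[["a"]], x$median_params[["b"]],
              x$median_params[["c"]]))
  cat(sprintf("  fits: %d attempted, %d accepted, %d used\n",
              x$n_fits_attempted, x$n_fits_accepted, nrow(x$kept_fits)))
  if (nrow(x$kept_fits)) {
    cat("  fits used (top half by R^2):\n")
    print(x$kept_fits, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.onset_fit <- function(object, ...) {
  c(object$estimate$median_params,
    onset_time = object$estimate$onset_time)
}

#' Predict the fitted summed curve
#'
#' Evaluates [summed_model()] with the aggregated (median) parameters.
#'
#' @param object an [onset_fit()].
#' @param newdata optional numeric vector of times (s); defaults to the
#'   frame mid-times of the fitted curve.
#' @param ... unused.
#' @return numeric vector of summed-model values (Bq.s/ml).
#' @export
predict.onset_fit <- function(object, newdata = NULL, ...) {
  p <- object$estimate$median_params
  if (any(!is.finite(p)))
    stop("no accepted fit: nothing to predict from", call. = FALSE)
  tt <- if (is.null(newdata)) object$curve$schedule$mid_time
        else as.numeric(newdata)
  summed_model(tt, p[["a"]], p[["b"]], p[["c"]])
}

#' @export
fitted.onset_fit <- function(object, ...) predict(object)

#' @export
residuals.onset_fit <- function(object, ...) {
  object$curve$values - predict(object)
}

#' @export
plot.onset_fit <- function(x, ...,
                           xlab = "Frame mid-time [s]",
                           ylab = "Summed activity [Bq.s/ml]") {
  tt <- x$curve$schedule$mid_time
  graphics::plot(tt, x$curve$values, xlab = xlab, ylab = ylab,
                 pch = 1, ...)
  e <- x$estimate
  if (is.finite(e$onset_time)) {
    graphics::lines(tt, predict(x), col = "red3", lwd = 2)
    graphics::abline(v = e$onset_time, lty = 2, col = "grey40")
    graphics::legend("topleft", bty = "n",
                     legend = c("summed TAC", "fit", "onset"),
                     col = c("black", "red3", "grey40"),
                     lty = c(NA, 1, 2), pch = c(1, NA, NA))
  }
  invisible(x)
}
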