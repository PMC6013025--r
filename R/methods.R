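# S3 methods for simulation results.

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Simulation config: %s, A_bulk = %g g/L (from t = %g h), cost = %g/h, alpha = %g g/g\n",
              x$medium, x$antibiotic_bulk, x$antibiotic_start_time,
              x$cost_c, x$alpha_detox))
  cat(sprintf("  inoculum %d R + %d S (%s), %g h at dt = %g h, seed %d\n",
              x$inoculum$n_R, x$inoculum$n_S, x$inoculum$arrangement,
              x$duration_h, x$dt_h, x$seed))
  print(x$geometry)
  invisible(x)
}

#' @export
print.biofilm_sim <- function(x, ...) {
  m <- x$metrics
  last <- m[nrow(m), ]
  cat(sprintf("<biofilm_sim> %s, A_bulk = %g g/L, %g h (seed %d)\n",
              x$config$medium, x$config$antibiotic_bulk,
              x$config$duration_h, x$config$seed))
  cat(sprintf("  final: %d R + %d S cells, height %.1f um, s_R = %s\n",
              last$count_R, last$count_S, last$biofilm_height_um,
              if (is.na(last$s_R)) "NA" else sprintf("%.2f", last$s_R)))
  invisible(x)
}

#' @export
summary.biofilm_sim <- function(object, ...) {
  structure(list(config = object$config, metrics = object$metrics),
            class = "summary.biofilm_sim")
}

#' @export
print.summary.biofilm_sim <- function(x, ...) {
  print(x$config)
  cat("\nMetrics time series:\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Plot a simulation result
#'
#' `which = "counts"` draws the cell-count trajectories of both lineages;
#' `"segregation"` the segregation index; `"cells"` the final spatial
#' arrangement (R dark red, S steel blue); `"fields"` the height profiles of
#' all solute fields at the final time.
#'
#' @param x a `biofilm_sim`.
#' @param which one of `"counts"`, `"segregation"`, `"cells"`, `"fields"`.
#' @param ... passed to the underlying base-graphics calls.
#' @export
plot.biofilm_sim <- function(x, which = c("counts", "segregation", "cells",
                                          "fields"), ...) {
  which <- match.arg(which)
  m <- x$metrics
  if (which == "counts") {
    graphics::matplot(m$time_h, cbind(m$count_R, m$count_S), type = "l",
                      lty = 1, lwd = 2, col = c("darkred", "steelblue"),
                      xlab = "time (h)", ylab = "cells", ...)
    graphics::legend("topleft", c("R", "S"), lwd = 2,
                     col = c("darkred", "steelblue"), bty = "n")
  } else if (which == "segregation") {
    graphics::plot(m$time_h, m$s_R, type = "l", lwd = 2, ylim = c(-1, 1),
                   xlab = "time (h)", ylab = expression(s[R]), ...)
    graphics::abline(h = 0, lty = 3)
  } else if (which == "cells") {
    cells <- x$cells
    graphics::plot(NA, xlim = c(0, x$config$geometry$width),
                   ylim = c(0, max(cells$y + cells$radius, 10)),
                   xlab = "x (um)", ylab = "y (um)", asp = 1, ...)
    graphics::symbols(cells$x, cells$y, circles = cells$radius,
                      inches = FALSE, add = TRUE, fg = NA,
                      bg = ifelse(cells$species == "R",
                                  grDevices::adjustcolor("darkred", 0.8),
                                  grDevices::adjustcolor("steelblue", 0.8)))
  } else {
    fields <- x$fields
    cols <- grDevices::hcl.colors(length(fields), "Dark 3")
    first <- TRUE
    for (i in seq_along(fields)) {
      p <- solute_height_profile(fields[[i]], x$config$geometry)
      if (first) {
        graphics::plot(p$mean_conc, p$height_um, type = "l", lwd = 2,
                       col = cols[i], xlab = "mean concentration (g/L)",
                       ylab = "height (um)", ...)
        first <- FALSE
      } else {
        graphics::lines(p$mean_conc, p$height_um, lwd = 2, col = cols[i])
      }
    }
    graphics::legend("topright", names(fields), lwd = 2, col = cols, bty = "n")
  }
  invisible(x)
}

#' @export
as.data.frame.biofilm_sim <- function(x, ...) x$metrics
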