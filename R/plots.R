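#' Plot a simulated heartbeat
#'
#' Two panels: the pressure-volume loop and the pressure/volume time
#' courses with the phase transitions marked.
#'
#' @param x an \code{emf_heartbeat}.
#' @param ... ignored.
#' @return invisibly \code{x}.
#' @export
plot.emf_heartbeat <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$V_lv_ml, kPa_to_mmHg(tr$p_lv_kPa), type = "l",
                 xlab = "LV volume (ml)", ylab = "LV pressure (mmHg)",
                 main = "PV loop")
  graphics::plot(tr$time_ms, kPa_to_mmHg(tr$p_lv_kPa), type = "l",
                 xlab = "time (ms)", ylab = "pressure (mmHg) / volume (ml)",
                 ylim = range(c(kPa_to_mmHg(tr$p_lv_kPa), tr$V_lv_ml)),
                 main = "traces")
  graphics::lines(tr$time_ms, kPa_to_mmHg(tr$p_ao_kPa), lty = 2)
  graphics::lines(tr$time_ms, tr$V_lv_ml, col = "grey40")
  graphics::abline(v = c(x$metrics$valve_open_t, x$metrics$valve_close_t),
                   lty = 3)
  graphics::legend("topright", c("p_lv", "p_ao", "V_lv"),
                   lty = c(1, 2, 1), col = c(1, 1, "grey40"), bty = "n",
                   cex = 0.8)
  invisible(x)
}

#' Plot a Klotz end-diastolic pressure-volume curve
#'
#' @param x a \code{klotz_curve}.
#' @param Vmax upper volume bound for the curve (ml).
#' @param ... ignored.
#' @return invisibly \code{x}.
#' @export
plot.klotz_curve <- function(x, Vmax = NULL, ...) {
  Vmax <- Vmax %||% (1.1 * x$V_m)
  V <- seq(x$V_0, Vmax, length.out = 200)
  graphics::plot(V, x$P_of_V(V), type = "l", xlab = "volume (ml)",
                 ylab = "pressure (mmHg)", main = "Klotz EDPVR")
  graphics::points(x$V_m, x$P_m, pch = 19)
  graphics::abline(v = x$V_0, lty = 3)
  graphics::mtext(sprintf("V0 = %.1f ml", x$V_0), side = 3, cex = 0.8)
  invisible(x)
}

#' @export
print.emf_heartbeat <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<emf_heartbeat> EDV %.1f ml, ESV %.1f ml, EF %.1f%%, ",
                     "p_peak %.1f mmHg\n  valve open %.0f ms, close %.0f ms, ",
                     "%d trace steps\n"),
              m$EDV, m$ESV, m$EF, kPa_to_mmHg(m$p_peak),
              m$valve_open_t, m$valve_close_t, nrow(x$trace)))
  invisible(x)
}

#' @export
print.activation_map <- function(x, ...) {
  fin <- x$t_a[is.finite(x$t_a)]
  cat(sprintf("<activation_map> %d vertices, t_a in [%.1f, %.1f] ms, %d unreached\n",
              length(x$t_a), min(fin), max(fin), sum(x$unreached)))
  invisible(x)
}

#' @export
print.klotz_curve <- function(x, ...) {
  cat(sprintf("<klotz_curve> V_m %.1f ml at %.1f mmHg -> V0 %.1f ml\n",
              x$V_m, x$P_m, x$V_0))
  invisible(x)
}
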