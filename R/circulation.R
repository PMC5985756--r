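#' Three-element Windkessel afterload models
#'
#' Lumped representations of the arterial system: the LV-side model couples
#' the ventricle through the open aortic valve (resistance R_av in series
#' with the characteristic impedance Z_c) to peripheral resistance R and
#' compliance C; per-outlet models provide outflow pressures for the CFD
#' stage. Pressures in kPa, flows in ml/ms unless stated otherwise;
#' resistances kPa ms/ml, compliances ml/kPa.
#'
#' @name circulation
NULL

#' LV-side Windkessel parameters
#' @param R peripheral resistance (kPa ms/ml).
#' @param Z_c characteristic impedance (kPa ms/ml).
#' @param C compliance (ml/kPa).
#' @param R_av open-valve resistance (kPa ms/ml).
#' @return list of class \code{windkessel_lv}.
#' @export
windkessel_lv <- function(R = 170.65, Z_c = 12.0, C = 6.75, R_av = 0) {
  stopifnot(R > 0, C > 0, Z_c >= 0, R_av >= 0)
  structure(list(R = R, Z_c = Z_c, C = C, R_av = R_av),
            class = "windkessel_lv")
}

#' One semi-implicit step of the LV Windkessel pressure ODE
#'
#' Backward-Euler update of
#' dp/dt = (1/C)(1 + (Z_c + R_av)/R) q + (Z_c + R_av) dq/dt - p/(RC),
#' with the flow terms supplied explicitly by the caller (the mechanics
#' coupling uses the previous step's flux).
#'
#' @param p_lv current pressure (kPa).
#' @param q_lv outflow (ml/ms, positive = ejecting).
#' @param dq_lv backward-difference of the flux (ml/ms^2).
#' @param params \code{\link{windkessel_lv}}.
#' @param dt step (ms).
#' @return updated pressure (kPa).
#' @export
wk3_lv_step <- function(p_lv, q_lv, dq_lv, params, dt) {
  stopifnot(dt > 0)
  Zt <- params$Z_c + params$R_av
  rhs <- p_lv + dt * ((1 / params$C) * (1 + Zt / params$R) * q_lv +
                        Zt * dq_lv)
  rhs / (1 + dt / (params$R * params$C))
}

#' Steady-state LV Windkessel pressure
#' @param q_lv steady flow (ml/ms).
#' @param params \code{\link{windkessel_lv}}.
#' @return pressure (kPa) with dp/dt = dq/dt = 0.
#' @export
wk3_lv_steady <- function(q_lv, params) {
  (params$R + params$Z_c + params$R_av) * q_lv
}

#' Per-outlet Windkessel parameters
#' @param R_i,Z_i resistances (kPa ms/ml).
#' @param C_i compliance (ml/kPa).
#' @param p_d0 initial distal pressure (kPa).
#' @return list of class \code{outlet_windkessel}.
#' @export
outlet_windkessel <- function(R_i, Z_i, C_i, p_d0 = 0) {
  stopifnot(R_i > 0, C_i > 0, Z_i >= 0)
  structure(list(R = R_i, Z = Z_i, C = C_i, p_d = p_d0),
            class = "outlet_windkessel")
}

#' One semi-implicit step of an outlet Windkessel DAE
#'
#' Backward-Euler update of C dp_d/dt + p_d/R = q with the previous step's
#' flux, then the algebraic output p_wk = Z q + p_d.
#'
#' @param wk an \code{\link{outlet_windkessel}} (carries its state
#'   \code{p_d}).
#' @param q_i outlet flux (ml/ms).
#' @param dt step (ms).
#' @return the updated \code{outlet_windkessel} with fields \code{p_d} and
#'   \code{p_wk} (kPa).
#' @export
outlet_wk_step <- function(wk, q_i, dt) {
  stopifnot(dt > 0)
  wk$p_d <- (wk$p_d + dt * q_i / wk$C) / (1 + dt / (wk$R * wk$C))
  wk$p_wk <- wk$Z * q_i + wk$p_d
  wk
}

#' Estimate outlet Windkessel parameters from clinical data
#'
#' Hydraulic Ohm analog: R_i = MAP / (alpha_i CO) with the impedance chosen
#' as 5\% of R_i and the compliance such that R_i C_i = 1000 ms.
#'
#' @param MAP mean arterial pressure (mmHg).
#' @param CO cardiac output (ml/s).
#' @param alpha_i fraction of cardiac output through this outlet, in (0, 1].
#' @return an \code{\link{outlet_windkessel}}.
#' @export
estimate_outlet_params <- function(MAP, CO, alpha_i) {
  if (alpha_i <= 0 || alpha_i > 1) stop_emf("alpha_i must lie in (0, 1]")
  R <- mmHg_to_kPa(MAP) / (alpha_i * CO / 1000)  # CO ml/s -> ml/ms
  outlet_windkessel(R_i = R, Z_i = 0.05 * R, C_i = 1000 / R)
}

#' Murray's-law flow splits
#'
#' alpha_i = r_i^3 / sum(r_j^3): flow through branching vessels scales with
#' the cube of the radius.
#'
#' @param radii vessel radii (mm).
#' @return fractions summing to 1.
#' @export
murray_splits <- function(radii) {
  if (length(radii) == 0) stop_emf("empty radius list")
  stopifnot(all(radii > 0))
  radii^3 / sum(radii^3)
}

#' Sample Windkessel parameter sets in a +/- 20\% box
#'
#' Uniform, independent box sampling around the supplied means; the search
#' space restriction used for the stochastic afterload sweeps.
#'
#' @param means named numeric vector of mean parameter values.
#' @param n number of samples.
#' @param seed RNG seed (reproducible draws).
#' @param spread half-width as a fraction of the mean.
#' @return data.frame with one row per sample.
#' @export
sample_windkessel <- function(means, n, seed = 1L, spread = 0.2) {
  stopifnot(n > 0)
  means <- unlist(means)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  out <- vapply(means, function(m)
    stats::runif(n, m * (1 - spread), m * (1 + spread)), numeric(n))
  out <- matrix(out, nrow = n, dimnames = list(NULL, names(means)))
  as.data.frame(out)
}

#' Afterload-fit diagnostics for a sampled parameter set
#'
#' Reports the three manual selection criteria used to judge an aortic
#' pressure trace against recordings: peak pressure, valve-closing pressure
#' and the diastolic exponential decay constant (RC time).
#'
#' @param trace data.frame with \code{time_ms} and \code{p_ao} (mmHg or kPa,
#'   reported as given).
#' @param ejection_end time (ms) at which the valve closes.
#' @return list with \code{p_peak}, \code{p_close}, \code{tau_decay_ms}.
#' @export
afterload_diagnostics <- function(trace, ejection_end) {
  stopifnot(all(c("time_ms", "p_ao") %in% names(trace)))
  p_peak <- max(trace$p_ao)
  i_close <- which.min(abs(trace$time_ms - ejection_end))
  p_close <- trace$p_ao[i_close]
  dia <- trace[trace$time_ms > ejection_end & trace$p_ao > 0, , drop = FALSE]
  tau <- NA_real_
  if (nrow(dia) > 5) {
    fit <- stats::lm(log(p_ao) ~ time_ms, data = dia)
    tau <- -1 / stats::coef(fit)[["time_ms"]]
  }
  list(p_peak = p_peak, p_close = p_close, tau_decay_ms = tau)
}

#' Split a trunk flow among outlets by fixed fractions
#' @param q_lv trunk flow.
#' @param alphas fractions (will be normalized).
#' @return per-outlet flows; their sum equals \code{q_lv} exactly.
#' @export
split_flow <- function(q_lv, alphas) {
  alphas <- alphas / sum(alphas)
  q_lv * alphas
}

#' Clinical record presets
#'
#' Printed clinical characteristics of the study cases. \code{source
#' = "catheter"} carries the acquisition table (EDV, ESV, SV, EF, HR, CO,
#' aortic pressures, valve-open pressure); \code{source = "comparison"}
#' carries the clinical columns of the model-comparison table.
#'
#' @param case \code{"28-Pre"} or \code{"44-Pre"}.
#' @param source which printed table to quote.
#' @return named list; volumes ml, EF \%, HR bpm, CO ml/s, pressures mmHg.
#' @export
clinical_record <- function(case = c("28-Pre", "44-Pre"),
                            source = c("catheter", "comparison")) {
  case <- match.arg(case); source <- match.arg(source)
  rec <- if (source == "catheter") {
    list("28-Pre" = list(EDV = 88.2, ESV = 30.6, SV = 57.54, EF = 65.3,
                         HR = 91, CO = 87.46, P_dia = 71.1, P_sys = 122.7,
                         MAP = 88.3, P_open = 71.33),
         "44-Pre" = list(EDV = 91.7, ESV = 31.6, SV = 60.09, EF = 65.5,
                         HR = 76, CO = 76.31, P_dia = 74.6, P_sys = 125.2,
                         MAP = 91.5, P_open = 74.78))
  } else {
    list("28-Pre" = list(EDV = 88.16, ESV = 30.62, SV = 57.54, EF = 65.27,
                         CO = 87.46, P_sys = 146.037),
         "44-Pre" = list(EDV = 91.68, ESV = 31.59, SV = 60.10, EF = 65.54,
                         CO = 76.31, P_sys = 158.413))
  }
  c(list(case = case), rec[[case]])
}

#' Printed per-outlet Windkessel presets
#'
#' The fitted outlet parameter tables for the four aortic outlets
#' (descending aorta DCA, brachiocephalic BCA, right/left subclavian
#' RSC/LSC). R and Z in kPa ms/ml, C in ml/kPa.
#'
#' @param case \code{"28-Pre"} or \code{"44-Pre"}.
#' @return named list of \code{\link{outlet_windkessel}} objects.
#' @export
outlet_preset <- function(case = c("28-Pre", "44-Pre")) {
  case <- match.arg(case)
  tab <- list(
    "28-Pre" = list(DCA = c(590.46, 29.52, 1.69), BCA = c(264.6, 13.23, 3.78),
                    RSC = c(1058.24, 52.91, 0.944), LSC = c(1058.24, 52.91, 0.944)),
    "44-Pre" = list(DCA = c(2480.07, 124.003, 0.403), BCA = c(276.01, 13.9, 3.62),
                    RSC = c(466.23, 23.31, 2.14), LSC = c(7440.2, 372.01, 0.134)))
  lapply(tab[[case]], function(v) outlet_windkessel(v[1], v[2], v[3]))
}

#' Printed flow-split fractions per outlet
#'
#' Fractions of total cardiac output through each plane. The second case
#' prints three values; the fourth outlet carries the documented remainder.
#'
#' @param case \code{"28-Pre"} or \code{"44-Pre"}.
#' @return named fractions (sum to 1).
#' @export
flow_split_preset <- function(case = c("28-Pre", "44-Pre")) {
  case <- match.arg(case)
  if (case == "28-Pre") {
    c(DCA = 0.23, BCA = 0.513, RSC = 0.1283, LSC = 0.1283)
  } else {
    a <- c(DCA = 0.0568, BCA = 0.5745, RSC = 0.3401)
    c(a, LSC = 1 - sum(a))  # remainder: the table prints three of four
  }
}
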