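#' Constitutive laws for myocardium, aorta and active contraction
#'
#' Point-wise hyperelastic strain-energy functions and their exact second
#' Piola-Kirchhoff stresses: the transversely isotropic Guccione law for the
#' myocardium, the isotropic exponential Demiray law for aorta, valves and
#' cushion, and a phenomenological active stress transient triggered by the
#' local activation time. Energies are in kPa; both laws carry a volumetric
#' penalty (kappa/2) (log J)^2 enforcing near-incompressibility.
#'
#' @name materials
NULL

#' Guccione material parameters
#'
#' Exponential anisotropy coefficients default to the standard fit
#' (b_f 18.48, b_t 3.58, b_fs 1.627); the stiffness scale \code{C_Guc} is
#' the parameter fitted against the Klotz end-diastolic relation.
#'
#' @param C_Guc stiffness scale (kPa).
#' @param b_f,b_t,b_fs dimensionless exponents (fiber, transverse, shear).
#' @param kappa bulk modulus (kPa).
#' @return a parameter list of class \code{guccione_params}.
#' @export
guccione_params <- function(C_Guc = 0.48, b_f = 18.48, b_t = 3.58,
                            b_fs = 1.627, kappa = 650) {
  stopifnot(C_Guc > 0, b_f > 0, b_t > 0, b_fs > 0, kappa > 0)
  structure(list(C_Guc = C_Guc, b_f = b_f, b_t = b_t, b_fs = b_fs,
                 kappa = kappa), class = "guccione_params")
}

#' Demiray material parameters
#'
#' Only the small-strain stiffness scale \code{C_tilde = a/(2b)} matters for
#' the applications here; \code{b} defaults to 1 and \code{a} is derived.
#' Defaults match an aortic wall (3000 kPa); use 30000 for valves and 300
#' for the apical cushion (with \code{kappa = 100}).
#'
#' @param C_tilde derived stiffness a/(2b) (kPa).
#' @param b dimensionless exponent.
#' @param kappa bulk modulus (kPa).
#' @return a parameter list of class \code{demiray_params}.
#' @export
demiray_params <- function(C_tilde = 3000, b = 1, kappa = 650) {
  stopifnot(C_tilde > 0, b > 0, kappa > 0)
  structure(list(a = 2 * b * C_tilde, b = b, kappa = kappa,
                 C_tilde = C_tilde), class = "demiray_params")
}

#' Active stress parameters
#'
#' Parameters of the tanh-squared active stress transient. The length
#' dependence (phi(lambda), lambda-dependent contraction time constant) is
#' implemented but off by default (\code{length_dependent = FALSE}), in
#' which case phi = 1 throughout. Time constants tau_c0 and tau_r are
#' interpreted in milliseconds.
#'
#' @param S_peak peak isometric tension (kPa).
#' @param t_dur transient duration (ms).
#' @param tau_c0 baseline contraction time constant (ms).
#' @param tau_r relaxation time constant (ms).
#' @param t_emd electromechanical delay (ms).
#' @param length_dependent enable phi(lambda) and tau_c(lambda).
#' @param lambda_0 stretch below which no tension is generated.
#' @param ld degree of length dependence (dimensionless).
#' @param ld_up length dependence of tau_c (ms).
#' @return a parameter list of class \code{active_params}.
#' @export
active_params <- function(S_peak = 60, t_dur = 380, tau_c0 = 30, tau_r = 30,
                          t_emd = 15, length_dependent = FALSE,
                          lambda_0 = 0.7, ld = 5, ld_up = 500) {
  stopifnot(S_peak >= 0, t_dur > 0, tau_c0 > 0, tau_r > 0)
  structure(list(S_peak = S_peak, t_dur = t_dur, tau_c0 = tau_c0,
                 tau_r = tau_r, t_emd = t_emd,
                 length_dependent = length_dependent,
                 lambda_0 = lambda_0, ld = ld, ld_up = ld_up),
            class = "active_params")
}

#' Fitted electromechanics parameter presets
#'
#' Named presets of the fitted electromechanics parameters for the study
#' cases: active stress transient, passive stiffness scale and the LV-side
#' Windkessel triple (R, Z in kPa ms/ml; C in ml/kPa).
#'
#' @param case one of \code{"28-Pre"}, \code{"28-Post"}, \code{"44-Pre"}.
#' @return list with \code{active} (\code{active_params}), \code{C_Guc},
#'   and \code{windkessel} (R, Z_c, C).
#' @export
em_preset <- function(case = c("28-Pre", "28-Post", "44-Pre")) {
  case <- match.arg(case)
  tab <- list(
    "28-Pre" = list(S_peak = 60, t_dur = 380, tau_c0 = 30, tau_r = 30,
                    t_emd = 15, C_Guc = 0.48, R = 170.65, Z = 12.00, C = 6.75),
    "28-Post" = list(S_peak = 55, t_dur = 380, tau_c0 = 30, tau_r = 30,
                     t_emd = 15, C_Guc = 0.48, R = 170.65, Z = 12.00, C = 6.75),
    "44-Pre" = list(S_peak = 90, t_dur = 400, tau_c0 = 50, tau_r = 50,
                    t_emd = 15, C_Guc = 0.48, R = 166.65, Z = 13.33, C = 7.42))
  p <- tab[[case]]
  list(case = case,
       active = active_params(S_peak = p$S_peak, t_dur = p$t_dur,
                              tau_c0 = p$tau_c0, tau_r = p$tau_r,
                              t_emd = p$t_emd),
       C_Guc = p$C_Guc,
       windkessel = list(R = p$R, Z_c = p$Z, C = p$C))
}

#' Deformation state at a material point
#'
#' @param F 3x3 deformation gradient.
#' @return list with \code{F}, \code{J}, \code{C}, \code{Cbar}, \code{Ebar}.
#' @export
deformation_state <- function(F) {
  F <- as.matrix(F)
  J <- det(F)
  if (J <= 0) stop_emf("inverted deformation: det F <= 0")
  C <- t(F) %*% F
  Cbar <- J^(-2 / 3) * C
  Ebar <- (Cbar - diag(3)) / 2
  list(F = F, J = J, C = C, Cbar = Cbar, Ebar = Ebar)
}

# ---- vectorized kernels (n x 9 tensor fields) ----

guccione_psi_S <- function(Fv, f0, s0, n0, p, want_stress = TRUE) {
  J <- t3_det(Fv)
  if (any(J <= 0)) stop_emf("inverted deformation: det F <= 0")
  guccione_psi_S_C(t3_mm(t3_t(Fv), Fv), f0, s0, n0, p, want_stress)
}

# C-based kernel (J = sqrt(det C)); used by the FE tangent via finite
# differences in C-space
guccione_psi_S_C <- function(C, f0, s0, n0, p, want_stress = TRUE) {
  detC <- t3_det(C)
  if (any(detC <= 0)) stop_emf("inverted deformation: det C <= 0")
  J <- sqrt(detC)
  Jm23 <- J^(-2 / 3)
  Cbar <- C * Jm23
  Ebar <- Cbar / 2
  Ebar[, c(1, 5, 9)] <- Ebar[, c(1, 5, 9)] - 0.5
  qff <- t3_quad(Ebar, f0)
  qss <- t3_quad(Ebar, s0)
  qnn <- t3_quad(Ebar, n0)
  qsn <- rowSums(s0 * t3_mv(Ebar, n0))
  qfs <- rowSums(f0 * t3_mv(Ebar, s0))
  qfn <- rowSums(f0 * t3_mv(Ebar, n0))
  Q <- p$b_f * qff^2 + p$b_t * (qss^2 + qnn^2 + 2 * qsn^2) +
    2 * p$b_fs * (qfs^2 + qfn^2)
  psi <- p$kappa / 2 * log(J)^2 + p$C_Guc / 2 * (exp(Q) - 1)
  if (!want_stress) return(list(psi = psi))
  A <- 2 * p$b_f * qff * t3_outer(f0, f0) +
    2 * p$b_t * (qss * t3_outer(s0, s0) + qnn * t3_outer(n0, n0)) +
    4 * p$b_t * qsn * t3_sym(t3_outer(s0, n0)) +
    4 * p$b_fs * (qfs * t3_sym(t3_outer(f0, s0)) +
                    qfn * t3_sym(t3_outer(f0, n0)))
  Cinv <- t3_inv(C)
  AC <- t3_ddot(A, C)
  S <- p$kappa * log(J) * Cinv +
    p$C_Guc * exp(Q) * 0.5 * Jm23 * (A - (AC / 3) * Cinv)
  list(psi = psi, S = S)
}

demiray_psi_S <- function(Fv, p, want_stress = TRUE) {
  J <- t3_det(Fv)
  if (any(J <= 0)) stop_emf("inverted deformation: det F <= 0")
  demiray_psi_S_C(t3_mm(t3_t(Fv), Fv), p, want_stress)
}

demiray_psi_S_C <- function(C, p, want_stress = TRUE) {
  detC <- t3_det(C)
  if (any(detC <= 0)) stop_emf("inverted deformation: det C <= 0")
  J <- sqrt(detC)
  Jm23 <- J^(-2 / 3)
  trCbar <- t3_tr(C) * Jm23
  ex <- exp(p$b * (trCbar - 3))
  psi <- p$kappa / 2 * log(J)^2 + p$a / (2 * p$b) * (ex - 1)
  if (!want_stress) return(list(psi = psi))
  Cinv <- t3_inv(C)
  I9 <- t3_eye(nrow(C))
  S <- p$kappa * log(J) * Cinv +
    p$a * ex * Jm23 * (I9 - (t3_tr(C) / 3) * Cinv)
  list(psi = psi, S = S)
}

#' Guccione strain-energy density
#'
#' @param state a \code{\link{deformation_state}}.
#' @param p \code{\link{guccione_params}}.
#' @param frame list with unit vectors \code{f0}, \code{s0}, \code{n0}.
#' @return energy density (kPa).
#' @export
psi_guccione <- function(state, p, frame) {
  Fv <- t3_from_matrix(state$F)
  guccione_psi_S(Fv, matrix(frame$f0, 1, 3), matrix(frame$s0, 1, 3),
                 matrix(frame$n0, 1, 3), p, want_stress = FALSE)$psi
}

#' Demiray strain-energy density
#'
#' @inheritParams psi_guccione
#' @param p \code{\link{demiray_params}}.
#' @return energy density (kPa).
#' @export
psi_demiray <- function(state, p) {
  demiray_psi_S(t3_from_matrix(state$F), p, want_stress = FALSE)$psi
}

#' Passive second Piola-Kirchhoff stress
#'
#' Exact analytic derivative S = 2 dPsi/dC of the selected strain-energy
#' function.
#'
#' @param state a \code{\link{deformation_state}}.
#' @param law \code{"guccione"} or \code{"demiray"}.
#' @param params matching parameter list.
#' @param frame fiber frame (required for Guccione).
#' @return symmetric 3x3 stress (kPa).
#' @export
pk2_passive <- function(state, law = c("guccione", "demiray"), params,
                        frame = NULL) {
  law <- match.arg(law)
  Fv <- t3_from_matrix(state$F)
  S <- if (law == "guccione") {
    if (is.null(frame)) stop_emf("guccione law needs a fiber frame")
    guccione_psi_S(Fv, matrix(frame$f0, 1, 3), matrix(frame$s0, 1, 3),
                   matrix(frame$n0, 1, 3), params)$S
  } else {
    demiray_psi_S(Fv, params)$S
  }
  matrix(S, 3, 3)
}

#' Active stress transient
#'
#' S_a(t) = S_peak phi(lambda) tanh^2(t_s / tau_c) tanh^2((t_dur - t_s) / tau_r)
#' for 0 < t_s < t_dur with t_s = t - t_a - t_emd, and zero otherwise. With
#' the default \code{length_dependent = FALSE}, phi = 1 and
#' tau_c = tau_c0.
#'
#' @param t time (ms), vectorized.
#' @param t_a local activation time (ms), scalar or vector.
#' @param lambda fiber stretch (used only when length dependence is on).
#' @param p \code{\link{active_params}}.
#' @return active stress (kPa).
#' @export
active_stress_scalar <- function(t, t_a = 0, lambda = 1, p = active_params()) {
  ts <- t - t_a - p$t_emd
  if (p$length_dependent) {
    phi <- pmax(tanh(p$ld * (lambda - p$lambda_0)), 0)
    tau_c <- p$tau_c0 + p$ld_up * (1 - phi)
  } else {
    phi <- 1
    tau_c <- p$tau_c0
  }
  out <- p$S_peak * phi * tanh(ts / tau_c)^2 * tanh((p$t_dur - ts) / p$tau_r)^2
  out[!(ts > 0 & ts < p$t_dur)] <- 0
  out
}

#' Active second Piola-Kirchhoff stress tensor
#'
#' S_act = S_a (f0 . C f0)^{-1} f0 x f0: rank-one tension along the fiber,
#' scaled by the inverse squared fiber stretch.
#'
#' @param C right Cauchy-Green tensor (3x3).
#' @param f0 unit fiber direction.
#' @param S_a active stress scalar (kPa).
#' @return 3x3 stress tensor (kPa).
#' @export
active_stress_tensor <- function(C, f0, S_a) {
  f0 <- as.numeric(f0)
  lam2 <- as.numeric(t(f0) %*% C %*% f0)
  stopifnot(lam2 > 0)
  S_a / lam2 * (f0 %o% f0)
}
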