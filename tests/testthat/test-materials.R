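frame_xyz <- list(f0 = c(1, 0, 0), s0 = c(0, 1, 0), n0 = c(0, 0, 1))

test_that("strain energies vanish at identity and split volumetric/isochoric", {
  st <- deformation_state(diag(3))
  expect_equal(psi_guccione(st, guccione_params(), frame_xyz), 0)
  expect_equal(psi_demiray(st, demiray_params()), 0)

  # pure volumetric stretch: isochoric exponent is zero
  a <- 1.07
  stv <- deformation_state(a * diag(3))
  gp <- guccione_params()
  expect_equal(psi_guccione(stv, gp, frame_xyz),
               gp$kappa / 2 * (3 * log(a))^2, tolerance = 1e-12)
  dp <- demiray_params()
  expect_equal(psi_demiray(stv, dp),
               dp$kappa / 2 * (3 * log(a))^2, tolerance = 1e-12)
})

test_that("uniaxial and equibiaxial energies match direct scalar evaluation", {
  # isochoric uniaxial fiber stretch lambda = 1.1
  lam <- 1.1
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  st <- deformation_state(F)
  gp <- guccione_params()
  # direct evaluation: Ebar diagonal, Q from its entries
  Eb <- (st$Cbar - diag(3)) / 2
  Q <- gp$b_f * Eb[1, 1]^2 + gp$b_t * (Eb[2, 2]^2 + Eb[3, 3]^2)
  expect_equal(psi_guccione(st, gp, frame_xyz),
               gp$C_Guc / 2 * (exp(Q) - 1), tolerance = 1e-12)

  # equibiaxial isochoric stretch for the isotropic law
  b <- 1.08
  F2 <- diag(c(b, b, 1 / b^2))
  st2 <- deformation_state(F2)
  dp <- demiray_params()
  trC <- 2 * b^2 + b^(-4)
  expect_equal(psi_demiray(st2, dp),
               dp$a / (2 * dp$b) * (exp(dp$b * (trC - 3)) - 1),
               tolerance = 1e-12)

  # frame indifference: rotated deformation gives identical energy
  th <- 0.45
  Q3 <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(psi_demiray(deformation_state(Q3 %*% F2), dp),
               psi_demiray(st2, dp), tolerance = 1e-12)
})

test_that("analytic PK2 stress matches finite differences of the energy", {
  set.seed(7)
  gp <- guccione_params()
  dp <- demiray_params()
  sqrtm <- function(C) {
    e <- eigen(C)
    e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors)
  }
  fd_stress <- function(psi_fun, C, h = 1e-6) {
    S <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      dC <- matrix(0, 3, 3)
      dC[i, j] <- dC[i, j] + h / 2
      dC[j, i] <- dC[j, i] + h / 2
      S[i, j] <- 2 * (psi_fun(sqrtm(C + dC)) - psi_fun(sqrtm(C - dC))) / (2 * h)
    }
    S
  }
  for (k in 1:100) {
    F <- diag(3) + 0.1 * matrix(rnorm(9), 3, 3)
    if (det(F) < 0.4) next
    st <- deformation_state(F)
    Sg <- pk2_passive(st, "guccione", gp, frame_xyz)
    Sg_fd <- fd_stress(function(Fh)
      psi_guccione(deformation_state(Fh), gp, frame_xyz), st$C)
    expect_equal(Sg, Sg_fd, tolerance = 1e-6)
    expect_equal(Sg, t(Sg), tolerance = 1e-12)

    Sd <- pk2_passive(st, "demiray", dp)
    Sd_fd <- fd_stress(function(Fh) psi_demiray(deformation_state(Fh), dp),
                       st$C)
    expect_equal(Sd, Sd_fd, tolerance = 1e-6)
    # isotropy: S commutes with C
    expect_equal(Sd %*% st$C, st$C %*% Sd, tolerance = 1e-8)
  }
  expect_error(deformation_state(diag(c(-1, 1, 1))), "inverted")
})

test_that("energies are non-negative under random isochoric perturbations", {
  set.seed(11)
  gp <- guccione_params(); dp <- demiray_params()
  for (k in 1:50) {
    A <- 0.1 * matrix(rnorm(9), 3, 3)
    F <- diag(3) + A
    F <- F / det(F)^(1 / 3)    # isochoric
    st <- deformation_state(F)
    expect_gte(psi_guccione(st, gp, frame_xyz), -1e-12)
    expect_gte(psi_demiray(st, dp), -1e-12)
  }
})

test_that("active stress transient gates, saturates, and stays continuous", {
  p28 <- active_params(S_peak = 60, t_dur = 380, tau_c0 = 30, tau_r = 30,
                       t_emd = 15)
  # onset and offset gates
  expect_equal(active_stress_scalar(10, t_a = 0, p = p28), 0)   # t_s < 0
  expect_equal(active_stress_scalar(15, t_a = 0, p = p28), 0)   # t_s = 0
  expect_equal(active_stress_scalar(395, t_a = 0, p = p28), 0)  # t_s = t_dur
  # saturation: maximum equals S_peak to 4 significant digits
  tgrid <- seq(0, 500, by = 0.1)
  smax <- max(active_stress_scalar(tgrid, t_a = 0, p = p28))
  expect_equal(signif(smax, 4), 60.0)
  # vanishes outside (t_a + t_emd, t_a + t_emd + t_dur), continuous inside
  s <- active_stress_scalar(tgrid, t_a = 40, p = p28)
  expect_true(all(s[tgrid <= 55 | tgrid >= 435] == 0))
  expect_lt(max(abs(diff(s))), 0.5)  # no jumps on a 0.1 ms grid
  # length dependence available behind the flag
  pl <- active_params(length_dependent = TRUE)
  expect_lt(active_stress_scalar(200, 0, lambda = 0.8, p = pl),
            active_stress_scalar(200, 0, lambda = 1.1, p = pl))
})

test_that("active stress tensor is rank-one along the fiber", {
  p <- active_params()
  f0 <- c(1, 0, 0)
  Sa <- 42
  expect_equal(active_stress_tensor(diag(3), f0, Sa), Sa * (f0 %o% f0))
  # fiber stretch lambda scales the prefactor by 1/lambda^2
  lam <- 1.15
  C <- diag(c(lam^2, 1, 1))
  expect_equal(active_stress_tensor(C, f0, Sa), Sa / lam^2 * (f0 %o% f0))
  # push-forward Cauchy stress is rank one with positive fiber eigenvalue
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  S <- active_stress_tensor(t(F) %*% F, f0, Sa)
  sigma <- F %*% S %*% t(F) / det(F)
  ev <- eigen(sigma, symmetric = TRUE)
  expect_equal(sum(abs(ev$values) > 1e-10), 1)
  expect_gt(max(ev$values), 0)
  fib_dir <- F %*% f0
  cosang <- abs(sum(ev$vectors[, 1] * fib_dir) /
                  sqrt(sum(fib_dir^2)))
  expect_equal(cosang, 1, tolerance = 1e-10)
})

test_that("fitted-case presets expose the expected parameter structure", {
  p <- em_preset("28-Pre")
  expect_s3_class(p$active, "active_params")
  expect_equal(p$active$S_peak, 60)
  expect_equal(p$windkessel$R, 170.65)
  p44 <- em_preset("44-Pre")
  expect_equal(p44$active$t_dur, 400)
  expect_false(em_preset("28-Post")$active$S_peak == p$active$S_peak)
})
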