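#' Orchestration of the weakly coupled electro-mechano-fluidic workflow
#'
#' One configuration drives the full chain: synthetic anatomy generation,
#' eikonal activation, the electromechanics heartbeat against the lumped
#' afterload, the kinematic transfer of wall motion onto the finer
#' non-conformal fluid mesh, and the moving-domain flow solve over the
#' ejection window. Coupling is strictly one-way (the flow never feeds back
#' on the mechanics). Every stage writes its artifacts to the run
#' directory, so stages can be re-run individually.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' All tunable constants addressable by name; presets reference the fitted
#' case \code{"28-Pre"} by default.
#'
#' @param seed integer seed recorded and used for every stochastic element.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    case = "28-Pre",
    anatomy = list(wall_thickness = 10, long_axis = 45, short_axis = 26,
                   base_cut = 0.3, resolution = 8),
    ep = list(v_f = 0.6, v_s = 0.4, v_n = 0.2, source_radius = 6),
    mechanics = list(dt = 5, t_end = 650, p_ED_mmHg = 10, p_ao0_mmHg = 71.1,
                     p_la_mmHg = 8, snapshot_stride = 1),
    transfer = list(refinement = 1.4, E0 = 100, nu0 = 0.3,
                    volume_ratio_threshold = 0.2, nu_stiff = 0.49),
    cfd = list(enabled = TRUE, dt = 1, rho_f = 1060, mu_f = 0.004,
               beta_backflow = 0.2, C_M = 0.0285),
    output = list(write_meshes = TRUE, write_snapshots = FALSE)
  )
}

#' Validate a pipeline configuration
#'
#' Schema check: required sections and fields present, numeric ranges sane.
#'
#' @param config configuration list (or path to a YAML file).
#' @return the validated configuration, invisibly errors otherwise.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("seed", "case", "anatomy", "ep", "mechanics", "transfer", "cfd")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop_emf("config missing sections: ", paste(miss, collapse = ", "))
  an <- config$anatomy
  stopifnot(an$wall_thickness > 0, an$resolution > 0,
            an$base_cut > 0, an$base_cut <= 0.9)
  stopifnot(config$mechanics$dt > 0, config$cfd$dt > 0)
  if (!config$case %in% c("28-Pre", "28-Post", "44-Pre"))
    stop_emf("unknown case preset: ", config$case)
  invisible(config)
}

#' Run the full pipeline
#'
#' @param config configuration list or YAML path (see
#'   \code{\link{default_config}}).
#' @param output_dir run directory (created).
#' @param stages subset of c("generate", "em", "transfer_cfd", "report").
#' @param dry_run validate and echo the configuration without computing.
#' @param verbose print stage progress.
#' @return list with the run \code{summary} (also written as JSON),
#'   \code{config}, and in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), output_dir = tempfile("emfrun"),
                         stages = c("generate", "em", "transfer_cfd", "report"),
                         dry_run = FALSE, verbose = TRUE) {
  config <- validate_config(config)
  if (dry_run) return(list(config = config, summary = NULL, dry_run = TRUE))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  yaml::write_yaml(config, file.path(output_dir, "config.yaml"))
  res <- list(config = config, output_dir = output_dir)
  on_fail <- function(stage, e) {
    writeLines(paste0("stage ", stage, " failed: ", conditionMessage(e)),
               file.path(output_dir, "error.txt"))
    stop_emf("stage ", stage, " failed (partial outputs kept in ",
             output_dir, "): ", conditionMessage(e))
  }

  if ("generate" %in% stages) {
    emf_log(verbose, "[generate] synthetic anatomy")
    res$mesh <- tryCatch({
      an <- config$anatomy
      lv <- make_lv_ellipsoid(wall_thickness = an$wall_thickness,
                              long_axis = an$long_axis,
                              short_axis = an$short_axis,
                              base_cut = an$base_cut,
                              resolution = an$resolution,
                              seed = config$seed)
      if (isTRUE(config$output$write_meshes))
        write_mesh(lv, file.path(output_dir, "lv_em.vtk"))
      yaml::write_yaml(attr(lv, "manifest"),
                       file.path(output_dir, "anatomy_manifest.yaml"))
      lv
    }, error = function(e) on_fail("generate", e))
  }

  if ("em" %in% stages) {
    emf_log(verbose, "[em] activation + heartbeat")
    res$em <- tryCatch({
      lv <- res$mesh %||% read_mesh(file.path(output_dir, "lv_em.vtk"))
      solid <- solid_submesh(lv)
      preset <- em_preset(config$case)
      ctx <- em_context(solid,
                        materials = default_materials(C_Guc = preset$C_Guc),
                        dirichlet_tags = c("dirichlet", "rim"))
      src <- apical_source(ctx$mesh, radius = config$ep$source_radius)
      am <- solve_eikonal(ctx$mesh, ctx$fibers,
                          conduction_velocities(config$ep$v_f, config$ep$v_s,
                                                config$ep$v_n),
                          src, region = "lv")
      mech <- config$mechanics
      wk <- windkessel_lv(R = preset$windkessel$R, Z_c = preset$windkessel$Z_c,
                          C = preset$windkessel$C, R_av = 1)
      hb <- run_heartbeat(ctx, am, act = preset$active, wk = wk,
                          p_ED = mmHg_to_kPa(mech$p_ED_mmHg),
                          p_ao0 = mmHg_to_kPa(mech$p_ao0_mmHg),
                          p_la = mmHg_to_kPa(mech$p_la_mmHg),
                          dt = mech$dt, t_end = mech$t_end,
                          store_stride = mech$snapshot_stride)
      write_trace_csv(hb$trace, file.path(output_dir, "em_trace.csv"))
      ta_csv <- data.frame(vertex = seq_along(am$t_a), t_a_ms = am$t_a)
      utils::write.csv(ta_csv, file.path(output_dir, "activation.csv"),
                       row.names = FALSE)
      list(ctx = ctx, activation = am, heartbeat = hb, solid = solid, lv = lv)
    }, error = function(e) on_fail("em", e))
  }

  if ("transfer_cfd" %in% stages && isTRUE(config$cfd$enabled)) {
    emf_log(verbose, "[transfer_cfd] kinematic transfer + ALE flow")
    res$cfd <- tryCatch({
      em <- res$em
      hb <- em$heartbeat
      win <- c(hb$metrics$valve_open_t, hb$metrics$valve_close_t)
      if (anyNA(win)) stop_emf("no ejection window in the EM run")
      cfd_mesh <- make_cfd_cavity(em$lv, refinement = config$transfer$refinement,
                                  seed = config$seed)
      if (isTRUE(config$output$write_meshes))
        write_mesh(cfd_mesh, file.path(output_dir, "cavity_cfd.vtk"))
      run <- run_ejection_cfd(em$lv, em$solid, hb, cfd_mesh, config,
                              output_dir, verbose = verbose)
      write_trace_csv(run$trace, file.path(output_dir, "cfd_trace.csv"))
      run
    }, error = function(e) on_fail("transfer_cfd", e))
  }

  if ("report" %in% stages) {
    emf_log(verbose, "[report] summary")
    res$summary <- tryCatch({
      s <- pipeline_summary(res, config)
      jsonlite::write_json(s, file.path(output_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      s
    }, error = function(e) on_fail("report", e))
  }
  res
}

# drive the ALE flow solve on the CFD cavity over the ejection window,
# moving the mesh via the two-stage kinematic transfer from the EM run
run_ejection_cfd <- function(lv_full, solid, hb, cfd_mesh, config,
                             output_dir = NULL, verbose = FALSE) {
  snap_t <- hb$snapshot_times
  win <- c(hb$metrics$valve_open_t, hb$metrics$valve_close_t)
  smap <- attr(solid, "vertex_map")
  bp <- submesh(lv_full, c("av", "mv", "lvbp"))
  bpmap <- attr(bp, "vertex_map")
  nv_full <- nrow(lv_full$vertices)
  bsurf <- sort(unique(as.vector(bp$boundary_facets)))
  bp_solve <- pe_factor(bp, bsurf)   # constant-coefficient solve, factor once
  # extend a solid displacement onto the full background mesh
  extend_full <- function(d_solid) {
    d_full <- matrix(0, nv_full, 3)
    d_full[smap, ] <- d_solid
    bvals <- d_full[bpmap[bsurf], , drop = FALSE]
    d_bp <- bp_solve(bvals)
    d_full[bpmap, ] <- d_bp
    d_full[smap, ] <- d_solid      # solid values win on the interface
    d_full
  }
  # the CFD surface vertices sit at fixed reference positions in the fixed
  # background mesh: locate them once
  surf_v <- sort(unique(as.vector(cfd_mesh$boundary_facets)))
  fix_v <- tagged_vertices(cfd_mesh, "outlet_1")
  mov_v <- setdiff(surf_v, fix_v)
  loc_surf <- locate_points(lv_full, cfd_mesh$vertices[mov_v, , drop = FALSE])
  d_at <- function(t) {
    # linear interpolation between mechanics snapshots
    t <- min(max(t, snap_t[1]), snap_t[length(snap_t)])
    k <- findInterval(t, snap_t, rightmost.closed = TRUE)
    k <- min(max(k, 1L), length(snap_t) - 1L)
    frac <- (t - snap_t[k]) / (snap_t[k + 1] - snap_t[k])
    (1 - frac) * hb$snapshots[[k]] + frac * hb$snapshots[[k + 1]]
  }
  pe_par <- pseudo_elastic_params(E0 = config$transfer$E0,
                                  nu0 = config$transfer$nu0,
                                  volume_ratio_threshold =
                                    config$transfer$volume_ratio_threshold,
                                  nu_stiff = config$transfer$nu_stiff)
  preset <- em_preset(config$case)
  props <- fluid_props(config$cfd$rho_f, config$cfd$mu_f,
                       config$cfd$beta_backflow)
  # outlet Windkessel at the valve orifice from the case's clinical data
  cl <- clinical_record(if (config$case == "44-Pre") "44-Pre" else "28-Pre")
  wk_out <- estimate_outlet_params(cl$MAP, cl$CO, 1)
  wk_out$p_d <- mmHg_to_kPa(cl$P_dia)
  dt <- config$cfd$dt
  n_steps <- cfd_step_count(win[1], win[2], dt)
  if (!is.null(config$cfd$max_steps))
    n_steps <- min(n_steps, as.integer(config$cfd$max_steps))
  state <- new_flow_state(cfd_mesh)
  # start the fluid mesh in the valve-opening configuration, otherwise the
  # first step sees the whole opening displacement as one-step mesh motion
  d_full0 <- extend_full(d_at(win[1]))
  dsurf0 <- interpolate_at(lv_full, loc_surf, d_full0)
  d_prev <- solve_pseudo_elastic(cfd_mesh,
                                 list(vertices = c(mov_v, fix_v),
                                      values = rbind(as.matrix(dsurf0),
                                                     matrix(0, length(fix_v), 3))),
                                 pe_par)
  state$d_mesh <- d_prev
  rows <- list()
  quality_log <- list()
  for (k in seq_len(n_steps)) {
    t_new <- win[1] + k * dt
    d_full <- extend_full(d_at(t_new))
    dsurf <- interpolate_at(lv_full, loc_surf, d_full)
    bidx <- c(mov_v, fix_v)
    bval <- rbind(as.matrix(dsurf), matrix(0, length(fix_v), 3))
    qs <- quality_stiffen(cfd_mesh, d_prev, E0 = pe_par$E0)
    nu_el <- nu_volume_stiffen(cfd_mesh,
                               abs(element_volumes(cfd_mesh,
                                                   cfd_mesh$vertices +
                                                     (d_prev %||% 0))),
                               abs(element_volumes(cfd_mesh)), pe_par)
    d_new <- solve_pseudo_elastic(cfd_mesh,
                                  list(vertices = bidx, values = bval),
                                  pe_par, E_elem = qs$E, nu_elem = nu_el)
    tra <- list(d = d_new)
    state <- step_ale_ns(state, cfd_mesh, d_new = tra$d,
                         outlets = list(outlet_1 = wk_out), props = props,
                         dt = dt, C_M = config$cfd$C_M)
    wk_out <- state$outlets$outlet_1
    q <- element_quality(cfd_mesh, cfd_mesh$vertices + tra$d)
    quality_log[[k]] <- c(worst = max(q$rescaled),
                          p80 = unname(stats::quantile(q$rescaled, 0.8)),
                          inverted = sum(q$inverted))
    rows[[k]] <- data.frame(time_ms = t_new,
                            q_outlet_ml_s = state$flux$outlet_1 * 1e6,
                            p_wk_kPa = wk_out$p_wk,
                            worst_quality = max(q$rescaled),
                            inverted = sum(q$inverted))
    d_prev <- tra$d
    emf_log(verbose, "  cfd t=%.1f ms q=%.1f ml/s worst quality %.3f",
            t_new, state$flux$outlet_1 * 1e6, max(q$rescaled))
  }
  list(trace = do.call(rbind, rows), n_steps = n_steps, state = state,
       quality = do.call(rbind, quality_log),
       dof = dof_count(cfd_mesh))
}

pipeline_summary <- function(res, config) {
  s <- list(case = config$case, seed = config$seed)
  if (!is.null(res$em)) {
    m <- res$em$heartbeat$metrics
    hr_period <- NA_real_
    s$em <- list(EDV_ml = m$EDV, ESV_ml = m$ESV, SV_ml = m$SV, EF_pct = m$EF,
                 p_peak_mmHg = kPa_to_mmHg(m$p_peak),
                 dpdt_max_mmHg_ms = kPa_to_mmHg(m$dpdt_max),
                 valve_open_ms = m$valve_open_t,
                 valve_close_ms = m$valve_close_t,
                 total_activation_ms =
                   max(res$em$activation$t_a[is.finite(res$em$activation$t_a)]),
                 dof = 3L * nrow(res$em$solid$vertices))
  }
  if (!is.null(res$cfd)) {
    tr <- res$cfd$trace
    s$cfd <- list(n_steps = res$cfd$n_steps,
                  dof_u = res$cfd$dof$dof_u, dof_p = res$cfd$dof$dof_p,
                  dof_total = res$cfd$dof$dof_total,
                  peak_flux_ml_s = max(tr$q_outlet_ml_s),
                  worst_quality = max(tr$worst_quality),
                  inverted_elements = sum(tr$inverted))
  }
  s
}

#' Compare simulated metrics with the clinical record
#'
#' Builds the comparison table (clinical vs simulated EDV, ESV, SV, EF, CO
#' with relative errors) from a completed run directory or an in-memory
#' result. Missing quantities are reported as gaps.
#'
#' @param run a \code{\link{run_pipeline}} result or a run directory path.
#' @param case clinical preset to compare against (default: the run's).
#' @return data.frame with columns metric, clinical, simulated, rel_error_pct.
#' @export
report_summary <- function(run, case = NULL) {
  if (is.character(run)) {
    sfile <- file.path(run, "summary.json")
    s <- if (file.exists(sfile)) jsonlite::read_json(sfile, simplifyVector = TRUE)
    else list()
    case <- case %||% s$case %||% "28-Pre"
    em <- s$em
  } else {
    case <- case %||% run$config$case
    em <- run$summary$em
  }
  if (identical(case, "28-Post")) case <- "28-Pre"
  cl <- clinical_record(case, source = "comparison")
  hr <- clinical_record(case, source = "catheter")$HR
  metrics <- c("EDV", "ESV", "SV", "EF", "CO")
  clin <- c(cl$EDV, cl$ESV, cl$SV, cl$EF, cl$CO)
  sim <- rep(NA_real_, 5)
  if (!is.null(em)) {
    period_s <- 60 / hr
    sim <- c(em$EDV_ml, em$ESV_ml, em$SV_ml, em$EF_pct,
             em$SV_ml / period_s)
  }
  data.frame(metric = metrics, clinical = clin, simulated = sim,
             rel_error_pct = 100 * abs(sim - clin) / clin)
}
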