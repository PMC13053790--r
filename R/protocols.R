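#' Protocol configuration for the two-phase loading experiments
#'
#' End-diastole: endocardial pressure `p_ed` with no active tension.
#' End-systole: model-appropriate end-systolic pressure (`p_es_healthy` for
#' the control model, `p_es_diseased` for the infarcted and implanted
#' models) with maximal activation (ct = 1, peak calcium at its maximum).
#'
#' @param p_ed end-diastolic pressure (Pa).
#' @param p_es_healthy end-systolic pressure of the control model (Pa).
#' @param p_es_diseased end-systolic pressure of the diseased models (Pa).
#' @param strain_kind `"fiber"` (fiber-direction Green strain E11) or
#'   `"first_principal"` (largest eigenvalue of E).
#' @param solver a [solver_config].
#' @return an object of class `protocol_config`.
#' @export
protocol_config <- function(p_ed = 1500, p_es_healthy = 13000,
                            p_es_diseased = 10000,
                            strain_kind = c("fiber", "first_principal"),
                            solver = solver_config()) {
  stopifnot(p_ed >= 0, p_es_healthy >= 0, p_es_diseased >= 0)
  structure(list(p_ed = p_ed, p_es_healthy = p_es_healthy,
                 p_es_diseased = p_es_diseased,
                 strain_kind = match.arg(strain_kind),
                 solver = solver),
            class = "protocol_config")
}

#' Pascals per mmHg
#' @export
MMHG_PA <- 133.322

#' Assemble one of the study's LV models
#'
#' Builds the mesh, region assignment and material mapping for the three
#' models compared in the simulation study, plus the patch-free variant
#' used in the stiffness-attribution analysis:
#' \describe{
#'   \item{control}{healthy material everywhere, no thinning, no patch;
#'     region sectors are still labelled so that regional strains can be
#'     compared across models on matched wall sectors.}
#'   \item{infarcted}{IZ thinned to 1/3 thickness with infarct-scar
#'     material; no patch.}
#'   \item{implanted}{as infarcted, but IZ carries the patch-implanted
#'     scar material and a passive epicardial patch layer covers the
#'     IZ + BZ window.}
#'   \item{patch_free}{implanted-type IZ material but no patch elements.}
#' }
#' The scar (IZ) of the diseased models generates no active tension
#' (`active_iz = FALSE`); the patch is passive by default.
#'
#' @param type model type.
#' @param geom an [lv_geometry].
#' @param infarct_fraction,thinning_ratio,patch_coverage,patch_thickness
#'   region parameters, see [region_spec()].
#' @param iz_scale factor applied to the IZ passive exponent coefficients
#'   (stiffness-sensitivity sweep); 1 = printed material.
#' @param active_iz logical, let the IZ develop active tension.
#' @param patch_active logical, let the patch develop active tension.
#' @return an object of class `lv_model`: mesh, materials, active regions.
#' @export
lv_model <- function(type = c("control", "infarcted", "implanted",
                              "patch_free"),
                     geom = lv_geometry(),
                     infarct_fraction = 0.134, thinning_ratio = 1 / 3,
                     patch_coverage = 0.228, patch_thickness = 1,
                     iz_scale = 1, active_iz = FALSE, patch_active = FALSE) {
  type <- match.arg(type)
  base <- build_lv_mesh(geom)
  spec <- switch(type,
    control = region_spec(infarct_fraction, 1, patch_coverage,
                          patch_thickness, patch = FALSE),
    infarcted = region_spec(infarct_fraction, thinning_ratio, patch_coverage,
                            patch_thickness, patch = FALSE),
    implanted = region_spec(infarct_fraction, thinning_ratio, patch_coverage,
                            patch_thickness, patch = TRUE),
    patch_free = region_spec(infarct_fraction, thinning_ratio, patch_coverage,
                             patch_thickness, patch = FALSE))
  mesh <- assign_regions(base, spec)
  iz_mat <- switch(type,
    control = material_params("healthy"),
    infarcted = material_params("infarcted"),
    implanted = material_params("implanted"),
    patch_free = material_params("implanted"))
  if (iz_scale != 1) iz_mat <- scale_material(iz_mat, iz_scale)
  materials <- list(IZ = iz_mat,
                    BZ = material_params("healthy"),
                    RZ = material_params("healthy"),
                    patch = material_params("patch"))
  active_regions <- if (type == "control") c("IZ", "BZ", "RZ")
                    else c("BZ", "RZ")
  if (active_iz && type != "control") active_regions <- c(active_regions, "IZ")
  if (patch_active) active_regions <- c(active_regions, "patch")
  structure(list(type = type, mesh = mesh, materials = materials,
                 active_regions = active_regions, geom = geom, spec = spec),
            class = "lv_model")
}

#' @export
print.lv_model <- function(x, ...) {
  cat(sprintf("LV model [%s]: %d elements, active regions: %s\n",
              x$type, nrow(x$mesh$elems),
              paste(x$active_regions, collapse = ", ")))
  invisible(x)
}

#' Solve the end-diastolic state
#'
#' Passive inflation at `p_ed` with no active force (T = 0).
#'
#' @param model an [lv_model].
#' @param config a [protocol_config].
#' @return a [solve_static()] `sim_state`.
#' @export
run_end_diastole <- function(model, config = protocol_config()) {
  solve_static(model$mesh, model$materials, pressure = config$p_ed, ct = 0,
               config = config$solver, active_regions = model$active_regions)
}

#' Solve the end-systolic state
#'
#' Model-appropriate end-systolic pressure together with maximal activation
#' (ct = 1, peak calcium at its maximum) in the active regions.
#'
#' @inheritParams run_end_diastole
#' @return a `sim_state`.
#' @export
run_end_systole <- function(model, config = protocol_config()) {
  p_es <- if (model$type == "control") config$p_es_healthy
          else config$p_es_diseased
  solve_static(model$mesh, model$materials, pressure = p_es, ct = 1,
               config = config$solver, active_regions = model$active_regions)
}

#' Ejection fraction from two states
#'
#' 100 (EDV - ESV) / EDV from deformed cavity volumes.
#'
#' @param ed,es `sim_state` objects (end-diastole, end-systole).
#' @return percent.
#' @export
ejection_fraction <- function(ed, es) {
  100 * (ed$cavity_volume - es$cavity_volume) / ed$cavity_volume
}

#' Regional mean strain report
#'
#' Volume-weighted mean over the wall elements of each region (IZ, BZ, RZ)
#' of the fiber-direction Green strain E11 or the first-principal Green
#' strain.
#'
#' @param state a `sim_state`.
#' @param strain_kind `"fiber"` or `"first_principal"`.
#' @return an object of class `regional_strain_report`: data.frame with
#'   columns `region`, `mean_strain`.
#' @export
regional_strain <- function(state, strain_kind = c("fiber", "first_principal")) {
  strain_kind <- match.arg(strain_kind)
  mesh <- state$mesh
  val <- if (strain_kind == "fiber") state$strains[, "Ef11"]
         else principal_strain(state)
  w <- state$strains[, "vol_ref"]
  out <- do.call(rbind, lapply(c("IZ", "BZ", "RZ"), function(rg) {
    sel <- mesh$region == rg
    if (!any(sel)) return(NULL)
    data.frame(region = rg,
               mean_strain = sum(val[sel] * w[sel]) / sum(w[sel]))
  }))
  structure(out, class = c("regional_strain_report", "data.frame"),
            strain_kind = strain_kind)
}

#' Relative strain reduction between two states
#'
#' Percent reduction of the regional mean strain of `state_b` relative to
#' `state_a` over matched wall sectors:
#' 100 (strain_a - strain_b) / |strain_a| for `mode = "relative"`, or
#' 100 (strain_a - strain_b) percentage points for `mode = "absolute"`.
#'
#' @param state_a,state_b `sim_state` objects on matched meshes.
#' @param region region label.
#' @param strain_kind `"fiber"` or `"first_principal"`.
#' @param mode `"relative"` (default) or `"absolute"`.
#' @return percent (scalar).
#' @export
strain_reduction <- function(state_a, state_b, region = "IZ",
                             strain_kind = c("fiber", "first_principal"),
                             mode = c("relative", "absolute")) {
  strain_kind <- match.arg(strain_kind)
  mode <- match.arg(mode)
  ra <- regional_strain(state_a, strain_kind)
  rb <- regional_strain(state_b, strain_kind)
  a <- ra$mean_strain[ra$region == region]
  b <- rb$mean_strain[rb$region == region]
  if (mode == "relative") 100 * (a - b) / abs(a) else 100 * (a - b)
}

#' Run the full two-phase protocol for a set of models
#'
#' Solves end-diastole and end-systole for each requested model and
#' derives ejection fractions and regional strain summaries. All solves
#' are deterministic.
#'
#' @param types character vector of model types.
#' @param geom an [lv_geometry].
#' @param config a [protocol_config].
#' @param ... passed to [lv_model()].
#' @return an object of class `lv_protocol_result`: named list per model
#'   with `ed`, `es` states, `ef`, and regional strain reports.
#' @export
run_protocol <- function(types = c("control", "infarcted", "implanted"),
                         geom = lv_geometry(),
                         config = protocol_config(), ...) {
  out <- lapply(types, function(tp) {
    model <- lv_model(tp, geom = geom, ...)
    ed <- run_end_diastole(model, config)
    es <- run_end_systole(model, config)
    list(model = model, ed = ed, es = es,
         ef = ejection_fraction(ed, es),
         strain_ed = regional_strain(ed, config$strain_kind),
         strain_es = regional_strain(es, config$strain_kind))
  })
  names(out) <- types
  structure(out, class = "lv_protocol_result")
}

#' @export
print.lv_protocol_result <- function(x, ...) {
  for (nm in names(x)) {
    cat(sprintf("%-10s EF = %5.1f %%  (EDV %.1f ml, ESV %.1f ml)\n", nm,
                x[[nm]]$ef, x[[nm]]$ed$cavity_volume,
                x[[nm]]$es$cavity_volume))
  }
  invisible(x)
}

#' Stiffness-sensitivity sweep of the patch-treated infarct material
#'
#' Rescales the implanted model's IZ passive exponent coefficients by each
#' factor, re-solves the two-phase protocol, and reports the regional
#' strain reductions against the infarcted baseline (all regions, at
#' end-systole by default).
#'
#' @param factors numeric vector of scale factors (1 = printed material).
#' @param geom an [lv_geometry].
#' @param config a [protocol_config].
#' @param baseline optional precomputed infarcted baseline entry from
#'   [run_protocol()] (avoids re-solving).
#' @param phase `"ES"` or `"ED"`: phase at which reductions are evaluated.
#' @param ... passed to [lv_model()].
#' @return data.frame with columns `factor`, `region`, `reduction`
#'   (percent, relative).
#' @export
stiffness_sweep <- function(factors = c(1, 0.5, 0.2), geom = lv_geometry(),
                            config = protocol_config(), baseline = NULL,
                            phase = c("ES", "ED"), ...) {
  phase <- match.arg(phase)
  if (is.null(baseline)) {
    baseline <- run_protocol("infarcted", geom = geom, config = config,
                             ...)$infarcted
  }
  base_state <- if (phase == "ES") baseline$es else baseline$ed
  rows <- lapply(factors, function(fc) {
    model <- lv_model("implanted", geom = geom, iz_scale = fc, ...)
    st <- if (phase == "ES") run_end_systole(model, config)
          else run_end_diastole(model, config)
    do.call(rbind, lapply(c("IZ", "BZ", "RZ"), function(rg)
      data.frame(factor = fc, region = rg,
                 reduction = strain_reduction(base_state, st, rg,
                                              config$strain_kind))))
  })
  do.call(rbind, rows)
}

#' Strain reduction of the patch-free variant
#'
#' The model with patch-treated (implanted-type) IZ material but no patch
#' elements, compared with the infarcted baseline: isolates the
#' contribution of the altered scar material from that of the patch layer.
#'
#' @inheritParams stiffness_sweep
#' @return data.frame with columns `region`, `reduction` (percent).
#' @export
patch_free_variant <- function(geom = lv_geometry(),
                               config = protocol_config(), baseline = NULL,
                               phase = c("ES", "ED"), ...) {
  phase <- match.arg(phase)
  if (is.null(baseline)) {
    baseline <- run_protocol("infarcted", geom = geom, config = config,
                             ...)$infarcted
  }
  base_state <- if (phase == "ES") baseline$es else baseline$ed
  model <- lv_model("patch_free", geom = geom, ...)
  st <- if (phase == "ES") run_end_systole(model, config)
        else run_end_diastole(model, config)
  do.call(rbind, lapply(c("IZ", "BZ", "RZ"), function(rg)
    data.frame(region = rg,
               reduction = strain_reduction(base_state, st, rg,
                                            config$strain_kind))))
}

#' Passive pressure-volume curve
#'
#' Sequence of passive inflations (no active tension) over a pressure
#' grid; the in-silico analogue of an ex-vivo passive filling experiment.
#'
#' @param model an [lv_model].
#' @param pressures_mmhg pressure grid (mmHg).
#' @param config a [protocol_config].
#' @return data.frame with columns `pressure_mmhg`, `pressure_pa`,
#'   `volume_ml`, of class `pv_curve`.
#' @export
passive_pv_curve <- function(model, pressures_mmhg = seq(0, 30, by = 5),
                             config = protocol_config()) {
  rows <- lapply(pressures_mmhg, function(pm) {
    p <- pm * MMHG_PA
    vol <- if (p == 0) cavity_volume(model$mesh) else {
      st <- solve_static(model$mesh, model$materials, pressure = p, ct = 0,
                         config = config$solver,
                         active_regions = model$active_regions)
      st$cavity_volume
    }
    data.frame(pressure_mmhg = pm, pressure_pa = p, volume_ml = vol)
  })
  structure(do.call(rbind, rows), class = c("pv_curve", "data.frame"))
}

#' Plot a passive pressure-volume curve
#'
#' @param x a `pv_curve`.
#' @param ... passed to [plot()].
#' @export
plot.pv_curve <- function(x, ...) {
  graphics::plot(x$volume_ml, x$pressure_mmhg, type = "b",
                 xlab = "cavity volume (ml)", ylab = "pressure (mmHg)", ...)
  invisible(x)
}

#' Deterministic JSON summary of a protocol result
#'
#' Serializes ejection fractions, cavity volumes and regional strains with
#' fixed formatting: identical configurations give bit-identical files.
#'
#' @param result an `lv_protocol_result`.
#' @param path output file; NULL returns the JSON string.
#' @return the JSON string, invisibly if written to file.
#' @export
protocol_summary_json <- function(result, path = NULL) {
  summ <- lapply(result, function(r) {
    list(type = r$model$type,
         edv_ml = round(r$ed$cavity_volume, 6),
         esv_ml = round(r$es$cavity_volume, 6),
         ef_percent = round(r$ef, 6),
         strain_ed = setNames(round(r$strain_ed$mean_strain, 8),
                              r$strain_ed$region),
         strain_es = setNames(round(r$strain_es$mean_strain, 8),
                              r$strain_es$region))
  })
  js <- jsonlite::toJSON(summ, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
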