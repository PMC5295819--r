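# The model catalogue: executable encodings of the in-scope printed
# conflict models.  Each entry stores its KRN expressions as printed (with
# obvious typographic slips resolved to the contextually consistent reading,
# noted inline), an initial-canvas recipe, a polariser recipe, a phase
# schedule, and events.  Growth rates are fractional rates per hour.
#
# The thickness rate is stored verbatim per model: the square conflict
# models print Knor = 0.044 while the dome/wedge models state thickness
# growth of 0.44 %/h (0.0044 per hour); both values are kept as printed
# rather than silently reconciled.

# default stated-world geometry for the square models: 100 um side, 2 um
# initial thickness (the source figures depict thin plates, thickness a few
# percent of the side; a thick plate cannot buckle at the printed rates),
# 1% sagitta
.square_side <- 100

square_recipe <- function(sagitta = 0.01 * .square_side, noise = 0,
                          clones = TRUE, size_preserving_edge = FALSE) {
  function(resolution = .square_side / 12, seed = 1) {
    cv <- make_square_canvas(.square_side, resolution = resolution,
                             curvature_sagitta = sagitta,
                             z_noise_amplitude = noise, seed = seed,
                             thickness = 2)
    cv <- setup_square_factors(cv)
    if (size_preserving_edge) cv <- setup_size_preserving_edge(cv)
    if (clones) cv <- induce_clones(cv, radius = 5, spacing = 25)
    cv
  }
}

strip_recipe <- function(width = 1060, height = 120) {
  function(resolution = height / 4, seed = 1) {
    cv <- make_strip_canvas(width, height, resolution = resolution,
                            thickness = 10)
    cv <- setup_wedge_factors(cv)
    cv$time <- 240  # the wedge models start at 10 DAI
    cv
  }
}

model_entry <- function(name, canvas_fn, polariser, phases, events = list(),
                        t_end = 15, description = "",
                        orthogonal_ablation = NULL) {
  structure(list(name = name, canvas_fn = canvas_fn, polariser = polariser,
                 phases = phases, events = events, t_end = t_end,
                 description = description,
                 orthogonal_ablation = orthogonal_ablation),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat("<tissue model>", x$name, "\n")
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  for (p in x$phases) {
    cat(sprintf("  phase %g..%g h:\n", p$t0, p$t1))
    out <- utils::capture.output(print(p$spec))
    cat(paste0("    ", out, collapse = "\n"), "\n")
  }
  invisible(x)
}

one_phase <- function(spec) list(list(t0 = 0, t1 = Inf, spec = spec))

# ---- the catalogue -------------------------------------------------------

build_catalogue <- function() {
  cat_ <- list()
  add <- function(entry) cat_[[entry$name]] <<- entry
  pol_none <- NULL
  pol_parallel <- pol_config(production = "BOTTOM", fixed = list(TOP = 0.01))
  pol_convergent <- pol_config(production = "FOCI", degradation = "EDGE")
  pol_channel <- pol_config(production = "BOTTOM", degradation = "TOPMID")
  pol_proxdist <- pol_config(production = "isource", fixed = list(isink = 0.01))

  ## square conflict models
  add(model_entry("fig1_isotropic", square_recipe(),
    pol_none,
    one_phase(growth_spec("0.03", "0.03", "0.044")),
    description = "uniform isotropic specified growth (conflict-free)"))
  add(model_entry("fig1_anisotropic", square_recipe(),
    pol_parallel,
    one_phase(growth_spec("0.03", "0.02", "0.044")),
    description = "uniform anisotropic growth in a parallel polarity field"))
  add(model_entry("fig1_surface", square_recipe(),
    pol_none,
    one_phase(growth_spec(knor = "0.044",
                          kpar_a = "0.06", kper_a = "0.06",
                          kpar_b = "0.05", kper_b = "0.05")),
    description = "surface conflict: A surface specified to grow faster"))
  add(model_entry("fig1_areal", square_recipe(),
    pol_none,
    one_phase(growth_spec("0.05 + 0.05*icentre", "0.05 + 0.05*icentre",
                          "0.044")),
    description = "areal conflict: faster isotropic growth at the centre"))
  add(model_entry("fig1_directional", square_recipe(),
    pol_convergent,
    one_phase(growth_spec("0.05", "0.02", "0.044")),
    description = "directional conflict in a convergent polarity field"))

  ## flat-start variants (seeded height noise instead of initial curvature)
  add(model_entry("fig1s1_areal_flat",
    square_recipe(sagitta = 0, noise = 0.001 * .square_side),
    pol_none,
    one_phase(growth_spec("0.05 + 0.05*icentre", "0.05 + 0.05*icentre",
                          "0.044")),
    description = "areal conflict from a flat noisy start"))
  add(model_entry("fig1s1_directional_flat",
    square_recipe(sagitta = 0, noise = 0.001 * .square_side),
    pol_convergent,
    one_phase(growth_spec("0.05", "0.02", "0.044")),
    description = "directional conflict from a flat noisy start"))

  ## orthogonal directional conflict family
  add(model_entry("fig6_orthogonal", square_recipe(),
    pol_convergent,
    one_phase(growth_spec(
      "0.05 + 0.05*sjun + 0.05*srim - 0.2*sjun*srim",
      "0.05 - 0.05*sjun - 0.05*srim + 0.2*sjun*srim", "0.044")),
    description = "orthogonal directional conflict, convergent field (Karea uniform)"))
  add(model_entry("fig6_T", square_recipe(),
    pol_convergent,
    one_phase(growth_spec(
      "0.05 + 0.05*sjun + 0.05*srim*ihalfside - 0.1*sjun*srim",
      "0.05 - 0.05*sjun - 0.05*srim*ihalfside + 0.1*sjun*srim", "0.044")),
    description = "T-shaped directional conflict"))
  add(model_entry("fig6_L", square_recipe(),
    pol_convergent,
    one_phase(growth_spec(
      "0.05 + 0.05*sjun*idistalhalf + 0.05*srim*ihalfside - 0.02*sjun*srim",
      "0.05 - 0.05*sjun*idistalhalf - 0.05*srim*ihalfside + 0.02*sjun*srim",
      "0.044")),
    description = "L-shaped directional conflict"))
  add(model_entry("fig6_I", square_recipe(),
    pol_convergent,
    one_phase(growth_spec(
      "0.05 + 0.05*sjun - 0.1*sjun*srim",
      "0.05 - 0.05*sjun + 0.1*sjun*srim", "0.044")),
    description = "directional conflict in the vertical domain only"))
  add(model_entry("fig6_one_arm", square_recipe(),
    pol_convergent,
    one_phase(growth_spec(
      "0.05 + 0.05*sjun*idistalhalf",
      "0.05 - 0.05*sjun*idistalhalf", "0.044")),
    description = "directional conflict in the upper half of the vertical domain"))
  add(model_entry("fig6_parallel", square_recipe(),
    pol_parallel,
    one_phase(growth_spec(
      "0.05 + 0.05*sjun - 0.05*srim",
      "0.05 - 0.05*sjun + 0.05*srim", "0.044")),
    description = "orthogonal directional conflict in a parallel polarity field"))
  add(model_entry("fig6_areal_orthogonal", square_recipe(),
    pol_none,
    one_phase(growth_spec(
      "0.05 + 0.05*sjun + 0.05*srim - 0.02*sjun*srim",
      "0.05 + 0.05*sjun + 0.05*srim - 0.02*sjun*srim", "0.044")),
    description = "areal conflict boosted in the orthogonal domains (isotropic)"))
  add(model_entry("fig6_channel", square_recipe(),
    pol_channel,
    one_phase(growth_spec(
      "0.05 + 0.05*sjun + 0.05*srim*imargins - 0.075*sjun*srim",
      "0.05 - 0.05*srim*imargins - 0.05*sjun + 0.075*sjun*srim", "0.044")),
    events = list(list(id = "lock_channel", time = 0,
                       action = function(cv) {
                         cen <- tri_centroids(cv)
                         side <- diff(range(cv$vertices[, 1]))
                         hw <- max(0.05 * side, cv$meta$target_edge %||% 0)
                         cv <- lock_polarity_channel(cv, which(abs(cen[, 1]) <= hw))
                         # the locked channel acts as a weak POL sink, so
                         # flanking polarity reorients toward the channel
                         update_polariser(cv, pol_config(
                           production = "BOTTOM", degradation = "TOPMID",
                           fixed = list(CHANNELSINK = 0.2)))
                       })),
    description = "orthogonal conflict with a locked proximodistal polarity channel"))

  ## combined conflicts
  add(model_entry("fig6s1_directional_areal", square_recipe(),
    pol_convergent,
    one_phase(growth_spec(
      "0.01 + 0.06*sjun - 0.12*sjun*srim",
      "0.01 + 0.06*srim - 0.12*sjun*srim", "0.01")),
    description = "directional plus areal conflict in the orthogonal domains"))
  add(model_entry("fig6s1_surface_directional", square_recipe(),
    pol_convergent,
    # the printed block labels the last two equations Kparb twice; the
    # second is read as Kperb (consistent with every other surface model)
    one_phase(growth_spec(knor = "0.044",
      kpar_a = "0.055 + 0.05*sjun + 0.05*srim - 0.2*sjun*srim",
      kper_a = "0.055 - 0.05*sjun - 0.05*srim + 0.2*sjun*srim",
      kpar_b = "0.05 + 0.05*sjun + 0.05*srim - 0.2*sjun*srim",
      kper_b = "0.05 - 0.05*sjun - 0.05*srim + 0.2*sjun*srim")),
    description = "surface plus orthogonal directional conflict"))
  add(model_entry("fig6s1_surface_areal",
    square_recipe(sagitta = 0, noise = 0.001 * .square_side),
    pol_none,
    one_phase(growth_spec(knor = "0.044",
      kpar_a = "0.03 + 0.025*icentre", kper_a = "0.03 + 0.025*icentre",
      kpar_b = "0.025 + 0.025*icentre", kper_b = "0.025 + 0.025*icentre")),
    description = "surface plus areal conflict from a flat noisy start"))

  ## conflicts through growth plus contraction (size preserving)
  add(model_entry("fig7_surface", square_recipe(),
    pol_none,
    one_phase(growth_spec(knor = "0",
      kpar_a = "0.005", kper_a = "0.005",
      kpar_b = "-0.005", kper_b = "-0.005")),
    t_end = 10,
    description = "surface conflict without overall growth"))
  add(model_entry("fig7_areal",
    square_recipe(size_preserving_edge = TRUE),
    pol_none,
    one_phase(growth_spec("0.019 - 0.032*iedge", "0.019 - 0.032*iedge", "0")),
    t_end = 10,
    description = "areal conflict without overall growth"))
  add(model_entry("fig7_directional", square_recipe(),
    pol_convergent,
    one_phase(growth_spec("0.01", "-0.01", "0")),
    t_end = 10,
    description = "convergent directional conflict without overall growth"))
  add(model_entry("fig7_orthogonal_parallel", square_recipe(),
    pol_parallel,
    one_phase(growth_spec(
      "0.05*sjun - 0.05*srim",
      "0.05*srim - 0.05*sjun", "0")),
    t_end = 10,
    description = "orthogonal directional conflict without overall growth (Karea = 0)"))

  ## div domes (phase I 10-12 DAI, phase II 12-24 DAI)
  div_I <- growth_spec(knor = "0.0044",
    kpar_b = "0.02 * inh(5, srad) * pro(0.8, ilis)",
    kpar_a = "0.02 * inh(5, srad) * pro(0.8, ilis) * inh(0.5, (srim > 0.4) * inh(100, srad))",
    kper_b = "0.005 * inh(3, srad)",
    kper_a = "0.005 * inh(3, srad)")
  # phase II as printed; the printed `inh(0.8, ilis)` in Kparb is read as
  # pro(0.8, ilis): the companion wedge model states the LIS boost of Kpar
  # is "the same as in the div model for phase II"
  div_II_kparb <- paste0("0.012 * inh(5, srad * pro(3, ilip)) * pro(0.8, ilis)",
                         " * inh(2, srim) * pro(0.8, slat * ibrim)")
  div_II_kperb <- "0.012 * inh(3, srad) * pro(2.5, srim) * inh(3, slat) * inh(3, smed)"
  div_II <- growth_spec(knor = "0.0044",
    kpar_b = div_II_kparb,
    kpar_a = paste0(div_II_kparb, " * inh(0.5, (srim > 0.4) * inh(100, srad))"),
    kper_b = div_II_kperb,
    kper_a = div_II_kperb)
  # the orthogonal-conflict interactions introduced at phase II
  div_II_orth_kparb <- "0.012 * inh(5, srad * pro(3, ilip)) * pro(0.8, ilis)"
  div_II_orth_kperb <- "0.012 * inh(3, srad) * inh(3, smed)"
  div_II_orth <- growth_spec(knor = "0.0044",
    kpar_b = div_II_orth_kparb,
    kpar_a = paste0(div_II_orth_kparb, " * inh(0.5, (srim > 0.4) * inh(100, srad))"),
    kper_b = div_II_orth_kperb,
    kper_a = div_II_orth_kperb)
  add(model_entry("fig9_div_domes", strip_recipe(),
    pol_proxdist,
    list(list(t0 = 240, t1 = 288, spec = div_I),
         list(t0 = 288, t1 = Inf, spec = div_II)),
    events = list(list(id = "clones", time = 300,
                       action = function(cv) induce_clones(cv, radius = 5, spacing = 60))),
    t_end = 576,
    description = "div mutant wedge: dome formation at the junction foci",
    orthogonal_ablation = list(phase2 = div_II_orth)))

  ## wild-type wedge
  wt_I_kparb <- paste0("0.02 * inh(5, srad) * pro(0.8, ilis) * pro(1.5, idiv*ilif)",
                       " * pro(0.8, idiv*iplt * pro(0.3, iplx) * inh(5, isource))")
  wt_I <- growth_spec(knor = "0.0044",
    kpar_b = wt_I_kparb,
    kpar_a = paste0(wt_I_kparb, " * inh(3, srim * inh(10, smed) * inh(100, srad))"),
    kper_b = "0.005 * inh(3, srad)",
    kper_a = "0.005 * inh(3, srad)")
  wt_II_kparb <- paste0(
    "0.012 * inh(5, srad * pro(3, ilip)) * pro(0.8, ilis)",
    " * pro(0.5, idiv*ilif)",
    " * pro(0.8, idiv*iplt * pro(0.3, iplx) * inh(5, isource))",
    " * inh(2, srim)",
    " * inh(0.2, (idiv > 0.95) * smed * ibrim)",
    " * inh(50, srad * ilis * pro(100, ihinge))",
    " * pro(0.8, slat * ibrim)")
  wt_II_kperb <- paste0(
    "0.012 * inh(3, srad)",
    " * pro(2.5, srim * pro(0.5, idiv))",
    " * inh(3, slat * inh(1, (idiv > 0.83)) * ilif)",
    " * inh(0.5, (idiv > 0.95) * pro(1, 4*srim + 1.5*ilis) * inh(100, iplx))",
    " * inh(3, smed * inh(10, iplt*idiv))",
    " * inh(2, (1 - idiv) * ilis * pro(2, isink) * inh(100, ihinge))",
    " * pro(4.8, idiv * ilip * ssec * inh(8, srim))")
  wt_II <- growth_spec(knor = "0.0044",
    kpar_b = wt_II_kparb,
    kpar_a = paste0(wt_II_kparb,
                    " * inh(3, idiv * srim * inh(10, smed) * inh(100, srad))"),
    kper_b = wt_II_kperb,
    kper_a = paste0(wt_II_kperb, " * inh(0.5, (idiv > 0.95) * ilip)"))
  # orthogonal ablation: phase-II directional-conflict interactions removed
  wt_II_orth_kparb <- paste0(
    "0.012 * inh(5, srad * pro(3, ilip)) * pro(0.8, ilis)",
    " * pro(0.5, idiv*ilif)",
    " * pro(0.8, idiv*iplt * pro(0.3, iplx) * inh(5, isource))",
    " * inh(0.2, (idiv > 0.95) * smed * ibrim)",
    " * inh(50, srad * ilis * pro(100, ihinge))")
  wt_II_orth_kperb <- paste0(
    "0.012 * inh(3, srad)",
    " * inh(0.5, (idiv > 0.95) * pro(1, 1.5*ilis) * inh(100, iplx))",
    " * inh(3, smed * inh(10, iplt*idiv))",
    " * inh(2, (1 - idiv) * ilis * pro(2, isink) * inh(100, ihinge))")
  wt_II_orth <- growth_spec(knor = "0.0044",
    kpar_b = wt_II_orth_kparb,
    kpar_a = paste0(wt_II_orth_kparb,
                    " * inh(3, idiv * srim * inh(10, smed) * inh(100, srad))"),
    kper_b = wt_II_orth_kperb,
    kper_a = paste0(wt_II_orth_kperb, " * inh(0.5, (idiv > 0.95) * ilip)"))
  add(model_entry("fig10_wt_wedge", strip_recipe(),
    pol_proxdist,
    list(list(t0 = 240, t1 = 288, spec = wt_I),
         list(t0 = 288, t1 = Inf, spec = wt_II)),
    events = list(
      list(id = "sinus_deflection", time = 288, action = function(cv) {
        # polarity deflects toward the new sinus sink on the B surface only
        cv <- freeze_polarity(cv, "A")
        update_polariser(cv, pol_config(production = "isource",
                                        degradation = "isinus",
                                        fixed = list(isink = 0.01)))
      }),
      list(id = "clones", time = 300,
           action = function(cv) induce_clones(cv, radius = 5, spacing = 60))),
    t_end = 576,
    description = "wild-type wedge with sinus polarity deflection at 12 DAI",
    orthogonal_ablation = list(phase2 = wt_II_orth)))

  cat_
}

.catalogue_cache <- new.env(parent = emptyenv())

catalogue <- function() {
  if (is.null(.catalogue_cache$models)) .catalogue_cache$models <- build_catalogue()
  .catalogue_cache$models
}

#' List the model catalogue
#' @return character vector of model names.
#' @export
list_models <- function() names(catalogue())

#' Retrieve a model configuration
#'
#' @param name catalogue name (see [list_models()]).
#' @return a `tissue_model` configuration.
#' @export
get_model <- function(name) {
  cat_ <- catalogue()
  if (!name %in% names(cat_)) {
    abort("unknown model `%s`; catalogue: %s", name,
          paste(names(cat_), collapse = ", "))
  }
  cat_[[name]]
}

#' Remove one conflict from a model (virtual mutant)
#'
#' @param model a `tissue_model` (or catalogue name).
#' @param conflict one of `"surface"` (A/B expressions equalised),
#'   `"areal"` (rates normalised per surface so `Kpar + Kper` is the
#'   constant 0.025 everywhere), `"directional"` (no polariser production:
#'   no polarity field, growth isotropic at the same areal rate) or
#'   `"orthogonal"` (the phase-II orthogonal-conflict interactions removed;
#'   only defined for models that declare them).
#' @param normalise_to constant for the areal normalisation.
#' @return the modified model configuration.
#' @export
ablate <- function(model, conflict = c("surface", "areal", "directional",
                                       "orthogonal"),
                   normalise_to = 0.025) {
  if (is.character(model)) model <- get_model(model)
  conflict <- match.arg(conflict)
  model$name <- paste0(model$name, "_no_", conflict)
  if (conflict == "surface") {
    model$phases <- lapply(model$phases, function(p) {
      p$spec$kpar_a <- p$spec$kpar_b
      p$spec$kper_a <- p$spec$kper_b
      p
    })
  } else if (conflict == "areal") {
    model$phases <- lapply(model$phases, function(p) {
      p$spec$normalise <- normalise_to
      p
    })
  } else if (conflict == "directional") {
    model$polariser <- NULL
    model$phases <- lapply(model$phases, function(p) {
      p$spec$isotropise <- TRUE
      p
    })
    # polarity-deflection events are meaningless without a polariser
    model$events <- Filter(function(ev) !identical(ev$id, "sinus_deflection"),
                           model$events)
  } else if (conflict == "orthogonal") {
    if (is.null(model$orthogonal_ablation)) {
      abort("model `%s` does not define an orthogonal-conflict ablation", model$name)
    }
    n <- length(model$phases)
    model$phases[[n]]$spec <- model$orthogonal_ablation$phase2
  }
  model
}

#' Build the initial canvas of a model
#'
#' @param model a `tissue_model` or name.
#' @param resolution target edge length (micrometres); `NULL` for the
#'   model default.
#' @param seed integer seed (height noise etc.).
#' @return a canvas with factors, polariser and polarity installed.
#' @export
model_canvas <- function(model, resolution = NULL, seed = 1) {
  if (is.character(model)) model <- get_model(model)
  cv <- if (is.null(resolution)) model$canvas_fn(seed = seed)
        else model$canvas_fn(resolution = resolution, seed = seed)
  if (!is.null(model$polariser)) cv <- update_polariser(cv, model$polariser)
  cv
}

#' Run a catalogue model
#'
#' @param name model name or `tissue_model`.
#' @param resolution target edge length (micrometres); `NULL` = default.
#' @param seed integer seed.
#' @param t_end end time (hours); `NULL` = the model default.
#' @param dt step (hours).
#' @param snapshot_every record a snapshot every this many hours (`Inf` for
#'   start/end only).
#' @param ... passed to [advance_canvas()] (solver controls).
#' @return list with the final `canvas`, the per-step `report` history, the
#'   `snapshots` list, clone statistics (`clones`) when clones exist, and
#'   the run record.
#' @export
run_model <- function(name, resolution = NULL, seed = 1, t_end = NULL,
                      dt = 1, snapshot_every = Inf, ...) {
  model <- if (is.character(name)) get_model(name) else name
  cv <- model_canvas(model, resolution = resolution, seed = seed)
  t_end <- t_end %||% model$t_end
  snapshots <- list()
  reports <- list()
  next_snap <- cv$time
  while (cv$time < t_end - 1e-9) {
    if (cv$time >= next_snap - 1e-9) {
      snapshots[[length(snapshots) + 1L]] <- list(time = cv$time,
                                                  vertices = cv$vertices,
                                                  triangles = cv$triangles)
      next_snap <- next_snap + snapshot_every
    }
    cv <- step_canvas(cv, model, dt = min(dt, t_end - cv$time), ...)
    reports[[length(reports) + 1L]] <- cbind(time = cv$time, conflict_report(cv))
  }
  snapshots[[length(snapshots) + 1L]] <- list(time = cv$time,
                                              vertices = cv$vertices,
                                              triangles = cv$triangles)
  clones <- if (!is.null(attr(cv, "clones"))) all_clone_stats(cv) else NULL
  list(canvas = cv, report = reports[[length(reports)]],
       report_history = reports, snapshots = snapshots, clones = clones,
       record = list(model = model$name, seed = seed, dt = dt,
                     t_end = t_end, resolution = resolution))
}
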