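#' Read a pipeline configuration
#'
#' Loads a YAML pipeline configuration (schema version 1): a global `seed`,
#' an ordered `stages` list, and per-stage parameter blocks (`phantom`,
#' `ensemble`, `align`, `classify`, `modes`, `curvature`). Unknown stages
#' are rejected up front. See [run_pipeline()] for the stage semantics.
#'
#' @param path Path to a YAML file, or a list already in config shape.
#' @return A validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(path) {
  if (is.character(path) && !file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    version = 1,
    seed = 1,
    stages = c("simulate", "align", "average", "fsc", "classify", "modes",
               "curvature"),
    phantom = list(box = 64, voxel_size = 5.4, snr = 1, membrane_R = 50),
    ensemble = list(n_particles = 100, occupancies = 1, tilt_spread = 10,
                    shift_sd = 6),
    align = list(cone_range = 16, cone_step = 8, inplane_step = 8,
                 shift_limit = 20, band_limit = 36, symmetry = TRUE,
                 iterations = 1),
    classify = list(K = 4, band_limit = 22, min_fraction = 0.01,
                    exclude = list()),
    modes = list(n_modes = 5),
    curvature = list(R_min = 20, R_max = 200, R_step = 10))
  cfg <- utils::modifyList(defaults, cfg)
  known <- c("simulate", "align", "average", "fsc", "classify", "modes",
             "curvature")
  bad <- setdiff(cfg$stages, known)
  if (length(bad))
    stop("unknown pipeline stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(cfg, class = c("pipeline_config", "list"))
}

write_provenance <- function(dir, stage, cfg, seed, extra = list()) {
  p <- c(list(stage = stage, seed = seed,
              config = unclass(cfg)[setdiff(names(cfg), "stages")],
              package_version = as.character(utils::packageVersion("tomosta"))),
         extra)
  jsonlite::write_json(p, file.path(dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the full pipeline
#'
#' Executes the configured stages in order -- simulate, align, average,
#' fsc (half-set refinement), classify, modes (eigenvolume PCA) and
#' curvature -- writing every product (MRC maps, TSV tables, JSON summaries)
#' into `out_dir` together with a per-stage provenance file recording the
#' stage seed and the configuration applied. All randomness derives from
#' the single global seed through named per-stage substreams, so a rerun
#' with the same configuration and seed reproduces the particle tables
#' bit-identically. A stage failure halts the run with a stage-scoped
#' error; products of earlier stages are kept.
#'
#' @param config A [pipeline_config()], a path to a YAML file, or a list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage products.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config
  else pipeline_config(config)
  if (is.character(config) && !file.exists(config))
    stop("config file not found: ", config, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list()
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = file.path(out_dir, "pipeline.log"),
        append = TRUE)
    message(msg)
  }
  for (stage in cfg$stages) {
    seed <- stage_seed(cfg$seed, stage)
    log_line("[%s] starting (seed %d)", stage, seed)
    res <- tryCatch(
      run_stage(stage, cfg, state, seed, out_dir, log_line),
      error = function(e)
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE))
    state <- res
    write_provenance(out_dir, stage, cfg, seed)
    log_line("[%s] done", stage)
  }
  invisible(state)
}

run_stage <- function(stage, cfg, state, seed, out_dir, log_line) {
  switch(stage,
    simulate = {
      ph <- do.call(phantom_spec, cfg$phantom)
      es <- do.call(ensemble_spec,
                    c(cfg$ensemble, list(seed = seed)))
      sim <- simulate_ensemble(es, ph, dir = file.path(out_dir, "particles"))
      state$sim <- sim
      state$pspec <- ph
      state$espec <- es
      state$reference <- make_phantom(ph)
      write_mrc(state$reference, file.path(out_dir, "initial_reference.mrc"))
      log_line("[simulate] %d particles, box %d, snr %g",
               es$n_particles, ph$box, ph$snr)
      state
    },
    align = {
      ac <- do.call(align_config, c(cfg$align, list(seed = seed)))
      state$align_cfg <- ac
      state$sim$records <- align_particles(state$sim$particles,
                                           state$sim$records,
                                           state$reference,
                                           state$sim$wedge, ac)
      log_line("[align] band limit %s A, C4 %s, mean cc %.3f",
               format(ac$band_limit), ac$symmetry,
               mean(state$sim$records$cc))
      write_particle_table(state$sim$records,
                           file.path(out_dir, "aligned_particles.tsv"))
      state
    },
    average = {
      ac <- state$align_cfg %||% do.call(align_config, cfg$align)
      state$average <- weighted_average(state$sim$particles,
                                        state$sim$records,
                                        state$sim$wedge, ac,
                                        state$pspec$tilt_scheme)
      write_mrc(state$average, file.path(out_dir, "average.mrc"))
      state
    },
    fsc = {
      ac <- state$align_cfg %||% do.call(align_config, cfg$align)
      ac$seed <- seed
      ref <- state$average %||% state$reference
      state$refine <- halfset_refine(state$sim$particles,
                                     state$sim$records, ref,
                                     state$sim$wedge, ac,
                                     state$pspec$tilt_scheme)
      state$sim$records <- state$refine$records
      write_mrc(state$refine$map, file.path(out_dir, "refined_map.mrc"))
      if (state$refine$branch == "halfset") {
        write_mrc(state$refine$map_A, file.path(out_dir, "half_map_A.mrc"))
        write_mrc(state$refine$map_B, file.path(out_dir, "half_map_B.mrc"))
        utils::write.table(as.data.frame(state$refine$fsc),
                           file.path(out_dir, "fsc.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
      log_line("[fsc] %s branch, resolution %.1f A",
               state$refine$branch, state$refine$resolution)
      state
    },
    classify = {
      cc <- classify_config(band_limit = cfg$classify$band_limit)
      res <- multireference_classify(state$sim$particles,
                                     state$sim$records, cfg$classify$K,
                                     state$sim$wedge, cc, seed = seed)
      res <- prune_classes(res, cfg$classify$min_fraction,
                           unlist(cfg$classify$exclude))
      state$classification <- res
      for (k in res$retained)
        write_mrc(res$class_averages[[k]],
                  file.path(out_dir, sprintf("class_%02d.mrc", k)))
      utils::write.table(occupancy_table(res),
                         file.path(out_dir, "occupancies.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      log_line("[classify] K=%d occupancies: %s", cfg$classify$K,
               paste(sprintf("%.0f%%", 100 * res$occupancies),
                     collapse = " "))
      state
    },
    modes = {
      res <- state$classification
      vols <- res$class_averages[res$retained]
      al <- align_class_averages(vols)
      dec <- eigenvolume_decompose(al$aligned)
      state$modes <- dec
      n_modes <- min(cfg$modes$n_modes, length(dec$variances))
      for (m in seq_len(n_modes)) {
        write_mrc(dec$eigenvolumes[[m]],
                  file.path(out_dir, sprintf("mode_%d_eigenvolume.mrc", m)))
        if (dec$n_classes >= 4) {
          hm <- mode_halfmaps(dec, m)
          write_mrc(hm$low, file.path(out_dir,
                                      sprintf("mode_%d_low.mrc", m)))
          write_mrc(hm$high, file.path(out_dir,
                                       sprintf("mode_%d_high.mrc", m)))
        }
      }
      if (length(dec$informativity))
        utils::write.table(
          data.frame(mode = seq_along(dec$informativity),
                     variance = dec$variances,
                     informativity = dec$informativity),
          file.path(out_dir, "informativity.tsv"), sep = "\t",
          quote = FALSE, row.names = FALSE)
      log_line("[modes] %d modes, informativity %s",
               length(dec$informativity),
               paste(sprintf("%.0f%%", 100 * dec$informativity),
                     collapse = " "))
      state
    },
    curvature = {
      map <- state$refine$map %||% state$average %||% state$reference
      fit <- fit_membrane_radius(
        map, seq(cfg$curvature$R_min, cfg$curvature$R_max,
                 by = cfg$curvature$R_step),
        membrane_z = state$pspec$membrane_z)
      state$curvature <- fit
      utils::write.table(fit$profile,
                         file.path(out_dir, "curvature_profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(R_nm = fit$R, curvature_per_nm = fit$curvature,
             score = fit$score, flat_score = fit$flat_score),
        file.path(out_dir, "curvature.json"), auto_unbox = TRUE,
        digits = NA)
      log_line("[curvature] R = %.1f nm (curvature %.4f 1/nm)",
               fit$R, fit$curvature)
      state
    },
    stop("unknown stage: ", stage, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
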