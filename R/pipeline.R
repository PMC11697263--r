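# End-to-end orchestration: [simulate|load] -> demux -> phasor (calibrate,
# smooth) -> unmix -> subtract (+ optional deconvolution) -> compose ->
# metrics.  All randomness flows from the single config seed, so a config
# run twice produces bit-identical bundles.  3-D z-stacks are processed as
# independent 2-D planes with shared gates by running the pipeline per
# plane with the same gate configuration.

#' Assemble / normalise a pipeline configuration
#'
#' Accepts a YAML or JSON file path, or an R list, and fills defaults.
#' Exactly one input source must be present: `input$stack` (path to a
#' stack written by [write_stack()]) or `input$simulation` (scene,
#' optics, dyes, timing, irf).
#'
#' @param config Path to a YAML/JSON file or a nested list.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config))
    stopf("config must be a list or a YAML/JSON path",
          class = "phasorFSTM_config_error")
  has_stack <- !is.null(config$input$stack)
  has_sim <- !is.null(config$input$simulation)
  if (has_stack == has_sim)
    stopf("config must provide exactly one input source: input$stack or input$simulation",
          class = "phasorFSTM_config_error")
  defaults <- list(
    seed = 1L,
    demux = list(boundary_bin = NULL, min_prominence = 0.05),
    phasor = list(harmonic = 1L, min_photons = 10,
                  smooth = list(kernel_px = 3L, passes = 1L),
                  calibration = list(tau_ref_ns = NULL, n_photons = 1e6),
                  gates = list(radius = 0.1)),
    fstm = list(delta = 2, deconvolve_iterations = 0L, colors = NULL),
    metrics = list(enabled = TRUE)
  )
  config <- utils::modifyList(defaults, config)
  if (!is.numeric(config$seed) || length(config$seed) != 1L)
    stopf("seed must be a single integer", class = "phasorFSTM_config_error")
  structure(config, class = "pipeline_config")
}

dyes_from_config <- function(lst) {
  check_dyes(lapply(seq_len(if (is.data.frame(lst)) nrow(lst) else length(lst)),
                    function(i) {
    d <- if (is.data.frame(lst)) as.list(lst[i, ]) else lst[[i]]
    dye_spec(d$name, d$lifetime_ns,
             if (is.null(d$brightness)) 1 else d$brightness)
  }))
}

scene_from_config <- function(sim) {
  structs <- lapply(sim$structures, function(s) {
    switch(s$type,
           bead = scene_bead(unlist(s$center_nm), s$diameter_nm, s$dye,
                             s$amplitude),
           blob = scene_blob(unlist(s$center_nm), s$sigma_nm, s$dye,
                             s$amplitude),
           filament = scene_filament(do.call(rbind, lapply(s$points_nm,
                                                           unlist)),
                                     s$width_nm, s$dye, s$amplitude),
           stopf("unknown structure type '%s'", s$type,
                 class = "phasorFSTM_config_error"))
  })
  scene(unlist(sim$extent_nm), structs)
}

run_stage <- function(name, expr, log) {
  log(sprintf("stage %s: start", name))
  tryCatch(expr, error = function(e) {
    log(sprintf("stage %s: FAILED (%s)", name, conditionMessage(e)))
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e),
          class = "phasorFSTM_pipeline_error")
  })
}

#' Run the complete phasor-FSTM pipeline
#'
#' @param config A [pipeline_config()] (or something coercible to one).
#' @param output_dir Directory for the result bundle; created if missing.
#'   `NULL` skips writing and returns the in-memory bundle only.
#' @return Invisibly, the result bundle: stack, decays, phasor fields,
#'   calibration records, label maps, per-dye component and
#'   super-resolution images, RGB overlay, metrics, and a run manifest.
#' @export
run_pipeline <- function(config, output_dir = config$output_dir %||% NULL) {
  config <- pipeline_config(unclass(config))
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message("[phasorFSTM] ", msg)
  }
  seed <- as.integer(config$seed)
  bundle <- list(config = config)

  # ---- input ----
  truth <- NULL
  optics <- NULL
  dyes <- NULL
  if (!is.null(config$input$simulation)) {
    sim_cfg <- config$input$simulation
    sim_out <- run_stage("simulate", {
      op <- do.call(optics_config, sim_cfg$optics %||% list())
      timing <- do.call(timing_config, sim_cfg$timing %||% list())
      irf <- do.call(irf_model, sim_cfg$irf %||% list())
      dy <- dyes_from_config(sim_cfg$dyes)
      sc <- scene_from_config(sim_cfg)
      bp <- unlist(sim_cfg$beam_power %||% c(gaussian = 1, donut = 1))
      out <- simulate_acquisition(sc, op, dy, timing, irf,
                                  seed = seed, beam_power = bp)
      list(stack = out$stack, truth = out$truth, optics = op, dyes = dy)
    }, log)
    stack <- sim_out$stack
    truth <- sim_out$truth
    optics <- sim_out$optics
    dyes <- sim_out$dyes
  } else {
    stack <- run_stage("load", read_stack(config$input$stack), log)
    if (!is.null(config$dyes)) dyes <- dyes_from_config(config$dyes)
  }
  if (is.null(dyes))
    stopf("no dye specification available (config$dyes required for loaded stacks)",
          class = "phasorFSTM_config_error")
  timing <- stack$timing
  bundle$stack <- stack
  bundle$truth <- truth

  # ---- demux ----
  boundary <- run_stage("demux", {
    b <- config$demux$boundary_bin
    if (is.null(b)) {
      b <- tryCatch(detect_boundary(stack, config$demux$min_prominence),
                    error = function(e) {
                      log(sprintf("boundary detection failed (%s); falling back to timing donut_pulse_bin",
                                  conditionMessage(e)))
                      timing$donut_pulse_bin
                    })
    }
    as.integer(b)
  }, log)
  decays <- run_stage("split", split_stack(stack, boundary), log)
  bundle$boundary_bin <- boundary
  bundle$decays <- decays

  # ---- phasor ----
  irf_cal <- if (!is.null(config$input$simulation))
    do.call(irf_model, config$input$simulation$irf %||% list())
  else irf_model()
  phset <- run_stage("phasor", {
    fields <- lapply(decays, phasor_transform,
                     harmonic = config$phasor$harmonic,
                     min_photons = config$phasor$min_photons)
    records <- list()
    tau_ref <- config$phasor$calibration$tau_ref_ns
    if (is.null(tau_ref))
      tau_ref <- max(vapply(dyes, `[[`, 0, "lifetime_ns"))
    for (nm in names(fields)) {
      ref_full <- simulate_reference_decay(
        tau_ref, timing, irf_cal, nm,
        n_photons = as.numeric(config$phasor$calibration$n_photons),
        seed = substream_seed(seed, 99L, match(nm, c("gaussian", "donut"))))
      win <- if (nm == "gaussian") seq_len(boundary)
             else (boundary + 1L):timing$n_bins
      cal <- calibrate_phasor(fields[[nm]], ref_full[win], tau_ref)
      fields[[nm]] <- cal$field
      records[[nm]] <- cal$record
    }
    sm <- config$phasor$smooth
    fields <- lapply(fields, smooth_phasor, kernel_px = sm$kernel_px,
                     passes = sm$passes)
    list(fields = fields, records = records, tau_ref = tau_ref)
  }, log)
  bundle$phasor <- phset

  # ---- unmix ----
  unmix <- run_stage("unmix", {
    gates <- lapply(phset$fields, function(f)
      suppressWarnings(gates_from_lifetimes(dyes, f$omega,
                                            config$phasor$gates$radius)))
    labels <- lapply(names(phset$fields), function(nm)
      assign_pixels(phset$fields[[nm]], gates[[nm]]))
    names(labels) <- names(phset$fields)
    comp <- extract_components(labels, decays$gaussian, decays$donut)
    list(gates = gates, labels = labels, components = comp)
  }, log)
  bundle$unmix <- unmix

  # ---- subtract / deconvolve ----
  sr <- run_stage("subtract", {
    delta <- config$fstm$delta
    iters <- config$fstm$deconvolve_iterations
    eff_psf <- NULL
    if (iters > 0L) {
      if (is.null(optics)) {
        log("deconvolution requested but no optics available; skipping")
        iters <- 0L
      } else eff_psf <- effective_fstm_psf(optics, delta)
    }
    out <- lapply(names(unmix$components$images), function(nm) {
      im <- unmix$components$images[[nm]]
      s <- subtract_weighted(im$gaussian, im$donut, delta)
      if (iters > 0L) s <- deconvolve_rl(s, eff_psf, iters)
      s
    })
    names(out) <- names(unmix$components$images)
    out
  }, log)
  bundle$sr <- sr
  bundle$delta <- config$fstm$delta

  # ---- compose ----
  bundle$overlay <- run_stage("compose",
                              compose_multicolor(sr, config$fstm$colors), log)

  # ---- metrics ----
  bundle$metrics <- run_stage("metrics", {
    bk <- unmix$components$bookkeeping
    m <- list(
      total_photons = bk$total,
      gaussian_percent = 100 * bk$gaussian_total / bk$total,
      donut_percent = 100 * bk$donut_total / bk$total,
      assigned = bk$assigned,
      unassigned = bk$unassigned,
      boundary_bin = boundary
    )
    fw <- lapply(names(sr), function(nm) {
      img <- sr[[nm]]
      spots <- find_spots(img$values, min_rel = 0.3, max_spots = 5L)
      if (!nrow(spots)) return(NULL)
      px <- img$pixel_size_nm
      lines <- list()
      for (k in seq_len(nrow(spots))) {
        cx <- (spots[k, 2L] - 0.5) * px; cy <- (spots[k, 1L] - 0.5) * px
        lines <- c(lines,
                   list(rbind(c(cx - 10 * px, cy), c(cx + 10 * px, cy)),
                        rbind(c(cx, cy - 10 * px), c(cx, cy + 10 * px))))
      }
      tryCatch(mean_fwhm(img, lines)[c("mean_nm", "se_nm", "n")],
               error = function(e) NULL)
    })
    names(fw) <- names(sr)
    m$fwhm <- fw[!vapply(fw, is.null, TRUE)]
    if (!is.null(truth)) {
      m$assignment <- tryCatch(
        assignment_scores(unmix$labels$gaussian, truth$labels),
        error = function(e) NULL)
    }
    m
  }, log)

  # ---- manifest / outputs ----
  manifest <- run_stage("manifest", {
    tmp <- tempfile(fileext = ".json")
    jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                         force = TRUE, digits = NA)
    h <- unname(tools::md5sum(tmp))
    unlink(tmp)
    list(config_hash = h, seed = seed,
         package_version = as.character(utils::packageVersion("phasorFSTM")),
         r_version = paste(R.version$major, R.version$minor, sep = "."))
  }, log)
  bundle$manifest <- manifest
  bundle$log <- log_lines

  if (!is.null(output_dir)) {
    run_stage("write", {
      dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
      p <- function(...) file.path(output_dir, ...)
      write_stack(stack, p("stack.tif"))
      write_decay_stack(decays$gaussian, p("decay_gaussian.tif"))
      write_decay_stack(decays$donut, p("decay_donut.tif"))
      for (nm in names(phset$fields)) {
        f <- phset$fields[[nm]]
        gg <- f$g; gg[is.na(gg)] <- 0
        ss <- f$s; ss[is.na(ss)] <- 0
        write_intensity_image(intensity_image(pmax(gg, 0), stack$pixel_size_nm),
                              p(sprintf("phasor_g_%s.tif", nm)))
        write_intensity_image(intensity_image(pmax(ss, 0), stack$pixel_size_nm),
                              p(sprintf("phasor_s_%s.tif", nm)))
        write_intensity_image(intensity_image(f$total, stack$pixel_size_nm),
                              p(sprintf("total_%s.tif", nm)))
      }
      for (nm in names(sr)) {
        write_intensity_image(unmix$components$images[[nm]]$gaussian,
                              p(sprintf("Ig_%s.tif", nm)))
        write_intensity_image(unmix$components$images[[nm]]$donut,
                              p(sprintf("Id_%s.tif", nm)))
        write_intensity_image(sr[[nm]], p(sprintf("Is_%s.tif", nm)))
      }
      png::writePNG(bundle$overlay, p("overlay.png"))
      jsonlite::write_json(
        list(metrics = serialize_metrics(bundle$metrics),
             manifest = manifest),
        p("metrics.json"), auto_unbox = TRUE, force = TRUE, digits = NA,
        pretty = TRUE)
      writeLines(log_lines, p("run.log"))
    }, log)
  }
  invisible(bundle)
}

serialize_metrics <- function(m) {
  m$assigned <- as.data.frame(as.table(m$assigned))
  if (!is.null(m$assignment)) {
    m$assignment <- list(per_class = m$assignment$per_class,
                         macro_f1 = m$assignment$macro_f1)
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
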