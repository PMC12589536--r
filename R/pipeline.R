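#' Default pipeline configuration
#'
#' A `run_config` is a plain list; this helper documents the recognized
#' keys and fills in defaults. Configurations can equally be read from a
#' YAML file (see [run_pipeline()]); keys given here override nothing —
#' explicit entries in the supplied config always win.
#'
#' @param out_dir output directory.
#' @param seed single integer seeding every stochastic stage.
#' @return A named list of configuration defaults.
#' @export
default_run_config <- function(out_dir = "comsli_out", seed = 1L) {
  list(
    out_dir = out_dir,
    seed = seed,
    # input: either a phantom spec (list of phantom_spec() arguments)
    # or measured data (tiff paths + angles)
    phantom = list(),
    input = NULL,          # list(paths=, angles=, pixel_size_um=)
    diffuser = NULL,       # tiff path(s) for a measured diffuser stack
    calibrate = FALSE,
    blur_sigma_px = 100,
    params = list(),       # profile_params() arguments
    kernels = c(1L, 7L, 14L, 71L),
    downsample_factors = integer(0),
    mufod_kernel_px = 7L,
    overlay_kernel = 15L,
    dwi = list(kernel_px = 1L, scale = 10, tilt_deg = 20),
    log_level = "info"
  )
}

#' Run the full scattered-light analysis pipeline
#'
#' Orchestrates calibrate -> analyze -> maps/crossings -> muFOD -> dMRI
#' export from a single configuration, writing every artifact plus a JSON
#' manifest (inputs, parameters, file checksums, package version) to
#' `out_dir`. Reruns with the same configuration and seed are idempotent:
#' identical checksums. Stage failures abort with a stage-tagged message.
#'
#' @param config a named list (see [default_run_config()]) or the path of
#'   a YAML file holding one. When `config$phantom` is non-empty, the
#'   input stack and matching diffuser are generated synthetically with
#'   `config$seed`; otherwise `config$input` must point at measured TIFFs.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(default_run_config(), config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) {
    if (identical(config$log_level, "quiet")) return(invisible())
    message(sprintf("[comsli] %s", sprintf(...)))
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  artifacts <- character(0)
  outp <- function(f) file.path(config$out_dir, f)

  # ---- input stage -------------------------------------------------------
  use_phantom <- length(config$phantom) > 0 || is.null(config$input)
  diffuser <- NULL
  stack <- stage("input", {
    if (use_phantom) {
      spec <- do.call(phantom_spec,
                      utils::modifyList(config$phantom,
                                        list(seed = config$seed)))
      log_msg("generating phantom %d x %d, %d angles",
              spec$shape[1], spec$shape[2], length(spec$angles))
      ph <- generate_phantom(spec)
      if (isTRUE(config$calibrate)) diffuser <- generate_diffuser(spec)
      ph$stack
    } else {
      log_msg("reading %d input file(s)", length(config$input$paths))
      read_angular_stack(config$input$paths, config$input$angles,
                         config$input$pixel_size_um %||% 1)
    }
  })
  if (!use_phantom && isTRUE(config$calibrate)) {
    diffuser <- stage("input", {
      if (is.null(config$diffuser))
        stop("calibrate = TRUE but no diffuser stack configured")
      read_angular_stack(config$diffuser, config$input$angles,
                         config$input$pixel_size_um %||% 1)
    })
  }

  # ---- calibration -------------------------------------------------------
  if (isTRUE(config$calibrate)) {
    stack <- stage("calibrate", {
      if (is.null(diffuser))
        stop("calibrate = TRUE but no diffuser stack configured")
      log_msg("flat-field correction (blur sigma %g px)",
              config$blur_sigma_px)
      cal <- normalize_diffuser(diffuser, config$blur_sigma_px)
      corrected <- flat_field_correct(stack, cal)
      artifacts <- c(artifacts,
                      write_angular_stack(corrected, outp("corrected.tif")))
      corrected
    })
  }

  # ---- orientation analysis ----------------------------------------------
  params <- do.call(profile_params, config$params)
  field <- stage("analyze", {
    log_msg("per-pixel orientation analysis")
    f <- analyze_stack(stack, params)
    artifacts <- c(artifacts, write_orientation_field(f, outp("field")))
    f
  })

  # ---- maps --------------------------------------------------------------
  stage("maps", {
    artifacts <- c(artifacts,
                    write_rgb_png(render_fom(field), outp("fom.png")),
                    write_rgb_png(vector_overlay(field,
                                                 config$overlay_kernel),
                                  outp("vectors.png")))
  })

  # ---- crossings ---------------------------------------------------------
  stage("crossings", {
    tab <- crossing_table(field, config$kernels)
    utils::write.csv(tab, outp("crossings.csv"), row.names = FALSE)
    artifacts <- c(artifacts, outp("crossings.csv"))
    for (fct in config$downsample_factors) {
      ds <- apparent_crossing_map(stack, fct, params)
      dtab <- crossing_table(ds, 1L)
      utils::write.csv(dtab, outp(sprintf("apparent_crossings_f%d.csv", fct)),
                       row.names = FALSE)
      artifacts <- c(artifacts, outp(sprintf("apparent_crossings_f%d.csv",
                                              fct)))
    }
  })

  # ---- muFOD -------------------------------------------------------------
  mufod <- stage("mufod", {
    m <- compute_mufod(field)
    artifacts <- c(artifacts,
                    write_mufod_csv(m, outp("mufod_whole.csv")),
                    plot_mufod_png(m, outp("mufod_whole.png")))
    m
  })

  # ---- dMRI bridge -------------------------------------------------------
  stage("dwi", {
    gt <- build_gradient_table(tilt_deg = config$dwi$tilt_deg %||% 20)
    dwi <- synthesize_dwi(field,
                          kernel_px = config$dwi$kernel_px %||% 1L,
                          scale = config$dwi$scale %||% 10,
                          gradient_table = gt)
    artifacts <- c(artifacts, export_dwi(dwi, outp("dwi")))
  })

  # ---- manifest ----------------------------------------------------------
  artifacts <- unname(artifacts)
  manifest <- list(
    package = "comsli",
    version = as.character(utils::packageVersion("comsli")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    n_pixels_analyzed = sum(field$mask),
    mufod_total = mufod$n_total,
    artifacts = data.frame(
      path = basename(artifacts),
      md5 = unname(tools::md5sum(artifacts)),
      stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  log_msg("wrote %d artifacts to %s", length(artifacts), config$out_dir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
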