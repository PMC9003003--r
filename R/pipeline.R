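# End-to-end pipeline and command-line interface.
#
# run_pipeline() ties the modules together: register -> composite ->
# reslice -> enhance -> project/metrics, writing a manifest that fully
# declares the run's inputs, configuration and outputs.

#' Run the full ST-OCTA pipeline
#'
#' @param input an [oct_volume4d()], or a path to a multi-page TIFF
#'   readable by [read_volume()].
#' @param cfg a [pipeline_config()].
#' @param composite_method `"stdev"`, `"mean"` or `"single"`.
#' @param register registration mode for [register_volume()]
#'   (`"none"` to skip).
#' @param out_dir output directory; created if missing. When `NULL`,
#'   nothing is written and the results are only returned.
#' @param save_steps also keep the 7 per-step checkpoints.
#' @param layout optional layout list for [read_volume()].
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A list with `enhanced` ([enface_stack()]), `input_stack`,
#'   `steps` (when requested), `manifest`.
#' @export
run_pipeline <- function(input, cfg = pipeline_config(),
                         composite_method = c("stdev", "mean", "single"),
                         register = c("both", "across_t", "across_z", "none"),
                         out_dir = NULL, save_steps = FALSE, layout = NULL,
                         seed = NULL) {
  composite_method <- match.arg(composite_method)
  register <- match.arg(register)
  t0 <- Sys.time()
  input_path <- if (is.character(input)) input else NA_character_
  v <- if (is.character(input)) read_volume(input, layout) else input
  stopifnot(inherits(v, "oct_volume4d"))
  if (composite_method == "stdev" && dim(v$data)[3] < 2)
    stop("--composite stdev requires an input with t >= 2 frames")

  if (register != "none") v <- register_volume(v, mode = register)
  comp <- composite_frames(v, composite_method)
  st <- reslice_to_enface(comp)
  enhanced <- enhance_stack(st, cfg, save_steps = save_steps)
  steps <- NULL
  if (save_steps) {
    steps <- enhanced
    enhanced <- steps$rollingball
  }

  outputs <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    enhanced_path <- file.path(out_dir, "enhanced.tif")
    write_stack(enhanced, enhanced_path, format = "float32")
    outputs <- c(outputs, enhanced_path)
    if (save_steps) {
      for (nm in names(steps)) {
        p <- file.path(out_dir, sprintf("step_%s.tif", nm))
        write_stack(steps[[nm]], p, format = "float32")
        outputs <- c(outputs, p)
      }
    }
  }

  manifest <- list(
    input = input_path,
    extents = as.list(stats::setNames(dim(v$data), c("x", "y", "t", "z"))),
    config = unclass(cfg),
    composite_method = composite_method,
    register = register,
    seed = seed,
    package_version = as.character(utils::packageVersion("stocta")),
    outputs = outputs,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  list(enhanced = enhanced, input_stack = st, steps = steps,
       manifest = manifest)
}

#' Write a projection image as PNG
#'
#' @param image numeric matrix (grayscale, rescaled to `[0, 1]` by max) or
#'   `[x, z, 3]` RGB array in `[0, 1]`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_projection_png <- function(image, path) {
  if (is.matrix(image)) {
    mx <- max(image)
    img <- if (mx > 0) image / mx else image
    png::writePNG(t(img), path)
  } else {
    png::writePNG(aperm(image, c(2, 1, 3)), path)
  }
  invisible(path)
}

.cli_config <- function(path) {
  if (is.null(path)) return(pipeline_config())
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

.cli_opt <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (!length(i)) return(default)
  if (i[1] == length(args)) stop("missing value for ", flag)
  args[i[1] + 1]
}

#' Command-line entry point
#'
#' Subcommands: `phantom` (generate and write the default phantom),
#' `enhance` (run the pipeline on a TIFF), `run` (phantom or TIFF through
#' the full pipeline with metrics), `baseline` (speckle variance). Returns
#' an exit status: 0 ok, 1 user error, 2 internal error. The installed
#' `st-octa` script (under `inst/cli`) forwards `commandArgs` here.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
stocta_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) {
      cat("usage: st-octa <phantom|enhance|baseline|run> [options]\n")
      return(invisible(1L))
    }
    cmd <- args[1]
    rest <- args[-1]
    cfg <- .cli_config(.cli_opt(rest, "--config"))
    out_dir <- .cli_opt(rest, "--out", "st-octa-out")
    seed <- as.integer(.cli_opt(rest, "--seed", "1"))
    switch(cmd,
      phantom = {
        ph <- generate_phantom(default_retina_spec(seed = seed))
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_stack(ph$volume, file.path(out_dir, "phantom.tif"))
        write_tiff_pages(lapply(seq_len(dim(ph$vessel_mask$data)[3]),
                                function(j) t(ph$vessel_mask$data[, , j]) * 255),
                         file.path(out_dir, "vessel_mask.tif"), "uint8")
        cat("phantom written to", out_dir, "\n")
        0L
      },
      enhance = ,
      run = {
        input <- .cli_opt(rest, "--in")
        method <- .cli_opt(rest, "--composite", "stdev")
        if (is.null(input)) {
          ph <- generate_phantom(default_retina_spec(seed = seed))
          input <- ph$volume
        }
        res <- run_pipeline(input, cfg, composite_method = method,
                            register = .cli_opt(rest, "--register", "both"),
                            out_dir = out_dir, seed = seed)
        slab_um <- as.numeric(.cli_opt(rest, "--slab-um", "60"))
        slab_start <- as.integer(.cli_opt(rest, "--slab-start", "1"))
        projs <- consecutive_slabs(res$enhanced, slab_start, slab_um,
                                   method = .cli_opt(rest, "--proj", "max"))
        for (i in seq_along(projs)) {
          write_projection_png(projs[[i]],
                               file.path(out_dir, sprintf("slab_%02d.png", i)))
        }
        cat("pipeline outputs written to", out_dir, "\n")
        0L
      },
      baseline = {
        input <- .cli_opt(rest, "--in")
        if (is.null(input)) stop("baseline requires --in <volume.tif>")
        v <- read_volume(input)
        sv <- speckle_variance(v)
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_stack(sv, file.path(out_dir, "speckle_variance.tif"),
                    format = "float32")
        0L
      },
      {
        cat("unknown subcommand:", cmd, "\n")
        1L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}
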