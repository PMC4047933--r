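# Image and tabular I/O, confocal-stack projection, configuration.

#' Read a grayscale intensity image
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG as a numeric matrix of raw
#' intensity values (TIFF values are returned unscaled; PNG values, which
#' the reader delivers in `[0, 1]`, are rescaled to the original integer
#' range). Multi-channel images require `channel`.
#'
#' @param path file path (.tif/.tiff/.png).
#' @param channel channel index to extract from a multi-channel image.
#' @return numeric matrix with attribute `bits_per_sample`.
#' @export
read_intensity_image <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(x, "bits.per.sample")
    if (is.null(bits)) bits <- 16L
  } else if (ext == "png") {
    x <- png::readPNG(path)
    bits <- 8L
    x <- x * 255
  } else {
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE)
  }
  if (length(dim(x)) == 3) {
    if (is.null(channel))
      stop("multi-channel image; pass `channel` (CLI flag --channel) to select one",
           call. = FALSE)
    x <- x[, , channel]
  }
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  attr(x, "bits_per_sample") <- as.integer(bits)
  x
}

#' Write a grayscale intensity image
#'
#' Writes a numeric matrix as a 16-bit grayscale TIFF (values min-max scaled
#' to the full range unless already within `[0, 1]`).
#'
#' @param image numeric matrix.
#' @param path output path (.tif/.tiff).
#' @return `path`, invisibly.
#' @export
write_intensity_image <- function(image, path) {
  x <- image
  storage.mode(x) <- "double"
  rng <- range(x)
  if (rng[1] < 0 || rng[2] > 1)
    x <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
  tiff::writeTIFF(x, path, bits.per.sample = 16L)
  invisible(path)
}

#' Maximum-intensity projection of a confocal z-stack
#'
#' @param stack list of same-shaped numeric matrices (z-slices).
#' @return pixelwise maximum across slices.
#' @export
max_project <- function(stack) {
  if (length(stack) == 0) stop("empty stack", call. = FALSE)
  d <- dim(stack[[1]])
  out <- stack[[1]]
  for (s in stack[-1]) {
    if (!all(dim(s) == d)) stop("all slices must have the same shape", call. = FALSE)
    out <- pmax(out, s)
  }
  out
}

#' Default pipeline configuration
#'
#' Collects every tunable pipeline parameter into one list that serializes
#' losslessly to YAML (see [read_config()] / [write_config()]).
#'
#' @param ... named overrides of the defaults.
#' @return list of class `filatrace_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    bank = list(lengths_px = c(15, 25), width_sigmas_px = c(1.5, 2.5),
                n_rotations = 12L,
                curvatures_per_px = c(0, 0.01, -0.01, 0.02, -0.02)),
    min_object_px = 20L,
    max_turn_deg = 30,
    min_length_px = 3,
    bin_width = NULL,
    pixel_size_um = NULL,
    max_match_dist_px = 5,
    seed = 1L)
  over <- list(...)
  # cfg[nm] <- list(...) keeps explicit NULLs (a plain [[<- would delete)
  for (nm in names(over)) cfg[nm] <- list(over[[nm]])
  structure(cfg, class = "filatrace_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname pipeline_config
#' @param config a `filatrace_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_bank <- function(config) {
  do.call(template_bank, config$bank)
}

#' Write tracing outputs to a directory
#'
#' Writes the per-filament table (`filaments.csv`: id, length_px, length_um,
#' n_pixels, mean_orientation_rad), the length histogram
#' (`histogram.csv`), a summary JSON (`summary.json`: filament count,
#' weighted mean +/- SE), the configuration echo (`config.yaml`) and a run
#' log with the seed and package version.
#'
#' @param result a [trace_filaments()] result.
#' @param config the [pipeline_config()] used.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  paths <- result$paths
  px_um <- config$pixel_size_um
  fil <- data.frame(
    id = seq_along(paths),
    length_px = vapply(paths, function(p) p$length_px, numeric(1)),
    length_um = if (is.null(px_um)) rep(NA_real_, length(paths)) else
      vapply(paths, function(p) p$length_px * px_um, numeric(1)),
    n_pixels = vapply(paths, function(p) nrow(p$pixels), integer(1)),
    mean_orientation_rad = vapply(paths, function(p)
      path_orientation(p$pixels), numeric(1)))
  write.csv(fil, file.path(out_dir, "filaments.csv"), row.names = FALSE)

  d <- result$distribution
  hist_df <- if (length(d$counts) > 0)
    data.frame(bin_start = d$bin_edges[-length(d$bin_edges)],
               bin_end = d$bin_edges[-1], count = d$counts)
  else data.frame(bin_start = numeric(0), bin_end = numeric(0),
                  count = integer(0))
  write.csv(hist_df, file.path(out_dir, "histogram.csv"), row.names = FALSE)

  jsonlite::write_json(
    list(n_filaments = result$summary$n_filaments,
         weighted_mean = result$summary$weighted_mean,
         weighted_mean_se = result$summary$weighted_mean_se,
         unit = result$summary$unit),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  write_config(config, file.path(out_dir, "config.yaml"))
  writeLines(c(sprintf("filatrace %s",
                       as.character(utils::packageVersion("filatrace"))),
               sprintf("seed: %d", config$seed)),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}
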