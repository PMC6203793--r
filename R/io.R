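# File formats: TIFF images and stacks, spot-table CSV, run-config JSON.

format_error <- function(msg) {
  stop(errorCondition(msg, class = c("qdfish_format_error", "error")))
}

#' Read a grayscale TIFF image or stack
#'
#' @param path Path to an 8- or 16-bit grayscale TIFF, single- or multi-page.
#' @param axis Axis of a multi-page file, `"z"` or `"time"`.
#' @param z_step_um z spacing recorded on a returned stack (default 0.22).
#' @return An [image_frame()] for single-page files, an [image_stack()] for
#'   multi-page files.  Unreadable, RGB, or non-integer files raise a
#'   `qdfish_format_error` with a message.
#' @export
read_image <- function(path, axis = c("z", "time"), z_step_um = 0.22) {
  axis <- match.arg(axis)
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      format_error(sprintf("not a readable TIFF (%s): %s",
                                           conditionMessage(e), path))
                    })
  if (!length(pages)) format_error(sprintf("TIFF contains no images: %s", path))
  to_frame <- function(pg) {
    if (length(dim(pg)) == 3L) {
      format_error(sprintf("RGB/multichannel TIFF not supported: %s", path))
    }
    bits <- if (max(pg) > 255) 16L else 8L
    image_frame(matrix(as.numeric(pg), nrow(pg), ncol(pg)), bit_depth = bits)
  }
  frames <- lapply(pages, to_frame)
  if (length(frames) == 1L) {
    frames[[1]]
  } else {
    image_stack(frames, axis = axis, z_step_um = z_step_um,
                times_s = if (axis == "time") seq_along(frames) - 1 else NULL)
  }
}

#' Write an image or stack as a grayscale TIFF
#'
#' @param x An [image_frame()], [image_stack()], matrix, or list of matrices.
#' @param path Output path.
#' @param bit_depth 8 or 16; defaults to the frame's recorded bit depth.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path, bit_depth = NULL) {
  frames <- if (inherits(x, "image_stack")) x$frames
            else if (is.list(x) && !inherits(x, "image_frame")) x
            else list(x)
  bit_depth <- bit_depth %||% (attr(frames[[1]], "bit_depth") %||% 16L)
  maxv <- 2^bit_depth - 1
  scaled <- lapply(frames, function(fr) {
    m <- as_pixel_matrix(fr)
    if (any(m < 0) || any(m > maxv)) {
      stop(sprintf("pixel values outside [0, %d]; quantize before writing", maxv),
           call. = FALSE)
    }
    round(m) / maxv
  })
  tiff::writeTIFF(if (length(scaled) == 1L) scaled[[1]] else scaled,
                  path, bits.per.sample = bit_depth, compression = "none")
  invisible(path)
}

spot_table_columns <- c("x_px", "y_px", "z_index", "amplitude", "background",
                        "glrt_score", "score_db", "depletion_round",
                        "residual_var", "converged")

#' Write / read a spot table as CSV
#'
#' Numeric columns are written at full double precision so that
#' `read_spot_table(write_spot_table(x))` round-trips exactly within 1e-12.
#'
#' @param spots A `fish_spots` object or spot-table data frame.
#' @param path CSV path.
#' @return `write_spot_table`: `path`, invisibly.  `read_spot_table`: the
#'   spot-table data frame (schema-checked; a missing required column is an
#'   error naming the column).
#' @export
write_spot_table <- function(spots, path) {
  if (inherits(spots, "fish_spots")) spots <- spots$spots
  out <- spots
  for (cn in names(out)) {
    if (is.double(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(spot_table_columns, names(tab))
  if (length(missing)) {
    stop(sprintf("spot table %s is missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tab$converged <- as.logical(tab$converged)
  tab$z_index <- as.integer(tab$z_index)
  tab$depletion_round <- as.integer(tab$depletion_round)
  tab
}

run_config_keys <- c("simulation", "psf", "detection", "calibration", "sweep",
                     "seed", "output_dir", "log_level")

#' Read / write a run configuration file
#'
#' A single JSON file with per-subcommand sections (`simulation`, `psf`,
#' `detection`, `calibration`, `sweep`) plus `seed`, `output_dir` and
#' `log_level`.  Unknown top-level keys are rejected; the file round-trips
#' losslessly.
#'
#' @param path JSON path.
#' @return `read_run_config`: a named list.  `write_run_config`: `path`,
#'   invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    format_error(sprintf("not a readable config (%s): %s",
                                         conditionMessage(e), path))
                  })
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg
}

#' @rdname read_run_config
#' @param config Named list of configuration sections.
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), run_config_keys)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
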