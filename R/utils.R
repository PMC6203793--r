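# Small shared internals.

# Accepts image_frame objects or plain matrices; returns a bare numeric matrix.
as_pixel_matrix <- function(x) {
  if (inherits(x, "image_frame")) x <- unclass(x)
  if (!is.matrix(x)) stop("expected an image matrix", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

# Deterministic sub-stream seeds: one integer master seed is folded with the
# indices of the cell / frame / channel being generated, so every generated
# object is reproducible independently of generation order.  A simple LCG
# fold, not cryptographic; result is in [1, 2^31 - 2].
substream_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483647
  s <- as.numeric(master) %% m
  for (i in idx) {
    s <- (s * 48271 + as.numeric(i) + 11) %% m
  }
  as.integer(s) + 1L
}

#' Elliptical cell mask
#'
#' @param size Image size, one number or `c(rows, cols)`.
#' @param center Ellipse centre `(x, y)` in 0-based pixel coordinates.
#' @param semi_axes Semi-axes `(rx, ry)` in pixels.
#' @return A logical matrix, `TRUE` inside the ellipse.
#' @export
ellipse_mask <- function(size, center, semi_axes) {
  if (length(size) == 1L) size <- rep(size, 2L)
  x <- matrix(0:(size[2] - 1L), size[1], size[2], byrow = TRUE)
  y <- matrix(0:(size[1] - 1L), size[1], size[2])
  ((x - center[1]) / semi_axes[1])^2 + ((y - center[2]) / semi_axes[2])^2 <= 1
}

# TRUE for each spot whose (rounded) centre pixel lies inside the mask.
spots_in_mask <- function(x, y, mask) {
  row <- round(y) + 1L
  col <- round(x) + 1L
  inside <- row >= 1L & row <= nrow(mask) & col >= 1L & col <= ncol(mask)
  inside[inside] <- mask[cbind(row[inside], col[inside])] != 0
  inside
}

`%||%` <- function(a, b) if (is.null(a)) b else a
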