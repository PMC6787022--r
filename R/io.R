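#' Write a frame stack to a multi-page TIFF
#'
#' Intensities are written as 8-bit grayscale (values are clamped to
#' 0-255). Acquisition metadata is not stored in the file; supply it again
#' when reading.
#'
#' @param stack A [frame_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$intensity)
  pages <- lapply(seq_len(d[3]), function(f) {
    pmin(pmax(stack$intensity[, , f] / 255, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a multi-page TIFF as a frame stack
#'
#' @param path TIFF file path.
#' @param frequency,magnification,sensor_pixel Acquisition metadata.
#' @return A [frame_stack()] with intensities on the 0-255 scale.
#' @export
read_frame_stack <- function(path, frequency, magnification, sensor_pixel = 13) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0L, dim = c(d[1], d[2], length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- as.integer(round(pages[[f]] * 255))
  frame_stack(arr, frequency = frequency, magnification = magnification,
              sensor_pixel = sensor_pixel)
}

#' Write / read trajectory and master-step tables
#'
#' Plain-CSV persistence for the two tabular interchange formats: the
#' trajectory table (`cell_id, frame, x_px, y_px` in pixels or
#' `cell_id, frame, t_s, x_um, y_um` in micrometres) and the master step
#' table (`cell_id, step_index, dx_um, dy_um, eps_um, tau_s, tau_wait_s,
#' tau_run_s`).
#'
#' @param x Tibble to write.
#' @param path CSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_trajectories <- function(x, path) {
  units <- attr(x, "units")
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path))
  attr(x, "units") <- if ("x_um" %in% names(x)) "um" else "px"
  x
}

#' @rdname write_trajectories
#' @export
write_master <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_master <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
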