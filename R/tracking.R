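#' Frame stack container
#'
#' A grayscale video: a `row x col x frame` intensity array together with
#' the acquisition metadata needed for unit conversion (frame rate,
#' magnification, sensor pixel pitch).
#'
#' @param intensity 3-D numeric or integer array, `row x col x frame`.
#' @param frequency Frame rate, Hz.
#' @param magnification Microscope magnification factor.
#' @param sensor_pixel Sensor pixel pitch, micrometres.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(intensity, frequency, magnification, sensor_pixel = 13) {
  d <- dim(intensity)
  if (is.null(d) || length(d) != 3L || any(d <= 0)) {
    stop("intensity must be a 3-D array with positive dimensions", call. = FALSE)
  }
  if (frequency <= 0 || magnification <= 0 || sensor_pixel <= 0) {
    stop("frequency, magnification and sensor_pixel must be positive", call. = FALSE)
  }
  structure(list(intensity = intensity, frequency = frequency,
                 magnification = magnification, sensor_pixel = sensor_pixel),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$intensity)
  cat("<frame_stack> ", d[1], " x ", d[2], " px, ", d[3], " frames @ ",
      x$frequency, " Hz, ", x$magnification, "X (",
      signif(x$sensor_pixel / x$magnification, 3), " um/px)\n", sep = "")
  invisible(x)
}

#' Detect cells in every frame of a stack
#'
#' Cells appear as compact groups of pixels whose intensity differs
#' markedly from their surroundings (darker under bright light), while
#' background pixels keep similar values over time. Two robust background
#' references are combined. Temporally, each pixel is compared against its
#' median over all frames, with noise scale `1.4826 * MAD` of the temporal
#' residuals — robust to the moving minority of cell pixels. Spatially,
#' each pixel is compared against its frame's median intensity (cells
#' occupy a negligible fraction of the field of view), which is what makes
#' a cell that never moves — later discarded as "completely idle" by
#' [filter_trajectories()] — detectable at all. A pixel is foreground in a
#' frame when either deviation exceeds `k_sigma` times the corresponding
#' robust scale; foreground pixels are grouped by 8-connectivity and
#' components smaller than `min_blob_pixels` are discarded, suppressing
#' residual noise. The detection is the centroid (arithmetic mean of
#' member pixel coordinates, hence fractional).
#'
#' An all-constant stack yields zero detections (not an error).
#'
#' @param stack A [frame_stack()].
#' @param k_sigma Threshold multiplier on the robust noise scale.
#' @param min_blob_pixels Minimum component size in pixels (cells occupy
#'   at least 2-3 pixels at a properly chosen magnification).
#' @param spatial Also compare pixels against the frame-wide median
#'   (default); set `FALSE` for a purely temporal background model, e.g.
#'   under non-uniform illumination.
#' @return Tibble `(frame, x_px, y_px, n_pixels)`; `frame` 0-based,
#'   centroids 0-based fractional pixels with `x` = column, `y` = row.
#' @export
detect_cells <- function(stack, k_sigma = 5, min_blob_pixels = 2,
                         spatial = TRUE) {
  stopifnot(inherits(stack, "frame_stack"), k_sigma > 0, min_blob_pixels >= 1)
  d <- dim(stack$intensity)
  npix <- d[1] * d[2]
  bg <- .stack_median_mad(stack$intensity, npix, d[3])
  med <- matrix(bg$median, d[1], d[2])
  scale <- matrix(1.4826 * bg$mad, d[1], d[2])

  out <- vector("list", d[3])
  for (f in seq_len(d[3])) {
    fg <- abs(stack$intensity[, , f] - med) > k_sigma * scale
    if (spatial) {
      frame <- stack$intensity[, , f]
      smed <- stats::median(frame)
      sscale <- 1.4826 * stats::median(abs(frame - smed))
      fg <- fg | abs(frame - smed) > k_sigma * sscale
    }
    if (!any(fg)) next
    lab <- .label_8connect(fg)
    idx <- which(lab > 0L)
    labs <- lab[idx]
    sizes <- tabulate(labs)
    keep <- which(sizes >= min_blob_pixels)
    if (length(keep) == 0L) next
    rows <- (idx - 1L) %% d[1]       # 0-based row = y
    cols <- (idx - 1L) %/% d[1]      # 0-based col = x
    cx <- vapply(keep, function(l) mean(cols[labs == l]), numeric(1))
    cy <- vapply(keep, function(l) mean(rows[labs == l]), numeric(1))
    out[[f]] <- tibble::tibble(frame = f - 1L, x_px = cx, y_px = cy,
                               n_pixels = sizes[keep])
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(frame = integer(), x_px = numeric(),
                          y_px = numeric(), n_pixels = integer())
  }
  res
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbour linking with a search radius: going frame by
#' frame, each open track claims the nearest unclaimed detection within
#' `search_radius` of its last position (globally closest pairs first;
#' exact ties broken by lower detection index). A detection farther than
#' `new_path_radius` from every open track end starts a new track; an
#' unclaimed detection within `new_path_radius` of some open track is
#' regarded as ambiguous and dropped for that frame. A track that goes
#' unmatched for more than `max_missed` consecutive frames is closed;
#' shorter dropouts are bridged (the trajectory simply skips the missing
#' frames).
#'
#' When two cells approach within the search radius, identity across the
#' encounter is not guaranteed — the tracker only promises that no
#' detection is assigned to two tracks.
#'
#' @param detections Tibble from [detect_cells()], sorted by frame.
#' @param search_radius Maximum per-frame displacement, pixels. A useful
#'   default is (maximum plausible speed x frame interval) / pixel size.
#' @param new_path_radius Radius beyond which an unmatched detection is
#'   considered a new cell; defaults to `search_radius`.
#' @param max_missed Number of consecutive missed frames tolerated before
#'   a track is closed.
#' @return Tibble `(cell_id, frame, x_px, y_px)` with attribute
#'   `units = "px"`; frame indices strictly increasing within each cell.
#' @export
link_detections <- function(detections, search_radius,
                            new_path_radius = search_radius, max_missed = 2) {
  if (search_radius <= 0) stop("search_radius must be positive", call. = FALSE)
  stopifnot(new_path_radius > 0, max_missed >= 0)
  if (nrow(detections) == 0L) {
    out <- tibble::tibble(cell_id = integer(), frame = integer(),
                          x_px = numeric(), y_px = numeric())
    attr(out, "units") <- "px"
    return(out)
  }
  detections <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(detections$frame))
  by_frame <- split(detections, detections$frame)

  # track state vectors
  tid <- integer(0); tx <- numeric(0); ty <- numeric(0)
  tmiss <- integer(0); topen <- logical(0)
  next_id <- 0L
  rec <- list(); nrec <- 0L

  add_point <- function(id, frame, x, y) {
    nrec <<- nrec + 1L
    rec[[nrec]] <<- c(id, frame, x, y)
  }

  all_frames <- seq(min(frames), max(frames))
  for (f in all_frames) {
    det <- by_frame[[as.character(f)]]
    open <- which(topen)
    if (is.null(det) || nrow(det) == 0L) {
      tmiss[open] <- tmiss[open] + 1L
      topen[open[tmiss[open] > max_missed]] <- FALSE
      next
    }
    nd <- nrow(det)
    claimed <- rep(FALSE, nd)
    matched_tracks <- integer(0)
    if (length(open) > 0L) {
      dmat <- outer(tx[open], det$x_px, `-`)^2 + outer(ty[open], det$y_px, `-`)^2
      dmat <- sqrt(dmat)
      repeat {
        m <- min(dmat)
        if (!is.finite(m) || m > search_radius) break
        hit <- which(dmat == m, arr.ind = TRUE)
        # tie-break: lower detection index, then lower track index
        hit <- hit[order(hit[, 2], hit[, 1]), , drop = FALSE][1, ]
        tr <- open[hit[1]]; de <- hit[2]
        tx[tr] <- det$x_px[de]; ty[tr] <- det$y_px[de]; tmiss[tr] <- 0L
        add_point(tid[tr], f, det$x_px[de], det$y_px[de])
        matched_tracks <- c(matched_tracks, tr)
        claimed[de] <- TRUE
        dmat[hit[1], ] <- Inf
        dmat[, de] <- Inf
      }
    }
    # unmatched open tracks age; close the stale ones
    un <- setdiff(open, matched_tracks)
    tmiss[un] <- tmiss[un] + 1L
    topen[un[tmiss[un] > max_missed]] <- FALSE
    # unclaimed detections: new track only if far from every open track end
    for (de in which(!claimed)) {
      if (length(open) > 0L) {
        dmin <- min(sqrt((tx[open] - det$x_px[de])^2 + (ty[open] - det$y_px[de])^2))
        if (dmin <= new_path_radius) next  # ambiguous, drop
      }
      next_id <- next_id + 1L
      tid <- c(tid, next_id); tx <- c(tx, det$x_px[de]); ty <- c(ty, det$y_px[de])
      tmiss <- c(tmiss, 0L); topen <- c(topen, TRUE)
      add_point(next_id, f, det$x_px[de], det$y_px[de])
    }
  }
  m <- do.call(rbind, rec)
  out <- tibble::tibble(cell_id = as.integer(m[, 1]), frame = as.integer(m[, 2]),
                        x_px = m[, 3], y_px = m[, 4])
  out <- out[order(out$cell_id, out$frame), , drop = FALSE]
  attr(out, "units") <- "px"
  out
}

#' Filter trajectories by duration and activity
#'
#' Keeps only trajectories of meaningful duration (`min_frames` samples or
#' more) that made at least one jump — i.e. at least one displacement of a
#' body length or more between successive recorded states. Completely idle
#' cells are thereby excluded from further analysis.
#'
#' Works on pixel-unit trajectories (give `magnification` so the body
#' length can be expressed in pixels) or on micrometre-unit trajectories.
#'
#' @param trajs Trajectory tibble from [link_detections()] (pixel units)
#'   or [convert_units()] (micrometres).
#' @param min_frames Minimum number of samples.
#' @param require_jump Require at least one supra-body-length displacement.
#' @param body_length Body length, micrometres.
#' @param magnification,sensor_pixel Conversion metadata, needed only for
#'   pixel-unit input.
#' @return The filtered tibble (same columns and units attribute).
#' @export
filter_trajectories <- function(trajs, min_frames = 10, require_jump = TRUE,
                                body_length = 3, magnification = NULL,
                                sensor_pixel = 13) {
  units <- attr(trajs, "units")
  if (is.null(units)) units <- if ("x_um" %in% names(trajs)) "um" else "px"
  if (units == "px") {
    if (is.null(magnification)) {
      stop("magnification is required to express body_length in pixels",
           call. = FALSE)
    }
    thr <- body_length * magnification / sensor_pixel
    xc <- "x_px"; yc <- "y_px"
  } else {
    thr <- body_length
    xc <- "x_um"; yc <- "y_um"
  }
  keep <- vapply(split(seq_len(nrow(trajs)), trajs$cell_id), function(ix) {
    if (length(ix) < min_frames) return(FALSE)
    if (!require_jump) return(TRUE)
    dx <- diff(trajs[[xc]][ix]); dy <- diff(trajs[[yc]][ix])
    any(sqrt(dx^2 + dy^2) >= thr)
  }, logical(1))
  out <- trajs[trajs$cell_id %in% as.integer(names(keep)[keep]), , drop = FALSE]
  attr(out, "units") <- units
  out
}

#' Default search radius from a plausible maximum speed
#'
#' The linking search radius should cover the largest per-frame
#' displacement a cell can plausibly make:
#' `(max speed x frame interval) / pixel size`.
#'
#' @param max_speed_um_s Maximum plausible cell speed, micrometres/second.
#' @param frequency Frame rate, Hz.
#' @param magnification Magnification factor.
#' @param sensor_pixel Sensor pixel pitch, micrometres.
#' @param slack Multiplicative safety factor.
#' @return Search radius in pixels.
#' @export
default_search_radius <- function(max_speed_um_s, frequency, magnification,
                                  sensor_pixel = 13, slack = 1.5) {
  stopifnot(max_speed_um_s > 0, frequency > 0, magnification > 0)
  slack * (max_speed_um_s / frequency) * magnification / sensor_pixel
}
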