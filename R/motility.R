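# Sperm motility from dark-field movies: global frame-subtraction score
# normalized to sperm density, per-cell percent motile by centroid tracking,
# and per-cell response latency after a photorelease flash.

#' Movie stack container
#'
#' @param frames Numeric array `H x W x T` of non-negative intensities
#'   (T >= 2), or a list of equal-size matrices.
#' @param fps Frame rate in Hz (25 for sea urchin, 40 for salmon
#'   recordings).
#' @param flash_frame Optional index of the UV-flash frame.
#' @return A list of class `movie_stack`.
#' @export
movie_stack <- function(frames, fps, flash_frame = NA_integer_) {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    stopifnot(all(vapply(frames, function(f) identical(dim(f), d),
                         logical(1))))
    frames <- array(unlist(frames), dim = c(d, length(frames)))
  }
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 2, fps > 0,
            all(frames >= 0))
  structure(list(frames = frames, fps = fps,
                 flash_frame = as.integer(flash_frame)),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<movie_stack> %d frames of %dx%d at %g Hz\n",
              d[3], d[1], d[2], x$fps))
  invisible(x)
}

#' Binarize a frame
#'
#' Automatic histogram (Otsu) threshold on the intensity-normalized frame;
#' a constant frame yields an all-background mask. The threshold is
#' histogram-derived, so the mask is invariant under global intensity
#' scaling.
#'
#' @param frame Non-negative intensity matrix.
#' @param method `"otsu"` (only method currently).
#' @return A logical mask of the same dimensions.
#' @export
binarize <- function(frame, method = "otsu") {
  method <- match.arg(method, "otsu")
  stopifnot(all(frame >= 0))
  rng <- range(frame)
  if (diff(rng) == 0) return(matrix(FALSE, nrow(frame), ncol(frame)))
  norm <- (frame - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  norm > thr
}

#' Frame-subtraction motility score
#'
#' For each consecutive frame pair, counts pixels whose binarized value
#' changed; the aggregate score is the mean changed-pixel count divided by
#' the mean raw pixel intensity of the stack (sperm-density normalization).
#'
#' @param stack A [movie_stack()].
#' @return A list of class `motility_score` with `per_pair` (changed-pixel
#'   counts), `density` (mean raw intensity), and `score` (aggregate;
#'   `NA` with a flag if the stack has zero mean intensity).
#' @export
motility_score <- function(stack) {
  f <- stack$frames
  nt <- dim(f)[3]
  masks <- lapply(seq_len(nt), function(i) binarize(f[, , i]))
  per_pair <- vapply(seq_len(nt - 1),
                     function(i) sum(masks[[i]] != masks[[i + 1]]),
                     numeric(1))
  density <- mean(f)
  structure(list(per_pair = per_pair, density = density,
                 score = if (density > 0) mean(per_pair) / density
                         else NA_real_,
                 undefined = density <= 0),
            class = "motility_score")
}

# Detect bright blobs in one frame: Otsu mask, connected components,
# centroids of components above the area cutoff.
detect_cells <- function(frame, min_area = 3) {
  mask <- binarize(frame)
  if (!any(mask)) {
    return(data.frame(x = numeric(0), y = numeric(0), area = numeric(0)))
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.integer(lab)
  idx <- which(lab > 0)
  rows <- (idx - 1) %% nrow(frame) + 1
  cols <- (idx - 1) %/% nrow(frame) + 1
  comp <- lab[idx]
  area <- tabulate(comp)
  cx <- tapply(rows, comp, mean)
  cy <- tapply(cols, comp, mean)
  keep <- area >= min_area
  data.frame(x = as.numeric(cx)[keep], y = as.numeric(cy)[keep],
             area = area[keep])
}

# Track each starting cell through the stack by nearest-neighbour linking.
# Returns, per cell, the start position, the per-step displacements and the
# maximal displacement from the start over the tracked segment.
track_cells <- function(stack, start_frame = 1L, end_frame = NULL,
                        min_area = 3, max_link_px = NULL) {
  f <- stack$frames
  nt <- dim(f)[3]
  end_frame <- end_frame %||% nt
  dets <- lapply(start_frame:end_frame,
                 function(i) detect_cells(f[, , i], min_area))
  cells0 <- dets[[1]]
  if (!nrow(cells0)) stop("zero detected cells", call. = FALSE)
  diameter <- 2 * sqrt(median(cells0$area) / pi)
  max_link <- max_link_px %||% (3 * diameter)
  ncell <- nrow(cells0)
  nstep <- length(dets) - 1L
  step_disp <- matrix(NA_real_, ncell, nstep)
  max_disp <- numeric(ncell)
  alive_until <- integer(ncell)
  for (ci in seq_len(ncell)) {
    px <- cells0$x[ci]; py <- cells0$y[ci]
    x0 <- px; y0 <- py
    alive_until[ci] <- 1L
    for (s in seq_len(nstep)) {
      d <- dets[[s + 1L]]
      if (!nrow(d)) break
      dist2 <- (d$x - px)^2 + (d$y - py)^2
      j <- which.min(dist2)
      if (sqrt(dist2[j]) > max_link) break
      step_disp[ci, s] <- sqrt(dist2[j])
      px <- d$x[j]; py <- d$y[j]
      md <- sqrt((px - x0)^2 + (py - y0)^2)
      if (md > max_disp[ci]) max_disp[ci] <- md
      alive_until[ci] <- s + 1L
    }
  }
  list(start = cells0, diameter = diameter, step_disp = step_disp,
       max_disp = max_disp, alive_until = alive_until)
}

#' Percent motile cells by tracking
#'
#' Detects cells in the first analysis frame, links them frame to frame by
#' nearest neighbour (maximal link distance 3 cell diameters), and classes a
#' cell motile if its displacement from the starting position exceeds the
#' threshold (default 2 cell diameters) at any point of the analysis window.
#'
#' @param stack A [movie_stack()].
#' @param window_s Analysis window length in seconds (default: whole
#'   stack).
#' @param min_area Minimum blob area (pixels) for a detection.
#' @param displacement_diameters Motile displacement threshold in cell
#'   diameters.
#' @param max_link_px Maximal frame-to-frame link distance (default 3 cell
#'   diameters).
#' @return A list of class `motility_report` with `percent_motile`,
#'   `n_cells`, the per-cell logical `motile`, and the estimated cell
#'   `diameter` (px).
#' @export
percent_motile <- function(stack, window_s = NULL, min_area = 3,
                           displacement_diameters = 2,
                           max_link_px = NULL) {
  nt <- dim(stack$frames)[3]
  end_frame <- if (is.null(window_s)) nt else
    min(nt, 1L + ceiling(window_s * stack$fps))
  tr <- track_cells(stack, 1L, end_frame, min_area, max_link_px)
  thr <- displacement_diameters * tr$diameter
  motile <- tr$max_disp > thr
  structure(list(percent_motile = 100 * mean(motile),
                 n_cells = length(motile), motile = motile,
                 diameter = tr$diameter, threshold_px = thr),
            class = "motility_report")
}

#' @export
print.motility_report <- function(x, ...) {
  cat(sprintf("<motility_report> %.1f%% motile of %d cells\n",
              x$percent_motile, x$n_cells))
  invisible(x)
}

#' Per-cell response latency after a flash
#'
#' Tracks every cell detected at the flash frame and reports, per cell, the
#' first post-flash time at which its frame-to-frame displacement exceeds
#' the speed threshold. Cells that never cross it get `Inf` latency; the
#' responder fraction counts cells with finite latency.
#'
#' @param stack A [movie_stack()].
#' @param flash_frame Index of the flash frame (defaults to the stack's).
#' @param speed_threshold_px Displacement per frame that counts as
#'   movement (default half a cell diameter).
#' @param min_consecutive Number of consecutive frames the displacement
#'   must stay above threshold. Transient single-frame centroid jumps occur
#'   when a passing cell's blob briefly merges with a static one; genuine
#'   swimming exceeds the threshold on every frame, so requiring a short
#'   run rejects those artifacts.
#' @param min_area Minimum blob area for a detection.
#' @return A list of class `latency_report` with `latency_s` (per cell),
#'   `responder_fraction`, and `n_cells`.
#' @export
response_latency <- function(stack, flash_frame = stack$flash_frame,
                             speed_threshold_px = NULL,
                             min_consecutive = 2L, min_area = 3) {
  nt <- dim(stack$frames)[3]
  if (is.na(flash_frame) || flash_frame < 1 || flash_frame > nt - 2)
    stop("flash_frame must leave at least 2 post-flash frames",
         call. = FALSE)
  tr <- track_cells(stack, as.integer(flash_frame), nt, min_area)
  thr <- speed_threshold_px %||% (0.5 * tr$diameter)
  lat <- apply(tr$step_disp, 1, function(d) {
    above <- !is.na(d) & d > thr
    run <- rle(above)
    starts <- cumsum(c(1, head(run$lengths, -1)))
    w <- starts[run$values & run$lengths >= min_consecutive]
    if (length(w)) w[1] / stack$fps else Inf
  })
  structure(list(latency_s = lat,
                 responder_fraction = mean(is.finite(lat)),
                 n_cells = length(lat), threshold_px = thr),
            class = "latency_report")
}

#' Read / write multi-frame TIFF movie stacks
#'
#' Thin wrappers over EBImage's TIFF support for the dark-field recordings.
#'
#' @param path TIFF file path.
#' @param fps,flash_frame Passed to [movie_stack()].
#' @export
read_movie_tiff <- function(path, fps, flash_frame = NA_integer_) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) a <- array(a, dim = c(dim(a), 1))
  movie_stack(a, fps, flash_frame)
}

#' @rdname read_movie_tiff
#' @param stack A [movie_stack()]; intensities are rescaled to `[0, 1]`
#'   for storage.
#' @export
write_movie_tiff <- function(stack, path) {
  f <- stack$frames
  f <- f / max(f, 1e-12)
  EBImage::writeImage(EBImage::Image(f), path, type = "tiff")
  invisible(path)
}
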