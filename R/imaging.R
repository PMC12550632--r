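# Synthetic dual-channel fluorescence imaging and classical cell counting.
#
# The instrument alternates LED color frame by frame, so even frames image
# one cell population (the "target" cells being pulled off) and odd frames
# the other (the monolayer, kept for QC). Cells are rendered as Gaussian
# blobs on a noisy background; counting is a deterministic classical
# detector — difference-of-Gaussians band-pass, threshold, connected
# components with an area gate — standing in for a trained network, which
# the analysis does not require: only per-frame counts feed downstream.

#' Synthetic two-channel scene
#'
#' Cell positions and optical parameters from which frames are rendered.
#' Target-channel centers are sampled with a minimum pairwise distance so
#' blobs stay resolvable; the monolayer channel gets its own independent
#' set.
#'
#' @param n_target,n_monolayer Cells per channel.
#' @param frame_dim Frame size in pixels, `c(width, height)` (default
#'   `c(256, 256)`; the instrument's full 4096 x 2160 also works, just
#'   slower).
#' @param cell_sigma_px Gaussian radius of a rendered cell in pixels
#'   (default 3).
#' @param min_separation_px Minimum center-to-center distance (default
#'   `6 * cell_sigma_px`).
#' @param amplitude Peak intensity of a cell above background (default
#'   100).
#' @param background Constant background level (default 50).
#' @param noise_sd Gaussian read-noise SD (default 20, i.e. SNR
#'   `amplitude / noise_sd` = 5).
#' @param pixel_size_nm Physical pixel size (default 170 nm), metadata
#'   only.
#' @param seed Optional seed for center placement.
#' @return An object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(n_target = 50, n_monolayer = 50,
                            frame_dim = c(256, 256), cell_sigma_px = 3,
                            min_separation_px = 6 * cell_sigma_px,
                            amplitude = 100, background = 50, noise_sd = 20,
                            pixel_size_nm = 170, seed = NULL) {
  if (cell_sigma_px <= 0) stop("cell_sigma_px must be > 0", call. = FALSE)
  place <- function(n) {
    if (n == 0) return(matrix(numeric(0), ncol = 2))
    margin <- 3 * cell_sigma_px
    pts <- matrix(NA_real_, n, 2)
    got <- 0; tries <- 0
    while (got < n) {
      tries <- tries + 1
      if (tries > 20000 * n)
        stop("cannot place cells with the requested separation; reduce n or min_separation_px",
             call. = FALSE)
      p <- c(runif(1, margin, frame_dim[1] - margin),
             runif(1, margin, frame_dim[2] - margin))
      if (got == 0 ||
          min(sqrt(rowSums(sweep(pts[seq_len(got), , drop = FALSE], 2, p)^2))) >=
            min_separation_px) {
        got <- got + 1
        pts[got, ] <- p
      }
    }
    pts
  }
  run <- function() list(target = place(n_target),
                         monolayer = place(n_monolayer))
  centers <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(centers = centers, frame_dim = frame_dim,
                 cell_sigma_px = cell_sigma_px, amplitude = amplitude,
                 background = background, noise_sd = noise_sd,
                 pixel_size_nm = pixel_size_nm),
            class = "synthetic_scene")
}

# Render one frame: background + Gaussian blob per center + optional noise.
.render_frame <- function(centers, frame_dim, sigma, amplitude, background,
                          noise_sd) {
  img <- matrix(background, nrow = frame_dim[1], ncol = frame_dim[2])
  if (nrow(centers)) {
    half <- ceiling(4 * sigma)
    win <- -half:half
    blob <- amplitude * exp(-outer(win^2, win^2, "+") / (2 * sigma^2))
    for (i in seq_len(nrow(centers))) {
      cx <- round(centers[i, 1]); cy <- round(centers[i, 2])
      xs <- cx + win; ys <- cy + win
      okx <- xs >= 1 & xs <= frame_dim[1]
      oky <- ys >= 1 & ys <= frame_dim[2]
      img[xs[okx], ys[oky]] <- img[xs[okx], ys[oky]] + blob[okx, oky]
    }
  }
  if (noise_sd > 0)
    img <- img + matrix(rnorm(length(img), sd = noise_sd),
                        nrow = nrow(img))
  img
}

#' Render an alternating-channel frame stack
#'
#' Produces the interleaved frame sequence the instrument records: even
#' frames (1st, 3rd, ...) image the target channel, odd frames the
#' monolayer. Target cells disappear over time according to
#' `departure_times`; the monolayer is static.
#'
#' @param scene A [synthetic_scene()].
#' @param n_frames Total frames (both channels interleaved).
#' @param frame_rate Frames per second (default 4).
#' @param departure_times Optional vector, one per target cell: the time
#'   (s) at which that cell leaves the field of view (`Inf` = stays). E.g.
#'   the `rupture_times` of a [simulate_trial()].
#' @param seed Optional seed (noise realization).
#' @return An object of class `frame_stack`: list with `frames` (list of
#'   matrices), `timestamps` (s), `channel` (`"target"`/`"monolayer"`
#'   alternating), and the scene.
#' @export
render_frames <- function(scene, n_frames, frame_rate = 4,
                          departure_times = NULL, seed = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  n_target <- nrow(scene$centers$target)
  if (is.null(departure_times)) departure_times <- rep(Inf, n_target)
  if (length(departure_times) != n_target)
    stop("departure_times must have one entry per target cell", call. = FALSE)
  run <- function() {
    ts <- (seq_len(n_frames) - 1) / frame_rate
    ch <- rep(c("target", "monolayer"), length.out = n_frames)
    frames <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      ctr <- if (ch[i] == "target")
        scene$centers$target[departure_times > ts[i], , drop = FALSE]
      else scene$centers$monolayer
      frames[[i]] <- .render_frame(ctr, scene$frame_dim, scene$cell_sigma_px,
                                   scene$amplitude, scene$background,
                                   scene$noise_sd)
    }
    list(frames = frames, timestamps = ts, channel = ch)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(c(res, list(scene = scene)), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames (%s), %dx%d px, %.3g s span\n",
              length(x$frames), paste(unique(x$channel), collapse = "+"),
              nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              max(x$timestamps)))
  invisible(x)
}

#' Split an interleaved stack into its two channels
#'
#' Even-position frames are the target channel and odd-position frames the
#' monolayer channel (1-based: positions 1, 3, ... are target). Timestamps
#' are preserved; output lengths differ by at most one.
#'
#' @param stack A [render_frames()] stack with alternating channel labels.
#' @return List of two `frame_stack`s: `target` and `monolayer`.
#' @export
demux_channels <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack$frames)
  expected <- rep(c("target", "monolayer"), length.out = n)
  if (!identical(stack$channel, expected))
    stop("channel labels do not alternate target/monolayer; cannot demultiplex",
         call. = FALSE)
  pick <- function(idx, label) structure(
    list(frames = stack$frames[idx], timestamps = stack$timestamps[idx],
         channel = rep(label, length(idx)), scene = stack$scene),
    class = "frame_stack")
  list(target = pick(seq(1, n, by = 2), "target"),
       monolayer = pick(seq(2, n, by = 2), "monolayer"))
}

#' Detector settings for classical cell counting
#'
#' @param sigma_small,sigma_large Difference-of-Gaussians scales in pixels;
#'   defaults (2, 6) bracket the default rendered cell size.
#' @param threshold Intensity threshold on the band-passed image. The
#'   default `NULL` sets it per frame to
#'   `k_mad` robust SDs above the median of the filtered image.
#' @param k_mad Robust-threshold multiplier (default 6).
#' @param min_area,max_area Connected-component area gate in pixels
#'   (defaults 4 and 2000).
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(sigma_small = 2, sigma_large = 6,
                            threshold = NULL, k_mad = 6, min_area = 4,
                            max_area = 2000) {
  if (sigma_small >= sigma_large)
    stop("sigma_small must be < sigma_large", call. = FALSE)
  structure(list(sigma_small = sigma_small, sigma_large = sigma_large,
                 threshold = threshold, k_mad = k_mad,
                 min_area = min_area, max_area = max_area),
            class = "detector_params")
}

#' Count cells in a single-channel frame
#'
#' Deterministic classical detection: difference-of-Gaussians band-pass
#' (suppressing both pixel noise and slowly-varying background), robust
#' threshold, connected-component labeling with an area gate, centroid
#' extraction.
#'
#' @param frame Numeric matrix of pixel intensities.
#' @param params A [detector_params()].
#' @return List with `count`, `centroids` (matrix of x, y), and `flags`
#'   (e.g. blank or saturated frame).
#' @export
count_cells <- function(frame, params = detector_params()) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  flags <- character(0)
  if (sd(frame) == 0) {
    return(list(count = 0L, centroids = matrix(numeric(0), ncol = 2),
                flags = "blank frame: zero intensity variance"))
  }
  img <- EBImage::Image(frame)
  dog <- EBImage::gblur(img, sigma = params$sigma_small) -
    EBImage::gblur(img, sigma = params$sigma_large)
  d <- EBImage::imageData(dog)
  thr <- params$threshold
  if (is.null(thr)) thr <- median(d) + params$k_mad * mad(d)
  mask <- d > thr
  if (!any(mask)) {
    return(list(count = 0L, centroids = matrix(numeric(0), ncol = 2),
                flags = "no objects above threshold"))
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labv <- as.integer(EBImage::imageData(lab))
  areas <- tabulate(labv)
  keep <- which(areas >= params$min_area & areas <= params$max_area)
  if (!length(keep)) {
    return(list(count = 0L, centroids = matrix(numeric(0), ncol = 2),
                flags = "no objects within area gate"))
  }
  nr <- nrow(frame)
  pos <- which(labv > 0)
  ok <- labv[pos] %in% keep
  pos <- pos[ok]; lv <- labv[labv > 0][ok]
  xs <- ((pos - 1) %% nr) + 1
  ys <- ((pos - 1) %/% nr) + 1
  cx <- tapply(xs, lv, mean)
  cy <- tapply(ys, lv, mean)
  list(count = length(keep),
       centroids = cbind(x = as.numeric(cx), y = as.numeric(cy)),
       flags = flags)
}

#' Count every frame of a demultiplexed stack
#'
#' Vectorizes [count_cells()] over a single-channel stack and returns the
#' schema the detachment module consumes. If a monolayer stack is supplied
#' its per-frame counts (interpolated onto the target timestamps) ride
#' along for QC.
#'
#' @param stack Single-channel `frame_stack` (from [demux_channels()]).
#' @param params A [detector_params()].
#' @param monolayer_stack Optional monolayer-channel stack.
#' @return A [count_trace()].
#' @export
stack_to_count_trace <- function(stack, params = detector_params(),
                                 monolayer_stack = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (length(unique(stack$channel)) != 1)
    stop("stack must be single-channel; demultiplex first", call. = FALSE)
  counts <- vapply(stack$frames, function(f) count_cells(f, params)$count,
                   integer(1))
  mono <- NULL
  if (!is.null(monolayer_stack)) {
    mc <- vapply(monolayer_stack$frames,
                 function(f) count_cells(f, params)$count, integer(1))
    mono <- round(approx(monolayer_stack$timestamps, mc,
                         xout = stack$timestamps, rule = 2)$y)
  }
  count_trace(stack$timestamps, counts, monolayer_counts = mono)
}

#' Write / read a frame stack as multi-page TIFF
#'
#' Intensities are scaled to `[0, 1]` by `scale` on write and restored on
#' read; channel labels and timestamps travel in a JSON sidecar
#' (`<path>.json`).
#'
#' @param stack A `frame_stack`.
#' @param path TIFF file path.
#' @param scale Full-scale intensity mapped to 1.0 (default 4095,
#'   12-bit).
#' @export
write_frame_stack <- function(stack, path, scale = 4095) {
  stopifnot(inherits(stack, "frame_stack"))
  imgs <- lapply(stack$frames, function(f) pmin(pmax(f / scale, 0), 1))
  tiff::writeTIFF(imgs, path, bits.per.sample = 16)
  jsonlite::write_json(
    list(timestamps = stack$timestamps, channel = stack$channel,
         scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  imgs <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(imgs, function(m) m * meta$scale)
  structure(list(frames = frames, timestamps = meta$timestamps,
                 channel = meta$channel, scene = NULL),
            class = "frame_stack")
}
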