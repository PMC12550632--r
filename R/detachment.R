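# Detachment: per-frame cell counts -> adhesion frequency and normalized
# detachment curves. Counts carry frame-to-frame detection jitter, so every
# normalization uses a median over a short window rather than a single frame.

#' Per-frame cell-count trace
#'
#' Timestamped cell counts for the target channel, optionally with a
#' monolayer-channel count (for QC) and the rotor speed recorded per frame.
#'
#' @param times Frame timestamps in seconds, strictly increasing.
#' @param target_counts Non-negative integer cell counts, one per frame.
#' @param monolayer_counts Optional monolayer-channel counts (QC).
#' @param rpm Optional rotor speed per frame.
#' @return An object of class `count_trace` (a data.frame).
#' @export
count_trace <- function(times, target_counts, monolayer_counts = NULL,
                        rpm = NULL) {
  n <- length(times)
  if (length(target_counts) != n)
    stop("times and target_counts must be aligned", call. = FALSE)
  if (n >= 2 && any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(target_counts < 0)) stop("counts must be >= 0", call. = FALSE)
  df <- data.frame(time_s = as.numeric(times),
                   target_count = as.numeric(target_counts))
  if (!is.null(monolayer_counts)) {
    if (length(monolayer_counts) != n)
      stop("monolayer_counts must be aligned with times", call. = FALSE)
    if (any(monolayer_counts < 0)) stop("counts must be >= 0", call. = FALSE)
    df$monolayer_count <- as.numeric(monolayer_counts)
  }
  if (!is.null(rpm)) {
    if (length(rpm) != n) stop("rpm must be aligned with times", call. = FALSE)
    df$rpm <- as.numeric(rpm)
  }
  structure(df, class = c("count_trace", "data.frame"))
}

#' Read / write a count trace as CSV
#'
#' Columns: `time_s`, `target_count` and optionally `monolayer_count`,
#' `rpm` — the same schema the simulator emits and the instrument pipeline
#' produces.
#'
#' @param trace A [count_trace()].
#' @param path File path.
#' @export
write_count_trace <- function(trace, path) {
  stopifnot(inherits(trace, "count_trace"))
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_trace
#' @export
read_count_trace <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "target_count") %in% names(df)))
    stop("count trace CSV needs columns time_s, target_count", call. = FALSE)
  count_trace(df$time_s, df$target_count,
              monolayer_counts = df[["monolayer_count"]],
              rpm = df[["rpm"]])
}

# Median count over frames within +/- window of t. Guards against the
# frame-to-frame detection fluctuation that a single-frame read-out would
# amplify.
robust_count <- function(trace, t, window = 2) {
  sel <- abs(trace$time_s - t) <= window
  if (!any(sel)) {
    # fall back to the nearest frame
    sel <- which.min(abs(trace$time_s - t))
  }
  median(trace$target_count[sel])
}

#' Adhesion frequency from a count trace
#'
#' The adhesion frequency is the fraction of cells still attached at the end
#' of the low-force gravity interval (just before the centrifuge starts)
#' relative to the count when the chamber was flipped. Both endpoint counts
#' are medians over a `window`-second neighbourhood to suppress detection
#' jitter.
#'
#' @param trace A [count_trace()].
#' @param t_flip Time (s) at which the chamber was inverted (start of the
#'   gravity interval).
#' @param t_centrifuge Time (s) of centrifuge activation; must exceed
#'   `t_flip`. The default places it a 2-minute gravity interval after a
#'   flip at 0 s.
#' @param window Half-width (s) of the median window at each endpoint
#'   (default 2 s). The two windows must not overlap.
#' @return An object of class `adhesion_result`: list with
#'   `adhesion_frequency` (clipped to `[0, 1]`), `n_initial`,
#'   `n_after_gravity`, `gravity_interval`.
#' @export
adhesion_frequency <- function(trace, t_flip = 0, t_centrifuge = 120,
                               window = 2) {
  stopifnot(inherits(trace, "count_trace"))
  span <- range(trace$time_s)
  if (t_flip >= t_centrifuge)
    stop("t_flip must precede t_centrifuge", call. = FALSE)
  if (t_flip < span[1] - window || t_centrifuge > span[2] + window)
    stop("t_flip and t_centrifuge must lie within the trace span",
         call. = FALSE)
  if (t_flip + window > t_centrifuge - window)
    stop("endpoint windows overlap; reduce `window`", call. = FALSE)
  n0 <- robust_count(trace, t_flip + window / 2, window)
  # window ending just before centrifuge activation
  sel <- trace$time_s >= (t_centrifuge - window) & trace$time_s < t_centrifuge
  n1 <- if (any(sel)) median(trace$target_count[sel])
        else robust_count(trace, t_centrifuge, window)
  if (n0 <= 0) stop("no cells at start: initial count is zero", call. = FALSE)
  structure(
    list(adhesion_frequency = min(max(n1 / n0, 0), 1),
         n_initial = n0, n_after_gravity = n1,
         gravity_interval = t_centrifuge - t_flip),
    class = "adhesion_result"
  )
}

#' @export
print.adhesion_result <- function(x, ...) {
  cat(sprintf("<adhesion_result> AF = %.3f (%g / %g cells, %g s gravity interval)\n",
              x$adhesion_frequency, x$n_after_gravity, x$n_initial,
              x$gravity_interval))
  invisible(x)
}

#' Build a normalized detachment curve
#'
#' Median-filters the raw counts, re-zeroes time to the chosen origin and
#' divides by a robust count at that origin, yielding the fraction of cells
#' still bound versus time. Two origins are supported: `"centrifuge_start"`
#' (normalize by the cells present when the force ramp starts — used for
#' lifetime fitting) and `"flip"` (normalize by the cells present at chamber
#' inversion — the denominator of the adhesion frequency).
#'
#' @param trace A [count_trace()].
#' @param origin `"centrifuge_start"` or `"flip"`.
#' @param t_origin Time (s) of that origin in the trace's clock.
#' @param smoothing_window Odd median-filter width in frames (default 5).
#' @param window Half-width (s) for the robust normalization count.
#' @param jitter_tol Tolerated upward excursion of the normalized curve
#'   above 1 (default 0.05), reflecting detection jitter; larger excursions
#'   raise a warning flag but are kept.
#' @return An object of class `detachment_curve`: data.frame with columns
#'   `time_s` (>= 0, re-zeroed) and `fraction_bound`, plus attributes
#'   `normalization_count`, `origin`, `flags`.
#' @export
build_detachment_curve <- function(trace,
                                   origin = c("centrifuge_start", "flip"),
                                   t_origin = 120, smoothing_window = 5,
                                   window = 2, jitter_tol = 0.05) {
  stopifnot(inherits(trace, "count_trace"))
  origin <- match.arg(origin)
  span <- range(trace$time_s)
  if (t_origin < span[1] || t_origin > span[2])
    stop("t_origin outside the trace span", call. = FALSE)
  if (smoothing_window %% 2 != 1)
    stop("smoothing_window must be odd", call. = FALSE)
  counts <- if (smoothing_window > 1 && nrow(trace) >= smoothing_window)
    as.numeric(runmed(trace$target_count, smoothing_window,
                      endrule = "median"))
  else trace$target_count
  smoothed <- trace
  smoothed$target_count <- counts
  n0 <- robust_count(smoothed, t_origin, window)
  if (n0 <= 0)
    stop("normalization count at the origin is zero", call. = FALSE)
  keep <- trace$time_s >= t_origin
  frac <- counts[keep] / n0
  flags <- character(0)
  if (any(frac > 1 + jitter_tol))
    flags <- c(flags, sprintf("fraction_bound exceeds 1 + %g (max %.3f)",
                              jitter_tol, max(frac)))
  frac[1] <- 1  # by construction: the origin defines the denominator
  structure(
    data.frame(time_s = trace$time_s[keep] - t_origin, fraction_bound = frac),
    normalization_count = n0, origin = origin, t_origin = t_origin,
    flags = flags,
    class = c("detachment_curve", "data.frame")
  )
}

#' Monolayer-coverage QC check
#'
#' Flags (never drops) a trial whose monolayer-channel count falls by more
#' than `max_drop` of its initial robust value — the signature of a bubble
#' entering the field of view or the monolayer delaminating.
#'
#' @param trace A [count_trace()] with a `monolayer_count` column.
#' @param max_drop Tolerated fractional drop (default 0.2).
#' @return List with `ok` (logical) and `min_relative` (worst relative
#'   monolayer count).
#' @export
monolayer_qc <- function(trace, max_drop = 0.2) {
  stopifnot(inherits(trace, "count_trace"))
  if (is.null(trace$monolayer_count))
    return(list(ok = NA, min_relative = NA_real_))
  k <- min(5, nrow(trace))
  if (k %% 2 == 0) k <- k - 1
  m <- if (k >= 3) as.numeric(runmed(trace$monolayer_count, k,
                                     endrule = "median"))
       else as.numeric(trace$monolayer_count)
  m0 <- median(head(m, 9))
  if (m0 <= 0) return(list(ok = FALSE, min_relative = 0))
  rel <- min(m) / m0
  list(ok = rel >= 1 - max_drop, min_relative = rel)
}

#' Average detachment curves onto a common time grid
#'
#' Linearly interpolates each curve onto `grid` and returns the pointwise
#' mean and sample standard deviation — the "mean curve with shaded band"
#' summary used to compare conditions.
#'
#' @param curves List of at least two [build_detachment_curve()] objects.
#' @param grid Time grid (s) within the curves' common span; defaults to 200
#'   points over the common span.
#' @return A data.frame with columns `time_s`, `mean_fraction`,
#'   `sd_fraction`, `n_curves`.
#' @export
average_curves <- function(curves, grid = NULL) {
  if (length(curves) < 2)
    stop("need at least two curves to average", call. = FALSE)
  lo <- max(vapply(curves, function(cv) min(cv$time_s), numeric(1)))
  hi <- min(vapply(curves, function(cv) max(cv$time_s), numeric(1)))
  if (lo >= hi)
    stop("curves have no overlapping time span", call. = FALSE)
  if (is.null(grid)) grid <- seq(lo, hi, length.out = 200)
  if (any(grid < lo) || any(grid > hi))
    stop("grid extends beyond the common span of the curves", call. = FALSE)
  mat <- vapply(curves, function(cv)
    approx(cv$time_s, cv$fraction_bound, xout = grid)$y,
    numeric(length(grid)))
  data.frame(time_s = grid,
             mean_fraction = rowMeans(mat),
             sd_fraction = apply(mat, 1, sd),
             n_curves = length(curves))
}
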