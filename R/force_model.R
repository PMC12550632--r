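# Force model: rotor speed -> per-cell centrifugal force, ramp design.
#
# A cell in the spinning chamber experiences F = m_eff * r * omega^2, where
# m_eff is the buoyancy-corrected mass of the cell. All public forces are in
# pN; lengths in the units stated per argument; SI internally.

#' Physical parameters of an assayed cell
#'
#' Bundles the quantities that determine the effective (buoyancy-corrected)
#' mass of a cell modeled as a sphere: diameter, cell mass density and the
#' density of the surrounding medium. The defaults describe a typical
#' lymphocyte-sized cell: 10 um diameter, density 1.07 g/mL, in an aqueous
#' medium of density 1.00 g/mL.
#'
#' @param diameter_um Cell diameter in micrometers; must be > 0.
#' @param cell_density Cell mass density in g/mL.
#' @param medium_density Medium mass density in g/mL. Must be strictly less
#'   than `cell_density`: a non-positive density contrast gives zero or
#'   negative effective mass and no defined pulling force.
#' @return An object of class `cell_params`.
#' @examples
#' cell_params()
#' effective_mass(cell_params(diameter_um = 12))
#' @export
cell_params <- function(diameter_um = 10, cell_density = 1.07,
                        medium_density = 1.00) {
  if (!is.numeric(diameter_um) || length(diameter_um) != 1 || diameter_um <= 0)
    stop("`diameter_um` must be a single positive number", call. = FALSE)
  if (cell_density <= medium_density)
    stop("cell_density (", cell_density, " g/mL) must exceed medium_density (",
         medium_density, " g/mL): the effective mass would be non-positive ",
         "and no centrifugal pulling force is defined", call. = FALSE)
  structure(
    list(diameter_um = diameter_um, cell_density = cell_density,
         medium_density = medium_density),
    class = "cell_params"
  )
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf(
    "<cell_params> d = %g um, rho_cell = %g g/mL, rho_medium = %g g/mL\n",
    x$diameter_um, x$cell_density, x$medium_density))
  cat(sprintf("  effective mass %.3e kg, 1 g force %.3f pN\n",
              effective_mass(x), gravity_force(x)))
  invisible(x)
}

#' Effective (buoyancy-corrected) mass of a cell
#'
#' \eqn{m_{eff} = \frac{\pi}{6} d^3 (\rho_{cell} - \rho_{medium})}: the mass
#' of a sphere of the cell's diameter times the density contrast with the
#' medium. This is the mass on which centrifugal and gravitational pulling
#' forces act.
#'
#' @param cell A [cell_params()] object.
#' @return Effective mass in kilograms.
#' @export
effective_mass <- function(cell) {
  stopifnot(inherits(cell, "cell_params"))
  d <- cell$diameter_um * 1e-6                                # m
  drho <- (cell$cell_density - cell$medium_density) * 1000    # kg/m^3
  pi / 6 * d^3 * drho
}

#' Default rotor radius of the benchtop centrifuge
#'
#' The effective rotor radius (distance from rotation axis to the sample
#' plane) used to convert rpm to centrifugal acceleration. The default is
#' derived from the instrument-class calibration that 3000 rpm corresponds
#' to about 1340 g (and 300 rpm to about 13 g):
#' \eqn{r = 1340\,g / \omega^2 \approx 0.133} m. Some instrument
#' descriptions quote ~1600 g at 3000 rpm (r ~ 0.159 m); pass that radius
#' explicitly if it matches your rotor.
#'
#' @return Rotor radius in meters.
#' @export
default_rotor_radius <- function() {
  1340 * .G_ACCEL / (2 * pi * 3000 / 60)^2
}

#' Per-cell centrifugal force at a rotor speed
#'
#' \eqn{F = m_{eff}\, r\, \omega^2} with \eqn{\omega = 2\pi\,rpm/60}.
#'
#' @param rpm Rotor speed(s), revolutions per minute; vectorized, must be
#'   >= 0.
#' @param radius Rotor radius in meters (> 0); default
#'   [default_rotor_radius()].
#' @param cell A [cell_params()] object.
#' @return Force in piconewtons, same length as `rpm`.
#' @examples
#' force_at_rpm(3000)  # ~482 pN for the default cell
#' @export
force_at_rpm <- function(rpm, radius = default_rotor_radius(),
                         cell = cell_params()) {
  if (any(rpm < 0)) stop("rpm must be >= 0", call. = FALSE)
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("radius must be a single positive number (meters)", call. = FALSE)
  omega <- 2 * pi * rpm / 60
  effective_mass(cell) * radius * omega^2 * 1e12
}

#' Rotor speed required for a target per-cell force
#'
#' Inverse of [force_at_rpm()].
#'
#' @param force_pN Target force(s) in pN, >= 0.
#' @inheritParams force_at_rpm
#' @return rpm, same length as `force_pN`.
#' @export
rpm_for_force <- function(force_pN, radius = default_rotor_radius(),
                          cell = cell_params()) {
  if (any(force_pN < 0)) stop("force_pN must be >= 0", call. = FALSE)
  sqrt(force_pN * 1e-12 / (effective_mass(cell) * radius)) * 60 / (2 * pi)
}

#' Per-cell gravitational force with the chamber inverted
#'
#' When the sealed chamber is flipped so that gravity pulls cells away from
#' the surface, each cell is loaded by \eqn{m_{eff} \times 9.81\,m/s^2} —
#' about 0.36 pN for the default cell parameters. This weak load defines the
#' "gravity interval" used to measure adhesion frequency.
#'
#' @inheritParams effective_mass
#' @return Force in piconewtons.
#' @export
gravity_force <- function(cell = cell_params()) {
  effective_mass(cell) * .G_ACCEL * 1e12
}

#' Stair-step rotor-speed protocol
#'
#' A timed schedule of rotor speeds plus the rotor radius, from which the
#' per-cell force versus time follows via [force_at_rpm()]. Steps are
#' piecewise-constant: each rpm holds from its `start_time` until the next
#' step (or `end_time` for the last).
#'
#' @param start_times Step start times in seconds, strictly increasing,
#'   first >= 0.
#' @param rpm Rotor speed per step (>= 0), same length as `start_times`.
#' @param rotor_radius Rotor radius in meters.
#' @param end_time End of the protocol in seconds (> last start time).
#' @param nominal_loading_rate Optional metadata: the loading rate in pN/s
#'   the schedule was designed to realize.
#' @return An object of class `ramp_protocol`.
#' @export
ramp_protocol <- function(start_times, rpm,
                          rotor_radius = default_rotor_radius(),
                          end_time = NULL, nominal_loading_rate = NULL) {
  if (length(start_times) != length(rpm))
    stop("start_times and rpm must have the same length", call. = FALSE)
  if (length(start_times) < 1) stop("at least one step required", call. = FALSE)
  if (any(diff(start_times) <= 0))
    stop("step start_times must be strictly increasing", call. = FALSE)
  if (any(rpm < 0)) stop("rpm must be >= 0", call. = FALSE)
  if (rotor_radius <= 0) stop("rotor_radius must be > 0", call. = FALSE)
  if (is.null(end_time)) {
    dt <- if (length(start_times) > 1) median(diff(start_times)) else 1
    end_time <- start_times[length(start_times)] + dt
  }
  if (end_time <= start_times[length(start_times)])
    stop("end_time must exceed the last step start time", call. = FALSE)
  structure(
    list(steps = data.frame(start_time_s = as.numeric(start_times),
                            rpm = as.numeric(rpm)),
         rotor_radius = rotor_radius, end_time = as.numeric(end_time),
         nominal_loading_rate = nominal_loading_rate),
    class = "ramp_protocol"
  )
}

#' @export
print.ramp_protocol <- function(x, ...) {
  cat(sprintf("<ramp_protocol> %d steps over [%g, %g] s, r = %.4f m",
              nrow(x$steps), x$steps$start_time_s[1], x$end_time,
              x$rotor_radius))
  if (!is.null(x$nominal_loading_rate))
    cat(sprintf(", nominal rate %g pN/s", x$nominal_loading_rate))
  cat(sprintf("\n  rpm %g .. %g\n", min(x$steps$rpm), max(x$steps$rpm)))
  invisible(x)
}

#' Design a stair-step schedule realizing a linear force ramp
#'
#' Builds a [ramp_protocol()] whose step-midpoint forces lie on the line
#' \eqn{F(t) = f_{start} + \dot F t}: during step \eqn{i} (spanning
#' `step_duration` seconds) the rotor runs at the speed whose force equals
#' the target line at the step midpoint. The deviation from the ideal ramp
#' is therefore at most `loading_rate * step_duration / 2` at any instant.
#'
#' @param loading_rate Target loading rate in pN/s (> 0).
#' @param f_max Final force in pN; the schedule ends once the line reaches
#'   `f_max`.
#' @param f_start Starting force in pN (default 0), `f_start < f_max`.
#' @param step_duration Duration of each stair step in seconds (default
#'   0.25 s).
#' @param radius Rotor radius in meters.
#' @param cell A [cell_params()] object.
#' @param t_start Protocol start time in seconds (default 0); use e.g. 120
#'   to start the ramp after a 2-minute gravity interval.
#' @param rpm_ceiling Maximum permissible rotor speed (default 3000 rpm).
#'   If `f_max` needs a higher speed the design is rejected.
#' @param hold_duration Seconds to hold the final speed after the ramp
#'   completes (default 0). A terminal hold lets slowly-detaching
#'   populations decay fully instead of being censored at the ramp end.
#' @return A `ramp_protocol` with `nominal_loading_rate` set.
#' @examples
#' design_ramp(4, f_max = 480)  # ~2 min schedule approaching the ~500 pN
#'                              # ceiling of a 3000 rpm rotor
#' @export
design_ramp <- function(loading_rate, f_max, f_start = 0,
                        step_duration = 0.25,
                        radius = default_rotor_radius(),
                        cell = cell_params(), t_start = 0,
                        rpm_ceiling = 3000, hold_duration = 0) {
  if (loading_rate <= 0) stop("loading_rate must be > 0", call. = FALSE)
  if (step_duration <= 0) stop("step_duration must be > 0", call. = FALSE)
  if (!(f_start >= 0 && f_start < f_max))
    stop("need 0 <= f_start < f_max", call. = FALSE)
  n_steps <- ceiling((f_max - f_start) / (loading_rate * step_duration))
  t_rel <- (seq_len(n_steps) - 1) * step_duration
  f_mid <- pmin(f_start + loading_rate * (t_rel + step_duration / 2), f_max)
  rpm <- rpm_for_force(f_mid, radius = radius, cell = cell)
  if (max(rpm) > rpm_ceiling) {
    f_ceiling <- force_at_rpm(rpm_ceiling, radius = radius, cell = cell)
    stop(sprintf(
      "f_max = %g pN is unreachable below the rpm ceiling of %g rpm (max force %.1f pN at this radius and cell)",
      f_max, rpm_ceiling, f_ceiling), call. = FALSE)
  }
  end_time <- t_start + n_steps * step_duration + hold_duration
  if (hold_duration > 0) {
    t_rel <- c(t_rel, n_steps * step_duration)
    rpm <- c(rpm, rpm_for_force(f_max, radius = radius, cell = cell))
  }
  ramp_protocol(t_start + t_rel, rpm, rotor_radius = radius,
                end_time = end_time,
                nominal_loading_rate = loading_rate)
}

#' Piecewise-constant force segments of a protocol
#'
#' Internal representation consumed by the rupture simulator: one row per
#' stair step with start/end time, force at the start and force rate (always
#' 0 for stair-step protocols).
#'
#' @param protocol A [ramp_protocol()].
#' @param cell A [cell_params()] object.
#' @return A data.frame with columns `t0`, `t1`, `f0`, `rate`.
#' @export
force_segments <- function(protocol, cell = cell_params()) {
  stopifnot(inherits(protocol, "ramp_protocol"))
  st <- protocol$steps$start_time_s
  f <- force_at_rpm(protocol$steps$rpm, radius = protocol$rotor_radius,
                    cell = cell)
  data.frame(t0 = st, t1 = c(st[-1], protocol$end_time), f0 = f, rate = 0)
}

#' Force versus time for a protocol
#'
#' Evaluates [force_at_rpm()] over the protocol's stair steps at the
#' requested sample times (piecewise-constant in time).
#'
#' @param protocol A [ramp_protocol()].
#' @param cell A [cell_params()] object.
#' @param sample_times Times (s) at which to evaluate; must lie within the
#'   protocol span `[first start, end_time]`.
#' @return An object of class `force_trace`: a data.frame with columns
#'   `time_s` and `force_pN`.
#' @export
force_trace <- function(protocol, cell = cell_params(), sample_times) {
  stopifnot(inherits(protocol, "ramp_protocol"))
  st <- protocol$steps$start_time_s
  if (any(sample_times < st[1]) || any(sample_times > protocol$end_time))
    stop(sprintf("sample_times must lie within the protocol span [%g, %g] s",
                 st[1], protocol$end_time), call. = FALSE)
  idx <- findInterval(sample_times, st, rightmost.closed = FALSE)
  f <- force_at_rpm(protocol$steps$rpm[idx], radius = protocol$rotor_radius,
                    cell = cell)
  structure(data.frame(time_s = as.numeric(sample_times), force_pN = f),
            class = c("force_trace", "data.frame"))
}

#' Read / write a ramp protocol as CSV
#'
#' The on-disk form is a two-column CSV (`start_time_s`, `rpm`); radius, end
#' time and nominal rate travel in `#`-prefixed header comments.
#'
#' @param protocol A [ramp_protocol()].
#' @param path File path.
#' @return `write_ramp_protocol` returns `path` invisibly;
#'   `read_ramp_protocol` returns a `ramp_protocol`.
#' @export
write_ramp_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "ramp_protocol"))
  hdr <- c(sprintf("# rotor_radius_m: %.10g", protocol$rotor_radius),
           sprintf("# end_time_s: %.10g", protocol$end_time))
  if (!is.null(protocol$nominal_loading_rate))
    hdr <- c(hdr, sprintf("# nominal_loading_rate_pn_s: %.10g",
                          protocol$nominal_loading_rate))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(protocol$steps, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ramp_protocol
#' @export
read_ramp_protocol <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_num <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(m) == 0) return(NULL)
    as.numeric(sub(paste0("^# ", key, ":\\s*"), "", m[1]))
  }
  df <- read.csv(text = paste(grep("^#", lines, value = TRUE,
                                   invert = TRUE), collapse = "\n"))
  ramp_protocol(df$start_time_s, df$rpm,
                rotor_radius = get_num("rotor_radius_m") %||%
                  default_rotor_radius(),
                end_time = get_num("end_time_s"),
                nominal_loading_rate = get_num("nominal_loading_rate_pn_s"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
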