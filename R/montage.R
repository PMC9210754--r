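#' Sensor montage
#'
#' The full wearable montage carries an inertial measurement unit (triaxial
#' accelerometer + triaxial gyroscope) at seven body sites -- waist, left/right
#' thigh, left/right shank, left/right foot -- and six plantar force-sensing
#' resistors (FSR), three per insole. That is 7 x 2 x 3 + 6 = 48 channels.
#'
#' Channel names follow `<location>_<sensor>_<axis>` for IMU channels
#' (e.g. `left_shank_gyroscope_x`) and `<location>_fsr` for pressure channels
#' (FSRs are single-valued, they carry no axis).
#'
#' @return A data frame with one row per channel, columns `location`, `sensor`,
#'   `axis` (`"none"` for FSR channels) and `channel` (the channel name), in
#'   canonical montage order: IMU sites (accelerometer then gyroscope, axes
#'   x/y/z) followed by the six sole FSRs.
#' @examples
#' nrow(montage()) # 48
#' @export
montage <- function() {
  imu_locations <- c(
    "waist", "left_thigh", "right_thigh", "left_shank", "right_shank",
    "left_foot", "right_foot"
  )
  sole_locations <- c(
    paste0("left_sole_", 1:3),
    paste0("right_sole_", 1:3)
  )
  imu <- expand.grid(
    axis = c("x", "y", "z"),
    sensor = c("accelerometer", "gyroscope"),
    location = imu_locations,
    stringsAsFactors = FALSE
  )[, c("location", "sensor", "axis")]
  fsr <- data.frame(
    location = sole_locations,
    sensor = "fsr",
    axis = "none",
    stringsAsFactors = FALSE
  )
  out <- rbind(imu, fsr)
  out$channel <- ifelse(
    out$sensor == "fsr",
    paste(out$location, "fsr", sep = "_"),
    paste(out$location, out$sensor, out$axis, sep = "_")
  )
  out
}

#' Select channels by body site and sensor type
#'
#' @param locations Character vector of site names (see [montage()]); the
#'   shorthand `"left_sole"`/`"right_sole"` expands to the three FSRs of that
#'   insole.
#' @param sensors Sensor types to keep; defaults to all three.
#' @return Character vector of channel names in montage order.
#' @examples
#' channels_at("left_shank") # 6 IMU channels
#' channels_at("left_sole")  # 3 FSR channels
#' @export
channels_at <- function(locations,
                        sensors = c("accelerometer", "gyroscope", "fsr")) {
  m <- montage()
  locations <- unlist(lapply(locations, function(l) {
    if (l %in% c("left_sole", "right_sole")) paste0(l, "_", 1:3) else l
  }))
  unknown <- setdiff(locations, m$location)
  if (length(unknown) > 0) {
    stop("unknown sensor location(s): ", paste(unknown, collapse = ", "))
  }
  m$channel[m$location %in% locations & m$sensor %in% sensors]
}

#' Enumerate the sixteen single-sensor configurations
#'
#' One configuration per IMU per site (7 sites x accelerometer/gyroscope)
#' plus one per insole (the three FSRs of a sole act as one pressure sensor),
#' i.e. 16 configurations in total.
#'
#' @return Named list of channel-name vectors.
#' @export
single_sensor_subsets <- function() {
  m <- montage()
  imu_locations <- unique(m$location[m$sensor != "fsr"])
  out <- list()
  for (loc in imu_locations) {
    for (sen in c("accelerometer", "gyroscope")) {
      out[[paste(loc, sen, sep = "_")]] <- channels_at(loc, sen)
    }
  }
  out[["left_sole_pressure"]] <- channels_at("left_sole")
  out[["right_sole_pressure"]] <- channels_at("right_sole")
  out
}

# Resolve a user-facing channel specification into channel names.
# Accepts a character vector of channel names, a location shorthand
# (e.g. "left_shank" -> its 6 IMU channels), or a list of such.
resolve_channels <- function(spec) {
  m <- montage()
  if (is.list(spec)) spec <- unlist(spec, use.names = FALSE)
  stopifnot(is.character(spec), length(spec) > 0)
  out <- character(0)
  for (s in spec) {
    if (s == "all") {
      out <- c(out, m$channel)
    } else if (s %in% m$channel) {
      out <- c(out, s)
    } else if (s %in% c(m$location, "left_sole", "right_sole")) {
      out <- c(out, channels_at(s))
    } else {
      stop("unknown channel or location: ", s)
    }
  }
  m$channel[m$channel %in% out]
}
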