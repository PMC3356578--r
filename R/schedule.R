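#' Lighting schedules
#'
#' A `light_schedule` describes the lighting protocol of an experiment as an
#' ordered list of contiguous segments (each an LD, dim-LD, DD or LL block),
#' plus optional acute light pulses and step changes ("shift events", e.g. a
#' 6 h advance of the LD cycle). All times in the package are timezone-free
#' elapsed hours from the experiment start; day `d` spans hours
#' `[24*d, 24*(d+1))`, with day 0 beginning at the reference midnight.
#'
#' Photoperiod 0 encodes constant darkness (DD), 24 constant light (LL).
#' A positive `advance_h` in a shift event moves lights-on (and hence
#' lights-off) *earlier* by that many hours for all days from `day` onward.
#'
#' @param segments data.frame with columns `start_day` (integer, first is 0),
#'   `n_days` (integer; `NA` for an open-ended final segment), `lights_on`
#'   (clock hour of lights-on, in `[0,24)`), `photoperiod_h` (hours of light
#'   per day, in `[0,24]`) and `lux` (intensity label such as `"150 lux"`,
#'   `"30 lux"`, `"DD"`, `"LL"`).
#' @param pulses data.frame with columns `start_h` (absolute hours),
#'   `duration_min` (> 0) and `lux`, or `NULL`.
#' @param shifts data.frame with columns `day` and `advance_h` (signed hours,
#'   positive = advance), or `NULL`.
#' @return An object of class `light_schedule`.
#' @seealso [ld_schedule()], [is_light()], [zt_of()], [lights_off_time()]
#' @export
light_schedule <- function(segments, pulses = NULL, shifts = NULL) {
  segments <- as.data.frame(segments)
  req <- c("start_day", "n_days", "lights_on", "photoperiod_h", "lux")
  if (!all(req %in% names(segments)))
    stop("segments must have columns: ", paste(req, collapse = ", "))
  segments <- segments[order(segments$start_day), , drop = FALSE]
  if (nrow(segments) < 1L) stop("at least one segment is required")
  if (segments$start_day[1] != 0L) stop("first segment must start at day 0")
  n <- nrow(segments)
  if (any(is.na(segments$n_days[-n])))
    stop("only the final segment may be open-ended (n_days = NA)")
  if (n > 1L) {
    expected <- segments$start_day[-n] + segments$n_days[-n]
    if (any(expected != segments$start_day[-1]))
      stop("segments must be contiguous and non-overlapping")
  }
  if (any(segments$photoperiod_h < 0 | segments$photoperiod_h > 24))
    stop("photoperiod_h must lie in [0, 24]")
  if (any(segments$lights_on < 0 | segments$lights_on >= 24))
    stop("lights_on must lie in [0, 24)")
  if (!is.null(pulses)) {
    pulses <- as.data.frame(pulses)
    if (!all(c("start_h", "duration_min") %in% names(pulses)))
      stop("pulses must have columns start_h, duration_min")
    if (is.null(pulses$lux)) pulses$lux <- "pulse"
    if (any(pulses$duration_min <= 0)) stop("pulse durations must be > 0")
  }
  if (!is.null(shifts)) {
    shifts <- as.data.frame(shifts)
    if (!all(c("day", "advance_h") %in% names(shifts)))
      stop("shifts must have columns day, advance_h")
    shifts <- shifts[order(shifts$day), , drop = FALSE]
  }
  structure(list(segments = segments, pulses = pulses, shifts = shifts),
            class = "light_schedule")
}

#' Convenience constructors for common protocols
#'
#' `ld_schedule()` builds a single LD (or dim-LD) block; `dd_schedule()` and
#' `ll_schedule()` build constant-condition blocks, optionally preceded by
#' `ld_days` of entrainment so that a projected Zeitgeber Time exists.
#'
#' @param n_days length of the (final) block in days; `NA` = open-ended.
#' @param lights_on clock hour of lights-on (default 07:00).
#' @param photoperiod_h hours of light per day (default 12, i.e. 12:12 LD).
#' @param lux intensity label.
#' @param ld_days LD days preceding the constant block (0 for none).
#' @return A [light_schedule()].
#' @export
ld_schedule <- function(n_days = NA, lights_on = 7, photoperiod_h = 12,
                        lux = "150 lux") {
  light_schedule(data.frame(start_day = 0L, n_days = n_days,
                            lights_on = lights_on,
                            photoperiod_h = photoperiod_h, lux = lux))
}

#' @rdname ld_schedule
#' @export
dd_schedule <- function(n_days = NA, ld_days = 0L, lights_on = 7,
                        photoperiod_h = 12) {
  seg <- data.frame(start_day = 0L, n_days = n_days, lights_on = lights_on,
                    photoperiod_h = 0, lux = "DD")
  if (ld_days > 0L) {
    seg <- rbind(
      data.frame(start_day = 0L, n_days = as.integer(ld_days),
                 lights_on = lights_on, photoperiod_h = photoperiod_h,
                 lux = "150 lux"),
      data.frame(start_day = as.integer(ld_days), n_days = n_days,
                 lights_on = lights_on, photoperiod_h = 0, lux = "DD"))
  }
  light_schedule(seg)
}

#' @rdname ld_schedule
#' @export
ll_schedule <- function(n_days = NA, ld_days = 0L, lights_on = 7,
                        photoperiod_h = 12) {
  s <- dd_schedule(n_days = n_days, ld_days = ld_days, lights_on = lights_on,
                   photoperiod_h = photoperiod_h)
  i <- nrow(s$segments)
  s$segments$photoperiod_h[i] <- 24
  s$segments$lux[i] <- "LL"
  s
}

last_day <- function(schedule) {
  seg <- schedule$segments
  n <- nrow(seg)
  if (is.na(seg$n_days[n])) Inf else seg$start_day[n] + seg$n_days[n] - 1L
}

# Effective per-day lighting parameters after applying shift events.
day_info <- function(schedule, day) {
  day <- as.integer(floor(day))
  if (day < 0L || day > last_day(schedule))
    stop("day ", day, " is outside the schedule's covered timeline")
  seg <- schedule$segments
  i <- max(which(seg$start_day <= day))
  lights_on <- seg$lights_on[i]
  if (!is.null(schedule$shifts)) {
    adv <- sum(schedule$shifts$advance_h[schedule$shifts$day <= day])
    lights_on <- (lights_on - adv) %% 24
  }
  list(day = day, lights_on = lights_on, photoperiod_h = seg$photoperiod_h[i],
       lux = seg$lux[i],
       is_ld = seg$photoperiod_h[i] > 0 && seg$photoperiod_h[i] < 24)
}

in_pulse <- function(schedule, t) {
  p <- schedule$pulses
  if (is.null(p) || nrow(p) == 0L) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (k in seq_len(nrow(p)))
    out <- out | (t >= p$start_h[k] & t < p$start_h[k] + p$duration_min[k] / 60)
  out
}

#' Is it light at time t?
#'
#' Evaluates the lighting state (scheduled light or an acute pulse) at one or
#' more absolute times.
#'
#' @param schedule a [light_schedule()].
#' @param t absolute time(s), hours from experiment start.
#' @return Logical vector, `TRUE` where `t` falls in scheduled light or
#'   inside a light pulse.
#' @export
is_light <- function(schedule, t) {
  if (any(t < 0) || any(t >= 24 * (last_day(schedule) + 1)))
    stop("t outside the schedule's covered timeline")
  out <- vapply(t, function(ti) {
    info <- day_info(schedule, floor(ti / 24))
    if (info$photoperiod_h >= 24) return(TRUE)
    if (info$photoperiod_h <= 0) return(FALSE)
    rel <- ti - 24 * info$day
    ((rel - info$lights_on) %% 24) < info$photoperiod_h
  }, logical(1))
  out | in_pulse(schedule, t)
}

#' Zeitgeber Time of an absolute time
#'
#' ZT0 is lights-on; ZT increases modulo 24. Under DD or LL the ZT is
#' projected from the phase of the last preceding LD day and the result
#' carries `attr(, "projected") = TRUE`; if no LD day precedes `t` the ZT is
#' undefined and an error is raised.
#'
#' @inheritParams is_light
#' @return Numeric vector of ZT hours in `[0, 24)`; attribute `projected` is
#'   `TRUE` if any element required projection.
#' @export
zt_of <- function(schedule, t) {
  projected <- FALSE
  out <- vapply(t, function(ti) {
    day <- floor(ti / 24)
    info <- day_info(schedule, day)
    if (!info$is_ld) {
      while (day >= 0 && !day_info(schedule, day)$is_ld) day <- day - 1
      if (day < 0)
        stop("ZT undefined: no preceding LD segment to project from")
      info <- day_info(schedule, day)
      projected <<- TRUE
    }
    (ti - 24 * floor(ti / 24) - info$lights_on) %% 24
  }, numeric(1))
  if (projected) attr(out, "projected") <- TRUE
  out
}

#' Lights-on / lights-off instants of a day
#'
#' Absolute time (hours from experiment start) of the lights-on or lights-off
#' transition on a given LD day. `lights_off_time(day)` equals that day's
#' lights-on plus its photoperiod and may fall past the day's midnight (e.g.
#' 18:6 LD with lights-on 06:00 gives hour 24).
#'
#' @param schedule a [light_schedule()].
#' @param day integer day index (day 0 = first day).
#' @return Absolute time in hours.
#' @export
lights_off_time <- function(schedule, day) {
  vapply(day, function(d) {
    info <- day_info(schedule, d)
    if (!info$is_ld)
      stop("lights_off_time undefined on day ", d, " (", info$lux, ")")
    24 * info$day + info$lights_on + info$photoperiod_h
  }, numeric(1))
}

#' @rdname lights_off_time
#' @export
lights_on_time <- function(schedule, day) {
  vapply(day, function(d) {
    info <- day_info(schedule, d)
    if (!info$is_ld)
      stop("lights_on_time undefined on day ", d, " (", info$lux, ")")
    24 * info$day + info$lights_on
  }, numeric(1))
}

#' Read / write a schedule config file
#'
#' Schedules round-trip through a structured JSON or YAML file holding the
#' segment table and optional `pulses` and `shifts` lists; the format is
#' chosen from the file extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param path file path.
#' @param schedule a [light_schedule()].
#' @return `read_schedule()` returns a [light_schedule()];
#'   `write_schedule()` returns `path` invisibly.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("schedule file not found: ", path)
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  seg <- as.data.frame(x$segments)
  if (!is.null(seg$n_days)) seg$n_days[seg$n_days < 0] <- NA
  pulses <- if (!is.null(x$pulses) && length(x$pulses)) as.data.frame(x$pulses)
  shifts <- if (!is.null(x$shifts) && length(x$shifts)) as.data.frame(x$shifts)
  light_schedule(seg, pulses = pulses, shifts = shifts)
}

#' @rdname read_schedule
#' @export
write_schedule <- function(schedule, path) {
  seg <- schedule$segments
  seg$n_days[is.na(seg$n_days)] <- -1L   # JSON/YAML-safe open-ended marker
  x <- list(segments = seg)
  if (!is.null(schedule$pulses)) x$pulses <- schedule$pulses
  if (!is.null(schedule$shifts)) x$shifts <- schedule$shifts
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lapply(x, function(df) lapply(as.list(df), as.vector)),
                     path)
  } else {
    jsonlite::write_json(x, path, dataframe = "columns", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.light_schedule <- function(x, ...) {
  cat("<light_schedule>\n")
  seg <- x$segments
  for (i in seq_len(nrow(seg))) {
    nd <- if (is.na(seg$n_days[i])) "open-ended" else paste(seg$n_days[i], "days")
    cat(sprintf("  day %d+ (%s): %s, lights on %05.2f h, photoperiod %g h\n",
                seg$start_day[i], nd, seg$lux[i], seg$lights_on[i],
                seg$photoperiod_h[i]))
  }
  if (!is.null(x$pulses))
    cat(sprintf("  %d light pulse(s)\n", nrow(x$pulses)))
  if (!is.null(x$shifts))
    for (i in seq_len(nrow(x$shifts)))
      cat(sprintf("  shift on day %d: %+g h (positive = advance)\n",
                  x$shifts$day[i], x$shifts$advance_h[i]))
  invisible(x)
}
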