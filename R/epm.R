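# Elevated-plus-maze analysis: zone classification from head position,
# debounced arm-entry detection, per-epoch open-arm metrics, and the
# position-triggered latched stimulation gate.

#' Elevated-plus-maze geometry
#'
#' A plus maze centred on the origin: open arms along +x/-x, closed arms
#' along +y/-y, a square centre. Zones are disjoint rectangles (the arm
#' polygons start where the centre square ends).
#'
#' @param arm_length Arm length, cm (default 50).
#' @param arm_width Arm width and centre side, cm (default 10).
#' @return An `epm_geometry` object: named list of 4 x 2 polygon vertex
#'   matrices (`open1`, `open2`, `closed1`, `closed2`, `centre`) plus
#'   arm direction vectors and dimensions.
#' @export
epm_geometry <- function(arm_length = 50, arm_width = 10) {
  stopifnot(arm_length > 0, arm_width > 0)
  h <- arm_width / 2
  rect <- function(x1, x2, y1, y2) {
    cbind(x = c(x1, x2, x2, x1), y = c(y1, y1, y2, y2))
  }
  polys <- list(
    centre = rect(-h, h, -h, h),
    open1 = rect(h, h + arm_length, -h, h),
    open2 = rect(-h - arm_length, -h, -h, h),
    closed1 = rect(-h, h, h, h + arm_length),
    closed2 = rect(-h, h, -h - arm_length, -h))
  structure(list(polygons = polys,
                 arm_directions = list(open1 = c(1, 0), open2 = c(-1, 0),
                                       closed1 = c(0, 1), closed2 = c(0, -1)),
                 arm_length = arm_length, arm_width = arm_width,
                 centre_half = h),
            class = "epm_geometry")
}

# ray-casting point-in-polygon (boundary counts as inside on the
# lower/left edge; zones are disjoint so frames get exactly one label)
point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Classify maze zone per frame from head position
#'
#' Head-point-in-polygon test against the five maze zones. Position gaps
#' (NA coordinates) up to `gap_limit` seconds are linearly interpolated;
#' longer gaps, and frames outside every polygon, become `off_maze`.
#'
#' @param track Data frame with `t`, `x`, `y` (seconds, cm).
#' @param geometry An [epm_geometry()].
#' @param gap_limit Maximum interpolatable gap, s (default 0.5).
#' @return Data frame `t`, `zone` (`open`, `closed`, `centre`,
#'   `off_maze`), `zone_detail` (arm identity).
#' @export
classify_zone <- function(track, geometry = epm_geometry(),
                          gap_limit = 0.5) {
  stopifnot(all(c("t", "x", "y") %in% names(track)),
            inherits(geometry, "epm_geometry"))
  x <- track$x; y <- track$y; t <- track$t
  na <- !is.finite(x) | !is.finite(y)
  long_gap <- logical(length(x))
  if (any(na) && any(!na)) {
    runs <- rle(na)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      gap_s <- t[min(ends[r] + 1L, length(t))] -
        t[max(starts[r] - 1L, 1L)]
      if (starts[r] > 1 && ends[r] < length(t) && gap_s <= gap_limit) next
      long_gap[starts[r]:ends[r]] <- TRUE
    }
    x <- stats::approx(t[!na], x[!na], xout = t, rule = 2)$y
    y <- stats::approx(t[!na], y[!na], xout = t, rule = 2)$y
  }
  detail <- rep("off_maze", length(x))
  for (nm in names(geometry$polygons)) {
    hit <- point_in_poly(x, y, geometry$polygons[[nm]])
    detail[hit & detail == "off_maze"] <- nm
  }
  detail[long_gap] <- "off_maze"
  zone <- zone_class_of_state(detail)
  data.frame(t = t, zone = zone, zone_detail = detail,
             stringsAsFactors = FALSE)
}

#' Detect debounced arm entries and arm-end events
#'
#' An entry event is placed at the first frame of each maximal run in an
#' arm zone lasting at least `debounce` seconds (brief flickers are
#' ignored). Within each qualifying visit an `arm_end_reached` event
#' marks the frame of maximum distance from the maze centre.
#'
#' @param zones Output of [classify_zone()].
#' @param track Optional track data frame (`x`, `y`) for arm-end
#'   distances; omit to skip arm-end events.
#' @param debounce Minimum visit duration, s (default 0.5).
#' @return An [event_table()] with `open_entry`, `closed_entry` and
#'   (when `track` given) `arm_end_reached` rows.
#' @export
detect_arm_entries <- function(zones, track = NULL, debounce = 0.5) {
  stopifnot(all(c("t", "zone") %in% names(zones)))
  if (!nrow(zones)) return(event_table(numeric(0), character(0)))
  z <- zones$zone
  t <- zones$t
  runs <- rle(z)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  ev_t <- numeric(0); ev_type <- character(0)
  for (r in seq_along(runs$values)) {
    if (!runs$values[r] %in% c("open", "closed")) next
    i1 <- starts[r]; i2 <- ends[r]
    dur <- t[min(i2 + 1L, length(t))] - t[i1]
    if (dur < debounce) next
    ev_t <- c(ev_t, t[i1])
    ev_type <- c(ev_type, paste0(runs$values[r], "_entry"))
    if (!is.null(track)) {
      d <- sqrt(track$x[i1:i2]^2 + track$y[i1:i2]^2)
      ev_t <- c(ev_t, t[i1 - 1L + which.max(d)])
      ev_type <- c(ev_type, "arm_end_reached")
    }
  }
  if (!length(ev_t)) return(event_table(numeric(0), character(0)))
  event_table(ev_t, ev_type)
}

default_epochs <- function(session_duration = 540, n = 3) {
  w <- session_duration / n
  lapply(seq_len(n) - 1, function(i) c(i * w, (i + 1) * w))
}

epoch_of <- function(t, epochs) {
  out <- rep(NA_integer_, length(t))
  for (i in seq_along(epochs)) {
    out[t >= epochs[[i]][1] & t < epochs[[i]][2]] <- i
  }
  # closing edge of the final epoch belongs to it
  out[t == epochs[[length(epochs)]][2]] <- length(epochs)
  out
}

#' Open-arm time per session epoch
#'
#' Sums open-zone dwell time within each epoch (default three 3-min
#' epochs tiling a 9-min session). Each frame contributes the interval
#' to the next frame.
#'
#' @param zones Output of [classify_zone()].
#' @param epochs List of `c(start, end)` second pairs tiling the
#'   session.
#' @return Numeric vector of seconds per epoch.
#' @export
open_arm_time_per_epoch <- function(zones, epochs = default_epochs()) {
  stopifnot(all(c("t", "zone") %in% names(zones)))
  t <- zones$t
  dt <- diff(t)
  dt <- c(dt, stats::median(dt))
  ep <- epoch_of(t, epochs)
  vapply(seq_along(epochs), function(i) {
    sum(dt[which(ep == i & zones$zone == "open")])
  }, numeric(1))
}

#' Per-epoch probability of entering the open arms
#'
#' Open entries divided by all arm entries (open + closed) within each
#' epoch; `NaN` (flagged) when the epoch has no arm entries.
#'
#' @param events An [event_table()].
#' @param epochs List of `c(start, end)` pairs.
#' @return Numeric vector, one probability per epoch.
#' @export
entry_probability <- function(events, epochs = default_epochs()) {
  is_entry <- events$type %in% c("open_entry", "closed_entry")
  ep <- epoch_of(events$time, epochs)
  vapply(seq_along(epochs), function(i) {
    sel <- is_entry & ep == i & !is.na(ep)
    n <- sum(sel)
    if (n == 0) return(NaN)
    sum(events$type[sel] == "open_entry") / n
  }, numeric(1))
}

#' Closed-loop stimulation gate
#'
#' Within the designated stimulation epoch the light turns on when the
#' mouse is in the centre or an open arm and latches on until the first
#' closed-arm frame (or the epoch/session ends). Outside the epoch the
#' light is always off. The `"constant"` variant delivers light during
#' the whole stimulation epoch irrespective of position.
#'
#' @param zones Output of [classify_zone()].
#' @param epochs List of `c(start, end)` pairs (default three 3-min
#'   epochs).
#' @param stim_epoch Index of the stimulation epoch (default 2); `NA`
#'   yields an all-off trace.
#' @param mode `"latched"` (default) or `"constant"`.
#' @param frequency_hz Stimulation frequency metadata (default 20).
#' @return A `gate_trace`: data frame `t`, `on`; attributes carry the
#'   trigger log (on/off times with reasons) and the frequency.
#' @export
closed_loop_gate <- function(zones, epochs = default_epochs(),
                             stim_epoch = 2,
                             mode = c("latched", "constant"),
                             frequency_hz = 20) {
  mode <- match.arg(mode)
  stopifnot(all(c("t", "zone") %in% names(zones)))
  t <- zones$t
  n <- length(t)
  on <- logical(n)
  log <- data.frame(time = numeric(0), action = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  if (!is.na(stim_epoch)) {
    in_epoch <- epoch_of(t, epochs) == stim_epoch
    in_epoch[is.na(in_epoch)] <- FALSE
    if (mode == "constant") {
      on <- in_epoch
      if (any(in_epoch)) {
        log <- rbind(log,
          data.frame(time = t[which(in_epoch)[1]], action = "on",
                     reason = "epoch start (constant)"),
          data.frame(time = t[max(which(in_epoch))], action = "off",
                     reason = "epoch end (constant)"))
      }
    } else {
      latched <- FALSE
      for (i in seq_len(n)) {
        if (!in_epoch[i]) {
          if (latched) {
            latched <- FALSE
            log <- rbind(log, data.frame(time = t[i], action = "off",
                                         reason = "epoch end"))
          }
          next
        }
        z <- zones$zone[i]
        if (!latched && z %in% c("centre", "open")) {
          latched <- TRUE
          log <- rbind(log, data.frame(time = t[i], action = "on",
                                       reason = paste0(z, " trigger")))
        } else if (latched && z == "closed") {
          latched <- FALSE
          log <- rbind(log, data.frame(time = t[i], action = "off",
                                       reason = "closed-arm entry"))
        }
        on[i] <- latched
      }
      if (latched) {
        log <- rbind(log, data.frame(time = t[n], action = "off",
                                     reason = "session end"))
      }
    }
  }
  out <- data.frame(t = t, on = on)
  attr(out, "trigger_log") <- log
  attr(out, "frequency_hz") <- frequency_hz
  attr(out, "mode") <- mode
  class(out) <- c("gate_trace", "data.frame")
  out
}
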