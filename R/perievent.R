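# Event-aligned epoch extraction and window statistics: 12 s epochs
# around behavioural events, baseline subtraction, bl/pre/post window
# means, superficial-minus-deep difference scores, ordinal entry splits,
# 20 s long epochs, and the Holm-Sidak step-down correction.

#' Peri-event analysis window specification
#'
#' Defaults follow the behavioural-photometry analysis: baseline (-6, -4) s,
#' pre (-2, 0) s, and event-type-specific post windows — (2, 4) s for
#' open-arm entry, (0, 4) s for closed-arm entry, (2, 4) s for all other
#' events. All windows are half-open `[start, end)`.
#'
#' @param bl Baseline window, s relative to the event.
#' @param pre Pre-event window.
#' @param post Named list of post windows per event type plus an
#'   `other` fallback.
#' @return A `window_spec` list.
#' @export
window_spec <- function(bl = c(-6, -4), pre = c(-2, 0),
                        post = list(open_entry = c(2, 4),
                                    closed_entry = c(0, 4),
                                    other = c(2, 4))) {
  stopifnot(bl[1] < bl[2], pre[1] < pre[2], bl[2] <= pre[1])
  for (w in post) stopifnot(length(w) == 2, w[1] < w[2])
  structure(list(bl = bl, pre = pre, post = post), class = "window_spec")
}

post_window_for <- function(spec, event_type) {
  if (event_type %in% names(spec$post)) return(spec$post[[event_type]])
  if (!event_type %in% known_event_types) {
    stop("unknown event type: ", event_type)
  }
  spec$post$other
}

window_cols <- function(tensor, window) {
  rel_t <- tensor$window[1] + (seq_len(ncol(tensor$epochs)) - 1) / tensor$fs
  which(rel_t >= window[1] & rel_t < window[2])
}

#' Extract event-aligned epochs from a trace
#'
#' Cuts half-open windows `[t + start, t + end)` around each event.
#' Events whose window would read outside the recording are dropped and
#' logged in `$dropped`.
#'
#' @param trace A [conditioned_trace()].
#' @param events An [event_table()] (or data frame with `time`, `type`).
#' @param window `c(start, end)` seconds relative to the event;
#'   `start < 0 < end`. Default the 12 s epoch `c(-6, 6)`.
#' @param fs Expected sampling rate; must match the trace.
#' @return A `perievent_tensor`: `epochs` (event x time matrix),
#'   `window`, `fs`, `events` (kept rows), `dropped` (with reasons),
#'   `baseline_subtracted` flag.
#' @export
extract_epochs <- function(trace, events, window = c(-6, 6),
                           fs = trace$fs) {
  stopifnot(inherits(trace, "conditioned_trace"),
            window[1] < 0, window[2] > 0)
  if (abs(fs - trace$fs) > 1e-9) {
    stop("requested fs does not match the trace")
  }
  n_samp <- round((window[2] - window[1]) * fs)
  n <- length(trace$values)
  keep <- logical(nrow(events)); reason <- character(nrow(events))
  starts <- integer(nrow(events))
  for (i in seq_len(nrow(events))) {
    i0 <- round((events$time[i] + window[1] - trace$start_time) * fs) + 1L
    if (i0 < 1) {
      reason[i] <- "window precedes recording start"
    } else if (i0 + n_samp - 1L > n) {
      reason[i] <- "window exceeds recording end"
    } else {
      keep[i] <- TRUE
      starts[i] <- i0
    }
  }
  epochs <- matrix(NA_real_, sum(keep), n_samp)
  ki <- which(keep)
  for (j in seq_along(ki)) {
    epochs[j, ] <- trace$values[starts[ki[j]]:(starts[ki[j]] + n_samp - 1L)]
  }
  dropped <- events[!keep, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- reason[!keep]
  structure(list(epochs = epochs, window = window, fs = fs,
                 events = events[keep, , drop = FALSE], dropped = dropped,
                 baseline_subtracted = FALSE, bl_window = NULL),
            class = "perievent_tensor")
}

#' Subtract the per-epoch baseline-window mean
#'
#' @param tensor A `perievent_tensor`.
#' @param bl_window Baseline window, s relative to the event; must lie
#'   inside the tensor window.
#' @return The tensor with each row recentred so its baseline-window
#'   mean is 0.
#' @export
baseline_subtract <- function(tensor, bl_window = c(-6, -4)) {
  stopifnot(inherits(tensor, "perievent_tensor"))
  if (bl_window[1] < tensor$window[1] || bl_window[2] > tensor$window[2]) {
    stop("baseline window outside the epoch window")
  }
  cols <- window_cols(tensor, bl_window)
  if (!length(cols)) stop("baseline window contains no samples")
  if (nrow(tensor$epochs)) {
    bl_means <- rowMeans(tensor$epochs[, cols, drop = FALSE])
    tensor$epochs <- tensor$epochs - bl_means
  }
  tensor$baseline_subtracted <- TRUE
  tensor$bl_window <- bl_window
  tensor
}

#' Baseline / pre / post window means per event and per animal
#'
#' The post window is chosen by event type per the [window_spec()].
#' Animal-level values are means of that animal's event means (all
#' events belong to one animal when no `animal` column is present).
#'
#' @param tensor A baseline-subtracted `perievent_tensor`.
#' @param spec A [window_spec()].
#' @param event_type Event type the tensor is aligned to.
#' @return List with `per_event` (data frame: event index, bl, pre,
#'   post) and `per_animal`.
#' @export
window_stats <- function(tensor, spec = window_spec(),
                         event_type = "open_entry") {
  stopifnot(inherits(tensor, "perievent_tensor"),
            inherits(spec, "window_spec"))
  if (!isTRUE(tensor$baseline_subtracted)) {
    stop("window_stats expects a baseline-subtracted tensor")
  }
  post_w <- post_window_for(spec, event_type)
  rows <- nrow(tensor$epochs)
  per_event <- data.frame(
    event = seq_len(rows),
    bl = if (rows) rowMeans(tensor$epochs[, window_cols(tensor, spec$bl),
                                          drop = FALSE]) else numeric(0),
    pre = if (rows) rowMeans(tensor$epochs[, window_cols(tensor, spec$pre),
                                           drop = FALSE]) else numeric(0),
    post = if (rows) rowMeans(tensor$epochs[, window_cols(tensor, post_w),
                                            drop = FALSE]) else numeric(0))
  animal <- if ("animal" %in% names(tensor$events)) {
    as.character(tensor$events$animal)
  } else rep("animal1", rows)
  per_event$animal <- animal
  per_animal <- do.call(rbind, lapply(split(per_event, per_event$animal),
    function(d) data.frame(animal = d$animal[1], n_events = nrow(d),
                           bl = mean(d$bl), pre = mean(d$pre),
                           post = mean(d$post))))
  rownames(per_animal) <- NULL
  list(per_event = per_event, per_animal = per_animal,
       windows = list(bl = spec$bl, pre = spec$pre, post = post_w))
}

#' Superficial-minus-deep difference time course and window means
#'
#' Positive values indicate a bias towards superficial-layer activity.
#'
#' @param sup_tensor,deep_tensor `perievent_tensor`s aligned to the
#'   identical event set.
#' @param spec A [window_spec()].
#' @param event_type Event type for the post window.
#' @return List with `tensor` (the element-wise difference), and
#'   `per_event` pre/post difference means.
#' @export
layer_difference <- function(sup_tensor, deep_tensor, spec = window_spec(),
                             event_type = "open_entry") {
  stopifnot(inherits(sup_tensor, "perievent_tensor"),
            inherits(deep_tensor, "perievent_tensor"))
  same <- nrow(sup_tensor$events) == nrow(deep_tensor$events) &&
    isTRUE(all.equal(sup_tensor$events$time, deep_tensor$events$time)) &&
    identical(dim(sup_tensor$epochs), dim(deep_tensor$epochs)) &&
    isTRUE(all.equal(sup_tensor$window, deep_tensor$window))
  if (!same) stop("tensors must be aligned to identical events and windows")
  diff_tensor <- sup_tensor
  diff_tensor$epochs <- sup_tensor$epochs - deep_tensor$epochs
  post_w <- post_window_for(spec, event_type)
  rows <- nrow(diff_tensor$epochs)
  per_event <- data.frame(
    event = seq_len(rows),
    pre = if (rows) rowMeans(diff_tensor$epochs[, window_cols(diff_tensor, spec$pre),
                                                drop = FALSE]) else numeric(0),
    post = if (rows) rowMeans(diff_tensor$epochs[, window_cols(diff_tensor, post_w),
                                                 drop = FALSE]) else numeric(0))
  list(tensor = diff_tensor, per_event = per_event)
}

#' Split events of a type into first / middle / last
#'
#' `middle` is every entry bar the first and last. A session with a
#' single event has `first == last`, an empty `middle`, and is flagged
#' for exclusion (matching the treatment of animals entering the open
#' arms only once).
#'
#' @param events An [event_table()].
#' @param type Event type to split (default `"open_entry"`).
#' @return List with `first`, `middle`, `last` (row indices into
#'   `events`) and `excluded` flag.
#' @export
ordinal_split <- function(events, type = "open_entry") {
  idx <- which(events$type == type)
  if (length(idx) == 0) {
    return(list(first = integer(0), middle = integer(0), last = integer(0),
                excluded = FALSE))
  }
  idx <- idx[order(events$time[idx])]
  n <- length(idx)
  list(first = idx[1],
       middle = if (n > 2) idx[2:(n - 1)] else integer(0),
       last = idx[n],
       excluded = n == 1)
}

#' Extract baseline-subtracted 20 s long epochs
#'
#' Convenience composition of [extract_epochs()] and
#' [baseline_subtract()] with the long-epoch parameters: window
#' (-10, 10) s, baseline (-10, -8) s.
#'
#' @inheritParams extract_epochs
#' @param window Epoch window (default `c(-10, 10)`).
#' @param bl Baseline window (default `c(-10, -8)`).
#' @return A baseline-subtracted `perievent_tensor`.
#' @export
long_epochs <- function(trace, events, window = c(-10, 10),
                        bl = c(-10, -8)) {
  baseline_subtract(extract_epochs(trace, events, window), bl)
}

#' Holm-Sidak step-down multiple-comparison correction
#'
#' Sorts the p-values ascending and sets
#' `adj_(i) = max_(j <= i) 1 - (1 - p_(j))^(m - j + 1)`, clipped to 1,
#' returned in the original order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' holm_sidak(c(0.01, 0.04))  # 0.0199, 0.04
holm_sidak <- function(pvalues) {
  stopifnot(is.numeric(pvalues), all(is.finite(pvalues)))
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  o <- order(pvalues)
  p_sorted <- pvalues[o]
  adj <- 1 - (1 - p_sorted)^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
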