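# Raw GPS fixes -> analysis-ready steps: complete-trip segmentation
# (same-day colony departure and return), even-interval rediscretization
# by linear interpolation in time, and step-length / turning-angle
# computation.

#' Segment complete foraging trips
#'
#' A trip is a maximal run of fixes outside the colony radius, extended
#' to include the last inside fix before departure and the first inside
#' fix at return. Trips are kept only when all their fixes fall on the
#' same calendar day (departure and return to the colony within the same
#' day); incomplete runs (no return, or spanning midnight) are discarded
#' and counted.
#'
#' @param traj data.frame with columns `bird_id`, `timestamp`
#'   (POSIXct), `x`, `y`; strictly increasing timestamps per bird.
#' @param colony_xy length-2 colony coordinates (m).
#' @param colony_radius on-colony radius (m); default 500.
#' @param tz timezone used to evaluate the calendar day.
#' @return list of trip data.frames (each with attribute `trip_id`),
#'   with attribute `n_dropped` counting discarded runs.
#' @export
segment_trips <- function(traj, colony_xy, colony_radius = 500,
                          tz = "UTC") {
  if (colony_radius <= 0) stop("colony_radius must be > 0")
  if (nrow(traj) == 0L)
    return(structure(list(), n_dropped = 0L))
  trips <- list()
  n_dropped <- 0L
  for (b in unique(traj$bird_id)) {
    tb <- traj[traj$bird_id == b, , drop = FALSE]
    tb <- tb[order(tb$timestamp), , drop = FALSE]
    if (any(diff(as.numeric(tb$timestamp)) <= 0))
      stop("timestamps must be strictly increasing within bird ", b)
    outside <- sqrt((tb$x - colony_xy[1])^2 +
                      (tb$y - colony_xy[2])^2) > colony_radius
    r <- rle(outside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      s <- starts[k] - 1L          # last inside fix before departure
      e <- ends[k] + 1L            # first inside fix at return
      if (s < 1L || e > nrow(tb)) { n_dropped <- n_dropped + 1L; next }
      seg <- tb[s:e, , drop = FALSE]
      days <- as.Date(seg$timestamp, tz = tz)
      if (length(unique(days)) > 1L) { n_dropped <- n_dropped + 1L; next }
      trip <- seg
      attr(trip, "trip_id") <- sprintf("%s_%s_%02d", b,
                                       format(days[1], "%Y%m%d"),
                                       length(trips) + 1L)
      trips[[length(trips) + 1L]] <- trip
    }
  }
  structure(trips, n_dropped = n_dropped)
}

#' Rediscretize a trip to an even time interval
#'
#' Positions at `t0, t0 + dt, t0 + 2 dt, ...` by linear interpolation
#' along the recorded path in time. Gaps longer than `max_gap` split the
#' trip into separately interpolated segments (with a warning).
#'
#' @param trip data.frame with `timestamp`, `x`, `y` (and any id
#'   columns, carried from the first fix).
#' @param dt target interval (s); default 900 (15 min).
#' @param max_gap largest bridgeable gap (s); default 3600.
#' @return list of rediscretized trip data.frames (length 1 unless the
#'   trip was split).
#' @export
rediscretize <- function(trip, dt = 900, max_gap = 3600) {
  if (nrow(trip) < 2L) stop("need at least 2 fixes")
  tnum <- as.numeric(trip$timestamp)
  gaps <- diff(tnum)
  seg_id <- cumsum(c(0, gaps > max_gap))
  if (max(seg_id) > 0)
    warning(sprintf("%d gap(s) exceed max_gap; trip split", max(seg_id)))
  out <- list()
  for (s in unique(seg_id)) {
    idx <- which(seg_id == s)
    if (length(idx) < 2L) next
    tt <- tnum[idx]
    grid <- seq(tt[1], tt[length(tt)], by = dt)
    xi <- stats::approx(tt, trip$x[idx], xout = grid)$y
    yi <- stats::approx(tt, trip$y[idx], xout = grid)$y
    seg <- trip[rep(idx[1], length(grid)), , drop = FALSE]
    seg$timestamp <- as.POSIXct(grid, tz = "UTC",
                                origin = "1970-01-01")
    seg$x <- xi
    seg$y <- yi
    rownames(seg) <- NULL
    attr(seg, "trip_id") <- paste0(attr(trip, "trip_id"),
                                   if (max(seg_id) > 0)
                                     paste0("_s", s + 1) else "")
    out[[length(out) + 1L]] <- seg
  }
  out
}

#' Steps and turning angles
#'
#' Euclidean step lengths between consecutive fixes and signed angular
#' change between consecutive headings, wrapped to `(-pi, pi]`
#' (counter-clockwise positive). The first step of each trip has an
#' undefined turn; zero-length steps have undefined heading, so the
#' following turn is also undefined.
#'
#' @param trips list of trip data.frames (as returned by
#'   [segment_trips()] / [rediscretize()], or any data.frame with
#'   `bird_id`, `timestamp`, `x`, `y`).
#' @return data.frame with one row per step: `bird_id`, `trip_id`,
#'   `stratum` (unique id), `timestamp` (step start), `x1,y1,x2,y2`,
#'   `sl`, `heading`, `turn`.
#' @export
steps_and_turns <- function(trips) {
  if (is.data.frame(trips)) trips <- list(trips)
  out <- list()
  for (trip in trips) {
    n <- nrow(trip)
    if (n < 2L) next
    dx <- diff(trip$x); dy <- diff(trip$y)
    sl <- sqrt(dx^2 + dy^2)
    heading <- ifelse(sl > 0, atan2(dy, dx), NA_real_)
    turn <- c(NA_real_, wrap_angle(diff(heading)))
    tid <- attr(trip, "trip_id")
    if (is.null(tid)) tid <- "trip1"
    out[[length(out) + 1L]] <-
      data.frame(bird_id = if ("bird_id" %in% names(trip))
        trip$bird_id[-n] else "bird1",
        trip_id = tid,
        timestamp = trip$timestamp[-n],
        x1 = trip$x[-n], y1 = trip$y[-n],
        x2 = trip$x[-1], y2 = trip$y[-1],
        sl = sl, heading = heading, turn = turn)
  }
  if (!length(out))
    return(data.frame(bird_id = character(), trip_id = character(),
                      timestamp = as.POSIXct(character()),
                      x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric(), sl = numeric(),
                      heading = numeric(), turn = numeric(),
                      stratum = integer()))
  steps <- do.call(rbind, out)
  steps$stratum <- seq_len(nrow(steps))
  rownames(steps) <- NULL
  steps
}
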