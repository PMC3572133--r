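# Exact stochastic simulation (direct-method SSA) of motor trajectories on
# a chemomechanical network, and extraction of classified dwell times.

#' Simulate a stepping trajectory
#'
#' Statistically exact realization of the network dynamics: exponential
#' waiting in each state, next transition drawn proportional to its rate.
#' The inner loop is compiled; R's RNG drives the draws, so the seed makes
#' runs fully reproducible.  Exactly one of \code{n_events}, \code{t_max} or
#' \code{n_steps} (mechanical events) bounds the run; the others may be left
#' infinite.
#'
#' @param net a \code{\link{motor_network}}.
#' @param cond a \code{\link{condition}}.
#' @param fm a \code{\link{force_model}}.
#' @param n_events stop after this many events (chemical + mechanical).
#' @param t_max stop at this simulated time (s).
#' @param n_steps stop after this many mechanical events.
#' @param seed integer seed (mandatory: reproducibility is part of the
#'   trajectory's identity).
#' @param init_state initial state label (default \code{"DD"}, the
#'   both-heads-ADP dwell state).
#' @param record \code{"all"} events, or \code{"mechanical"} only --- the
#'   memory-flat choice for long dwell-collection runs, sufficient for
#'   dwell extraction and position traces.
#' @return An object of class \code{motor_trajectory}: data frame
#'   \code{events} (time, transition index, offset), the position trace is
#'   available via \code{\link{trajectory_positions}}; metadata in
#'   attributes.
#' @examples
#' traj <- simulate_motor(build_unicycle(), condition(atp = 1000),
#'                        n_steps = 100, seed = 1)
#' @export
simulate_motor <- function(net, cond, fm = force_model(),
                           n_events = Inf, t_max = Inf, n_steps = Inf,
                           seed, init_state = "DD",
                           record = c("all", "mechanical")) {
  record <- match.arg(record)
  if (missing(seed)) stop("a seed is mandatory for simulation")
  if (!is.finite(n_events) && !is.finite(t_max) && !is.finite(n_steps))
    stop("one of n_events, t_max, n_steps must be finite")
  tr <- net$transitions
  rates <- transition_rates_at(net, cond, fm)
  init <- match(init_state, net$states)
  if (is.na(init)) stop("unknown initial state '", init_state, "'")
  set.seed(seed)
  res <- ssa_run_cpp(length(net$states),
                     match(tr$from, net$states) - 1L,
                     match(tr$to, net$states) - 1L,
                     rates, tr$offset,
                     init - 1L,
                     as.numeric(n_events), as.numeric(t_max),
                     as.numeric(n_steps), record == "all")
  events <- data.frame(time = res$time, transition = res$transition,
                       offset = res$offset)
  structure(list(events = events,
                 final_state = net$states[res$final_state],
                 final_time = res$final_time,
                 n_events = res$n_events,
                 absorbed = res$absorbed,
                 record = record,
                 network_id = net$id, condition = cond, force_model = fm,
                 seed = seed, init_state = init_state,
                 step_size = fm$step_size),
            class = "motor_trajectory")
}

#' @export
#' @method print motor_trajectory
print.motor_trajectory <- function(x, ...) {
  nmech <- sum(x$events$offset != 0)
  cat(sprintf("Motor trajectory ('%s', seed %d): %d events (%d steps), %.4g s\n",
              x$network_id, x$seed, nrow(x$events), nmech, x$final_time))
  if (x$absorbed) cat("  note: trajectory absorbed (zero total exit rate)\n")
  invisible(x)
}

#' Position trace of a trajectory
#'
#' Position changes only at mechanical events, by exactly one step size.
#'
#' @param traj a \code{motor_trajectory}.
#' @return data frame \code{t_s}, \code{position_nm}, starting at (0, 0).
#' @export
trajectory_positions <- function(traj) {
  ev <- traj$events[traj$events$offset != 0L, ]
  data.frame(t_s = c(0, ev$time),
             position_nm = c(0, cumsum(ev$offset) * traj$step_size))
}

#' @export
#' @method plot motor_trajectory
plot.motor_trajectory <- function(x, ...) {
  pos <- trajectory_positions(x)
  graphics::plot(pos$t_s, pos$position_nm, type = "s", xlab = "time (s)",
                 ylab = "position (nm)", main = "Stepping trajectory", ...)
  invisible(x)
}

#' Extract classified dwell times from a trajectory
#'
#' A dwell is the interval between two successive mechanical events; the
#' partial intervals before the first and after the last step are discarded.
#' Each record keeps the direction of the step that started the dwell
#' (\code{prev}) and the one that ended it (\code{next}).
#'
#' @param traj a \code{motor_trajectory}.
#' @return An object of class \code{dwell_sample}: data frame with columns
#'   \code{dwell_s}, \code{prev}, \code{next} (\code{"f"}/\code{"b"});
#'   condition, seed and network id in attributes.  Fewer than two
#'   mechanical events give an empty sample with a warning.
#' @examples
#' traj <- simulate_motor(build_unicycle(), condition(atp = 1000),
#'                        n_steps = 50, seed = 1)
#' dw <- extract_dwells(traj)
#' @export
extract_dwells <- function(traj) {
  ev <- traj$events[traj$events$offset != 0L, ]
  if (nrow(ev) < 2) {
    warning("fewer than 2 mechanical events: empty dwell sample")
    return(dwell_sample(numeric(0), character(0), character(0),
                        condition = traj$condition, seed = traj$seed,
                        network_id = traj$network_id))
  }
  dir <- ifelse(ev$offset > 0, "f", "b")
  n <- nrow(ev)
  dwell_sample(diff(ev$time), dir[-n], dir[-1],
               condition = traj$condition, seed = traj$seed,
               network_id = traj$network_id)
}

#' Construct a dwell sample
#'
#' @param dwell_s dwell durations (s), all > 0.
#' @param prev,nxt step direction starting / ending each dwell ("f"/"b").
#' @param condition,seed,network_id provenance metadata.
#' @return a \code{dwell_sample} data frame.
#' @export
dwell_sample <- function(dwell_s, prev, nxt, condition = NULL, seed = NULL,
                         network_id = NULL) {
  if (any(dwell_s <= 0)) stop("dwell times must be > 0")
  if (!all(prev %in% c("f", "b")) || !all(nxt %in% c("f", "b")))
    stop("step directions must be 'f' or 'b'")
  out <- data.frame(dwell_s = dwell_s, prev = prev, nxt, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[3] <- "next"
  attr(out, "condition") <- condition
  attr(out, "seed") <- seed
  attr(out, "network_id") <- network_id
  class(out) <- c("dwell_sample", "data.frame")
  out
}

#' Bin a dwell sample into an area-normalized histogram
#'
#' Dwells shorter than the detection dead time are discarded (finite
#' experimental resolution); uniform bins start at 0 and the density is
#' normalized so the histogram area is 1 over the retained sample.  When a
#' fixed edge vector is supplied (to match an observed histogram), dwells
#' beyond the last edge still count in the normalization, so lost tail mass
#' shows up as reduced density rather than being silently renormalized.
#'
#' @param x a \code{dwell_sample} or numeric vector of dwell times (s).
#' @param bin_width bin width (s); ignored when \code{edges} is given.
#' @param dead_time detection dead time (s); dwells below it are dropped.
#' @param edges optional uniform bin-edge vector starting at 0.
#' @return An object of class \code{dwell_histogram}: data frame
#'   \code{t_lo}, \code{t_hi}, \code{density} with attributes
#'   \code{bin_width}, \code{n} (retained dwells), \code{overflow}
#'   (fraction beyond the last edge).
#' @examples
#' h <- dwell_histogram(c(0.1, 0.2, 0.25, 0.7), bin_width = 0.2)
#' sum(h$density * attr(h, "bin_width"))   # area 1
#' @export
dwell_histogram <- function(x, bin_width = NULL, dead_time = 0, edges = NULL) {
  dw <- if (is.data.frame(x)) x$dwell_s else x
  dw <- dw[dw >= dead_time]
  if (!length(dw))
    stop("no dwells remain after dead-time filtering")
  if (is.null(edges)) {
    if (is.null(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
    edges <- seq(0, by = bin_width, length.out = ceiling(max(dw) / bin_width) + 1)
    if (max(dw) >= edges[length(edges)])
      edges <- c(edges, edges[length(edges)] + bin_width)
  } else {
    if (edges[1] != 0) stop("bin edges must start at 0")
    widths <- diff(edges)
    if (any(abs(widths - widths[1]) > 1e-9 * widths[1]))
      stop("bin edges must be uniform")
    bin_width <- widths[1]
  }
  n_total <- length(dw)
  inside <- dw < edges[length(edges)]
  counts <- if (any(inside))
    tabulate(findInterval(dw[inside], edges, rightmost.closed = FALSE),
             nbins = length(edges) - 1)
  else numeric(length(edges) - 1)
  density <- counts / (n_total * bin_width)
  out <- data.frame(t_lo = edges[-length(edges)], t_hi = edges[-1],
                    density = density)
  attr(out, "bin_width") <- bin_width
  attr(out, "n") <- n_total
  attr(out, "dead_time") <- dead_time
  attr(out, "overflow") <- 1 - sum(inside) / n_total
  class(out) <- c("dwell_histogram", "data.frame")
  out
}

#' @export
#' @method print dwell_histogram
print.dwell_histogram <- function(x, ...) {
  cat(sprintf("Dwell-time histogram: %d bins of %g s, n = %d, area = %.6g\n",
              nrow(x), attr(x, "bin_width"), attr(x, "n"),
              sum(x$density) * attr(x, "bin_width")))
  invisible(x)
}

#' @export
#' @method plot dwell_histogram
plot.dwell_histogram <- function(x, ...) {
  graphics::plot(NA, xlim = range(c(x$t_lo, x$t_hi)),
                 ylim = c(0, max(x$density) * 1.05),
                 xlab = "dwell time (s)", ylab = "probability density (1/s)",
                 main = "Dwell-time histogram", ...)
  graphics::rect(x$t_lo, 0, x$t_hi, x$density, col = "grey80")
  invisible(x)
}
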