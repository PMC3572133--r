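# Synthetic single-molecule datasets with known ground truth.  These
# emulate the statistical structure of experimental dwell-time histograms
# (finite sample size, fixed bin width, optional detection dead time) while
# keeping the generating parameters alongside the data.

#' Generate a synthetic dwell-time dataset
#'
#' Simulates the requested network until \code{n_dwells} dwell times are
#' collected, bins them at the requested width, and packages histogram, raw
#' sample and generating parameters together.  The bundle is reproducible
#' bit-for-bit from its parameters and seed.
#'
#' @param network \code{"unicycle"}, \code{"branched"}, or a
#'   \code{\link{motor_network}} object.
#' @param rc rate constants (defaults to the packaged values; gating enters
#'   here via \code{gating_g}).
#' @param cond a \code{\link{condition}}.
#' @param fm a \code{\link{force_model}}.
#' @param n_dwells number of dwell times to collect (>= 100).
#' @param bin_width histogram bin width (s).
#' @param dead_time detection dead time (s), default 0.
#' @param seed integer seed.
#' @return An object of class \code{synthetic_bundle} with elements
#'   \code{histogram}, \code{sample}, \code{params}.
#' @examples
#' b <- generate_synthetic("unicycle", cond = condition(atp = 1000),
#'                         n_dwells = 200, bin_width = 0.02, seed = 1)
#' @export
generate_synthetic <- function(network = c("unicycle", "branched"),
                               rc = NULL, cond, fm = force_model(),
                               n_dwells = 2000, bin_width, dead_time = 0,
                               seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (n_dwells < 100) stop("n_dwells must be >= 100")
  if (is.character(network)) {
    network <- match.arg(network)
    if (is.null(rc))
      rc <- if (network == "branched") rate_constants(gating_g = 10) else rate_constants()
    net <- switch(network, unicycle = build_unicycle(rc),
                  branched = build_branched(rc))
  } else {
    net <- network
    rc <- net$rates
  }
  traj <- simulate_motor(net, cond, fm, n_steps = n_dwells + 1, seed = seed,
                         record = "mechanical")
  dw <- extract_dwells(traj)
  if (nrow(dw) < n_dwells)
    warning("trajectory terminated early: ", nrow(dw), " dwells collected")
  hist <- dwell_histogram(dw, bin_width = bin_width, dead_time = dead_time)
  structure(list(histogram = hist, sample = dw,
                 params = list(network_id = net$id, rates = rc, condition = cond,
                               force_model = fm, n_dwells = n_dwells,
                               bin_width = bin_width, dead_time = dead_time,
                               seed = seed)),
            class = "synthetic_bundle")
}

#' @export
#' @method print synthetic_bundle
print.synthetic_bundle <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("Synthetic dwell dataset: '%s', N = %d, seed = %d\n",
                     "  [ATP] = %g uM, [ADP] = %g uM, F = %g pN, ",
                     "g = %g, bin = %g s\n"),
              p$network_id, nrow(x$sample), p$seed, p$condition$atp,
              p$condition$adp, p$condition$force, p$rates$gating_g,
              p$bin_width))
  invisible(x)
}

#' Deterministic suite of synthetic fixtures
#'
#' Covers the characteristic single-molecule conditions: saturating ATP,
#' saturating ATP with 400 uM ADP added (the distribution broadens), the
#' two limiting-ATP conditions (10 and 2 uM) where gating shapes the
#' distribution, one substall-load and one superstall-load branched case
#' (the latter under the threshold chemical force policy, where slip steps
#' dominate and the dwell distribution collapses to a single exponential).
#' All fixtures are drawn from the branched network with gating g = 10.
#'
#' @param seed base integer seed; each fixture derives its own sub-seed.
#' @param n_dwells dwells per fixture (default 2000).
#' @return named list of \code{synthetic_bundle}s, with a \code{manifest}
#'   attribute (data frame of the generating parameters).
#' @examples
#' \donttest{suite <- make_fixture_suite(seed = 1, n_dwells = 200)}
#' @export
make_fixture_suite <- function(seed, n_dwells = 2000) {
  if (missing(seed)) stop("a seed is mandatory")
  fm0 <- force_model()
  fm3 <- force_model(chem_force_mode = "threshold")
  plan <- list(
    sat_atp    = list(cond = condition(atp = 1000, adp = 0.1), fm = fm0, bw = 0.02),
    adp_400    = list(cond = condition(atp = 1000, adp = 400), fm = fm0, bw = 0.05),
    atp_10     = list(cond = condition(atp = 10, adp = 0.1), fm = fm0, bw = 0.05),
    atp_2      = list(cond = condition(atp = 2, adp = 0.1), fm = fm0, bw = 0.1),
    substall   = list(cond = condition(atp = 2, adp = 0.1, force = 1),
                      fm = fm0, bw = 0.1),
    superstall = list(cond = condition(atp = 2, adp = 0.1, force = 5),
                      fm = fm3, bw = 0.2))
  rc <- rate_constants(gating_g = 10)
  out <- vector("list", length(plan)); names(out) <- names(plan)
  rows <- list()
  for (i in seq_along(plan)) {
    s <- plan[[i]]
    sub_seed <- (seed + 1000L * i) %% .Machine$integer.max
    out[[i]] <- generate_synthetic("branched", rc = rc, cond = s$cond,
                                   fm = s$fm, n_dwells = n_dwells,
                                   bin_width = s$bw, seed = sub_seed)
    rows[[i]] <- data.frame(fixture = names(plan)[i], network = "branched",
                            gating_g = rc$gating_g, atp_uM = s$cond$atp,
                            adp_uM = s$cond$adp, p_uM = s$cond$p,
                            force_pN = s$cond$force,
                            chem_force_mode = s$fm$chem_force_mode,
                            n_dwells = n_dwells, bin_width_s = s$bw,
                            dead_time_s = 0, seed = sub_seed)
  }
  attr(out, "manifest") <- do.call(rbind, rows)
  out
}
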