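# Gating quantification: scan the branched-network model against an
# observed dwell-time histogram with an RMSD objective on the binned
# densities, and locate the onset of the RMSD plateau.

#' Root-mean-square deviation between two histograms
#'
#' \code{sqrt(mean((d1 - d2)^2))} over bins.  Both histograms must share
#' identical bin edges: matching the bin size of the model to the observed
#' data is the caller's duty and no silent rebinning is performed.
#'
#' @param observed,model \code{dwell_histogram} objects (or data frames with
#'   \code{t_lo}, \code{t_hi}, \code{density}).
#' @return RMSD in density units (1/s).
#' @examples
#' h1 <- dwell_histogram(c(0.05, 0.15), bin_width = 0.1)
#' hist_rmsd(h1, h1)    # 0
#' @export
hist_rmsd <- function(observed, model) {
  if (nrow(observed) != nrow(model) ||
      any(abs(observed$t_lo - model$t_lo) > 1e-9) ||
      any(abs(observed$t_hi - model$t_hi) > 1e-9))
    stop("histograms have different bin edges; rebin the model to the observed edges")
  sqrt(mean((observed$density - model$density)^2))
}

# simulate a model histogram on the observed edges
model_histogram <- function(net, cond, fm, n_dwells, edges, dead_time, seed) {
  traj <- simulate_motor(net, cond, fm, n_steps = n_dwells + 1, seed = seed,
                         record = "mechanical")
  dwell_histogram(extract_dwells(traj), edges = edges, dead_time = dead_time)
}

#' Fit the gating parameter by an RMSD scan
#'
#' For each candidate gating ratio g, the branched network is simulated at
#' the observed condition, the resulting dwells are binned onto the
#' observed histogram's edges, and the RMSD between the two densities is
#' recorded.  The RMSD decreases with g until ADP release from the leading
#' head no longer competes with ATP binding and the curve saturates; the
#' reported estimate is the saturation onset, i.e. the smallest g whose
#' RMSD is within one plateau standard deviation of the plateau level
#' (plateau = mean RMSD over the upper half of the grid).  Because the
#' saturating half of the curve is flat by construction, the estimate is a
#' lower bound on the true gating ratio rather than a point estimate.
#'
#' All grid points are simulated with the same seed (common random
#' numbers), so the scan is deterministic given (observed, seed) and grid
#' ordering is not scrambled by seed-to-seed noise.
#'
#' @param observed an area-normalized \code{dwell_histogram}.
#' @param cond the \code{\link{condition}} the data were recorded at.
#' @param rc rate constants; \code{gating_g} is overridden by the grid.
#' @param fm a \code{\link{force_model}}.
#' @param g_grid ascending gating ratios to scan, all >= 1.
#' @param sim_n dwells per model simulation (default: the observed N, so
#'   the objective carries matched sampling noise).
#' @param dead_time dead time applied to the model dwells (s).
#' @param seed integer seed.
#' @return An object of class \code{gating_fit}: \code{scan} (data frame of
#'   g and RMSD), \code{g_hat}, \code{plateau}, \code{plateau_sd}.
#' @examples
#' \donttest{
#' obs <- generate_synthetic("branched", cond = condition(atp = 2, adp = 0.1),
#'                           n_dwells = 500, bin_width = 0.1, seed = 7)
#' fit <- fit_gating(obs$histogram, condition(atp = 2, adp = 0.1), seed = 8)
#' coef(fit)
#' }
#' @export
fit_gating <- function(observed, cond, rc = rate_constants(gating_g = 10),
                       fm = force_model(), g_grid = c(1, 2, 5, 10, 20, 50),
                       sim_n = NULL, dead_time = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.unsorted(g_grid, strictly = TRUE) || any(g_grid < 1))
    stop("g_grid must be strictly ascending with all values >= 1")
  area <- sum(observed$density) * attr(observed, "bin_width")
  if (abs(area - 1) > 0.05)
    warning("observed histogram area deviates from 1 (", signif(area, 4), ")")
  if (is.null(sim_n)) sim_n <- attr(observed, "n")
  edges <- c(observed$t_lo, observed$t_hi[nrow(observed)])

  rmsd <- vapply(g_grid, function(g) {
    rc_g <- rc; rc_g$gating_g <- g
    net <- build_branched(rc_g)
    hist_rmsd(observed,
              model_histogram(net, cond, fm, sim_n, edges, dead_time, seed))
  }, numeric(1))

  est <- plateau_onset(g_grid, rmsd)
  structure(list(scan = data.frame(g = g_grid, rmsd = rmsd),
                 g_hat = est$onset, plateau = est$plateau,
                 plateau_sd = est$sd, condition = cond, sim_n = sim_n,
                 seed = seed),
            class = "gating_fit")
}

# plateau = mean of the upper half of the grid; onset = smallest grid point
# whose value is within one plateau standard deviation of the plateau
plateau_onset <- function(grid, value) {
  n <- length(grid)
  if (n == 1) return(list(onset = grid[1], plateau = value[1], sd = 0))
  top <- seq(ceiling(n / 2) + ifelse(n %% 2 == 0, 1, 0), n)
  if (length(top) < 2) top <- c(n - 1, n)
  plateau <- mean(value[top])
  s <- stats::sd(value[top])
  onset <- grid[which(value <= plateau + s)[1]]
  list(onset = onset, plateau = plateau, sd = s)
}

#' @export
#' @method print gating_fit
print.gating_fit <- function(x, ...) {
  cat("Gating-parameter RMSD scan\n")
  print(transform(x$scan, rmsd = signif(rmsd, 5)), row.names = FALSE)
  cat(sprintf("  plateau %.5g +/- %.2g 1/s; saturation onset g_hat = %g (lower bound)\n",
              x$plateau, x$plateau_sd, x$g_hat))
  invisible(x)
}

#' @export
#' @method summary gating_fit
summary.gating_fit <- function(object, ...) {
  cat(sprintf(paste0("Gating fit at [ATP] = %g uM, [ADP] = %g uM, F = %g pN ",
                     "(sim N = %d, seed = %d)\n"),
              object$condition$atp, object$condition$adp,
              object$condition$force, object$sim_n, object$seed))
  print(object)
}

#' @export
#' @method coef gating_fit
coef.gating_fit <- function(object, ...) c(gating_g = object$g_hat)

#' @export
#' @method plot gating_fit
plot.gating_fit <- function(x, ...) {
  graphics::plot(x$scan$g, x$scan$rmsd, type = "b", log = "x",
                 xlab = "gating ratio g", ylab = "RMSD (1/s)",
                 main = "RMSD vs gating parameter", ...)
  graphics::abline(h = x$plateau + x$plateau_sd, lty = 2)
  graphics::abline(v = x$g_hat, col = 2, lty = 3)
  invisible(x)
}

#' Co-fit the ATP binding rate by an RMSD scan
#'
#' With the gating ratio held fixed, scans the second-order ATP binding
#' constant over a grid and returns the RMSD minimizer.  Common random
#' numbers across grid points, as in \code{\link{fit_gating}}.
#'
#' @inheritParams fit_gating
#' @param kappa_grid ATP binding constants to scan, 1/(uM s), all > 0
#'   (default: 25 log-spaced points over [0.3, 3]).
#' @param g_fixed gating ratio held fixed during the scan.
#' @return An object of class \code{atp_fit}: \code{scan}, \code{kappa_hat}.
#' @export
fit_atp_binding <- function(observed, cond, rc = rate_constants(),
                            fm = force_model(),
                            kappa_grid = exp(seq(log(0.3), log(3), length.out = 25)),
                            g_fixed = 10, sim_n = NULL, dead_time = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (any(kappa_grid <= 0)) stop("kappa_grid must be > 0")
  if (is.null(sim_n)) sim_n <- attr(observed, "n")
  edges <- c(observed$t_lo, observed$t_hi[nrow(observed)])

  rmsd <- vapply(kappa_grid, function(kap) {
    rc_k <- rc; rc_k$atp_bind <- kap; rc_k$gating_g <- g_fixed
    net <- build_branched(rc_k)
    hist_rmsd(observed,
              model_histogram(net, cond, fm, sim_n, edges, dead_time, seed))
  }, numeric(1))

  structure(list(scan = data.frame(kappa = kappa_grid, rmsd = rmsd),
                 kappa_hat = kappa_grid[which.min(rmsd)],
                 g_fixed = g_fixed, condition = cond, sim_n = sim_n,
                 seed = seed),
            class = "atp_fit")
}

#' @export
#' @method print atp_fit
print.atp_fit <- function(x, ...) {
  cat(sprintf("ATP-binding RMSD scan (g fixed at %g): kappa_hat = %.4g 1/(uM s)\n",
              x$g_fixed, x$kappa_hat))
  invisible(x)
}

#' @export
#' @method coef atp_fit
coef.atp_fit <- function(object, ...) c(atp_bind = object$kappa_hat)

#' @export
#' @method plot atp_fit
plot.atp_fit <- function(x, ...) {
  graphics::plot(x$scan$kappa, x$scan$rmsd, type = "b", log = "x",
                 xlab = "ATP binding rate (1/(uM s))", ylab = "RMSD (1/s)",
                 main = "RMSD vs ATP binding rate", ...)
  graphics::abline(v = x$kappa_hat, col = 2, lty = 3)
  invisible(x)
}
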