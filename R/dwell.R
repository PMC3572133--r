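# Dwell-time machinery: first-passage analysis of the absorbing chain.
# All densities here are phase-type, i.e. mixtures of exponentials with the
# decay rates given by the spectrum of the negated transient generator.

chain_eigen <- function(chain) {
  eg <- eigen(chain$Q)
  V <- eg$vectors
  # condition of the eigenvector basis decides whether the spectral
  # representation is trustworthy; a (near-)defective generator falls back
  # to a decomposition-free propagator
  defective <- FALSE
  Vinv <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vinv) || !all(is.finite(Mod(Vinv)))) defective <- TRUE
  else if (rcond(Mod(V)) < 1e-12) defective <- TRUE
  list(values = eg$values, V = V, Vinv = Vinv, defective = defective)
}

unit_vec <- function(states, init) {
  if (is.character(init)) {
    p0 <- stats::setNames(numeric(length(states)), states)
    if (!init %in% states) stop("unknown initial state '", init, "'")
    p0[init] <- 1
  } else {
    p0 <- init
    if (length(p0) != length(states)) stop("initial mix has wrong length")
    if (is.null(names(p0))) names(p0) <- states
    p0 <- p0[states]
    if (abs(sum(p0) - 1) > 1e-8) stop("initial mix must sum to 1")
  }
  p0
}

target_vector <- function(chain, directions) {
  rows <- chain$channels$direction %in% directions
  if (!any(rows)) return(stats::setNames(numeric(length(chain$states)), chain$states))
  colSums(chain$A[rows, , drop = FALSE])
}

#' Absorption probabilities of the single-site chain
#'
#' First-step analysis: solves the linear system for the probability that a
#' walk started in each transient state is eventually absorbed through each
#' mechanical channel, and aggregates channels into forward and backward
#' step probabilities.
#'
#' @param chain an \code{\link{build_absorbing_chain}} result.
#' @return An object of class \code{absorption_result}: \code{pi} is a
#'   2 x k matrix (rows \code{"forward"}, \code{"backward"}; columns the
#'   transient states), \code{channels} the per-channel k-column matrix, and
#'   \code{init_states} the post-forward / post-backward landing states.
#' @examples
#' ch <- build_absorbing_chain(build_unicycle(), condition(atp = 1000))
#' absorption_probabilities(ch)
#' @export
absorption_probabilities <- function(chain) {
  U <- tryCatch(solve(-chain$Q), error = function(e)
    stop("degenerate chain: singular transient generator"))
  Pi_ch <- chain$A %*% U
  pi_dir <- rbind(
    forward = colSums(Pi_ch[chain$channels$direction == "forward", , drop = FALSE]),
    backward = colSums(Pi_ch[chain$channels$direction == "backward", , drop = FALSE]))
  colnames(pi_dir) <- chain$states
  structure(list(pi = pi_dir, channels = Pi_ch,
                 init_states = chain$init_states),
            class = "absorption_result")
}

#' @export
#' @method print absorption_result
print.absorption_result <- function(x, ...) {
  cat("Absorption probabilities (columns = initial transient state):\n")
  print(round(x$pi, 6))
  invisible(x)
}

make_dwell_dist <- function(chain, init, directions, kind) {
  p0 <- unit_vec(chain$states, init)
  a <- target_vector(chain, directions)
  pi_mass <- drop(a %*% solve(-chain$Q) %*% p0)
  if (pi_mass <= 0) stop("undefined conditional density: absorption probability is 0")
  eg <- chain_eigen(chain)
  if (!eg$defective) {
    coef <- as.vector(a %*% eg$V) * as.vector(eg$Vinv %*% p0)
    rates <- -eg$values
    keep <- Mod(coef) > 0 | Re(rates) > 0   # keep all; zero-weight terms harmless
    d <- list(rates = rates[keep], weights = coef[keep] / pi_mass,
              pi = pi_mass, kind = kind, method = "spectral",
              complex = any(Im(rates) != 0))
  } else {
    d <- list(rates = NULL, weights = NULL, pi = pi_mass, kind = kind,
              method = "propagator", complex = FALSE)
  }
  d$Q <- chain$Q; d$a <- a; d$p0 <- p0
  structure(d, class = "dwell_dist")
}

#' Conditional dwell-time density
#'
#' Density of the first-passage time to a given step direction, conditioned
#' on taking that step, for a walk started in \code{init} (a state label,
#' typically one of the post-step landing states, or a probability mix over
#' states).  Computed from the spectral decomposition of the transient
#' generator as an exponential mixture; a defective generator triggers a
#' matrix-exponential propagator fallback (see \code{$method}).
#'
#' @param chain an absorbing chain.
#' @param init initial state label or probability vector over states.
#' @param target \code{"forward"} or \code{"backward"}.
#' @return A \code{dwell_dist} object; evaluate with \code{\link{ddwell}} /
#'   \code{\link{pdwell}}.
#' @examples
#' ch <- build_absorbing_chain(build_unicycle(), condition(atp = 1000))
#' rho <- conditional_density(ch, init = "DT", target = "forward")
#' ddwell(rho, c(0.01, 0.1))
#' @export
conditional_density <- function(chain, init, target = c("forward", "backward")) {
  target <- match.arg(target)
  make_dwell_dist(chain, init, target, kind = paste0("conditional(", target, ")"))
}

#' Forward, backward and total dwell-time densities
#'
#' Mixes the conditional first-passage densities over the stationary law of
#' the embedded step chain: after each mechanical step the motor lands in a
#' definite state (DT after the main forward step, TD after a backstep, EE
#' after a slip), and the sequence of landing states is itself a Markov
#' chain whose stationary distribution supplies the mixture weights.  The
#' total density is \code{rho = p_f * rho_f + p_b * rho_b} with the
#' stationary step-type frequencies \code{p_f}, \code{p_b}.
#'
#' @param chain an absorbing chain.
#' @return A list with \code{rho_f}, \code{rho_b}, \code{rho_total}
#'   (\code{dwell_dist} objects; \code{rho_b} is NULL with a warning flag if
#'   backward absorption is impossible), step-type frequencies \code{p_f},
#'   \code{p_b}, and the stationary landing distribution \code{start_mix}.
#' @examples
#' ch <- build_absorbing_chain(build_unicycle(), condition(atp = 1000))
#' sd <- step_densities(ch)
#' sd$p_b
#' @export
step_densities <- function(chain) {
  ab <- absorption_probabilities(chain)
  ch <- chain$channels
  landings <- sort(unique(ch$landing))
  # embedded chain over landing states: K[l', l] = P(next landing l' | start l)
  K <- matrix(0, length(landings), length(landings),
              dimnames = list(landings, landings))
  for (i in seq_len(nrow(ch)))
    K[ch$landing[i], ] <- K[ch$landing[i], ] + ab$channels[i, landings]
  q <- stationary_of_kernel(K)
  start_mix <- stats::setNames(numeric(length(chain$states)), chain$states)
  start_mix[landings] <- q

  p_f <- drop(ab$pi["forward", ] %*% start_mix)
  p_b <- drop(ab$pi["backward", ] %*% start_mix)

  rho_f <- if (p_f > 0) make_dwell_dist(chain, start_mix, "forward", "forward") else NULL
  rho_b <- if (p_b > 0) make_dwell_dist(chain, start_mix, "backward", "backward") else NULL
  warn <- is.null(rho_f) || is.null(rho_b)
  if (warn) warning("one step direction is unreachable; total density uses the reachable side")
  rho_total <- make_dwell_dist(chain, start_mix, c("forward", "backward"), "total")
  list(rho_f = rho_f, rho_b = rho_b, rho_total = rho_total,
       p_f = p_f, p_b = p_b, start_mix = start_mix, one_sided = warn)
}

# stationary distribution of a column-stochastic kernel (columns sum to 1)
stationary_of_kernel <- function(K) {
  k <- ncol(K)
  M <- rbind(K - diag(k), rep(1, k))
  b <- c(numeric(k), 1)
  q <- stats::setNames(as.vector(qr.solve(M, b)), colnames(K))
  q[q < 0 & q > -1e-12] <- 0
  q / sum(q)
}

#' Evaluate a dwell-time density
#'
#' @param d a \code{dwell_dist}.
#' @param t times (s); negative times give density 0.
#' @return density values, 1/s.
#' @export
ddwell <- function(d, t) {
  out <- numeric(length(t))
  pos <- t >= 0
  if (!any(pos)) return(out)
  tp <- t[pos]
  if (d$method == "spectral") {
    vals <- vapply(tp, function(ti)
      Re(sum(d$weights * exp(-d$rates * ti))), numeric(1))
  } else {
    vals <- vapply(tp, function(ti) {
      P <- as.matrix(Matrix::expm(Matrix::Matrix(d$Q * ti))) %*% d$p0
      drop(d$a %*% P) / d$pi
    }, numeric(1))
  }
  out[pos] <- pmax(vals, 0)
  out
}

#' Cumulative distribution of a dwell-time density
#'
#' @inheritParams ddwell
#' @return P(dwell <= t).
#' @export
pdwell <- function(d, t) {
  out <- numeric(length(t))
  pos <- t > 0
  if (!any(pos)) return(out)
  tp <- t[pos]
  if (d$method == "spectral") {
    vals <- vapply(tp, function(ti)
      Re(sum(d$weights / d$rates * (1 - exp(-d$rates * ti)))), numeric(1))
  } else {
    Qi <- solve(d$Q)
    vals <- vapply(tp, function(ti) {
      P <- as.matrix(Matrix::expm(Matrix::Matrix(d$Q * ti))) %*% d$p0
      drop(d$a %*% Qi %*% (P - d$p0)) / d$pi
    }, numeric(1))
  }
  out[pos] <- pmin(pmax(vals, 0), 1)
  out
}

#' @export
#' @method print dwell_dist
print.dwell_dist <- function(x, ...) {
  cat(sprintf("Dwell-time density [%s], method = %s\n", x$kind, x$method))
  if (x$method == "spectral") {
    lam <- sort(Re(x$rates))
    cat(sprintf("  %d exponential components; slowest decay rate %.6g 1/s\n",
                length(x$rates), min(lam[lam > 1e-300])))
  }
  cat(sprintf("  absorption probability pi = %.6g, mean = %.6g s\n",
              x$pi, mean(x)))
  invisible(x)
}

#' @export
#' @method mean dwell_dist
mean.dwell_dist <- function(x, ...) {
  if (x$method == "spectral") return(Re(sum(x$weights / x$rates^2)))
  Qi2 <- solve(x$Q) %*% solve(x$Q)
  drop(x$a %*% Qi2 %*% x$p0) / x$pi
}

#' @export
#' @method plot dwell_dist
plot.dwell_dist <- function(x, tmax = NULL, n = 400, log = "", ...) {
  if (is.null(tmax)) tmax <- 6 * mean(x)
  tt <- seq(0, tmax, length.out = n)
  graphics::plot(tt, ddwell(x, tt), type = "l", xlab = "dwell time (s)",
                 ylab = "probability density (1/s)", log = log,
                 main = paste("Dwell-time density:", x$kind), ...)
  invisible(x)
}

#' Decay spectrum of the transient generator
#'
#' Eigenvalue magnitudes of the negated transient generator, sorted
#' ascending; the smallest governs the tail of every dwell-time density.
#' For an acyclic transient graph (e.g. the uni-cycle with blocked reverse
#' chemistry and no ADP) the spectrum equals the per-state exit rates.
#'
#' @param chain an absorbing chain.
#' @return numeric vector (class \code{decay_spectrum}) of decay rates in
#'   1/s; attribute \code{complex} flags complex eigenvalue pairs (reported
#'   by magnitude).
#' @examples
#' decay_spectrum(build_absorbing_chain(build_unicycle(), condition(atp = 1000)))
#' @export
decay_spectrum <- function(chain) {
  ev <- eigen(-chain$Q, only.values = TRUE)$values
  cx <- any(abs(Im(ev)) > 1e-9 * (abs(Re(ev)) + 1))
  out <- sort(Mod(ev))
  structure(out, complex = cx, class = "decay_spectrum")
}

#' @export
#' @method print decay_spectrum
print.decay_spectrum <- function(x, ...) {
  cat("Decay spectrum (1/s):", paste(signif(unclass(x), 8), collapse = ", "), "\n")
  if (isTRUE(attr(x, "complex")))
    cat("  note: complex eigenvalue pair(s); magnitudes reported\n")
  invisible(x)
}

#' Time-dependent occupancies of the absorbing chain
#'
#' Solves the master equation with absorbing boundaries for a walk started
#' in \code{init}: transient-state occupancies plus the cumulative
#' probability absorbed in the forward and backward directions.  Uses the
#' spectral propagator; a defective generator falls back to the matrix
#' exponential (reported in the \code{method} attribute).
#'
#' @param chain an absorbing chain.
#' @param init initial state label.
#' @param times strictly increasing time grid starting at 0 (s).
#' @return A data frame (class \code{occupancy_trajectory}) with one row per
#'   time and columns per transient state plus \code{forward}, \code{backward}.
#' @examples
#' ch <- build_absorbing_chain(build_unicycle(), condition(atp = 1000))
#' solve_occupancies(ch, "DT", c(0, 0.005, 0.01))
#' @export
solve_occupancies <- function(chain, init, times) {
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
    stop("time grid must be strictly increasing and start at 0")
  p0 <- unit_vec(chain$states, init)
  eg <- chain_eigen(chain)
  k <- length(chain$states)
  propagate <- if (!eg$defective) {
    c0 <- eg$Vinv %*% p0
    function(ti) Re(eg$V %*% (exp(eg$values * ti) * c0))
  } else {
    function(ti) as.matrix(Matrix::expm(Matrix::Matrix(chain$Q * ti))) %*% p0
  }
  Qi <- solve(chain$Q)
  AQ <- chain$A %*% Qi
  rows <- lapply(times, function(ti) {
    P <- propagate(ti)
    abs_occ <- drop(AQ %*% (P - p0))
    fwd <- sum(abs_occ[chain$channels$direction == "forward"])
    bwd <- sum(abs_occ[chain$channels$direction == "backward"])
    c(stats::setNames(pmax(drop(P), 0), chain$states),
      forward = max(fwd, 0), backward = max(bwd, 0))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(time = times, out)
  attr(out, "method") <- if (eg$defective) "propagator" else "spectral"
  attr(out, "init") <- init
  class(out) <- c("occupancy_trajectory", "data.frame")
  out
}

#' Mean dwell time (mean first-passage time to absorption)
#'
#' Linear-solve first moment: \code{sum(solve(-Q) \%*\% p0)}.  Agrees with the
#' first moment of the total density from the same initial state.
#'
#' @param chain an absorbing chain.
#' @param init initial state label or probability mix.
#' @return mean dwell in seconds.
#' @examples
#' ch <- build_absorbing_chain(build_unicycle(), condition(atp = 1000))
#' mean_dwell(ch, "DT")
#' @export
mean_dwell <- function(chain, init) {
  p0 <- unit_vec(chain$states, init)
  sum(solve(-chain$Q, p0))
}
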