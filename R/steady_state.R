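# Periodic (non-absorbing) steady state: the network repeats along the
# filament, so mechanical transitions wrap back onto the same state set and
# the stationary distribution over chemical states determines the fluxes
# and the motor velocity.

# full generator with mechanical wrap-around; columns are source states
periodic_generator <- function(net, cond, fm) {
  tr <- net$transitions
  rates <- transition_rates_at(net, cond, fm)
  k <- length(net$states)
  W <- matrix(0, k, k, dimnames = list(net$states, net$states))
  for (i in seq_len(nrow(tr))) {
    f <- match(tr$from[i], net$states); t <- match(tr$to[i], net$states)
    if (f != t) W[t, f] <- W[t, f] + rates[i]
    # self-loops (slip steps EE -> EE) do not move probability between
    # states; they only carry flux, handled separately
  }
  diag(W) <- diag(W) - colSums(W)
  list(W = W, rates = rates)
}

# closed communicating classes (no outgoing edge) of a boolean adjacency
# matrix with rows = source; returns a list of index vectors
closed_classes <- function(adj) {
  k <- nrow(adj)
  reach <- adj | diag(TRUE, k)
  for (m in seq_len(k)) reach <- reach | (reach %*% reach) > 0
  out <- list(); assigned <- logical(k)
  for (i in seq_len(k)) {
    if (assigned[i]) next
    cls <- which(reach[i, ] & reach[, i])
    assigned[cls] <- TRUE
    # closed iff nothing reachable outside the class
    if (all(which(reach[i, ]) %in% cls)) out[[length(out) + 1L]] <- cls
  }
  out
}

# Grassmann-Taksar-Heyman stationary vector of an irreducible rate matrix
# (rows = source, zero diagonal); uses only additions and multiplications
# of non-negative numbers, hence no catastrophic cancellation
gth_stationary <- function(R) {
  k <- nrow(R)
  if (k == 1) return(1)
  A <- R; S <- numeric(k)
  for (n in k:2) {
    S[n] <- sum(A[n, 1:(n - 1)])
    if (S[n] <= 0)
      stop("GTH elimination hit a reducible block; chain not irreducible")
    for (i in 1:(n - 1)) {
      f <- A[i, n] / S[n]
      if (f > 0) A[i, 1:(n - 1)] <- A[i, 1:(n - 1)] + f * A[n, 1:(n - 1)]
    }
  }
  p <- numeric(k); p[1] <- 1
  for (n in 2:k) p[n] <- sum(p[1:(n - 1)] * A[1:(n - 1), n]) / S[n]
  p / sum(p)
}

# structural connectivity over the undirected transition graph
check_connected <- function(net) {
  k <- length(net$states)
  adj <- matrix(FALSE, k, k, dimnames = list(net$states, net$states))
  for (i in seq_len(nrow(net$transitions))) {
    f <- net$transitions$from[i]; t <- net$transitions$to[i]
    adj[f, t] <- TRUE; adj[t, f] <- TRUE
  }
  seen <- logical(k); seen[1] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nxt <- which(apply(adj[, frontier, drop = FALSE], 1, any) & !seen)
    seen[nxt] <- TRUE; frontier <- nxt
  }
  if (!all(seen))
    stop("transition graph is disconnected; components: {",
         paste(net$states[seen], collapse = ","), "} vs {",
         paste(net$states[!seen], collapse = ","), "}")
  invisible(TRUE)
}

#' Steady state of the periodically repeated network
#'
#' Null-space solve of the site-collapsed generator.  Returns the stationary
#' probability of each chemical state, the net (excess) flux through every
#' transition, and the motor velocity \code{v = step_size * sum(offset *
#' rate * P[from])} over the mechanical transitions.
#'
#' @param net a \code{\link{motor_network}}.
#' @param cond a \code{\link{condition}}.
#' @param fm a \code{\link{force_model}}.
#' @return An object of class \code{steady_state_result} with elements
#'   \code{p} (stationary probabilities), \code{flux} (per-transition net
#'   probability flux, 1/s), \code{velocity} (nm/s) and \code{divergence}
#'   (net flux imbalance per state; ~0).
#' @examples
#' ss <- periodic_steady_state(build_unicycle(), condition(atp = 1000))
#' ss$p
#' @export
periodic_steady_state <- function(net, cond, fm = force_model()) {
  check_connected(net)
  pg <- periodic_generator(net, cond, fm)
  W <- pg$W
  k <- ncol(W)
  # rate matrix with rows = source (self-loops excluded: they carry flux but
  # move no probability)
  R <- t(W); diag(R) <- 0
  # stationary mass lives on the closed communicating classes of the
  # rate > 0 digraph; more than one closed class means the stationary
  # distribution is not unique under this condition
  cls <- closed_classes(R > 0)
  if (length(cls) > 1)
    stop("stationary distribution is not unique at this condition; ",
         "closed classes: ",
         paste(vapply(cls, function(i)
           paste0("{", paste(net$states[i], collapse = ","), "}"),
           character(1)), collapse = " vs "))
  cc <- cls[[1]]
  p <- stats::setNames(numeric(k), net$states)
  # GTH elimination: subtraction-free, so it stays accurate when rates span
  # tens of orders of magnitude (e.g. Boltzmann factors under high load)
  p[cc] <- gth_stationary(R[cc, cc, drop = FALSE])

  tr <- net$transitions
  flux <- pg$rates * p[tr$from]
  mech <- tr$offset != 0L
  v <- fm$step_size * sum(tr$offset[mech] * flux[mech])

  # flux divergence per state (self-loops excluded; they are divergence-free)
  div <- stats::setNames(numeric(k), net$states)
  for (i in seq_len(nrow(tr))) {
    if (tr$from[i] != tr$to[i]) {
      div[tr$from[i]] <- div[tr$from[i]] - flux[i]
      div[tr$to[i]] <- div[tr$to[i]] + flux[i]
    }
  }
  structure(list(p = p, flux = flux, velocity = v, divergence = div,
                 condition = cond, network_id = net$id),
            class = "steady_state_result")
}

#' @export
#' @method print steady_state_result
print.steady_state_result <- function(x, ...) {
  cat(sprintf("Periodic steady state ('%s'): v = %.6g nm/s\n",
              x$network_id, x$velocity))
  print(round(x$p, 6))
  invisible(x)
}

#' Motor velocity at a condition
#'
#' @inheritParams periodic_steady_state
#' @return velocity in nm/s (positive = towards the filament plus end).
#' @examples
#' velocity(build_unicycle(), condition(atp = 1000))   # ~406 nm/s
#' @export
velocity <- function(net, cond, fm = force_model()) {
  periodic_steady_state(net, cond, fm)$velocity
}

#' Force-velocity relation
#'
#' Evaluates the steady-state velocity on a grid of load forces, holding the
#' nucleotide concentrations of \code{cond} fixed.
#'
#' @inheritParams periodic_steady_state
#' @param forces numeric vector of loads (pN).
#' @return data frame with columns \code{F_pN}, \code{v_nm_per_s}.
#' @examples
#' force_velocity_curve(build_unicycle(), condition(atp = 1000),
#'                      forces = c(0, 0.5, 1))
#' @export
force_velocity_curve <- function(net, cond, fm = force_model(), forces) {
  stopifnot(is.numeric(forces), all(is.finite(forces)))
  v <- vapply(forces, function(f) {
    cf <- cond; cf$force <- f
    velocity(net, cf, fm)
  }, numeric(1))
  data.frame(F_pN = forces, v_nm_per_s = v)
}

#' Stall force
#'
#' Root of the force-velocity relation inside a bracket, by bisection to
#' 1e-3 pN.  The uni-cycle with blocked reverse chemistry has strictly
#' positive velocity at every load, so it has no stall force and \code{NA}
#' is returned with a diagnostic; stalling requires the mechanical slip
#' cycle of the branched network.
#'
#' @inheritParams periodic_steady_state
#' @param bracket length-2 force interval to search (pN).
#' @return stall force (pN), or \code{NA} with attribute \code{reason} if
#'   the velocity does not change sign in the bracket.
#' @examples
#' stall_force(build_branched(), condition(atp = 2, adp = 0.1), bracket = c(0, 5))
#' @export
stall_force <- function(net, cond, fm = force_model(), bracket = c(0, 5)) {
  vf <- function(f) { cf <- cond; cf$force <- f; velocity(net, cf, fm) }
  v1 <- vf(bracket[1]); v2 <- vf(bracket[2])
  if (sign(v1) == sign(v2) || v1 == 0 && v2 == 0) {
    out <- NA_real_
    attr(out, "reason") <- sprintf(
      "no sign change in bracket [%g, %g] pN (v = %.4g and %.4g nm/s)",
      bracket[1], bracket[2], v1, v2)
    return(out)
  }
  stats::uniroot(vf, interval = bracket, tol = 1e-3)$root
}

#' Cycle occupation weights
#'
#' Apportions the stationary probability among the tagged network cycles
#' (F = chemomechanical, E = enzymatic, M = mechanical slip).  A state whose
#' outgoing transitions all carry one tag contributes its whole probability
#' to that cycle; a shared state is split in proportion to its outgoing flux
#' through each cycle's transitions (a transition carrying several tags
#' splits its flux equally among them).
#'
#' @inheritParams periodic_steady_state
#' @return named numeric vector of weights summing to 1.
#' @examples
#' cycle_occupation(build_branched(), condition(atp = 1000, adp = 0.1))
#' @export
cycle_occupation <- function(net, cond, fm = force_model()) {
  ss <- periodic_steady_state(net, cond, fm)
  tr <- net$transitions
  if (any(vapply(tr$cycles, length, integer(1)) == 0))
    stop("untagged transitions: every transition needs at least one cycle tag")
  all_cycles <- sort(unique(unlist(tr$cycles)))
  w <- stats::setNames(numeric(length(all_cycles)), all_cycles)
  rates <- transition_rates_at(net, cond, fm)
  for (s in net$states) {
    out_idx <- which(tr$from == s)
    out_rate <- rates[out_idx]
    tot <- sum(out_rate)
    share <- stats::setNames(numeric(length(all_cycles)), all_cycles)
    if (tot <= 0) {
      # isolated sink under this condition: split equally among its cycles
      cyc <- unique(unlist(tr$cycles[out_idx]))
      if (!length(cyc)) cyc <- all_cycles
      share[cyc] <- 1 / length(cyc)
    } else {
      for (j in seq_along(out_idx)) {
        cyc <- tr$cycles[[out_idx[j]]]
        share[cyc] <- share[cyc] + out_rate[j] / tot / length(cyc)
      }
    }
    w <- w + ss$p[s] * share
  }
  w / sum(w)
}
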