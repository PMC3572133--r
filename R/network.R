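#' Construct a chemomechanical motor network
#'
#' Low-level constructor used by \code{\link{build_unicycle}},
#' \code{\link{build_branched}} and the network-file reader.  States are
#' labelled by the nucleotide occupancy of the (trailing, leading) head pair
#' (T = ATP, D = ADP, E = empty), e.g. \code{"TD"}.  Chemical transitions stay
#' at the current filament site (offset 0); mechanical transitions step the
#' motor by one site (offset +1 forward, -1 backward).
#'
#' @param states character vector of state labels.
#' @param transitions data frame with columns \code{from}, \code{to},
#'   \code{rate} (rate-constant name), \code{law} (\code{"binding"},
#'   \code{"release"} or \code{"mechanical"}), \code{species} (nucleotide for
#'   chemical laws, NA otherwise), \code{direction} (mechanical laws),
#'   \code{slip} (logical), \code{offset} (integer in -1..1) and
#'   \code{cycles} (list column of cycle tags among "F", "E", "M").
#' @param rates a \code{\link{rate_constants}} object resolving the names.
#' @param id short network identifier.
#' @return An object of class \code{motor_network}.
#' @export
motor_network <- function(states, transitions, rates, id = "custom") {
  stopifnot(is.character(states), length(states) >= 2)
  if (anyDuplicated(states)) stop("duplicate state labels")
  need <- c("from", "to", "rate", "law", "species", "direction", "slip",
            "offset", "cycles")
  miss <- setdiff(need, names(transitions))
  if (length(miss)) stop("transitions lack columns: ", paste(miss, collapse = ", "))
  bad <- !(transitions$from %in% states) | !(transitions$to %in% states)
  if (any(bad)) stop("transition references unknown state: row ",
                     paste(which(bad), collapse = ", "))
  if (any(transitions$law == "mechanical" & transitions$offset == 0))
    stop("mechanical transitions must have offset +1 or -1")
  if (any(transitions$law != "mechanical" & transitions$offset != 0))
    stop("chemical transitions must have offset 0")
  for (nm in transitions$rate) resolve_rate(nm, rates)  # fail early
  structure(list(states = states, transitions = transitions,
                 rates = rates, id = id),
            class = "motor_network")
}

#' @export
#' @method print motor_network
print.motor_network <- function(x, ...) {
  nmech <- sum(x$transitions$offset != 0)
  cat(sprintf("Motor network '%s': %d states, %d transitions (%d mechanical)\n",
              x$id, length(x$states), nrow(x$transitions), nmech))
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  invisible(x)
}

tr_row <- function(from, to, rate, law, species = NA_character_,
                   direction = NA_character_, slip = FALSE, offset = 0L,
                   cycles = "F") {
  data.frame(from = from, to = to, rate = rate, law = law, species = species,
             direction = direction, slip = slip, offset = as.integer(offset),
             cycles = I(list(cycles)), stringsAsFactors = FALSE)
}

#' Uni-cycle network of myosin V
#'
#' The four-state chemomechanical cycle DD -> ED -> TD -> DT -> DD: ADP
#' release from the trailing head, ATP binding, the 36-nm forward step that
#' swaps head roles, and hydrolysis + phosphate release.  The backward step
#' DT -> TD and the reverse chemistry (ATP dissociation, phosphate binding)
#' close the network; the latter two default to zero rate.
#'
#' @param rc a \code{\link{rate_constants}} object.
#' @return A \code{\link{motor_network}} with 4 states and 8 transitions.
#' @examples
#' net <- build_unicycle(rate_constants())
#' @export
build_unicycle <- function(rc = rate_constants()) {
  tr <- rbind(
    tr_row("DD", "ED", "adp_release_trail", "release", species = "ADP"),
    tr_row("ED", "DD", "adp_bind", "binding", species = "ADP"),
    tr_row("ED", "TD", "atp_bind", "binding", species = "ATP"),
    tr_row("TD", "ED", "atp_dissoc", "release", species = "ATP"),
    tr_row("TD", "DT", "step_fwd", "mechanical", direction = "forward",
           offset = +1L),
    tr_row("DT", "TD", "step_bwd", "mechanical", direction = "backward",
           offset = -1L),
    tr_row("DT", "DD", "p_release", "release", species = "P"),
    tr_row("DD", "DT", "p_bind", "binding", species = "P"))
  motor_network(c("DD", "ED", "TD", "DT"), tr, rc, id = "unicycle")
}

#' Branched (three-cycle) network of myosin V
#'
#' Extends the uni-cycle by ADP release from the leading head (gated by the
#' ratio \code{gating_g}: leading-head release rate =
#' \code{adp_release_trail / gating_g}), the doubly-empty state EE, ADP
#' rebinding, and the purely mechanical slip steps out of EE that carry the
#' superstall ratcheting (cycle M).  Leading-head release and the surrounding
#' chemistry form the enzymatic cycle E; the uni-cycle transitions keep their
#' chemomechanical tag F.
#'
#' @param rc a \code{\link{rate_constants}} object (gating and slip rates used).
#' @return A \code{\link{motor_network}} with 6 states.
#' @examples
#' net <- build_branched(rate_constants(gating_g = 10))
#' @export
build_branched <- function(rc = rate_constants(gating_g = 10)) {
  uni <- build_unicycle(rc)
  tr <- rbind(
    uni$transitions,
    tr_row("DD", "DE", "adp_release_lead", "release", species = "ADP",
           cycles = "E"),
    tr_row("ED", "EE", "adp_release_lead", "release", species = "ADP",
           cycles = "E"),
    tr_row("DE", "EE", "adp_release_trail", "release", species = "ADP",
           cycles = "E"),
    tr_row("EE", "ED", "adp_bind", "binding", species = "ADP", cycles = "E"),
    tr_row("EE", "DE", "adp_bind", "binding", species = "ADP", cycles = "E"),
    tr_row("DE", "DD", "adp_bind", "binding", species = "ADP", cycles = "E"),
    tr_row("EE", "EE", "slip_fwd", "mechanical", direction = "forward",
           slip = TRUE, offset = +1L, cycles = "M"),
    tr_row("EE", "EE", "slip_bwd", "mechanical", direction = "backward",
           slip = TRUE, offset = -1L, cycles = "M"))
  motor_network(c("DD", "ED", "TD", "DT", "DE", "EE"), tr, rc, id = "branched")
}

# evaluate all transition rates of a network at a condition
transition_rates_at <- function(net, cond, fm) {
  tr <- net$transitions
  vapply(seq_len(nrow(tr)), function(i) {
    law <- list(type = tr$law[i], species = tr$species[i],
                direction = tr$direction[i], slip = tr$slip[i])
    transition_rate(resolve_rate(tr$rate[i], net$rates), law, cond, fm)
  }, numeric(1))
}

#' Absorbing-boundary Markov chain for one filament site
#'
#' Restricts the network to a single lattice site: chemical transitions stay
#' among the transient states, while every mechanical transition feeds an
#' absorbing channel at a neighbouring site.  Each channel keeps its step
#' direction and the state the motor lands in after the step, so dwell times
#' conditioned on the preceding and following step direction can be read off.
#' The generator is in columns-are-sources convention: \code{Q[i, j]} is the
#' rate from transient state j to transient state i, and the diagonal holds
#' minus the total exit rate (including absorption).
#'
#' @param net a \code{\link{motor_network}}.
#' @param cond a \code{\link{condition}}.
#' @param fm a \code{\link{force_model}}.
#' @return An object of class \code{absorbing_chain} with elements
#'   \code{states}, \code{Q} (transient generator), \code{A} (channel x state
#'   absorption-rate matrix), \code{channels} (direction, landing state),
#'   and \code{init_states} (post-forward and post-backward landing states of
#'   the main stepping transitions).
#' @examples
#' ch <- build_absorbing_chain(build_unicycle(), condition(atp = 1000))
#' @export
build_absorbing_chain <- function(net, cond, fm = force_model()) {
  tr <- net$transitions
  rates <- transition_rates_at(net, cond, fm)
  k <- length(net$states)
  idx <- function(s) match(s, net$states)

  Q <- matrix(0, k, k, dimnames = list(net$states, net$states))
  mech <- which(tr$offset != 0L)
  chem <- which(tr$offset == 0L)
  for (i in chem) Q[idx(tr$to[i]), idx(tr$from[i])] <-
      Q[idx(tr$to[i]), idx(tr$from[i])] + rates[i]

  channels <- data.frame(
    transition = mech,
    direction = ifelse(tr$offset[mech] > 0, "forward", "backward"),
    from = tr$from[mech], landing = tr$to[mech], rate = rates[mech],
    stringsAsFactors = FALSE)
  A <- matrix(0, nrow(channels), k,
              dimnames = list(NULL, net$states))
  for (c in seq_len(nrow(channels)))
    A[c, idx(channels$from[c])] <- A[c, idx(channels$from[c])] + channels$rate[c]

  # total exit rate per source state; chemical self-loops cannot occur, so
  # the column sums of Q at this point are the chemical out-rates
  exit <- colSums(Q) + colSums(A)
  diag(Q) <- -exit
  if (any(exit <= 0))
    stop("degenerate chain: state(s) with zero exit rate: ",
         paste(net$states[exit <= 0], collapse = ", "))

  fwd_main <- which(channels$direction == "forward" & !tr$slip[channels$transition])
  bwd_main <- which(channels$direction == "backward" & !tr$slip[channels$transition])
  init_states <- c(
    post_forward = if (length(fwd_main)) channels$landing[fwd_main[1]] else
      channels$landing[channels$direction == "forward"][1],
    post_backward = if (length(bwd_main)) channels$landing[bwd_main[1]] else
      channels$landing[channels$direction == "backward"][1])

  structure(list(states = net$states, Q = Q, A = A, channels = channels,
                 init_states = init_states, condition = cond,
                 force_model = fm, network_id = net$id),
            class = "absorbing_chain")
}

#' @export
#' @method print absorbing_chain
print.absorbing_chain <- function(x, ...) {
  cat(sprintf("Absorbing chain ('%s'): %d transient states, %d absorption channels\n",
              x$network_id, length(x$states), nrow(x$channels)))
  cat("  exit rates (1/s):",
      paste(sprintf("%s: %g", x$states, -diag(x$Q)), collapse = ", "), "\n")
  invisible(x)
}
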