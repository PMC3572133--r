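#' Rate constants of the myosin V chemomechanical network
#'
#' Collects the bare (zero-load, unit-concentration) rate constants of the
#' motor's chemical and mechanical transitions.  The defaults are the
#' experimentally determined values for the uni-cycle network of myosin V:
#' second-order binding constants in 1/(uM s), first-order rates in 1/s.
#'
#' @param atp_bind ATP binding to the empty trailing head, 1/(uM s).
#' @param adp_bind ADP binding, 1/(uM s).
#' @param adp_release_trail ADP release from the trailing head, 1/s.
#' @param p_release lumped hydrolysis + phosphate release on the DT -> DD
#'   transition, 1/s.
#' @param step_fwd bare forward stepping rate, 1/s.
#' @param step_bwd bare backward stepping rate, 1/s.
#' @param gating_g dimensionless gating ratio >= 1: ADP release from the
#'   leading head proceeds at \code{adp_release_trail / gating_g}.  \code{g = 1}
#'   means no gating (symmetric heads).
#' @param atp_dissoc ATP dissociation from the trailing head, 1/s (default 0:
#'   the reverse cycle is strongly suppressed under in vitro conditions).
#' @param p_bind phosphate binding, 1/(uM s) (default 0).
#' @param slip_fwd,slip_bwd bare rates of the purely mechanical slip steps out
#'   of the doubly-empty EE state (branched network only), 1/s.  Equal bare
#'   rates are the thermodynamically consistent default: a slip consumes no
#'   chemical free energy, so it cannot be biased at zero load.  The default
#'   magnitude is anchored at superstall: with symmetric load sharing the
#'   backward slip rate reaches ~1.5/s at 5 pN, the order of the observed
#'   ratcheting step rate, which makes slips negligible below stall.
#' @return An object of class \code{rate_constants}.
#' @examples
#' rc <- rate_constants()           # uni-cycle defaults
#' rc10 <- rate_constants(gating_g = 10)
#' @export
rate_constants <- function(atp_bind = 0.9,
                           adp_bind = 4.5,
                           adp_release_trail = 12,
                           p_release = 250,
                           step_fwd = 7000,
                           step_bwd = 0.65,
                           gating_g = 1,
                           atp_dissoc = 0,
                           p_bind = 0,
                           slip_fwd = 5e-10,
                           slip_bwd = 5e-10) {
  rc <- list(atp_bind = atp_bind, adp_bind = adp_bind,
             adp_release_trail = adp_release_trail, p_release = p_release,
             step_fwd = step_fwd, step_bwd = step_bwd,
             gating_g = gating_g, atp_dissoc = atp_dissoc, p_bind = p_bind,
             slip_fwd = slip_fwd, slip_bwd = slip_bwd)
  for (nm in names(rc)) {
    v <- rc[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("rate constant '", nm, "' must be a single number")
    if (v < 0) stop("rate constant '", nm, "' must be >= 0")
  }
  if (rc$gating_g < 1)
    stop("gating_g must be >= 1 (gating can only slow the leading head)")
  structure(rc, class = "rate_constants")
}

#' @export
#' @method print rate_constants
print.rate_constants <- function(x, ...) {
  cat("Rate constants (myosin V chemomechanical network)\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 18), format(v)), sep = "\n")
  invisible(x)
}

#' Resolve a named rate constant, including derived ones
#'
#' The leading-head ADP release rate is derived:
#' \code{adp_release_lead = adp_release_trail / gating_g}.
#' @param name rate-constant name.
#' @param rc a \code{\link{rate_constants}} object.
#' @return the bare rate value.
#' @keywords internal
resolve_rate <- function(name, rc) {
  if (name == "adp_release_lead") return(rc$adp_release_trail / rc$gating_g)
  if (is.null(rc[[name]])) stop("unknown rate constant '", name, "'")
  rc[[name]]
}

#' Load-dependence model for transition rates
#'
#' Mechanical forward/backward rates pick up Boltzmann factors
#' \code{exp(-theta * F * l / kBT)} and \code{exp((1 - theta) * F * l / kBT)},
#' which satisfy the thermodynamic balance ratio
#' \code{forward / backward = exp(-F * l / kBT)} for any load-sharing factor
#' theta.  The same factors apply to the main stepping transition and to the
#' mechanical slip steps of the branched network.
#'
#' Chemical rates are load-independent by default (\code{chem_force_mode =
#' "none"}).  The \code{"threshold"} policy suppresses only the two nucleotide
#' binding rates (ATP and ADP) above a threshold force by
#' \code{exp(-scale * (F - thr) * l / kBT)}; release rates are never affected.
#'
#' @param theta load-sharing factor of the mechanical transitions, in [0,1].
#' @param step_size motor step size l, nm.
#' @param kBT thermal energy, pN nm (4.114 at 298 K).
#' @param chem_force_mode \code{"none"} or \code{"threshold"}.
#' @param chem_force_threshold threshold force, pN (used by "threshold" mode).
#' @param chem_force_scale dimensionless suppression scale ("threshold" mode).
#' @return An object of class \code{force_model}.
#' @examples
#' fm <- force_model()                     # symmetric sharing, no chemical load
#' fm3 <- force_model(chem_force_mode = "threshold")  # superstall regime
#' @export
force_model <- function(theta = 0.5, step_size = 36, kBT = 4.114,
                        chem_force_mode = c("none", "threshold"),
                        chem_force_threshold = 2,
                        chem_force_scale = 1) {
  chem_force_mode <- match.arg(chem_force_mode)
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  if (step_size <= 0) stop("step_size must be > 0")
  if (kBT <= 0) stop("kBT must be > 0")
  structure(list(theta = theta, step_size = step_size, kBT = kBT,
                 chem_force_mode = chem_force_mode,
                 chem_force_threshold = chem_force_threshold,
                 chem_force_scale = chem_force_scale),
            class = "force_model")
}

#' @export
#' @method print force_model
print.force_model <- function(x, ...) {
  cat("Force model: theta =", x$theta, ", step size =", x$step_size,
      "nm, kBT =", x$kBT, "pN nm\n")
  cat("  chemical load dependence:", x$chem_force_mode)
  if (x$chem_force_mode == "threshold")
    cat(" (threshold ", x$chem_force_threshold, " pN, scale ",
        x$chem_force_scale, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Experimental condition: nucleotide concentrations and load
#'
#' @param atp,adp,p concentrations in uM (>= 0).
#' @param force external load in pN; positive values resist forward motion,
#'   negative values assist it.
#' @return An object of class \code{motor_condition}.
#' @examples
#' condition(atp = 1000)               # saturating ATP, no load
#' condition(atp = 2, adp = 0.1, force = 1)
#' @export
condition <- function(atp = 0, adp = 0, p = 0, force = 0) {
  for (nm in c("atp", "adp", "p")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("concentration '", nm, "' must be a single number >= 0")
  }
  if (!is.numeric(force) || length(force) != 1L || !is.finite(force))
    stop("force must be a single finite number")
  structure(list(atp = atp, adp = adp, p = p, force = force),
            class = "motor_condition")
}

#' @export
#' @method print motor_condition
print.motor_condition <- function(x, ...) {
  cat(sprintf("Condition: [ATP] = %g uM, [ADP] = %g uM, [P] = %g uM, F = %g pN\n",
              x$atp, x$adp, x$p, x$force))
  invisible(x)
}

# mechanical Boltzmann factor; direction "forward"/"backward"
mech_force_factor <- function(direction, cond, fm) {
  theta <- fm$theta
  fl <- cond$force * fm$step_size / fm$kBT
  expo <- if (direction == "forward") -theta * fl else (1 - theta) * fl
  if (!is.finite(expo)) stop("non-finite force exponent (|F l / kBT| overflow)")
  out <- exp(expo)
  if (!is.finite(out)) stop("force factor overflow at F = ", cond$force, " pN")
  out
}

# chemical load factor: 1 unless the threshold policy applies to this law
chem_force_factor <- function(kind, species, cond, fm) {
  if (fm$chem_force_mode == "none") return(1)
  if (kind != "binding" || !(species %in% c("ATP", "ADP"))) return(1)
  if (cond$force <= fm$chem_force_threshold) return(1)
  expo <- -fm$chem_force_scale *
    (cond$force - fm$chem_force_threshold) * fm$step_size / fm$kBT
  if (!is.finite(expo)) stop("non-finite force exponent in chemical factor")
  exp(expo)
}

#' Effective transition rate under a condition and force model
#'
#' Maps a bare rate constant and its rate law to the effective transition
#' rate: binding laws are first order in the named nucleotide concentration,
#' release laws are concentration-independent, and mechanical laws carry the
#' Boltzmann load factors of the force model.
#'
#' @param kappa bare rate constant (1/s, or 1/(uM s) for binding laws).
#' @param law a list describing the rate law: \code{list(type = "binding",
#'   species = "ATP")}, \code{list(type = "release", species = "ADP")}, or
#'   \code{list(type = "mechanical", direction = "forward", slip = FALSE)}.
#' @param cond a \code{\link{condition}}.
#' @param fm a \code{\link{force_model}}.
#' @return effective rate in 1/s (finite, >= 0).
#' @examples
#' transition_rate(0.9, list(type = "binding", species = "ATP"),
#'                 condition(atp = 1), force_model())   # 0.9 / s
#' @export
transition_rate <- function(kappa, law, cond, fm) {
  if (!is.numeric(kappa) || kappa < 0) stop("rate constant must be >= 0")
  type <- law$type
  if (type == "binding") {
    conc <- switch(law$species,
                   ATP = cond$atp, ADP = cond$adp, P = cond$p,
                   stop("undefined species '", law$species, "'"))
    rate <- kappa * conc * chem_force_factor("binding", law$species, cond, fm)
  } else if (type == "release") {
    rate <- kappa * chem_force_factor("release", law$species, cond, fm)
  } else if (type == "mechanical") {
    rate <- kappa * mech_force_factor(law$direction, cond, fm)
  } else {
    stop("unknown rate law type '", type, "'")
  }
  if (!is.finite(rate) || rate < 0) stop("effective rate is not a finite non-negative number")
  rate
}
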