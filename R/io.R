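# File formats.  All text, SI-unit column headers: s, nm, pN, 1/s, uM.
# Histograms always carry explicit bin edges; nothing is inferred on read.

#' Read / write a network description (JSON)
#'
#' The JSON schema mirrors the in-memory representation: \code{states[]} and
#' \code{transitions[]} with \code{from}, \code{to}, \code{rate},
#' \code{law\{type, species|direction, slip\}}, \code{offset},
#' \code{cycles[]}.  Two bundled files ship with the package:
#' \code{unicycle.json} and \code{branched_default.json} (see
#' \code{system.file("extdata", package = "dwellnet")}).
#'
#' @param path file path.
#' @param rc rate constants used to resolve rate names on read.
#' @return \code{read_network}: a \code{\link{motor_network}}.
#' @export
read_network <- function(path, rc = rate_constants(gating_g = 10)) {
  j <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stop("malformed network file '", path,
                                         "': ", conditionMessage(e)))
  if (is.null(j$states) || is.null(j$transitions))
    stop("network file lacks 'states' or 'transitions'")
  rows <- lapply(j$transitions, function(t) {
    law <- t$law
    tr_row(t$from, t$to, t$rate, law$type,
           species = if (is.null(law$species)) NA_character_ else law$species,
           direction = if (is.null(law$direction)) NA_character_ else law$direction,
           slip = isTRUE(law$slip), offset = t$offset,
           cycles = unlist(t$cycles))
  })
  motor_network(unlist(j$states), do.call(rbind, rows), rc,
                id = if (is.null(j$id)) "custom" else j$id)
}

#' @rdname read_network
#' @param net a \code{motor_network} to serialize.
#' @export
write_network <- function(net, path) {
  tr <- net$transitions
  jlist <- list(
    id = net$id,
    states = as.list(net$states),
    transitions = lapply(seq_len(nrow(tr)), function(i) {
      law <- list(type = tr$law[i])
      if (!is.na(tr$species[i])) law$species <- tr$species[i]
      if (!is.na(tr$direction[i])) law$direction <- tr$direction[i]
      if (tr$slip[i]) law$slip <- TRUE
      list(from = tr$from[i], to = tr$to[i], rate = tr$rate[i], law = law,
           offset = tr$offset[i], cycles = as.list(tr$cycles[[i]]))
    }))
  jsonlite::write_json(jlist, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read / write a rate-constant table (TSV: name, value)
#'
#' @param path file path.
#' @return \code{read_rates}: a \code{\link{rate_constants}} object; values
#'   present in the file override the defaults.
#' @export
read_rates <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("name", "value") %in% names(tab)))
    stop("rates table must have columns 'name' and 'value'")
  args <- as.list(stats::setNames(tab$value, tab$name))
  known <- names(formals(rate_constants))
  bad <- setdiff(names(args), known)
  if (length(bad)) stop("unknown rate constant(s) in table: ",
                        paste(bad, collapse = ", "))
  do.call(rate_constants, args)
}

#' @rdname read_rates
#' @param rc a \code{rate_constants} object.
#' @export
write_rates <- function(rc, path) {
  utils::write.table(data.frame(name = names(unlist(rc)), value = unlist(rc)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a histogram (CSV: t_lo, t_hi, density)
#'
#' Non-uniform bins are rejected on read.
#' @param path file path.
#' @return \code{read_histogram}: a \code{dwell_histogram}.
#' @export
read_histogram <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_lo", "t_hi", "density")
  if (!all(need %in% names(tab)))
    stop("histogram file must have columns t_lo, t_hi, density")
  w <- tab$t_hi - tab$t_lo
  if (any(abs(w - w[1]) > 1e-9 * w[1])) stop("non-uniform bins rejected")
  if (any(abs(tab$t_lo[-1] - tab$t_hi[-nrow(tab)]) > 1e-9 * w[1]))
    stop("bins must be contiguous")
  out <- tab[need]
  attr(out, "bin_width") <- w[1]
  attr(out, "n") <- NA_integer_
  class(out) <- c("dwell_histogram", "data.frame")
  out
}

#' @rdname read_histogram
#' @param h a \code{dwell_histogram}.
#' @export
write_histogram <- function(h, path) {
  utils::write.csv(data.frame(t_lo = h$t_lo, t_hi = h$t_hi,
                              density = h$density),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a dwell sample (CSV: dwell_s, prev, next)
#'
#' Zero or negative dwells are rejected (a dwell is a strictly positive
#' interval between two steps).
#' @param path file path.
#' @return \code{read_dwells}: a \code{dwell_sample}.
#' @export
read_dwells <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("dwell_s", "prev", "next")
  if (!all(need %in% names(tab)))
    stop("dwell file must have columns dwell_s, prev, next")
  dwell_sample(tab$dwell_s, tab$prev, tab[["next"]])
}

#' @rdname read_dwells
#' @param dw a \code{dwell_sample}.
#' @export
write_dwells <- function(dw, path) {
  utils::write.csv(as.data.frame(dw), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trajectory position trace (CSV: t_s, position_nm)
#'
#' @param traj a \code{motor_trajectory}.
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(trajectory_positions(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Export a dwell-time density on a grid (CSV: t_s, density)
#'
#' The grid is cubically graded towards 0 so that fast decay components are
#' resolved and the trapezoidal area of the file reproduces the unit
#' normalization tightly.
#'
#' @param d a \code{dwell_dist}.
#' @param path file path.
#' @param tmax grid end (default: 25 / slowest decay rate when the spectral
#'   representation is available, else 10 mean dwells).
#' @param n grid points.
#' @export
write_density <- function(d, path, tmax = NULL, n = 4000) {
  if (is.null(tmax)) {
    tmax <- if (d$method == "spectral") 25 / min(Re(d$rates)) else 10 * mean(d)
  }
  tt <- tmax * seq(0, 1, length.out = n)^3
  utils::write.csv(data.frame(t_s = tt, density = ddwell(d, tt)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
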