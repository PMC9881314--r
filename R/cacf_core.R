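# Coherence-adaptive clutter filtering: per pixel, select the clutter filter
# whose output maximizes local short-lag spatial coherence and emit that
# filter's velocity estimate.

#' Select the coherence-maximizing filter
#'
#' Argmax over per-filter SLSC values; exact ties (within 1e-12) are broken
#' toward the lower cutoff (the identity "no filter" member is lowest).
#'
#' @param slsc_by_filter Numeric vector of per-filter SLSC values at one
#'   pixel; `NA` entries are ignored.
#' @return List with `index` (winning bank member), `tie` (logical).
#' @export
select_optimal_filter <- function(slsc_by_filter) {
  ok <- is.finite(slsc_by_filter)
  if (!any(ok)) stop("all coherence values are undefined")
  mx <- max(slsc_by_filter[ok])
  winners <- which(ok & slsc_by_filter > mx - 1e-12)
  list(index = min(winners), tie = length(winners) > 1L)
}

#' Run coherence-adaptive clutter filtering on a channel ensemble
#'
#' Focuses and demodulates the ensemble once, then for every bank member
#' filters the channel slow-time signals, computes per-pixel SLSC and the
#' Kasai velocity of the beam-summed output, and finally selects per pixel
#' the member with maximal SLSC, copying its velocity estimate bit-exact
#' into the output map.
#'
#' @param ens A `cacf_ensemble`.
#' @param bank A `cacf_filter_bank`.
#' @param depths Pixel depths along the beam (metres).
#' @param Q Maximum short-lag for SLSC (default 10).
#' @param coherence_method Estimator passed to [coherence_function()].
#' @param kernel Axial velocity kernel in metres (default 1 wavelength).
#' @param max_lag Largest coherence lag to compute (default `max(Q, 20)` so
#'   SLSC can be re-evaluated at larger Q from the diagnostics).
#' @return An object of class `cacf_result`: `velocity`, `selection`
#'   (bank index per pixel), `slsc_win`, `tie`, `slsc_by_filter` (pixel x
#'   member), `velocity_by_filter`, `coherence_by_filter` (list of
#'   `cacf_coherence`), `bank_cutoffs`, `depths`, `Q`, `valid`.
#' @export
run_cacf <- function(ens, bank, depths, Q = 10,
                     coherence_method = "point", kernel = NULL,
                     max_lag = NULL) {
  if (length(bank) == 0) stop("empty filter bank")
  cfg <- ens$cfg
  if (attr(bank, "K") %||% bank[[1]]$K != cfg$ensemble_length) {
    stop("bank and ensemble disagree on the slow-time length K")
  }
  if (Q < 1 || Q > cfg$m_rx - 1) stop("Q out of range")
  if (is.null(max_lag)) max_lag <- max(Q, 20)
  max_lag <- min(max_lag, dim(ens$samples)[2] - 1L)
  iq0 <- focus_and_demodulate(ens, depths)
  np <- length(depths)
  nf <- length(bank)
  slsc_mat <- matrix(NA_real_, np, nf)
  vel_mat <- matrix(NA_real_, np, nf)
  coh_list <- vector("list", nf)
  for (fi in seq_len(nf)) {
    iqf <- iq0
    iqf$iq <- apply_filter(iq0$iq, bank[[fi]])
    coh <- coherence_function(iqf, lags = 0:max_lag,
                              method = coherence_method)
    coh_list[[fi]] <- coh
    slsc_mat[, fi] <- slsc(coh, Q)
    vm <- estimate_velocity(beamsum(iqf), cfg, kernel = kernel)
    vel_mat[, fi] <- vm$velocity
  }
  selection <- rep(NA_integer_, np)
  tie <- rep(FALSE, np)
  slsc_win <- rep(NA_real_, np)
  velocity <- rep(NA_real_, np)
  for (p in seq_len(np)) {
    if (!any(is.finite(slsc_mat[p, ]))) next  # invalid pixel: no selection
    sel <- select_optimal_filter(slsc_mat[p, ])
    selection[p] <- sel$index
    tie[p] <- sel$tie
    slsc_win[p] <- slsc_mat[p, sel$index]
    velocity[p] <- vel_mat[p, sel$index]
  }
  structure(list(velocity = velocity, selection = selection,
                 slsc_win = slsc_win, tie = tie,
                 slsc_by_filter = slsc_mat, velocity_by_filter = vel_mat,
                 coherence_by_filter = coh_list,
                 bank_cutoffs = bank_cutoffs(bank), depths = depths,
                 Q = Q, valid = !is.na(selection)),
            class = "cacf_result")
}

#' @export
print.cacf_result <- function(x, ...) {
  cat(sprintf("<cacf_result> %d pixels, %d bank members, Q=%d\n",
              length(x$velocity), ncol(x$slsc_by_filter), x$Q))
  cat(sprintf("  selected cutoffs: %s\n",
              paste(format(sort(unique(x$bank_cutoffs[x$selection]))),
                    collapse = " ")))
  invisible(x)
}

#' Fraction of pixels selecting the "no filter" member
#'
#' @param result A `cacf_result` (or an integer selection vector).
#' @param mask Logical vector marking the pixels to count (e.g. in-vessel);
#'   must select at least one pixel.
#' @return Fraction in `[0, 1]` of masked pixels whose selected member is
#'   the identity.
#' @export
no_filter_fraction <- function(result, mask) {
  sel <- if (inherits(result, "cacf_result")) result$selection else result
  if (!any(mask)) stop("mask selects no pixels")
  mean(sel[mask] == 1L, na.rm = TRUE)
}

#' Re-select filters from stored SLSC diagnostics at another Q
#'
#' Uses the per-filter coherence functions retained in a [run_cacf()] result
#' to recompute SLSC, the per-pixel selection, and the output velocity for a
#' different short-lag value without re-running the pipeline.
#'
#' @param result A `cacf_result` with `coherence_by_filter` diagnostics.
#' @param Q New maximum short-lag.
#' @return A `cacf_result` for the new Q.
#' @export
reselect_q <- function(result, Q) {
  nf <- length(result$coherence_by_filter)
  np <- length(result$velocity)
  slsc_mat <- matrix(NA_real_, np, nf)
  for (fi in seq_len(nf)) {
    slsc_mat[, fi] <- slsc(result$coherence_by_filter[[fi]], Q)
  }
  out <- result
  out$Q <- Q
  out$slsc_by_filter <- slsc_mat
  for (p in seq_len(np)) {
    if (!any(is.finite(slsc_mat[p, ]))) {
      out$selection[p] <- NA_integer_
      out$velocity[p] <- NA_real_
      next
    }
    sel <- select_optimal_filter(slsc_mat[p, ])
    out$selection[p] <- sel$index
    out$tie[p] <- sel$tie
    out$slsc_win[p] <- slsc_mat[p, sel$index]
    out$velocity[p] <- result$velocity_by_filter[p, sel$index]
  }
  out$valid <- !is.na(out$selection)
  out
}
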