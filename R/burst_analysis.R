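#' Population firing rate and characteristic spike spacing
#'
#' \eqn{\nu = N_s / T} (total spikes over covered time) and its inverse
#' \eqn{t_\nu = T / N_s}, the average spike spacing if spikes were uniformly
#' distributed.  `t_nu` is the reference scale for the burst-detection gap
#' threshold.
#'
#' @param raster a `spike_raster`.
#' @return list with `nu`, `t_nu` (NA with `undefined_t_nu = TRUE` for an
#'   empty raster) and `n_spikes`.
#' @export
firing_rate <- function(raster) {
  if (raster$duration <= 0) stop("raster duration must be > 0")
  ns <- nrow(raster$events)
  if (ns == 0L)
    return(list(nu = 0, t_nu = NA_real_, undefined_t_nu = TRUE, n_spikes = 0L))
  list(nu = ns / raster$duration, t_nu = raster$duration / ns,
       undefined_t_nu = FALSE, n_spikes = ns)
}

#' Detect network bursts in a spike raster
#'
#' Pooled spike times are split wherever the gap between consecutive spikes
#' is at least \eqn{\min(N t_\nu / 2,\ 3 d)}; groups in which fewer than
#' `participation` of the `N` neurons fire are discarded.  The rate-based
#' scale is the mean single-neuron interspike interval \eqn{N t_\nu =
#' N T / N_s} (computed on the full raster, before any splitting): the
#' pooled scale \eqn{t_\nu} itself degenerates for synchronized populations,
#' where every gap between burst slices exceeds it, and would cut each
#' slice into its own "burst".  For a single-neuron raster the two scales
#' coincide.  In practice `3 d` is the binding bound for bursting rasters:
#' consecutive slices inside a burst are separated by roughly one interspike
#' interval (at least `d`), while quiescent gaps are orders of magnitude
#' longer.
#'
#' @param raster a `spike_raster`.
#' @param d transmission delay (same time units as the raster).
#' @param N population size (defaults to the raster's).
#' @param participation minimum fraction of distinct neurons per burst
#'   (default 0.2).
#' @return data.frame of class `burst_events`, one row per burst: `start`,
#'   `end`, `spike_count`, `participants`; the member spike indices are kept
#'   in the `members` attribute (list of integer vectors into
#'   `raster$events`).
#' @export
detect_bursts <- function(raster, d, N = raster$N, participation = 0.2) {
  if (N <= 0) stop("N must be > 0")
  ev <- raster$events
  fr <- firing_rate(raster)
  empty <- structure(data.frame(start = numeric(0), end = numeric(0),
                                spike_count = integer(0),
                                participants = integer(0)),
                     members = list(), class = c("burst_events", "data.frame"))
  if (fr$undefined_t_nu) return(empty)
  thr <- min(N * fr$t_nu / 2, 3 * d)
  tms <- ev$time
  brk <- which(diff(tms) >= thr)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(tms))
  keep <- logical(length(starts))
  members <- vector("list", length(starts))
  for (g in seq_along(starts)) {
    idx <- starts[g]:ends[g]
    parts <- length(unique(ev$id[idx]))
    if (parts >= participation * N) {
      keep[g] <- TRUE
      members[[g]] <- idx
    }
  }
  if (!any(keep)) return(empty)
  members <- members[keep]
  out <- data.frame(
    start = tms[starts[keep]],
    end = tms[ends[keep]],
    spike_count = ends[keep] - starts[keep] + 1L,
    participants = vapply(members, function(i) length(unique(ev$id[i])), 1L))
  structure(out, members = members, class = c("burst_events", "data.frame"))
}

#' Burst and interburst statistics
#'
#' @param bursts a `burst_events` table from [detect_bursts()].
#' @param raster the `spike_raster` the bursts were detected in.
#' @param discard number of initial bursts to drop (synchronization
#'   transient; default 0).
#' @return list of class `burst_summary`: `ibis` (gaps between consecutive
#'   bursts, start minus previous end), `t_bs` (durations), `n_bursts`,
#'   `mean_ns` and `modal_ns` (mean/modal spikes per participating neuron
#'   per burst), `mean_isi` (mean intra-burst interspike interval of
#'   individual neurons) and `per_neuron_counts` (list of count tables).
#' @export
burst_statistics <- function(bursts, raster, discard = 0L) {
  members <- attr(bursts, "members")
  if (discard > 0L && nrow(bursts)) {
    sel <- seq_len(nrow(bursts)) > discard
    members <- members[sel]
    bursts <- bursts[sel, , drop = FALSE]
  }
  nb <- nrow(bursts)
  ev <- raster$events
  ibis <- if (nb >= 2L) bursts$start[-1] - bursts$end[-nb] else numeric(0)
  t_bs <- if (nb >= 1L) bursts$end - bursts$start else numeric(0)
  counts <- vector("list", nb)
  isis <- numeric(0)
  for (g in seq_len(nb)) {
    idx <- members[[g]]
    counts[[g]] <- table(ev$id[idx])
    sp <- split(ev$time[idx], ev$id[idx])
    gaps <- unlist(lapply(sp, function(tt) if (length(tt) > 1L) diff(sort(tt))))
    isis <- c(isis, gaps)
  }
  all_counts <- unlist(lapply(counts, as.integer))
  modal <- if (length(all_counts)) {
    tb <- table(all_counts)
    as.integer(names(tb)[which.max(tb)])
  } else NA_integer_
  structure(list(ibis = ibis, t_bs = t_bs, n_bursts = nb,
                 mean_ns = if (length(all_counts)) mean(all_counts) else NA_real_,
                 modal_ns = modal,
                 mean_isi = if (length(isis)) mean(isis) else NA_real_,
                 per_neuron_counts = counts),
            class = "burst_summary")
}

#' @export
print.burst_summary <- function(x, ...) {
  cat(sprintf("Burst summary: %d bursts\n", x$n_bursts))
  if (x$n_bursts) {
    cat(sprintf("  spikes/neuron/burst: modal = %d, mean = %.3g\n",
                x$modal_ns, x$mean_ns))
    cat(sprintf("  T_B: mean = %.4g;  IBI: mean = %.4g;  intra-burst ISI: mean = %.4g\n",
                mean(x$t_bs), if (length(x$ibis)) mean(x$ibis) else NA,
                x$mean_isi))
  }
  invisible(x)
}

#' Phase-space occupancy histogram of a trajectory
#'
#' Two-dimensional histogram of the sampled (V, w) states, the numerical
#' picture of the bursting attractor.  Bin edges are anchored at the origin
#' in both coordinates so histograms from different runs align.
#'
#' @param traj a `state_trajectory` (all recorded neurons are pooled), or a
#'   list with numeric `V` and `w`.
#' @param v_bin,w_bin bin widths; defaults 0.025 and 0.05 dimensionless
#'   (0.05 mV and 1 pA at the default physical scales).
#' @param log take `log1p` of the counts (occupancy spans decades because
#'   the state moves much faster through the burst than the recovery).
#' @return list with `counts` (matrix, V bins by w bins), `v_breaks`,
#'   `w_breaks`, `n` (total samples).
#' @export
attractor_histogram <- function(traj, v_bin = 0.025, w_bin = 0.05,
                                log = FALSE) {
  V <- as.numeric(traj$V); w <- as.numeric(traj$w)
  if (!length(V)) stop("empty trajectory")
  vi <- floor(V / v_bin); wi <- floor(w / w_bin)
  v_lev <- seq(min(vi), max(vi))
  w_lev <- seq(min(wi), max(wi))
  counts <- table(factor(vi, levels = v_lev), factor(wi, levels = w_lev))
  counts <- matrix(as.integer(counts), nrow = length(v_lev),
                   dimnames = NULL)
  if (log) counts <- log1p(counts)
  list(counts = counts,
       v_breaks = c(v_lev, max(v_lev) + 1) * v_bin,
       w_breaks = c(w_lev, max(w_lev) + 1) * w_bin,
       n = length(V))
}
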