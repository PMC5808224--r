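#' Simulation configuration
#'
#' @param dt integration step (dimensionless time; default 0.01, i.e. 0.2 ms
#'   at a 20 ms membrane time constant).  The transmission delay must be an
#'   integer multiple of `dt`.
#' @param duration total simulated time (dimensionless).
#' @param w_init_mean,w_init_sd initial adaptation drawn from a normal
#'   distribution.  Defaults 2.5 and 0.5 dimensionless, i.e. 50 pA and 10 pA
#'   at the default physical scales (gL ΔT = 20 pA).
#' @param v_init_low,v_init_high range of the uniform initial potential;
#'   `NULL` means `[Vr, 0]` (a desynchronized subthreshold start).
#' @param seed integer seed for the initial conditions.
#' @param record_ids 0-based ids of neurons whose (V, w) trajectories are
#'   stored (default: neuron 0).
#' @param record_every store every n-th step of the trajectory (default 1).
#' @param transient_bursts number of initial bursts to discard before
#'   computing statistics (used by downstream analysis; default 3).
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(dt = 0.01, duration = 100,
                              w_init_mean = 2.5, w_init_sd = 0.5,
                              v_init_low = NULL, v_init_high = NULL,
                              seed = 1L, record_ids = 0L, record_every = 1L,
                              transient_bursts = 3L) {
  if (dt <= 0) stop("dt must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  structure(list(dt = dt, duration = duration,
                 w_init_mean = w_init_mean, w_init_sd = w_init_sd,
                 v_init_low = v_init_low, v_init_high = v_init_high,
                 seed = as.integer(seed), record_ids = as.integer(record_ids),
                 record_every = as.integer(record_every),
                 transient_bursts = as.integer(transient_bursts)),
            class = "sim_config")
}

#' Spike raster
#'
#' @param id integer vector of 0-based neuron ids.
#' @param time numeric vector of spike times (same length), sorted ascending.
#' @param N population size.
#' @param duration covered time span.
#' @return object of class `spike_raster` with a two-column `events`
#'   data frame.
#' @export
spike_raster <- function(id, time, N, duration) {
  if (length(id) != length(time)) stop("id and time lengths differ")
  if (is.unsorted(time)) {
    o <- order(time)
    id <- id[o]; time <- time[o]
  }
  if (length(time) && (min(time) < 0 || max(time) > duration))
    stop("spike times outside [0, duration]")
  if (length(id) && (min(id) < 0 || max(id) >= N))
    stop("neuron ids outside [0, N)")
  structure(list(events = data.frame(id = as.integer(id), time = time),
                 N = as.integer(N), duration = duration),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("Spike raster: %d spikes from %d neurons over %g time units\n",
              nrow(x$events), x$N, x$duration))
  invisible(x)
}

#' Write / read a spike raster as two-column text (`neuron_id time`)
#' @param raster a `spike_raster`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_raster <- function(raster, path) {
  utils::write.table(raster$events, path, row.names = FALSE,
                     col.names = c("neuron_id", "time"), quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @param N,duration population size and time span; inferred from the file
#'   when omitted.
#' @export
read_raster <- function(path, N = NULL, duration = NULL) {
  df <- utils::read.table(path, header = TRUE)
  names(df) <- c("id", "time")
  if (is.null(N)) N <- if (nrow(df)) max(df$id) + 1L else 1L
  if (is.null(duration)) duration <- if (nrow(df)) max(df$time) else 0
  spike_raster(df$id, df$time, N, duration)
}

# ---- fixed-step engine --------------------------------------------------

# Integrates the dimensionless aEIF network with delayed alpha PSCs.
# adjacency in CSR-by-source form: ptr (length N+1, 1-based cumulative) and
# tgt (1-based target ids ordered by source).  deliver_gain is the increment
# applied to the auxiliary synaptic variable y1 per delivered presynaptic
# spike (s * I0 for unit-weight edges); an impulse A on y1 produces the
# current A * t * exp(-t / tau_s).
.sim_engine <- function(N, ptr, tgt, deliver_gain, p, syn, cfg,
                        V0, w0) {
  dt <- cfg$dt
  D <- round(syn$d / dt)
  if (abs(D * dt - syn$d) > 1e-9 * max(1, syn$d) || D < 1L)
    stop("config error: delay d must be a positive integer multiple of dt")
  n_steps <- ceiling(cfg$duration / dt)
  EL <- p$EL; Ie <- p$Ie; a <- p$a; tau_w <- p$tau_w
  Vr <- p$Vr; Vpeak <- p$Vpeak; b <- p$b
  Eprop <- exp(-dt / syn$tau_s)
  V <- V0; w <- w0
  y1 <- numeric(N); y2 <- numeric(N)
  buf <- matrix(0, nrow = D, ncol = N)
  rec_idx <- cfg$record_ids + 1L
  rec_idx <- rec_idx[rec_idx >= 1L & rec_idx <= N]
  every <- max(1L, cfg$record_every)
  n_rec <- length(rec_idx)
  n_samp <- if (n_rec) (n_steps %/% every) + 1L else 0L
  rec_t <- numeric(n_samp)
  rec_V <- matrix(NA_real_, n_samp, n_rec)
  rec_w <- matrix(NA_real_, n_samp, n_rec)
  samp <- 0L
  sp_id <- vector("list", 256L); sp_t <- vector("list", 256L); n_ev <- 0L
  t <- 0
  for (step in seq_len(n_steps)) {
    slot <- ((step - 1L) %% D) + 1L
    due <- buf[slot, ]
    buf[slot, ] <- 0
    # reset rule: a neuron above cutoff at step start spikes now
    spikers <- which(V > Vpeak)
    if (length(spikers)) {
      n_ev <- n_ev + 1L
      if (n_ev > length(sp_id)) {           # grow event storage
        sp_id <- c(sp_id, vector("list", length(sp_id)))
        sp_t <- c(sp_t, vector("list", length(sp_t)))
      }
      sp_id[[n_ev]] <- spikers - 1L
      sp_t[[n_ev]] <- rep.int(t, length(spikers))
      V[spikers] <- Vr
      w[spikers] <- w[spikers] + b
      # schedule PSC arrival at t + d in all out-neighbours
      nv <- ptr[spikers + 1L] - ptr[spikers]
      keep <- nv > 0L
      if (any(keep)) {
        idx <- sequence(nv[keep], from = ptr[spikers[keep]])
        buf[slot, ] <- buf[slot, ] + tabulate(tgt[idx], nbins = N)
      }
    }
    if (n_rec && (step - 1L) %% every == 0L) {
      samp <- samp + 1L
      rec_t[samp] <- t
      rec_V[samp, ] <- V[rec_idx]
      rec_w[samp, ] <- w[rec_idx]
    }
    y1 <- y1 + deliver_gain * due
    # exact propagation of the linear alpha-PSC system over dt gives the
    # end-of-step synaptic current, enabling an explicit Heun (2nd order)
    # update of (V, w); the exponential is clamped at Vpeak
    y2n <- (y2 + dt * y1) * Eprop
    f1V <- -(V - EL) + exp(pmin(V, Vpeak)) - w + Ie + y2
    f1w <- (a * (V - EL) - w) / tau_w
    Vp1 <- V + dt * f1V
    wp1 <- w + dt * f1w
    f2V <- -(Vp1 - EL) + exp(pmin(Vp1, Vpeak)) - wp1 + Ie + y2n
    f2w <- (a * (Vp1 - EL) - wp1) / tau_w
    V <- V + dt * 0.5 * (f1V + f2V)
    w <- w + dt * 0.5 * (f1w + f2w)
    y2 <- y2n
    y1 <- y1 * Eprop
    t <- t + dt
    if (step %% 2000L == 0L && anyNA(V + w))
      stop(sprintf("numerical blow-up: non-finite state at t = %g (dt too large?)", t))
  }
  if (!all(is.finite(V)) || !all(is.finite(w)))
    stop("numerical blow-up: non-finite state at end of run")
  id <- if (n_ev) unlist(sp_id[seq_len(n_ev)]) else integer(0)
  tm <- if (n_ev) unlist(sp_t[seq_len(n_ev)]) else numeric(0)
  traj <- NULL
  if (n_rec) {
    keep <- seq_len(samp)
    traj <- structure(list(t = rec_t[keep],
                           V = rec_V[keep, , drop = FALSE],
                           w = rec_w[keep, , drop = FALSE],
                           ids = rec_idx - 1L),
                      class = "state_trajectory")
  }
  list(raster = spike_raster(id, tm, N, cfg$duration), traj = traj,
       final = list(V = V, w = w))
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("State trajectory: %d samples, %d recorded neuron(s)\n",
              length(x$t), length(x$ids)))
  invisible(x)
}

#' Simulate an aEIF network with delayed alpha-shaped synapses
#'
#' Fixed-step integration of the full network system: each neuron follows the
#' dimensionless aEIF flow; when its potential exceeds `Vpeak` it is reset,
#' its adaptation is incremented by `b`, and one alpha-shaped PSC is
#' scheduled after the transmission delay `d` in every out-neighbour.  PSCs
#' superpose linearly and are integrated through an auxiliary linear system
#' updated with exact exponential propagators, with delivery through a ring
#' buffer of length `d/dt`.
#'
#' @param net a `directed_network`.
#' @param p an `aeif_dimless` parameter set.
#' @param syn a [synapse_params()] object (dimensionless units).
#' @param cfg a [simulation_config()].
#' @param V0,w0 optional explicit initial states (length-N vectors);
#'   otherwise drawn from the distributions in `cfg` using `cfg$seed`.
#' @return list with elements `raster` (a `spike_raster`), `traj` (a
#'   `state_trajectory` or NULL) and `final` (final state).
#' @export
simulate <- function(net, p, syn, cfg, V0 = NULL, w0 = NULL) {
  N <- net$N
  e <- net$edges
  o <- order(e[, "source"])
  tgt <- e[o, "target"] + 1L
  n_out <- tabulate(e[, "source"] + 1L, nbins = N)
  ptr <- c(1L, 1L + cumsum(n_out))
  set.seed(cfg$seed)
  if (is.null(w0)) w0 <- stats::rnorm(N, cfg$w_init_mean, cfg$w_init_sd)
  if (is.null(V0)) {
    lo <- if (is.null(cfg$v_init_low)) p$Vr else cfg$v_init_low
    hi <- if (is.null(cfg$v_init_high)) 0 else cfg$v_init_high
    V0 <- stats::runif(N, lo, hi)
  }
  .sim_engine(N, ptr, tgt, deliver_gain = syn$s * syn$I0,
              p = p, syn = syn, cfg = cfg, V0 = V0, w0 = w0)
}

#' Simulate the equivalent autapse neuron
#'
#' Single neuron whose own spikes return after the delay `d` as alpha PSCs
#' of strength `k_mean * s`: the mean-field reduction of a synchronized
#' fixed in-degree network with in-degree `k_mean`.  Serves as the numerical
#' oracle for the analytic burst model.
#'
#' @param k_mean effective in-degree multiplying the synaptic strength.
#' @inheritParams simulate
#' @param V0,w0 optional scalar initial state.
#' @return as [simulate()].
#' @export
simulate_equivalent_neuron <- function(k_mean, p, syn, cfg,
                                       V0 = NULL, w0 = NULL) {
  set.seed(cfg$seed)
  if (is.null(w0)) w0 <- stats::rnorm(1, cfg$w_init_mean, cfg$w_init_sd)
  if (is.null(V0)) {
    lo <- if (is.null(cfg$v_init_low)) p$Vr else cfg$v_init_low
    hi <- if (is.null(cfg$v_init_high)) 0 else cfg$v_init_high
    V0 <- stats::runif(1, lo, hi)
  }
  .sim_engine(1L, ptr = c(1L, 2L), tgt = 1L,
              deliver_gain = k_mean * syn$s * syn$I0,
              p = p, syn = syn, cfg = cfg, V0 = V0, w0 = w0)
}
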