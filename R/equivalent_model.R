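#' Burst-onset adaptation level
#'
#' A network burst starts when the slowly decaying adaptation current passes
#' under the minimum of the V-nullcline, \eqn{w_{min} = 1 + E_L + I_e}
#' (the value of [v_nullcline_w()] at \eqn{V = 0} with no synaptic input).
#' Only defined in the spiking regime (`Ie` above rheobase).
#'
#' @param p an `aeif_dimless` parameter set.
#' @return the onset value `w_min` (dimensionless current).
#' @export
burst_onset_w <- function(p) {
  if (has_stable_fixed_point(p))
    stop("non-spiking regime: Ie is below the rheobase current, no bursting")
  1 + p$EL + p$Ie
}

# classed error used to signal that no further spike can occur
.burst_end <- function(msg) {
  stop(structure(class = c("burst_end_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Quasi-static interspike interval at a given adaptation level
#'
#' Time between consecutive spikes inside a burst when the adaptation current
#' is frozen at `w` (valid because \eqn{\tau_w} is much larger than the
#' interspike interval).  For the Dirac coupling, the neuron decays from the
#' reset for one transmission delay `d`, receives the volley as an
#' instantaneous kick \eqn{\bar k Q_s}, and then climbs to the cutoff under
#' the frozen-`w` flow:
#' \deqn{t_s(w) = d + \int_{V_0}^{V_{peak}} \frac{dV}{e^V - V + E_L + I_e - w},
#'   \quad V_0 = V_l(d) + \bar k Q_s.}
#' For the continuous coupling the climb starts at the reset potential under
#' the constant burst current `I_const` (no discrete delivery).  The interval
#' grows monotonically with `w` and diverges as the start point approaches
#' the nullcline: this is what stretches the late burst slices.
#'
#' @param w frozen adaptation current.
#' @param p an `aeif_dimless` parameter set.
#' @param syn a [synapse_params()].
#' @param k_mean mean in-degree scaling the coupling.
#' @param model `"dirac"` (delayed kick) or `"continuous"` (constant current).
#' @param I_const constant synaptic current for the continuous model.
#' @return interspike interval (dimensionless time).  Throws a classed
#'   `burst_end_error` when no further spike can occur at this `w`.
#' @export
interspike_time <- function(w, p, syn, k_mean,
                            model = c("dirac", "continuous"), I_const = 0) {
  model <- match.arg(model)
  if (model == "dirac") {
    K <- k_mean * psc_charge(syn)
    V0 <- linearized_V(syn$d, p$Vr, w, p) + K
    wmin_eff <- 1 + p$EL + p$Ie
    thr <- if (w >= wmin_eff) nullcline_threshold_V(w, p) else -Inf
    if (V0 <= thr)
      .burst_end("burst terminates: post-delivery potential at or below the nullcline threshold")
    if (V0 >= p$Vpeak) return(syn$d)        # kick overshoots the cutoff
    u <- p$EL + p$Ie - w
    f <- function(V) 1 / (exp(V) - V + u)
    syn$d + stats::integrate(f, V0, p$Vpeak, rel.tol = 1e-10,
                             subdivisions = 500L)$value
  } else {
    u <- p$EL + p$Ie + I_const - w
    if (1 + u <= 0)                          # flow min at V = 0 is 1 + u
      .burst_end("burst terminates: adaptation above the shifted nullcline minimum")
    f <- function(V) 1 / (exp(V) - V + u)
    stats::integrate(f, p$Vr, p$Vpeak, rel.tol = 1e-10,
                     subdivisions = 500L)$value
  }
}

#' Number of spikes per burst
#'
#' \eqn{n_s = \lceil (w^* - w_{min})/b \rceil} (minimum 1): each burst spike
#' raises the adaptation by exactly `b` starting from the onset value, and
#' spiking stops once the termination threshold is passed.
#'
#' @param w_star termination threshold.
#' @param w_min onset value (`w_star >= w_min`).
#' @param b spike-triggered adaptation increment (> 0).
#' @return integer spike count.
#' @export
n_spikes <- function(w_star, w_min, b) {
  if (b <= 0) stop("unbounded burst: b must be > 0")
  if (w_star < w_min) stop("w_star must be >= w_min")
  max(1L, as.integer(ceiling((w_star - w_min) / b - 1e-12)))
}

#' Peak adaptation reached at burst end
#'
#' For fixed in-degree networks the adaptation moves by discrete steps of `b`
#' from `w_min`, so the peak is \eqn{w_{min} + n_s b}; with topological
#' heterogeneity the population average is smooth and the peak equals the
#' statistical termination threshold `w_star` itself.
#'
#' @inheritParams n_spikes
#' @param heterogeneous logical; TRUE for heterogeneous (Gaussian-like)
#'   networks.
#' @return peak adaptation `w_max`.
#' @export
w_max_of <- function(w_star, w_min, b, heterogeneous = FALSE) {
  if (heterogeneous) return(w_star)
  w_min + n_spikes(w_star, w_min, b) * b
}

#' Dirac-coupling termination threshold
#'
#' Solves the self-consistent termination condition for instantaneous
#' (Dirac) synapses on a synchronized fixed in-degree network: the
#' post-kick potential equals the right-branch nullcline threshold,
#' \deqn{V_r e^{-d} + (E_L + I_e - w^*)(1 - e^{-d}) + \bar k Q_s
#'   = V_{NV}(w^*),}
#' i.e. \eqn{w^* = E_L + I_e - V_r - e^{d}\,[W_{-1}(-e^{E_L + I_e - w^*}) +
#' \bar k Q_s]}, solved with Brent's method on a bracket
#' `[w_min, w_min + 100 b + 10 kQs]` (widened geometrically up to 5 times).
#'
#' @param p an `aeif_dimless` parameter set (spiking regime).
#' @param syn a [synapse_params()].
#' @param k_mean mean in-degree (`k_mean * psc_charge(syn) > 0`).
#' @return the threshold `w_star`; the residual of the self-consistent
#'   relation at the returned value is below 1e-10.
#' @export
solve_w_star_dirac <- function(p, syn, k_mean) {
  wmin <- burst_onset_w(p)
  K <- k_mean * psc_charge(syn)
  if (K <= 0) stop("no coupling: k_mean * Qs must be > 0")
  ed <- exp(-syn$d)
  resid <- function(w) {
    u <- p$EL + p$Ie - w
    r <- (p$Vr - u) * ed + K + lambert_wm1_exp(u)
    ifelse(is.finite(r), r, -1e12)
  }
  lo <- wmin
  if (resid(lo) <= 0)
    stop("no-bursting-solution: coupling too weak to sustain a second spike")
  hi <- wmin + 100 * p$b + 10 * K
  n_widen <- 0L
  while (resid(hi) > 0 && n_widen < 5L) {
    hi <- wmin + (hi - wmin) * 4
    n_widen <- n_widen + 1L
  }
  if (resid(hi) > 0)
    stop("no-bursting-solution: termination condition has no sign change ",
         "(one volley regenerates the burst indefinitely)")
  w_star <- stats::uniroot(resid, c(lo, hi), tol = 1e-13)$root
  if (abs(resid(w_star)) > 1e-10)
    stop("root-finder failed to reach residual < 1e-10")
  w_star
}

#' Continuous-coupling termination threshold
#'
#' Models a strongly heterogeneous burst as a constant synaptic current
#' \eqn{I_s^{(c)}} flowing for the whole burst.  Charge matching with the
#' spiking picture requires \eqn{I_s^{(c)} T_B = n_s \bar k Q_s}; the shifted
#' nullcline gives \eqn{w^* = 1 + E_L + I_e + I_s^{(c)}}; and the
#' termination self-consistency reads
#' \eqn{w^* = w_{min} + b[\bar t_s(w^*) - d] + \bar k Q_s} with
#' \eqn{\bar t_s = T_B/(n_s - 1)} the mean in-burst interspike interval.
#' Solved by damped fixed-point iteration (damping 0.5) over
#' \eqn{(I_s^{(c)}, n_s, T_B)} until successive `w_star` values differ by
#' less than `tol`.
#'
#' @inheritParams solve_w_star_dirac
#' @param tol convergence tolerance on `w_star` (default 1e-8).
#' @param max_iter iteration cap (default 200).
#' @return `w_star`, with attributes `I_s` (converged burst current),
#'   `n_s`, `T_B`, `tbar_s` and `iterations`.
#' @export
solve_w_star_continuous <- function(p, syn, k_mean, tol = 1e-8,
                                    max_iter = 200L) {
  wmin <- burst_onset_w(p)
  K <- k_mean * psc_charge(syn)
  if (K <= 0) stop("no coupling: k_mean * Qs must be > 0")
  Is <- max(K, p$b)                       # initial guess for the burst current
  w_star <- wmin + Is
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    ns <- n_spikes(wmin + Is, wmin, p$b)
    TB <- ns * K / Is                     # charge matching
    tbar <- TB / max(ns - 1L, 1L)
    w_new <- wmin + p$b * (tbar - syn$d) + K
    Is_new <- max(w_new - wmin, 1e-12)
    trace <- c(trace, w_new)
    if (it > 1L && abs(w_new - w_star) < tol) {
      out <- w_new
      attr(out, "I_s") <- Is_new
      attr(out, "n_s") <- n_spikes(out, wmin, p$b)
      attr(out, "T_B") <- attr(out, "n_s") * K / Is_new
      attr(out, "tbar_s") <- attr(out, "T_B") / max(attr(out, "n_s") - 1L, 1L)
      attr(out, "iterations") <- it
      return(out)
    }
    w_star <- w_new
    Is <- 0.5 * Is + 0.5 * Is_new         # damped update
    if (!is.finite(Is) || Is <= 0)
      stop("no-bursting-solution: continuous burst current collapsed to zero")
  }
  stop("iteration-failure: continuous model did not converge in ", max_iter,
       " iterations; trace tail: ",
       paste(signif(utils::tail(trace, 5), 8), collapse = ", "))
}

#' Alpha-coupling termination threshold (semi-numeric)
#'
#' For the full alpha-shaped kernel the V-nullcline moves during the burst
#' and a closed-form threshold is not available; instead the equivalent
#' autapse neuron is integrated from burst onset (`V = 0`, `w = w_min`) and
#' the burst end is detected when an interspike interval exceeds `cutoff`
#' times the previous one.  Returns the adaptation value at the last spike
#' (just before its increment), the semi-numeric analogue of the Dirac and
#' continuous thresholds, which it brackets.
#'
#' @inheritParams solve_w_star_dirac
#' @param dt integration step (default `min(0.01, tau_s/20)`).
#' @param duration simulated horizon (default 100 time units; extended
#'   automatically if the burst has not terminated).
#' @param cutoff interspike growth factor signalling termination (default 10).
#' @return `w_star`, with attributes `n_s`, `spike_times`, `isis`, `w_max`
#'   (value after the last increment) and `T_B`.
#' @export
solve_w_star_alpha <- function(p, syn, k_mean, dt = NULL, duration = 100,
                               cutoff = 10) {
  wmin <- burst_onset_w(p)
  if (is.null(dt)) dt <- min(0.01, syn$tau_s / 20)
  dt <- syn$d / max(1, round(syn$d / dt))   # make d a multiple of dt
  for (try in 1:3) {
    cfg <- simulation_config(dt = dt, duration = duration, seed = 1L,
                             record_ids = 0L, record_every = 1L)
    sim <- simulate_equivalent_neuron(k_mean, p, syn, cfg,
                                      V0 = 0, w0 = wmin)
    st <- sim$raster$events$time
    if (length(st) >= 1L) {
      isis <- diff(st)
      end_j <- length(st)
      if (length(isis) >= 2L) {
        grew <- which(isis[-1] > cutoff * isis[-length(isis)])
        if (length(grew)) end_j <- grew[1] + 1L
      }
      # terminated if a long quiet tail follows the last counted spike
      quiet <- duration - st[end_j]
      last_isi <- if (end_j > 1L) st[end_j] - st[end_j - 1L] else st[1]
      if (quiet > cutoff * last_isi || end_j < length(st)) {
        idx <- round(st[seq_len(end_j)] / dt) + 1L   # trajectory sample at spike
        w_at <- sim$traj$w[idx, 1L] - p$b            # recorded value is post-reset
        out <- as.numeric(w_at[end_j])
        attr(out, "n_s") <- end_j
        attr(out, "spike_times") <- st[seq_len(end_j)]
        attr(out, "isis") <- if (end_j > 1L) diff(st[seq_len(end_j)]) else numeric(0)
        attr(out, "w_max") <- as.numeric(out) + p$b
        attr(out, "T_B") <- st[end_j] - st[1]
        return(out)
      }
    }
    duration <- duration * 4                 # not terminated yet: extend
  }
  stop("alpha model: burst did not terminate within the simulated horizon")
}

#' In-burst duration from the quasi-static interspike chain
#'
#' \eqn{T_B = \sum_{j=1}^{n_s - 1} t_s(w_{min} + j b)}; zero for a
#' single-spike burst.
#'
#' @param ns spikes per burst.
#' @param w_min onset adaptation.
#' @inheritParams interspike_time
#' @return list with `T_B`, the per-interval `isis`, and their mean `tbar_s`.
#' @export
burst_duration <- function(ns, w_min, p, syn, k_mean,
                           model = c("dirac", "continuous"), I_const = 0) {
  model <- match.arg(model)
  if (ns < 1L) stop("ns must be >= 1")
  if (ns == 1L) return(list(T_B = 0, isis = numeric(0), tbar_s = NA_real_))
  isis <- vapply(seq_len(ns - 1L), function(j)
    interspike_time(w_min + j * p$b, p, syn, k_mean, model, I_const),
    numeric(1))
  list(T_B = sum(isis), isis = isis, tbar_s = mean(isis))
}

#' Post-burst recovery times
#'
#' After the last spike the neuron undergoes a strong hyperpolarization
#' (duration `T_down`, computed by integrating the uncoupled flow from
#' `(V_r, w_max)` until the potential minimum), then tracks the slow decay
#' of the adaptation current along its quasi-equilibrium
#' (`T_R`, closed form from the linearized recovery flow):
#' \deqn{T_R = \frac{\tau_w}{1 + a}\,
#'   \ln\!\frac{w^{(2)} - a I_e/(1 + a)}{w_{min} - a I_e/(1 + a)},}
#' and the interburst interval is \eqn{IBI = T_{down} + T_R + 1}, the final
#' 1 being the first-spike initiation time (one membrane time constant).
#'
#' @param p an `aeif_dimless` parameter set.
#' @param w_max peak adaptation at burst end.
#' @param w_min onset adaptation.
#' @param w2 adaptation at the start of the slow recovery; defaults to
#'   `w_max` (the hyperpolarization overshoot is brief on the `tau_w`
#'   scale).
#' @param dt integration step for the hyperpolarization segment.
#' @return list with `T_down`, `T_R`, `IBI`, `V_min` (lowest potential
#'   reached) and `w2` (value used).
#' @export
recovery_times <- function(p, w_max, w_min, w2 = NULL, dt = 0.005) {
  if (w_max <= w_min) stop("w_max must exceed w_min")
  wi <- p$a * p$Ie / (1 + p$a)
  if (w_min <= wi)
    stop("degenerate-recovery: w never decays to the onset value (no bursting)")
  if (is.null(w2)) w2 <- w_max
  down <- .hyperpolarization_descent(p, w_max, dt)
  T_R <- p$tau_w / (1 + p$a) * log((w2 - wi) / (w_min - wi))
  list(T_down = down$t, T_R = T_R, IBI = down$t + T_R + 1,
       V_min = down$V_min, w2 = w2)
}

# integrate the uncoupled flow from (Vr, w_max) to the potential minimum
# (classical RK4, fixed step); returns the descent time and the minimum
.hyperpolarization_descent <- function(p, w_max, dt = 0.005, t_max = 200) {
  f <- function(s) c(-(s[1] - p$EL) + exp(min(s[1], p$Vpeak)) - s[2] + p$Ie,
                     (p$a * (s[1] - p$EL) - s[2]) / p$tau_w)
  s <- c(p$Vr, w_max)
  t <- 0
  if (f(s)[1] >= 0)
    return(list(t = 0, V_min = p$Vr))      # no descent: already at/above minimum
  while (t < t_max) {
    k1 <- f(s); k2 <- f(s + dt / 2 * k1); k3 <- f(s + dt / 2 * k2)
    k4 <- f(s + dt * k3)
    s_new <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    if (f(s_new)[1] >= 0)
      return(list(t = t, V_min = s_new[1]))
    s <- s_new
  }
  stop("hyperpolarization descent did not reach a potential minimum by t = ", t_max)
}

#' Predict the full burst structure from the equivalent model
#'
#' Chains onset level, termination threshold (per coupling model), spikes
#' per burst, peak adaptation, in-burst interspike intervals, burst duration
#' and recovery times into a complete analytic description of the
#' synchronized bursting attractor, without simulating the network.
#'
#' @param p an `aeif_dimless` parameter set (spiking regime).
#' @param syn a [synapse_params()].
#' @param k_mean mean in-degree of the network.
#' @param model coupling idealization: `"dirac"` (instantaneous kicks,
#'   synchronized fixed in-degree networks), `"alpha"` (full kernel,
#'   semi-numeric), or `"continuous"` (constant burst current, strongly
#'   heterogeneous networks).
#' @param w2 recovery-start adaptation override (see [recovery_times()]).
#' @return object of class `burst_prediction`: fields `model`, `w_star`,
#'   `w_min`, `w_max`, `n_s`, `isis`, `T_B`, `T_down`, `T_R`, `IBI`, `nu`
#'   (mean rate `n_s / (IBI + T_B)`), `I_s` (continuous model only) and
#'   `w2`.
#' @export
#' @examples
#' p <- dimless_params(EL = -10, Vr = -4, Vpeak = 5, tau_w = 60,
#'                     a = 0.2, b = 3.5, Ie = 12)
#' syn <- synapse_params(s = 856, tau_s = 0.05, d = 0.15, I0 = 0.05)
#' predict_bursts(p, syn, k_mean = 100, model = "dirac")
predict_bursts <- function(p, syn, k_mean,
                           model = c("dirac", "alpha", "continuous"),
                           w2 = NULL) {
  model <- match.arg(model)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("predict[", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  wmin <- stage("onset", burst_onset_w(p))
  Is <- 0
  if (model == "dirac") {
    w_star <- stage("w_star", solve_w_star_dirac(p, syn, k_mean))
    ns <- n_spikes(w_star, wmin, p$b)
    wmax <- w_max_of(w_star, wmin, p$b, heterogeneous = FALSE)
    bd <- stage("isis", burst_duration(ns, wmin, p, syn, k_mean, "dirac"))
  } else if (model == "continuous") {
    w_star_a <- stage("w_star", solve_w_star_continuous(p, syn, k_mean))
    w_star <- as.numeric(w_star_a)
    Is <- attr(w_star_a, "I_s")
    ns <- n_spikes(w_star, wmin, p$b)
    wmax <- w_max_of(w_star, wmin, p$b, heterogeneous = TRUE)
    bd <- stage("isis", burst_duration(ns, wmin, p, syn, k_mean,
                                       "continuous", I_const = Is))
  } else {
    w_star_a <- stage("w_star", solve_w_star_alpha(p, syn, k_mean))
    w_star <- as.numeric(w_star_a)
    ns <- attr(w_star_a, "n_s")
    wmax <- as.numeric(attr(w_star_a, "w_max"))
    bd <- list(T_B = attr(w_star_a, "T_B"), isis = attr(w_star_a, "isis"),
               tbar_s = if (ns > 1) mean(attr(w_star_a, "isis")) else NA_real_)
  }
  rec <- stage("recovery", recovery_times(p, wmax, wmin, w2 = w2))
  pred <- structure(list(
    model = model, w_star = w_star, w_min = wmin, w_max = wmax,
    n_s = ns, isis = bd$isis, tbar_s = bd$tbar_s, T_B = bd$T_B,
    T_down = rec$T_down, T_R = rec$T_R, IBI = rec$IBI,
    nu = ns / (rec$IBI + bd$T_B), V_min = rec$V_min, I_s = Is,
    w2 = rec$w2), class = "burst_prediction")
  attr(pred, "scale") <- param_scale(p)
  stopifnot(pred$w_min <= pred$w_star + 1e-9,
            pred$w_star <= pred$w_max + 1e-9,
            pred$n_s >= 1, pred$T_B >= 0, pred$IBI >= 0)
  pred
}

#' @export
print.burst_prediction <- function(x, ...) {
  cat(sprintf("Burst prediction (%s coupling):\n", x$model))
  cat(sprintf("  w_min = %.4g  w* = %.4g  w_max = %.4g\n",
              x$w_min, x$w_star, x$w_max))
  cat(sprintf("  n_s = %d spikes/burst, T_B = %.4g, IBI = %.4g (T_down = %.3g, T_R = %.4g)\n",
              x$n_s, x$T_B, x$IBI, x$T_down, x$T_R))
  cat(sprintf("  mean ISI = %.4g, rate nu = %.4g, V_min = %.4g\n",
              ifelse(is.na(x$tbar_s), NA, x$tbar_s), x$nu, x$V_min))
  sc <- attr(x, "scale")
  if (!is.null(sc)) {
    tm <- sc$Cm / sc$gL
    cat(sprintf("  physical: T_B = %.4g ms, IBI = %.4g ms, w_max = %.4g pA, V_min = %.4g mV\n",
                x$T_B * tm, x$IBI * tm, x$w_max * sc$gL * sc$DeltaT,
                sc$Vth + x$V_min * sc$DeltaT))
  }
  invisible(x)
}

#' Burst prediction as a JSON-ready list
#'
#' @param pred a `burst_prediction`.
#' @return nested list with a `dimensionless` block and, when physical
#'   scales are attached, a `physical` block (ms, pA, mV).
#' @export
prediction_as_list <- function(pred) {
  dimless <- pred[c("model", "w_star", "w_min", "w_max", "n_s", "T_B",
                    "T_down", "T_R", "IBI", "nu", "tbar_s", "V_min", "I_s")]
  dimless$isis <- as.numeric(pred$isis)
  out <- list(dimensionless = dimless)
  sc <- attr(pred, "scale")
  if (!is.null(sc)) {
    tm <- sc$Cm / sc$gL; Iu <- sc$gL * sc$DeltaT
    out$physical <- list(
      T_B_ms = pred$T_B * tm, T_down_ms = pred$T_down * tm,
      T_R_ms = pred$T_R * tm, IBI_ms = pred$IBI * tm,
      rate_per_s = pred$nu / tm * 1000,
      w_star_pA = pred$w_star * Iu, w_min_pA = pred$w_min * Iu,
      w_max_pA = pred$w_max * Iu,
      V_min_mV = sc$Vth + pred$V_min * sc$DeltaT,
      isis_ms = as.numeric(pred$isis) * tm)
  }
  out
}
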