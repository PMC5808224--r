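#' Neuron state
#'
#' @param V membrane potential (dimensionless).
#' @param w adaptation current (dimensionless).
#' @param t time (dimensionless).
#' @return object of class `neuron_state`.
#' @export
neuron_state <- function(V, w, t = 0) {
  if (!all(is.finite(c(V, w, t)))) stop("neuron_state: non-finite values")
  structure(list(V = V, w = w, t = t), class = "neuron_state")
}

#' Dimensionless aEIF drift field
#'
#' Right-hand side of the subthreshold flow:
#' \eqn{\dot V = -(V - E_L) + e^V - w + I_e + I_{syn}},
#' \eqn{\dot w = (a (V - E_L) - w)/\tau_w}.
#'
#' @param state a [neuron_state()].
#' @param p an `aeif_dimless` parameter set.
#' @param I_syn instantaneous synaptic current (dimensionless), default 0.
#' @return list with elements `dV` and `dw`.
#' @export
drift <- function(state, p, I_syn = 0) {
  if (!all(is.finite(c(state$V, state$w)))) stop("drift: non-finite state")
  dV <- -(state$V - p$EL) + exp(state$V) - state$w + p$Ie + I_syn
  dw <- (p$a * (state$V - p$EL) - state$w) / p$tau_w
  list(dV = dV, dw = dw)
}

#' Apply the aEIF reset rule
#'
#' When the potential exceeds the cutoff `Vpeak`, the potential is reset to
#' `Vr` and the adaptation current is incremented by `b`; time is unchanged.
#'
#' @inheritParams drift
#' @return the reset [neuron_state()].
#' @export
apply_reset <- function(state, p) {
  neuron_state(V = p$Vr, w = state$w + p$b, t = state$t)
}

#' Rheobase drive of the dimensionless aEIF neuron
#'
#' Drive at which the V- and w-nullclines become tangent and the two fixed
#' points annihilate: \eqn{I_{rh} = (1 + a)(\ln(1 + a) - 1 - E_L)}.  For
#' \eqn{I_e > I_{rh}} no fixed point exists and the neuron spikes tonically;
#' below it a stable rest state exists.
#'
#' @param p an `aeif_dimless` parameter set (only `a` and `EL` are used).
#' @return the rheobase current (dimensionless).
#' @export
rheobase_current <- function(p) {
  (1 + p$a) * (log1p(p$a) - 1 - p$EL)
}

#' Does the neuron possess a stable rest state?
#'
#' TRUE iff `Ie < rheobase_current(p)` (strict: the degenerate tangency is
#' treated as spiking).
#'
#' @inheritParams rheobase_current
#' @return logical flag.
#' @export
has_stable_fixed_point <- function(p) {
  p$Ie < rheobase_current(p)
}

#' V-nullcline of the dimensionless aEIF model
#'
#' \eqn{w_{NV}(V) = -(V - E_L) + e^V + I_e + I_s}; its unique minimum sits at
#' \eqn{V = 0} with value \eqn{1 + E_L + I_e + I_s}, which is the
#' burst-onset adaptation level (see [burst_onset_w()]).
#'
#' @param V potential(s), dimensionless; vectorized.
#' @param p an `aeif_dimless` parameter set.
#' @param I_s constant synaptic current shifting the nullcline (default 0).
#' @return nullcline adaptation value(s) w.
#' @export
v_nullcline_w <- function(V, p, I_s = 0) {
  -(V - p$EL) + exp(V) + p$Ie + I_s
}

#' Effective spike threshold: right branch of the V-nullcline
#'
#' For adaptation `w` at or above the nullcline minimum, returns the
#' larger-V solution \eqn{V_{NV}(w)} of \eqn{w_{NV}(V) = w},
#' \deqn{V_{NV}(w) = u - W_{-1}(-e^{u}), \quad u = E_L + I_e + I_s - w,}
#' using the lower Lambert branch.  A trajectory delivered above this
#' potential escapes to a spike; below it, the potential decays.
#'
#' @param w adaptation value(s); vectorized.
#' @inheritParams v_nullcline_w
#' @return threshold potential(s) \eqn{V_{NV}(w) \ge 0}.
#' @export
nullcline_threshold_V <- function(w, p, I_s = 0) {
  wmin <- 1 + p$EL + p$Ie + I_s
  if (any(w < wmin - 1e-12))
    stop("no nullcline crossing: w below the nullcline minimum (burst cannot terminate there)")
  u <- p$EL + p$Ie + I_s - w
  u - lambert_wm1_exp(u)
}

#' Linearized subthreshold membrane solution
#'
#' Solution of the flow with the exponential term dropped and `w` frozen:
#' \eqn{V_l(t) = V_0 e^{-t} + (E_L + I_e - w)(1 - e^{-t})}.  Valid while the
#' potential stays well below threshold; used for the decay segment between a
#' spike and the delayed arrival of its network echo.
#'
#' @param t time(s) since the segment start (>= 0); vectorized.
#' @param V0 initial potential (the reset potential for post-spike segments).
#' @param w frozen adaptation current.
#' @param p an `aeif_dimless` parameter set.
#' @param I_s additional constant current (default 0).
#' @return potential(s) at time `t`.
#' @export
linearized_V <- function(t, V0, w, p, I_s = 0) {
  if (any(t < 0)) stop("linearized_V: t must be >= 0")
  Vinf <- p$EL + p$Ie + I_s - w
  V0 * exp(-t) + Vinf * (1 - exp(-t))
}

#' Alpha-shaped post-synaptic current kernel
#'
#' Current at time `t` after delivery (the caller applies the transmission
#' delay): 0 for `t <= 0`, otherwise
#' \eqn{m \, s I_0 \, t \, e^{-t/\tau_s}} for multiplicity `m` simultaneous
#' presynaptic spikes.  Peaks at \eqn{t = \tau_s} with value
#' \eqn{m s I_0 \tau_s / e}.
#'
#' @param t time(s) since delivery; vectorized.
#' @param syn a [synapse_params()] object.
#' @param multiplicity number of simultaneous presynaptic spikes (>= 0).
#' @return synaptic current(s), dimensionless.
#' @export
alpha_psc_current <- function(t, syn, multiplicity = 1) {
  if (multiplicity < 0) stop("multiplicity must be >= 0")
  ifelse(t > 0, multiplicity * syn$s * syn$I0 * t * exp(-t / syn$tau_s), 0)
}

#' Total charge of one alpha-shaped PSC
#'
#' \eqn{Q_s = s I_0 \tau_s^2}, the integral of the kernel over all time.
#'
#' @param syn a [synapse_params()] object.
#' @return transferred charge (dimensionless).
#' @export
psc_charge <- function(syn) {
  syn$s * syn$I0 * syn$tau_s^2
}
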