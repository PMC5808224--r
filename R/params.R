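#' Physiological aEIF parameters
#'
#' Bundle of adaptive exponential integrate-and-fire (aEIF) neuron parameters
#' in physical units.  The model reads
#' \deqn{C_m \dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_{th})/\Delta_T}
#'   - w + I_e + I_s,}
#' \deqn{\tau_w \dot w = a (V - E_L) - w,}
#' with reset \eqn{V \leftarrow V_r}, \eqn{w \leftarrow w + b} when
#' \eqn{V > V_{peak}}.
#'
#' @param Cm membrane capacitance (pF).
#' @param gL leak conductance (nS).
#' @param EL resting potential (mV).
#' @param DeltaT spike slope factor (mV).
#' @param Vth threshold potential (mV).
#' @param Vr reset potential (mV); must satisfy `Vr < Vth` (single-spike,
#'   non-bursting cells).
#' @param Vpeak spike cutoff (mV).
#' @param tau_w adaptation timescale (ms); must exceed the membrane time
#'   constant `Cm/gL`.
#' @param a subthreshold adaptation conductance (nS).
#' @param b spike-triggered adaptation increment (pA).
#' @param Ie constant external drive (pA).
#' @return object of class `aeif_phys`.
#' @seealso [to_dimensionless()]
#' @export
aeif_params <- function(Cm, gL, EL, DeltaT, Vth, Vr, Vpeak, tau_w, a, b, Ie) {
  p <- list(Cm = Cm, gL = gL, EL = EL, DeltaT = DeltaT, Vth = Vth, Vr = Vr,
            Vpeak = Vpeak, tau_w = tau_w, a = a, b = b, Ie = Ie)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("aeif_params: '", nm, "' must be a finite numeric scalar")
  }
  if (Cm <= 0)  stop("invalid parameters: Cm > 0 violated")
  if (gL <= 0)  stop("invalid parameters: gL > 0 violated")
  if (DeltaT <= 0) stop("invalid parameters: DeltaT > 0 violated")
  if (tau_w <= 0)  stop("invalid parameters: tau_w > 0 violated")
  if (a < 0) stop("invalid parameters: a >= 0 violated")
  if (b < 0) stop("invalid parameters: b >= 0 violated")
  if (!(Vr < Vth)) stop("invalid parameters: Vr < Vth violated (intrinsic bursting excluded)")
  if (!(tau_w > Cm / gL))
    stop("invalid parameters: tau_w > Cm/gL violated (adaptation must be slow)")
  structure(p, class = "aeif_phys")
}

#' Dimensionless aEIF parameters
#'
#' Parameters of the dimensionless aEIF system
#' \deqn{\dot V = -(V - E_L) + e^V - w + I_e + I_s, \qquad
#'   \tau_w \dot w = a (V - E_L) - w,}
#' where potentials are measured in units of the slope factor
#' \eqn{\Delta_T} relative to the threshold (so the threshold maps to 0),
#' currents in units of \eqn{g_L \Delta_T}, and time in units of the membrane
#' time constant \eqn{\tau_m = C_m / g_L}.
#'
#' @param EL,Vr,Vpeak dimensionless resting, reset and cutoff potentials;
#'   `Vr < 0 < Vpeak` is required.
#' @param tau_w dimensionless adaptation time (membrane time constants),
#'   must be much larger than 1.
#' @param a dimensionless subthreshold adaptation coupling (>= 0).
#' @param b dimensionless spike-triggered increment (>= 0).
#' @param Ie dimensionless external drive.
#' @param scale optional named list (`Vth`, `DeltaT`, `gL`, `Cm`) recording
#'   the physical scales; carried along so results can be reported in
#'   physical units.
#' @return object of class `aeif_dimless`.
#' @export
dimless_params <- function(EL, Vr, Vpeak, tau_w, a, b, Ie, scale = NULL) {
  p <- list(EL = EL, Vr = Vr, Vpeak = Vpeak, tau_w = tau_w,
            a = a, b = b, Ie = Ie)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("dimless_params: '", nm, "' must be a finite numeric scalar")
  }
  if (!(Vr < 0)) stop("invalid parameters: Vr < 0 violated (reset above threshold)")
  if (!(Vpeak > 0)) stop("invalid parameters: Vpeak > 0 violated")
  if (tau_w <= 1) stop("invalid parameters: tau_w >> 1 violated")
  if (a < 0) stop("invalid parameters: a >= 0 violated")
  if (b < 0) stop("invalid parameters: b >= 0 violated")
  if (!is.null(scale)) {
    need <- c("Vth", "DeltaT", "gL", "Cm")
    if (!all(need %in% names(scale)))
      stop("scale must provide ", paste(need, collapse = ", "))
  }
  structure(p, scale = scale, class = "aeif_dimless")
}

#' Map physiological aEIF parameters to the dimensionless system
#'
#' Applies the change of variables \eqn{V = (\tilde V - \tilde V_{th}) /
#' \tilde\Delta_T}, \eqn{w = \tilde w / (\tilde g_L \tilde\Delta_T)},
#' \eqn{t = \tilde t \, \tilde g_L / \tilde C_m}, currents scaled by
#' \eqn{\tilde g_L \tilde\Delta_T}, \eqn{a = \tilde a / \tilde g_L},
#' \eqn{b = \tilde b / (\tilde g_L \tilde \Delta_T)} and
#' \eqn{\tau_w = \tilde\tau_w \tilde g_L / \tilde C_m}.  This mapping is the
#' unique affine rescaling that turns the physical equations into the
#' dimensionless form with a bare \eqn{e^V} term and unit coefficient on
#' \eqn{(V - E_L)}.
#'
#' @param p an [aeif_params()] object.
#' @return an [dimless_params()] object with the physical scales attached.
#' @export
#' @examples
#' p <- aeif_params(Cm = 200, gL = 10, EL = -70, DeltaT = 2, Vth = -50,
#'                  Vr = -58, Vpeak = -40, tau_w = 1200, a = 2, b = 70,
#'                  Ie = 240)
#' to_dimensionless(p)
to_dimensionless <- function(p) {
  stopifnot(inherits(p, "aeif_phys"))
  Iu <- p$gL * p$DeltaT                   # current unit, pA
  dimless_params(
    EL     = (p$EL - p$Vth) / p$DeltaT,
    Vr     = (p$Vr - p$Vth) / p$DeltaT,
    Vpeak  = (p$Vpeak - p$Vth) / p$DeltaT,
    tau_w  = p$tau_w * p$gL / p$Cm,
    a      = p$a / p$gL,
    b      = p$b / Iu,
    Ie     = p$Ie / Iu,
    scale  = list(Vth = p$Vth, DeltaT = p$DeltaT, gL = p$gL, Cm = p$Cm)
  )
}

#' @export
print.aeif_dimless <- function(x, ...) {
  cat("Dimensionless aEIF parameters:\n")
  cat(sprintf("  E_L = %g  V_r = %g  V_peak = %g\n", x$EL, x$Vr, x$Vpeak))
  cat(sprintf("  tau_w = %g  a = %g  b = %g  I_e = %g\n",
              x$tau_w, x$a, x$b, x$Ie))
  sc <- attr(x, "scale")
  if (!is.null(sc))
    cat(sprintf("  scales: Vth = %g mV, DeltaT = %g mV, gL = %g nS, Cm = %g pF (tau_m = %g ms)\n",
                sc$Vth, sc$DeltaT, sc$gL, sc$Cm, sc$Cm / sc$gL))
  invisible(x)
}

#' @export
print.aeif_phys <- function(x, ...) {
  cat("Physiological aEIF parameters:\n")
  cat(sprintf("  Cm = %g pF, gL = %g nS (tau_m = %g ms)\n", x$Cm, x$gL, x$Cm / x$gL))
  cat(sprintf("  EL = %g, Vth = %g, Vr = %g, Vpeak = %g mV, DeltaT = %g mV\n",
              x$EL, x$Vth, x$Vr, x$Vpeak, x$DeltaT))
  cat(sprintf("  tau_w = %g ms, a = %g nS, b = %g pA, Ie = %g pA\n",
              x$tau_w, x$a, x$b, x$Ie))
  invisible(x)
}

#' Synaptic parameters for alpha-shaped post-synaptic currents
#'
#' A presynaptic spike at time \eqn{t_j} produces, after a transmission delay
#' \eqn{d}, the current \eqn{I(t) = s I_0 (t - t_j - d) e^{-(t - t_j -
#' d)/\tau_s}} in every postsynaptic target.  The total transferred charge is
#' \eqn{Q_s = s I_0 \tau_s^2} (see [psc_charge()]).
#'
#' All quantities are in the dimensionless units of [dimless_params()]; the
#' default unit current `I0` corresponds to 1 pA expressed in units of
#' \eqn{g_L \Delta_T} when a `scale` is supplied.
#'
#' @param s synaptic strength (>= 0).
#' @param tau_s synaptic time constant (> 0, membrane time constants).
#' @param d transmission delay (> 0, membrane time constants).
#' @param I0 unit current; dimensionless equivalent of 1 pA, i.e.
#'   \eqn{1/(g_L \Delta_T)} for the scales in use.
#' @return object of class `synapse_params` with derived field `Qs`.
#' @export
synapse_params <- function(s, tau_s, d, I0 = 1) {
  for (v in list(s = s, tau_s = tau_s, d = d, I0 = I0))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("synapse_params: all fields must be finite numeric scalars")
  if (tau_s <= 0) stop("invalid parameters: tau_s > 0 violated")
  if (d <= 0) stop("invalid parameters: d > 0 violated")
  if (s < 0) stop("invalid parameters: s >= 0 violated")
  if (I0 <= 0) stop("invalid parameters: I0 > 0 violated")
  structure(list(s = s, tau_s = tau_s, d = d, I0 = I0,
                 Qs = s * I0 * tau_s^2),
            class = "synapse_params")
}

#' @export
print.synapse_params <- function(x, ...) {
  cat(sprintf("Alpha synapse: s = %g, tau_s = %g, d = %g, I0 = %g  (Qs = %g)\n",
              x$s, x$tau_s, x$d, x$I0, x$Qs))
  invisible(x)
}

# ---- unit conversion helpers -------------------------------------------

#' Physical scales of a dimensionless parameter set
#' @param p an `aeif_dimless` object.
#' @return the scale list, or NULL when the set was built directly in
#'   dimensionless form.
#' @export
param_scale <- function(p) attr(p, "scale")

#' Convert dimensionless quantities to physical units
#'
#' @param x numeric vector of dimensionless values.
#' @param scale scale list as attached by [to_dimensionless()].
#' @param what one of `"time"` (to ms), `"current"` (to pA),
#'   `"potential"` (to mV), `"rate"` (to 1/ms).
#' @return numeric vector in physical units.
#' @export
to_physical <- function(x, scale, what = c("time", "current", "potential", "rate")) {
  what <- match.arg(what)
  if (is.null(scale)) stop("no physical scale attached to these parameters")
  switch(what,
    time      = x * scale$Cm / scale$gL,
    current   = x * scale$gL * scale$DeltaT,
    potential = scale$Vth + x * scale$DeltaT,
    rate      = x * scale$gL / scale$Cm)
}

# ---- parameter file I/O -------------------------------------------------

#' Read a neuron/synapse parameter file
#'
#' YAML file with a mandatory top-level `units:` field (`physical` or
#' `dimensionless`), a `neuron:` block, and optionally a `synapse:` block and
#' a `network:` block (`k_mean`, `k_sd`, `N`).  Physical files are converted
#' to dimensionless immediately; mixed unit systems are refused.
#'
#' @param path path to a YAML parameter file.
#' @return list with elements `neuron` (`aeif_dimless`), `synapse`
#'   (`synapse_params` or NULL), `network` (list or NULL) and `units`
#'   (declared unit system of the file).
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$units) || !cfg$units %in% c("physical", "dimensionless"))
    stop("parameter file must declare units: physical|dimensionless")
  if (is.null(cfg$neuron)) stop("parameter file must contain a 'neuron' block")
  nb <- cfg$neuron
  if (cfg$units == "physical") {
    need <- c("Cm", "gL", "EL", "DeltaT", "Vth", "Vr", "Vpeak", "tau_w", "a", "b", "Ie")
    miss <- setdiff(need, names(nb))
    if (length(miss)) stop("neuron block missing fields: ", paste(miss, collapse = ", "))
    phys <- do.call(aeif_params, nb[need])
    p <- to_dimensionless(phys)
    syn <- NULL
    if (!is.null(cfg$synapse)) {
      sb <- cfg$synapse
      miss <- setdiff(c("s", "tau_s_ms", "d_ms"), names(sb))
      if (length(miss)) stop("synapse block missing fields: ", paste(miss, collapse = ", "))
      tau_m <- phys$Cm / phys$gL
      syn <- synapse_params(s = sb$s, tau_s = sb$tau_s_ms / tau_m,
                            d = sb$d_ms / tau_m, I0 = 1 / (phys$gL * phys$DeltaT))
    }
  } else {
    need <- c("EL", "Vr", "Vpeak", "tau_w", "a", "b", "Ie")
    miss <- setdiff(need, names(nb))
    if (length(miss)) stop("neuron block missing fields: ", paste(miss, collapse = ", "))
    if (any(c("Cm", "gL", "Vth", "DeltaT") %in% names(nb)))
      stop("mixed unit systems refused: physical fields in a dimensionless file")
    p <- do.call(dimless_params, nb[need])
    syn <- NULL
    if (!is.null(cfg$synapse)) {
      sb <- cfg$synapse
      miss <- setdiff(c("s", "tau_s", "d"), names(sb))
      if (length(miss)) stop("synapse block missing fields: ", paste(miss, collapse = ", "))
      syn <- synapse_params(s = sb$s, tau_s = sb$tau_s, d = sb$d,
                            I0 = if (is.null(sb$I0)) 1 else sb$I0)
    }
  }
  list(neuron = p, synapse = syn, network = cfg$network, units = cfg$units)
}
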