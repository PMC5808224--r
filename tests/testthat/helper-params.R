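# Shared fixtures, built in code.

# reference dimensionless parameter set (oscillatory, quasi-static
# adaptation) and its synapse; identical to set1_parameters() but spelled
# out so unit tests do not depend on the packaged constants
ref_params <- function() {
  dimless_params(EL = -10, Vr = -4, Vpeak = 5, tau_w = 60,
                 a = 0.2, b = 3.5, Ie = 12,
                 scale = list(Vth = -50, DeltaT = 2, gL = 10, Cm = 200))
}

ref_synapse <- function(s = 856) {
  synapse_params(s = s, tau_s = 0.05, d = 0.15, I0 = 0.05)
}

ref_phys <- function() {
  aeif_params(Cm = 200, gL = 10, EL = -70, DeltaT = 2, Vth = -50,
              Vr = -58, Vpeak = -40, tau_w = 1200, a = 2, b = 70, Ie = 240)
}

# brute-force rheobase: bisect on Ie over a dense sign-scan of the
# fixed-point equation e^V - (1+a)(V - EL) + Ie on V in [-50, 5]
grid_rheobase <- function(EL, a, vgrid = seq(-50, 5, length.out = 20001)) {
  has_fp <- function(Ie) {
    f <- exp(vgrid) - (1 + a) * (vgrid - EL) + Ie
    any(f <= 0)
  }
  lo <- -100; hi <- 100
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (has_fp(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
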