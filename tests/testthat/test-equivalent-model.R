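test_that("burst onset sits at the nullcline minimum", {
  p <- ref_params()
  expect_equal(burst_onset_w(p), 3)
  expect_equal(burst_onset_w(p), v_nullcline_w(0, p))
  # numerical minimization oracle
  expect_equal(burst_onset_w(p),
               optimize(function(V) v_nullcline_w(V, p), c(-20, 10))$objective,
               tolerance = 1e-6)
  sub <- dimless_params(-10, -4, 5, 60, 0.2, 3.5, Ie = 5)
  expect_error(burst_onset_w(sub), "non-spiking")
})

test_that("dirac threshold solves its equation and grows with coupling", {
  p <- ref_params()
  ws_prev <- -Inf
  for (s in c(700, 800, 900, 1000)) {
    syn <- ref_synapse(s)
    ws <- solve_w_star_dirac(p, syn, 100)
    # residual of the self-consistent relation
    u <- p$EL + p$Ie - ws
    res <- (p$Vr - u) * exp(-syn$d) + 100 * psc_charge(syn) + lambert_wm1(-exp(u))
    expect_lt(abs(res), 1e-10)
    # equivalently: post-kick potential meets the threshold branch
    V0 <- linearized_V(syn$d, p$Vr, ws, p) + 100 * psc_charge(syn)
    expect_equal(V0, nullcline_threshold_V(ws, p), tolerance = 1e-9)
    expect_gt(ws, ws_prev)
    ws_prev <- ws
  }
  expect_error(solve_w_star_dirac(p, ref_synapse(5), 100), "no-bursting")
})

test_that("continuous solver meets all three of its defining relations", {
  p <- ref_params(); syn <- ref_synapse()
  K <- 100 * psc_charge(syn)
  ws <- solve_w_star_continuous(p, syn, 100)
  Is <- attr(ws, "I_s"); ns <- attr(ws, "n_s")
  TB <- attr(ws, "T_B"); tbar <- attr(ws, "tbar_s")
  expect_equal(as.numeric(ws), 1 + p$EL + p$Ie + Is)           # nullcline
  expect_lt(abs(Is * TB - ns * K), 1e-6)                        # charge match
  expect_lt(abs(as.numeric(ws) - (3 + p$b * (tbar - syn$d) + K)), 1e-6)
  expect_equal(ns, n_spikes(as.numeric(ws), 3, p$b))
})

test_that("alpha solution shrinks to the dirac one as tau_s -> 0 at fixed charge", {
  p <- ref_params()
  # coupling chosen mid-band of the 3-spike regime via the exact inverse of
  # the dirac termination relation (well away from ill-conditioned counts)
  w_target <- 3 + 2.5 * p$b
  u <- p$EL + p$Ie - w_target
  K <- -((p$Vr - u) * exp(-0.15) + lambert_wm1(-exp(u)))
  syn_d <- synapse_params(s = K / (100 * 0.05 * 0.05^2), tau_s = 0.05,
                          d = 0.15, I0 = 0.05)
  wd <- solve_w_star_dirac(p, syn_d, 100)
  expect_equal(wd, w_target, tolerance = 1e-8)
  wmax_d <- w_max_of(wd, 3, p$b)
  ts <- 0.004
  syn_a <- synapse_params(s = K / (100 * 0.05 * ts^2), tau_s = ts,
                          d = 0.15, I0 = 0.05)
  wa <- solve_w_star_alpha(p, syn_a, 100)
  expect_equal(as.numeric(attr(wa, "w_max")), wmax_d, tolerance = 0.03)
})

test_that("alpha solution lies between the continuous and dirac thresholds", {
  p <- ref_params()
  for (s in c(808, 856, 904)) {
    syn <- ref_synapse(s)
    wd <- solve_w_star_dirac(p, syn, 100)
    wc <- as.numeric(solve_w_star_continuous(p, syn, 100))
    wa <- as.numeric(solve_w_star_alpha(p, syn, 100))
    expect_gte(wa, min(wd, wc))
    expect_lte(wa, max(wd, wc))
  }
})

test_that("spike count is the ceiling of the adaptation gap over b", {
  expect_equal(n_spikes(10, 0, 3.5), 3L)
  expect_equal(n_spikes(7, 0, 3.5), 2L)
  expect_equal(n_spikes(0.1, 0, 3.5), 1L)
  expect_equal(n_spikes(0, 0, 3.5), 1L)
  expect_error(n_spikes(10, 0, 0), "unbounded")
  expect_error(n_spikes(-1, 0, 1), "w_min")
})

test_that("peak adaptation follows the discrete or smooth form as appropriate", {
  expect_equal(w_max_of(12, 2, 3.5, heterogeneous = TRUE), 12)
  expect_equal(w_max_of(12, 2, 3.5, heterogeneous = FALSE), 2 + 3 * 3.5)
  # exact multiple: (w*-wmin)=10.5 is 3 steps
  expect_equal(w_max_of(12.5, 2, 3.5), 2 + 3 * 3.5)
})

test_that("interspike interval grows with adaptation and stretches near termination", {
  # moderate coupling so that no delivery overshoots the cutoff (an
  # overshooting kick fires immediately and pins the interval at d)
  p <- ref_params(); syn <- ref_synapse(700)
  ws <- solve_w_star_dirac(p, syn, 100)
  K <- 100 * psc_charge(syn)
  w_lo <- 3 + p$b
  expect_lt(linearized_V(syn$d, p$Vr, w_lo, p) + K, p$Vpeak)
  ts_lo <- interspike_time(w_lo, p, syn, 100, "dirac")
  prev <- -Inf
  for (w in seq(w_lo, ws - 0.05, length.out = 12)) {
    ts <- interspike_time(w, p, syn, 100, "dirac")
    expect_gt(ts, prev)
    prev <- ts
  }
  expect_gte(interspike_time(ws - 1e-6, p, syn, 100, "dirac"), 5 * ts_lo)
  expect_error(interspike_time(ws + 0.5, p, syn, 100, "dirac"),
               class = "burst_end_error")
  # dirac intervals match the event-driven oracle interval by interval
  orc <- event_driven_dirac_burst(p, syn, 100)
  for (j in seq_len(orc$n_s - 1)) {
    ts <- interspike_time(3 + j * p$b, p, syn, 100, "dirac")
    expect_equal(ts, orc$isis[j], tolerance = 0.1)
  }
})

test_that("burst duration is the sum of the interspike chain", {
  p <- ref_params(); syn <- ref_synapse()
  expect_equal(burst_duration(1, 3, p, syn, 100)$T_B, 0)
  b3 <- burst_duration(3, 3, p, syn, 100)
  expect_equal(b3$T_B,
               interspike_time(3 + p$b, p, syn, 100) +
               interspike_time(3 + 2 * p$b, p, syn, 100))
  expect_equal(b3$tbar_s, mean(b3$isis))
})

test_that("recovery: closed form specializes at a = 0 and IBI scales with tau_w", {
  p0 <- dimless_params(-10, -4, 5, 60, a = 0, b = 3.5, Ie = 12)
  rec <- recovery_times(p0, w_max = 24, w_min = 3)
  expect_equal(rec$T_R, 60 * log(24 / 3))
  expect_equal(rec$IBI, rec$T_down + rec$T_R + 1)
  # w2 override is honoured
  rec2 <- recovery_times(p0, 24, 3, w2 = 20)
  expect_equal(rec2$T_R, 60 * log(20 / 3))
  expect_error(recovery_times(dimless_params(-10, -4, 5, 60, 5, 3.5, 12),
                              24, 3), "degenerate-recovery")
  # IBI approximately linear in tau_w over a 10x sweep
  taus <- seq(20, 200, length.out = 10)
  ibis <- vapply(taus, function(tw) {
    pp <- dimless_params(-10, -4, 5, tw, 0.2, 3.5, 12)
    recovery_times(pp, 24, 3)$IBI
  }, numeric(1))
  expect_gt(summary(lm(ibis ~ taus))$r.squared, 0.99)
})

test_that("prediction chain keeps its structural invariants", {
  p <- ref_params(); syn <- ref_synapse()
  for (model in c("dirac", "alpha", "continuous")) {
    pred <- predict_bursts(p, syn, 100, model = model)
    expect_lte(pred$w_min, pred$w_star + 1e-9)
    expect_lte(pred$w_star, pred$w_max + 1e-9)
    expect_gte(pred$n_s, 1)
    expect_gte(pred$T_B, 0)
    expect_equal(pred$IBI, pred$T_down + pred$T_R + 1)
    expect_equal(pred$nu, pred$n_s / (pred$IBI + pred$T_B))
  }
  pd <- predict_bursts(p, syn, 100, model = "dirac")
  expect_equal(pd$w_max - pd$w_min, pd$n_s * p$b)      # fixed in-degree form
  # stage names surface in errors
  expect_error(predict_bursts(dimless_params(-10, -4, 5, 60, 0.2, 3.5, 5),
                              syn, 100), "predict\\[onset\\]")
})

test_that("vanishing coupling degenerates to tonic spiking", {
  # deep quasi-static regime: the cycle decomposition (descent + recovery +
  # first-spike initiation) is asymptotic in tau_w, so the 5 percent match
  # to the true tonic period is asserted there
  p <- dimless_params(EL = -10, Vr = -4, Vpeak = 5, tau_w = 400,
                      a = 0.2, b = 3.5, Ie = 12)
  pred <- NULL
  for (s in c(290, 310)) {
    syn <- ref_synapse(s)
    pred <- tryCatch(predict_bursts(p, syn, 100, model = "dirac"),
                     error = function(e) NULL)
    if (!is.null(pred)) break
  }
  expect_false(is.null(pred))
  expect_lte(pred$n_s, 2)
  cfg <- simulation_config(dt = 0.005, duration = 4000, seed = 1)
  tonic <- simulate_equivalent_neuron(0, p, ref_synapse(0), cfg)
  isi_tonic <- mean(tail(diff(tonic$raster$events$time), 3))
  expect_equal(pred$IBI + pred$T_B, isi_tonic, tolerance = 0.05)
})

test_that("batch predictors agree with the scalar solvers", {
  p <- ref_params()
  ss <- c(700, 760, 820, 880, 940, 1000)
  K <- vapply(ss, function(s) 100 * psc_charge(ref_synapse(s)), numeric(1))
  n <- length(ss)
  bd <- predict_dirac_batch(rep(p$EL, n), rep(p$Vr, n), rep(p$Vpeak, n),
                            rep(p$tau_w, n), rep(p$a, n), rep(p$b, n),
                            rep(p$Ie, n), K, rep(0.15, n))
  bc <- predict_continuous_batch(rep(p$EL, n), rep(p$Vr, n), rep(p$Vpeak, n),
                                 rep(p$tau_w, n), rep(p$a, n), rep(p$b, n),
                                 rep(p$Ie, n), K, rep(0.15, n))
  for (i in seq_len(n)) {
    syn <- ref_synapse(ss[i])
    wd <- solve_w_star_dirac(p, syn, 100)
    expect_equal(bd$w_star[i], wd, tolerance = 1e-8)
    expect_equal(bd$n_s[i], n_spikes(wd, 3, p$b))
    pd <- predict_bursts(p, syn, 100, "dirac")
    expect_equal(bd$IBI[i], pd$IBI, tolerance = 0.02)
    expect_equal(bd$T_B[i], pd$T_B, tolerance = 0.02)
    # the continuous fixed point can fail to exist at an n_s boundary
    # (period-2 cycle of the damped iteration); scalar and batch must agree
    # on both outcomes
    wc <- tryCatch(solve_w_star_continuous(p, syn, 100),
                   error = function(e) e)
    if (inherits(wc, "error")) {
      expect_match(conditionMessage(wc), "iteration-failure")
      expect_false(bc$ok[i])
    } else {
      expect_true(bc$ok[i])
      expect_equal(bc$w_star[i], as.numeric(wc), tolerance = 1e-6)
    }
  }
})
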