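#' Parameter ranges for the aEIF parameter-space exploration
#'
#' Uniform sampling bounds, in physical units, spanning plausible cortical
#' aEIF values.  All bounds are user-configurable; the defaults were chosen
#' once to cover adaptive oscillatory regimes with a comfortable acceptance
#' fraction through the validity filters.
#'
#' @param ... named `c(low, high)` overrides for any of `Cm` (pF), `gL`
#'   (nS), `EL`, `Vth`, `Vr` (mV), `DeltaT` (mV), `tau_w` (ms), `a` (nS),
#'   `b` (pA), `Ie` (pA).
#' @return named list of `c(low, high)` bounds, class `parameter_ranges`.
#' @export
parameter_ranges <- function(...) {
  rg <- list(Cm = c(100, 300), gL = c(5, 15), EL = c(-75, -60),
             DeltaT = c(1, 3), Vth = c(-55, -45), Vr = c(-68, -48),
             tau_w = c(300, 2000), a = c(0, 4), b = c(10, 120),
             Ie = c(100, 500))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(rg)) stop("unknown parameter: ", nm)
    v <- over[[nm]]
    if (length(v) != 2L || v[1] >= v[2]) stop("range for ", nm, " must be c(low, high)")
    rg[[nm]] <- v
  }
  structure(rg, class = "parameter_ranges")
}

#' Draw random parameter sets
#'
#' Independent uniform draws per parameter over the given ranges;
#' reproducible under `seed`.
#'
#' @param ranges a [parameter_ranges()] list.
#' @param n number of sets.
#' @param seed integer RNG seed.
#' @return data.frame with one column per parameter and `n` rows.
#' @export
sample_parameter_sets <- function(ranges, n, seed) {
  set.seed(as.integer(seed))
  out <- lapply(unclass(ranges), function(rg) stats::runif(n, rg[1], rg[2]))
  as.data.frame(out)
}

#' Biological validity filter for one parameter set
#'
#' A parameter set is accepted iff (1) it is in the spiking regime (no
#' stable fixed point), (2) the equivalent model returned a coherent
#' bursting solution, (3) the predicted post-burst potential stays at or
#' above -120 mV, (4) the predicted peak adaptation current stays at or
#' below 1000 pA, and (5) the reset lies below threshold (no intrinsic
#' cellular bursting).  All violated rules are reported.
#'
#' @param p an `aeif_dimless` parameter set with physical scales attached.
#' @param pred a `burst_prediction`, or anything else (e.g. a failure
#'   condition or NULL) when the model produced no solution.
#' @param v_floor_mV,w_ceiling_pA filter thresholds.
#' @return list with `accept` (logical) and `reasons` (character vector of
#'   violated rules, empty when accepted).
#' @export
validity_filter <- function(p, pred, v_floor_mV = -120, w_ceiling_pA = 1000) {
  sc <- param_scale(p)
  if (is.null(sc)) stop("validity_filter needs physical scales on the parameter set")
  reasons <- character(0)
  if (has_stable_fixed_point(p)) reasons <- c(reasons, "stable-fixed-point")
  if (!(p$Vr < 0)) reasons <- c(reasons, "intrinsic-bursting")
  if (!inherits(pred, "burst_prediction")) {
    reasons <- c(reasons, "no-solution")
  } else {
    if (sc$Vth + pred$V_min * sc$DeltaT < v_floor_mV)
      reasons <- c(reasons, "voltage-floor")
    if (pred$w_max * sc$gL * sc$DeltaT > w_ceiling_pA)
      reasons <- c(reasons, "adaptation-ceiling")
  }
  list(accept = length(reasons) == 0L, reasons = reasons)
}

#' Explore the aEIF parameter space through the equivalent model
#'
#' Samples parameter sets, pushes them through the vectorized Dirac-model
#' predictor, applies the biological validity filters, and correlates burst
#' properties (IBI, burst duration, spikes per burst, mean in-burst ISI; in
#' physical units) with the neuronal parameters.
#'
#' @param n number of sets to draw.
#' @param seed integer RNG seed.
#' @param ranges a [parameter_ranges()] list.
#' @param synapse physical synapse description: list with `s`, `tau_s_ms`,
#'   `d_ms`.
#' @param k_mean mean in-degree of the (implicit) network.
#' @param model coupling idealization used for the batch predictions;
#'   `"continuous"` (default: the spike-driven increment `b` enters the
#'   termination threshold directly, and large random ensembles are
#'   heterogeneous-network-like) or `"dirac"`.
#' @param pca also return the principal-component decomposition of the
#'   standardized accepted table (default FALSE).
#' @return object of class `exploration_result`: `accepted` (params +
#'   predicted properties, physical units), `rejections` (named counts per
#'   filter), `n_sampled`, `correlation` (parameters x properties Pearson
#'   matrix), optionally `pca`.
#' @export
explore <- function(n, seed, ranges = parameter_ranges(),
                    synapse = list(s = 856, tau_s_ms = 1, d_ms = 3),
                    k_mean = 100, model = c("continuous", "dirac"),
                    pca = FALSE) {
  model <- match.arg(model)
  tab <- sample_parameter_sets(ranges, n, seed)
  Iu <- tab$gL * tab$DeltaT
  tau_m <- tab$Cm / tab$gL
  EL <- (tab$EL - tab$Vth) / tab$DeltaT
  Vr <- (tab$Vr - tab$Vth) / tab$DeltaT
  Vpeak <- rep(5, n)                      # cutoff convention: Vth + 5 DeltaT
  tau_w <- tab$tau_w / tau_m
  a <- tab$a / tab$gL
  b <- tab$b / Iu
  Ie <- tab$Ie / Iu
  tau_s <- synapse$tau_s_ms / tau_m
  d <- synapse$d_ms / tau_m
  K <- k_mean * synapse$s * (1 / Iu) * tau_s^2
  res <- if (model == "dirac")
    predict_dirac_batch(EL, Vr, Vpeak, tau_w, a, b, Ie, K, d)
  else predict_continuous_batch(EL, Vr, Vpeak, tau_w, a, b, Ie, K, d,
                                w_max_form = "ceiling")
  reason <- res$reason
  # reset at or above threshold dominates every other rule
  bursting_cell <- Vr >= 0
  reason[bursting_cell] <- "intrinsic-bursting"
  ok <- res$ok & !bursting_cell
  v_min_mV <- tab$Vth + res$V_min * tab$DeltaT
  w_max_pA <- res$w_max * Iu
  floor_bad <- ok & v_min_mV < -120
  reason[floor_bad] <- "voltage-floor"
  ceil_bad <- ok & !floor_bad & w_max_pA > 1000
  reason[ceil_bad] <- "adaptation-ceiling"
  ok <- ok & !floor_bad & !ceil_bad
  accepted <- cbind(tab[ok, , drop = FALSE],
                    data.frame(IBI = res$IBI[ok] * tau_m[ok],
                               T_B = res$T_B[ok] * tau_m[ok],
                               n_s = res$n_s[ok],
                               mean_ISI = res$mean_isi[ok] * tau_m[ok],
                               w_max_pA = w_max_pA[ok],
                               V_min_mV = v_min_mV[ok]))
  rej <- table(reason[!ok])
  corr <- correlation_matrix(accepted)
  out <- list(accepted = accepted,
              rejections = stats::setNames(as.integer(rej), names(rej)),
              n_sampled = n, n_accepted = sum(ok),
              correlation = corr, seed = as.integer(seed),
              k_mean = k_mean, synapse = synapse, model = model)
  if (pca) {
    cols <- c(names(parameter_ranges()), c("IBI", "T_B", "n_s", "mean_ISI"))
    cols <- intersect(cols, names(accepted))
    out$pca <- stats::prcomp(accepted[, cols], center = TRUE, scale. = TRUE)
  }
  structure(out, class = "exploration_result")
}

#' @export
print.exploration_result <- function(x, ...) {
  cat(sprintf("Parameter-space exploration: %d sampled, %d accepted (%.1f%%)\n",
              x$n_sampled, x$n_accepted, 100 * x$n_accepted / x$n_sampled))
  if (length(x$rejections)) {
    cat("  rejections:\n")
    for (nm in names(x$rejections))
      cat(sprintf("    %-20s %d\n", nm, x$rejections[[nm]]))
  }
  cat("  correlation of parameters with burst properties:\n")
  print(round(x$correlation, 2))
  invisible(x)
}

#' Parameter/property Pearson correlation matrix
#'
#' Standardizes every column (zero mean, unit variance) and computes the
#' pairwise Pearson correlations between neuronal parameters and predicted
#' burst properties.  Constant columns yield NA entries (flagged with a
#' warning).
#'
#' @param accepted data.frame of accepted parameter sets with prediction
#'   columns, as produced by [explore()].
#' @param params,properties column subsets to correlate.
#' @return matrix (parameters in rows, properties in columns), entries in
#'   `[-1, 1]` or NA.
#' @export
correlation_matrix <- function(accepted,
                               params = c("EL", "DeltaT", "Vth", "Vr",
                                          "tau_w", "a", "b", "Ie", "Cm", "gL"),
                               properties = c("IBI", "T_B", "n_s", "mean_ISI")) {
  params <- intersect(params, names(accepted))
  properties <- intersect(properties, names(accepted))
  if (!nrow(accepted)) stop("no accepted rows to correlate")
  z <- scale(as.matrix(accepted[, c(params, properties)]))
  const <- attr(z, "scaled:scale") == 0 | !is.finite(attr(z, "scaled:scale"))
  if (any(const)) {
    warning("constant column(s): ", paste(colnames(z)[const], collapse = ", "),
            " - correlations undefined")
    z[, const] <- NA_real_
  }
  m <- suppressWarnings(stats::cor(z[, params, drop = FALSE],
                                   z[, properties, drop = FALSE],
                                   use = "pairwise.complete.obs"))
  m
}
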