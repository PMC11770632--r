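# 1:1 binding-model fits used for hit confirmation, plus forward
# simulators for parameter-recovery studies.
#
# Models:
#   SPR steady state   R(C) = Rmax * C / (C + KD)
#   SPR/BLI kinetics   association  R(t) = C*Rmax/(C+KD) * (1 - exp(-(ka*C+kd) t))
#                      dissociation R(t) = R0 * exp(-kd t),  KD = kd/ka
#   DSF melt           F(T) = Fmin + (Fmax - Fmin) / (1 + exp((Tm - T)/slope))
#   FP displacement    4-parameter logistic; the displacement constant is
#                      reported as the inflection (IC50)
# Nonlinear least squares via Levenberg-Marquardt (minpack.lm).

.fit_result <- function(parameters, se, residual_norm, converged,
                        flags = character(0), kind) {
  structure(list(parameters = parameters, se = se,
                 residual_norm = residual_norm, converged = converged,
                 flags = flags, kind = kind),
            class = "bind_fit")
}

#' @export
print.bind_fit <- function(x, ...) {
  cat(sprintf("bind_fit (%s): %s\n", x$kind,
              if (x$converged) "converged" else "NOT converged"))
  for (nm in names(x$parameters))
    cat(sprintf("  %-6s %.6g (se %.3g)\n", nm, x$parameters[[nm]],
                if (nm %in% names(x$se)) x$se[[nm]] else NA))
  cat(sprintf("  residual norm %.4g\n", x$residual_norm))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a titration series
#'
#' @param concentration analyte concentrations (molar), strictly
#'   increasing and positive.
#' @param response measured responses (RU, polarization or fluorescence).
#' @param kind assay kind label.
#' @return a `titration_series` data.frame.
#' @export
titration_series <- function(concentration, response,
                             kind = c("spr_steady", "fp", "dsf")) {
  kind <- match.arg(kind)
  stopifnot(length(concentration) == length(response),
            all(concentration > 0), !is.unsorted(concentration, strictly = TRUE))
  structure(data.frame(concentration = concentration, response = response),
            kind = kind, class = c("titration_series", "data.frame"))
}

#' Fit the 1:1 steady-state affinity model
#'
#' Least-squares fit of `R(C) = Rmax * C / (C + KD)` with positive
#' parameter bounds. A series with no appreciable curvature over the
#' tested range (response effectively linear in concentration) is
#' flagged non-converged.
#'
#' @param ts a `titration_series` (or data.frame with `concentration`,
#'   `response`), at least 4 concentrations.
#' @return a `bind_fit` with `KD` (molar) and `Rmax`.
#' @export
fit_steady_state <- function(ts) {
  stopifnot(nrow(ts) >= 4L)
  C <- ts$concentration; R <- ts$response
  start <- list(KD = stats::median(C), Rmax = max(R) * 1.5)
  fit <- try(minpack.lm::nlsLM(R ~ Rmax * C / (C + KD), start = start,
                               lower = c(KD = 1e-15, Rmax = 1e-12),
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    # a hyperbola degenerates to a line when KD >> max(C); diagnose that
    # regime explicitly so the caller can tell it from a numeric failure
    lin <- stats::lm(R ~ 0 + C)
    r2 <- 1 - sum(stats::resid(lin)^2) / sum((R - mean(R))^2)
    flags <- if (r2 > 0.999) "no_curvature" else "fit_failed"
    return(.fit_result(c(KD = NA, Rmax = NA), c(), Inf, FALSE,
                       flags, "spr_steady"))
  }
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  resid_norm <- sqrt(sum(stats::resid(fit)^2))
  flags <- character(0)
  converged <- TRUE
  # curvature check: a KD far above the top concentration means the data
  # constrain only the linear regime Rmax/KD, not KD itself
  if (est["KD"] > 50 * max(C)) {
    flags <- c(flags, "no_curvature")
    converged <- FALSE
  }
  .fit_result(est, se, resid_norm, converged, flags, "spr_steady")
}

#' Simulate or construct a sensorgram
#'
#' @param time time grid (s) covering association then dissociation.
#' @param traces matrix (time x concentration) of responses.
#' @param concentrations analyte concentrations (molar), one per column.
#' @param t_assoc end of the association window (s); dissociation starts
#'   there.
#' @return a `sensorgram` list.
#' @export
sensorgram <- function(time, traces, concentrations, t_assoc) {
  traces <- as.matrix(traces)
  stopifnot(length(time) == nrow(traces),
            length(concentrations) == ncol(traces),
            t_assoc > min(time), t_assoc < max(time))
  structure(list(time = time, traces = traces,
                 concentrations = concentrations, t_assoc = t_assoc),
            class = "sensorgram")
}

.kinetic_traces <- function(time, conc, ka, kd, rmax, t_assoc, r0 = NULL) {
  KD <- kd / ka
  sapply(seq_along(conc), function(j) {
    C <- conc[j]
    req <- C * rmax / (C + KD)
    kobs <- ka * C + kd
    assoc <- req * (1 - exp(-kobs * pmin(time, t_assoc)))
    r_end <- if (is.null(r0)) req * (1 - exp(-kobs * t_assoc)) else r0[j]
    ifelse(time <= t_assoc, assoc, r_end * exp(-kd * (time - t_assoc)))
  })
}

#' Global kinetic fit of a 1:1 binding model
#'
#' Used for SPR and BLI sensorgrams alike.
#' Association and dissociation phases of all concentrations are fitted
#' jointly with shared `ka`, `kd`, `Rmax` (and a per-curve dissociation
#' amplitude `R0`); `KD` is reported as `kd/ka`. Rate constants are
#' fitted on the log scale to keep them positive. When the dissociation
#' window shows essentially no decay (`kd * t_dissoc < 0.01`) the rate
#' estimates are flagged as unreliable.
#'
#' @param sg a `sensorgram`.
#' @return a `bind_fit` with `ka` (1/(M s)), `kd` (1/s), `KD` (M), `Rmax`.
#' @export
fit_kinetic_1to1 <- function(sg) {
  stopifnot(inherits(sg, "sensorgram"))
  time <- sg$time; conc <- sg$concentrations; t_assoc <- sg$t_assoc
  y <- as.numeric(sg$traces)
  nconc <- length(conc)

  # starting values: kd from the tail decay, ka from kobs regression
  rmax0 <- max(sg$traces)
  kd0 <- 0.5 / (max(time) - t_assoc)
  ka0 <- kd0 / (stats::median(conc))
  p0 <- c(log_ka = log(ka0), log_kd = log(kd0), rmax = rmax0 * 1.2,
          stats::setNames(as.numeric(sg$traces[which.min(abs(time - t_assoc)), ]),
                          paste0("r0_", seq_len(nconc))))

  resid_fn <- function(p) {
    ka <- exp(p[["log_ka"]]); kd <- exp(p[["log_kd"]])
    r0 <- as.numeric(p[paste0("r0_", seq_len(nconc))])
    pred <- .kinetic_traces(time, conc, ka, kd, p[["rmax"]], t_assoc, r0 = r0)
    as.numeric(pred) - y
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  ka <- exp(p[["log_ka"]]); kd <- exp(p[["log_kd"]])
  est <- c(ka = ka, kd = kd, KD = kd / ka, Rmax = p[["rmax"]])
  cov <- try(solve(fit$hessian) * 2 * fit$deviance /
               max(1, length(y) - length(p)), silent = TRUE)
  se <- if (inherits(cov, "try-error")) c(ka = NA, kd = NA) else {
    sdlog <- sqrt(pmax(diag(cov)[1:2], 0))
    c(ka = ka * sdlog[1], kd = kd * sdlog[2])
  }
  flags <- character(0)
  converged <- fit$info %in% 1:4
  if (kd * (max(time) - t_assoc) < 0.01) {
    flags <- c(flags, "no_observable_decay")
  }
  .fit_result(est, se, sqrt(fit$deviance), converged, flags, "spr_kinetic")
}

#' Fit a Boltzmann sigmoid to a thermal melt curve
#'
#' `F(T) = Fmin + (Fmax - Fmin) / (1 + exp((Tm - T)/slope))`; the melting
#' temperature `Tm` is the midpoint of the transition. A flat or
#' transition-free curve is returned non-converged.
#'
#' @param temperatures temperatures (degrees C), at least 8 points
#'   spanning the transition.
#' @param fluorescence dye fluorescence at each temperature.
#' @return a `bind_fit` with `Tm` (degrees C), `slope`, `Fmin`, `Fmax`.
#' @export
fit_boltzmann_tm <- function(temperatures, fluorescence) {
  stopifnot(length(temperatures) == length(fluorescence),
            length(temperatures) >= 8L)
  T_ <- temperatures; F_ <- fluorescence
  rng <- diff(range(F_))
  if (rng <= .Machine$double.eps * 100 * max(abs(F_), 1))
    return(.fit_result(c(Tm = NA, slope = NA, Fmin = NA, Fmax = NA), c(),
                       Inf, FALSE, "flat_curve", "dsf"))
  start <- list(Fmin = min(F_), Fmax = max(F_),
                Tm = T_[which.min(abs(F_ - (min(F_) + rng / 2)))], slope = 2)
  fit <- try(minpack.lm::nlsLM(
    F_ ~ Fmin + (Fmax - Fmin) / (1 + exp((Tm - T_) / slope)), start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(.fit_result(c(Tm = NA, slope = NA, Fmin = NA, Fmax = NA), c(),
                       Inf, FALSE, "fit_failed", "dsf"))
  est <- stats::coef(fit)[c("Tm", "slope", "Fmin", "Fmax")]
  se <- summary(fit)$coefficients[, "Std. Error"]
  converged <- est[["Tm"]] > min(T_) && est[["Tm"]] < max(T_) &&
    est[["slope"]] > 0
  .fit_result(est, se, sqrt(sum(stats::resid(fit)^2)), converged,
              if (converged) character(0) else "tm_outside_range", "dsf")
}

#' Fit a fluorescence-polarization displacement curve
#'
#' 4-parameter logistic
#' `P(C) = bottom + (top - bottom) / (1 + (C / IC50)^h)`;
#' the displacement constant `Kdisp` is reported as the inflection
#' (IC50). Curves whose dynamic range is below 20% of the top plateau
#' are flagged `non_displacing`.
#'
#' @param ts a `titration_series` of compound dose vs polarization
#'   (polarization decreasing with dose for a displacer).
#' @return a `bind_fit` with `Kdisp` (molar), `hill`, `top`, `bottom`.
#' @export
fit_fp_displacement <- function(ts) {
  C <- ts$concentration; P <- ts$response
  rng <- max(P) - min(P)
  if (rng < 0.2 * max(abs(P)))
    return(.fit_result(c(Kdisp = NA, hill = NA, top = max(P), bottom = min(P)),
                       c(), Inf, FALSE, "non_displacing", "fp"))
  start <- list(top = max(P), bottom = min(P),
                IC50 = exp(mean(log(range(C)))), h = 1)
  fit <- try(minpack.lm::nlsLM(
    P ~ bottom + (top - bottom) / (1 + (C / IC50)^h), start = start,
    lower = c(top = -Inf, bottom = -Inf, IC50 = 1e-15, h = 0.1),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(.fit_result(c(Kdisp = NA, hill = NA, top = NA, bottom = NA), c(),
                       Inf, FALSE, "fit_failed", "fp"))
  co <- stats::coef(fit)
  est <- c(Kdisp = unname(co["IC50"]), hill = unname(co["h"]),
           top = unname(co["top"]), bottom = unname(co["bottom"]))
  se <- summary(fit)$coefficients[, "Std. Error"]
  .fit_result(est, c(Kdisp = unname(se["IC50"])),
              sqrt(sum(stats::resid(fit)^2)), TRUE, character(0), "fp")
}

#' Cheng-Prusoff correction of a displacement IC50
#'
#' Optional post-hoc transform `Ki = IC50 / (1 + [probe]/KD_probe)`.
#'
#' @param ic50 fitted inflection (molar).
#' @param probe_concentration labeled-probe concentration (molar).
#' @param probe_kd probe dissociation constant (molar).
#' @return corrected inhibition constant (molar).
#' @export
cheng_prusoff <- function(ic50, probe_concentration, probe_kd) {
  ic50 / (1 + probe_concentration / probe_kd)
}

#' Selectivity matrix of normalized percent binding
#'
#' Each cell is the mean over replicates of
#' `100 * R_obs / R_max_theoretical`, where the theoretical maximal
#' response scales the immobilized protein surface capacity by the
#' compound/protein mass ratio (see [theoretical_rmax()]). Values are
#' clamped to `[0, 120]`; cells exceeding 120% before clamping are
#' flagged super-stoichiometric. Cells lacking a theoretical Rmax are
#' marked not computable (`NA`).
#'
#' @param panel data.frame with `compound`, `protein`, `response` (RU)
#'   and optionally `replicate`.
#' @param rmax data.frame with `compound`, `protein`,
#'   `rmax_theoretical`.
#' @return numeric matrix (compound x protein) of percent binding, with
#'   attribute `over_range` (logical matrix).
#' @export
selectivity_matrix <- function(panel, rmax) {
  panel <- data.table::as.data.table(panel)
  rmax <- data.table::as.data.table(rmax)
  stopifnot(all(c("compound", "protein", "response") %in% names(panel)),
            all(c("compound", "protein", "rmax_theoretical") %in% names(rmax)))
  agg <- panel[, list(mean_response = mean(response), n = .N),
               by = c("compound", "protein")]
  agg <- merge(agg, rmax, by = c("compound", "protein"), all.x = TRUE)
  agg$percent <- 100 * agg$mean_response / agg$rmax_theoretical
  compounds <- unique(panel$compound)
  proteins <- unique(panel$protein)
  m <- matrix(NA_real_, length(compounds), length(proteins),
              dimnames = list(compounds, proteins))
  over <- matrix(FALSE, length(compounds), length(proteins),
                 dimnames = list(compounds, proteins))
  for (r in seq_len(nrow(agg))) {
    v <- agg$percent[r]
    if (is.na(v)) next
    over[agg$compound[r], agg$protein[r]] <- v > 120
    m[agg$compound[r], agg$protein[r]] <- min(max(v, 0), 120)
  }
  structure(m, over_range = over)
}

#' Theoretical maximal SPR response for a 1:1 interaction
#'
#' `Rmax = immobilized_RU * MW_analyte / MW_ligand` (ligand = the
#' immobilized protein).
#'
#' @param immobilized_ru immobilized protein level (RU).
#' @param mw_analyte analyte (compound) molecular weight (Da).
#' @param mw_ligand immobilized protein molecular weight (Da).
#' @return theoretical Rmax (RU).
#' @export
theoretical_rmax <- function(immobilized_ru, mw_analyte, mw_ligand) {
  immobilized_ru * mw_analyte / mw_ligand
}

#' Simulate a binding assay from known parameters
#'
#' Forward-simulates the closed-form model of the requested assay and
#' adds i.i.d. Gaussian noise with coefficient of variation `cv`
#' (relative to the dynamic range).
#'
#' @param kind one of `"spr_steady"`, `"spr_kinetic"`, `"dsf"`, `"fp"`.
#' @param true_params named list of model parameters:
#'   steady state `KD`, `Rmax`; kinetic `ka`, `kd`, `Rmax`; DSF `Tm`,
#'   `slope`, `Fmin`, `Fmax`; FP `Kdisp`, `hill`, `top`, `bottom`.
#' @param design named list: titrations take `concentrations`
#'   (or `top`, `dilution`, `n_points`); kinetics take `time`,
#'   `concentrations`, `t_assoc`; DSF takes `temperatures`.
#' @param cv Gaussian noise CV (fraction of the dynamic range).
#' @param seed integer seed.
#' @return a `titration_series`, `sensorgram`, or (for DSF) a data.frame
#'   with `temperature` and `fluorescence`.
#' @export
simulate_assay <- function(kind = c("spr_steady", "spr_kinetic", "dsf", "fp"),
                           true_params, design = list(), cv = 0, seed = 1L) {
  kind <- match.arg(kind)
  tp <- true_params
  with_seed(seed, {
    noisy <- function(y) {
      if (cv <= 0) return(y)
      y + stats::rnorm(length(y), sd = cv * diff(range(y)))
    }
    if (kind == "spr_steady") {
      C <- design$concentrations
      if (is.null(C))
        C <- design$top / design$dilution^(seq_len(design$n_points) - 1)
      C <- sort(C)
      R <- tp$Rmax * C / (C + tp$KD)
      titration_series(C, noisy(R), kind = "spr_steady")
    } else if (kind == "spr_kinetic") {
      tr <- .kinetic_traces(design$time, design$concentrations,
                            tp$ka, tp$kd, tp$Rmax, design$t_assoc)
      sensorgram(design$time, noisy(tr), design$concentrations, design$t_assoc)
    } else if (kind == "dsf") {
      T_ <- design$temperatures
      F_ <- tp$Fmin + (tp$Fmax - tp$Fmin) / (1 + exp((tp$Tm - T_) / tp$slope))
      data.frame(temperature = T_, fluorescence = noisy(F_))
    } else {
      C <- sort(design$concentrations)
      P <- tp$bottom + (tp$top - tp$bottom) / (1 + (C / tp$Kdisp)^tp$hill)
      titration_series(C, noisy(P), kind = "fp")
    }
  })
}
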