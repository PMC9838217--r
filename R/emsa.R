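#' Fraction bound from EMSA band intensities
#'
#' Converts an unbound-band intensity to "1 - relative band intensity":
#' `Y = 1 - (D_x - D_bound) / (D_0 - D_bound)`, where `D_x` is the unbound
#' DNA band intensity at protein concentration X, `D_0` the unbound
#' intensity at zero protein, and `D_bound` the intensity of an equal area
#' in an empty lane (the 100%-bound background). Y is 0 at `D_x = D_0`
#' and 1 at `D_x = D_bound`; noisy values outside \[0, 1\] are returned
#' unclipped.
#'
#' @param D_x unbound band intensity (vectorised).
#' @param D_0 unbound intensity at zero protein.
#' @param D_bound empty-lane background intensity.
#' @return numeric vector of fractions bound.
#' @export
band_fraction <- function(D_x, D_0, D_bound) {
  if (D_0 == D_bound) {
    stop("degenerate normalisation: D_0 equals D_bound", call. = FALSE)
  }
  1 - (D_x - D_bound) / (D_0 - D_bound)
}

#' Fit a hyperbolic binding isotherm
#'
#' Unweighted nonlinear least squares of `Y = Bmax * X / (Kd + X)` to a
#' protein titration, the standard one-site binding model: `Bmax` is the
#' maximum fraction bound and `Kd` the apparent dissociation constant (in
#' the units of X, conventionally micromolar). Initial values default to
#' `Bmax = max(Y)` and `Kd` = the X whose Y is closest to half-maximum;
#' Kd is constrained to (0, 10 * max(X)] and Bmax to (0, 1.5] so that
#' non-binding titrations are reported as not converged rather than
#' diverging. Y values outside \[0, 1\] are kept as-is (clipping would
#' bias Kd); values outside \[-0.2, 1.2\] trigger a warning.
#'
#' @param curve data.frame with numeric columns `X` (concentration, >= 0)
#'   and `Y` (fraction bound), at least 3 points with at least 2 distinct
#'   nonzero X.
#' @param init optional named list/vector with starting `Kd` and `Bmax`.
#' @return object of class `isotherm_fit`: list with `Kd`, `Bmax`, `rss`,
#'   `converged`, `se` (named vector, NA if unavailable), `note`, `data`.
#'   For titrations with no detectable binding, `converged` is FALSE and
#'   the parameters are NA, mirroring binding constants that "could not be
#'   determined".
#' @export
fit_isotherm <- function(curve, init = NULL) {
  stopifnot(is.data.frame(curve), all(c("X", "Y") %in% names(curve)))
  X <- as.numeric(curve$X)
  Y <- as.numeric(curve$Y)
  ok <- !is.na(X) & !is.na(Y)
  X <- X[ok]; Y <- Y[ok]
  if (any(X < 0)) stop("negative concentrations", call. = FALSE)
  if (length(X) < 3L || length(unique(X[X > 0])) < 2L) {
    stop("need >= 3 points with >= 2 distinct nonzero concentrations",
         call. = FALSE)
  }
  n_out <- sum(Y < -0.2 | Y > 1.2)
  if (n_out > 0L) {
    warning(n_out, " point(s) with fraction bound outside [-0.2, 1.2]",
            call. = FALSE)
  }
  if (max(Y) < 0.05) {
    return(structure(list(Kd = NA_real_, Bmax = NA_real_, rss = NA_real_,
                          converged = FALSE,
                          se = c(Kd = NA_real_, Bmax = NA_real_),
                          note = paste("no detectable binding;",
                                       "dissociation constant could not be",
                                       "determined"),
                          data = data.frame(X = X, Y = Y)),
                     class = "isotherm_fit"))
  }
  Bmax0 <- min(max(Y), 1.5)
  Xpos <- X[X > 0]
  Kd0 <- Xpos[which.min(abs(Y[X > 0] - Bmax0 / 2))]
  if (!is.null(init)) {
    Kd0 <- init[["Kd"]] %||% Kd0
    Bmax0 <- init[["Bmax"]] %||% Bmax0
  }
  dat <- data.frame(X = X, Y = Y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      Y ~ Bmax * X / (Kd + X), data = dat,
      start = list(Kd = Kd0, Bmax = Bmax0),
      lower = c(Kd = 1e-12, Bmax = 1e-12),
      upper = c(Kd = 10 * max(X), Bmax = 1.5),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(Kd = NA_real_, Bmax = NA_real_, rss = NA_real_,
                          converged = FALSE,
                          se = c(Kd = NA_real_, Bmax = NA_real_),
                          note = conditionMessage(fit),
                          data = dat),
                     class = "isotherm_fit"))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Kd = NA_real_, Bmax = NA_real_))
  structure(list(Kd = unname(est["Kd"]), Bmax = unname(est["Bmax"]),
                 rss = sum(stats::residuals(fit)^2),
                 converged = isTRUE(fit$convInfo$isConv),
                 se = c(Kd = unname(se["Kd"]), Bmax = unname(se["Bmax"])),
                 note = "",
                 data = dat),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<isotherm_fit> Kd = %.4g, Bmax = %.4g (rss %.3g)\n",
                x$Kd, x$Bmax, x$rss))
  } else {
    cat("<isotherm_fit> not converged:", x$note, "\n")
  }
  invisible(x)
}

#' Predicted fraction bound under a fitted isotherm
#'
#' @param object an `isotherm_fit`.
#' @param X concentrations at which to evaluate. `X = Kd` returns
#'   `Bmax / 2` exactly.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.isotherm_fit <- function(object, X, ...) {
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  object$Bmax * X / (object$Kd + X)
}

#' Simulate an EMSA gel quantification
#'
#' Generates unbound-band intensities for a protein titration under the
#' hyperbolic isotherm, with optional Gaussian noise proportional to the
#' dynamic range:
#' `D_x = D_bound + (D_0 - D_bound) * (1 - Bmax*X/(Kd+X)) + N(0, noise_sd * |D_0 - D_bound|)`.
#' At zero noise, [band_fraction()] recovers the isotherm exactly.
#'
#' @param Kd ground-truth dissociation constant (> 0).
#' @param Bmax ground-truth maximum fraction bound (default 1).
#' @param concentrations protein concentrations of the lanes.
#' @param noise_sd Gaussian noise SD as a fraction of `|D_0 - D_bound|`
#'   (default 0).
#' @param D_0 unbound intensity at zero protein (default 1000).
#' @param D_bound empty-lane background (default 100).
#' @param probe_nM labelled probe concentration recorded as metadata
#'   (default 68.1).
#' @param rng_seed optional seed; when given, generation is deterministic
#'   and the caller's RNG state is untouched.
#' @return object of class `gel_quantification`: list with `lanes`
#'   (data.frame `X_uM`, `D_x`), `D_0`, `D_bound`, `probe_nM`.
#' @export
simulate_gel <- function(Kd, Bmax = 1, concentrations, noise_sd = 0,
                         D_0 = 1000, D_bound = 100, probe_nM = 68.1,
                         rng_seed = NULL) {
  stopifnot(Kd > 0, noise_sd >= 0, all(concentrations >= 0),
            D_0 != D_bound)
  gen <- function() {
    Y <- Bmax * concentrations / (Kd + concentrations)
    D_x <- D_bound + (D_0 - D_bound) * (1 - Y)
    if (noise_sd > 0) {
      D_x <- D_x + stats::rnorm(length(D_x),
                                sd = noise_sd * abs(D_0 - D_bound))
    }
    D_x
  }
  D_x <- if (is.null(rng_seed)) gen() else with_seed(rng_seed, gen())
  structure(list(lanes = data.frame(X_uM = concentrations, D_x = D_x),
                 D_0 = D_0, D_bound = D_bound, probe_nM = probe_nM),
            class = "gel_quantification")
}

#' Binding curve from a gel quantification
#'
#' Applies [band_fraction()] to every lane.
#'
#' @param gel a `gel_quantification` (from [simulate_gel()] or
#'   [read_gel_table()]).
#' @return data.frame with columns `X` and `Y`, ready for
#'   [fit_isotherm()].
#' @export
gel_binding_curve <- function(gel) {
  stopifnot(inherits(gel, "gel_quantification"))
  data.frame(X = gel$lanes$X_uM,
             Y = band_fraction(gel$lanes$D_x, gel$D_0, gel$D_bound))
}
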