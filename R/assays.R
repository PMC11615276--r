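#' Impedance-based specific cytolysis
#'
#' Specific cytolysis in percent from normalized Cell Indexes:
#' `100 - (CI_x / CI_non_transduced * 100)`. Values below zero (target
#' outgrowth under the TCR condition) are returned as-is and flagged via the
#' `outgrowth` attribute.
#'
#' @param ci_x Normalized Cell Index of the TCR-transduced condition
#'   (nonnegative; vectorized).
#' @param ci_non_transduced Normalized Cell Index of the non-transduced
#'   control (positive).
#' @return Numeric vector of percent specific cytolysis with logical
#'   attribute `outgrowth`.
#' @export
specific_cytolysis <- function(ci_x, ci_non_transduced) {
  if (any(ci_non_transduced <= 0))
    stop("CI of the non-transduced control must be > 0", call. = FALSE)
  if (any(ci_x < 0))
    stop("CI values must be nonnegative", call. = FALSE)
  out <- 100 - (ci_x / ci_non_transduced * 100)
  attr(out, "outgrowth") <- out < 0
  out
}

#' Fit a one-phase exponential dissociation decay
#'
#' Nonlinear least squares of `signal(t) = plateau + amplitude * exp(-k t)`
#' to a multimer-dissociation trace. Initialization: plateau at the signal
#' minimum (0 when `with_plateau = FALSE`), amplitude at the signal range,
#' and `k` from a log-linear regression of the plateau-subtracted signal.
#' The dissociation half-life is `t_half = ln(2) / k`.
#'
#' @param time Nondecreasing time points in seconds (at least 5).
#' @param signal Nonnegative trace values (e.g. multimer fluorescence
#'   ratio).
#' @param with_plateau Fit a free plateau term (default `TRUE`).
#' @return Object of class `koff_fit` with components `k`, `plateau`,
#'   `amplitude`, `t_half`, `rss`, `fitted`, `data`, `with_plateau`.
#' @export
fit_koff <- function(time, signal, with_plateau = TRUE) {
  if (length(time) != length(signal) || length(time) < 5L)
    stop("need at least 5 (time, signal) points", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (any(signal < 0)) stop("signal must be nonnegative", call. = FALSE)
  if (diff(range(signal)) < .Machine$double.eps)
    stop("signal is constant; no decay to fit", call. = FALSE)

  plateau0 <- if (with_plateau) min(signal) else 0
  amp0 <- max(signal) - plateau0
  pos <- signal - plateau0 > amp0 * 1e-6
  k0 <- if (sum(pos) >= 2) {
    sl <- unname(coef(stats::lm(log(signal[pos] - plateau0 + amp0 * 1e-6) ~
                                  time[pos]))[2])
    if (is.finite(sl) && sl < 0) -sl else log(2) / (diff(range(time)) / 3)
  } else log(2) / (diff(range(time)) / 3)

  df <- data.frame(t = time, s = signal)
  fit <- tryCatch({
    if (with_plateau)
      minpack.lm::nlsLM(s ~ plateau + amplitude * exp(-k * t), data = df,
                        start = list(plateau = plateau0,
                                     amplitude = max(amp0, 1e-8), k = k0),
                        lower = c(0, 1e-12, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(s ~ amplitude * exp(-k * t), data = df,
                        start = list(amplitude = max(amp0, 1e-8), k = k0),
                        lower = c(1e-12, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e)
    stop(sprintf("decay fit failed: %s (init plateau=%.4g amplitude=%.4g k=%.4g)",
                 conditionMessage(e), plateau0, amp0, k0), call. = FALSE))

  cf <- coef(fit)
  k <- unname(cf["k"])
  if (!is.finite(k) || k <= 0)
    stop(sprintf("decay fit returned non-positive rate k = %.4g", k),
         call. = FALSE)
  structure(list(
    k = k,
    plateau = if (with_plateau) unname(cf["plateau"]) else 0,
    amplitude = unname(cf["amplitude"]),
    t_half = log(2) / k,
    rss = sum(residuals(fit)^2),
    fitted = stats::fitted(fit),
    data = df, with_plateau = with_plateau
  ), class = "koff_fit")
}

#' @export
print.koff_fit <- function(x, ...) {
  cat("One-phase exponential dissociation fit\n")
  cat(sprintf("  k = %.6g /s   t1/2 = %.4g s   plateau = %.4g   amplitude = %.4g\n",
              x$k, x$t_half, x$plateau, x$amplitude))
  cat(sprintf("  RSS = %.4g over %d points\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
coef.koff_fit <- function(object, ...) {
  c(plateau = object$plateau, amplitude = object$amplitude, k = object$k)
}

#' @export
predict.koff_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t else
    if (is.data.frame(newdata)) newdata$t else newdata
  object$plateau + object$amplitude * exp(-object$k * t)
}

#' @export
residuals.koff_fit <- function(object, ...) {
  object$data$s - predict(object)
}

#' Fit a four-parameter logistic dose-response curve (EC50)
#'
#' Fits `response = bottom + (top - bottom) / (1 + 10^(hill * (log10(EC50)
#' - log10(conc))))` by nonlinear least squares on the log10 concentration
#' axis. EC50 is reported in the concentration units supplied (molar in the
#' standard workflow). A flat response returns a flagged degenerate fit, not
#' a number; an EC50 outside the tested range is flagged extrapolated.
#'
#' @param conc Concentrations (at least 4 distinct values, > 0).
#' @param response Assay readouts at those concentrations.
#' @return Object of class `ec50_fit` with `bottom`, `top`, `ec50`, `hill`,
#'   `rss`, `degenerate`, `extrapolated`, `data`.
#' @export
fit_ec50 <- function(conc, response) {
  if (length(conc) != length(response))
    stop("conc and response lengths differ", call. = FALSE)
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct concentrations", call. = FALSE)
  if (any(conc <= 0)) stop("concentrations must be > 0", call. = FALSE)

  rng <- diff(range(response))
  if (rng < 1e-8 * max(1, abs(mean(response)))) {
    return(structure(list(bottom = NA_real_, top = NA_real_,
                          ec50 = NA_real_, hill = NA_real_, rss = NA_real_,
                          degenerate = TRUE, extrapolated = FALSE,
                          data = data.frame(conc = conc, response = response)),
                     class = "ec50_fit"))
  }

  lx <- log10(conc)
  # monotone direction from the dose-response correlation
  up <- stats::cor(lx, response) >= 0
  half <- (min(response) + max(response)) / 2
  l50 <- lx[which.min(abs(response - half))]
  df <- data.frame(lx = lx, y = response)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(hill * (l50p - lx))),
      data = df,
      start = list(bottom = min(response), top = max(response),
                   l50p = l50, hill = if (up) 1 else -1),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop(sprintf("EC50 fit failed: %s", conditionMessage(e)),
           call. = FALSE))

  cf <- coef(fit)
  bottom <- unname(cf["bottom"]); top <- unname(cf["top"])
  hill <- unname(cf["hill"])
  # canonicalize so bottom <= top (flip hill sign accordingly)
  if (bottom > top) {
    tmp <- bottom; bottom <- top; top <- tmp; hill <- -hill
  }
  ec50 <- 10^unname(cf["l50p"])
  structure(list(
    bottom = bottom, top = top, ec50 = ec50, hill = hill,
    rss = sum(residuals(fit)^2),
    degenerate = FALSE,
    extrapolated = ec50 < min(conc) || ec50 > max(conc),
    data = data.frame(conc = conc, response = response)
  ), class = "ec50_fit")
}

#' @export
print.ec50_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Four-parameter logistic fit: degenerate (flat response)\n")
    return(invisible(x))
  }
  cat("Four-parameter logistic dose-response fit\n")
  cat(sprintf("  EC50 = %.4g   hill = %.3g   bottom = %.4g   top = %.4g%s\n",
              x$ec50, x$hill, x$bottom, x$top,
              if (x$extrapolated) "   [extrapolated]" else ""))
  invisible(x)
}

#' @export
coef.ec50_fit <- function(object, ...) {
  c(bottom = object$bottom, top = object$top, ec50 = object$ec50,
    hill = object$hill)
}

#' @export
predict.ec50_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else
    if (is.data.frame(newdata)) newdata$conc else newdata
  if (object$degenerate) return(rep(NA_real_, length(conc)))
  object$bottom + (object$top - object$bottom) /
    (1 + 10^(object$hill * (log10(object$ec50) - log10(conc))))
}

#' Cytokine log2 fold-change ratios between two conditions
#'
#' Per shared analyte: `log2((num + floor) / (den + floor))`, with an
#' additive floor at the assay's lower detection limit so zero
#' concentrations stay defined.
#'
#' @param panel_num,panel_den Named numeric vectors of analyte
#'   concentrations (pg/mL).
#' @param floor Additive floor in pg/mL (default 1).
#' @return Named numeric vector of log2 ratios over the shared analytes.
#' @export
cytokine_log2_ratio <- function(panel_num, panel_den, floor = 1) {
  shared <- intersect(names(panel_num), names(panel_den))
  if (length(shared) == 0L)
    stop("panels share no analytes", call. = FALSE)
  if (any(panel_num[shared] < 0) || any(panel_den[shared] < 0))
    stop("concentrations must be nonnegative", call. = FALSE)
  log2((panel_num[shared] + floor) / (panel_den[shared] + floor))
}

# Monoisotopic residue masses (Da), standard Unimod/CODATA values.
RESIDUE_MASS <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313)
MASS_WATER <- 18.0105646863
MASS_PROTON <- 1.00727646688

#' Theoretical monoisotopic peptide m/z
#'
#' Mass-to-charge ratio of an unmodified peptide ion for inclusion lists:
#' `(sum of monoisotopic residue masses + water + charge * proton) /
#' charge`.
#'
#' @param sequence Peptide sequence over the 20 standard amino acids.
#' @param charge Positive integer charge state.
#' @return Object of class `peptide_ion` with `sequence`, `charge`, `mz`
#'   (full precision; printed to 4 decimals).
#' @examples
#' peptide_mz("RLFLGLAIK", 2)  # 515.8422
#' @export
peptide_mz <- function(sequence, charge) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a nonempty amino-acid string", call. = FALSE)
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge))
    stop("charge must be a positive integer", call. = FALSE)
  aa <- strsplit(sequence, "")[[1]]
  bad <- which(!(aa %in% names(RESIDUE_MASS)))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", aa[bad[1]], bad[1]),
         call. = FALSE)
  m <- sum(RESIDUE_MASS[aa]) + MASS_WATER
  structure(list(sequence = sequence, charge = as.integer(charge),
                 mz = (m + charge * MASS_PROTON) / charge),
            class = "peptide_ion")
}

#' @export
print.peptide_ion <- function(x, ...) {
  cat(sprintf("%s %d+  m/z = %.4f\n", x$sequence, x$charge, x$mz))
  invisible(x)
}
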