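#' Build a control table for the phase-variability regression
#'
#' One row per control subject and session: the trial-to-trial circular SD
#' of the phase at the cued frequency, and the decoding accuracy averaged
#' over stimulation lengths.
#'
#' @param subject,session Identifiers.
#' @param phase_sd Circular SD in radians (>= 0).
#' @param mean_accuracy Accuracy fraction in `[0, 1]`.
#' @param decoder Decoder name.
#' @return A `control_table` data frame.
#' @export
control_table <- function(subject, session, phase_sd, mean_accuracy, decoder) {
  if (any(phase_sd < 0)) stop("phase_sd must be >= 0")
  if (any(mean_accuracy < 0 | mean_accuracy > 1))
    stop("mean_accuracy must lie in [0, 1]")
  out <- data.frame(subject = subject, session = session,
                    phase_sd = phase_sd, mean_accuracy = mean_accuracy,
                    decoder = decoder)
  class(out) <- c("control_table", "data.frame")
  out
}

#' Impute a missing decoding accuracy from phase variability
#'
#' Regression-based imputation of an unobserved accuracy (e.g. a patient's
#' scalp accuracy) from the trial-to-trial phase variability: ordinary
#' least squares of control accuracies on control phase SDs, then, per
#' session and iteration, a draw from the t predictive distribution at the
#' patient's phase SD (prediction + residual- and leverage-scaled t noise),
#' clipped to `[0, 1]`. Reported are the mean and SD over iterations.
#' When the controls lie exactly on a line the predictive noise vanishes
#' and the imputed SD is 0.
#'
#' @param controls A [control_table()] (a single decoder's rows).
#' @param patient_phase_sd Named numeric vector of phase SDs, one per
#'   session to impute.
#' @param n_iter Number of imputation iterations (default 100).
#' @param seed Seed for the draws.
#' @return An `imputation_result` data frame with one row per session:
#'   `session`, `phase_sd`, `imputed_mean`, `imputed_sd`, `n_iterations`.
#' @export
impute_patient_accuracy <- function(controls, patient_phase_sd, n_iter = 100,
                                    seed = 1) {
  stopifnot(is.data.frame(controls),
            all(c("phase_sd", "mean_accuracy") %in% names(controls)))
  if (length(unique(controls$phase_sd)) < 3)
    stop("need at least 3 distinct control phase_sd values for the regression")
  if (!is.null(controls$decoder) && length(unique(controls$decoder)) > 1)
    stop("fit one regression per decoder: pass a single decoder's rows")
  fit <- lm(mean_accuracy ~ phase_sd, data = controls)
  n <- nrow(controls)
  s <- suppressWarnings(summary(fit)$sigma)   # zero-residual fits warn
  xbar <- mean(controls$phase_sd)
  ssx <- sum((controls$phase_sd - xbar)^2)
  sessions <- names(patient_phase_sd) %||% seq_along(patient_phase_sd)
  with_seed(seed, {
    rows <- lapply(seq_along(patient_phase_sd), function(i) {
      x0 <- patient_phase_sd[i]
      m <- as.numeric(coef(fit)[1] + coef(fit)[2] * x0)
      se_pred <- s * sqrt(1 + 1 / n + (x0 - xbar)^2 / ssx)
      draws <- m + rt(n_iter, df = n - 2) * se_pred
      draws <- pmin(1, pmax(0, draws))
      data.frame(session = sessions[i], phase_sd = as.numeric(x0),
                 imputed_mean = mean(draws), imputed_sd = sd(draws),
                 n_iterations = n_iter)
    })
    out <- do.call(rbind, rows)
    attr(out, "fit") <- fit
    class(out) <- c("imputation_result", "data.frame")
    out
  })
}
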