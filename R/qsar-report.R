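#' Fit the QSAR and assemble the full validation report
#'
#' End-to-end modeling stage: scans the component count by LOO q2 on the
#' training rows, fits the final NIPALS PLS, and collects every reported
#' statistic — q2, n, R2, SEE, F, external r2_pred and SEP (when test rows
#' are present), and the per-field contribution percentages.
#'
#' @param descriptors a `field_descriptors` from [assemble_descriptors()]
#' @param y response (composite Z), one value per descriptor row
#' @param split optional character vector (`"train"`/`"test"`) per row; all
#'   rows train when omitted
#' @param max_components component-scan cap
#' @param criterion component choice: `"q2max"` or `"sep_min"`
#' @return object of class `qsar_report`: `n_components`, `q2`, `csdep`,
#'   `r2`, `see`, `f_stat`, `r2_pred`, `sep`, `contributions`,
#'   `training_mean`, `component_scan`, and the fitted `model`
#' @export
fit_qsar <- function(descriptors, y, split = NULL, max_components = 10L,
                     criterion = "q2max") {
  stopifnot(inherits(descriptors, "field_descriptors"))
  y <- as.numeric(y)
  n <- nrow(descriptors$X)
  stopifnot(length(y) == n)
  if (is.null(split)) split <- rep("train", n)
  stopifnot(length(split) == n, all(split %in% c("train", "test")))
  tr <- split == "train"
  Xtr <- descriptors$X[tr, , drop = FALSE]
  ytr <- y[tr]

  scan <- scan_components(Xtr, ytr, max_components, criterion)
  model <- suppressWarnings(fit_pls(Xtr, ytr, scan$n_components))
  contrib <- field_contributions(model, descriptors$columns$field, Xtr)

  r2_pred <- sep <- NA_real_
  if (any(!tr)) {
    ext <- external_validation(model, descriptors$X[!tr, , drop = FALSE],
                               y[!tr], training_mean = mean(ytr))
    r2_pred <- ext$r2_pred
    sep <- ext$sep
  }
  structure(
    list(n_components = model$n_components, q2 = scan$q2, csdep = scan$csdep,
         r2 = model$r2, see = model$see, f_stat = model$f_stat,
         r2_pred = r2_pred, sep = sep, contributions = contrib,
         training_mean = mean(ytr), component_scan = scan$scan,
         model = model, split = split),
    class = "qsar_report"
  )
}

#' @export
print.qsar_report <- function(x, ...) {
  cat(sprintf("<qsar_report> n = %d, q2 = %.3f, R2 = %.3f, SEE = %.3g, F = %.4g\n",
              x$n_components, x$q2, x$r2, x$see, x$f_stat))
  if (is.finite(x$r2_pred)) {
    cat(sprintf("  external: r2_pred = %.3f, SEP = %.3g\n", x$r2_pred, x$sep))
  }
  cat("  contributions:",
      paste(sprintf("%s %.1f%%", names(x$contributions), x$contributions),
            collapse = ", "), "\n")
  invisible(x)
}

# JSON-safe view of a qsar_report (model kept as coefficients only)
qsar_report_to_list <- function(report) {
  list(
    n_components = report$n_components, q2 = report$q2, csdep = report$csdep,
    r2 = report$r2, see = report$see, f_stat = report$f_stat,
    r2_pred = report$r2_pred, sep = report$sep,
    contributions = as.list(report$contributions),
    training_mean = report$training_mean,
    component_scan = report$component_scan,
    coefficients = unname(report$model$coefficients),
    intercept = report$model$intercept
  )
}
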