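# Error metrics and the 1987 Clarke Error Grid.

#' Regression error metrics for glucose estimation
#'
#' MARD is the mean absolute relative difference,
#' `mean(|pred - ref| / ref) * 100` (%); RD are the signed per-point
#' relative differences `(pred - ref) / ref`. R-squared is
#' `1 - SS_res / SS_tot` (undefined, `NA`, for n < 2).
#'
#' @param y_ref Reference glucose (mmol/L, all > 0).
#' @param y_pred Predicted glucose (mmol/L).
#' @return Object of class `eval_report`: `mse`, `rmse`, `mae`, `mard`,
#'   `r2`, `n`, `rd`.
#' @export
compute_metrics <- function(y_ref, y_pred) {
  n <- length(y_ref)
  if (n == 0L || length(y_pred) != n)
    ppg_stop("y_ref and y_pred must have equal, nonzero length",
             "ppg_validation_error")
  if (any(y_ref <= 0))
    ppg_stop("MARD undefined: y_ref must be > 0", "ppg_validation_error")
  err <- y_pred - y_ref
  structure(list(
    mse = mean(err^2),
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    mard = mean(abs(err) / y_ref) * 100,
    r2 = if (n < 2L) NA_real_ else 1 - sum(err^2) / sum((y_ref - mean(y_ref))^2),
    n = n,
    rd = err / y_ref), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d\n  MSE %.4f (mmol/L)^2  RMSE %.4f  MAE %.4f mmol/L\n  MARD %.2f%%  R2 %s\n",
              x$n, x$mse, x$rmse, x$mae, x$mard,
              if (is.na(x$r2)) "NA" else sprintf("%.4f", x$r2)))
  invisible(x)
}

#' Clarke Error Grid zone of one or more (reference, prediction) pairs
#'
#' Inputs in mmol/L are converted to mg/dL (x 18.016) and the canonical
#' 1987 piecewise zone inequalities applied. Zone A is predictions within
#' 20% of the reference, or both values below 70 mg/dL. The C, D and E
#' region inequalities are strict, so points on a shared boundary fall to
#' the better (earlier-letter) zone. Inequality by inequality:
#'
#' * A: `|pred - ref| <= 0.2 ref`, or `ref < 70` and `pred < 70`
#' * C: `70 <= ref <= 290` and `pred > ref + 110`, or `130 <= ref <= 180`
#'   and `pred < (7/5) ref - 182`
#' * D: `ref > 240` and `70 < pred < 180`, or `ref < 175/3` and
#'   `70 < pred < 180`, or `175/3 <= ref <= 70` and
#'   `(6/5) ref < pred < 180`
#' * E: `ref > 180` and `pred < 70`, or `ref < 70` and `pred > 180`
#' * B: everything else
#'
#' @param ref,pred Glucose values, mmol/L (> 0); recycled to equal length.
#' @return Character vector of zones `"A"` ... `"E"`.
#' @export
clarke_zone <- function(ref, pred) {
  if (any(ref <= 0) || any(pred <= 0))
    ppg_stop("glucose values must be > 0", "ppg_validation_error")
  k <- max(length(ref), length(pred))
  x <- rep_len(ref, k) * MGDL_PER_MMOL
  y <- rep_len(pred, k) * MGDL_PER_MMOL
  zone <- character(k)
  in_a <- abs(y - x) <= 0.2 * x | (x < 70 & y < 70)
  in_c <- (x >= 70 & x <= 290 & y > x + 110) |
          (x >= 130 & x <= 180 & y < (7 / 5) * x - 182)
  in_d <- (x > 240 & y > 70 & y < 180) |
          (x < 175 / 3 & y > 70 & y < 180) |
          (x >= 175 / 3 & x <= 70 & y > (6 / 5) * x & y < 180)
  in_e <- (x > 180 & y < 70) | (x < 70 & y > 180)
  zone[] <- "B"
  zone[in_e] <- "E"
  zone[in_d] <- "D"
  zone[in_c] <- "C"
  zone[in_a] <- "A"
  zone
}

#' Clarke Error Grid report
#'
#' @param y_ref,y_pred Glucose vectors, mmol/L.
#' @return Object of class `clarke_report`: per-point `zones` and
#'   `percentages` (named A-E, summing to 100).
#' @export
clarke_report <- function(y_ref, y_pred) {
  if (length(y_ref) == 0L || length(y_ref) != length(y_pred))
    ppg_stop("y_ref and y_pred must have equal, nonzero length",
             "ppg_validation_error")
  zones <- clarke_zone(y_ref, y_pred)
  counts <- table(factor(zones, levels = c("A", "B", "C", "D", "E")))
  structure(list(zones = zones,
                 percentages = stats::setNames(
                   100 * as.vector(counts) / length(zones),
                   c("A", "B", "C", "D", "E")),
                 n = length(zones)),
            class = "clarke_report")
}

#' @export
print.clarke_report <- function(x, ...) {
  p <- x$percentages
  cat(sprintf("<clarke_report> n = %d  A %.1f%%  B %.1f%%  C %.1f%%  D %.1f%%  E %.1f%%\n",
              x$n, p[1], p[2], p[3], p[4], p[5]))
  invisible(x)
}

#' Export a Clarke scatter as CSV (`ref,pred,zone`)
#' @param y_ref,y_pred Glucose vectors, mmol/L.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clarke_csv <- function(y_ref, y_pred, path) {
  zones <- clarke_zone(y_ref, y_pred)
  write.csv(data.frame(ref = y_ref, pred = y_pred, zone = zones),
            path, row.names = FALSE)
  invisible(path)
}
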