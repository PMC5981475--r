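#' Reconstruct contact force from parameter estimates
#'
#' Re-evaluates the Hunt-Crossley law along the \emph{reference} trajectory
#' using the per-step parameter estimates:
#' \eqn{\hat F_k = \hat K_k d_k^{\hat n_k} + \hat B_k d_k^{\hat n_k}
#' \dot d_k^{\hat p_k}}.  Comparing \eqn{\hat F} with the reference force
#' scores the estimation quality in force units, where it matters for haptic
#' rendering, rather than in the weakly identifiable parameter space.
#'
#' @param params_hat n x 4 matrix (columns K, B, n, p) of per-step estimates,
#'   or a single [hc_params()] applied to every step.
#' @param d Reference displacements (length n).
#' @param d_dot Reference velocities (length n, or scalar).
#' @return Reconstructed force series (length n).
#' @export
reconstruct_force <- function(params_hat, d, d_dot) {
  n <- length(d)
  if (length(d_dot) == 1) d_dot <- rep(d_dot, n)
  if (length(d_dot) != n) stop("reconstruct_force: length mismatch between d and d_dot")
  if (is.null(dim(params_hat))) {
    params_hat <- matrix(unclass(params_hat), n, 4, byrow = TRUE)
  }
  if (nrow(params_hat) != n) {
    stop("reconstruct_force: need one parameter row per step (", n,
         "), got ", nrow(params_hat))
  }
  hc_force_raw(params_hat[, 1], params_hat[, 2], params_hat[, 3],
               params_hat[, 4], d, d_dot)
}

#' Force-reconstruction error metrics
#'
#' Mean absolute error, maximum absolute error, and root-mean-square error of
#' a reconstructed force series against its reference, over all steps
#' (transients included -- the largest errors typically occur there).
#'
#' @param F_hat Reconstructed force series.
#' @param F_ref Reference force series (same length, at least 1).
#' @return List of class \code{"error_report"}: \code{mean_error},
#'   \code{max_error}, \code{rmse}, \code{per_step_error}.
#' @export
error_metrics <- function(F_hat, F_ref) {
  if (length(F_hat) == 0) stop("error_metrics: empty input")
  if (length(F_hat) != length(F_ref)) {
    stop("error_metrics: series lengths differ (", length(F_hat), " vs ",
         length(F_ref), ")")
  }
  e <- abs(F_hat - F_ref)
  structure(list(mean_error = mean(e), max_error = max(e),
                 rmse = sqrt(mean(e^2)), per_step_error = e),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("mean error %.4f | max error %.4f | RMSE %.4f (n = %d)\n",
              x$mean_error, x$max_error, x$rmse, length(x$per_step_error)))
  invisible(x)
}

#' Read an indentation record from delimited text
#'
#' Expects a CSV with header columns \code{time}, \code{displacement},
#' \code{force}, and optionally \code{velocity}.  When the velocity column is
#' absent it is filled by central finite differences of displacement over
#' time (one-sided at the endpoints).  All columns must be numeric; the first
#' offending row is named in the error.
#'
#' @param path File path.
#' @param quiet Suppress the row-count log line on stderr.
#' @return data.frame with columns \code{time}, \code{displacement},
#'   \code{velocity}, \code{force}.
#' @export
read_indentation_csv <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("read_indentation_csv: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time", "displacement", "force")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("read_indentation_csv: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) stop("read_indentation_csv: file has no data rows")
  cols <- intersect(c("time", "displacement", "velocity", "force"), names(df))
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & df[[cl]] != "NA")
    if (length(bad) > 0) {
      stop("read_indentation_csv: non-numeric value in column '", cl,
           "' at data row ", bad[1], " (file line ", bad[1] + 1, ")")
    }
    if (anyNA(v)) {
      stop("read_indentation_csv: missing value in column '", cl,
           "' at data row ", which(is.na(v))[1])
    }
    df[[cl]] <- v
  }
  if (!"velocity" %in% names(df)) {
    df$velocity <- finite_difference(df$displacement, df$time)
  }
  if (!quiet) {
    message("read_indentation_csv: ", nrow(df),
            " rows (units as recorded: displacement mm, force mN assumed)")
  }
  df[, c("time", "displacement", "velocity", "force")]
}

## Central differences in the interior, one-sided at the endpoints.
finite_difference <- function(x, t) {
  n <- length(x)
  if (n == 1) return(0)
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) / (t[2] - t[1])
  v[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    v[i] <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
  }
  v
}

#' Run a filter on a user-supplied indentation record
#'
#' Ingestion path for measured force/displacement streams (e.g. master-slave
#' robotic indentation): the record's displacement and force become the
#' measurement stream and, absent an independent reference, also the
#' reference for force reconstruction.
#'
#' @param record data.frame from [read_indentation_csv()].
#' @param config A [scenario_config()] carrying the filter settings
#'   (init_params, Q, R, M, theta_T, P0, seed); trajectory fields are taken
#'   from the record.
#' @param filter \code{"ukf"} or \code{"rwstukf"}.
#' @return An \code{"hc_filter_run"} object.
#' @export
fit_indentation <- function(record, config, filter = c("ukf", "rwstukf")) {
  filter <- match.arg(filter)
  n <- nrow(record)
  data <- data.frame(t = seq_len(n),
                     d_true = record$displacement,
                     d_dot_true = record$velocity,
                     F_true = record$force,
                     d_meas = record$displacement,
                     F_meas = record$force)
  cfg <- config
  cfg$n_steps <- n
  cfg$local_error <- NULL
  run <- run_filter_on_scenario(cfg, filter, data = data)
  run$config$scenario <- "user_data"
  run
}

#' Side-by-side comparison of filter error metrics
#'
#' @param runs Named list of \code{"hc_filter_run"} objects (or of
#'   [monte_carlo()] results, whose \code{summary} means are used).
#' @return data.frame with one metric per row and one column per filter.
#' @export
comparison_table <- function(runs) {
  col <- function(r) {
    if (inherits(r, "hc_filter_run")) {
      with(r$metrics, c(mean_error, max_error, rmse))
    } else {
      as.numeric(r$summary[c("mean_error", "max_error", "rmse")])
    }
  }
  out <- data.frame(metric = c("mean_error", "max_error", "rmse"))
  for (nm in names(runs)) out[[nm]] <- col(runs[[nm]])
  out
}
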