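REGIME_LEVELS <- c("0", "10", "20")
TIME_LEVELS <- c("5", "10", "20")
LOCATION_LEVELS <- c("in", "out")

#' Assemble a labelled lifetime dataset
#'
#' One row per fitted lifetime, tagged with the experimental condition:
#' oxygen regime (\% O2 in N2 applied to the chamber), minutes after probe
#' administration, and probe location relative to the vasculature
#' (`"in"` = intravascular, `"out"` = extravascular).
#'
#' @param tau lifetimes in ns, > 0.
#' @param regime oxygen regime, one of 0, 10, 20 (\% O2 in N2).
#' @param time_post_admin minutes post administration, one of 5, 10, 20.
#' @param location `"in"` or `"out"`.
#' @param subject_id optional subject/egg label.
#' @return data frame of class `lifetime_dataset` with factor columns.
#' @export
lifetime_dataset <- function(tau, regime, time_post_admin, location,
                             subject_id = NA_character_) {
  check_positive_finite(tau, "tau")
  regime <- factor(as.character(regime), levels = REGIME_LEVELS)
  time_post_admin <- factor(as.character(time_post_admin), levels = TIME_LEVELS)
  location <- factor(as.character(location), levels = LOCATION_LEVELS)
  if (anyNA(regime)) stop("`regime` must be one of 0, 10, 20", call. = FALSE)
  if (anyNA(time_post_admin)) stop("`time_post_admin` must be one of 5, 10, 20",
                                   call. = FALSE)
  if (anyNA(location)) stop("`location` must be 'in' or 'out'", call. = FALSE)
  structure(data.frame(tau = tau, regime = regime,
                       time_post_admin = time_post_admin,
                       location = location,
                       subject_id = as.character(subject_id)),
            class = c("lifetime_dataset", "data.frame"))
}

#' Six-number distribution summary of a lifetime sample
#'
#' The feature vector used for clustering experimental conditions:
#' minimum, first quartile, arithmetic mean, median, third quartile and
#' maximum of the lifetimes, in that order. Quartiles use linear
#' interpolation between order statistics at positions `1 + (n-1)p`
#' (R's default quantile type 7, the convention of `summary()`).
#'
#' @param tau numeric lifetimes in ns, at least one value.
#' @return named numeric vector
#'   `(minimum, q1, mean, median, q3, maximum)`.
#' @examples
#' summary_vector(c(1, 2, 3, 4, 5))
#' @export
summary_vector <- function(tau) {
  if (length(tau) == 0 || any(!is.finite(tau))) {
    stop("`tau` must be a non-empty finite sample", call. = FALSE)
  }
  q <- quantile(tau, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  c(minimum = q[1], q1 = q[2], mean = mean(tau), median = q[3],
    q3 = q[4], maximum = q[5])
}

#' Relative median-mean offset (rel_Md)
#'
#' `rel_Md = 2 (median - mean) / (median + mean)`: a dimensionless
#' asymmetry indicator of the lifetime distribution. Zero indicates
#' Gaussian-like (symmetric) behaviour; values of order 0.03 already mark
#' strongly skewed condition cells.
#'
#' @param tau numeric lifetimes, at least one value.
#' @return scalar in (-2, 2).
#' @examples
#' rel_md(c(1, 2, 3, 4, 100)) # -1.52
#' @export
rel_md <- function(tau) {
  if (length(tau) == 0 || any(!is.finite(tau))) {
    stop("`tau` must be a non-empty finite sample", call. = FALSE)
  }
  m <- mean(tau); md <- median(tau)
  if (md + m == 0) stop("mean + median is zero", call. = FALSE)
  2 * (md - m) / (md + m)
}

#' Relative out-vs-in lifetime contrast (rel_OI)
#'
#' `rel_OI = 2 (mean_out - mean_in) / (mean_out + mean_in)`: the
#' oxygenation-contrast indicator between extravascular (`out`) and
#' intravascular (`in`) mean lifetimes measured under the same regime and
#' time. Antisymmetric under swapping its arguments.
#'
#' @param mean_out,mean_in mean lifetimes in ns, > 0.
#' @return dimensionless scalar (vectorised).
#' @examples
#' rel_oi(733.6, 710.8) # ~0.032
#' @export
rel_oi <- function(mean_out, mean_in) {
  check_positive_finite(mean_out, "mean_out")
  check_positive_finite(mean_in, "mean_in")
  2 * (mean_out - mean_in) / (mean_out + mean_in)
}

#' Per-condition summary table with indicators and oxygenation
#'
#' Aggregates a lifetime dataset into one row per present condition cell in
#' the fixed order regime (0, 10, 20) x time (5, 10, 20) x location
#' (in, out), with the mean and median lifetime, `rel_Md`, `rel_OI`
#' (populated only on `out` rows, from the paired `in` row of the same
#' regime and time), and \% O2 from the Stern-Volmer calibration applied to
#' the mean lifetime. `percent_o2_printed` truncates to 2 decimals, the
#' convention of the published table.
#'
#' @param dataset a [lifetime_dataset()].
#' @param constants a [calibration_constants()] object.
#' @return data frame of class `condition_table`.
#' @export
condition_table <- function(dataset, constants = calibration_constants()) {
  stopifnot(inherits(dataset, "lifetime_dataset"))
  if (nrow(dataset) == 0) stop("empty dataset", call. = FALSE)
  cells <- expand.grid(location = LOCATION_LEVELS, time_post_admin = TIME_LEVELS,
                       regime = REGIME_LEVELS, stringsAsFactors = FALSE)
  cells <- cells[, c("regime", "time_post_admin", "location")]
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- dataset$regime == cells$regime[i] &
      dataset$time_post_admin == cells$time_post_admin[i] &
      dataset$location == cells$location[i]
    if (!any(sel)) next
    tau <- dataset$tau[sel]
    rows[[length(rows) + 1]] <- data.frame(
      regime = cells$regime[i], time_post_admin = cells$time_post_admin[i],
      location = cells$location[i], n = sum(sel),
      mean_tau = mean(tau), median_tau = median(tau), rel_md = rel_md(tau))
  }
  tab <- do.call(rbind, rows)
  tab$rel_oi <- NA_real_
  for (i in which(tab$location == "out")) {
    j <- which(tab$location == "in" & tab$regime == tab$regime[i] &
                 tab$time_post_admin == tab$time_post_admin[i])
    if (length(j) == 1) {
      tab$rel_oi[i] <- rel_oi(tab$mean_tau[i], tab$mean_tau[j])
    } else {
      warning("no 'in' partner for regime ", tab$regime[i], ", ",
              tab$time_post_admin[i], " min; rel_OI left absent",
              call. = FALSE)
    }
  }
  tab$percent_o2 <- tau_to_oxygen(tab$mean_tau, constants)$percent_o2
  tab$percent_o2_printed <- truncate_decimals(tab$percent_o2, 2)
  rownames(tab) <- NULL
  structure(tab, class = c("condition_table", "data.frame"))
}

#' Read / write lifetime datasets as delimited text
#'
#' Tab-separated columns `tau_ns, regime_pct, time_min, location,
#' subject_id` with a header row.
#'
#' @param path file path.
#' @return `read_lifetime_dataset()` returns a [lifetime_dataset()].
#' @export
read_lifetime_dataset <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("numeric", "character", "character",
                                   "character", "character"))
  lifetime_dataset(tab$tau_ns, tab$regime_pct, tab$time_min, tab$location,
                   tab$subject_id)
}

#' @rdname read_lifetime_dataset
#' @param dataset a [lifetime_dataset()] to write.
#' @export
write_lifetime_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "lifetime_dataset"))
  out <- data.frame(tau_ns = dataset$tau,
                    regime_pct = as.character(dataset$regime),
                    time_min = as.character(dataset$time_post_admin),
                    location = as.character(dataset$location),
                    subject_id = dataset$subject_id)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.condition_table <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y$mean_tau <- round(y$mean_tau, 1)
  y$median_tau <- round(y$median_tau, 1)
  y$rel_md <- round(y$rel_md, 3)
  y$rel_oi <- round(y$rel_oi, 3)
  y$percent_o2 <- NULL
  print(y, ...)
  invisible(x)
}
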