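#' Construct a lifetime map
#'
#' Per-pixel lifetime and intensity grids from lifetime imaging (PLIM for
#' phosphorescence in ns, FLIM for fluorescence). Pixels where no lifetime
#' was fitted (dark areas) are `NA` in `tau`.
#'
#' @param tau numeric matrix of lifetimes (ns for PLIM); `NA` = undefined.
#' @param intensity numeric matrix of summed counts, same shape.
#' @param channel `"PLIM"` or `"FLIM"`.
#' @return object of class `lifetime_map`.
#' @export
lifetime_map <- function(tau, intensity, channel = c("PLIM", "FLIM")) {
  channel <- match.arg(channel)
  tau <- as.matrix(tau); intensity <- as.matrix(intensity)
  if (!all(dim(tau) == dim(intensity))) {
    stop("`tau` and `intensity` must have identical shape", call. = FALSE)
  }
  if (any(tau[!is.na(tau)] <= 0)) {
    stop("defined lifetimes must be > 0", call. = FALSE)
  }
  structure(list(tau = tau, intensity = intensity, channel = channel),
            class = "lifetime_map")
}

#' @export
print.lifetime_map <- function(x, ...) {
  cat("lifetime_map (", x$channel, "): ", nrow(x$tau), "x", ncol(x$tau),
      " pixels, ", sum(!is.na(x$tau)), " defined\n", sep = "")
  invisible(x)
}

#' Fit every pixel of a decay stack into a lifetime map
#'
#' Runs [fit_mono()] or [fit_bi_fixed()] on each pixel's decay trace.
#' Pixels with fewer than `min_counts` total counts are left undefined
#' (`NA`), reproducing the dark areas of low-signal regions; defined
#' pixels carry the fitted `tau1` and the summed intensity.
#'
#' @param stack a `decay_stack`: list with `time_ns` (shared bin centres)
#'   and `counts` (array `ny x nx x n_bins`), e.g. from
#'   [generate_scene()].
#' @param model `"mono"` or `"bi_fixed"`.
#' @param min_counts intensity threshold below which a pixel stays
#'   undefined.
#' @param tau2_fixed fixed second lifetime for `model = "bi_fixed"`.
#' @param channel passed to [lifetime_map()].
#' @return a [lifetime_map()].
#' @export
fit_map <- function(stack, model = c("mono", "bi_fixed"), min_counts = 50,
                    tau2_fixed = 20000, channel = "PLIM") {
  model <- match.arg(model)
  if (is.null(stack$counts) || length(stack$counts) == 0) {
    stop("empty stack", call. = FALSE)
  }
  dims <- dim(stack$counts)
  stopifnot(length(dims) == 3, dims[3] == length(stack$time_ns))
  tau <- matrix(NA_real_, dims[1], dims[2])
  intensity <- matrix(0, dims[1], dims[2])
  for (i in seq_len(dims[1])) {
    for (j in seq_len(dims[2])) {
      y <- stack$counts[i, j, ]
      intensity[i, j] <- sum(y)
      if (intensity[i, j] < min_counts) next
      tr <- decay_trace(stack$time_ns, y)
      fit <- if (model == "mono") fit_mono(tr) else
        fit_bi_fixed(tr, tau2_fixed = tau2_fixed)
      if (isTRUE(fit$converged)) tau[i, j] <- fit$tau1
    }
  }
  lifetime_map(tau, intensity, channel = channel)
}

scope_values <- function(map, roi = NULL) {
  v <- map$tau
  if (!is.null(roi)) {
    roi <- as.matrix(roi)
    if (!all(dim(roi) == dim(v))) {
      stop("ROI mask shape must match the map", call. = FALSE)
    }
    if (!any(roi)) stop("ROI is empty", call. = FALSE)
    v[!roi] <- NA
  }
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no defined pixels in scope", call. = FALSE)
  v
}

#' Lifetime histogram of a map
#'
#' Counts defined pixels (optionally restricted to an ROI mask) into
#' lifetime bins of fixed width. Bin edges are aligned to multiples of
#' `bin_width` and extended to cover the data, so the total count always
#' equals the number of defined in-scope pixels. Default width 10 ns
#' matches the 100-1000 ns display range of phosphorescence maps.
#'
#' @param map a [lifetime_map()].
#' @param roi optional logical matrix mask.
#' @param bin_width bin width in ns.
#' @return data frame with `bin_lo`, `bin_hi` (bins are `[lo, hi)`), and
#'   `count`.
#' @export
map_histogram <- function(map, roi = NULL, bin_width = 10) {
  stopifnot(inherits(map, "lifetime_map"), bin_width > 0)
  v <- scope_values(map, roi)
  lo <- bin_width * floor(min(v) / bin_width)
  hi <- bin_width * (floor(max(v) / bin_width) + 1)
  breaks <- seq(lo, hi, by = bin_width)
  idx <- findInterval(v, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             count = counts)
}

#' Split a lifetime map into two populations at a threshold
#'
#' Partitions defined pixels at a lifetime threshold (default 600 ns, the
#' boundary separating the short-lifetime extracellular population from
#' the long-lifetime intracellular one in a bimodal map) and reports each
#' population's size, mean lifetime, oxygen estimate from that mean, and
#' pixel mask. An empty side is returned with `n = 0`, not an error.
#'
#' @param map a [lifetime_map()].
#' @param threshold lifetime threshold in ns; the lower population is
#'   `tau < threshold`, the upper `tau >= threshold`.
#' @param constants [calibration_constants()] for the oxygen estimates
#'   (PLIM maps only; for FLIM maps oxygen is returned as `NA`).
#' @return list with elements `lower` and `upper`, each a list
#'   `(n, mean_tau, percent_o2, mask)`, plus `threshold`.
#' @export
split_bimodal <- function(map, threshold = 600,
                          constants = calibration_constants()) {
  stopifnot(inherits(map, "lifetime_map"))
  if (!any(!is.na(map$tau))) stop("no defined pixels", call. = FALSE)
  side <- function(mask) {
    n <- sum(mask, na.rm = TRUE)
    mean_tau <- if (n > 0) mean(map$tau[which(mask)]) else NA_real_
    o2 <- if (n > 0 && map$channel == "PLIM") {
      tau_to_oxygen(mean_tau, constants)$percent_o2
    } else NA_real_
    mask[is.na(mask)] <- FALSE
    list(n = n, mean_tau = mean_tau, percent_o2 = o2, mask = mask)
  }
  list(lower = side(map$tau < threshold),
       upper = side(map$tau >= threshold),
       threshold = threshold)
}

#' Pixel-wise oxygen map
#'
#' Applies the Stern-Volmer conversion [tau_to_oxygen()] to every defined
#' pixel of a PLIM map. Undefined pixels stay `NA`; pixels whose lifetime
#' exceeds the zero-oxygen lifetime are flagged in `below_calibration`.
#' FLIM maps are refused: the calibration is defined for the
#' phosphorescent oxygen probe only.
#'
#' @param map a [lifetime_map()] with `channel = "PLIM"`.
#' @param constants a [calibration_constants()] object.
#' @return object of class `oxygen_map`: list with `percent_o2` matrix,
#'   logical `below_calibration` matrix, and `constants`.
#' @export
oxygen_map <- function(map, constants = calibration_constants()) {
  stopifnot(inherits(map, "lifetime_map"))
  if (map$channel != "PLIM") {
    stop("oxygen conversion is defined for PLIM maps only", call. = FALSE)
  }
  pct <- map$tau
  def <- !is.na(map$tau)
  if (any(def)) {
    pct[def] <- tau_to_oxygen(map$tau[def], constants)$percent_o2
  }
  structure(list(percent_o2 = pct,
                 below_calibration = !is.na(pct) & pct < 0,
                 constants = constants),
            class = "oxygen_map")
}

#' Region-of-interest statistics of a lifetime map
#'
#' Mean, median and standard deviation of the lifetime and of the
#' pixel-wise oxygen estimate over the defined pixels of an ROI (or of the
#' whole map when `roi` is `NULL`).
#'
#' @param map a [lifetime_map()].
#' @param roi optional logical matrix mask (same shape as the map).
#' @param constants a [calibration_constants()] object.
#' @return data frame with rows `tau_ns` and (for PLIM) `percent_o2`,
#'   columns `mean`, `median`, `sd`, `n`.
#' @export
roi_stats <- function(map, roi = NULL, constants = calibration_constants()) {
  stopifnot(inherits(map, "lifetime_map"))
  v <- scope_values(map, roi)
  out <- data.frame(mean = mean(v), median = median(v),
                    sd = if (length(v) > 1) sd(v) else 0, n = length(v),
                    row.names = "tau_ns")
  if (map$channel == "PLIM") {
    o2 <- tau_to_oxygen(v, constants)$percent_o2
    out <- rbind(out, percent_o2 = data.frame(
      mean = mean(o2), median = median(o2),
      sd = if (length(o2) > 1) sd(o2) else 0, n = length(o2)))
  }
  out
}

#' Read / write dense numeric grids as delimited text
#'
#' Tab-separated matrix text with `NA` for undefined pixels; used for
#' lifetime maps, intensity grids, oxygen maps and ROI masks.
#'
#' @param x numeric or logical matrix.
#' @param path file path.
#' @return `read_grid()` returns a numeric matrix.
#' @export
write_grid <- function(x, path) {
  write.table(as.matrix(x), path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  as.matrix(read.table(path, sep = "\t", header = FALSE))
}
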