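#' Construct a time-binned luminescence decay trace
#'
#' @param time_ns bin centres in nanoseconds, strictly increasing.
#' @param counts photon counts per bin, non-negative, same length.
#' @param background scalar (or per-bin) background count estimate.
#' @param meta free-form list of labels (condition, location, ...).
#' @return object of class `decay_trace`.
#' @export
decay_trace <- function(time_ns, counts, background = 0, meta = list()) {
  stopifnot(is.numeric(time_ns), is.numeric(counts),
            length(time_ns) == length(counts))
  if (length(time_ns) < 2 || any(diff(time_ns) <= 0)) {
    stop("`time_ns` must be strictly increasing with >= 2 bins", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("`counts` must be finite and non-negative", call. = FALSE)
  }
  if (any(background < 0)) stop("`background` must be >= 0", call. = FALSE)
  structure(list(time_ns = as.numeric(time_ns), counts = as.numeric(counts),
                 background = background, meta = meta),
            class = "decay_trace")
}

#' @export
print.decay_trace <- function(x, ...) {
  cat("decay_trace:", length(x$time_ns), "bins,",
      format(x$time_ns[1]), "-", format(x$time_ns[length(x$time_ns)]),
      "ns, total", format(sum(x$counts)), "counts\n")
  invisible(x)
}

decay_model <- function(t, tau1, amplitude1, baseline = 0,
                        tau2 = NULL, amplitude2 = 0) {
  y <- amplitude1 * exp(-t / tau1) + baseline
  if (!is.null(tau2) && amplitude2 > 0) y <- y + amplitude2 * exp(-t / tau2)
  y
}

#' Simulate a luminescence decay trace
#'
#' Expected counts per bin follow `A1*exp(-t/tau1) [+ A2*exp(-t/tau2)] + B`
#' evaluated at bin centres. `noise = "poisson"` draws per-bin Poisson counts
#' (photon counting); `"gaussian"` adds additive noise with standard
#' deviation `sigma` (analog detection); `"none"` returns the expectation.
#'
#' @param tau1 lifetime of the main component, ns (> 0).
#' @param amplitude1 amplitude of the main component, counts (>= 0).
#' @param baseline constant offset, counts (>= 0).
#' @param n_bins number of time bins.
#' @param t_max end of the acquisition window, ns; if shorter than
#'   `3 * tau1` the trace is flagged in `meta$short_window`.
#' @param seed integer seed; required for stochastic noise modes.
#' @param tau2,amplitude2 optional second exponential component.
#' @param noise `"poisson"`, `"gaussian"` or `"none"`.
#' @param sigma Gaussian noise standard deviation (counts).
#' @return a [decay_trace()]; `meta$truth` stores the generating parameters.
#' @examples
#' tr <- simulate_decay(650, 1e4, noise = "none")
#' @export
simulate_decay <- function(tau1, amplitude1, baseline = 0,
                           n_bins = 256, t_max = 5 * tau1, seed = NULL,
                           tau2 = NULL, amplitude2 = 0,
                           noise = c("poisson", "none", "gaussian"),
                           sigma = 1) {
  noise <- match.arg(noise)
  check_positive_finite(tau1, "tau1")
  if (!is.null(tau2)) check_positive_finite(tau2, "tau2")
  stopifnot(amplitude1 >= 0, amplitude2 >= 0, baseline >= 0, n_bins >= 2)
  t <- seq(0, t_max, length.out = n_bins + 1)
  t <- (t[-1] + t[-length(t)]) / 2 # bin centres
  mu <- decay_model(t, tau1, amplitude1, baseline, tau2, amplitude2)
  meta <- list(truth = list(tau1 = tau1, amplitude1 = amplitude1,
                            baseline = baseline, tau2 = tau2,
                            amplitude2 = amplitude2),
               noise = noise)
  if (t_max < 3 * tau1) meta$short_window <- TRUE
  counts <- switch(noise,
    none = mu,
    poisson = {
      if (is.null(seed)) stop("`seed` is required for poisson noise",
                              call. = FALSE)
      with_seed(seed, rpois(length(mu), mu))
    },
    gaussian = {
      if (is.null(seed)) stop("`seed` is required for gaussian noise",
                              call. = FALSE)
      with_seed(seed, pmax(mu + rnorm(length(mu), 0, sigma), 0))
    })
  decay_trace(t, counts, background = baseline, meta = meta)
}

#' Subtract a background level from a decay trace
#'
#' Element-wise `counts - background`, floored at zero (counts cannot go
#' negative). Mirrors the autofluorescence subtraction applied to gated
#' in vivo acquisitions. The input trace is not modified.
#'
#' @param trace a [decay_trace()].
#' @param background scalar or per-bin counts, >= 0; defaults to the
#'   trace's own background estimate.
#' @return a new `decay_trace` with background removed (and set to 0).
#' @export
subtract_background <- function(trace, background = trace$background) {
  stopifnot(inherits(trace, "decay_trace"))
  if (any(background < 0)) stop("`background` must be >= 0", call. = FALSE)
  decay_trace(trace$time_ns, pmax(trace$counts - background, 0),
              background = 0, meta = trace$meta)
}

# Shared least-squares machinery. Initialisation: baseline from the trace
# tail, then tau and A from a log-linear regression of the
# baseline-corrected counts over the early, well-populated bins.
init_mono <- function(t, y) {
  n <- length(t)
  b0 <- mean(y[seq(max(1, n - max(3, n %/% 20) + 1), n)])
  z <- y - b0
  use <- which(z > max(z) * 1e-3 & z > 0)
  if (length(use) < 2) {
    use <- order(y, decreasing = TRUE)[seq_len(max(2, n %/% 4))]
    z <- pmax(y - min(y), .Machine$double.eps)
  }
  fit <- lm(log(z[use]) ~ t[use])
  slope <- coef(fit)[[2]]
  tau0 <- if (is.finite(slope) && slope < 0) -1 / slope else diff(range(t)) / 3
  a0 <- exp(coef(fit)[[1]])
  list(A = max(a0, max(y) - b0, .Machine$double.eps),
       tau = max(tau0, diff(t)[1]), B = max(b0, 0))
}

fit_window_subset <- function(trace, fit_window) {
  t <- trace$time_ns; y <- trace$counts
  if (!is.null(fit_window)) {
    keep <- t >= fit_window[1] & t <= fit_window[2]
    t <- t[keep]; y <- y[keep]
  }
  if (sum(y > 0) < 5) stop("need >= 5 bins with positive counts in the window",
                           call. = FALSE)
  list(t = t, y = y)
}

chi2_reduced <- function(obs, fitted, n_par) {
  sum((obs - fitted)^2 / pmax(obs, 1)) / max(length(obs) - n_par, 1)
}

fit_failure <- function(model, message) {
  structure(list(model = model, converged = FALSE, message = message),
            class = "decay_fit")
}

#' Fit a mono-exponential decay
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `A1*exp(-t/tau1) + B` to a decay trace, initialised from a log-linear
#' regression. The reduced chi-square uses Poisson-variance weights
#' `var = max(counts, 1)` so a good photon-counting fit has `chi2 ~ 1`.
#'
#' @param trace a [decay_trace()].
#' @param fit_window optional `c(start, end)` time range in ns (e.g. a
#'   detection gate); default is the full trace.
#' @return object of class `decay_fit` with `tau1`, `amplitude1`,
#'   `baseline`, `chi2_reduced`, `model = "mono"`, `converged`. On
#'   non-convergence a fit-failure object (`converged = FALSE`) is
#'   returned rather than NaN estimates.
#' @examples
#' tr <- simulate_decay(650, 1e4, noise = "none")
#' fit_mono(tr)$tau1
#' @export
fit_mono <- function(trace, fit_window = NULL) {
  stopifnot(inherits(trace, "decay_trace"))
  if (all(trace$counts == 0)) stop("all-zero counts", call. = FALSE)
  w <- fit_window_subset(trace, fit_window)
  ini <- init_mono(w$t, w$y)
  resid_fn <- function(p) w$y - (p[1] * exp(-w$t / p[2]) + p[3])
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(A = ini$A, tau = ini$tau, B = ini$B),
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) return(fit_failure("mono", conditionMessage(fit)))
  if (!fit$info %in% 1:4) return(fit_failure("mono", fit$message))
  p <- fit$par
  if (!is.finite(p[["tau"]]) || p[["tau"]] <= 0 || p[["A"]] < 0) {
    return(fit_failure("mono", "estimates outside the physical domain"))
  }
  yhat <- decay_model(w$t, p[["tau"]], p[["A"]], p[["B"]])
  structure(list(model = "mono", converged = TRUE,
                 tau1 = p[["tau"]], amplitude1 = p[["A"]], baseline = p[["B"]],
                 chi2_reduced = chi2_reduced(w$y, yhat, 3),
                 fitted = yhat, time_ns = w$t),
            class = "decay_fit")
}

#' Fit a bi-exponential decay with a fixed long-lived component
#'
#' Fits `A1*exp(-t/tau1) + A2*exp(-t/tau2_fixed) + B` with `tau2` held at a
#' configured value (default 20,000 ns, the convention for per-pixel
#' phosphorescence maps where a sparse very-long-lived component is
#' absorbed by a fixed second exponential). Free parameters are
#' `A1, tau1, A2, B`; the amplitude fraction `A2/(A1+A2)` of the fixed
#' component is reported but not thresholded.
#'
#' @inheritParams fit_mono
#' @param tau2_fixed fixed second lifetime in ns (> 0).
#' @return a `decay_fit` with additionally `tau2`, `amplitude2`,
#'   `amplitude_fraction2`, `model = "bi_fixed"`.
#' @export
fit_bi_fixed <- function(trace, tau2_fixed = 20000, fit_window = NULL) {
  stopifnot(inherits(trace, "decay_trace"))
  check_positive_finite(tau2_fixed, "tau2_fixed")
  if (all(trace$counts == 0)) stop("all-zero counts", call. = FALSE)
  w <- fit_window_subset(trace, fit_window)
  ini <- init_mono(w$t, w$y)
  resid_fn <- function(p) {
    w$y - (p[1] * exp(-w$t / p[2]) + p[3] * exp(-w$t / tau2_fixed) + p[4])
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(A1 = ini$A, tau1 = ini$tau,
                               A2 = ini$A * 1e-3, B = ini$B),
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(fit_failure("bi_fixed", conditionMessage(fit)))
  }
  if (!fit$info %in% 1:4) return(fit_failure("bi_fixed", fit$message))
  p <- fit$par
  if (!is.finite(p[["tau1"]]) || p[["tau1"]] <= 0 || p[["A1"]] < 0) {
    return(fit_failure("bi_fixed", "estimates outside the physical domain"))
  }
  yhat <- decay_model(w$t, p[["tau1"]], p[["A1"]], p[["B"]],
                      tau2_fixed, p[["A2"]])
  structure(list(model = "bi_fixed", converged = TRUE,
                 tau1 = p[["tau1"]], amplitude1 = p[["A1"]],
                 tau2 = tau2_fixed, amplitude2 = p[["A2"]],
                 amplitude_fraction2 = p[["A2"]] / (p[["A1"]] + p[["A2"]]),
                 baseline = p[["B"]],
                 chi2_reduced = chi2_reduced(w$y, yhat, 4),
                 fitted = yhat, time_ns = w$t),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (!x$converged) {
    cat("decay_fit (", x$model, "): DID NOT CONVERGE -", x$message, "\n")
    return(invisible(x))
  }
  cat("decay_fit (", x$model, "): tau1 =", format(x$tau1), "ns, A1 =",
      format(x$amplitude1), ", baseline =", format(x$baseline),
      ", chi2_red =", format(x$chi2_reduced), "\n")
  if (x$model == "bi_fixed") {
    cat("  fixed tau2 =", format(x$tau2), "ns, A2 fraction =",
        format(x$amplitude_fraction2), "\n")
  }
  invisible(x)
}

#' Read / write decay traces as two-column delimited text
#'
#' Format: comment header lines `# key: value` carrying metadata, then
#' whitespace-delimited columns `time_ns counts`.
#'
#' @param path file path.
#' @return `read_decay_trace()` returns a [decay_trace()];
#'   `write_decay_trace()` returns `path` invisibly.
#' @export
read_decay_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    i <- regexpr(":", kv)
    if (i > 0) meta[[trimws(substr(kv, 1, i - 1))]] <-
        trimws(substr(kv, i + 1, nchar(kv)))
  }
  tab <- read.table(text = lines[!grepl("^#", lines) & nzchar(lines)],
                    col.names = c("time_ns", "counts"))
  decay_trace(tab$time_ns, tab$counts, meta = meta)
}

#' @rdname read_decay_trace
#' @param trace a [decay_trace()] to write.
#' @export
write_decay_trace <- function(trace, path) {
  stopifnot(inherits(trace, "decay_trace"))
  meta <- trace$meta[vapply(trace$meta, function(x)
    is.character(x) || is.numeric(x), logical(1))]
  hdr <- sprintf("# %s: %s", names(meta), vapply(meta, format, character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(data.frame(time_ns = trace$time_ns, counts = trace$counts),
              con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
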