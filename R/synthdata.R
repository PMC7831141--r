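#' Specification of one synthetic condition cell
#'
#' Describes the lifetime distribution to generate for one experimental
#' condition: its target mean, target distribution asymmetry (rel_Md),
#' dispersion and sample size.
#'
#' @param regime oxygen regime (\% O2 in N2): 0, 10 or 20.
#' @param time_post_admin minutes post administration: 5, 10 or 20.
#' @param location `"in"` or `"out"`.
#' @param target_mean target mean lifetime, ns (> 0).
#' @param target_rel_md target [rel_md()], `|target_rel_md| < 2`.
#' @param dispersion sd-like scale in ns; default is a coefficient of
#'   variation of 0.08.
#' @param n_samples number of lifetimes to draw (>= 1).
#' @return object of class `condition_spec`.
#' @export
condition_spec <- function(regime, time_post_admin, location, target_mean,
                           target_rel_md = 0,
                           dispersion = 0.08 * target_mean,
                           n_samples = 500) {
  check_positive_finite(target_mean, "target_mean")
  check_positive_finite(dispersion, "dispersion")
  stopifnot(abs(target_rel_md) < 2, n_samples >= 1)
  structure(list(regime = as.character(regime),
                 time_post_admin = as.character(time_post_admin),
                 location = match.arg(location, c("in", "out")),
                 target_mean = target_mean, target_rel_md = target_rel_md,
                 dispersion = dispersion, n_samples = as.integer(n_samples)),
            class = "condition_spec")
}

# Draw a sample with prescribed mean, sd-scale and median-mean offset.
# Family: shifted gamma. The target rel_md fixes the population median
# Md = mean (2 + r) / (2 - r); the gamma shape k is solved from
#   (k - qgamma(0.5, k)) / sqrt(k) = |Md - mean| / sd
# on the decreasing branch of that function (k above its argmax ~0.285,
# where the attainable maximum is ~0.414). delta < 0 uses the
# right-skewed gamma directly; delta > 0 its reflection; delta ~ 0 the
# Gaussian limit. Draws are kept strictly positive by resampling the
# (vanishingly rare) non-positive values.
rskewed <- function(n, mean, sd, rel_md_target) {
  md <- mean * (2 + rel_md_target) / (2 - rel_md_target)
  delta <- md - mean
  if (abs(delta) < 1e-10 * mean) {
    x <- rnorm(n, mean, sd)
  } else {
    g <- function(k) (k - qgamma(0.5, k)) / sqrt(k)
    kstar <- optimize(g, c(0.01, 5), maximum = TRUE)
    ratio <- abs(delta) / sd
    if (ratio >= kstar$objective) {
      stop("target rel_md unattainable for the shifted-gamma family at ",
           "this dispersion (need |median-mean|/sd < ",
           format(kstar$objective, digits = 3), ")", call. = FALSE)
    }
    k <- uniroot(function(k) g(k) - ratio, c(kstar$maximum, 1e8),
                 tol = 1e-12)$root
    theta <- sd / sqrt(k)
    draw <- rgamma(n, shape = k, scale = theta)
    x <- if (delta < 0) mean - k * theta + draw else mean + k * theta - draw
  }
  bad <- which(x <= 0)
  guard <- 0
  while (length(bad) > 0 && guard < 100) {
    x[bad] <- rnorm(length(bad), mean, sd / 10)
    bad <- which(x <= 0)
    guard <- guard + 1
  }
  x
}

#' Generate synthetic lifetimes for one condition cell
#'
#' Draws `n_samples` lifetimes from a skewed (shifted-gamma) distribution
#' whose population mean equals `target_mean` and whose population
#' [rel_md()] equals `target_rel_md` (the sample statistics converge to
#' the targets as `n` grows). Symmetric targets fall back to a Gaussian.
#' Bit-identical reproducible under a fixed seed.
#'
#' @param spec a [condition_spec()].
#' @param seed integer seed (mandatory).
#' @return a [lifetime_dataset()] with `n_samples` rows; `subject_id`
#'   cycles over ten synthetic subjects.
#' @export
generate_condition_samples <- function(spec, seed) {
  stopifnot(inherits(spec, "condition_spec"))
  tau <- with_seed(seed, rskewed(spec$n_samples, spec$target_mean,
                                 spec$dispersion, spec$target_rel_md))
  lifetime_dataset(tau, spec$regime, spec$time_post_admin, spec$location,
                   subject_id = paste0("egg",
                                       rep_len(1:10, spec$n_samples)))
}

#' Condition specifications of the published CAM table
#'
#' Returns the 18 condition cells of the in vivo chorioallantoic-membrane
#' study (3 oxygen regimes x 3 administration times x in/out of vessels)
#' with their published mean lifetimes and rel_Md values as generation
#' targets.
#'
#' @param n_samples lifetimes per cell (default 500: the study measured
#'   ten eggs per condition with repeated point decays per egg; the
#'   default is sized so the regime structure is resolvable by the
#'   clustering stage at the default dispersion).
#' @param dispersion_cv coefficient of variation of the lifetime
#'   dispersion (default 0.08).
#' @return list of 18 [condition_spec()]s.
#' @export
table1_specs <- function(n_samples = 500, dispersion_cv = 0.08) {
  tab <- data.frame(
    regime = rep(c("0", "10", "20"), each = 6),
    time   = rep(rep(c("5", "10", "20"), each = 2), 3),
    loc    = rep(c("in", "out"), 9),
    mean   = c(710.8, 733.6, 743.1, 768.4, 774.3, 796.6,
               626.5, 670.4, 616.6, 683.3, 679.6, 681.1,
               609.0, 633.3, 624.9, 651.3, 644.6, 648.5),
    rel_md = c(0.029, 0.009, 0.013, 0.024, -0.006, 0.030,
               0.005, -0.013, 0.000, -0.018, -0.001, -0.004,
               0.012, -0.005, 0.008, 0.012, 0.005, -0.011))
  lapply(seq_len(nrow(tab)), function(i) {
    condition_spec(tab$regime[i], tab$time[i], tab$loc[i], tab$mean[i],
                   tab$rel_md[i], dispersion = dispersion_cv * tab$mean[i],
                   n_samples = n_samples)
  })
}

#' Generate a full synthetic dataset from a list of condition specs
#'
#' Each cell gets its own seed derived deterministically from the
#' top-level seed and the cell labels.
#'
#' @param specs list of [condition_spec()]s, e.g. [table1_specs()].
#' @param seed integer top-level seed.
#' @return a [lifetime_dataset()] with the rows of all cells.
#' @export
generate_dataset <- function(specs, seed) {
  parts <- lapply(specs, function(sp) {
    generate_condition_samples(
      sp, derive_seed(seed, paste(sp$regime, sp$time_post_admin,
                                  sp$location)))
  })
  out <- do.call(rbind, parts)
  structure(out, class = c("lifetime_dataset", "data.frame"))
}

#' Specification of a synthetic lifetime scene
#'
#' A 2-D scene with labelled regions of constant lifetime and intensity
#' over an optional uniform background, emulating a field of cells
#' (long-lifetime, low-oxygen interiors) in an extracellular medium.
#'
#' @param shape `c(ny, nx)` grid shape.
#' @param regions named list; each element a list with `mask` (logical
#'   matrix), `tau` (ns) and `intensity` (expected total counts per
#'   pixel). Regions must not overlap.
#' @param background `NULL` for empty (dark) background, else a list
#'   `(tau, intensity)` filling all pixels outside the regions.
#' @param channel `"PLIM"` or `"FLIM"`.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(shape, regions, background = NULL,
                       channel = c("PLIM", "FLIM")) {
  channel <- match.arg(channel)
  stopifnot(length(shape) == 2, all(shape >= 1))
  cover <- matrix(0L, shape[1], shape[2])
  for (r in regions) {
    stopifnot(is.list(r), all(dim(r$mask) == shape))
    check_positive_finite(r$tau, "region tau")
    cover <- cover + r$mask
  }
  if (any(cover > 1)) stop("regions overlap", call. = FALSE)
  if (!is.null(background)) check_positive_finite(background$tau, "background tau")
  structure(list(shape = shape, regions = regions, background = background,
                 channel = channel),
            class = "scene_spec")
}

#' Circular mask helper
#'
#' @param shape `c(ny, nx)`.
#' @param center `c(row, col)` of the disc centre.
#' @param radius disc radius in pixels.
#' @return logical matrix.
#' @export
disc_mask <- function(shape, center, radius) {
  outer(seq_len(shape[1]), seq_len(shape[2]),
        function(i, j) (i - center[1])^2 + (j - center[2])^2 <= radius^2)
}

#' Named scene presets
#'
#' * `"fig5_cells"`: extracellular background at 650 ns with three
#'   cell-like discs at 800 ns (the two-population configuration of a
#'   probe excluded from cytoplasm vs. endocytosed probe).
#' * `"fig8_h2o2"`: background quenched to 400 ns (peroxide-treated
#'   medium, ~35\% O2) with 800 ns cell interiors.
#' * `"uniform"`: constant 650 ns field.
#' * `"cells_dark_bg"`: the fig5 discs over an empty background (dark,
#'   unfit pixels outside the cells).
#'
#' @param name preset name.
#' @param shape grid shape, default `c(24, 24)`.
#' @return a [scene_spec()].
#' @export
scene_preset <- function(name = c("fig5_cells", "fig8_h2o2", "uniform",
                                  "cells_dark_bg"),
                         shape = c(24, 24)) {
  name <- match.arg(name)
  discs <- list(
    cell1 = list(mask = disc_mask(shape, shape * 0.3, min(shape) * 0.14),
                 tau = 800, intensity = 3000),
    cell2 = list(mask = disc_mask(shape, shape * 0.7, min(shape) * 0.17),
                 tau = 800, intensity = 3000),
    cell3 = list(mask = disc_mask(shape, c(shape[1] * 0.25, shape[2] * 0.75),
                                  min(shape) * 0.10),
                 tau = 800, intensity = 3000))
  switch(name,
    fig5_cells = scene_spec(shape, discs,
                            background = list(tau = 650, intensity = 2000)),
    fig8_h2o2 = scene_spec(shape, discs,
                           background = list(tau = 400, intensity = 2000)),
    uniform = scene_spec(shape, list(),
                         background = list(tau = 650, intensity = 2000)),
    cells_dark_bg = scene_spec(shape, discs, background = NULL))
}

#' Generate a per-pixel decay stack from a scene
#'
#' Every pixel's expected decay follows its region's lifetime via the
#' mono-exponential model, with the pixel amplitude scaled so the expected
#' total counts equal the region intensity. `noise = "poisson"` draws
#' photon-counting noise; `"none"` returns expectations. Ground-truth
#' region masks are returned for accuracy scoring.
#'
#' @param spec a [scene_spec()] (or preset name for [scene_preset()]).
#' @param noise `"none"` or `"poisson"`.
#' @param seed integer seed (required for Poisson noise).
#' @param n_bins,t_max time binning of the simulated decays (ns).
#' @return list with `stack` (a `decay_stack`: `time_ns` + `counts` array
#'   `ny x nx x n_bins`), `masks` (named list of logical matrices,
#'   including `background` if present), and `spec`.
#' @export
generate_scene <- function(spec, noise = c("none", "poisson"), seed = NULL,
                           n_bins = 64, t_max = 4000) {
  if (is.character(spec)) spec <- scene_preset(spec)
  stopifnot(inherits(spec, "scene_spec"))
  noise <- match.arg(noise)
  t <- seq(0, t_max, length.out = n_bins + 1)
  t <- (t[-1] + t[-length(t)]) / 2
  ny <- spec$shape[1]; nx <- spec$shape[2]
  mu <- array(0, c(ny, nx, n_bins))
  masks <- lapply(spec$regions, `[[`, "mask")
  bg_mask <- Reduce(`&`, lapply(masks, `!`), matrix(TRUE, ny, nx))
  fill <- function(mask, tau, intensity) {
    shape_t <- exp(-t / tau)
    a <- intensity / sum(shape_t)
    idx <- which(mask)
    for (b in seq_len(n_bins)) {
      plane <- mu[, , b]
      plane[idx] <- a * shape_t[b]
      mu[, , b] <<- plane
    }
  }
  for (r in spec$regions) fill(r$mask, r$tau, r$intensity)
  if (!is.null(spec$background)) {
    fill(bg_mask, spec$background$tau, spec$background$intensity)
    masks$background <- bg_mask
  }
  counts <- if (noise == "none") mu else {
    if (is.null(seed)) stop("`seed` is required for poisson noise",
                            call. = FALSE)
    array(with_seed(seed, rpois(length(mu), mu)), dim(mu))
  }
  list(stack = structure(list(time_ns = t, counts = counts),
                         class = "decay_stack"),
       masks = masks, spec = spec)
}
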