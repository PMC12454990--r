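# Comparison with (real or synthetic) measured skin temperatures, validation
# statistics, and equivalent-layer heat-source calibration.

# measurement sites and the model segment each maps onto; the back has no
# model segment of its own and is compared against the shoulder skin node
.sites <- c(head = "head", upper_arm = "upper_arm", lower_arm = "lower_arm",
            l_chest = "chest", r_chest = "chest",
            l_abdomen = "abdomen", r_abdomen = "abdomen",
            l_thigh = "l_thigh", r_thigh = "r_thigh",
            l_calf = "l_calf", r_calf = "r_calf",
            back = "shoulder")
.bilateral_pairs <- list(chest = c("l_chest", "r_chest"),
                         abdomen = c("l_abdomen", "r_abdomen"),
                         thigh = c("l_thigh", "r_thigh"),
                         calf = c("l_calf", "r_calf"))

#' Measurement site names
#'
#' The twelve button-logger sites and the model segment each is compared
#' against (bilateral chest/abdomen sites share one model segment; the back
#' maps to the shoulder segment).
#'
#' @return Named character vector: site -> model segment.
#' @export
measurement_sites <- function() .sites

#' Simulated skin temperature at each measurement site
#'
#' @param result A `simulation_result`.
#' @return Named vector of skin temperatures, degrees C, one per site.
#' @export
site_temperatures <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  stats::setNames(result$steady$T[.sites, "skin"], names(.sites))
}

#' Generate synthetic button-logger measurements
#'
#' Emulates the field protocol: per-site series of skin temperature at
#' one-minute cadence, equal to the simulated steady skin temperature plus
#' Gaussian sensor noise (sd `noise_sd`, default 0.05 degrees C, the loggers'
#' stated accuracy) plus, on the four bilateral site pairs, a per-side
#' constant offset (Gaussian, sd `bilateral_sd`) standing in for left-right
#' physiological asymmetry. Defaults keep the mean absolute left-right
#' difference well inside the 2 degree field observation. Reproducible given
#' the seed; the caller's RNG state is untouched.
#'
#' @param result A converged `simulation_result`.
#' @param noise_sd Sensor noise standard deviation, degrees C.
#' @param bilateral_sd Per-side offset standard deviation, degrees C.
#' @param seed Integer seed.
#' @param n_samples Series length (default 60 one-minute samples).
#' @return Object of class `measurement_set`: matrix `n_samples` x 12 sites
#'   with attributes `Ta`, `ensemble`, `seed`, `interval_s`.
#' @export
generate_synthetic_measurements <- function(result, noise_sd = 0.05,
                                            bilateral_sd = 0.6, seed = 1,
                                            n_samples = 60) {
  stopifnot(inherits(result, "simulation_result"), result$converged,
            noise_sd >= 0, bilateral_sd >= 0, n_samples >= 1, n_samples <= 60)
  base <- site_temperatures(result)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  offset <- stats::setNames(numeric(length(.sites)), names(.sites))
  for (p in .bilateral_pairs)
    offset[p] <- stats::rnorm(2, 0, bilateral_sd)
  series <- sapply(names(.sites), function(s)
    base[[s]] + offset[[s]] + stats::rnorm(n_samples, 0, noise_sd))
  series <- matrix(series, nrow = n_samples,
                   dimnames = list(NULL, names(.sites)))
  if (any(series <= -40 | series >= 85))
    stop("generated temperature outside the sensor range (-40, 85) C")
  structure(series, class = "measurement_set",
            Ta = result$env$Ta, ensemble = attr(result$clothing, "name"),
            seed = seed, interval_s = 60)
}

#' Write / read measurement CSV
#'
#' Long format `timestamp, site, temperature_C`, timestamps in seconds at
#' one-minute cadence. The reader validates the cadence, the site names and
#' the sensor range.
#'
#' @param meas A `measurement_set`.
#' @param path CSV path.
#' @return `write_measurements`: `path`, invisibly. `read_measurements`: a
#'   `measurement_set`.
#' @export
write_measurements <- function(meas, path) {
  stopifnot(inherits(meas, "measurement_set"))
  n <- nrow(meas)
  long <- data.frame(
    timestamp = rep(seq(0, by = attr(meas, "interval_s"), length.out = n),
                    times = ncol(meas)),
    site = rep(colnames(meas), each = n),
    temperature_C = as.vector(meas)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "site", "temperature_C")
  if (!all(need %in% names(long))) stop("measurement CSV needs columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(long$site), names(.sites))
  if (length(bad)) stop("unknown measurement site(s): ", paste(bad, collapse = ", "))
  ts <- sort(unique(long$timestamp))
  if (length(ts) > 1 && any(diff(ts) != 60))
    stop("sampling interval must be 60 s")
  if (length(ts) > 60) stop("series longer than the 60-sample protocol")
  if (any(long$temperature_C <= -40 | long$temperature_C >= 85))
    stop("temperature outside the sensor range (-40, 85) C")
  sites <- unique(long$site)
  m <- sapply(sites, function(s)
    long$temperature_C[long$site == s][order(long$timestamp[long$site == s])])
  structure(matrix(m, ncol = length(sites), dimnames = list(NULL, sites)),
            class = "measurement_set", interval_s = 60)
}

.stable_means <- function(meas, stable_window = 30) {
  n <- nrow(meas)
  take <- max(1, n - stable_window + 1):n
  colMeans(meas[take, , drop = FALSE])
}

#' Relative error between simulated and measured skin temperatures
#'
#' Per site, `100 * |T_sim - mean(T_meas, stable)| / mean(T_meas, stable)`
#' with temperatures in degrees C and the measured value taken as the mean of
#' the final `stable_window` one-minute samples (default 30). Also reports
#' the maximum over sites, the relative error of the site-mean body
#' temperature, and the mean absolute bilateral (left-right) difference of
#' the measured values.
#'
#' @param sim Named per-site simulated temperatures (degrees C), or a
#'   `simulation_result` (sites derived via [site_temperatures()]).
#' @param meas A `measurement_set`.
#' @param stable_window Number of trailing samples averaged.
#' @return Object of class `error_report`: list with `per_site` (%),
#'   `max_relative_error` (%), `mean_temperature_error` (%),
#'   `mean_bilateral_diff` (degrees C).
#' @export
relative_errors <- function(sim, meas, stable_window = 30) {
  if (inherits(sim, "simulation_result")) sim <- site_temperatures(sim)
  stopifnot(nrow(meas) >= 1)
  common <- intersect(names(sim), colnames(meas))
  if (!length(common)) stop("validation error: no common measurement sites")
  m <- .stable_means(meas, stable_window)[common]
  err <- 100 * abs(sim[common] - m) / m
  pairs_here <- Filter(function(p) all(p %in% colnames(meas)), .bilateral_pairs)
  bil <- if (length(pairs_here)) {
    mm <- .stable_means(meas, stable_window)
    mean(vapply(pairs_here, function(p) abs(mm[p[1]] - mm[p[2]]), numeric(1)))
  } else NA_real_
  structure(list(
    per_site = err,
    max_relative_error = max(err),
    mean_temperature_error = 100 * abs(mean(sim[common]) - mean(m)) / mean(m),
    mean_bilateral_diff = bil
  ), class = "error_report")
}

#' Skin-temperature change relative to a baseline ambient
#'
#' Given results (or site temperatures) at several ambient temperatures, the
#' absolute change of each site relative to the baseline run, and the mean of
#' those changes per site.
#'
#' @param sweep A list of `simulation_result`s, a numeric matrix
#'   (sites x ambients), or a numeric vector (one site across ambients).
#' @param baseline_index Index of the reference entry (default 1).
#' @return List with `changes` (per site x non-baseline ambient, degrees C)
#'   and `mean_change` (per site).
#' @export
head_change_summary <- function(sweep, baseline_index = 1) {
  if (is.list(sweep) && all(vapply(sweep, inherits, TRUE, "simulation_result")))
    sweep <- sapply(sweep, site_temperatures)
  if (is.vector(sweep) && is.numeric(sweep)) sweep <- matrix(sweep, nrow = 1)
  stopifnot(is.matrix(sweep), ncol(sweep) >= 2)
  if (baseline_index < 1 || baseline_index > ncol(sweep))
    stop("validation error: baseline index not present")
  changes <- abs(sweep[, -baseline_index, drop = FALSE] - sweep[, baseline_index])
  list(changes = changes, mean_change = rowMeans(changes))
}

#' Reference ranges for equivalent-layer heat sources
#'
#' Published per-segment ranges (W) of the calibrated equivalent-layer heat
#' source over the 0-14 degree ambient span, used by
#' [calibrate_equivalent_heat_sources()] to flag calibrated values as in or
#' out of range. Segments without a published range carry `NA`.
#'
#' @return Data frame with `segment`, `lo`, `hi` (W).
#' @export
equivalent_source_ranges <- function() {
  data.frame(
    segment = .segments,
    lo = c(22.04, NA, 1.10, 5.40, 0.63, 2.27, NA, 3.30, 2.12, 12.19, 11.38, NA),
    hi = c(43.54, NA, 12.12, 24.72, 2.35, 4.53, NA, 7.03, 6.07, 22.87, 20.69, NA)
  )
}

#' Calibrate equivalent-layer heat sources against target skin temperatures
#'
#' For each requested segment, a scalar root find on the equivalent-layer
#' heat source (replacing that segment's metabolic + work + shivering input)
#' such that the steady skin temperature matches the target within `tol`
#' (default 0.05 degrees C). Segments are calibrated one at a time with the
#' rest of the body at its default physiology. Calibrated values are flagged
#' against [equivalent_source_ranges()].
#'
#' @param model,clothing,env Simulation inputs.
#' @param target_skin_T Named vector of target skin temperatures, degrees C.
#' @param bounds Named list of `(lo, hi)` source bounds, W; the root is
#'   bracketed within `c(0.1*lo, 10*hi)`. Default `c(0.5, 60)` per segment.
#' @param tol Temperature match tolerance, degrees C.
#' @param options Passed to [simulate_body()].
#' @return Data frame: `segment`, `source_W`, `target_C`, `achieved_C`,
#'   `in_bounds` (against the reference ranges; `NA` where no range exists).
#' @export
calibrate_equivalent_heat_sources <- function(model, clothing, env,
                                              target_skin_T, bounds = NULL,
                                              tol = 0.05, options = list()) {
  stopifnot(!is.null(names(target_skin_T)),
            all(names(target_skin_T) %in% .segments))
  ranges <- equivalent_source_ranges()
  out <- lapply(names(target_skin_T), function(segname) {
    target <- target_skin_T[[segname]]
    b <- if (!is.null(bounds) && !is.null(bounds[[segname]])) bounds[[segname]] else c(0.5, 60)
    stopifnot(length(b) == 2, b[1] <= b[2])
    bracket <- c(0.1 * b[1], 10 * b[2])
    # steady skin temperature is monotone increasing in the source, so a
    # simulation pushed outside the physical temperature range by a large
    # trial source counts as "far above target"
    skin_at <- function(Q) {
      ov <- stats::setNames(Q, segname)
      tryCatch({
        res <- simulate_body(model, clothing, env, mode = "steady",
                             options = c(options, list(eq_source_override = ov)))
        res$steady$T[segname, "skin"]
      }, error = function(e) 50)
    }
    f <- function(Q) skin_at(Q) - target
    flo <- f(bracket[1]); fhi <- f(bracket[2])
    if (flo * fhi > 0)
      stop("calibration error: root not bracketed for segment ", segname,
           " within [", bracket[1], ", ", bracket[2], "] W")
    r <- stats::uniroot(f, bracket, f.lower = flo, f.upper = fhi, tol = 1e-3)
    achieved <- target + r$f.root
    if (abs(achieved - target) > tol)
      stop("calibration error: segment ", segname, " matched only to ",
           format(abs(achieved - target), digits = 3), " C")
    rng <- ranges[ranges$segment == segname, ]
    data.frame(segment = segname, source_W = r$root, target_C = target,
               achieved_C = achieved,
               in_bounds = if (is.na(rng$lo)) NA else (r$root >= rng$lo & r$root <= rng$hi))
  })
  do.call(rbind, out)
}

#' Realized equivalent-layer heat sources of a steady state
#'
#' The total heat (metabolism with cold boost, external work, shivering)
#' entering each segment's equivalent layer at the converged state — the
#' quantity [calibrate_equivalent_heat_sources()] recovers.
#'
#' @param result A `simulation_result`.
#' @return Named vector, W.
#' @export
equivalent_sources <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  with(result$fluxes, stats::setNames(Q[, 2] + W_work + Ch, .segments))
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> max site error %.2f%%, mean-temperature error %.2f%%, mean |L-R| %.2f C\n",
              x$max_relative_error, x$mean_temperature_error, x$mean_bilateral_diff))
  invisible(x)
}
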