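# PSII thermal-tolerance trait extraction from chlorophyll fluorescence
# temperature ramps: Tcrit (slow/fast-rise breakpoint of basal fluorescence
# F0) and Tmax (temperature of maximum F0), plus per-species acclimation
# deltas between treatment arms.

#' Read fluorescence traces from a long-format CSV
#'
#' @param path CSV with columns `sample_id`, `species_id`, `treatment`,
#'   `direction` (heating/cooling), `temperature_C`, `f0`.
#' @return a list of trace lists, one per `sample_id`, each with fields
#'   `sample_id`, `species_id`, `treatment`, `direction`, `temperature`, `f0`.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "species_id", "treatment", "direction",
            "temperature_C", "f0")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_data("trace file %s missing column(s): %s", path,
              paste(missing, collapse = ", "))
  lapply(split(df, df$sample_id), function(b) {
    list(sample_id = b$sample_id[1], species_id = b$species_id[1],
         treatment = tolower(b$treatment[1]),
         direction = tolower(b$direction[1]),
         temperature = b$temperature_C, f0 = b$f0)
  })
}

# QC: drop non-finite points, average duplicate temperatures, sort along the
# ramp direction. Returns temperature/f0 on the analysis axis (temperature
# negated for cooling ramps so the rise phase is always toward +T).
prepare_trace <- function(trace) {
  temp <- trace$temperature
  f0 <- trace$f0
  ok <- is.finite(temp) & is.finite(f0)
  temp <- temp[ok]; f0 <- f0[ok]
  if (any(f0 < 0)) stop_data("trace %s has negative F0", trace$sample_id)
  cooling <- identical(trace$direction, "cooling")
  if (cooling) temp <- -temp
  o <- order(temp)
  temp <- temp[o]; f0 <- f0[o]
  if (anyDuplicated(temp)) {
    f0 <- as.numeric(tapply(f0, temp, mean))
    temp <- sort(unique(temp))
  }
  if (length(temp) < 20L)
    stop_data("trace %s has fewer than 20 usable points", trace$sample_id)
  list(temp = temp, f0 = f0, cooling = cooling)
}

smooth_f0 <- function(f0, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window >= length(f0)) window <- length(f0) - (1 - length(f0) %% 2L)
  as.numeric(stats::runmed(f0, window))
}

#' Critical temperature from a fluorescence ramp
#'
#' Fits the continuous two-segment piecewise-linear model
#' `F0 = b0 + b1 * T + b2 * (T - psi)+` by least squares, with the breakpoint
#' `psi` searched on a dense grid over the central 80% of the temperature
#' range, and returns `t_crit` as the RSS-minimizing breakpoint — the onset
#' of the fast rise in basal fluorescence. Cooling ramps are analyzed on the
#' negated temperature axis and the result negated back. The trace is first
#' truncated at its smoothed F0 maximum, since the slow/fast-rise breakpoint
#' precedes the fluorescence peak.
#'
#' @param trace a trace list (see [read_traces()]).
#' @param grid_step breakpoint grid resolution in degrees C, default 0.1.
#' @param min_improvement minimum relative RSS improvement over a single
#'   straight line for a breakpoint to be accepted, default 0.05.
#' @param smoothing_window rolling-median window used for the pre-fit
#'   truncation at the F0 peak.
#' @return a `tcrit_fit`: list with `t_crit` (degrees C, original axis),
#'   `slope_slow`, `slope_fast`, `rss`, `rss_line`, `n_points`,
#'   `slow_fast_warning` (TRUE when the fast-phase slope does not exceed the
#'   slow-phase slope), `sample_id`.
#' @export
fit_tcrit <- function(trace, grid_step = 0.1, min_improvement = 0.05,
                      smoothing_window = 5) {
  tr <- prepare_trace(trace)
  temp <- tr$temp; f0 <- tr$f0
  # truncate at the (smoothed) fluorescence peak; breakpoint lies below it
  sm <- smooth_f0(f0, smoothing_window)
  peak <- which.max(sm)
  if (peak > 20L) {
    temp <- temp[seq_len(peak)]
    f0 <- f0[seq_len(peak)]
  }
  rng <- range(temp)
  span <- diff(rng)
  lo <- rng[1] + 0.1 * span
  hi <- rng[2] - 0.1 * span
  grid <- seq(lo, hi, by = grid_step)
  if (length(grid) < 3L) stop_data("temperature range too narrow for breakpoint search")
  rss_line <- sum(stats::lm.fit(cbind(1, temp), f0)$residuals^2)
  rss <- vapply(grid, function(psi) {
    X <- cbind(1, temp, pmax(temp - psi, 0))
    sum(stats::lm.fit(X, f0)$residuals^2)
  }, numeric(1))
  best <- which.min(rss)
  if (best == 1L || best == length(grid))
    stop_data("no breakpoint detected in trace %s (RSS minimum at search boundary)",
              trace$sample_id %||% "<unnamed>")
  improvement <- if (rss_line > 0) (rss_line - rss[best]) / rss_line else 0
  if (improvement < min_improvement)
    stop_data("no breakpoint detected in trace %s (two-segment fit no better than a line)",
              trace$sample_id %||% "<unnamed>")
  psi <- grid[best]
  X <- cbind(1, temp, pmax(temp - psi, 0))
  beta <- stats::lm.fit(X, f0)$coefficients
  slope_slow <- beta[2]
  slope_fast <- beta[2] + beta[3]
  warn <- abs(slope_fast) <= abs(slope_slow)
  if (warn)
    warn_data("trace %s: fast-phase slope does not exceed slow-phase slope",
              trace$sample_id %||% "<unnamed>")
  structure(list(
    t_crit = if (tr$cooling) -psi else psi,
    slope_slow = unname(slope_slow), slope_fast = unname(slope_fast),
    rss = rss[best], rss_line = rss_line, n_points = length(temp),
    slow_fast_warning = warn, sample_id = trace$sample_id %||% NA_character_
  ), class = "tcrit_fit")
}

#' @export
print.tcrit_fit <- function(x, ...) {
  cat(sprintf("Tcrit = %.2f C (slopes %.4g -> %.4g, RSS %.4g, n = %d)%s\n",
              x$t_crit, x$slope_slow, x$slope_fast, x$rss, x$n_points,
              if (x$slow_fast_warning) "  [slope warning]" else ""))
  invisible(x)
}

#' Temperature of maximum basal fluorescence
#'
#' Returns the temperature at the global maximum of rolling-median-smoothed
#' F0. Ties are resolved to the earlier temperature along the ramp direction
#' (the side where Tcrit lies); a maximum at a trace endpoint is flagged as a
#' possibly truncated ramp.
#'
#' @param trace a trace list.
#' @param smoothing_window rolling-median window in points, default 5.
#' @return a list with `t_max` (degrees C, original axis) and
#'   `endpoint_flag`.
#' @export
extract_tmax <- function(trace, smoothing_window = 5) {
  tr <- prepare_trace(trace)
  sm <- smooth_f0(tr$f0, smoothing_window)
  is_max <- sm >= max(sm) - .Machine$double.eps^0.5 * max(abs(sm), 1)
  idx <- which(is_max)[1]  # earliest along ramp direction
  endpoint <- idx == 1L || idx == length(sm)
  if (endpoint)
    warn_data("trace %s: F0 maximum at ramp endpoint (possible truncation)",
              trace$sample_id %||% "<unnamed>")
  list(t_max = if (tr$cooling) -tr$temp[idx] else tr$temp[idx],
       endpoint_flag = endpoint)
}

#' Thermal traits for a set of traces
#'
#' Runs [fit_tcrit()] and [extract_tmax()] on every trace.
#'
#' @param traces list of traces from [read_traces()].
#' @param grid_step,smoothing_window passed through to the extractors.
#' @return data.frame: `sample_id`, `species_id`, `treatment`, `direction`,
#'   `t_crit`, `t_max`, `endpoint_flag`, `slope_warning`.
#' @export
thermal_traits <- function(traces, grid_step = 0.1, smoothing_window = 5) {
  rows <- lapply(traces, function(tr) {
    fit <- fit_tcrit(tr, grid_step = grid_step,
                     smoothing_window = smoothing_window)
    tm <- extract_tmax(tr, smoothing_window = smoothing_window)
    data.frame(sample_id = tr$sample_id, species_id = tr$species_id,
               treatment = tr$treatment, direction = tr$direction,
               t_crit = fit$t_crit, t_max = tm$t_max,
               endpoint_flag = tm$endpoint_flag,
               slope_warning = fit$slow_fast_warning,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-species acclimation deltas
#'
#' For each species, trait and ramp direction, computes the difference
#' between the treatment-arm mean and the control mean: hot arm for heating
#' traces (`Tcrit_hot`, `Tmax_hot`), cold arm for cooling traces
#' (`Tcrit_cold`, `Tmax_cold`). Positive hot deltas mean gained heat
#' tolerance; positive cold deltas (critical temperatures moving toward 0)
#' mean worsened cold performance. Species missing either arm are omitted
#' with a warning.
#'
#' @param traits data.frame from [thermal_traits()].
#' @return data.frame: `species_id`, `trait` (Tcrit_hot, Tmax_hot,
#'   Tcrit_cold, Tmax_cold), `delta` (degrees C), `n_treat`, `n_control`.
#' @export
acclimation_deltas <- function(traits) {
  combos <- list(
    Tcrit_hot  = list(dir = "heating", arm = "hot",  col = "t_crit"),
    Tmax_hot   = list(dir = "heating", arm = "hot",  col = "t_max"),
    Tcrit_cold = list(dir = "cooling", arm = "cold", col = "t_crit"),
    Tmax_cold  = list(dir = "cooling", arm = "cold", col = "t_max"))
  rows <- list()
  for (sp in sort(unique(traits$species_id))) {
    for (trait in names(combos)) {
      cb <- combos[[trait]]
      blk <- traits[traits$species_id == sp & traits$direction == cb$dir, ]
      treat_v <- blk[[cb$col]][blk$treatment == cb$arm]
      ctl_v <- blk[[cb$col]][blk$treatment == "control"]
      if (!length(treat_v) || !length(ctl_v)) {
        warn_data("species %s missing an arm for %s; omitted", sp, trait)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        species_id = sp, trait = trait,
        delta = mean(treat_v) - mean(ctl_v),
        n_treat = length(treat_v), n_control = length(ctl_v),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
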