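#' Binned per-neuron firing rate of a population
#'
#' @param spikes data.frame with `time` (ms) and `id`, e.g. the `spikes`
#'   component of a `"wm_sim"`.
#' @param population integer vector of neuron ids.
#' @param bin_ms bin width (ms).
#' @param t_max end of the analysed interval (ms); defaults to the last
#'   spike time rounded up to a full bin.
#' @return data.frame with `time` (bin start, ms) and `rate` (Hz per
#'   neuron: population spike count / bin width / population size).
#' @export
population_rate <- function(spikes, population, bin_ms = 5,
                            t_max = NULL) {
  if (bin_ms <= 0) stop("bin_ms must be positive", call. = FALSE)
  if (length(population) == 0) stop("empty population", call. = FALSE)
  if (is.null(t_max))
    t_max <- if (nrow(spikes)) ceiling(max(spikes$time) / bin_ms) * bin_ms
             else bin_ms
  breaks <- seq(0, t_max, by = bin_ms)
  if (breaks[length(breaks)] < t_max) breaks <- c(breaks, t_max)
  ts <- spikes$time[spikes$id %in% population]
  ts <- ts[ts >= 0 & ts < t_max]
  counts <- if (length(ts)) {
    tabulate(findInterval(ts, breaks, rightmost.closed = FALSE),
             nbins = length(breaks) - 1)
  } else rep(0L, length(breaks) - 1)
  widths <- diff(breaks)
  data.frame(time = breaks[-length(breaks)],
             rate = counts / (widths / 1000) / length(population))
}

#' Detect population spikes in a rate series
#'
#' A population spike (PS) is a brief synchronized volley of a selective
#' population. Operationally: a contiguous excursion of the binned
#' population rate above `threshold_factor` times the mean rate over a
#' baseline window (with an absolute floor for silent baselines); the
#' excursion's peak bin gives the PS time, and excursions closer than
#' `min_separation_ms` are merged into one event.
#'
#' @param rate a data.frame from [population_rate()] (`time`, `rate`).
#' @param baseline_window length-2 numeric, ms interval whose mean rate
#'   defines the baseline.
#' @param threshold_factor multiple of the baseline rate that an excursion
#'   must exceed.
#' @param min_separation_ms events closer than this are merged.
#' @param abs_floor_hz absolute threshold floor (Hz), also used when the
#'   baseline rate is zero.
#' @param spikes,population optionally, the raster and population ids used
#'   to compute per-PS participation (fraction of the population firing
#'   within the excursion); omitted -> participation is NA.
#' @param min_participation events in which fewer than this fraction of the
#'   population fires are discarded (brief rate blips over the threshold
#'   are not synchronized volleys). Applied only when `spikes` and
#'   `population` are supplied.
#' @return An object of class `"ps_train"`: data.frame with `time` (peak
#'   time, ms), `peak_rate` (Hz), `participation`; attributes `threshold`
#'   and `baseline_rate`.
#' @export
detect_population_spikes <- function(rate, baseline_window,
                                     threshold_factor = 10,
                                     min_separation_ms = 50,
                                     abs_floor_hz = 10,
                                     spikes = NULL, population = NULL,
                                     min_participation = 0.25) {
  stopifnot(is.data.frame(rate), all(c("time", "rate") %in% names(rate)))
  bin <- if (nrow(rate) > 1) mean(diff(rate$time)) else 1
  if (baseline_window[2] > max(rate$time) + bin)
    stop("rate series shorter than the baseline window", call. = FALSE)
  in_base <- rate$time >= baseline_window[1] & rate$time < baseline_window[2]
  if (!any(in_base)) stop("baseline window outside the series", call. = FALSE)
  base_rate <- mean(rate$rate[in_base])
  thr <- max(threshold_factor * base_rate, abs_floor_hz)
  above <- rate$rate > thr
  if (!any(above)) {
    out <- data.frame(time = numeric(0), peak_rate = numeric(0),
                      participation = numeric(0))
    return(structure(out, class = c("ps_train", "data.frame"),
                     threshold = thr, baseline_rate = base_rate))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- cbind(starts[r$values], ends[r$values])
  # merge excursions separated by less than min_separation_ms
  merged <- list(seg[1, ])
  if (nrow(seg) > 1) {
    for (i in 2:nrow(seg)) {
      last <- merged[[length(merged)]]
      gap_ms <- (seg[i, 1] - last[2]) * bin
      if (gap_ms < min_separation_ms) {
        merged[[length(merged)]] <- c(last[1], seg[i, 2])
      } else merged[[length(merged) + 1]] <- seg[i, ]
    }
  }
  events <- lapply(merged, function(sg) {
    idx <- sg[1]:sg[2]
    peak <- idx[which.max(rate$rate[idx])]
    part <- NA_real_
    if (!is.null(spikes) && !is.null(population)) {
      t0 <- rate$time[sg[1]]
      t1 <- rate$time[sg[2]] + bin
      firing <- unique(spikes$id[spikes$time >= t0 & spikes$time < t1 &
                                   spikes$id %in% population])
      part <- length(firing) / length(population)
    }
    c(time = rate$time[peak], peak_rate = rate$rate[peak],
      participation = part)
  })
  out <- as.data.frame(do.call(rbind, events))
  if (!is.null(spikes) && !is.null(population))
    out <- out[out$participation >= min_participation, , drop = FALSE]
  structure(out, class = c("ps_train", "data.frame"),
            threshold = thr, baseline_rate = base_rate)
}

#' Per-neuron firing-rate difference between two windows
#'
#' The memory readout of the delay period: each neuron's spike-count rate in
#' the delay window minus its rate in the spontaneous window,
#' `dr_i = N_d_i / dt_d - N_s_i / dt_s`. Antisymmetric under swapping the
#' two windows.
#'
#' @param spikes raster data.frame (`time`, `id`).
#' @param population integer vector of neuron ids.
#' @param spontaneous_interval,delay_interval length-2 numeric (ms).
#' @param t_range simulated time range (ms) used to validate the windows;
#'   `NULL` skips the check.
#' @return list with `dr` (Hz, one value per population neuron), `r_s`,
#'   `r_d` (the two per-neuron rates) and the two windows.
#' @export
firing_rate_difference <- function(spikes, population, spontaneous_interval,
                                   delay_interval, t_range = NULL) {
  for (w in list(spontaneous_interval, delay_interval)) {
    if (diff(w) <= 0) stop("intervals must have positive length", call. = FALSE)
    if (!is.null(t_range) && (w[1] < t_range[1] || w[2] > t_range[2]))
      stop("interval outside the simulated range", call. = FALSE)
  }
  count_in <- function(w) {
    sel <- spikes$time >= w[1] & spikes$time < w[2] &
      spikes$id %in% population
    cnt <- table(factor(spikes$id[sel], levels = population))
    as.numeric(cnt)
  }
  r_s <- count_in(spontaneous_interval) / diff(spontaneous_interval) * 1000
  r_d <- count_in(delay_interval) / diff(delay_interval) * 1000
  list(dr = r_d - r_s, r_s = r_s, r_d = r_d,
       spontaneous_interval = spontaneous_interval,
       delay_interval = delay_interval)
}

#' Count memory items still held by alternating population spikes
#'
#' A loaded population counts as held over a window when its PS train has no
#' silent gap longer than `gap_factor * T_max` — the analytic maximal
#' limit-cycle period being the longest interval after which facilitation
#' can still regenerate a volley. Gaps are measured between consecutive PSs
#' and against both window edges, so a population that falls silent midway
#' is not held.
#'
#' @param ps_trains list of [detect_population_spikes()] results, one per
#'   loaded population.
#' @param window length-2 numeric (ms), after the last item load.
#' @param T_max analytic maximal period (ms), see [tmax_estimate()].
#' @param gap_factor allowed gap in units of `T_max`.
#' @return integer: number of held populations, with attribute `held`
#'   (logical per train).
#' @export
count_held_items <- function(ps_trains, window, T_max, gap_factor = 2) {
  if (diff(window) <= 0) stop("empty window", call. = FALSE)
  held <- vapply(ps_trains, function(tr) {
    ts <- tr$time[tr$time >= window[1] & tr$time <= window[2]]
    if (length(ts) == 0) return(FALSE)
    gaps <- diff(c(window[1], sort(ts), window[2]))
    max(gaps) <= gap_factor * T_max
  }, logical(1))
  structure(sum(held), held = held)
}

#' Analytic maximal period of the facilitation limit cycle
#'
#' The longest interval between reactivations for which the network can
#' still regenerate a population spike, set by the depression recovery and
#' the decay of facilitation:
#' `T_max = tau_d * log((tau_f / tau_d) / (1 - U))`.
#' Defaults give `200 * log(7.5 / 0.81) = 445.1` ms.
#'
#' @param params an [stp_params()] object.
#' @return `T_max` in ms.
#' @examples
#' tmax_estimate(stp_params())           # 445.1
#' tmax_estimate(stp_params(tau_f = 3000))
#' @export
tmax_estimate <- function(params) {
  arg <- (params$tau_f / params$tau_d) / (1 - params$U)
  if (arg <= 1)
    stop("no limit cycle: tau_f/(tau_d*(1-U)) must exceed 1", call. = FALSE)
  params$tau_d * log(arg)
}

#' Analytic working-memory capacity estimate
#'
#' The number of items that can be interleaved on the limit cycle: the
#' ratio of the maximal period to the spacing between successive population
#' spikes, `N_c = T_max / t_s`.
#'
#' @param T_max maximal limit-cycle period (ms).
#' @param t_s inter-population-spike spacing (ms).
#' @return `N_c` (dimensionless).
#' @examples
#' capacity_estimate(tmax_estimate(stp_params()), 160)  # ~2.8
#' @export
capacity_estimate <- function(T_max, t_s) {
  if (t_s <= 0) stop("t_s must be positive", call. = FALSE)
  T_max / t_s
}

#' Median spacing between consecutive population spikes across populations
#'
#' Pools the PS times of the given trains, sorts them, and returns the
#' median interval between consecutive events — the `t_s` entering
#' [capacity_estimate()] when several held populations alternate.
#'
#' @param ps_trains list of `"ps_train"` objects.
#' @param window optional length-2 numeric restricting the pooled times.
#' @return median spacing (ms), or `NA` with fewer than two events.
#' @export
ps_spacing <- function(ps_trains, window = NULL) {
  ts <- sort(unlist(lapply(ps_trains, function(tr) tr$time)))
  if (!is.null(window)) ts <- ts[ts >= window[1] & ts <= window[2]]
  if (length(ts) < 2) return(NA_real_)
  stats::median(diff(ts))
}
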