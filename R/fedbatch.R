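#' Define a fed-batch supplementation schedule
#'
#' Discrete feed events: at each event time a volume of liquid (water or
#' glycerol solution) carrying a glycerol mass is added instantaneously.
#'
#' @param times event times (h), strictly increasing.
#' @param volumes_L added volume per event (L), nonnegative.
#' @param glycerol_g added glycerol mass per event (g), nonnegative.
#' @param initial_volume_L broth volume at inoculation (L).
#' @return an object of class `ep_feed`.
#' @export
#' @examples
#' # 1 L of 30% w/v glycerol (300 g) at 40 h and 60 h into 15 L
#' feed_schedule(c(40, 60), c(1, 1), c(300, 300), initial_volume_L = 15)
feed_schedule <- function(times = numeric(0), volumes_L = numeric(0),
                          glycerol_g = numeric(0), initial_volume_L) {
  ep_assert(length(times) == length(volumes_L) &&
              length(times) == length(glycerol_g),
            "epferm_usage_error", "event vectors must have equal length")
  ep_assert(all(diff(times) > 0), "epferm_usage_error",
            "event times must be strictly increasing")
  ep_assert(all(volumes_L >= 0) && all(glycerol_g >= 0),
            "epferm_usage_error",
            "added volumes and masses must be nonnegative")
  ep_assert(is.numeric(initial_volume_L) && initial_volume_L > 0,
            "epferm_usage_error", "'initial_volume_L' must be positive")
  structure(
    list(events = data.frame(time = as.numeric(times),
                             volume_L = as.numeric(volumes_L),
                             glycerol_g = as.numeric(glycerol_g)),
         initial_volume_L = initial_volume_L),
    class = "ep_feed"
  )
}

#' @export
print.ep_feed <- function(x, ...) {
  cat(sprintf("<ep_feed> V0 = %g L, %d event(s)\n", x$initial_volume_L,
              nrow(x$events)))
  if (nrow(x$events)) print(x$events, row.names = FALSE)
  invisible(x)
}

#' Simulate a fed-batch fermentation
#'
#' Integrates the batch dynamics (state `Cs`, `X`, `Cp`; constant volume)
#' between feed events. Each event is an instantaneous mass balance:
#' `V' = V + dV`, `Cs' = (Cs V + m_glycerol)/V'`, `X' = X V / V'`,
#' `Cp' = Cp V / V'`, so biomass and product masses are conserved exactly
#' and substrate mass increases by the fed mass. The output contains each
#' event time twice (state just before and just after the feed).
#'
#' @param kind model kind, see [growth_rate()].
#' @param params an [kinetic_params()] object; `C0` and `X0` are the
#'   concentrations at inoculation.
#' @param schedule an [feed_schedule()].
#' @param times output grid (h), starting at 0 and spanning every event.
#' @param kd first-order product decay rate (1/h), default 0.
#' @return an `ep_batch` data frame with an additional `volume_L` column.
#' @export
#' @examples
#' p <- kinetic_params(0.08, 15, 0.45, 19.63, C0 = 20, X0 = 0.8, kp = 50)
#' fs <- feed_schedule(c(40, 60), c(1, 1), c(0, 0), 15)
#' sim <- simulate_fed_batch("aibe", p, fs, seq(0, 80, by = 2))
#' tail(sim)
simulate_fed_batch <- function(kind, params, schedule, times, kd = 0) {
  check_kind(kind)
  ep_assert(inherits(params, "ep_kinparams"), "epferm_usage_error",
            "'params' must be an ep_kinparams")
  ep_assert(inherits(schedule, "ep_feed"), "epferm_usage_error",
            "'schedule' must be an ep_feed")
  ep_assert(is.numeric(times) && times[1] == 0 && all(diff(times) > 0),
            "epferm_usage_error",
            "'times' must start at 0 and be strictly increasing")
  ev <- schedule$events
  if (nrow(ev) && (min(ev$time) <= min(times) || max(ev$time) >= max(times))) {
    ep_stop("epferm_schedule_error",
            "feed events must fall strictly inside the simulation horizon")
  }
  p <- params
  rhs <- function(t, y, parms) {
    Cs <- max(y[1], CS_FLOOR)
    X <- y[2]
    Cp <- y[3]
    mu <- batch_mu(kind, p, Cs, X, Cp)
    dCs <- -mu * X / p$Yb
    if (y[1] <= CS_FLOOR && dCs < 0) dCs <- 0
    list(c(dCs, mu * X, -p$Yp * dCs - kd * Cp))
  }

  bounds <- c(0, ev$time, max(times))
  state <- c(p$C0, p$X0, 0)
  V <- schedule$initial_volume_L
  out <- NULL
  for (seg in seq_len(length(bounds) - 1L)) {
    lo <- bounds[seg]
    hi <- bounds[seg + 1L]
    grid <- sort(unique(c(lo, times[times > lo & times < hi], hi)))
    o <- deSolve::ode(state, grid, rhs, parms = NULL,
                      rtol = 1e-8, atol = 1e-10)
    if (any(!is.finite(o))) {
      ep_stop("epferm_integration_failure_error",
              sprintf("non-finite state during %s fed-batch integration",
                      kind))
    }
    # the first row of a later segment repeats the post-event state row
    out <- rbind(out, cbind(o, volume_L = V)[if (seg == 1L) TRUE else -1L, ,
                                             drop = FALSE])
    state <- o[nrow(o), -1]
    if (seg <= nrow(ev)) {
      Vn <- V + ev$volume_L[seg]
      state <- c((state[1] * V + ev$glycerol_g[seg]) / Vn,
                 state[2] * V / Vn,
                 state[3] * V / Vn)
      V <- Vn
      # post-event state at the event time (time appears twice)
      out <- rbind(out, c(ev$time[seg], state, volume_L = V))
    }
  }
  df <- data.frame(
    time_h = out[, 1],
    substrate_g_per_L = pmax(out[, 2], CS_FLOOR),
    biomass_g_per_L = out[, 3],
    product = out[, 4],
    volume_L = out[, 5]
  )
  rownames(df) <- NULL
  new_ep_batch(df, kind, params, C0_eff = p$C0 + p$X0 / p$Yb)
}
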