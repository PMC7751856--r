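# Reductions of trip logs to the standard descriptive surfaces: mode share by
# distance, zone trip rates, store-visit maps, median trip distance.

#' Non-motorized mode share by distance bin
#'
#' Per group and half-open distance bin `[lo, hi)`, the share of trips made by
#' non-motorized means (walking, cycling) and the trip count. Empty bins are
#' absent from the result, not zero.
#'
#' @param log trip log from [run_simulation()].
#' @param bins strictly increasing bin edges in miles (last may be `Inf`).
#' @return data.frame: `group`, `bin_lo`, `bin_hi`, `trips`,
#'   `nonmotorized_share`.
#' @export
mode_share_by_distance <- function(log, bins = c(0:10, Inf)) {
  if (nrow(log) == 0) stop_fmt("trip log is empty")
  if (is.unsorted(bins, strictly = TRUE)) stop_fmt("bins must be strictly increasing")
  bin <- findInterval(log$distance_miles, bins)
  keep <- bin >= 1 & bin < length(bins)
  dt <- data.table::data.table(group = log$group[keep], bin = bin[keep],
                               nm = !log$motorized[keep])
  agg <- dt[, list(trips = .N, nonmotorized_share = mean(nm)),
            by = c("group", "bin")]
  data.table::setorderv(agg, c("group", "bin"))
  out <- data.frame(group = agg$group,
                    bin_lo = bins[agg$bin], bin_hi = bins[agg$bin + 1],
                    trips = agg$trips,
                    nonmotorized_share = agg$nonmotorized_share)
  attr(out, "total_binned") <- sum(out$trips)
  out
}

#' Weekly shopping-trip rates by zone
#'
#' Per group: average shopping trips per week per household, split by shopping
#' zone (zone trips divided by group agents times weeks). Also returns the
#' population-level share of all trips per zone.
#'
#' @param log trip log.
#' @param agents the placed agent table the log was simulated from.
#' @param weeks simulated horizon; defaults to the log's `weeks` attribute.
#' @return list of class `zone_trip_summary` with `per_group` (data.frame
#'   `group`, `zone`, `trips_per_week`) and `population_shares` (named vector
#'   over zones, summing to 1).
#' @export
zone_trip_summary <- function(log, agents, weeks = attr(log, "weeks")) {
  if (is.null(weeks)) stop_fmt("weeks not given and not on the log")
  if (!all(log$agent_id %in% agents$agent_id))
    stop_fmt("join error: trip log contains agent ids missing from `agents`")
  zl <- zone_levels()
  dt <- data.table::data.table(group = log$group,
                               zone = factor(log$zone, levels = zl))
  counts <- dt[, list(trips = .N), by = c("group", "zone")]
  n_agents <- table(factor(agents$group, levels = unique(agents$group)))
  counts$trips_per_week <- counts$trips /
    (as.numeric(n_agents[counts$group]) * weeks)
  data.table::setorderv(counts, c("group", "zone"))
  pop <- tapply(rep(1, nrow(dt)), dt$zone, sum, default = 0)
  pop <- pop / sum(pop)
  structure(list(per_group = data.frame(group = counts$group,
                                        zone = as.character(counts$zone),
                                        trips = counts$trips,
                                        trips_per_week = counts$trips_per_week),
                 population_shares = setNames(as.numeric(pop), zl),
                 weeks = weeks),
            class = "zone_trip_summary")
}

#' @export
print.zone_trip_summary <- function(x, ...) {
  cat("Population zone shares:\n")
  print(round(x$population_shares, 3))
  cat("\nPer-group weekly trips per household by zone:\n")
  print(x$per_group, row.names = FALSE)
  invisible(x)
}

#' Store-visit map
#'
#' Per group and store: weekly visit rate, visit rate normalized by the global
#' maximum across all groups, and the share of motorized trips to that store.
#'
#' @param log trip log.
#' @param stores store table (`id` required); stores referenced by the log
#'   must exist.
#' @param weeks simulated horizon; defaults to the log's attribute.
#' @return data.frame: `group`, `store_id`, `visits_per_week`,
#'   `normalized_rate`, `motorized_share`.
#' @export
store_visit_map <- function(log, stores, weeks = attr(log, "weeks")) {
  if (is.null(weeks)) stop_fmt("weeks not given and not on the log")
  if (!all(log$store_id %in% stores$id))
    stop_fmt("trip log references unknown stores")
  dt <- data.table::data.table(group = log$group, store_id = log$store_id,
                               mot = log$motorized)
  agg <- dt[, list(visits = .N, motorized_share = mean(mot)),
            by = c("group", "store_id")]
  agg$visits_per_week <- agg$visits / weeks
  agg$normalized_rate <- agg$visits_per_week / max(agg$visits_per_week)
  data.table::setorderv(agg, c("group", "store_id"))
  out <- data.frame(group = agg$group, store_id = agg$store_id,
                    visits = agg$visits,
                    visits_per_week = agg$visits_per_week,
                    normalized_rate = agg$normalized_rate,
                    motorized_share = agg$motorized_share)
  attr(out, "total_visits") <- sum(out$visits)
  out
}

#' Median trip distance
#'
#' The median of trip network distances (miles), the simulator's headline
#' output. Even counts use the midpoint convention. With
#' `per = "agent_week"`, medians are taken over per-agent-week total
#' distances instead of single trips.
#'
#' @param log trip log.
#' @param by `"group"` for one median per group, `"population"` for a single
#'   pooled value.
#' @param per `"trip"` (default) or `"agent_week"`.
#' @return named numeric vector (groups with no trips are absent).
#' @export
median_trip_distance <- function(log, by = c("group", "population"),
                                 per = c("trip", "agent_week")) {
  by <- match.arg(by); per <- match.arg(per)
  if (nrow(log) == 0) stop_fmt("trip log is empty")
  x <- log$distance_miles
  if (per == "agent_week") {
    dt <- data.table::data.table(g = log$group, a = log$agent_id, w = log$week,
                                 d = log$distance_miles)
    tot <- dt[, list(d = sum(d)), by = c("g", "a", "w")]
    if (by == "population") return(c(population = median(tot$d)))
    out <- tapply(tot$d, tot$g, median)
    return(setNames(as.numeric(out), names(out)))
  }
  if (by == "population") return(c(population = median(x)))
  out <- tapply(x, log$group, median)
  setNames(as.numeric(out), names(out))
}

#' Plot non-motorized share by distance (convenience)
#'
#' @param profile output of [mode_share_by_distance()].
#' @return a ggplot object.
#' @export
plot_mode_share <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_fmt("ggplot2 is required for plotting")
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = bin_lo + 0.5, y = nonmotorized_share)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "distance to store (miles)",
                  y = "non-motorized share of trips")
}
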