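# The AgentGroup container: one income-by-age stratum bundling all the
# empirical probability distributions the decision engine draws from.

#' Construct an agent group
#'
#' @param name group name (one of [agent_group_names()]).
#' @param income_stratum,age_stratum stratum labels.
#' @param sample_size respondent count behind the group's distributions.
#' @param car_ownership_prob probability a household in the group has a car.
#' @param trip_count_values,trip_count_probs categorical distribution of
#'   shopping trips per week (nonnegative integers).
#' @param type_consideration_prob probability a trip starts by fixing a store
#'   type (a proxy for what groceries to buy).
#' @param mode_first_prob probability the travel mode is decided before the
#'   store (otherwise store first).
#' @param store_type_weights named weights over store types, used when a trip
#'   considers type.
#' @param store_pool data.frame with `store_id`, `weight`: the group's
#'   preferred stores and their visit weights (normalized internally).
#' @param noncar_mode_probs named probabilities over `bus`, `taxi`, `walk`,
#'   `bike` for carless mode-first trips.
#' @param distance_bins increasing bin edges (miles) for the distance-
#'   conditional mode table, last edge `Inf`.
#' @param nonmotorized_by_bin probability a carless store-first trip is
#'   non-motorized, per distance bin (length `length(distance_bins) - 1`).
#' @param walk_frac_nm fraction of non-motorized trips that are walks (rest
#'   are bike).
#' @param bus_frac_mot fraction of carless motorized trips by bus (rest taxi).
#' @param household_size_mean mean persons per household in the group.
#' @return an object of class `agent_group`.
#' @export
agent_group <- function(name, income_stratum, age_stratum, sample_size,
                        car_ownership_prob,
                        trip_count_values, trip_count_probs,
                        type_consideration_prob, mode_first_prob,
                        store_type_weights, store_pool,
                        noncar_mode_probs,
                        distance_bins = c(0:10, Inf),
                        nonmotorized_by_bin,
                        walk_frac_nm = 0.65, bus_frac_mot = 0.8,
                        household_size_mean = 2.2) {
  assert_prob(car_ownership_prob, "car_ownership_prob")
  assert_prob(type_consideration_prob, "type_consideration_prob")
  assert_prob(mode_first_prob, "mode_first_prob")
  assert_prob(nonmotorized_by_bin, "nonmotorized_by_bin")
  if (length(trip_count_values) != length(trip_count_probs))
    stop_fmt("trip-count values and probabilities differ in length")
  if (any(trip_count_values < 0) || any(trip_count_values != round(trip_count_values)))
    stop_fmt("trip counts must be nonnegative integers")
  if (nrow(store_pool) < 1) stop_fmt("store_pool must be nonempty")
  if (length(nonmotorized_by_bin) != length(distance_bins) - 1)
    stop_fmt("nonmotorized_by_bin must have one entry per distance bin")
  nm <- c("bus", "taxi", "walk", "bike")
  if (!all(nm %in% names(noncar_mode_probs)))
    stop_fmt("noncar_mode_probs must name bus, taxi, walk, bike")
  structure(list(
    name = name,
    income_stratum = income_stratum,
    age_stratum = age_stratum,
    sample_size = as.integer(sample_size),
    car_ownership_prob = car_ownership_prob,
    trip_count_values = as.integer(trip_count_values),
    trip_count_probs = normalize_weights(trip_count_probs, "trip_count_probs"),
    type_consideration_prob = type_consideration_prob,
    mode_first_prob = mode_first_prob,
    store_type_weights = normalize_weights(store_type_weights, "store_type_weights"),
    store_pool = data.frame(store_id = as.character(store_pool$store_id),
                            weight = normalize_weights(store_pool$weight, "store pool weights")),
    noncar_mode_probs = normalize_weights(noncar_mode_probs[nm], "noncar_mode_probs"),
    distance_bins = distance_bins,
    nonmotorized_by_bin = nonmotorized_by_bin,
    walk_frac_nm = walk_frac_nm,
    bus_frac_mot = bus_frac_mot,
    household_size_mean = household_size_mean
  ), class = "agent_group")
}

#' @export
print.agent_group <- function(x, ...) {
  cat(sprintf("<agent_group %s: n=%d, P(car)=%.2f, E[trips/wk]=%.2f, %d stores>\n",
              x$name, x$sample_size, x$car_ownership_prob,
              sum(x$trip_count_values * x$trip_count_probs),
              nrow(x$store_pool)))
  invisible(x)
}

#' Write / read group fixtures as JSON
#'
#' @param groups named list of [agent_group()] objects.
#' @param path file path (`groups.json`).
#' @export
write_groups_json <- function(groups, path) {
  payload <- lapply(groups, function(g) {
    g$store_type_weights <- as.list(g$store_type_weights)
    g$noncar_mode_probs <- as.list(g$noncar_mode_probs)
    unclass(g)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_groups_json
#' @export
read_groups_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(payload, function(g) {
    agent_group(
      name = g$name, income_stratum = g$income_stratum,
      age_stratum = g$age_stratum, sample_size = g$sample_size,
      car_ownership_prob = g$car_ownership_prob,
      trip_count_values = g$trip_count_values,
      trip_count_probs = g$trip_count_probs,
      type_consideration_prob = g$type_consideration_prob,
      mode_first_prob = g$mode_first_prob,
      store_type_weights = unlist(g$store_type_weights),
      store_pool = as.data.frame(g$store_pool),
      noncar_mode_probs = unlist(g$noncar_mode_probs),
      distance_bins = g$distance_bins,
      nonmotorized_by_bin = g$nonmotorized_by_bin,
      walk_frac_nm = g$walk_frac_nm, bus_frac_mot = g$bus_frac_mot,
      household_size_mean = g$household_size_mean
    )
  })
  setNames(out, vapply(out, `[[`, "", "name"))
}
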