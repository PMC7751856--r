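# Weekly grocery-shopping decision process. Every week an agent draws a
# number of trips; for each trip it (i) decides whether to fix a store type
# first (a proxy for what groceries to buy), (ii) decides whether mode or
# store is chosen first, then (iii) draws mode and store. Households with a
# car always drive. Carless mode-first trips pick the store with exponential
# distance decay for walking/cycling; carless store-first trips pick the mode
# from a distance-binned table.

MODE_LABELS <- c("car", "bus", "taxi", "walk", "bike")

#' Simulation configuration
#'
#' @param weeks number of simulated weeks.
#' @param seed integer seed for the run; per-agent RNG streams are derived
#'   from it so results do not depend on agent iteration order.
#' @param lambda_walk,lambda_bike exponential distance-decay scales (miles)
#'   for store choice on walking / cycling mode-first trips.
#' @param distance_bins default bin edges (miles) for distance-conditional
#'   mode tables, last edge `Inf`.
#' @param mode_first_prob optional global override of every group's
#'   probability of deciding the mode before the store.
#' @param type_consideration_prob optional global override of every group's
#'   probability of filtering stores by type.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(weeks = 52, seed = 1,
                              lambda_walk = 3, lambda_bike = 6,
                              distance_bins = c(0:10, Inf),
                              mode_first_prob = NULL,
                              type_consideration_prob = NULL) {
  if (weeks < 1) stop_fmt("weeks must be >= 1")
  if (lambda_walk <= 0 || lambda_bike <= 0) stop_fmt("decay scales must be positive")
  if (is.unsorted(distance_bins, strictly = TRUE)) stop_fmt("distance_bins must be strictly increasing")
  structure(list(weeks = as.integer(weeks), seed = as.integer(seed),
                 lambda_walk = lambda_walk, lambda_bike = lambda_bike,
                 distance_bins = distance_bins,
                 mode_first_prob = mode_first_prob,
                 type_consideration_prob = type_consideration_prob),
            class = "simulation_config")
}

#' Read / write a simulation configuration as YAML
#' @param path file path.
#' @param cfg a [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  bins <- unlist(y$distance_bins)
  bins <- as.numeric(ifelse(bins %in% c(".inf", "Inf", "inf"), Inf, bins))
  simulation_config(weeks = y$weeks %||% 52, seed = y$seed %||% 1,
                    lambda_walk = y$lambda_walk %||% 3,
                    lambda_bike = y$lambda_bike %||% 6,
                    distance_bins = if (length(bins)) bins else c(0:10, Inf),
                    mode_first_prob = y$mode_first_prob,
                    type_consideration_prob = y$type_consideration_prob)
}

#' @rdname read_simulation_config
#' @export
write_simulation_config <- function(cfg, path) {
  y <- unclass(cfg)
  y$distance_bins <- ifelse(is.infinite(y$distance_bins), "Inf", y$distance_bins)
  yaml::write_yaml(y, path)
  invisible(path)
}

# Apply config overrides and precompute the per-group structures the trip
# sampler needs: type-restricted pool subsets and renormalized weights.
resolve_group <- function(g, cfg) {
  tau <- cfg$type_consideration_prob %||% g$type_consideration_prob
  mu <- cfg$mode_first_prob %||% g$mode_first_prob
  theta <- g$store_type_weights
  pool_types <- attr(g$store_pool, "store_type")
  if (is.null(pool_types))
    stop_fmt("group %s: store pool lacks type annotations; use prepare_groups()", g$name)
  subsets <- vector("list", length(theta) + 1L)
  subw <- vector("list", length(theta) + 1L)
  subsets[[1]] <- seq_len(nrow(g$store_pool))
  subw[[1]] <- g$store_pool$weight
  for (k in seq_along(theta)) {
    idx <- which(pool_types == names(theta)[k])
    if (length(idx) == 0) { idx <- subsets[[1]]; w <- subw[[1]] }  # empty restriction: full pool
    else w <- normalize_weights(g$store_pool$weight[idx])
    subsets[[k + 1L]] <- idx; subw[[k + 1L]] <- w
  }
  list(name = g$name, tau = tau, mu = mu, theta = as.numeric(theta),
       subsets = subsets, subw = subw,
       trip_values = g$trip_count_values, trip_probs = g$trip_count_probs,
       nu = as.numeric(g$noncar_mode_probs),  # bus, taxi, walk, bike
       bins = g$distance_bins, nm_by_bin = g$nonmotorized_by_bin,
       walk_frac = g$walk_frac_nm, bus_frac = g$bus_frac_mot,
       lambda_walk = cfg$lambda_walk, lambda_bike = cfg$lambda_bike,
       pool_ids = g$store_pool$store_id)
}

# Annotate each group's store pool with store types/zones from the
# environment (required by the trip sampler).
prepare_groups <- function(groups, env) {
  lapply(groups, function(g) {
    m <- match(g$store_pool$store_id, env$stores$id)
    if (anyNA(m))
      stop_fmt("group %s: pool stores missing from environment: %s", g$name,
               paste(g$store_pool$store_id[is.na(m)], collapse = ", "))
    attr(g$store_pool, "store_type") <- env$stores$store_type[m]
    attr(g$store_pool, "zone") <- env$stores$zone[m]
    g
  })
}

#' Draw weekly shopping-trip counts
#'
#' Samples from the group's empirical trips-per-week distribution using the
#' current RNG state.
#' @param group an [agent_group()].
#' @param n number of draws.
#' @return integer vector of trip counts.
#' @export
draw_trip_count <- function(group, n = 1) {
  group$trip_count_values[
    sample_idx(length(group$trip_count_values), n, group$trip_count_probs)]
}

#' Decide whether to restrict the trip to one store type
#'
#' With the group's type-consideration probability, draws a store type and
#' restricts the pool to stores of that type (weights renormalized); otherwise
#' returns the full pool. An empty restriction falls back to the full pool.
#'
#' @param group an [agent_group()] whose pool carries type annotations
#'   (see groups built by [build_group_fixtures()]).
#' @return data.frame `store_id`, `weight` (summing to 1).
#' @export
decide_store_type_filter <- function(group) {
  pool <- group$store_pool
  types <- attr(pool, "store_type")
  out <- pool
  if (runif(1) < group$type_consideration_prob) {
    tw <- group$store_type_weights
    t <- names(tw)[sample_idx(length(tw), 1, as.numeric(tw))]
    idx <- which(types == t)
    if (length(idx)) {
      out <- pool[idx, , drop = FALSE]
      attr(out, "store_type") <- types[idx]
      attr(out, "zone") <- attr(pool, "zone")[idx]
    }
  }
  out$weight <- normalize_weights(out$weight)
  rownames(out) <- NULL
  out
}

# store-choice weights: pool weight times exponential distance decay for
# non-motorized modes (motorized modes have no decay)
store_choice_weights <- function(weight, d, mode, cfg) {
  lam <- switch(mode, walk = cfg$lambda_walk, bike = cfg$lambda_bike, Inf)
  if (is.finite(lam)) weight * exp(-d / lam) else weight
}

# distance-binned non-motorized probability; distances beyond the last finite
# edge use the open-ended tail bin
nm_prob_at_distance <- function(group, dist) {
  bin <- findInterval(dist, group$distance_bins)
  bin <- pmin(pmax(bin, 1L), length(group$nonmotorized_by_bin))
  group$nonmotorized_by_bin[bin]
}

draw_noncar_mode_at_distance <- function(group, dist) {
  p <- nm_prob_at_distance(group, dist)
  if (runif(1) < p) {
    if (runif(1) < group$walk_frac_nm) "walk" else "bike"
  } else {
    if (runif(1) < group$bus_frac_mot) "bus" else "taxi"
  }
}

#' Choose travel mode first, then the store
#'
#' Car owners drive. Carless agents draw a mode from the group's marginal
#' non-car mode distribution, then draw the store from the candidate pool with
#' exponential distance decay for walking/cycling.
#'
#' @param agent list or one-row data.frame with `house_id` and `has_car`.
#' @param group an [agent_group()].
#' @param pool candidate pool (e.g. from [decide_store_type_filter()]).
#' @param od an `od_matrix`.
#' @param cfg a [simulation_config()].
#' @return list with `mode` and `store_id`.
#' @export
select_mode_first <- function(agent, group, pool, od, cfg = simulation_config()) {
  d <- od[as.character(agent$house_id), pool$store_id]
  if (isTRUE(agent$has_car)) {
    mode <- "car"
  } else {
    nu <- group$noncar_mode_probs
    mode <- names(nu)[sample_idx(length(nu), 1, as.numeric(nu))]
  }
  w <- store_choice_weights(pool$weight, d, mode, cfg)
  store <- pool$store_id[sample_idx(nrow(pool), 1, w)]
  list(mode = mode, store_id = store)
}

#' Choose the store first, then the travel mode
#'
#' The store is drawn from the candidate pool weights (no distance decay).
#' Car owners drive; carless agents draw the mode from the group's
#' distance-binned non-car mode table evaluated at the network distance to the
#' chosen store.
#'
#' @inheritParams select_mode_first
#' @return list with `store_id` and `mode`.
#' @export
select_store_first <- function(agent, group, pool, od, cfg = simulation_config()) {
  store <- pool$store_id[sample_idx(nrow(pool), 1, pool$weight)]
  if (isTRUE(agent$has_car)) {
    mode <- "car"
  } else {
    dist <- od[as.character(agent$house_id), store]
    mode <- draw_noncar_mode_at_distance(group, dist)
  }
  list(store_id = store, mode = mode)
}

# ---- vectorized per-agent trip sampler --------------------------------------

# Draws all trips of one agent over `weeks` weeks using the ambient RNG.
# `pg` is a resolve_group() result, `d` the agent's distances to its group's
# pool stores. Returns integer vectors (week, pool index, mode code).
sim_agent_trips <- function(pg, d, has_car, weeks) {
  nw <- pg$trip_values[sample_idx(length(pg$trip_values), weeks, pg$trip_probs)]
  n <- sum(nw)
  if (n == 0L)
    return(list(week = integer(0), pool_idx = integer(0), mode = integer(0),
                n_drawn = nw))
  week <- rep.int(seq_len(weeks), nw)
  tidx <- integer(n)
  filt <- runif(n) < pg$tau
  if (any(filt)) tidx[filt] <- sample_idx(length(pg$theta), sum(filt), pg$theta)
  store <- integer(n); mode <- integer(n)

  if (has_car) {
    mode[] <- 1L
    for (ti in sort(unique(tidx))) {
      idx <- which(tidx == ti)
      sub <- pg$subsets[[ti + 1L]]
      store[idx] <- sub[sample_idx(length(sub), length(idx), pg$subw[[ti + 1L]])]
    }
  } else {
    mf <- runif(n) < pg$mu
    if (any(mf)) mode[mf] <- 1L + sample_idx(4L, sum(mf), pg$nu)
    lc <- integer(n)                       # decay class: 0 none, 1 walk, 2 bike
    lc[mf & mode == 4L] <- 1L
    lc[mf & mode == 5L] <- 2L
    for (ti in sort(unique(tidx))) {
      for (l in sort(unique(lc[tidx == ti]))) {
        idx <- which(tidx == ti & lc == l)
        sub <- pg$subsets[[ti + 1L]]
        w <- pg$subw[[ti + 1L]]
        if (l > 0L) {
          lam <- if (l == 1L) pg$lambda_walk else pg$lambda_bike
          w <- w * exp(-d[sub] / lam)
        }
        store[idx] <- sub[sample_idx(length(sub), length(idx), w)]
      }
    }
    sf <- which(!mf)
    if (length(sf)) {
      bin <- findInterval(d[store[sf]], pg$bins)
      bin <- pmin(pmax(bin, 1L), length(pg$nm_by_bin))
      is_nm <- runif(length(sf)) < pg$nm_by_bin[bin]
      msf <- integer(length(sf))
      if (any(is_nm))
        msf[is_nm] <- ifelse(runif(sum(is_nm)) < pg$walk_frac, 4L, 5L)
      if (any(!is_nm))
        msf[!is_nm] <- ifelse(runif(sum(!is_nm)) < pg$bus_frac, 2L, 3L)
      mode[sf] <- msf
    }
  }
  list(week = week, pool_idx = store, mode = mode, n_drawn = nw)
}

#' Simulate one week of shopping for one agent
#'
#' Draws the weekly trip count and runs the full per-trip decision process,
#' using the current RNG state.
#'
#' @param agent list or one-row data.frame with `agent_id`, `group`,
#'   `house_id`, `has_car`.
#' @param groups named list of [agent_group()] objects.
#' @param env a [load_environment()] bundle.
#' @param od an `od_matrix`.
#' @param cfg a [simulation_config()].
#' @param week week index recorded on the trips.
#' @return data.frame of trip records (possibly zero rows).
#' @export
simulate_week <- function(agent, groups, env, od, cfg = simulation_config(),
                          week = 1L) {
  g <- groups[[as.character(agent$group)]]
  if (is.null(g)) stop_fmt("unknown agent group: %s", agent$group)
  g <- prepare_groups(list(g), env)[[1]]
  pg <- resolve_group(g, cfg)
  d <- od[as.character(agent$house_id), pg$pool_ids]
  res <- sim_agent_trips(pg, d, isTRUE(agent$has_car), 1L)
  assemble_trips(list(res), list(pg), group_of = 1L,
                 agent_ids = agent$agent_id %||% NA_integer_,
                 group_names = as.character(agent$group),
                 d_list = list(d), env = env, week_offset = week - 1L)
}

#' Run the full simulation
#'
#' Simulates every agent over `cfg$weeks` weeks. Each agent has an
#' independent RNG stream derived from `cfg$seed` and its `agent_id`, so the
#' trip log is identical under any permutation of the agent list.
#'
#' @param agents placed agents from [instantiate_agents()].
#' @param groups named list of [agent_group()] objects.
#' @param env a [load_environment()] bundle.
#' @param od an `od_matrix`.
#' @param cfg a [simulation_config()].
#' @return data.frame trip log: `agent_id`, `group`, `week`, `store_id`,
#'   `store_type`, `zone`, `mode`, `motorized`, `distance_miles`. Attribute
#'   `weeks` carries the simulated horizon; attribute `n_drawn` the total of
#'   all weekly trip-count draws (equal to the row count).
#' @export
run_simulation <- function(agents, groups, env, od, cfg = simulation_config()) {
  groups <- prepare_groups(groups, env)
  gnames <- names(groups)
  pgs <- lapply(groups, resolve_group, cfg = cfg)
  od_cols <- lapply(pgs, function(pg) {
    m <- match(pg$pool_ids, colnames(od))
    if (anyNA(m)) stop_fmt("OD matrix lacks pool stores for group %s", pg$name)
    m
  })
  hrow <- match(as.character(agents$house_id), rownames(od))
  if (anyNA(hrow)) stop_fmt("OD matrix lacks %d agent houses", sum(is.na(hrow)))
  gi <- match(as.character(agents$group), gnames)
  if (anyNA(gi)) stop_fmt("agents reference unknown groups")

  # per-group distance submatrices (houses x pool)
  od_g <- lapply(od_cols, function(cols) od[, cols, drop = FALSE])

  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old_seed, envir = globalenv()))

  n_agents <- nrow(agents)
  results <- vector("list", n_agents)
  d_cache <- vector("list", n_agents)
  total_drawn <- 0
  for (i in seq_len(n_agents)) {
    set.seed(agent_stream_seed(cfg$seed, agents$agent_id[i]))
    d <- od_g[[gi[i]]][hrow[i], ]
    res <- sim_agent_trips(pgs[[gi[i]]], d, agents$has_car[i], cfg$weeks)
    total_drawn <- total_drawn + sum(res$n_drawn)
    results[[i]] <- res
    d_cache[[i]] <- d
  }
  log <- assemble_trips(results, pgs, group_of = gi,
                        agent_ids = agents$agent_id,
                        group_names = as.character(agents$group),
                        d_list = d_cache, env = env, week_offset = 0L)
  attr(log, "weeks") <- cfg$weeks
  attr(log, "seed") <- cfg$seed
  attr(log, "n_drawn") <- total_drawn
  log
}

# Build the trip-record table from per-agent sampler output.
assemble_trips <- function(results, pgs, group_of, agent_ids, group_names,
                           d_list, env, week_offset = 0L) {
  counts <- vapply(results, function(r) length(r$week), integer(1))
  total <- sum(counts)
  store_lut <- lapply(pgs, function(pg) match(pg$pool_ids, env$stores$id))
  agent_col <- rep(agent_ids, counts)
  group_col <- rep(group_names, counts)
  week_col <- unlist(lapply(results, `[[`, "week"), use.names = FALSE) + week_offset
  mode_col <- unlist(lapply(results, `[[`, "mode"), use.names = FALSE)
  if (total == 0L) {
    out <- data.frame(agent_id = integer(0), group = character(0),
                      week = integer(0), store_id = character(0),
                      store_type = character(0), zone = character(0),
                      mode = character(0), motorized = logical(0),
                      distance_miles = numeric(0))
    return(out)
  }
  sidx <- integer(total); dist <- numeric(total)
  pos <- 0L
  for (i in seq_along(results)) {
    k <- counts[i]
    if (k == 0L) next
    pidx <- results[[i]]$pool_idx
    sidx[pos + seq_len(k)] <- store_lut[[group_of[i]]][pidx]
    dist[pos + seq_len(k)] <- d_list[[i]][pidx]
    pos <- pos + k
  }
  out <- data.table::data.table(
    agent_id = agent_col,
    group = group_col,
    week = as.integer(week_col),
    store_id = env$stores$id[sidx],
    store_type = env$stores$store_type[sidx],
    zone = env$stores$zone[sidx],
    mode = MODE_LABELS[mode_col],
    motorized = mode_col <= 3L,
    distance_miles = dist
  )
  data.table::setDF(out)
  out
}

#' Write a trip log to CSV
#' @param log trip log from [run_simulation()].
#' @param path file path.
#' @export
write_trip_log <- function(log, path) {
  data.table::fwrite(log, path)
  invisible(path)
}
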