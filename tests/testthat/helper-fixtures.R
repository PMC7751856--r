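# Shared fixtures and independent oracles, built in code at test time.

# ---- independent all-pairs shortest-path oracle (Floyd-Warshall) ------------

fw_oracle <- function(nodes, edges) {
  n <- nrow(nodes)
  idx <- setNames(seq_len(n), as.character(nodes$id))
  d <- matrix(Inf, n, n, dimnames = list(nodes$id, nodes$id))
  diag(d) <- 0
  for (e in seq_len(nrow(edges))) {
    i <- idx[as.character(edges$from[e])]; j <- idx[as.character(edges$to[e])]
    d[i, j] <- min(d[i, j], edges$length[e])
    d[j, i] <- d[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    dk <- d[i, k] + d[k, ]
    upd <- dk < d[i, ]
    d[i, upd] <- dk[upd]
  }
  d
}

# random connected planar-coordinate network with <= n nodes
random_network <- function(n, seed) {
  set.seed(seed)
  nodes <- data.frame(id = as.character(seq_len(n)),
                      x = runif(n, 0, 10), y = runif(n, 0, 10))
  # random spanning tree, then extra edges
  from <- to <- integer(0)
  for (i in 2:n) { from <- c(from, sample(i - 1, 1)); to <- c(to, i) }
  extra <- matrix(sample(n, 2 * n, replace = TRUE), ncol = 2)
  extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
  from <- c(from, extra[, 1]); to <- c(to, extra[, 2])
  len <- sqrt((nodes$x[from] - nodes$x[to])^2 + (nodes$y[from] - nodes$y[to])^2)
  keep <- len > 0
  edges <- unique(data.frame(from = as.character(pmin(from, to)[keep]),
                             to = as.character(pmax(from, to)[keep]),
                             length = len[keep]))
  list(nodes = nodes, edges = edges, net = road_network(nodes, edges))
}

# ---- toy environment for decision-engine tests ------------------------------

# a path network with one house at the origin and three stores at 1, 4 and
# 8 miles, spanning the neighborhood and city zones
toy_env <- function() {
  nodes <- data.frame(id = c("n0", "n1", "n4", "n8"),
                      x = c(0, 1, 4, 8), y = 0)
  edges <- data.frame(from = c("n0", "n1", "n4"), to = c("n1", "n4", "n8"))
  net <- road_network(nodes, edges)
  zones <- zone_partition(cbind(c(-1, 2, 2, -1), c(-1, -1, 1, 1)),
                          cbind(c(-2, 10, 10, -2), c(-2, -2, 2, 2)))
  houses <- data.frame(id = "H1", tract_id = "T01", x = 0, y = 0, node = "n0")
  stores <- data.frame(id = c("A", "B", "C"),
                       store_type = c("convenience", "independent_supermarket",
                                      "chain_supermarket"),
                       x = c(1, 4, 8), y = 0, node = c("n1", "n4", "n8"))
  stores$zone <- classify_zone(stores$x, stores$y, zones)
  env <- structure(list(network = net, houses = houses, stores = stores,
                        zones = zones), class = "fabm_env")
  list(env = env, od = build_od_matrix(net, houses, stores))
}

toy_group <- function(pool = data.frame(store_id = c("A", "B", "C"),
                                        weight = c(1, 1, 1)),
                      trip_values = 2L, trip_probs = 1,
                      car_ownership_prob = 0,
                      type_consideration_prob = 0,
                      mode_first_prob = 0.5,
                      noncar_mode_probs = c(bus = .25, taxi = .25,
                                            walk = .25, bike = .25),
                      nonmotorized_by_bin = c(rep(1, 6), rep(0, 5)),
                      store_type_weights = c(convenience = 1,
                                             independent_supermarket = 1,
                                             chain_supermarket = 1)) {
  agent_group(
    name = "CoLwInYg", income_stratum = "<20k", age_stratum = "18-44",
    sample_size = 33, car_ownership_prob = car_ownership_prob,
    trip_count_values = trip_values, trip_count_probs = trip_probs,
    type_consideration_prob = type_consideration_prob,
    mode_first_prob = mode_first_prob,
    store_type_weights = store_type_weights,
    store_pool = pool,
    noncar_mode_probs = noncar_mode_probs,
    nonmotorized_by_bin = nonmotorized_by_bin
  )
}

toy_agent <- function(has_car = FALSE) {
  list(agent_id = 1L, group = "CoLwInYg", house_id = "H1", has_car = has_car)
}

# ---- cached packaged fixtures and the reference full-scale run --------------

.cache <- new.env(parent = emptyenv())

packaged_bundle <- function() {
  if (is.null(.cache$bundle)) .cache$bundle <- fixture_bundle()
  .cache$bundle
}

# the packaged study run: upscaled population, 52 weeks, seed 42
packaged_run <- function() {
  if (is.null(.cache$run)) {
    b <- packaged_bundle()
    agents <- upscale_population(b$respondents, b$tracts, seed = 42)
    agents <- instantiate_agents(agents, b$env$houses, b$groups, seed = 42)
    cfg <- simulation_config(weeks = 52, seed = 42)
    log <- run_simulation(agents, b$groups, b$env, b$od, cfg)
    .cache$run <- list(agents = agents, log = log, cfg = cfg)
  }
  .cache$run
}

# cluster-robust 3-sigma half-width for a trip-level share: trips are
# clustered within agents (house and car status are shared), so the binomial
# formula understates the sampling variance
share_tol3 <- function(success, agent_id) {
  p <- mean(success)
  s_a <- tapply(success, agent_id, sum)
  n_a <- tapply(rep(1, length(success)), agent_id, sum)
  v <- sum((s_a - p * n_a)^2) / sum(n_a)^2
  3 * sqrt(v)
}
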