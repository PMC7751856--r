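# The weekly shopping decision process on a toy path-network environment.

test_that("trip counts follow the group distribution", {
  g5 <- toy_group(trip_values = 5L, trip_probs = 1)
  expect_true(all(draw_trip_count(g5, 100) == 5L))

  g <- toy_group(trip_values = c(0L, 2L, 5L, 9L), trip_probs = c(.1, .3, .4, .2))
  set.seed(1)
  draws <- draw_trip_count(g, 10000)
  gof <- suppressWarnings(
    stats::chisq.test(table(factor(draws, levels = c(0, 2, 5, 9))),
                      p = c(.1, .3, .4, .2)))
  expect_gt(gof$p.value, 0.01)
})

test_that("type filtering restricts and renormalizes the pool", {
  t <- toy_env()
  groups <- groceryabm:::prepare_groups(list(CoLwInYg = toy_group()), t$env)

  g0 <- groups$CoLwInYg
  g0$type_consideration_prob <- 0
  for (i in 1:5) expect_equal(decide_store_type_filter(g0)$store_id, c("A", "B", "C"))

  # single-type pool with certain consideration: restriction is the identity
  pool1 <- data.frame(store_id = "A", weight = 1)
  g1 <- toy_group(pool = pool1, type_consideration_prob = 1,
                  store_type_weights = c(convenience = 1))
  g1 <- groceryabm:::prepare_groups(list(CoLwInYg = g1), t$env)$CoLwInYg
  expect_equal(decide_store_type_filter(g1)$store_id, "A")

  # mixed pool, certain consideration of convenience only
  g2 <- toy_group(type_consideration_prob = 1,
                  store_type_weights = c(convenience = 1))
  g2 <- groceryabm:::prepare_groups(list(CoLwInYg = g2), t$env)$CoLwInYg
  set.seed(2)
  out <- decide_store_type_filter(g2)
  expect_equal(out$store_id, "A")          # the only convenience store
  expect_equal(sum(out$weight), 1)
})

test_that("car owners always drive, whichever decision order", {
  t <- toy_env()
  g <- groceryabm:::prepare_groups(list(CoLwInYg = toy_group()), t$env)$CoLwInYg
  a <- toy_agent(has_car = TRUE)
  set.seed(3)
  for (i in 1:20) {
    expect_equal(select_mode_first(a, g, g$store_pool, t$od)$mode, "car")
    expect_equal(select_store_first(a, g, g$store_pool, t$od)$mode, "car")
  }
})

test_that("mode-first walking store choice decays exponentially with distance", {
  t <- toy_env()
  # two equal-weight stores at 1 and 4 miles; walkers only
  pool <- data.frame(store_id = c("A", "B"), weight = c(1, 1))
  g <- toy_group(pool = pool,
                 noncar_mode_probs = c(bus = 0, taxi = 0, walk = 1, bike = 0))
  g <- groceryabm:::prepare_groups(list(CoLwInYg = g), t$env)$CoLwInYg
  a <- toy_agent(has_car = FALSE)
  cfg <- simulation_config(lambda_walk = 3)
  set.seed(4)
  picks <- replicate(10000, select_mode_first(a, g, g$store_pool, t$od, cfg)$store_id)
  p_near <- exp(-1 / 3) / (exp(-1 / 3) + exp(-4 / 3))    # ~0.731
  expect_lt(abs(mean(picks == "A") - p_near), 3 * sqrt(p_near * (1 - p_near) / 10000))

  # a single-store pool is chosen regardless of mode
  g1 <- toy_group(pool = data.frame(store_id = "B", weight = 1))
  g1 <- groceryabm:::prepare_groups(list(CoLwInYg = g1), t$env)$CoLwInYg
  expect_equal(select_mode_first(a, g1, g1$store_pool, t$od, cfg)$store_id, "B")
})

test_that("store-first choice follows pool weights and distance-binned modes", {
  t <- toy_env()
  pool <- data.frame(store_id = c("A", "B"), weight = c(3, 1))
  g <- groceryabm:::prepare_groups(list(CoLwInYg = toy_group(pool = pool)), t$env)$CoLwInYg
  a <- toy_agent(has_car = FALSE)
  set.seed(5)
  picks <- replicate(10000, select_store_first(a, g, g$store_pool, t$od)$store_id)
  expect_lt(abs(mean(picks == "A") - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))

  # motorized-only beyond 6 miles: the 8-mile store is reached by bus or taxi
  g8 <- toy_group(pool = data.frame(store_id = "C", weight = 1))
  g8 <- groceryabm:::prepare_groups(list(CoLwInYg = g8), t$env)$CoLwInYg
  set.seed(6)
  modes <- replicate(200, select_store_first(a, g8, g8$store_pool, t$od)$mode)
  expect_true(all(modes %in% c("bus", "taxi")))
})

test_that("weekly simulation conserves trip counts and is deterministic", {
  t <- toy_env()
  groups <- list(CoLwInYg = toy_group(trip_values = c(0L, 3L), trip_probs = c(.5, .5)))
  a <- toy_agent()

  set.seed(7)
  lens <- replicate(50, nrow(simulate_week(a, groups, t$env, t$od)))
  expect_true(all(lens %in% c(0L, 3L)))   # output length equals the drawn count

  set.seed(8); w1 <- simulate_week(a, groups, t$env, t$od)
  set.seed(8); w2 <- simulate_week(a, groups, t$env, t$od)
  expect_identical(w1, w2)
})

test_that("full runs fill records from the OD matrix and the store table", {
  t <- toy_env()
  groups <- list(CoLwInYg = toy_group(trip_values = 2L, trip_probs = 1))
  agents <- data.frame(agent_id = 1:6, group = "CoLwInYg", tract_id = "T01",
                       house_id = "H1", has_car = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  cfg <- simulation_config(weeks = 1, seed = 9)
  log <- run_simulation(agents, groups, t$env, t$od, cfg)
  expect_equal(nrow(log), 12)             # 6 agents x 1 week x 2 trips
  expect_equal(nrow(log), attr(log, "n_drawn"))
  # every distance equals the OD entry; every zone matches the store's zone
  expect_equal(log$distance_miles, unname(t$od["H1", log$store_id]))
  expect_equal(log$zone, t$env$stores$zone[match(log$store_id, t$env$stores$id)])
  expect_equal(log$motorized, log$mode %in% c("car", "bus", "taxi"))
  expect_true(all(log$mode[log$agent_id %in% c(1, 3, 5)] == "car"))

  # byte-identical reruns, and invariance to agent order
  log2 <- run_simulation(agents, groups, t$env, t$od, cfg)
  expect_identical(log, log2)
  perm <- agents[c(4, 2, 6, 1, 3, 5), ]
  logp <- run_simulation(perm, groups, t$env, t$od, cfg)
  for (id in agents$agent_id) {
    a_rows <- log[log$agent_id == id, ]
    p_rows <- logp[logp$agent_id == id, ]
    rownames(a_rows) <- rownames(p_rows) <- NULL
    expect_identical(a_rows, p_rows)
  }
})

test_that("config YAML round-trips", {
  cfg <- simulation_config(weeks = 10, seed = 5, lambda_walk = 2.5,
                           mode_first_prob = 0.4)
  path <- tempfile(fileext = ".yaml")
  write_simulation_config(cfg, path)
  cfg2 <- read_simulation_config(path)
  expect_equal(cfg2$weeks, 10L)
  expect_equal(cfg2$lambda_walk, 2.5)
  expect_equal(cfg2$mode_first_prob, 0.4)
  expect_equal(cfg2$distance_bins, cfg$distance_bins)
})
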