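# Synthetic city generation, survey emulation, and zone-share calibration.

test_that("store placement matches the recipe counts per zone exactly", {
  env <- packaged_bundle()$env
  recipe <- city_recipe()
  hist <- table(factor(env$stores$zone, levels = zone_levels()))
  expect_equal(as.integer(hist), unname(rowSums(recipe$store_counts)[zone_levels()]))
  bytype <- table(env$stores$zone, env$stores$store_type)
  for (z in zone_levels()) for (ty in default_store_types()) {
    n <- if (ty %in% colnames(bytype)) bytype[z, ty] else 0L
    expect_equal(as.integer(n), unname(recipe$store_counts[z, ty]))
  }
})

test_that("a one-store-per-zone recipe yields one store in each zone", {
  counts <- rbind(neighborhood = c(0, 1, 0, 0, 0),
                  city         = c(0, 1, 0, 0, 0),
                  suburbs      = c(1, 0, 0, 0, 0))
  colnames(counts) <- default_store_types()
  env <- generate_synthetic_city(city_recipe(store_counts = counts), seed = 4)
  expect_equal(nrow(env$stores), 3)
  expect_setequal(env$stores$zone, zone_levels())
})

test_that("the synthetic survey reproduces the sample design", {
  b <- packaged_bundle()
  r <- b$respondents
  expect_equal(nrow(r), 188)
  sizes <- table(factor(r$group, levels = agent_group_names()))
  expect_equal(as.integer(sizes), unname(group_sample_sizes()))
  expect_equal(sum(group_sample_sizes()), 188L)
  expect_equal(r$group, stratify_respondent(r$age, r$income))

  # lowest-income stratum household size: mean 2.20
  low <- r$persons[r$income < 20000]
  expect_lt(abs(mean(low) - 2.20), 3 * stats::sd(low) / sqrt(length(low)))
})

test_that("fixture generation is seed-deterministic", {
  b1 <- fixture_bundle(seed = 77)
  b2 <- fixture_bundle(seed = 77)
  expect_identical(b1$respondents, b2$respondents)
  expect_identical(b1$tracts, b2$tracts)
  expect_identical(lapply(b1$groups, `[[`, "store_pool"),
                   lapply(b2$groups, `[[`, "store_pool"))
})

test_that("calibrated pools hit the zone-share targets analytically", {
  b <- packaged_bundle()
  cfg <- simulation_config()
  store_zone <- setNames(b$env$stores$zone, b$env$stores$id)
  store_type <- setNames(b$env$stores$store_type, b$env$stores$id)
  hrows <- match(b$env$houses$id, rownames(b$od))
  n_houses <- table(b$env$houses$tract_id)
  for (g in agent_group_names()) {
    gr <- b$groups[[g]]
    pool <- gr$store_pool
    D <- b$od[hrows, pool$store_id, drop = FALSE]
    tm <- match(b$env$houses$tract_id, b$tracts$tract_id)
    p_h <- b$tracts$household_count[tm] * b$tracts[[g]][tm] /
      as.numeric(n_houses[b$env$houses$tract_id])
    p_h <- p_h / sum(p_h)
    K <- list(matrix(1, nrow(D), ncol(D)), exp(-D / cfg$lambda_walk),
              exp(-D / cfg$lambda_bike))
    cps <- groceryabm:::decay_class_probs(gr$car_ownership_prob,
                                          gr$mode_first_prob, gr$noncar_mode_probs)
    pi_s <- groceryabm:::expected_store_probs(
      pool$weight, store_type[pool$store_id], gr$store_type_weights,
      gr$type_consideration_prob, K, cps, p_h)
    share <- tapply(pi_s, factor(store_zone[pool$store_id], levels = zone_levels()),
                    sum, default = 0)
    expect_lt(max(abs(share - b$targets$zone_shares[g, ])), 1e-6)
  }
  # the printed aggregates for the core-poor young group
  expect_equal(unname(b$targets$zone_shares["CoLwInYg", ]), c(0.25, 0.57, 0.18))
})

test_that("calibration is a projection: feasible groups are unchanged", {
  w <- c(0.6, 0.4)
  D <- matrix(c(1, 2), nrow = 1)   # one house, two stores, one zone
  K <- list(matrix(1, 1, 2))
  out <- groceryabm:::calibrate_zone_weights(
    w, pool_zones = c("neighborhood", "neighborhood"),
    pool_types = c("convenience", "dollar"),
    theta = c(convenience = 0.5, dollar = 0.5), tau = 0.5,
    K_list = K, class_probs = c(none = 1), p_h = 1,
    target = c(neighborhood = 1, city = 0, suburbs = 0))
  expect_equal(out$weight, w)
  expect_equal(out$iterations, 1L)

  # infeasible target: positive share in a zone with no pool store
  expect_error(groceryabm:::calibrate_zone_weights(
    w, pool_zones = c("neighborhood", "neighborhood"),
    pool_types = c("convenience", "dollar"),
    theta = c(convenience = 0.5, dollar = 0.5), tau = 0.5,
    K_list = K, class_probs = c(none = 1), p_h = 1,
    target = c(neighborhood = 0.5, city = 0.5, suburbs = 0)),
    "calibration error")
})

test_that("all fixture distributions are normalized probabilities", {
  b <- packaged_bundle()
  for (g in b$groups) {
    expect_equal(sum(g$trip_count_probs), 1)
    expect_equal(sum(g$store_pool$weight), 1)
    expect_equal(sum(g$store_type_weights), 1)
    expect_equal(sum(g$noncar_mode_probs), 1)
    expect_true(all(g$nonmotorized_by_bin >= 0 & g$nonmotorized_by_bin <= 1))
  }
  # the design mixture mean of weekly trips is the published ~5/week
  n <- group_sample_sizes()
  means <- vapply(b$groups, function(g) sum(g$trip_count_values * g$trip_count_probs),
                  numeric(1))
  expect_equal(sum(n * means[names(n)]) / sum(n), 5, tolerance = 1e-6)
})

test_that("fixture files round-trip through their plain-text formats", {
  b <- packaged_bundle()
  dir <- tempfile("fixio"); dir.create(dir)
  write_fixture_files(b, dir)
  g2 <- read_groups_json(file.path(dir, "groups.json"))
  expect_equal(names(g2), agent_group_names())
  expect_equal(g2$CoLwInYg$store_pool$weight, b$groups$CoLwInYg$store_pool$weight)
  expect_equal(g2$MeInYg$trip_count_probs, b$groups$MeInYg$trip_count_probs)
  r2 <- read.csv(file.path(dir, "respondents.csv"))
  expect_equal(nrow(r2), 188)
})
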