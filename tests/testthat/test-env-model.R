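# Spatial environment: zone classification, shortest paths, OD matrices,
# GeoJSON loading and its validation errors.

test_that("zone classification is exhaustive with closed inner boundaries", {
  zones <- zone_partition(cbind(c(0, 2, 2, 0), c(0, 0, 2, 2)),
                          cbind(c(-2, 5, 5, -2), c(-2, -2, 5, 5)))
  expect_equal(classify_zone(1, 1, zones), "neighborhood")      # centroid
  expect_equal(classify_zone(4, 4, zones), "city")
  expect_equal(classify_zone(10, 0, zones), "suburbs")          # outside city
  # boundary points belong to the innermost zone containing them
  expect_equal(classify_zone(2, 1, zones), "neighborhood")      # edge
  expect_equal(classify_zone(0, 0, zones), "neighborhood")      # vertex
  expect_equal(classify_zone(5, 5, zones), "city")              # outer edge
  # exhaustive and mutually exclusive over a point sample
  set.seed(1)
  z <- classify_zone(runif(500, -4, 8), runif(500, -4, 8), zones)
  expect_true(all(z %in% zone_levels()))
})

test_that("non-nested zone polygons are rejected", {
  expect_error(
    zone_partition(cbind(c(0, 9, 9, 0), c(0, 0, 2, 2)),
                   cbind(c(-2, 5, 5, -2), c(-2, -2, 5, 5))),
    "partition error")
})

test_that("shortest path distances match hand-computed cases", {
  nodes <- data.frame(id = c("a", "b"), x = c(0, 2.5), y = 0)
  edges <- data.frame(from = "a", to = "b", length = 2.5)
  net <- road_network(nodes, edges)
  expect_equal(shortest_path_distance(net, "a", "a"), 0)
  expect_equal(shortest_path_distance(net, "a", "b"), 2.5)

  # unit square with a 1.2-mile diagonal: the diagonal beats the 2.0 detour
  sq_nodes <- data.frame(id = as.character(1:4),
                         x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  sq_edges <- data.frame(from = c("1", "2", "3", "4", "1"),
                         to = c("2", "3", "4", "1", "3"),
                         length = c(1, 1, 1, 1, 1.2))
  sq <- road_network(sq_nodes, sq_edges)
  expect_equal(shortest_path_distance(sq, "1", "3"), 1.2)
  expect_equal(shortest_path_distance(sq, "2", "4"), 2)
  expect_equal(shortest_path_distance(sq, "1", "3"),
               shortest_path_distance(sq, "3", "1"))
})

test_that("edge lengths must be positive", {
  nodes <- data.frame(id = c("a", "b"), x = c(0, 1), y = 0)
  expect_error(road_network(nodes, data.frame(from = "a", to = "b", length = 0)),
               "positive")
})

test_that("OD distances equal the Floyd-Warshall oracle on random networks", {
  for (seed in 1:5) {
    n <- sample(10:50, 1)
    rn <- random_network(n, seed = seed)
    ora <- fw_oracle(rn$nodes, rn$edges)
    pick_h <- rn$nodes[sample(n, 6), ]
    pick_s <- rn$nodes[sample(n, 5), ]
    houses <- data.frame(id = paste0("h", seq_len(6)), x = pick_h$x, y = pick_h$y,
                         node = pick_h$id)
    stores <- data.frame(id = paste0("s", seq_len(5)), x = pick_s$x, y = pick_s$y,
                         node = pick_s$id)
    od <- build_od_matrix(rn$net, houses, stores)
    expect_equal(unname(od[cbind(houses$id, rep(stores$id, each = 6))]),
                 unname(ora[cbind(pick_h$id, rep(pick_s$id, each = 6))]),
                 tolerance = 1e-12)
    # symmetry and triangle inequality over the oracle-verified matrix
    full <- igraph::distances(rn$net$graph)
    expect_equal(full, t(full))
    k <- sample(n, 1)
    expect_true(all(full <= full[, k] %o% rep(1, n) + rep(1, n) %o% full[k, ] + 1e-9))
  }
})

test_that("OD matrix handles co-located and path-graph cases", {
  nodes <- data.frame(id = c("a", "b", "c"), x = c(0, 1, 3), y = 0)
  edges <- data.frame(from = c("a", "b"), to = c("b", "c"))
  net <- road_network(nodes, edges)   # lengths from coordinates: 1 and 2
  houses <- data.frame(id = c("h1", "h2"), x = c(0, 1), y = 0)
  stores <- data.frame(id = c("s1", "s2"), x = c(0, 3), y = 0)
  od <- build_od_matrix(net, houses, stores)
  expect_equal(od["h1", "s1"], 0)                    # same snapped node
  expect_equal(od["h1", "s2"], 3)
  expect_equal(od["h2", "s1"], 1)
  expect_equal(od["h2", "s2"], 2)
})

test_that("snapping beyond the radius names the offending feature", {
  nodes <- data.frame(id = c("a", "b"), x = c(0, 1), y = 0)
  net <- road_network(nodes, data.frame(from = "a", to = "b"))
  houses <- data.frame(id = "far_house", x = 0, y = 5)
  stores <- data.frame(id = "s1", x = 1, y = 0)
  expect_error(build_od_matrix(net, houses, stores), "far_house")
})

test_that("environment loading validates schema and connectivity", {
  dir <- tempfile("envio"); dir.create(dir)
  env <- generate_synthetic_city(seed = 99, dir = dir)
  expect_s3_class(env, "fabm_env")
  expect_setequal(unique(env$stores$zone), zone_levels())

  # a store without store_type is a schema error naming the feature
  st <- read_geojson(file.path(dir, "stores.geojson"))
  st$features[[1]]$properties$store_type <- NULL
  bad <- file.path(dir, "stores_bad.geojson")
  jsonlite::write_json(unclass(st), bad, auto_unbox = TRUE, digits = NA)
  expect_error(
    load_environment(list(houses = file.path(dir, "houses.geojson"),
                          stores = bad,
                          roads = file.path(dir, "roads.geojson"),
                          zones = file.path(dir, "zones.geojson"))),
    "schema error.*store_type")

  # an unreachable island is a connectivity error
  rd <- read_geojson(file.path(dir, "roads.geojson"))
  rd$features <- c(rd$features, list(list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = list(c(100, 100), c(101, 100))),
    properties = list())))
  badrd <- file.path(dir, "roads_bad.geojson")
  jsonlite::write_json(unclass(rd), badrd, auto_unbox = TRUE, digits = NA)
  hs <- read_geojson(file.path(dir, "houses.geojson"))
  hs$features[[1]]$geometry$coordinates <- c(100, 100)
  badhs <- file.path(dir, "houses_bad.geojson")
  jsonlite::write_json(unclass(hs), badhs, auto_unbox = TRUE, digits = NA)
  expect_error(
    load_environment(list(houses = badhs, stores = file.path(dir, "stores.geojson"),
                          roads = badrd, zones = file.path(dir, "zones.geojson"))),
    "connectivity error")
})

test_that("OD matrix round-trips through CSV", {
  t <- toy_env()
  path <- tempfile(fileext = ".csv")
  write_od_csv(t$od, path)
  od2 <- read_od_csv(path)
  expect_equal(unclass(od2)[rownames(t$od), colnames(t$od)],
               unclass(t$od)[, , drop = FALSE],
               ignore_attr = TRUE)
})
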