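# Reductions: mode share by distance, zone summaries, store maps, medians.

make_log <- function(distance, mode, group = "G1", agent_id = 1L, week = 1L,
                     zone = "city", store_id = "S1", weeks = 1L) {
  n <- length(distance)
  log <- data.frame(
    agent_id = rep_len(agent_id, n), group = rep_len(group, n),
    week = rep_len(week, n), store_id = rep_len(store_id, n),
    store_type = "convenience", zone = rep_len(zone, n),
    mode = rep_len(mode, n),
    motorized = rep_len(mode, n) %in% c("car", "bus", "taxi"),
    distance_miles = distance)
  attr(log, "weeks") <- weeks
  log
}

test_that("non-motorized share is computed per half-open distance bin", {
  log <- make_log(2.2, "walk")
  prof <- mode_share_by_distance(log, bins = 0:11)
  expect_equal(nrow(prof), 1)              # empty bins are absent, not zero
  expect_equal(prof$bin_lo, 2)
  expect_equal(prof$bin_hi, 3)
  expect_equal(prof$nonmotorized_share, 1)

  allcar <- make_log(c(0.5, 3.7, 9.9), "car")
  prof2 <- mode_share_by_distance(allcar, bins = 0:11)
  expect_true(all(prof2$nonmotorized_share == 0))
  expect_equal(sum(prof2$trips), 3)        # conservation
})

test_that("zone summary gives weekly per-household rates and global shares", {
  log <- make_log(rep(1, 8), "car", zone = "neighborhood", week = rep(1:4, 2),
                  weeks = 4L)
  agents <- data.frame(agent_id = 1L, group = "G1")
  zs <- zone_trip_summary(log, agents)
  nb <- zs$per_group[zs$per_group$zone == "neighborhood", ]
  expect_equal(nb$trips_per_week, 2)       # 8 trips / (1 agent x 4 weeks)
  expect_equal(sum(zs$population_shares), 1)

  orphan <- log; orphan$agent_id <- 99L
  expect_error(zone_trip_summary(orphan, agents), "join error")
})

test_that("store map normalizes by the global maximum and conserves counts", {
  stores <- data.frame(id = c("S1", "S2"))
  one <- make_log(1, "car")
  m1 <- store_visit_map(one, stores)
  expect_equal(m1$normalized_rate, 1)
  expect_equal(m1$motorized_share, 1)      # car-only store

  log <- rbind(make_log(rep(1, 6), "car", store_id = "S1"),
               make_log(rep(2, 2), "walk", store_id = "S2", agent_id = 2L))
  attr(log, "weeks") <- 2L
  m <- store_visit_map(log, stores)
  expect_equal(max(m$normalized_rate), 1)
  expect_equal(sum(m$visits_per_week), nrow(log) / 2)   # total trips / weeks
  expect_equal(m$motorized_share[m$store_id == "S2"], 0)
})

test_that("median trip distance follows the midpoint convention and a sort oracle", {
  expect_equal(unname(median_trip_distance(make_log(c(1, 3, 7), "car"))), 3)
  expect_equal(unname(median_trip_distance(make_log(c(1, 3), "car"))), 2)

  sort_median <- function(x) {             # independent oracle
    s <- sort(x); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  set.seed(21)
  for (i in 1:5) {
    n <- sample(100:10000, 1)
    x <- round(stats::rexp(n, 0.2), 2)
    log <- make_log(x, "car", group = sample(c("G1", "G2"), n, replace = TRUE))
    med <- median_trip_distance(log, by = "group")
    for (g in names(med)) expect_equal(unname(med[g]), sort_median(x[log$group == g]))
    expect_equal(unname(median_trip_distance(log, by = "population")), sort_median(x))
  }
})

test_that("reductions are invariant to permutations of the log", {
  set.seed(31)
  n <- 500
  log <- make_log(runif(n, 0, 12), sample(travel_modes(), n, replace = TRUE),
                  group = sample(c("G1", "G2"), n, TRUE),
                  agent_id = sample(1:20, n, TRUE),
                  zone = sample(zone_levels(), n, TRUE),
                  store_id = sample(c("S1", "S2", "S3"), n, TRUE),
                  week = sample(1:4, n, TRUE), weeks = 4L)
  perm <- log[sample(n), ]; attr(perm, "weeks") <- 4L
  expect_equal(mode_share_by_distance(log), mode_share_by_distance(perm),
               ignore_attr = TRUE)
  expect_equal(median_trip_distance(log), median_trip_distance(perm))
  expect_equal(store_visit_map(log, data.frame(id = c("S1", "S2", "S3"))),
               store_visit_map(perm, data.frame(id = c("S1", "S2", "S3"))),
               ignore_attr = TRUE)
})
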