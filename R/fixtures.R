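# Synthetic study-area fixtures: a three-zone city on a grid road network
# with stores clustered along arterial corridors, a stratified synthetic
# survey sample, census-tract profiles, and group fixtures whose store-pool
# weights are calibrated so the simulated aggregates reproduce the published
# ones (zone-visit shares, no-car shares, trip rates, non-motorized bands).

# ---- calibration targets ----------------------------------------------------

#' Calibration targets for the packaged fixtures
#'
#' The aggregate travel patterns the packaged synthetic fixtures are
#' calibrated to reproduce: per-group shopping-zone visit shares, car
#' ownership, weekly trip-count means, household sizes, and non-motorized
#' travel shares. Population-level constraints (23% of all trips in the
#' neighborhood, 35% in the suburbs, a mixture mean of 5.0 trips per week)
#' are enforced exactly by solving the largest group's (CoLwInMiAg) zone
#' shares and trip mean from the other seven groups.
#'
#' @return a list of class `calibration_targets`.
#' @export
calibration_targets <- function() {
  gn <- agent_group_names()
  n <- group_sample_sizes()

  trip_means <- setNames(c(5.4, NA, 3.0, 5.4, 4.4, 3.0, 11.2, 4.0), gn)
  pop_trips_mean <- 5.0
  trip_means["CoLwInMiAg"] <-
    (sum(n) * pop_trips_mean - sum(n[gn != "CoLwInMiAg"] * trip_means[gn != "CoLwInMiAg"])) /
    n["CoLwInMiAg"]

  zone <- rbind(
    CoLwInYg    = c(0.25, 0.57, 0.18),
    CoLwInMiAg  = c(NA, NA, NA),
    CoLwInOld   = c(0.30, 0.45, 0.25),
    LwInYg      = c(0.22, 0.42, 0.36),
    LwInMiAg    = c(0.24, 0.38, 0.38),
    LwInOld     = c(0.28, 0.42, 0.30),
    MeInYg      = c(0.11, 0.36, 0.53),
    MeInMiAgOld = c(0.20, 0.30, 0.50)
  )
  colnames(zone) <- zone_levels()
  pop_zone <- c(neighborhood = 0.23, suburbs = 0.35)
  w <- n * trip_means                       # expected weekly trips per group
  others <- gn != "CoLwInMiAg"
  nb <- (sum(w) * pop_zone["neighborhood"] -
           sum(w[others] * zone[others, "neighborhood"])) / w["CoLwInMiAg"]
  su <- (sum(w) * pop_zone["suburbs"] -
           sum(w[others] * zone[others, "suburbs"])) / w["CoLwInMiAg"]
  zone["CoLwInMiAg", ] <- c(nb, 1 - nb - su, su)
  if (any(zone < 0 | zone > 1)) stop_fmt("infeasible zone-share targets")

  structure(list(
    zone_shares = zone,
    trip_means = trip_means,
    trip_max = 20L,
    # car ownership = 1 - no-car probability
    no_car = setNames(c(0.60, 0.40, 0.30, 0.35, 0.22, 0.15, 0.10, 0.10), gn),
    # P(non-motorized | carless trip); overall group non-motorized share is
    # no_car * nm_conditional
    nm_conditional = setNames(c(0.75, 0.625, 1 / 3, 0.30, 0.545, 1 / 3, 0.80, 0.30), gn),
    # distance (miles) beyond which non-motorized travel is absent
    nm_cutoff = setNames(c(9, 8, 6, 6, 8, 6, Inf, 8), gn),
    nm_curve = c(d0 = 5, scale = 1.5),     # logistic decline of the bin table
    walk_frac_nm = 0.65,
    bus_frac_mot = 0.80,
    household_size_mean = setNames(c(2.20, 2.20, 2.20, 2.37, 2.37, 2.37, 2.56, 2.56), gn),
    mode_first_prob = 0.5,
    type_consideration_prob = 0.5,
    # tilt of the type-consideration weights toward full-grocery outlets
    type_tilt = c(chain_supermarket = 2.0, independent_supermarket = 1.5,
                  convenience = 0.5, dollar = 0.7, other = 1.0),
    population = c(pop_zone, trips_mean = pop_trips_mean),
    total_households = 14520L,
    n_tracts = 23L
  ), class = "calibration_targets")
}

#' Write calibration targets to YAML
#' @param targets a [calibration_targets()] list.
#' @param path file path.
#' @export
write_targets_yaml <- function(targets, path) {
  y <- unclass(targets)
  y$zone_shares <- as.data.frame(y$zone_shares)
  y$nm_cutoff <- ifelse(is.infinite(y$nm_cutoff), "Inf", y$nm_cutoff)
  yaml::write_yaml(lapply(y, function(v) if (is.matrix(v)) as.data.frame(v) else v), path)
  invisible(path)
}

# ---- synthetic city ---------------------------------------------------------

#' Recipe for the synthetic three-zone city
#'
#' A square study region on a grid road network. The case-study neighborhood
#' (just under 10 square miles, 23 tracts) is nested in the city (12 x 12
#' miles), which is nested in the region; everything outside the city is
#' suburbs. Stores cluster along arterial corridors running out of the
#' neighborhood across the city and into the suburbs.
#'
#' @param extent region side length (miles).
#' @param spacing road-grid spacing (miles).
#' @param neighborhood,city bounding boxes `c(xmin, ymin, xmax, ymax)`.
#' @param houses_per_tract houses generated per census tract.
#' @param store_counts zone-by-type store counts.
#' @return list of class `city_recipe`.
#' @export
city_recipe <- function(extent = 20, spacing = 0.5,
                        neighborhood = c(10, 6, 13.2, 9.1),
                        city = c(4, 4, 16, 16),
                        houses_per_tract = 30,
                        store_counts = NULL) {
  if (is.null(store_counts)) {
    store_counts <- rbind(
      neighborhood = c(chain_supermarket = 0, independent_supermarket = 2,
                       convenience = 3, dollar = 2, other = 1),
      city         = c(0, 6, 6, 4, 4),
      suburbs      = c(6, 3, 2, 1, 2)
    )
    colnames(store_counts) <- default_store_types()
  }
  # arterial corridors (x1, y1, x2, y2), axis-aligned
  corridors <- list(
    main_east = c(10, 7.5, 20, 7.5),     # through neighborhood, city, suburbs
    west      = c(4, 8.5, 9.5, 8.5),     # city, west of the neighborhood
    north     = c(12.5, 6, 12.5, 16),    # through neighborhood, north city
    suburb_ns = c(18.5, 2, 18.5, 18)     # suburban arterial
  )
  structure(list(extent = extent, spacing = spacing,
                 neighborhood = neighborhood, city = city,
                 corridors = corridors,
                 houses_per_tract = houses_per_tract,
                 store_counts = store_counts,
                 n_tracts = 23L),
            class = "city_recipe")
}

rect_ring <- function(b) {
  cbind(c(b[1], b[3], b[3], b[1], b[1]), c(b[2], b[2], b[4], b[4], b[2]))
}

# grid nodes lying on an axis-aligned corridor segment
corridor_nodes <- function(nodes, seg, tol = 1e-9) {
  if (abs(seg[2] - seg[4]) < tol) {       # horizontal
    which(abs(nodes$y - seg[2]) < tol & nodes$x >= seg[1] - tol & nodes$x <= seg[3] + tol)
  } else {
    which(abs(nodes$x - seg[1]) < tol & nodes$y >= seg[2] - tol & nodes$y <= seg[4] + tol)
  }
}

# tract cell of a point: 6 x 4 grid over the neighborhood, last two cells
# merged to give 23 tracts
tract_of_point <- function(x, y, nb) {
  cx <- pmin(pmax(findInterval(x, seq(nb[1], nb[3], length.out = 7),
                               rightmost.closed = TRUE), 1), 6)
  cy <- pmin(pmax(findInterval(y, seq(nb[2], nb[4], length.out = 5),
                               rightmost.closed = TRUE), 1), 4)
  cell <- (cy - 1L) * 6L + cx
  cell[cell == 24L] <- 23L
  sprintf("T%02d", cell)
}

#' Generate the synthetic city environment
#'
#' Writes `houses.geojson`, `stores.geojson`, `roads.geojson`,
#' `zones.geojson` to `dir` and loads them back through
#' [load_environment()], so the returned bundle is validated by construction.
#'
#' @param recipe a [city_recipe()].
#' @param seed integer seed.
#' @param dir output directory for the GeoJSON files.
#' @return a `fabm_env` bundle.
#' @export
generate_synthetic_city <- function(recipe = city_recipe(), seed = 1,
                                    dir = tempfile("city")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- recipe$spacing
  ax <- seq(0, recipe$extent, by = sp)
  nodes <- data.frame(id = as.character(seq_len(length(ax)^2)),
                      x = rep(ax, times = length(ax)),
                      y = rep(ax, each = length(ax)))
  zones <- list(neighborhood = rect_ring(recipe$neighborhood),
                city = rect_ring(recipe$city))

  # grid roads as one LineString per row/column
  lines <- c(
    lapply(ax, function(yy) cbind(ax, yy)),
    lapply(ax, function(xx) cbind(xx, ax))
  )

  with_local_seed(seed, {
    # stores on corridor nodes, stratified by zone and type; only nodes whose
    # zone is stable under the placement jitter (+/- 0.1 mi) are eligible
    zp <- zone_partition(zones$neighborhood, zones$city)
    node_zone <- classify_zone(nodes$x, nodes$y, zp)
    jit <- 0.12
    stable <- node_zone == classify_zone(nodes$x - jit, nodes$y - jit, zp) &
      node_zone == classify_zone(nodes$x + jit, nodes$y + jit, zp) &
      node_zone == classify_zone(nodes$x - jit, nodes$y + jit, zp) &
      node_zone == classify_zone(nodes$x + jit, nodes$y - jit, zp)
    corr_idx <- sort(unique(unlist(lapply(recipe$corridors, corridor_nodes,
                                          nodes = nodes))))
    corr_idx <- corr_idx[stable[corr_idx]]
    stores <- NULL
    s_ct <- 0L
    for (z in rownames(recipe$store_counts)) {
      elig <- corr_idx[node_zone[corr_idx] == z]
      need <- sum(recipe$store_counts[z, ])
      if (need > length(elig))
        stop_fmt("recipe error: %d stores requested in zone %s but only %d corridor nodes",
                 need, z, length(elig))
      pick <- elig[sample.int(length(elig), need)]
      types <- rep(colnames(recipe$store_counts), recipe$store_counts[z, ])
      for (i in seq_len(need)) {
        s_ct <- s_ct + 1L
        stores <- rbind(stores, data.frame(
          id = sprintf("S%02d", s_ct),
          store_type = types[i],
          x = nodes$x[pick[i]] + runif(1, -0.1, 0.1),
          y = nodes$y[pick[i]] + runif(1, -0.1, 0.1)
        ))
      }
    }

    # houses: jittered around grid nodes inside each tract cell
    nb <- recipe$neighborhood
    in_nb <- which(nodes$x >= nb[1] & nodes$x <= nb[3] &
                     nodes$y >= nb[2] & nodes$y <= nb[4])
    node_tract <- tract_of_point(nodes$x[in_nb], nodes$y[in_nb], nb)
    houses <- NULL
    h_ct <- 0L
    for (t in sprintf("T%02d", 1:23)) {
      cand <- in_nb[node_tract == t]
      if (!length(cand)) stop_fmt("recipe error: tract %s contains no road nodes", t)
      pick <- cand[sample_idx(length(cand), recipe$houses_per_tract)]
      hx <- nodes$x[pick] + runif(recipe$houses_per_tract, -0.17, 0.17)
      hy <- nodes$y[pick] + runif(recipe$houses_per_tract, -0.17, 0.17)
      houses <- rbind(houses, data.frame(
        id = sprintf("H%04d", h_ct + seq_len(recipe$houses_per_tract)),
        tract_id = t, x = hx, y = hy))
      h_ct <- h_ct + recipe$houses_per_tract
    }
    rownames(stores) <- rownames(houses) <- NULL

    write_geojson_points(houses[, c("x", "y", "id", "tract_id")],
                         file.path(dir, "houses.geojson"))
    write_geojson_points(stores[, c("x", "y", "id", "store_type")],
                         file.path(dir, "stores.geojson"))
    write_geojson_lines(lines, file.path(dir, "roads.geojson"))
    write_geojson_zones(zones, file.path(dir, "zones.geojson"))
  })
  load_environment(dir)
}

# ---- tract profiles ---------------------------------------------------------

#' Synthesize census-tract household profiles
#'
#' Tract group mixes are Dirichlet draws centered on the survey sample
#' proportions, then raked (iterative proportional fitting) so the
#' household-weighted aggregate mix equals the sample proportions exactly.
#'
#' @param targets a [calibration_targets()] list.
#' @param seed integer seed.
#' @param concentration Dirichlet concentration (larger = tracts closer to
#'   the sample mix).
#' @return data.frame: `tract_id`, `household_count`, one column per group.
#' @export
synthesize_tracts <- function(targets = calibration_targets(), seed = 1,
                              concentration = 60) {
  gn <- agent_group_names()
  p <- group_sample_sizes() / sum(group_sample_sizes())
  nt <- targets$n_tracts
  H <- targets$total_households
  with_local_seed(seed, {
    counts <- as.integer(rmultinom(1, H, rep(1 / nt, nt)))
    mix <- t(vapply(seq_len(nt), function(i) {
      g <- rgamma(length(gn), shape = concentration * p)
      g / sum(g)
    }, numeric(length(gn))))
    colnames(mix) <- gn
    # rake: household-weighted column means -> sample proportions, rows -> 1
    for (it in 1:500) {
      colw <- as.numeric(counts %*% mix) / H
      mix <- sweep(mix, 2, p / colw, `*`)
      mix <- mix / rowSums(mix)
      if (max(abs(as.numeric(counts %*% mix) / H - p)) < 1e-13) break
    }
    data.frame(tract_id = sprintf("T%02d", seq_len(nt)),
               household_count = counts, mix, check.names = FALSE)
  })
}

# ---- synthetic survey sample ------------------------------------------------

# truncated-Poisson trips-per-week pmf with an exactly matched mean
trip_pmf <- function(mean, max = 20L) {
  vals <- 0:max
  f <- function(lam) sum(vals * dpois(vals, lam)) / sum(dpois(vals, lam)) - mean
  lam <- uniroot(f, c(1e-8, max * 2))$root
  p <- dpois(vals, lam)
  list(values = vals, probs = p / sum(p))
}

group_stratum <- function(g) {
  inc <- c(CoLwInYg = 1, CoLwInMiAg = 1, CoLwInOld = 1, LwInYg = 2,
           LwInMiAg = 2, LwInOld = 2, MeInYg = 3, MeInMiAgOld = 3)[g]
  age <- c(CoLwInYg = 1, CoLwInMiAg = 2, CoLwInOld = 3, LwInYg = 1,
           LwInMiAg = 2, LwInOld = 3, MeInYg = 1, MeInMiAgOld = 2)[g]
  list(income = inc, age = age)
}

#' Emulate the stratified survey sample
#'
#' Generates the 188 synthetic respondents with the exact per-group sizes of
#' the survey, attributes consistent with the calibration targets, and
#' per-respondent reported store pools over the synthetic city (zone mix
#' drawn from the group's target zone shares, with every zone guaranteed at
#' least one report per group).
#'
#' @param targets a [calibration_targets()] list.
#' @param env a `fabm_env` bundle (for store ids and zones).
#' @param seed integer seed.
#' @return data.frame of 188 respondents: `respondent_id`, `group`, `age`,
#'   `income`, `has_car`, `persons`, `trips_per_week`, `stores`
#'   (semicolon-separated reported store ids).
#' @export
emulate_survey_sample <- function(targets = calibration_targets(), env,
                                  seed = 1) {
  gn <- agent_group_names()
  sizes <- group_sample_sizes()
  stores_by_zone <- split(env$stores$id, env$stores$zone)
  inc_lo <- c(2000, 20000, 50000); inc_hi <- c(19999, 49999, 120000)
  age_lo <- c(18, 45, 65); age_hi <- c(44, 64, 90)

  with_local_seed(seed, {
    rows <- lapply(gn, function(g) {
      n <- sizes[[g]]
      st <- group_stratum(g)
      pmf <- trip_pmf(targets$trip_means[[g]], targets$trip_max)
      # ages: the merged medium-income group spans 45+
      ahi <- if (g == "MeInMiAgOld") 90 else age_hi[st$age]
      zs <- targets$zone_shares[g, ]
      pools <- vapply(seq_len(n), function(i) {
        k <- sample(4:8, 1)
        zz <- zone_levels()[sample_idx(3L, k, as.numeric(zs))]
        if (i == 1L) zz <- c(zone_levels(), zz)  # guarantee zone coverage
        picks <- vapply(zz, function(z) {
          sz <- stores_by_zone[[z]]
          sz[sample_idx(length(sz), 1L)]
        }, "")
        paste(picks, collapse = ";")
      }, "")
      data.frame(
        respondent_id = sprintf("%s_%02d", g, seq_len(n)),
        group = g,
        age = round(runif(n, age_lo[st$age], ahi)),
        income = round(runif(n, inc_lo[st$income], inc_hi[st$income])),
        has_car = runif(n) < (1 - targets$no_car[[g]]),
        persons = 1L + rpois(n, targets$household_size_mean[[g]] - 1),
        trips_per_week = pmf$values[sample_idx(length(pmf$values), n, pmf$probs)],
        stores = pools
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# ---- analytic choice law & zone calibration ---------------------------------

# Expected store-selection probabilities for one group under the full
# decision law, given pool weights w. D is the houses x pool distance matrix,
# p_h the expected house distribution of the group's agents.
# Returns the pool-length probability vector.
expected_store_probs <- function(w, pool_types, theta, tau, K_list, class_probs, p_h) {
  P <- length(w)
  subsets <- c(list(seq_len(P)),
               lapply(names(theta), function(t) which(pool_types == t)))
  sub_prob <- c(1 - tau, tau * as.numeric(theta))
  pi <- numeric(P)
  for (cl in seq_along(K_list)) {
    pc <- class_probs[cl]
    if (pc <= 0) next
    K <- K_list[[cl]]
    for (s in seq_along(subsets)) {
      if (sub_prob[s] <= 0) next
      S <- subsets[[s]]
      if (!length(S)) S <- seq_len(P)   # empty type restriction: full pool
      W <- K[, S, drop = FALSE] * rep(w[S], each = nrow(K))
      WN <- W / rowSums(W)
      pi[S] <- pi[S] + pc * sub_prob[s] * as.numeric(p_h %*% WN)
    }
  }
  pi
}

# decay-class probabilities (no decay / walk decay / bike decay) implied by
# car ownership, decision order, and the carless mode distribution
decay_class_probs <- function(car_prob, mu, nu) {
  p_nd <- car_prob + (1 - car_prob) * (mu * (nu[["bus"]] + nu[["taxi"]]) + (1 - mu))
  c(none = p_nd,
    walk = (1 - car_prob) * mu * nu[["walk"]],
    bike = (1 - car_prob) * mu * nu[["bike"]])
}

# Calibrate pool weights by zone so the expected zone-visit shares equal the
# targets: iterative proportional scaling of the three zone blocks under the
# full (nonlinear) decision law.
calibrate_zone_weights <- function(w, pool_zones, pool_types, theta, tau,
                                   K_list, class_probs, p_h, target,
                                   tol = 1e-9, max_iter = 400) {
  zl <- zone_levels()
  target <- target[zl]
  present <- tapply(w, factor(pool_zones, levels = zl), sum, default = 0)
  if (any(target > 0 & present == 0))
    stop_fmt("calibration error: positive zone target but no pool store in zone %s",
             paste(zl[target > 0 & present == 0], collapse = ", "))
  zi <- match(pool_zones, zl)
  for (it in seq_len(max_iter)) {
    pi <- expected_store_probs(w, pool_types, theta, tau, K_list, class_probs, p_h)
    share <- tapply(pi, factor(pool_zones, levels = zl), sum, default = 0)
    err <- max(abs(share - target), na.rm = TRUE)
    if (err < tol) return(list(weight = w, shares = share, iterations = it))
    fac <- ifelse(share > 0, target / share, 1)
    w <- normalize_weights(w * fac[zi])
  }
  stop_fmt("calibration error: zone calibration did not converge (err %.2e)", err)
}

# Distance-bin distribution of carless store-first trips (no decay), used to
# scale the non-motorized mode table.
sf_distance_bins <- function(w, pool_types, theta, tau, D, p_h, bins) {
  P <- length(w)
  subsets <- c(list(seq_len(P)),
               lapply(names(theta), function(t) which(pool_types == t)))
  sub_prob <- c(1 - tau, tau * as.numeric(theta))
  nb <- length(bins) - 1L
  binmat <- matrix(pmin(pmax(findInterval(D, bins), 1L), nb), nrow = nrow(D))
  q <- numeric(nb)
  for (s in seq_along(subsets)) {
    if (sub_prob[s] <= 0) next
    S <- subsets[[s]]
    if (!length(S)) S <- seq_len(P)
    W <- D[, S, drop = FALSE]; W[] <- rep(w[S], each = nrow(D))
    WN <- W / rowSums(W)
    J <- WN * p_h                       # joint (house, store) probabilities
    bm <- binmat[, S, drop = FALSE]
    q <- q + sub_prob[s] * as.numeric(tapply(as.numeric(J),
                                             factor(as.numeric(bm), levels = seq_len(nb)),
                                             sum, default = 0))
  }
  q
}

# scale the logistic non-motorized curve so the expected store-first
# non-motorized share equals the target x
scale_nm_curve <- function(q, bins, cutoff, d0, scale, x) {
  mids <- (head(bins, -1) + bins[-1]) / 2
  mids[is.infinite(mids)] <- bins[length(bins) - 1] + 2
  base <- plogis((d0 - mids) / scale)
  base[head(bins, -1) >= cutoff] <- 0
  reach <- sum(q[base > 0])
  if (reach < x)
    stop_fmt("calibration error: non-motorized target %.2f unreachable (max %.2f under the distance cutoff)",
             x, reach)
  f <- function(cc) sum(q * pmin(1, cc * base)) - x
  cc <- uniroot(f, c(0, 1e6), tol = 1e-12)$root
  pmin(1, cc * base)
}

#' Build calibrated agent-group fixtures
#'
#' Derives each group's store pool from the synthetic respondents' reports,
#' then calibrates the pool weights by zone (iterative proportional scaling
#' under the full decision law, averaging over the group's expected house
#' distribution and car ownership) so the expected zone-visit shares equal
#' the calibration targets, and scales the distance-binned non-motorized
#' mode table so the expected non-motorized share among carless trips equals
#' its target.
#'
#' @param respondents output of [emulate_survey_sample()].
#' @param env a `fabm_env` bundle.
#' @param od the OD matrix over `env`.
#' @param targets a [calibration_targets()] list.
#' @param tracts tract profiles from [synthesize_tracts()]; used to weight
#'   houses by each group's expected placement. `NULL` weights houses
#'   uniformly.
#' @param cfg a [simulation_config()] supplying the decay scales and bins.
#' @return named list of [agent_group()] objects.
#' @export
build_group_fixtures <- function(respondents, env, od,
                                 targets = calibration_targets(),
                                 tracts = NULL,
                                 cfg = simulation_config()) {
  gn <- agent_group_names()
  store_type_of <- setNames(env$stores$store_type, env$stores$id)
  store_zone_of <- setNames(env$stores$zone, env$stores$id)
  hrows <- match(env$houses$id, rownames(od))

  # expected house weights per group
  house_w <- function(g) {
    if (is.null(tracts)) return(rep(1 / nrow(env$houses), nrow(env$houses)))
    n_houses <- table(env$houses$tract_id)
    tm <- match(env$houses$tract_id, tracts$tract_id)
    wt <- tracts$household_count[tm] * tracts[[g]][tm] /
      as.numeric(n_houses[env$houses$tract_id])
    wt / sum(wt)
  }

  out <- lapply(gn, function(g) {
    rr <- respondents[respondents$group == g, ]
    reports <- unlist(strsplit(rr$stores, ";", fixed = TRUE))
    tab <- table(reports)
    pool <- data.frame(store_id = names(tab), weight = as.numeric(tab))
    pool$weight <- normalize_weights(pool$weight)
    pool_types <- store_type_of[pool$store_id]
    pool_zones <- store_zone_of[pool$store_id]

    tilt <- targets$type_tilt
    type_mass <- tapply(pool$weight, factor(pool_types, levels = names(tilt)),
                        sum, default = 0)
    theta <- normalize_weights(type_mass * tilt)
    theta <- theta[theta > 0]

    x <- targets$nm_conditional[[g]]
    nu <- c(bus = targets$bus_frac_mot * (1 - x),
            taxi = (1 - targets$bus_frac_mot) * (1 - x),
            walk = targets$walk_frac_nm * x,
            bike = (1 - targets$walk_frac_nm) * x)

    D <- od[hrows, pool$store_id, drop = FALSE]
    p_h <- house_w(g)
    car <- 1 - targets$no_car[[g]]
    mu <- targets$mode_first_prob
    tau <- targets$type_consideration_prob
    K_list <- list(none = matrix(1, nrow(D), ncol(D)),
                   walk = exp(-D / cfg$lambda_walk),
                   bike = exp(-D / cfg$lambda_bike))
    cps <- decay_class_probs(car, mu, nu)
    cal <- calibrate_zone_weights(pool$weight, pool_zones, pool_types, theta,
                                  tau, K_list, cps, p_h,
                                  targets$zone_shares[g, ])
    pool$weight <- cal$weight

    bins <- cfg$distance_bins
    q <- sf_distance_bins(pool$weight, pool_types, theta, tau, D, p_h, bins)
    nm_by_bin <- scale_nm_curve(q, bins, targets$nm_cutoff[[g]],
                                targets$nm_curve[["d0"]],
                                targets$nm_curve[["scale"]], x)

    pmf <- trip_pmf(targets$trip_means[[g]], targets$trip_max)
    st <- group_stratum(g)
    agent_group(
      name = g,
      income_stratum = income_strata()[st$income],
      age_stratum = if (g == "MeInMiAgOld") "45+" else age_strata()[st$age],
      sample_size = group_sample_sizes()[[g]],
      car_ownership_prob = car,
      trip_count_values = pmf$values, trip_count_probs = pmf$probs,
      type_consideration_prob = tau,
      mode_first_prob = mu,
      store_type_weights = theta,
      store_pool = pool,
      noncar_mode_probs = nu,
      distance_bins = bins,
      nonmotorized_by_bin = nm_by_bin,
      walk_frac_nm = targets$walk_frac_nm,
      bus_frac_mot = targets$bus_frac_mot,
      household_size_mean = targets$household_size_mean[[g]]
    )
  })
  setNames(out, gn)
}

# ---- packaged bundle --------------------------------------------------------

#' Build the packaged synthetic study fixtures
#'
#' Generates the synthetic city, tract profiles, the 188-respondent sample,
#' the OD matrix, and the calibrated group fixtures, all from one seed. This
#' bundle is the packaged study condition every analysis and test runs on.
#'
#' @param seed integer seed for the fixture generators (the packaged data
#'   use the default).
#' @param recipe a [city_recipe()].
#' @param targets a [calibration_targets()] list.
#' @param cfg a [simulation_config()].
#' @param dir directory for the environment GeoJSON files.
#' @return list of class `fixture_bundle`: `env`, `od`, `tracts`,
#'   `respondents`, `groups`, `targets`, `recipe`.
#' @export
fixture_bundle <- function(seed = 2008, recipe = city_recipe(),
                           targets = calibration_targets(),
                           cfg = simulation_config(),
                           dir = tempfile("city")) {
  env <- generate_synthetic_city(recipe, seed = seed, dir = dir)
  od <- build_od_matrix(env$network, env$houses, env$stores)
  tracts <- synthesize_tracts(targets, seed = seed + 1L)
  respondents <- emulate_survey_sample(targets, env, seed = seed + 2L)
  groups <- build_group_fixtures(respondents, env, od, targets,
                                 tracts = tracts, cfg = cfg)
  structure(list(env = env, od = od, tracts = tracts,
                 respondents = respondents, groups = groups,
                 targets = targets, recipe = recipe),
            class = "fixture_bundle")
}

#' Write all fixture files to a directory
#'
#' Environment GeoJSONs are written by [generate_synthetic_city()]; this adds
#' `respondents.csv`, `tracts.csv`, `groups.json`, `od.csv` and
#' `calibration_targets.yaml`.
#'
#' @param bundle a [fixture_bundle()].
#' @param dir output directory.
#' @export
write_fixture_files <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(bundle$respondents, file.path(dir, "respondents.csv"), row.names = FALSE)
  write.csv(bundle$tracts, file.path(dir, "tracts.csv"), row.names = FALSE)
  write_groups_json(bundle$groups, file.path(dir, "groups.json"))
  write_od_csv(bundle$od, file.path(dir, "od.csv"))
  write_targets_yaml(bundle$targets, file.path(dir, "calibration_targets.yaml"))
  invisible(dir)
}
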