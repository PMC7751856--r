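# Agent groups (income x age strata), population upscaling, agent placement.

#' Agent group names
#'
#' The eight income-by-age strata. The two highest-income older cells are
#' merged into a single group (`MeInMiAgOld`).
#' @return character vector of the eight group names.
#' @export
agent_group_names <- function() {
  c("CoLwInYg", "CoLwInMiAg", "CoLwInOld",
    "LwInYg", "LwInMiAg", "LwInOld",
    "MeInYg", "MeInMiAgOld")
}

#' Survey sample sizes per group
#'
#' Respondent counts of the stratified survey sample (total N = 188).
#' @return named integer vector.
#' @export
group_sample_sizes <- function() {
  setNames(c(33L, 43L, 15L, 23L, 28L, 11L, 13L, 22L), agent_group_names())
}

income_strata <- function() c("<20k", "20k-49.99k", ">=50k")
age_strata <- function() c("18-44", "45-64", "65+")

#' Assign a respondent to an income-by-age agent group
#'
#' Income rows: below $20,000; $20,000 to $49,999; $50,000 and above. Age
#' columns: 18-44, 45-64, 65 and over. The two highest-income cells for ages
#' 45+ are merged.
#'
#' @param age age in years (>= 18).
#' @param income annual household income in USD.
#' @return character vector of group names.
#' @export
stratify_respondent <- function(age, income) {
  if (any(age < 18)) stop_fmt("domain error: respondents must be 18 years or older")
  if (any(income < 0)) stop_fmt("domain error: income must be nonnegative")
  inc <- findInterval(income, c(0, 20000, 50000))  # 1, 2, 3
  ag <- findInterval(age, c(18, 45, 65))           # 1, 2, 3
  out <- character(length(age))
  grid <- matrix(c("CoLwInYg", "CoLwInMiAg", "CoLwInOld",
                   "LwInYg", "LwInMiAg", "LwInOld",
                   "MeInYg", "MeInMiAgOld", "MeInMiAgOld"),
                 nrow = 3, byrow = TRUE)
  grid[cbind(inc, ag)]
}

#' Upscale the survey sample to the tract household population
#'
#' Sample-based Monte Carlo proportional upscaling: for each tract, draw its
#' household count of group labels from the tract's group mix (multinomial),
#' then for each label resample one respondent record from that group with
#' replacement, copying its attributes.
#'
#' @param respondents data.frame with at least `respondent_id` and `group`;
#'   all other columns are copied onto the resampled agents.
#' @param tracts data.frame with `tract_id`, `household_count` and one column
#'   per group name holding the tract's group mix (each row sums to 1).
#' @param seed integer seed; the result is fully reproducible.
#' @return data.frame of agents: `agent_id`, `group`, `tract_id`,
#'   `respondent_id` and the copied respondent attribute columns.
#' @export
upscale_population <- function(respondents, tracts, seed) {
  gn <- agent_group_names()
  if (!all(gn %in% names(tracts)))
    stop_fmt("tracts table lacks group-mix columns: %s",
             paste(setdiff(gn, names(tracts)), collapse = ", "))
  if (any(tracts$household_count <= 0))
    stop_fmt("tract household counts must be positive")
  counts_by_group <- table(factor(respondents$group, levels = gn))
  mix <- as.matrix(tracts[, gn])
  if (any(mix[, counts_by_group == 0] > 0))
    stop_fmt("configuration error: tract group mix puts mass on a group with no respondents")
  by_group <- split(seq_len(nrow(respondents)), factor(respondents$group, levels = gn))

  with_local_seed(seed, {
    picked <- integer(0); tract_of <- character(0)
    for (t in seq_len(nrow(tracts))) {
      n_t <- tracts$household_count[t]
      draw <- as.integer(rmultinom(1, n_t, prob = mix[t, ]))
      for (g in seq_along(gn)) {
        if (draw[g] == 0) next
        rows <- by_group[[g]]
        picked <- c(picked, rows[sample_idx(length(rows), draw[g])])
        tract_of <- c(tract_of, rep(as.character(tracts$tract_id[t]), draw[g]))
      }
    }
    agents <- respondents[picked, , drop = FALSE]
    rownames(agents) <- NULL
    agents$tract_id <- tract_of
    agents$agent_id <- seq_len(nrow(agents))
    agents[, c("agent_id", "group", "tract_id",
               setdiff(names(agents), c("agent_id", "group", "tract_id")))]
  })
}

#' Place agents in houses and draw household attributes
#'
#' Each agent is assigned uniformly at random to a house in its tract
#' (multiple agents per house allowed). Car access is Bernoulli with the
#' group's car-ownership probability; household size is 1 plus a Poisson draw
#' matched to the group's mean household size.
#'
#' @param agents output of [upscale_population()].
#' @param houses data.frame with `id` and `tract_id`.
#' @param groups named list of [agent_group()] objects.
#' @param seed integer seed.
#' @return `agents` with columns `house_id`, `has_car`, `persons` added.
#' @export
instantiate_agents <- function(agents, houses, groups, seed) {
  houses_by_tract <- split(as.character(houses$id), as.character(houses$tract_id))
  need <- unique(agents$tract_id)
  missing <- setdiff(need, names(houses_by_tract))
  if (length(missing))
    stop_fmt("placement error: tract(s) with agents but no houses: %s",
             paste(missing, collapse = ", "))
  with_local_seed(seed, {
    house_id <- character(nrow(agents))
    for (t in need) {
      idx <- which(agents$tract_id == t)
      hh <- houses_by_tract[[t]]
      house_id[idx] <- hh[sample_idx(length(hh), length(idx))]
    }
    p_car <- vapply(groups, function(g) g$car_ownership_prob, numeric(1))
    mu <- vapply(groups, function(g) g$household_size_mean, numeric(1))
    gi <- match(agents$group, names(groups))
    agents$house_id <- house_id
    agents$has_car <- rbinom(nrow(agents), 1, p_car[gi]) == 1
    agents$persons <- 1L + rpois(nrow(agents), pmax(mu[gi] - 1, 0))
    agents
  })
}
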