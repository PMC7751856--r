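# Variance-based global sensitivity analysis: Saltelli cross-sampling design,
# Jansen estimators for first- and total-order Sobol indices with bootstrap
# confidence intervals, and a driver that evaluates the shopping simulator
# over its uncertain decision parameters.

#' Define a sensitivity-analysis problem
#'
#' @param params named list of length-2 numeric ranges, e.g.
#'   `list(mode_first_prob = c(0, 1))`.
#' @return object of class `sa_problem`.
#' @export
sa_problem <- function(params) {
  if (!length(params) || is.null(names(params)))
    stop_fmt("params must be a named list of ranges")
  for (nm in names(params)) {
    r <- params[[nm]]
    if (length(r) != 2 || r[2] <= r[1])
      stop_fmt("parameter %s: range must be c(lo, hi) with hi > lo", nm)
  }
  structure(list(params = params, k = length(params)), class = "sa_problem")
}

#' Saltelli cross-sampling design
#'
#' Generates the `N * (2k + 2)` parameter vectors of the Saltelli scheme: the
#' two base matrices A and B (a scrambled Sobol' quasi-random sample in 2k
#' dimensions, see [sobol_points()]), plus the k `AB_i` matrices (A with
#' column i from B) and the k `BA_i` matrices. Deterministic given the seed.
#'
#' @param problem an [sa_problem()].
#' @param N base sample size (a power of 2 is recommended).
#' @param seed integer seed.
#' @return numeric matrix with `N * (2k + 2)` rows, one column per parameter,
#'   with a `layout` attribute naming each row's block.
#' @export
saltelli_sample <- function(problem, N, seed = 1) {
  if (N < 1 || N != round(N)) stop_fmt("N must be a positive integer")
  k <- problem$k
  u <- sobol_points(as.integer(N), 2L * k, seed = seed)
  A <- u[, seq_len(k), drop = FALSE]
  B <- u[, k + seq_len(k), drop = FALSE]
  blocks <- vector("list", 2L * k + 2L)
  labels <- character(2L * k + 2L)
  blocks[[1]] <- A; labels[1] <- "A"
  for (i in seq_len(k)) {
    ABi <- A; ABi[, i] <- B[, i]
    blocks[[1L + i]] <- ABi; labels[1L + i] <- paste0("AB", i)
    BAi <- B; BAi[, i] <- A[, i]
    blocks[[1L + k + i]] <- BAi; labels[1L + k + i] <- paste0("BA", i)
  }
  blocks[[2L * k + 2L]] <- B; labels[2L * k + 2L] <- "B"
  m <- do.call(rbind, blocks)
  # scale to ranges
  for (j in seq_len(k)) {
    r <- problem$params[[j]]
    m[, j] <- r[1] + m[, j] * (r[2] - r[1])
  }
  colnames(m) <- names(problem$params)
  attr(m, "layout") <- rep(labels, each = as.integer(N))
  attr(m, "N") <- as.integer(N)
  m
}

#' Sobol sensitivity indices (Jansen estimators)
#'
#' First-order (S1) and total-order (ST) indices from model outputs aligned
#' with a [saltelli_sample()] design, with percentile bootstrap confidence
#' intervals. For a constant output all indices are zero.
#'
#' @param y numeric vector of model outputs, one per design row.
#' @param problem the [sa_problem()] used for the design.
#' @param N the base sample size used for the design.
#' @param n_boot bootstrap replicates for the confidence intervals.
#' @param conf confidence level.
#' @return data.frame of class `sa_result`: `parameter`, `S1`, `S1_lo`,
#'   `S1_hi`, `ST`, `ST_lo`, `ST_hi`.
#' @export
sobol_indices <- function(y, problem, N, n_boot = 200, conf = 0.95) {
  k <- problem$k
  if (length(y) != N * (2 * k + 2))
    stop_fmt("alignment error: expected %d outputs (N(2k+2)), got %d",
             N * (2 * k + 2), length(y))
  if (any(!is.finite(y))) stop_fmt("outputs must be finite")
  idx_block <- function(b) (b - 1L) * N + seq_len(N)
  yA <- y[idx_block(1L)]
  yB <- y[idx_block(2L * k + 2L)]
  yAB <- lapply(seq_len(k), function(i) y[idx_block(1L + i)])
  yBA <- lapply(seq_len(k), function(i) y[idx_block(1L + k + i)])

  est <- function(rows) {
    a <- yA[rows]; b <- yB[rows]
    V <- var(c(a, b))
    if (V <= .Machine$double.eps * max(1, mean(c(a, b))^2))
      return(list(S1 = rep(0, k), ST = rep(0, k)))
    S1 <- numeric(k); ST <- numeric(k)
    for (i in seq_len(k)) {
      abi <- yAB[[i]][rows]; bai <- yBA[[i]][rows]
      # Jansen, averaged over the symmetric AB/BA blocks
      S1[i] <- 1 - (mean((b - abi)^2) + mean((a - bai)^2)) / (4 * V)
      ST[i] <- (mean((a - abi)^2) + mean((b - bai)^2)) / (4 * V)
    }
    list(S1 = S1, ST = ST)
  }
  point <- est(seq_len(N))
  boots1 <- matrix(NA_real_, n_boot, k); bootst <- matrix(NA_real_, n_boot, k)
  for (r in seq_len(n_boot)) {
    rows <- sample.int(N, N, replace = TRUE)
    e <- est(rows)
    boots1[r, ] <- e$S1; bootst[r, ] <- e$ST
  }
  alpha <- (1 - conf) / 2
  out <- data.frame(
    parameter = names(problem$params),
    S1 = point$S1,
    S1_lo = apply(boots1, 2, quantile, alpha),
    S1_hi = apply(boots1, 2, quantile, 1 - alpha),
    ST = point$ST,
    ST_lo = apply(bootst, 2, quantile, alpha),
    ST_hi = apply(bootst, 2, quantile, 1 - alpha)
  )
  class(out) <- c("sa_result", class(out))
  out
}

#' Write sensitivity results to CSV
#' @param res an `sa_result`.
#' @param path file path.
#' @export
write_sa_csv <- function(res, path) {
  write.csv(as.data.frame(res), path, row.names = FALSE)
  invisible(path)
}

#' Sensitivity analysis of the shopping simulator
#'
#' Evaluates the full simulation at every design point of a Saltelli sample
#' over the uncertain decision parameters (any of `mode_first_prob`,
#' `type_consideration_prob`, `lambda_walk`, `lambda_bike`; parameters with
#' other names are ignored by the model and get indices near zero) and
#' computes Sobol indices of the median trip distance. Replicates use common
#' random numbers: the same simulation seeds are reused at every design
#' point, so parameter-free variation cancels.
#'
#' @param problem an [sa_problem()].
#' @param bundle simulation inputs: list with `agents`, `groups`, `env`, `od`
#'   (e.g. a subset of a [fixture_bundle()]).
#' @param N base sample size.
#' @param weeks simulated weeks per evaluation (reduced-scale default).
#' @param n_agents number of agents used per evaluation (head of the agent
#'   table after a seeded shuffle); `Inf` for all.
#' @param replicates stochastic replicates averaged per design point.
#' @param seed integer seed controlling design, agent subsampling and the
#'   common random numbers.
#' @param by passed to [median_trip_distance()] (`"population"` pools trips).
#' @return list of class `model_sa`: `result` (an `sa_result`), `design`,
#'   `y`, and the evaluation settings.
#' @export
run_model_sa <- function(problem, bundle, N = 64, weeks = 20, n_agents = 1000,
                         replicates = 1, seed = 1, by = "population") {
  design <- saltelli_sample(problem, N, seed = seed)
  agents <- bundle$agents
  if (is.finite(n_agents) && n_agents < nrow(agents)) {
    pick <- with_local_seed(seed + 1L, sample.int(nrow(agents), n_agents))
    agents <- agents[pick, , drop = FALSE]
  }
  known <- c("mode_first_prob", "type_consideration_prob",
             "lambda_walk", "lambda_bike")
  rep_seeds <- vapply(seq_len(replicates),
                      function(r) agent_stream_seed(seed, 7919L + r), integer(1))
  y <- numeric(nrow(design))
  for (r in seq_len(nrow(design))) {
    pars <- as.list(design[r, ])
    cfg <- simulation_config(
      weeks = weeks, seed = rep_seeds[1],
      lambda_walk = pars$lambda_walk %||% 3,
      lambda_bike = pars$lambda_bike %||% 6,
      mode_first_prob = pars$mode_first_prob,
      type_consideration_prob = pars$type_consideration_prob
    )
    vals <- numeric(replicates)
    for (rr in seq_len(replicates)) {
      cfg$seed <- rep_seeds[rr]
      log <- run_simulation(agents, bundle$groups, bundle$env, bundle$od, cfg)
      vals[rr] <- unname(median_trip_distance(log, by = by)[1])
    }
    y[r] <- mean(vals)
  }
  res <- sobol_indices(y, problem, N)
  structure(list(result = res, design = design, y = y,
                 N = N, weeks = weeks, n_agents = nrow(agents),
                 replicates = replicates, seed = seed),
            class = "model_sa")
}

#' @export
print.model_sa <- function(x, ...) {
  cat(sprintf("<model_sa: N=%d, %d evaluations, %d agents x %d weeks>\n",
              x$N, length(x$y), x$n_agents, x$weeks))
  print(x$result)
  invisible(x)
}
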