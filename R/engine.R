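#' Learning parameters of the imitation dynamics
#'
#' Two scalars govern interorganizational learning on the network: the
#' information-cost parameter `lam` (the temperature of the Boltzmann
#' learning-object selection) and the noise parameter `xi` (the
#' temperature of the Fermi strategy-adoption rule). `alpha` is a
#' per-subject adjusting weight added to a neighbor's gain before the
#' Boltzmann weighting; the default 0 leaves the propensity for high gains
#' unmodified.
#'
#' @param lam Information cost, `> 0`. Small values make subjects pick the
#'   highest-earning neighbor almost deterministically.
#' @param xi Noise, `> 0`. As `xi -> 0` a subject adopts the selected
#'   neighbor's strategy only when the neighbor earned strictly more; as
#'   `xi -> Inf` adoption becomes a coin flip.
#' @param alpha Adjusting weight, a single number applied to every subject
#'   or a vector named by node id.
#' @return An object of class `learning_params`.
#' @export
learning_params <- function(lam = 1, xi = 1, alpha = 0) {
  stopifnot(is.numeric(lam), length(lam) == 1L, is.finite(lam), lam > 0,
            is.numeric(xi), length(xi) == 1L, is.finite(xi), xi > 0,
            is.numeric(alpha), all(is.finite(alpha)))
  structure(list(lam = as.numeric(lam), xi = as.numeric(xi), alpha = alpha),
            class = "learning_params")
}

#' Fermi strategy-adoption probability
#'
#' Probability that a subject with gain `u_i` adopts the strategy of a
#' selected subject with gain `u_j`:
#' \deqn{\omega = 1 / (1 + \exp((u_i - u_j)/\xi)).}
#' At equal gains the probability is 1/2; as `xi -> 0` it tends to the
#' step function (adopt iff `u_i < u_j`).
#'
#' @param u_i,u_j Gains of the focal and selected subject (vectorized).
#' @param xi Noise parameter, `> 0`.
#' @return Adoption probability in (0, 1).
#' @export
adoption_probability <- function(u_i, u_j, xi) {
  stopifnot(is.numeric(xi), xi > 0)
  1 / (1 + exp((u_i - u_j) / xi))
}

# --- internal engine context ------------------------------------------------
# Precomputes everything the per-round loops need: integer node indexing in
# sorted-id order, the cross-type edge list (only those edges carry game
# payoff), and adjacency lists (all edges carry learning connectivity).
build_engine <- function(net) {
  ids <- igraph::V(net)$name
  roles <- node_roles(net)
  n <- length(ids)
  el <- igraph::as_edgelist(net, names = FALSE)
  is_srs <- unname(roles == "SRS")
  cross <- el[is_srs[el[, 1]] != is_srs[el[, 2]], , drop = FALSE]
  # orient cross edges as (srs index, grs index)
  if (nrow(cross)) {
    flip <- !is_srs[cross[, 1]]
    cross[flip, ] <- cross[flip, c(2, 1)]
  }
  nbrs <- lapply(seq_len(n), function(i)
    as.integer(igraph::neighbors(net, i)))
  list(ids = ids, n = n, roles = unname(roles), is_srs = is_srs,
       srs_of_cross = cross[, 1], grs_of_cross = cross[, 2], nbrs = nbrs)
}

expand_alpha <- function(alpha, ids) {
  if (length(alpha) == 1L) return(rep(as.numeric(alpha), length(ids)))
  if (!is.null(names(alpha)) && all(ids %in% names(alpha)))
    return(as.numeric(alpha[ids]))
  if (length(alpha) == length(ids)) return(as.numeric(alpha))
  stop("alpha must be a scalar, a vector named by node id, ",
       "or one value per node", call. = FALSE)
}

#' Initialize node strategies at given positive proportions
#'
#' Assigns exactly `round(n_srs * m0)` SRSs and `round(n_grs * r0)` GRSs
#' the positive strategy, chosen uniformly at random within each role
#' (exact-count assignment rather than independent Bernoulli draws, which
#' removes binomial noise in the initial condition). Uses the current RNG
#' state; seed beforehand for reproducibility.
#'
#' @param net A [typed_network()].
#' @param m0 Initial positive proportion among SRSs, in \[0, 1\].
#' @param r0 Initial positive proportion among GRSs, in \[0, 1\].
#' @return Named character vector of `"positive"`/`"negative"` per node.
#' @export
initialize_strategies <- function(net, m0, r0) {
  check_state(m0, r0)   # same unit-interval validation as the mean field
  roles <- node_roles(net)
  strat <- stats::setNames(rep("negative", length(roles)), names(roles))
  for (role in c("SRS", "GRS")) {
    members <- names(roles)[roles == role]
    k <- round(length(members) * if (role == "SRS") m0 else r0)
    if (k > 0)
      strat[sample(members, k)] <- "positive"
  }
  strat
}

#' Per-round accumulated gains
#'
#' Plays every edge of the network once. Only cross-type (GRS--SRS) edges
#' carry game payoff, evaluated from the two-role payoff matrix via
#' [pair_payoff()]; same-type edges contribute zero gain but still count
#' as learning channels in [evolve_step()]. A node's gain `u_i` is the sum
#' over its cross-type neighbor games, recomputed fresh each round
#' (isolated nodes and nodes with only same-type ties get 0).
#'
#' @param net A [typed_network()].
#' @param strategies Named strategy vector as from [initialize_strategies()].
#' @param params A [game_params()] object.
#' @return Named numeric vector of per-node gains.
#' @export
play_round <- function(net, strategies, params) {
  eng <- build_engine(net)
  u <- play_round_idx(eng, strat_to_int(strategies, eng), params)
  stats::setNames(u, eng$ids)
}

strat_to_int <- function(strategies, eng) {
  if (is.null(names(strategies)) || !all(eng$ids %in% names(strategies)))
    stop("strategies must be a vector named by node id covering every node",
         call. = FALSE)
  s <- strategies[eng$ids]
  bad <- !(s %in% .strategies)
  if (any(bad))
    stop("invalid strategy label(s): ",
         paste(unique(s[bad]), collapse = ", "), call. = FALSE)
  as.integer(s == "positive")
}

# vectorized payoff accumulation over cross edges; strat is 0/1 by node index
play_round_idx <- function(eng, strat, params) {
  pm <- payoff_matrices(params)
  u <- numeric(eng$n)
  if (length(eng$srs_of_cross)) {
    si <- strat[eng$srs_of_cross] + 1L      # 1 = negative, 2 = positive
    gi <- strat[eng$grs_of_cross] + 1L
    cell <- cbind(si, gi)
    u_srs <- pm$srs[cell]
    u_grs <- pm$grs[cell]
    u <- u +
      as.numeric(rowsum_by(u_srs, eng$srs_of_cross, eng$n)) +
      as.numeric(rowsum_by(u_grs, eng$grs_of_cross, eng$n))
  }
  u
}

rowsum_by <- function(x, index, n) {
  out <- numeric(n)
  agg <- rowsum(x, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Boltzmann selection of a learning object
#'
#' Samples which neighbor a focal subject will observe: neighbor `j` is
#' chosen with probability proportional to `exp((u_j + alpha_j) / lam)`
#' over the focal subject's neighbor set (self excluded). Computed with a
#' max-shift so large gains cannot overflow; probabilities are unchanged
#' by the shift. Uses the current RNG state.
#'
#' @param i Node id of the focal subject.
#' @param net A [typed_network()].
#' @param payoffs Named gain vector from [play_round()].
#' @param learning A [learning_params()] object.
#' @return The selected neighbor's id, or `NA` for an isolated node.
#' @export
select_learning_target <- function(i, net, payoffs, learning = learning_params()) {
  stopifnot(inherits(learning, "learning_params"))
  eng <- build_engine(net)
  idx <- match(i, eng$ids)
  if (is.na(idx)) stop("unknown node id: ", i, call. = FALSE)
  alpha <- expand_alpha(learning$alpha, eng$ids)
  nb <- eng$nbrs[[idx]]
  if (!length(nb)) return(NA_character_)
  u <- payoffs[eng$ids][nb]
  j <- sample_boltzmann(nb, u + alpha[nb], learning$lam)
  eng$ids[j]
}

sample_boltzmann <- function(candidates, scores, lam) {
  w <- exp((scores - max(scores)) / lam)
  candidates[sample.int(length(candidates), 1L, prob = w)]
}

#' One synchronous imitation update
#'
#' Given the current strategies and the gains of the completed round,
#' every node independently (i) selects a learning object among its
#' neighbors by the Boltzmann rule and (ii) adopts that neighbor's
#' current-round strategy with the Fermi probability
#' [adoption_probability()], otherwise keeping its own. All adoptions are
#' applied simultaneously. Strategy labels transfer across roles by
#' default — a GRS may copy "positive"/"negative" from an SRS neighbor and
#' vice versa; set `cross_role_learning = FALSE` to restrict the candidate
#' set to same-role neighbors.
#'
#' @inheritParams play_round
#' @param payoffs Named gain vector from [play_round()] for `strategies`.
#' @param learning A [learning_params()] object.
#' @param cross_role_learning Allow imitation across roles (default TRUE).
#' @return The updated named strategy vector.
#' @export
evolve_step <- function(net, strategies, payoffs, learning = learning_params(),
                        cross_role_learning = TRUE) {
  eng <- build_engine(net)
  strat <- strat_to_int(strategies, eng)
  u <- payoffs[eng$ids]
  alpha <- expand_alpha(learning$alpha, eng$ids)
  new <- evolve_step_idx(eng, strat, u, alpha, learning, cross_role_learning)
  stats::setNames(.strategies[new + 1L], eng$ids)
}

evolve_step_idx <- function(eng, strat, u, alpha, learning,
                            cross_role_learning = TRUE) {
  new <- strat
  for (i in seq_len(eng$n)) {
    nb <- eng$nbrs[[i]]
    if (!cross_role_learning)
      nb <- nb[eng$is_srs[nb] == eng$is_srs[i]]
    if (!length(nb)) next
    j <- sample_boltzmann(nb, u[nb] + alpha[nb], learning$lam)
    w <- stats::runif(1)    # one adoption draw per node, used or not
    if (strat[j] != strat[i] &&
        w < adoption_probability(u[i], u[j], learning$xi))
      new[i] <- strat[j]
  }
  new
}

#' Simulation configuration
#'
#' Bundles everything one networked-game experiment needs: payoff and
#' learning parameters, the network (or a generator configuration from
#' which one network is drawn per run), initial positive proportions,
#' round and replicate counts, and the base seed. Replicate `k` runs with
#' seed `seed + k - 1`, so replicates are independently reproducible.
#'
#' @param params A [game_params()] object.
#' @param learning A [learning_params()] object.
#' @param network A [typed_network()] or a [generator_config()] (the
#'   default generator emulates the 19-GRS/49-SRS case network).
#' @param m0,r0 Initial positive proportions for SRSs and GRSs.
#' @param rounds Maximum number of rounds per replicate.
#' @param reps Number of replicates.
#' @param seed Base integer seed.
#' @param quiescence_window Number of consecutive rounds without any
#'   strategy change after which a replicate stops early (its stable
#'   values are carried forward to `rounds`, which is exact for the gains
#'   since payoffs are deterministic given strategies).
#' @param cross_role_learning Allow imitation across roles (default TRUE).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(params = game_params(),
                              learning = learning_params(),
                              network = generator_config(),
                              m0 = 0.1, r0 = 0.4,
                              rounds = 100, reps = 20, seed = 1L,
                              quiescence_window = 20,
                              cross_role_learning = TRUE) {
  stopifnot(inherits(params, "game_params"),
            inherits(learning, "learning_params"),
            inherits(network, "typed_network") ||
              inherits(network, "generator_config"),
            rounds >= 1, reps >= 1,
            quiescence_window >= 1,
            is.numeric(seed), is.finite(seed),
            is.logical(cross_role_learning))
  check_state(m0, r0)
  structure(list(params = params, learning = learning, network = network,
                 m0 = m0, r0 = r0, rounds = as.integer(rounds),
                 reps = as.integer(reps), seed = as.integer(seed),
                 quiescence_window = as.integer(quiescence_window),
                 cross_role_learning = cross_role_learning),
            class = "simulation_config")
}

#' Run the networked evolutionary game
#'
#' For each replicate: seed the RNG with `seed + replicate - 1`,
#' initialize strategies at the configured proportions, then alternate
#' [play_round()] and [evolve_step()] until `rounds` rounds or until no
#' strategy has changed for `quiescence_window` consecutive rounds. Each
#' round records, *before* the update, the proportion of positive
#' strategies overall and by role (PPS) and the mean per-node gain.
#'
#' @param config A [simulation_config()].
#' @return An object of class `game_trajectory`: a list with
#'   * `trajectory` — data frame `(rep, round, pps_all, pps_grs, pps_srs,
#'     mean_gain)`, `rounds` rows per replicate (round 1 is the initial
#'     state);
#'   * `mean` — the replicate-averaged series by round;
#'   * `absorbed` — per-replicate round at which the quiescence stop
#'     triggered (`NA` if the replicate ran to the horizon);
#'   * `network`, `config`.
#' @examples
#' cfg <- simulation_config(reps = 2, rounds = 40, seed = 7)
#' traj <- run_simulation(cfg)
#' final_pps(traj)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  net <- if (inherits(config$network, "generator_config"))
    generate_network(config$network) else config$network
  eng <- build_engine(net)
  alpha <- expand_alpha(config$learning$alpha, eng$ids)
  n_srs <- sum(eng$is_srs); n_grs <- eng$n - n_srs
  rounds <- config$rounds
  rows_per_rep <- rounds
  out <- vector("list", config$reps)
  absorbed <- rep(NA_integer_, config$reps)

  for (rep_i in seq_len(config$reps)) {
    res <- with_seed(config$seed + rep_i - 1L, {
      strat_chr <- initialize_strategies(net, config$m0, config$r0)
      strat <- strat_to_int(strat_chr, eng)
      pps_all <- pps_grs <- pps_srs <- mg <- numeric(rows_per_rep)
      quiet <- 0L
      stopped_at <- NA_integer_
      t <- 1L
      while (t <= rounds) {
        u <- play_round_idx(eng, strat, config$params)
        pps_srs[t] <- sum(strat[eng$is_srs]) / n_srs
        pps_grs[t] <- sum(strat[!eng$is_srs]) / n_grs
        pps_all[t] <- sum(strat) / eng$n
        mg[t] <- mean(u)
        new <- evolve_step_idx(eng, strat, u, alpha, config$learning,
                               config$cross_role_learning)
        quiet <- if (all(new == strat)) quiet + 1L else 0L
        strat <- new
        if (quiet >= config$quiescence_window && t < rounds) {
          stopped_at <- t
          idx <- (t + 1L):rounds    # strategies frozen: carry values forward
          pps_all[idx] <- pps_all[t]; pps_grs[idx] <- pps_grs[t]
          pps_srs[idx] <- pps_srs[t]; mg[idx] <- mg[t]
          break
        }
        t <- t + 1L
      }
      list(df = data.frame(rep = rep_i, round = seq_len(rows_per_rep),
                           pps_all = pps_all, pps_grs = pps_grs,
                           pps_srs = pps_srs, mean_gain = mg),
           stopped_at = stopped_at)
    })
    out[[rep_i]] <- res$df
    absorbed[rep_i] <- res$stopped_at
  }

  traj <- do.call(rbind, out)
  mean_df <- stats::aggregate(
    traj[, c("pps_all", "pps_grs", "pps_srs", "mean_gain")],
    by = list(round = traj$round), FUN = mean)
  structure(list(trajectory = traj, mean = mean_df, absorbed = absorbed,
                 network = net, config = config),
            class = "game_trajectory")
}

#' @export
print.game_trajectory <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Networked game trajectory: %d replicate(s) x %d rounds\n",
              cfg$reps, cfg$rounds))
  cat(sprintf("  final replicate-mean PPS (last %d rounds): %.4f\n",
              cfg$quiescence_window, final_pps(x)))
  cat(sprintf("  replicates quiescent before horizon: %d of %d\n",
              sum(!is.na(x$absorbed)), cfg$reps))
  invisible(x)
}

#' Final proportion of positive strategies
#'
#' The long-run summary statistic of a simulation: the mean of `pps_all`
#' (or another recorded column) over the last `window` rounds of each
#' replicate, averaged over replicates. Using a window rather than the
#' single last round makes the statistic robust to late single-node flips.
#'
#' @param traj A [run_simulation()] result.
#' @param window Number of final rounds to average; defaults to the
#'   configuration's `quiescence_window`.
#' @param measure Trajectory column to summarize (default `"pps_all"`).
#' @return A single number.
#' @export
final_pps <- function(traj, window = NULL, measure = "pps_all") {
  stopifnot(inherits(traj, "game_trajectory"))
  if (is.null(window)) window <- traj$config$quiescence_window
  tr <- traj$trajectory
  last <- tr$round > max(tr$round) - window
  per_rep <- tapply(tr[[measure]][last], tr$rep[last], mean)
  mean(per_rep)
}

#' Plot replicate-averaged trajectories
#'
#' Line plot of the replicate-averaged PPS (overall and by role) or mean
#' gain against the round number. Requires ggplot2.
#'
#' @param traj A [run_simulation()] result.
#' @param measure `"pps"` (overall + per-role proportions) or `"gain"`.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj, measure = c("pps", "gain")) {
  measure <- match.arg(measure)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_trajectory() requires the ggplot2 package", call. = FALSE)
  m <- traj$mean
  if (measure == "gain") {
    return(ggplot2::ggplot(m, ggplot2::aes(round, mean_gain)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "round", y = "average gain"))
  }
  long <- data.frame(
    round = rep(m$round, 3),
    series = rep(c("all", "GRS", "SRS"), each = nrow(m)),
    pps = c(m$pps_all, m$pps_grs, m$pps_srs))
  ggplot2::ggplot(long, ggplot2::aes(round, pps, colour = series)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "round", y = "proportion of positive strategies")
}

utils::globalVariables(c("mean_gain", "pps", "series"))
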