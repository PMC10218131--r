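test_that("initialization hits the requested positive counts exactly", {
  net <- generate_network(generator_config(seed = 2))
  roles <- node_roles(net)
  set.seed(1)
  s <- initialize_strategies(net, 0.1, 0.4)
  expect_equal(sum(s[roles == "SRS"] == "positive"), round(49 * 0.1))  # 5
  expect_equal(sum(s[roles == "GRS"] == "positive"), round(19 * 0.4))  # 8
  expect_true(all(initialize_strategies(net, 0, 0) == "negative"))
  expect_true(all(initialize_strategies(net, 1, 1) == "positive"))
})

test_that("round gains sum cross-type games only and reset each round", {
  p <- baseline_params(gamma = 0.6)
  net <- mixed_net()
  s <- c(g1 = "positive", g2 = "negative", s1 = "positive",
         s2 = "negative", s3 = "positive")
  u <- play_round(net, s, p)
  # s1 plays one game (with g1): positive vs positive with reward
  expect_equal(unname(u["s1"]), 8 - 2 + 0.6)
  # g1 plays s1 (positive/positive) and the g1-g2 tie carries no payoff
  expect_equal(unname(u["g1"]), 3 - 5)
  # s2 touches only the same-type edge s1-s2; s3 is isolated
  expect_equal(unname(u["s2"]), 0)
  expect_equal(unname(u["s3"]), 0)
  expect_equal(unname(u["g2"]), 0)
  # gains recomputed fresh: same state twice gives identical gains
  expect_identical(u, play_round(net, s, p))
})

test_that("Boltzmann selection matches brute-force softmax probabilities", {
  # star: focal SRS hub s1 with neighbors g1 (u=1) and s2 (u=0), lam = 1
  net <- typed_network(
    data.frame(id = c("g1", "s1", "s2"), role = c("GRS", "SRS", "SRS")),
    data.frame(source = c("s1", "s1"), target = c("g1", "s2")))
  u <- c(g1 = 1, s1 = 5, s2 = 0)
  set.seed(99)
  picks <- replicate(4000, select_learning_target("s1", net, u))
  p_hat <- mean(picks == "g1")
  expect_equal(p_hat, exp(1) / (1 + exp(1)), tolerance = 0.03)
  # lam -> large: selection approaches uniform
  set.seed(100)
  picks <- replicate(4000, select_learning_target(
    "s1", net, u, learning_params(lam = 1e6)))
  expect_equal(mean(picks == "g1"), 0.5, tolerance = 0.03)
  # isolated node has nobody to learn from
  net2 <- typed_network(data.frame(id = c("a", "b"), role = c("GRS", "SRS")),
                        data.frame())
  expect_true(is.na(select_learning_target("a", net2, c(a = 0, b = 0))))
})

test_that("selection is numerically safe for very large gains", {
  net <- pair_net()
  set.seed(5)
  expect_identical(
    select_learning_target("g1", net, c(g1 = 0, s1 = 1e6)), "s1")
})

test_that("Fermi adoption probabilities match the closed form", {
  expect_equal(adoption_probability(3, 3, 1), 0.5)
  expect_equal(adoption_probability(1, 0, 1), 1 / (1 + exp(1)))
  expect_equal(adoption_probability(0, 1, 1), 1 / (1 + exp(-1)))
  # xi -> 0: step function (adopt iff the target earned strictly more)
  expect_equal(adoption_probability(0, 1, 1e-9), 1)
  expect_equal(adoption_probability(1, 0, 1e-9), 0)
  expect_error(adoption_probability(0, 1, 0))
})

test_that("homogeneous strategy states are absorbing", {
  net <- generate_network(generator_config(seed = 3))
  p <- baseline_params(gamma = 0.6, delta = 1)
  for (lab in c("positive", "negative")) {
    s <- setNames(rep(lab, igraph::vcount(net)), igraph::V(net)$name)
    u <- play_round(net, s, p)
    set.seed(17)
    expect_identical(evolve_step(net, s, u), s)
  }
})

test_that("a near-deterministic two-node update copies the richer subject", {
  net <- pair_net()
  p <- baseline_params()
  s <- c(g1 = "positive", s1 = "negative")
  u <- play_round(net, s, p)   # SRS earns pi_e = 8, GRS earns -2 + beta*0
  expect_gt(u["s1"], u["g1"])
  set.seed(23)
  new <- evolve_step(net, s, u, learning_params(xi = 1e-9))
  expect_identical(unname(new["g1"]), "negative")  # copies the richer SRS
  expect_identical(unname(new["s1"]), "negative")  # never copies the poorer
})

test_that("role-restricted learning never transfers labels across roles", {
  net <- mixed_net()
  p <- baseline_params()
  # all GRSs negative, all SRSs positive; without cross-role learning the
  # only mixed-role channels are inert, so the split can only persist
  s <- c(g1 = "negative", g2 = "negative", s1 = "positive",
         s2 = "positive", s3 = "positive")
  u <- play_round(net, s, p)
  set.seed(31)
  for (k in 1:10) {
    s2 <- evolve_step(net, s, u, cross_role_learning = FALSE)
    roles <- node_roles(net)
    expect_true(all(s2[roles == "GRS"] == "negative"))
    expect_true(all(s2[roles == "SRS"] == "positive"))
  }
})

test_that("trajectories conserve the role-weighted PPS identity every round", {
  cfg <- simulation_config(m0 = 0.3, r0 = 0.5, reps = 3, rounds = 30,
                           seed = 42)
  traj <- run_simulation(cfg)
  tr <- traj$trajectory
  expect_equal(tr$pps_all * 68, tr$pps_grs * 19 + tr$pps_srs * 49,
               tolerance = 1e-12)
})

test_that("runs are bit-identical under a fixed seed", {
  cfg <- simulation_config(reps = 3, rounds = 25, seed = 77)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$trajectory, t2$trajectory)
  expect_identical(t1$absorbed, t2$absorbed)
})

test_that("homogeneous initial conditions stay homogeneous for whole runs", {
  cfg1 <- simulation_config(m0 = 1, r0 = 1, reps = 2, rounds = 15, seed = 4)
  expect_true(all(run_simulation(cfg1)$trajectory$pps_all == 1))
  cfg0 <- simulation_config(m0 = 0, r0 = 0, reps = 2, rounds = 15, seed = 4)
  t0 <- run_simulation(cfg0)
  expect_true(all(t0$trajectory$pps_all == 0))
  # all-negative round gain: per-node average of the NEG/NEG sums
  net <- t0$network
  el <- igraph::as_edgelist(net)
  roles <- node_roles(net)
  n_cross <- sum(roles[el[, 1]] != roles[el[, 2]])
  expect_equal(t0$trajectory$mean_gain[1], (8 - 3) * n_cross / 68)
})

test_that("on a complete two-role graph the SRS positives decline", {
  # mean-field echo: with gamma + delta < c_e the positive-participation
  # bracket is negative, so m should fall from its initial value. The
  # complete graph provides the within-role learning channels the echo
  # needs (on a purely bipartite graph SRSs only see far-poorer GRSs and
  # the Fermi rule freezes them).
  n_g <- 19; n_s <- 49
  ids <- c(sprintf("g%02d", 1:n_g), sprintf("s%02d", 1:n_s))
  roles <- rep(c("GRS", "SRS"), c(n_g, n_s))
  pairs <- t(utils::combn(ids, 2))
  edges <- data.frame(source = pairs[, 1], target = pairs[, 2])
  net <- typed_network(data.frame(id = ids, role = roles), edges)
  cfg <- simulation_config(params = baseline_params(), network = net,
                           m0 = 0.5, r0 = 0.5, reps = 5, rounds = 40,
                           seed = 19)
  traj <- run_simulation(cfg)
  first <- traj$mean$pps_srs[1]
  last <- tail(traj$mean$pps_srs, 1)
  expect_lt(last, first)
  expect_lt(last, 0.1)
})

test_that("early-stopped replicates carry their frozen state forward", {
  cfg <- simulation_config(m0 = 0, r0 = 0, reps = 1, rounds = 50,
                           quiescence_window = 5, seed = 12)
  traj <- run_simulation(cfg)
  expect_equal(nrow(traj$trajectory), 50)
  expect_equal(traj$absorbed[1], 5)
  expect_equal(length(unique(traj$trajectory$mean_gain)), 1L)
})
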