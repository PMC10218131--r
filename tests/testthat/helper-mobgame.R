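# shared fixtures for the mobgame test suite (built in code, no data files)

# baseline parameterization used by the canonical experiments
baseline_params <- function(gamma = 0, delta = 0) {
  game_params(pi_e = 8, c_e = 2, pi_g = 3, c_g = 5, c_v = 1, c_s = 2,
              beta = 0.3, gamma = gamma, delta = delta)
}

# random valid parameter set for property-style tests
random_params <- function() {
  pi_e <- runif(1, 1, 10)
  game_params(pi_e = pi_e,
              c_e = runif(1, 0.05, pi_e * 0.9),
              pi_g = runif(1, 0.1, 10),
              c_g = runif(1, 0.1, 10),
              c_v = runif(1, 0.1, 5),
              c_s = runif(1, 0.1, 5),
              beta = runif(1),
              gamma = runif(1, 0, 4),
              delta = runif(1, 0, 4))
}

# one SRS joined to one GRS
pair_net <- function() {
  typed_network(data.frame(id = c("g1", "s1"), role = c("GRS", "SRS")),
                data.frame(source = "g1", target = "s1"))
}

# SRS star: one SRS hub with a GRS, plus an isolated SRS and a same-type edge
mixed_net <- function() {
  typed_network(
    data.frame(id = c("g1", "g2", "s1", "s2", "s3"),
               role = c("GRS", "GRS", "SRS", "SRS", "SRS")),
    data.frame(source = c("g1", "s1", "g1"),
               target = c("s1", "s2", "g2")))
}

# independent Det/Tr oracle: the printed closed forms for the four corner
# equilibria, as functions of the parameters
corner_detr_oracle <- function(point, p) {
  A <- p$pi_g - p$c_g + p$beta * p$delta + p$c_s + p$c_v
  gd <- p$gamma + p$delta
  switch(point,
    "(0,0)" = c(det = -p$c_e * A, tr = -p$c_e + A),
    "(0,1)" = c(det = (p$c_e - gd) * A, tr = gd - p$c_e - A),
    "(1,0)" = c(det = p$c_e * (p$pi_g - p$c_g + p$c_v),
                tr = p$c_e + p$pi_g - p$c_g + p$c_v),
    "(1,1)" = c(det = (gd - p$c_e) * (p$pi_g - p$c_g + p$c_v),
                tr = -(gd - p$c_e) - (p$pi_g - p$c_g + p$c_v)))
}
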