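#' Read a simulation configuration from YAML
#'
#' The YAML schema mirrors [simulation_config()]:
#'
#' ```yaml
#' params:   {pi_e: 8, c_e: 2, pi_g: 3, c_g: 5, c_v: 1, c_s: 2,
#'            beta: 0.3, gamma: 0, delta: 0}
#' learning: {lam: 1, xi: 1, alpha: 0}
#' network:
#'   node_file: nodes.csv      # either CSV pair,
#'   edge_file: edges.csv
#'   # graphml: net.graphml    # ... or GraphML,
#'   # generator: {n_grs: 19, n_srs: 49, mean_degree: 4,
#'   #             p_same_type: 0.3, seed: 1}   # ... or generator
#' m0: 0.1
#' r0: 0.4
#' rounds: 100
#' reps: 20
#' seed: 1
#' quiescence_window: 20
#' cross_role_learning: true
#' ```
#'
#' Every section is optional; omitted sections fall back to the
#' [simulation_config()] defaults. Relative network paths are resolved
#' against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  x <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(x$params)) args$params <- do.call(game_params, x$params)
  if (!is.null(x$learning)) args$learning <- do.call(learning_params, x$learning)
  if (!is.null(x$network)) {
    nw <- x$network
    rel <- function(p) if (file.exists(p)) p else file.path(dirname(path), p)
    args$network <-
      if (!is.null(nw$node_file)) read_network(rel(nw$node_file),
                                               rel(nw$edge_file))
      else if (!is.null(nw$graphml)) read_network_graphml(rel(nw$graphml))
      else if (!is.null(nw$generator)) do.call(generator_config, nw$generator)
      else stop("network section must give node_file/edge_file, graphml, ",
                "or generator", call. = FALSE)
  }
  for (nm in c("m0", "r0", "rounds", "reps", "seed",
               "quiescence_window", "cross_role_learning"))
    if (!is.null(x[[nm]])) args[[nm]] <- x[[nm]]
  do.call(simulation_config, args)
}
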