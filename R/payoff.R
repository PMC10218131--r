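#' Game parameters for the mobilization-participation game
#'
#' Bundles the nine payoff parameters of the asymmetric two-role game between
#' government resource subjects (GRSs, choosing positive/negative
#' *mobilization*) and social resource subjects (SRSs, choosing
#' positive/negative *participation*).
#'
#' The defaults are the baseline parameterization used throughout the
#' package's worked examples and scenario runners, with the reward and
#' penalty switched off (`gamma = delta = 0`).
#'
#' @param pi_e Routine operating return of an SRS (payoff units). Must be
#'   positive and exceed `c_e`.
#' @param c_e Extra cost an SRS pays for positive participation.
#' @param pi_g Credibility gain of a GRS under positive mobilization.
#' @param c_g Organizational cost a GRS pays for positive mobilization.
#' @param c_v Credibility loss a GRS suffers under negative mobilization.
#' @param c_s Public-dissatisfaction cost added when both sides are negative.
#' @param beta Compensation rate: a positive GRS recovers `beta * delta`
#'   from the penalty imposed on a negative SRS.
#' @param gamma Reward paid to a positive SRS facing a positive GRS. `0`
#'   expresses "no reward".
#' @param delta Penalty imposed on a negative SRS facing a positive GRS.
#'   `0` expresses "no penalty".
#'
#' @return An object of class `game_params`: a named list of the nine
#'   parameters, validated against the model's sign constraints.
#'
#' @examples
#' p <- game_params()                       # baseline, no intervention
#' p2 <- game_params(gamma = 0.6)           # switch on a reward
#' pair_payoff("positive", "positive", p2)
#' @export
game_params <- function(pi_e = 8, c_e = 2, pi_g = 3, c_g = 5,
                        c_v = 1, c_s = 2, beta = 0.3,
                        gamma = 0, delta = 0) {
  p <- list(pi_e = pi_e, c_e = c_e, pi_g = pi_g, c_g = c_g,
            c_v = c_v, c_s = c_s, beta = beta, gamma = gamma, delta = delta)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("game parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    p[[nm]] <- as.numeric(v)
  }
  if (p$pi_e <= 0) stop("pi_e must be > 0", call. = FALSE)
  if (p$pi_e <= p$c_e) stop("pi_e must exceed c_e", call. = FALSE)
  if (p$c_g <= 0) stop("c_g must be > 0", call. = FALSE)
  if (p$c_v <= 0) stop("c_v must be > 0", call. = FALSE)
  if (p$c_s <= 0) stop("c_s must be > 0", call. = FALSE)
  if (p$beta < 0 || p$gamma < 0 || p$delta < 0)
    stop("beta, gamma and delta must be >= 0", call. = FALSE)
  structure(p, class = "game_params")
}

#' @export
print.game_params <- function(x, ...) {
  cat("Mobilization-participation game parameters\n")
  cat(sprintf("  SRS:  pi_e = %g, c_e = %g\n", x$pi_e, x$c_e))
  cat(sprintf("  GRS:  pi_g = %g, c_g = %g, c_v = %g, c_s = %g\n",
              x$pi_g, x$c_g, x$c_v, x$c_s))
  cat(sprintf("  Intervention: gamma = %g (reward), delta = %g (penalty), beta = %g (compensation)\n",
              x$gamma, x$delta, x$beta))
  invisible(x)
}

#' @export
format.game_params <- function(x, ...) {
  paste(names(x), unlist(x), sep = "=", collapse = ", ")
}

# canonical strategy labels; "positive" means positive mobilization for a
# GRS and positive participation for an SRS
.strategies <- c("negative", "positive")

as_strategy <- function(x) {
  if (is.logical(x) && length(x) == 1L && !is.na(x))
    return(.strategies[x + 1L])
  if (!is.character(x) || length(x) != 1L || !(x %in% .strategies))
    stop("strategy must be \"positive\" or \"negative\", got: ",
         deparse(substitute(x)), " = ", paste(format(x), collapse = ", "),
         call. = FALSE)
  x
}

#' Pairwise payoff of one SRS-GRS game
#'
#' Evaluates one cell of the two-role payoff matrix. Both subjects hold a
#' binary strategy; the cell payoffs are:
#'
#' | SRS \ GRS | positive | negative |
#' |---|---|---|
#' | positive | `(pi_e - c_e + gamma, pi_g - c_g)` | `(pi_e - c_e, -c_v)` |
#' | negative | `(pi_e - delta, pi_g - c_g + beta*delta)` | `(pi_e, -c_v - c_s)` |
#'
#' @param srs_strategy,grs_strategy `"positive"` or `"negative"`.
#' @param params A [game_params()] object.
#' @return A list with numeric elements `srs_gain` and `grs_gain`.
#' @examples
#' pair_payoff("negative", "negative", game_params())
#' @export
pair_payoff <- function(srs_strategy, grs_strategy, params) {
  stopifnot(inherits(params, "game_params"))
  s <- as_strategy(srs_strategy)
  g <- as_strategy(grs_strategy)
  m <- payoff_matrices(params)
  list(srs_gain = m$srs[s, g], grs_gain = m$grs[s, g])
}

# 2x2 payoff lookup tables, rows = SRS strategy, cols = GRS strategy
payoff_matrices <- function(params) {
  p <- params
  dn <- list(srs = .strategies, grs = .strategies)
  srs <- matrix(c(p$pi_e,         p$pi_e - p$delta,            # SRS negative
                  p$pi_e - p$c_e, p$pi_e - p$c_e + p$gamma),   # SRS positive
                nrow = 2, byrow = TRUE, dimnames = dn)
  grs <- matrix(c(-p$c_v - p$c_s, p$pi_g - p$c_g + p$beta * p$delta,
                  -p$c_v,         p$pi_g - p$c_g),
                nrow = 2, byrow = TRUE, dimnames = dn)
  list(srs = srs, grs = grs)
}

#' Read or write game parameters as YAML/JSON
#'
#' Parameters are stored as a flat mapping keyed by the symbol names
#' `pi_e, c_e, pi_g, c_g, c_v, c_s, beta, gamma, delta`. The format is
#' chosen by file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path File to read from / write to.
#' @param params A [game_params()] object.
#' @return `read_game_params()` returns a validated [game_params()] object;
#'   `write_game_params()` returns `path` invisibly.
#' @export
read_game_params <- function(path) {
  x <- switch(file_format(path),
              yaml = yaml::read_yaml(path),
              json = jsonlite::read_json(path, simplifyVector = TRUE))
  x <- as.list(x)
  known <- names(formals(game_params))
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("unknown game parameter(s) in ", path, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  do.call(game_params, x)
}

#' @rdname read_game_params
#' @export
write_game_params <- function(params, path) {
  stopifnot(inherits(params, "game_params"))
  x <- unclass(params)
  switch(file_format(path),
         yaml = yaml::write_yaml(x, path),
         json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA))
  invisible(path)
}

file_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return("yaml")
  if (ext == "json") return("json")
  stop("unsupported file extension '", ext, "' (use .yaml, .yml or .json)",
       call. = FALSE)
}
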