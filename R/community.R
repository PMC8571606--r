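#' Define a strain community relative to a focal strain
#'
#' A community is a set of `N >= 2` strains, one of which is the *focal*
#' strain whose fate is predicted. Every other strain `i` is characterised by
#' the per-generation selection coefficient `s_i` of the focal strain measured
#' against it in a pairwise competition; the fitness of strain `i` relative to
#' the focal strain is `w_fi = 1 - s_i` and the focal strain itself has
#' `w_ff = 1`. Positive `s_i` therefore means the focal strain beats strain
#' `i`, and `w_fi < 1`.
#'
#' @param strains Character vector of strain names (length `N >= 2`).
#' @param focal Name of the focal strain; must appear in `strains`.
#' @param selection Named numeric vector of per-generation selection
#'   coefficients of the focal strain versus each non-focal strain. Names must
#'   cover exactly the non-focal strains. Each `1 - s_i` must be positive.
#' @param initial_focal_frequency Initial frequency `x_f(t0)` of the focal
#'   strain, strictly inside (0, 1).
#' @return An object of class `community`: a list with elements `strains`,
#'   `focal`, `selection`, `fitness` (the `w_fi`, focal included at 1) and
#'   `initial_focal_frequency`.
#' @examples
#' comm <- community(c("mCherry", "NCYC132"), focal = "mCherry",
#'                   selection = c(NCYC132 = 0.18),
#'                   initial_focal_frequency = 0.5)
#' initial_frequencies(comm)
#' @seealso [predict_trajectory()], [simulate_bottleneck_regime()]
#' @export
community <- function(strains, focal, selection, initial_focal_frequency = 0.5) {
  if (!is.character(strains) || length(strains) < 2L)
    stop("'strains' must be a character vector with at least 2 strains")
  if (anyDuplicated(strains))
    stop("strain names must be unique")
  if (length(focal) != 1L || !focal %in% strains)
    stop("'focal' must name exactly one strain in 'strains'")
  others <- setdiff(strains, focal)
  if (is.null(names(selection)) || !setequal(names(selection), others))
    stop("'selection' must be named with exactly the non-focal strains: ",
         paste(others, collapse = ", "))
  selection <- selection[others]
  if (!all(is.finite(selection)))
    stop("selection coefficients must be finite")
  w <- 1 - selection
  if (any(w <= 0))
    stop("each relative fitness w_fi = 1 - s_i must be positive")
  x0 <- initial_focal_frequency
  if (!is.numeric(x0) || length(x0) != 1L || x0 <= 0 || x0 >= 1)
    stop("'initial_focal_frequency' must be strictly between 0 and 1")
  fitness <- c(1, w)
  names(fitness) <- c(focal, others)
  fitness <- fitness[strains]
  structure(
    list(strains = strains, focal = focal, selection = selection,
         fitness = fitness, initial_focal_frequency = x0),
    class = "community")
}

#' @export
print.community <- function(x, ...) {
  cat("Strain community (", length(x$strains), " strains)\n", sep = "")
  cat("  focal: ", x$focal, " at x0 = ", x$initial_focal_frequency, "\n", sep = "")
  for (s in names(x$selection))
    cat(sprintf("  s(focal vs %s) = %+.3f  (w = %.3f)\n",
                s, x$selection[[s]], 1 - x$selection[[s]]))
  invisible(x)
}

#' Initial frequency state of a community
#'
#' The focal strain starts at its configured frequency `x_f(t0)`; the
#' remaining strains split the rest equally, `x_i(t0) = (1 - x_f(t0))/(N - 1)`.
#'
#' @param comm A [community()].
#' @return A `frequency_state`: named frequency vector (summing to 1) with a
#'   `generation` attribute of 0.
#' @export
initial_frequencies <- function(comm) {
  stopifnot(inherits(comm, "community"))
  n <- length(comm$strains)
  x <- rep((1 - comm$initial_focal_frequency) / (n - 1), n)
  names(x) <- comm$strains
  x[comm$focal] <- comm$initial_focal_frequency
  frequency_state(x, generation = 0)
}

frequency_state <- function(frequencies, generation) {
  if (any(frequencies < 0))
    stop("frequencies must be non-negative")
  if (abs(sum(frequencies) - 1) > 1e-12)
    stop("frequencies must sum to 1 (within 1e-12)")
  structure(frequencies, generation = generation, class = "frequency_state")
}

#' Advance a frequency state by selection
#'
#' One application of the haploid replicator update: every strain's frequency
#' is multiplied by its fitness relative to the focal strain and renormalised
#' by the population mean fitness,
#' `x_i(t+1) = x_i(t) w_fi / sum_k x_k(t) w_fk`. With `generations != 1` the
#' fitnesses act as `w_fi^g`, which iterates the one-generation map `g` times
#' in closed form (the map is exponential in `t`).
#'
#' @param state A `frequency_state` (named, same strains as `comm`).
#' @param comm The [community()].
#' @param generations Number of generations to advance (default 1; may be
#'   fractional, e.g. the 8.97 generations of a 1:500 regrowth).
#' @return The advanced `frequency_state`.
#' @export
step_frequencies <- function(state, comm, generations = 1) {
  stopifnot(inherits(comm, "community"))
  x <- as.numeric(state)
  names(x) <- names(state)
  x <- x[comm$strains]
  wg <- comm$fitness^generations
  xw <- x * wg
  mean_fitness <- sum(xw)
  if (!is.finite(mean_fitness) || mean_fitness <= 0)
    stop("population mean fitness must be positive")
  g0 <- attr(state, "generation")
  if (is.null(g0)) g0 <- 0
  frequency_state(xw / mean_fitness, generation = g0 + generations)
}

frequency_trajectory <- function(generations, freqs, focal, kind) {
  freqs <- as.matrix(freqs)
  if (length(generations) != nrow(freqs))
    stop("one frequency row per generation required")
  if (is.unsorted(generations, strictly = TRUE))
    stop("generations must be strictly increasing")
  df <- data.frame(generation = generations, freqs, check.names = FALSE)
  structure(df, focal = focal, kind = kind,
            class = c("frequency_trajectory", "data.frame"))
}

#' @export
print.frequency_trajectory <- function(x, ...) {
  cat(sprintf("<%s frequency trajectory: %d states, generations %g..%g, focal '%s'>\n",
              attr(x, "kind"), nrow(x), min(x$generation), max(x$generation),
              attr(x, "focal")))
  print.data.frame(utils::head(as.data.frame(x), 5), row.names = FALSE)
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Focal-strain frequencies of a trajectory
#'
#' @param traj A `frequency_trajectory`.
#' @return Numeric vector of focal frequencies, one per recorded generation.
#' @export
focal_frequencies <- function(traj) {
  stopifnot(inherits(traj, "frequency_trajectory"))
  focal <- attr(traj, "focal")
  if (!focal %in% names(traj))
    stop("trajectory does not record the focal strain '", focal, "'")
  traj[[focal]]
}

#' Deterministic frequency forecast
#'
#' Iterates the replicator update from [initial_frequencies()] for `horizon`
#' generations, assuming constant selection and no mutation or drift. For two
#' strains this reproduces the closed form
#' `x_f(t) = x0 / (x0 + (1 - x0) w^t)`.
#'
#' @param comm A [community()].
#' @param horizon Number of generations to forecast (default 400).
#' @param record_every Record a state every this many generations (default 1);
#'   generation 0 and the final generation are always recorded.
#' @return A `frequency_trajectory` of kind `"predicted"`.
#' @export
predict_trajectory <- function(comm, horizon = 400, record_every = 1) {
  stopifnot(inherits(comm, "community"))
  if (!is.numeric(horizon) || horizon < 1)
    stop("'horizon' must be >= 1 generation")
  if (record_every <= 0)
    stop("'record_every' must be positive")
  state <- initial_frequencies(comm)
  record_at <- unique(c(seq(0, horizon, by = record_every), horizon))
  out <- matrix(NA_real_, nrow = length(record_at), ncol = length(comm$strains),
                dimnames = list(NULL, comm$strains))
  out[1, ] <- as.numeric(state)
  for (k in seq_along(record_at)[-1]) {
    state <- step_frequencies(state, comm, record_at[k] - record_at[k - 1])
    out[k, ] <- as.numeric(state)
  }
  frequency_trajectory(record_at, out, focal = comm$focal, kind = "predicted")
}

#' Generations of regrowth per serial transfer
#'
#' After an `d`-fold dilution the culture doubles back to its pre-dilution
#' density, taking `log2(d)` generations. The 1:500 regime used in the
#' propagations gives `log2(500) = 8.97`, i.e. around 9 generations per
#' transfer.
#'
#' @param dilution Fold dilution at each transfer (> 1).
#' @return Number of generations per transfer (base-2 convention; contrast
#'   with [generations_elapsed()], which uses the natural-log convention of
#'   the fitness assay).
#' @export
generations_per_transfer <- function(dilution = 500) {
  if (!is.numeric(dilution) || length(dilution) != 1L || dilution <= 1)
    stop("'dilution' must be a single number > 1")
  log2(dilution)
}

#' Stochastic serial-transfer simulation
#'
#' Extends the deterministic model with the population bottleneck of the
#' serial-transfer regime: each cycle applies deterministic selection for
#' `growth_generations_per_transfer` generations, then samples the
#' `census_at_transfer` founder cells of the next cycle multinomially from the
#' current frequencies. A strain drawn 0 times is extinct and stays extinct.
#' The default census is the number of cells transferred in the experimental
#' regime: a 200 ul well grown to OD600 1 diluted 1:500, i.e.
#' `od_to_cells(1, 0.2)/500` (about 1.19e4 cells).
#'
#' @param comm A [community()].
#' @param n_transfers Number of growth/dilution cycles.
#' @param census_at_transfer Founder cells sampled at each transfer (>= 1).
#' @param growth_generations_per_transfer Generations of deterministic
#'   selection per cycle; default `generations_per_transfer(500)`.
#' @param seed Optional integer seed for reproducibility.
#' @return A `frequency_trajectory` of kind `"simulated"`, recorded at
#'   generation 0 and after every transfer.
#' @export
simulate_bottleneck_regime <- function(comm, n_transfers,
                                       census_at_transfer = od_to_cells(1, 0.2) / 500,
                                       growth_generations_per_transfer =
                                         generations_per_transfer(500),
                                       seed = NULL) {
  stopifnot(inherits(comm, "community"))
  if (!is.numeric(n_transfers) || n_transfers < 1)
    stop("'n_transfers' must be >= 1")
  if (!is.numeric(census_at_transfer) || census_at_transfer < 1)
    stop("'census_at_transfer' must be >= 1 cell")
  if (!is.null(seed)) set.seed(seed)
  census <- round(census_at_transfer)
  g <- growth_generations_per_transfer
  state <- initial_frequencies(comm)
  gens <- c(0, seq_len(n_transfers) * g)
  out <- matrix(NA_real_, nrow = n_transfers + 1L, ncol = length(comm$strains),
                dimnames = list(NULL, comm$strains))
  out[1, ] <- as.numeric(state)
  for (k in seq_len(n_transfers)) {
    state <- step_frequencies(state, comm, g)
    founders <- as.vector(stats::rmultinom(1, size = census, prob = as.numeric(state)))
    state <- frequency_state(stats::setNames(founders / census, comm$strains),
                             generation = attr(state, "generation"))
    out[k + 1L, ] <- as.numeric(state)
  }
  frequency_trajectory(gens, out, focal = comm$focal, kind = "simulated")
}

#' Classify the focal strain's fate from a trajectory
#'
#' Applies the experimental calling rule: the focal strain is *fixed* if its
#' frequency exceeds `fixation_threshold` at `consecutive_points` or more
#' successive recorded time points, *extinct* if it falls below
#' `extinction_threshold` for an equally long run, and *persisting* otherwise.
#' Defaults operationalise "above 99% for more than 2 sequential time points"
#' (read as at least 3) with a symmetric 1% extinction threshold.
#'
#' @param traj A `frequency_trajectory`.
#' @param fixation_threshold Frequency above which the strain counts as fixed
#'   (default 0.99).
#' @param extinction_threshold Frequency below which it counts as extinct
#'   (default 0.01).
#' @param consecutive_points Minimum run length of qualifying recorded points
#'   (default 3).
#' @return An `outcome_call`: list with `outcome` (`"fixed"`, `"extinct"` or
#'   `"persisting"`) and `at_generation` (first generation of the qualifying
#'   run; `NA` when persisting).
#' @export
classify_outcome <- function(traj, fixation_threshold = 0.99,
                             extinction_threshold = 0.01,
                             consecutive_points = 3) {
  stopifnot(inherits(traj, "frequency_trajectory"))
  if (nrow(traj) == 0L)
    stop("trajectory has no recorded states")
  x <- focal_frequencies(traj)
  if (nrow(traj) < consecutive_points) {
    warning("fewer recorded points (", nrow(traj), ") than 'consecutive_points' (",
            consecutive_points, "); returning 'persisting'")
    return(outcome_call("persisting", NA_real_))
  }
  first_run <- function(flags) {
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= consecutive_points)
    if (!length(hit)) return(NA_integer_)
    ends[hit[1]] - r$lengths[hit[1]] + 1L
  }
  i_fix <- first_run(x > fixation_threshold)
  i_ext <- first_run(x < extinction_threshold)
  if (!is.na(i_fix) && (is.na(i_ext) || i_fix <= i_ext))
    outcome_call("fixed", traj$generation[i_fix])
  else if (!is.na(i_ext))
    outcome_call("extinct", traj$generation[i_ext])
  else
    outcome_call("persisting", NA_real_)
}

outcome_call <- function(outcome, at_generation) {
  structure(list(outcome = outcome, at_generation = at_generation),
            class = "outcome_call")
}

#' @export
print.outcome_call <- function(x, ...) {
  if (x$outcome == "persisting") cat("outcome: persisting\n")
  else cat(sprintf("outcome: %s (from generation %g)\n", x$outcome, x$at_generation))
  invisible(x)
}

#' Compare a predicted trajectory with observations
#'
#' Interpolates the prediction linearly to the observed generations and
#' reports per-time-point residuals (`observed - predicted`) plus a summary:
#' the mean absolute error, and the sign of the lag between observed and
#' predicted resolution. The lag sign is positive when the observed trajectory
#' resolves (crosses 1% while declining, or 99% while rising) *later* than
#' predicted -- the direction seen experimentally, where extinctions ran slower
#' than the constant-selection forecast.
#'
#' @param predicted A `frequency_trajectory` (kind `"predicted"` typically).
#' @param observed A `frequency_trajectory` with observed focal frequencies.
#' @return List with `residuals` (data.frame: generation, observed, predicted,
#'   residual), `mae`, and `lag_sign` (+1 observed slower, -1 faster, 0
#'   equal/no resolution).
#' @export
compare_prediction_to_observation <- function(predicted, observed) {
  stopifnot(inherits(predicted, "frequency_trajectory"),
            inherits(observed, "frequency_trajectory"))
  gp <- predicted$generation
  go <- observed$generation
  if (min(go) > max(gp) || max(go) < min(gp))
    stop("observed and predicted time ranges are disjoint")
  if (min(go) < min(gp) || max(go) > max(gp))
    stop("observed time points must lie within the predicted horizon")
  xp <- focal_frequencies(predicted)
  xo <- focal_frequencies(observed)
  pred_at_obs <- stats::approx(gp, xp, xout = go)$y
  res <- data.frame(generation = go, observed = xo, predicted = pred_at_obs,
                    residual = xo - pred_at_obs)
  crossing <- function(gen, x) {
    # first resolution time: crossing 0.01 downwards or 0.99 upwards
    lo <- which(x < 0.01); hi <- which(x > 0.99)
    t_lo <- if (length(lo)) gen[lo[1]] else Inf
    t_hi <- if (length(hi)) gen[hi[1]] else Inf
    min(t_lo, t_hi)
  }
  t_pred <- crossing(gp, xp)
  t_obs <- crossing(go, xo)
  lag_sign <- if (is.infinite(t_pred) && is.infinite(t_obs)) 0
              else sign(t_obs - t_pred)
  list(residuals = res, mae = mean(abs(res$residual)), lag_sign = lag_sign)
}
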