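#' Paired competition counts
#'
#' Cell counts of the fluorescent reference (focal) strain and its
#' non-fluorescent rival at the start and end of a competition assay, as
#' measured by flow cytometry.
#'
#' @param fluor_initial,fluor_final Fluorescent-strain counts `X_i`, `X_f`.
#' @param nonfluor_initial,nonfluor_final Non-fluorescent counts.
#' @param assay_id Assay label.
#' @return A `competition_counts` object.
#' @export
competition_counts <- function(fluor_initial, fluor_final,
                               nonfluor_initial, nonfluor_final,
                               assay_id = "assay") {
  counts <- c(fluor_initial, fluor_final, nonfluor_initial, nonfluor_final)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("all counts must be finite and non-negative")
  if (fluor_initial <= 0 || nonfluor_initial <= 0)
    stop("initial counts must be positive")
  structure(list(assay_id = assay_id,
                 fluor_initial = fluor_initial, fluor_final = fluor_final,
                 nonfluor_initial = nonfluor_initial,
                 nonfluor_final = nonfluor_final),
            class = "competition_counts")
}

#' @export
print.competition_counts <- function(x, ...) {
  cat(sprintf("<competition '%s': fluor %g -> %g, nonfluor %g -> %g>\n",
              x$assay_id, x$fluor_initial, x$fluor_final,
              x$nonfluor_initial, x$nonfluor_final))
  invisible(x)
}

#' Generations elapsed by the reference strain
#'
#' `t = ln(X_f / X_i)` of the fluorescent reference strain -- the natural-log
#' generation convention of the competition assay (one "generation" is an
#' e-fold expansion here, unlike the base-2 doublings of
#' [generations_per_transfer()]).
#'
#' @param counts A [competition_counts()].
#' @return Number of generations; negative (with a warning) if the reference
#'   shrank.
#' @export
generations_elapsed <- function(counts) {
  stopifnot(inherits(counts, "competition_counts"))
  if (counts$fluor_final <= 0)
    stop("fluorescent final count must be positive to define generations")
  t <- log(counts$fluor_final / counts$fluor_initial)
  if (t < 0)
    warning("reference strain shrank during the assay (t = ",
            signif(t, 4), " generations)")
  t
}

#' Competitive fitness per generation
#'
#' The selection coefficient of the fluorescent (focal) strain:
#' `S/g = ln(R_f / R_i) / t` where `R = fluor/nonfluor` at each time point and
#' `t` is [generations_elapsed()]. Positive values mean the fluorescent strain
#' is favoured. Zero counts are replaced by `pseudocount` (with a warning) so
#' the statistic stays finite; estimates with `t <= 0` are marked invalid.
#'
#' @param counts A [competition_counts()].
#' @param pseudocount Count substituted for zeros before forming ratios
#'   (default 1).
#' @return A `fitness_estimate` with `s_per_generation`, `generations`,
#'   `valid`, `assay_id`.
#' @export
fitness_per_generation <- function(counts, pseudocount = 1) {
  stopifnot(inherits(counts, "competition_counts"))
  nf_i <- counts$nonfluor_initial
  nf_f <- counts$nonfluor_final
  fl_i <- counts$fluor_initial
  fl_f <- counts$fluor_final
  if (nf_f == 0 || fl_f == 0) {
    warning("zero final count replaced by pseudocount ", pseudocount,
            " in assay '", counts$assay_id, "'; estimate is unreliable")
    if (nf_f == 0) nf_f <- pseudocount
    if (fl_f == 0) fl_f <- pseudocount
  }
  t <- suppressWarnings(log(fl_f / fl_i))
  valid <- is.finite(t) && t > 0
  if (!valid)
    warning("non-positive generations (t = ", signif(t, 4),
            "); estimate marked invalid")
  r_i <- fl_i / nf_i
  r_f <- fl_f / nf_f
  s <- if (valid) log(r_f / r_i) / t else NA_real_
  fitness_estimate(s_per_generation = s, generations = t, valid = valid,
                   assay_id = counts$assay_id)
}

fitness_estimate <- function(s_per_generation, generations = NA_real_,
                             valid = TRUE, assay_id = NA_character_,
                             n_replicates = 1L, mean = s_per_generation,
                             sd = NA_real_, two_sem = NA_real_) {
  structure(list(s_per_generation = s_per_generation, generations = generations,
                 valid = valid, assay_id = assay_id,
                 n_replicates = n_replicates, mean = mean, sd = sd,
                 two_sem = two_sem),
            class = "fitness_estimate")
}

#' @export
print.fitness_estimate <- function(x, ...) {
  if (x$n_replicates > 1L) {
    cat(sprintf("<fitness: mean S/g = %+.4f +/- %.4f 2SEM (n = %d)>\n",
                x$mean, x$two_sem, x$n_replicates))
  } else if (!x$valid) {
    cat(sprintf("<fitness '%s': invalid (t = %g)>\n", x$assay_id, x$generations))
  } else {
    cat(sprintf("<fitness '%s': S/g = %+.4f over t = %.3f generations>\n",
                x$assay_id, x$s_per_generation, x$generations))
  }
  invisible(x)
}

#' Aggregate replicate fitness estimates
#'
#' Mean and twice the standard error of the mean across valid replicates --
#' the reporting convention of the assay (point estimate +/- 2SEM).
#'
#' @param estimates List of `fitness_estimate` objects (>= 2 valid ones).
#' @return A `fitness_estimate` carrying `mean`, `sd`, `two_sem`,
#'   `n_replicates`.
#' @export
aggregate_replicates <- function(estimates) {
  if (inherits(estimates, "fitness_estimate")) estimates <- list(estimates)
  ok <- vapply(estimates, function(e) inherits(e, "fitness_estimate") && e$valid,
               logical(1))
  s <- vapply(estimates[ok], function(e) e$s_per_generation, numeric(1))
  if (length(s) < 2L)
    stop("at least 2 valid replicate estimates are required")
  m <- mean(s)
  sdev <- stats::sd(s)
  fitness_estimate(s_per_generation = m, valid = TRUE,
                   n_replicates = length(s), mean = m, sd = sdev,
                   two_sem = 2 * sdev / sqrt(length(s)))
}

#' Change in community fitness after evolution
#'
#' Both the ancestral and the evolved community are competed against the same
#' fluorescent reference strain, so the measured `S/g` values are from the
#' *reference's* perspective; the community's fitness change is the negated
#' difference, `delta = -(evolved - ancestral)`. For populations where the
#' fluorescent strain had fixed, the evolved community was instead competed
#' against the non-fluorescent ancestor and the estimate must first be shifted
#' by the ancestral reference-vs-ancestor competition (`correction`).
#'
#' @param ancestral,evolved `fitness_estimate` objects (aggregated means are
#'   used when present).
#' @param correction Optional `fitness_estimate` for the reference-vs-ancestor
#'   competition; required when `correction_required = TRUE`.
#' @param correction_required Set `TRUE` for the fluorescent-fixed case to
#'   insist on a correction.
#' @return The community fitness change (positive = community improved).
#' @export
community_fitness_change <- function(ancestral, evolved, correction = NULL,
                                     correction_required = !is.null(correction)) {
  val <- function(e) {
    stopifnot(inherits(e, "fitness_estimate"))
    if (!e$valid) stop("invalid fitness estimate")
    e$mean
  }
  a <- val(ancestral)
  ev <- val(evolved)
  if (correction_required && is.null(correction))
    stop("this comparison used a different reference; a correction estimate is required")
  if (!is.null(correction)) ev <- ev + val(correction)
  -(ev - a)
}

#' Read competition counts from CSV
#'
#' Long format written by [write_competition_counts()]: columns `assay_id`,
#' `replicate`, `timepoint` (`initial`/`final`), `fluorescent_count`,
#' `nonfluorescent_count`.
#'
#' @param path CSV file path.
#' @return List of [competition_counts()], one per assay/replicate.
#' @export
read_competition_counts <- function(path) {
  df <- utils::read.csv(path)
  need <- c("assay_id", "replicate", "timepoint",
            "fluorescent_count", "nonfluorescent_count")
  if (!all(need %in% names(df)))
    stop("competition CSV must have columns: ", paste(need, collapse = ", "))
  key <- interaction(df$assay_id, df$replicate, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    ini <- g[g$timepoint == "initial", ]
    fin <- g[g$timepoint == "final", ]
    if (nrow(ini) != 1L || nrow(fin) != 1L)
      stop("each assay/replicate needs exactly one initial and one final row")
    competition_counts(ini$fluorescent_count, fin$fluorescent_count,
                       ini$nonfluorescent_count, fin$nonfluorescent_count,
                       assay_id = paste0(g$assay_id[1], "/", g$replicate[1]))
  })
  out[order(names(out))]
}

#' Write competition counts to CSV
#'
#' @param counts A [competition_counts()] or list of them.
#' @param path Output CSV path.
#' @param replicate Replicate labels (recycled).
#' @return `path`, invisibly.
#' @export
write_competition_counts <- function(counts, path, replicate = NULL) {
  if (inherits(counts, "competition_counts")) counts <- list(counts)
  if (is.null(replicate)) replicate <- seq_along(counts)
  replicate <- rep_len(replicate, length(counts))
  df <- do.call(rbind, Map(function(ct, rep) rbind(
    data.frame(assay_id = ct$assay_id, replicate = rep, timepoint = "initial",
               fluorescent_count = ct$fluor_initial,
               nonfluorescent_count = ct$nonfluor_initial),
    data.frame(assay_id = ct$assay_id, replicate = rep, timepoint = "final",
               fluorescent_count = ct$fluor_final,
               nonfluorescent_count = ct$nonfluor_final)),
    counts, replicate))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Tidy fitness results table
#'
#' @param estimates List of `fitness_estimate` objects.
#' @return data.frame with one row per estimate (`assay_id`,
#'   `s_per_generation`, `generations`, `valid`).
#' @export
fitness_results_table <- function(estimates) {
  if (inherits(estimates, "fitness_estimate")) estimates <- list(estimates)
  do.call(rbind, lapply(estimates, function(e)
    data.frame(assay_id = e$assay_id, s_per_generation = e$s_per_generation,
               generations = e$generations, valid = e$valid)))
}
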