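#' Generate a synthetic logistic growth curve
#'
#' Logistic trajectory
#' `OD(t) = K OD0 e^{rt} / (K + OD0 (e^{rt} - 1))` sampled on a regular grid,
#' plus i.i.d. Gaussian plate-reader noise truncated at zero (negative draws
#' are redrawn). Defaults emulate the experimental regime: 20-min sampling for
#' 48 h starting from a ~1e4-cell inoculum in a 200 ul well (OD 0.003) in a
#' well that saturates near OD 1.
#'
#' @param rate Intrinsic per-hour growth rate (> 0).
#' @param carrying_capacity Saturation OD `K` (> `initial_od`).
#' @param initial_od Inoculum OD `OD0` (> 0).
#' @param interval Sampling interval in minutes (> 0).
#' @param duration Total duration in hours (> 0).
#' @param noise_sd Reader noise standard deviation in OD units (>= 0).
#' @param seed Optional integer seed.
#' @param well_id Well label.
#' @return A [growth_curve()] with `duration*60/interval + 1` readings.
#' @export
gen_growth_curve <- function(rate = 0.34, carrying_capacity = 1.0,
                             initial_od = 0.003, interval = 20, duration = 48,
                             noise_sd = 0, seed = NULL, well_id = "A1") {
  if (rate <= 0) stop("'rate' must be positive")
  if (initial_od <= 0) stop("'initial_od' must be positive")
  if (carrying_capacity <= initial_od)
    stop("'carrying_capacity' must exceed 'initial_od'")
  if (interval <= 0 || duration <= 0)
    stop("'interval' and 'duration' must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, duration, by = interval / 60)
  ert <- exp(rate * tt)
  od <- carrying_capacity * initial_od * ert /
    (carrying_capacity + initial_od * (ert - 1))
  if (noise_sd > 0) {
    noisy <- od + stats::rnorm(length(od), 0, noise_sd)
    bad <- which(noisy < 0)
    while (length(bad)) {  # truncate noise at zero by redrawing
      noisy[bad] <- od[bad] + stats::rnorm(length(bad), 0, noise_sd)
      bad <- bad[noisy[bad] < 0]
    }
    od <- noisy
  }
  growth_curve(tt, od, well_id = well_id)
}

#' Generate synthetic competition counts with known selection
#'
#' Produces paired fluorescent/non-fluorescent counts for which the
#' `S/g = ln(Rf/Ri)/t` estimator is the exact algebraic inverse: the
#' fluorescent (focal) strain expands `fold_expansion`-fold, defining
#' `t = ln(fold_expansion)` generations, and the rival's final abundance is
#' set so the log-ratio change per generation equals `s` exactly.
#'
#' With `sampling = "multinomial"`, cytometer measurement noise is added:
#' the composition at each time point is replaced by `events` multinomial
#' draws from the true frequencies, rescaled to the true total population
#' size (event counts alone carry no absolute-abundance scale, which the
#' generations formula needs).
#'
#' @param s True per-generation selection coefficient of the focal strain,
#'   in (-1, 1).
#' @param initial_total Total cells at the start (default 1e5).
#' @param initial_focal_fraction Starting focal fraction in (0, 1); the assay
#'   mixes 1:1 so the default is 0.5.
#' @param fold_expansion Fold expansion of the focal strain (> 1; the 1:500
#'   48-h regime gives 500).
#' @param sampling `"noiseless"` or `"multinomial"`.
#' @param events Cytometer events per sample for multinomial sampling
#'   (default 10000).
#' @param seed Optional integer seed.
#' @param assay_id Assay label.
#' @return A [competition_counts()] object.
#' @export
gen_competition_counts <- function(s, initial_total = 1e5,
                                   initial_focal_fraction = 0.5,
                                   fold_expansion = 500,
                                   sampling = c("noiseless", "multinomial"),
                                   events = 10000, seed = NULL,
                                   assay_id = "synthetic") {
  sampling <- match.arg(sampling)
  if (abs(s) >= 1) stop("'s' must be in (-1, 1)")
  if (fold_expansion <= 1) stop("'fold_expansion' must exceed 1")
  if (initial_focal_fraction <= 0 || initial_focal_fraction >= 1)
    stop("'initial_focal_fraction' must be strictly between 0 and 1")
  if (sampling == "multinomial" && (!is.numeric(events) || events <= 0))
    stop("'events' must be a positive integer for multinomial sampling")
  if (!is.null(seed)) set.seed(seed)
  fl_i <- initial_total * initial_focal_fraction
  nf_i <- initial_total * (1 - initial_focal_fraction)
  t <- log(fold_expansion)
  fl_f <- fl_i * fold_expansion
  # R_f = R_i * exp(s t)  =>  nonfluor grows by fold_expansion * exp(-s t)
  nf_f <- nf_i * fold_expansion * exp(-s * t)
  if (sampling == "multinomial") {
    events <- as.integer(events)
    resample <- function(fl, nf) {
      total <- fl + nf
      k <- stats::rmultinom(1, size = events, prob = c(fl, nf) / total)
      c(fl = k[1] / events * total, nf = k[2] / events * total)
    }
    ini <- resample(fl_i, nf_i)
    fin <- resample(fl_f, nf_f)
    fl_i <- ini[["fl"]]; nf_i <- ini[["nf"]]
    fl_f <- fin[["fl"]]; nf_f <- fin[["nf"]]
    if (fl_i <= 0 || nf_i <= 0)
      stop("multinomial sampling produced an empty initial class; ",
           "increase 'events'")
  }
  competition_counts(fl_i, fl_f, nf_i, nf_f, assay_id = assay_id)
}

#' Generate an observed-style frequency trajectory
#'
#' Runs the community engine -- deterministic ([predict_trajectory()]) or with
#' bottleneck drift ([simulate_bottleneck_regime()]) -- and samples the focal
#' frequency at the requested observation times (linear interpolation between
#' engine recording points), emulating the sporadic flow-cytometry
#' measurements of a propagation experiment.
#'
#' @param comm A [community()] (must be non-empty).
#' @param n_transfers Number of serial transfers the propagation spans.
#' @param census_at_transfer Founder cells at each bottleneck (used when
#'   `drift = TRUE`).
#' @param drift Include multinomial bottleneck sampling?
#' @param observation_times Generations at which the focal frequency is
#'   observed; must lie within `[0, n_transfers * generations-per-transfer]`.
#' @param generations_per_cycle Generations of growth per transfer (default
#'   `generations_per_transfer(500)`).
#' @param seed Optional integer seed.
#' @return A `frequency_trajectory` of kind `"observed"` recording the focal
#'   strain only.
#' @export
gen_trajectory <- function(comm, n_transfers, census_at_transfer = od_to_cells(1, 0.2) / 500,
                           drift = TRUE, observation_times = NULL,
                           generations_per_cycle = generations_per_transfer(500),
                           seed = NULL) {
  if (!inherits(comm, "community") || length(comm$strains) < 2L)
    stop("'comm' must be a community with at least 2 strains")
  horizon <- n_transfers * generations_per_cycle
  if (is.null(observation_times))
    observation_times <- seq(0, horizon, by = generations_per_cycle)
  if (any(observation_times < 0) || any(observation_times > horizon + 1e-9))
    stop("'observation_times' must lie within [0, ", signif(horizon, 6), "]")
  observation_times <- sort(unique(observation_times))
  traj <- if (drift) {
    simulate_bottleneck_regime(comm, n_transfers = n_transfers,
                               census_at_transfer = census_at_transfer,
                               growth_generations_per_transfer = generations_per_cycle,
                               seed = seed)
  } else {
    predict_trajectory(comm, horizon = ceiling(horizon), record_every = 1)
  }
  x_obs <- stats::approx(traj$generation, focal_frequencies(traj),
                         xout = observation_times, rule = 2)$y
  freqs <- matrix(x_obs, ncol = 1, dimnames = list(NULL, comm$focal))
  frequency_trajectory(observation_times, freqs, focal = comm$focal,
                       kind = "observed")
}

#' Write a frequency trajectory to CSV
#'
#' Long format: `replicate,generation,focal_frequency`.
#'
#' @param traj A `frequency_trajectory`, or named list of them (names become
#'   replicate labels).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (inherits(traj, "frequency_trajectory")) traj <- list(`1` = traj)
  if (is.null(names(traj))) names(traj) <- seq_along(traj)
  df <- do.call(rbind, Map(function(tr, nm)
    data.frame(replicate = nm, generation = tr$generation,
               focal_frequency = focal_frequencies(tr)),
    traj, names(traj)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read frequency trajectories from CSV
#'
#' @param path CSV with columns `replicate,generation,focal_frequency` (as
#'   written by [write_trajectory()]); a missing `replicate` column is treated
#'   as a single replicate.
#' @param focal Focal strain label to attach (default `"focal"`).
#' @return Named list of `frequency_trajectory` objects of kind `"observed"`.
#' @export
read_trajectory <- function(path, focal = "focal") {
  df <- utils::read.csv(path)
  if (!all(c("generation", "focal_frequency") %in% names(df)))
    stop("trajectory CSV needs columns 'generation' and 'focal_frequency'")
  if (!"replicate" %in% names(df)) df$replicate <- 1
  lapply(split(df, df$replicate), function(g) {
    g <- g[order(g$generation), ]
    freqs <- matrix(g$focal_frequency, ncol = 1, dimnames = list(NULL, focal))
    frequency_trajectory(g$generation, freqs, focal = focal, kind = "observed")
  })
}

#' Generate a synthetic mpileup stream with planted variants
#'
#' Emits one record per position in the 6-column samtools mpileup text
#' dialect (chrom, 1-based position, reference base, depth, read bases, base
#' qualities; `.`/`,` for strand-coded reference matches, upper/lower case
#' for strand-coded mismatches). Planted variants are supported by
#' `variant_fraction` of reads split across both strands -- unless listed in
#' `strand_bias_at`, in which case all supporting reads sit on the forward
#' strand (a typical alignment artifact the downstream filter must reject).
#' Non-variant positions accumulate independent sequencing errors at
#' `error_rate`. With `include_mapq = TRUE` a 7th column of per-read mapping
#' qualities (phred+33) is added (the `samtools mpileup -s` dialect).
#'
#' @param genome_length Number of reference positions (>= 1).
#' @param variant_positions Integer positions of planted SNPs (1-based,
#'   within the genome), or a data.frame with columns `pos`, `alt` (and
#'   optionally `contig`).
#' @param depth Reads per position (>= 1).
#' @param error_rate Per-base sequencing error rate in `[0, 0.5)`.
#' @param strand_bias_at Positions (subset of the variant positions) whose
#'   support is confined to the forward strand.
#' @param seed Optional integer seed.
#' @param contig Contig name for plain integer `variant_positions`.
#' @param variant_fraction Fraction of reads supporting a planted variant
#'   (default 0.9; must be >= the downstream 0.8 threshold to be callable).
#' @param base_quality Phred base quality of emitted bases (default 40).
#' @param mapping_quality Phred mapping quality when `include_mapq` (default 60).
#' @param include_mapq Emit the 7-column dialect with mapping qualities?
#' @return Character vector of mpileup lines (one per position), with
#'   attribute `truth`: data.frame of planted `contig`, `pos`, `ref`, `alt`,
#'   `strand_biased`.
#' @export
gen_pileup <- function(genome_length, variant_positions = integer(),
                       depth = 10, error_rate = 0.01,
                       strand_bias_at = integer(), seed = NULL,
                       contig = "chrI", variant_fraction = 0.9,
                       base_quality = 40, mapping_quality = 60,
                       include_mapq = FALSE) {
  if (genome_length < 1) stop("'genome_length' must be >= 1")
  if (depth < 1) stop("'depth' must be >= 1")
  if (error_rate < 0 || error_rate >= 0.5)
    stop("'error_rate' must be in [0, 0.5)")
  if (is.data.frame(variant_positions)) {
    vp <- variant_positions
    if (!"pos" %in% names(vp)) stop("variant data.frame needs a 'pos' column")
    if (is.null(vp$contig)) vp$contig <- contig
    if (is.null(vp$alt)) vp$alt <- NA_character_
  } else {
    vp <- data.frame(contig = rep(contig, length(variant_positions)),
                     pos = as.integer(variant_positions),
                     alt = rep(NA_character_, length(variant_positions)))
  }
  if (nrow(vp) && any(vp$pos < 1 | vp$pos > genome_length))
    stop("variant positions must lie within the genome")
  if (length(strand_bias_at) && !all(strand_bias_at %in% vp$pos))
    stop("'strand_bias_at' must be a subset of the variant positions")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, genome_length, replace = TRUE)
  qchar <- rawToChar(as.raw(33L + base_quality))
  mchar <- rawToChar(as.raw(33L + mapping_quality))
  depth <- as.integer(depth)

  # strand pattern: balanced forward/reverse, shuffled per position
  n_var <- nrow(vp)
  alt_for <- function(r) sample(setdiff(bases, r), 1)
  if (n_var) {
    vp$ref <- ref[vp$pos]
    fill <- is.na(vp$alt)
    vp$alt[fill] <- vapply(vp$ref[fill], alt_for, character(1))
    if (any(vp$alt == vp$ref))
      stop("a planted alt allele equals the reference base")
    vp$strand_biased <- vp$pos %in% strand_bias_at
  } else {
    vp$ref <- character(0); vp$strand_biased <- logical(0)
  }

  err_mat <- if (error_rate > 0)
    matrix(stats::runif(genome_length * depth) < error_rate,
           nrow = genome_length) else
    matrix(FALSE, nrow = genome_length, ncol = depth)
  err_mat[vp$pos, ] <- FALSE

  lines <- character(genome_length)
  quals <- strrep(qchar, depth)
  mquals <- strrep(mchar, depth)
  n_fwd <- ceiling(depth / 2)
  is_var <- logical(genome_length)
  is_var[vp$pos] <- TRUE
  var_ix <- integer(genome_length)
  var_ix[vp$pos] <- seq_len(max(1L, n_var))
  for (p in seq_len(genome_length)) {
    strands <- sample(rep(c(TRUE, FALSE), c(n_fwd, depth - n_fwd)))
    if (is_var[p]) {
      v <- vp[var_ix[p], ]
      n_sup <- max(1L, round(variant_fraction * depth))
      if (v$strand_biased) {
        # all supporting reads forward; remaining reference reads reverse
        strands <- c(rep(TRUE, n_sup), rep(FALSE, depth - n_sup))
        sup <- seq_len(n_sup)
      } else {
        # support split across strands as evenly as the strand mix allows
        fwd_ix <- which(strands); rev_ix <- which(!strands)
        take_f <- min(length(fwd_ix), ceiling(n_sup / 2))
        take_r <- min(length(rev_ix), n_sup - take_f)
        sup <- c(fwd_ix[seq_len(take_f)], rev_ix[seq_len(take_r)])
      }
      symb <- ifelse(strands, ".", ",")
      symb[sup] <- ifelse(strands[sup], v$alt, tolower(v$alt))
    } else {
      symb <- ifelse(strands, ".", ",")
      errs <- which(err_mat[p, ])
      if (length(errs)) {
        eb <- vapply(errs, function(i) alt_for(ref[p]), character(1))
        symb[errs] <- ifelse(strands[errs], eb, tolower(eb))
      }
    }
    lines[p] <- if (include_mapq)
      paste(contig, p, ref[p], depth, paste(symb, collapse = ""), quals, mquals,
            sep = "\t")
    else
      paste(contig, p, ref[p], depth, paste(symb, collapse = ""), quals,
            sep = "\t")
  }
  attr(lines, "truth") <- vp[, c("contig", "pos", "ref", "alt", "strand_biased")]
  lines
}

#' Write mpileup lines to a file
#'
#' @param lines Character vector from [gen_pileup()] (or any mpileup text).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(lines, path) {
  writeLines(lines, path)
  invisible(path)
}
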