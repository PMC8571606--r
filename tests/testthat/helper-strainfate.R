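# Shared fixtures: closed forms and the experiment's selection coefficients.

# logistic OD(t) with intrinsic rate r, capacity K, inoculum od0
logistic_od <- function(t, r, K = 1, od0 = 0.003) {
  K * od0 * exp(r * t) / (K + od0 * (exp(r * t) - 1))
}

# two-strain replicator closed form: focal frequency after t generations
# against a single competitor of relative fitness w
two_strain_closed_form <- function(x0, w, t) {
  x0 / (x0 + (1 - x0) * w^t)
}

# pairwise selection coefficients of the focal strain vs each competitor
fig_selection <- c(L968 = -0.05, SPW23 = -0.14, R435 = -0.18, NCYC132 = 0.18)

pair_community <- function(s, x0 = 0.5) {
  community(c("focal", "rival"), focal = "focal",
            selection = c(rival = s), initial_focal_frequency = x0)
}

# community of the focal strain plus a subset of the named competitors
subset_community <- function(members, x0 = 0.5) {
  community(c("focal", members), focal = "focal",
            selection = fig_selection[members], initial_focal_frequency = x0)
}

# brute-force two-strain Wright-Fisher serial-transfer oracle:
# deterministic selection w^g then binomial census sampling, until loss
# or fixation of the focal strain; returns TRUE if the focal went extinct
wf_focal_extinct <- function(x0, w, census, g, max_transfers = 1000) {
  x <- x0
  for (k in seq_len(max_transfers)) {
    x <- x / (x + (1 - x) * w^g)
    x <- stats::rbinom(1, census, x) / census
    if (x == 0) return(TRUE)
    if (x == 1) return(FALSE)
  }
  NA
}
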