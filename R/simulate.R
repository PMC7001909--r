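# Stochastic simulation: exact Gillespie paths for validation and a hybrid
# exact/tau-leaping simulator for synthetic cohorts at realistic sizes.

#' Default simulation-study parameter set
#'
#' The biologically motivated rates used throughout the validation study:
#' `mu1 = 3.1`, `b1 = 9`, `d1 = 8.8`, `mu2 = 1e-5`, `b2 = 9.2`, `d2 = 8.8`
#' (net growth rates 0.2 and 0.4 per cell per year).
#' @export
sim_params <- function() model_params(3.1, 9, 8.8, 1e-5, 9.2, 8.8)

#' Exact Gillespie simulation of one individual
#'
#' Simulates the continuous-time Markov jump process exactly and records
#' the compartment sizes at the requested times.
#'
#' @param theta a [model_params()] object.
#' @param t_end final time in years.
#' @param record_times times at which to record the state (default yearly).
#' @param seed optional RNG seed.
#' @param A0,M0 initial compartment sizes.
#' @param max_events guard on the number of simulated events; exceeding it
#'   raises an error suggesting the hybrid simulator.
#' @return data.frame with `time`, `A`, `M`.
#' @export
gillespie_run <- function(theta, t_end, record_times = NULL, seed = NULL,
                          A0 = 0, M0 = 0, max_events = 1e8) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(record_times)) record_times <- seq(0, t_end, by = 1)
  record_times <- sort(record_times)
  res <- gillespie_cpp(as_par_vector(theta), record_times, A0, M0, max_events)
  data.frame(time = record_times, A = res$A, M = res$M)
}

#' Hybrid simulation of a synthetic cohort
#'
#' Each individual is simulated with exact stochastic simulation while both
#' compartments are below `switch_threshold` cells and with tau-leaping
#' (relative propensity change bounded by `eps`) above it; whichever
#' compartment is still small keeps an exact sub-clock inside each leap.  A
#' fraction `lam` of individuals is adenoma-resistant and stays at
#' `A = M = 0`.
#'
#' @param theta a [model_params()] object.
#' @param n number of individuals.
#' @param ages assessment ages: either one age per individual, or a pool
#'   from which each individual's single assessment age is drawn uniformly.
#' @param lam resistant fraction in `[0, 1]`.
#' @param seed optional RNG seed.
#' @param switch_threshold exact-to-tau-leap compartment size threshold.
#' @param eps tau-leap relative propensity-change bound.
#' @param tau_max upper bound on a single leap (years).
#' @return data.frame with `id`, `age`, `A`, `M`, `resistant`.
#' @export
hybrid_cohort <- function(theta, n, ages, lam = 0, seed = NULL,
                          switch_threshold = 300, eps = 0.03,
                          tau_max = 0.25) {
  if (!is.null(seed)) set.seed(seed)
  if (lam < 0 || lam > 1) stop("lam must be in [0, 1]")
  age_i <- if (length(ages) == n) ages else
    ages[sample.int(length(ages), n, replace = TRUE)]
  resistant <- runif(n) < lam
  A <- numeric(n); M <- numeric(n)
  if (any(!resistant)) {
    res <- hybrid_assess_cpp(as_par_vector(theta), age_i[!resistant],
                             switch_threshold, switch_threshold, eps, tau_max)
    A[!resistant] <- res$A; M[!resistant] <- res$M
  }
  data.frame(id = seq_len(n), age = age_i, A = A, M = M,
             resistant = resistant)
}

#' Hybrid simulation with longitudinal records
#'
#' Like [hybrid_cohort()] but every individual is recorded at every time in
#' `record_times` (used by the synthetic registry generator).
#'
#' @inheritParams hybrid_cohort
#' @param record_times sorted recording times in years.
#' @return list with matrices `A`, `M` (`n` rows) and the `resistant` flag.
#' @export
hybrid_trajectories <- function(theta, n, record_times, lam = 0, seed = NULL,
                                switch_threshold = 300, eps = 0.03,
                                tau_max = 0.25) {
  if (!is.null(seed)) set.seed(seed)
  resistant <- runif(n) < lam
  nt <- length(record_times)
  A <- matrix(0, n, nt); M <- matrix(0, n, nt)
  n_sim <- sum(!resistant)
  if (n_sim > 0) {
    res <- hybrid_traj_cpp(as_par_vector(theta), n_sim,
                           sort(record_times), switch_threshold,
                           switch_threshold, eps, tau_max)
    A[!resistant, ] <- res$A; M[!resistant, ] <- res$M
  }
  list(A = A, M = M, resistant = resistant, times = sort(record_times))
}

#' Convert raw cohort sizes to mm-binned observations
#'
#' Mimics how lesions enter endoscopy and registry databases: each
#' compartment size is converted to its equivalent reported dimension,
#' rounded to the nearest mm (0 mm when below the 0.5 mm detection scale),
#' and mapped to a half-open cell-count bin of width +/- 0.5 mm.  Identical
#' rows are aggregated into weights.
#'
#' @param cohort output of [hybrid_cohort()].
#' @param compartments which compartments to emit rows for.
#' @param cells_per_cm3,half_width_mm size-conversion settings.
#' @param max_mm top-coding cap: lesions reported at or above this size go
#'   into the open bin `(max_mm - 0.5, Inf)` mm, mirroring how registries
#'   record rare very large masses.
#' @return a `crc_obs` data.frame.
#' @export
cohort_to_observations <- function(cohort, compartments = c("A", "M"),
                                   cells_per_cm3 = 1e8,
                                   half_width_mm = 0.5, max_mm = 100) {
  pieces <- lapply(compartments, function(cp) {
    counts <- if (cp == "A") cohort$A else cohort$M
    mm <- pmin(round(cells_to_mm(counts, cells_per_cm3)), max_mm)
    data.frame(compartment = cp, age = cohort$age, mm = mm)
  })
  df <- do.call(rbind, pieces)
  agg <- stats::aggregate(list(weight = rep(1, nrow(df))),
                          by = list(compartment = df$compartment,
                                    age = df$age, mm = df$mm), FUN = sum)
  bins <- bin_from_report(agg$mm, half_width_mm, cells_per_cm3)
  bins$upper[agg$mm >= max_mm] <- Inf
  observations(agg$compartment, agg$age, bins$lower, bins$upper, agg$weight)
}

#' Synthetic endoscopy and cancer-registry tables
#'
#' Emulates the structure of endoscopy-procedure and cancer-registry
#' extracts from a simulated cohort: a colonoscopy table of reported
#' adenoma sizes (including zero findings) for the screening ages, a
#' carcinoma size table with one row per incident (first-detected) cancer,
#' and a per-age incidence/at-risk registry table in which previously
#' detected cancers are censored.  The generating truth is returned
#' alongside for recovery tests.
#'
#' @param theta a [model_params()] object.
#' @param n cohort size.
#' @param lam resistant fraction.
#' @param max_age follow-up horizon (years; yearly records).
#' @param scope_ages ages with colonoscopy cross-sections.
#' @param scope_fraction fraction of the cohort scoped at each scope age.
#' @param detect_mm carcinoma detection threshold (reported mm).
#' @param seed optional RNG seed.
#' @param ... further arguments to [hybrid_trajectories()].
#' @return list with `adenoma` (age, size_mm), `cancer` (age, size_mm),
#'   `registry` (age, incident_count, at_risk_count) and `truth`
#'   (parameters plus the true censored-prevalent counts per age).
#' @export
synth_registry <- function(theta, n, lam = 0, max_age = 60,
                           scope_ages = 40:49, scope_fraction = 0.1,
                           detect_mm = 10, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ages <- seq_len(max_age)
  tr <- hybrid_trajectories(theta, n, ages, lam = lam, ...)
  detect_cells <- mm_to_cells(detect_mm)
  detected <- tr$M >= detect_cells
  first <- apply(detected, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  inc_age <- ages[first]

  has <- !is.na(first)
  cancer <- data.frame(
    age = inc_age[has],
    size_mm = round(cells_to_mm(tr$M[cbind(which(has), first[has])])))

  registry <- data.frame(
    age = ages,
    incident_count = vapply(ages, function(a) sum(inc_age == a, na.rm = TRUE),
                            numeric(1)),
    at_risk_count = vapply(ages, function(a)
      sum(is.na(inc_age) | inc_age > a), numeric(1)))

  prevalent <- data.frame(
    age = ages,
    true_prevalent = vapply(ages, function(a)
      sum(inc_age < a, na.rm = TRUE), numeric(1)))

  scope_ages <- intersect(scope_ages, ages)
  aden <- do.call(rbind, lapply(scope_ages, function(a) {
    idx <- which(runif(n) < scope_fraction & (is.na(inc_age) | inc_age > a))
    data.frame(age = a, size_mm = round(cells_to_mm(tr$A[idx, match(a, ages)])))
  }))

  list(adenoma = aden, cancer = cancer, registry = registry,
       truth = list(theta = theta, lam = lam, detect_mm = detect_mm,
                    prevalent = prevalent))
}
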