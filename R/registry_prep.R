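# Registry prevalence imputation and assembly of likelihood-ready
# observation sets from endoscopy / registry tables.

#' Impute censored prevalent cancer cases from incidence data
#'
#' Cancer registries record incident cases `I(t)` and at-risk counts `R(t)`
#' but censor previously diagnosed (prevalent) cases.  Normalizing by the
#' (unknown, possibly varying) total population and iterating
#' `Rhat(t) = Rhat(t-1) * (1 - I(t) / (R(t) + I(t)))` from `Rhat = 1` at
#' the youngest age gives the at-risk proportion; the incident and
#' prevalent proportions follow as `Ihat(t) = Rhat(t-1) - Rhat(t)` and
#' `Phat(t) = 1 - Rhat(t-1)`.  The absolute prevalent count is recovered
#' through the estimated total population `T(t) = I(t) / Ihat(t)`, i.e.
#' `P(t) = I(t) * Phat(t) / Ihat(t)`.
#'
#' @param registry data.frame with columns `age`, `incident_count`,
#'   `at_risk_count` (contiguous ages).
#' @return data.frame with `age`, `R_hat`, `I_hat`, `P_hat`, `P`
#'   (imputed prevalent count) and `T` (estimated total population;
#'   `NA` where no incidence occurred).
#' @export
impute_prevalence <- function(registry) {
  stopifnot(all(c("age", "incident_count", "at_risk_count") %in%
                  names(registry)))
  registry <- registry[order(registry$age), ]
  if (any(diff(registry$age) != 1))
    stop("registry ages must be contiguous")
  I <- registry$incident_count; R <- registry$at_risk_count
  if (any(I < 0) || any(R < 0)) stop("counts must be non-negative")
  if (any(I > 0 & (R + I) <= 0)) stop("incident cases require an at-risk pool")
  n <- nrow(registry)
  R_hat <- I_hat <- P_hat <- P <- Tt <- numeric(n)
  prev <- 1
  for (i in seq_len(n)) {
    frac <- if (R[i] + I[i] > 0) I[i] / (R[i] + I[i]) else 0
    I_hat[i] <- prev * frac
    R_hat[i] <- prev - I_hat[i]
    P_hat[i] <- 1 - prev
    if (I_hat[i] > 0) {
      P[i] <- I[i] * P_hat[i] / I_hat[i]
      Tt[i] <- I[i] / I_hat[i]
    } else {
      P[i] <- 0
      Tt[i] <- NA_real_
    }
    prev <- R_hat[i]
  }
  data.frame(age = registry$age, R_hat = R_hat, I_hat = I_hat,
             P_hat = P_hat, P = P, T = Tt)
}

#' Assemble a likelihood-ready observation set from registry-style tables
#'
#' Adenoma findings (reported mm, 0 for a normal colonoscopy) become
#' compartment-A rows; carcinoma sizes become compartment-M rows binned
#' +/- `half_width_mm`; imputed prevalent cases are added as one weighted
#' compartment-M row per age in the open bin above `prevalent_bin_mm`
#' (their sizes are censored in the registry).
#'
#' @param adenoma data.frame `age`, `size_mm` (may be NULL).
#' @param cancer data.frame `age`, `size_mm` (may be NULL).
#' @param prevalence output of [impute_prevalence()] (may be NULL to skip
#'   prevalent imputation rows).
#' @param age_range optional `c(min, max)`; rows outside are dropped with a
#'   message.
#' @param prevalent_bin_mm lower mm edge of the censored-prevalent bin
#'   (default 40).
#' @param half_width_mm,cells_per_cm3 size-conversion settings.
#' @return a `crc_obs` data.frame.
#' @export
build_observations <- function(adenoma = NULL, cancer = NULL,
                               prevalence = NULL, age_range = NULL,
                               prevalent_bin_mm = 40, half_width_mm = 0.5,
                               cells_per_cm3 = 1e8) {
  clip <- function(df) {
    if (is.null(df) || is.null(age_range)) return(df)
    keep <- df$age >= age_range[1] & df$age <= age_range[2]
    if (any(!keep))
      message("dropping ", sum(!keep), " rows outside the age window")
    df[keep, , drop = FALSE]
  }
  adenoma <- clip(adenoma); cancer <- clip(cancer)
  pieces <- list()
  mk <- function(df, cp) {
    agg <- stats::aggregate(list(weight = rep(1, nrow(df))),
                            by = list(age = df$age, mm = df$size_mm),
                            FUN = sum)
    bins <- bin_from_report(agg$mm, half_width_mm, cells_per_cm3)
    observations(cp, agg$age, bins$lower, bins$upper, agg$weight)
  }
  if (!is.null(adenoma) && nrow(adenoma) > 0)
    pieces$A <- mk(adenoma, "A")
  if (!is.null(cancer) && nrow(cancer) > 0)
    pieces$M <- mk(cancer, "M")
  if (!is.null(prevalence)) {
    pv <- if (!is.null(age_range))
      prevalence[prevalence$age >= age_range[1] &
                   prevalence$age <= age_range[2], , drop = FALSE]
    else prevalence
    w <- round(pv$P)
    keep <- w >= 1
    if (any(keep))
      pieces$prev <- observations("M", pv$age[keep],
                                  mm_to_cells(prevalent_bin_mm,
                                              cells_per_cm3),
                                  Inf, w[keep])
  }
  if (length(pieces) == 0)
    return(observations(character(), numeric(), numeric(), numeric(),
                        numeric()))
  validate_observations(do.call(rbind, pieces))
}
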