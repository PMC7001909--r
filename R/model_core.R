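#' Model parameters of the two-type branching process
#'
#' Bundles the six per-year rates of the process and derives the two net
#' growth rates.  `mu1` is the adenoma initiation (immigration) rate in cells
#' per year; all other rates are per cell per year.
#'
#' @param mu1 adenoma initiation rate (cells/year), immigration into A.
#' @param b1,d1 birth and death rate of adenoma cells.
#' @param mu2 adenoma-to-carcinoma transformation rate.
#' @param b2,d2 birth and death rate of malignant cells.
#' @param d_equal logical flag recording the `d1 == d2` restriction used for
#'   registry-style fits; purely informational, the rates themselves govern
#'   all computations.
#' @return An object of class `crc_params`: a list with the six rates plus
#'   derived `gamma1 = b1 - d1` and `gamma2 = b2 - d2`.
#' @examples
#' theta <- model_params(mu1 = 3.1, b1 = 9, d1 = 8.8,
#'                       mu2 = 1e-5, b2 = 9.2, d2 = 8.8)
#' theta$gamma1  # 0.2
#' @export
model_params <- function(mu1, b1, d1, mu2 = 0, b2 = 0, d2 = 0,
                         d_equal = FALSE) {
  rates <- c(mu1 = mu1, b1 = b1, d1 = d1, mu2 = mu2, b2 = b2, d2 = d2)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and non-negative")
  out <- as.list(rates)
  out$gamma1 <- b1 - d1
  out$gamma2 <- b2 - d2
  out$d_equal <- isTRUE(d_equal)
  class(out) <- "crc_params"
  out
}

#' @export
print.crc_params <- function(x, ...) {
  cat("Two-type branching process rates (per year):\n")
  cat(sprintf("  A: mu1 = %g, b1 = %g, d1 = %g  (gamma1 = %g)\n",
              x$mu1, x$b1, x$d1, x$gamma1))
  cat(sprintf("  M: mu2 = %g, b2 = %g, d2 = %g  (gamma2 = %g)\n",
              x$mu2, x$b2, x$d2, x$gamma2))
  invisible(x)
}

as_par_vector <- function(theta) {
  stopifnot(inherits(theta, "crc_params"))
  c(theta$mu1, theta$b1, theta$d1, theta$mu2, theta$b2, theta$d2)
}

#' Convert a reported lesion diameter to a cell count
#'
#' Endoscopists report the largest lesion dimension in mm.  Lesions are
#' treated as half-ellipsoids with all three semi-axes equal to half the
#' reported dimension, i.e. volume `pi * d^3 / 12`, and tissue is taken to
#' hold `cells_per_cm3` cells per cubic centimetre (default 1e8).
#'
#' @param d reported diameter(s) in mm.
#' @param cells_per_cm3 packing density, cells per cm^3.
#' @return Integer-valued cell counts (rounded half up), same length as `d`.
#' @examples
#' mm_to_cells(10)   # ~2.618e7 cells
#' @export
mm_to_cells <- function(d, cells_per_cm3 = 1e8) {
  if (any(!is.finite(d) & !is.infinite(d)) || any(d < 0))
    stop("diameter must be non-negative")
  out <- cells_per_cm3 * (pi / 12) * (d / 10)^3
  ifelse(is.infinite(out), out, floor(out + 0.5))
}

#' Inverse of [mm_to_cells()]: equivalent reported diameter of a cell count
#' @param n cell count(s).
#' @inheritParams mm_to_cells
#' @return Diameter in mm (continuous, not rounded).
#' @export
cells_to_mm <- function(n, cells_per_cm3 = 1e8) {
  if (any(n < 0)) stop("cell count must be non-negative")
  10 * (12 * n / (pi * cells_per_cm3))^(1 / 3)
}

#' Cell-count bin of a reported mm size
#'
#' Registry sizes are recorded to the nearest mm, so a reported size `m`
#' stands for the interval `m +/- half_width_mm`.  Bins are half-open
#' `(L, U]` in cells; a reported 0 (normal colonoscopy, nothing detected)
#' yields a bin that contains 0 cells, encoded with `lower = -1`.
#'
#' @param reported_mm reported size(s) in mm; may be `Inf` for an open upper
#'   bound (not usual; see `upper_mm`).
#' @param half_width_mm half-width of the reporting bin (default 0.5 mm).
#' @inheritParams mm_to_cells
#' @return data.frame with columns `lower` and `upper` (cells); `lower = -1`
#'   encodes a zero-containing bin.
#' @examples
#' bin_from_report(10)        # (mm_to_cells(9.5), mm_to_cells(10.5)]
#' bin_from_report(0)$lower   # -1: the bin contains a lesion-free finding
#' @export
bin_from_report <- function(reported_mm, half_width_mm = 0.5,
                            cells_per_cm3 = 1e8) {
  if (any(reported_mm < 0)) stop("reported size must be non-negative")
  if (half_width_mm <= 0) stop("half_width_mm must be positive")
  lo_mm <- pmax(reported_mm - half_width_mm, 0)
  lower <- mm_to_cells(lo_mm, cells_per_cm3)
  upper <- mm_to_cells(reported_mm + half_width_mm, cells_per_cm3)
  lower[reported_mm == 0] <- -1
  if (any(lower >= upper)) stop("degenerate bin: lower >= upper")
  data.frame(lower = lower, upper = upper)
}

#' Build a size-binned observation set
#'
#' One row per (possibly weighted) lesion finding: the compartment it refers
#' to (`"A"` adenoma, `"M"` carcinoma), the age at observation and the
#' half-open cell-count bin `(lower, upper]`.  `lower = -1` marks a bin that
#' contains 0 cells (a lesion-free finding), which is where the
#' resistant-fraction mixture of [mixture_likelihood()] applies.
#'
#' @param compartment character vector of "A"/"M".
#' @param age ages in years (> 0).
#' @param lower,upper cell-count bounds; `upper` may be `Inf`.
#' @param weight positive integer multiplicities (default 1).
#' @return A `crc_obs` data.frame.
#' @export
observations <- function(compartment, age, lower, upper, weight = 1) {
  obs <- data.frame(compartment = as.character(compartment),
                    age = as.numeric(age),
                    lower = as.numeric(lower),
                    upper = as.numeric(upper),
                    weight = as.numeric(weight))
  validate_observations(obs)
}

#' @rdname observations
#' @param obs a data.frame to check and stamp as `crc_obs`.
#' @export
validate_observations <- function(obs) {
  stopifnot(is.data.frame(obs),
            all(c("compartment", "age", "lower", "upper", "weight") %in%
                  names(obs)))
  if (!all(obs$compartment %in% c("A", "M")))
    stop("compartment must be 'A' or 'M'")
  if (any(obs$age <= 0)) stop("age must be positive")
  if (any(obs$lower < -1)) stop("lower must be >= -1 (-1 encodes a zero bin)")
  if (any(obs$lower >= obs$upper)) stop("degenerate bin: lower >= upper")
  if (any(obs$weight < 1) || any(obs$weight != floor(obs$weight)))
    stop("weight must be a positive integer")
  class(obs) <- c("crc_obs", "data.frame")
  obs
}

#' Read / write observation CSV files
#'
#' Two schemas are accepted by `read_observations()`:
#' cell-level `compartment,age_years,lower_cells,upper_cells,weight`
#' (`upper_cells` may be the literal `inf`), or mm-level
#' `compartment,age_years,size_mm` which is converted through
#' [bin_from_report()].
#'
#' @param path CSV file path.
#' @param half_width_mm,cells_per_cm3 passed to [bin_from_report()] for
#'   mm-level input.
#' @return A `crc_obs` data.frame.
#' @export
read_observations <- function(path, half_width_mm = 0.5,
                              cells_per_cm3 = 1e8) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("size_mm" %in% names(df)) {
    bins <- bin_from_report(df$size_mm, half_width_mm, cells_per_cm3)
    obs <- data.frame(compartment = df$compartment, age = df$age_years,
                      lower = bins$lower, upper = bins$upper,
                      weight = if ("weight" %in% names(df)) df$weight else 1)
  } else {
    up <- df$upper_cells
    if (is.character(up)) up <- ifelse(tolower(up) == "inf", Inf, as.numeric(up))
    obs <- data.frame(compartment = df$compartment, age = df$age_years,
                      lower = as.numeric(df$lower_cells), upper = up,
                      weight = if ("weight" %in% names(df)) df$weight else 1)
  }
  validate_observations(obs)
}

#' @rdname read_observations
#' @param obs a `crc_obs` data.frame.
#' @export
write_observations <- function(obs, path) {
  obs <- validate_observations(obs)
  out <- data.frame(compartment = obs$compartment, age_years = obs$age,
                    lower_cells = obs$lower,
                    upper_cells = ifelse(is.infinite(obs$upper), "inf",
                                         obs$upper),
                    weight = obs$weight)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
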