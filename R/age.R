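# Moment-based allele-age estimation with demographic calibration.
#
# Association between a mutation and a linked marker allele decays by a
# factor (1 - theta) per generation, so the observed Bengtsson-Thomson
# delta dates the founder event: g = log(delta) / log(1 - theta).  Because
# the mutation-bearing lineage grew from a single chromosome, most extant
# copies are recent and the naive estimator is biased young; the
# Luria-Delbrueck correction -(1/r) ln(theta/r) compensates under
# exponential lineage growth at rate r.

#' Exponential population growth rate
#'
#' Solves `T1 = T0 * exp(g * r)` for the per-generation growth rate:
#' `r = ln(T1/T0) / g`.
#'
#' @param T0 ancestral population size.
#' @param T1 present population size.
#' @param g_demo generations elapsed between the two census points.
#' @return Growth rate per generation.
#' @examples
#' growth_rate(3e6, 60e6, 100.48)  # ~0.03
#' @export
growth_rate <- function(T0, T1, g_demo) {
  if (T0 <= 0 || T1 <= 0 || g_demo <= 0) stop("T0, T1 and g_demo must be positive")
  log(T1 / T0) / g_demo
}

#' Sampled fraction of mutation-bearing chromosomes
#'
#' Estimates `f`, the proportion of all mutation-bearing chromosomes in the
#' population that entered the sample:
#' `f = sampled / (male_population * disease_incidence * mutation_fraction)`,
#' where the denominator is the expected number of carrier chromosomes
#' (hemizygous males) in the population.
#'
#' @param male_population number of males in the population.
#' @param disease_incidence disease frequency per male birth.
#' @param mutation_fraction proportion of disease attributable to this
#'   mutation.
#' @param sampled_chromosomes number of carrier chromosomes sampled.
#' @return The fraction `f` in (0, 1\].
#' @examples
#' sampled_fraction(28e6, 1/5000, 0.076, 24)  # ~0.06
#' @export
sampled_fraction <- function(male_population, disease_incidence,
                             mutation_fraction, sampled_chromosomes) {
  if (male_population <= 0 || disease_incidence <= 0 || mutation_fraction <= 0)
    stop("population, incidence and mutation fraction must be positive")
  if (sampled_chromosomes < 0) stop("sampled_chromosomes must be non-negative")
  f <- sampled_chromosomes / (male_population * disease_incidence * mutation_fraction)
  if (f > 1) stop("sampled chromosomes exceed the estimated carrier count (f > 1)")
  f
}

#' Demographic model for age calibration
#'
#' Bundles the census calibration of the growth rate with the
#' generation-time convention.
#'
#' @inheritParams growth_rate
#' @param years_per_generation years per generation (default 25).
#' @return List of class `demographic_model` with `T0`, `T1`, `g_demo`,
#'   `r`, `years_per_generation`.
#' @export
demographic_model <- function(T0, T1, g_demo, years_per_generation = 25) {
  if (years_per_generation <= 0) stop("years_per_generation must be positive")
  structure(list(T0 = T0, T1 = T1, g_demo = g_demo,
                 r = growth_rate(T0, T1, g_demo),
                 years_per_generation = years_per_generation),
            class = "demographic_model")
}

#' Moment estimator of allele age
#'
#' `g = log(delta) / log(1 - theta)`: the number of generations over which
#' association decaying by `(1 - theta)` per generation reaches the
#' observed `delta`.  Base-invariant (any logarithm base gives the same
#' ratio).  `delta = 1` gives age 0; `delta <= 0` leaves the estimator
#' undefined and raises an error of class `founderage_undefined_age`.
#'
#' @param delta Bengtsson-Thomson delta, in (0, 1\].
#' @param theta recombination fraction, in (0, 1).
#' @return Age in generations (uncorrected).
#' @examples
#' moment_age(0.85, 0.0031)  # 52.3
#' @export
moment_age <- function(delta, theta) {
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)")
  if (delta > 1) stop("delta must not exceed 1")
  if (delta <= 0)
    stop(errorCondition("age undefined for delta <= 0 (no residual association)",
                        class = "founderage_undefined_age"))
  log(delta) / log(1 - theta)
}

#' Luria-Delbrueck growth correction
#'
#' Additive correction `-(1/r) * ln(theta / r)` (generations) for the
#' growth of the mutation-bearing lineage: sampling extant carriers of an
#' exponentially growing clone over-weights recent branches, so the naive
#' moment age underestimates; this term compensates.  It vanishes when
#' `theta = r` and grows as the marker gets closer to the mutation.
#'
#' @param theta recombination fraction (> 0).
#' @param r lineage growth rate per generation (> 0).
#' @return Correction in generations.
#' @examples
#' luria_delbruck_correction(0.0031, 0.03)  # 75.7
#' @export
luria_delbruck_correction <- function(theta, r) {
  if (theta <= 0 || r <= 0) stop("theta and r must be positive")
  -(1 / r) * log(theta / r)
}

#' Corrected allele age at one marker
#'
#' Total age = moment estimate + Luria-Delbrueck correction, with the
#' years conversion.
#'
#' @inheritParams moment_age
#' @param r growth rate per generation.
#' @param years_per_generation years per generation.
#' @param marker optional marker label.
#' @return Object of class `age_estimate`: list with `marker`, `delta`,
#'   `theta`, `g_uncorrected`, `correction`, `g_total`, `years`.
#' @examples
#' corrected_age(0.85, 0.0031, r = 0.03)  # 128 generations, 3200 years
#' @export
corrected_age <- function(delta, theta, r = 0.03, years_per_generation = 25,
                          marker = NA_character_) {
  g0 <- moment_age(delta, theta)
  corr <- luria_delbruck_correction(theta, r)
  g <- g0 + corr
  structure(list(marker = marker, delta = delta, theta = theta,
                 g_uncorrected = g0, correction = corr, g_total = g,
                 years = generations_to_years(g, years_per_generation)),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("Age at %s: delta = %.3f, theta = %.4f -> %.2f + %.2f = %.2f generations (%.0f years)\n",
              if (is.na(x$marker)) "marker" else x$marker, x$delta, x$theta,
              x$g_uncorrected, x$correction, x$g_total, x$years))
  invisible(x)
}

#' Convert generations to years
#'
#' @param g generations.
#' @param years_per_generation years per generation (default 25).
#' @return Years.
#' @export
generations_to_years <- function(g, years_per_generation = 25) {
  if (years_per_generation <= 0) stop("years_per_generation must be positive")
  g * years_per_generation
}

#' Per-marker age table
#'
#' Applies the corrected moment estimator marker by marker, feeding each
#' marker's exact-count delta and map-derived theta.  Markers whose delta
#' is undefined or non-positive get `NA` ages with a note.
#'
#' @param assoc an [association_table()].
#' @param map the [marker_map].
#' @param r growth rate per generation.
#' @param years_per_generation years per generation.
#' @return data.frame of class `age_table`, one row per marker: `marker`,
#'   `theta`, `delta`, `g_uncorrected`, `correction`, `g_total`, `years`,
#'   `note`.
#' @export
age_table <- function(assoc, map, r = 0.03, years_per_generation = 25) {
  stopifnot(inherits(assoc, "association_table"), inherits(map, "marker_map"))
  theta <- map$theta[match(assoc$marker, map$name)]
  rows <- lapply(seq_len(nrow(assoc)), function(i) {
    d <- assoc$delta[i]
    if (is.na(d) || d <= 0)
      return(data.frame(marker = assoc$marker[i], theta = theta[i], delta = d,
                        g_uncorrected = NA_real_, correction = NA_real_,
                        g_total = NA_real_, years = NA_real_,
                        note = "age undefined (delta <= 0 or fixed allele)"))
    a <- corrected_age(d, theta[i], r, years_per_generation, assoc$marker[i])
    data.frame(marker = a$marker, theta = a$theta, delta = a$delta,
               g_uncorrected = a$g_uncorrected, correction = a$correction,
               g_total = a$g_total, years = a$years,
               note = if (a$g_total < 0)
                 "negative corrected age (theta > r: correction dominates)"
               else "")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("age_table", "data.frame")
  out
}
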