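# Per-marker allelic association between the mutation and marker alleles:
# allele proportions, difference-in-proportions (Wald) test, Fisher's exact
# test, and the Bengtsson-Thomson linkage-disequilibrium delta.

#' Allele counts on disease and normal chromosomes
#'
#' Counts chromosomes carrying a given allele at a given marker, separately
#' for the disease and control groups.  Chromosomes missing the allele at
#' that marker are excluded from that marker's denominators only (pairwise
#' deletion).
#'
#' @param table a [chromosome_table].
#' @param marker marker name.
#' @param allele fragment length (bp).
#' @return Named integer vector `c(k_D, n_D, k_N, n_N)`: carriers/total on
#'   disease and normal (control) chromosomes.
#' @export
allele_proportions <- function(table, marker, allele) {
  stopifnot(inherits(table, "chromosome_table"))
  if (!marker %in% table$map$name) stop("unknown marker: ", marker)
  g <- table$records$group
  x <- table$records[[marker]]
  ok <- !is.na(x)
  c(k_D = sum(x[ok & g == "disease"] == allele),
    n_D = sum(ok & g == "disease"),
    k_N = sum(x[ok & g == "control"] == allele),
    n_N = sum(ok & g == "control"))
}

#' Difference in allele proportions with Wald interval and Z-test
#'
#' Tests whether an allele is more frequent on disease than on normal
#' chromosomes: `delta_p = p_D - p_N` with the Wald 95% interval
#' `delta_p +/- z * sqrt(p_D(1-p_D)/n_D + p_N(1-p_N)/n_N)`.  The two-sided
#' p-value follows the classical two-proportion Z-test, whose standard
#' error pools the groups under the null of equal proportions:
#' `Z = delta_p / sqrt(p(1-p)(1/n_D + 1/n_N))` with
#' `p = (k_D + k_N)/(n_D + n_N)`.  No continuity correction is applied.
#'
#' @param k_D,n_D allele carriers / total disease chromosomes.
#' @param k_N,n_N same for normal chromosomes.
#' @param conf_level confidence level (default 0.95, i.e. z = 1.96).
#' @return List with `p_D`, `p_N`, `delta_p`, `ci_low`, `ci_high`, `z`,
#'   `p_value`.
#' @examples
#' diff_proportions_test(21, 24, 16, 96)  # delta_p 0.708, CI 0.556-0.860
#' @export
diff_proportions_test <- function(k_D, n_D, k_N, n_N, conf_level = 0.95) {
  if (n_D <= 0 || n_N <= 0) stop("zero denominator in proportion test")
  p_D <- k_D / n_D
  p_N <- k_N / n_N
  dp <- p_D - p_N
  se <- sqrt(p_D * (1 - p_D) / n_D + p_N * (1 - p_N) / n_N)
  # conventional z = 1.96 at the 95% level (the field's reporting habit),
  # exact normal quantile otherwise
  zq <- if (abs(conf_level - 0.95) < 1e-12) 1.96
        else stats::qnorm(1 - (1 - conf_level) / 2)
  pp <- (k_D + k_N) / (n_D + n_N)
  se0 <- sqrt(pp * (1 - pp) * (1 / n_D + 1 / n_N))
  if (se0 == 0) {
    z <- if (dp == 0) 0 else sign(dp) * Inf
  } else z <- dp / se0
  list(p_D = p_D, p_N = p_N, delta_p = dp,
       ci_low = dp - zq * se, ci_high = dp + zq * se,
       z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Bengtsson-Thomson linkage-disequilibrium delta
#'
#' `delta = (p_D - p_N) / (1 - p_N)`: the excess frequency of the associated
#' allele on disease chromosomes, normalised by its room to increase.  Under
#' complete association (every disease chromosome carries the allele)
#' `delta = 1`; negative values indicate the allele is rarer on disease
#' chromosomes.  Undefined when the allele is fixed in controls
#' (`p_N = 1`); this is signalled as an error of class
#' `founderage_undefined_delta`.
#'
#' @inheritParams diff_proportions_test
#' @return The delta statistic (scalar).
#' @examples
#' bt_delta(23, 24, 29, 96)  # 0.940
#' @export
bt_delta <- function(k_D, n_D, k_N, n_N) {
  if (n_D <= 0 || n_N <= 0) stop("zero denominator in delta")
  p_D <- k_D / n_D
  p_N <- k_N / n_N
  if (p_N >= 1)
    stop(errorCondition("delta undefined: allele fixed on normal chromosomes (p_N = 1)",
                        class = "founderage_undefined_delta"))
  (p_D - p_N) / (1 - p_N)
}

#' Bootstrap confidence interval for delta
#'
#' Nonparametric bootstrap of the Bengtsson-Thomson delta: chromosomes are
#' resampled with replacement within group (equivalently, carrier counts are
#' redrawn binomially at the observed proportions), and percentile bounds
#' taken over the resampled deltas.  Resamples with the allele fixed in the
#' control group (delta undefined) are dropped.
#'
#' @inheritParams diff_proportions_test
#' @param n_boot number of bootstrap resamples.
#' @param conf_level confidence level.
#' @return List with `ci_low`, `ci_high`, `n_dropped`.
#' @export
bt_delta_ci <- function(k_D, n_D, k_N, n_N, n_boot = 10000, conf_level = 0.95) {
  kD <- rbinom(n_boot, n_D, k_D / n_D)
  kN <- rbinom(n_boot, n_N, k_N / n_N)
  ok <- kN < n_N
  d <- (kD[ok] / n_D - kN[ok] / n_N) / (1 - kN[ok] / n_N)
  a <- (1 - conf_level) / 2
  q <- quantile(d, c(a, 1 - a), names = FALSE)
  list(ci_low = q[1L], ci_high = q[2L], n_dropped = sum(!ok))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value under the hypergeometric null with both margins
#' fixed, using the minimum-likelihood convention: the p-value is the sum of
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table (with relative
#' tolerance 1e-7 on the comparison, so ties are counted).  This is the
#' most common two-sided convention; alternatives (doubling the smaller
#' tail) can give different values.
#'
#' @param x 2x2 matrix of non-negative integer counts with positive row and
#'   column margins.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(2, 1, 1, 2), 2))  # 1
#' @export
fisher_exact <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L))) stop("x must be a 2x2 table")
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  rs <- rowSums(x); cs <- colSums(x)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate table: zero row or column margin")
  lo <- max(0L, cs[1L] - rs[2L])
  hi <- min(cs[1L], rs[1L])
  supp <- lo:hi
  pr <- dhyper(supp, rs[1L], rs[2L], cs[1L])
  p_obs <- pr[supp == x[1L, 1L]]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

#' Per-marker association table against the ancestral haplotype
#'
#' Builds the full association summary: for each marker, the ancestral
#' allele's counts and proportions on disease vs normal chromosomes, the
#' Wald difference-in-proportions test, the Bengtsson-Thomson delta, and a
#' seeded bootstrap percentile interval for delta.
#'
#' @param table a [chromosome_table] containing both groups.
#' @param ancestral the founder haplotype; inferred when omitted.
#' @param n_boot bootstrap resamples for the delta interval (0 to skip).
#' @param conf_level confidence level for all intervals.
#' @param boot_seed seed for the bootstrap (local RNG stream; the caller's
#'   RNG state is untouched).
#' @return data.frame of class `association_table`, one row per marker in
#'   map order with columns `marker`, `allele`, `k_D`, `n_D`, `k_N`, `n_N`,
#'   `p_D`, `p_N`, `delta_p`, `ci_low`, `ci_high`, `p_value`, `delta`,
#'   `delta_ci_low`, `delta_ci_high`.
#' @examples
#' map <- read_marker_map(founder_example("xq28_marker_map.tsv"))
#' tab <- read_chromosomes(c(founder_example("xq28_disease_chromosomes.tsv"),
#'                           founder_example("xq28_control_chromosomes_synthetic.tsv")),
#'                         map)
#' at <- association_table(tab)
#' round(at$delta, 3)
#' @export
association_table <- function(table, ancestral = infer_ancestral(table),
                              n_boot = 10000, conf_level = 0.95,
                              boot_seed = 1L) {
  stopifnot(inherits(table, "chromosome_table"))
  if (table$n_control == 0L)
    stop("association requires control chromosomes (none present)")
  if (table$n_disease == 0L)
    stop("association requires disease chromosomes (none present)")
  rows <- lapply(table$map$name, function(mk) {
    al <- as.integer(ancestral[[mk]])
    k <- allele_proportions(table, mk, al)
    dt <- diff_proportions_test(k["k_D"], k["n_D"], k["k_N"], k["n_N"], conf_level)
    del <- tryCatch(bt_delta(k["k_D"], k["n_D"], k["k_N"], k["n_N"]),
                    founderage_undefined_delta = function(e) NA_real_)
    dci <- c(NA_real_, NA_real_)
    if (n_boot > 0 && !is.na(del)) {
      ci <- with_local_seed(boot_seed, bt_delta_ci(k["k_D"], k["n_D"], k["k_N"],
                                                   k["n_N"], n_boot, conf_level))
      dci <- c(ci$ci_low, ci$ci_high)
    }
    data.frame(marker = mk, allele = al,
               k_D = k[["k_D"]], n_D = k[["n_D"]],
               k_N = k[["k_N"]], n_N = k[["n_N"]],
               p_D = dt$p_D, p_N = dt$p_N, delta_p = dt$delta_p,
               ci_low = dt$ci_low, ci_high = dt$ci_high,
               p_value = dt$p_value, delta = del,
               delta_ci_low = dci[1L], delta_ci_high = dci[2L])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("association_table", "data.frame")
  out
}

# run expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
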