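# Forward-time branching-process simulation of founder-haplotype decay.
#
# A single founder chromosome carrying the mutation expands as a Poisson
# branching process (each carrier leaves Poisson(exp(r)) copies per
# generation); every transmission is a meiosis in which marker alleles can
# recombine against a background allele pool.  The lineage is conditioned on
# being ascertainable today: runs where it dies out, or ends smaller than
# the requested sample, are restarted.  Disease chromosomes are sampled
# without replacement from the present-day lineage; controls are drawn
# i.i.d. from the background pool.

#' Simulation configuration
#'
#' @param map a [marker_map].
#' @param founder_haplotype [infer_ancestral()]-style haplotype carried by
#'   the founder chromosome (named integer vector in map order).
#' @param background_freqs per-marker allele frequency spectra: a named
#'   list (one element per marker, map order) of named numeric vectors
#'   (allele bp -> probability, summing to 1).  See
#'   [background_from_controls()].
#' @param g true mutation age in generations (>= 0).
#' @param r lineage growth rate per generation.
#' @param n_disease,n_control chromosomes sampled at present.
#' @param recomb_model `"per_marker_independent"` (each marker allele is
#'   independently replaced with probability theta per meiosis) or
#'   `"haldane_map"` (crossover points placed as a Poisson process on the
#'   Haldane-transformed map; alleles distal to an odd number of crossovers
#'   relative to the mutation are replaced from one background chromosome).
#'   Both give single-marker replacement probability exactly theta.
#' @param slippage_rate optional per-marker, per-meiosis stepwise mutation
#'   rate (one repeat unit up or down); default 0.
#' @param max_restarts restart budget for extinct / under-sized lineages.
#' @param pop_cap optional ceiling on the tracked carrier population
#'   (default `Inf`, the exact branching process).  When finite, the
#'   lineage is uniformly downsampled to the cap each generation once it
#'   exceeds it.  Per-chromosome marker retention is unchanged (every
#'   sampled chromosome still undergoes exactly `g` meioses); only the
#'   coancestry of the sample increases slightly, which widens summary
#'   statistics' spread.  Used to keep large validation runs cheap; must be
#'   at least `n_disease`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(map, founder_haplotype, background_freqs,
                       g, r = 0.03, n_disease = 24, n_control = 96,
                       recomb_model = c("per_marker_independent", "haldane_map"),
                       slippage_rate = 0, max_restarts = 1000,
                       pop_cap = Inf) {
  stopifnot(inherits(map, "marker_map"),
            identical(names(founder_haplotype), map$name),
            g >= 0, r > 0 || g == 0, n_disease >= 1, n_control >= 0,
            slippage_rate >= 0, slippage_rate <= 1, pop_cap >= n_disease)
  recomb_model <- match.arg(recomb_model)
  if (!is.list(background_freqs) ||
      !identical(names(background_freqs), map$name))
    stop("background_freqs must be a named list with one spectrum per marker, in map order")
  for (m in map$name) {
    s <- background_freqs[[m]]
    if (is.null(names(s)) || any(s < 0) || abs(sum(s) - 1) > 1e-9)
      stop("background spectrum for ", m,
           " must be a named non-negative vector summing to 1")
  }
  structure(list(map = map,
                 founder_haplotype = as.integer(founder_haplotype),
                 background_freqs = background_freqs, g = as.integer(g),
                 r = r, n_disease = as.integer(n_disease),
                 n_control = as.integer(n_control),
                 recomb_model = recomb_model, slippage_rate = slippage_rate,
                 max_restarts = max_restarts, pop_cap = pop_cap),
            class = "sim_config")
}

#' Empirical background spectra from control chromosomes
#'
#' Fits per-marker allele frequency spectra from the control group of a
#' chromosome table, for use as [sim_config()] background.
#'
#' @param table a [chromosome_table] with control chromosomes.
#' @return Named list of per-marker named frequency vectors.
#' @export
background_from_controls <- function(table) {
  stopifnot(inherits(table, "chromosome_table"))
  a <- allele_matrix(table, "control")
  if (!nrow(a)) stop("no control chromosomes to fit background spectra from")
  out <- lapply(seq_len(ncol(a)), function(j) {
    x <- a[, j]; x <- x[!is.na(x)]
    tab <- table(x)
    setNames(as.numeric(tab) / sum(tab), names(tab))
  })
  names(out) <- table$map$name
  out
}

# --- internal simulation core (matrices only, no data.frame overhead) ----

# Batch-simulate lineage-size trajectories until one survives to generation
# g with at least n_min chromosomes.  Returns list(z = trajectory of length
# g + 1 with z[1] = 1, restarts = failed attempts before the success).
sim_trajectory <- function(g, r, n_min, max_restarts, pop_cap = Inf,
                           batch = 32L) {
  if (g == 0L) return(list(z = 1L, restarts = 0L))
  er <- exp(r)
  failed <- 0L
  repeat {
    Z <- matrix(0L, nrow = batch, ncol = g + 1L)
    Z[, 1L] <- 1L
    for (t in seq_len(g)) {
      zt <- rpois(batch, Z[, t] * er)
      if (any(zt > 5e6))
        stop("lineage exceeded 5e6 chromosomes; reduce g * r or set pop_cap")
      Z[, t + 1L] <- if (is.finite(pop_cap)) pmin(zt, as.integer(pop_cap)) else zt
    }
    ok <- which(Z[, g + 1L] >= n_min)
    if (length(ok)) {
      restarts <- failed + ok[1L] - 1L
      if (restarts > max_restarts)
        stop("lineage extinct or smaller than the requested sample in ",
             restarts, " attempts (max_restarts = ", max_restarts, ")")
      return(list(z = Z[ok[1L], ], restarts = restarts))
    }
    failed <- failed + batch
    if (failed > max_restarts)
      stop("lineage extinct or smaller than the requested sample in ",
           failed, " attempts (max_restarts = ", max_restarts, ")")
  }
}

# draw n alleles from a named spectrum (safe for single-allele spectra)
draw_background <- function(spec, n) {
  alleles <- as.integer(names(spec))
  if (length(alleles) == 1L) return(rep(alleles, n))
  as.integer(sample(alleles, n, replace = TRUE, prob = spec))
}

# apply one generation of meioses to pop (n x m matrix), returning offspring
# alleles after recombination (and optional slippage)
meiose <- function(pop, config) {
  n <- nrow(pop); m <- ncol(pop)
  map <- config$map
  if (config$recomb_model == "per_marker_independent") {
    for (j in seq_len(m)) {
      hit <- runif(n) < map$theta[j]
      if (any(hit))
        pop[hit, j] <- draw_background(config$background_freqs[[j]], sum(hit))
    }
  } else {
    # Haldane map: transform each marker's theta back to map distance
    # d = -ln(1 - 2 theta)/2 Morgans so that P(odd crossovers) = theta
    # exactly; crossovers on each side of the mutation share one Poisson
    # process, so replacement is correlated along an arm.
    mut <- attr(map, "mutation_position_mb")
    d <- -log(1 - 2 * map$theta) / 2
    side <- sign(map$position_mb - mut)
    repl <- matrix(FALSE, n, m)
    for (s in c(-1, 1)) {
      js <- which(side == s)
      if (!length(js)) next
      js <- js[order(d[js])]
      inc <- diff(c(0, d[js]))
      cross <- matrix(rpois(n * length(js), rep(inc, each = n)), nrow = n)
      parity <- (t(apply(cross, 1L, cumsum)) %% 2L) == 1L
      if (length(js) == 1L) parity <- matrix(parity, ncol = 1L)
      repl[, js] <- parity
    }
    if (any(repl)) {
      # replaced alleles come from one background chromosome per meiosis
      bg <- vapply(seq_len(m),
                   function(j) draw_background(config$background_freqs[[j]], n),
                   integer(n))
      if (n == 1L) bg <- matrix(bg, nrow = 1L)
      pop[repl] <- bg[repl]
    }
  }
  if (config$slippage_rate > 0) {
    step <- rep(2L, m)
    if (!is.null(map$repeat_unit)) {
      ru <- nchar(as.character(map$repeat_unit))
      step[!is.na(ru)] <- ru[!is.na(ru)]
    }
    slip <- matrix(runif(n * m) < config$slippage_rate, n, m)
    if (any(slip)) {
      dir <- sample(c(-1L, 1L), sum(slip), replace = TRUE)
      pop[slip] <- pop[slip] + dir * rep(step, each = n)[slip]
    }
  }
  pop
}

# core forward simulation; returns matrices + trajectory
simulate_core <- function(config) {
  g <- config$g
  m <- nrow(config$map)
  if (g == 0L) {
    # age zero: every carrier chromosome *is* the founder chromosome
    dis <- matrix(config$founder_haplotype, nrow = config$n_disease,
                  ncol = m, byrow = TRUE)
    traj <- 1L
    restarts <- 0L
  } else {
    tr <- sim_trajectory(g, config$r, config$n_disease, config$max_restarts,
                         config$pop_cap)
    z <- tr$z
    restarts <- tr$restarts
    pop <- matrix(config$founder_haplotype, nrow = 1L, ncol = m)
    for (t in seq_len(g)) {
      parents <- sample.int(nrow(pop), z[t + 1L], replace = TRUE)
      pop <- meiose(pop[parents, , drop = FALSE], config)
    }
    dis <- pop[sample.int(nrow(pop), config$n_disease), , drop = FALSE]
    traj <- z
  }
  ctl <- vapply(seq_len(m),
                function(j) draw_background(config$background_freqs[[j]],
                                            config$n_control),
                integer(config$n_control))
  if (config$n_control == 1L) ctl <- matrix(ctl, nrow = 1L)
  if (config$n_control == 0L) ctl <- matrix(integer(0), 0L, m)
  colnames(dis) <- colnames(ctl) <- config$map$name
  list(disease = dis, control = ctl, trajectory = traj, restarts = restarts)
}

# per-marker delta-hat from allele matrices, ancestral allele = founder's;
# NA where the founder allele is fixed among controls
delta_hat_matrices <- function(dis, ctl, founder) {
  vapply(seq_along(founder), function(j) {
    pD <- mean(dis[, j] == founder[j])
    pN <- mean(ctl[, j] == founder[j])
    if (pN >= 1) return(NA_real_)
    (pD - pN) / (1 - pN)
  }, numeric(1L))
}

#' Simulate a synthetic disease/control cohort
#'
#' Runs the forward branching-process model from a single founder
#' chromosome for `g` generations and samples a present-day cohort.  Fully
#' reproducible from `seed`; the caller's RNG state is left untouched.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return Object of class `sim_result`: list with `table` (a
#'   [chromosome_table] of sampled disease + control chromosomes), `true_g`,
#'   `lineage_trajectory` (carrier count per generation, starting at the
#'   single founder), `restarts`, `seed`.
#' @examples
#' map <- read_marker_map(founder_example("xq28_marker_map.tsv"))
#' tab <- read_chromosomes(c(founder_example("xq28_disease_chromosomes.tsv"),
#'                           founder_example("xq28_control_chromosomes_synthetic.tsv")),
#'                         map)
#' cfg <- sim_config(map, infer_ancestral(tab), background_from_controls(tab),
#'                   g = 50, r = 0.1)
#' sim <- simulate_cohort(cfg, seed = 1)
#' sim$table$n_disease
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  core <- with_local_seed(seed, simulate_core(config))
  nd <- nrow(core$disease); nc <- nrow(core$control)
  rec <- data.frame(
    sample_id = c(sprintf("SIMD%04d", seq_len(nd)), sprintf("SIMC%04d", seq_len(nc))),
    family_id = c(sprintf("SIMFD%04d", seq_len(nd)), sprintf("SIMFC%04d", seq_len(nc))),
    group = rep(c("disease", "control"), c(nd, nc)),
    stringsAsFactors = FALSE)
  rec <- cbind(rec, as.data.frame(rbind(core$disease, core$control)))
  structure(list(table = chromosome_table(config$map, rec),
                 true_g = config$g,
                 lineage_trajectory = core$trajectory,
                 restarts = core$restarts, seed = seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Simulated cohort: true g = %d, lineage %d -> %d chromosomes (%d restart(s)), seed %d\n",
              x$true_g, x$lineage_trajectory[1L],
              x$lineage_trajectory[length(x$lineage_trajectory)],
              x$restarts, x$seed))
  print(x$table)
  invisible(x)
}

#' Parameter-recovery experiment for the age estimators
#'
#' Simulates `n_reps` cohorts at a known age and re-estimates the age from
#' each via the association + age-estimation pipeline (per-marker delta-hat
#' fed to the moment estimator, optionally with the Luria-Delbrueck
#' correction; markers with undefined or non-positive delta-hat are dropped
#' within a replicate, and a replicate with no usable marker is excluded).
#' Replicate `k` runs on a seed drawn from a stream seeded with `seed`, so
#' the experiment is reproducible and replicates are independent.
#'
#' @param config a [sim_config()] carrying the true age `g`.
#' @param n_reps number of replicates (>= 2).
#' @param estimator `"moment"` (uncorrected) or `"corrected"`.
#' @param seed master seed.
#' @return Object of class `recovery_experiment`: list with `estimates`
#'   (per-replicate mean age over usable markers), `true_g`, `bias`,
#'   `rmse`, `median`, `interval` (empirical 2.5/97.5% quantiles),
#'   `n_excluded`.
#' @export
recovery_experiment <- function(config, n_reps, estimator = c("moment", "corrected"),
                                seed = 1L) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 2)
  estimator <- match.arg(estimator)
  rep_seeds <- with_local_seed(seed, sample.int(2^31 - 2, n_reps))
  est <- vapply(seq_len(n_reps), function(k) {
    core <- with_local_seed(rep_seeds[k], simulate_core(config))
    dh <- delta_hat_matrices(core$disease, core$control, config$founder_haplotype)
    ok <- !is.na(dh) & dh > 0
    if (!any(ok)) return(NA_real_)
    g_hat <- log(dh[ok]) / log(1 - config$map$theta[ok])
    if (estimator == "corrected")
      g_hat <- g_hat + vapply(config$map$theta[ok], luria_delbruck_correction,
                              numeric(1L), r = config$r)
    mean(g_hat)
  }, numeric(1L))
  excl <- sum(is.na(est))
  use <- est[!is.na(est)]
  structure(list(estimates = est, true_g = config$g, estimator = estimator,
                 bias = mean(use) - config$g,
                 rmse = sqrt(mean((use - config$g)^2)),
                 median = stats::median(use),
                 interval = quantile(use, c(0.025, 0.975), names = FALSE),
                 n_excluded = excl, n_reps = n_reps, seed = seed),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf("Recovery of g = %d (%s estimator, %d replicates, %d excluded)\n",
              x$true_g, x$estimator, x$n_reps, x$n_excluded))
  cat(sprintf("  bias %.2f, RMSE %.2f, median %.2f, empirical 95%% interval [%.1f, %.1f]\n",
              x$bias, x$rmse, x$median, x$interval[1L], x$interval[2L]))
  invisible(x)
}

#' Rejection-ABC posterior for the mutation age
#'
#' Likelihood-free Bayesian inference of the age: for each candidate age on
#' `g_grid` (uniform prior), cohorts are simulated and accepted when the
#' Euclidean distance between the simulated and observed per-marker
#' delta-hat vectors is at most `tolerance`.  Acceptance frequencies,
#' normalised, form the posterior; the credible interval is read off the
#' posterior quantiles.
#'
#' @param observed a [chromosome_table] with disease and control
#'   chromosomes (the data to match).
#' @param config_template a [sim_config()] supplying map, founder
#'   haplotype, background, growth rate and sample sizes; its `g` is
#'   ignored.
#' @param g_grid candidate ages (generations).
#' @param n_sims_per_g simulations per grid point.
#' @param tolerance acceptance radius on the delta-hat summary vector.
#' @param seed integer seed.
#' @param conf_level credible level (default 0.95).
#' @return Object of class `abc_posterior`: list with `g_grid`, `weights`,
#'   `n_accepted`, `posterior_mean`, `credible_interval`, `tolerance`.
#' @export
abc_posterior <- function(observed, config_template, g_grid, n_sims_per_g,
                          tolerance, seed = 1L, conf_level = 0.95) {
  stopifnot(inherits(observed, "chromosome_table"),
            inherits(config_template, "sim_config"), length(g_grid) >= 1L,
            n_sims_per_g >= 1L, tolerance >= 0)
  dis <- allele_matrix(observed, "disease")
  ctl <- allele_matrix(observed, "control")
  dis <- dis[rowSums(is.na(dis)) == 0L, , drop = FALSE]
  ctl <- ctl[rowSums(is.na(ctl)) == 0L, , drop = FALSE]
  obs <- delta_hat_matrices(dis, ctl, config_template$founder_haplotype)
  acc <- with_local_seed(seed, {
    vapply(g_grid, function(g) {
      cfg <- config_template
      cfg$g <- as.integer(g)
      hits <- 0L
      for (k in seq_len(n_sims_per_g)) {
        core <- tryCatch(simulate_core(cfg), error = function(e) NULL)
        if (is.null(core)) next
        dh <- delta_hat_matrices(core$disease, core$control,
                                 cfg$founder_haplotype)
        ok <- !is.na(dh) & !is.na(obs)
        if (!all(!is.na(obs) == ok)) next  # sim undefined where obs defined
        dist <- sqrt(sum((dh[ok] - obs[ok])^2))
        if (dist <= tolerance) hits <- hits + 1L
      }
      hits
    }, integer(1L))
  })
  if (sum(acc) == 0L)
    stop("no simulations accepted; increase tolerance or n_sims_per_g")
  w <- acc / sum(acc)
  a <- (1 - conf_level) / 2
  cw <- cumsum(w)
  ci <- c(g_grid[which(cw >= a)[1L]], g_grid[which(cw >= 1 - a)[1L]])
  structure(list(g_grid = g_grid, weights = w, n_accepted = acc,
                 posterior_mean = sum(w * g_grid), credible_interval = ci,
                 tolerance = tolerance, seed = seed),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("ABC posterior over %d ages (%d acceptances, tolerance %.3g)\n",
              length(x$g_grid), sum(x$n_accepted), x$tolerance))
  cat(sprintf("  posterior mean %.1f generations, credible interval [%d, %d]\n",
              x$posterior_mean, x$credible_interval[1L], x$credible_interval[2L]))
  invisible(x)
}
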