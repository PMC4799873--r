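# founder_fit: the package's central model object.  One call runs the full
# founder-effect analysis (haplotype grouping -> association -> linkage ->
# age estimation) and returns a classed object with the usual modelling
# methods.

#' Fit the founder-effect model to a disease/control cohort
#'
#' Runs the complete analysis on a [chromosome_table]: infers the ancestral
#' haplotype, groups disease chromosomes into haplotypes, computes
#' per-marker allelic association (difference in proportions, Fisher's
#' exact test on haplotype carriage, Bengtsson-Thomson delta), two-point
#' LOD linkage (optionally with a tight marker cluster treated as one
#' locus), and the Luria-Delbrueck-corrected moment age at every marker.
#'
#' @param table a [chromosome_table] with disease and control chromosomes.
#' @param r lineage/population growth rate per generation (default 0.03).
#' @param years_per_generation years per generation (default 25).
#' @param cluster optional character vector of marker names treated jointly
#'   as a single linkage locus.
#' @param n_boot bootstrap resamples for delta intervals (0 to skip).
#' @param conf_level confidence level for intervals.
#' @param boot_seed seed for the delta bootstrap.
#' @return Object of class `founder_fit`: list with elements `table`,
#'   `ancestral`, `haplotypes` ([group_haplotypes()]), `carriage` (2x2
#'   carriage table over all disease haplotypes), `fisher_p`, `association`
#'   ([association_table()]), `linkage` ([linkage_table()]), `ages`
#'   ([age_table()]), `r`, `years_per_generation`, `call`.
#' @examples
#' map <- read_marker_map(founder_example("xq28_marker_map.tsv"))
#' tab <- read_chromosomes(c(founder_example("xq28_disease_chromosomes.tsv"),
#'                           founder_example("xq28_control_chromosomes_synthetic.tsv")),
#'                         map)
#' fit <- founder_fit(tab, cluster = c("STR24", "STR22", "STR13"))
#' fit
#' @export
founder_fit <- function(table, r = 0.03, years_per_generation = 25,
                        cluster = NULL, n_boot = 10000, conf_level = 0.95,
                        boot_seed = 1L) {
  stopifnot(inherits(table, "chromosome_table"))
  anc <- infer_ancestral(table)
  hap <- group_haplotypes(table, anc)
  carriage <- carriage_contingency(hap, table, hap$table$label)
  fisher_p <- fisher_exact(carriage)
  assoc <- association_table(table, anc, n_boot = n_boot,
                             conf_level = conf_level, boot_seed = boot_seed)
  link <- linkage_table(table, anc, cluster = cluster)
  ages <- age_table(assoc, table$map, r = r,
                    years_per_generation = years_per_generation)
  structure(list(table = table, ancestral = anc, haplotypes = hap,
                 carriage = carriage, fisher_p = fisher_p,
                 association = assoc, linkage = link, ages = ages,
                 cluster = cluster, r = r,
                 years_per_generation = years_per_generation,
                 call = match.call()),
            class = "founder_fit")
}

#' @export
print.founder_fit <- function(x, ...) {
  cat("Founder-effect analysis\n")
  cat(sprintf("  %d disease / %d control chromosomes, %d markers\n",
              x$table$n_disease, x$table$n_control, nrow(x$table$map)))
  cat("  Ancestral haplotype:",
      paste(names(x$ancestral), as.integer(x$ancestral), sep = ":",
            collapse = " "), "\n")
  cat(sprintf("  Modal haplotype H1: %d/%d (%.0f%%); Fisher carriage p = %.3g\n",
              x$haplotypes$table$count[1L], x$haplotypes$n,
              100 * x$haplotypes$table$frequency[1L], x$fisher_p))
  best <- which.max(vapply(x$linkage, `[[`, numeric(1L), "lod_max"))
  cat(sprintf("  Max LOD: %.2f at theta = %.2f (%s)\n",
              x$linkage[[best]]$lod_max, x$linkage[[best]]$theta_max,
              x$linkage[[best]]$locus))
  g <- x$ages$g_total[!is.na(x$ages$g_total) & x$ages$note == ""]
  if (length(g))
    cat(sprintf("  Corrected moment age: %.1f-%.1f generations (%.0f-%.0f years; %d marker(s) flagged)\n",
                min(g), max(g), min(g) * x$years_per_generation,
                max(g) * x$years_per_generation,
                sum(!is.na(x$ages$g_total) & x$ages$note != "")))
  invisible(x)
}

#' @export
summary.founder_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.founder_fit")
}

#' @export
print.summary.founder_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nHaplotypes (disease chromosomes):\n")
  print(f$haplotypes)
  cat("\nAllelic association (ancestral allele per marker):\n")
  a <- f$association
  a[, c("p_D", "p_N", "delta_p", "ci_low", "ci_high", "delta")] <-
    round(a[, c("p_D", "p_N", "delta_p", "ci_low", "ci_high", "delta")], 3)
  a$p_value <- signif(a$p_value, 3)
  print(as.data.frame(a[, c("marker", "allele", "p_D", "p_N", "delta_p",
                            "ci_low", "ci_high", "p_value", "delta")]),
        row.names = FALSE)
  cat("\nTwo-point linkage:\n")
  for (l in f$linkage) print(l)
  cat("\nAge estimates:\n")
  ag <- f$ages
  ag[, c("g_uncorrected", "correction", "g_total")] <-
    round(ag[, c("g_uncorrected", "correction", "g_total")], 2)
  ag$years <- round(ag$years)
  ag$delta <- round(ag$delta, 3)
  print(as.data.frame(ag), row.names = FALSE)
  invisible(x)
}

#' @export
coef.founder_fit <- function(object, ...) {
  setNames(object$association$delta, object$association$marker)
}

#' @export
plot.founder_fit <- function(x, which = c("lod", "posterior"), ...) {
  which <- match.arg(which)
  curves <- lapply(x$linkage, `[[`, "lod_curve")
  ylim <- range(unlist(lapply(curves, `[[`, "lod")), 0, finite = TRUE)
  plot(NA, xlim = c(0, 0.5), ylim = ylim, xlab = "recombination fraction theta",
       ylab = "LOD", main = "Two-point LOD curves", ...)
  for (i in seq_along(curves))
    lines(curves[[i]]$theta, curves[[i]]$lod, col = i, lty = 1)
  abline(h = c(LOD_LINKAGE_THRESHOLD, LOD_EXCLUSION_THRESHOLD), lty = 3)
  legend("topright", legend = names(x$linkage), col = seq_along(curves),
         lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}

#' Simulate cohorts from a fitted founder model
#'
#' Draws synthetic cohorts whose generating parameters mirror the fit: the
#' founder haplotype is the fitted ancestral haplotype, the background pool
#' is the empirical control spectrum, sample sizes match the data, and the
#' age defaults to the fitted mean corrected age.
#'
#' @param object a [founder_fit].
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param g true age for the simulation (defaults to the rounded mean
#'   fitted corrected age).
#' @param r growth rate (defaults to the fit's).
#' @param ... passed to [sim_config()].
#' @return List of [simulate_cohort()] results (length `nsim`).
#' @export
simulate.founder_fit <- function(object, nsim = 1, seed = 1L, g = NULL,
                                 r = NULL, ...) {
  if (is.null(g)) g <- round(mean(object$ages$g_total, na.rm = TRUE))
  if (is.null(r)) r <- object$r
  cfg <- sim_config(object$table$map, object$ancestral,
                    background_from_controls(object$table),
                    g = g, r = r, n_disease = object$table$n_disease,
                    n_control = object$table$n_control, ...)
  seeds <- with_local_seed(seed, sample.int(2^31 - 2, nsim))
  lapply(seeds, function(s) simulate_cohort(cfg, s))
}

# fixed-decimal formatting used by all report writers
fmt <- function(x, digits) ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))

#' Write the report tables of a fitted founder model
#'
#' Emits four tab-separated files into `dir`: `haplotypes.tsv` (haplotype
#' grouping with counts and frequencies), `association.tsv` (proportions,
#' Wald intervals, p-values, delta with bootstrap interval),
#' `linkage.tsv` (NR/R, theta_max, max LOD per locus; a footnote comment
#' records that the cluster row is the sum of member LODs at a shared
#' theta), and `ages.tsv` (per-marker corrected ages).  Proportions and
#' delta are printed with 3 decimals, LOD and generations with 2; column
#' order is fixed, so identical fits produce byte-identical files.
#'
#' @param fit a [founder_fit].
#' @param dir output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_report_tables <- function(fit, dir) {
  stopifnot(inherits(fit, "founder_fit"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  paths <- character(0)

  h <- fit$haplotypes$table
  h$frequency <- fmt(h$frequency, 3)
  p <- file.path(dir, "haplotypes.tsv")
  write.table(h, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  a <- as.data.frame(fit$association)
  for (col in c("p_D", "p_N", "delta_p", "ci_low", "ci_high", "delta",
                "delta_ci_low", "delta_ci_high"))
    a[[col]] <- fmt(a[[col]], 3)
  a$p_value <- signif(a$p_value, 4)
  p <- file.path(dir, "association.tsv")
  write.table(a, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  l <- do.call(rbind, lapply(fit$linkage, function(r)
    data.frame(locus = r$locus, NR = r$NR, R = r$R,
               theta_max = fmt(r$theta_max, 2), lod_max = fmt(r$lod_max, 2))))
  p <- file.path(dir, "linkage.tsv")
  con <- file(p, "w")
  writeLines(paste("# cluster rows report the sum of member LOD curves",
                   "maximised at a shared theta"), con)
  write.table(l, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  paths <- c(paths, p)

  g <- as.data.frame(fit$ages)
  g$delta <- fmt(g$delta, 3)
  for (col in c("g_uncorrected", "correction", "g_total"))
    g[[col]] <- fmt(g[[col]], 2)
  g$years <- fmt(g$years, 0)
  g$theta <- fmt(g$theta, 4)
  p <- file.path(dir, "ages.tsv")
  write.table(g, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  invisible(paths)
}

#' Run the full analysis pipeline on input files
#'
#' Reads the marker map and chromosome files, fits the founder model, and
#' writes the four report tables plus a JSON run manifest
#' (`manifest.json`: input digests, package version, seed, parameters,
#' timestamp).  Re-running on identical inputs reproduces all tables
#' byte-identically (only the manifest timestamp differs).  Any stage
#' failure aborts with the failing stage named.
#'
#' @param chrom_path character vector of chromosome TSV paths.
#' @param map_path marker map TSV path.
#' @param out_dir output directory.
#' @param r growth rate per generation.
#' @param years_per_generation years per generation.
#' @param cluster marker names treated as one linkage locus (NULL for
#'   none).
#' @param n_boot bootstrap resamples for delta intervals.
#' @param seed seed for the bootstrap.
#' @param verbose emit progress messages.
#' @return The [founder_fit], invisibly.
#' @export
run_all <- function(chrom_path, map_path, out_dir, r = 0.03,
                    years_per_generation = 25,
                    cluster = NULL, n_boot = 10000, seed = 1L,
                    verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    say("stage ", name, " ...")
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }
  map <- stage("cohort_io", read_marker_map(map_path))
  tab <- stage("cohort_io", read_chromosomes(chrom_path, map))
  say("  ", tab$n_disease, " disease + ", tab$n_control, " control chromosomes")
  anc <- stage("haplotype_analysis", infer_ancestral(tab))
  hap <- stage("haplotype_analysis", group_haplotypes(tab, anc))
  assoc <- stage("allelic_association",
                 association_table(tab, anc, n_boot = n_boot, boot_seed = seed))
  link <- stage("linkage_lod", linkage_table(tab, anc, cluster = cluster))
  ages <- stage("age_estimation",
                age_table(assoc, map, r = r,
                          years_per_generation = years_per_generation))
  fit <- structure(list(table = tab, ancestral = anc, haplotypes = hap,
                        carriage = carriage_contingency(hap, tab, hap$table$label),
                        fisher_p = NA_real_, association = assoc,
                        linkage = link, ages = ages, cluster = cluster,
                        r = r, years_per_generation = years_per_generation,
                        call = match.call()),
                   class = "founder_fit")
  fit$fisher_p <- stage("allelic_association", fisher_exact(fit$carriage))
  paths <- stage("report", write_report_tables(fit, out_dir))
  manifest <- list(
    inputs = as.list(setNames(unname(tools::md5sum(c(chrom_path, map_path))),
                              basename(c(chrom_path, map_path)))),
    package_version = as.character(packageVersion("founderage")),
    seed = seed,
    parameters = list(r = r, years_per_generation = years_per_generation,
                      cluster = cluster, n_boot = n_boot),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("wrote ", length(paths) + 1L, " files to ", out_dir)
  invisible(fit)
}
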