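# Two-point LOD-score linkage between the mutation and each marker.
#
# Unrelated disease chromosomes sharing / not sharing the ancestral allele
# at a marker are treated as nonrecombinant / recombinant descendants of the
# founder chromosome.  This is the classical two-point phase-known LOD, not
# a pedigree likelihood: each chromosome contributes one informative
# "meiosis" from the founder.

#' LOD-score classification thresholds
#'
#' Conventional decision bounds for two-point linkage: LOD above
#' `LOD_LINKAGE_THRESHOLD` (3, i.e. 1000:1 odds) is taken as evidence for
#' linkage; LOD below `LOD_EXCLUSION_THRESHOLD` (-2) excludes it.
#'
#' @format Numeric constants.
#' @export
LOD_LINKAGE_THRESHOLD <- 3

#' @rdname LOD_LINKAGE_THRESHOLD
#' @export
LOD_EXCLUSION_THRESHOLD <- -2

#' Two-point LOD score
#'
#' `LOD(theta) = NR log10(1-theta) + R log10(theta) + (NR+R) log10(2)`,
#' the log10 likelihood ratio of linkage at recombination fraction `theta`
#' against free recombination (`theta = 0.5`).  Computed as
#' `NR log10(2(1-theta)) + R log10(2 theta)` so that the value at
#' `theta = 0.5` is exactly zero.  At `theta = 0` the score is
#' `NR log10(2)` when `R = 0` and `-Inf` when `R > 0` (a recombinant is
#' impossible under complete linkage).
#'
#' @param NR nonrecombinant count.
#' @param R recombinant count.
#' @param theta recombination fraction(s) in \[0, 0.5\]; vectorised.
#' @return LOD score(s).
#' @examples
#' lod(18, 6, 0.25)  # 1.36
#' @export
lod <- function(NR, R, theta) {
  stopifnot(NR >= 0, R >= 0, all(theta >= 0), all(theta <= 0.5))
  nr_term <- NR * log10(2 * (1 - theta))
  r_term <- ifelse(theta == 0, if (R == 0) 0 else -Inf, R * log10(2 * theta))
  nr_term + r_term
}

#' Count nonrecombinant and recombinant disease chromosomes at a marker
#'
#' A disease chromosome is nonrecombinant at a marker when it carries the
#' ancestral allele there, recombinant otherwise; chromosomes missing the
#' marker are excluded.  One chromosome per family is counted.
#'
#' @param table a [chromosome_table].
#' @param ancestral the founder haplotype.
#' @param marker marker name.
#' @return Named integer vector `c(NR, R)`.
#' @export
count_recombinants <- function(table, ancestral, marker) {
  stopifnot(inherits(table, "chromosome_table"))
  if (!marker %in% table$map$name) stop("unknown marker: ", marker)
  table <- dedupe_families(table)
  x <- table$records[[marker]][table$records$group == "disease"]
  x <- x[!is.na(x)]
  c(NR = sum(x == as.integer(ancestral[[marker]])),
    R = sum(x != as.integer(ancestral[[marker]])))
}

#' Maximise the two-point LOD over theta
#'
#' The maximum-likelihood recombination fraction has the closed form
#' `theta_max = R / (NR + R)` (the binomial MLE), clamped to \[0, 0.5\]; the
#' maximum LOD is the score there.  A reporting curve over a theta grid is
#' attached.
#'
#' @param NR,R nonrecombinant / recombinant counts, `NR + R > 0`.
#' @param locus label for the result.
#' @param grid theta grid for the reported curve.
#' @return Object of class `linkage_result`: list with `locus`, `NR`, `R`,
#'   `theta_max`, `lod_max`, `lod_curve` (data.frame `theta`, `lod`).
#' @examples
#' maximize_lod(21, 3)  # theta_max 0.125, LOD 3.30
#' @export
maximize_lod <- function(NR, R, locus = NA_character_,
                         grid = seq(0.01, 0.5, by = 0.01)) {
  stopifnot(NR >= 0, R >= 0, NR + R > 0)
  th <- min(max(R / (NR + R), 0), 0.5)
  structure(list(locus = locus, NR = as.integer(NR), R = as.integer(R),
                 theta_max = th, lod_max = lod(NR, R, th),
                 lod_curve = data.frame(theta = grid, lod = lod(NR, R, grid))),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("Two-point linkage at %s: NR = %d, R = %d, theta_max = %.3f, max LOD = %.2f\n",
              if (is.na(x$locus)) "locus" else x$locus, x$NR, x$R,
              x$theta_max, x$lod_max))
  invisible(x)
}

#' Joint LOD for a cluster of tightly linked markers
#'
#' Markers separated by negligible distance (here, the intragenic STRs) can
#' be treated as a single locus.  The cluster score is the *sum* of the
#' member LOD curves, maximised at a shared theta; the summed log-likelihood
#' is again of two-point form in the pooled counts, so
#' `theta_max = sum(R) / sum(NR + R)` analytically.  With identical member
#' counts this equals `members x` the single-marker maximum at the common
#' `R/(NR+R)`.
#'
#' @param results list of [maximize_lod()] results for the member markers.
#' @param label cluster label.
#' @return A `linkage_result` for the cluster (NR, R are pooled counts;
#'   `lod_max` is the summed score at the shared maximiser).
#' @export
cluster_lod <- function(results, label = NULL) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1L), "linkage_result")))
  if (length(results) == 1L) return(results[[1L]])
  NRs <- vapply(results, `[[`, integer(1L), "NR")
  Rs <- vapply(results, `[[`, integer(1L), "R")
  th <- min(max(sum(Rs) / sum(NRs + Rs), 0), 0.5)
  grid <- results[[1L]]$lod_curve$theta
  curve <- Reduce(`+`, lapply(results, function(r) r$lod_curve$lod))
  if (is.null(label))
    label <- paste(vapply(results, `[[`, character(1L), "locus"), collapse = "/")
  structure(list(locus = label, NR = sum(NRs), R = sum(Rs),
                 theta_max = th,
                 lod_max = sum(vapply(results, function(r) lod(r$NR, r$R, th),
                                      numeric(1L))),
                 lod_curve = data.frame(theta = grid, lod = curve)),
            class = "linkage_result")
}

#' Per-marker (and cluster) linkage table
#'
#' Runs [count_recombinants()] + [maximize_lod()] for every marker of the
#' map, and optionally adds a joint row for a marker cluster.
#'
#' @param table a [chromosome_table].
#' @param ancestral founder haplotype; inferred when omitted.
#' @param cluster character vector of marker names to also report as a
#'   single locus (NULL for none).
#' @return List of `linkage_result` objects, named by locus.
#' @export
linkage_table <- function(table, ancestral = infer_ancestral(table),
                          cluster = NULL) {
  res <- lapply(table$map$name, function(mk) {
    k <- count_recombinants(table, ancestral, mk)
    maximize_lod(k[["NR"]], k[["R"]], locus = mk)
  })
  names(res) <- table$map$name
  if (!is.null(cluster)) {
    missing <- setdiff(cluster, table$map$name)
    if (length(missing)) stop("cluster markers not in map: ",
                              paste(missing, collapse = ", "))
    cl <- cluster_lod(res[cluster])
    res[[cl$locus]] <- cl
  }
  res
}
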