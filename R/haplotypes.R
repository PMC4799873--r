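# Ancestral-haplotype inference and haplotype grouping on disease
# chromosomes.

#' Infer the ancestral (founder) haplotype
#'
#' The founder haplotype is estimated as the marker-wise modal allele among
#' the disease chromosomes: under a founder effect most mutation-bearing
#' chromosomes still carry the founder allele at tightly linked markers, so
#' the mode at each marker recovers the founder state.  Ties are broken
#' deterministically in favour of the smallest fragment length.
#'
#' Chromosomes with any missing allele are excluded (a partial haplotype
#' cannot vote consistently), as are second and further chromosomes from the
#' same family (see Details of [group_haplotypes()]).
#'
#' @param table a [chromosome_table] with at least one complete disease
#'   chromosome.
#' @return Object of class `haplotype`: a named integer vector of alleles in
#'   map order.
#' @examples
#' fit_tab <- read_chromosomes(founder_example("xq28_disease_chromosomes.tsv"),
#'                             read_marker_map(founder_example("xq28_marker_map.tsv")))
#' infer_ancestral(fit_tab)
#' @export
infer_ancestral <- function(table) {
  stopifnot(inherits(table, "chromosome_table"))
  a <- complete_disease_alleles(table)
  if (!nrow(a)) stop("no complete disease chromosomes to infer an ancestral haplotype from")
  anc <- apply(a, 2L, function(col) {
    tab <- table(col)
    alleles <- as.integer(names(tab))
    # modal allele; ties -> smallest fragment length
    min(alleles[tab == max(tab)])
  })
  structure(as.integer(anc), names = colnames(a), class = "haplotype")
}

#' @export
print.haplotype <- function(x, ...) {
  lab <- attr(x, "label")
  cat("Haplotype", if (!is.null(lab)) paste0("(", lab, ")") else "", "\n")
  print(setNames(as.integer(x), names(x)))
  invisible(x)
}

# complete-genotype disease chromosomes, one per family
complete_disease_alleles <- function(table) {
  table <- dedupe_families(table)
  a <- allele_matrix(table, "disease")
  complete <- rowSums(is.na(a)) == 0L
  n_excl <- sum(!complete)
  if (n_excl) message(n_excl, " disease chromosome(s) with missing alleles excluded from haplotype grouping")
  a[complete, , drop = FALSE]
}

#' Group disease chromosomes into haplotypes
#'
#' Distinct complete haplotypes among the disease chromosomes are counted
#' and labelled `H1`, `H2`, ... by descending count; ties among equal counts
#' are ordered lexicographically by allele vector, so labels never depend on
#' input record order.  Each haplotype is also classified by its number of
#' marker mismatches against the ancestral haplotype, the natural measure of
#' how far recombination (or slippage) has eroded the founder state.
#'
#' One chromosome per family enters the grouping: unrelated index
#' chromosomes are the unit of independent descent from the founder.
#' Chromosomes with missing alleles are excluded with a message.
#'
#' @param table a [chromosome_table].
#' @param ancestral the founder [infer_ancestral()] haplotype; inferred from
#'   `table` when omitted.
#' @return Object of class `haplotype_summary`: list with `table` (label,
#'   per-marker alleles, count, frequency, mismatches), `ancestral`, `n`
#'   (complete disease chromosomes), `n_excluded`.
#' @export
group_haplotypes <- function(table, ancestral = infer_ancestral(table)) {
  stopifnot(inherits(table, "chromosome_table"), inherits(ancestral, "haplotype"))
  if (!identical(names(ancestral), table$map$name))
    stop("ancestral haplotype markers do not match the table's map")
  a <- complete_disease_alleles(table)
  if (!nrow(a)) stop("no complete disease chromosomes to group")
  key <- apply(a, 1L, paste, collapse = "/")
  counts <- table(key)
  uniq <- a[!duplicated(key), , drop = FALSE]
  ukey <- key[!duplicated(key)]
  cnt <- as.integer(counts[ukey])
  # order: descending count, then lexicographic allele vector
  ord <- do.call(order, c(list(-cnt), as.data.frame(uniq)))
  uniq <- uniq[ord, , drop = FALSE]
  cnt <- cnt[ord]
  mism <- colSums(t(uniq) != as.integer(ancestral))
  out <- data.frame(label = paste0("H", seq_along(cnt)), uniq,
                    count = cnt, frequency = cnt / sum(cnt),
                    mismatches = as.integer(mism),
                    check.names = FALSE, row.names = NULL)
  structure(list(table = out, ancestral = ancestral, n = sum(cnt),
                 n_excluded = table$n_disease - sum(cnt)),
            class = "haplotype_summary")
}

#' @export
print.haplotype_summary <- function(x, ...) {
  cat(sprintf("Haplotype grouping of %d disease chromosomes (%d excluded)\n",
              x$n, x$n_excluded))
  df <- x$table
  df$frequency <- sprintf("%d/%d (%.0f%%)", df$count, x$n, 100 * df$frequency)
  print(df[, setdiff(names(df), "count")], row.names = FALSE)
  cat("Ancestral haplotype:", paste(as.integer(x$ancestral), collapse = " "), "\n")
  invisible(x)
}

#' Haplotype-carriage contingency table
#'
#' Cross-tabulates carriage of a chosen set of haplotypes against
#' disease/control status, for Fisher's exact test of whether the
#' mutation-associated haplotypes are absent from the population sample.
#' A control chromosome "carries" a haplotype when its complete allele
#' vector matches exactly.
#'
#' @param summary a [group_haplotypes()] result.
#' @param controls a [chromosome_table] holding the control chromosomes
#'   (genotyped on the same map).
#' @param which character vector of haplotype labels (subset of
#'   `summary$table$label`); may be empty.
#' @return 2x2 integer matrix, rows `carrier`/`non-carrier`, columns
#'   `disease`/`control`.
#' @examples
#' map <- read_marker_map(founder_example("xq28_marker_map.tsv"))
#' tab <- read_chromosomes(c(founder_example("xq28_disease_chromosomes.tsv"),
#'                           founder_example("xq28_control_chromosomes_synthetic.tsv")),
#'                         map)
#' hs <- group_haplotypes(tab)
#' ct <- carriage_contingency(hs, tab, hs$table$label)
#' fisher_exact(ct)
#' @export
carriage_contingency <- function(summary, controls, which) {
  stopifnot(inherits(summary, "haplotype_summary"),
            inherits(controls, "chromosome_table"))
  unknown <- setdiff(which, summary$table$label)
  if (length(unknown))
    stop("unknown haplotype label(s): ", paste(unknown, collapse = ", "))
  if (!identical(controls$map$name, names(summary$ancestral)))
    stop("control table map does not match the haplotype summary")
  sel <- summary$table$label %in% which
  d_car <- sum(summary$table$count[sel])
  a <- allele_matrix(controls, "control")
  a <- a[rowSums(is.na(a)) == 0L, , drop = FALSE]
  hmat <- as.matrix(summary$table[sel, controls$map$name, drop = FALSE])
  c_car <- if (nrow(hmat) && nrow(a))
    sum(apply(a, 1L, function(r) any(colSums(t(hmat) != r) == 0L)))
  else 0L
  m <- matrix(as.integer(c(d_car, summary$n - d_car, c_car, nrow(a) - c_car)),
              nrow = 2L,
              dimnames = list(c("carrier", "non-carrier"),
                              c("disease", "control")))
  m
}
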