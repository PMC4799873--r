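# Chromosome tables: hemizygous haplotypes, one chromosome per row,
# labelled disease (mutation-bearing) or control.

#' Construct a chromosome table
#'
#' A chromosome table couples a [marker_map] with hemizygous genotype
#' records: one row per chromosome, one integer allele (fragment length in
#' bp) per marker, `NA` for a failed genotype.  Every subject is a single
#' chromosome (males are hemizygous for the X), so group denominators are
#' chromosome counts.
#'
#' @param map a [marker_map].
#' @param records data.frame with columns `sample_id`, `family_id`, `group`
#'   (each `"disease"` or `"control"`) and one integer column per marker,
#'   named as in the map.
#' @return Object of class `chromosome_table`: a list with elements `map`,
#'   `records` (allele columns reordered to map order), `n_disease`,
#'   `n_control`.
#' @export
chromosome_table <- function(map, records) {
  stopifnot(inherits(map, "marker_map"), is.data.frame(records))
  meta <- c("sample_id", "family_id", "group")
  if (!all(meta %in% names(records)))
    stop("records must have columns: ", paste(meta, collapse = ", "))
  have <- setdiff(names(records), meta)
  if (!setequal(have, map$name))
    stop("allele columns do not match the marker map; expected {",
         paste(map$name, collapse = ", "), "}, got {",
         paste(have, collapse = ", "), "}")
  bad <- setdiff(unique(records$group), c("disease", "control"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (must be 'disease' or 'control')")
  records <- records[, c(meta, map$name), drop = FALSE]
  for (m in map$name) records[[m]] <- as.integer(records[[m]])
  records$sample_id <- as.character(records$sample_id)
  records$family_id <- as.character(records$family_id)
  records$group <- as.character(records$group)
  rownames(records) <- NULL
  structure(list(map = map, records = records,
                 n_disease = sum(records$group == "disease"),
                 n_control = sum(records$group == "control")),
            class = "chromosome_table")
}

#' @export
print.chromosome_table <- function(x, ...) {
  cat(sprintf("Chromosome table: %d disease + %d control chromosomes, %d markers\n",
              x$n_disease, x$n_control, nrow(x$map)))
  print(head(x$records, 6L))
  if (nrow(x$records) > 6L) cat("...\n")
  invisible(x)
}

# allele matrix (chromosomes x markers) for one group
allele_matrix <- function(table, group = c("disease", "control")) {
  group <- match.arg(group)
  rec <- table$records[table$records$group == group, , drop = FALSE]
  as.matrix(rec[, table$map$name, drop = FALSE])
}

#' Read chromosome records from tab-separated files
#'
#' Expects header columns `sample_id`, `family_id`, `group` followed by one
#' column per marker of the map (integer fragment lengths in bp, `NA`
#' missing).  Several paths may be given (e.g. a disease file and a control
#' file); their records are concatenated.  Records with *all* alleles
#' missing are rejected with a warning reporting the count.
#'
#' @param path character vector of file paths.
#' @param map the [marker_map] the genotypes refer to.
#' @return A [chromosome_table].
#' @examples
#' map <- read_marker_map(founder_example("xq28_marker_map.tsv"))
#' tab <- read_chromosomes(c(founder_example("xq28_disease_chromosomes.tsv"),
#'                           founder_example("xq28_control_chromosomes_synthetic.tsv")),
#'                         map)
#' tab$n_disease; tab$n_control
#' @export
read_chromosomes <- function(path, map) {
  stopifnot(inherits(map, "marker_map"))
  parts <- lapply(path, function(pth) {
    p <- read_tsv_dialect(pth)
    meta <- c("sample_id", "family_id", "group")
    if (!identical(p$header[1:3], meta))
      stop("chromosome file ", pth, " must start with columns: ",
           paste(meta, collapse = ", "))
    if (!setequal(p$header[-(1:3)], map$name))
      stop("allele columns in ", pth, " do not match the marker map")
    if (!length(p$rows)) {
      df <- as.data.frame(setNames(rep(list(character(0)), length(p$header)), p$header))
      return(df)
    }
    df <- tsv_rows_to_df(p, pth)
    for (m in map$name) {
      v <- suppressWarnings(as.integer(df[[m]]))
      bad <- which(is.na(v) & !is.na(df[[m]]))
      if (length(bad))
        stop(sprintf("non-integer allele in %s at line %d, marker %s: '%s'",
                     pth, p$line_numbers[bad[1L]], m, df[[m]][bad[1L]]))
      df[[m]] <- v
    }
    df
  })
  rec <- do.call(rbind, lapply(parts, function(df)
    df[, c("sample_id", "family_id", "group",
           intersect(names(df), map$name)), drop = FALSE]))
  if (nrow(rec)) {
    allele <- as.matrix(rec[, map$name, drop = FALSE])
    empty <- rowSums(!is.na(allele)) == 0L
    if (any(empty)) {
      warning(sum(empty), " record(s) with all alleles missing were dropped")
      rec <- rec[!empty, , drop = FALSE]
    }
  }
  chromosome_table(map, rec)
}

#' Write chromosome records to a tab-separated file
#'
#' Inverse of [read_chromosomes()]; a write-then-read round trip reproduces
#' the records (and hence all derived statistics) exactly.
#'
#' @param table a [chromosome_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chromosomes <- function(table, path) {
  stopifnot(inherits(table, "chromosome_table"))
  write.table(table$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Import pre-phased LINKAGE/PED-style rows
#'
#' Interoperability importer for pre-phased pedigree-format genotypes with
#' *two* allele columns per marker.  Because this package models hemizygous
#' chromosomes, the second allele column of each marker is ignored (with a
#' warning).  Expected columns: `sample_id`, `family_id`, `group`, then two
#' unlabelled-by-marker columns per map marker, in map order.
#'
#' @param path file path.
#' @param map the [marker_map].
#' @return A [chromosome_table].
#' @export
read_linkage_ped <- function(path, map) {
  p <- read_tsv_dialect(path)
  nm <- 2L * nrow(map) + 3L
  nf <- lengths(p$rows)
  if (length(p$header) != nm || any(nf != nm))
    stop("PED-style file must have 3 meta columns + 2 columns per marker (",
         nm, " total)")
  warning("PED-style input: second allele column of each marker ignored ",
          "(hemizygous model)")
  m <- do.call(rbind, p$rows)
  df <- data.frame(sample_id = m[, 1L], family_id = m[, 2L], group = m[, 3L],
                   stringsAsFactors = FALSE)
  first <- m[, 3L + 2L * seq_len(nrow(map)) - 1L, drop = FALSE]
  first[first == "NA" | first == "0"] <- NA
  for (j in seq_len(nrow(map))) df[[map$name[j]]] <- as.integer(first[, j])
  chromosome_table(map, df)
}

# One chromosome per unrelated family among disease records: the founder
# analysis assumes independent descent, so related chromosomes would be
# pseudo-replicates.  Keeps the first record per family_id, warns on extras.
dedupe_families <- function(table) {
  rec <- table$records
  dis <- rec$group == "disease"
  dup <- logical(nrow(rec))
  dup[dis] <- duplicated(rec$family_id[dis])
  if (any(dup)) {
    warning(sum(dup), " disease chromosome(s) from already-represented ",
            "families dropped (one chromosome per family)")
    rec <- rec[!dup, , drop = FALSE]
    return(chromosome_table(table$map, rec))
  }
  table
}
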