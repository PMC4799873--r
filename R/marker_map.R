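# Marker maps: ordered STR markers around a disease mutation on one
# chromosome, with recombination fractions derived from physical distance.

#' Construct a marker map
#'
#' A marker map holds the flanking microsatellite markers of a disease
#' mutation, ordered by physical position, together with the mutation
#' position.  The per-marker recombination fraction `theta` is always
#' *derived* from physical distance under the 1 Mb ~ 1 cM rule
#' (`theta = |position_mb - mutation_position_mb| * 0.01`, clamped to 0.5),
#' never stored independently, so the map can be edited without the two
#' drifting apart.
#'
#' No Haldane or Kosambi transform is applied: at the sub-centimorgan
#' distances this analysis targets the map functions are indistinguishable
#' from linearity.
#'
#' @param markers data.frame with at least columns `name` (unique strings)
#'   and `position_mb` (positive numeric, megabases); optional metadata
#'   columns (`xq_band`, `repeat_unit`, `allele_min`, `allele_max`) are kept.
#' @param mutation_position_mb physical position of the mutation (Mb).
#' @param mutation_name label for the mutation locus.
#' @return An object of class `marker_map`: a data.frame of markers sorted
#'   by position with a derived `theta` column, and attributes
#'   `mutation_position_mb` and `mutation_name`.
#' @examples
#' mp <- marker_map(data.frame(name = c("A", "B"), position_mb = c(153.82, 154.86)),
#'                  mutation_position_mb = 154.13)
#' mp$theta  # 0.0031 0.0073
#' @export
marker_map <- function(markers, mutation_position_mb, mutation_name = "mutation") {
  stopifnot(is.data.frame(markers), all(c("name", "position_mb") %in% names(markers)))
  markers$name <- as.character(markers$name)
  markers$position_mb <- as.numeric(markers$position_mb)
  if (anyDuplicated(markers$name))
    stop("duplicate marker names: ", paste(unique(markers$name[duplicated(markers$name)]), collapse = ", "))
  if (any(!is.finite(markers$position_mb)) || any(markers$position_mb <= 0))
    stop("marker positions must be positive finite numbers (Mb)")
  if (!is.numeric(mutation_position_mb) || length(mutation_position_mb) != 1L ||
      !is.finite(mutation_position_mb) || mutation_position_mb <= 0)
    stop("mutation_position_mb must be a single positive number")
  markers <- markers[order(markers$position_mb), , drop = FALSE]
  rownames(markers) <- NULL
  markers$theta <- mb_to_theta(markers$position_mb, mutation_position_mb)
  structure(markers,
            mutation_position_mb = mutation_position_mb,
            mutation_name = mutation_name,
            class = c("marker_map", "data.frame"))
}

#' Convert physical distance to recombination fraction
#'
#' Applies the 1 Mb ~ 1 cM approximation: `theta = |dMb| * 0.01`, clamped
#' at the free-recombination bound 0.5.
#'
#' @param position_mb marker position(s), Mb.
#' @param mutation_position_mb mutation position, Mb.
#' @return Numeric vector of recombination fractions in \[0, 0.5\].
#' @export
mb_to_theta <- function(position_mb, mutation_position_mb) {
  pmin(abs(position_mb - mutation_position_mb) * 0.01, 0.5)
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("Marker map: %d markers, mutation '%s' at %.2f Mb\n",
              nrow(x), attr(x, "mutation_name"), attr(x, "mutation_position_mb")))
  print.data.frame(x, ...)
  invisible(x)
}

# Parse the package's tab-separated dialect: UTF-8, "#" comment lines,
# "NA" = missing.  Returns list(header, rows, line_numbers).
read_tsv_dialect <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("no content in ", path)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  list(header = trimws(fields[[1L]]),
       rows = fields[-1L],
       line_numbers = lineno[-1L])
}

#' Read a marker map from a tab-separated file
#'
#' The file must carry header columns `name` and `position_mb`, one row per
#' locus, and exactly one row with `type` equal to `"mutation"` naming the
#' disease locus; remaining rows are markers.  Lines starting with `#` are
#' comments; `NA` marks missing metadata.
#'
#' @param path path to the TSV file.
#' @return A [marker_map].
#' @examples
#' map <- read_marker_map(founder_example("xq28_marker_map.tsv"))
#' round(map$theta, 4)
#' @export
read_marker_map <- function(path) {
  p <- read_tsv_dialect(path)
  need <- c("name", "position_mb")
  if (!all(need %in% p$header))
    stop("marker map file must have columns: ", paste(need, collapse = ", "))
  df <- tsv_rows_to_df(p, path)
  pos <- suppressWarnings(as.numeric(df$position_mb))
  bad <- which(is.na(pos) & !is.na(df$position_mb))
  if (length(bad))
    stop(sprintf("non-numeric position_mb in %s at line %d: '%s'",
                 path, p$line_numbers[bad[1L]], df$position_mb[bad[1L]]))
  df$position_mb <- pos
  if (is.null(df$type)) df$type <- "marker"
  is_mut <- !is.na(df$type) & df$type == "mutation"
  if (sum(is_mut) != 1L)
    stop("marker map file must contain exactly one row with type = 'mutation' (found ",
         sum(is_mut), ")")
  mut <- df[is_mut, , drop = FALSE]
  mk <- df[!is_mut, setdiff(names(df), "type"), drop = FALSE]
  for (col in intersect(c("allele_min", "allele_max"), names(mk)))
    mk[[col]] <- suppressWarnings(as.integer(mk[[col]]))
  marker_map(mk, mutation_position_mb = mut$position_mb, mutation_name = mut$name)
}

# assemble a character data.frame from parsed rows, checking field counts
tsv_rows_to_df <- function(p, path) {
  nh <- length(p$header)
  nf <- lengths(p$rows)
  if (any(nf != nh))
    stop(sprintf("malformed row in %s at line %d: %d fields, expected %d",
                 path, p$line_numbers[which(nf != nh)[1L]], nf[nf != nh][1L], nh))
  m <- do.call(rbind, p$rows)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- p$header
  df[df == "NA"] <- NA
  df
}

#' Write a marker map to a tab-separated file
#'
#' Inverse of [read_marker_map()]: emits the markers plus the mutation row.
#'
#' @param map a [marker_map].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(map, path) {
  stopifnot(inherits(map, "marker_map"))
  df <- as.data.frame(map)
  df$theta <- NULL
  df$type <- "marker"
  mut <- df[1L, , drop = FALSE]
  mut[1L, ] <- NA
  mut$name <- attr(map, "mutation_name")
  mut$position_mb <- attr(map, "mutation_position_mb")
  mut$type <- "mutation"
  out <- rbind(df, mut)
  out <- out[order(out$position_mb), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Path to a packaged example data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a vector of file names.
#' @export
founder_example <- function(file = NULL) {
  if (is.null(file))
    dir(system.file("extdata", package = "founderage"))
  else
    system.file("extdata", file, package = "founderage", mustWork = TRUE)
}
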