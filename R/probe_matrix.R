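# ProbeMatrix: probe x sample intensity table plus the probe -> gene map.
# Probes are rows, samples are columns; intensities are raw (or quantile
# normalized) fluorescence values, never log transformed.

#' Construct a probe-level intensity matrix
#'
#' Bundles a probes-by-samples matrix of non-negative intensities with a
#' total probe-to-gene (probe set) map and validates the result. "Gene"
#' throughout the package means probe set: the group of probes interrogating
#' one transcript.
#'
#' @param values numeric matrix, rows = probes, columns = samples; all values
#'   finite and `>= 0` (arbitrary fluorescence units).
#' @param probe_ids character vector of unique probe identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @param probe_to_gene named character vector mapping every probe id to its
#'   gene id (names are probe ids).
#' @param validate run [validate_probe_matrix()] (default `TRUE`); internal
#'   callers that provably preserve the invariants may skip it.
#' @return An object of class `probe_matrix` with fields `values`,
#'   `probe_ids`, `sample_ids`, `probe_to_gene`.
#' @examples
#' pm <- probe_matrix(matrix(1:4, 2, 2,
#'                           dimnames = list(c("p1", "p2"), c("s1", "s2"))),
#'                    probe_to_gene = c(p1 = "g1", p2 = "g1"))
#' n_probes_per_gene(pm)
#' @export
probe_matrix <- function(values, probe_ids = rownames(values),
                         sample_ids = colnames(values), probe_to_gene,
                         validate = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || is.null(sample_ids)) {
    pt_validation_error("probe and sample ids are required (dimnames or arguments)")
  }
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  map <- as.character(probe_to_gene)
  names(map) <- names(probe_to_gene)
  dimnames(values) <- list(probe_ids, sample_ids)
  pm <- structure(
    list(values = values, probe_ids = probe_ids, sample_ids = sample_ids,
         probe_to_gene = map),
    class = "probe_matrix"
  )
  if (validate) validate_probe_matrix(pm)
  pm
}

#' Validate a probe_matrix
#'
#' Checks the class invariants: unique probe/sample ids, a total map between
#' matrix probes and the probe-to-gene map, and finite non-negative
#' intensities. Ids are compared by case-sensitive byte equality.
#'
#' @param pm a `probe_matrix`.
#' @return `pm`, invisibly; signals a validation error otherwise.
#' @export
validate_probe_matrix <- function(pm) {
  if (!inherits(pm, "probe_matrix")) {
    pt_validation_error("not a probe_matrix object")
  }
  dup <- pm$probe_ids[duplicated(pm$probe_ids)]
  if (length(dup)) {
    pt_validation_error(paste0("duplicate probe id: '", dup[[1L]], "'"))
  }
  dup <- pm$sample_ids[duplicated(pm$sample_ids)]
  if (length(dup)) {
    pt_validation_error(paste0("duplicate sample id: '", dup[[1L]], "'"))
  }
  if (nrow(pm$values) != length(pm$probe_ids) ||
      ncol(pm$values) != length(pm$sample_ids)) {
    pt_validation_error("matrix dimensions do not match id vectors")
  }
  map_probes <- names(pm$probe_to_gene)
  if (is.null(map_probes) && length(pm$probe_to_gene)) {
    pt_validation_error("probe_to_gene must be named by probe id")
  }
  dup <- map_probes[duplicated(map_probes)]
  if (length(dup)) {
    pt_validation_error(paste0("probe id mapped twice: '", dup[[1L]], "'"))
  }
  missing_in_map <- setdiff(pm$probe_ids, map_probes)
  if (length(missing_in_map)) {
    pt_validation_error(paste0("probe '", missing_in_map[[1L]],
                               "' present in matrix but absent from map"))
  }
  extra_in_map <- setdiff(map_probes, pm$probe_ids)
  if (length(extra_in_map)) {
    pt_validation_error(paste0("probe '", extra_in_map[[1L]],
                               "' present in map but absent from matrix"))
  }
  if (length(pm$values) && (anyNA(pm$values) || !all(is.finite(pm$values)))) {
    pt_validation_error("intensities must all be finite")
  }
  if (length(pm$values) && any(pm$values < 0)) {
    pt_validation_error("intensities must all be >= 0")
  }
  invisible(pm)
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes x %d samples, %d genes\n",
              length(x$probe_ids), length(x$sample_ids),
              length(unique(x$probe_to_gene))))
  invisible(x)
}

#' Number of probes per gene
#'
#' @param pm a `probe_matrix`.
#' @return Named integer vector, one entry per gene, sorted by gene id.
#' @export
n_probes_per_gene <- function(pm) {
  tab <- table(pm$probe_to_gene[pm$probe_ids])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Restrict a probe matrix to a subset of samples
#'
#' @param pm a `probe_matrix`.
#' @param sample_ids samples to keep, in the requested order.
#' @return A `probe_matrix` with the selected columns.
#' @export
subset_samples <- function(pm, sample_ids) {
  sample_ids <- as.character(sample_ids)
  missing <- setdiff(sample_ids, pm$sample_ids)
  if (length(missing)) {
    pt_validation_error(paste0("unknown sample id: '", missing[[1L]], "'"))
  }
  probe_matrix(pm$values[, sample_ids, drop = FALSE],
               probe_ids = pm$probe_ids, sample_ids = sample_ids,
               probe_to_gene = pm$probe_to_gene, validate = FALSE)
}

#' Read a probe matrix and its probe-set map from tab-separated text
#'
#' The matrix file is TSV: first row sample ids (an optional leading corner
#' label is tolerated), first column probe ids, remaining cells numeric
#' intensities. The map file is two-column TSV `probe_id TAB gene_id`
#' without a header. Missing values are not permitted: a cell that does not
#' parse as a non-negative number (including the string "NA") is a parse
#' error reported with its row and column.
#'
#' @param path matrix TSV path.
#' @param map_path probe-to-gene map TSV path.
#' @return A validated [probe_matrix()]; row order follows the file.
#' @export
read_probe_matrix <- function(path, map_path) {
  lines <- read_lines_checked(path)
  if (length(lines) < 1L) pt_parse_error(paste0("empty matrix file: ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]
  n_body_cells <- if (length(body)) lengths(body)[[1L]] else length(header)
  if (length(body) && !all(lengths(body) == n_body_cells)) {
    bad <- which(lengths(body) != n_body_cells)[[1L]]
    pt_parse_error(sprintf("ragged row %d in %s", bad + 1L, path))
  }
  sample_ids <- if (length(header) == n_body_cells) header[-1L] else header
  if (length(body) && length(sample_ids) != n_body_cells - 1L) {
    pt_parse_error(sprintf("header of %s has %d fields but rows have %d",
                           path, length(header), n_body_cells))
  }
  probe_ids <- vapply(body, `[[`, character(1), 1L)
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  vals <- suppressWarnings(as.numeric(cells))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[[1L]] - 1L
    r <- bad %/% length(sample_ids) + 1L
    c_ <- bad %% length(sample_ids) + 1L
    pt_parse_error(sprintf(
      "non-numeric intensity '%s' at data row %d, column '%s' of %s",
      cells[bad + 1L], r, sample_ids[c_], path))
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0)[[1L]] - 1L
    r <- bad %/% length(sample_ids) + 1L
    c_ <- bad %% length(sample_ids) + 1L
    pt_parse_error(sprintf(
      "negative intensity at data row %d, column '%s' of %s",
      r, sample_ids[c_], path))
  }
  values <- matrix(vals, nrow = length(body), ncol = length(sample_ids),
                   byrow = TRUE)
  map <- read_probe_map(map_path)
  probe_matrix(values, probe_ids = probe_ids, sample_ids = sample_ids,
               probe_to_gene = map)
}

read_probe_map <- function(map_path) {
  lines <- read_lines_checked(map_path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && !all(lengths(fields) == 2L)) {
    bad <- which(lengths(fields) != 2L)[[1L]]
    pt_parse_error(sprintf("map line %d of %s does not have 2 fields",
                           bad, map_path))
  }
  map <- vapply(fields, `[[`, character(1), 2L)
  names(map) <- vapply(fields, `[[`, character(1), 1L)
  map
}

read_lines_checked <- function(path) {
  tryCatch(suppressWarnings(readLines(path, warn = FALSE)),
           error = function(e) pt_io_error(paste0("cannot read ", path, ": ",
                                                  conditionMessage(e))))
}

fmt_num <- function(x) {
  out <- formatC(x, digits = 15, format = "g", width = 1)
  out[x == round(x) & abs(x) < 1e15] <-
    formatC(x[x == round(x) & abs(x) < 1e15], format = "d", width = 1)
  out
}

write_lines_checked <- function(lines, path) {
  tryCatch(writeLines(lines, path),
           error = function(e) pt_io_error(paste0("cannot write ", path, ": ",
                                                  conditionMessage(e))))
}

#' Write a probe matrix (and optionally its map) as tab-separated text
#'
#' Numbers are written with enough digits that a read/write round trip is
#' exact for integer-valued intensities and within 1e-9 relative error for
#' reals.
#'
#' @param pm a `probe_matrix`.
#' @param path output matrix TSV path.
#' @param map_path optional output path for the probe-to-gene map TSV.
#' @return `pm`, invisibly.
#' @export
write_probe_matrix <- function(pm, path, map_path = NULL) {
  validate_probe_matrix(pm)
  header <- paste(c("probe_id", pm$sample_ids), collapse = "\t")
  if (length(pm$probe_ids)) {
    cells <- matrix(fmt_num(pm$values), nrow = nrow(pm$values))
    rows <- paste(pm$probe_ids,
                  apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  } else {
    rows <- character(0)
  }
  write_lines_checked(c(header, rows), path)
  if (!is.null(map_path)) {
    write_lines_checked(
      paste(pm$probe_ids, pm$probe_to_gene[pm$probe_ids], sep = "\t"),
      map_path)
  }
  invisible(pm)
}
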