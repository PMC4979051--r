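# TwoGroupDesign: the A/B condition labeling of samples.

#' Construct a two-condition design
#'
#' @param condition_of named character vector mapping sample id to "A" or
#'   "B". Both conditions need at least two samples so the pooled variance of
#'   the t-statistic is estimable.
#' @return An object of class `two_group_design`.
#' @examples
#' des <- two_group_design(c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
#' samples_of(des, "A")
#' @export
two_group_design <- function(condition_of) {
  cond <- as.character(condition_of)
  names(cond) <- names(condition_of)
  if (is.null(names(cond)) || any(!nzchar(names(cond)))) {
    pt_validation_error("condition_of must be named by sample id")
  }
  if (anyDuplicated(names(cond))) {
    dup <- names(cond)[duplicated(names(cond))][[1L]]
    pt_validation_error(paste0("duplicate sample id in design: '", dup, "'"))
  }
  bad <- setdiff(unique(cond), c("A", "B"))
  if (length(bad)) {
    pt_validation_error(paste0("condition must be 'A' or 'B', got '",
                               bad[[1L]], "'"))
  }
  n_a <- sum(cond == "A")
  n_b <- sum(cond == "B")
  if (n_a < 2L || n_b < 2L) {
    pt_validation_error(sprintf(
      "need >= 2 samples per condition to estimate variance (got A=%d, B=%d)",
      n_a, n_b))
  }
  structure(list(condition_of = cond, n_A = n_a, n_B = n_b),
            class = "two_group_design")
}

#' Samples assigned to one condition
#'
#' @param design a `two_group_design`.
#' @param condition `"A"` or `"B"`.
#' @return Character vector of sample ids.
#' @export
samples_of <- function(design, condition) {
  names(design$condition_of)[design$condition_of == condition]
}

#' @export
print.two_group_design <- function(x, ...) {
  cat(sprintf("two_group_design: %d samples in A, %d in B\n", x$n_A, x$n_B))
  invisible(x)
}

#' Read condition labels from two-column TSV (sample_id TAB A|B)
#'
#' @param path labels TSV path; no header expected.
#' @return A [two_group_design()].
#' @export
read_labels <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && !all(lengths(fields) == 2L)) {
    bad <- which(lengths(fields) != 2L)[[1L]]
    pt_parse_error(sprintf("labels line %d of %s does not have 2 fields",
                           bad, path))
  }
  cond <- vapply(fields, `[[`, character(1), 2L)
  names(cond) <- vapply(fields, `[[`, character(1), 1L)
  two_group_design(cond)
}

#' Write condition labels as two-column TSV
#'
#' @param design a `two_group_design`.
#' @param path output path.
#' @return `design`, invisibly.
#' @export
write_labels <- function(design, path) {
  write_lines_checked(
    paste(names(design$condition_of), design$condition_of, sep = "\t"), path)
  invisible(design)
}
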