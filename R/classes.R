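#' @keywords internal
"_PACKAGE"

#' Canonical group labels of the reciprocal-cross design
#'
#' The pipeline works on a fixed four-level design: two purebred parental
#' lines (`P1`, `P2`) and the two reciprocal hybrids (`F1A` = sire P1 x dam
#' P2, `F1B` = sire P2 x dam P1). External labels (e.g. CC/RR/CR/RC line
#' codes) are mapped onto these via `group_map` arguments, so nothing else
#' in the package is organism- or study-specific.
#'
#' @format Character vector of length four.
#' @export
GROUPS <- c("P1", "P2", "F1A", "F1B")

#' Build a validated count matrix container
#'
#' Bundles an integer gene x sample count matrix with per-gene transcript
#' lengths (bp). Counts must be integral and non-negative -- fractional
#' values are rejected rather than rounded, so FPKM or TPM tables cannot be
#' passed in by mistake.
#'
#' @param counts Numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names. Values must be whole numbers >= 0.
#' @param gene_lengths Named numeric vector of positive transcript lengths
#'   in bp; names must cover `rownames(counts)`. Genes lacking a length are
#'   dropped with a warning.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (integer matrix) and `gene_lengths` (named integer vector
#'   aligned to the rows of `counts`).
#' @export
count_matrix <- function(counts, gene_lengths) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must carry gene row names and sample column names", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ",
         rownames(counts)[duplicated(rownames(counts))][1], call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         colnames(counts)[duplicated(colnames(counts))][1], call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "counts must be non-negative integers; offending cell gene '%s', sample '%s' (value %s)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, 1], bad[1, 2]])), call. = FALSE)
  }
  if (is.null(names(gene_lengths)))
    stop("`gene_lengths` must be named by gene id", call. = FALSE)
  missing_len <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing_len) > 0) {
    warning(sprintf("dropping %d gene(s) lacking a length entry: %s",
                    length(missing_len),
                    paste(utils::head(missing_len, 5), collapse = ", ")),
            call. = FALSE)
    counts <- counts[setdiff(rownames(counts), missing_len), , drop = FALSE]
  }
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(!is.finite(gene_lengths) | gene_lengths <= 0))
    stop("gene lengths must be positive", call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 gene_lengths = stats::setNames(as.integer(gene_lengths),
                                                rownames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Build a validated sample sheet
#'
#' @param sample_id Character vector of unique sample ids.
#' @param group Character vector of group labels; mapped through
#'   `group_map` and then required to lie in [GROUPS].
#' @param group_map Optional named character vector mapping external labels
#'   to canonical ones, e.g. `c(CC = "P1", RR = "P2", CR = "F1A", RC = "F1B")`.
#' @return A data.frame with columns `sample_id`, `group` (factor over
#'   [GROUPS]), of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, group, group_map = NULL) {
  sample_id <- as.character(sample_id)
  group <- map_groups(as.character(group), group_map)
  if (anyDuplicated(sample_id))
    stop("duplicate sample id: ", sample_id[duplicated(sample_id)][1],
         call. = FALSE)
  if (length(sample_id) != length(group))
    stop("sample_id and group lengths differ", call. = FALSE)
  structure(data.frame(sample_id = sample_id,
                       group = factor(group, levels = GROUPS)),
            class = c("sample_sheet", "data.frame"))
}

map_groups <- function(group, group_map = NULL) {
  if (!is.null(group_map)) {
    hit <- group %in% names(group_map)
    group[hit] <- unname(group_map[group[hit]])
  }
  unknown <- setdiff(unique(group), GROUPS)
  if (length(unknown) > 0)
    stop("unknown group label(s) with no mapping: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  group
}

#' Build a validated phenotype table
#'
#' Individual-level trait records (e.g. abdominal fat percentage, AFP) for
#' the four design groups.
#'
#' @param individual_id,group,sex,trait Vectors of equal length; `sex` in
#'   `{"F","M"}`; `trait` finite and >= 0 (percent units for AFP).
#' @inheritParams sample_sheet
#' @return data.frame of class `phenotype_table` with columns
#'   `individual_id`, `group`, `sex`, `trait`.
#' @export
phenotype_table <- function(individual_id, group, sex, trait,
                            group_map = NULL) {
  group <- map_groups(as.character(group), group_map)
  sex <- as.character(sex)
  if (!all(sex %in% c("F", "M")))
    stop("sex must be 'F' or 'M'", call. = FALSE)
  trait <- as.numeric(trait)
  if (any(!is.finite(trait)))
    stop("trait values must be finite", call. = FALSE)
  if (any(trait < 0))
    stop("negative trait value for individual ",
         as.character(individual_id)[which(trait < 0)[1]], call. = FALSE)
  structure(data.frame(individual_id = as.character(individual_id),
                       group = factor(group, levels = GROUPS),
                       sex = sex, trait = trait),
            class = c("phenotype_table", "data.frame"))
}

#' Check that every count-matrix sample is covered by the sample sheet
#' @param cm A [count_matrix()].
#' @param sheet A [sample_sheet()].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_design <- function(cm, sheet) {
  missing <- setdiff(colnames(cm$counts), sheet$sample_id)
  if (length(missing) > 0)
    stop("sample(s) absent from sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab <- table(factor(sheet$group[sheet$sample_id %in% colnames(cm$counts)],
                      levels = GROUPS))
  small <- names(tab)[tab > 0 & tab < 2]
  if (length(small) > 0)
    stop("group(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
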