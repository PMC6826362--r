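# Readers/writers for the plain-text formats the pipeline touches:
# count TSV + length TSV, GMT gene sets, phenotype CSV/TSV, sample sheets.
# Delimiter for phenotype files is sniffed from the extension.

#' Read a gene x sample count matrix and gene-length table
#'
#' @param path TSV with a header row of sample ids; first column gene ids.
#' @param lengths_path TSV with header `gene_id<TAB>length_bp`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, lengths_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("count table needs gene ids plus >= 1 sample",
                          call. = FALSE)
  gene_ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric count at gene '%s', sample '%s'",
                 gene_ids[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  }
  rownames(m) <- gene_ids
  len <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(len)))
    stop("lengths table must have columns gene_id and length_bp",
         call. = FALSE)
  count_matrix(m, stats::setNames(len$length_bp, len$gene_id))
}

#' Write a count matrix (and its lengths) as TSV
#' @param cm A [count_matrix()].
#' @param path,lengths_path Output TSV paths (lengths skipped if `NULL`).
#' @export
write_count_matrix <- function(cm, path, lengths_path = NULL) {
  out <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(lengths_path)) {
    utils::write.table(
      data.frame(gene_id = names(cm$gene_lengths),
                 length_bp = unname(cm$gene_lengths)),
      lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then member gene ids. Duplicate members within a
#' set are deduplicated; lines with fewer than three fields are errors.
#'
#' @param path GMT file path.
#' @return Named list of class `gene_set_collection`; each element is
#'   `list(description =, genes = character vector)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 member",
                   i, length(f)), call. = FALSE)
    if (f[1] %in% names(sets))
      stop("duplicate set name: ", f[1], call. = FALSE)
    sets[[f[1]]] <- list(description = f[2], genes = unique(f[-(1:2)]))
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param sets A `gene_set_collection` (see [read_gmt()]).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

sniff_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an individual-level phenotype table
#'
#' @param path CSV or TSV with header columns `individual_id`, `group`,
#'   `sex`, `trait`; delimiter sniffed from the extension.
#' @inheritParams sample_sheet
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path, group_map = NULL) {
  tab <- utils::read.table(path, sep = sniff_sep(path), header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if ("trait" %in% names(tab)) tab$trait <- as.numeric(tab$trait)
  need <- c("individual_id", "group", "sex", "trait")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("phenotype table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  phenotype_table(tab$individual_id, tab$group, tab$sex, tab$trait,
                  group_map = group_map)
}

#' Write a phenotype table (delimiter from extension)
#' @param pheno A [phenotype_table()].
#' @param path Output path.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = sniff_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet TSV (columns sample_id, group)
#' @param path TSV path.
#' @inheritParams sample_sheet
#' @return A [sample_sheet()].
#' @export
read_sample_sheet <- function(path, group_map = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(tab)))
    stop("sample sheet must have columns sample_id and group", call. = FALSE)
  sample_sheet(tab$sample_id, tab$group, group_map = group_map)
}

#' Write a sample sheet TSV
#' @param sheet A [sample_sheet()].
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
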