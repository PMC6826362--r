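# Expression filtering and negative-binomial Wald differential expression.
#
# The test is deliberately self-contained (method-of-moments dispersion, no
# shrinkage, no independent filtering): per gene, group means are estimated
# on library-size-normalised counts, log2FC = log2((m_num + c)/(m_den + c))
# with pseudo-mean c, the SE comes from the delta method under the NB
# variance mu + alpha*mu^2, and the Wald statistic is referred to a
# standard normal. A "MID" pseudo-group (average of the two parental group
# means, variances propagated) supports the additivity test.

#' Compute an FPKM expression matrix
#'
#' FPKM_{g,s} = counts_{g,s} * 1e9 / (length_g * libsize_s).
#'
#' @param cm A [count_matrix()].
#' @param library_sizes Per-sample library sizes, or `"column-sum"`
#'   (default) to use the column totals.
#' @return Numeric matrix of FPKM values, same dimnames as the counts.
#' @export
compute_fpkm <- function(cm, library_sizes = "column-sum") {
  if (identical(library_sizes, "column-sum"))
    library_sizes <- colSums(cm$counts)
  if (any(library_sizes <= 0)) stop("zero library size", call. = FALSE)
  sweep(cm$counts / cm$gene_lengths, 2, library_sizes, "/") * 1e9
}

#' Filter genes on mean FPKM
#'
#' Retains a gene iff its mean FPKM across ALL samples is >= `threshold`
#' (genes with average FPKM below 1 are removed under the default).
#'
#' @param fpkm FPKM matrix from [compute_fpkm()].
#' @param threshold Mean-FPKM cutoff (default 1).
#' @return Character vector of retained gene ids.
#' @export
filter_low_expression <- function(fpkm, threshold = 1.0) {
  rownames(fpkm)[rowMeans(fpkm) >= threshold]
}

#' Library-size scaling factors
#'
#' `"median-ratio"` (default): median of per-gene ratios to the
#' geometric-mean reference gene (genes with any zero excluded) -- robust
#' to composition bias when a minority of genes dominates a group's
#' library. `"colsum"`: column sum divided by the geometric mean of the
#' column sums; simple but biased when strongly asymmetric genes (e.g.
#' over-dominant hybrids) shift the totals.
#'
#' @param counts Integer count matrix.
#' @param method `"median-ratio"` or `"colsum"`.
#' @return Named numeric vector of size factors (geometric mean ~ 1).
#' @export
size_factors <- function(counts, method = c("median-ratio", "colsum")) {
  method <- match.arg(method)
  if (method == "colsum") {
    cs <- colSums(counts)
    if (any(cs == 0)) stop("sample with zero total count", call. = FALSE)
    return(cs / exp(mean(log(cs))))
  }
  keep <- rowSums(counts == 0) == 0
  if (!any(keep)) stop("median-ratio needs >= 1 gene with no zero counts",
                       call. = FALSE)
  logref <- rowMeans(log(counts[keep, , drop = FALSE]))
  apply(counts[keep, , drop = FALSE], 2,
        function(x) exp(stats::median(log(x) - logref)))
}

#' Method-of-moments NB dispersion estimates
#'
#' Per gene: within-group sample variances of the normalised counts are
#' pooled (weighted by group df), the pooled mean is the overall mean, and
#' alpha = max(alpha_floor, (V - M) / M^2). Degenerate genes (zero mean or
#' under-dispersed) sit at the floor.
#'
#' @param cm A [count_matrix()] (already filtered).
#' @param samples A [sample_sheet()].
#' @param sf Size factors from [size_factors()]; computed if `NULL`.
#' @param alpha_floor Lower bound on alpha (default 1e-8).
#' @return Named numeric vector of dispersions, one per gene.
#' @export
estimate_dispersion <- function(cm, samples, sf = NULL, alpha_floor = 1e-8) {
  y <- normalized_counts(cm, sf)
  groups <- group_columns(samples, colnames(y))
  vnum <- 0; vden <- 0
  for (g in names(groups)) {
    cols <- groups[[g]]
    if (length(cols) < 2) next
    m <- rowMeans(y[, cols, drop = FALSE])
    v <- rowSums((y[, cols, drop = FALSE] - m)^2) / (length(cols) - 1)
    vnum <- vnum + (length(cols) - 1) * v
    vden <- vden + (length(cols) - 1)
  }
  if (vden == 0) stop("no group with >= 2 samples", call. = FALSE)
  v_pooled <- vnum / vden
  m_pooled <- rowMeans(y)
  alpha <- ifelse(m_pooled > 0, (v_pooled - m_pooled) / m_pooled^2, 0)
  stats::setNames(pmax(alpha_floor, alpha), rownames(y))
}

normalized_counts <- function(cm, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(cm$counts)
  sweep(cm$counts, 2, sf, "/")
}

group_columns <- function(samples, sample_ids) {
  g <- as.character(samples$group[match(sample_ids, samples$sample_id)])
  if (anyNA(g)) stop("sample(s) missing from sample sheet: ",
                     paste(sample_ids[is.na(g)], collapse = ", "),
                     call. = FALSE)
  split(sample_ids, factor(g, levels = GROUPS))
}

#' Specify a differential-expression contrast
#'
#' @param name Contrast label carried into the results.
#' @param numerator,denominator Group labels from [GROUPS], or `"MID"` for
#'   the mid-parent pseudo-group (average of the P1 and P2 group means with
#'   variances propagated).
#' @return A list of class `contrast_spec`.
#' @export
contrast_spec <- function(name, numerator, denominator) {
  ok <- c(GROUPS, "MID")
  if (!numerator %in% ok || !denominator %in% ok)
    stop("unknown group in contrast '", name, "'", call. = FALSE)
  structure(list(name = name, numerator = numerator,
                 denominator = denominator), class = "contrast_spec")
}

#' The standard contrast set for the reciprocal-cross design
#'
#' The five pairwise contrasts (parents; each cross vs each parent) plus
#' the two mid-parent contrasts used by the additivity test.
#'
#' @return Named list of [contrast_spec()] objects.
#' @export
default_contrasts <- function() {
  specs <- list(
    contrast_spec("P2_vs_P1", "P2", "P1"),
    contrast_spec("F1A_vs_P1", "F1A", "P1"),
    contrast_spec("F1A_vs_P2", "F1A", "P2"),
    contrast_spec("F1B_vs_P1", "F1B", "P1"),
    contrast_spec("F1B_vs_P2", "F1B", "P2"),
    contrast_spec("F1A_vs_MID", "F1A", "MID"),
    contrast_spec("F1B_vs_MID", "F1B", "MID"))
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

# Mean and variance-of-the-mean of normalised counts for one side of a
# contrast; "MID" averages the parental group means.
side_moments <- function(y, groups, side, alpha) {
  grp_mom <- function(g) {
    cols <- groups[[g]]
    if (length(cols) == 0) stop("contrast side '", g, "' has no samples",
                                call. = FALSE)
    m <- rowMeans(y[, cols, drop = FALSE])
    list(m = m, v = (m + alpha * m^2) / length(cols))
  }
  if (side == "MID") {
    a <- grp_mom("P1"); b <- grp_mom("P2")
    list(m = (a$m + b$m) / 2, v = (a$v + b$v) / 4)
  } else {
    grp_mom(side)
  }
}

#' Negative-binomial Wald test for one contrast
#'
#' @param cm A [count_matrix()] restricted to the genes under test.
#' @param samples A [sample_sheet()].
#' @param contrast A [contrast_spec()].
#' @param dispersions Named alpha vector from [estimate_dispersion()].
#' @param sf Size factors (computed from `cm` if `NULL`).
#' @param pseudo_mean Pseudo-mean c added to both group means inside the
#'   log2 ratio (default 0.5 normalised counts) to guard against zeros.
#' @return data.frame of class `contrast_result` with columns `gene_id`,
#'   `log2_fold_change`, `standard_error`, `wald_stat`, `p_value`,
#'   `p_adjusted`, `contrast_name` (BH adjustment within this contrast).
#' @export
nb_wald_test <- function(cm, samples, contrast, dispersions, sf = NULL,
                         pseudo_mean = 0.5) {
  stopifnot(inherits(contrast, "contrast_spec"))
  y <- normalized_counts(cm, sf)
  groups <- group_columns(samples, colnames(y))
  for (g in setdiff(unique(c(contrast$numerator, contrast$denominator)), "MID"))
    if (length(groups[[g]]) < 2)
      stop("group ", g, " has fewer than 2 samples", call. = FALSE)
  alpha <- dispersions[rownames(y)]
  if (anyNA(alpha)) stop("dispersion missing for some genes", call. = FALSE)
  num <- side_moments(y, groups, contrast$numerator, alpha)
  den <- side_moments(y, groups, contrast$denominator, alpha)
  c0 <- pseudo_mean
  lfc <- log2((num$m + c0) / (den$m + c0))
  se <- sqrt(num$v / (num$m + c0)^2 + den$v / (den$m + c0)^2) / log(2)
  wald <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(wald))
  res <- data.frame(gene_id = rownames(y), log2_fold_change = lfc,
                    standard_error = se, wald_stat = wald, p_value = p,
                    p_adjusted = bh_adjust(p),
                    contrast_name = contrast$name, row.names = NULL)
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, capped at 1, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Run the full filter + contrast battery
#'
#' Computes FPKM from the raw counts, applies the mean-FPKM filter, then
#' runs every contrast on the retained genes with a shared dispersion
#' estimate; BH is applied within each contrast separately.
#'
#' @param cm A [count_matrix()] of raw counts.
#' @param samples A [sample_sheet()].
#' @param specs List of [contrast_spec()]s (default [default_contrasts()]).
#' @param fpkm_threshold Mean-FPKM filter cutoff (default 1; 0 disables).
#' @param norm_method Size-factor method, see [size_factors()].
#' @param alpha_floor,pseudo_mean Passed to [estimate_dispersion()] and
#'   [nb_wald_test()].
#' @return List of class `de_result`: `results` (named list of
#'   `contrast_result` data.frames), `retained_genes`, `n_filtered`,
#'   `size_factors`, `dispersions`.
#' @export
run_contrasts <- function(cm, samples, specs = default_contrasts(),
                          fpkm_threshold = 1.0,
                          norm_method = c("median-ratio", "colsum"),
                          alpha_floor = 1e-8, pseudo_mean = 0.5) {
  norm_method <- match.arg(norm_method)
  validate_design(cm, samples)
  fpkm <- compute_fpkm(cm)
  keep <- filter_low_expression(fpkm, fpkm_threshold)
  n_filtered <- nrow(cm$counts) - length(keep)
  if (length(keep) == 0) {
    warning("no genes pass the expression filter", call. = FALSE)
    return(structure(list(results = stats::setNames(list(), character(0)),
                          retained_genes = character(0),
                          n_filtered = n_filtered,
                          size_factors = NULL, dispersions = NULL),
                     class = "de_result"))
  }
  cmk <- count_matrix(cm$counts[keep, , drop = FALSE],
                      cm$gene_lengths[keep])
  sf <- size_factors(cmk$counts, norm_method)
  disp <- estimate_dispersion(cmk, samples, sf, alpha_floor)
  results <- lapply(specs, function(sp)
    nb_wald_test(cmk, samples, sp, disp, sf, pseudo_mean))
  names(results) <- vapply(specs, `[[`, "", "name")
  structure(list(results = results, retained_genes = keep,
                 n_filtered = n_filtered, size_factors = sf,
                 dispersions = disp),
            class = "de_result")
}
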