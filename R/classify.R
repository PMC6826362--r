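# Inheritance-mode classification of hybrid gene expression.
#
# Per gene and per cross, four contrast calls (parents; hybrid vs each
# parent; hybrid vs mid-parent) are reduced to one of twelve types,
# collapsed to five categories:
#   additivity            I, XII
#   high-parent dominance II, IV
#   low-parent dominance  IX, XI
#   over-dominance        V, VI, VIII
#   under-dominance       III, VII, X
# Rules are applied in fixed precedence (over/under, then high/low parent,
# then additive, then none) so every evidence tuple maps to exactly one
# type-or-none. Subtype numbering vs parent direction follows the
# conventional twelve-bin scheme.

TYPE_CATEGORY <- c(I = "additive", XII = "additive",
                   II = "high_parent", IV = "high_parent",
                   IX = "low_parent", XI = "low_parent",
                   V = "over", VI = "over", VIII = "over",
                   III = "under", VII = "under", X = "under")

TYPES <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
           "IX", "X", "XI", "XII")

CATEGORIES <- c("additive", "high_parent", "low_parent", "over", "under")
NONADDITIVE <- c("high_parent", "low_parent", "over", "under")

call_one <- function(padj, lfc, alpha) {
  # strict "< alpha" per the published decision rule; padj == alpha is ns
  if (padj < alpha) { if (lfc > 0) "up" else if (lfc < 0) "down" else "ns" }
  else "ns"
}

#' Reduce one gene's contrast rows to an evidence tuple
#'
#' Each contrast is mapped to `up`/`down`/`ns` using `p_adjusted < alpha`
#' and the sign of the log2 fold change; the point-estimate signs of the
#' hybrid-vs-parent fold changes are kept for the between-parents check of
#' the additivity rule.
#'
#' @param parent_row Row of the P2-vs-P1 contrast (`up` = P2 higher).
#' @param f1_vs_p1,f1_vs_p2,f1_vs_mid Rows of the hybrid contrasts
#'   (`up` = hybrid higher).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @return List of class `mode_evidence`: calls `parent`, `vs_p1`,
#'   `vs_p2`, `vs_mid` plus point-estimate signs `sign_p1`, `sign_p2`.
#' @export
call_directions <- function(parent_row, f1_vs_p1, f1_vs_p2, f1_vs_mid,
                            alpha = 0.05) {
  rows <- list(parent_row, f1_vs_p1, f1_vs_p2, f1_vs_mid)
  if (any(vapply(rows, is.null, TRUE)) ||
      any(vapply(rows, nrow, 0L) != 1))
    stop("each contrast must contribute exactly one row", call. = FALSE)
  ids <- vapply(rows, function(r) r$gene_id, "")
  if (length(unique(ids)) != 1)
    stop("contrast rows refer to different genes: ",
         paste(unique(ids), collapse = ", "), call. = FALSE)
  structure(list(
    gene_id = ids[1],
    parent = call_one(parent_row$p_adjusted, parent_row$log2_fold_change, alpha),
    vs_p1  = call_one(f1_vs_p1$p_adjusted, f1_vs_p1$log2_fold_change, alpha),
    vs_p2  = call_one(f1_vs_p2$p_adjusted, f1_vs_p2$log2_fold_change, alpha),
    vs_mid = call_one(f1_vs_mid$p_adjusted, f1_vs_mid$log2_fold_change, alpha),
    sign_p1 = sign(f1_vs_p1$log2_fold_change),
    sign_p2 = sign(f1_vs_p2$log2_fold_change)),
    class = "mode_evidence")
}

#' Classify one evidence tuple into a type and category
#'
#' @param evidence A `mode_evidence` from [call_directions()], or any list
#'   with the same fields.
#' @return List: `type` (one of the twelve roman numerals or `"none"`) and
#'   `category` (one of the five categories or `"other"`).
#' @export
classify_gene <- function(evidence) {
  e <- evidence
  p1_higher <- e$parent == "down"   # P2-vs-P1 down => P1 higher
  p2_higher <- e$parent == "up"
  type <- "none"
  if (e$vs_p1 == "up" && e$vs_p2 == "up") {
    type <- if (p1_higher) "V" else if (p2_higher) "VIII" else "VI"
  } else if (e$vs_p1 == "down" && e$vs_p2 == "down") {
    type <- if (p1_higher) "III" else if (p2_higher) "X" else "VII"
  } else if (p1_higher && e$vs_p1 == "ns" && e$vs_p2 == "up") {
    type <- "II"                    # at the higher parent P1, above P2
  } else if (p2_higher && e$vs_p2 == "ns" && e$vs_p1 == "up") {
    type <- "IV"
  } else if (p2_higher && e$vs_p1 == "ns" && e$vs_p2 == "down") {
    type <- "IX"                    # at the lower parent P1, below P2
  } else if (p1_higher && e$vs_p2 == "ns" && e$vs_p1 == "down") {
    type <- "XI"
  } else if (p1_higher && e$vs_mid == "ns" &&
             e$sign_p1 < 0 && e$sign_p2 > 0) {
    type <- "I"                     # strictly between, at the mid-parent
  } else if (p2_higher && e$vs_mid == "ns" &&
             e$sign_p1 > 0 && e$sign_p2 < 0) {
    type <- "XII"
  }
  list(type = type,
       category = if (type == "none") "other" else unname(TYPE_CATEGORY[type]))
}

#' Classify every eligible gene for one cross
#'
#' A gene enters classification when it is significant in at least one of
#' the three pairwise contrasts involving this cross or the parents; genes
#' non-significant everywhere are conserved and excluded.
#'
#' @param de A `de_result` from [run_contrasts()], or a plain named list of
#'   `contrast_result` data.frames.
#' @param cross `"F1A"` or `"F1B"`.
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @return data.frame of class `mode_calls`: `gene_id`, `cross`, `type`,
#'   `category`, and the four calls `parent`, `vs_p1`, `vs_p2`, `vs_mid`.
#' @export
classify_all <- function(de, cross = c("F1A", "F1B"), alpha = 0.05) {
  cross <- match.arg(cross)
  results <- if (inherits(de, "de_result")) de$results else de
  need <- c("P2_vs_P1", paste0(cross, "_vs_P1"), paste0(cross, "_vs_P2"),
            paste0(cross, "_vs_MID"))
  miss <- setdiff(need, names(results))
  if (length(miss) > 0)
    stop("missing contrast(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  par <- results[["P2_vs_P1"]]
  vp1 <- results[[paste0(cross, "_vs_P1")]]
  vp2 <- results[[paste0(cross, "_vs_P2")]]
  mid <- results[[paste0(cross, "_vs_MID")]]
  stopifnot(identical(par$gene_id, vp1$gene_id),
            identical(par$gene_id, vp2$gene_id),
            identical(par$gene_id, mid$gene_id))

  sig <- function(r) r$p_adjusted < alpha
  dir <- function(r) ifelse(sig(r),
                            ifelse(r$log2_fold_change > 0, "up",
                                   ifelse(r$log2_fold_change < 0, "down", "ns")),
                            "ns")
  entered <- sig(par) | sig(vp1) | sig(vp2)
  idx <- which(entered)
  parent_call <- dir(par); p1_call <- dir(vp1); p2_call <- dir(vp2)
  mid_call <- dir(mid)
  s1 <- sign(vp1$log2_fold_change); s2 <- sign(vp2$log2_fold_change)
  calls <- lapply(idx, function(i) {
    cl <- classify_gene(list(parent = parent_call[i], vs_p1 = p1_call[i],
                             vs_p2 = p2_call[i], vs_mid = mid_call[i],
                             sign_p1 = s1[i], sign_p2 = s2[i]))
    data.frame(gene_id = par$gene_id[i], cross = cross, type = cl$type,
               category = cl$category, parent = parent_call[i],
               vs_p1 = p1_call[i], vs_p2 = p2_call[i], vs_mid = mid_call[i])
  })
  out <- if (length(calls) > 0) do.call(rbind, calls) else
    data.frame(gene_id = character(0), cross = character(0),
               type = character(0), category = character(0),
               parent = character(0), vs_p1 = character(0),
               vs_p2 = character(0), vs_mid = character(0))
  class(out) <- c("mode_calls", "data.frame")
  out
}

#' Collapse twelve type counts to the five-category summary
#'
#' @param type_counts Named non-negative integer vector over the roman
#'   numerals `I` ... `XII` (missing types count as zero).
#' @return List of class `category_summary`: `counts` (named vector over
#'   additive/high_parent/low_parent/over/under), `nonadditive_total`, and
#'   `proportions_pct` (the four non-additive categories as percentages of
#'   the non-additive total; `NA` when that total is zero).
#' @export
aggregate_categories <- function(type_counts) {
  tc <- stats::setNames(rep(0, length(TYPES)), TYPES)
  unknown <- setdiff(names(type_counts), TYPES)
  if (length(unknown) > 0)
    stop("unknown type label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  tc[names(type_counts)] <- type_counts
  if (any(tc < 0)) stop("negative type count", call. = FALSE)
  counts <- c(
    additive    = unname(tc["I"] + tc["XII"]),
    high_parent = unname(tc["II"] + tc["IV"]),
    low_parent  = unname(tc["IX"] + tc["XI"]),
    over        = unname(tc["V"] + tc["VI"] + tc["VIII"]),
    under       = unname(tc["III"] + tc["VII"] + tc["X"]))
  nat <- sum(counts[NONADDITIVE])
  props <- if (nat > 0) 100 * counts[NONADDITIVE] / nat else
    stats::setNames(rep(NA_real_, 4), NONADDITIVE)
  structure(list(counts = counts, nonadditive_total = nat,
                 proportions_pct = props),
            class = "category_summary")
}

#' Count types from a set of mode calls
#' @param calls A `mode_calls` data.frame from [classify_all()].
#' @return Named integer vector over the twelve types.
#' @export
count_types <- function(calls) {
  tab <- table(factor(calls$type[calls$type != "none"], levels = TYPES))
  stats::setNames(as.integer(tab), TYPES)
}

#' Genes sharing a category across both crosses
#'
#' @param calls_a,calls_b `mode_calls` for the two crosses.
#' @param category One of the five category labels.
#' @return Sorted character vector of gene ids holding that category in
#'   both crosses.
#' @export
shared_category_genes <- function(calls_a, calls_b, category) {
  if (!category %in% c(CATEGORIES, "other"))
    stop("unknown category: ", category, call. = FALSE)
  sort(intersect(calls_a$gene_id[calls_a$category == category],
                 calls_b$gene_id[calls_b$category == category]))
}
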