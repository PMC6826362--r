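# Hypergeometric over-representation analysis against a GMT collection.
# The universe is the tested population (genes passing the expression
# filter); set memberships are restricted to it before testing.

#' Hypergeometric over-representation analysis
#'
#' For each set, the one-sided upper-tail p-value `P(X >= k)` with
#' `X ~ Hypergeom(N, K, n_study)`, where `N` is the universe size, `K` the
#' universe-restricted set size, `n_study` the study-list size and `k` the
#' observed overlap. Sets empty after universe restriction are skipped
#' (not tested), and BH FDR is computed across the tested sets only.
#'
#' @param study Character vector of study gene ids (e.g. the over-dominant
#'   genes of one cross). Genes outside the universe are dropped with a
#'   warning.
#' @param universe Character vector: the tested population.
#' @param sets A `gene_set_collection` from [read_gmt()].
#' @return data.frame of class `enrichment_result`, sorted by p then name:
#'   `set_name`, `description`, `k`, `K`, `n_study`, `N`, `p_value`,
#'   `fdr`, `overlap` (comma-joined gene ids).
#' @export
hypergeom_ora <- function(study, universe, sets) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  study <- unique(study)
  outside <- setdiff(study, universe)
  if (length(outside) > 0) {
    warning(sprintf("dropping %d study gene(s) outside the universe",
                    length(outside)), call. = FALSE)
    study <- intersect(study, universe)
  }
  if (length(study) == 0)
    stop("study list empty after universe restriction", call. = FALSE)
  N <- length(universe)
  n_study <- length(study)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]]$genes, universe)
    K <- length(members)
    if (K == 0) return(NULL)
    hit <- intersect(study, members)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n_study, lower.tail = FALSE)
    data.frame(set_name = nm, description = sets[[nm]]$description,
               k = k, K = K, n_study = n_study, N = N, p_value = p,
               fdr = NA_real_,
               overlap = paste(sort(hit), collapse = ","))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(structure(data.frame(set_name = character(0)),
                     class = c("enrichment_result", "data.frame")))
  res <- do.call(rbind, rows)
  res$fdr <- bh_adjust(res$p_value)
  res <- res[order(res$p_value, res$set_name), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Names of sets significant at an FDR threshold
#'
#' @param results An `enrichment_result` from [hypergeom_ora()].
#' @param fdr_threshold Strict cutoff on FDR (default 0.05).
#' @return Character vector of set names, sorted by ascending p.
#' @export
significant_sets <- function(results, fdr_threshold = 0.05) {
  hit <- results[results$fdr < fdr_threshold, , drop = FALSE]
  hit$set_name[order(hit$p_value)]
}
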