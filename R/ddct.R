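# Relative qPCR quantification by the 2^-ddCt method.
#
# Technical replicates are averaged on the Ct scale, then per sample
# dCt = Ct(target) - Ct(reference); ddCt subtracts the calibrator-group
# mean dCt, and fold change = 2^-ddCt (amplification efficiency fixed
# at 2). Any constant Ct shift applied to target and reference alike
# cancels in dCt, so fold changes are invariant to it.

#' Fold changes by the 2^-ddCt method
#'
#' @param ct data.frame with columns `sample_id`, `group`, `gene`, `ct`
#'   (and optionally `replicate`); one reference gene plus one or more
#'   target genes per sample, each with >= 1 technical replicate.
#' @param calibrator_group Group whose mean dCt anchors ddCt = 0.
#' @param reference_gene Name of the reference (housekeeping) gene as it
#'   appears in the `gene` column (default `"GAPDH"`).
#' @return data.frame of class `fold_change_result`, one row per sample x
#'   target gene: `sample_id`, `group`, `gene`, `delta_ct`, `ddct`,
#'   `fold_change`; attribute `group_summary` holds the per group x gene
#'   mean fold change and SD.
#' @export
ddct_fold_change <- function(ct, calibrator_group, reference_gene = "GAPDH") {
  need <- c("sample_id", "group", "gene", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss) > 0)
    stop("Ct table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(ct$ct))) stop("non-finite Ct value", call. = FALSE)
  if (!calibrator_group %in% ct$group)
    stop("calibrator group '", calibrator_group, "' absent from Ct table",
         call. = FALSE)
  if (!reference_gene %in% ct$gene)
    stop("reference gene '", reference_gene, "' absent from Ct table",
         call. = FALSE)

  # replicate Cts averaged per (sample, gene) before any differencing
  avg <- stats::aggregate(ct ~ sample_id + group + gene, data = ct,
                          FUN = mean)
  ref <- avg[avg$gene == reference_gene, c("sample_id", "ct")]
  names(ref)[2] <- "ref_ct"
  tgt <- avg[avg$gene != reference_gene, , drop = FALSE]
  if (nrow(tgt) == 0) stop("no target gene rows", call. = FALSE)
  no_ref <- setdiff(unique(tgt$sample_id), ref$sample_id)
  if (length(no_ref) > 0)
    stop("sample(s) missing the reference gene: ",
         paste(no_ref, collapse = ", "), call. = FALSE)
  m <- merge(tgt, ref, by = "sample_id")
  m$delta_ct <- m$ct - m$ref_ct

  out <- do.call(rbind, lapply(split(m, m$gene), function(d) {
    cal_mean <- mean(d$delta_ct[d$group == calibrator_group])
    if (is.nan(cal_mean))
      stop("calibrator group has no samples for gene ", d$gene[1],
           call. = FALSE)
    d$ddct <- d$delta_ct - cal_mean
    d$fold_change <- 2^(-d$ddct)
    d[, c("sample_id", "group", "gene", "delta_ct", "ddct", "fold_change")]
  }))
  rownames(out) <- NULL
  summ <- stats::aggregate(fold_change ~ group + gene, data = out,
                           FUN = function(x) c(mean = mean(x),
                                               sd = stats::sd(x)))
  summ <- data.frame(group = summ$group, gene = summ$gene,
                     mean_fold_change = summ$fold_change[, "mean"],
                     sd_fold_change = summ$fold_change[, "sd"])
  attr(out, "group_summary") <- summ
  class(out) <- c("fold_change_result", "data.frame")
  out
}
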