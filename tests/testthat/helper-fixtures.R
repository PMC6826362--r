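# Shared in-code fixtures and small oracles.

# Tiny deterministic count matrix: counts chosen by the caller, lengths 1kb.
tiny_cm <- function(counts, lengths = NULL) {
  if (is.null(lengths))
    lengths <- stats::setNames(rep(1000L, nrow(counts)), rownames(counts))
  count_matrix(counts, lengths)
}

# Deterministic two-group design: n samples per group drawn from `groups`.
tiny_sheet <- function(groups, n = 3) {
  g <- rep(groups, each = n)
  sample_sheet(sprintf("%s_%d", g, sequence(rep(n, length(groups)))), g)
}

# One-row contrast result, for feeding call_directions directly.
contrast_row <- function(gene_id = "g1", lfc = 0, padj = 1, p = padj) {
  data.frame(gene_id = gene_id, log2_fold_change = lfc,
             standard_error = 0.1, wald_stat = lfc / 0.1, p_value = p,
             p_adjusted = padj, contrast_name = "x")
}

# Exhaustive enumeration of evidence tuples: all 3^4 call combinations,
# with point-estimate signs consistent with the hybrid-vs-parent calls
# (a significant call fixes the sign; ns leaves both signs possible).
enumerate_evidence <- function() {
  calls <- c("up", "down", "ns")
  grid <- expand.grid(parent = calls, vs_p1 = calls, vs_p2 = calls,
                      vs_mid = calls, s1 = c(1, -1), s2 = c(1, -1),
                      stringsAsFactors = FALSE)
  ok <- (grid$vs_p1 == "ns" | grid$s1 == ifelse(grid$vs_p1 == "up", 1, -1)) &
        (grid$vs_p2 == "ns" | grid$s2 == ifelse(grid$vs_p2 == "up", 1, -1))
  grid <- grid[ok, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i)
    list(parent = grid$parent[i], vs_p1 = grid$vs_p1[i],
         vs_p2 = grid$vs_p2[i], vs_mid = grid$vs_mid[i],
         sign_p1 = grid$s1[i], sign_p2 = grid$s2[i]))
}

# Relabel P1 <-> P2 in an evidence tuple.
swap_parents_evidence <- function(e) {
  flip <- function(x) c(up = "down", down = "up", ns = "ns")[[x]]
  list(parent = flip(e$parent), vs_p1 = e$vs_p2, vs_p2 = e$vs_p1,
       vs_mid = e$vs_mid, sign_p1 = e$sign_p2, sign_p2 = e$sign_p1)
}

# Independent factorial-based hypergeometric upper tail, for small N.
hyper_upper_enum <- function(k, K, N, n) {
  kk <- max(k, 0):min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Reported 12-type counts fixture path.
type_counts_path <- function() {
  system.file("extdata", "inheritance_type_counts.tsv",
              package = "hetexpress", mustWork = TRUE)
}

afp_summary_path <- function() {
  system.file("extdata", "afp_group_summary.tsv", package = "hetexpress",
              mustWork = TRUE)
}
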