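# Seeded generator for reciprocal-cross count matrices with known
# ground-truth inheritance modes, plus truncated-Gaussian AFP-like
# phenotypes. Stands in for unreleased study data in every test.

MODES <- c("conserved", "additive", "high_parent", "low_parent",
           "over", "under")

#' Simulation configuration for reciprocal-cross data
#'
#' @param seed Integer RNG seed; a fixed seed makes every output
#'   bit-reproducible.
#' @param n_per_group Replicates per group: a single integer (default 6) or
#'   a named vector over [GROUPS] (the liver RNA-seq design of the
#'   motivating study was 6/6/6/5 for P1/P2/F1A/F1B).
#' @param genes_per_mode Named integer vector over the six modes
#'   `conserved`, `additive`, `high_parent`, `low_parent`, `over`, `under`.
#' @param baseline_mean Expected count of a conserved gene at library size
#'   1e6 (default 100).
#' @param parent_log2_diff log2 difference between the parental means for
#'   every non-conserved gene (default 2); which parent is higher is
#'   randomised per gene.
#' @param dominance_log2_shift log2 shift of the hybrids above the higher
#'   parent (over-dominance) or below the lower parent (under-dominance);
#'   default 1.5.
#' @param dispersion NB dispersion alpha in the variance function
#'   `mu + alpha * mu^2` (default 0.05, a conventional bulk RNA-seq value).
#' @param library_sizes Per-sample library sizes: scalar recycled to all
#'   samples (default 1e6) or a vector of length `sum(n_per_group)`.
#' @param cross_shift_log2 Optional parent-of-origin effect: log2 shift
#'   added to the F1B means only (default 0, reciprocal symmetry).
#' @param phenotypes data.frame with columns `sex`, `group`, `n`, `mean`,
#'   `sd` describing the trait distribution per group; defaults to
#'   [default_afp_phenotypes()].
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_per_group = 6L,
                              genes_per_mode = c(conserved = 1000L,
                                                 additive = 100L,
                                                 high_parent = 100L,
                                                 low_parent = 100L,
                                                 over = 100L,
                                                 under = 100L),
                              baseline_mean = 100,
                              parent_log2_diff = 2,
                              dominance_log2_shift = 1.5,
                              dispersion = 0.05,
                              library_sizes = 1e6,
                              cross_shift_log2 = 0,
                              phenotypes = default_afp_phenotypes()) {
  if (length(n_per_group) == 1L)
    n_per_group <- stats::setNames(rep(as.integer(n_per_group), 4), GROUPS)
  if (!all(GROUPS %in% names(n_per_group)))
    stop("n_per_group must be scalar or named over ", paste(GROUPS, collapse = ", "),
         call. = FALSE)
  n_per_group <- n_per_group[GROUPS]
  if (any(n_per_group < 2))
    stop("n_per_group must be >= 2 in every group (contrasts impossible otherwise)",
         call. = FALSE)
  genes_per_mode <- unlist(genes_per_mode)   # tolerate YAML-style lists
  gpm <- stats::setNames(rep(0L, length(MODES)), MODES)
  gpm[names(genes_per_mode)] <- as.integer(genes_per_mode)
  if (!all(names(genes_per_mode) %in% MODES))
    stop("unknown mode in genes_per_mode", call. = FALSE)
  if (sum(gpm) == 0) stop("zero genes requested", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (baseline_mean <= 0) stop("baseline_mean must be positive", call. = FALSE)
  if (any(library_sizes <= 0)) stop("library sizes must be positive", call. = FALSE)
  structure(list(seed = as.integer(seed), n_per_group = n_per_group,
                 genes_per_mode = gpm, baseline_mean = baseline_mean,
                 parent_log2_diff = parent_log2_diff,
                 dominance_log2_shift = dominance_log2_shift,
                 dispersion = dispersion, library_sizes = library_sizes,
                 cross_shift_log2 = cross_shift_log2,
                 phenotypes = phenotypes),
            class = "simulation_config")
}

#' Default AFP phenotype structure
#'
#' Group means and SDs of abdominal fat percentage (females and males) and
#' the per-group slaughter numbers observed in a six-week broiler x layer
#' reciprocal-cross experiment; the purebred layer line (P2) deposits no
#' abdominal fat at that age, so its SD of 0 forces truncation at zero.
#'
#' @return data.frame with columns `sex`, `group`, `n`, `mean`, `sd`.
#' @export
default_afp_phenotypes <- function() {
  data.frame(
    sex   = rep(c("F", "M"), each = 4),
    group = rep(c("P1", "P2", "F1A", "F1B"), 2),
    n     = c(8L, 8L, 10L, 15L, 10L, 9L, 15L, 10L),
    mean  = c(1.86, 0.00, 2.14, 1.65, 1.90, 0.00, 1.61, 2.42),
    sd    = c(0.35, 0.00, 0.40, 0.70, 0.37, 0.00, 0.43, 0.45))
}

# Noiseless group-mean vector for one gene of a given mode.
# hi_is_p1 picks which parent carries the higher expression.
mode_means <- function(mode, baseline, parent_log2_diff,
                       dominance_log2_shift, hi_is_p1) {
  hi <- baseline * 2^(parent_log2_diff / 2)
  lo <- baseline * 2^(-parent_log2_diff / 2)
  if (mode == "conserved") {
    p1 <- p2 <- f1 <- baseline
  } else {
    p1 <- if (hi_is_p1) hi else lo
    p2 <- if (hi_is_p1) lo else hi
    f1 <- switch(mode,
                 additive    = (hi + lo) / 2,
                 high_parent = hi,
                 low_parent  = lo,
                 over        = hi * 2^dominance_log2_shift,
                 under       = lo * 2^(-dominance_log2_shift))
  }
  c(P1 = p1, P2 = p2, F1A = f1, F1B = f1)
}

#' Generate a reciprocal-cross count matrix with known truth
#'
#' Per gene, group means are fixed by the planted inheritance mode
#' (conserved; additive = hybrids at the parental mid-point; high-/low-
#' parent dominance = hybrids at the higher/lower parent; over-/under-
#' dominance = hybrids shifted beyond the higher/lower parent), then counts
#' are drawn NB(mean x library-size factor, dispersion). Both crosses share
#' the mode unless `cross_shift_log2` requests a parent-of-origin shift.
#'
#' @param config A [simulation_config()].
#' @return List with elements `counts` (a [count_matrix()]), `samples`
#'   (a [sample_sheet()]) and `truth` (data.frame: `gene_id`, `true_mode`,
#'   `mean_P1`, `mean_P2`, `mean_F1A`, `mean_F1B`).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  gpm <- config$genes_per_mode
  modes <- rep(names(gpm), gpm)
  n_genes <- length(modes)
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))

  hi_is_p1 <- stats::runif(n_genes) < 0.5
  mu <- t(vapply(seq_len(n_genes), function(i) {
    mode_means(modes[i], config$baseline_mean, config$parent_log2_diff,
               config$dominance_log2_shift, hi_is_p1[i])
  }, stats::setNames(numeric(4), GROUPS)))
  mu[, "F1B"] <- mu[, "F1B"] * 2^config$cross_shift_log2

  npg <- config$n_per_group
  sample_group <- rep(GROUPS, npg)
  sample_ids <- unlist(lapply(GROUPS, function(g)
    sprintf("%s_%d", g, seq_len(npg[g]))))
  n_samples <- length(sample_ids)
  lib <- rep_len(config$library_sizes, n_samples)

  counts <- matrix(0L, n_genes, n_samples,
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_len(n_samples)) {
    m <- mu[, sample_group[j]] * lib[j] / 1e6
    counts[, j] <- if (config$dispersion == 0) {
      stats::rpois(n_genes, m)
    } else {
      stats::rnbinom(n_genes, mu = m, size = 1 / config$dispersion)
    }
  }
  lengths <- stats::setNames(
    as.integer(round(stats::runif(n_genes, 200, 10000))), gene_ids)

  truth <- data.frame(gene_id = gene_ids, true_mode = modes,
                      mean_P1 = mu[, "P1"], mean_P2 = mu[, "P2"],
                      mean_F1A = mu[, "F1A"], mean_F1B = mu[, "F1B"],
                      row.names = NULL)
  list(counts = count_matrix(counts, lengths),
       samples = sample_sheet(sample_ids, sample_group),
       truth = truth)
}

#' Generate individual-level phenotypes
#'
#' Gaussian noise around per-group means, truncated at zero (the trait is a
#' percentage >= 0; a group configured with mean 0 and sd 0 is exactly 0).
#'
#' @param config A [simulation_config()]; its `phenotypes` element gives
#'   per sex x group `n`, `mean`, `sd`.
#' @return A [phenotype_table()].
#' @export
generate_phenotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ph <- config$phenotypes
  if (any(ph$sd < 0)) stop("phenotype sd must be >= 0", call. = FALSE)
  set.seed(config$seed + 1L)
  rows <- lapply(seq_len(nrow(ph)), function(i) {
    vals <- pmax(0, stats::rnorm(ph$n[i], ph$mean[i], ph$sd[i]))
    data.frame(individual_id = sprintf("%s_%s_%d", ph$sex[i], ph$group[i],
                                       seq_len(ph$n[i])),
               group = ph$group[i], sex = ph$sex[i], trait = vals)
  })
  tab <- do.call(rbind, rows)
  phenotype_table(tab$individual_id, tab$group, tab$sex, tab$trait)
}

#' Write all simulation outputs to a directory
#'
#' Emits `counts.tsv`, `lengths.tsv`, `samples.tsv`, `truth.tsv` and
#' `phenotypes.tsv`.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_counts(config)
  write_count_matrix(sim$counts, file.path(dir, "counts.tsv"),
                     file.path(dir, "lengths.tsv"))
  write_sample_sheet(sim$samples, file.path(dir, "samples.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_phenotypes(generate_phenotypes(config),
                   file.path(dir, "phenotypes.tsv"))
  invisible(dir)
}
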