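test_that("FPKM follows count * 1e9 / (length * libsize) and its invariances", {
  cm <- tiny_cm(matrix(c(10L, 0L), 2, 1,
                       dimnames = list(c("a", "b"), "s1")))
  f <- compute_fpkm(cm, library_sizes = 1e6)
  expect_equal(f["a", 1], 10.0)
  expect_equal(f["b", 1], 0.0)

  # joint scaling of counts and library sizes cancels
  cm2 <- tiny_cm(matrix(c(20L, 0L), 2, 1,
                        dimnames = list(c("a", "b"), "s1")))
  expect_equal(compute_fpkm(cm2, library_sizes = 2e6), f)
  expect_error(compute_fpkm(cm, library_sizes = 0), "zero library size")
})

test_that("mean-FPKM filter keeps >= threshold and drops below", {
  f <- matrix(c(0.99, 0.99, 1.0, 1.0, 5, 0.1), 3, 2, byrow = TRUE,
              dimnames = list(c("low", "edge", "mixed"), c("s1", "s2")))
  expect_setequal(filter_low_expression(f), c("edge", "mixed"))
  expect_false("low" %in% filter_low_expression(f))     # mean 0.99 removed
  expect_true("edge" %in% filter_low_expression(f))     # mean exactly 1 kept
  expect_setequal(filter_low_expression(f, 0), rownames(f))
})

test_that("median-ratio size factors recover known library scalings", {
  set.seed(21)
  mu <- rexp(400, 1 / 200) + 10
  scale_true <- c(1, 2, 0.5, 1)
  counts <- sapply(scale_true, function(s) rpois(400, mu * s))
  dimnames(counts) <- list(sprintf("g%03d", 1:400), paste0("s", 1:4))
  sf <- size_factors(counts)
  expect_equal(unname(sf / exp(mean(log(sf)))),
               scale_true / exp(mean(log(scale_true))), tolerance = 0.05)
  expect_error(size_factors(matrix(0L, 2, 2)), ".")
})

test_that("moment dispersion estimates hit the floor and the truth", {
  # zero within-group variance -> floor
  flat <- tiny_cm(matrix(rep(c(5L, 9L), each = 4), 2, 4, byrow = TRUE,
                         dimnames = list(c("a", "b"), paste0("s", 1:4))))
  sheet <- tiny_sheet(c("P1", "P2"), 2)
  colnames(flat$counts) <- sheet$sample_id
  d <- estimate_dispersion(flat, sheet, sf = rep(1, 4))
  expect_equal(unname(d), rep(1e-8, 2))

  # NB truth alpha = 0.1 at n = 50 per group
  sim <- generate_counts(simulation_config(
    seed = 31, n_per_group = 50, genes_per_mode = c(conserved = 400),
    dispersion = 0.1))
  dd <- estimate_dispersion(sim$counts, sim$samples)
  expect_gt(median(dd), 0.05)
  expect_lt(median(dd), 0.2)

  # Poisson counts -> alpha near the floor on average
  simp <- generate_counts(simulation_config(
    seed = 32, n_per_group = 50, genes_per_mode = c(conserved = 400),
    dispersion = 0))
  dp <- estimate_dispersion(simp$counts, simp$samples)
  expect_lt(median(dp), 0.01)
})

test_that("NB Wald statistic behaves on deterministic inputs", {
  mk <- function(m1, m2, n = 6) {
    counts <- matrix(as.integer(c(rep(m1, n), rep(m2, n))), 1,
                     dimnames = list("g1", sprintf("s%d", 1:(2 * n))))
    tiny_cm(counts)
  }
  sheet <- tiny_sheet(c("P1", "P2"), 6)
  same <- mk(100, 100)
  colnames(same$counts) <- sheet$sample_id
  r0 <- nb_wald_test(same, sheet, contrast_spec("c", "P2", "P1"),
                     c(g1 = 0.05), sf = rep(1, 12))
  expect_equal(r0$log2_fold_change, 0)
  expect_equal(r0$p_value, 1)

  big <- mk(100, 800)
  colnames(big$counts) <- sheet$sample_id
  r1 <- nb_wald_test(big, sheet, contrast_spec("c", "P2", "P1"),
                     c(g1 = 0.05), sf = rep(1, 12))
  expect_lt(r1$p_value, 1e-4)
  expect_gt(r1$log2_fold_change, 2.9)

  # antisymmetry under side swap
  r2 <- nb_wald_test(big, sheet, contrast_spec("c", "P1", "P2"),
                     c(g1 = 0.05), sf = rep(1, 12))
  expect_equal(r2$log2_fold_change, -r1$log2_fold_change)
  expect_equal(r2$p_value, r1$p_value)
})

test_that("NB Wald type-I error is near nominal under the null", {
  sim <- generate_counts(simulation_config(
    seed = 7, genes_per_mode = c(conserved = 5000)))
  de <- run_contrasts(sim$counts, sim$samples,
                      specs = list(contrast_spec("P2_vs_P1", "P2", "P1")))
  rate <- mean(de$results$P2_vs_P1$p_value < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.08)
})

test_that("rejection probability grows with the planted effect size", {
  power_at <- function(diff) {
    sim <- generate_counts(simulation_config(
      seed = 50 + round(diff * 10), parent_log2_diff = diff,
      genes_per_mode = c(conserved = 200, additive = 300)))
    de <- run_contrasts(sim$counts, sim$samples,
                        specs = list(contrast_spec("P2_vs_P1", "P2", "P1")))
    r <- de$results$P2_vs_P1
    planted <- sim$truth$gene_id[sim$truth$true_mode == "additive"]
    mean(r$p_value[r$gene_id %in% planted] < 0.05)
  }
  p <- vapply(c(0.25, 1, 3), power_at, 0)
  expect_true(all(diff(p) > 0))
  expect_gt(p[3], 0.99)
})

test_that("BH adjustment matches the hand-executed step-up and its properties", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(13)
  p <- runif(200)^2
  q <- bh_adjust(p)
  expect_true(all(q >= p))                       # never smaller
  perm <- sample(200)
  expect_equal(bh_adjust(p[perm]), q[perm])      # permutation-equivariant
})

test_that("run_contrasts ranks planted genes first and handles edge cases", {
  sim <- generate_counts(simulation_config(
    seed = 77, genes_per_mode = c(conserved = 100, additive = 2),
    parent_log2_diff = 3))
  de <- run_contrasts(sim$counts, sim$samples)
  r <- de$results$P2_vs_P1
  planted <- sim$truth$gene_id[sim$truth$true_mode == "additive"]
  top2 <- r$gene_id[order(r$p_adjusted, r$p_value)][1:2]
  expect_setequal(top2, planted)

  # all genes filtered out -> warning and empty result set
  expect_warning(
    empty <- run_contrasts(sim$counts, sim$samples, fpkm_threshold = 1e9),
    "no genes pass")
  expect_length(empty$results, 0)

  # a group contrasted with itself is null: no adjusted discoveries
  null_sim <- generate_counts(simulation_config(
    seed = 78, genes_per_mode = c(conserved = 1000)))
  deN <- run_contrasts(null_sim$counts, null_sim$samples,
                       specs = list(contrast_spec("self", "P1", "P1")))
  expect_equal(sum(deN$results$self$p_adjusted < 0.05), 0)

  expect_error(contrast_spec("bad", "NOPE", "P1"), "unknown group")
})
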