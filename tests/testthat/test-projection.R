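test_that("centroid construction reports coverage, weighting and collapses duplicates", {
  sig <- make_signature(c("FN1", "BGN", "COMP"), c(1.5, -2, 1))
  m <- matrix(rnorm(4 * 6), 4, 6,
              dimnames = list(c("P1", "P2", "P3", "P4"), paste0("s", 1:6)))
  m["P2", ] <- m["P2", ] * 10  # most variable FN1 probe
  cohort <- make_ds(m, scale = "log-ratio")
  map <- c(P1 = "FN1", P2 = "FN1", P3 = "BGN", P4 = "OTHER")

  cen <- build_centroid(sig, cohort, weighting = "lfc", symbol_map = map)
  expect_identical(sort(cen$symbols), c("BGN", "FN1"))
  expect_true("P2" %in% cen$genes)                     # highest-IQR row kept
  expect_false("P1" %in% cen$genes)
  expect_equal(cen$coverage, 2 / 3)
  expect_equal(unname(cen$values[match("FN1", cen$symbols)]), 1.5)

  cs <- build_centroid(sig, cohort, weighting = "sign", symbol_map = map)
  expect_true(all(abs(cs$values) == 1))

  # full coverage when every signature gene is a cohort row
  full <- make_ds(matrix(rnorm(18), 3, 6,
                         dimnames = list(c("FN1", "BGN", "COMP"), paste0("s", 1:6))),
                  scale = "log-ratio")
  expect_identical(build_centroid(sig, full)$coverage, 1)

  expect_error(build_centroid(sig, make_ds(matrix(rnorm(6), 1, 6,
                 dimnames = list("FN1", paste0("s", 1:6))), scale = "log-ratio")),
               "fewer than 2")
})

test_that("sample scores are Pearson correlations with the centroid", {
  sig <- make_signature(c("A", "B", "C"), c(1, -1, 2))
  w <- c(1, -1, 2)
  m <- cbind(prop = 3 * w + 5,      # positive affine image -> r = 1
             neg = -w,              # r = -1
             hand = c(0, 1, 2))     # r = 3/sqrt(84)
  rownames(m) <- c("A", "B", "C")
  cohort <- make_ds(m, scale = "log-ratio")
  cen <- build_centroid(sig, cohort)
  sc <- score_samples(cen, cohort, center_genes = FALSE)
  expect_equal(sc$score[sc$sample_id == "prop"], 1, tolerance = 1e-12)
  expect_equal(sc$score[sc$sample_id == "neg"], -1, tolerance = 1e-12)
  expect_equal(sc$score[sc$sample_id == "hand"], 3 / sqrt(84), tolerance = 1e-12)
  expect_true(all(sc$n_genes_used == 3L))
})

test_that("scores are invariant to per-sample affine rescaling", {
  set.seed(3)
  sig <- make_signature(sprintf("G%02d", 1:20), rnorm(20) + c(2, -2))
  m <- matrix(rnorm(20 * 5), 20, 5,
              dimnames = list(sprintf("G%02d", 1:20), paste0("s", 1:5)))
  cohort <- make_ds(m, scale = "log-ratio")
  cen <- build_centroid(sig, cohort)
  base <- score_samples(cen, cohort, center_genes = FALSE)$score
  m2 <- m
  m2[, 2] <- 7.3 * m[, 2] + 11      # positive scale + shift on one sample
  sc2 <- score_samples(cen, make_ds(m2, scale = "log-ratio"),
                       center_genes = FALSE)$score
  expect_equal(sc2, base, tolerance = 1e-12)
})

test_that("samples with too few usable genes score NA with a warning", {
  sig <- make_signature(c("A", "B", "C"), c(1, -1, 2))
  m <- cbind(ok = c(1, 0, 2), bad = c(5, NA, NA))
  rownames(m) <- c("A", "B", "C")
  cohort <- make_ds(m, scale = "log-ratio")
  cen <- build_centroid(sig, cohort)
  expect_warning(sc <- score_samples(cen, cohort, center_genes = FALSE),
                 "scored NA")
  expect_true(is.na(sc$score[sc$sample_id == "bad"]))
  expect_identical(sc$n_genes_used[sc$sample_id == "bad"], 1L)
})

test_that("subset comparison reproduces Welch arithmetic", {
  sc <- data.frame(sample_id = paste0("s", 1:4),
                   score = c(0.1, 0.3, -0.2, 0.0))
  lab <- data.frame(sample_id = paste0("s", 1:4),
                    subset = c("diffuse1", "diffuse1", "limited", "normal-like"))
  res <- compare_subsets(sc, lab, target = "diffuse1")
  expect_equal(res$target_mean, 0.2)
  expect_equal(res$rest_mean, -0.1)
  expect_equal(res$difference, 0.3)
  expect_equal(res$t, 0.3 / sqrt(0.02 / 2 + 0.02 / 2), tolerance = 1e-10)
  ref <- t.test(c(0.1, 0.3), c(-0.2, 0.0))
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
})

test_that("subset comparison handles identical and zero-variance groups", {
  sc <- data.frame(sample_id = paste0("s", 1:6),
                   score = rep(c(0.2, -0.1), each = 3))
  lab <- data.frame(sample_id = paste0("s", 1:6),
                    subset = rep(c("diffuse1", "limited"), each = 3))
  res <- compare_subsets(sc, lab, target = "diffuse1")
  expect_equal(res$difference, 0.3)
  expect_identical(res$p, .Machine$double.xmin)  # zero-variance underflow rule

  sc$score <- rep(0.1, 6)
  same <- compare_subsets(sc, lab, target = "diffuse1")
  expect_identical(same$difference, 0)
  expect_identical(same$p, 1)

  expect_error(compare_subsets(sc[1:2, ], lab, target = "diffuse1"),
               ">= 2 scored samples")
})

test_that("concordance fractions count signed subset deviations", {
  # all-up signature; subset means exactly (+, -, +, +, -): 3/5 concordant
  sig <- make_signature(paste0("G", 1:5), rep(2, 5))
  means <- c(1, -1, 1, 1, -1)
  m <- cbind(a = means, b = means, c = -means, d = -means)  # medians 0
  rownames(m) <- paste0("G", 1:5)
  cohort <- make_ds(m, scale = "log-ratio")
  lab <- data.frame(sample_id = colnames(m),
                    subset = c("T", "T", "R", "R"))
  res <- concordance_fractions(sig, cohort, lab, null_band = 0,
                               center_genes = FALSE)
  expect_equal(res$concordant_frac[res$subset == "T"], 3 / 5)
  expect_equal(res$concordant_frac[res$subset == "R"], 2 / 5)

  # all-zero subset means: strict sign rule counts nothing
  zero <- make_ds(matrix(0, 5, 4, dimnames = dimnames(m)), scale = "log-ratio")
  rz <- concordance_fractions(sig, zero, lab, null_band = 0,
                              center_genes = FALSE)
  expect_true(all(rz$concordant_frac == 0))
})

test_that("noise-free planted subsets reach full concordance", {
  sig <- make_signature(paste0("G", 1:40), c(rep(2, 15), rep(-2, 25)))
  sim <- simulate_cohort(sig, cohort_sim_config(seed = 2, gene_noise_sd = 1e-3,
                                                platform_coverage = 1,
                                                n_background_genes = 50L))
  res <- concordance_fractions(sig, sim$dataset)
  expect_equal(res$concordant_frac[res$subset == "diffuse1"], 1)
  expect_equal(res$concordant_frac[res$subset == "diffuse2"], 1)
})

test_that("average-linkage clustering over 1 - Pearson behaves as computed by hand", {
  base <- c(1, 5, 2, 8, 3)
  m <- cbind(s1 = base, s2 = base + 2, s3 = -base)  # s1 = s2 up to shift
  rownames(m) <- paste0("G", 1:5)
  tree <- cluster_samples(make_ds(m, scale = "log-ratio"))
  expect_s3_class(tree, "hclust")
  expect_equal(tree$height[1], 0, tolerance = 1e-12)   # r(s1,s2) = 1
  expect_equal(tree$height[2], 2, tolerance = 1e-12)   # 1 - (-1)
  expect_identical(sort(tree$labels[-tree$merge[1, ]]), c("s1", "s2"))

  # permuting samples leaves the merge-height multiset unchanged
  tree2 <- cluster_samples(make_ds(m[, c(3, 1, 2)], scale = "log-ratio"))
  expect_equal(sort(tree2$height), sort(tree$height), tolerance = 1e-12)

  mc <- m; mc[, 2] <- 4  # constant sample
  expect_error(cluster_samples(make_ds(mc, scale = "log-ratio")),
               "constant expression.*s2")
})

test_that("signature overlap partitions shared genes by direction", {
  a <- make_signature(c("g1", "g2", "g3"), c(2, 2, -2))
  b <- make_signature(c("g2", "g3", "g4"), c(2, 2, -2))
  rep_ <- overlap_signatures(a, b)
  expect_identical(rep_$n_intersect, 2L)
  expect_identical(rep_$concordant_up, "G2")
  expect_identical(rep_$n_concordant_down, 0L)
  expect_identical(rep_$discordant, "G3")
  expect_identical(rep_$a_only, "G1")
  # partition identity
  expect_identical(rep_$n_concordant_up + rep_$n_concordant_down + rep_$n_discordant,
                   rep_$n_intersect)

  same <- overlap_signatures(a, a)
  expect_identical(same$n_intersect, same$n_a)
  expect_identical(same$n_discordant, 0L)

  disjoint <- overlap_signatures(a, make_signature(c("x1", "x2"), c(2, 2)))
  expect_identical(disjoint$n_intersect, 0L)
})
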