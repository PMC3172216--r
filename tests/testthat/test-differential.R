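test_that("fit_gene_models computes two-group sufficient statistics", {
  fit <- fit_gene_models(toy_two_group(), c("perturbed", "control"), "48h")
  expect_equal(fit$lfc, 4)          # mean(5,7) - mean(1,3)
  expect_equal(fit$s_sq, 2)         # pooled variance of two variance-2 groups
  expect_identical(fit$df_residual, 2L)
  expect_identical(c(fit$n1, fit$n2), c(2L, 2L))

  # identical groups -> lfc 0
  m <- rbind(G1 = c(2, 4, 2, 4))
  colnames(m) <- c("c1", "c2", "p1", "p2")
  ds <- make_ds(m, condition = c("control", "control", "perturbed", "perturbed"),
                time = "48h")
  expect_equal(fit_gene_models(ds, c("perturbed", "control"), "48h")$lfc, 0)

  # shift invariance of differences and variances
  ds2 <- toy_two_group(); ds2$values <- ds2$values + 100
  fit2 <- fit_gene_models(ds2, c("perturbed", "control"), "48h")
  expect_equal(fit2$lfc, fit$lfc)
  expect_equal(fit2$s_sq, fit$s_sq)
})

test_that("fit_gene_models rejects unusable designs", {
  ds <- toy_two_group()
  ds$annotations$condition[1] <- "other"
  expect_error(fit_gene_models(ds, c("perturbed", "control"), "48h"),
               ">= 2 samples per condition")
  lin <- toy_two_group(); lin$scale <- "linear"
  expect_error(fit_gene_models(lin, c("perturbed", "control"), "48h"),
               "log-scale")
})

test_that("prior estimation handles the zero-dispersion limit and scales correctly", {
  expect_error(estimate_prior(rep(1, 5), 2), ">= 10")

  p0 <- estimate_prior(rep(2.5, 100), 2)
  expect_identical(p0$d0, Inf)       # no excess dispersion
  # bias-corrected geometric mean: exp(mean(log s^2) - digamma(df/2) + log(df/2))
  expect_equal(p0$s0_sq, 2.5 * exp(-digamma(1)))

  set.seed(13)
  s_sq <- 1 * 4 / rchisq(5000, 4) * rchisq(5000, 2) / 2  # s0=1, d0=4, df=2
  p1 <- estimate_prior(s_sq, 2)
  p4 <- estimate_prior(4 * s_sq, 2)
  expect_equal(p4$d0, p1$d0, tolerance = 1e-10)      # scale equivariance
  expect_equal(p4$s0_sq, 4 * p1$s0_sq, tolerance = 1e-10)
})

test_that("moderated t matches hand arithmetic and its limits", {
  fit <- fit_gene_models(toy_two_group(), c("perturbed", "control"), "48h")

  tab <- moderate_t(fit, ebayes_prior(d0 = 2, s0_sq = 1), time = "48h")
  expect_equal(tab$s_tilde_sq, 1.5)                   # (2*1 + 2*2)/4
  expect_equal(tab$t_mod, 4 / sqrt(1.5), tolerance = 1e-10)  # 3.2660 on 4 df
  expect_equal(tab$df_total, 4)
  expect_equal(tab$p, 2 * pt(-4 / sqrt(1.5), 4), tolerance = 1e-12)

  # d0 = 0: ordinary pooled two-sample t
  t0 <- moderate_t(fit, ebayes_prior(d0 = 0, s0_sq = 1))
  pooled <- t.test(c(5, 7), c(1, 3), var.equal = TRUE)
  expect_equal(t0$t_mod, unname(pooled$statistic), tolerance = 1e-10)
  expect_equal(t0$p, pooled$p.value, tolerance = 1e-10)

  # d0 = Inf: full shrinkage to s0 for every gene, normal tail
  tinf <- moderate_t(fit, ebayes_prior(d0 = Inf, s0_sq = 3))
  expect_identical(tinf$s_tilde_sq, 3)
  expect_equal(tinf$p, 2 * pnorm(-abs(tinf$t_mod)), tolerance = 1e-12)
})

test_that("shrunken variances always lie between s_sq and s0_sq", {
  set.seed(21)
  n <- 500
  fit <- data.frame(gene = sprintf("G%03d", 1:n), lfc = rnorm(n),
                    s_sq = rexp(n), df_residual = 2, mean_expr = 8,
                    n1 = 2, n2 = 2)
  tab <- moderate_t(fit, ebayes_prior(d0 = 3, s0_sq = 1))
  expect_true(all(tab$s_tilde_sq >= pmin(fit$s_sq, 1) - 1e-12))
  expect_true(all(tab$s_tilde_sq <= pmax(fit$s_sq, 1) + 1e-12))
})

test_that("whole differential stage agrees with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(17)
  m <- matrix(rnorm(2000 * 4, 8, 1), 2000, 4,
              dimnames = list(sprintf("G%04d", 1:2000), c("c1", "c2", "p1", "p2")))
  m[1:100, 3:4] <- m[1:100, 3:4] + 1.5
  ann <- data.frame(sample_id = colnames(m),
                    condition = c("control", "control", "perturbed", "perturbed"),
                    time = "48h", stringsAsFactors = FALSE)
  ds <- expression_dataset(m, "log2-vst", ann)
  tab <- run_differential(ds, c("perturbed", "control"), "48h")
  fit <- fit_gene_models(ds, c("perturbed", "control"), "48h")
  prior <- estimate_prior(fit$s_sq, fit$df_residual)

  lfit <- limma::eBayes(limma::lmFit(m, cbind(1, ann$condition == "perturbed")))
  expect_equal(prior$d0, lfit$df.prior, tolerance = 1e-8)
  expect_equal(prior$s0_sq, lfit$s2.prior, tolerance = 1e-8)
  expect_equal(tab$lfc, unname(lfit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(tab$t_mod, unname(lfit$t[, 2]), tolerance = 1e-8)
  expect_equal(tab$p, unname(lfit$p.value[, 2]), tolerance = 1e-8)
})

test_that("BH adjustment reproduces hand computations and the stats oracle", {
  expect_equal(bh_adjust(c(0.001, 0.008, 0.039, 0.041)),
               c(0.004, 0.016, 0.041, 0.041))
  expect_identical(bh_adjust(0.03), 0.03)              # m = 1
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))    # ties propagate down
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\(0, 1\\]")

  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
  }
})

test_that("derive_signature applies both thresholds by hand", {
  tab <- data.frame(gene = paste0("g", 1:6), time = "48h",
                    lfc = c(2.1, 0.5, 3.0, -1.4, 1.0, 0.1),
                    s_sq = 1, s_tilde_sq = 1, df_residual = 2, df_total = 4,
                    mean_expr = 8, t_mod = 1,
                    p = c(0.001, 0.001, 0.2, 0.005, 0.009, 0.5),
                    q = c(0.001, 0.001, 0.2, 0.005, 0.009, 0.5),
                    direction = c("up", "up", "up", "down", "up", "up"),
                    stringsAsFactors = FALSE)
  sig <- derive_signature(tab, fdr = 0.01, fold = 2, name = "toy")
  expect_identical(sig$entries$gene, c("G1", "G4", "G5"))  # symbols uppercased
  expect_identical(sig$entries$direction, c("up", "down", "up"))
  expect_identical(c(sig$n_up, sig$n_down), c(2L, 1L))

  tab$q <- rep(1 - 1e-9, 6)
  expect_identical(nrow(derive_signature(tab)$entries), 0L)

  tab$q <- c(0.001, 0.001, 0.2, 0.005, 0.009, 0.5)
  sig1 <- derive_signature(tab, fdr = 0.01, fold = 1)
  expect_identical(nrow(sig1$entries), sum(tab$q < 0.01))  # q-only selection
})
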