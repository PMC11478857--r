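# Regressions, group comparisons, normality gate, and x50.

test_that("fit_linear recovers exact lines and handles degeneracies", {
  f <- fit_linear(1:10, 2 * (1:10) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)
  # constant response: R^2 defined as 0 and flagged
  g <- fit_linear(1:5, rep(3, 5))
  expect_equal(g$r_squared, 0)
  expect_true(g$degenerate)
  expect_error(fit_linear(rep(1, 5), 1:5), "constant")
  expect_error(fit_linear(1:2, 1:2), "3 points")
})

test_that("noisy lines at design noise stay above the R^2 bound in >= 95% of replicates", {
  x <- seq(0, 1, by = 0.1)
  # sigma chosen so the expected R^2 is ~0.98
  sigma <- sqrt(9 * stats::var(x) * (1 / 0.98 - 1) * 10 / 11)
  hits <- withr::with_seed(10, {
    sum(replicate(100, {
      y <- 3 * x + stats::rnorm(length(x), sd = sigma)
      r2 <- fit_linear(x, y)$r_squared
      r2 >= 0.95 && r2 <= 1
    }))
  })
  expect_gte(hits, 95)
})

test_that("R^2 is invariant under affine rescaling of both variables", {
  withr::with_seed(11, {
    x <- runif(20)
    y <- 1.5 * x + stats::rnorm(20, sd = 0.2)
    r2 <- fit_linear(x, y)$r_squared
    expect_equal(fit_linear(10 * x - 3, -2 * y + 7)$r_squared, r2)
  })
})

test_that("gradient analysis returns four regressions, exact on noiseless linear truth", {
  wt <- rep(seq(0, 1, by = 0.1), each = 3)
  df <- data.frame(wt_pct = wt, cells_per_ml = 2e8 * wt,
                   alpha_npm = 2 + 12 * wt, c_mps = 1483.5 + 5 * wt,
                   replicate = rep(1:3, 11))
  regs <- gradient_analysis(df)
  expect_named(regs, c("alpha_vs_wt", "alpha_vs_cells", "c_vs_wt",
                       "c_vs_cells"))
  for (r in regs) expect_equal(r$r_squared, 1)
  expect_equal(regs$alpha_vs_wt$slope, 12)
  # shuffled responses carry no signal
  shuffled <- df
  shuffled$alpha_npm <- withr::with_seed(12, sample(df$alpha_npm))
  expect_lt(gradient_analysis(shuffled)$alpha_vs_wt$r_squared, 0.3)
  expect_error(gradient_analysis(df[df$wt_pct < 0.2, ]), "3 distinct")
})

test_that("ANOVA/Tukey letters separate well-separated groups and join equivalent ones", {
  # indistinguishable groups share one letter (deterministic fixture:
  # between-group differences far below within-group spread)
  same <- list(a = c(9.2, 10.8, 10.1), b = c(9.3, 10.6, 10.0),
               c = c(9.2, 10.7, 10.2))
  cmp <- anova_tukey(same)
  expect_true(all(cmp$letters == cmp$letters[1]))
  # means separated by >> 10 pooled SDs: every letter distinct
  far <- withr::with_seed(14, {
    list(a = rnorm(3, 0, 1), b = rnorm(3, 50, 1), c = rnorm(3, 100, 1))
  })
  cmp2 <- anova_tukey(far)
  expect_lt(cmp2$anova_p, 0.05)
  expect_length(unique(cmp2$letters), 3)
  expect_true(all(cmp2$pairwise$significant))
  expect_error(anova_tukey(list(a = 1:3)), "2 groups")
  expect_error(anova_tukey(list(a = 1:3, b = 2)), "2 observations")
})

test_that("Tukey-Kramer supports unequal group sizes", {
  gr <- withr::with_seed(15, {
    list(a = rnorm(4, 0), b = rnorm(7, 0.2), c = rnorm(5, 30))
  })
  cmp <- anova_tukey(gr)
  expect_equal(unname(cmp$n), c(4L, 7L, 5L))
  expect_equal(cmp$letters[["a"]], cmp$letters[["b"]])
  expect_false(cmp$letters[["c"]] %in% c(cmp$letters[["a"]],
                                         cmp$letters[["b"]]))
})

test_that("letter display is consistent with the pairwise significance matrix", {
  # two groups share a letter iff their adjusted p >= alpha
  withr::with_seed(16, {
    for (rep_i in 1:20) {
      k <- sample(3:5, 1)
      means <- sample(c(0, 0, 1, 5, 20), k)
      gr <- stats::setNames(
        lapply(means, function(m) rnorm(sample(3:6, 1), m, 1)),
        letters[seq_len(k)])
      cmp <- anova_tukey(gr)
      share <- function(g1, g2) {
        any(strsplit(cmp$letters[[g1]], "")[[1]] %in%
              strsplit(cmp$letters[[g2]], "")[[1]])
      }
      for (i in seq_len(nrow(cmp$pairwise))) {
        p <- cmp$pairwise[i, ]
        expect_identical(share(p$group1, p$group2), p$p_adjusted >= 0.05)
      }
      expect_true(all(nchar(cmp$letters) > 0))
    }
  })
})

test_that("three-phase pattern: Ringer and filtrate share a letter, suspension differs", {
  gr <- withr::with_seed(17, {
    list(ringer = rnorm(3, 2.0, 0.008),
         suspension = rnorm(3, 14.0, 0.05),
         filtrate = rnorm(3, 2.0, 0.008))
  })
  cmp <- anova_tukey(gr)
  expect_equal(cmp$letters[["ringer"]], cmp$letters[["filtrate"]])
  expect_false(cmp$letters[["suspension"]] == cmp$letters[["ringer"]])
})

test_that("Shapiro-Wilk gate passes normal samples and rejects heavy tails", {
  res <- withr::with_seed(18, {
    normal_pass <- sum(replicate(100, {
      shapiro_wilk_gate(list(g = rnorm(30)))$normal
    }))
    lognormal_fail <- sum(replicate(100, {
      !shapiro_wilk_gate(list(g = rlnorm(30, sdlog = 1)))$normal
    }))
    c(normal_pass, lognormal_fail)
  })
  expect_gte(res[1], 90)
  expect_gt(res[2], 50)
  expect_error(shapiro_wilk_gate(list(g = 1:2)), "3 observations")
})

test_that("non-normal groups are excluded from ANOVA when gated", {
  gr <- withr::with_seed(19, {
    list(a = rnorm(20, 0), b = rnorm(20, 5),
         weird = rlnorm(20, sdlog = 1.5))
  })
  expect_warning(cmp <- anova_tukey(gr, normality_gate = TRUE),
                 "non-normal")
  expect_named(cmp$means, c("a", "b"))
})

test_that("x50 follows the log-linear interpolation rule", {
  # all mass in one bin: geometric midpoint, flagged
  p1 <- particle_size_distribution(c(4, 6), 100)
  expect_warning(x <- compute_x50(p1), "degenerate")
  expect_equal(x, sqrt(24), tolerance = 1e-12)
  # symmetric-in-log distribution about 5 um
  edges <- 5 * exp(seq(-1, 1, length.out = 9))
  dens <- c(5, 10, 15, 20, 20, 15, 10, 5)
  p2 <- particle_size_distribution(edges, dens, normalize = TRUE)
  expect_equal(compute_x50(p2), 5)
})

test_that("binned lognormal x50 matches the analytic median on default and refined grids", {
  prof <- make_strain_profiles()$w3470
  psd <- generate_psd(prof)
  half_bin <- exp(diff(log(psd$bin_edges))[1] / 2)
  expect_lt(abs(log(compute_x50(psd)) - log(5.80)), log(half_bin))
  # 10x refined grid: within one (refined) bin width of the analytic median
  fine_edges <- exp(seq(log(0.7), log(70), length.out = 601))
  fine <- generate_psd(prof, bin_edges = fine_edges)
  med <- mixture_median_oracle(prof$psd$medians, prof$psd$log_sds,
                               prof$psd$weights)
  expect_lt(abs(log(compute_x50(fine)) - log(med)),
            diff(log(fine_edges))[1])
})
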