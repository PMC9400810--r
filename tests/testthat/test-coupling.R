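test_that("Spearman rho: worked 5-point example and monotone identity", {
  r <- spearman_test(c(1, 2, 3, 4, 5), c(3, 1, 2, 5, 4))
  expect_equal(r$rho, 0.6, tolerance = 1e-12)  # 1 - 6*8/(5*24)
  expect_equal(r$method, "exact")
  m <- spearman_test(1:8, exp(1:8))            # strictly monotone map
  expect_equal(m$rho, 1)
  expect_equal(m$p, 2 / factorial(8))          # identity + reversal only
  # invariance under strictly increasing transforms of either variable
  set.seed(1)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(spearman_test(x, y)$rho, spearman_test(exp(x), y^3 + y)$rho)
})

test_that("exact permutation null matches an independent enumeration", {
  for (n in c(4, 5, 6)) {
    P <- oracle_permutations(n)
    rho_null <- 1 - 6 * rowSums(sweep(P, 2, seq_len(n))^2) / (n * (n^2 - 1))
    mine <- spearman_null_rhos(n)
    expect_equal(sort(mine), sort(rho_null), tolerance = 1e-12)
    # p for an arbitrary observed pair equals the brute-force tail
    set.seed(n)
    x <- sample(n); y <- sample(n)
    obs <- spearman_test(x, y)
    expect_equal(obs$p, mean(abs(rho_null) >= abs(obs$rho) - 1e-12))
  }
  # n=5, rho=1: 2/5! * (# permutations attaining |rho|=1)
  expect_equal(spearman_test(1:5, 1:5)$p, 2 / factorial(5))
})

test_that("large-n and tied inputs fall back to the t approximation", {
  set.seed(2)
  x <- rnorm(30); y <- x + rnorm(30)
  r <- spearman_test(x, y)
  expect_equal(r$method, "t-approximation")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
  xt <- c(1, 1, 2, 3, 4, 5, 6)
  expect_equal(spearman_test(xt, rnorm(7))$method, "t-approximation")
  expect_error(spearman_test(rep(1, 8), rnorm(8)), "constant")
})

test_that("correlogram: cell layout, report filter, undefined cells", {
  set.seed(3)
  subs <- sprintf("s%02d", 1:8)
  cells <- expand.grid(band = eeg_bands()$band, roi = "F",
                       hemisphere = c("L", "R"), stringsAsFactors = FALSE)
  tone <- rnorm(8)
  power_df <- do.call(rbind, lapply(subs, function(s)
    cbind(subject = s, cells,
          power_db = 12 + 2 * tone[match(s, subs)] + rnorm(nrow(cells), 0, .1))))
  hrv_df <- data.frame(subject = subs, rmssd_ms = 40 + 10 * tone + rnorm(8, 0, 1),
                       sdnn_ms = rnorm(8), sd1_ms = NA_real_, hf_ms2 = rnorm(8))
  cg <- spearman_correlogram(power_df, hrv_df)
  expect_equal(nrow(cg), nrow(cells) * 4)
  strong <- cg[cg$hrv_param == "rmssd_ms", ]
  expect_true(all(strong$rho > 0.5))
  expect_true(all(strong$passes_report_filter == (strong$rho >= 0.5 & strong$p < 0.05)))
  undef <- cg[cg$hrv_param == "sd1_ms", ]
  expect_true(all(undef$undefined))
  expect_true(all(!undef$passes_report_filter))
  expect_error(spearman_correlogram(power_df[power_df$subject %in% subs[1:3], ],
                                    hrv_df), "at least 5")
})

test_that("group ANOVA: null identity, Bonferroni definition, detection power", {
  df0 <- data.frame(variable = "v", group = rep(c("a", "b"), each = 4),
                    value = rep(c(1, 2, 3, 4), 2))
  r0 <- group_compare(df0, family_size = 4)
  expect_equal(r0$p_bonferroni, 1)
  expect_equal(r0$F, 0)
  # corrected p == min(1, m * p_raw) against brute force, random families
  set.seed(4)
  for (i in 1:25) {
    m <- sample(1:8, 1)
    df <- data.frame(variable = "x", group = rep(c("a", "b"), each = 6),
                     value = rnorm(12))
    r <- group_compare(df, family_size = m)
    expect_equal(r$p_bonferroni, min(1, m * r$p_raw), tolerance = 1e-12)
    # F from an independent route
    f_lm <- anova(lm(value ~ group, df))[["F value"]][1]
    expect_equal(r$F, f_lm, tolerance = 1e-9)
  }
  # separated groups are detected
  set.seed(5)
  hits <- mean(replicate(100, {
    df <- data.frame(variable = "x",
                     group = rep(c("a", "b"), c(11, 7)),
                     value = c(rnorm(11, 0), rnorm(7, 3)))
    group_compare(df, family_size = 1)$p_bonferroni < 0.05
  }))
  expect_gte(hits, 0.95)
  expect_error(group_compare(data.frame(variable = "v",
                                        group = rep(c("a", "b"), each = 2),
                                        value = rep(1, 4))), "degenerate")
})

rand_design <- function(n, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, c("F", "C", "P", "T", "O")))
  as.data.frame(X)
}

test_that("best-subset regression: exact recovery with minimal subset", {
  X <- rand_design(12, 6)
  y <- 2 + 3 * X$F
  fit <- best_subset_regression(X, y)
  expect_equal(fit$included_predictors, "F")
  expect_equal(unname(fit$coefficients["F"]), 3, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 2, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-12)
  expect_false(fit$saturated)
})

test_that("adjusted R^2 matches its defining formula; selected beats full model", {
  for (seed in 1:20) {
    X <- rand_design(14, seed)
    set.seed(seed + 1000)
    y <- 1 + X$C - 0.5 * X$T + rnorm(14)
    fit <- best_subset_regression(X, y)
    # brute-force oracle on every fitted subset
    for (i in seq_len(nrow(fit$all_subsets))) {
      s <- strsplit(fit$all_subsets$subset[i], "\\+")[[1]]
      lmfit <- lm(y ~ ., data = cbind(X[, s, drop = FALSE], y = y))
      expect_equal(fit$all_subsets$r2[i], summary(lmfit)$r.squared,
                   tolerance = 1e-9)
      expect_equal(fit$all_subsets$r2_adj[i], summary(lmfit)$adj.r.squared,
                   tolerance = 1e-9)
    }
    full <- fit$all_subsets$r2_adj[fit$all_subsets$k == 5]
    expect_gte(fit$r2_adj, full)
    expect_lte(fit$r2_adj, fit$r2 + 1e-12)
    expect_lt(abs(sum(fit$residuals)), 1e-9)
  }
})

test_that("coefficient SEs, Pearson residuals and saturation flag", {
  X <- rand_design(18, 9)
  set.seed(10)
  y <- 1 + 2 * X$F + rnorm(18)
  fit <- best_subset_regression(X, y)
  ref <- lm(y ~ ., data = cbind(X[, fit$included_predictors, drop = FALSE], y = y))
  sref <- summary(ref)
  expect_equal(unname(fit$se), unname(sref$coefficients[, "Std. Error"]),
               tolerance = 1e-9)
  expect_equal(unname(fit$pearson_residuals),
               unname(residuals(ref) / sref$sigma), tolerance = 1e-9)
  # n = 7 with the full 5-predictor model: one residual df -> saturated flag
  X7 <- rand_design(7, 11)
  y7 <- as.matrix(X7) %*% c(1, -1, 2, 0.5, -2) + rnorm(7, sd = 0.01)
  fit7 <- best_subset_regression(X7, as.numeric(y7))
  if (length(fit7$included_predictors) == 5) expect_true(fit7$saturated)
  expect_equal(fit7$n, 7)
  # slope equivariance under predictor rescaling
  Xs <- X; Xs$F <- Xs$F * 10
  fs <- best_subset_regression(Xs, y)
  expect_equal(unname(fs$coefficients["F"]),
               unname(fit$coefficients["F"]) / 10, tolerance = 1e-9)
})

test_that("degenerate designs are skipped with a log, not fit", {
  X <- rand_design(10, 12)
  X$C <- X$F                      # collinear pair
  y <- 1 + X$F + rnorm(10)
  fit <- best_subset_regression(X, y)
  expect_true(any(grepl("rank deficient", fit$skipped)))
  expect_false(all(c("F", "C") %in% fit$included_predictors))
})
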