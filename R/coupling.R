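#' Cross-modal coupling statistics
#'
#' Spearman correlograms between band/ROI power and HRV parameters (with the
#' |rho| >= 0.5 and p < 0.05 reporting filter), two-group one-way ANOVA with
#' Bonferroni correction, and exhaustive best-subset OLS with adjusted-R^2
#' selection and residual diagnostics.
#'
#' @name coupling
NULL

# cache of exact Spearman null distributions (rho over all n! rank
# permutations), keyed by n
.spearman_null_cache <- new.env(parent = emptyenv())

.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(rep(k, nrow(sub)), sub + (sub >= k))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Exact Spearman null distribution of rho for sample size n (no ties)
#'
#' @param n sample size (2..9)
#' @return numeric vector of rho over all n! permutations
#' @export
spearman_null_rhos <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearman_null_cache[[key]])) return(.spearman_null_cache[[key]])
  if (n > 9) stop("exact enumeration limited to n <= 9")
  P <- .all_permutations(n)
  S <- rowSums(sweep(P, 2, seq_len(n))^2)
  rho <- 1 - 6 * S / (n * (n^2 - 1))
  .spearman_null_cache[[key]] <- rho
  rho
}

#' Spearman rank correlation with small-sample exact p-value
#'
#' Average ranks for ties; two-sided p by full permutation enumeration when
#' n <= 9 and neither variable is tied, by the t approximation otherwise.
#'
#' @param x,y numeric vectors
#' @return list: `rho`, `p`, `method` ("exact" or "t-approximation")
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (anyNA(x) || anyNA(y)) stop("missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant variable: Spearman correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  tied <- anyDuplicated(x) || anyDuplicated(y)
  if (n <= 9 && !tied) {
    null <- spearman_null_rhos(n)
    p <- mean(abs(null) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    if (abs(rho) >= 1 - 1e-12) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), n - 2)
    }
    method <- "t-approximation"
  }
  list(rho = rho, p = p, method = method)
}

#' Spearman correlogram between band/ROI power and HRV parameters
#'
#' One cell per band x (ROI, hemisphere) x HRV parameter. Cells where either
#' variable is constant or missing are flagged undefined (NA rho) rather
#' than silently zero. The reporting filter marks cells with |rho| >= 0.5
#' and p < 0.05.
#'
#' @param power_df tidy band-power table: subject, band, roi, hemisphere,
#'   power_db
#' @param hrv_df per-subject HRV table: subject plus columns named in
#'   `hrv_params`
#' @param group optional label copied into the output
#' @param hrv_params HRV parameter columns to correlate
#' @param min_n minimum subjects (contract: >= 5)
#' @return data.frame of cells: group, band, roi, hemisphere, hrv_param, n,
#'   rho, p, undefined, passes_report_filter
#' @export
spearman_correlogram <- function(power_df, hrv_df, group = NA_character_,
                                 hrv_params = c("sdnn_ms", "rmssd_ms",
                                                "sd1_ms", "hf_ms2"),
                                 min_n = 5) {
  subs <- intersect(unique(power_df$subject), hrv_df$subject)
  if (length(subs) < min_n)
    stop("need at least ", min_n, " matched subjects, have ", length(subs))
  cells <- unique(power_df[, c("band", "roi", "hemisphere")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- power_df$band == cells$band[i] & power_df$roi == cells$roi[i] &
      power_df$hemisphere == cells$hemisphere[i]
    pw <- power_df[sel, ]
    x <- pw$power_db[match(subs, pw$subject)]
    for (par in hrv_params) {
      y <- hrv_df[[par]][match(subs, hrv_df$subject)]
      res <- tryCatch(spearman_test(x, y), error = function(e) NULL)
      undef <- is.null(res) || anyNA(x) || anyNA(y)
      rows[[length(rows) + 1L]] <- data.frame(
        group = group, band = cells$band[i], roi = cells$roi[i],
        hemisphere = cells$hemisphere[i], hrv_param = par, n = length(subs),
        rho = if (undef) NA_real_ else res$rho,
        p = if (undef) NA_real_ else res$p,
        undefined = undef,
        passes_report_filter = if (undef) FALSE
        else abs(res$rho) >= 0.5 && res$p < 0.05)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-group one-way ANOVA per variable with Bonferroni correction
#'
#' @param df long data.frame with columns variable, group, value (one row
#'   per subject per variable)
#' @param family_size Bonferroni family size m; default = number of distinct
#'   variables in `df`. Corrected p = min(1, m * p_raw).
#' @return data.frame: variable, n1, n2, F, p_raw, p_bonferroni, family_size
#' @export
group_compare <- function(df, family_size = NULL) {
  vars <- unique(df$variable)
  m <- if (is.null(family_size)) length(vars) else family_size
  gl <- unique(df$group)
  if (length(gl) != 2) stop("exactly two groups required")
  rows <- lapply(vars, function(v) {
    d <- df[df$variable == v, ]
    a <- d$value[d$group == gl[1]]; b <- d$value[d$group == gl[2]]
    if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 subjects")
    if (stats::var(c(a, b)) == 0)
      stop("degenerate variance in both groups for variable ", v)
    ma <- mean(a); mb <- mean(b); gm <- mean(c(a, b))
    ssb <- length(a) * (ma - gm)^2 + length(b) * (mb - gm)^2
    ssw <- sum((a - ma)^2) + sum((b - mb)^2)
    dfw <- length(a) + length(b) - 2
    Fv <- ssb / (ssw / dfw)
    p <- stats::pf(Fv, 1, dfw, lower.tail = FALSE)
    data.frame(variable = v, n1 = length(a), n2 = length(b), F = Fv,
               p_raw = p, p_bonferroni = min(1, m * p), family_size = m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exhaustive best-subset OLS with adjusted-R^2 selection
#'
#' Fits ordinary least squares (intercept included, QR solve) for every
#' non-empty subset of the predictors that leaves at least one residual
#' degree of freedom, and selects the subset maximizing adjusted R^2 =
#' 1 - (1 - R^2)(n - 1)/(n - k - 1). Ties go to fewer predictors, then to
#' the lexicographically earlier subset in the declared predictor order.
#' Pearson residuals are raw residuals / sqrt(SSE / (n - k - 1)); a
#' Shapiro-Wilk test on them flags non-normality at 5%.
#'
#' @param X data.frame or matrix of predictors (columns named, conventionally
#'   F, C, P, T, O)
#' @param y numeric response (an HRV parameter per subject)
#' @param predictors predictor order used for tie-breaking
#' @return object of class `regression_fit`: `included_predictors`,
#'   `coefficients`, `se`, `r2`, `r2_adj`, `residuals`, `pearson_residuals`,
#'   `shapiro_w`, `shapiro_p`, `shapiro_reject`, `saturated`, `n`,
#'   `all_subsets` (data.frame of every fitted subset)
#' @export
best_subset_regression <- function(X, y, predictors = colnames(X)) {
  X <- as.matrix(X)[, predictors, drop = FALSE]
  n <- length(y)
  if (n < 4) stop("need at least 4 subjects")
  if (nrow(X) != n || anyNA(X) || anyNA(y)) stop("predictors/response invalid")
  sst <- sum((y - mean(y))^2)
  subsets <- list()
  for (k in seq_along(predictors))
    subsets <- c(subsets, utils::combn(predictors, k, simplify = FALSE))
  fits <- list(); log_skipped <- character(0)
  for (s in subsets) {
    k <- length(s)
    if (n - k - 1 < 1) {
      log_skipped <- c(log_skipped, paste0(paste(s, collapse = "+"),
                                           ": no residual df"))
      next
    }
    M <- cbind(`(Intercept)` = 1, X[, s, drop = FALSE])
    qrM <- qr(M)
    if (qrM$rank < ncol(M)) {
      log_skipped <- c(log_skipped, paste0(paste(s, collapse = "+"),
                                           ": rank deficient"))
      next
    }
    beta <- qr.coef(qrM, y)
    res <- y - M %*% beta
    sse <- sum(res^2)
    r2 <- if (sst > 0) 1 - sse / sst else NA_real_
    r2a <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
    fits[[length(fits) + 1L]] <- list(subset = s, k = k, beta = beta,
                                      res = as.numeric(res), sse = sse,
                                      r2 = r2, r2_adj = r2a, qr = qrM)
  }
  if (!length(fits)) stop("all subsets skipped: ",
                          paste(log_skipped, collapse = "; "))
  tab <- data.frame(
    subset = vapply(fits, function(f) paste(f$subset, collapse = "+"), ""),
    k = vapply(fits, function(f) f$k, numeric(1)),
    r2 = vapply(fits, function(f) f$r2, numeric(1)),
    r2_adj = vapply(fits, function(f) f$r2_adj, numeric(1)))
  best_adj <- max(tab$r2_adj)
  tied <- which(tab$r2_adj >= best_adj - 1e-12)
  tied <- tied[order(tab$k[tied])]        # fewer predictors first; subset
  best <- fits[[tied[1]]]                 # enumeration is already lexicographic
  k <- best$k
  sigma2 <- best$sse / (n - k - 1)
  Rinv <- backsolve(qr.R(best$qr), diag(k + 1))
  se <- sqrt(sigma2 * rowSums(Rinv^2))
  names(se) <- c("(Intercept)", best$subset)
  pres <- if (sigma2 > .Machine$double.eps * max(1, sst))
    best$res / sqrt(sigma2) else rep(0, n)
  sw <- if (n >= 3 && stats::sd(pres) > 0) stats::shapiro.test(pres)
        else list(statistic = NA_real_, p.value = NA_real_)
  structure(list(
    included_predictors = best$subset,
    coefficients = best$beta, se = se,
    r2 = best$r2, r2_adj = best$r2_adj,
    residuals = best$res, pearson_residuals = pres,
    shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
    shapiro_reject = !is.na(sw$p.value) && sw$p.value < 0.05,
    saturated = (n - k - 1) == 1,
    n = n, all_subsets = tab, skipped = log_skipped),
    class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "<regression_fit> n=%d, predictors {%s}, R2=%.3f, adj R2=%.3f%s\n",
    x$n, paste(x$included_predictors, collapse = ","), x$r2, x$r2_adj,
    if (x$saturated) " [saturated]" else ""))
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  cat(sprintf("Shapiro-Wilk on Pearson residuals: W=%.3f, p=%.4f%s\n",
              x$shapiro_w, x$shapiro_p,
              if (isTRUE(x$shapiro_reject)) " (non-normal at 5%)" else ""))
  invisible(x)
}
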