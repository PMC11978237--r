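#' Between-task comparison of one outcome
#'
#' Repeated-measures comparison of a scalar outcome across the three tasks
#' within participants. Shapiro-Wilk on each task's values gates the path:
#' all normal gives one-way repeated-measures ANOVA (with Mauchly's test of
#' sphericity and Greenhouse-Geisser-corrected degrees of freedom when it
#' rejects), otherwise the Friedman rank test. A significant overall test is
#' followed by the three pairwise within-participant comparisons (each
#' normality-gated between paired t and Wilcoxon signed-rank) with
#' Bonferroni correction (m = 3, capped at 1).
#'
#' @param data long data.frame with columns participant, task, value; or a
#'   wide participant x task matrix.
#' @param alpha significance level (gate and overall test).
#' @return list of class `task_comparison`: `test`, `statistic`, `df`,
#'   `p`, sphericity/epsilon fields for the ANOVA path, `posthoc`
#'   data.frame (pair, test, statistic, p_raw, p_adj, median_diff), `n`,
#'   `n_dropped`.
#' @export
compare_tasks <- function(data, alpha = 0.05) {
  if (is.matrix(data)) {
    wide <- data
  } else {
    need <- c("participant", "task", "value")
    if (!all(need %in% names(data)))
      stop("long input needs columns participant, task, value")
    tasks <- unique(data$task)
    parts <- unique(data$participant)
    wide <- matrix(NA_real_, length(parts), length(tasks),
                   dimnames = list(parts, tasks))
    for (i in seq_len(nrow(data)))
      wide[as.character(data$participant[i]), as.character(data$task[i])] <-
        data$value[i]
  }
  complete <- stats::complete.cases(wide)
  n_dropped <- sum(!complete)
  wide <- wide[complete, , drop = FALSE]
  n <- nrow(wide)
  k <- ncol(wide)
  if (n < 3L) stop("need at least 3 complete participants")
  if (k < 2L) stop("need at least 2 tasks")

  if (all(abs(wide - rowMeans(wide)) < 1e-12)) {
    # no within-participant task differences at all: trivially no effect
    out <- list(n = n, n_dropped = n_dropped, tasks = colnames(wide),
                test = "degenerate", statistic = 0, df = NA_real_, p = 1,
                posthoc = NULL)
    class(out) <- "task_comparison"
    return(out)
  }

  sw_p <- apply(wide, 2, function(col) {
    tryCatch(stats::shapiro.test(col)$p.value, error = function(e) 0)
  })
  normal <- all(sw_p >= alpha)
  out <- list(n = n, n_dropped = n_dropped, tasks = colnames(wide),
              normality_p = sw_p)

  if (normal) {
    rm <- rm_anova(wide)
    out$test <- "rm_anova"
    out$statistic <- rm$F
    out$sphericity_p <- rm$mauchly_p
    out$epsilon <- rm$epsilon
    out$gg_applied <- rm$gg_applied
    out$df <- rm$df
    out$p <- rm$p
  } else {
    fr <- stats::friedman.test(wide)
    out$test <- "friedman"
    out$statistic <- unname(fr$statistic)
    out$df <- unname(fr$parameter)
    out$p <- fr$p.value
  }

  out$posthoc <- NULL
  if (!is.na(out$p) && out$p < alpha && k >= 3L) {
    cmb <- utils::combn(colnames(wide), 2)
    ph <- lapply(seq_len(ncol(cmb)), function(j) {
      a <- wide[, cmb[1, j]]
      b <- wide[, cmb[2, j]]
      bt <- test_bias(a, b, alpha)
      data.frame(pair = paste(cmb[1, j], cmb[2, j], sep = " vs "),
                 test = bt$test, statistic = bt$statistic,
                 p_raw = bt$p, median_diff = stats::median(a - b))
    })
    ph <- do.call(rbind, ph)
    ph$p_adj <- stats::p.adjust(ph$p_raw, method = "bonferroni")
    out$posthoc <- ph
  }
  class(out) <- "task_comparison"
  out
}

# One-way repeated-measures ANOVA on a complete n x k matrix, with Mauchly's
# sphericity test and Greenhouse-Geisser epsilon computed from orthonormal
# contrasts of the within-participant covariance. GG correction is applied
# to both df when Mauchly rejects at 0.05.
rm_anova <- function(wide, mauchly_alpha = 0.05) {
  n <- nrow(wide); k <- ncol(wide)
  grand <- mean(wide)
  taskm <- colMeans(wide)
  subjm <- rowMeans(wide)
  ss_task <- n * sum((taskm - grand)^2)
  resid <- sweep(sweep(wide, 2, taskm), 1, subjm - grand)
  ss_err <- sum(resid^2)
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  f <- (ss_task / df1) / (ss_err / df2)

  # orthonormal contrasts; M is the covariance of the contrast scores
  C <- t(qr.Q(qr(cbind(1, diag(k))))[, 2:k, drop = FALSE])
  M <- C %*% stats::cov(wide) %*% t(C)
  eps <- sum(diag(M))^2 / (df1 * sum(M^2))
  dM <- det(M)
  mauchly_p <- NA_real_
  if (k > 2L && dM > 0) {
    W <- dM / (sum(diag(M)) / df1)^df1
    dcoef <- 1 - (2 * df1^2 + df1 + 2) / (6 * df1 * (n - 1))
    chi <- -(n - 1) * dcoef * log(W)
    mauchly_p <- stats::pchisq(chi, df1 * (df1 + 1) / 2 - 1, lower.tail = FALSE)
  }
  gg <- !is.na(mauchly_p) && mauchly_p < mauchly_alpha
  if (gg) {
    p <- stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE)
    df <- c(eps * df1, eps * df2)
  } else {
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    df <- c(df1, df2)
  }
  list(F = f, p = p, df = df, epsilon = eps, mauchly_p = mauchly_p,
       gg_applied = gg)
}

#' @export
print.task_comparison <- function(x, ...) {
  if (x$test == "degenerate") {
    cat("No within-participant task differences (degenerate comparison)\n")
    return(invisible(x))
  }
  if (x$test == "rm_anova") {
    cat(sprintf("Repeated-measures ANOVA: F(%.2f, %.2f) = %.3f, p = %.4g%s\n",
                x$df[1], x$df[2], x$statistic, x$p,
                if (isTRUE(x$gg_applied)) " (Greenhouse-Geisser)" else ""))
  } else {
    cat(sprintf("Friedman test: chi-squared(%d) = %.3f, p = %.4g\n",
                x$df, x$statistic, x$p))
  }
  if (!is.null(x$posthoc)) {
    cat("Post hoc (Bonferroni):\n")
    print.data.frame(x$posthoc[c("pair", "test", "p_raw", "p_adj",
                                 "median_diff")], row.names = FALSE)
  }
  invisible(x)
}

#' Between-group comparison of one outcome
#'
#' Two-group comparison (typically female vs male smartphone outcomes):
#' Shapiro-Wilk in each group gates between the two-sample t test (pooled
#' variance) and the Wilcoxon rank-sum test. Constant data in both groups
#' with equal constants gives a degenerate result with no p value.
#'
#' @param values numeric outcome values.
#' @param groups group labels (exactly two levels after dropping NAs).
#' @param alpha significance level of the normality gate.
#' @return list with `test`, `statistic`, `p`, `group_medians`, `n`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]
  groups <- as.character(groups[ok])
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("need exactly 2 groups")
  a <- values[groups == lev[1]]
  b <- values[groups == lev[2]]
  if (length(a) < 3L || length(b) < 3L) stop("need n >= 3 per group")
  meds <- c(stats::median(a), stats::median(b))
  names(meds) <- lev
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && a[1] == b[1]) {
    return(list(test = "degenerate", statistic = NA_real_, p = NA_real_,
                group_medians = meds, n = c(length(a), length(b))))
  }
  sw <- vapply(list(a, b), function(g) {
    tryCatch(stats::shapiro.test(g)$p.value, error = function(e) 0)
  }, numeric(1))
  if (all(sw >= alpha)) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
         group_medians = meds, n = c(length(a), length(b)))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    list(test = "wilcoxon rank-sum", statistic = unname(wt$statistic),
         p = wt$p.value, group_medians = meds, n = c(length(a), length(b)))
  }
}
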