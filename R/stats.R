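#' Group-level statistical wrappers
#'
#' Normality-gated paired comparisons (paired t-test vs Wilcoxon
#' signed-rank), two-way repeated-measures ANOVA with per-time corrected
#' contrasts, and one-way ANOVA with Holm-Sidak contrasts, mirroring the
#' tests reported alongside the pipeline's figures.
#'
#' @name stats-module
NULL

# D'Agostino-Pearson K^2 omnibus normality test (skewness + kurtosis
# z-statistics); used instead of Shapiro-Wilk for n > 50.
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 20) stop("D'Agostino-Pearson requires n >= 20")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  # skewness z (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  zs <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis z (Anscombe-Glynn 1983)
  eg2 <- -6 / (n + 1)
  vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eg2) / sqrt(vg2)
  beta <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / beta * (2 / beta + sqrt(1 + 4 / beta^2))
  zk <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- zs^2 + zk^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE))
}

normality_p <- function(x) {
  if (length(unique(x)) < 3L) return(0)  # degenerate: treat as non-normal
  if (length(x) > 50) dagostino_pearson(x)$p_value
  else shapiro.test(x)$p.value
}

#' Normality-gated paired comparison
#'
#' The paired differences are tested for normality (Shapiro-Wilk for
#' n <= 50, D'Agostino-Pearson above); normal differences get a paired
#' t-test, otherwise a Wilcoxon signed-rank test. All-zero differences are
#' a documented degenerate case reported with p = 1.
#'
#' @param x,y paired samples of equal length (>= 3).
#' @param normality_alpha significance level of the normality gate
#'   (default 0.05).
#' @return list of class `gated_test`: `test`, `statistic`, `p_value`,
#'   `normality_p`, `n`.
#' @export
paired_compare <- function(x, y, normality_alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must have equal lengths")
  if (length(x) < 3L) stop("need at least 3 pairs")
  d <- x - y
  if (all(d == 0)) {
    return(structure(list(test = "paired t-test (degenerate: all-zero differences)",
                          statistic = NA_real_, p_value = 1,
                          normality_p = NA_real_, n = length(x)),
                     class = "gated_test"))
  }
  np <- normality_p(d)
  if (np >= normality_alpha) {
    tt <- t.test(x, y, paired = TRUE)
    res <- list(test = "paired t-test", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
    res <- list(test = "Wilcoxon signed-rank",
                statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  structure(c(res, list(normality_p = np, n = length(x))),
            class = "gated_test")
}

#' @export
print.gated_test <- function(x, ...) {
  cat(sprintf("<gated_test> %s: statistic = %.4g, p = %.4g (normality p = %.3g, n = %d)\n",
              x$test, x$statistic, x$p_value, x$normality_p, x$n))
  invisible(x)
}

# Step-down Holm-Sidak adjustment; monotone by construction.
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    a <- 1 - (1 - p[o[i]])^(m - i + 1)
    running <- max(running, a)
    adj[o[i]] <- min(1, running)
  }
  adj
}

adjust_p <- function(p, correction) {
  switch(correction,
         bonferroni = pmin(1, p * length(p)),
         `holm-sidak` = holm_sidak(p),
         stop("unknown correction: ", correction))
}

check_balanced <- function(tab, f1, f2) {
  counts <- table(tab[[f1]], tab[[f2]])
  if (length(unique(as.vector(counts))) != 1L) {
    miss <- which(counts != max(counts), arr.ind = TRUE)
    stop("unbalanced design; deficient cells: ",
         paste(apply(miss, 1L, function(i)
           paste0(rownames(counts)[i[1]], "/", colnames(counts)[i[2]])),
           collapse = ", "))
  }
}

#' Two-way repeated-measures ANOVA with per-time contrasts
#'
#' Fits `value ~ group * time + Error(unit)` on a balanced long-format
#' table (`group` between units, `time` within), then compares groups at
#' each time bin with unpaired t-tests corrected across bins.
#'
#' @param table long-format data frame with columns `unit_id`, `group`,
#'   `time_bin`, `value`; one row per (unit, time) cell.
#' @param correction `"bonferroni"` (default) or `"holm-sidak"`.
#' @return list of class `rm_anova`: `anova` (data frame of effects with F
#'   and p) and `contrasts` (data frame `time_bin`, `statistic`, `p_raw`,
#'   `p_adj`).
#' @export
two_way_rm_anova <- function(table, correction = c("bonferroni",
                                                   "holm-sidak")) {
  correction <- match.arg(correction)
  need <- c("unit_id", "group", "time_bin", "value")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(table[, c("unit_id", "group", "time_bin")]))
    stop("duplicate (unit, group, time_bin) keys")
  check_balanced(table, "group", "time_bin")
  tab <- data.frame(unit_id = factor(table$unit_id),
                    group = factor(table$group),
                    time_bin = factor(table$time_bin),
                    value = table$value)
  fit <- aov(value ~ group * time_bin + Error(unit_id), data = tab)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    s <- stratum[[1]]
    keep <- !grepl("Residuals", rownames(s))
    for (i in which(keep))
      rows[[length(rows) + 1L]] <- data.frame(
        effect = trimws(rownames(s)[i]),
        df = s[i, "Df"], F = s[i, "F value"], p = s[i, "Pr(>F)"])
  }
  anova_tab <- do.call(rbind, rows)
  bins <- levels(tab$time_bin)
  groups <- levels(tab$group)
  if (length(groups) != 2L)
    stop("per-time contrasts require exactly two groups")
  con <- do.call(rbind, lapply(bins, function(b) {
    sub <- tab[tab$time_bin == b, ]
    tt <- t.test(value ~ group, data = sub, var.equal = FALSE)
    data.frame(time_bin = b, statistic = unname(tt$statistic),
               p_raw = tt$p.value)
  }))
  con$p_adj <- adjust_p(con$p_raw, correction)
  structure(list(anova = anova_tab, contrasts = con,
                 correction = correction),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("<rm_anova> effects:\n")
  print(x$anova, row.names = FALSE)
  cat(sprintf("per-time contrasts (%s-adjusted):\n", x$correction))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA with corrected pairwise contrasts
#'
#' @param values numeric outcomes.
#' @param groups group labels (>= 2 groups).
#' @param correction `"holm-sidak"` (default) or `"bonferroni"`.
#' @return list of class `oneway_anova`: `anova` (F, df, p) and `contrasts`
#'   (pairwise unpaired t-tests with raw and adjusted p).
#' @export
one_way_anova <- function(values, groups,
                          correction = c("holm-sidak", "bonferroni")) {
  correction <- match.arg(correction)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  fit <- aov(values ~ groups)
  s <- summary(fit)[[1]]
  pairs <- utils::combn(levels(groups), 2L)
  con <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tt <- t.test(values[groups == a], values[groups == b])
    data.frame(group_a = a, group_b = b,
               statistic = unname(tt$statistic), p_raw = tt$p.value)
  }))
  con$p_adj <- adjust_p(con$p_raw, correction)
  structure(list(
    anova = data.frame(df = s[1, "Df"], F = s[1, "F value"],
                       p = s[1, "Pr(>F)"]),
    contrasts = con, correction = correction),
    class = "oneway_anova")
}
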