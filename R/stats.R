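#' One-way ANOVA on raw groups
#'
#' Classic fixed-effects one-way analysis of variance (equal-variance
#' between/within decomposition), delegated to [stats::aov()].
#'
#' @param groups list of numeric vectors, one per group (each n >= 2), or a
#'   data frame with `value` and `group` columns.
#' @return list of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`, plus `ms_within` and the group layout (used by Tukey).
#' @export
anova_oneway <- function(groups) {
  df <- as_group_frame(groups)
  tab <- table(df$group)
  if (length(tab) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2L)) stop("every group needs n >= 2", call. = FALSE)
  gm <- tapply(df$value, df$group, mean)
  grand <- mean(df$value)
  ssb <- sum(tab * (gm - grand)^2)
  sst <- sum((df$value - grand)^2)
  if (ssb <= 1e-12 * max(sst, 1e-300)) {
    # identical group means (possibly identical constants): F = 0 by
    # definition; aov's numeric route returns 0/0 noise here
    return(structure(list(F = 0, df_between = length(tab) - 1L,
                          df_within = nrow(df) - length(tab), p = 1,
                          ms_within = (sst - ssb) / (nrow(df) - length(tab)),
                          group_n = as.integer(tab), group_means = gm,
                          group_labels = names(tab), fit = NULL),
                     class = "anova_result"))
  }
  fit <- stats::aov(value ~ group, data = df)
  an <- stats::anova(fit)
  structure(list(F = an[1L, "F value"],
                 df_between = an[1L, "Df"],
                 df_within = an[2L, "Df"],
                 p = an[1L, "Pr(>F)"],
                 ms_within = an[2L, "Mean Sq"],
                 group_n = as.integer(tab),
                 group_means = gm,
                 group_labels = names(tab),
                 fit = fit),
            class = "anova_result")
}

as_group_frame <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    return(data.frame(value = as.numeric(groups$value),
                      group = factor(groups$group)))
  }
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("g", seq_along(groups))
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(labs, lengths(groups)), levels = labs))
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' One-way ANOVA from per-group summary statistics
#'
#' Recovers the exact between/within decomposition from group sizes, means
#' and standard deviations: `SS_between = sum n_i (mean_i - grand)^2` and
#' `SS_within = sum (n_i - 1) sd_i^2`. Given the summaries of a raw cohort
#' this reproduces [anova_oneway()] exactly, which makes the published
#' per-stage summary rows testable without the raw images.
#'
#' @param summaries data frame with columns `n`, `mean`, `sd` (and
#'   optionally `stage`/`label` for labelling).
#' @return an `anova_result` (without a model fit).
#' @export
anova_from_summary <- function(summaries) {
  if (!all(c("n", "mean", "sd") %in% names(summaries)))
    stop("summaries must provide n, mean and sd", call. = FALSE)
  n <- summaries$n; m <- summaries$mean; s <- summaries$sd
  if (length(n) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(!is.finite(n) | !is.finite(m) | !is.finite(s)) || any(n < 2))
    stop("invalid summary rows", call. = FALSE)
  N <- sum(n)
  k <- length(n)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  dfb <- k - 1L
  dfw <- N - k
  msw <- ssw / dfw
  Fv <- if (ssb < 1e-14 * max(ssw, 1)) 0 else (ssb / dfb) / msw
  p <- if (Fv == 0) 1 else stats::pf(Fv, dfb, dfw, lower.tail = FALSE)
  labs <- summaries$stage
  if (is.null(labs)) labs <- summaries$label
  if (is.null(labs)) labs <- paste0("g", seq_len(k))
  structure(list(F = Fv, df_between = dfb, df_within = dfw, p = p,
                 ms_within = msw, group_n = as.integer(n),
                 group_means = stats::setNames(m, labs),
                 group_labels = as.character(labs)),
            class = "anova_result")
}

#' Tukey HSD multiple comparisons
#'
#' All-pairs comparisons after a one-way ANOVA. Raw groups are delegated to
#' [stats::TukeyHSD()]; summary rows use the Tukey-Kramer studentized-range
#' procedure (`q = |diff| / sqrt(ms_within/2 * (1/n_i + 1/n_j))`, adjusted p
#' from [stats::ptukey()]), which handles the unequal group sizes of the
#' screening cohort.
#'
#' @param x list of numeric group vectors, a `value`/`group` data frame, or
#'   a summary data frame with `n`, `mean`, `sd`.
#' @param alpha significance level for the `significant` flag.
#' @return data frame of class `tukey_result`: one row per pair with
#'   `diff`, `q`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(x, alpha = 0.05) {
  if (is.data.frame(x) && all(c("n", "mean", "sd") %in% names(x)))
    return(tukey_from_summary(x, alpha))
  a <- anova_oneway(x)
  if (is.null(a$fit)) {
    # degenerate ANOVA (identical group means): no pair differs
    labs <- a$group_labels
    ij <- t(utils::combn(seq_along(labs), 2L))
    out <- data.frame(pair = paste(labs[ij[, 2L]], labs[ij[, 1L]], sep = "-"),
                      diff = as.numeric(a$group_means[ij[, 2L]] -
                                          a$group_means[ij[, 1L]]),
                      q = 0, p_adj = 1, significant = FALSE)
    class(out) <- c("tukey_result", class(out))
    return(out)
  }
  tk <- stats::TukeyHSD(a$fit)$group
  labs <- a$group_labels
  ij <- t(utils::combn(seq_along(labs), 2L))
  pair <- paste(labs[ij[, 2L]], labs[ij[, 1L]], sep = "-")
  tk <- tk[match(pair, rownames(tk)), , drop = FALSE]
  se <- sqrt(a$ms_within / 2 * (1 / a$group_n[ij[, 1L]] + 1 / a$group_n[ij[, 2L]]))
  out <- data.frame(pair = pair, diff = tk[, "diff"],
                    q = abs(tk[, "diff"]) / se,
                    p_adj = tk[, "p adj"],
                    significant = tk[, "p adj"] < alpha,
                    row.names = NULL)
  class(out) <- c("tukey_result", class(out))
  out
}

tukey_from_summary <- function(summaries, alpha = 0.05) {
  a <- anova_from_summary(summaries)
  n <- a$group_n; m <- a$group_means; labs <- a$group_labels
  k <- length(n)
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    d <- m[[j]] - m[[i]]
    se <- sqrt(a$ms_within / 2 * (1 / n[i] + 1 / n[j]))
    q <- abs(d) / se
    p <- stats::ptukey(q, nmeans = k, df = a$df_within, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(pair = paste(labs[j], labs[i], sep = "-"),
                 diff = d, q = q, p_adj = p, significant = p < alpha)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tukey_result", class(out))
  out
}

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson correlation via [stats::cor.test()]; the two-sided
#' p-value comes from `t = r sqrt(n-2) / sqrt(1-r^2)` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-degenerate.
#' @return list of class `correlation_result`: `r`, `n`, `t`, `p`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), n = length(x),
                 t = unname(ct$statistic), p = ct$p.value),
            class = "correlation_result")
}

#' p-value implied by a printed correlation coefficient
#'
#' For a reported `r` at sample size `n`, the two-sided p-value of the
#' t statistic `r sqrt(n-2) / sqrt(1-r^2)` on `n - 2` df. Used to check
#' published correlation tables without the raw measurements.
#'
#' @param r correlation coefficient in (-1, 1).
#' @param n sample size (>= 3).
#' @return list with `r`, `n`, `t`, `p`.
#' @export
pearson_from_r <- function(r, n) {
  stopifnot(n >= 3, abs(r) < 1)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, n = as.integer(n), t = t,
       p = 2 * stats::pt(-abs(t), df = n - 2))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, t = %.3f, p = %.4g)\n",
              x$r, x$n, x$t, x$p))
  invisible(x)
}

#' Shapiro-Wilk normality report for a cohort
#'
#' Optional per-group normality check (reported, never used as a gate).
#'
#' @param cohort data frame from [sample_cohort()] or a results table.
#' @param variables variable columns to test.
#' @return data frame with `stage`, `variable`, `W`, `p`.
#' @export
normality_report <- function(cohort, variables = setdiff(names(cohort),
                                                         c("eye_id", "stage"))) {
  rows <- list()
  for (v in variables) for (st in unique(cohort$stage)) {
    vals <- cohort[[v]][cohort$stage == st]
    vals <- vals[is.finite(vals)]
    if (length(vals) >= 3L) {
      sw <- stats::shapiro.test(vals)
      rows[[length(rows) + 1L]] <- data.frame(stage = st, variable = v,
                                              W = unname(sw$statistic),
                                              p = sw$p.value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
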