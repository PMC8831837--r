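#' Published per-stage summary tables for the ROP screening cohort
#'
#' The per-stage summary statistics of the screening cohort the method was
#' reported on: image and patient counts per ROP stage (with left/right eye
#' counts), and median / min / max / mean / sd of the temporal artery and
#' vein angles (TAA, TVA, degrees) and widths (TAW, TVW, pixels). These
#' rows serve two roles: as inputs to the summary-statistics routes of the
#' ANOVA / Tukey machinery, and as design parameters for
#' [cohort_spec()] simulation.
#'
#' @return list with data frames `counts` (stage, patients, images, os, od)
#'   and `summaries` (stage, variable, n, median, min, max, mean, sd).
#' @export
rop_reference_tables <- function() {
  counts <- data.frame(
    stage = c("none", "stage1", "stage2", "stage3"),
    patients = c(44L, 19L, 20L, 35L),
    images = c(66L, 28L, 33L, 49L),
    os = c(32L, 13L, 16L, 31L),
    od = c(34L, 15L, 17L, 18L))
  stages <- counts$stage
  n <- counts$images
  summaries <- rbind(
    data.frame(stage = stages, variable = "TAA", n = n,
               median = c(122.44, 117.12, 112.48, 92.15),
               min = c(98.53, 87.48, 89.50, 57.66),
               max = c(150.80, 139.76, 135.30, 134.28),
               mean = c(122.42, 114.23, 111.87, 92.72),
               sd = c(10.02, 14.95, 10.52, 13.93)),
    data.frame(stage = stages, variable = "TVA", n = n,
               median = c(123.75, 119.52, 116.49, 102.69),
               min = c(88.62, 87.51, 84.14, 65.14),
               max = c(168.55, 157.29, 147.49, 160.09),
               mean = c(123.96, 120.79, 115.26, 102.86),
               sd = c(16.55, 18.65, 14.83, 21.91)),
    data.frame(stage = stages, variable = "TAW", n = n,
               median = c(4.31, 4.29, 4.04, 4.59),
               min = c(3.03, 3.36, 3.44, 3.46),
               max = c(5.20, 5.18, 5.07, 5.99),
               mean = c(4.21, 4.22, 4.10, 4.58),
               sd = c(0.51, 0.49, 0.39, 0.59)),
    data.frame(stage = stages, variable = "TVW", n = n,
               median = c(5.66, 5.75, 5.59, 6.29),
               min = c(4.26, 4.78, 4.04, 4.43),
               max = c(7.03, 6.75, 6.97, 6.98),
               mean = c(5.63, 5.75, 5.61, 6.03),
               sd = c(0.60, 0.52, 0.68, 0.65)))
  rownames(summaries) <- NULL
  list(counts = counts, summaries = summaries)
}

#' Cohort simulation specification
#'
#' Per-stage group sizes and normal `(mean, sd)` parameters for each
#' measured variable, optionally with a joint correlation structure across
#' variables within each eye.
#'
#' @param groups data frame with columns `stage`, `variable`, `n`, `mean`,
#'   `sd` (the layout of `rop_reference_tables()$summaries`).
#' @param correlation optional correlation matrix across the distinct
#'   variables (dimnames must name them); draws then come from a joint
#'   multivariate normal per eye.
#' @param n_scale multiplier applied to every group size.
#' @param seed integer RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = rop_reference_tables()$summaries,
                        correlation = NULL, n_scale = 1, seed = 1L) {
  stopifnot(all(c("stage", "variable", "n", "mean", "sd") %in% names(groups)))
  if (any(groups$sd <= 0)) stop("sds must be positive", call. = FALSE)
  if (any(round(groups$n * n_scale) < 2))
    stop("group sizes must be at least 2", call. = FALSE)
  vars <- unique(groups$variable)
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (is.null(dimnames(correlation)) ||
        !all(vars %in% rownames(correlation)))
      stop("correlation matrix must carry the variable names", call. = FALSE)
    ev <- eigen(correlation[vars, vars], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("correlation matrix is not positive semi-definite", call. = FALSE)
  }
  structure(list(groups = groups, correlation = correlation,
                 n_scale = n_scale, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sample a synthetic measurement cohort
#'
#' Draws per-eye measurements from the per-stage normal distributions of a
#' [cohort_spec()]. Without a correlation matrix the variables are drawn
#' independently; with one, each eye's variables come from a joint
#' multivariate normal with the specified correlations (and the per-stage
#' means/sds). Fully reproducible from the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with columns `eye_id`, `stage`, and one column per
#'   variable.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  g <- spec$groups
  vars <- unique(g$variable)
  stages <- unique(g$stage)
  out <- list()
  for (st in stages) {
    sub <- g[g$stage == st, , drop = FALSE]
    ns <- round(sub$n[match(vars, sub$variable)] * spec$n_scale)
    if (length(unique(ns)) != 1L)
      stop("group sizes must agree across variables within a stage",
           call. = FALSE)
    n <- ns[1L]
    mu <- sub$mean[match(vars, sub$variable)]
    sd <- sub$sd[match(vars, sub$variable)]
    draws <- if (is.null(spec$correlation)) {
      vapply(seq_along(vars), function(j) stats::rnorm(n, mu[j], sd[j]),
             numeric(n))
    } else {
      R <- spec$correlation[vars, vars]
      Sigma <- diag(sd) %*% R %*% diag(sd)
      MASS::mvrnorm(n, mu, Sigma)
    }
    draws <- matrix(draws, nrow = n,
                    dimnames = list(NULL, vars))
    out[[st]] <- data.frame(stage = st, draws, check.names = FALSE)
  }
  res <- do.call(rbind, out)
  res <- cbind(eye_id = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}
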