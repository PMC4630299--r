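#' Per-sample measurement series
#'
#' A sample's (well's) series of per-time-point flow ratios (or any per-well
#' summary values), its group label, and optional cell-type label.
#'
#' @param sample_id Sample/well identifier.
#' @param values Numeric values (NA entries are dropped).
#' @param group \code{"control"} or \code{"treated"}.
#' @param cell_type Optional label.
#' @return A \code{SampleSeries}.
#' @export
sample_series <- function(sample_id, values, group = c("control", "treated"),
                          cell_type = NA_character_) {
  group <- match.arg(group)
  values <- values[!is.na(values)]
  structure(list(sample_id = sample_id, values = values, group = group,
                 cell_type = cell_type, n = length(values)),
            class = "SampleSeries")
}

#' Pooled-control Dunnett comparisons
#'
#' Pools the control samples into a single reference group, fits a one-way
#' ANOVA across (pooled control, treated sample 1, treated sample 2, ...),
#' and computes Dunnett many-to-one simultaneous 95% confidence intervals
#' for each treated sample's mean difference from the pooled control
#' (two-sided, family level \code{alpha}). A treated sample is flagged
#' significant iff its simultaneous CI excludes 0. Critical points come
#' from the equicorrelated multivariate-t machinery in
#' \pkg{multcomp}/\pkg{mvtnorm}.
#'
#' Observations are the retained per-time-point values within each sample,
#' matching the published analysis in which each treated well's time points
#' are compared against the pooled control wells.
#'
#' @param controls List of control \code{\link{sample_series}} (>= 2).
#' @param treated List of treated \code{\link{sample_series}}.
#' @param alpha Family-wise error level (default 0.05).
#' @return A \code{DunnettResult}: data frame with per-treated-sample
#'   \code{estimate} (mean difference vs pooled control), \code{lower},
#'   \code{upper}, \code{significant}.
#' @export
pooled_dunnett <- function(controls, treated, alpha = 0.05) {
  stopifnot(length(controls) >= 2, length(treated) >= 1)
  all_n <- vapply(c(controls, treated), `[[`, integer(1), "n")
  if (any(all_n < 2)) stop("every series needs n >= 2 retained values")
  ctrl_vals <- unlist(lapply(controls, `[[`, "values"))
  trt_ids <- vapply(treated, function(s) as.character(s$sample_id), character(1))
  df <- data.frame(
    y = c(ctrl_vals, unlist(lapply(treated, `[[`, "values"))),
    g = factor(c(rep("control", length(ctrl_vals)),
                 rep(trt_ids, vapply(treated, `[[`, integer(1), "n"))),
               levels = c("control", trt_ids)))
  if (stats::var(df$y) < .Machine$double.eps)
    stop("degenerate variance: all observations identical")
  fit <- stats::aov(y ~ g, data = df)
  if (stats::deviance(fit) < .Machine$double.eps)
    stop("degenerate residual variance in the one-way ANOVA")
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  # The multivariate-t quantile is evaluated by quasi-Monte-Carlo; pin the
  # RNG locally so identical inputs give identical intervals.
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(1905L)
  ci <- stats::confint(glht_fit, level = 1 - alpha)$confint
  out <- data.frame(sample = trt_ids,
                    estimate = ci[, "Estimate"],
                    lower = ci[, "lwr"], upper = ci[, "upr"],
                    row.names = NULL)
  out$significant <- out$lower > 0 | out$upper < 0
  class(out) <- c("DunnettResult", class(out))
  out
}

#' Welch two-sample t-test with percent change
#'
#' Two-sided Welch (unequal-variance) t-test between two series, reporting
#' the percent change of \code{b} relative to \code{a}:
#' \code{100 * (mean(b) - mean(a)) / mean(a)}.
#'
#' @param a,b \code{\link{sample_series}} (or numeric vectors).
#' @return List with \code{t}, \code{p}, \code{percent_change},
#'   \code{mean_a}, \code{mean_b}.
#' @export
two_sample_t <- function(a, b) {
  va <- if (inherits(a, "SampleSeries")) a$values else a[!is.na(a)]
  vb <- if (inherits(b, "SampleSeries")) b$values else b[!is.na(b)]
  stopifnot(length(va) >= 2, length(vb) >= 2)
  if (stats::var(c(va, vb)) < .Machine$double.eps)
    stop("degenerate variance: all observations identical")
  tt <- stats::t.test(vb, va, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       percent_change = 100 * (mean(vb) - mean(va)) / mean(va),
       mean_a = mean(va), mean_b = mean(vb))
}

#' Per-sample and per-group screen summary
#'
#' Summarizes a flow table against a manifest: per sample, the mean, SD,
#' 95% t-CI and n of retained time points; per (cell type, treatment)
#' group, the aggregate of per-sample means.
#'
#' @param flow_table A \code{\link{build_flow_table}} result.
#' @param manifest Data frame with columns \code{sample} (matching flow
#'   table columns), \code{group}, and optionally \code{cell_type}.
#' @return List with data frames \code{per_sample} and \code{per_group}.
#' @export
summarize_screen <- function(flow_table, manifest) {
  stopifnot(all(c("sample", "group") %in% names(manifest)))
  cols <- colnames(flow_table)
  if (!all(cols %in% manifest$sample))
    stop("manifest does not cover all flow-table samples")
  if (!"cell_type" %in% names(manifest)) manifest$cell_type <- "all"
  per_sample <- do.call(rbind, lapply(cols, function(s) {
    x <- flow_table[, s]; x <- x[!is.na(x)]
    mrow <- manifest[manifest$sample == s, ][1, ]
    n <- length(x)
    se <- if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_
    hw <- if (n >= 2) stats::qt(0.975, n - 1) * se else 0
    data.frame(sample = s, group = mrow$group, cell_type = mrow$cell_type,
               mean = mean(x), sd = if (n >= 2) stats::sd(x) else 0,
               ci_lower = mean(x) - hw, ci_upper = mean(x) + hw, n = n)
  }))
  per_group <- do.call(rbind, lapply(
    split(per_sample, list(per_sample$cell_type, per_sample$group), drop = TRUE),
    function(g) data.frame(cell_type = g$cell_type[1], group = g$group[1],
                           mean = mean(g$mean), sd = stats::sd(g$mean),
                           n_samples = nrow(g))))
  rownames(per_group) <- NULL
  list(per_sample = per_sample, per_group = per_group)
}
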