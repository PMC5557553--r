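check_groups <- function(groups, min_per_group = 2) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < min_per_group))
    stop("each group needs at least ", min_per_group, " values",
         call. = FALSE)
  invisible(sizes)
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition: `F = MSB / MSW` with
#' `(k - 1, N - k)` degrees of freedom, p-value from the F distribution.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups) {
  check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  res <- stats::oneway.test(x ~ g, var.equal = TRUE)
  list(F = unname(res$statistic),
       df1 = as.integer(res$parameter[["num df"]]),
       df2 = as.integer(res$parameter[["denom df"]]),
       p = unname(res$p.value))
}

#' Bartlett's test of equal variances
#'
#' @param groups List of numeric vectors, each with >= 2 values and positive
#'   variance.
#' @return List with `chi2`, `df`, `p`.
#' @export
bartlett_test <- function(groups) {
  check_groups(groups)
  if (any(vapply(groups, stats::var, numeric(1)) == 0))
    stop("zero-variance group: Bartlett statistic undefined", call. = FALSE)
  res <- stats::bartlett.test(groups)
  list(chi2 = unname(res$statistic),
       df = as.integer(res$parameter),
       p = unname(res$p.value))
}

#' Tukey's honest significant difference test
#'
#' All pairwise differences of group means compared against the studentized
#' range critical value `qtukey(1 - alpha, k, df_within) * se_ij` with
#' `se_ij = sqrt(MSW / 2 * (1/n_i + 1/n_j))`.
#'
#' @param groups List of numeric vectors (ANOVA-valid).
#' @param alpha Family-wise significance level (default 0.05).
#' @return data.frame with one row per ordered pair `(i, j)`, `i < j`:
#'   `group1`, `group2`, `diff` (mean_i - mean_j), `crit`, `p_adj`,
#'   `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  sizes <- check_groups(groups)
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  dfw <- sum(sizes) - k
  msw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1))) / dfw
  q_crit <- stats::qtukey(1 - alpha, k, dfw)
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(msw / 2 * (1 / sizes[i] + 1 / sizes[j]))
    d <- means[i] - means[j]
    p_adj <- stats::ptukey(abs(d) / se, k, dfw, lower.tail = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      group1 = i, group2 = j, diff = d, crit = q_crit * se,
      p_adj = p_adj, significant = abs(d) > q_crit * se)
  }
  do.call(rbind, rows)
}

#' Paired t-test
#'
#' t statistic on the paired differences with `n - 1` degrees of freedom.
#' Degenerate inputs (zero-variance differences) are flagged rather than
#' erroring: identical vectors give `t = 0`, a constant nonzero difference
#' gives an infinite `t` with `degenerate = TRUE`.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1L, p = 1, degenerate = FALSE))
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0,
                degenerate = TRUE))
  }
  res <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(res$statistic), df = as.integer(res$parameter),
       p = unname(res$p.value), degenerate = FALSE)
}

#' Aggregate trajectories across replicates
#'
#' Mean and standard deviation of each probe series at each recorded
#' iteration, across replicates.
#'
#' @param traj Tidy trajectory data.frame (from [run_experiment()]); an
#'   optional `condition` column is carried through the grouping.
#' @return data.frame with `series`, `iteration`, `phase` (and `condition`
#'   if present), `mean`, `sd`, `n`.
#' @export
summarize_trajectories <- function(traj) {
  if (nrow(traj) < 1) stop("need at least one replicate", call. = FALSE)
  keys <- intersect(c("condition", "series", "iteration", "phase"),
                    names(traj))
  agg <- stats::aggregate(traj$value, traj[keys], function(v) {
    c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
      n = length(v))
  })
  out <- cbind(agg[keys], as.data.frame(agg$x))
  out[order(out$series, out$iteration), ]
}

#' Extract an end-of-phase score table
#'
#' One CS value per replicate for a given series at a given checkpoint
#' iteration (e.g. the point of topology change).
#'
#' @param traj Tidy trajectory data.frame.
#' @param series Series name (e.g. `"CS_G"`).
#' @param iteration Checkpoint iteration (cumulative count); defaults to the
#'   last recorded iteration of the series.
#' @return data.frame with `replicate`, `value` (and `condition` if present).
#' @export
extract_scores <- function(traj, series, iteration = NULL) {
  sub <- traj[traj$series == series, ]
  if (is.null(iteration)) iteration <- max(sub$iteration)
  sub <- sub[sub$iteration == iteration, ]
  keys <- intersect(c("condition", "replicate", "value"), names(sub))
  rownames(sub) <- NULL
  sub[keys]
}

#' Omnibus comparison report for grouped CS scores
#'
#' One-way ANOVA across groups with Bartlett's check of equal variances and
#' Tukey HSD post-hoc pairs. A Bartlett violation is flagged
#' (`bartlett_ok = FALSE`) but does not block the ANOVA: with very large mean
#' differences the omnibus conclusion is reported regardless.
#'
#' @param groups Named list of numeric score vectors (one per condition).
#' @param alpha Significance level for the post-hoc test (default 0.05).
#' @return List with `anova`, `bartlett`, `bartlett_ok`, `tukey` (the Tukey
#'   table with condition names substituted).
#' @export
anova_report <- function(groups, alpha = 0.05) {
  an <- one_way_anova(groups)
  bt <- tryCatch(bartlett_test(groups),
                 error = function(e) list(chi2 = NA_real_, df = NA_integer_,
                                          p = NA_real_))
  tk <- tukey_hsd(groups, alpha)
  nm <- names(groups)
  if (!is.null(nm)) {
    tk$group1 <- nm[tk$group1]
    tk$group2 <- nm[tk$group2]
  }
  list(anova = an, bartlett = bt,
       bartlett_ok = !is.na(bt$p) && bt$p > 0.05, tukey = tk)
}

#' Write a statistics report as CSV and JSON
#'
#' @param report A list of [anova_report()] results, named by condition set
#'   (e.g. network size).
#' @param csv_path,json_path Output paths. The CSV holds one row per test
#'   (size label, F, df1, df2, ANOVA p, Bartlett chi2, Bartlett p).
#' @return Invisibly, `report`.
#' @export
write_stats_report <- function(report, csv_path, json_path) {
  rows <- lapply(names(report), function(nm) {
    r <- report[[nm]]
    data.frame(label = nm, F = r$anova$F, df1 = r$anova$df1,
               df2 = r$anova$df2, anova_p = r$anova$p,
               bartlett_chi2 = r$bartlett$chi2, bartlett_p = r$bartlett$p)
  })
  utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(report)
}
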