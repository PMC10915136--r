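#' Normality gate for grouped feature values
#'
#' Runs the Lilliefors (Kolmogorov-Smirnov with estimated parameters) test
#' on every group. A feature is treated as normally distributed only if no
#' group rejects at the given significance level. Degenerate groups
#' (constant values, or fewer than 4 observations) are flagged and treated
#' as non-normal.
#'
#' @param values numeric vector of feature values.
#' @param groups group membership (factor or character).
#' @param alpha per-group significance level (default 0.05).
#' @return list with `normal` (logical), `p_values` (per group) and
#'   `degenerate` (per group logical).
#' @export
normality_gate <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  split_vals <- split(values, groups)
  p <- vapply(split_vals, function(v) {
    if (length(v) < 4L || sd(v) == 0) return(NA_real_)
    nortest::lillie.test(v)$p.value
  }, numeric(1))
  degenerate <- is.na(p)
  normal <- !any(degenerate) && all(p >= alpha)
  list(normal = normal, p_values = p, degenerate = degenerate)
}

# internal: Dunn's post-hoc test with tie-corrected rank variance and Holm
# adjustment; returns data.frame(group1, group2, z, p_raw, p_adj)
dunn_posthoc <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[a]] + 1 / n[[b]]))
    z[i] <- (rbar[[a]] - rbar[[b]]) / se
    p_raw[i] <- 2 * pnorm(-abs(z[i]))
  }
  data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ], statistic = z,
    p_raw = p_raw, p_adj = p.adjust(p_raw, "holm"),
    stringsAsFactors = FALSE
  )
}

#' Normality-gated group comparison
#'
#' Compares a feature across groups along one of two branches selected by
#' the [normality_gate()]:
#' * non-normal: Kruskal-Wallis omnibus (significance level
#'   `alpha_nonparam`, default 0.001) with Dunn's post-hoc test under Holm
#'   adjustment;
#' * normal: Levene's test for variance homogeneity, one-way ANOVA
#'   (significance level `alpha_param`) and pairwise Student t tests
#'   (Welch) with Holm adjustment.
#'
#' @param values numeric feature values.
#' @param groups group membership.
#' @param feature name used in the report.
#' @param alpha_nonparam,alpha_param omnibus significance levels for the
#'   two branches.
#' @param alpha_normality gate level for the per-group Lilliefors tests.
#' @return a `group_comparison`: list with `feature`, `branch`,
#'   `normality`, `levene_p` (normal branch only), `omnibus_statistic`,
#'   `omnibus_p`, `alpha`, `significant`, `pairwise` (data frame with Holm
#'   adjusted p-values and flags).
#' @export
compare_groups <- function(values, groups, feature = "feature",
                           alpha_nonparam = 0.001, alpha_param = 0.001,
                           alpha_normality = 0.05) {
  groups <- as.factor(groups)
  if (any(tapply(values, groups, length) == 0) || nlevels(groups) < 2L) {
    stop("need at least two non-empty groups")
  }
  gate <- normality_gate(values, groups, alpha_normality)
  if (gate$normal) {
    lev_p <- car::leveneTest(values ~ groups)[1, "Pr(>F)"]
    fit <- aov(values ~ groups)
    sm <- summary(fit)[[1]]
    om_stat <- sm[1, "F value"]
    om_p <- sm[1, "Pr(>F)"]
    pt <- pairwise.t.test(values, groups,
      p.adjust.method = "none",
      pool.sd = FALSE
    )$p.value
    pairs <- which(!is.na(pt), arr.ind = TRUE)
    praw <- pt[pairs]
    pw <- data.frame(
      group1 = colnames(pt)[pairs[, 2]], group2 = rownames(pt)[pairs[, 1]],
      statistic = NA_real_, p_raw = praw, p_adj = p.adjust(praw, "holm"),
      stringsAsFactors = FALSE
    )
    branch <- "ANOVA+t-Holm"
    alpha <- alpha_param
  } else {
    kw <- kruskal.test(values, groups)
    om_stat <- unname(kw$statistic)
    om_p <- kw$p.value
    pw <- dunn_posthoc(values, groups)
    lev_p <- NA_real_
    branch <- "KW+Dunn-Holm"
    alpha <- alpha_nonparam
  }
  pw$significant <- pw$p_adj < alpha
  structure(
    list(
      feature = feature, branch = branch, normality = gate,
      levene_p = lev_p, omnibus_statistic = om_stat, omnibus_p = om_p,
      alpha = alpha, significant = om_p < alpha, pairwise = pw
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s | %s | omnibus p = %.3g (alpha %.4g)%s\n",
    x$feature, x$branch, x$omnibus_p, x$alpha,
    if (x$significant) " *" else ""
  ))
  if (nrow(x$pairwise)) {
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Trophectoderm versus inner-cell-mass density test
#'
#' Kruskal-Wallis test of the mean nuclear dry-mass density between TE and
#' ICM nuclei, with significance declared at `alpha = 1e-4`. If either
#' compartment is empty the comparison is reported as not testable.
#'
#' @param records data frame with `compartment` and `dmd_pg_per_um3`
#'   columns (see [assign_compartment()]).
#' @param alpha significance threshold.
#' @return a `group_comparison`-like list with `testable`, `omnibus_p`,
#'   `significant`, and the per-compartment sample sizes.
#' @export
te_icm_test <- function(records, alpha = 1e-4) {
  n_te <- sum(records$compartment == "TE")
  n_icm <- sum(records$compartment == "ICM")
  if (n_te == 0L || n_icm == 0L) {
    return(structure(
      list(
        feature = "dmd_pg_per_um3", testable = FALSE, n_te = n_te,
        n_icm = n_icm, omnibus_p = NA_real_, significant = NA, alpha = alpha
      ),
      class = "group_comparison"
    ))
  }
  kw <- kruskal.test(
    records$dmd_pg_per_um3,
    factor(records$compartment, levels = c("ICM", "TE"))
  )
  structure(
    list(
      feature = "dmd_pg_per_um3", branch = "KW", testable = TRUE,
      n_te = n_te, n_icm = n_icm,
      omnibus_statistic = unname(kw$statistic), omnibus_p = kw$p.value,
      alpha = alpha, significant = kw$p.value < alpha,
      pairwise = data.frame()
    ),
    class = "group_comparison"
  )
}

#' Feature-by-feature statistics report
#'
#' Runs [compare_groups()] for every feature column and assembles a tidy
#' report table.
#'
#' @param data data frame of feature columns plus a grouping column.
#' @param group_col name of the grouping column.
#' @param features character vector of feature columns (default: all
#'   numeric columns except the group).
#' @param ... passed to [compare_groups()].
#' @return list with `table` (one row per feature: branch, omnibus p,
#'   significance) and `comparisons` (the full objects).
#' @export
stats_report <- function(data, group_col = "health", features = NULL, ...) {
  if (is.null(features)) {
    features <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))], group_col
    )
  }
  comps <- lapply(features, function(f) {
    compare_groups(data[[f]], data[[group_col]], feature = f, ...)
  })
  names(comps) <- features
  tab <- do.call(rbind, lapply(comps, function(cmp) {
    data.frame(
      feature = cmp$feature, branch = cmp$branch,
      omnibus_p = cmp$omnibus_p, alpha = cmp$alpha,
      significant = cmp$significant, stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  list(table = tab, comparisons = comps)
}
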