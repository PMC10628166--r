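#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty
#' otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
significance_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance: the F statistic is
#' the between-group mean square over the within-group mean square. When
#' the within-group variance is exactly zero but group means differ, the
#' convention `F = Inf`, `p = 0` is returned (flagged as degenerate).
#'
#' @param values numeric vector.
#' @param groups grouping factor (>= 2 groups, each with >= 2 values).
#' @return list with `F`, `p`, `df` (between, within) and `degenerate`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 values; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  n <- length(values)
  k <- nlevels(groups)
  gm <- tapply(values, groups, mean)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  ssb <- sum(sizes * (gm - mean(values))^2)
  if (ssw <= .Machine$double.eps * sum(values^2)) {
    if (ssb > 0) {
      return(list(F = Inf, p = 0, df = c(k - 1L, n - k), degenerate = TRUE))
    }
    return(list(F = 0, p = 1, df = c(k - 1L, n - k), degenerate = TRUE))
  }
  fit <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter), degenerate = FALSE)
}

#' Pairwise post-hoc Student t-tests with Bonferroni correction
#'
#' Pooled-variance two-sample t-tests for every pair of groups (Welch's
#' form via `var_equal = FALSE`), with Bonferroni-adjusted p-values
#' `min(1, m * p)` over the `m` pairs. Pairs with zero pooled variance are
#' flagged degenerate (`t = 0, p = 1` for equal means, `t = +-Inf, p = 0`
#' otherwise).
#'
#' @param values numeric vector.
#' @param groups grouping factor.
#' @param var_equal pooled-variance Student form (default) or Welch.
#' @return data.frame with columns group1, group2, t, df, p_raw, p_adj,
#'   stars, degenerate.
#' @export
posthoc_ttests <- function(values, groups, var_equal = TRUE) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  prs <- utils::combn(levels(groups), 2L)
  rows <- apply(prs, 2L, function(pr) {
    a <- values[groups == pr[1]]
    b <- values[groups == pr[2]]
    res <- tryCatch(stats::t.test(a, b, var.equal = var_equal),
                    error = function(e) NULL)
    if (is.null(res)) {
      if (isTRUE(all.equal(mean(a), mean(b)))) {
        data.frame(group1 = pr[1], group2 = pr[2], t = 0, df = length(a) + length(b) - 2,
                   p_raw = 1, degenerate = TRUE, stringsAsFactors = FALSE)
      } else {
        data.frame(group1 = pr[1], group2 = pr[2], t = sign(mean(a) - mean(b)) * Inf,
                   df = length(a) + length(b) - 2, p_raw = 0, degenerate = TRUE,
                   stringsAsFactors = FALSE)
      }
    } else {
      data.frame(group1 = pr[1], group2 = pr[2], t = unname(res$statistic),
                 df = unname(res$parameter), p_raw = res$p.value,
                 degenerate = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * nrow(out))
  out$stars <- significance_stars(out$p_adj)
  out[, c("group1", "group2", "t", "df", "p_raw", "p_adj", "stars", "degenerate")]
}

#' Group comparison of morphometry features
#'
#' For each feature column: a one-way ANOVA across the status groups plus
#' Bonferroni-corrected pairwise post-hoc t-tests. The unit of analysis is
#' the cell by default; `by_subject = TRUE` averages each feature per
#' subject first, which respects within-subject correlation at the cost of
#' power (a deliberate deviation option, off by default).
#'
#' @param features data.frame from [extract_features()] with a `group`
#'   column.
#' @param feature_cols feature columns to compare.
#' @param group_col name of the grouping column.
#' @param by_subject aggregate to per-subject means (needs a `subject_id`
#'   column) before testing.
#' @return list with `anova` (data.frame: feature, F, p, stars) and
#'   `pairwise` (data.frame from [posthoc_ttests()] with a feature column).
#' @export
group_comparisons <- function(features,
                              feature_cols = c("volume_fl", "dry_mass_pg",
                                               "mean_overall_ri", "mean_nuclear_ri"),
                              group_col = "group", by_subject = FALSE) {
  stopifnot(group_col %in% names(features))
  if (by_subject) {
    stopifnot("subject_id" %in% names(features))
    agg <- stats::aggregate(features[feature_cols],
                            by = list(subject_id = features$subject_id,
                                      group = features[[group_col]]),
                            FUN = mean, na.rm = TRUE)
    names(agg)[names(agg) == "group"] <- group_col
    features <- agg
  }
  av <- list(); pw <- list()
  for (f in feature_cols) {
    ok <- is.finite(features[[f]])
    a <- anova_oneway(features[[f]][ok], features[[group_col]][ok])
    av[[f]] <- data.frame(feature = f, F = a$F, p = a$p,
                          stars = significance_stars(a$p), stringsAsFactors = FALSE)
    p <- posthoc_ttests(features[[f]][ok], features[[group_col]][ok])
    p <- cbind(data.frame(feature = f, stringsAsFactors = FALSE), p)
    pw[[f]] <- p
  }
  list(anova = do.call(rbind, c(av, make.row.names = FALSE)),
       pairwise = do.call(rbind, c(pw, make.row.names = FALSE)))
}

#' Shell-density comparisons across status and outcome
#'
#' For every component (overall, nuclear) and every shell: a one-way ANOVA
#' of shell density across the status groups, and (when outcome labels are
#' present at T1) a Student t-test of survivors versus non-survivors at T1.
#' Within each component-by-test family the p-values are Bonferroni
#' corrected over the shells.
#'
#' @param shells data.frame from [shell_profiles_for_cohort()] with columns
#'   component, d1..dK, group and (optionally) outcome.
#' @param groups status groups the ANOVA requires; an error lists any that
#'   are absent.
#' @param include_prognosis run the T1 survivor vs non-survivor t-test.
#' @return data.frame with columns component, shell, test, statistic,
#'   p_raw, p_adj, stars.
#' @export
shell_comparisons <- function(shells, groups = c("H", "T1", "T2", "T3"),
                              include_prognosis = TRUE) {
  stopifnot("component" %in% names(shells), "group" %in% names(shells))
  absent <- setdiff(groups, unique(shells$group))
  if (length(absent)) {
    stop("missing status groups in shell table: ", paste(absent, collapse = ", "))
  }
  dcols <- grep("^d[0-9]+$", names(shells), value = TRUE)
  dcols <- dcols[order(as.integer(sub("^d", "", dcols)))]
  out <- list()
  for (comp in unique(shells$component)) {
    sub <- shells[shells$component == comp, ]
    av <- lapply(dcols, function(dc) {
      keep <- sub$group %in% groups
      a <- anova_oneway(sub[[dc]][keep], sub$group[keep])
      data.frame(component = comp, shell = as.integer(sub("^d", "", dc)),
                 test = "anova_status", statistic = a$F, p_raw = a$p,
                 stringsAsFactors = FALSE)
    })
    av <- do.call(rbind, av)
    av$p_adj <- pmin(1, av$p_raw * nrow(av))
    out[[paste0(comp, "_anova")]] <- av
    if (include_prognosis) {
      t1 <- sub[sub$group == "T1" & sub$outcome %in% c("survivor", "non-survivor"), ]
      miss <- setdiff(c("survivor", "non-survivor"), unique(t1$outcome))
      if (length(miss)) {
        stop("missing outcome labels at T1: ", paste(miss, collapse = ", "))
      }
      tt <- lapply(dcols, function(dc) {
        p <- posthoc_ttests(t1[[dc]], t1$outcome)
        data.frame(component = comp, shell = as.integer(sub("^d", "", dc)),
                   test = "ttest_T1_outcome", statistic = p$t[1], p_raw = p$p_raw[1],
                   stringsAsFactors = FALSE)
      })
      tt <- do.call(rbind, tt)
      tt$p_adj <- pmin(1, tt$p_raw * nrow(tt))
      out[[paste0(comp, "_ttest")]] <- tt
    }
  }
  out <- do.call(rbind, c(out, make.row.names = FALSE))
  out$stars <- significance_stars(out$p_adj)
  out
}

#' Correlate a morphology feature with clinical covariates
#'
#' Pearson correlation between a cell morphology feature and each clinical
#' covariate. `mode = "timepoint_means"` pairs the per-status-group means
#' (one point per group, the figure-style pairing over a handful of time
#' points); `mode = "per_subject"` pairs per-subject means.
#'
#' @param features data.frame holding the feature, the covariates, and
#'   `group` / `subject_id` columns (e.g. [extract_features()] output merged
#'   with the cohort table).
#' @param covariates character vector of covariate column names.
#' @param mode pairing mode.
#' @param feature feature column name.
#' @return data.frame with columns covariate, rho, n.
#' @export
correlate_features <- function(features, covariates,
                               mode = c("timepoint_means", "per_subject"),
                               feature = "mean_overall_ri") {
  mode <- match.arg(mode)
  by_col <- if (mode == "timepoint_means") "group" else "subject_id"
  stopifnot(by_col %in% names(features), feature %in% names(features),
            all(covariates %in% names(features)))
  fx <- tapply(features[[feature]], features[[by_col]], mean, na.rm = TRUE)
  if (length(fx) < 3L) stop("fewer than 3 pairs for correlation (", length(fx),
                            " levels of ", by_col, ")")
  rows <- lapply(covariates, function(cv) {
    cy <- tapply(features[[cv]], features[[by_col]], mean, na.rm = TRUE)
    data.frame(covariate = cv, rho = stats::cor(fx, cy[names(fx)]),
               n = length(fx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
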