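# Agreement and classification-validation statistics: Bland-Altman limits
# of agreement, ICC(2,1) absolute agreement, Cohen's kappa, rank
# correlations, percent agreement, Mann-Whitney ROC AUC with DeLong CI,
# Youden-index cut-off selection, per-age cut-off derivation, and
# repeated-measures method comparison.

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`; limits of agreement `mean(d) +/- 1.96 sd(d)`;
#' confidence interval of the mean difference by the t distribution with
#' n - 1 df; proportional-bias trend by OLS of the differences on the
#' pairwise means.
#'
#' @param a,b Paired measurements (equal length, n >= 3).
#' @return A `bland_altman_report` list: `mean_difference`, `sd_difference`,
#'   `loa_lower`, `loa_upper`, `ci_mean_low`, `ci_mean_high`,
#'   `pct_within_loa`, `trend_slope`, `trend_r2`, `trend_pvalue`,
#'   `zero_variance` flag, `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 3) stop("at least 3 pairs are required")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  zero_var <- s == 0
  loa <- m + c(-1, 1) * 1.96 * s
  tcrit <- stats::qt(0.975, n - 1)
  ci <- m + c(-1, 1) * tcrit * s / sqrt(n)
  pct <- 100 * mean(d >= loa[1] & d <= loa[2])
  avg <- (a + b) / 2
  if (zero_var || stats::sd(avg) == 0) {
    trend <- list(slope = NA_real_, r2 = NA_real_, p = NA_real_)
  } else {
    fit <- fit_linear_model(avg, d)
    tval <- fit$slope / fit$se_slope
    trend <- list(slope = fit$slope, r2 = fit$r_squared,
                  p = 2 * stats::pt(-abs(tval), n - 2))
  }
  structure(list(
    mean_difference = m, sd_difference = s,
    loa_lower = loa[1], loa_upper = loa[2],
    ci_mean_low = ci[1], ci_mean_high = ci[2],
    pct_within_loa = pct,
    trend_slope = trend$slope, trend_r2 = trend$r2, trend_pvalue = trend$p,
    zero_variance = zero_var, n = n
  ), class = "bland_altman_report")
}

#' Intraclass correlation, two-way absolute agreement, single measure
#'
#' ICC(2,1)/ICC(A,1): computed from the two-way ANOVA mean squares of the
#' subjects-by-methods table, `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC -
#' MSE))`. Absolute agreement penalizes systematic offsets between methods.
#'
#' @param a,b Paired measurements (equal length, n >= 3, not both constant).
#' @return The intraclass correlation coefficient.
#' @export
icc_agreement <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 3) stop("at least 3 pairs are required")
  x <- cbind(a, b)
  if (stats::sd(x) == 0) stop("ICC undefined: all measurements identical")
  k <- 2
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  grand <- mean(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom == 0) stop("ICC undefined: zero total variance")
  (msr - mse) / denom
}

#' Cohen's unweighted kappa
#'
#' `(p_o - p_e) / (1 - p_e)`, expected agreement from the product of the
#' two raters' marginal distributions.
#'
#' @param labels_a,labels_b Categorical label vectors of equal length.
#' @return Kappa.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors must have equal length")
  n <- length(labels_a)
  if (n == 0) stop("empty label vectors")
  levs <- union(unique(as.character(labels_a)), unique(as.character(labels_b)))
  fa <- factor(as.character(labels_a), levels = levs)
  fb <- factor(as.character(labels_b), levels = levs)
  tab <- table(fa, fb) / n
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (pe >= 1) stop("kappa undefined: both raters constant with the same label")
  (po - pe) / (1 - pe)
}

#' Association between two numeric vectors
#'
#' Pearson product-moment, Spearman rank, or Kendall tau-b (the tie-corrected
#' tau computed by [stats::cor()]).
#'
#' @param a,b Numeric vectors of equal length, n >= 3.
#' @param method One of `"pearson"`, `"spearman"`, `"tau_b"`.
#' @return The coefficient.
#' @export
association <- function(a, b, method = c("pearson", "spearman", "tau_b")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 3) stop("at least 3 pairs are required")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("association undefined: zero variance input")
  }
  stats::cor(a, b, method = switch(method, tau_b = "kendall", method))
}

#' Percent agreement between two label vectors
#'
#' @param labels_a,labels_b Categorical vectors of equal, non-zero length.
#' @return Percentage of positions with matching labels.
#' @export
percent_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors must have equal length")
  if (length(labels_a) == 0) stop("empty label vectors")
  100 * mean(as.character(labels_a) == as.character(labels_b))
}

# Orient scores so that larger means more likely positive.
.oriented_scores <- function(scores, positives, direction) {
  if (direction == "less_is_positive") -scores else scores
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC by the Mann-Whitney formulation (ties count one half); the
#' confidence interval uses DeLong's closed-form variance of the paired
#' placement values. When `direction = "auto"` the orientation giving
#' AUC >= 0.5 is chosen and recorded.
#'
#' @param scores Numeric scores.
#' @param positives Logical indicator (or 0/1) per score.
#' @param direction `"auto"` (default), `"greater_is_positive"` or
#'   `"less_is_positive"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A `roc_analysis` list: `auc`, `auc_ci_low`, `auc_ci_high`,
#'   `direction`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, positives,
                    direction = c("auto", "greater_is_positive", "less_is_positive"),
                    conf_level = 0.95) {
  direction <- match.arg(direction)
  positives <- as.logical(positives)
  if (length(scores) != length(positives)) stop("scores and positives must align")
  if (!any(positives) || all(positives)) {
    stop("ROC requires at least one positive and one negative case")
  }
  auc_of <- function(s) {
    pos <- s[positives]; neg <- s[!positives]
    r <- rank(c(pos, neg), ties.method = "average")
    np <- length(pos); nn <- length(neg)
    (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  }
  if (direction == "auto") {
    direction <- if (auc_of(scores) >= 0.5) "greater_is_positive" else "less_is_positive"
  }
  s <- .oriented_scores(scores, positives, direction)
  pos <- s[positives]; neg <- s[!positives]
  np <- length(pos); nn <- length(neg)
  auc <- auc_of(s)
  # DeLong placement values
  v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)), numeric(1))
  v01 <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)), numeric(1))
  var_auc <- (if (np > 1) stats::var(v10) / np else 0) +
             (if (nn > 1) stats::var(v01) / nn else 0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- auc + c(-1, 1) * z * sqrt(var_auc)
  structure(list(
    auc = auc,
    auc_ci_low = max(0, ci[1]), auc_ci_high = min(1, ci[2]),
    direction = direction, n_pos = np, n_neg = nn
  ), class = "roc_analysis")
}

#' Bootstrap confidence interval for the ROC AUC
#'
#' Seeded stratified nonparametric bootstrap alternative to the DeLong CI.
#'
#' @inheritParams roc_auc
#' @param B Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @return Numeric vector `c(low, high)` (percentile interval).
#' @export
roc_auc_boot_ci <- function(scores, positives, B = 2000, seed = 1,
                            conf_level = 0.95) {
  positives <- as.logical(positives)
  set.seed(seed)
  ip <- which(positives); ineg <- which(!positives)
  reps <- replicate(B, {
    idx <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    roc_auc(scores[idx], positives[idx], direction = "greater_is_positive")$auc
  })
  alpha <- (1 - conf_level) / 2
  as.numeric(stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE))
}

#' Optimal cut-off by the Youden index
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' sorted scores plus minus/plus infinity. The threshold maximizing
#' Youden's J = sensitivity + specificity - 1 is selected; ties are broken
#' toward higher sensitivity, then toward the lower threshold. Under
#' `greater_is_positive` a case is called positive when its score exceeds
#' the threshold; under `less_is_positive` when below it.
#'
#' @inheritParams roc_auc
#' @param direction `"greater_is_positive"` or `"less_is_positive"`.
#' @return List: `cutoff`, `sensitivity`, `specificity`, `youden_j`,
#'   `direction`.
#' @export
youden_cutoff <- function(scores, positives,
                          direction = c("greater_is_positive", "less_is_positive")) {
  direction <- match.arg(direction)
  positives <- as.logical(positives)
  if (length(scores) != length(positives)) stop("scores and positives must align")
  if (!any(positives) || all(positives)) {
    stop("cut-off selection requires both classes present")
  }
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  eval_thr <- function(t) {
    called_pos <- if (direction == "greater_is_positive") scores > t else scores < t
    sens <- mean(called_pos[positives])
    spec <- mean(!called_pos[!positives])
    c(sens = sens, spec = spec, j = sens + spec - 1)
  }
  m <- t(vapply(cand, eval_thr, numeric(3)))
  best_j <- max(m[, "j"])
  sel <- which(m[, "j"] >= best_j - 1e-12)
  sel <- sel[m[sel, "sens"] >= max(m[sel, "sens"]) - 1e-12]
  pick <- sel[which.min(cand[sel])]
  list(cutoff = cand[pick], sensitivity = unname(m[pick, "sens"]),
       specificity = unname(m[pick, "spec"]), youden_j = unname(m[pick, "j"]),
       direction = direction)
}

#' Derive a PAH cut-off table from a cohort with observed skeletal ages
#'
#' Within each integer age group, records are labelled late / on-time /
#' early from the difference between observed skeletal age and
#' chronological age; the inferior cut-off comes from a ROC analysis of
#' PAH for late-vs-rest (low PAH flags late), the superior cut-off from
#' early-vs-rest (high PAH flags early). AUC with DeLong CI, sensitivity
#' and specificity at the selected threshold are attached per side. Age
#' groups missing a class get a warning and an unset cut-off for that side.
#'
#' An age group with fewer than `min_cases` records in a class is treated as
#' missing that class (a one- or two-case ROC threshold is not meaningful);
#' if the two sides still cross, the side with the lower AUC is unset with a
#' warning, so a returned table always satisfies inferior < superior.
#'
#' @param cohort A `cohort_table` carrying `observed_sa_years` and PAH.
#' @param pah_field `"tw3"` or `"kr"`.
#' @param kr_table Coefficient table when `pah_field = "kr"`.
#' @param min_cases Minimum number of records per class for a side's ROC
#'   analysis (default 3).
#' @return A `cutoff_table` with per-side ROC metadata.
#' @export
derive_cutoff_table <- function(cohort, pah_field = c("tw3", "kr"),
                                kr_table = NULL, min_cases = 3) {
  pah_field <- match.arg(pah_field)
  if (pah_field == "kr" && is.null(kr_table)) kr_table <- default_kr_table()
  sa <- cohort$observed_sa_years
  if (is.null(sa) || any(is.na(sa))) {
    stop("every record must carry observed_sa_years to derive cut-offs")
  }
  pah <- vapply(seq_len(nrow(cohort)), function(i) {
    .record_pah(as.list(cohort[i, ]), pah_field, kr_table)
  }, numeric(1))
  grp <- suppressMessages(age_group(cohort$decimal_age))
  status <- classify_by_sa_difference(sa, cohort$decimal_age)

  ages <- sort(unique(grp))
  rows <- lapply(ages, function(a) {
    sel <- grp == a
    p <- pah[sel]; st <- status[sel]
    out <- data.frame(age_group = a, inferior_cutoff = NA_real_,
                      superior_cutoff = NA_real_,
                      auc_late = NA_real_, auc_late_ci_low = NA_real_,
                      auc_late_ci_high = NA_real_, sens_late = NA_real_,
                      spec_late = NA_real_,
                      auc_early = NA_real_, auc_early_ci_low = NA_real_,
                      auc_early_ci_high = NA_real_, sens_early = NA_real_,
                      spec_early = NA_real_, n = sum(sel))
    side <- function(pos, dir) {
      roc <- roc_auc(p, pos, direction = dir)
      cut <- youden_cutoff(p, pos, direction = dir)
      list(roc = roc, cut = cut)
    }
    if (sum(st == "late") >= min_cases && sum(st != "late") >= min_cases) {
      r <- side(st == "late", "less_is_positive")
      out$inferior_cutoff <- r$cut$cutoff
      out$auc_late <- r$roc$auc
      out$auc_late_ci_low <- r$roc$auc_ci_low
      out$auc_late_ci_high <- r$roc$auc_ci_high
      out$sens_late <- r$cut$sensitivity
      out$spec_late <- r$cut$specificity
    } else {
      warning(sprintf("age group %d: fewer than %d late maturers; inferior cut-off unset",
                      a, min_cases))
    }
    if (sum(st == "early") >= min_cases && sum(st != "early") >= min_cases) {
      r <- side(st == "early", "greater_is_positive")
      out$superior_cutoff <- r$cut$cutoff
      out$auc_early <- r$roc$auc
      out$auc_early_ci_low <- r$roc$auc_ci_low
      out$auc_early_ci_high <- r$roc$auc_ci_high
      out$sens_early <- r$cut$sensitivity
      out$spec_early <- r$cut$specificity
    } else {
      warning(sprintf("age group %d: fewer than %d early maturers; superior cut-off unset",
                      a, min_cases))
    }
    if (!is.na(out$inferior_cutoff) && !is.na(out$superior_cutoff) &&
        out$inferior_cutoff >= out$superior_cutoff) {
      if (isTRUE(out$auc_late >= out$auc_early)) {
        warning(sprintf("age group %d: crossing cut-offs; superior side (lower AUC) unset", a))
        out$superior_cutoff <- NA_real_
        out[c("auc_early", "auc_early_ci_low", "auc_early_ci_high",
              "sens_early", "spec_early")] <- NA_real_
      } else {
        warning(sprintf("age group %d: crossing cut-offs; inferior side (lower AUC) unset", a))
        out$inferior_cutoff <- NA_real_
        out[c("auc_late", "auc_late_ci_low", "auc_late_ci_high",
              "sens_late", "spec_late")] <- NA_real_
      }
    }
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  .validate_cutoff_table(tab)
  class(tab) <- c("cutoff_table", "data.frame")
  tab
}

#' Repeated-measures comparison of several methods
#'
#' One-way repeated-measures ANOVA treating subjects as blocks, followed by
#' pairwise paired t-tests with Bonferroni adjustment (p multiplied by the
#' number of pairs, capped at 1). Pairs with zero within-pair variance are
#' flagged degenerate: p = 1 when the mean difference is also zero, NA
#' otherwise.
#'
#' @param values Numeric matrix, subjects in rows, methods in columns
#'   (>= 3 subjects, >= 2 methods, no missing cells).
#' @return List with `f_statistic`, `df`, `p_value`, and `pairs` (a
#'   data.frame of pairwise mean differences, t statistics, adjusted
#'   p-values and degeneracy flags).
#' @export
compare_methods_repeated <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 3) stop("at least 3 subjects are required")
  if (k < 2) stop("at least 2 methods are required")
  if (any(!is.finite(values))) stop("matrix has missing or non-finite cells")
  if (is.null(colnames(values))) colnames(values) <- paste0("m", seq_len(k))

  grand <- mean(values)
  ss_subj <- k * sum((rowMeans(values) - grand)^2)
  ss_meth <- n * sum((colMeans(values) - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_meth
  df_meth <- k - 1
  df_err <- (k - 1) * (n - 1)
  ms_meth <- ss_meth / df_meth
  ms_err <- ss_err / df_err
  if (ms_err == 0) {
    fstat <- if (ms_meth == 0) NA_real_ else Inf
    pval <- if (ms_meth == 0) 1 else 0
  } else {
    fstat <- ms_meth / ms_err
    pval <- stats::pf(fstat, df_meth, df_err, lower.tail = FALSE)
  }

  combs <- utils::combn(k, 2)
  npairs <- ncol(combs)
  pairs <- do.call(rbind, lapply(seq_len(npairs), function(j) {
    i1 <- combs[1, j]; i2 <- combs[2, j]
    d <- values[, i1] - values[, i2]
    md <- mean(d); sdd <- stats::sd(d)
    if (sdd == 0) {
      data.frame(method_a = colnames(values)[i1], method_b = colnames(values)[i2],
                 mean_difference = md, t_statistic = NA_real_,
                 p_adjusted = if (md == 0) 1 else NA_real_,
                 degenerate = TRUE, stringsAsFactors = FALSE)
    } else {
      tt <- md / (sdd / sqrt(n))
      p <- 2 * stats::pt(-abs(tt), n - 1)
      data.frame(method_a = colnames(values)[i1], method_b = colnames(values)[i2],
                 mean_difference = md, t_statistic = tt,
                 p_adjusted = min(1, p * npairs),
                 degenerate = FALSE, stringsAsFactors = FALSE)
    }
  }))
  list(f_statistic = fstat, df = c(df_meth, df_err), p_value = pval, pairs = pairs)
}

#' Full paired-method agreement report
#'
#' Convenience wrapper computing the numeric-agreement suite (Pearson,
#' Spearman, ICC, Bland-Altman) between two measurement vectors and, when
#' label vectors are supplied, the categorical suite (Cohen's kappa,
#' Kendall's tau-b on the ordered labels, percent agreement).
#'
#' @param a,b Paired numeric measurements.
#' @param labels_a,labels_b Optional paired categorical labels.
#' @return An `agreement_report` list.
#' @export
agreement_report <- function(a, b, labels_a = NULL, labels_b = NULL) {
  rep <- list(
    pearson_r = association(a, b, "pearson"),
    spearman_rho = association(a, b, "spearman"),
    icc = icc_agreement(a, b),
    bland_altman = bland_altman(a, b)
  )
  if (!is.null(labels_a) && !is.null(labels_b)) {
    la <- factor(as.character(labels_a), levels = .maturity_levels)
    lb <- factor(as.character(labels_b), levels = .maturity_levels)
    if (any(is.na(la)) || any(is.na(lb))) {
      la <- factor(as.character(labels_a))
      lb <- factor(as.character(labels_b), levels = levels(la))
    }
    rep$kappa <- cohen_kappa(labels_a, labels_b)
    rep$tau_b <- association(as.numeric(la), as.numeric(lb), "tau_b")
    rep$pct_agreement <- percent_agreement(labels_a, labels_b)
  }
  structure(rep, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  ba <- x$bland_altman
  cat(sprintf("Pearson r %.3f | Spearman rho %.3f | ICC(2,1) %.3f\n",
              x$pearson_r, x$spearman_rho, x$icc))
  cat(sprintf("Bland-Altman: mean diff %.3f (LoA %.3f to %.3f), %.0f%% within LoA\n",
              ba$mean_difference, ba$loa_lower, ba$loa_upper, ba$pct_within_loa))
  if (!is.null(x$kappa)) {
    cat(sprintf("kappa %.3f | tau-b %.3f | %% agreement %.1f\n",
                x$kappa, x$tau_b, x$pct_agreement))
  }
  invisible(x)
}
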