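#' Partial eta squared from an F statistic and its degrees of freedom
#'
#' `eta_p2 = F * df1 / (F * df1 + df2)`. This identity lets any reported
#' effect size be reproduced (or audited) directly from the printed F and
#' degrees of freedom, including Greenhouse-Geisser-corrected, fractional
#' ones.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (> 0; may be
#'   fractional after sphericity correction).
#' @return Partial eta squared in \[0, 1).
#' @export
#' @examples
#' partial_eta_squared(11.06, 1, 18)  # 0.381
partial_eta_squared <- function(f, df1, df2) {
  if (any(f < 0) || any(df1 <= 0) || any(df2 <= 0))
    abort_config("require f >= 0 and positive degrees of freedom")
  (f * df1) / (f * df1 + df2)
}

# Normalized (k-1) x k contrast matrix orthogonal to the unit vector.
orthonormal_contrasts <- function(k) {
  h <- stats::contr.helmert(k)          # k x (k-1)
  h <- sweep(h, 2, sqrt(colSums(h^2)), "/")
  t(h)
}

#' Greenhouse-Geisser epsilon for a repeated-measures factor
#'
#' Computed from the (pooled within-group) sample covariance of the k
#' condition scores: with `E = C S C'` for an orthonormal contrast matrix C,
#' `epsilon = tr(E)^2 / ((k-1) * tr(E^2))`, bounded by \[1/(k-1), 1\];
#' epsilon = 1 iff the contrast covariance is spherical.
#'
#' @param scores n x k matrix of condition scores (one row per participant),
#'   already centred per group if groups are present — see
#'   [pooled_condition_cov()].
#' @param cov_matrix Alternatively, a precomputed k x k covariance matrix.
#' @return Epsilon in \[1/(k-1), 1\].
#' @export
gg_epsilon <- function(scores = NULL, cov_matrix = NULL) {
  S <- if (is.null(cov_matrix)) stats::cov(scores) else cov_matrix
  k <- ncol(S)
  if (k < 2) abort_config("need at least two within-subject levels")
  C <- orthonormal_contrasts(k)
  E <- C %*% S %*% t(C)
  denom <- (k - 1) * sum(E * E)
  if (!is.finite(denom) || denom <= 0) {
    warning("singular condition covariance; epsilon set to its lower bound",
            call. = FALSE)
    return(1 / (k - 1))
  }
  eps <- sum(diag(E))^2 / denom
  min(1, max(1 / (k - 1), eps))
}

#' Pooled within-group covariance of condition scores
#'
#' Centres each group's score matrix on its own condition means and pools the
#' cross-products over `N - g` degrees of freedom — the covariance estimate
#' the sphericity machinery of a mixed design uses.
#'
#' @param scores n x k matrix of condition scores.
#' @param group Factor of length n assigning rows to groups.
#' @return k x k covariance matrix.
#' @export
pooled_condition_cov <- function(scores, group) {
  group <- as.factor(group)
  k <- ncol(scores)
  cp <- matrix(0, k, k)
  for (g in levels(group)) {
    m <- scores[group == g, , drop = FALSE]
    m <- sweep(m, 2, colMeans(m))
    cp <- cp + t(m) %*% m
  }
  cp / (nrow(scores) - nlevels(group))
}

# Mauchly's sphericity test on the pooled contrast covariance.
mauchly_sphericity <- function(S, df_error) {
  k <- ncol(S)
  d <- k - 1
  C <- orthonormal_contrasts(k)
  E <- C %*% S %*% t(C)
  detE <- det(E)
  if (!is.finite(detE) || detE <= 0)
    return(list(W = 0, p = 0))
  W <- detE / (sum(diag(E)) / d)^d
  f <- (2 * d^2 + d + 2) / (6 * d)
  chi2 <- -(df_error - f) * log(W)
  df <- d * (d + 1) / 2 - 1
  list(W = W, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Two-way mixed repeated-measures ANOVA (Condition x Group)
#'
#' One between-subject factor (age group) crossed with one within-subject
#' factor (surface condition), one score per participant per condition
#' (repeated trials must be averaged first — see [aggregate_trials()]).
#' Sums of squares are computed from first principles on the balanced design:
#' the between-subjects stratum splits into group and subjects-within-group,
#' the within stratum into condition, condition x group and the
#' condition x subjects-within-group error; their sum is verified against the
#' total sum of squares. Greenhouse-Geisser correction of the within-factor
#' degrees of freedom is applied when Mauchly's test rejects sphericity at
#' `sphericity_alpha` (or always/never, per `gg`).
#'
#' @param data Data frame with columns `participant`, `group`, `condition`
#'   and the response named by `dv` (one row per participant x condition).
#' @param dv Name of the response column (default `"value"`).
#' @param gg `"mauchly"` (default: correct when sphericity is rejected at
#'   `sphericity_alpha`), `"always"`, or `"never"`.
#' @param sphericity_alpha Mauchly gate level (default 0.05).
#' @param alpha_adj Family-adjusted significance level to record in the table
#'   (default 0.05; see [holm_family_alpha()]).
#' @return A tibble with one row per effect (`condition`, `group`,
#'   `condition:group`): `F`, `df1`, `df2` (corrected where applicable), `p`,
#'   `eta_p2`, `gg_epsilon`, `gg_applied`, `mauchly_p`, `alpha_adj`,
#'   `significant`.
#' @export
mixed_rm_anova <- function(data, dv = "value", gg = c("mauchly", "always", "never"),
                           sphericity_alpha = 0.05, alpha_adj = 0.05) {
  gg <- match.arg(gg)
  need <- c("participant", "group", "condition", dv)
  miss <- setdiff(need, names(data))
  if (length(miss))
    abort_data(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  y <- data[[dv]]
  if (any(!is.finite(y))) abort_data(sprintf("non-finite values in '%s'", dv))
  part <- as.factor(as.character(data$participant))
  grp <- as.factor(as.character(data$group))
  cond <- as.factor(as.character(data$condition))
  k <- nlevels(cond)
  g <- nlevels(grp)
  tab <- table(part, cond)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)[1, ]
    abort_data(sprintf(
      "unbalanced design: participant '%s' has %d values for condition '%s' (need exactly 1; average trials first)",
      rownames(tab)[bad[1]], tab[bad[1], bad[2]], colnames(tab)[bad[2]]))
  }
  pg <- tapply(as.character(grp), part, unique)
  if (any(lengths(pg) != 1))
    abort_data("each participant must belong to exactly one group")
  n_per <- table(unlist(pg))
  if (any(n_per < 2)) abort_data("need at least 2 participants per group")
  if (length(unique(n_per)) != 1)
    abort_data("groups must be balanced (equal participants per group)")
  n <- unname(n_per[1])
  N <- n * g
  if (var(y) == 0) abort_data("degenerate data: zero variance in the response")

  gm <- mean(y)
  ss_total <- sum((y - gm)^2)
  subj_mean <- tapply(y, part, mean)
  ss_between_subj <- k * sum((subj_mean - gm)^2)
  grp_mean <- tapply(y, grp, mean)
  ss_group <- n * k * sum((grp_mean - gm)^2)
  ss_subj_within <- ss_between_subj - ss_group
  cond_mean <- tapply(y, cond, mean)
  ss_cond <- g * n * sum((cond_mean - gm)^2)
  cell_mean <- tapply(y, list(grp, cond), mean)
  ss_cells <- n * sum((cell_mean - gm)^2)
  ss_inter <- ss_cells - ss_group - ss_cond
  ss_err_within <- ss_total - ss_between_subj - ss_cond - ss_inter
  # guard against numerically negative SS on degenerate inputs
  ss_inter <- max(ss_inter, 0)
  ss_err_within <- max(ss_err_within, 0)

  stopifnot(abs((ss_group + ss_subj_within + ss_cond + ss_inter + ss_err_within) -
                  ss_total) <= 1e-8 * max(1, ss_total))

  df_group <- g - 1
  df_subj <- g * (n - 1)
  df_cond <- k - 1
  df_inter <- (g - 1) * (k - 1)
  df_err <- (k - 1) * g * (n - 1)

  ms_subj <- ss_subj_within / df_subj
  ms_err <- ss_err_within / df_err
  f_group <- (ss_group / df_group) / ms_subj
  f_cond <- (ss_cond / df_cond) / ms_err
  f_inter <- (ss_inter / df_inter) / ms_err

  scores <- matrix(y[order(part, cond)], nrow = N, ncol = k, byrow = TRUE)
  grp_by_part <- factor(unlist(pg)[levels(part)])
  S <- pooled_condition_cov(scores, grp_by_part)
  eps <- gg_epsilon(cov_matrix = S)
  mau <- mauchly_sphericity(S, df_error = N - g)
  apply_gg <- switch(gg,
                     mauchly = mau$p < sphericity_alpha,
                     always = TRUE,
                     never = FALSE)

  eff <- function(effect, f, d1, d2, within) {
    use_gg <- within && apply_gg
    d1c <- if (use_gg) eps * d1 else d1
    d2c <- if (use_gg) eps * d2 else d2
    p <- pf(f, d1c, d2c, lower.tail = FALSE)
    tibble::tibble(
      effect = effect, F = f, df1 = d1c, df2 = d2c, p = p,
      eta_p2 = partial_eta_squared(f, d1c, d2c),
      gg_epsilon = if (within) eps else NA_real_,
      gg_applied = within && apply_gg,
      mauchly_p = if (within) mau$p else NA_real_,
      alpha_adj = alpha_adj,
      significant = p < alpha_adj
    )
  }
  dplyr::bind_rows(
    eff("condition", f_cond, df_cond, df_err, within = TRUE),
    eff("group", f_group, df_group, df_subj, within = FALSE),
    eff("condition:group", f_inter, df_inter, df_err, within = TRUE)
  )
}

#' Average repeated trials to one score per participant x condition
#'
#' @param data Long tibble with columns `participant`, `group`, `condition`,
#'   `trial`, and metric columns (or `metric`/`value` long pairs).
#' @param dv Metric column to aggregate, or `NULL` to aggregate every numeric
#'   column except `trial`.
#' @return Tibble with one row per participant x condition.
#' @export
aggregate_trials <- function(data, dv = NULL) {
  keys <- c("participant", "group", "condition")
  miss <- setdiff(keys, names(data))
  if (length(miss))
    abort_data(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  cols <- if (is.null(dv)) {
    setdiff(names(data)[vapply(data, is.numeric, logical(1))],
            c("trial", "participant"))
  } else dv
  dplyr::summarise(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(keys))),
    dplyr::across(dplyr::all_of(cols), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
}

#' Family-wise adjusted significance level
#'
#' The family alpha divides 0.05 by the number of tests in the family: two
#' per dependent variable (the condition main effect and the
#' condition x group interaction), i.e. `0.05 / (n_dvs * 2)`. A five-DV
#' family therefore tests at 0.005.
#'
#' @param n_dvs Number of dependent variables in the family (>= 1).
#' @param base_alpha Unadjusted level (default 0.05).
#' @param tests_per_dv Tests counted per DV (default 2).
#' @return Adjusted alpha.
#' @export
#' @examples
#' holm_family_alpha(5)  # 0.005
holm_family_alpha <- function(n_dvs, base_alpha = 0.05, tests_per_dv = 2) {
  check_scalar_number(n_dvs, "n_dvs", positive = TRUE, integerish = TRUE)
  base_alpha / (n_dvs * tests_per_dv)
}

#' Sequential Holm step-down adjusted p-values
#'
#' The true sequentially rejective procedure, provided alongside the divided
#' single-alpha rule of [holm_family_alpha()]; thin wrapper over
#' `stats::p.adjust(method = "holm")` so the two conventions can be compared
#' on the same family.
#'
#' @param p Raw p-values of the family.
#' @return Holm-adjusted p-values.
#' @export
holm_sequential <- function(p) stats::p.adjust(p, method = "holm")

#' Bonferroni-adjusted post hoc pairwise comparisons
#'
#' Run only after a significant omnibus effect (requests without one are
#' refused). Within each group, paired t-tests compare all condition pairs;
#' when `between = TRUE`, two-sample t-tests additionally compare the groups
#' at each condition (the interaction follow-up). Every raw p-value is
#' multiplied by the number of comparisons in its family and capped at 1.
#'
#' @param data One score per participant x condition (see
#'   [aggregate_trials()]), columns `participant`, `group`, `condition`, and
#'   `dv`.
#' @param dv Response column name (default `"value"`).
#' @param omnibus_p P-value of the omnibus effect being followed up.
#' @param alpha Significance level the omnibus was tested at.
#' @param between Also compare groups at each condition (default FALSE).
#' @return Tibble with `contrast`, `group`/`condition` context columns,
#'   `estimate`, `p_raw`, `multiplier`, `p_adj`.
#' @export
posthoc_pairwise <- function(data, dv = "value", omnibus_p, alpha = 0.05,
                             between = FALSE) {
  if (!(omnibus_p < alpha))
    abort_data(sprintf(
      "post hoc refused: omnibus p (%.4f) is not significant at alpha = %g",
      omnibus_p, alpha))
  conds <- unique(as.character(data$condition))
  groups <- unique(as.character(data$group))
  rows <- list()
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  m_within <- length(pairs)
  for (gl in groups) {
    dg <- data[data$group == gl, ]
    for (pr in pairs) {
      a <- dg[dg$condition == pr[1], ]
      b <- dg[dg$condition == pr[2], ]
      common <- intersect(a$participant, b$participant)
      x <- a[[dv]][match(common, a$participant)]
      y <- b[[dv]][match(common, b$participant)]
      d <- x - y
      p_raw <- if (sd(d) == 0) 1 else t.test(x, y, paired = TRUE)$p.value
      rows[[length(rows) + 1L]] <- tibble::tibble(
        contrast = paste(pr[1], "-", pr[2]), scope = "within", group = gl,
        condition = NA_character_, estimate = mean(d), p_raw = p_raw,
        multiplier = m_within, p_adj = min(1, p_raw * m_within))
    }
  }
  if (between && length(groups) == 2) {
    m_btw <- length(conds)
    for (cl in conds) {
      a <- data[data$condition == cl & data$group == groups[1], ][[dv]]
      b <- data[data$condition == cl & data$group == groups[2], ][[dv]]
      p_raw <- if (sd(c(a, b)) == 0) 1 else t.test(a, b)$p.value
      rows[[length(rows) + 1L]] <- tibble::tibble(
        contrast = paste(groups[1], "-", groups[2]), scope = "between",
        group = NA_character_, condition = cl, estimate = mean(a) - mean(b),
        p_raw = p_raw, multiplier = m_btw, p_adj = min(1, p_raw * m_btw))
    }
  }
  dplyr::bind_rows(rows)
}

#' Default dependent-variable families for the family-wise adjustment
#'
#' Mirrors the study's grouping: fear VAS, preparatory step timing,
#' preparatory CoM, preparatory CCI (phases i-ii), compensatory step
#' characteristics, total CoM excursions, compensatory CCI (iii-iv), and the
#' seven joint excursions.
#'
#' @return Named list of character vectors of metric names.
#' @export
default_dv_families <- function() {
  list(
    vas = c("vas_likely", "vas_concern"),
    step_prep = c("cop_on", "step_on"),
    com_prep = c("prep_com_acc_ap", "prep_com_acc_ml",
                 "prep_com_exc_ap", "prep_com_exc_ml"),
    onsets = paste0("onset_", emg_channels()),
    cci_prep = c("cci_i", "cci_ii"),
    step_comp = c("step_off", "step_time", "step_length", "step_width"),
    com_total = c("total_com_exc_ap", "total_com_exc_ml"),
    cci_comp = c("cci_iii", "cci_iv"),
    joints = c("exc_ankle", "exc_knee", "exc_hip", "exc_lumbar",
               "exc_thorax", "exc_shoulder", "exc_elbow")
  )
}

#' Mixed ANOVA over every metric of a cohort table, with family alphas
#'
#' Aggregates trials, then runs [mixed_rm_anova()] per metric with the
#' family-wise alpha of the family the metric belongs to.
#'
#' @param cohort_metrics Long tibble: `participant`, `group`, `condition`,
#'   `trial`, `metric`, `value`.
#' @param families Named list of metric-name vectors (default
#'   [default_dv_families()]); metrics not listed in any family are tested at
#'   `0.05 / 2`.
#' @param ... Passed to [mixed_rm_anova()].
#' @return Tibble: one row per metric x effect, including `family` and
#'   `alpha_adj`.
#' @export
analyze_cohort_metrics <- function(cohort_metrics,
                                   families = default_dv_families(), ...) {
  need <- c("participant", "group", "condition", "metric", "value")
  miss <- setdiff(need, names(cohort_metrics))
  if (length(miss))
    abort_data(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  fam_of <- function(m) {
    hit <- names(families)[vapply(families, function(v) m %in% v, logical(1))]
    if (length(hit)) hit[1] else NA_character_
  }
  out <- list()
  for (m in unique(cohort_metrics$metric)) {
    dm <- cohort_metrics[cohort_metrics$metric == m, ]
    dm <- aggregate_trials(dm, dv = "value")
    if (any(!is.finite(dm$value))) next
    fam <- fam_of(m)
    alpha <- if (is.na(fam)) holm_family_alpha(1)
             else holm_family_alpha(length(families[[fam]]))
    res <- tryCatch(mixed_rm_anova(dm, dv = "value", alpha_adj = alpha, ...),
                    error = function(e) {
                      warning(sprintf("metric '%s' not analyzable: %s", m,
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
    if (is.null(res)) next
    res$metric <- m
    res$family <- fam
    out[[m]] <- res
  }
  if (!length(out)) {
    warning("no metric could be analyzed", call. = FALSE)
    return(tibble::tibble(metric = character(0), family = character(0),
                          effect = character(0), F = numeric(0),
                          df1 = numeric(0), df2 = numeric(0), p = numeric(0),
                          eta_p2 = numeric(0), gg_epsilon = numeric(0),
                          gg_applied = logical(0), mauchly_p = numeric(0),
                          alpha_adj = numeric(0), significant = logical(0)))
  }
  dplyr::relocate(dplyr::bind_rows(out), "metric", "family")
}
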