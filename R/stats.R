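# Statistical battery: normality screen, correlations, stepwise regression,
# repeated-measures ANOVA with Holm post-hocs, and the 4-level stepped model.

#' Magnitude label for a correlation coefficient
#'
#' Thresholds 0.1, 0.3, 0.5, 0.8 for trivial / small / moderate / strong /
#' very strong.
#'
#' @param r Correlation coefficient(s).
#' @return Character vector of labels.
#' @export
correlation_magnitude <- function(r) {
  cut(abs(r), breaks = c(-Inf, 0.1, 0.3, 0.5, 0.8, Inf),
      labels = c("trivial", "small", "moderate", "strong", "very strong"),
      right = FALSE)
}

#' Magnitude label for Cohen's d
#'
#' Thresholds 0.2, 0.5, 0.8 for trivial / small / moderate / strong /
#' very strong (the last band above 0.8).
#'
#' @param d Effect size(s).
#' @return Character vector of labels.
#' @export
effect_magnitude <- function(d) {
  cut(abs(d), breaks = c(-Inf, 0.2, 0.5, 0.8, 1.3, Inf),
      labels = c("trivial", "small", "moderate", "strong", "very strong"),
      right = FALSE)
}

#' Screen variables for distribution normality
#'
#' Shapiro-Wilk test per variable, plus a robust outlier flag (samples more
#' than `outlier_z` robust SDs from the median). Nothing is removed:
#' exclusion is an explicit, documented action by the analyst.
#'
#' @param data Data.frame of numeric variables (athletes in rows).
#' @param alpha Significance level for the normality flag.
#' @param outlier_z Robust z threshold for the outlier flag.
#' @return Data.frame: `variable, W, p, normal, degenerate, n_outliers`.
#' @export
screen_normality <- function(data, alpha = 0.05, outlier_z = 3.5) {
  data <- as.data.frame(data)
  rows <- lapply(names(data), function(nm) {
    x <- data[[nm]]
    x <- x[is.finite(x)]
    if (length(x) < 3)
      stop("need at least 3 observations per variable (", nm, ")")
    if (sd(x) < 1e-12) {
      return(data.frame(variable = nm, W = NA_real_, p = NA_real_,
                        normal = NA, degenerate = TRUE, n_outliers = 0L))
    }
    sw <- shapiro.test(x)
    md <- median(x)
    rsd <- stats::mad(x)
    n_out <- if (rsd > 0) sum(abs(x - md) / rsd > outlier_z) else 0L
    data.frame(variable = nm, W = unname(sw$statistic), p = sw$p.value,
               normal = sw$p.value >= alpha, degenerate = FALSE,
               n_outliers = as.integer(n_out))
  })
  do.call(rbind, rows)
}

#' Pearson correlation with Fisher 95% confidence interval
#'
#' Two-sided Pearson correlation with the Fisher-z confidence interval and a
#' qualitative magnitude label (thresholds 0.1/0.3/0.5/0.8).
#'
#' @param x,y Numeric vectors (n >= 4, non-constant).
#' @param conf_level Confidence level for the interval.
#' @return A one-row data.frame of class `correlation_result`:
#'   `r, ci_low, ci_high, p, n, magnitude`.
#' @export
#' @examples
#' pearson_with_ci(1:10, (1:10) + rnorm(10))
pearson_with_ci <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 paired observations")
  # variance below 0.1% of the variable's scale is measurement-noise level:
  # a correlation on it would be meaningless (e.g. dissipation-free cohorts)
  if (sd(x) < 1e-3 * (1 + abs(mean(x))) || sd(y) < 1e-3 * (1 + abs(mean(y))))
    stop("degenerate input (no meaningful variance): correlation undefined")
  ct <- cor.test(x, y, conf.level = conf_level)
  r <- unname(ct$estimate)
  out <- data.frame(r = r,
                    ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
                    p = ct$p.value, n = length(x),
                    magnitude = as.character(correlation_magnitude(r)))
  class(out) <- c("correlation_result", class(out))
  out
}

#' Stepwise multiple regression with standardized coefficients
#'
#' Forward selection with backward elimination: at each step the candidate
#' with the smallest partial-F p-value enters if `p < enter_p`; after each
#' entry, included predictors whose p-value has risen above `remove_p` are
#' dropped. All variables are z-scored first, so coefficients are
#' standardized betas; the R-squared increment is recorded at each entry.
#' An empty model (no candidate passes entry) is a valid outcome, reported
#' as no clear prediction.
#'
#' @param y Response vector.
#' @param candidates Data.frame or named matrix of candidate predictors.
#' @param enter_p P-to-enter threshold.
#' @param remove_p P-to-remove threshold.
#' @return List of class `stepwise_result`: `selected` (ordered names),
#'   `coefficients` (standardized beta, p, R2_change per selected
#'   predictor, in entry order), `r_squared`, `adj_r_squared`, `F`, `df`,
#'   `model_p`, `n`, `empty`.
#' @export
stepwise_regression <- function(y, candidates, enter_p = 0.05,
                                remove_p = 0.10) {
  X <- as.data.frame(candidates)
  stopifnot(nrow(X) == length(y))
  n <- length(y)
  if (n <= ncol(X) + 2)
    warning("sample size (", n, ") is small for ", ncol(X),
            " candidates: stepwise selection is unstable")
  zs <- function(v) if (sd(v) < 1e-12) rep(0, length(v)) else
    (v - mean(v)) / sd(v)
  yz <- zs(y)
  Xz <- as.data.frame(lapply(X, zs))
  usable <- vapply(X, function(v) sd(v) > 1e-12, logical(1))

  selected <- character(0)
  entry_r2 <- numeric(0)
  r2_prev <- 0
  repeat {
    pool <- setdiff(names(Xz)[usable], selected)
    if (!length(pool)) break
    trial <- vapply(pool, function(cand) {
      fit <- lm(yz ~ ., data = Xz[, c(selected, cand), drop = FALSE])
      cf <- summary(fit)$coefficients
      if (cand %in% rownames(cf)) cf[cand, 4] else NA_real_
    }, numeric(1))
    if (all(!is.finite(trial)) || min(trial, na.rm = TRUE) >= enter_p) break
    best <- pool[which.min(trial)]
    selected <- c(selected, best)
    fit <- lm(yz ~ ., data = Xz[, selected, drop = FALSE])
    r2 <- summary(fit)$r.squared
    entry_r2 <- c(entry_r2, setNames(r2 - r2_prev, best))
    r2_prev <- r2
    # backward check
    repeat {
      cf <- summary(lm(yz ~ ., data = Xz[, selected, drop = FALSE]))$coefficients
      ps <- cf[intersect(selected, rownames(cf)), 4]
      if (!length(ps) || max(ps) <= remove_p) break
      drop_var <- names(ps)[which.max(ps)]
      selected <- setdiff(selected, drop_var)
      entry_r2 <- entry_r2[names(entry_r2) != drop_var]
      r2_prev <- if (length(selected))
        summary(lm(yz ~ ., data = Xz[, selected, drop = FALSE]))$r.squared else 0
    }
  }

  if (!length(selected)) {
    out <- list(selected = character(0), coefficients = NULL,
                r_squared = 0, adj_r_squared = 0, F = NA_real_,
                df = c(NA_integer_, NA_integer_), model_p = NA_real_,
                n = n, empty = TRUE)
    class(out) <- "stepwise_result"
    return(out)
  }
  fit <- lm(yz ~ ., data = Xz[, selected, drop = FALSE])
  sm <- summary(fit)
  cf <- sm$coefficients
  coefs <- data.frame(
    predictor = selected,
    beta = cf[selected, 1],
    p = cf[selected, 4],
    R2_change = unname(entry_r2[selected]),
    row.names = NULL)
  out <- list(selected = selected,
              coefficients = coefs,
              r_squared = sm$r.squared,
              adj_r_squared = sm$adj.r.squared,
              F = unname(sm$fstatistic[1]),
              df = unname(sm$fstatistic[2:3]),
              model_p = unname(pf(sm$fstatistic[1], sm$fstatistic[2],
                                  sm$fstatistic[3], lower.tail = FALSE)),
              n = n, empty = FALSE)
  class(out) <- "stepwise_result"
  out
}

#' @export
print.stepwise_result <- function(x, ...) {
  if (x$empty) {
    cat("<stepwise_result> no clear model prediction (no predictor entered)\n")
    return(invisible(x))
  }
  cat(sprintf("<stepwise_result> R2 = %.3f (adj %.3f), F(%d, %d) = %.1f, p = %.3g\n",
              x$r_squared, x$adj_r_squared, x$df[1], x$df[2], x$F, x$model_p))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' One-way repeated-measures ANOVA with Holm post-hocs and Cohen's d
#'
#' Within-subject one-way ANOVA across conditions (course sections), with
#' all pairwise paired comparisons Holm-corrected and Cohen's d per pair.
#' Cohen's d is computed from the mean difference over the pooled SD of the
#' two conditions (a paired difference-SD variant `d_z` is reported
#' alongside). With three or more levels the Greenhouse-Geisser epsilon and
#' corrected p-value are reported; the uncorrected F is primary.
#'
#' @param mat Numeric matrix, athletes x conditions (complete; column names
#'   are condition labels).
#' @return List of class `anova_result`: `F, df, p, gg_epsilon, p_gg`,
#'   `pairs` (data.frame with `raw_p, holm_p, d, d_z, magnitude`).
#' @export
rm_anova_holm <- function(mat) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop("matrix must be complete (every athlete in every condition)")
  n <- nrow(mat); k <- ncol(mat)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("c", seq_len(k))
  if (n < 2 || k < 2) stop("need at least 2 athletes and 2 conditions")
  grand <- mean(mat)
  ss_cond <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- k * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  Fval <- if (ms_err > 0) ms_cond / ms_err else 0
  pval <- pf(Fval, df1, df2, lower.tail = FALSE)

  gg <- NA_real_; p_gg <- NA_real_
  if (k >= 3) {
    S <- stats::cov(mat)
    gg <- (sum(diag(S)) - k * mean(S))^2 /
      ((k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * mean(S)^2))
    gg <- min(max(gg, 1 / (k - 1)), 1)
    p_gg <- pf(Fval, gg * df1, gg * df2, lower.tail = FALSE)
  }

  prs <- utils::combn(colnames(mat), 2)
  pair_rows <- lapply(seq_len(ncol(prs)), function(j) {
    a <- mat[, prs[1, j]]; b <- mat[, prs[2, j]]
    dvec <- a - b
    tt <- tryCatch(t.test(a, b, paired = TRUE),
                   error = function(e) list(p.value = NA_real_))
    pooled <- sqrt((var(a) + var(b)) / 2)
    d <- if (pooled > 0) mean(dvec) / pooled else 0
    dz <- if (sd(dvec) > 0) mean(dvec) / sd(dvec) else 0
    data.frame(pair = paste(prs[1, j], "vs", prs[2, j]),
               a = prs[1, j], b = prs[2, j],
               mean_diff = mean(dvec), raw_p = tt$p.value,
               d = d, d_z = dz,
               magnitude = as.character(effect_magnitude(d)))
  })
  pairs <- do.call(rbind, pair_rows)
  pairs$holm_p <- p.adjust(pairs$raw_p, method = "holm")
  out <- list(F = Fval, df = c(df1, df2), p = pval,
              gg_epsilon = gg, p_gg = p_gg, pairs = pairs, n = n)
  class(out) <- "anova_result"
  out
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.2f, p = %.4g (GG eps %.2f, p %.4g)\n",
              x$df[1], x$df[2], x$F, x$p, x$gg_epsilon, x$p_gg))
  print(x$pairs[, c("pair", "mean_diff", "raw_p", "holm_p", "d", "magnitude")],
        digits = 3)
  invisible(x)
}

#' Run the four-level stepped analysis model on a cohort
#'
#' Executes the stepped analysis on every dataset (course plus the three
#' sections):
#' \describe{
#'   \item{Level 1}{stepwise regression of course time `T` on the section's
#'     energy-dissipation index and path length (`de_per_vin`, `L`).}
#'   \item{Level 2}{Pearson correlations of sectional radial force `F_r`
#'     with `T` and with sectional `de_per_vin`.}
#'   \item{Level 3}{stepwise regression of `F_r` on force magnitude `F_tot`
#'     and force application effectiveness `RF`.}
#'   \item{Level 4}{stepwise regression of `F_tot` on outside-limb force
#'     `F_out` and limb balance `F_diff`.}
#' }
#'
#' @param summaries List of `run_summary` objects (one per athlete).
#' @param enter_p,remove_p Stepwise criteria.
#' @return List of class `stepped_model_report`: per dataset
#'   (`course, speed, overspeed, flat`) the four level results, plus the
#'   athlete-level data table and any warnings.
#' @export
run_stepped_model <- function(summaries, enter_p = 0.05, remove_p = 0.10) {
  n <- length(summaries)
  notes <- character(0)
  if (n < 10)
    notes <- c(notes, paste0("cohort of ", n,
      " athletes is below the recommended minimum of 10; estimates are unstable"))
  tab <- cohort_table(summaries)
  datasets <- c("course", "speed", "overspeed", "flat")
  res <- lapply(datasets, function(ds) {
    d <- tab[tab$dataset == ds, ]
    lvl1 <- stepwise_regression(d$T, d[, c("de_per_vin", "L")],
                                enter_p, remove_p)
    lvl2 <- list(
      T_vs_Fr = tryCatch(pearson_with_ci(d$F_r, d$T),
                         error = function(e) e$message),
      de_vs_Fr = tryCatch(pearson_with_ci(d$F_r, d$de_per_vin),
                          error = function(e) e$message))
    lvl3 <- stepwise_regression(d$F_r, d[, c("F_tot", "RF")],
                                enter_p, remove_p)
    lvl4 <- stepwise_regression(d$F_tot, d[, c("F_out", "F_diff")],
                                enter_p, remove_p)
    list(level1 = lvl1, level2 = lvl2, level3 = lvl3, level4 = lvl4)
  })
  names(res) <- datasets
  out <- list(datasets = res, data = tab, n_athletes = n, notes = notes)
  class(out) <- "stepped_model_report"
  if (length(notes)) warning(paste(notes, collapse = "; "))
  out
}

# athlete x dataset table of the variables entering the stepped model
cohort_table <- function(summaries) {
  rows <- lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    stopifnot(inherits(s, "run_summary"))
    course <- data.frame(athlete = i, dataset = "course", t(s$course),
                         T = s$T)
    secs <- lapply(rownames(s$sections), function(sec)
      data.frame(athlete = i, dataset = sec, s$sections[sec, ], T = s$T))
    do.call(rbind, c(list(course), secs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.stepped_model_report <- function(x, ...) {
  cat("<stepped_model_report> ", x$n_athletes, " athletes\n", sep = "")
  for (ds in names(x$datasets)) {
    r <- x$datasets[[ds]]
    l3 <- if (r$level3$empty) "no model" else
      sprintf("R2 = %.3f", r$level3$r_squared)
    l2 <- if (is.data.frame(r$level2$T_vs_Fr))
      sprintf("%+.2f", r$level2$T_vs_Fr$r) else "degenerate"
    cat(sprintf("  %-9s L1 %s | L2 r(T, F_r) = %s | L3 %s | L4 %s\n", ds,
                if (r$level1$empty) "no model" else
                  sprintf("R2 = %.2f", r$level1$r_squared),
                l2, l3,
                if (r$level4$empty) "no model" else
                  sprintf("R2 = %.3f", r$level4$r_squared)))
  }
  invisible(x)
}
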