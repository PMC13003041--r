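#' Group statistics used by the neuropathology pipeline
#'
#' Wrappers with a uniform `test_result` return value around the
#' statistical procedures applied to the pipeline's outputs: Mann-Whitney
#' U (ordinal ADI scores, two groups), Shapiro-Wilk normality screening,
#' two-way ANOVA (treatment x sex, each time point analysed
#' independently), ANCOVA with body weight as covariate, and the power
#' calculation behind the group sizes.
#'
#' @name pipeline_stats
NULL

test_result <- function(method, statistic_name, statistic, p_value,
                        df = NULL, notes = character(0), ss = NULL) {
  structure(list(method = method, statistic_name = statistic_name,
                 statistic = unname(statistic), df = df,
                 p_value = unname(p_value), notes = notes, ss = ss),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  dfs <- if (is.null(x$df)) "" else
    sprintf("(%s) ", paste(x$df, collapse = ","))
  cat(sprintf("%s: %s%s = %.4g, p = %.4g\n", x$method, x$statistic_name,
              dfs, x$statistic, x$p_value))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test with midranks for ties. The U statistic is
#' computed for the first sample, `U = R_x - n_x(n_x+1)/2`. The two-sided
#' p-value uses the tie-corrected normal approximation with a 0.5
#' continuity correction; for small untied samples
#' (`n_x + n_y <= max_exact`) the exact enumeration p-value is used
#' instead.
#'
#' @param x,y non-empty numeric samples (x first: for ADI comparisons,
#'   males).
#' @param max_exact largest pooled size for which the exact p-value is
#'   computed when there are no ties (default 12).
#' @return A `test_result` with `statistic_name = "U"`.
#' @export
mann_whitney <- function(x, y, max_exact = 12) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  pooled <- c(x, y)
  ties <- any(duplicated(pooled))
  use_exact <- !ties && length(pooled) <= max_exact
  r <- rank(pooled)
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE))
  notes <- c(if (ties) "midranks; tie-corrected variance",
             if (use_exact) "exact enumeration p"
             else "normal approximation with continuity correction")
  stopifnot(isTRUE(all.equal(unname(wt$statistic), U)))
  test_result("Mann-Whitney U test", "U", U, wt$p.value, notes = notes)
}

#' Shapiro-Wilk normality test
#'
#' W statistic and p-value from normal-order-statistic coefficients
#' (Royston's algorithm), for sample sizes 3 to 50.
#'
#' @param x numeric sample, 3 <= n <= 50, non-constant.
#' @return A `test_result` with `statistic_name = "W"`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3 || length(x) > 50)
    stop("sample size must be between 3 and 50")
  if (sd(x) == 0) stop("zero-variance sample")
  sw <- shapiro.test(x)
  test_result("Shapiro-Wilk normality test", "W", sw$statistic, sw$p.value)
}

check_cells <- function(data, factor_a, factor_b) {
  tab <- table(data[[factor_a]], data[[factor_b]])
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s = %s, %s = %s",
                 factor_a, rownames(tab)[empty[1]],
                 factor_b, colnames(tab)[empty[2]]))
  }
}

#' Two-way ANOVA (treatment x sex)
#'
#' Least-squares fit of `response ~ A * B` with Type II sums of squares,
#' computed as nested-model residual-sum-of-squares differences (each term
#' tested against the model containing the terms it is marginal to); Type
#' III is available via sum-to-zero contrasts. For balanced designs the
#' types coincide. Degenerate inputs (zero residual variance) yield zero
#' or undefined F with the sums of squares still reported. The response
#' may be log-transformed first; the applied transform is recorded in the
#' result notes.
#'
#' @param table data frame with the response and both factors.
#' @param response response column name.
#' @param factor_a,factor_b factor column names (>= 2 levels each, no
#'   empty cell).
#' @param interaction include the A:B interaction (default TRUE).
#' @param transform `"none"` or `"log"` (natural log; positive response).
#' @param ss_type sums-of-squares type, 2 (default) or 3.
#' @return Named list of `test_result`s: one per factor and, when
#'   requested, the interaction.
#' @export
two_way_anova <- function(table, response, factor_a = "group",
                          factor_b = "sex", interaction = TRUE,
                          transform = c("none", "log"), ss_type = 2) {
  transform <- match.arg(transform)
  for (f in c(factor_a, factor_b)) {
    table[[f]] <- factor(table[[f]])
    if (nlevels(table[[f]]) < 2) stop("factor with fewer than 2 levels: ", f)
  }
  check_cells(table, factor_a, factor_b)
  y <- table[[response]]
  if (transform == "log") {
    if (any(y <= 0)) stop("log transform requires a positive response")
    table[[response]] <- log(y)
  }
  full_rhs <- if (interaction) paste(factor_a, "*", factor_b) else
    paste(factor_a, "+", factor_b)
  rss <- function(rhs) {
    fm <- as.formula(paste(response, "~", rhs))
    f <- lm(fm, data = table)
    list(rss = sum(f$residuals^2), df = f$df.residual)
  }
  full <- rss(full_rhs)
  additive <- paste(factor_a, "+", factor_b)
  # Type II: each term tested against the model containing every other
  # term it is marginal to
  comparisons <- list()
  comparisons[[factor_a]] <- c(factor_b, additive)
  comparisons[[factor_b]] <- c(factor_a, additive)
  if (interaction)
    comparisons[[paste0(factor_a, ":", factor_b)]] <- c(additive, full_rhs)
  if (ss_type == 3) {
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old))
    fit3 <- lm(as.formula(paste(response, "~", full_rhs)), data = table)
    dr <- drop1(fit3, scope = as.formula(paste("~", full_rhs)), test = "F")
  }
  notes <- c(sprintf("Type %s SS", ss_type),
             if (transform == "log") "log-transformed response")
  out <- lapply(names(comparisons), function(tm) {
    if (ss_type == 3 && tm %in% rownames(dr)) {
      ss <- dr[tm, "Sum of Sq"]; df1 <- dr[tm, "Df"]
    } else {
      reduced <- rss(comparisons[[tm]][1])
      nested <- rss(comparisons[[tm]][2])
      ss <- reduced$rss - nested$rss
      df1 <- reduced$df - nested$df
    }
    ms_res <- full$rss / full$df
    Fv <- (ss / df1) / ms_res
    test_result("two-way ANOVA", "F", Fv,
                pf(Fv, df1, full$df, lower.tail = FALSE),
                df = c(df1, full$df), notes = notes, ss = ss)
  })
  names(out) <- names(comparisons)
  out
}

#' ANCOVA: group effect adjusted for a covariate
#'
#' Fits `response ~ group + covariate` by least squares and reports the
#' covariate-adjusted group F (Type II).
#'
#' @param table data frame.
#' @param response,group,covariate column names; the covariate must be
#'   numeric and non-constant, and must vary within groups.
#' @return A `test_result` for the adjusted group effect.
#' @export
ancova <- function(table, response, group, covariate) {
  table[[group]] <- factor(table[[group]])
  cv <- table[[covariate]]
  if (!is.numeric(cv) || sd(cv) == 0) stop("covariate must be numeric and non-constant")
  within_sd <- tapply(cv, table[[group]], sd)
  if (all(within_sd == 0, na.rm = TRUE))
    stop("covariate is constant within every group (collinear with group)")
  fit_full <- lm(as.formula(paste(response, "~", group, "+", covariate)),
                 data = table)
  fit_cov <- lm(as.formula(paste(response, "~", covariate)), data = table)
  ss_group <- sum(fit_cov$residuals^2) - sum(fit_full$residuals^2)
  df1 <- fit_cov$df.residual - fit_full$df.residual
  ms_res <- sum(fit_full$residuals^2) / fit_full$df.residual
  Fv <- (ss_group / df1) / ms_res
  test_result("ANCOVA", "F", Fv,
              pf(Fv, df1, fit_full$df.residual, lower.tail = FALSE),
              df = c(df1, fit_full$df.residual),
              notes = sprintf("adjusted for %s", covariate),
              ss = ss_group)
}

#' Per-group sample size for a standardised effect
#'
#' Two-sample, two-sided comparison at standardised effect size `d`:
#' the normal approximation with small-sample correction,
#' `n = 2 (z_{1-alpha/2} + z_{power})^2 / d^2 + z_{1-alpha/2}^2 / 4`,
#' rounded to the nearest integer, plus the exact noncentral-t solution.
#'
#' @param d standardised effect size (> 0).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return List with `n` (rounded corrected approximation), `n_approx`
#'   (unrounded), and `n_exact` (noncentral-t solution, `NA` when the
#'   root finder cannot bracket it).
#' @export
power_sample_size <- function(d, alpha = 0.05, power = 0.80) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  za <- qnorm(1 - alpha / 2)
  zb <- qnorm(power)
  n_approx <- 2 * (za + zb)^2 / d^2 + za^2 / 4
  n_exact <- tryCatch(
    power.t.test(delta = d, sd = 1, sig.level = alpha, power = power)$n,
    error = function(e) NA_real_)
  list(n = round_half_up(n_approx), n_approx = n_approx, n_exact = n_exact)
}
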