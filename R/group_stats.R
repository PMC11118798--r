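#' Bonferroni-corrected alpha level
#'
#' @param alpha_family familywise alpha (0 < alpha <= 1).
#' @param m number of tests (>= 1).
#' @return `alpha_family / m` (e.g. 0.05 / 32 = 0.0015625, displayed
#'   0.00156).
#' @export
bonferroni <- function(alpha_family, m) {
  if (!is.numeric(alpha_family) || alpha_family <= 0 || alpha_family > 1)
    stop("alpha_family must be in (0, 1]", call. = FALSE)
  if (!is.numeric(m) || m < 1) stop("m must be a positive integer",
                                    call. = FALSE)
  alpha_family / m
}

#' Critical t value (upper-tail quantile)
#'
#' The upper-tail Student-t quantile at probability `alpha`.  Under the
#' study design convention df = n - 1 = 14, `t_critical(0.00156, 14)`
#' reproduces the published significance threshold 3.563.
#'
#' @param alpha upper-tail probability (0 < alpha < 1).
#' @param df degrees of freedom (>= 1).
#' @return dimensionless threshold.
#' @export
t_critical <- function(alpha, df) {
  stopifnot(alpha > 0, alpha < 1, df >= 1)
  stats::qt(1 - alpha, df)
}

#' One-sample t-test of group DB values against a null reference
#'
#' `t = (mean(db) - null_mean) / (sd(db) / sqrt(n))`, df = n - 1.
#' Significance uses the symmetric rule `|t| >= t_critical(alpha, df)`;
#' the reported p-value is the matching upper-tail probability of `|t|`,
#' so `p < alpha` iff the threshold rule fires.
#'
#' @param db_values per-participant weights (n >= 3).
#' @param null_mean reference mean (e.g. from [fit_null_reference()]).
#' @param alpha per-test (already corrected) alpha.
#' @return list: `group_mean`, `group_sem`, `t_stat`, `df`, `p_value`,
#'   `significant`.
#' @export
connection_ttest <- function(db_values, null_mean = 0, alpha = 0.05) {
  n <- length(db_values)
  if (n < 3) stop("need at least 3 participants", call. = FALSE)
  s <- stats::sd(db_values)
  if (s == 0) stop("degenerate (zero-variance) group values", call. = FALSE)
  se <- s / sqrt(n)
  t_stat <- (mean(db_values) - null_mean) / se
  df <- n - 1
  p <- stats::pt(abs(t_stat), df, lower.tail = FALSE)
  list(group_mean = mean(db_values), group_sem = se, t_stat = t_stat,
       df = df, p_value = p,
       significant = abs(t_stat) >= t_critical(alpha, df))
}

#' Regression of connectivity values on a covariate
#'
#' Ordinary least squares of per-participant DB values on a pain-rating
#' covariate: slope, Pearson r, and the two-sided p-value for a nonzero
#' slope.  Bonferroni correction over tested connections is applied by
#' the caller via [bonferroni()].
#'
#' @param covariate numeric covariate (e.g. first-contact pain rating).
#' @param db_values per-participant weights, same length.
#' @return list: `slope`, `intercept`, `r`, `p_value`, `n`.
#' @export
regress_db <- function(covariate, db_values) {
  n <- length(db_values)
  stopifnot(length(covariate) == n)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(covariate) == 0) stop("constant covariate", call. = FALSE)
  fit <- stats::lm(db_values ~ covariate)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(stats::cor(covariate, db_values)),
       p_value = sm$coefficients[2, 4], n = n)
}

#' Group-by-covariate ANCOVA for one connection
#'
#' Fits `db ~ group + covariate + group:covariate` and reports type-III
#' style partial F tests (sum-to-zero group coding, each term tested by
#' removing its columns from the full model), so the interaction p-value
#' is invariant to group coding.  Per-group mean DB values are reported
#' alongside, matching the published table layout.
#'
#' @param group_labels factor/character of group membership (2 groups,
#'   n >= 3 each).
#' @param covariate numeric covariate.
#' @param db_values numeric weights.
#' @return data.frame with one row per effect (`group`, `covariate`,
#'   `interaction`): `p_value`, `F`, plus per-group mean and SEM columns.
#' @export
ancova <- function(group_labels, covariate, db_values) {
  g <- factor(group_labels)
  if (nlevels(g) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(g) < 3)) stop("each group needs n >= 3", call. = FALSE)
  n <- length(db_values)
  stopifnot(length(g) == n, length(covariate) == n)
  gc <- ifelse(g == levels(g)[1], 1, -1)          # sum-to-zero coding
  xc <- covariate - mean(covariate)
  X_full <- cbind(intercept = 1, group = gc, covariate = xc,
                  interaction = gc * xc)
  rss <- function(X) {
    fit <- stats::lm.fit(X, db_values)
    sum(fit$residuals^2)
  }
  rss_full <- rss(X_full)
  df_resid <- n - ncol(X_full)
  out <- lapply(c("group", "covariate", "interaction"), function(term) {
    rss_red <- rss(X_full[, colnames(X_full) != term, drop = FALSE])
    Fv <- (rss_red - rss_full) / (rss_full / df_resid)
    data.frame(effect = term, F = Fv,
               p_value = stats::pf(Fv, 1, df_resid, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  for (lv in levels(g)) {
    v <- db_values[g == lv]
    res[[paste0("mean_", lv)]] <- mean(v)
    res[[paste0("sem_", lv)]] <- stats::sd(v) / sqrt(length(v))
  }
  res
}

#' Collect per-participant fits into a connectivity matrix
#'
#' @param fits list of `sapm_fit` objects (consistent connection sets).
#' @param include_latent include latent-link weights.
#' @return matrix participants x connections.
#' @export
db_matrix <- function(fits, include_latent = FALSE) {
  labs <- names(fits[[1]]$db)
  if (!include_latent) labs <- labs[!grepl("^int[0-9]+->", labs)]
  out <- t(vapply(fits, function(f) f$db[labs], numeric(length(labs))))
  colnames(out) <- labs
  rownames(out) <- names(fits)
  out
}

#' Group statistics table (published-table layout)
#'
#' Per connection: group mean, SEM, T against the null-reference mean,
#' and a Bonferroni-corrected significance flag.  The correction counts
#' inter-region connections only (latent links are not tested).
#'
#' @param fits_by_cell named list: one entry per group/condition cell,
#'   each a list of `sapm_fit` objects (one per participant).
#' @param null_ref a `sapm_null_reference`, or `NULL` for a zero
#'   reference.
#' @param alpha_family familywise alpha (default 0.05).
#' @return object of class `sapm_group_stats`: data.frame `rows` plus
#'   `alpha_family`, `m_tests`, `alpha_corrected`, `t_threshold`
#'   (df from the first cell's group size).
#' @export
summarize_table <- function(fits_by_cell, null_ref = NULL,
                            alpha_family = 0.05) {
  labs0 <- colnames(db_matrix(fits_by_cell[[1]]))
  m_tests <- length(labs0)
  alpha_corr <- bonferroni(alpha_family, m_tests)
  rows <- list()
  df_first <- NULL
  for (cell in names(fits_by_cell)) {
    mat <- db_matrix(fits_by_cell[[cell]])
    if (!identical(colnames(mat), labs0))
      stop("inconsistent connection sets across cells", call. = FALSE)
    for (cn in colnames(mat)) {
      nm <- if (!is.null(null_ref)) unname(null_ref$mean[cn]) else 0
      if (is.na(nm)) nm <- 0
      tt <- connection_ttest(mat[, cn], null_mean = nm, alpha = alpha_corr)
      if (is.null(df_first)) df_first <- tt$df
      rows[[paste(cell, cn)]] <- data.frame(
        cell = cell, connection = cn, group_mean = tt$group_mean,
        group_sem = tt$group_sem, t_stat = tt$t_stat, p_value = tt$p_value,
        significant = tt$significant, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(rows = out, alpha_family = alpha_family, m_tests = m_tests,
                 alpha_corrected = alpha_corr,
                 t_threshold = t_critical(alpha_corr, df_first)),
            class = "sapm_group_stats")
}

#' @export
print.sapm_group_stats <- function(x, ...) {
  cat(sprintf(
    "Group connectivity statistics: %d tests, corrected p < %.5g (T >= %.3f)\n",
    x$m_tests, x$alpha_corrected, x$t_threshold))
  sig <- x$rows[x$rows$significant, ]
  for (i in seq_len(nrow(sig)))
    cat(sprintf("  %-12s %-22s %6.3f +/- %.3f  T = %.2f\n", sig$cell[i],
                sig$connection[i], sig$group_mean[i], sig$group_sem[i],
                sig$t_stat[i]))
  invisible(x)
}

#' Format a group statistics table as aligned text
#'
#' @param x a `sapm_group_stats`.
#' @return character vector of lines (mean +/- SEM with T values;
#'   significant entries marked with `*`).
#' @export
format_group_stats <- function(x) {
  r <- x$rows
  c(sprintf("corrected p threshold %.5g; T-threshold %.3f; %d tests",
            x$alpha_corrected, x$t_threshold, x$m_tests),
    sprintf("%-12s %-22s %8.3f +/- %.3f  T=%6.2f%s",
            r$cell, r$connection, r$group_mean, r$group_sem, r$t_stat,
            ifelse(r$significant, " *", "")))
}
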