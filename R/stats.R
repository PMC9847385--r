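# Cohort comparison statistics: Mann-Whitney U (exact by enumeration for
# small tieless samples, normal approximation with tie and continuity
# correction otherwise) and the two-sample t test. Two-sided p-values
# throughout; significance at alpha = 0.05.

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank ties. The reported statistic is
#' `U = min(U_a, U_b)`. The p-value is exact (full enumeration of group
#' labelings) when `n_a + n_b <= exact_max_n` and there are no ties, and
#' otherwise uses the normal approximation with tie correction and a 0.5
#' continuity correction.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param alpha Significance level.
#' @param exact_max_n Largest combined sample size for the exact path.
#' @return A `vl_test` object with fields `statistic_name`, `statistic`,
#'   `p_value`, `method`, `n_a`, `n_b`, `alpha`, `significant`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
mann_whitney_u <- function(a, b, alpha = 0.05, exact_max_n = 16L) {
  if (length(a) == 0 || length(b) == 0) {
    vl_abort("both groups must be non-empty", "viralint_input_error")
  }
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u <- min(ua, na * nb - ua)
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && n <= exact_max_n) {
    method <- "exact"
    combos <- combn(n, na)
    uperm <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    p <- mean(pmin(uperm, na * nb - uperm) <= u + 1e-9)
  } else {
    method <- "normal_approx"
    tt <- table(c(a, b))
    sigma2 <- na * nb / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - na * nb / 2 + 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(z))
    }
  }
  new_vl_test("mannwhitney_u", statistic = u, p_value = p, method = method,
              n_a = na, n_b = nb, alpha = alpha)
}

#' Two-sample t test
#'
#' Welch's t test by default (`welch = FALSE` gives the pooled-variance
#' Student variant). Degenerate inputs follow a fixed contract: both
#' variances zero with equal means gives p = 1; both zero with different
#' means gives p = 0.
#'
#' @param a,b Numeric vectors with at least two values each.
#' @param welch Use the Welch statistic and Welch-Satterthwaite df?
#' @param alpha Significance level.
#' @return A `vl_test` object (fields as in [mann_whitney_u()], plus `df`).
#' @export
two_sample_t <- function(a, b, welch = TRUE, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2) {
    vl_abort("each group needs at least two values", "viralint_input_error")
  }
  if (var(a) == 0 && var(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(new_vl_test("t", statistic = if (same) 0 else
      Inf * sign(mean(a) - mean(b)),
      p_value = if (same) 1 else 0, method = "degenerate",
      n_a = length(a), n_b = length(b), alpha = alpha, df = NA_real_))
  }
  ht <- t.test(a, b, var.equal = !welch)
  new_vl_test("t", statistic = unname(ht$statistic),
              p_value = ht$p.value,
              method = if (welch) "welch" else "student",
              n_a = length(a), n_b = length(b), alpha = alpha,
              df = unname(ht$parameter))
}

new_vl_test <- function(statistic_name, statistic, p_value, method,
                        n_a, n_b, alpha, df = NULL) {
  structure(list(statistic_name = statistic_name, statistic = statistic,
                 p_value = p_value, method = method, n_a = n_a, n_b = n_b,
                 df = df, alpha = alpha,
                 significant = p_value < alpha),
            class = "vl_test")
}

#' @export
print.vl_test <- function(x, ...) {
  cat("<vl_test> ", x$statistic_name, " = ", format(x$statistic),
      ", p = ", format.pval(x$p_value), " (", x$method, "; n = ", x$n_a,
      "/", x$n_b, ")", if (x$significant) "  *" else "", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.vl_test <- function(x, ...) {
  tibble(statistic_name = x$statistic_name, statistic = x$statistic,
         p_value = x$p_value, method = x$method,
         n_a = x$n_a, n_b = x$n_b, significant = x$significant)
}

#' @export
glance.vl_test <- function(x, ...) tidy(x)

#' Compare two cohorts of per-sample breakpoint tables
#'
#' Builds the group-comparison report over annotated (or plain) breakpoint
#' tables from a case and a control cohort: per-sample breakpoint counts
#' with a Mann-Whitney U test, per-chromosome counts with per-chromosome t
#' tests (unadjusted by default; `p_adjust = "BH"` applies
#' Benjamini-Hochberg), per-sample DNase-I counts with a Mann-Whitney U
#' test when a `dnase` column is present, and the region-class
#' distribution per group.
#'
#' @param case,control Breakpoint tibbles (one row per breakpoint, with a
#'   `sample_id` column; `dnase` and `region_class` columns are used when
#'   present).
#' @param case_samples,control_samples Full sample rosters (so samples with
#'   zero breakpoints count as zeros); default: samples present in the
#'   tables.
#' @param alpha Significance level.
#' @param p_adjust Multiple-testing adjustment for the per-chromosome
#'   tests: "none" (default) or any `stats::p.adjust` method.
#' @return A `cohort_comparison` object; see [tidy.cohort_comparison()].
#' @export
summarize_cohorts <- function(case, control,
                              case_samples = unique(case$sample_id),
                              control_samples = unique(control$sample_id),
                              alpha = 0.05, p_adjust = "none") {
  count_per_sample <- function(tbl, samples, what = NULL) {
    cnt <- tbl |> count(.data$sample_id, name = "n")
    out <- tibble(sample_id = samples) |>
      left_join(cnt, by = "sample_id") |>
      mutate(n = coalesce(.data$n, 0L))
    out$n
  }
  n_case <- count_per_sample(case, case_samples)
  n_ctrl <- count_per_sample(control, control_samples)
  counts_by_sample <- bind_rows(
    tibble(sample_id = case_samples, group = "case", n_breakpoints = n_case),
    tibble(sample_id = control_samples, group = "control",
           n_breakpoints = n_ctrl))
  count_test <- mann_whitney_u(n_case, n_ctrl, alpha = alpha)

  # per-chromosome per-sample counts, tested per chromosome
  chrom_counts <- function(tbl, samples, group) {
    tbl |>
      count(.data$sample_id, chrom = normalize_chrom(.data$chrom)) |>
      complete(sample_id = samples,
               chrom = unique(normalize_chrom(c(case$chrom, control$chrom))),
               fill = list(n = 0L)) |>
      mutate(group = group)
  }
  cc <- bind_rows(chrom_counts(case, case_samples, "case"),
                  chrom_counts(control, control_samples, "control"))
  per_chromosome <- cc |>
    group_by(.data$chrom) |>
    summarise(
      n_case = sum(.data$n[.data$group == "case"]),
      n_control = sum(.data$n[.data$group == "control"]),
      p_value = {
        x <- .data$n[.data$group == "case"]
        y <- .data$n[.data$group == "control"]
        if (length(x) >= 2 && length(y) >= 2)
          two_sample_t(x, y, alpha = alpha)$p_value else NA_real_
      },
      .groups = "drop") |>
    mutate(p_value = if (p_adjust == "none") .data$p_value else
      stats::p.adjust(.data$p_value, method = p_adjust),
      significant = !is.na(.data$p_value) & .data$p_value < alpha)

  dnase_test <- NULL
  if ("dnase" %in% names(case) && "dnase" %in% names(control)) {
    d_case <- count_per_sample(filter(case, .data$dnase > 0), case_samples)
    d_ctrl <- count_per_sample(filter(control, .data$dnase > 0),
                               control_samples)
    dnase_test <- mann_whitney_u(d_case, d_ctrl, alpha = alpha)
  }

  region <- NULL
  if ("region_class" %in% names(case) &&
      "region_class" %in% names(control)) {
    region <- bind_rows(mutate(case, group = "case"),
                        mutate(control, group = "control")) |>
      count(.data$group, region_class = factor(.data$region_class,
                                               levels = REGION_LEVELS),
            .drop = FALSE, name = "n") |>
      group_by(.data$group) |>
      mutate(region_class = as.character(.data$region_class),
             pct = round(100 * .data$n / max(1L, sum(.data$n)), 2)) |>
      ungroup()
  }

  structure(list(counts_by_sample = counts_by_sample,
                 count_test = count_test,
                 per_chromosome = per_chromosome,
                 dnase_test = dnase_test,
                 region_distribution = region,
                 alpha = alpha),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  nc <- table(x$counts_by_sample$group)
  cat("<cohort_comparison> ", nc[["case"]], " case vs ", nc[["control"]],
      " control samples\n", sep = "")
  cat("  total breakpoints: case ",
      sum(x$counts_by_sample$n_breakpoints[x$counts_by_sample$group ==
                                             "case"]),
      ", control ",
      sum(x$counts_by_sample$n_breakpoints[x$counts_by_sample$group ==
                                             "control"]), "\n", sep = "")
  cat("  per-sample count Mann-Whitney p = ",
      format.pval(x$count_test$p_value), "\n", sep = "")
  if (!is.null(x$dnase_test)) {
    cat("  DNase-I count Mann-Whitney p = ",
        format.pval(x$dnase_test$p_value), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a cohort comparison
#'
#' One row per statistical test in the report (the per-sample count test,
#' the DNase-I count test when present, and one row per per-chromosome t
#' test).
#'
#' @param x A [summarize_cohorts()] object.
#' @param ... Unused.
#' @return A tibble with columns `test`, `statistic_name`, `statistic`,
#'   `p_value`, `significant`.
#' @export
tidy.cohort_comparison <- function(x, ...) {
  rows <- list(
    tidy(x$count_test) |> mutate(test = "breakpoint_count", .before = 1))
  if (!is.null(x$dnase_test)) {
    rows <- c(rows, list(tidy(x$dnase_test) |>
                           mutate(test = "dnase_count", .before = 1)))
  }
  rows <- c(rows, list(
    x$per_chromosome |>
      transmute(test = paste0("chromosome_", .data$chrom),
                statistic_name = "t", statistic = NA_real_,
                p_value = .data$p_value, method = "welch",
                n_a = NA_integer_, n_b = NA_integer_,
                significant = .data$significant)))
  bind_rows(rows)
}

#' @export
glance.cohort_comparison <- function(x, ...) {
  g <- x$counts_by_sample$group
  tibble(n_case = sum(g == "case"), n_control = sum(g == "control"),
         total_case = sum(x$counts_by_sample$n_breakpoints[g == "case"]),
         total_control = sum(x$counts_by_sample$n_breakpoints[g ==
                                                                "control"]),
         count_p_value = x$count_test$p_value,
         dnase_p_value = x$dnase_test$p_value %||% NA_real_,
         n_significant_chromosomes = sum(x$per_chromosome$significant),
         alpha = x$alpha)
}
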