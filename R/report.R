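#' Assembly N50
#'
#' The smallest length L such that scaffolds of length at least L jointly
#' cover at least half of the assembly.
#'
#' @param lengths Numeric vector of scaffold lengths in bp (all > 0).
#' @return N50 in bp.
#' @examples
#' compute_n50(c(70, 10, 10, 10))  # 70
#' @export
compute_n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length list", call. = FALSE)
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  s <- sort(lengths, decreasing = TRUE)
  i <- which(cumsum(s) >= sum(s) / 2)[1]
  s[i]
}

#' Adjusted logit transform of proportions
#'
#' `log(p' / (1 - p'))` with `p'` the input clamped into
#' `[adjustment, 1 - adjustment]`, so proportions of exactly 0 or 1 map to
#' finite values; interior proportions are untouched. Used to transform
#' percentage outcomes before linear modeling.
#'
#' @param p Proportions in `[0,1]`.
#' @param adjustment Squeeze width in `[0, 0.5)` (default 0.025).
#' @return Numeric vector of logits.
#' @examples
#' logit_adjusted(0.5)              # 0
#' logit_adjusted(0, 0.025)         # log(0.025 / 0.975)
#' @export
logit_adjusted <- function(p, adjustment = 0.025) {
  if (adjustment >= 0.5 || adjustment < 0) {
    stop("adjustment must lie in [0, 0.5)", call. = FALSE)
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("proportions must lie in [0,1]", call. = FALSE)
  }
  q <- pmin(pmax(p, adjustment), 1 - adjustment)
  log(q / (1 - q))
}

#' Per-assembly summary report
#'
#' Counts and percentages summarizing one screened assembly: stage-1
#' category counts, stage-2 partition of foreign candidates, contaminant
#' scaffolds (at least two contaminant CDS and no confident-resident CDS)
#' with their cumulative length, and the assembly N50.
#'
#' Denominators: `pct_contaminant_of_all` uses all CDS;
#' `pct_contaminant_of_assigned` and `pct_hgt_of_assigned` use CDS with a
#' stage-1 assignment other than orphan/unassigned (the set for which a
#' taxonomy call was possible — the most meaningful denominator);
#' `pct_uncertain_of_foreign` uses the foreign candidates.
#'
#' @param annotations Stage-2 annotations from [classify_foreign()].
#' @param table The [build_scaffold_table()] result.
#' @param scaffold_lengths Named numeric vector of scaffold lengths in bp.
#' @return A one-row tibble (an assembly report).
#' @export
summarize_assembly <- function(annotations, table, scaffold_lengths) {
  stopifnot(inherits(table, "scaffold_table"))
  a <- annotations
  n_total <- nrow(a)
  n_orphan <- sum(a$stage1 == "orphan")
  n_unassigned <- sum(a$stage1 == "unassigned")
  n_assigned <- n_total - n_orphan - n_unassigned
  n_foreign <- sum(a$stage1 == "foreign")

  fg <- foreign_groups()
  group_counts <- vapply(fg, function(g) {
    sum(a$stage1 == "foreign" & !is.na(a$foreign_group) &
          a$foreign_group == g)
  }, integer(1))
  names(group_counts) <- paste0("n_foreign_", fg)

  n_contam <- sum(a$stage2 == "contaminant_candidate")
  n_hgt <- sum(a$stage2 == "hgt_candidate")
  n_unc <- sum(a$stage2 == "uncertain")

  cs <- contaminant_scaffolds(a, table)
  cs_len <- unname(scaffold_lengths[cs])
  if (length(cs) && anyNA(cs_len)) {
    warning("length unknown for contaminant scaffold(s): ",
            paste(cs[is.na(cs_len)], collapse = ", "), call. = FALSE)
  }
  cum_bp <- if (length(cs)) sum(cs_len, na.rm = TRUE) else 0

  pct <- function(num, den) if (den > 0) 100 * num / den else 0

  dplyr::bind_cols(
    tibble(
      n_cds_total = n_total,
      n_orphan = n_orphan,
      n_unassigned = n_unassigned,
      n_assigned = n_assigned,
      n_confident_arthropod = sum(a$stage1 == "confident_arthropod"),
      n_other_metazoa = sum(a$stage1 == "other_metazoa"),
      n_foreign = n_foreign
    ),
    as_tibble(as.list(group_counts)),
    tibble(
      n_contaminant_cds = n_contam,
      n_hgt_cds = n_hgt,
      n_uncertain_cds = n_unc,
      n_contaminant_scaffolds = length(cs),
      contaminant_scaffold_cumulative_bp = cum_bp,
      pct_contaminant_of_all = pct(n_contam, n_total),
      pct_contaminant_of_assigned = pct(n_contam, n_assigned),
      pct_hgt_of_assigned = pct(n_hgt, n_assigned),
      pct_uncertain_of_foreign = pct(n_unc, n_foreign),
      n50_bp = compute_n50(scaffold_lengths)
    )
  )
}

# scaffolds with >= 2 contaminant CDS and no confident-resident CDS
contaminant_scaffolds <- function(annotations, table) {
  cc <- consistency_check(annotations, table)
  cc$scaffold_id
}

#' Regression of the uncertain fraction on assembly N50
#'
#' Fits an ordinary least-squares model of
#' `logit(uncertain fraction of foreign candidates)` on `log10(N50)`
#' across assemblies. Fragmented assemblies (low N50) have more scaffolds
#' carrying a single CDS, so synteny adjudicates fewer foreign candidates
#' and the uncertain fraction rises — the fitted slope is expected to be
#' negative.
#'
#' @param reports A tibble of at least 3 assembly reports
#'   ([summarize_assembly()] rows) with nonzero foreign candidates.
#' @param adjustment Logit squeeze (default 0.025).
#' @return An object of class `xenoscan_n50_fit` wrapping the `lm` fit;
#'   supports [tidy()], [glance()] and [autoplot()].
#' @export
n50_uncertain_regression <- function(reports, adjustment = 0.025) {
  reports <- filter(reports, .data$n_foreign > 0)
  if (nrow(reports) < 3L) {
    stop("need at least 3 reports with foreign candidates", call. = FALSE)
  }
  d <- tibble(
    log10_n50 = log10(reports$n50_bp),
    logit_uncertain = logit_adjusted(
      reports$pct_uncertain_of_foreign / 100, adjustment)
  )
  if (stats::var(d$log10_n50) == 0) {
    stop("zero variance in log10(N50)", call. = FALSE)
  }
  fit <- stats::lm(logit_uncertain ~ log10_n50, data = d)
  structure(list(fit = fit, data = d), class = "xenoscan_n50_fit")
}

#' @export
print.xenoscan_n50_fit <- function(x, ...) {
  g <- glance(x)
  cat("<xenoscan_n50_fit>  logit(uncertain) ~ log10(N50)\n")
  cat(sprintf("  slope = %.4f  intercept = %.4f  R^2 = %.4f  p = %.4g\n",
              coef(x$fit)[2], coef(x$fit)[1], g$r_squared, g$p_value))
  invisible(x)
}

#' @rdname n50_uncertain_regression
#' @param x An `xenoscan_n50_fit` object.
#' @param ... Ignored.
#' @method tidy xenoscan_n50_fit
#' @export
tidy.xenoscan_n50_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p_value = s[, "Pr(>|t|)"]
  )
}

#' @rdname n50_uncertain_regression
#' @method glance xenoscan_n50_fit
#' @export
glance.xenoscan_n50_fit <- function(x, ...) {
  s <- summary(x$fit)
  slope_row <- s$coefficients["log10_n50", ]
  tibble(
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    slope = unname(slope_row["Estimate"]),
    intercept = unname(coef(x$fit)[1]),
    p_value = unname(slope_row["Pr(>|t|)"]),
    n = nrow(x$data)
  )
}

#' @rdname n50_uncertain_regression
#' @param object An `xenoscan_n50_fit` object.
#' @method autoplot xenoscan_n50_fit
#' @export
autoplot.xenoscan_n50_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$log10_n50,
                               y = .data$logit_uncertain)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = "log10(N50)",
                  y = "logit(uncertain fraction of foreign candidates)") +
    ggplot2::theme_minimal()
}

#' Plot the stage-1/stage-2 category composition of a report
#'
#' @param report A one-row tibble from [summarize_assembly()].
#' @return A ggplot bar chart of CDS category counts.
#' @export
plot_report <- function(report) {
  counts <- tibble(
    category = c("confident resident", "other metazoa", "orphan",
                 "unassigned", "contaminant", "HGT", "uncertain"),
    n = c(report$n_confident_arthropod, report$n_other_metazoa,
          report$n_orphan, report$n_unassigned, report$n_contaminant_cds,
          report$n_hgt_cds, report$n_uncertain_cds)
  )
  ggplot2::ggplot(counts, ggplot2::aes(x = stats::reorder(.data$category,
                                                          -.data$n),
                                       y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "CDS count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
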