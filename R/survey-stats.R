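#' Construct a contingency table of observed counts
#'
#' @param counts A numeric matrix of nonnegative integer counts, at
#'   least 2 x 2, with a positive grand total. Dimnames, when present,
#'   label outcome levels (rows) and groups (columns).
#' @return An object of class `contingency_table` (a matrix).
#' @export
contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("contingency table needs at least 2 rows and 2 columns",
         call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(counts) <= 0) {
    stop("contingency table has an empty grand total", call. = FALSE)
  }
  structure(counts, class = c("contingency_table", class(counts)))
}

#' Pearson chi-square test of independence
#'
#' The classical Pearson statistic \eqn{\sum (O - E)^2 / E} over a
#' contingency table, with \eqn{(r-1)(c-1)} degrees of freedom and a
#' two-sided upper-tail p-value. No continuity correction is applied by
#' default — the uncorrected form is what national survey-outcome
#' comparisons of this kind report; Yates' correction is available for
#' 2 x 2 tables via `correct = TRUE`.
#'
#' @param table A [contingency_table()] (or plain count matrix).
#' @param correct Apply Yates' continuity correction (2 x 2 only).
#' @return An object of class `chi_square_result` with `statistic`,
#'   `df`, `p_value`, `expected` and `observed`.
#' @examples
#' pearson_chi_square(rbind(c(538, 83), c(517, 165)))  # ~24.7 on 1 df
#' @export
pearson_chi_square <- function(table, correct = FALSE) {
  if (!inherits(table, "contingency_table")) {
    table <- contingency_table(table)
  }
  obs <- unclass(table)
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (any(expected == 0)) {
    stop("degenerate table: an expected count is zero (empty row or ",
         "column margin)", call. = FALSE)
  }
  dev <- abs(obs - expected)
  if (correct) {
    if (!all(dim(obs) == c(2, 2))) {
      stop("continuity correction applies to 2 x 2 tables only",
           call. = FALSE)
    }
    dev <- pmax(dev - 0.5, 0)
  }
  statistic <- sum(dev^2 / expected)
  df <- (nrow(obs) - 1L) * (ncol(obs) - 1L)
  structure(list(
    statistic = statistic, df = df,
    p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
    expected = expected, observed = obs
  ), class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("<chi_square_result> X^2 = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Compare a binary outcome across groups
#'
#' Builds the yes/no by group contingency table from per-group "yes"
#' counts and totals, computes per-group percentages (2 dp), and tests
#' independence with the uncorrected Pearson chi-square.
#'
#' @param yes_counts Integer "yes" counts per group.
#' @param totals Integer group totals (each >= its yes count).
#' @param groups Optional group labels.
#' @param outcome Optional outcome name carried into the result.
#' @return An object of class `outcome_comparison`: `outcome`,
#'   `groups`, `yes`, `total`, `percent`, and `chi_square` (a
#'   `chi_square_result`).
#' @examples
#' compare_outcome(c(314, 48), c(1055, 248))  # X^2 ~ 10.8
#' @export
compare_outcome <- function(yes_counts, totals, groups = NULL,
                            outcome = NA_character_) {
  if (length(yes_counts) != length(totals) || length(totals) < 2) {
    stop("need matching yes counts and totals for at least 2 groups",
         call. = FALSE)
  }
  if (any(yes_counts > totals)) {
    stop("yes count exceeds its group total", call. = FALSE)
  }
  if (is.null(groups)) {
    groups <- names(yes_counts) %||% paste0("group", seq_along(yes_counts))
  }
  tab <- contingency_table(rbind(yes = yes_counts,
                                 no = totals - yes_counts))
  colnames(tab) <- groups
  structure(list(
    outcome = outcome, groups = groups,
    yes = as.integer(yes_counts), total = as.integer(totals),
    percent = round(100 * yes_counts / totals, 2),
    chi_square = pearson_chi_square(tab)
  ), class = "outcome_comparison")
}

#' @export
print.outcome_comparison <- function(x, ...) {
  cat("<outcome_comparison>",
      if (!is.na(x$outcome)) x$outcome else "", "\n")
  for (i in seq_along(x$groups)) {
    cat(sprintf("  %s: %d/%d (%.2f%%)\n", x$groups[i], x$yes[i],
                x$total[i], x$percent[i]))
  }
  print(x$chi_square)
  invisible(x)
}

# registry of follow-up survey outcomes, in report-table order
survey_outcomes <- function() {
  data.frame(
    column = c("recall_correct", "very_motivated", "very_optimistic",
               "very_anxious", "very_worried", "spoke_family",
               "found_info", "told_others",
               "increased_activity", "lost_weight", "improved_diet",
               "reduced_smoking", "reduced_stress", "limited_alcohol",
               "saw_gp", "heart_health_check", "bp_check",
               "cholesterol_test", "diabetes_test"),
    label = c("Recall of correct heart age category",
              "Very motivated (a great deal/a lot)",
              "Very optimistic (a great deal/a lot)",
              "Very anxious (a great deal/a lot)",
              "Very worried (a great deal/a lot)",
              "Spoke to family about familial history",
              "Found out more information",
              "Told others about the calculator",
              "Increased physical activity", "Lost weight",
              "Improved diet", "Reduced or quit smoking",
              "Reduced stress", "Limited alcohol intake",
              "Saw general practitioner", "Had a heart health check up",
              "Had a blood pressure check",
              "Had a blood test for cholesterol",
              "Had a test for diabetes or sugar levels"),
    section = rep(c("psychological", "lifestyle", "clinical"),
                  times = c(8, 6, 5)),
    denominator = c(rep("all", 11), "smokers", rep("all", 7)),
    stringsAsFactors = FALSE
  )
}

#' Build the follow-up outcome table from survey records
#'
#' Produces one comparison per survey outcome, grouping respondents
#' with an older heart age against those with a younger or equal heart
#' age, in the report's order (psychological, lifestyle change,
#' clinical risk assessment). The smoking-reduction row is computed
#' among current smokers only. Records with a missing heart-age
#' category are excluded and their number attached as the
#' `excluded` attribute. A comparison whose table is degenerate (an
#' empty margin, e.g. no smokers in one group) yields `NA` statistics
#' for that row rather than an error.
#'
#' @param records A data frame with a `category` column
#'   (`"older"`/`"younger"`/`"equal"`), a logical `smoker` column, and
#'   one logical column per outcome (see the `column` field of the
#'   internal registry; missing outcome columns are skipped).
#' @return A data frame of class `survey_outcome_table`, one row per
#'   outcome, with overall and per-group counts, percentages (2 dp),
#'   and the chi-square statistic, df and p-value.
#' @export
build_table2 <- function(records) {
  stopifnot(is.data.frame(records), "category" %in% names(records))
  excluded <- sum(is.na(records$category))
  if (excluded > 0) {
    message("excluding ", excluded, " record(s) with missing heart-age ",
            "category")
    records <- records[!is.na(records$category), , drop = FALSE]
  }
  bad <- setdiff(unique(records$category),
                 c("older", "younger", "equal"))
  if (length(bad)) {
    stop("unknown heart-age category value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  grp <- ifelse(records$category == "older", "older", "younger_equal")
  if (length(unique(grp)) < 2) {
    stop("degenerate table: all records fall in one heart-age group",
         call. = FALSE)
  }
  reg <- survey_outcomes()
  reg <- reg[reg$column %in% names(records), , drop = FALSE]
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    col <- reg$column[i]
    keep <- if (reg$denominator[i] == "smokers") {
      isTRUE_v(records$smoker)
    } else {
      rep(TRUE, nrow(records))
    }
    yes <- records[[col]] & keep
    n_old <- sum(keep & grp == "older")
    n_ye <- sum(keep & grp == "younger_equal")
    y_old <- sum(yes & grp == "older", na.rm = TRUE)
    y_ye <- sum(yes & grp == "younger_equal", na.rm = TRUE)
    stat <- df <- p <- NA_real_
    if (n_old > 0 && n_ye > 0 && (y_old + y_ye) > 0 &&
        (y_old + y_ye) < (n_old + n_ye)) {
      cmp <- compare_outcome(c(y_old, y_ye), c(n_old, n_ye),
                             groups = c("older", "younger_equal"),
                             outcome = col)
      stat <- cmp$chi_square$statistic
      df <- cmp$chi_square$df
      p <- cmp$chi_square$p_value
    }
    n_all <- n_old + n_ye
    data.frame(
      outcome = col, label = reg$label[i], section = reg$section[i],
      yes_all = y_old + y_ye, n_all = n_all,
      pct_all = round(100 * (y_old + y_ye) / n_all, 2),
      yes_older = y_old, n_older = n_old,
      pct_older = round(100 * y_old / n_old, 2),
      yes_younger_equal = y_ye, n_younger_equal = n_ye,
      pct_younger_equal = round(100 * y_ye / n_ye, 2),
      statistic = stat, df = df, p_value = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  class(out) <- c("survey_outcome_table", class(out))
  out
}

isTRUE_v <- function(x) !is.na(x) & x
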