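#' Construct a contingency table
#'
#' Cross-tabulates one categorical/binary variable against the binary birth
#' weight outcome (or any second categorical column). Rows with a missing
#' value in either column are dropped (complete-case, with the count
#' recorded in the result).
#'
#' @param data A `synthetic_cohort`, `cohort`, or data.frame.
#' @param variable Column name of the variable to tabulate.
#' @param outcome Column name of the outcome (default `"outcome"`).
#' @return An object of class `contingency_table` with `counts`,
#'   `row_labels`, `col_labels`, and `n_dropped`.
#' @export
build_contingency <- function(data, variable, outcome = "outcome") {
  df <- as_cohort_df(data)
  for (col in c(variable, outcome)) {
    if (!col %in% names(df)) {
      stop(sprintf("column `%s` not found", col), call. = FALSE)
    }
  }
  v <- df[[variable]]
  y <- df[[outcome]]
  keep <- !(is.na(v) | is.na(y))
  n_dropped <- sum(!keep)
  tab <- table(factor(v[keep]), factor(y[keep]))
  if (nrow(tab) < 2L) {
    stop(sprintf("variable `%s` is constant: degenerate table", variable),
         call. = FALSE)
  }
  if (ncol(tab) < 2L) {
    stop(sprintf("outcome `%s` is constant: degenerate table", outcome),
         call. = FALSE)
  }
  contingency_table(unclass(tab), rownames(tab), colnames(tab),
                    n_dropped = n_dropped)
}

#' Create a contingency table from raw counts
#'
#' @param counts An r x c matrix of nonnegative integer counts (r, c >= 2).
#' @param row_labels,col_labels Optional dimension labels.
#' @param n_dropped Number of complete-case-dropped rows (bookkeeping).
#' @return A `contingency_table`.
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL,
                              n_dropped = 0L) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(counts) < 1) stop("grand total must be >= 1", call. = FALSE)
  structure(list(
    counts = matrix(as.numeric(counts), nrow(counts), ncol(counts)),
    row_labels = row_labels %||% paste0("r", seq_len(nrow(counts))),
    col_labels = col_labels %||% paste0("c", seq_len(ncol(counts))),
    n_dropped = as.integer(n_dropped)
  ), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- x$counts
  dimnames(m) <- list(x$row_labels, x$col_labels)
  print(m)
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' The uncorrected Pearson statistic `sum((O - E)^2 / E)` with expected
#' counts from the row/column margins, `df = (r-1)(c-1)`, and the upper-tail
#' chi-square p-value. No continuity correction is applied: for 2 x 2 tables
#' of epidemiological screening counts this is the convention that matches
#' published contingency statistics for this cohort.
#'
#' @param table A `contingency_table` (or plain count matrix).
#' @return A list with `statistic`, `df`, `p_value`, and `expected`.
#' @export
pearson_chi_square <- function(table) {
  if (!inherits(table, "contingency_table")) table <- contingency_table(table)
  counts <- table$counts
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column margin: statistic undefined", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic),
       df = unname(ct$parameter),
       p_value = unname(ct$p.value),
       expected = ct$expected)
}

as_cohort_df <- function(data) {
  if (inherits(data, c("synthetic_cohort", "cohort"))) {
    df <- as.data.frame(data$X)
    df$treatment <- data$t
    df$outcome <- data$y_obs
    df
  } else {
    as.data.frame(data)
  }
}

#' Chi-square association screen over many variables
#'
#' Tabulates each listed variable against the outcome and computes the
#' uncorrected Pearson chi-square, mirroring a published-style screening
#' table (variable, per-level counts by outcome, statistic, df, p-value).
#'
#' @param data A cohort or data.frame.
#' @param variables Character vector of columns to screen (default: all
#'   except the outcome and treatment columns).
#' @param outcome Outcome column name.
#' @return A data.frame with one row per variable, plus an attribute
#'   `"tables"` holding the underlying `contingency_table`s.
#' @export
association_screen <- function(data, variables = NULL, outcome = "outcome") {
  df <- as_cohort_df(data)
  if (is.null(variables)) {
    variables <- setdiff(names(df), c(outcome, "treatment"))
  }
  tabs <- list()
  rows <- lapply(variables, function(v) {
    tab <- tryCatch(build_contingency(df, v, outcome), error = function(e) NULL)
    if (is.null(tab)) {
      return(data.frame(variable = v, levels = NA_integer_, n = NA_real_,
                        statistic = NA_real_, df = NA_integer_,
                        p_value = NA_real_))
    }
    tabs[[v]] <<- tab
    res <- pearson_chi_square(tab)
    data.frame(variable = v, levels = nrow(tab$counts), n = sum(tab$counts),
               statistic = res$statistic, df = res$df, p_value = res$p_value)
  })
  out <- do.call(rbind, rows)
  attr(out, "tables") <- tabs
  out
}

#' Write an association screening report to CSV
#'
#' @param screen Result of [association_screen()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_association_report <- function(screen, path) {
  write.csv(screen, path, row.names = FALSE)
  invisible(path)
}
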