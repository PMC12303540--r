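# Group comparison layer: Mann-Whitney U tests per task and parameter,
# demographics summary, and headline effect sizes.

#' Mann-Whitney U test
#'
#' U is the number of (x, y) pairs with x below y plus half the ties; the
#' reported statistic is min(U, n1*n2 - U). The two-sided p-value is exact
#' (full enumeration of the rank distribution) when the smaller sample has
#' at most 8 observations and there are no ties; otherwise the normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `U`, `p`, and `method` (`"exact"` or
#'   `"normal-approximation"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("degenerate input: empty sample")
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))                      # midranks
  r1 <- sum(r[seq_len(n1)])
  # U for x: pairs with x_i < y_j (+ half ties) = n1*n2 + n1(n1+1)/2 - R1
  u_x <- n1 * n2 + n1 * (n1 + 1) / 2 - r1
  u <- min(u_x, n1 * n2 - u_x)
  ties <- any(duplicated(c(x, y)))
  if (min(n1, n2) <= 8 && !ties) {
    combos <- utils::combn(n1 + n2, n1)
    rk <- rank(c(x, y))
    all_u <- n1 * n2 + n1 * (n1 + 1) / 2 -
      apply(combos, 2L, function(idx) sum(rk[idx]))
    # folding U to min(U, n1*n2 - U) merges the two tails, so the two-sided
    # p-value is the plain tail probability of the folded statistic
    all_u <- pmin(all_u, n1 * n2 - all_u)
    p <- min(1, sum(all_u <= u + 1e-9) / ncol(combos))
    list(U = u, p = p, method = "exact")
  } else {
    N <- n1 + n2
    tab <- table(c(x, y))
    tie_term <- sum(tab^3 - tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = u, p = 1, method = "normal-approximation"))
    z <- (abs(u_x - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
    z <- max(0, z)
    list(U = u, p = min(1, 2 * stats::pnorm(-z)), method = "normal-approximation")
  }
}

#' Compare gait parameters between groups
#'
#' Repetitions are first averaged within participant and task (the analysis
#' unit is the participant), then each (task, parameter) cell is tested with
#' [mann_whitney_u()]. No multiplicity adjustment gates significance; a
#' Benjamini-Hochberg column is appended as supplementary information only.
#'
#' @param table data frame with columns `participant`, `group` (control /
#'   csvd), `task` (normal / dual / fast), `repetition`, and numeric feature
#'   columns.
#' @param parameters character vector of feature columns to test; default:
#'   every numeric column that is not a key or demographic.
#' @return data frame of class `comparison_table` with one row per (task,
#'   parameter): group means and SDs, `U`, `p`, `method`, `p_bh`.
#' @export
compare_groups <- function(table, parameters = NULL) {
  need <- c("participant", "group", "task")
  if (!all(need %in% names(table)))
    stop("design error: need columns ", paste(need, collapse = ", "))
  groups <- unique(table$group)
  if (!all(c("control", "csvd") %in% groups))
    stop("design error: both groups (control, csvd) must be present")
  if (is.null(parameters)) {
    skip <- c("participant", "group", "task", "repetition", "age", "sex",
              "height", "weight", "bmi")
    parameters <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                          skip)
  }
  for (g in c("control", "csvd"))
    if (length(unique(table$participant[table$group == g])) < 2L)
      stop("design error: fewer than 2 participants in group ", g)

  rows <- list()
  for (task in unique(table$task)) {
    sub <- table[table$task == task, , drop = FALSE]
    for (par in parameters) {
      agg <- stats::aggregate(sub[[par]],
                              by = list(participant = sub$participant,
                                        group = sub$group),
                              FUN = mean, na.rm = TRUE)
      xc <- agg$x[agg$group == "control"]
      xd <- agg$x[agg$group == "csvd"]
      xc <- xc[is.finite(xc)]; xd <- xd[is.finite(xd)]
      if (length(xc) < 2L || length(xd) < 2L) next
      mw <- mann_whitney_u(xc, xd)
      rows[[length(rows) + 1L]] <- data.frame(
        task = task, parameter = par,
        control_mean = mean(xc), control_sd = stats::sd(xc),
        csvd_mean = mean(xd), csvd_sd = stats::sd(xd),
        U = mw$U, p = mw$p, method = mw$method,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Demographics summary table
#'
#' Per continuous variable (age, height, weight, BMI): group means and SDs
#' with a Welch two-sample t-test p-value; for sex, counts and a chi-square
#' test.
#'
#' @param table feature table with one row per participant (or more; the
#'   first row per participant is used) and demographic columns.
#' @return data frame with variable, group summaries and p-values.
#' @export
demographics_table <- function(table) {
  first <- table[!duplicated(table$participant), , drop = FALSE]
  rows <- list()
  for (v in intersect(c("age", "height", "weight", "bmi"), names(first))) {
    xc <- first[[v]][first$group == "control"]
    xd <- first[[v]][first$group == "csvd"]
    p <- tryCatch(stats::t.test(xc, xd)$p.value, error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, control_mean = mean(xc), control_sd = stats::sd(xc),
      csvd_mean = mean(xd), csvd_sd = stats::sd(xd), p = p,
      stringsAsFactors = FALSE)
  }
  if ("sex" %in% names(first)) {
    tab <- table(first$group, first$sex)
    p <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                  error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "sex (fraction male)",
      control_mean = mean(first$sex[first$group == "control"] == "male"),
      control_sd = NA_real_,
      csvd_mean = mean(first$sex[first$group == "csvd"] == "male"),
      csvd_sd = NA_real_, p = p, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Headline effect summary
#'
#' Per task: the relative step-regularity deficit of the CSVD-like group,
#' (control - csvd) / control, and the head-angle gaps (control mean minus
#' csvd mean, degrees) for head-to-body and head-to-ground.
#'
#' @param comparison a `comparison_table` from [compare_groups()].
#' @return data frame with task, regularity_rel_diff (fraction),
#'   head_to_body_gap_deg, head_to_ground_gap_deg.
#' @export
headline_effects <- function(comparison) {
  get_row <- function(task, par) {
    r <- comparison[comparison$task == task & comparison$parameter == par, ]
    if (!nrow(r)) NULL else r[1L, ]
  }
  tasks <- unique(comparison$task)
  if (!any(comparison$parameter == "step_regularity") &&
      !any(comparison$parameter %in% c("head_to_body_mean", "head_to_ground_mean")))
    stop("design error: comparison lacks regularity and head-angle rows")
  rows <- lapply(tasks, function(task) {
    reg <- get_row(task, "step_regularity")
    hb <- get_row(task, "head_to_body_mean")
    hg <- get_row(task, "head_to_ground_mean")
    data.frame(
      task = task,
      regularity_rel_diff = if (is.null(reg)) NA_real_ else
        (reg$control_mean - reg$csvd_mean) / reg$control_mean,
      head_to_body_gap_deg = if (is.null(hb)) NA_real_ else
        hb$control_mean - hb$csvd_mean,
      head_to_ground_gap_deg = if (is.null(hg)) NA_real_ else
        hg$control_mean - hg$csvd_mean,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
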