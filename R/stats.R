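# Group comparison statistics: t-test, one-way ANOVA, repeated-measures
# ANOVA, and the treatment screen report.

group_descriptives <- function(y, g) {
  do.call(rbind, lapply(levels(g), function(l) {
    v <- y[g == l]
    data.frame(group = l, n = length(v), mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
  }))
}

#' Compare groups with the study's statistical tests
#'
#' Pooled-variance two-sample t-test, one-way ANOVA, or subject-blocked
#' repeated-measures ANOVA, with exact degrees of freedom. Convention for
#' degenerate inputs: if every group has zero within-group variance and all
#' group means are identical, the statistic is 0 and `p = 1`.
#'
#' @param table data.frame holding the response and factor columns.
#' @param response Name of the numeric response column.
#' @param factor Name of the grouping column.
#' @param design `"t_test"`, `"one_way"` or `"rm_anova"`.
#' @param subject Name of the subject-identifier column (required for
#'   `rm_anova`).
#' @param alternative Alternative hypothesis for the t-test (two-sided by
#'   default; one-sided alternatives refer to the first factor level minus
#'   the second).
#' @return Object of class `mito_test`: list with `test`, `statistic`, `df`,
#'   `p_value` and `descriptives` (n, mean, SEM per group).
#' @export
compare_groups <- function(table, response, factor,
                           design = c("t_test", "one_way", "rm_anova"),
                           subject = NULL,
                           alternative = c("two.sided", "less", "greater")) {
  design <- match.arg(design)
  alternative <- match.arg(alternative)
  y <- table[[response]]
  g <- droplevels(base::factor(table[[factor]]))
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  ns <- tabulate(g)
  if (any(ns < 2)) stop("every group needs n >= 2")
  desc <- group_descriptives(y, g)
  wvar <- tapply(y, g, stats::var)
  degenerate <- all(wvar == 0)
  if (degenerate && length(unique(tapply(y, g, mean))) == 1) {
    return(structure(list(test = design, statistic = 0,
                          df = c(NA_real_, NA_real_), p_value = 1,
                          descriptives = desc), class = "mito_test"))
  }
  if (design == "t_test") {
    if (nlevels(g) != 2) stop("t_test requires exactly 2 groups")
    if (degenerate) {
      res <- list(statistic = Inf, df = sum(ns) - 2, p_value = 0)
    } else {
      tt <- stats::t.test(y ~ g, var.equal = TRUE, alternative = alternative)
      res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                  p_value = tt$p.value)
    }
    out <- list(test = "t_test", statistic = res$statistic,
                df = res$df, p_value = res$p_value, descriptives = desc)
  } else if (design == "one_way") {
    s <- summary(stats::aov(y ~ g))[[1]]
    out <- list(test = "one_way", statistic = s[1, "F value"],
                df = c(s[1, "Df"], s[2, "Df"]), p_value = s[1, "Pr(>F)"],
                descriptives = desc)
  } else {
    if (is.null(subject)) stop("rm_anova requires a subject column")
    s_id <- base::factor(table[[subject]][ok])
    fit <- stats::aov(y ~ g + Error(s_id / g))
    strata <- summary(fit)
    within <- strata[[length(strata)]][[1]]
    out <- list(test = "rm_anova", statistic = within[1, "F value"],
                df = c(within[1, "Df"], within[2, "Df"]),
                p_value = within[1, "Pr(>F)"], descriptives = desc)
  }
  structure(out, class = "mito_test")
}

#' @export
print.mito_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, df = (%s), p = %.4g\n", x$test,
              x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p_value))
  print(x$descriptives, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Treatment screen over compartments, states and metrics
#'
#' Compares a control and a treatment condition per (compartment, state,
#' metric) cell-level measurement with two-sided pooled-variance t-tests,
#' reporting effect direction, statistic, degrees of freedom and p-value.
#' When both microglia and neurons are present, a whole-cell
#' microglia-versus-neuron contrast of the overall percent change is added
#' per condition. Raw p-values are reported (no multiple-testing correction
#' by default, matching the screening convention); set `p_adjust = "BH"` for
#' Benjamini-Hochberg adjusted significance calls.
#'
#' @param metrics Long-format metrics table from [analyze_cohort()] covering
#'   at least the two conditions.
#' @param control,treatment Condition tokens to compare.
#' @param alpha Significance threshold.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Object of class `screen_report`: list with `comparisons` (one row
#'   per compartment x state x metric), optional `class_contrast`, and the
#'   settings. Comparisons where either group has fewer than 2 cells are
#'   recorded with `NA` statistics and a warning.
#' @export
screen_report <- function(metrics, control, treatment, alpha = 0.05,
                          p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  sub <- metrics[metrics$condition %in% c(control, treatment), ]
  if (!nrow(sub)) stop("metrics contain neither condition")
  mg <- sub[sub$cell_class == "microglia" | !"neuron" %in% sub$cell_class, ]
  if (!nrow(mg)) mg <- sub
  keys <- unique(mg[, c("compartment", "state", "metric")])
  rows <- list(); skipped <- character(0)
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    d <- mg[mg$compartment == k$compartment & mg$state == k$state &
              mg$metric == k$metric, ]
    nc <- sum(d$condition == control); ntr <- sum(d$condition == treatment)
    row <- data.frame(compartment = k$compartment, state = k$state,
                      metric = k$metric, n_control = nc, n_treatment = ntr,
                      mean_control = NA_real_, mean_treatment = NA_real_,
                      direction = NA_real_, statistic = NA_real_,
                      df = NA_real_, p_value = NA_real_)
    if (nc >= 2 && ntr >= 2) {
      d$condition <- base::factor(d$condition, levels = c(control, treatment))
      tt <- compare_groups(d, "value", "condition", "t_test")
      mc <- mean(d$value[d$condition == control])
      mt <- mean(d$value[d$condition == treatment])
      row$mean_control <- mc; row$mean_treatment <- mt
      row$direction <- sign(mt - mc)
      row$statistic <- tt$statistic; row$df <- tt$df[1]
      row$p_value <- tt$p_value
    } else {
      skipped <- c(skipped, sprintf("%s/%s/%s (n = %d vs %d)", k$compartment,
                                    k$state, k$metric, nc, ntr))
    }
    rows[[i]] <- row
  }
  comparisons <- do.call(rbind, rows)
  padj <- if (p_adjust == "BH")
    stats::p.adjust(comparisons$p_value, "BH") else comparisons$p_value
  comparisons$significant <- !is.na(padj) & padj <= alpha
  if (length(skipped))
    warning("comparisons skipped (n < 2): ", paste(skipped, collapse = "; "))

  contrast <- NULL
  if (all(c("microglia", "neuron") %in% sub$cell_class)) {
    crows <- list()
    for (cond in unique(sub$condition)) {
      d <- sub[sub$condition == cond & sub$state == "overall" &
                 sub$metric == "pct_change" &
                 ((sub$cell_class == "microglia" &
                     sub$compartment == "whole_cell") |
                    (sub$cell_class == "neuron" & sub$compartment == "soma")), ]
      if (length(unique(d$cell_class)) == 2 &&
          all(table(d$cell_class) >= 2)) {
        tt <- compare_groups(d, "value", "cell_class", "t_test")
        crows[[cond]] <- data.frame(
          condition = cond,
          mean_microglia = mean(d$value[d$cell_class == "microglia"]),
          mean_neuron = mean(d$value[d$cell_class == "neuron"]),
          statistic = tt$statistic, df = tt$df[1], p_value = tt$p_value,
          significant = tt$p_value <= alpha)
      }
    }
    if (length(crows)) contrast <- do.call(rbind, crows)
  }
  structure(list(comparisons = comparisons, class_contrast = contrast,
                 control = control, treatment = treatment, alpha = alpha,
                 p_adjust = p_adjust),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>", x$control, "vs", x$treatment, "(alpha =", x$alpha,
      ")\n")
  print(x$comparisons, row.names = FALSE, digits = 4)
  if (!is.null(x$class_contrast)) {
    cat("microglia vs neuron contrast:\n")
    print(x$class_contrast, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write a screen report as JSON, CSV and Markdown
#'
#' @param report A [screen_report()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_screen_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pj <- file.path(dir, "screen_report.json")
  pc <- file.path(dir, "screen_report.csv")
  pm <- file.path(dir, "screen_report.md")
  jsonlite::write_json(unclass(report), pj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  utils::write.csv(report$comparisons, pc, row.names = FALSE)
  md <- c(sprintf("# Screen: %s vs %s (alpha = %g)", report$control,
                  report$treatment, report$alpha), "",
          "| compartment | state | metric | direction | t | df | p | sig |",
          "|---|---|---|---|---|---|---|---|",
          apply(report$comparisons, 1, function(r)
            sprintf("| %s | %s | %s | %s | %s | %s | %s | %s |",
                    r[["compartment"]], r[["state"]], r[["metric"]],
                    r[["direction"]], signif(as.numeric(r[["statistic"]]), 4),
                    r[["df"]], signif(as.numeric(r[["p_value"]]), 4),
                    r[["significant"]])))
  writeLines(md, pm)
  invisible(c(pj, pc, pm))
}
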