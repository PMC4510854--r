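# Group-level statistics: Student's t (paired or unpaired), one-way ANOVA
# with a Games-Howell post hoc (pairwise Welch-type comparisons against the
# studentized range distribution, appropriate under unequal variances), and
# the Kruskal-Wallis rank test. Base R supplies every distribution; the
# Games-Howell procedure itself is implemented here as no installed package
# provides it.

#' Run the standard group tests on a measurement column
#'
#' @param data A data frame.
#' @param value Name of the numeric value column.
#' @param group Name of the grouping column.
#' @param tests Character subset of `c("t", "anova", "games_howell",
#'   "kruskal")`; defaults to everything applicable (t only for 2 groups).
#' @param paired Paired t-test (2 groups, equal n, matched order).
#' @return An object of class `group_test_report`; [tidy()] returns the
#'   test rows (statistic, df, p) and [glance()] the descriptive
#'   means +/- SE per group. Pairwise Games-Howell comparisons sit in
#'   `$pairwise`.
#' @export
run_group_tests <- function(data, value, group,
                            tests = c("t", "anova", "games_howell", "kruskal"),
                            paired = FALSE) {
  v <- data[[value]]
  g <- factor(data[[group]])
  ok <- stats::complete.cases(v, g)
  v <- v[ok]; g <- droplevels(g[ok])
  k <- nlevels(g)
  if (k < 2L) abort("Need at least 2 groups.")
  sizes <- table(g)
  if (any(sizes < 2L)) {
    abort(paste0(
      "Group size < 2: ",
      paste(names(sizes)[sizes < 2L], collapse = ", ")
    ))
  }
  tests <- match.arg(tests, several.ok = TRUE)
  desc <- tibble(
    group = levels(g),
    n_count = as.integer(sizes),
    mean_stat = as.numeric(tapply(v, g, mean)),
    se_stat = as.numeric(tapply(v, g, stats::sd)) / sqrt(as.integer(sizes))
  )
  rows <- list()
  pairwise <- NULL
  if ("t" %in% tests && k == 2L) {
    tt <- stats::t.test(v ~ g, paired = paired, var.equal = FALSE)
    rows[[length(rows) + 1L]] <- tibble(
      test = if (paired) "paired_t" else "welch_t",
      statistic_stat = unname(tt$statistic),
      df_stat = unname(tt$parameter), p_value_p = tt$p.value
    )
  }
  if ("anova" %in% tests && k >= 2L) {
    fit <- stats::aov(v ~ g)
    s <- summary(fit)[[1L]]
    rows[[length(rows) + 1L]] <- tibble(
      test = "anova_f",
      statistic_stat = s[["F value"]][1L],
      df_stat = s[["Df"]][1L], df2_stat = s[["Df"]][2L],
      p_value_p = s[["Pr(>F)"]][1L]
    )
  }
  if ("games_howell" %in% tests && k >= 3L) {
    pairwise <- games_howell(v, g)
  }
  if ("kruskal" %in% tests) {
    kw <- stats::kruskal.test(v ~ g)
    rows[[length(rows) + 1L]] <- tibble(
      test = "kruskal_wallis",
      statistic_stat = unname(kw$statistic),
      df_stat = unname(kw$parameter), p_value_p = kw$p.value
    )
  }
  structure(
    list(
      descriptives = desc,
      tests = bind_rows(rows),
      pairwise = pairwise,
      k_groups = k, paired = paired
    ),
    class = "group_test_report"
  )
}

#' Games-Howell post hoc pairwise comparisons
#'
#' For every pair of groups: Welch-type statistic
#' `t = |m_i - m_j| / sqrt(s_i^2/n_i + s_j^2/n_j)` with Welch-Satterthwaite
#' degrees of freedom, referred to the studentized range distribution with
#' `k` means (`p = P(q >= t * sqrt(2))`). Robust to unequal variances and
#' group sizes.
#'
#' @param values Numeric vector.
#' @param groups Factor of the same length.
#' @param conf_level Confidence level for the interval on the difference.
#' @return Tibble: `group1`, `group2`, `diff_stat`, `se_stat`, `df_stat`,
#'   `statistic_stat` (q value), `p_value_p`, `conf_low_stat`,
#'   `conf_high_stat`.
#' @export
games_howell <- function(values, groups, conf_level = 0.95) {
  g <- droplevels(factor(groups))
  k <- nlevels(g)
  if (k < 2L) abort("Need at least 2 groups.")
  m <- tapply(values, g, mean)
  s2 <- tapply(values, g, stats::var)
  n <- tapply(values, g, length)
  pairs <- utils::combn(levels(g), 2L)
  out <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    se2 <- s2[[i]] / n[[i]] + s2[[j]] / n[[j]]
    se <- sqrt(se2)
    df <- se2^2 / ((s2[[i]] / n[[i]])^2 / (n[[i]] - 1) +
      (s2[[j]] / n[[j]])^2 / (n[[j]] - 1))
    diff <- m[[i]] - m[[j]]
    q <- abs(diff) / se * sqrt(2)
    p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    qcrit <- stats::qtukey(conf_level, nmeans = k, df = df)
    tibble(
      group1 = i, group2 = j,
      diff_stat = diff, se_stat = se, df_stat = df,
      statistic_stat = q, p_value_p = p,
      conf_low_stat = diff - qcrit * se / sqrt(2),
      conf_high_stat = diff + qcrit * se / sqrt(2)
    )
  })
  bind_rows(out)
}

#' @export
print.group_test_report <- function(x, ...) {
  cat("<group_test_report>", x$k_groups, "groups\n")
  print(x$descriptives)
  print(x$tests)
  if (!is.null(x$pairwise)) {
    cat("Games-Howell pairwise:\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' @rdname run_group_tests
#' @param x A `group_test_report`.
#' @param ... Unused.
#' @export
tidy.group_test_report <- function(x, ...) {
  main <- x$tests
  if (!is.null(x$pairwise)) {
    pw <- x$pairwise |>
      mutate(test = paste0("games_howell:", .data$group1, "-", .data$group2)) |>
      select("test", "statistic_stat", "df_stat", "p_value_p")
    main <- bind_rows(main, pw)
  }
  main
}

#' @rdname run_group_tests
#' @export
glance.group_test_report <- function(x, ...) {
  x$descriptives
}
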