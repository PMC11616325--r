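#' Two-sided Mann-Whitney test
#'
#' Unpaired, two-tailed Mann-Whitney (Wilcoxon rank-sum) comparison of two
#' groups. The exact null distribution is used when both groups have at
#' most 10 observations and there are no ties; otherwise the normal
#' approximation with tie correction is used. Two identical
#' (zero-spread) groups return p = 1.
#'
#' @param group_a,group_b Numeric vectors, each with at least 3 values.
#' @param variable,age_weeks,family_id Optional labels carried into the
#'   result.
#' @return A one-row tibble: `variable`, `age_weeks`, `test_name`,
#'   `statistic` (U of the first group), `p_raw`, `family_id`.
#' @export
mann_whitney <- function(group_a, group_b, variable = NA_character_,
                         age_weeks = NA_real_, family_id = NA_character_) {
  if (length(group_a) < 3L || length(group_b) < 3L)
    abort("Each group needs at least 3 observations.")
  degenerate <- length(unique(c(group_a, group_b))) == 1L
  if (degenerate) {
    u <- length(group_a) * length(group_b) / 2
    p <- 1
  } else {
    ties <- any(duplicated(c(group_a, group_b)))
    use_exact <- length(group_a) <= 10L && length(group_b) <= 10L && !ties
    ht <- suppressWarnings(
      wilcox.test(group_a, group_b, exact = use_exact, correct = !use_exact)
    )
    u <- unname(ht$statistic)
    p <- min(ht$p.value, 1)
  }
  tibble::tibble(variable = variable, age_weeks = age_weeks,
                 test_name = "mann_whitney", statistic = u, p_raw = p,
                 family_id = family_id)
}

#' Welch's two-sample t-test
#'
#' Two-sided t-test with the Welch-Satterthwaite degrees of freedom,
#' appropriate for unequal group variances.
#'
#' @inheritParams mann_whitney
#' @return A one-row tibble: `variable`, `age_weeks`, `test_name`,
#'   `statistic` (t), `df`, `p_raw`, `family_id`. Both groups having zero
#'   variance yields `NA` with a warning.
#' @export
welch_t <- function(group_a, group_b, variable = NA_character_,
                    age_weeks = NA_real_, family_id = NA_character_) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    abort("Each group needs at least 2 observations.")
  if (var(group_a) == 0 && var(group_b) == 0) {
    warn("Both groups have zero variance; Welch's t is undefined.")
    return(tibble::tibble(variable = variable, age_weeks = age_weeks,
                          test_name = "welch_t", statistic = NA_real_,
                          df = NA_real_, p_raw = NA_real_,
                          family_id = family_id))
  }
  ht <- t.test(group_a, group_b, var.equal = FALSE)
  tibble::tibble(variable = variable, age_weeks = age_weeks,
                 test_name = "welch_t", statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_raw = ht$p.value,
                 family_id = family_id)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforced, and the rejection
#' set at the desired false-discovery rate.
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @param q Desired FDR (default 0.05).
#' @return A tibble with `p_raw`, `p_adjusted`, `reject`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    abort("p-values must lie in [0, 1].")
  adj <- p.adjust(p_values, method = "BH")
  tibble::tibble(p_raw = p_values, p_adjusted = adj, reject = adj <= q)
}

#' Two-way ANOVA with Type III sums of squares
#'
#' Unbalanced two-way ANOVA of a response on genotype, age and their
#' interaction, using sum-to-zero contrasts and Type III (marginal) sums of
#' squares, as appropriate when cell sizes differ.
#'
#' @param data Data frame containing the response and the two factors.
#' @param value,genotype,age Column names (strings) of the response and
#'   factors.
#' @return A tibble with rows `interaction`, `time point`,
#'   `genetic background`, `residual`, `total` and columns `ss`, `df`,
#'   `ms`, `f`, `p`. The total row is the corrected total (Type III source
#'   SS need not sum to it on unbalanced data).
#' @export
two_way_anova <- function(data, value = "water_delivery",
                          genotype = "genotype", age = "age_weeks") {
  df <- tibble::tibble(
    y = data[[value]],
    g = factor(data[[genotype]]),
    a = factor(data[[age]])
  )
  df <- df[complete.cases(df), ]
  cells <- table(df$g, df$a)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("Empty design cell: genotype '%s' at age '%s'.",
                  rownames(cells)[empty[1]], colnames(cells)[empty[2]]),
          class = "bcsfbasl_structure_error")
  }
  fit <- lm(y ~ g * a, data = df,
            contrasts = list(g = "contr.sum", a = "contr.sum"))
  a3 <- tryCatch(car::Anova(fit, type = "III"),
                 error = function(e) NULL)
  if (!is.null(a3)) {
    pick <- function(row) {
      c(ss = a3[row, "Sum Sq"], df = a3[row, "Df"],
        f = a3[row, "F value"], p = a3[row, "Pr(>F)"])
    }
    src <- rbind(
      interaction = pick("g:a"),
      `time point` = pick("a"),
      `genetic background` = pick("g"),
      residual = pick("Residuals")
    )
  } else {
    # degenerate case (e.g. zero residual variance): marginal SS by
    # explicit full/reduced column drops on the sum-contrast model matrix
    mm <- model.matrix(fit)
    rss <- function(cols) sum(lm.fit(mm[, cols, drop = FALSE],
                                     df$y)$residuals^2)
    full_rss <- rss(seq_len(ncol(mm)))
    df_res <- nrow(df) - ncol(mm)
    ss_of <- function(pattern) {
      cols <- grep(pattern, colnames(mm))
      rss(setdiff(seq_len(ncol(mm)), cols)) - full_rss
    }
    mk <- function(ss, dfx) {
      fval <- (ss / dfx) / (full_rss / df_res)
      c(ss = ss, df = dfx,
        f = fval, p = stats::pf(fval, dfx, df_res, lower.tail = FALSE))
    }
    ng <- nlevels(df$g) - 1L
    na_ <- nlevels(df$a) - 1L
    src <- rbind(
      interaction = mk(ss_of(":"), ng * na_),
      `time point` = mk(ss_of("^a\\d+$"), na_),
      `genetic background` = mk(ss_of("^g\\d+$"), ng),
      residual = c(ss = full_rss, df = df_res, f = NA, p = NA)
    )
  }
  total_ss <- sum((df$y - mean(df$y))^2)
  out <- tibble::tibble(
    source = c(rownames(src), "total"),
    ss = as.numeric(c(src[, "ss"], total_ss)),
    df = as.numeric(c(src[, "df"], nrow(df) - 1)),
    f = as.numeric(c(src[, "f"], NA_real_)),
    p = as.numeric(c(src[, "p"], NA_real_))
  )
  out$ms <- out$ss / out$df
  out$ms[out$source == "total"] <- NA_real_
  out[, c("source", "ss", "df", "ms", "f", "p")]
}

#' Two-way ANOVA from cell summary statistics
#'
#' Computes the same Type III table as [two_way_anova()] from per-cell
#' sufficient statistics (mean, SEM, n). A surrogate dataset realising each
#' cell's exact mean and standard deviation is constructed and analysed;
#' since the ANOVA depends on the data only through those sufficient
#' statistics, the result is identical to the subject-level analysis.
#'
#' @param summaries Data frame with columns `genotype`, `age_weeks`,
#'   `mean`, `sem`, `n` (one row per design cell, all n >= 2).
#' @return A tibble in the format of [two_way_anova()].
#' @export
anova_from_summary <- function(summaries) {
  if (any(summaries$n < 2))
    abort("Every cell needs n >= 2 to reconstruct within-cell variance.")
  surrogate <- summaries |>
    dplyr::mutate(.cell = dplyr::row_number()) |>
    dplyr::group_by(.data$.cell) |>
    dplyr::reframe(
      genotype = .data$genotype,
      age_weeks = .data$age_weeks,
      value = cell_surrogate(.data$mean, .data$sem, .data$n)
    )
  two_way_anova(surrogate, value = "value")
}

# n values with exactly the requested mean and sample SD (= sem * sqrt(n)).
cell_surrogate <- function(mean, sem, n) {
  u <- seq_len(n) - (n + 1) / 2
  u <- u / sd(u)
  mean + sem * sqrt(n) * u
}

#' Sidak-adjusted pairwise cell comparisons
#'
#' Post-hoc pairwise comparisons of design-cell means after a two-way
#' ANOVA, using the pooled residual mean square, with Sidak's correction
#' \eqn{p_{adj} = 1 - (1 - p)^m} over the m comparisons. The default
#' comparison set is every between-genotype pair at the same age plus every
#' within-genotype pair of ages.
#'
#' @inheritParams two_way_anova
#' @param comparisons Optional two-column data frame of cell labels
#'   (`"genotype:age"`) to compare; `NULL` for the default set.
#' @return A tibble with one row per comparison: the two cells, mean
#'   difference, t statistic, residual df, raw and Sidak-adjusted p.
#' @export
sidak_posthoc <- function(data, value = "water_delivery",
                          genotype = "genotype", age = "age_weeks",
                          comparisons = NULL) {
  df <- tibble::tibble(
    y = data[[value]],
    g = factor(data[[genotype]]),
    a = factor(data[[age]])
  )
  df <- df[complete.cases(df), ]
  df$cell <- interaction(df$g, df$a, sep = ":")
  fit <- lm(y ~ cell, data = df)
  ms_res <- sum(stats::residuals(fit)^2) / fit$df.residual
  stats_by_cell <- df |>
    dplyr::group_by(.data$g, .data$a, .data$cell) |>
    dplyr::summarise(m = mean(.data$y), n = dplyr::n(), .groups = "drop")

  if (is.null(comparisons)) {
    same_age <- stats_by_cell |>
      dplyr::group_by(.data$a) |>
      dplyr::reframe(pairs_of(.data$cell))
    within_geno <- stats_by_cell |>
      dplyr::group_by(.data$g) |>
      dplyr::reframe(pairs_of(.data$cell))
    comparisons <- dplyr::bind_rows(same_age[c("cell_1", "cell_2")],
                                    within_geno[c("cell_1", "cell_2")])
  }
  m <- nrow(comparisons)
  if (m == 0L)
    return(tibble::tibble(cell_1 = character(), cell_2 = character(),
                          diff = numeric(), statistic = numeric(),
                          df = numeric(), p_raw = numeric(),
                          p_adjusted = numeric()))
  lk <- setNames(seq_len(nrow(stats_by_cell)),
                 as.character(stats_by_cell$cell))
  purrr::pmap_dfr(comparisons, function(cell_1, cell_2) {
    i <- lk[[as.character(cell_1)]]; j <- lk[[as.character(cell_2)]]
    d <- stats_by_cell$m[i] - stats_by_cell$m[j]
    se <- sqrt(ms_res * (1 / stats_by_cell$n[i] + 1 / stats_by_cell$n[j]))
    tval <- d / se
    p <- 2 * pt(-abs(tval), fit$df.residual)
    tibble::tibble(cell_1 = as.character(cell_1),
                   cell_2 = as.character(cell_2),
                   diff = d, statistic = tval, df = fit$df.residual,
                   p_raw = p, p_adjusted = sidak_adjust(p, m))
  })
}

#' Sidak adjustment
#'
#' @param p Raw p-value(s).
#' @param m Number of comparisons in the family.
#' @return Adjusted p-value(s) \eqn{1 - (1-p)^m}, capped at 1.
#' @export
sidak_adjust <- function(p, m) pmin(1 - (1 - p)^m, 1)

pairs_of <- function(cells) {
  cells <- as.character(cells)
  if (length(cells) < 2L)
    return(tibble::tibble(cell_1 = character(), cell_2 = character()))
  cb <- utils::combn(cells, 2L)
  tibble::tibble(cell_1 = cb[1, ], cell_2 = cb[2, ])
}

#' Group comparisons across ages with FDR control
#'
#' The study's comparison layer: for each variable and time point, compare
#' control and 3xTg groups with the configured test (Mann-Whitney for MRI
#' variables, Welch's t for behaviour), then adjust p-values by
#' Benjamini-Hochberg separately within each family (all MRI comparisons
#' form one family, behaviour comparisons another).
#'
#' @param records Subject records (see [quantify_cohort()]); excluded
#'   subjects are dropped.
#' @param variables Named character vector mapping variable column names to
#'   `"mann_whitney"` or `"welch_t"`; defaults to Mann-Whitney for the MRI
#'   variables present and Welch for `n_entries`/`sa_score`.
#' @param families Named character vector mapping variable names to family
#'   ids; defaults to `"mri"` for MRI variables and `"behaviour"` for
#'   behaviour scores.
#' @param q Desired FDR within each family.
#' @param reference Genotype label taken as group A (default "control").
#' @return A tibble of comparison results with `p_adjusted` and `reject`.
#' @export
compare_groups <- function(records, variables = NULL, families = NULL,
                           q = 0.05, reference = "control") {
  if ("excluded" %in% names(records))
    records <- dplyr::filter(records, !.data$excluded)
  if (is.null(variables)) {
    mri <- intersect(c("water_delivery", "t1_csf", "ventricular_volume",
                       grep("^(cbf|t1)_", names(records), value = TRUE)),
                     names(records))
    beh <- intersect(c("n_entries", "sa_score"), names(records))
    variables <- c(setNames(rep("mann_whitney", length(mri)), mri),
                   setNames(rep("welch_t", length(beh)), beh))
  }
  if (is.null(families)) {
    families <- setNames(
      ifelse(variables == "welch_t", "behaviour", "mri"),
      names(variables))
  }
  ages <- sort(unique(records$age_weeks))
  res <- purrr::map_dfr(names(variables), function(v) {
    purrr::map_dfr(ages, function(aw) {
      sub <- dplyr::filter(records, .data$age_weeks == aw)
      ga <- sub[[v]][sub$genotype == reference]
      gb <- sub[[v]][sub$genotype != reference]
      ga <- ga[is.finite(ga)]; gb <- gb[is.finite(gb)]
      fn <- if (variables[[v]] == "mann_whitney") mann_whitney else welch_t
      fn(ga, gb, variable = v, age_weeks = aw,
         family_id = families[[v]])
    })
  })
  res |>
    dplyr::group_by(.data$family_id) |>
    dplyr::mutate(
      p_adjusted = p.adjust(.data$p_raw, method = "BH"),
      reject = .data$p_adjusted <= q
    ) |>
    dplyr::ungroup()
}
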