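test_that("Mann-Whitney exact branch matches full enumeration", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_raw, 0.1)
  expect_equal(res$statistic, 0)
  set.seed(61)
  for (na in 3:6) for (nb in 3:6) {
    a <- runif(na); b <- runif(nb) + 0.3
    expect_equal(mann_whitney(a, b)$p_raw, mw_enum_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney handles degenerate and tied data", {
  expect_equal(mann_whitney(rep(2, 5), rep(2, 5))$p_raw, 1)
  # ties force the corrected normal approximation; p stays in (0, 1]
  p <- mann_whitney(c(1, 1, 2, 3), c(2, 3, 3, 4))$p_raw
  expect_gt(p, 0); expect_lte(p, 1)
  expect_error(mann_whitney(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("Welch's t matches the textbook formula and is antisymmetric", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  res <- welch_t(a, b)
  se2 <- var(a) / 4 + var(b) / 4
  t_ref <- (mean(a) - mean(b)) / sqrt(se2)
  df_ref <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  p_ref <- 2 * pt(-abs(t_ref), df_ref)
  expect_equal(res$statistic, t_ref)
  expect_equal(res$df, df_ref)
  expect_equal(res$p_raw, p_ref)
  rev <- welch_t(b, a)
  expect_equal(rev$statistic, -res$statistic)
  expect_equal(rev$p_raw, res$p_raw)
  eq <- welch_t(c(1, 2, 3), c(2, 1, 3))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_raw, 1)
  expect_warning(zz <- welch_t(c(1, 1), c(2, 2)), "zero variance")
  expect_true(is.na(zz$p_raw))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(0.03)$p_adjusted, 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$p_adjusted, rep(0.04, 4))
  set.seed(67)
  for (i in 1:20) {
    p <- runif(sample(3:20, 1))^sample(1:3, 1)
    out <- bh_fdr(p, q = 0.05)
    ref <- bh_def(p, q = 0.05)
    expect_equal(out$p_adjusted, ref$adjusted)
    expect_equal(out$reject, ref$reject)
    expect_true(all(out$p_adjusted >= out$p_raw))
  }
})

test_that("BH at q = 0.05 controls the empirical FDR on null simulations", {
  set.seed(71)
  any_rej <- replicate(2000, any(bh_fdr(runif(16), q = 0.05)$reject))
  # all-null FDR equals the probability of any rejection
  fdr <- mean(any_rej)
  expect_lte(fdr, 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))
})

test_that("unbalanced Type III ANOVA reproduces the design degrees of freedom", {
  set.seed(73)
  n_cells <- c(10, 7, 7, 7, 10, 10, 10, 10)
  d <- tibble::tibble(
    genotype = rep(rep(c("control", "3xTg"), each = 4), n_cells),
    age_weeks = rep(rep(c(8, 14, 20, 32), 2), n_cells),
    water_delivery = rnorm(71, 1, 0.25)
  )
  tab <- two_way_anova(d)
  expect_equal(tab$df[tab$source == "genetic background"], 1)
  expect_equal(tab$df[tab$source == "time point"], 3)
  expect_equal(tab$df[tab$source == "interaction"], 3)
  expect_equal(tab$df[tab$source == "residual"], 63)
  expect_equal(tab$df[tab$source == "total"], 70)
  expect_equal(sum(tab$df[tab$source != "total"]), 70)
})

test_that("Type III sums of squares match explicit model-comparison refits", {
  set.seed(79)
  for (i in 1:5) {
    n_cells <- sample(3:9, 8, replace = TRUE)
    g <- rep(rep(c("c", "t"), each = 4), n_cells)
    a <- rep(rep(c(8, 14, 20, 32), 2), n_cells)
    y <- rnorm(length(g), mean = as.numeric(g == "t") * 0.5 + a / 40)
    d <- tibble::tibble(genotype = g, age_weeks = a, water_delivery = y)
    tab <- two_way_anova(d)
    ref <- type3_ss_refit(y, g, a)
    expect_equal(tab$ss[tab$source == "genetic background"], ref$genotype,
                 tolerance = 1e-9)
    expect_equal(tab$ss[tab$source == "time point"], ref$age,
                 tolerance = 1e-9)
    expect_equal(tab$ss[tab$source == "interaction"], ref$interaction,
                 tolerance = 1e-9)
    expect_equal(tab$ss[tab$source == "residual"], ref$residual,
                 tolerance = 1e-9)
  }
})

test_that("Type III equals Type I on a balanced design", {
  set.seed(83)
  d <- tibble::tibble(
    genotype = rep(c("c", "t"), each = 20),
    age_weeks = rep(rep(c(8, 14, 20, 32), each = 5), 2),
    water_delivery = rnorm(40)
  )
  tab <- two_way_anova(d)
  fit <- lm(water_delivery ~ genotype * age_factor,
            data = dplyr::mutate(d, age_factor = factor(age_weeks)))
  t1 <- stats::anova(fit)
  expect_equal(tab$ss[tab$source == "genetic background"],
               t1["genotype", "Sum Sq"], tolerance = 1e-9)
  expect_equal(tab$ss[tab$source == "time point"],
               t1["age_factor", "Sum Sq"], tolerance = 1e-9)
  expect_equal(tab$ss[tab$source == "interaction"],
               t1["genotype:age_factor", "Sum Sq"], tolerance = 1e-9)
})

test_that("missing design cells raise a structural error naming the cell", {
  d <- tibble::tibble(
    genotype = c("c", "c", "t"),
    age_weeks = c(8, 8, 8),
    water_delivery = c(1, 2, 3)
  )
  d$age_weeks[3] <- 14
  expect_error(two_way_anova(d), class = "bcsfbasl_structure_error")
})

test_that("summary-statistic ANOVA is sufficient for the subject-level table", {
  set.seed(89)
  n_cells <- c(10, 7, 7, 7, 10, 10, 10, 10)
  d <- tibble::tibble(
    genotype = rep(rep(c("control", "3xTg"), each = 4), n_cells),
    age_weeks = rep(rep(c(8, 14, 20, 32), 2), n_cells),
    water_delivery = rnorm(71, rep(c(0.7, 1.3), c(31, 40)), 0.3)
  )
  summ <- d |>
    dplyr::group_by(genotype, age_weeks) |>
    dplyr::summarise(n = dplyr::n(), sem = sd(water_delivery) / sqrt(n),
                     mean = mean(water_delivery), .groups = "drop")
  tab_sub <- two_way_anova(d)
  tab_sum <- anova_from_summary(summ)
  expect_equal(tab_sum$ss, tab_sub$ss, tolerance = 1e-10)
  expect_equal(tab_sum$f, tab_sub$f, tolerance = 1e-10)

  # zero SEMs with distinct means: residual SS collapses to zero
  summ0 <- dplyr::mutate(summ, sem = 0)
  tab0 <- anova_from_summary(summ0)
  expect_equal(tab0$ss[tab0$source == "residual"], 0, tolerance = 1e-20)
  expect_error(anova_from_summary(dplyr::mutate(summ, n = 1)), "n >= 2")
})

test_that("published group summaries give an overwhelming genotype effect", {
  spec <- default_cohort_spec()
  summ <- tibble::tibble(genotype = spec$genotype,
                         age_weeks = spec$age_weeks, n = spec$n,
                         mean = spec$water_delivery_mean,
                         sem = spec$water_delivery_sem)
  tab <- anova_from_summary(summ)
  expect_equal(tab$df[tab$source == "genetic background"], 1)
  expect_equal(tab$df[tab$source == "residual"], 63)
  expect_lt(tab$p[tab$source == "genetic background"], 0.001)
})

test_that("Sidak correction follows its closed form and default pairing set", {
  expect_equal(sidak_adjust(0.01, 4), 1 - 0.99^4)
  expect_equal(sidak_adjust(0.2, 1), 0.2)
  p <- seq(0.01, 0.5, by = 0.07)
  expect_true(all(diff(sidak_adjust(p, 5)) > 0))

  set.seed(97)
  n_cells <- c(10, 7, 7, 7, 10, 10, 10, 10)
  d <- tibble::tibble(
    genotype = rep(rep(c("control", "3xTg"), each = 4), n_cells),
    age_weeks = rep(rep(c(8, 14, 20, 32), 2), n_cells),
    water_delivery = rnorm(71, rep(c(0.7, 1.3), c(31, 40)), 0.2)
  )
  ph <- sidak_posthoc(d)
  expect_equal(nrow(ph), 16) # 4 between-genotype + 2 x 6 within-genotype
  expect_equal(ph$p_adjusted, sidak_adjust(ph$p_raw, 16))
  expect_true(all(ph$df == 63))
  # between-genotype contrasts dominate
  between <- grepl("control", ph$cell_1) != grepl("control", ph$cell_2)
  expect_true(all(ph$p_adjusted[between] < 0.01))
})

test_that("Sidak post-hoc t statistics agree with emmeans pooled comparisons", {
  skip_if_not_installed("emmeans")
  set.seed(101)
  d <- tibble::tibble(
    genotype = rep(rep(c("control", "3xTg"), each = 2), c(5, 6, 7, 8)),
    age_weeks = rep(rep(c(8, 14), 2), c(5, 6, 7, 8)),
    water_delivery = rnorm(26, 1, 0.3)
  )
  ph <- sidak_posthoc(d)
  fit <- lm(water_delivery ~ cell,
            data = dplyr::mutate(d, cell = interaction(
              factor(genotype), factor(age_weeks), sep = ":")))
  em <- summary(emmeans::emmeans(fit, pairwise ~ cell,
                                 adjust = "none")$contrasts)
  key <- function(c1, c2) paste(pmin(c1, c2), pmax(c1, c2))
  lab <- gsub("[()]", "", em$contrast)
  em_t <- setNames(abs(em$t.ratio),
                   key(sub(" - .*", "", lab), sub(".* - ", "", lab)))
  for (i in seq_len(nrow(ph))) {
    k <- key(ph$cell_1[i], ph$cell_2[i])
    expect_equal(abs(ph$statistic[i]), unname(em_t[[k]]), tolerance = 1e-8)
  }
})

test_that("group comparisons run per variable and age with family-wise FDR", {
  set.seed(103)
  n_cells <- c(10, 7, 7, 7, 10, 10, 10, 10)
  rec <- tibble::tibble(
    genotype = rep(rep(c("control", "3xTg"), each = 4), n_cells),
    age_weeks = rep(rep(c(8, 14, 20, 32), 2), n_cells),
    water_delivery = rnorm(71, rep(c(0.7, 1.3), c(31, 40)), 0.1),
    t1_csf = rnorm(71, 3.6, 0.3),
    n_entries = round(rnorm(71, 30, 5)),
    sa_score = rnorm(71, 60, 10),
    excluded = FALSE
  )
  cmp <- compare_groups(rec)
  expect_equal(nrow(cmp), 4 * 4) # 4 variables x 4 ages
  expect_setequal(unique(cmp$family_id), c("mri", "behaviour"))
  expect_true(all(cmp$test_name[cmp$variable == "sa_score"] == "welch_t"))
  expect_true(all(cmp$test_name[cmp$variable == "water_delivery"] ==
                    "mann_whitney"))
  # strong genotype effect on water delivery survives FDR at every age
  wd <- dplyr::filter(cmp, variable == "water_delivery")
  expect_true(all(wd$reject))
  # BH is applied within family, not jointly
  mri <- dplyr::filter(cmp, family_id == "mri")
  expect_equal(mri$p_adjusted,
               p.adjust(mri$p_raw, "BH"))
})
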