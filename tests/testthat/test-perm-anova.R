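test_that("F statistics match hand expansion and the lm oracle", {
  # identical groups -> F = 0
  d0 <- data.frame(pd = c(3, 3, 3, 3), sex = factor(c("F", "F", "M", "M")))
  expect_equal(anova_f(pd ~ sex, d0)$F, 0)

  # {1,2,3} vs {4,5,6}: SSB = 13.5, SSW = 4, F = 13.5 on df (1, 4)
  d1 <- data.frame(pd = 1:6, sex = factor(rep(c("A", "B"), each = 3)))
  tab <- anova_f(pd ~ sex, d1)
  expect_equal(tab$F, 13.5)
  expect_equal(tab$df, 1L)
  expect_equal(attr(tab, "df_res"), 4L)

  # random designs vs anova(lm()) sequential sums of squares
  set.seed(1)
  for (rep in 1:120) {
    d <- if (rep %% 2) rand_one_way() else rand_two_way()
    form <- if (rep %% 2) pd ~ sex else pd ~ sex * region
    got <- anova_f(form, d)
    want <- anova(lm(form, d))
    k <- nrow(got)
    expect_equal(got$ss, want[["Sum Sq"]][seq_len(k)], tolerance = 1e-10)
    expect_equal(got$F, want[["F value"]][seq_len(k)], tolerance = 1e-10)
    expect_equal(got$df, want[["Df"]][seq_len(k)])
    expect_equal(attr(got, "df_res"), want[["Df"]][k + 1L])
  }
})

test_that("Type II sums of squares agree with the car oracle", {
  set.seed(2)
  for (rep in 1:30) {
    d <- rand_two_way()
    got <- anova_f(pd ~ sex * region, d, ss_type = "II")
    want <- car::Anova(lm(pd ~ sex * region, d), type = 2)
    expect_equal(got$ss, want[["Sum Sq"]][1:3], tolerance = 1e-10)
    expect_equal(got$F, want[["F value"]][1:3], tolerance = 1e-10)
  }
})

test_that("design validation rejects sparse or degenerate layouts", {
  d <- data.frame(pd = c(1, 2, 3), sex = factor(c("F", "F", "M")))
  expect_error(anova_f(pd ~ sex, d), "fewer than 2 observations")
  d2 <- expand.grid(sex = c("F", "M"), region = c("NW", "rest"))
  d2 <- d2[rep(1:3, each = 3), ]  # M:rest cell empty
  d2$pd <- rnorm(nrow(d2))
  expect_error(anova_f(pd ~ sex * region, d2), "empty cell 'M:rest'")
  d3 <- data.frame(pd = rnorm(4), sex = factor(rep("F", 4)))
  expect_error(anova_f(pd ~ sex, d3), "fewer than two observed levels")
  d4 <- data.frame(pd = c(1, NA, 3, 4), sex = factor(rep(c("F", "M"), 2)))
  expect_error(perm_anova(pd ~ sex, d4, n_perm = 9), "NA in model")
})

test_that("permutation p-values behave: +1 correction, determinism, relabeling", {
  d <- data.frame(pd = c(0, 1, 0, 5, 6, 7),
                  sex = factor(rep(c("F", "M"), each = 3)))
  f1 <- perm_anova(pd ~ sex, d, n_perm = 499, seed = 42)
  expect_gte(f1$table$p_perm, 1 / 500)
  expect_lte(f1$table$p_perm, 1)
  # deterministic under a fixed seed
  f2 <- perm_anova(pd ~ sex, d, n_perm = 499, seed = 42)
  expect_identical(f1$table$p_perm, f2$table$p_perm)
  # invariant to relabeling factor levels
  d_rel <- d
  d_rel$sex <- factor(ifelse(d$sex == "F", "zz", "aa"))
  f3 <- perm_anova(pd ~ sex, d_rel, n_perm = 499, seed = 42)
  expect_identical(f1$table$p_perm, f3$table$p_perm)

  # constant response -> p = 1 for every term
  dc <- data.frame(pd = rep(2, 8), sex = factor(rep(c("F", "M"), 4)),
                   region = factor(rep(c("NW", "rest"), each = 4)))
  fc <- perm_anova(pd ~ sex * region, dc, n_perm = 99, seed = 1)
  expect_equal(fc$table$p_perm, rep(1, 3))
  expect_error(perm_anova(pd ~ sex, d, n_perm = 0), "n_perm")
})

test_that("exhaustive enumeration reproduces the 2/20 perfectly-separated case", {
  d <- data.frame(pd = c(0, 0, 0, 10, 10, 10),
                  sex = factor(rep(c("F", "M"), each = 3)))
  fe <- perm_anova(pd ~ sex, d, exact = TRUE)
  expect_equal(fe$table$p_perm, 0.1)  # 2 of the 20 assignments separate
  expect_equal(fe$n_perm, factorial(6))
  # and matches the fully independent combn/lm oracle
  expect_equal(fe$table$p_perm, oracle_exhaustive_p(d$pd, d$sex))

  # exact vs Monte-Carlo within sampling error on a noisier design
  set.seed(5)
  d2 <- data.frame(pd = round(rnorm(7, 5, 2), 1),
                   sex = factor(c("F", "F", "F", "M", "M", "M", "M")))
  p_ex <- perm_anova(pd ~ sex, d2, exact = TRUE)$table$p_perm
  expect_equal(p_ex, oracle_exhaustive_p(d2$pd, d2$sex), tolerance = 1e-12)
  p_mc <- perm_anova(pd ~ sex, d2, n_perm = 4999, seed = 9)$table$p_perm
  expect_lt(abs(p_mc - p_ex),
            3 * sqrt(p_ex * (1 - p_ex) / 4999) + 1 / 5000)
})

test_that("freedman-lane scheme runs and detects a real effect", {
  set.seed(8)
  d <- data.frame(pd = c(rnorm(10, 0), rnorm(10, 4)),
                  sex = factor(rep(c("F", "M"), each = 10)),
                  region = factor(rep(c("NW", "rest"), 10)))
  fl <- perm_anova(pd ~ sex * region, d, n_perm = 499, seed = 3,
                   scheme = "freedman_lane")
  expect_lt(fl$table$p_perm[1], 0.05)
  expect_equal(fl$scheme, "freedman_lane")
})

test_that("model methods expose coefficients, residuals, predictions and plots", {
  d <- data.frame(pd = c(1, 2, 3, 7, 8, 9),
                  sex = factor(rep(c("F", "M"), each = 3)))
  fit <- perm_anova(pd ~ sex, d, n_perm = 99, seed = 4)
  expect_equal(unname(coef(fit)["(Intercept)"]), 2)
  expect_equal(unname(coef(fit)["sexM"]), 6)
  expect_equal(unname(fitted(fit)), rep(c(2, 8), each = 3))
  expect_equal(unname(resid(fit)), d$pd - unname(fitted(fit)))
  expect_equal(unname(predict(fit, data.frame(sex = factor("M", c("F", "M"))))),
               8)
  expect_output(print(fit), "Permutation ANOVA")
  expect_output(print(summary(fit)), "seed: 4")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("report runs one-way everywhere and two-way where cells allow", {
  set.seed(10)
  mk_pd <- function(marker, n_nw_f, n_nw_m, n_rest_f, n_rest_m) {
    structure(data.frame(
      individual = paste0(marker, seq_len(n_nw_f + n_nw_m + n_rest_f + n_rest_m)),
      sex = c(rep("F", n_nw_f), rep("M", n_nw_m),
              rep("F", n_rest_f), rep("M", n_rest_m)),
      region = c(rep("NW_Europe", n_nw_f + n_nw_m),
                 rep("SE_refugia", n_rest_f), rep("Pannonian", n_rest_m)),
      marker = marker,
      pd = rpois(n_nw_f + n_nw_m + n_rest_f + n_rest_m, 4),
      sites_used = 400L), class = c("pd_table", "data.frame"))
  }
  # group sizes chosen to give the study's degrees of freedom:
  # 53 individuals -> one-way df (1, 51), two-way residual df 49
  pd_long <- mk_pd("marker_long", 8, 10, 17, 18)
  # 33 -> (1, 31); 16 -> (1, 14)
  pd_mid <- mk_pd("marker_mid", 5, 5, 11, 12)
  pd_short <- mk_pd("marker_short", 2, 3, 5, 6)
  rep_tab <- pd_anova_report(rbind(pd_long, pd_mid, pd_short),
                             n_perm = 99, seed = 1)$summary
  one <- rep_tab[rep_tab$model == "one_way", ]
  expect_equal(one$df_den[one$marker == "marker_long"], 51L)
  expect_equal(one$df_den[one$marker == "marker_mid"], 31L)
  expect_equal(one$df_den[one$marker == "marker_short"], 14L)
  two <- rep_tab[rep_tab$model == "two_way" & rep_tab$marker == "marker_long", ]
  expect_equal(unique(two$df_den), 49L)
  expect_equal(two$term, c("sex", "region2", "sex:region2"))
})
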