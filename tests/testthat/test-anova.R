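test_that("combined ANOVA matches the brute-force mean decomposition", {
  tr <- small_trial(n_genotypes = 5, seed = 31)
  sub <- as.data.frame(tr$data[tr$data$trait == "GY", ])
  oracle <- brute_force_ss(sub)
  tab <- combined_anova(tr$data, "GY")
  for (src in names(oracle)) {
    got <- tab$SS[tab$source == src]
    expect_equal(got, unname(oracle[src]), tolerance = 1e-9,
                 label = sprintf("SS(%s)", src))
  }
  # conservation asserted independently of the oracle
  expect_equal(sum(tab$SS), sum((sub$value - mean(sub$value))^2))
  expect_equal(sum(tab$df), nrow(sub) - 1)
})

test_that("ANOVA statistics are invariant to record order", {
  tr <- small_trial(n_genotypes = 4, seed = 8)
  tab1 <- combined_anova(tr$data, "GY")
  set.seed(1)
  shuffled <- trial_data(as.data.frame(tr$data)[sample(nrow(tr$data)), ])
  tab2 <- combined_anova(shuffled, "GY")
  expect_equal(as.data.frame(tab1), as.data.frame(tab2))
})

test_that("df column reproduces the full-design pattern at panel scale", {
  tr <- generate_trial(synthetic_config(n_genotypes = 156, var_G = 400,
                                        var_e = 900, seed = 4))
  tab <- combined_anova(tr$data, "GY")
  df_of <- function(s) tab$df[tab$source == s]
  expect_equal(df_of("G"), 155)
  expect_equal(df_of("G:SD"), 155)
  expect_equal(df_of("G:Y"), 155)
  expect_equal(df_of("G:SD:Y"), 155)
  expect_equal(df_of("Rep(SD:Y)"), 4)
  expect_equal(df_of("Residual"), 620)
})

test_that("declared error terms drive the F ratios and can be overridden", {
  tr <- small_trial(n_genotypes = 6, seed = 13)
  tab <- combined_anova(tr$data, "GY")
  ms <- function(s) tab$MS[tab$source == s]
  expect_equal(tab$F[tab$source == "SD"], ms("SD") / ms("SD:Y"))
  expect_equal(tab$F[tab$source == "G"], ms("G") / ms("G:Y"))
  expect_equal(tab$F[tab$source == "G:SD"], ms("G:SD") / ms("G:SD:Y"))
  expect_equal(tab$error_term[tab$source == "G:Y"], "Residual")
  tab2 <- combined_anova(tr$data, "GY", error_terms = list(G = "Residual"))
  expect_equal(tab2$F[tab2$source == "G"], ms("G") / ms("Residual"))
})

test_that("noise-free data put all SS in the sowing-date contrast", {
  tr <- generate_trial(synthetic_config(n_genotypes = 5, mu_normal = 800,
                                        stress_penalty = 0.25, seed = 2))
  tab <- combined_anova(tr$data, "GY")
  expect_gt(tab$SS[tab$source == "SD"], 0)
  others <- tab$SS[tab$source != "SD"]
  expect_true(all(abs(others) < 1e-6 * tab$SS[tab$source == "SD"]))
})

test_that("unbalanced data are refused with a pointer to exclusions", {
  tr <- small_trial(n_genotypes = 4, seed = 21)
  df <- as.data.frame(tr$data)
  df <- df[!(df$genotype == "G002" & df$condition == "stress"), ]
  expect_error(combined_anova(trial_data(df), "GY"), "G002")
})

test_that("per-condition ANOVA has the single-condition structure", {
  tr <- small_trial(n_genotypes = 6, seed = 17)
  tab <- per_condition_anova(tr$data, "GY", "normal")
  expect_identical(tab$source, c("Y", "Rep(Y)", "G", "G:Y", "Residual"))
  expect_equal(tab$df[tab$source == "G"], 5)
  # textbook balanced identity: SS(G) = r*y*sum((gbar_i - gbar)^2)
  sub <- tr$data[tr$data$trait == "GY" & tr$data$condition == "normal", ]
  g <- tapply(sub$value, sub$genotype, mean)
  expect_equal(tab$SS[tab$source == "G"], 2 * 2 * sum((g - mean(g))^2),
               tolerance = 1e-10)
  expect_equal(sum(tab$SS), sum((sub$value - mean(sub$value))^2))
})

test_that("a zero error mean square yields the infinite-F sentinel", {
  # genotype signal with no noise at all
  tr <- generate_trial(synthetic_config(n_genotypes = 5, var_G = 400,
                                        seed = 3))
  tab <- per_condition_anova(tr$data, "GY", "stress")
  expect_identical(tab$F[tab$source == "G"], Inf)
  expect_identical(tab$p[tab$source == "G"], 0)
})

test_that("variance components solve the EMS equations and truncate", {
  # arithmetic on published-scale mean squares (TKW-like): r = y = 2
  tab <- structure(
    data.frame(source = c("Y", "Rep(Y)", "G", "G:Y", "Residual"),
               df = c(1, 2, 155, 155, 620),
               SS = NA, MS = c(100, 10, 118, 1.81, 3.27)),
    design = list(n_reps = 2, n_years = 2),
    class = c("anova_table", "data.frame"))
  vc <- variance_components(tab)
  expect_equal(vc$sigma2_G, (118 - 1.81) / 4)
  expect_equal(round_half_away(vc$sigma2_G, 2), 29.05)
  expect_equal(vc$sigma2_e, 3.27)
  expect_equal(vc$sigma2_GxY, 0)  # (1.81 - 3.27)/2 < 0 truncates
  expect_identical(unname(vc$flags[["sigma2_GxY"]]), "truncated")
  expect_lt(vc$raw[["sigma2_GxY"]], 0)

  tab$MS[tab$source == "G"] <- 1.0  # MS_G < MS_GxY
  vc2 <- variance_components(tab)
  expect_equal(vc2$sigma2_G, 0)
  expect_identical(unname(vc2$flags[["sigma2_G"]]), "truncated")
})

test_that("heritability follows sigma2_G/sigma2_P with the np sentinel", {
  vc <- structure(list(sigma2_G = 400, sigma2_GxY = 100, sigma2_e = 1600,
                       raw = c(sigma2_G = 400, sigma2_GxY = 100,
                               sigma2_e = 1600),
                       flags = c(sigma2_G = "ok", sigma2_GxY = "ok",
                                 sigma2_e = "ok"),
                       design = list(n_reps = 2, n_years = 2)),
                  class = "variance_components")
  h <- broad_sense_heritability(vc)
  expect_equal(h$h2b, 400 / (400 + 100 / 2 + 1600 / 4))
  vc$sigma2_GxY <- 0; vc$sigma2_e <- 0
  expect_equal(broad_sense_heritability(vc)$h2b, 1)
  vc$sigma2_G <- 0; vc$flags[["sigma2_G"]] <- "truncated"
  h_np <- broad_sense_heritability(vc)
  expect_true(is.na(h_np$h2b))
  expect_identical(h_np$label, "np")
})

test_that("recovery: moment estimates are unbiased at panel scale", {
  set.seed(104)
  n_sim <- 120
  est <- matrix(NA_real_, n_sim, 2,
                dimnames = list(NULL, c("s2G", "h2b")))
  for (i in seq_len(n_sim)) {
    tr <- generate_trial(synthetic_config(
      n_genotypes = 156, var_G = 400, var_GxY = 100, var_e = 1600,
      seed = sample.int(1e6, 1)))
    vc <- variance_components(per_condition_anova(tr$data, "GY", "normal"))
    est[i, "s2G"] <- vc$raw[["sigma2_G"]]
    est[i, "h2b"] <- broad_sense_heritability(vc)$h2b
  }
  se_g <- sd(est[, "s2G"]) / sqrt(n_sim)
  expect_lt(abs(mean(est[, "s2G"]) - 400), 3 * se_g)
  # |bias| below 10% of truth
  expect_lt(abs(mean(est[, "s2G"]) - 400), 40)
  h_true <- 400 / (400 + 100 / 2 + 1600 / 4)
  hm <- mean(est[, "h2b"], na.rm = TRUE)
  expect_lt(abs(hm - h_true), 0.05)
})

test_that("CV reproduces the residual coefficient of variation", {
  tr <- small_trial(n_genotypes = 8, seed = 41)
  tab <- combined_anova(tr$data, "GY")
  expect_equal(attr(tab, "CV_percent"),
               100 * sqrt(tab$MS[tab$source == "Residual"]) /
                 attr(tab, "grand_mean"))
  expect_gte(attr(tab, "R2"), 0); expect_lte(attr(tab, "R2"), 1)
})

test_that("LSD is the t-quantile times the standard error of a difference", {
  expect_equal(lsd(0, 100, 10), 0)
  expect_equal(lsd(2358, 620, 624), 5.39872647, tolerance = 1e-7)
  expect_equal(lsd(4 * 2358, 620, 624), 2 * lsd(2358, 620, 624))
  expect_error(lsd(10, 0, 5), "df_error")
})

test_that("the outlier screen flags a planted gross error and only it", {
  tr <- small_trial(n_genotypes = 12, seed = 55, var_e = 400)
  clean <- screen_outliers(tr$data, "GY")
  df <- as.data.frame(tr$data)
  hit <- which(df$genotype == "G004" & df$condition == "normal" &
                 df$year == 1 & df$rep == 1 & df$trait == "GY")
  df$value[hit] <- df$value[hit] + 50 * sqrt(400)
  flagged <- screen_outliers(trial_data(df), "GY")
  expect_true(nrow(flagged) >= 1)
  expect_true("G004" %in% flagged$genotype)
  expect_gt(max(abs(flagged$rstudent)), 3)
  # removal is explicit, never automatic
  drop <- flagged[flagged$genotype == "G004", ]
  ds2 <- remove_records(trial_data(df), drop)
  expect_equal(nrow(ds2), nrow(df) - nrow(drop))
})
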