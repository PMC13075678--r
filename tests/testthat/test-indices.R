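# the ten published top-selection rows: printed per-genotype condition means
# with the full-panel means XP = 899, XS = 674 g/m2
top_panel <- function() {
  yield_summary(
    genotype = c("75", "74", "139", "185", "5", "140", "71", "186", "143", "93"),
    YP = c(979, 988, 898, 1007, 1046, 931, 923, 974, 959, 919),
    YS = c(898, 862, 800, 833, 834, 771, 775, 776, 772, 766),
    XP = 899, XS = 674)
}

test_that("indices reproduce the published worked rows at printed rounding", {
  idx <- stress_indices(top_panel())
  row <- function(g) idx[idx$genotype == g, ]
  expect_equal(round_half_away(row("75")$HSI, 2), 0.33)
  expect_equal(round_half_away(row("75")$MP, 0), 939)
  expect_equal(round_half_away(row("75")$STI, 2), 1.09)
  expect_equal(round_half_away(row("74")$HSI, 2), 0.51)
  expect_equal(round_half_away(row("74")$STI, 2), 1.05)
  expect_equal(round_half_away(row("139")$HSI, 2), 0.44)
  expect_equal(round_half_away(row("5")$STI, 2), 1.08)
  # unrounded spot values against direct arithmetic
  expect_equal(row("75")$HSI, 0.330582226762, tolerance = 1e-10)
  expect_equal(row("5")$STI, 1.07938990424, tolerance = 1e-10)
})

test_that("a no-loss genotype collapses the index family correctly", {
  s <- yield_summary(c("a", "b"), YP = c(800, 900), YS = c(800, 700))
  idx <- stress_indices(s)
  a <- idx[idx$genotype == "a", ]
  expect_equal(a$HSI, 0); expect_equal(a$YSI, 1)
  expect_equal(a$TOL, 0); expect_equal(a$PYR, 0)
  expect_equal(a$MP, 800); expect_equal(a$GMP, 800); expect_equal(a$HM, 800)
})

test_that("analytic identities hold on every generated panel", {
  set.seed(105)
  for (rep in 1:5) {
    tr <- generate_trial(reference_trial_config(seed = sample.int(1e6, 1),
                                                n_genotypes = 60))
    idx <- stress_indices(genotype_condition_means(tr$data))
    xp <- attr(idx, "XP"); xs <- attr(idx, "XS")
    expect_equal(idx$PYR, 100 * (1 - idx$YSI), tolerance = 1e-12)
    expect_equal(idx$HSI, (1 - idx$YSI) / (1 - xs / xp), tolerance = 1e-12)
    expect_equal(idx$STI, idx$GMP^2 / xp^2, tolerance = 1e-12)
    expect_equal(idx$MRP, idx$YI + idx$YP / xp, tolerance = 1e-12)
    # AM-GM-HM ordering, equality iff YP = YS
    expect_true(all(idx$HM <= idx$GMP + 1e-12))
    expect_true(all(idx$GMP <= idx$MP + 1e-12))
    eq <- abs(idx$YP - idx$YS) < 1e-12
    expect_identical(abs(idx$MP - idx$HM) < 1e-9, eq)
    # forced correlations
    expect_equal(cor(idx$YSI, idx$HSI), -1, tolerance = 1e-12)
    expect_equal(cor(idx$HSI, idx$PYR), 1, tolerance = 1e-12)
  }
})

test_that("dimensionless indices are scale invariant; productivity ones scale", {
  s1 <- top_panel()
  k <- 3.7
  s2 <- yield_summary(s1$genotype, k * s1$YP, k * s1$YS,
                      XP = k * attr(s1, "XP"), XS = k * attr(s1, "XS"))
  i1 <- stress_indices(s1); i2 <- stress_indices(s2)
  for (col in c("HSI", "YSI", "STI", "YI", "MRP", "PYR")) {
    expect_equal(i2[[col]], i1[[col]], tolerance = 1e-12, label = col)
  }
  for (col in c("TOL", "MP", "GMP", "HM")) {
    expect_equal(i2[[col]], k * i1[[col]], tolerance = 1e-12, label = col)
  }
})

test_that("degenerate panels are refused or flagged per genotype", {
  s <- yield_summary(c("a", "b"), YP = c(800, 900), YS = c(800, 900))
  expect_error(stress_indices(s), "XP equals XS")
  s2 <- yield_summary(c("a", "b", "c"), YP = c(0, 900, 800),
                      YS = c(10, 700, 600))
  idx <- suppressWarnings(stress_indices(s2))
  a <- idx[idx$genotype == "a", ]
  expect_true(is.na(a$HSI) && is.na(a$YSI) && is.na(a$PYR) && is.na(a$HM))
  expect_identical(a$class, "unclassified")
})

test_that("HSI classes are a partition with inclusive printed boundaries", {
  s <- yield_summary(paste0("g", 1:5), YP = rep(1000, 5),
                     # YS chosen to land HSI exactly on 0.33/0.8/1.3/1.31/2
                     YS = 1000 * (1 - c(0.33, 0.8, 1.3, 1.31, 2) * 0.25),
                     XP = 1000, XS = 750)
  idx <- stress_indices(s)
  expect_equal(idx$HSI, c(0.33, 0.8, 1.3, 1.31, 2), tolerance = 1e-12)
  expect_identical(idx$class, c("tolerant", "tolerant", "semi_tolerant",
                                "susceptible", "susceptible"))
  # every defined-HSI genotype is in exactly one class
  expect_true(all(idx$class %in% c("tolerant", "semi_tolerant", "susceptible")))
  # alternative susceptible boundary is available
  alt <- classify_hsi(idx, hsi_thresholds(susceptible_min = 1.2))
  expect_identical(alt$class[3], "susceptible")
})

test_that("composite mean-rank ordering matches exhaustive enumeration", {
  s <- yield_summary(c("x", "y", "z"), YP = c(900, 1000, 800),
                     YS = c(850, 700, 790), XP = 900, XS = 780)
  idx <- stress_indices(s)
  rk <- composite_rank(idx)
  # brute force: score every genotype by explicitly ranking each index
  # against the other genotypes, then order by the mean
  vals <- as.data.frame(idx)[, c("HSI", "MP", "STI")]
  brute <- rowMeans(cbind(rank(vals$HSI), rank(-vals$MP), rank(-vals$STI)))
  expect_identical(rk$genotype, idx$genotype[order(brute, idx$HSI)])
  expect_equal(sort(rk$mean_rank), sort(unname(brute)))
})

test_that("total ties give equal mean ranks and stable id ordering", {
  s <- yield_summary(c("b", "c", "a"), YP = rep(900, 3), YS = rep(700, 3),
                     XP = 900, XS = 700 * 0.9)
  rk <- composite_rank(stress_indices(s))
  expect_true(all(rk$mean_rank == 2))
  expect_identical(rk$genotype, c("a", "b", "c"))
})

test_that("the published panel's best mean-rank genotype is number 75", {
  rk <- composite_rank(stress_indices(top_panel()))
  expect_identical(rk$genotype[1], "75")
  expect_identical(top_genotypes(rk, 1)$Genotype, "75")
  expect_error(composite_rank(stress_indices(top_panel()),
                              indices = "NOPE", directions = "low_is_good"),
               "unknown index")
})

test_that("HSI-on-MP selection finds planted high-MP low-HSI genotypes", {
  # collinear points leave nothing below the line
  s_lin <- yield_summary(paste0("g", 1:5),
                         YP = c(800, 850, 900, 950, 1000),
                         YS = c(800, 850, 900, 950, 1000) * 0.75,
                         XP = 900, XS = 700)
  idx_lin <- stress_indices(s_lin)
  expect_length(hsi_mp_selection(idx_lin)$selected, 0)

  # one genotype with high MP and suppressed HSI must be selected
  set.seed(7)
  yp <- runif(20, 700, 1100)
  ys <- yp * (1 - runif(20, 0.2, 0.3))
  yp <- c(yp, 1100); ys <- c(ys, 1050)  # high MP, tiny loss
  s <- yield_summary(c(paste0("g", 1:20), "star"), yp, ys)
  sel <- hsi_mp_selection(stress_indices(s))
  expect_true("star" %in% sel$selected)

  # invariance to relabeling
  s2 <- yield_summary(c(paste0("h", 1:20), "star2"), yp, ys)
  sel2 <- hsi_mp_selection(stress_indices(s2))
  expect_length(sel$selected, length(sel2$selected))
  expect_true("star2" %in% sel2$selected)

  expect_error(hsi_mp_selection(stress_indices(
    yield_summary(c("a", "b", "c"), YP = c(900, 900, 900),
                  YS = c(700, 700, 700), XS = 650))), "zero variance")
})
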