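# Brute-force sum-of-squares oracle: explicit marginal/cell-mean
# decomposition of the balanced two-condition multi-year layout, written
# independently of the package's ANOVA path (no lm/anova involved).
brute_force_ss <- function(df) {
  m <- mean(df$value)
  ng <- length(unique(df$genotype)); nc <- length(unique(df$condition))
  ny <- length(unique(df$year)); nr <- length(unique(df$rep))
  mean_by <- function(...) tapply(df$value, list(...), mean)

  mi <- mean_by(df$genotype); mj <- mean_by(df$condition); mk <- mean_by(df$year)
  mjk <- mean_by(df$condition, df$year)
  mjkl <- mean_by(df$condition, df$year, df$rep)
  mij <- mean_by(df$genotype, df$condition)
  mik <- mean_by(df$genotype, df$year)
  mijk <- mean_by(df$genotype, df$condition, df$year)

  ss <- c(
    Y = ng * nc * nr * sum((mk - m)^2),
    SD = ng * ny * nr * sum((mj - m)^2),
    `SD:Y` = ng * nr * sum((mjk - outer(mj, rep(1, ny)) -
                              outer(rep(1, nc), mk) + m)^2),
    `Rep(SD:Y)` = ng * sum((mjkl - as.vector(mjk))^2),
    G = nc * ny * nr * sum((mi - m)^2),
    `G:SD` = ny * nr * sum((mij - outer(mi, rep(1, nc)) -
                              outer(rep(1, ng), mj) + m)^2),
    `G:Y` = nc * nr * sum((mik - outer(mi, rep(1, ny)) -
                             outer(rep(1, ng), mk) + m)^2))
  gsdy <- 0
  for (i in seq_len(ng)) for (j in seq_len(nc)) for (k in seq_len(ny)) {
    gsdy <- gsdy + (mijk[i, j, k] - mij[i, j] - mik[i, k] - mjk[j, k] +
                      mi[i] + mj[j] + mk[k] - m)^2
  }
  ss["G:SD:Y"] <- nr * gsdy
  total <- sum((df$value - m)^2)
  ss["Residual"] <- total - sum(ss)
  ss
}

# small balanced trial used across ANOVA tests
small_trial <- function(n_genotypes = 5, seed = 11, var_G = 400,
                        var_GxSD = 100, var_Y = 50, var_SDxY = 80,
                        var_GxY = 60, var_GxSDxY = 90, var_rep = 20,
                        var_e = 900) {
  generate_trial(synthetic_config(
    n_genotypes = n_genotypes, mu_normal = 899, stress_penalty = 0.25,
    var_G = var_G, var_GxSD = var_GxSD, var_Y = var_Y, var_SDxY = var_SDxY,
    var_GxY = var_GxY, var_GxSDxY = var_GxSDxY, var_rep = var_rep,
    var_e = var_e, seed = seed))
}
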