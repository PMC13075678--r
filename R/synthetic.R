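#' Configuration for a synthetic two-sowing-date trial
#'
#' Describes the design sizes, condition means and variance components of a
#' simulated multi-environment wheat trial in which a late sowing date imposes
#' terminal heat stress. The simulated observation for genotype i, condition
#' j, year k, replicate l is
#'
#' \deqn{y_{ijkl} = \mu_j + g_i + (g sd)_{ij} + y_k + (sd y)_{jk} +
#'   (g y)_{ik} + (g sd y)_{ijk} + r_{l(jk)} + b + \epsilon_{ijkl}}
#'
#' with \eqn{\mu_{stress} = \mu_{normal} (1 - penalty)} and every random term
#' drawn independently Gaussian with its configured variance. The stress
#' penalty shifts the condition mean; genotype-specific heat sensitivity
#' enters only through the genotype x sowing-date interaction.
#'
#' @param n_genotypes,n_years,n_reps design counts (defaults 156, 2, 2).
#' @param mu_normal panel mean yield under normal sowing, g/m2.
#' @param stress_penalty proportional mean reduction under stress, in `[0, 1)`.
#' @param var_G genotype main-effect variance (g2/m4).
#' @param var_GxSD genotype x sowing-date interaction variance.
#' @param var_Y,var_SDxY year and sowing-date x year variances.
#' @param var_GxY,var_GxSDxY genotype x year and three-way variances.
#' @param var_rep replicate-within-(sowing date x year) variance.
#' @param var_block optional incomplete-block variance (0 by default: block
#'   effects are treated as negligible and the layout analyzed as an RCBD; a
#'   nonzero value is available for robustness experiments).
#' @param blocks_per_rep number of incomplete blocks per replicate when
#'   `var_block > 0`.
#' @param var_e residual plot error variance.
#' @param seed master seed; every random term draws from its own sub-stream
#'   derived from it, so e.g. changing `var_e` does not perturb the realized
#'   genotype effects.
#' @param extra_traits named list of additional traits to simulate alongside
#'   the yield trait; each element is a list that may supply `mu_normal`,
#'   `stress_penalty`, `var_G`, `var_GxSD`, `var_Y`, `var_SDxY`, `var_GxY`,
#'   `var_GxSDxY`, `var_rep`, `var_e` (unspecified components default to 0).
#' @param yield_trait code under which the yield trait is recorded ("GY").
#' @return A list of class `synthetic_config`.
#' @seealso [generate_trial()], [reference_trial_config()]
#' @export
synthetic_config <- function(n_genotypes = 156, n_years = 2, n_reps = 2,
                             mu_normal = 899, stress_penalty = 0.25,
                             var_G = 0, var_GxSD = 0, var_Y = 0,
                             var_SDxY = 0, var_GxY = 0, var_GxSDxY = 0,
                             var_rep = 0, var_block = 0, blocks_per_rep = 12,
                             var_e = 0, seed = 1, extra_traits = list(),
                             yield_trait = "GY") {
  cfg <- list(n_genotypes = n_genotypes, n_years = n_years, n_reps = n_reps,
              mu_normal = mu_normal, stress_penalty = stress_penalty,
              var_G = var_G, var_GxSD = var_GxSD, var_Y = var_Y,
              var_SDxY = var_SDxY, var_GxY = var_GxY,
              var_GxSDxY = var_GxSDxY, var_rep = var_rep,
              var_block = var_block, blocks_per_rep = blocks_per_rep,
              var_e = var_e, seed = as.integer(seed),
              extra_traits = extra_traits, yield_trait = yield_trait)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  vars <- c("var_G", "var_GxSD", "var_Y", "var_SDxY", "var_GxY",
            "var_GxSDxY", "var_rep", "var_block", "var_e")
  for (v in vars) {
    if (cfg[[v]] < 0) stopf("%s must be non-negative", v)
  }
  if (cfg$stress_penalty < 0 || cfg$stress_penalty >= 1) {
    stopf("stress_penalty must lie in [0, 1)")
  }
  if (cfg$mu_normal < 0) stopf("mu_normal must be non-negative")
  for (n in c("n_genotypes", "n_years", "n_reps")) {
    if (cfg[[n]] < 1) stopf("%s must be >= 1", n)
  }
  invisible(cfg)
}

#' Reference configuration emulating a large heat-screening trial
#'
#' Defaults calibrated to a 156-genotype spring wheat panel evaluated under
#' fall (normal) and spring (terminal heat stress) sowing over two years with
#' two replicates: panel mean grain yield 899 g/m2 under normal sowing, a 25%
#' mean reduction under stress, between-genotype standard deviations of the
#' genotype means near 130 (normal) and 100 (stress) g/m2, and a residual
#' plot variance giving a residual CV near 6%. Three companion traits are
#' included: days to flowering (large condition effect), thousand-kernel
#' weight, and grain protein percentage (near-zero condition effect with
#' dominant genotype variance, the typical quality-trait pattern).
#'
#' @param seed master seed.
#' @param n_genotypes number of genotypes (156 by default; smaller panels
#'   scale the design down without other changes).
#' @return A `synthetic_config`.
#' @export
reference_trial_config <- function(seed = 1, n_genotypes = 156) {
  synthetic_config(
    n_genotypes = n_genotypes, n_years = 2, n_reps = 2,
    mu_normal = 899, stress_penalty = 0.25,
    var_G = 9500, var_GxSD = 4000, var_Y = 300, var_SDxY = 400,
    var_GxY = 500, var_GxSDxY = 1500, var_rep = 30, var_e = 2358,
    seed = seed,
    extra_traits = list(
      DF  = list(mu_normal = 159.5, stress_penalty = 0.454,
                 var_G = 4.0, var_GxSD = 0.3, var_Y = 0.5, var_SDxY = 1.0,
                 var_GxY = 0.3, var_GxSDxY = 0.9, var_rep = 0.05,
                 var_e = 0.91),
      TKW = list(mu_normal = 42.4, stress_penalty = 0.1439,
                 var_G = 14, var_GxSD = 1.0, var_Y = 0.2, var_SDxY = 0.1,
                 var_GxY = 0.15, var_GxSDxY = 0.3, var_rep = 0.05,
                 var_e = 3.27),
      PGP = list(mu_normal = 13.06, stress_penalty = 0.0122,
                 var_G = 0.17, var_GxSD = 0.002, var_Y = 0.005,
                 var_SDxY = 0.01, var_GxY = 0.003, var_GxSDxY = 0.01,
                 var_rep = 0.002, var_e = 0.091)
    ))
}

# one sub-seed per random term so components can be changed independently
sub_seed <- function(master, offset) (master + 77003L * offset) %% 2147483629L

draw <- function(n, var, master, offset) {
  set.seed(sub_seed(master, offset))
  if (var == 0) rep(0, n) else stats::rnorm(n, 0, sqrt(var))
}

simulate_one_trait <- function(cfg, trait_cfg, seed_shift) {
  ng <- cfg$n_genotypes; ny <- cfg$n_years; nr <- cfg$n_reps
  tc <- trait_cfg
  master <- sub_seed(cfg$seed, seed_shift)

  g    <- draw(ng, tc$var_G, master, 1L)
  gsd  <- matrix(draw(ng * 2, tc$var_GxSD, master, 2L), ng, 2)
  yr   <- draw(ny, tc$var_Y, master, 3L)
  sdy  <- matrix(draw(2 * ny, tc$var_SDxY, master, 4L), 2, ny)
  gy   <- matrix(draw(ng * ny, tc$var_GxY, master, 5L), ng, ny)
  gsdy <- array(draw(ng * 2 * ny, tc$var_GxSDxY, master, 6L), c(ng, 2, ny))
  repe <- array(draw(2 * ny * nr, tc$var_rep, master, 7L), c(2, ny, nr))

  grid <- expand.grid(genotype = seq_len(ng), condition = 1:2,
                      year = seq_len(ny), rep = seq_len(nr),
                      KEEP.OUT.ATTRS = FALSE)
  nb <- cfg$blocks_per_rep
  block <- ((grid$genotype - 1L) %/% ceiling(ng / nb)) + 1L
  if (tc$var_block > 0) {
    be <- array(draw(2 * ny * nr * nb, tc$var_block, master, 8L),
                c(2, ny, nr, nb))
    blk <- be[cbind(grid$condition, grid$year, grid$rep, block)]
  } else blk <- 0
  eps <- draw(nrow(grid), tc$var_e, master, 9L)

  mu <- c(tc$mu_normal, tc$mu_normal * (1 - tc$stress_penalty))
  y <- mu[grid$condition] +
    g[grid$genotype] +
    gsd[cbind(grid$genotype, grid$condition)] +
    yr[grid$year] +
    sdy[cbind(grid$condition, grid$year)] +
    gy[cbind(grid$genotype, grid$year)] +
    gsdy[cbind(grid$genotype, grid$condition, grid$year)] +
    repe[cbind(grid$condition, grid$year, grid$rep)] +
    blk + eps

  list(values = y, grid = grid, block = block, g = g, gsd = gsd, mu = mu)
}

#' Generate a synthetic plot-level trial
#'
#' Draws a fully balanced trial from the model described in
#' [synthetic_config()], together with a truth record holding the realized
#' genotype effects and the implied true expectations, for parameter-recovery
#' testing. The truth record is never consumed by the analysis functions.
#'
#' @param cfg a `synthetic_config`.
#' @return A list with elements:
#' \describe{
#'   \item{data}{a [trial_data] object (yield trait plus any extra traits).}
#'   \item{truth}{data.frame keyed by genotype with the realized main effect
#'     `g`, interaction effects `gsd_normal`/`gsd_stress`, the true expected
#'     condition means `true_YP`/`true_YS` (expectations over years, reps and
#'     plot error), the implied `true_HSI`, and the `true_class` label under
#'     the default thresholds.}
#'   \item{config}{the configuration used.}
#' }
#' @examples
#' tr <- generate_trial(synthetic_config(n_genotypes = 12, var_G = 400,
#'                                       var_e = 900, seed = 42))
#' tr$data
#' @export
generate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  validate_synthetic_config(cfg)
  cond_lab <- c("normal", "stress")
  gname <- sprintf("G%03d", seq_len(cfg$n_genotypes))

  yield_cfg <- cfg[c("mu_normal", "stress_penalty", "var_G", "var_GxSD",
                     "var_Y", "var_SDxY", "var_GxY", "var_GxSDxY",
                     "var_rep", "var_block", "var_e")]
  trait_cfgs <- c(stats::setNames(list(yield_cfg), cfg$yield_trait),
                  lapply(cfg$extra_traits, function(tc) {
                    defaults <- list(mu_normal = 0, stress_penalty = 0,
                                     var_G = 0, var_GxSD = 0, var_Y = 0,
                                     var_SDxY = 0, var_GxY = 0,
                                     var_GxSDxY = 0, var_rep = 0,
                                     var_block = 0, var_e = 0)
                    utils::modifyList(defaults, tc)
                  }))

  pieces <- vector("list", length(trait_cfgs))
  truth <- NULL
  for (t in seq_along(trait_cfgs)) {
    sim <- simulate_one_trait(cfg, trait_cfgs[[t]], seed_shift = t * 101L)
    pieces[[t]] <- data.frame(
      genotype = gname[sim$grid$genotype],
      condition = cond_lab[sim$grid$condition],
      year = sim$grid$year, rep = sim$grid$rep, block = sim$block,
      trait = names(trait_cfgs)[t], value = sim$values,
      stringsAsFactors = FALSE)
    if (t == 1L) {
      true_yp <- sim$mu[1] + sim$g + sim$gsd[, 1]
      true_ys <- sim$mu[2] + sim$g + sim$gsd[, 2]
      xp <- mean(true_yp); xs <- mean(true_ys)
      true_hsi <- if (xp != xs) (1 - true_ys / true_yp) / (1 - xs / xp)
                  else rep(NA_real_, length(true_yp))
      truth <- data.frame(
        genotype = gname, g = sim$g,
        gsd_normal = sim$gsd[, 1], gsd_stress = sim$gsd[, 2],
        true_YP = true_yp, true_YS = true_ys, true_HSI = true_hsi,
        true_class = classify_hsi_values(true_hsi, hsi_thresholds()),
        stringsAsFactors = FALSE)
    }
  }
  ds <- trial_data(do.call(rbind, pieces))
  list(data = ds, truth = truth, config = cfg)
}

#' Write a synthetic trial and its truth sidecar to disk
#'
#' @param trial a list as returned by [generate_trial()].
#' @param data_path path for the canonical long-format CSV.
#' @param truth_path path for the truth sidecar CSV (genotype, realized
#'   effects, true expected condition means).
#' @return `data_path`, invisibly.
#' @export
write_synthetic_trial <- function(trial, data_path, truth_path) {
  write_trial_csv(trial$data, data_path)
  utils::write.csv(trial$truth, truth_path, row.names = FALSE)
  invisible(data_path)
}
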