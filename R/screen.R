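#' Run the full heat-tolerance screen
#'
#' One-call orchestration of the analysis pipeline on a plot-level trial:
#' combined and per-condition ANOVA per trait, variance components and
#' broad-sense heritability, condition means with stress-induced reductions,
#' the ten stress indices with HSI classification and composite mean-rank
#' selection, the HSI-on-MP regression selection, Pearson correlation
#' matrices (traits per condition, indices across the panel) and PCA of the
#' standardized genotype means.
#'
#' @param data a [trial_data] object; exactly one of `data`/`config` must be
#'   given.
#' @param config a [synthetic_config]; the trial is generated from it.
#' @param yield_trait trait code used for the stress indices (`"GY"`).
#' @param traits traits to analyze (all by default).
#' @param thresholds an [hsi_thresholds()] object.
#' @param rank_indices,rank_directions passed to [composite_rank()].
#' @param alpha significance level for the LSD.
#' @param top_k size of the reported top selection.
#' @return An object of class `heat_screen` with elements `data`, `truth`
#'   (synthetic runs only), `anova` (per trait: combined, per-condition,
#'   variance components, heritability, LSD), `summary_table`, `indices`
#'   (ranked index table), `selection` (HSI-on-MP), `correlations` (per
#'   condition + indices), `pca` (per condition, pooled, indices), `top`,
#'   and the call parameters.
#' @examples
#' scr <- heat_screen(config = reference_trial_config(seed = 7,
#'                                                    n_genotypes = 24))
#' scr
#' @export
heat_screen <- function(data = NULL, config = NULL, yield_trait = "GY",
                        traits = NULL, thresholds = hsi_thresholds(),
                        rank_indices = c("HSI", "MP", "STI"),
                        rank_directions = c("low_is_good", "high_is_good",
                                            "high_is_good"),
                        alpha = 0.05, top_k = 10) {
  if (is.null(data) == is.null(config)) {
    stopf("supply exactly one of 'data' or 'config'")
  }
  truth <- NULL
  if (!is.null(config)) {
    sim <- generate_trial(config)
    data <- sim$data
    truth <- sim$truth
  }
  traits <- traits %||% attr(data, "traits")$code
  if (!yield_trait %in% traits) traits <- c(yield_trait, traits)
  design <- trial_design(data)

  anova_stage <- lapply(stats::setNames(traits, traits), function(tr) {
    comb <- combined_anova(data, tr)
    per <- lapply(stats::setNames(c("normal", "stress"),
                                  c("normal", "stress")), function(cond) {
      tab <- per_condition_anova(data, tr, cond)
      vc <- variance_components(tab)
      list(anova = tab, vc = vc, h2b = broad_sense_heritability(vc))
    })
    res <- comb[comb$source == "Residual", ]
    n_per_mean <- design$n_conditions * design$n_years * design$n_reps
    list(combined = comb, per_condition = per,
         lsd = lsd(res$MS, res$df, n_per_mean, alpha))
  })

  summary_table <- condition_summary(data, traits)
  summary_table$h2b_normal <- vapply(
    traits, function(tr) anova_stage[[tr]]$per_condition$normal$h2b$label,
    character(1))
  summary_table$h2b_stress <- vapply(
    traits, function(tr) anova_stage[[tr]]$per_condition$stress$h2b$label,
    character(1))

  gm <- genotype_condition_means(data, yield_trait)
  idx <- stress_indices(gm, thresholds)
  ranked <- composite_rank(idx, rank_indices, rank_directions)
  selection <- hsi_mp_selection(idx)

  index_cols <- c("YP", "YS", "TOL", "GMP", "MP", "YSI", "HSI", "STI",
                  "YI", "HM", "MRP", "PYR")
  correlations <- list(
    normal = pearson_matrix(genotype_mean_table(data, traits, "normal")),
    stress = pearson_matrix(genotype_mean_table(data, traits, "stress")),
    indices = pearson_matrix(as.data.frame(idx)[, index_cols]))

  pca <- list(
    normal = trait_pca(genotype_mean_table(data, traits, "normal")),
    stress = trait_pca(genotype_mean_table(data, traits, "stress")),
    pooled = trait_pca(genotype_mean_table(data, traits)),
    indices = trait_pca(as.data.frame(idx)[, index_cols]))

  structure(list(data = data, truth = truth, design = design,
                 anova = anova_stage, summary_table = summary_table,
                 indices = ranked, selection = selection,
                 correlations = correlations, pca = pca,
                 top = top_genotypes(ranked, top_k),
                 params = list(yield_trait = yield_trait, traits = traits,
                               thresholds = thresholds,
                               rank_indices = rank_indices,
                               rank_directions = rank_directions,
                               alpha = alpha, top_k = top_k,
                               config = config)),
            class = "heat_screen")
}

#' @export
print.heat_screen <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "Heat-tolerance screen: %d genotypes x %d conditions x %d years x %d reps\n",
    d$n_genotypes, d$n_conditions, d$n_years, d$n_reps))
  gy <- x$summary_table[x$summary_table$trait == x$params$yield_trait, ]
  cat(sprintf("%s: %.0f g/m2 (normal) vs %.0f g/m2 (stress), %.1f%% reduction\n",
              x$params$yield_trait, gy$mean_normal, gy$mean_stress,
              gy$reduction_pct))
  cls <- table(factor(x$indices$class,
                      levels = c("tolerant", "semi_tolerant", "susceptible")))
  cat(sprintf("HSI classes: %d tolerant / %d semi-tolerant / %d susceptible\n",
              cls[1], cls[2], cls[3]))
  cat(sprintf("Top genotype by mean rank of {%s}: %s\n",
              paste(x$params$rank_indices, collapse = ", "),
              x$top$Genotype[1]))
  invisible(x)
}

#' @export
summary.heat_screen <- function(object, ...) {
  x <- object
  print(x)
  cat("\nCondition means, reductions and heritability:\n")
  st <- x$summary_table
  st[, 2:6] <- lapply(st[, 2:6], function(v) signif(v, 4))
  print.data.frame(st, row.names = FALSE)
  cat(sprintf("\nTop %d genotypes (mean rank of %s):\n",
              nrow(x$top), paste(x$params$rank_indices, collapse = "/")))
  print.data.frame(x$top, row.names = FALSE)
  cat("\nHSI-on-MP regression selection:",
      if (length(x$selection$selected) > 0)
        paste(x$selection$selected, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' @export
plot.heat_screen <- function(x, which = c("hsi_mp", "biplot"), ...) {
  which <- match.arg(which)
  if (which == "hsi_mp") {
    idx <- x$indices
    cols <- c(tolerant = "forestgreen", semi_tolerant = "goldenrod",
              susceptible = "firebrick", unclassified = "grey60")
    plot(idx$MP, idx$HSI, pch = 19, col = cols[idx$class],
         xlab = "Mean productivity MP (g/m2)",
         ylab = "Heat susceptibility index HSI", ...)
    graphics::abline(x$selection$intercept, x$selection$slope, lty = 2)
    graphics::abline(v = x$selection$mp_mean, lty = 3)
    sel <- idx$genotype %in% x$selection$selected
    if (any(sel)) graphics::points(idx$MP[sel], idx$HSI[sel], cex = 1.8)
    graphics::legend("topleft", legend = names(cols), col = cols, pch = 19,
                     bty = "n", cex = 0.8)
  } else {
    bc <- biplot_coords(x$pca$indices)
    plot(bc$scores[, 2], bc$scores[, 3], pch = 20, col = "grey50",
         xlab = sprintf("PC1 (%.1f%%)", 100 * x$pca$indices$proportion[1]),
         ylab = sprintf("PC2 (%.1f%%)", 100 * x$pca$indices$proportion[2]),
         ...)
    graphics::arrows(0, 0, bc$loadings[, 2], bc$loadings[, 3],
                     length = 0.08, col = "firebrick")
    graphics::text(bc$loadings[, 2] * 1.08, bc$loadings[, 3] * 1.08,
                   bc$loadings$variable, col = "firebrick", cex = 0.8)
  }
  invisible(x)
}

#' Simulate new trials from a fitted screen's configuration
#'
#' For screens run on synthetic configurations, draws `nsim` fresh trials
#' with new seeds derived from `seed`.
#'
#' @param object a `heat_screen` run with `config =`.
#' @param nsim number of trials.
#' @param seed base seed.
#' @param ... unused.
#' @return List of [generate_trial()] results.
#' @export
simulate.heat_screen <- function(object, nsim = 1, seed = NULL, ...) {
  cfg <- object$params$config
  if (is.null(cfg)) stopf("screen was not run from a synthetic configuration")
  seed <- seed %||% cfg$seed
  lapply(seq_len(nsim), function(i) {
    args <- unclass(cfg)
    args$seed <- sub_seed(seed, i)
    generate_trial(do.call(synthetic_config, args))
  })
}

# stable polynomial hash of the run parameters, for provenance headers
config_hash <- function(params) {
  s <- utf8ToInt(paste(deparse(params), collapse = ""))
  h <- 17
  for (b in s) h <- (h * 31 + b) %% 67108859
  sprintf("%08x", h)
}

#' Write the report bundle of a screen
#'
#' Emits the output tables as CSV files in `dir`, each with a provenance
#' header (`# heattol <version> | config <hash> | seed <seed>`): condition
#' summary, combined ANOVA per trait, per-condition ANOVA, index table with
#' classes and ranks, top-k selection, correlation matrices, PCA loadings and
#' scores, and a log of excluded genotypes. Output is byte-identical across
#' reruns with the same input and seed.
#'
#' @param x a `heat_screen`.
#' @param dir output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_screen_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(x$params$config)) x$params$config$seed else NA
  hdr <- sprintf("# heattol %s | config %s | seed %s",
                 as.character(utils::packageVersion("heattol")),
                 config_hash(x$params), seed)
  emit <- function(df, file) {
    path <- file.path(dir, file)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, sep = ",",
                                        row.names = FALSE, quote = FALSE,
                                        append = TRUE))
    path
  }
  emit(x$summary_table, "condition_summary.csv")
  for (tr in names(x$anova)) {
    emit(as.data.frame(x$anova[[tr]]$combined),
         sprintf("anova_combined_%s.csv", tr))
    for (cond in c("normal", "stress")) {
      emit(as.data.frame(x$anova[[tr]]$per_condition[[cond]]$anova),
           sprintf("anova_%s_%s.csv", cond, tr))
    }
  }
  emit(as.data.frame(x$indices), "stress_indices.csv")
  emit(x$top, "top_genotypes.csv")
  for (nm in names(x$correlations)) {
    r <- x$correlations[[nm]]
    emit(data.frame(variable = r$variables, round(r$r, 4)),
         sprintf("correlation_%s.csv", nm))
    emit(data.frame(variable = r$variables, r$stars),
         sprintf("correlation_%s_stars.csv", nm))
  }
  for (nm in names(x$pca)) {
    p <- x$pca[[nm]]
    emit(data.frame(variable = rownames(p$loadings),
                    round(p$loadings, 6)),
         sprintf("pca_%s_loadings.csv", nm))
    emit(data.frame(id = rownames(p$scores), round(p$scores, 6)),
         sprintf("pca_%s_scores.csv", nm))
  }
  gm <- genotype_condition_means(x$data, x$params$yield_trait)
  excl <- attr(gm, "excluded")
  writeLines(c(hdr, "# genotypes excluded from the yield summary (missing a condition)",
               if (length(excl) > 0) excl else "# none"),
             file.path(dir, "exclusions.log"))
  invisible(dir)
}
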