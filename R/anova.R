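#' Combined ANOVA over sowing dates and years
#'
#' Balanced combined analysis of variance for one trait under a randomized
#' complete block framework (the alpha-lattice layout is collapsed to an RCBD
#' when inter-block effects are negligible; the `block` column is ignored).
#' Sources are Y, SD, SD:Y, Rep(SD:Y), G, G:SD, G:Y, G:SD:Y and Residual.
#' Sums of squares are the orthogonal partition of the balanced layout
#' (computed through a sequential linear-model fit, which coincides with the
#' textbook marginal-mean decomposition under balance).
#'
#' F-ratio denominators follow the mixed-model expectations for fixed G and
#' SD with random Y and Rep: fixed effects are tested against their
#' interaction with year (SD and Y against SD:Y; G against G:Y; G:SD against
#' G:SD:Y) while the random interactions and Rep(SD:Y) are tested against the
#' residual. The assignment can be overridden per source.
#'
#' @param ds a `trial_data` object, balanced for `trait`.
#' @param trait trait code.
#' @param error_terms named list overriding the denominator source for any
#'   numerator source, e.g. `list(G = "Residual")`.
#' @return An object of class `anova_table`: data.frame with columns
#'   `source`, `df`, `SS`, `MS`, `F`, `p`, `error_term`, `stars`; attributes
#'   `grand_mean`, `R2`, `CV_percent`, `trait`, `design`. A zero denominator
#'   MS with positive numerator yields `F = Inf`, `p = 0`.
#' @export
combined_anova <- function(ds, trait, error_terms = list()) {
  check_balance(ds, trait)
  sub <- ds[ds$trait == trait & !is.na(ds$value), , drop = FALSE]
  if (length(unique(sub$condition)) < 2 || length(unique(sub$year)) < 2) {
    stopf("combined ANOVA needs at least 2 sowing dates and 2 years")
  }
  G <- factor(sub$genotype); SD <- factor(sub$condition)
  Y <- factor(sub$year); R <- factor(sub$rep)
  fit <- stats::lm(sub$value ~ Y + SD + G + Y:SD + Y:SD:R + G:SD + G:Y + G:SD:Y)
  # only the SS/df partition is consumed; F and p are re-derived against the
  # declared error terms, so anova()'s residual-based tests (and its perfect-
  # fit warning) are irrelevant here
  an <- suppressWarnings(stats::anova(fit))

  pretty <- c("Y" = "Y", "SD" = "SD", "G" = "G", "Y:SD" = "SD:Y",
              "Y:SD:R" = "Rep(SD:Y)", "SD:G" = "G:SD", "Y:G" = "G:Y",
              "Y:SD:G" = "G:SD:Y", "Residuals" = "Residual")
  rows <- data.frame(source = unname(pretty[rownames(an)]),
                     df = an$Df, SS = an$`Sum Sq`, MS = an$`Mean Sq`,
                     stringsAsFactors = FALSE)
  order_sources <- c("Y", "SD", "SD:Y", "Rep(SD:Y)", "G", "G:SD", "G:Y",
                     "G:SD:Y", "Residual")
  rows <- rows[match(order_sources, rows$source), ]

  default_terms <- list("Y" = "SD:Y", "SD" = "SD:Y", "SD:Y" = "Residual",
                        "Rep(SD:Y)" = "Residual", "G" = "G:Y",
                        "G:SD" = "G:SD:Y", "G:Y" = "Residual",
                        "G:SD:Y" = "Residual")
  terms <- utils::modifyList(default_terms, error_terms)
  finish_anova_table(rows, terms, sub$value, trait, trial_design(ds))
}

#' Per-condition ANOVA
#'
#' Combined-over-years analysis of a single sowing-date condition: sources
#' Y, Rep(Y), G, G:Y, Residual. G is tested against G:Y (year random), Y
#' against Rep(Y), and the random terms against the residual. Supplies the
#' mean squares consumed by [variance_components()] and
#' [broad_sense_heritability()].
#'
#' @inheritParams combined_anova
#' @param condition `"normal"` or `"stress"`.
#' @return An `anova_table`, as for [combined_anova()].
#' @export
per_condition_anova <- function(ds, trait, condition,
                                error_terms = list()) {
  condition <- normalize_condition(condition)
  check_balance(ds, trait)
  sub <- ds[ds$trait == trait & !is.na(ds$value) &
              ds$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0) stopf("no records for condition '%s'", condition)
  if (length(unique(sub$year)) < 2) stopf("need at least 2 years")
  G <- factor(sub$genotype); Y <- factor(sub$year); R <- factor(sub$rep)
  fit <- stats::lm(sub$value ~ Y + G + Y:R + G:Y)
  an <- suppressWarnings(stats::anova(fit))
  pretty <- c("Y" = "Y", "G" = "G", "Y:R" = "Rep(Y)", "Y:G" = "G:Y",
              "Residuals" = "Residual")
  rows <- data.frame(source = unname(pretty[rownames(an)]),
                     df = an$Df, SS = an$`Sum Sq`, MS = an$`Mean Sq`,
                     stringsAsFactors = FALSE)
  order_sources <- c("Y", "Rep(Y)", "G", "G:Y", "Residual")
  rows <- rows[match(order_sources, rows$source), ]
  default_terms <- list("Y" = "Rep(Y)", "Rep(Y)" = "Residual",
                        "G" = "G:Y", "G:Y" = "Residual")
  terms <- utils::modifyList(default_terms, error_terms)
  finish_anova_table(rows, terms, sub$value, trait, trial_design(ds),
                     condition = condition)
}

check_balance <- function(ds, trait) {
  if (!is_balanced(ds, trait)) {
    gm <- try(genotype_condition_means(ds, trait), silent = TRUE)
    excl <- if (!inherits(gm, "try-error")) attr(gm, "excluded") else character(0)
    stopf(paste0(
      "trait '%s' is not balanced; the balanced ANOVA requires every ",
      "genotype x condition x year x rep cell. %s"),
      trait,
      if (length(excl) > 0)
        sprintf("Genotypes missing a condition: %s.",
                paste(excl, collapse = ", "))
      else "See the exclusion report from genotype_condition_means().")
  }
}

finish_anova_table <- function(rows, terms, values, trait, design,
                               condition = NULL) {
  rows$F <- NA_real_; rows$p <- NA_real_
  rows$error_term <- NA_character_
  # mean squares at floating-point rounding level of the dominant source are
  # treated as exact zeros (degenerate noise-free layouts)
  eps <- 1e-10 * max(rows$MS, 0)
  for (i in seq_len(nrow(rows))) {
    src <- rows$source[i]
    if (src == "Residual" || is.null(terms[[src]])) next
    den <- rows[rows$source == terms[[src]], , drop = FALSE]
    if (nrow(den) != 1) stopf("error term '%s' missing for source '%s'",
                              terms[[src]], src)
    rows$error_term[i] <- terms[[src]]
    if (den$MS > eps) {
      rows$F[i] <- rows$MS[i] / den$MS
      rows$p[i] <- stats::pf(rows$F[i], rows$df[i], den$df,
                             lower.tail = FALSE)
    } else if (rows$MS[i] > eps) {
      rows$F[i] <- Inf; rows$p[i] <- 0
    }
  }
  rows$stars <- sig_stars(rows$p)
  total_ss <- sum((values - mean(values))^2)
  resid <- rows[rows$source == "Residual", ]
  stopifnot(abs(sum(rows$SS) - total_ss) <= 1e-8 * max(total_ss, 1),
            sum(rows$df) == length(values) - 1)
  structure(rows,
            grand_mean = mean(values),
            R2 = 1 - resid$SS / total_ss,
            CV_percent = 100 * sqrt(resid$MS) / mean(values),
            trait = trait, design = design, condition = condition,
            class = c("anova_table", "data.frame"))
}

#' @export
print.anova_table <- function(x, ...) {
  hdr <- sprintf("Balanced ANOVA for trait %s%s", attr(x, "trait"),
                 if (!is.null(attr(x, "condition")))
                   sprintf(" (%s condition)", attr(x, "condition")) else "")
  cat(hdr, "\n")
  out <- as.data.frame(x)
  out$SS <- signif(out$SS, 6); out$MS <- signif(out$MS, 6)
  out$F <- signif(out$F, 4); out$p <- signif(out$p, 3)
  print.data.frame(out, row.names = FALSE)
  cat(sprintf("Grand mean %.4g | R2 %.3f | CV %.2f%%\n",
              attr(x, "grand_mean"), attr(x, "R2"), attr(x, "CV_percent")))
  invisible(x)
}

#' Variance components from a per-condition ANOVA
#'
#' Method-of-moments solution of the expected mean squares of the balanced
#' genotype x year design with r replicates:
#' \deqn{\sigma^2_e = MS_{res};\quad
#'   \sigma^2_{GY} = (MS_{GY} - MS_{res})/r;\quad
#'   \sigma^2_G = (MS_G - MS_{GY})/(r y)}
#' Negative solutions are truncated to zero and flagged; the raw values are
#' retained for diagnostics.
#'
#' @param table an `anova_table` from [per_condition_anova()] (needs sources
#'   G, G:Y, Residual).
#' @param design design counts (list with `n_reps`, `n_years`); taken from
#'   the table's attribute when omitted.
#' @return A list of class `variance_components` with elements `sigma2_G`,
#'   `sigma2_GxY`, `sigma2_e` (truncated at 0), `raw` (unmodified values) and
#'   `flags` (`"ok"` or `"truncated"` per component).
#' @export
variance_components <- function(table, design = attr(table, "design")) {
  stopifnot(inherits(table, "anova_table"))
  need <- c("G", "G:Y", "Residual")
  if (!all(need %in% table$source)) {
    stopf("ANOVA table lacks source row(s): %s",
          paste(setdiff(need, table$source), collapse = ", "))
  }
  ms <- function(s) table$MS[table$source == s]
  r <- design$n_reps; y <- design$n_years
  raw <- c(sigma2_G = (ms("G") - ms("G:Y")) / (r * y),
           sigma2_GxY = (ms("G:Y") - ms("Residual")) / r,
           sigma2_e = ms("Residual"))
  trunc <- pmax(raw, 0)
  structure(list(sigma2_G = unname(trunc["sigma2_G"]),
                 sigma2_GxY = unname(trunc["sigma2_GxY"]),
                 sigma2_e = unname(trunc["sigma2_e"]),
                 raw = raw,
                 flags = ifelse(raw < 0, "truncated", "ok"),
                 design = list(n_reps = r, n_years = y)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (method of moments):\n")
  for (nm in c("sigma2_G", "sigma2_GxY", "sigma2_e")) {
    cat(sprintf("  %-11s %10.4g  [%s]\n", nm, x[[nm]],
                x$flags[[nm]]))
  }
  invisible(x)
}

#' Broad-sense heritability on a genotype-mean basis
#'
#' h2b = sigma2_G / sigma2_P with the phenotypic variance of genotype means
#' \deqn{\sigma^2_P = \sigma^2_G + \sigma^2_{GY}/y + \sigma^2_e/(r y).}
#' When the genotype component truncates to zero the estimate is reported as
#' non-predictive (`"np"`), the convention used when ANOVA provides no usable
#' genetic signal for the trait.
#'
#' @param vc a `variance_components` object.
#' @param design list with `n_reps` and `n_years`; defaults to the design
#'   recorded in `vc`.
#' @return A list of class `heritability`: `h2b` (in `[0, 1]`, or `NA` when
#'   non-predictive), `label` (formatted percent or `"np"`), `sigma2_P`, and
#'   the components used.
#' @export
broad_sense_heritability <- function(vc, design = vc$design) {
  stopifnot(inherits(vc, "variance_components"))
  r <- design$n_reps; y <- design$n_years
  s2p <- vc$sigma2_G + vc$sigma2_GxY / y + vc$sigma2_e / (r * y)
  np <- vc$sigma2_G <= 0 || vc$flags[["sigma2_G"]] == "truncated"
  h2b <- if (np || s2p == 0) NA_real_ else vc$sigma2_G / s2p
  structure(list(h2b = h2b,
                 label = if (is.na(h2b)) "np"
                         else sprintf("%.0f", 100 * h2b),
                 sigma2_P = s2p, components = vc),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("Broad-sense heritability: %s%s\n", x$label,
              if (x$label != "np") "%" else " (non-predictive)"))
  invisible(x)
}

#' Fisher's least significant difference
#'
#' @param ms_error error mean square.
#' @param df_error its degrees of freedom (>= 1).
#' @param n_per_mean number of observations behind each compared mean.
#' @param alpha two-sided significance level (0.05 by default).
#' @return `t(1 - alpha/2, df_error) * sqrt(2 ms_error / n_per_mean)`.
#' @export
lsd <- function(ms_error, df_error, n_per_mean, alpha = 0.05) {
  if (ms_error < 0) stopf("ms_error must be non-negative")
  if (df_error < 1) stopf("df_error must be >= 1")
  if (n_per_mean < 1) stopf("n_per_mean must be >= 1")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  stats::qt(1 - alpha / 2, df_error) * sqrt(2 * ms_error / n_per_mean)
}

#' Screen for outlying plots via studentized residuals
#'
#' Fits a preliminary RCBD model (replicate + genotype) within each
#' condition x year environment and flags plots whose externally studentized
#' residual exceeds the threshold in absolute value. Flagged plots are
#' reported, never removed automatically: removal is an explicit user action
#' (see [remove_records()]), reserved for observations with a non-experimental
#' cause.
#'
#' @param ds a `trial_data` object.
#' @param trait trait code.
#' @param threshold absolute studentized-residual cutoff (default 3).
#' @return data.frame of flagged records with their `rstudent` values (zero
#'   rows when nothing is flagged).
#' @export
screen_outliers <- function(ds, trait, threshold = 3) {
  sub <- ds[ds$trait == trait & !is.na(ds$value), , drop = FALSE]
  env <- interaction(sub$condition, sub$year, drop = TRUE)
  out <- lapply(split(seq_len(nrow(sub)), env), function(idx) {
    d <- sub[idx, , drop = FALSE]
    if (length(unique(d$genotype)) < 2 || length(unique(d$rep)) < 2) {
      return(NULL)
    }
    fit <- stats::lm(value ~ factor(rep) + factor(genotype), data = d)
    rs <- stats::rstudent(fit)
    flag <- which(!is.na(rs) & abs(rs) > threshold)
    if (length(flag) == 0) return(NULL)
    cbind(d[flag, , drop = FALSE], rstudent = rs[flag])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- cbind(as.data.frame(ds)[0, ], rstudent = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Remove specific plot records from a dataset
#'
#' @param ds a `trial_data` object.
#' @param records data.frame identifying rows to drop (columns `genotype`,
#'   `condition`, `year`, `rep`, `trait`), e.g. a subset of
#'   [screen_outliers()] output.
#' @return A new `trial_data` without those records.
#' @export
remove_records <- function(ds, records) {
  key <- function(d) paste(d$genotype, normalize_condition(d$condition),
                           d$year, d$rep, d$trait, sep = "\r")
  keep <- !(key(ds) %in% key(records))
  trial_data(as.data.frame(ds)[keep, , drop = FALSE], attr(ds, "traits"))
}
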