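#' HSI classification thresholds
#'
#' Genotypes are grouped by heat susceptibility index as tolerant
#' (HSI <= `tolerant_max`), semi-tolerant (`tolerant_max` < HSI <=
#' `susceptible_min`) and susceptible (HSI > `susceptible_min`). The default
#' boundaries are 0.8 and 1.3, inclusive on the left class as written.
#'
#' @param tolerant_max upper bound of the tolerant class (inclusive).
#' @param susceptible_min upper bound of the semi-tolerant class (inclusive);
#'   some screens use 1.2 here instead.
#' @return A list of class `hsi_thresholds`.
#' @export
hsi_thresholds <- function(tolerant_max = 0.8, susceptible_min = 1.3) {
  if (!(tolerant_max < susceptible_min)) {
    stopf("tolerant_max must be below susceptible_min")
  }
  structure(list(tolerant_max = tolerant_max,
                 susceptible_min = susceptible_min),
            class = "hsi_thresholds")
}

classify_hsi_values <- function(hsi, thr) {
  ifelse(is.na(hsi), "unclassified",
         ifelse(hsi <= thr$tolerant_max, "tolerant",
                ifelse(hsi <= thr$susceptible_min, "semi_tolerant",
                       "susceptible")))
}

#' Compute the ten yield-based stress tolerance and sensitivity indices
#'
#' For each genotype with mean yield YP under normal sowing and YS under
#' terminal heat stress, and panel means XP/XS, computes:
#' \itemize{
#'   \item HSI = (1 - YS/YP) / (1 - XS/XP) — heat susceptibility index;
#'     relative loss normalized by the panel's relative loss (low = tolerant)
#'   \item YSI = YS/YP — yield stability index
#'   \item STI = (YS x YP) / XP^2 — stress tolerance index
#'   \item TOL = YP - YS; MP = (YP + YS)/2; GMP = sqrt(YP x YS);
#'     HM = 2 YP YS / (YP + YS)
#'   \item YI = YS/XS; MRP = YS/XS + YP/XP; PYR = 100 (YP - YS)/YP
#' }
#' GMP is the geometric mean of the two condition yields; the raw product
#' YP x YS (= STI x XP^2), which some reports print under the GMP label, is
#' also returned as `yield_product`.
#'
#' @param summaries a `yield_summary` (from [genotype_condition_means()] or
#'   [yield_summary()]).
#' @param thresholds an [hsi_thresholds()] object used to fill the `class`
#'   column.
#' @return A data.frame of class `index_table` with one row per genotype:
#'   `genotype`, `YP`, `YS`, the ten indices, `yield_product` and `class`;
#'   attributes `XP`, `XS`. Genotypes with `YP = 0` get `NA` for the ratio
#'   indices (YSI, HSI, PYR, HM) and class `"unclassified"`.
#' @examples
#' s <- yield_summary("g75", YP = 979, YS = 898, XP = 899, XS = 674)
#' stress_indices(s)
#' @export
stress_indices <- function(summaries, thresholds = hsi_thresholds()) {
  stopifnot(inherits(summaries, "yield_summary"))
  xp <- attr(summaries, "XP"); xs <- attr(summaries, "XS")
  if (xp <= 0 || xs <= 0) stopf("panel means XP and XS must be positive")
  if (xp == xs) {
    stopf("XP equals XS: the panel shows no mean stress response, HSI is undefined")
  }
  yp <- summaries$YP; ys <- summaries$YS
  ok <- yp > 0
  d <- 1 - xs / xp

  hsi <- ifelse(ok, (1 - ys / yp) / d, NA_real_)
  tab <- data.frame(
    genotype = summaries$genotype,
    YP = yp, YS = ys,
    TOL = yp - ys,
    MP = (yp + ys) / 2,
    GMP = sqrt(yp * ys),
    HM = ifelse(ok, 2 * yp * ys / (yp + ys), NA_real_),
    HSI = hsi,
    YSI = ifelse(ok, ys / yp, NA_real_),
    STI = yp * ys / xp^2,
    YI = ys / xs,
    MRP = ys / xs + yp / xp,
    PYR = ifelse(ok, 100 * (yp - ys) / yp, NA_real_),
    yield_product = yp * ys,
    stringsAsFactors = FALSE)
  tab$class <- classify_hsi_values(tab$HSI, thresholds)
  structure(tab, XP = xp, XS = xs, thresholds = thresholds,
            class = c("index_table", "data.frame"))
}

#' @export
print.index_table <- function(x, digits = 2, ...) {
  cat(sprintf("Stress index table: %d genotypes (XP = %.1f, XS = %.1f g/m2)\n",
              nrow(x), attr(x, "XP"), attr(x, "XS")))
  cls <- table(factor(x$class, levels = c("tolerant", "semi_tolerant",
                                          "susceptible", "unclassified")))
  cat(sprintf("Classes: %d tolerant, %d semi-tolerant, %d susceptible, %d unclassified\n",
              cls["tolerant"], cls["semi_tolerant"], cls["susceptible"],
              cls["unclassified"]))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = digits + 2)
  if (nrow(x) > 10) cat(sprintf("... and %d more genotypes\n", nrow(x) - 10))
  invisible(x)
}

#' Re-classify an index table by HSI
#'
#' @param table an `index_table`.
#' @param thresholds an [hsi_thresholds()] object.
#' @return The table with its `class` column (and threshold attribute)
#'   replaced. Every genotype with a defined HSI falls in exactly one class;
#'   undefined HSI yields `"unclassified"`.
#' @export
classify_hsi <- function(table, thresholds = hsi_thresholds()) {
  stopifnot(inherits(table, "index_table"))
  table$class <- classify_hsi_values(table$HSI, thresholds)
  attr(table, "thresholds") <- thresholds
  table
}

#' Composite mean-rank selection
#'
#' Ranks genotypes within each chosen index (rank 1 = best in that index's
#' direction, ties receive average ranks), averages the ranks, and orders the
#' table by mean rank. The default aggregates HSI (low is good) with MP and
#' STI (high is good), so selection favours low susceptibility combined with
#' high productivity.
#'
#' @param table an `index_table`.
#' @param indices index column names to aggregate.
#' @param directions one of `"low_is_good"`/`"high_is_good"` per index.
#' @return The table with per-index rank columns (`rank_<index>`),
#'   `mean_rank`, and `overall_rank`, sorted ascending by mean rank; ties are
#'   broken by lower HSI and then genotype id, so the ordering is total and
#'   reproducible.
#' @export
composite_rank <- function(table,
                           indices = c("HSI", "MP", "STI"),
                           directions = c("low_is_good", "high_is_good",
                                          "high_is_good")) {
  stopifnot(inherits(table, "index_table"))
  if (length(indices) != length(directions)) {
    stopf("indices and directions must have equal length")
  }
  bad <- setdiff(indices, names(table))
  if (length(bad) > 0) stopf("unknown index name(s): %s",
                             paste(bad, collapse = ", "))
  if (!all(directions %in% c("low_is_good", "high_is_good"))) {
    stopf("directions must be 'low_is_good' or 'high_is_good'")
  }
  rk <- mapply(function(ix, dir) {
    v <- table[[ix]]
    rank(if (dir == "low_is_good") v else -v,
         ties.method = "average", na.last = "keep")
  }, indices, directions)
  colnames(rk) <- paste0("rank_", indices)
  out <- cbind(as.data.frame(table), rk)
  out$mean_rank <- rowMeans(rk)
  ord <- order(out$mean_rank, out$HSI, out$genotype)
  out <- out[ord, , drop = FALSE]
  out$overall_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, XP = attr(table, "XP"), XS = attr(table, "XS"),
            thresholds = attr(table, "thresholds"),
            rank_indices = indices, rank_directions = directions,
            class = c("index_table", "data.frame"))
}

#' Select genotypes combining high productivity with low susceptibility
#'
#' Fits an ordinary least-squares regression of HSI on mean productivity
#' (MP) across the panel, then selects genotypes whose MP exceeds the panel
#' mean and whose HSI falls below the fitted line (negative residual):
#' better-than-expected tolerance at high productivity.
#'
#' @param table an `index_table` with at least 3 genotypes having defined
#'   HSI and MP.
#' @return A list with `selected` (character vector of genotype ids, ordered
#'   by increasingly negative residual), `fit` (the `lm` object of HSI ~ MP),
#'   `intercept`, `slope` and `mp_mean`.
#' @export
hsi_mp_selection <- function(table) {
  stopifnot(inherits(table, "index_table"))
  ok <- !is.na(table$HSI) & !is.na(table$MP)
  if (sum(ok) < 3) stopf("need at least 3 genotypes with defined HSI and MP")
  d <- table[ok, , drop = FALSE]
  if (stats::var(d$MP) == 0) {
    stopf("MP has zero variance: the HSI-on-MP regression is degenerate")
  }
  fit <- stats::lm(HSI ~ MP, data = d)
  resid <- stats::residuals(fit)
  sel <- d$MP > mean(d$MP) & resid < 0
  ordsel <- d$genotype[sel][order(resid[sel])]
  list(selected = ordsel, fit = fit,
       intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       mp_mean = mean(d$MP))
}

#' Format a top-k selection table
#'
#' Rounds a ranked index table to the precision conventional in published
#' screening reports (yields and MP to whole g/m2, HSI and STI to 2 d.p.,
#' ties rounded half away from zero) and returns the leading `k` rows with
#' columns Rank, Genotype, YP, YS, HSI, MP, STI.
#'
#' @param ranked an `index_table` that has been through [composite_rank()].
#' @param k number of genotypes to keep.
#' @return A plain data.frame.
#' @export
top_genotypes <- function(ranked, k = 10) {
  stopifnot(inherits(ranked, "index_table"))
  if (is.null(ranked$overall_rank)) stopf("run composite_rank() first")
  h <- utils::head(ranked, k)
  data.frame(Rank = h$overall_rank,
             Genotype = h$genotype,
             YP = round_half_away(h$YP, 0),
             YS = round_half_away(h$YS, 0),
             HSI = round_half_away(h$HSI, 2),
             MP = round_half_away(h$MP, 0),
             STI = round_half_away(h$STI, 2),
             stringsAsFactors = FALSE)
}
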