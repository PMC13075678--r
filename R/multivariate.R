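#' Genotype-mean table for correlation and PCA
#'
#' Builds the genotype x variable matrix on which trait correlations and PCA
#' operate: one value per genotype per trait, obtained by averaging plots
#' within the requested condition (the granularity at which screening reports
#' quote one correlation per trait pair per condition). With both conditions
#' requested the condition-specific genotype means are stacked as separate
#' rows (pooled-environment mode); use `wide = TRUE` to instead concatenate
#' them as separate columns (`<trait>_normal`, `<trait>_stress`).
#'
#' @param ds a `trial_data` object.
#' @param traits trait codes (all by default).
#' @param condition `"normal"`, `"stress"`, or both (default both).
#' @param wide with two conditions, concatenate as columns instead of
#'   stacking rows.
#' @return A numeric data.frame, rownames = genotype (suffixed by condition
#'   in stacked mode), with a `condition` attribute in stacked mode.
#' @export
genotype_mean_table <- function(ds, traits = NULL,
                                condition = c("normal", "stress"),
                                wide = FALSE) {
  traits <- traits %||% attr(ds, "traits")$code
  condition <- normalize_condition(condition)
  one <- function(cond) {
    sub <- ds[ds$condition == cond & ds$trait %in% traits &
                !is.na(ds$value), , drop = FALSE]
    m <- tapply(sub$value, list(sub$genotype, sub$trait), mean)
    as.data.frame(m[, traits, drop = FALSE])
  }
  if (length(condition) == 1) return(one(condition))
  tabs <- lapply(condition, one)
  if (wide) {
    stopifnot(identical(rownames(tabs[[1]]), rownames(tabs[[2]])))
    out <- cbind(tabs[[1]], tabs[[2]])
    names(out) <- c(paste0(traits, "_", condition[1]),
                    paste0(traits, "_", condition[2]))
    return(out)
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- unlist(lapply(seq_along(condition), function(i)
    paste0(rownames(tabs[[i]]), ".", condition[i])))
  attr(out, "condition") <- rep(condition, vapply(tabs, nrow, 1L))
  out
}

#' Pairwise Pearson correlation matrix with significance flags
#'
#' Pearson r on pairwise-complete cases, with two-sided p-values from the
#' t transform `t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom, and
#' the star convention of trial reports (`*` p < 0.05, `**` p < 0.01,
#' `ns` otherwise). Pairs with fewer than 3 complete cases or a
#' zero-variance member get `NA` and are flagged.
#'
#' @param x numeric data.frame or matrix, observations x variables.
#' @return A list of class `correlation_matrix`: `r`, `p`, `n` (pairwise
#'   counts), `stars`, `variables`, and `degenerate` (names of zero-variance
#'   variables).
#' @export
pearson_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stopf("correlation input must be numeric")
  v <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  colnames(x) <- v
  k <- ncol(x)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(v, v))
  n <- matrix(0L, k, k, dimnames = list(v, v))
  degenerate <- character(0)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- stats::complete.cases(x[, i], x[, j])
      nij <- sum(ok)
      n[i, j] <- n[j, i] <- nij
      if (i == j) {
        if (nij > 1 && stats::sd(x[ok, i]) == 0) degenerate <- c(degenerate, v[i])
        r[i, j] <- 1
        next
      }
      if (nij < 3) next
      si <- stats::sd(x[ok, i]); sj <- stats::sd(x[ok, j])
      if (si == 0 || sj == 0) next
      rij <- stats::cor(x[ok, i], x[ok, j])
      r[i, j] <- r[j, i] <- rij
      # guard |r| = 1 exactly: t is infinite, p = 0
      tt <- rij * sqrt((nij - 2) / max(1 - rij^2, 0))
      p[i, j] <- p[j, i] <- if (!is.finite(tt)) 0
        else 2 * stats::pt(abs(tt), nij - 2, lower.tail = FALSE)
    }
  }
  stars <- matrix(sig_stars(p), k, k, dimnames = list(v, v))
  diag(stars) <- ""
  structure(list(r = r, p = p, n = n, stars = stars, variables = v,
                 degenerate = unique(degenerate)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson correlations among %d variables\n", length(x$variables)))
  disp <- matrix(paste0(formatC(x$r, digits = digits, format = "f"),
                        ifelse(x$stars %in% c("*", "**"), x$stars, "")),
                 nrow = nrow(x$r), dimnames = dimnames(x$r))
  disp[is.na(x$r)] <- "."
  diag(disp) <- ""
  print(as.data.frame(disp), right = TRUE)
  if (length(x$degenerate) > 0) {
    cat("Zero-variance variables:", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Principal component analysis of a genotype-mean table
#'
#' Eigen-decomposition of the correlation matrix (`standardize = TRUE`,
#' z-scored complete cases — the default) or covariance matrix of the input.
#' Eigenvector signs are fixed deterministically: within each component the
#' loading of largest magnitude is made positive (ties broken by variable
#' order), so output is reproducible across platforms and BLAS builds.
#'
#' @param x numeric data.frame or matrix, observations x variables; rows
#'   with any missing value are dropped (complete-case analysis).
#' @param standardize scale each variable to unit variance (default TRUE).
#' @return A list of class `pca_result`: `loadings` (variables x components,
#'   orthonormal), `scores` (complete observations x components),
#'   `sdev`, `var_explained` (eigenvalues), `proportion`,
#'   `cumulative_proportion`, `center`, `scale`, `n_used`.
#' @export
trait_pca <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stopf("PCA needs at least 2 variables")
  cc <- stats::complete.cases(x)
  xc <- x[cc, , drop = FALSE]
  if (nrow(xc) < 3) stopf("PCA needs at least 3 complete cases")
  sds <- apply(xc, 2, stats::sd)
  if (standardize && any(sds == 0)) {
    stopf("constant column under standardization: %s",
          paste(colnames(xc)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(xc, center = TRUE, scale. = standardize)
  load <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(load))) {
    top <- which.max(abs(load[, j]))
    if (load[top, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2
  structure(list(loadings = load, scores = scores, sdev = pc$sdev,
                 var_explained = ev, proportion = ev / sum(ev),
                 cumulative_proportion = cumsum(ev) / sum(ev),
                 center = pc$center,
                 scale = if (standardize) pc$scale else NULL,
                 n_used = nrow(xc)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, n = 5, ...) {
  k <- min(n, length(x$sdev))
  cat(sprintf("PCA on %d complete observations, %d variables\n",
              x$n_used, nrow(x$loadings)))
  smry <- rbind(`Eigenvalue` = x$var_explained[1:k],
                `Proportion` = x$proportion[1:k],
                `Cumulative` = x$cumulative_proportion[1:k])
  colnames(smry) <- paste0("PC", 1:k)
  print(round(smry, 3))
  invisible(x)
}

#' Biplot coordinates from a PCA result
#'
#' Scores for genotypes and scaled loadings for variables on two chosen
#' components, ready for plotting or CSV export.
#'
#' @param pca a `pca_result`.
#' @param components two component indices (default 1:2).
#' @param loading_scale multiplier applied to loadings for display (default
#'   scales the largest loading arrow to the score range).
#' @return List with data.frames `scores` and `loadings`.
#' @export
biplot_coords <- function(pca, components = c(1, 2), loading_scale = NULL) {
  stopifnot(inherits(pca, "pca_result"), length(components) == 2)
  sc <- pca$scores[, components, drop = FALSE]
  ld <- pca$loadings[, components, drop = FALSE]
  if (is.null(loading_scale)) {
    loading_scale <- 0.8 * max(abs(sc)) / max(abs(ld))
  }
  list(scores = data.frame(id = rownames(sc), sc, check.names = FALSE),
       loadings = data.frame(variable = rownames(ld), ld * loading_scale,
                             check.names = FALSE))
}
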