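#' Construct a plot-level trial dataset
#'
#' A `trial_data` object holds plot-level observations from a two-condition
#' (normal vs. heat-stress sowing date) multi-year wheat trial in long format:
#' one row per genotype x condition x year x replicate x trait. It is the
#' common currency of every analysis function in the package.
#'
#' @param records data.frame with columns `genotype`, `condition` (one of
#'   `"normal"`/`"stress"`; aliases `"fall"`/`"spring"` are accepted), `year`,
#'   `rep`, optionally `block`, `trait`, and numeric `value`.
#' @param traits optional data.frame with columns `code` and `units` declaring
#'   trait metadata; inferred from the records when omitted.
#' @return An object of class `trial_data`: the long-format data.frame with a
#'   `design` attribute giving the counts `n_genotypes`, `n_conditions`,
#'   `n_years`, `n_reps` and a `traits` attribute.
#' @seealso [read_trial_csv()], [generate_trial()]
#' @export
trial_data <- function(records, traits = NULL) {
  required <- c("genotype", "condition", "year", "rep", "trait", "value")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stopf("trial records lack required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  records$condition <- normalize_condition(records$condition)
  if (!"block" %in% names(records)) records$block <- NA_integer_
  records$genotype <- as.character(records$genotype)
  records$trait <- as.character(records$trait)
  if (!is.numeric(records$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(records$value))) &
                   !is.na(records$value) & records$value != "")
    if (length(bad) > 0) {
      stopf("non-numeric trait value in row %d ('%s')",
            bad[1], records$value[bad[1]])
    }
    records$value <- suppressWarnings(as.numeric(records$value))
  }
  if (any(records$rep < 1, na.rm = TRUE)) {
    stopf("replicate numbers must be >= 1")
  }
  key <- paste(records$genotype, records$condition, records$year,
               records$rep, records$trait, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[which(duplicated(key))[1], ]
    stopf("duplicate record for genotype '%s', condition '%s', year %s, rep %s, trait '%s'",
          d$genotype, d$condition, d$year, d$rep, d$trait)
  }
  records <- records[, c("genotype", "condition", "year", "rep", "block",
                         "trait", "value")]
  if (is.null(traits)) {
    traits <- data.frame(code = sort(unique(records$trait)),
                         units = NA_character_,
                         stringsAsFactors = FALSE)
  }
  structure(records,
            design = infer_design(records),
            traits = traits,
            class = c("trial_data", "data.frame"))
}

normalize_condition <- function(x) {
  x <- tolower(as.character(x))
  map <- c(normal = "normal", fall = "normal", nc = "normal",
           stress = "stress", spring = "stress", hs = "stress")
  out <- unname(map[x])
  if (anyNA(out)) {
    stopf("unknown condition label(s): %s",
          paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

infer_design <- function(records) {
  list(n_genotypes  = length(unique(records$genotype)),
       n_conditions = length(unique(records$condition)),
       n_years      = length(unique(records$year)),
       n_reps       = length(unique(records$rep)))
}

#' @export
print.trial_data <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf(
    "Trial dataset: %d genotypes x %d condition(s) x %d year(s) x %d rep(s)\n",
    d$n_genotypes, d$n_conditions, d$n_years, d$n_reps))
  cat(sprintf("Traits (%d): %s\n", nrow(attr(x, "traits")),
              paste(attr(x, "traits")$code, collapse = ", ")))
  cat(sprintf("%d plot-level records (%d missing values)\n",
              nrow(x), sum(is.na(x$value))))
  invisible(x)
}

#' Design counts of a trial dataset
#'
#' @param ds a `trial_data` object.
#' @return Named list `n_genotypes`, `n_conditions`, `n_years`, `n_reps`.
#' @export
trial_design <- function(ds) attr(ds, "design")

#' Check whether a trait is fully balanced
#'
#' A trait is balanced when every genotype x condition x year x replicate cell
#' holds exactly one non-missing observation.
#'
#' @param ds a `trial_data` object.
#' @param trait trait code.
#' @return Logical scalar.
#' @export
is_balanced <- function(ds, trait) {
  sub <- ds[ds$trait == trait & !is.na(ds$value), , drop = FALSE]
  d <- attr(ds, "design")
  expected <- d$n_genotypes * d$n_conditions * d$n_years * d$n_reps
  nrow(sub) == expected &&
    !anyDuplicated(paste(sub$genotype, sub$condition, sub$year, sub$rep))
}

#' Read a plot-level trial table from delimited text
#'
#' Reads either the canonical long format (header
#' `genotype,condition,year,rep,block,trait,value`) or a wide format in which
#' every non-key column is a trait. Column names can be remapped via
#' `dialect`, so files using e.g. `entry` for the genotype column load without
#' editing.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect named list mapping canonical names (`genotype`, `condition`,
#'   `year`, `rep`, `block`, `trait`, `value`) to the column names used in the
#'   file; unmentioned names are looked up as-is.
#' @param sep field separator, comma by default.
#' @return A [trial_data] object.
#' @export
read_trial_csv <- function(path, dialect = list(), sep = ",") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  canon <- c("genotype", "condition", "year", "rep", "block", "trait", "value")
  colmap <- vapply(canon, function(nm) dialect[[nm]] %||% nm, character(1))
  for (nm in c("genotype", "condition", "year", "rep")) {
    if (!colmap[[nm]] %in% names(raw)) {
      stopf("input lacks required column '%s'%s", colmap[[nm]],
            if (colmap[[nm]] != nm) sprintf(" (mapped from '%s')", nm) else "")
    }
  }
  keys <- data.frame(genotype  = raw[[colmap[["genotype"]]]],
                     condition = raw[[colmap[["condition"]]]],
                     year      = raw[[colmap[["year"]]]],
                     rep       = raw[[colmap[["rep"]]]],
                     stringsAsFactors = FALSE)
  if (colmap[["block"]] %in% names(raw)) {
    keys$block <- raw[[colmap[["block"]]]]
  }
  long_in <- colmap[["trait"]] %in% names(raw) &&
    colmap[["value"]] %in% names(raw)
  if (long_in) {
    keys$trait <- raw[[colmap[["trait"]]]]
    keys$value <- raw[[colmap[["value"]]]]
    return(trial_data(keys))
  }
  trait_cols <- setdiff(names(raw), colmap)
  if (length(trait_cols) == 0) {
    stopf("input has no trait columns (and no '%s'/'%s' long-format pair)",
          colmap[["trait"]], colmap[["value"]])
  }
  pieces <- lapply(trait_cols, function(tc) {
    k <- keys
    k$trait <- tc
    k$value <- raw[[tc]]
    k
  })
  trial_data(do.call(rbind, pieces))
}

#' Write a trial dataset as canonical long-format CSV
#'
#' Values are written with 17 significant digits so that
#' `read_trial_csv(write_trial_csv(ds))` reproduces every double exactly.
#'
#' @param ds a `trial_data` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(ds, path) {
  out <- as.data.frame(ds)
  out$value <- ifelse(is.na(out$value), "",
                      sprintf("%.17g", out$value))
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standardize a harvested plot mass to grams per square metre
#'
#' Field plots here harvest a fixed sampled area (0.40 m2 for two 1.0 m rows
#' at 0.20 m spacing), so per-plot grain and biological mass are divided by
#' the harvested area (equivalently multiplied by 2.5) to report yields on a
#' g/m2 basis.
#'
#' @param raw_mass harvested mass in grams (vectorized).
#' @param harvested_area harvested area in m2; must be positive.
#' @return Yield in g/m2.
#' @examples
#' standardize_yield(100, 0.40)  # 250 g/m2
#' @export
standardize_yield <- function(raw_mass, harvested_area = 0.40) {
  if (any(harvested_area <= 0)) stopf("harvested_area must be positive")
  raw_mass / harvested_area
}

#' Harvest index of a plot
#'
#' HI = 100 * GY / BY, the percentage of biological yield partitioned into
#' grain. Computed per plot and then averaged across plots (the per-plot mean
#' differs from the ratio of condition means whenever yields vary: Jensen's
#' inequality).
#'
#' @param gy grain yield, g/m2 (vectorized).
#' @param by biological yield, g/m2; must be positive.
#' @return HI in percent. Plots with `gy > by` are biologically implausible;
#'   a warning is raised but the value is still returned.
#' @export
harvest_index <- function(gy, by) {
  if (any(by == 0)) stopf("biological yield of zero: harvest index undefined")
  if (any(gy < 0, na.rm = TRUE)) stopf("grain yield must be non-negative")
  if (any(gy > by, na.rm = TRUE)) {
    warnf("%d plot(s) have GY > BY (harvest index above 100%%)",
          sum(gy > by, na.rm = TRUE))
  }
  100 * gy / by
}

#' Per-genotype condition means of a trait
#'
#' Averages a trait over years and replicates within each condition, giving
#' the per-genotype normal-condition mean (YP) and stress mean (YS) plus the
#' panel means XP and XS (unweighted means of the genotype means). These are
#' the inputs of every stress tolerance index.
#'
#' @param ds a `trial_data` object.
#' @param trait trait code, `"GY"` by default.
#' @return A data.frame of class `yield_summary` with columns `genotype`,
#'   `YP`, `YS` and attributes `XP`, `XS`, `trait`, and `excluded` (a
#'   character vector of genotypes missing a condition entirely, reported
#'   rather than silently dropped).
#' @export
genotype_condition_means <- function(ds, trait = "GY") {
  sub <- ds[ds$trait == trait & !is.na(ds$value), , drop = FALSE]
  if (nrow(sub) == 0) stopf("trait '%s' has no non-missing records", trait)
  m <- tapply(sub$value, list(sub$genotype, sub$condition), mean)
  if (!all(c("normal", "stress") %in% colnames(m))) {
    stopf("trait '%s' is not observed under both conditions", trait)
  }
  yp <- m[, "normal"]
  ys <- m[, "stress"]
  excluded <- rownames(m)[is.na(yp) | is.na(ys)]
  keep <- !(rownames(m) %in% excluded)
  out <- data.frame(genotype = rownames(m)[keep],
                    YP = unname(yp[keep]), YS = unname(ys[keep]),
                    stringsAsFactors = FALSE)
  structure(out,
            XP = mean(out$YP), XS = mean(out$YS),
            trait = trait, excluded = excluded,
            class = c("yield_summary", "data.frame"))
}

#' Assemble a yield summary from explicit values
#'
#' Builds the same object [genotype_condition_means()] returns, from already
#' summarized per-genotype means — e.g. published panel tables. Panel means
#' `XP`/`XS` may be supplied explicitly when they come from a larger panel
#' than the genotypes listed.
#'
#' @param genotype genotype identifiers.
#' @param YP per-genotype mean yield under normal sowing, g/m2.
#' @param YS per-genotype mean yield under stress, g/m2.
#' @param XP,XS panel mean yields; default to the means of `YP`/`YS`.
#' @return A `yield_summary` data.frame.
#' @export
yield_summary <- function(genotype, YP, YS,
                          XP = mean(YP), XS = mean(YS)) {
  stopifnot(length(genotype) == length(YP), length(YP) == length(YS))
  if (any(c(YP, YS) < 0, na.rm = TRUE)) stopf("yields must be non-negative")
  structure(data.frame(genotype = as.character(genotype),
                       YP = YP, YS = YS, stringsAsFactors = FALSE),
            XP = XP, XS = XS, trait = "GY", excluded = character(0),
            class = c("yield_summary", "data.frame"))
}

#' Percent reduction of a trait mean under stress
#'
#' @param mean_normal trait mean under normal sowing; must be positive.
#' @param mean_stress trait mean under heat stress.
#' @return 100 * (mean_normal - mean_stress) / mean_normal. Negative when the
#'   trait increased under stress.
#' @examples
#' mean_reduction(899, 674)  # ~25% grain-yield loss
#' @export
mean_reduction <- function(mean_normal, mean_stress) {
  if (any(mean_normal == 0)) stopf("mean_normal of zero: reduction undefined")
  if (any(mean_normal < 0)) stopf("mean_normal must be positive")
  100 * (mean_normal - mean_stress) / mean_normal
}

#' Per-condition trait means and stress-induced reductions
#'
#' Condition-level summary across the whole panel: per-trait means under each
#' condition, between-genotype standard deviations of the genotype means, and
#' the percent mean reduction under stress.
#'
#' @param ds a `trial_data` object.
#' @param traits trait codes; all traits by default.
#' @return data.frame with columns `trait`, `mean_normal`, `sd_normal`,
#'   `mean_stress`, `sd_stress`, `reduction_pct`.
#' @export
condition_summary <- function(ds, traits = NULL) {
  traits <- traits %||% attr(ds, "traits")$code
  rows <- lapply(traits, function(tr) {
    gm <- genotype_condition_means(ds, tr)
    data.frame(trait = tr,
               mean_normal = attr(gm, "XP"),
               sd_normal = stats::sd(gm$YP),
               mean_stress = attr(gm, "XS"),
               sd_stress = stats::sd(gm$YS),
               reduction_pct = mean_reduction(attr(gm, "XP"), attr(gm, "XS")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
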