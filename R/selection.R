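# Key-parameter selection: aggregate features per cellularity level,
# correlate level means with TC, cross-check with the lasso, drop
# redundancies and rank.

.featureColumnsOf <- function(table) {
  drop <- c("patch_id", "nucleus", "tc_label")
  setdiff(names(table)[vapply(table, is.numeric, TRUE)], drop)
}

#' Aggregate a labelled feature table by cellularity level
#'
#' Rows are snapped to the 11-point cellularity grid (0, 0.1, ..., 1.0)
#' when their `tc_label` lies within 0.025 of a grid point (others are
#' dropped), and each feature is summarised per level by its mean,
#' standard deviation, minimum and maximum.
#'
#' @param table feature table with a `tc_label` column (see
#'   [extractFeatureTable()]).
#' @param features feature column names (default: all numeric feature
#'   columns).
#' @return data.frame with columns `level`, `feature`, `mean`, `sd`,
#'   `min`, `max`.
#' @export
aggregateByTC <- function(table, features = NULL) {
  if (is.null(table$tc_label) || all(is.na(table$tc_label)))
    stop("table must carry tc_label values")
  if (is.null(features)) features <- .featureColumnsOf(table)
  tc <- table$tc_label
  grid <- round(tc * 10) / 10
  ok <- !is.na(tc) & abs(tc - grid) <= 0.025 + 1e-12
  table <- table[ok, , drop = FALSE]
  level <- grid[ok]
  if (length(unique(level)) < 3)
    stop("insufficient levels: need rows at >= 3 distinct cellularity levels")
  out <- lapply(features, function(f) {
    v <- table[[f]]
    data.frame(level = sort(unique(level)), feature = f,
               mean = as.numeric(tapply(v, level, mean)),
               sd = as.numeric(tapply(v, level, stats::sd)),
               min = as.numeric(tapply(v, level, min)),
               max = as.numeric(tapply(v, level, max)))
  })
  res <- do.call(rbind, out)
  res$sd[is.na(res$sd)] <- 0
  rownames(res) <- NULL
  res
}

#' Correlate level-mean features with cellularity
#'
#' Ordinary least squares of the per-level feature mean against the
#' cellularity level; `r` is the Pearson correlation of the same pairs.
#' A zero-variance feature gets `r = 0` and is flagged.
#'
#' @param summary output of [aggregateByTC()].
#' @return data.frame with columns `feature`, `r`, `slope`,
#'   `zero_variance`.
#' @export
correlateFeaturesToTC <- function(summary) {
  stopifnot(all(c("level", "feature", "mean") %in% names(summary)))
  feats <- unique(summary$feature)
  rows <- lapply(feats, function(f) {
    s <- summary[summary$feature == f, ]
    if (length(unique(s$level)) < 3)
      stop("insufficient levels for feature ", f)
    if (stats::sd(s$mean) < 1e-12)
      return(data.frame(feature = f, r = 0, slope = 0,
                        zero_variance = TRUE))
    slope <- stats::cov(s$level, s$mean) / stats::var(s$level)
    data.frame(feature = f, r = stats::cor(s$level, s$mean),
               slope = slope, zero_variance = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Lasso cross-check of feature relevance
#'
#' L1-regularised linear regression of `tc_label` on the z-scored
#' features (`glmnet`), with the penalty chosen by seeded 5-fold
#' cross-validation at `lambda.min`; selected features are those with a
#' non-zero coefficient there. With strongly correlated informative
#' features the parsimony-oriented one-standard-error rule prunes
#' redundant group members, so the minimum-CV-error penalty is used and
#' redundancy is handled explicitly downstream.
#'
#' @param table labelled feature table.
#' @param features feature column names (default: all).
#' @param seed integer seed for the CV fold assignment.
#' @return character vector of selected feature names.
#' @export
lassoSelect <- function(table, features = NULL, seed = 0) {
  if (is.null(features)) features <- .featureColumnsOf(table)
  y <- table$tc_label
  ok <- !is.na(y)
  X <- as.matrix(table[ok, features, drop = FALSE])
  y <- y[ok]
  keep <- apply(X, 2, stats::sd) > 1e-12
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) return(character())
  X <- scale(X)
  if (nrow(X) < 2 * ncol(X))
    warning("fewer than 2 rows per feature; lasso may be unstable")
  foldid <- .withSeed(seed, sample(rep(seq_len(5), length.out = nrow(X))))
  cv <- glmnet::cv.glmnet(X, y, alpha = 1, foldid = foldid)
  b <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
  names(b)[b != 0]
}

#' Select the key parameters most correlated with cellularity
#'
#' The selection procedure: aggregate per cellularity level
#' ([aggregateByTC()]), correlate level means with TC
#' ([correlateFeaturesToTC()]), cross-check with the lasso on the raw
#' rows ([lassoSelect()]). A feature is kept when `|r| >= rThreshold`
#' (0.80; sign-agnostic, since the strongest correlates of cellularity
#' are negative) *and* the lasso selected it; redundant features
#' (pairwise `|Pearson| > redundancyThreshold` on the raw columns) are
#' then pruned keeping the higher-`|r|` member. The result is ordered
#' by decreasing `|r|`.
#'
#' @param table labelled feature table.
#' @param rThreshold minimum `|r|` (default 0.80).
#' @param redundancyThreshold pairwise correlation above which two kept
#'   features are redundant (default 0.95).
#' @param seed seed forwarded to [lassoSelect()].
#' @param features feature column names (default: all).
#' @return a [SelectionResult].
#' @export
selectKeyParameters <- function(table, rThreshold = 0.80,
                                redundancyThreshold = 0.95, seed = 0,
                                features = NULL) {
  if (is.null(features)) features <- .featureColumnsOf(table)
  agg <- aggregateByTC(table, features)
  corr <- correlateFeaturesToTC(agg)
  lsel <- lassoSelect(table, features, seed = seed)
  corr$lasso <- corr$feature %in% lsel
  corr$kept <- abs(corr$r) >= rThreshold & corr$lasso
  # redundancy pruning among kept features, strongest |r| first
  kept <- corr$feature[corr$kept]
  if (length(kept) > 1) {
    ord <- kept[order(-abs(corr$r[match(kept, corr$feature)]))]
    X <- as.matrix(table[, ord, drop = FALSE])
    cm <- suppressWarnings(abs(stats::cor(X)))
    cm[is.na(cm)] <- 0
    retained <- character()
    for (f in ord) {
      if (!length(retained) ||
          all(cm[f, retained] <= redundancyThreshold))
        retained <- c(retained, f)
    }
    corr$kept <- corr$feature %in% retained
  }
  if (!any(corr$kept))
    warning("empty selection: no feature passed both criteria; ",
            "consider a top-k fallback by |r|")
  corr <- corr[order(-abs(corr$r)), ]
  rownames(corr) <- NULL
  new("SelectionResult",
      perFeature = corr[, c("feature", "r", "slope", "lasso", "kept")],
      tcLevels = sort(unique(agg$level)),
      nSelected = sum(corr$kept))
}

#' The canonical 22-parameter feature manifest
#'
#' Default feature subset used to train the nucleus classifiers without
#' re-running selection: five nucleus geometry parameters
#' (eccentricity, roundness, major/minor axis, perimeter), the regional
#' block at the 30-pixel window (nuclei density concentration and the
#' three 4-bin HSV histograms -- the smallest window correlates best
#' with cellularity), and four global parameters (mean V, nuclei and
#' background concentrations, and the stroma pink-filter mean).
#'
#' @return character vector of 22 feature column names.
#' @export
keyParameterSet <- function() {
  c("eccentricity", "roundness", "major_axis", "minor_axis", "perimeter",
    "conc_nuclei_w30",
    paste0("hist_h_b", 1:4, "_w30"),
    paste0("hist_s_b", 1:4, "_w30"),
    paste0("hist_v_b", 1:4, "_w30"),
    "global_mean_v", "global_conc_nuclei", "global_conc_background",
    "stroma_filter_mean")
}

#' Write a selection result to CSV and a feature manifest
#'
#' @param result a [SelectionResult].
#' @param csvPath path of the per-feature CSV (feature, r, slope,
#'   lasso, kept).
#' @param manifestPath optional path of a plain-text manifest listing
#'   the kept features, one per line (consumed by the classifier).
#' @return `csvPath`, invisibly.
#' @export
writeSelection <- function(result, csvPath, manifestPath = NULL) {
  utils::write.csv(result@perFeature, csvPath, row.names = FALSE)
  if (!is.null(manifestPath))
    writeLines(result@perFeature$feature[result@perFeature$kept],
               manifestPath)
  invisible(csvPath)
}
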