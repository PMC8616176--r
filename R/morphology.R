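# Morphology feature tables: reference robust-Z normalization, iterative
# variance/correlation feature reduction, and per-feature group testing.

feature_columns <- function(df) {
  setdiff(names(df), c("cell_id", "group"))
}

#' Robust-Z normalize features against a reference population
#'
#' Each feature is standardized to the median and MAD of the same feature in
#' the reference (drug-sensitive) cell population:
#' `z = (x - ref_median) / (1.4826 * ref_MAD)`. Features whose reference MAD
#' is (numerically) zero — below 1e-6 of the dataset's median feature MAD —
#' are flagged and centred but not scaled, so near-constant features keep
#' their near-zero variance and fall to [reduce_features()]' variance floor.
#' Rows with missing values are dropped and counted.
#'
#' @param table Data frame with `cell_id`, `group` and feature columns.
#' @param reference_group Label of the reference population (>= 10 cells).
#' @return List with `normalized` (same layout, features on the robust-Z
#'   scale), `stats` (per-feature reference `median`, `mad_raw`, scaled
#'   `mad`, `zero_mad` flag) and `n_dropped`.
#' @export
robust_z_reference <- function(table, reference_group = "fusion_negative") {
  feats <- feature_columns(table)
  if (!length(feats)) stop_clonefit("no feature columns found")
  if (!reference_group %in% table$group)
    stop_clonefit("reference group '%s' absent from the table", reference_group)
  complete <- stats::complete.cases(table[feats])
  n_dropped <- sum(!complete)
  table <- table[complete, ]
  ref <- table[table$group == reference_group, feats, drop = FALSE]
  if (nrow(ref) < 10L)
    stop_clonefit("reference group needs at least 10 cells, has %d", nrow(ref))

  med <- vapply(ref, median, 1)
  mad_raw <- vapply(ref, function(x) median(abs(x - median(x))), 1)
  tol <- 1e-6 * max(median(mad_raw), .Machine$double.eps)
  zero_mad <- mad_raw <= tol
  scale <- ifelse(zero_mad, 1, 1.4826 * mad_raw)

  normalized <- table
  for (j in seq_along(feats)) {
    normalized[[feats[j]]] <- (table[[feats[j]]] - med[j]) / scale[j]
  }
  list(normalized = normalized,
       stats = data.frame(feature = feats, median = unname(med),
                          mad_raw = unname(mad_raw),
                          mad = unname(1.4826 * mad_raw),
                          zero_mad = unname(zero_mad),
                          stringsAsFactors = FALSE),
       n_dropped = n_dropped)
}

#' Iterative variance and correlation feature reduction
#'
#' Repeats until stable: (1) drop features whose variance is below
#' `var_floor` ("inactive"); (2) while any retained pair has
#' `|Pearson r| > corr_cut`, take the most correlated violating pair and drop
#' the member with the higher mean absolute correlation to all remaining
#' features (ties broken by feature name), logging the kept partner
#' ("redundant"). The retained set therefore contains no pair above the
#' correlation cut, and rerunning the reduction on its own output removes
#' nothing.
#'
#' @param table Normalized feature table (data frame with feature columns,
#'   e.g. the `normalized` element of [robust_z_reference()]), or a numeric
#'   matrix.
#' @param var_floor Variance floor on the normalized scale (default 1e-3).
#' @param corr_cut Absolute Pearson correlation cut (default 0.85).
#' @return An object of class `reduced_features`: `retained` (feature
#'   names), `removed` (data frame: `feature`, `reason` in
#'   `{inactive, redundant}`, `partner`).
#' @export
reduce_features <- function(table, var_floor = 1e-3, corr_cut = 0.85) {
  mat <- if (is.data.frame(table)) {
    as.matrix(table[feature_columns(table)])
  } else {
    as.matrix(table)
  }
  if (ncol(mat) < 2L) stop_clonefit("feature reduction needs >= 2 features")
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("feat_%03d", seq_len(ncol(mat)))

  removed <- data.frame(feature = character(0), reason = character(0),
                        partner = character(0), stringsAsFactors = FALSE)
  log_removal <- function(feature, reason, partner = NA_character_) {
    removed[nrow(removed) + 1L, ] <<- list(feature, reason, partner)
  }

  repeat {
    changed <- FALSE
    vars <- apply(mat, 2, var)
    inactive <- colnames(mat)[vars < var_floor]
    if (length(inactive)) {
      for (f in inactive) log_removal(f, "inactive")
      mat <- mat[, setdiff(colnames(mat), inactive), drop = FALSE]
      changed <- TRUE
    }
    if (ncol(mat) == 0L)
      stop_clonefit("all features removed; lower 'var_floor' or raise 'corr_cut'")
    if (ncol(mat) >= 2L) {
      cm <- abs(stats::cor(mat))
      diag(cm) <- 0
      while (max(cm) > corr_cut) {
        pair <- which(cm == max(cm), arr.ind = TRUE)[1, ]
        i <- rownames(cm)[pair[1]]; j <- colnames(cm)[pair[2]]
        mean_abs <- rowMeans(cm) * ncol(cm) / max(ncol(cm) - 1, 1)
        drop <- if (mean_abs[i] > mean_abs[j]) i
          else if (mean_abs[j] > mean_abs[i]) j
          else sort(c(i, j))[2]          # tie: drop the later name
        keep <- setdiff(c(i, j), drop)
        log_removal(drop, "redundant", keep)
        sel <- setdiff(colnames(cm), drop)
        cm <- cm[sel, sel, drop = FALSE]
        mat <- mat[, sel, drop = FALSE]
        changed <- TRUE
        if (ncol(mat) < 2L) break
      }
    }
    if (!changed) break
  }
  structure(list(retained = colnames(mat), removed = removed,
                 var_floor = var_floor, corr_cut = corr_cut),
            class = "reduced_features")
}

#' @export
print.reduced_features <- function(x, ...) {
  cat(sprintf("<reduced_features> %d retained, %d removed (%d inactive, %d redundant)\n",
              length(x$retained), nrow(x$removed),
              sum(x$removed$reason == "inactive"),
              sum(x$removed$reason == "redundant")))
  invisible(x)
}

#' Per-feature group difference tests
#'
#' Two-sided Welch t-test per feature on per-cell values, with
#' Benjamini-Hochberg adjusted p-values reported alongside the raw ones.
#' Features degenerate in both groups (zero variance) get p = 1 and a flag.
#'
#' @param table Normalized feature table with a `group` column (exactly 2
#'   groups, >= 3 cells each).
#' @param features Optional subset of feature names to test (e.g. the
#'   `retained` set of [reduce_features()]).
#' @return Data frame: `feature`, `statistic`, `p`, `p_adj`, `degenerate`.
#' @export
test_features <- function(table, features = NULL) {
  groups <- unique(table$group)
  if (length(groups) != 2L)
    stop_clonefit("test_features expects exactly 2 groups, found %d",
                  length(groups))
  if (any(tabulate(factor(table$group)) < 3L))
    stop_clonefit("each group needs at least 3 cells")
  feats <- features %||% feature_columns(table)
  g1 <- table$group == groups[1]
  rows <- lapply(feats, function(f) {
    a <- table[[f]][g1]; b <- table[[f]][!g1]
    if (var(a) == 0 && var(b) == 0) {
      return(data.frame(feature = f, statistic = 0, p = 1, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    tt <- t.test(a, b)
    data.frame(feature = f, statistic = unname(tt$statistic), p = tt$p.value,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[, c("feature", "statistic", "p", "p_adj", "degenerate")]
}
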