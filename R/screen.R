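# Multi-plate 384-well screen normalization and hit calling.

#' Normalize screen counts by per-plate control median fold change
#'
#' Batch correction: each well's count is divided by the median count of the
#' negative-control wells on the same plate, so a plate-wide multiplicative
#' distortion cancels exactly and the median control fold change per plate is
#' 1 by construction.
#'
#' @param wells Data frame in the plate dialect of [gen_screen()]: columns
#'   `plate_id`, `role` (`compound` / `negative_control`), `count`, plus
#'   `compound`, `dose_uM`, `cell_line` for the downstream hit rules.
#' @return An object of class `normalized_screen`: `wells` (input plus
#'   `fold_change`) and `plate_stats` (per-plate control median, MAD, n).
#' @export
normalize_plates <- function(wells) {
  need <- c("plate_id", "role", "count")
  if (!all(need %in% names(wells)))
    stop_clonefit("wells must have columns %s", paste(need, collapse = ", "))
  if (any(wells$count < 0)) stop_clonefit("counts must be non-negative")
  stats <- lapply(split(wells, wells$plate_id), function(p) {
    ctrl <- p$count[p$role == "negative_control"]
    if (!length(ctrl) || all(ctrl <= 0))
      stop_clonefit("plate '%s' has no usable negative-control wells",
                    p$plate_id[1])
    data.frame(plate_id = p$plate_id[1], ctrl_median = median(ctrl),
               ctrl_mad = mad(ctrl), n_ctrl = length(ctrl),
               stringsAsFactors = FALSE)
  })
  plate_stats <- do.call(rbind, stats)
  rownames(plate_stats) <- NULL
  wells$fold_change <- wells$count /
    plate_stats$ctrl_median[match(wells$plate_id, plate_stats$plate_id)]
  structure(list(wells = wells, plate_stats = plate_stats),
            class = "normalized_screen")
}

#' @export
print.normalized_screen <- function(x, ...) {
  cat(sprintf("<normalized_screen> %d wells on %d plates\n",
              nrow(x$wells), nrow(x$plate_stats)))
  print(x$plate_stats)
  invisible(x)
}

#' Robust Z-score against a reference population
#'
#' `z = (x - median) / (1.4826 * MAD)`, the normal-consistent robust
#' standardization. When the MAD is zero the standard deviation is used
#' instead (flagged); when both are zero all scores are 0 (flagged).
#'
#' @param x Numeric vector (>= 10 values).
#' @return List with `z`, `center`, `scale`, and `method` in
#'   `{"mad", "sd_fallback", "degenerate"}`.
#' @export
robust_z <- function(x) {
  if (length(x) < 10L) stop_clonefit("robust_z needs at least 10 values")
  center <- median(x)
  scale <- mad(x)          # stats::mad already applies the 1.4826 constant
  method <- "mad"
  if (scale == 0) {
    scale <- sd(x)
    method <- "sd_fallback"
  }
  if (is.na(scale) || scale == 0) {
    return(list(z = rep(0, length(x)), center = center, scale = 0,
                method = "degenerate"))
  }
  list(z = (x - center) / scale, center = center, scale = scale,
       method = method)
}

#' Attach dataset-wide robust Z-scores to a normalized screen
#'
#' Scores each compound well's fold change against all compound wells of the
#' same cell line (controls excluded from the reference population).
#'
#' @param norm A [normalize_plates()] result.
#' @return The `normalized_screen` with a `robust_z` column on compound wells
#'   (NA on controls) and a `z_method` per-cell-line attribute.
#' @export
screen_robust_z <- function(norm) {
  stopifnot(inherits(norm, "normalized_screen"))
  w <- norm$wells
  if (!"cell_line" %in% names(w)) w$cell_line <- "all"
  w$robust_z <- NA_real_
  methods <- character(0)
  for (line in unique(w$cell_line)) {
    idx <- which(w$cell_line == line & w$role == "compound")
    rz <- robust_z(w$fold_change[idx])
    w$robust_z[idx] <- rz$z
    methods[line] <- rz$method
  }
  norm$wells <- w
  attr(norm, "z_method") <- methods
  norm
}

#' Call primary screen hits by the <50\%-of-control rule
#'
#' A compound is a primary hit when its normalized count falls below
#' `threshold` (default 0.5, i.e. <50\% of the DMSO control) at one or more
#' doses in *every* required cell line. Compounds not measured in every
#' required line are excluded with a warning. Replicate wells are averaged
#' per compound x dose x line before thresholding.
#'
#' @param norm A [normalize_plates()] (or [screen_robust_z()]) result.
#' @param cell_lines Required cell lines (default: all lines present).
#' @param threshold Fold-change hit threshold.
#' @return Data frame per compound: `compound`, `primary_hit`,
#'   `n_lines_with_hit_dose`, `min_fold_change`.
#' @export
call_primary_hits <- function(norm, cell_lines = NULL, threshold = 0.5) {
  stopifnot(inherits(norm, "normalized_screen"))
  w <- norm$wells[norm$wells$role == "compound", ]
  if (is.null(cell_lines)) cell_lines <- unique(w$cell_line)
  prof <- aggregate(fold_change ~ compound + dose_uM + cell_line, data = w,
                    FUN = mean)
  rows <- lapply(split(prof, prof$compound), function(d) {
    present <- unique(d$cell_line)
    if (!all(cell_lines %in% present)) return(NULL)
    per_line_hit <- vapply(cell_lines, function(line)
      any(d$fold_change[d$cell_line == line] < threshold), TRUE)
    data.frame(compound = d$compound[1],
               primary_hit = all(per_line_hit),
               n_lines_with_hit_dose = sum(per_line_hit),
               min_fold_change = min(d$fold_change),
               stringsAsFactors = FALSE)
  })
  missing <- names(rows)[vapply(rows, is.null, TRUE)]
  if (length(missing))
    warning(sprintf("excluding %d compound(s) not measured in all required cell lines",
                    length(missing)), call. = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out[order(out$compound), ]
}

#' Nominate validation hits by the robust Z-score rule
#'
#' A compound is nominated when its robust Z-score is below `z_cut` (default
#' -2) at `min_doses` or more dose points. By default the per-line Z-scores
#' are first averaged across cell lines at each dose (`aggregate = "mean"`);
#' `aggregate = "per_line"` instead requires the criterion within every
#' single line.
#'
#' @param norm A [screen_robust_z()] result (must carry `robust_z`).
#' @param min_doses Minimum number of qualifying dose points (default 2).
#' @param z_cut Z-score cutoff (default -2).
#' @param aggregate `"mean"` or `"per_line"`.
#' @return Data frame per compound: `compound`, `nominated`,
#'   `n_doses_below_cut`, `min_z`.
#' @export
nominate_validation_hits <- function(norm, min_doses = 2, z_cut = -2,
                                     aggregate = c("mean", "per_line")) {
  stopifnot(inherits(norm, "normalized_screen"))
  aggregate <- match.arg(aggregate)
  w <- norm$wells[norm$wells$role == "compound", ]
  if (!"robust_z" %in% names(w) || all(is.na(w$robust_z)))
    stop_clonefit("run screen_robust_z() before nominating hits")
  prof <- stats::aggregate(robust_z ~ compound + dose_uM + cell_line,
                           data = w, FUN = mean)
  rows <- lapply(split(prof, prof$compound), function(d) {
    if (aggregate == "mean") {
      per_dose <- stats::aggregate(robust_z ~ dose_uM, data = d, FUN = mean)
      n_below <- sum(per_dose$robust_z < z_cut)
      minz <- min(per_dose$robust_z)
    } else {
      per_dose <- stats::aggregate(robust_z ~ dose_uM, data = d, FUN = max)
      n_below <- sum(per_dose$robust_z < z_cut)   # worst line must qualify
      minz <- min(per_dose$robust_z)
    }
    data.frame(compound = d$compound[1], nominated = n_below >= min_doses,
               n_doses_below_cut = n_below, min_z = minz,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$compound), ]
}
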