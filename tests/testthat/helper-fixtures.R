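# Shared fixture builders for the test suite. All synthetic data are built
# in code at test time; nothing is read from disk.

# Exact 4PL viability values over a log-spaced dose grid.
fourpl_values <- function(dose, top = 1, bottom = 0, hill = 1, ec50 = 10) {
  bottom + (top - bottom) / (1 + (dose / ec50)^hill)
}

log_dose_grid <- function(from = 0.1, to = 1000, n = 9) {
  10^seq(log10(from), log10(to), length.out = n)
}

# Counts for two clones differing only in division rate, with an identical
# per-division drug effect: x_c = x0 * (x_ctrl/x0)^gamma(d) where
# gamma(d) = log2(1 + GR(d)) and GR(d) is a shared GR dose curve. By
# construction both clones have the same GR curve (hence GR50) while their
# end-point viabilities (hence IC50s) differ with the number of divisions.
per_division_counts <- function(doses, doubling_h, duration_h = 72,
                                x0 = 100, gr_inf = -0.2, gec50 = 0.3) {
  k <- duration_h / doubling_h          # divisions over the treatment window
  x_ctrl <- x0 * 2^k
  gr_true <- gr_inf + (1 - gr_inf) / (1 + doses / gec50)
  gamma <- log2(1 + gr_true)
  list(x_c = x0 * (x_ctrl / x0)^gamma, x0 = x0, x_ctrl = x_ctrl,
       gr_true = gr_true)
}

# Small hand-built screen table: one value per compound x dose x line, one
# plate per line with 8 control wells.
manual_screen_table <- function(fold_matrix, doses, lines,
                                baseline = 1000) {
  stopifnot(length(dim(fold_matrix)) == 3)
  rows <- list()
  plate_no <- 0
  for (li in seq_along(lines)) {
    plate_no <- plate_no + 1
    plate_id <- sprintf("plate_%02d", plate_no)
    rows[[length(rows) + 1]] <- data.frame(
      plate_id = plate_id, well = sprintf("A%02d", 1:8),
      role = "negative_control", compound = NA_character_,
      dose_uM = NA_real_, cell_line = lines[li], count = baseline,
      stringsAsFactors = FALSE)
    for (ci in seq_len(dim(fold_matrix)[1])) {
      for (di in seq_along(doses)) {
        rows[[length(rows) + 1]] <- data.frame(
          plate_id = plate_id, well = sprintf("B%02d", ci * 10 + di),
          role = "compound", compound = sprintf("cmpd_%03d", ci),
          dose_uM = doses[di], cell_line = lines[li],
          count = baseline * fold_matrix[ci, di, li],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
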