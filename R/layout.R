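#' Row labels for a microtitre plate
#'
#' Letter-pair convention: A-Z then AA, AB, ... (a 1536-well plate uses
#' A-AF).
#'
#' @param n Number of rows.
#' @return Character vector of labels.
#' @export
plate_row_labels <- function(n = 32) {
  if (n < 1 || n > 52) stop_bad("`n` rows must be in 1..52")
  c(LETTERS, paste0("A", LETTERS))[seq_len(n)]
}

#' 1536-well screening plate layout with control columns
#'
#' The screening layout dedicates three control columns: column 1 carries a
#' positive-inhibitor (cambinol) dose series in 16 doses at 1:2 dilutions
#' from 285 uM (each dose in two adjacent rows), column 2 is the no-enzyme
#' negative control (background), column 3 the saturating positive control
#' (full uninhibited signal), and columns 4-48 hold test compounds. Every
#' well has exactly one role.
#'
#' @param n_rows,n_cols Plate dimensions (default 32 x 48 = 1536 wells).
#' @param pos_series_top Top concentration of the control dose series, uM.
#' @param pos_series_n Number of doses in the control series.
#' @param pos_series_dilution Fold dilution between consecutive doses.
#' @return An object of class `plate_layout` with a `wells` data frame
#'   (row, col, role, series_conc_um).
#' @export
plate_layout <- function(n_rows = 32, n_cols = 48, pos_series_top = 285,
                         pos_series_n = 16, pos_series_dilution = 2) {
  if (n_cols < 4) stop_bad("layout needs at least 4 columns")
  if (pos_series_n > n_rows) stop_bad("more control doses than rows")
  rows <- plate_row_labels(n_rows)
  wells <- expand.grid(row = rows, col = seq_len(n_cols),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  wells$role <- ifelse(wells$col == 1, "pos_series",
                ifelse(wells$col == 2, "neg_control",
                ifelse(wells$col == 3, "pos_control", "compound")))
  doses <- pos_series_top / pos_series_dilution^(seq_len(pos_series_n) - 1)
  # spread the dose series down column 1, each dose in n_rows/pos_series_n
  # consecutive wells
  rep_per_dose <- ceiling(n_rows / pos_series_n)
  series <- rep(doses, each = rep_per_dose)[seq_len(n_rows)]
  wells$series_conc_um <- NA_real_
  wells$series_conc_um[wells$col == 1] <- series
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 pos_series_doses = doses, wells = wells),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %d x %d (%d wells), %d-dose control series %g-%g uM\n",
              x$n_rows, x$n_cols, x$n_rows * x$n_cols,
              length(x$pos_series_doses), max(x$pos_series_doses),
              min(x$pos_series_doses)))
  invisible(x)
}

#' Number of test-compound wells in a layout
#' @param layout A [plate_layout()].
#' @return Integer count of wells with role "compound".
#' @export
n_compound_wells <- function(layout) {
  sum(layout$wells$role == "compound")
}

#' Primary-screen dose scheme
#'
#' Four doses starting at 57 uM with 5-fold dilutions (the primary qHTS
#' scheme), or any top/`n`/`fold` combination.
#'
#' @param top Top dose, uM.
#' @param n Number of doses.
#' @param fold Dilution factor.
#' @return Increasing numeric vector of doses, uM.
#' @export
dose_scheme <- function(top = 57, n = 4, fold = 5) {
  if (n < 1) stop_bad("dose scheme needs at least one dose")
  sort(top / fold^(seq_len(n) - 1))
}
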