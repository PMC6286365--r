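#' Z-prime plate quality statistic
#'
#' Z' = 1 - 3(sd_pos + sd_neg)/|mean_pos - mean_neg|, using sample (n-1)
#' standard deviations. Z' <= 1 always; values >= 0.5 conventionally denote
#' an excellent assay. Symmetric in the two arms and invariant under affine
#' rescaling applied to both.
#'
#' @param pos,neg RFU vectors for the positive and negative control arms
#'   (>= 2 values each).
#' @return Z' (dimensionless).
#' @examples
#' z_prime(c(2500, 2500), c(119, 119)) # 1: noiseless limit
#' @export
z_prime <- function(pos, neg) {
  if (length(pos) < 2 || length(neg) < 2) {
    stop_bad("each control arm needs >= 2 values")
  }
  mp <- mean(pos); mn <- mean(neg)
  if (mp == mn) stop_bad("control means are equal; separation undefined")
  1 - 3 * (stats::sd(pos) + stats::sd(neg)) / abs(mp - mn)
}

#' Signal-to-background ratio
#'
#' Ratio of positive-control to negative-control mean RFU.
#'
#' @inheritParams z_prime
#' @return mean(pos)/mean(neg).
#' @export
signal_to_background <- function(pos, neg) {
  mn <- mean(neg)
  if (!is.finite(mn) || mn <= 0) {
    stop_bad("negative-control mean must be > 0 for signal/background")
  }
  mean(pos) / mn
}

#' Positional-effect screen over the compound field
#'
#' Flags rows or columns whose median compound-well signal deviates from the
#' plate-wide compound-field median by more than `threshold` (a fraction,
#' default 20%). The screen is run per plate on compound-role wells
#' (including vehicle-only field wells).
#'
#' @param wells Well table from [simulate_plate()] / [read_plate_csv()].
#' @param threshold Allowed fractional deviation of a row/column median.
#' @return List with `flag` (TRUE if any deviation exceeds the threshold)
#'   and `deviations`, a data frame (plate_id, axis, index, median_rfu,
#'   rel_deviation, flagged).
#' @export
positional_effect <- function(wells, threshold = 0.2) {
  fld <- wells[wells$role == "compound", , drop = FALSE]
  if (nrow(fld) == 0) stop_bad("no compound-field wells to screen")
  res <- lapply(split(fld, fld$plate_id), function(p) {
    md <- stats::median(p$rfu)
    one_axis <- function(axis) {
      g <- split(p$rfu, p[[axis]])
      data.frame(plate_id = p$plate_id[1], axis = axis,
                 index = names(g),
                 median_rfu = vapply(g, stats::median, numeric(1)),
                 stringsAsFactors = FALSE)
    }
    rbind(one_axis("row"), one_axis("col"))
  })
  dev <- do.call(rbind, res)
  rownames(dev) <- NULL
  plate_median <- vapply(split(fld$rfu, fld$plate_id), stats::median,
                         numeric(1))
  dev$rel_deviation <- dev$median_rfu / plate_median[dev$plate_id] - 1
  dev$flagged <- abs(dev$rel_deviation) > threshold
  list(flag = any(dev$flagged), deviations = dev)
}

#' Per-plate quality-control summary
#'
#' Computes control-arm means and SDs, Z', signal/background and the
#' positional-effect flag for every plate in a well table. Uses the
#' saturating positive-control column as the positive arm and the no-enzyme
#' column as the negative arm (per-plate controls).
#'
#' @inheritParams positional_effect
#' @return Data frame with one row per plate: plate_id, pos_mean, pos_sd,
#'   neg_mean, neg_sd, z_prime, signal_to_background, positional_flag,
#'   pass (z_prime >= `z_min`).
#' @param z_min Z' pass threshold (default 0.5).
#' @export
plate_qc <- function(wells, threshold = 0.2, z_min = 0.5) {
  plates <- split(wells, wells$plate_id)
  out <- lapply(plates, function(p) {
    pos <- p$rfu[p$role == "pos_control"]
    neg <- p$rfu[p$role == "neg_control"]
    zp <- z_prime(pos, neg)
    data.frame(
      plate_id = p$plate_id[1],
      pos_mean = mean(pos), pos_sd = stats::sd(pos),
      neg_mean = mean(neg), neg_sd = stats::sd(neg),
      z_prime = zp,
      signal_to_background = signal_to_background(pos, neg),
      positional_flag = positional_effect(p, threshold)$flag,
      pass = zp >= z_min,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
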