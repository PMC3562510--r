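## Densitometry fold-change statistics and sorted-cell purity arithmetic.

#' Fold change of a U3 band between burn and no-burn arms
#'
#' Each lane's band density is normalized to its beta-actin density to give
#' a relative intensity; the fold change is the ratio of arm means
#' (burn / no-burn) and significance comes from a two-sided two-sample
#' Student's t-test on the relative intensities across experiments
#' (equal-variance by default, `var_equal = FALSE` for Welch). With
#' `mode = "ratio"` the test is instead a one-sample t-test of the
#' per-experiment burn/no-burn ratios against 1 (replicates paired by
#' `experiment_replicate`).
#'
#' Degenerate inputs follow explicit conventions: identical zero-variance
#' arms give p = 1 (no evidence of change), differing zero-variance arms
#' give p = 0; a zero no-burn mean leaves the fold undefined (`NA`) and
#' flagged, mirroring unmeasured low-expression bands.
#'
#' @param measurements data.frame with columns band_id, organ, cell_type,
#'   condition, experiment_replicate, band_density, actin_density.
#' @param band,organ,cell Selection of the matched band.
#' @param burn_condition Condition compared against `no_burn`.
#' @param var_equal Classic Student (TRUE, default) or Welch.
#' @param mode `"intensity"` (default) or `"ratio"`.
#' @return One-row data.frame: band_id, organ, cell_type, condition, fold,
#'   p, significant (p < 0.05), flag.
#' @export
fold_change <- function(measurements, band, organ, cell,
                        burn_condition = "burn_24h", var_equal = TRUE,
                        mode = c("intensity", "ratio")) {
  mode <- match.arg(mode)
  need <- c("band_id", "organ", "cell_type", "condition",
            "experiment_replicate", "band_density", "actin_density")
  stopifnot(all(need %in% names(measurements)))
  if (any(measurements$actin_density <= 0)) {
    stop("actin_density must be positive", call. = FALSE)
  }
  if (any(measurements$band_density < 0)) {
    stop("band_density must be non-negative", call. = FALSE)
  }
  sub <- measurements[measurements$band_id == band &
                        measurements$organ == organ &
                        measurements$cell_type == cell, , drop = FALSE]
  r <- sub$band_density / sub$actin_density
  r_burn <- r[sub$condition == burn_condition]
  r_ctrl <- r[sub$condition == "no_burn"]
  if (length(r_burn) < 2 || length(r_ctrl) < 2) {
    stop("need at least 2 replicates per arm", call. = FALSE)
  }
  flag <- ""
  if (mean(r_ctrl) == 0) {
    fold <- NA_real_
    flag <- "fold undefined: no-burn mean is zero"
    p <- NA_real_
  } else if (mode == "intensity") {
    fold <- mean(r_burn) / mean(r_ctrl)
    if (stats::sd(r_burn) == 0 && stats::sd(r_ctrl) == 0) {
      p <- if (mean(r_burn) == mean(r_ctrl)) 1 else 0
    } else {
      p <- stats::t.test(r_burn, r_ctrl, var.equal = var_equal)$p.value
    }
  } else {
    rep_burn <- sub$experiment_replicate[sub$condition == burn_condition]
    rep_ctrl <- sub$experiment_replicate[sub$condition == "no_burn"]
    common <- intersect(rep_burn, rep_ctrl)
    ratio <- r_burn[base::match(common, rep_burn)] /
      r_ctrl[base::match(common, rep_ctrl)]
    fold <- mean(ratio)
    if (stats::sd(ratio) == 0) {
      p <- if (fold == 1) 1 else 0
    } else {
      p <- stats::t.test(ratio, mu = 1)$p.value
    }
  }
  data.frame(band_id = band, organ = organ, cell_type = cell,
             condition = burn_condition, fold = fold, p = p,
             significant = !is.na(p) & p < 0.05, flag = flag,
             stringsAsFactors = FALSE)
}

#' Fold-change table over all matched bands
#'
#' Applies [fold_change()] to every (band, organ, cell) combination present
#' in both arms, adding a significance star column.
#'
#' @inheritParams fold_change
#' @return data.frame with one row per testable combination.
#' @export
fold_change_table <- function(measurements, burn_condition = "burn_24h",
                              var_equal = TRUE) {
  keys <- unique(measurements[, c("band_id", "organ", "cell_type")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    out <- tryCatch(
      fold_change(measurements, keys$band_id[i], keys$organ[i],
                  keys$cell_type[i], burn_condition, var_equal),
      error = function(e) NULL)
    out
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (!is.null(out)) out$star <- ifelse(out$significant, "*", "")
  out
}

#' Relative expression from qPCR cycle thresholds
#'
#' Delta-Ct quantification against the beta-actin control:
#' `efficiency^-(ct_target - ct_actin)` (efficiency 2 assumes perfect
#' doubling per cycle).
#'
#' @param ct_target,ct_actin Cycle thresholds.
#' @param efficiency Amplification efficiency (default 2).
#' @return Relative expression level(s).
#' @export
relative_expression <- function(ct_target, ct_actin, efficiency = 2) {
  efficiency^-(ct_target - ct_actin)
}

#' Relative purity of a sorted lymphocyte population
#'
#' Under the assumption that a sorted population contains only B- and
#' T-cells and that CD20 and Thy1 are exclusively expressed in B- and
#' T-cells respectively, the B-cell purity is `CD20 / (CD20 + Thy1)` and
#' the T-cell purity its complement (the two always sum to exactly 1).
#' Marker levels are beta-actin-normalized relative quantities (e.g. from
#' [relative_expression()]).
#'
#' @param cd20,thy1 Normalized marker levels (non-negative, not both zero).
#' @param cell_type `"B"` or `"T"`.
#' @return Purity fraction in `[0, 1]`.
#' @export
purity <- function(cd20, thy1, cell_type = c("B", "T")) {
  cell_type <- match.arg(cell_type)
  if (cd20 < 0 || thy1 < 0) stop("marker levels must be >= 0", call. = FALSE)
  if (cd20 + thy1 == 0) stop("both markers zero", call. = FALSE)
  if (cell_type == "B") cd20 / (cd20 + thy1) else thy1 / (cd20 + thy1)
}
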