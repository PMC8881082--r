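#' Null-model LLG from the low-quality tail of a score scatter
#'
#' For one evaluation unit, estimates the LLG that pure-noise models achieve,
#' by extrapolating the roughly linear low-GDT_HA region of the GDT_HA vs LLG
#' scatter to GDT_HA = 0. The procedure: bin the models into `n_bins`
#' equal-width GDT_HA bins; within each bin take an iteratively trimmed mean
#' (repeatedly dropping points with LLG more than `trim_sigma` SDs below the
#' current bin mean); keep the populated bins in the bottom `bottom_frac` of
#' the GDT_HA axis; of those, keep bins whose average lies within
#' `keep_sigma` SDs of the grand average of bin averages; sort the kept bins
#' by average LLG and take the middle `middle_frac`; fit a least-squares line
#' through the surviving (bin mean GDT_HA, bin mean LLG) points and return its
#' y-intercept.
#'
#' @param gdt_ha,llg paired vectors: GDT_HA (0-100 scale) and LLG per model.
#' @param n_bins number of equal-width bins over `gdt_range`.
#' @param bottom_frac fraction of the GDT_HA axis regarded as the noise floor.
#' @param trim_sigma within-bin trimming threshold (SDs below the mean).
#' @param keep_sigma across-bin outlier threshold (SDs of bin averages).
#' @param middle_frac central fraction of sorted bin averages kept for the
#'   line fit.
#' @param min_bins minimum populated bottom bins required.
#' @param gdt_range the GDT_HA axis (default the full 0-100 score range).
#' @return the y-intercept (nats).
#' @export
null_model_llg <- function(gdt_ha, llg, n_bins = 100, bottom_frac = 0.35,
                           trim_sigma = 1, keep_sigma = 3, middle_frac = 0.8,
                           min_bins = 5, gdt_range = c(0, 100)) {
  stopifnot(length(gdt_ha) == length(llg))
  edges <- seq(gdt_range[1], gdt_range[2], length.out = n_bins + 1)
  bin <- findInterval(gdt_ha, edges, rightmost.closed = TRUE, all.inside = TRUE)
  avg <- lapply(split(data.frame(g = gdt_ha, l = llg), bin), function(d) {
    repeat {                              # iterative 1-sigma lower trim
      m <- mean(d$l); s <- sd(d$l)
      if (is.na(s) || s == 0) break
      keep <- d$l >= m - trim_sigma * s
      if (all(keep)) break
      d <- d[keep, , drop = FALSE]
    }
    c(g = mean(d$g), l = mean(d$l))
  })
  bins <- data.frame(bin = as.integer(names(avg)), do.call(rbind, avg))
  bottom <- bins[bins$bin <= floor(bottom_frac * n_bins), , drop = FALSE]
  if (nrow(bottom) < min_bins)
    stop_rellg(sprintf("only %d populated bins in the bottom %.0f%% of GDT_HA (need %d)",
                       nrow(bottom), 100 * bottom_frac, min_bins), "null_undefined")
  grand <- mean(bottom$l); sdb <- sd(bottom$l)
  if (is.finite(sdb) && sdb > 0)
    bottom <- bottom[abs(bottom$l - grand) <= keep_sigma * sdb, , drop = FALSE]
  bottom <- bottom[order(bottom$l), , drop = FALSE]
  drop <- floor((1 - middle_frac) / 2 * nrow(bottom))
  if (drop > 0) bottom <- bottom[(drop + 1):(nrow(bottom) - drop), , drop = FALSE]
  if (nrow(bottom) < 2)
    stop_rellg("too few bins survive filtering to fit the null line", "null_undefined")
  unname(coef(lm(l ~ g, data = bottom))[1])
}

#' Difference LLG: score above the null-model baseline
#'
#' Subtracts the evaluation-unit-specific null-model LLG and floors at zero:
#' models scoring below the noise baseline (e.g. fully downweighted by huge
#' error estimates, or failed calculations) are assigned a score of zero.
#'
#' @param score LLG score (nats), vectorized.
#' @param null the null-model LLG for the same evaluation unit.
#' @return `pmax(score - null, 0)`.
#' @export
dllg <- function(score, null) pmax(score - null, 0)

#' Two-pass Z-score group ranking with outlier handling
#'
#' CASP-style ranking over a table of model scores. Per target, Z-scores of
#' the rank-1 model scores are computed from the mean and SD of all groups;
#' groups below -2 in that first pass are treated as outliers and the mean
#' and SD recomputed without them; final Z-scores (for all groups) are
#' floored at -2. A group's ranking score is the sum of its per-target
#' Z-scores, with a penalty of -2 for every target for which it submitted no
#' model.
#'
#' @param table data frame with columns `group`, `target`, `model` (rank
#'   within group, 1-5), `score`; extra columns are ignored. Only
#'   `model == 1` rows enter the ranking.
#' @param population_sd divide by n (TRUE, the default) rather than n-1.
#' @param z_floor the Z-score floor and outlier threshold.
#' @param missing_penalty penalty per missing (group, target).
#' @return an object of class `rellg_ranking`: list with `groups` (data frame
#'   `group`, `sum_z`, `n_missing`, sorted by `sum_z`), `z` (target x group
#'   matrix of floored Z-scores, NA where missing), and `degenerate_targets`
#'   (targets whose post-outlier SD was zero; their Z-scores are set to 0).
#' @export
zscore_ranking <- function(table, population_sd = TRUE, z_floor = -2,
                           missing_penalty = -2) {
  stopifnot(all(c("group", "target", "model", "score") %in% names(table)))
  t1 <- table[table$model == 1, , drop = FALSE]
  groups <- sort(unique(as.character(table$group)))
  targets <- sort(unique(as.character(table$target)))
  if (length(groups) < 2) stop_rellg("ranking needs at least 2 groups", "ranking")
  sdfun <- if (population_sd)
    function(x) sqrt(mean((x - mean(x))^2)) else sd
  z <- matrix(NA_real_, length(targets), length(groups),
              dimnames = list(targets, groups))
  degenerate <- character(0)
  for (tg in targets) {
    rows <- t1[as.character(t1$target) == tg, , drop = FALSE]
    if (nrow(rows) < 2) next
    x <- setNames(rows$score, as.character(rows$group))
    s1 <- sdfun(x)
    keep <- if (s1 > 0) (x - mean(x)) / s1 >= z_floor else rep(TRUE, length(x))
    m2 <- mean(x[keep]); s2 <- sdfun(x[keep])
    if (!is.finite(s2) || s2 == 0) {
      zi <- rep(0, length(x))
      degenerate <- c(degenerate, tg)
    } else {
      zi <- pmax((x - m2) / s2, z_floor)
    }
    z[tg, names(x)] <- zi
  }
  sum_z <- apply(z, 2, function(col) sum(col, na.rm = TRUE) +
                   missing_penalty * sum(is.na(col)))
  res <- data.frame(group = groups, sum_z = as.numeric(sum_z),
                    n_missing = as.integer(colSums(is.na(z))))
  res <- res[order(-res$sum_z), ]; rownames(res) <- NULL
  structure(list(groups = res, z = z, degenerate_targets = degenerate),
            class = "rellg_ranking")
}

#' @export
print.rellg_ranking <- function(x, ...) {
  cat(sprintf("Z-score ranking over %d targets, %d groups\n",
              nrow(x$z), ncol(x$z)))
  print(x$groups, row.names = FALSE)
  if (length(x$degenerate_targets))
    cat("targets with zero score spread (Z set to 0):",
        paste(x$degenerate_targets, collapse = ", "), "\n")
  invisible(x)
}
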