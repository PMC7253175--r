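#' Sidak multiplicity adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, monotone in `p` and never below the raw value.
#'
#' @param p Raw p-values.
#' @param m Number of contrasts in the family (default `length(p)`).
#' @return Adjusted p-values, capped at 1.
#' @export
sidak_adjust <- function(p, m = length(p)) pmin(1, 1 - (1 - p)^m)

as_tier_df <- function(x, group, prefix) {
  # accept a list of roi_summary objects or a data.frame(sample, tier, percent)
  if (is.data.frame(x)) {
    df <- x
    if (!all(c("sample", "tier", "percent") %in% names(df)))
      stop("data.frame input needs columns sample, tier, percent")
  } else {
    df <- do.call(rbind, lapply(seq_along(x), function(i) {
      s <- x[[i]]
      stopifnot(inherits(s, "roi_summary"))
      fr <- s$fractions[c("low", "mid", "high")]
      data.frame(sample = if (is.na(s$sample_id)) sprintf("%s%02d", prefix, i)
                          else s$sample_id,
                 tier = names(fr), percent = 100 * unname(fr))
    }))
  }
  df$group <- group
  df
}

#' Compare tier fractions between two groups
#'
#' Two-factor repeated-measures model (group between samples, tier
#' repeated within sample) fitted by split-plot ANOVA, with per-tier group
#' contrasts extracted via estimated marginal means and Sidak-adjusted
#' over the tier family. Effect sizes are differences of group means in
#' percentage points.
#'
#' @param a,b Per-group data: lists of [roi_summary()] objects, or
#'   data.frames with columns `sample`, `tier`, `percent`.
#' @param group_names Labels for the two groups.
#' @param alpha Significance level for the flags (default 0.05).
#' @return data.frame: `tier`, `estimate_pp` (a - b), `se`, `df`, `p_raw`,
#'   `p_adj`, `significant`.
#' @export
compare_tier_fractions <- function(a, b, group_names = c("A", "B"), alpha = 0.05) {
  da <- as_tier_df(a, group_names[1], "A")
  db <- as_tier_df(b, group_names[2], "B")
  if (length(unique(da$sample)) < 2 || length(unique(db$sample)) < 2)
    stop("need at least 2 samples per group")
  d <- rbind(da, db)
  d$group <- factor(d$group, levels = group_names)
  d$tier <- factor(d$tier, levels = c("low", "mid", "high"))
  d$sample <- factor(paste(d$group, d$sample, sep = ":"))
  # build the call with the data inlined so downstream re-evaluation by
  # emmeans does not depend on this function's environment
  fit <- do.call(stats::aov,
                 list(percent ~ group * tier + Error(sample), data = d))
  em <- suppressMessages(emmeans::emmeans(fit, ~ group | tier, data = d))
  ct <- summary(emmeans::contrast(em, "pairwise"), adjust = "none")
  out <- data.frame(tier = ct$tier, estimate_pp = ct$estimate, se = ct$SE,
                    df = ct$df, p_raw = ct$p.value,
                    p_adj = sidak_adjust(ct$p.value, nrow(ct)))
  out$significant <- out$p_adj < alpha
  out
}

profile_matrix <- function(profiles, tier) {
  mats <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "slice_profile"))
    sel <- p[p$tier == tier, ]
    stats::setNames(sel$percent, sel$slice)
  })
  slices <- names(mats[[1]])
  for (m in mats)
    if (!identical(names(m), slices)) stop("mismatched slice grids across samples")
  do.call(rbind, mats)
}

#' Slice-onset comparison along the metaphysis
#'
#' Reproduces the slice-arrow presentation: each slice's tier fraction is
#' contrasted against the baseline slice at one end of the region (paired
#' across samples within one group, or two-sample between groups), p-values
#' are Sidak-adjusted over the tested slices, and the onset is where
#' significance begins. With `baseline = "distal"` the reference is the
#' first (growth-plate) slice and the reported onset is the first
#' significant slice scanning away from it.
#'
#' Slices with missing fractions (zero cross-sectional area) are dropped
#' pairwise; their reduced `n` is recorded.
#'
#' @param profiles List of [slice_profile()] data.frames (one per sample).
#' @param profiles_b Optional second group for a between-group per-slice
#'   comparison; default `NULL` compares slices within `profiles`.
#' @param tier Tier to compare (`"low"`, `"mid"` or `"high"`).
#' @param baseline `"distal"` (first slice) or `"proximal"` (last slice);
#'   within-group mode only.
#' @param alpha Significance level.
#' @return A `slice_comparison`: `table` (slice, estimate_pp, sem, n,
#'   p_raw, p_adj, significant), `onset_first`, `onset_last`, `mode`,
#'   `tier`, `alpha`.
#' @export
slice_onset <- function(profiles, profiles_b = NULL, tier = "high",
                        baseline = c("distal", "proximal"), alpha = 0.05) {
  baseline <- match.arg(baseline)
  M <- profile_matrix(profiles, tier)
  if (nrow(M) < 2) stop("need at least 2 samples per group")
  slices <- as.integer(colnames(M))
  ns <- ncol(M)

  if (is.null(profiles_b)) {
    ref_col <- if (baseline == "distal") 1L else ns
    test_cols <- setdiff(seq_len(ns), ref_col)
    D <- M[, test_cols, drop = FALSE] - M[, ref_col]
    n <- colSums(!is.na(D))
    mean_d <- colMeans(D, na.rm = TRUE)
    sd_d <- apply(D, 2, stats::sd, na.rm = TRUE)
    sem <- sd_d / sqrt(n)
    tstat <- mean_d / sem
    p <- 2 * stats::pt(-abs(tstat), pmax(n - 1, 1))
    p[n < 2] <- NA_real_
    tab <- data.frame(slice = slices[test_cols], estimate_pp = mean_d,
                      sem = sem, n = n, p_raw = p)
    mode <- sprintf("within-group vs %s baseline (slice %d)", baseline,
                    slices[ref_col])
  } else {
    B <- profile_matrix(profiles_b, tier)
    if (!identical(colnames(B), colnames(M))) stop("mismatched slice grids across groups")
    if (nrow(B) < 2) stop("need at least 2 samples per group")
    na <- colSums(!is.na(M)); nb <- colSums(!is.na(B))
    ma <- colMeans(M, na.rm = TRUE); mb <- colMeans(B, na.rm = TRUE)
    va <- apply(M, 2, stats::var, na.rm = TRUE); vb <- apply(B, 2, stats::var, na.rm = TRUE)
    sem <- sqrt(va / na + vb / nb)
    tstat <- (ma - mb) / sem
    dfw <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tstat), dfw)
    p[na < 2 | nb < 2] <- NA_real_
    tab <- data.frame(slice = slices, estimate_pp = ma - mb, sem = sem,
                      n = pmin(na, nb), p_raw = p)
    mode <- "between-group per slice"
  }
  m_tests <- sum(!is.na(tab$p_raw))
  tab$p_adj <- sidak_adjust(tab$p_raw, m_tests)
  tab$significant <- !is.na(tab$p_adj) & tab$p_adj < alpha
  sig <- tab$slice[tab$significant]
  out <- list(table = tab,
              onset_first = if (length(sig)) min(sig) else NA_integer_,
              onset_last = if (length(sig)) max(sig) else NA_integer_,
              mode = mode, tier = tier, alpha = alpha)
  class(out) <- "slice_comparison"
  out
}

#' @export
print.slice_comparison <- function(x, ...) {
  cat(sprintf("<slice_comparison> %s | tier %s | %d slices tested, %d significant at alpha = %g\n",
              x$mode, x$tier, sum(!is.na(x$table$p_raw)), sum(x$table$significant),
              x$alpha))
  if (!is.na(x$onset_first))
    cat(sprintf("  significance spans slices %d..%d\n", x$onset_first, x$onset_last))
  invisible(x)
}
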