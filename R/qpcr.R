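#' Delta-CT normalization
#'
#' `dct = ct_target - ct_reference`: the cycle-threshold of the target gene
#' normalized to the reference gene (the study used RPL13). Records with a
#' missing reference CT are skipped with a warning.
#'
#' @param records data.frame with columns `sample`, `group`, `ct_target`,
#'   `ct_reference` (CT values finite and > 0).
#' @return the input with rows with missing reference dropped and a `dct`
#'   column appended.
#' @export
delta_ct <- function(records) {
  need <- c("sample", "group", "ct_target", "ct_reference")
  if (!all(need %in% names(records)))
    stop("qPCR table needs columns ", paste(need, collapse = ", "))
  bad <- is.na(records$ct_reference)
  if (any(bad)) {
    warning(sum(bad), " record(s) without reference CT skipped: ",
            paste(utils::head(records$sample[bad], 5), collapse = ", "))
    records <- records[!bad, , drop = FALSE]
  }
  if (any(!is.finite(records$ct_target) | records$ct_target <= 0 |
            records$ct_reference <= 0))
    stop("CT values must be finite and > 0")
  records$dct <- records$ct_target - records$ct_reference
  records
}

#' Delta-delta-CT fold changes relative to a control group
#'
#' `ddct = dct_sample - mean(dct of the control group)` and
#' `fold = 2^(-ddct)` per sample. The control aggregate is the arithmetic
#' mean of the control-group delta-CT values (equivalently the geometric
#' mean on the linear scale), so the fold change of the control aggregate
#' is exactly 1. Group summaries report mean and SD of the per-sample
#' folds, the format of the study's figures.
#'
#' @param dcts a [delta_ct()] result.
#' @param control_group label of the control group (e.g. the CD25-negative
#'   sort gate or the bursa).
#' @return list with `per_sample` (data.frame: sample, group, dct, ddct,
#'   fold, control_group) and `summary` (data.frame per group: n,
#'   mean_fold, sd_fold).
#' @export
ddct_fold_change <- function(dcts, control_group) {
  if (!control_group %in% dcts$group)
    stop("unknown control group: ", control_group)
  ctrl <- mean(dcts$dct[dcts$group == control_group])
  per <- data.frame(sample = dcts$sample, group = dcts$group,
                    dct = dcts$dct, ddct = dcts$dct - ctrl,
                    stringsAsFactors = FALSE)
  per$fold <- 2^(-per$ddct)
  per$control_group <- control_group
  agg <- do.call(rbind, lapply(split(per, per$group), function(d)
    data.frame(group = d$group[1], n = nrow(d), mean_fold = mean(d$fold),
               sd_fold = stats::sd(d$fold), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  list(per_sample = per, summary = agg)
}

#' Map p-values to the study's significance stars
#'
#' @param p numeric p-values.
#' @return character: `***` for p <= 0.001, `**` for p <= 0.01, `*` for
#'   p <= 0.05, `""` otherwise.
#' @export
signif_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p <= 0.001, "***",
                              ifelse(p <= 0.01, "**",
                                     ifelse(p <= 0.05, "*", ""))))
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Fixed-effects one-way ANOVA followed by Tukey's honestly-significant-
#' difference pairwise comparisons (studentized range distribution), the
#' group-comparison procedure annotated in the study's figure legends.
#' Degenerate input with zero variance everywhere and equal group means
#' yields F = 0 and p = 1.
#'
#' @param values numeric response values (e.g. per-sample fold changes).
#' @param group group labels (>= 2 groups, >= 2 values per group).
#' @return list with `f_stat`, `p_omnibus`, and `pairwise` (data.frame:
#'   group pair, mean difference, Tukey-adjusted p, stars).
#' @export
anova_tukey <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (any(table(group) < 2)) stop("need >= 2 values per group")
  gm <- tapply(values, group, mean)
  within_var <- tapply(values, group, stats::var)
  if (all(within_var < 1e-300)) {
    if (max(gm) - min(gm) < 1e-12) {
      pairs <- t(utils::combn(levels(group), 2))
      pw <- data.frame(group1 = pairs[, 2], group2 = pairs[, 1],
                       diff = 0, p_tukey = 1, stars = "",
                       stringsAsFactors = FALSE)
      return(list(f_stat = 0, p_omnibus = 1, pairwise = pw))
    }
    stop("zero within-group variance with unequal means: F is unbounded")
  }
  fit <- stats::aov(values ~ group)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  # TukeyHSD rows follow combn(levels, 2) order as "second-first"
  pairs <- t(utils::combn(levels(group), 2))
  pw <- data.frame(group1 = pairs[, 2], group2 = pairs[, 1],
                   diff = tk[, "diff"], p_tukey = tk[, "p adj"],
                   stars = signif_stars(tk[, "p adj"]),
                   stringsAsFactors = FALSE)
  rownames(pw) <- NULL
  list(f_stat = an[["F value"]][1], p_omnibus = an[["Pr(>F)"]][1],
       pairwise = pw)
}
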