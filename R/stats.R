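#' Dose-response table of signature amplitudes
#'
#' Per-dose mean and standard error of the maximal calcium elevation.
#'
#' @param features feature table from [summarize_plate()] (needs `dose`
#'   and `delta_uM` columns).
#' @return data.frame with `dose`, `n`, `mean_delta_uM`, `se_uM`,
#'   `single_rep` (SE reported as 0 with a flag when n = 1), sorted by
#'   ascending dose.
#' @export
dose_response <- function(features) {
  stopifnot(is.data.frame(features),
            all(c("dose", "delta_uM") %in% names(features)))
  if (nrow(features) == 0L) stop("empty feature table")
  sp <- split(features$delta_uM, features$dose)
  doses <- as.numeric(names(sp))
  out <- data.frame(
    dose = doses,
    n = vapply(sp, length, integer(1)),
    mean_delta_uM = vapply(sp, mean, numeric(1)),
    se_uM = vapply(sp, function(x)
      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0,
      numeric(1)),
    single_rep = vapply(sp, function(x) length(x) == 1L, logical(1)),
    row.names = NULL)
  out[order(out$dose), , drop = FALSE]
}

#' Percent inhibition with Student's t test
#'
#' Inhibition of the maximal calcium elevation by a pre-treatment
#' (e.g. the plasma-membrane channel blocker La3+), computed on group
#' means: `100 * (1 - mean(treated) / mean(control))`, with an
#' equal-variance two-sample t test on the per-well amplitudes (Welch's
#' variant by flag).
#'
#' @param control,treated numeric vectors of per-well amplitudes (any
#'   consistent unit), or feature tables with a `delta_uM` column.
#' @param welch use Welch's unequal-variance t test.
#' @return list: `percent`, `p_value`, `statistic`, `df`, group means
#'   and sizes.
#' @export
percent_inhibition <- function(control, treated, welch = FALSE) {
  pull <- function(x)
    if (is.data.frame(x)) x$delta_uM else as.numeric(x)
  ctl <- pull(control); trt <- pull(treated)
  stopifnot(length(ctl) >= 1L, length(trt) >= 1L)
  if (mean(ctl) <= 0) stop("control mean amplitude must be positive")
  pct <- 100 * (1 - mean(trt) / mean(ctl))
  tt <- if (length(ctl) > 1L && length(trt) > 1L) {
    # zero within-group variance makes the t statistic degenerate
    tryCatch(stats::t.test(ctl, trt, var.equal = !welch),
             error = function(e) NULL)
  } else NULL
  list(percent = pct,
       p_value = if (is.null(tt)) NA_real_ else tt$p.value,
       statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
       mean_control = mean(ctl), mean_treated = mean(trt),
       n_control = length(ctl), n_treated = length(trt))
}

# Compact letter display from a logical "significantly different"
# matrix, groups ordered by decreasing mean: the classic insert-absorb
# sweep. Returns one letter string per group (in input order).
compact_letters <- function(sig, means) {
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  sets <- list()
  for (a in seq_len(k)) {
    i <- ord[a]; j <- a
    while (j < k) {
      cand <- ord[a:(j + 1L)]
      if (any(sig[cand, cand])) break
      j <- j + 1L
    }
    grp <- sort(ord[a:j])
    if (!any(vapply(sets, function(s) all(grp %in% s), logical(1))))
      sets[[length(sets) + 1L]] <- grp
  }
  lets <- character(k)
  for (s in seq_along(sets))
    for (g in sets[[s]])
      lets[g] <- paste0(lets[g], letters[s])
  lets
}

#' Leaf-section profile with ANOVA and Tukey letters
#'
#' Per-section mean and SE of the maximal calcium elevation along the
#' leaf blade, with a one-way ANOVA and Tukey HSD pairwise comparisons at
#' `alpha`; sections sharing no letter differ significantly. Letters are
#' assigned greedily from the highest mean. With fewer than two replicates
#' per section the letters are omitted (`NA`).
#'
#' @param features feature table from [summarize_plate()] (needs
#'   `section_id` and `delta_uM`).
#' @param alpha significance level of the Tukey comparisons.
#' @return data.frame with `section_id`, `n`, `mean_delta_uM`, `se_uM`,
#'   `letters`, ordered by section id.
#' @export
section_profile <- function(features, alpha = 0.05) {
  stopifnot(is.data.frame(features),
            all(c("section_id", "delta_uM") %in% names(features)))
  features <- features[!is.na(features$section_id), , drop = FALSE]
  sp <- split(features$delta_uM, features$section_id)
  if (length(sp) < 2L) stop("need >= 2 sections for a profile")
  ids <- names(sp)
  out <- data.frame(
    section_id = ids,
    n = vapply(sp, length, integer(1)),
    mean_delta_uM = vapply(sp, mean, numeric(1)),
    se_uM = vapply(sp, function(x)
      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0,
      numeric(1)),
    letters = NA_character_, row.names = NULL)
  # natural section order S1, S2, ..., S10
  num <- suppressWarnings(as.integer(sub("^S", "", out$section_id)))
  if (!anyNA(num)) out <- out[order(num), , drop = FALSE]
  if (all(out$n >= 2L)) {
    df <- data.frame(y = features$delta_uM,
                     g = factor(features$section_id, levels = out$section_id))
    fit <- stats::aov(y ~ g, data = df)
    mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
    k <- nrow(out)
    sig <- matrix(FALSE, k, k)
    if (mse > 0) {
      tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
      cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
      for (r in seq_len(nrow(tk))) {
        i <- match(cmp[[r]][1L], out$section_id)
        j <- match(cmp[[r]][2L], out$section_id)
        sig[i, j] <- sig[j, i] <- tk[r, "p adj"] < alpha
      }
    } else {
      # zero residual variance: any difference in means is significant
      sig <- outer(out$mean_delta_uM, out$mean_delta_uM,
                   function(a, b) abs(a - b) > 0)
    }
    out$letters <- compact_letters(sig, out$mean_delta_uM)
  }
  rownames(out) <- NULL
  out
}
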