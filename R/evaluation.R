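#' Confusion-matrix counts
#'
#' @param tp,fp,fn,tn Non-negative counts of true positives, false
#'   positives, false negatives and true negatives.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0)) stop("counts must be non-negative")
  structure(as.list(v), class = "confusion_counts")
}

#' Tally confusion counts from truth/prediction vectors
#'
#' @param truth,prediction Logical vectors (or vectors coercible to
#'   logical) with `TRUE` = wheeze, aligned by file.
#' @return A [confusion_counts()].
#' @export
tally_confusion <- function(truth, prediction) {
  truth <- as.logical(truth); prediction <- as.logical(prediction)
  stopifnot(length(truth) == length(prediction))
  confusion_counts(tp = sum(truth & prediction),
                   fp = sum(!truth & prediction),
                   fn = sum(truth & !prediction),
                   tn = sum(!truth & !prediction))
}

#' Sensitivity, specificity, PPV and NPV
#'
#' Each metric is reported only when its denominator is positive; a
#' zero-denominator metric is `NA` (undefined) while the others remain
#' defined.
#'
#' @param c A [confusion_counts()].
#' @return A `wheeze_metrics` object holding the four proportions; its
#'   print method shows percentages rounded half-up to one decimal.
#' @export
metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    sensitivity = safe(c$tp, c$tp + c$fn),
    specificity = safe(c$tn, c$tn + c$fp),
    ppv = safe(c$tp, c$tp + c$fp),
    npv = safe(c$tn, c$tn + c$fn),
    counts = c), class = "wheeze_metrics")
}

#' Metric value as a display percentage
#'
#' @param m A `wheeze_metrics` object.
#' @param which Metric name.
#' @return Percentage rounded half-up to one decimal (NA if undefined).
#' @export
metric_pct <- function(m, which) {
  round_half_up(m[[which]] * 100, 1)
}

#' @export
print.wheeze_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else
    sprintf("%.1f%%", round_half_up(v * 100, 1))
  cat(sprintf(paste0("Sensitivity %s (%d/%d)\nSpecificity %s (%d/%d)\n",
                     "PPV         %s (%d/%d)\nNPV         %s (%d/%d)\n"),
              fmt(x$sensitivity), x$counts$tp, x$counts$tp + x$counts$fn,
              fmt(x$specificity), x$counts$tn, x$counts$tn + x$counts$fp,
              fmt(x$ppv), x$counts$tp, x$counts$tp + x$counts$fp,
              fmt(x$npv), x$counts$tn, x$counts$tn + x$counts$fn))
  invisible(x)
}

# ---- Jonckheere-Terpstra trend test --------------------------------------

jt_statistic <- function(groups) {
  k <- length(groups)
  J <- 0
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    x <- groups[[i]]; y <- groups[[j]]
    cmp <- outer(x, y, "<")
    eqs <- outer(x, y, "==")
    J <- J + sum(cmp) + 0.5 * sum(eqs)
  }
  J
}

# exact null pmf of J for untied data: J is the convolution of independent
# Mann-Whitney counts U(n_1+...+n_{j-1}, n_j)
jt_exact_pmf <- function(sizes) {
  pmf <- 1
  off <- 0L
  m <- sizes[1]
  for (j in 2:length(sizes)) {
    nj <- sizes[j]
    u <- stats::dwilcox(0:(m * nj), m, nj)
    pmf <- stats::convolve(pmf, rev(u), type = "open")
    m <- m + nj
  }
  pmax(pmf, 0)  # FFT round-off
}

# full enumeration of group assignments (handles ties exactly)
jt_enum_pmf_values <- function(pool, sizes) {
  res <- new.env(); res$v <- numeric(0)
  recurse <- function(remaining, gi, acc) {
    if (gi > length(sizes)) { res$v <- c(res$v, jt_statistic(acc)); return() }
    cmb <- utils::combn(length(remaining), sizes[gi])
    for (ci in seq_len(ncol(cmb))) {
      sel <- cmb[, ci]
      recurse(remaining[-sel], gi + 1L,
              c(acc, list(remaining[sel])))
    }
  }
  recurse(pool, 1L, list())
  res$v
}

multinomial_count <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

#' Jonckheere-Terpstra test for an ordered trend across groups
#'
#' The statistic is the sum of pairwise Mann-Whitney counts over group
#' pairs in the stated order, with ties counted one half. For small samples
#' (total n at most `exact_max`) the p-value is exact: by convolution of
#' Mann-Whitney null distributions when the data are untied, by complete
#' enumeration of group assignments when tied (and the assignment count is
#' tractable). Otherwise a normal approximation with tie-corrected variance
#' and continuity correction is used. Degenerate data (every observation
#' equal) give p = 1 by convention.
#'
#' @param groups List of numeric vectors in increasing hypothesized order.
#' @param alternative `"two_sided"`, `"increasing"` or `"decreasing"`.
#' @param exact_max Largest total n for which an exact p-value is computed.
#' @return A list: `statistic`, `p_value`, `method`.
#' @export
jonckheere_terpstra <- function(groups,
                                alternative = c("two_sided", "increasing",
                                                "decreasing"),
                                exact_max = 12L) {
  alternative <- match.arg(alternative)
  if (!is.list(groups) || length(groups) < 2)
    stop("input error: need an ordered list of at least two groups")
  groups <- lapply(groups, as.numeric)
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("input error: empty group")
  pool <- unlist(groups)
  N <- length(pool)
  J <- jt_statistic(groups)

  if (length(unique(pool)) == 1L)
    return(list(statistic = J, p_value = 1, method = "degenerate"))

  has_ties <- anyDuplicated(pool) > 0
  if (N <= exact_max && (!has_ties || multinomial_count(sizes) <= 2e5)) {
    if (!has_ties) {
      pmf <- jt_exact_pmf(sizes)
      support <- seq_along(pmf) - 1
      p_ge <- sum(pmf[support >= J - 1e-9])
      p_le <- sum(pmf[support <= J + 1e-9])
    } else {
      vals <- jt_enum_pmf_values(pool, sizes)
      p_ge <- mean(vals >= J - 1e-9)
      p_le <- mean(vals <= J + 1e-9)
    }
    method <- "exact"
  } else {
    mu <- (N^2 - sum(sizes^2)) / 4
    t_sizes <- as.numeric(table(pool))
    s2 <- function(v) sum(v * (v - 1) * (2 * v + 5))
    s3 <- function(v) sum(v * (v - 1) * (v - 2))
    s4 <- function(v) sum(v * (v - 1))
    sig2 <- (N * (N - 1) * (2 * N + 5) - s2(sizes) - s2(t_sizes)) / 72 +
      s3(sizes) * s3(t_sizes) / (36 * N * (N - 1) * (N - 2)) +
      s4(sizes) * s4(t_sizes) / (8 * N * (N - 1))
    sig <- sqrt(sig2)
    p_ge <- stats::pnorm((J - mu - 0.5) / sig, lower.tail = FALSE)
    p_le <- stats::pnorm((J - mu + 0.5) / sig)
    method <- "normal approximation"
  }
  p <- switch(alternative,
              increasing = p_ge,
              decreasing = p_le,
              two_sided = min(1, 2 * min(p_ge, p_le)))
  list(statistic = J, p_value = min(1, max(0, p)), method = method)
}

# ---- corpus summaries ----------------------------------------------------

#' Summarise detected wheeze sounds across a corpus
#'
#' Groups each file's wheeze-labelled tracks into "wheeze sounds" (maximal
#' sets of temporally overlapping tracks) and reports, per wheeze sound,
#' the number of simultaneous local-maximum tracks, plus summary statistics
#' of track frequency, intensity margin and duration, and the
#' monophonic/polyphonic split.
#'
#' @param per_file List with one element per file, each a list holding
#'   `tracks` (a `candidate_tracks`) and `labels` (list of
#'   [classify_track()] results).
#' @return A list: `histogram` (named integer vector: tracks-per-sound
#'   counts), `n_sounds`, `stats` (data frame of mean/SD/range for
#'   frequency, margin and duration), `n_monophonic`, `n_polyphonic`.
#' @export
summarize_tracks <- function(per_file) {
  counts <- integer(0)
  freq <- numeric(0); marg <- numeric(0); dur <- numeric(0)
  for (f in per_file) {
    lab <- vapply(f$labels, function(l) l$label, character(1))
    s <- f$tracks$summary[lab == "wheeze", , drop = FALSE]
    if (nrow(s) == 0) next
    freq <- c(freq, s$mean_freq_hz)
    marg <- c(marg, s$mean_margin_db)
    dur <- c(dur, s$duration_ms)
    # cluster overlapping intervals into wheeze sounds
    o <- order(s$start_s)
    grp_end <- -Inf; sizes <- integer(0)
    for (i in o) {
      if (s$start_s[i] < grp_end) {
        sizes[length(sizes)] <- sizes[length(sizes)] + 1L
        grp_end <- max(grp_end, s$end_s[i])
      } else {
        sizes <- c(sizes, 1L)
        grp_end <- s$end_s[i]
      }
    }
    counts <- c(counts, sizes)
  }
  hist <- if (length(counts)) table(factor(counts, levels = seq_len(max(counts))))
          else table(integer(0))
  stat_row <- function(x) data.frame(mean = mean(x), sd = stats::sd(x),
                                     min = min(x), max = max(x))
  stats <- if (length(freq))
    cbind(quantity = c("freq_hz", "margin_db", "duration_ms"),
          rbind(stat_row(freq), stat_row(marg), stat_row(dur)))
  else data.frame(quantity = character(), mean = numeric(), sd = numeric(),
                  min = numeric(), max = numeric())
  list(histogram = as.integer(hist), n_sounds = length(counts),
       stats = stats,
       n_monophonic = sum(counts == 1L), n_polyphonic = sum(counts > 1L))
}

#' Rates from a tracks-per-wheeze-sound histogram
#'
#' @param counts Integer vector: `counts[k]` wheeze sounds had `k`
#'   simultaneous local-maximum tracks.
#' @return A list: `total` wheeze sounds, and a data frame `table` with
#'   `n_points`, `n_sounds`, `rate_pct` and `cum_rate_pct` (percentages
#'   rounded half-up to one decimal).
#' @export
track_count_summary <- function(counts) {
  total <- sum(counts)
  rate <- round_half_up(counts / total * 100, 1)
  list(total = total,
       table = data.frame(n_points = seq_along(counts), n_sounds = counts,
                          rate_pct = rate,
                          cum_rate_pct = round_half_up(
                            cumsum(counts) / total * 100, 1)))
}
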