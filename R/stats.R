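#' Wilcoxon rank-sum test (two-sided)
#'
#' Non-parametric two-sample comparison by rank sums, with midranks for ties.
#' For combined sample sizes up to 20 the p-value is exact, by enumerating all
#' assignments of the pooled midranks to the first sample; above that, the
#' normal approximation with tie and continuity corrections is used. Both
#' tails are counted via the doubling rule, capped at 1.
#'
#' @param a,b Numeric samples, each of size >= 2, all values finite.
#' @param exact_limit Combined sample size up to which the exact enumeration
#'   is used.
#' @return A list of class `rank_sum_test` with `statistic` (rank sum of
#'   `a`), `p_value`, `method` (`"exact"` or `"normal"`), and the sample
#'   sizes.
#' @export
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))$p_value  # exact 1/3
rank_sum_test <- function(a, b, exact_limit = 20L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 values", call. = FALSE)
  }
  if (any(!is.finite(c(a, b)))) stop("samples must be finite", call. = FALSE)
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both samples; p = 1", call. = FALSE)
    return(structure(list(statistic = sum(rank(pooled)[seq_len(na)]),
                          p_value = 1, method = "degenerate",
                          n_a = na, n_b = nb),
                     class = "rank_sum_test"))
  }
  r <- rank(pooled)  # midranks
  w <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  if (n <= exact_limit) {
    combos <- utils::combn(n, na)
    sums <- colSums(matrix(r[combos], nrow = na))
    # two-sided by doubling the smaller tail (midrank sums are symmetric
    # about mu under the null)
    lo <- mean(sums <= w + 1e-9)
    hi <- mean(sums >= w - 1e-9)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(w - mu) - 0.5) / sqrt(sigma2)  # continuity-corrected
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal"
  }
  structure(list(statistic = w, p_value = p, method = method,
                 n_a = na, n_b = nb),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat("Wilcoxon rank-sum test (", x$method, "): W = ", format(x$statistic),
      ", n = (", x$n_a, ", ", x$n_b, "), two-sided p = ",
      format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

signif_tier <- function(p) {
  ifelse(p < 1e-5, "*****",
         ifelse(p < 5e-5, "****",
                ifelse(p < 0.005, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Cohort summary statistics and pairwise tests
#'
#' Per-group mean and standard error (sample standard deviation over
#' `sqrt(n)`) for each metric, plus all pairwise two-sided rank-sum tests
#' between groups. Significance tiers follow the printed conventions
#' (`*` p < 0.05, `**` p < 0.005, `****` p < 0.00005, `*****` p < 0.00001).
#' No multiple-testing correction is applied; the number of uncorrected
#' contrasts is attached as attribute `n_contrasts` and flagged in a warning
#' field of the returned object.
#'
#' @param table Data frame with columns `animal_id`, `group`, `metric`,
#'   `value` (one value per animal and metric).
#' @return A list of class `cohort_summary` with `summary` (group x metric
#'   means and SEs), `pairwise` (contrast table with statistics, p-values and
#'   tiers) and `n_contrasts`.
#' @export
summarize_groups <- function(table) {
  need <- c("animal_id", "group", "metric", "value")
  if (!all(need %in% names(table))) {
    stop("table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(table[c("animal_id", "metric")])) {
    stop("one value per animal x metric required", call. = FALSE)
  }
  table$group <- as.character(table$group)
  counts <- table(unique(table[c("animal_id", "group")])$group)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning("excluding group(s) with n < 2: ", paste(small, collapse = ", "),
            call. = FALSE)
    table <- table[!table$group %in% small, , drop = FALSE]
  }
  groups <- sort(unique(table$group))
  metrics <- unique(table$metric)

  summ <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(groups, function(g) {
      v <- table$value[table$metric == m & table$group == g]
      data.frame(metric = m, group = g, n = length(v), mean = mean(v),
                 se = stats::sd(v) / sqrt(length(v)))
    }))
  }))

  pairs <- if (length(groups) >= 2L) utils::combn(groups, 2L) else
    matrix(character(), 2L, 0L)
  pw <- do.call(rbind, lapply(metrics, function(m) {
    if (!ncol(pairs)) return(NULL)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
      v1 <- table$value[table$metric == m & table$group == g1]
      v2 <- table$value[table$metric == m & table$group == g2]
      tst <- rank_sum_test(v1, v2)
      data.frame(metric = m, group1 = g1, group2 = g2,
                 statistic = tst$statistic, p_value = tst$p_value,
                 method = tst$method, signif = signif_tier(tst$p_value))
    }))
  }))

  if (is.null(summ)) {
    summ <- data.frame(metric = character(), group = character(),
                       n = integer(), mean = numeric(), se = numeric())
  }
  if (is.null(pw)) {
    pw <- data.frame(metric = character(), group1 = character(),
                     group2 = character(), statistic = numeric(),
                     p_value = numeric(), method = character(),
                     signif = character())
  }
  structure(list(summary = summ, pairwise = pw, n_contrasts = nrow(pw)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", length(unique(x$summary$group)), " groups, ",
      length(unique(x$summary$metric)), " metrics, ", x$n_contrasts,
      " uncorrected pairwise contrasts\n", sep = "")
  print(x$summary, row.names = FALSE)
  if (nrow(x$pairwise)) print(x$pairwise, row.names = FALSE)
  invisible(x)
}
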