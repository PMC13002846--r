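# Descriptive comorbidity-burden statistics and nonparametric group
# comparisons. The Kruskal-Wallis H and its p-value come from
# stats::kruskal.test (tie-corrected); the epsilon-squared effect size,
# Dunn's post-hoc z statistics and the Mann-Whitney U summary are
# computed here because base R does not expose them directly.

#' Summarise a distribution of per-patient comorbidity counts
#'
#' Median and quartiles by the inclusive linear-interpolation convention
#' (R's default quantile type 7), plus a histogram over observed values.
#'
#' @param counts non-empty numeric vector.
#' @return list with `n`, `median`, `p25`, `p75`, `min`, `max`,
#'   `histogram` (data frame `value`, `n`, `percent`).
#' @export
summarize_distribution <- function(counts) {
  stop_if(length(counts) == 0L, "counts must be non-empty")
  q <- stats::quantile(counts, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tab <- table(counts)
  list(n = length(counts),
       median = q[2], p25 = q[1], p75 = q[3],
       min = min(counts), max = max(counts),
       histogram = data.frame(value = as.numeric(names(tab)),
                              n = as.integer(tab),
                              percent = 100 * as.integer(tab) / length(counts)))
}

#' Mann-Whitney U test (normal approximation)
#'
#' U from midranks, two-sided p from the normal approximation with
#' tie-corrected variance and continuity correction. The reported
#' statistic is the smaller of U and `n_a n_b - U`, the usual tabled form.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @return list of class `group_comparison` with `test_name`,
#'   `statistic` (smaller U), `z`, `p_value`, group sizes.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  stop_if(length(group_a) == 0L || length(group_b) == 0L,
          "both groups must be non-empty")
  n1 <- length(group_a); n2 <- length(group_b)
  r <- rank(c(group_a, group_b))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u <- min(u1, n1 * n2 - u1)
  mu <- n1 * n2 / 2
  nn <- n1 + n2
  ties <- table(c(group_a, group_b))
  tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
  if (sigma2 <= 0) {
    z <- 0; p <- 1
  } else {
    # continuity-corrected z for the first group's U
    z <- (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(test_name = "mann_whitney_u", statistic = u, u_a = u1,
                 z = z, p_value = p, n = c(n1, n2)),
            class = "group_comparison")
}

#' Kruskal-Wallis test with Dunn-Holm post-hoc comparisons
#'
#' H and its chi-square p-value are delegated to [stats::kruskal.test()]
#' (tie-corrected). Effect size is `epsilon^2 = H / (N - 1)`. Pairwise
#' Dunn z statistics use the tie-corrected rank variance
#' `(N(N+1)/12 - sum(t^3 - t)/(12(N-1))) (1/n_i + 1/n_j)` with two-sided
#' normal p-values, Holm step-down adjusted.
#'
#' @param groups named list of at least two non-empty numeric vectors.
#' @return list of class `group_comparison` with `statistic` (H),
#'   `p_value`, `effect_size` (epsilon squared), `pairwise` (data frame
#'   `group_a`, `group_b`, `z`, `p_raw`, `p_adjusted`).
#' @export
kruskal_wallis_dunn <- function(groups) {
  stop_if(length(groups) < 2L, "need at least two groups")
  stop_if(any(lengths(groups) == 0L), "every group must be non-empty")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kw <- stats::kruskal.test(x, g)
  N <- length(x)
  H <- unname(kw$statistic)

  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  ties <- table(x)
  tie_adj <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    ni <- length(groups[[pr[1]]]); nj <- length(groups[[pr[2]]])
    se <- sqrt((N * (N + 1) / 12 - tie_adj) * (1 / ni + 1 / nj))
    z <- (mean_ranks[[pr[1]]] - mean_ranks[[pr[2]]]) / se
    data.frame(group_a = pr[1], group_b = pr[2], z = z,
               p_raw = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  pw$p_adjusted <- stats::p.adjust(pw$p_raw, method = "holm")
  rownames(pw) <- NULL
  structure(list(test_name = "kruskal_wallis_dunn",
                 statistic = H, p_value = kw$p.value,
                 effect_size = H / (N - 1),
                 pairwise = pw),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$test_name, ": statistic =", format(x$statistic),
      ", p =", format(x$p_value))
  if (!is.null(x$effect_size))
    cat(", epsilon^2 =", format(x$effect_size))
  cat("\n")
  invisible(x)
}
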