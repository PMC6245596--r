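#' Wilcoxon signed-rank test on paired frequency vectors
#'
#' Two-sided paired test on the differences `F2 - F`. Zero differences are
#' dropped (Wilcoxon's exclusion rule); if every difference is zero the
#' vectors are indistinguishable and the p-value is 1. With at most
#' `exact_limit` nonzero pairs the exact null distribution of the
#' signed-rank statistic is computed by convolution over the (mid)ranks —
#' ties included, which the textbook tables and [stats::wilcox.test()]'s
#' exact path do not handle — and otherwise a normal approximation with the
#' tie-corrected variance is used.
#'
#' High p-values mean the two frequency profiles are statistically alike;
#' low values mean the experiments distributed flux over the network
#' differently.
#'
#' @param F,F2 numeric frequency vectors of equal length, same reaction
#'   order.
#' @param exact_limit use the exact null for up to this many nonzero pairs
#'   (default 25).
#' @return The two-sided p-value, with attribute `pairs_used` = number of
#'   nonzero differences entering the statistic.
#' @export
wilcoxon_signed_rank <- function(F, F2, exact_limit = 25L) {
  if (length(F) != length(F2))
    stop("frequency vectors differ in length (", length(F), " vs ",
         length(F2), ")", call. = FALSE)
  d <- F2 - F
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(structure(1.0, pairs_used = 0L))
  r <- rank(abs(d))  # midranks under ties
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, W)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(p, pairs_used = n)
}

# Exact two-sided p-value of the signed-rank statistic for given (mid)ranks:
# convolve the 2^n equiprobable sign assignments over the doubled ranks
# (doubling makes midranks integral), then fold both tails at the observed W.
signed_rank_exact_p <- function(r, W) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- numeric(total + 1L)  # counts[v + 1] = #assignments with 2*W == v
  counts[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(total + 1L - ri)])
    counts <- counts + shifted
  }
  counts <- counts / 2^length(r2)
  w2 <- as.integer(round(2 * W))
  p_le <- sum(counts[seq_len(w2 + 1L)])
  p_ge <- sum(counts[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Chi-bar-squared divergence between two frequency vectors
#'
#' The chi-square-style statistic `sum_i (F2_i - F_i)^2 / F_i`, taken over
#' the reactions with `F_i > 0`; reactions the reference experiment never
#' used (`F_i = 0`) are skipped and their count reported, so
#' representativeness gaps stay visible instead of becoming masked
#' infinities. Larger values mean a larger difference between the two
#' experiments' frequency profiles. No p-value is attached: the reaction
#' frequencies are structurally dependent, so the statistic cannot be
#' referred to a chi-square distribution — it is a raw divergence measure.
#' Note it is not symmetric: `F` is the reference denominator.
#'
#' @param F reference frequency vector (denominator).
#' @param F2 comparison frequency vector.
#' @return The statistic (`>= 0`), with attributes `pairs_used` and
#'   `skipped`.
#' @export
chi_bar_squared <- function(F, F2) {
  if (length(F) != length(F2))
    stop("frequency vectors differ in length (", length(F), " vs ",
         length(F2), ")", call. = FALSE)
  use <- F > 0
  stat <- sum((F2[use] - F[use])^2 / F[use])
  structure(stat, pairs_used = sum(use), skipped = sum(!use))
}

#' Compare two extraction experiments' frequency tables
#'
#' Aligns the two tables by reaction id (they must cover the same reaction
#' universe — which in particular refuses to mix split-level with
#' merged-level tables) and computes both comparison statistics, echoing
#' each side's iteration count and penalization.
#'
#' @param a,b `frequency_table` objects (see [frequency_table()] /
#'   [read_frequency_tsv()]). `a` is the reference side for
#'   [chi_bar_squared()].
#' @return One-row data frame: `wilcoxon_p`, `chi_bar`,
#'   `pairs_used_wilcoxon`, `pairs_used_chibar`, `skipped_chibar`,
#'   `N_A`, `N_B`, `p_A`, `p_B`.
#' @export
compare_frequency_tables <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  only_a <- setdiff(a$reaction_id, b$reaction_id)
  only_b <- setdiff(b$reaction_id, a$reaction_id)
  if (length(only_a) || length(only_b))
    stop("frequency tables cover different reaction universes; ",
         "only in first: {", paste(only_a, collapse = ", "), "}; ",
         "only in second: {", paste(only_b, collapse = ", "), "}",
         call. = FALSE)
  meta <- list(N_A = attr(a, "N"), N_B = attr(b, "N"),
               p_A = attr(a, "p"), p_B = attr(b, "p"))
  b <- b[match(a$reaction_id, b$reaction_id), ]
  wp <- wilcoxon_signed_rank(a$frequency, b$frequency)
  cb <- chi_bar_squared(a$frequency, b$frequency)
  data.frame(wilcoxon_p = as.numeric(wp),
             chi_bar = as.numeric(cb),
             pairs_used_wilcoxon = attr(wp, "pairs_used"),
             pairs_used_chibar = attr(cb, "pairs_used"),
             skipped_chibar = attr(cb, "skipped"),
             N_A = as.numeric(meta$N_A %||% NA),
             N_B = as.numeric(meta$N_B %||% NA),
             p_A = as.numeric(meta$p_A %||% NA),
             p_B = as.numeric(meta$p_B %||% NA))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
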