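# Nonparametric cohort statistics: paired Wilcoxon signed-rank and
# Mann-Whitney U with exact small-sample p-values (shift-algorithm
# enumeration over the full permutation distribution, midranks for ties,
# zeros dropped), Friedman's test across the three aortic locations with an
# exact-permutation option, pairwise Wilcoxon follow-ups, and Pearson's
# chi-square for nominal data. Cohorts of the size studied here (around 20
# subjects) always take the exact paths at the default thresholds.

test_result <- function(test, statistic, p_value, n_effective, method, ...) {
  structure(list(test = test, statistic = statistic,
                 p_value = min(max(p_value, 0), 1),
                 n_effective = n_effective, method = method, ...),
            class = "aorta_test")
}

#' @export
print.aorta_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s, n = %d)\n",
              x$test, x$statistic, x$p_value, x$method, x$n_effective))
  invisible(x)
}

# distribution of the positive-rank sum over all 2^n sign assignments,
# on the doubled-rank integer lattice; returns counts indexed by sum 0..S
signed_rank_distribution <- function(r2) {
  S <- sum(r2)
  counts <- numeric(S + 1)
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(S + 1 - r)])
    counts <- counts + shifted
  }
  counts
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (Wilcoxon's original convention, as in
#' SPSS); absolute differences are ranked with midranks for ties. The
#' statistic is `W = min(W+, W-)`. For `n <= exact_threshold` the two-sided
#' p-value is exact over all `2^n` sign assignments (computed by the shift
#' algorithm, which agrees with brute-force enumeration); beyond that a
#' tie-corrected normal approximation is used.
#'
#' @param b,fu paired measurements (baseline and follow-up), equal length;
#'   alternatively supply `differences`
#' @param differences optional vector of paired differences (fu - b)
#' @param exact_threshold maximum n for the exact path (default 25)
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (direction of the mean difference)
#' @return an `aorta_test` result: statistic W, p-value, effective n,
#'   method label
#' @export
wilcoxon_signed_rank <- function(b = NULL, fu = NULL, differences = NULL,
                                 exact_threshold = 25,
                                 alternative = c("two.sided", "less",
                                                 "greater")) {
  alternative <- match.arg(alternative)
  if (is.null(differences)) {
    stopifnot(length(b) == length(fu))
    keep <- !is.na(b) & !is.na(fu)
    differences <- fu[keep] - b[keep]
  }
  d <- differences[differences != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate sample: all paired differences are zero")
  rk <- rank(abs(d))               # midranks
  wplus <- sum(rk[d > 0])
  wminus <- sum(rk[d < 0])
  W <- min(wplus, wminus)
  S <- sum(rk)
  if (n <= exact_threshold) {
    r2 <- as.integer(round(2 * rk))
    counts <- signed_rank_distribution(r2)
    total <- 2^n
    w2 <- round(2 * wplus)
    S2 <- sum(r2)
    p_le <- sum(counts[seq_len(w2 + 1)]) / total        # P(W+ <= obs)
    p_ge <- sum(counts[(w2 + 1):(S2 + 1)]) / total      # P(W+ >= obs)
    p <- switch(alternative,
      two.sided = {
        lo <- round(2 * min(wplus, wminus))
        sum(counts[seq_len(lo + 1)]) / total +
          sum(counts[(S2 - lo + 1):(S2 + 1)]) / total
      },
      greater = p_ge,
      less = p_le)
    method <- "exact"
  } else {
    mu <- S / 2
    sg <- sqrt(sum(rk^2) / 4)
    z <- (wplus - mu) / sg
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z))
    method <- "approximate"
  }
  test_result("Wilcoxon signed-rank", W, p, n, method,
              w_plus = wplus, w_minus = wminus)
}

# distribution of the group-A doubled rank sum over all C(N, nA) labelings
rank_sum_distribution <- function(r2, nA) {
  S <- sum(r2)
  f <- matrix(0, nA + 1, S + 1)
  f[1, 1] <- 1
  for (r in r2) {
    fj <- f
    for (j in seq(nA, 1)) {
      fj[j + 1, (r + 1):(S + 1)] <- f[j + 1, (r + 1):(S + 1)] +
        f[j, seq_len(S + 1 - r)]
    }
    f <- fj
  }
  f[nA + 1, ]
}

#' Mann-Whitney U test for two independent groups
#'
#' Pooled midranks; `U = min(U_A, U_B)`. For total `nA + nB <=
#' exact_threshold` the p-value is exact over all `choose(nA + nB, nA)`
#' group labelings; otherwise a tie-corrected normal approximation is used.
#'
#' @param a,b numeric vectors for the two groups
#' @param exact_threshold maximum total sample size for the exact path
#'   (default 20)
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (location of group `a` relative to `b`)
#' @return an `aorta_test` result
#' @export
mann_whitney_u <- function(a, b, exact_threshold = 20,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  nA <- length(a); nB <- length(b)
  if (nA == 0L || nB == 0L) stop("both groups must be nonempty")
  N <- nA + nB
  rk <- rank(c(a, b))
  RA <- sum(rk[seq_len(nA)])
  UA <- RA - nA * (nA + 1) / 2
  UB <- nA * nB - UA
  U <- min(UA, UB)
  if (N <= exact_threshold) {
    r2 <- as.integer(round(2 * rk))
    counts <- rank_sum_distribution(r2, nA)
    total <- choose(N, nA)
    base2 <- nA * (nA + 1)                      # doubled-U offset
    u2 <- round(2 * RA) - base2                 # doubled U_A
    idx_u <- function(u) u + base2 + 1          # doubled U -> counts index
    p_le <- sum(counts[seq_len(idx_u(u2))]) / total
    p_ge <- sum(counts[idx_u(u2):length(counts)]) / total
    p <- switch(alternative,
      two.sided = {
        lo2 <- round(2 * U)
        hi2 <- 2 * nA * nB - lo2
        sum(counts[seq_len(idx_u(lo2))]) / total +
          sum(counts[idx_u(hi2):length(counts)]) / total
      },
      greater = p_ge,
      less = p_le)
    method <- "exact"
  } else {
    tie_tab <- table(rk)
    sg <- sqrt(nA * nB / 12 *
                 (N + 1 - sum(tie_tab^3 - tie_tab) / (N * (N - 1))))
    z <- (UA - nA * nB / 2) / sg
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z))
    method <- "approximate"
  }
  test_result("Mann-Whitney U", U, p, N, method, U_A = UA, U_B = UB)
}

friedman_statistic <- function(colsum_r, n, k, tie_term) {
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  if (denom <= 0) return(0)
  12 * sum((colsum_r - n * (k + 1) / 2)^2) / denom
}

#' Friedman test across repeated locations
#'
#' Within-subject midranks; chi-square-distributed tie-corrected Friedman
#' statistic with `k - 1` degrees of freedom. For `k = 3` and `n <=
#' exact_max_n` an exact permutation p-value (full enumeration of
#' within-subject rank orderings via dynamic programming) is available.
#'
#' @param values n x k numeric matrix (subjects x conditions)
#' @param exact use the exact permutation distribution (k = 3 only)
#' @param exact_max_n largest n for the exact path (default 8)
#' @return an `aorta_test` result
#' @export
friedman_test <- function(values, exact = FALSE, exact_max_n = 8) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (k < 3L) stop("at least 3 conditions are required")
  if (n < 2L) stop("at least 2 subjects are required")
  r <- t(apply(values, 1, rank))
  tie_term <- sum(apply(r, 1, function(u) {
    tb <- table(u); sum(tb^3 - tb)
  }))
  Q <- friedman_statistic(colSums(r), n, k, tie_term)
  if (exact && k == 3L && n <= exact_max_n) {
    # enumerate within-subject orderings; the statistic depends only on the
    # column sums, so convolve their joint distribution subject by subject
    states <- list()  # key "r1_r2" (doubled) -> probability
    acc <- new.env(parent = emptyenv())
    assign("0_0", 1, envir = acc)
    for (i in seq_len(n)) {
      perms <- unique(t(apply(permutations3(), 1, function(p) r[i, p])))
      nxt <- new.env(parent = emptyenv())
      for (key in ls(acc)) {
        pr <- get(key, envir = acc)
        rr <- as.numeric(strsplit(key, "_")[[1]])
        for (j in seq_len(nrow(perms))) {
          k2 <- paste(rr[1] + round(2 * perms[j, 1]),
                      rr[2] + round(2 * perms[j, 2]), sep = "_")
          prev <- if (exists(k2, envir = nxt)) get(k2, envir = nxt) else 0
          assign(k2, prev + pr / nrow(perms), envir = nxt)
        }
      }
      acc <- nxt
    }
    tot_r <- sum(r)
    p <- 0
    for (key in ls(acc)) {
      rr <- as.numeric(strsplit(key, "_")[[1]]) / 2
      cs <- c(rr[1], rr[2], tot_r - rr[1] - rr[2])
      q <- friedman_statistic(cs, n, k, tie_term)
      if (q >= Q - 1e-9) p <- p + get(key, envir = acc)
    }
    return(test_result("Friedman", Q, p, n, "exact", df = k - 1))
  }
  p <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
  test_result("Friedman", Q, p, n, "chi-square approximation", df = k - 1)
}

permutations3 <- function() {
  matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
         ncol = 3, byrow = TRUE)
}

#' Pairwise Wilcoxon tests after a Friedman test
#'
#' Tests every pair of the three locations with the paired signed-rank test.
#' Unadjusted p-values are reported (matching common clinical practice for
#' post-hoc location comparisons); a Bonferroni column is available but off
#' by default. Degenerate pairs (all differences zero) are flagged and
#' assigned p = 1.
#'
#' @param values n x k numeric matrix (subjects x conditions)
#' @param labels condition labels (default column names or L1..Lk)
#' @param bonferroni add a Bonferroni-adjusted column
#' @param exact_threshold passed to [wilcoxon_signed_rank()]
#' @return data.frame with one row per pair
#' @export
pairwise_wilcoxon_after_friedman <- function(values, labels = NULL,
                                             bonferroni = FALSE,
                                             exact_threshold = 25) {
  values <- as.matrix(values)
  k <- ncol(values)
  if (is.null(labels)) labels <- colnames(values) %||% paste0("L", seq_len(k))
  pairs <- utils::combn(k, 2)
  res <- data.frame(pair = character(0), statistic = numeric(0),
                    p_value = numeric(0), n_effective = integer(0),
                    method = character(0), degenerate = logical(0))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    out <- tryCatch(
      wilcoxon_signed_rank(values[, i1], values[, i2],
                           exact_threshold = exact_threshold),
      error = function(e) NULL)
    if (is.null(out)) {
      res[nrow(res) + 1, ] <- list(paste(labels[i1], labels[i2], sep = " vs "),
                                   NA_real_, 1, 0L, "degenerate", TRUE)
    } else {
      res[nrow(res) + 1, ] <- list(paste(labels[i1], labels[i2], sep = " vs "),
                                   out$statistic, out$p_value,
                                   out$n_effective, out$method, FALSE)
    }
  }
  if (bonferroni) res$p_bonferroni <- pmin(1, res$p_value * nrow(res))
  res
}

#' Pearson chi-square test of independence for nominal data
#'
#' Pearson statistic without continuity correction against independence of
#' rows and columns; a small-expected-count flag is raised when any expected
#' cell count falls below 5.
#'
#' @param table r x c matrix of counts
#' @return an `aorta_test` result with `df` and `small_expected` fields
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column marginal")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  small <- any(ht$expected < 5)
  if (small)
    warning("some expected counts are below 5; chi-square approximation is weak")
  test_result("Chi-square", unname(ht$statistic), unname(ht$p.value),
              sum(table), "chi-square approximation",
              df = unname(ht$parameter), small_expected = small)
}
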