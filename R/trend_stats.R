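#' @title Trend statistics for ordered-group cohorts
#' @description Nonparametric battery used for ordered age groups: exact
#'   r x c contingency testing (Freeman-Halton) with pairwise Bonferroni
#'   follow-up, pairwise Mann-Whitney tests, the Jonckheere-Terpstra
#'   ordered-trend test, Kendall rank correlation (tau-b), and Shapiro-Wilk
#'   normality screening. All p-values are two-sided.
#' @name trend_stats
NULL

trend_result <- function(statistic_name, statistic, p_raw, z_value = NA_real_,
                         p_adjusted = NA_real_, n_per_group = integer(),
                         sidedness = "two", extra = NULL) {
  structure(list(statistic_name = statistic_name, statistic = statistic,
                 z_value = z_value, p_raw = p_raw, p_adjusted = p_adjusted,
                 n_per_group = n_per_group, sidedness = sidedness,
                 extra = extra),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> %s = %.4g", x$statistic_name, x$statistic))
  if (!is.na(x$z_value)) cat(sprintf(", z = %.4g", x$z_value))
  cat(sprintf(", p = %.4g (%s-sided)", x$p_raw, x$sidedness))
  if (!is.na(x$p_adjusted)) cat(sprintf(", p_adj = %.4g", x$p_adjusted))
  cat("\n")
  invisible(x)
}

# log hypergeometric probability of a completed r x c table given margins
log_table_prob <- function(lfact_cells, row_sums, col_sums) {
  sum(lfactorial(row_sums)) + sum(lfactorial(col_sums)) -
    lfactorial(sum(row_sums)) - lfact_cells
}

#' Freeman-Halton exact test for an r x c contingency table
#'
#' Exact generalization of Fisher's test to r x c tables: the two-sided p is
#' the total null (multivariate hypergeometric) probability of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (comparison tolerance 1e-12). Computed by exhaustive
#' enumeration over the fixed margins, feasible for the small tables of
#' group-level categorical comparisons.
#'
#' @param counts nonnegative integer matrix, rows = groups, columns =
#'   categories (e.g. positive / negative). All row sums must be positive.
#' @return a `trend_result` with `statistic` = the observed table
#'   probability and `p_raw` = the two-sided exact p. `extra$total_prob`
#'   holds the enumeration mass (equals 1 up to rounding).
#' @export
fisher_exact_rxc <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) stop("need at least 2 groups (rows)")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  row_sums <- rowSums(counts); col_sums <- colSums(counts)
  if (any(row_sums == 0)) stop("zero row sum: every group needs observations")
  logp_obs <- log_table_prob(sum(lfactorial(counts)), row_sums, col_sums)
  p_obs <- exp(logp_obs)

  R <- nrow(counts); C <- ncol(counts)
  acc <- new.env(parent = emptyenv())
  acc$p <- 0; acc$tot <- 0
  # enumerate rows 1..R-1 cell by cell; last row is fixed by the margins
  recurse_row <- function(i, col_left, lf) {
    if (i == R) {
      lp <- log_table_prob(lf + sum(lfactorial(col_left)), row_sums, col_sums)
      pr <- exp(lp)
      acc$tot <- acc$tot + pr
      if (pr <= p_obs + 1e-12) acc$p <- acc$p + pr
      return(invisible())
    }
    cells <- integer(C)
    recurse_cell <- function(j, left) {
      if (j == C) {
        if (left > col_left[C]) return(invisible())
        cells[C] <<- left
        recurse_row(i + 1L, col_left - cells, lf + sum(lfactorial(cells)))
        return(invisible())
      }
      hi <- min(left, col_left[j])
      for (v in 0:hi) {
        cells[j] <<- v
        recurse_cell(j + 1L, left - v)
      }
    }
    recurse_cell(1L, row_sums[i])
  }
  recurse_row(1L, col_sums, 0)
  trend_result("fisher_exact", statistic = p_obs, p_raw = min(acc$p, 1),
               n_per_group = row_sums,
               extra = list(total_prob = acc$tot, table = counts))
}

#' Pairwise Fisher exact tests with Bonferroni correction
#'
#' Runs the two-sided 2 x 2 Fisher exact test for every pair of groups and
#' multiplies each raw p by the number of pairs, K(K-1)/2, capping at 1.
#'
#' @param counts K x C integer matrix (K >= 3 rows).
#' @return list of `trend_result`s named `"<i>_vs_<j>"` by row name or index.
#' @export
pairwise_fisher_bonferroni <- function(counts) {
  counts <- as.matrix(counts)
  K <- nrow(counts)
  if (K < 3L) stop("pairwise follow-up needs at least 3 groups")
  m <- K * (K - 1) / 2
  nm <- rownames(counts) %||% as.character(seq_len(K))
  out <- list()
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    res <- fisher_exact_rxc(counts[c(i, j), , drop = FALSE])
    res$p_adjusted <- min(1, m * res$p_raw)
    out[[paste0(nm[i], "_vs_", nm[j])]] <- res
  }
  out
}

# U statistic: number of (x_i, y_j) pairs with x_i > y_j, plus half the ties
u_statistic <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact two-sided p for the Mann-Whitney U by dynamic programming over the
# permutation distribution of the (tie-averaged) rank sum; counts are exact
# in double precision for the sizes admitted (n1*n2 <= 400)
mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  ir <- as.integer(round(2 * rank(c(x, y))))  # doubled ranks are integers
  S <- sum(sort(ir, decreasing = TRUE)[seq_len(n1)])
  f <- matrix(0, n1 + 1L, S + 1L)  # f[k+1, s+1] = #subsets of size k, sum s
  f[1, 1] <- 1
  for (w in ir) {
    for (k in seq(n1, 1L)) {
      src <- f[k, seq_len(S + 1L - w)]
      f[k + 1L, (w + 1L):(S + 1L)] <- f[k + 1L, (w + 1L):(S + 1L)] + src
    }
  }
  counts <- f[n1 + 1L, ]
  s_vals <- which(counts > 0) - 1L                # doubled rank sums
  u_vals <- (s_vals - n1 * (n1 + 1L)) / 2         # corresponding U
  u_obs <- u_statistic(x, y)
  dev <- abs(u_obs - n1 * n2 / 2)
  sum(counts[counts > 0][abs(u_vals - n1 * n2 / 2) >= dev - 1e-9]) / choose(N, n1)
}

#' Mann-Whitney U test (tie-aware, exact for small samples)
#'
#' `U` counts the pairs where the first sample wins, plus half the tied
#' pairs, so `U + U' = n1 * n2`. The two-sided p comes from exhaustive
#' enumeration of the permutation distribution when `n1 * n2 <= 400`, and
#' from the tie-corrected normal approximation (with continuity correction)
#' otherwise. An optional Bonferroni multiplier yields `p_adjusted`.
#'
#' @param x,y numeric samples (both nonempty).
#' @param adjust_m Bonferroni multiplier (number of comparisons in the
#'   family; default 1 = no adjustment).
#' @return a `trend_result` with `statistic` = U.
#' @export
mann_whitney <- function(x, y, adjust_m = 1L) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  U <- u_statistic(x, y)
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- if (sig2 > 0) (U - mu - 0.5 * sign(U - mu)) / sqrt(sig2) else 0
  p <- if (n1 * n2 <= 400) mw_exact_p(x, y) else min(1, 2 * stats::pnorm(-abs(z)))
  trend_result("U", statistic = U, z_value = z, p_raw = p,
               p_adjusted = min(1, adjust_m * p), n_per_group = c(n1, n2))
}

# Jonckheere-Terpstra statistic: sum over ordered group pairs i < j of the
# number of (a in group i, b in group j) pairs with b > a, plus half the ties
jt_statistic <- function(groups) {
  K <- length(groups)
  jt <- 0
  for (i in seq_len(K - 1)) for (j in (i + 1):K)
    jt <- jt + u_statistic(groups[[j]], groups[[i]])
  jt
}

jt_moments <- function(groups) {
  n <- lengths(groups)
  N <- sum(n)
  pooled <- unlist(groups)
  t <- as.numeric(table(pooled))
  mu <- (N^2 - sum(n^2)) / 4
  v1 <- (N * (N - 1) * (2 * N + 5) - sum(n * (n - 1) * (2 * n + 5)) -
         sum(t * (t - 1) * (2 * t + 5))) / 72
  v2 <- sum(n * (n - 1) * (n - 2)) * sum(t * (t - 1) * (t - 2)) /
        (36 * N * (N - 1) * (N - 2))
  v3 <- sum(n * (n - 1)) * sum(t * (t - 1)) / (8 * N * (N - 1))
  list(mu = mu, sigma2 = v1 + v2 + v3)
}

#' Jonckheere-Terpstra test for an ordered trend across K groups
#'
#' Tests for a monotone trend in location across K >= 3 groups whose order
#' is fixed a priori (e.g. increasing age). The statistic is
#' `JT = sum_{i<j} U_ij`, where `U_ij` counts the pairs (a in group i,
#' b in group j) with `b > a` plus half the ties; under the null its
#' tie-corrected mean and variance give `z = (JT - mu) / sigma` and a
#' two-sided normal p. A decreasing trend across the declared order yields
#' `z < 0`. `mode = "permutation"` instead shuffles the pooled values across
#' groups (sizes preserved, seeded) and reports the two-sided permutation p.
#'
#' @param groups list of numeric samples in increasing group order, K >= 3,
#'   each nonempty.
#' @param mode `"normal_approx"` (default) or `"permutation"`.
#' @param n_perm number of permutations.
#' @param seed integer seed for permutation mode.
#' @return a `trend_result` with `statistic` = JT.
#' @export
jonckheere_terpstra <- function(groups, mode = c("normal_approx", "permutation"),
                                n_perm = 10000L, seed = NULL) {
  mode <- match.arg(mode)
  if (length(groups) < 3L) stop("the ordered-trend test needs K >= 3 groups")
  if (any(lengths(groups) == 0L)) stop("every group must be nonempty")
  jt <- jt_statistic(groups)
  mo <- jt_moments(groups)
  z <- if (mo$sigma2 > 0) (jt - mo$mu) / sqrt(mo$sigma2) else 0
  if (mode == "normal_approx") {
    p <- if (mo$sigma2 > 0) min(1, 2 * stats::pnorm(-abs(z))) else 1
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    pooled <- unlist(groups)
    sizes <- lengths(groups)
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    stat <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      perm <- sample(pooled)
      gp <- lapply(seq_along(sizes), function(i) perm[starts[i]:ends[i]])
      stat[b] <- jt_statistic(gp)
    }
    p_lo <- (1 + sum(stat <= jt)) / (1 + n_perm)
    p_hi <- (1 + sum(stat >= jt)) / (1 + n_perm)
    p <- min(1, 2 * min(p_lo, p_hi))
  }
  trend_result("JT", statistic = jt, z_value = z, p_raw = p,
               n_per_group = lengths(groups))
}

#' Kendall rank correlation (tau-b) between group rank and a value
#'
#' Quantifies the strength and direction of an ordered-group trend as the
#' tie-corrected Kendall coefficient tau-b between the per-observation group
#' rank (1 < 2 < ... < K, heavily tied by construction) and the measured
#' value, with a two-sided p from the tie-corrected normal approximation
#' (delegated to [stats::cor.test()]).
#'
#' @param group_ranks integer/numeric ordinal group rank per observation.
#' @param values numeric value per observation.
#' @return a `trend_result` with `statistic` = tau-b; when all values are
#'   identical tau is undefined and returned as `NA` with a warning.
#' @export
kendall_tau <- function(group_ranks, values) {
  if (length(group_ranks) != length(values)) stop("length mismatch")
  if (length(unique(group_ranks)) < 2L) stop("need >= 2 distinct group ranks")
  if (length(unique(values)) < 2L) {
    warning("all values identical: Kendall tau is undefined")
    return(trend_result("tau", statistic = NA_real_, p_raw = NA_real_,
                        n_per_group = as.integer(table(group_ranks))))
  }
  ct <- stats::cor.test(group_ranks, values, method = "kendall",
                        exact = FALSE, continuity = FALSE)
  trend_result("tau", statistic = unname(ct$estimate),
               z_value = unname(ct$statistic), p_raw = ct$p.value,
               n_per_group = as.integer(table(group_ranks)))
}

#' Shapiro-Wilk normality screen
#'
#' Thin wrapper over the standard Shapiro-Wilk implementation, used to
#' decide (at alpha = 0.05) whether parametric summaries are defensible;
#' the cohorts analyzed here invariably fail it, hence medians throughout.
#'
#' @param sample numeric vector, 3 <= n <= 5000.
#' @return a `trend_result` with `statistic` = W.
#' @export
normality_screen <- function(sample) {
  n <- length(sample)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  sw <- stats::shapiro.test(sample)
  trend_result("W_shapiro", statistic = unname(sw$statistic), p_raw = sw$p.value,
               n_per_group = n)
}

group_summary <- function(values, groups, levels) {
  do.call(rbind, lapply(levels, function(g) {
    v <- values[groups == g]
    v <- v[!is.na(v)]
    data.frame(group = g, n = length(v),
               median = if (length(v)) stats::median(v) else NA_real_,
               iqr = if (length(v)) stats::IQR(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_)
  }))
}

#' Full ordered-group cohort report
#'
#' Per-group descriptive summaries (n, median, IQR, maximum - medians
#' because the distributions are non-normal) for body count, mean diameter
#' and mean peak intensity, followed by the test battery in the standard
#' order: Shapiro-Wilk screen per group, pairwise Mann-Whitney with
#' Bonferroni correction, Jonckheere-Terpstra (by default only when the
#' group medians are monotone in the declared order - the "pattern
#' consistent with an ordered trend" gate - with `always_jt = TRUE` to
#' override), and Kendall tau on (group rank, value) pairs. The categorical
#' cytoplasmic-labeling flag is tested with the exact r x c test plus
#' pairwise Bonferroni follow-up.
#'
#' @param table cohort data.frame (as from [write_cohort_table()]'s schema);
#'   only `excluded = FALSE` rows are analyzed.
#' @param group_levels group levels in increasing order.
#' @param alpha significance level used in the printed report.
#' @param always_jt run the trend test regardless of the monotonicity gate.
#' @return list of class `cohort_report`.
#' @export
cohort_report <- function(table, group_levels = c("young", "middle", "old"),
                          alpha = 0.05, always_jt = FALSE) {
  if (nrow(table) == 0L) stop("empty cohort table")
  if (is.null(table$excluded)) table$excluded <- FALSE
  an <- table[!table$excluded, , drop = FALSE]
  if (nrow(an) == 0L) stop("no analysis rows after exclusions")
  present <- group_levels[group_levels %in% an$group]
  out <- list(group_levels = group_levels, alpha = alpha,
              n_analysis = nrow(an), n_excluded = sum(table$excluded))
  vars <- c(n_bodies = "n_bodies", mean_diameter_um = "mean_diameter_um",
            mean_max_intensity = "mean_max_intensity")
  out$summaries <- lapply(vars, function(v) group_summary(an[[v]], an$group, present))
  flags <- !is.na(an$cytoplasmic_flag)
  out$cytoplasmic_counts <- vapply(present, function(g)
    sum(an$cytoplasmic_flag[an$group == g & flags]), numeric(1))
  if (length(present) < 2L) {
    warning("fewer than 2 nonempty groups: descriptive summary only")
    class(out) <- "cohort_report"
    return(out)
  }
  K <- length(present)
  m <- K * (K - 1) / 2
  out$tests <- lapply(vars, function(v) {
    res <- list()
    samples <- lapply(present, function(g) {
      s <- an[[v]][an$group == g]
      s[!is.na(s)]
    })
    names(samples) <- present
    if (any(lengths(samples) == 0L)) return(NULL)  # e.g. all-NA means
    res$shapiro <- lapply(samples, function(s)
      if (length(s) >= 3 && length(unique(s)) > 1) normality_screen(s) else NULL)
    res$pairwise <- list()
    for (i in seq_len(K - 1)) for (j in (i + 1):K)
      res$pairwise[[paste0(present[i], "_vs_", present[j])]] <-
        mann_whitney(samples[[i]], samples[[j]], adjust_m = m)
    if (K >= 3) {
      med <- vapply(samples, stats::median, numeric(1))
      monotone <- all(diff(med) <= 0) || all(diff(med) >= 0)
      trendy <- monotone && !all(diff(med) == 0)
      if (always_jt || trendy) {
        res$jonckheere <- jonckheere_terpstra(samples)
        gr <- rep(seq_len(K), lengths(samples))
        res$kendall <- kendall_tau(gr, unlist(samples))
      }
    }
    res
  })
  counts <- cbind(positive = out$cytoplasmic_counts,
                  negative = vapply(present, function(g)
                    sum(!an$cytoplasmic_flag[an$group == g & flags]), numeric(1)))
  rownames(counts) <- present
  if (all(rowSums(counts) > 0) && any(flags)) {
    out$cytoplasmic_fisher <- fisher_exact_rxc(counts)
    if (K >= 3) out$cytoplasmic_pairwise <- pairwise_fisher_bonferroni(counts)
  }
  class(out) <- "cohort_report"
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d analysis nuclei (%d excluded), groups: %s\n",
              x$n_analysis, x$n_excluded, paste(x$group_levels, collapse = " < ")))
  for (v in names(x$summaries)) {
    cat("\n--", v, "--\n")
    print(x$summaries[[v]], row.names = FALSE)
    tt <- x$tests[[v]]
    if (!is.null(tt)) {
      for (nm in names(tt$pairwise)) {
        r <- tt$pairwise[[nm]]
        cat(sprintf("  MW %s: U = %g, p_adj = %.4g\n", nm, r$statistic, r$p_adjusted))
      }
      if (!is.null(tt$jonckheere))
        cat(sprintf("  JT = %g, z = %.3g, p = %.4g; tau = %.3g (p = %.4g)\n",
                    tt$jonckheere$statistic, tt$jonckheere$z_value,
                    tt$jonckheere$p_raw, tt$kendall$statistic, tt$kendall$p_raw))
    }
  }
  if (!is.null(x$cytoplasmic_fisher)) {
    cat(sprintf("\nCytoplasmic labeling: exact r x c p = %.4g\n",
                x$cytoplasmic_fisher$p_raw))
    for (nm in names(x$cytoplasmic_pairwise))
      cat(sprintf("  Fisher %s: p_adj = %.4g\n", nm,
                  x$cytoplasmic_pairwise[[nm]]$p_adjusted))
  }
  invisible(x)
}
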