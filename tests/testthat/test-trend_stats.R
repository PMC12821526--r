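# --- exact r x c (Freeman-Halton) -------------------------------------------

test_that("the exact r x c test reproduces the cytoplasmic-labeling table p", {
  tab <- matrix(c(9, 45, 5, 28, 0, 42), nrow = 3, byrow = TRUE)
  res <- fisher_exact_rxc(tab)
  expect_equal(signif(res$p_raw, 3), 0.00866)
  # enumeration over the fixed margins covers the whole null: mass sums to 1
  expect_equal(res$extra$total_prob, 1, tolerance = 1e-9)
})

test_that("degenerate and symmetric tables behave as expected", {
  expect_equal(fisher_exact_rxc(matrix(c(1, 1, 1, 1), 2, 2))$p_raw, 1)
  expect_error(fisher_exact_rxc(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               "zero row")
  expect_error(fisher_exact_rxc(matrix(c(1, 2), 1, 2)), "2 groups")
})

test_that("enumeration agrees with the hypergeometric reference on random tables", {
  set.seed(12)
  for (r in 1:50) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2, 2)
    if (any(rowSums(tab) == 0)) next
    expect_equal(fisher_exact_rxc(tab)$p_raw, fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
  for (r in 1:10) {
    tab <- matrix(sample(0:8, 6, replace = TRUE), 3, 2)
    if (any(rowSums(tab) == 0)) next
    expect_equal(fisher_exact_rxc(tab)$p_raw, fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("pairwise Fisher applies the Bonferroni factor K(K-1)/2 exactly", {
  tab <- matrix(c(9, 45, 5, 28, 0, 42), nrow = 3, byrow = TRUE,
                dimnames = list(c("young", "middle", "old"), NULL))
  pw <- pairwise_fisher_bonferroni(tab)
  expect_named(pw, c("young_vs_middle", "young_vs_old", "middle_vs_old"))
  for (r in pw)
    expect_equal(r$p_adjusted, min(1, 3 * r$p_raw))
  ident <- matrix(c(5, 10, 5, 10, 5, 10), nrow = 3, byrow = TRUE)
  expect_true(all(vapply(pairwise_fisher_bonferroni(ident),
                         function(r) r$p_adjusted, numeric(1)) == 1))
})

# --- Mann-Whitney ------------------------------------------------------------

test_that("U counts first-sample wins plus half ties; U + U' = n1*n2", {
  m <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_identical(m$statistic, 0)
  expect_identical(mann_whitney(c(4, 5, 6), c(1, 2, 3))$statistic, 9)
  expect_equal(m$p_raw, 0.1)   # exact: 2/20 extreme assignments
  tie <- mann_whitney(c(5, 5, 5), c(5, 5, 5))
  expect_identical(tie$statistic, 4.5)
  expect_equal(tie$p_raw, 1)
  set.seed(3)
  for (r in 1:10) {
    x <- sample(0:6, sample(2:8, 1), replace = TRUE)
    y <- sample(0:6, sample(2:8, 1), replace = TRUE)
    expect_equal(mann_whitney(x, y)$statistic +
                   mann_whitney(y, x)$statistic, length(x) * length(y))
  }
})

test_that("exact Mann-Whitney p matches full enumeration for n <= 8", {
  brute_p <- function(x, y) {
    pooled <- c(x, y); n1 <- length(x); N <- length(pooled)
    u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    obs_dev <- abs(u_of(x, y) - n1 * (N - n1) / 2)
    sets <- combn(N, n1)
    hits <- 0
    for (i in seq_len(ncol(sets))) {
      u <- u_of(pooled[sets[, i]], pooled[-sets[, i]])
      if (abs(u - n1 * (N - n1) / 2) >= obs_dev - 1e-9) hits <- hits + 1
    }
    hits / ncol(sets)
  }
  set.seed(8)
  for (r in 1:12) {
    x <- sample(0:5, sample(3:8, 1), replace = TRUE)  # heavy ties
    y <- sample(0:5, sample(3:8, 1), replace = TRUE)
    expect_equal(mann_whitney(x, y)$p_raw, brute_p(x, y), tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney matches the tie-corrected normal reference", {
  set.seed(21)
  x <- rpois(54, 6); y <- rpois(42, 4.5)   # n1*n2 > 400 -> normal path
  m <- mann_whitney(x, y, adjust_m = 3)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(m$statistic, unname(ref$statistic))
  expect_equal(m$p_raw, ref$p.value, tolerance = 1e-9)
  expect_equal(m$p_adjusted, min(1, 3 * m$p_raw))
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

# --- Jonckheere-Terpstra -----------------------------------------------------

test_that("JT attains its maximum on perfectly increasing groups", {
  j <- jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_identical(j$statistic, 12)   # sum n_i n_j over pairs
  expect_gt(j$z_value, 0)
  flat <- jonckheere_terpstra(list(c(7, 7), c(7, 7), c(7, 7)))
  expect_identical(flat$z_value, 0)
  expect_equal(flat$p_raw, 1)
  expect_error(jonckheere_terpstra(list(1:3, 4:6)), "K >= 3")
  expect_error(jonckheere_terpstra(list(1:3, numeric(0), 4:6)), "nonempty")
})

test_that("JT reduces to Mann-Whitney for two groups", {
  set.seed(14)
  for (r in 1:8) {
    x <- rpois(6, 5); y <- rpois(7, 6)
    expect_equal(nbquant:::jt_statistic(list(x, y)),
                 mann_whitney(y, x)$statistic)   # U counting second-group wins
  }
})

test_that("strictly decreasing trends give z < 0, the reported sign convention", {
  set.seed(2)
  for (r in 1:10) {
    g <- list(rpois(12, 9) + 3, rpois(12, 6) + 1, rpois(12, 3))
    expect_lt(jonckheere_terpstra(g)$z_value, 0)
  }
})

test_that("JT permutation p matches exhaustive enumeration; normal p is close", {
  jt_stat <- nbquant:::jt_statistic
  exact_jt_p <- function(g) {
    pooled <- unlist(g); n <- lengths(g); N <- sum(n)
    obs <- jt_stat(g)
    idx1 <- combn(N, n[1])
    tot <- 0; lo <- 0; hi <- 0
    for (i in seq_len(ncol(idx1))) {
      rest <- setdiff(seq_len(N), idx1[, i])
      idx2 <- combn(rest, n[2])
      for (j in seq_len(ncol(idx2))) {
        s <- jt_stat(list(pooled[idx1[, i]], pooled[idx2[, j]],
                          pooled[setdiff(rest, idx2[, j])]))
        tot <- tot + 1
        if (s <= obs + 1e-9) lo <- lo + 1
        if (s >= obs - 1e-9) hi <- hi + 1
      }
    }
    min(1, 2 * min(lo / tot, hi / tot))
  }
  set.seed(99)
  for (r in 1:4) {
    g <- list(rpois(4, 5), rpois(4, 5), rpois(4, 4))
    pe <- exact_jt_p(g)
    pp <- jonckheere_terpstra(g, mode = "permutation", n_perm = 20000,
                              seed = 7)$p_raw
    pn <- jonckheere_terpstra(g)$p_raw
    expect_lt(abs(pp - pe), 0.02)
    expect_lt(abs(pn - pe), 0.05)  # normal approximation at n = 4
  }
})

# --- Kendall tau and normality ----------------------------------------------

test_that("Kendall tau-b matches direct concordance counting with ties", {
  tau_b <- function(x, y) {
    n <- length(x); C <- 0; D <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
    n0 <- n * (n - 1) / 2
    tx <- table(x); ty <- table(y)
    (C - D) / sqrt((n0 - sum(tx * (tx - 1) / 2)) * (n0 - sum(ty * (ty - 1) / 2)))
  }
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(10, 20, 30, 40))$statistic, 1)
  set.seed(4)
  for (r in 1:8) {
    g <- rep(1:3, each = 5)
    v <- rpois(15, 5)
    if (length(unique(v)) < 2) next
    expect_equal(kendall_tau(g, v)$statistic, tau_b(g, v), tolerance = 1e-12)
  }
  # balanced construction: values independent of group
  g <- rep(1:3, each = 4); v <- rep(c(1, 2, 3, 4), 3)
  expect_equal(kendall_tau(g, v)$statistic, 0)
  expect_warning(res <- kendall_tau(c(1, 1, 2, 2), c(5, 5, 5, 5)), "undefined")
  expect_true(is.na(res$statistic))
  expect_error(kendall_tau(c(1, 1), c(2, 3)), "distinct")
})

test_that("normality screening flags skewed counts and respects invariances", {
  set.seed(6)
  x <- rexp(40)
  res <- normality_screen(x)
  expect_lt(res$p_raw, 0.05)
  expect_gt(res$statistic, 0); expect_lte(res$statistic, 1)
  expect_equal(normality_screen(3 + 2 * x)$statistic, res$statistic,
               tolerance = 1e-9)
  expect_error(normality_screen(c(1, 2)), "3 <= n")
})

# --- cohort report -----------------------------------------------------------

test_that("cohort summaries report medians and run the gated battery", {
  set.seed(42)
  n <- c(young = 30, middle = 25, old = 25)
  lam <- c(8, 6, 4)
  rows <- do.call(rbind, lapply(1:3, function(g) {
    k <- rpois(n[g], lam[g])
    data.frame(source_id = "s", nucleus_id = seq_len(n[g]) + 100 * g,
               group = names(n)[g], n_bodies = k,
               mean_diameter_um = ifelse(k > 0, runif(n[g], 0.4, 1), NA),
               mean_max_intensity = ifelse(k > 0, runif(n[g], 80, 200), NA),
               cytoplasmic_flag = runif(n[g]) < c(0.3, 0.25, 0.02)[g],
               excluded = FALSE, exclusion_reason = "none",
               stringsAsFactors = FALSE)
  }))
  rep <- cohort_report(rows)
  s <- rep$summaries$n_bodies
  expect_identical(s$group, c("young", "middle", "old"))
  expect_equal(s$n, unname(n))
  expect_equal(s$median,
               vapply(names(n), function(g) median(rows$n_bodies[rows$group == g]),
                      numeric(1)), ignore_attr = TRUE)
  # decreasing planted trend: gate opens, JT and tau run and agree in sign
  expect_false(is.null(rep$tests$n_bodies$jonckheere))
  expect_lt(rep$tests$n_bodies$jonckheere$z_value, 0)
  expect_lt(rep$tests$n_bodies$kendall$statistic, 0)
  expect_length(rep$tests$n_bodies$pairwise, 3L)
  expect_false(is.null(rep$cytoplasmic_fisher))
  expect_output(print(rep), "cohort_report")

  expect_equal(median(c(4, 5, 6, 7)), 5.5)  # reporting convention
  one <- rows[rows$group == "young", ]
  expect_warning(r1 <- cohort_report(one), "fewer than 2")
  expect_null(r1$tests)
  expect_error(cohort_report(rows[0, ]), "empty")
})

test_that("excluded rows never reach the statistics", {
  rows <- data.frame(source_id = "s", nucleus_id = 1:40,
                     group = rep(c("young", "old"), each = 20),
                     n_bodies = c(rpois(20, 8), rpois(20, 4)),
                     mean_diameter_um = NA_real_, mean_max_intensity = NA_real_,
                     cytoplasmic_flag = FALSE,
                     excluded = rep(c(FALSE, TRUE), 20),
                     exclusion_reason = "none", stringsAsFactors = FALSE)
  rep <- cohort_report(rows, group_levels = c("young", "old"))
  expect_identical(rep$n_analysis, 20L)
  expect_equal(sum(rep$summaries$n_bodies$n), 20)
})
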