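# Statistical layer checked against closed forms and independent
# brute-force rank computations.

brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

brute_kw <- function(x, g) {
  # direct rank-sum formula with tie correction
  g <- factor(g)
  n <- length(x)
  r <- rank(x)
  Rj <- tapply(r, g, sum)
  nj <- tapply(r, g, length)
  H <- 12 / (n * (n + 1)) * sum(Rj^2 / nj) - 3 * (n + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

test_that("Spearman closed-form examples", {
  expect_equal(spearman_corr(c(1, 2, 3), c(2, 4, 6))$statistic, 1)
  # ranks (1,2,3) vs (3,1,2): sum d^2 = 6 -> rho = 1 - 36/24 = -0.5
  expect_equal(spearman_corr(c(1, 2, 3), c(3, 1, 2))$statistic, -0.5)
  expect_equal(spearman_corr(1:8, exp(-(1:8)))$statistic, -1)
  expect_error(spearman_corr(c(1, 2), c(3, 4)), "at least 3")
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
  # pairwise deletion of incomplete pairs
  r <- spearman_corr(c(1, 2, NA, 4, 5), c(2, 4, 1, NA, 10))
  expect_equal(r$n, 3)
})

test_that("exact permutation p-values match full enumeration", {
  # n = 5, distinct values: enumerate all 120 permutations independently
  set.seed(3)
  x <- rnorm(5); y <- rnorm(5)
  r <- spearman_corr(x, y)
  perms <- arraystrain:::permutations_of(5)
  rhos <- apply(perms, 1, function(p) brute_spearman(x, y[p]))
  expect_equal(r$p.value, mean(abs(rhos) >= abs(r$statistic) - 1e-12))
  # the t-approximation branch agrees with cor.test for larger n
  x2 <- rnorm(40); y2 <- x2 + rnorm(40)
  r2 <- spearman_corr(x2, y2)
  ct <- suppressWarnings(cor.test(x2, y2, method = "spearman"))
  expect_equal(r2$statistic, unname(ct$estimate), tolerance = 1e-12)
})

test_that("Spearman and Kruskal-Wallis match brute force on 100 random small sets", {
  set.seed(2024)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    # draw with ties about half the time
    x <- if (i %% 2) rnorm(n) else sample(1:4, n, replace = TRUE) + 0
    y <- if (i %% 3) rnorm(n) else sample(1:3, n, replace = TRUE) + 0
    g <- sample(letters[1:3], n, replace = TRUE)
    if (sd(x) > 0 && sd(y) > 0) {
      expect_equal(spearman_corr(x, y)$statistic, brute_spearman(x, y),
                   tolerance = 1e-10)
    }
    if (length(unique(g)) >= 2 && sd(x) > 0) {
      got <- kw_dunn(x, g)
      expect_equal(got$statistic, brute_kw(x, g), tolerance = 1e-10)
      ref <- kruskal.test(x, factor(g))
      expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("Dunn z statistics separate well-shifted groups", {
  set.seed(11)
  x <- c(rnorm(20), rnorm(20) + 10, rnorm(20) + 20)
  g <- rep(c("a", "b", "c"), each = 20)
  res <- kw_dunn(x, g)
  expect_lt(res$p.value, 1e-10)
  expect_true(all(res$posthoc$p_adj < 0.001))
  expect_equal(nrow(res$posthoc), 3) # all pairs covered
  # identical observations: H = 0, p = 1
  same <- kw_dunn(rep(3, 12), rep(c("a", "b"), 6))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(24, mean = rep(c(0, i / 4), each = 12))
    g <- rep(c("a", "b"), each = 12)
    res <- anova_tukey(x, g)
    tt <- t.test(x ~ g, var.equal = TRUE)
    expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  }
  # degenerate identical data
  same <- anova_tukey(rep(2, 12), rep(c("a", "b", "c"), 4))
  expect_equal(same$statistic, 0)
})

test_that("Tukey HSD flags all corner-vs-other contrasts for planted strains", {
  lay <- electrode_layout(array_spec(6, 6))
  set.seed(4)
  strain <- c(corner = 0.03, ring3 = 0.02, ring2 = 0.015,
              ring1 = 0.012)[as.character(lay$group)] + rnorm(36, 0, 5e-4)
  res <- anova_tukey(strain, lay$group)
  expect_lt(res$p.value, 1e-4)
  corner_pairs <- grepl("corner", res$posthoc$pair)
  expect_true(all(res$posthoc$p_adj[corner_pairs] < 0.01))
})

test_that("the strain report excludes screened and unconnected electrodes", {
  lay <- electrode_layout(array_spec(4, 4), "corners")
  strain <- data.frame(electrode_id = lay$electrode_id,
                       avg_strain = seq(0.01, 0.04, length.out = 16),
                       group = lay$group, connected = lay$connected)
  metrics <- data.frame(electrode_id = 1:16,
                        functional = rep(c(TRUE, FALSE), c(14, 2)),
                        m_norm = seq(1, 0, length.out = 16))
  rep1 <- correlate_strain_metrics(strain, metrics, columns = "m_norm")
  used <- rep1$data$electrode_id
  expect_false(any(!lay$connected[used]))
  expect_false(any(used %in% c(15, 16)))
  expect_equal(rep1$spearman$rho, -1)
  expect_equal(rep1$spearman$n, sum(lay$connected & metrics$functional))
})

test_that("per-array and pooled fits are both reported", {
  set.seed(6)
  strain <- data.frame(electrode_id = 1:40,
                       avg_strain = runif(40),
                       group = rep(c("ring1", "ring2"), 20))
  metrics <- data.frame(electrode_id = 1:40,
                        functional = TRUE,
                        array = rep(c("A", "B"), each = 20),
                        m_norm = NA)
  metrics$m_norm <- 1 - strain$avg_strain + rnorm(40, 0, 0.1)
  rep1 <- correlate_strain_metrics(strain, metrics, columns = "m_norm")
  expect_setequal(rep1$spearman$array, c("pooled", "A", "B"))
  expect_true(all(rep1$spearman$rho < 0))
})
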