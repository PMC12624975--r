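# Rank-based statistical layer: Spearman rank correlation (exact
# permutation p for small n), Kruskal-Wallis with Dunn's post-hoc test,
# one-way ANOVA with Tukey HSD, and the strain-vs-metric report.

avg_rank <- function(x) rank(x, ties.method = "average")

#' Spearman rank-order correlation
#'
#' Average-rank handling of ties; incomplete pairs are deleted pairwise.
#' The two-sided p-value is an exact permutation probability for n <= 9
#' and the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} otherwise.
#'
#' @param x,y Numeric vectors.
#' @return List of class `correlation_result`: `statistic` (rho),
#'   `p.value`, `n`, `method`.
#' @export
spearman_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Spearman correlation undefined")
  rx <- avg_rank(x); ry <- avg_rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    # exact permutation distribution of rho, vectorized: with fixed rank
    # vectors, rho is affine in the permuted cross-sum
    perms <- permutations_of(n)
    rref <- avg_rank(y)
    M <- matrix(rref[perms], nrow(perms), n)
    cross <- as.numeric(M %*% rx)
    sx <- sum((rx - mean(rx))^2)
    sy <- sum((rref - mean(rref))^2)
    rhos <- (cross - n * mean(rx) * mean(rref)) / sqrt(sx * sy)
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  structure(list(statistic = rho, p.value = min(1, p), n = n,
                 method = "spearman"), class = "correlation_result")
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    out[r + seq_len(rows), 1] <- k
    rest <- setdiff(seq_len(n), k)
    out[r + seq_len(rows), -1] <- matrix(rest[sub], rows, n - 1)
    r <- r + rows
  }
  out
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Tie-corrected H statistic with a chi-squared reference distribution,
#' followed by Dunn z statistics for every group pair.  Dunn p-values are
#' reported raw and Holm-adjusted (the multiplicity correction is a
#' configurable analysis choice).
#'
#' @param x Numeric observations.
#' @param g Group labels.
#' @param p_adjust Multiplicity adjustment for the Dunn table (a
#'   [stats::p.adjust()] method; default `"holm"`).
#' @return List of class `correlation_result`: `statistic` (H),
#'   `p.value`, `df`, `n`, `groups` (per-group n and medians), `posthoc`
#'   (pairwise Dunn table).
#' @export
kw_dunn <- function(x, g, p_adjust = "holm") {
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- factor(g[ok], exclude = NULL)
  g <- droplevels(g)
  k <- nlevels(g)
  n <- length(x)
  stopifnot(k >= 2, n >= 5)
  r <- avg_rank(x)
  nj <- tapply(r, g, length)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_sum <- sum(ties^3 - ties)
  corr <- 1 - tie_sum / (n^3 - n)
  H <- if (corr <= 0) 0 else
    (12 / (n * (n + 1)) * sum(nj * rbar^2) - 3 * (n + 1)) / corr
  H <- max(0, H)
  p <- stats::pchisq(H, k - 1, lower.tail = FALSE)
  if (corr <= 0) p <- 1 # all observations identical
  s2 <- n * (n + 1) / 12 - tie_sum / (12 * (n - 1))
  pairs <- utils::combn(levels(g), 2)
  z <- apply(pairs, 2, function(pr) {
    (rbar[pr[1]] - rbar[pr[2]]) /
      sqrt(s2 * (1 / nj[pr[1]] + 1 / nj[pr[2]]))
  })
  z[!is.finite(z)] <- 0
  praw <- 2 * stats::pnorm(-abs(z))
  posthoc <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                        z = as.numeric(z), p_raw = praw,
                        p_adj = stats::p.adjust(praw, p_adjust))
  structure(list(statistic = H, p.value = p, df = k - 1, n = n,
                 groups = data.frame(group = levels(g), n = as.integer(nj),
                                     median = as.numeric(tapply(x, g, stats::median))),
                 posthoc = posthoc, method = "kruskal-dunn"),
            class = "correlation_result")
}

#' One-way ANOVA with Tukey HSD post-hoc
#'
#' Wraps [stats::aov()] and [stats::TukeyHSD()]; used for the modeled
#' (strain) group comparisons, where normality is acceptable.
#'
#' @param x Numeric observations.
#' @param g Group labels.
#' @return List of class `correlation_result`: `statistic` (F),
#'   `p.value`, `df`, `n`, `groups`, `posthoc` (Tukey table).
#' @export
anova_tukey <- function(x, g) {
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(factor(g[ok]))
  stopifnot(nlevels(g) >= 2, all(tapply(x, g, length) >= 2))
  if (stats::var(x) == 0) { # all observations identical: degenerate
    pairs <- utils::combn(levels(g), 2)
    return(structure(list(
      statistic = 0, p.value = 1, df = c(nlevels(g) - 1L, length(x) - nlevels(g)),
      n = length(x),
      groups = data.frame(group = levels(g), n = as.integer(table(g)),
                          mean = as.numeric(tapply(x, g, mean))),
      posthoc = data.frame(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                           diff = 0, lwr = 0, upr = 0, p_adj = 1),
      method = "anova-tukey"), class = "correlation_result"))
  }
  fit <- stats::aov(x ~ g)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  posthoc <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        p_adj = tk[, "p adj"], row.names = NULL)
  Fv <- s[["F value"]][1]
  pv <- s[["Pr(>F)"]][1]
  if (is.na(Fv)) { Fv <- 0; pv <- 1 } # zero residual + zero group variance
  structure(list(statistic = Fv, p.value = pv,
                 df = c(s[["Df"]][1], s[["Df"]][2]), n = length(x),
                 groups = data.frame(group = levels(g),
                                     n = as.integer(table(g)),
                                     mean = as.numeric(tapply(x, g, mean))),
                 posthoc = posthoc, method = "anova-tukey"),
            class = "correlation_result")
}

#' @exportS3Method base::print
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g, n = %d\n",
              x$method, x$statistic, x$p.value, x$n))
  invisible(x)
}

#' Strain-versus-performance correlation report
#'
#' Joins a per-electrode strain table with normalized performance
#' metrics, excludes nonfunctional and unconnected electrodes, and
#' reports per-metric Spearman correlations (pooled and per array when an
#' `array` column is present) plus ring-group Kruskal-Wallis/Dunn tests
#' of each metric.
#'
#' @param strain An [electrode_strain_table()] (or any data.frame with
#'   `electrode_id`, `avg_strain`, `group`, optionally `connected`).
#' @param metrics Per-electrode data.frame with `electrode_id`, a logical
#'   `functional` column and the metric columns (typically
#'   `electrode_metrics` from [run_metric_pipeline()], or any table of
#'   normalized values); an optional `array` column splits per-array
#'   fits.
#' @param columns Metric columns to correlate (default: all `"_norm"`
#'   columns).
#' @return List of class `strain_report`: `spearman` (data.frame of rho,
#'   p, n per metric and array), `ring_tests` (named list of [kw_dunn()]
#'   results), `data` (the joined analysis table).
#' @export
correlate_strain_metrics <- function(strain, metrics,
                                     columns = grep("_norm$", names(metrics),
                                                    value = TRUE)) {
  df <- merge(as.data.frame(strain), as.data.frame(metrics), by = "electrode_id")
  if (!is.null(df$connected)) df <- df[df$connected, ]
  if (!is.null(df$functional)) df <- df[df$functional, ]
  arrays <- if (!is.null(df$array)) unique(df$array) else character(0)
  rows <- list()
  for (cl in columns) {
    add <- function(sub, label) {
      ok <- stats::complete.cases(sub$avg_strain, sub[[cl]])
      if (sum(ok) < 3) return()
      r <- spearman_corr(sub$avg_strain[ok], sub[[cl]][ok])
      rows[[length(rows) + 1]] <<- data.frame(
        metric = cl, array = label, rho = r$statistic, p = r$p.value, n = r$n)
    }
    add(df, "pooled")
    for (a in arrays) add(df[df$array == a, ], as.character(a))
  }
  ring <- lapply(columns, function(cl) {
    ok <- stats::complete.cases(df[[cl]], df$group)
    if (sum(ok) < 5 || length(unique(df$group[ok])) < 2) return(NULL)
    kw_dunn(df[[cl]][ok], df$group[ok])
  })
  names(ring) <- columns
  structure(list(spearman = do.call(rbind, rows),
                 ring_tests = ring[!vapply(ring, is.null, TRUE)],
                 data = df), class = "strain_report")
}

#' Heatmap of a per-electrode quantity over the array grid
#'
#' Returns a ggplot object when ggplot2 is installed, otherwise draws a
#' base-graphics image.
#'
#' @param table data.frame with `row`, `col` and the value column.
#' @param value Column name to plot.
#' @export
plot_array_heatmap <- function(table, value = "avg_strain") {
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    ggplot2::ggplot(table, ggplot2::aes(.data[["col"]], .data[["row"]],
                                        fill = .data[[value]])) +
      ggplot2::geom_tile() +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "column", y = "row", fill = value)
  } else {
    m <- matrix(NA_real_, max(table$row) + 1, max(table$col) + 1)
    m[cbind(table$row + 1, table$col + 1)] <- table[[value]]
    graphics::image(t(m), main = value)
    invisible(NULL)
  }
}
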