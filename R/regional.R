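# Regional SSR statistics and cohort-level group comparison.

#' Quadrant mean SSR at a time frame
#'
#' Mean SSR over valid, unflagged surface vertices per quadrant, optionally
#' restricted to one or more anatomical segments. Quadrants left empty after
#' validity filtering are reported as `NA`.
#'
#' @param wss a `wall_shear_field` with SSR (see [ssr()]).
#' @param quadrants per-vertex quadrant factor from [quadrant_labels()].
#' @param segments per-vertex segment factor from [segment_split()];
#'   optional.
#' @param segment segment name(s) to keep (default all).
#' @param frame frame index into the shear field (default 1).
#' @return named numeric vector, one mean per quadrant level.
#' @export
quadrant_mean_ssr <- function(wss, quadrants, segments = NULL, segment = NULL,
                              frame = 1L) {
  if (is.null(wss$ssr)) stop("compute ssr() first")
  keep <- wss$valid[, frame] & !wss$flagged[, frame]
  keep[is.na(keep)] <- FALSE
  if (!is.null(segment)) {
    if (is.null(segments)) stop("segment filter given without segment labels")
    keep <- keep & segments %in% segment
  }
  vals <- wss$ssr[, frame]
  out <- vapply(levels(quadrants), function(q) {
    sel <- keep & quadrants == q
    if (!any(sel)) NA_real_ else mean(vals[sel])
  }, numeric(1L))
  out
}

#' SSR profile along the centerline
#'
#' Circumferential mean (and max) of valid SSR per centerline station,
#' against arc length, optionally restricted to a segment — the along-vessel
#' view that localizes shear alteration.
#'
#' @inheritParams quadrant_mean_ssr
#' @param geometry the `vessel_geometry` the shear field was computed on.
#' @return data frame with `station`, `arclength` (mm), `ssr_mean`,
#'   `ssr_max`, `n_valid`.
#' @export
ssr_profile <- function(wss, geometry, segments = NULL, segment = NULL,
                        frame = 1L) {
  if (is.null(wss$ssr)) stop("compute ssr() first")
  keep <- wss$valid[, frame] & !wss$flagged[, frame]
  keep[is.na(keep)] <- FALSE
  if (!is.null(segment)) {
    if (is.null(segments)) stop("segment filter given without segment labels")
    keep <- keep & segments %in% segment
  }
  st <- geometry$surface$station
  stations <- sort(unique(st[keep]))
  vals <- wss$ssr[, frame]
  data.frame(
    station = stations,
    arclength = geometry$arclength[stations],
    ssr_mean = vapply(stations, function(s) mean(vals[keep & st == s]),
                      numeric(1L)),
    ssr_max = vapply(stations, function(s) max(vals[keep & st == s]),
                     numeric(1L)),
    n_valid = vapply(stations, function(s) sum(keep & st == s), numeric(1L))
  )
}

#' Empirical cumulative frequency and percentiles
#'
#' ECDF of a marker over surface nodes plus a percentile function using
#' linear interpolation between closest ranks (the convention under which
#' the 90th percentile of 1..100 is 90.1).
#'
#' @param values finite numeric values (>= 1).
#' @return list with `ecdf` (a function), `sorted` values, `n`, and
#'   `percentile(q)` for q in \[0, 100\].
#' @export
cumulative_frequency <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values")
  s <- sort(values)
  n <- length(s)
  pct <- function(q) {
    if (any(q < 0 | q > 100)) stop("percentile q must be in [0, 100]")
    h <- (n - 1) * q / 100 + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  list(ecdf = stats::ecdf(s), sorted = s, n = n, percentile = pct)
}

#' Kruskal-Wallis rank test across groups
#'
#' H statistic with tie correction; the p value comes from the chi-square
#' approximation with k - 1 degrees of freedom (default) or from exact
#' enumeration of all group assignments (recommended for the small group
#' sizes typical here, e.g. 4 + 4 + 4). For tie-free data the exact null
#' distribution depends only on the group sizes and is cached across calls.
#'
#' @param groups list of >= 2 numeric vectors.
#' @param method `"chisq"` or `"exact"`.
#' @param max_enum maximum number of assignments to enumerate exactly;
#'   beyond this, `method = "exact"` falls back to Monte Carlo with
#'   `n_perm` draws.
#' @param n_perm Monte Carlo permutations for the fallback.
#' @return object of class `group_test`: `H`, `p`, `method`, `sizes`.
#' @export
kruskal_wallis <- function(groups, method = c("chisq", "exact"),
                           max_enum = 2e5, n_perm = 4000L) {
  method <- match.arg(method)
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("each group needs at least one value")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3L) stop("need at least 3 values in total")
  g <- factor(rep(seq_along(groups), sizes))
  if (stats::var(x) == 0) {
    return(structure(list(H = 0, p = 1, method = method, sizes = sizes),
                     class = "group_test"))
  }
  kt <- stats::kruskal.test(x, g)
  H <- unname(kt$statistic)
  if (method == "chisq") {
    p <- kt$p.value
  } else {
    r <- rank(x)
    ties <- any(duplicated(x))
    Hnull <- kw_null_distribution(sizes, r, ties, max_enum, n_perm)
    p <- mean(Hnull >= H - 1e-12)
  }
  structure(list(H = H, p = p, method = method, sizes = sizes),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis (%s): H = %.4f, p = %.4g (groups n = %s)\n",
              x$method, x$H, x$p, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

# H statistic for a rank assignment, with tie correction factor
kw_H_from_ranksums <- function(Rsum, sizes, N, tie_factor) {
  H <- 12 / (N * (N + 1)) * sum(Rsum^2 / sizes) - 3 * (N + 1)
  H / tie_factor
}

kw_tie_factor <- function(r, N) {
  tb <- table(r)
  1 - sum(tb^3 - tb) / (N^3 - N)
}

.kw_cache <- new.env(parent = emptyenv())

# exact (or Monte Carlo) null distribution of H given group sizes and the
# observed ranks
kw_null_distribution <- function(sizes, r, ties, max_enum, n_perm) {
  N <- sum(sizes)
  tf <- kw_tie_factor(r, N)
  n_assign <- exp(lgamma(N + 1) - sum(lgamma(sizes + 1)))
  key <- paste(sort(sizes), collapse = "-")
  if (!ties && n_assign <= max_enum) {
    cached <- .kw_cache[[key]]
    if (!is.null(cached)) return(cached)
  }
  if (n_assign <= max_enum) {
    # enumerate all partitions of the ranks into groups of the given sizes
    Hs <- numeric(0)
    assignments <- enumerate_partitions(seq_len(N), sizes)
    Hs <- vapply(assignments, function(parts) {
      Rsum <- vapply(parts, function(ix) sum(r[ix]), numeric(1L))
      kw_H_from_ranksums(Rsum, sizes, N, tf)
    }, numeric(1L))
  } else {
    Hs <- vapply(seq_len(n_perm), function(i) {
      rp <- sample(r)
      off <- c(0L, cumsum(sizes))
      Rsum <- vapply(seq_along(sizes), function(gi)
        sum(rp[(off[gi] + 1L):off[gi + 1L]]), numeric(1L))
      kw_H_from_ranksums(Rsum, sizes, N, tf)
    }, numeric(1L))
  }
  if (!ties && n_assign <= max_enum) .kw_cache[[key]] <- Hs
  Hs
}

# all ways to split `items` into ordered groups of the given sizes
enumerate_partitions <- function(items, sizes) {
  if (length(sizes) == 1L) return(list(list(items)))
  out <- list()
  picks <- utils::combn(length(items), sizes[1L], simplify = FALSE)
  for (p in picks) {
    head <- items[p]
    rest <- enumerate_partitions(items[-p], sizes[-1L])
    for (rst in rest) out[[length(out) + 1L]] <- c(list(head), rst)
  }
  out
}

#' Scheffe post hoc contrasts on the original values
#'
#' All pairwise group contrasts with the Scheffe simultaneous criterion: the
#' contrast F statistic `(mean_i - mean_j)^2 / (MSE (1/n_i + 1/n_j))` is
#' compared against `(k - 1) F_{alpha, k-1, N-k}`; the reported p value is
#' `P(F_{k-1, N-k} >= F_c / (k - 1))`. Running Scheffe contrasts after a
#' rank-based omnibus test is unusual, but it operates on the original
#' measured values by design here; see [dunn_posthoc()] for a rank-based
#' alternative.
#'
#' @param groups named list of >= 3 numeric vectors.
#' @param alpha significance level (default 0.05).
#' @return data frame of pairwise contrasts with `statistic`, `p`,
#'   `significant`; attribute `degenerate` is TRUE when all within-group
#'   variance is zero.
#' @export
scheffe_posthoc <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 3L) stop("Scheffe post hoc needs at least 3 groups")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
  sizes <- lengths(groups)
  N <- sum(sizes)
  means <- vapply(groups, mean, numeric(1L))
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1L)))
  df2 <- N - k
  mse <- sse / df2
  degenerate <- mse <= 0
  pairs <- utils::combn(k, 2L)
  res <- data.frame(
    group1 = names(groups)[pairs[1L, ]],
    group2 = names(groups)[pairs[2L, ]],
    diff = means[pairs[1L, ]] - means[pairs[2L, ]]
  )
  if (degenerate) {
    res$statistic <- ifelse(res$diff == 0, 0, Inf)
    res$p <- ifelse(res$diff == 0, 1, 0)
  } else {
    res$statistic <- res$diff^2 /
      (mse * (1 / sizes[pairs[1L, ]] + 1 / sizes[pairs[2L, ]]))
    res$p <- stats::pf(res$statistic / (k - 1), k - 1, df2, lower.tail = FALSE)
  }
  res$significant <- res$p < alpha
  attr(res, "degenerate") <- degenerate
  rownames(res) <- NULL
  res
}

#' Dunn's rank-based post hoc test
#'
#' Pairwise z tests on mean ranks with tie correction (unadjusted p values),
#' the conventional follow-up to a Kruskal-Wallis omnibus test.
#'
#' @inheritParams scheffe_posthoc
#' @return data frame of pairwise comparisons.
#' @export
dunn_posthoc <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
  sizes <- lengths(groups)
  N <- sum(sizes)
  r <- rank(unlist(groups, use.names = FALSE))
  off <- c(0L, cumsum(sizes))
  rmean <- vapply(seq_len(k), function(i)
    mean(r[(off[i] + 1L):off[i + 1L]]), numeric(1L))
  tb <- table(r)
  tie_term <- sum(tb^3 - tb) / (12 * (N - 1))
  pairs <- utils::combn(k, 2L)
  se <- sqrt((N * (N + 1) / 12 - tie_term) *
               (1 / sizes[pairs[1L, ]] + 1 / sizes[pairs[2L, ]]))
  z <- (rmean[pairs[1L, ]] - rmean[pairs[2L, ]]) / se
  data.frame(group1 = names(groups)[pairs[1L, ]],
             group2 = names(groups)[pairs[2L, ]],
             z = z, p = 2 * stats::pnorm(-abs(z)),
             significant = 2 * stats::pnorm(-abs(z)) < alpha)
}

#' Standard error of the mean
#' @param x numeric vector.
#' @return s.e.m., or `NA` for fewer than 2 values.
#' @export
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Assemble cohort report tables
#'
#' Builds the standard cohort summaries from a per-case table: per-group
#' mean +/- s.e.m. of each requested column, and (when reference columns are
#' present) percentage-error comparisons between two estimates of the same
#' marker against a ground-truth column.
#'
#' @param cases data frame with a `group` column and numeric marker columns.
#' @param value_cols columns to summarize (default: all numeric).
#' @return list with `group_table` (mean, sem, n per group and marker) and
#'   the input `cases`; prints as formatted "mean +/- sem" text.
#' @export
cohort_report <- function(cases, value_cols = NULL) {
  if (!"group" %in% names(cases)) stop("cases must have a 'group' column")
  if (is.null(value_cols))
    value_cols <- names(cases)[vapply(cases, is.numeric, logical(1L))]
  groups <- unique(as.character(cases$group))
  rows <- list()
  for (gv in groups) {
    sub <- cases[cases$group == gv, , drop = FALSE]
    for (col in value_cols) {
      v <- sub[[col]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = gv, marker = col, n = sum(is.finite(v)),
        mean = mean(v[is.finite(v)]), sem = sem(v))
    }
  }
  out <- list(group_table = do.call(rbind, rows), cases = cases)
  class(out) <- "cohort_report"
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  gt <- x$group_table
  gt$summary <- ifelse(is.na(gt$sem),
                       sprintf("%.3g (n = %d)", gt$mean, gt$n),
                       sprintf("%.3g +/- %.3g", gt$mean, gt$sem))
  print(gt[, c("group", "marker", "n", "summary")], row.names = FALSE)
  invisible(x)
}
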