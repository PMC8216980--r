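#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition: with groups \eqn{g = 1..k} of
#' sizes \eqn{n_g},
#' \deqn{SS_B = \sum_g n_g (\bar y_g - \bar y)^2, \quad
#'       SS_W = \sum_g \sum_i (y_{gi} - \bar y_g)^2,}
#' \eqn{F = (SS_B/(k-1)) / (SS_W/(N-k))} with the p-value from the F
#' distribution. Degenerate inputs are defined explicitly: all values
#' identical gives F = 0 (p = 1); zero within-group variance with unequal
#' means gives F = Inf, p = 0.
#'
#' @param data Data frame in long format.
#' @param value,group Column names (strings) of the response and the
#'   grouping factor.
#' @return An object of class `oneway_anova`: list with `statistic` (F),
#'   `df` (between, within), `p_value`, `ms_within`, and a `groups` tibble
#'   (n, mean, variance per group). Has [tidy()] and [glance()] methods.
#' @examples
#' df <- data.frame(y = c(1, 2, 3, 4, 5, 6),
#'                  g = rep(c("a", "b"), each = 3))
#' glance(one_way_anova(df, "y", "g")) # F = 13.5
#' @export
one_way_anova <- function(data, value = "value", group = "group") {
  y <- data[[value]]
  g <- as.character(data[[group]])
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  groups <- tibble::tibble(group = g, y = y) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$y),
                     variance = if (dplyr::n() > 1) stats::var(.data$y)
                                else NA_real_,
                     .groups = "drop")
  k <- nrow(groups)
  n_tot <- length(y)
  if (k < 2) abort("one_way_anova(): need at least 2 groups")
  if (n_tot <= k) abort("one_way_anova(): need more values than groups")
  grand <- mean(y)
  ssb <- sum(groups$n * (groups$mean - grand)^2)
  ssw <- sum((y - groups$mean[match(g, groups$group)])^2)
  df_b <- k - 1
  df_w <- n_tot - k
  if (ssw == 0) {
    f_stat <- if (ssb == 0) 0 else Inf
    p <- if (ssb == 0) 1 else 0
  } else {
    f_stat <- (ssb / df_b) / (ssw / df_w)
    p <- pf(f_stat, df_b, df_w, lower.tail = FALSE)
  }
  structure(
    list(statistic = f_stat, df = c(between = df_b, within = df_w),
         p_value = p, ss = c(between = ssb, within = ssw),
         ms_within = ssw / df_w, groups = groups,
         value = value, group = group),
    class = "oneway_anova"
  )
}

#' @export
print.oneway_anova <- function(x, ...) {
  cat("One-way ANOVA:", x$value, "~", x$group, "\n")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n",
              x$df["between"], x$df["within"], x$statistic, x$p_value))
  invisible(x)
}

#' @method glance oneway_anova
#' @export
glance.oneway_anova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df_between = x$df[["between"]],
                 df_within = x$df[["within"]], p_value = x$p_value,
                 ms_within = x$ms_within)
}

#' @method tidy oneway_anova
#' @export
tidy.oneway_anova <- function(x, ...) x$groups

# Compact letter display by the insert-and-absorb algorithm: start from a
# single column holding every group; for each significant pair split every
# column containing both (one copy drops each member), then absorb columns
# contained in others. Two groups share a letter iff non-significant.
# Letters follow descending group means, the usual boxplot annotation order.
assign_letters <- function(group_names, means, nonsig) {
  k <- length(group_names)
  cols <- list(seq_len(k)) # columns of group indices
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (nonsig[i, j]) next
      new_cols <- list()
      for (cc in cols) {
        if (i %in% cc && j %in% cc) {
          new_cols <- c(new_cols, list(setdiff(cc, i)), list(setdiff(cc, j)))
        } else {
          new_cols <- c(new_cols, list(cc))
        }
      }
      # absorb: drop any column that is a subset of another
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  rank_of <- rank(-means, ties.method = "first")
  cols <- cols[order(vapply(cols, function(cc) min(rank_of[cc]), numeric(1)))]
  letters_used <- letters[seq_along(cols)]
  out <- vapply(seq_len(k), function(gi) {
    paste0(letters_used[vapply(cols, function(cc) gi %in% cc, logical(1))],
           collapse = "")
  }, character(1))
  tibble::tibble(group = group_names, letters = out)
}

#' Fisher LSD pairwise comparisons with compact letter display
#'
#' Unadjusted pairwise t tests on the pooled within-group mean square from
#' a one-way ANOVA:
#' \deqn{t_{ij} = (\bar y_i - \bar y_j) /
#'       \sqrt{MS_W (1/n_i + 1/n_j)}, \quad df = N - k.}
#' By default the test is protected: pairwise tests are only declared
#' significant when the omnibus ANOVA itself is significant at `alpha`.
#' Letters are assigned so two groups share a letter iff their pairwise
#' difference is non-significant, alphabet in order of descending means.
#'
#' @param fit A [one_way_anova()] object.
#' @param alpha Significance level (default 0.05).
#' @param protected Require ANOVA p < alpha before declaring any pairwise
#'   difference (default TRUE).
#' @return List of class `fisher_lsd` with `pairwise` (tibble: group1,
#'   group2, estimate, statistic, p_value, significant) and `letters`
#'   (tibble: group, letters). Groups of size 1 are allowed (their variance
#'   is pooled from the rest) and flagged in `singletons`.
#' @export
fisher_lsd <- function(fit, alpha = 0.05, protected = TRUE) {
  stopifnot(inherits(fit, "oneway_anova"))
  gr <- fit$groups
  k <- nrow(gr)
  pairs <- utils::combn(seq_len(k), 2)
  df_w <- fit$df[["within"]]
  est <- gr$mean[pairs[1, ]] - gr$mean[pairs[2, ]]
  se <- sqrt(fit$ms_within * (1 / gr$n[pairs[1, ]] + 1 / gr$n[pairs[2, ]]))
  tval <- ifelse(se == 0, ifelse(est == 0, 0, Inf * sign(est)), est / se)
  pval <- 2 * pt(abs(tval), df_w, lower.tail = FALSE)
  omnibus_ok <- !protected || fit$p_value < alpha
  signif <- omnibus_ok & pval < alpha
  pairwise <- tibble::tibble(
    group1 = gr$group[pairs[1, ]], group2 = gr$group[pairs[2, ]],
    estimate = est, statistic = tval, p_value = pval,
    significant = signif
  )
  nonsig <- matrix(TRUE, k, k)
  for (idx in seq_len(ncol(pairs))) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    nonsig[i, j] <- nonsig[j, i] <- !signif[idx]
  }
  structure(
    list(pairwise = pairwise,
         letters = assign_letters(gr$group, gr$mean, nonsig),
         alpha = alpha, protected = protected,
         singletons = gr$group[gr$n == 1]),
    class = "fisher_lsd"
  )
}

#' @export
print.fisher_lsd <- function(x, ...) {
  cat("Fisher LSD at alpha =", x$alpha,
      if (x$protected) "(protected)" else "(unprotected)", "\n")
  print(x$letters)
  invisible(x)
}

#' @method tidy fisher_lsd
#' @export
tidy.fisher_lsd <- function(x, ...) x$pairwise

#' Box-plot descriptive statistics
#'
#' Quartiles by linear interpolation (quantile type 7), mean, min/max
#' whiskers, and outliers by the Tukey 1.5 IQR rule (values outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`).
#'
#' @param x Numeric vector, n >= 1 (NAs dropped).
#' @return List with `q1`, `median`, `q3`, `mean`, `min`, `max`,
#'   `outliers` (values) and `n`.
#' @export
box_stats <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) abort("box_stats(): need at least one value")
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  out <- x[x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr]
  list(q1 = q[1], median = q[2], q3 = q[3], mean = mean(x),
       min = min(x), max = max(x), outliers = out, n = length(x))
}

#' Bray-Curtis dissimilarity
#'
#' \deqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}
#' on non-negative abundance vectors: 0 for identical communities, 1 for
#' disjoint ones.
#'
#' @param x,y Non-negative numeric vectors of equal length, not both zero.
#' @return Dissimilarity in [0, 1].
#' @examples
#' bray_curtis(c(2, 1), c(1, 1)) # 1/5
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) {
    abort("bray_curtis(): vectors differ in length")
  }
  if (any(x < 0) || any(y < 0)) {
    abort("bray_curtis(): abundances must be >= 0")
  }
  tot <- sum(x + y)
  if (tot == 0) abort("bray_curtis(): both vectors are all zero")
  sum(abs(x - y)) / tot
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param mat Sites x species abundance matrix (rows are communities).
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- bray_curtis(mat[i, ], mat[j, ])
    }
  }
  d
}

#' Agglomerative hierarchical clustering
#'
#' Classic agglomerative clustering on a dissimilarity matrix with
#' average (UPGMA, default), complete or single linkage, implemented with
#' the Lance-Williams update. Ties are broken deterministically by the
#' lexicographically smallest (i, j) pair of current cluster indices.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @param linkage "average", "complete" or "single".
#' @return Object of class `ahc`: list with `merge` (n-1 x 2, negative =
#'   singleton site, positive = earlier merge, hclust convention),
#'   `height`, `labels`, `linkage`. `as.hclust()` works on it.
#' @export
ahc_cluster <- function(d, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) abort("ahc_cluster(): need at least two sites")
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0)) {
    abort("ahc_cluster(): need a symmetric matrix with zero diagonal")
  }
  labels <- rownames(d) %||% as.character(seq_len(n))
  active <- seq_len(n)          # current cluster ids (row indices in d)
  id <- -seq_len(n)             # hclust-style ids
  size <- rep(1, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  work <- d
  diag(work) <- Inf
  for (step in seq_len(n - 1)) {
    sub <- work[active, active, drop = FALSE]
    # first minimum in column-major upper scan -> smallest (i, j) pair
    best <- Inf; bi <- bj <- NA_integer_
    for (jj in seq_along(active)) {
      for (ii in seq_len(jj - 1)) {
        if (sub[ii, jj] < best) { best <- sub[ii, jj]; bi <- ii; bj <- jj }
      }
    }
    a <- active[bi]; b <- active[bj]
    merge[step, ] <- sort(c(id[a], id[b]))
    height[step] <- best
    # Lance-Williams update into slot a
    for (k in setdiff(active, c(a, b))) {
      dk <- switch(linkage,
        average = (size[a] * work[a, k] + size[b] * work[b, k]) /
          (size[a] + size[b]),
        complete = max(work[a, k], work[b, k]),
        single = min(work[a, k], work[b, k])
      )
      work[a, k] <- work[k, a] <- dk
    }
    size[a] <- size[a] + size[b]
    id[a] <- step
    active <- setdiff(active, b)
  }
  structure(list(merge = merge, height = height, labels = labels,
                 linkage = linkage, method = linkage),
            class = "ahc")
}

#' @export
as.hclust.ahc <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = hclust_order(x$merge), labels = x$labels,
                 method = x$linkage, call = match.call(),
                 dist.method = "user"),
            class = "hclust")
}

# leaf order by recursive traversal of the merge tree
hclust_order <- function(merge) {
  n <- nrow(merge) + 1
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  rec(nrow(merge))
}

#' (Canonical) correspondence analysis
#'
#' Unconstrained mode (`constraints = NULL`) is classical CA: the
#' chi-square standardized residual matrix
#' \deqn{S = D_r^{-1/2}(P - r c^\top) D_c^{-1/2}}
#' of the relative-frequency table `P` is decomposed by SVD; squared
#' singular values are the per-dimension inertias. Constrained mode (CCA)
#' first projects the rows of `S` onto the space spanned by the site
#' covariates under row-mass weighting, then decomposes the projection, so
#' the reported dimensions are the constrained axes; inertia fractions are
#' relative to the total (unconstrained) inertia and hence sum to at most
#' one.
#'
#' @param table Non-negative sites x variables matrix or data frame with
#'   no all-zero row or column.
#' @param constraints Optional data frame / matrix of site covariates
#'   (factors allowed); must be full column rank after weighting and
#'   centering.
#' @return Object of class `lake_ca`: `site_scores` and `variable_scores`
#'   (principal coordinates), `eigenvalues`, `inertia_fractions`,
#'   `total_inertia`, `constrained` flag. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
correspondence_analysis <- function(table, constraints = NULL) {
  x <- as.matrix(table)
  if (any(x < 0)) abort("correspondence_analysis(): table must be >= 0")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    abort("correspondence_analysis(): all-zero row or column")
  }
  p <- x / sum(x)
  r <- rowSums(p)
  cc <- colSums(p)
  s <- diag(1 / sqrt(r)) %*% (p - r %o% cc) %*% diag(1 / sqrt(cc))
  total_inertia <- sum(s^2)

  constrained <- !is.null(constraints)
  if (constrained) {
    z <- stats::model.matrix(~., data = as.data.frame(constraints))[, -1,
                                                                    drop = FALSE]
    if (nrow(z) != nrow(x)) {
      abort("correspondence_analysis(): constraints rows != table rows")
    }
    # row-mass weighted centering and projection
    zc <- sweep(z, 2, colSums(z * r) / sum(r))
    zw <- zc * sqrt(r)
    qrz <- qr(zw)
    if (qrz$rank < ncol(zw)) {
      abort("correspondence_analysis(): rank-deficient constraints")
    }
    s_fit <- qr.fitted(qrz, s)
    dec <- svd(s_fit)
  } else {
    dec <- svd(s)
  }
  tol <- max(dim(x)) * max(dec$d) * .Machine$double.eps * 100
  keep <- which(dec$d > max(tol, 1e-12))
  if (length(keep) == 0) {
    return(structure(list(
      site_scores = matrix(0, nrow(x), 0),
      variable_scores = matrix(0, ncol(x), 0),
      eigenvalues = numeric(0), inertia_fractions = numeric(0),
      total_inertia = total_inertia, constrained = constrained
    ), class = "lake_ca"))
  }
  d <- dec$d[keep]
  u <- dec$u[, keep, drop = FALSE]
  v <- dec$v[, keep, drop = FALSE]
  site <- diag(1 / sqrt(r)) %*% u %*% diag(d, length(d))
  vars <- diag(1 / sqrt(cc)) %*% v %*% diag(d, length(d))
  dimn <- paste0("dim", seq_along(d))
  dimnames(site) <- list(rownames(x) %||% seq_len(nrow(x)), dimn)
  dimnames(vars) <- list(colnames(x) %||% seq_len(ncol(x)), dimn)
  structure(list(
    site_scores = site, variable_scores = vars,
    eigenvalues = d^2,
    inertia_fractions = d^2 / total_inertia,
    total_inertia = total_inertia, constrained = constrained
  ), class = "lake_ca")
}

#' @export
print.lake_ca <- function(x, ...) {
  cat(if (x$constrained) "Canonical correspondence analysis"
      else "Correspondence analysis", "\n")
  cat("Total inertia:", format(x$total_inertia, digits = 4), "\n")
  if (length(x$inertia_fractions) > 0) {
    cat("Inertia fractions:",
        paste(sprintf("%.1f%%", 100 * head(x$inertia_fractions, 4)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy lake_ca
#' @export
tidy.lake_ca <- function(x, ...) {
  dplyr::bind_rows(
    tibble::as_tibble(x$site_scores, rownames = "label") |>
      dplyr::mutate(score_type = "site", .before = 1),
    tibble::as_tibble(x$variable_scores, rownames = "label") |>
      dplyr::mutate(score_type = "variable", .before = 1)
  )
}

#' @method glance lake_ca
#' @export
glance.lake_ca <- function(x, ...) {
  tibble::tibble(
    total_inertia = x$total_inertia,
    n_dimensions = length(x$eigenvalues),
    inertia_dim1 = x$inertia_fractions[1] %||% NA_real_,
    inertia_dim2 = if (length(x$inertia_fractions) >= 2)
      x$inertia_fractions[2] else NA_real_,
    constrained = x$constrained
  )
}
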