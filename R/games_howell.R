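# Games-Howell pairwise comparisons.
#
# The post-hoc test of choice when group variances are visibly unequal:
# Welch-type standard errors and degrees of freedom, with the statistic
# q = |diff| * sqrt(2) / SE referred to the studentized-range
# distribution for k groups (base R's ptukey).

#' Games-Howell post-hoc test
#'
#' @param values Numeric vector of the metric.
#' @param groups Factor or character vector of group labels, parallel
#'   to `values`.
#' @param alpha Significance level for the compact-letter display.
#' @return A list of class `games_howell`: `table` (one row per pair:
#'   means, mean difference, SE, Welch df, q statistic, adjusted P) and
#'   `letters` (named compact-letter display; groups sharing no letter
#'   differ at `alpha`).
#' @export
games_howell <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  lv <- levels(groups)
  k <- length(lv)
  if (k < 2) stop("need at least 2 groups")
  n <- tapply(values, groups, length)
  if (any(n < 2)) stop("every group needs at least 2 observations")
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, stats::var)

  pairs <- utils::combn(lv, 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se2 <- v[i] / n[i] + v[j] / n[j]
    se <- sqrt(se2)
    if (se == 0) {
      # identical constant groups: no detectable difference
      return(data.frame(group1 = i, group2 = j, mean1 = m[i], mean2 = m[j],
                        diff = m[i] - m[j], se = 0, df = NA_real_,
                        q = 0, p_adj = 1, degenerate = TRUE))
    }
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    q <- abs(m[i] - m[j]) * sqrt(2) / se
    p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    data.frame(group1 = i, group2 = j, mean1 = m[i], mean2 = m[j],
               diff = m[i] - m[j], se = se, df = df, q = q, p_adj = p,
               degenerate = (v[i] == 0 && n[i] == 2) || (v[j] == 0 && n[j] == 2))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  letters_out <- cld_insert_absorb(lv, tab, m, alpha)
  structure(list(table = tab, letters = letters_out, alpha = alpha),
            class = "games_howell")
}

# Compact-letter display by insert-and-absorb over the significance
# graph; groups ordered by mean descending for deterministic output.
cld_insert_absorb <- function(lv, tab, means, alpha) {
  ord <- lv[order(-means[lv])]
  differ <- function(a, b) {
    hit <- (tab$group1 == a & tab$group2 == b) |
           (tab$group1 == b & tab$group2 == a)
    any(tab$p_adj[hit] < alpha)
  }
  sets <- list()
  for (g in ord) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (!any(vapply(sets[[s]], function(o) differ(g, o), TRUE))) {
        sets[[s]] <- c(sets[[s]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- g
  }
  # absorb subsets
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i != j && keep[i] && keep[j] && all(sets[[i]] %in% sets[[j]]))
      keep[i] <- FALSE
  }
  sets <- sets[keep]
  lab <- vapply(lv, function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, TRUE))],
          collapse = "")
  }, "")
  names(lab) <- lv
  lab
}
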