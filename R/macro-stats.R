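# Tukey honest-significant-difference comparisons computable from summary
# statistics (mean, SD, n per group), with compact-letter grouping. Raw data
# are not needed: the pooled within-group variance comes from the SDs and
# the studentized-range distribution supplies the p-values
# (Tukey-Kramer harmonic-mean correction for unequal n).

#' Tukey HSD pairwise comparisons from summary statistics
#'
#' Pools the within-group variance from the group SDs
#' (`MSE = sum((n-1) s^2) / sum(n-1)`), forms the studentized-range
#' statistic `q = |m_i - m_j| / sqrt(MSE / n_h)` per pair (`n_h` the
#' harmonic mean of the two group sizes) and takes p-values from the
#' studentized range distribution with `k` groups and `sum(n - 1)` error
#' degrees of freedom.
#'
#' @param means,sds,ns Per-group means, standard deviations and sizes
#'   (equal length, `ns >= 2`).
#' @param groups Group names; default `names(means)` or `G1..Gk`.
#' @param alpha Significance threshold (default 0.05).
#' @return A data frame with one row per pair: `group1`, `group2`, `diff`,
#'   `se`, `q`, `p`, `significant`; attributes `mse` and `df`.
#' @export
tukey_from_summary <- function(means, sds, ns, groups = NULL, alpha = 0.05) {
  k <- length(means)
  if (k < 2) stop("need at least 2 groups")
  if (length(sds) != k || length(ns) != k) stop("means/sds/ns length mismatch")
  if (any(ns < 2)) stop("every group needs n >= 2")
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  groups <- groups %||% names(means) %||% paste0("G", seq_len(k))

  df <- sum(ns - 1)
  mse <- sum((ns - 1) * sds^2) / df
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    group1 = groups[pairs[1, ]], group2 = groups[pairs[2, ]],
    diff = means[pairs[1, ]] - means[pairs[2, ]],
    stringsAsFactors = FALSE)
  n_h <- 2 / (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]])
  out$se <- sqrt(mse / n_h)
  if (mse <= 0) {
    # degenerate: no within-group spread; unequal means are infinitely
    # separated by convention
    out$q <- ifelse(out$diff == 0, 0, Inf)
    out$p <- ifelse(out$diff == 0, 1, 0)
  } else {
    out$q <- abs(out$diff) / out$se
    out$p <- stats::ptukey(out$q, nmeans = k, df = df, lower.tail = FALSE)
  }
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  attr(out, "mse") <- mse
  attr(out, "df") <- df
  out
}

#' Compact letter display from pairwise significance
#'
#' Groups share a letter iff they are not significantly different. Letters
#' are the maximal mutually-non-significant cliques, labelled in order of
#' their best (largest) group mean, so the group with the highest mean
#' always carries "a".
#'
#' @param significant Either the data frame returned by
#'   [tukey_from_summary()] or a symmetric k x k logical matrix of
#'   pairwise significance.
#' @param means Group means (named, or in the order of the groups).
#' @param groups Group names; inferred when possible.
#' @return Named character vector of letter strings, one per group.
#' @export
assign_letters <- function(significant, means, groups = NULL) {
  if (is.data.frame(significant)) {
    groups <- groups %||% unique(c(significant$group1, significant$group2))
    k <- length(groups)
    sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
    for (r in seq_len(nrow(significant))) {
      i <- significant$group1[r]
      j <- significant$group2[r]
      sig[i, j] <- sig[j, i] <- significant$significant[r]
    }
  } else {
    sig <- as.matrix(significant)
    k <- nrow(sig)
    groups <- groups %||% rownames(sig) %||% paste0("G", seq_len(k))
    dimnames(sig) <- list(groups, groups)
  }
  k <- length(groups)
  if (length(means) != k) stop("`means` must have one entry per group")
  means <- stats::setNames(as.numeric(means), groups)

  # maximal cliques of the non-significance graph (k is small: enumerate)
  compatible <- function(set) {
    if (length(set) < 2) return(TRUE)
    all(!sig[set, set][upper.tri(diag(length(set)))])
  }
  subsets <- unlist(lapply(seq_len(k), function(sz) {
    utils::combn(seq_len(k), sz, simplify = FALSE)
  }), recursive = FALSE)
  cliques <- Filter(compatible, subsets)
  is_maximal <- vapply(cliques, function(s) {
    !any(vapply(cliques, function(t) length(t) > length(s) && all(s %in% t),
                logical(1)))
  }, logical(1))
  cliques <- cliques[is_maximal]

  # order cliques by their best member's mean, descending
  best <- vapply(cliques, function(s) max(means[s]), numeric(1))
  cliques <- cliques[order(-best)]
  letters_out <- stats::setNames(rep("", k), groups)
  for (ci in seq_along(cliques)) {
    for (g in cliques[[ci]]) {
      letters_out[g] <- paste0(letters_out[g], letters[ci])
    }
  }
  letters_out
}

#' Tukey comparisons and letters for a whole summary table
#'
#' Convenience driver over a long-format table of per-parameter,
#' per-group summary statistics.
#'
#' @param stats_df Data frame with columns `parameter`, `group`, `mean`,
#'   `sd`, `n`.
#' @param alpha Significance threshold.
#' @return A list with `pairwise` (all pairwise rows, with a `parameter`
#'   column) and `letters` (per parameter/group compact letter display).
#' @export
tukey_table <- function(stats_df, alpha = 0.05) {
  needed <- c("parameter", "group", "mean", "sd", "n")
  if (!all(needed %in% names(stats_df))) {
    stop("`stats_df` needs columns: ", paste(needed, collapse = ", "))
  }
  pairwise <- NULL
  letters_df <- NULL
  for (par in unique(stats_df$parameter)) {
    sub <- stats_df[stats_df$parameter == par, ]
    res <- tukey_from_summary(sub$mean, sub$sd, sub$n, groups = sub$group,
                              alpha = alpha)
    ltr <- assign_letters(res, sub$mean, groups = sub$group)
    pairwise <- rbind(pairwise, cbind(parameter = par, res))
    letters_df <- rbind(letters_df, data.frame(
      parameter = par, group = sub$group, mean = sub$mean, sd = sub$sd,
      n = sub$n, letter = unname(ltr[sub$group]), stringsAsFactors = FALSE))
  }
  list(pairwise = pairwise, letters = letters_df)
}

#' Published macro-composition summary statistics
#'
#' The per-month mean and standard deviation of the macro-composition and
#' proteolysis parameters of Pecorino Romano PDO cheese produced in January,
#' April and June (n = 15 per month assumed: 45 samples over 3 balanced
#' months), as published. The `letter` column carries the published
#' compact-letter annotations for reference.
#'
#' @return Data frame with columns `parameter`, `group`, `mean`, `sd`, `n`,
#'   `letter`.
#' @export
macro_composition_table <- function() {
  path <- system.file("extdata", "macro_composition.csv",
                      package = "pecomics", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
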