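.check_groups <- function(features, groups) {
  stopifnot(is.data.frame(features), "allele" %in% names(features))
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list of allele vectors")
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members))
    stop("groups must partition the alleles (duplicate membership)")
  miss <- setdiff(members, features$allele)
  if (length(miss))
    stop("group member(s) without features: ", paste(miss, collapse = ", "))
  if (any(lengths(groups) < 1)) stop("group sizes must be >= 1")
  invisible(members)
}

#' Per-group means of structural features
#'
#' Arithmetic mean of each feature within each allele group; logical
#' features (e.g. regular-secondary-structure membership) are averaged as
#' fractions. Alleles with an absent value are excluded per feature; a
#' group left empty for a feature is an error.
#'
#' @param features data.frame with an \code{allele} column and one column
#'   per feature (numeric or logical).
#' @param groups named list of character vectors of alleles; the groups
#'   must partition their union (e.g. phenotype category, optionally
#'   crossed with construction method).
#' @return data.frame: \code{group}, \code{feature}, \code{mean},
#'   \code{n_used}.
#' @export
groupMeans <- function(features, groups) {
  .check_groups(features, groups)
  feat_cols <- setdiff(names(features), "allele")
  out <- do.call(rbind, lapply(names(groups), function(g) {
    rows <- features[features$allele %in% groups[[g]], , drop = FALSE]
    do.call(rbind, lapply(feat_cols, function(f) {
      x <- as.numeric(rows[[f]])
      n <- sum(!is.na(x))
      if (n == 0)
        stop("group '", g, "' has no non-missing values for feature '", f, "'")
      data.frame(group = g, feature = f, mean = mean(x, na.rm = TRUE),
                 n_used = n)
    }))
  }))
  rownames(out) <- NULL
  out
}

.perm_pvals <- function(features, groups, label_draws) {
  ## label_draws: matrix, one column per draw, entries are allele indices
  ## (a permutation of the member indices); rows blocked by group.
  feat_cols <- setdiff(names(features), "allele")
  members <- unlist(groups, use.names = FALSE)
  midx <- match(members, features$allele)
  gsizes <- lengths(groups)
  gend <- cumsum(gsizes)
  gstart <- gend - gsizes + 1
  obs <- groupMeans(features, groups)
  n_draw <- ncol(label_draws)
  out <- obs
  out$null_mean <- NA_real_
  out$null_sd <- NA_real_
  out$p_low <- NA_real_
  out$p_high <- NA_real_
  for (f in feat_cols) {
    x <- as.numeric(features[[f]])[midx]   # feature values, member order
    for (gi in seq_along(groups)) {
      rows_g <- label_draws[gstart[gi]:gend[gi], , drop = FALSE]
      nulls <- colMeans(matrix(x[rows_g], nrow = nrow(rows_g)), na.rm = TRUE)
      k <- which(out$group == names(groups)[gi] & out$feature == f)
      ob <- out$mean[k]
      out$null_mean[k] <- mean(nulls)
      out$null_sd[k] <- stats::sd(nulls)
      tol <- 1e-12 * max(1, abs(ob))
      out$p_high[k] <- (1 + sum(nulls >= ob - tol)) / (n_draw + 1)
      out$p_low[k] <- (1 + sum(nulls <= ob + tol)) / (n_draw + 1)
    }
  }
  out
}

#' Permutation test of feature-category association
#'
#' Empirical two-tailed test of whether each group's feature mean is
#' higher or lower than expected by chance: alleles are randomly
#' reassigned to the groups (preserving group sizes) \code{n_perm} times,
#' the same per-group feature means are recomputed on each reassignment,
#' and one-sided empirical probabilities are reported with the add-one
#' correction \code{p_high = (1 + #\{null >= observed\}) / (n_perm + 1)}
#' (and \code{p_low} analogously). One reassignment is shared across all
#' groups and features, preserving the covariance among the five
#' measurements. Deterministic for a fixed seed.
#'
#' @param features data.frame with \code{allele} plus feature columns.
#' @param groups named list partitioning the alleles.
#' @param n_perm number of random reassignments (assay convention:
#'   10,000).
#' @param seed integer seed for the reassignment PRNG (Mersenne-Twister
#'   via \code{set.seed}).
#' @return data.frame: \code{group}, \code{feature}, \code{mean} (the
#'   observed group mean), \code{n_used}, \code{null_mean},
#'   \code{null_sd}, \code{p_low}, \code{p_high}, plus attributes
#'   \code{"n_perm"} and \code{"seed"}.
#' @export
permutationTest <- function(features, groups, n_perm = 10000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  members <- .check_groups(features, groups)
  n <- length(members)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  draws <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out <- .perm_pvals(features, groups, draws)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

## all distinct assignments of n items into blocks of the given sizes,
## as a matrix of item indices (rows blocked by group, one column per
## assignment)
.enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  rec <- function(avail, sizes) {
    if (length(sizes) == 0) return(matrix(integer(0), nrow = 0, ncol = 1))
    k <- sizes[1]
    ## combn(x, m) treats a scalar x as seq_len(x); guard that case
    picks <- if (length(avail) == 1) matrix(avail, 1, 1)
             else utils::combn(avail, k)
    cols <- lapply(seq_len(ncol(picks)), function(j) {
      top <- picks[, j]
      rest <- rec(setdiff(avail, top), sizes[-1])
      rbind(matrix(rep(top, ncol(rest)), nrow = k), rest)
    })
    do.call(cbind, cols)
  }
  rec(seq_len(n), sizes)
}

#' Exact small-n version of the permutation test
#'
#' Enumerates every distinct assignment of the alleles to the groups
#' (respecting sizes) and computes exact tail probabilities, including
#' the observed assignment in the numerator and denominator so the result
#' is directly comparable to \code{\link{permutationTest}}'s add-one
#' estimator. Intended as the exact oracle for small instances.
#'
#' @param features data.frame with \code{allele} plus feature columns.
#' @param groups named list partitioning the alleles.
#' @param max_assignments refuse instances larger than this (default 1e6).
#' @return data.frame as in \code{\link{permutationTest}}, with attribute
#'   \code{"n_assignments"}.
#' @export
exhaustiveTest <- function(features, groups, max_assignments = 1e6) {
  members <- .check_groups(features, groups)
  sizes <- lengths(groups)
  n_assign <- exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
  if (n_assign > max_assignments)
    stop("about ", format(n_assign, digits = 3), " assignments; ",
         "use permutationTest for instances this large")
  ## enumerate group-index patterns; within-group order is irrelevant for
  ## means, so enumerate unordered set assignments
  draws <- .enumerate_assignments(sizes)
  feat_cols <- setdiff(names(features), "allele")
  midx <- match(members, features$allele)
  gsizes <- lengths(groups)
  gend <- cumsum(gsizes)
  gstart <- gend - gsizes + 1
  obs <- groupMeans(features, groups)
  out <- obs
  out$null_mean <- NA_real_; out$null_sd <- NA_real_
  out$p_low <- NA_real_; out$p_high <- NA_real_
  for (f in feat_cols) {
    x <- as.numeric(features[[f]])[midx]
    for (gi in seq_along(groups)) {
      rows_g <- draws[gstart[gi]:gend[gi], , drop = FALSE]
      nulls <- colMeans(matrix(x[rows_g], nrow = nrow(rows_g)), na.rm = TRUE)
      k <- which(out$group == names(groups)[gi] & out$feature == f)
      ob <- out$mean[k]
      tol <- 1e-12 * max(1, abs(ob))
      out$null_mean[k] <- mean(nulls)
      out$null_sd[k] <- stats::sd(nulls)
      out$p_high[k] <- sum(nulls >= ob - tol) / length(nulls)
      out$p_low[k] <- sum(nulls <= ob + tol) / length(nulls)
    }
  }
  attr(out, "n_assignments") <- ncol(draws)
  out
}
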