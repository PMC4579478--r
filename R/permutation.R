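## Distance-based permutation inference: PERMANOVA (ADONIS-style partition
## of a distance matrix by model terms) and ANOSIM (rank-based analysis of
## similarity).  Both permute raw sample labels freely and use the add-one
## permutation p-value, so p is never exactly zero and is exactly
## reproducible given (n_perm, seed).

#' PERMANOVA: permutational multivariate ANOVA on a distance matrix
#'
#' Partitions the total sum of squares of a distance matrix by model terms
#' in the given (sequential, Type I) order, following the McArdle-Anderson
#' trace formulation: the squared distances are Gower-centered into G and
#' the sum of squares explained by a design is tr(H G) for its hat matrix
#' H.  The pseudo-F of each term uses the residual mean square of the full
#' model; p-values come from free permutation of sample labels,
#' p = (1 + #\{permuted F >= observed F\}) / (1 + n_perm).
#'
#' @param d symmetric distance matrix (e.g. [bray_curtis()]) or `dist`
#' @param metadata a [sample_metadata()] (or any data.frame with a
#'   `sample_id` column) covering the samples of `d`
#' @param terms character vector of model terms over metadata columns, in
#'   the order they should enter the model; interactions as `"a:b"`
#' @param n_perm number of permutations (>= 99)
#' @param seed integer seed for the permutation stream (required)
#' @return a `permanova` object: per-term Df, SumOfSqs, R2, pseudo-F and
#'   permutation p, plus residual and total rows
#' @export
permanova <- function(d, metadata, terms, n_perm = 999, seed = NULL) {
  if (is.null(seed)) stop("a seed is required for permutation tests",
                          call. = FALSE)
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  d <- as_distance_matrix(d)
  n <- nrow(d)
  ids <- rownames(d)
  df <- as.data.frame(metadata)
  if (!is.null(ids) && "sample_id" %in% names(df)) {
    idx <- match(ids, df$sample_id)
    if (anyNA(idx))
      stop("metadata does not cover sample(s): ",
           paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
    df <- df[idx, , drop = FALSE]
  } else if (nrow(df) != n)
    stop("metadata rows do not match distance matrix", call. = FALSE)
  for (v in unique(unlist(lapply(terms, function(t)
    all.vars(stats::reformulate(t)))))) {
    if (!v %in% names(df))
      stop("term variable not in metadata: ", v, call. = FALSE)
    col <- df[[v]]
    if (is.factor(col)) col <- droplevels(col)
    if (!is.numeric(col) && length(unique(col)) < 2L)
      stop("term '", v, "' has a single level", call. = FALSE)
    df[[v]] <- col
  }

  g <- gower_center(d)
  ss_total <- sum(diag(g))
  ## cumulative hat matrices, intercept first
  hats <- vector("list", length(terms) + 1L)
  ranks <- integer(length(terms) + 1L)
  hats[[1]] <- matrix(1 / n, n, n)
  ranks[1] <- 1L
  for (i in seq_along(terms)) {
    X <- stats::model.matrix(stats::reformulate(terms[seq_len(i)]), df)
    qrX <- qr(X)
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    hats[[i + 1L]] <- tcrossprod(Q)
    ranks[i + 1L] <- qrX$rank
  }
  df_terms <- diff(ranks)
  if (any(df_terms == 0L))
    stop("term(s) contribute no model degrees of freedom: ",
         paste(terms[df_terms == 0L], collapse = ", "), call. = FALSE)
  df_res <- n - ranks[length(ranks)]
  if (df_res < 1L) stop("no residual degrees of freedom", call. = FALSE)

  trHG <- function(gmat) vapply(hats, function(h) sum(h * gmat), 0)
  f_stats <- function(gmat) {
    tr <- trHG(gmat)
    ss <- diff(tr)
    ss_res <- sum(diag(gmat)) - tr[length(tr)]
    (ss / df_terms) / (ss_res / df_res)
  }
  tr_obs <- trHG(g)
  ss_terms <- diff(tr_obs)
  ss_res <- ss_total - tr_obs[length(tr_obs)]
  f_obs <- (ss_terms / df_terms) / (ss_res / df_res)

  set.seed(seed)
  exceed <- numeric(length(terms))
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    exceed <- exceed + (f_stats(g[p, p]) >= f_obs)
  }
  pvals <- (1 + exceed) / (1 + n_perm)

  tab <- data.frame(Df = c(df_terms, df_res, n - 1L),
                    SumOfSqs = c(ss_terms, ss_res, ss_total),
                    R2 = c(ss_terms, ss_res, ss_total) / ss_total,
                    F = c(f_obs, NA, NA),
                    `Pr(>F)` = c(pvals, NA, NA),
                    row.names = c(terms, "Residual", "Total"),
                    check.names = FALSE)
  structure(list(table = tab, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (%d free permutations, seed %d)\n",
              x$n_perm, x$seed))
  print(x$table, digits = 4)
  invisible(x)
}

#' ANOSIM: rank-based analysis of similarity
#'
#' R = (mean between-group rank - mean within-group rank) / (M / 2), with
#' ranks over all M = n(n-1)/2 pairwise distances.  R near 1 indicates
#' strong separation between groups; R near 0 indicates none.  Significance
#' by free permutation of the grouping with the add-one rule.
#'
#' @param d symmetric distance matrix or `dist`
#' @param grouping factor-like vector of group labels, aligned with the
#'   samples of `d` (or named by sample id)
#' @param n_perm number of permutations (>= 99)
#' @param seed integer seed (required)
#' @return an `anosim` object with elements `R`, `p`, `n_perm`, `seed`
#' @export
anosim <- function(d, grouping, n_perm = 999, seed = NULL) {
  if (is.null(seed)) stop("a seed is required for permutation tests",
                          call. = FALSE)
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  d <- as_distance_matrix(d)
  n <- nrow(d)
  if (!is.null(names(grouping)) && !is.null(rownames(d)))
    grouping <- grouping[rownames(d)]
  grouping <- as.factor(as.vector(grouping))
  if (length(grouping) != n)
    stop("grouping length does not match distance matrix", call. = FALSE)
  if (nlevels(droplevels(grouping)) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(table(grouping) < 2L))
    stop("every group needs at least two samples", call. = FALSE)

  lower <- lower.tri(d)
  r <- rank(d[lower])                   # average ranks for ties
  M <- n * (n - 1) / 2
  same <- outer(grouping, grouping, "==")[lower]
  stat <- function(same_vec)
    (mean(r[!same_vec]) - mean(r[same_vec])) / (M / 2)
  R_obs <- stat(same)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    gp <- grouping[sample.int(n)]
    same_p <- outer(gp, gp, "==")[lower]
    exceed <- exceed + (stat(same_p) >= R_obs)
  }
  structure(list(R = R_obs, p = (1 + exceed) / (1 + n_perm),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "anosim")
}

#' @export
print.anosim <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$R, x$p, x$n_perm, x$seed))
  invisible(x)
}
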