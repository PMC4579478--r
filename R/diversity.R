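#' Per-sample richness and Shannon diversity
#'
#' Richness is the number of OTUs detected (count > 0) in a sample; Shannon
#' diversity is H = -sum p_i ln p_i over the sample's nonzero relative
#' abundances, in nats (0 ln 0 is taken as 0).  H is bounded above by
#' ln(richness).
#'
#' @param x an [otu_table()]
#' @return named vector, one value per sample
#' @export
richness <- function(x) {
  m <- otu_counts(x)
  rowSums(m > 0)
}

#' @rdname richness
#' @export
shannon <- function(x) {
  m <- otu_counts(x)
  ls <- rowSums(m)
  if (any(ls == 0))
    stop("Shannon diversity undefined for zero-library samples: ",
         paste(rownames(m)[ls == 0], collapse = ", "), call. = FALSE)
  p <- m / ls
  apply(p, 1L, function(pi) {
    pi <- pi[pi > 0]
    -sum(pi * log(pi))
  })
}

#' Model diversity against niche and depth
#'
#' Ordinary least squares of a per-sample diversity index on the sample
#' covariates, with per-term F and p from sequential (Type I) sums of
#' squares.  The default model is additive in niche (categorical) and depth
#' (numeric meters).
#'
#' @param diversity named numeric vector (names = sample ids), e.g. from
#'   [shannon()] or [richness()]
#' @param metadata a [sample_metadata()]
#' @param formula right-hand-side model formula over metadata columns
#'   (default `~ niche + depth`)
#' @return a `diversity_model`: the fitted `lm` and its sequential ANOVA
#'   table
#' @export
diversity_model <- function(diversity, metadata, formula = ~ niche + depth) {
  idx <- match(names(diversity), metadata$sample_id)
  if (anyNA(idx))
    stop("diversity values without metadata record: ",
         paste(names(diversity)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(metadata[idx, , drop = FALSE])
  df$niche <- droplevels(df$niche)
  vars <- all.vars(formula)
  if ("niche" %in% vars && nlevels(df$niche) < 2L)
    stop("niche has a single level; cannot model a niche effect",
         call. = FALSE)
  df$.y <- as.numeric(diversity)
  fit <- stats::lm(stats::update(formula, .y ~ .), data = df)
  X <- stats::model.matrix(fit)
  if (fit$rank < ncol(X)) {
    aliased <- colnames(X)[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  tab <- suppressWarnings(stats::anova(fit))
  if (stats::var(df$.y) < 1e-20 * (mean(df$.y)^2 + 1)) {
    n_terms <- nrow(tab) - 1L          # constant response: no effects
    tab$`F value`[seq_len(n_terms)] <- 0
    tab$`Pr(>F)`[seq_len(n_terms)] <- 1
  }
  structure(list(model = fit, table = tab, formula = formula),
            class = "diversity_model")
}

#' @export
print.diversity_model <- function(x, ...) {
  cat("Diversity model (sequential ANOVA):\n")
  print(x$table)
  invisible(x)
}

#' @export
coef.diversity_model <- function(object, ...) stats::coef(object$model)
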