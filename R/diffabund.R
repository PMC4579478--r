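#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR control with monotonicity enforcement (a thin,
#' validating wrapper around [stats::p.adjust()]): q >= p for every test and
#' the ordering of p-values is preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return vector of q-values, same length and names as `p`
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Quasi-Poisson differential abundance
#'
#' Fits, per OTU, a log-linear quasi-Poisson regression of counts on the
#' design (`stats::glm` with `family = quasipoisson`, i.e. IRLS), with
#' log(library size) as exposure offset so that effects are on relative
#' abundance.  Each OTU's model is compared with the intercept-only model by
#' an F-test: F = (deviance drop / df drop) / phi, with the dispersion phi
#' estimated as Pearson X^2 / (n - p) from the full model.  P-values are
#' BH-adjusted across tested OTUs.
#'
#' OTUs that are zero in every sample are skipped (status `"all_zero"`);
#' fits that do not converge are flagged (status `"not_converged"`) and
#' excluded from the FDR adjustment.
#'
#' @param x an [otu_table()]
#' @param metadata a [sample_metadata()] covering the samples of `x`
#' @param design right-hand-side formula over metadata columns (default
#'   `~ niche`); the first non-intercept coefficients give the reported rate
#'   ratios
#' @param min_prevalence only test OTUs detected in at least this fraction
#'   of samples (default 0 = test everything not all-zero)
#' @return a `diff_abundance` object whose `table` has one row per OTU:
#'   rate ratios per coefficient, `dispersion`, `F`, `df1`, `df2`, `p`, `q`
#'   and `status`
#' @export
diff_abundance <- function(x, metadata, design = ~ niche,
                           min_prevalence = 0) {
  md <- metadata_for(x, metadata)
  md$niche <- droplevels(md$niche)
  vars <- all.vars(design)
  for (v in vars) {
    col <- md[[v]]
    nlev <- if (is.numeric(col)) Inf else length(unique(col))
    if (nlev < 2L)
      stop("design variable '", v, "' has a single level", call. = FALSE)
  }
  m <- otu_counts(x)
  off <- log(rowSums(m))
  prev <- colMeans(m > 0)
  keep <- prev > 0 & prev >= min_prevalence
  full_formula <- stats::update(design, .count ~ . + offset(.off))

  rows <- vector("list", ncol(m))
  names(rows) <- colnames(m)
  rr_names <- NULL
  for (j in seq_len(ncol(m))) {
    oid <- colnames(m)[j]
    if (prev[j] == 0) {
      rows[[j]] <- list(status = "all_zero")
      next
    }
    if (!keep[j]) {
      rows[[j]] <- list(status = "filtered")
      next
    }
    dat <- md
    dat$.count <- m[, j]
    dat$.off <- off
    fit <- suppressWarnings(
      stats::glm(full_formula, family = stats::quasipoisson(),
                 data = dat))
    phi <- sum(stats::residuals(fit, type = "pearson")^2) /
      stats::df.residual(fit)
    df1 <- fit$df.null - fit$df.residual
    df2 <- stats::df.residual(fit)
    if (!fit$converged || df2 < 1L || !is.finite(phi) || phi < 0) {
      rows[[j]] <- list(status = "not_converged")
      next
    }
    ddev <- max(0, fit$null.deviance - fit$deviance)
    if (ddev < 1e-8) ddev <- 0            # numerically exact fit of null
    if (phi < 1e-12) {
      ## perfect full-model fit: no dispersion left to test against
      Fstat <- if (ddev == 0) 0 else Inf
    } else {
      Fstat <- (ddev / df1) / phi
    }
    pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    rr <- exp(stats::coef(fit)[-1])
    if (is.null(rr_names)) rr_names <- names(rr)
    rows[[j]] <- list(status = "ok", dispersion = phi, F = Fstat,
                      df1 = df1, df2 = df2, p = pval, rr = rr)
  }

  status <- vapply(rows, `[[`, "", "status")
  get_num <- function(field) vapply(rows, function(r)
    if (identical(r$status, "ok")) r[[field]] else NA_real_, 0)
  tab <- data.frame(otu_id = names(rows),
                    dispersion = get_num("dispersion"),
                    F = get_num("F"), df1 = get_num("df1"),
                    df2 = get_num("df2"), p = get_num("p"),
                    status = status, stringsAsFactors = FALSE,
                    row.names = names(rows))
  if (!is.null(rr_names)) {
    for (k in seq_along(rr_names)) {
      tab[[paste0("RR_", rr_names[k])]] <- vapply(rows, function(r)
        if (identical(r$status, "ok")) unname(r$rr[k]) else NA_real_, 0)
    }
  }
  tab$q <- NA_real_
  ok <- status == "ok"
  tab$q[ok] <- bh_adjust(tab$p[ok])
  structure(list(table = tab, design = design, n_tested = sum(ok),
                 n_skipped = sum(!ok)),
            class = "diff_abundance")
}

#' @export
print.diff_abundance <- function(x, n = 10, ...) {
  cat(sprintf("Quasi-Poisson differential abundance: %d OTUs tested, %d skipped\n",
              x$n_tested, x$n_skipped))
  cat(sprintf("design: %s\n", deparse(x$design)))
  tab <- x$table[x$table$status == "ok", , drop = FALSE]
  tab <- tab[order(tab$q, tab$p), , drop = FALSE]
  print(utils::head(tab[setdiff(names(tab), "status")], n), digits = 4)
  invisible(x)
}

#' @export
summary.diff_abundance <- function(object, q_cutoff = 0.05, ...) {
  tab <- object$table
  sig <- sum(tab$q <= q_cutoff, na.rm = TRUE)
  cat(sprintf("%d of %d tested OTUs significant at q <= %g\n",
              sig, object$n_tested, q_cutoff))
  invisible(list(n_significant = sig, n_tested = object$n_tested))
}
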