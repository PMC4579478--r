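## Predicted-metagenome stage: copy-number-normalized projection of OTU
## abundances onto gene families, pathway aggregation, per-taxon
## contribution shares, and per-pathway group comparison.

#' Predict per-sample gene-family profiles from OTU counts
#'
#' predicted(sample, family) = sum over reference-covered OTUs of
#' (count / ssu_copies) x gene_copy: counts are first normalized by the
#' OTU's 16S copy number (so organism abundance, not amplicon abundance, is
#' projected) and then multiplied into its gene-family copy numbers.  OTUs
#' absent from the reference are excluded; the excluded read fraction is
#' reported per sample.  The projection is linear and non-negative.
#'
#' @param x an [otu_table()]
#' @param ref a [gene_copy_table()]
#' @return a `function_profile`: `counts` (samples x gene families, real
#'   non-negative) and `excluded_fraction` (named per-sample fraction of
#'   reads belonging to uncovered OTUs)
#' @export
predict_metagenome <- function(x, ref) {
  stopifnot(inherits(ref, "gene_copy_table"))
  if (any(ref$ssu_copies <= 0))
    stop("reference ssu_copies must be positive", call. = FALSE)
  m <- otu_counts(x)
  covered <- intersect(colnames(m), names(ref$ssu_copies))
  ls <- rowSums(m)
  excluded <- if (length(covered) < ncol(m))
    rowSums(m[, setdiff(colnames(m), covered), drop = FALSE]) / ls
  else stats::setNames(numeric(nrow(m)), rownames(m))
  if (!length(covered))
    stop("no OTU of the table is covered by the reference", call. = FALSE)
  norm <- sweep(m[, covered, drop = FALSE], 2L,
                ref$ssu_copies[covered], `/`)
  profile <- norm %*% ref$gene_copy[covered, , drop = FALSE]
  zero_rows <- rownames(profile)[rowSums(profile) == 0]
  structure(list(counts = profile,
                 excluded_fraction = excluded,
                 uncovered_otus = setdiff(colnames(m), covered),
                 zero_samples = zero_rows),
            class = "function_profile")
}

#' @export
print.function_profile <- function(x, ...) {
  cat(sprintf("predicted metagenome: %d samples x %d gene families\n",
              nrow(x$counts), ncol(x$counts)))
  if (length(x$uncovered_otus))
    cat(sprintf("%d OTUs uncovered by the reference (max excluded read fraction %.3f)\n",
                length(x$uncovered_otus), max(x$excluded_fraction)))
  if (length(x$zero_samples))
    cat("samples with empty profile:",
        paste(x$zero_samples, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate gene families into pathways
#'
#' Sums predicted gene-family counts into pathways.  The family-to-pathway
#' map may be many-to-many: a family counts once into every pathway it maps
#' to.  Families with no mapping are collected into an `"UNMAPPED"` bucket,
#' so the conservation identity holds: the pathway matrix total equals the
#' sum over families of (family count x number of pathways it maps to, or 1
#' if unmapped).
#'
#' @param fp a `function_profile` from [predict_metagenome()]
#' @param pathway_map named list, family id -> character vector of pathway
#'   ids; defaults to the map carried by the reference if `fp` was built
#'   from one (pass explicitly otherwise)
#' @return a `pathway_profile`: `counts` (samples x pathways)
#' @export
aggregate_pathways <- function(fp, pathway_map) {
  stopifnot(inherits(fp, "function_profile"))
  fams <- colnames(fp$counts)
  pw_of <- lapply(fams, function(f) {
    p <- pathway_map[[f]]
    if (is.null(p) || !length(p)) "UNMAPPED" else p
  })
  pathways <- sort(unique(unlist(pw_of)))
  out <- matrix(0, nrow = nrow(fp$counts), ncol = length(pathways),
                dimnames = list(rownames(fp$counts), pathways))
  for (i in seq_along(fams))
    for (p in pw_of[[i]])
      out[, p] <- out[, p] + fp$counts[, i]
  structure(list(counts = out), class = "pathway_profile")
}

#' @export
print.pathway_profile <- function(x, ...) {
  cat(sprintf("pathway profile: %d samples x %d pathways\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Per-taxon contribution shares to a gene-family set
#'
#' For a set of gene families (e.g. the transporter families), computes each
#' taxon's share of the total predicted counts over a sample scope:
#' share(taxon) = predicted counts from that taxon's OTUs / total predicted
#' counts.  Shares sum to 1 whenever the total is positive.
#'
#' @param x an [otu_table()]
#' @param ref a [gene_copy_table()]
#' @param tax a [taxonomy_map()]
#' @param families non-empty character vector of gene family ids
#' @param rank taxonomic rank at which to group OTUs (default `"genus"`)
#' @param samples optional sample scope
#' @return named numeric vector of shares (descending); empty, with a
#'   warning, when the total predicted count over the family set is zero
#' @export
taxon_contribution <- function(x, ref, tax, families, rank = "genus",
                               samples = NULL) {
  if (!length(families)) stop("family set is empty", call. = FALSE)
  rank <- match.arg(rank, TAX_RANKS)
  missing <- setdiff(families, colnames(ref$gene_copy))
  if (length(missing))
    stop("unknown gene family id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- otu_counts(x)
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  covered <- intersect(colnames(m), names(ref$ssu_copies))
  totals <- colSums(m[, covered, drop = FALSE])
  fam_copy <- rowSums(ref$gene_copy[covered, families, drop = FALSE])
  contrib <- totals / ref$ssu_copies[covered] * fam_copy
  if (sum(contrib) == 0) {
    warning("total predicted count over the family set is zero; ",
            "shares undefined", call. = FALSE)
    return(stats::setNames(numeric(0), character(0)))
  }
  label <- tax[[rank]][match(covered, tax$otu_id)]
  label[is.na(label)] <- "unclassified"
  shares <- tapply(contrib, label, sum) / sum(contrib)
  sort(c(shares), decreasing = TRUE)
}

#' Per-pathway group comparison (one-way ANOVA)
#'
#' Tests each pathway for differences in relative abundance across groups
#' (niches by default): each sample's pathway counts are normalized by the
#' sample total, then a one-way ANOVA F-test is run per pathway and p-values
#' are BH-adjusted across pathways.
#'
#' @param pp a `pathway_profile` from [aggregate_pathways()]
#' @param metadata a [sample_metadata()]
#' @param group metadata column defining the groups (default `"niche"`)
#' @return data.frame with one row per pathway: `F`, `df1`, `df2`, `p`, `q`,
#'   ordered by `F` descending
#' @export
pathway_group_test <- function(pp, metadata, group = "niche") {
  stopifnot(inherits(pp, "pathway_profile"))
  m <- pp$counts
  idx <- match(rownames(m), metadata$sample_id)
  if (anyNA(idx))
    stop("metadata does not cover sample(s): ",
         paste(rownames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
  grp <- metadata[[group]][idx]
  if (is.factor(grp)) grp <- droplevels(grp)
  grp <- as.factor(as.vector(grp))
  if (nlevels(grp) < 2L)
    stop("grouping '", group, "' has a single level", call. = FALSE)
  ls <- rowSums(m)
  if (any(ls == 0))
    stop("sample(s) with empty pathway profile: ",
         paste(rownames(m)[ls == 0], collapse = ", "), call. = FALSE)
  rel <- m / ls
  res <- lapply(colnames(rel), function(pw) {
    y <- rel[, pw]
    if (stats::var(y) < 1e-20 * (mean(y)^2 + 1)) {
      ## constant relative abundance: no group effect by construction
      return(data.frame(pathway = pw, F = 0, df1 = nlevels(grp) - 1L,
                        df2 = length(y) - nlevels(grp), p = 1,
                        stringsAsFactors = FALSE))
    }
    a <- suppressWarnings(stats::anova(stats::lm(y ~ grp)))
    data.frame(pathway = pw, F = a$`F value`[1], df1 = a$Df[1],
               df2 = a$Df[2], p = a$`Pr(>F)`[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out[order(-out$F), , drop = FALSE]
}
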