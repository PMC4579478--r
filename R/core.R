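## Core-microbiome computation: occupancy (prevalence) per OTU, thresholded
## core sets under an exact integer membership rule, prevalence sweeps over a
## fixed percent grid, the stabilization rule for picking the core threshold,
## and set algebra of core memberships across niches and species.

presence_counts <- function(x, samples = NULL, min_count = 1L) {
  m <- otu_counts(x)
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(m))
    if (length(missing))
      stop("scope samples not in table: ", paste(missing, collapse = ", "),
           call. = FALSE)
    m <- m[samples, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("empty sample scope", call. = FALSE)
  colSums(m >= min_count)
}

#' Per-OTU prevalence within a sample scope
#'
#' Prevalence is the fraction of scope samples in which the OTU is detected
#' (count >= `min_count`, default 1, i.e. presence = any nonzero count).
#'
#' @param x an [otu_table()]
#' @param samples character vector of sample ids defining the scope; default
#'   all samples
#' @param min_count detection floor; a sample counts as occupied when the
#'   OTU's count is at least this value
#' @return named numeric vector of fractions in \[0, 1\]
#' @export
prevalence <- function(x, samples = NULL, min_count = 1L) {
  k <- presence_counts(x, samples, min_count)
  n <- if (is.null(samples)) nrow(x) else length(samples)
  k / n
}

#' Core membership at a prevalence threshold
#'
#' An OTU belongs to the core of a scope at threshold `t` percent iff it is
#' present in at least `t`% of the scope samples.  Membership is decided in
#' integer arithmetic (`100 * k >= t * n` with `k` the presence count), so
#' boundary cases are exact: with n = 16 samples at t = 30, k = 5 is a member
#' (500 >= 480) and k = 4 is not.
#'
#' @param x an [otu_table()], or a named vector of presence *counts*
#'   (integers; supply `n_samples` in that case)
#' @param threshold integer percent in \[0, 100\]
#' @param samples optional scope (sample ids) when `x` is a table
#' @param n_samples number of scope samples when `x` is a count vector
#' @param min_count detection floor (see [prevalence()])
#' @param scope optional label describing the scope (species/niche)
#' @return a `core_set`: members, per-member prevalence, threshold and scope
#' @export
core_at_threshold <- function(x, threshold, samples = NULL,
                              n_samples = NULL, min_count = 1L,
                              scope = NULL) {
  if (threshold < 0 || threshold > 100 || threshold != round(threshold))
    stop("threshold must be an integer percent in [0, 100]", call. = FALSE)
  if (inherits(x, "otu_table") || is.matrix(x)) {
    k <- presence_counts(x, samples, min_count)
    n <- if (is.null(samples)) nrow(x) else length(samples)
  } else {
    if (is.null(n_samples))
      stop("n_samples is required when x is a presence-count vector",
           call. = FALSE)
    k <- x
    n <- n_samples
  }
  observed <- k >= 1L
  member <- observed & (100 * k >= threshold * n)
  structure(list(scope = scope, threshold = as.integer(threshold),
                 members = names(k)[member],
                 prevalence = (k / n)[member],
                 presence_counts = k[member],
                 n_samples = as.integer(n)),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core set (%s): %d OTUs at >= %d%% of %d samples\n",
              if (is.null(x$scope)) "unscoped"
              else paste(unlist(x$scope), collapse = "/"),
              length(x$members), x$threshold, x$n_samples))
  invisible(x)
}

#' Prevalence sweep over the threshold grid
#'
#' Computes the core size (number of member OTUs) at every threshold of the
#' percent grid `0, step, 2*step, ..., 100`.  The resulting curve is
#' non-increasing; its value at 0 is the number of OTUs observed at all in
#' the scope.
#'
#' @inheritParams core_at_threshold
#' @param step grid step in percent (default 2)
#' @return a `prevalence_curve`: integer thresholds and core sizes
#' @export
prevalence_sweep <- function(x, samples = NULL, step = 2L, min_count = 1L,
                             scope = NULL) {
  if (step < 1 || step > 100 || 100 %% step != 0)
    stop("step must be a positive integer divisor of 100", call. = FALSE)
  k <- presence_counts(x, samples, min_count)
  n <- if (is.null(samples)) nrow(x) else length(samples)
  k <- k[k >= 1L]                       # only OTUs observed in scope
  thresholds <- seq(0L, 100L, by = as.integer(step))
  core_size <- vapply(thresholds, function(t) sum(100 * k >= t * n),
                      integer(1))
  structure(list(scope = scope, thresholds = thresholds,
                 core_size = stats::setNames(core_size, thresholds),
                 n_samples = as.integer(n)),
            class = "prevalence_curve")
}

#' @export
print.prevalence_curve <- function(x, ...) {
  cat(sprintf("prevalence curve (%s): %d observed OTUs, n = %d samples\n",
              if (is.null(x$scope)) "unscoped"
              else paste(unlist(x$scope), collapse = "/"),
              x$core_size[[1]], x$n_samples))
  print(x$core_size)
  invisible(x)
}

#' Stabilization threshold of one or more prevalence curves
#'
#' The stabilization threshold is the smallest grid point at which the core
#' size stops changing relative to the previous grid point, simultaneously
#' in every supplied curve.  A grid point only becomes eligible for a curve
#' once that curve has registered at least one nonzero change (the leading
#' plateau at very low thresholds, where every observed OTU trivially
#' qualifies, is skipped); a curve that never changes, or never stabilizes
#' after changing, yields no threshold and a warning.
#'
#' @param curves a `prevalence_curve` or list of them (e.g. one per
#'   preparation type); all must share the same threshold grid
#' @param each if `TRUE`, return the per-curve stabilization points (a
#'   diagnostic) instead of the joint threshold
#' @return the joint threshold (integer percent), or `NA` with a warning if
#'   no grid point stabilizes all curves; for `each = TRUE`, a named integer
#'   vector with one entry per curve
#' @export
stabilization_threshold <- function(curves, each = FALSE) {
  if (inherits(curves, "prevalence_curve")) curves <- list(curves)
  if (!length(curves)) stop("need at least one curve", call. = FALSE)
  grid <- curves[[1]]$thresholds
  for (cv in curves)
    if (!identical(cv$thresholds, grid))
      stop("curves have mismatched threshold grids", call. = FALSE)
  eligible <- vapply(curves, function(cv) {
    d <- diff(cv$core_size)
    changed <- cumsum(d != 0) > 0
    c(FALSE, d == 0 & changed)          # position aligned with grid
  }, logical(length(grid)))
  eligible <- matrix(eligible, nrow = length(grid))
  if (each) {
    res <- apply(eligible, 2L, function(e)
      if (any(e)) grid[which(e)[1]] else NA_integer_)
    names(res) <- vapply(seq_along(curves), function(i) {
      sc <- curves[[i]]$scope
      if (is.null(sc)) sprintf("curve%d", i)
      else paste(unlist(sc), collapse = "/")
    }, "")
    return(res)
  }
  joint <- rowSums(eligible) == length(curves)
  if (!any(joint)) {
    warning("no stabilization point: core size never stops changing ",
            "simultaneously across the supplied curves", call. = FALSE)
    return(NA_integer_)
  }
  grid[which(joint)[1]]
}

#' Combine per-niche core sets into a species core
#'
#' The combined core is the union of the per-preparation cores, with
#' provenance recording, for every member, the niches whose core contains
#' it.  This recovers core members that are rare or undetectable in the
#' whole-community preparation but consistently present in a dissected
#' niche.
#'
#' @param cores named list of `core_set` objects (names = niches); all must
#'   share the same threshold
#' @return a `combined_core`: members, provenance, per-niche totals and
#'   counts of members unique to each niche
#' @export
combine_cores <- function(cores) {
  stopifnot(length(cores) >= 1)
  thr <- unique(vapply(cores, function(cs) cs$threshold, integer(1)))
  if (length(thr) != 1L)
    stop("cannot combine cores at mixed thresholds: ",
         paste(thr, collapse = ", "), call. = FALSE)
  if (is.null(names(cores)))
    names(cores) <- vapply(seq_along(cores), function(i)
      sprintf("set%d", i), "")
  members <- sort(unique(unlist(lapply(cores, `[[`, "members"))))
  prov <- lapply(members, function(m)
    names(cores)[vapply(cores, function(cs) m %in% cs$members, TRUE)])
  names(prov) <- members
  n_unique <- vapply(names(cores), function(nv)
    sum(lengths(prov) == 1L &
          vapply(prov, function(p) identical(p, nv), TRUE)), integer(1))
  structure(list(threshold = thr, members = members, provenance = prov,
                 niche_totals = vapply(cores, function(cs)
                   length(cs$members), integer(1)),
                 n_unique = n_unique),
            class = "combined_core")
}

#' @export
print.combined_core <- function(x, ...) {
  cat(sprintf("combined core at %d%%: %d OTUs (union of %s)\n",
              x$threshold, length(x$members),
              paste(sprintf("%s: %d", names(x$niche_totals),
                            x$niche_totals), collapse = ", ")))
  cat("members unique to one niche: ",
      paste(sprintf("%s: %d", names(x$n_unique), x$n_unique),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

as_member_set <- function(x) {
  if (inherits(x, "core_set") || inherits(x, "combined_core"))
    return(x$members)
  as.character(x)
}

#' Three-set Venn partition of core memberships
#'
#' Counts the seven exclusive regions of three member sets (e.g. the
#' holobiont, tissue and endosymbiotic cores of one species) plus each set's
#' total.  Region counts always sum to the size of the union, and each set's
#' total equals the sum of its four regions.
#'
#' @param a,b,c `core_set`s, `combined_core`s or plain character vectors
#' @param names labels for the three sets
#' @return a `venn_summary` with components `totals` and `regions` (named
#'   `"100"`, `"010"`, `"001"`, `"110"`, `"101"`, `"011"`, `"111"`, a digit
#'   per set in order)
#' @export
venn_summary <- function(a, b, c, names = c("A", "B", "C")) {
  sets <- list(as_member_set(a), as_member_set(b), as_member_set(c))
  universe <- unique(unlist(sets))
  inA <- universe %in% sets[[1]]
  inB <- universe %in% sets[[2]]
  inC <- universe %in% sets[[3]]
  key <- paste0(inA + 0L, inB + 0L, inC + 0L)
  regions <- stats::setNames(integer(7),
                             c("100", "010", "001", "110", "101", "011",
                               "111"))
  tab <- table(key)
  regions[names(tab)] <- as.integer(tab)
  structure(list(set_names = names,
                 totals = stats::setNames(lengths(sets), names),
                 regions = regions,
                 union_size = length(universe)),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("Venn partition of", paste(x$set_names, collapse = " / "), "\n")
  cat("totals:", paste(sprintf("%s = %d", x$set_names, x$totals),
                       collapse = ", "), "\n")
  cat(sprintf("shared by all three: %d\n", x$regions[["111"]]))
  excl <- x$regions[c("100", "010", "001")]
  cat("exclusive:", paste(sprintf("%s = %d", x$set_names, excl),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Cross-species universal core taxa
#'
#' Matches combined-core members across species at a taxonomic rank (OTU ids
#' are never compared across species: each species has its own id space, so
#' universal taxa can only be matched taxonomically).  Returns the
#' intersection of the species-wise label sets at `rank`, excluding
#' `"unclassified"`.
#'
#' @param cores list (one per species) of `combined_core` / `core_set`
#'   objects or member id vectors
#' @param taxonomies a single [taxonomy_map()] covering all species, or a
#'   list of maps parallel to `cores`
#' @param rank rank at which to match (default `"genus"`)
#' @return character vector of taxon labels present in every species' core
#' @export
universal_core <- function(cores, taxonomies, rank = "genus") {
  stopifnot(length(cores) >= 2)
  rank <- match.arg(rank, TAX_RANKS)
  if (inherits(taxonomies, "taxonomy_map"))
    taxonomies <- rep(list(taxonomies), length(cores))
  label_sets <- lapply(seq_along(cores), function(i) {
    members <- as_member_set(cores[[i]])
    tx <- taxonomies[[i]]
    idx <- match(members, tx$otu_id)
    if (anyNA(idx)) {
      warning("no taxonomy for core member(s): ",
              paste(members[is.na(idx)], collapse = ", "),
              "; skipped", call. = FALSE)
      idx <- idx[!is.na(idx)]
    }
    setdiff(unique(tx[[rank]][idx]), "unclassified")
  })
  sort(Reduce(intersect, label_sets))
}

#' Rare-biosphere summary of a core set
#'
#' Bands core members by their mean relative abundance across the
#' whole-community samples, showing how much of the core sits in the rare
#' biosphere (e.g. below 1% relative abundance) despite being consistently
#' present.
#'
#' @param core a `core_set`, `combined_core` or member id vector
#' @param x an [otu_table()] holding the whole-community samples
#' @param samples optional whole-community sample scope
#' @param cutoffs ascending relative-abundance cutoffs in (0, 1); default
#'   `c(0.01, 0.05)` giving bands `< 1%`, `1-5%` and `> 5%`
#' @return named integer vector of band counts (sums to the number of
#'   members), with per-member mean abundances as attribute
#'   `"mean_relab"`
#' @export
rare_core_summary <- function(core, x, samples = NULL,
                              cutoffs = c(0.01, 0.05)) {
  if (any(diff(cutoffs) <= 0) || any(cutoffs <= 0) || any(cutoffs >= 1))
    stop("cutoffs must be ascending fractions in (0, 1)", call. = FALSE)
  members <- as_member_set(core)
  m <- otu_counts(x)
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  rel <- m / rowSums(m)
  mean_relab <- stats::setNames(numeric(length(members)), members)
  absent <- setdiff(members, colnames(m))
  if (length(absent))
    warning(length(absent), " core member(s) absent from the ",
            "whole-community table; counted in the lowest band",
            call. = FALSE)
  hit <- intersect(members, colnames(m))
  mean_relab[hit] <- colMeans(rel[, hit, drop = FALSE])
  breaks <- c(-Inf, cutoffs, Inf)
  pct <- function(p) {
    v <- p * 100
    if (v == round(v)) sprintf("%d%%", as.integer(v)) else sprintf("%g%%", v)
  }
  labels <- c(paste0("<", pct(cutoffs[1])),
              if (length(cutoffs) > 1)
                vapply(seq_len(length(cutoffs) - 1), function(i)
                  paste0(pct(cutoffs[i]), "-", pct(cutoffs[i + 1])), ""),
              paste0(">", pct(cutoffs[length(cutoffs)])))
  band <- cut(mean_relab, breaks = breaks, labels = labels, right = TRUE)
  out <- stats::setNames(as.integer(table(band)), labels)
  attr(out, "mean_relab") <- mean_relab
  out
}
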