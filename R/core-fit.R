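#' Fit the niche-resolved core microbiome of one host species
#'
#' The central analysis: for every preparation type (niche) of one host
#' species, sweep core size over the prevalence-threshold grid, select the
#' core threshold by the stabilization rule (the lowest grid point at which
#' core size stops changing in every niche simultaneously) unless a
#' threshold is given, extract the per-niche cores, combine them into the
#' species core with provenance, partition three-niche memberships into Venn
#' regions, and band the combined core by whole-community relative abundance
#' (rare-biosphere summary).
#'
#' @param x an [otu_table()]
#' @param metadata a [sample_metadata()] covering every sample of `x`
#' @param species host species to analyse; required only when `metadata`
#'   holds more than one species
#' @param threshold core threshold in percent; `NULL` (default) selects it by
#'   [stabilization_threshold()], falling back to 30 with a warning if the
#'   curves never stabilize
#' @param grid_step sweep grid step in percent (default 2)
#' @param levels additional annotation thresholds at which cores are
#'   recorded (default 30, 50, 75, 90)
#' @param min_count detection floor for presence (default 1)
#' @param whole_community_niche niche whose samples define the
#'   whole-community scope for the rare-biosphere summary (default
#'   `"holobiont"`; falls back to all samples when absent)
#' @return an object of class `core_microbiome` with components `curves`
#'   (per-niche `prevalence_curve`s), `t_star`, `threshold`, `cores`
#'   (per-niche `core_set`s at `threshold`), `cores_at_levels`, `combined`
#'   (a `combined_core`), `venn` (when the species has exactly three
#'   niches), `rare_summary`, and bookkeeping fields.
#' @seealso [universal_core()] to intersect fits across species.
#' @examples
#' sim <- generate_community(synthetic_spec(
#'   species = "coral", niches = list(coral = c("holobiont", "tissue",
#'                                              "endosymbiotic")),
#'   samples_per_niche = 8, n_otus = 200, n_core = 20,
#'   depth_range = list(coral = c(5, 40)), seed = 7))
#' fit <- core_microbiome(sim$otu_table, sim$metadata)
#' fit
#' @export
core_microbiome <- function(x, metadata, species = NULL, threshold = NULL,
                            grid_step = 2L, levels = c(30L, 50L, 75L, 90L),
                            min_count = 1L,
                            whole_community_niche = "holobiont") {
  md <- metadata_for(x, metadata)
  sp_all <- unique(md$species)
  if (is.null(species)) {
    if (length(sp_all) > 1L)
      stop("metadata holds several species (",
           paste(sp_all, collapse = ", "),
           "); pick one with the 'species' argument", call. = FALSE)
    species <- sp_all
  }
  if (!species %in% sp_all)
    stop("species '", species, "' not present in metadata", call. = FALSE)
  md <- md[md$species == species, , drop = FALSE]
  if (any(levels < 0 | levels > 100 | levels != round(levels)))
    stop("annotation levels must be integer percents in [0, 100]",
         call. = FALSE)
  niches <- as.character(sort(unique(md$niche)))

  scope_samples <- lapply(niches, function(nv)
    md$sample_id[as.character(md$niche) == nv])
  names(scope_samples) <- niches

  curves <- lapply(niches, function(nv)
    prevalence_sweep(x, scope_samples[[nv]], step = grid_step,
                     min_count = min_count,
                     scope = list(species = species, niche = nv)))
  names(curves) <- niches

  t_star <- stabilization_threshold(curves)
  if (is.null(threshold)) {
    if (is.na(t_star)) {
      warning("no stabilization point; using the conservative 30% ",
              "threshold", call. = FALSE)
      threshold <- 30L
    } else threshold <- t_star
  }

  core_for <- function(t) {
    cs <- lapply(niches, function(nv)
      core_at_threshold(x, t, samples = scope_samples[[nv]],
                        min_count = min_count,
                        scope = list(species = species, niche = nv)))
    names(cs) <- niches
    cs
  }
  cores <- core_for(threshold)
  cores_at_levels <- lapply(levels, core_for)
  names(cores_at_levels) <- as.character(levels)

  combined <- combine_cores(cores)
  venn <- if (length(niches) == 3L)
    venn_summary(cores[[1]], cores[[2]], cores[[3]], names = niches)
  else NULL

  whole <- if (whole_community_niche %in% niches)
    scope_samples[[whole_community_niche]] else md$sample_id
  rare <- rare_core_summary(combined, x, samples = whole)

  n_observed <- sum(presence_counts(x, md$sample_id, min_count) >= 1L)
  structure(list(species = species, niches = niches,
                 scope_samples = scope_samples,
                 n_observed = n_observed,
                 curves = curves, t_star = t_star,
                 threshold = as.integer(threshold),
                 cores = cores, cores_at_levels = cores_at_levels,
                 combined = combined, venn = venn, rare_summary = rare,
                 grid_step = as.integer(grid_step),
                 levels = as.integer(levels), min_count = min_count),
            class = "core_microbiome")
}

#' @export
print.core_microbiome <- function(x, ...) {
  cat(sprintf("Core microbiome of %s (%d OTUs observed)\n",
              x$species, x$n_observed))
  cat(sprintf("threshold: %d%%%s\n", x$threshold,
              if (!is.na(x$t_star) && x$t_star == x$threshold)
                " (stabilization point)" else ""))
  for (nv in x$niches)
    cat(sprintf("  %-14s core: %3d OTUs (n = %d samples)\n", nv,
                length(x$cores[[nv]]$members), x$cores[[nv]]$n_samples))
  cat(sprintf("combined core: %d OTUs\n", length(x$combined$members)))
  if (!is.null(x$venn))
    cat(sprintf("shared by all niches: %d; exclusive: %s\n",
                x$venn$regions[["111"]],
                paste(sprintf("%s = %d", x$venn$set_names,
                              x$venn$regions[c("100", "010", "001")]),
                      collapse = ", ")))
  invisible(x)
}

#' @export
summary.core_microbiome <- function(object, ...) {
  x <- object
  lvl <- names(x$cores_at_levels)
  size_tab <- t(vapply(x$cores_at_levels, function(cs)
    vapply(cs, function(s) length(s$members), integer(1)),
    integer(length(x$niches))))
  combined_sizes <- vapply(x$cores_at_levels, function(cs)
    length(combine_cores(cs)$members), integer(1))
  out <- list(species = x$species, threshold = x$threshold,
              t_star = x$t_star, n_observed = x$n_observed,
              sizes_at_levels = cbind(size_tab, combined = combined_sizes),
              pct_of_community = round(100 * combined_sizes / x$n_observed,
                                       2),
              rare_summary = x$rare_summary)
  class(out) <- "summary.core_microbiome"
  out
}

#' @export
print.summary.core_microbiome <- function(x, ...) {
  cat(sprintf("Core microbiome summary: %s\n", x$species))
  cat(sprintf("observed OTUs: %d; selected threshold: %d%% (t* = %s)\n",
              x$n_observed, x$threshold,
              ifelse(is.na(x$t_star), "none", paste0(x$t_star, "%"))))
  cat("core sizes by annotation level:\n")
  print(x$sizes_at_levels)
  cat("combined core as % of observed community:\n")
  print(x$pct_of_community)
  cat("combined core by whole-community mean relative abundance:\n")
  rs <- x$rare_summary
  attributes(rs) <- list(names = names(rs))
  print(rs)
  invisible(x)
}

#' @export
plot.core_microbiome <- function(x, ...) {
  sizes <- vapply(x$curves, `[[`, x$curves[[1]]$core_size, "core_size")
  graphics::matplot(x$curves[[1]]$thresholds, sizes, type = "s", lty = 1,
                    lwd = 2, col = seq_along(x$niches),
                    xlab = "prevalence threshold (% of samples)",
                    ylab = "core size (OTUs)",
                    main = sprintf("Prevalence sweep: %s", x$species), ...)
  if (!is.na(x$t_star))
    graphics::abline(v = x$t_star, lty = 2, col = "grey40")
  graphics::legend("topright", legend = x$niches,
                   col = seq_along(x$niches), lty = 1, lwd = 2, bty = "n")
  invisible(x)
}
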