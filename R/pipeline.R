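## End-to-end orchestration: simulate (or load) -> per-species core fits ->
## universal core -> diversity -> ordination -> permutation tests ->
## differential abundance -> predicted metagenomes -> JSON run report.
## Every stochastic stage draws from a seed derived from the single run
## seed, so a rerun with the same config is byte-identical.

#' Pipeline run configuration
#'
#' Validates and normalizes the configuration for [run_pipeline()].  Either
#' give input paths (`otu_table`, `metadata`, optionally `taxonomy`,
#' `gene_reference`, `pathway_map`) or omit them to simulate a community
#' from `spec`.
#'
#' @param outdir output directory (created if needed)
#' @param seed integer master seed; required (all randomness derives from
#'   it)
#' @param inputs optional named list of input paths
#' @param spec a [synthetic_spec()] used when no inputs are given; its seed
#'   is overridden by `seed`
#' @param grid_step prevalence sweep step in percent
#' @param levels core annotation levels (integer percents in \[0, 100\])
#' @param match_rank rank for cross-species core matching
#' @param n_perm permutations for PERMANOVA / ANOSIM
#' @param min_count detection floor for presence
#' @param min_prevalence prevalence filter for differential abundance
#' @return a validated `run_config`
#' @export
run_config <- function(outdir, seed, inputs = NULL, spec = NULL,
                       grid_step = 2L, levels = c(30L, 50L, 75L, 90L),
                       match_rank = "genus", n_perm = 199L,
                       min_count = 1L, min_prevalence = 0.1) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required", call. = FALSE)
  if (any(levels < 0 | levels > 100 | levels != round(levels)))
    stop("invalid annotation level(s): ",
         paste(levels[levels < 0 | levels > 100 | levels != round(levels)],
               collapse = ", "), " (must be integer percents in [0, 100])",
         call. = FALSE)
  if (100 %% grid_step != 0)
    stop("grid_step must divide 100", call. = FALSE)
  match_rank <- match.arg(match_rank, TAX_RANKS)
  if (is.null(inputs)) {
    if (is.null(spec)) spec <- synthetic_spec(seed = as.integer(seed))
    else spec$seed <- as.integer(seed)
  }
  structure(list(outdir = outdir, seed = as.integer(seed),
                 inputs = inputs, spec = spec,
                 grid_step = as.integer(grid_step),
                 levels = as.integer(levels), match_rank = match_rank,
                 n_perm = as.integer(n_perm),
                 min_count = as.integer(min_count),
                 min_prevalence = min_prevalence),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `spec` block is
#' passed to [synthetic_spec()] (scalar fields only).
#'
#' @param path YAML file
#' @param ... overrides applied on top of the file's values
#' @return a `run_config`
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  overrides <- list(...)
  for (k in names(overrides)) y[[k]] <- overrides[[k]]
  if (!is.null(y$spec)) y$spec <- do.call(synthetic_spec, y$spec)
  do.call(run_config, y)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

subset_species <- function(x, metadata, sp) {
  md <- metadata_for(x, metadata)
  keep <- md$sample_id[md$species == sp]
  m <- otu_counts(x)[keep, , drop = FALSE]
  m <- m[, colSums(m) > 0, drop = FALSE]   # OTUs observed in this species
  otu_table(m)
}

#' Run the full niche-resolved core-microbiome pipeline
#'
#' Executes, in dependency order: simulation (or loading), per-species core
#' fits ([core_microbiome()]), cross-species [universal_core()], diversity
#' (richness/Shannon + [diversity_model()]), Bray-Curtis ordination
#' ([pcoa()]), [permanova()] and [anosim()], quasi-Poisson
#' [diff_abundance()], and predicted metagenomes
#' ([predict_metagenome()] / [aggregate_pathways()] /
#' [pathway_group_test()] / [taxon_contribution()]).  All result files are
#' TSV; a single JSON run report collects parameters, warnings and headline
#' numbers.  Output is byte-identical across reruns with the same
#' configuration and seed.
#'
#' @param config a `run_config` (or a YAML path, read with
#'   [read_run_config()])
#' @return the run report, invisibly (also written to
#'   `<outdir>/report.json`)
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(parameters = list(
    seed = config$seed, grid_step = config$grid_step,
    levels = config$levels, match_rank = config$match_rank,
    n_perm = config$n_perm, min_count = config$min_count,
    min_prevalence = config$min_prevalence))
  report$warnings <- list()
  report$files <- character(0)
  current_stage <- "setup"
  note_warning <- function(w) {
    report$warnings[[length(report$warnings) + 1]] <<-
      list(stage = current_stage, message = conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    write_tsv(df, path)
    report$files <<- c(report$files, name)
    path
  }

  res <- withCallingHandlers(tryCatch({
    ## ---- inputs ----
    current_stage <- "simulate"
    if (is.null(config$inputs)) {
      sim <- generate_community(config$spec)
      x <- sim$otu_table
      tax <- sim$taxonomy
      metadata <- sim$metadata
      ref <- generate_gene_reference(config$spec)
      ground_truth <- sim$ground_truth
      write_otu_table(x, file.path(outdir, "otu_table.tsv"),
                      dialect = "biom_classic", taxonomy = tax)
      write_taxonomy(tax, file.path(outdir, "taxonomy.tsv"))
      write_metadata(metadata, file.path(outdir, "metadata.tsv"))
      write_gene_copy_table(ref, file.path(outdir, "gene_reference.tsv"),
                            file.path(outdir, "pathway_map.tsv"))
      report$files <- c(report$files, "otu_table.tsv", "taxonomy.tsv",
                        "metadata.tsv", "gene_reference.tsv",
                        "pathway_map.tsv")
    } else {
      current_stage <- "load"
      x <- read_otu_table(config$inputs$otu_table,
                          dialect = config$inputs$dialect %||% "classic_tsv")
      tax <- if (!is.null(config$inputs$taxonomy))
        read_taxonomy(config$inputs$taxonomy)
      else attr(x, "taxonomy")
      metadata <- read_metadata(config$inputs$metadata)
      ref <- if (!is.null(config$inputs$gene_reference))
        read_gene_copy_table(config$inputs$gene_reference,
                             config$inputs$pathway_map)
      else NULL
      ground_truth <- NULL
    }
    check_metadata_covers(x, metadata)
    md <- metadata_for(x, metadata)
    species_list <- unique(md$species)

    ## ---- per-species core fits ----
    current_stage <- "core"
    fits <- list()
    for (sp in species_list) {
      xs <- subset_species(x, metadata, sp)
      fit <- core_microbiome(xs, metadata, species = sp,
                             grid_step = config$grid_step,
                             levels = config$levels,
                             min_count = config$min_count)
      fits[[sp]] <- fit
      curve_df <- data.frame(threshold = fit$curves[[1]]$thresholds)
      for (nv in fit$niches)
        curve_df[[nv]] <- unname(fit$curves[[nv]]$core_size)
      emit(curve_df, sprintf("curves_%s.tsv", sp))
      mem <- fit$combined$members
      emit(data.frame(
        otu_id = mem,
        provenance = vapply(fit$combined$provenance[mem], paste,
                            "", collapse = ","),
        vapply(fit$niches, function(nv) {
          pr <- prevalence(xs, fit$scope_samples[[nv]],
                           min_count = config$min_count)
          round(pr[mem], 4)
        }, numeric(length(mem))),
        check.names = FALSE), sprintf("core_%s.tsv", sp))
      sm <- summary(fit)
      report$core[[sp]] <- list(
        n_observed = fit$n_observed, t_star = fit$t_star,
        threshold = fit$threshold,
        niche_core_sizes = as.list(fit$combined$niche_totals),
        combined_size = length(fit$combined$members),
        sizes_at_levels = apply(sm$sizes_at_levels, 1, as.list),
        pct_of_community = as.list(sm$pct_of_community),
        rare_bands = as.list(fit$rare_summary),
        venn = if (!is.null(fit$venn)) as.list(fit$venn$regions))
    }

    ## ---- universal core ----
    current_stage <- "universal"
    universal <- NULL
    if (length(fits) >= 2 && !is.null(tax)) {
      universal <- universal_core(lapply(fits, `[[`, "combined"), tax,
                                  rank = config$match_rank)
      emit(data.frame(rank = config$match_rank, taxon = universal),
           "universal_core.tsv")
      report$universal <- list(rank = config$match_rank, taxa = universal)
    }

    ## ---- diversity ----
    current_stage <- "diversity"
    div <- data.frame(sample_id = sample_ids(x),
                      richness = unname(richness(x)),
                      shannon = round(unname(shannon(x)), 6))
    emit(div, "diversity.tsv")
    ## depth enters the models only where it varies within the species
    ## (a species sampled at a single depth has no depth effect to fit)
    depth_varies <- vapply(species_list, function(sp)
      length(unique(md$depth[md$species == sp])) > 1L, TRUE)
    names(depth_varies) <- species_list
    for (sp in species_list) {
      xs <- subset_species(x, metadata, sp)
      form <- if (depth_varies[[sp]]) ~ niche + depth else ~ niche
      dm_sh <- diversity_model(shannon(xs), metadata, formula = form)
      dm_ri <- diversity_model(richness(xs), metadata, formula = form)
      report$diversity[[sp]] <- list(
        shannon_niche_p = dm_sh$table["niche", "Pr(>F)"],
        richness_niche_p = dm_ri$table["niche", "Pr(>F)"])
    }

    ## ---- ordination + permutation tests ----
    current_stage <- "ordination"
    for (sp in species_list) {
      xs <- subset_species(x, metadata, sp)
      d <- bray_curtis(xs, relative = TRUE)
      emit(data.frame(sample_id = rownames(d),
                      round(as.data.frame(unclass(d)), 6),
                      check.names = FALSE),
           sprintf("braycurtis_%s.tsv", sp))
      pc <- pcoa(d)
      k <- min(3L, ncol(pc$coordinates))
      emit(data.frame(sample_id = rownames(pc$coordinates),
                      round(as.data.frame(
                        pc$coordinates[, seq_len(k), drop = FALSE]), 6)),
           sprintf("pcoa_%s.tsv", sp))
      current_stage <- "permanova"
      pv_terms <- if (depth_varies[[sp]])
        c("niche", "depth", "niche:depth") else "niche"
      pv <- permanova(d, metadata, pv_terms,
                      n_perm = config$n_perm,
                      seed = derive_seed(config$seed, 11L))
      emit(cbind(term = rownames(pv$table), round(pv$table, 6)),
           sprintf("permanova_%s.tsv", sp))
      mds <- metadata_for(xs, metadata)
      an <- anosim(d, stats::setNames(as.character(mds$niche),
                                      mds$sample_id),
                   n_perm = config$n_perm,
                   seed = derive_seed(config$seed, 12L))
      report$beta[[sp]] <- list(
        permanova_niche_p = pv$table["niche", "Pr(>F)"],
        permanova_niche_R2 = pv$table["niche", "R2"],
        anosim_R = an$R, anosim_p = an$p,
        pcoa_axis1_pct = 100 * pc$proportion_explained[1])
    }

    ## ---- differential abundance ----
    current_stage <- "diffabund"
    for (sp in species_list) {
      xs <- subset_species(x, metadata, sp)
      da <- diff_abundance(xs, metadata, design = ~ niche,
                           min_prevalence = config$min_prevalence)
      tab <- da$table[da$table$status == "ok", , drop = FALSE]
      tab <- tab[order(tab$q, tab$p), , drop = FALSE]
      num <- vapply(tab, is.numeric, TRUE)
      tab[num] <- lapply(tab[num], function(v) signif(v, 6))
      emit(tab[setdiff(names(tab), "status")],
           sprintf("diffabund_%s.tsv", sp))
      report$diffabund[[sp]] <- list(
        n_tested = da$n_tested,
        n_significant_q05 = sum(tab$q <= 0.05, na.rm = TRUE),
        top_otus = utils::head(tab$otu_id, 5))
    }

    ## ---- predicted metagenomes ----
    current_stage <- "predict"
    if (!is.null(ref)) {
      fp <- predict_metagenome(x, ref)
      emit(data.frame(sample_id = rownames(fp$counts),
                      round(as.data.frame(fp$counts), 4),
                      check.names = FALSE), "function_profile.tsv")
      pp <- aggregate_pathways(fp, ref$pathway_map)
      emit(data.frame(sample_id = rownames(pp$counts),
                      round(as.data.frame(pp$counts), 4),
                      check.names = FALSE), "pathway_profile.tsv")
      for (sp in species_list) {
        mds <- md[md$species == sp, , drop = FALSE]
        ppx <- structure(list(counts =
                                pp$counts[mds$sample_id, , drop = FALSE]),
                         class = "pathway_profile")
        pt <- pathway_group_test(ppx, metadata)
        pt[c("F", "p", "q")] <- lapply(pt[c("F", "p", "q")], signif, 6)
        emit(pt, sprintf("pathway_tests_%s.tsv", sp))
        report$pathways[[sp]] <- list(top_pathways =
                                        utils::head(pt$pathway, 5))
      }
      ## transporter contribution in the endosymbiotic niche, where present
      endo <- md$sample_id[md$niche == "endosymbiotic"]
      if (length(endo) && !is.null(tax) &&
          "K_transport" %in% colnames(ref$gene_copy)) {
        shares <- taxon_contribution(x, ref, tax, "K_transport",
                                     rank = config$match_rank,
                                     samples = endo)
        report$transport_contribution <- as.list(
          round(utils::head(shares, 5), 4))
      }
    }

    current_stage <- "report"
    report$ground_truth_available <- !is.null(ground_truth)
    path <- file.path(outdir, "report.json")
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    report$files <- c(report$files, "report.json")
    report
  }, error = function(e) {
    writeLines(c("INCOMPLETE RUN", paste("failed stage:", current_stage),
                 paste("error:", conditionMessage(e)),
                 "files written:", report$files),
               file.path(outdir, "MANIFEST"))
    stop("[stage ", current_stage, "] ", conditionMessage(e),
         call. = FALSE)
  }), warning = note_warning)
  invisible(res)
}
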