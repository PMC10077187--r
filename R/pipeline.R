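# End-to-end pipeline: counts -> SparCC -> signed bipartite networks ->
# topology, nestedness nulls, modules/roles, core taxa, robustness.

.default_config <- function() {
  list(
    habitat = "",
    prevalence_fraction = 0.5,
    rarefy_depth_bacteria = NULL,      # NULL skips rarefaction
    rarefy_depth_eukaryotes = NULL,
    step_order = "rarefy_then_filter", # or "filter_then_rarefy"
    sparcc = list(n_draws = 20L, exclusion_threshold = 0.1,
                  max_exclusion_rounds = 10L, n_boot = 100L),
    r_threshold = 0.6,
    p_threshold = 0.05,
    n_rand = 100L,                     # nestedness null randomizations
    robustness_reps = 100L,
    restarts = 10L,                    # modularity restarts
    robustness_signs = "positive",     # the mutualistic network by default
    seed = 1L)
}

#' Assemble and validate a pipeline configuration
#'
#' Unspecified fields take the study-style defaults (prevalence fraction 0.5,
#' correlation threshold 0.6, p threshold 0.05, 100 null randomizations, 100
#' robustness replicates). Accepts a YAML file path or a named list.
#'
#' @param config named list or YAML path; may contain `synthetic` (arguments
#'   to [synthetic_spec()]) or `inputs` (paths `bacteria`, `eukaryotes` and
#'   optional `taxonomy`).
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.default_config(), config)
  for (f in c("r_threshold", "p_threshold"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stopf("config error: %s must lie strictly inside (0, 1)", f)
  if (cfg$prevalence_fraction <= 0 || cfg$prevalence_fraction > 1)
    stopf("config error: prevalence_fraction must be in (0, 1]")
  if (is.null(cfg$synthetic) && is.null(cfg$inputs))
    stopf("config error: provide either 'synthetic' or 'inputs'")
  structure(cfg, class = c("pipeline_config", "list"))
}

.log_msg <- function(...) message("[biparcc] ", sprintf(...))

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes: input acquisition (synthetic generation or table reading) ->
#' rarefaction and prevalence filtering -> sample alignment -> pooled SparCC
#' with permutation p-values -> edge thresholding -> cross-kingdom extraction
#' -> per-sign networks -> topology report, nestedness null test, module
#' detection with z-c roles, core-taxa symmetry, and co-extinction
#' robustness. All stage seeds derive deterministically from the master
#' seed, so a rerun with the same config reproduces every number.
#'
#' @param config a [pipeline_config()], list, or YAML path.
#' @param out_dir output directory (created if missing); reports are JSON,
#'   tables TSV, networks GraphML.
#' @return The report bundle (named list), invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # --- inputs -------------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$synthetic)) {
    .log_msg("generating synthetic community")
    args <- cfg$synthetic
    # YAML-friendly planted-edge shorthand
    if (!is.null(args$n_pos) || !is.null(args$n_neg) ||
        !is.null(args$magnitude)) {
      args$planted <- planted_edges(args$n_pos %||% 24, args$n_neg %||% 16,
                                    args$magnitude %||% 0.9)
      args$n_pos <- args$n_neg <- args$magnitude <- NULL
    }
    args$seed <- args$seed %||% derive_seed(cfg$seed, "simulate")
    sim <- stage("simulate", generate_community(do.call(synthetic_spec, args)))
    bact <- sim$bacteria; euk <- sim$eukaryotes
    taxonomy <- sim$truth$taxonomy
    truth <- sim$truth
  } else {
    .log_msg("reading input tables")
    bact <- stage("read", read_otu_table(cfg$inputs$bacteria, "bacteria"))
    euk <- stage("read", read_otu_table(cfg$inputs$eukaryotes,
                                        "microeukaryote"))
    taxonomy <- if (!is.null(cfg$inputs$taxonomy))
      stage("read", read_taxonomy(cfg$inputs$taxonomy)) else NULL
  }

  # --- rarefy / filter ----------------------------------------------------
  do_rarefy <- function() {
    if (!is.null(cfg$rarefy_depth_bacteria))
      bact <<- stage("rarefy", rarefy(bact, cfg$rarefy_depth_bacteria,
                                      derive_seed(cfg$seed, "rarefy_b")))
    if (!is.null(cfg$rarefy_depth_eukaryotes))
      euk <<- stage("rarefy", rarefy(euk, cfg$rarefy_depth_eukaryotes,
                                     derive_seed(cfg$seed, "rarefy_e")))
  }
  do_filter <- function() {
    bact <<- stage("filter", prevalence_filter(bact, cfg$prevalence_fraction))
    euk <<- stage("filter", prevalence_filter(euk, cfg$prevalence_fraction))
  }
  if (identical(cfg$step_order, "filter_then_rarefy")) {
    do_filter(); do_rarefy()
  } else {
    do_rarefy(); do_filter()
  }
  aligned <- stage("align", align_samples(euk, bact))
  euk <- aligned$a; bact <- aligned$b
  .log_msg("%d microeukaryotic and %d bacterial OTUs over %d samples",
           nrow(euk$counts), nrow(bact$counts), ncol(euk$counts))

  # --- SparCC -------------------------------------------------------------
  pooled <- rbind(euk$counts, bact$counts)
  .log_msg("SparCC on %d pooled OTUs (%d draws, %d permutations)",
           nrow(pooled), cfg$sparcc$n_draws, cfg$sparcc$n_boot)
  fit <- stage("sparcc", sparcc(pooled, n_draws = cfg$sparcc$n_draws,
                                seed = derive_seed(cfg$seed, "sparcc"),
                                exclusion_threshold = cfg$sparcc$exclusion_threshold,
                                max_exclusion_rounds = cfg$sparcc$max_exclusion_rounds))
  sig <- stage("sparcc", sparcc_pvalues(pooled, fit,
                                        n_boot = cfg$sparcc$n_boot,
                                        seed = derive_seed(cfg$seed, "boot")))
  edges <- stage("edges", significant_edges(fit, sig, cfg$r_threshold,
                                            cfg$p_threshold))
  cross <- stage("edges", extract_cross_kingdom(edges, rownames(euk$counts),
                                                rownames(bact$counts)))
  write_edges(cross, file.path(out_dir, "edges.tsv"))
  .log_msg("%d significant edges, %d cross-kingdom", nrow(edges),
           nrow(cross))

  # --- networks and per-sign analyses -------------------------------------
  nets <- stage("build", split_by_sign(cross, cfg$habitat, taxonomy))
  report <- list(schema_version = "1.0",
                 n_edges_total = nrow(edges),
                 n_edges_cross_kingdom = nrow(cross))
  for (sgn in c("positive", "negative")) {
    net <- nets[[sgn]]
    if (nrow(net$weights) == 0L || ncol(net$weights) == 0L) {
      .log_msg("%s network is empty; skipping its analyses", sgn)
      report[[sgn]] <- list(empty = TRUE)
      next
    }
    .log_msg("analysing %s network", sgn)
    write_edges(net$edges, file.path(out_dir, paste0(sgn, "_edges.tsv")))
    export_graphml(net, file.path(out_dir, paste0(sgn, "_network.graphml")))
    met <- stage("metrics", network_report(net))
    nest <- if (nrow(net$weights) >= 2 && ncol(net$weights) >= 2)
      stage("nestedness",
            nodf_significance(net, cfg$n_rand,
                              derive_seed(cfg$seed, paste0("nodf_", sgn))))
    else NULL
    part <- stage("modules",
                  dirt_lpawb_plus(net, cfg$restarts,
                                  derive_seed(cfg$seed, paste0("mod_", sgn))))
    roles <- stage("modules", node_roles(net, part))
    utils::write.table(roles, file.path(out_dir, paste0(sgn, "_roles.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    nm <- stage("metrics", node_metrics(net))
    utils::write.table(nm, file.path(out_dir, paste0(sgn, "_nodes.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rob <- NULL
    if (sgn %in% cfg$robustness_signs) {
      rob <- lapply(c(rows = "rows", cols = "cols"), function(g) {
        rnd <- extinction_random(net, g, cfg$robustness_reps,
                                 derive_seed(cfg$seed, paste0("rr_", sgn, g)))
        gen <- extinction_generalist_first(net, g, cfg$robustness_reps,
                                           derive_seed(cfg$seed,
                                                       paste0("rg_", sgn, g)))
        list(random = list(mean_R = rnd$mean_R, sd_R = rnd$sd_R),
             generalist_first = list(mean_R = gen$mean_R, sd_R = gen$sd_R),
             n_replicates = cfg$robustness_reps)
      })
    }
    sgn_report <- list(
      metrics = unclass(met),
      nestedness = if (!is.null(nest))
        list(observed_NODF = nest$observed, null_mean = mean(nest$null),
             null_sd = stats::sd(nest$null), p_higher = nest$p_higher,
             p_lower = nest$p_lower, n_rand = nest$n_rand),
      modularity = list(Q = part$Q, n_modules = part$n_modules,
                        roles = as.list(table(roles$role))),
      robustness = rob)
    .write_json(sgn_report, file.path(out_dir, paste0(sgn, "_report.json")))
    report[[sgn]] <- sgn_report
  }

  # --- core taxa ----------------------------------------------------------
  if (is.null(report$positive$empty) && is.null(report$negative$empty)) {
    core <- stage("core", core_taxa(nets$positive, nets$negative))
    utils::write.table(core$nodes, file.path(out_dir, "core_taxa.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$core <- list(n_core = as.list(core$n_core),
                        coverage = as.list(core$coverage))
  }

  # --- ground truth + manifest --------------------------------------------
  if (!is.null(truth))
    write_ground_truth(truth, file.path(out_dir, "ground_truth.tsv"))
  manifest <- list(
    package = "biparcc",
    version = as.character(utils::packageVersion("biparcc")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = unclass(cfg))
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  .write_json(report, file.path(out_dir, "report.json"))
  .log_msg("done; reports in %s", out_dir)
  invisible(report)
}
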