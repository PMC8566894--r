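# End-to-end orchestration: load or simulate a dataset, then run
# diversity -> NCM -> phylogenetic null models -> NST -> phylogenetic signal
# -> drivers, with one global seed fanned out per stage and a machine-
# readable report.

.config_keys <- list(
  top = c("input", "simulate", "rarefy_depth", "seed", "output_dir",
          "group_var", "env_variable", "n_null", "n_perm_permanova",
          "bnti_threshold", "rc_threshold", "nst_metric", "nst_variant",
          "nst_panova_n_null", "nst_panova_n_perm", "network"),
  input = c("otu_table", "tree", "metadata", "orientation"),
  simulate = c("n_samples", "n_taxa", "regime", "m", "sigma_w", "N", "depth",
               "generations", "lognormal_sigma", "sigma2_bm", "trait_root",
               "seed"),
  network = c("r_threshold", "p_threshold", "min_reads"))

#' Validate a pipeline configuration
#'
#' Checks the schema before any computation: unknown keys are rejected by
#' name, exactly one of `input` / `simulate` must be present, and numeric
#' parameters must be sane.
#'
#' @param config a named list (parsed from JSON or built in R).
#' @return the config with defaults filled in.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .config_keys$top)
  if (length(unknown))
    stop("unknown configuration key: ", paste(unknown, collapse = ", "))
  for (blk in c("input", "simulate", "network")) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), .config_keys[[blk]])
      if (length(bad))
        stop("unknown configuration key: ", blk, "$",
             paste(bad, collapse = ", "))
    }
  }
  if (is.null(config$input) == is.null(config$simulate))
    stop("config needs exactly one of 'input' or 'simulate'")
  config$seed <- config$seed %||% 1
  config$n_null <- config$n_null %||% 999
  config$n_perm_permanova <- config$n_perm_permanova %||% 9999
  config$bnti_threshold <- config$bnti_threshold %||% 2
  config$rc_threshold <- config$rc_threshold %||% 0.95
  config$nst_metric <- config$nst_metric %||% "bray"
  config$nst_variant <- config$nst_variant %||% "abundance"
  config$nst_panova_n_null <- config$nst_panova_n_null %||% 49
  config$nst_panova_n_perm <- config$nst_panova_n_perm %||% 199
  config$env_variable <- config$env_variable %||% "temperature"
  config$network <- utils::modifyList(
    list(r_threshold = 0.5, p_threshold = 0.05, min_reads = 10),
    config$network %||% list())
  if (config$n_null < 99) stop("n_null must be >= 99")
  config
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  path
}

dist_to_long <- function(d, value_name) {
  out <- pair_index(attr(d, "Labels"))
  out[[value_name]] <- as.vector(d)
  out
}

#' Run the full assembly-inference pipeline
#'
#' Executes, in dependency order: data loading or simulation, optional
#' rarefaction, alpha/beta diversity, the Sloan NCM fit, betaNTI + RC-Bray +
#' process classification, NST (per group when a grouping variable is
#' configured, with a permutational ANOVA between the first two groups),
#' phylogenetic signal of the configured environmental variable, and the
#' driver statistics (Mantel, PERMANOVA, co-occurrence network). All
#' randomness derives from the global seed via per-stage sub-seeds, so the
#' same config yields byte-identical tables.
#'
#' @param config configuration list (see [validate_config()]) or path to a
#'   JSON config.
#' @param output_dir overrides `config$output_dir`; `NULL` keeps results in
#'   memory only.
#' @return object of class `assembly_report`: list of per-stage results plus
#'   `stages` (status/seconds/outputs per stage), `seed` and `config`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_config(config)
  outdir <- output_dir %||% config$output_dir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  report <- list(seed = seed, config = config,
                 stages = list(), results = list())

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    report$stages[[name]] <<- list(status = "succeeded",
                                   seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  emit <- function(df, file) {
    if (!is.null(outdir)) write_tsv(df, file.path(outdir, file))
  }

  dat <- run_stage("data", function() {
    if (!is.null(config$simulate)) {
      ds <- do.call(simulate_dataset,
                    utils::modifyList(config$simulate,
                                      list(seed = config$simulate$seed %||% seed)))
      list(community = ds$community, tree = ds$tree, env = ds$env,
           dataset = ds)
    } else {
      inp <- config$input
      list(community = read_otu_table(inp$otu_table,
                                      orientation = inp$orientation %||% "taxa-rows"),
           tree = read_phylogeny(inp$tree),
           env = read_sample_metadata(inp$metadata))
    }
  })
  comm <- dat$community
  if (!is.null(config$rarefy_depth))
    comm <- run_stage("rarefy", function()
      rarefy_even_depth(comm, config$rarefy_depth,
                        seed = stage_seed(seed, "rarefy")))
  env <- dat$env[dat$env$sample_id %in% rownames(comm), , drop = FALSE]

  groups <- NULL
  if (!is.null(config$group_var)) {
    if (!config$group_var %in% colnames(env))
      stop("group_var not in metadata: ", config$group_var)
    groups <- env[[config$group_var]][match(rownames(comm), env$sample_id)]
  }

  alpha <- run_stage("diversity", function() {
    a <- alpha_diversity(comm)
    emit(a, "alpha_diversity.tsv")
    a
  })
  bray <- dissimilarity(comm, "bray")
  emit(dist_to_long(bray, "bray_curtis"), "bray_curtis.tsv")

  ncm_fit <- run_stage("ncm", function() {
    fit <- fit_ncm(comm)
    emit(fit$taxa, "ncm_taxa.tsv")
    fit
  })

  processes <- run_stage("stegen", function() {
    bn <- beta_nti(comm, dat$tree, n_null = config$n_null,
                   seed = stage_seed(seed, "bnti"))
    rc <- rc_bray(comm, n_null = config$n_null,
                  seed = stage_seed(seed, "rc"))
    cls <- classify_processes(bn, rc, config$bnti_threshold,
                              config$rc_threshold)
    emit(cls$pairs, "assembly_processes.tsv")
    cls
  })

  nst_res <- run_stage("nst", function() {
    if (!is.null(groups) && all(table(groups) >= 3) &&
        length(unique(groups)) >= 2) {
      per_group <- lapply(split(rownames(comm), groups), function(ids)
        nst(comm, config$nst_metric, config$nst_variant,
            n_null = config$n_null, group = ids,
            seed = stage_seed(seed, "nst")))
      lv <- names(per_group)
      pan <- nst_panova(comm,
                        split(rownames(comm), groups)[lv[1:2]],
                        metric = config$nst_metric,
                        variant = config$nst_variant,
                        n_null = config$nst_panova_n_null,
                        n_perm = config$nst_panova_n_perm,
                        seed = stage_seed(seed, "nst_panova"))
      tab <- data.frame(group = lv,
                        nst = vapply(per_group, `[[`, numeric(1), "nst"),
                        perm_mean = vapply(per_group, `[[`, numeric(1), "perm_mean"),
                        perm_sd = vapply(per_group, `[[`, numeric(1), "perm_sd"))
      emit(tab, "nst.tsv")
      list(per_group = per_group, panova = pan, table = tab)
    } else {
      one <- nst(comm, config$nst_metric, config$nst_variant,
                 n_null = config$n_null, seed = stage_seed(seed, "nst"))
      tab <- data.frame(group = "all", nst = one$nst,
                        perm_mean = one$perm_mean, perm_sd = one$perm_sd)
      emit(tab, "nst.tsv")
      list(per_group = list(all = one), panova = NULL, table = tab)
    }
  })

  signal <- run_stage("signal", function() {
    if (!config$env_variable %in% colnames(env)) {
      NULL
    } else {
      tab <- phylo_signal_table(comm, env, dat$tree, config$env_variable,
                                n_perm = config$n_null,
                                seed = stage_seed(seed, "signal"))
      emit(tab, "phylo_signal.tsv")
      tab
    }
  })

  drivers <- run_stage("drivers", function() {
    out <- list()
    if (config$env_variable %in% colnames(env)) {
      ev <- env[[config$env_variable]][match(rownames(comm), env$sample_id)]
      if (!anyNA(ev) && stats::sd(ev) > 0) {
        denv <- stats::dist(ev)
        attr(denv, "Labels") <- rownames(comm)
        out$mantel <- mantel_test(bray, denv, n_perm = config$n_null,
                                  seed = stage_seed(seed, "mantel"))
      }
    }
    if (!is.null(groups) && length(unique(groups)) >= 2 &&
        all(table(groups) >= 2))
      out$permanova <- permanova(bray, groups,
                                 n_perm = config$n_perm_permanova,
                                 seed = stage_seed(seed, "permanova"))
    net <- correlation_network(comm, env,
                               r_threshold = config$network$r_threshold,
                               p_threshold = config$network$p_threshold,
                               min_reads = config$network$min_reads)
    topo <- node_topology(net)
    if (!is.null(outdir)) {
      write_network(net, file.path(outdir, "network_edges.tsv"))
      write_tsv(topo, file.path(outdir, "node_topology.tsv"))
    }
    out$network <- net
    out$topology <- topo
    out
  })

  report$results <- list(community = comm, alpha = alpha, bray = bray,
                         ncm = ncm_fit, processes = processes, nst = nst_res,
                         signal = signal, drivers = drivers)
  if (!is.null(outdir)) {
    summary_json <- list(
      seed = seed,
      n_samples = nrow(comm), n_taxa = ncol(comm),
      ncm = list(m = ncm_fit$m, Nm = ncm_fit$Nm, r_squared = ncm_fit$r_squared),
      process_fractions = as.list(processes$fractions),
      nst = stats::setNames(as.list(nst_res$table$nst), nst_res$table$group),
      stages = report$stages)
    jsonlite::write_json(summary_json, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(report, class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  cat("assembly pipeline report (seed", x$seed, ")\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-10s %s (%.2fs)\n", nm, x$stages[[nm]]$status,
                x$stages[[nm]]$seconds))
  invisible(x)
}
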