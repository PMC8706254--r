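# End-to-end orchestration: align -> alpha -> beta -> null models ->
# partition -> NCM / SAD -> Mantel, from a single declarative config.

#' Default pipeline configuration
#'
#' Returns the full config list with every stage enabled and the
#' conventional parameter defaults (999 randomizations for the null
#' models, 1000 for NTI, 9999 Mantel permutations, thresholds 2 and 0.95).
#' Override entries as needed and pass the result to [run_pipeline()].
#'
#' @param out_dir Output directory.
#' @param seed Global seed; every stochastic stage derives its own
#'   substream from it by stage name.
#' @return A nested config list.
#' @export
default_config <- function(out_dir = tempfile("phyloassembly_run_"), seed = 1) {
  list(
    input = NULL,      # list(table =, tree =, metadata =) of file paths
    simulate = NULL,   # or a simulate block: list(regime =, n_taxa =, ...)
    stages = c("alpha", "beta", "nullmodels", "partition", "ncm", "sad",
               "mantel"),
    seed = seed,
    out_dir = out_dir,
    alpha = list(n_null = 1000, weighted = FALSE, rarefy = FALSE),
    beta = list(weighted_bmntd = TRUE, unifrac_normalized = TRUE),
    nullmodels = list(n_null = 999, weighted = TRUE),
    partition = list(group_by = "layer", scheme = "within_group"),
    ncm = list(group_by = "layer", ci = "wilson"),
    mantel = list(n_perm = 9999, method = "pearson",
                  variables = c("pH", "EC", "SOM", "TN", "AN", "NH4", "NO3",
                                "TP", "AP"),
                  geo_mode = "haversine_km")
  )
}

#' Run the community-assembly pipeline
#'
#' Executes the enabled stages in dependency order on either input files
#' (`config$input`) or a simulated scenario (`config$simulate`). All
#' stochastic stages draw their seeds deterministically from the global
#' seed, so identical configs produce byte-identical outputs. Any stage
#' error halts the run with the stage name; the report lists every written
#' file plus per-stage warnings (dropped taxa, undefined pairs, skipped
#' groups).
#'
#' @param config Config list (see [default_config()]) or path to a YAML
#'   file with the same structure.
#' @return A run report list: `manifest` (named vector of written files),
#'   `warnings`, `config_hash`, `seed`, `summary` (key per-stage numbers).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  config <- utils::modifyList(base, config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- character(0)
  warns <- character(0)
  summary <- list()
  note <- function(w) warns <<- c(warns, w)
  emit <- function(name, path) manifest[name] <<- path

  run_stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      note(paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (", length(manifest), " file(s) already written)", call. = FALSE)
    })
  }

  # ---- inputs ----
  dat <- run_stage("input", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      do.call(simulate_scenario, c(sim, list(seed = seed)))
    } else if (!is.null(config$input)) {
      tab <- read_count_table(config$input$table)
      tree <- if (!is.null(config$input$tree)) read_tree(config$input$tree)
      md <- if (!is.null(config$input$metadata)) read_metadata(config$input$metadata)
      align_inputs(tab, tree, md)
    } else stop("config needs either an input block or a simulate block")
  })
  counts <- dat$counts
  tree <- dat$tree
  md <- dat$metadata
  if (!is.null(dat$dropped_taxa) && dat$dropped_taxa > 0)
    note(paste0("align: dropped ", dat$dropped_taxa, " taxa absent from tree"))
  grouping_of <- function(col) {
    if (is.null(md) || is.null(col) || !col %in% colnames(md)) NULL
    else stats::setNames(as.character(md[[col]]), md$sample_id)
  }

  stages <- config$stages
  bnti <- rc <- NULL

  if ("alpha" %in% stages) run_stage("alpha", {
    a <- config$alpha
    tab <- alpha_diversity(counts, tree, n_null = a$n_null,
                           weighted = a$weighted, rarefy = a$rarefy,
                           seed = stage_seed(seed, "alpha"))
    f <- file.path(out_dir, "alpha.tsv")
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("alpha", f)
    summary$mean_shannon <- mean(tab$shannon)
    summary$mean_sr <- mean(tab$SR)
  })

  if ("beta" %in% stages) run_stage("beta", {
    b <- config$beta
    emit("bray_curtis",
         write_pairwise_matrix(bray_curtis(counts),
                               file.path(out_dir, "bray_curtis.tsv")))
    if (!is.null(tree)) {
      emit("wunifrac",
           write_pairwise_matrix(
             weighted_unifrac(counts, tree, normalized = b$unifrac_normalized),
             file.path(out_dir, "wunifrac.tsv")))
      emit("bmntd",
           write_pairwise_matrix(
             beta_mntd(counts, tree, weighted = b$weighted_bmntd),
             file.path(out_dir, "bmntd.tsv")))
    }
  })

  if ("nullmodels" %in% stages) run_stage("nullmodels", {
    nm <- config$nullmodels
    bnti <- beta_nti(counts, tree, n_null = nm$n_null,
                      weighted = nm$weighted,
                      seed = stage_seed(seed, "bnti"))
    rc <- raup_crick_bray(counts, n_null = nm$n_null,
                           seed = stage_seed(seed, "rcbray"))
    emit("bnti", write_pairwise_matrix(bnti, file.path(out_dir, "bnti.tsv")))
    emit("rcbray", write_pairwise_matrix(rc, file.path(out_dir, "rcbray.tsv")))
    prov <- list(n_null = nm$n_null, weighted = nm$weighted,
                 seed_bnti = stage_seed(seed, "bnti"),
                 seed_rcbray = stage_seed(seed, "rcbray"),
                 n_undefined = attr(bnti, "n_undefined"))
    f <- file.path(out_dir, "nullmodels_provenance.json")
    jsonlite::write_json(prov, f, auto_unbox = TRUE, digits = NA)
    emit("nullmodels_provenance", f)
  })

  if ("partition" %in% stages) run_stage("partition", {
    if (is.null(bnti)) stop("partition requires the nullmodels stage")
    pt <- config$partition
    part_all <- partition_fractions(bnti, rc, grouping = NULL)
    f1 <- file.path(out_dir, "partition_pairs.tsv")
    utils::write.table(part_all$pairs, f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("partition_pairs", f1)
    summaries <- part_all$summary
    grp <- grouping_of(pt$group_by)
    if (!is.null(grp)) {
      part_grp <- partition_fractions(bnti, rc, grouping = grp,
                                      scheme = pt$scheme)
      summaries <- rbind(summaries, part_grp$summary)
    }
    f2 <- file.path(out_dir, "partition_summary.tsv")
    utils::write.table(summaries, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("partition_summary", f2)
    summary$stochastic_pct <-
      part_all$summary$stochastic_pct[part_all$summary$group == "all"]
  })

  if ("ncm" %in% stages) run_stage("ncm", {
    fit <- fit_ncm(counts, ci = config$ncm$ci)
    f <- file.path(out_dir, "ncm_otus.tsv")
    utils::write.table(cbind(otu = rownames(fit$taxa), fit$taxa), f,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("ncm_otus", f)
    fits <- list(all = fit)
    grp <- grouping_of(config$ncm$group_by)
    if (!is.null(grp))
      fits <- c(fits, ncm_per_group(counts, grp, ci = config$ncm$ci))
    js <- lapply(fits, function(x)
      list(m = x$m, r2 = x$r2, N = x$N, d = x$d, n_samples = x$n_samples,
           partition = as.list(table(x$taxa$partition))))
    f2 <- file.path(out_dir, "ncm_fit.json")
    jsonlite::write_json(js, f2, auto_unbox = TRUE, digits = NA)
    emit("ncm_fit", f2)
    summary$ncm_m <- fit$m
    summary$ncm_r2 <- fit$r2
  })

  if ("sad" %in% stages) run_stage("sad", {
    sad <- fit_lognormal_sad(rowSums(counts))
    js <- list(
      lognormal = sad$lognormal[c("S0", "a", "mode_octave", "aic")],
      geometric = sad$geometric[c("A", "b", "aic")],
      octave_counts = as.list(sad$octave_counts))
    f <- file.path(out_dir, "sad_fit.json")
    jsonlite::write_json(js, f, auto_unbox = TRUE, digits = NA)
    emit("sad_fit", f)
    summary$sad_lognormal_aic <- sad$lognormal$aic
    summary$sad_geometric_aic <- sad$geometric$aic
  })

  if ("mantel" %in% stages && !is.null(md)) run_stage("mantel", {
    mt <- config$mantel
    vars <- intersect(mt$variables, colnames(md))
    if (length(vars) == 0) stop("no mantel variables present in metadata")
    denv <- env_distance(md, vars)
    dgeo <- geo_distance(md, mode = mt$geo_mode)
    dbc <- bray_curtis(counts)
    res <- list(
      bray_env = mantel_test(dbc, denv, method = mt$method,
                             n_perm = mt$n_perm,
                             seed = stage_seed(seed, "mantel1")),
      bray_geo = mantel_test(dbc, dgeo, method = mt$method,
                             n_perm = mt$n_perm,
                             seed = stage_seed(seed, "mantel2")))
    if (!is.null(bnti)) {
      zb <- bnti
      zb[is.na(zb)] <- 0
      diag(zb) <- 0
      res$bnti_env_partial_geo <- partial_mantel_test(
        zb, denv, dgeo, method = mt$method, n_perm = 999,
        seed = stage_seed(seed, "mantel3"))
      res$bnti_geo_partial_env <- partial_mantel_test(
        zb, dgeo, denv, method = mt$method, n_perm = 999,
        seed = stage_seed(seed, "mantel4"))
    }
    f <- file.path(out_dir, "mantel.json")
    jsonlite::write_json(res, f, auto_unbox = TRUE, digits = NA)
    emit("mantel", f)
    summary$mantel_bray_env_r <- res$bray_env$r
    summary$mantel_bray_geo_r <- res$bray_geo$r
  })

  report <- list(manifest = manifest, warnings = warns,
                 config_hash = config_hash(config), seed = seed,
                 summary = summary)
  f <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA)
  report$report_path <- f
  report
}

# Hash of the analysis-relevant config (the output location is excluded, so
# the same analysis written to two directories hashes identically).
config_hash <- function(config) {
  config$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[sort(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}
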