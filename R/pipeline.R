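.STAGE_ORDER <- c("simulate", "repeats", "annotate", "targets", "cohort",
                  "motility")

#' Validate a pipeline run configuration
#'
#' A run configuration is a list (or path to a JSON file) with a global
#' `seed`, an `outdir`, the `stages` to run, and optional per-stage parameter
#' blocks (`simulate`, `repeats`, `annotate`, `targets`, `cohort`,
#' `motility`). Validation happens before any stage executes; a stage whose
#' upstream inputs are neither produced by an earlier requested stage nor
#' supplied as explicit paths is a configuration error.
#'
#' @param config List or JSON file path.
#' @return The normalized configuration list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$outdir)) stop("config needs an 'outdir'")
  if (is.null(config$stages)) config$stages <- .STAGE_ORDER
  bad <- setdiff(config$stages, .STAGE_ORDER)
  if (length(bad)) stop("unknown stage: ", bad[1L])
  config$stages <- .STAGE_ORDER[.STAGE_ORDER %in% config$stages]
  sim_on <- "simulate" %in% config$stages
  need_sim <- c(repeats = "peaks/genome", annotate = "peaks/genes",
                targets = "de/bound genes", cohort = "expression matrices",
                motility = "detections")
  for (st in intersect(names(need_sim), config$stages)) {
    has_paths <- !is.null(config[[st]]) && !is.null(config[[st]]$inputs)
    if (!sim_on && !has_paths)
      stop(sprintf("stage '%s' needs %s: enable the simulate stage or supply %s$inputs",
                   st, need_sim[[st]], st))
  }
  config
}

.p <- function(cfg, stage, key, default) {
  v <- cfg[[stage]][[key]]
  if (is.null(v)) default else v
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate, repeats, annotate, targets, cohort, motility), writing each
#' stage's TSV outputs under `outdir` and a JSON manifest with per-file MD5
#' checksums, per-stage wall-clock, the seed, and a hash of the
#' configuration. Deterministic given the configuration: re-running with the
#' same config reproduces identical checksums.
#'
#' @param config List or JSON path, see [validate_run_config()].
#' @return The manifest, invisibly; also written to `outdir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_run_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- file.path(outdir, "config.json")
  jsonlite::write_json(cfg[setdiff(names(cfg), "outdir")], cfg_json,
                       auto_unbox = TRUE, pretty = TRUE)
  simcfg <- do.call(sim_config, c(list(seed = cfg$seed),
                                  cfg$simulate[names(cfg$simulate) %in%
                                                 names(formals(sim_config))]))
  manifest <- list(tool = "regulonforge",
                   version = as.character(utils::packageVersion("regulonforge")),
                   seed = cfg$seed,
                   config_hash = unname(tools::md5sum(cfg_json)),
                   stages = list())
  state <- list()
  for (st in cfg$stages) {
    t0 <- proc.time()[["elapsed"]]
    sd <- file.path(outdir, st)
    files <- character()
    tryCatch({
      if (st == "simulate") {
        state$gp <- simulate_genome_and_peaks(simcfg, dir = sd)
        state$gd <- simulate_gene_models_and_de(simcfg, dir = sd)
        state$co <- simulate_cohort(simcfg, dir = sd)
        state$sv <- simulate_survival(simcfg, dir = sd)
        state$tr <- simulate_tracks(simcfg, dir = sd)
        files <- list.files(sd, full.names = TRUE)
      } else if (st == "repeats") {
        dir.create(sd, showWarnings = FALSE)
        prof <- profile_peaks(state$gp$peaks, state$gp$genome,
                              width = .p(cfg, "repeats", "window", 500L),
                              separate = isTRUE(cfg$repeats$separate))
        f <- file.path(sd, "repeat_profile.tsv")
        write_table(as.data.frame(prof), f,
                    params = list(window = .p(cfg, "repeats", "window", 500L)))
        files <- f
      } else if (st == "annotate") {
        dir.create(sd, showWarnings = FALSE)
        peaks <- state$gp$peaks; genes <- state$gd$genes
        cls <- data.frame(name = peaks$name,
                          class = classify_peak(peaks, genes))
        flank <- .p(cfg, "annotate", "flank", 5000L)
        bg <- bound_genes(peaks, genes, flank)
        f1 <- file.path(sd, "peak_classes.tsv")
        f2 <- file.path(sd, "bound_genes.tsv")
        write_table(cls, f1, params = list(
          promoter = "-3000/+1000 around TSS",
          promoter_pct = promoter_fraction(peaks, genes)))
        write_table(data.frame(gene_id = bg), f2, params = list(flank = flank))
        files <- c(f1, f2)
        state$bound <- bg
      } else if (st == "targets") {
        dir.create(sd, showWarnings = FALSE)
        degs <- filter_degs(state$gd$de,
                            fc_threshold = .p(cfg, "targets", "fc", 1.5),
                            fdr_threshold = .p(cfg, "targets", "fdr", 0.05),
                            experiment_id = "synthetic")
        dts <- call_direct_targets(state$bound, degs)
        f1 <- file.path(sd, "deg_up.txt"); f2 <- file.path(sd, "deg_down.txt")
        f3 <- file.path(sd, "direct_targets.tsv")
        writeLines(sort(degs$up), f1); writeLines(sort(degs$down), f2)
        write_table(data.frame(
          set = c("bound", "positive", "negative"),
          count = c(dts$counts[["bound"]], dts$counts[["positive"]],
                    dts$counts[["negative"]]),
          genes = c("", paste(sort(dts$positive), collapse = ","),
                    paste(sort(dts$negative), collapse = ","))), f3,
          params = list(fc = degs$fc_threshold, fdr = degs$fdr_threshold))
        files <- c(f1, f2, f3)
      } else if (st == "cohort") {
        dir.create(sd, showWarnings = FALSE)
        rs <- range_screen(state$co$tumors, state$co$celllines,
                           p_cut = .p(cfg, "cohort", "p_cut", 0.01))
        cs <- correlation_screen(
          cbind(state$co$tumors),
          "REGULATOR",
          setdiff(rownames(state$co$tumors), "REGULATOR"),
          q_cut = .p(cfg, "cohort", "q_cut", 0.01))
        km <- km_logrank(state$sv, split = "median")
        f1 <- file.path(sd, "range_screen.tsv")
        f2 <- file.path(sd, "correlation_screen.tsv")
        f3 <- file.path(sd, "survival_logrank.tsv")
        write_table(rs$table, f1, params = list(pass = length(rs$pass)))
        write_table(cs, f2)
        write_table(data.frame(chi2 = km$chi2, p = km$p, cutoff = km$cutoff,
                               n_high = km$n_high, n_low = km$n_low), f3)
        files <- c(f1, f2, f3)
      } else if (st == "motility") {
        dir.create(sd, showWarnings = FALSE)
        tracks <- split_tracks(state$tr$detections)
        kept <- filter_tracks(tracks,
                              min_mean_quality = .p(cfg, "motility", "min_quality", 100),
                              min_occurrences = .p(cfg, "motility", "min_occ", 10L),
                              roi = .p(cfg, "motility", "roi", c(0, 0, 800, 800)))
        mt <- track_metrics_table(kept)
        f <- file.path(sd, "track_metrics.tsv")
        write_table(mt, f, params = list(n_input = length(tracks),
                                         n_kept = length(kept)))
        files <- f
      }
    }, error = function(e)
      stop(sprintf("stage '%s' failed: %s", st, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[st]] <- list(
      outputs = as.list(tools::md5sum(sort(files))),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
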