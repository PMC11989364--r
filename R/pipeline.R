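#' @title One-command orchestration of the full analysis
#' @description
#' `run_pipeline()` chains curation, the essential-site scan, the residue
#' interaction network, SASA, pocket detection or Fpocket ingestion, and the
#' consensus stage, writing all report artifacts to an output directory. The
#' analysis itself is deterministic; `seed` is threaded only to stochastic
#' extras. A machine-readable manifest (configuration echo, input checksum,
#' per-stage wall times, warnings) is written on every run, success or
#' failure.
#' @name pipeline_cli
NULL

#' Pipeline configuration
#'
#' Defaults mirror the published analysis protocol: ten slowest modes, the
#' top-25% essentiality quartile, the top-5% betweenness quantile and the
#' 4.5-Angstrom heavy-atom contact cutoff (the 10-Angstrom elastic-network
#' cutoff is the scalar network model's conventional default).
#'
#' @param input path to a PDB file.
#' @param output_dir output directory (created if absent).
#' @param keep_chains chain ids to keep, or `NULL` for all.
#' @param drop_waters,drop_hetero curation flags (default both `TRUE`).
#' @param enm_cutoff elastic-network cutoff, Angstrom (default 10).
#' @param n_modes slow modes averaged in the scan (default 10).
#' @param essa_quantile essentiality quantile (default 0.75).
#' @param contact_cutoff contact cutoff, Angstrom (default 4.5).
#' @param rin_quantile hub quantile (default 0.95).
#' @param pocket_source `"builtin"` or `"fpocket:<dir>"`.
#' @param pocket_rank_key `"median"` or `"max"`.
#' @param sasa_min consensus accessibility threshold, Angstrom^2 (default 5).
#' @param seed integer seed for stochastic extras (default 1).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, output_dir, keep_chains = NULL,
                            drop_waters = TRUE, drop_hetero = TRUE,
                            enm_cutoff = 10, n_modes = 10L,
                            essa_quantile = 0.75, contact_cutoff = 4.5,
                            rin_quantile = 0.95, pocket_source = "builtin",
                            pocket_rank_key = "median", sasa_min = 5,
                            seed = 1L) {
  stopifnot(enm_cutoff > 0, contact_cutoff > 0,
            essa_quantile > 0, essa_quantile < 1,
            rin_quantile > 0, rin_quantile < 1, n_modes >= 1)
  if (!(identical(pocket_source, "builtin") ||
        startsWith(pocket_source, "fpocket:"))) {
    stop("pocket_source must be 'builtin' or 'fpocket:<dir>'", call. = FALSE)
  }
  structure(list(input = input, output_dir = output_dir,
                 keep_chains = keep_chains, drop_waters = drop_waters,
                 drop_hetero = drop_hetero, enm_cutoff = enm_cutoff,
                 n_modes = as.integer(n_modes), essa_quantile = essa_quantile,
                 contact_cutoff = contact_cutoff, rin_quantile = rin_quantile,
                 pocket_source = pocket_source,
                 pocket_rank_key = match.arg(pocket_rank_key, c("median", "max")),
                 sasa_min = sasa_min, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full allosteric-site pipeline
#'
#' Writes `essa.tsv`, `rin_nodes.tsv`, `rin_edges.tsv`, `pockets.tsv`,
#' `consensus.json` and `manifest.json` into the configured output
#' directory. Stage errors are recorded in the manifest (with the failed
#' stage named) and then re-raised.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the output directory path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "allopocket",
    version = as.character(utils::packageVersion("allopocket")),
    config = config[setdiff(names(config), character(0))],
    input_md5 = NA_character_,
    stages = list(), warnings = list(), status = "running")
  class(manifest$config) <- NULL
  warns <- character(0)
  stage_times <- list()
  failed_stage <- NULL
  write_manifest <- function() {
    manifest$warnings <- as.list(warns)
    manifest$stages <- stage_times
    jsonlite::write_json(sort_keys(manifest), file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
  }
  run_stage <- function(name, expr) {
    failed_stage <<- name
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    stage_times[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    failed_stage <<- NULL
    res
  }
  result <- tryCatch({
    model <- run_stage("load", {
      m <- load_structure(config$input)
      manifest$input_md5 <- unname(tools::md5sum(config$input))
      m
    })
    model <- run_stage("curate", curate(model, keep_chains = config$keep_chains,
                                        drop_waters = config$drop_waters,
                                        drop_hetero = config$drop_hetero))
    profile <- run_stage("essa", essa_scan(model, cutoff = config$enm_cutoff,
                                           n_modes = config$n_modes,
                                           quantile = config$essa_quantile))
    rin <- run_stage("rin", build_rin(model, contact_cutoff = config$contact_cutoff,
                                      quantile = config$rin_quantile))
    sasa <- run_stage("sasa", compute_sasa(model))
    pockets <- run_stage("pockets", {
      if (identical(config$pocket_source, "builtin")) {
        detect_pockets_grid(model)
      } else {
        parse_fpocket_output(sub("^fpocket:", "", config$pocket_source), model)
      }
    })
    consensus <- run_stage("consensus", {
      scored <- score_pockets(pockets, profile, sasa = sasa,
                              rank_key = config$pocket_rank_key)
      find_consensus_sites(scored,
                           essential = select_essential(profile, config$essa_quantile),
                           hubs = select_hubs(rin, config$rin_quantile),
                           sasa = sasa, sasa_min = config$sasa_min)
    })
    run_stage("write", {
      write_essa_tsv(profile, file.path(config$output_dir, "essa.tsv"))
      write_rin_tsv(rin, file.path(config$output_dir, "rin_nodes.tsv"),
                    file.path(config$output_dir, "rin_edges.tsv"))
      write_consensus(consensus, file.path(config$output_dir, "pockets.tsv"),
                      file.path(config$output_dir, "consensus.json"))
    })
    manifest$status <- "ok"
    write_manifest()
    list(model = model, profile = profile, rin = rin, sasa = sasa,
         consensus = consensus)
  }, error = function(e) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- if (is.null(failed_stage)) "unknown" else failed_stage
    manifest$error <<- conditionMessage(e)
    write_manifest()
    stop(e)
  })
  invisible(structure(list(output_dir = config$output_dir, result = result),
                      class = "allo_run"))
}
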