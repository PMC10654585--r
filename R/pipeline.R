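#' Configuration for an end-to-end pipeline run
#'
#' All referenced input paths must exist at run start. Optional stages
#' (distances, delimitation, reconciliation) run only when their inputs
#' are given.
#'
#' @param occurrence,roster,evidence paths to the occurrence table, host
#'   roster and classification evidence (required).
#' @param out_dir output directory (created if absent).
#' @param fasta optional aligned FASTA for the distance stage.
#' @param tanglegrams optional list of lists with elements `host`,
#'   `symbiont`, `phi` (file paths) for the reconciliation stage.
#' @param gene_flow_threshold K2P proportion for gene-flow calls.
#' @param costs an `event_costs`.
#' @param delimit_grid threshold grid for OTU delimitation.
#' @param digits decimals for displayed shares.
#' @param seed integer seed recorded in the manifest (the pipeline's
#'   stages are deterministic; the seed matters only when simulated
#'   inputs are produced in the same session).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(occurrence, roster, evidence, out_dir,
                            fasta = NULL, tanglegrams = NULL,
                            gene_flow_threshold = 0.05,
                            costs = event_costs(),
                            delimit_grid = seq(0.005, 0.15, by = 0.005),
                            digits = 1, seed = 1) {
  paths <- c(occurrence, roster, evidence, fasta,
             unlist(tanglegrams, use.names = FALSE))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop_hostspec(paste0("input path(s) not found: ",
                         paste(missing, collapse = ", ")),
                  "hostspec_config_error")
  structure(list(occurrence = occurrence, roster = roster,
                 evidence = evidence, out_dir = out_dir, fasta = fasta,
                 tanglegrams = tanglegrams,
                 gene_flow_threshold = gene_flow_threshold,
                 costs = costs, delimit_grid = delimit_grid,
                 digits = digits, seed = seed),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_hostspec(paste0("stage '", name, "' failed: ",
                         conditionMessage(e)),
                  "hostspec_stage_error"))
}

#' Run the full analysis pipeline
#'
#' Reads and validates the occurrence data, classifies taxa, writes the
#' prevalence and co-occurrence tables, estimates the transmission-rate
#' ratio with its QSM-assignment bounds, and (when inputs are supplied)
#' computes the K2P distance matrix with gene-flow calls and OTU
#' delimitation and the pooled reconciliation census. All outputs are
#' plain TSV/JSON written deterministically, plus a run manifest
#' recording the package version, seed, thresholds and event costs, so a
#' re-run with the same config is byte-identical.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  ds <- stage("read_occurrence",
              read_occurrence_table(config$occurrence, config$roster))
  ev <- stage("classification", read_evidence_table(config$evidence))
  ds <- stage("classification",
              assign_categories(ds, ev, config$gene_flow_threshold))
  stage("classification", {
    cls <- data.frame(taxon = ds$taxa$name, category = ds$taxa$category)
    cls <- cls[order(cls$taxon), ]
    utils::write.table(cls, out("classification.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  prev <- stage("tables", prevalence_table(ds))
  stage("tables", {
    utils::write.table(prev$taxa, out("prevalence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(prev$subtotals, out("prevalence_subtotals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  cooc <- stage("tables", cooccurrence_table(ds))
  stage("tables", {
    df <- data.frame(combination = COMBO_KEYS, hosts = cooc$host_counts,
                     cooc$record_counts)
    utils::write.table(df, out("cooccurrence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  est <- stage("rates", estimate_transmission(cooc, config$digits))
  stage("rates", jsonlite::write_json(
    list(counts = as.list(est$counts), n_records = est$n_records,
         share_specific_pct = est$share_specific_pct,
         share_alien_pct = est$share_alien_pct,
         share_qsm_pct = est$share_qsm_pct,
         ratio_point = est$ratio_point,
         ratio_lower = est$ratio_lower, ratio_upper = est$ratio_upper),
    out("transmission.json"), auto_unbox = TRUE, digits = NA))

  dmat <- NULL; part <- NULL
  if (!is.null(config$fasta)) {
    seqs <- stage("distances", read_fasta(config$fasta))
    dmat <- stage("distances", k2p_matrix(seqs))
    stage("distances", write_distance_matrix(dmat, out("distance_matrix.tsv")))
    part <- stage("delimit", delimit_otus(dmat, config$delimit_grid))
    stage("delimit", {
      df <- data.frame(
        label = unlist(part$clusters),
        cluster = rep(seq_along(part$clusters),
                      vapply(part$clusters, length, integer(1))))
      df <- df[order(df$label), ]
      utils::write.table(df, out("partition.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
  }

  census <- NULL
  if (!is.null(config$tanglegrams)) {
    recs <- stage("reconcile", lapply(config$tanglegrams, function(tg)
      reconcile(read_tanglegram(tg$host, tg$symbiont, tg$phi),
                config$costs)))
    census <- Reduce(`+`, lapply(recs, count_events))
    stage("reconcile", {
      ev_df <- do.call(rbind, lapply(seq_along(recs), function(i)
        cbind(lineage = i, recs[[i]]$events)))
      utils::write.table(ev_df, out("events.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(as.list(census), out("census.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }

  stage("manifest", jsonlite::write_json(
    list(package = "hostspec",
         version = as.character(utils::packageVersion("hostspec")),
         seed = config$seed,
         gene_flow_threshold = config$gene_flow_threshold,
         event_costs = as.list(unclass(config$costs)),
         delimit_grid = config$delimit_grid,
         digits = config$digits),
    out("manifest.json"), auto_unbox = TRUE, digits = NA))

  invisible(list(dataset = ds, prevalence = prev, cooccurrence = cooc,
                 estimate = est, distances = dmat, partition = part,
                 census = census))
}
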