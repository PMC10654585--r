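#' Classify a symbiont taxon into a host-specificity category
#'
#' Applies three criteria in fixed priority:
#' \enumerate{
#'   \item ecological rule: quill- and skin-dwelling taxa are always
#'     `"qsm"`, whatever their host range, because their contact
#'     transmission (and possible phoresy) is not comparable with that of
#'     vane-dwelling plumage mites;
#'   \item exclusivity rule: a vane taxon found only on the focal host is
#'     `"specific"`, provided any known sister taxon lives on a congeneric
#'     brood parasite (or is unknown) and any genetic distance to the
#'     nearest foster-parent mite exceeds the gene-flow threshold;
#'   \item proximity rule: everything else -- found on foster parents, or
#'     genetically continuous with a foster-parent mite -- is `"alien"`.
#' }
#' Molecular evidence is optional: occurrence exclusivity alone suffices
#' for `"specific"` when no sequence data exist.
#'
#' @param evidence a one-row data.frame or list with fields `taxon`,
#'   `found_on_focal_host`, `found_on_foster_hosts`, `ecological_group`,
#'   `sister_taxon_host` (binomial or `"unknown"`/`NA`), and
#'   `distance_to_nearest_foster_mite` (K2P proportion or `NA`).
#' @param gene_flow_threshold K2P proportion at or below which two
#'   populations are treated as exchanging genes (default 0.05).
#' @param focal_genus genus of the focal host; a sister taxon hosted by a
#'   congener of this genus is consistent with the `"specific"` category.
#' @return one of `"specific"`, `"alien"`, `"qsm"`.
#' @export
classify_taxon <- function(evidence, gene_flow_threshold = 0.05,
                           focal_genus = "Molothrus") {
  ev <- as.list(evidence)
  if (!(gene_flow_threshold > 0 && gene_flow_threshold < 1))
    stop_hostspec("gene_flow_threshold must be in (0, 1)",
                  "hostspec_validation_error")
  on_focal <- isTRUE(as.logical(ev$found_on_focal_host))
  on_foster <- isTRUE(as.logical(ev$found_on_foster_hosts))
  if (!on_focal && !on_foster)
    stop_hostspec(paste0("taxon ", ev$taxon %||% "?",
                         " found on no host at all"),
                  "hostspec_evidence_error")
  d <- ev$distance_to_nearest_foster_mite
  d <- if (is.null(d) || length(d) == 0) NA_real_ else suppressWarnings(as.numeric(d))
  if (!is.na(d) && d < 0)
    stop_hostspec("distance must be >= 0", "hostspec_evidence_error")

  if (identical(ev$ecological_group, "quill_skin")) return("qsm")

  sister <- ev$sister_taxon_host
  sister <- if (is.null(sister) || length(sister) == 0) NA_character_
            else as.character(sister)
  sister_ok <- is.na(sister) || sister %in% c("", "unknown", "Unknown") ||
    identical(strsplit(sister, "\\s+")[[1]][1], focal_genus)

  if (on_focal && !on_foster && sister_ok && (is.na(d) || d > gene_flow_threshold))
    return("specific")
  "alien"
}

#' Assign host-specificity categories across a dataset
#'
#' Classifies every registered taxon from an evidence table and writes the
#' categories back into the dataset. Classification is a pure function of
#' the evidence, so dataset row order never matters.
#'
#' @param dataset an `occurrence_dataset`.
#' @param evidence data.frame with one row per taxon (columns as in
#'   [classify_taxon()], including `taxon`).
#' @param gene_flow_threshold passed to [classify_taxon()].
#' @param focal_genus passed to [classify_taxon()].
#' @return the dataset with `taxa$category` filled in.
#' @export
assign_categories <- function(dataset, evidence, gene_flow_threshold = 0.05,
                              focal_genus = "Molothrus") {
  evidence <- as.data.frame(evidence, stringsAsFactors = FALSE)
  missing <- setdiff(dataset$taxa$name, evidence$taxon)
  if (length(missing))
    stop_hostspec(paste0("no classification evidence for: ",
                         paste(missing, collapse = ", ")),
                  "hostspec_coverage_error")
  m <- match(dataset$taxa$name, evidence$taxon)
  dataset$taxa$category <- vapply(m, function(i)
    classify_taxon(evidence[i, , drop = FALSE], gene_flow_threshold,
                   focal_genus),
    character(1))
  validate_occurrence_dataset(dataset)
  dataset
}

#' Read a classification-evidence table
#'
#' TSV/CSV with columns `taxon`, `found_on_focal_host`,
#' `found_on_foster_hosts`, `ecological_group`, `sister_taxon_host`,
#' `distance_to_nearest_foster_mite` (empty/NA when no sequence exists).
#'
#' @param path evidence file.
#' @return data.frame.
#' @export
read_evidence_table <- function(path) {
  ev <- read_delim_sniff(path)
  need <- c("taxon", "found_on_focal_host", "found_on_foster_hosts",
            "ecological_group")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop_hostspec(paste0("evidence table missing column(s): ",
                         paste(miss, collapse = ", ")),
                  "hostspec_schema_error")
  if (is.null(ev$sister_taxon_host)) ev$sister_taxon_host <- NA_character_
  if (is.null(ev$distance_to_nearest_foster_mite))
    ev$distance_to_nearest_foster_mite <- NA_real_
  ev
}
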