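#' Occurrence datasets: host roster, taxon register, and records
#'
#' An `occurrence_dataset` bundles three tables:
#' \describe{
#'   \item{hosts}{one row per examined host individual (`id`, `species`,
#'     `source`, `locality`), including individuals that carried no
#'     symbionts at all -- prevalence denominators need them;}
#'   \item{taxa}{one row per symbiont taxon (`name`, `genus`, `family`,
#'     `ecological_group` in \{"vane", "quill_skin"\}, `category` in
#'     \{"specific", "alien", "qsm", "unassigned"\});}
#'   \item{records}{one row per unique (host individual, taxon) pair with
#'     an `abundance` count of specimens (>= 1).}
#' }
#' A "record" is a presence/absence unit: a host individual either carries
#' a taxon (one record, whatever the specimen count) or it does not.
#' Specimen counts are kept separately as `abundance`.
#'
#' @param hosts data.frame with columns `id`, `species` and optionally
#'   `source`, `locality`.
#' @param taxa data.frame with columns `name`, `genus`, `family`,
#'   `ecological_group` and optionally `category`.
#' @param records data.frame with columns `host_id`, `taxon`, `abundance`.
#' @return an object of class `occurrence_dataset`.
#' @export
occurrence_dataset <- function(hosts, taxa, records) {
  hosts <- as.data.frame(hosts, stringsAsFactors = FALSE)
  taxa <- as.data.frame(taxa, stringsAsFactors = FALSE)
  records <- as.data.frame(records, stringsAsFactors = FALSE)

  if (!all(c("id", "species") %in% names(hosts)))
    stop_hostspec("host roster needs columns 'id' and 'species'",
                  "hostspec_schema_error")
  if (is.null(hosts$source)) hosts$source <- "wild_capture"
  if (is.null(hosts$locality)) hosts$locality <- NA_character_

  if (!all(c("name", "genus", "family", "ecological_group") %in% names(taxa)))
    stop_hostspec(
      "taxon table needs columns 'name', 'genus', 'family', 'ecological_group'",
      "hostspec_schema_error")
  if (is.null(taxa$category)) taxa$category <- "unassigned"

  if (nrow(records) > 0 &&
      !all(c("host_id", "taxon", "abundance") %in% names(records)))
    stop_hostspec("records need columns 'host_id', 'taxon', 'abundance'",
                  "hostspec_schema_error")
  if (nrow(records) == 0)
    records <- data.frame(host_id = character(), taxon = character(),
                          abundance = integer(), stringsAsFactors = FALSE)

  ds <- structure(
    list(hosts = hosts, taxa = taxa,
         records = records[, c("host_id", "taxon", "abundance")]),
    class = "occurrence_dataset")
  validate_occurrence_dataset(ds)
  ds
}

#' Validate an occurrence dataset's invariants
#'
#' Checks uniqueness of host ids, taxon names, and (host, taxon) record
#' pairs; referential integrity of records against roster and register;
#' positive integer abundances; legal enum values; and the rule that
#' quill-and-skin taxa may only be `qsm` or `unassigned` (their contact
#' transmission is not comparable with vane mites, so they are never
#' counted as "specific" or "alien").
#'
#' @param ds an `occurrence_dataset`.
#' @return `ds`, invisibly, if valid; otherwise a classed error.
#' @export
validate_occurrence_dataset <- function(ds) {
  hosts <- ds$hosts; taxa <- ds$taxa; records <- ds$records

  if (anyDuplicated(hosts$id))
    stop_hostspec("duplicate host ids in roster", "hostspec_validation_error")
  if (any(!nzchar(hosts$species)) || anyNA(hosts$species))
    stop_hostspec("empty host species name", "hostspec_validation_error")
  bad_src <- setdiff(unique(hosts$source),
                     c("wild_capture", "roadkill", "museum_skin"))
  if (length(bad_src))
    stop_hostspec(paste0("unknown sample source: ",
                         paste(bad_src, collapse = ", ")),
                  "hostspec_validation_error")

  if (anyDuplicated(taxa$name))
    stop_hostspec("duplicate taxon names", "hostspec_validation_error")
  bad_eco <- setdiff(unique(taxa$ecological_group), c("vane", "quill_skin"))
  if (length(bad_eco))
    stop_hostspec(paste0("unknown ecological group: ",
                         paste(bad_eco, collapse = ", ")),
                  "hostspec_validation_error")
  bad_cat <- setdiff(unique(taxa$category),
                     c("specific", "alien", "qsm", "unassigned"))
  if (length(bad_cat))
    stop_hostspec(paste0("unknown category: ", paste(bad_cat, collapse = ", ")),
                  "hostspec_validation_error")
  qs <- taxa$ecological_group == "quill_skin" &
    !(taxa$category %in% c("qsm", "unassigned"))
  if (any(qs))
    stop_hostspec(paste0("quill/skin taxa must be 'qsm' or 'unassigned': ",
                         paste(taxa$name[qs], collapse = ", ")),
                  "hostspec_validation_error")

  if (nrow(records)) {
    if (anyNA(records$abundance) || any(records$abundance < 1) ||
        any(records$abundance != as.integer(records$abundance)))
      stop_hostspec("abundance must be an integer >= 1",
                    "hostspec_validation_error")
    dup <- duplicated(records[, c("host_id", "taxon")])
    if (any(dup))
      stop_hostspec(
        paste0("duplicate (host, taxon) record(s): ",
               paste(utils::head(paste(records$host_id[dup],
                                       records$taxon[dup]), 5),
                     collapse = "; ")),
        "hostspec_referential_error")
    orphan_h <- setdiff(records$host_id, hosts$id)
    if (length(orphan_h))
      stop_hostspec(paste0("record host(s) absent from roster: ",
                           paste(utils::head(orphan_h, 5), collapse = ", ")),
                    "hostspec_referential_error")
    orphan_t <- setdiff(records$taxon, taxa$name)
    if (length(orphan_t))
      stop_hostspec(paste0("record taxon/taxa absent from register: ",
                           paste(utils::head(orphan_t, 5), collapse = ", ")),
                    "hostspec_referential_error")
  }
  invisible(ds)
}

#' Read an occurrence table plus host roster
#'
#' The occurrence file is TSV/CSV (delimiter sniffed from the header line)
#' with columns `host_id`, `host_species`, `source`, `taxon`, `genus`,
#' `family`, `ecological_group`, `abundance` and optionally `category`.
#' The roster file lists every examined host (`id`, `species`, and
#' optionally `source`, `locality`) so that symbiont-free hosts are
#' representable. Duplicate (host, taxon) rows are an error, never merged.
#'
#' @param path occurrence table file.
#' @param host_roster roster file.
#' @return an `occurrence_dataset`.
#' @export
read_occurrence_table <- function(path, host_roster) {
  occ <- read_delim_sniff(path)
  roster <- read_delim_sniff(host_roster)

  need <- c("host_id", "host_species", "source", "taxon", "genus", "family",
            "ecological_group", "abundance")
  miss <- setdiff(need, names(occ))
  if (nrow(occ) > 0 && length(miss))
    stop_hostspec(paste0("occurrence table missing column(s): ",
                         paste(miss, collapse = ", ")),
                  "hostspec_schema_error")
  if (!all(c("id", "species") %in% names(roster)))
    stop_hostspec("roster missing column 'id' or 'species'",
                  "hostspec_schema_error")

  hosts <- data.frame(id = as.character(roster$id),
                      species = as.character(roster$species),
                      source = if (is.null(roster$source)) "wild_capture"
                               else as.character(roster$source),
                      locality = if (is.null(roster$locality)) NA_character_
                                 else as.character(roster$locality),
                      stringsAsFactors = FALSE)

  if (nrow(occ) == 0) {
    taxa <- data.frame(name = character(), genus = character(),
                       family = character(), ecological_group = character(),
                       category = character(), stringsAsFactors = FALSE)
    return(occurrence_dataset(hosts, taxa, data.frame()))
  }

  ## cross-check host species/source between the two files where both give them
  m <- match(occ$host_id, hosts$id)
  if (anyNA(m))
    stop_hostspec(paste0("record host(s) absent from roster: ",
                         paste(unique(occ$host_id[is.na(m)]), collapse = ", ")),
                  "hostspec_referential_error")

  first <- !duplicated(occ$taxon)
  taxa <- data.frame(name = as.character(occ$taxon[first]),
                     genus = as.character(occ$genus[first]),
                     family = as.character(occ$family[first]),
                     ecological_group = as.character(occ$ecological_group[first]),
                     category = if ("category" %in% names(occ))
                       as.character(occ$category[first]) else "unassigned",
                     stringsAsFactors = FALSE)
  records <- data.frame(host_id = as.character(occ$host_id),
                        taxon = as.character(occ$taxon),
                        abundance = suppressWarnings(as.integer(occ$abundance)),
                        stringsAsFactors = FALSE)
  if (anyNA(records$abundance) || any(records$abundance < 1))
    stop_hostspec("abundance must be an integer >= 1",
                  "hostspec_validation_error")
  occurrence_dataset(hosts, taxa, records)
}

read_delim_sniff <- function(path) {
  if (!file.exists(path))
    stop_hostspec(paste0("file not found: ", path), "hostspec_io_error")
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = TRUE)
}

#' Write an occurrence dataset back to TSV
#'
#' Emits the occurrence table (sorted by host id then taxon) and the
#' roster (sorted by id), so repeated writes of the same dataset are
#' byte-identical.
#'
#' @param ds an `occurrence_dataset`.
#' @param path occurrence table output file.
#' @param roster_path roster output file (optional; skipped when `NULL`).
#' @return `ds`, invisibly.
#' @export
write_occurrence_table <- function(ds, path, roster_path = NULL) {
  validate_occurrence_dataset(ds)
  r <- ds$records
  i <- order(r$host_id, r$taxon)
  r <- r[i, , drop = FALSE]
  hm <- match(r$host_id, ds$hosts$id)
  tm <- match(r$taxon, ds$taxa$name)
  out <- data.frame(host_id = r$host_id,
                    host_species = ds$hosts$species[hm],
                    source = ds$hosts$source[hm],
                    taxon = r$taxon,
                    genus = ds$taxa$genus[tm],
                    family = ds$taxa$family[tm],
                    ecological_group = ds$taxa$ecological_group[tm],
                    category = ds$taxa$category[tm],
                    abundance = r$abundance,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(roster_path)) {
    h <- ds$hosts[order(ds$hosts$id), , drop = FALSE]
    utils::write.table(h, roster_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(ds)
}

#' @export
print.occurrence_dataset <- function(x, ...) {
  n_with <- length(unique(x$records$host_id))
  cat("Occurrence dataset\n")
  cat(sprintf("  hosts examined : %d (%d with records, %d without)\n",
              nrow(x$hosts), n_with, nrow(x$hosts) - n_with))
  cat(sprintf("  taxa           : %d\n", nrow(x$taxa)))
  cat(sprintf("  records (p/a)  : %d\n", nrow(x$records)))
  cat(sprintf("  total abundance: %d\n", sum(x$records$abundance)))
  tab <- table(factor(x$taxa$category,
                      c("specific", "alien", "qsm", "unassigned")))
  cat("  taxon categories:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
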