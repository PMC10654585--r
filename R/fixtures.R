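## Published marginal counts for the shiny-cowbird feather-mite survey:
## 144 examined hosts, 365 presence/absence records, 1246 specimens,
## 29 taxa in three host-specificity categories.

molothrus_taxa <- function() {
  tab <- rbind(
    ## name, genus, family, group, category, records, abundance
    c("Amerodectes molothrus", "Amerodectes", "Proctophyllodidae", "vane", "specific", 87, 355),
    c("Mesalgoides sp. 1", "Mesalgoides", "Psoroptoididae", "vane", "specific", 44, 122),
    c("Proctophyllodes molothrus", "Proctophyllodes", "Proctophyllodidae", "vane", "specific", 86, 344),
    c("Trouessartia sp. 6", "Trouessartia", "Trouessartiidae", "vane", "specific", 19, 49),
    c("Xolalgoides sp. 1", "Xolalgoides", "Xolalgidae", "vane", "specific", 37, 115),
    c("Amerodectes bilineatus", "Amerodectes", "Proctophyllodidae", "vane", "alien", 1, 5),
    c("Analges sp. 1", "Analges", "Analgidae", "vane", "alien", 2, 33),
    c("Analges sp. 5", "Analges", "Analgidae", "vane", "alien", 1, 7),
    c("Analges sp. 6", "Analges", "Analgidae", "vane", "alien", 2, 11),
    c("Analges ticotico", "Analges", "Analgidae", "vane", "alien", 1, 6),
    c("Mesalgoides sp. 2", "Mesalgoides", "Psoroptoididae", "vane", "alien", 11, 14),
    c("Mesalgoides sp. 3", "Mesalgoides", "Psoroptoididae", "vane", "alien", 4, 7),
    c("Platyacarus sp.", "Platyacarus", "Kramerellidae", "vane", "alien", 2, 12),
    c("Proctophyllodes aff. atyeoi", "Proctophyllodes", "Proctophyllodidae", "vane", "alien", 4, 16),
    c("Proctophyllodes cf. thraupis", "Proctophyllodes", "Proctophyllodidae", "vane", "alien", 4, 12),
    c("Proctophyllodes sp. 16", "Proctophyllodes", "Proctophyllodidae", "vane", "alien", 2, 7),
    c("Proctophyllodes sp. 4", "Proctophyllodes", "Proctophyllodidae", "vane", "alien", 4, 8),
    c("Proctophyllodes sp. 5", "Proctophyllodes", "Proctophyllodidae", "vane", "alien", 6, 13),
    c("Proctophyllodes carmenmirandae", "Proctophyllodes", "Proctophyllodidae", "vane", "alien", 5, 9),
    c("Trouessartia aff. megaplax", "Trouessartia", "Trouessartiidae", "vane", "alien", 2, 13),
    c("Trouessartia capensis", "Trouessartia", "Trouessartiidae", "vane", "alien", 10, 18),
    c("Trouessartia sp. 7", "Trouessartia", "Trouessartiidae", "vane", "alien", 3, 10),
    c("Trouessartia cf. sicaliae", "Trouessartia", "Trouessartiidae", "vane", "alien", 1, 2),
    c("Xolalgoides sp. 2", "Xolalgoides", "Xolalgidae", "vane", "alien", 4, 11),
    c("Dermationidae gen. sp.", "Dermationidae gen.", "Dermationidae", "quill_skin", "qsm", 6, 10),
    c("Dermoglyphus cf. passerinus", "Dermoglyphus", "Dermoglyphidae", "quill_skin", "qsm", 8, 16),
    c("Microlichus cf. americanus", "Microlichus", "Epidermoptidae", "quill_skin", "qsm", 4, 4),
    c("Metamicrolichus cf. phasianus", "Metamicrolichus", "Epidermoptidae", "quill_skin", "qsm", 2, 7),
    c("Strelkoviacarus brasiliensis", "Strelkoviacarus", "Analgidae", "quill_skin", "qsm", 3, 10))
  df <- data.frame(name = tab[, 1], genus = tab[, 2], family = tab[, 3],
                   ecological_group = tab[, 4], category = tab[, 5],
                   n_records = as.integer(tab[, 6]),
                   abundance = as.integer(tab[, 7]),
                   stringsAsFactors = FALSE)
  stopifnot(sum(df$n_records) == 365, sum(df$abundance) == 1246)
  df
}

## Host-individual co-occurrence block structure: hosts per exclusive
## category combination and records per combination split by category.
molothrus_blocks <- function() {
  data.frame(
    combo = c("S", "A", "Q", "S+A", "S+Q", "A+Q", "S+A+Q", "none"),
    hosts = c(73, 7, 1, 36, 14, 1, 7, 5),
    specific = c(147, 0, 0, 73, 36, 0, 17, 0),
    alien = c(0, 9, 0, 48, 0, 1, 11, 0),
    qsm = c(0, 0, 1, 0, 14, 1, 7, 0),
    stringsAsFactors = FALSE)
}

## Allocate a category's per-taxon record counts over the host blocks
## that contain the category: row sums = per-taxon counts, column sums =
## per-block record counts, every cell <= number of hosts in the block.
## Deterministic proportional allocation with a largest-remainder style
## repair pass.
allocate_counts <- function(taxon_counts, block_hosts, block_records) {
  stopifnot(sum(taxon_counts) == sum(block_records))
  nt <- length(taxon_counts); ng <- length(block_records)
  alloc <- matrix(0L, nt, ng)
  rem <- block_records
  ord <- order(-taxon_counts)
  for (t in ord) {
    c_t <- taxon_counts[t]
    if (c_t == 0) next
    cap <- pmin(block_hosts, rem)
    if (sum(cap) < c_t) stop("infeasible allocation")
    ideal <- if (sum(rem) > 0) c_t * rem / sum(rem) else rep(0, ng)
    a <- pmin(floor(ideal), cap)
    short <- c_t - sum(a)
    frac <- ideal - floor(ideal)
    while (short > 0) {
      slack <- cap - a
      cand <- which(slack > 0)
      if (!length(cand)) stop("infeasible allocation")
      pick <- cand[order(-frac[cand], cand)][1]
      a[pick] <- a[pick] + 1L
      frac[pick] <- -1         # each block gets at most one remainder bump
      short <- short - 1L
    }
    alloc[t, ] <- a
    rem <- rem - a
  }
  stopifnot(all(rem == 0), all(rowSums(alloc) == taxon_counts),
            all(colSums(alloc) == block_records),
            all(t(alloc) <= block_hosts))
  alloc
}

#' Packaged occurrence dataset of the shiny-cowbird mite survey
#'
#' A synthetic per-host reconstruction consistent with the published
#' summary tables of the shiny-cowbird survey: 144 examined hosts (5
#' without mites), 29 taxa, 365 unique host-taxon records, 1246
#' specimens, with the exact per-taxon record and abundance counts, the
#' category subtotals (273/69/23 records), and the per-host co-occurrence
#' block structure (73 specific-only hosts, 36 specific+alien, 14
#' specific+QSM, 7 with all three, 7 alien-only, 1 QSM-only, 1
#' alien+QSM). The assignment of individual records to individual hosts
#' within those constraints is a deterministic construction, not the
#' original field data, which is why every host- or record-level
#' statistic computed from the published tables is reproduced while
#' per-host identities are arbitrary.
#'
#' @return an `occurrence_dataset` with categories assigned.
#' @export
molothrus_dataset <- function() {
  tx <- molothrus_taxa()
  blocks <- molothrus_blocks()

  host_ids <- sprintf("MB%03d", seq_len(144))
  combo_of_host <- rep(blocks$combo, blocks$hosts)
  hosts_in <- split(host_ids, factor(combo_of_host, blocks$combo))

  records <- list()
  cat_blocks <- list(specific = "specific", alien = "alien", qsm = "qsm")
  for (cat in names(cat_blocks)) {
    in_cat <- blocks[[cat]] > 0
    bh <- blocks$hosts[in_cat]
    br <- blocks[[cat]][in_cat]
    combos <- blocks$combo[in_cat]
    t_idx <- which(tx$category == cat)
    alloc <- allocate_counts(tx$n_records[t_idx], bh, br)
    for (g in seq_along(combos)) {
      ids <- hosts_in[[combos[g]]]
      ptr <- 0L
      for (ti in seq_along(t_idx)) {
        k <- alloc[ti, g]
        if (k == 0) next
        pos <- ((ptr + seq_len(k) - 1L) %% length(ids)) + 1L
        ptr <- ptr + k
        records[[length(records) + 1]] <- data.frame(
          host_id = ids[pos], taxon = tx$name[t_idx[ti]],
          abundance = 1L, stringsAsFactors = FALSE)
      }
    }
  }
  rec <- do.call(rbind, records)

  ## distribute each taxon's extra specimens round-robin over its records
  rec <- rec[order(rec$taxon, rec$host_id), , drop = FALSE]
  for (i in seq_len(nrow(tx))) {
    rows <- which(rec$taxon == tx$name[i])
    extra <- tx$abundance[i] - length(rows)
    if (extra > 0) {
      bump <- rep(seq_along(rows), length.out = extra)
      add <- tabulate(bump, nbins = length(rows))
      rec$abundance[rows] <- rec$abundance[rows] + add
    }
  }

  hosts <- data.frame(
    id = host_ids, species = "Molothrus bonariensis",
    source = rep(c("wild_capture", "roadkill", "museum_skin"),
                 c(22, 10, 112)),
    locality = NA_character_, stringsAsFactors = FALSE)
  taxa <- tx[, c("name", "genus", "family", "ecological_group", "category")]
  occurrence_dataset(hosts, taxa, rec)
}

#' Packaged classification-evidence table for the survey taxa
#'
#' One row per taxon with the occurrence and molecular evidence that
#' drives the category rules: specific taxa occur only on the focal host
#' (two of them with a congeneric sister taxon on the other cowbird
#' species and a deep distance to the nearest foster-parent mite), alien
#' taxa occur on foster parents as well, and quill/skin taxa carry the
#' `quill_skin` ecological flag. Distances are K2P proportions; most taxa
#' have none (sequence data existed for only a few).
#'
#' @return data.frame of classification evidence.
#' @export
molothrus_evidence <- function() {
  tx <- molothrus_taxa()
  ev <- data.frame(
    taxon = tx$name,
    found_on_focal_host = TRUE,
    found_on_foster_hosts = tx$category == "alien",
    ecological_group = tx$ecological_group,
    sister_taxon_host = NA_character_,
    distance_to_nearest_foster_mite = NA_real_,
    stringsAsFactors = FALSE)
  ev$sister_taxon_host[ev$taxon == "Amerodectes molothrus"] <- "Molothrus ater"
  ev$distance_to_nearest_foster_mite[ev$taxon == "Amerodectes molothrus"] <- 0.095
  ev$sister_taxon_host[ev$taxon == "Proctophyllodes molothrus"] <- "Molothrus ater"
  ev$distance_to_nearest_foster_mite[ev$taxon == "Proctophyllodes molothrus"] <- 0.055
  ev$distance_to_nearest_foster_mite[ev$taxon == "Trouessartia cf. sicaliae"] <- 0.036
  ev
}

#' The three cowbird-associated lineage tanglegrams
#'
#' Small tanglegrams encoding the three phylogenetically independent
#' cowbird-associated mite lineages and their hosts, with intervening
#' host taxa so the icterid and thraupid clades are not sisters:
#' \describe{
#'   \item{Amerodectes}{a sister pair on the two cowbird species plus the
#'     monophyletic foster lineage on \emph{Sicalis};}
#'   \item{Proctophyllodes}{a sister pair on the two cowbird species in
#'     an outgroup context whose host is outside Icteridae;}
#'   \item{Trouessartia}{a lineage on \emph{Sicalis flaveola} with a
#'     derived population on the cowbird.}
#' }
#' Under default event costs their pooled maximum-parsimony census is 2
#' codivergences (the within-\emph{Molothrus} splits of the
#' \emph{Amerodectes} and \emph{Proctophyllodes} pairs) and 3 host
#' switches.
#'
#' @return named list of three `tanglegram` objects.
#' @export
molothrus_tanglegrams <- function() {
  amer_host <- read_newick(text = paste0(
    "((((Molothrus_ater,Molothrus_bonariensis),Agelaius_phoeniceus),",
    "(Cardinalis_cardinalis,Zonotrichia_capensis)),",
    "((Sicalis_flaveola,Sicalis_luteola),(Tangara_sayaca,Thraupis_episcopus)));"))
  amer_symb <- read_newick(text =
    "((Amerodectes_tretiakae,Amerodectes_molothrus),Amerodectes_sp_Sicalis);")
  amer <- tanglegram(amer_host, amer_symb, c(
    Amerodectes_tretiakae = "Molothrus_ater",
    Amerodectes_molothrus = "Molothrus_bonariensis",
    Amerodectes_sp_Sicalis = "Sicalis_flaveola"))

  proc_host <- read_newick(text = paste0(
    "(((Molothrus_ater,Molothrus_bonariensis),Agelaius_phoeniceus),",
    "((Zonotrichia_capensis,Ammodramus_humeralis),",
    "(Cardinalis_cardinalis,Piranga_flava)));"))
  proc_symb <- read_newick(text = paste0(
    "((Proctophyllodes_sp_M_ater,Proctophyllodes_molothrus),",
    "Proctophyllodes_outgroup);"))
  proc <- tanglegram(proc_host, proc_symb, c(
    Proctophyllodes_sp_M_ater = "Molothrus_ater",
    Proctophyllodes_molothrus = "Molothrus_bonariensis",
    Proctophyllodes_outgroup = "Zonotrichia_capensis"))

  trou_host <- read_newick(text = paste0(
    "((Molothrus_bonariensis,Agelaius_phoeniceus),",
    "((Sicalis_flaveola,Sicalis_luteola),Tangara_sayaca));"))
  trou_symb <- read_newick(text =
    "(Trouessartia_sicaliae_SF,Trouessartia_sicaliae_MB);")
  trou <- tanglegram(trou_host, trou_symb, c(
    Trouessartia_sicaliae_SF = "Sicalis_flaveola",
    Trouessartia_sicaliae_MB = "Molothrus_bonariensis"))

  list(Amerodectes = amer, Proctophyllodes = proc, Trouessartia = trou)
}

#' Pooled reconciliation census over the three lineage tanglegrams
#'
#' Reconciles each lineage separately and sums the event censuses.
#'
#' @param costs an `event_costs`.
#' @return named integer vector (cospeciation, duplication, switch,
#'   loss) summed over the three lineages.
#' @export
molothrus_census <- function(costs = event_costs()) {
  tgs <- molothrus_tanglegrams()
  Reduce(`+`, lapply(tgs, function(tg) count_events(reconcile(tg, costs))))
}
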