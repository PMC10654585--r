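#' Per-taxon prevalence and abundance table
#'
#' One row per taxon: prevalence (% of all examined host individuals
#' carrying it -- symbiont-free hosts count in the denominator), share of
#' presence/absence records, record count, specimen count, and share of
#' total abundance. Category subtotals are appended at one decimal;
#' per-taxon percentages are kept at two decimals. All percentages round
#' half-up.
#'
#' @param dataset an `occurrence_dataset` with categories assigned.
#' @return an object of class `prevalence_table`: a list with `taxa`
#'   (per-taxon data.frame), `subtotals` (per-category data.frame) and the
#'   denominators used.
#' @export
prevalence_table <- function(dataset) {
  validate_occurrence_dataset(dataset)
  n_hosts <- nrow(dataset$hosts)
  if (n_hosts == 0)
    stop_hostspec("no examined hosts: prevalence denominator is zero",
                  "hostspec_denominator_error")
  r <- dataset$records
  n_rec <- nrow(r)
  n_abn <- sum(r$abundance)

  tx <- dataset$taxa
  rows <- lapply(seq_len(nrow(tx)), function(i) {
    ri <- r[r$taxon == tx$name[i], , drop = FALSE]
    data.frame(
      taxon = tx$name[i],
      category = tx$category[i],
      prevalence_pct = round_half_up(nrow(ri) / n_hosts * 100, 2),
      record_share_pct = if (n_rec) round_half_up(nrow(ri) / n_rec * 100, 2) else 0,
      n_records = nrow(ri),
      n_specimens = sum(ri$abundance),
      abundance_share_pct = if (n_abn) round_half_up(sum(ri$abundance) / n_abn * 100, 2) else 0,
      stringsAsFactors = FALSE)
  })
  taxa_df <- do.call(rbind, rows)
  ## deterministic order: category then taxon name
  taxa_df <- taxa_df[order(factor(taxa_df$category,
                                  c("specific", "alien", "qsm", "unassigned")),
                           taxa_df$taxon), , drop = FALSE]
  rownames(taxa_df) <- NULL

  cats <- intersect(c("specific", "alien", "qsm", "unassigned"),
                    unique(taxa_df$category))
  subs <- lapply(cats, function(cc) {
    ri <- r[r$taxon %in% tx$name[tx$category == cc], , drop = FALSE]
    hosts_with <- length(unique(ri$host_id))
    data.frame(
      category = cc,
      n_taxa = sum(tx$category == cc),
      prevalence_pct = round_half_up(hosts_with / n_hosts * 100, 1),
      record_share_pct = if (n_rec) round_half_up(nrow(ri) / n_rec * 100, 1) else 0,
      n_records = nrow(ri),
      n_specimens = sum(ri$abundance),
      abundance_share_pct = if (n_abn) round_half_up(sum(ri$abundance) / n_abn * 100, 1) else 0,
      stringsAsFactors = FALSE)
  })
  structure(list(taxa = taxa_df, subtotals = do.call(rbind, subs),
                 n_hosts = n_hosts, n_records = n_rec, n_specimens = n_abn),
            class = "prevalence_table")
}

#' @export
print.prevalence_table <- function(x, ...) {
  cat(sprintf("Prevalence table: %d taxa, %d hosts, %d records, %d specimens\n",
              nrow(x$taxa), x$n_hosts, x$n_records, x$n_specimens))
  print(x$taxa, row.names = FALSE)
  cat("Subtotals by category:\n")
  print(x$subtotals, row.names = FALSE)
  invisible(x)
}

COMBO_KEYS <- c("S", "A", "Q", "S+A", "S+Q", "A+Q", "S+A+Q", "none")

combo_key <- function(cats) {
  s <- "specific" %in% cats
  a <- "alien" %in% cats
  q <- "qsm" %in% cats
  key <- paste(c(if (s) "S", if (a) "A", if (q) "Q"), collapse = "+")
  if (key == "") "none" else key
}

#' Co-occurrence of host-specificity categories within host individuals
#'
#' Assigns every examined host individual to exactly one exclusive
#' combination of the categories present on it (S = specific, A = alien,
#' Q = quill-and-skin; `"none"` for symbiont-free hosts), and splits the
#' record counts of each combination by category.
#'
#' @param dataset an `occurrence_dataset` with categories assigned.
#' @return an object of class `cooccurrence_summary` with `host_counts`
#'   (named vector over the eight combinations), `record_counts`
#'   (combination x category matrix), and totals.
#' @export
cooccurrence_table <- function(dataset) {
  validate_occurrence_dataset(dataset)
  r <- dataset$records
  cat_of <- dataset$taxa$category[match(r$taxon, dataset$taxa$name)]
  if (any(cat_of == "unassigned"))
    stop_hostspec(paste0("unassigned category for taxa: ",
                         paste(unique(r$taxon[cat_of == "unassigned"]),
                               collapse = ", ")),
                  "hostspec_coverage_error")
  host_combo <- vapply(dataset$hosts$id, function(h)
    combo_key(cat_of[r$host_id == h]), character(1))
  host_counts <- table(factor(host_combo, COMBO_KEYS))
  host_counts <- stats::setNames(as.integer(host_counts), COMBO_KEYS)

  rc <- matrix(0L, length(COMBO_KEYS), 3,
               dimnames = list(COMBO_KEYS, c("specific", "alien", "qsm")))
  combo_of_rec <- host_combo[match(r$host_id, dataset$hosts$id)]
  for (i in seq_len(nrow(r)))
    rc[combo_of_rec[i], cat_of[i]] <- rc[combo_of_rec[i], cat_of[i]] + 1L

  structure(list(host_counts = host_counts, record_counts = rc,
                 n_hosts = nrow(dataset$hosts),
                 n_hosts_with_records = sum(host_counts[setdiff(COMBO_KEYS, "none")]),
                 n_records = nrow(r)),
            class = "cooccurrence_summary")
}

#' Headline co-occurrence percentages with explicit denominators
#'
#' Derived quantities with the denominator each one uses spelled out:
#' host-combination percentages come with both the all-hosts denominator
#' (prevalence convention) and the hosts-carrying-symbionts denominator
#' ("cases" convention) because the two conventions give different
#' numbers (e.g. 73/144 vs 73/139); record shares always use the total
#' record count.
#'
#' @param object a `cooccurrence_summary`.
#' @param ... unused.
#' @return data.frame with columns `quantity`, `value`, `numerator`,
#'   `denominator`.
#' @export
summary.cooccurrence_summary <- function(object, ...) {
  hc <- object$host_counts
  rc <- object$record_counts
  n_all <- object$n_hosts
  n_with <- object$n_hosts_with_records
  n_rec <- object$n_records
  with_s <- sum(hc[c("S", "S+A", "S+Q", "S+A+Q")])
  multi <- c("S+A", "S+Q", "A+Q", "S+A+Q")
  co_spec <- sum(rc[multi, "specific"])
  row <- function(q, num, den, digits = 1)
    data.frame(quantity = q,
               value = round_half_up(num / den * 100, digits),
               numerator = num, denominator = den, stringsAsFactors = FALSE)
  out <- rbind(
    row("hosts_with_specific_pct_of_all", with_s, n_all),
    row("hosts_with_specific_pct_of_mite_bearing", with_s, n_with),
    row("specific_only_hosts_pct_of_all", hc[["S"]], n_all),
    row("specific_only_hosts_pct_of_mite_bearing", hc[["S"]], n_with),
    row("alien_only_hosts_pct_of_all", hc[["A"]], n_all),
    row("single_category_hosts_pct_of_all", sum(hc[c("S", "A", "Q")]), n_all),
    row("cooccurrence_hosts_pct_of_all", sum(hc[multi]), n_all),
    row("cooccurring_specific_records_pct_of_records", co_spec, n_rec),
    row("cooccurring_alien_records_pct_of_records", sum(rc[multi, "alien"]), n_rec),
    row("cooccurring_qsm_records_pct_of_records", sum(rc[multi, "qsm"]), n_rec),
    row("alien_only_records_pct_of_records", rc["A", "alien"], n_rec),
    row("specific_only_records_pct_of_records", rc["S", "specific"], n_rec))
  out$n_hosts_with_specific <- with_s
  rownames(out) <- NULL
  out
}

#' @export
print.cooccurrence_summary <- function(x, ...) {
  cat(sprintf("Co-occurrence summary: %d hosts (%d with records), %d records\n",
              x$n_hosts, x$n_hosts_with_records, x$n_records))
  df <- data.frame(combination = COMBO_KEYS,
                   hosts = x$host_counts,
                   hosts_pct = round_half_up(x$host_counts / x$n_hosts * 100, 1),
                   x$record_counts,
                   stringsAsFactors = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Estimate the conspecific : interspecific transmission-rate ratio
#'
#' On a brood-parasitic host there is no vertical conspecific
#' transmission (q_vc = 0), so every record of a host-specific symbiont
#' reflects horizontal conspecific transmission (q_hc), while records of
#' foster-parent ("alien") symbionts reflect interspecific transmission
#' (q_vi + q_hi). Quill-and-skin records have an undetermined route and
#' are used only to bound the ratio: the lower bound assigns them all to
#' the interspecific side, the upper bound all to the conspecific side.
#'
#' Record-count shares are rounded half-up to one decimal and the bounds
#' are computed from the rounded shares (lower = s/(100 - s), upper =
#' (s + q)/a), matching the tabulated arithmetic; the point ratio is kept
#' unrounded with a one-decimal display. A zero interspecific share
#' yields infinite ratios, flagged rather than raised.
#'
#' @param x a `cooccurrence_summary`, an `occurrence_dataset` with
#'   categories assigned, or a named numeric vector/list with elements
#'   `specific`, `alien`, `qsm` of record counts.
#' @param digits decimals for shares and displayed ratios (default 1).
#' @return an object of class `transmission_estimate`.
#' @export
estimate_transmission <- function(x, digits = 1) {
  counts <-
    if (inherits(x, "cooccurrence_summary")) colSums(x$record_counts)
    else if (inherits(x, "occurrence_dataset")) colSums(cooccurrence_table(x)$record_counts)
    else {
      v <- unlist(x)
      if (!all(c("specific", "alien", "qsm") %in% names(v)))
        stop_hostspec("need named counts 'specific', 'alien', 'qsm'",
                      "hostspec_validation_error")
      v[c("specific", "alien", "qsm")]
    }
  counts <- as.numeric(counts)
  names(counts) <- c("specific", "alien", "qsm")
  if (anyNA(counts) || any(counts < 0))
    stop_hostspec("record counts must be non-negative",
                  "hostspec_validation_error")
  total <- sum(counts)
  if (total <= 0)
    stop_hostspec("no records: shares undefined", "hostspec_validation_error")

  shares <- round_half_up(counts / total * 100, digits)
  s <- shares[["specific"]]; a <- shares[["alien"]]; q <- shares[["qsm"]]

  ratio_point <- if (counts[["alien"]] > 0) counts[["specific"]] / counts[["alien"]] else Inf
  ratio_lower_raw <- if (100 - s > 0) s / (100 - s) else Inf
  ratio_upper_raw <- if (a > 0) (s + q) / a else Inf

  structure(list(
    counts = stats::setNames(counts, c("specific", "alien", "qsm")),
    n_records = total,
    share_specific_pct = s, share_alien_pct = a, share_qsm_pct = q,
    ratio_point = ratio_point,
    ratio_point_display = round_half_up(ratio_point, digits),
    ratio_lower = round_half_up(ratio_lower_raw, digits),
    ratio_upper = round_half_up(ratio_upper_raw, digits),
    ratio_lower_raw = ratio_lower_raw,
    ratio_upper_raw = ratio_upper_raw,
    digits = digits), class = "transmission_estimate")
}

#' @export
print.transmission_estimate <- function(x, ...) {
  cat("Transmission-route estimate (record shares)\n")
  cat(sprintf("  conspecific horizontal (q_hc, specific) : %5.1f%%  (%d records)\n",
              x$share_specific_pct, x$counts[["specific"]]))
  cat(sprintf("  interspecific (q_vi + q_hi, alien)      : %5.1f%%  (%d records)\n",
              x$share_alien_pct, x$counts[["alien"]]))
  cat(sprintf("  undetermined route (QSM)                : %5.1f%%  (%d records)\n",
              x$share_qsm_pct, x$counts[["qsm"]]))
  fmt <- function(v) if (is.finite(v)) sprintf("%.*f", x$digits, v) else "Inf"
  cat(sprintf("  conspecific:interspecific ratio: %s (QSM-assignment bounds %s - %s)\n",
              fmt(x$ratio_point_display), fmt(x$ratio_lower),
              fmt(x$ratio_upper)))
  invisible(x)
}

#' @export
summary.transmission_estimate <- function(object, ...) {
  print(object)
  cat(sprintf("  unrounded point ratio: %.4f\n", object$ratio_point))
  cat(sprintf("  bounds before display rounding: %.4f - %.4f\n",
              object$ratio_lower_raw, object$ratio_upper_raw))
  invisible(object)
}

#' @export
coef.transmission_estimate <- function(object, ...) {
  c(share_specific_pct = object$share_specific_pct,
    share_alien_pct = object$share_alien_pct,
    share_qsm_pct = object$share_qsm_pct,
    ratio = object$ratio_point)
}

#' QSM-assignment bounds of the transmission-rate ratio
#'
#' Not a statistical confidence interval: the bounds bracket the ratio
#' over the two extreme assignments of the undetermined quill-and-skin
#' records (all interspecific vs all conspecific).
#'
#' @param object a `transmission_estimate`.
#' @param parm,level ignored (present for the generic).
#' @param ... unused.
#' @return 1 x 2 matrix with columns `lower`, `upper`.
#' @export
confint.transmission_estimate <- function(object, parm, level = 0.95, ...) {
  matrix(c(object$ratio_lower, object$ratio_upper), 1, 2,
         dimnames = list("ratio", c("lower", "upper")))
}
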