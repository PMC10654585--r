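#' Configuration for the transmission simulator
#'
#' Encodes the four-route transmission model for a focal host. In
#' brood-parasite mode the vertical conspecific route is structurally
#' absent (`q_vc = 0`): chicks are reared by foster parents, so
#' host-specific symbionts can only arrive by horizontal conspecific
#' contact.
#'
#' @param n_focal_hosts focal host individuals to simulate.
#' @param n_foster_species number of foster-parent species.
#' @param foster_mite_pool symbiont taxa per foster species.
#' @param focal_specific_pool host-specific symbiont taxa.
#' @param q_vc per-offspring vertical conspecific probability; must be 0
#'   in brood-parasite mode.
#' @param q_vi per-rearing acquisition probability per foster taxon
#'   (vertical interspecific).
#' @param q_hc per-contact acquisition probability per specific taxon
#'   (horizontal conspecific).
#' @param q_hi per-contact acquisition probability per foster taxon
#'   (horizontal interspecific).
#' @param n_contacts_conspecific,n_contacts_interspecific contact counts
#'   per focal host.
#' @param seed integer RNG seed.
#' @param brood_parasite logical; forces `q_vc = 0` when `TRUE`.
#' @param foster_weights optional probability weights over foster species
#'   (default uniform).
#' @return object of class `transmission_sim_config`.
#' @export
transmission_sim_config <- function(n_focal_hosts, n_foster_species = 10,
                                    foster_mite_pool = 3,
                                    focal_specific_pool = 5,
                                    q_vc = 0, q_vi = 0.1, q_hc = 0.05,
                                    q_hi = 0, n_contacts_conspecific = 10,
                                    n_contacts_interspecific = 5,
                                    seed = 1, brood_parasite = TRUE,
                                    foster_weights = NULL) {
  if (n_focal_hosts < 1)
    stop_hostspec("need at least one focal host", "hostspec_config_error")
  probs <- c(q_vc = q_vc, q_vi = q_vi, q_hc = q_hc, q_hi = q_hi)
  if (any(probs < 0 | probs > 1))
    stop_hostspec("transmission probabilities must be in [0, 1]",
                  "hostspec_config_error")
  if (brood_parasite && q_vc != 0)
    stop_hostspec("brood-parasite mode forces q_vc = 0",
                  "hostspec_config_error")
  if (!is.null(foster_weights) &&
      length(foster_weights) != n_foster_species)
    stop_hostspec("foster_weights length must match n_foster_species",
                  "hostspec_config_error")
  structure(list(n_focal_hosts = n_focal_hosts,
                 n_foster_species = n_foster_species,
                 foster_mite_pool = foster_mite_pool,
                 focal_specific_pool = focal_specific_pool,
                 q_vc = q_vc, q_vi = q_vi, q_hc = q_hc, q_hi = q_hi,
                 n_contacts_conspecific = n_contacts_conspecific,
                 n_contacts_interspecific = n_contacts_interspecific,
                 seed = seed, brood_parasite = brood_parasite,
                 foster_weights = foster_weights),
            class = "transmission_sim_config")
}

#' Expected per-host record counts under a transmission configuration
#'
#' Closed forms used as the recovery oracle. A specific taxon is recorded
#' on a host with probability `1 - (1 - q_hc)^n_contacts_conspecific`.
#' An alien taxon of foster species s is recorded with probability
#' `1 - (1 - q_vi I(reared by s)) (1 - q_hi / F)^n_contacts_interspecific`
#' (uniform foster choice; each interspecific contact partner is uniform
#' over the F foster species).
#'
#' @param config a `transmission_sim_config` (uniform foster weights).
#' @return list with `specific`, `alien` expected record counts per host
#'   and `ratio` of the two.
#' @export
expected_record_counts <- function(config) {
  S <- config$focal_specific_pool
  Fn <- config$n_foster_species
  pool <- config$foster_mite_pool
  e_spec <- S * (1 - (1 - config$q_hc)^config$n_contacts_conspecific)
  c_h <- (1 - config$q_hi / Fn)^config$n_contacts_interspecific
  e_alien <- pool * (1 - (1 - config$q_vi) * c_h) +
    (Fn - 1) * pool * (1 - c_h)
  list(specific = e_spec, alien = e_alien,
       ratio = if (e_alien > 0) e_spec / e_alien else Inf)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate occurrence data under the four-route transmission model
#'
#' Each focal host is reared by one foster species (acquiring each of its
#' pool taxa with probability `q_vi`), then undergoes
#' `n_contacts_conspecific` conspecific contacts (each specific-pool
#' taxon acquired with per-contact probability `q_hc`) and
#' `n_contacts_interspecific` interspecific contacts with uniformly
#' chosen foster species (each partner-pool taxon acquired with
#' per-contact probability `q_hi`). The first acquisition of a taxon
#' creates the presence/absence record; repeats increment its abundance.
#' Category labels equal the pool of origin, so estimator recovery can be
#' checked against the configured rates.
#'
#' @param config a `transmission_sim_config`.
#' @return list with `dataset` (an `occurrence_dataset`),
#'   `true_expected` (the [expected_record_counts()] oracle), and
#'   `config`.
#' @export
simulate_transmission <- function(config) {
  stopifnot(inherits(config, "transmission_sim_config"))
  with_seed(config$seed, {
    n <- config$n_focal_hosts
    S <- config$focal_specific_pool
    Fn <- config$n_foster_species
    pool <- config$foster_mite_pool
    w <- config$foster_weights %||% rep(1 / Fn, Fn)
    w <- w / sum(w)

    host_ids <- sprintf("FH%04d", seq_len(n))
    spec_taxa <- sprintf("specific_taxon_%02d", seq_len(S))
    alien_taxa <- as.vector(outer(seq_len(pool), seq_len(Fn), function(t, s)
      sprintf("foster%02d_taxon_%02d", s, t)))

    recs <- vector("list", 3)
    ## conspecific horizontal: acquisitions ~ Binom(contacts, q_hc)
    acq <- matrix(stats::rbinom(n * S, config$n_contacts_conspecific,
                                config$q_hc), n, S)
    idx <- which(acq > 0, arr.ind = TRUE)
    recs[[1]] <- data.frame(host_id = host_ids[idx[, 1]],
                            taxon = spec_taxa[idx[, 2]],
                            abundance = acq[idx], stringsAsFactors = FALSE)

    ## vertical interspecific: one rearing foster per host
    foster <- sample.int(Fn, n, replace = TRUE, prob = w)
    vert <- matrix(stats::rbinom(n * pool, 1, config$q_vi), n, pool)
    ## horizontal interspecific: contacts split over partner species
    hor <- matrix(0L, n, Fn * pool)
    if (config$q_hi > 0 && config$n_contacts_interspecific > 0) {
      partners <- matrix(sample.int(Fn, n * config$n_contacts_interspecific,
                                    replace = TRUE, prob = w),
                         n, config$n_contacts_interspecific)
      for (s in seq_len(Fn)) {
        m_s <- rowSums(partners == s)
        for (t in seq_len(pool)) {
          col <- (s - 1) * pool + t
          hor[, col] <- stats::rbinom(n, m_s, config$q_hi)
        }
      }
    }
    alien_acq <- hor
    for (t in seq_len(pool)) {
      col <- (foster - 1) * pool + t
      alien_acq[cbind(seq_len(n), col)] <-
        alien_acq[cbind(seq_len(n), col)] + vert[, t]
    }
    idx <- which(alien_acq > 0, arr.ind = TRUE)
    recs[[2]] <- data.frame(host_id = host_ids[idx[, 1]],
                            taxon = alien_taxa[idx[, 2]],
                            abundance = alien_acq[idx],
                            stringsAsFactors = FALSE)

    records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
    records <- records[order(records$host_id, records$taxon), , drop = FALSE]

    hosts <- data.frame(id = host_ids, species = "Molothrus bonariensis",
                        source = "wild_capture", locality = NA_character_,
                        stringsAsFactors = FALSE)
    taxa <- data.frame(
      name = c(spec_taxa, alien_taxa),
      genus = "Simulatus", family = "Simulatidae",
      ecological_group = "vane",
      category = c(rep("specific", S), rep("alien", Fn * pool)),
      stringsAsFactors = FALSE)
    list(dataset = occurrence_dataset(hosts, taxa, records),
         true_expected = expected_record_counts(config),
         config = config)
  })
}

#' Simulate a pair of sequences at a target K2P distance
#'
#' Sites mutate independently with the transition and transversion
#' probabilities that solve the K2P expectation for distance `d` at
#' transition/transversion rate ratio `ts_tv` (kappa): with
#' `k = ts_tv`, the per-site transition probability is
#' `1/4 + 1/4 exp(-4d/(k+2)) - 1/2 exp(-2d(k+1)/(k+2))` and the total
#' transversion probability `1/2 - 1/2 exp(-4d/(k+2))`; plugging these
#' back into the K2P formula returns exactly `d`.
#'
#' @param d target distance (substitutions per site), >= 0.
#' @param ts_tv transition/transversion rate ratio, finite and > 0.
#' @param length alignment length in sites.
#' @param seed integer RNG seed.
#' @param ancestor optional starting sequence (A/C/G/T string); when given
#'   it is returned as `seq_a` and `length` is ignored, which allows
#'   several taxa to be simulated on a shared alignment.
#' @return named character vector of two aligned sequences `seq_a`,
#'   `seq_b`.
#' @export
simulate_k2p_pair <- function(d, ts_tv = 2, length = 1000, seed = 1,
                              ancestor = NULL) {
  if (!is.finite(d) || d < 0)
    stop_hostspec("d must be finite and >= 0", "hostspec_config_error")
  if (!is.finite(ts_tv) || ts_tv <= 0)
    stop_hostspec("ts_tv must be finite and > 0", "hostspec_config_error")
  if (length < 1) stop_hostspec("length must be >= 1", "hostspec_config_error")
  k <- ts_tv
  e1 <- exp(-4 * d / (k + 2))
  p_ts <- 1 / 4 + e1 / 4 - exp(-2 * d * (k + 1) / (k + 2)) / 2
  p_tv <- 1 / 2 - e1 / 2
  if (1 - 2 * p_ts - p_tv < 0.1)
    warning("target distance close to saturation; estimates may be undefined")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  with_seed(seed, {
    anc <- if (is.null(ancestor))
      sample(c("A", "C", "G", "T"), length, replace = TRUE)
    else strsplit(toupper(ancestor), "")[[1]]
    length <- length(anc)
    u <- stats::runif(length)
    der <- anc
    is_ts <- u < p_ts
    der[is_ts] <- transition[anc[is_ts]]
    is_tv <- !is_ts & u < p_ts + p_tv
    if (any(is_tv)) {
      pick <- stats::runif(sum(is_tv)) < 0.5
      der[is_tv] <- mapply(function(base, first)
        transversions[[base]][if (first) 1 else 2],
        anc[is_tv], pick)
    }
    c(seq_a = paste(anc, collapse = ""), seq_b = paste(der, collapse = ""))
  })
}

#' Configuration for the cophylogeny simulator
#'
#' @param n_host_leaves leaves of the host tree (>= 2).
#' @param p_cospeciate probability a symbiont lineage tracks a host
#'   split; lineages that do not track it follow one daughter (a sorting
#'   loss on the other).
#' @param rate_switch per-host-split probability that a symbiont lineage
#'   speciates with one daughter jumping to a uniformly chosen
#'   contemporary host lineage (its own host included, which yields a
#'   duplication).
#' @param rate_loss per-host-split extinction probability per symbiont
#'   lineage.
#' @param seed integer RNG seed.
#' @param max_retry replicates with fewer than two surviving symbionts
#'   are redrawn at most this many times before erroring.
#' @return object of class `cophylo_sim_config`.
#' @export
cophylo_sim_config <- function(n_host_leaves, p_cospeciate = 0.9,
                               rate_switch = 0.1, rate_loss = 0.05,
                               seed = 1, max_retry = 100) {
  if (n_host_leaves < 2)
    stop_hostspec("need at least 2 host leaves", "hostspec_config_error")
  probs <- c(p_cospeciate, rate_switch, rate_loss)
  if (any(probs < 0 | probs > 1))
    stop_hostspec("probabilities must be in [0, 1]", "hostspec_config_error")
  structure(list(n_host_leaves = n_host_leaves,
                 p_cospeciate = p_cospeciate, rate_switch = rate_switch,
                 rate_loss = rate_loss, seed = seed, max_retry = max_retry),
            class = "cophylo_sim_config")
}

#' Simulate a tanglegram by cospeciation, host switch and loss events
#'
#' The host tree grows by splitting a uniformly chosen extant lineage
#' until it has the requested number of leaves. Symbionts start as one
#' lineage on the host root and react to each host split: lineages on the
#' splitting host cospeciate with probability `p_cospeciate`, otherwise
#' follow one daughter (a sorting loss); every lineage then speciates
#' with probability `rate_switch`, one daughter jumping to a random
#' contemporary host (a duplication when the target is its own host), and
#' dies with probability `rate_loss`. Extinct subtrees are pruned and
#' unifurcations suppressed, so the returned symbiont tree is binary.
#' The true event log counts every event as simulated, including those on
#' lineages that later went extinct.
#'
#' @param config a `cophylo_sim_config`.
#' @return list with `tanglegram`, `events` (named counts: cospeciation,
#'   duplication, switch, loss), and `config`.
#' @export
simulate_cophylogeny <- function(config) {
  stopifnot(inherits(config, "cophylo_sim_config"))
  with_seed(config$seed, {
    for (attempt in seq_len(config$max_retry)) {
      out <- cophylo_once(config)
      if (!is.null(out)) return(out)
    }
    stop_hostspec("all symbionts went extinct in every replicate attempt",
                  "hostspec_config_error")
  })
}

cophylo_once <- function(config) {
  n_target <- config$n_host_leaves
  host_children <- list()          # host id -> c(a, b) once split
  active_hosts <- 1L
  next_host <- 2L

  symb <- list(list(id = 1L, host = 1L, kids = NULL, alive = TRUE))
  next_symb <- 2L
  events <- c(cospeciation = 0L, duplication = 0L, switch = 0L, loss = 0L)

  new_symb <- function(host) {
    s <- list(id = next_symb, host = host, kids = NULL, alive = TRUE)
    symb[[next_symb]] <<- s
    next_symb <<- next_symb + 1L
    s$id
  }

  while (length(active_hosts) < n_target) {
    hx <- active_hosts[sample.int(length(active_hosts), 1)]
    a <- next_host; b <- next_host + 1L
    next_host <- next_host + 2L
    host_children[[as.character(hx)]] <- c(a, b)
    active_hosts <- c(setdiff(active_hosts, hx), a, b)

    alive_ids <- which(vapply(symb, function(s) s$alive, logical(1)))
    for (i in alive_ids) {
      if (symb[[i]]$host == hx) {
        if (stats::runif(1) < config$p_cospeciate) {
          k1 <- new_symb(a); k2 <- new_symb(b)
          symb[[i]]$kids <- c(k1, k2)
          symb[[i]]$alive <- FALSE
          events[["cospeciation"]] <- events[["cospeciation"]] + 1L
        } else {
          symb[[i]]$host <- if (stats::runif(1) < 0.5) a else b
          events[["loss"]] <- events[["loss"]] + 1L   # missed the boat
        }
      }
    }
    alive_ids <- which(vapply(symb, function(s) s$alive, logical(1)))
    for (i in alive_ids) {
      if (stats::runif(1) < config$rate_switch) {
        target <- active_hosts[sample.int(length(active_hosts), 1)]
        k1 <- new_symb(symb[[i]]$host); k2 <- new_symb(target)
        symb[[i]]$kids <- c(k1, k2)
        symb[[i]]$alive <- FALSE
        if (target == symb[[i]]$host)
          events[["duplication"]] <- events[["duplication"]] + 1L
        else events[["switch"]] <- events[["switch"]] + 1L
      }
    }
    alive_ids <- which(vapply(symb, function(s) s$alive, logical(1)))
    for (i in alive_ids) {
      if (stats::runif(1) < config$rate_loss) {
        symb[[i]]$alive <- FALSE
        symb[[i]]$extinct <- TRUE
        events[["loss"]] <- events[["loss"]] + 1L
      }
    }
  }

  host_label <- stats::setNames(sprintf("H%02d", seq_along(active_hosts)),
                                as.character(sort(active_hosts)))
  host_newick <- function(id) {
    kk <- host_children[[as.character(id)]]
    if (is.null(kk)) host_label[[as.character(id)]]
    else paste0("(", host_newick(kk[1]), ",", host_newick(kk[2]), ")")
  }
  host_tree <- read_newick(text = paste0(host_newick(1L), ";"))

  ## prune the symbiont genealogy to surviving leaves
  phi <- character(0)
  leaf_ct <- 0L
  prune <- function(id) {
    s <- symb[[id]]
    if (is.null(s$kids)) {
      if (!s$alive) return(NULL)
      leaf_ct <<- leaf_ct + 1L
      lab <- sprintf("m%02d", leaf_ct)
      phi[[lab]] <<- host_label[[as.character(s$host)]]
      return(lab)
    }
    sub <- Filter(Negate(is.null), lapply(s$kids, prune))
    if (length(sub) == 0) return(NULL)
    if (length(sub) == 1) return(sub[[1]])
    paste0("(", sub[[1]], ",", sub[[2]], ")")
  }
  nwk <- prune(1L)
  if (is.null(nwk) || leaf_ct < 2) return(NULL)
  symb_tree <- read_newick(text = paste0(nwk, ";"))
  list(tanglegram = tanglegram(host_tree, symb_tree, phi),
       events = events, config = config)
}
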