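#' Host-symbiont tanglegram
#'
#' Bundles a rooted binary host tree, a rooted binary symbiont tree, and
#' the leaf association map `phi` sending every symbiont leaf to the host
#' leaf it lives on. Hosts without symbionts are allowed; several
#' symbiont leaves may share one host leaf.
#'
#' @param host_tree,symbiont_tree [ape::phylo] trees (validated as rooted
#'   and binary).
#' @param phi named character vector: names are symbiont leaf labels,
#'   values host leaf labels.
#' @return object of class `tanglegram`.
#' @export
tanglegram <- function(host_tree, symbiont_tree, phi) {
  host_tree <- validate_binary_tree(host_tree)
  symbiont_tree <- validate_binary_tree(symbiont_tree)
  miss <- setdiff(symbiont_tree$tip.label, names(phi))
  if (length(miss))
    stop_hostspec(paste0("phi missing symbiont leaves: ",
                         paste(miss, collapse = ", ")),
                  "hostspec_phi_error")
  phi <- phi[symbiont_tree$tip.label]
  bad <- setdiff(unname(phi), host_tree$tip.label)
  if (length(bad))
    stop_hostspec(paste0("phi maps to unknown host leaves: ",
                         paste(bad, collapse = ", ")),
                  "hostspec_phi_error")
  structure(list(host_tree = host_tree, symbiont_tree = symbiont_tree,
                 phi = phi),
            class = "tanglegram")
}

#' Read a tanglegram from two Newick files and a leaf-map TSV
#'
#' @param host_path,symbiont_path Newick files.
#' @param phi_path two-column TSV (symbiont leaf, host leaf), with or
#'   without a header line.
#' @return a `tanglegram`.
#' @export
read_tanglegram <- function(host_path, symbiont_path, phi_path) {
  host <- read_newick(host_path)
  symb <- read_newick(symbiont_path)
  df <- utils::read.table(phi_path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (identical(tolower(df[1, 1]), "symbiont")) df <- df[-1, , drop = FALSE]
  tanglegram(host, symb, stats::setNames(as.character(df[[2]]),
                                         as.character(df[[1]])))
}

#' @export
print.tanglegram <- function(x, ...) {
  cat(sprintf("Tanglegram: %d host leaves, %d symbiont leaves\n",
              ape::Ntip(x$host_tree), ape::Ntip(x$symbiont_tree)))
  for (s in names(x$phi)) cat(sprintf("  %s -> %s\n", s, x$phi[[s]]))
  invisible(x)
}

#' Event costs for parsimony reconciliation
#'
#' Defaults (0, 1, 1, 1): free codivergence and unit duplication, host
#' switch and loss, the usual convention of event-based parsimony
#' reconciliation tools.
#'
#' @param cospeciation cost >= 0.
#' @param duplication,switch,loss costs > 0.
#' @return object of class `event_costs` (named numeric vector).
#' @export
event_costs <- function(cospeciation = 0, duplication = 1, switch = 1,
                        loss = 1) {
  v <- c(cospeciation = cospeciation, duplication = duplication,
         switch = switch, loss = loss)
  if (anyNA(v) || any(!is.finite(v)))
    stop_hostspec("event costs must be finite", "hostspec_validation_error")
  if (cospeciation < 0 || duplication <= 0 || switch <= 0 || loss <= 0)
    stop_hostspec("need cospeciation >= 0 and positive other costs",
                  "hostspec_validation_error")
  structure(v, class = "event_costs")
}

## ---- tree bookkeeping -----------------------------------------------------

tree_info <- function(tr) {
  n_tip <- ape::Ntip(tr)
  n_all <- n_tip + tr$Nnode
  edge <- tr$edge
  parent <- rep(NA_integer_, n_all)
  parent[edge[, 2]] <- edge[, 1]
  children <- vector("list", n_all)
  for (v in seq_len(n_all)) children[[v]] <- edge[edge[, 1] == v, 2]
  root <- setdiff(edge[, 1], edge[, 2])[1]

  ## postorder over all nodes
  po <- integer(0)
  stack <- root
  while (length(stack)) {           # preorder, then reverse
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    po <- c(po, v)
    stack <- c(stack, children[[v]])
  }
  postorder <- rev(po)

  depth <- rep(NA_real_, n_all)
  depth[root] <- 0
  for (v in po[-1]) depth[v] <- depth[parent[v]] + 1

  ## D[i, j] = TRUE iff i lies in the subtree rooted at j (i at-or-below j)
  D <- matrix(FALSE, n_all, n_all)
  for (v in postorder) {
    D[v, v] <- TRUE
    for (ch in children[[v]]) D[, v] <- D[, v] | D[, ch]
  }
  comparable <- D | t(D)

  name_of <- character(n_all)
  for (v in seq_len(n_all)) {
    tips <- sort(tr$tip.label[which(D[seq_len(n_tip), v])])
    name_of[v] <- if (v <= n_tip) tr$tip.label[v]
                  else paste(tips, collapse = "+")
  }
  canon <- order(order(name_of))    # rank used for deterministic tie-breaks

  list(tree = tr, n_tip = n_tip, n_all = n_all, root = root,
       parent = parent, children = children, postorder = postorder,
       depth = depth, D = D, comparable = comparable,
       name_of = name_of, canon = canon)
}

## ---- dynamic program ------------------------------------------------------

#' Minimal reconciliation cost table
#'
#' Dynamic program over symbiont nodes (postorder) x host nodes. A leaf
#' costs 0 at its associated host leaf and is unreachable elsewhere; an
#' internal symbiont node mapped to host node h takes the cheapest of
#' \itemize{
#'   \item cospeciation: its children descend into the two distinct child
#'     subtrees of h,
#'   \item duplication: both children stay at or below h,
#'   \item host switch: one child stays at or below h, the other jumps to
#'     any host node not ancestrally comparable with h,
#' }
#' each host edge traversed on the way down charging one loss. The
#' optimum is the minimum over host nodes at the symbiont root. Switches
#' are undated: any non-ancestral host is a legal recipient.
#'
#' @param tanglegram a `tanglegram`.
#' @param costs an `event_costs`.
#' @return object of class `mpr_cost_table` with matrices `C` (enter
#'   exactly at h), `IN` (enter at-or-below h), `OUT` (cheapest
#'   incomparable landing), and `optimum`.
#' @export
mpr_cost <- function(tanglegram, costs = event_costs()) {
  stopifnot(inherits(tanglegram, "tanglegram"))
  if (!inherits(costs, "event_costs")) costs <- do.call(event_costs, as.list(costs))
  H <- tree_info(tanglegram$host_tree)
  S <- tree_info(tanglegram$symbiont_tree)
  co <- costs[["cospeciation"]]; du <- costs[["duplication"]]
  sw <- costs[["switch"]]; lo <- costs[["loss"]]

  phi_idx <- match(tanglegram$phi, tanglegram$host_tree$tip.label)
  names(phi_idx) <- names(tanglegram$phi)

  nS <- S$n_all; nH <- H$n_all
  C <- matrix(Inf, nS, nH)
  IN <- matrix(Inf, nS, nH)
  OUT <- matrix(Inf, nS, nH)
  incomp <- !H$comparable

  for (p in S$postorder) {
    if (p <= S$n_tip) {
      C[p, phi_idx[[S$tree$tip.label[p]]]] <- 0
    } else {
      k <- S$children[[p]]
      p1 <- k[1]; p2 <- k[2]
      for (h in seq_len(nH)) {
        best <- du + IN[p1, h] + IN[p2, h]
        hk <- H$children[[h]]
        if (length(hk) == 2) {
          spec <- co + min(IN[p1, hk[1]] + IN[p2, hk[2]],
                           IN[p1, hk[2]] + IN[p2, hk[1]])
          if (spec < best) best <- spec
        }
        tr_cost <- sw + min(IN[p1, h] + OUT[p2, h], IN[p2, h] + OUT[p1, h])
        if (tr_cost < best) best <- tr_cost
        C[p, h] <- best
      }
    }
    for (h in H$postorder) {
      v <- C[p, h]
      for (ch in H$children[[h]]) v <- min(v, lo + IN[p, ch])
      IN[p, h] <- v
    }
    for (h in seq_len(nH)) {
      inc <- which(incomp[, h])
      OUT[p, h] <- if (length(inc)) min(C[p, inc]) else Inf
    }
  }
  structure(list(C = C, IN = IN, OUT = OUT,
                 optimum = min(C[S$root, ]),
                 H = H, S = S, costs = costs, phi_idx = phi_idx),
            class = "mpr_cost_table")
}

#' @export
print.mpr_cost_table <- function(x, ...) {
  cat(sprintf("MPR cost table: %d symbiont x %d host nodes, optimum %g\n",
              nrow(x$C), ncol(x$C), x$optimum))
  invisible(x)
}

## number of co-optimal backtraces of the DP (distinct event structures)
count_optima <- function(ct) {
  H <- ct$H; S <- ct$S
  co <- ct$costs[["cospeciation"]]; du <- ct$costs[["duplication"]]
  sw <- ct$costs[["switch"]]; lo <- ct$costs[["loss"]]
  nS <- S$n_all; nH <- H$n_all
  CN <- matrix(0, nS, nH); INN <- matrix(0, nS, nH); OUTN <- matrix(0, nS, nH)
  eq <- function(a, b) is.finite(a) & is.finite(b) & abs(a - b) < 1e-9
  for (p in S$postorder) {
    if (p <= S$n_tip) {
      CN[p, ct$phi_idx[[S$tree$tip.label[p]]]] <- 1
    } else {
      k <- S$children[[p]]; p1 <- k[1]; p2 <- k[2]
      for (h in seq_len(nH)) {
        tot <- 0
        if (eq(ct$C[p, h], du + ct$IN[p1, h] + ct$IN[p2, h]))
          tot <- tot + INN[p1, h] * INN[p2, h]
        hk <- H$children[[h]]
        if (length(hk) == 2) {
          if (eq(ct$C[p, h], co + ct$IN[p1, hk[1]] + ct$IN[p2, hk[2]]))
            tot <- tot + INN[p1, hk[1]] * INN[p2, hk[2]]
          if (eq(ct$C[p, h], co + ct$IN[p1, hk[2]] + ct$IN[p2, hk[1]]))
            tot <- tot + INN[p1, hk[2]] * INN[p2, hk[1]]
        }
        if (eq(ct$C[p, h], sw + ct$IN[p1, h] + ct$OUT[p2, h]))
          tot <- tot + INN[p1, h] * OUTN[p2, h]
        if (eq(ct$C[p, h], sw + ct$IN[p2, h] + ct$OUT[p1, h]))
          tot <- tot + INN[p2, h] * OUTN[p1, h]
        CN[p, h] <- tot
      }
    }
    for (h in H$postorder) {
      v <- if (eq(ct$IN[p, h], ct$C[p, h])) CN[p, h] else 0
      for (ch in H$children[[h]])
        if (eq(ct$IN[p, h], lo + ct$IN[p, ch])) v <- v + INN[p, ch]
      INN[p, h] <- v
    }
    for (h in seq_len(nH)) {
      inc <- which(!ct$H$comparable[, h])
      OUTN[p, h] <- sum(CN[p, inc][eq(ct$C[p, inc], ct$OUT[p, h])])
    }
  }
  sum(CN[S$root, ][eq(ct$C[S$root, ], ct$optimum)])
}

## ---- backtrace ------------------------------------------------------------

#' Extract one optimal reconciliation from a cost table
#'
#' Deterministic tie-breaking: at equal cost prefer cospeciation over
#' duplication over host switch, and among equally cheap host placements
#' take the one whose canonical label (sorted leaf set) is smallest. The
#' number of co-optimal solutions of the dynamic program is reported
#' alongside the single reconciliation returned.
#'
#' @param tanglegram a `tanglegram`.
#' @param costs an `event_costs`.
#' @param cost_table optional precomputed [mpr_cost()] table.
#' @return object of class `reconciliation`: `mapping` (symbiont node ->
#'   host node, canonical labels), `events` data.frame, `counts` census,
#'   `total_cost`, `n_optimal`, `costs`.
#' @export
backtrace <- function(tanglegram, costs = event_costs(), cost_table = NULL) {
  ct <- cost_table %||% mpr_cost(tanglegram, costs)
  H <- ct$H; S <- ct$S
  co <- ct$costs[["cospeciation"]]; du <- ct$costs[["duplication"]]
  sw <- ct$costs[["switch"]]; lo <- ct$costs[["loss"]]
  eq <- function(a, b) is.finite(a) & is.finite(b) & abs(a - b) < 1e-9
  events <- list()
  mapping <- character(0)
  sname <- function(p) if (p <= S$n_tip) S$tree$tip.label[p]
                       else paste0("node_", S$name_of[p])

  add_event <- function(p, type, host, recipient = NA_character_) {
    events[[length(events) + 1]] <<- data.frame(
      symbiont = sname(p), event = type, host = H$name_of[host],
      recipient = recipient, stringsAsFactors = FALSE)
  }

  pick_min <- function(idx, vals) {        # smallest canonical label wins ties
    m <- min(vals)
    cand <- idx[eq(vals, m)]
    cand[order(H$canon[cand])][1]
  }

  ## follow the IN chain from h down to the node where the lineage settles
  resolve_in <- function(p, h) {
    while (!eq(ct$IN[p, h], ct$C[p, h])) {
      kids <- H$children[[h]]
      nxt <- kids[eq(ct$IN[p, h], lo + ct$IN[p, kids])]
      nxt <- nxt[order(H$canon[nxt])][1]
      add_event(p, "loss", h)              # lineage lost on the sibling edge
      h <- nxt
    }
    h
  }

  resolve <- function(p, h) {              # p enters exactly at h
    mapping[[sname(p)]] <<- H$name_of[h]
    if (p <= S$n_tip) return(invisible())
    k <- S$children[[p]]; p1 <- k[1]; p2 <- k[2]
    hk <- H$children[[h]]
    ## preference: cospeciation > duplication > switch
    if (length(hk) == 2) {
      for (ord in list(c(1, 2), c(2, 1))) {
        if (eq(ct$C[p, h], co + ct$IN[p1, hk[ord[1]]] + ct$IN[p2, hk[ord[2]]])) {
          add_event(p, "cospeciation", h)
          resolve(p1, resolve_in(p1, hk[ord[1]]))
          resolve(p2, resolve_in(p2, hk[ord[2]]))
          return(invisible())
        }
      }
    }
    if (eq(ct$C[p, h], du + ct$IN[p1, h] + ct$IN[p2, h])) {
      add_event(p, "duplication", h)
      resolve(p1, resolve_in(p1, h))
      resolve(p2, resolve_in(p2, h))
      return(invisible())
    }
    for (ord in list(c(p1, p2), c(p2, p1))) {
      stay <- ord[1]; move <- ord[2]
      if (eq(ct$C[p, h], sw + ct$IN[stay, h] + ct$OUT[move, h])) {
        inc <- which(!H$comparable[, h])
        tgt <- pick_min(inc, ct$C[move, inc])
        add_event(p, "switch", h, H$name_of[tgt])
        resolve(stay, resolve_in(stay, h))
        resolve(move, tgt)
        return(invisible())
      }
    }
    stop_hostspec("backtrace failed to reproduce the DP optimum",
                  "hostspec_internal_error")
  }

  start <- pick_min(seq_len(H$n_all), ct$C[S$root, ])
  resolve(S$root, start)

  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(symbiont = character(), event = character(),
                        host = character(), recipient = character())
  counts <- c(cospeciation = sum(ev$event == "cospeciation"),
              duplication = sum(ev$event == "duplication"),
              switch = sum(ev$event == "switch"),
              loss = sum(ev$event == "loss"))
  total <- sum(counts * c(co, du, sw, lo))
  if (!eq(total, ct$optimum))
    stop_hostspec("event census does not reproduce the optimal cost",
                  "hostspec_internal_error")
  structure(list(mapping = mapping, events = ev, counts = counts,
                 total_cost = total, n_optimal = count_optima(ct),
                 costs = ct$costs, tanglegram = tanglegram),
            class = "reconciliation")
}

#' Reconcile a tanglegram by event-based maximum parsimony
#'
#' Convenience wrapper: [mpr_cost()] then [backtrace()].
#'
#' @inheritParams backtrace
#' @return a `reconciliation`.
#' @export
reconcile <- function(tanglegram, costs = event_costs()) {
  backtrace(tanglegram, costs)
}

#' Event census of a reconciliation
#'
#' Counts per event type; losses are counted once per traversed host
#' edge. Codivergences, duplications and switches together always equal
#' the number of internal symbiont nodes.
#'
#' @param rec a `reconciliation`.
#' @return named integer vector (cospeciation, duplication, switch, loss).
#' @export
count_events <- function(rec) {
  stopifnot(inherits(rec, "reconciliation"))
  rec$counts
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf(
    "Reconciliation: cost %g (%d co-optimal solution(s))\n", x$total_cost,
    x$n_optimal))
  cat(sprintf("  cospeciation %d, duplication %d, switch %d, loss %d\n",
              x$counts[["cospeciation"]], x$counts[["duplication"]],
              x$counts[["switch"]], x$counts[["loss"]]))
  if (nrow(x$events)) print(x$events, row.names = FALSE)
  invisible(x)
}

## ---- exhaustive reference implementation ----------------------------------

#' Brute-force minimal reconciliation cost by exhaustive enumeration
#'
#' Enumerates every assignment of internal symbiont nodes to host nodes
#' and prices each directly from the event definitions (cospeciation into
#' distinct child subtrees, duplication at-or-below, switch to a
#' non-comparable host, losses per traversed edge). Exponential in the
#' symbiont tree size -- intended as an independent check of [mpr_cost()]
#' on trees with at most about six leaves, never for real analyses.
#'
#' @inheritParams mpr_cost
#' @return the minimal total cost (numeric scalar).
#' @export
mpr_brute_force <- function(tanglegram, costs = event_costs()) {
  if (!inherits(costs, "event_costs")) costs <- do.call(event_costs, as.list(costs))
  H <- tree_info(tanglegram$host_tree)
  S <- tree_info(tanglegram$symbiont_tree)
  co <- costs[["cospeciation"]]; du <- costs[["duplication"]]
  sw <- costs[["switch"]]; lo <- costs[["loss"]]
  phi_idx <- match(tanglegram$phi, tanglegram$host_tree$tip.label)
  names(phi_idx) <- names(tanglegram$phi)

  internal <- S$postorder[S$postorder > S$n_tip]
  if (!length(internal)) return(0)
  n_comb <- H$n_all^length(internal)
  if (n_comb > 5e6)
    stop_hostspec("tanglegram too large for exhaustive enumeration",
                  "hostspec_validation_error")
  grid <- as.matrix(expand.grid(rep(list(seq_len(H$n_all)), length(internal)),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- as.character(internal)

  node_map <- function(v) {
    if (v <= S$n_tip) rep(phi_idx[[S$tree$tip.label[v]]], nrow(grid))
    else grid[, as.character(v)]
  }
  Dm <- H$D; dep <- H$depth; cmp <- H$comparable
  at <- function(i, j) Dm[cbind(i, j)]       # i at-or-below j
  total <- rep(0, nrow(grid))
  for (p in internal) {
    h <- node_map(p)
    k <- S$children[[p]]
    h1 <- node_map(k[1]); h2 <- node_map(k[2])
    costp <- rep(Inf, nrow(grid))
    ## duplication
    ok <- at(h1, h) & at(h2, h)
    costp[ok] <- pmin(costp[ok],
                      du + lo * (dep[h1[ok]] - dep[h[ok]] +
                                 dep[h2[ok]] - dep[h[ok]]))
    ## cospeciation (both child orders)
    kidL <- vapply(H$children, function(x) if (length(x)) x[1] else NA_integer_,
                   integer(1))
    kidR <- vapply(H$children, function(x) if (length(x)) x[2] else NA_integer_,
                   integer(1))
    hl <- kidL[h]; hr <- kidR[h]
    intern <- !is.na(hl)
    for (ordering in list(c(1, 2), c(2, 1))) {
      a <- list(h1, h2)[[ordering[1]]]; b <- list(h1, h2)[[ordering[2]]]
      ok <- intern & !is.na(hl) & at(a, ifelse(is.na(hl), 1L, hl)) &
        at(b, ifelse(is.na(hr), 1L, hr)) & intern
      costp[ok] <- pmin(costp[ok],
                        co + lo * (dep[a[ok]] - dep[hl[ok]] +
                                   dep[b[ok]] - dep[hr[ok]]))
    }
    ## switch (either child jumps)
    for (ordering in list(c(1, 2), c(2, 1))) {
      stay <- list(h1, h2)[[ordering[1]]]; move <- list(h1, h2)[[ordering[2]]]
      ok <- at(stay, h) & !cmp[cbind(move, h)]
      costp[ok] <- pmin(costp[ok],
                        sw + lo * (dep[stay[ok]] - dep[h[ok]]))
    }
    total <- total + costp
  }
  min(total)
}
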