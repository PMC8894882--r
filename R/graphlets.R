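# Static and temporal bipartite graphlets: exhaustive catalogues for small
# sizes, and 2-edge delta-t-window counting over the diagnosis event stream.

# ---- static catalogue -------------------------------------------------------

# Canonical form of a parity-labelled bipartite edge set: minimum over all
# permutations of patients and of diseases of the sorted "p-d" pair strings.
canonical_static <- function(pe, de, n_p, n_d) {
  best <- NULL
  for (pp in perms(n_p)) {
    for (dp in perms(n_d)) {
      lab <- paste0("p", pp[pe], "-d", dp[de])
      key <- paste(sort(lab), collapse = "|")
      if (is.null(best) || key < best) best <- key
    }
  }
  best
}

perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in perms(n - 1L)) {
      tail <- seq_len(n)[-i][rest]
      out[[length(out) + 1L]] <- c(i, tail)
    }
  }
  out
}

# Automorphism orbits of an undirected graph on n nodes (parity ignored),
# by brute force over all node permutations.
node_orbits <- function(adj) {
  n <- nrow(adj)
  orbit <- seq_len(n)
  for (pp in perms(n)) {
    if (all(adj[pp, pp] == adj)) {
      for (v in seq_len(n)) {
        a <- min(orbit[v], orbit[pp[v]])
        orbit[orbit == orbit[v] | orbit == orbit[pp[v]]] <- a
      }
    }
  }
  match(orbit, sort(unique(orbit)))
}

connected_graph <- function(pe, de, n_p, n_d) {
  n <- n_p + n_d
  adj <- matrix(FALSE, n, n)
  for (e in seq_along(pe)) {
    adj[pe[e], n_p + de[e]] <- TRUE
    adj[n_p + de[e], pe[e]] <- TRUE
  }
  seen <- rep(FALSE, n); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  list(connected = all(seen), adj = adj)
}

#' Exhaustive catalogue of static bipartite graphlets
#'
#' All connected bipartite graphs with 2 to `max_nodes` nodes, up to
#' isomorphisms that preserve the patient/disease parity, together with their
#' automorphism orbit partitions (orbits are computed on topology alone,
#' ignoring parity). For `max_nodes = 4` there are exactly 7 classes: the
#' single edge; the patient-centred and disease-centred 3-node wedges; the two
#' 4-node stars, the 4-node path and the 4-cycle.
#'
#' @param max_nodes Largest graphlet size, in 2..4.
#' @return `data.frame` with columns `id`, `n_nodes`, `n_patients`,
#'   `n_diseases`, `n_edges`, `edges` (canonical edge list string),
#'   `orbits` (orbit labels per node, patients first), `n_orbits`.
#' @export
static_graphlets <- function(max_nodes = 4) {
  if (!max_nodes %in% 2:4) stop("max_nodes must be 2, 3 or 4")
  seen <- character(0)
  rows <- list()
  for (n in 2:max_nodes) {
    for (n_p in 1:(n - 1)) {
      n_d <- n - n_p
      cells <- expand.grid(p = seq_len(n_p), d = seq_len(n_d))
      n_cells <- nrow(cells)
      for (mask in 1:(2^n_cells - 1)) {
        sel <- which(bitwAnd(mask, 2^(seq_len(n_cells) - 1)) > 0)
        pe <- cells$p[sel]; de <- cells$d[sel]
        if (length(unique(pe)) < n_p || length(unique(de)) < n_d) next
        cg <- connected_graph(pe, de, n_p, n_d)
        if (!cg$connected) next
        key <- canonical_static(pe, de, n_p, n_d)
        if (key %in% seen) next
        seen <- c(seen, key)
        orb <- node_orbits(cg$adj)
        rows[[length(rows) + 1L]] <- data.frame(
          n_nodes = n, n_patients = n_p, n_diseases = n_d,
          n_edges = length(pe), edges = key,
          orbits = paste(orb, collapse = ","),
          n_orbits = length(unique(orb)), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$n_nodes, out$n_edges, out$edges), , drop = FALSE]
  out <- data.frame(id = paste0("G", seq_len(nrow(out)) - 1L), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# ---- temporal catalogue -----------------------------------------------------

# Canonical form of an ordered temporal edge sequence: relabel patients and
# diseases by order of first appearance (the unique parity-preserving
# relabelling consistent with the fixed edge order).
canonical_temporal <- function(pe, de) {
  pl <- match(pe, unique(pe))
  dl <- match(de, unique(de))
  paste(paste0("p", pl, "-d", dl), collapse = " < ")
}

#' Exhaustive catalogue of temporal bipartite graphlets
#'
#' All strictly time-ordered sequences of 1 to `max_edges` patient-disease
#' edges whose induced static graph is connected, up to parity-preserving
#' relabelling that fixes the edge order. Repeated appearances of the same
#' static edge are allowed (a repeat diagnosis is a distinct temporal edge).
#' Each class is linked to its induced static graphlet. For `m = 2` there are
#' exactly three classes: the repeated pair, the patient-centred wedge (one
#' patient, two diseases, in order) and the disease-centred wedge (one
#' disease, two patients).
#'
#' @param max_edges Largest number of temporal edges, in 1..3.
#' @return `data.frame` with columns `id`, `n_edges`, `n_nodes`, `sequence`
#'   (canonical ordered edge string), `static_edges` (canonical induced static
#'   form), `static_id` (id in [static_graphlets()]).
#' @export
temporal_graphlets <- function(max_edges = 3) {
  if (!max_edges %in% 1:3) stop("max_edges must be 1, 2 or 3")
  statics <- static_graphlets(4)
  seen <- character(0)
  rows <- list()
  for (m in 1:max_edges) {
    # enough node labels: at most m patients and m diseases
    cells <- expand.grid(p = seq_len(m), d = seq_len(m))
    idx <- rep(list(seq_len(nrow(cells))), m)
    grid <- do.call(expand.grid, idx)
    for (r in seq_len(nrow(grid))) {
      sel <- as.integer(grid[r, ])
      pe <- cells$p[sel]; de <- cells$d[sel]
      pl <- match(pe, unique(pe)); dl <- match(de, unique(de))
      key <- canonical_temporal(pe, de)
      if (key %in% seen) next
      if (any(pl != pe) || any(dl != de)) next  # not in canonical labelling
      n_p <- length(unique(pe)); n_d <- length(unique(de))
      cg <- connected_graph(pe, de, n_p, n_d)
      if (!cg$connected) next
      seen <- c(seen, key)
      ue <- !duplicated(paste(pe, de))
      skey <- canonical_static(pe[ue], de[ue], n_p, n_d)
      sid <- statics$id[match(skey, statics$edges)]
      rows[[length(rows) + 1L]] <- data.frame(
        n_edges = m, n_nodes = n_p + n_d, sequence = key,
        static_edges = skey, static_id = sid, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$n_edges, out$n_nodes, out$sequence), , drop = FALSE]
  out <- data.frame(id = paste0("T", seq_len(nrow(out))), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# ---- 2-edge counting --------------------------------------------------------

# Ordered within-group pair count: number of pairs (i, j) with
# t_i < t_j and t_j - t_i <= dt, t sorted ascending.
ordered_pairs_within <- function(t, dt) {
  if (length(t) < 2) return(0)
  hi <- findInterval(t, t, left.open = TRUE)        # strictly earlier events
  lo <- findInterval(t - dt, t, left.open = TRUE)   # events before the window
  sum(hi - lo)
}

scope_filter <- function(events, scope) {
  switch(scope,
         all = events,
         pre = events[events$years_to_smi < 0, , drop = FALSE],
         post = events[events$years_to_smi >= 0, , drop = FALSE])
}

graphlet_result <- function(d1, d2, d3, delta_t, scope) {
  counts <- c(D1 = as.numeric(d1), D2 = as.numeric(d2), D3 = as.numeric(d3))
  total <- sum(counts)
  structure(list(delta_t = delta_t, scope = toupper(scope), counts = counts,
                 fractions = if (total > 0) counts / total
                             else c(D1 = NA_real_, D2 = NA_real_,
                                    D3 = NA_real_),
                 total = total),
            class = "graphlet_counts")
}

#' Count 2-edge temporal graphlets in a diagnosis event stream
#'
#' Counts every ordered pair of events (e1, e2) with `t1 < t2` and
#' `t2 - t1 <= delta_t` (in years) sharing at least one node, classified as:
#' `D1` same (patient, disease) pair repeated; `D2` same patient, two
#' different diseases (progression-type wedge); `D3` same disease, two
#' different patients (selection-type wedge). Events with identical
#' timestamps never pair (the temporal order must be strict), so codes inside
#' one admission episode do not form pairs with each other. Scope `"pre"`
#' restricts to events strictly before the owning patient's first SMI date,
#' `"post"` to events on/after it; a pair straddling the boundary is counted
#' in neither restricted scope. The patients' index SMI events are part of the
#' stream and are counted.
#'
#' The implementation is a per-group sliding-window sweep (cost proportional
#' to events x window occupancy); [count_graphlets_bruteforce()] is the
#' explicit all-pairs oracle with the identical contract.
#'
#' @param events Event stream from [build_event_stream()], time-sorted.
#' @param delta_t Window length in years (>= 0); internally converted to days
#'   via 365.25.
#' @param scope `"all"`, `"pre"` or `"post"`.
#' @return Object of class `graphlet_counts`: `delta_t`, `scope`, `counts`
#'   (named D1/D2/D3), `fractions`, `total`.
#' @export
count_graphlets <- function(events, delta_t, scope = c("all", "pre", "post")) {
  scope <- match.arg(scope)
  if (delta_t < 0) stop("delta_t must be >= 0")
  ev <- scope_filter(events, scope)
  if (nrow(ev) == 0) return(graphlet_result(0, 0, 0, delta_t, scope))
  t <- as.numeric(ev$timestamp)
  if (is.unsorted(t)) stop("events must be sorted by timestamp")
  dt_days <- delta_t * 365.25
  sum_groups <- function(f) {
    s <- 0
    for (tt in split(t, f)) s <- s + ordered_pairs_within(sort(tt), dt_days)
    s
  }
  s_pair <- sum_groups(paste(ev$patient_id, ev$code3, sep = "\r"))
  s_pat <- sum_groups(ev$patient_id)
  s_dis <- sum_groups(ev$code3)
  graphlet_result(s_pair, s_pat - s_pair, s_dis - s_pair, delta_t, scope)
}

#' @rdname count_graphlets
#' @export
count_graphlets_bruteforce <- function(events, delta_t,
                                       scope = c("all", "pre", "post")) {
  scope <- match.arg(scope)
  if (delta_t < 0) stop("delta_t must be >= 0")
  ev <- scope_filter(events, scope)
  n <- nrow(ev)
  if (n == 0) return(graphlet_result(0, 0, 0, delta_t, scope))
  t <- as.numeric(ev$timestamp)
  dt_days <- delta_t * 365.25
  ti <- matrix(t, n, n)                 # ti[i, j] = t_i
  tj <- t(ti)                           # tj[i, j] = t_j
  in_window <- ti < tj & (tj - ti) <= dt_days
  same_p <- outer(ev$patient_id, ev$patient_id, "==")
  same_d <- outer(ev$code3, ev$code3, "==")
  d1 <- sum(in_window & same_p & same_d)
  d2 <- sum(in_window & same_p & !same_d)
  d3 <- sum(in_window & !same_p & same_d)
  graphlet_result(d1, d2, d3, delta_t, scope)
}

#' @export
print.graphlet_counts <- function(x, ...) {
  cat(sprintf("2-edge temporal graphlets (%s scope, delta_t = %g y): total %g\n",
              x$scope, x$delta_t, x$total))
  for (k in names(x$counts)) {
    cat(sprintf("  %s: %g (%.1f%%)\n", k, x$counts[[k]],
                100 * x$fractions[[k]]))
  }
  invisible(x)
}
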