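# Aggregated temporal bipartite patient-diagnosis networks.

#' Build an aggregated bipartite patient-diagnosis network
#'
#' One patient node per patient with at least one retained edge in the window,
#' one disease node per 3-character code with at least one edge; an undirected
#' edge links patient and disease, weighted by the number of diagnosis events
#' of that pair inside the window. Each patient's own index SMI code is
#' excluded everywhere, so a patient whose only diagnoses are their index code
#' has no node. Patient nodes carry gender, ethnicity, index code and age at
#' first SMI diagnosis; each edge carries the patient's age (whole years) at
#' the first diagnosis of that pair.
#'
#' @param events Event stream from [build_event_stream()].
#' @param patients Patient table.
#' @param window `NULL` (all events) or numeric `c(lo, hi)` in years-to-SMI.
#'   Windows are closed-left, open-right `[lo, hi)` unless `closed_right` is
#'   `TRUE` (used for the final sliding window so the span is partitioned
#'   without double counting).
#' @param closed_right Include events at exactly `hi`.
#' @param label Window label stored on the network (e.g. `"PRE"`).
#' @return Object of class `smi_bipartite`: list with `patients`, `diseases`,
#'   `edges` data frames and the `window` label.
#' @export
build_network <- function(events, patients, window = NULL,
                          closed_right = FALSE, label = NULL) {
  ev <- events
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] <= window[2])
    keep <- ev$years_to_smi >= window[1] &
      (if (closed_right) ev$years_to_smi <= window[2]
       else ev$years_to_smi < window[2])
    ev <- ev[keep, , drop = FALSE]
  }
  own_smi <- patients$first_smi_code[match(ev$patient_id, patients$patient_id)]
  ev <- ev[ev$code3 != own_smi, , drop = FALSE]
  if (nrow(ev) == 0) {
    net <- list(patients = data.frame(patient_id = character(0)),
                diseases = data.frame(code3 = character(0)),
                edges = data.frame(patient_id = character(0),
                                   code3 = character(0),
                                   weight = integer(0),
                                   age_first_dx = integer(0)),
                window = if (is.null(label)) window else label)
    class(net) <- "smi_bipartite"
    return(net)
  }
  key <- paste(ev$patient_id, ev$code3, sep = "\r")
  o <- order(key, ev$timestamp)
  ev <- ev[o, , drop = FALSE]
  key <- key[o]
  first <- !duplicated(key)
  edges <- data.frame(patient_id = ev$patient_id[first],
                      code3 = ev$code3[first],
                      weight = as.integer(table(key)[key[first]]),
                      stringsAsFactors = FALSE)
  pidx <- match(edges$patient_id, patients$patient_id)
  edges$age_first_dx <- floor(as.numeric(ev$timestamp[first] -
                                           patients$dob[pidx]) / 365.25)
  pid <- sort(unique(edges$patient_id))
  i <- match(pid, patients$patient_id)
  pat <- data.frame(
    patient_id = pid,
    gender = patients$gender[i], ethnicity = patients$ethnicity[i],
    first_smi_code = patients$first_smi_code[i],
    age_at_smi = as.numeric(patients$first_smi_date[i] - patients$dob[i]) /
      365.25,
    stringsAsFactors = FALSE)
  dcode <- sort(unique(edges$code3))
  dis <- data.frame(code3 = dcode, chapter = icd10_chapter(dcode),
                    stringsAsFactors = FALSE)
  net <- list(patients = pat, diseases = dis,
              edges = edges[order(edges$patient_id, edges$code3), ,
                            drop = FALSE],
              window = if (is.null(label)) window else label)
  rownames(net$edges) <- NULL
  class(net) <- "smi_bipartite"
  net
}

#' Pre- and post-SMI networks
#'
#' Splits the event stream at each patient's first SMI date (events dated
#' exactly on the index date count as post) and builds one aggregated network
#' per side.
#'
#' @inheritParams build_network
#' @return List with elements `pre` and `post`, both `smi_bipartite`.
#' @export
build_pre_post <- function(events, patients) {
  list(pre = build_network(events, patients, window = c(-Inf, 0),
                           label = "PRE"),
       post = build_network(events, patients, window = c(0, Inf),
                            closed_right = TRUE, label = "POST"))
}

#' Snapshot sequence of bipartite networks
#'
#' Sliding mode: fixed-length windows `[t, t + delta_t)` stepping by `step`
#' over the observed years-to-SMI span (final window closed so every event is
#' covered). Cumulative mode: windows `(-Inf, t]` with thresholds stepping
#' over the span, so node and edge sets grow monotonically.
#'
#' @inheritParams build_network
#' @param delta_t Window length in years (> 0).
#' @param step Step between window starts in years. Default 1.
#' @param mode `"sliding"` or `"cumulative"`.
#' @return Object of class `smi_snapshots`: list of `window` (c(lo, hi)),
#'   `midpoint`, `network` entries plus `mode`, `delta_t`, `step`.
#' @export
build_snapshots <- function(events, patients, delta_t = 5, step = 1,
                            mode = c("sliding", "cumulative")) {
  mode <- match.arg(mode)
  if (delta_t <= 0) stop("delta_t must be > 0")
  lo <- floor(min(events$years_to_smi))
  hi <- ceiling(max(events$years_to_smi))
  snaps <- list()
  if (mode == "sliding") {
    starts <- seq(lo, max(lo, hi - delta_t), by = step)
    for (s in starts) {
      last <- (s + delta_t >= hi)
      net <- build_network(events, patients, window = c(s, s + delta_t),
                           closed_right = last,
                           label = sprintf("[%g,%g]", s, s + delta_t))
      snaps[[length(snaps) + 1L]] <-
        list(window = c(s, s + delta_t), midpoint = s + delta_t / 2,
             network = net)
    }
  } else {
    thresholds <- seq(lo + step, hi, by = step)
    if (length(thresholds) == 0 || max(thresholds) < hi) {
      thresholds <- c(thresholds, hi)
    }
    for (tt in thresholds) {
      net <- build_network(events, patients, window = c(-Inf, tt),
                           closed_right = TRUE,
                           label = sprintf("(-Inf,%g]", tt))
      snaps[[length(snaps) + 1L]] <-
        list(window = c(-Inf, tt), midpoint = tt, network = net)
    }
  }
  structure(list(snapshots = snaps, mode = mode, delta_t = delta_t,
                 step = step), class = "smi_snapshots")
}

#' Convert a bipartite network to an igraph graph
#'
#' Vertices are patients then diseases, with logical attribute `type`
#' (`FALSE` = patient, `TRUE` = disease) and attribute `side`.
#'
#' @param net An `smi_bipartite`.
#' @return An igraph graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "smi_bipartite"))
  vnames <- c(net$patients$patient_id, net$diseases$code3)
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$patient_id, to = net$edges$code3,
               weight = net$edges$weight),
    directed = FALSE,
    vertices = data.frame(name = vnames,
                          type = c(rep(FALSE, nrow(net$patients)),
                                   rep(TRUE, nrow(net$diseases)))))
  g
}

#' Summary statistics of a bipartite network
#'
#' Node/edge counts, mean degrees overall and per side, density
#' (edges / (patients x diseases)), number of connected components and the
#' percentage of nodes in the giant component.
#'
#' @param object An `smi_bipartite`.
#' @param ... Unused.
#' @return A one-row `data.frame` of class `smi_bipartite_summary`.
#' @export
summary.smi_bipartite <- function(object, ...) {
  np <- nrow(object$patients); nd <- nrow(object$diseases)
  ne <- nrow(object$edges)
  if (ne == 0) {
    out <- data.frame(window = format_window(object$window), n_nodes = 0L,
                      n_patients = 0L, n_diseases = 0L, n_edges = 0L,
                      mean_degree = 0, mean_patient_degree = 0,
                      mean_disease_degree = 0, density = 0,
                      n_components = 0L, gcr = NA_real_)
    class(out) <- c("smi_bipartite_summary", "data.frame")
    return(out)
  }
  g <- as_igraph(object)
  comp <- igraph::components(g)
  out <- data.frame(
    window = format_window(object$window),
    n_nodes = np + nd, n_patients = np, n_diseases = nd, n_edges = ne,
    mean_degree = 2 * ne / (np + nd),
    mean_patient_degree = ne / np,
    mean_disease_degree = ne / nd,
    density = ne / (np * nd),
    n_components = comp$no,
    gcr = 100 * max(comp$csize) / (np + nd))
  class(out) <- c("smi_bipartite_summary", "data.frame")
  out
}

format_window <- function(w) {
  if (is.null(w)) "ALL" else if (is.character(w)) w
  else sprintf("[%g,%g]", w[1], w[2])
}

#' @export
print.smi_bipartite <- function(x, ...) {
  cat(sprintf(
    "Bipartite patient-diagnosis network [%s]: %d patients, %d diseases, %d edges\n",
    format_window(x$window), nrow(x$patients), nrow(x$diseases),
    nrow(x$edges)))
  invisible(x)
}

# patients x diseases sparse incidence matrix (0/1), dimnames attached.
incidence_matrix <- function(net, weighted = FALSE) {
  i <- match(net$edges$patient_id, net$patients$patient_id)
  j <- match(net$edges$code3, net$diseases$code3)
  Matrix::sparseMatrix(
    i = i, j = j,
    x = if (weighted) net$edges$weight else rep(1, nrow(net$edges)),
    dims = c(nrow(net$patients), nrow(net$diseases)),
    dimnames = list(net$patients$patient_id, net$diseases$code3))
}

#' One-mode projection of a bipartite network
#'
#' Two same-side nodes are linked iff they share at least one neighbour on the
#' other side; the edge weight is the number of shared neighbours.
#'
#' @param net An `smi_bipartite`.
#' @param side `"patients"` or `"diseases"`.
#' @return Object of class `smi_projection`: list with `nodes` (data frame of
#'   node attributes) and `edges` (`from`, `to`, `weight`).
#' @export
project <- function(net, side = c("patients", "diseases")) {
  side <- match.arg(side)
  if (nrow(net$edges) == 0) stop("cannot project an empty network")
  B <- incidence_matrix(net)
  M <- if (side == "patients") Matrix::tcrossprod(B)
       else Matrix::crossprod(B)
  M <- methods::as(Matrix::triu(M, k = 1), "TsparseMatrix")
  nodes <- if (side == "patients") net$patients else net$diseases
  edges <- data.frame(from = rownames(M)[M@i + 1L],
                      to = colnames(M)[M@j + 1L],
                      weight = M@x, stringsAsFactors = FALSE)
  edges <- edges[edges$weight > 0, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, side = side),
            class = "smi_projection")
}

#' Serialise a bipartite network to edge-list and node-attribute CSVs
#'
#' @param net An `smi_bipartite`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @export
write_network <- function(net, dir, prefix = "network") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  e <- net$edges
  e$window <- format_window(net$window)
  utils::write.csv(e, file.path(dir, paste0(prefix, "_edges.csv")),
                   row.names = FALSE)
  p <- net$patients; p$side <- "patient"
  d <- net$diseases; d$side <- "disease"
  names(p)[names(p) == "patient_id"] <- "node"
  names(d)[names(d) == "code3"] <- "node"
  nodes <- merge(p, d, all = TRUE, sort = FALSE)
  utils::write.csv(nodes, file.path(dir, paste0(prefix, "_nodes.csv")),
                   row.names = FALSE)
  invisible(dir)
}
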