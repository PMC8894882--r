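# Structural statistics: degree profiles, degree-degree mixing, second-order
# neighbourhoods, peer-attribute correlation, average efficiency, chapter
# lift, projection modularity.

# Tie-corrected Kendall tau (tau-b); NA when either variable is constant or
# fewer than two observations.
kendall_tau <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y, method = "kendall")
}

node_degrees <- function(net) {
  kp <- table(factor(net$edges$patient_id,
                     levels = net$patients$patient_id))
  kd <- table(factor(net$edges$code3, levels = net$diseases$code3))
  list(patients = as.integer(kp), diseases = as.integer(kd))
}

#' Grouped mean degrees with 95% confidence intervals
#'
#' Mean unweighted degree per group, with normal-approximation 95% CIs
#' (`mean +/- 1.96 SE`). Grouping: `"side"` (patients vs diseases),
#' `"chapter"` (disease nodes by ICD-10 chapter), or `"age_band"` (patient
#' nodes by age at first SMI diagnosis).
#'
#' @param net An `smi_bipartite`.
#' @param group_by One of `"side"`, `"chapter"`, `"age_band"`.
#' @param age_breaks Breaks for age bands (left-closed). Default
#'   `c(0, 30, 45, 60, Inf)`.
#' @return `data.frame` with columns `group`, `n`, `mean_degree`, `ci_lo`,
#'   `ci_hi`, `degenerate` (single-member group flag).
#' @export
degree_profile <- function(net, group_by = c("side", "chapter", "age_band"),
                           age_breaks = c(0, 30, 45, 60, Inf)) {
  group_by <- match.arg(group_by)
  if (nrow(net$edges) == 0) stop("network is empty")
  deg <- node_degrees(net)
  if (group_by == "side") {
    vals <- c(deg$patients, deg$diseases)
    grp <- c(rep("patients", length(deg$patients)),
             rep("diseases", length(deg$diseases)))
  } else if (group_by == "chapter") {
    vals <- deg$diseases
    grp <- net$diseases$chapter
  } else {
    vals <- deg$patients
    grp <- as.character(cut(net$patients$age_at_smi, age_breaks,
                            right = FALSE))
  }
  agg <- split(vals, grp)
  out <- data.frame(
    group = names(agg),
    n = lengths(agg),
    mean_degree = vapply(agg, mean, numeric(1)),
    stringsAsFactors = FALSE)
  se <- vapply(agg, function(v) {
    if (length(v) < 2) 0 else stats::sd(v) / sqrt(length(v))
  }, numeric(1))
  out$ci_lo <- out$mean_degree - 1.96 * se
  out$ci_hi <- out$mean_degree + 1.96 * se
  out$degenerate <- out$n < 2
  rownames(out) <- NULL
  out
}

#' Degree-degree mixing profile
#'
#' For every node on the chosen side, the mean unweighted degree of its direct
#' neighbours `knn`, the per-degree average `<knn>(k)`, and the tie-corrected
#' Kendall tau between a node's degree and its `knn` (negative tau =
#' disassortative mixing).
#'
#' @param net An `smi_bipartite`.
#' @param side `"patients"` or `"diseases"`.
#' @return List of class `smi_mixing`: `per_node` (`node`, `k`, `knn`),
#'   `per_degree` (`k`, `mean_knn`, `n`), `tau`, `side`.
#' @export
mixing_profile <- function(net, side = c("patients", "diseases")) {
  side <- match.arg(side)
  deg <- node_degrees(net)
  B <- incidence_matrix(net)
  if (side == "patients") {
    k <- deg$patients
    knn <- as.numeric(B %*% deg$diseases) / pmax(k, 1)
    nodes <- net$patients$patient_id
  } else {
    k <- deg$diseases
    knn <- as.numeric(Matrix::crossprod(B, deg$patients)) / pmax(k, 1)
    nodes <- net$diseases$code3
  }
  per_node <- data.frame(node = nodes, k = k, knn = knn,
                         stringsAsFactors = FALSE)
  per_node <- per_node[per_node$k > 0, , drop = FALSE]
  agg <- split(per_node$knn, per_node$k)
  per_degree <- data.frame(k = as.integer(names(agg)),
                           mean_knn = vapply(agg, mean, numeric(1)),
                           n = lengths(agg))
  rownames(per_degree) <- NULL
  structure(list(per_node = per_node, per_degree = per_degree,
                 tau = kendall_tau(per_node$k, per_node$knn), side = side),
            class = "smi_mixing")
}

#' Second-order neighbourhood of a node
#'
#' Nodes at graph distance exactly 2 from `node` (necessarily the same side in
#' a bipartite graph), excluding the node itself: the union of its neighbours'
#' neighbours minus `node`.
#'
#' @param net An `smi_bipartite`.
#' @param node A patient id or disease code present in the network.
#' @return Character vector of same-side node names.
#' @export
second_order <- function(net, node) {
  if (node %in% net$patients$patient_id) {
    nb <- net$edges$code3[net$edges$patient_id == node]
    nn <- net$edges$patient_id[net$edges$code3 %in% nb]
  } else if (node %in% net$diseases$code3) {
    nb <- net$edges$patient_id[net$edges$code3 == node]
    nn <- net$edges$code3[net$edges$patient_id %in% nb]
  } else {
    stop("node not in network: ", node)
  }
  sort(setdiff(unique(nn), node))
}

# Per-node second-order neighbourhood sizes for a whole side, via sparse
# boolean products.
second_order_sizes <- function(net, side) {
  B <- incidence_matrix(net)
  A <- if (side == "patients") Matrix::tcrossprod(B != 0)
       else Matrix::crossprod(B != 0)
  A <- A != 0
  Matrix::diag(A) <- FALSE
  as.integer(Matrix::rowSums(A))
}

#' Degree / second-order-size correlations
#'
#' Kendall tau between a node's degree `k` and its number of distinct
#' second-order neighbours `|N(N(v))|`, and between its mean neighbour degree
#' `knn` and `|N(N(v))|`. A high tau(k, |NN|) means conditions with many
#' comorbidities are simply prevalent conditions; a high tau(knn, |NN|) would
#' instead point at conditions concentrating in multimorbid patients.
#'
#' @param net An `smi_bipartite`.
#' @param side `"patients"` or `"diseases"`.
#' @return List: `per_node` (`node`, `k`, `knn`, `nn_size`), `tau_k_nn`,
#'   `tau_knn_nn`.
#' @export
second_order_correlations <- function(net, side = c("patients", "diseases")) {
  side <- match.arg(side)
  mp <- mixing_profile(net, side)
  if (nrow(mp$per_node) < 2) stop("need at least 2 nodes on side ", side)
  nn <- second_order_sizes(net, side)
  names(nn) <- if (side == "patients") net$patients$patient_id
               else net$diseases$code3
  per_node <- mp$per_node
  per_node$nn_size <- nn[per_node$node]
  list(per_node = per_node,
       tau_k_nn = kendall_tau(per_node$k, per_node$nn_size),
       tau_knn_nn = kendall_tau(per_node$knn, per_node$nn_size))
}

#' Peer-attribute correlation over second-order neighbourhoods
#'
#' For each patient, the mean of `attribute` over the patients at distance 2
#' (patients sharing at least one condition), and the Kendall tau between a
#' patient's own attribute and that peer mean. Patients with no second-order
#' peers are excluded from the correlation.
#'
#' @param net An `smi_bipartite`.
#' @param attribute Name of a numeric column of `net$patients`. Default
#'   `"age_at_smi"`.
#' @return List: `per_node` (`node`, `value`, `peer_mean`, `n_peers`), `tau`.
#' @export
peer_attribute <- function(net, attribute = "age_at_smi") {
  if (!attribute %in% names(net$patients)) {
    stop("attribute not defined on patient nodes: ", attribute)
  }
  val <- net$patients[[attribute]]
  if (!is.numeric(val)) stop("attribute must be numeric: ", attribute)
  B <- incidence_matrix(net) != 0
  A <- Matrix::tcrossprod(B)
  A <- A != 0
  Matrix::diag(A) <- FALSE
  n_peers <- as.integer(Matrix::rowSums(A))
  peer_sum <- as.numeric(A %*% val)
  peer_mean <- ifelse(n_peers > 0, peer_sum / n_peers, NA_real_)
  per_node <- data.frame(node = net$patients$patient_id, value = val,
                         peer_mean = peer_mean, n_peers = n_peers,
                         stringsAsFactors = FALSE)
  keep <- per_node$n_peers > 0
  list(per_node = per_node,
       tau = kendall_tau(per_node$value[keep], per_node$peer_mean[keep]))
}

#' Average efficiency of a bipartite network
#'
#' `E = 1/(|S|(|S|-1)) * sum_{i != j in S} 1/d_ij`, where distances are
#' unweighted shortest paths on the full bipartite graph and unreachable pairs
#' contribute 0. `node_subset` restricts the pair set S (to patient nodes or
#' disease nodes) while distances are still measured through the whole graph.
#'
#' @param net An `smi_bipartite`.
#' @param node_subset `"all"`, `"patients"` or `"diseases"`.
#' @return List of class `smi_efficiency`: `value`, `node_subset`, `n`,
#'   `window`.
#' @export
efficiency <- function(net, node_subset = c("all", "patients", "diseases")) {
  node_subset <- match.arg(node_subset)
  g <- as_igraph(net)
  vs <- switch(node_subset,
               all = igraph::V(g)$name,
               patients = net$patients$patient_id,
               diseases = net$diseases$code3)
  n <- length(vs)
  if (n < 2) stop("node subset must contain at least 2 nodes")
  d <- igraph::distances(g, v = vs, to = vs, weights = NA)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  structure(list(value = sum(inv) / (n * (n - 1)), node_subset = node_subset,
                 n = n, window = format_window(net$window)),
            class = "smi_efficiency")
}

#' Observed/expected chapter lift between pre- and post-SMI diagnoses
#'
#' Cell (A, B) is `P(A, B) / (P(A) P(B))` where `P(A)` is the fraction of
#' patients with at least one pre-SMI diagnosis in chapter A, `P(B)` the
#' fraction with at least one post-SMI diagnosis in chapter B, and `P(A, B)`
#' the fraction with both. Lift > 1 means the pre/post chapter association is
#' stronger than expected under independence. Cells with a zero marginal are
#' `NA`.
#'
#' @param splits Output of [condition_splits()].
#' @return List of class `smi_chapter_lift`: `lift` matrix (pre chapters x
#'   post chapters), `support` joint count matrix, `n_patients`.
#' @export
chapter_lift <- function(splits) {
  n <- nrow(splits)
  if (n < 1) stop("need at least one patient")
  pre_ch <- lapply(splits$pre_existing,
                   function(s) unique(icd10_chapter(s)))
  post_ch <- lapply(splits$post_set,
                    function(s) unique(icd10_chapter(s)))
  chapters <- sort(unique(c(unlist(pre_ch), unlist(post_ch))))
  if (length(chapters) == 0) stop("no retained conditions in any patient")
  pre_m <- vapply(chapters, function(ch)
    vapply(pre_ch, function(s) ch %in% s, logical(1)), logical(n))
  post_m <- vapply(chapters, function(ch)
    vapply(post_ch, function(s) ch %in% s, logical(1)), logical(n))
  pre_m <- matrix(pre_m, nrow = n); post_m <- matrix(post_m, nrow = n)
  pA <- colMeans(pre_m); pB <- colMeans(post_m)
  joint <- crossprod(pre_m, post_m)          # counts of patients with both
  lift <- (joint / n) / outer(pA, pB)
  lift[outer(pA, pB) == 0] <- NA_real_
  dimnames(lift) <- dimnames(joint) <- list(pre = chapters, post = chapters)
  structure(list(lift = lift, support = joint, n_patients = n),
            class = "smi_chapter_lift")
}

#' Newman modularity of a one-mode projection under an attribute partition
#'
#' Standard weighted modularity `Q = sum_c (e_cc - a_c^2)` of an
#' `smi_projection`, with communities given by a node attribute or an explicit
#' named membership vector.
#'
#' @param proj An [project()] result.
#' @param partition Either the name of a column of `proj$nodes` or a named
#'   vector mapping every node to a community label.
#' @return Modularity `Q`.
#' @export
graph_modularity <- function(proj, partition) {
  stopifnot(inherits(proj, "smi_projection"))
  node_ids <- if (proj$side == "patients") proj$nodes$patient_id
              else proj$nodes$code3
  if (is.character(partition) && length(partition) == 1 &&
      partition %in% names(proj$nodes)) {
    member <- proj$nodes[[partition]]
    names(member) <- node_ids
  } else {
    member <- partition
  }
  miss <- setdiff(node_ids, names(member))
  if (length(miss)) {
    stop("partition does not cover node(s): ", paste(miss, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(
    proj$edges, directed = FALSE,
    vertices = data.frame(name = node_ids))
  igraph::modularity(g, as.integer(factor(member[node_ids])),
                     weights = proj$edges$weight)
}
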