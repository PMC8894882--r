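# Degree-preserving null model for bipartite networks and z-score
# significance testing of scalar network statistics.

#' Degree-preserving rewiring of a bipartite network
#'
#' Repeatedly applies accepted double-edge swaps: edges A-X and B-Y become A-Y
#' and B-X. A proposal is rejected (and retried) when it would duplicate an
#' existing edge or involves a shared endpoint, so both unweighted degree
#' sequences are conserved exactly and the graph stays simple and bipartite.
#' Edge weights are reset to 1 (the null ensemble is unweighted), so only
#' weight-free statistics are meaningful on rewired networks. If no valid swap
#' can be found (e.g. a complete bipartite graph) the input connections are
#' returned unchanged with a warning.
#'
#' @param net An `smi_bipartite` with at least 2 edges.
#' @param n_swaps Number of accepted swaps; default `10 * n_edges`.
#' @param max_tries Proposal budget before giving up; default
#'   `200 * n_swaps`.
#' @return A rewired `smi_bipartite` (same nodes and attributes, weights 1).
#' @export
rewire_bipartite <- function(net, n_swaps = 10 * nrow(net$edges),
                             max_tries = 200 * n_swaps) {
  m <- nrow(net$edges)
  if (m < 2) stop("network must have at least 2 edges")
  pi <- match(net$edges$patient_id, net$patients$patient_id)
  di <- match(net$edges$code3, net$diseases$code3)
  res <- rewire_edges_cpp(pi, di, n_swaps, max_tries)
  if (res$accepted < n_swaps) {
    warning(sprintf("rewiring saturated: %d of %d swaps accepted",
                    as.integer(res$accepted), as.integer(n_swaps)))
  }
  out <- net
  out$edges <- data.frame(patient_id = net$patients$patient_id[res$patient],
                          code3 = net$diseases$code3[res$disease],
                          weight = 1L,
                          age_first_dx = NA_integer_,
                          stringsAsFactors = FALSE)
  out$edges <- out$edges[order(out$edges$patient_id, out$edges$code3), ,
                         drop = FALSE]
  rownames(out$edges) <- NULL
  out
}

#' z-score and two-tailed p-value of an observed statistic against a null
#'
#' `z = (phi_o - mean(phi_r)) / sd(phi_r)`; `p = 2 * pnorm(-|z|)`. Returns
#' `NA` z/p when the null standard deviation is zero (the statistic is
#' conserved by the null).
#'
#' @param phi_o Observed value.
#' @param null_mean,null_sd Null-ensemble mean and standard deviation.
#' @return List with `z` and `p`.
#' @export
z_significance <- function(phi_o, null_mean, null_sd) {
  if (!is.finite(null_sd) || null_sd == 0) {
    return(list(z = NA_real_, p = NA_real_))
  }
  z <- (phi_o - null_mean) / null_sd
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Null-model significance test of a network statistic
#'
#' Evaluates `statistic` on the observed network and on `n_replicates`
#' independently rewired copies, and reports the null mean/SD, the z-score and
#' the two-tailed normal p-value (plus the empirical percentile of the
#' observed value in the null sample, as a diagnostic).
#'
#' @param net An `smi_bipartite`.
#' @param statistic Function `smi_bipartite -> numeric(1)`; must be
#'   weight-free (rewired networks have unit weights).
#' @param n_replicates Number of null replicates. Default 1000.
#' @param n_swaps Accepted swaps per replicate. Default `10 * n_edges`.
#' @param seed Integer seed for the replicate stream.
#' @param name Statistic name carried in the result.
#' @return Object of class `null_test_result`: `statistic`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `p_two_tailed`, `empirical_percentile`,
#'   `n_replicates`, `seed`, `null_values`.
#' @export
null_test <- function(net, statistic, n_replicates = 1000,
                      n_swaps = 10 * nrow(net$edges), seed = 1L,
                      name = deparse(substitute(statistic))) {
  set.seed(seed)
  phi_o <- statistic(net)
  vals <- vapply(seq_len(n_replicates), function(i) {
    statistic(rewire_bipartite(net, n_swaps))
  }, numeric(1))
  mu <- mean(vals); sdev <- stats::sd(vals)
  zp <- z_significance(phi_o, mu, sdev)
  structure(list(statistic = name, observed = phi_o, null_mean = mu,
                 null_sd = sdev, z = zp$z, p_two_tailed = zp$p,
                 empirical_percentile = mean(vals < phi_o) +
                   0.5 * mean(vals == phi_o),
                 n_replicates = n_replicates, seed = seed,
                 null_values = vals),
            class = "null_test_result")
}

#' @export
print.null_test_result <- function(x, ...) {
  cat(sprintf(
    "Null test of %s: observed %.4g, null %.4g +/- %.4g (n=%d)\n",
    x$statistic, x$observed, x$null_mean, x$null_sd, x$n_replicates))
  if (is.na(x$z)) {
    cat("  z undefined (null SD is zero: statistic conserved by the null)\n")
  } else {
    cat(sprintf("  z = %.3f, two-tailed p = %.3g\n", x$z, x$p_two_tailed))
  }
  invisible(x)
}
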