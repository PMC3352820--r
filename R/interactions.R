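#' Spent-medium interaction effect of one species on another
#'
#' The interaction effect is the recipient's mean maximum growth rate on
#' medium previously used by the donor minus its mean maximum growth rate
#' on unused medium (doublings/day); `relative` is the corresponding ratio
#' of means. Significance comes from a two-sided permutation test on the
#' difference of means and the uncertainty of `relative` from a percentile
#' bootstrap over replicates. The edge is classed `negative`/`positive`
#' when `p < alpha` with the matching sign, `neutral` otherwise.
#'
#' @param used,unused Numeric vectors of the recipient's V_MAX replicates
#'   on used and unused medium (>= 2 each).
#' @param donor,recipient,treatment Edge metadata; donor and recipient
#'   assays must come from the same treatment.
#' @param alpha Significance level (default 0.05, two-sided).
#' @param B Permutations for the p-value.
#' @param n_boot Bootstrap resamples for the CI of `relative`.
#' @param seed Integer seed (drives both permutations and bootstrap).
#' @return One-row tibble of class `interaction_edge` columns: `donor`,
#'   `recipient`, `treatment`, `effect`, `relative`, `ci_lo`, `ci_hi`,
#'   `p`, `sign`.
#' @export
interaction_effect <- function(used, unused, donor = "donor",
                               recipient = "recipient",
                               treatment = "ancestral", alpha = 0.05,
                               B = 1000, n_boot = 1000, seed = NULL) {
  assert_that(length(used) >= 2 && length(unused) >= 2,
              "need >= 2 replicates per side")
  effect <- mean(used) - mean(unused)
  pt <- perm_diff_test(used, unused, B = B,
                       seed = if (is.null(seed)) NULL else child_seed(seed, "perm"))
  relative <- if (mean(unused) > 0) mean(used) / mean(unused) else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (!is.na(relative)) {
    if (!is.null(seed)) set.seed(child_seed(seed, "boot"))
    ratios <- vapply(seq_len(n_boot), function(b) {
      u <- used[sample.int(length(used), replace = TRUE)]
      v <- unused[sample.int(length(unused), replace = TRUE)]
      if (mean(v) > 0) mean(u) / mean(v) else NA_real_
    }, numeric(1))
    ci <- unname(quantile(ratios, c(0.025, 0.975), na.rm = TRUE))
  }
  sign_class <- if (pt$p < alpha && effect < 0) "negative"
  else if (pt$p < alpha && effect > 0) "positive"
  else "neutral"
  out <- tibble::tibble(donor = donor, recipient = recipient,
                        treatment = treatment, effect = effect,
                        relative = relative, ci_lo = ci[1], ci_hi = ci[2],
                        p = pt$p, sign = sign_class)
  class(out) <- c("interaction_edge", class(out))
  out
}

#' Assemble interaction edges into a directed network
#'
#' One node per species; each edge carries the growth effect (arrow
#' width), sign class (colour class) and a dashed flag marking neutral
#' (non-significant) edges.
#'
#' @param edges Tibble of [interaction_effect()] rows sharing one
#'   treatment; duplicate (donor, recipient) pairs are rejected.
#' @return An [igraph::graph] with edge attributes `effect`, `sign`,
#'   `dashed`, `p` and graph attribute `treatment`.
#' @export
build_network <- function(edges) {
  need <- c("donor", "recipient", "effect", "sign")
  assert_that(all(need %in% names(edges)),
              paste("missing columns:",
                    paste(setdiff(need, names(edges)), collapse = ", ")))
  if ("treatment" %in% names(edges)) {
    assert_that(length(unique(edges$treatment)) <= 1,
                "edges must share a single treatment")
  }
  dup <- edges |>
    dplyr::count(.data$donor, .data$recipient) |>
    dplyr::filter(.data$n > 1)
  assert_that(nrow(dup) == 0,
              paste("duplicate donor->recipient pairs:",
                    paste(dup$donor, dup$recipient, collapse = "; ")))
  species <- sort(unique(c(edges$donor, edges$recipient)))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$donor, to = edges$recipient,
                   effect = edges$effect, sign = edges$sign,
                   dashed = as.integer(edges$sign == "neutral"),
                   p = if ("p" %in% names(edges)) edges$p else NA_real_),
    directed = TRUE, vertices = species)
  if ("treatment" %in% names(edges) && nrow(edges) > 0) {
    g <- igraph::set_graph_attr(g, "treatment", edges$treatment[1])
  }
  g
}

#' Write an interaction network to CSV, DOT or GraphML
#'
#' The CSV edge list round-trips exactly; DOT and GraphML carry the sign
#' and effect attributes for downstream rendering.
#'
#' @param network An [build_network()] graph.
#' @param path Output file path.
#' @param format One of `"csv"`, `"dot"`, `"graphml"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path, format = c("csv", "dot", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- igraph::as_data_frame(network, what = "edges")
    readr::write_csv(tibble::as_tibble(df), path)
  } else {
    igraph::write_graph(network, path,
                        format = if (format == "dot") "dot" else "graphml")
  }
  invisible(path)
}

#' Read an interaction-network edge list written by [write_network()]
#'
#' @param path CSV path.
#' @return Tibble of edges (`from`, `to`, `effect`, `sign`, `dashed`, `p`).
#' @export
read_network_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' All pairwise interaction edges within one treatment
#'
#' Convenience wrapper running [interaction_effect()] for every ordered
#' (donor, recipient) pair found in a V_MAX table containing `unused` and
#' `used:<donor>` substrates.
#'
#' @param vmax_rows [vmax_table()] rows for one treatment.
#' @param alpha,B,seed Passed to [interaction_effect()].
#' @return Tibble of interaction edges.
#' @export
interaction_edges <- function(vmax_rows, alpha = 0.05, B = 1000, seed = NULL) {
  tr <- unique(vmax_rows$treatment)
  assert_that(length(tr) == 1, "vmax_rows must come from a single treatment")
  species <- sort(unique(vmax_rows$species))
  out <- list()
  for (rec in species) {
    unused <- vmax_rows$vmax[vmax_rows$species == rec &
                               vmax_rows$substrate == "unused"]
    for (don in setdiff(species, rec)) {
      used <- vmax_rows$vmax[vmax_rows$species == rec &
                               vmax_rows$substrate == paste0("used:", don)]
      if (length(used) < 2 || length(unused) < 2) next
      out[[length(out) + 1]] <- interaction_effect(
        used, unused, donor = don, recipient = rec, treatment = tr,
        alpha = alpha, B = B,
        seed = if (is.null(seed)) NULL else child_seed(seed, tr, don, rec))
    }
  }
  dplyr::bind_rows(out)
}
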