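# ---------------------------------------------------------------------------
# In-silico mutations, the mutation scan, Monte-Carlo robustness to
# activation noise, and per-rule Boolean sensitivity.
# ---------------------------------------------------------------------------

#' Apply a gain- or loss-of-function mutation
#'
#' A mutation clamps one node's update rule to a constant for the whole
#' analysis: `loss` clamps to 0, `gain` to 1.  Mutating an input node fixes
#' that micro-environment bit in every swept environment.
#'
#' @param net A `boolean_network`.
#' @param node Node name.
#' @param kind `"loss"` or `"gain"`.
#' @return The mutated `boolean_network`, with the mutation recorded in
#'   `attr(, "mutation")`.
#' @examples
#' net <- boolean_network(list(A = "B", B = "A"))
#' apply_mutation(net, "A", "loss")
#' @export
apply_mutation <- function(net, node, kind = c("loss", "gain")) {
  kind <- match.arg(kind)
  if (!node %in% net$nodes) abort(sprintf("unknown node '%s'", node))
  rules <- net$rules
  rules[[node]] <- bx_const(if (kind == "loss") 0L else 1L)
  out <- boolean_network(rules, inputs = setdiff(net$inputs, node))
  attr(out, "mutation") <- stats::setNames(if (kind == "loss") 0L else 1L, node)
  out
}

#' Scan single gain- and loss-of-function mutations
#'
#' Runs a full micro-environment sweep under every requested clamp and
#' classifies each mutation against the wild-type sweep: `no_effect`
#' (identical per-environment behavior labels), `behavior_lost` (some
#' behavior signature appears in no attractor of any environment), or
#' `response_changed` (anything else).  With the default `mutations = NULL`
#' all `2 * n` single mutations are scanned; for the bundled 64-node model
#' that is 128 sweeps and several CPU-hours, so targeted scans pass a subset.
#'
#' @param net A `boolean_network` with declared inputs.
#' @param mutations A data frame with columns `node` and `kind`
#'   (loss/gain), or `NULL` for all single mutations.
#' @param wild_type Optional pre-computed wild-type `ec_sweep` (recomputed
#'   when missing).
#' @param progress Print one line per mutation.
#' @return An `ec_mutation_scan` tibble: one row per mutation with `node`,
#'   `kind`, per-label environment counts, behavior-existence flags, and
#'   `effect` classification; the wild-type sweep is kept in
#'   `attr(, "wild_type")`.
#' @export
mutation_scan <- function(net, mutations = NULL, wild_type = NULL,
                          progress = FALSE) {
  if (is.null(mutations)) {
    mutations <- tidyr::expand_grid(node = net$nodes, kind = c("loss", "gain"))
  }
  mutations <- as_tibble(mutations)
  if (!all(c("node", "kind") %in% names(mutations))) {
    abort("mutations must have columns 'node' and 'kind'")
  }
  bad <- setdiff(mutations$node, net$nodes)
  if (length(bad) > 0) abort(sprintf("unknown node '%s'", bad[1]))
  if (is.null(wild_type)) wild_type <- sweep_environments(net)
  rows <- purrr::pmap(mutations, function(node, kind) {
    clamp <- stats::setNames(if (kind == "loss") 0L else 1L, node)
    sw <- sweep_environments(net, mutations = clamp)
    if (progress) {
      message(sprintf("%s %s: %s", node, kind,
                      paste(levels(sw$behavior),
                            tabulate(sw$behavior, 4), collapse = " ")))
    }
    tab <- table(sw$behavior)
    tibble(
      node = node, kind = kind,
      phalanx = as.integer(tab[["Phalanx"]]),
      stalk = as.integer(tab[["Stalk"]]),
      tip = as.integer(tab[["Tip"]]),
      atypical = as.integer(tab[["Atypical"]]),
      tip_exists = any(sw$has_tip),
      stalk_exists = any(sw$has_stalk),
      phalanx_exists = any(sw$has_phalanx),
      same_as_wild_type = identical(as.integer(sw$behavior),
                                    as.integer(wild_type$behavior)))
  })
  out <- dplyr::bind_rows(rows)
  out$effect <- ifelse(out$same_as_wild_type, "no_effect",
                ifelse(!(out$tip_exists & out$stalk_exists & out$phalanx_exists),
                       "behavior_lost", "response_changed"))
  class(out) <- c("ec_mutation_scan", class(out))
  attr(out, "wild_type") <- wild_type
  out
}

#' Summarize a mutation scan
#' @param x An `ec_mutation_scan`.
#' @param ... Unused.
#' @return One-row tibble: counts of the three effect classes and of
#'   mutations losing each behavior.
#' @export
glance.ec_mutation_scan <- function(x, ...) {
  tibble(
    n_mutations = nrow(x),
    no_effect = sum(x$effect == "no_effect"),
    response_changed = sum(x$effect == "response_changed"),
    behavior_lost = sum(x$effect == "behavior_lost"),
    tip_lost = sum(!x$tip_exists),
    stalk_lost = sum(!x$stalk_exists),
    phalanx_lost = sum(!x$phalanx_exists))
}

#' Flip one uniformly chosen variable of a state
#'
#' Hamming-distance-1 perturbation used by the robustness experiments; every
#' variable, inputs included, is equally likely to be flipped.
#'
#' @param state Named 0/1 state vector.
#' @return The perturbed state.
#' @export
perturb_state <- function(state) {
  i <- sample.int(length(state), 1L)
  state[i] <- 1L - state[i]
  state
}

#' Robustness of attractor determination to activation noise
#'
#' Samples `n` uniform random full-network states; for each, a copy at
#' Hamming distance one (one uniformly chosen variable flipped, inputs
#' included) is created and both states are iterated to their attractors.
#' `mode = "attractor"` reports the fraction of pairs reaching the identical
#' attractor (canonical state-set equality); `mode = "behavior"` the
#' fraction reaching attractors with the same behavior label.  Per-behavior
#' fractions condition on the unperturbed trajectory's label ("relevant
#' experiments").
#'
#' @param net A `boolean_network` (<= 64 nodes) containing the behavior
#'   marker nodes.
#' @param mode `"behavior"` or `"attractor"`.
#' @param n Number of replicates.
#' @param seed Integer seed for the deterministic counter-based generator;
#'   identical `(n, seed)` reproduce identical results bit for bit.
#' @param cache_log2 log2 size of the trajectory cache (memory/speed knob;
#'   does not affect results).
#' @return An `ec_robustness` list: `mode`, `n`, `seed`, `fraction_same`,
#'   and a tibble `per_behavior` with denominators.
#' @export
robustness_experiment <- function(net, mode = c("behavior", "attractor"),
                                  n = 1e6, seed = 1L, cache_log2 = 24L) {
  mode <- match.arg(mode)
  markers <- ec_marker_nodes()
  missing <- setdiff(markers, net$nodes)
  if (length(missing) > 0) abort(sprintf("network lacks marker node '%s'", missing[1]))
  if (n < 1) abort("n must be at least 1")
  r <- .cpp_robustness(compile_program(net), length(net$nodes),
                       match(markers, net$nodes) - 1L,
                       n, as.double(seed), as.double(cache_log2))
  same <- if (mode == "behavior") r$same_behavior else r$same_attractor
  per <- tibble(
    behavior = c("Tip", "Stalk", "Phalanx"),
    n_relevant = c(r$denom_tip, r$denom_stalk, r$denom_phalanx),
    n_same_behavior = c(r$match_tip, r$match_stalk, r$match_phalanx))
  per$fraction_same <- ifelse(per$n_relevant > 0,
                              per$n_same_behavior / per$n_relevant, NA_real_)
  structure(
    list(mode = mode, n = n, seed = seed,
         fraction_same = same / r$n,
         per_behavior = per,
         n_attractors_seen = r$n_attractors_seen),
    class = "ec_robustness")
}

#' @export
print.ec_robustness <- function(x, ...) {
  cat(sprintf("Robustness to single-bit activation noise (%s mode)\n", x$mode))
  cat(sprintf("  n = %g, seed = %d: %.4f%% of pairs unchanged\n",
              x$n, x$seed, 100 * x$fraction_same))
  if (x$mode == "behavior") {
    for (i in seq_len(nrow(x$per_behavior))) {
      cat(sprintf("  %-8s %.4f%% of %g relevant experiments\n",
                  x$per_behavior$behavior[i],
                  100 * x$per_behavior$fraction_same[i],
                  x$per_behavior$n_relevant[i]))
    }
  }
  invisible(x)
}

#' @export
glance.ec_robustness <- function(x, ...) {
  tibble(mode = x$mode, n = x$n, seed = x$seed,
         fraction_same = x$fraction_same,
         tip = x$per_behavior$fraction_same[1],
         stalk = x$per_behavior$fraction_same[2],
         phalanx = x$per_behavior$fraction_same[3])
}

#' Per-rule sensitivity to activation noise
#'
#' For every update rule `f_i`, estimates the probability that its output
#' differs between a uniform random state and a copy with one uniformly
#' chosen variable (of all `n`) flipped, from `n_samples` Monte-Carlo pairs
#' per rule.  The analytic value — the rule's summed Boolean influence over
#' its regulators divided by `n` — is computed exactly alongside whenever
#' the rule's support has at most `analytic_cap` variables.
#'
#' @param net A `boolean_network` (<= 64 nodes).
#' @param n_samples Monte-Carlo pairs per rule.
#' @param seed Integer seed (deterministic counter-based streams, one per
#'   rule).
#' @param analytic_cap Largest support size for which the exact influence
#'   sum is enumerated.
#' @return An `ec_sensitivity` tibble: `node`, `estimate`, `analytic`, `n`,
#'   `seed`.
#' @export
rule_sensitivity <- function(net, n_samples = 5e5, seed = 1L,
                             analytic_cap = 20L) {
  r <- .cpp_sensitivity(compile_program(net), length(net$nodes),
                        n_samples, as.double(seed), as.integer(analytic_cap))
  out <- tibble(
    node = net$nodes,
    estimate = r$estimate,
    analytic = r$analytic,
    n = n_samples,
    seed = as.integer(seed))
  class(out) <- c("ec_sensitivity", class(out))
  out
}

#' @export
glance.ec_sensitivity <- function(x, ...) {
  tibble(
    n_rules = nrow(x),
    mean_sensitivity = mean(x$estimate),
    min_sensitivity = min(x$estimate),
    max_sensitivity = max(x$estimate),
    most_sensitive = x$node[which.max(x$estimate)],
    least_sensitive = x$node[which.min(x$estimate)])
}

#' Plot per-rule sensitivities
#'
#' @param object An `ec_sensitivity`.
#' @param ... Unused.
#' @return A ggplot of rules ordered by estimated sensitivity, with the mean
#'   as a reference line.
#' @importFrom ggplot2 geom_point geom_hline theme element_text
#' @export
autoplot.ec_sensitivity <- function(object, ...) {
  df <- dplyr::arrange(object, .data$estimate)
  df$node <- factor(df$node, levels = df$node)
  ggplot(df, aes(x = .data$node, y = .data$estimate)) +
    geom_point() +
    geom_hline(yintercept = mean(df$estimate), colour = "red") +
    labs(x = NULL, y = "update-rule sensitivity") +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1,
                                     size = 6))
}
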