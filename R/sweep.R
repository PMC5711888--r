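# ---------------------------------------------------------------------------
# Exhaustive micro-environment sweep.
# ---------------------------------------------------------------------------

#' Sweep all micro-environments and classify the induced behavior
#'
#' For each of the `2^k` assignments of the network's `k` input nodes the
#' exact attractor set of the clamped network is computed, every attractor is
#' labeled by the behavior signatures, and the environment receives the
#' shared label when all its attractors agree on one of Tip/Stalk/Phalanx,
#' or `Atypical` otherwise (mixed labels, or any attractor whose states do
#' not match a signature).  Proliferation is rolled up the same way: an
#' environment is classed `all`, `some` or `none` by the share of its
#' attractors in which beta-catenin and LEF1 are jointly active in every
#' state.
#'
#' Enumeration is exact for every environment: inputs are clamped, constants
#' propagated, and the free core solved by explicit successor tabulation
#' (small cores) or the BDD eventual-image backend (large cores); identical
#' clamped cores are shared across environments.  The full sweep of the
#' bundled model visits all 65,536 environments in a few minutes of CPU time.
#'
#' @param net A `boolean_network` with declared inputs (at most 30).
#' @param mutations Optional named 0/1 vector: nodes clamped to a constant
#'   for the whole sweep (gain = 1, loss = 0).  Clamped input nodes override
#'   the environment bit (the sweep still reports all `2^k` codes).
#' @param brute_cap,bdd_node_budget Backend tuning, see
#'   [enumerate_attractors_env()].
#' @return An `ec_sweep` tibble with one row per environment: `env`
#'   (code), one 0/1 column per input, `behavior`, `n_attractors`,
#'   `proliferation`, and logical `has_tip`/`has_stalk`/`has_phalanx`
#'   (whether any attractor of the environment carries the signature).
#' @examples
#' \donttest{
#' sw <- sweep_environments(angiogenesis_network())
#' glance(sw)
#' }
#' @export
sweep_environments <- function(net, mutations = NULL, brute_cap = 22L,
                               bdd_node_budget = 6e7) {
  k <- length(net$inputs)
  if (k == 0) abort("network has no declared inputs to sweep")
  if (k > 30) abort("too many inputs for an exhaustive sweep")
  n <- length(net$nodes)
  if (n > 64) abort("the sweep engine requires at most 64 nodes")
  markers <- c(ec_marker_nodes(), ec_proliferation_nodes())
  missing <- setdiff(markers, net$nodes)
  if (length(missing) > 0) {
    abort(sprintf("network lacks marker node '%s'", missing[1]))
  }
  mut_idx <- integer(); mut_val <- integer()
  if (!is.null(mutations)) {
    bad <- setdiff(names(mutations), net$nodes)
    if (length(bad) > 0) abort(sprintf("unknown node '%s'", bad[1]))
    mut_idx <- match(names(mutations), net$nodes) - 1L
    mut_val <- as.integer(mutations)
    if (!all(mut_val %in% c(0L, 1L))) abort("mutation values must be 0 or 1")
  }
  r <- .cpp_sweep(compile_program(net), n,
                  match(net$inputs, net$nodes) - 1L,
                  match(markers, net$nodes) - 1L,
                  mut_idx, mut_val,
                  as.integer(brute_cap), bdd_node_budget, TRUE)
  codes <- seq_len(2^k) - 1L
  bits <- vapply(seq_len(k), function(j) {
    bitwAnd(bitwShiftR(codes, k - j), 1L)
  }, integer(length(codes)))
  colnames(bits) <- net$inputs
  out <- tibble(
    env = codes,
    as_tibble(bits),
    behavior = factor(c("Phalanx", "Stalk", "Tip", "Atypical")[r$behavior],
                      levels = c("Phalanx", "Stalk", "Tip", "Atypical")),
    n_attractors = r$n_attractors,
    proliferation = factor(c("all", "some", "none")[r$proliferation],
                           levels = c("all", "some", "none")),
    has_tip = r$has_tip, has_stalk = r$has_stalk, has_phalanx = r$has_phalanx)
  class(out) <- c("ec_sweep", class(out))
  attr(out, "inputs") <- net$inputs
  attr(out, "mutations") <- mutations
  attr(out, "n_cores") <- r$n_cores
  out
}

#' Summarize a sweep
#'
#' @param x An `ec_sweep`.
#' @param ... Unused.
#' @return One-row tibble with environment counts per behavior label,
#'   proliferation-class counts, and total attractors.
#' @importFrom generics glance
#' @export
glance.ec_sweep <- function(x, ...) {
  tab <- table(x$behavior)
  pro <- table(x$proliferation)
  tibble(
    n_environments = nrow(x),
    phalanx = as.integer(tab[["Phalanx"]]),
    stalk = as.integer(tab[["Stalk"]]),
    tip = as.integer(tab[["Tip"]]),
    atypical = as.integer(tab[["Atypical"]]),
    behavior_determined = nrow(x) - as.integer(tab[["Atypical"]]),
    prolif_all = as.integer(pro[["all"]]),
    prolif_some = as.integer(pro[["some"]]),
    prolif_none = as.integer(pro[["none"]]),
    total_attractors = sum(x$n_attractors))
}

#' @export
print.ec_sweep <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Micro-environment sweep: %d environments\n", g$n_environments))
  cat(sprintf("  Tip %d | Stalk %d | Phalanx %d | Atypical %d\n",
              g$tip, g$stalk, g$phalanx, g$atypical))
  cat(sprintf("  proliferation all/some/none: %d/%d/%d; attractors: %d\n",
              g$prolif_all, g$prolif_some, g$prolif_none, g$total_attractors))
  if (!is.null(attr(x, "mutations"))) {
    m <- attr(x, "mutations")
    cat("  mutations:", paste(names(m), m, sep = "=", collapse = ", "), "\n")
  }
  NextMethod()
}

#' Behavior subgroups keyed by shared input characteristics
#'
#' Splits the Tip/Stalk environments of a sweep the way the model's summary
#' tables do: Tip environments by the presence of a paracrine VEGF ligand
#' (VEGFAxxxP or VEGFC_Dp), and Stalk environments into the three
#' characteristic requirement patterns.
#'
#' @param sweep An `ec_sweep` of the bundled model.
#' @return Tibble with columns `subgroup`, `n_environments`, `n_attractors`.
#' @export
sweep_subgroups <- function(sweep) {
  paracrine <- sweep$VEGFAxxxP == 1L | sweep$VEGFC_Dp == 1L
  tip <- sweep$behavior == "Tip"
  stalk <- sweep$behavior == "Stalk"
  wnt <- sweep$WNT5a == 1L | sweep$WNT7a == 1L
  stalk1 <- stalk & !paracrine & wnt & !(sweep$Oxygen == 1L & sweep$IGF == 1L & sweep$AMPATP == 1L)
  stalk2 <- stalk & !paracrine & wnt & sweep$Oxygen == 1L & sweep$IGF == 1L & sweep$AMPATP == 1L
  stalk3 <- stalk & !wnt
  rows <- list(
    tip_paracrine_vegf = tip & paracrine,
    tip_autocrine_vegf = tip & !paracrine,
    stalk_wnt = stalk1,
    stalk_wnt_nutrient = stalk2,
    stalk_tgfb_no_wnt = stalk3,
    phalanx = sweep$behavior == "Phalanx",
    atypical = sweep$behavior == "Atypical")
  tibble(
    subgroup = names(rows),
    n_environments = vapply(rows, sum, 0L, USE.NAMES = FALSE),
    n_attractors = vapply(rows, function(m) sum(sweep$n_attractors[m]), 0L,
                          USE.NAMES = FALSE))
}

#' Group environments of one behavior by maximal shared input literals
#'
#' Greedy cover: repeatedly takes the largest subset of the remaining
#' environments that share the most specific common input pattern, reporting
#' each group's fixed literals.  Group numbering is a presentation artifact;
#' only the per-group counts are meaningful.
#'
#' @param sweep An `ec_sweep`.
#' @param behavior One of `"Tip"`, `"Stalk"`, `"Phalanx"`, `"Atypical"`.
#' @param max_groups Stop after this many groups (safety valve).
#' @return Tibble with `group`, `pattern` (comma-separated fixed literals,
#'   `name` for active, `!name` for inactive), `n_environments`.
#' @export
environment_groups <- function(sweep, behavior, max_groups = 100L) {
  inputs <- attr(sweep, "inputs")
  rows <- sweep[sweep$behavior == behavior, , drop = FALSE]
  bits <- as.matrix(rows[, inputs, drop = FALSE])
  remaining <- rep(TRUE, nrow(bits))
  groups <- list()
  while (any(remaining) && length(groups) < max_groups) {
    sub <- bits[remaining, , drop = FALSE]
    # literals shared by every remaining environment
    shared_on <- colSums(sub) == nrow(sub)
    shared_off <- colSums(sub) == 0
    # refine: pick the input that splits the remainder most unevenly and fix
    # its majority value, until the fixed pattern covers a maximal block
    fixed <- ifelse(shared_on, 1L, ifelse(shared_off, 0L, NA_integer_))
    free <- which(is.na(fixed))
    covered <- rep(TRUE, nrow(sub))
    while (length(free) > 0) {
      frac <- colMeans(sub[covered, free, drop = FALSE])
      j <- free[which.max(pmax(frac, 1 - frac))]
      v <- as.integer(frac[match(j, free)] >= 0.5)
      keep <- sub[, j] == v
      if (all(keep[covered])) { fixed[j] <- v; free <- setdiff(free, j); next }
      # fixing j would split; stop if current pattern already isolates a block
      if (max(frac, 1 - frac) == 1) break
      fixed[j] <- v
      covered <- covered & keep
      free <- setdiff(free, j)
    }
    sel <- rep(TRUE, nrow(sub))
    for (j in which(!is.na(fixed))) sel <- sel & sub[, j] == fixed[j]
    pattern <- paste(ifelse(fixed[!is.na(fixed)] == 1,
                            inputs[!is.na(fixed)],
                            paste0("!", inputs[!is.na(fixed)])),
                     collapse = ",")
    idx_rem <- which(remaining)
    groups[[length(groups) + 1L]] <- tibble(
      group = length(groups) + 1L, pattern = pattern,
      n_environments = sum(sel))
    remaining[idx_rem[sel]] <- FALSE
  }
  dplyr::bind_rows(groups)
}

#' Plot a sweep summary
#'
#' @param object An `ec_sweep`.
#' @param ... Unused.
#' @return A ggplot: environment counts per behavior, filled by
#'   proliferation class.
#' @importFrom ggplot2 autoplot ggplot aes geom_bar labs
#' @export
autoplot.ec_sweep <- function(object, ...) {
  ggplot(object, aes(x = .data$behavior, fill = .data$proliferation)) +
    geom_bar() +
    labs(x = "EC behavior induced by the micro-environment",
         y = "number of micro-environments",
         fill = "attractors\nthat divide")
}
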