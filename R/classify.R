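# ---------------------------------------------------------------------------
# EC behavior classification from marker signatures.
#
# Marker signatures over four nodes separate the three canonical endothelial
# behaviors: Tip cells (migratory sprout leaders) are NRP1+ DLL4a+ AKT-,
# Stalk cells (proliferative followers) JAGa+ NRP1-, and Phalanx cells
# (quiescent, stable vessels) AKT+ JAGa- NRP1-.  The three signatures are
# pairwise unsatisfiable, so every state carries at most one label.
# ---------------------------------------------------------------------------

#' Marker signatures of the endothelial cell behaviors
#'
#' @return A named list of signatures; each signature is a named 0/1 vector
#'   of marker constraints.
#' @examples
#' ec_signatures()
#' @export
ec_signatures <- function() {
  list(
    Tip = c(NRP1 = 1L, DLL4a = 1L, AKT = 0L),
    Stalk = c(JAGa = 1L, NRP1 = 0L),
    Phalanx = c(AKT = 1L, JAGa = 0L, NRP1 = 0L))
}

ec_marker_nodes <- function() c("NRP1", "DLL4a", "AKT", "JAGa")
ec_proliferation_nodes <- function() c("betacatenin", "LEF1")

#' Classify a single state by its marker signature
#'
#' @param state Named 0/1 vector covering at least the marker nodes NRP1,
#'   DLL4a, AKT and JAGa (a full network state works).
#' @param signatures Signature list, by default [ec_signatures()].
#' @return One of `"Tip"`, `"Stalk"`, `"Phalanx"`, `"Other"`.
#' @examples
#' classify_state(c(NRP1 = 1, DLL4a = 1, AKT = 0, JAGa = 0))
#' @export
classify_state <- function(state, signatures = ec_signatures()) {
  for (lab in names(signatures)) {
    sig <- signatures[[lab]]
    vals <- state[names(sig)]
    if (anyNA(vals)) {
      abort(sprintf("state does not cover marker node '%s'",
                    names(sig)[is.na(vals)][1]))
    }
    if (all(as.integer(vals) == sig)) return(lab)
  }
  "Other"
}

#' Classify an attractor by the behavior of its states
#'
#' The attractor inherits a behavior label only when every state in the cycle
#' carries the same signature; mixed cycles (e.g. oscillating between Tip and
#' Stalk patterns) and cycles containing unlabeled states are atypical.
#'
#' @param attractor A `bn_attractor` (or a 0/1 state matrix with named
#'   columns).
#' @param signatures Signature list, by default [ec_signatures()].
#' @return One of `"Tip"`, `"Stalk"`, `"Phalanx"`, `"Atypical"`.
#' @export
classify_attractor <- function(attractor, signatures = ec_signatures()) {
  states <- if (inherits(attractor, "bn_attractor")) attractor$states else attractor
  labs <- unique(apply(states, 1, function(s) classify_state(s, signatures)))
  if (length(labs) == 1 && labs != "Other") labs else "Atypical"
}

#' Classify an attractor's proliferation status
#'
#' Cyclin-D1-mediated cell-cycle entry requires beta-catenin together with
#' LEF1; an attractor is proliferative ("divides") when both are active in
#' every state, i.e. the growth signal is sustained along the whole cycle.
#'
#' @param attractor A `bn_attractor` (or state matrix).
#' @param mode `"all_states"` (default: both markers active in every state)
#'   or `"any_state"` (in at least one state).
#' @return `TRUE` if the attractor divides.
#' @export
classify_proliferation <- function(attractor, mode = c("all_states", "any_state")) {
  mode <- match.arg(mode)
  states <- if (inherits(attractor, "bn_attractor")) attractor$states else attractor
  on <- states[, "betacatenin"] == 1L & states[, "LEF1"] == 1L
  if (mode == "all_states") all(on) else any(on)
}
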