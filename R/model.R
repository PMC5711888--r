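# ---------------------------------------------------------------------------
# The bundled angiogenesis model.
# ---------------------------------------------------------------------------

#' The 64-node angiogenesis network
#'
#' Loads the bundled synchronous Boolean model of endothelial-cell behavior
#' during sprouting angiogenesis: 64 nodes covering the ANG/TIE, HIF,
#' AMPK/mTOR, VEGF, IGF, FGF, PLC-gamma/Calcium, PI3K/AKT, NO, NOTCH, WNT and
#' TGF-beta signaling pathways plus the shear-stress mechanosensors.  The 16
#' extracellular micro-environment variables (ligands, oxygen, AMP:ATP ratio,
#' shear stress) are inputs held constant through identity self-loops, so a
#' micro-environment is one of the 2^16 = 65,536 input assignments.
#'
#' The Greek-letter node is stored under the ASCII identifier `betacatenin`;
#' `display_names` in [angiogenesis_metadata()] maps identifiers to display
#' labels.
#'
#' @return A `boolean_network` with 64 nodes and 16 declared inputs.
#' @examples
#' net <- angiogenesis_network()
#' n_nodes(net)
#' @export
angiogenesis_network <- function() {
  path <- system.file("extdata", "angiogenesis64.bnet", package = "angionet",
                      mustWork = TRUE)
  meta <- angiogenesis_metadata()
  read_network(path, inputs = meta$inputs)
}

#' Metadata for the bundled angiogenesis model
#'
#' @return A list with the declared `inputs` (in environment bit order, first
#'   input = most significant bit), the behavior marker `signatures`, the
#'   `proliferation_markers`, and `display_names`.
#' @export
angiogenesis_metadata <- function() {
  path <- system.file("extdata", "angiogenesis64.json", package = "angionet",
                      mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' The four reference micro-environments
#'
#' Four worked micro-environments with known expected behaviors under the
#' bundled model: a perfused, oxygenated quiescent vessel (Phalanx); the same
#' environment with paracrine processed VEGF-C/D or with paracrine VEGF-A
#' (both Tip); and a Notch/WNT/TGF-beta environment without VEGF (Stalk).
#'
#' @param net The bundled network (supply only to avoid re-reading it).
#' @return A tibble with columns `name`, `code`, `expected`, and the
#'   environment assignment in a list column `env`.
#' @export
reference_environments <- function(net = angiogenesis_network()) {
  specs <- list(
    quiescent = list(active = c("ANG1", "Oxygen", "ShearStress"),
                     expected = "Phalanx"),
    paracrine_vegfc = list(active = c("VEGFC_Dp", "ANG1", "Oxygen", "ShearStress"),
                           expected = "Tip"),
    paracrine_vegfa = list(active = c("VEGFAxxxP", "ANG1", "Oxygen", "ShearStress"),
                           expected = "Tip"),
    notch_wnt_tgfb = list(active = c("ANG1", "Oxygen", "ShearStress", "DLL4p",
                                     "WNT5a", "TGFB1"),
                          expected = "Stalk"))
  envs <- lapply(specs, function(sp) {
    do.call(micro_environment,
            c(list(net), as.list(stats::setNames(rep(1L, length(sp$active)),
                                                 sp$active))))
  })
  tibble(
    name = names(specs),
    code = vapply(envs, function(e) attr(e, "code"), 0, USE.NAMES = FALSE),
    expected = vapply(specs, function(sp) sp$expected, "", USE.NAMES = FALSE),
    env = unname(envs))
}
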