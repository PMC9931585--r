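#' Default eight-type panel for synthetic cohorts
#'
#' A compact panel pairing eight canonical lineage markers with the eight
#' cell types the synthetic generator plants by default, plus three
#' functional markers (proliferation, hypoxia response, ERK signalling).
#' Priorities put the most specific immune markers first so that
#' majority-vote ties resolve toward the rarer, better-defined lineages.
#'
#' @return a [marker_panel()].
#' @export
default_panel <- function() {
  m <- data.frame(
    name = c("FOXP3", "CD20", "CD8a", "CD4", "CD68", "CD66b", "CD31",
             "panCK", "Ki67", "HIF1a", "pERK"),
    role = c(rep("lineage", 8), rep("functional", 3)),
    priority_rank = c(1:8, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  marker_panel(m)
}

#' Cell types of the default synthetic panel
#' @return named character vector, lineage marker -> cell type.
#' @export
default_types <- function() {
  c(FOXP3 = "Treg", CD20 = "B cell", CD8a = "Tc", CD4 = "TH",
    CD68 = "Macrophage", CD66b = "Neutrophil", CD31 = "Endothelial",
    panCK = "Tumour")
}

#' Default lineage rules for the synthetic panel
#' @return a [type_rules()] data.frame.
#' @export
default_rules <- function() {
  tp <- default_types()
  type_rules(names(tp), unname(tp))
}

#' Immune cell types of a type set
#' @param types character vector of type labels.
#' @return the subset conventionally counted as immune.
#' @export
immune_types <- function(types) {
  setdiff(types, c("Tumour", "Endothelial", "Stromal", "undefined"))
}

#' A 17-type lung adenocarcinoma panel preset
#'
#' A fuller preset mirroring the cell types distinguishable in a ~35-plex
#' lung adenocarcinoma IMC panel: tumour, endothelium, stroma and 14 immune
#' populations, with macrophages split by CD163 and intermediate monocytes
#' resolved as CD14+CD16+ via secondary-marker rules. The exact
#' marker-to-type hierarchy of any given study is curated per panel; this
#' preset is a documented, configurable default, not an assertion of any
#' particular study's hierarchy. Four markers with inconsistent staining
#' behaviour in tissue (GM-CSFR, PD-1, PD-L1, B7-H3) are excluded from
#' analysis by default.
#'
#' @return list with elements `panel` (a [marker_panel()]) and `rules`
#'   (a [type_rules()] data.frame).
#' @export
luad_panel <- function() {
  lineage <- c("FOXP3", "CD20", "CD8a", "CD4", "CD57", "Tryptase", "CD66b",
               "CD68", "CD11c", "CD14", "CD16", "CD138", "aSMA", "CD31",
               "panCK")
  functional <- c("CD163", "Ki67", "HIF1a", "pERK", "ARG1", "MMP9",
                  "GranzymeB", "CD45RO", "Vimentin", "pSTAT3", "CC3",
                  "CD45", "HLA-DR", "CD3", "CD11b", "CD15")
  excluded <- c("GM-CSFR", "PD-1", "PD-L1", "B7-H3")
  m <- data.frame(
    name = c(lineage, functional, excluded),
    role = c(rep("lineage", length(lineage)),
             rep("functional", length(functional)),
             rep("excluded", length(excluded))),
    priority_rank = c(seq_along(lineage),
                      rep(NA_integer_, length(functional) + length(excluded))),
    stringsAsFactors = FALSE
  )
  panel <- marker_panel(m)
  rules <- type_rules(
    lineage,
    c("Treg", "B cell", "Tc", "TH", "NK", "Mast cell", "Neutrophil",
      "Macrophage", "Dendritic cell", "Classical monocyte",
      "Non-classical monocyte", "Plasma cell", "Stromal", "Endothelial",
      "Tumour"))
  rules$secondary_marker[rules$marker == "CD68"] <- "CD163"
  rules$secondary_type[rules$marker == "CD68"] <- "CD163 macrophage"
  rules$secondary_marker[rules$marker == "CD14"] <- "CD16"
  rules$secondary_type[rules$marker == "CD14"] <- "Intermediate monocyte"
  list(panel = panel, rules = rules)
}
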