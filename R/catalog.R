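#' Catalog of the 38 CD4+ T-cell histone modifications
#'
#' The 20 histone methylations and 18 histone acetylations whose binary
#' presence calls the analysis consumes. Catalog order (methylations first,
#' then acetylations) is the reproducible default ordering for heatmaps and
#' synthetic presets.
#'
#' @param type `"all"` (default, 38 names in catalog order),
#'   `"methylation"` (20) or `"acetylation"` (18).
#' @return character vector of modification names.
#' @examples
#' length(markCatalog())          # 38
#' head(markCatalog("acetylation"))
#' @export
markCatalog <- function(type = c("all", "methylation", "acetylation")) {
  type <- match.arg(type)
  methylations <- c(
    "H3K27me2", "H3K4me1", "H3K79me2", "H3K9me3", "H4K20me3",
    "H3K27me3", "H3K4me2", "H3K79me3", "H3R2me1", "H4R3me2",
    "H2BK5me1", "H3K36me1", "H3K4me3", "H3K9me1", "H3R2me2",
    "H3K27me1", "H3K36me3", "H3K79me1", "H3K9me2", "H4K20me1"
  )
  acetylations <- c(
    "H2AK5ac", "H2BK20ac", "H3K23ac", "H3K9ac", "H4K8ac",
    "H2AK9ac", "H2BK5ac", "H3K27ac", "H4K12ac", "H4K91ac",
    "H2BK120ac", "H3K14ac", "H3K36ac", "H4K16ac", "H2BK12ac",
    "H3K18ac", "H3K4ac", "H4K5ac"
  )
  switch(type,
    all = c(methylations, acetylations),
    methylation = methylations,
    acetylation = acetylations
  )
}
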