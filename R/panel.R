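#' The 10-gene marker panel
#'
#' The assay measures promoter methylation of ten breast-cancer-specific
#' genes split across two PCR marker sets (cartridges), each with its own
#' ACTB internal reference. Five panel members are fixed by the assay
#' (AKR1B1, APC, COL6A2, HOXB4, RASSF1); the remainder of the panel is
#' configuration-driven, so the default fills the second marker set with
#' placeholder names that can be replaced by any ten-gene layout.
#'
#' @param genes character vector of ten gene symbols (marker set 1 first).
#' @return data.frame with columns `gene` and `marker_set` (1 or 2).
#' @examples
#' default_panel()
#' @export
default_panel <- function(genes = c("AKR1B1", "APC", "COL6A2", "HOXB4", "RASSF1",
                                    "MKR06", "MKR07", "MKR08", "MKR09", "MKR10")) {
  if (length(genes) != 10L || anyDuplicated(genes))
    stop("panel must contain exactly 10 distinct gene names", call. = FALSE)
  data.frame(gene = as.character(genes),
             marker_set = rep(1:2, each = 5L),
             stringsAsFactors = FALSE)
}

#' @keywords internal
check_panel <- function(panel) {
  stopifnot(is.data.frame(panel), all(c("gene", "marker_set") %in% names(panel)))
  if (nrow(panel) != 10L || anyDuplicated(panel$gene))
    stop("panel must contain exactly 10 distinct genes", call. = FALSE)
  if (!all(sort(unique(panel$marker_set)) == 1:2))
    stop("panel genes must be partitioned across marker sets 1 and 2", call. = FALSE)
  invisible(panel)
}

# reference gene name used in plate and Ct tables
ACTB <- "ACTB"
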