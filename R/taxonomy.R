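#' Class taxonomy for sticky-trap monitoring
#'
#' The default taxonomy holds the two whitefly pests *Bemisia tabaci*
#' (BEMITA) and *Trialeurodes vaporariorum* (TRIAVA), the parasitoid
#' *Encarsia formosa* (ENCAFO), the predatory bug *Macrolophus pygmaeus*
#' (MACRPY), and the trap-background "garbage" class BKGRND that absorbs
#' the yellow surface and every non-target insect.  The background class is
#' what makes sliding-window prediction of whole traps possible.
#'
#' @param pooled if `TRUE`, return the categorically pooled taxonomy where
#'   the two whitefly species are merged into BEM-TRI.
#' @return character vector of class labels, in canonical order.
#' @export
trap_taxonomy <- function(pooled = FALSE) {
  if (pooled) c("BEM-TRI", "ENCAFO", "MACRPY", "BKGRND")
  else c("BEMITA", "TRIAVA", "ENCAFO", "MACRPY", "BKGRND")
}

# labels the synthetic generator can render; CLUTTER is drawn on scenes but
# never annotated -- non-target insects belong to the background
renderable_labels <- function() c(trap_taxonomy(), "CLUTTER")

assert_labels <- function(labels, taxonomy, what = "label") {
  bad <- setdiff(unique(as.character(labels)), taxonomy)
  if (length(bad))
    stopf("unknown %s(s): %s (taxonomy: %s)", what,
          paste(bad, collapse = ", "), paste(taxonomy, collapse = ", "))
  invisible(TRUE)
}
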