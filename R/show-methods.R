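#' @describeIn CatcherStrand-class Compact display.
#' @param object A `CatcherStrand`.
#' @export
setMethod("show", "CatcherStrand", function(object) {
  iv <- object@targetInterval
  cat("CatcherStrand '", object@name, "' (", object@boundStrand,
      "-bound)\n", sep = "")
  cat("  locus:   ", as.character(seqnames(iv)), ":", start(iv) - 1L, "-",
      end(iv), " (0-based half-open)\n", sep = "")
  cat("  domains: release[", length(object@releaseSite),
      "] + binding[", length(object@bindingSite),
      "] + adapter[", length(object@adapter), "] nt\n", sep = "")
  cat("  5'->3':  ", as.character(fullSequence(object)), "\n", sep = "")
})

#' @describeIn CatcherLibrary-class Compact display.
#' @param object A `CatcherLibrary`.
#' @export
setMethod("show", "CatcherLibrary", function(object) {
  cat("CatcherLibrary with", length(object), "catcher strand(s)\n")
  if (length(object)) {
    iv <- targetIntervals(object)
    tids <- unique(as.character(seqnames(iv)))
    cat("  targets:    ", paste(tids, collapse = ", "), "\n")
    cat("  bindingLen: ", object@params@bindingLen, " nt; adapter ",
        length(object@params@adapterSeq), " nt; toehold ",
        object@params@releaseLen, " nt\n", sep = "")
    strands <- mcols(iv)$boundStrand
    cat("  strands:    ", sum(strands == "sense"), "sense /",
        sum(strands == "antisense"), "antisense\n")
  }
})

#' @describeIn MixtureSet-class Compact display.
#' @param object A `MixtureSet`.
#' @export
setMethod("show", "MixtureSet", function(object) {
  cat("MixtureSet with", length(object), "member(s)\n")
  if (length(object))
    cat("  lengths ", min(width(object@seqs)), "-",
        max(width(object@seqs)), " nt; ",
        sum(object@duplex), " duplex; ",
        format(sum(as.numeric(object@molecules)), big.mark = ","),
        " molecules total\n", sep = "")
})

#' @describeIn PulldownResult-class Compact display.
#' @param object A `PulldownResult`.
#' @export
setMethod("show", "PulldownResult", function(object) {
  tab <- object@tab
  cat("PulldownResult:", nrow(tab), "member(s),",
      sum(tab$targeted), "targeted\n")
  cat("  pools: supernatant", sum(tab$supernatant),
      "| pellet", sum(tab$pelletRetained),
      "| released", sum(tab$released), "\n")
  if (sum(tab$released) > 0)
    cat("  released-pool purity:",
        format(100 * releasedPurity(object), digits = 4), "%\n")
})

#' @describeIn DepletionProfile-class Compact display.
#' @param object A `DepletionProfile`.
#' @export
setMethod("show", "DepletionProfile", function(object) {
  r <- object@ratio
  cat("DepletionProfile for '", object@transcript, "' (", length(r),
      " bases, ", sum(is.na(r)), " masked)\n", sep = "")
  cat("  depletion efficiency: ",
      format(object@efficiency, digits = 4), "\n", sep = "")
})

#' @describeIn PolymerSpec-class Compact display.
#' @param object A `PolymerSpec`.
#' @export
setMethod("show", "PolymerSpec", function(object) {
  cat("PolymerSpec '", object@name, "'\n", sep = "")
  fmt <- function(x) if (is.na(x)) "NA" else format(x, digits = 4)
  cat("  composition m/n/o: ", fmt(object@m), "/", fmt(object@n), "/",
      fmt(object@o), "\n", sep = "")
  cat("  Mw ", fmt(object@Mw), " g/mol; Rh ", fmt(object@Rh),
      " nm; Rg ", fmt(object@Rg), " nm; nu ", fmt(object@nu), "\n",
      sep = "")
})
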