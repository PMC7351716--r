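#' Construct a mixture of library members
#'
#' @param seqs Named `DNAStringSet` (or named character vector) of member
#'   sequences.
#' @param molecules Molecule count per member (recycled).
#' @param duplex Logical duplex flag per member (recycled).
#' @return A [MixtureSet-class].
#' @examples
#' mixtureSet(c(A = "ACGTACGTACGTACGTACGT"), molecules = 1000)
#' @export
mixtureSet <- function(seqs, molecules = 1L, duplex = FALSE) {
  seqs <- .asDNASet(seqs, "member sequences")
  n <- length(seqs)
  new("MixtureSet", seqs = seqs,
      molecules = as.integer(rep_len(molecules, n)),
      duplex = rep_len(as.logical(duplex), n))
}

#' Accessors for mixtures
#' @param x A [MixtureSet-class].
#' @return `memberSeqs()`: named `DNAStringSet`; `molecules()`: integer
#'   counts; `isDuplex()`: logical flags.
#' @name mixture-accessors
NULL

#' @rdname mixture-accessors
#' @export
memberSeqs <- function(x) x@seqs

#' @rdname mixture-accessors
#' @export
molecules <- function(x) setNames(x@molecules, names(x@seqs))

#' @rdname mixture-accessors
#' @export
isDuplex <- function(x) setNames(x@duplex, names(x@seqs))

#' @describeIn MixtureSet-class Number of members.
#' @param x A `MixtureSet`.
#' @export
setMethod("length", "MixtureSet", function(x) length(x@seqs))

#' Construct simulation parameters
#'
#' Defaults reflect the measured ensemble efficiencies of the reference
#' pulldown experiments: 88% single-strand capture, 89.8% duplex capture,
#' 90% TMSD release, 98% non-target retention (2% nonspecific capture), and
#' no nonspecific release.
#'
#' @param eCapture,eCaptureDs,eRelease,pNonspecific,pNonspecificRelease
#'   Per-molecule probabilities, see [SimParams-class].
#' @param minMatch Minimum contiguous complementarity (nt) for targeting.
#' @param seed Integer RNG seed, `NA` to use the current RNG state.
#' @return A [SimParams-class].
#' @examples
#' simParams()
#' @export
simParams <- function(eCapture = 0.88, eCaptureDs = 0.898, eRelease = 0.90,
                      pNonspecific = 0.02, pNonspecificRelease = 0,
                      minMatch = 20L, seed = NA_integer_) {
  new("SimParams", eCapture = eCapture, eCaptureDs = eCaptureDs,
      eRelease = eRelease, pNonspecific = pNonspecific,
      pNonspecificRelease = pNonspecificRelease,
      minMatch = as.integer(minMatch), seed = as.integer(seed))
}

# longest contiguous complementarity between a member strand and a binding
# site: the member hybridizes wherever it matches the reverse complement of
# the binding site
.complementarity <- function(member, bindingSite, duplex) {
  rcSite <- reverseComplement(bindingSite)
  len <- .lcs_dp(as.character(member), as.character(rcSite))[1L]
  if (duplex) {
    # either strand of the duplex can hybridize the binding site
    len2 <- .lcs_dp(as.character(reverseComplement(member)),
                    as.character(rcSite))[1L]
    len <- max(len, len2)
  }
  len
}

#' Classify mixture members as targeted or non-targeted by a library
#'
#' A member is targeted when it (or, for a duplex, either of its strands)
#' shares at least `minMatch` contiguous complementary bases with some
#' binding site in the library. The best-matching catcher is recorded: it
#' is the catcher through which the member is captured, and the one whose
#' release strand can later set it free.
#'
#' @param mixture A [MixtureSet-class].
#' @param csl A [CatcherLibrary-class] (an empty library targets nothing).
#' @param minMatch Minimum contiguous complementarity in nt.
#' @return A `DataFrame` with columns `member`, `targeted`, `catcher`
#'   (best-matching catcher or `NA`), `matchLen`.
#' @export
classifyTargets <- function(mixture, csl, minMatch = 20L) {
  stopifnot(is(mixture, "MixtureSet"), is(csl, "CatcherLibrary"))
  members <- names(mixture@seqs)
  sites <- bindingSites(csl)
  best <- integer(length(members))
  bestCatcher <- rep(NA_character_, length(members))
  for (i in seq_along(members)) {
    for (j in seq_along(sites)) {
      len <- .complementarity(mixture@seqs[[i]], sites[[j]],
                              mixture@duplex[i])
      if (len > best[i]) {
        best[i] <- len
        bestCatcher[i] <- names(sites)[j]
      }
    }
  }
  targeted <- best >= minMatch
  DataFrame(member = members, targeted = targeted,
            catcher = ifelse(targeted, bestCatcher, NA_character_),
            matchLen = best)
}

#' Simulate the capture (pulldown) step
#'
#' Each molecule of a targeted member is captured independently with
#' probability `eCapture` (`eCaptureDs` for duplex members); non-targeted
#' molecules are captured nonspecifically with `pNonspecific` (overridable
#' per member for components known to adsorb). Captured molecules end up
#' encapsulated in the precipitated pellet; the rest stay in the
#' supernatant. Counts are conserved per member and the draw is
#' reproducible for a fixed `params@seed`.
#'
#' @param mixture A [MixtureSet-class].
#' @param csl A [CatcherLibrary-class].
#' @param params A [SimParams-class].
#' @param pNonspecificOverride Optional named numeric: per-member
#'   nonspecific capture probabilities overriding `pNonspecific`.
#' @return A [PulldownResult-class] with zero released counts.
#' @export
simulateCapture <- function(mixture, csl, params = simParams(),
                            pNonspecificOverride = NULL) {
  stopifnot(is(mixture, "MixtureSet"), is(params, "SimParams"))
  cls <- classifyTargets(mixture, csl, params@minMatch)
  p <- ifelse(cls$targeted,
              ifelse(mixture@duplex, params@eCaptureDs, params@eCapture),
              params@pNonspecific)
  if (!is.null(pNonspecificOverride)) {
    idx <- match(names(pNonspecificOverride), cls$member)
    if (anyNA(idx)) stop("override names unknown members")
    repl <- !cls$targeted[idx]
    p[idx[repl]] <- pNonspecificOverride[repl]
  }
  captured <- .withSeed(params@seed,
                        rbinom(length(p), mixture@molecules, p))
  tab <- DataFrame(member = cls$member, targeted = cls$targeted,
                   catcher = cls$catcher,
                   initial = mixture@molecules,
                   supernatant = mixture@molecules - captured,
                   pelletRetained = captured,
                   released = 0L)
  metadata(tab)$catcherNames <- catcherNames(csl)
  new("PulldownResult", tab = tab, params = params)
}

#' Simulate the TMSD release step
#'
#' Pellet molecules of members whose capturing catcher has a supplied
#' release strand are released with probability `eRelease`; nonspecifically
#' captured molecules are released with `pNonspecificRelease` (0 by
#' default: lacking the right toehold, they stay adsorbed in the pellet).
#' This is the second stage of the dual selection - capture selects on the
#' binding site, release selects again on the release site - which is what
#' keeps the released pool essentially free of non-target contamination.
#'
#' @param captureResult A [PulldownResult-class] from [simulateCapture()].
#' @param releaseStrands Release strands as returned by
#'   [designReleaseStrands()] (a named `DNAStringSet`) or simply the
#'   character vector of catcher names to release. `NULL` releases nothing.
#' @param params A [SimParams-class]; defaults to the capture parameters.
#' @param knownCatchers Catcher names considered valid (default: the
#'   library catalogue recorded by [simulateCapture()]); a release strand
#'   naming any other catcher is a configuration error.
#' @param seed Optional seed for this step (default: `params@seed + 1` when
#'   the capture seed was set, so the two stages use distinct streams).
#' @return A [PulldownResult-class] with the released pool filled in.
#' @export
simulateRelease <- function(captureResult, releaseStrands,
                            params = captureResult@params,
                            knownCatchers = NULL, seed = NULL) {
  stopifnot(is(captureResult, "PulldownResult"))
  tab <- captureResult@tab
  relNames <- if (is.null(releaseStrands)) character()
              else if (is.character(releaseStrands)) releaseStrands
              else names(releaseStrands)
  if (is.null(knownCatchers))
    knownCatchers <- unique(c(metadata(tab)$catcherNames,
                              tab$catcher[!is.na(tab$catcher)]))
  unknown <- setdiff(relNames, knownCatchers)
  if (length(unknown))
    stop("release strand(s) name unknown catcher(s): ",
         paste(unknown, collapse = ", "))
  pRel <- ifelse(!is.na(tab$catcher) & tab$catcher %in% relNames,
                 params@eRelease,
                 ifelse(!tab$targeted, params@pNonspecificRelease, 0))
  if (is.null(seed))
    seed <- if (is.na(params@seed)) NA_integer_ else params@seed + 1L
  released <- .withSeed(seed,
                        rbinom(nrow(tab), tab$pelletRetained, pRel))
  tab$released <- released
  tab$pelletRetained <- tab$pelletRetained - released
  new("PulldownResult", tab = tab, params = params)
}

#' Analytic expectations of the catch-and-release process
#'
#' Closed-form ensemble expectations implied by the per-molecule
#' probabilities: targeted depletion from the supernatant equals
#' `eCapture`, non-target retention equals `1 - pNonspecific`, end-to-end
#' yield equals `eCapture * eRelease`, and the released-pool purity follows
#' from the targeted and non-targeted input abundances.
#'
#' @param params A [SimParams-class].
#' @param targetedMolecules,nontargetMolecules Input abundances used for
#'   the purity expectation (defaults 1 and 1).
#' @return A data.frame with columns `quantity` and `value` (fractions).
#' @examples
#' expectedFractions(simParams())
#' @export
expectedFractions <- function(params = simParams(),
                              targetedMolecules = 1,
                              nontargetMolecules = 1) {
  relT <- targetedMolecules * params@eCapture * params@eRelease
  relN <- nontargetMolecules * params@pNonspecific *
    params@pNonspecificRelease
  purity <- if (relT + relN > 0) relT / (relT + relN) else NA_real_
  data.frame(
    quantity = c("targeted_depletion", "nontarget_retention",
                 "release_efficiency", "end_to_end_yield",
                 "released_pool_purity"),
    value = c(params@eCapture, 1 - params@pNonspecific, params@eRelease,
              params@eCapture * params@eRelease, purity))
}

#' Summarize a pulldown result
#'
#' Per-member and pooled fractions: depletion (fraction of input removed
#' from the supernatant), retention (fraction left in the supernatant),
#' release efficiency (released / captured), end-to-end yield (released /
#' input), and for the pooled rows the released-pool purity (targeted
#' fraction of all released molecules).
#'
#' @param result A [PulldownResult-class].
#' @param file Optional TSV path to write the per-member table to.
#' @return A data.frame; members with zero input molecules are dropped.
#' @export
summarizePulldown <- function(result, file = NULL) {
  stopifnot(is(result, "PulldownResult"))
  tab <- as.data.frame(result@tab)
  tab <- tab[tab$initial > 0, , drop = FALSE]
  if (nrow(tab) == 0L) {
    out <- data.frame(member = character(), targeted = logical(),
                      depletion = numeric(), retention = numeric(),
                      release = numeric(), yield = numeric())
    if (!is.null(file))
      write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(out)
  }
  captured <- tab$pelletRetained + tab$released
  out <- data.frame(
    member = tab$member, targeted = tab$targeted,
    depletion = captured / tab$initial,
    retention = tab$supernatant / tab$initial,
    release = ifelse(captured > 0, tab$released / captured, NA_real_),
    yield = tab$released / tab$initial)
  pooled <- function(sel, label) {
    s <- tab[sel, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    cap <- sum(s$pelletRetained) + sum(s$released)
    data.frame(member = label, targeted = NA,
               depletion = cap / sum(s$initial),
               retention = sum(s$supernatant) / sum(s$initial),
               release = if (cap > 0) sum(s$released) / cap else NA_real_,
               yield = sum(s$released) / sum(s$initial))
  }
  out <- rbind(out, pooled(tab$targeted, "pooled_targeted"),
               pooled(!tab$targeted, "pooled_nontargeted"))
  attr(out, "purity") <- if (sum(tab$released) > 0)
    sum(tab$released[tab$targeted]) / sum(tab$released) else NA_real_
  if (!is.null(file))
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Released-pool purity of a pulldown result
#'
#' @param result A [PulldownResult-class].
#' @return Fraction of released molecules that are targeted members
#'   (`NA` if nothing was released).
#' @export
releasedPurity <- function(result) {
  tab <- result@tab
  tot <- sum(tab$released)
  if (tot == 0) return(NA_real_)
  sum(tab$released[tab$targeted]) / tot
}

#' Result table of a pulldown
#' @param result A [PulldownResult-class].
#' @return The per-member `DataFrame` of pool counts.
#' @export
pulldownCounts <- function(result) result@tab
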