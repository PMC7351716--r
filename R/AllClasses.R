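#' Design parameters for catcher strand libraries
#'
#' Holds the tunable geometry of a catcher strand library: the binding-site
#' length, the shared adapter that hybridizes the polymer-grafted anchor
#' strand, the toehold (release-site) length, and the tiling/alternation
#' policy.
#'
#' @slot bindingLen Binding-site length in nt (default 38).
#' @slot adapterSeq `DNAString`, the shared adapter domain complementary to
#'   the polymer anchor strand (22 nt by default).
#' @slot releaseLen Toehold length in nt; 0 omits the release site so the
#'   catcher can only be released by denaturation (default 10).
#' @slot alternate Alternate sense/antisense-binding catchers along a tiled
#'   region (default `TRUE`).
#' @slot startStrand Strand bound by the first tile, `"sense"` or
#'   `"antisense"`.
#' @slot tileStep Step between tile starts in nt; equal to `bindingLen`
#'   gives contiguous non-overlapping tiles (the default), larger leaves
#'   gaps, smaller overlaps.
#' @slot minOfftargetK Default minimum shared-substring length (nt) reported
#'   by the off-target screen (default 16).
#' @slot releaseMaxComplement Maximum exact complementarity (nt) tolerated
#'   between a generated toehold and any target segment (default 6).
#' @export
setClass("DesignParams", representation(
  bindingLen = "integer",
  adapterSeq = "DNAString",
  releaseLen = "integer",
  alternate = "logical",
  startStrand = "character",
  tileStep = "integer",
  minOfftargetK = "integer",
  releaseMaxComplement = "integer"
))

setValidity("DesignParams", function(object) {
  msg <- character()
  if (object@bindingLen < 10L)
    msg <- c(msg, "bindingLen must be >= 10 nt")
  if (object@releaseLen < 0L)
    msg <- c(msg, "releaseLen must be >= 0")
  if (!object@startStrand %in% c("sense", "antisense"))
    msg <- c(msg, "startStrand must be 'sense' or 'antisense'")
  if (object@tileStep < 1L)
    msg <- c(msg, "tileStep must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A single three-domain catcher strand
#'
#' A catcher strand links one target segment to the polymer. Read 5'->3' it
#' is the concatenation of an optional single-stranded release site (the
#' TMSD toehold), a binding site complementary to the target segment, and a
#' shared adapter that hybridizes the polymer-grafted anchor strand.
#'
#' A sense-bound catcher carries the reverse complement of the target's
#' sense segment; an antisense-bound catcher carries the sense segment
#' verbatim (the complement of the antisense strand).
#'
#' @slot name Catcher identifier.
#' @slot targetInterval Length-1 `GRanges` on the targeted transcript
#'   (1-based internally; exported sheets print 0-based half-open).
#' @slot boundStrand `"sense"` or `"antisense"` - which target strand the
#'   binding site hybridizes.
#' @slot bindingSite `DNAString`, the target-complementary domain.
#' @slot adapter `DNAString`, the shared anchor-complementary domain.
#' @slot releaseSite `DNAString`; zero length means no toehold.
#' @export
setClass("CatcherStrand", representation(
  name = "character",
  targetInterval = "GRanges",
  boundStrand = "character",
  bindingSite = "DNAString",
  adapter = "DNAString",
  releaseSite = "DNAString"
))

setValidity("CatcherStrand", function(object) {
  msg <- character()
  if (length(object@targetInterval) != 1L)
    msg <- c(msg, "targetInterval must have length 1")
  if (!object@boundStrand %in% c("sense", "antisense"))
    msg <- c(msg, "boundStrand must be 'sense' or 'antisense'")
  if (length(object@bindingSite) != width(object@targetInterval))
    msg <- c(msg, "bindingSite length must equal target interval width")
  if (length(object@adapter) == 0L)
    msg <- c(msg, "adapter must be non-empty")
  if (length(msg)) msg else TRUE
})

#' A catcher strand library (CSL)
#'
#' An ordered, validated collection of catcher strands tiling one or more
#' target regions. All members share one adapter and every binding site is
#' unique, so each catcher addresses exactly one locus.
#'
#' @slot catchers List of [CatcherStrand-class] objects.
#' @slot params The [DesignParams-class] used to build the library.
#' @slot targets `GRanges` of the tiled regions.
#' @export
setClass("CatcherLibrary", representation(
  catchers = "list",
  params = "DesignParams",
  targets = "GRanges"
))

setValidity("CatcherLibrary", function(object) {
  msg <- character()
  if (!all(vapply(object@catchers, is, logical(1), "CatcherStrand")))
    return("catchers must all be CatcherStrand objects")
  if (length(object@catchers)) {
    adapters <- vapply(object@catchers,
                       function(x) as.character(x@adapter), character(1))
    if (length(unique(adapters)) != 1L)
      msg <- c(msg, "all catchers must share one adapter")
    sites <- vapply(object@catchers,
                    function(x) as.character(x@bindingSite), character(1))
    if (anyDuplicated(sites))
      msg <- c(msg, paste("binding sites must be unique; duplicated:",
                          paste(unique(sites[duplicated(sites)]),
                                collapse = ", ")))
    nms <- vapply(object@catchers, function(x) x@name, character(1))
    if (anyDuplicated(nms))
      msg <- c(msg, "catcher names must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' A mixture of single- or double-stranded DNA library members
#'
#' Represents an input pool for pulldown simulation: named member sequences,
#' molecule counts, and a duplex flag for double-stranded members (whose
#' capture must out-compete sense/antisense re-hybridization and therefore
#' carries its own capture probability).
#'
#' @slot seqs Named `DNAStringSet` of member sequences.
#' @slot molecules Integer molecule count per member.
#' @slot duplex Logical, double-stranded member?
#' @export
setClass("MixtureSet", representation(
  seqs = "DNAStringSet",
  molecules = "integer",
  duplex = "logical"
))

setValidity("MixtureSet", function(object) {
  msg <- character()
  n <- length(object@seqs)
  if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
    msg <- c(msg, "member sequences must have unique names")
  if (length(object@molecules) != n || length(object@duplex) != n)
    msg <- c(msg, "molecules and duplex must parallel seqs")
  if (any(object@molecules < 0L))
    msg <- c(msg, "molecule counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Stochastic pulldown simulation parameters
#'
#' Per-molecule Bernoulli probabilities of the catch-and-release process.
#' Defaults are the ensemble efficiencies measured densitometrically for the
#' reference material: 88% capture of single-stranded targets, 89.8% capture
#' of duplex targets, 90% TMSD release, 2% nonspecific capture of
#' non-targets, and no nonspecific release (residual nonspecifically
#' adsorbed molecules stay in the pellet, which is what makes the
#' released pool pure).
#'
#' @slot eCapture Capture probability for targeted single-stranded members.
#' @slot eCaptureDs Capture probability for targeted duplex members.
#' @slot eRelease TMSD release probability for captured targets whose
#'   release strand is supplied.
#' @slot pNonspecific Capture probability for non-targeted members.
#' @slot pNonspecificRelease Release probability for nonspecifically
#'   captured molecules (default 0).
#' @slot minMatch Minimum contiguous complementarity (nt) for a member to
#'   count as targeted by a binding site.
#' @slot seed Integer RNG seed (NA leaves the RNG state alone).
#' @export
setClass("SimParams", representation(
  eCapture = "numeric",
  eCaptureDs = "numeric",
  eRelease = "numeric",
  pNonspecific = "numeric",
  pNonspecificRelease = "numeric",
  minMatch = "integer",
  seed = "integer"
))

setValidity("SimParams", function(object) {
  p <- c(object@eCapture, object@eCaptureDs, object@eRelease,
         object@pNonspecific, object@pNonspecificRelease)
  if (any(p < 0 | p > 1))
    return("all probabilities must be in [0, 1]")
  if (object@minMatch < 1L)
    return("minMatch must be >= 1")
  TRUE
})

#' Result of a simulated pulldown
#'
#' Per-member molecule counts in the three pools after capture (and,
#' optionally, release). Molecules are conserved: for every member,
#' `supernatant + pelletRetained + released == initial`.
#'
#' @slot tab A `DataFrame` with columns `member`, `targeted`, `catcher`
#'   (capturing catcher name or `NA`), `initial`, `supernatant`,
#'   `pelletRetained`, `released`.
#' @slot params The [SimParams-class] used.
#' @export
setClass("PulldownResult", representation(
  tab = "DataFrame",
  params = "SimParams"
))

setValidity("PulldownResult", function(object) {
  tab <- object@tab
  need <- c("member", "targeted", "catcher", "initial", "supernatant",
            "pelletRetained", "released")
  if (!all(need %in% colnames(tab)))
    return(paste("tab must have columns:", paste(need, collapse = ", ")))
  if (any(tab$supernatant + tab$pelletRetained + tab$released !=
          tab$initial))
    return("molecule counts not conserved (supernatant + pellet + released != initial)")
  if (any(c(tab$supernatant, tab$pelletRetained, tab$released) < 0))
    return("negative molecule counts")
  TRUE
})

#' Per-base depletion profile of one transcript
#'
#' The treated-to-control ratio of library-size-normalized per-base
#' coverage ("relative base count"); `1 - ratio` is the per-base depletion.
#' Positions failing the control coverage filter are `NA`.
#'
#' @slot transcript Transcript identifier.
#' @slot ratio Numeric per-base relative base count (NA where masked).
#' @slot targets `GRanges` of the directly CSL-targeted intervals on this
#'   transcript (may be empty).
#' @slot efficiency Per-transcript depletion efficiency `1 - mean(ratio)`
#'   over the evaluation interval, clipped to `[0, 1]`.
#' @slot normFactors Named numeric, the library-size factors used
#'   (`treated`, `control`).
#' @export
setClass("DepletionProfile", representation(
  transcript = "character",
  ratio = "numeric",
  targets = "GRanges",
  efficiency = "numeric",
  normFactors = "numeric"
))

setValidity("DepletionProfile", function(object) {
  r <- object@ratio[!is.na(object@ratio)]
  if (any(r < 0)) return("relative base counts must be >= 0")
  TRUE
})

#' Polymer chain specification and conformation summary
#'
#' Chain composition (acrylate units `m`, acrylamide units `n`, anchor
#' strands per chain `o`) together with flow-fractionation-derived
#' quantities: weight-average molecular weight, hydrodynamic and gyration
#' radii, and the conformation scaling exponent of R_g = K * M^nu (about
#' 0.33 for a compact sphere, 0.5 for a statistical chain in a theta
#' solvent). Unset numeric slots are `NA_real_`.
#'
#' @slot name Variant name.
#' @slot m,n,o Chain composition counts.
#' @slot Mw Weight-average molecular weight (g/mol).
#' @slot Rh Hydrodynamic radius (nm).
#' @slot Rg Gyration radius (nm).
#' @slot nu Scaling exponent (dimensionless).
#' @slot K Scaling prefactor.
#' @export
setClass("PolymerSpec", representation(
  name = "character", m = "numeric", n = "numeric", o = "numeric",
  Mw = "numeric", Rh = "numeric", Rg = "numeric",
  nu = "numeric", K = "numeric"
))

setValidity("PolymerSpec", function(object) {
  vals <- c(object@m, object@n, object@o, object@Mw, object@Rh, object@Rg)
  if (any(!is.na(vals) & vals <= 0))
    return("physical quantities must be > 0 where set")
  if (!is.na(object@nu) && (object@nu <= 0.2 || object@nu >= 0.8))
    warning("scaling exponent outside the usual (0.2, 0.8) range")
  TRUE
})

#' Configuration for the synthetic-data generators
#'
#' Controls the seeded generators that emulate the study inputs: toy
#' transcriptomes, the 10-member A-J-style ssDNA library (20-190 nt),
#' cDNA-style fragment pools with the 150-700 nt size distribution, and
#' matched control/depleted coverage pairs.
#'
#' @slot seed Integer RNG seed.
#' @slot nGenes Number of synthetic transcripts.
#' @slot lengthRange Transcript length bounds (nt).
#' @slot abundance `"uniform"` or `"dominated"` (a few transcripts consume a
#'   large fraction of reads, as high-abundance genes do in the motivating
#'   libraries).
#' @slot dominantFraction Read mass fraction assigned to the dominant
#'   gene(s) under the `"dominated"` model.
#' @slot fragmentRange Fragment length bounds (nt), default 150-700.
#' @slot reads Total fragment count.
#' @export
setClass("FixtureConfig", representation(
  seed = "integer",
  nGenes = "integer",
  lengthRange = "integer",
  abundance = "character",
  dominantFraction = "numeric",
  fragmentRange = "integer",
  reads = "integer"
))

setValidity("FixtureConfig", function(object) {
  msg <- character()
  if (length(object@lengthRange) != 2L ||
      any(object@lengthRange <= 0L) || diff(object@lengthRange) < 0L)
    msg <- c(msg, "lengthRange must be two ordered positive bounds")
  if (length(object@fragmentRange) != 2L ||
      any(object@fragmentRange <= 0L) || diff(object@fragmentRange) < 0L)
    msg <- c(msg, "fragmentRange must be two ordered positive bounds")
  if (object@dominantFraction < 0 || object@dominantFraction > 1)
    msg <- c(msg, "dominantFraction must be in [0, 1]")
  if (object@nGenes < 0L) msg <- c(msg, "nGenes must be >= 0")
  if (object@reads < 0L) msg <- c(msg, "reads must be >= 0")
  if (length(msg)) msg else TRUE
})
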