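#' TPM from raw counts and effective lengths
#'
#' Standard length-normalized rate: `rate_g = count_g / length_g`,
#' `TPM_g = 1e6 * rate_g / sum(rates)`, computed per sample. Each column
#' with any nonzero count sums to exactly one million.
#'
#' @param counts Numeric vector or genes-by-samples matrix of raw counts.
#' @param lengths Positive effective lengths, one per gene.
#' @return TPM values with the same shape as `counts`; an all-zero column
#'   yields an all-zero column with a warning.
#' @examples
#' tpmFromCounts(c(gA = 100, gB = 100), c(1000, 2000))
#' @export
tpmFromCounts <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("lengths must be > 0")
  one <- function(cnt) {
    rate <- cnt / lengths
    tot <- sum(rate)
    if (tot == 0) {
      warning("all counts zero; returning all-zero TPM column")
      return(rate)
    }
    1e6 * rate / tot
  }
  if (is.matrix(counts)) {
    if (nrow(counts) != length(lengths))
      stop("counts rows must match lengths")
    apply(counts, 2, one)
  } else {
    if (length(counts) != length(lengths))
      stop("counts must match lengths")
    one(counts)
  }
}

#' Assemble an expression table
#'
#' Wraps counts (optional) and TPM in a
#' [SummarizedExperiment::SummarizedExperiment] with gene lengths in the
#' row data, the container downstream evaluation functions accept.
#'
#' @param counts Genes-by-samples count matrix (rownames = genes).
#' @param lengths Effective gene lengths.
#' @return A `SummarizedExperiment` with assays `counts` and `tpm`.
#' @export
expressionTable <- function(counts, lengths) {
  counts <- as.matrix(counts)
  tpm <- tpmFromCounts(counts, lengths)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, tpm = tpm),
    rowData = DataFrame(length = lengths, row.names = rownames(counts)))
}

.tpmMatrix <- function(x) {
  if (is(x, "SummarizedExperiment"))
    return(SummarizedExperiment::assay(x, "tpm"))
  as.matrix(x)
}

#' Count genes detected above a TPM threshold
#'
#' @param x TPM matrix/vector or a `SummarizedExperiment` from
#'   [expressionTable()].
#' @param threshold TPM threshold; genes strictly above it count
#'   (default 1, the conventional detection cutoff).
#' @return Integer count per sample.
#' @examples
#' countExpressedGenes(c(0.5, 1.0, 2.0), threshold = 1)
#' @export
countExpressedGenes <- function(x, threshold = 1) {
  stopifnot(threshold >= 0)
  tpm <- .tpmMatrix(x)
  if (is.null(dim(tpm))) tpm <- matrix(tpm, ncol = 1L)
  colSums(tpm > threshold)
}

#' Library-size factors from untargeted transcripts
#'
#' Depleting a handful of high-abundance targets shrinks the total read
#' count, so treated and control tracks cannot be compared on raw totals.
#' The factors are therefore the total coverage over transcripts that no
#' catcher targets, in each condition.
#'
#' @param treated,control Named lists of per-base coverage vectors (or
#'   `RleList`s).
#' @param untargeted Transcript ids with no targeted region.
#' @return Named numeric `c(treated=, control=)`.
#' @export
librarySizeFactors <- function(treated, control, untargeted) {
  tot <- function(tracks) sum(vapply(untargeted, function(tid) {
    v <- tracks[[tid]]
    if (is.null(v)) stop("untargeted transcript '", tid, "' missing")
    sum(as.numeric(v))
  }, numeric(1)))
  c(treated = tot(treated), control = tot(control))
}

#' Per-base relative base count after pulldown
#'
#' Computes `r_i = (treated_i / N_t) / (control_i / N_c)` along one
#' transcript, where `N_t`, `N_c` are library-size factors from untargeted
#' transcripts. Positions whose control depth is below `minCov` are masked
#' `NA` (low-coverage ratios are noise-dominated, and division by zero is
#' meaningless). `1 - r_i` is the per-base depletion; the per-transcript
#' efficiency is `1 - mean(r_i)` over the evaluation interval, clipped to
#' `[0, 1]`.
#'
#' @param treated,control Per-base depth vectors (or `Rle`) for one
#'   transcript; equal lengths required.
#' @param transcript Transcript identifier.
#' @param normFactors Named numeric `c(treated=, control=)`; defaults to
#'   equal factors.
#' @param minCov Minimum control depth for a position to be evaluated
#'   (default 10).
#' @param window Odd moving-average window for optional smoothing of the
#'   ratio trace (default 1, off).
#' @param targets `GRanges` of directly targeted intervals on this
#'   transcript (annotation only).
#' @param evalRegion Optional length-1 `GRanges` restricting the efficiency
#'   average (e.g. the directly targeted region); default whole transcript.
#' @return A [DepletionProfile-class].
#' @examples
#' ctrl <- rep(100L, 50)
#' trt <- rep(50L, 50)
#' profile <- relativeBaseCount(trt, ctrl, "t1")
#' depletionEfficiency(profile)  # 0.5
#' @export
relativeBaseCount <- function(treated, control, transcript = "transcript",
                              normFactors = c(treated = 1, control = 1),
                              minCov = 10L, window = 1L,
                              targets = GRanges(), evalRegion = NULL) {
  treated <- as.numeric(treated)
  control <- as.numeric(control)
  if (length(treated) != length(control))
    stop("treated and control tracks differ in length")
  if (any(treated < 0) || any(control < 0))
    stop("coverage must be non-negative")
  if (!all(c("treated", "control") %in% names(normFactors)))
    stop("normFactors must be named c(treated=, control=)")
  if (any(normFactors <= 0)) stop("normFactors must be > 0")
  r <- (treated / normFactors[["treated"]]) /
    (control / normFactors[["control"]])
  r[control < minCov] <- NA_real_
  if (window > 1L) {
    if (window %% 2L == 0L) stop("window must be odd")
    half <- (window - 1L) %/% 2L
    sm <- vapply(seq_along(r), function(i) {
      w <- r[max(1L, i - half):min(length(r), i + half)]
      if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
    }, numeric(1))
    sm[is.na(r)] <- NA_real_
    r <- sm
  }
  idx <- seq_along(r)
  if (!is.null(evalRegion)) {
    stopifnot(is(evalRegion, "GRanges"), length(evalRegion) == 1L)
    idx <- start(evalRegion):min(end(evalRegion), length(r))
  }
  vals <- r[idx]
  eff <- if (all(is.na(vals))) NA_real_
         else min(max(1 - mean(vals, na.rm = TRUE), 0), 1)
  new("DepletionProfile", transcript = transcript, ratio = unname(r),
      targets = targets, efficiency = eff,
      normFactors = c(treated = normFactors[["treated"]],
                      control = normFactors[["control"]]))
}

#' Accessors for depletion profiles
#' @param profile A [DepletionProfile-class].
#' @return `relativeBaseCounts()`: the per-base ratio (NA = masked);
#'   `depletionEfficiency()`: the per-transcript efficiency in `[0, 1]`.
#' @name profile-accessors
NULL

#' @rdname profile-accessors
#' @export
relativeBaseCounts <- function(profile) profile@ratio

#' @rdname profile-accessors
#' @export
depletionEfficiency <- function(profile) profile@efficiency

#' Per-target depletion efficiency from TPM tables
#'
#' Removing abundant targets renormalizes TPM for every other gene, so the
#' raw treated/control TPM ratio overstates non-target abundance and
#' understates target depletion. The treated column is first rescaled by
#' the median treated/control ratio over reference (untargeted) genes;
#' the efficiency of each target is then `1 - rescaled ratio`, clipped to
#' `[0, 1]`.
#'
#' @param x TPM matrix (or `SummarizedExperiment`) with treated and control
#'   columns; rownames are genes.
#' @param targets Target gene ids.
#' @param reference Untargeted reference gene ids (non-empty, disjoint from
#'   `targets`).
#' @param treated,control Column names or indices (defaults `"treated"`,
#'   `"control"`).
#' @return Named numeric vector of per-target efficiencies.
#' @export
depletionEfficiencyFromTpm <- function(x, targets, reference,
                                       treated = "treated",
                                       control = "control") {
  tpm <- .tpmMatrix(x)
  if (length(reference) == 0L) stop("reference gene set is empty")
  if (length(intersect(targets, reference)))
    stop("targets and reference genes must be disjoint")
  missing <- setdiff(c(targets, reference), rownames(tpm))
  if (length(missing))
    stop("genes absent from the table: ", paste(missing, collapse = ", "))
  tr <- tpm[, treated]
  ct <- tpm[, control]
  refRatio <- median(tr[reference] / ct[reference], na.rm = TRUE)
  if (!is.finite(refRatio) || refRatio <= 0)
    stop("reference genes give no finite rescaling factor")
  ratio <- (tr[targets] / ct[targets]) / refRatio
  eff <- pmin(pmax(1 - ratio, 0), 1)
  setNames(eff, targets)
}

#' Correlation QC between two expression columns
#'
#' Spearman and Pearson correlations over `log10(TPM + pseudocount)`,
#' excluding the depleted target genes - the check that a targeted
#' depletion left the rest of the expression profile unbiased.
#'
#' @param a,b Named TPM vectors (shared gene names required).
#' @param exclude Gene ids to drop (the depleted targets).
#' @param pseudocount Added before the log (default 1).
#' @return Named numeric `c(spearman=, pearson=)`.
#' @export
correlationQC <- function(a, b, exclude = character(), pseudocount = 1) {
  genes <- setdiff(intersect(names(a), names(b)), exclude)
  if (length(genes) < 3L)
    stop("need at least 3 shared genes after exclusion")
  la <- log10(a[genes] + pseudocount)
  lb <- log10(b[genes] + pseudocount)
  c(spearman = cor(la, lb, method = "spearman"),
    pearson = cor(la, lb, method = "pearson"))
}

#' Unpaired two-tailed pooled-variance t-test
#'
#' Student's two-sample t-test with pooled variance and
#' `df = n_a + n_b - 2` (so two groups of three give 4 degrees of freedom,
#' the design used for the triplicate expression comparisons). Degenerate
#' inputs are handled explicitly: zero pooled variance with equal means
#' gives `t = 0, p = 1`; with unequal means the statistic is infinite and
#' `p = 0`.
#'
#' @param groupA,groupB Numeric vectors, each of length >= 2.
#' @return A list with `t`, `p`, `df`, and `infinite` (logical flag).
#' @examples
#' unpairedTTest(c(1, 2, 3), c(4, 5, 6))
#' @export
unpairedTTest <- function(groupA, groupB) {
  na <- length(groupA); nb <- length(groupB)
  if (na < 2L || nb < 2L) stop("each group needs >= 2 values")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(groupA) + (nb - 1) * stats::var(groupB)) /
    df
  dm <- mean(groupA) - mean(groupB)
  if (sp2 == 0) {
    if (dm == 0) return(list(t = 0, p = 1, df = df, infinite = FALSE))
    return(list(t = sign(dm) * Inf, p = 0, df = df, infinite = TRUE))
  }
  t <- dm / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df), df = df, infinite = FALSE)
}
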