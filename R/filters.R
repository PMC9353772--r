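#' Occurrence filters and matrix cleaning
#'
#' Reproducibility-style feature filtering and blank handling for aligned
#' matrices. All operations preserve feature order, are idempotent, and treat
#' missingness as the primary information channel (the downstream networks
#' are occurrence-driven).
#'
#' @name aligned-filters
NULL

#' @describeIn aligned-filters keep features detected in at least \code{k}
#'   samples overall (the usual "appears at least twice" reproducibility
#'   filter is \code{k = 2}).
#' @param x a [MassFeatureSet-class].
#' @param k integer occurrence threshold (>= 1).
#' @export
filterMinGlobalOccurrence <- function(x, k = 2) {
    stopifnot(k >= 1)
    keep <- rowSums(occurrenceMatrix(x)) >= k
    if (!any(keep)) stop("filter removed every feature")
    x[keep, ]
}

#' @describeIn aligned-filters keep features detected in at least \code{k}
#'   samples of at least one class (stricter, class-aware variant).
#' @export
filterMinClassOccurrence <- function(x, k = 2) {
    stopifnot(k >= 1)
    cl <- classLabels(x)
    if (any(is.na(cl))) stop("class labels required (some are NA)")
    occ <- occurrenceMatrix(x)
    perClass <- vapply(unique(cl), function(g)
        rowSums(occ[, cl == g, drop = FALSE]), numeric(nrow(x)))
    keep <- apply(perClass >= k, 1, any)
    if (!any(keep)) stop("filter removed every feature")
    x[keep, ]
}

#' @describeIn aligned-filters subtract the per-feature mean of the blank
#'   samples from every non-blank sample; results \code{<= 0} become missing;
#'   the blank samples are dropped from the output.
#' @param blankIds character, sample ids of the blanks (defaults to the ids
#'   recorded by [readAlignedMatrix()] in \code{metadata(x)$blanks}).
#' @export
subtractBlanks <- function(x, blankIds = metadata(x)$blanks) {
    if (is.null(blankIds) || !length(blankIds))
        stop("no blank sample ids supplied")
    if (!all(blankIds %in% sampleIds(x)))
        stop("unknown blank sample id(s): ",
             paste(setdiff(blankIds, sampleIds(x)), collapse = ", "))
    keepSamples <- setdiff(sampleIds(x), blankIds)
    if (!length(keepSamples)) stop("all samples are blanks")
    m <- intensityMatrix(x)
    blankMean <- rowMeans(m[, blankIds, drop = FALSE], na.rm = TRUE)
    blankMean[is.nan(blankMean)] <- 0   # feature never seen in any blank
    out <- m[, keepSamples, drop = FALSE] - blankMean
    out[!is.na(out) & out <= 0] <- NA
    res <- MassFeatureSet(out, neutralMass(x), classLabels(x)[keepSamples])
    metadata(res)$blanks <- character(0)
    res
}

#' @describeIn aligned-filters merge features whose masses are equal after
#'   rounding to \code{massDecimals} decimals (e.g. identical m/z at
#'   different retention times). Occurrence is the union; co-occurring cell
#'   intensities are combined with \code{combine} (sum by default — the
#'   network layer only consumes presence, so the choice cannot affect sMDiN
#'   structure). The merged feature keeps the first id and the mean mass of
#'   its members.
#' @param massDecimals integer, decimals for mass equality (default 6,
#'   matching typical FT-ICR reporting precision).
#' @param combine function combining co-occurring intensities.
#' @export
mergeDuplicateMasses <- function(x, massDecimals = 6, combine = sum) {
    stopifnot(massDecimals >= 0)
    key <- sprintf(paste0("%.", massDecimals, "f"), neutralMass(x))
    if (!anyDuplicated(key)) return(x)
    groups <- split(seq_len(nrow(x)), factor(key, levels = unique(key)))
    m <- intensityMatrix(x)
    rows <- lapply(groups, function(idx) {
        if (length(idx) == 1L) return(m[idx, ])
        apply(m[idx, , drop = FALSE], 2, function(col)
            if (all(is.na(col))) NA_real_ else combine(col[!is.na(col)]))
    })
    out <- do.call(rbind, rows)
    ids <- vapply(groups, function(idx) featureIds(x)[idx[1]], character(1))
    rownames(out) <- ids
    mass <- vapply(groups, function(idx) mean(neutralMass(x)[idx]), numeric(1))
    res <- MassFeatureSet(out, mass, classLabels(x))
    metadata(res) <- metadata(x)
    res
}
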