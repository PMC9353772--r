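#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- rowData colData rowData<- colData<-
NULL

#' MassFeatureSet: aligned feature-by-sample matrices with neutral masses
#'
#' The sole experimental input of the workflow: an aligned untargeted
#' metabolomics matrix holding one neutral monoisotopic mass (Da) per feature
#' and one intensity column per sample, with \code{NA} encoding a missing
#' (undetected) feature. Class labels live in \code{colData}. Extends
#' \linkS4class{SummarizedExperiment}, so all of its subsetting and accessor
#' machinery applies.
#'
#' Missingness is a first-class state here, never conflated with zero after
#' ingestion: the per-sample networks downstream are driven by feature
#' occurrence, not intensity.
#'
#' No additional slots; the contract is enforced by the validity method:
#' positive masses in \code{rowData()$neutral_mass}, unique feature and
#' sample ids, a \code{class_label} column in \code{colData}, nonnegative
#' intensities, and at least one non-missing value per sample.
#'
#' @seealso [MassFeatureSet()] for construction,
#'   [readAlignedMatrix()] for file input.
#' @export
setClass("MassFeatureSet", contains = "SummarizedExperiment")

.validMassFeatureSet <- function(object) {
    msg <- NULL
    if (!"intensity" %in% names(assays(object)))
        msg <- c(msg, "assay 'intensity' is required")
    if (!"neutral_mass" %in% names(rowData(object)))
        msg <- c(msg, "rowData must contain 'neutral_mass'")
    else {
        m <- rowData(object)$neutral_mass
        if (any(!is.finite(m)) || any(m <= 0))
            msg <- c(msg, "all neutral masses must be positive finite numbers")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "feature ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (!"class_label" %in% names(colData(object)))
        msg <- c(msg, "colData must contain 'class_label'")
    x <- assays(object)[["intensity"]]
    if (!is.null(x) && ncol(x) > 0) {
        if (any(x[!is.na(x)] < 0))
            msg <- c(msg, "intensities must be nonnegative")
        if (nrow(x) > 0 && any(colSums(!is.na(x)) == 0))
            msg <- c(msg, "every sample must have at least one non-missing intensity")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("MassFeatureSet", .validMassFeatureSet)

#' MDBTable: mass-difference-based building blocks
#'
#' A registry of named elemental-composition deltas (over C, H, N, O, P, S)
#' with their exact monoisotopic mass changes. Each row of \code{counts} is a
#' signed element-count vector; \code{deltaMass} is the absolute monoisotopic
#' mass of that delta, recomputed from the composition (direction is handled
#' by the undirected network, so only the magnitude is stored).
#'
#' @slot label character, unique MDB names.
#' @slot counts integer matrix, MDBs x elements (columns C,H,N,O,P,S), signed.
#' @slot deltaMass numeric, absolute monoisotopic mass change in Da.
#' @seealso [defaultMDBs()], [loadMDBTable()], [monoisotopicMass()]
#' @export
setClass("MDBTable", representation(
    label = "character",
    counts = "matrix",
    deltaMass = "numeric"
))

.validMDBTable <- function(object) {
    msg <- NULL
    n <- length(object@label)
    if (anyDuplicated(object@label))
        msg <- c(msg, "MDB labels must be unique")
    if (nrow(object@counts) != n || length(object@deltaMass) != n)
        msg <- c(msg, "label, counts and deltaMass must have matching length")
    if (!identical(colnames(object@counts), .ELEMENTS))
        msg <- c(msg, "counts columns must be C,H,N,O,P,S")
    if (n > 0) {
        if (any(rowSums(object@counts != 0) == 0))
            msg <- c(msg, "every MDB needs at least one nonzero element count")
        if (any(abs(object@counts) > 100))
            msg <- c(msg, "element counts bounded to |count| <= 100")
        recomputed <- abs(monoisotopicMass(object@counts))
        if (any(abs(recomputed - object@deltaMass) > 1e-6))
            msg <- c(msg, "deltaMass must equal the monoisotopic mass of the composition")
        if (any(object@deltaMass <= 0))
            msg <- c(msg, "deltaMass must be positive")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("MDBTable", .validMDBTable)

#' MassDiffNet: a mass-difference network
#'
#' An undirected graph whose vertices are mass features (carrying their
#' neutral masses) and whose edges record which MDB explains the mass
#' difference between the two endpoints, together with the residual of the
#' match in ppm of the larger mass. Parallel edges are legal only with
#' distinct MDB labels (a pair may in principle be matched by more than one
#' transformation). Both the dataset-level network and the per-sample
#' subnetworks (sMDiNs, isolated nodes removed) are represented by this
#' class.
#'
#' @slot graph an \code{igraph} object with vertex attribute \code{mass} and
#'   edge attributes \code{mdb} and \code{residual_ppm}.
#' @slot universeSize integer, number of features in the originating matrix
#'   (the denominator for the percentage of connected nodes).
#' @seealso [buildMDiN()], [deriveSMDiN()], [summarizeNetwork()]
#' @export
setClass("MassDiffNet", representation(
    graph = "ANY",
    universeSize = "integer"
))

.validMassDiffNet <- function(object) {
    msg <- NULL
    g <- object@graph
    if (!igraph::is_igraph(g))
        msg <- c(msg, "graph slot must be an igraph object")
    else {
        if (igraph::is_directed(g))
            msg <- c(msg, "mass-difference networks are undirected")
        if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$mass))
            msg <- c(msg, "vertices must carry a 'mass' attribute")
        if (any(igraph::which_loop(g)))
            msg <- c(msg, "self-edges are not allowed")
    }
    if (length(object@universeSize) != 1L || object@universeSize < 0L)
        msg <- c(msg, "universeSize must be a single nonnegative integer")
    if (is.null(msg)) TRUE else msg
}
setValidity("MassDiffNet", .validMassDiffNet)
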