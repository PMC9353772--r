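## Monoisotopic atomic masses (Da), IUPAC/CODATA, >= 9 significant decimals.
## C is exactly 12 by definition of the unified atomic mass unit.
.ELEMENTS <- c("C", "H", "N", "O", "P", "S")
.ATOMIC_MASS <- c(
    C = 12.0,
    H = 1.007825032,
    N = 14.003074005,
    O = 15.994914620,
    P = 30.973761998,
    S = 31.972071174
)
.ELECTRON_MASS <- 0.000548580

#' Monoisotopic mass of an elemental-composition delta
#'
#' Computes the signed monoisotopic mass (Da) of a composition change over
#' the CHNOPS elements as the count-weighted sum of monoisotopic atomic
#' masses. Net-loss deltas yield negative values; the MDB registry stores
#' absolute values because the network is undirected.
#'
#' @param delta a named numeric vector of signed element counts (names among
#'   C, H, N, O, P, S), or a matrix with those columns (one row per delta).
#' @return numeric, the signed monoisotopic mass(es) in Da.
#' @examples
#' monoisotopicMass(c(C = 1, H = 2))        # methylation, 14.015650
#' monoisotopicMass(c(O = 1, N = -1, H = -1)) # deamination, -0.984016 signed
#' @export
monoisotopicMass <- function(delta) {
    if (is.matrix(delta)) {
        bad <- setdiff(colnames(delta), .ELEMENTS)
        if (length(bad))
            stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
        if (any(rowSums(delta != 0) == 0))
            stop("all-zero elemental delta")
        return(as.numeric(delta %*% .ATOMIC_MASS[colnames(delta)]))
    }
    bad <- setdiff(names(delta), .ELEMENTS)
    if (length(bad) || is.null(names(delta)))
        stop("unknown element symbol(s): ",
             paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
    if (all(delta == 0)) stop("all-zero elemental delta")
    sum(.ATOMIC_MASS[names(delta)] * delta)
}

.asCountMatrix <- function(rows) {
    counts <- matrix(0L, nrow = length(rows), ncol = length(.ELEMENTS),
                     dimnames = list(names(rows), .ELEMENTS))
    for (i in seq_along(rows))
        counts[i, names(rows[[i]])] <- as.integer(rows[[i]])
    counts
}

#' Construct an MDB table from labels and signed element counts
#'
#' @param label character vector of unique MDB names.
#' @param counts numeric/integer matrix of signed element counts with columns
#'   C, H, N, O, P, S (extra ordering is fixed up; missing elements are 0).
#' @return an [MDBTable-class] with \code{deltaMass} computed from the
#'   compositions.
#' @export
MDBTable <- function(label, counts) {
    if (is.null(colnames(counts)))
        stop("counts must have element column names")
    full <- matrix(0L, nrow = nrow(counts), ncol = length(.ELEMENTS),
                   dimnames = list(label, .ELEMENTS))
    bad <- setdiff(colnames(counts), .ELEMENTS)
    if (length(bad))
        stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    full[, colnames(counts)] <- as.integer(round(counts))
    new("MDBTable", label = as.character(label), counts = full,
        deltaMass = abs(monoisotopicMass(full)))
}

## Table of transformations shipped with the package. Compositions are the
## net elemental changes; the glycation pair (carboxymethylation and
## carboxyethylation) is optional and aimed at systems where methylglyoxal
## chemistry matters. Note: the hydroxymethylation entry is labelled CHOH for
## continuity with common MDB lists but its composition is CHO (29.002740 Da),
## the mass those lists actually use.
.DEFAULT_MDB_ROWS <- list(
    "O(-NH)"    = c(O = 1, N = -1, H = -1),
    "NH3(-O)"   = c(N = 1, H = 3, O = -1),
    "H2"        = c(H = 2),
    "CH2"       = c(C = 1, H = 2),
    "O"         = c(O = 1),
    "H2O"       = c(H = 2, O = 1),
    "NCH"       = c(N = 1, C = 1, H = 1),
    "CO"        = c(C = 1, O = 1),
    "CHOH"      = c(C = 1, H = 1, O = 1),
    "S"         = c(S = 1),
    "C2H2O"     = c(C = 2, H = 2, O = 1),
    "CONH"      = c(C = 1, O = 1, N = 1, H = 1),
    "CO2"       = c(C = 1, O = 2),
    "SO3"       = c(S = 1, O = 3),
    "PO3H"      = c(P = 1, O = 3, H = 1)
)
.GLYCATION_MDB_ROWS <- list(
    "CHCOOH"    = c(C = 2, H = 2, O = 2),
    "CCH3COOH"  = c(C = 3, H = 4, O = 2)
)

#' Default mass-difference building blocks
#'
#' The 15 small (< 80 Da), ubiquitous biochemical transformations used to
#' build mass-difference networks, covering all six CHNOPS elements:
#' deamination, transamination, (de)hydrogenation, methylation, oxygenation,
#' condensation/dehydration, formidoyl transfer, formylation,
#' hydroxymethylation, -SH transfer, acetylation, carbamoyl transfer,
#' (de)carboxylation, sulfation and phosphorylation. With
#' \code{includeGlycation = TRUE} the two glycation-related MDBs
#' (carboxymethylation CHCOOH and carboxyethylation CCH3COOH) are added,
#' giving 17.
#'
#' @param includeGlycation logical, add the two glycation MDBs.
#' @return an [MDBTable-class].
#' @examples
#' length(defaultMDBs())            # 15
#' length(defaultMDBs(TRUE))        # 17
#' @export
defaultMDBs <- function(includeGlycation = FALSE) {
    rows <- .DEFAULT_MDB_ROWS
    if (includeGlycation)
        rows <- c(rows, .GLYCATION_MDB_ROWS)
    MDBTable(names(rows), .asCountMatrix(rows))
}

#' Read an MDB table from CSV
#'
#' Expects columns \code{label}, any subset of \code{C,H,N,O,P,S} (signed
#' counts, missing treated as 0) and optionally \code{mass}. The delta mass
#' is always recomputed from the composition; a stated \code{mass} deviating
#' by more than 1e-5 Da from the recomputed value is an error (it flags a
#' wrong composition).
#'
#' @param path CSV file path.
#' @return an [MDBTable-class]; an empty file yields an empty table with a
#'   warning.
#' @export
loadMDBTable <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
    if (nrow(df) == 0) {
        warning("empty MDB table: ", path)
        return(new("MDBTable", label = character(0),
                   counts = matrix(0L, 0, length(.ELEMENTS),
                                   dimnames = list(NULL, .ELEMENTS)),
                   deltaMass = numeric(0)))
    }
    if (!"label" %in% names(df)) stop("MDB CSV needs a 'label' column")
    if (anyDuplicated(df$label))
        stop("duplicate MDB labels: ",
             paste(unique(df$label[duplicated(df$label)]), collapse = ", "))
    elems <- intersect(.ELEMENTS, names(df))
    if (!length(elems)) stop("MDB CSV needs at least one element column")
    counts <- as.matrix(df[, elems, drop = FALSE])
    counts[is.na(counts)] <- 0
    tab <- MDBTable(df$label, counts)
    if ("mass" %in% names(df)) {
        off <- abs(df$mass - tab@deltaMass)
        if (any(off > 1e-5))
            stop("stated mass disagrees with composition for: ",
                 paste(df$label[off > 1e-5], collapse = ", "),
                 " (max deviation ", format(max(off)), " Da)")
    }
    tab
}

#' Theoretical m/z of a singly charged reference ion
#'
#' Helper for intensity normalization by a reference feature: computes the
#' theoretical [M-H]- or [M+H]+ m/z of a neutral composition, electron mass
#' included. The classic ESI- lock mass leucine enkephalin (C28H37N5O7)
#' gives 554.262022 for [M-H]-.
#'
#' @param composition named vector of element counts of the neutral molecule.
#' @param mode "neg" ([M-H]-) or "pos" ([M+H]+).
#' @return numeric m/z.
#' @examples
#' referenceIonMass(c(C = 28, H = 37, N = 5, O = 7))  # 554.262022
#' @export
referenceIonMass <- function(composition, mode = c("neg", "pos")) {
    mode <- match.arg(mode)
    M <- monoisotopicMass(composition)
    if (mode == "neg") M - .ATOMIC_MASS[["H"]] + .ELECTRON_MASS
    else M + .ATOMIC_MASS[["H"]] - .ELECTRON_MASS
}

#' @describeIn MDBTable-accessors MDB names.
#' @param x an \code{MDBTable}.
#' @export
setMethod("mdbLabels", "MDBTable", function(x) x@label)

#' @describeIn MDBTable-accessors absolute delta masses (Da), named by label.
#' @export
setMethod("mdbMasses", "MDBTable", function(x) stats::setNames(x@deltaMass, x@label))

#' @describeIn MDBTable-accessors signed element-count matrix.
#' @export
setMethod("mdbCounts", "MDBTable", function(x) x@counts)

#' @export
setMethod("length", "MDBTable", function(x) length(x@label))

#' @export
setMethod("[", "MDBTable", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, x@label)
    new("MDBTable", label = x@label[i],
        counts = x@counts[i, , drop = FALSE], deltaMass = x@deltaMass[i])
})

#' @export
setMethod("show", "MDBTable", function(object) {
    cat(sprintf("MDBTable with %d building block(s)\n", length(object)))
    if (length(object))
        print(data.frame(label = object@label,
                         delta_mass = sprintf("%.6f", object@deltaMass),
                         row.names = NULL))
})

#' Accessors for MDBTable
#'
#' @name MDBTable-accessors
#' @rdname MDBTable-accessors
NULL
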