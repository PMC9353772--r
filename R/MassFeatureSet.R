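#' Construct a MassFeatureSet
#'
#' @param intensities numeric matrix, features x samples, \code{NA} = missing.
#'   Rownames are feature ids (generated if absent), colnames sample ids.
#' @param neutralMass numeric vector of neutral monoisotopic masses (Da), one
#'   per feature.
#' @param classLabels character vector of per-sample class labels (recycled
#'   single value allowed), or a named vector mapped by sample id.
#' @return a [MassFeatureSet-class].
#' @examples
#' x <- matrix(c(10, NA, 3, 5, 2, NA), nrow = 3,
#'             dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
#' mfs <- MassFeatureSet(x, neutralMass = c(100.1, 200.2, 300.3),
#'                       classLabels = c("A", "B"))
#' @export
MassFeatureSet <- function(intensities, neutralMass,
                           classLabels = rep(NA_character_, ncol(intensities))) {
    intensities <- as.matrix(intensities)
    if (is.null(rownames(intensities)))
        rownames(intensities) <- sprintf("F%04d", seq_len(nrow(intensities)))
    if (is.null(colnames(intensities)))
        colnames(intensities) <- sprintf("S%03d", seq_len(ncol(intensities)))
    if (length(neutralMass) != nrow(intensities))
        stop("need one neutral mass per feature")
    if (!is.null(names(classLabels)))
        classLabels <- classLabels[colnames(intensities)]
    if (length(classLabels) == 1L)
        classLabels <- rep(classLabels, ncol(intensities))
    se <- SummarizedExperiment(
        assays = list(intensity = intensities),
        rowData = DataFrame(neutral_mass = as.numeric(neutralMass),
                            row.names = rownames(intensities)),
        colData = DataFrame(class_label = as.character(classLabels),
                            row.names = colnames(intensities)))
    new("MassFeatureSet", se)
}

#' Accessors for MassFeatureSet
#'
#' @param x a \code{MassFeatureSet}.
#' @param value replacement class labels.
#' @name MassFeatureSet-accessors
#' @rdname MassFeatureSet-accessors
NULL

#' @describeIn MassFeatureSet-accessors neutral masses (Da), named by feature.
#' @export
setMethod("neutralMass", "MassFeatureSet", function(x)
    stats::setNames(rowData(x)$neutral_mass, rownames(x)))

#' @describeIn MassFeatureSet-accessors per-sample class labels, named.
#' @export
setMethod("classLabels", "MassFeatureSet", function(x)
    stats::setNames(colData(x)$class_label, colnames(x)))

#' @describeIn MassFeatureSet-accessors set class labels.
#' @export
setMethod("classLabels<-", "MassFeatureSet", function(x, value) {
    if (!is.null(names(value))) value <- value[colnames(x)]
    colData(x)$class_label <- as.character(value)
    validObject(x)
    x
})

#' @describeIn MassFeatureSet-accessors the intensity matrix (NA = missing).
#' @export
setMethod("intensityMatrix", "MassFeatureSet", function(x)
    assays(x)[["intensity"]])

#' @describeIn MassFeatureSet-accessors feature ids.
#' @export
setMethod("featureIds", "MassFeatureSet", function(x) rownames(x))

#' @describeIn MassFeatureSet-accessors sample ids.
#' @export
setMethod("sampleIds", "MassFeatureSet", function(x) colnames(x))

#' @describeIn MassFeatureSet-accessors logical presence matrix
#'   (TRUE = feature detected in sample).
#' @export
setMethod("occurrenceMatrix", "MassFeatureSet", function(x)
    !is.na(assays(x)[["intensity"]]))

#' @export
setMethod("show", "MassFeatureSet", function(object) {
    x <- assays(object)[["intensity"]]
    cat(sprintf("MassFeatureSet: %d features x %d samples\n",
                nrow(object), ncol(object)))
    if (nrow(object))
        cat(sprintf("  mass range: %.6f - %.6f Da\n",
                    min(rowData(object)$neutral_mass),
                    max(rowData(object)$neutral_mass)))
    if (ncol(object)) {
        cl <- colData(object)$class_label
        cat(sprintf("  classes: %s\n",
                    paste(names(table(cl)), table(cl), sep = ":", collapse = " ")))
        cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(is.na(x))))
    }
})

#' Read an aligned feature x sample matrix
#'
#' Parses a TSV/CSV with one row per feature: a feature-id column (optional,
#' first column if named \code{feature_id}), a mass column (named
#' \code{neutral_mass}, \code{mass} or \code{m/z}) and one intensity column
#' per sample. Empty cells, \code{NA} and (by default) zeros become missing
#' values; masses are parsed at full precision.
#'
#' Class labels and blank-sample names are supplied through a sidecar JSON
#' config (\code{classes}: sample id to label map; optional \code{blanks}:
#' character vector) rather than encoded in sample names.
#'
#' @param path delimited text file (delimiter sniffed from the extension:
#'   \code{.csv} is comma, anything else tab).
#' @param zeroIsMissing logical; treat 0 as missing (alignment software
#'   commonly writes 0 for absence). Default TRUE.
#' @param configPath optional sidecar JSON with class labels / blank ids.
#' @return a [MassFeatureSet-class]; blank ids from the sidecar are stored in
#'   \code{metadata(x)$blanks}.
#' @export
readAlignedMatrix <- function(path, zeroIsMissing = TRUE, configPath = NULL) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, colClasses = "character",
                            na.strings = c("", "NA"))
    nm <- names(df)
    idCol <- which(tolower(nm) %in% c("feature_id", "feature", "id"))[1]
    massCol <- which(tolower(nm) %in% c("neutral_mass", "mass", "m/z", "mz"))[1]
    if (is.na(massCol)) stop("no mass column found (neutral_mass/mass/m/z)")
    ids <- if (!is.na(idCol)) df[[idCol]] else sprintf("F%04d", seq_len(nrow(df)))
    if (anyDuplicated(ids))
        stop("duplicate feature ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    mass <- suppressWarnings(as.numeric(df[[massCol]]))
    if (any(is.na(mass) & !is.na(df[[massCol]])) || any(is.na(mass)))
        stop("non-numeric mass at row(s): ",
             paste(which(is.na(mass)), collapse = ", "))
    sampleCols <- setdiff(seq_along(nm), c(idCol, massCol))
    x <- vapply(df[sampleCols], function(col) suppressWarnings(as.numeric(col)),
                numeric(nrow(df)))
    x <- matrix(x, nrow = nrow(df),
                dimnames = list(ids, nm[sampleCols]))
    if (zeroIsMissing) x[!is.na(x) & x == 0] <- NA
    labels <- rep(NA_character_, ncol(x))
    names(labels) <- colnames(x)
    blanks <- character(0)
    if (!is.null(configPath)) {
        cfg <- jsonlite::read_json(configPath, simplifyVector = TRUE)
        if (!is.null(cfg$classes)) {
            cl <- unlist(cfg$classes)
            labels[intersect(names(cl), names(labels))] <-
                cl[intersect(names(cl), names(labels))]
        }
        if (!is.null(cfg$blanks)) blanks <- as.character(cfg$blanks)
    }
    out <- MassFeatureSet(x, mass, labels)
    metadata(out)$blanks <- blanks
    out
}

#' Write an aligned matrix to TSV
#'
#' Columns: \code{feature_id}, \code{neutral_mass} (full precision), one
#' column per sample; missing cells written empty. A sidecar JSON with the
#' class labels can be written next to it. Round-trips through
#' [readAlignedMatrix()] reproduce masses and the exact missingness pattern.
#'
#' @param x a [MassFeatureSet-class].
#' @param path output TSV path.
#' @param configPath optional path for the class-label sidecar JSON.
#' @return invisibly, \code{path}.
#' @export
writeAlignedMatrix <- function(x, path, configPath = NULL) {
    df <- data.frame(feature_id = featureIds(x),
                     neutral_mass = sprintf("%.9f", neutralMass(x)),
                     check.names = FALSE)
    m <- intensityMatrix(x)
    for (s in colnames(m)) df[[s]] <- ifelse(is.na(m[, s]), "",
                                             format(m[, s], digits = 15))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(configPath)) {
        cl <- as.list(classLabels(x))
        jsonlite::write_json(list(classes = cl), configPath, auto_unbox = TRUE)
    }
    invisible(path)
}
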