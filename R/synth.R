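#' Synthetic aligned matrices with planted transformation families
#'
#' Emulates the structure that sample mass-difference networks exploit in
#' real high-resolution data: CHNOPS formulas within biologically plausible
#' elemental-ratio bounds, families of features linked by exact MDB mass
#' differences (the planted edges), sub-ppm mass error, class-structured
#' feature occurrence (each class over-expresses features generated by its
#' own enriched MDB), log-normal intensities and missingness encoding
#' absence.
#'
#' @name synthetic-data
NULL

## elemental-ratio plausibility bounds for generated formulas:
## H/C 0.2-3.1, O/C <= 1.5, N/C <= 1.3, S/C <= 0.8, P/C <= 0.3, P/O <= 0.34,
## at least one carbon and one hydrogen
.validFormula <- function(cnt) {
    if (any(cnt < 0)) return(FALSE)
    C <- cnt[["C"]]; H <- cnt[["H"]]
    if (C < 1 || H < 1) return(FALSE)
    if (H < 0.2 * C || H > 3.1 * C) return(FALSE)
    if (cnt[["O"]] > 1.5 * C) return(FALSE)
    if (cnt[["N"]] > 1.3 * C) return(FALSE)
    if (cnt[["S"]] > 0.8 * C) return(FALSE)
    if (cnt[["P"]] > 0.3 * C) return(FALSE)
    if (cnt[["P"]] > 0.34 * cnt[["O"]]) return(FALSE)
    TRUE
}

.formulaString <- function(cnt) {
    paste0(vapply(.ELEMENTS, function(e)
        if (cnt[[e]] > 0) paste0(e, cnt[[e]]) else "", character(1)),
        collapse = "")
}

#' @describeIn synthetic-data draw \code{n} distinct random CHNOPS formulas
#'   obeying all ratio bounds, with monoisotopic masses inside
#'   \code{massRange}. Rejection sampling around metabolite-like element
#'   distributions; reproducible under \code{seed}.
#' @param n number of formulas.
#' @param seed RNG seed.
#' @param massRange allowed monoisotopic mass window (Da).
#' @return integer matrix n x 6 (columns C,H,N,O,P,S), rownames = formula
#'   strings.
#' @export
generateFormulaUniverse <- function(n, seed = 1, massRange = c(80, 1000)) {
    stopifnot(n >= 1)
    withSeed(seed, {
        out <- matrix(0L, nrow = 0, ncol = length(.ELEMENTS),
                      dimnames = list(NULL, .ELEMENTS))
        seen <- character(0)
        while (nrow(out) < n) {
            C <- sample(4:35, 1)
            H <- max(1L, min(round(3.1 * C),
                             round(stats::rnorm(1, 1.7 * C, 0.35 * C))))
            O <- stats::rbinom(1, min(round(1.5 * C), 14L), 0.35)
            N <- stats::rbinom(1, min(round(1.3 * C), 6L), 0.2)
            S <- stats::rbinom(1, 2L, 0.08)
            P <- stats::rbinom(1, 2L, 0.08)
            cnt <- c(C = C, H = H, N = N, O = O, P = P, S = S)[.ELEMENTS]
            if (!.validFormula(cnt)) next
            m <- monoisotopicMass(rbind(cnt))
            if (m < massRange[1] || m > massRange[2]) next
            key <- .formulaString(cnt)
            if (key %in% seen) next
            seen <- c(seen, key)
            out <- rbind(out, cnt)
        }
        rownames(out) <- seen
        out
    })
}

#' @describeIn synthetic-data grow MDB-linked families: starting from seed
#'   formulas, repeatedly apply a randomly chosen MDB delta (addition or
#'   subtraction) to a randomly chosen family member, keeping only results
#'   that remain valid formulas inside \code{massRange} and are new; each
#'   accepted application is recorded as a planted (parent, child, mdb)
#'   edge. With \code{depth} rounds each seed family gains up to
#'   \code{depth} members.
#' @param seeds formula count matrix (rownames = formula strings), e.g. from
#'   [generateFormulaUniverse()].
#' @param mdbs an [MDBTable-class] supplying the deltas.
#' @param depth applications per seed family.
#' @param maxTries rejection retries per attempted application.
#' @return list with \code{formulas} (count matrix, seeds first) and
#'   \code{edges} (data.frame parent, child, mdb).
#' @export
growMDBFamilies <- function(seeds, mdbs = defaultMDBs(), depth = 4,
                            seed = 1, massRange = c(80, 1000),
                            maxTries = 20) {
    stopifnot(depth >= 0)
    counts <- mdbCounts(mdbs)
    withSeed(seed, {
        formulas <- seeds
        family <- lapply(seq_len(nrow(seeds)), function(i) i)
        edges <- data.frame(parent = character(0), child = character(0),
                            mdb = character(0), stringsAsFactors = FALSE)
        for (d in seq_len(depth)) {
            for (fam in seq_along(family)) {
                for (try in seq_len(maxTries)) {
                    parent <- sample(family[[fam]], 1)
                    b <- sample(length(mdbs), 1)
                    sign <- sample(c(-1L, 1L), 1)
                    cand <- formulas[parent, ] + sign * counts[b, ]
                    if (!.validFormula(cand)) next
                    m <- monoisotopicMass(rbind(cand))
                    if (m < massRange[1] || m > massRange[2]) next
                    key <- .formulaString(cand)
                    if (key %in% rownames(formulas)) next
                    formulas <- rbind(formulas, cand)
                    rownames(formulas)[nrow(formulas)] <- key
                    family[[fam]] <- c(family[[fam]], nrow(formulas))
                    edges <- rbind(edges, data.frame(
                        parent = rownames(formulas)[parent], child = key,
                        mdb = mdbLabels(mdbs)[b], stringsAsFactors = FALSE))
                    break
                }
            }
        }
        list(formulas = formulas, edges = edges)
    })
}

#' Synthetic-dataset configuration
#'
#' Defaults mirror a small but realistic high-resolution study: three
#' classes of five replicates, a few hundred features spanning 80-1000 Da,
#' sub-ppm consensus mass error (0.2 ppm, well inside the 1 ppm matching
#' tolerance), strong class structure in occurrence (90% presence of a
#' class's own enriched features against a 10% background) and log-normal
#' intensities on the scale of FT-ICR peak heights.
#'
#' @param nClasses number of classes.
#' @param samplesPerClass replicates per class.
#' @param nSeedFormulas seed formulas for family growth.
#' @param familyDepth MDB applications per seed family.
#' @param corePresenceProb Bernoulli presence probability of core features
#'   in every sample.
#' @param enrichedPresenceProb presence of a class's enriched features in
#'   its own samples.
#' @param backgroundPresenceProb presence of enriched features outside their
#'   class.
#' @param enrichedMdbPerClass character vector of MDB labels (one per
#'   class); \code{NULL} picks the first \code{nClasses} of CH2, O, H2O,
#'   CO, H2. Core families are grown with the remaining MDBs so a class's
#'   enriched transformation only enters the network through that class's
#'   planted features.
#' @param enrichedPerClassFraction fraction of core features each class's
#'   MDB is applied to.
#' @param massErrorPpm consensus mass error, applied once per feature.
#' @param intensityMeanlog,intensitySdlog log-normal intensity parameters.
#' @param mdbs the [MDBTable-class] universe.
#' @param seed master seed.
#' @return list of class \code{synth_config}.
#' @export
syntheticConfig <- function(nClasses = 3, samplesPerClass = 5,
                            nSeedFormulas = 30, familyDepth = 4,
                            corePresenceProb = 0.8,
                            enrichedPresenceProb = 0.9,
                            backgroundPresenceProb = 0.1,
                            enrichedMdbPerClass = NULL,
                            enrichedPerClassFraction = 0.4,
                            massErrorPpm = 0.2,
                            intensityMeanlog = 14, intensitySdlog = 1,
                            mdbs = defaultMDBs(), seed = 42) {
    if (is.null(enrichedMdbPerClass))
        enrichedMdbPerClass <- c("CH2", "O", "H2O", "CO", "H2")[seq_len(nClasses)]
    stopifnot(length(enrichedMdbPerClass) == nClasses,
              all(enrichedMdbPerClass %in% mdbLabels(mdbs)),
              corePresenceProb >= 0, corePresenceProb <= 1,
              enrichedPresenceProb >= 0, enrichedPresenceProb <= 1,
              backgroundPresenceProb >= 0, backgroundPresenceProb <= 1,
              massErrorPpm >= 0)
    structure(as.list(environment()), class = "synth_config")
}

#' @describeIn synthetic-data generate a full synthetic
#'   [MassFeatureSet-class] plus ground truth. Core families are grown from
#'   random seed formulas with the non-enriched MDBs and are present in
#'   every sample at \code{corePresenceProb}; each class additionally plants
#'   children of its enriched MDB on a random subset of core features, which
#'   occur at \code{enrichedPresenceProb} inside the class and
#'   \code{backgroundPresenceProb} elsewhere. Consensus masses carry one
#'   uniform relative error per feature; detected cells get log-normal
#'   intensities, absent cells are missing.
#' @param cfg a [syntheticConfig()].
#' @return list with \code{data} (a \code{MassFeatureSet}) and \code{truth}
#'   (formulas, exact masses, planted edges, per-class enriched MDB,
#'   per-feature enrichment class, labels).
#' @export
generateDataset <- function(cfg = syntheticConfig()) {
    stopifnot(inherits(cfg, "synth_config"))
    seeds <- generateFormulaUniverse(cfg$nSeedFormulas,
                                     seed = .subSeed(cfg$seed, 1))
    coreMdbs <- cfg$mdbs[setdiff(mdbLabels(cfg$mdbs), cfg$enrichedMdbPerClass)]
    fam <- growMDBFamilies(seeds, coreMdbs, depth = cfg$familyDepth,
                           seed = .subSeed(cfg$seed, 2))
    formulas <- fam$formulas
    edges <- fam$edges
    nCore <- nrow(formulas)
    enrichClass <- rep(NA_character_, nCore)
    classes <- LETTERS[seq_len(cfg$nClasses)]
    counts <- mdbCounts(cfg$mdbs)
    withSeed(.subSeed(cfg$seed, 3), {
        for (ci in seq_len(cfg$nClasses)) {
            b <- match(cfg$enrichedMdbPerClass[ci], mdbLabels(cfg$mdbs))
            parents <- sample(nCore,
                              max(2, round(cfg$enrichedPerClassFraction * nCore)))
            for (p in parents) {
                cand <- formulas[p, ] + counts[b, ]
                if (!.validFormula(cand)) cand <- formulas[p, ] - counts[b, ]
                if (!.validFormula(cand)) next
                m <- monoisotopicMass(rbind(cand))
                if (m < 80 || m > 1000) next
                key <- .formulaString(cand)
                if (key %in% rownames(formulas)) next
                formulas <- rbind(formulas, cand)
                rownames(formulas)[nrow(formulas)] <- key
                enrichClass <- c(enrichClass, classes[ci])
                edges <- rbind(edges, data.frame(
                    parent = rownames(formulas)[p], child = key,
                    mdb = mdbLabels(cfg$mdbs)[b], stringsAsFactors = FALSE))
            }
        }
    })
    nFeat <- nrow(formulas)
    exactMass <- monoisotopicMass(formulas)
    labels <- rep(classes, each = cfg$samplesPerClass)
    sampleIds <- paste0(rep(classes, each = cfg$samplesPerClass), "_",
                        rep(seq_len(cfg$samplesPerClass), cfg$nClasses))
    withSeed(.subSeed(cfg$seed, 4), {
        obsMass <- exactMass *
            (1 + stats::runif(nFeat, -cfg$massErrorPpm, cfg$massErrorPpm) * 1e-6)
        prob <- matrix(cfg$corePresenceProb, nrow = nFeat,
                       ncol = length(labels))
        for (ci in seq_len(cfg$nClasses)) {
            rows <- which(enrichClass == classes[ci])
            prob[rows, ] <- cfg$backgroundPresenceProb
            prob[rows, labels == classes[ci]] <- cfg$enrichedPresenceProb
        }
        present <- matrix(stats::runif(length(prob)) < prob, nrow = nFeat)
        for (j in seq_len(ncol(present))) {
            tries <- 0
            while (!any(present[, j]) && tries < 100) {
                present[, j] <- stats::runif(nFeat) < prob[, j]
                tries <- tries + 1
            }
            if (!any(present[, j])) stop("sample ", sampleIds[j],
                                         " drew no features")
        }
        x <- matrix(NA_real_, nFeat, length(labels),
                    dimnames = list(rownames(formulas), sampleIds))
        x[present] <- stats::rlnorm(sum(present), cfg$intensityMeanlog,
                                    cfg$intensitySdlog)
    })
    data <- MassFeatureSet(x, obsMass, stats::setNames(labels, sampleIds))
    list(data = data,
         truth = list(formulas = formulas, exactMass = exactMass,
                      observedMass = stats::setNames(obsMass,
                                                     rownames(formulas)),
                      plantedEdges = edges,
                      enrichedMdbPerClass = stats::setNames(
                          cfg$enrichedMdbPerClass, classes),
                      featureEnrichedClass = stats::setNames(
                          enrichClass, rownames(formulas)),
                      classLabels = stats::setNames(labels, sampleIds)))
}
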