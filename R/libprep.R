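# Library preparation: molecule descriptors, the five filtering rules used
# to assemble in-silico EI-MS libraries from structure databases, and
# within/cross-dataset deduplication.
#
# Descriptors come from Open Babel (via ChemmineOB): average molecular
# weight, Crippen-type logP, molecular formula (for the element whitelist)
# and InChI/InChIKey. The canonical identity key is the full 27-character
# InChIKey, which is robust to SMILES representation differences; canonical
# SMILES is available as an alternative.

#' The 11-element whitelist for EI-MS library molecules
#'
#' Elements compatible with GC-MS analysis of volatile small molecules:
#' H, C, O, N, P, S, Cl, F, Br, I, Si.
#' @export
elementWhitelist <- c("H", "C", "O", "N", "P", "S", "Cl", "F", "Br", "I", "Si")

#' Compute molecule descriptors from SMILES
#'
#' Parses each SMILES with the structure toolkit and returns, per
#' molecule: canonical identity key, average molecular weight (Da),
#' element set, ionic flag and Crippen-type logP. A molecule is flagged
#' ionic when any atom carries a nonzero formal charge after sanitization
#' (detected through the InChI charge/proton layers) or the record is a
#' multi-fragment salt with charged components.
#'
#' @param smiles character vector of SMILES strings.
#' @param dataset source tag recorded with each molecule.
#' @param key identity key type: \code{"inchikey"} (default) or
#'   \code{"cansmi"}.
#' @return data.frame with columns \code{smiles}, \code{canonical_key},
#'   \code{mol_mass}, \code{elements} (list column of element symbols),
#'   \code{is_ionic}, \code{logp}, \code{dataset}.
#' @examples
#' \donttest{
#' computeDescriptors(c("CCO", "[Na+].[Cl-]"))
#' }
#' @export
computeDescriptors <- function(smiles, dataset = "",
                               key = c("inchikey", "cansmi")) {
    key <- match.arg(key)
    rows <- lapply(smiles, function(smi) {
        d <- tryCatch(.obDescriptors(smi, key),
                      error = function(e)
                          stop("cannot compute descriptors for SMILES '",
                               smi, "': ", conditionMessage(e), call. = FALSE))
        d
    })
    out <- data.frame(
        smiles = as.character(smiles),
        canonical_key = vapply(rows, `[[`, character(1), "key"),
        mol_mass = vapply(rows, `[[`, numeric(1), "mw"),
        is_ionic = vapply(rows, `[[`, logical(1), "ionic"),
        logp = vapply(rows, `[[`, numeric(1), "logp"),
        dataset = dataset,
        stringsAsFactors = FALSE
    )
    out$elements <- lapply(rows, `[[`, "elements")
    out[, c("smiles", "canonical_key", "mol_mass", "elements",
            "is_ionic", "logp", "dataset")]
}

.obDescriptors <- function(smi, key) {
    props <- ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", smi,
                                                        identity))
    formula <- props$formula[1L]
    if (is.na(formula) || !nzchar(formula) || props$MW[1L] <= 0)
        stop("unparseable or empty structure")
    inchi <- props$InChI[1L]
    cansmi <- props$cansmi[1L]
    ionic <- grepl("/q", inchi, fixed = TRUE) ||
        grepl("/p", inchi, fixed = TRUE) ||
        grepl("\\[[^]]*[+-][0-9]*\\]", cansmi)
    k <- if (key == "inchikey") {
        ik <- trimws(ChemmineOB::convertFormat("SMI", "INCHIKEY", smi))
        if (!nzchar(ik)) stop("InChIKey generation failed")
        ik
    } else {
        cansmi
    }
    list(key = k, mw = props$MW[1L], elements = .parseFormula(formula),
         ionic = ionic, logp = props$logP[1L])
}

# element symbols from a Hill formula, ignoring any trailing charge
.parseFormula <- function(formula) {
    formula <- gsub("[+-][0-9]*$", "", formula)
    m <- gregexpr("[A-Z][a-z]?", formula)[[1L]]
    unique(substring(formula, m, m + attr(m, "match.length") - 1L))
}

#' Apply the library filtering rules R1-R4
#'
#' The four per-molecule rules for EI-MS library membership:
#' \itemize{
#'   \item R1: molecular mass strictly less than \code{massMax} (1000 Da);
#'   \item R2: all elements within the 11-element whitelist;
#'   \item R3: not an ionic compound;
#'   \item R4: logP within \code{logpRange} (-12 to 24, inclusive bounds).
#' }
#' Rule R5 (deduplication) is a set-level operation handled by
#' [dedupWithin()] and [dedupAcross()]. The rules are order-independent
#' and a molecule passes iff all four pass.
#'
#' @param records descriptor data.frame from [computeDescriptors()].
#' @param massMax exclusive upper molecular-mass bound in Da.
#' @param logpRange inclusive logP bounds.
#' @param whitelist allowed element symbols.
#' @return the input data.frame with added columns \code{passed} (logical)
#'   and \code{failed_rules} (list column of rule identifiers).
#' @export
applyFilters <- function(records, massMax = 1000,
                         logpRange = c(-12, 24),
                         whitelist = elementWhitelist) {
    fails <- lapply(seq_len(nrow(records)), function(i) {
        f <- character(0)
        if (records$mol_mass[i] >= massMax) f <- c(f, "R1")
        if (!all(records$elements[[i]] %in% whitelist)) f <- c(f, "R2")
        if (records$is_ionic[i]) f <- c(f, "R3")
        if (records$logp[i] < logpRange[1L] || records$logp[i] > logpRange[2L])
            f <- c(f, "R4")
        f
    })
    records$failed_rules <- fails
    records$passed <- lengths(fails) == 0L
    records
}

#' Deduplicate molecules within one dataset (rule R5)
#'
#' Keeps the first occurrence of each canonical key; output order is
#' stable.
#'
#' @param records descriptor data.frame.
#' @return the deduplicated data.frame.
#' @export
dedupWithin <- function(records) {
    records[!duplicated(records$canonical_key), , drop = FALSE]
}

#' Deduplicate molecules across datasets
#'
#' Datasets are given in priority order: a molecule present in dataset i
#' is removed from every later dataset, so the union of the outputs has
#' strictly unique canonical keys.
#'
#' @param datasets list of descriptor data.frames, each already
#'   deduplicated within itself, ordered by priority.
#' @return list of data.frames of the same length, with cross-dataset
#'   duplicates removed from lower-priority members.
#' @export
dedupAcross <- function(datasets) {
    seen <- character(0)
    out <- vector("list", length(datasets))
    for (i in seq_along(datasets)) {
        d <- datasets[[i]]
        keep <- !(d$canonical_key %in% seen)
        out[[i]] <- d[keep, , drop = FALSE]
        seen <- c(seen, d$canonical_key[keep])
    }
    names(out) <- names(datasets)
    out
}

#' Bookkeeping of filtered library sizes
#'
#' Given the post-filter, cross-deduplicated component set sizes of a
#' library build, returns the composite set sizes implied by the
#' deduplication guarantee (disjoint components, so unions are sums).
#' \code{components} must be a named numeric vector; \code{compose} is a
#' named list mapping each composite to the component names it unions.
#'
#' @param components named numeric vector of disjoint component sizes.
#' @param compose named list of character vectors naming components.
#' @return named numeric vector of composite sizes.
#' @examples
#' librarySizes(c(a = 10, b = 5), list(ab = c("a", "b")))
#' @export
librarySizes <- function(components, compose) {
    stopifnot(!is.null(names(components)), !anyDuplicated(names(components)))
    vapply(compose, function(parts) {
        miss <- setdiff(parts, names(components))
        if (length(miss))
            stop("unknown components: ", paste(miss, collapse = ", "))
        sum(components[parts])
    }, numeric(1))
}

#' Read a SMILES list file
#'
#' One molecule per line; an optional tab-separated second field is taken
#' as the molecule id.
#'
#' @param path file path.
#' @return data.frame with columns \code{smiles} and \code{id}.
#' @export
readSmilesList <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t")
    data.frame(
        smiles = vapply(parts, `[[`, character(1), 1L),
        id = vapply(seq_along(parts), function(i)
            if (length(parts[[i]]) > 1L) parts[[i]][2L]
            else sprintf("mol%d", i), character(1)),
        stringsAsFactors = FALSE
    )
}

#' Write a filter report table
#'
#' Tab-separated exclusion report: one row per molecule with its key,
#' descriptors, pass flag and failed rules.
#'
#' @param records filtered data.frame from [applyFilters()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeFilterReport <- function(records, path) {
    out <- data.frame(
        smiles = records$smiles,
        canonical_key = records$canonical_key,
        mol_mass = records$mol_mass,
        elements = vapply(records$elements, paste, character(1),
                          collapse = ","),
        is_ionic = records$is_ionic,
        logp = records$logp,
        dataset = records$dataset,
        passed = records$passed,
        failed_rules = vapply(records$failed_rules, paste, character(1),
                              collapse = ","),
        stringsAsFactors = FALSE
    )
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
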