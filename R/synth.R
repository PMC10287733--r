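# Synthetic EI-MS data generator. Stands in for an in-silico predicted
# library plus measured queries: sparse integer-m/z spectra with
# heavy-tailed intensities, fragment co-occurrence structure for the
# embedding to learn, and a tunable measured-vs-predicted perturbation
# model (intensity jitter, peak dropout, spurious peaks, and swaps of a
# fragment to its alternative m/z position).

#' Construct SynthParams
#'
#' Defaults describe the benchmark conditions used throughout the
#' package's tests: a 2000-molecule library over m/z 50-500, a mean of 30
#' peaks per spectrum, Pareto(1.2) intensity tails, a 300-fragment shared
#' pool organized into 80 molecule classes, and a perturbation level
#' calibrated so that the median weighted cosine between a spectrum and
#' its perturbed copy falls in the 0.7-0.95 band typical of
#' predicted-vs-measured EI spectra.
#'
#' @param nMolecules library size.
#' @param mzRange integer (min, max) fragment m/z in Da, within (0, 1000].
#' @param peaksPerSpectrum mean peak count (Poisson, floored at 3).
#' @param intensityTail Pareto shape for intensities (smaller = heavier
#'   tail).
#' @param sharedFragmentPool size of the common fragment vocabulary.
#' @param nClasses number of molecule classes sharing fragment signatures.
#' @param noise list: \code{jitterSd}, \code{dropoutProb},
#'   \code{spuriousRate}, \code{swapProb} (see [SynthParams-class]).
#' @param seed RNG seed.
#' @return a [SynthParams-class].
#' @export
SynthParams <- function(nMolecules = 2000L, mzRange = c(50L, 500L),
                        peaksPerSpectrum = 30, intensityTail = 1.2,
                        sharedFragmentPool = 300L,
                        nClasses = max(1L, as.integer(nMolecules / 25)),
                        noise = list(jitterSd = 0.25, dropoutProb = 0.08,
                                     spuriousRate = 2, swapProb = 0.45),
                        seed = 1L) {
    new("SynthParams", nMolecules = as.integer(nMolecules),
        mzRange = as.integer(mzRange),
        peaksPerSpectrum = peaksPerSpectrum,
        intensityTail = intensityTail,
        sharedFragmentPool = as.integer(sharedFragmentPool),
        nClasses = as.integer(nClasses), noise = noise,
        seed = as.integer(seed))
}

# run expr under a local, seeded RNG without disturbing the caller's state
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", globalenv())
        on.exit(assign(".Random.seed", old, globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Generate a synthetic spectral library
#'
#' Each molecule belongs to a class; its spectrum mixes fragments from
#' the class signature (co-occurring across the class), fragments from
#' the global shared pool, and private fragments unique to the molecule.
#' Every pool fragment carries an alternative m/z one or two Da away; a
#' molecule's spectrum uses one of the two positions, and different
#' molecules choose differently, so both positions co-occur with the same
#' companions across the corpus — the structure a peak-word embedding can
#' learn. Intensities are Pareto-tailed and base-peak normalized; the
#' metadata mass sits a few Da above the largest fragment. Deterministic
#' given the seed.
#'
#' @param p a [SynthParams-class].
#' @return list with elements \code{spectra} (list of
#'   [Spectrum-class], source \code{"predicted"}), \code{truth} (named
#'   character, spectrum id -> molecule key), \code{mass} (named numeric,
#'   spectrum id -> molecular mass) and \code{altMz} (named list,
#'   spectrum id -> named numeric mapping a peak's m/z to its alternative
#'   position, used by [perturbSpectrum()]).
#' @export
makeLibrary <- function(p) {
    stopifnot(is(p, "SynthParams"))
    if (p@nMolecules < 1L) stop("nMolecules must be >= 1")
    .withSeed(p@seed, {
        lo <- p@mzRange[1L]
        hi <- p@mzRange[2L]
        poolN <- min(p@sharedFragmentPool, hi - lo + 1L)
        poolMz <- sort(sample(lo:hi, poolN))
        poolAlt <- poolMz + sample(c(-2L, -1L, 1L, 2L), poolN, replace = TRUE)
        poolAlt <- pmin(pmax(poolAlt, lo), hi)
        sigSize <- 12L
        classSig <- lapply(seq_len(p@nClasses), function(c)
            sample(poolN, min(sigSize, poolN)))
        classOf <- sample(p@nClasses, p@nMolecules, replace = TRUE)

        spectra <- vector("list", p@nMolecules)
        altMz <- vector("list", p@nMolecules)
        ids <- sprintf("LIB%05d", seq_len(p@nMolecules))
        keys <- sprintf("MOL%05d", seq_len(p@nMolecules))
        mass <- numeric(p@nMolecules)
        for (i in seq_len(p@nMolecules)) {
            k <- max(3L, rpois(1L, p@peaksPerSpectrum))
            sig <- classSig[[classOf[i]]]
            # ~60% class-signature fragments, ~20% global pool, remainder
            # private; topped up so the spectrum has exactly k distinct
            # peaks and the Poisson peak-count law holds empirically
            fragIdx <- sample(sig, min(round(0.6 * k), length(sig)))
            nShared <- min(round(0.2 * k), poolN)
            fragIdx <- unique(c(fragIdx, sample(poolN, nShared)))
            # per-molecule variant choice: primary or alternative position
            useAlt <- runif(length(fragIdx)) < 0.5
            fmz <- ifelse(useAlt, poolAlt[fragIdx], poolMz[fragIdx])
            alt <- ifelse(useAlt, poolMz[fragIdx], poolAlt[fragIdx])
            keep <- !duplicated(fmz)
            fmz <- fmz[keep][seq_len(min(sum(keep), k))]
            alt <- alt[keep][seq_len(length(fmz))]
            avail <- setdiff(lo:hi, fmz)
            nPriv <- max(0L, k - length(fmz))
            pmz <- if (nPriv > 0L) sample(avail, min(nPriv, length(avail)))
                   else integer(0)
            mzv <- c(fmz, pmz)
            ints <- runif(length(mzv))^(-1 / p@intensityTail)
            mass[i] <- max(mzv) + sample(0:20, 1L)
            s <- normalizeSpectrum(Spectrum(ids[i], mzv, ints,
                                            name = keys[i],
                                            molMass = mass[i],
                                            source = "predicted"))
            spectra[[i]] <- s
            altMz[[i]] <- setNames(alt, fmz)
        }
        names(altMz) <- ids
        list(spectra = spectra, truth = setNames(keys, ids),
             mass = setNames(mass, ids), altMz = altMz)
    })
}

#' Perturb a spectrum (measured-vs-predicted gap)
#'
#' Applies, in order: fragment-position swaps (each peak listed in
#' \code{altMz} moves to its alternative m/z with probability
#' \code{swapProb}), multiplicative log-normal intensity jitter, peak
#' dropout (never dropping below one peak; the base peak survives a total
#' wipe-out), and spurious low-intensity peaks (Poisson count). The
#' result is re-normalized. With all noise terms zero the input is
#' returned exactly. Neither the molecule key (name) nor the metadata
#' mass is changed.
#'
#' @param s a [Spectrum-class].
#' @param p a [SynthParams-class] (its \code{noise} is used).
#' @param altMz named numeric mapping m/z to alternative m/z (optional;
#'   from [makeLibrary()]).
#' @param id id for the perturbed copy (default: \code{"Q<id>"}).
#' @return the perturbed [Spectrum-class], source \code{"measured"}.
#' @export
perturbSpectrum <- function(s, p, altMz = NULL,
                            id = paste0("Q", spectrumId(s))) {
    stopifnot(is(s, "Spectrum"), is(p, "SynthParams"))
    nz <- p@noise
    if (nz$jitterSd == 0 && nz$dropoutProb == 0 && nz$spuriousRate == 0 &&
        nz$swapProb == 0) {
        out <- s
        out@id <- as.character(id)
        out@source <- "measured"
        return(out)
    }
    mzv <- mz(s)
    iv <- intensity(s)
    if (!is.null(altMz) && length(altMz) && nz$swapProb > 0) {
        hit <- match(names(altMz), as.character(mzv))
        swap <- !is.na(hit) & runif(length(altMz)) < nz$swapProb
        mzv[hit[swap]] <- unname(altMz[swap])
    }
    if (nz$jitterSd > 0)
        iv <- iv * exp(rnorm(length(iv), 0, nz$jitterSd))
    if (nz$dropoutProb > 0) {
        keep <- runif(length(iv)) >= nz$dropoutProb
        if (!any(keep)) keep[which.max(iv)] <- TRUE
        mzv <- mzv[keep]
        iv <- iv[keep]
    }
    if (nz$spuriousRate > 0) {
        nspur <- rpois(1L, nz$spuriousRate)
        if (nspur > 0L) {
            smz <- sample(p@mzRange[1L]:p@mzRange[2L], nspur, replace = TRUE)
            sint <- runif(nspur, 0, 0.05) * max(iv)
            mzv <- c(mzv, smz)
            iv <- c(iv, sint)
        }
    }
    normalizeSpectrum(Spectrum(id, mzv, iv, name = s@name,
                               smiles = s@smiles, molMass = s@molMass,
                               source = "measured"))
}

#' Generate a perturbed query set from a library
#'
#' Perturbs each selected library spectrum once under a local seeded RNG,
#' producing measured-style queries whose truth keys and masses are
#' inherited from the library.
#'
#' @param lib library list from [makeLibrary()].
#' @param p a [SynthParams-class].
#' @param which indices or ids of library spectra to perturb (default:
#'   all).
#' @param seed RNG seed for the perturbations.
#' @return list with \code{spectra}, \code{truth} and \code{mass} for the
#'   queries.
#' @export
makeQueries <- function(lib, p, which = NULL, seed = p@seed + 1L) {
    ids <- vapply(lib$spectra, spectrumId, character(1))
    sel <- if (is.null(which)) seq_along(ids)
           else if (is.character(which)) match(which, ids)
           else which
    .withSeed(seed, {
        qs <- lapply(sel, function(i)
            perturbSpectrum(lib$spectra[[i]], p, altMz = lib$altMz[[ids[i]]]))
        qids <- vapply(qs, spectrumId, character(1))
        list(spectra = qs,
             truth = setNames(unname(lib$truth[ids[sel]]), qids),
             mass = setNames(unname(lib$mass[ids[sel]]), qids))
    })
}
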