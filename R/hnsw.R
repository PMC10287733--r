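# R surface of the from-scratch HNSW index. The graph lives in native
# code behind an external pointer; these wrappers add the S4 handle,
# validity checks, structural audits and a versioned plain-text (JSON)
# persistence format.

#' Construct HNSWParams
#'
#' @param M maximum bidirectional links per node per layer; layer 0 allows
#'   \code{2*M}.
#' @param efConstruction candidate-list size during insertion.
#' @param ef candidate-list size during search.
#' @param mL level-generation multiplier; default \code{1/log(M)}, the
#'   standard choice for the exponential level law.
#' @param seed RNG seed for level assignment.
#' @param heuristic spread-preserving neighbour selection (default) or
#'   plain closest-M (\code{FALSE}).
#' @return an [HNSWParams-class].
#' @export
HNSWParams <- function(M = 64L, efConstruction = 600L, ef = 300L,
                       mL = 1 / log(M), seed = 1L, heuristic = TRUE) {
    new("HNSWParams", M = as.integer(M),
        efConstruction = as.integer(efConstruction), ef = as.integer(ef),
        mL = mL, seed = as.integer(seed), heuristic = heuristic)
}

#' Create an empty HNSW index
#'
#' @param dim vector dimensionality.
#' @param params an [HNSWParams-class].
#' @return an [HNSWIndex-class] handle.
#' @export
hnswIndex <- function(dim, params = HNSWParams()) {
    stopifnot(is(params, "HNSWParams"))
    ptr <- .hnsw_create(as.integer(dim), params@M, params@efConstruction,
                        params@ef, params@mL, as.double(params@seed),
                        params@heuristic)
    new("HNSWIndex", ptr = ptr, dim = as.integer(dim), params = params)
}

#' Insert vectors into an HNSW index
#'
#' Vectors are inserted sequentially in row order (the deterministic,
#' tested configuration): each draws a level from the exponential level
#' law, descends greedily from the entry point to its level, then links
#' bidirectionally to M selected neighbours per layer, pruning overfull
#' neighbour lists. The index is modified in place; duplicate ids and
#' dimension mismatches are errors.
#'
#' @param index an [HNSWIndex-class].
#' @param vectors numeric matrix (rows = vectors) or a single vector.
#' @param ids character ids; defaults to the matrix rownames.
#' @return the index, invisibly.
#' @export
hnswInsert <- function(index, vectors, ids = rownames(vectors)) {
    stopifnot(is(index, "HNSWIndex"))
    if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1L)
    if (is.null(ids)) stop("ids are required (or set matrix rownames)")
    if (anyDuplicated(ids)) stop("duplicate ids in insertion batch")
    .hnsw_insert(index@ptr, as.character(ids), vectors)
    invisible(index)
}

#' k-nearest-neighbour search in an HNSW index
#'
#' Greedy descent with candidate-list size 1 from the top layer to
#' layer 1, then a full search-layer pass with candidate-list size
#' \code{ef} on layer 0; the K nearest of the dynamic candidate list are
#' returned by ascending squared Euclidean distance. Requires
#' \code{K <= ef}.
#'
#' @param index an [HNSWIndex-class].
#' @param q query vector, or matrix of queries (rows).
#' @param K neighbours to return.
#' @param ef search-time candidate-list size; defaults to the index
#'   parameter.
#' @return for a single query, a candidate data.frame with columns
#'   \code{rank}, \code{id}, \code{distance} (squared Euclidean) and
#'   \code{similarity} (cosine, assuming unit-norm vectors:
#'   \eqn{1 - d/2}); for a query matrix, a list of such data.frames.
#' @export
hnswSearch <- function(index, q, K, ef = index@params@ef) {
    stopifnot(is(index, "HNSWIndex"))
    single <- is.null(dim(q))
    if (single) q <- matrix(q, nrow = 1L)
    if (K > ef) stop("K must not exceed ef")
    res <- .hnsw_search(index@ptr, q, as.integer(K), as.integer(ef))
    out <- lapply(seq_len(nrow(q)), function(i) {
        d <- res$distances[[i]]
        df <- data.frame(
            rank = seq_along(d), id = res$ids[[i]], distance = d,
            similarity = 1 - d / 2, stringsAsFactors = FALSE
        )
        attr(df, "metric") <- "squared_euclidean"
        df
    })
    if (single) out[[1L]] else out
}

#' Number of vectors in an HNSW index
#' @param index an [HNSWIndex-class].
#' @return integer count.
#' @export
hnswSize <- function(index) .hnsw_size(index@ptr)

#' Distance-evaluation counter of an HNSW index
#'
#' Every squared-Euclidean evaluation performed by construction or search
#' is counted; the counter underpins the sublinear-scaling diagnostics.
#'
#' @param index an [HNSWIndex-class].
#' @param reset zero the counter after reading.
#' @return numeric count.
#' @export
hnswDistEvals <- function(index, reset = FALSE) {
    .hnsw_dist_evals(index@ptr, reset)
}

#' Dump the layered graph structure
#'
#' Returns ids, per-node levels, per-layer adjacency (1-based positions),
#' the entry point and the top level — the raw material for structural
#' audits.
#'
#' @param index an [HNSWIndex-class].
#' @return list with elements \code{ids}, \code{levels}, \code{layers},
#'   \code{entry}, \code{maxLevel}.
#' @export
hnswGraph <- function(index) .hnsw_graph(index@ptr)

#' Structural audit of an HNSW index
#'
#' Checks the three graph invariants: every edge is bidirectional within
#' its layer; neighbour-list lengths respect the degree bounds (M per
#' layer, 2M on layer 0); and a node of level l appears in layers 0..l
#' only. The entry point must sit on the top layer.
#'
#' @param index an [HNSWIndex-class].
#' @return named logical vector with elements \code{bidirectional},
#'   \code{degreeBounds}, \code{layerMembership}, \code{entryOnTop}.
#' @export
hnswAudit <- function(index) {
    g <- hnswGraph(index)
    M <- index@params@M
    n <- length(g$ids)
    bidir <- TRUE
    degree <- TRUE
    member <- TRUE
    for (layer in seq_along(g$layers)) {
        cap <- if (layer == 1L) 2L * M else M
        adj <- g$layers[[layer]]
        for (i in seq_len(n)) {
            nb <- adj[[i]]
            if (is.null(nb)) {
                if (g$levels[i] >= layer - 1L) member <- FALSE
                next
            }
            if (g$levels[i] < layer - 1L) member <- FALSE
            if (length(nb) > cap) degree <- FALSE
            for (j in nb)
                if (!(i %in% adj[[j]])) bidir <- FALSE
        }
    }
    entryOnTop <- n == 0L ||
        g$levels[g$entry] == g$maxLevel
    c(bidirectional = bidir, degreeBounds = degree,
      layerMembership = member, entryOnTop = entryOnTop)
}

#' Draw HNSW insertion levels
#'
#' Levels follow \eqn{l = \lfloor -\ln(u)\, m_L \rfloor} with u uniform on
#' (0,1), i.e. the survival function is \eqn{P(l \ge k) = e^{-k/m_L}}.
#' With \code{raw = TRUE} the underlying exponential draws (mean
#' \eqn{m_L}) are returned from the identical RNG stream, which is useful
#' for checking the level law against its closed form.
#'
#' @param n number of draws.
#' @param mL level multiplier (>= 0; 0 degenerates to level 0 always).
#' @param seed RNG seed.
#' @param raw return the continuous exponential draws instead of floors.
#' @return numeric vector of levels (or raw draws).
#' @export
assignLevel <- function(n, mL, seed = 1L, raw = FALSE) {
    .hnsw_assign_levels(as.integer(n), mL, as.double(seed), raw)
}

#' Save / load an HNSW index
#'
#' The index is written as a versioned JSON container holding the
#' parameters, RNG state, vectors at full precision, per-node levels and
#' per-layer adjacency. Loading reconstructs the graph exactly, so
#' subsequent searches are bit-identical; a file with a different or
#' missing version tag is an explicit error.
#'
#' @param index an [HNSWIndex-class].
#' @param path file path.
#' @return \code{hnswLoad}: the restored [HNSWIndex-class].
#' @export
hnswSave <- function(index, path) {
    s <- .hnsw_serialize(index@ptr)
    n <- length(s$ids)
    # adjacency as a flat (node, layer, neighbour) edge table: immune to
    # JSON shape simplification on reload
    edge <- do.call(rbind, lapply(seq_len(n), function(i) {
        nl <- s$links[[i]]
        do.call(rbind, lapply(seq_along(nl), function(l) {
            v <- nl[[l]]
            if (length(v) == 0L) NULL else cbind(i, l - 1L, as.integer(v))
        }))
    }))
    obj <- list(
        format = "eimatch-hnsw-1",
        dim = s$dim, M = s$M, efConstruction = s$efConstruction,
        ef = s$ef, mL = s$mL, seed = s$seed, heuristic = s$heuristic,
        rngState = s$rngState, entry = s$entry, maxLevel = s$maxLevel,
        ids = s$ids, levels = s$levels, vectors = s$vectors,
        edgeNode = if (is.null(edge)) integer(0) else edge[, 1L],
        edgeLayer = if (is.null(edge)) integer(0) else edge[, 2L],
        edgeNeighbor = if (is.null(edge)) integer(0) else edge[, 3L]
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                                null = "null"), path)
    invisible(path)
}

#' @rdname hnswSave
#' @export
hnswLoad <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    s <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE),
                                     simplifyVector = TRUE),
                  error = function(e) stop("corrupted index file: ", path))
    if (is.null(s$format) || !identical(s$format, "eimatch-hnsw-1"))
        stop("not an eimatch HNSW index file (or wrong version): ", path)
    n <- length(s$ids)
    vec <- s$vectors
    if (n == 0L) {
        params <- HNSWParams(M = s$M, efConstruction = s$efConstruction,
                             ef = s$ef, mL = s$mL, seed = s$seed,
                             heuristic = s$heuristic)
        idx <- hnswIndex(s$dim, params)
        return(idx)
    }
    if (is.null(dim(vec))) vec <- matrix(vec, nrow = n)
    levels <- as.integer(s$levels)
    links <- lapply(seq_len(n), function(i)
        rep(list(integer(0)), levels[i] + 1L))
    if (length(s$edgeNode)) {
        nodeF <- factor(s$edgeNode, levels = seq_len(n))
        byNode <- split(data.frame(layer = as.integer(s$edgeLayer),
                                   nb = as.integer(s$edgeNeighbor)), nodeF)
        for (i in seq_len(n)) {
            d <- byNode[[i]]
            if (nrow(d) == 0L) next
            for (l in unique(d$layer))
                links[[i]][[l + 1L]] <- d$nb[d$layer == l]
        }
    }
    ser <- list(dim = as.integer(s$dim), M = as.integer(s$M),
                efConstruction = as.integer(s$efConstruction),
                ef = as.integer(s$ef), mL = s$mL, seed = as.double(s$seed),
                heuristic = s$heuristic, rngState = as.character(s$rngState),
                entry = as.integer(s$entry), maxLevel = as.integer(s$maxLevel),
                ids = as.character(s$ids), levels = as.integer(s$levels),
                vectors = vec, links = links)
    ptr <- .hnsw_deserialize(ser)
    params <- HNSWParams(M = ser$M, efConstruction = ser$efConstruction,
                         ef = ser$ef, mL = ser$mL, seed = ser$seed,
                         heuristic = ser$heuristic)
    new("HNSWIndex", ptr = ptr, dim = ser$dim, params = params)
}

setMethod("show", "HNSWIndex", function(object) {
    info <- .hnsw_info(object@ptr)
    cat(sprintf(
        "HNSWIndex: %d vectors (d = %d), M = %d, efConstruction = %d, ef = %d, top level %d\n",
        info$count, info$dim, info$M, info$efConstruction, info$ef,
        info$maxLevel
    ))
    invisible(object)
})
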