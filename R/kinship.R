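#' Truncate a pedigree to a fixed number of ancestral generations
#'
#' Keeps each focal animal and every ancestor reachable within
#' \code{n_gen} parent steps; parents beyond the horizon are set unknown,
#' turning boundary ancestors into founders.
#'
#' @param ped data.frame (animal, sire, dam), \code{"0"} = unknown
#' @param focal_ids animals of interest (must be present)
#' @param n_gen number of parent steps to keep, default 4
#' @return truncated pedigree data.frame, parents before offspring
#' @export
truncatePedigree <- function(ped, focal_ids, n_gen = 4) {
    stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
    ped$animal <- as.character(ped$animal)
    ped$sire <- as.character(ped$sire)
    ped$dam <- as.character(ped$dam)
    if (!all(focal_ids %in% ped$animal))
        stop("focal ids missing from pedigree: ",
             paste(setdiff(focal_ids, ped$animal), collapse = ", "))
    sire <- stats::setNames(ped$sire, ped$animal)
    dam <- stats::setNames(ped$dam, ped$animal)
    depth <- stats::setNames(rep(-1L, nrow(ped)), ped$animal)
    frontier <- unique(as.character(focal_ids))
    depth[frontier] <- 0L
    d <- 0L
    while (length(frontier) && d < n_gen) {
        parents <- setdiff(unique(c(sire[frontier], dam[frontier])), "0")
        parents <- parents[parents %in% names(depth)]
        fresh <- parents[depth[parents] < 0L]
        depth[fresh] <- d + 1L
        frontier <- parents  # revisit lets a shallower path extend deeper
        d <- d + 1L
        frontier <- frontier[depth[frontier] <= d]
    }
    keep <- names(depth)[depth >= 0L]
    out <- ped[ped$animal %in% keep, , drop = FALSE]
    horizon <- names(depth)[depth == n_gen]
    cut <- out$animal %in% horizon |
        !(out$sire %in% keep) | !(out$dam %in% keep)
    ## unknown parents for animals at the horizon or whose parents were dropped
    out$sire[out$animal %in% horizon | !(out$sire %in% keep)] <- "0"
    out$dam[out$animal %in% horizon | !(out$dam %in% keep)] <- "0"
    .topoSortPedigree(out)
}

## Kahn topological sort; rejects cycles naming one involved animal.
.topoSortPedigree <- function(ped) {
    n <- nrow(ped)
    idx <- stats::setNames(seq_len(n), ped$animal)
    parents <- cbind(ifelse(ped$sire %in% names(idx), idx[ped$sire], 0L),
                     ifelse(ped$dam %in% names(idx), idx[ped$dam], 0L))
    placed <- rep(FALSE, n)
    order <- integer(0)
    repeat {
        ready <- which(!placed &
                       (parents[, 1] == 0L | placed[pmax(parents[, 1], 1L)]) &
                       (parents[, 2] == 0L | placed[pmax(parents[, 2], 1L)]))
        if (!length(ready)) break
        placed[ready] <- TRUE
        order <- c(order, ready)
    }
    if (length(order) < n)
        stop("pedigree cycle detected involving animal '",
             ped$animal[which(!placed)[1L]], "'")
    out <- ped[order, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Additive (numerator) relationship matrix by the tabular method
#'
#' a(i,i) = 1 + a(sire_i, dam_i)/2; a(i,j) = (a(j, sire_i) + a(j, dam_i))/2
#' for previously processed j; unknown parents contribute 0. Returned is
#' the focal-by-focal submatrix. As the error covariance of a generalized
#' least squares scan the overall scale is immaterial (the scan is
#' invariant to it), so the conventional numerator matrix A (not A/2) is
#' used.
#'
#' @param ped pedigree data.frame, typically from
#'   \code{\link{truncatePedigree}}
#' @param focal_ids animals to return (rows/columns of the result)
#' @return symmetric positive semidefinite matrix with dimnames
#'   \code{focal_ids}; diagonal >= 1
#' @export
aMatrix <- function(ped, focal_ids) {
    ped <- .topoSortPedigree(data.frame(animal = as.character(ped$animal),
                                        sire = as.character(ped$sire),
                                        dam = as.character(ped$dam),
                                        stringsAsFactors = FALSE))
    if (!all(focal_ids %in% ped$animal))
        stop("focal ids missing from pedigree: ",
             paste(setdiff(focal_ids, ped$animal), collapse = ", "))
    n <- nrow(ped)
    idx <- stats::setNames(seq_len(n), ped$animal)
    s <- ifelse(ped$sire == "0", 0L, idx[ped$sire])
    d <- ifelse(ped$dam == "0", 0L, idx[ped$dam])
    A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
    for (i in seq_len(n)) {
        si <- s[i]; di <- d[i]
        A[i, i] <- 1 + if (si > 0L && di > 0L) A[si, di] / 2 else 0
        if (i > 1L) {
            j <- seq_len(i - 1L)
            aj <- ((if (si > 0L) A[j, si] else 0) +
                   (if (di > 0L) A[j, di] else 0)) / 2
            A[i, j] <- aj
            A[j, i] <- aj
        }
    }
    A[as.character(focal_ids), as.character(focal_ids), drop = FALSE]
}

#' Kinship error covariance from a pedigree
#'
#' Convenience wrapper: truncate to \code{n_gen} generations and build the
#' A-matrix over the study samples.
#'
#' @param ped full pedigree data.frame (animal, sire, dam)
#' @param focal_ids study sample ids
#' @param n_gen generations of pedigree to use, default 4
#' @return focal-by-focal additive relationship matrix
#' @export
kinshipMatrix <- function(ped, focal_ids, n_gen = 4) {
    aMatrix(truncatePedigree(ped, focal_ids, n_gen), focal_ids)
}
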