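#' Per-species motif presence probabilities for BBLS
#'
#' Converts the per-species best hits at one site into leaf probabilities
#' on the phylogeny: p_i equals the species' best NLOD when its z-score is
#' at least `zFloor`, and 0 otherwise (too-low z means no confidence the
#' motif is present). Species absent from the alignment get 0.
#'
#' @param hits DataFrame from [bestSpeciesHits()].
#' @param tree an [ape::phylo] tree whose tip labels are species names.
#' @param zFloor z threshold below which p is set to 0 (default 1.64,
#'   one-sided p 0.05).
#' @param refSpecies optional reference species; with `refCertain = TRUE`
#'   its probability is forced to 1 rather than its own NLOD.
#' @param refCertain force the reference probability to 1 (default FALSE).
#' @return named numeric vector over all tree leaves, values in `[0, 1]`.
#' @export
leafProbabilities <- function(hits, tree, zFloor = 1.64,
                              refSpecies = NULL, refCertain = FALSE) {
  df <- as.data.frame(hits)
  missing <- setdiff(df$species, tree$tip.label)
  if (length(missing) > 0L)
    stop("species not in tree: ", paste(missing, collapse = ", "))
  p <- setNames(numeric(length(tree$tip.label)), tree$tip.label)
  keep <- df$z >= zFloor
  if (!is.null(refSpecies)) keep <- keep | df$species == refSpecies
  p[df$species[keep]] <- df$nlod[keep]
  if (!is.null(refSpecies) && refCertain) p[refSpecies] <- 1
  pmin(pmax(p, 0), 1)
}

# logical matrix: for every edge (row of tree$edge), which tips lie below
# its child node; one postorder accumulation
.tipsBelowEdges <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  below <- matrix(FALSE, ntip + nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (i in seq_len(nrow(tr$edge))) {
    pa <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
    below[pa, ] <- below[pa, ] | below[ch, ]
  }
  list(tree = tr, below = below[tr$edge[, 2L], , drop = FALSE])
}

.asLeafVector <- function(x, tree, what) {
  tips <- tree$tip.label
  if (!is.null(names(x))) {
    extra <- setdiff(names(x), tips)
    if (length(extra) > 0L)
      stop("species not in tree: ", paste(extra, collapse = ", "))
    full <- setNames(numeric(length(tips)), tips)
    full[names(x)] <- x
    return(full)
  }
  if (length(x) != length(tips))
    stop(what, " must be named or have one entry per tree leaf")
  setNames(as.numeric(x), tips)
}

#' Branch length score (BLS) of a binary presence vector
#'
#' Total branch length of the minimal subtree spanning all species whose
#' presence indicator is 1 (the subtree connecting them through their most
#' recent common ancestor, taken unrooted); 0 when at most one species is
#' present.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param sigma binary vector (named by species, or one entry per leaf).
#' @return non-negative BLS, at most the total tree branch length.
#' @export
bls <- function(tree, sigma) {
  sigma <- .asLeafVector(sigma, tree, "sigma")
  if (!all(sigma %in% c(0, 1))) stop("sigma must be binary")
  tb <- .tipsBelowEdges(tree)
  cnt <- as.vector(tb$below %*% sigma)
  tot <- sum(sigma)
  sum(tb$tree$edge.length[cnt >= 1 & cnt <= tot - 1])
}

#' Bayesian branch length score by exhaustive enumeration
#'
#' The expected BLS over all 2^N binary presence patterns, each weighted by
#' the product of the independent leaf probabilities. Exact but
#' exponential: serves as the oracle for [bbls()] on small trees.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param p presence probabilities in `[0, 1]` (named, or one per leaf).
#' @return the expected BLS.
#' @export
bblsBruteForce <- function(tree, p) {
  p <- .asLeafVector(p, tree, "p")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  free <- which(p > 0)
  n <- length(free)
  if (n > 15L)
    stop("too many uncertain species (", n, "); use bbls() instead")
  if (n == 0L) return(0)
  ntip <- length(p)
  combos <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sigma <- matrix(0, ntip, nrow(combos))
  sigma[free, ] <- t(combos)
  w <- apply(combos, 1L, function(s)
    prod(ifelse(s == 1, p[free], 1 - p[free])))
  tb <- .tipsBelowEdges(tree)
  cnt <- tb$below %*% sigma                     # edges x patterns
  tot <- colSums(sigma)
  inTree <- (cnt >= 1) & sweep(cnt, 2L, tot - 1, "<=")
  blsAll <- as.vector(tb$tree$edge.length %*% inTree)
  sum(w * blsAll)
}

#' Bayesian branch length score (BBLS) by dynamic programming
#'
#' Computes the expected BLS in linear time: by independence of the leaf
#' presence events, a branch belongs to the spanning subtree with
#' probability (1 - prod(1-p) over leaves on one side) * (1 - prod(1-p)
#' over leaves on the other side), so BBLS is the branch-length-weighted
#' sum of these probabilities, computed in one post-order and one pre-order
#' pass. Agrees with [bblsBruteForce()] to 1e-9 and reduces to [bls()] for
#' binary probabilities.
#'
#' @inheritParams bblsBruteForce
#' @return the BBLS, in `[0, total tree branch length]`.
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:2);")
#' bbls(tr, c(A = 1, B = 0.5))   # 0.5 * 3
#' @export
bbls <- function(tree, p) {
  p <- .asLeafVector(p, tree, "p")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  nE <- nrow(edge)
  # post-order: qd[v] = prod(1 - p_i) over leaves below v
  qd <- rep(1, ntip + nnode)
  qd[seq_len(ntip)] <- 1 - p
  for (i in seq_len(nE)) qd[edge[i, 1L]] <- qd[edge[i, 1L]] * qd[edge[i, 2L]]
  # pre-order: qu[v] = prod(1 - p_i) over leaves NOT below v
  # qu[child] = qu[parent] * prod(qd[siblings]); sibling products avoid
  # dividing by qd[child], which can be 0 when some p_i = 1
  root <- ntip + 1L
  qu <- rep(NA_real_, ntip + nnode)
  qu[root] <- 1
  childrenOf <- split(edge[, 2L], edge[, 1L])
  for (i in rev(seq_len(nE))) {            # reverse postorder = preorder
    pa <- edge[i, 1L]; ch <- edge[i, 2L]
    sibs <- setdiff(childrenOf[[as.character(pa)]], ch)
    qu[ch] <- qu[pa] * prod(qd[sibs])
  }
  sum(tr$edge.length * (1 - qd[edge[, 2L]]) * (1 - qu[edge[, 2L]]))
}

#' Total branch length of a tree
#'
#' Upper bound for BLS/BBLS.
#'
#' @param tree an [ape::phylo].
#' @return sum of all branch lengths.
#' @export
totalBranchLength <- function(tree) sum(tree$edge.length)
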