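# Neighbor-joining clone similarity trees from p-distances on the
# reference-coordinate matrix. The agglomeration is the standard
# Saitou-Nei procedure with a deterministic tie-break; the result is an
# ape "phylo" object so the usual tree toolchain applies.

#' p-distance between two aligned rows
#'
#' Proportion of differing sites among columns where both rows carry an
#' unambiguous base; gap- or ambiguity-containing columns are excluded.
#'
#' @param a,b Equal-length gapped strings (or character vectors).
#' @return Substitutions per site.
#' @examples
#' p_distance("ACGT", "ACGA")  # 0.25
#' @export
p_distance <- function(a, b) {
  if (length(a) == 1L) a <- strsplit(a, "")[[1L]]
  if (length(b) == 1L) b <- strsplit(b, "")[[1L]]
  if (length(a) != length(b)) stop("rows must have equal length")
  ok <- a %in% BASES & b %in% BASES
  if (!any(ok)) stop("no comparable columns; p-distance undefined")
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Pairwise p-distance matrix for a clone set
#'
#' @param cm A `clone_matrix`.
#' @param mc The reference `minicircle`; when supplied, the reference arc
#'   sequence is included as an extra row labelled by the reference id.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
clone_distances <- function(cm, mc = NULL) {
  rows <- lapply(seq_along(cm$clone_ids), function(i) cm$columns[i, ])
  labels <- cm$clone_ids
  if (!is.null(mc)) {
    ref <- strsplit(subseq_circular(mc$seq, cm$arc)$residues, "")[[1L]]
    rows <- c(list(ref), rows)
    labels <- c(cm$ref_id, labels)
  }
  n <- length(rows)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- p_distance(rows[[i]], rows[[j]])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining: at each step the pair minimizing
#' the Q criterion is agglomerated, with ties broken deterministically by
#' the smallest (i, j) label pair in matrix order. Negative branch lengths
#' are clamped to zero with a warning. The unrooted tree is returned as an
#' ape `phylo` with a trifurcating root.
#'
#' @param d Symmetric distance matrix with labels (>= 3 taxa).
#' @return An object of class `phylo`.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- neighbor_joining(d)  # branch lengths 1, 1, 3
#' @export
neighbor_joining <- function(d) {
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  if (n < 3L) stop("neighbor joining requires at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0) || any(!is.finite(d)))
    stop("distance matrix must be symmetric, finite, with zero diagonal")
  labels <- rownames(d)
  # node ids: 1..n tips, internal nodes numbered n+2, n+3, ... (n+1 = root)
  node_of <- seq_len(n)
  next_internal <- n + 2L
  edges <- matrix(integer(0), 0, 2)
  lens <- numeric(0)
  D <- d
  active <- seq_len(n)
  clamp <- function(x) {
    if (x < 0) {
      warning("negative branch length clamped to 0")
      return(0)
    }
    x
  }
  while (length(active) > 3L) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    best <- c(NA_integer_, NA_integer_)
    bestq <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * Dm[i, j] - r[i] - r[j]
        if (q < bestq - 1e-12) {
          bestq <- q
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    bi <- 0.5 * Dm[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- Dm[i, j] - bi
    u <- next_internal
    next_internal <- next_internal + 1L
    edges <- rbind(edges, c(u, node_of[active[i]]), c(u, node_of[active[j]]))
    lens <- c(lens, clamp(bi), clamp(bj))
    newd <- 0.5 * (Dm[i, ] + Dm[j, ] - Dm[i, j])
    ai <- active[i]; aj <- active[j]
    D[ai, active] <- D[active, ai] <- newd
    D[ai, ai] <- 0
    node_of[ai] <- u
    active <- setdiff(active, aj)
  }
  # join the last three at the trifurcating root (node n+1)
  a <- active
  root <- n + 1L
  b1 <- 0.5 * (D[a[1], a[2]] + D[a[1], a[3]] - D[a[2], a[3]])
  b2 <- 0.5 * (D[a[1], a[2]] + D[a[2], a[3]] - D[a[1], a[3]])
  b3 <- 0.5 * (D[a[1], a[3]] + D[a[2], a[3]] - D[a[1], a[2]])
  edges <- rbind(edges, c(root, node_of[a[1]]), c(root, node_of[a[2]]),
                 c(root, node_of[a[3]]))
  lens <- c(lens, clamp(b1), clamp(b2), clamp(b3))
  tr <- list(edge = edges, edge.length = lens, tip.label = labels,
             Nnode = max(next_internal - 1L, root) - n)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Build a neighbor-joining clone tree and optionally write Newick
#'
#' @param cm A `clone_matrix`.
#' @param mc Optional reference `minicircle` to include as a leaf.
#' @param path Optional Newick output path.
#' @return The `phylo` tree, invisibly if `path` is given.
#' @export
clone_tree <- function(cm, mc = NULL, path = NULL) {
  tr <- neighbor_joining(clone_distances(cm, mc))
  if (!is.null(path)) {
    ape::write.tree(tr, path)
    return(invisible(tr))
  }
  tr
}
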