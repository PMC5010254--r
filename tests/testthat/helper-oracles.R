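# Independent oracles used to validate the dynamic-programming kernels.
# These deliberately take different algorithmic routes from the package
# implementations (exhaustive enumeration instead of DP recurrences).

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force optimal global alignment score by enumerating every monotone
# matching between positions of a and b. For a fixed matching the optimal
# gap arrangement places each segment's unmatched residues as one
# contiguous run per sequence (extra gap openings only lose score), so the
# score is match/mismatch over matched pairs plus per-segment gap costs.
oracle_global_score <- function(a, b, params = align_params()) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av)
  m <- length(bv)
  gap_cost <- function(len) ifelse(len > 0, params$gap_open +
                                     len * params$gap_extend, 0)
  best <- -Inf
  for (k in 0:min(n, m)) {
    ia_all <- if (k == 0) matrix(integer(0), 0, 1) else combn(n, k)
    jb_all <- if (k == 0) matrix(integer(0), 0, 1) else combn(m, k)
    for (ci in seq_len(ncol(ia_all))) {
      ia <- ia_all[, ci]
      bounds_a <- c(0L, ia, n + 1L)
      ga <- diff(bounds_a) - 1L
      for (cj in seq_len(ncol(jb_all))) {
        jb <- jb_all[, cj]
        sub <- sum(ifelse(av[ia] == bv[jb], params$match, params$mismatch))
        gb <- diff(c(0L, jb, m + 1L)) - 1L
        sc <- sub + sum(gap_cost(ga)) + sum(gap_cost(gb))
        if (sc > best) best <- sc
      }
    }
  }
  best
}

wc_pair_score <- function(x, y, match, mismatch) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ifelse(comp[x] == y, match, mismatch)
}

# Exhaustive best inverted-repeat score over all disjoint, ordered arm
# pairs whose alignment contains at most `max_gaps` gap positions. An
# alignment is indexed by (arm1 start p, arm2 end q, the ordered sides and
# times of its gap positions); for each (p, q) and each gap-side sequence
# the family is scanned exactly with running maxima over the gap times
# (zero-length segments between gaps included), so the search is
# exhaustive over that family without building alignments explicitly.
oracle_ir_best <- function(s, match = 3, mismatch = -4, gap = 5,
                           max_gaps = 2) {
  sv <- strsplit(s, "")[[1L]]
  n <- length(sv)
  # diagonal with s1 skips in arm 1 and s2 skips in arm 2: cumulative pair
  # scores C[e + 1] over the leading run of valid (non-crossing) pairs
  diag_cum <- function(p, q, s1, s2, Tmax) {
    v <- 0:(Tmax - 1)
    xs <- p + v + s1
    ys <- q - v - s2
    ok <- xs < ys & ys >= 1 & xs <= n
    L <- if (all(ok)) Tmax else which.min(ok) - 1L
    if (L == 0L) return(NULL)
    c(0, cumsum(wc_pair_score(sv[xs[1:L]], sv[ys[1:L]], match, mismatch)))
  }
  side_seqs <- list(integer(0))
  grow <- list(integer(0))
  for (k in seq_len(max_gaps)) {
    grow <- unlist(lapply(grow, function(x) list(c(x, 1L), c(x, 2L))),
                   recursive = FALSE)
    side_seqs <- c(side_seqs, grow)
  }
  best <- 0
  for (p in 1:(n - 1)) {
    for (q in (p + 1):n) {
      T0 <- (q - p + 1) %/% 2
      if (T0 < 1) next
      for (sides in side_seqs) {
        s1 <- 0L; s2 <- 0L
        # V[e + 1] = best score after e pairs in the current state
        V <- diag_cum(p, q, 0L, 0L, T0)
        if (length(sides) == 0L) {
          best <- max(best, V[-1L])
          next
        }
        feasible <- TRUE
        for (side in sides) {
          if (side == 1L) s1 <- s1 + 1L else s2 <- s2 + 1L
          Cj <- diag_cum(p, q, s1, s2, T0)
          if (is.null(Cj)) { feasible <- FALSE; break }
          m <- min(length(V), length(Cj))
          run <- cummax(V[1:m] - Cj[1:m])
          pad <- if (length(Cj) > m) rep(run[m], length(Cj) - m) else NULL
          V <- Cj + c(run, pad) - gap
        }
        if (feasible && length(V) > 1L) best <- max(best, V[-1L])
      }
    }
  }
  best
}

# additive distance matrix from a random tree via path lengths
random_additive_matrix <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = function(k) stats::runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  list(tree = tr, d = d[ord, ord])
}
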