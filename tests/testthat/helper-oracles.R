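# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive everything from first principles (plain R,
# no calls into the package's clustering path) so implementation bugs
# cannot cancel out.

random_seqs <- function(n, len, n_mut = 0:10) {
  base <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  vapply(seq_len(n), function(i) {
    s <- strsplit(base, "")[[1]]
    for (k in seq_len(sample(n_mut, 1))) {
      p <- sample(len, 1)
      s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    }
    paste(s, collapse = "")
  }, character(1))
}

random_records <- function(n, len, n_mut = 0:10) {
  seqs <- random_seqs(n, len, n_mut)
  assign_groups(seq_tbl(paste0("s", seq_len(n)), seqs))
}

hamming_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  mean(av == bv)
}

# Plain-R global alignment oracle under the fixed scoring (match +1,
# mismatch -1, gap -2) with diagonal-then-up traceback preference.
# Returns the optimal score and the identity of the traced alignment.
oracle_nw <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  F <- matrix(0, n + 1, m + 1)
  F[1, ] <- -2 * (0:m)
  F[, 1] <- -2 * (0:n)
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (av[i] == bv[j]) 1 else -1
      F[i + 1, j + 1] <- max(F[i, j] + s, F[i, j + 1] - 2, F[i + 1, j] - 2)
    }
  }
  i <- n; j <- m; match <- 0; cols <- 0
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        F[i + 1, j + 1] == F[i, j] + (if (av[i] == bv[j]) 1 else -1)) {
      match <- match + (av[i] == bv[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && F[i + 1, j + 1] == F[i, j + 1] - 2) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1
  }
  list(score = F[n + 1, m + 1], identity = match / cols)
}

oracle_identity_matrix <- function(seqs) {
  n <- length(seqs)
  outer(seq_len(n), seq_len(n),
        Vectorize(function(i, j) hamming_identity(seqs[i], seqs[j])))
}

# Naive agglomerative partition at one cutoff: keep explicit cluster sets and
# recompute every cross-cluster linkage from the base matrix at every step,
# merging the best pair while it still meets the cutoff. O(n^3) per call.
oracle_linkage <- function(sim, A, B, linkage) {
  cross <- sim[A, B, drop = FALSE]
  switch(linkage, min = max(cross), max = min(cross), avg = mean(cross))
}

oracle_agglomerative_partition <- function(sim, linkage, cutoff,
                                           tol = 1e-9) {
  clusters <- as.list(seq_len(nrow(sim)))
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- -Inf
    pick <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        v <- oracle_linkage(sim, clusters[[i]], clusters[[j]], linkage)
        if (v > best + tol) {
          best <- v
          pick <- c(i, j)
        } else if (v > best - tol) {
          # tie: lexicographically smallest (min-member, min-member) pair
          cand <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
          inc <- sort(c(min(clusters[[pick[1]]]), min(clusters[[pick[2]]])))
          if (cand[1] < inc[1] || (cand[1] == inc[1] && cand[2] < inc[2])) {
            pick <- c(i, j)
          }
        }
      }
    }
    if (best < cutoff - tol) break
    clusters[[pick[1]]] <- sort(c(clusters[[pick[1]]], clusters[[pick[2]]]))
    clusters[[pick[2]]] <- NULL
  }
  clusters
}

# Literal re-simulation of the greedy centroid rule: compare each record (in
# order) to every existing centroid, join the best match at/above the cutoff
# (ties to the earliest-founded), else found a new cluster.
oracle_greedy_partition <- function(seqs, order, cutoff, tol = 1e-9) {
  centroids <- integer(0)
  members <- list()
  for (idx in order) {
    if (length(centroids) == 0) {
      centroids <- idx
      members <- list(idx)
      next
    }
    ids <- vapply(centroids, function(c) hamming_identity(seqs[idx], seqs[c]),
                  numeric(1))
    best <- which(ids > max(ids) - tol)[1]
    if (ids[best] >= cutoff - tol) {
      members[[best]] <- c(members[[best]], idx)
    } else {
      centroids <- c(centroids, idx)
      members[[length(members) + 1]] <- idx
    }
  }
  members
}

# canonical form of a partition for label-free comparison
canon <- function(clusters) {
  if (is.integer(clusters) || is.numeric(clusters)) {
    clusters <- split(seq_along(clusters), clusters)
  }
  unname(clusters[order(vapply(clusters, min, numeric(1)))]) |>
    lapply(function(m) sort(unname(m)))
}

membership_of <- function(ring_tbl, n) {
  m <- integer(n)
  for (k in seq_len(nrow(ring_tbl))) m[ring_tbl$members[[k]]] <- ring_tbl$cluster_id[k]
  m
}

refines <- function(fine, coarse) {
  all(vapply(split(seq_along(fine), fine),
             function(m) length(unique(coarse[m])) == 1, logical(1)))
}
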