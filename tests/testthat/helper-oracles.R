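# Fixture builders and independent oracles shared across the test files.

# Build a long allele profile from four count vectors (one per
# generation/allele block), replicates inferred from length.
make_profile <- function(f0_w, f0_c, f1_w, f1_c, gene_id = "g1") {
  nr <- length(f0_w)
  reps <- paste0("rep", seq_len(nr))
  out <- dplyr::bind_rows(
    tibble::tibble(generation = "F0", allele = "W", replicate = reps, count = f0_w),
    tibble::tibble(generation = "F0", allele = "C", replicate = reps, count = f0_c),
    tibble::tibble(generation = "F1", allele = "W", replicate = reps, count = f1_w),
    tibble::tibble(generation = "F1", allele = "C", replicate = reps, count = f1_c)
  )
  out$gene_id <- gene_id
  out$count <- as.integer(out$count)
  out[, c("gene_id", "replicate", "generation", "allele", "count")]
}

# Stack several single-gene profiles into one.
stack_profiles <- function(...) dplyr::bind_rows(...)

# Brute-force NB log-likelihood maximization over a dense (intercept,
# effect) lattice with staged refinement; independent of the IRLS path.
grid_loglik_max <- function(y, x, phi, offset = rep(0, length(y))) {
  ll_at <- function(b0, b1) {
    mu <- exp(b0 + b1 * x + offset)
    sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
  b0_centre <- log(mean(y) + 0.5)
  b1_centre <- 0
  half <- c(3, 0.15, 0.0075)
  best <- c(b0_centre, b1_centre)
  for (h in half) {
    b0s <- seq(best[1] - h, best[1] + h, length.out = 81)
    b1s <- seq(best[2] - h, best[2] + h, length.out = 81)
    ll <- outer(b0s, b1s, Vectorize(ll_at))
    idx <- arrayInd(which.max(ll), dim(ll))
    best <- c(b0s[idx[1]], b1s[idx[2]])
  }
  ll_at(best[1], best[2])
}

# 1-D version for intercept-only models.
grid_loglik_max_1d <- function(y, phi, offset = rep(0, length(y))) {
  ll_at <- function(b0) {
    mu <- exp(b0 + offset)
    sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
  best <- log(mean(y) + 0.5)
  for (h in c(3, 0.15, 0.0075)) {
    b0s <- seq(best - h, best + h, length.out = 2001)
    best <- b0s[which.max(vapply(b0s, ll_at, numeric(1)))]
  }
  ll_at(best)
}

# Exhaustive all-pairs shortest-path betweenness (counts all shortest paths
# by BFS-free enumeration over simple paths; graphs must be tiny).
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  all_paths <- function(from, to) {
    paths <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == to) {
        paths[[length(paths) + 1]] <<- path
        return(invisible())
      }
      for (nb in which(adj[last, ] > 0)) {
        if (!nb %in% path) walk(c(path, nb))
      }
    }
    walk(from)
    paths
  }
  score <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        inner <- setdiff(p, c(s, t))
        score[inner] <- score[inner] + 1 / length(shortest)
      }
    }
  }
  score
}

# Per-component normalization matching the package's convention.
normalize_betweenness <- function(score, adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1
    frontier <- v
    comp[v] <- cid
    while (length(frontier) > 0) {
      nxt <- unique(unlist(lapply(frontier, function(u) which(adj[u, ] > 0))))
      nxt <- nxt[is.na(comp[nxt])]
      comp[nxt] <- cid
      frontier <- nxt
    }
  }
  out <- numeric(n)
  for (k in unique(comp)) {
    vs <- which(comp == k)
    m <- length(vs)
    out[vs] <- if (m < 3) 0 else score[vs] / ((m - 1) * (m - 2) / 2)
  }
  out
}

# Hypergeometric upper tail by direct pmf summation.
hyper_tail <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}
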