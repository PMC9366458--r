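# Fixture builders and independent brute-force oracles used across tests.

nwk <- function(text) read_trees(text = text)

tr_bal4 <- function() nwk("((a,b),(c,d));")[[1]]
tr_alt4 <- function() nwk("((a,c),(b,d));")[[1]]
tr_star4 <- function() nwk("(a,b,c,d);")[[1]]

# Splits as a list of canonical label-set sides (independent of the
# package's internal representation: uses ape's bipartition machinery).
oracle_splits <- function(phy) {
  phy <- ape::unroot(phy)
  bp <- ape::prop.part(phy)
  labs <- attr(bp, "labels")
  n <- length(labs)
  sides <- lapply(bp, function(i) sort(labs[i]))
  sides <- Filter(function(s) length(s) >= 2 && length(s) <= n - 2, sides)
  # canonicalise: use the side not containing the alphabetically first label
  first <- sort(labs)[1]
  sides <- lapply(sides, function(s) {
    if (first %in% s) sort(setdiff(labs, s)) else s
  })
  unique(sides)
}

# Quartet status by direct split containment (independent of the path-based
# implementation): ab|cd iff some edge separates {a,b} from {c,d}.
oracle_quartet_distance <- function(t1, t2) {
  labs <- sort(t1$tip.label)
  status_one <- function(phy, q) {
    sides <- oracle_splits(phy)
    sides <- c(sides, lapply(sides, function(s) setdiff(labs, s)))
    for (s in sides) {
      inn <- q %in% s
      if (sum(inn) == 2) {
        pair <- sort(q[inn])
        if (identical(pair, sort(q[1:2])) || identical(pair, sort(q[3:4])))
          return("12|34")
        if (identical(pair, sort(q[c(1, 3)])) ||
            identical(pair, sort(q[c(2, 4)])))
          return("13|24")
        if (identical(pair, sort(q[c(1, 4)])) ||
            identical(pair, sort(q[c(2, 3)])))
          return("14|23")
      }
    }
    "unresolved"
  }
  quartets <- combn(labs, 4)
  sum(vapply(seq_len(ncol(quartets)), function(i) {
    q <- quartets[, i]
    status_one(t1, q) != status_one(t2, q)
  }, logical(1)))
}

# Per-split clustering information and pairwise shared information computed
# from label sets with plain table() arithmetic.
oracle_cid <- function(t1, t2) {
  labs <- sort(t1$tip.label)
  n <- length(labs)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  h_split <- function(side) n * ent(c(length(side), n - length(side)) / n)
  shared <- function(s1, s2) {
    x <- factor(labs %in% s1, levels = c(FALSE, TRUE))
    y <- factor(labs %in% s2, levels = c(FALSE, TRUE))
    tab <- table(x, y) / n
    mi <- ent(rowSums(tab)) + ent(colSums(tab)) - ent(as.vector(tab))
    n * mi
  }
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  H1 <- sum(vapply(s1, h_split, numeric(1)))
  H2 <- sum(vapply(s2, h_split, numeric(1)))
  k1 <- length(s1); k2 <- length(s2)
  if (k1 == 0 || k2 == 0) return(H1 + H2)
  W <- outer(seq_len(k1), seq_len(k2),
             Vectorize(function(i, j) shared(s1[[i]], s2[[j]])))
  H1 + H2 - 2 * oracle_best_matching(W)
}

# Exhaustive maximum matching over all injections of the smaller split set
# into the larger (factorial search; for oracle-scale trees only).
oracle_best_matching <- function(W) {
  if (nrow(W) > ncol(W)) W <- t(W)
  k1 <- nrow(W); k2 <- ncol(W)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- 0
  for (cols in combn(k2, k1, simplify = FALSE)) {
    for (p in perms(cols)) {
      sc <- sum(W[cbind(seq_len(k1), p)])
      if (sc > best) best <- sc
    }
  }
  best
}

# Phylogenetic information via exhaustive topology counting with
# phangorn::allTrees (n <= 8).  Topologies are indexed by split key once
# per n, so "fraction of trees containing these splits" is set
# intersection.
oracle_pid_env <- new.env()
oracle_split_index <- function(n) {
  key <- as.character(n)
  if (!is.null(oracle_pid_env[[key]])) return(oracle_pid_env[[key]])
  at <- phangorn::allTrees(n, rooted = FALSE,
                           tip.label = sort(sprintf("t%d", 1:n)))
  sets <- lapply(at, oracle_splits)
  map <- new.env(hash = TRUE)
  for (i in seq_along(sets)) {
    for (s in sets[[i]]) {
      kk <- paste(s, collapse = "|")
      map[[kk]] <- c(map[[kk]], i)
    }
  }
  idx <- list(n_trees = length(sets), map = map)
  oracle_pid_env[[key]] <- idx
  idx
}

# Fraction of n-leaf binary topologies containing every split in `sides`
# (labels must be t1..tn).
oracle_split_fraction <- function(sides, n) {
  idx <- oracle_split_index(n)
  ids <- lapply(sides, function(s) idx$map[[paste(s, collapse = "|")]])
  if (any(vapply(ids, is.null, logical(1)))) return(0)
  length(Reduce(intersect, ids)) / idx$n_trees
}

oracle_pid <- function(t1, t2) {
  labs <- sort(t1$tip.label)
  n <- length(labs)
  h_split <- function(side) -log2(oracle_split_fraction(list(side), n))
  shared <- function(a, b) {
    fr <- oracle_split_fraction(list(a, b), n)
    if (fr == 0) return(0)
    h_split(a) + h_split(b) + log2(fr)
  }
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  H1 <- sum(vapply(s1, h_split, numeric(1)))
  H2 <- sum(vapply(s2, h_split, numeric(1)))
  k1 <- length(s1); k2 <- length(s2)
  if (k1 == 0 || k2 == 0) return(H1 + H2)
  W <- outer(seq_len(k1), seq_len(k2),
             Vectorize(function(i, j) shared(s1[[i]], s2[[j]])))
  H1 + H2 - 2 * oracle_best_matching(W)
}

# Rank-list brute force for trustworthiness/continuity.
oracle_trust_cont <- function(d, pts, k) {
  n <- nrow(d)
  dm <- as.matrix(dist(pts))
  rk <- function(D, i) {
    o <- order(D[i, ], seq_len(n)); o <- o[o != i]
    r <- integer(n); r[o] <- seq_len(n - 1); r
  }
  tsum <- csum <- 0
  for (i in seq_len(n)) {
    ro <- rk(d, i); rm <- rk(dm, i)
    for (j in seq_len(n)) {
      if (j == i) next
      if (rm[j] <= k && ro[j] > k) tsum <- tsum + ro[j] - k
      if (ro[j] <= k && rm[j] > k) csum <- csum + rm[j] - k
    }
  }
  norm <- 2 / (n * k * (2 * n - 3 * k - 1))
  c(trust = 1 - norm * tsum, cont = 1 - norm * csum)
}

# Tie-free Kendall tau by direct pair-concordance count.
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  (conc - disc) / choose(n, 2)
}

# Euclidean point-set fixtures.
line_points <- function(n, seed = 1) {
  set.seed(seed)
  matrix(sort(runif(n)), ncol = 1)
}
square_points <- function(n, seed = 1) {
  set.seed(seed)
  cbind(runif(n), runif(n))
}
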