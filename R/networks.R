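# Population graphs: complete, Erdos-Renyi, Barabasi-Albert, power-law
# configuration model and random regular, plus the contact matrix
# P[j, i] = A[j, i] / k_j used by the node-level ODEs.
#
# Graphs are undirected and simple, with 0-based node ids (matching the
# edge-list file format).  Standard generators (ER, BA, regular) are
# delegated to igraph; the uncorrelated power-law sampler is implemented
# here: degrees drawn from P(k) proportional to k^-gamma on
# [k_min, floor(sqrt(n))] (structural cutoff, suppressing degree
# correlations), sum forced even by redrawing one degree, then stub
# matching with rejection of self-loops and multi-edges (up to 100
# re-match rounds over the offending stubs, after which leftovers are
# dropped).

# Constructor + invariant checks.  `edges` is a 2-column matrix of 0-based
# ids with no self-loops or duplicates.
new_network <- function(n, edges, model = "custom") {
  n <- as.integer(n)
  if (is.null(edges) || length(edges) == 0) {
    edges <- matrix(integer(0), ncol = 2)
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 0) || any(edges >= n)) {
      stop("edge endpoints must be in [0, n)", call. = FALSE)
    }
    if (any(edges[, 1] == edges[, 2])) {
      stop("self-loops are not allowed", call. = FALSE)
    }
    # canonical order: smaller id first, then sort rows
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, 2:1]
    key <- edges[, 1] * as.double(n) + edges[, 2]
    if (anyDuplicated(key)) stop("duplicate edges", call. = FALSE)
    edges <- edges[order(key), , drop = FALSE]
  }
  degrees <- tabulate(c(edges[, 1], edges[, 2]) + 1L, nbins = n)
  structure(list(n = n, edges = edges, degrees = degrees, model = model),
            class = "rumour_network")
}

#' @export
print.rumour_network <- function(x, ...) {
  cat(sprintf("undirected network (%s): n = %d, %d edges, mean degree %.2f\n",
              x$model, x$n, nrow(x$edges), mean(x$degrees)))
  invisible(x)
}

#' Complete graph
#'
#' @param n Number of nodes (>= 2).
#' @return A `rumour_network` with all n(n-1)/2 edges.
#' @export
#' @examples
#' gen_complete(5)
gen_complete <- function(n) {
  stopifnot(n >= 2)
  idx <- t(utils::combn(n, 2)) - 1L
  new_network(n, idx, model = "complete")
}

#' Erdos-Renyi random graph
#'
#' Each unordered pair is connected independently with probability `p`.
#'
#' @param n Number of nodes.
#' @param p Edge probability in \[0, 1\].
#' @param seed RNG seed (the generator is deterministic given `seed`).
#' @return A `rumour_network`.
#' @export
gen_er <- function(n, p, seed = NULL) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  g <- with_seed(seed, igraph::sample_gnp(n, p))
  new_network(n, igraph::as_edgelist(g, names = FALSE) - 1L, model = "er")
}

#' Barabasi-Albert scale-free graph
#'
#' Growth with linear preferential attachment from an m-node seed clique;
#' each new node attaches `m` edges.  The degree distribution has a
#' power-law tail with exponent close to 3.
#'
#' @param n Number of nodes.
#' @param m Edges added per new node (1 <= m < n).
#' @param seed RNG seed.
#' @return A `rumour_network`.
#' @export
gen_ba <- function(n, m, seed = NULL) {
  stopifnot(m >= 1, m < n)
  g <- with_seed(seed, igraph::sample_pa(
    n, power = 1, m = m, directed = FALSE,
    start.graph = igraph::make_full_graph(m)))
  g <- igraph::simplify(g)
  new_network(n, igraph::as_edgelist(g, names = FALSE) - 1L, model = "ba")
}

#' Uncorrelated power-law configuration-model graph
#'
#' Degrees are drawn from P(k) proportional to k^-gamma on
#' \[k_min, floor(sqrt(n))\] (the structural cutoff keeps the graph free of
#' degree correlations), the degree sum is forced even by redrawing one
#' degree, and stubs are matched uniformly with rejection of self-loops
#' and multi-edges: offending stubs are re-shuffled among themselves for up
#' to 100 rounds, after which any still-offending stubs are dropped.
#'
#' @param n Number of nodes.
#' @param gamma Power-law exponent, in (2, 3.5\].
#' @param k_min Minimum degree (>= 1).
#' @param seed RNG seed.
#' @return A `rumour_network`.
#' @export
gen_powerlaw_config <- function(n, gamma, k_min, seed = NULL) {
  stopifnot(gamma > 2, gamma <= 3.5, k_min >= 1)
  k_max <- floor(sqrt(n))
  if (k_min >= k_max) stop("`k_min` must be below sqrt(n)", call. = FALSE)
  with_seed(seed, {
    ks <- k_min:k_max
    pk <- ks^(-gamma)
    degs <- sample(ks, n, replace = TRUE, prob = pk)
    while (sum(degs) %% 2 != 0) {
      degs[sample.int(n, 1)] <- sample(ks, 1, prob = pk)
    }
    # stub matching with rejection
    stubs <- rep.int(seq_len(n) - 1L, degs)
    edge_key <- function(a, b) {
      lo <- pmin(a, b); hi <- pmax(a, b)
      lo * as.double(n) + hi
    }
    kept_a <- integer(0); kept_b <- integer(0)
    seen <- double(0)
    pool <- sample(stubs)
    for (round in 1:100) {
      if (length(pool) < 2) break
      a <- pool[seq(1, length(pool), by = 2)]
      b <- pool[seq(2, length(pool), by = 2)]
      key <- edge_key(a, b)
      ok <- a != b & !(key %in% seen) & !duplicated(key)
      kept_a <- c(kept_a, a[ok]); kept_b <- c(kept_b, b[ok])
      seen <- c(seen, key[ok])
      bad <- c(a[!ok], b[!ok])
      if (length(bad) == 0) break
      if (length(bad) < 2) break
      pool <- sample(bad)  # after 100 rounds the leftovers are dropped
    }
    if (length(kept_a) == 0) {
      stop("could not realise a simple graph; use a larger `n`",
           call. = FALSE)
    }
    new_network(n, cbind(kept_a, kept_b), model = "powerlaw")
  })
}

#' Random regular graph
#'
#' @param n Number of nodes.
#' @param k Common degree (n * k must be even, k < n).
#' @param seed RNG seed.
#' @return A `rumour_network`.
#' @export
gen_regular <- function(n, k, seed = NULL) {
  stopifnot(k >= 0, k < n)
  if ((n * k) %% 2 != 0) {
    stop("`n * k` must be even for a k-regular graph", call. = FALSE)
  }
  g <- with_seed(seed, igraph::sample_k_regular(n, k))
  new_network(n, igraph::as_edgelist(g, names = FALSE) - 1L,
              model = "regular")
}

#' Contact weight matrix
#'
#' Row-stochastic (over neighbours) sparse matrix with
#' P\[j, i\] = A\[j, i\] / k_j: the probability that node j's next contact is
#' its neighbour i.  Isolated nodes get an all-zero row.
#'
#' @param network A `rumour_network`.
#' @return A sparse `dgCMatrix`.
#' @export
contact_weights <- function(network) {
  stopifnot(inherits(network, "rumour_network"))
  n <- network$n
  e <- network$edges + 1L
  from <- c(e[, 1], e[, 2])
  to <- c(e[, 2], e[, 1])
  Matrix::sparseMatrix(i = from, j = to,
                       x = 1 / network$degrees[from],
                       dims = c(n, n))
}

# Compressed adjacency (0-based CSR) for the C++ Monte Carlo engine.
csr_adjacency <- function(network) {
  n <- network$n
  e <- network$edges + 1L
  from <- c(e[, 1], e[, 2])
  to <- c(e[, 2], e[, 1])
  o <- order(from)
  ptr <- c(0L, cumsum(tabulate(from, nbins = n)))
  list(ptr = as.integer(ptr), idx = as.integer(to[o] - 1L))
}

#' Read / write whitespace-delimited edge lists
#'
#' One edge per line as two non-negative 0-based integer ids; lines
#' beginning with `#` are comments.  `write_edgelist` records the node
#' count in a `# n = <n>` header so isolated trailing nodes survive the
#' round trip.
#'
#' @param path File path.
#' @return `read_edgelist` returns a `rumour_network`; `write_edgelist`
#'   returns `path` invisibly.
#' @export
read_edgelist <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  n_declared <- NA_integer_
  hdr <- grep("^#\\s*n\\s*=\\s*[0-9]+", lines, value = TRUE)
  if (length(hdr) > 0) {
    n_declared <- as.integer(sub("^#\\s*n\\s*=\\s*", "", hdr[1]))
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0 && is.na(n_declared)) {
    stop("no edges and no '# n = <n>' header: node count undeterminable",
         call. = FALSE)
  }
  a <- integer(length(body)); b <- integer(length(body))
  for (i in seq_along(body)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    ok <- length(parts) == 2 && all(grepl("^[0-9]+$", parts))
    if (!ok) {
      stop(sprintf("malformed edge on line %d: '%s'", lineno[i], body[i]),
           call. = FALSE)
    }
    a[i] <- as.integer(parts[1]); b[i] <- as.integer(parts[2])
    if (a[i] == b[i]) {
      stop(sprintf("self-loop on line %d: '%s'", lineno[i], body[i]),
           call. = FALSE)
    }
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  if (anyDuplicated(cbind(lo, hi))) {
    dup <- which(duplicated(cbind(lo, hi)))[1]
    stop(sprintf("duplicate edge on line %d", lineno[dup]), call. = FALSE)
  }
  n <- if (!is.na(n_declared)) n_declared else max(a, b) + 1L
  new_network(n, cbind(a, b))
}

#' @rdname read_edgelist
#' @param network A `rumour_network` to write.
#' @export
write_edgelist <- function(network, path) {
  stopifnot(inherits(network, "rumour_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n = %d", network$n), con)
  if (nrow(network$edges) > 0) {
    writeLines(paste(network$edges[, 1], network$edges[, 2]), con)
  }
  invisible(path)
}

# Expected mean degree of the truncated power law P(k) ~ k^-gamma on
# [k_min, floor(sqrt(n))], and the k_min whose expected mean degree is
# closest to `target`.  Used when matching <k> across gamma values.
powerlaw_mean_degree <- function(gamma, n, k_min) {
  ks <- k_min:floor(sqrt(n))
  sum(ks^(1 - gamma)) / sum(ks^(-gamma))
}

#' Minimum degree matching a target mean degree
#'
#' Chooses `k_min` so the truncated power law P(k) ~ k^-gamma on
#' \[k_min, sqrt(n)\] has expected mean degree closest to `target`.
#'
#' @param gamma Power-law exponent.
#' @param n Number of nodes.
#' @param target Target mean degree.
#' @return An integer `k_min`.
#' @export
powerlaw_kmin_for_mean <- function(gamma, n, target) {
  cands <- 1:max(2, floor(sqrt(n)) - 1)
  means <- vapply(cands, function(k) powerlaw_mean_degree(gamma, n, k),
                  numeric(1))
  cands[which.min(abs(means - target))]
}
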