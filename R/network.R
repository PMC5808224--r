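#' Directed network with prescribed in-degrees
#'
#' Internal constructor; use [fixed_in_degree_network()] or
#' [gaussian_in_degree_network()].
#'
#' @param N node count.
#' @param edges two-column integer matrix (source, target), 0-based ids.
#' @param meta metadata list (generator, k_mean, k_sd, seed, ...).
#' @return object of class `directed_network` with fields `N`, `edges`,
#'   `k_in` (in-degree sequence) and `meta`.
#' @keywords internal
new_directed_network <- function(N, edges, meta) {
  storage.mode(edges) <- "integer"
  colnames(edges) <- c("source", "target")
  k_in <- tabulate(edges[, "target"] + 1L, nbins = N)
  structure(list(N = as.integer(N), edges = edges, k_in = k_in, meta = meta),
            class = "directed_network")
}

# draw k distinct uniform sources (excluding `target`) for one node
.draw_sources <- function(N, k, target) {
  if (k == 0L) return(integer(0))
  src <- sample.int(N - 1L, k, replace = FALSE) - 1L
  # shift indices >= target up by one to skip the self-edge
  src + (src >= target)
}

#' Fixed in-degree random digraph
#'
#' Every node receives exactly `k` incoming edges from distinct, uniformly
#' chosen other nodes (no self-edges, no duplicate edges).  The out-degree
#' distribution is then binomial with mean `k`.
#'
#' @param N number of nodes (> 1).
#' @param k in-degree of every node, `0 <= k <= N - 1`.
#' @param seed integer RNG seed; identical seeds give identical edge lists.
#' @return a `directed_network`.
#' @export
#' @examples
#' net <- fixed_in_degree_network(6, 2, seed = 1)
#' nrow(net$edges)   # 12
#' table(net$k_in)   # all in-degrees equal 2
fixed_in_degree_network <- function(N, k, seed) {
  N <- as.integer(N); k <- as.integer(k)
  if (N < 2L) stop("N must be at least 2")
  if (k < 0L || k > N - 1L)
    stop("infeasible degree: need 0 <= k <= N - 1")
  set.seed(as.integer(seed))
  src <- integer(N * k)
  if (k > 0L) {
    for (i in seq_len(N))
      src[((i - 1L) * k + 1L):(i * k)] <- .draw_sources(N, k, i - 1L)
  }
  edges <- cbind(source = src, target = rep(0:(N - 1L), each = k))
  if (k == 0L) edges <- edges[0, , drop = FALSE]
  new_directed_network(N, edges,
    meta = list(generator = "fixed_in_degree", k_mean = k, k_sd = 0,
                seed = as.integer(seed)))
}

#' Gaussian in-degree random digraph
#'
#' Per-node in-degrees are drawn from a normal distribution with mean
#' `k_mean` and standard deviation `k_sd`, rounded to the nearest integer and
#' clipped to `[0, N - 1]`; sources are then chosen uniformly without
#' replacement among the other nodes.  With `k_sd = 0` this reduces exactly
#' to [fixed_in_degree_network()] (same seed policy).
#'
#' @param N number of nodes (> 1).
#' @param k_mean mean in-degree, in `(0, N - 1)`.
#' @param k_sd in-degree standard deviation (>= 0).
#' @param seed integer RNG seed.
#' @return a `directed_network`.
#' @export
gaussian_in_degree_network <- function(N, k_mean, k_sd, seed) {
  N <- as.integer(N)
  if (N < 2L) stop("N must be at least 2")
  if (k_mean <= 0 || k_mean >= N - 1) stop("k_mean must lie in (0, N - 1)")
  if (k_sd < 0) stop("k_sd must be >= 0")
  set.seed(as.integer(seed))
  k <- if (k_sd == 0) rep(round(k_mean), N) else round(stats::rnorm(N, k_mean, k_sd))
  n_clip <- sum(k < 0L | k > N - 1L)
  if (n_clip > 0.001 * N)
    message("gaussian_in_degree_network: clipping affected ", n_clip,
            " of ", N, " nodes")
  k <- pmin.int(pmax.int(k, 0L), N - 1L)
  src <- vector("list", N)
  for (i in seq_len(N)) src[[i]] <- .draw_sources(N, k[i], i - 1L)
  edges <- cbind(source = unlist(src),
                 target = rep(0:(N - 1L), times = k))
  if (sum(k) == 0L) edges <- matrix(integer(0), 0, 2)
  new_directed_network(N, edges,
    meta = list(generator = "gaussian_in_degree", k_mean = k_mean,
                k_sd = k_sd, seed = as.integer(seed), n_clipped = n_clip))
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("Directed network: %d nodes, %d edges (%s, k_mean = %g, k_sd = %g, seed = %d)\n",
              x$N, nrow(x$edges), x$meta$generator, x$meta$k_mean,
              x$meta$k_sd, x$meta$seed))
  invisible(x)
}

#' Write a network as edge-list CSV plus JSON metadata sidecar
#'
#' The CSV has header `source,target` with 0-based node ids; the sidecar
#' (`<path>.json`) stores `N` and the generator metadata so the round-trip
#' through [read_network()] is exact.
#'
#' @param net a `directed_network`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  utils::write.csv(as.data.frame(net$edges), path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(list(N = net$N), net$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network from an edge-list CSV (with optional JSON sidecar)
#'
#' @param path CSV path as written by [write_network()]; a missing sidecar is
#'   tolerated (N is then inferred from the edge list).
#' @return a `directed_network`.
#' @export
read_network <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("source", "target") %in% names(df)))
    stop("edge list must have 'source,target' header")
  edges <- cbind(source = as.integer(df$source), target = as.integer(df$target))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    N <- meta$N
    meta$N <- NULL
  } else {
    N <- max(edges) + 1L
    meta <- list(generator = "file", k_mean = NA, k_sd = NA, seed = NA)
  }
  new_directed_network(N, edges, meta)
}
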