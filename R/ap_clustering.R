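# Exemplar-based affinity propagation (Frey & Dueck responsibility /
# availability message passing), written directly against the similarity
# matrices produced by build_similarity(). The preference (self-similarity)
# is set to a quantile of the off-diagonal similarities, so cluster
# granularity emerges from the data; q = 0.5 (the median) is the default
# used for both genome and trait clustering.

#' Set the affinity-propagation preference from a quantile
#'
#' Writes the q-th quantile (linear interpolation) of the off-diagonal
#' similarity values onto the diagonal. q = 0 gives the minimum (fewest
#' clusters), q = 1 the maximum.
#'
#' @param S square similarity matrix (a `similarity_matrix` object or plain
#'   matrix); off-diagonal entries must be finite.
#' @param q quantile in \[0, 1\].
#' @return the matrix with its diagonal set; the chosen preference is
#'   stored in attribute `preference`.
#' @export
set_preference <- function(S, q = 0.5) {
  if (inherits(S, "similarity_matrix")) S <- S$S
  S <- as.matrix(S)
  if (!nrow(S)) ta_stop("empty similarity matrix")
  off <- S[row(S) != col(S)]
  if (length(off) && any(!is.finite(off))) ta_stop("non-finite off-diagonal similarity")
  pref <- if (length(off)) unname(quantile(off, q, type = 7)) else 0
  diag(S) <- pref
  attr(S, "preference") <- pref
  S
}

#' Affinity propagation clustering
#'
#' Damped responsibility/availability message passing on a similarity
#' matrix whose diagonal holds the preferences (see [set_preference()]).
#' Iteration stops when the exemplar set has been stable for `convits`
#' sweeps or after `maxit` sweeps. A seeded jitter of relative magnitude
#' `jitter` breaks exact degeneracies deterministically; remaining ties are
#' broken toward the smallest item index. After convergence, each cluster's
#' exemplar is refined to the member maximizing total within-cluster
#' similarity (one pass), and items are assigned to their most similar
#' exemplar.
#'
#' @param S square similarity matrix with the diagonal (preference) set.
#' @param damping message damping factor in \[0.5, 1).
#' @param maxit maximum sweeps.
#' @param convits sweeps of unchanged exemplar set required to declare
#'   convergence.
#' @param jitter relative magnitude of the seeded degeneracy-breaking
#'   noise (0 disables it).
#' @param seed integer seed for the jitter.
#' @return object of class `ap_result`: list with `cluster` (named integer
#'   vector item -> cluster id, ids contiguous from 1), `exemplars` (named
#'   character vector cluster id -> item id), `n_iterations`, `converged`,
#'   `net_similarity`, `preference`.
#' @export
affinity_propagation <- function(S, damping = 0.9, maxit = 1000L,
                                 convits = 100L, jitter = 1e-9, seed = 1L) {
  if (inherits(S, "similarity_matrix")) {
    ta_stop("set the preference first (set_preference) before clustering")
  }
  S <- as.matrix(S)
  n <- nrow(S)
  if (n != ncol(S)) ta_stop("similarity matrix must be square")
  ids <- rownames(S)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (any(!is.finite(S))) ta_stop("similarity matrix has non-finite entries")
  S0 <- S                                     # jitter-free copy for scoring
  if (n == 1L) {
    res <- structure(list(cluster = setNames(1L, ids),
                          exemplars = setNames(ids, "1"),
                          n_iterations = 0L, converged = TRUE,
                          net_similarity = S0[1L, 1L],
                          preference = S0[1L, 1L]),
                     class = "ap_result")
    return(res)
  }
  if (jitter > 0) {
    set.seed(seed)
    scale <- (max(S) - min(S))
    if (scale == 0) scale <- 1
    S <- S + jitter * scale * matrix(runif(n * n), n, n)
  }
  A <- R <- matrix(0, n, n)
  idx <- seq_len(n)
  ex_prev <- integer()
  stable <- 0L
  it <- 0L
  converged <- FALSE
  while (it < maxit) {
    it <- it + 1L
    # responsibilities: r(i,k) = s(i,k) - max_{k' != k} [a(i,k') + s(i,k')]
    AS <- A + S
    j1 <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(idx, j1)]
    AS[cbind(idx, j1)] <- -Inf
    m2 <- AS[cbind(idx, max.col(AS, ties.method = "first"))]
    Rnew <- S - m1
    Rnew[cbind(idx, j1)] <- S[cbind(idx, j1)] - m2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities: a(i,k) = min(0, r(k,k) + sum_{i' != i,k} max(0, r(i',k)))
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, ex_prev)) {
      stable <- stable + 1L
      if (stable >= convits && length(ex)) { converged <- TRUE; break }
    } else {
      stable <- 0L
      ex_prev <- ex
    }
  }
  ex <- which(diag(A) + diag(R) > 0)
  if (!length(ex)) ex <- which.max(diag(A) + diag(R))
  if (!converged) {
    ta_warn("affinity propagation did not converge in %d iterations", maxit)
  }
  # assign to the most similar exemplar (ties -> smallest exemplar index)
  assign_to <- ex[max.col(S0[, ex, drop = FALSE], ties.method = "first")]
  assign_to[ex] <- ex
  # one refinement pass: within each cluster pick the member maximizing
  # total similarity to the cluster, then re-assign
  new_ex <- vapply(ex, function(e) {
    members <- which(assign_to == e)
    scores <- colSums(S0[members, members, drop = FALSE])
    members[which.max(scores)]
  }, 0L)
  new_ex <- sort(unique(new_ex))
  assign_to <- new_ex[max.col(S0[, new_ex, drop = FALSE], ties.method = "first")]
  assign_to[new_ex] <- new_ex
  cluster_of <- match(assign_to, new_ex)
  cluster <- setNames(cluster_of, ids)
  exemplars <- setNames(ids[new_ex], as.character(seq_along(new_ex)))
  ns <- sum(S0[cbind(idx, assign_to)])
  structure(list(cluster = cluster, exemplars = exemplars,
                 n_iterations = it, converged = converged,
                 net_similarity = ns,
                 preference = mean(diag(S0))),
            class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("ap_result: %d items in %d clusters (net similarity %.4f, %s in %d iterations)\n",
              length(x$cluster), length(x$exemplars), x$net_similarity,
              if (x$converged) "converged" else "NOT converged", x$n_iterations))
  invisible(x)
}

#' Exact exemplar clustering by exhaustive search
#'
#' Independent oracle for small problems: enumerates every non-empty
#' exemplar subset, assigns each item to its most similar exemplar, and
#' returns the subset maximizing net similarity (sum of member-to-exemplar
#' similarities plus exemplar preferences). Exponential in n.
#'
#' @param S square similarity matrix with the diagonal (preference) set.
#' @param max_n refuse problems larger than this.
#' @return an `ap_result` with the optimal clustering.
#' @export
brute_force_exemplars <- function(S, max_n = 10L) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (n > max_n) ta_stop("brute force limited to n <= %d (got %d)", max_n, n)
  ids <- rownames(S)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  best <- -Inf
  best_ex <- NULL
  for (mask in seq_len(2^n - 1L)) {
    ex <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    assign_to <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
    assign_to[ex] <- ex
    val <- sum(S[cbind(seq_len(n), assign_to)])
    if (val > best + 1e-12) { best <- val; best_ex <- ex }
  }
  ex <- best_ex
  assign_to <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assign_to[ex] <- ex
  used <- sort(unique(assign_to))
  cluster <- setNames(match(assign_to, used), ids)
  structure(list(cluster = cluster,
                 exemplars = setNames(ids[used], as.character(seq_along(used))),
                 n_iterations = NA_integer_, converged = TRUE,
                 net_similarity = sum(S[cbind(seq_len(n), assign_to)]),
                 preference = mean(diag(S))),
            class = "ap_result")
}

#' Agglomerate affinity-propagation clusters into a dendrogram
#'
#' Greedy merging of an exemplar clustering down to `k_target` clusters.
#' At each step every cluster pair is scored by its best joint exemplar —
#' the member of the union maximizing mean similarity to the other members
#' — and the best-scoring pair is merged. Used for dendrogram export only.
#'
#' @param S similarity matrix used for the clustering (diagonal set).
#' @param result an `ap_result`.
#' @param k_target number of clusters to merge down to.
#' @return list with `cluster` (named merged assignment at `k_target`),
#'   `merges` (data frame: step, cluster_a, cluster_b, joint_exemplar,
#'   score).
#' @export
agglomerate_exemplars <- function(S, result, k_target) {
  S <- as.matrix(S)
  ids <- rownames(S)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(S)))
  k <- length(result$exemplars)
  if (k_target > k) ta_stop("k_target (%d) exceeds cluster count (%d)", k_target, k)
  groups <- split(ids, result$cluster[ids])
  merges <- list()
  step <- 0L
  while (length(groups) > k_target) {
    nms <- names(groups)
    best <- -Inf; bi <- bj <- NA; bex <- NA
    for (i in seq_along(groups)[-length(groups)]) {
      for (j in (i + 1L):length(groups)) {
        u <- c(groups[[i]], groups[[j]])
        sc <- vapply(u, function(e) mean(S[setdiff(u, e), e]), 0)
        w <- which.max(sc)
        if (sc[w] > best) { best <- sc[w]; bi <- i; bj <- j; bex <- u[w] }
      }
    }
    step <- step + 1L
    merges[[step]] <- data.frame(step = step, cluster_a = nms[bi],
                                 cluster_b = nms[bj], joint_exemplar = bex,
                                 score = best, stringsAsFactors = FALSE)
    groups[[bi]] <- c(groups[[bi]], groups[[bj]])
    groups <- groups[-bj]
  }
  cluster <- integer(length(ids))
  names(cluster) <- ids
  for (i in seq_along(groups)) cluster[groups[[i]]] <- i
  list(cluster = cluster,
       merges = if (step) do.call(rbind, merges) else
         data.frame(step = integer(), cluster_a = character(),
                    cluster_b = character(), joint_exemplar = character(),
                    score = numeric()))
}
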