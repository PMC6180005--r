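# Affinity propagation (Frey & Dueck) over a gene similarity matrix.
#
# Exemplar-based clustering by message passing: responsibilities r(i,k)
# say how well-suited k is as exemplar for i relative to other candidates;
# availabilities a(i,k) accumulate the support k has gathered. Both are
# damped. The diagonal "preference" controls how readily points become
# exemplars and hence the number of clusters.

#' Affinity-propagation configuration
#'
#' Defaults follow the conventional settings used for gene clustering by
#' functional similarity: at most 500 iterations, convergence declared
#' after 50 iterations of unchanged exemplars, damping 0.95, preference set
#' to the median of the off-diagonal similarities.
#'
#' @param max_iterations maximum message-passing iterations (default 500).
#' @param convits iterations of stable exemplar set required to declare
#'   convergence (default 50).
#' @param damping damping factor in \[0.5, 1) (default 0.95).
#' @param preference numeric preference, or `"median"` (default) for the
#'   median of off-diagonal similarities.
#' @param jitter_scale scale of the seed-controlled degeneracy-breaking
#'   noise, applied as `jitter_scale * (max - min similarity) * 1e-12`.
#' @param seed integer seed for the jitter (default 1).
#' @return an object of class `ap_config`.
#' @export
ap_config <- function(max_iterations = 500L, convits = 50L, damping = 0.95,
                      preference = "median", jitter_scale = 1, seed = 1L) {
  if (damping < 0.5 || damping >= 1) stop("damping must lie in [0.5, 1)")
  if (convits >= max_iterations) stop("convits must be below max_iterations")
  structure(list(max_iterations = as.integer(max_iterations),
                 convits = as.integer(convits),
                 damping = damping, preference = preference,
                 jitter_scale = jitter_scale, seed = as.integer(seed)),
            class = "ap_config")
}

# deterministic hash of a label pair + seed, mapped to [-0.5, 0.5]
.pair_hash <- function(a, b, seed) {
  x <- utf8ToInt(paste(a, b, seed, sep = "\r"))
  h <- 0
  for (ch in x) h <- (h * 131 + ch) %% 2147483647
  h / 2147483647 - 0.5
}

#' Cluster genes by affinity propagation
#'
#' @param sim symmetric similarity matrix with dimnames (e.g. from
#'   [gene_sim_matrix()]).
#' @param config an [ap_config].
#' @return an object of class `ap_clustering`: list with `clusters` (named
#'   character: gene -> exemplar label), `exemplars`, `converged`,
#'   `iterations`, `preference`.
#' @examples
#' s <- rbind(c(1, .9, .1), c(.9, 1, .1), c(.1, .1, 1))
#' dimnames(s) <- list(letters[1:3], letters[1:3])
#' affinity_propagation(s)
#' @export
affinity_propagation <- function(sim, config = ap_config()) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim)) stop("sim must be a square matrix")
  if (max(abs(sim - t(sim))) > 1e-8) stop("similarity matrix is not symmetric")
  n <- nrow(sim)
  ids <- rownames(sim)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  if (n == 1L) {
    return(structure(list(clusters = stats::setNames(ids, ids),
                          exemplars = ids, converged = TRUE, iterations = 0L,
                          preference = NA_real_),
                     class = "ap_clustering"))
  }

  off <- sim[row(sim) != col(sim)]
  pref <- if (identical(config$preference, "median")) stats::median(off)
          else as.numeric(config$preference)

  S <- sim
  diag(S) <- pref
  rng <- diff(range(S))
  if (rng == 0) rng <- 1
  # degeneracy-breaking jitter keyed on the gene labels and the seed, so a
  # permutation of the input permutes the jitter with it (equivariance)
  # and reruns are bit-for-bit reproducible without touching the RNG state
  jit <- outer(ids, ids, function(a, b) {
    mapply(function(x, y) .pair_hash(x, y, config$seed), a, b)
  })
  S <- S + jit * config$jitter_scale * rng * 1e-12

  lam <- config$damping
  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  exemplar_history <- matrix(FALSE, n, config$convits)
  converged <- FALSE
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L

    AS <- A + S
    first <- apply(AS, 1L, max)
    first_idx <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), first_idx)] <- -Inf
    second <- apply(AS2, 1L, max)
    Rnew <- S - first
    Rnew[cbind(seq_len(n), first_idx)] <- S[cbind(seq_len(n), first_idx)] - second
    R <- lam * R + (1 - lam) * Rnew

    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dAnew <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dAnew
    A <- lam * A + (1 - lam) * Anew

    ex <- diag(A) + diag(R) > 0
    exemplar_history[, (it - 1L) %% config$convits + 1L] <- ex
    if (it >= config$convits && any(ex)) {
      stable <- all(apply(exemplar_history, 1L, function(z) all(z) || !any(z)))
      if (stable) { converged <- TRUE; break }
    }
  }

  ex_idx <- which(diag(A) + diag(R) > 0)
  if (length(ex_idx) == 0L) ex_idx <- which.max(diag(A) + diag(R))
  assign_idx <- ex_idx[max.col(S[, ex_idx, drop = FALSE], ties.method = "first")]
  assign_idx[ex_idx] <- ex_idx
  if (!converged) {
    warning("affinity propagation did not converge in ", config$max_iterations,
            " iterations; returning the current assignment")
  }
  structure(list(clusters = stats::setNames(ids[assign_idx], ids),
                 exemplars = ids[ex_idx], converged = converged,
                 iterations = it, preference = pref),
            class = "ap_clustering")
}

#' @export
print.ap_clustering <- function(x, ...) {
  cat("Affinity-propagation clustering: ", length(x$clusters), " genes, ",
      length(x$exemplars), " cluster(s)",
      if (x$converged) " (converged in " else " (NOT converged after ",
      x$iterations, " iterations)\n", sep = "")
  for (e in x$exemplars) {
    members <- names(x$clusters)[x$clusters == e]
    cat("  [", e, "] ", paste(members, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Cluster membership as a data.frame
#' @param x an `ap_clustering`.
#' @param ... unused.
#' @return data.frame with columns `gene`, `cluster`, `exemplar`.
#' @export
as.data.frame.ap_clustering <- function(x, ...) {
  ex <- unname(x$clusters)
  data.frame(gene = names(x$clusters),
             cluster = match(ex, x$exemplars),
             exemplar = ex,
             stringsAsFactors = FALSE)
}
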