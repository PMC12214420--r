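#' Partition constructor
#'
#' A partition assigns every in-mask voxel a label in `1..K`; every label is
#' occupied.
#'
#' @param labels integer vector of length `mask$n` with values in `1..K`.
#' @param mask a [voxel_mask()].
#' @param K number of clusters; defaults to `max(labels)`.
#' @return An object of class `partition`.
#' @export
new_partition <- function(labels, mask, K = max(labels), validate = TRUE) {
  labels <- as.integer(labels)
  if (validate) {
    stopifnot(length(labels) == mask$n, all(labels >= 1L), all(labels <= K))
    if (length(unique(labels)) != K)
      stop("partition has empty labels: expected ", K, " occupied clusters")
  }
  structure(list(labels = labels, K = as.integer(K), mask = mask),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d voxels in %d clusters (sizes %s)\n",
              length(x$labels), x$K,
              paste(utils::head(sort(tabulate(x$labels, x$K)), 8), collapse = ", ")))
  invisible(x)
}

#' Spectral clustering configuration
#'
#' Numerical knobs for [spectral_partition()]. None of these are part of the
#' statistical model; they control determinism and convergence.
#'
#' @param K number of clusters, >= 1.
#' @param eig_tol eigensolver tolerance (ARPACK path), > 0.
#' @param kmeans_restarts random restarts of k-means on the embedding, >= 1.
#' @param kmeans_max_iter k-means iteration cap.
#' @param seed RNG seed for k-means initialization.
#' @param method `"auto"` (dense eigendecomposition up to `dense_threshold`
#'   voxels, ARPACK beyond), `"dense"`, or `"arpack"`.
#' @param dense_threshold problem size at which `"auto"` switches to ARPACK.
#' @param partition_method `"recursive"` (default): recursive two-way
#'   normalized cut, each bipartition from the Fiedler vector with the
#'   splitting threshold swept to minimize the true 2-way ncut —
#'   deterministic and directly tied to the cut objective. `"kway"`: k-means
#'   (k-means++ initialized) on the K-eigenvector embedding.
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(K, eig_tol = 1e-8, kmeans_restarts = 10,
                            kmeans_max_iter = 100, seed = 1,
                            method = c("auto", "dense", "arpack"),
                            dense_threshold = 2048,
                            partition_method = c("recursive", "kway")) {
  stopifnot(K >= 1, eig_tol > 0, kmeans_restarts >= 1, kmeans_max_iter >= 1)
  structure(list(K = as.integer(K), eig_tol = eig_tol,
                 kmeans_restarts = as.integer(kmeans_restarts),
                 kmeans_max_iter = as.integer(kmeans_max_iter),
                 seed = as.integer(seed), method = match.arg(method),
                 dense_threshold = as.integer(dense_threshold),
                 partition_method = match.arg(partition_method)),
            class = "spectral_config")
}

# Coerce input to a symmetric nonnegative similarity matrix + optional mask.
as_similarity_matrix <- function(s) {
  if (inherits(s, "sparse_similarity")) return(list(mat = s$mat, mask = s$mask))
  if (inherits(s, "group_similarity")) return(list(mat = s$mat, mask = s$mask))
  if (is.matrix(s)) return(list(mat = methods::as(Matrix::Matrix(s, sparse = TRUE), "CsparseMatrix"), mask = NULL))
  if (methods::is(s, "Matrix")) return(list(mat = methods::as(s, "CsparseMatrix"), mask = NULL))
  stop("unsupported similarity input of class ", paste(class(s), collapse = "/"))
}

# K largest eigenvectors of the symmetric normalized adjacency
# D^{-1/2} W D^{-1/2}; returns the Shi-Malik (random-walk) embedding rows
# D^{-1/2} U. These are the K smallest eigenvectors of the random-walk
# Laplacian L_rw = I - D^{-1} W.
spectral_embedding <- function(W, K, cfg) {
  n <- nrow(W)
  d <- Matrix::rowSums(W)
  dis <- 1 / sqrt(d)
  method <- cfg$method
  if (method == "auto") method <- if (n <= cfg$dense_threshold) "dense" else "arpack"
  if (n <= max(64L, 4L * K)) method <- "dense"  # ARPACK needs nev < ncv <= n
  if (method == "dense") {
    A <- as.matrix(W) * outer(dis, dis)
    U <- eigen((A + t(A)) / 2, symmetric = TRUE)$vectors[, seq_len(K), drop = FALSE]
  } else {
    A <- Matrix::Diagonal(x = dis) %*% W %*% Matrix::Diagonal(x = dis)
    A <- Matrix::forceSymmetric(A)
    res <- igraph::arpack(function(x, extra) as.numeric(A %*% x),
                          options = list(n = n, nev = K,
                                         ncv = min(n, max(4L * K, 20L)),
                                         which = "LA", maxiter = 3000,
                                         tol = cfg$eig_tol),
                          sym = TRUE)
    U <- matrix(res$vectors, nrow = n)[, seq_len(K), drop = FALSE]
  }
  U * dis
}

# Best two-way normalized cut of the subgraph on `nodes`: random-walk
# Fiedler vector, then every splitting threshold along its sorted order is
# evaluated by the exact 2-way ncut (incremental cut/volume bookkeeping).
# Returns NULL when the subgraph cannot be split spectrally.
best_bipartition <- function(W, nodes, cfg) {
  n <- length(nodes)
  if (n < 2L) return(NULL)
  Ws <- W[nodes, nodes, drop = FALSE]
  d <- Matrix::rowSums(Ws)
  if (any(d <= 0)) {
    # internally disconnected singletons: split them off at zero cost
    z <- d <= 0
    if (all(z)) return(list(ncut = 0, left = nodes[1], right = nodes[-1]))
    return(list(ncut = 0, left = nodes[z], right = nodes[!z]))
  }
  f <- spectral_embedding(Ws, 2L, cfg)[, 2]
  ord <- order(f, nodes)  # secondary key: determinism under ties
  Wo <- methods::as(Ws[ord, ord, drop = FALSE], "TsparseMatrix")
  dord <- d[ord]
  vol_left <- cumsum(dord)
  vol_total <- vol_left[n]
  adj_i <- split(seq_along(Wo@i), Wo@i + 1L)
  wA <- numeric(n)  # weight from each vertex into the growing left part
  cut <- 0
  ncut_at <- numeric(n - 1L)
  jj <- Wo@j + 1L; xx <- Wo@x
  for (t in seq_len(n - 1L)) {
    cut <- cut + dord[t] - 2 * wA[t]
    ids <- adj_i[[as.character(t)]]
    if (!is.null(ids)) {
      tgt <- jj[ids]
      wA[tgt] <- wA[tgt] + xx[ids]
    }
    ncut_at[t] <- cut / vol_left[t] + cut / (vol_total - vol_left[t])
  }
  t <- which.min(ncut_at)
  list(ncut = ncut_at[t], left = nodes[ord[seq_len(t)]],
       right = nodes[ord[seq.int(t + 1L, n)]])
}

# Recursive two-way normalized cut down to K clusters: repeatedly apply the
# cheapest available bipartition (greedy on the 2-way ncut value).
recursive_ncut <- function(W, K, cfg) {
  n <- nrow(W)
  clusters <- list(seq_len(n))
  splits <- list(best_bipartition(W, clusters[[1]], cfg))
  while (length(clusters) < K) {
    vals <- vapply(splits, function(s) if (is.null(s)) Inf else s$ncut, numeric(1))
    b <- which.min(vals)
    if (!is.finite(vals[b])) {
      # no spectral split available; halve the largest multi-voxel cluster
      sizes <- lengths(clusters)
      sizes[sizes < 2L] <- 0L
      b <- which.max(sizes)
      mem <- clusters[[b]]
      s <- list(left = mem[1], right = mem[-1])
    } else {
      s <- splits[[b]]
    }
    clusters <- c(clusters[-b], list(s$left, s$right))
    splits <- c(splits[-b],
                list(best_bipartition(W, s$left, cfg),
                     best_bipartition(W, s$right, cfg)))
  }
  labels <- integer(n)
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  labels
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center. Essential here: the spectral
# embedding of a well-separated graph is K tight point clouds, where
# uniform random initialization routinely leaves a cloud without a center
# and Lloyd iterations cannot recover.
kmeanspp_centers <- function(V, K) {
  n <- nrow(V)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1L)
  d2 <- colSums((t(V) - V[centers[1], ])^2)
  for (k in seq_len(K - 1L)) {
    tot <- sum(d2)
    centers[k + 1L] <- if (tot <= 0) sample.int(n, 1L) else
      sample.int(n, 1L, prob = d2 / tot)
    d2 <- pmin(d2, colSums((t(V) - V[centers[k + 1L], ])^2))
  }
  V[centers, , drop = FALSE]
}

# k-means on the embedding rows: restarts of k-means++ initialized Lloyd,
# best within-cluster sum of squares kept; guard for fewer distinct rows
# than K.
embedding_kmeans <- function(V, K, cfg) {
  with_seed(cfg$seed, {
    uniq <- unique(round(V, 10))
    if (nrow(uniq) < K) {
      # degenerate embedding: cluster the distinct rows, then split the
      # largest clusters until K labels are occupied
      labels <- match(data.frame(t(round(V, 10))), data.frame(t(uniq)))
      labels <- as.integer(labels)
      while (length(unique(labels)) < K) {
        sizes <- tabulate(labels)
        big <- which.max(sizes)
        mem <- which(labels == big)
        labels[mem[seq_len(ceiling(length(mem) / 2))]] <- max(labels) + 1L
      }
      return(labels)
    }
    best <- NULL
    for (r in seq_len(cfg$kmeans_restarts)) {
      ctr <- kmeanspp_centers(V, K)
      km <- tryCatch(
        stats::kmeans(V, centers = ctr, iter.max = cfg$kmeans_max_iter),
        error = function(e) NULL)
      if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
        best <- km
    }
    if (is.null(best))
      best <- stats::kmeans(V, centers = K, nstart = cfg$kmeans_restarts,
                            iter.max = cfg$kmeans_max_iter)
    best$cluster
  })
}

# Relabel clusters 1..K by order of first occurrence (determinism).
canonical_labels <- function(labels) {
  match(labels, unique(labels))
}

#' Normalized-cut spectral partition of a similarity graph
#'
#' Shi-Malik normalized cut on the random-walk Laplacian
#' \eqn{L_{rw} = I - D^{-1}W}. The default (`partition_method =
#' "recursive"`) recursively bipartitions the graph: each split thresholds
#' the Fiedler vector at the point minimizing the exact two-way ncut, and
#' the cheapest available split is applied until K clusters exist —
#' deterministic, and each boundary gets its own eigenproblem. The
#' `"kway"` alternative runs k-means (k-means++ initialization) on the rows
#' of the K smallest eigenvectors.
#' When the similarity graph has exactly K connected components
#' the components themselves are returned — they are the exact optimum and
#' the eigenbasis is indicator-spanned. Isolated voxels (zero similarity to
#' every neighbour) are excluded from the eigenproblem and afterwards
#' attached to the cluster of the spatially nearest non-isolated voxel
#' (Euclidean mm distance; ties broken toward the lowest label).
#'
#' @param s a `sparse_similarity`, `group_similarity`, or a symmetric
#'   nonnegative matrix.
#' @param cfg a [spectral_config()]; alternatively pass `K` (and optionally
#'   `seed`) directly.
#' @param K,seed shorthand used when `cfg` is `NULL`.
#' @param mask optional [voxel_mask()] when `s` is a bare matrix.
#' @return A [new_partition()] with attribute `"n_isolated"`.
#' @export
spectral_partition <- function(s, cfg = NULL, K = NULL, seed = 1, mask = NULL) {
  if (is.null(cfg)) {
    if (is.null(K)) stop("supply `cfg` or `K`")
    cfg <- spectral_config(K, seed = seed)
  }
  sm <- as_similarity_matrix(s)
  if (is.null(sm$mask)) sm$mask <- mask
  W <- sm$mat
  Matrix::diag(W) <- 0
  n <- nrow(W)
  K <- cfg$K
  if (K > n) stop("K = ", K, " exceeds the number of voxels (", n, ")")
  labels <- integer(n)
  deg <- Matrix::rowSums(W)
  act <- which(deg > 0)
  iso <- which(deg <= 0)
  if (length(act) < K)
    stop("only ", length(act), " non-isolated voxels for K = ", K)
  if (K == 1L) {
    labels[] <- 1L
  } else {
    Wa <- W[act, act, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(Wa > 0, mode = "undirected")
    comp <- igraph::components(g)
    if (comp$no > K)
      stop("similarity graph has ", comp$no,
           " connected components among non-isolated voxels; K = ", K,
           " is infeasible")
    la <- if (comp$no == K) {
      as.integer(comp$membership)
    } else if (cfg$partition_method == "recursive") {
      recursive_ncut(Wa, K, cfg)
    } else {
      V <- spectral_embedding(Wa, K, cfg)
      embedding_kmeans(V, K, cfg)
    }
    labels[act] <- canonical_labels(la)
  }
  if (length(iso) > 0) {
    if (is.null(sm$mask)) {
      warning(length(iso), " isolated voxel(s) and no mask geometry; assigned label 1")
      labels[iso] <- 1L
    } else {
      xyz <- mask_coords_mm(sm$mask)
      for (v in iso) {
        d2 <- colSums((t(xyz[act, , drop = FALSE]) - xyz[v, ])^2)
        best <- min(d2)
        cand <- labels[act[d2 <= best + 1e-12]]
        labels[v] <- min(cand)
      }
    }
  }
  p <- new_partition(canonical_labels(labels),
                     mask = if (is.null(sm$mask)) synthetic_line_mask(n) else sm$mask,
                     K = K)
  attr(p, "n_isolated") <- length(iso)
  p
}

# Placeholder 1D geometry for partitions built from bare matrices.
synthetic_line_mask <- function(n) {
  voxel_mask(array(TRUE, dim = c(n, 1, 1)))
}

#' Report or repair spatial contiguity of a partition
#'
#' Counts, per cluster, its connected components in the neighbour graph. In
#' repair mode each cluster keeps its largest component and every detached
#' fragment is reassigned to the neighbouring cluster with which it shares
#' the most graph edges (ties toward the lowest label), iterating until all
#' clusters are connected.
#'
#' @param p a `partition`.
#' @param g a [build_neighbor_graph()] on the same mask.
#' @param mode `"report"` (default) or `"repair"`.
#' @return list with `partition` (repaired or input), `components`
#'   (per-label component counts), `n_reassigned`.
#' @export
contiguity_repair <- function(p, g, mode = c("report", "repair")) {
  mode <- match.arg(mode)
  stopifnot(inherits(p, "partition"), inherits(g, "neighbor_graph"))
  if (!identical(p$mask$linear, g$mask$linear))
    stop("partition and neighbor graph are on different masks")
  labels <- p$labels
  n_reassigned <- 0L
  cluster_components <- function(labels) {
    e <- g$edges
    same <- labels[e[, 1]] == labels[e[, 2]]
    gr <- igraph::graph_from_edgelist(e[same, , drop = FALSE], directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0L, p$mask$n - igraph::vcount(gr)))
    igraph::components(gr)$membership
  }
  repeat {
    memb <- cluster_components(labels)
    counts <- vapply(seq_len(p$K), function(k)
      length(unique(memb[labels == k])), integer(1))
    if (mode == "report" || all(counts <= 1L)) break
    # reassign every fragment (non-largest component) of the worst cluster set
    changed <- FALSE
    for (k in which(counts > 1L)) {
      mem <- which(labels == k)
      comps <- split(mem, memb[mem])
      keep <- which.max(lengths(comps))
      for (ci in setdiff(seq_along(comps), keep)) {
        frag <- comps[[ci]]
        nb <- unlist(g$adjacency[frag])
        nb_lab <- labels[nb]
        nb_lab <- nb_lab[nb_lab != k]
        if (length(nb_lab) == 0L) next  # fragment borders nothing else; leave
        tab <- table(nb_lab)
        target <- as.integer(names(tab)[tab == max(tab)])
        labels[frag] <- min(target)
        n_reassigned <- n_reassigned + length(frag)
        changed <- TRUE
      }
      if (changed) break  # recompute components before touching other clusters
    }
    if (!changed) break
  }
  occupied <- sort(unique(labels))
  part <- if (mode == "repair" && length(occupied) < p$K) {
    new_partition(match(labels, occupied), p$mask, K = length(occupied))
  } else {
    new_partition(labels, p$mask, K = p$K)
  }
  memb <- cluster_components(part$labels)
  counts <- vapply(seq_len(part$K), function(k)
    length(unique(memb[part$labels == k])), integer(1))
  list(partition = part,
       components = data.frame(label = seq_len(part$K),
                               size = tabulate(part$labels, part$K),
                               n_components = counts),
       n_reassigned = n_reassigned)
}

#' Write a partition as TSV (voxel index, label)
#' @param p a `partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(p, path) {
  utils::write.table(data.frame(voxel = seq_along(p$labels) - 1L, label = p$labels),
                     path, sep = "\t", row.names = FALSE, col.names = TRUE)
  invisible(path)
}
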