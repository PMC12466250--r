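# Spatio-temporal consistency clustering: the motion-consistency integral,
# cardiac phase normalization, the hybrid appearance/motion descriptor,
# the Gaussian affinity graph with its combinatorial Laplacian L = D - W,
# spectral clustering, DBSCAN refinement, and cluster-quality measures.

#' Motion-consistency integral of a flow field
#'
#' Accumulates, over all valid frame pairs, the squared spatial gradient
#' magnitude of the flow field:
#' `I_motion(x, y) = sum_t ||grad V_t(x, y)||^2 * dt`, with `dt = 1` frame.
#' The gradient comprises the four partial derivatives (row and column
#' derivatives of both flow components), computed by central differences
#' with replicated borders. Coherently moving tissue yields small values;
#' lesion-induced local motion heterogeneity yields large ones.
#'
#' @param flow A [flow_field()]; pairs with `valid_mask == FALSE` are
#'   skipped.
#' @param roi Optional `H x W` logical region of interest carried along in
#'   the result.
#' @return An object of class `motion_map` with fields `values` (`H x W`,
#'   non-negative) and `roi`.
#' @export
motion_integral <- function(flow, roi = NULL) {
  stopifnot(inherits(flow, "flow_field"))
  d <- dim(flow$vectors)
  if (d[1] == 0) stop("flow field has no frame pairs")
  acc <- matrix(0, d[2], d[3])
  for (t in seq_len(d[1])) {
    if (!flow$valid_mask[t]) next
    gu <- .central_gradient(flow$vectors[t, , , 1])
    gv <- .central_gradient(flow$vectors[t, , , 2])
    acc <- acc + gu$dr^2 + gu$dc^2 + gv$dr^2 + gv$dc^2
  }
  structure(list(values = acc, roi = roi), class = "motion_map")
}

#' Phase-normalize a flow field over the cardiac cycle
#'
#' Cardiac motion is cyclic: global contraction/relaxation peaks
#' (end-systole, end-diastole) carry large motion energy that would
#' dominate the motion-consistency integral and mimic abnormality in
#' healthy tissue. This operation computes the global motion energy of
#' each frame pair (mean squared flow magnitude), excludes pairs whose
#' energy is strictly above the `energy_quantile` of the cycle's energies
#' (by clearing their `valid_mask`), and rolls the cycle so the
#' minimum-energy pair comes first.
#'
#' @param flow A [flow_field()].
#' @param energy_quantile Fraction in `(0, 1]`; default 0.8.
#' @return A [flow_field()] with reordered pairs and updated `valid_mask`.
#' @export
phase_normalize <- function(flow, energy_quantile = 0.8) {
  stopifnot(inherits(flow, "flow_field"),
            energy_quantile > 0, energy_quantile <= 1)
  np <- dim(flow$vectors)[1]
  energy <- vapply(seq_len(np), function(t)
    mean(flow$vectors[t, , , 1]^2 + flow$vectors[t, , , 2]^2), numeric(1))
  thresh <- stats::quantile(energy, energy_quantile, names = FALSE)
  keep <- flow$valid_mask & !(energy > thresh)
  if (!any(keep)) stop("phase normalization excluded every frame pair")
  origin <- which.min(energy)
  ord <- ((origin - 1L + 0:(np - 1L)) %% np) + 1L
  flow_field(flow$vectors[ord, , , , drop = FALSE], keep[ord])
}

#' Hybrid appearance/motion descriptor
#'
#' Combines spatial appearance and temporal motion evidence per pixel:
#' `Ds(x, y) = lambda_s * S(x, y) + lambda_t * I_motion(x, y)`, where the
#' spatial term `S` is the temporal mean intensity of the sequence. With
#' `standardize = TRUE` (default) each term is z-scored over the ROI
#' before weighting, so the two weights act on comparable scales.
#'
#' @param seq A [cine_sequence()].
#' @param motion A `motion_map` from [motion_integral()] on the same grid.
#' @param lambda_s,lambda_t Non-negative weights (default 0.5 each); they
#'   must not both be zero.
#' @param standardize Z-score each term over the ROI before weighting.
#' @param roi Optional `H x W` logical ROI; defaults to `motion$roi`, or
#'   the full grid.
#' @return An object of class `descriptor_map` with fields `values`,
#'   `lambda_s`, `lambda_t`, `roi`.
#' @export
hybrid_descriptor <- function(seq, motion, lambda_s = 0.5, lambda_t = 0.5,
                              standardize = TRUE, roi = NULL) {
  stopifnot(inherits(seq, "cine_sequence"), inherits(motion, "motion_map"),
            lambda_s >= 0, lambda_t >= 0)
  if (lambda_s == 0 && lambda_t == 0)
    stop("lambda_s and lambda_t must not both be zero")
  d <- dim(seq$frames)
  if (!all(d[2:3] == dim(motion$values)))
    stop("sequence and motion map shapes disagree")
  if (is.null(roi)) roi <- motion$roi
  if (is.null(roi)) roi <- matrix(TRUE, d[2], d[3])
  S <- apply(seq$frames, c(2, 3), mean)
  I <- motion$values
  if (standardize) {
    zscore <- function(m) {
      mu <- mean(m[roi]); sdv <- stats::sd(m[roi])
      if (!is.finite(sdv) || sdv == 0) sdv <- 1
      (m - mu) / sdv
    }
    S <- zscore(S); I <- zscore(I)
  }
  structure(list(values = lambda_s * S + lambda_t * I,
                 lambda_s = lambda_s, lambda_t = lambda_t, roi = roi),
            class = "descriptor_map")
}

#' Build the Gaussian affinity graph and its Laplacian over an ROI
#'
#' Nodes are the ROI pixels. For node pairs within `neighbor_radius`
#' (Chebyshev distance) the affinity is the Gaussian kernel
#' `W_ij = exp(-|Ds(i) - Ds(j)|^2 / (2 sigma^2))`; other off-diagonal
#' entries are 0 and `W_ii = 1`. The degree matrix is
#' `D = diag(rowSums(W))` and the combinatorial Laplacian `L = D - W`.
#' Sparsification to a local neighbourhood keeps the graph tractable on
#' full image grids.
#'
#' @param desc A `descriptor_map` from [hybrid_descriptor()].
#' @param roi `H x W` logical mask of nodes; defaults to `desc$roi`.
#' @param sigma Gaussian kernel scale (> 0), default 1.5.
#' @param neighbor_radius Chebyshev neighbourhood radius in pixels,
#'   default 3.
#' @param max_nodes Guard against quadratic blow-up; exceeding it is an
#'   error advising subsampling of the ROI.
#' @return An object of class `affinity_graph` with fields `nodes`
#'   (`n x 2` matrix of (row, col)), `W`, `degree`, `laplacian` (sparse
#'   `Matrix` objects) and `sigma`.
#' @export
build_affinity <- function(desc, roi = NULL, sigma = 1.5,
                           neighbor_radius = 3L, max_nodes = 20000L) {
  stopifnot(inherits(desc, "descriptor_map"), sigma > 0, neighbor_radius >= 1)
  if (is.null(roi)) roi <- desc$roi
  if (is.null(roi) || !any(roi)) stop("ROI is empty")
  h <- nrow(desc$values); w <- ncol(desc$values)
  idx <- matrix(0L, h, w)
  nodes <- which(roi, arr.ind = TRUE)
  colnames(nodes) <- c("row", "col")
  n <- nrow(nodes)
  if (n > max_nodes)
    stop(sprintf(paste0(
      "ROI has %d pixels (max_nodes = %d); subsample the ROI or raise ",
      "max_nodes"), n, max_nodes))
  idx[nodes] <- seq_len(n)
  vals <- desc$values[nodes]

  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  R <- as.integer(neighbor_radius)
  offsets <- expand.grid(dr = -R:R, dc = -R:R)
  offsets <- offsets[offsets$dr > 0 | (offsets$dr == 0 & offsets$dc > 0), ]
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets$dr[k]; dc <- offsets$dc[k]
    r2 <- nodes[, 1] + dr; c2 <- nodes[, 2] + dc
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
    j <- integer(n); j[ok] <- idx[cbind(r2[ok], c2[ok])]
    ok <- ok & j > 0
    if (!any(ok)) next
    i <- which(ok)
    wgt <- exp(-(vals[i] - vals[j[i]])^2 / (2 * sigma^2))
    ii <- c(ii, i); jj <- c(jj, j[i]); ww <- c(ww, wgt)
  }
  W <- Matrix::sparseMatrix(i = c(ii, jj, seq_len(n)),
                            j = c(jj, ii, seq_len(n)),
                            x = c(ww, ww, rep(1, n)), dims = c(n, n))
  D <- Matrix::Diagonal(n, Matrix::rowSums(W))
  structure(list(nodes = nodes, W = W, degree = D, laplacian = D - W,
                 sigma = sigma),
            class = "affinity_graph")
}

#' Construct an affinity graph from an explicit affinity matrix
#'
#' Wraps a symmetric non-negative affinity matrix (unit diagonal) into the
#' graph container used by [spectral_cluster()], computing the degree
#' matrix and the combinatorial Laplacian `L = D - W`.
#'
#' @param W `n x n` symmetric affinity matrix with entries in `[0, 1]` and
#'   unit diagonal (dense or sparse).
#' @param nodes Optional `n x 2` node coordinates; defaults to trivial
#'   1-D positions.
#' @param sigma Kernel scale recorded as metadata (default `NA`).
#' @return An object of class `affinity_graph`.
#' @export
affinity_graph <- function(W, nodes = NULL, sigma = NA_real_) {
  W <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  n <- nrow(W)
  if (ncol(W) != n) stop("W must be square")
  if (max(abs(W - Matrix::t(W))) > 1e-10) stop("W must be symmetric")
  if (any(W@x < 0) || any(W@x > 1 + 1e-12)) stop("W entries must lie in [0, 1]")
  if (any(abs(Matrix::diag(W) - 1) > 1e-12)) stop("W must have unit diagonal")
  if (is.null(nodes)) nodes <- cbind(row = seq_len(n), col = rep(1L, n))
  D <- Matrix::Diagonal(n, Matrix::rowSums(W))
  structure(list(nodes = nodes, W = W, degree = D, laplacian = D - W,
                 sigma = sigma),
            class = "affinity_graph")
}

# Smallest-k eigenvectors of a symmetric sparse Laplacian. Dense solve for
# small n; shifted ARPACK (largest of sI - L) otherwise.
#' @noRd
.laplacian_eigenvectors <- function(L, k) {
  n <- nrow(L)
  if (n <= 500) {
    e <- eigen(as.matrix(L), symmetric = TRUE)
    return(e$vectors[, n:(n - k + 1), drop = FALSE])
  }
  shift <- 2 * max(Matrix::diag(L)) + 1
  mv <- function(x, extra = NULL) as.numeric(shift * x - L %*% x)
  res <- igraph::arpack(mv, sym = TRUE,
                        options = list(n = n, nev = k,
                                       ncv = min(n, max(4 * k + 10, 25)),
                                       which = "LA", maxiter = 3000))
  v <- res$vectors
  if (is.null(dim(v))) v <- matrix(v, ncol = 1)
  v[, seq_len(k), drop = FALSE]
}

# Greedy single-node refinement of a bipartition towards lower normalized
# cut (first-improvement passes, incremental updates, deterministic).
#' @noRd
.ncut_refine <- function(W, in_a, max_passes = 10L) {
  n <- length(in_a)
  deg <- Matrix::rowSums(W)
  Wo <- W - Matrix::Diagonal(n, Matrix::diag(W))
  odeg <- Matrix::rowSums(Wo)          # total off-diagonal links per node
  la <- as.numeric(Wo %*% in_a)        # off-diagonal links into side A
  vol_a <- sum(deg[in_a]); vol_b <- sum(deg[!in_a])
  cut <- sum(la[!in_a])
  ncut_val <- function(cut, va, vb)
    if (va <= 0 || vb <= 0) Inf else cut * (1 / va + 1 / vb)
  cur <- ncut_val(cut, vol_a, vol_b)
  for (p in seq_len(max_passes)) {
    improved <- FALSE
    for (i in seq_len(n)) {
      l_ia <- la[i]; l_ib <- odeg[i] - l_ia
      if (in_a[i]) {
        newcut <- cut - l_ib + l_ia
        cand <- ncut_val(newcut, vol_a - deg[i], vol_b + deg[i])
      } else {
        newcut <- cut - l_ia + l_ib
        cand <- ncut_val(newcut, vol_a + deg[i], vol_b - deg[i])
      }
      if (cand < cur - 1e-12) {
        col <- as.numeric(Wo[, i])
        if (in_a[i]) {
          in_a[i] <- FALSE; vol_a <- vol_a - deg[i]; vol_b <- vol_b + deg[i]
          la <- la - col
        } else {
          in_a[i] <- TRUE; vol_a <- vol_a + deg[i]; vol_b <- vol_b - deg[i]
          la <- la + col
        }
        cut <- newcut; cur <- cand; improved <- TRUE
      }
    }
    if (!improved) break
  }
  in_a
}

# Normalized cut of a bipartition given sparse W (diagonal included in
# volumes, excluded from the cut automatically since both sides differ).
#' @noRd
.ncut <- function(W, in_a) {
  vol_a <- sum(Matrix::rowSums(W)[in_a])
  vol_b <- sum(Matrix::rowSums(W)[!in_a])
  if (vol_a == 0 || vol_b == 0) return(Inf)
  cut <- sum(W[in_a, !in_a, drop = FALSE])
  cut * (1 / vol_a + 1 / vol_b)
}

#' Spectral clustering of an affinity graph
#'
#' Embeds nodes with the eigenvectors of the `k` smallest eigenvalues of
#' the combinatorial Laplacian `L = D - W`, row-normalizes the embedding,
#' and partitions it with seeded k-means. For `k = 2` the partition is
#' additionally compared against the best normalized-cut sweep of the
#' Fiedler vector and the lower-cut split is kept (the classical sweep
#' refinement). Soft memberships are the softmax of negative squared
#' embedding distances to the k-means centroids (temperature 1).
#'
#' @param graph An [build_affinity()] result.
#' @param k Number of clusters (2 <= k <= n), default 6. A scalar
#'   descriptor needs enough levels to separate a lesion's appearance mode
#'   from the motion-boundary mode that surrounds it; fewer clusters tend
#'   to merge the two.
#' @param seed Integer seed making the k-means initialisation
#'   deterministic.
#' @return An object of class `cluster_assignment` with fields `labels`
#'   (0-based integers, -1 reserved for noise), `k`, `soft` (`n x k`
#'   row-stochastic matrix) and `nodes`.
#' @export
spectral_cluster <- function(graph, k = 6L, seed = 1L) {
  stopifnot(inherits(graph, "affinity_graph"), k >= 2)
  n <- nrow(graph$nodes)
  if (k > n) stop("k must not exceed the number of nodes")
  if (k == n) {
    soft <- diag(n)
    return(structure(list(labels = 0:(n - 1L), k = n, soft = soft,
                          nodes = graph$nodes),
                     class = "cluster_assignment"))
  }
  Wo <- graph$W - Matrix::Diagonal(n, Matrix::diag(graph$W))
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    Wo > 0, mode = "undirected"))
  if (comp$no > k)
    warning(sprintf("graph has %d components but k = %d; clustering proceeds",
                    comp$no, k))
  U <- .laplacian_eigenvectors(graph$laplacian, k)
  nrm <- sqrt(rowSums(U^2)); nrm[nrm == 0] <- 1
  U <- U / nrm
  km <- .with_seed(seed,
    stats::kmeans(U, centers = k, nstart = 10, iter.max = 100))
  labels <- km$cluster - 1L
  if (k == 2) {
    # sweep-cut refinement (Shi-Malik): consider threshold splits along
    # both the combinatorial Fiedler vector and the generalized
    # (normalized-Laplacian) Fiedler vector, keep the lowest normalized cut
    f1 <- .laplacian_eigenvectors(graph$laplacian, 2)[, 2]
    dhalf <- 1 / sqrt(Matrix::diag(graph$degree))
    Lsym <- Matrix::Diagonal(n, dhalf) %*% graph$laplacian %*%
      Matrix::Diagonal(n, dhalf)
    Lsym <- (Lsym + Matrix::t(Lsym)) / 2
    f2 <- dhalf * .laplacian_eigenvectors(Lsym, 2)[, 2]
    candidates <- list(labels == 0)
    for (f in list(f1, f2)) {
      ordv <- order(f)
      fam <- list(cut = Inf, in_a = NULL)
      for (m in seq_len(n - 1)) {
        in_a <- logical(n); in_a[ordv[seq_len(m)]] <- TRUE
        cutv <- .ncut(graph$W, in_a)
        if (cutv < fam$cut - 1e-12) fam <- list(cut = cutv, in_a = in_a)
      }
      candidates[[length(candidates) + 1L]] <- fam$in_a
    }
    best <- list(cut = .ncut(graph$W, labels == 0), lab = labels)
    for (cand in candidates) {
      in_a <- .ncut_refine(graph$W, cand)
      if (!any(in_a) || all(in_a)) next
      cutv <- .ncut(graph$W, in_a)
      if (cutv < best$cut - 1e-12)
        best <- list(cut = cutv, lab = ifelse(in_a, 0L, 1L))
    }
    labels <- best$lab
    # recompute centroids for the possibly updated partition
    km$centers <- rbind(colMeans(U[labels == 0, , drop = FALSE]),
                        colMeans(U[labels == 1, , drop = FALSE]))
  }
  d2 <- vapply(seq_len(k), function(j)
    rowSums((U - matrix(km$centers[j, ], n, k, byrow = TRUE))^2), numeric(n))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = n)
  soft <- exp(-d2)
  soft <- soft / rowSums(soft)
  structure(list(labels = as.integer(labels), k = as.integer(k), soft = soft,
                 nodes = graph$nodes),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d nodes, k = %d, %d noise\n",
              length(x$labels), x$k, sum(x$labels == -1L)))
  invisible(x)
}

# Plain DBSCAN over 2-D integer-ish coordinates with Euclidean eps.
# minPts counts the point itself. Returns 0-based labels, -1 = noise.
#' @noRd
.dbscan_points <- function(coords, eps, min_samples) {
  n <- nrow(coords)
  if (n == 0) return(integer(0))
  # neighbour lists via an offset stencil on a padded occupancy grid
  r0 <- min(coords[, 1]); c0 <- min(coords[, 2])
  gr <- coords[, 1] - r0 + 1L; gc <- coords[, 2] - c0 + 1L
  H <- max(gr); W <- max(gc)
  grid <- matrix(0L, H, W)
  grid[cbind(gr, gc)] <- seq_len(n)
  R <- floor(eps)
  offs <- expand.grid(dr = -R:R, dc = -R:R)
  offs <- offs[offs$dr^2 + offs$dc^2 <= eps^2, ]
  neigh <- vector("list", n)
  cnt <- integer(n)
  for (k in seq_len(nrow(offs))) {
    rr <- gr + offs$dr[k]; cc <- gc + offs$dc[k]
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    j <- integer(n); j[ok] <- grid[cbind(rr[ok], cc[ok])]
    hit <- which(j > 0)
    cnt[hit] <- cnt[hit] + 1L
    for (i in hit) neigh[[i]] <- c(neigh[[i]], j[i])
  }
  core <- cnt >= min_samples
  labels <- rep(-1L, n)
  cl <- -1L
  for (s in seq_len(n)) {
    if (!core[s] || labels[s] != -1L) next
    cl <- cl + 1L
    labels[s] <- cl
    queue <- neigh[[s]]
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      if (labels[p] == -1L) {
        labels[p] <- cl
        if (core[p]) queue <- c(queue, neigh[[p]])
      }
    }
  }
  labels
}

#' Refine a spectral clustering with density-based (DBSCAN) clustering
#'
#' Within each spectral cluster, runs DBSCAN over the node pixel
#' coordinates (Euclidean `eps`, `min_samples` counting the point itself).
#' Spatially disconnected fragments become separate clusters; fragments
#' below the density threshold and density-unreachable points are labelled
#' noise (-1). The cluster count may grow. Soft memberships refer to the
#' spectral clusters and are therefore dropped from the refined
#' assignment.
#'
#' @param assign A `cluster_assignment` (e.g. from [spectral_cluster()]).
#' @param nodes Optional `n x 2` coordinates; defaults to `assign$nodes`.
#' @param eps Neighbourhood radius in pixels, default 2.5.
#' @param min_samples Minimum neighbourhood size for a core point,
#'   default 5.
#' @return A refined `cluster_assignment` (labels relabelled 0..k'-1 in
#'   deterministic order, `soft = NULL`).
#' @export
dbscan_refine <- function(assign, nodes = NULL, eps = 2.5, min_samples = 5L) {
  stopifnot(inherits(assign, "cluster_assignment"), eps > 0, min_samples >= 1)
  if (is.null(nodes)) nodes <- assign$nodes
  if (is.null(nodes) || nrow(nodes) != length(assign$labels))
    stop("node coordinates missing or inconsistent with labels")
  out <- rep(-1L, length(assign$labels))
  next_label <- 0L
  for (cl in sort(unique(assign$labels[assign$labels >= 0]))) {
    sel <- which(assign$labels == cl)
    if (length(sel) == 0) next
    sub <- .dbscan_points(nodes[sel, , drop = FALSE], eps, min_samples)
    pos <- sub >= 0
    out[sel[pos]] <- sub[pos] + next_label
    if (any(pos)) next_label <- next_label + max(sub) + 1L
  }
  structure(list(labels = out,
                 k = length(unique(out[out >= 0])),
                 soft = NULL, nodes = nodes),
            class = "cluster_assignment")
}

#' Per-node membership entropy of a clustering
#'
#' `H(x) = -sum_k p_k(x) log p_k(x)` in nats, from the soft membership
#' matrix; hard labels are one-hot encoded first (entropy 0). The mean is
#' taken over non-noise nodes.
#'
#' @param assign A `cluster_assignment`.
#' @return `list(per_node =, mean =)`.
#' @export
cluster_entropy <- function(assign) {
  stopifnot(inherits(assign, "cluster_assignment"))
  n <- length(assign$labels)
  soft <- assign$soft
  if (is.null(soft)) {
    k <- max(assign$k, 1L)
    soft <- matrix(0, n, k)
    pos <- assign$labels >= 0
    soft[cbind(which(pos), assign$labels[pos] + 1L)] <- 1
    soft[!pos, ] <- 1 / k
  }
  if (any(abs(rowSums(soft) - 1) > 1e-6))
    stop("soft membership rows must sum to 1")
  p <- soft
  per <- -rowSums(ifelse(p > 0, p * log(p), 0))
  keep <- assign$labels != -1L
  list(per_node = per,
       mean = if (any(keep)) mean(per[keep]) else NA_real_)
}

#' Cluster compactness as explained descriptor variance
#'
#' `100 * (1 - pooled within-cluster variance / total variance)` of the
#' descriptor values at the nodes, clipped to `[0, 100]`. Variances are
#' population variances; noise nodes are excluded.
#'
#' @param assign A `cluster_assignment` carrying node coordinates.
#' @param desc The `descriptor_map` the clustering was computed on.
#' @return Compactness percentage in `[0, 100]`.
#' @export
cluster_compactness <- function(assign, desc) {
  stopifnot(inherits(assign, "cluster_assignment"),
            inherits(desc, "descriptor_map"))
  keep <- assign$labels >= 0
  if (!any(keep)) stop("no non-noise cluster present")
  vals <- desc$values[assign$nodes[keep, , drop = FALSE]]
  labs <- assign$labels[keep]
  tot <- mean((vals - mean(vals))^2)
  if (tot == 0) {
    warning("zero total descriptor variance; compactness is 100")
    return(100)
  }
  within <- 0
  for (cl in unique(labs)) {
    v <- vals[labs == cl]
    within <- within + sum((v - mean(v))^2)
  }
  within <- within / length(vals)
  .clamp(100 * (1 - within / tot), 0, 100)
}
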