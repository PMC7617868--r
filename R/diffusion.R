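#' Standardise a feature matrix
#'
#' Every column is centred and scaled to unit (population) standard
#' deviation, either over all rows jointly (`global`, appropriate when all
#' runs probe the same behaviour, e.g. a closed track at varying density) or
#' within each run separately (`per_run`, appropriate when runs differ
#' strongly, e.g. egress recordings from heterogeneous sources).
#'
#' @param fm a [build_feature_matrix()] result.
#' @param mode `"global"` or `"per_run"`.
#' @return an object of class `standardised_features` with unit-variance
#'   `values`, the row `meta`, the standardisation `mode` and the per-group
#'   centre/scale in `stats`.
#' @export
standardise <- function(fm, mode = c("global", "per_run")) {
  stopifnot(inherits(fm, "feature_matrix"))
  mode <- match.arg(mode)
  values <- fm$values
  groups <- if (mode == "global") {
    rep("all", nrow(values))
  } else {
    fm$meta$run_id
  }
  out <- values
  stats <- list()
  for (g in unique(groups)) {
    rows <- which(groups == g)
    if (length(rows) < 2L) {
      stop(sprintf("standardisation group '%s' has fewer than 2 rows", g),
           call. = FALSE)
    }
    block <- values[rows, , drop = FALSE]
    mu <- colMeans(block)
    sigma <- sqrt(colMeans(sweep(block, 2L, mu)^2))
    zero <- sigma < 1e-12
    if (any(zero)) {
      stop(sprintf(
        "constant column(s) cannot be standardised in group '%s': %s",
        g, paste(colnames(values)[zero], collapse = ", ")), call. = FALSE)
    }
    out[rows, ] <- sweep(sweep(block, 2L, mu), 2L, sigma, "/")
    stats[[g]] <- list(centre = mu, scale = sigma)
  }
  structure(list(values = out, meta = fm$meta, mode = mode, stats = stats,
                 exclusions = fm$exclusions),
            class = "standardised_features")
}

#' Pairwise Euclidean distance matrix in feature space
#'
#' @param sf a [standardise()] result (or a bare numeric matrix).
#' @return dense M x M symmetric matrix with zero diagonal; row metadata is
#'   attached as the `meta` attribute when available.
#' @export
distance_matrix <- function(sf) {
  values <- if (inherits(sf, "standardised_features")) sf$values else sf
  stopifnot(is.matrix(values), !anyNA(values))
  D <- as.matrix(stats::dist(values))
  dimnames(D) <- NULL
  if (inherits(sf, "standardised_features")) {
    attr(D, "meta") <- sf$meta
    attr(D, "mode") <- sf$mode
    attr(D, "exclusions") <- sf$exclusions
  }
  D
}

#' Sparsified inverse-distance affinity network
#'
#' Affinities are `1 / max(D_ij, eps)` off the diagonal (the `eps` clamp
#' handles duplicate feature rows, which thereby become near-certain mutual
#' neighbours). The matrix is then thresholded: an entry survives iff it
#' ranks among the top `p` scores of row i *or* of row j. The criterion is
#' symmetric and guarantees every node at least `min(p, M - 1)` links, so a
#' moderate `p` keeps the network connected while discarding the long
#' feature-space distances that carry no local-similarity information.
#'
#' @param D distance matrix from [distance_matrix()].
#' @param p neighbour-count parameter (default 20); must satisfy `M > p`.
#' @param eps distance clamp for coincident rows (default 1e-12).
#' @return an object of class `similarity_network`: sparse symmetric `C`
#'   (`Matrix::dsCMatrix`), `p`, `eps`, node `degrees`, kept edge count and
#'   row metadata.
#' @export
similarity <- function(D, p = 20, eps = 1e-12) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  M <- nrow(D)
  p <- as.integer(p)
  if (p < 1L) stop("p must be a positive integer", call. = FALSE)
  if (M <= p) {
    stop(sprintf("M = %d rows but p = %d: thresholding is degenerate (need M > p)",
                 M, p), call. = FALSE)
  }
  C <- 1 / pmax(D, eps)
  diag(C) <- 0
  # p-th largest off-diagonal score per row (diagonal zeros cannot reach it
  # because every off-diagonal affinity is positive and there are >= p of them)
  thr <- apply(C, 1L, function(r) sort(r, decreasing = TRUE)[p])
  keep <- (C >= thr) | (C >= rep(thr, each = M))  # row i's or row j's top p
  C[!keep] <- 0
  Cs <- Matrix::forceSymmetric(Matrix::drop0(Matrix::Matrix(C, sparse = TRUE)))
  degrees <- Matrix::colSums(Cs != 0)
  structure(list(C = Cs, p = p, eps = eps,
                 degrees = as.numeric(degrees),
                 n_edges = sum(Cs != 0) / 2,
                 meta = attr(D, "meta"),
                 mode = attr(D, "mode"),
                 exclusions = attr(D, "exclusions")),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf(
    "<similarity_network> %d nodes, %d edges, p = %d, degree range [%d, %d]\n",
    nrow(x$C), x$n_edges, x$p, min(x$degrees), max(x$degrees)))
  invisible(x)
}

#' Random-walk normalised graph Laplacian
#'
#' `L = I - D^-1 C` with `D` the diagonal of weighted node degrees
#' `d_j = sum_n C_nj` (row and column sums coincide because `C` is
#' symmetric). Rows of `L` sum to zero, so the constant vector spans the
#' null space on a connected network.
#'
#' @param net a [similarity()] network (or a symmetric non-negative sparse
#'   matrix).
#' @return sparse M x M Laplacian.
#' @export
laplacian <- function(net) {
  C <- if (inherits(net, "similarity_network")) net$C else net
  d <- Matrix::colSums(C)
  if (any(d == 0)) {
    stop("isolated node(s) with zero degree: Laplacian undefined",
         call. = FALSE)
  }
  M <- nrow(C)
  Matrix::Diagonal(M) - Matrix::Diagonal(M, 1 / d) %*% C
}

#' Diffusion-map embedding from a similarity network
#'
#' Computes the spectrum of the random-walk normalised Laplacian through its
#' symmetric conjugate `L_sym = I - D^-1/2 C D^-1/2` (same eigenvalues;
#' numerically stable symmetric eigensolve), recovers the random-walk
#' eigenvectors as `psi = D^-1/2 u`, unit-normalises them and fixes signs so
#' each eigenvector's largest-magnitude entry is positive. Eigenvalues lie
#' in `[0, 2]`; the zero eigenvalue's multiplicity equals the number of
#' connected components, so a connected network has exactly one, whose
#' constant eigenvector carries no information and is dropped. The returned
#' coordinates are the eigenvectors of the `K` smallest positive
#' eigenvalues, which span the main directions of variation in the data.
#'
#' @param net a [similarity()] network.
#' @param K number of embedding coordinates (default 3).
#' @param zero_tol relative tolerance (w.r.t. the largest eigenvalue) below
#'   which an eigenvalue counts as zero (default 1e-8).
#' @return an object of class `diffusion_embedding`: ascending
#'   `eigenvalues`, `zero_multiplicity`, M x K `vectors` (columns
#'   `ev1..evK`), row `meta` and the network parameters.
#' @export
embed <- function(net, K = 3, zero_tol = 1e-8) {
  stopifnot(inherits(net, "similarity_network"))
  C <- net$C
  M <- nrow(C)
  g <- igraph::graph_from_adjacency_matrix(C != 0, mode = "undirected")
  ncomp <- igraph::components(g)$no
  if (ncomp > 1L) {
    stop(structure(class = c("pedmap_disconnected_error", "error", "condition"),
                   list(message = sprintf(
                     paste0("similarity network has %d connected components ",
                            "(zero eigenvalue multiplicity %d); a larger p ",
                            "(less aggressive thresholding) should be selected"),
                     ncomp, ncomp),
                     call = sys.call(-1L),
                     zero_multiplicity = ncomp)))
  }
  if (K < 1L || K > M - 1L) {
    stop(sprintf("K = %d embedding coordinates requested but only %d available",
                 K, M - 1L), call. = FALSE)
  }
  d <- Matrix::colSums(C)
  dis <- 1 / sqrt(d)
  S <- Matrix::Diagonal(M, dis) %*% C %*% Matrix::Diagonal(M, dis)
  Lsym <- diag(M) - as.matrix(Matrix::forceSymmetric(S))
  eig <- eigen(Lsym, symmetric = TRUE)
  lambda <- rev(eig$values)              # ascending
  lambda[lambda < 0 & lambda > -1e-10] <- 0
  U <- eig$vectors[, rev(seq_len(M)), drop = FALSE]
  nzero <- sum(lambda <= zero_tol * max(lambda, .Machine$double.eps))
  # the graph component count is exact; eigenvalue counting is its
  # floating-point shadow (they agree on any sane input)
  zero_multiplicity <- ncomp
  sel <- (zero_multiplicity + 1L):(zero_multiplicity + K)
  psi <- U[, sel, drop = FALSE] * dis
  for (j in seq_len(K)) {
    psi[, j] <- psi[, j] / sqrt(sum(psi[, j]^2))
    if (psi[which.max(abs(psi[, j])), j] < 0) psi[, j] <- -psi[, j]
  }
  colnames(psi) <- paste0("ev", seq_len(K))
  structure(list(eigenvalues = lambda,
                 zero_multiplicity = zero_multiplicity,
                 n_zero_numeric = nzero,
                 vectors = psi, K = K, zero_tol = zero_tol,
                 p = net$p, eps = net$eps, mode = net$mode,
                 meta = net$meta, exclusions = net$exclusions),
            class = "diffusion_embedding")
}

#' @export
print.diffusion_embedding <- function(x, ...) {
  cat(sprintf(
    "<diffusion_embedding> %d agents, K = %d, zero multiplicity %d\n",
    nrow(x$vectors), x$K, x$zero_multiplicity))
  cat("smallest positive eigenvalues:",
      paste(signif(x$eigenvalues[(x$zero_multiplicity + 1):
                                   (x$zero_multiplicity + x$K)], 4),
            collapse = ", "), "\n")
  invisible(x)
}

#' Run the full diffusion-map pipeline
#'
#' Convenience wrapper: trajectory table (or prebuilt feature matrix) ->
#' feature extraction -> standardisation -> distance matrix -> thresholded
#' affinity network -> spectral embedding.
#'
#' @param x a [trajectory_table()] or [build_feature_matrix()] result.
#' @param p neighbour parameter of the affinity thresholding (default 20).
#' @param K number of embedding coordinates (default 3).
#' @param mode standardisation mode, see [standardise()].
#' @param zero_tol see [embed()].
#' @return a [embed()] `diffusion_embedding`.
#' @export
diffusion_map <- function(x, p = 20, K = 3, mode = c("global", "per_run"),
                          zero_tol = 1e-8) {
  mode <- match.arg(mode)
  fm <- if (inherits(x, "feature_matrix")) x else build_feature_matrix(x)
  embed(similarity(distance_matrix(standardise(fm, mode = mode)), p = p),
        K = K, zero_tol = zero_tol)
}

#' Write an embedding as CSV with a JSON sidecar
#'
#' The CSV holds `run_id`, `agent_id`, `source` and the embedding
#' coordinates `ev1..evK`; the sidecar records eigenvalues, zero
#' multiplicity, the network and standardisation parameters and the
#' feature-stage exclusion log.
#'
#' @param embedding a [embed()] result.
#' @param path CSV output path; the sidecar goes to the same path with a
#'   `.json` extension unless `json_path` is given.
#' @param json_path optional sidecar path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path, json_path = NULL) {
  stopifnot(inherits(embedding, "diffusion_embedding"))
  json_path <- json_path %||% sub("\\.[^.]*$", ".json", path)
  df <- cbind(embedding$meta, as.data.frame(embedding$vectors))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(
    eigenvalues = embedding$eigenvalues,
    zero_multiplicity = embedding$zero_multiplicity,
    p = embedding$p,
    K = embedding$K,
    standardisation_mode = embedding$mode,
    eps = embedding$eps,
    zero_tol = embedding$zero_tol,
    exclusions = embedding$exclusions),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
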