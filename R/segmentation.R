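#' GrabCut-style foreground extraction
#'
#' Binary segmentation inside a detector bounding box: pixels outside the
#' box are hard background, pixels inside start as unknown foreground.
#' Foreground and background colors are each modeled by a K-component
#' full-covariance Gaussian mixture; segmentation alternates (i) an EM
#' refit of both mixtures on the pixels currently carrying their label
#' and (ii) a global min-cut of the mixture-likelihood energy with an
#' 8-neighbor contrast-sensitive smoothness term. Both steps can only
#' lower the energy, so the energy trace is non-increasing.
#'
#' @name segmentation
NULL

# run code with an isolated RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Trimap from a bounding box
#'
#' @param dim Image dimensions `c(height, width)`.
#' @param box Normalized bounding box (see [bounding_box()]).
#' @return Integer matrix: 0 = sure background (outside the box),
#'   1 = unknown (inside).
#' @export
make_trimap <- function(dim, box) {
  h <- dim[1]; w <- dim[2]
  ys <- (seq_len(h) - 0.5) / h
  xs <- (seq_len(w) - 0.5) / w
  trimap <- matrix(0L, h, w)
  trimap[ys >= box[["ymin"]] & ys < box[["ymax"]],
         xs >= box[["xmin"]] & xs < box[["xmax"]]] <- 1L
  if (!any(trimap == 1L)) {
    stop("bounding box covers no pixel at this resolution", call. = FALSE)
  }
  trimap
}

img_to_pixels <- function(image) {
  cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
        as.vector(image[, , 3]))
}

# 8-connectivity neighbor pairs (each unordered pair once) for an h x w
# grid in column-major order; returns p, q indices and 1/distance.
neighbor_pairs <- function(h, w) {
  idx <- matrix(seq_len(h * w), h, w)
  p <- c(as.vector(idx[-h, ]), as.vector(idx[, -w]),
         as.vector(idx[-h, -w]), as.vector(idx[-1, -w]))
  q <- c(as.vector(idx[-1, ]), as.vector(idx[, -1]),
         as.vector(idx[-1, -1]), as.vector(idx[-h, -1]))
  invdist <- c(rep(1, (h - 1) * w), rep(1, h * (w - 1)),
               rep(1 / sqrt(2), 2 * (h - 1) * (w - 1)))
  list(p = p, q = q, invdist = invdist)
}

#' Contrast scale beta for the smoothness term
#'
#' `beta = 1 / (2 * mean squared 8-neighbor color difference)`, computed
#' once per image; 0 for a perfectly uniform image.
#'
#' @param image H x W x 3 array in [0, 1].
#' @return Non-negative scalar.
#' @export
compute_beta <- function(image) {
  h <- dim(image)[1]; w <- dim(image)[2]
  X <- img_to_pixels(image)
  nb <- neighbor_pairs(h, w)
  d2 <- rowSums((X[nb$p, , drop = FALSE] - X[nb$q, , drop = FALSE])^2)
  m <- mean(d2)
  if (m <= .Machine$double.eps) 0 else 1 / (2 * m)
}

## ---- Gaussian mixture machinery -------------------------------------

GMM_COV_REG <- 1e-5

gmm_comp_logdens <- function(X, mean, cov) {
  R <- chol(cov)
  logdet <- 2 * sum(log(diag(R)))
  Z <- backsolve(R, t(X) - mean, transpose = TRUE)
  -0.5 * (colSums(Z^2) + logdet + ncol(X) * log(2 * pi))
}

# n x K matrix of log(weight_k * N_k(x))
gmm_weighted_logdens <- function(model, X) {
  K <- length(model$weights)
  out <- matrix(-Inf, nrow(X), K)
  for (k in seq_len(K)) {
    if (model$weights[k] <= 0) next
    out[, k] <- log(model$weights[k]) +
      gmm_comp_logdens(X, model$means[k, ], model$covs[[k]])
  }
  out
}

logsumexp_rows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

# log mixture density per pixel
gmm_loglik <- function(model, X) {
  logsumexp_rows(gmm_weighted_logdens(model, X))
}

# k-means-seeded mixture fit; K shrinks to the number of distinct colors
gmm_fit <- function(X, K = 5) {
  ux <- unique(X)
  K <- min(K, nrow(ux))
  if (K == 1) {
    assign <- rep(1L, nrow(X))
  } else {
    centers <- ux[sample.int(nrow(ux), K), , drop = FALSE]
    km <- suppressWarnings(stats::kmeans(X, centers = centers,
                                         iter.max = 20, algorithm = "Lloyd"))
    assign <- km$cluster
  }
  weights <- numeric(K)
  means <- matrix(0, K, ncol(X))
  covs <- vector("list", K)
  for (k in seq_len(K)) {
    sel <- assign == k
    weights[k] <- mean(sel)
    Xi <- X[sel, , drop = FALSE]
    if (nrow(Xi) == 0) {
      means[k, ] <- colMeans(X)
      covs[[k]] <- diag(GMM_COV_REG, ncol(X))
      next
    }
    means[k, ] <- colMeans(Xi)
    covs[[k]] <- if (nrow(Xi) < 2) {
      diag(GMM_COV_REG, ncol(X))
    } else {
      stats::cov(Xi) * (nrow(Xi) - 1) / nrow(Xi) + diag(GMM_COV_REG, ncol(X))
    }
  }
  list(weights = weights, means = means, covs = covs)
}

# EM refit; returns the refit only if it does not lower the data
# likelihood (guards energy monotonicity in degenerate cases)
gmm_em <- function(model, X, steps = 2) {
  best <- model
  best_ll <- sum(gmm_loglik(model, X))
  cur <- model
  for (s in seq_len(steps)) {
    W <- gmm_weighted_logdens(cur, X)
    lse <- logsumexp_rows(W)
    R <- exp(W - lse)
    Nk <- colSums(R)
    K <- length(cur$weights)
    for (k in seq_len(K)) {
      if (Nk[k] < 1e-8) next
      mu <- colSums(R[, k] * X) / Nk[k]
      D <- t(X) - mu
      cv <- (D %*% (R[, k] * t(D))) / Nk[k] + diag(GMM_COV_REG, ncol(X))
      cur$means[k, ] <- mu
      cur$covs[[k]] <- cv
    }
    cur$weights <- Nk / sum(Nk)
    ll <- sum(gmm_loglik(cur, X))
    if (ll >= best_ll) {
      best <- cur
      best_ll <- ll
    }
  }
  best
}

## ---- Energy and min-cut ---------------------------------------------

#' GrabCut energy of a labeling
#'
#' Data term: sum over pixels of the negative log mixture likelihood of
#' the pixel color under its label's model. Smoothness term:
#' `gamma * sum over 8-neighbor pairs with differing labels of
#' (1/dist) * exp(-beta * ||color difference||^2)`.
#'
#' @param labels Logical H x W matrix, TRUE = foreground.
#' @param models List with `fg` and `bg` mixture models (as produced
#'   internally; see [segment_box()]).
#' @param image H x W x 3 array in [0, 1].
#' @param gamma Smoothness strength.
#' @param beta Contrast scale (see [compute_beta()]).
#' @return Scalar energy.
#' @export
seg_energy <- function(labels, models, image, gamma, beta) {
  h <- dim(image)[1]; w <- dim(image)[2]
  X <- img_to_pixels(image)
  fg <- as.vector(labels)
  data_term <- 0
  if (any(fg)) {
    data_term <- data_term - sum(gmm_loglik(models$fg, X[fg, , drop = FALSE]))
  }
  if (any(!fg)) {
    data_term <- data_term - sum(gmm_loglik(models$bg, X[!fg, , drop = FALSE]))
  }
  nb <- neighbor_pairs(h, w)
  differ <- fg[nb$p] != fg[nb$q]
  smooth <- 0
  if (any(differ)) {
    d2 <- rowSums((X[nb$p[differ], , drop = FALSE] -
                   X[nb$q[differ], , drop = FALSE])^2)
    smooth <- gamma * sum(nb$invdist[differ] * exp(-beta * d2))
  }
  data_term + smooth
}

#' Globally optimal labeling for fixed color models
#'
#' Solves the binary labeling that minimizes [seg_energy()] over the
#' unknown region of the trimap (sure-background pixels stay background)
#' by an s-t min-cut.
#'
#' @param image H x W x 3 array.
#' @param trimap Integer matrix from [make_trimap()].
#' @param models List with `fg` and `bg` mixture models.
#' @param gamma Smoothness strength.
#' @param beta Contrast scale.
#' @return Logical H x W matrix, TRUE = foreground.
#' @export
min_cut_labels <- function(image, trimap, models, gamma, beta) {
  h <- dim(image)[1]; w <- dim(image)[2]
  X <- img_to_pixels(image)
  unknown <- which(as.vector(trimap) == 1L)
  n <- length(unknown)
  node_of <- integer(h * w)
  node_of[unknown] <- seq_len(n)
  src <- n + 1L
  snk <- n + 2L

  d_fg <- -gmm_loglik(models$fg, X[unknown, , drop = FALSE])
  d_bg <- -gmm_loglik(models$bg, X[unknown, , drop = FALSE])

  nb <- neighbor_pairs(h, w)
  pu <- node_of[nb$p]
  qu <- node_of[nb$q]
  wgt <- gamma * nb$invdist *
    exp(-beta * rowSums((X[nb$p, , drop = FALSE] - X[nb$q, , drop = FALSE])^2))

  both <- pu > 0 & qu > 0
  # pair with exactly one endpoint unknown: fixed-background neighbor
  # penalizes labeling the unknown endpoint foreground
  p_only <- pu > 0 & qu == 0
  q_only <- qu > 0 & pu == 0
  bnode <- c(pu[p_only], qu[q_only])
  bw <- c(wgt[p_only], wgt[q_only])
  if (length(bnode) > 0) {
    add <- tapply(bw, bnode, sum)
    d_fg[as.integer(names(add))] <- d_fg[as.integer(names(add))] + add
  }
  # shift per-pixel terminal capacities so both are >= 0
  m <- pmin(d_fg, d_bg)
  cap_src <- d_bg - m   # paid when the pixel ends on the sink (bg) side
  cap_snk <- d_fg - m   # paid when the pixel ends on the source (fg) side

  edges <- rbind(
    cbind(rep(src, n), seq_len(n)),
    cbind(seq_len(n), rep(snk, n)),
    cbind(pu[both], qu[both]),
    cbind(qu[both], pu[both])
  )
  caps <- c(cap_src, cap_snk, wgt[both], wgt[both])
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  if (igraph::vcount(g) < snk) {
    g <- igraph::add_vertices(g, snk - igraph::vcount(g))
  }
  flow <- igraph::max_flow(g, source = src, target = snk, capacity = caps)
  fg_nodes <- setdiff(as.integer(flow$partition1), src)
  labels <- matrix(FALSE, h, w)
  labels[unknown[fg_nodes]] <- TRUE
  labels
}

#' Segment the foreground inside a bounding box
#'
#' Classic fully automatic GrabCut loop: initialize foreground = box
#' interior, fit K-component Gaussian mixtures to the two regions, then
#' iterate EM refits and min-cuts. If the cut empties the foreground,
#' the full box is returned as foreground and flagged.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param box Normalized bounding box.
#' @param iterations Number of refit/cut rounds.
#' @param K Mixture components per color model.
#' @param gamma Smoothness strength.
#' @param seed Seed for the k-means component initialization.
#' @return List of class `seg_mask`: `mask` (logical matrix),
#'   `area_fraction`, `fallback` (logical), `energy_trace` (energy after
#'   the initial fit and after each iteration), `beta`, `models`.
#' @export
segment_box <- function(image, box, iterations = 5, K = 5, gamma = 50,
                        seed = 42L) {
  trimap <- make_trimap(dim(image)[1:2], box)
  if (!any(trimap == 0L)) {
    stop("bounding box must leave some sure-background margin",
         call. = FALSE)
  }
  X <- img_to_pixels(image)
  beta <- compute_beta(image)
  labels <- trimap == 1L
  models <- with_local_seed(seed, list(
    fg = gmm_fit(X[as.vector(labels), , drop = FALSE], K),
    bg = gmm_fit(X[!as.vector(labels), , drop = FALSE], K)
  ))
  trace <- seg_energy(labels, models, image, gamma, beta)
  fallback <- FALSE
  for (it in seq_len(iterations)) {
    fg_px <- X[as.vector(labels), , drop = FALSE]
    bg_px <- X[!as.vector(labels), , drop = FALSE]
    if (nrow(fg_px) > 0) models$fg <- gmm_em(models$fg, fg_px)
    if (nrow(bg_px) > 0) models$bg <- gmm_em(models$bg, bg_px)
    labels <- min_cut_labels(image, trimap, models, gamma, beta)
    trace <- c(trace, seg_energy(labels, models, image, gamma, beta))
    if (!any(labels)) break
  }
  if (!any(labels)) {
    labels <- trimap == 1L
    fallback <- TRUE
  }
  structure(list(mask = labels, area_fraction = mean(labels),
                 fallback = fallback, energy_trace = trace, beta = beta,
                 models = models),
            class = "seg_mask")
}

#' Foreground area fraction of a mask
#' @param mask A `seg_mask` or logical matrix.
#' @return Foreground pixels / total pixels.
#' @export
mask_area <- function(mask) {
  if (inherits(mask, "seg_mask")) mask <- mask$mask
  mean(mask)
}

#' Write a segmentation mask as a single-channel PNG
#' @param mask A `seg_mask` or logical matrix.
#' @param path Output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  if (inherits(mask, "seg_mask")) mask <- mask$mask
  png::writePNG(mask * 1.0, path)
  invisible(path)
}
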