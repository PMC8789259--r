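## Computational grid construction from tissue label maps, the
## Laplace-Dirichlet solver, and rule-based fiber assignment.

#' Build a structured computational grid from a tissue label map
#'
#' Each voxel of the (2D, single-slice) label map is subdivided into
#' square elements so the element edge length approximates the target
#' resolution; element labels are inherited from the parent voxel, and
#' dense-fibrosis elements are flagged non-conducting.
#'
#' @param labelmap A `tissue_labels` object (single slice) or integer
#'   matrix.
#' @param target_resolution_um Target element edge length (micrometers).
#' @param slice Slice index if the label map has several.
#' @return List of class `ventricular_grid`: element label matrix,
#'   conducting flags, element size `dx_mm`, and node-grid dimensions
#'   `nnx`, `nny` (nodes are element corners, index
#'   `i + nnx * (j - 1)`).
#' @export
build_grid <- function(labelmap, target_resolution_um = 355, slice = 1L) {
  if (target_resolution_um <= 0) stop("target resolution must be positive")
  if (inherits(labelmap, "tissue_labels")) {
    spacing <- labelmap$spacing[[1]]
    lab <- labelmap$labels
    lab <- if (length(dim(lab)) == 3) lab[, , slice] else lab
  } else {
    spacing <- attr(labelmap, "spacing_mm")
    if (is.null(spacing)) spacing <- 2
    lab <- labelmap
  }
  if (!any(lab %in% c(1L, 2L, 3L))) stop("label map has no myocardium")
  k <- max(1L, as.integer(round(spacing * 1000 / target_resolution_um)))
  elab <- lab[rep(seq_len(nrow(lab)), each = k),
              rep(seq_len(ncol(lab)), each = k), drop = FALSE]
  grid <- list(elem_label = elab,
               conducting = elab == 1L | elab == 2L,
               dx_mm = spacing / k,
               nx = nrow(elab), ny = ncol(elab),
               nnx = nrow(elab) + 1L, nny = ncol(elab) + 1L)
  class(grid) <- "ventricular_grid"
  grid
}

# nodes touching at least one conducting element
grid_active_nodes <- function(grid) {
  act <- matrix(FALSE, grid$nnx, grid$nny)
  cond <- grid$conducting
  idx <- which(cond, arr.ind = TRUE)
  for (d in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
    act[cbind(idx[, 1] + d[1], idx[, 2] + d[2])] <- TRUE
  act
}

#' Solve the Laplace equation with Dirichlet boundary sets
#'
#' Discrete harmonic field on the conducting region of the grid
#' (5-point stencil, unit edge weights, natural no-flux elsewhere),
#' with fixed values on two or more disjoint node sets.  Used to define
#' transmural and apicobasal coordinates for rule-based fiber
#' orientation.
#'
#' @param grid A `ventricular_grid`.
#' @param boundary_sets List of integer node-index vectors.
#' @param boundary_values Numeric vector, one value per set.
#' @return Numeric vector over all grid nodes (`NA` at inactive nodes).
#' @export
solve_laplace <- function(grid, boundary_sets, boundary_values) {
  stopifnot(length(boundary_sets) == length(boundary_values),
            length(boundary_sets) >= 2)
  if (any(lengths(boundary_sets) == 0)) stop("empty Dirichlet set")
  if (length(unique(unlist(boundary_sets))) != length(unlist(boundary_sets)))
    stop("Dirichlet sets must be disjoint")
  nnx <- grid$nnx; nny <- grid$nny
  nn <- nnx * nny
  act <- as.vector(grid_active_nodes(grid))
  bnodes <- unlist(boundary_sets)
  if (any(!act[bnodes])) stop("Dirichlet node outside the conducting region")

  # node-node links flanked by a conducting element
  cond <- grid$conducting
  links <- list()
  # horizontal links: (i,j)-(i+1,j), flanking elements (i, j-1), (i, j)
  eidx <- function(a, b) {
    ok <- a >= 1 & a <= grid$nx & b >= 1 & b <= grid$ny
    out <- logical(length(a)); out[ok] <- cond[cbind(a[ok], b[ok])]
    out
  }
  hi <- expand.grid(i = seq_len(nnx - 1), j = seq_len(nny))
  hok <- eidx(hi$i, hi$j - 1) | eidx(hi$i, hi$j)
  links[[1]] <- cbind(hi$i[hok] + nnx * (hi$j[hok] - 1),
                      hi$i[hok] + 1 + nnx * (hi$j[hok] - 1))
  vi <- expand.grid(i = seq_len(nnx), j = seq_len(nny - 1))
  vok <- eidx(vi$i - 1, vi$j) | eidx(vi$i, vi$j)
  links[[2]] <- cbind(vi$i[vok] + nnx * (vi$j[vok] - 1),
                      vi$i[vok] + nnx * vi$j[vok])
  ed <- rbind(links[[1]], links[[2]])

  # connectivity: every active node must reach a Dirichlet node
  comp <- rep(FALSE, nn)
  comp[bnodes] <- TRUE
  adj <- rbind(ed, ed[, 2:1])
  ord <- order(adj[, 1])
  adj <- adj[ord, , drop = FALSE]
  ptr <- c(0, cumsum(tabulate(adj[, 1], nn)))
  frontier <- bnodes
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      if (ptr[v + 1] > ptr[v]) {
        nb <- adj[(ptr[v] + 1):ptr[v + 1], 2]
        nb <- nb[!comp[nb]]
        comp[nb] <- TRUE
        nxt <- c(nxt, nb)
      }
    }
    frontier <- nxt
  }
  if (any(act & !comp))
    stop("conducting region has a component touching no Dirichlet boundary")

  w <- rep(1, nrow(ed))
  L <- Matrix::sparseMatrix(i = c(ed[, 1], ed[, 2]), j = c(ed[, 2], ed[, 1]),
                            x = -c(w, w), dims = c(nn, nn))
  dg <- -Matrix::rowSums(L)
  L <- L + Matrix::Diagonal(nn, dg)
  b <- rep(0, nn)
  fixed <- rep(FALSE, nn)
  val <- rep(0, nn)
  for (s in seq_along(boundary_sets)) {
    fixed[boundary_sets[[s]]] <- TRUE
    val[boundary_sets[[s]]] <- boundary_values[s]
  }
  free <- which(act & !fixed)
  sol <- rep(NA_real_, nn)
  sol[fixed] <- val[fixed]
  if (length(free)) {
    rhs <- -as.numeric(L[free, which(fixed), drop = FALSE] %*% val[fixed])
    x <- Matrix::solve(L[free, free, drop = FALSE], rhs)
    sol[free] <- as.numeric(x)
  }
  sol
}

#' Assign per-element fiber orientations by the rule-based method
#'
#' For each conducting element the transmural unit gradient defines the
#' wall-normal direction; the fiber lies in the plane orthogonal to it,
#' rotated out of the circumferential direction toward the apicobasal
#' axis by a helix angle interpolated linearly in transmural depth from
#' `angle_endo_deg` (endocardium, depth 0) to `angle_epi_deg`
#' (epicardium, depth 1).  Elements with a vanishing gradient take the
#' average orientation of their neighbors.
#'
#' @param grid A `ventricular_grid`.
#' @param transmural Nodal transmural field from [solve_laplace()]
#'   (0 endo, 1 epi).
#' @param apicobasal Optional nodal apicobasal field; for a single
#'   short-axis slice the apicobasal direction is the slice normal.
#' @param angle_endo_deg,angle_epi_deg Helix angles at the surfaces.
#' @return List of class `fiber_field`: `fibers` (n_elements x 3 unit
#'   vectors, row per element in column-major element order),
#'   `angle_deg`, `theta_inplane` (radians, in-plane projection
#'   direction), `depth`, and `normal`.
#' @export
assign_fibers <- function(grid, transmural, apicobasal = NULL,
                          angle_endo_deg = 60, angle_epi_deg = -60) {
  nnx <- grid$nnx
  tm <- matrix(transmural, nnx, grid$nny)
  ne <- grid$nx * grid$ny
  fib <- matrix(NA_real_, ne, 3)
  ang <- rep(NA_real_, ne)
  theta <- rep(NA_real_, ne)
  depth <- rep(NA_real_, ne)
  nrm <- matrix(NA_real_, ne, 3)
  cond <- grid$conducting
  degenerate <- integer(0)
  for (j in seq_len(grid$ny)) for (i in seq_len(grid$nx)) {
    if (!cond[i, j]) next
    e <- i + grid$nx * (j - 1)
    c00 <- tm[i, j]; c10 <- tm[i + 1, j]
    c01 <- tm[i, j + 1]; c11 <- tm[i + 1, j + 1]
    d <- mean(c(c00, c10, c01, c11))
    gx <- ((c10 + c11) - (c00 + c01)) / (2 * grid$dx_mm)
    gy <- ((c01 + c11) - (c00 + c10)) / (2 * grid$dx_mm)
    gn <- sqrt(gx^2 + gy^2)
    depth[e] <- d
    if (gn < 1e-12) { degenerate <- c(degenerate, e); next }
    nx_ <- gx / gn; ny_ <- gy / gn
    ec <- c(-ny_, nx_, 0)              # circumferential, in plane
    el <- c(0, 0, 1)                   # apicobasal (slice normal)
    a <- (1 - d) * angle_endo_deg + d * angle_epi_deg
    ar <- a * pi / 180
    f <- cos(ar) * ec + sin(ar) * el
    fib[e, ] <- f / sqrt(sum(f^2))
    ang[e] <- a
    theta[e] <- atan2(ec[2], ec[1])
    nrm[e, ] <- c(nx_, ny_, 0)
  }
  if (length(degenerate)) {
    # neighbor-average fallback for flat-field elements
    for (e in degenerate) {
      i <- ((e - 1) %% grid$nx) + 1
      j <- ((e - 1) %/% grid$nx) + 1
      nbs <- c(e - 1, e + 1, e - grid$nx, e + grid$nx)
      nbs <- nbs[nbs >= 1 & nbs <= ne & !is.na(ang[pmax(pmin(nbs, ne), 1)])]
      if (length(nbs)) {
        f <- colMeans(fib[nbs, , drop = FALSE])
        fib[e, ] <- f / sqrt(sum(f^2))
        ang[e] <- mean(ang[nbs]); theta[e] <- mean(theta[nbs])
      } else {
        fib[e, ] <- c(1, 0, 0); ang[e] <- 0; theta[e] <- 0
      }
    }
    message(length(degenerate),
            " element(s) had a vanishing transmural gradient; ",
            "neighbor-average fiber used")
  }
  structure(list(fibers = fib, angle_deg = ang, theta_inplane = theta,
                 depth = depth, normal = nrm),
            class = "fiber_field")
}

#' Endocardial and epicardial node sets of an annular grid
#'
#' Boundary nodes of the conducting region, split into the inner
#' (endocardial) and outer (epicardial) surface by distance from the
#' conducting-region centroid.  For a sheet without a cavity all
#' boundary nodes are returned as `epi` and `endo` is empty.
#'
#' @param grid A `ventricular_grid`.
#' @return List with integer node-index vectors `endo` and `epi`.
#' @export
boundary_node_sets <- function(grid) {
  act <- grid_active_nodes(grid)
  nnx <- grid$nnx; nny <- grid$nny
  cond <- grid$conducting
  elem_at <- function(a, b) {
    ok <- a >= 1 & a <= grid$nx & b >= 1 & b <= grid$ny
    out <- logical(length(a)); out[ok] <- cond[cbind(a[ok], b[ok])]
    out
  }
  idx <- which(act, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  n_adj <- elem_at(i - 1, j - 1) + elem_at(i, j - 1) +
    elem_at(i - 1, j) + elem_at(i, j)
  boundary <- idx[n_adj < 4, , drop = FALSE]
  if (nrow(boundary) == 0) stop("no boundary nodes found")
  ci <- mean(idx[, 1]); cj <- mean(idx[, 2])
  r <- sqrt((boundary[, 1] - ci)^2 + (boundary[, 2] - cj)^2)
  node_id <- boundary[, 1] + nnx * (boundary[, 2] - 1)
  # bimodal radius (annulus) vs unimodal (sheet edge)
  rmid <- (max(r) + min(r)) / 2
  inner <- r < rmid
  if (min(r) > 0.6 * max(r) || sum(inner) < 4) {
    list(endo = integer(0), epi = node_id)
  } else {
    list(endo = node_id[inner], epi = node_id[!inner])
  }
}
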