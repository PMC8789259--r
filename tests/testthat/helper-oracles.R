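# Independent oracles used across the test files.

# 4-connected component count of a logical matrix (brute-force BFS)
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] > 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    nx <- nrow(mask)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      i <- ((v - 1) %% nx) + 1; j <- ((v - 1) %/% nx) + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ncol(mask)) {
          w <- ii + nx * (jj - 1)
          if (mask[w] && lab[w] == 0L) { lab[w] <- comp; queue <- c(queue, w) }
        }
      }
    }
  }
  comp
}

# dense first-principles Laplacian assembly for a ventricular_grid:
# unit-weight graph Laplacian over node links flanked by a conducting
# element, solved with base R's solve()
dense_laplace_oracle <- function(grid, boundary_sets, boundary_values) {
  nnx <- grid$nnx; nny <- grid$nny; nn <- nnx * nny
  cond <- grid$conducting
  A <- matrix(0, nn, nn)
  elem_ok <- function(a, b) a >= 1 && a <= grid$nx && b >= 1 && b <= grid$ny &&
    cond[a, b]
  add_link <- function(p, q) {
    A[p, p] <<- A[p, p] + 1; A[q, q] <<- A[q, q] + 1
    A[p, q] <<- A[p, q] - 1; A[q, p] <<- A[q, p] - 1
  }
  for (j in seq_len(nny)) for (i in seq_len(nnx - 1)) {
    if (elem_ok(i, j - 1) || elem_ok(i, j))
      add_link(i + nnx * (j - 1), i + 1 + nnx * (j - 1))
  }
  for (j in seq_len(nny - 1)) for (i in seq_len(nnx)) {
    if (elem_ok(i - 1, j) || elem_ok(i, j))
      add_link(i + nnx * (j - 1), i + nnx * j)
  }
  fixed <- unlist(boundary_sets)
  vals <- rep(boundary_values, lengths(boundary_sets))
  act <- which(diag(A) > 0)
  free <- setdiff(act, fixed)
  sol <- rep(NA_real_, nn)
  sol[fixed] <- vals
  if (length(free)) {
    rhs <- -A[free, fixed, drop = FALSE] %*% vals
    sol[free] <- solve(A[free, free, drop = FALSE], rhs)
  }
  sol
}

# small annular label map for induction-related tests
tiny_ring <- function(arcs = list()) ring_substrate(arcs)
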