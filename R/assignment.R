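#' Optimal one-to-one assignment (Hungarian algorithm)
#'
#' Solves the rectangular linear assignment problem by the Jonker-Volgonant
#' style shortest augmenting path method with dual potentials (O(n^3)).
#' Infeasible pairings are marked `Inf` in the cost matrix; the solver
#' maximises the number of feasible assignments first and minimises their
#' total cost second (dummy padding costs are chosen so that any feasible
#' pairing is always preferred over leaving both items unassigned).
#'
#' This solver backs both left/right stereo matching and frame-to-frame
#' trajectory linking.
#'
#' @param cost Numeric matrix (rows = sources, columns = targets); entries
#'   must be non-negative or `Inf` (infeasible).
#' @return Integer vector of length `nrow(cost)`: for each row the assigned
#'   column index, or `NA` if the row is left unassigned.
#' @examples
#' m <- rbind(c(4, 1, 3), c(2, 0, 5), c(3, 2, 2))
#' solve_assignment(m)   # 2, 1, 3
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost)) stop("'cost' must be a matrix")
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L) return(integer(0))
  if (m == 0L) return(rep(NA_integer_, n))
  if (any(is.nan(cost)) || any(cost < 0, na.rm = TRUE))
    stop("'cost' entries must be non-negative numbers or Inf")

  k <- max(n, m)
  finite <- cost[is.finite(cost)]
  maxf <- if (length(finite)) max(finite, 0) else 0
  pad <- maxf * k + 1          # dummy assignment: worse than any feasible sum
  big <- (pad + 1) * (k + 1)   # infeasible sentinel: worse than any dummy sum

  a <- matrix(pad, k, k)
  block <- cost
  block[!is.finite(block)] <- big
  a[seq_len(n), seq_len(m)] <- block

  p <- hungarian_square(a)     # p[j] = row assigned to column j

  ans <- rep(NA_integer_, n)
  for (j in seq_len(m)) {
    i <- p[j]
    if (i <= n && is.finite(cost[i, j])) ans[i] <- j
  }
  ans
}

# Shortest-augmenting-path Hungarian on a square finite cost matrix.
# Returns p: p[j] = row assigned to column j.
hungarian_square <- function(a) {
  n <- nrow(a)
  u <- numeric(n)           # row potentials
  v <- numeric(n)           # column potentials
  p <- integer(n)           # p[j]: row assigned to column j (0 = none)

  for (i in seq_len(n)) {
    minv <- rep(Inf, n)     # tentative reduced distance to each column
    way  <- integer(n)      # predecessor column on the alternating tree
    used <- rep(FALSE, n)
    i0 <- i; j0 <- 0L       # j0 = 0 marks the virtual root column
    repeat {
      nu <- which(!used)
      cur <- a[i0, nu] - u[i0] - v[nu]
      upd <- cur < minv[nu]
      if (any(upd)) {
        idx <- nu[upd]
        minv[idx] <- cur[upd]
        way[idx] <- j0
      }
      j1 <- nu[which.min(minv[nu])]
      delta <- minv[j1]
      # grow potentials on the tree, shrink slack off it
      uc <- which(used)
      u[i] <- u[i] + delta
      if (length(uc)) {
        u[p[uc]] <- u[p[uc]] + delta
        v[uc] <- v[uc] - delta
      }
      minv[nu] <- minv[nu] - delta
      used[j1] <- TRUE
      if (p[j1] == 0L) { j0 <- j1; break }
      i0 <- p[j1]
      j0 <- j1
    }
    # augment along the alternating path back to the root
    j <- j0
    repeat {
      pj <- way[j]
      if (pj == 0L) { p[j] <- i; break }
      p[j] <- p[pj]
      j <- pj
    }
  }
  p
}
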