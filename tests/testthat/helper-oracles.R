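# Independent oracles and small fixture builders. Everything here is kept
# deliberately naive (brute force, generating functions, exhaustive search)
# and separate from the package's own code paths.

# --- brute-force connected components (BFS) on a vertex subset ------------
bfComponents <- function(subset, adj) {
  lab <- integer(length(subset))
  names(lab) <- subset
  cur <- 0L
  for (v in subset) {
    if (lab[as.character(v)] != 0L) next
    cur <- cur + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (lab[as.character(u)] != 0L) next
      lab[as.character(u)] <- cur
      nb <- intersect(adj[[u]], subset)
      queue <- c(queue, nb[lab[as.character(nb)] == 0L])
    }
  }
  lab
}

# --- closed-form homogeneous-sphere potential (radial dipole) -------------
# Surface potential of a radial unit dipole at distance b from the centre of
# a homogeneous conducting sphere (radius R, conductivity sigma) with an
# insulating exterior, summed in closed form via Legendre generating
# functions:
#   sum_{n>=1} (2n+1) x^n P_n(c) = 2x(c - x)/D^{3/2} + 1/sqrt(D) - 1,
#   D = 1 - 2xc + x^2,  x = b/R.
homRadialPotential <- function(R, sigma, b, cosGamma) {
  x <- b / R
  D <- 1 - 2 * x * cosGamma + x^2
  series <- 2 * x * (cosGamma - x) / D^1.5 + 1 / sqrt(D) - 1
  series / (x * 4 * pi * sigma * R^2)
}

# --- exhaustive grid search of the ReML objective -------------------------
# Maximises freeEnergy (data + hyperprior terms) over a regular lambda grid;
# returns the argmax grid point and the grid step.
gridSearchLambda <- function(Y, comps, hyper, lo, hi, nGrid) {
  p <- length(comps)
  d <- ncol(Y)
  S <- tcrossprod(Y) / d
  axes <- replicate(p, seq(lo, hi, length.out = nGrid), simplify = FALSE)
  grid <- as.matrix(expand.grid(axes))
  best <- -Inf; arg <- grid[1, ]
  for (i in seq_len(nrow(grid))) {
    f <- tryCatch(as.numeric(freeEnergy(S, comps, grid[i, ], hyper, d = d)),
                  error = function(e) -Inf)
    if (f > best) { best <- f; arg <- grid[i, ] }
  }
  list(lambda = as.numeric(arg), F = best,
       step = (hi - lo) / (nGrid - 1))
}

# --- random symmetric PSD matrix ------------------------------------------
randomPSD <- function(m, rank = m) {
  A <- matrix(rnorm(m * rank), m, rank)
  S <- tcrossprod(A) / rank
  (S + t(S)) / 2
}

# --- tiny chain source space ----------------------------------------------
# s vertices along a line (inside a notional sphere), adjacency i ~ i+1.
chainSourceSpace <- function(s, spacing = 0.005) {
  v <- cbind(seq_len(s) * spacing - (s + 1) * spacing / 2, 0, 0.03)
  nrm <- matrix(rep(c(0, 0, 1), each = s), s, 3)
  adj <- lapply(seq_len(s), function(i)
    sort(intersect(c(i - 1L, i + 1L), seq_len(s))))
  new("SourceSpace", vertices = v, normals = nrm,
      faces = matrix(integer(0), 0, 3), adjacency = adj)
}

# --- shared desk-scale geometry (built once per test run) -----------------
testGeometry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      src <- makeIcosphereSourceSpace(2, 0.07)
      hm <- sphericalHeadModel()
      G <- computeLeadField(hm, electrodeCap(32, 0.1), src)
      cache <<- list(src = src, head = hm, G = G)
    }
    cache
  }
})
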