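#' @include AllClasses.R
NULL

.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

.subdivide_once <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  midcache <- new.env(hash = TRUE)
  nv <- nrow(v)
  newv <- list()
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- midcache[[key]]
    if (!is.null(hit)) return(hit)
    p <- (v[i, ] + v[j, ]) / 2
    p <- p / sqrt(sum(p^2))
    nv <<- nv + 1L
    newv[[length(newv) + 1L]] <<- p
    midcache[[key]] <- nv
    nv
  }
  nf <- matrix(0L, nrow(f) * 4L, 3L)
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    nf[(t - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(c, ca, bc), c(ab, bc, ca))
  }
  list(vertices = rbind(v, do.call(rbind, newv)), faces = nf)
}

.faces_to_adjacency <- function(faces, s) {
  adj <- vector("list", s)
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  sp <- split(e[, 2], e[, 1])
  for (nm in names(sp)) adj[[as.integer(nm)]] <- sort(unique(sp[[nm]]))
  for (i in seq_len(s)) if (is.null(adj[[i]])) adj[[i]] <- integer(0)
  adj
}

#' Geodesic icosphere source space
#'
#' Builds a geodesic sphere mesh by repeated midpoint subdivision of the
#' icosahedron, projected onto the sphere of the given radius. The vertex
#' count is 10 * 4^subdivisions + 2. Normals are the outward radial unit
#' vectors — the fixed dipole orientations. Serves as the desk-scale
#' stand-in for a downsampled cortical surface.
#'
#' @param subdivisions integer in 0..6.
#' @param radius sphere radius in metres.
#' @return a [SourceSpace-class].
#' @examples
#' src <- makeIcosphereSourceSpace(2, 0.07)
#' nSources(src)  # 162
#' @export
makeIcosphereSourceSpace <- function(subdivisions = 2L, radius = 0.07) {
  stopifnot(subdivisions >= 0L, subdivisions <= 6L, radius > 0)
  mesh <- .icosahedron()
  for (i in seq_len(subdivisions)) mesh <- .subdivide_once(mesh)
  nrm <- mesh$vertices
  new("SourceSpace",
      vertices = mesh$vertices * radius,
      normals = nrm,
      faces = mesh$faces,
      adjacency = .faces_to_adjacency(mesh$faces, nrow(mesh$vertices)))
}

#' Assign per-vertex region labels
#'
#' @param object a [SourceSpace-class].
#' @param value character vector, one label per vertex.
#' @return the relabelled source space.
#' @export
setGeneric("regionLabels<-", function(object, value)
  standardGeneric("regionLabels<-"))

#' @rdname regionLabels-set
#' @name regionLabels<-
#' @aliases regionLabels<-,SourceSpace-method
#' @export
setMethod("regionLabels<-", "SourceSpace", function(object, value) {
  object@regionLabels <- as.character(value)
  validObject(object)
  object
})

#' Grow a connected mesh patch
#'
#' Breadth-first ring growth from a seed vertex: the patch contains the
#' seed and all vertices within \code{nRings} adjacency hops. Used to
#' define simulated cortical patches.
#'
#' @param src a [SourceSpace-class].
#' @param seedVertex 1-based seed vertex index.
#' @param nRings number of adjacency rings to add (0 = seed only).
#' @return sorted integer vector of 1-based vertex indices.
#' @export
meshPatch <- function(src, seedVertex, nRings = 1L) {
  adj <- adjacency(src)
  stopifnot(seedVertex >= 1L, seedVertex <= length(adj))
  patch <- seedVertex
  frontier <- seedVertex
  for (r in seq_len(nRings)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), patch)
    if (!length(nxt)) break
    patch <- c(patch, nxt)
    frontier <- nxt
  }
  sort(as.integer(patch))
}

#' Mean edge length of a source space
#'
#' @param src a [SourceSpace-class].
#' @return mean Euclidean distance between adjacent vertices, metres.
#' @export
meshEdgeLength <- function(src) {
  v <- vertices(src)
  adj <- adjacency(src)
  tot <- 0; n <- 0L
  for (i in seq_along(adj)) for (j in adj[[i]]) if (j > i) {
    tot <- tot + sqrt(sum((v[i, ] - v[j, ])^2))
    n <- n + 1L
  }
  tot / n
}
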