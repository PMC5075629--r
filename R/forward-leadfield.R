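#' @include AllClasses.R
NULL

#' Spherical head model constructor
#'
#' Concentric-shell conductor, innermost (brain) to outermost (scalp).
#' Defaults: radii 0.087 / 0.092 / 0.100 m, conductivities 0.33 /
#' 0.33/80 / 0.33 S/m (the literature-standard 1 : 1/80 : 1 brain : skull :
#' scalp ratio), series truncation at 100 terms (converged well past
#' the 1e-10 relative tail level for source eccentricities up to ~0.75;
#' a warning reports the tail magnitude otherwise).
#'
#' @param radii increasing shell radii, metres.
#' @param conductivities shell conductivities, S/m.
#' @param nTerms spherical-harmonic truncation order.
#' @return a [SphericalHeadModel-class].
#' @export
sphericalHeadModel <- function(radii = c(0.087, 0.092, 0.100),
                               conductivities = c(0.33, 0.33 / 80, 0.33),
                               nTerms = 100L) {
  new("SphericalHeadModel", radii = radii, conductivities = conductivities,
      nTerms = as.integer(nTerms))
}

## Radial transfer factors t_n for a multilayer sphere.
##
## Per harmonic order n the potential in shell k is
##   V_k(rho) = a_k rho^n + b_k rho^-(n+1)   (rho = r / R_outer),
## with the dipole's infinite-medium term contributing a known
## rho^-(n+1) coefficient in the innermost shell. Continuity of V and of
## sigma dV/dr at every interface plus the insulating outer boundary give a
## small linear system per n; t_n maps a unit rho^-(n+1) source coefficient
## to the potential on the outer surface. For a homogeneous sphere
## t_n = (2n+1)/n, the classical result.
.sphere_transfer <- function(head, nTerms) {
  radii <- head@radii
  sig <- head@conductivities
  L <- length(radii)
  rho <- radii / radii[L]
  t_n <- numeric(nTerms)
  for (n in seq_len(nTerms)) {
    if (L == 1L) { t_n[n] <- (2 * n + 1) / n; next }
    ## Downward propagation in the scaled variables u = a rho^n,
    ## v = b rho^-(n+1), starting from the insulating scalp condition
    ## (n a_L = (n+1) b_L at rho = 1) and carrying an explicit log scale so
    ## the inward-growing v never overflows. At the innermost interface the
    ## v part must match the source's rho^-(n+1) coefficient, which fixes
    ## the overall amplitude and hence the surface transfer t_n.
    u <- 1; v <- n / (n + 1)      # at rho = 1, normalisation a_L = 1
    Vscalp <- u + v
    logScale <- 0
    for (k in seq(L - 1L, 1L)) {
      ## move inward within layer k+1 from rho[k+1] (or 1) to rho[k]
      r1 <- if (k + 1L == L) 1 else rho[k + 1L]
      lr <- log(rho[k] / r1)
      lu <- if (u != 0) log(abs(u)) + n * lr else -Inf
      lv <- if (v != 0) log(abs(v)) - (n + 1) * lr else -Inf
      Mx <- max(lu, lv)
      u <- sign(u) * exp(lu - Mx)
      v <- sign(v) * exp(lv - Mx)
      logScale <- logScale + Mx
      ## cross the interface into layer k (continuity of V and sigma dV/dr)
      rs <- sig[k + 1L] / sig[k]
      sumUV <- u + v
      flux <- rs * (n * u - (n + 1) * v)
      u <- ((n + 1) * sumUV + flux) / (2 * n + 1)
      v <- (n * sumUV - flux) / (2 * n + 1)
    }
    ## layer-1 rho^-(n+1) coefficient must equal the unit source coefficient
    logB1 <- log(abs(v)) + (n + 1) * log(rho[1]) + logScale
    t_n[n] <- sign(v) * Vscalp * exp(-logB1)
  }
  t_n
}

## Potentials (volts per A m) at unit-radius electrode directions E (m x 3)
## on the outer surface, from dipoles at positions P (s x 3, metres) with
## unit moments along directions M (s x 3). Vectorised over the full m x s
## grid; series accumulated with Legendre recursions.
.sphere_potentials <- function(head, E, P, M, nTerms = head@nTerms,
                               tailWarn = 1e-10) {
  sig1 <- head@conductivities[1]
  R <- head@radii[length(head@radii)]
  b <- sqrt(rowSums(P^2))
  inner <- head@radii[1]
  bad <- which(b >= inner)
  if (length(bad))
    stop("source vertex ", bad[1], " lies on/outside the innermost shell (|r| = ",
         signif(b[bad[1]], 4), " >= ", inner, ")")
  rhat <- P / pmax(b, .Machine$double.eps)
  rhat[b < 1e-12, ] <- M[b < 1e-12, , drop = FALSE]  # centre dipole: axis = moment
  mr <- rowSums(rhat * M)                      # radial moment component
  qt <- M - rhat * mr                          # tangential moment vector
  Cm <- E %*% t(rhat)                          # cos(gamma), m x s
  Cm <- pmin(pmax(Cm, -1), 1)
  Dm <- E %*% t(qt)                            # e_hat . q_t, m x s
  t_n <- .sphere_transfer(head, nTerms)
  m <- nrow(E); s <- nrow(P)
  G <- matrix(0, m, s)
  Pn_1 <- matrix(1, m, s)       # P_0
  Pn <- Cm                      # P_1
  dPn_1 <- matrix(0, m, s)      # P_0'
  dPn <- matrix(1, m, s)        # P_1'
  lastTerm <- 0
  for (n in seq_len(nTerms)) {
    radial_b <- ifelse(b < 1e-12 & n == 1, 1, b^(n - 1))   # b^0 at centre
    coef <- t_n[n] / (4 * pi * sig1) * radial_b * R^(-(n + 1))
    term <- (Pn * rep(n * mr * coef, each = m)) + (dPn * Dm * rep(coef, each = m))
    G <- G + term
    lastTerm <- max(abs(term))
    ## advance Legendre recursions to order n + 1
    Pn1 <- ((2 * n + 1) * Cm * Pn - n * Pn_1) / (n + 1)
    dPn1 <- (n + 1) * Pn + Cm * dPn
    Pn_1 <- Pn; Pn <- Pn1
    dPn_1 <- dPn; dPn <- dPn1
  }
  if (lastTerm > tailWarn * max(abs(G), .Machine$double.eps))
    warning(sprintf(
      "spherical series not fully converged at nTerms = %d (tail term %.3g)",
      nTerms, lastTerm))
  G
}

#' Scalp potential of dipoles in a multilayer sphere
#'
#' Potentials on the outer (scalp) surface generated by current dipoles
#' inside the innermost shell, by the analytic concentric-sphere series.
#' Units: volts per (A m) of dipole moment.
#'
#' @param head a [SphericalHeadModel-class].
#' @param electrodes m x 3 electrode positions, metres; radially projected
#'   onto the outer surface (electrodes must not lie inside it).
#' @param dipolePos s x 3 dipole positions, metres, strictly inside the
#'   innermost shell.
#' @param dipoleMoment s x 3 dipole moment directions (unit vectors).
#' @param nTerms series truncation (default from \code{head}).
#' @return m x s matrix of potentials, V/(A m).
#' @export
sphericalPotential <- function(head, electrodes, dipolePos, dipoleMoment,
                               nTerms = head@nTerms) {
  stopifnot(is(head, "SphericalHeadModel"))
  electrodes <- rbind(electrodes)
  dipolePos <- rbind(dipolePos)
  dipoleMoment <- rbind(dipoleMoment)
  R <- head@radii[length(head@radii)]
  er <- sqrt(rowSums(electrodes^2))
  if (any(er < R * (1 - 1e-6)))
    stop("electrodes must lie on or outside the outer shell")
  E <- electrodes / er  # radial projection onto the scalp surface
  .sphere_potentials(head, E, dipolePos, dipoleMoment, nTerms)
}

#' Compute a lead field for a spherical head model
#'
#' Fills G[j, k] with the referenced scalp potential at electrode j from a
#' unit dipole (1 nA m) at source vertex k oriented along its outward
#' normal, using the analytic multilayer-sphere series. Output units are
#' microvolts per nA m, matching the package's EEG unit convention.
#'
#' @param head a [SphericalHeadModel-class].
#' @param electrodes m x 3 numeric matrix of electrode positions (metres),
#'   optionally with rownames as channel labels, or a data.frame with
#'   columns label, x, y, z (see [readElectrodes()]).
#' @param src a [SourceSpace-class] with sources strictly inside the
#'   innermost shell.
#' @param reference "average" (default) applies the average-reference
#'   projector so every column of G sums to zero; "none" returns raw
#'   potentials against the series' implicit infinity reference. G and the
#'   EEG data it is used with must share a reference.
#' @param nTerms series truncation (default from \code{head}).
#' @return a [LeadField-class].
#' @export
computeLeadField <- function(head, electrodes, src,
                             reference = c("average", "none"),
                             nTerms = head@nTerms) {
  reference <- match.arg(reference)
  stopifnot(is(head, "SphericalHeadModel"), is(src, "SourceSpace"))
  if (is.data.frame(electrodes)) {
    labels <- as.character(electrodes$label)
    electrodes <- as.matrix(electrodes[, c("x", "y", "z")])
  } else {
    electrodes <- as.matrix(electrodes)
    labels <- rownames(electrodes)
    if (is.null(labels)) labels <- sprintf("E%02d", seq_len(nrow(electrodes)))
  }
  V <- sphericalPotential(head, electrodes, vertices(src), normals(src),
                          nTerms = nTerms)
  if (reference == "average") V <- averageReferenceProjector(nrow(V)) %*% V
  G <- V * 1e-3   # V/(A m) -> uV/(nA m)
  new("LeadField", gain = G, channelNames = labels,
      sourceSpaceId = sprintf("s%d", nSources(src)))
}

#' Average-reference projector
#'
#' The m x m projector I - 11'/m that re-references potentials to their
#' instantaneous mean across channels. The lead field and the EEG data must
#' share a reference; applying this projector to both is the package's
#' default convention.
#'
#' @param m number of channels.
#' @return m x m projection matrix.
#' @export
averageReferenceProjector <- function(m) {
  diag(m) - matrix(1 / m, m, m)
}

#' Quasi-uniform electrode cap
#'
#' Places n electrodes quasi-uniformly (Fibonacci spiral) over the upper
#' portion of the scalp sphere — a synthetic stand-in for a recording
#' montage.
#'
#' @param n number of electrodes.
#' @param radius scalp radius, metres.
#' @param coverage fraction of the full sphere area covered, from the
#'   vertex down (default 0.6, an extended cap).
#' @return n x 3 matrix of positions with channel-label rownames.
#' @export
electrodeCap <- function(n = 32L, radius = 0.1, coverage = 0.6) {
  stopifnot(n >= 1L, coverage > 0, coverage <= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * coverage * i / n          # cos(theta) from 1 down
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n) - 1L)
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- radius * cbind(r * cos(th), r * sin(th), z)
  rownames(pos) <- sprintf("E%02d", seq_len(n))
  pos
}

#' Read electrode positions from delimited text
#'
#' Expects columns label, x, y, z (metres), whitespace- or comma-separated,
#' with '#' comments allowed.
#'
#' @param path file path.
#' @return data.frame with columns label, x, y, z.
#' @export
readElectrodes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[,\\s]+", perl = TRUE)
  df <- data.frame(
    label = vapply(parts, `[`, "", 1L),
    x = as.numeric(vapply(parts, `[`, "", 2L)),
    y = as.numeric(vapply(parts, `[`, "", 3L)),
    z = as.numeric(vapply(parts, `[`, "", 4L)),
    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(df[, 2:4]))))
    stop("non-numeric electrode coordinates in ", path)
  df
}
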