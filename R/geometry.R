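# Internal backbone geometry: NeRF atom placement, dihedrals, ideal-helix
# chain construction.  Angles are in degrees at every interface.

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.unit <- function(v) v / sqrt(sum(v * v))

# NeRF: place atom D from atoms A-B-C, bond |C-D|, angle B-C-D, dihedral A-B-C-D
.placeAtom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  c + bc * d[1L] + m * d[2L] + n * d[3L]
}

# signed dihedral A-B-C-D in degrees, in (-180, 180]
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  c1 <- .cross3(b1, b2)
  c2 <- .cross3(b2, b3)
  x <- sum(c1 * c2)
  y <- sum(.cross3(c1, c2) * .unit(b2))
  atan2(y, x) * 180 / pi
}

# ideal bond lengths (Angstrom) and angles (degrees) for a trans polypeptide
.BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.521,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5)

# Build N/CA/C/O coordinates for given phi/psi (omega fixed trans = 180).
# Consecutive CA-CA distances are ~3.80 A for any dihedrals.
.buildBackbone <- function(phi, psi) {
  L <- length(phi)
  stopifnot(length(psi) == L, L >= 1L)
  g <- .BB_GEOM
  N <- CA <- C <- O <- matrix(NA_real_, L, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C[1L, ] <- CA[1L, ] + g$ca_c * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in seq_len(L)) {
    if (i > 1L) {
      N[i, ] <- .placeAtom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                           g$c_n, g$ang_ca_c_n, psi[i - 1L])
      CA[i, ] <- .placeAtom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                            g$n_ca, g$ang_c_n_ca, 180)
      C[i, ] <- .placeAtom(C[i - 1L, ], N[i, ], CA[i, ],
                           g$ca_c, g$ang_n_ca_c, phi[i])
    }
    # carbonyl O in the peptide plane, trans to the next N
    O[i, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ],
                         g$c_o, g$ang_ca_c_o, psi[i] + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

# Ideal tetrahedral CB from backbone N, CA, C
.cbFromBackbone <- function(n, ca, c) {
  v1 <- .unit(n - ca)
  v2 <- .unit(c - ca)
  bisector <- .unit(-(v1 + v2))
  perp <- .unit(.cross3(v2, v1))
  half <- 54.75 * pi / 180  # half the tetrahedral angle
  ca + .BB_GEOM$ca_cb * (cos(half) * bisector + sin(half) * perp)
}

# phi/psi for all residues; NA at chain termini where undefined
.phiPsi <- function(N, CA, C) {
  L <- nrow(CA)
  phi <- psi <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i > 1L) {
      phi[i] <- .dihedral(C[i - 1L, ], N[i, ], CA[i, ], C[i, ])
    }
    if (i < L) {
      psi[i] <- .dihedral(N[i, ], CA[i, ], C[i, ], N[i + 1L, ])
    }
  }
  list(phi = phi, psi = psi)
}
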