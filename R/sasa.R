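#' @title Solvent-accessible surface area (sphere-point sampling)
#' @description
#' Per-atom SASA by the classic sphere-sampling construction: each heavy atom
#' is inflated by the probe radius (1.4 Angstrom water probe by default), a
#' deterministic golden-spiral lattice of points is placed on the inflated
#' sphere, and the accessible fraction is the share of points not buried
#' inside any neighbouring inflated sphere. The lattice is fixed for a given
#' `n_points`, so results carry no randomness. Used only to decide whether
#' consensus-site residues are solvent accessible.
#' @name sasa
NULL

# van der Waals radii (Angstrom) by element; Bondi-style values.
VDW_RADII <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               SE = 1.90, MG = 1.73, ZN = 1.39, FE = 1.40, MN = 1.61,
               CA = 2.31, "NA" = 2.27, K = 2.75, CU = 1.40, NI = 1.63)
VDW_FALLBACK <- 1.7

#' van der Waals radius lookup
#'
#' @param element character vector of element symbols.
#' @return numeric radii in Angstrom; unknown elements get 1.7 with a warning.
#' @export
vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(element[unknown]), collapse = ", "),
            "; using fallback radius ", VDW_FALLBACK, " Angstrom", call. = FALSE)
    r[unknown] <- VDW_FALLBACK
  }
  unname(r)
}

# Deterministic quasi-uniform unit-sphere lattice (golden-spiral / Fibonacci).
sphere_lattice <- function(n_points) {
  i <- seq_len(n_points) - 0.5
  z <- 1 - 2 * i / n_points
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-residue solvent-accessible surface area
#'
#' @param model a curated [allo_structure]; hydrogens are ignored.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param n_points sphere-lattice points per atom (default 960).
#' @return an `allo_sasa` data.frame: `key`, `sasa` (Angstrom^2 per residue),
#'   with `probe` and `n_points` in attributes.
#' @export
compute_sasa <- function(model, probe = 1.4, n_points = 960L) {
  a <- model$atoms[!model$atoms$is_hydrogen, , drop = FALSE]
  coords <- as.matrix(a[, c("x", "y", "z")])
  atom_sasa <- atom_sasa_values(coords, vdw_radius(a$element), probe, n_points)
  per_res <- tapply(atom_sasa, a$key, sum)
  rt <- residue_table(model)
  out <- data.frame(key = rt$key,
                    sasa = as.numeric(per_res[rt$key]),
                    stringsAsFactors = FALSE)
  out$sasa[is.na(out$sasa)] <- 0
  attr(out, "probe") <- probe
  attr(out, "n_points") <- as.integer(n_points)
  class(out) <- c("allo_sasa", "data.frame")
  out
}

# Core sphere-sampling routine over an arbitrary coordinate/radius set.
atom_sasa_values <- function(coords, radii, probe = 1.4, n_points = 960L) {
  n <- nrow(coords)
  if (n == 0L) return(numeric(0))
  lattice <- sphere_lattice(n_points)
  inflated <- radii + probe
  out <- numeric(n)
  d <- as.matrix(stats::dist(coords))
  for (i in seq_len(n)) {
    ri <- inflated[i]
    nb <- which(d[i, ] < ri + inflated & seq_len(n) != i)
    pts <- sweep(lattice * ri, 2, coords[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
          (pts[, 3] - coords[j, 3])^2
        free <- free & dj2 > inflated[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else {
      frac <- 1
    }
    out[i] <- frac * 4 * pi * ri^2
  }
  out
}
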