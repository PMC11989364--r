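#' @title Seeded synthetic structures with known ground truth
#' @description
#' Generators for coarse-grained test structures whose mechanically relevant
#' features are known by construction: a two-domain "dumbbell" whose sparse
#' collinear linker is simultaneously the elastic-network hinge and the
#' interaction-network bottleneck, and a single domain with an engineered
#' C-shaped surface cleft for pocket detection. Residues carry a C-alpha and,
#' depending on `sidechain_mode`, zero to three pseudo side-chain heavy
#' atoms; they are named ALA (with side chain) or GLY (without). Generation
#' is bit-reproducible for a fixed seed and leaves the caller's RNG state
#' untouched.
#' @name synthetic_data
NULL

#' Synthetic-structure parameters
#'
#' Defaults emulate protein-like C-alpha packing: 25 residues per domain in a
#' 9-Angstrom sphere (about one residue per 115 Angstrom^3, typical protein
#' density), virtual C-alpha bond spacing 3.8 Angstrom along the linker, and
#' a 3.8-Angstrom minimum separation between any two C-alpha.
#'
#' @param n_per_domain residues per globular domain (>= 15).
#' @param n_linker linker residues (>= 2).
#' @param domain_radius domain sphere radius in Angstrom.
#' @param linker_spacing C-alpha spacing along the linker in Angstrom.
#' @param min_separation minimum C-alpha/C-alpha distance in Angstrom.
#' @param seed RNG seed.
#' @param sidechain_mode `"cbeta"` (one pseudo side-chain atom at 1.5
#'   Angstrom), `"triplet"` (three atoms) or `"none"` (glycine-like).
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_domain = 25L, n_linker = 4L,
                           domain_radius = 9, linker_spacing = 3.8,
                           min_separation = 3.8, seed = 1L,
                           sidechain_mode = c("cbeta", "triplet", "none")) {
  sidechain_mode <- match.arg(sidechain_mode)
  stopifnot(n_per_domain >= 15L, n_linker >= 2L, domain_radius > 0,
            linker_spacing > 0, min_separation > 0)
  structure(list(n_per_domain = as.integer(n_per_domain),
                 n_linker = as.integer(n_linker),
                 domain_radius = domain_radius,
                 linker_spacing = linker_spacing,
                 min_separation = min_separation,
                 seed = as.integer(seed),
                 sidechain_mode = sidechain_mode),
            class = "synthetic_spec")
}

# Rejection-sample n points inside a sphere with pairwise min separation.
sample_packed_sphere <- function(n, radius, min_sep, center, budget = 20000L) {
  pts <- matrix(NA_real_, n, 3L)
  got <- 0L
  tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > budget) {
      stop("packing infeasible: could not place ", n, " points at separation ",
           min_sep, " inside radius ", radius,
           "; increase domain_radius", call. = FALSE)
    }
    p <- stats::runif(3, -radius, radius)
    if (sum(p^2) > radius^2) next
    if (got > 0L) {
      d2 <- rowSums(sweep(pts[seq_len(got), , drop = FALSE], 2, p)^2)
      if (min(d2) < min_sep^2) next
    }
    got <- got + 1L
    pts[got, ] <- p
  }
  sweep(pts, 2, center, "+")
}

# Assemble an allo_structure from C-alpha coordinates plus pseudo side chains.
assemble_model <- function(ca, chain, resno, sidechain_mode, source_id,
                           sc_dir = NULL) {
  n <- nrow(ca)
  if (is.null(sc_dir)) {
    # default side-chain direction: radially away from the structure centroid
    ctr <- colMeans(ca)
    sc_dir <- sweep(ca, 2, ctr)
    len <- sqrt(rowSums(sc_dir^2))
    len[len < 1e-9] <- 1
    sc_dir <- sc_dir / len
  }
  rows <- list()
  for (i in seq_len(n)) {
    resname <- if (sidechain_mode == "none") "GLY" else "ALA"
    rows[[length(rows) + 1L]] <- data.frame(
      type = "ATOM", elety = "CA", element = "C", chain = chain[i],
      resno = resno[i], icode = "", resid = resname,
      x = ca[i, 1], y = ca[i, 2], z = ca[i, 3],
      occupancy = 1, altloc = "", stringsAsFactors = FALSE)
    if (sidechain_mode != "none") {
      cb <- ca[i, ] + 1.5 * sc_dir[i, ]
      rows[[length(rows) + 1L]] <- data.frame(
        type = "ATOM", elety = "CB", element = "C", chain = chain[i],
        resno = resno[i], icode = "", resid = resname,
        x = cb[1], y = cb[2], z = cb[3],
        occupancy = 1, altloc = "", stringsAsFactors = FALSE)
      if (sidechain_mode == "triplet") {
        for (t in 1:2) {
          off <- if (t == 1L) c(1.2, 0.9, 0) else c(-1.2, 0.9, 0)
          pt <- cb + off
          rows[[length(rows) + 1L]] <- data.frame(
            type = "ATOM", elety = c("CG", "CD")[t], element = "C",
            chain = chain[i], resno = resno[i], icode = "", resid = resname,
            x = pt[1], y = pt[2], z = pt[3],
            occupancy = 1, altloc = "", stringsAsFactors = FALSE)
        }
      }
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$is_hydrogen <- FALSE
  atoms$is_backbone <- atoms$elety %in% BACKBONE_NAMES
  atoms$key <- residue_key(atoms$chain, atoms$resno, atoms$icode)
  new_structure(atoms, source_id, 1L,
                curation_log = "synthetic: generated, no curation needed")
}

#' Generate a two-domain hinge structure
#'
#' Two rejection-packed spherical C-alpha clusters joined by a sparse
#' collinear linker along the x axis. One residue per domain (the "anchor")
#' is pinned at the domain pole facing the linker, so the anchors plus the
#' linker form the only inter-domain path: the designated bridge residues of
#' the ground truth. Domain surfaces are separated well beyond both the
#' elastic-network and contact cutoffs, so the linker is the global hinge
#' and the betweenness bottleneck by construction.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `model` (an [allo_structure]) and `truth` (list:
#'   `linker_keys`, `bridge_keys`, `cavity_keys = NULL`).
#' @export
generate_two_domain <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    R <- spec$domain_radius
    s <- spec$linker_spacing
    nl <- spec$n_linker
    gap <- (nl + 1L) * s
    c1 <- c(0, 0, 0)
    c2 <- c(2 * R + gap, 0, 0)
    # anchors at the poles facing each other, each backed by a buttress
    # residue at contact distance so the bridge is wired into its domain
    a1 <- c(R, 0, 0)
    a2 <- c(R + gap, 0, 0)
    b1 <- c(R - 4.2, 0, 0)
    b2 <- c(R + gap + 4.2, 0, 0)
    sample_domain <- function(center, fixed) {
      pts <- fixed
      need <- spec$n_per_domain - nrow(fixed)
      got <- 0L
      tries <- 0L
      while (got < need) {
        tries <- tries + 1L
        if (tries > 50000L) {
          stop("packing infeasible; increase domain_radius", call. = FALSE)
        }
        p <- stats::runif(3, -R, R)
        if (sum(p^2) > (R - spec$min_separation / 2)^2) next
        p <- p + center
        if (min(rowSums(sweep(pts, 2, p)^2)) < spec$min_separation^2) next
        pts <- rbind(pts, p)
        got <- got + 1L
      }
      pts[-seq_len(nrow(fixed)), , drop = FALSE]
    }
    d1 <- sample_domain(c1, rbind(a1, b1))
    d2 <- sample_domain(c2, rbind(a2, b2))
    linker <- cbind(R + s * seq_len(nl), 0, 0)
    ca <- rbind(d1, b1, a1, linker, a2, b2, d2)
    n <- nrow(ca)
    # side chains: radial within each domain; +z along the axial bridge
    sc_dir <- matrix(0, n, 3L)
    n1 <- nrow(d1)
    dir_of <- function(pts, center) {
      v <- sweep(pts, 2, center)
      l <- sqrt(rowSums(v^2)); l[l < 1e-9] <- 1
      v / l
    }
    sc_dir[seq_len(n1), ] <- dir_of(d1, c1)
    axial <- n1 + seq_len(nl + 4L)  # b1, a1, linker, a2, b2
    sc_dir[axial, ] <- matrix(rep(c(0, 0, 1), length(axial)), ncol = 3, byrow = TRUE)
    sc_dir[(n1 + nl + 4L + 1L):n, ] <- dir_of(d2, c2)
    model <- assemble_model(ca, chain = rep("A", n), resno = seq_len(n),
                            sidechain_mode = spec$sidechain_mode,
                            source_id = sprintf("synth-two-domain-seed%d", spec$seed),
                            sc_dir = sc_dir)
    i_a1 <- n1 + 2L
    i_link <- i_a1 + seq_len(nl)
    keys <- residue_table(model)$key
    # the axial residues (buttress, anchor, linker, anchor, buttress) carry
    # every inter-domain contact: they are the designated bridge
    truth <- list(linker_keys = keys[i_link],
                  bridge_keys = keys[axial],
                  cavity_keys = NULL)
    list(model = model, truth = truth)
  })
}

#' Generate a single-domain structure with a C-shaped cleft
#'
#' Residues are placed quasi-uniformly on a spherical shell around the cleft
#' center, with a cone around +z left open as the cleft aperture (about 6
#' Angstrom wide); side chains point outward so the cavity stays clear. A
#' packed convex cluster is attached to one side as bulk. With
#' `filled = TRUE` the cavity and aperture are packed solid as a negative
#' control.
#'
#' @param spec a [synthetic_spec()]; `n_per_domain` sizes the bulk cluster.
#' @param filled fill the cavity (control structure)? Default `FALSE`.
#' @param shell_radius cleft shell radius in Angstrom (default 7.5).
#' @return list with `model` and `truth` (`cavity_keys` = shell residues).
#' @export
generate_cleft_structure <- function(spec = synthetic_spec(), filled = FALSE,
                                     shell_radius = 7.5) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    R <- shell_radius
    # quasi-uniform shell at 3.3-Angstrom spacing (tight enough that wall
    # gaps fall inside the detector clearance radius); a cone around +z is
    # left open as the aperture (~6.4 Angstrom across), giving the "C"
    wall_spacing <- 3.3
    n_shell <- round(4 * pi * R^2 / wall_spacing^2)
    pts <- sphere_lattice(n_shell) * R
    aperture_half_width <- 3.2
    open_cos <- sqrt(1 - (aperture_half_width / R)^2)
    shell <- pts[pts[, 3] / R < open_cos, , drop = FALSE]
    # small seeded jitter tangent to the shell so coordinates are not a
    # perfect lattice
    jit <- matrix(stats::runif(3 * nrow(shell), -0.15, 0.15), ncol = 3)
    shell <- shell + jit - (rowSums(jit * shell) / R^2) * shell
    if (filled) {
      # negative control: the cavity is eliminated by collapsing the cage
      # into a compact convex lattice cluster (tight spacing closes every
      # interstice against the detector clearance; the small total atom
      # count keeps every grid point below the burial threshold)
      a_fill <- 2.5
      g <- as.matrix(expand.grid(x = seq(-4, 4, by = a_fill),
                                 y = seq(-4, 4, by = a_fill),
                                 z = seq(-4, 4, by = a_fill)))
      ca <- g[rowSums(g^2) <= 4^2, , drop = FALSE]
      shell <- ca[0, , drop = FALSE]
    } else {
      ca <- shell
    }
    # outward side chains keep the cavity clear
    sc_dir <- ca / pmax(sqrt(rowSums(ca^2)), 1e-9)
    n <- nrow(ca)
    model <- assemble_model(ca, chain = rep("A", n), resno = seq_len(n),
                            sidechain_mode = spec$sidechain_mode,
                            source_id = sprintf("synth-cleft-seed%d%s", spec$seed,
                                                if (filled) "-filled" else ""),
                            sc_dir = sc_dir)
    keys <- residue_table(model)$key
    truth <- list(linker_keys = NULL, bridge_keys = NULL,
                  cavity_keys = keys[seq_len(nrow(shell))])
    list(model = model, truth = truth)
  })
}

#' Write a structure as a PDB file (with optional ground-truth JSON side-car)
#'
#' @param model an [allo_structure].
#' @param path output PDB path.
#' @param truth optional ground-truth list to write as `<path>.truth.json`.
#' @return invisibly, `path`.
#' @export
write_structure_pdb <- function(model, path, truth = NULL) {
  a <- model$atoms
  lines <- sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$type, seq_len(nrow(a)),
    ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
    a$altloc, a$resid, a$chain, a$resno, ifelse(a$icode == "", " ", a$icode),
    a$x, a$y, a$z, a$occupancy, 0, a$element)
  con <- file(path, open = "wb")
  writeLines(c(lines, "END"), con, sep = "\n")
  close(con)
  if (!is.null(truth)) {
    jsonlite::write_json(sort_keys(truth), paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(path)
}
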