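# Shared fixtures and independent oracles, built in code at test time.

# One fixed-width PDB ATOM/HETATM record.
pdb_line <- function(type = "ATOM", serial = 1, name = "CA", alt = "",
                     resn = "ALA", chain = "A", resno = 1, icode = "",
                     x = 0, y = 0, z = 0, occ = 1, element = "C") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          alt, resn, chain, resno, ifelse(icode == "", " ", icode),
          x, y, z, occ, 0, element)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# ALA-GLY-ALA single chain, 3.8 A apart, heavy atoms only.
fixture_tripeptide <- function() {
  mk_res <- function(resno, resn, x0) {
    ats <- list(c("N", "N", 0), c("CA", "C", 0.5), c("C", "C", 1.0),
                c("O", "O", 1.4))
    if (resn == "ALA") ats <- c(ats, list(c("CB", "C", 0.7)))
    unlist(lapply(seq_along(ats), function(i) {
      a <- ats[[i]]
      pdb_line(serial = resno * 10 + i, name = a[1], resn = resn,
               resno = resno, x = x0 + as.numeric(a[3]),
               y = if (a[1] == "CB") 1.5 else 0, element = a[2])
    }))
  }
  write_pdb_fixture(c(mk_res(1, "ALA", 0), mk_res(2, "GLY", 3.8),
                      mk_res(3, "ALA", 7.6)))
}

# Chains A,B,C + 5 waters + GNP + Mg hetero residues.
fixture_multichain_hetero <- function() {
  lines <- character(0)
  s <- 0
  for (ch in c("A", "B", "C")) {
    for (r in 1:2) {
      s <- s + 1
      lines <- c(lines,
                 pdb_line(serial = s, name = "CA", resn = "ALA", chain = ch,
                          resno = r, x = s * 4),
                 pdb_line(serial = s + 100, name = "CB", resn = "ALA",
                          chain = ch, resno = r, x = s * 4, y = 1.5))
    }
  }
  for (w in 1:5) {
    lines <- c(lines, pdb_line(type = "HETATM", serial = 200 + w, name = "O",
                               resn = "HOH", chain = "A", resno = 100 + w,
                               x = 50 + w * 3, element = "O"))
  }
  lines <- c(lines,
             pdb_line(type = "HETATM", serial = 301, name = "PA", resn = "GNP",
                      chain = "A", resno = 201, x = 70, element = "P"),
             pdb_line(type = "HETATM", serial = 302, name = "MG", resn = "MG",
                      chain = "A", resno = 202, x = 75, element = "MG"))
  write_pdb_fixture(lines)
}

# Random connected C-alpha chain (3.8 A virtual bonds): connected at any
# cutoff above the bond length by construction.
random_chain_coords <- function(n) {
  steps <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
  steps <- 3.8 * steps / sqrt(rowSums(steps^2))
  apply(rbind(0, steps), 2, cumsum)
}

# Independent brute-force weighted betweenness: enumerate every simple path
# between each pair, keep the minimum-weight ones, split credit equally,
# exclude endpoints, normalize by 2/((n-1)(n-2)). Only for tiny graphs.
brute_betweenness <- function(n, edges) {
  # edges: data.frame i, j, w
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]; w <- edges$w[r]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  score <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- list(); best <- Inf
    walk <- function(v, visited, wsum, trail) {
      if (wsum > best + 1e-9) return()
      if (v == t) {
        if (wsum < best - 1e-9) { best <<- wsum; paths <<- list(trail) }
        else if (abs(wsum - best) <= 1e-9) paths[[length(paths) + 1L]] <<- trail
        return()
      }
      nb <- adj[[v]]
      if (is.null(nb)) return()
      for (r in seq_len(nrow(nb))) {
        u <- nb[r, 1]
        if (!visited[u]) {
          vis <- visited; vis[u] <- TRUE
          walk(u, vis, wsum + nb[r, 2], c(trail, u))
        }
      }
    }
    vis <- rep(FALSE, n); vis[s] <- TRUE
    walk(s, vis, 0, s)
    if (length(paths) == 0) next
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      score[interior] <- score[interior] + 1 / length(paths)
    }
  }
  if (n >= 3) score * 2 / ((n - 1) * (n - 2)) else rep(0, n)
}

# Independent linear-interpolation percentile (matches the documented
# convention; written from the order-statistics definition).
brute_percentile <- function(x, q) {
  xs <- sort(x)
  h <- (length(xs) - 1) * q
  lo <- floor(h)
  xs[lo + 1] + (h - lo) * (xs[min(lo + 2, length(xs))] - xs[lo + 1])
}

# Compact convex lattice ball written as a PDB fixture (no cavity).
fixture_convex_ball <- function() {
  g <- as.matrix(expand.grid(x = seq(-4, 4, by = 2.5),
                             y = seq(-4, 4, by = 2.5),
                             z = seq(-4, 4, by = 2.5)))
  g <- g[rowSums(g^2) <= 16, , drop = FALSE]
  lines <- vapply(seq_len(nrow(g)), function(i) {
    pdb_line(serial = i, name = "CA", resn = "GLY", resno = i,
             x = g[i, 1], y = g[i, 2], z = g[i, 3])
  }, character(1))
  write_pdb_fixture(lines)
}

fpocket_fixture_dir <- function() {
  system.file("extdata", "fpocket_synthetic_out", package = "allopocket")
}
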