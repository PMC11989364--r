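#' @title Pocket detection, Fpocket ingestion, scoring and consensus
#' @description
#' Pockets come from one of two sources: a built-in grid detector (lattice
#' points that are clear of the van der Waals envelope yet buried by
#' surrounding heavy atoms, clustered by flood fill) or a parsed Fpocket
#' output directory, whose druggability score and total SASA are read
#' verbatim and never recomputed. Each pocket is then scored with the median
#' and maximum essential-site z-score of its residues, and the consensus
#' stage marks pockets containing solvent-accessible residues that are both
#' essential (top-25% z) and hubs (top-5% betweenness) as putative
#' allosteric sites.
#' @name pockets
NULL

new_pocket_set <- function(df, residues, source) {
  structure(list(table = df, residues = residues, source = source),
            class = "allo_pockets")
}

#' @export
print.allo_pockets <- function(x, ...) {
  cat(sprintf("<allo_pockets> %d pocket(s), source = %s\n",
              nrow(x$table), x$source))
  invisible(x)
}

#' Grid-based cavity detection
#'
#' Lays a cubic lattice (spacing `spacing`) over the padded bounding box of
#' the heavy atoms and keeps points that (a) are at least 2.2 Angstrom from
#' every heavy atom and (b) have at least `burial_min` heavy atoms within
#' 8 Angstrom. Kept points are clustered by 6-connected flood fill; clusters
#' of at least `cluster_min` points become pockets, whose residues are those
#' with any heavy atom within 5 Angstrom of a cluster point. Fully
#' deterministic; a stand-in for an external pocket finder when its output
#' is not at hand.
#'
#' @param model a curated [allo_structure].
#' @param spacing lattice spacing in Angstrom (default 1.0).
#' @param burial_min minimum heavy atoms within the 8-Angstrom burial shell
#'   (default 18).
#' @param cluster_min minimum cluster size in lattice points (default 15).
#' @return an `allo_pockets` object with `source = "builtin"`.
#' @export
detect_pockets_grid <- function(model, spacing = 1.0, burial_min = 18L,
                                cluster_min = 15L) {
  clearance <- 2.2
  shell <- 8.0
  res_cut <- 5.0
  a <- model$atoms[!model$atoms$is_hydrogen, , drop = FALSE]
  coords <- as.matrix(a[, c("x", "y", "z")])
  pad <- 2
  lo <- apply(coords, 2, min) - pad
  hi <- apply(coords, 2, max) + pad
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  blocked <- array(FALSE, c(nx, ny, nz))
  burial <- array(0L, c(nx, ny, nz))
  cl_off <- offset_template(clearance, spacing)
  sh_off <- offset_template(shell, spacing)
  for (k in seq_len(nrow(coords))) {
    ci <- round((coords[k, ] - lo) / spacing) + 1
    blocked <- mark_cells(blocked, ci, cl_off, coords[k, ], lo, spacing,
                          clearance, TRUE)
    burial <- mark_cells(burial, ci, sh_off, coords[k, ], lo, spacing,
                         shell, FALSE)
  }
  keep <- !blocked & burial >= burial_min
  comp <- flood_fill_6(keep)
  ids_all <- setdiff(sort(unique(as.integer(comp))), 0L)
  sizes <- vapply(ids_all, function(i) sum(comp == i), integer(1))
  big <- sizes >= cluster_min
  ids <- ids_all[big][order(-sizes[big], ids_all[big])]
  rows <- list(); members <- list()
  rt <- residue_table(model, strict = FALSE)
  for (p in seq_along(ids)) {
    idx <- which(comp == ids[p], arr.ind = TRUE)
    pts <- cbind(gx[idx[, 1]], gy[idx[, 2]], gz[idx[, 3]])
    near <- rep(FALSE, nrow(coords))
    for (q in seq_len(nrow(pts))) {
      d2 <- (coords[, 1] - pts[q, 1])^2 + (coords[, 2] - pts[q, 2])^2 +
        (coords[, 3] - pts[q, 3])^2
      near <- near | d2 <= res_cut^2
    }
    res <- unique(a$key[near])
    res <- rt$key[rt$key %in% res]  # canonical order
    rows[[p]] <- data.frame(pocket_id = p, source = "builtin",
                            n_points = nrow(pts), n_residues = length(res),
                            sasa_total = NA_real_, druggability = NA_real_,
                            stringsAsFactors = FALSE)
    members[[p]] <- res
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pocket_id = integer(), source = character(),
               n_points = integer(), n_residues = integer(),
               sasa_total = numeric(), druggability = numeric(),
               stringsAsFactors = FALSE)
  new_pocket_set(df, members, "builtin")
}

# Offsets (index deltas) of lattice cells within `radius` of a cell center.
offset_template <- function(radius, spacing) {
  m <- ceiling(radius / spacing) + 1L
  g <- expand.grid(dx = -m:m, dy = -m:m, dz = -m:m)
  as.matrix(g)
}

# Mark (logical) or increment (integer) lattice cells within `radius` of an
# atom. `ci` is the nearest cell index of the atom.
mark_cells <- function(arr, ci, offsets, atom, lo, spacing, radius, logical_mode) {
  dims <- dim(arr)
  ix <- ci[1] + offsets[, 1]; iy <- ci[2] + offsets[, 2]; iz <- ci[3] + offsets[, 3]
  ok <- ix >= 1 & ix <= dims[1] & iy >= 1 & iy <= dims[2] & iz >= 1 & iz <= dims[3]
  ix <- ix[ok]; iy <- iy[ok]; iz <- iz[ok]
  px <- lo[1] + (ix - 1) * spacing
  py <- lo[2] + (iy - 1) * spacing
  pz <- lo[3] + (iz - 1) * spacing
  d2 <- (px - atom[1])^2 + (py - atom[2])^2 + (pz - atom[3])^2
  hit <- d2 <= radius^2
  if (!any(hit)) return(arr)
  lin <- cbind(ix[hit], iy[hit], iz[hit])
  if (logical_mode) arr[lin] <- TRUE else arr[lin] <- arr[lin] + 1L
  arr
}

# 6-connected flood fill over a logical 3D array; returns component labels.
flood_fill_6 <- function(keep) {
  dims <- dim(keep)
  comp <- array(0L, dims)
  lab <- 0L
  idx_all <- which(keep)
  nxy <- dims[1] * dims[2]
  for (start in idx_all) {
    if (comp[start] != 0L) next
    lab <- lab + 1L
    stack <- start
    comp[start] <- lab
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      z <- (v - 1L) %/% nxy
      rem <- (v - 1L) %% nxy
      y <- rem %/% dims[1]
      x <- rem %% dims[1]
      nb <- integer(0)
      if (x > 0L) nb <- c(nb, v - 1L)
      if (x < dims[1] - 1L) nb <- c(nb, v + 1L)
      if (y > 0L) nb <- c(nb, v - dims[1])
      if (y < dims[2] - 1L) nb <- c(nb, v + dims[1])
      if (z > 0L) nb <- c(nb, v - nxy)
      if (z < dims[3] - 1L) nb <- c(nb, v + nxy)
      nb <- nb[keep[nb] & comp[nb] == 0L]
      comp[nb] <- lab
      stack <- c(stack, nb)
    }
  }
  comp
}

#' Parse an Fpocket output directory
#'
#' Reads the standard Fpocket layout: an `*_info.txt` summary whose
#' per-pocket blocks carry "Druggability Score" and "Total SASA", and
#' `pockets/pocket<N>_atm.pdb` files giving each pocket's atoms. Scores are
#' attached verbatim; nothing is recomputed.
#'
#' @param dir_path an Fpocket `*_out` directory.
#' @param model optional [allo_structure]; pocket residues absent from it
#'   trigger a warning but are kept by key.
#' @return an `allo_pockets` object with `source = "fpocket"`.
#' @export
parse_fpocket_output <- function(dir_path, model = NULL) {
  if (!dir.exists(dir_path)) stop("no such directory: ", dir_path, call. = FALSE)
  info <- list.files(dir_path, pattern = "_info\\.txt$", full.names = TRUE)
  if (length(info) == 0L) {
    stop("missing Fpocket info file (*_info.txt) in ", dir_path, call. = FALSE)
  }
  lines <- readLines(info[1L], warn = FALSE)
  heads <- grep("^Pocket\\s+[0-9]+", lines)
  parse_field <- function(block, field, lineno) {
    hit <- grep(paste0("^\\s*", field, "\\s*:"), block)
    if (length(hit) == 0L) return(NA_real_)
    val <- sub(paste0("^\\s*", field, "\\s*:\\s*"), "", block[hit[1L]])
    num <- suppressWarnings(as.numeric(trimws(val)))
    if (is.na(num)) {
      stop("parse error in ", basename(info[1L]), " at line ",
           lineno + hit[1L] - 1L, ": non-numeric value for '", field, "'",
           call. = FALSE)
    }
    num
  }
  rows <- list(); members <- list()
  for (h in seq_along(heads)) {
    pid <- as.integer(sub("^Pocket\\s+([0-9]+).*", "\\1", lines[heads[h]]))
    end <- if (h < length(heads)) heads[h + 1L] - 1L else length(lines)
    block <- lines[(heads[h] + 1L):end]
    drug <- parse_field(block, "Druggability Score", heads[h] + 1L)
    sasa <- parse_field(block, "Total SASA", heads[h] + 1L)
    atm <- file.path(dir_path, "pockets", sprintf("pocket%d_atm.pdb", pid))
    res <- character(0)
    if (file.exists(atm)) {
      pm <- load_structure(atm, source_id = sprintf("pocket%d", pid))
      res <- unique(pm$atoms$key)
      if (!is.null(model)) {
        absent <- setdiff(res, unique(model$atoms$key))
        if (length(absent)) {
          warning("pocket ", pid, " references residue(s) absent from the model: ",
                  paste(absent, collapse = ", "), call. = FALSE)
        }
      }
    }
    rows[[h]] <- data.frame(pocket_id = pid, source = "fpocket",
                            n_points = NA_integer_, n_residues = length(res),
                            sasa_total = sasa, druggability = drug,
                            stringsAsFactors = FALSE)
    members[[h]] <- res
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pocket_id = integer(), source = character(),
               n_points = integer(), n_residues = integer(),
               sasa_total = numeric(), druggability = numeric(),
               stringsAsFactors = FALSE)
  new_pocket_set(df, members, "fpocket")
}

#' Attach essential-site scores (and optionally SASA) to pockets
#'
#' Fills `essa_median` and `essa_max` with the median/maximum z-score of each
#' pocket's residues and ranks pockets by the chosen aggregate (descending).
#' For built-in pockets a per-residue SASA profile can be supplied to fill
#' `sasa_total` as the sum over member residues; Fpocket SASA values are
#' never overwritten.
#'
#' @param pockets an `allo_pockets`.
#' @param profile an `allo_essa` profile.
#' @param sasa optional `allo_sasa` profile.
#' @param rank_key `"median"` (default) or `"max"`.
#' @return the `allo_pockets` with scores filled and rows ranked.
#' @export
score_pockets <- function(pockets, profile, sasa = NULL,
                          rank_key = c("median", "max")) {
  rank_key <- match.arg(rank_key)
  df <- pockets$table
  med <- rep(NA_real_, nrow(df)); mx <- rep(NA_real_, nrow(df))
  unscored <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    res <- pockets$residues[[i]]
    miss <- setdiff(res, profile$key)
    if (length(miss)) {
      warning("pocket ", df$pocket_id[i], ": ", length(miss),
              " residue(s) missing from the scan profile ignored", call. = FALSE)
    }
    z <- profile$z[match(intersect(res, profile$key), profile$key)]
    if (length(z) == 0L) {
      unscored[i] <- TRUE
      next
    }
    med[i] <- stats::median(z)
    mx[i] <- max(z)
  }
  df$essa_median <- med
  df$essa_max <- mx
  df$unscored <- unscored
  if (!is.null(sasa) && pockets$source == "builtin") {
    df$sasa_total <- vapply(pockets$residues, function(res) {
      sum(sasa$sasa[match(intersect(res, sasa$key), sasa$key)])
    }, numeric(1))
  }
  keyval <- if (rank_key == "median") df$essa_median else df$essa_max
  ord <- order(unscored, -keyval)  # unscored pockets rank last
  pockets$table <- df[ord, , drop = FALSE]
  rownames(pockets$table) <- NULL
  pockets$residues <- pockets$residues[ord]
  pockets$rank_key <- rank_key
  pockets
}

#' Consensus allosteric-site nomination
#'
#' The mutual residue set is `essential` intersected with `hubs`, restricted
#' to residues with SASA at least `sasa_min`. A pocket containing at least
#' one mutual residue is a consensus pocket; consensus pockets are ranked by
#' (mutual-residue count, essential-site aggregate). Pocket pairs sharing at
#' least one residue are reported as back-to-back neighbours.
#'
#' @param pockets a scored `allo_pockets` (see [score_pockets()]).
#' @param essential character vector of essential residue keys.
#' @param hubs character vector of hub residue keys.
#' @param sasa an `allo_sasa` profile over the same model.
#' @param sasa_min per-residue accessibility threshold in Angstrom^2
#'   (default 5).
#' @return an `allo_consensus` list: `mutual` (accessible essential-and-hub
#'   keys), `pockets` (table with `n_mutual` and `consensus` columns, ranked),
#'   `residues`, `back_to_back` (data.frame of pocket-id pairs and shared
#'   residues), `sasa_min`.
#' @export
find_consensus_sites <- function(pockets, essential, hubs, sasa,
                                 sasa_min = 5) {
  mutual <- intersect(essential, hubs)
  acc <- sasa$key[sasa$sasa >= sasa_min]
  mutual <- intersect(mutual, acc)
  df <- pockets$table
  df$n_mutual <- vapply(pockets$residues, function(res)
    length(intersect(res, mutual)), integer(1))
  df$consensus <- df$n_mutual >= 1L
  keyval <- if (identical(pockets$rank_key, "max")) df$essa_max else df$essa_median
  keyval[is.na(keyval)] <- -Inf
  ord <- order(-df$n_mutual, -keyval)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  residues <- pockets$residues[ord]
  b2b <- list()
  if (nrow(df) >= 2L) {
    for (i in seq_len(nrow(df) - 1L)) {
      for (j in seq.int(i + 1L, nrow(df))) {
        shared <- intersect(residues[[i]], residues[[j]])
        if (length(shared)) {
          b2b[[length(b2b) + 1L]] <- data.frame(
            pocket_i = df$pocket_id[i], pocket_j = df$pocket_id[j],
            n_shared = length(shared),
            shared = paste(shared, collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  back_to_back <- if (length(b2b)) do.call(rbind, b2b) else
    data.frame(pocket_i = integer(), pocket_j = integer(),
               n_shared = integer(), shared = character(),
               stringsAsFactors = FALSE)
  structure(list(mutual = sort(mutual), pockets = df, residues = residues,
                 back_to_back = back_to_back, sasa_min = sasa_min),
            class = "allo_consensus")
}

#' Write pocket table and consensus report
#'
#' @param consensus an `allo_consensus`.
#' @param pockets_path TSV output path for the pocket table.
#' @param json_path JSON output path for the consensus report.
#' @return invisibly, `json_path`.
#' @export
write_consensus <- function(consensus, pockets_path, json_path) {
  df <- consensus$pockets
  cols <- c("pocket_id", "source", "n_residues", "essa_median", "essa_max",
            "sasa_total", "druggability", "n_mutual", "consensus")
  write_tsv_det(df[, cols], pockets_path)
  rep <- list(
    mutual_residues = as.list(consensus$mutual),
    sasa_min = consensus$sasa_min,
    consensus_pockets = lapply(which(df$consensus), function(i) list(
      pocket_id = df$pocket_id[i], n_mutual = df$n_mutual[i],
      essa_median = df$essa_median[i], essa_max = df$essa_max[i],
      residues = as.list(consensus$residues[[i]]))),
    back_to_back = lapply(seq_len(nrow(consensus$back_to_back)), function(i)
      as.list(consensus$back_to_back[i, ])))
  jsonlite::write_json(sort_keys(rep), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(json_path)
}
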