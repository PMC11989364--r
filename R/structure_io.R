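#' @title Curated heavy-atom structure models
#' @description
#' An `allo_structure` is a light container around a per-atom data frame (one
#' row per atom, bio3d-style columns) plus bookkeeping: `source_id`, the index
#' of the PDB MODEL that was read, and a `curation_log` recording every
#' curation step applied. It is the common input of the elastic-network,
#' interaction-network, SASA and pocket stages.
#'
#' Atom columns: `type` (ATOM/HETATM), `elety` (atom name), `element`,
#' `chain`, `resno`, `icode`, `resid` (3-letter residue name), `x`, `y`, `z`,
#' `occupancy`, `is_backbone`, `is_hydrogen`, `key` (see [residue_key()]).
#' @name allo_structure
NULL

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")
WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

new_structure <- function(atoms, source_id, model_index, curation_log = character()) {
  structure(list(atoms = atoms, source_id = source_id,
                 model_index = model_index, curation_log = curation_log),
            class = "allo_structure")
}

#' @export
print.allo_structure <- function(x, ...) {
  rt <- residue_table(x, strict = FALSE)
  cat(sprintf("<allo_structure> %s (MODEL %d): %d chains, %d residues, %d atoms\n",
              x$source_id, x$model_index,
              length(unique(x$atoms$chain)), nrow(rt), nrow(x$atoms)))
  if (length(x$curation_log))
    cat(paste0("  curation: ", x$curation_log, collapse = "\n"), "\n")
  invisible(x)
}

# Extract the lines of one MODEL block (1-based index); files without MODEL
# records count as a single model.
select_model_lines <- function(lines, model_index) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {
    if (model_index != 1L) stop("file has a single model; model_index = ",
                                model_index, " is out of range", call. = FALSE)
    return(lines)
  }
  if (model_index < 1L || model_index > length(starts)) {
    stop("model_index = ", model_index, " out of range (file has ",
         length(starts), " MODEL records)", call. = FALSE)
  }
  ends <- grep("^ENDMDL", lines)
  beg <- starts[model_index]
  fin <- ends[ends > beg]
  fin <- if (length(fin)) fin[1L] else length(lines)
  lines[(beg + 1L):(fin - 1L)]
}

# Derive the element symbol from a PDB atom name when columns 77-78 are blank.
element_from_name <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("FE", "MG", "MN", "ZN", "CA", "NA", "CL", "BR", "SE", "CU", "NI", "CO"),
         two, toupper(substr(nm, 1, 1)))
}

#' Load one model of a PDB file
#'
#' Reads a PDB file (via bio3d), selects one MODEL of a multi-model file, and
#' resolves alternate locations keeping the highest-occupancy copy of each
#' atom (ties broken by first occurrence in the file). No curation is applied;
#' waters and hetero residues are retained until [curate()].
#'
#' @param path path to a PDB file.
#' @param model_index 1-based MODEL selector (default first model).
#' @param source_id identifier stored on the model; defaults to the file stem.
#' @return an [allo_structure] object.
#' @export
load_structure <- function(path, model_index = 1L, source_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (length(rec) == 0L) {
    stop("parse error in ", path, ": no ATOM/HETATM records found", call. = FALSE)
  }
  short <- rec[nchar(lines[rec]) < 54L]
  if (length(short)) {
    stop("parse error in ", path, " at line ", short[1L],
         ": ATOM/HETATM record too short for coordinates", call. = FALSE)
  }
  model_lines <- select_model_lines(lines, as.integer(model_index))
  if (!any(grepl("^(ATOM  |HETATM)", model_lines))) {
    stop("selected MODEL ", model_index, " of ", path, " contains no atoms",
         call. = FALSE)
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(c(model_lines, "END"), tmp)
  pdb <- bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE, verbose = FALSE,
                         hex = TRUE)
  a <- pdb$atom
  chain <- ifelse(is.na(a$chain), "", a$chain)
  icode <- ifelse(is.na(a$insert), "", a$insert)
  alt <- ifelse(is.na(a$alt), "", a$alt)
  occ <- ifelse(is.na(a$o), 1, a$o)
  element <- ifelse(is.na(a$elesy) | a$elesy == "",
                    element_from_name(a$elety), toupper(a$elesy))
  atoms <- data.frame(
    type = a$type, elety = a$elety, element = element,
    chain = chain, resno = a$resno, icode = icode, resid = a$resid,
    x = a$x, y = a$y, z = a$z, occupancy = occ, altloc = alt,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x + atoms$y + atoms$z))) {
    stop("parse error in ", path, ": non-finite coordinates", call. = FALSE)
  }
  # altloc resolution: group atoms that differ only by altloc code
  gid <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$resid, atoms$elety,
               sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), factor(gid, levels = unique(gid))),
                        function(idx) {
                          if (length(idx) == 1L) return(idx)
                          idx[which.max(atoms$occupancy[idx])]
                        }), use.names = FALSE)
  atoms <- atoms[sort(keep), , drop = FALSE]
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  atoms$is_backbone <- atoms$type == "ATOM" & atoms$elety %in% BACKBONE_NAMES
  atoms$key <- residue_key(atoms$chain, atoms$resno, atoms$icode)
  rownames(atoms) <- NULL
  if (is.null(source_id)) source_id <- tools::file_path_sans_ext(basename(path))
  new_structure(atoms, source_id, as.integer(model_index))
}

#' Curate a structure for network analysis
#'
#' Restricts to selected chains, strips waters and (by default) all other
#' hetero residues, and drops any residue lacking a C-alpha atom (network
#' nodes are placed at C-alpha positions). Every step is appended to the
#' model's curation log. Hetero retention (`drop_hetero = FALSE`) keeps
#' ligands/ions as extra residues.
#'
#' @param model an [allo_structure].
#' @param keep_chains character vector of chain ids, or `NULL` for all chains.
#' @param drop_waters remove water residues (HOH/WAT/DOD)? Default `TRUE`.
#' @param drop_hetero remove non-water HETATM residues? Default `TRUE`.
#' @return a curated [allo_structure].
#' @export
curate <- function(model, keep_chains = NULL, drop_waters = TRUE,
                   drop_hetero = TRUE) {
  stopifnot(inherits(model, "allo_structure"))
  atoms <- model$atoms
  log <- model$curation_log
  if (!is.null(keep_chains)) {
    missing <- setdiff(keep_chains, unique(atoms$chain))
    if (length(missing)) {
      stop("chain(s) not in structure: ", paste(missing, collapse = ", "),
           "; available: ", paste(sort(unique(atoms$chain)), collapse = ", "),
           call. = FALSE)
    }
    atoms <- atoms[atoms$chain %in% keep_chains, , drop = FALSE]
    log <- c(log, paste0("kept chains: ", paste(sort(keep_chains), collapse = ",")))
  }
  if (drop_waters) {
    is_w <- atoms$resid %in% WATER_NAMES
    if (any(is_w)) log <- c(log, sprintf("removed %d water atoms", sum(is_w)))
    else log <- c(log, "removed 0 water atoms")
    atoms <- atoms[!is_w, , drop = FALSE]
  }
  if (drop_hetero) {
    is_h <- atoms$type == "HETATM" & !(atoms$resid %in% WATER_NAMES)
    if (any(is_h)) log <- c(log, sprintf("removed %d hetero atoms", sum(is_h)))
    else log <- c(log, "removed 0 hetero atoms")
    atoms <- atoms[!is_h, , drop = FALSE]
  }
  # polymer residues retained for network analysis need a C-alpha
  has_ca <- atoms$key %in% atoms$key[atoms$elety == "CA" & !atoms$is_hydrogen]
  drop_res <- unique(atoms$key[atoms$type == "ATOM" & !has_ca])
  if (length(drop_res)) {
    warning("dropping ", length(drop_res), " residue(s) without C-alpha: ",
            paste(utils::head(drop_res, 5L), collapse = ", "), call. = FALSE)
    log <- c(log, sprintf("dropped %d residue(s) without C-alpha", length(drop_res)))
    atoms <- atoms[!(atoms$key %in% drop_res), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  out <- new_structure(atoms, model$source_id, model$model_index, log)
  out
}

# Canonical residue ordering: chain order as encountered in the file, then
# author residue number, then insertion code.
residue_order <- function(atoms) {
  first <- !duplicated(atoms$key)
  df <- atoms[first, c("key", "chain", "resno", "icode", "resid"), drop = FALSE]
  chain_rank <- match(df$chain, unique(atoms$chain))
  df[order(chain_rank, df$resno, df$icode), , drop = FALSE]
}

#' Per-residue heavy-atom table
#'
#' Deterministically ordered residue inventory of a (curated) model: chain
#' order as in the file, then residue number, then insertion code. Heavy-atom
#' counts (`n_heavy`) exclude hydrogens; `n_sidechain_heavy` additionally
#' excludes backbone atoms, so glycine scores 0.
#'
#' @param model an [allo_structure].
#' @param strict error if the model is empty (default `TRUE`).
#' @return data.frame with columns `key`, `chain`, `resno`, `icode`, `resname`,
#'   `n_heavy`, `n_sidechain_heavy`.
#' @export
residue_table <- function(model, strict = TRUE) {
  stopifnot(inherits(model, "allo_structure"))
  atoms <- model$atoms
  if (nrow(atoms) == 0L) {
    if (strict) stop("empty model", call. = FALSE)
    return(data.frame(key = character(), chain = character(), resno = integer(),
                      icode = character(), resname = character(),
                      n_heavy = integer(), n_sidechain_heavy = integer(),
                      stringsAsFactors = FALSE))
  }
  ord <- residue_order(atoms)
  heavy <- !atoms$is_hydrogen
  sc <- heavy & !atoms$is_backbone
  n_heavy <- vapply(ord$key, function(k) sum(heavy & atoms$key == k), integer(1))
  n_sc <- vapply(ord$key, function(k) sum(sc & atoms$key == k), integer(1))
  out <- data.frame(key = ord$key, chain = ord$chain, resno = ord$resno,
                    icode = ord$icode, resname = ord$resid,
                    n_heavy = unname(n_heavy), n_sidechain_heavy = unname(n_sc),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Heavy-atom coordinate matrix for one residue key.
residue_heavy_coords <- function(model, key) {
  a <- model$atoms
  sel <- a$key == key & !a$is_hydrogen
  as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
}

# Side-chain heavy-atom coordinates for one residue key.
residue_sidechain_coords <- function(model, key) {
  a <- model$atoms
  sel <- a$key == key & !a$is_hydrogen & !a$is_backbone
  as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
}

#' Write the residue table as TSV
#'
#' @param model an [allo_structure].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_residue_table <- function(model, path) {
  rt <- residue_table(model)
  write_tsv_det(rt[, c("chain", "resno", "icode", "resname",
                       "n_heavy", "n_sidechain_heavy")], path)
}
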