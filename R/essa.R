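#' @title Essential-site scanning by eigenvalue perturbation
#' @description
#' Each residue is perturbed in turn by inserting extra network nodes at its
#' side-chain heavy atoms, mimicking the local crowding of a bound ligand.
#' The response is measured as the percent shift of each of the ten slowest
#' nonzero eigenvalues relative to the unperturbed network,
#' \deqn{\Delta\lambda_k(i)\% = 100\,(\lambda_k(i) - \lambda_k)/\lambda_k,}
#' averaged over the ten modes, and z-scored across residues. Residues in the
#' top quartile of z are flagged essential; they tend to sit at global hinges
#' and at orthosteric/allosteric sites.
#' @name essa
NULL

#' Insert side-chain nodes for one residue
#'
#' Returns the reference node set augmented with one node per side-chain
#' heavy atom of the target residue. The core nodes are unchanged; inserted
#' nodes get synthetic labels. A residue without side-chain heavy atoms
#' (glycine) yields the input unchanged with attribute `skipped = TRUE`.
#'
#' @param nodes reference `allo_nodes` (from [build_nodes()]).
#' @param model the curated [allo_structure] the nodes came from.
#' @param target residue key to perturb.
#' @return augmented `allo_nodes`.
#' @export
perturb_residue <- function(nodes, model, target) {
  stopifnot(inherits(nodes, "allo_nodes"))
  if (!target %in% nodes$labels) {
    stop("unknown target residue: ", target, call. = FALSE)
  }
  sc <- residue_sidechain_coords(model, target)
  if (nrow(sc) == 0L) {
    attr(nodes, "skipped") <- TRUE
    return(nodes)
  }
  out <- structure(list(
    coords = rbind(nodes$coords, sc),
    labels = c(nodes$labels, paste0(target, "@sc", seq_len(nrow(sc)))),
    n_core = nodes$n_core), class = "allo_nodes")
  attr(out, "skipped") <- FALSE
  out
}

#' Percent eigenvalue shifts between reference and perturbed spectra
#'
#' Rank-paired percent shifts of nonzero eigenvalues:
#' `100 * (lambda_pert - lambda_ref) / lambda_ref` per mode.
#'
#' @param lambda_ref reference nonzero eigenvalues (ascending).
#' @param lambda_pert perturbed nonzero eigenvalues (ascending, same length).
#' @return numeric vector of percent shifts, one per mode.
#' @export
eigenvalue_shift <- function(lambda_ref, lambda_pert) {
  if (length(lambda_ref) != length(lambda_pert)) {
    stop("reference and perturbed eigenvalue lists differ in length",
         call. = FALSE)
  }
  if (any(lambda_ref <= 0) || any(lambda_pert <= 0)) {
    stop("nonpositive eigenvalue passed; zero modes must be excluded",
         call. = FALSE)
  }
  100 * (lambda_pert - lambda_ref) / lambda_ref
}

#' Scan every residue for essentiality
#'
#' For each residue of the model: insert its side-chain heavy-atom nodes,
#' recompute the slow spectrum at the same cutoff, and record the mean
#' percent shift over the `n_modes` slowest nonzero eigenvalues. Mean shifts
#' are z-scored with the population mean/SD over non-skipped residues;
#' residues without side-chain heavy atoms are flagged `skipped`, assigned a
#' mean shift of 0 before z-scoring, and can never be essential.
#'
#' @param model a curated [allo_structure].
#' @param cutoff spring cutoff in Angstrom (default 10).
#' @param n_modes number of slow modes averaged (default 10).
#' @param quantile essentiality quantile for [select_essential()]
#'   (default 0.75, i.e. the top 25%).
#' @return an `allo_essa` data.frame (one row per residue: `key`, `chain`,
#'   `resno`, `icode`, `resname`, `mean_shift_pct`, `z`, `essential`,
#'   `skipped`) with scan metadata in attributes.
#' @export
essa_scan <- function(model, cutoff = 10, n_modes = 10L, quantile = 0.75) {
  rt <- residue_table(model)
  nodes <- build_nodes(model)
  K0 <- build_kirchhoff(nodes, cutoff)
  ref <- slow_eigenvalues(compute_modes(K0, n_modes = n_modes))
  n <- nrow(rt)
  mean_shift <- numeric(n)
  skipped <- logical(n)
  for (i in seq_len(n)) {
    pn <- perturb_residue(nodes, model, rt$key[i])
    if (isTRUE(attr(pn, "skipped"))) {
      skipped[i] <- TRUE
      mean_shift[i] <- 0
      next
    }
    Kp <- build_kirchhoff(pn, cutoff)
    pert <- slow_eigenvalues(compute_modes(Kp, n_modes = n_modes))
    mean_shift[i] <- mean(eigenvalue_shift(ref, pert))
  }
  if (all(skipped)) {
    stop("no perturbable residues: every residue lacks side-chain heavy atoms",
         call. = FALSE)
  }
  mu <- mean(mean_shift[!skipped])
  sigma <- pop_sd(mean_shift[!skipped])
  if (sigma == 0) {
    warning("all mean shifts identical; z-scores set to 0", call. = FALSE)
    z <- rep(0, n)
  } else {
    z <- (mean_shift - mu) / sigma
  }
  out <- data.frame(key = rt$key, chain = rt$chain, resno = rt$resno,
                    icode = rt$icode, resname = rt$resname,
                    mean_shift_pct = mean_shift, z = z,
                    essential = FALSE, skipped = skipped,
                    stringsAsFactors = FALSE)
  out$essential <- out$key %in% select_essential(out, quantile)
  attr(out, "meta") <- list(cutoff = cutoff, n_modes = as.integer(n_modes),
                            quantile = quantile, mu = mu, sigma = sigma)
  class(out) <- c("allo_essa", "data.frame")
  out
}

#' Select essential residues from a scan profile
#'
#' Residues whose z-score reaches the `quantile`-th percentile (linear
#' interpolation) of z over non-skipped residues; ties at the threshold are
#' included. Skipped residues are never selected.
#'
#' @param profile an `allo_essa` profile (or data.frame with `key`, `z`,
#'   `skipped`).
#' @param quantile fraction in (0, 1); default 0.75.
#' @return character vector of essential residue keys.
#' @export
select_essential <- function(profile, quantile = 0.75) {
  ok <- !profile$skipped
  sel <- select_top_quantile(profile$z[ok], quantile)
  profile$key[ok][sel]
}

#' Write an essential-site profile as TSV (+ optional JSON metadata)
#'
#' @param profile an `allo_essa` profile.
#' @param path output TSV path.
#' @param json_path optional path for the scan metadata JSON.
#' @return invisibly, `path`.
#' @export
write_essa_tsv <- function(profile, path, json_path = NULL) {
  df <- as.data.frame(profile)[, c("chain", "resno", "icode", "resname",
                                   "mean_shift_pct", "z", "essential", "skipped")]
  write_tsv_det(df, path)
  if (!is.null(json_path)) {
    meta <- attr(profile, "meta")
    jsonlite::write_json(sort_keys(meta), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
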