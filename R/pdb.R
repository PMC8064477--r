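## Pseudo-atom PDB I/O for array models.
##
## One atom per component site.  Column conventions (the coarse-grained
## dialect used throughout):
##   * residue name encodes the site kind (table below);
##   * residue number is the CSU id (chain IDs cycle A-Z, a-z, 0-9);
##   * occupancy carries the ToD id (0/1), B-factor the CheA monomer;
##   * atom serial is the site id; coordinates are Angstrom.
## Half-site bearings and binding-slot annotations cannot be stored in
## PDB columns; they travel in a JSON sidecar (<path>.json) which also
## holds the CSU registry and lattice vectors, giving a lossless
## round-trip.

PDB_KIND_CODES <- c(MCP_DIMER = "MCP", CHEA_P5 = "AP5", CHEA_P4 = "AP4",
                    CHEA_P3 = "AP3", CHEA_LINKER_ANCHOR = "ALN",
                    CHEA_ATP_SITE = "ATP", CHEW_CORE = "CWC",
                    CHEW_FLANK = "CWF")

chain_for_csu <- function(csu_id) {
  pool <- c(LETTERS, letters, as.character(0:9))
  pool[(csu_id - 1L) %% length(pool) + 1L]
}

#' Write an array model as pseudo-atom PDB with JSON sidecar
#'
#' @param model an \code{array_model}.
#' @param path output PDB path; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_model_pdb <- function(model, path, sidecar = TRUE) {
  stopifnot(inherits(model, "array_model"))
  s <- model$sites
  n <- nrow(s)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(cbind(s$x, s$y, s$z))),
                   type = rep("ATOM", n),
                   eleno = s$site_id,
                   elety = rep("CA", n),
                   resid = unname(PDB_KIND_CODES[s$kind]),
                   chain = chain_for_csu(s$csu_id),
                   resno = s$csu_id,
                   o = s$tod_id,
                   b = s$monomer)
  if (sidecar) {
    side <- list(format = "chemoarray-model", version = 1L,
                 symmetry = model$symmetry, a = model$a,
                 baseplate_z = model$baseplate_z,
                 lattice_vectors = model$lattice_vectors,
                 surface = model$surface,
                 registry = model$registry,
                 sites = model$sites)
    jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                         auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' Read an array model written by \code{\link{write_model_pdb}}
#'
#' When the JSON sidecar is present the full model (bearings, slots,
#' registry) is restored and cross-checked against the PDB atoms; without
#' it, a reduced model (kinds, ownership, positions) is reconstructed
#' from the PDB columns alone.
#'
#' @param path PDB path.
#' @return an \code{array_model}.
#' @export
read_model_pdb <- function(path) {
  if (!file.exists(path)) stop_param("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("PDB parse error in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  bad <- which(!at$resid %in% PDB_KIND_CODES)
  if (length(bad))
    stop("PDB parse error: unknown residue code '", at$resid[bad[1]],
         "' at atom record ", bad[1], call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    sites <- as.data.frame(side$sites)
    ## canonical column order and types (JSON round-trip loses both)
    cols <- c("site_id", "kind", "monomer", "csu_id", "tod_id",
              "x", "y", "z", "u", "v", "angle",
              "b1x", "b1y", "b1z", "b2x", "b2y", "b2z",
              "slot_x", "slot_y", "slot_z", "ring_x", "ring_y")
    missing_cols <- setdiff(cols, names(sites))
    for (mc in missing_cols) sites[[mc]] <- NA_real_
    sites <- sites[cols]
    for (ic in c("site_id", "monomer", "csu_id", "tod_id"))
      sites[[ic]] <- as.integer(sites[[ic]])
    for (nc in setdiff(cols, c("site_id", "kind", "monomer", "csu_id",
                               "tod_id")))
      sites[[nc]] <- as.numeric(sites[[nc]])
    if (nrow(sites) != nrow(at))
      stop("sidecar/PDB mismatch: ", nrow(sites), " sites vs ",
           nrow(at), " atoms", call. = FALSE)
    surface <- side$surface
    if (!is.null(surface)) surface <- list(centre = surface$centre,
                                           radius = surface$radius)
    return(structure(list(sites = sites,
                          registry = as.data.frame(side$registry),
                          lattice_vectors = matrix(unlist(side$lattice_vectors),
                                                   2, 2),
                          symmetry = side$symmetry, a = side$a,
                          baseplate_z = side$baseplate_z,
                          surface = surface),
                     class = "array_model"))
  }
  kind <- names(PDB_KIND_CODES)[match(at$resid, PDB_KIND_CODES)]
  sites <- data.frame(site_id = at$eleno, kind = kind,
                      monomer = as.integer(at$b), csu_id = at$resno,
                      tod_id = as.integer(at$o),
                      x = at$x, y = at$y, z = at$z,
                      u = at$x, v = at$y,
                      angle = NA_real_, b1x = NA_real_, b1y = NA_real_,
                      b1z = NA_real_, b2x = NA_real_, b2y = NA_real_,
                      b2z = NA_real_, slot_x = NA_real_,
                      slot_y = NA_real_, slot_z = NA_real_,
                      ring_x = NA_real_, ring_y = NA_real_)
  structure(list(sites = sites,
                 registry = data.frame(csu_id = sort(unique(sites$csu_id))),
                 lattice_vectors = NULL, symmetry = NA_character_,
                 a = NA_real_, baseplate_z = -min(sites$z),
                 surface = NULL),
            class = "array_model")
}
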